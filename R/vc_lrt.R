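#' @name vc_model
#' @title Variance-component model for pathway screening
#'
#' @description
#' The phenotypic covariance is modelled as
#' \deqn{\Omega = \sigma^2_{Total}\,(2\Phi\,h^2_r + 2E\,h^2_{gp} + I\,e^2)}
#' with fixed effects `X beta` in the mean, where `Phi` is the expected
#' pedigree kinship, `E` the empirical pathway-specific kinship (PSGRM) and
#' `I` the identity; `h2r + h2gp + e2 = 1`. Both models are fitted by
#' maximum likelihood under multivariate normality with `beta` and
#' `sigma^2` profiled out analytically (GLS) at each variance-fraction
#' value. The pathway effect is tested with a likelihood-ratio test of
#' `h2gp = 0`; because the parameter sits on its boundary the null
#' reference is a 50:50 mixture of a point mass at zero and chi-square with
#' 1 df.
#'
#' Internally the two-kernel model is reparameterized as
#' `Omega/sigma^2 = h K(gamma) + (1 - h) I` with
#' `K(gamma) = (1 - gamma) 2Phi + gamma 2E`, `h2r = h (1 - gamma)`,
#' `h2gp = h gamma`. For each mixing value `gamma` one symmetric
#' eigendecomposition of `K(gamma)` makes every profiled-likelihood
#' evaluation in `h` O(n); the fit is a global grid search over `gamma`
#' with an exact inner line search, optionally polished by a continuous
#' Brent search over `gamma`. The eigendecompositions depend only on the
#' kernels, so they can be cached and reused across phenotype replicates.
NULL

# ---- profiled likelihood on a diagonalized kernel -------------------------

# w: eigenvalue weights of Omega/sigma2; Xr, yr: rotated design/response.
# Returns the profiled ML log-likelihood and GLS estimates.
profile_loglik <- function(w, Xr, yr, reml = FALSE) {
  n <- length(yr)
  p <- ncol(Xr)
  iw <- 1 / w
  XtWX <- crossprod(Xr, Xr * iw)
  XtWy <- crossprod(Xr, yr * iw)
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(beta)) return(list(loglik = -Inf, beta = NULL, sigma2 = NA))
  r <- yr - Xr %*% beta
  q <- sum(r * r * iw)
  if (reml) {
    sigma2 <- q / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma2) + sum(log(w)) +
                    determinant(XtWX, logarithm = TRUE)$modulus[1] + (n - p))
  } else {
    sigma2 <- q / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + sum(log(w)) + n)
  }
  list(loglik = as.numeric(ll), beta = beta[, 1], sigma2 = sigma2)
}

# Maximize over total genetic fraction h in [0, 1) for fixed spectrum d.
# Evaluates the h = 0 boundary explicitly so boundary solutions are exact.
fit_h_spectrum <- function(d, Xr, yr, reml = FALSE, tol = 1e-8) {
  f <- function(h) profile_loglik(h * d + (1 - h), Xr, yr, reml)$loglik
  hi <- 1 - 1e-9
  opt <- stats::optimize(f, c(0, hi), maximum = TRUE, tol = tol)
  cand_h <- c(0, opt$maximum, hi)
  cand_ll <- c(f(0), opt$objective, f(hi))
  best <- which.max(cand_ll)
  h <- cand_h[best]
  fit <- profile_loglik(h * d + (1 - h), Xr, yr, reml)
  list(h = h, loglik = fit$loglik, beta = fit$beta, sigma2 = fit$sigma2)
}

# ---- design construction --------------------------------------------------

#' Read a phenotype/covariate table
#'
#' Tab-delimited with header; requires columns `IID` and `TRAIT`, typically
#' plus `SEX`, `AGE`, `SMOKE` and optional `PC1..PCk`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# Listwise-complete design matrix. Returns y, X (with intercept), ids.
build_design <- function(pheno, covariates) {
  stopifnot(all(c("IID", "TRAIT") %in% names(pheno)))
  missing_cov <- setdiff(covariates, names(pheno))
  if (length(missing_cov)) {
    stop("covariate column(s) absent from phenotype table: ",
         paste(missing_cov, collapse = ", "))
  }
  cols <- pheno[, c("TRAIT", covariates), drop = FALSE]
  keep <- stats::complete.cases(cols)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("build_design: dropping ", n_drop,
            " individual(s) with missing trait/covariates")
  }
  pheno <- pheno[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(pheno[, covariates, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  list(y = pheno$TRAIT, X = X, ids = as.character(pheno$IID))
}

# ---- fitted-model container ----------------------------------------------

vc_fit <- function(loglik, sigma2, h2r, h2gp, beta, n, iterations,
                   converged = TRUE, tol = 1e-6) {
  structure(list(
    loglik = loglik, sigma2_total = sigma2,
    h2r = h2r, h2gp = h2gp, e2 = 1 - h2r - h2gp,
    beta = beta, n = n, iterations = iterations, converged = converged,
    boundary = c(h2r = h2r <= tol, h2gp = h2gp <= tol,
                 e2 = (1 - h2r - h2gp) <= tol)),
    class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("vc_fit: logLik =", format(x$loglik, digits = 8),
      " sigma2 =", signif(x$sigma2_total, 4), "\n",
      " h2r =", signif(x$h2r, 4), " h2gp =", signif(x$h2gp, 4),
      " e2 =", signif(x$e2, 4),
      if (any(x$boundary)) paste0(" [boundary: ",
        paste(names(x$boundary)[x$boundary], collapse = ","), "]"), "\n")
  invisible(x)
}

# ---- null (polygenic) model ----------------------------------------------

#' Fit the null polygenic model
#'
#' Maximizes the MVN likelihood with covariance
#' `sigma^2 (2 Phi h2r + I e2)` over `h2r` in \[0, 1\], with fixed effects
#' profiled out by GLS. One symmetric eigendecomposition of `2 Phi` makes
#' each likelihood evaluation O(n).
#'
#' @param pheno Phenotype data.frame (see [read_phenotypes()]).
#' @param phi Theoretical [kinship_matrix] covering all phenotyped ids.
#' @param covariates Character vector of covariate column names entered as
#'   fixed effects (same set in null and alternative models).
#' @param reml Use REML instead of ML (LRTs should always use ML fits).
#' @param spectrum Optional precomputed `list(U, d)` eigendecomposition of
#'   the aligned kernel `2 Phi` (as produced internally); used to reuse
#'   work across phenotype replicates.
#' @return A `vc_fit` with `h2gp = 0`.
#' @export
fit_null <- function(pheno, phi, covariates = c("SEX", "AGE", "SMOKE"),
                     reml = FALSE, spectrum = NULL) {
  d <- build_design(pheno, covariates)
  if (is.null(spectrum)) {
    K <- 2 * align_kinship(phi, d$ids)$phi
    check_psd_kernel(K, "2*Phi")
    eg <- eigen(K, symmetric = TRUE)
    spectrum <- list(U = eg$vectors, d = pmax(eg$values, 0))
  }
  Xr <- crossprod(spectrum$U, d$X)
  yr <- drop(crossprod(spectrum$U, d$y))
  fit <- fit_h_spectrum(spectrum$d, Xr, yr, reml = reml)
  vc_fit(fit$loglik, fit$sigma2, h2r = fit$h, h2gp = 0,
         beta = stats::setNames(fit$beta, colnames(d$X)),
         n = length(yr), iterations = 1L)
}

check_psd_kernel <- function(K, label) {
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6 * max(1, max(abs(K)))) {
    stop(label, " is not positive semidefinite (min eigenvalue ",
         signif(ev_min, 3), "); run make_kernel() first")
  }
  invisible(TRUE)
}

# ---- two-kernel (pathway) model ------------------------------------------

#' Precompute mixing-grid eigendecompositions for the two-kernel fit
#'
#' The expensive part of [fit_pathway()] is one eigendecomposition of
#' `K(gamma)` per mixing value. When many phenotype replicates are fitted
#' against the same pair of kernels (simulation studies, calibration runs),
#' compute this once and pass it to [fit_pathway()].
#'
#' @param A Null kernel `2 Phi` (aligned matrix).
#' @param B Pathway kernel `2 E` (aligned matrix, PSD).
#' @param X Fixed-effect design matrix (with intercept), aligned.
#' @param gammas Mixing grid in \[0, 1\]; must include 0.
#' @return A cache object for [fit_pathway()].
#' @export
two_kernel_cache <- function(A, B, X, gammas = seq(0, 1, length.out = 21)) {
  stopifnot(identical(dim(A), dim(B)), nrow(A) == nrow(X))
  if (min(gammas) > 0) gammas <- c(0, gammas)
  layers <- lapply(gammas, function(g) {
    eg <- eigen((1 - g) * A + g * B, symmetric = TRUE)
    list(gamma = g, U = eg$vectors, d = pmax(eg$values, 0),
         Xr = crossprod(eg$vectors, X))
  })
  structure(list(layers = layers, gammas = gammas, A = A, B = B, X = X),
            class = "two_kernel_cache")
}

#' Fit the alternative (pathway) variance-component model
#'
#' Maximizes the MVN likelihood with covariance
#' `sigma^2 (2 Phi h2r + 2 E h2gp + I e2)` over the simplex
#' `h2r, h2gp >= 0`, `h2r + h2gp <= 1`, using the kernel-mixing
#' reparameterization described in [vc_model]. The mixing grid always
#' contains `gamma = 0`, where the model reduces exactly to the null fit,
#' so `loglik_alt >= loglik_null` holds by construction.
#'
#' @inheritParams fit_null
#' @param e_kernel PSD pathway kernel `2E` (matrix from [make_kernel()]),
#'   with ids as dimnames.
#' @param gammas Mixing grid (see [two_kernel_cache()]).
#' @param cache Optional [two_kernel_cache()] built for the aligned
#'   kernels/design; overrides `phi`, `e_kernel` and `gammas`.
#' @param refine If TRUE (default), polish the grid solution with a
#'   continuous Brent search over `gamma` in the bracketing interval (one
#'   eigendecomposition per evaluation).
#' @return A `vc_fit`.
#' @export
fit_pathway <- function(pheno, phi, e_kernel,
                        covariates = c("SEX", "AGE", "SMOKE"),
                        gammas = seq(0, 1, length.out = 21),
                        cache = NULL, refine = TRUE, reml = FALSE) {
  d <- build_design(pheno, covariates)
  if (is.null(cache)) {
    A <- 2 * align_kinship(phi, d$ids)$phi
    ids_e <- rownames(e_kernel)
    if (is.null(ids_e) || !all(d$ids %in% ids_e)) {
      stop("pathway kernel lacks some phenotyped sample ids")
    }
    B <- e_kernel[d$ids, d$ids]
    check_psd_kernel(A, "2*Phi")
    check_psd_kernel(B, "pathway kernel")
    cache <- two_kernel_cache(A, B, d$X, gammas)
  }
  fit_pathway_cached(d$y, cache, refine = refine, reml = reml,
                     beta_names = colnames(d$X))
}

#' Fit the two-kernel model against a precomputed cache
#'
#' Low-level workhorse behind [fit_pathway()], exposed for replicate
#' studies: `y` must be aligned with the rows of the design matrix the
#' cache was built with, and no listwise filtering is applied.
#'
#' @param y Numeric response vector.
#' @param cache A [two_kernel_cache()].
#' @param refine Continuous Brent polish over the mixing parameter.
#' @param reml Use REML (LRTs should use ML).
#' @param beta_names Optional names for the fixed-effect estimates.
#' @return A `vc_fit`.
#' @export
fit_pathway_cached <- function(y, cache, refine = TRUE, reml = FALSE,
                               beta_names = NULL) {
  evals <- 0L
  per_layer <- lapply(cache$layers, function(L) {
    yr <- drop(crossprod(L$U, y))
    f <- fit_h_spectrum(L$d, L$Xr, yr, reml = reml)
    evals <<- evals + 1L
    c(list(gamma = L$gamma), f)
  })
  lls <- vapply(per_layer, `[[`, numeric(1), "loglik")
  best <- which.max(lls)
  sol <- per_layer[[best]]

  if (refine && length(cache$gammas) > 1) {
    gs <- cache$gammas
    lo <- gs[max(1, best - 1)]
    hi <- gs[min(length(gs), best + 1)]
    if (hi > lo) {
      fg <- function(g) {
        eg <- eigen((1 - g) * cache$A + g * cache$B, symmetric = TRUE)
        Xr <- crossprod(eg$vectors, cache$X)
        yr <- drop(crossprod(eg$vectors, y))
        evals <<- evals + 1L
        fit <- fit_h_spectrum(pmax(eg$values, 0), Xr, yr, reml = reml)
        fit$gamma <- g
        fit
      }
      opt <- stats::optimize(function(g) fg(g)$loglik, c(lo, hi),
                             maximum = TRUE, tol = 1e-4)
      if (opt$objective > sol$loglik) sol <- fg(opt$maximum)
    }
  }
  gamma <- if (is.null(sol$gamma)) cache$gammas[best] else sol$gamma
  beta <- sol$beta
  if (!is.null(beta_names)) names(beta) <- beta_names
  vc_fit(sol$loglik, sol$sigma2,
         h2r = sol$h * (1 - gamma), h2gp = sol$h * gamma,
         beta = beta, n = length(y), iterations = evals)
}

# ---- boundary LRT ---------------------------------------------------------

#' Boundary likelihood-ratio test with 50:50 mixture reference
#'
#' `T = max(0, 2 (loglik_alt - loglik_null))`; because `h2gp` is tested on
#' the boundary of its parameter space, T is referred to a 50:50 mixture of
#' a point mass at zero and chi-square(1): `p = 0.5 * P(chi2_1 >= T)` for
#' `T > 0` and `p = 1` at `T = 0` (conservative convention keeping
#' p in (0, 1\]).
#'
#' @param loglik_null,loglik_alt Log-likelihoods of the nested ML fits.
#' @param tol Tolerance for small negative T due to numerical noise
#'   (beyond it, the alternative fit is declared inconsistent).
#' @return list with `statistic` and `p`.
#' @examples
#' lrt_mixture_p(-100, -100 + 3.841459 / 2)$p  # 0.025
#' @export
lrt_mixture_p <- function(loglik_null, loglik_alt, tol = 1e-6) {
  if (!is.finite(loglik_null) || !is.finite(loglik_alt)) {
    stop("non-finite log-likelihood in LRT")
  }
  t_raw <- 2 * (loglik_alt - loglik_null)
  if (t_raw < -tol) {
    stop("alternative log-likelihood below null by ", -t_raw,
         "; refit the alternative model (nested models)")
  }
  statistic <- max(0, t_raw)
  p <- if (statistic <= tol) 1
       else 0.5 * stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  list(statistic = statistic, p = p)
}

# ---- screen orchestration -------------------------------------------------

#' Screen gene pathways with the PSGRM variance-component test
#'
#' Full pipeline: for every pathway in a GMT file, map genes to flanked
#' windows, extract VCF genotypes, optionally filter by MAF, estimate the
#' PSGRM with the robust pairwise estimator, repair it to a PSD kernel, fit
#' null and alternative models by ML and compute the boundary-mixture LRT
#' p-value. The null model is fitted once and shared. Per-pathway failures
#' are isolated and reported via the `status` column; they never abort the
#' screen.
#'
#' @param vcf Path to the VCF with all genotypes.
#' @param ped A [pedigree] or path to a PED file.
#' @param pheno Phenotype data.frame or path (see [read_phenotypes()]).
#' @param gmt Named list of gene sets or path to a GMT file.
#' @param transcripts Transcript table data.frame or path
#'   (see [read_transcripts()]).
#' @param flank Window flank in bp (default 5000).
#' @param covariates Fixed-effect columns of the phenotype table.
#' @param pcs Optional matrix/data.frame of principal-component scores with
#'   an `IID` column, joined as extra covariates.
#' @param maf_below Optional MAF threshold: keep variants with MAF strictly
#'   below it (e.g. 0.05, 0.01).
#' @param min_pair_variants Minimum shared variants per pair for the robust
#'   estimator (see [robust_kinship()]).
#' @param kernel_mode PSD repair mode for [make_kernel()].
#' @param gammas Mixing grid for [fit_pathway()].
#' @param refine Continuous refinement in [fit_pathway()].
#' @return data.frame with one row per pathway: `pathway`, `n_genes`,
#'   `n_variants`, `h2r_null`, `h2r_alt`, `h2gp`, `loglik_null`,
#'   `loglik_alt`, `lrt`, `p`, `p_bh`, `p_bonf`, `repair_delta`, `status`;
#'   sorted by p. Untestable pathways carry NA statistics and a reason code
#'   (`no_genes`, `no_variants`, `fit_failed: ...`).
#' @export
screen_pathways <- function(vcf, ped, pheno, gmt, transcripts,
                            flank = 5000,
                            covariates = c("SEX", "AGE", "SMOKE"),
                            pcs = NULL, maf_below = NULL,
                            min_pair_variants = 50,
                            kernel_mode = "bend",
                            gammas = seq(0, 1, length.out = 21),
                            refine = TRUE) {
  if (is.character(ped)) ped <- parse_ped(ped)
  if (is.character(pheno)) pheno <- read_phenotypes(pheno)
  if (is.character(gmt)) gmt <- parse_gmt(gmt)
  if (is.character(transcripts)) transcripts <- read_transcripts(transcripts)
  if (!is.null(pcs)) {
    if (is.character(pcs)) pcs <- utils::read.table(pcs, header = TRUE,
                                                    sep = "\t")
    pheno <- merge(pheno, pcs, by = "IID", sort = FALSE)
    covariates <- c(covariates, setdiff(names(pcs), "IID"))
  }
  phi <- expected_kinship(ped)
  design <- build_design(pheno, covariates)
  null_fit <- fit_null(pheno, phi, covariates)

  rows <- lapply(names(gmt), function(pw) {
    res <- data.frame(pathway = pw, n_genes = NA_integer_,
                      n_variants = NA_integer_, h2r_null = null_fit$h2r,
                      h2r_alt = NA_real_, h2gp = NA_real_,
                      loglik_null = null_fit$loglik, loglik_alt = NA_real_,
                      lrt = NA_real_, p = NA_real_,
                      repair_delta = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    tryCatch({
      reg <- build_regions(pw, gmt[[pw]], transcripts, flank = flank)
      res$n_genes <- nrow(reg$regions)
      g <- extract_genotypes(vcf, reg, samples = design$ids)
      if (!is.null(maf_below) && !is_empty_genotypes(g)) {
        g <- maf_filter(g, maf_below)
      }
      res$n_variants <- n_variants(g)
      if (is_empty_genotypes(g)) {
        res$status <- "no_variants"
        return(res)
      }
      e <- psgrm(g, phi = phi, min_variants = min_pair_variants)
      kern <- make_kernel(e, mode = kernel_mode)
      res$repair_delta <- attr(kern, "repair_delta")
      alt <- fit_pathway(pheno, phi, kern, covariates = covariates,
                         gammas = gammas, refine = refine)
      lrt <- lrt_mixture_p(null_fit$loglik, alt$loglik)
      res$h2r_alt <- alt$h2r
      res$h2gp <- alt$h2gp
      res$loglik_alt <- alt$loglik
      res$lrt <- lrt$statistic
      res$p <- lrt$p
      res
    }, error = function(e) {
      res$status <- if (grepl("no genes resolvable", conditionMessage(e))) {
        "no_genes"
      } else paste0("fit_failed: ", conditionMessage(e))
      res
    })
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$p_bonf <- stats::p.adjust(out$p, method = "bonferroni")
  out <- out[order(out$p, out$pathway), ]
  rownames(out) <- NULL
  out
}
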