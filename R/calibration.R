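#' Build a fixed simulation world for replicated model fitting
#'
#' Simulates the study design once — pedigree, gene-dropped genotypes,
#' expected kinship, the PSGRM kernel of the (single) pathway, fixed
#' covariates — and precomputes everything the per-replicate fits reuse:
#' the null-kernel spectrum, the Cholesky root used to draw polygenic
#' values, and the two-kernel mixing cache. Phenotype replicates drawn
#' against this world redraw only the random trait components, which is
#' what makes hundreds of replicates affordable: the expensive
#' eigendecompositions depend only on the kernels.
#'
#' @param cfg A [sim_config()].
#' @param gammas Mixing grid for the cached two-kernel fits.
#' @return list with `cfg`, `ped`, `g`, `phi`, `A` (2 Phi), `B` (repaired
#'   PSGRM kernel), `chol_2phi`, `cov_fixed`, `X`, `spectrum` (eigen of A),
#'   `cache` ([two_kernel_cache()]).
#' @export
study_world <- function(cfg, gammas = seq(0, 1, length.out = 33)) {
  ped <- simulate_pedigree(cfg)
  g <- gene_drop(ped, cfg)
  phi <- expected_kinship(ped)
  A <- 2 * phi$phi
  e <- psgrm(g, phi = phi)
  B <- make_kernel(e)[ped$iid, ped$iid]
  n <- length(ped$iid)
  chol_2phi <- chol(A + diag(1e-8, n))
  s1 <- simulate_phenotype(ped, g, cfg, phi = phi, chol_2phi = chol_2phi,
                           replicate = 1)
  cov_fixed <- s1$pheno[, c("SEX", "AGE", "SMOKE")]
  X <- cbind(`(Intercept)` = 1, as.matrix(cov_fixed))
  eg <- eigen(A, symmetric = TRUE)
  spectrum <- list(U = eg$vectors, d = pmax(eg$values, 0))
  cache <- two_kernel_cache(A, B, X, gammas)
  list(cfg = cfg, ped = ped, g = g, phi = phi, A = A, B = B,
       chol_2phi = chol_2phi, cov_fixed = cov_fixed, X = X,
       spectrum = spectrum, cache = cache)
}

#' Replicated null/alternative fits over a fixed world
#'
#' For each phenotype replicate: simulate the trait from `world$cfg`
#' (covariates held fixed), fit the null polygenic model and the two-kernel
#' pathway model by ML, and compute the boundary LRT. Used by the
#' calibration, type-I-error and parameter-recovery studies.
#'
#' @param world A [study_world()].
#' @param n_reps Number of phenotype replicates.
#' @param refine Continuous gamma refinement per replicate (slower; the
#'   cached grid is accurate to ~1e-2 in the LRT statistic).
#' @return data.frame with one row per replicate: `T` (LRT statistic),
#'   `p` (mixture p-value), `h2r_null`, `h2r_alt`, `h2gp`,
#'   `h2gp_realized`.
#' @export
replicate_fits <- function(world, n_reps, refine = FALSE) {
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    s <- simulate_phenotype(world$ped, world$g, world$cfg, phi = world$phi,
                            chol_2phi = world$chol_2phi, replicate = r,
                            covariate_data = world$cov_fixed)
    f0 <- fit_null(s$pheno, world$phi, spectrum = world$spectrum)
    f1 <- fit_pathway_cached(s$pheno$TRAIT, world$cache, refine = refine)
    lrt <- lrt_mixture_p(f0$loglik, f1$loglik)
    out[[r]] <- data.frame(T = lrt$statistic, p = lrt$p,
                           h2r_null = f0$h2r, h2r_alt = f1$h2r,
                           h2gp = f1$h2gp,
                           h2gp_realized = s$truth$h2gp_realized)
  }
  do.call(rbind, out)
}

#' Null-calibration study of the boundary LRT
#'
#' Runs `n_reps` phenotype replicates with no pathway effect
#' (`h2gp = 0`) over a fixed simulated world and summarizes the boundary
#' behavior of the LRT: the fraction of replicates with `T = 0` (the
#' mixture reference implies at least one half asymptotically) and the
#' empirical type-I error of the mixture p-value.
#'
#' @param cfg A [sim_config()] with `h2gp = 0`.
#' @param n_reps Number of replicates (default 400).
#' @param alpha Nominal level for the type-I error summary (default 0.05).
#' @param boundary_tol LRT statistics at or below this count as boundary
#'   (default 1e-6).
#' @return list with `boundary_fraction`, `type1`, `fits` (the per-replicate
#'   table), `n_reps`, `mc_se_boundary`, `mc_se_type1`.
#' @export
null_calibration_study <- function(cfg, n_reps = 400, alpha = 0.05,
                                   boundary_tol = 1e-6) {
  stopifnot(cfg$h2gp == 0)
  world <- study_world(cfg)
  fits <- replicate_fits(world, n_reps)
  boundary <- mean(fits$T <= boundary_tol)
  type1 <- mean(fits$p < alpha)
  list(boundary_fraction = boundary, type1 = type1, fits = fits,
       n_reps = n_reps,
       mc_se_boundary = sqrt(boundary * (1 - boundary) / n_reps),
       mc_se_type1 = sqrt(alpha * (1 - alpha) / n_reps))
}
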