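#' Pairwise sufficient statistics for robust kinship
#'
#' For every pair of individuals, counts over the pair's jointly non-missing
#' variants: both-heterozygous sites (`n_hethet`), opposite-homozygote sites
#' (`n_opphom`), each individual's heterozygous sites restricted to the
#' pair's shared sites (`n_het_i`, `n_het_j`), and the number of shared
#' sites (`n_valid`). These are the sufficient statistics of the robust
#' pairwise kinship estimator: no allele frequencies enter, which is what
#' makes the estimator robust to latent population heterogeneity.
#'
#' All counts are computed with dense matrix cross-products, so cost is a
#' handful of `n x m` by `m x n` multiplications.
#'
#' @param g A [genotype_matrix] with at least 2 samples and 1 variant.
#' @return An object of class `pair_counts`: list of n x n matrices
#'   `n_hethet`, `n_opphom`, `n_het_i` (rows index i), `n_valid`, plus
#'   `ids`. `n_het_i[i, j]` is i's heterozygote count over sites shared
#'   with j; the j-count is its transpose.
#' @export
pair_counts <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$dosage) < 2) stop("need >= 2 samples")
  if (ncol(g$dosage) < 1) stop("need >= 1 variant")
  D <- g$dosage
  M <- !is.na(D)
  D0 <- D; D0[!M] <- 0
  H <- (D0 == 1) & M
  A0 <- (D0 == 0) & M
  A2 <- (D0 == 2) & M
  storage.mode(M) <- "double"
  storage.mode(H) <- "double"
  storage.mode(A0) <- "double"
  storage.mode(A2) <- "double"
  n_valid <- tcrossprod(M)
  n_hethet <- tcrossprod(H)
  n_opphom <- tcrossprod(A0, A2)
  n_opphom <- n_opphom + t(n_opphom)
  n_het_i <- tcrossprod(H, M)
  ids <- g$ids
  dimnames(n_valid) <- dimnames(n_hethet) <- dimnames(n_opphom) <-
    dimnames(n_het_i) <- list(ids, ids)
  structure(list(n_hethet = n_hethet, n_opphom = n_opphom,
                 n_het_i = n_het_i, n_valid = n_valid, ids = ids),
            class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("pair_counts:", length(x$ids), "samples,",
      "max shared sites", max(x$n_valid[upper.tri(x$n_valid)]), "\n")
  invisible(x)
}

#' Robust empirical kinship (PSGRM) from pair counts
#'
#' Implements the robust between-family pairwise kinship estimator
#' \deqn{\hat\phi_{ij} = \frac12 - \frac{N_{Aa}^{(i)} + N_{Aa}^{(j)}
#'   - 2 N_{Aa,Aa} + 4 N_{AA,aa}}{4\,\min(N_{Aa}^{(i)}, N_{Aa}^{(j)})}}
#' which uses only heterozygote-concordance and opposite-homozygote counts
#' and is therefore free of allele-frequency estimates (robust to latent
#' structure). Identical genomes give exactly 0.5; pairs from diverged
#' groups can give negative values, which are retained (PSD repair is a
#' separate, explicit step in [make_kernel()]).
#'
#' Pairs with fewer than `min_variants` jointly non-missing sites, or with
#' no heterozygous site in either member, are unestimable: they are imputed
#' with the theoretical pedigree kinship when `phi` is supplied (otherwise
#' 0) and counted in the returned object.
#'
#' @param counts A [pair_counts] object.
#' @param phi Optional theoretical [kinship_matrix] used to fill
#'   unestimable pairs (aligned by id).
#' @param min_variants Minimum jointly non-missing variants for a pair to
#'   be estimated (default 50; below this, tiny pathways produce wild
#'   estimates).
#' @param diag_inbreeding If TRUE, set the diagonal to 0.5 * (1 + f) with f
#'   estimated from each individual's homozygosity excess relative to the
#'   cohort allele frequencies (requires `g`); default uses the non-inbred
#'   convention phi_ii = 0.5.
#' @param g The source [genotype_matrix]; only needed for
#'   `diag_inbreeding = TRUE`.
#' @return A [kinship_matrix] with `kind = "empirical"`, per-pair
#'   supporting-variant counts, and attribute `n_unestimable`.
#' @export
robust_kinship <- function(counts, phi = NULL, min_variants = 50,
                           diag_inbreeding = FALSE, g = NULL) {
  stopifnot(inherits(counts, "pair_counts"))
  n <- length(counts$ids)
  het_i <- counts$n_het_i
  het_j <- t(het_i)
  het_min <- pmin(het_i, het_j)
  est <- 0.5 - (het_i + het_j - 2 * counts$n_hethet +
                  4 * counts$n_opphom) / (4 * het_min)
  bad <- counts$n_valid < min_variants | het_min == 0
  diag(bad) <- FALSE
  n_unest <- sum(bad[upper.tri(bad)])
  if (n_unest > 0) {
    fill <- if (!is.null(phi)) align_kinship(phi, counts$ids)$phi[bad] else 0
    est[bad] <- fill
    message("robust_kinship: ", n_unest, " pair(s) unestimable (min ",
            min_variants, " shared variants); imputed with ",
            if (is.null(phi)) "0" else "pedigree kinship")
  }
  off <- upper.tri(est)
  if (all(bad[off])) {
    stop("all pairs unestimable: use a larger pathway or reduce missingness")
  }
  diag(est) <- 0.5
  if (diag_inbreeding) {
    if (is.null(g)) stop("diag_inbreeding = TRUE requires the genotype matrix g")
    diag(est) <- 0.5 * (1 + inbreeding_from_hom_excess(g))
  }
  est <- (est + t(est)) / 2
  k <- kinship_matrix(est, kind = "empirical",
                      n_variants = counts$n_valid)
  attr(k, "n_unestimable") <- n_unest
  k
}

# f_i = 1 - observed het / expected het, expected from cohort allele freqs
inbreeding_from_hom_excess <- function(g) {
  p <- g$maf
  M <- !is.na(g$dosage)
  exp_het <- M %*% ifelse(is.na(p), 0, 2 * p * (1 - p))
  obs_het <- rowSums(g$dosage == 1, na.rm = TRUE)
  f <- 1 - obs_het / pmax(exp_het[, 1], .Machine$double.eps)
  pmax(f, 0)
}

#' Estimate a PSGRM directly from genotypes
#'
#' Convenience wrapper: [pair_counts()] then [robust_kinship()].
#'
#' @inheritParams robust_kinship
#' @param g A [genotype_matrix].
#' @return A [kinship_matrix], `kind = "empirical"`.
#' @export
psgrm <- function(g, phi = NULL, min_variants = 50,
                  diag_inbreeding = FALSE) {
  robust_kinship(pair_counts(g), phi = phi, min_variants = min_variants,
                 diag_inbreeding = diag_inbreeding, g = g)
}

#' Prepare a PSD model kernel 2E from an empirical kinship matrix
#'
#' The multivariate-normal likelihood needs a positive semidefinite
#' covariance kernel, but the robust estimator can produce indefinite
#' matrices (negative eigenvalues from negative off-diagonal estimates).
#' Repair modes:
#' \describe{
#'   \item{bend}{(default) eigendecompose, floor eigenvalues at 0,
#'     reconstruct, then rescale so the mean diagonal matches the input.}
#'   \item{clip}{set negative off-diagonal kinships to 0 first, then bend.}
#'   \item{raw}{return 2E unmodified; a downstream fit may fail and that is
#'     the caller's risk.}
#' }
#'
#' @param e A [kinship_matrix] (`kind = "empirical"`; a theoretical matrix
#'   is accepted and simply doubled).
#' @param mode One of `"bend"`, `"clip"`, `"raw"`.
#' @return The kernel matrix `2E` (dimnames = ids) with attributes
#'   `repair_delta` (Frobenius norm of the applied change) and `mode`.
#' @export
make_kernel <- function(e, mode = c("bend", "clip", "raw")) {
  mode <- match.arg(mode)
  stopifnot(inherits(e, "kinship_matrix"))
  K <- 2 * e$phi
  if (max(abs(K - t(K))) > 1e-8) stop("kernel input must be symmetric")
  K0 <- K
  if (mode == "clip") {
    off <- row(K) != col(K)
    K[off & K < 0] <- 0
  }
  if (mode != "raw") {
    eg <- eigen(K, symmetric = TRUE)
    if (min(eg$values) < 0) {
      vals <- pmax(eg$values, 0)
      K <- eg$vectors %*% (vals * t(eg$vectors))
      md <- mean(diag(K))
      if (md > 0) K <- K * (mean(diag(K0)) / md)
      K <- (K + t(K)) / 2
    }
  }
  dimnames(K) <- dimnames(K0)
  attr(K, "repair_delta") <- sqrt(sum((K - K0)^2))
  attr(K, "mode") <- mode
  K
}

#' Write a kernel/GRM in square and long form
#'
#' @param K Kernel matrix with id dimnames (as from [make_kernel()]).
#' @param path Square tab-delimited output (id header).
#' @param long_path Optional long-format output (id1, id2, n_variants,
#'   kinship-scale value K/2).
#' @param n_variants Optional per-pair variant-count matrix.
#' @return Invisibly, `path`.
#' @export
write_kernel <- function(K, path, long_path = NULL, n_variants = NULL) {
  k <- kinship_matrix(K / 2, kind = "empirical", n_variants = n_variants)
  write_kinship(k, path, long_path)
}
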