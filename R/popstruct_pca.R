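#' Greedy windowed LD pruning
#'
#' Scans variants in position order in windows of `window` variants
#' advancing by `step`; within a window, for any pair with squared dosage
#' correlation above `r2_max` the later variant (by column order) is
#' dropped. Deterministic. Intended for common variants only: variants with
#' MAF below `min_maf` are removed first (pruning on rare variants is
#' unstable).
#'
#' @param g A [genotype_matrix].
#' @param r2_max Maximum allowed squared correlation (default 0.1:
#'   "low mutual LD").
#' @param window Window size in variants (default 100).
#' @param step Window advance in variants (default 25).
#' @param min_maf MAF floor applied before pruning (default 0.05).
#' @return A [genotype_matrix] with the retained variants.
#' @export
ld_prune <- function(g, r2_max = 0.1, window = 100, step = 25,
                     min_maf = 0.05) {
  stopifnot(r2_max > 0, r2_max <= 1, window >= 2, step >= 1)
  common <- which(!is.na(g$maf) & g$maf >= min_maf)
  g <- subset_variants(g, common)
  m <- n_variants(g)
  if (m == 0) stop("no variants with MAF >= ", min_maf, " to prune")
  keep <- rep(TRUE, m)
  start <- 1
  repeat {
    end <- min(start + window - 1, m)
    idx <- start:end
    idx <- idx[keep[idx]]
    if (length(idx) >= 2) {
      r2 <- suppressWarnings(
        stats::cor(g$dosage[, idx, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 0
      for (a in seq_along(idx)) {
        if (!keep[idx[a]]) next
        hit <- which(r2[a, ] > r2_max)
        hit <- hit[hit > a & keep[idx[hit]]]
        keep[idx[hit]] <- FALSE
      }
    }
    if (end == m) break
    start <- start + step
  }
  subset_variants(g, which(keep))
}

#' Principal components of founder genotypes
#'
#' Computes genetic PCs on founders only and returns the variant loadings
#' so that non-founders can be projected afterwards ([pc_project()]). This
#' founders-then-project scheme prevents the leading PCs from capturing
#' family structure instead of ancestry. Dosages are centered and scaled by
#' founder mean/standard deviation; variants monomorphic in founders are
#' dropped. Each loading vector's largest-magnitude element is forced
#' positive so signs are reproducible.
#'
#' @param g A [genotype_matrix] (typically LD-pruned common variants).
#' @param ped A [pedigree]; founders are the members with both parents
#'   missing.
#' @param k Number of components (default 5).
#' @return An object of class `pc_projection`: list with `variants`
#'   (indices into `g`), `center`, `scale`, `loadings` (variants x k),
#'   `scores` (founders x k), `founder_ids`, `k`.
#' @export
founder_pca <- function(g, ped, k = 5) {
  stopifnot(inherits(ped, "pedigree"))
  founders <- intersect(ped$iid[ped$founder], g$ids)
  if (length(founders) == 0) stop("no genotyped founders")
  if (length(founders) < k + 1) {
    stop("need at least k + 1 = ", k + 1, " genotyped founders, have ",
         length(founders))
  }
  Df <- g$dosage[founders, , drop = FALSE]
  center <- colMeans(Df, na.rm = TRUE)
  scale <- apply(Df, 2, stats::sd, na.rm = TRUE)
  poly <- which(!is.na(scale) & scale > 0)
  if (length(poly) < k) stop("fewer polymorphic founder variants than k")
  Df <- Df[, poly, drop = FALSE]
  center <- center[poly]; scale <- scale[poly]
  Z <- sweep(sweep(Df, 2, center), 2, scale, "/")
  Z[is.na(Z)] <- 0  # founder-mean imputation of missing calls
  sv <- svd(Z, nu = k, nv = k)
  loadings <- sv$v
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    piv <- which.max(abs(loadings[, j]))
    if (loadings[piv, j] < 0) {
      loadings[, j] <- -loadings[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- founders
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(variants = poly, center = center, scale = scale,
                 loadings = loadings, scores = scores,
                 founder_ids = founders, k = k),
            class = "pc_projection")
}

#' @export
print.pc_projection <- function(x, ...) {
  cat("pc_projection:", x$k, "components from", length(x$founder_ids),
      "founders x", length(x$variants), "variants\n")
  invisible(x)
}

#' Project individuals onto founder principal components
#'
#' Scores every individual in `g` on the founder-derived components:
#' dosages are centered/scaled with the *founder* statistics and multiplied
#' by the loadings. Missing dosages are mean-imputed (i.e. contribute 0
#' after centering). Founders reproduce their [founder_pca()] scores
#' exactly. Individuals missing more than `max_missing` of the PCA variants
#' are flagged unreliable.
#'
#' @param pc A `pc_projection` from [founder_pca()].
#' @param g A [genotype_matrix] containing the PCA variants (same variant
#'   columns as the matrix `founder_pca` was run on).
#' @param max_missing Missing-fraction threshold for the reliability flag
#'   (default 0.5).
#' @return data.frame: `IID`, `PC1..PCk`, `unreliable` (logical).
#' @export
pc_project <- function(pc, g, max_missing = 0.5) {
  D <- g$dosage[, pc$variants, drop = FALSE]
  miss <- rowMeans(is.na(D))
  Z <- sweep(sweep(D, 2, pc$center), 2, pc$scale, "/")
  Z[is.na(Z)] <- 0
  scores <- Z %*% pc$loadings
  colnames(scores) <- paste0("PC", seq_len(pc$k))
  data.frame(IID = g$ids, scores, unreliable = miss > max_missing,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write PC scores to a tab-delimited file
#' @param scores data.frame from [pc_project()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pcs <- function(scores, path) {
  utils::write.table(scores[, c("IID", grep("^PC", names(scores),
                                            value = TRUE))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
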