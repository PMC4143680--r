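#' Genotype dosage matrix container
#'
#' Holds an individuals x variants matrix of minor-allele dosages (0/1/2,
#' `NA` = missing call) with per-variant metadata. The minor allele is
#' defined within the sample set the matrix was built over: any column whose
#' counted allele has frequency above 0.5 is flipped (dosage -> 2 - dosage),
#' so every MAF is in \[0, 0.5\].
#'
#' @param dosage Numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns; entries in \{0, 1, 2, NA\}.
#' @param variants data.frame with one row per column of `dosage`: columns
#'   `chrom`, `pos`, `ref`, `alt`, `id` (any may be NA for simulated data),
#'   and optionally `region` (source gene/region label).
#' @return An object of class `genotype_matrix`: list with `dosage`,
#'   `variants`, `ids` and per-variant `maf` (computed over non-missing
#'   calls).
#' @export
genotype_matrix <- function(dosage, variants = NULL) {
  stopifnot(is.matrix(dosage))
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  }
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must lie in {0, 1, 2, NA}")
  if (is.null(variants)) {
    variants <- data.frame(chrom = rep(NA_character_, ncol(dosage)),
                           pos = NA_integer_, ref = NA_character_,
                           alt = NA_character_,
                           id = if (ncol(dosage)) paste0("v", seq_len(ncol(dosage)))
                                else character(0))
  }
  stopifnot(nrow(variants) == ncol(dosage))
  af <- colMeans(dosage, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) {
    dosage[, flip] <- 2 - dosage[, flip, drop = FALSE]
    af[flip] <- 1 - af[flip]
  }
  variants$flipped <- flip
  rownames(variants) <- NULL
  structure(list(dosage = dosage, variants = variants,
                 ids = rownames(dosage), maf = unname(af)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "variants; median MAF",
      signif(stats::median(x$maf, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Number of variants in a genotype matrix
#' @param g A [genotype_matrix].
#' @return Integer count (0 for the empty sentinel).
#' @export
n_variants <- function(g) ncol(g$dosage)

#' Is this the empty-matrix sentinel?
#' @param g A [genotype_matrix].
#' @return TRUE if the matrix holds no variants.
#' @export
is_empty_genotypes <- function(g) ncol(g$dosage) == 0L

#' Subset a genotype matrix by variant index
#'
#' MAF (and minor-allele orientation) is recomputed for the retained sample
#' set, so subsetting keeps the container's invariants.
#'
#' @param g A [genotype_matrix].
#' @param j Integer or logical index over variants.
#' @param i Optional integer/logical/character index over samples.
#' @return A [genotype_matrix].
#' @export
subset_variants <- function(g, j, i = NULL) {
  if (is.null(i)) i <- seq_len(nrow(g$dosage))
  genotype_matrix(g$dosage[i, j, drop = FALSE],
                  g$variants[j, setdiff(names(g$variants), "flipped"),
                             drop = FALSE])
}

#' Filter variants by minor allele frequency
#'
#' Retains variants with MAF strictly below `max_maf` (the convention used
#' for the rare-variant strata MAF < 0.05 and MAF < 0.01). MAF is computed
#' over non-missing calls in the full sample set of `g`. Removing all
#' variants returns the empty-matrix sentinel rather than erroring, so a
#' pathway can be reported untestable downstream.
#'
#' @param g A [genotype_matrix].
#' @param max_maf Threshold in (0, 0.5].
#' @return A [genotype_matrix] (possibly empty).
#' @export
maf_filter <- function(g, max_maf) {
  stopifnot(is.numeric(max_maf), length(max_maf) == 1, max_maf > 0,
            max_maf <= 0.5)
  keep <- !is.na(g$maf) & g$maf < max_maf
  subset_variants(g, keep)
}
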