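#' Deviation of an empirical PSGRM from the pedigree kinship
#'
#' Summarizes pairwise absolute deviations `|phi_hat - phi|` stratified by
#' pedigree relatedness: related pairs (`phi > 0`, same family with nonzero
#' expected sharing) and unrelated pairs (`phi = 0`). Pairs flagged
#' unestimable in the empirical matrix (no supporting variants) are
#' excluded and counted. A PSGRM estimated from many variants should show
#' small deviations; small pathways deviate more, and it is exactly that
#' deviation that carries pathway-specific signal.
#'
#' @param e Empirical [kinship_matrix] (the PSGRM).
#' @param phi Theoretical [kinship_matrix]; must cover the same samples.
#' @param min_variants Pairs with fewer supporting variants are excluded
#'   when `e` carries per-pair counts (default 1).
#' @return data.frame (class `deviation_summary`) with one row: columns
#'   `n_pairs_related`, `n_pairs_unrelated`, `n_excluded`,
#'   `mean_dev_related`, `mean_dev_unrelated`.
#' @export
kinship_deviation <- function(e, phi, min_variants = 1) {
  if (!setequal(e$ids, phi$ids)) {
    stop("empirical and theoretical kinship matrices cover different samples")
  }
  phi <- align_kinship(phi, e$ids)
  up <- upper.tri(e$phi)
  dev <- abs(e$phi - phi$phi)[up]
  rel <- (phi$phi > 0)[up]
  ok <- if (!is.null(e$n_variants)) (e$n_variants >= min_variants)[up]
        else rep(TRUE, sum(up))
  out <- data.frame(
    n_pairs_related = sum(rel & ok),
    n_pairs_unrelated = sum(!rel & ok),
    n_excluded = sum(!ok),
    mean_dev_related = mean(dev[rel & ok]),
    mean_dev_unrelated = mean(dev[!rel & ok]))
  class(out) <- c("deviation_summary", "data.frame")
  out
}

#' Genomic inflation factor and QQ table for pathway p-values
#'
#' Transforms p-values to the chi-square(1) scale and reports
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)` (denominator
#' 0.4549364) together with plot-ready QQ pairs against uniform order
#' statistics `i / (m + 1)`. Under the boundary-mixture null, half of the
#' p-values sit at 1 and lambda is deflated below 1; `lambda_positive`
#' restricts the computation to p < 1 (tests with a strictly positive LRT
#' statistic), which is the variant closer to a standard chi-square
#' calibration. Both are reported.
#'
#' @param p Numeric vector of p-values in (0, 1\]; at least 10 finite
#'   values required.
#' @return An object of class `qq_report`: list with `lambda`,
#'   `lambda_positive`, `n`, and `table` (data.frame `expected`,
#'   `observed` sorted ascending).
#' @export
genomic_inflation <- function(p) {
  p <- p[is.finite(p)]
  if (length(p) < 10) stop("need at least 10 finite p-values")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  med_null <- stats::qchisq(0.5, df = 1)  # 0.4549364
  lambda <- stats::median(chi) / med_null
  pos <- p < 1
  lambda_pos <- if (sum(pos) >= 10) stats::median(chi[pos]) / med_null
                else NA_real_
  m <- length(p)
  tab <- data.frame(expected = seq_len(m) / (m + 1), observed = sort(p))
  structure(list(lambda = lambda, lambda_positive = lambda_pos, n = m,
                 table = tab),
            class = "qq_report")
}

#' @export
print.qq_report <- function(x, ...) {
  cat("qq_report:", x$n, "p-values; lambda =", signif(x$lambda, 4),
      "; lambda (T > 0 only) =", signif(x$lambda_positive, 4), "\n")
  invisible(x)
}

#' Write a QQ report to a plot-ready tab-delimited file
#'
#' Header comment lines carry lambda (all tests) and lambda restricted to
#' positive LRT statistics; the body is the expected/observed table.
#'
#' @param qq A `qq_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qq <- function(qq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# lambda=", qq$lambda),
               paste0("# lambda_positive=", qq$lambda_positive),
               paste0("# n=", qq$n)), con)
  utils::write.table(qq$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
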