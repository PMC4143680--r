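#' Parse a PED-style pedigree file
#'
#' Reads a whitespace-delimited pedigree file with columns FID, IID, PAT,
#' MAT, SEX (additional columns are ignored) and returns a validated
#' [pedigree] object. `"0"` (or `NA`) denotes a missing parent. An individual
#' with both parents missing is a founder. A parent id that never appears as
#' an individual row is an error: silently auto-created founders would
#' corrupt the expected kinship matrix.
#'
#' @param path Path to a PED-style text file. Lines starting with `#` are
#'   skipped.
#' @return A `pedigree` object; see [pedigree()].
#' @examples
#' ped_file <- tempfile(fileext = ".ped")
#' writeLines(c("FAM1 dad 0 0 1", "FAM1 mom 0 0 2", "FAM1 kid dad mom 1"),
#'            ped_file)
#' ped <- parse_ped(ped_file)
#' sum(ped$founder)
#' @export
parse_ped <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character",
                           col.names = paste0("V", 1:5), fill = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 5) stop("pedigree file needs >= 5 columns (FID IID PAT MAT SEX)")
  # tolerate a header row
  if (nrow(tab) && toupper(tab[1, 2]) %in% c("IID", "ID", "INDIVIDUAL")) {
    tab <- tab[-1, , drop = FALSE]
  }
  pedigree(fid = tab[[1]], iid = tab[[2]], father = tab[[3]],
           mother = tab[[4]], sex = suppressWarnings(as.integer(tab[[5]])))
}

#' Construct a validated pedigree
#'
#' Validates structural invariants (unique ids, parents present, no
#' individual its own ancestor) and computes a topological order in which
#' every parent precedes its children. Missing parents are encoded `"0"` or
#' `NA`. Sex codes are stored for covariate use only; the kinship recursion
#' does not use them.
#'
#' @param fid,iid,father,mother Character vectors of equal length.
#' @param sex Integer vector (1 = male, 2 = female, 0/NA = unknown).
#' @return An object of class `pedigree`: a list with `fid`, `iid`,
#'   `father`, `mother`, `sex`, `founder` (logical), `order` (indices in
#'   topological order), and parent index vectors `fidx`, `midx` (NA for
#'   missing parents).
#' @export
pedigree <- function(fid, iid, father, mother, sex = NULL) {
  n <- length(iid)
  fid <- as.character(fid); iid <- as.character(iid)
  father <- as.character(father); mother <- as.character(mother)
  if (is.null(sex)) sex <- rep(NA_integer_, n)
  stopifnot(length(fid) == n, length(father) == n, length(mother) == n)
  if (anyDuplicated(iid)) {
    stop("duplicate individual id(s): ",
         paste(unique(iid[duplicated(iid)]), collapse = ", "))
  }
  miss <- function(x) is.na(x) | x == "0" | x == ""
  father[miss(father)] <- NA_character_
  mother[miss(mother)] <- NA_character_
  fidx <- match(father, iid)
  midx <- match(mother, iid)
  bad_f <- !is.na(father) & is.na(fidx)
  bad_m <- !is.na(mother) & is.na(midx)
  if (any(bad_f | bad_m)) {
    stop("parent id(s) not present as individuals: ",
         paste(unique(c(father[bad_f], mother[bad_m])), collapse = ", "))
  }
  founder <- is.na(fidx) & is.na(midx)

  # Kahn topological sort; leftover nodes imply a cycle.
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fidx[i], midx[i])) {
      if (!is.na(p)) {
        if (p == i) stop("individual '", iid[i], "' is its own parent")
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(iid[setdiff(seq_len(n), ord)], collapse = ", "))
  }
  structure(list(fid = fid, iid = iid, father = father, mother = mother,
                 sex = as.integer(sex), founder = founder, order = ord,
                 fidx = fidx, midx = midx),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", length(x$iid), "individuals,",
      length(unique(x$fid)), "family(ies),", sum(x$founder), "founders\n")
  invisible(x)
}

#' Number of individuals in a pedigree
#' @param ped A [pedigree].
#' @return Integer count.
#' @export
ped_size <- function(ped) length(ped$iid)

#' Expected (theoretical) kinship matrix from a pedigree
#'
#' Computes pairwise kinship coefficients phi by the standard recursion:
#' founders are unrelated and non-inbred (phi_ii = 1/2), for a non-founder i
#' phi_ii = (1 + phi(father_i, mother_i)) / 2 and, processing individuals in
#' topological order, phi_ij = (phi(father_i, j) + phi(mother_i, j)) / 2 for
#' any j already processed. A missing parent of a half-typed individual acts
#' as a unique unrelated founder (its contribution to the recursion is 0).
#' Individuals from different families have kinship exactly 0, so the matrix
#' is block-diagonal across families.
#'
#' @param ped A [pedigree].
#' @return A [kinship_matrix] with `kind = "theoretical"`, rows/columns in
#'   the pedigree's input order.
#' @examples
#' ped <- pedigree(fid = c(1, 1, 1), iid = c("a", "b", "c"),
#'                 father = c("0", "0", "a"), mother = c("0", "0", "b"))
#' expected_kinship(ped)$phi["a", "c"]  # parent-offspring: 0.25
#' @export
expected_kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$iid)
  phi <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
  done <- logical(n)
  for (i in ped$order) {
    f <- ped$fidx[i]; m <- ped$midx[i]
    pf <- if (!is.na(f)) phi[f, ] else numeric(n)
    pm <- if (!is.na(m)) phi[m, ] else numeric(n)
    if (ped$founder[i]) {
      phi[i, i] <- 0.5
    } else {
      row <- (pf + pm) / 2
      row[!done] <- 0
      phi[i, ] <- row
      phi[, i] <- row
      phi[i, i] <- 0.5 * (1 + if (!is.na(f) && !is.na(m)) phi[f, m] else 0)
    }
    done[i] <- TRUE
  }
  kinship_matrix(phi, kind = "theoretical")
}

#' Kinship matrix container
#'
#' A symmetric matrix of pairwise kinship coefficients with a role tag:
#' `"theoretical"` for the pedigree expectation Phi (entries in \[0, 1\],
#' 2*Phi positive semidefinite) or `"empirical"` for a marker-based estimate
#' such as the PSGRM, whose off-diagonal entries may legitimately be negative
#' and which is only guaranteed PSD after [make_kernel()] repair.
#'
#' @param phi Symmetric numeric matrix with dimnames set to sample ids.
#' @param kind `"theoretical"` or `"empirical"`.
#' @param n_variants Optional symmetric integer matrix of per-pair supporting
#'   variant counts (empirical kind only).
#' @return An object of class `kinship_matrix`: list with `phi`, `ids`,
#'   `kind`, `n_variants`.
#' @export
kinship_matrix <- function(phi, kind = c("theoretical", "empirical"),
                           n_variants = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(phi), nrow(phi) == ncol(phi))
  if (is.null(rownames(phi))) {
    rownames(phi) <- colnames(phi) <- paste0("S", seq_len(nrow(phi)))
  }
  if (max(abs(phi - t(phi))) > 1e-8) stop("kinship matrix must be symmetric")
  phi <- (phi + t(phi)) / 2
  if (kind == "theoretical" && (min(phi) < -1e-12 || max(phi) > 1 + 1e-12)) {
    stop("theoretical kinship entries must lie in [0, 1]")
  }
  structure(list(phi = phi, ids = rownames(phi), kind = kind,
                 n_variants = n_variants),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix (", x$kind, "): ", length(x$ids), " samples, ",
      "range [", signif(min(x$phi), 3), ", ", signif(max(x$phi), 3), "]\n",
      sep = "")
  invisible(x)
}

#' Subset/reorder a kinship matrix to a set of sample ids
#' @param k A [kinship_matrix].
#' @param ids Character vector of ids, all present in `k`.
#' @return A [kinship_matrix] over `ids` in the given order.
#' @export
align_kinship <- function(k, ids) {
  missing <- setdiff(ids, k$ids)
  if (length(missing)) {
    stop("samples absent from kinship matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  kinship_matrix(k$phi[ids, ids, drop = FALSE], kind = k$kind,
                 n_variants = if (!is.null(k$n_variants))
                   k$n_variants[ids, ids, drop = FALSE])
}

#' Write a kinship matrix to tab-delimited files
#'
#' @param k A [kinship_matrix].
#' @param path Output path for the square form: id header row, one row per
#'   sample with leading id column.
#' @param long_path Optional path for the long form: columns IID1, IID2,
#'   N_VARIANTS (NA for theoretical), KINSHIP; upper triangle including the
#'   diagonal.
#' @return Invisibly, `path`.
#' @export
write_kinship <- function(k, path, long_path = NULL) {
  sq <- data.frame(IID = k$ids, k$phi, check.names = FALSE)
  utils::write.table(sq, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long_path)) {
    idx <- which(upper.tri(k$phi, diag = TRUE), arr.ind = TRUE)
    long <- data.frame(
      IID1 = k$ids[idx[, 1]], IID2 = k$ids[idx[, 2]],
      N_VARIANTS = if (!is.null(k$n_variants)) k$n_variants[idx] else NA,
      KINSHIP = k$phi[idx])
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a square kinship matrix written by [write_kinship()]
#' @param path File path.
#' @param kind Kind tag to attach.
#' @return A [kinship_matrix].
#' @export
read_kinship <- function(path, kind = "empirical") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  kinship_matrix(m, kind = kind)
}
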