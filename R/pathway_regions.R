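#' Parse a GMT gene-set file
#'
#' Standard GMT: one pathway per line, tab-delimited fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. A gene may belong to more
#' than one pathway; order is preserved.
#'
#' @param path Path to a GMT file.
#' @return Named list: one character vector of gene symbols per pathway.
#' @export
parse_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop("GMT line ", k, ": expected name, description and >= 1 gene")
    }
    out[[fields[1]]] <- fields[-(1:2)]
  }
  out
}

#' Read a transcript table of gene models
#'
#' Tab-delimited with header columns `gene`, `transcript`, `chrom`,
#' `strand`, `txStart`, `txEnd` in 1-based inclusive coordinates (isoforms
#' as separate rows). Alternatively a BED file (0-based half-open) can be
#' read with `format = "bed"`, using columns chrom/start/end/name(gene);
#' coordinates are converted to 1-based inclusive at this boundary.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return data.frame with columns gene, transcript, chrom, strand,
#'   txStart, txEnd.
#' @export
read_transcripts <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("gene", "transcript", "chrom", "strand", "txStart", "txEnd")
    if (!all(need %in% names(tab))) {
      stop("transcript table must have columns: ", paste(need, collapse = ", "))
    }
    tab <- tab[need]
  } else {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 4) stop("BED input needs >= 4 columns (name = gene)")
    tab <- data.frame(gene = tab[[4]],
                      transcript = if (ncol(tab) >= 4) tab[[4]] else NA,
                      chrom = tab[[1]], strand = if (ncol(tab) >= 6) tab[[6]] else "+",
                      txStart = tab[[2]] + 1L, txEnd = tab[[3]],
                      stringsAsFactors = FALSE)
  }
  bad <- tab$txStart > tab$txEnd
  if (any(bad)) stop("transcript rows with txStart > txEnd: ",
                     paste(utils::head(tab$transcript[bad], 5), collapse = ", "))
  tab
}

strip_symbol <- function(x) toupper(sub("\\.[0-9]+$", "", x))

#' Map gene symbols to flanked genomic windows
#'
#' For each requested gene, the longest isoform (by `txEnd - txStart + 1`;
#' ties broken by lexicographically smallest transcript id) is selected and
#' extended by `flank` bp on both genomic sides (clipped at position 1).
#' With `strand_aware = TRUE` the upstream/downstream flanks may differ and
#' are applied relative to the annotated strand. Symbols are matched
#' case-insensitively after stripping version suffixes; unresolvable symbols
#' are collected, reported with a warning and skipped.
#'
#' @param pathway Pathway name (provenance only).
#' @param genes Character vector of gene symbols.
#' @param models Transcript table from [read_transcripts()].
#' @param flank Flank size in bp on each side (default 5000, chosen to
#'   capture proximal regulatory sequence).
#' @param strand_aware If TRUE, apply `flank_up` upstream and `flank_down`
#'   downstream of the transcript relative to strand.
#' @param flank_up,flank_down Asymmetric flanks used when `strand_aware`.
#' @return An object of class `pathway_regions`: list with `pathway`,
#'   `regions` (data.frame gene, chrom, start, end), `missing_genes`,
#'   `flank`.
#' @export
build_regions <- function(pathway, genes, models, flank = 5000,
                          strand_aware = FALSE, flank_up = flank,
                          flank_down = flank) {
  stopifnot(flank >= 0)
  key <- strip_symbol(models$gene)
  want <- strip_symbol(unique(genes))
  found <- want[want %in% key]
  missing_genes <- setdiff(want, key)
  if (length(missing_genes)) {
    warning("pathway '", pathway, "': ", length(missing_genes),
            " gene(s) not in transcript table: ",
            paste(utils::head(missing_genes, 10), collapse = ", "))
  }
  if (!length(found)) {
    stop("pathway '", pathway, "': no genes resolvable in transcript table")
  }
  rows <- lapply(found, function(gsym) {
    iso <- models[key == gsym, , drop = FALSE]
    span <- iso$txEnd - iso$txStart + 1
    best <- iso[order(-span, iso$transcript), , drop = FALSE][1, ]
    if (strand_aware && identical(best$strand, "-")) {
      s <- best$txStart - flank_down; e <- best$txEnd + flank_up
    } else {
      s <- best$txStart - flank_up; e <- best$txEnd + flank_down
    }
    data.frame(gene = best$gene, chrom = as.character(best$chrom),
               start = max(1, s), end = e, stringsAsFactors = FALSE)
  })
  structure(list(pathway = pathway, regions = do.call(rbind, rows),
                 missing_genes = missing_genes, flank = flank),
            class = "pathway_regions")
}

#' @export
print.pathway_regions <- function(x, ...) {
  cat("pathway_regions '", x$pathway, "': ", nrow(x$regions), " gene windows",
      if (length(x$missing_genes)) paste0(" (", length(x$missing_genes),
                                          " unresolved)"), "\n", sep = "")
  invisible(x)
}

#' Convert pathway regions to a GRanges of merged query windows
#' @param regions A `pathway_regions` object.
#' @return A `GRanges` (1-based inclusive, unmerged; one range per gene).
#' @export
regions_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$regions$chrom,
    ranges = IRanges::IRanges(start = regions$regions$start,
                              end = regions$regions$end),
    gene = regions$regions$gene)
}

#' Extract pathway genotypes from a VCF
#'
#' Reads biallelic SNVs falling inside any of the pathway's gene windows
#' (inclusive ends) and returns a minor-allele dosage matrix. Variants
#' covered by several overlapping gene windows are included once.
#' Multi-allelic records and non-SNVs are skipped and counted. Missing
#' genotypes are preserved as `NA`; variants missing in more than
#' `max_missing` of samples are dropped (protects the pairwise-count
#' kinship estimator).
#'
#' @param vcf Path to a VCF 4.x file (plain or bgzipped).
#' @param regions A `pathway_regions` object.
#' @param samples Optional character vector of sample ids to extract, in
#'   the desired order; ids absent from the VCF raise an error.
#' @param max_missing Per-variant missing-call fraction above which the
#'   variant is dropped (default 0.2).
#' @return A [genotype_matrix] (empty sentinel when no variants fall in the
#'   windows), with attributes `n_skipped_multiallelic`,
#'   `n_dropped_missing`.
#' @export
extract_genotypes <- function(vcf, regions, samples = NULL,
                              max_missing = 0.2) {
  v <- VariantAnnotation::readVcf(vcf)
  vcf_samples <- colnames(v)
  if (is.null(samples)) samples <- vcf_samples
  absent <- setdiff(samples, vcf_samples)
  if (length(absent)) {
    stop("sample id(s) not present in VCF: ",
         paste(utils::head(absent, 10), collapse = ", "))
  }
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- VariantAnnotation::alt(v)
  n_alt <- S4Vectors::elementNROWS(alt)
  is_snv <- n_alt == 1L &
    BiocGenerics::width(rr) == 1L &
    S4Vectors::unstrsplit(methods::as(alt, "CharacterList")) %in%
      c("A", "C", "G", "T")
  n_skipped <- sum(!is_snv)
  gr <- regions_granges(regions)
  # suppressWarnings: disjoint seqlevels (no variants on a window's
  # chromosome) is a legitimate no-hit case, not a user problem
  hit <- suppressWarnings(IRanges::overlapsAny(rr, gr, type = "any")) &
    is_snv
  out <- empty_extraction(samples)
  if (!any(hit)) {
    attr(out, "n_skipped_multiallelic") <- n_skipped
    attr(out, "n_dropped_missing") <- 0L
    return(out)
  }
  v <- v[hit, samples]
  rr <- SummarizedExperiment::rowRanges(v)
  gt <- VariantAnnotation::geno(v)$GT
  dos <- gt_to_dosage(gt)
  # label each variant with the first gene window covering it
  ov <- suppressWarnings(GenomicRanges::findOverlaps(rr, gr,
                                                     select = "first"))
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = as.character(unlist(methods::as(VariantAnnotation::alt(v),
                                          "CharacterList"))),
    id = rownames(gt),
    region = regions$regions$gene[ov],
    stringsAsFactors = FALSE)
  # de-duplicate identical (chrom, pos, alt) records
  dup <- duplicated(variants[c("chrom", "pos", "alt")])
  miss_rate <- rowMeans(is.na(dos))
  drop_missing <- miss_rate > max_missing
  n_dropped <- sum(drop_missing & !dup)
  keep <- !dup & !drop_missing
  out <- if (any(keep)) {
    genotype_matrix(t(dos[keep, , drop = FALSE]),
                    variants[keep, , drop = FALSE])
  } else empty_extraction(samples)
  attr(out, "n_skipped_multiallelic") <- n_skipped
  attr(out, "n_dropped_missing") <- n_dropped
  out
}

empty_extraction <- function(samples) {
  genotype_matrix(matrix(numeric(0), nrow = length(samples), ncol = 0,
                         dimnames = list(samples, NULL)),
                  data.frame(chrom = character(0), pos = integer(0),
                             ref = character(0), alt = character(0),
                             id = character(0), region = character(0)))
}

# GT strings -> alt-allele counts; any genotype containing "." is missing
gt_to_dosage <- function(gt) {
  map <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
           "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2,
           "0" = 0, "1" = 1)
  d <- map[gt]
  dim(d) <- dim(gt)
  dimnames(d) <- dimnames(gt)
  d
}
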