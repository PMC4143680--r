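make_tx <- function() {
  data.frame(
    gene = c("G1", "G1", "G2", "G3", "G3", "G4"),
    transcript = c("t1.b", "t1.a", "t2", "t3.1", "t3.2", "t4"),
    chrom = c("1", "1", "1", "2", "2", "2"),
    strand = c("+", "+", "-", "+", "+", "-"),
    txStart = c(10001L, 10001L, 40001L, 3000L, 3000L, 100001L),
    txEnd = c(12000L, 15000L, 41000L, 4000L, 3500L, 101000L),
    stringsAsFactors = FALSE)
}

test_that("parse_gmt keeps order and shared genes; rejects short lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pwA\tdesc\tG1\tG2", "pwB\tdesc\tG2\tG3"), path)
  gmt <- parse_gmt(path)
  expect_equal(names(gmt), c("pwA", "pwB"))
  expect_true("G2" %in% gmt$pwA && "G2" %in% gmt$pwB)

  writeLines(c("pwA\tdesc\tG1", "pwEmpty\tdesc"), path)
  expect_error(parse_gmt(path), "line 2")
})

test_that("build_regions picks the longest isoform and flanks both sides", {
  reg <- build_regions("pw", c("G1"), make_tx(), flank = 5000)
  # isoforms 10001-12000 and 10001-15000: longest spans to 15000
  expect_equal(reg$regions$start, 5001)
  expect_equal(reg$regions$end, 20000)
})

test_that("build_regions clips at position 1 and breaks ties by transcript id", {
  reg <- build_regions("pw", "G3", make_tx(), flank = 5000)
  expect_equal(reg$regions$start, 1)  # 3000 - 5000 clipped
  # equal-span tie: lexicographically smallest transcript id wins
  tx <- make_tx()
  tx$txEnd[4] <- 3500L  # make t3.1 and t3.2 identical spans
  reg2 <- build_regions("pw", "G3", tx, flank = 0)
  expect_equal(reg2$regions$start, 3000)
  expect_equal(reg2$regions$end, 3500)
})

test_that("unresolvable genes warn and an all-missing pathway errors", {
  expect_warning(reg <- build_regions("pw", c("G1", "NOPE"), make_tx()),
                 "NOPE")
  expect_equal(nrow(reg$regions), 1)
  expect_equal(reg$missing_genes, "NOPE")
  expect_error(suppressWarnings(build_regions("pw", "NOPE", make_tx())),
               "no genes resolvable")
})

test_that("gene symbols match case-insensitively with version suffixes", {
  reg <- build_regions("pw", c("g1.2"), make_tx(), flank = 0)
  expect_equal(reg$regions$gene, "G1")
})

test_that("windows are monotone in flank", {
  r1 <- build_regions("pw", c("G1", "G2"), make_tx(), flank = 1000)
  r2 <- build_regions("pw", c("G1", "G2"), make_tx(), flank = 5000)
  expect_true(all(r2$regions$start <= r1$regions$start))
  expect_true(all(r2$regions$end >= r1$regions$end))
})

# small VCF written through the simulator writer
toy_vcf <- function(pos, chrom = "1", ids = c("s1", "s2", "s3"),
                    dosages = NULL, env = parent.frame()) {
  m <- length(pos)
  if (is.null(dosages)) dosages <- matrix(1, length(ids), m)
  rownames(dosages) <- ids
  g <- genotype_matrix(dosages,
                       data.frame(chrom = chrom, pos = as.integer(pos),
                                  ref = "A", alt = "C",
                                  id = paste0("v", seq_len(m)),
                                  stringsAsFactors = FALSE))
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = env)
  write_sim_vcf(g, path)
  path
}

test_that("extract_genotypes respects inclusive window boundaries", {
  tx <- data.frame(gene = "G", transcript = "t", chrom = "1", strand = "+",
                   txStart = 1000L, txEnd = 2000L)
  reg <- build_regions("pw", "G", tx, flank = 100)
  # window is [900, 2100]
  vcf <- toy_vcf(pos = c(899, 900, 1500, 2100, 2101))
  g <- extract_genotypes(vcf, reg)
  expect_equal(sort(g$variants$pos), c(900, 1500, 2100))
})

test_that("overlapping gene windows deduplicate shared variants", {
  tx <- data.frame(gene = c("Ga", "Gb"), transcript = c("ta", "tb"),
                   chrom = "1", strand = "+",
                   txStart = c(1000L, 1500L), txEnd = c(2000L, 2500L))
  reg <- build_regions("pw", c("Ga", "Gb"), tx, flank = 0)
  vcf <- toy_vcf(pos = c(1600, 1700))  # inside both windows
  g <- extract_genotypes(vcf, reg)
  expect_equal(n_variants(g), 2)
})

test_that("empty extraction returns the untestable sentinel, not an error", {
  tx <- data.frame(gene = "G", transcript = "t", chrom = "9", strand = "+",
                   txStart = 1000L, txEnd = 2000L)
  reg <- build_regions("pw", "G", tx, flank = 0)
  vcf <- toy_vcf(pos = c(10, 20), chrom = "1")
  g <- extract_genotypes(vcf, reg)
  expect_true(is_empty_genotypes(g))
})

test_that("unknown sample ids raise with offenders named", {
  tx <- data.frame(gene = "G", transcript = "t", chrom = "1", strand = "+",
                   txStart = 1000L, txEnd = 2000L)
  reg <- build_regions("pw", "G", tx, flank = 0)
  vcf <- toy_vcf(pos = 1500)
  expect_error(extract_genotypes(vcf, reg, samples = c("s1", "zz")), "zz")
})

test_that("dosages are minor-allele oriented after extraction", {
  tx <- data.frame(gene = "G", transcript = "t", chrom = "1", strand = "+",
                   txStart = 1000L, txEnd = 2000L)
  reg <- build_regions("pw", "G", tx, flank = 0)
  # ALT is the major allele here (dosage 2,2,1): cohort MAF must flip it
  vcf <- toy_vcf(pos = 1500, dosages = matrix(c(2, 2, 1), 3, 1))
  g <- extract_genotypes(vcf, reg)
  expect_equal(unname(g$dosage[, 1]), c(0, 0, 1))
  expect_equal(g$maf, 1 / 6)
})

test_that("maf_filter is strict and composes as min(a, b)", {
  set.seed(9)
  g <- random_geno(40, 10, seed = 9,
                   maf = c(0.5, 0.3, 0.2, 0.1, 0.06, 0.04, 0.02, 0.009,
                           0.12, 0.25))
  at_05 <- maf_filter(g, 0.05)
  expect_true(all(at_05$maf < 0.05))
  # exact-threshold variant is removed (strict inequality)
  d <- g$dosage
  d[, 1] <- rep(c(0, 1), 20)  # MAF exactly 0.5... kept only if < 0.5
  g2 <- genotype_matrix(d)
  expect_equal(g2$maf[1], 0.25)  # dosage 0/1 alternating gives af 0.25
  d[, 1] <- rep(c(0, 2), 20)    # af exactly 0.5
  g2 <- genotype_matrix(d)
  f <- maf_filter(g2, 0.5)
  expect_equal(n_variants(f), sum(g2$maf < 0.5))
  # composition
  a <- maf_filter(maf_filter(g, 0.2), 0.07)
  b <- maf_filter(g, min(0.2, 0.07))
  expect_equal(a$variants$id, b$variants$id)
  expect_equal(a$dosage, b$dosage)
})

test_that("extraction drops high-missingness variants and keeps NA calls", {
  ids <- paste0("s", 1:10)
  d <- matrix(1, 10, 2, dimnames = list(ids, NULL))
  d[1:4, 1] <- NA  # 40% missing -> dropped at default 20% threshold
  d[1, 2] <- NA    # 10% missing -> kept, NA preserved
  tx <- data.frame(gene = "G", transcript = "t", chrom = "1", strand = "+",
                   txStart = 1L, txEnd = 5000L)
  reg <- build_regions("pw", "G", tx, flank = 0)
  vcf <- toy_vcf(pos = c(100, 200), ids = ids, dosages = d)
  g <- extract_genotypes(vcf, reg)
  expect_equal(n_variants(g), 1)
  expect_equal(attr(g, "n_dropped_missing"), 1L)
  expect_true(is.na(g$dosage["s1", 1]))
})

test_that("multi-allelic and indel records are skipped with a count", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=10000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    "1\t100\tv1\tA\tC,G\t.\tPASS\t.\tGT\t0/1\t0/0",
    "1\t200\tv2\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0",
    "1\t300\tv3\tA\tC\t.\tPASS\t.\tGT\t0/1\t1/1"), path)
  tx <- data.frame(gene = "G", transcript = "t", chrom = "1", strand = "+",
                   txStart = 1L, txEnd = 5000L)
  reg <- build_regions("pw", "G", tx, flank = 0)
  g <- extract_genotypes(path, reg)
  expect_equal(n_variants(g), 1)
  expect_equal(g$variants$pos, 300)
  expect_equal(attr(g, "n_skipped_multiallelic"), 2L)
})
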