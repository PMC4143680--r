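# exhaustive per-variant loop: the independent oracle for pair_counts
brute_counts <- function(d, i, j) {
  ok <- !is.na(d[i, ]) & !is.na(d[j, ])
  a <- d[i, ok]; b <- d[j, ok]
  list(n_hethet = sum(a == 1 & b == 1),
       n_opphom = sum((a == 0 & b == 2) | (a == 2 & b == 0)),
       n_het_i = sum(a == 1), n_het_j = sum(b == 1),
       n_valid = sum(ok))
}

king_phi <- function(cc) {
  0.5 - (cc$n_het_i + cc$n_het_j - 2 * cc$n_hethet + 4 * cc$n_opphom) /
    (4 * min(cc$n_het_i, cc$n_het_j))
}

test_that("pair_counts equals the exhaustive per-variant loop", {
  g <- random_geno(20, 200, seed = 5, miss = 0.1)
  pc <- pair_counts(g)
  set.seed(6)
  for (k in 1:25) {
    ij <- sample(20, 2)
    b <- brute_counts(g$dosage, ij[1], ij[2])
    expect_equal(pc$n_hethet[ij[1], ij[2]], b$n_hethet)
    expect_equal(pc$n_opphom[ij[1], ij[2]], b$n_opphom)
    expect_equal(pc$n_het_i[ij[1], ij[2]], b$n_het_i)
    expect_equal(pc$n_het_i[ij[2], ij[1]], b$n_het_j)
    expect_equal(pc$n_valid[ij[1], ij[2]], b$n_valid)
  }
  # count invariants
  up <- upper.tri(pc$n_valid)
  expect_true(all(pc$n_hethet[up] <= pmin(pc$n_het_i, t(pc$n_het_i))[up]))
  expect_true(all(pc$n_valid[up] >= pc$n_hethet[up] + pc$n_opphom[up]))
})

test_that("pair_counts handles hand-built corner cases", {
  # identical vectors with 5 hets and 3 homs
  v <- c(1, 1, 1, 1, 1, 0, 2, 0)
  g <- genotype_matrix(rbind(a = v, b = v))
  pc <- pair_counts(g)
  expect_equal(pc$n_hethet["a", "b"], 5)
  expect_equal(pc$n_opphom["a", "b"], 0)
  expect_equal(pc$n_het_i["a", "b"], 5)
  # fully opposite homozygotes
  g2 <- genotype_matrix(rbind(a = c(0, 0, 2), b = c(2, 2, 0)))
  pc2 <- pair_counts(g2)
  expect_equal(pc2$n_opphom["a", "b"], 3)
  expect_equal(pc2$n_hethet["a", "b"], 0)
})

test_that("robust_kinship calibrates at 0.5 for identical genomes and goes
          negative for opposite ones", {
  set.seed(11)
  v <- rbinom(120, 2, 0.4)
  v[1:10] <- 1  # guarantee heterozygotes
  g <- genotype_matrix(rbind(a = v, b = v))
  k <- robust_kinship(pair_counts(g), min_variants = 10)
  expect_equal(k$phi["a", "b"], 0.5)
  expect_equal(diag(k$phi), c(a = 0.5, b = 0.5))

  # many opposite homozygotes, no shared hets -> negative estimate retained
  a <- c(rep(0, 50), rep(2, 50), 1, 1, 0, 0)
  b <- c(rep(2, 50), rep(0, 50), 0, 0, 1, 1)
  g2 <- genotype_matrix(rbind(a = a, b = b))
  k2 <- robust_kinship(pair_counts(g2), min_variants = 10)
  expect_lt(k2$phi["a", "b"], 0)
})

test_that("robust_kinship is invariant to allele-label flips", {
  g <- random_geno(15, 300, seed = 21)
  k1 <- robust_kinship(pair_counts(g), min_variants = 10)
  d <- g$dosage
  set.seed(22)
  flip <- runif(ncol(d)) < 0.5
  d[, flip] <- 2 - d[, flip]
  # bypass the container's automatic minor-allele orientation: counts only
  pc <- pair_counts(structure(list(dosage = d, ids = rownames(d)),
                              class = "genotype_matrix"))
  k2 <- robust_kinship(pc, min_variants = 10)
  expect_equal(k2$phi, k1$phi)
})

test_that("unestimable pairs fall back to pedigree kinship and are counted", {
  ped <- trio_ped()
  phi <- expected_kinship(ped)
  set.seed(77)
  d <- matrix(rbinom(3 * 60, 2, 0.4), 3, 60,
              dimnames = list(ped$iid, NULL))
  d["kid", 6:60] <- NA  # kid shares only 5 sites with either parent
  g <- genotype_matrix(d)
  expect_message(k <- robust_kinship(pair_counts(g), phi = phi,
                                     min_variants = 10),
                 "unestimable")
  expect_equal(attr(k, "n_unestimable"), 2L)
  expect_equal(k$phi["dad", "kid"], 0.25)  # imputed from the pedigree
  expect_equal(k$phi["mom", "kid"], 0.25)

  # nothing estimable at all -> error even with phi available
  g2 <- genotype_matrix(matrix(1, 3, 3, dimnames = list(ped$iid, NULL)))
  expect_error(suppressMessages(robust_kinship(pair_counts(g2), phi = phi,
                                               min_variants = 5)),
               "all pairs unestimable")
})

test_that("gene-dropped PSGRM recovers pedigree kinship by relationship class", {
  cfg <- sim_config(n_families = 8, genes_per_pathway = 10,
                    variants_per_gene = 200, seed = 99)
  ped <- simulate_pedigree(cfg)
  g <- gene_drop(ped, cfg)
  phi <- expected_kinship(ped)
  k <- psgrm(g, phi = phi)
  up <- upper.tri(phi$phi)
  cls <- cut(phi$phi[up], c(-Inf, 0.01, 0.1, 0.2, 0.3, Inf))
  dev <- tapply(k$phi[up] - phi$phi[up], cls, mean)
  expect_true(all(abs(dev[!is.na(dev)]) < 0.05))
  # overall deviation small with 2000 variants
  expect_lt(mean(abs(k$phi[up] - phi$phi[up])), 0.03)
})

test_that("estimator consistency: deviation shrinks as variants grow", {
  cfg0 <- sim_config(n_families = 5, seed = 5)
  ped <- simulate_pedigree(cfg0)
  phi <- expected_kinship(ped)
  up <- upper.tri(phi$phi)
  devs <- sapply(c(250, 1000, 4000), function(m) {
    cfg <- sim_config(n_families = 5, genes_per_pathway = 1,
                      variants_per_gene = m, seed = 5)
    g <- gene_drop(ped, cfg)
    k <- psgrm(g, phi = phi)
    mean(abs(k$phi[up] - phi$phi[up]))
  })
  expect_true(all(diff(devs) < 0))
})

test_that("make_kernel repairs indefiniteness and keeps PSD inputs intact", {
  # PSD input untouched
  phi <- expected_kinship(three_gen_ped())
  K <- make_kernel(kinship_matrix(phi$phi, kind = "empirical"))
  expect_equal(attr(K, "repair_delta"), 0)
  expect_equal(unname(K), unname(2 * phi$phi), ignore_attr = TRUE)

  # forced indefinite 2x2: phi scale [[0.5,-0.75],[-0.75,0.5]]
  m <- matrix(c(0.5, -0.75, -0.75, 0.5), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  K2 <- make_kernel(kinship_matrix(m, kind = "empirical"), mode = "bend")
  ev <- eigen(K2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(min(ev), 0, tolerance = 1e-12)
  expect_gt(attr(K2, "repair_delta"), 0)

  # clip zeroes negative off-diagonals first
  K3 <- make_kernel(kinship_matrix(m, kind = "empirical"), mode = "clip")
  expect_gte(min(eigen(K3, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  expect_equal(K3["a", "b"], 0)

  # raw passes through
  K4 <- make_kernel(kinship_matrix(m, kind = "empirical"), mode = "raw")
  expect_equal(unname(K4), unname(2 * m), ignore_attr = TRUE)
})

test_that("bend repair distance is bounded by the negative eigenvalue mass", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 12
    m <- matrix(rnorm(n * n, sd = 0.2), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0.5
    e <- kinship_matrix(m, kind = "empirical")
    K <- make_kernel(e, mode = "bend")
    ev <- eigen(2 * m, symmetric = TRUE, only.values = TRUE)$values
    neg_mass <- sum(abs(ev[ev < 0]))
    # flooring alone moves the matrix by sqrt(sum(neg^2)) <= sum|neg|;
    # diagonal rescaling adds a comparable amount at most
    expect_lte(attr(K, "repair_delta"), 2 * neg_mass + 1e-8)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("kernel writer round-trips", {
  g <- random_geno(8, 150, seed = 44)
  e <- robust_kinship(pair_counts(g), min_variants = 10)
  K <- make_kernel(e)
  sq <- withr::local_tempfile(fileext = ".tsv")
  write_kernel(K, sq, n_variants = e$n_variants)
  k2 <- read_kinship(sq)
  expect_equal(2 * k2$phi, K, ignore_attr = TRUE, tolerance = 1e-9)
})
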