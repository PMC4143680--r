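# Shared fixture builders. Everything is generated in code at test time.

# trio: two founders + child
trio_ped <- function() {
  pedigree(fid = c("T", "T", "T"), iid = c("dad", "mom", "kid"),
           father = c("0", "0", "dad"), mother = c("0", "0", "mom"),
           sex = c(1L, 2L, 1L))
}

# two founder couples, full sibs in F1, one F2 from a sib-cousin setup
three_gen_ped <- function() {
  pedigree(
    fid = rep("A", 8),
    iid = c("gf", "gm", "s1", "s2", "sp1", "sp2", "c1", "c2"),
    father = c("0", "0", "gf", "gf", "0", "0", "s1", "s2"),
    mother = c("0", "0", "gm", "gm", "0", "0", "sp1", "sp2"),
    sex = c(1L, 2L, 1L, 1L, 2L, 2L, 1L, 2L))
}

# full-sib mating: child of sibs is inbred, phi_ii = 0.625
incest_ped <- function() {
  pedigree(fid = rep("I", 5), iid = c("f", "m", "b1", "b2", "kid"),
           father = c("0", "0", "f", "f", "b1"),
           mother = c("0", "0", "m", "m", "b2"),
           sex = c(1L, 2L, 1L, 2L, 1L))
}

write_ped_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".ped",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# random pedigree via the simulator with small settings
random_ped <- function(seed, n_families = 2, generations = 3,
                       sibship_lambda = 1.5) {
  simulate_pedigree(sim_config(n_families = n_families,
                               generations = generations,
                               sibship_lambda = sibship_lambda,
                               seed = seed))
}

# random genotype matrix with optional missingness
random_geno <- function(n, m, seed, miss = 0, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.05, 0.5)
  d <- sapply(maf, function(p) rbinom(n, 2, p))
  if (miss > 0) d[runif(length(d)) < miss] <- NA
  genotype_matrix(matrix(d, nrow = n))
}

# Monte-Carlo gene-dropping kinship oracle: drops uniquely labelled founder
# alleles down the pedigree and estimates phi_ij as the probability that a
# random allele from i matches a random allele from j identically by
# descent. Vectorized over `drops` independent loci.
gene_drop_kinship_mc <- function(ped, drops = 200000, seed = 1) {
  set.seed(seed)
  n <- length(ped$iid)
  H1 <- matrix(0L, n, drops)
  H2 <- matrix(0L, n, drops)
  next_label <- 1L
  for (i in ped$order) {
    f <- ped$fidx[i]; m <- ped$midx[i]
    if (is.na(f)) {
      H1[i, ] <- next_label; next_label <- next_label + 1L
    } else {
      pick <- runif(drops) < 0.5
      H1[i, ] <- ifelse(pick, H1[f, ], H2[f, ])
    }
    if (is.na(m)) {
      H2[i, ] <- next_label; next_label <- next_label + 1L
    } else {
      pick <- runif(drops) < 0.5
      H2[i, ] <- ifelse(pick, H1[m, ], H2[m, ])
    }
  }
  est <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
  se <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
  for (i in seq_len(n)) {
    for (j in i:n) {
      sh <- ((H1[i, ] == H1[j, ]) + (H1[i, ] == H2[j, ]) +
               (H2[i, ] == H1[j, ]) + (H2[i, ] == H2[j, ])) / 4
      if (i == j) sh <- (2 + (H1[i, ] == H2[i, ]) * 2) / 4
      est[i, j] <- est[j, i] <- mean(sh)
      se[i, j] <- se[j, i] <- stats::sd(sh) / sqrt(drops)
    }
  }
  list(phi = est, se = se)
}

# Dense-matrix MVN profiled log-likelihood: independent oracle for the
# spectral fitting path (direct solve / determinant, no eigen trick).
dense_profile_loglik <- function(y, X, Omega) {
  n <- length(y)
  Oi <- solve(Omega)
  beta <- solve(t(X) %*% Oi %*% X, t(X) %*% Oi %*% y)
  r <- y - X %*% beta
  q <- drop(t(r) %*% Oi %*% r)
  s2 <- q / n
  ld <- determinant(Omega, logarithm = TRUE)$modulus[1]
  list(loglik = -0.5 * (n * log(2 * pi * s2) + ld + n),
       beta = drop(beta), sigma2 = s2)
}
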