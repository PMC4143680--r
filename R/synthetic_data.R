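#' Simulation configuration
#'
#' Collects every knob of the synthetic study generator. Defaults describe
#' the study design the package is calibrated against: 20 three-generation
#' extended families (about 600 individuals), whole-pathway gene-dropped
#' genotypes with a rare/common founder MAF mixture, a quantitative trait
#' with mean 120 and total variance 225 (a systolic-blood-pressure-like
#' scale), sex/age/smoking covariate effects, residual polygenic fraction
#' `h2r = 0.3` and no pathway effect unless requested.
#'
#' @param n_families Number of independent families (default 20).
#' @param generations Generations per family (default 3).
#' @param sibship_lambda Sibship sizes are `1 + Poisson(sibship_lambda)`
#'   (default 3.4, giving ~30 members per three-generation family).
#' @param n_pathways Number of synthetic pathways (default 1).
#' @param genes_per_pathway Genes per pathway (default 10).
#' @param variants_per_gene Variants per gene (default 200).
#' @param maf_rare_frac Fraction of variants drawn from the rare MAF range
#'   (default 0.2).
#' @param maf_rare_range,maf_common_range Uniform founder-MAF ranges for
#'   rare and common variants (defaults U(0.001, 0.01) and U(0.05, 0.5)).
#' @param h2r Target residual polygenic variance fraction (default 0.3).
#' @param h2gp Target pathway-specific variance fraction (default 0).
#' @param causal_pathway Index of the pathway carrying the causal variants
#'   when `h2gp > 0` (default 1).
#' @param causal_frac Fraction of the causal pathway's variants that are
#'   causal (default 0.1).
#' @param causal_min_maf Causal variants are sampled among variants with
#'   founder MAF at or above this (default 0.05); per-variant effects are
#'   frequency-standardized (variance-equalized), so allowing very rare
#'   causal variants would concentrate the signal in a few copies.
#' @param beta_sex,beta_age,beta_smoke Covariate effects in trait units
#'   (defaults 5, 0.5, 6).
#' @param trait_mean,sigma2_total Trait intercept and total residual
#'   variance (defaults 120, 225).
#' @param ld_block If TRUE, founder haplotypes within a gene are generated
#'   with block copying (positive within-gene LD); default FALSE
#'   (independent variants).
#' @param ld_switch Haplotype switch probability per adjacent variant in
#'   `ld_block` mode (default 0.1).
#' @param seed Integer RNG seed recorded in every output header.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 20, generations = 3,
                       sibship_lambda = 3.4,
                       n_pathways = 1, genes_per_pathway = 10,
                       variants_per_gene = 200,
                       maf_rare_frac = 0.2,
                       maf_rare_range = c(0.001, 0.01),
                       maf_common_range = c(0.05, 0.5),
                       h2r = 0.3, h2gp = 0,
                       causal_pathway = 1, causal_frac = 0.1,
                       causal_min_maf = 0.05,
                       beta_sex = 5, beta_age = 0.5, beta_smoke = 6,
                       trait_mean = 120, sigma2_total = 225,
                       ld_block = FALSE, ld_switch = 0.1,
                       seed = 1) {
  cfg <- as.list(environment())
  if (cfg$h2r + cfg$h2gp >= 1) stop("h2r + h2gp must be < 1")
  stopifnot(n_families >= 1, generations >= 2, n_pathways >= 1,
            genes_per_pathway >= 1, variants_per_gene >= 1,
            maf_rare_frac >= 0, maf_rare_frac <= 1, sigma2_total > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-generation pedigree
#'
#' Families are built generation by generation: a founder couple, each
#' child marries an unrelated founder who joins the pedigree, and each
#' couple's sibship size is `1 + Poisson(sibship_lambda)`. Members of the
#' last generation are unmarried. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A [pedigree].
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(cfg$seed %% .Machine$integer.max)
  fid <- iid <- father <- mother <- character(0)
  sex <- integer(0)
  for (f in seq_len(cfg$n_families)) {
    fam <- sprintf("F%02d", f)
    add <- function(id, pa, ma, sx) {
      fid <<- c(fid, fam); iid <<- c(iid, id)
      father <<- c(father, pa); mother <<- c(mother, ma)
      sex <<- c(sex, sx)
    }
    p1 <- paste0(fam, "_G1_1"); p2 <- paste0(fam, "_G1_2")
    add(p1, "0", "0", 1L); add(p2, "0", "0", 2L)
    couples <- list(c(p1, p2))
    counter <- 0L
    for (g in 2:cfg$generations) {
      next_couples <- list()
      for (cp in couples) {
        n_kids <- 1L + stats::rpois(1, cfg$sibship_lambda)
        for (k in seq_len(n_kids)) {
          counter <- counter + 1L
          kid <- sprintf("%s_G%d_%d", fam, g, counter)
          kid_sex <- sample(1:2, 1)
          add(kid, cp[1], cp[2], kid_sex)
          if (g < cfg$generations) {
            counter <- counter + 1L
            sp <- sprintf("%s_G%d_%d", fam, g, counter)
            add(sp, "0", "0", if (kid_sex == 1L) 2L else 1L)
            next_couples[[length(next_couples) + 1L]] <-
              if (kid_sex == 1L) c(kid, sp) else c(sp, kid)
          }
        }
      }
      couples <- next_couples
    }
  }
  pedigree(fid, iid, father, mother, sex)
}

#' Lay out synthetic pathways, genes and variant coordinates
#'
#' Each pathway gets its own synthetic chromosome; gene `j` spans
#' `[(j-1)*50000 + 20001, (j-1)*50000 + 30000]` with its variants evenly
#' spaced inside the transcript, so default 5 kb windows never bleed into a
#' neighboring gene. Emits the matching transcript table and GMT structure
#' so the region-mapping code is exercised with real file formats.
#'
#' @param cfg A [sim_config()].
#' @return list with `variants` (data.frame chrom/pos/ref/alt/id/region/
#'   pathway), `transcripts` (transcript table), `gmt` (named list).
#' @keywords internal
pathway_layout <- function(cfg) {
  vrows <- list(); trows <- list(); gmt <- list()
  for (p in seq_len(cfg$n_pathways)) {
    chrom <- as.character(p)
    pname <- sprintf("PATHWAY_%02d", p)
    genes <- sprintf("P%02dG%02d", p, seq_len(cfg$genes_per_pathway))
    gmt[[pname]] <- genes
    for (j in seq_len(cfg$genes_per_pathway)) {
      tx_start <- (j - 1) * 50000 + 20001
      tx_end <- tx_start + 9999
      trows[[length(trows) + 1L]] <- data.frame(
        gene = genes[j], transcript = paste0(genes[j], ".t1"),
        chrom = chrom, strand = if (j %% 2) "+" else "-",
        txStart = tx_start, txEnd = tx_end, stringsAsFactors = FALSE)
      pos <- tx_start + round(seq(0, 9999,
                                  length.out = cfg$variants_per_gene))
      pos <- pos + seq_len(cfg$variants_per_gene) %% 2  # de-tie rounding
      vrows[[length(vrows) + 1L]] <- data.frame(
        chrom = chrom, pos = as.integer(pos), ref = "A", alt = "C",
        id = sprintf("%s_v%03d", genes[j], seq_len(cfg$variants_per_gene)),
        region = genes[j], pathway = pname, stringsAsFactors = FALSE)
    }
  }
  list(variants = do.call(rbind, vrows),
       transcripts = do.call(rbind, trows), gmt = gmt)
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder haplotype alleles are Bernoulli draws at per-variant founder
#' MAFs; every offspring inherits one uniformly chosen allele from each
#' parent, independently per variant (unlinked variants; optional
#' within-gene block LD via `cfg$ld_block`). Deterministic given
#' `cfg$seed`.
#'
#' @param ped A [pedigree].
#' @param cfg A [sim_config()].
#' @param variants Optional variant metadata data.frame (from
#'   [pathway_layout()]); default generates
#'   `n_pathways * genes_per_pathway * variants_per_gene` variants.
#' @param maf Optional vector of founder MAFs (length = number of
#'   variants); default drawn from the configured rare/common mixture.
#' @return A [genotype_matrix] with attributes `founder_maf` (the
#'   generating MAFs) and `pathway` (per-variant pathway label, when
#'   `variants` carries one).
#' @export
gene_drop <- function(ped, cfg, variants = NULL, maf = NULL) {
  set.seed((cfg$seed + 1) %% .Machine$integer.max)
  if (is.null(variants)) variants <- pathway_layout(cfg)$variants
  m <- nrow(variants)
  n <- length(ped$iid)
  if (is.null(maf)) {
    rare <- stats::runif(m) < cfg$maf_rare_frac
    maf <- ifelse(rare,
                  stats::runif(m, cfg$maf_rare_range[1], cfg$maf_rare_range[2]),
                  stats::runif(m, cfg$maf_common_range[1], cfg$maf_common_range[2]))
  }
  stopifnot(length(maf) == m)
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  draw_founder_hap <- function() {
    if (!cfg$ld_block) return(as.integer(stats::runif(m) < maf))
    # block LD: latent uniform copied along a gene, refreshed on switch
    u <- stats::runif(m)
    gene <- variants$region
    refresh <- c(TRUE, gene[-1] != gene[-m]) | stats::runif(m) < cfg$ld_switch
    for (t in seq_len(m)) if (!refresh[t]) u[t] <- u[t - 1]
    as.integer(u < maf)
  }
  for (i in ped$order) {
    if (ped$founder[i]) {
      H1[i, ] <- draw_founder_hap()
      H2[i, ] <- draw_founder_hap()
    } else {
      f <- ped$fidx[i]; m_ <- ped$midx[i]
      pick <- stats::runif(m) < 0.5
      H1[i, ] <- if (!is.na(f)) ifelse(pick, H1[f, ], H2[f, ])
                 else draw_founder_hap()
      pick <- stats::runif(m) < 0.5
      H2[i, ] <- if (!is.na(m_)) ifelse(pick, H1[m_, ], H2[m_, ])
                 else draw_founder_hap()
    }
  }
  dos <- H1 + H2
  rownames(dos) <- ped$iid
  g <- genotype_matrix(dos, variants[, c("chrom", "pos", "ref", "alt", "id",
                                         "region")[
                           c("chrom", "pos", "ref", "alt", "id", "region")
                           %in% names(variants)], drop = FALSE])
  attr(g, "founder_maf") <- maf
  if ("pathway" %in% names(variants)) attr(g, "pathway") <- variants$pathway
  g
}

#' Simulate a phenotype with known variance fractions
#'
#' Builds `y = mu + X beta + g_poly + g_path + eps`:
#' \itemize{
#'   \item covariates: sex from the pedigree (female = 1), age ~ U(20, 80),
#'     smoking ~ Bernoulli(0.3);
#'   \item `g_poly` ~ MVN(0, sigma2 h2r 2Phi), sampled through the
#'     Cholesky root of 2Phi;
#'   \item `g_path`: frequency-standardized effects on the sampled causal
#'     variants of the causal pathway;
#'   \item `eps` i.i.d. normal with the remaining fraction.
#' }
#' Each random component is rescaled so its realized sample variance
#' equals its target fraction of `sigma2_total` exactly (recorded in the
#' returned truth object), which makes per-replicate "truth" well defined
#' for parameter-recovery studies.
#'
#' @param ped A [pedigree].
#' @param g A [genotype_matrix] from [gene_drop()] (needed when
#'   `cfg$h2gp > 0`).
#' @param cfg A [sim_config()].
#' @param phi Optional precomputed theoretical [kinship_matrix].
#' @param chol_2phi Optional precomputed upper Cholesky factor of
#'   2 Phi (+ 1e-8 I), aligned to `ped$iid`; reused across replicates.
#' @param replicate Integer stirred into the seed so replicate r is
#'   reproducible in isolation.
#' @param covariate_data Optional data.frame with columns `SEX`, `AGE`,
#'   `SMOKE` aligned to `ped$iid`. In multi-replicate studies the
#'   covariates are part of the fixed study design: draw them once
#'   (replicate 1) and pass them here so later replicates redraw only the
#'   random trait components.
#' @return list with `pheno` (data.frame IID, TRAIT, SEX, AGE, SMOKE) and
#'   `truth` (list: targets, realized fractions, causal variant ids and
#'   effects, per-individual genetic values).
#' @export
simulate_phenotype <- function(ped, g, cfg, phi = NULL, chol_2phi = NULL,
                               replicate = 1, covariate_data = NULL) {
  set.seed((cfg$seed + 1000L * replicate + 2L) %% .Machine$integer.max)
  n <- length(ped$iid)
  s2 <- cfg$sigma2_total
  if (cfg$h2gp > 0 && (is.null(g) || is_empty_genotypes(g))) {
    stop("h2gp > 0 requires gene-dropped genotypes")
  }
  if (is.null(covariate_data)) {
    sex <- as.integer(ped$sex == 2L)  # female = 1
    sex[is.na(sex)] <- 0L
    age <- stats::runif(n, 20, 80)
    smoke <- stats::rbinom(n, 1, 0.3)
  } else {
    stopifnot(nrow(covariate_data) == n)
    sex <- covariate_data$SEX
    age <- covariate_data$AGE
    smoke <- covariate_data$SMOKE
  }

  rescale <- function(x, target_var) {
    v <- stats::var(x)
    if (v <= 0) {
      if (target_var > 0) stop("degenerate component: variance target ",
                               target_var, " infeasible")
      return(x * 0)
    }
    (x - mean(x)) * sqrt(target_var / v)
  }

  g_poly <- numeric(n)
  if (cfg$h2r > 0) {
    if (is.null(chol_2phi)) {
      if (is.null(phi)) phi <- expected_kinship(ped)
      chol_2phi <- chol(2 * align_kinship(phi, ped$iid)$phi +
                          diag(1e-8, n))
    }
    g_poly <- rescale(drop(crossprod(chol_2phi, stats::rnorm(n))),
                      cfg$h2r * s2)
  }

  g_path <- numeric(n)
  causal <- character(0); effects <- numeric(0)
  if (cfg$h2gp > 0) {
    pw <- attr(g, "pathway")
    in_pw <- if (is.null(pw)) rep(TRUE, n_variants(g))
             else pw == sprintf("PATHWAY_%02d", cfg$causal_pathway)
    eligible <- which(in_pw & !is.na(g$maf) & g$maf >= cfg$causal_min_maf)
    if (!length(eligible)) stop("no eligible causal variants (MAF >= ",
                                cfg$causal_min_maf, ")")
    n_causal <- max(1L, round(cfg$causal_frac * sum(in_pw)))
    idx <- sort(sample(eligible, min(n_causal, length(eligible))))
    p <- g$maf[idx]
    effects <- stats::rnorm(length(idx)) / sqrt(2 * p * (1 - p))
    D <- g$dosage[ped$iid, idx, drop = FALSE]
    D[is.na(D)] <- 0
    g_path <- rescale(drop(D %*% effects), cfg$h2gp * s2)
    causal <- g$variants$id[idx]
  }

  e2 <- 1 - cfg$h2r - cfg$h2gp
  eps <- rescale(stats::rnorm(n), e2 * s2)
  y <- cfg$trait_mean + cfg$beta_sex * sex + cfg$beta_age * age +
    cfg$beta_smoke * smoke + g_poly + g_path + eps

  pheno <- data.frame(IID = ped$iid, TRAIT = y, SEX = sex, AGE = age,
                      SMOKE = smoke, stringsAsFactors = FALSE)
  truth <- list(h2r = cfg$h2r, h2gp = cfg$h2gp,
                h2r_realized = stats::var(g_poly) / s2,
                h2gp_realized = stats::var(g_path) / s2,
                causal = causal, effects = effects,
                g_poly = g_poly, g_path = g_path)
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete study (pedigree, genotypes, pathways, phenotype)
#'
#' One call producing every input the screening pipeline consumes, in
#' memory and optionally on disk in the pipeline's native formats (PED,
#' VCF 4.2, GMT, transcript table, phenotype TSV).
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; when given, writes `sim.ped`,
#'   `sim.vcf`, `sim.gmt`, `sim_transcripts.tsv`, `sim_pheno.tsv`.
#' @return list with `ped`, `genotypes`, `gmt`, `transcripts`, `pheno`,
#'   `truth`, `phi`, `config`, and `files` (paths, when written).
#' @export
simulate_study <- function(cfg, out_dir = NULL) {
  layout <- pathway_layout(cfg)
  ped <- simulate_pedigree(cfg)
  g <- gene_drop(ped, cfg, variants = layout$variants)
  phi <- expected_kinship(ped)
  sim <- simulate_phenotype(ped, g, cfg, phi = phi)
  out <- list(ped = ped, genotypes = g, gmt = layout$gmt,
              transcripts = layout$transcripts, pheno = sim$pheno,
              truth = sim$truth, phi = phi, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      ped = file.path(out_dir, "sim.ped"),
      vcf = file.path(out_dir, "sim.vcf"),
      gmt = file.path(out_dir, "sim.gmt"),
      transcripts = file.path(out_dir, "sim_transcripts.tsv"),
      pheno = file.path(out_dir, "sim_pheno.tsv"))
    write_ped(ped, files$ped, seed = cfg$seed)
    write_sim_vcf(g, files$vcf, seed = cfg$seed)
    write_gmt(out$gmt, files$gmt)
    write_transcripts(out$transcripts, files$transcripts, seed = cfg$seed)
    write_phenotypes(sim$pheno, files$pheno, seed = cfg$seed)
    out$files <- files
  }
  out
}

# ---- plain-text writers ---------------------------------------------------

#' Write a pedigree in PED format
#' @param ped A [pedigree].
#' @param path Output path.
#' @param seed Optional seed recorded in a header comment.
#' @return Invisibly, `path`.
#' @export
write_ped <- function(ped, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  tab <- data.frame(ped$fid, ped$iid,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    ifelse(is.na(ped$sex), 0L, ped$sex))
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write simulated genotypes as a VCF 4.2 file
#'
#' Emits unphased GT calls with contig header lines; dosage is written as
#' the ALT allele count.
#'
#' @param g A [genotype_matrix].
#' @param path Output path (plain text).
#' @param seed Optional seed recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_sim_vcf <- function(g, path, seed = NULL) {
  v <- g$variants
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  D <- g$dosage[, ord, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(seed)) writeLines(paste0("##simseed=", seed), con)
  for (ch in unique(v$chrom)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                       max(v$pos[v$chrom == ch]) + 10000L), con)
  }
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$ids), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(k) {
    dos <- D[, k]
    gt <- ifelse(is.na(dos), "./.", gt_code[dos + 1])
    paste(c(v$chrom[k], v$pos[k], v$id[k],
            if (is.na(v$ref[k])) "A" else v$ref[k],
            if (is.na(v$alt[k])) "C" else v$alt[k],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write gene sets in GMT format
#' @param gmt Named list of gene-symbol vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gmt, path) {
  lines <- vapply(names(gmt), function(nm) {
    paste(c(nm, "synthetic", gmt[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a transcript table
#' @param transcripts data.frame as from [read_transcripts()].
#' @param path Output path.
#' @param seed Optional seed recorded in a header comment.
#' @return Invisibly, `path`.
#' @export
write_transcripts <- function(transcripts, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  utils::write.table(transcripts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a phenotype/covariate table
#' @param pheno data.frame with IID, TRAIT and covariate columns.
#' @param path Output path.
#' @param seed Optional seed recorded in a header comment.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(pheno, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  utils::write.table(pheno, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
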