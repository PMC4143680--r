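# pathkin

Pathway-specific genetic relationship matrix (PSGRM) screening for
quantitative traits on pedigrees.

## The problem

Whole-genome sequencing of family studies yields tens of millions of
variants; testing them one at a time buries real signal under multiple
testing. `pathkin` reduces the problem to one test per *gene pathway*: all
sequence variants in or near the genes of a pathway are summarized into an
empirical kinship kernel, that kernel is added as a second random effect to
the standard pedigree-based polygenic model, and its contribution is tested
with a single degree-of-freedom likelihood-ratio test. Pathways that absorb
a significant share of trait heritability are candidates for focused
follow-up of their member genes. The intended users are statistical
geneticists working with extended pedigrees (family WGS studies), where
rare variants segregate and classical variance-component machinery applies.

## The model

For trait values with fixed effects Xβ (sex, age, smoking, optional genetic
PCs), the phenotypic covariance is

    Ω = σ²_Total ( 2Φ h²r + 2E h²gp + I e² ),   h²r + h²gp + e² = 1

where Φ is the expected pedigree kinship (recursion over parents), E is the
PSGRM — pairwise kinship estimated from the pathway's variants with the
robust (allele-frequency-free) estimator

    φ̂_ij = 1/2 − [N_Aa^(i) + N_Aa^(j) − 2·N_Aa,Aa + 4·N_AA,aa]
                 / [4·min(N_Aa^(i), N_Aa^(j))]

— and I is the identity. Null (h²gp = 0) and alternative models are fitted
by maximum likelihood; T = 2(ℓ_alt − ℓ_null) is referred to a 50:50 mixture
of a point mass at zero and χ²₁ because the parameter is tested on its
boundary: p = ½·P(χ²₁ ≥ T) for T > 0 and p = 1 at T = 0.

See `vignettes/pathkin-methods.Rmd` for estimator details, the kernel-mixing
fitting strategy, PSD repair of indefinite kernels, and the simulator's
assumptions.

## Worked example

Simulate a study (10 extended families, 5 pathways of 5 genes × 80
variants, pathway 3 carrying h²gp = 0.2) and screen it:

```r
library(pathkin)

cfg <- sim_config(n_families = 10, n_pathways = 5, genes_per_pathway = 5,
                  variants_per_gene = 80, h2r = 0.3, h2gp = 0.2,
                  causal_pathway = 3, seed = 42)
sim <- simulate_study(cfg, out_dir = "demo")

sim$ped
#> pedigree: 290 individuals, 10 family(ies), 63 founders
sim$genotypes
#> genotype_matrix: 290 samples x 2000 variants; median MAF 0.217

res <- screen_pathways(sim$files$vcf, sim$files$ped, sim$files$pheno,
                       sim$files$gmt, sim$files$transcripts)
res[, c("pathway", "n_variants", "h2gp", "lrt", "p", "status")]
#>      pathway n_variants   h2gp  lrt       p status
#> 1 PATHWAY_03        400 0.2841 6.99 0.00409     ok
#> 2 PATHWAY_01        400 0.0902 1.46 0.11341     ok
#> 3 PATHWAY_04        400 0.0630 1.04 0.15375     ok
#> 4 PATHWAY_02        400 0.0000 0.00 1.00000     ok
#> 5 PATHWAY_05        400 0.0000 0.00 1.00000     ok
```

The planted causal pathway ranks first: its kernel absorbs an estimated
28% of trait variance (ĥ²gp = 0.28, true 0.2 — single-replicate noise),
with boundary-mixture p = 0.004. The two pathways whose kernels add
nothing sit exactly at the boundary (T = 0, p = 1), which is the expected
behavior in about half of truly null fits.

The same pipeline is scriptable via subcommands (`simulate`, `regions`,
`pca`, `grm`, `screen`, `diag`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pathkin", package = "pathkin"))')
Rscript "$CLI" simulate --out demo --seed 42 --families 10
Rscript "$CLI" screen --vcf demo/sim.vcf --ped demo/sim.ped \
  --pheno demo/sim_pheno.tsv --gmt demo/sim.gmt \
  --genes demo/sim_transcripts.tsv --out demo/screen
```

Every run writes a `manifest.json` (version, seed, config hash, input
checksums).

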