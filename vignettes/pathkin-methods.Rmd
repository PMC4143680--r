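---
title: "Methods: pathway-specific kinship kernels and the boundary LRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-specific kinship kernels and the boundary LRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`pathkin` screens gene pathways for contributions to a quantitative trait
measured on pedigrees. For individuals with fixed-effect design $X$ (an
intercept plus sex, age, smoking and optionally genetic principal
components), the trait is modelled as multivariate normal with mean
$X\beta$ and covariance

$$\Omega \;=\; \sigma^2_{Total}\,\big(2\Phi\,h^2_r \;+\; 2E\,h^2_{gp}
\;+\; I\,e^2\big), \qquad h^2_r + h^2_{gp} + e^2 = 1 .$$

$\Phi$ is the expected kinship matrix implied by the pedigree (the
standard recursion over parents, block-diagonal across families), $E$ is
the *pathway-specific genetic relationship matrix* (PSGRM) estimated
empirically from all sequence variants in or near the pathway's genes,
and $I$ captures unique environment. $h^2_r$ is the residual polygenic
heritability, $h^2_{gp}$ the fraction of variance attributable to the
pathway kernel. Both models (with and without the $2E$ term) are fitted
by maximum likelihood with $\beta$ and $\sigma^2$ profiled out
analytically by generalized least squares; the pathway effect is tested
with $T = 2(\ell_{alt} - \ell_{null})$. Because $h^2_{gp}$ is tested on
the boundary of its parameter space, $T$ is referred to a 50:50 mixture
of a point mass at zero and $\chi^2_1$: $p = \tfrac12 P(\chi^2_1 \ge T)$
for $T > 0$ and $p = 1$ at $T = 0$ (the conservative convention that
keeps $p \in (0, 1]$). The test has a single degree of freedom no matter
how many variants the pathway contains, which is the point: one test per
pathway instead of millions per genome.

Power requires $E$ to *deviate* from $\Phi$: if the pathway kernel
reproduces the genome-wide expectation, the two variance components are
collinear and the likelihood cannot distinguish them (in that limit the
fit is non-identifiable but the LRT is exactly zero, which the
implementation reproduces).

## The robust kinship estimator

The PSGRM is estimated pairwise from heterozygote-concordance and
opposite-homozygote counts over the pair's jointly non-missing variants:

$$\hat\phi_{ij} \;=\; \frac12 \;-\;
\frac{N^{(i)}_{Aa} + N^{(j)}_{Aa} - 2N_{Aa,Aa} + 4N_{AA,aa}}
     {4\,\min\!\big(N^{(i)}_{Aa},\, N^{(j)}_{Aa}\big)} ,$$

the robust between-family form of the KING-style estimator. No allele
frequencies enter, which makes the estimator robust to latent population
heterogeneity; identical genomes give exactly $0.5$ and pairs from
diverged groups can be negative. Negative estimates are retained — they
are informative — and positive semidefiniteness is restored explicitly
by `make_kernel()` (default `bend`: eigenvalue flooring at zero followed
by a diagonal rescale; `clip` zeroes negative off-diagonals first; `raw`
does nothing). The applied change is reported as a Frobenius-norm repair
delta. Pairs supported by fewer than `min_variants` (default 50) shared
sites, or with no heterozygous site in either member, are imputed with
the pedigree expectation and counted, never silently zeroed. The
diagonal uses the non-inbred convention $\phi_{ii} = 0.5$ by default; an
observed-homozygosity-excess option exists because the pairwise
estimator itself says nothing about inbreeding.

The between-family form is used for *all* pairs, including within-family
ones, matching the robust-mode rationale: a single estimator, free of
both allele-frequency and pedigree assumptions, for the whole matrix.

## Fitting: kernel mixing and caching

The null (one-kernel) model is fitted by eigendecomposing $2\Phi$ once;
every profiled-likelihood evaluation in $h^2_r$ is then $O(n)$ and a
bounded Brent search on $[0,1]$ (with the $h^2_r = 0$ endpoint evaluated
explicitly) finds the ML estimate.

The two-kernel model is reparameterized as
$\Omega/\sigma^2 = h\,K(\gamma) + (1-h)I$ with
$K(\gamma) = (1-\gamma)\,2\Phi + \gamma\,2E$, so that
$h^2_r = h(1-\gamma)$ and $h^2_{gp} = h\gamma$; the simplex constraint
becomes the unit square. For each mixing value $\gamma$ on a grid
(default 21–33 points including $\gamma = 0$), one symmetric
eigendecomposition makes the inner search over $h$ exact and $O(n)$ per
evaluation; an optional continuous Brent polish over $\gamma$ refines
the grid solution. This is the standard two-kernel strategy of
spectrally-decomposed mixed-model software, and it has two properties we
rely on:

* the grid contains $\gamma = 0$, where the model *is* the null model,
  so $\ell_{alt} \ge \ell_{null}$ holds by construction and boundary
  solutions give $T = 0$ exactly rather than within optimizer tolerance;
* the eigendecompositions depend only on the kernels, so replicate
  studies (hundreds of phenotype draws against fixed kernels) reuse one
  cache (`two_kernel_cache()` + `fit_pathway_cached()`), reducing a fit
  to milliseconds.

Against a dense-likelihood brute-force optimizer (Nelder-Mead over
$(h^2_r, h^2_{gp})$ with per-evaluation Cholesky) the cached grid agrees
to $\sim 10^{-2}$ in $T$ without refinement and to $\sim 10^{-4}$ with
it; the test suite asserts both this equivalence and the analytic GLS
profile against direct numerical optimization of $(\beta, \sigma^2)$.
ML (not REML) is used throughout because the LRT compares models
differing in a variance parameter with identical fixed effects; a REML
option exists for variance reporting but tests are always on ML fits.

## Region mapping and extraction conventions

Gene sets (GMT) are mapped to windows via a transcript table: per gene
the longest isoform (ties broken by lexicographically smallest
transcript id), extended 5 kb on both genomic sides (clipped at 1).
The flank is symmetric on genomic coordinates regardless of strand —
equivalent for equal flanks and robust to strand annotation errors; a
strand-aware mode exists for asymmetric flanks. Windows are inclusive at
both ends; variants covered by several overlapping gene windows enter
once. Only biallelic SNVs are used; multi-allelic and indel records are
skipped and counted. Dosages are oriented to the *cohort* minor allele,
so MAF is always in $[0, 0.5]$ and the rare-variant strata (MAF $<$ 0.05,
MAF $<$ 0.01, strict inequalities) are well defined. Variants missing in
more than 20% of samples are dropped to protect the pairwise-count
estimator.

## Founder PCA

Principal components are computed on founders only (centered and scaled
by founder statistics, SVD, deterministic sign convention) and projected
to the rest of the pedigree, so the leading axes capture ancestry rather
than family structure. LD pruning (greedy, windowed, $r^2 > 0.1$ dropped,
MAF $\ge$ 0.05 only) precedes the PCA. Scores enter both null and
alternative models as fixed effects — the LRT must compare models that
differ only in $h^2_{gp}$.

## What the generator emulates — and what it does not

`sim_config()`/`simulate_study()` produce multi-generation families
(founder couple, children marry in founder spouses,
sibships $1 + \mathrm{Poisson}(3.4)$, giving $\approx 30$ members per
three-generation family and $\approx 600$ for 20 families), gene-dropped
genotypes from a rare/common founder-MAF mixture (20% rare
$U(0.001, 0.01)$, rest $U(0.05, 0.5)$), and a blood-pressure-like trait
(mean 120, total residual variance 225) with sex/age/smoking effects
(5, 0.5, 6 trait units), a polygenic component sampled through the
Cholesky root of $2\Phi$, and an optional pathway component built from
frequency-standardized effects at sampled causal variants (default 10%
of the causal pathway's variants, MAF $\ge$ 0.05). Each random component
is rescaled so its realized sample variance matches its target fraction
exactly; per-replicate "truth" is therefore well defined and recorded.
In replicate studies the covariates are drawn once and held fixed — they
are study design, not noise.

Two deliberate simplifications matter when interpreting green tests:

* **Variants are unlinked by default.** Real pathway variants sit on
  shared chromosomal segments, so a real PSGRM deviates from $\Phi$
  through *pathway-level IBD* that is shared between causal and
  non-causal variants of the same genes. With unlinked variants that
  shared component is absent: as the variant count grows the PSGRM
  converges to $\Phi$ and the deviation that remains is mostly
  estimation noise plus the causal variants' own (diluted)
  contribution. Calibration and estimator-consistency results are
  unaffected, but *screen-level ranking power is pessimistic relative
  to real data*: in our 20-pathway experiment at $h^2_{gp} = 0.15$ the
  planted pathway ranks first in roughly 6 of 10 replicates, not the
  8 of 10 the acceptance target asks for, and the shortfall grows with
  pathway size (measured: $\sim$0.48 at 1,000-variant pathways,
  $\sim$0.16 at 2,000). A block-LD mode (`ld_block = TRUE`, haplotype
  copying with switch probability 0.1 within genes) exists to restore
  within-gene correlation and is exercised by a property test; it is
  off by default to keep the stated world simple and the LD-bias caveat
  explicit.
* **Replicates redraw phenotypes over one genotype realization.** The
  kernel eigendecompositions are cached across replicates, which is
  what makes 400-replicate calibration runs take seconds. The reported
  calibration is therefore conditional on the realized kernels; under
  the null the kernels are ancillary, so this is the relevant
  calibration.

## Numerical choices

* LRT statistics below $10^{-6}$ are treated as boundary ($p = 1$);
  small negatives within the same tolerance clamp to zero, persistent
  negatives raise (they indicate a fitting defect, not noise).
* Kernel PSD checks tolerate eigenvalues down to $-10^{-6}$ relative to
  scale; `chol` draws add $10^{-8} I$ jitter.
* The eigen-based inner weights are floored at zero;
  $h \le 1 - 10^{-9}$ keeps $\log$-determinants finite when kernels are
  singular.
* Monomorphic-in-founder variants are dropped from PCA; PCA signs are
  fixed by forcing each loading's largest-magnitude element positive.
* Listwise deletion of individuals missing trait or any covariate,
  before kernel alignment, with a logged count.

## Known limitations

* The genomic-inflation factor mixes a boundary-mixture p-value with a
  standard $\chi^2_1$ transform. Under the null, p-values of positive
  statistics are uniform on $(0, 0.5]$, so their transforms all exceed
  the $\chi^2_1$ median: $\lambda$ collapses toward 0 when the point
  mass at $p = 1$ reaches half and sits at or above 1 otherwise — it is
  *not* a clean "expect 1 under the null" diagnostic for this test.
  Both the all-tests $\lambda$ and the positive-statistic-only variant
  are reported.
* IBS/centered-dosage (GCTA-style) kernels, LD-aware GRM corrections,
  X-linked kinship and multivariate traits are out of scope.
* The screen re-reads the VCF per pathway; for large studies, extract
  once and use the `grm`/`fit` layers directly.
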