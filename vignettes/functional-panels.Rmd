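---
title: "Benchmarking functional variant panels for genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking functional variant panels for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

Commercial dairy-cattle genomic selection runs on generic SNP-chip panels.
An alternative is to genotype only variants with functional evidence —
production-trait GWAS tags, cis molecular-QTL tags from RNA-seq
(exon expression, intron expression, splicing efficiency, allele-specific
expression), allele-specific binding and chromatin QTL, and
predicted-deleterious coding variants — and ask whether such a panel
predicts breeding values better than an equally sized random draw from the
chip.  `funcpanel` implements that comparison end to end: variant tagging,
LD-aware panel construction with MAF-spectrum matching, BayesC$\pi$
whole-genome regression, and paired cross-validated evaluation, plus a
synthetic-population generator so the whole pipeline is testable without
proprietary herd data.

## Phenotype adjustment

Raw phenotypes are adjusted by ordinary least squares,

$$\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{e},$$

where $\mathbf{X}$ carries contemporary group, breed (optionally breed ×
age), and covariates such as heterosis and inbreeding coefficients;
Legendre polynomial bases for days-in-milk trajectories can be supplied as
covariate columns (`legendre_basis()`).  The residuals
$\mathbf{y}-\mathbf{X}\hat{\boldsymbol\beta}$ — yield deviations — are the
response for everything downstream.  OLS is used deliberately: the
adjustment model is a pure fixed-effects equation, and the minimum-norm
pseudo-inverse handles rank-deficient designs (aliased columns are
reported, residuals are unaffected).  Traits are adjusted one at a time.

## The BayesC$\pi$ model

For adjusted phenotype $y_i$ and marker dosages $z_{ij}$,

$$y_i = \mu + \sum_j z_{ij}\,\alpha_j \delta_j + e_i,$$

with $\delta_j \sim \text{Bernoulli}(1-\pi)$, $\alpha_j \mid \delta_j = 1
\sim N(0, \sigma^2_\alpha)$ (a common effect variance), $e_i \sim
N(0,\sigma^2_e)$, scaled inverse-$\chi^2$ priors on both variances
($\nu = 4.2$), and a uniform prior on $\pi$, updated each Gibbs iteration
as $\pi \mid k \sim \text{Beta}(m-k+1,\,k+1)$ where $k$ is the number of
markers currently in the model.  The sampler (compiled C++) visits markers
in a fixed position order, samples each $\delta_j$ with $\alpha_j$
integrated out, maintains the residual vector incrementally, and uses R's
RNG so chains are reproducible from a seed.  GEBVs are
$\hat g_i = \sum_j z_{ij}\,\widehat{E[\alpha_j\delta_j]}$.

Prior scales are set at run time so the prior mode matches an assumed
heritability (default 0.3) split over the expected number of included
markers; both are free parameters, and experiments on simulated traits set
`assumed_h2` to the trait's simulated value.  Two limits are used as
oracles in the tests: with $\pi$ fixed at 0 and both variances fixed the
posterior mean effects converge to the ridge solution with
$\lambda = \sigma^2_e/\sigma^2_\alpha$ (checked to 2% relative RMS), and
with a pure-noise response the model keeps markers out.

The default chain (10,000 iterations, 2,000 burn-in, thinning 10) is a
desk-scale schedule chosen to mix well at the panel sizes (tens to a few
thousand markers) and training sizes (hundreds to a few thousand
individuals) the package simulates; `bayescpi_config(preset = "paper")`
switches to the production schedule of 300,000 iterations, 50,000 burn-in
and thinning 200 used for herd-scale evaluations.

## Variant tagging

* **GWAS tags** (`iterative_conditional_gwas`): single-marker least-squares
  scans on yield deviations; per iteration the most significant variant per
  chromosome with $p < 1.9\times10^{-10}$ joins the tag set and is fitted
  as a covariate in the next round, until no new hits appear.  Tags are
  selected strictly between iterations and never removed; ties break by
  smaller p, lower position, then id, so the tag set does not depend on
  input order.  The production analogue used a mixed-model LOCO engine on
  hundreds of mid-infrared traits; the reusable procedural content is the
  iterate-and-condition loop, so the scan here is covariate-adjusted least
  squares (a polygenic background can be supplied as covariates).
* **cis molecular QTL** (`cis_scan`): per feature, regress the molecular
  phenotype on every variant within a symmetric, closed 1 Mb window with
  MAF > 0.1; if the best p beats the class threshold ($10^{-6}$; $10^{-8}$
  for exon expression), that variant is the feature's tag; tags are
  deduplicated across features.  Splicing efficiency is
  $\mathrm{logit}\!\big((s+c)/(s+u+2c)\big)$ per junction; intron
  (pre-mRNA) expression is standardized $\log(u+1)$ — a simple monotone
  variance-stabilising transform used instead of a model-based VST, a
  deliberate zero-dependency deviation.
* **Allele-specific QTL** (`ase_two_stage_test`): stage 1 pools allelic
  reads over heterozygous carriers of each candidate and computes
  $Z = (\sum m - \sum p)/\sqrt{\sum m + \sum p}$; candidates with two-sided
  normal $p < 10^{-3}$ proceed.  Stage 2 regresses the per-individual log
  allelic ratio $\log\!\big((m+c)/(p+c)\big)$, $c = 0.5$, on the
  candidate's **heterozygote indicator**.  A cis allele unbalances
  expression only in heterozygotes — both homozygote classes are balanced —
  so the log-ratio is non-monotone in dosage and a raw dosage slope would
  have little or no power; heterozygosity is the coding with power against
  exactly the imbalance model being tested.  Final thresholds:
  $10^{-8}$ (expression), $10^{-6}$ (binding), MAF > 0.1.

## Panel construction

The benchmark ("current") panel applies the chip QC cascade in order:
MAF $\ge$ 0.02, call rate $\ge$ 0.9, greedy LD pruning keeping the
earlier-position member of any pair with $r^2 > 0.9$ within 1 Mb, and
removal of variants with exact Hardy–Weinberg test $p < 0.15$ (mid-p
convention, so the null removal rate is the nominal 15%).

Functional candidates are collapsed to LD blocks by single-linkage
clustering over pairs with $r^2 \ge 0.98$ within 1 Mb (the blocking
algorithm is not dictated by the comparison being made; single linkage is
cheap and order-independent, and a no-window mode provides the brute-force
transitive closure used as the test oracle).  One representative per block
is chosen by annotation tier — gene-expression QTL classes, then coding,
then GWAS, then the rest — with ties broken by more class labels, then
position.  Representatives are then subsampled within half-open MAF bins
of width 0.05 (top bin closed at 0.5) to match the benchmark panel's bin
counts, weighting candidates by the number of distinct classes they carry;
finally only biallelic variants with MAF $\ge$ 0.1 are kept.  Each
functional panel is compared against a uniform random sample of equal size
from the current panel.

## Evaluation

`make_folds` splits individuals into k mutually exclusive folds of
near-equal size (91,215 ids at k = 5 give folds of 18,243 and training
sets of 72,972).  Accuracy is the Pearson correlation between GEBV and
adjusted phenotype within the held-out fold — the literal definition used
for the production comparison; no $\sqrt{h^2}$ rescaling is applied.
Improvement is $100\times(\text{Functional}-\text{Current})/\text{Current}$.
One fold plan is shared by every panel in an experiment so comparisons are
paired, and chain seeds are derived from panel content and trait, so two
panels with identical variant sets score identically (making the
self-comparison improvement exactly zero).  A single baseline draw per
functional panel is the default; `n_baseline_draws` enables multi-draw
averaging.

## What the synthetic data emulates — and what it does not

`simulate_population` builds, per chromosome, a founder pool of base
haplotypes (allele frequencies from a symmetric Beta(0.4, 0.4), giving the
U-shaped spectrum of sequence variants) padded with gene-conversion-style
mosaics of two base haplotypes; individuals are pairs of recombinant
gametes (Poisson crossovers).  This haplotype-mosaic scheme produces block
LD and a realistic MAF spectrum at trivial cost, but it is a stand-in for
imputed sequence data: it has no coalescent genealogy, no pedigree or
breed structure, no phasing or imputation error.  Passing tests therefore
demonstrate the pipeline's statistical machinery, not robustness to those
real-data features.

Traits: percent traits and milk volume are primary traits with additive
genetic values from class-enriched causal draws (Normal effects rescaled
to hit the target h2 on a unit biological-variance scale) plus fixed
effects (contemporary group SD 0.5, breed SD 0.3, heterosis +0.3,
inbreeding −0.5 — realistic magnitudes, set once) and Normal residuals.
Yield traits are percent × volume with multiplicative lognormal noise
(CV 0.05), so they carry compounded measurement error; the evaluation
reproduces the qualitative consequence — yield traits are predicted less
accurately than their parent percent traits.  Default heritabilities
(fat 0.55 / protein 0.50 percent, volume 0.35) are typical lactation-trait
values; no generative truth for effect sizes or per-class causal fractions
exists to copy, so enrichment odds are free parameters.

Molecular counts: allele-specific reads are Binomial with the maternal
fraction shifted to $0.5 + \delta$ in heterozygous carriers of an active
regulatory variant (parental phase is known in simulation; by convention
the alt allele sits on the maternal haplotype, as in an F2 cross with
breed-differentiated founders); spliced/unspliced junction reads follow a
logistic dose–response in regulatory dosage.  Rows exist only where the
assay is informative (heterozygous at the feature's transcribed marker;
nonzero junction depth).

## Numerical choices and degenerate inputs

Monomorphic variants get $\beta = 0$, $p = 1$ and a flag; p-values are
clamped to the smallest positive double so noiseless associations stay in
$(0, 1]$.  Missing dosages are mean-imputed (training means at prediction
time).  Zero-variance phenotypes are an error; an empty panel degrades to
an intercept-only GEBV with a warning.  Zero-total count rows are dropped
only when the pseudocount is zero.  MAF exactly 0.5 belongs to the top
histogram bin.  All randomness flows from one root seed expanded per
module by a documented integer scheme (`derive_seed`), and every generator
and sampler is byte-reproducible from its seed.

## Problem sizes used in the tests

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the statistical contrasts are stable: ridge
agreement at n = 200, m = 50; architecture recovery at 2,000 training /
500 validation individuals and 5,000 markers with 50 causals (3 seeds);
the functional-vs-random contrast at 800 individuals, 450 variants and 10
replicate seeds with 5-fold cross-validation.  The herd-scale numbers
reported for the motivating comparison (tens of thousands of cows and
markers) come from proprietary records and are not recomputable here; the
package reproduces the pipeline's properties, not those figures.

## Known limitations

No multi-trait or BayesA/B/R variants; no breed-stratified validation or
bias/dispersion diagnostics beyond accuracy; no phasing, imputation or
read-level processing; the generic panel here is built from unannotated
simulated variants, whereas a real chip's ascertainment is more complex.
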