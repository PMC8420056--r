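---
title: "Models and methods behind droughtmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind droughtmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

droughtmet chains six analysis stages — feature processing, drought-response
calling, metabolite GWAS, eQTL mapping, network/hub analysis, and metabolomic
prediction — behind a synthetic-data generator whose ground truth makes every
stage falsifiable. This vignette explains each model, the parameters that
matter, the numerical choices, and what the synthetic data do and do not
establish about real data.

## The synthetic world

`generate_genotypes()` draws subpopulation allele frequencies from a
Balding–Nichols model (Beta with parameters p(1−F)/F, (1−p)(1−F)/F around an
ancestral frequency p ~ U(0.1, 0.9); divergence F = 0.15 by default).
Haplotypes come from a Gaussian copula whose correlation decays as
exp(−d/(L/2)) with physical distance d and resets at block boundaries of
length L (`ld_block_len`, default 5 kb), so SNPs within a block show LD that
decays with distance while blocks are exactly independent. This is the
simplest generator that produces *both* confounders the mixed model must
correct: global structure (Q, from the subpopulation frequencies) and
relatedness (K, from shared haplotypes). Realized minor-allele frequency is
filtered at `maf_min` (default 0.05, the panel convention).

`generate_metabolome()` builds each metabolite's natural-log abundance as
baseline (U(10, 18), spanning the wide dynamic range of LC-MS intensities) +
optional SNP dosage effect + optional drought shift + N(0, σ) noise with
σ = 0.6 (a ~60–80% coefficient of variation, typical for untargeted
profiling; no noise model is published for such data, so log-normality is an
explicit assumption). SNP effects are scaled as
β = ±√(pve/(1−pve))·σ/sd(g), which fixes the expected per-SNP variance
fraction at `pve` on the log scale. Drought shifts are log2 fold changes
N(`fc_log2_mean` = 2, 0.4) with P(up) = 0.85, applied to a `drought_frac`
(default 0.25) subset under the stressed condition only — roughly the
responsive fraction and up/down skew a drought metabolome shows. Redundant
duplicate features share retention time within 0.2 min (|Δrt| ≤ 0.1 by
construction), carry log-scale correlation > 0.99, alternate ionization
modes, and are labeled in the truth so the collapse step has an exact
answer. Missingness is completely at random at `missing_rate` (default 0.1,
the same order as the 20% completeness filter downstream). Optional *hub*
drivers add expression-proportional terms from designated genes onto
(preferentially drought-shifted) target metabolites, giving the network
stage a recoverable degree structure.

`generate_expression()` assigns *cis* effects to SNPs within 20 kb of the
target gene body and *trans* effects to SNPs > 1 Mb away or on another
chromosome, at a target per-SNP variance fraction on the log2 scale; a
configurable fraction of effects is active under only one condition, and the
truth records which. `generate_phenotype()` squashes a weighted sum of
`n_drivers` standardized metabolites plus noise through a logistic function,
giving a survival-rate-like trait in [0, 1]; the noise is scaled so the
latent trait has heritability `h2`. The logistic form is a modeling choice —
the field trait has no published generative model — and over the central
±2 SD it is near-linear, so a linear fit on the true drivers recovers R² ≈
h2 (the suite checks [0.5, 0.7] at h2 = 0.6). Biomass traits add
environment, replicate-within-environment, and line effects for the BLUP
stage.

**What the generator does not emulate:** real adduct chemistry and isotope
structure, retention-time drift, batch trends, left-censored (intensity-
dependent) missingness, LD from demographic history, selection, or
metabolite–metabolite pathway correlations. Tests passing on this world show
the *algorithms* are correct and calibrated, not that any biological
conclusion transfers.

One consequence worth knowing: because missingness is MCAR while imputation
is the half-minimum convention (designed for left-censored data), imputed
cells sit in the far low tail of the log distribution and attenuate m-trait
heritability roughly in proportion to the missing rate. Real data, where
missingness concentrates at low intensities, are *less* damaged by half-min
imputation than this synthetic world — the pipeline's power estimates on
MCAR data are conservative in that respect.

## Feature processing

The missingness filter keeps a feature iff its missing fraction is ≤ 20% in
the well-watered *and* the drought-stressed condition (removal is by feature,
never by line). The published three-step redundancy removal maps to: (i)
|Δrt| ≤ `rt_tol` = 0.2 min, (ii) an MS/MS co-occurrence criterion we accept
as an optional externally supplied boolean compatibility matrix (raw spectra
are not modeled), (iii) cross-line correlation > `corr_min` = 0.95. Grouping
is by connected components of the pairwise graph within each ionization
mode, then groups are merged across modes by criteria (i) and (iii) applied
to group representatives. Correlation is computed on log intensities with
the WW and DS profiles stacked — grouping is a property of the feature, not
of the condition, so both conditions inform it — and `use_log = FALSE` is
available. The representative intensity of a group is the member with the
fewest missing values (ties: larger median intensity, then lexicographic
feature id) — the published text does not state a rule, and completeness is
the property downstream stages care about. The rt comparison carries a 1e-9
slack because 0.2 is not exactly representable in binary floating point.

Normalization equalizes per-sample medians to the grand median of sample
medians (per batch first when batch labels are given), which makes the step
exactly idempotent; remaining missing values are imputed at half the
per-metabolite minimum, then everything is natural-log transformed. Fold
changes are computed on the raw (pre-log) normalized scale, so the log base
is presentational.

## Drought-response calling

OPLS-DA is implemented in the Trygg–Wold form for a single centered class
indicator y: the predictive weight is w ∝ Xᵀy normalized to unit length;
each orthogonal component removes the y-orthogonal part of the loading
vector and deflates X; the final predictive component is re-extracted from
the deflated matrix. Metabolites are centered and unit-variance scaled
first (standard for VIP comparability), constant metabolites are excluded
with a warning. With one predictive component VIPⱼ = √(p wⱼ²), so mean
VIP² = 1 exactly — a single perfectly discriminating metabolite has VIP 1,
which is why the VIP ≥ 1 gate reads as "above-average contribution".
`n_ortho` defaults to 1 (the published protocol does not state its count;
configurable). Note the single-component R²Y does not vanish under the
null: for n samples and p metabolites it concentrates near p/n, so R²Y is
interpreted relative to that baseline, not to zero.

The paired *t*-test runs on per-line DS − WW log differences (pairwise
complete; < 3 pairs gives NA and leaves the BH family), with
Benjamini–Hochberg adjustment across all tested metabolites jointly. The
intersection rule — VIP ≥ 1 AND FDR ≤ 0.05 AND (FC ≥ 2 OR FC ≤ 0.5) — is
monotone in each statistic; a ratio cannot be negative, so the two-sided
reading of "|FC| ≥ 2" is ratio ≥ 2 or ≤ 1/2.

## Association scans

`kinship()` is the VanRaden centered form; `mlm_scan()` uses P3D/EMMAX:
variance components are REML-estimated once under the null (profiled
restricted likelihood over δ = σ²e/σ²g on a log grid of [e⁻¹⁸, e¹⁸],
optimized with `stats::optimize` after one spectral decomposition of K),
then each SNP is tested by GLS on the whitened scale with a two-sided t
(df = n − q − 1). Per-SNP REML would be orders slower for no calibration
gain at these scales. Missing dosages are mean-imputed per SNP;
monomorphic SNPs are skipped and recorded. Forcing `var_ratio = Inf`
reduces the scan exactly to PC-adjusted OLS (a tested identity). The
per-SNP variance explained is reported as the squared partial correlation
on the whitened, covariate-adjusted scale — an internal, comparable
definition; the published protocol never states its formula, so these numbers
are comparable only within the package.

The suggestive threshold is 1/Meff. `effective_marker_count()` approximates
the black-box marker-effective-number tool with the simpleM eigenvalue rule
(smallest k eigenvalues of the windowed SNP correlation matrix explaining
≥ 99.5% of the trace, summed over windows of 100 SNPs); an externally
computed Meff can be injected wherever a threshold is taken. mQTL
clustering chains significant SNPs per chromosome when gaps are strictly
below 10 kb; the peak SNP has the smallest p (ties: smaller position).
Candidate genes require a significant SNP inside the gene body (1-based
inclusive) — an LD-extension variant is left as an optional
radius, disabled by default, because the stated rule is within-gene.
Known-QTL co-localization counts any ≥ 1 bp interval overlap, with BED
input converted from 0-based half-open on import.

For eQTLs, expression is log2(x+1)-transformed (the source does not state
its transform), scanned per gene with the same engine at P < 4.2 × 10⁻⁸,
clustered with the 10-kb rule, and classified *cis* iff the lead SNP falls
in the gene span ± 20 kb (positional, strand-ignored, gene-body-anchored —
the TSS-anchored alternative is not distinguishable from the published
wording). "Shared" across conditions means the same gene has loci with
overlapping merged intervals in both scans; the published procedure never operationalizes
locus identity across conditions, so this explicit rule is the package's.

## Networks, hubs, enrichment

Gene–metabolite edges are simple regressions of metabolite on log2
expression; the slope test is algebraically the correlation t-test, so the
direction of regression is presentational. Co-expression edges use the
t-transform of Pearson r. The hub null reassigns each edge's gene endpoint
uniformly over the gene universe (metabolite endpoints fixed), preserving
the metabolite degree sequence and edge count — the balls-in-bins structure
that makes a per-gene degree threshold meaningful; a whole-metabolite
reassignment mode sits behind `mode = "metabolite"`. Degrees are pooled
over genes × permutations and the threshold is the smallest k with
empirical P(degree ≥ k) < 0.01, capped at the edge count (the pooled tail
was chosen because the published procedure does not distinguish per-gene
from pooled nulls; at the published scales they agree). At 1000
permutations the estimate matches the exact binomial tail in the tested
configurations. Enrichment is the one-sided hypergeometric test with BH
adjustment; pathways with no universe member are skipped.

## Prediction

`rrblup_fit()` solves y = 1μ + Mα + e with α ~ N(0, σ²αI) through the
equivalent kernel form: λ = σ²e/σ²α by spectral REML on MMᵀ, GLS intercept,
and α̂ = Mᵀ(MMᵀ + λI)⁻¹(y − μ̂), computed through the eigendecomposition so
near-singular MMᵀ (noiseless y, λ → 0) stays stable. Cross-validation
shuffles lines into k random folds per repeat — the fold draw is documented
as `sample(rep(seq_len(k), length.out = n))` so it can be reproduced
independently from the seed — and accuracy is the Pearson r between
assembled out-of-fold predictions and observations (the rrBLUP community
convention; R² is recoverable by squaring). The bootstrap comparison of two
predictor sets resamples paired CV repeats (the resampling unit is the
repeat; the published protocol does not state its unit), takes the ratio of mean
accuracies, and inverts the basic (reverse-percentile) interval: p is the
smallest level at which the interval excludes 1, computed as
2·min(P(t* ≤ 2θ̂−1), P(t* ≥ 2θ̂−1)) with a (count+1)/(R+1) continuity
correction, which keeps p in (0, 1] and uniform under an exchangeable null.
A non-positive reference accuracy leaves the ratio undefined and is
reported as NA rather than an error inside the pipeline.

`phenotype_blup()` fits value = mean + environment + replicate(environment)
+ genotype + error by REML through lme4, with environment fixed by default
(`env_fixed = FALSE` makes it random; the published formula is ambiguous on
this point) and genotype BLUPs as the de-noised trait. `stepwise_select()`
is bidirectional stepwise OLS minimizing AIC = n·ln(RSS/n) + 2k, hard-capped
at ⌊n/10⌋ steps, followed by repeated k-fold CV (default 5-fold × 10) of the
selected model reporting mean squared correlation.

## Pipeline, determinism, problem sizes

`pipeline_config()` gathers every threshold with the published defaults
(missingness 0.2; rt 0.2 min; r 0.95; VIP 1; FDR 0.05; FC 2; MAF 0.05; 5
PCs; 10-kb gap; eQTL 4.2e-8; cis window 20 kb; OLS edges 1e-5; co-expression
4.67e-9; 1000 permutations at α 0.01; 10-fold × 100 CV) and echoes itself
into every run's output directory; `run_pipeline()` executes the stages in
order, writes per-stage TSVs, and emits a summary JSON in which every number
is recomputable from the stage files. All randomness flows from one integer
seed (generators save and restore the global RNG state), so identical
configurations give byte-identical summaries.

The bundled synthetic scale is 120 lines × 2000 SNPs × 400 metabolites with
60 genes — large enough that every stage has signal to find, small enough
that the full pipeline completes in well under a minute on one CPU. The
test suite runs calibration at 5000 SNPs (genomic inflation), power loops
at n = 385 over 20 seeds (matching the panel size the thresholds were
designed for), and stepwise recovery at n = 385 with 60 candidate
metabolites; the acceptance script uses 10-seed power loops and 25 CV
repeats. These sizes are the package's validation choices: estimates at
other scales follow from the same functions.

## Known limitations

Single-response OPLS-DA only (no multi-class, no Q² component selection);
single-marker association (no multi-locus or epistasis models); the
effective marker number is a simpleM approximation, not the published
tool's exact algorithm; hub thresholds depend on the chosen null mode when
metabolite degrees are very unbalanced; survival rates near 0 or 1 compress
under the logistic squash, attenuating correlations at extreme
heritabilities; and everything stated above about MCAR missingness versus
left-censored reality applies to any power number computed on synthetic
data.
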