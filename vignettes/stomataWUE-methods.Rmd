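---
title: "Methods: stomatal traits, field adjustment, association scanning and BWB modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stomatal traits, field adjustment, association scanning and BWB modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomataWUE)
```

`stomataWUE` chains five analyses that together connect stomatal anatomy to
water-use physiology and its genetic basis in an inbred sorghum panel. This
vignette documents the models, the parameters that matter, the numerical
choices, and what the synthetic test bed does and does not establish.

## Anatomical trait derivation

Grass stomata are dumbbell-shaped; both the stomatal complex and the open
pore are well approximated by rectangles. From per-stoma measurements
(lengths in µm) we compute stomatal size SS = SL × SCW and maximum pore
area PA~max~ = PL × GCW. Because 4–5 stomata are scored per impression, the
aggregation order matters: the package averages per-stoma *products*
(`mean(SL*SCW)`), the unbiased estimator of mean area, rather than
multiplying trait means. Both orders are available via
`mean_of_products = FALSE`; on typical within-impression variation the two
differ by well under 1%.

Stomatal density is `mean(counts) / fov_area` with the field-of-view area
fixed at 0.59 mm² (two fields per impression at 10× magnification). SPALA
(stomatal pore area per leaf area, µm² mm⁻²) is PA~max~ × SD.

The anatomical maximum conductance to water vapor uses a one-end-corrected
diffusion equation,
$$g_{sw.max} = \frac{d \cdot SD \cdot PA_{max}}
 {v \left( l + \frac{\pi}{2}\sqrt{PA_{max}/\pi} \right)},$$
with $d = 2.49\times10^{-5}\,\mathrm{m^2\,s^{-1}}$,
$v = 0.0245\,\mathrm{m^3\,mol^{-1}}$ (25 °C), and pore depth $l = GCW/2$.
The public API keeps field units (mm⁻², µm², mol m⁻² s⁻¹); SI conversion is
internal, and the test suite verifies agreement with an independent
brute-force SI computation to 10⁻¹² relative error. π enters at full double
precision; `stomatal_constants(pi_value = 3.1415)` reproduces computations
done with the truncated constant (a ~3×10⁻⁵ relative shift, far below
measurement error). Density-like traits (SD, SPALA, g) sum over the two
leaf surfaces; size-like traits (SS, PA~max~) average. Aggregation requires
both surfaces — there is no silent single-surface fallback, because a
missing surface biases every total downward by roughly half.

## Field mixed model

Plot-level traits are adjusted with
`trait ~ row + column + AveT + AveH + (1 | accession)`, fitted by REML
through `lme4::lmer()`. Row and column enter as categorical fixed effects
by default: the field gradient is not assumed linear, and factors absorb
arbitrary spatial patterns (a numeric option exists for sparse layouts).
Aliased fixed-effect columns — routine in unbalanced field layouts — are
dropped with a message rather than erroring. A fit with the accession
variance at the boundary is flagged (`boundary`), not discarded.

Accession predictions add the BLUP to the fixed part evaluated at
reference covariates (the fixed-effect predictor averaged over all plots,
which centers AveT/AveH and averages row/column effects out). An
`"observed"` mode instead averages the fixed part over each accession's own
plots, reproducing a predict-then-average workflow; the reference mode is
the default because it compares accessions at a common environment. A small
AIC utility (`compare_weather_models`, maximum-likelihood refits) supports
the keep-or-drop decision on the weather covariates.

## Association scan

Markers with minor allele frequency strictly below 3% are excluded
(`maf_filter`; a marker exactly at the boundary is retained, matching the
stated "below" rule). Population structure is summarized by the first
3 principal components of the column-centered dosage matrix (SVD, with a
deterministic sign convention). The scan itself is ordinary least squares
of the accession-level prediction on (intercept, PCs, dosage), with
two-sided t-tests on the dosage coefficient at $n-k-2$ degrees of freedom
and a Bonferroni threshold $\alpha/M$. Missing dosages are mean-imputed per
marker at scan time only; the genotype container preserves missingness.

This is a deliberate design decision: multi-stage mixed-model scans
(FarmCPU-style, kinship random effects) are published methods whose
internals are not this package's contribution, so the package ships a
transparent PC-adjusted OLS instead and says so in every results header.
Consequences: on a panel with strong relatedness the OLS scan is
anti-conservative relative to a kinship-aware model; the Q–Q table
(`qq_table`) is the diagnostic for that. On the synthetic panel (no family
structure beyond the PCs) the permuted-null p-values are uniform and the
family-wise error is controlled, which the acceptance suite verifies.

Candidate genes are collected in ±75 kb windows around significant SNPs
with inclusive overlap — a gene touching the window boundary counts, since
partial-overlap handling is otherwise arbitrary. Chromosome labels are
normalized (leading "Chr" stripped) for matching only; originals are
preserved in output.

## Haplotype classes

Accessions homozygous at all focal loci get an allele string (reference
base for dosage 0, alternative for dosage 2, in marker order);
heterozygous/missing accessions are excluded with a logged count, since an
inbred panel's residual heterozygosity is more likely a genotyping artifact
than a true state. Classes are labeled Hap1…HapK ordered by ascending
alternative-allele count, ties broken by descending frequency then
alphabetically — so Hap1 is always the all-reference configuration and HapK
the all-alternative one without hard-coding. An explicit `anchor` vector
fixes an exact ordering when a fixed display layout is needed.

Group differences use one-way ANOVA with Tukey HSD. Pairwise p-values come
from the studentized-range distribution with the Tukey–Kramer adjustment
for unequal group sizes (haplotype classes are strongly unbalanced — the
all-reference class typically holds half the panel). Compact letters are
assigned from the maximal cliques of the "not significantly different"
graph, which guarantees the display invariant exactly: two classes share a
letter if and only if their Tukey p ≥ α.

## Ball–Woodrow–Berry fitting

The BWB model is $g_{sw} = m \cdot A_n H_s / C_s + g_0$, with the ball
index $A_n H_s/C_s$ in mol m⁻² s⁻¹ so that the slope $m$ is dimensionless.
$H_s$ must be a fraction in (0, 1]; a value above 1 raises an explicit
"percent passed where fraction expected" error, because silently fitting
percent RH scales $m$ by 100. Fits are per accession × treatment ×
replicate (ordinary least squares), then compared at the replicate level:
per-accession Student's t-tests of $m$ between WW and WS, a two-way
accession × treatment fixed-effects ANOVA, and the Pearson correlation of
$m$ with fit-level iWUE (taken at the highest-PPFD record, where the
measurement is closest to the saturating-light operating point). A pooled
reporting mode (`bwb_pooled_points`) averages the biological replicates per
accession × PPFD first, giving the 11 × 8 = 88 regression points per water
regime used for treatment-level regressions. $g_0$ is unconstrained — a
negative intercept is flagged, not clipped — with an opt-in non-negativity
switch left off by default.

## The synthetic panel

The generator emulates the study conditions stage by stage, under one
master seed with independent child seeds per sub-generator (genotypes,
field, impressions, gas exchange), so any stage can be regenerated alone
and identical seeds give byte-identical pipelines.

* **Genotypes** — 360 inbred accessions (dosages in {0, 2}; readers still
  accept heterozygotes) × 5,000 SNPs on 10 chromosomes, per-marker
  alternative-allele frequency uniform on [0.05, 0.5]. A 3-SNP causal block
  sits on chromosome 1 at 77,550,396 / 78,561,058 / 78,619,413 (C/T, C/T,
  G/A) with allele frequency 0.3; loci 2 and 3 copy locus 1's allele with
  probability ρ = 0.4 — a simple, seedable linkage mechanism, with no
  coalescent machinery and hence no realistic genome-wide LD decay.
* **Field phenotypes** — per plot: mean + row + column effects (Gaussian,
  SD = 0.3 × residual SD), batch weather terms (four batches, AveT 24–30 °C,
  AveH 50–65%), causal effects (per alternative allele: SD_total −8 mm⁻²,
  A~n~ −1.2 µmol m⁻² s⁻¹, g~sw~ −0.02 mol m⁻² s⁻¹, iWUE +4 µmol mol⁻¹ —
  alternative alleles trade assimilation for efficiency), an accession
  random intercept, and residual noise. Three plots per accession on a
  36 × 30 grid.
* **Impressions** — Poisson counts at density × 0.59 mm² over two fields of
  view; abaxial density 1.255 × adaxial (and dimension-specific abaxial
  factors of 3–12%); lognormal guard-cell dimensions whose accession-level
  component is anti-correlated with density (target r = −0.3), emulating
  the density–size trade-off. Within-accession error magnitudes are
  order-of-magnitude choices (accession log-SD 0.1, per-stoma log-SD 0.05),
  not calibrated values, and are exposed in the config.
* **Light responses** — A~n~(Q) follows a non-rectangular hyperbola
  (φ = 0.06, θ = 0.7, R~d~ = 1.5; A~max~ 35 under WW, 20 under WS). This
  functional form is a standard stand-in for measured curves, not a claim
  about the data-generating process. g~sw~ follows the BWB relation with
  g₀ = 0.05, noise SD 0.02 truncated at 0.005 mol m⁻² s⁻¹ (no non-physical
  negatives), at the 11-level PPFD schedule (1600 acclimation + 1500 … 50).
  Slopes are per haplotype class: WW slopes 9.5 … 4.5 declining from
  class 1 to 8; under WS classes 1–5 drop by 3.4–5.0 while classes 6–8 keep
  their WW slope — the plastic-vs-conservative contrast the growth-chamber
  comparison is designed to detect.

What passing tests show: the estimators recover the generating parameters
(REML variances, BWB slopes, causal-marker effects) and the pipeline's
bookkeeping is exact. What they do not show: performance under realistic
LD, kinship structure, shared-environment confounding between weather and
genotype, or non-Gaussian measurement error — none of which the generator
emulates.

## Numerical choices and problem sizes

Scan regressions are vectorized through a QR residualization of phenotype
and dosages on the covariate block (exact Frisch–Waugh, identical to
per-marker `lm()` to 10⁻¹⁰, as tested). Zero-variance markers return
β = 0, p = 1 with a flag rather than NA, keeping downstream tables
rectangular. PCA and PC-score signs follow a largest-loading-positive
convention so runs are reproducible across BLAS implementations.

The validation suites run at sizes chosen to keep the full check under a
few minutes while leaving comfortable statistical margins: 1,000 random
anatomical geometries for the conductance oracle; 200 noisy curves for
slope recovery (±5% on the mean); 50 replicates of a 360 × 3 balanced
design for REML recovery (median within [0.8, 1.2] at true variance 1);
20 panels of 360 accessions × 2,000 markers for scan power and permuted-null
calibration; and 20 growth-chamber simulations for the interaction rate.

## Known limitations

Single random effect only (no spatial autocorrelation or multi-trial
models); no kinship-aware scan; haplotypes are unphased homozygous
configurations, not inferred phased haplotypes; the Medlyn-type optimal
stomatal model is out of scope; BWB fitting assumes steady-state records
and does not model induction dynamics.
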