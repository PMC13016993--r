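# stomataWUE

Stomatal trait derivation, genome-wide association scanning, and
Ball–Woodrow–Berry (BWB) stomatal-conductance modeling for sorghum
diversity panels.

Water-use efficiency in C4 crops is shaped by stomatal anatomy (how many
stomata a leaf carries and how large their pores are), by the operational
behavior of those stomata under changing light and water supply, and by the
genetics segregating both. `stomataWUE` implements the full analysis chain
used to dissect this in an inbred sorghum association panel, with a
seedable synthetic-data generator so every stage can be exercised and
validated without access to panel data. It is aimed at plant physiologists
and quantitative geneticists working with leaf-impression measurements,
LI-6800-style gas-exchange records, and SNP genotype matrices.

## What it computes

**Anatomical traits** from leaf impressions, per surface (adaxial/abaxial)
and aggregated: stomatal density SD = mean count / 0.59 mm² field of view;
rectangular stomatal size SS = SL × SCW and maximum pore area
PA_max = PL × GCW; pore area per leaf area SPALA = PA_max × SD; and the
anatomical maximum stomatal conductance with one-end correction,

    g_sw.max = d · SD · PA_max / [ v · ( l + (π/2)·√(PA_max/π) ) ]

with d = 2.49×10⁻⁵ m² s⁻¹ (water-vapor diffusivity), v = 0.0245 m³ mol⁻¹
(molar volume of air at 25 °C), and pore depth l = GCW/2. Totals sum over
surfaces (SD_total = SD_ad + SD_ab, likewise SPALA and g); sizes average.

**Field adjustment**: the plot-level mixed model
`trait ~ row + column + AveT + AveH + (1 | accession)` fitted by REML
(via lme4), with BLUP-based accession predictions for downstream mapping.

**Association scan**: MAF ≥ 3% filtering, genotype PCA (3 PCs as
population-structure covariates), per-marker OLS with t-tests, a Bonferroni
threshold α/M (0.05/234,264 markers renders as 2.13×10⁻⁷), and
candidate-gene extraction in ±75 kb windows. The scan is a transparent
PC-adjusted single-marker OLS; kinship-aware multi-stage scans are out of
scope and the substitution is recorded in every results header.

**Haplotypes**: multi-locus allele strings at focal SNPs (e.g. the 3-SNP
block on chromosome 1 at 77.55–78.62 Mb), class labels Hap1 (all-reference)
through HapK (all-alternative), per-class trait means ± SD, and one-way
ANOVA with Tukey HSD compact letters.

**BWB modeling**: per-replicate fits of `gsw = m · An·Hs/Cs + g0` over
11-level light-response curves, Student's t contrasts of the slope m
between well-watered (WW) and water-stressed (WS) regimes, a two-way
accession × treatment ANOVA, and the slope–iWUE correlation
(iWUE = An/gsw).

## Worked example

```r
library(stomataWUE)

# anatomical conductance for SD = 150 mm^-2, PAmax = 50 um^2, GCW = 5 um
gsw_max_anatomical(SD = 150, PAmax = 50, GCW = 5)
#> [1] 0.8695044

cfg  <- sim_config(n_accessions = 120, n_markers = 1000, seed = 42)
gen  <- simulate_genotypes(cfg)
ph   <- simulate_field_phenotypes(gen$G, gen$truth, cfg)
fit  <- fit_random_intercept_reml(ph, "iWUE")
fit
#> Random-intercept REML fit for iWUE
#>   sigma2_accession = 118.919, sigma2_residual = 37.1106
#>   360 plots, 120 accessions; logREML = -1152.568

Gf   <- maf_filter(gen$G)
scan <- single_marker_scan(Gf, predict_accession_values(fit),
                           genotype_pcs(Gf, 3), trait = "iWUE")
scan
#> PC-adjusted single-marker scan for iWUE
#>   995 markers tested on 120 accessions (3 PCs)
#>   Bonferroni threshold 5.03e-05 (alpha = 0.05): 3 significant
significant_markers(scan)$id
#> [1] "S01_77550396" "S01_78561058" "S01_78619413"
```

All three simulated causal SNPs clear the Bonferroni bar; their positive
betas on iWUE reflect the generator's convention that alternative alleles
lower stomatal density and conductance but raise water-use efficiency.
Haplotype grouping and the growth-chamber contrast follow the same objects:

```r
build_haplotypes(gen$G, attr(gen$truth, "causal_ids"))
#> haplotype_table: 8 classes over 3 loci ( S01_77550396, S01_78561058, S01_78619413 )
#>  class allele_string alt_count  n
#>   Hap1           CCG         0 54
#>   ...
#>   Hap8           TTA         3 16

fits <- fit_bwb_all(simulate_gas_exchange(cfg))
cmp  <- compare_slopes(fits)
cmp$interaction_p   # 9.03e-08: slope response to stress differs by accession
cmp$m_iwue_cor$r    # -0.854: steeper BWB slope, lower iWUE
```

An end-to-end run (`run_pipeline(pipeline_config(...))`, or the thin
wrapper `inst/scripts/run_pipeline.R`) writes per-stage CSV/TSV outputs and
a JSON manifest with the seed and config hash.

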