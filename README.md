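# isopqtl

Serum-proteome pQTL analysis for isolated-population cohorts, as a tested,
reusable R pipeline.

Population isolates carry private rare variants that genetic drift has
pushed to workable frequencies, which makes them unusually powerful for
mapping protein quantitative trait loci (pQTLs): variants associated with
circulating protein levels. `isopqtl` implements the full analysis such a
study runs — and, because individual-level cohort data are
access-controlled, a synthetic-cohort generator that emulates the study
design so the whole pipeline can be exercised, tested and calibrated from
a single seed.

The stages, each usable on its own:

- **Phenotypes** — Olink-style NPX quality control: LOD censoring,
  missingness filters (proteins > 40% missing are dropped), joint
  covariate adjustment (age, age², sex, plate, season, per-sample mean
  NPX) and rank-based inverse-normal transformation.
- **Genostats** — variant QC (missingness > 1%, MAC < 10, Hardy–Weinberg
  exact test at 10⁻⁵), LD r², VIF-based LD pruning (`50 5 2`), the
  standardized genomic relatedness matrix, genomic-control λ, and the
  study-wide significance threshold α/(N_eff · M_eff), where M_eff is the
  ratio of the sum to the maximum of the phenotype-correlation
  eigenvalues.
- **Association** — per-protein linear mixed model: REML on an
  eigendecomposed GRM, Wald tests with the null-model variance ratio,
  overall and sex-stratified.
- **Meta** — allele harmonization against the variant map and
  fixed-effect inverse-variance (METAL-style) meta-analysis of the two
  cohorts; Cochran's-Q sex-heterogeneity test.
- **Signals** — greedy LD + distance peak extraction (P < 10⁻⁶,
  r² > 0.2 pruning, 2 Mb grouping), clumping (r² 0.1 / 1 Mb), and
  stepwise approximate conditional/joint (COJO-style) selection of
  independent variants from summary statistics plus an LD reference.
- **Annotate** — cis/trans (within 1 Mb of the gene start), drift folds
  against a cosmopolitan reference (with a packaged catalogue of 15 rare
  drifted pQTLs), novelty by conditioning on known signals, pleiotropic
  gene flags, replication with r² > 0.8 proxies at a Bonferroni
  threshold.
- **Coloc** — Wakefield-ABF colocalization (priors 10⁻⁴/10⁻⁴/10⁻⁵,
  PP4 > 0.8), on statistics conditioned per independent signal.
- **MR** — two-sample Mendelian randomization: Wald ratio for single
  instruments, fixed-effect IVW otherwise, Benjamini–Hochberg adjustment
  across all protein–trait pairs.

Everything takes and returns tibbles, composes with the pipe, and carries
`tidy()`/`glance()` methods and `plot_*()` helpers (Manhattan, QQ with
λ_GC, MR forest).

## Worked example

Simulate two isolate cohorts with four strong planted cis effects and run
the pipeline end to end:

```r
library(isopqtl)
library(dplyr)

cfg <- sim_config(n_samples_per_cohort = 500, n_variants = 3000,
                  n_proteins = 8, ld_rho = 0.5, ld_block_size = 10,
                  n_cis_effects = 4, n_trans_effects = 0,
                  effect_sizes = c(1.4, -1.3, 1.5, -1.4), seed = 78)
res <- run_pipeline(run_config(sim = cfg, n_gwas = 1000,
                               sex_stratified = FALSE,
                               lambda_band = c(0, Inf)))

res$peaks |> filter(significant)
res$independent |> select(protein, rsid, joint_beta, joint_se, joint_p)
```

```
# A tibble: 3 × 6
  protein chrom   start     end index_rsid  index_p
1 PROT2   1     2215000 2220000 rs245      1.52e-75
2 PROT7   8     1600000 2445000 rs2221     1.81e-61
3 PROT8   2     2410000 2410000 rs583      1.64e-72

# A tibble: 4 × 5
  protein rsid   joint_beta joint_se   joint_p
1 PROT2   rs245      -0.883   0.0382 3.94e-118
2 PROT7   rs2221      0.865   0.0395 2.60e-106
3 PROT7   rs2390     -0.756   0.0943 1.01e- 15
4 PROT8   rs583       0.998   0.0449 2.85e-109
```

The three study-wide-significant peaks sit exactly on the planted loci
(`rs245`, `rs583`, and the PROT7 locus on chromosome 8, where the
conditional analysis correctly resolves *two* independent variants,
`rs2221` and `rs2390`, matching the two planted effects). Joint effect
sizes are on the inverse-normal scale, so the planted 1.4–1.5 NPX/allele
effects appear attenuated by the phenotype's total standard deviation.
`res$annotation` classifies all four as cis and, after conditioning on the
built-in known-signal catalogue (which contains half the planted truth),
labels `rs245` novel and the catalogued ones known. The `lambda_band`
override disables the λ_GC protein filter, which at a 3,000-variant panel
would misfire on median sampling noise; the calibration that validates the
filter itself runs at 20,000 variants (see the methods vignette).

On the drift side, the packaged catalogue of rare drifted pQTLs
reproduces the published arithmetic directly:

```r
cat15 <- drifted_pqtl_catalogue()
drift <- annotate_drift(
  cat15 |> transmute(variant_id = rsid, cohort = cohorts, maf = cohort_maf),
  cat15 |> transmute(variant_id = rsid, ref_maf = reference_maf))
min(drift$fold[is.finite(drift$fold)])   # 2.25
sum(drift$rare_in_reference)             # 15
```

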