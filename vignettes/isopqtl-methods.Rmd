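---
title: "Methods: pQTL mapping in isolated populations with isopqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pQTL mapping in isolated populations with isopqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopqtl)
```

# Scope and model

`isopqtl` implements a complete protein-quantitative-trait-locus (pQTL)
analysis for the study design typical of founder-population cohorts: two
related isolate cohorts measured on an Olink-style NPX protein panel, with
whole-genome genotypes, meta-analyzed and carried through signal
extraction, annotation, colocalization and Mendelian randomization. Because
individual-level data of such studies are access-controlled, the package
ships a synthetic-cohort generator that reproduces the statistical features
the pipeline must cope with, so every stage is testable end to end from a
single seed.

## Phenotype model

NPX values are natural-log-scale relative abundances. The measurement model
used by the generator, and assumed by the QC stage, is

$$ y_{ij} = \mu_j + \beta_{g}^\top g_i + u_{ij} + f_j(\text{age}_i,
\text{sex}_i, \text{plate}_i, \text{season}_i) + s_i + \varepsilon_{ij}, $$

for sample $i$ and protein $j$: planted variant effects $\beta_g$ (NPX per
ALT allele), a polygenic term $u$ with covariance proportional to the
realized GRM, fixed covariate effects, a per-sample mean shift $s_i$, and
Gaussian noise. Values below a per-protein limit of detection (LOD) are
unreliable; the LOD sits at a configurable quantile of each protein's
distribution.

The QC stage mirrors the standard sequence: values strictly below the LOD
are set missing (a value exactly at the LOD is kept); proteins with
missing/below-LOD proportion *greater than* 40% are dropped, as are samples
with missing covariates; each protein is regressed on intercept, age,
age squared, sex, plate indicators, season and the per-sample mean NPX
(computed across all assays *before* any protein is excluded); and the
residuals are mapped to standard normal quantiles by the rank-based inverse
normal transform with offset $(r - 0.5)/n$ and average ranks for ties — a
symmetric, standard choice. Aliased design columns (plate confounded with
season, which the plating-by-collection-date design makes likely) are
dropped with a warning rather than failing.

A consequence worth knowing: adjusting for the per-sample mean across all
assays leaks a fraction $\sim 1/P$ of each protein's own signal back into
every other protein. On a panel of hundreds of assays this is negligible;
on a toy panel of five proteins it visibly attenuates planted effects and
can create spurious cross-protein associations. Simulated panels used in
the tests therefore carry 20-40 proteins.

## Association model

Per protein, a linear mixed model $y = \mu + u + e$,
$u \sim N(0, \lambda\sigma^2 K)$, is fitted by REML: $K$ is eigendecomposed
once, the restricted likelihood is profiled over $\mu, \sigma^2$ and
maximized over $\log\lambda \in [-10, 10]$ by Brent search. Each variant is
then tested by a Wald test in the whitened model with $\lambda$ held at its
null value, using the $t$ reference with $n-2$ degrees of freedom at finite
$n$; with $\lambda = 0$ or an identity GRM this reduces exactly to OLS
(tested to $10^{-8}$). Missing hard-call dosages are mean-imputed.

The GRM is the standardized estimator
$K = \frac{1}{M}\sum_m z_m z_m^\top$, $z_m = (g_m - 2p_m)/\sqrt{2p_m q_m}$,
over LD-pruned variants with MAF above 1% passing the Hardy–Weinberg exact
test. One deliberate departure from the single-GRM convention: at
desk-scale panel sizes (thousands of variants rather than millions) a
tested variant is a non-trivial fraction of the GRM, and this proximal
contamination distorts test statistics badly enough to move the
genomic-control factor of a protein with one strong pQTL outside any
reasonable band. `run_pipeline()` therefore uses leave-one-chromosome-out
GRMs by default (`loco` in `run_config()`), assembled cheaply from
per-chromosome components; the simulator spreads its panel over 10
chromosomes so each leave-out removes only a tenth of the relatedness
information.

The post-association protein filter excludes proteins with
$\lambda_{GC} < 0.97$ or $> 1.05$ in either cohort. This band presumes the
median of millions of test statistics, whose sampling error is nil. With a
simulated panel of $M$ effective variants, $\mathrm{sd}(\lambda_{GC})
\approx 1.3/\sqrt{M}$: at $M = 20{,}000$ the band is meaningful
(and the null pipeline stays inside it); at $M \le 3{,}000$ it evicts
proteins at random, so the machinery tests that are about peak recovery
disable it explicitly.

## Meta-analysis and signal extraction

Cohorts are combined per variant by fixed-effect inverse-variance
weighting (the METAL scheme): $w_i = 1/se_i^2$,
$\hat\beta = \sum w_i \beta_i / \sum w_i$, $se = (\sum w_i)^{-1/2}$.
Alleles truncated upstream are restored from the variant map by frequency
matching; at multiallelic sites the alternate allele minimizing the
frequency difference is taken, and exact ties are dropped rather than
guessed. Sex-specific meta-analyses are contrasted per variant by
$Q = (\beta_m - \beta_f)^2/(se_m^2 + se_f^2) \sim \chi^2_1$, with a
Bonferroni threshold over the pQTLs tested.

Peaks are extracted by the greedy routine: sort variants below $10^{-6}$ by
P, remove everything in LD at $r^2 > 0.2$ with each survivor, group
survivors within 2 Mb, and index each group by its lowest P-value; index
variants must have MAC $\ge 10$ and pass Hardy–Weinberg. The study-wide
threshold is $\alpha/(N_\mathrm{eff} M_\mathrm{eff})$ with
$N_\mathrm{eff}$ the LD-pruned variant count (VIF pruning, windows of 50
advanced by 5, VIF bound 2) and $M_\mathrm{eff}$ the ratio of the sum to
the maximum of the phenotype correlation eigenvalues, rounded to the
nearest integer for the division because that is how the published
arithmetic is done. With the study's counts
($N_\mathrm{eff} = 5{,}078{,}182$, $M_\mathrm{eff} = 132$) this reproduces
$7.45 \times 10^{-11}$.

Conditionally independent variants per locus come from a stepwise
approximate joint analysis on summary statistics with a genotype reference
panel for LD (the COJO construction): with
$D_j = 2f_j(1-f_j)n_j$ and the LD correlation matrix $R$, the joint
coefficients solve $(D^{1/2} R D^{1/2})\,b = D\,\hat\beta_\mathrm{marg}$,
with the phenotypic variance taken as 1 on the INT scale. Selection starts
from the lowest P-value, adds the candidate with the best conditional P
while it is below the entry threshold and its LD with the selected set is
below $r^2 = 0.9$, and backward-removes anything whose joint P rises above
the threshold. Candidates are pre-thinned by clumping at $r^2 = 0.1$ in
1 Mb. The entry threshold defaults to the study-wide threshold (the
original tooling's default is not stated; this is configurable). Adjacent
peaks within 1 Mb or in LD at $r^2 > 0.1$ are merged automatically — a
conservative, config-exposed surrogate for what is a manual review step in
practice, not a reproduction of it.

## Annotation

A variant is *cis* for a protein when it lies within 1 Mb of the encoding
gene's start on the same chromosome (start-anchored, boundary inclusive;
both choices documented and configurable), else *trans*. Drift is the
ratio of the cohort minor-allele frequency to a cosmopolitan reference
(gnomAD-NFE-like) MAF, with an infinite-fold sentinel when the reference
frequency is zero (such variants are excluded from minimum-finite-fold
summaries). The packaged catalogue of 15 rare drifted pQTLs reproduces the
printed arithmetic: minimum finite fold 2.25, all 15 below 1% in the
reference. Novelty is declared when no catalogued signal lies within 1 Mb
of the index, or when the index association survives conditioning on the
catalogued variants' dosages at the study-wide threshold; novelty is
monotone in the catalogue by construction. Trans signals inside the eight
highly pleiotropic loci (KLKB1, ABO, APOE, FUT2, F12, VTN, CFH, HLA) are
flagged. Replication requires P below $0.05/n_\mathrm{sought}$ *and* a
concordant direction, with proxy lookup at $r^2 > 0.8$ within 1 Mb when
the variant is absent from the replication statistics.

## Colocalization and Mendelian randomization

Colocalization uses Wakefield approximate Bayes factors,
$\log\mathrm{ABF} = \tfrac12\log(1-r) + \tfrac12 z^2 r$ with
$r = W^2/(W^2 + se^2)$, combined over the five standard hypotheses with
priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and colocalization
declared at $PP_4 > 0.8$. The prior effect sd is $W = 1$ per trait — on
the INT-standardized analysis scale this is the parameterization of the
ABF-based implementation the field uses; whether the original analysis
used per-trait defaults is not determinable, so it is config-exposed.
When a peak carries several independent variants, each is colocalized on
statistics conditioned on the others ($\pm$1 Mb regions). With one
variant, $PP_3 = 0$ exactly.

MR instruments are the conditionally independent pQTLs per protein, minus
anything without an rsid; absent instruments may be replaced by an
$r^2 > 0.8$ proxy present in the outcome statistics. Unresolvable
palindromic instruments (outcome effect-allele frequency in 0.42–0.58) are
dropped. A single instrument gives the Wald ratio $\beta = b_y/b_x$ with
delta-method $se = |se_y/b_x|$; two or more give fixed-effect IVW,
$\hat\beta = \sum b_x b_y / se_y^2 \big/ \sum b_x^2/se_y^2$. No
random-effects or Egger variants are fitted — deliberately out of scope
for instrument counts of ten or fewer. P-values are BH-adjusted jointly
across all protein–trait pairs.

# The synthetic cohorts

The generator (`simulate_cohorts()`) emulates, per seed: ancestral ALT
frequencies from the U-shaped Beta(0.5, 0.5); one Balding–Nichols step per
cohort, $p_c \sim \mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$,
which is the standard divergence model for an isolate splitting from a
cosmopolitan ancestor (the reference table keeps the ancestral values, so
founder-style drift of rare alleles arises naturally and is catalogued in
the ground truth); haplotypes from a Gaussian-copula first-order Markov
chain with within-block latent autocorrelation `ld_rho` (block boundaries
reset the chain and never span chromosomes) — enough LD structure for
every $r^2$-based rule downstream at a fraction of a coalescent
simulator's cost, with the caveat that indicator-scale correlation is
attenuated relative to the latent parameter; sibship blocks in which
children inherit whole parental haplotypes, giving expected full-sib
relatedness 0.5 without a pedigree model; covariates with plate following
collection order and season flipped on 10% of samples so that plate and
season are strongly but not perfectly confounded; and LOD censoring at the
configured quantile.

Default study conditions are 1,000 samples per cohort, 5,000 variants on
10 chromosomes, 20 proteins, $F_{st} = 0.02$, LD blocks of 20 at latent
correlation 0.8, sibships of 4, 5 cis and 2 trans effects with sd 0.8 NPX
per allele, polygenic $h^2 = 0.2$, 5% LOD censoring. Tests and the
acceptance script state their own sizes where a check needs a particular
information content (for example, 20,000 variants for the lambda-band
calibration, where the band's sampling error is small, and 2,500 variants
with sibships for heritability recovery).

The outcome-GWAS generator (`simulate_outcome_gwas()`) draws an
independent unrelated sample, builds each trait as the stated causal
effects times the *standardized* protein levels plus unit noise, and
reports marginal per-variant statistics. Standardizing the protein levels
makes the stated protein-to-trait effects per-SD quantities, matching the
INT-standardized exposure scale — without it the MR recovery target would
be scale-inconsistent. Genotypes are generated block-by-block under
per-block seeds so memory stays flat in the outcome sample size. What the
generator does *not* emulate: realistic human LD maps, X-chromosome
dosage, fine-scale population structure within cohorts, assay epitope
artefacts, or sample overlap between exposure and outcome — so passing
tests demonstrate the pipeline's statistical machinery, not robustness to
those real-data complications.

# Numerical choices and degenerate inputs

- The Hardy–Weinberg exact test enumerates heterozygote counts of the
  observed parity in log space and sums configurations no more probable
  than the observed one (with a $1+10^{-12}$ tolerance on the comparison);
  monomorphic input returns 1. It matches an independent
  `choose()`-based enumeration exactly for totals up to 50.
- VIF pruning computes VIFs as the diagonal of the inverse window
  correlation matrix, with a $10^{-10}$ ridge when exact collinearity makes
  it singular; removal order is highest VIF, then lower MAF, then earlier
  position, and variants are processed sorted by position so the result is
  input-order invariant.
- REML is maximized on $\log\lambda \in [-10, 10]$ to a $10^{-6}$
  argument tolerance; a GRM eigenvalue below $-10^{-6}$ is rejected as
  non-PSD, and small negative eigenvalues are clamped to zero. Fits on
  fewer than 30 samples are refused.
- The COJO linear systems get a $10^{-8}$ relative ridge only if singular;
  the collinearity cap makes this rare. Conditioning a variant on a
  near-perfect proxy correctly drives its conditional effect to zero.
- Exact frequency ties in multiallelic allele matching, and palindromic
  instruments at intermediate frequency, are dropped rather than guessed.
- Log-sum-exp and log-diff-exp guard all posterior arithmetic; a
  single-variant region yields $PP_3 = 0$ by construction rather than by
  underflow.
- All randomness flows from one integer seed through R's default
  Mersenne-Twister generator; a fixed seed reproduces every output
  byte-for-byte, including the run manifest (which deliberately contains
  no timestamps).

# Known limitations

The lambda-GC filter and the mixed model behave differently at simulated
panel sizes than at WGS scale, as discussed above; the LOCO default and
the calibrated test sizes are the package's response. The approximate
conditional analysis reconstructs joint effects under a phenotypic
variance of 1 and a shared effective $n$ (the median), which is standard
but approximate when cohort overlap varies by variant. Proxy-based MR
instruments keep the exposure effect of the original variant rather than
re-estimating at the proxy, a documented simplification. The manual
peak-merging step of real analyses is approximated by an automated rule
and is not a reproduction of any particular set of curation decisions.
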