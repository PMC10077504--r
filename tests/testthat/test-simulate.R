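test_that("fixed seed gives identical outputs across runs", {
  cfg <- sim_config(n_samples_per_cohort = 60, n_variants = 200,
                    n_proteins = 3, seed = 9)
  a <- simulate_cohorts(cfg)
  b <- simulate_cohorts(cfg)
  expect_identical(a$cohorts$cohort1$panel$dosage,
                   b$cohorts$cohort1$panel$dosage)
  expect_identical(a$cohorts$cohort2$proteins$npx,
                   b$cohorts$cohort2$proteins$npx)
  expect_identical(a$truth$planted, b$truth$planted)
  ga <- simulate_outcome_gwas(cfg, a$truth, n_gwas = 500)
  gb <- simulate_outcome_gwas(cfg, b$truth, n_gwas = 500)
  expect_identical(ga, gb)
})

test_that("config validation rejects out-of-range values", {
  expect_error(sim_config(drift_fst = 1.2), "drift_fst")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(polygenic_h2 = -0.1), "polygenic_h2")
  expect_error(sim_config(n_proteins = 2, n_cis_effects = 10,
                          n_trans_effects = 7),
               "8 independent signals")
})

test_that("no-drift limit: cohort MAFs match reference within sampling error", {
  cfg <- sim_config(n_samples_per_cohort = 500, n_variants = 400,
                    n_proteins = 2, drift_fst = 0, ld_rho = 0,
                    relatedness_block_size = 1, geno_missing_rate = 0,
                    n_cis_effects = 0, n_trans_effects = 0, seed = 21)
  sim <- simulate_cohorts(cfg)
  p0 <- sim$reference_af$ref_af
  emp <- colMeans(sim$cohorts$cohort1$panel$dosage) / 2
  # binomial error on 2n = 1000 draws
  se <- sqrt(p0 * (1 - p0) / 1000)
  expect_lt(mean(abs(emp - p0) > 4 * se), 0.01)
})

test_that("realized Fst over common variants tracks drift_fst", {
  cfg <- sim_config(n_samples_per_cohort = 300, n_variants = 10000,
                    n_proteins = 1, drift_fst = 0.04, ld_rho = 0,
                    relatedness_block_size = 1, geno_missing_rate = 0,
                    n_cis_effects = 0, n_trans_effects = 0, seed = 31)
  sim <- simulate_cohorts(cfg)
  p0 <- sim$reference_af$ref_af
  p1 <- colMeans(sim$cohorts$cohort1$panel$dosage) / 2
  common <- p0 > 0.05 & p0 < 0.95
  # Hudson-style estimator of divergence from the ancestral frequencies
  num <- (p1[common] - p0[common])^2
  den <- p0[common] * (1 - p0[common])
  fst <- mean(num) / mean(den)
  expect_lt(abs(fst - cfg$drift_fst) / cfg$drift_fst, 0.2)
})

test_that("below-LOD proportion per protein is close to lod_quantile", {
  cfg <- sim_config(n_samples_per_cohort = 800, n_variants = 150,
                    n_proteins = 5, lod_quantile = 0.05, seed = 41)
  sim <- simulate_cohorts(cfg)
  pm <- sim$cohorts$cohort1$proteins
  below <- colMeans(sweep(pm$npx, 2, pm$lod, `<`))
  expect_true(all(abs(below - 0.05) <= 0.02))
})

test_that("null model: no planted effects, h2 = 0 gives uniform P-values", {
  cfg <- sim_config(n_samples_per_cohort = 400, n_variants = 3000,
                    n_proteins = 4, polygenic_h2 = 0, ld_rho = 0,
                    relatedness_block_size = 1,
                    n_cis_effects = 0, n_trans_effects = 0, seed = 51)
  sim <- simulate_cohorts(cfg)
  co <- sim$cohorts$cohort1
  adj <- adjust_and_int(filter_proteins(censor_below_lod(co$proteins))$matrix)
  y <- adj$residuals[, 1]
  ok <- !is.na(y)
  sidx <- match(rownames(adj$residuals)[ok], co$panel$samples)
  sub <- isopqtl::subset_panel(co$panel, samples = sidx)
  fit <- fit_null_lmm(y[ok], diag(length(sidx)))
  a <- lmm_assoc(y[ok], sub, fit)
  expect_lt(fit$h2, 0.15)
  expect_gt(lambda_gc(a$p_wald), 0.92)
  expect_lt(lambda_gc(a$p_wald), 1.08)
})

test_that("planted cis effect is recovered by OLS on the raw matrices", {
  cfg <- sim_config(n_samples_per_cohort = 1000, n_variants = 500,
                    n_proteins = 3, n_cis_effects = 1, n_trans_effects = 0,
                    effect_sizes = 1.0, polygenic_h2 = 0, seed = 61)
  sim <- simulate_cohorts(cfg)
  pl <- sim$truth$planted
  co <- sim$cohorts$cohort1
  g <- co$panel$dosage[, pl$variant_id[1]]
  y <- co$proteins$npx[, pl$protein[1]]
  cov <- co$proteins$covariates
  ols <- lm(y ~ g + cov$age + I(cov$age^2) + cov$sex + factor(cov$plate) +
              cov$season)
  est <- coef(summary(ols))["g", ]
  expect_lt(abs(est["Estimate"] - 1.0), 3 * est["Std. Error"])
})

test_that("sibship blocks produce full-sib relatedness near 0.5", {
  cfg <- sim_config(n_samples_per_cohort = 200, n_variants = 4000,
                    n_proteins = 1, relatedness_block_size = 2, ld_rho = 0,
                    geno_missing_rate = 0,
                    n_cis_effects = 0, n_trans_effects = 0, seed = 71)
  sim <- simulate_cohorts(cfg)
  co <- sim$cohorts$cohort1
  K <- compute_grm(co$panel)
  fam <- sim$cohorts$cohort1$family
  sib_pairs <- which(outer(fam, fam, `==`) & upper.tri(K), arr.ind = TRUE)
  expect_equal(mean(K[sib_pairs]), 0.5, tolerance = 0.1)
  unrel <- which(outer(fam, fam, `!=`) & upper.tri(K), arr.ind = TRUE)
  expect_lt(abs(mean(K[unrel])), 0.05)
})

test_that("outcome GWAS: planted causal effect shows at instrument, null elsewhere", {
  cfg <- sim_config(
    n_samples_per_cohort = 100, n_variants = 500, n_proteins = 3,
    n_cis_effects = 1, n_trans_effects = 0, effect_sizes = 1.0,
    seed = 81)
  sim <- simulate_cohorts(cfg)
  pl <- sim$truth$planted
  truth <- sim$truth
  truth$causal_protein_effects <- tibble::tibble(
    protein = pl$protein[1], trait = "T1", beta = 0.5)
  out <- simulate_outcome_gwas(cfg, truth, n_gwas = 4000, overlap = 1)
  hit <- out[out$rsid == pl$variant_id[1], ]
  # per-SD causal effect times the instrument's per-SD exposure effect
  p <- hit$eaf
  expo_sd <- sqrt(pl$beta[1]^2 * 2 * p * (1 - p) + 1)
  expected <- 0.5 * pl$beta[1] / expo_sd
  expect_lt(abs(hit$beta - expected), 3 * hit$se)
  null_b <- out[out$chrom != pl$chrom[1], ]
  expect_lt(abs(mean(null_b$beta / null_b$se)), 0.1)
})

test_that("zero overlap leaves no usable instruments", {
  cfg <- sim_config(n_samples_per_cohort = 80, n_variants = 200,
                    n_proteins = 2, n_cis_effects = 1, n_trans_effects = 0,
                    seed = 91)
  sim <- simulate_cohorts(cfg)
  out <- simulate_outcome_gwas(cfg, sim$truth, n_gwas = 300, overlap = 0)
  expect_equal(nrow(out), 0)
  expo <- tibble::tibble(rsid = sim$truth$planted$variant_id,
                         chrom = sim$truth$planted$chrom,
                         pos = sim$truth$planted$pos,
                         allele1 = "G", allele0 = "A",
                         beta = 1, se = 0.1)
  instr <- select_instruments(expo, out, panel = NULL)
  expect_equal(nrow(mr_estimate(instr)), 0)
})
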