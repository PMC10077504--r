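test_that("HWE exact test matches full enumeration for n <= 50", {
  expect_equal(hwe_exact_test(20, 0, 0), 1.0)
  expect_equal(hwe_exact_test(0, 2, 0), hwe_oracle(0, 2, 0))
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25))
  set.seed(12)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    n0 <- sample(0:n, 1)
    n1 <- sample(0:(n - n0), 1)
    n2 <- n - n0 - n1
    expect_equal(hwe_exact_test(n0, n1, n2), hwe_oracle(n0, n1, n2),
                 tolerance = 1e-12,
                 info = paste(n0, n1, n2))
  }
  expect_error(hwe_exact_test(-1, 0, 2), "non-negative")
})

test_that("variant QC applies the MAC, missingness and HWE boundaries", {
  set.seed(13)
  n <- 500
  G <- matrix(rbinom(n * 6, 2, 0.3), n, 6)
  G[, 2] <- c(rep(1, 9), rep(0, n - 9))            # MAC 9 -> removed
  G[, 3] <- c(rep(1, 10), rep(0, n - 10))          # MAC 10 -> kept
  G[1:8, 4] <- NA                                  # 1.6% missing -> removed
  G[1:5, 5] <- NA                                  # 1.0% missing -> kept
  G[, 6] <- rep(1, n)                              # all hets: HWE fails
  qc <- variant_qc(make_panel(G))
  expect_false("v2" %in% qc$panel$variants$variant_id)
  expect_true("v3" %in% qc$panel$variants$variant_id)
  expect_false("v4" %in% qc$panel$variants$variant_id)
  expect_true("v5" %in% qc$panel$variants$variant_id)
  expect_false("v6" %in% qc$panel$variants$variant_id)
  expect_equal(qc$qc$fail[qc$qc$variant_id == "v6"], "hwe")
})

test_that("constructed fixture: variants failing exactly one rule are removed", {
  set.seed(14)
  n <- 1000
  m <- 100
  G <- matrix(rbinom(n * m, 2, 0.4), n, m)
  fail_mac <- 1:3
  fail_miss <- 4:5
  fail_hwe <- 6:7
  for (j in fail_mac) G[, j] <- c(rep(1, 5), rep(0, n - 5))
  for (j in fail_miss) G[sample(n, 25), j] <- NA
  for (j in fail_hwe) G[, j] <- rep(c(1, 1, 1, 0), n / 4) # excess hets
  qc <- variant_qc(make_panel(G))
  expect_equal(nrow(qc$panel$variants), 93)
})

test_that("ld_r2: identity, complement invariance, independence bound", {
  set.seed(15)
  g <- rbinom(10000, 2, 0.4)
  panel <- make_panel(cbind(g, 2 - g, rbinom(10000, 2, 0.3)))
  expect_equal(ld_r2(panel, 1, 2), 1.0)
  expect_equal(ld_r2(panel, "v1", "v1"), 1.0)
  expect_lt(ld_r2(panel, 1, 3), 0.01)
  # fewer than 2 complete pairs -> NA
  G <- cbind(c(1, NA, NA), c(NA, 1, 0))
  expect_true(is.na(ld_r2(make_panel(G), 1, 2)))
})

test_that("VIF pruning matches an exhaustive reference on small windows", {
  set.seed(16)
  n <- 400
  # three mutually correlated variants (pairwise r2 ~ 0.6) in one window
  base <- rbinom(n, 2, 0.5)
  flip <- function(g, k) {
    i <- sample(n, k)
    g[i] <- 2 - g[i]
    g
  }
  G <- cbind(base, flip(base, 60), flip(base, 60),
             rbinom(n, 2, 0.3), rbinom(n, 2, 0.4))
  panel <- make_panel(G)
  kept <- ld_prune(panel, window = 10, step = 5, vif = 2)

  # exhaustive search: largest subset whose max VIF is within the bound
  best <- character()
  ids <- panel$variants$variant_id
  for (size in length(ids):1) {
    combos <- utils::combn(ids, size, simplify = FALSE)
    ok <- Filter(function(s) {
      R <- suppressWarnings(cor(G[, match(s, ids), drop = FALSE]))
      max(isopqtl:::vif_from_corr(R)) <= 2
    }, combos)
    if (length(ok) > 0) { best <- ok; break }
  }
  expect_true(length(kept) == length(best[[1]]))
  expect_true(any(vapply(best, function(s) setequal(s, kept), logical(1))))
})

test_that("pruning keeps independent variants, drops exact duplicates, order-invariant", {
  set.seed(17)
  n <- 300
  G <- sapply(1:6, function(i) rbinom(n, 2, runif(1, 0.2, 0.5)))
  panel <- make_panel(G)
  expect_equal(length(ld_prune(panel)), 6)

  Gd <- cbind(G[, 1:3], G[, 3])
  expect_equal(length(ld_prune(make_panel(Gd))), 3)

  # shuffling input variant order leaves the kept set unchanged
  perm <- sample(6)
  panel_perm <- make_panel(G[, perm],
                           pos = (1e6 + (perm - 1) * 5000))
  expect_setequal(ld_prune(panel_perm), paste0("v", 1:6))
})

test_that("GRM: duplicates near 1, unrelated near 0, PSD, unit trace", {
  set.seed(18)
  n <- 150
  m <- 10000
  G <- matrix(rbinom(n * m, 2, 0.3), n, m)
  G[2, ] <- G[1, ]  # duplicate sample
  K <- compute_grm(make_panel(G))
  expect_equal(K[1, 2], 1, tolerance = 0.05)
  off <- K[upper.tri(K)][-1]
  expect_lt(max(abs(off)), 0.1)
  expect_equal(mean(diag(K)), 1, tolerance = 0.05)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
})

test_that("lambda_gc definition, calibration and scale equivariance", {
  expect_equal(lambda_gc(0.5), 1.0)
  set.seed(19)
  p <- runif(1e6)
  lam <- lambda_gc(p)
  expect_gt(lam, 0.99); expect_lt(lam, 1.01)
  # doubling every chi-square statistic doubles lambda
  chi <- qchisq(p[1:1000], 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(lambda_gc(p2), 2 * lambda_gc(p[1:1000]), tolerance = 1e-10)
  expect_error(lambda_gc(numeric(0)), "no P-values")
})

test_that("significance threshold from the phenotype correlation spectrum", {
  plan <- significance_threshold(100, diag(10))
  expect_equal(plan$m_eff_reported, 10L)
  expect_equal(plan$threshold, 0.05 / 1000)

  ones <- matrix(1, 7, 7)
  expect_equal(significance_threshold(1, ones)$m_eff_reported, 1L)

  expect_error(significance_threshold(10, matrix(2, 3, 3)), "unit diagonal")
  expect_error(significance_threshold(10, matrix(1, 2, 3)), "square")
})

test_that("genotype panels round-trip through GT-only VCF", {
  skip_if_not_installed("vcfR")
  set.seed(99)
  G <- matrix(rbinom(60, 2, 0.4), 10, 6)
  G[2, 3] <- NA
  panel <- make_panel(G, chrom = rep(c("1", "2"), each = 3))
  path <- tempfile(fileext = ".vcf")
  write_panel_vcf(panel, path)
  back <- read_panel_vcf(path)
  expect_equal(back$dosage, panel$dosage * 1.0, ignore_attr = TRUE)
  expect_equal(back$variants$variant_id, panel$variants$variant_id)
  expect_equal(back$variants$pos, panel$variants$pos)
  expect_equal(back$samples, panel$samples)
  unlink(path)
})
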