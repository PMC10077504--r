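# helper: wrap summary stats + a dosage matrix into the pieces the signal
# functions need
stats_panel <- function(G, p, chrom = NULL, pos = NULL) {
  panel <- make_panel(G, chrom = chrom, pos = pos)
  meta <- tibble::tibble(
    rsid = panel$variants$variant_id, chrom = panel$variants$chrom,
    pos = panel$variants$pos, af = colMeans(G, na.rm = TRUE) / 2,
    beta = 0, se = 1, p = p, n_total = nrow(G))
  list(panel = panel, meta = meta)
}

test_that("peak extraction follows the greedy LD + distance-grouping trace", {
  set.seed(41)
  n <- 600
  g1 <- rbinom(n, 2, 0.4)
  g2 <- g1
  g2[sample(n, 150)] <- rbinom(150, 2, 0.4)  # r2 ~ 0.5 with g1
  g3 <- rbinom(n, 2, 0.3)                    # independent, far away
  sp <- stats_panel(cbind(g1, g2, g3), p = c(1e-20, 1e-15, 1e-9),
                    pos = c(1.0e6, 1.1e6, 5.0e6))
  stopifnot(isopqtl::ld_r2(sp$panel, 1, 2) > 0.2)
  pk <- extract_peaks(sp$meta, sp$panel, study_threshold = 1e-10)
  expect_equal(nrow(pk), 2)
  expect_setequal(pk$index_rsid, c("v1", "v3"))
  expect_equal(sort(unlist(pk$members)), c("v1", "v3"))  # v2 removed by LD
  expect_equal(pk$significant, c(TRUE, FALSE))           # 1e-9 above 1e-10

  # single significant variant: one peak indexed by it
  sp2 <- stats_panel(cbind(rbinom(n, 2, 0.3)), p = 1e-8)
  pk2 <- extract_peaks(sp2$meta, sp2$panel)
  expect_equal(pk2$index_rsid, "v1")

  # empty significant set
  pk3 <- extract_peaks(sp2$meta |> dplyr::mutate(p = 0.5), sp2$panel)
  expect_equal(nrow(pk3), 0)
})

test_that("peak extraction equals the brute-force reference on random instances", {
  set.seed(42)
  n <- 200
  for (rep in 1:60) {
    m <- sample(5:20, 1)
    # blocks of correlated variants scattered over two chromosomes
    G <- matrix(0L, n, m)
    j <- 1
    while (j <= m) {
      blk <- min(sample(1:4, 1), m - j + 1)
      G[, j:(j + blk - 1)] <- sim_ld_block(n, blk, maf = runif(1, 0.1, 0.5),
                                           rho = runif(1, 0.5, 0.99))
      j <- j + blk
    }
    chrom <- sort(sample(c("1", "2"), m, replace = TRUE))
    pos <- ave(seq_len(m), chrom, FUN = function(i)
      1e6 + cumsum(sample(c(5e4, 1.5e6, 2.5e6), length(i), replace = TRUE,
                          prob = c(0.7, 0.2, 0.1))))
    p <- 10^-runif(m, 0, 15)
    sp <- stats_panel(G, p = p, chrom = chrom, pos = pos)
    pk <- extract_peaks(sp$meta, sp$panel, p_extract = 1e-6, min_mac = 0,
                        hwe_alpha = 0)
    R2 <- suppressWarnings(cor(G)^2)
    oracle <- peaks_oracle(sp$meta, R2, 1e-6, 0.2, 2e6)
    if (is.null(oracle)) {
      expect_equal(nrow(pk), 0)
    } else {
      expect_equal(nrow(pk), length(oracle))
      expect_setequal(pk$index_rsid,
                      vapply(oracle, `[[`, "", "index"))
      got_members <- lapply(pk$members, sort)
      expect_setequal(got_members, lapply(oracle, `[[`, "members"))
    }
  }
})

test_that("clumping retains independent variants and absorbs correlated ones", {
  set.seed(43)
  n <- 500
  G_ind <- sapply(1:4, function(i) rbinom(n, 2, 0.3))
  sp <- stats_panel(G_ind, p = c(1e-10, 1e-8, 1e-6, 1e-4))
  cl <- clump(sp$meta, sp$panel)
  expect_equal(nrow(cl), 4)

  blk <- sim_ld_block(n, 2, maf = 0.4, rho = 0.95)
  sp2 <- stats_panel(blk, p = c(1e-12, 1e-7), pos = c(1e6, 1.2e6))
  stopifnot(isopqtl::ld_r2(sp2$panel, 1, 2) > 0.1)
  cl2 <- clump(sp2$meta, sp2$panel)
  expect_equal(cl2$rsid, "v1")
  expect_equal(unlist(cl2$members), "v2")

  # 50-variant block agrees with an exhaustive greedy reference
  G50 <- sim_ld_block(n, 50, maf = 0.3, rho = 0.8)
  p50 <- 10^-runif(50, 0, 12)
  sp3 <- stats_panel(G50, p = p50)
  cl3 <- clump(sp3$meta, sp3$panel)
  # reference: independent greedy rewrite
  R2 <- suppressWarnings(cor(G50)^2)
  ord <- order(p50)
  alive <- rep(TRUE, 50); kept <- integer()
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i); alive[i] <- FALSE
    near <- which(alive & abs(sp3$meta$pos - sp3$meta$pos[i]) <= 1e6)
    alive[near[R2[i, near] > 0.1]] <- FALSE
  }
  expect_setequal(cl3$rsid, paste0("v", kept))
})

test_that("single causal variant: joint estimate equals marginal", {
  set.seed(44)
  n <- 1000
  G <- sim_ld_block(n, 8, maf = 0.3, rho = 0.7)
  y <- 0.6 * scale(G[, 4]) + rnorm(n)
  y <- (y - mean(y)) / sd(y)
  st <- marginal_stats(G, y)
  panel <- make_panel(G)
  sel <- cojo_select(st, panel, entry_p = 1e-6)
  expect_equal(sel$rsid, "v4")
  expect_equal(sel$joint_beta, sel$beta, tolerance = 1e-6)
  expect_equal(sel$joint_se, sel$se, tolerance = 0.05)
})

test_that("two independent causals: joint betas match individual-level OLS", {
  set.seed(45)
  n <- 1500
  G1 <- sim_ld_block(n, 5, maf = 0.35, rho = 0.8)
  G2 <- sim_ld_block(n, 5, maf = 0.25, rho = 0.8)
  G <- cbind(G1, G2)   # two unlinked blocks
  y <- 0.5 * G[, 2] + 0.4 * G[, 8] + rnorm(n)
  y <- y / sd(y)
  st <- marginal_stats(G, y)
  panel <- make_panel(G)
  sel <- cojo_select(st, panel, entry_p = 1e-6)
  expect_setequal(sel$rsid, c("v2", "v8"))
  ols <- summary(lm(y ~ G[, 2] + G[, 8]))$coefficients
  for (k in 1:2) {
    row <- sel[sel$rsid == c("v2", "v8")[k], ]
    expect_lt(abs(row$joint_beta - ols[k + 1, 1]), 3 * ols[k + 1, 2])
  }

  # pairwise reference r2 of selected variants is below the cap
  expect_lt(ld_r2(panel, sel$rsid[1], sel$rsid[2]), 0.9)
})

test_that("collinearity cap excludes near-duplicates regardless of P", {
  set.seed(46)
  n <- 800
  g <- rbinom(n, 2, 0.4)
  g2 <- g; g2[sample(n, 10)] <- rbinom(10, 2, 0.4)  # r2 ~ 0.97
  G <- cbind(g, g2)
  y <- 0.7 * g + rnorm(n); y <- y / sd(y)
  st <- marginal_stats(G, y)
  panel <- make_panel(G)
  stopifnot(ld_r2(panel, 1, 2) > 0.9)
  sel <- cojo_select(st, panel, entry_p = 1e-4)
  expect_equal(nrow(sel), 1)
})

test_that("conditioning: nothing, a perfect proxy, and a planted two-causal region", {
  set.seed(47)
  n <- 1200
  G <- sim_ld_block(n, 6, maf = 0.3, rho = 0.6)
  y <- 0.5 * G[, 2] + 0.5 * G[, 5] + rnorm(n)
  y <- y / sd(y)
  st <- marginal_stats(G, y)
  panel <- make_panel(G)

  # condition on nothing: statistics unchanged
  c0 <- cojo_condition(st, panel, character(0))
  expect_equal(c0$beta, st$beta)

  # conditioning on a perfect proxy absorbs the signal
  Gp <- cbind(G, G[, 2])
  stp <- marginal_stats(Gp, y)
  cp <- cojo_condition(stp, make_panel(Gp), "v7")
  expect_lt(abs(cp$beta[cp$rsid == "v2"]), 3 * cp$se[cp$rsid == "v2"])
  expect_lt(abs(cp$beta[cp$rsid == "v2"]), 0.05)

  # conditioning on causal 2 leaves causal 1 near its true joint effect
  c1 <- cojo_condition(st, panel, "v5")
  ols <- summary(lm(y ~ G[, 2] + G[, 5]))$coefficients
  row <- c1[c1$rsid == "v2", ]
  expect_lt(abs(row$beta - ols[2, 1]), 3 * row$se)
})

test_that("adjacent peaks merge by distance or LD, idempotently", {
  set.seed(48)
  n <- 400
  G <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4), rbinom(n, 2, 0.2))
  panel <- make_panel(G, chrom = c("1", "1", "1"),
                      pos = c(1e6, 1.5e6, 8e6))
  peaks <- tibble::tibble(
    peak_id = 1:3, chrom = "1", start = c(1e6, 1.5e6, 8e6),
    end = c(1e6, 1.5e6, 8e6), index_rsid = c("v1", "v2", "v3"),
    index_p = c(1e-20, 1e-12, 1e-15), n_members = 1L,
    members = list("v1", "v2", "v3"), significant = TRUE)
  merged <- merge_adjacent_peaks(peaks, panel)
  expect_equal(nrow(merged), 2)          # peaks 0.5 Mb apart merge
  expect_true("v1" %in% merged$index_rsid)  # lower P wins the merged index
  expect_equal(sort(unlist(
    merged$members[merged$index_rsid == "v1"])), c("v1", "v2"))

  # far-apart uncorrelated peaks unchanged; merging is idempotent
  merged2 <- merge_adjacent_peaks(merged, panel)
  expect_equal(merged2$index_rsid, merged$index_rsid)
  expect_equal(merged2$start, merged$start)
})
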