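test_that("cis/trans classification anchored at the gene start, 1 Mb inclusive", {
  genes <- tibble::tibble(
    protein = c("MMP2", "PRSS27", "X"),
    chrom = c("16", "16", "3"),
    gene_start = c(55478830, 2750000, 5e6))
  v <- tibble::tibble(
    rsid = c("rs144755357", "rs681343", "a", "b"),
    chrom = c("16", "19", "3", "3"),
    pos = c(55496937, 48703417, 6e6, 4e6 - 1),
    protein = c("MMP2", "PRSS27", "X", "X"))
  out <- classify_cis_trans(v, genes)
  expect_equal(out$cis_trans,
               c("cis",     # MMP2 variant 18 kb from the MMP2 gene start
                 "trans",   # PRSS27 signal on another chromosome (FUT2 locus)
                 "cis",     # exactly 1,000,000 bp away: inclusive boundary
                 "trans"))  # 1,000,001 bp away

  out2 <- classify_cis_trans(v[1, ], genes[genes$protein == "Y", ])
  expect_equal(out2$cis_trans, "unclassified")
})

test_that("drift folds: printed catalogue arithmetic and sentinels", {
  cat <- drifted_pqtl_catalogue()
  expect_equal(nrow(cat), 15)
  drift <- annotate_drift(
    cat |> dplyr::transmute(variant_id = rsid, cohort = cohorts,
                            maf = cohort_maf),
    cat |> dplyr::transmute(variant_id = rsid, ref_maf = reference_maf))
  eno2 <- drift[drift$variant_id == "rs184861396", ]
  expect_equal(eno2$fold, 2.25)
  aplp1 <- drift[drift$variant_id == "rs767668877", ]
  expect_true(is.infinite(aplp1$fold))
  expect_true(all(drift$rare_in_reference))
  expect_equal(min(drift$fold[is.finite(drift$fold)]), 2.25)

  # cohort MAF equal to reference: fold exactly 1, not drifted
  d2 <- annotate_drift(
    tibble::tibble(variant_id = "v", cohort = "c1", maf = 0.05),
    tibble::tibble(variant_id = "v", ref_maf = 0.05))
  expect_equal(d2$fold, 1.0)
  expect_false(d2$drifted)

  # variant absent from the reference dropped with log
  d3 <- annotate_drift(
    tibble::tibble(variant_id = c("v", "w"), cohort = "c1",
                   maf = c(0.05, 0.1)),
    tibble::tibble(variant_id = "v", ref_maf = 0.05))
  expect_equal(nrow(d3), 1)
  expect_equal(attr(d3, "dropped"), "w")
})

test_that("novelty: window rule, self-conditioning, and monotonicity", {
  set.seed(52)
  n <- 900
  blk <- sim_ld_block(n, 4, maf = 0.3, rho = 0.5)
  far <- rbinom(n, 2, 0.4)
  G <- cbind(blk, far)
  panel <- make_panel(G, chrom = rep("1", 5),
                      pos = c(1e6, 1.1e6, 1.2e6, 1.3e6, 9e6))
  # two independent causals in the block, one known
  y <- 0.8 * G[, 1] + 0.8 * G[, 3] + rnorm(n)
  y <- (y - mean(y)) / sd(y)
  fit <- fit_null_lmm(y, diag(n))
  thr <- 1e-8

  # no known variant near v5: novel by the window rule
  known_far <- tibble::tibble(rsid = "v1", chrom = "1", pos = 1e6)
  out <- condition_on_known(y, panel, fit, "v5", known_far, thr)
  expect_equal(out$status, "novel")

  # the index itself catalogued: absorbed, not novel
  out2 <- condition_on_known(y, panel, fit, "v1",
                             tibble::tibble(rsid = "v1", chrom = "1",
                                            pos = 1e6), thr)
  expect_equal(out2$status, "known")

  # catalogue holds only causal 1: causal 3 stays significant -> novel
  out3 <- condition_on_known(y, panel, fit, "v3", known_far, thr)
  expect_equal(out3$status, "novel")
  expect_equal(out3$n_conditioned, 1L)

  # monotonicity: enlarging the catalogue never turns known into novel
  known_both <- tibble::tibble(rsid = c("v1", "v3"), chrom = "1",
                               pos = c(1e6, 1.2e6))
  out4 <- condition_on_known(y, panel, fit, "v2", known_far, thr)
  out5 <- condition_on_known(y, panel, fit, "v2", known_both, thr)
  if (out4$status == "known") expect_equal(out5$status, "known")
})

test_that("pleiotropic gene flags match the configured list, HLA as a region", {
  genes <- c("FUT2", "CCR3", "ABO", "HLA-DRB1", "MEP1B")
  expect_equal(flag_pleiotropic(genes),
               c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(flag_pleiotropic(genes, pleiotropic = character(0)),
               rep(FALSE, 5))
})

test_that("replication: Bonferroni threshold, direct and proxy lookup", {
  set.seed(53)
  n <- 700
  g1 <- rbinom(n, 2, 0.3)
  g2 <- g1; g2[sample(n, 20)] <- rbinom(20, 2, 0.3)  # tight proxy of g1
  G <- cbind(g1, g2, rbinom(n, 2, 0.4))
  panel <- make_panel(G, pos = c(1e6, 1.05e6, 5e6))
  disc <- tibble::tibble(
    rsid = c("v1", "v3"), chrom = "1", pos = c(1e6, 5e6),
    allele1 = "G", allele0 = "A", beta = c(0.5, -0.3))
  stopifnot(ld_r2(panel, 1, 2) > 0.8)
  repl <- tibble::tibble(
    rsid = c("v2", "v3"), allele1 = "G", allele0 = "A",
    beta = c(0.45, 0.3), se = 0.05, p = c(1e-6, 1e-6))
  out <- replication_lookup(disc, repl, panel)
  expect_equal(out$threshold, rep(0.05 / 2, 2))
  # v1 absent, carried by its r2>0.8 proxy v2, same direction
  expect_equal(out$status[out$rsid == "v1"], "replicated")
  expect_true(out$via_proxy[out$rsid == "v1"])
  expect_equal(out$proxy_rsid[out$rsid == "v1"], "v2")
  # v3 present but with the opposite direction: not replicated
  expect_equal(out$status[out$rsid == "v3"], "not_replicated")

  # direction agreement makes replication invariant to global allele flips
  repl_flip <- repl |>
    dplyr::mutate(allele1 = "A", allele0 = "G", beta = -beta)
  out_flip <- replication_lookup(disc, repl_flip, panel)
  expect_equal(out_flip$status[out_flip$rsid == "v3"], "not_replicated")

  # nothing available: absent
  out2 <- replication_lookup(disc[2, ], repl[0, ], panel)
  expect_equal(out2$status, "absent")

  # 371 variants sought reproduces the printed per-test threshold
  disc371 <- tibble::tibble(
    rsid = paste0("x", 1:371), chrom = "9", pos = seq_len(371),
    allele1 = "G", allele0 = "A", beta = 1)
  out371 <- replication_lookup(disc371, repl[0, ], panel)
  expect_equal(signif(out371$threshold[1], 3), 1.35e-4)
})
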