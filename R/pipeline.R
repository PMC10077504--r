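#' Pipeline configuration with study-default parameters
#'
#' Collects every stage parameter with its canonical default: peak entry P
#' 1e-6, peak LD drop r2 0.2, 2 Mb grouping, clumping r2 0.1 in 1 Mb, 1 Mb
#' cis window, colocalization priors 1e-4/1e-4/1e-5 with posterior 0.8,
#' proxy r2 0.8, alpha 0.05, lambda-GC band [0.97, 1.05], variant
#' missingness cap 1%, protein missingness cap 40%, MAC 10, HWE 1e-5, GRM
#' MAF 1%, VIF pruning 50/5/2. Overrides are recorded in the run manifest.
#'
#' @param sim A [sim_config()] describing the synthetic cohorts (or `NULL`
#'   when a pre-built simulation is passed to [run_pipeline()]).
#' @param ... Named parameter overrides (must match a default's name).
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), ...) {
  defaults <- list(
    p_extract = 1e-6, r2_drop = 0.2, group_dist = 2e6,
    clump_r2 = 0.1, clump_window = 1e6,
    cis_window = 1e6,
    coloc_p1 = 1e-4, coloc_p2 = 1e-4, coloc_p12 = 1e-5,
    coloc_posterior = 0.8, coloc_w = 1,
    proxy_r2 = 0.8, alpha = 0.05,
    lambda_band = c(0.97, 1.05),
    max_missing_variant = 0.01, max_missing_protein = 0.40,
    min_mac = 10, hwe_alpha = 1e-5, grm_min_maf = 0.01,
    prune_window = 50, prune_step = 5, prune_vif = 2,
    merge_r2 = 0.1, merge_dist = 1e6,
    n_gwas = 10000, gwas_overlap = 0.9,
    sex_stratified = TRUE, loco = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  stop_if_not(length(bad) == 0,
              paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over)
  cfg$overridden <- names(over)
  cfg$sim <- sim
  structure(cfg, class = "run_config")
}

#' Run the full pQTL pipeline on a simulated study
#'
#' Executes, in order: phenotype QC (LOD censoring, missingness filters,
#' covariate adjustment, INT), variant QC and GRM construction, per-protein
#' mixed-model association in each cohort, the lambda-GC protein filter,
#' allele harmonization and inverse-variance meta-analysis, peak
#' extraction and merging, LD clumping and stepwise conditional/joint
#' selection, annotation (cis/trans, drift versus the reference table,
#' novelty by conditioning on the known-signal catalogue), sex
#' heterogeneity at the independent variants, colocalization against the
#' simulated outcome GWAS, and two-sample MR with BH adjustment. All stage
#' outputs are returned; when `out_dir` is given they are also written as
#' TSV files together with a deterministic JSON manifest (package version,
#' seed, parameters, row counts per stage).
#'
#' @param config A [run_config()].
#' @param sim Optional pre-built [simulate_cohorts()] result; by default
#'   the simulation described by `config$sim` is generated.
#' @param replication Optional replication summary statistics (`rsid`,
#'   `allele1`, `allele0`, `beta`, `se`, `p`); when supplied, the
#'   independent variants are looked up (with LD proxies) at the
#'   Bonferroni threshold over the variants sought.
#' @param out_dir Optional output directory.
#' @return A list of stage outputs (see details in the packaged analysis
#'   vignette).
#' @export
run_pipeline <- function(config, sim = NULL, replication = NULL,
                         out_dir = NULL) {
  stop_if_not(inherits(config, "run_config"), "config must be a run_config")
  if (is.null(sim)) sim <- simulate_cohorts(config$sim)
  counts <- list()

  # --- phenotypes ---
  pheno <- lapply(sim$cohorts, function(co) {
    cens <- censor_below_lod(co$proteins)
    filt <- filter_proteins(cens, max_missing = config$max_missing_protein)
    adj <- adjust_and_int(filt$matrix)
    list(adjusted = adj, excluded = filt$excluded_proteins,
         covariates = filt$matrix$covariates)
  })
  proteins <- Reduce(intersect, lapply(pheno, function(x)
    colnames(x$adjusted$residuals)))
  counts$proteins_analyzed <- length(proteins)

  # --- variant QC and GRM per cohort (LOCO by default: the GRM used to
  # test chromosome c is built from the pruned variants off c, avoiding
  # proximal contamination at desk-scale panel sizes) ---
  geno <- lapply(sim$cohorts, function(co) {
    qc <- variant_qc(co$panel, max_missing = config$max_missing_variant,
                     min_mac = config$min_mac,
                     hwe_alpha = config$hwe_alpha)
    pruned <- ld_prune(qc$panel, window = config$prune_window,
                       step = config$prune_step, vif = config$prune_vif)
    grm_panel <- subset_panel(qc$panel, variants = pruned)
    # per-chromosome GRM components so the leave-one-chromosome-out
    # matrices cost one pass over the data
    chroms <- unique(grm_panel$variants$chrom)
    comp <- lapply(setNames(chroms, chroms), function(chr) {
      sub <- subset_panel(grm_panel,
                          variants = grm_panel$variants$chrom == chr)
      m_used <- tryCatch({
        K_c <- compute_grm(sub, min_maf = config$grm_min_maf,
                           hwe_alpha = config$hwe_alpha)
        list(K = K_c, m = attr(K_c, "m_variants"))
      }, error = function(e) NULL)
      m_used
    })
    comp <- comp[!vapply(comp, is.null, logical(1))]
    m_tot <- sum(vapply(comp, function(x) x$m, numeric(1)))
    K_sum <- Reduce(`+`, lapply(comp, function(x) x$K * x$m))
    K <- K_sum / m_tot
    K_loco <- NULL
    if (isTRUE(config$loco) && length(comp) > 1L) {
      K_loco <- lapply(setNames(names(comp), names(comp)), function(chr) {
        (K_sum - comp[[chr]]$K * comp[[chr]]$m) / (m_tot - comp[[chr]]$m)
      })
    }
    list(qc = qc, pruned = pruned, K = K, K_loco = K_loco)
  })
  counts$variants_pass_qc <- vapply(geno, function(g) nrow(g$qc$panel$variants),
                                    integer(1))

  # --- significance threshold: N_eff from cohort 1, M_eff from its
  # phenotype correlation matrix ---
  n_eff <- length(geno[[1]]$pruned)
  res1 <- pheno[[1]]$adjusted$residuals[, proteins, drop = FALSE]
  pheno_corr <- suppressWarnings(cor(res1, use = "pairwise.complete.obs"))
  pheno_corr[is.na(pheno_corr)] <- 0
  diag(pheno_corr) <- 1
  plan <- significance_threshold(n_eff, pheno_corr, alpha = config$alpha)

  # --- association per protein per cohort ---
  assoc <- list()
  eig_cache <- list()
  for (ci in seq_along(sim$cohorts)) {
    cname <- names(sim$cohorts)[ci]
    qc_panel <- geno[[ci]]$qc$panel
    K <- geno[[ci]]$K
    res <- pheno[[ci]]$adjusted$residuals
    assoc[[cname]] <- list()
    chroms <- unique(qc_panel$variants$chrom)
    for (pp in proteins) {
      y <- res[, pp]
      ok <- !is.na(y)
      # map residual rows back onto panel samples (QC may have dropped some)
      sidx <- match(rownames(res)[ok], qc_panel$samples)
      hash <- digest_mask(ok)
      sub <- subset_panel(qc_panel, samples = sidx)
      parts <- lapply(chroms, function(chr) {
        Kc <- if (isTRUE(config$loco) && !is.null(geno[[ci]]$K_loco) &&
                    !is.null(geno[[ci]]$K_loco[[chr]])) {
          geno[[ci]]$K_loco[[chr]]
        } else K
        ck <- paste0(cname, ":", if (isTRUE(config$loco)) chr else "all",
                     ":", hash)
        if (is.null(eig_cache[[ck]])) {
          Ks <- Kc[sidx, sidx, drop = FALSE]
          eig_cache[[ck]] <<- eigen((Ks + t(Ks)) / 2, symmetric = TRUE)
        }
        fit <- fit_null_lmm(y[ok], K = NULL, eig = eig_cache[[ck]])
        sub_chr <- subset_panel(sub,
                                variants = sub$variants$chrom == chr)
        lmm_assoc(y[ok], sub_chr, fit)
      })
      assoc[[cname]][[pp]] <- bind_rows(parts) |>
        arrange(.data$chrom, .data$pos)
    }
  }

  # --- lambda-GC protein filter ---
  lam <- lapply(assoc, lambda_gc_filter, band = config$lambda_band)
  keep_prot <- Reduce(intersect, lapply(lam, function(l)
    l$protein[l$keep]))
  counts$proteins_lambda_pass <- length(keep_prot)

  # --- meta-analysis per protein ---
  meta <- lapply(setNames(keep_prot, keep_prot), function(pp) {
    ivw_meta(assoc[[1]][[pp]], assoc[[2]][[pp]])
  })
  counts$meta_variants <- sum(vapply(meta, nrow, integer(1)))

  # --- merged cross-cohort panel for LD ---
  merged_panel <- new_genotype_panel(
    rbind(sim$cohorts[[1]]$panel$dosage, sim$cohorts[[2]]$panel$dosage),
    sim$cohorts[[1]]$panel$variants,
    c(sim$cohorts[[1]]$panel$samples, sim$cohorts[[2]]$panel$samples))

  # --- peaks, clumping, conditional selection ---
  peaks <- list(); cojo <- list()
  for (pp in keep_prot) {
    pk <- extract_peaks(meta[[pp]], merged_panel,
                        p_extract = config$p_extract,
                        r2_drop = config$r2_drop,
                        group_dist = config$group_dist,
                        study_threshold = plan$threshold,
                        min_mac = config$min_mac,
                        hwe_alpha = config$hwe_alpha)
    pk <- merge_adjacent_peaks(pk, merged_panel,
                               merge_r2 = config$merge_r2,
                               merge_dist = config$merge_dist)
    if (nrow(pk) > 0) pk$protein <- pp
    peaks[[pp]] <- pk
    sig <- pk |> filter(.data$significant)
    if (nrow(sig) == 0) next
    sets <- lapply(seq_len(nrow(sig)), function(k) {
      region <- meta[[pp]] |>
        filter(.data$chrom == sig$chrom[k],
               .data$pos >= sig$start[k] - 1e6,
               .data$pos <= sig$end[k] + 1e6,
               .data$p < config$p_extract)
      cl <- clump(region, merged_panel, r2 = config$clump_r2,
                  window = config$clump_window)
      cand <- region |> filter(.data$rsid %in% cl$rsid)
      cs <- cojo_select(cand, merged_panel, entry_p = plan$threshold)
      if (nrow(cs) > 0) {
        cs$peak_id <- sig$peak_id[k]
        cs$protein <- pp
      }
      cs
    })
    cojo[[pp]] <- bind_rows(sets)
  }
  peaks_tbl <- bind_rows(peaks)
  cojo_tbl <- bind_rows(cojo)
  counts$peaks <- nrow(peaks_tbl)
  counts$independent_variants <- nrow(cojo_tbl)

  # --- annotation ---
  annot <- NULL
  if (nrow(cojo_tbl) > 0) {
    annot <- classify_cis_trans(
      cojo_tbl |> select("rsid", "chrom", "pos", "protein"),
      sim$truth$gene_locations |>
        select("protein", "chrom", "gene_start"),
      window = config$cis_window)
    cohort_afs <- bind_rows(lapply(names(sim$cohorts), function(cn) {
      pnl <- sim$cohorts[[cn]]$panel
      idx <- match(cojo_tbl$rsid, pnl$variants$variant_id)
      tibble(variant_id = cojo_tbl$rsid, cohort = cn,
             maf = maf_of(colMeans(pnl$dosage[, idx, drop = FALSE],
                                   na.rm = TRUE) / 2))
    }))
    drift <- annotate_drift(cohort_afs,
                            sim$reference_af |>
                              select("variant_id", "ref_maf"))
    # novelty: condition cohort-1 association on the known catalogue
    res1m <- pheno[[1]]$adjusted$residuals
    novelty <- bind_rows(lapply(unique(cojo_tbl$protein), function(pp) {
      y <- res1m[, pp]; ok <- !is.na(y)
      sidx <- match(rownames(res1m)[ok], geno[[1]]$qc$panel$samples)
      sub <- subset_panel(geno[[1]]$qc$panel, samples = sidx)
      fit <- fit_null_lmm(y[ok], geno[[1]]$K[sidx, sidx, drop = FALSE])
      ids <- cojo_tbl$rsid[cojo_tbl$protein == pp]
      ids <- ids[ids %in% sub$variants$variant_id]
      if (length(ids) == 0) return(NULL)
      condition_on_known(y[ok], sub, fit, ids, sim$known_signals,
                         plan$threshold) |> mutate(protein = pp)
    }))
    annot <- annot |>
      left_join(novelty, by = c("rsid", "protein"))
    if (!is.null(replication)) {
      disc <- cojo_tbl |>
        mutate(allele1 = "G", allele0 = "A", beta = .data$joint_beta) |>
        select("rsid", "chrom", "pos", "allele1", "allele0", "beta")
      repl <- replication_lookup(disc, replication, merged_panel,
                                 proxy_r2 = config$proxy_r2,
                                 alpha = config$alpha)
      annot <- annot |>
        left_join(repl |> select("rsid", replication = "status",
                                 "proxy_rsid"),
                  by = "rsid")
    }
  }

  # --- sex heterogeneity at the independent variants ---
  sexhet <- NULL
  if (isTRUE(config$sex_stratified) && nrow(cojo_tbl) > 0) {
    sex_meta <- lapply(c(male = 1, female = 0), function(sx) {
      per_cohort <- lapply(seq_along(sim$cohorts), function(ci) {
        cov <- pheno[[ci]]$covariates
        res <- pheno[[ci]]$adjusted$residuals
        panel_ids <- intersect(cojo_tbl$rsid,
                               geno[[ci]]$qc$panel$variants$variant_id)
        if (length(panel_ids) == 0) return(NULL)
        out <- lapply(unique(cojo_tbl$protein), function(pp) {
          y <- res[, pp]
          mask <- !is.na(y) & cov$sex == sx
          if (sum(mask) < 30) return(NULL)
          sidx <- match(rownames(res)[mask], geno[[ci]]$qc$panel$samples)
          sub <- subset_panel(geno[[ci]]$qc$panel, samples = sidx)
          sub <- subset_panel(sub, variants = intersect(
            cojo_tbl$rsid[cojo_tbl$protein == pp],
            sub$variants$variant_id))
          if (nrow(sub$variants) == 0) return(NULL)
          K <- geno[[ci]]$K[sidx, sidx, drop = FALSE]
          fit <- fit_null_lmm(y[mask], K)
          lmm_assoc(y[mask], sub, fit)
        })
        bind_rows(out)
      })
      if (any(vapply(per_cohort, is.null, logical(1)))) return(NULL)
      ivw_meta(per_cohort[[1]], per_cohort[[2]])
    })
    if (!is.null(sex_meta$male) && !is.null(sex_meta$female)) {
      sexhet <- sex_het_test(sex_meta$male, sex_meta$female,
                             alpha = config$alpha)
    }
  }

  # --- outcome GWAS, colocalization, MR ---
  outcome <- simulate_outcome_gwas(config$sim, sim$truth,
                                   n_gwas = config$n_gwas,
                                   overlap = config$gwas_overlap)
  traits <- unique(outcome$trait)
  coloc_res <- list(); mr_res <- list()
  if (nrow(cojo_tbl) > 0) {
    for (pp in unique(cojo_tbl$protein)) {
      sel <- cojo_tbl |> filter(.data$protein == pp)
      for (tr in traits) {
        out_tr <- outcome |> filter(.data$trait == tr)
        # colocalization per independent variant, conditioned on the others
        for (k in seq_len(nrow(sel))) {
          region <- meta[[pp]] |>
            filter(.data$chrom == sel$chrom[k],
                   abs(.data$pos - sel$pos[k]) <= 1e6)
          others <- setdiff(sel$rsid[sel$peak_id == sel$peak_id[k]],
                            sel$rsid[k])
          reg_stats <- if (length(others) > 0) {
            cojo_condition(region, merged_panel, others)
          } else region
          shared <- intersect(reg_stats$rsid, out_tr$rsid)
          if (length(shared) == 0) next
          cres <- coloc_region(
            reg_stats, out_tr |> select("rsid", "beta", "se"),
            p1 = config$coloc_p1, p2 = config$coloc_p2,
            p12 = config$coloc_p12, W1 = config$coloc_w,
            W2 = config$coloc_w,
            posterior_threshold = config$coloc_posterior)
          cres$protein <- pp; cres$trait <- tr; cres$rsid <- sel$rsid[k]
          coloc_res[[length(coloc_res) + 1L]] <- cres
        }
        # MR
        expo <- sel |>
          transmute(rsid = .data$rsid, chrom = .data$chrom,
                    pos = .data$pos,
                    allele1 = "G", allele0 = "A",
                    beta = .data$joint_beta, se = .data$joint_se)
        instr <- select_instruments(expo, out_tr, merged_panel,
                                    proxy_r2 = config$proxy_r2)
        est <- mr_estimate(instr)
        if (nrow(est) > 0) {
          est$protein <- pp; est$trait <- tr
          mr_res[[length(mr_res) + 1L]] <- est
        }
      }
    }
  }
  coloc_tbl <- bind_rows(coloc_res)
  mr_tbl <- bind_rows(mr_res)
  if (nrow(mr_tbl) > 0) mr_tbl$p_fdr <- fdr_adjust(mr_tbl$p)
  counts$coloc_tests <- nrow(coloc_tbl)
  counts$mr_pairs <- nrow(mr_tbl)

  manifest <- list(
    package = "isopqtl",
    version = as.character(packageVersion("isopqtl")),
    seed = config$sim$seed,
    parameters = config[setdiff(names(config),
                                c("sim", "overridden"))],
    overridden = config$overridden,
    sim = config$sim[setdiff(names(config$sim),
                             "causal_protein_effects")],
    counts = counts,
    threshold = plan$threshold,
    n_eff = plan$n_eff, m_eff_reported = plan$m_eff_reported)

  result <- list(
    sim = sim, phenotypes = pheno, genotypes = geno, plan = plan,
    association = assoc, lambda = lam, meta = meta, peaks = peaks_tbl,
    independent = cojo_tbl, annotation = annot, sex_het = sexhet,
    outcome_gwas = outcome, coloc = coloc_tbl, mr = mr_tbl,
    manifest = manifest)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# stable short hash of a logical mask (no external digest dependency)
digest_mask <- function(mask) {
  paste0(sum(mask), ":", paste(range(which(mask)), collapse = "-"), ":",
         sum(which(mask)))
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) return(invisible(NULL))
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(result$peaks, "peaks")
  wr(result$independent, "independent_variants")
  wr(result$annotation, "annotation")
  wr(result$sex_het, "sex_heterogeneity")
  wr(result$coloc, "colocalization")
  wr(result$mr, "mendelian_randomization")
  wr(result$outcome_gwas, "outcome_gwas")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
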