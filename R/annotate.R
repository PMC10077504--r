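#' Classify variants as cis or trans relative to the encoding gene
#'
#' A variant is cis for a protein when it lies on the same chromosome and
#' within `window` base pairs of the start of the gene encoding that
#' protein (boundary inclusive); otherwise it is trans. Proteins with no
#' known gene location get an `unclassified` sentinel.
#'
#' @param variants Tibble with `rsid`, `chrom`, `pos` and `protein`.
#' @param gene_locations Tibble with `protein`, `chrom`, `gene_start`.
#' @param window Cis window in base pairs (anchored at the gene start).
#' @return `variants` with `cis_trans` and `dist_to_gene` columns added.
#' @export
classify_cis_trans <- function(variants, gene_locations, window = 1e6) {
  gi <- match(variants$protein, gene_locations$protein)
  gchrom <- gene_locations$chrom[gi]
  gstart <- gene_locations$gene_start[gi]
  dist <- ifelse(!is.na(gchrom) & variants$chrom == gchrom,
                 abs(variants$pos - gstart), Inf)
  cls <- case_when(
    is.na(gchrom) ~ "unclassified",
    dist <= window ~ "cis",
    TRUE ~ "trans")
  variants |> mutate(cis_trans = cls,
                     dist_to_gene = ifelse(is.finite(dist), dist, NA_real_))
}

#' Annotate allele-frequency drift against a reference population
#'
#' For each signal variant and cohort, the drift fold is the cohort minor
#' allele frequency divided by the reference (cosmopolitan) MAF; a zero
#' reference frequency yields an infinite fold, which is reported but
#' excluded from minimum-finite-fold summaries. Variants rare in the
#' reference (`reference MAF < rare_cut`) are flagged, as are variants
#' whose fold reaches `min_fold` in at least one cohort. Both frequency
#' sources must be on the minor-allele scale; variants absent from the
#' reference are dropped with a log attribute.
#'
#' @param cohort_afs Long tibble: `variant_id` (or `rsid`), `cohort`, `maf`.
#' @param reference Tibble: `variant_id` (or `rsid`), `ref_maf`.
#' @param min_fold Fold threshold flagging drifted variants.
#' @param rare_cut Reference-MAF threshold for the rare flag.
#' @return Tibble: `variant_id`, `cohort`, `cohort_maf`, `reference_maf`,
#'   `fold`, `rare_in_reference`, `drifted`.
#' @export
annotate_drift <- function(cohort_afs, reference, min_fold = 2.25,
                           rare_cut = 0.01) {
  ca <- as_tibble(cohort_afs)
  if (!"variant_id" %in% names(ca) && "rsid" %in% names(ca)) {
    ca <- rename(ca, variant_id = "rsid")
  }
  ref <- as_tibble(reference)
  if (!"variant_id" %in% names(ref) && "rsid" %in% names(ref)) {
    ref <- rename(ref, variant_id = "rsid")
  }
  ri <- match(ca$variant_id, ref$variant_id)
  dropped <- unique(ca$variant_id[is.na(ri)])
  ca <- ca[!is.na(ri), , drop = FALSE]
  ref_maf <- ref$ref_maf[ri[!is.na(ri)]]
  fold <- ifelse(ref_maf == 0, Inf, ca$maf / ref_maf)
  out <- tibble(
    variant_id = ca$variant_id, cohort = ca$cohort,
    cohort_maf = ca$maf, reference_maf = ref_maf, fold = fold,
    rare_in_reference = ref_maf < rare_cut,
    drifted = fold >= min_fold)
  attr(out, "dropped") <- dropped
  out
}

#' Built-in catalogue of rare drifted pQTL variants
#'
#' Fifteen pQTL variants that are rare (reference MAF below 1 percent) in
#' non-Finnish Europeans but drifted up in frequency, by at least 2.25-fold,
#' in one or both Hellenic isolate discovery cohorts. Frequencies are
#' proportions on the minor-allele scale.
#'
#' @return A tibble with `protein`, `chrom`, `pos`, `rsid`, `cohorts`,
#'   `cis_trans`, `cohort_maf`, `reference_maf`, `consequence`.
#' @export
drifted_pqtl_catalogue <- function() {
  path <- system.file("extdata", "drifted_pqtls.tsv", package = "isopqtl",
                      mustWork = TRUE)
  as_tibble(read.delim(path, colClasses = c(chrom = "character")))
}

#' Declare signal novelty by conditioning on known variants
#'
#' A signal is novel when either no catalogued variant lies within
#' `window` base pairs of its index variant, or the index association
#' remains study-wide significant after adding the dosages of the
#' catalogued variants as covariates to the mixed-model test. Catalogued
#' variants absent from the panel cannot be conditioned on and are logged.
#'
#' @param y Adjusted phenotype aligned with the panel samples.
#' @param panel `genotype_panel` carrying the index and known variants.
#' @param fit [fit_null_lmm()] result for `y`.
#' @param index_rsids Index variants of the signals to assess.
#' @param known Catalogue tibble: `rsid`, `chrom`, `pos`.
#' @param study_threshold Study-wide significance threshold.
#' @param window Search window around the index variant.
#' @return Tibble: `rsid`, `status` (`novel` / `known`), `n_conditioned`,
#'   `p_conditional`.
#' @export
condition_on_known <- function(y, panel, fit, index_rsids, known,
                               study_threshold, window = 1e6) {
  v <- panel$variants
  G <- impute_dosage(panel$dosage * 1.0)
  not_conditionable <- setdiff(known$rsid, v$variant_id)
  rows <- lapply(index_rsids, function(rs) {
    i <- match(rs, v$variant_id)
    stop_if_not(!is.na(i), paste0("index variant ", rs, " not in panel"))
    nearby <- known[known$chrom == v$chrom[i] &
                      abs(known$pos - v$pos[i]) <= window, , drop = FALSE]
    cond_ids <- intersect(nearby$rsid, v$variant_id)
    if (length(cond_ids) == 0L) {
      return(tibble(rsid = rs, status = "novel", n_conditioned = 0L,
                    p_conditional = NA_real_))
    }
    if (rs %in% cond_ids) {
      # conditioning on the index itself absorbs the signal entirely
      return(tibble(rsid = rs, status = "known",
                    n_conditioned = length(cond_ids), p_conditional = 1))
    }
    C <- G[, match(cond_ids, v$variant_id), drop = FALSE]
    wt <- wald_conditional(y, G[, i], C, fit)
    tibble(rsid = rs,
           status = if (!is.na(wt$p) && wt$p < study_threshold) "novel"
                    else "known",
           n_conditioned = length(cond_ids), p_conditional = wt$p)
  })
  out <- bind_rows(rows)
  attr(out, "not_conditionable") <- not_conditionable
  out
}

#' Flag trans signals located in highly pleiotropic genes
#'
#' @param genes Character vector: the gene containing (or nearest to) each
#'   trans signal.
#' @param pleiotropic Configured list of pleiotropic genes; the default is
#'   the eight loci associated with multiple proteins across studies. The
#'   `HLA` entry matches the whole HLA region (any gene name starting
#'   `HLA`).
#' @return Logical vector.
#' @export
flag_pleiotropic <- function(genes,
                             pleiotropic = c("KLKB1", "ABO", "APOE", "FUT2",
                                             "F12", "VTN", "CFH", "HLA")) {
  if (length(pleiotropic) == 0L) return(rep(FALSE, length(genes)))
  direct <- genes %in% pleiotropic
  hla <- "HLA" %in% pleiotropic & startsWith(genes, "HLA")
  direct | hla
}

#' Replication lookup with LD proxies
#'
#' Each discovery variant is looked up directly in the replication summary
#' statistics; when absent, the best available proxy within `window` base
#' pairs at r-squared above `proxy_r2` on the LD panel is substituted.
#' A variant replicates when its (or its proxy's) replication P-value is
#' below `alpha / n_sought` (Bonferroni over the variants sought) and the
#' effect direction agrees with discovery after allele alignment.
#'
#' @param discovery Tibble of the variants sought: `rsid`, `chrom`, `pos`,
#'   `allele1`, `allele0`, `beta`.
#' @param replication Replication summary tibble with the same columns plus
#'   `se`, `p`.
#' @param panel LD source `genotype_panel` (for proxy search).
#' @param proxy_r2 Minimum proxy LD.
#' @param alpha Familywise rate; per-test threshold is `alpha/n_sought`.
#' @return Tibble: `rsid`, `status` (`replicated`, `not_replicated`,
#'   `absent`), `via_proxy`, `proxy_rsid`, `proxy_r2`, `p_replication`,
#'   `threshold`.
#' @export
replication_lookup <- function(discovery, replication, panel,
                               proxy_r2 = 0.8, alpha = 0.05) {
  n_sought <- nrow(discovery)
  thr <- alpha / max(1L, n_sought)
  v <- panel$variants
  rows <- lapply(seq_len(n_sought), function(i) {
    d <- discovery[i, ]
    hit <- replication[replication$rsid == d$rsid, , drop = FALSE]
    via_proxy <- FALSE; proxy_id <- NA_character_; pr2 <- NA_real_
    d_beta <- d$beta
    if (nrow(hit) == 0L) {
      # proxy search on the panel
      di <- match(d$rsid, v$variant_id)
      if (!is.na(di)) {
        cand <- which(v$chrom == v$chrom[di] &
                        abs(v$pos - v$pos[di]) <= 1e6 &
                        v$variant_id %in% replication$rsid &
                        v$variant_id != d$rsid)
        if (length(cand) > 0L) {
          r2s <- vapply(cand, function(j) ld_r2(panel, di, j), numeric(1))
          ok <- !is.na(r2s) & r2s > proxy_r2
          if (any(ok)) {
            best <- cand[ok][which.max(r2s[ok])]
            proxy_id <- v$variant_id[best]
            pr2 <- max(r2s[ok])
            hit <- replication[replication$rsid == proxy_id, , drop = FALSE]
            via_proxy <- TRUE
          }
        }
      }
    }
    if (nrow(hit) == 0L) {
      return(tibble(rsid = d$rsid, status = "absent", via_proxy = FALSE,
                    proxy_rsid = NA_character_, proxy_r2 = NA_real_,
                    p_replication = NA_real_, threshold = thr))
    }
    h <- hit[1, ]
    flip <- 1
    if (!via_proxy && all(c("allele1", "allele0") %in% names(h)) &&
        !is.na(d$allele1)) {
      if (h$allele1 == d$allele0 && h$allele0 == d$allele1) flip <- -1
    }
    agree <- sign(h$beta * flip) == sign(d_beta)
    tibble(rsid = d$rsid,
           status = if (h$p < thr && agree) "replicated" else "not_replicated",
           via_proxy = via_proxy, proxy_rsid = proxy_id, proxy_r2 = pr2,
           p_replication = h$p, threshold = thr)
  })
  bind_rows(rows)
}
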