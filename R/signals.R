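#' Extract association peaks by greedy LD pruning and distance grouping
#'
#' Variants passing `p_extract` are sorted by increasing P-value; for each
#' in turn, variants in LD at r-squared above `r2_drop` (same chromosome)
#' are removed, and the survivor moves on. Surviving variants located
#' within `group_dist` of each other are then grouped, and each group's
#' index variant is the one with the lowest P-value. Candidate index
#' variants must have minor allele count at least `min_mac` and pass the
#' Hardy-Weinberg exact test at `hwe_alpha` on the LD panel.
#'
#' @param meta Meta-analysis tibble (`rsid`, `chrom`, `pos`, `p`, ...).
#' @param panel `genotype_panel` used as the LD source (typically merged
#'   cross-cohort genotypes).
#' @param p_extract Entry P-value threshold for peak extraction.
#' @param r2_drop LD pruning threshold.
#' @param group_dist Grouping distance in base pairs (rule is strictly
#'   less-than).
#' @param study_threshold Study-wide significance threshold; peaks whose
#'   index P is not below it are flagged `significant = FALSE`.
#' @param min_mac,hwe_alpha Candidate filters applied on the panel.
#' @return A tibble of peaks: `peak_id`, `chrom`, `start`, `end`,
#'   `index_rsid`, `index_p`, `n_members`, `members` (list column),
#'   `significant`.
#' @export
extract_peaks <- function(meta, panel, p_extract = 1e-6, r2_drop = 0.2,
                          group_dist = 2e6, study_threshold = NULL,
                          min_mac = 10, hwe_alpha = 1e-5) {
  cand <- meta |> filter(.data$p < p_extract)
  if (nrow(cand) == 0L) return(empty_peaks())
  # candidate index-variant QC on the LD panel
  in_panel <- cand$rsid %in% panel$variants$variant_id
  cand <- cand[in_panel, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_peaks())
  idx <- match(cand$rsid, panel$variants$variant_id)
  G <- impute_dosage(panel$dosage[, idx, drop = FALSE] * 1.0)
  Graw <- panel$dosage[, idx, drop = FALSE]
  n_obs <- colSums(!is.na(Graw))
  alt <- colSums(Graw, na.rm = TRUE)
  mac <- pmin(alt, 2 * n_obs - alt)
  hwe <- apply(Graw, 2, hwe_from_dosage)
  ok <- mac >= min_mac & !is.na(hwe) & hwe >= hwe_alpha
  cand <- cand[ok, , drop = FALSE]
  G <- G[, ok, drop = FALSE]
  if (nrow(cand) == 0L) return(empty_peaks())

  # greedy LD pruning in ascending P order
  ord <- order(cand$p, cand$chrom, cand$pos)
  alive <- rep(TRUE, nrow(cand))
  survivors <- integer()
  for (i in ord) {
    if (!alive[i]) next
    survivors <- c(survivors, i)
    same_chr <- alive & cand$chrom == cand$chrom[i]
    same_chr[i] <- FALSE
    for (j in which(same_chr)) {
      r2 <- r2_pair(G[, i], G[, j])
      if (!is.na(r2) && r2 > r2_drop) alive[j] <- FALSE
    }
    alive[i] <- FALSE
  }
  surv <- cand[survivors, , drop = FALSE] |> arrange(.data$chrom, .data$pos)

  # distance grouping of survivors
  grp <- integer(nrow(surv))
  g <- 0L
  for (i in seq_len(nrow(surv))) {
    if (i == 1L || surv$chrom[i] != surv$chrom[i - 1L] ||
        surv$pos[i] - surv$pos[i - 1L] >= group_dist) {
      g <- g + 1L
    }
    grp[i] <- g
  }
  surv$.grp <- grp
  peaks <- surv |>
    group_by(.data$.grp) |>
    summarise(
      chrom = first(.data$chrom), start = min(.data$pos),
      end = max(.data$pos),
      index_rsid = .data$rsid[which.min(.data$p)],
      index_p = min(.data$p), n_members = n(),
      members = list(.data$rsid), .groups = "drop") |>
    select(-".grp") |>
    arrange(.data$chrom, .data$start) |>
    mutate(peak_id = row_number(), .before = 1)
  peaks$significant <- if (is.null(study_threshold)) NA else
    peaks$index_p < study_threshold
  peaks
}

empty_peaks <- function() {
  tibble(peak_id = integer(), chrom = character(), start = double(),
         end = double(), index_rsid = character(), index_p = double(),
         n_members = integer(), members = list(), significant = logical())
}

#' Greedy LD clumping of summary statistics
#'
#' Variants are visited by ascending P-value; each retained variant absorbs
#' (and removes from candidacy) all variants within `window` base pairs on
#' the same chromosome whose LD with it exceeds `r2`.
#'
#' @param meta Summary-statistic tibble (`rsid`, `chrom`, `pos`, `p`).
#' @param panel LD source `genotype_panel`.
#' @param r2 LD threshold for assignment.
#' @param window Distance window in base pairs.
#' @return Tibble of retained index variants with their absorbed members:
#'   `rsid`, `chrom`, `pos`, `p`, `members` (list column).
#' @export
clump <- function(meta, panel, r2 = 0.1, window = 1e6) {
  keep <- meta$rsid %in% panel$variants$variant_id
  m <- meta[keep, , drop = FALSE]
  if (nrow(m) == 0L) {
    return(tibble(rsid = character(), chrom = character(), pos = double(),
                  p = double(), members = list()))
  }
  idx <- match(m$rsid, panel$variants$variant_id)
  G <- impute_dosage(panel$dosage[, idx, drop = FALSE] * 1.0)
  ord <- order(m$p, m$chrom, m$pos)
  alive <- rep(TRUE, nrow(m))
  out <- list()
  for (i in ord) {
    if (!alive[i]) next
    alive[i] <- FALSE
    near <- which(alive & m$chrom == m$chrom[i] &
                    abs(m$pos - m$pos[i]) <= window)
    mem <- character()
    for (j in near) {
      r2ij <- r2_pair(G[, i], G[, j])
      if (!is.na(r2ij) && r2ij > r2) {
        alive[j] <- FALSE
        mem <- c(mem, m$rsid[j])
      }
    }
    out[[length(out) + 1L]] <- tibble(
      rsid = m$rsid[i], chrom = m$chrom[i], pos = m$pos[i], p = m$p[i],
      members = list(mem))
  }
  bind_rows(out) |> arrange(.data$chrom, .data$pos)
}

# ---- approximate joint/conditional algebra ----------------------------
#
# Summary-statistic reconstruction of the multiple regression of the
# phenotype on a set of variants: with D_j = 2 f_j (1 - f_j) n_j the
# (scaled) genotype sum of squares and W_j = D_j * beta_j the score,
# X'X is approximated by B = sqrt(D) R sqrt(D) with R the reference LD
# correlation matrix, so the joint effects are solve(B, W). The phenotypic
# variance is taken as 1 (INT scale).

cojo_engine <- function(stats, R, var_y = 1) {
  D <- 2 * stats$af * (1 - stats$af) * stats$n
  W <- D * stats$beta
  list(D = D, W = W, R = R, n = median(stats$n), var_y = var_y)
}

cojo_joint <- function(eng, sel) {
  k <- length(sel)
  sD <- sqrt(eng$D[sel])
  B <- eng$R[sel, sel, drop = FALSE] * tcrossprod(sD)
  Binv <- tryCatch(solve(B), error = function(e)
    solve(B + diag(1e-8 * diag(B), k)))
  b <- drop(Binv %*% eng$W[sel])
  rss <- eng$n * eng$var_y - sum(b * eng$W[sel])
  sigma2 <- max(rss, 1e-12) / (eng$n - k)
  se <- sqrt(pmax(diag(Binv), 0) * sigma2)
  p <- 2 * pnorm(-abs(b / se))
  list(beta = b, se = se, p = p, sigma2 = sigma2)
}

cojo_conditional <- function(eng, sel, cand) {
  jf <- cojo_joint(eng, sel)
  sDs <- sqrt(eng$D[sel])
  out <- lapply(cand, function(j) {
    bj <- eng$R[j, sel, drop = FALSE] * sqrt(eng$D[j]) * sDs  # B_{jS}
    b_cond <- eng$W[j] / eng$D[j] - drop(bj %*% jf$beta) / eng$D[j]
    se_cond <- sqrt(jf$sigma2 / eng$D[j])
    tibble(idx = j, beta_cond = b_cond, se_cond = se_cond,
           p_cond = 2 * pnorm(-abs(b_cond / se_cond)))
  })
  bind_rows(out)
}

#' Stepwise approximate conditional and joint model selection
#'
#' COJO-style forward selection from summary statistics plus a reference LD
#' panel: starting from the lowest-P variant, the candidate with the
#' smallest conditional P-value given the selected set is added while that
#' P-value is below `entry_p` and its maximum LD with the selected set is
#' below `collinearity_r2`; a final joint fit is run and any selected
#' variant whose joint P rises to or above `entry_p` is removed
#' (backward step). Candidates absent from the LD panel are skipped
#' (ids in the `skipped` attribute).
#'
#' @param meta Summary statistics of the candidate variants (typically the
#'   [clump()] indices of one region): `rsid`, `chrom`, `pos`, `af`,
#'   `beta`, `se`, `p`, `n_total` (or `n`).
#' @param panel LD reference `genotype_panel` with the same allele
#'   orientation.
#' @param entry_p Conditional/joint P-value threshold (the study-wide
#'   threshold by default choice of the caller).
#' @param collinearity_r2 Maximum LD allowed between selected variants.
#' @param var_y Phenotypic variance (1 on the INT scale).
#' @return Tibble of conditionally independent variants with `joint_beta`,
#'   `joint_se`, `joint_p` and the marginal `beta`, `se`, `p`.
#' @export
cojo_select <- function(meta, panel, entry_p, collinearity_r2 = 0.9,
                        var_y = 1) {
  stats <- normalize_n(meta)
  in_panel <- stats$rsid %in% panel$variants$variant_id
  skipped <- stats$rsid[!in_panel]
  stats <- stats[in_panel, , drop = FALSE]
  if (nrow(stats) == 0L || min(stats$p) >= entry_p) {
    out <- empty_cojo()
    attr(out, "skipped") <- skipped
    return(out)
  }
  R <- ld_matrix(panel, stats$rsid)
  eng <- cojo_engine(stats, R, var_y)

  sel <- which.min(stats$p)
  repeat {
    cand <- setdiff(seq_len(nrow(stats)), sel)
    # collinearity cap against the already-selected set
    if (length(cand) > 0L) {
      maxr2 <- apply(R[cand, sel, drop = FALSE]^2, 1, max)
      cand <- cand[maxr2 < collinearity_r2]
    }
    added <- FALSE
    if (length(cand) > 0L) {
      cond <- cojo_conditional(eng, sel, cand)
      best <- cond[which.min(cond$p_cond), ]
      if (best$p_cond < entry_p) {
        sel <- c(sel, best$idx)
        added <- TRUE
      }
    }
    # backward elimination on the joint fit
    dropped_any <- FALSE
    if (length(sel) > 1L) {
      jf <- cojo_joint(eng, sel)
      worst <- which.max(jf$p)
      if (jf$p[worst] >= entry_p) {
        sel <- sel[-worst]
        dropped_any <- TRUE
      }
    }
    if (!added && !dropped_any) break
  }
  jf <- cojo_joint(eng, sel)
  ord <- order(stats$chrom[sel], stats$pos[sel])
  out <- tibble(
    rsid = stats$rsid[sel], chrom = stats$chrom[sel], pos = stats$pos[sel],
    af = stats$af[sel],
    beta = stats$beta[sel], se = stats$se[sel], p = stats$p[sel],
    joint_beta = unname(jf$beta), joint_se = unname(jf$se),
    joint_p = unname(jf$p))[ord, ]
  attr(out, "skipped") <- skipped
  out
}

empty_cojo <- function() {
  tibble(rsid = character(), chrom = character(), pos = double(),
         af = double(), beta = double(), se = double(), p = double(),
         joint_beta = double(), joint_se = double(), joint_p = double())
}

normalize_n <- function(meta) {
  stats <- as_tibble(meta)
  if (!"n" %in% names(stats) && "n_total" %in% names(stats)) {
    stats$n <- stats$n_total
  }
  if (!"p" %in% names(stats) && "p_wald" %in% names(stats)) {
    stats$p <- stats$p_wald
  }
  stop_if_not(all(c("rsid", "chrom", "pos", "af", "beta", "se", "p", "n")
                  %in% names(stats)), "missing summary-statistic columns")
  stats
}

#' Condition summary statistics on a set of variants
#'
#' Approximate conditional beta, SE and P for every remaining variant given
#' the variants in `condition_on`, using the same summary-statistic algebra
#' as [cojo_select()] but with no selection. Conditioning on nothing
#' returns the input statistics unchanged; a variant in near-perfect LD
#' with a conditioning variant has its signal absorbed (conditional beta
#' near zero).
#'
#' @param meta Region summary statistics (see [cojo_select()] columns).
#' @param panel LD reference `genotype_panel`.
#' @param condition_on Character vector of rsids to condition on.
#' @param var_y Phenotypic variance.
#' @return Tibble with `beta`, `se`, `p` replaced by their conditional
#'   values (conditioning variants excluded from the rows).
#' @export
cojo_condition <- function(meta, panel, condition_on, var_y = 1) {
  stats <- normalize_n(meta)
  if (length(condition_on) == 0L) {
    return(stats |> select("rsid", "chrom", "pos", "af", "beta", "se",
                           "p", "n"))
  }
  in_panel <- stats$rsid %in% panel$variants$variant_id
  skipped <- stats$rsid[!in_panel]
  stats <- stats[in_panel, , drop = FALSE]
  cond_set <- intersect(condition_on, stats$rsid)
  stop_if_not(length(cond_set) > 0,
              "no conditioning variant found in the statistics/panel")
  R <- ld_matrix(panel, stats$rsid)
  eng <- cojo_engine(stats, R, var_y)
  sel <- match(cond_set, stats$rsid)
  cand <- setdiff(seq_len(nrow(stats)), sel)
  if (length(cand) == 0L) {
    out <- stats[0, c("rsid", "chrom", "pos", "af", "beta", "se", "p", "n")]
    attr(out, "skipped") <- skipped
    return(out)
  }
  cond <- cojo_conditional(eng, sel, cand)
  out <- tibble(
    rsid = stats$rsid[cond$idx], chrom = stats$chrom[cond$idx],
    pos = stats$pos[cond$idx], af = stats$af[cond$idx],
    beta = cond$beta_cond, se = cond$se_cond, p = cond$p_cond,
    n = stats$n[cond$idx]) |>
    arrange(.data$chrom, .data$pos)
  attr(out, "skipped") <- skipped
  out
}

#' Merge adjacent peaks
#'
#' Automated surrogate for the manual review of regions where extended LD
#' splits one locus into several peaks: adjacent peaks are merged when
#' their index variants are within `merge_dist` of each other or in LD at
#' r-squared above `merge_r2`; the merged index is the lowest-P index.
#' Idempotent: merging a merged set changes nothing.
#'
#' @param peaks Peak tibble from [extract_peaks()].
#' @param panel LD source `genotype_panel`.
#' @param merge_r2 LD threshold on index variants.
#' @param merge_dist Distance threshold in base pairs.
#' @return A peak tibble with `peak_id` renumbered.
#' @export
merge_adjacent_peaks <- function(peaks, panel, merge_r2 = 0.1,
                                 merge_dist = 1e6) {
  if (nrow(peaks) < 2L) return(peaks)
  pk <- peaks |> arrange(.data$chrom, .data$start)
  # distance between index variants
  index_pos <- function(k) {
    m <- match(pk$index_rsid[k], panel$variants$variant_id)
    if (is.na(m)) pk$start[k] else panel$variants$pos[m]
  }
  repeat {
    merged <- FALSE
    if (nrow(pk) < 2L) break
    for (i in seq_len(nrow(pk) - 1L)) {
      j <- i + 1L
      if (pk$chrom[i] != pk$chrom[j]) next
      dist_ok <- abs(index_pos(i) - index_pos(j)) <= merge_dist
      r2 <- if (pk$index_rsid[i] %in% panel$variants$variant_id &&
                pk$index_rsid[j] %in% panel$variants$variant_id) {
        ld_r2(panel, pk$index_rsid[i], pk$index_rsid[j])
      } else NA_real_
      ld_ok <- !is.na(r2) && r2 > merge_r2
      if (dist_ok || ld_ok) {
        keep_i <- pk$index_p[i] <= pk$index_p[j]
        new_row <- pk[if (keep_i) i else j, ]
        new_row$start <- min(pk$start[i], pk$start[j])
        new_row$end <- max(pk$end[i], pk$end[j])
        new_row$n_members <- pk$n_members[i] + pk$n_members[j]
        new_row$members <- list(c(pk$members[[i]], pk$members[[j]]))
        pk <- bind_rows(pk[-c(i, j), ], new_row) |>
          arrange(.data$chrom, .data$start)
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  pk |> mutate(peak_id = row_number())
}
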