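#' Restore full alleles in summary statistics from the variant map
#'
#' Association output may carry alleles truncated to one character (the
#' GEMMA convention). Records are joined to the variant map by chromosome
#' and position; for biallelic sites the minor/major alleles are matched by
#' frequency, and for multiallelic sites the alternate allele whose map
#' frequency is closest to the summary-statistic MAF is assigned. Exact
#' frequency ties are ambiguous and the record is dropped, as are positions
#' absent from the map; dropped records are listed in the `dropped`
#' attribute.
#'
#' @param stats Association tibble (`chrom`, `pos`, `af`, `allele1`,
#'   `allele0`, ...).
#' @param vcf_variants Variant map tibble: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, and ALT frequency `af`; multiallelic sites appear as
#'   several rows sharing `chrom`/`pos`.
#' @return `stats` with `allele1`/`allele0`/`rsid` replaced by the matched
#'   map values.
#' @export
harmonize_alleles <- function(stats, vcf_variants) {
  key <- paste(vcf_variants$chrom, vcf_variants$pos)
  skey <- paste(stats$chrom, stats$pos)
  out <- vector("list", nrow(stats))
  dropped <- character()
  for (i in seq_len(nrow(stats))) {
    hits <- vcf_variants[key == skey[i], , drop = FALSE]
    if (nrow(hits) == 0L) {
      dropped <- c(dropped, paste0(skey[i], " (absent from map)"))
      next
    }
    rec <- stats[i, , drop = FALSE]
    stat_maf <- maf_of(rec$af)
    if (nrow(hits) == 1L) {
      # biallelic: orient by frequency; the stats effect-allele frequency
      # identifies whether the effect allele is the map ALT or REF
      if (abs(rec$af - hits$af) <= abs(rec$af - (1 - hits$af))) {
        rec$allele1 <- hits$alt
        rec$allele0 <- hits$ref
      } else {
        rec$allele1 <- hits$ref
        rec$allele0 <- hits$alt
      }
      rec$rsid <- hits$variant_id
      out[[i]] <- rec
    } else {
      dif <- abs(stat_maf - maf_of(hits$af))
      best <- which(dif == min(dif))
      if (length(best) > 1L) {
        dropped <- c(dropped, paste0(skey[i], " (frequency tie)"))
        next
      }
      rec$allele1 <- hits$alt[best]
      rec$allele0 <- hits$ref[best]
      rec$rsid <- hits$variant_id[best]
      out[[i]] <- rec
    }
  }
  res <- bind_rows(out)
  attr(res, "dropped") <- dropped
  res
}

#' Fixed-effect inverse-variance-weighted meta-analysis of two cohorts
#'
#' The METAL-style scheme: weights `w = 1/se^2`, combined
#' `beta = sum(w * beta) / sum(w)`, `se = 1/sqrt(sum(w))`, two-sided normal
#' P. Records are joined by chromosome, position and allele pair; a record
#' whose alleles are swapped between cohorts has its effect sign flipped
#' before combining, and records whose allele pairs cannot be reconciled
#' are dropped (listed in the `dropped` attribute). Variants present in a
#' single cohort pass through with `cohorts_present = 1`.
#'
#' @param stats_a,stats_b Harmonized association tibbles (see
#'   [harmonize_alleles()]); columns `chrom`, `pos`, `rsid`, `allele1`,
#'   `allele0`, `af`, `beta`, `se`, `p_wald`, `n`.
#' @return Meta tibble: `rsid`, `chrom`, `pos`, `allele1`, `allele0`, `af`
#'   (sample-size weighted), `beta`, `se`, `p`, `direction` (one character
#'   per cohort: `+`, `-` or `?`), `n_total`, `cohorts_present`.
#' @export
ivw_meta <- function(stats_a, stats_b) {
  a <- stats_a |> mutate(.key = paste(.data$chrom, .data$pos))
  b <- stats_b |> mutate(.key = paste(.data$chrom, .data$pos))
  all_keys <- union(a$.key, b$.key)
  ia <- match(all_keys, a$.key)
  ib <- match(all_keys, b$.key)
  rows <- vector("list", length(all_keys))
  dropped <- character()
  for (k in seq_along(all_keys)) {
    ra <- if (!is.na(ia[k])) a[ia[k], ] else NULL
    rb <- if (!is.na(ib[k])) b[ib[k], ] else NULL
    if (!is.null(ra) && !is.null(rb)) {
      if (ra$allele1 == rb$allele1 && ra$allele0 == rb$allele0) {
        flip <- 1
      } else if (ra$allele1 == rb$allele0 && ra$allele0 == rb$allele1) {
        flip <- -1
      } else {
        dropped <- c(dropped, all_keys[k])
        next
      }
      b2 <- flip * rb$beta
      af2 <- if (flip == 1) rb$af else 1 - rb$af
      w <- c(1 / ra$se^2, 1 / rb$se^2)
      beta <- sum(w * c(ra$beta, b2)) / sum(w)
      se <- 1 / sqrt(sum(w))
      rows[[k]] <- tibble(
        rsid = ra$rsid, chrom = ra$chrom, pos = ra$pos,
        allele1 = ra$allele1, allele0 = ra$allele0,
        af = (ra$n * ra$af + rb$n * af2) / (ra$n + rb$n),
        beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
        direction = paste0(dirchar(ra$beta), dirchar(b2)),
        n_total = ra$n + rb$n, cohorts_present = 2L)
    } else {
      r <- if (is.null(ra)) rb else ra
      rows[[k]] <- tibble(
        rsid = r$rsid, chrom = r$chrom, pos = r$pos,
        allele1 = r$allele1, allele0 = r$allele0, af = r$af,
        beta = r$beta, se = r$se, p = 2 * pnorm(-abs(r$beta / r$se)),
        direction = if (is.null(rb)) paste0(dirchar(r$beta), "?")
                    else paste0("?", dirchar(r$beta)),
        n_total = r$n, cohorts_present = 1L)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    res <- tibble(rsid = character(), chrom = character(), pos = double(),
                  allele1 = character(), allele0 = character(),
                  af = double(), beta = double(), se = double(),
                  p = double(), direction = character(),
                  n_total = double(), cohorts_present = integer())
  } else {
    res <- bind_rows(rows) |> arrange(.data$chrom, .data$pos)
  }
  attr(res, "dropped") <- dropped
  res
}

dirchar <- function(beta) ifelse(beta >= 0, "+", "-")

#' Sex-heterogeneity test between male and female meta-analysis results
#'
#' Cochran's-Q-type contrast per variant:
#' `Q = (beta_m - beta_f)^2 / (se_m^2 + se_f^2)` referred to chi-squared
#' with 1 df. Significance is declared at a Bonferroni-corrected level
#' `alpha / n_tests`.
#'
#' @param meta_male,meta_female Meta tibbles from [ivw_meta()] (matched by
#'   `rsid`).
#' @param alpha Familywise rate for the Bonferroni threshold.
#' @param n_tests Number of pQTLs tested; defaults to the number of shared
#'   variants.
#' @return Tibble: `rsid`, `beta_male`, `beta_female`, `q`, `p_het`,
#'   `threshold`, `significant`.
#' @export
sex_het_test <- function(meta_male, meta_female, alpha = 0.05,
                         n_tests = NULL) {
  shared <- intersect(meta_male$rsid, meta_female$rsid)
  if (is.null(n_tests)) n_tests <- length(shared)
  m <- meta_male[match(shared, meta_male$rsid), ]
  f <- meta_female[match(shared, meta_female$rsid), ]
  flip <- ifelse(m$allele1 == f$allele1, 1, -1)
  q <- (m$beta - flip * f$beta)^2 / (m$se^2 + f$se^2)
  thr <- alpha / max(1L, n_tests)
  tibble(
    rsid = shared, beta_male = m$beta, beta_female = flip * f$beta,
    q = q, p_het = pchisq(q, df = 1, lower.tail = FALSE),
    threshold = thr,
    significant = pchisq(q, df = 1, lower.tail = FALSE) < thr)
}
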