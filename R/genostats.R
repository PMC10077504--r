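#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: conditioning on the observed allele counts, the
#' P-value is the total probability of heterozygote configurations as or
#' less probable than the observed one. Monomorphic input returns 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Two-sided exact P-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stop_if_not(n_hom_ref >= 0 && n_het >= 0 && n_hom_alt >= 0,
              "counts must be non-negative")
  n <- n_hom_ref + n_het + n_hom_alt
  stop_if_not(n >= 1, "need at least one genotype")
  n_a <- 2 * min(n_hom_ref, n_hom_alt) + n_het  # minor allele count
  if (n_a == 0) return(1.0)
  # heterozygote counts share the parity of the minor allele count
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  # log P(n_het = h | n, n_a) up to a common constant
  logp <- vapply(hets, function(h) {
    hom_minor <- (n_a - h) / 2
    hom_major <- n - h - hom_minor
    h * log(2) - lgamma(hom_minor + 1) - lgamma(hom_major + 1) - lgamma(h + 1)
  }, numeric(1))
  pr <- exp(logp - logsumexp(logp))
  p_obs <- pr[hets == n_het]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# vectorized over hard-call dosage columns; returns NA for non-integer input
hwe_from_dosage <- function(g) {
  g <- g[!is.na(g)]
  n0 <- sum(g == 0); n1 <- sum(g == 1); n2 <- sum(g == 2)
  if (n0 + n1 + n2 == 0) return(NA_real_)
  hwe_exact_test(n0, n1, n2)
}

#' Variant-level quality control
#'
#' Removes variants with missingness above `max_missing`, minor allele count
#' below `min_mac`, or an exact Hardy-Weinberg P-value below `hwe_alpha`;
#' the QC record of every variant is kept for reporting.
#'
#' @param panel A `genotype_panel` with dosages in \{0, 1, 2, NA\}.
#' @param max_missing Maximum tolerated per-variant missingness (rule is
#'   strictly greater-than).
#' @param min_mac Minimum minor allele count (rule is `mac < min_mac`).
#' @param hwe_alpha HWE exact-test significance cutoff.
#' @return A list: `panel` (kept variants), `qc` (per-variant tibble with
#'   `maf`, `mac`, `missingness`, `hwe_p`, `pass`, `fail`).
#' @export
variant_qc <- function(panel, max_missing = 0.01, min_mac = 10,
                       hwe_alpha = 1e-5) {
  G <- panel$dosage
  n <- nrow(G)
  n_obs <- colSums(!is.na(G))
  missingness <- (n - n_obs) / n
  alt <- colSums(G, na.rm = TRUE)
  mac <- pmin(alt, 2 * n_obs - alt)
  maf <- ifelse(n_obs > 0, mac / (2 * n_obs), NA_real_)
  hwe_p <- apply(G, 2, hwe_from_dosage)

  fail <- rep("", ncol(G))
  fail[missingness > max_missing] <- "missingness"
  fail[mac < min_mac] <- paste0(fail[mac < min_mac], ";mac")
  fail[!is.na(hwe_p) & hwe_p < hwe_alpha] <-
    paste0(fail[!is.na(hwe_p) & hwe_p < hwe_alpha], ";hwe")
  fail <- sub("^;", "", fail)
  pass <- fail == ""

  qc <- tibble(
    variant_id = panel$variants$variant_id,
    maf = maf, mac = mac, missingness = missingness, hwe_p = hwe_p,
    pass = pass, fail = fail)
  list(panel = subset_panel(panel, variants = which(pass)), qc = qc)
}

#' Subset a genotype panel by variants and/or samples
#'
#' @param panel A `genotype_panel`.
#' @param variants,samples Indices, logical masks, or id/name vectors; `NULL`
#'   keeps everything.
#' @return The subset `genotype_panel`.
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  vi <- seq_len(nrow(panel$variants))
  si <- seq_along(panel$samples)
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) {
      match(variants, panel$variants$variant_id)
    } else if (is.logical(variants)) which(variants) else variants
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) {
      match(samples, panel$samples)
    } else if (is.logical(samples)) which(samples) else samples
  }
  new_genotype_panel(panel$dosage[si, vi, drop = FALSE],
                     panel$variants[vi, , drop = FALSE],
                     panel$samples[si])
}

#' Squared LD between two variants
#'
#' Squared Pearson correlation of dosages over pairwise-complete samples;
#' sign-invariant by construction. `NA` when fewer than two complete pairs
#' or a variant is monomorphic on the shared samples.
#'
#' @param panel A `genotype_panel`.
#' @param i,j Variant ids or column indices.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(panel, i, j) {
  if (is.character(i)) i <- match(i, panel$variants$variant_id)
  if (is.character(j)) j <- match(j, panel$variants$variant_id)
  r2_pair(panel$dosage[, i], panel$dosage[, j])
}

# correlation matrix of mean-imputed dosages for the given variant ids
ld_matrix <- function(panel, ids = NULL) {
  G <- impute_dosage(panel$dosage * 1.0)
  if (!is.null(ids)) {
    idx <- if (is.character(ids)) match(ids, panel$variants$variant_id) else ids
    G <- G[, idx, drop = FALSE]
  }
  sds <- apply(G, 2, sd)
  R <- suppressWarnings(cor(G))
  R[is.na(R)] <- 0
  diag(R) <- 1
  R
}

# variance inflation factors from a correlation matrix (diag of inverse);
# a tiny ridge keeps exact collinearity finite but enormous
vif_from_corr <- function(R) {
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(diag(inv))) || any(diag(inv) < 0)) {
    inv <- solve(R + diag(1e-10, nrow(R)))
  }
  diag(inv)
}

#' Sliding-window variance-inflation-factor LD pruning
#'
#' Within each window of `window` variants advanced by `step`, variants are
#' removed greedily - highest VIF first, ties broken by lower MAF then by
#' earlier position - until every remaining variant's VIF (from regression
#' on the other remaining variants in the window) is at most `vif`. Output
#' is invariant to input variant order: variants are processed sorted by
#' chromosome and position.
#'
#' @param panel A QC'd `genotype_panel`.
#' @param window Window size in variants.
#' @param step Window shift in variants.
#' @param vif VIF bound (2 corresponds to R-squared 0.5 on the others).
#' @return Character vector of kept variant ids, in map order.
#' @export
ld_prune <- function(panel, window = 50, step = 5, vif = 2.0) {
  v <- panel$variants
  ord <- order(v$chrom, v$pos)
  G <- impute_dosage(panel$dosage * 1.0)[, ord, drop = FALSE]
  v <- v[ord, , drop = FALSE]
  p_hat <- colMeans(G) / 2
  mafs <- maf_of(p_hat)
  keep <- mafs > 0  # monomorphic variants carry no information

  for (chr in unique(v$chrom)) {
    idx_chr <- which(v$chrom == chr)
    m <- length(idx_chr)
    starts <- unique(c(seq(1L, max(1L, m - 1L), by = step)))
    for (s in starts) {
      win <- idx_chr[s:min(s + window - 1L, m)]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      repeat {
        R <- suppressWarnings(cor(G[, win, drop = FALSE]))
        R[is.na(R)] <- 0; diag(R) <- 1
        vifs <- vif_from_corr(R)
        if (max(vifs) <= vif) break
        worst <- which(vifs == max(vifs))
        if (length(worst) > 1L) {
          worst <- worst[order(mafs[win[worst]], win[worst])][1L]
        }
        keep[win[worst]] <- FALSE
        win <- win[-worst]
        if (length(win) < 2L) break
      }
    }
  }
  v$variant_id[keep]
}

#' Empirical genomic relatedness matrix
#'
#' Standardized GRM: the average over variants of outer products of
#' `(dosage - 2p) / sqrt(2p(1-p))`, with missing dosages mean-imputed per
#' variant. Variants are filtered to MAF above `min_maf` and HWE exact-test
#' pass; callers wanting the conventional construction should LD-prune the
#' panel first (see [ld_prune()]).
#'
#' @param panel A `genotype_panel`.
#' @param min_maf Minimum MAF (strict) for inclusion.
#' @param hwe_alpha HWE exact-test cutoff.
#' @return A symmetric samples-by-samples matrix with `mean(diag)` close
#'   to 1.
#' @export
compute_grm <- function(panel, min_maf = 0.01, hwe_alpha = 1e-5) {
  G <- impute_dosage(panel$dosage * 1.0)
  p_hat <- colMeans(G) / 2
  hwe_p <- apply(panel$dosage, 2, hwe_from_dosage)
  use <- maf_of(p_hat) > min_maf & !is.na(hwe_p) & hwe_p >= hwe_alpha
  stop_if_not(sum(use) > 0, "no usable variants for the GRM")
  Z <- sweep(G[, use, drop = FALSE], 2, 2 * p_hat[use])
  Z <- sweep(Z, 2, sqrt(2 * p_hat[use] * (1 - p_hat[use])), "/")
  K <- tcrossprod(Z) / sum(use)
  dimnames(K) <- list(panel$samples, panel$samples)
  attr(K, "m_variants") <- sum(use)
  K
}

#' Genomic-control inflation factor
#'
#' Median of the chi-squared(1 df) quantiles of the P-values divided by the
#' chi-squared(1) median (computed, not hard-coded).
#'
#' @param pvalues P-values in (0, 1].
#' @return The inflation factor lambda-GC.
#' @export
lambda_gc <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  stop_if_not(length(pvalues) > 0, "no P-values supplied")
  stop_if_not(all(pvalues > 0 & pvalues <= 1), "P-values must be in (0, 1]")
  chisq <- qchisq(pvalues, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Study-wide significance threshold from effective test counts
#'
#' The familywise threshold is `alpha / (n_eff * m_eff)`: `n_eff` effective
#' variants (e.g. the LD-pruned count from [ld_prune()]) times `m_eff`
#' effective phenotypes. `m_eff` is the ratio of the sum of the eigenvalues
#' of the phenotype correlation matrix to its largest eigenvalue; it is
#' reported (and used in the division) rounded to the nearest integer, with
#' the unrounded value kept alongside.
#'
#' @param n_eff Effective number of variants.
#' @param pheno_corr Phenotype correlation matrix (symmetric, unit
#'   diagonal). Ignored when `m_eff` is given directly.
#' @param alpha Familywise error rate.
#' @param m_eff Optional: effective number of phenotypes, already computed.
#' @return A list of class `significance_plan`: `n_eff`, `m_eff`
#'   (unrounded), `m_eff_reported`, `alpha`, `threshold`.
#' @export
significance_threshold <- function(n_eff, pheno_corr = NULL, alpha = 0.05,
                                   m_eff = NULL) {
  stop_if_not(n_eff >= 1, "n_eff must be positive")
  if (is.null(m_eff)) {
    stop_if_not(is.matrix(pheno_corr) &&
                  nrow(pheno_corr) == ncol(pheno_corr),
                "pheno_corr must be a square matrix")
    stop_if_not(max(abs(diag(pheno_corr) - 1)) < 1e-8,
                "pheno_corr must have unit diagonal")
    ev <- eigen((pheno_corr + t(pheno_corr)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    m_eff <- sum(ev) / max(ev)
  }
  m_rep <- as.integer(round(m_eff))
  structure(list(
    n_eff = n_eff, m_eff = m_eff, m_eff_reported = m_rep, alpha = alpha,
    threshold = alpha / (n_eff * m_rep)
  ), class = "significance_plan")
}

#' @export
print.significance_plan <- function(x, ...) {
  cat("<significance_plan> n_eff = ", format(x$n_eff), ", m_eff = ",
      x$m_eff_reported, ", alpha = ", x$alpha, "\n  threshold = ",
      format(x$threshold, digits = 3), "\n", sep = "")
  invisible(x)
}
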