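#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with standard error `se` and a normal prior with
#' standard deviation `W` on the true effect, the log approximate Bayes
#' factor of association versus null is
#' `0.5 * log(1 - r) + 0.5 * z^2 * r` with `r = W^2 / (W^2 + se^2)` and
#' `z = beta / se`. Vectorized over variants.
#'
#' @param beta,se Effect estimates and standard errors (`se > 0`).
#' @param W Prior standard deviation of the true effect.
#' @return Log ABF per variant.
#' @export
wakefield_abf <- function(beta, se, W = 1) {
  stop_if_not(all(is.finite(beta)) && all(is.finite(se)) && all(se > 0),
              "beta and se must be finite with se > 0")
  stop_if_not(W >= 0, "W must be non-negative")
  r <- W^2 / (W^2 + se^2)
  z <- beta / se
  0.5 * log(1 - r) + 0.5 * z^2 * r
}

#' Colocalization posteriors for two traits over one region
#'
#' Standard five-hypothesis enumeration over a shared variant set: H0 no
#' association; H1/H2 one causal variant for trait 1/2 only; H3 two
#' distinct causal variants; H4 one shared causal variant. Per-variant
#' Wakefield ABFs for each trait are combined with per-variant priors
#' `p1`, `p2` (single-trait causal) and `p12` (shared causal) by
#' log-sum-exp. With a single variant H3 is impossible and its posterior
#' is exactly zero.
#'
#' @param region Tibble with one row per variant: `beta1`, `se1`, `beta2`,
#'   `se2` (aligned alleles across traits).
#' @param p1,p2,p12 Prior probabilities that a variant is causal for trait
#'   1, trait 2, or both.
#' @param W1,W2 Prior effect-size standard deviations per trait (1 on the
#'   INT-standardized scale).
#' @param posterior_threshold Posterior for declaring colocalization.
#' @return One-row tibble: `pp0`..`pp4`, `n_variants`, `colocalized`.
#' @export
coloc_posteriors <- function(region, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             W1 = 1, W2 = 1, posterior_threshold = 0.8) {
  stop_if_not(nrow(region) >= 1, "empty variant set")
  stop_if_not(p1 > 0 && p1 < 1 && p2 > 0 && p2 < 1 && p12 > 0 && p12 < 1,
              "priors must be in (0, 1)")
  stop_if_not(p12 <= min(p1, p2), "p12 must not exceed p1 or p2")
  l1 <- wakefield_abf(region$beta1, region$se1, W1)
  l2 <- wakefield_abf(region$beta2, region$se2, W2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  # sum over ordered pairs (j, k), j != k
  s_distinct <- logdiffexp(s1 + s2, s12)

  h <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    h3 = log(p1) + log(p2) + s_distinct,
    h4 = log(p12) + s12)
  pp <- exp(h - logsumexp(h))
  tibble(
    pp0 = pp[["h0"]], pp1 = pp[["h1"]], pp2 = pp[["h2"]],
    pp3 = pp[["h3"]], pp4 = pp[["h4"]],
    n_variants = nrow(region),
    colocalized = pp[["h4"]] > posterior_threshold)
}

#' Colocalize a pQTL signal with an outcome trait over a region
#'
#' Convenience wrapper joining pQTL and outcome summary statistics by rsid
#' and running [coloc_posteriors()]; when a peak carries several
#' conditionally independent variants, pass statistics conditioned on the
#' other independent variants (see [cojo_condition()]).
#'
#' @param pqtl_stats Tibble `rsid`, `beta`, `se` for the protein trait.
#' @param outcome_stats Tibble `rsid`, `beta`, `se` for the outcome trait.
#' @param ... Passed to [coloc_posteriors()].
#' @return One-row tibble as [coloc_posteriors()], with `n_variants` the
#'   shared variant count.
#' @export
coloc_region <- function(pqtl_stats, outcome_stats, ...) {
  shared <- inner_join(
    pqtl_stats |> select("rsid", beta1 = "beta", se1 = "se"),
    outcome_stats |> select("rsid", beta2 = "beta", se2 = "se"),
    by = "rsid")
  stop_if_not(nrow(shared) >= 1, "no shared variants between the traits")
  coloc_posteriors(shared, ...)
}
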