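#' Fit the null linear mixed model by REML
#'
#' Model: `y = mu + u + e` with `u ~ N(0, lambda * sigma2 * K)` and
#' `e ~ N(0, sigma2 * I)`. `K` is eigendecomposed once; the restricted
#' likelihood is profiled over `mu` and `sigma2` and maximized over
#' `log(lambda)` on `[-10, 10]` by Brent search.
#'
#' @param y Adjusted phenotype vector, complete on its samples.
#' @param K GRM restricted to the same samples, in the same order.
#' @param eig Optional precomputed `eigen(K, symmetric = TRUE)` result, to
#'   amortize the decomposition across proteins sharing a sample set.
#' @return An `lmm_fit`: `lambda` (genetic-to-residual variance ratio),
#'   `h2 = lambda / (1 + lambda)`, `sigma2`, `log_reml`, and the cached
#'   eigendecomposition used by [lmm_assoc()].
#' @export
fit_null_lmm <- function(y, K, eig = NULL) {
  n <- length(y)
  stop_if_not(n >= 30, "refusing to fit a mixed model on fewer than 30 samples")
  stop_if_not(!anyNA(y), "y must be complete; subset before fitting")
  if (is.null(eig)) {
    stop_if_not(is.matrix(K) && nrow(K) == n && ncol(K) == n,
                "K must be an n x n matrix matching y")
    eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  }
  stop_if_not(min(eig$values) > -1e-6, "K is not positive semi-definite")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  xs <- drop(crossprod(U, rep(1, n)))

  reml <- function(log_lambda) {
    w <- exp(log_lambda) * d + 1
    sxx <- sum(xs^2 / w)
    sxy <- sum(xs * ys / w)
    syy <- sum(ys^2 / w)
    rss <- syy - sxy^2 / sxx
    s2 <- rss / (n - 1)
    -0.5 * (sum(log(w)) + log(sxx) + (n - 1) * log(s2))
  }
  opt <- optimize(reml, c(-10, 10), maximum = TRUE, tol = 1e-6)
  lambda <- exp(opt$maximum)
  w <- lambda * d + 1
  sxx <- sum(xs^2 / w); sxy <- sum(xs * ys / w); syy <- sum(ys^2 / w)
  sigma2 <- (syy - sxy^2 / sxx) / (n - 1)
  structure(list(
    lambda = lambda, h2 = lambda / (1 + lambda), sigma2 = sigma2,
    log_reml = opt$objective, n = n, U = U, d = d
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> n = ", x$n, ", lambda = ", format(x$lambda, digits = 4),
      " (h2 = ", format(x$h2, digits = 3), "), sigma2 = ",
      format(x$sigma2, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Mixed-model single-variant association scan
#'
#' Wald test of the dosage effect per variant, with the variance ratio
#' `lambda` fixed at its null-model REML estimate: the model is rotated
#' into the GRM eigenbasis, whitened, and each variant tested by weighted
#' least squares. Two-sided P-values come from the t distribution with
#' `n - 2` degrees of freedom. Missing dosages are mean-imputed; variants
#' monomorphic on the analysis samples are skipped (ids in the
#' `skipped` attribute).
#'
#' With `lambda = 0` (or an identity GRM) the statistics reduce exactly to
#' ordinary least squares.
#'
#' @param y Adjusted phenotype, aligned with the panel's samples.
#' @param panel A QC'd `genotype_panel`.
#' @param fit The [fit_null_lmm()] result for `y`.
#' @return A tibble with columns `chrom`, `pos`, `rsid`, `allele1` (effect
#'   = ALT), `allele0`, `af`, `beta`, `se`, `p_wald`, `n`, `mac`.
#' @export
lmm_assoc <- function(y, panel, fit) {
  n <- length(y)
  stop_if_not(n == length(panel$samples),
              "y and panel must cover the same samples")
  stop_if_not(inherits(fit, "lmm_fit") && fit$n == n,
              "fit must be an lmm_fit on the same samples")
  G <- panel$dosage * 1.0
  n_obs <- colSums(!is.na(G))
  af <- colSums(G, na.rm = TRUE) / (2 * n_obs)
  mac <- pmin(colSums(G, na.rm = TRUE), 2 * n_obs - colSums(G, na.rm = TRUE))
  G <- impute_dosage(G)
  poly <- af > 0 & af < 1

  sw <- sqrt(fit$lambda * fit$d + 1)
  yt <- drop(crossprod(fit$U, y)) / sw
  xt <- drop(crossprod(fit$U, rep(1, n))) / sw
  Gt <- crossprod(fit$U, G) / sw

  # residualize on the (whitened) intercept
  xx <- sum(xt^2)
  yr <- yt - xt * (sum(xt * yt) / xx)
  Gr <- Gt - outer(xt, drop(crossprod(Gt, xt)) / xx)
  sgg <- colSums(Gr^2)
  sgy <- drop(crossprod(Gr, yr))
  syy <- sum(yr^2)
  beta <- ifelse(poly & sgg > 0, sgy / sgg, NA_real_)
  rss <- syy - beta^2 * sgg
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sgg))
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df = n - 2)

  out <- tibble(
    chrom = panel$variants$chrom, pos = panel$variants$pos,
    rsid = panel$variants$variant_id,
    allele1 = panel$variants$alt, allele0 = panel$variants$ref,
    af = af, beta = beta, se = se, p_wald = p, n = n, mac = mac)
  skipped <- out$rsid[!poly | !is.finite(out$se)]
  out <- out[poly & is.finite(out$se), , drop = FALSE]
  attr(out, "skipped") <- skipped
  out
}

# Wald test of g with extra covariates, in the whitened model; used for
# conditioning association on known variants
wald_conditional <- function(y, g, covars, fit) {
  n <- length(y)
  sw <- sqrt(fit$lambda * fit$d + 1)
  X <- cbind(intercept = 1, covars)
  yt <- drop(crossprod(fit$U, y)) / sw
  Xt <- crossprod(fit$U, X) / sw
  gt <- drop(crossprod(fit$U, g)) / sw
  q <- qr(Xt)
  yr <- qr.resid(q, yt)
  gr <- qr.resid(q, gt)
  sgg <- sum(gr^2)
  if (sgg < 1e-12) {
    return(list(beta = 0, se = NA_real_, p = 1))
  }
  beta <- sum(gr * yr) / sgg
  df <- n - q$rank - 1
  rss <- sum(yr^2) - beta^2 * sgg
  se <- sqrt(max(rss, 0) / (df * sgg))
  list(beta = beta, se = se, p = 2 * pt(-abs(beta / se), df = df))
}

#' Sex-stratified association
#'
#' Runs two independent mixed-model scans on the sex-restricted samples,
#' re-using the GRM sub-matrix for each stratum. A stratum with fewer than
#' 30 samples is skipped (`NULL` entry) with a warning.
#'
#' @param y Adjusted phenotype aligned with the panel's samples.
#' @param panel A `genotype_panel`.
#' @param K GRM over the panel samples.
#' @param sex 0/1 vector (1 = male by convention).
#' @return A list with elements `male` and `female`, each an association
#'   tibble as from [lmm_assoc()] or `NULL`.
#' @export
sex_stratified_assoc <- function(y, panel, K, sex) {
  stop_if_not(length(sex) == length(y), "sex must align with y")
  run_stratum <- function(mask, label) {
    if (sum(mask) < 30) {
      warn(paste0("stratum '", label, "' has fewer than 30 samples; skipped"))
      return(NULL)
    }
    sub <- subset_panel(panel, samples = which(mask))
    fit <- fit_null_lmm(y[mask], K[mask, mask, drop = FALSE])
    lmm_assoc(y[mask], sub, fit)
  }
  list(male = run_stratum(sex == 1, "male"),
       female = run_stratum(sex == 0, "female"))
}

#' Exclude proteins with inflated or deflated association statistics
#'
#' Post-association filter: proteins whose genomic-control lambda falls
#' outside the given band in any cohort are flagged for exclusion from
#' downstream stages.
#'
#' @param assoc_by_protein Named list (protein -> association tibble, or a
#'   list of such lists for several cohorts).
#' @param band Acceptable lambda-GC interval.
#' @return Tibble: `protein`, `lambda_gc`, `keep`.
#' @export
lambda_gc_filter <- function(assoc_by_protein, band = c(0.97, 1.05)) {
  rows <- lapply(names(assoc_by_protein), function(pp) {
    lam <- lambda_gc(assoc_by_protein[[pp]]$p_wald)
    tibble(protein = pp, lambda_gc = lam,
           keep = lam >= band[1] & lam <= band[2])
  })
  bind_rows(rows)
}
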