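#' Censor NPX values below the limit of detection
#'
#' Values strictly below a protein's LOD are unreliable and are set to
#' missing; a value exactly at the LOD is retained. Censoring counts per
#' protein are attached as the `censoring` attribute.
#'
#' @param matrix A `protein_matrix` (see [simulate_cohorts()]), with a LOD
#'   defined for every protein column.
#' @return The censored `protein_matrix`.
#' @export
censor_below_lod <- function(matrix) {
  stop_if_not(inherits(matrix, "protein_matrix"),
              "matrix must be a protein_matrix")
  prot <- colnames(matrix$npx)
  missing_lod <- setdiff(prot, names(matrix$lod))
  if (length(missing_lod) > 0) {
    abort(paste0("no LOD for protein(s): ",
                 paste(missing_lod, collapse = ", ")))
  }
  npx <- matrix$npx
  counts <- integer(length(prot))
  for (j in seq_along(prot)) {
    below <- !is.na(npx[, j]) & npx[, j] < matrix$lod[[prot[j]]]
    counts[j] <- sum(below)
    npx[below, j] <- NA_real_
  }
  out <- new_protein_matrix(npx, matrix$lod, matrix$covariates)
  attr(out, "censoring") <- tibble(protein = prot, n_censored = counts,
                                   prop_censored = counts / nrow(npx))
  out
}

#' Filter proteins by missingness and drop samples with missing covariates
#'
#' Proteins whose combined missing / below-LOD proportion exceeds
#' `max_missing` are removed (the threshold itself is retained: the rule is
#' "greater than"). Samples with any missing covariate among age, sex,
#' plate, season are dropped. The per-sample mean NPX across all assays is
#' computed here, before any protein is excluded, and stored in the
#' covariate sheet for the adjustment step.
#'
#' @param matrix A censored `protein_matrix`.
#' @param max_missing Maximum tolerated missingness proportion per protein.
#' @return A list: `matrix` (filtered `protein_matrix`), `excluded_proteins`
#'   (tibble with the offending proportions), `excluded_samples`.
#' @export
filter_proteins <- function(matrix, max_missing = 0.40) {
  stop_if_not(inherits(matrix, "protein_matrix"),
              "matrix must be a protein_matrix")
  npx <- matrix$npx
  cov <- matrix$covariates

  # per-sample mean NPX across *all* assays, pre-exclusion
  sample_mean_npx <- rowMeans(npx, na.rm = TRUE)

  cov_needed <- intersect(c("age", "sex", "plate", "season"), names(cov))
  ok_sample <- complete.cases(cov[, cov_needed, drop = FALSE]) &
    is.finite(sample_mean_npx)
  excluded_samples <- cov$sample_id[!ok_sample]

  npx <- npx[ok_sample, , drop = FALSE]
  cov <- cov[ok_sample, , drop = FALSE]
  cov$sample_mean_npx <- sample_mean_npx[ok_sample]

  miss <- colMeans(is.na(npx))
  drop <- miss > max_missing
  excluded <- tibble(protein = colnames(npx)[drop],
                     prop_missing = unname(miss[drop]))
  npx <- npx[, !drop, drop = FALSE]

  list(
    matrix = new_protein_matrix(npx, matrix$lod[colnames(npx)], cov),
    excluded_proteins = excluded,
    excluded_samples = excluded_samples
  )
}

#' Covariate adjustment and inverse-normal transformation
#'
#' Per protein, fits an ordinary least-squares regression of NPX on
#' intercept, age, age squared, sex, plate indicators (first plate as
#' reference), season and the per-sample mean NPX, on that protein's
#' non-missing samples, then maps the residual ranks to standard normal
#' quantiles (offset `(rank - 0.5)/n`, ties averaged). Aliased design
#' columns (e.g. a plate perfectly confounded with season) are dropped with
#' a warning rather than failing.
#'
#' @param matrix A filtered `protein_matrix`. If `sample_mean_npx` is not
#'   already in the covariate sheet (see [filter_proteins()]) it is computed
#'   from the current matrix.
#' @return An `adjusted_phenotypes` object: `residuals` (samples x proteins,
#'   standard-normal scale), `n` per protein, `samples`, `dropped_terms`.
#' @export
adjust_and_int <- function(matrix) {
  stop_if_not(inherits(matrix, "protein_matrix"),
              "matrix must be a protein_matrix")
  npx <- matrix$npx
  cov <- matrix$covariates
  if (!"sample_mean_npx" %in% names(cov)) {
    cov$sample_mean_npx <- rowMeans(npx, na.rm = TRUE)
  }
  X <- build_design(cov)

  res <- matrix(NA_real_, nrow(npx), ncol(npx), dimnames = dimnames(npx))
  dropped <- character()
  for (j in seq_len(ncol(npx))) {
    y <- npx[, j]
    ok <- !is.na(y)
    fit <- lm.fit(X[ok, , drop = FALSE], y[ok])
    alias <- colnames(X)[is.na(fit$coefficients)]
    dropped <- union(dropped, alias)
    res[ok, j] <- int_transform(fit$residuals)
  }
  if (length(dropped) > 0) {
    warn(paste0("dropped aliased design column(s): ",
                paste(dropped, collapse = ", ")))
  }
  structure(list(
    residuals = res,
    n = colSums(!is.na(res)),
    samples = cov$sample_id,
    dropped_terms = dropped
  ), class = "adjusted_phenotypes")
}

# design matrix for the NPX adjustment; plate as dummy indicators
build_design <- function(cov) {
  df <- data.frame(
    age = cov$age, age2 = cov$age^2, sex = cov$sex,
    plate = factor(cov$plate), season = cov$season,
    sample_mean_npx = cov$sample_mean_npx
  )
  model.matrix(~ age + age2 + sex + plate + season + sample_mean_npx,
               data = df)
}

#' @export
print.adjusted_phenotypes <- function(x, ...) {
  cat("<adjusted_phenotypes> ", nrow(x$residuals), " samples x ",
      ncol(x$residuals), " proteins (INT residuals)\n", sep = "")
  invisible(x)
}
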