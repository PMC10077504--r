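# Internal numerical helpers.

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# rank-based inverse normal transform, (rank - 0.5)/n offset, average ties;
# NAs are preserved and excluded from the rank denominator
int_transform <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0L) return(out)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / n)
  out
}

# minor allele frequency from an ALT allele frequency
maf_of <- function(af) pmin(af, 1 - af)

# squared Pearson correlation on pairwise-complete observations,
# NA when fewer than 2 complete pairs or either vector is constant
r2_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

# mean-impute missing entries of a dosage matrix, column-wise
impute_dosage <- function(G) {
  if (!anyNA(G)) return(G)
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  G[idx] <- mu[idx[, 2L]]
  G
}

stop_if_not <- function(cond, msg) {
  if (!cond) abort(msg)
  invisible(TRUE)
}
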