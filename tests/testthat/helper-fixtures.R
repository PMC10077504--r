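# Shared fixtures and independent oracles used across test files.

# small two-cohort simulation reused by several tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohorts(sim_config(
        n_samples_per_cohort = 250, n_variants = 600, n_proteins = 6,
        ld_rho = 0.6, ld_block_size = 10, n_cis_effects = 3,
        n_trans_effects = 1, effect_sizes = c(1.2, -1.0, 0.9, 1.1),
        seed = 101))
    }
    cache
  }
})

# construct a genotype panel directly from a dosage matrix
make_panel <- function(G, chrom = NULL, pos = NULL) {
  m <- ncol(G)
  variants <- tibble::tibble(
    variant_id = paste0("v", seq_len(m)),
    chrom = chrom %||% rep("1", m),
    pos = pos %||% (1e6 + (seq_len(m) - 1) * 5000),
    ref = "A", alt = "G")
  isopqtl:::new_genotype_panel(G, variants, paste0("s", seq_len(nrow(G))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# construct a protein matrix with given NPX values and LOD
make_protein_matrix <- function(npx, lod = NULL, covariates = NULL) {
  n <- nrow(npx)
  if (is.null(colnames(npx))) colnames(npx) <- paste0("P", seq_len(ncol(npx)))
  if (is.null(rownames(npx))) rownames(npx) <- paste0("s", seq_len(n))
  if (is.null(lod)) lod <- setNames(rep(-Inf, ncol(npx)), colnames(npx))
  if (is.null(covariates)) {
    covariates <- tibble::tibble(
      sample_id = rownames(npx),
      age = round(seq(30, 70, length.out = n)),
      sex = as.integer(seq_len(n) %% 3 == 0),
      plate = rep_len(1:4, n),
      season = c(rep(0, floor(n / 2)), rep(1, n - floor(n / 2))))
  }
  isopqtl:::new_protein_matrix(npx, lod, covariates)
}

# independent HWE oracle: enumerate heterozygote configurations from first
# principles with choose()-based conditional probabilities
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * min(n0, n2) + n1
  if (na == 0) return(1)
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  probs <- sapply(hets, function(h) {
    homm <- (na - h) / 2
    homM <- n - h - homm
    exp(lfactorial(n) - lfactorial(homm) - lfactorial(homM) -
          lfactorial(h) + h * log(2) +
          lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n))
  })
  probs <- probs / sum(probs)
  obs <- probs[hets == n1]
  sum(probs[probs <= obs + 1e-12])
}

# brute-force reference for peak extraction (independent O(n^2) rewrite)
peaks_oracle <- function(stats, R2, p_extract, r2_drop, group_dist) {
  cand <- which(stats$p < p_extract)
  cand <- cand[order(stats$p[cand])]
  survivors <- integer()
  removed <- logical(nrow(stats))
  for (i in cand) {
    if (removed[i]) next
    survivors <- c(survivors, i)
    for (j in cand) {
      if (j != i && !removed[j] && stats$chrom[j] == stats$chrom[i] &&
          !is.na(R2[i, j]) && R2[i, j] > r2_drop) {
        removed[j] <- TRUE
      }
    }
    removed[i] <- TRUE
  }
  if (length(survivors) == 0) return(NULL)
  sv <- stats[survivors, ]
  sv <- sv[order(sv$chrom, sv$pos), ]
  groups <- list()
  for (k in seq_len(nrow(sv))) {
    if (k == 1 || sv$chrom[k] != sv$chrom[k - 1] ||
        sv$pos[k] - sv$pos[k - 1] >= group_dist) {
      groups[[length(groups) + 1]] <- k
    } else {
      groups[[length(groups)]] <- c(groups[[length(groups)]], k)
    }
  }
  lapply(groups, function(idx) {
    g <- sv[idx, ]
    list(index = g$rsid[which.min(g$p)], members = sort(g$rsid),
         index_p = min(g$p))
  })
}

# correlated dosage block for coloc/cojo scenarios
sim_ld_block <- function(n, m, maf = 0.3, rho = 0.9) {
  z <- matrix(rnorm(2 * n * m), 2 * n, m)
  if (m > 1) {
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
  }
  H <- (z < qnorm(maf)) * 1L
  H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
}

# marginal summary stats of y on each column of G
marginal_stats <- function(G, y, chrom = NULL, pos = NULL) {
  n <- length(y)
  Gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  sxx <- colSums(Gc^2)
  beta <- as.vector(crossprod(Gc, yc)) / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sxx))
  tibble::tibble(
    rsid = paste0("v", seq_len(ncol(G))),
    chrom = chrom %||% rep("1", ncol(G)),
    pos = pos %||% (1e6 + (seq_len(ncol(G)) - 1) * 5000),
    af = colMeans(G) / 2, beta = beta, se = se,
    p = 2 * pt(-abs(beta / se), df = n - 2), n = n)
}
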