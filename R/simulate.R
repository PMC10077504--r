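#' Configuration for the synthetic isolate-cohort generator
#'
#' Bundles every knob of the simulator with defaults chosen to emulate a
#' two-cohort founder-population pQTL study design: two related isolate
#' cohorts whose allele frequencies have drifted from a shared ancestral
#' (cosmopolitan reference) population, blocky LD, sibship relatedness,
#' planted cis/trans protein effects, covariate structure (age, age-squared,
#' sex, plate, season, per-sample mean shift), a polygenic component, and
#' left-censoring at a per-protein limit of detection (LOD).
#'
#' @param n_samples_per_cohort Samples per cohort.
#' @param n_variants Number of biallelic variants on the panel.
#' @param n_proteins Number of protein assays.
#' @param drift_fst Balding-Nichols divergence parameter between each cohort
#'   and the ancestral population, in (0, 1); 0 disables drift.
#' @param ld_block_size Variants per LD block.
#' @param ld_rho Latent first-order autocorrelation of haplotype alleles
#'   within a block, in `[0, 1)`; 0 gives linkage equilibrium.
#' @param n_cis_effects,n_trans_effects Number of planted cis (within 1 Mb of
#'   the encoding gene's start) and trans protein effects.
#' @param effect_size_sd Standard deviation of planted effect sizes, in NPX
#'   units per ALT allele; overridden by `effect_sizes` when supplied.
#' @param effect_sizes Optional numeric vector of exact planted effect sizes,
#'   recycled over the planted effects in order (cis first).
#' @param polygenic_h2 Proportion of the unit residual NPX variance explained
#'   by a polygenic term with covariance proportional to the realized GRM.
#' @param lod_quantile Per-protein quantile at which the LOD is placed;
#'   roughly this proportion of values falls below the LOD.
#' @param n_chrom Number of chromosomes the panel is spread over (LD blocks
#'   never span a chromosome boundary).
#' @param relatedness_block_size Sibship size; full sibs share parental
#'   haplotypes, making the GRM non-trivial. 1 gives unrelated samples.
#' @param causal_protein_effects Data frame with columns `protein`, `trait`,
#'   `beta`: true causal protein-to-trait effects used by
#'   [simulate_outcome_gwas()].
#' @param causal_min_maf Minimum ancestral MAF for planted causal variants.
#' @param drift_fold Fold threshold used when recording drifted variants in
#'   the ground truth (cohort MAF / reference MAF).
#' @param geno_missing_rate Per-genotype missing rate.
#' @param seed Integer seed; a fixed seed makes all outputs reproducible
#'   (R's default Mersenne-Twister RNG).
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohorts()], [simulate_outcome_gwas()]
#' @export
sim_config <- function(n_samples_per_cohort = 1000,
                       n_variants = 5000,
                       n_proteins = 20,
                       drift_fst = 0.02,
                       ld_block_size = 20,
                       ld_rho = 0.8,
                       n_cis_effects = 5,
                       n_trans_effects = 2,
                       effect_size_sd = 0.8,
                       effect_sizes = NULL,
                       polygenic_h2 = 0.2,
                       lod_quantile = 0.05,
                       n_chrom = 10,
                       relatedness_block_size = 4,
                       causal_protein_effects = NULL,
                       causal_min_maf = 0.05,
                       drift_fold = 2.25,
                       geno_missing_rate = 0.002,
                       seed = 1L) {
  cfg <- list(
    n_samples_per_cohort = as.integer(n_samples_per_cohort),
    n_variants = as.integer(n_variants),
    n_proteins = as.integer(n_proteins),
    drift_fst = drift_fst,
    ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho,
    n_cis_effects = as.integer(n_cis_effects),
    n_trans_effects = as.integer(n_trans_effects),
    effect_size_sd = effect_size_sd,
    effect_sizes = effect_sizes,
    polygenic_h2 = polygenic_h2,
    lod_quantile = lod_quantile,
    n_chrom = as.integer(n_chrom),
    relatedness_block_size = as.integer(relatedness_block_size),
    causal_protein_effects = if (is.null(causal_protein_effects)) {
      tibble(protein = character(), trait = character(), beta = double())
    } else {
      as_tibble(causal_protein_effects)
    },
    causal_min_maf = causal_min_maf,
    drift_fold = drift_fold,
    geno_missing_rate = geno_missing_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if_not(cfg$n_samples_per_cohort > 0 && cfg$n_variants > 0 &&
                cfg$n_proteins > 0, "counts must be positive")
  stop_if_not(cfg$drift_fst >= 0 && cfg$drift_fst < 1,
              "drift_fst must be in [0, 1)")
  stop_if_not(cfg$ld_rho >= 0 && cfg$ld_rho < 1, "ld_rho must be in [0, 1)")
  stop_if_not(cfg$polygenic_h2 >= 0 && cfg$polygenic_h2 < 1,
              "polygenic_h2 must be in [0, 1)")
  stop_if_not(cfg$lod_quantile >= 0 && cfg$lod_quantile < 1,
              "lod_quantile must be a proportion")
  stop_if_not(cfg$relatedness_block_size >= 1,
              "relatedness_block_size must be >= 1")
  if (cfg$n_cis_effects + cfg$n_trans_effects > cfg$n_proteins * 8L) {
    abort(paste0(
      "too many planted effects: at most 8 independent signals per protein ",
      "are supported (", cfg$n_proteins * 8L, " for ", cfg$n_proteins,
      " proteins)"))
  }
  invisible(cfg)
}

# ---- containers --------------------------------------------------------

new_genotype_panel <- function(dosage, variants, samples) {
  dimnames(dosage) <- list(samples, variants$variant_id)
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", length(x$samples), " samples x ",
      nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

new_protein_matrix <- function(npx, lod, covariates) {
  structure(list(npx = npx, lod = lod, covariates = covariates),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat("<protein_matrix> ", nrow(x$npx), " samples x ", ncol(x$npx),
      " proteins (NPX)\n", sep = "")
  invisible(x)
}

# Deterministic variant map shared by the cohort and outcome generators:
# chromosomes are contiguous chunks whose size is a multiple of the LD
# block size, 5 kb inter-variant spacing, positions restarting at 1 Mb.
variant_map <- function(config) {
  m <- config$n_variants
  chunk <- max(config$ld_block_size,
               ceiling(m / config$n_chrom / config$ld_block_size) *
                 config$ld_block_size)
  chrom_idx <- (seq_len(m) - 1L) %/% chunk + 1L
  within <- (seq_len(m) - 1L) %% chunk
  tibble(
    variant_id = paste0("rs", seq_len(m)),
    chrom = as.character(chrom_idx),
    pos = 1e6 + within * 5000,
    ref = "A", alt = "G")
}

# ---- haplotype machinery ----------------------------------------------

# Haplotypes via a Gaussian-copula first-order Markov chain: latent AR(1)
# normals with autocorrelation rho inside each LD block (chains restart at
# block boundaries), thresholded at qnorm(freq) so marginal allele
# frequencies are exact. Indicator correlation is below rho but monotone in
# it, which is all the r2-based logic downstream needs.
r_haplotypes <- function(n_hap, freqs, block_size, rho) {
  m <- length(freqs)
  z <- matrix(rnorm(n_hap * m), n_hap, m)
  if (rho > 0 && m > 1L) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) {
      if ((j - 1L) %% block_size != 0L) {
        z[, j] <- rho * z[, j - 1L] + s * z[, j]
      }
    }
  }
  H <- matrix(0L, n_hap, m)
  thr <- qnorm(freqs)
  for (j in 1:m) H[, j] <- as.integer(z[, j] < thr[j])
  H
}

# Sibship-block diploid sampling: each family draws 4 parental haplotypes;
# each child inherits one whole haplotype per parent (no recombination), so
# full sibs have expected relatedness 0.5.
r_cohort_dosage <- function(n, freqs, block_size, rho, sib_size) {
  n_fam <- ceiling(n / sib_size)
  H <- r_haplotypes(4L * n_fam, freqs, block_size, rho)
  pat <- integer(n); mat <- integer(n)
  k <- 0L
  for (f in seq_len(n_fam)) {
    base <- 4L * (f - 1L)
    n_kids <- min(sib_size, n - k)
    pat[k + seq_len(n_kids)] <- base + sample(1:2, n_kids, replace = TRUE)
    mat[k + seq_len(n_kids)] <- base + sample(3:4, n_kids, replace = TRUE)
    k <- k + n_kids
  }
  fam <- rep(seq_len(n_fam), each = sib_size)[1:n]
  list(dosage = H[pat, , drop = FALSE] + H[mat, , drop = FALSE], family = fam)
}

# ---- main generator ----------------------------------------------------

#' Simulate two isolate cohorts with planted pQTLs and ground truth
#'
#' Generates, from a single seed, everything the downstream pipeline
#' consumes: a genotype panel and NPX protein matrix per cohort, a reference
#' allele-frequency table playing the role of a cosmopolitan (gnomAD-NFE
#' -like) population, a known-signal catalogue, and the full ground truth.
#'
#' Ancestral ALT-allele frequencies are drawn from a U-shaped Beta(0.5, 0.5)
#' distribution; each cohort's frequencies then take one Balding-Nichols
#' step, `p_c ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = drift_fst`, while
#' the reference table keeps the ancestral values, so founder-style drift of
#' rare alleles arises naturally. Haplotypes carry within-block Markov LD,
#' sibship blocks make the realized GRM non-trivial, and each protein's NPX
#' value is the sum of planted variant effects, a polygenic term, fixed
#' covariate effects (age, age squared, sex, plate, season, a per-sample
#' mean shift) and Gaussian noise; the per-protein LOD sits at
#' `lod_quantile` of the realized distribution.
#'
#' @param config A [sim_config()].
#' @return A list of class `isopqtl_sim` with elements `cohorts` (each a
#'   list with `panel`, `proteins`, `family`), `reference_af`,
#'   `known_signals` and `truth` (planted effects, drifted variants, causal
#'   protein-trait effects, gene locations).
#' @examples
#' sim <- simulate_cohorts(sim_config(n_samples_per_cohort = 100,
#'                                    n_variants = 300, n_proteins = 4,
#'                                    seed = 7))
#' sim$truth$planted
#' @export
simulate_cohorts <- function(config) {
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  validate_sim_config(config)
  set.seed(config$seed)
  m <- config$n_variants
  n <- config$n_samples_per_cohort
  P <- config$n_proteins

  variants <- variant_map(config)
  p0 <- pmin(pmax(rbeta(m, 0.5, 0.5), 0.01), 0.99)
  variants$ancestral_af <- p0

  # gene locations: one encoding gene per protein, anchored at a variant
  proteins <- paste0("PROT", seq_len(P))
  gene_idx <- sample.int(m, P, replace = FALSE)
  genes <- tibble(
    protein = proteins, gene = paste0("GENE", seq_len(P)),
    chrom = variants$chrom[gene_idx], gene_start = variants$pos[gene_idx]
  )

  planted <- plant_effects(config, variants, genes, p0)

  # cohort frequencies: one Balding-Nichols step each
  cohort_freq <- function() {
    if (config$drift_fst <= 0) return(p0)
    F <- config$drift_fst
    pmin(pmax(rbeta(m, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F),
              1 / (4 * n)), 1 - 1 / (4 * n))
  }

  cohorts <- list()
  drifted <- list()
  for (co in 1:2) {
    pc <- cohort_freq()
    cd <- r_cohort_dosage(n, pc, config$ld_block_size, config$ld_rho,
                          config$relatedness_block_size)
    G <- cd$dosage
    if (config$geno_missing_rate > 0) {
      nmiss <- rbinom(1L, length(G), config$geno_missing_rate)
      if (nmiss > 0) G[sample.int(length(G), nmiss)] <- NA_integer_
    }
    samples <- sprintf("C%dS%04d", co, seq_len(n))
    panel <- new_genotype_panel(G, variants, samples)
    pm <- simulate_npx(config, panel, planted, co, cd$family)
    cohorts[[paste0("cohort", co)]] <-
      list(panel = panel, proteins = pm, family = cd$family)

    emp_maf <- maf_of(colMeans(G, na.rm = TRUE) / 2)
    ref_maf <- maf_of(p0)
    fold <- ifelse(ref_maf == 0, Inf, emp_maf / ref_maf)
    hit <- which(fold >= config$drift_fold & emp_maf > 0)
    drifted[[co]] <- tibble(
      variant_id = variants$variant_id[hit], cohort = paste0("cohort", co),
      cohort_maf = emp_maf[hit], reference_maf = ref_maf[hit],
      fold = fold[hit])
  }

  reference_af <- tibble(
    variant_id = variants$variant_id, chrom = variants$chrom,
    pos = variants$pos, ref = variants$ref, alt = variants$alt,
    ref_af = p0, ref_maf = maf_of(p0))

  # catalogue half of the planted variants as "known" signals
  known <- planted[seq_len(nrow(planted)) %% 2L == 1L, , drop = FALSE]
  known_signals <- tibble(
    rsid = known$variant_id, chrom = known$chrom, pos = known$pos,
    trait = known$protein, source = "synthetic-catalogue")

  structure(list(
    cohorts = cohorts,
    reference_af = reference_af,
    known_signals = known_signals,
    truth = list(planted = planted, drifted = bind_rows(drifted),
                 causal_protein_effects = config$causal_protein_effects,
                 gene_locations = genes, polygenic_h2 = config$polygenic_h2),
    config = config
  ), class = "isopqtl_sim")
}

# choose planted cis/trans variants and effect sizes
plant_effects <- function(config, variants, genes, p0) {
  eligible <- which(maf_of(p0) >= config$causal_min_maf)
  rows <- list()
  betas <- if (!is.null(config$effect_sizes)) {
    rep_len(config$effect_sizes, config$n_cis_effects + config$n_trans_effects)
  } else {
    rnorm(config$n_cis_effects + config$n_trans_effects,
          0, config$effect_size_sd)
  }
  k <- 0L
  per_protein <- integer(nrow(genes))
  pick_protein <- function() {
    cand <- which(per_protein < 8L)
    cand[sample.int(length(cand), 1L)]
  }
  for (i in seq_len(config$n_cis_effects)) {
    g <- pick_protein()
    win <- eligible[variants$chrom[eligible] == genes$chrom[g] &
                      abs(variants$pos[eligible] - genes$gene_start[g]) <= 1e6]
    stop_if_not(length(win) > 0, "no eligible cis variant near a gene")
    v <- win[sample.int(length(win), 1L)]
    k <- k + 1L; per_protein[g] <- per_protein[g] + 1L
    rows[[k]] <- tibble(variant_id = variants$variant_id[v],
                        chrom = variants$chrom[v], pos = variants$pos[v],
                        protein = genes$protein[g], beta = betas[k],
                        type = "cis")
  }
  for (i in seq_len(config$n_trans_effects)) {
    g <- pick_protein()
    far <- eligible[variants$chrom[eligible] != genes$chrom[g] |
                      abs(variants$pos[eligible] - genes$gene_start[g]) > 5e6]
    stop_if_not(length(far) > 0, "no eligible trans variant")
    v <- far[sample.int(length(far), 1L)]
    k <- k + 1L; per_protein[g] <- per_protein[g] + 1L
    rows[[k]] <- tibble(variant_id = variants$variant_id[v],
                        chrom = variants$chrom[v], pos = variants$pos[v],
                        protein = genes$protein[g], beta = betas[k],
                        type = "trans")
  }
  if (k == 0L) {
    return(tibble(variant_id = character(), chrom = character(),
                  pos = double(), protein = character(), beta = double(),
                  type = character()))
  }
  bind_rows(rows)
}

# NPX matrix for one cohort: planted effects + polygenic + covariates + noise
simulate_npx <- function(config, panel, planted, cohort_index, family) {
  n <- length(panel$samples)
  P <- config$n_proteins
  proteins <- paste0("PROT", seq_len(P))
  G <- impute_dosage(panel$dosage * 1.0)

  age <- round(runif(n, 25, 85))
  sex <- rbinom(n, 1L, 0.5)
  plate <- (seq_len(n) - 1L) %/% 90L + 1L
  season_base <- as.integer(plate <= max(plate) / 2)  # plating follows season
  season <- ifelse(runif(n) < 0.9, season_base, 1L - season_base)
  shift <- rnorm(n, 0, 0.3)  # per-sample mean NPX shift

  # polygenic component with covariance proportional to the realized GRM
  h2 <- config$polygenic_h2
  poly <- matrix(0, n, P)
  if (h2 > 0) {
    # polygenic background carried by low-frequency and common variants,
    # the same class the empirical GRM is built from
    p_hat <- colMeans(G) / 2
    keep <- p_hat > 0.01 & p_hat < 0.99
    Z <- scale(G[, keep, drop = FALSE])
    a <- matrix(rnorm(sum(keep) * P, 0, sqrt(h2 / sum(keep))), sum(keep), P)
    poly <- Z %*% a
  }

  npx <- matrix(0, n, P, dimnames = list(panel$samples, proteins))
  n_plate <- max(plate)
  for (j in seq_len(P)) {
    b0 <- rnorm(1, 5, 1)
    b_age <- rnorm(1, 0, 0.005); b_age2 <- rnorm(1, 0, 5e-5)
    b_sex <- rnorm(1, 0, 0.3); b_season <- rnorm(1, 0, 0.2)
    b_plate <- rnorm(n_plate, 0, 0.2)
    gv <- rep(0, n)
    pl <- planted[planted$protein == proteins[j], , drop = FALSE]
    for (r in seq_len(nrow(pl))) {
      gv <- gv + pl$beta[r] * G[, pl$variant_id[r]]
    }
    npx[, j] <- b0 + b_age * age + b_age2 * age^2 + b_sex * sex +
      b_season * season + b_plate[plate] + shift + gv + poly[, j] +
      rnorm(n, 0, sqrt(1 - h2))
  }
  lod <- apply(npx, 2, quantile, probs = config$lod_quantile, names = FALSE)
  covariates <- tibble(
    sample_id = panel$samples, age = age, sex = sex, plate = plate,
    season = season, cohort = paste0("cohort", cohort_index), family = family)
  new_protein_matrix(npx, setNames(lod, proteins), covariates)
}

#' Simulate outcome-trait GWAS summary statistics
#'
#' Draws an independent sample of `n_gwas` unrelated individuals from the
#' ancestral population underlying a simulated study, constructs each
#' outcome trait as the sum of the causal protein levels times their stated
#' effects plus unit Gaussian noise, and reports marginal per-variant
#' regression summary statistics (beta, SE, P) per trait, as a downstream
#' two-sample MR stage would consume them. Only a fraction `overlap` of
#' panel variants is reported, to exercise proxy lookup.
#'
#' Genotypes are generated block-by-block under per-block seeds so memory
#' stays flat in `n_gwas`; protein levels in the outcome sample combine the
#' planted variant effects with residual noise on the same NPX scale.
#'
#' @param config The [sim_config()] used for [simulate_cohorts()].
#' @param truth The `truth` element of a [simulate_cohorts()] result.
#' @param n_gwas Outcome-sample size.
#' @param overlap Fraction of panel variants present in the outcome
#'   summary statistics.
#' @return A tibble per trait, bound with a `trait` column: `rsid`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`.
#' @export
simulate_outcome_gwas <- function(config, truth, n_gwas = 10000,
                                  overlap = 0.9) {
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  stop_if_not(overlap >= 0 && overlap <= 1, "overlap must be in [0, 1]")
  base_seed <- (config$seed + 1000003L) %% .Machine$integer.max
  m <- config$n_variants
  bs <- config$ld_block_size
  n_blocks <- ceiling(m / bs)
  # regenerate the same ancestral frequencies simulate_cohorts drew first
  set.seed(config$seed)
  p0 <- pmin(pmax(rbeta(m, 0.5, 0.5), 0.01), 0.99)
  set.seed(base_seed)

  effects <- truth$causal_protein_effects
  traits <- unique(effects$trait)
  if (length(traits) == 0L) traits <- "null_trait"
  planted <- truth$planted

  gen_block <- function(b) {
    cols <- ((b - 1L) * bs + 1L):min(b * bs, m)
    set.seed((base_seed + 7919L * b) %% .Machine$integer.max)
    H <- r_haplotypes(2L * n_gwas, p0[cols], bs, config$ld_rho)
    H[seq_len(n_gwas), , drop = FALSE] +
      H[n_gwas + seq_len(n_gwas), , drop = FALSE]
  }

  # pass 1: causal blocks -> protein levels -> traits
  var_ids <- paste0("rs", seq_len(m))
  causal_idx <- match(planted$variant_id, var_ids)
  causal_blocks <- sort(unique((causal_idx - 1L) %/% bs + 1L))
  causal_dos <- list()
  for (b in causal_blocks) {
    cols <- ((b - 1L) * bs + 1L):min(b * bs, m)
    Gb <- gen_block(b)
    for (i in which(causal_idx %in% cols)) {
      causal_dos[[planted$variant_id[i]]] <- Gb[, match(causal_idx[i], cols)]
    }
  }
  set.seed((base_seed + 13L) %% .Machine$integer.max)
  h2 <- config$polygenic_h2
  all_prot <- unique(c(planted$protein, effects$protein))
  prot_levels <- matrix(0, n_gwas, length(all_prot),
                        dimnames = list(NULL, all_prot))
  for (pp in all_prot) {
    gv <- rep(0, n_gwas)
    pl <- planted[planted$protein == pp, , drop = FALSE]
    for (r in seq_len(nrow(pl))) gv <- gv + pl$beta[r] * causal_dos[[pl$variant_id[r]]]
    lvl <- gv + rnorm(n_gwas, 0, 1)
    # standardize so the stated causal effects are per SD of protein,
    # matching the INT-standardized exposure scale of the pQTL stage
    prot_levels[, pp] <- lvl / sd(lvl)
  }
  trait_mat <- matrix(0, n_gwas, length(traits),
                      dimnames = list(NULL, traits))
  for (tr in traits) {
    y <- rnorm(n_gwas, 0, 1)
    eff <- effects[effects$trait == tr, , drop = FALSE]
    for (r in seq_len(nrow(eff))) {
      y <- y + eff$beta[r] * prot_levels[, eff$protein[r]]
    }
    trait_mat[, tr] <- y
  }

  # which variants appear in the outcome statistics
  set.seed((base_seed + 29L) %% .Machine$integer.max)
  keep <- sort(sample.int(m, floor(overlap * m)))

  # pass 2: marginal statistics per block
  vmap <- variant_map(config)
  chrom <- vmap$chrom
  pos <- vmap$pos
  res_acc <- list()
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1L) * bs + 1L):min(b * bs, m)
    use <- intersect(cols, keep)
    if (length(use) == 0L) next
    Gb <- gen_block(b)[, match(use, cols), drop = FALSE]
    Gc <- sweep(Gb, 2, colMeans(Gb))
    sxx <- colSums(Gc^2)
    poly_ok <- sxx > 0
    for (tr in traits) {
      y <- trait_mat[, tr]
      yc <- y - mean(y)
      sxy <- as.vector(crossprod(Gc, yc))
      beta <- ifelse(poly_ok, sxy / sxx, NA_real_)
      rss <- sum(yc^2) - beta^2 * sxx
      se <- sqrt(pmax(rss, 0) / ((n_gwas - 2) * sxx))
      pval <- 2 * pt(-abs(beta / se), df = n_gwas - 2)
      res_acc[[length(res_acc) + 1L]] <- tibble(
        trait = tr, rsid = var_ids[use], chrom = chrom[use], pos = pos[use],
        effect_allele = "G", other_allele = "A",
        eaf = colMeans(Gb) / 2, beta = beta, se = se, p = pval, n = n_gwas)
    }
  }
  if (length(res_acc) == 0L) {
    return(tibble(trait = character(), rsid = character(),
                  chrom = character(), pos = double(),
                  effect_allele = character(), other_allele = character(),
                  eaf = double(), beta = double(), se = double(),
                  p = double(), n = double()))
  }
  bind_rows(res_acc) |>
    filter(!is.na(.data$beta)) |>
    arrange(.data$trait, .data$chrom, .data$pos)
}
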