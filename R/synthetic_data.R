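# Synthetic GWAS summary statistics with known ground truth.
#
# Two generators, both built on closed-form AR(1) within-block LD
# (corr(i, j) = ld_rho^|i-j|), so LD scores are exact and every covariance is
# positive definite by construction:
#   * simulate_pair: per-segment causal configurations drawn from a model
#     prior, for exercising the pairwise Bayesian engine end to end;
#   * simulate_tritrait: an infinitesimal polygenic model for three traits
#     with specified heritabilities and genetic correlations, for the LDSC
#     and partial-correlation stages.
# Sample overlap is modelled at the noise level: the estimation errors of
# two studies sharing Ns individuals with phenotypic correlation rho_pheno
# are correlated C = Ns * rho_pheno / sqrt(n1 * n2) at each SNP.
# Positions are synthetic (one pseudo-chromosome per 100 segments, 1 kb
# spacing) and emitted in valid sumstats/BED/LD-score dialects so the real
# readers are exercised.

ar1_cor <- function(k, rho) {
  if (rho == 0) return(diag(k))
  rho^abs(outer(seq_len(k), seq_len(k), "-"))
}

ar1_ldscores <- function(k, rho) rowSums(ar1_cor(k, rho)^2)

#' Configuration for the two-trait pairwise simulation
#'
#' Defaults reflect the conditions the pairwise analysis is designed for:
#' two large, non-overlapping GWAS (sample sizes matching a depression
#' meta-analysis and a biobank neuroticism study), mostly-null genome with a
#' minority of associated segments, and strongly associated causal variants
#' (`effect_scale` is the expected chi-square at the causal SNP).
#'
#' @param n_segments number of LD segments.
#' @param snps_per_segment SNPs per segment.
#' @param ld_rho AR(1) LD correlation parameter, in [0, 1).
#' @param pi_true prior over the five causal models (null, trait-1 only,
#'   trait-2 only, shared, separate) used to draw each segment's model.
#' @param effect_scale expected chi-square at a causal SNP for the affected
#'   trait.
#' @param n1,n2 sample sizes of the two studies.
#' @param n_overlap individuals shared between the studies.
#' @param rho_pheno phenotypic correlation among shared individuals.
#' @param effect_dist `"fixed"` draws causal z-score means of fixed magnitude
#'   `sqrt(effect_scale - 1)` with random sign; `"normal"` draws them
#'   N(0, effect_scale - 1).
#' @param seed RNG seed; the generator is bit-reproducible given the config.
#' @export
pair_sim_config <- function(n_segments = 500, snps_per_segment = 50,
                            ld_rho = 0.5,
                            pi_true = c(0.70, 0.05, 0.05, 0.15, 0.05),
                            effect_scale = 80,
                            n1 = 431394, n2 = 329821,
                            n_overlap = 0, rho_pheno = 0,
                            effect_dist = c("fixed", "normal"), seed = 1) {
  effect_dist <- match.arg(effect_dist)
  stopifnot(
    n_segments >= 1, snps_per_segment >= 1,
    ld_rho >= 0, ld_rho < 1,
    length(pi_true) == 5, all(pi_true >= 0),
    effect_scale > 1, n1 > 0, n2 > 0,
    n_overlap >= 0, n_overlap <= min(n1, n2),
    abs(rho_pheno) <= 1
  )
  if (abs(sum(pi_true) - 1) > 1e-8) stop("pi_true must sum to 1")
  structure(
    list(n_segments = n_segments, snps_per_segment = snps_per_segment,
         ld_rho = ld_rho, pi_true = pi_true, effect_scale = effect_scale,
         n1 = n1, n2 = n2, n_overlap = n_overlap, rho_pheno = rho_pheno,
         effect_dist = effect_dist, seed = seed),
    class = "pair_sim_config"
  )
}

# synthetic coordinates: one pseudo-chromosome per 100 segments, 1 kb spacing
segment_coordinates <- function(n_segments, k) {
  seg <- seq_len(n_segments)
  chrom <- (seg - 1) %/% 100 + 1
  within <- (seg - 1) %% 100
  start <- within * k * 1000L
  data.frame(segment = seg, chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(start + k * 1000L),
             stringsAsFactors = FALSE)
}

sumstats_frame <- function(snp_id, chrom, bp, z, n) {
  data.frame(
    SNP = snp_id, CHR = chrom, BP = bp, A1 = "A", A2 = "G",
    Z = z, P = 2 * pnorm(-abs(z)), N = n, stringsAsFactors = FALSE
  )
}

#' Simulate two-trait GWAS summary statistics with segment causal models
#'
#' Per segment, a causal model is drawn from `pi_true`; causal SNP(s) are
#' placed uniformly (distinct SNPs for the separate-signals model); causal
#' z-score means propagate through the AR(1) LD matrix (marginal mean =
#' LD x direct mean); and noise is drawn with the within-segment LD
#' correlation per trait and the overlap-induced cross-trait correlation
#' `C = n_overlap * rho_pheno / sqrt(n1 n2)` at each SNP. The shared model
#' places independent effects for the two traits at the same SNP, matching
#' the analysis model. LD scores are computed exactly from the generating LD
#' matrix.
#'
#' @param config a [pair_sim_config()].
#' @param dir optional directory: when given, sumstats, BED blocks, LD
#'   scores and the truth table are also written there as text files.
#' @return list with `sumstats1`, `sumstats2` (generic-dialect data.frames),
#'   `blocks`, `ldscores` (with attribute `M`), `truth`, `config`.
#' @export
simulate_pair <- function(config, dir = NULL) {
  stopifnot(inherits(config, "pair_sim_config"))
  set.seed(config$seed)
  k <- config$snps_per_segment
  ns <- config$n_segments
  R <- ar1_cor(k, config$ld_rho)
  tL <- t(chol(R))
  l2 <- ar1_ldscores(k, config$ld_rho)
  C <- config$n_overlap * config$rho_pheno / sqrt(config$n1 * config$n2)

  model <- sample(0:4, ns, replace = TRUE, prob = config$pi_true)
  draw_lambda <- function(m) {
    s <- sqrt(config$effect_scale - 1)
    if (config$effect_dist == "fixed") sample(c(-s, s), m, replace = TRUE)
    else rnorm(m, 0, s)
  }

  G1 <- matrix(rnorm(k * ns), k, ns)
  G2 <- matrix(rnorm(k * ns), k, ns)
  Z1 <- tL %*% G1
  Z2 <- tL %*% (C * G1 + sqrt(1 - C^2) * G2)

  causal1 <- rep(NA_integer_, ns)
  causal2 <- rep(NA_integer_, ns)
  for (s in seq_len(ns)) {
    m <- model[s]
    if (m == 0) next
    if (m == 1) {
      i <- sample.int(k, 1)
      causal1[s] <- i
      Z1[, s] <- Z1[, s] + R[, i] * draw_lambda(1)
    } else if (m == 2) {
      i <- sample.int(k, 1)
      causal2[s] <- i
      Z2[, s] <- Z2[, s] + R[, i] * draw_lambda(1)
    } else if (m == 3) {
      i <- sample.int(k, 1)
      causal1[s] <- causal2[s] <- i
      Z1[, s] <- Z1[, s] + R[, i] * draw_lambda(1)
      Z2[, s] <- Z2[, s] + R[, i] * draw_lambda(1)
    } else {
      ij <- sample.int(k, 2) # distinct
      causal1[s] <- ij[1]
      causal2[s] <- ij[2]
      Z1[, s] <- Z1[, s] + R[, ij[1]] * draw_lambda(1)
      Z2[, s] <- Z2[, s] + R[, ij[2]] * draw_lambda(1)
    }
  }

  coords <- segment_coordinates(ns, k)
  snp_seg <- rep(seq_len(ns), each = k)
  within <- rep(seq_len(k), ns)
  snp_id <- paste0("rs", seq_len(k * ns))
  chrom <- coords$chrom[snp_seg]
  bp <- coords$start[snp_seg] + (within - 1L) * 1000L + 1L

  ss1 <- sumstats_frame(snp_id, chrom, bp, as.vector(Z1), config$n1)
  ss2 <- sumstats_frame(snp_id, chrom, bp, as.vector(Z2), config$n2)
  blocks <- coords[, c("chrom", "start", "end")]
  ldsc <- data.frame(snp_id = snp_id, ld_score = rep(l2, ns),
                     stringsAsFactors = FALSE)
  attr(ldsc, "M") <- k * ns
  model_names <- c("null", "trait1", "trait2", "shared", "separate")
  seg_offset <- (coords$segment - 1L) * k
  truth <- data.frame(
    segment = coords$segment, block_id = coords$segment - 1L,
    model = model_names[model + 1L],
    causal1 = snp_id[seg_offset + causal1],
    causal2 = snp_id[seg_offset + causal2],
    stringsAsFactors = FALSE
  )

  out <- list(sumstats1 = ss1, sumstats2 = ss2, blocks = blocks,
              ldscores = ldsc, truth = truth, config = config)
  if (!is.null(dir)) write_simulation(out, dir)
  out
}

#' Configuration for the three-trait polygenic simulation
#'
#' Infinitesimal-model generator for the LDSC / partial-correlation stages.
#' The default genetic correlation matrix is the flagship decomposition
#' fixture: traits (Y, MD, NEU) with `rg(MD, NEU) = 0.68`, `rg(Y, MD) = 0.5`
#' and `rg(Y, NEU) = 0.34`, so that the standardised coefficient of Y on MD
#' adjusting for NEU is exactly 0.5 and on NEU adjusting for MD exactly 0.
#'
#' @param m_snps total SNPs.
#' @param block_size SNPs per LD block.
#' @param ld_rho AR(1) LD parameter within blocks; a vector is recycled
#'   across blocks, giving the genome-wide spread of LD scores that
#'   identifies the LDSC slope against the intercept.
#' @param h2 per-trait heritabilities (length 3).
#' @param rg_matrix 3x3 genetic correlation matrix (unit diagonal, PD).
#' @param n per-trait sample sizes (length 3).
#' @param n_overlap 3x3 symmetric matrix of pairwise shared sample counts
#'   (diagonal ignored); scalar 0 for no overlap.
#' @param rho_pheno 3x3 phenotypic correlation among shared individuals (or
#'   scalar).
#' @param traits trait labels.
#' @param seed RNG seed.
#' @export
tri_sim_config <- function(m_snps = 20000, block_size = 50,
                           ld_rho = c(0.2, 0.5, 0.8),
                           h2 = c(0.3, 0.3, 0.3),
                           rg_matrix = matrix(c(1, 0.5, 0.34,
                                                0.5, 1, 0.68,
                                                0.34, 0.68, 1), 3, 3),
                           n = c(50000, 50000, 50000),
                           n_overlap = 0, rho_pheno = 0,
                           traits = c("Y", "MD", "NEU"), seed = 1) {
  stopifnot(
    m_snps >= block_size, block_size >= 1, all(ld_rho >= 0), all(ld_rho < 1),
    length(h2) == 3, all(h2 > 0), all(h2 <= 1),
    is.matrix(rg_matrix), all(dim(rg_matrix) == 3),
    max(abs(rg_matrix - t(rg_matrix))) < 1e-12,
    all(abs(diag(rg_matrix) - 1) < 1e-12),
    length(n) == 3, all(n > 0), length(traits) == 3
  )
  if (length(n_overlap) == 1) n_overlap <- matrix(n_overlap, 3, 3)
  if (length(rho_pheno) == 1) rho_pheno <- matrix(rho_pheno, 3, 3)
  if (min(eigen(rg_matrix, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("rg_matrix must be positive definite")
  }
  stopifnot(all(n_overlap[upper.tri(n_overlap)] <= min(n)))
  structure(
    list(m_snps = m_snps, block_size = block_size, ld_rho = ld_rho,
         h2 = h2, rg_matrix = rg_matrix, n = n, n_overlap = n_overlap,
         rho_pheno = rho_pheno, traits = traits, seed = seed),
    class = "tri_sim_config"
  )
}

#' Simulate three-trait polygenic GWAS summary statistics
#'
#' Under the infinitesimal model, per-SNP true standardised effects are drawn
#' from a trivariate normal with covariance `diag(sqrt(h2)) rg diag(sqrt(h2))
#' / M`; marginal z-scores are `sqrt(n_t) * R beta_t + e_t` with within-block
#' LD `R` and overlap-structured noise correlation across traits. LD scores
#' are exact.
#'
#' @param config a [tri_sim_config()].
#' @param dir optional output directory for text files.
#' @return list with `sumstats` (named list of three generic-dialect
#'   data.frames), `ldscores` (attribute `M`), `truth`, `config`.
#' @export
simulate_tritrait <- function(config, dir = NULL) {
  stopifnot(inherits(config, "tri_sim_config"))
  set.seed(config$seed)
  k <- config$block_size
  nblk <- config$m_snps %/% k
  m <- nblk * k
  rho_blk <- rep_len(config$ld_rho, nblk)
  rho_set <- unique(rho_blk)
  Rs <- lapply(rho_set, function(r) ar1_cor(k, r))
  tLs <- lapply(Rs, function(R) t(chol(R)))
  l2s <- lapply(Rs, function(R) rowSums(R^2))
  blk_of <- match(rho_blk, rho_set)

  D <- diag(sqrt(config$h2))
  Sg <- D %*% config$rg_matrix %*% D
  beta <- matrix(rnorm(m * 3), m, 3) %*% chol(Sg / m)

  Cn <- diag(3)
  for (t in 1:2) for (u in (t + 1):3) {
    Cn[t, u] <- Cn[u, t] <- config$n_overlap[t, u] * config$rho_pheno[t, u] /
      sqrt(config$n[t] * config$n[u])
  }
  if (min(eigen(Cn, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("overlap structure implies a non-positive-definite noise correlation")
  }
  E <- matrix(rnorm(m * 3), m, 3) %*% chol(Cn)

  Z <- matrix(NA_real_, m, 3)
  for (t in 1:3) {
    sig <- matrix(NA_real_, k, nblk)
    noi <- matrix(NA_real_, k, nblk)
    bmat <- matrix(beta[, t], k, nblk)
    emat <- matrix(E[, t], k, nblk)
    for (g in seq_along(rho_set)) {
      sel <- blk_of == g
      sig[, sel] <- Rs[[g]] %*% bmat[, sel, drop = FALSE]
      noi[, sel] <- tLs[[g]] %*% emat[, sel, drop = FALSE]
    }
    Z[, t] <- sqrt(config$n[t]) * as.vector(sig) + as.vector(noi)
  }

  snp_id <- paste0("rs", seq_len(m))
  blk <- rep(seq_len(nblk), each = k)
  chrom <- as.character((blk - 1) %/% 100 + 1)
  within_chrom_blk <- (blk - 1) %% 100
  bp <- within_chrom_blk * k * 1000L + (rep(seq_len(k), nblk) - 1L) * 1000L + 1L

  sumstats <- setNames(lapply(1:3, function(t) {
    sumstats_frame(snp_id, chrom, bp, Z[, t], config$n[t])
  }), config$traits)
  ldsc <- data.frame(
    snp_id = snp_id,
    ld_score = as.vector(vapply(blk_of, function(g) l2s[[g]], numeric(k))),
    stringsAsFactors = FALSE
  )
  attr(ldsc, "M") <- m

  Rg <- config$rg_matrix
  dimnames(Rg) <- list(config$traits, config$traits)
  pc <- partial_coefficients(Rg, config$traits[1], config$traits[2:3])
  truth <- list(h2 = setNames(config$h2, config$traits), rg = Rg,
                partial_b = pc$b, residual_u = pc$u,
                noise_correlation = Cn)

  out <- list(sumstats = sumstats, ldscores = ldsc, truth = truth,
              config = config)
  if (!is.null(dir)) write_simulation(out, dir)
  out
}

# emit a simulation as the text files the pipeline readers consume
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(dir, file), quote = FALSE, sep = "\t",
                       row.names = FALSE)
  }
  if (!is.null(sim$sumstats1)) {
    wt(sim$sumstats1, "trait1.sumstats.tsv")
    wt(sim$sumstats2, "trait2.sumstats.tsv")
    utils::write.table(sim$blocks, file.path(dir, "blocks.bed"),
                       quote = FALSE, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    wt(sim$truth, "truth.tsv")
  } else {
    for (nm in names(sim$sumstats)) {
      wt(sim$sumstats[[nm]], paste0(nm, ".sumstats.tsv"))
    }
    h2 <- sim$truth$h2
    wt(data.frame(trait = names(h2), h2 = unname(h2)), "truth_h2.tsv")
  }
  write_ldscores(sim$ldscores, file.path(dir, "ldscores.tsv"))
  cfg <- sim$config
  fields <- vapply(cfg, function(v) paste(format(v, digits = 15), collapse = ","),
                   character(1))
  writeLines(paste(names(fields), fields, sep = ": "),
             file.path(dir, "config.yaml"))
  invisible(dir)
}
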