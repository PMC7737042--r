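# The Bayesian pairwise-GWAS engine.
#
# Per SNP, the evidence for association is a Wakefield approximate Bayes
# factor (ABF): the ratio of the marginal likelihood of the observed effect
# under a N(0, W) prior on the true standardised effect to its likelihood
# under the null. Per segment, regional Bayes factors (RBFs) aggregate
# per-SNP ABFs under an at-most-one-causal-variant-per-trait assumption with
# a uniform prior over SNPs, for four non-null causal models:
#   1 trait-1 only, 2 trait-2 only, 3 shared causal signal, 4 separate
#   causal signals.
# Genome-wide model priors are estimated by maximising the mixture marginal
# likelihood over segments, and per-segment posterior model probabilities
# follow by Bayes' rule. Sample overlap between the two studies enters as a
# correlation C between the null z-scores, estimated from segments that show
# no association with either trait.

#' ABF parameters
#'
#' Bundles the prior-variance grid on the standardised effect and the null
#' z-score correlation induced by sample overlap.
#'
#' @param W_grid prior variances averaged with equal weight; defaults follow
#'   the standard pairwise-GWAS grid.
#' @param C null z-score correlation from sample overlap, in (-1, 1).
#' @export
abf_params <- function(W_grid = c(0.01, 0.1, 0.5), C = 0) {
  stopifnot(length(W_grid) >= 1, all(W_grid > 0), length(C) == 1, abs(C) < 1)
  structure(list(W_grid = W_grid, C = C), class = "abf_params")
}

#' Wakefield approximate Bayes factor
#'
#' For an observed z-score with squared standard error `v` of the
#' standardised effect and prior variance `W` on the true effect, the ABF in
#' favour of association is `sqrt(1 - r) * exp(z^2 * r / 2)` with
#' `r = W / (v + W)`. Computed in log space.
#'
#' @param z signed z-score(s); must be finite.
#' @param v squared standard error(s) of the standardised effect (`1/n` under
#'   the standardised-genotype approximation).
#' @param W prior variance (scalar).
#' @param log return the natural log of the Bayes factor.
#' @export
wakefield_abf <- function(z, v, W, log = FALSE) {
  stopifnot(all(v > 0), length(W) == 1, W > 0)
  if (any(!is.finite(z))) stop("non-finite z-score passed to wakefield_abf")
  r <- W / (v + W)
  labf <- 0.5 * log1p(-r) + z^2 * r / 2
  if (log) labf else exp(labf)
}

# log ABF averaged with equal weight over the prior-variance grid (univariate)
labf_grid <- function(z, v, W_grid) {
  m <- vapply(W_grid, function(W) wakefield_abf(z, v, W, log = TRUE),
              numeric(length(z)))
  if (length(z) == 1L) m <- matrix(m, nrow = 1L)
  row_log_mean_exp(m)
}

# log density ratio of two zero-mean bivariate normals evaluated at (z1, z2)
# (vectorised over observations; covariances are scalars)
l2dens <- function(z1, z2, s11, s22, s12) {
  det <- s11 * s22 - s12^2
  if (any(det <= 0)) stop("singular covariance in bivariate Bayes factor")
  -log(2 * pi) - 0.5 * log(det) -
    0.5 * (s22 * z1^2 - 2 * s12 * z1 * z2 + s11 * z2^2) / det
}

#' Bivariate approximate Bayes factor with sample-overlap correction
#'
#' The evidence at a single SNP for causal model 1 (trait 1 affected),
#' 2 (trait 2 affected) or 3 (both affected through the same variant), as a
#' ratio of bivariate normal densities of `(z1, z2)`. The null covariance is
#' `[[1, C], [C, 1]]`; each affected trait `t` adds `W/v_t` to its diagonal
#' entry (the marginal z-variance under association), with the off-diagonal
#' unchanged. The Bayes factor is averaged with equal weight over `W_grid`
#' for each affected trait (a Cartesian grid for model 3). With `C = 0`,
#' model 3 factorises into the product of the two univariate ABFs.
#'
#' @param z1,z2 z-scores for the two traits (vectors of equal length).
#' @param v1,v2 squared standard errors of the standardised effects.
#' @param params an [abf_params()] object.
#' @param model 1, 2 or 3.
#' @param log return the natural log.
#' @export
bivariate_abf <- function(z1, z2, v1, v2, params, model, log = FALSE) {
  stopifnot(inherits(params, "abf_params"), model %in% 1:3)
  if (any(!is.finite(z1)) || any(!is.finite(z2))) {
    stop("non-finite z-score passed to bivariate_abf")
  }
  C <- params$C
  W <- params$W_grid
  null <- l2dens(z1, z2, 1, 1, C)
  combos <- switch(as.character(model),
    "1" = lapply(W, function(w) l2dens(z1, z2, 1 + w / v1, 1, C) - null),
    "2" = lapply(W, function(w) l2dens(z1, z2, 1, 1 + w / v2, C) - null),
    "3" = {
      grid <- expand.grid(w1 = W, w2 = W)
      lapply(seq_len(nrow(grid)), function(i) {
        l2dens(z1, z2, 1 + grid$w1[i] / v1, 1 + grid$w2[i] / v2, C) - null
      })
    }
  )
  m <- do.call(cbind, combos)
  out <- row_log_mean_exp(m)
  if (log) out else exp(out)
}

#' Per-SNP evidence for the pairwise model
#'
#' Computes, for every SNP, the log Bayes factors for the three single-SNP
#' causal patterns (trait-1 only, trait-2 only, shared), overlap-corrected
#' and averaged over the prior grid.
#'
#' @inheritParams bivariate_abf
#' @return a numeric matrix with columns `lbf1`, `lbf2`, `lbf3`.
#' @export
snp_evidence <- function(z1, z2, v1, v2, params) {
  cbind(
    lbf1 = bivariate_abf(z1, z2, v1, v2, params, 1, log = TRUE),
    lbf2 = bivariate_abf(z1, z2, v1, v2, params, 2, log = TRUE),
    lbf3 = bivariate_abf(z1, z2, v1, v2, params, 3, log = TRUE)
  )
}

#' Regional Bayes factors for a segment
#'
#' Aggregates per-SNP evidence over the k SNPs of a segment under at most one
#' causal variant per trait, uniform over SNPs:
#' `rbf1 = mean_i BF1_i`, `rbf2 = mean_i BF2_i`, `rbf3 = mean_i BF3_i`, and
#' for two distinct causal variants
#' `rbf4 = (sum_i BF1_i * sum_j BF2_j - sum_i BF1_i BF2_i) / (k (k - 1))`
#' (zero for k = 1). All sums use log-sum-exp.
#'
#' @param evidence matrix from [snp_evidence()] for the segment's SNPs.
#' @param log return natural logs (the default; `rbf4 = 0` maps to `-Inf`).
#' @return named vector `c(rbf1, rbf2, rbf3, rbf4)`.
#' @export
regional_bfs <- function(evidence, log = TRUE) {
  evidence <- rbind(evidence)
  k <- nrow(evidence)
  if (k == 0) stop("regional_bfs: segment has no SNPs")
  l1 <- logsumexp(evidence[, 1])
  l2 <- logsumexp(evidence[, 2])
  l3 <- logsumexp(evidence[, 3])
  lrbf4 <- if (k == 1) {
    -Inf
  } else {
    lcross <- logsumexp(evidence[, 1] + evidence[, 2])
    log_diff_exp(l1 + l2, lcross) - log(k) - log(k - 1)
  }
  out <- c(rbf1 = l1 - log(k), rbf2 = l2 - log(k), rbf3 = l3 - log(k),
           rbf4 = lrbf4)
  if (!log) out <- exp(out)
  out
}

#' Estimate genome-wide model priors by marginal maximum likelihood
#'
#' Maximises `sum_segments log(pi0 + sum_m pi_m * rbf_m)` over the
#' probability simplex via a softmax parameterisation and BFGS with analytic
#' gradient, from several deterministic starting points. Works for the full
#' five-model problem (`lrbf` with 4 columns) and the two-model single-trait
#' problem (1 column). A flat likelihood (all RBFs ~ 1) is flagged as
#' non-identified.
#'
#' @param lrbf matrix of per-segment log regional Bayes factors (one column
#'   per non-null model; the null RBF is 1 by construction).
#' @param tol relative log-likelihood tolerance used for convergence and for
#'   the non-identifiability check.
#' @param min_segments minimum number of usable segments.
#' @return a `model_priors` list: `pi` (named, `pi0` first), `loglik`,
#'   `converged`, `non_identified`.
#' @export
estimate_priors <- function(lrbf, tol = 1e-8, min_segments = 20) {
  if (!is.matrix(lrbf)) lrbf <- matrix(lrbf, ncol = 1)
  n_seg <- nrow(lrbf)
  if (n_seg < min_segments) {
    stop("prior estimation needs at least ", min_segments,
         " usable segments (got ", n_seg, ")")
  }
  m <- ncol(lrbf)
  B <- cbind(0, lrbf) # include the null model, log RBF 0

  loglik_at <- function(theta) {
    ls <- c(0, theta)
    lp <- ls - logsumexp(ls)
    sum(row_logsumexp(sweep(B, 2, lp, "+")))
  }
  nll <- function(theta) -loglik_at(theta)
  gr <- function(theta) {
    ls <- c(0, theta)
    lp <- ls - logsumexp(ls)
    A <- sweep(B, 2, lp, "+")
    L <- row_logsumexp(A)
    tbar <- colSums(exp(A - L))
    -(tbar[-1] - n_seg * exp(lp)[-1])
  }

  starts <- list(rep(0, m), rep(-2, m), rep(-5, m), rep(1, m),
                 (-1)^(seq_len(m)) * 2)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nll, gr, method = "BFGS",
            control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("prior estimation failed from every starting point")

  ls <- c(0, best$par)
  pi <- exp(ls - logsumexp(ls))
  names(pi) <- paste0("pi", 0:m)
  ll <- -best$value
  non_identified <- abs(ll - loglik_at(rep(0, m))) <= tol * max(1, abs(ll))
  structure(
    list(pi = pi, loglik = ll, converged = best$convergence == 0,
         non_identified = non_identified),
    class = "model_priors"
  )
}

#' Posterior model probabilities for segments
#'
#' `ppa_m = pi_m * rbf_m / (pi0 + sum_m pi_m * rbf_m)` with the null RBF
#' fixed at 1; rows sum to one.
#'
#' @param lrbf matrix (or vector) of per-segment log regional Bayes factors,
#'   one column per non-null model.
#' @param priors a `model_priors` object (or a bare simplex vector, `pi0`
#'   first).
#' @return matrix of posterior probabilities with columns `ppa0..ppa_m`.
#' @export
segment_posteriors <- function(lrbf, priors) {
  pi <- if (inherits(priors, "model_priors")) priors$pi else priors
  if (!is.matrix(lrbf)) {
    # a bare vector is one segment's RBFs when its length matches the model
    # count, otherwise a per-segment column for the two-model problem
    lrbf <- if (length(lrbf) == length(pi) - 1) rbind(lrbf, deparse.level = 0)
            else matrix(lrbf, ncol = 1)
  }
  stopifnot(length(pi) == ncol(lrbf) + 1, all(pi >= 0),
            abs(sum(pi) - 1) < 1e-6)
  A <- sweep(cbind(0, lrbf), 2, log(pi), "+")
  ppa <- exp(A - row_logsumexp(A))
  colnames(ppa) <- paste0("ppa", 0:ncol(lrbf))
  ppa
}

#' Single-trait per-segment association posteriors
#'
#' The two-model (null vs associated) restriction of the pairwise machinery,
#' used as the pre-step that finds segments unassociated with either trait
#' before estimating the sample-overlap correlation. Per segment the regional
#' Bayes factor is the mean univariate ABF over its SNPs; the two-model prior
#' is estimated by the same marginal-likelihood maximisation.
#'
#' @param z,v per-variant z-scores and squared standard errors.
#' @param segments per-variant block ids (`NA` = unassigned, excluded).
#' @param W_grid prior-variance grid for the univariate ABF.
#' @param min_snps segments with fewer SNPs are excluded from prior
#'   estimation (still scored).
#' @return list with `ppa` (named by block id), `lrbf`, `k`, `priors`.
#' @export
single_trait_segment_ppa <- function(z, v, segments, W_grid = c(0.01, 0.1, 0.5),
                                     min_snps = 10) {
  ok <- !is.na(segments)
  labf <- labf_grid(z[ok], v[ok], W_grid)
  seg <- segments[ok]
  idx <- split(seq_along(seg), seg)
  lrbf <- vapply(idx, function(i) logsumexp(labf[i]) - log(length(i)),
                 numeric(1))
  k <- lengths(idx)
  usable <- k >= min_snps
  priors <- estimate_priors(matrix(lrbf[usable], ncol = 1))
  ppa <- segment_posteriors(matrix(lrbf, ncol = 1), priors)[, 2]
  names(ppa) <- names(lrbf)
  list(ppa = ppa, lrbf = lrbf, k = k, priors = priors)
}

#' Estimate the null z-score correlation from unassociated segments
#'
#' Pearson correlation of the two traits' effect sizes over all variants in
#' segments whose single-trait posterior probability of association is below
#' `threshold` for both traits — the sample-overlap correction supplied to
#' the full pairwise model.
#'
#' @param paired a `paired_variants` data.frame.
#' @param segments per-variant block ids aligned to `paired`.
#' @param ppa1,ppa2 per-segment association PPAs named by block id.
#' @param threshold segments with both PPAs below this are retained.
#' @param use_beta correlate betas instead of z-scores (requires beta
#'   columns).
#' @return list with `C`, `n_variants`, `n_segments`.
#' @export
estimate_null_correlation <- function(paired, segments, ppa1, ppa2,
                                      threshold = 0.2, use_beta = FALSE) {
  null_blocks <- intersect(names(ppa1)[ppa1 < threshold],
                           names(ppa2)[ppa2 < threshold])
  sel <- !is.na(segments) & as.character(segments) %in% null_blocks
  if (!any(sel)) {
    stop("no segments with posterior probability of association < ",
         threshold, " for both traits; cannot estimate the null correlation")
  }
  x1 <- if (use_beta) paired$beta1[sel] else paired$z1[sel]
  x2 <- if (use_beta) paired$beta2[sel] else paired$z2[sel]
  if (use_beta && (is.null(x1) || is.null(x2))) {
    stop("use_beta = TRUE but the paired table carries no betas")
  }
  list(C = cor(x1, x2), n_variants = sum(sel),
       n_segments = length(null_blocks))
}

#' Classify segments from posterior model probabilities
#'
#' Applies the labelling rules: a segment is `NEITHER` when its total
#' posterior probability of association (`1 - ppa0`) is below
#' `ppa_total_threshold` and it has no genome-wide significant hit for either
#' trait (this rule takes precedence); otherwise `TRAIT1_ONLY` when the
#' trait-1-only model has the highest posterior among the four causal models
#' and the segment has a genome-wide significant hit for trait 1 but not
#' trait 2 (`TRAIT2_ONLY` symmetric); `BOTH` when the shared model wins;
#' `SEPARATE` when the two-signal model wins; `UNCLASSIFIED` otherwise
#' (including exact posterior ties).
#'
#' @param ppa matrix of posterior probabilities (`ppa0..ppa4`).
#' @param gws1,gws2 logical flags: segment contains a genome-wide significant
#'   variant for trait 1 / trait 2.
#' @param ppa_total_threshold threshold on `1 - ppa0` for the `NEITHER` rule.
#' @return character vector of labels.
#' @export
classify_segments <- function(ppa, gws1, gws2, ppa_total_threshold = 0.2) {
  ppa <- rbind(ppa)
  stopifnot(ncol(ppa) == 5, nrow(ppa) == length(gws1),
            length(gws1) == length(gws2))
  n <- nrow(ppa)
  lab <- rep("UNCLASSIFIED", n)
  alt <- ppa[, 2:5, drop = FALSE]
  mx <- do.call(pmax, as.data.frame(alt))
  tie <- rowSums(alt == mx) > 1
  am <- max.col(alt, ties.method = "first")
  am[tie] <- NA_integer_
  lab[!is.na(am) & am == 1 & gws1 & !gws2] <- "TRAIT1_ONLY"
  lab[!is.na(am) & am == 2 & gws2 & !gws1] <- "TRAIT2_ONLY"
  lab[!is.na(am) & am == 3] <- "BOTH"
  lab[!is.na(am) & am == 4] <- "SEPARATE"
  neither <- (1 - ppa[, 1]) < ppa_total_threshold & !gws1 & !gws2
  lab[neither] <- "NEITHER"
  lab
}

#' @export
print.model_priors <- function(x, ...) {
  cat("Genome-wide model priors (marginal ML):\n")
  print(round(x$pi, 4))
  cat("log-likelihood:", format(x$loglik), "\n")
  if (x$non_identified) cat("note: likelihood is flat; priors not identified\n")
  invisible(x)
}
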