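# Partial genetic correlations via multiple regression on the genetic
# covariance matrix.
#
# For a third trait Y and two focal traits (labelled MD and Neu after the
# package's flagship use case), the 3x3 genetic covariance matrix S is built
# from univariate and cross-trait LDSC on one shared variant set and one
# shared jackknife partition. The model
#   Y_g = b1 * MD_g + b2 * Neu_g + u_Y
# is fitted on the standardised (correlation) scale by the matrix solve
# b = R_xx^-1 r_xy; the standardised coefficients are reported as the
# adjusted ("partial") correlations MD.adjNeu and Neu.adjMD, with true
# partial correlations as a secondary quantity. All uncertainty propagates
# through the entry-aligned block jackknife.

#' Build the genetic covariance matrix for three traits
#'
#' Aligns three summary-statistics sets (the first trait is the allele
#' reference) and the LD score table to one shared variant universe, sorts by
#' (chromosome, position), and fills all six unique entries of the 3x3
#' genetic covariance matrix from univariate / cross-trait LDSC on the
#' identical variant set and jackknife partition.
#'
#' @param ss_list named list of exactly three `sumstats` objects; the
#'   conventional order is (Y, MD, Neu).
#' @param ldscores LD score table from [read_ldscores()] (or any data.frame
#'   with `snp_id`, `ld_score`).
#' @param M variant count behind the LD scores; defaults to `attr(ldscores,
#'   "M")`.
#' @param n_blocks jackknife blocks shared by every entry.
#' @return a `genetic_covariance_fit`: `traits`, `S` (3x3), `reps`
#'   (n_blocks x 3 x 3 array, entry-aligned), `intercepts`, `n_variants`.
#' @export
build_genetic_covariance <- function(ss_list, ldscores, M = attr(ldscores, "M"),
                                     n_blocks = 200) {
  stopifnot(is.list(ss_list), length(ss_list) == 3)
  if (is.null(names(ss_list)) || any(!nzchar(names(ss_list)))) {
    names(ss_list) <- c("Y", "MD", "NEU")
  }
  traits <- names(ss_list)
  if (is.null(M)) stop("M (variant count behind the LD scores) is required")

  ref <- ss_list[[1]]
  zs <- list(setNames(ref$z, ref$snp_id))
  ns <- list(setNames(ref$n, ref$snp_id))
  common <- intersect(ref$snp_id, ldscores$snp_id)
  for (t in 2:3) {
    pa <- align_pair(ref, ss_list[[t]])
    zs[[t]] <- setNames(pa$z2, pa$snp_id)
    ns[[t]] <- setNames(pa$n2, pa$snp_id)
    common <- intersect(common, pa$snp_id)
  }
  if (length(common) < n_blocks) {
    stop("only ", length(common), " variants shared across the three traits ",
         "and the LD scores; need at least n_blocks = ", n_blocks)
  }
  # deterministic order: (chrom, bp) when the reference carries positions
  io <- match(common, ref$snp_id)
  ord <- if (!is.null(ref$chrom) && !is.null(ref$bp)) {
    order(chrom_key(ref$chrom[io]), ref$bp[io])
  } else {
    order(match(common, ldscores$snp_id))
  }
  common <- common[ord]
  l2 <- ldscores$ld_score[match(common, ldscores$snp_id)]
  Z <- vapply(zs, function(v) unname(v[common]), numeric(length(common)))
  N <- vapply(ns, function(v) unname(v[common]), numeric(length(common)))

  S <- matrix(NA_real_, 3, 3, dimnames = list(traits, traits))
  reps <- array(NA_real_, c(n_blocks, 3, 3),
                dimnames = list(NULL, traits, traits))
  intercepts <- matrix(NA_real_, 3, 3, dimnames = list(traits, traits))
  fits <- list()
  for (t in 1:3) {
    f <- univariate_ldsc(Z[, t], N[, t], l2, M, n_blocks)
    if (f$est <= 0) {
      stop("non-positive heritability estimate for trait '", traits[t],
           "' (", format(f$est), "); cannot standardise")
    }
    S[t, t] <- f$est
    reps[, t, t] <- f$reps$est
    intercepts[t, t] <- f$intercept
    fits[[paste(traits[t], traits[t], sep = ":")]] <- f
  }
  for (t in 1:2) for (u in (t + 1):3) {
    f <- cross_trait_ldsc(Z[, t], Z[, u], N[, t], N[, u], l2, M, n_blocks)
    S[t, u] <- S[u, t] <- f$est
    reps[, t, u] <- reps[, u, t] <- f$reps$est
    intercepts[t, u] <- intercepts[u, t] <- f$intercept
    fits[[paste(traits[t], traits[u], sep = ":")]] <- f
  }
  structure(
    list(traits = traits, S = S, reps = reps, intercepts = intercepts,
         n_blocks = n_blocks, n_variants = length(common), M = M,
         fits = fits),
    class = "genetic_covariance_fit"
  )
}

#' Standardised regression coefficients from a correlation matrix
#'
#' The core matrix solve: for outcome `y` and predictors `x`,
#' `b = R_xx^-1 r_xy` with residual variance `u = 1 - r_xy' b`. Refuses
#' collinear predictors (`|r_x1x2| >= 0.999`) and non-positive-definite
#' correlation matrices.
#'
#' @param R correlation matrix with dimnames.
#' @param y outcome trait name.
#' @param x predictor trait names (length 2).
#' @return list with `b` (named), `u`.
#' @export
partial_coefficients <- function(R, y, x) {
  stopifnot(length(x) == 2, all(c(y, x) %in% rownames(R)))
  if (abs(R[x[1], x[2]]) >= 0.999) {
    stop("predictors collinear: |r(", x[1], ",", x[2], ")| = ",
         format(abs(R[x[1], x[2]])))
  }
  if (min(eigen(R[c(y, x), c(y, x)], symmetric = TRUE,
                only.values = TRUE)$values) <= 1e-10) {
    stop("genetic correlation matrix is not positive definite")
  }
  r_xy <- R[x, y]
  b <- solve(R[x, x], r_xy)
  list(b = setNames(b, x), u = 1 - sum(r_xy * b))
}

#' Fit the genetic multiple regression and partial correlations
#'
#' Standardises the genetic covariance matrix to a correlation matrix,
#' solves for the standardised coefficients of `y` on the two predictors,
#' and propagates uncertainty by recomputing everything on each
#' delete-one-block jackknife replicate of S. Also reports the unadjusted
#' genetic correlations of `y` with each predictor and the classical partial
#' correlations (which rescale the standardised coefficients by residual
#' variances).
#'
#' @param S_fit a `genetic_covariance_fit`.
#' @param y outcome trait (default: first trait).
#' @param x predictor traits (default: the other two).
#' @return a `partial_regression` list: `b`, `b_se`, `b_p`, `u`, `r_xy`,
#'   `r_se`, `r_p`, `partial_r`, and `reps` (`b` and `r` replicate matrices).
#' @export
fit_partial_regression <- function(S_fit, y = S_fit$traits[1],
                                   x = setdiff(S_fit$traits, y)) {
  stopifnot(inherits(S_fit, "genetic_covariance_fit"), length(x) == 2)
  R <- stats::cov2cor(S_fit$S)
  pc <- partial_coefficients(R, y, x)
  r_xy <- setNames(R[x, y], x)
  r12 <- R[x[1], x[2]]
  partial_r <- setNames(c(
    (r_xy[1] - r_xy[2] * r12) / sqrt((1 - r_xy[2]^2) * (1 - r12^2)),
    (r_xy[2] - r_xy[1] * r12) / sqrt((1 - r_xy[1]^2) * (1 - r12^2))
  ), x)

  nb <- S_fit$n_blocks
  b_reps <- matrix(NA_real_, nb, 2, dimnames = list(NULL, x))
  r_reps <- matrix(NA_real_, nb, 2, dimnames = list(NULL, x))
  for (i in seq_len(nb)) {
    Si <- S_fit$reps[i, , ]
    dimnames(Si) <- dimnames(S_fit$S)
    if (any(diag(Si) <= 0)) {
      stop("non-positive heritability in jackknife replicate ", i,
           "; partial-correlation SEs are unstable")
    }
    Ri <- stats::cov2cor(Si)
    if (abs(Ri[x[1], x[2]]) >= 0.999) {
      stop("collinear predictors in jackknife replicate ", i)
    }
    b_reps[i, ] <- solve(Ri[x, x], Ri[x, y])
    r_reps[i, ] <- Ri[x, y]
  }
  b_se <- apply(b_reps, 2, jackknife_se)
  r_se <- apply(r_reps, 2, jackknife_se)
  wald_p <- function(est, se) ifelse(se > 0, 2 * pnorm(-abs(est) / se), NA_real_)
  structure(
    list(y = y, x = x, b = pc$b, u = pc$u, b_se = setNames(b_se, x),
         b_p = setNames(wald_p(pc$b, b_se), x),
         r_xy = r_xy, r_se = setNames(r_se, x),
         r_p = setNames(wald_p(r_xy, r_se), x),
         partial_r = partial_r,
         reps = list(b = b_reps, r = r_reps), n_blocks = nb),
    class = "partial_regression"
  )
}

#' One-sided attenuation test
#'
#' Tests whether an adjusted (partial) correlation is smaller in magnitude
#' than its unadjusted counterpart, using the jackknife SE of the paired
#' difference `|r| - |b|` and a one-sided Wald p-value for a positive
#' difference. A sign flip of the adjusted estimate counts as attenuation
#' and is flagged.
#'
#' @param r unadjusted correlation.
#' @param b adjusted (standardised) coefficient.
#' @param r_reps,b_reps aligned jackknife replicates of both.
#' @return list with `difference`, `se`, `p`, `sign_flip`.
#' @export
test_attenuation <- function(r, b, r_reps, b_reps) {
  if (length(r_reps) != length(b_reps)) {
    stop("misaligned jackknife replicates (", length(r_reps), " vs ",
         length(b_reps), ")")
  }
  d <- abs(r) - abs(b)
  d_reps <- abs(r_reps) - abs(b_reps)
  se <- jackknife_se(d_reps)
  if (se == 0) {
    if (d == 0) {
      p <- 0.5
    } else {
      warning("zero jackknife variance for a nonzero attenuation difference")
      p <- 0
    }
  } else {
    p <- pnorm(d / se, lower.tail = FALSE)
  }
  list(difference = unname(d), se = se, p = unname(p),
       sign_flip = unname(sign(r) != sign(b) & b != 0))
}

#' Benjamini-Yekutieli FDR correction
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence,
#' with the harmonic-sum factor `c(m) = sum_{i<=m} 1/i`. q-values are
#' monotone in p-rank and capped at 1.
#'
#' @param p p-values in (0, 1].
#' @param method adjustment method (passed to [stats::p.adjust()]).
#' @return q-values aligned to `p` (empty input gives empty output).
#' @export
fdr_correct <- function(p, method = "BY") {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = method)
}

#' Classify a trait's pattern of full and partial genetic correlations
#'
#' Applies the grouping rules used to summarise partial-correlation results:
#' `NEITHER` (no unadjusted correlation significant), `MD_SPECIFIC` /
#' `NEU_SPECIFIC` (only one unadjusted correlation significant),
#' `MD_ADJ_SPECIFIC` / `NEU_ADJ_SPECIFIC` (both unadjusted significant but
#' only one adjusted), downgraded to `POSSIBLE_*` when the 95% intervals of
#' the two adjusted estimates overlap, and `BOTH` otherwise.
#'
#' @param q_md,q_neu q-values for the unadjusted correlations with MD / Neu.
#' @param q_adj_md,q_adj_neu q-values for the adjusted coefficients.
#' @param adj_md,adj_neu adjusted estimates.
#' @param adj_md_se,adj_neu_se their standard errors.
#' @param alpha significance level on q-values.
#' @return a single label string.
#' @export
classify_pattern <- function(q_md, q_neu, q_adj_md, q_adj_neu,
                             adj_md, adj_md_se, adj_neu, adj_neu_se,
                             alpha = 0.05) {
  sig <- function(q) is.finite(q) && q < alpha
  if (!sig(q_md) && !sig(q_neu)) return("NEITHER")
  if (sig(q_md) && !sig(q_neu)) return("MD_SPECIFIC")
  if (!sig(q_md) && sig(q_neu)) return("NEU_SPECIFIC")
  ci_md <- adj_md + c(-1, 1) * qnorm(0.975) * adj_md_se
  ci_neu <- adj_neu + c(-1, 1) * qnorm(0.975) * adj_neu_se
  overlap <- ci_md[1] <= ci_neu[2] && ci_neu[1] <= ci_md[2]
  if (sig(q_adj_md) && !sig(q_adj_neu)) {
    return(if (overlap) "POSSIBLE_MD_ADJ_SPECIFIC" else "MD_ADJ_SPECIFIC")
  }
  if (sig(q_adj_neu) && !sig(q_adj_md)) {
    return(if (overlap) "POSSIBLE_NEU_ADJ_SPECIFIC" else "NEU_ADJ_SPECIFIC")
  }
  "BOTH"
}
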