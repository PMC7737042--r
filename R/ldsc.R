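# LD score regression (LDSC) with block-jackknife standard errors.
#
# Univariate: E[chi2_j] = 1 + a + n_j * h2 * l_j / M, so regressing chi2 on
# x_j = n_j * l_j / M gives h2 as the slope and 1 + a as the intercept.
# Cross-trait: E[z1_j z2_j] = rho_g * sqrt(n1 n2) * l_j / M + intercept,
# where the intercept absorbs sample overlap (Ns * rho_pheno / sqrt(n1 n2)).
# Weights follow the standard LDSC scheme (heteroscedasticity x LD
# over-counting), fitted in two steps: an unweighted first pass supplies the
# predicted means that enter the weights of the final weighted fit. Standard
# errors come from a delete-one-block jackknife over contiguous blocks of
# equal variant count (variants sorted by chromosome and position upstream).

jackknife_partition <- function(n, n_blocks) {
  ceiling(seq_len(n) * n_blocks / n)
}

# weighted least squares of y on (1, x) with delete-one-block jackknife;
# weights are held fixed across replicates (LDSC convention)
wls_jackknife <- function(y, x, w, blocks, n_blocks) {
  contrib <- cbind(w, w * x, w * x * x, w * y, w * x * y)
  bs <- rowsum(contrib, blocks)
  tot <- colSums(bs)
  solve2 <- function(sw, swx, swxx, swy, swxy) {
    den <- sw * swxx - swx^2
    slope <- (sw * swxy - swx * swy) / den
    intercept <- (swy - slope * swx) / sw
    cbind(slope, intercept)
  }
  full <- solve2(tot[1], tot[2], tot[3], tot[4], tot[5])
  del <- sweep(-bs, 2, tot, "+")
  reps <- solve2(del[, 1], del[, 2], del[, 3], del[, 4], del[, 5])
  list(
    slope = full[1, 1], intercept = full[1, 2],
    slope_se = jackknife_se(reps[, 1]),
    intercept_se = jackknife_se(reps[, 2]),
    reps = data.frame(slope = reps[, 1], intercept = reps[, 2])
  )
}

ols_fit <- function(y, x) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  den <- n * sum(x * x) - sx^2
  slope <- (n * sum(x * y) - sx * sy) / den
  c(intercept = (sy - slope * sx) / n, slope = slope)
}

# predicted per-variant mean used inside the LDSC weights; the slope is
# clamped to a correlation-scale range and the prediction floored away from 0
ldsc_weight_pred <- function(intercept, slope, x) {
  pmax(intercept + pmin(pmax(slope, -1), 1) * x, 0.1)
}

new_ldsc_fit <- function(est, intercept, est_se, intercept_se, reps,
                         n_blocks, n_variants, M, type) {
  structure(
    list(est = est, intercept = intercept, est_se = est_se,
         intercept_se = intercept_se, reps = reps, n_blocks = n_blocks,
         n_variants = n_variants, M = M, type = type),
    class = "ldsc_fit"
  )
}

#' Univariate LD score regression
#'
#' Estimates the SNP heritability `h2` by regressing `chi2 = z^2` on LD
#' scores under `E[chi2_j] = 1 + a + n_j h2 l_j / M`, with two-step LDSC
#' weights and a delete-one-block jackknife for standard errors. Variants
#' must already be ordered by (chromosome, position); jackknife blocks are
#' contiguous with equal variant counts.
#'
#' @param z signed z-scores.
#' @param n per-variant sample sizes (scalar or vector).
#' @param ldscores per-variant LD scores aligned to `z`.
#' @param M number of variants the LD scores sum over.
#' @param n_blocks number of jackknife blocks.
#' @return an `ldsc_fit` with `est` (= h2), `intercept`, their SEs and the
#'   per-replicate estimates.
#' @export
univariate_ldsc <- function(z, n, ldscores, M, n_blocks = 200) {
  k <- length(z)
  if (k < n_blocks) {
    stop("fewer variants (", k, ") than jackknife blocks (", n_blocks, ")")
  }
  stopifnot(length(ldscores) == k, M > 0)
  if (length(n) == 1) n <- rep(n, k)
  chi2 <- z^2
  x <- n * ldscores / M
  f0 <- ols_fit(chi2, x)
  pred <- ldsc_weight_pred(f0["intercept"], f0["slope"], x)
  w <- 1 / (pmax(ldscores, 1) * 2 * pred^2)
  blocks <- jackknife_partition(k, n_blocks)
  fit <- wls_jackknife(chi2, x, w, blocks, n_blocks)
  new_ldsc_fit(fit$slope, fit$intercept, fit$slope_se, fit$intercept_se,
               setNames(fit$reps, c("est", "intercept")), n_blocks, k, M,
               "h2")
}

#' Cross-trait LD score regression
#'
#' Estimates the genetic covariance `rho_g` by regressing `z1 * z2` on LD
#' scores under `E[z1_j z2_j] = rho_g sqrt(n1 n2) l_j / M + intercept`; the
#' intercept absorbs sample overlap. Weights combine each trait's predicted
#' chi2 mean (from its own unweighted first pass) with the predicted
#' cross-product, so that `z2 == z1` reproduces the univariate fit exactly.
#'
#' @param z1,z2 z-scores on the shared, identically ordered variant set.
#' @param n1,n2 per-variant sample sizes.
#' @inheritParams univariate_ldsc
#' @return an `ldsc_fit` with `est` (= rho_g) and `intercept`.
#' @export
cross_trait_ldsc <- function(z1, z2, n1, n2, ldscores, M, n_blocks = 200) {
  k <- length(z1)
  if (k < n_blocks) {
    stop("fewer variants (", k, ") than jackknife blocks (", n_blocks, ")")
  }
  stopifnot(length(z2) == k, length(ldscores) == k, M > 0)
  if (length(n1) == 1) n1 <- rep(n1, k)
  if (length(n2) == 1) n2 <- rep(n2, k)
  y <- z1 * z2
  x <- sqrt(n1 * n2) * ldscores / M
  x1 <- n1 * ldscores / M
  x2 <- n2 * ldscores / M
  f1 <- ols_fit(z1^2, x1)
  f2 <- ols_fit(z2^2, x2)
  fc <- ols_fit(y, x)
  pred1 <- ldsc_weight_pred(f1["intercept"], f1["slope"], x1)
  pred2 <- ldsc_weight_pred(f2["intercept"], f2["slope"], x2)
  predc <- ldsc_weight_pred(fc["intercept"], fc["slope"], x)
  w <- 1 / (pmax(ldscores, 1) * (pred1 * pred2 + predc^2))
  blocks <- jackknife_partition(k, n_blocks)
  fit <- wls_jackknife(y, x, w, blocks, n_blocks)
  new_ldsc_fit(fit$slope, fit$intercept, fit$slope_se, fit$intercept_se,
               setNames(fit$reps, c("est", "intercept")), n_blocks, k, M,
               "gcov")
}

#' Genetic correlation from three LDSC fits
#'
#' `rg = rho_g / sqrt(h2_1 * h2_2)`, with the standard error obtained by
#' recomputing the full ratio on each aligned delete-one-block jackknife
#' replicate, and a two-sided Wald p-value.
#'
#' @param fit11,fit22 univariate `ldsc_fit`s for the two traits.
#' @param fit12 cross-trait `ldsc_fit`.
#' @return an `rg_estimate` list: `rg`, `se`, `p`, `reps`, `fits`.
#' @export
genetic_correlation <- function(fit11, fit22, fit12) {
  stopifnot(inherits(fit11, "ldsc_fit"), inherits(fit22, "ldsc_fit"),
            inherits(fit12, "ldsc_fit"))
  if (fit11$est <= 0 || fit22$est <= 0) {
    stop("non-positive heritability estimate; genetic correlation is ",
         "unreliable (h2_1 = ", format(fit11$est), ", h2_2 = ",
         format(fit22$est), ")")
  }
  if (fit11$n_blocks != fit12$n_blocks || fit22$n_blocks != fit12$n_blocks) {
    stop("jackknife partitions of the three fits are not aligned")
  }
  rg <- fit12$est / sqrt(fit11$est * fit22$est)
  h1r <- fit11$reps$est
  h2r <- fit22$reps$est
  if (any(h1r <= 0) || any(h2r <= 0)) {
    stop("non-positive heritability in a jackknife replicate; ",
         "genetic correlation SE is unstable")
  }
  reps <- fit12$reps$est / sqrt(h1r * h2r)
  se <- jackknife_se(reps)
  p <- if (se > 0) 2 * pnorm(-abs(rg) / se) else NA_real_
  structure(
    list(rg = rg, se = se, p = p, reps = reps,
         fits = list(fit11 = fit11, fit22 = fit22, fit12 = fit12)),
    class = "rg_estimate"
  )
}

#' Read a two-column LD score table
#'
#' Tab-delimited file with header columns `SNP` and `L2` (or `snp_id` /
#' `ld_score`). The variant count `M` is read from a one-number sidecar file
#' `<path>.M` when present, else must be supplied downstream.
#'
#' @param path path to the LD score table.
#' @return data.frame with `snp_id`, `ld_score` and attribute `M` (or `NULL`).
#' @export
read_ldscores <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  isnp <- match(TRUE, nm %in% c("snp", "snp_id"))
  il2 <- match(TRUE, nm %in% c("l2", "ld_score", "ldscore"))
  if (is.na(isnp) || is.na(il2)) {
    stop("LD score table '", path, "' needs SNP and L2 columns")
  }
  out <- data.frame(snp_id = as.character(df[[isnp]]),
                    ld_score = as.numeric(df[[il2]]),
                    stringsAsFactors = FALSE)
  mfile <- paste0(path, ".M")
  if (file.exists(mfile)) {
    attr(out, "M") <- as.numeric(readLines(mfile)[1])
  }
  out
}

#' Write an LD score table (with its M sidecar)
#' @param x data.frame with `snp_id`, `ld_score`.
#' @param path output path; `M` is written to `<path>.M`.
#' @param M variant count the scores sum over (default: attribute of `x`).
#' @export
write_ldscores <- function(x, path, M = attr(x, "M")) {
  utils::write.table(
    data.frame(SNP = x$snp_id, L2 = x$ld_score),
    path, quote = FALSE, sep = "\t", row.names = FALSE
  )
  if (!is.null(M)) writeLines(format(M, scientific = FALSE), paste0(path, ".M"))
  invisible(path)
}

#' @export
print.ldsc_fit <- function(x, ...) {
  lab <- if (x$type == "h2") "h2" else "genetic covariance"
  cat("LD score regression (", x$n_variants, " variants, ", x$n_blocks,
      " jackknife blocks)\n", sep = "")
  cat(sprintf("  %s: %.4f (SE %.4f)\n", lab, x$est, x$est_se))
  cat(sprintf("  intercept: %.4f (SE %.4f)\n", x$intercept, x$intercept_se))
  invisible(x)
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("genetic correlation: %.4f (SE %.4f, p = %.3g)\n",
              x$rg, x$se, x$p))
  invisible(x)
}
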