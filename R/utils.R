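# Numeric helpers shared across modules. All Bayes-factor arithmetic is done
# in log space; these primitives keep that honest.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) logsumexp(x) - log(length(x))

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows
log_diff_exp <- function(a, b) {
  if (!is.finite(a) || b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Row-wise logsumexp / log-mean-exp over the columns of a matrix
row_logsumexp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- mx[!is.finite(mx)]
  out
}

row_log_mean_exp <- function(m) row_logsumexp(m) - log(ncol(m))

# Delete-one-block jackknife standard error from replicate estimates
jackknife_se <- function(reps) {
  nb <- length(reps)
  sqrt((nb - 1) / nb * sum((reps - mean(reps))^2))
}

# Chromosome labels as sortable integers ("1".."22", tolerating "chr" prefixes)
chrom_key <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  suppressWarnings(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
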