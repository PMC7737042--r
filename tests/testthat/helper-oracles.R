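# Independent oracles used by the test suite. These deliberately avoid the
# package's computational paths: numerical integration instead of the closed
# form, plain-space enumeration instead of log-sum-exp recursions, explicit
# step-up instead of p.adjust, grid search instead of quasi-Newton.

# ABF by numerical integration of the marginal likelihood ratio:
# int N(bhat; b, v) N(b; 0, W) db / N(bhat; 0, v)
oracle_abf_numeric <- function(z, v, W) {
  bhat <- z * sqrt(v)
  marg <- stats::integrate(
    function(b) dnorm(bhat, b, sqrt(v)) * dnorm(b, 0, sqrt(W)),
    -Inf, Inf, rel.tol = 1e-10, abs.tol = 0
  )$value
  marg / dnorm(bhat, 0, sqrt(v))
}

# regional Bayes factors by exhaustive enumeration over causal
# configurations, in plain (non-log) space; ev is the snp_evidence matrix
oracle_regional_brute <- function(ev) {
  bf1 <- exp(ev[, 1]); bf2 <- exp(ev[, 2]); bf3 <- exp(ev[, 3])
  k <- length(bf1)
  rbf4 <- 0
  if (k > 1) {
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j) rbf4 <- rbf4 + bf1[i] * bf2[j]
    }
    rbf4 <- rbf4 / (k * (k - 1))
  }
  c(rbf1 = mean(bf1), rbf2 = mean(bf2), rbf3 = mean(bf3), rbf4 = rbf4)
}

# Benjamini-Yekutieli step-up, brute force over all thresholds
oracle_by <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  raw <- m * cm * p[o] / seq_len(m)
  q <- rev(cummin(rev(raw)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# enumerate all compositions of `total` into `parts` nonnegative integers
compositions <- function(total, parts) {
  if (parts == 1) return(matrix(total, ncol = 1))
  out <- lapply(0:total, function(i) {
    cbind(i, compositions(total - i, parts - 1))
  })
  do.call(rbind, out)
}

# grid search over the probability simplex for the prior MLE; two stages
# (coarse step 0.02 over the whole simplex, then step 0.01 in a +/-0.05 box
# around the coarse optimum, offsets summing to zero to stay on the simplex)
oracle_prior_grid <- function(lrbf) {
  B <- exp(cbind(0, lrbf))
  score <- function(P) rowSums(log(pmax(P %*% t(B), 1e-300)))
  m <- ncol(B)
  coarse <- compositions(50, m) / 50
  best <- coarse[which.max(score(coarse)), ]
  d <- as.matrix(expand.grid(rep(list(-5:5), m - 1)))
  d <- cbind(d, -rowSums(d))
  fine <- sweep(d / 100, 2, best, "+")
  fine <- fine[apply(fine, 1, min) >= 0, , drop = FALSE]
  unname(fine[which.max(score(fine)), ])
}

# small toy sumstats file on disk; returns the path
write_toy_sumstats <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  path
}

toy_sumstats_df <- function(n = 5, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  data.frame(
    SNP = paste0("rs", seq_len(n)), CHR = "1", BP = seq_len(n) * 1000L,
    A1 = "A", A2 = "G", Z = z, P = 2 * pnorm(-abs(z)), N = 10000,
    stringsAsFactors = FALSE
  )
}
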