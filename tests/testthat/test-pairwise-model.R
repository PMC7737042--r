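test_that("wakefield_abf matches its analytic fixed points", {
  # z = 0, v = W: r = 1/2, ABF = sqrt(1/2)
  expect_equal(wakefield_abf(0, 0.1, 0.1), sqrt(0.5), tolerance = 1e-12)
  # vanishing prior variance: no evidence either way
  expect_equal(wakefield_abf(3, 0.01, 1e-12), 1, tolerance = 1e-6)
  # strong-signal value, cross-checked against numerical integration below
  expect_equal(wakefield_abf(5, 0.01, 0.1), 2.597e4, tolerance = 1e-3)
  expect_equal(wakefield_abf(5, 0.01, 0.1),
               oracle_abf_numeric(5, 0.01, 0.1), tolerance = 1e-8)
  expect_error(wakefield_abf(NaN, 0.01, 0.1), "non-finite")
  # log-space agrees with naive space where the latter is finite
  z <- seq(-6, 6, by = 0.5)
  expect_equal(wakefield_abf(z, 0.01, 0.5, log = TRUE),
               log(wakefield_abf(z, 0.01, 0.5)), tolerance = 1e-12)
})

test_that("bivariate shared-model ABF factorises at C = 0 and matches a density oracle", {
  z1 <- c(0, 1.5, -3); z2 <- c(2, -0.5, 3)
  v1 <- rep(1e-4, 3); v2 <- rep(2e-4, 3)
  for (w in c(0.01, 0.1, 0.5)) {
    p0 <- abf_params(W_grid = w, C = 0)
    expect_equal(
      bivariate_abf(z1, z2, v1, v2, p0, 3, log = TRUE),
      wakefield_abf(z1, v1, w, log = TRUE) +
        wakefield_abf(z2, v2, w, log = TRUE),
      tolerance = 1e-10
    )
    expect_equal(bivariate_abf(z1, z2, v1, v2, p0, 1, log = TRUE),
                 wakefield_abf(z1, v1, w, log = TRUE), tolerance = 1e-10)
  }

  # z1 = z2 = 0 with a vanishing prior: identical densities, BF -> 1
  expect_equal(bivariate_abf(0, 0, 0.01, 0.01, abf_params(1e-14, 0.3), 3), 1,
               tolerance = 1e-6)

  # pinned regression constant, recomputed from two explicit 2x2 densities
  dens2 <- function(z, S) {
    exp(-log(2 * pi) - 0.5 * log(det(S)) -
          0.5 * drop(t(z) %*% solve(S) %*% z))
  }
  S0 <- matrix(c(1, 0.5, 0.5, 1), 2)
  S1 <- matrix(c(1 + 0.1 / 0.01, 0.5, 0.5, 1 + 0.1 / 0.01), 2)
  oracle <- dens2(c(3, 3), S1) / dens2(c(3, 3), S0)
  got <- bivariate_abf(3, 3, 0.01, 0.01, abf_params(0.1, 0.5), 3)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(got, 14.536883681372, tolerance = 1e-10)
})

test_that("regional Bayes factors follow the enumeration formulae", {
  # hand-enumerated k = 2 example
  ev <- cbind(log(c(4, 1)), log(c(2, 1)), log(c(8, 1)))
  rbf <- exp(regional_bfs(ev))
  expect_equal(unname(rbf), c(2.5, 1.5, 4.5, 3.0), tolerance = 1e-12)

  # k = 1: no two distinct SNPs, rbf4 = 0
  one <- regional_bfs(cbind(log(4), log(2), log(8)))
  expect_equal(unname(exp(one["rbf4"])), 0)

  # null data: every BF 1
  flat <- exp(regional_bfs(matrix(0, 3, 3)))
  expect_equal(unname(flat), c(1, 1, 1, 1), tolerance = 1e-12)

  expect_error(regional_bfs(matrix(numeric(0), 0, 3)), "no SNPs")
})

test_that("regional Bayes factors match brute-force enumeration for k <= 6", {
  set.seed(202)
  p <- abf_params(C = 0.3)
  for (k in 2:6) {
    z1 <- rnorm(k, 0, 2); z2 <- rnorm(k, 0, 2)
    ev <- snp_evidence(z1, z2, rep(1e-4, k), rep(1e-4, k), p)
    expect_equal(unname(exp(regional_bfs(ev))),
                 unname(oracle_regional_brute(ev)),
                 tolerance = 1e-10)
  }
})

test_that("prior estimation matches a simplex grid-search oracle and flags flat likelihoods", {
  lrbf3 <- log(rbind(c(50, 1, 1, 1), c(1, 1, 40, 2), c(0.1, 0.1, 0.1, 0.1)))
  # replicate the three segments to meet the minimum segment count; the MLE
  # is unchanged by replication
  fit <- estimate_priors(lrbf3[rep(1:3, 7), ])
  oracle <- oracle_prior_grid(lrbf3)
  expect_lt(max(abs(fit$pi - oracle)), 0.02)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
  expect_false(fit$non_identified)

  flat <- estimate_priors(matrix(0, 25, 4))
  expect_true(flat$non_identified)
  expect_true(all(flat$pi >= 0))
  expect_equal(sum(flat$pi), 1, tolerance = 1e-10)

  expect_error(estimate_priors(matrix(0, 5, 4)), "at least 20")
})

test_that("segment posteriors follow Bayes' rule and sum to one", {
  # pi uniform, rbf = (2, 1, 5, 2): denominator 2.2
  ppa <- segment_posteriors(log(c(2, 1, 5, 2)), rep(0.2, 5))
  expect_equal(unname(drop(ppa)),
               c(0.2, 0.4, 0.2, 1.0, 0.4) / 2.2, tolerance = 1e-12)
  # rbf all 1: posterior equals prior
  pi <- c(0.4, 0.1, 0.2, 0.2, 0.1)
  expect_equal(unname(drop(segment_posteriors(rep(0, 4), pi))), pi,
               tolerance = 1e-12)
  # rbf3 -> infinity: ppa3 -> 1
  expect_equal(unname(segment_posteriors(c(0, 0, 700, 0), rep(0.2, 5))[, 4]),
               1, tolerance = 1e-12)
  # property: rows sum to 1 for random valid inputs
  set.seed(5)
  for (i in 1:20) {
    pi <- runif(5); pi <- pi / sum(pi)
    lrbf <- matrix(rnorm(40, 0, 5), 10, 4)
    expect_equal(unname(rowSums(segment_posteriors(lrbf, pi))), rep(1, 10),
                 tolerance = 1e-12)
  }
})

test_that("two-model posterior reduces to the closed form", {
  # pi1 = 0.1, rbf = 9: PPA = 0.9 / (0.9 + 0.9) = 0.5
  expect_equal(unname(segment_posteriors(matrix(log(9), 1, 1),
                                         c(0.9, 0.1))[, 2]), 0.5,
               tolerance = 1e-12)
  # rbf = 1: PPA = pi1
  expect_equal(unname(segment_posteriors(matrix(0, 1, 1),
                                         c(0.9, 0.1))[, 2]), 0.1,
               tolerance = 1e-12)
})

test_that("single-trait segment posteriors are calibrated on null data", {
  set.seed(31)
  n_seg <- 200; k <- 25
  z <- rnorm(n_seg * k)
  seg <- rep(seq_len(n_seg), each = k)
  st <- single_trait_segment_ppa(z, rep(1e-4, n_seg * k), seg)
  expect_length(st$ppa, n_seg)
  # on pure noise the association prior collapses and few segments pass 0.2
  expect_lt(mean(st$ppa >= 0.2), 0.05)
  expect_equal(mean(st$ppa), unname(st$priors$pi[2]), tolerance = 0.05)
})

test_that("the null z-score correlation is computed over doubly-null segments", {
  paired <- data.frame(z1 = rnorm(100), stringsAsFactors = FALSE)
  paired$z2 <- paired$z1
  seg <- rep(1:10, each = 10)
  ppa <- setNames(rep(0.05, 10), 1:10)
  est <- estimate_null_correlation(paired, seg, ppa, ppa)
  expect_equal(est$C, 1)
  expect_equal(est$n_variants, 100L)
  hot <- setNames(rep(0.9, 10), 1:10)
  expect_error(estimate_null_correlation(paired, seg, hot, ppa),
               "cannot estimate")
})

test_that("segment classification applies the precedence rules", {
  # trait-1-only model wins with a GWS hit for trait 1 only
  expect_equal(classify_segments(c(0.05, 0.80, 0.05, 0.05, 0.05),
                                 TRUE, FALSE), "TRAIT1_ONLY")
  # same posteriors without the GWS pattern: unclassified
  expect_equal(classify_segments(c(0.05, 0.80, 0.05, 0.05, 0.05),
                                 FALSE, FALSE), "UNCLASSIFIED")
  # low total association and no hits: NEITHER
  expect_equal(classify_segments(c(0.90, 0.025, 0.025, 0.025, 0.025),
                                 FALSE, FALSE), "NEITHER")
  # shared model wins regardless of single-trait GWS flags
  expect_equal(classify_segments(c(0.10, 0.05, 0.05, 0.60, 0.20),
                                 TRUE, FALSE), "BOTH")
  expect_equal(classify_segments(c(0.10, 0.05, 0.05, 0.20, 0.60),
                                 TRUE, TRUE), "SEPARATE")
  # exact tie between causal models: never fabricate a winner
  expect_equal(classify_segments(c(0.2, 0.3, 0.3, 0.1, 0.1), TRUE, FALSE),
               "UNCLASSIFIED")
  # NEITHER takes precedence over the argmax rules
  expect_equal(classify_segments(c(0.85, 0.09, 0.02, 0.02, 0.02),
                                 FALSE, FALSE), "NEITHER")
})

test_that("a trait's total association posterior is monotone in its z-scores", {
  # holds for independent studies (C = 0); with overlap the null density
  # itself moves with z, so no per-SNP monotonicity is guaranteed
  set.seed(77)
  pi <- c(0.6, 0.1, 0.1, 0.1, 0.1)
  for (C in 0) {
    p <- abf_params(C = C)
    for (rep in 1:5) {
      k <- 5
      z1 <- rnorm(k, 0, 2); z2 <- rnorm(k, 0, 2)
      v <- rep(1e-4, k)
      assoc1 <- vapply(seq(0, 4, by = 0.5), function(bump) {
        zz <- z1
        zz[1] <- zz[1] + sign(zz[1] + (zz[1] == 0)) * bump
        ev <- snp_evidence(zz, z2, v, v, p)
        ppa <- segment_posteriors(rbind(regional_bfs(ev))[1, ], pi)
        sum(ppa[, c(2, 4, 5)])
      }, numeric(1))
      expect_true(all(diff(assoc1) >= -1e-10))
    }
  }
})
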