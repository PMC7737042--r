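r3 <- function(r12, ry1, ry2, traits = c("Y", "MD", "NEU")) {
  R <- matrix(c(1, ry1, ry2, ry1, 1, r12, ry2, r12, 1), 3, 3,
              dimnames = list(traits, traits))
  R
}

test_that("the standardised-coefficient solve matches its algebraic fixed points", {
  # the worked decomposition case: r(MD,NEU)=0.68, r(Y,MD)=0.5, r(Y,NEU)=0.34
  pc <- partial_coefficients(r3(0.68, 0.5, 0.34), "Y", c("MD", "NEU"))
  expect_equal(unname(pc$b), c(0.5, 0), tolerance = 1e-12)
  # orthogonal predictors: coefficients equal the marginal correlations
  pc0 <- partial_coefficients(r3(0, 0.4, -0.2), "Y", c("MD", "NEU"))
  expect_equal(unname(pc0$b), c(0.4, -0.2), tolerance = 1e-12)
  # no outcome correlation: zero coefficients, unit residual variance
  pcn <- partial_coefficients(r3(0.5, 0, 0), "Y", c("MD", "NEU"))
  expect_equal(unname(pcn$b), c(0, 0))
  expect_equal(pcn$u, 1)
  # error modes
  expect_error(partial_coefficients(r3(0.9995, 0.3, 0.3), "Y", c("MD", "NEU")),
               "collinear")
  expect_error(partial_coefficients(r3(0.2, 0.9, -0.9), "Y", c("MD", "NEU")),
               "positive definite")
})

test_that("standardised coefficients are bounded on random PD correlation matrices", {
  set.seed(15)
  tries <- 0
  while (tries < 50) {
    r12 <- runif(1, -0.9, 0.9); ry1 <- runif(1, -0.9, 0.9)
    ry2 <- runif(1, -0.9, 0.9)
    R <- r3(r12, ry1, ry2)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-6) next
    tries <- tries + 1
    pc <- partial_coefficients(R, "Y", c("MD", "NEU"))
    bound <- (1 + abs(r12)) / (1 - r12^2) * max(abs(c(ry1, ry2)))
    expect_lte(max(abs(pc$b)), bound + 1e-12)
    # variance decomposition holds by construction
    expect_equal(sum(R[c("MD", "NEU"), "Y"] * pc$b) + pc$u, 1,
                 tolerance = 1e-8)
  }
})

test_that("the matrix solve agrees with a Monte-Carlo regression oracle", {
  set.seed(16)
  R <- r3(0.68, 0.5, 0.34)
  X <- matrix(rnorm(3 * 2e5), ncol = 3) %*% chol(R)
  fit <- stats::lm.fit(cbind(1, X[, 2:3]), X[, 1])
  pc <- partial_coefficients(R, "Y", c("MD", "NEU"))
  expect_equal(unname(pc$b), unname(fit$coefficients[2:3]), tolerance = 0.01)
})

test_that("the genetic covariance matrix recovers a known three-trait structure", {
  sim <- simulate_tritrait(tri_sim_config(seed = 19))
  ss <- lapply(sim$sumstats, pairgwas:::as_sumstats)
  S_fit <- build_genetic_covariance(ss, sim$ldscores, n_blocks = 200)
  S_true <- diag(sqrt(sim$truth$h2)) %*% sim$truth$rg %*%
    diag(sqrt(sim$truth$h2))
  for (t in 1:3) for (u in t:3) {
    se <- pairgwas:::jackknife_se(S_fit$reps[, t, u])
    expect_lt(abs(S_fit$S[t, u] - S_true[t, u]), 2.5 * se)
  }
  # degenerate duplicate trait refuses downstream
  ss_dup <- ss
  ss_dup[["Y"]] <- ss[["MD"]]
  S_dup <- build_genetic_covariance(ss_dup, sim$ldscores, n_blocks = 100)
  expect_error(fit_partial_regression(S_dup, y = "Y", x = c("MD", "NEU")),
               "positive definite|collinear")
})

test_that("fit_partial_regression propagates jackknife uncertainty coherently", {
  sim <- simulate_tritrait(tri_sim_config(m_snps = 10000, seed = 23))
  ss <- lapply(sim$sumstats, pairgwas:::as_sumstats)
  S_fit <- build_genetic_covariance(ss, sim$ldscores, n_blocks = 100)
  reg <- fit_partial_regression(S_fit)
  expect_equal(sum(reg$b * reg$r_xy) + reg$u, 1, tolerance = 1e-8)
  expect_equal(unname(reg$b_p < 1), c(TRUE, TRUE))
  expect_identical(dim(reg$reps$b), c(100L, 2L))
  # truth: b = (0.5, 0)
  expect_lt(abs(reg$b["MD"] - 0.5), 3 * reg$b_se["MD"])
  expect_lt(abs(reg$b["NEU"] - 0), 3 * reg$b_se["NEU"])
})

test_that("the attenuation test handles identical, degenerate and misaligned inputs", {
  reps <- rnorm(50, 0.4, 0.01)
  same <- test_attenuation(0.4, 0.4, reps, reps)
  expect_equal(same$difference, 0)
  expect_equal(same$p, 0.5)
  # constant nonzero difference: SE 0, p -> 0 with a warning
  expect_warning(
    deg <- test_attenuation(0.5, 0.3, rep(0.5, 50), rep(0.3, 50)),
    "zero jackknife variance"
  )
  expect_equal(deg$p, 0)
  expect_error(test_attenuation(0.5, 0.3, rnorm(50), rnorm(49)), "misaligned")
  # a sign flip counts as attenuation and is flagged
  flip <- test_attenuation(0.4, -0.1, rnorm(50, 0.4, 0.05),
                           rnorm(50, -0.1, 0.05))
  expect_true(flip$sign_flip)
  expect_gt(flip$difference, 0)
})

test_that("Benjamini-Yekutieli q-values follow the step-up definition", {
  # hand-computed: c(3) = 11/6
  expect_equal(fdr_correct(c(0.01, 0.02, 0.5)),
               c(0.055, 0.055, 11 / 12), tolerance = 1e-12)
  expect_equal(fdr_correct(0.03), 0.03) # c(1) = 1
  expect_identical(fdr_correct(numeric(0)), numeric(0))
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(1:15, 1))
    q_by <- fdr_correct(p)
    expect_true(all(q_by >= p - 1e-15))
    expect_true(all(p.adjust(p, "BH") <= q_by + 1e-15))
    expect_equal(q_by, oracle_by(p), tolerance = 1e-12)
  }
})

test_that("pattern labels follow the grouping rules", {
  expect_equal(classify_pattern(0.01, 0.6, 0.5, 0.5, 0.3, 0.1, 0.1, 0.1),
               "MD_SPECIFIC")
  expect_equal(classify_pattern(0.6, 0.01, 0.5, 0.5, 0.3, 0.1, 0.1, 0.1),
               "NEU_SPECIFIC")
  expect_equal(classify_pattern(0.9, 0.9, 0.9, 0.9, 0, 0.1, 0, 0.1),
               "NEITHER")
  # both unadjusted significant; adjusted MD only, intervals apart
  expect_equal(classify_pattern(0.01, 0.01, 0.01, 0.8,
                                0.5, 0.05, 0.0, 0.05),
               "MD_ADJ_SPECIFIC")
  # same but overlapping adjusted intervals
  expect_equal(classify_pattern(0.01, 0.01, 0.01, 0.8,
                                0.5, 0.3, 0.0, 0.3),
               "POSSIBLE_MD_ADJ_SPECIFIC")
  expect_equal(classify_pattern(0.01, 0.01, 0.8, 0.01,
                                0.0, 0.05, 0.5, 0.05),
               "NEU_ADJ_SPECIFIC")
  expect_equal(classify_pattern(0.01, 0.01, 0.01, 0.01,
                                0.4, 0.05, 0.4, 0.05),
               "BOTH")
})
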