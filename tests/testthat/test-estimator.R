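# Posterior-simulation machinery checked against closed forms on hand-built
# posteriors with fixed parameters.

test_that("independent disorders reproduce the product formula", {
  p <- c(0.015, 0.020, 0.025, 0.035, 0.040, 0.060)
  fit <- make_fixed_fit(qnorm(p), rep(0, 6), diag(6), diag(6))
  s <- category_prevalence(fit, 1, n_inner = 20000, seed = 5)
  expect_lt(abs(s$median - (1 - prod(1 - p))), 0.005)
  expect_lt(abs(s$median - enum_at_least_k(p, 1)), 0.005)
  # k = 2 against the 2^D enumeration oracle
  s2 <- category_prevalence(fit, 2, n_inner = 50000, seed = 5)
  expect_lt(abs(s2$median - enum_at_least_k(p, 2)), 0.002)
  # random prevalence vectors
  set.seed(8)
  for (r in 1:3) {
    pr <- runif(4, 0.02, 0.3)
    fr <- make_fixed_fit(qnorm(pr), rep(0, 4), diag(4), diag(4))
    sr <- category_prevalence(fr, 1, n_inner = 20000, seed = r)
    expect_lt(abs(sr$median - (1 - prod(1 - pr))), 0.01)
  }
})

test_that("comonotone disorders collapse the category to one disorder", {
  ones <- matrix(1, 3, 3)
  ones[ones == 1] <- 0.999; diag(ones) <- 1   # numerically PD stand-in for 1
  fit <- make_fixed_fit(qnorm(rep(0.05, 3)), rep(0, 3), diag(3), ones)
  s <- category_prevalence(fit, 1, n_inner = 20000, seed = 2)
  expect_lt(abs(s$median - 0.05), 0.01)
  coh <- simulate_cohort(fit, 4000, seed = 3)
  agree <- mean(coh$diagnoses[, 1] == coh$diagnoses[, 2])
  expect_gt(agree, 0.99)
})

test_that("at-least-k estimates are monotone in k for every draw", {
  set.seed(14)
  oC <- rand_corr(5)
  fit <- make_fixed_fit(qnorm(runif(5, 0.05, 0.3)), runif(5, 0, 0.3),
                        rand_corr(5), oC, n_draws = 100)
  pis <- anyprev:::category_pi(fit, n_inner = 2000, shared = FALSE)
  expect_true(all(diff(t(pis)) <= 0))        # within every draw
})

test_that("cohort column means match the heterogeneity-mixture marginal", {
  theta <- qnorm(c(0.03, 0.10))
  tau <- c(0.5, 0.2)
  fit <- make_fixed_fit(theta, tau, diag(2), diag(2))
  coh <- simulate_cohort(fit, 2e5, seed = 21)
  # E[Phi(theta + tau Z)] by Gauss-Hermite-style quadrature
  marg <- sapply(1:2, function(d) {
    z <- seq(-6, 6, length.out = 4001)
    sum(pnorm(theta[d] + tau[d] * z) * dnorm(z)) * (z[2] - z[1])
  })
  expect_lt(max(abs(unname(colMeans(coh$diagnoses)) - marg)), 0.01)
})

test_that("prediction intervals are at least as wide as HDIs", {
  set.seed(33)
  # a posterior with real spread: draws differ
  M <- 300
  fit <- make_fixed_fit(qnorm(c(0.04, 0.08, 0.12)), c(0.4, 0.3, 0.2),
                        exch <- {m <- matrix(0.3, 3, 3); diag(m) <- 1; m},
                        diag(3), n_draws = M)
  fit$theta <- fit$theta + matrix(rnorm(M * 3, 0, 0.1), M, 3)
  s <- category_prevalence(fit, 1, n_inner = 2000, seed = 9)
  expect_gte(s$pi_high - s$pi_low, s$hdi_high - s$hdi_low)
  expect_true(s$hdi_low <= s$median && s$median <= s$hdi_high)
})

test_that("conditional probabilities match independence and orthant oracles", {
  # independence: conditional equals the target's marginal
  fit <- make_fixed_fit(qnorm(c(0.10, 0.06)), c(0, 0), diag(2), diag(2))
  s <- conditional_probability(fit, "d1", "d2", n_inner = 40000, seed = 3)
  expect_lt(abs(s$median - 0.06), 0.01)
  # perfect comorbidity: conditional is 1
  oC <- matrix(c(1, 0.999, 0.999, 1), 2)
  fit2 <- make_fixed_fit(qnorm(c(0.07, 0.07)), c(0, 0), diag(2), oC)
  s2 <- conditional_probability(fit2, "d1", "d2", n_inner = 20000, seed = 4)
  expect_gt(s2$median, 0.95)
  # rho = 0.5 at 3%/3% against numeric orthant integration
  oC3 <- matrix(c(1, 0.5, 0.5, 1), 2)
  fit3 <- make_fixed_fit(qnorm(c(0.03, 0.03)), c(0, 0), diag(2), oC3)
  s3 <- conditional_probability(fit3, "d1", "d2", n_inner = 3e5, seed = 5)
  oracle <- anyprev:::bvn_orthant(qnorm(0.97), qnorm(0.97), 0.5) / 0.03
  expect_lt(abs(s3$median - oracle), 0.01)
  expect_error(conditional_probability(fit3, character(0), "d2", seed = 1),
               "empty|unknown")
  expect_error(conditional_probability(fit3, "d1", "d1", seed = 1),
               "conditioning set")
})

test_that("per-study predictions track the observed data", {
  cfg <- preset_config("sim1")
  dat <- generate_meta_analysis(cfg, 44)
  fit <- suppressWarnings(
    fit_model1(dat, cfg$omega_C, config = sampler_config(2, 600, 300, seed = 4,
                                                         thin = 3)))
  pred <- per_study_predictions(fit, dat, mode = "per-disorder", seed = 2,
                                n_draws = 200)
  expect_equal(nrow(pred), 20 * 6)
  obs <- pred[!is.na(pred$observed), ]
  inside <- mean(obs$observed >= obs$hdi_low - 1e-9 &
                 obs$observed <= obs$hdi_high + 1e-9)
  expect_gt(inside, 0.8)    # predictive bands capture most observed values
  # a sample measuring one disorder: any-measured equals that disorder
  panel <- fit$panel
  one <- dat$samples[rowSums(!is.na(dat$samples[, unclass(panel)])) == 1, ]
  if (nrow(one)) {
    pa <- per_study_predictions(fit, dat, mode = "any-measured", seed = 2,
                                n_draws = 200)
    d1 <- unclass(panel)[which(!is.na(one[1, unclass(panel)]))]
    a <- pa[pa$sample_id == one$sample_id[1], ]
    b <- pred[pred$sample_id == one$sample_id[1] & pred$quantity == d1, ]
    expect_equal(a$median, b$median, tolerance = 0.02)
  }
  expect_error(per_study_predictions(fit, case_study_table1(), seed = 1),
               "clusters")
})
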