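# Correctness checks for the MCMC core against analytic oracles. Problem
# sizes are kept small; every fit is seeded.

prior_only_data <- function(D = 3) {
  panel <- disorder_panel(paste0("d", seq_len(D)))
  s <- data.frame(sample_id = "s1", cluster_id = "s1", N = 0L,
                  any_count = 0L, stringsAsFactors = FALSE)
  for (d in unclass(panel)) s[[d]] <- 0L
  meta_dataset(s, panel)
}

test_that("a prior-only fit reproduces the analytic priors", {
  d <- prior_only_data(3)
  fit <- suppressWarnings(
    fit_model1(d, diag(3), config = sampler_config(4, 6000, 1000, seed = 7)))
  # Phi(theta) quantiles match the prior prevalence range
  q <- quantile(pnorm(fit$theta[, 1]), c(0.025, 0.5, 0.975))
  expected <- prior_prevalence_range(-1.88, 0.30, qnorm(0.975))
  expect_equal(unname(q[1]), unname(expected["low"]), tolerance = 0.1)
  expect_equal(unname(q[2]), pnorm(-1.88), tolerance = 0.02)
  expect_equal(unname(q[3]), unname(expected["high"]), tolerance = 0.05)
  # tau: half-normal(0.25) median and upper quantile
  expect_equal(unname(median(fit$tau[, 2])), 0.25 * qnorm(0.75),
               tolerance = 0.015)
  expect_equal(unname(quantile(fit$tau[, 2], 0.95)), 0.25 * qnorm(0.975),
               tolerance = 0.03)
  # LKJ(2) marginal in D = 3: r ~ 2 Beta(2.5, 2.5) - 1, var = 1/6
  r <- fit$omega_B[, 1, 2]
  expect_lt(abs(mean(r)), 0.03)
  expect_lt(abs(var(r) - 1 / 6), 0.01)
})

test_that("a huge sample pins the posterior at the observed proportion", {
  d <- two_disorder_data(100000, 3000, 3000)
  fit <- fit_model1(d, diag(2), priors = prevalence_priors(tau_sd = 0.01),
                    config = sampler_config(4, 1500, 750, seed = 11))
  med <- apply(pnorm(fit$theta), 2, median)
  expect_true(all(abs(med - 0.03) < 0.005))
})

test_that("the univariate limit matches brute-force numeric integration", {
  # one disorder observed, tiny tau prior: the posterior of Phi(theta)
  # reduces to the single-binomial posterior under the probit-normal prior,
  # which a quadrature oracle evaluates directly
  N <- 200L; x <- 9L
  d <- two_disorder_data(N, x, NA)
  fit <- suppressWarnings(
    fit_model1(d, diag(2), priors = prevalence_priors(tau_sd = 0.005),
               config = sampler_config(4, 3000, 1000, seed = 13)))
  # oracle: p(theta | x) over a fine grid
  th <- seq(-4, 0, length.out = 20001)
  lp <- dnorm(th, -1.88, 0.30, log = TRUE) +
    x * pnorm(th, log.p = TRUE) + (N - x) * pnorm(th, lower.tail = FALSE,
                                                  log.p = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  o_mean <- sum(th * w)
  o_sd <- sqrt(sum((th - o_mean)^2 * w))
  expect_lt(abs(mean(fit$theta[, 1]) - o_mean), 0.02)
  expect_lt(abs(sd(fit$theta[, 1]) - o_sd), 0.015)
})

test_that("omega draws are symmetric unit-diagonal positive-definite", {
  cfg <- preset_config("sim1")
  dat <- generate_meta_analysis(cfg, 5)
  fit <- suppressWarnings(
    fit_model1(dat, cfg$omega_C, config = sampler_config(2, 400, 200, seed = 3,
                                                         thin = 2)))
  idx <- round(seq(1, nrow(fit$theta), length.out = 25))
  for (m in idx) {
    oB <- fit$omega_B[m, , ]
    expect_equal(oB, t(oB), tolerance = 1e-10)
    expect_equal(diag(oB), rep(1, 6), tolerance = 1e-10)
    expect_gt(min(eigen(oB, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_true(all(fit$tau >= 0))
  # Sigma_B is reconstructable from tau and omega_B by construction
  m <- idx[1]
  SB <- diag(fit$tau[m, ]) %*% fit$omega_B[m, , ] %*% diag(fit$tau[m, ])
  expect_equal(SB[2, 4],
               unname(fit$tau[m, 2] * fit$omega_B[m, 2, 4] * fit$tau[m, 4]))
})

test_that("samples sharing a cluster share one study-level mu", {
  panel <- disorder_panel(c("a", "b"))
  s <- data.frame(sample_id = c("s1", "s2"), cluster_id = c("c1", "c1"),
                  N = c(300L, 500L), any_count = NA_integer_,
                  a = c(9L, 16L), b = c(12L, 19L))
  d <- meta_dataset(s, panel)
  fit <- suppressWarnings(
    fit_model1(d, diag(2), config = sampler_config(2, 500, 250, seed = 5,
                                                   thin = 2)))
  expect_equal(length(fit$clusters), 1L)
  expect_equal(dim(fit$mu)[2], 1L)
})

test_that("an unobserved cluster's mu marginal is the between-study law", {
  # a zero-N sample contributes no likelihood, so its mu draws must follow
  # N(theta_d, tau_d) conditionally -- i.e. (mu - theta) / tau is standard
  # normal across draws, whatever omega_B does
  panel <- disorder_panel(c("a", "b"))
  s <- data.frame(sample_id = c("s1", "s2"), cluster_id = c("c1", "c2"),
                  N = c(400L, 0L), any_count = NA_integer_,
                  a = c(12L, 0L), b = c(20L, 0L))
  d <- meta_dataset(s, panel)
  fit <- suppressWarnings(
    fit_model1(d, diag(2), config = sampler_config(4, 3000, 1000, seed = 9)))
  z <- (fit$mu[, "c2", 1] - fit$theta[, 1]) / fit$tau[, 1]
  expect_equal(mean(z), 0, tolerance = 0.03)
  expect_equal(sd(z), 1, tolerance = 0.03)
  expect_lt(abs(skewness <- mean(z^3)), 0.1)
})

test_that("degenerate inputs are rejected with informative errors", {
  panel1 <- disorder_panel("only")
  s1 <- data.frame(sample_id = "s1", cluster_id = "s1", N = 10L,
                   any_count = 2L, only = 2L)
  expect_error(fit_model1(meta_dataset(s1, panel1), matrix(1, 1, 1)),
               "at least two disorders")
  d <- two_disorder_data(100, 3, 5)
  expect_error(fit_model2(d), "IPD")
  expect_error(fit_model1(d, matrix(c(1, 2, 2, 1), 2)), "positive definite")
  # a disorder measured nowhere triggers a warning, not an error
  s <- data.frame(sample_id = "s1", cluster_id = "s1", N = 100L,
                  any_count = NA_integer_, a = 3L, b = NA_integer_)
  dd <- meta_dataset(s, disorder_panel(c("a", "b")))
  w <- capture_warnings(
    fit_model1(dd, diag(2), config = sampler_config(2, 300, 150, seed = 2,
                                                    thin = 2)))
  expect_true(any(grepl("observed in no sample", w)))
})

test_that("convergence diagnostics detect failure and need two chains", {
  fit <- make_fixed_fit(qnorm(c(0.02, 0.05)), c(0.1, 0.1), diag(2), diag(2),
                        n_draws = 400)
  set.seed(1)
  # well-mixed: independent draws
  fit$theta <- matrix(rnorm(800, -2, 0.1), 400, 2)
  fit$tau <- matrix(abs(rnorm(800, 0.2, 0.05)), 400, 2)
  rep1 <- convergence_report(fit)
  expect_true(all(rep1$rhat < 1.02, na.rm = TRUE))
  # two chains stuck at different constants: split R-hat blows up
  fit$theta[, 1] <- rep(c(-2, -1), each = 200)
  rep2 <- convergence_report(fit)
  expect_gt(rep2$rhat[rep2$parameter == "theta.1"], 2)
  expect_false(attr(rep2, "pass"))
  fit$chain <- rep(1L, 400)
  expect_error(convergence_report(fit), "two chains")
})

test_that("model 2 recovers a known latent correlation (tetrachoric oracle)", {
  panel <- disorder_panel(c("a", "b"))
  set.seed(99)
  n <- 4000; rho <- 0.6
  L <- t(chol(matrix(c(1, rho, rho, 1), 2)))
  lat <- t(qnorm(0.3) + L %*% matrix(rnorm(2 * n), 2))
  y <- (lat > 0) + 0L
  colnames(y) <- c("a", "b")
  s <- data.frame(sample_id = "s1", cluster_id = "s1", N = n,
                  any_count = sum(rowSums(y) > 0),
                  a = sum(y[, 1]), b = sum(y[, 2]))
  d <- meta_dataset(s, panel, ipd = list(s1 = y))
  fit <- suppressWarnings(
    fit_model2(d, config = sampler_config(2, 600, 300, seed = 12, thin = 12)))
  # independent tetrachoric oracle: ML on the 2x2 table with fixed margins
  p1 <- mean(y[, 1]); p2 <- mean(y[, 2])
  tab <- table(factor(y[, 1], 0:1), factor(y[, 2], 0:1))
  nll <- function(r) {
    p11 <- anyprev:::bvn_orthant(-qnorm(p1), -qnorm(p2), r)
    -(tab[2, 2] * log(p11) + tab[2, 1] * log(p1 - p11) +
        tab[1, 2] * log(p2 - p11) + tab[1, 1] * log(1 - p1 - p2 + p11))
  }
  oracle <- optimize(nll, c(-0.95, 0.95))$minimum
  expect_lt(abs(median(fit$omega_C[, 1, 2]) - oracle), 0.1)
  expect_lt(abs(median(fit$omega_C[, 1, 2]) - rho), 0.1)
})

test_that("model 2 centres omega_C at zero for independent diagnoses", {
  panel <- disorder_panel(c("a", "b"))
  set.seed(42)
  n <- 2500
  y <- cbind(a = rbinom(n, 1, 0.25), b = rbinom(n, 1, 0.3))
  s <- data.frame(sample_id = "s1", cluster_id = "s1", N = n,
                  any_count = sum(rowSums(y) > 0),
                  a = sum(y[, 1]), b = sum(y[, 2]))
  d <- meta_dataset(s, panel, ipd = list(s1 = y))
  fit <- suppressWarnings(
    fit_model2(d, config = sampler_config(2, 500, 250, seed = 6, thin = 10)))
  expect_lt(abs(median(fit$omega_C[, 1, 2])), 0.08)
})

test_that("draw persistence writes labelled columns for every parameter", {
  cfg <- preset_config("sim1")
  dat <- generate_meta_analysis(cfg, 8)
  fit <- suppressWarnings(
    fit_model1(dat, cfg$omega_C, config = sampler_config(2, 300, 150, seed = 4,
                                                         thin = 1)))
  f <- tempfile(fileext = ".csv")
  write_draws(fit, f)
  got <- read.csv(f)
  expect_equal(nrow(got), nrow(fit$theta))
  expect_true(all(c("chain", "theta.1", "tau.6", "omegaB.1.2",
                    "mu.study_01.1") %in% names(got)))
  expect_equal(got$theta.2, unname(fit$theta[, 2]))
})
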