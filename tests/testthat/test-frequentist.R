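test_that("logit effects reproduce direct arithmetic, with zero-cell care", {
  d <- case_study_table1()
  ef <- logit_effects(d)
  expect_equal(nrow(ef), 17)
  # Zar: 99/453 -> logit(0.2185) ~ -1.275
  zar <- ef[ef$sample_id == "Zar_2002", ]
  expect_equal(zar$yi, log((99 / 453) / (1 - 99 / 453)), tolerance = 1e-12)
  expect_lt(abs(zar$yi - (-1.275)), 0.002)
  expect_equal(zar$x, 6L)
  # Kersting reported 0%: 0.5 events / 66 with finite effect and variance
  k <- ef[ef$sample_id == "Kersting_2009", ]
  p <- 0.5 / 66
  expect_equal(k$yi, log(p / (1 - p)))
  expect_equal(k$vi, 1 / 0.5 + 1 / 65.5)
  expect_true(all(is.finite(ef$yi)) && all(ef$vi > 0))
  # p = 0.5 maps to zero
  d50 <- two_disorder_data(10, 5, 5)
  d50$samples$any_count <- 5L
  expect_equal(logit_effects(d50)$yi, 0)
})

test_that("half-panel filter retains the documented subsets", {
  d <- case_study_table1()
  expect_equal(nrow(filter_half(d, 3)$samples), 12)   # incl. Wenzel 2005 (no any-count)
  expect_equal(sum(!is.na(filter_half(d, 3)$samples$any_count)), 11)
  expect_equal(sort(filter_half(d, 6)$samples$sample_id),
               c("Fairbrother_2016", "Uguz_2010", "Zar_2002"))
  expect_equal(nrow(filter_half(d, 1)$samples), 20)
})

test_that("equal-variance REML pooling matches its closed form", {
  set.seed(11)
  yi <- rnorm(8, -2, 0.6)
  v <- 0.05
  rows <- data.frame(sample_id = letters[1:8], yi = yi, vi = rep(v, 8), x = 1:8)
  r <- reml_pool(rows)
  expect_equal(r$pooled_logit, mean(yi), tolerance = 1e-6)
  expect_equal(r$tau_logit^2, max(0, var(yi) - v), tolerance = 1e-6)
  # identical effects with tiny variances: tau collapses to zero
  rows2 <- data.frame(sample_id = letters[1:5], yi = rep(-1.2, 5),
                      vi = rep(1e-4, 5), x = 1:5)
  r2 <- reml_pool(rows2)
  expect_equal(r2$tau_logit, 0)
  expect_equal(r2$pooled_logit, -1.2, tolerance = 1e-8)
  expect_lt(r2$ci_high - r2$ci_low, 0.02)
  expect_error(reml_pool(rows2[1, ]), "at least 2")
})

test_that("REML pooling and meta-regression agree with metafor on random data", {
  skip_if_not_installed("metafor")
  set.seed(21)
  for (i in 1:20) {
    k <- sample(6:15, 1)
    vi <- runif(k, 0.02, 0.4)
    x <- sample(1:6, k, replace = TRUE)
    yi <- rnorm(k, -2 + 0.2 * x, sqrt(vi + 0.15))
    ctl <- list(tol = 1e-10, maxiter = 500, stepadj = 0.5)
    rows <- data.frame(sample_id = seq_len(k), yi = yi, vi = vi, x = x)
    r <- reml_pool(rows)
    o <- metafor::rma(yi, vi, method = "REML", control = ctl)
    expect_lt(abs(r$pooled_logit - as.numeric(o$b)), 5e-5)
    expect_lt(abs(r$tau_logit - sqrt(o$tau2)), 5e-5)
    expect_lt(abs(r$ci_low - o$ci.lb), 5e-5)
    if (length(unique(x)) >= 2) {
      m <- reml_metareg(rows, predict_at = 6)
      om <- metafor::rma(yi, vi, mods = ~x, method = "REML", control = ctl)
      pr <- predict(om, newmods = 6)
      expect_lt(abs(m$pooled_logit - as.numeric(pr$pred)), 5e-5)
      expect_lt(abs(m$slope - as.numeric(om$b[2])), 5e-5)
      expect_lt(abs(m$slope_p - as.numeric(om$pval[2])), 2e-4)
      expect_lt(abs(m$ci_low - as.numeric(pr$ci.lb)), 2e-4)
    }
  }
})

test_that("meta-regression collapses to subgroup pooling and flags constant x", {
  # two x values, equal variances: the fitted line passes through the
  # subgroup means, so the prediction at an observed x equals that
  # subgroup's pooled mean
  rows <- data.frame(sample_id = 1:4, yi = c(-2.0, -1.8, -1.1, -0.9),
                     vi = rep(0.05, 4), x = c(2, 2, 5, 5))
  m <- reml_metareg(rows, predict_at = 5)
  expect_equal(m$pooled_logit, mean(c(-1.1, -0.9)), tolerance = 1e-6)
  const <- data.frame(sample_id = 1:4, yi = rnorm(4), vi = rep(0.1, 4), x = 3)
  expect_error(reml_metareg(const), "constant")
  expect_error(reml_metareg(rows[1:2, ]), "at least 3")
})

test_that("slope test is calibrated under a zero-slope truth", {
  set.seed(31)
  p <- replicate(200, {
    k <- 12
    vi <- runif(k, 0.03, 0.1)
    x <- sample(1:6, k, replace = TRUE)
    yi <- rnorm(k, -2, sqrt(vi + 0.05))
    reml_metareg(data.frame(sample_id = 1:k, yi = yi, vi = vi, x = x))$slope_p
  })
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.05)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("back-transformation preserves the ordering of pooled estimates", {
  d <- case_study_table1()
  tb <- frequentist_table(d)
  expect_equal(order(tb$prev), order(qnorm(tb$prev / 100)))
  expect_true(all(tb$ci_low <= tb$prev & tb$prev <= tb$ci_high))
})
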