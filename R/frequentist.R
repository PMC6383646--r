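#' Logit-scale effect sizes for the "any disorder" prevalences
#'
#' Computes, for every sample reporting an any-disorder count, the
#' logit-transformed prevalence `yi = log(p / (1 - p))`, its large-sample
#' variance `vi = 1 / (N p) + 1 / (N (1 - p))`, and the number of disorders
#' the sample measured (the meta-regression predictor). Samples with a
#' boundary prevalence (0 or 1) receive the customary only-zero-cells
#' correction: 0.5 is added to the event count and 1 to N for that sample
#' alone.
#'
#' @param data a [meta_dataset()].
#' @return data.frame with columns `sample_id`, `yi`, `vi`, `x`.
#' @export
logit_effects <- function(data) {
  stopifnot(inherits(data, "meta_dataset"))
  s <- data$samples
  keep <- !is.na(s$any_count)
  if (!any(keep)) stop("no samples report an any-disorder count")
  s <- s[keep, , drop = FALSE]
  x <- measured_disorders(data)[s$sample_id]
  ev <- as.numeric(s$any_count)
  n <- as.numeric(s$N)
  corr <- ev == 0 | ev == n
  ev[corr] <- ev[corr] + 0.5
  n[corr] <- n[corr] + 1
  p <- ev / n
  data.frame(sample_id = s$sample_id,
             yi = log(p / (1 - p)),
             vi = 1 / (n * p) + 1 / (n * (1 - p)),
             x = as.integer(x),
             stringsAsFactors = FALSE)
}

#' Restrict a dataset to samples measuring at least a minimum panel fraction
#'
#' @param data a [meta_dataset()].
#' @param min_measured minimum number of measured disorders for retention;
#'   defaults to half the panel, rounded up.
#' @return A [meta_dataset()] containing the retained samples (IPD blocks of
#'   dropped samples are dropped too).
#' @export
filter_half <- function(data, min_measured = ceiling(n_disorders(data$panel) / 2)) {
  stopifnot(inherits(data, "meta_dataset"))
  keep <- measured_disorders(data) >= min_measured
  samples <- data$samples[keep, , drop = FALSE]
  if (!nrow(samples)) stop("no samples measure ", min_measured, "+ disorders")
  ipd <- data$ipd[intersect(names(data$ipd), samples$sample_id)]
  meta_dataset(samples, data$panel, ipd)
}

# Restricted log-likelihood of the random-effects model y ~ N(X beta, vi + tau2),
# profiled over beta. X is the fixed-effects design matrix.
restricted_ll <- function(tau2, yi, vi, X) {
  w <- 1 / (vi + tau2)
  XtWX <- crossprod(X, X * w)
  beta <- solve(XtWX, crossprod(X, yi * w))
  r <- yi - drop(X %*% beta)
  ld <- determinant(XtWX, logarithm = TRUE)$modulus
  -0.5 * (sum(log(vi + tau2)) + ld + sum(w * r^2))
}

reml_fit <- function(yi, vi, X, tol = 1e-10) {
  upper <- max(10 * stats::var(yi), 10 * max(vi), 1)
  opt <- optimize(restricted_ll, c(0, upper), yi = yi, vi = vi, X = X,
                  maximum = TRUE, tol = tol)
  tau2 <- opt$maximum
  # the profile can be maximized at the boundary tau2 = 0
  if (restricted_ll(0, yi, vi, X) >= opt$objective) tau2 <- 0
  w <- 1 / (vi + tau2)
  XtWX <- crossprod(X, X * w)
  V <- solve(XtWX)
  beta <- drop(V %*% crossprod(X, yi * w))
  list(beta = beta, vcov = V, tau2 = tau2)
}

inv_logit <- function(x) 1 / (1 + exp(-x))

meta_result <- function(est, se, tau2, k, slope = NA_real_, slope_p = NA_real_) {
  ci <- est + c(-1, 1) * qnorm(0.975) * se
  structure(list(pooled_logit = est, se = se, ci_low = ci[1], ci_high = ci[2],
                 tau_logit = sqrt(tau2), tau_probit_approx = sqrt(tau2) / 1.6,
                 slope = slope, slope_p = slope_p, k_samples = k,
                 pooled_prev = inv_logit(est),
                 ci_prev_low = inv_logit(ci[1]),
                 ci_prev_high = inv_logit(ci[2])),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("REML random-effects pool of %d samples\n", x$k_samples))
  cat(sprintf("  prevalence %.1f%% [%.1f, %.1f], tau(logit) = %.3f\n",
              100 * x$pooled_prev, 100 * x$ci_prev_low, 100 * x$ci_prev_high,
              x$tau_logit))
  if (!is.na(x$slope))
    cat(sprintf("  slope per disorder = %.3f (Wald p = %.4f)\n",
                x$slope, x$slope_p))
  invisible(x)
}

#' Random-effects pooling of logit effects by restricted maximum likelihood
#'
#' Fits the standard random-effects meta-analysis on the logit scale: the
#' between-study variance `tau^2` maximizes the restricted log-likelihood
#' (direct numeric maximization, floored at zero), the pooled mean uses
#' inverse-variance weights `1 / (vi + tau^2)`, and the 95% CI is Wald-z.
#' Dependence between samples sharing a cluster is deliberately ignored,
#' matching how these univariate analyses are conducted in practice.
#'
#' @param rows output of [logit_effects()] (or any data.frame with `yi`, `vi`).
#' @return A `meta_result` with pooled logit estimate, Wald CI, `tau_logit`,
#'   and back-transformed prevalences.
#' @export
reml_pool <- function(rows) {
  if (nrow(rows) < 2) stop("need at least 2 samples to pool")
  X <- matrix(1, nrow(rows), 1)
  f <- reml_fit(rows$yi, rows$vi, X)
  meta_result(f$beta[1], sqrt(f$vcov[1, 1]), f$tau2, nrow(rows))
}

#' REML meta-regression on the number of disorders measured
#'
#' Mixed-effects meta-regression of the logit any-disorder effects on the
#' number of disorders each sample measured, with extrapolation to a
#' hypothetical study measuring `predict_at` disorders (typically the full
#' panel). The returned estimate and Wald CI are the fitted value at
#' `predict_at`; `slope_p` is the Wald-z p-value for the per-disorder slope.
#'
#' @param rows output of [logit_effects()].
#' @param predict_at number of disorders at which to predict (default: the
#'   largest observed `x`).
#' @return A `meta_result`.
#' @export
reml_metareg <- function(rows, predict_at = max(rows$x)) {
  if (nrow(rows) < 3) stop("need at least 3 samples for meta-regression")
  if (length(unique(rows$x)) < 2)
    stop("number of disorders measured is constant; slope is not identifiable")
  X <- cbind(1, rows$x)
  f <- reml_fit(rows$yi, rows$vi, X)
  xv <- c(1, predict_at)
  est <- sum(xv * f$beta)
  se <- sqrt(drop(t(xv) %*% f$vcov %*% xv))
  slope <- f$beta[2]
  slope_se <- sqrt(f$vcov[2, 2])
  slope_p <- 2 * pnorm(-abs(slope / slope_se))
  meta_result(est, se, f$tau2, nrow(rows), slope = slope, slope_p = slope_p)
}

#' Case-study comparator table
#'
#' Runs the full set of univariate comparators on a dataset: random-effects
#' pooling of all eligible samples (FRE), of samples measuring at least half
#' (FRE-H) and all (FRE-A) of the panel, and meta-regression on the number of
#' disorders measured with extrapolation to the full panel (FRE-M, FRE-MH).
#'
#' @param data a [meta_dataset()].
#' @return data.frame with one row per method: `method`, `k_samples`,
#'   `prev`, `ci_low`, `ci_high` (percent), `tau_probit`, `tau_logit`,
#'   `slope_p`.
#' @export
frequentist_table <- function(data) {
  D <- n_disorders(data$panel)
  half <- ceiling(D / 2)
  specs <- list(
    "FRE"    = list(min = 1, reg = FALSE),
    "FRE-H"  = list(min = half, reg = FALSE),
    "FRE-A"  = list(min = D, reg = FALSE),
    "FRE-M"  = list(min = 1, reg = TRUE),
    "FRE-MH" = list(min = half, reg = TRUE))
  rows <- lapply(names(specs), function(m) {
    sp <- specs[[m]]
    d <- if (sp$min > 1) filter_half(data, sp$min) else data
    ef <- logit_effects(d)
    r <- if (sp$reg) reml_metareg(ef, predict_at = D) else reml_pool(ef)
    data.frame(method = m, k_samples = r$k_samples,
               prev = 100 * r$pooled_prev,
               ci_low = 100 * r$ci_prev_low, ci_high = 100 * r$ci_prev_high,
               tau_probit = r$tau_probit_approx, tau_logit = r$tau_logit,
               slope_p = r$slope_p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
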