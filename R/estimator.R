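# Helpers shared by the posterior-simulation routines: lower Cholesky factors
# of Sigma_B (= diag(tau) L_B) and omega_C per posterior draw, flattened to
# draws x D*D for the C++ kernels.

chol_lower <- function(m) t(chol(m))

draw_factors <- function(fit, draw_idx) {
  D <- ncol(fit$theta)
  M <- length(draw_idx)
  LS <- matrix(0, M, D * D)
  LC <- matrix(0, M, D * D)
  for (i in seq_len(M)) {
    m <- draw_idx[i]
    LB <- chol_lower(fit$omega_B[m, , ])
    LS[i, ] <- as.vector(diag(fit$tau[m, ]) %*% LB)
    LC[i, ] <- as.vector(chol_lower(fit$omega_C[m, , ]))
  }
  list(theta = fit$theta[draw_idx, , drop = FALSE], LS = LS, LC = LC)
}

select_draws <- function(fit, n_draws) {
  M <- nrow(fit$theta)
  if (is.null(n_draws) || n_draws >= M) seq_len(M)
  else round(seq(1, M, length.out = n_draws))
}

prevalence_summary <- function(values, pi_values = NULL, mass = 0.95) {
  h <- hdi(values, mass)
  out <- list(median = median(values), hdi_low = h[[1]], hdi_high = h[[2]],
              pi_low = NA_real_, pi_high = NA_real_)
  if (!is.null(pi_values)) {
    p <- hdi(pi_values, mass)
    out$pi_low <- p[[1]]
    out$pi_high <- p[[2]]
  }
  structure(out, class = "prevalence_summary")
}

#' @export
print.prevalence_summary <- function(x, ...) {
  cat(sprintf("%.1f%% [%.1f, %.1f]", 100 * x$median, 100 * x$hdi_low,
              100 * x$hdi_high))
  if (!is.na(x$pi_low))
    cat(sprintf(", 95%% PI (%.1f%%, %.1f%%)", 100 * x$pi_low, 100 * x$pi_high))
  cat("\n")
  invisible(x)
}

#' Simulate a hypothetical cohort from the posterior
#'
#' Draws `n_participants` hypothetical participants: each participant's study
#' effect `mu*` is drawn from `MVN(theta, Sigma_B)` under one posterior draw,
#' the latent trait from `MVN(mu*, omega_C)`, and diagnoses by thresholding
#' at zero. In `"one-study-per-draw"` mode all participants assigned to the
#' same posterior draw share a single new study (the prediction-interval
#' construction); in `"one-study-per-participant"` mode every participant
#' comes from a fresh study.
#'
#' @param fit a `prevalence_fit`.
#' @param n_participants number of hypothetical participants.
#' @param mode `"one-study-per-participant"` (default) or
#'   `"one-study-per-draw"`.
#' @param seed integer seed.
#' @return list with `diagnoses` (binary participants x D matrix) and `draw`
#'   (the posterior draw index backing each row).
#' @export
simulate_cohort <- function(fit, n_participants,
                            mode = c("one-study-per-participant",
                                     "one-study-per-draw"),
                            seed) {
  stopifnot(inherits(fit, "prevalence_fit"), n_participants >= 1)
  mode <- match.arg(mode)
  set.seed(seed)
  fac <- draw_factors(fit, seq_len(nrow(fit$theta)))
  res <- cpp_simulate_cohort(fac$theta, fac$LS, fac$LC,
                             as.integer(n_participants),
                             mode == "one-study-per-draw")
  colnames(res$diagnoses) <- unclass(fit$panel)
  res
}

category_pi <- function(fit, n_inner, shared, n_draws = NULL) {
  idx <- select_draws(fit, n_draws)
  fac <- draw_factors(fit, idx)
  cnt <- cpp_category_counts(fac$theta, fac$LS, fac$LC,
                             as.integer(n_inner), shared)
  cnt / n_inner                      # draws x D matrix of P(>= k), k = 1..D
}

#' Posterior category prevalence: probability of at least k disorders
#'
#' For each posterior draw m, the prevalence `pi_m(k)` of carrying at least
#' `k` of the D panel disorders is estimated by Monte Carlo: `n_inner`
#' hypothetical participants, each from its own new study drawn from that
#' posterior draw's parameters. The summary reports the median and 95% HDI
#' over the `pi_m`. The 95% prediction interval for a single new study is
#' computed the same way except that each posterior draw contributes one new
#' study shared by all of its participants.
#'
#' @param fit a `prevalence_fit`.
#' @param k minimum number of disorders (1 to D).
#' @param n_inner participants simulated per posterior draw (default 1000).
#' @param seed integer seed.
#' @param prediction_interval also compute the new-study prediction interval?
#' @return A `prevalence_summary`.
#' @export
category_prevalence <- function(fit, k = 1, n_inner = 1000, seed,
                                prediction_interval = TRUE) {
  stopifnot(inherits(fit, "prevalence_fit"))
  D <- ncol(fit$theta)
  if (k < 1 || k > D) stop("k must lie in 1..", D)
  set.seed(seed)
  post <- category_pi(fit, n_inner, shared = FALSE)
  pred <- if (prediction_interval) category_pi(fit, n_inner, shared = TRUE)
  prevalence_summary(post[, k], if (prediction_interval) pred[, k])
}

# numerically integrated upper-orthant probability of a standardized
# bivariate normal: P(Z1 > a, Z2 > b) with correlation rho
bvn_orthant <- function(a, b, rho) {
  if (abs(rho) >= 1) {
    if (rho >= 1) return(pnorm(max(a, b), lower.tail = FALSE))
    return(max(0, 1 - pnorm(a) - pnorm(b)))
  }
  f <- function(z) dnorm(z) *
    pnorm((b - rho * z) / sqrt(1 - rho^2), lower.tail = FALSE)
  stats::integrate(f, a, Inf, rel.tol = 1e-10)$value
}

#' Conditional comorbidity probability
#'
#' Posterior probability that a participant from a random new study carries
#' `target` given that they carry every disorder in `given`, estimated per
#' posterior draw by Monte Carlo simulation of hypothetical participants. If
#' the conditioning event is so rare that it is unobserved in some draws, the
#' inner sample is enlarged; with a single conditioning disorder, draws still
#' lacking the event fall back to numeric bivariate-orthant integration over
#' simulated study effects rather than returning NaN.
#'
#' @param fit a `prevalence_fit`.
#' @param given character vector (or indices) of conditioning disorders.
#' @param target the target disorder (name or index), not in `given`.
#' @param n_inner participants per posterior draw (default 2000).
#' @param seed integer seed.
#' @return A `prevalence_summary` (prediction interval computed from
#'   one-study-per-draw cohorts).
#' @export
conditional_probability <- function(fit, given, target, n_inner = 2000, seed) {
  stopifnot(inherits(fit, "prevalence_fit"))
  nms <- unclass(fit$panel)
  gi <- if (is.character(given)) match(given, nms) else as.integer(given)
  ti <- if (is.character(target)) match(target, nms) else as.integer(target)
  if (!length(gi)) stop("empty conditioning set")
  if (anyNA(gi) || anyNA(ti)) stop("unknown disorder name")
  if (ti %in% gi) stop("target must not be part of the conditioning set")
  set.seed(seed)
  fac <- draw_factors(fit, seq_len(nrow(fit$theta)))
  cnt <- cpp_joint_counts(fac$theta, fac$LS, fac$LC, as.integer(n_inner),
                          as.integer(gi), as.integer(ti))
  zero <- cnt[, 1] == 0
  if (any(zero)) {                       # enlarge the inner sample once
    idx <- which(zero)
    more <- cpp_joint_counts(fac$theta[idx, , drop = FALSE],
                             fac$LS[idx, , drop = FALSE],
                             fac$LC[idx, , drop = FALSE],
                             as.integer(10 * n_inner),
                             as.integer(gi), as.integer(ti))
    cnt[idx, ] <- cnt[idx, ] + more
  }
  cond <- ifelse(cnt[, 1] > 0, cnt[, 2] / cnt[, 1], NA_real_)
  still <- which(is.na(cond))
  if (length(still)) {
    if (length(gi) == 1) {
      D <- ncol(fit$theta)
      for (m in still) {                 # orthant integration over study effects
        LS <- matrix(fac$LS[m, ], D, D)
        rho <- fit$omega_C[m, gi, ti]
        num <- den <- 0
        for (r in seq_len(200)) {
          mu <- fac$theta[m, ] + drop(LS %*% rnorm(D))
          pg <- bvn_orthant(-mu[gi], -mu[ti], rho)
          den <- den + pnorm(mu[gi])
          num <- num + pg
        }
        cond[m] <- num / den
      }
    } else {
      stop(length(still), " posterior draw(s) never produced the conditioning ",
           "event; increase n_inner")
    }
  }
  set.seed(seed + 1L)
  prevalence_summary(cond, conditional_pi(fit, fac, gi, ti, n_inner))
}

# prediction-interval analogue: one new study per posterior draw, conditional
# probability within that single study
conditional_pi <- function(fit, fac, gi, ti, n_inner) {
  M <- nrow(fac$theta)
  D <- ncol(fit$theta)
  out <- numeric(M)
  for (m in seq_len(M)) {
    LS <- matrix(fac$LS[m, ], D, D)
    mu <- fac$theta[m, ] + drop(LS %*% rnorm(D))
    rho <- fit$omega_C[m, gi[1], ti]
    if (length(gi) == 1) {
      num <- bvn_orthant(-mu[gi], -mu[ti], rho)
      den <- pnorm(mu[gi])
      out[m] <- if (den > 0) num / den else NA_real_
    } else {
      LC <- matrix(fac$LC[m, ], D, D)
      z <- matrix(rnorm(n_inner * D), n_inner, D)
      y <- sweep(z %*% t(LC), 2, mu, "+") > 0
      g <- rowSums(y[, gi, drop = FALSE]) == length(gi)
      out[m] <- if (any(g)) mean(y[g, ti]) else NA_real_
    }
  }
  out[is.finite(out)]
}

#' Per-study posterior predictions
#'
#' Posterior predictive prevalences for every sample in a dataset: for each
#' posterior draw, `N_s` participants are simulated from the sample's own
#' cluster-level study effect `mu` and the comorbidity correlation, and the
#' simulated prevalence of each disorder -- and, in `"any-measured"` mode, of
#' having at least one of the disorders that sample actually measured -- is
#' recorded. Predictions are produced for unmeasured disorders too, since
#' `mu` is defined for the full panel.
#'
#' @param fit a `prevalence_fit` covering the dataset's clusters.
#' @param data the [meta_dataset()] the model was fitted to.
#' @param mode `"per-disorder"` or `"any-measured"`.
#' @param seed integer seed.
#' @param n_draws posterior draws used per sample (default 500; subsampled
#'   evenly from the chains).
#' @return data.frame with `sample_id`, `quantity` (disorder name or
#'   `"any_measured"`), `observed` (reported proportion or NA), `median`,
#'   `hdi_low`, `hdi_high`.
#' @export
per_study_predictions <- function(fit, data,
                                  mode = c("per-disorder", "any-measured"),
                                  seed, n_draws = 500) {
  stopifnot(inherits(fit, "prevalence_fit"), inherits(data, "meta_dataset"))
  mode <- match.arg(mode)
  s <- data$samples
  if (!all(s$cluster_id %in% fit$clusters))
    stop("fit does not cover all clusters in the dataset")
  set.seed(seed)
  idx <- select_draws(fit, n_draws)
  D <- ncol(fit$theta)
  LC <- matrix(0, length(idx), D * D)
  for (i in seq_along(idx))
    LC[i, ] <- as.vector(chol_lower(fit$omega_C[idx[i], , ]))
  out <- list()
  for (r in seq_len(nrow(s))) {
    ci <- match(s$cluster_id[r], fit$clusters)
    mu <- fit$mu[idx, ci, , drop = FALSE]
    mu <- matrix(mu, length(idx), D)
    meas <- !is.na(as.matrix(s[r, unclass(data$panel), drop = FALSE])[1, ])
    pred <- cpp_study_pred(mu, LC, as.integer(s$N[r]), meas)
    if (mode == "per-disorder") {
      for (d in seq_len(D)) {
        h <- hdi(pred[, d])
        obs <- s[[unclass(data$panel)[d]]][r]
        out[[length(out) + 1]] <- data.frame(
          sample_id = s$sample_id[r], quantity = unclass(data$panel)[d],
          observed = if (is.na(obs)) NA_real_ else obs / s$N[r],
          median = median(pred[, d]), hdi_low = h[[1]], hdi_high = h[[2]],
          stringsAsFactors = FALSE)
      }
    } else {
      h <- hdi(pred[, D + 1])
      out[[length(out) + 1]] <- data.frame(
        sample_id = s$sample_id[r], quantity = "any_measured",
        observed = if (is.na(s$any_count[r])) NA_real_ else
          s$any_count[r] / s$N[r],
        median = median(pred[, D + 1]), hdi_low = h[[1]], hdi_high = h[[2]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
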