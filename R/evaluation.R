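#' Apply the competing estimators to one simulated meta-analysis
#'
#' Generates a synthetic meta-analysis from `cfg` and estimates the
#' any-disorder prevalence with each requested method: the univariate
#' logit-scale REML comparators (`FRE`, `FRE-H`, `FRE-M`, `FRE-MH`) applied
#' to the any-of-measured-disorders estimates, and the Bayesian multivariate
#' models (`BMV-K` = aggregate-only with a supplied `omega_C`, `BMV-IPD` =
#' aggregate + IPD with `omega_C` estimated). Frequentist intervals are
#' back-transformed Wald 95% CIs; Bayesian intervals are 95% HDIs of the
#' posterior category prevalence. A method failing on a degenerate replicate
#' (e.g. a constant meta-regression predictor) is recorded as NA rather than
#' aborting the batch.
#'
#' @param cfg a [sim_config()].
#' @param methods subset of `c("FRE","FRE-H","FRE-M","FRE-MH","BMV-K","BMV-IPD")`.
#' @param seed integer seed for the replicate (generation and fitting).
#' @param omega_C_known correlation matrix for `BMV-K` (defaults to the
#'   config's generating `omega_C`).
#' @param sampler a [sampler_config()] for the Bayesian methods.
#' @param priors a [prevalence_priors()].
#' @param n_inner inner cohort size per posterior draw for the Bayesian
#'   category prevalence.
#' @return data.frame with columns `method`, `estimate`, `low`, `high`,
#'   `slope_p`, `error`.
#' @export
run_replicate <- function(cfg, methods = c("FRE", "FRE-H", "FRE-M", "FRE-MH"),
                          seed, omega_C_known = cfg$omega_C,
                          sampler = sampler_config(chains = 4, iterations = 1000,
                                                   warmup = 500, seed = seed),
                          priors = prevalence_priors(), n_inner = 500) {
  stopifnot(inherits(cfg, "sim_config"))
  known <- c("FRE", "FRE-H", "FRE-M", "FRE-MH", "BMV-K", "BMV-IPD")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  data <- generate_meta_analysis(cfg, seed)
  D <- n_disorders(cfg$panel)
  half <- ceiling(D / 2)
  one <- function(method) {
    res <- tryCatch({
      switch(method,
        "FRE" = {
          r <- reml_pool(logit_effects(data))
          c(r$pooled_prev, r$ci_prev_low, r$ci_prev_high, NA)
        },
        "FRE-H" = {
          r <- reml_pool(logit_effects(filter_half(data, half)))
          c(r$pooled_prev, r$ci_prev_low, r$ci_prev_high, NA)
        },
        "FRE-M" = {
          r <- reml_metareg(logit_effects(data), predict_at = D)
          c(r$pooled_prev, r$ci_prev_low, r$ci_prev_high, r$slope_p)
        },
        "FRE-MH" = {
          r <- reml_metareg(logit_effects(filter_half(data, half)),
                            predict_at = D)
          c(r$pooled_prev, r$ci_prev_low, r$ci_prev_high, r$slope_p)
        },
        "BMV-K" = {
          fit <- fit_model1(data, omega_C_known, priors, sampler)
          s <- category_prevalence(fit, 1, n_inner, seed = seed + 17L,
                                   prediction_interval = FALSE)
          c(s$median, s$hdi_low, s$hdi_high, NA)
        },
        "BMV-IPD" = {
          fit <- fit_model2(data, priors, sampler)
          s <- category_prevalence(fit, 1, n_inner, seed = seed + 17L,
                                   prediction_interval = FALSE)
          c(s$median, s$hdi_low, s$hdi_high, NA)
        })
    }, error = function(e) e)
    if (inherits(res, "error"))
      data.frame(method = method, estimate = NA_real_, low = NA_real_,
                 high = NA_real_, slope_p = NA_real_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(method = method, estimate = res[1], low = res[2],
                 high = res[3], slope_p = res[4], error = NA_character_,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(methods, one))
}

#' Coverage, bias, width and power of the competing estimators
#'
#' Runs [run_replicate()] over `n_reps` independently generated
#' meta-analyses and aggregates against the process's brute-force true
#' prevalence: per method, the median estimate, median bias, the percentage
#' of replicates whose 95% interval covers the truth (with binomial
#' Monte-Carlo error `sqrt(c(1-c)/n)` on the percent scale), the mean
#' interval width, and -- for the meta-regression methods -- the power of the
#' two-sided Wald slope test at alpha = 0.05.
#'
#' @inheritParams run_replicate
#' @param n_reps number of simulated meta-analyses (>= 2).
#' @param true_prev the generating category prevalence; computed via
#'   [true_category_prevalence()] when NULL.
#' @param truth_participants,truth_reps problem size for the brute-force
#'   truth when it has to be computed.
#' @return data.frame of class `evaluation_report` with one row per method.
#' @export
evaluate_methods <- function(cfg, n_reps = 100,
                             methods = c("FRE", "FRE-H", "FRE-M", "FRE-MH"),
                             seed = 1, omega_C_known = cfg$omega_C,
                             sampler = NULL, priors = prevalence_priors(),
                             n_inner = 500, true_prev = NULL,
                             truth_participants = 10000, truth_reps = 10000) {
  stopifnot(n_reps >= 2)
  if (is.null(true_prev))
    true_prev <- true_category_prevalence(cfg, 1, truth_participants,
                                          truth_reps, seed = seed)
  reps <- lapply(seq_len(n_reps), function(r) {
    sub <- (seed * 2003L + r) %% .Machine$integer.max
    smp <- if (is.null(sampler))
      sampler_config(chains = 4, iterations = 1000, warmup = 500, seed = sub)
    else sampler_config(sampler$chains, sampler$iterations, sampler$warmup,
                        seed = sub, thin = sampler$thin)
    cbind(rep = r, run_replicate(cfg, methods, seed = sub,
                                 omega_C_known = omega_C_known, sampler = smp,
                                 priors = priors, n_inner = n_inner))
  })
  all <- do.call(rbind, reps)
  out <- lapply(methods, function(m) {
    x <- all[all$method == m & !is.na(all$estimate), , drop = FALSE]
    n <- nrow(x)
    cov <- mean(x$low <= true_prev & true_prev <= x$high)
    data.frame(method = m, n_ok = n,
               median_estimate = median(x$estimate),
               median_bias = median(x$estimate) - true_prev,
               coverage = 100 * cov,
               mc_error = 100 * sqrt(cov * (1 - cov) / n),
               mean_width = 100 * mean(x$high - x$low),
               power = if (all(is.na(x$slope_p))) NA_real_ else
                 100 * mean(x$slope_p < 0.05, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), true_prev = true_prev,
            replicates = all, class = c("evaluation_report", "data.frame"))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation over %d replicates; true any-disorder prevalence %.2f%%\n",
              max(attr(x, "replicates")$rep), 100 * attr(x, "true_prev")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
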