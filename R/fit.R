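#' Priors for the hierarchical prevalence model
#'
#' Defaults encode a mildly informative prior for rare disorders: the
#' `N(-1.88, 0.30^2)` probit-scale location prior makes population
#' prevalences between roughly 0.6% and 10% probable (within 2 SD), and the
#' half-normal(0.25) heterogeneity prior makes between-study SDs above 0.5
#' unlikely. The LKJ shape applies to both the between-study (`omega_B`) and
#' within-study comorbidity (`omega_C`) correlation matrices; the default of
#' 2 mildly favours moderate correlations over extreme ones.
#'
#' @param theta_mean,theta_sd normal prior on the probit-scale population
#'   prevalence of each disorder.
#' @param tau_sd scale of the half-normal prior on each between-study SD.
#' @param lkj_shape LKJ concentration (> 0) for both correlation matrices.
#' @return list of class `prevalence_priors`.
#' @export
prevalence_priors <- function(theta_mean = -1.88, theta_sd = 0.30,
                              tau_sd = 0.25, lkj_shape = 2) {
  stopifnot(theta_sd > 0, tau_sd > 0, lkj_shape > 0)
  structure(list(theta_mean = theta_mean, theta_sd = theta_sd,
                 tau_sd = tau_sd, lkj_shape = lkj_shape),
            class = "prevalence_priors")
}

#' MCMC sampler settings
#'
#' @param chains number of independent chains (>= 2 so that split-R-hat can
#'   be computed).
#' @param iterations total iterations per chain, including warmup.
#' @param warmup adaptation iterations discarded per chain.
#' @param seed integer seed; chain c runs under a sub-seed derived
#'   deterministically from it.
#' @param thin internal sweeps per recorded iteration (default 8). The
#'   random-walk updates are cheap, so thinning buys effective sample size at
#'   a small constant cost without changing the number of stored draws.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4, iterations = 5000, warmup = 2500,
                           seed = 1, thin = 8) {
  stopifnot(chains >= 2, warmup >= 1, warmup < iterations, thin >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 thin = as.integer(thin)),
            class = "sampler_config")
}

check_corr <- function(m, D, what) {
  m <- as.matrix(m)
  if (!isTRUE(all.equal(dim(m), c(D, D))) ||
      !isTRUE(all.equal(m, t(m), tolerance = 1e-8)) ||
      !isTRUE(all.equal(diag(m), rep(1, D), check.attributes = FALSE)))
    stop(what, " must be a symmetric unit-diagonal ", D, "x", D, " matrix")
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
    stop(what, " must be positive definite")
  m
}

prepare_fit_data <- function(data, require_ipd) {
  D <- n_disorders(data$panel)
  if (D < 2)
    stop("the multivariate model requires a panel of at least two disorders")
  s <- data$samples
  cl <- unique(s$cluster_id)
  cnt <- as.matrix(s[, unclass(data$panel), drop = FALSE])
  counts <- ifelse(is.na(cnt), -1L, cnt)
  storage.mode(counts) <- "integer"
  never <- colSums(!is.na(cnt)) == 0
  has_ipd_col <- if (length(data$ipd))
    sapply(seq_len(D), function(d)
      any(vapply(data$ipd, function(y) !anyNA(y[, d]), TRUE))) else rep(FALSE, D)
  if (any(never & !has_ipd_col))
    warning("disorder(s) observed in no sample: ",
            paste(unclass(data$panel)[never & !has_ipd_col], collapse = ", "),
            " (posterior equals the prior)")
  is_ipd <- s$sample_id %in% names(data$ipd)
  if (require_ipd && !any(is_ipd))
    stop("the IPD model requires at least one attached IPD block")
  if (!any(!is.na(cnt)) && !any(is_ipd)) stop("nothing to fit")
  ipd_rows <- matrix(integer(0), 0, D)
  ipd_sample <- integer(0)
  if (any(is_ipd)) {
    blocks <- lapply(names(data$ipd), function(id) {
      y <- data$ipd[[id]]
      y[is.na(y)] <- -1L
      list(y = y, s = match(id, s$sample_id) - 1L)
    })
    ipd_rows <- do.call(rbind, lapply(blocks, `[[`, "y"))
    ipd_sample <- unlist(lapply(blocks, function(b) rep(b$s, nrow(b$y))))
  }
  list(D = D, Ns = as.integer(s$N), counts = counts,
       cluster = match(s$cluster_id, cl) - 1L, clusters = cl,
       is_ipd = is_ipd, ipd_rows = ipd_rows, ipd_sample = as.integer(ipd_sample))
}

run_chains <- function(pd, estimate_omega_C, omega_C, priors, config) {
  D <- pd$D
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed((config$seed * 1009L + ch * 7919L) %% .Machine$integer.max)
    chains[[ch]] <- run_sampler(
      pd$Ns, pd$counts, pd$cluster, length(pd$clusters), pd$is_ipd,
      pd$ipd_rows, pd$ipd_sample,
      estimate_omega_C, omega_C,
      priors$theta_mean, priors$theta_sd, priors$tau_sd, priors$lkj_shape,
      config$iterations, config$warmup,
      if (is.null(config$thin)) 8L else config$thin, init_jitter = 0.5)
  }
  chains
}

assemble_draws <- function(chains, pd, panel, model, priors, config) {
  D <- pd$D
  C <- length(pd$clusters)
  kp <- nrow(chains[[1]]$theta)
  bind <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  theta <- bind("theta"); colnames(theta) <- unclass(panel)
  tau <- bind("tau"); colnames(tau) <- unclass(panel)
  oB <- bind("omega_B"); oC <- bind("omega_C"); muf <- bind("mu")
  n <- nrow(theta)
  omega_B <- array(t(oB), c(D, D, n))
  omega_C <- array(t(oC), c(D, D, n))
  mu <- array(t(muf), c(D, C, n))          # flattened cluster-major
  mu <- aperm(mu, c(3, 2, 1))              # draws x clusters x D
  omega_B <- aperm(omega_B, c(3, 1, 2))
  omega_C <- aperm(omega_C, c(3, 1, 2))
  dimnames(mu) <- list(NULL, pd$clusters, unclass(panel))
  fit <- structure(list(
    panel = panel, model = model,
    theta = theta, tau = tau, omega_B = omega_B, omega_C = omega_C, mu = mu,
    chain = rep(seq_along(chains), each = kp),
    clusters = pd$clusters,
    accept = lapply(chains, `[[`, "accept"),
    priors = priors, config = config), class = "prevalence_fit")
  fit$diagnostics <- convergence_report(fit)
  fit$converged <- attr(fit$diagnostics, "pass")
  if (!fit$converged)
    warning("convergence diagnostics failed (max R-hat ",
            sprintf("%.3f", max(fit$diagnostics$rhat, na.rm = TRUE)),
            ", min ESS ",
            sprintf("%.0f", min(fit$diagnostics$ess, na.rm = TRUE)),
            "); treat this fit with caution", call. = FALSE)
  fit
}

#' Fit the aggregate-only multivariate prevalence model (Model 1)
#'
#' Hierarchical Bayesian model for aggregate counts: cluster-level
#' probit-scale prevalences `mu_c ~ MVN(theta, Sigma_B)` with
#' `Sigma_B[d,d'] = tau_d * omega_B[d,d'] * tau_d'`, and for every sample and
#' observed disorder `n_{s,d} ~ Binomial(N_s, Phi(mu_{c(s),d}))`
#' independently given `mu`. Samples sharing a `cluster_id` share one `mu`
#' vector. Without IPD the within-study comorbidity correlation is not
#' identifiable, so `omega_C` must be supplied and is carried through
#' unchanged into posterior simulation.
#'
#' @param data a [meta_dataset()] (attached IPD blocks, if any, are ignored
#'   by this model).
#' @param omega_C known within-study latent correlation matrix.
#' @param priors a [prevalence_priors()].
#' @param config a [sampler_config()].
#' @return A `prevalence_fit` holding posterior draws of `theta`, `tau`,
#'   `omega_B`, `mu` (with `omega_C` constant), per-parameter split-R-hat and
#'   effective sample sizes, and a `converged` flag (R-hat <= 1.05 and
#'   ESS >= 200 for all reported parameters).
#' @export
fit_model1 <- function(data, omega_C, priors = prevalence_priors(),
                       config = sampler_config()) {
  stopifnot(inherits(data, "meta_dataset"))
  data$ipd <- list()
  data$samples$ipd_available <- FALSE
  pd <- prepare_fit_data(data, require_ipd = FALSE)
  omega_C <- check_corr(omega_C, pd$D, "omega_C")
  chains <- run_chains(pd, FALSE, omega_C, priors, config)
  assemble_draws(chains, pd, data$panel, 1L, priors, config)
}

#' Fit the combined aggregate + IPD model (Model 2)
#'
#' As [fit_model1()], except that for samples with attached IPD the aggregate
#' binomial likelihood is replaced by a latent multivariate probit:
#' `y_{s,d,i} = 1{ytilde_{s,d,i} > 0}` with
#' `ytilde_{s,*,i} ~ MVN(mu_{s,*}, omega_C)` (unit variances), the
#' comorbidity correlation `omega_C` receives an LKJ prior and is estimated,
#' and latent coordinates of unmeasured disorders are imputed within the
#' model. Uncertainty in `omega_C` propagates into every posterior summary.
#'
#' @inheritParams fit_model1
#' @return A `prevalence_fit`; `omega_C` now varies across draws.
#' @export
fit_model2 <- function(data, priors = prevalence_priors(),
                       config = sampler_config()) {
  stopifnot(inherits(data, "meta_dataset"))
  pd <- prepare_fit_data(data, require_ipd = TRUE)
  chains <- run_chains(pd, TRUE, diag(pd$D), priors, config)
  assemble_draws(chains, pd, data$panel, 2L, priors, config)
}

#' @export
print.prevalence_fit <- function(x, ...) {
  D <- ncol(x$theta)
  cat(sprintf("prevalence_fit (Model %d): %d draws x %d disorders, %d clusters\n",
              x$model, nrow(x$theta), D, length(x$clusters)))
  med <- apply(pnorm(x$theta), 2, median)
  h <- apply(pnorm(x$theta), 2, hdi)
  for (d in seq_len(D))
    cat(sprintf("  %-16s Phi(theta) = %.1f%% [%.1f, %.1f], tau = %.2f\n",
                colnames(x$theta)[d], 100 * med[d], 100 * h[1, d],
                100 * h[2, d], median(x$tau[, d])))
  cat(if (isTRUE(x$converged)) "  diagnostics: passed" else
      "  diagnostics: FAILED", "(R-hat <= 1.05, ESS >= 200)\n")
  invisible(x)
}
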