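# Split-R-hat and effective sample size, computed per parameter from the
# chain-labelled draw matrix (each chain split in half, rank-free version).

split_chains <- function(x, chain) {
  out <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    n <- length(v)
    h <- floor(n / 2)
    out[[length(out) + 1]] <- v[seq_len(h)]
    out[[length(out) + 1]] <- v[(n - h + 1):n]
  }
  out
}

rhat_split <- function(x, chain) {
  sp <- split_chains(x, chain)
  m <- length(sp)
  n <- length(sp[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(sp, mean, 0)
  vars <- vapply(sp, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 1e-300) return(if (B <= 1e-300) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(x, chain) {
  sp <- split_chains(x, chain)
  m <- length(sp)
  n <- length(sp[[1]])
  if (n < 4) return(NA_real_)
  means <- vapply(sp, mean, 0)
  vars <- vapply(sp, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  varp <- (n - 1) / n * W + B / n
  if (varp <= 1e-300) return(m * n)
  lag_max <- min(n - 2, 400)
  acov <- sapply(sp, function(v)
    acf(v, lag.max = lag_max, type = "covariance", plot = FALSE,
        demean = TRUE)$acf[, 1, 1])
  rho <- c(1, 1 - (W - rowMeans(acov)[-1]) / varp)  # lags 0..lag_max
  # Geyer initial positive + monotone sequence on paired sums
  npair <- floor(length(rho) / 2)
  tau_sum <- 0
  prev <- Inf
  for (k in seq_len(npair)) {
    p <- rho[2 * k - 1] + rho[2 * k]
    if (p < 0) break
    p <- min(p, prev)
    prev <- p
    tau_sum <- tau_sum + p
  }
  tau_int <- max(2 * tau_sum - 1, 1 / (m * n))
  m * n / tau_int
}

#' Convergence diagnostics for a fitted prevalence model
#'
#' Computes split-R-hat and effective sample size (ESS, Geyer initial
#' monotone sequence estimator) for every scalar parameter of a
#' `prevalence_fit`: each `theta_d`, `tau_d`, the free entries of `omega_B`
#' (and `omega_C` when estimated), and every cluster-level `mu_{c,d}`. The
#' overall pass flag requires R-hat <= 1.05 and ESS >= 200 everywhere.
#'
#' @param fit a `prevalence_fit` from [fit_model1()] or [fit_model2()].
#' @return data.frame with columns `parameter`, `rhat`, `ess`, and an
#'   attribute `pass` (logical).
#' @export
convergence_report <- function(fit) {
  stopifnot(inherits(fit, "prevalence_fit"))
  chain <- fit$chain
  if (length(unique(chain)) < 2)
    stop("convergence diagnostics need at least two chains")
  D <- ncol(fit$theta)
  cols <- list()
  nm <- character(0)
  for (d in seq_len(D)) {
    cols[[length(cols) + 1]] <- fit$theta[, d]; nm <- c(nm, paste0("theta.", d))
    cols[[length(cols) + 1]] <- fit$tau[, d];   nm <- c(nm, paste0("tau.", d))
  }
  for (d in seq_len(D - 1)) for (e in (d + 1):D) {
    cols[[length(cols) + 1]] <- fit$omega_B[, d, e]
    nm <- c(nm, paste0("omegaB.", d, ".", e))
    if (fit$model == 2L) {
      cols[[length(cols) + 1]] <- fit$omega_C[, d, e]
      nm <- c(nm, paste0("omegaC.", d, ".", e))
    }
  }
  for (c in seq_along(fit$clusters)) for (d in seq_len(D)) {
    cols[[length(cols) + 1]] <- fit$mu[, c, d]
    nm <- c(nm, paste0("mu.", fit$clusters[c], ".", d))
  }
  rhat <- vapply(cols, rhat_split, 0, chain = chain)
  ess <- vapply(cols, ess_basic, 0, chain = chain)
  out <- data.frame(parameter = nm, rhat = rhat, ess = ess,
                    stringsAsFactors = FALSE)
  attr(out, "pass") <- all(rhat <= 1.05, na.rm = TRUE) &&
    all(ess >= 200, na.rm = TRUE)
  out
}
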