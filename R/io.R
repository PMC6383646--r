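#' Persist posterior draws as a columnar CSV with a diagnostics sidecar
#'
#' One row per draw; columns `chain`, `theta.d`, `tau.d`,
#' `omegaB.d.dprime`, `omegaC.d.dprime` (upper triangle) and
#' `mu.<cluster>.d`. Convergence diagnostics are written next to the CSV as
#' JSON (`<path>.diag.json`) when the jsonlite package is available.
#'
#' @param fit a `prevalence_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "prevalence_fit"))
  D <- ncol(fit$theta)
  df <- data.frame(chain = fit$chain)
  for (d in seq_len(D)) df[[paste0("theta.", d)]] <- fit$theta[, d]
  for (d in seq_len(D)) df[[paste0("tau.", d)]] <- fit$tau[, d]
  for (d in seq_len(D - 1)) for (e in (d + 1):D) {
    df[[paste0("omegaB.", d, ".", e)]] <- fit$omega_B[, d, e]
    df[[paste0("omegaC.", d, ".", e)]] <- fit$omega_C[, d, e]
  }
  for (c in seq_along(fit$clusters)) for (d in seq_len(D))
    df[[paste0("mu.", fit$clusters[c], ".", d)]] <- fit$mu[, c, d]
  write.csv(df, path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- list(model = fit$model, panel = as.character(unclass(fit$panel)),
                 clusters = as.character(fit$clusters),
                 converged = isTRUE(fit$converged),
                 diagnostics = fit$diagnostics)
    jsonlite::write_json(side, paste0(path, ".diag.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
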