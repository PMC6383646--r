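# Shared fixtures: a hand-built posterior with fixed parameters (so estimator
# kernels can be checked against closed forms), random correlation matrices,
# and a small two-disorder dataset builder.

make_fixed_fit <- function(theta, tau, omega_B, omega_C, n_draws = 200) {
  D <- length(theta)
  structure(list(
    panel = disorder_panel(paste0("d", seq_len(D))), model = 1L,
    theta = matrix(theta, n_draws, D, byrow = TRUE,
                   dimnames = list(NULL, paste0("d", seq_len(D)))),
    tau = matrix(tau, n_draws, D, byrow = TRUE),
    omega_B = aperm(array(omega_B, c(D, D, n_draws)), c(3, 1, 2)),
    omega_C = aperm(array(omega_C, c(D, D, n_draws)), c(3, 1, 2)),
    mu = array(qnorm(0.5), c(n_draws, 1, D)),
    chain = rep(1:2, each = n_draws / 2),
    clusters = "c1", converged = TRUE), class = "prevalence_fit")
}

rand_corr <- function(D, strength = 3) {
  A <- matrix(rnorm(D * (D + strength)), D + strength, D)
  cov2cor(crossprod(A))
}

two_disorder_data <- function(n1, x1a, x1b, cluster = NULL) {
  panel <- disorder_panel(c("a", "b"))
  s <- data.frame(sample_id = "s1", cluster_id = "s1", N = as.integer(n1),
                  any_count = NA_integer_, a = as.integer(x1a),
                  b = as.integer(x1b), stringsAsFactors = FALSE)
  meta_dataset(s, panel)
}

# brute-force P(at least k of D) for independent disorders by enumerating
# all 2^D outcomes
enum_at_least_k <- function(p, k) {
  D <- length(p)
  tot <- 0
  for (m in 0:(2^D - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(D)]
    if (sum(bits) >= k)
      tot <- tot + prod(ifelse(bits == 1, p, 1 - p))
  }
  tot
}
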