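# Dense reference implementations, independent of the package's
# Woodbury/profiling code paths, plus small fixture builders shared by the
# test files.

# -2 log marginal likelihood (constants excluded) by brute-force dense
# linear algebra: explicit V_i, solve(), determinant().
dense_neg2ll <- function(stacked, G, sigma2, method = "ML") {
  Vs <- lapply(stacked$days, function(d) {
    V <- d$Z %*% G %*% t(d$Z)
    diag(V) <- diag(V) + sigma2
    V
  })
  A <- Reduce(`+`, Map(function(d, V) t(d$X) %*% solve(V, d$X),
                       stacked$days, Vs))
  u <- Reduce(`+`, Map(function(d, V) t(d$X) %*% solve(V, d$Y),
                       stacked$days, Vs))
  beta <- solve(A, u)
  obj <- 0
  for (i in seq_along(Vs)) {
    d <- stacked$days[[i]]
    r <- d$Y - d$X %*% beta
    obj <- obj + as.numeric(determinant(Vs[[i]], logarithm = TRUE)$modulus) +
      as.numeric(t(r) %*% solve(Vs[[i]], r))
  }
  if (method == "REML")
    obj <- obj + as.numeric(determinant(A, logarithm = TRUE)$modulus)
  obj
}

# GLS fixed effects by dense normal equations.
dense_gls <- function(stacked, G, sigma2) {
  Vs <- lapply(stacked$days, function(d) {
    V <- d$Z %*% G %*% t(d$Z)
    diag(V) <- diag(V) + sigma2
    V
  })
  A <- Reduce(`+`, Map(function(d, V) t(d$X) %*% solve(V, d$X),
                       stacked$days, Vs))
  u <- Reduce(`+`, Map(function(d, V) t(d$X) %*% solve(V, d$Y),
                       stacked$days, Vs))
  as.numeric(solve(A, u))
}

# Conditional-mean predictor of one day's random effects, dense.
dense_blup <- function(day, G, sigma2, beta) {
  V <- day$Z %*% G %*% t(day$Z)
  diag(V) <- diag(V) + sigma2
  as.numeric(G %*% t(day$Z) %*% solve(V, day$Y - day$X %*% beta))
}

# random symmetric positive-definite matrix
random_pd <- function(q, scale = 0.05) {
  M <- matrix(stats::rnorm(q * q), q)
  scale * (crossprod(M) / q + diag(0.2, q))
}

# Small simulated stacked dataset under the canonical two-mood network.
make_stacked <- function(N = 3, n_occ = 4, spec = example_spec(2), seed = 1,
                         missing_rate = 0) {
  cfg <- sim_config(spec, n_days = N, n_per_day = n_occ,
                    candidate_pool = 4000, missing_rate = missing_rate,
                    seed = seed)
  stack_dataset(simulate_dataset(cfg), spec$k)
}

# Near-noiseless specification: fixed effects only, vanishing noise.
noiseless_spec <- function(k = 2) {
  spec <- example_spec(k)
  larmex_spec(spec$beta_ar, spec$beta_e, spec$beta_c,
              matrix(0, spec$q, spec$q), "diagonal", sigma2 = 1e-30)
}

# A fit-state stub for exercising the BLUP formula at chosen components.
fit_state <- function(stacked, beta, G, sigma2) {
  structure(list(beta_hat = beta, G_hat = G, sigma2_hat = sigma2,
                 k = stacked$k, q = stacked$q,
                 day_index = vapply(stacked$days, function(d) d$day_index, 0)),
            class = "larmex_fit")
}
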