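test_that("covariance parameterizations decode to valid components and round-trip", {
  set.seed(201)
  # diagonal
  G <- diag(exp(stats::rnorm(8, -3, 1)), 8)
  th <- encode_cov_param(G, 0.02, "diagonal", 2)
  dec <- decode_cov_param(th, "diagonal", 2)
  expect_equal(dec$G, G, tolerance = 1e-12)
  expect_equal(dec$sigma2, 0.02, tolerance = 1e-14)

  # compound symmetric
  Gcs <- build_G(rep(0.04, 8), 0.012, "compound_symmetric", 2)
  th2 <- encode_cov_param(Gcs, 0.05, "compound_symmetric", 2)
  dec2 <- decode_cov_param(th2, "compound_symmetric", 2)
  expect_equal(dec2$G, Gcs, tolerance = 1e-10)
  expect_equal(dec2$sigma2, 0.05, tolerance = 1e-12)

  # block structure: covariance only within the AR and exo/const blocks
  Gbl <- build_G(rep(0.04, 8), 0.012, "block_cs_ar_exo_independent", 2)
  expect_identical(Gbl[1, 5], 0)
  expect_identical(Gbl[2, 3], 0.012)
  expect_identical(Gbl[5, 7], 0.012)
  th3 <- encode_cov_param(Gbl, 0.02, "block_cs_ar_exo_independent", 2)
  dec3 <- decode_cov_param(th3, "block_cs_ar_exo_independent", 2)
  expect_equal(dec3$G, Gbl, tolerance = 1e-10)

  # arbitrary theta always decodes to PSD G and positive sigma2
  for (i in 1:20) {
    theta <- stats::rnorm(9, 0, 3)
    d <- decode_cov_param(theta, "diagonal", 2)
    expect_true(all(diag(d$G) >= 0) && d$sigma2 > 0)
    dc <- decode_cov_param(stats::rnorm(3, 0, 3), "compound_symmetric", 2)
    ev <- eigen(dc$G, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("the marginal covariance is Z G Z' + sigma2 I", {
  stacked <- make_stacked(N = 2, n_occ = 5, seed = 12)
  day <- stacked$days[[1]]
  expect_equal(marginal_cov(day, diag(0, 8), 0.3),
               diag(0.3, length(day$Y)), tolerance = 1e-14)

  ident_day <- list(day_index = 1L, Y = stats::rnorm(8), X = diag(8),
                    Z = diag(8), n_transitions = 4L)
  expect_equal(marginal_cov(ident_day, diag(1, 8), 1), diag(2, 8),
               tolerance = 1e-14)

  set.seed(13)
  G <- random_pd(8)
  V <- marginal_cov(day, G, 0.07)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0.07 - 1e-10)
  expect_error(marginal_cov(day, -diag(1, 8), 0.1), "positive semi-definite")
})

test_that("GLS reduces to pooled OLS when G = 0 and recovers beta exactly on
          noiseless data", {
  stacked <- make_stacked(N = 4, n_occ = 6, seed = 21)
  X <- do.call(rbind, lapply(stacked$days, function(d) d$X))
  Y <- unlist(lapply(stacked$days, function(d) d$Y))
  ols <- as.numeric(solve(crossprod(X), crossprod(X, Y)))
  g <- gls_beta(stacked, diag(0, 8), 0.13)
  expect_equal(unname(g$beta_hat), ols, tolerance = 1e-10)
  expect_false(g$generalized)

  noiseless <- make_stacked(N = 4, n_occ = 10, spec = noiseless_spec(2),
                            seed = 22)
  g0 <- gls_beta(noiseless, diag(0, 8), 1)
  expect_equal(unname(g0$beta_hat),
               c(0.3, -0.3, -0.3, 0.3, 0.3, -0.3, 0, 0), tolerance = 1e-8)
})

test_that("GLS agrees with the dense normal-equations oracle", {
  set.seed(23)
  for (i in 1:5) {
    stacked <- make_stacked(N = 3, n_occ = 5, seed = 23 + i)
    G <- random_pd(8)
    s2 <- stats::runif(1, 0.01, 0.2)
    g <- gls_beta(stacked, G, s2)
    expect_equal(unname(g$beta_hat), dense_gls(stacked, G, s2),
                 tolerance = 1e-10)
  }
})

test_that("a singular design falls back to a flagged generalized inverse", {
  stacked <- make_stacked(N = 2, n_occ = 4, seed = 29)
  # duplicate a column's worth of collinearity: zero out the exogenous input
  for (i in seq_along(stacked$days)) {
    stacked$days[[i]]$X[, 5:6] <- 0
    stacked$days[[i]]$Z <- stacked$days[[i]]$X
  }
  g <- gls_beta(stacked, diag(0.01, 8), 0.05)
  expect_true(g$generalized)
  expect_true(all(is.finite(g$beta_hat)))
})

test_that("the likelihood matches a dense multivariate-normal oracle", {
  # zero residuals and V = I give an objective of exactly 0 under ML
  noiseless <- make_stacked(N = 3, n_occ = 5, spec = noiseless_spec(2),
                            seed = 31)
  th0 <- encode_cov_param(diag(0, 8), 1, "diagonal", 2)
  expect_equal(neg2_loglik(th0, noiseless, "ML"), 0, tolerance = 1e-8)

  set.seed(32)
  for (i in 1:10) {
    stacked <- make_stacked(N = 3, n_occ = 4, seed = 320 + i)
    G <- random_pd(8)
    s2 <- stats::runif(1, 0.01, 0.2)
    th <- encode_cov_param(G, s2, "diagonal", 2)
    # encode/decode keeps only the diagonal under the diagonal tag
    Gd <- diag(diag(G), 8)
    expect_equal(neg2_loglik(th, stacked, "ML"),
                 dense_neg2ll(stacked, Gd, s2, "ML"), tolerance = 1e-8)
    expect_equal(neg2_loglik(th, stacked, "REML"),
                 dense_neg2ll(stacked, Gd, s2, "REML"), tolerance = 1e-8)
  }

  # near-singular components give a large flagged value, not an error
  bad <- encode_cov_param(diag(1e10, 8), 1e-280, "diagonal", 2)
  val <- neg2_loglik(bad, noiseless, "ML")
  expect_true(is.finite(val))
})

test_that("REML fitting recovers the generating parameters", {
  spec <- example_spec(2)
  stacked <- make_stacked(N = 36, n_occ = 10, seed = 55)
  fit <- suppressMessages(fit_larmex(stacked))
  expect_true(fit$converged)
  truth <- c(0.3, -0.3, -0.3, 0.3, 0.3, -0.3, 0, 0)
  expect_lt(max(abs(fit$beta_hat - truth)), 0.25)
  expect_lt(abs(fit$sigma2_hat - 0.02), 0.01)
  ev <- eigen(fit$cov_beta, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_identical(nrow(fit$blups), 36L)

  # the reported objective is the profiled optimum of the public likelihood
  expect_equal(neg2_loglik(fit$theta, stacked, "REML"), fit$neg2ll,
               tolerance = 1e-8)
  probe <- fit$theta + c(0.05, rep(0, 8))
  expect_gt(neg2_loglik(probe, stacked, "REML"), fit$neg2ll)
})

test_that("near-noiseless data drives the fit to the exact coefficients", {
  stacked <- make_stacked(N = 6, n_occ = 10, spec = noiseless_spec(2),
                          seed = 66)
  fit <- suppressMessages(fit_larmex(stacked))
  truth <- c(0.3, -0.3, -0.3, 0.3, 0.3, -0.3, 0, 0)
  expect_lt(max(abs(fit$beta_hat - truth)), 1e-6)
  expect_lt(fit$sigma2_hat, 1e-8)
})

test_that("with no true day-level variation the variance components vanish", {
  spec <- example_spec(2)
  spec0 <- larmex_spec(spec$beta_ar, spec$beta_e, spec$beta_c,
                       matrix(0, 8, 8), "diagonal", 0.02)
  cfg <- sim_config(spec0, n_days = 120, candidate_pool = 500, seed = 99)
  stacked <- stack_dataset(simulate_dataset(cfg))
  fit <- suppressMessages(fit_larmex(stacked))
  expect_equal(fit$sigma2_hat, 0.02, tolerance = 0.1)
  expect_lt(max(diag(fit$G_hat)), 0.01)
  expect_lt(max(abs(fit$blups)), 0.15)
})

test_that("REML and ML estimates coalesce as days accumulate", {
  diffs <- vapply(c(8, 36, 144), function(N) {
    stacked <- make_stacked(N = N, n_occ = 10, seed = 300 + N)
    fr <- suppressMessages(fit_larmex(stacked, method = "REML"))
    fm <- suppressMessages(fit_larmex(stacked, method = "ML"))
    max(abs(fr$beta_hat - fm$beta_hat))
  }, 0)
  expect_true(all(diff(diffs) < 0))
})

test_that("BLUPs match the conditional-mean formula and shrink with G", {
  stacked <- make_stacked(N = 4, n_occ = 8, seed = 71)
  set.seed(72)
  G <- random_pd(8)
  s2 <- 0.05
  beta <- stats::rnorm(8, 0, 0.2)
  fs <- fit_state(stacked, beta, G, s2)
  b <- blup_all(fs, stacked)
  for (i in seq_along(stacked$days)) {
    expect_equal(as.numeric(b[i, ]),
                 dense_blup(stacked$days[[i]], G, s2, beta), tolerance = 1e-10)
  }

  # G = 0 -> every BLUP is exactly zero
  b0 <- blup_all(fit_state(stacked, beta, matrix(0, 8, 8), s2), stacked)
  expect_identical(max(abs(b0)), 0)

  # zero-residual day -> zero BLUP
  noiseless <- make_stacked(N = 2, n_occ = 6, spec = noiseless_spec(2),
                            seed = 73)
  truth <- c(0.3, -0.3, -0.3, 0.3, 0.3, -0.3, 0, 0)
  bz <- blup_all(fit_state(noiseless, truth, G, s2), noiseless)
  expect_lt(max(abs(bz)), 1e-10)

  # shrinkage path: scaling G down shrinks every day's BLUP toward zero
  scales <- c(1, 0.1, 0.01, 1e-6)
  norms <- vapply(scales, function(s) {
    max(abs(blup_all(fit_state(stacked, beta, s * G, s2), stacked)))
  }, 0)
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4], 1e-4)

  fit <- suppressMessages(fit_larmex(stacked))
  expect_error(blup(fit, day_index = 99), "not part of the fit")
  expect_equal(blup(fit, day_index = stacked$days[[2]]$day_index),
               fit$blups[2, ])
})

test_that("the REML solution agrees with lme4 on a shared dataset", {
  skip_if_not_installed("lme4")
  stacked <- make_stacked(N = 20, n_occ = 10, seed = 81)
  fit <- suppressMessages(fit_larmex(stacked))

  X <- do.call(rbind, lapply(stacked$days, function(d) d$X))
  Y <- unlist(lapply(stacked$days, function(d) d$Y))
  day <- factor(unlist(lapply(stacked$days,
                              function(d) rep(d$day_index, length(d$Y)))))
  df <- data.frame(y = Y, X, day = day)
  fml <- y ~ 0 + ar_1_1 + ar_1_2 + ar_2_1 + ar_2_2 + e_1 + e_2 + c_1 + c_2 +
    (0 + ar_1_1 + ar_1_2 + ar_2_1 + ar_2_2 + e_1 + e_2 + c_1 + c_2 || day)
  lfit <- lme4::lmer(fml, data = df, REML = TRUE,
                     control = lme4::lmerControl(calc.derivs = FALSE))
  expect_equal(unname(fit$beta_hat), unname(lme4::fixef(lfit)),
               tolerance = 1e-3)
  expect_equal(fit$sigma2_hat, lme4::getME(lfit, "sigma")^2, tolerance = 1e-2)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  lme4_g <- vc$vcov[match(ranef_names(2), vc$var1)]
  expect_equal(unname(diag(fit$G_hat)), lme4_g, tolerance = 5e-3)
  # identical objective up to the constant (n - p) log(2pi) that we exclude
  n_p <- stacked$total_obs - 8
  expect_equal(fit$neg2ll + n_p * log(2 * pi), lme4::REMLcrit(lfit),
               tolerance = 1e-4)
})
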