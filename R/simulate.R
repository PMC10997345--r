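#' Simulation settings for the data-generating process
#'
#' The generator mirrors a typical ecological momentary assessment design:
#' `n_days` days with a nominal `n_per_day` prompts per day. Each day gets
#' its own coefficient set `beta + b_i`, with `b_i ~ N(0, G)` retained by
#' rejection sampling so that the day's autoregressive matrix is stable.
#' Trajectories start every morning from an initial value drawn uniformly
#' from `init_range`, independent of the previous evening; the exogenous
#' input is drawn uniformly from `exo_range`.
#'
#' @param spec a [larmex_spec()].
#' @param n_days number of days `N`.
#' @param n_per_day nominal observations per day (default 10); at least 2.
#' @param candidate_pool number of candidate random-effect vectors used for
#'   stability rejection sampling (default 20000).
#' @param init_range interval for the initial mood values.
#' @param exo_range interval for the exogenous input.
#' @param missing_rate probability in `[0, 1)` that an occasion is missing
#'   completely at random.
#' @param exo_per_day if `TRUE`, one exogenous value is drawn per day and
#'   held constant; by default a fresh value is drawn per occasion.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `"larmex_sim_config"`.
#' @export
sim_config <- function(spec, n_days, n_per_day = 10L, candidate_pool = 20000L,
                       init_range = c(-0.5, 0.5), exo_range = c(0, 0.5),
                       missing_rate = 0, exo_per_day = FALSE, seed = NULL) {
  stopifnot(inherits(spec, "larmex_spec"))
  if (n_days < 1L) stop("'n_days' must be >= 1")
  if (n_per_day < 2L) stop("'n_per_day' must be >= 2")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must be in [0, 1)")
  structure(list(spec = spec, n_days = as.integer(n_days),
                 n_per_day = as.integer(n_per_day),
                 candidate_pool = as.integer(candidate_pool),
                 init_range = init_range, exo_range = exo_range,
                 missing_rate = missing_rate, exo_per_day = exo_per_day,
                 seed = seed),
            class = "larmex_sim_config")
}

## Moduli of the eigenvalues of many AR matrices, vectorised for k = 2.
## `Bmat` holds one row-major flattened k x k matrix per row.
spectral_radii <- function(Bmat, k) {
  if (k == 2L) {
    tr <- Bmat[, 1L] + Bmat[, 4L]
    dt <- Bmat[, 1L] * Bmat[, 4L] - Bmat[, 2L] * Bmat[, 3L]
    disc <- tr^2 - 4 * dt
    out <- numeric(nrow(Bmat))
    re <- disc >= 0
    sq <- sqrt(disc[re])
    out[re] <- pmax(abs((tr[re] + sq) / 2), abs((tr[re] - sq) / 2))
    out[!re] <- sqrt(dt[!re])  # complex pair: |lambda|^2 = det
    out
  } else {
    apply(Bmat, 1L, function(b)
      max(Mod(eigen(matrix(b, k, k, byrow = TRUE), only.values = TRUE)$values)))
  }
}

## Factor R with G = R %*% t(R) for a PSD matrix (eigen-based, rank-revealing).
psd_factor <- function(G, tol = 1e-12) {
  e <- eigen(G, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(1, max(e$values)))
    stop("covariance matrix is not positive semi-definite")
  lam <- pmax(e$values, 0)
  keep <- lam > tol * max(lam, 1)
  if (!any(keep)) return(matrix(0, nrow(G), 1L))
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam[keep]), sum(keep))
}

#' Rejection-sample stable day-level random effects
#'
#' Draws `candidate_pool` random-effect vectors from `N(0, G)`, retains
#' those for which `beta_ar + b_ar` is stable (spectral radius below 1), and
#' samples `n_days` of the retained draws without replacement.
#'
#' @param config a [sim_config()].
#' @return List of [day_draw()]s of length `config$n_days`, with attributes
#'   `retention` (fraction of candidates that were stable) and
#'   `sign_rate` / `sign_rate_unfiltered` (fraction of retained / all
#'   candidates preserving the trait sign structure, see
#'   [sign_preserved()]).
#' @export
sample_day_draws <- function(config) {
  spec <- config$spec
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- spec$k
  q <- spec$q
  n_cand <- config$candidate_pool
  R <- psd_factor(spec$G)
  B <- matrix(stats::rnorm(n_cand * ncol(R)), n_cand) %*% t(R)
  fixed <- c(as.vector(t(spec$beta_ar)), spec$beta_e)
  Bar <- sweep(B[, seq_len(k^2), drop = FALSE], 2L, fixed[seq_len(k^2)], "+")
  stable <- spectral_radii(Bar, k) < 1
  retention <- mean(stable)
  net <- sweep(B[, seq_len(k^2 + k), drop = FALSE], 2L, fixed, "+")
  keep <- fixed != 0  # zero fixed effects carry no edge to preserve
  pres <- rowSums(sign(net[, keep, drop = FALSE]) ==
                    matrix(sign(fixed[keep]), n_cand, sum(keep),
                           byrow = TRUE)) == sum(keep)
  n_stable <- sum(stable)
  if (n_stable < config$n_days)
    stop(sprintf(paste0("only %d of %d candidate draws were stable ",
                        "(retention %.3f); need %d days"),
                 n_stable, n_cand, retention, config$n_days))
  idx <- which(stable)
  pick <- idx[sample.int(n_stable, config$n_days)]
  draws <- lapply(seq_along(pick), function(j)
    unflatten_ranef(B[pick[j], ], k, day_index = j, spec = spec))
  attr(draws, "retention") <- retention
  attr(draws, "sign_rate") <- mean(pres[stable])
  attr(draws, "sign_rate_unfiltered") <- mean(pres)
  draws
}

#' Simulate one day of EMA observations
#'
#' Iterates the day-level VAR(1) from a fresh uniform initial value,
#' injecting Gaussian noise `N(0, sigma2 I)` at every transition. Both the
#' noisy and the noiseless (noise-free recursion from the same start and
#' inputs) trajectories are returned.
#'
#' @param spec a [larmex_spec()].
#' @param draw a stable [day_draw()].
#' @param n_occ number of occasions in the day (at least 2).
#' @param init_range,exo_range sampling intervals for the initial moods and
#'   the exogenous input.
#' @param exo_per_day hold the exogenous value constant within the day?
#' @return A `data.frame` with columns `day`, `occasion` (`0 .. n_occ-1`),
#'   `m1..mk`, `e`, `observed`, and an attribute `"noiseless"` holding the
#'   noise-free mood trajectory as an `n_occ x k` matrix.
#' @export
simulate_day <- function(spec, draw, n_occ,
                         init_range = c(-0.5, 0.5), exo_range = c(0, 0.5),
                         exo_per_day = FALSE) {
  if (n_occ < 2L) stop("'n_occ' must be >= 2 (no transition possible)")
  if (isFALSE(draw$stable))
    stop("day ", draw$day_index, " has an unstable coefficient matrix")
  k <- spec$k
  B <- assemble_coefficients(spec, draw)
  m <- matrix(NA_real_, n_occ, k)
  m_true <- m
  m[1L, ] <- stats::runif(k, init_range[1L], init_range[2L])
  m_true[1L, ] <- m[1L, ]
  e <- if (exo_per_day) {
    rep(stats::runif(1L, exo_range[1L], exo_range[2L]), n_occ)
  } else {
    stats::runif(n_occ, exo_range[1L], exo_range[2L])
  }
  sd_eps <- sqrt(spec$sigma2)
  for (t in 2:n_occ) {
    mean_t <- B$B_ar %*% m[t - 1L, ] + B$B_e * e[t] + B$B_c
    m[t, ] <- mean_t + stats::rnorm(k, 0, sd_eps)
    m_true[t, ] <- B$B_ar %*% m_true[t - 1L, ] + B$B_e * e[t] + B$B_c
  }
  out <- data.frame(day = draw$day_index, occasion = 0:(n_occ - 1L))
  for (j in seq_len(k)) out[[paste0("m", j)]] <- m[, j]
  out$e <- e
  out$observed <- TRUE
  attr(out, "noiseless") <- m_true
  out
}

#' Simulate a full EMA dataset
#'
#' Draws `n_days` stable day-level coefficient sets, simulates each day,
#' applies missingness, and attaches the ground truth (day draws and
#' noiseless trajectories). Reproducible given `config$seed`; each day uses
#' its own derived RNG stream so days are independent.
#'
#' @param config a [sim_config()].
#' @return A long-format `data.frame` of class `"ema_dataset"` with columns
#'   `day`, `occasion`, `m1..mk`, `e`, `observed`, and attributes `spec`,
#'   `draws`, `noiseless`, `retention`.
#' @export
simulate_dataset <- function(config) {
  spec <- config$spec
  if (!is.null(config$seed)) set.seed(config$seed)
  day_seeds <- sample.int(.Machine$integer.max - 1L, config$n_days + 2L)
  cfg2 <- config
  cfg2$seed <- day_seeds[1L]
  draws <- sample_day_draws(cfg2)
  blocks <- vector("list", config$n_days)
  for (i in seq_len(config$n_days)) {
    set.seed(day_seeds[i + 1L])
    blocks[[i]] <- simulate_day(spec, draws[[i]], config$n_per_day,
                                init_range = config$init_range,
                                exo_range = config$exo_range,
                                exo_per_day = config$exo_per_day)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  noiseless <- do.call(rbind, lapply(blocks, attr, "noiseless"))
  attr(out, "spec") <- spec
  attr(out, "draws") <- draws
  attr(out, "noiseless") <- noiseless
  attr(out, "retention") <- attr(draws, "retention")
  class(out) <- c("ema_dataset", "data.frame")
  if (config$missing_rate > 0) {
    set.seed(day_seeds[config$n_days + 2L])
    out <- apply_missingness(out, config$missing_rate)
  }
  out
}

#' Mark occasions missing completely at random
#'
#' Each occasion (the whole prompt, all moods at once) is independently
#' marked unobserved with probability `rate`. Ground-truth attributes are
#' untouched.
#'
#' @param data an `"ema_dataset"` (or compatible long `data.frame`).
#' @param rate missingness probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return The dataset with updated `observed` flags.
#' @export
apply_missingness <- function(data, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("'rate' must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(data)
  miss <- stats::runif(nrow(data)) < rate
  data$observed <- data$observed & !miss
  data
}

#' Monte-Carlo signal-to-noise ratio of the data-generating process
#'
#' The SNR is the variance of the noiseless one-step signal
#' `B_ar m[t-1] + B_e e[t] + B_c` divided by the noise variance `sigma2`
#' (not in decibels). The signal variance is measured per mood channel over
#' noiseless trajectories — pooled across occasions and days, averaged over
#' the channels — with day-level coefficients redrawn (stability-retained)
#' per day. The trajectories are started from the neutral state 0 so that
#' the measured signal is the variance generated by the dynamics, inputs
#' and day-to-day coefficient variation rather than by the arbitrary
#' initial draw; see the package vignette for the rationale.
#'
#' @param spec a [larmex_spec()].
#' @param sigma2 noise variance; defaults to `spec$sigma2`. Must be > 0.
#' @param n_mc minimum number of simulated transitions to pool (>= 1e4
#'   recommended; the study calibration uses >= 1e5).
#' @param n_per_day occasions per simulated day.
#' @param exo_range exogenous input interval.
#' @param pooling `"per_channel"` (default; average of per-channel signal
#'   variances) or `"pooled"` (single variance across both channels, which
#'   additionally counts the between-channel mean separation as signal).
#' @param init either `"neutral"` (start at 0, default) or `"uniform"`
#'   (start from `init_range`).
#' @param init_range initial-value interval when `init = "uniform"`.
#' @param seed optional integer seed.
#' @return The estimated SNR (a single number).
#' @export
compute_snr <- function(spec, sigma2 = spec$sigma2, n_mc = 1e5,
                        n_per_day = 10L, exo_range = c(0, 0.5),
                        pooling = c("per_channel", "pooled"),
                        init = c("neutral", "uniform"),
                        init_range = c(-0.5, 0.5), seed = NULL) {
  pooling <- match.arg(pooling)
  init <- match.arg(init)
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop("'sigma2' must be > 0 (SNR undefined)")
  if (!is.null(seed)) set.seed(seed)
  k <- spec$k
  n_tr <- n_per_day - 1L
  n_days <- ceiling(n_mc / (k * n_tr))
  ## oversample candidates so that >= n_days survive the stability filter
  pool <- ceiling(n_days * 1.5) + 1000L
  cfg <- sim_config(spec, n_days = n_days, candidate_pool = pool)
  cfg$seed <- NULL
  draws <- sample_day_draws(cfg)
  q <- spec$q
  Bflat <- t(vapply(draws, flatten_ranef, numeric(q)))
  Bflat <- sweep(Bflat, 2L, c(as.vector(t(spec$beta_ar)), spec$beta_e,
                              spec$beta_c), "+")
  Bar <- Bflat[, seq_len(k^2), drop = FALSE]
  Be <- Bflat[, k^2 + seq_len(k), drop = FALSE]
  Bc <- Bflat[, k^2 + k + seq_len(k), drop = FALSE]
  m <- if (init == "neutral") {
    matrix(0, n_days, k)
  } else {
    matrix(stats::runif(n_days * k, init_range[1L], init_range[2L]), n_days, k)
  }
  S <- array(NA_real_, c(n_days, n_tr, k))
  for (t in seq_len(n_tr)) {
    e <- stats::runif(n_days, exo_range[1L], exo_range[2L])
    s <- matrix(0, n_days, k)
    for (r in seq_len(k)) {
      acc <- Bc[, r] + Be[, r] * e
      for (c in seq_len(k))
        acc <- acc + Bar[, (r - 1L) * k + c] * m[, c]
      s[, r] <- acc
    }
    S[, t, ] <- s
    m <- s
  }
  sig_var <- if (pooling == "per_channel") {
    mean(vapply(seq_len(k), function(r) stats::var(as.vector(S[, , r])),
                numeric(1L)))
  } else {
    stats::var(as.vector(S))
  }
  sig_var / sigma2
}

## --- file I/O -------------------------------------------------------------

#' Write / read EMA datasets as CSV
#'
#' The long format has one row per observation occasion with columns
#' `day, occasion, m1..mk, e, observed`.
#'
#' @param data an `"ema_dataset"` / long `data.frame`.
#' @param path file path.
#' @return `path` invisibly (`write_ema_csv`), or the dataset
#'   (`read_ema_csv`).
#' @export
write_ema_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ema_csv
#' @export
read_ema_csv <- function(path) {
  out <- utils::read.csv(path)
  need <- c("day", "occasion", "m1", "e", "observed")
  missing <- setdiff(need, names(out))
  if (length(missing))
    stop("EMA CSV is missing column(s): ", paste(missing, collapse = ", "))
  out$observed <- as.logical(out$observed)
  class(out) <- c("ema_dataset", "data.frame")
  out
}

#' Write the simulated ground truth as a sidecar CSV
#'
#' One row per day: the flattened true random effects (canonical order) and
#' the stability flag.
#'
#' @param data a simulated `"ema_dataset"` carrying a `draws` attribute.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(data, path) {
  draws <- attr(data, "draws")
  if (is.null(draws)) stop("dataset carries no ground-truth draws")
  k <- nrow(draws[[1L]]$b_ar)
  tab <- do.call(rbind, lapply(draws, function(d) {
    row <- as.data.frame(as.list(flatten_ranef(d)))
    cbind(data.frame(day = d$day_index), row, data.frame(stable = d$stable))
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
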