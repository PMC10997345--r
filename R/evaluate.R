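#' Run parameter-recovery replicates over a simulation grid
#'
#' For every grid cell (a combination of number of days `N`, noise variance
#' `sigma2`, and missingness rate) this simulates `n_reps` independent
#' datasets from the model — fresh stability-retained day draws each
#' replicate — fits each by [fit_larmex()], and records per-parameter
#' relative estimation errors `ree = |est - true| / |true|`.
#'
#' One row is produced per replicate and parameter. Fixed effects get
#' groups `fixed_ar`, `fixed_exo`, `fixed_const`; fitted variance
#' components get `g_var` and `sigma2`. BLUP rows (one per day and random
#' effect, groups `blup_ar`, `blup_exo`, `blup_const`) compare the day's
#' realized network coefficient `beta + b_i` against its prediction
#' `beta_hat + blup_i`: the day-varying coefficient is the quantity with a
#' network interpretation, and a relative error on the zero-mean deviation
#' `b_i` alone is dominated by true values arbitrarily close to zero. The
#' raw deviations are kept in columns `b_true` / `b_est`.
#'
#' Individual fit failures are recorded (`converged = FALSE`, `ree = NA`
#' when the fit errors out) and are not fatal; a cell only errors when more
#' than half of its fits fail.
#'
#' @param spec a [larmex_spec()]; its `sigma2` is overridden per cell.
#' @param grid data frame (or list for [expand.grid()]) with any of the
#'   columns `N`, `sigma2`, `missing_rate`; missing columns get defaults
#'   `N = 36`, `sigma2 = spec$sigma2`, `missing_rate = 0`.
#' @param n_reps replicates per cell (>= 1).
#' @param seed root seed; every (cell, replicate) pair gets its own derived
#'   seed so the run is reproducible and parallelizable.
#' @param n_per_day nominal observations per day.
#' @param candidate_pool rejection-sampling pool per replicate.
#' @param structure,method passed to [fit_larmex()].
#' @return A `data.frame` of class `"larmex_records"` with columns `cell`,
#'   `N`, `sigma2`, `missing_rate`, `k`, `rep`, `group`, `param`, `day`,
#'   `true`, `est`, `se`, `ree`, `converged`.
#' @export
run_replicates <- function(spec, grid, n_reps, seed = 1L, n_per_day = 10L,
                           candidate_pool = 20000L, structure = "diagonal",
                           method = "REML") {
  if (n_reps < 1L) stop("'n_reps' must be >= 1")
  if (!is.data.frame(grid)) grid <- expand.grid(grid)
  if (is.null(grid$N)) grid$N <- 36L
  if (is.null(grid$sigma2)) grid$sigma2 <- spec$sigma2
  if (is.null(grid$missing_rate)) grid$missing_rate <- 0
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, nrow(grid) * n_reps),
                  nrow(grid), n_reps)
  out <- vector("list", nrow(grid) * n_reps)
  idx <- 0L
  for (ci in seq_len(nrow(grid))) {
    cell_spec <- spec
    cell_spec$sigma2 <- grid$sigma2[ci]
    n_fail <- 0L
    for (r in seq_len(n_reps)) {
      idx <- idx + 1L
      rec <- tryCatch(
        one_replicate(cell_spec, N = grid$N[ci],
                      missing_rate = grid$missing_rate[ci],
                      n_per_day = n_per_day, candidate_pool = candidate_pool,
                      structure = structure, method = method,
                      seed = seeds[ci, r]),
        error = function(e) NULL)
      if (is.null(rec)) {
        n_fail <- n_fail + 1L
        rec <- data.frame(group = "fixed_ar", param = NA_character_,
                          day = NA_integer_, true = NA_real_, est = NA_real_,
                          se = NA_real_, b_true = NA_real_, b_est = NA_real_,
                          ree = NA_real_, converged = FALSE)
      }
      rec$cell <- ci
      rec$N <- grid$N[ci]
      rec$sigma2 <- grid$sigma2[ci]
      rec$missing_rate <- grid$missing_rate[ci]
      rec$k <- spec$k
      rec$rep <- r
      out[[idx]] <- rec
    }
    if (n_fail > n_reps / 2)
      stop(sprintf("more than half of the fits failed in cell %d (N=%d, sigma2=%g, missing=%g)",
                   ci, grid$N[ci], grid$sigma2[ci], grid$missing_rate[ci]))
  }
  records <- do.call(rbind, out)
  front <- c("cell", "N", "sigma2", "missing_rate", "k", "rep")
  records <- records[, c(front, setdiff(names(records), front))]
  class(records) <- c("larmex_records", "data.frame")
  records
}

one_replicate <- function(spec, N, missing_rate, n_per_day, candidate_pool,
                          structure, method, seed) {
  cfg <- sim_config(spec, n_days = N, n_per_day = n_per_day,
                    candidate_pool = candidate_pool,
                    missing_rate = missing_rate, seed = seed)
  data <- simulate_dataset(cfg)
  stacked <- stack_dataset(data, spec$k)
  fit <- suppressMessages(fit_larmex(stacked, structure = structure,
                                     method = method))
  replicate_record(spec, data, fit)
}

## Per-parameter comparison of one fit against the simulation truth.
replicate_record <- function(spec, data, fit) {
  k <- spec$k
  q <- spec$q
  nm <- ranef_names(k)
  grp <- c(rep("ar", k^2), rep("exo", k), rep("const", k))
  truth_beta <- c(as.vector(t(spec$beta_ar)), spec$beta_e, spec$beta_c)
  se <- sqrt(pmax(diag(fit$cov_beta), 0))
  fixed <- data.frame(group = paste0("fixed_", grp), param = nm,
                      day = NA_integer_, true = truth_beta,
                      est = as.numeric(fit$beta_hat), se = se)
  varcomp <- data.frame(group = c(rep("g_var", q), "sigma2"),
                        param = c(paste0("g_", nm), "sigma2"),
                        day = NA_integer_,
                        true = c(diag(spec$G), spec$sigma2),
                        est = c(diag(fit$G_hat), fit$sigma2_hat),
                        se = NA_real_)
  draws <- attr(data, "draws")
  fitted_days <- fit$day_index
  true_b <- t(vapply(draws, flatten_ranef, numeric(q)))
  keep <- vapply(draws, function(d) d$day_index, 0) %in% fitted_days
  true_b <- true_b[keep, , drop = FALSE]
  blups <- fit$blups
  ## day-level coefficients: realized beta + b_i vs predicted beta_hat + blup
  B_true <- sweep(true_b, 2L, truth_beta, "+")
  B_est <- sweep(blups, 2L, as.numeric(fit$beta_hat), "+")
  blup_rows <- data.frame(
    group = rep(paste0("blup_", grp), each = nrow(blups)),
    param = rep(nm, each = nrow(blups)),
    day = rep(fitted_days, times = q),
    true = as.numeric(B_true), est = as.numeric(B_est), se = NA_real_)
  fixed$b_true <- NA_real_
  fixed$b_est <- NA_real_
  varcomp$b_true <- NA_real_
  varcomp$b_est <- NA_real_
  blup_rows$b_true <- as.numeric(true_b)
  blup_rows$b_est <- as.numeric(blups)
  rec <- rbind(fixed, varcomp, blup_rows)
  rec$ree <- ifelse(rec$true != 0, abs(rec$est - rec$true) / abs(rec$true),
                    NA_real_)
  rec$converged <- fit$converged
  rec
}

#' Percentile bootstrap confidence intervals per cell and parameter
#'
#' Summarizes a replicate table into per-cell percentile intervals (default
#' 2.5%, 50%, 97.5%) for every fixed effect and for the random-effect
#' standard deviations (reported on the SD scale).
#'
#' @param records a [run_replicates()] table.
#' @param level confidence level (default 0.95).
#' @return A `data.frame` with one row per (cell, parameter): `lower`,
#'   `median`, `upper`, `n_reps`.
#' @export
bootstrap_ci <- function(records, level = 0.95) {
  alpha <- (1 - level) / 2
  rec <- records[records$group %in%
                   c("fixed_ar", "fixed_exo", "fixed_const", "g_var", "sigma2") &
                   !is.na(records$est), , drop = FALSE]
  rec$est[rec$group == "g_var"] <- sqrt(rec$est[rec$group == "g_var"])
  rec$true[rec$group == "g_var"] <- sqrt(rec$true[rec$group == "g_var"])
  key <- interaction(rec$cell, rec$param, drop = TRUE)
  pieces <- split(rec, key)
  small <- vapply(pieces, nrow, 0L) < 20L
  if (any(small))
    stop("fewer than 20 replicates for: ",
         paste(utils::head(names(pieces)[small], 5L), collapse = ", "))
  out <- do.call(rbind, lapply(pieces, function(p) {
    qs <- stats::quantile(p$est, c(alpha, 0.5, 1 - alpha), names = FALSE)
    data.frame(cell = p$cell[1L], N = p$N[1L], sigma2 = p$sigma2[1L],
               missing_rate = p$missing_rate[1L], group = p$group[1L],
               param = p$param[1L], true = p$true[1L],
               lower = qs[1L], median = qs[2L], upper = qs[3L],
               n_reps = nrow(p))
  }))
  rownames(out) <- NULL
  out[order(out$cell, out$group, out$param), ]
}

#' Median (or mean) relative estimation error by parameter group
#'
#' Groups follow the network representation: fixed autoregressive, fixed
#' exogenous, BLUP autoregressive, BLUP exogenous. Constants are excluded,
#' as are BLUP comparisons whose true day-level coefficient is at most
#' `exclude_below` in magnitude (relative error is unstable near zero).
#'
#' @param records a [run_replicates()] table.
#' @param exclude_below magnitude threshold for true day-level coefficients
#'   (default 0.02).
#' @param stat `"median"` (default) or `"mean"`.
#' @return A `data.frame` with one row per (cell, group) plus the combined
#'   `fixed` and `blup` rows; column `ree` holds the summary.
#' @export
ree_summary <- function(records, exclude_below = 0.02,
                        stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "median") stats::median else mean
  rec <- records[records$group %in% c("fixed_ar", "fixed_exo",
                                      "blup_ar", "blup_exo") &
                   !is.na(records$ree), , drop = FALSE]
  drop_blup <- grepl("^blup", rec$group) & abs(rec$true) <= exclude_below
  rec <- rec[!drop_blup, , drop = FALSE]
  if (!nrow(rec)) {
    out <- data.frame(cell = integer(0), N = integer(0), sigma2 = numeric(0),
                      missing_rate = numeric(0), group = character(0),
                      ree = numeric(0), stat = character(0))
    return(out)
  }
  rec$family <- ifelse(grepl("^fixed", rec$group), "fixed", "blup")
  per_group <- stats::aggregate(ree ~ cell + N + sigma2 + missing_rate + group,
                                data = rec, FUN = f)
  per_family <- stats::aggregate(ree ~ cell + N + sigma2 + missing_rate + family,
                                 data = rec, FUN = f)
  names(per_family)[names(per_family) == "family"] <- "group"
  out <- rbind(per_group, per_family)
  out$stat <- stat
  out[order(out$cell, out$group), ]
}

#' Median fixed-effect error as a function of compliance
#'
#' Runs the recovery experiment over a grid of day counts and
#' missing-completely-at-random rates and tabulates the median relative
#' estimation error of the network fixed effects per cell.
#'
#' @param spec a [larmex_spec()].
#' @param N_list day counts.
#' @param rates missingness rates (default `c(0, 0.1, 0.2, 0.3)`).
#' @param n_reps replicates per cell.
#' @param seed root seed.
#' @param ... passed to [run_replicates()].
#' @return List with `table` (rows `N`, columns one per rate, entries
#'   median fixed-effect REE) and the underlying `records`.
#' @export
missingness_curve <- function(spec, N_list, rates = c(0, 0.1, 0.2, 0.3),
                              n_reps = 100L, seed = 1L, ...) {
  if (any(rates < 0 | rates >= 1)) stop("rates must be in [0, 1)")
  grid <- expand.grid(N = N_list, missing_rate = rates)
  records <- run_replicates(spec, grid, n_reps = n_reps, seed = seed, ...)
  summ <- ree_summary(records)
  fixed <- summ[summ$group == "fixed", ]
  tab <- stats::xtabs(ree ~ N + missing_rate, data = fixed)
  list(table = tab, records = records)
}

#' Scalability comparison between network sizes
#'
#' Runs the recovery experiment for a two-mood and a four-mood network at
#' matched day counts and tabulates average fixed- and random-effect
#' relative estimation errors per day count and network size.
#'
#' @param spec_k2,spec_k4 the two specifications (see [example_spec()]).
#' @param N_list day counts.
#' @param n_reps replicates per cell.
#' @param seed root seed.
#' @param ... passed to [run_replicates()].
#' @return List with `table` (columns `k`, `N`, `fixed`, `blup` median REE)
#'   and the per-size `records`.
#' @export
scaling_comparison <- function(spec_k2, spec_k4, N_list, n_reps = 20L,
                               seed = 1L, ...) {
  run_one <- function(spec, off) {
    records <- run_replicates(spec, data.frame(N = N_list), n_reps = n_reps,
                              seed = seed + off, ...)
    summ <- ree_summary(records)
    data.frame(k = spec$k,
               N = summ$N[summ$group == "fixed"],
               fixed = summ$ree[summ$group == "fixed"],
               blup = summ$ree[summ$group == "blup"],
               records = I(list(records)))
  }
  r2 <- run_one(spec_k2, 0L)
  r4 <- run_one(spec_k4, 1L)
  tab <- rbind(r2[, c("k", "N", "fixed", "blup")],
               r4[, c("k", "N", "fixed", "blup")])
  list(table = tab, records_k2 = r2$records[[1L]], records_k4 = r4$records[[1L]])
}

#' Approximate power against per-parameter null cutoffs
#'
#' For each replicate a Wald interval `est +/- z * se` is formed for every
#' fixed effect; the null value `cutoff` is rejected when it falls outside
#' the interval. The per-cell rejection fraction approximates power when
#' the cutoff differs from the true value (and the type-I error rate when
#' it equals it).
#'
#' @param records a [run_replicates()] table.
#' @param cutoffs named numeric vector of null values, names matching the
#'   fixed-effect parameters (see [ranef_names()]).
#' @param level confidence level of the Wald interval.
#' @return A `data.frame` with one row per (cell, parameter) and column
#'   `power`.
#' @export
power_analysis <- function(records, cutoffs, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  rec <- records[grepl("^fixed", records$group) &
                   records$param %in% names(cutoffs) &
                   !is.na(records$est), , drop = FALSE]
  rec$cutoff <- cutoffs[rec$param]
  rec$reject <- abs(rec$est - rec$cutoff) > z * rec$se
  out <- stats::aggregate(reject ~ cell + N + sigma2 + missing_rate + param,
                          data = rec, FUN = mean)
  names(out)[names(out) == "reject"] <- "power"
  out
}
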