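#' Build one day's stacked design from long-format EMA data
#'
#' Transforms a day block into the stacked mixed-model form
#' `Y = X beta + Z b + eps`. A transition row is created for the occasion
#' pair `(t-1, t)` only when both occasions were observed and are adjacent
#' in the nominal schedule (listwise deletion of broken pairs; no pairs
#' across days). The response is the mood at `t`, the covariates are the
#' lagged moods at `t-1` and the exogenous value at `t` (contemporaneous
#' with the response), plus a constant.
#'
#' Rows are stacked channel-major: all mood-1 rows, then all mood-2 rows,
#' and so on. Columns follow the canonical coefficient order (see
#' [ranef_names()]): for mood channel `c`, the lagged moods occupy columns
#' `(c-1)k+1 .. ck`, the exogenous value column `k^2 + c`, and the constant
#' column `k^2 + k + c`; all other entries are zero. In the full model the
#' fixed- and random-effects designs coincide, `X = Z`.
#'
#' @param day_df one day's rows (columns `occasion`, `m1..mk`, `e`,
#'   `observed`), occasions sorted increasing.
#' @param k number of mood variables.
#' @return An object of class `"larmex_stacked_day"` (list with
#'   `day_index`, `Y`, `X`, `Z`, `n_transitions`), or `NULL` when the day
#'   has no usable transition.
#' @export
build_day_design <- function(day_df, k) {
  mood_cols <- paste0("m", seq_len(k))
  if (!all(mood_cols %in% names(day_df)))
    stop("day block does not contain mood columns ", paste(mood_cols, collapse = ", "),
         "; does 'k' match the data?")
  day_df <- day_df[order(day_df$occasion), , drop = FALSE]
  occ <- day_df$occasion
  obs <- day_df$observed
  ## usable pairs: consecutive nominal occasions, both observed
  pair_to <- which(obs[-1L] & obs[-length(obs)] & diff(occ) == 1L) + 1L
  n_tr <- length(pair_to)
  if (n_tr == 0L) return(NULL)
  q <- k^2 + 2L * k
  M <- as.matrix(day_df[, mood_cols, drop = FALSE])
  lag <- M[pair_to - 1L, , drop = FALSE]
  e <- day_df$e[pair_to]
  Y <- numeric(k * n_tr)
  X <- matrix(0, k * n_tr, q)
  for (c in seq_len(k)) {
    rows <- (c - 1L) * n_tr + seq_len(n_tr)
    Y[rows] <- M[pair_to, c]
    X[rows, (c - 1L) * k + seq_len(k)] <- lag
    X[rows, k^2 + c] <- e
    X[rows, k^2 + k + c] <- 1
  }
  colnames(X) <- ranef_names(k)
  structure(list(day_index = day_df$day[1L], Y = Y, X = X, Z = X,
                 n_transitions = n_tr),
            class = "larmex_stacked_day")
}

#' Stack a whole EMA dataset into mixed-model form
#'
#' Applies [build_day_design()] to every day and pools the result. Days
#' without a single usable transition are dropped with a warning.
#'
#' @param data long-format EMA data (columns `day`, `occasion`, `m1..mk`,
#'   `e`, `observed`).
#' @param k number of mood variables; by default inferred from the `m*`
#'   columns.
#' @return An object of class `"larmex_stacked"`: list with `days` (list of
#'   stacked days), `k`, `q`, `total_obs` (sum of `k * n_transitions`),
#'   `dropped_days`.
#' @export
stack_dataset <- function(data, k = NULL) {
  if (is.null(k)) k <- sum(grepl("^m[0-9]+$", names(data)))
  if (k < 1L) stop("could not infer 'k' from the data columns")
  day_ids <- unique(data$day)
  days <- list()
  dropped <- integer(0)
  for (d in day_ids) {
    sd <- build_day_design(data[data$day == d, , drop = FALSE], k)
    if (is.null(sd)) dropped <- c(dropped, d) else days[[length(days) + 1L]] <- sd
  }
  if (length(dropped))
    warning("dropped ", length(dropped), " day(s) with no usable transitions: ",
            paste(dropped, collapse = ", "))
  if (!length(days))
    stop("no usable transitions in the dataset")
  structure(list(days = days, k = as.integer(k),
                 q = as.integer(k^2 + 2 * k),
                 total_obs = as.integer(sum(vapply(days, function(d)
                   length(d$Y), 0L))),
                 dropped_days = as.integer(dropped)),
            class = "larmex_stacked")
}

#' @export
print.larmex_stacked <- function(x, ...) {
  cat("Stacked LARMEx data: ", length(x$days), " day(s), k = ", x$k,
      ", q = ", x$q, ", ", x$total_obs, " stacked observations\n", sep = "")
  if (length(x$dropped_days))
    cat("  dropped days:", paste(x$dropped_days, collapse = ", "), "\n")
  invisible(x)
}

#' Rule-of-thumb identifiability check
#'
#' Predicting `q = k^2 + 2k` random effects per day requires the number of
#' stacked observations, `k * sum(n_i - 1)`, to surpass the number of
#' random effects, `q * N`. With a balanced design this reduces to the
#' bound `k < n_bar - 2`, where `n_bar` is the mean number of observed
#' occasions per day. The check warns but never aborts.
#'
#' @param stacked a [stack_dataset()] result.
#' @return Invisibly, a list with `n_obs`, `n_ranef`, `ok`, `k`, `n_bar`,
#'   `bound_ok` (`k < n_bar - 2`). A warning is signalled when `ok` is
#'   `FALSE`.
#' @export
check_identifiability <- function(stacked) {
  k <- stacked$k
  N <- length(stacked$days)
  n_obs <- stacked$total_obs
  n_ranef <- as.integer(stacked$q * N)
  n_bar <- mean(vapply(stacked$days, function(d) d$n_transitions + 1, 0))
  out <- list(n_obs = n_obs, n_ranef = n_ranef, ok = n_obs > n_ranef,
              k = k, n_bar = n_bar, bound_ok = k < n_bar - 2)
  if (!out$ok)
    warning(sprintf(paste0("identifiability rule of thumb fails: %d stacked ",
                           "observations for %d random effects (k = %d should ",
                           "be less than n_bar - 2 = %.1f)"),
                    n_obs, n_ranef, k, n_bar - 2))
  invisible(out)
}
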