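#' Model specification for an exogenous linear autoregressive mixed-effects
#' network
#'
#' A LARMEx model describes `k` mood variables measured repeatedly within
#' days. Within day `i` the moods evolve as a first-order vector
#' autoregression with an exogenous input,
#' `m[t] = B_ar %*% m[t-1] + B_e * e[t] + B_c + eps[t]`, where every
#' coefficient is the sum of a subject-level fixed effect (`beta_*`, the
#' trait) and a day-level random effect (`b_*`, the state) drawn from
#' `N(0, G)`. Residuals are white noise with variance `sigma2` per channel.
#'
#' The `q = k^2 + 2k` random effects are ordered row-major over the
#' autoregressive matrix, then the exogenous coefficients, then the
#' constants; this order is shared with the design-matrix columns built by
#' [build_day_design()].
#'
#' @param beta_ar `k x k` matrix of fixed auto-/cross-lagged coefficients.
#'   Its spectral radius must be below 1 (a stable trait network).
#' @param beta_e length-`k` vector of fixed contemporaneous exogenous
#'   coefficients.
#' @param beta_c length-`k` vector of fixed constants (default zero).
#' @param G `q x q` symmetric positive semi-definite random-effects
#'   covariance with `q = k^2 + 2k`.
#' @param G_structure covariance structure tag, one of `"diagonal"`,
#'   `"compound_symmetric"`, `"block_cs_ar_exo_independent"`. Under
#'   `"diagonal"` all off-diagonal entries of `G` must be exactly zero.
#' @param sigma2 residual noise variance, strictly positive.
#'
#' @return An object of class `"larmex_spec"`: a list with elements `k`,
#'   `q`, `beta_ar`, `beta_e`, `beta_c`, `G`, `G_structure`, `sigma2`.
#' @seealso [example_spec()], [day_draw()], [assemble_coefficients()]
#' @export
larmex_spec <- function(beta_ar, beta_e, beta_c = NULL, G,
                        G_structure = c("diagonal", "compound_symmetric",
                                        "block_cs_ar_exo_independent"),
                        sigma2) {
  G_structure <- match.arg(G_structure)
  beta_ar <- as.matrix(beta_ar)
  k <- nrow(beta_ar)
  if (k < 1L || ncol(beta_ar) != k)
    stop("'beta_ar' must be a square k x k matrix with k >= 1")
  beta_e <- as.numeric(beta_e)
  if (length(beta_e) != k)
    stop("'beta_e' must have length k = ", k)
  if (is.null(beta_c)) beta_c <- rep(0, k)
  beta_c <- as.numeric(beta_c)
  if (length(beta_c) != k)
    stop("'beta_c' must have length k = ", k)
  q <- as.integer(k^2) + 2L * k
  G <- as.matrix(G)
  if (nrow(G) != q || ncol(G) != q)
    stop("'G' must be ", q, " x ", q, " (q = k^2 + 2k)")
  if (max(abs(G - t(G))) > 1e-10 * max(1, max(abs(G))))
    stop("'G' must be symmetric")
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(ev)))
    stop("'G' must be positive semi-definite")
  if (G_structure == "diagonal" && any(G[upper.tri(G)] != 0))
    stop("off-diagonal entries of 'G' must be exactly 0 under the diagonal structure")
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop("'sigma2' must be strictly positive")
  if (!all(is.finite(beta_ar)))
    stop("'beta_ar' has non-finite entries")
  if (max(Mod(eigen(beta_ar, only.values = TRUE)$values)) >= 1)
    stop("spectral radius of 'beta_ar' must be below 1")
  structure(
    list(k = k, q = q, beta_ar = beta_ar, beta_e = beta_e, beta_c = beta_c,
         G = G, G_structure = G_structure, sigma2 = sigma2),
    class = "larmex_spec"
  )
}

#' @export
print.larmex_spec <- function(x, ...) {
  cat("LARMEx model specification\n")
  cat("  moods (k):", x$k, "  random effects (q):", x$q, "\n")
  cat("  beta_ar:\n")
  print(round(x$beta_ar, 4))
  cat("  beta_e: ", paste(round(x$beta_e, 4), collapse = " "), "\n")
  cat("  beta_c: ", paste(round(x$beta_c, 4), collapse = " "), "\n")
  cat("  G: ", x$G_structure, ", mean diag ", round(mean(diag(x$G)), 4),
      "; sigma2 = ", x$sigma2, "\n", sep = "")
  invisible(x)
}

#' Canonical example networks
#'
#' The moderately connected two-mood network used throughout the simulation
#' study: positive self-loops of 0.3, cross-lagged couplings of -0.3, and an
#' external-factor node activating mood 1 (+0.3) and suppressing mood 2
#' (-0.3), with zero constants, independent day-level random effects of
#' variance `g` on all coefficients, and noise variance `sigma2`.
#'
#' For `k = 4` (two positive- and two negative-valence moods) no canonical
#' coefficients are established; the returned stand-in uses self-loops of
#' 0.3, within-valence couplings of +0.15, between-valence couplings of
#' -0.15 (spectral radius 0.75), exogenous +0.3 on the positive and -0.3 on
#' the negative moods, and a diagonal `G` whose default variance is
#' calibrated so that the signal-to-noise ratio at `sigma2 = 0.02` is about
#' 6, matching the two-mood setting.
#'
#' @param k network size, 2 or 4.
#' @param sigma2 residual noise variance.
#' @param g day-level random-effect variance (diagonal of `G`). The default
#'   is 0.03 for `k = 2` and 0.0235 for `k = 4`.
#' @return A [larmex_spec()].
#' @export
example_spec <- function(k = 2, sigma2 = 0.02, g = NULL) {
  if (k == 2) {
    if (is.null(g)) g <- 0.03
    beta_ar <- matrix(c(0.3, -0.3, -0.3, 0.3), 2, 2, byrow = TRUE)
    beta_e <- c(0.3, -0.3)
  } else if (k == 4) {
    if (is.null(g)) g <- 0.0235
    s <- 0.15
    beta_ar <- matrix(-s, 4, 4)
    beta_ar[1:2, 1:2] <- s
    beta_ar[3:4, 3:4] <- s
    diag(beta_ar) <- 0.3
    beta_e <- c(0.3, 0.3, -0.3, -0.3)
  } else {
    stop("only k = 2 and k = 4 example networks are provided")
  }
  q <- k^2 + 2L * k
  larmex_spec(beta_ar, beta_e, rep(0, k), diag(g, q),
              G_structure = "diagonal", sigma2 = sigma2)
}

#' Names of the stacked random-effect / fixed-effect vector
#'
#' Order: autoregressive coefficients row-major (`ar_r_c` is the effect of
#' mood `c` at t-1 on mood `r` at t), then exogenous (`e_1 .. e_k`), then
#' constants (`c_1 .. c_k`).
#'
#' @param k number of mood variables.
#' @return Character vector of length `k^2 + 2k`.
#' @export
ranef_names <- function(k) {
  ar <- as.vector(t(outer(seq_len(k), seq_len(k),
                          function(r, c) paste0("ar_", r, "_", c))))
  c(ar, paste0("e_", seq_len(k)), paste0("c_", seq_len(k)))
}

#' One day's realized random effects
#'
#' @param b_ar `k x k` matrix of day-level autoregressive deviations.
#' @param b_e length-`k` vector of exogenous deviations.
#' @param b_c length-`k` vector of constant deviations.
#' @param day_index integer day label.
#' @param spec optional [larmex_spec()]; when given, the `stable` flag is
#'   computed from the summed matrix `beta_ar + b_ar`.
#' @return An object of class `"larmex_draw"` with fields `day_index`,
#'   `b_ar`, `b_e`, `b_c`, `stable`.
#' @export
day_draw <- function(b_ar, b_e, b_c, day_index = 1L, spec = NULL) {
  b_ar <- as.matrix(b_ar)
  k <- nrow(b_ar)
  if (ncol(b_ar) != k) stop("'b_ar' must be square")
  if (length(b_e) != k) stop("'b_e' must have length ", k)
  if (length(b_c) != k) stop("'b_c' must have length ", k)
  stable <- if (is.null(spec)) NA else is_stable(spec$beta_ar + b_ar)
  structure(list(day_index = as.integer(day_index), b_ar = b_ar,
                 b_e = as.numeric(b_e), b_c = as.numeric(b_c),
                 stable = stable),
            class = "larmex_draw")
}

#' Flatten a day draw into the canonical q-vector
#'
#' Row-major `b_ar`, then `b_e`, then `b_c` — the same order as the columns
#' of the random-effects design matrix `Z`.
#'
#' @param draw a [day_draw()].
#' @return Named numeric vector of length `k^2 + 2k`.
#' @export
flatten_ranef <- function(draw) {
  k <- nrow(draw$b_ar)
  out <- c(as.vector(t(draw$b_ar)), draw$b_e, draw$b_c)
  names(out) <- ranef_names(k)
  out
}

#' Rebuild a day draw from a flattened q-vector
#'
#' @param b numeric vector of length `k^2 + 2k` in the canonical order.
#' @param k number of mood variables.
#' @param day_index integer day label.
#' @param spec optional [larmex_spec()] to compute the stability flag.
#' @return A [day_draw()].
#' @export
unflatten_ranef <- function(b, k, day_index = 1L, spec = NULL) {
  q <- k^2 + 2L * k
  if (length(b) != q) stop("'b' must have length ", q)
  day_draw(matrix(b[seq_len(k^2)], k, k, byrow = TRUE),
           b[k^2 + seq_len(k)], b[k^2 + k + seq_len(k)],
           day_index = day_index, spec = spec)
}

#' Day-level coefficients as the sum of fixed and random effects
#'
#' @param spec a [larmex_spec()].
#' @param draw a [day_draw()] with matching dimensions.
#' @return List with components `B_ar` (`k x k`), `B_e`, `B_c` (length `k`).
#' @export
assemble_coefficients <- function(spec, draw) {
  k <- spec$k
  if (!identical(dim(draw$b_ar), dim(spec$beta_ar)))
    stop("dimension mismatch between 'beta_ar' and 'b_ar'")
  if (length(draw$b_e) != k)
    stop("dimension mismatch between 'beta_e' and 'b_e'")
  if (length(draw$b_c) != k)
    stop("dimension mismatch between 'beta_c' and 'b_c'")
  list(B_ar = spec$beta_ar + draw$b_ar,
       B_e = spec$beta_e + draw$b_e,
       B_c = spec$beta_c + draw$b_c)
}

#' Stability of an autoregressive coefficient matrix
#'
#' A VAR(1) day is stable when every eigenvalue of its coefficient matrix
#' has modulus strictly below 1 (spectral radius criterion).
#'
#' @param B_ar square coefficient matrix.
#' @return `TRUE` or `FALSE`.
#' @export
is_stable <- function(B_ar) {
  B_ar <- as.matrix(B_ar)
  if (nrow(B_ar) != ncol(B_ar)) stop("'B_ar' must be square")
  if (!all(is.finite(B_ar))) stop("'B_ar' has non-finite entries")
  max(Mod(eigen(B_ar, only.values = TRUE)$values)) < 1
}

#' Sign pattern of the network edges
#'
#' The network representation keeps only the autoregressive and exogenous
#' coefficients; constants carry no edge.
#'
#' @param spec a [larmex_spec()].
#' @return List with entrywise signs `ar_signs` (`k x k`) and `e_signs`
#'   (length `k`), values in `-1, 0, 1`.
#' @export
sign_pattern <- function(spec) {
  list(ar_signs = sign(spec$beta_ar), e_signs = sign(spec$beta_e))
}

#' Does a day preserve the trait network's sign structure?
#'
#' `TRUE` when every summed autoregressive and exogenous coefficient
#' `beta + b` has the same strict sign as its fixed effect. Edges whose
#' fixed effect is exactly zero are excluded from the check; a summed
#' coefficient that is exactly zero counts as not preserved.
#'
#' @param spec a [larmex_spec()].
#' @param draw a [day_draw()].
#' @return `TRUE` or `FALSE`.
#' @export
sign_preserved <- function(spec, draw) {
  B <- assemble_coefficients(spec, draw)
  fixed <- c(as.vector(t(spec$beta_ar)), spec$beta_e)
  summed <- c(as.vector(t(B$B_ar)), B$B_e)
  keep <- fixed != 0
  all(sign(summed[keep]) == sign(fixed[keep]))
}

## --- config file serialization -------------------------------------------

#' Write a model specification to a YAML config file
#'
#' `G` is stored by structure: its shared (or per-effect) variance and the
#' off-diagonal covariance, under nested keys `G: {structure, variance,
#' covariance}`.
#'
#' @param spec a [larmex_spec()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spec_config <- function(spec, path) {
  v <- diag(spec$G)
  if (max(v) - min(v) < 1e-12) v <- v[1]
  off <- spec$G[upper.tri(spec$G)]
  cov <- if (length(off) && max(abs(off)) > 0) off[which.max(abs(off))] else 0
  cfg <- list(
    k = spec$k,
    beta_ar = lapply(seq_len(spec$k), function(r) as.numeric(spec$beta_ar[r, ])),
    beta_e = as.numeric(spec$beta_e),
    beta_c = as.numeric(spec$beta_c),
    G = list(structure = spec$G_structure,
             variance = as.numeric(v),
             covariance = as.numeric(cov)),
    sigma2 = spec$sigma2
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a model specification from a YAML config file
#'
#' @param path file written by [write_spec_config()] or hand-authored with
#'   keys `k`, `beta_ar`, `beta_e`, `beta_c`, `G.structure`, `G.variance`,
#'   `G.covariance`, `sigma2`.
#' @return A [larmex_spec()].
#' @export
read_spec_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("k", "beta_ar", "beta_e", "G", "sigma2")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("config is missing key(s): ", paste(missing, collapse = ", "))
  k <- as.integer(cfg$k)
  q <- k^2 + 2L * k
  beta_ar <- do.call(rbind, lapply(cfg$beta_ar, as.numeric))
  structure_tag <- cfg$G$structure %||% "diagonal"
  v <- as.numeric(cfg$G$variance)
  if (length(v) == 1L) v <- rep(v, q)
  if (length(v) != q) stop("G.variance must be scalar or length ", q)
  covv <- as.numeric(cfg$G$covariance %||% 0)
  G <- build_G(v, covv, structure_tag, k)
  larmex_spec(beta_ar, as.numeric(cfg$beta_e),
              as.numeric(cfg$beta_c %||% rep(0, k)),
              G, G_structure = structure_tag, sigma2 = as.numeric(cfg$sigma2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a covariance matrix from variance/covariance summaries
#'
#' @param v per-effect variances (length `q`).
#' @param covv shared off-diagonal covariance.
#' @param structure_tag one of the structures accepted by [larmex_spec()].
#' @param k number of mood variables.
#' @return `q x q` covariance matrix.
#' @keywords internal
build_G <- function(v, covv, structure_tag, k) {
  q <- k^2 + 2L * k
  G <- diag(v, q)
  if (structure_tag == "compound_symmetric" && covv != 0) {
    G[] <- covv
    diag(G) <- v
  } else if (structure_tag == "block_cs_ar_exo_independent" && covv != 0) {
    ar <- seq_len(k^2)
    ex <- (k^2 + 1L):q
    G[ar, ar] <- covv
    G[ex, ex] <- covv
    diag(G) <- v
  }
  G
}
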