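#' Unconstrained parameterization of the covariance components
#'
#' Maps `(G, sigma2)` to an unconstrained real vector `theta` and back.
#' Variances enter on the log-standard-deviation scale; compound-symmetric
#' correlations through a scaled logistic onto the positive-definite range
#' `(-1/(block-1), 1)`. The decoded `G` is always positive semi-definite
#' and the decoded `sigma2` always positive.
#'
#' * `diagonal`: `theta = (log sd_1 .. log sd_q, log sigma)`.
#' * `compound_symmetric`: `theta = (log sd, z(rho), log sigma)` — one
#'   shared variance and one shared correlation.
#' * `block_cs_ar_exo_independent`: as compound symmetric, but the shared
#'   correlation applies within the autoregressive block and within the
#'   exogenous/constant block only; the two blocks are independent.
#'
#' @param G random-effects covariance.
#' @param sigma2 residual variance.
#' @param structure covariance structure tag.
#' @param k number of mood variables.
#' @param theta unconstrained parameter vector.
#' @return `encode_cov_param` returns `theta`; `decode_cov_param` returns
#'   `list(G, sigma2)`.
#' @export
encode_cov_param <- function(G, sigma2, structure = "diagonal", k) {
  q <- k^2 + 2L * k
  if (structure == "diagonal") {
    c(0.5 * log(pmax(diag(G), 1e-300)), 0.5 * log(sigma2))
  } else {
    v <- mean(diag(G))
    off <- if (structure == "compound_symmetric") {
      G[upper.tri(G)]
    } else {
      ar <- seq_len(k^2)
      c(G[ar, ar][upper.tri(G[ar, ar])],
        G[-ar, -ar][upper.tri(G[-ar, -ar])])
    }
    rho <- mean(off) / v
    lo <- cs_rho_lower(structure, k)
    z <- stats::qlogis((rho - lo) / (1 - lo))
    c(0.5 * log(v), z, 0.5 * log(sigma2))
  }
}

#' @rdname encode_cov_param
#' @export
decode_cov_param <- function(theta, structure = "diagonal", k) {
  q <- k^2 + 2L * k
  if (structure == "diagonal") {
    if (length(theta) != q + 1L) stop("theta must have length ", q + 1L)
    list(G = diag(exp(2 * theta[seq_len(q)]), q),
         sigma2 = exp(2 * theta[q + 1L]))
  } else {
    if (length(theta) != 3L) stop("theta must have length 3")
    v <- exp(2 * theta[1L])
    lo <- cs_rho_lower(structure, k)
    rho <- lo + (1 - lo) * stats::plogis(theta[2L])
    list(G = build_G(rep(v, q), rho * v, structure, k),
         sigma2 = exp(2 * theta[3L]))
  }
}

## lower PD bound for the shared correlation: -1/(block size - 1)
cs_rho_lower <- function(structure, k) {
  q <- k^2 + 2L * k
  blk <- if (structure == "compound_symmetric") q else max(k^2, 2L * k)
  -1 / (blk - 1) + 1e-6
}

n_theta <- function(structure, k) {
  if (structure == "diagonal") k^2 + 2L * k + 1L else 3L
}

#' Marginal covariance of one day's stacked response
#'
#' `V_i = Z_i G Z_i' + sigma2 * I`.
#'
#' @param day a `"larmex_stacked_day"`.
#' @param G random-effects covariance (positive semi-definite).
#' @param sigma2 residual variance.
#' @return The dense symmetric positive-definite matrix `V_i`.
#' @export
marginal_cov <- function(day, G, sigma2) {
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev))))
    stop("'G' must be positive semi-definite")
  V <- day$Z %*% G %*% t(day$Z)
  diag(V) <- diag(V) + sigma2
  (V + t(V)) / 2
}

## Per-day cross-products; everything the likelihood needs.
day_crossprods <- function(day) {
  list(Cxx = crossprod(day$X), Cxy = crossprod(day$X, day$Y),
       Cyy = sum(day$Y^2), Czz = crossprod(day$Z),
       Czx = crossprod(day$Z, day$X), Czy = crossprod(day$Z, day$Y),
       n = length(day$Y))
}

stacked_crossprods <- function(stacked) {
  cps <- lapply(stacked$days, day_crossprods)
  attr(cps, "p") <- ncol(stacked$days[[1L]]$X)
  attr(cps, "n_tot") <- stacked$total_obs
  cps
}

## Accumulated GLS/likelihood parts for given (R, sigma2), with G = R R'.
## Uses the Woodbury identity on the per-day cross-products so each day
## costs O(q^3) regardless of its length. Returns NULL on factorization
## failure (optimizer-safe caller turns that into a large objective value).
lik_parts <- function(cps, R, sigma2) {
  p <- attr(cps, "p")
  A <- matrix(0, p, p)
  u <- numeric(p)
  yvy <- 0
  logdet <- 0
  r <- ncol(R)
  for (cp in cps) {
    P <- crossprod(R, cp$Czx)          # r x p
    Qv <- crossprod(R, cp$Czy)         # r x 1
    W <- crossprod(R, cp$Czz %*% R) / sigma2
    diag(W) <- diag(W) + 1
    cW <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(cW)) return(NULL)
    WiP <- backsolve(cW, backsolve(cW, P, transpose = TRUE))
    WiQ <- backsolve(cW, backsolve(cW, Qv, transpose = TRUE))
    A <- A + (cp$Cxx - crossprod(P, WiP) / sigma2) / sigma2
    u <- u + (cp$Cxy - crossprod(P, WiQ) / sigma2) / sigma2
    yvy <- yvy + (cp$Cyy - crossprod(Qv, WiQ) / sigma2) / sigma2
    logdet <- logdet + cp$n * log(sigma2) + 2 * sum(log(diag(cW)))
  }
  list(A = A, u = u, yvy = as.numeric(yvy), logdet = logdet)
}

solve_or_ginv <- function(A, b = NULL) {
  out <- tryCatch({
    res <- if (is.null(b)) chol2inv(chol(A)) else solve(A, b)
    attr(res, "generalized") <- FALSE
    res
  }, error = function(e) NULL)
  if (is.null(out)) {
    Ai <- MASS::ginv(A)
    res <- if (is.null(b)) Ai else Ai %*% b
    attr(res, "generalized") <- TRUE
    res
  } else out
}

#' Generalized least squares estimate of the fixed effects
#'
#' `beta = (sum X' V^-1 X)^-1 sum X' V^-1 Y` with
#' `V_i = Z_i G Z_i' + sigma2 I`, together with
#' `Cov(beta) = (sum X' V^-1 X)^-1`. A Moore-Penrose generalized inverse is
#' substituted (and flagged) when the cross-product sum is singular.
#'
#' @param stacked a [stack_dataset()] result.
#' @param G random-effects covariance.
#' @param sigma2 residual variance.
#' @return List with `beta_hat`, `cov_beta`, and logical `generalized`.
#' @export
gls_beta <- function(stacked, G, sigma2) {
  cps <- stacked_crossprods(stacked)
  R <- psd_factor(G)
  parts <- lik_parts(cps, R, sigma2)
  if (is.null(parts)) stop("marginal covariance factorization failed")
  if (max(abs(parts$A)) == 0) stop("all-zero design: fixed effects not estimable")
  cov_beta <- solve_or_ginv(parts$A)
  beta_hat <- as.numeric(cov_beta %*% parts$u)
  names(beta_hat) <- colnames(stacked$days[[1L]]$X)
  list(beta_hat = beta_hat, cov_beta = unclass(cov_beta),
       generalized = isTRUE(attr(cov_beta, "generalized")))
}

#' Profiled -2 log-likelihood of the covariance parameters
#'
#' Decodes `theta` into `(G, sigma2)`, profiles the fixed effects out by
#' generalized least squares, and returns (constants excluded)
#' `sum log|V_i| + sum r_i' V_i^-1 r_i`, plus `log|sum X' V^-1 X|` for
#' REML. Numerical failure of a factorization returns a large finite value
#' flagged with `attr(., "failed")` so that optimizers can recover.
#'
#' @param theta unconstrained covariance parameters
#'   (see [encode_cov_param()]).
#' @param stacked a [stack_dataset()] result.
#' @param method `"ML"` or `"REML"`.
#' @param structure covariance structure tag.
#' @return The objective value (single number).
#' @export
neg2_loglik <- function(theta, stacked, method = c("REML", "ML"),
                        structure = "diagonal") {
  method <- match.arg(method)
  cps <- if (inherits(stacked, "larmex_stacked")) {
    stacked_crossprods(stacked)
  } else stacked
  dec <- decode_cov_param(theta, structure, k_from_q(attr(cps, "p")))
  R <- psd_factor(dec$G)
  fail_value <- function() {
    out <- 1e10
    attr(out, "failed") <- TRUE
    out
  }
  parts <- lik_parts(cps, R, dec$sigma2)
  if (is.null(parts)) return(fail_value())
  cov_beta <- solve_or_ginv(parts$A)
  beta <- as.numeric(cov_beta %*% parts$u)
  quad <- parts$yvy - 2 * sum(beta * parts$u) +
    as.numeric(crossprod(beta, parts$A %*% beta))
  obj <- parts$logdet + quad
  if (method == "REML") {
    cA <- tryCatch(chol(parts$A), error = function(e) NULL)
    if (is.null(cA)) return(fail_value())
    obj <- obj + 2 * sum(log(diag(cA)))
  }
  if (!is.finite(obj)) return(fail_value())
  obj
}

k_from_q <- function(q) {
  k <- (-2 + sqrt(4 + 4 * q)) / 2
  as.integer(round(k))
}

## Profiled objective over the *relative* covariance parameters phi
## (G = sigma2 * Lambda Lambda'), with sigma2 eliminated analytically:
##   ML:   sigma2_hat = Q / n,        REML: sigma2_hat = Q / (n - p).
## This is the same profiling that lme4 uses and keeps the search space at
## q (diagonal) or 2 (compound-symmetric) dimensions.
profiled_obj <- function(phi, cps, method, structure, k) {
  p <- attr(cps, "p")
  n_tot <- attr(cps, "n_tot")
  Rrel <- rel_factor(phi, structure, k)
  if (is.null(Rrel)) return(1e10)
  parts <- lik_parts(cps, Rrel, 1)
  if (is.null(parts)) return(1e10)
  cov_beta <- solve_or_ginv(parts$A)
  beta <- as.numeric(cov_beta %*% parts$u)
  Q <- parts$yvy - 2 * sum(beta * parts$u) +
    as.numeric(crossprod(beta, parts$A %*% beta))
  Q <- max(Q, 1e-12)
  ## parts$logdet here is log|I + Z Lambda Lambda' Z'| summed over days
  if (method == "ML") {
    obj <- n_tot * log(Q / n_tot) + parts$logdet + n_tot
  } else {
    df <- n_tot - p
    cA <- tryCatch(chol(parts$A), error = function(e) NULL)
    if (is.null(cA)) return(1e10)
    obj <- df * log(Q / df) + parts$logdet + 2 * sum(log(diag(cA))) + df
  }
  if (!is.finite(obj)) 1e10 else obj
}

## relative factor Lambda with G/sigma2 = Lambda Lambda'
rel_factor <- function(phi, structure, k) {
  q <- k^2 + 2L * k
  if (structure == "diagonal") {
    diag(exp(phi), q)
  } else {
    v <- exp(2 * phi[1L])
    lo <- cs_rho_lower(structure, k)
    rho <- lo + (1 - lo) * stats::plogis(phi[2L])
    G <- build_G(rep(v, q), rho * v, structure, k)
    tryCatch(t(chol(G)), error = function(e) NULL)
  }
}

phi_from_rel <- function(G, sigma2, structure, k) {
  if (structure == "diagonal") {
    0.5 * log(pmax(diag(G) / sigma2, 1e-300))
  } else {
    th <- encode_cov_param(G, sigma2, structure, k)
    c(th[1L] - th[3L], th[2L])
  }
}

#' Fit the LARMEx model by maximum or restricted maximum likelihood
#'
#' Minimizes the profiled objective of [neg2_loglik()] over an
#' unconstrained covariance parameterization with a quasi-Newton optimizer
#' (numeric gradients), profiling both the fixed effects (generalized least
#' squares) and the residual variance analytically. Up to `restarts`
#' jittered restarts are attempted when the optimizer reports failure. The
#' result is deterministic given the data and starting point.
#'
#' @param stacked a [stack_dataset()] result.
#' @param structure covariance structure tag (default `"diagonal"`,
#'   matching independent day-level random effects).
#' @param method `"REML"` (default; corrects the variance components for
#'   the degrees of freedom lost to the fixed effects) or `"ML"` (for
#'   likelihood-ratio use).
#' @param start optional starting value for the full `theta`
#'   (see [encode_cov_param()]).
#' @param control list; `rel_tol` (objective change, default 1e-8),
#'   `grad_tol` (gradient norm, default 1e-5), `max_iter` (default 500),
#'   `restarts` (default 5).
#' @return An object of class `"larmex_fit"`: `beta_hat`, `G_hat`,
#'   `sigma2_hat`, `cov_beta`, `blups` (N x q matrix, one row per retained
#'   day), `neg2ll`, `theta`, `method`, `structure`, `converged`, `n_iter`,
#'   `gradient_norm`, `generalized_inverse`, `identifiability`.
#' @export
fit_larmex <- function(stacked, structure = "diagonal",
                       method = c("REML", "ML"), start = NULL,
                       control = list()) {
  method <- match.arg(method)
  ctrl <- utils::modifyList(list(rel_tol = 1e-8, grad_tol = 1e-5,
                                 max_iter = 500L, restarts = 5L), control)
  ident <- withCallingHandlers(check_identifiability(stacked),
                               warning = function(w) {
                                 message("note: ", conditionMessage(w))
                                 invokeRestart("muffleWarning")
                               })
  k <- stacked$k
  cps <- stacked_crossprods(stacked)
  n_phi <- if (structure == "diagonal") stacked$q else 2L
  if (is.null(start)) {
    ## day-level variation comparable to the noise: relative sd ~ sqrt(1/2)
    phi0 <- if (structure == "diagonal") {
      rep(0.5 * log(0.5), n_phi)
    } else c(0.5 * log(0.5), 0)
  } else {
    dec <- decode_cov_param(start, structure, k)
    phi0 <- phi_from_rel(dec$G, dec$sigma2, structure, k)
  }
  obj <- function(phi) profiled_obj(phi, cps, method, structure, k)
  lower <- rep(-8, n_phi)
  upper <- rep(6, n_phi)
  if (structure != "diagonal") { lower[2L] <- -12; upper[2L] <- 12 }
  best <- NULL
  n_iter <- 0L
  converged <- FALSE
  for (attempt in 0:ctrl$restarts) {
    phi_start <- if (attempt == 0L) phi0 else {
      set.seed(1000L + attempt)
      phi0 + stats::rnorm(n_phi, 0, 0.5 * attempt)
    }
    phi_start <- pmin(pmax(phi_start, lower), upper)
    res <- tryCatch(
      stats::nlminb(phi_start, obj, lower = lower, upper = upper,
                    control = list(rel.tol = ctrl$rel_tol,
                                   iter.max = ctrl$max_iter,
                                   eval.max = 4L * ctrl$max_iter)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_iter <- n_iter + res$iterations
    if (is.null(best) || res$objective < best$objective - 1e-9) best <- res
    if (res$convergence == 0 && res$objective < 1e9) { converged <- TRUE; break }
  }
  if (is.null(best)) stop("optimization failed on every attempt")
  phi <- best$par
  ## numeric gradient norm at the optimum (central differences)
  h <- 1e-5
  g <- vapply(seq_along(phi), function(j) {
    ph <- phi; ph[j] <- phi[j] + h; f1 <- obj(ph)
    ph[j] <- phi[j] - h; f0 <- obj(ph)
    (f1 - f0) / (2 * h)
  }, 0)
  at_bound <- phi <= lower + 1e-7 | phi >= upper - 1e-7
  grad_norm <- sqrt(sum(g[!at_bound]^2))
  converged <- converged && (grad_norm < max(ctrl$grad_tol, 1e-3 * abs(best$objective)) ||
                               all(at_bound))

  ## recover the absolute covariance components at the optimum
  Rrel <- rel_factor(phi, structure, k)
  parts <- lik_parts(cps, Rrel, 1)
  cov_rel <- solve_or_ginv(parts$A)
  beta <- as.numeric(cov_rel %*% parts$u)
  Q <- parts$yvy - 2 * sum(beta * parts$u) +
    as.numeric(crossprod(beta, parts$A %*% beta))
  df <- if (method == "REML") attr(cps, "n_tot") - attr(cps, "p") else attr(cps, "n_tot")
  sigma2_hat <- max(Q / df, 1e-12)
  G_hat <- sigma2_hat * tcrossprod(Rrel)
  theta_hat <- encode_cov_param(G_hat, sigma2_hat, structure, k)
  names(beta) <- colnames(stacked$days[[1L]]$X)
  cov_beta <- sigma2_hat * unclass(cov_rel)
  fit <- list(
    beta_hat = beta, G_hat = G_hat, sigma2_hat = sigma2_hat,
    cov_beta = cov_beta, method = method, structure = structure,
    theta = theta_hat,
    neg2ll = neg2_loglik(theta_hat, stacked, method, structure),
    converged = converged, n_iter = n_iter, gradient_norm = grad_norm,
    generalized_inverse = isTRUE(attr(cov_rel, "generalized")),
    identifiability = ident,
    day_index = vapply(stacked$days, function(d) d$day_index, 0),
    k = k, q = stacked$q)
  class(fit) <- "larmex_fit"
  fit$blups <- blup_all(fit, stacked)
  fit
}

## BLUPs for every day: b_i = G Z' V^-1 (Y - X beta).
blup_all <- function(fit, stacked) {
  G <- fit$G_hat
  s2 <- fit$sigma2_hat
  R <- psd_factor(G)
  out <- matrix(0, length(stacked$days), fit$q)
  for (i in seq_along(stacked$days)) {
    d <- stacked$days[[i]]
    cp <- day_crossprods(d)
    g <- cp$Czy - cp$Czx %*% fit$beta_hat
    P <- crossprod(R, g)
    W <- crossprod(R, cp$Czz %*% R) / s2
    diag(W) <- diag(W) + 1
    cW <- chol(W)
    WiP <- backsolve(cW, backsolve(cW, P, transpose = TRUE))
    zvr <- (g - cp$Czz %*% (R %*% WiP) / s2) / s2
    out[i, ] <- as.numeric(G %*% zvr)
  }
  colnames(out) <- ranef_names(fit$k)
  rownames(out) <- fit$day_index
  out
}

#' Best linear unbiased predictor of one day's random effects
#'
#' Evaluates `b_i = G_hat Z_i' V_i^-1 (Y_i - X_i beta_hat)` at the fitted
#' covariance components.
#'
#' @param fit a [fit_larmex()] result.
#' @param day_index which day; `NULL` returns the matrix of all BLUPs.
#' @return A named q-vector (or the `N x q` matrix).
#' @export
blup <- function(fit, day_index = NULL) {
  if (is.null(day_index)) return(fit$blups)
  i <- match(day_index, fit$day_index)
  if (is.na(i)) stop("day ", day_index, " was not part of the fit")
  fit$blups[i, ]
}

#' @export
print.larmex_fit <- function(x, ...) {
  cat("LARMEx fit (", x$method, ", G structure: ", x$structure, ")\n", sep = "")
  cat("  days:", length(x$day_index), "\n")
  cat("  -2 logLik (constants excluded):", format(x$neg2ll, digits = 8), "\n")
  cat("  converged:", x$converged, " iterations:", x$n_iter,
      " |grad|:", format(x$gradient_norm, digits = 3), "\n")
  est <- cbind(estimate = x$beta_hat, se = sqrt(pmax(diag(x$cov_beta), 0)),
               g_var = diag(x$G_hat))
  print(round(est, 4))
  cat("  sigma2_hat:", round(x$sigma2_hat, 5), "\n")
  invisible(x)
}

#' Serialize a fit to JSON and the BLUPs to CSV
#'
#' @param fit a [fit_larmex()] result.
#' @param json_path path for the JSON report (skipped when `NULL`).
#' @param blup_path path for the per-day BLUP CSV (skipped when `NULL`).
#' @return Invisibly, the report list.
#' @export
write_fit_report <- function(fit, json_path = NULL, blup_path = NULL) {
  report <- list(
    method = fit$method, structure = fit$structure,
    beta_hat = as.list(fit$beta_hat),
    G_hat = unname(apply(fit$G_hat, 1L, as.numeric, simplify = FALSE)),
    sigma2_hat = fit$sigma2_hat,
    cov_beta = unname(apply(fit$cov_beta, 1L, as.numeric, simplify = FALSE)),
    neg2ll = fit$neg2ll,
    convergence = list(converged = fit$converged, n_iter = fit$n_iter,
                       gradient_norm = fit$gradient_norm,
                       generalized_inverse = fit$generalized_inverse),
    identifiability = fit$identifiability)
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(blup_path)) {
    tab <- data.frame(day = fit$day_index)
    tab <- cbind(tab, as.data.frame(fit$blups))
    utils::write.csv(tab, blup_path, row.names = FALSE)
  }
  invisible(report)
}
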