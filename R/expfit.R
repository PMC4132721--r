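#' Single-exponential fit of a kinetic trace
#'
#' Unweighted least-squares fit of `F(t) = A * (1 - exp(-k * t))`, the
#' progress law of a single-cycle reaction obeying pseudo-first-order
#' kinetics.  Initialization: `A0 = max(F)` and `k0 = ln(2) / t_half` with
#' `t_half` the first time F exceeds `A0 / 2`; bounds `A` in `[0, 1.2]`,
#' `k > 0`.  Masked points are dropped, never imputed.  Standard errors
#' come from the fit covariance; non-convergence and under-determined
#' traces are flagged, never silently propagated as NaN.
#'
#' A fit is flagged `low_confidence` when fewer than 4 unmasked points are
#' available, when the sampling does not span both the rise and the plateau
#' of the fitted curve (`k * max(t) < 2` or first sample already at
#' `> 90%` of plateau), or when the optimizer failed.
#'
#' @param trace A [kinetic_trace()].
#' @return An object of class `exp_fit`: list with `position`, `A`, `k`,
#'   `A_se`, `k_se`, `rss`, `sigma`, `n`, `converged`, `low_confidence`.
#' @export
fit_single_exponential <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  ok <- !trace$masked & !is.na(trace$F)
  t <- trace$times[ok]
  y <- trace$F[ok]
  n <- length(t)
  degenerate <- n < 2L || all(y <= 0) || max(t) <= 0
  if (degenerate) {
    return(new_exp_fit(trace$position, A = 0, k = NA_real_,
                       A_se = NA_real_, k_se = NA_real_, rss = sum(y^2),
                       n = n, converged = FALSE, low_confidence = TRUE))
  }
  fit <- fit_progress_model(t, y, model = "single")
  low <- n < 4L || !fit$converged ||
    (is.finite(fit$k) && fit$k * max(t) < 2) ||
    (is.finite(fit$k) && fit$A > 0 &&
       min(y[t == min(t)]) > 0.9 * fit$A)
  new_exp_fit(trace$position, fit$A, fit$k, fit$A_se, fit$k_se, fit$rss,
              n = n, converged = fit$converged, low_confidence = low)
}

new_exp_fit <- function(position, A, k, A_se, k_se, rss, n, converged,
                        low_confidence) {
  structure(list(position = as.integer(position), A = A, k = k,
                 A_se = A_se, k_se = k_se, rss = rss,
                 sigma = if (n > 2) sqrt(rss / (n - 2)) else NA_real_,
                 n = n, converged = converged,
                 low_confidence = low_confidence),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit> position %d: A = %.4f (se %.2g), k = %.4g /s (se %.2g)%s%s\n",
    x$position, x$A, x$A_se, x$k, x$k_se,
    if (!x$converged) " [NOT CONVERGED]" else "",
    if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

# Shared fitting backend for the progress-curve models:
#   single: F = A (1 - exp(-k t))           (pure single exponential)
#   lag:    F = A (1 - (1 + k t) exp(-k t)) (two sequential slow steps of
#           equal rate -- the minimal sigmoidal/lagged alternative with the
#           same number of parameters)
fit_progress_model <- function(t, y, model = c("single", "lag")) {
  model <- match.arg(model)
  fn <- if (model == "single")
    function(A, k) A * (1 - exp(-k * t))
  else
    function(A, k) A * (1 - (1 + k * t) * exp(-k * t))
  A0 <- max(y)
  above <- which(y >= A0 / 2)
  t_half <- if (length(above)) max(t[above[1]], min(t[t > 0])) else max(t) / 2
  k0 <- log(2) / t_half
  if (model == "lag") k0 <- 2 * k0  # Erlang-2 mean is 2/k
  start <- list(A = min(max(A0, 1e-3), 1.2), k = k0)
  env <- environment()
  fit <- tryCatch({
    m <- if (model == "single")
      stats::nls(y ~ A * (1 - exp(-k * t)), start = start,
                 algorithm = "port", lower = c(A = 0, k = 1e-12),
                 upper = c(A = 1.2, k = Inf),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE))
    else
      stats::nls(y ~ A * (1 - (1 + k * t) * exp(-k * t)), start = start,
                 algorithm = "port", lower = c(A = 0, k = 1e-12),
                 upper = c(A = 1.2, k = Inf),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE))
    co <- summary(m)$coefficients
    list(A = co["A", "Estimate"], k = co["k", "Estimate"],
         A_se = co["A", "Std. Error"], k_se = co["k", "Std. Error"],
         rss = sum(stats::resid(m)^2), converged = TRUE)
  }, error = function(e) NULL)
  if (!is.null(fit)) return(fit)
  # Fallback: bounded quasi-Newton on the residual sum of squares, with
  # standard errors from the Gauss-Newton approximation J'J.
  rss_fn <- function(par) sum((y - fn(par[1], par[2]))^2)
  opt <- tryCatch(
    stats::optim(c(start$A, start$k), rss_fn, method = "L-BFGS-B",
                 lower = c(0, 1e-12), upper = c(1.2, Inf)),
    error = function(e) NULL)
  if (is.null(opt))
    return(list(A = start$A, k = start$k, A_se = NA_real_, k_se = NA_real_,
                rss = rss_fn(c(start$A, start$k)), converged = FALSE))
  A <- opt$par[1]; k <- opt$par[2]
  J <- cbind(
    if (model == "single") 1 - exp(-k * t) else 1 - (1 + k * t) * exp(-k * t),
    if (model == "single") A * t * exp(-k * t) else A * k * t^2 * exp(-k * t))
  n <- length(y)
  s2 <- opt$value / max(n - 2, 1)
  V <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  ses <- if (is.null(V)) c(NA_real_, NA_real_) else sqrt(pmax(diag(V), 0))
  list(A = A, k = k, A_se = ses[1], k_se = ses[2], rss = opt$value,
       converged = opt$convergence == 0)
}

#' Lag detection in a kinetic trace
#'
#' Compares the single-exponential fit (no lag: the reaction is rate-limited
#' by one slow step) against a sequential two-step alternative of equal
#' parameter count, `F = A (1 - (1 + k t) exp(-k t))`, whose initial slope
#' is zero (a lag phase).  Model preference is by AIC; a lower AIC for the
#' two-step model indicates a detectable lag, i.e. at least two comparably
#' slow steps.
#'
#' @param trace A [kinetic_trace()].
#' @return An object of class `lag_test`: list with `preferred` (one of
#'   `"no_lag"`, `"lag"`, `"undecidable"`), `delta_aic`
#'   (AIC(lag) - AIC(single); negative favors the lag model), and both
#'   fits.
#' @export
detect_lag <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  ok <- !trace$masked & !is.na(trace$F)
  t <- trace$times[ok]
  y <- trace$F[ok]
  n <- length(t)
  if (n < 4L || all(y <= 0)) {
    return(structure(list(preferred = "undecidable", delta_aic = NA_real_,
                          single = NULL, lag = NULL), class = "lag_test"))
  }
  f1 <- fit_progress_model(t, y, "single")
  f2 <- fit_progress_model(t, y, "lag")
  aic <- function(rss, p) n * log(max(rss, 1e-300) / n) + 2 * p
  delta <- aic(f2$rss, 2) - aic(f1$rss, 2)
  preferred <- if (!f1$converged && !f2$converged) "undecidable"
  else if (delta < 0) "lag" else "no_lag"
  structure(list(preferred = preferred, delta_aic = delta,
                 single = f1, lag = f2), class = "lag_test")
}

#' @export
print.lag_test <- function(x, ...) {
  cat(sprintf("<lag_test> preferred: %s (delta AIC = %.3g)\n",
              x$preferred, x$delta_aic))
  invisible(x)
}
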