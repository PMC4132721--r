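#' Deterministic progress curve of the unwinding chain
#'
#' Solves the linear first-order master equation of the single-run reaction
#' chain: bound complex --(k_act)--> step 1 --(k_U1)--> ... --> unwound,
#' with every translocation intermediate i branching irreversibly to an
#' absorbing dissociated state at rate `k_Di`.  The fraction of input
#' complexes in the unwound state is evaluated at each requested time via
#' the matrix exponential of the (constant) rate matrix; accuracy is that of
#' the scaling-and-squaring Pade algorithm (relative error well below the
#' documented 1e-9 tolerance for these small, well-scaled generators).
#'
#' The curve rises from `F(0) = 0` to the asymptote
#' [total_amplitude()]`(scheme)`, is monotone non-decreasing, and -- when
#' stepping is much faster than activation -- is close to the single
#' exponential `A * (1 - exp(-k_act * t))`.
#'
#' @param scheme A [rate_scheme()].
#' @param times Non-negative times in seconds (sorted internally).
#' @return An object of class `unwinding_curve`: list with `times` and
#'   `fraction_unwound`.
#' @examples
#' sch <- uniform_rate_scheme(10, k_act = 0.01, k_U = 50, k_D = 0)
#' simulate_progress(sch, c(0, 50, 100, 500))
#' @export
simulate_progress <- function(scheme, times) {
  stopifnot(inherits(scheme, "rate_scheme"))
  if (!is.numeric(times) || length(times) == 0L || anyNA(times))
    stop("`times` must be numeric and non-missing", call. = FALSE)
  if (any(times < 0))
    stop("negative times are not allowed", call. = FALSE)
  times <- sort(unique(as.numeric(times)))
  Q <- chain_generator(scheme)
  unw <- nrow(Q) - 1L  # unwound state index
  f <- vapply(times, function(t) {
    if (t == 0) return(0)
    P <- Matrix::expm(Q * t)
    as.numeric(P[1L, unw])
  }, numeric(1))
  f <- scheme$baseline_amplitude * pmin(pmax(f, 0), 1)
  f <- cummax(f)  # guard against sub-tolerance numerical dips
  unwinding_curve(times, f)
}

# Rate matrix (generator) of the chain, states:
# 1 = pre-activation bound complex, 2..(n+1) = intermediates about to take
# step 1..n, n+2 = unwound (absorbing), n+3 = dissociated (absorbing).
chain_generator <- function(scheme) {
  n <- n_steps(scheme)
  m <- n + 3L
  Q <- matrix(0, m, m)
  Q[1L, 1L] <- -scheme$k_act
  Q[1L, 2L] <- scheme$k_act
  for (i in seq_len(n)) {
    r <- i + 1L
    Q[r, r] <- -(scheme$k_U[i] + scheme$k_D[i])
    Q[r, r + 1L] <- scheme$k_U[i]      # step n feeds the unwound state
    Q[r, m] <- Q[r, m] + scheme$k_D[i]
  }
  Matrix::Matrix(Q)
}

#' Unwinding progress curve container
#'
#' @param times Strictly increasing times in seconds, starting at or after 0.
#' @param fraction_unwound Values in `[0, 1]`, non-decreasing, one per time;
#'   must be 0 at `t = 0` if time 0 is present.
#' @return An object of class `unwinding_curve`.
#' @export
unwinding_curve <- function(times, fraction_unwound) {
  if (length(times) != length(fraction_unwound))
    stop("`times` and `fraction_unwound` must have the same length",
         call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(fraction_unwound < -1e-12) || any(fraction_unwound > 1 + 1e-12))
    stop("`fraction_unwound` must lie in [0, 1]", call. = FALSE)
  if (any(diff(fraction_unwound) < -1e-9))
    stop("`fraction_unwound` must be non-decreasing", call. = FALSE)
  if (length(times) && times[1] == 0 && fraction_unwound[1] > 1e-9)
    stop("`fraction_unwound` must be 0 at t = 0", call. = FALSE)
  structure(list(times = as.numeric(times),
                 fraction_unwound = pmin(pmax(fraction_unwound, 0), 1)),
            class = "unwinding_curve")
}

#' @export
print.unwinding_curve <- function(x, ...) {
  cat(sprintf("<unwinding_curve> %d time points, t in [%g, %g] s, F up to %.4f\n",
              length(x$times), min(x$times), max(x$times),
              max(x$fraction_unwound)))
  invisible(x)
}

#' Time at which the control curve reaches a given extent
#'
#' Locates, by bisection on the deterministic progress curve, the time at
#' which the unperturbed (control) reaction reaches an absolute fraction
#' unwound `extent`.  Used to pick the endpoint-selection time of a NAIM
#' experiment.
#'
#' @param scheme A [rate_scheme()].
#' @param extent Target absolute fraction unwound, strictly between 0 and
#'   the scheme's asymptotic amplitude.
#' @param tol Relative time tolerance of the bisection.
#' @return Time in seconds.
#' @export
time_at_extent <- function(scheme, extent, tol = 1e-6) {
  stopifnot(inherits(scheme, "rate_scheme"))
  A <- total_amplitude(scheme)
  if (!is.numeric(extent) || length(extent) != 1L || extent <= 0)
    stop("`extent` must be a single value in (0, asymptote)", call. = FALSE)
  if (extent >= A)
    stop(sprintf(
      "requested extent %.4g is not reachable: control asymptote is %.4g",
      extent, A), call. = FALSE)
  f_at <- function(t) simulate_progress(scheme, t)$fraction_unwound[1]
  upper <- 1 / scheme$k_act
  while (f_at(upper) < extent) upper <- upper * 2
  stats::uniroot(function(t) f_at(t) - extent, c(0, upper),
                 tol = tol * upper)$root
}
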