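#' Raw interference ratios from an endpoint selection
#'
#' Converts paired band tables of a NAIM experiment into per-position kappa
#' ratios.  Each lane is first normalized to its total intensity
#' (total-lane normalization; supplying a reference band instead is left to
#' the caller by pre-scaling), then
#' `kappa_i = (I_unsel,i / sum I_unsel) / (I_sel,i / sum I_sel)`:
#' `kappa > 1` means the position is depleted from the unwound (selected)
#' pool, i.e. the modification there is detrimental.  When parent
#' phosphorothioate tables are supplied, each kappa is divided by the
#' parent's kappa at the same position, cancelling interference caused by
#' the alpha-S tag itself.
#'
#' @param selected,unselected Band tables (data frames with `position`,
#'   `intensity`) of the unwound pool and the input pool; position sets
#'   must match.
#' @param parent_selected,parent_unselected Optional band tables of the
#'   parent alpha-S library, for tag-effect cancellation.
#' @param ceiling Cap applied when a selected-pool band is zero (kappa
#'   would be infinite); capped positions are flagged.
#' @return Data frame with columns `position`, `kappa`, `capped`.
#' @export
kappa_from_selection <- function(selected, unselected,
                                 parent_selected = NULL,
                                 parent_unselected = NULL,
                                 ceiling = 32) {
  kap <- kappa_pair(selected, unselected, ceiling)
  if (!is.null(parent_selected) || !is.null(parent_unselected)) {
    if (is.null(parent_selected) || is.null(parent_unselected))
      stop("both parent band tables must be supplied for correction",
           call. = FALSE)
    par <- kappa_pair(parent_selected, parent_unselected, ceiling)
    if (!identical(par$position, kap$position))
      stop("parent tables cover different positions", call. = FALSE)
    kap$kappa <- kap$kappa / par$kappa
    kap$capped <- kap$capped | par$capped
  }
  n_cap <- sum(kap$capped)
  if (n_cap > 0L)
    tr_log("kappa_from_selection: %d kappa value(s) capped at %g",
           n_cap, ceiling)
  kap
}

kappa_pair <- function(selected, unselected, ceiling) {
  for (tb in list(selected, unselected))
    if (!is.data.frame(tb) ||
        !all(c("position", "intensity") %in% names(tb)))
      stop("band tables need columns position, intensity", call. = FALSE)
  selected <- selected[order(selected$position), ]
  unselected <- unselected[order(unselected$position), ]
  if (!identical(as.integer(selected$position),
                 as.integer(unselected$position)))
    stop("selected and unselected tables cover different positions",
         call. = FALSE)
  ts <- sum(selected$intensity)
  tu <- sum(unselected$intensity)
  if (ts <= 0 || tu <= 0)
    stop("lane totals must be positive", call. = FALSE)
  fs <- selected$intensity / ts
  fu <- unselected$intensity / tu
  capped <- fs == 0 & fu > 0
  kappa <- ifelse(fs > 0, fu / fs, ifelse(fu > 0, ceiling, NA_real_))
  kappa <- pmin(kappa, ceiling)
  capped <- capped | (is.finite(kappa) & kappa >= ceiling)
  data.frame(position = as.integer(selected$position), kappa = kappa,
             capped = capped)
}

#' Normalized lambda interference profile
#'
#' Maps raw kappa ratios to signed, SD-scaled interference factors:
#' `lambda_i = (log2 kappa_i - median) / (MAD * 1.4826)`, with the robust
#' center and scale estimated over the profile itself.  Under a pure-noise
#' profile lambda is approximately standard normal, so a threshold of 2.5
#' corresponds to the two-sided 98.8% interval; `lambda > 0` is detrimental
#' (depletion from the unwound pool), `lambda < 0` favorable.  The robust
#' z-score is isolated here so an alternative normalization can be swapped
#' in.
#'
#' @param kappas Data frame from [kappa_from_selection()] (columns
#'   `position`, `kappa`, optionally `capped`), at least 10 finite
#'   positions.
#' @param threshold Significance threshold in SD units (default 2.5).
#' @param scale_floor Noise floor for the robust scale, in log2-kappa
#'   units.  With the default 0 a (half-)constant profile is an error;
#'   a positive floor bypasses it, so that e.g. identical pools yield an
#'   all-zero, nowhere-significant profile.
#' @return An object of class `interference_profile`: data frame with
#'   columns `position`, `kappa`, `lambda`, `significant` (plus `capped`
#'   if supplied); threshold kept as attribute.
#' @export
lambda_normalize <- function(kappas, threshold = 2.5, scale_floor = 0) {
  if (!is.data.frame(kappas) ||
      !all(c("position", "kappa") %in% names(kappas)))
    stop("`kappas` must have columns position, kappa", call. = FALSE)
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  ok <- is.finite(kappas$kappa) & kappas$kappa > 0
  if (sum(ok) < 10L)
    stop("at least 10 positions with finite kappa are required for ",
         "robust scale estimation", call. = FALSE)
  lk <- log2(kappas$kappa)
  ctr <- stats::median(lk[ok])
  scl <- stats::mad(lk[ok])  # MAD * 1.4826
  if (scl <= scale_floor) {
    if (scale_floor > 0) scl <- scale_floor
    else stop("zero scale: the kappa profile is (half-)constant, lambda ",
              "is undefined", call. = FALSE)
  }
  lambda <- ifelse(ok, (lk - ctr) / scl, NA_real_)
  out <- data.frame(position = as.integer(kappas$position),
                    kappa = kappas$kappa, lambda = lambda,
                    significant = is.finite(lambda) &
                      abs(lambda) > threshold)
  if ("capped" %in% names(kappas)) out$capped <- kappas$capped
  structure(out, class = c("interference_profile", "data.frame"),
            threshold = threshold)
}

#' @export
print.interference_profile <- function(x, ...) {
  cat(sprintf(
    "<interference_profile> %d positions, %d significant at |lambda| > %g\n",
    nrow(x), sum(x$significant, na.rm = TRUE), attr(x, "threshold")))
  invisible(x)
}

#' Cumulative detrimental-interference curve
#'
#' Running sum along the track of the detrimental part of the profile,
#' `max(lambda, 0)`; step-like rises localize interference clusters.
#' Favorable (negative) values do not decrement the curve.
#'
#' @param profile An [lambda_normalize()] result.
#' @return Data frame with columns `position`, `cumulative`
#'   (non-decreasing).
#' @export
cumulative_curve <- function(profile) {
  stopifnot(inherits(profile, "interference_profile"))
  p <- profile[order(profile$position), ]
  contrib <- pmax(ifelse(is.finite(p$lambda), p$lambda, 0), 0)
  data.frame(position = p$position, cumulative = cumsum(contrib))
}

#' Clusters of significant detrimental interference
#'
#' Maximal runs of positions with `lambda > threshold`, where consecutive
#' members of a run may be at most `gap` positions apart (default 1:
#' strictly contiguous).  The cluster center is the lambda-weighted mean
#' position, rounded to the nearest integer.
#'
#' @param profile An [lambda_normalize()] result.
#' @param threshold Positive lambda threshold (defaults to the profile's
#'   own significance threshold).
#' @param gap Maximum spacing between consecutive cluster members.
#' @return Data frame with columns `start`, `end`, `center`, `peak_lambda`,
#'   `n_positions` (zero rows if nothing is significant).
#' @export
find_clusters <- function(profile, threshold = NULL, gap = 1L) {
  stopifnot(inherits(profile, "interference_profile"))
  threshold <- threshold %||% attr(profile, "threshold")
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  p <- profile[order(profile$position), ]
  hit <- is.finite(p$lambda) & p$lambda > threshold
  empty <- data.frame(start = integer(), end = integer(),
                      center = integer(), peak_lambda = numeric(),
                      n_positions = integer())
  if (!any(hit)) return(empty)
  pos <- p$position[hit]
  lam <- p$lambda[hit]
  run <- cumsum(c(1L, diff(pos) > gap))
  do.call(rbind, lapply(split(seq_along(pos), run), function(idx) {
    data.frame(start = pos[idx[1]], end = pos[idx[length(idx)]],
               center = as.integer(round(
                 stats::weighted.mean(pos[idx], lam[idx]))),
               peak_lambda = max(lam[idx]),
               n_positions = length(idx))
  }))
}

#' Positional autocorrelation of an interference profile
#'
#' Mean-removed, variance-normalized autocorrelation of the continuous
#' lambda profile over lags 1..`max_lag` (lag 0 is 1 by construction).
#' The lag of the first local maximum is the step-size estimate.  Its
#' significance is judged against a permutation null: the profile is
#' shuffled `n_perm` times and the 95th percentile of the maximum
#' autocorrelation over all lags forms the noise band; a profile whose
#' local maxima all stay inside the band is flagged non-periodic.
#'
#' @param profile An [lambda_normalize()] result (or any numeric vector of
#'   lambda values); profile length must exceed `2 * max_lag`.
#' @param max_lag Largest lag in nucleotides (default 20).
#' @param n_perm Number of shuffles for the noise band (default 1000).
#' @param seed Seed for the permutation draws.
#' @return An object of class `autocorr_result`: list with `lags` (0..max),
#'   `acf`, `step_size` (first significant local-maximum lag; `NA` when
#'   non-periodic), `first_local_max_lag`, `first_local_max_value`,
#'   `periodic` (logical), `null_q95`.
#' @export
interference_autocorrelation <- function(profile, max_lag = 20L,
                                         n_perm = 1000L, seed = NULL) {
  x <- if (inherits(profile, "interference_profile"))
    profile$lambda[order(profile$position)] else as.numeric(profile)
  x <- ifelse(is.finite(x), x, 0)  # masked positions carry no signal
  L <- length(x)
  if (!is_count(max_lag)) stop("`max_lag` must be a positive integer",
                               call. = FALSE)
  if (L <= 2L * max_lag)
    stop("profile length must exceed 2 * max_lag", call. = FALSE)
  if (stats::var(x) == 0)
    stop("constant profile: autocorrelation is undefined", call. = FALSE)
  ac_fun <- function(v) as.numeric(stats::acf(v, lag.max = max_lag,
                                              plot = FALSE,
                                              demean = TRUE)$acf)
  ac <- ac_fun(x)  # index 1 = lag 0
  lag_vals <- ac[-1]
  # local maxima strictly above the left neighbor, not below the right one;
  # the boundary lag max_lag is excluded (one-sided evidence only)
  is_max <- vapply(seq_len(max_lag - 1L), function(m) {
    left <- if (m == 1L) ac[1] else lag_vals[m - 1L]
    lag_vals[m] > left && lag_vals[m] >= lag_vals[m + 1L]
  }, logical(1))
  maxima <- which(is_max)
  null_q95 <- with_seed(seed, {
    null_max <- vapply(seq_len(n_perm), function(i) {
      max(ac_fun(sample(x))[-1])
    }, numeric(1))
    stats::quantile(null_max, 0.95, names = FALSE)
  })
  sig <- maxima[lag_vals[maxima] > null_q95]
  periodic <- length(sig) > 0L
  structure(list(
    lags = 0:max_lag, acf = ac,
    step_size = if (periodic) sig[1] else NA_integer_,
    first_local_max_lag = if (length(maxima)) maxima[1] else NA_integer_,
    first_local_max_value = if (length(maxima)) lag_vals[maxima[1]]
                            else NA_real_,
    periodic = periodic, null_q95 = null_q95, n_perm = n_perm),
    class = "autocorr_result")
}

#' @export
print.autocorr_result <- function(x, ...) {
  if (x$periodic)
    cat(sprintf(
      "<autocorr_result> periodic: step size %d nt (acf %.3f > null q95 %.3f)\n",
      x$step_size, x$acf[x$step_size + 1L], x$null_q95))
  else
    cat(sprintf(
      "<autocorr_result> no periodicity above the 95%% noise band (q95 %.3f)\n",
      x$null_q95))
  invisible(x)
}
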