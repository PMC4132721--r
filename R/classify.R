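#' Control statistics over replicate fits
#'
#' Means and standard deviations of the fitted amplitude and rate over
#' independent control experiments; these set the scale for per-position
#' significance calls.
#'
#' @param fits A list of [fit_single_exponential()] results (at least 2).
#' @return An object of class `control_stats` with fields `A_mean`, `A_sd`,
#'   `k_mean`, `k_sd`, `n_replicates`.
#' @export
control_statistics <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L)
    stop("at least 2 control replicate fits are required", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "exp_fit")))
  A <- vapply(fits, `[[`, numeric(1), "A")
  k <- vapply(fits, `[[`, numeric(1), "k")
  structure(list(A_mean = mean(A), A_sd = stats::sd(A),
                 k_mean = mean(k), k_sd = stats::sd(k),
                 n_replicates = length(fits)),
            class = "control_stats")
}

#' @export
print.control_stats <- function(x, ...) {
  cat(sprintf(
    "<control_stats> n = %d: A = %.4f +/- %.4f, k = %.4g +/- %.2g /s\n",
    x$n_replicates, x$A_mean, x$A_sd, x$k_mean, x$k_sd))
  invisible(x)
}

#' Normal-interval coverage of an SD band
#'
#' Two-sided coverage, in percent, of the interval `mean +/- sd_band * SD`
#' under a normal reference: the confidence level attached to the 1-SD and
#' 2.5-SD classification bands (68.3% and 98.8%).
#'
#' @param sd_band Positive threshold in SD units.
#' @return Coverage in percent, vectorized.
#' @examples
#' sd_band_coverage(c(1, 2.5))
#' @export
sd_band_coverage <- function(sd_band) {
  if (any(sd_band <= 0)) stop("`sd_band` must be positive", call. = FALSE)
  100 * (2 * stats::pnorm(sd_band) - 1)
}

#' Classify per-position fits against control dispersion
#'
#' Converts each position's fitted amplitude and rate into z-scores against
#' the control mean and SD, flags them at the 1-SD and 2.5-SD bands (68.3%
#' and 98.8% normal coverage), and assigns a class from the amplitude
#' z-score: `detrimental` (z < -2.5), `favorable` (z > +2.5), `slight`
#' (1 < |z| <= 2.5), `indistinguishable` otherwise.  Amplitude and rate are
#' classified independently; the rate flags are reported alongside.
#'
#' @param fits List of [fit_single_exponential()] results (one per
#'   position).
#' @param control A [control_statistics()] result with positive SDs.
#' @param sd_bands Two increasing positive thresholds (default `c(1, 2.5)`).
#' @return An object of class `position_profile`: data frame with columns
#'   `position`, `A`, `A_se`, `k`, `k_se`, `zA`, `zk`, `class`,
#'   `A_within_1sd`, `A_within_2.5sd`, `A_outside`, `k_within_1sd`,
#'   `k_within_2.5sd`, `k_outside`, `converged`, `low_confidence`; the
#'   control stats are attached as attribute `control`.
#' @export
classify_positions <- function(fits, control, sd_bands = c(1, 2.5)) {
  stopifnot(inherits(control, "control_stats"))
  if (!is.list(fits) || !length(fits) ||
      !all(vapply(fits, inherits, logical(1), "exp_fit")))
    stop("`fits` must be a list of exp_fit objects", call. = FALSE)
  if (length(sd_bands) != 2L || any(sd_bands <= 0) || diff(sd_bands) <= 0)
    stop("`sd_bands` must be two increasing positive thresholds",
         call. = FALSE)
  if (!is.finite(control$A_sd) || control$A_sd <= 0 ||
      !is.finite(control$k_sd) || control$k_sd <= 0)
    stop("control SDs are zero or undefined; more (or more variable) ",
         "control replicates are required", call. = FALSE)
  b1 <- sd_bands[1]
  b2 <- sd_bands[2]
  rows <- lapply(fits, function(f) {
    zA <- (f$A - control$A_mean) / control$A_sd
    zk <- if (is.finite(f$k)) (f$k - control$k_mean) / control$k_sd
          else NA_real_
    cls <- if (!is.finite(zA)) NA_character_
    else if (zA < -b2) "detrimental"
    else if (zA > b2) "favorable"
    else if (abs(zA) > b1) "slight"
    else "indistinguishable"
    data.frame(position = f$position, A = f$A, A_se = f$A_se, k = f$k,
               k_se = f$k_se, zA = zA, zk = zk, class = cls,
               A_within_1sd = is.finite(zA) & abs(zA) <= b1,
               A_within_2.5sd = is.finite(zA) & abs(zA) <= b2,
               A_outside = is.finite(zA) & abs(zA) > b2,
               k_within_1sd = is.finite(zk) & abs(zk) <= b1,
               k_within_2.5sd = is.finite(zk) & abs(zk) <= b2,
               k_outside = is.finite(zk) & abs(zk) > b2,
               converged = f$converged, low_confidence = f$low_confidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  n_bad <- sum(!out$converged)
  if (n_bad > 0L)
    tr_log("classify_positions: %d non-converged fit(s)", n_bad)
  structure(out, class = c("position_profile", "data.frame"),
            control = control, sd_bands = sd_bands)
}

#' @export
print.position_profile <- function(x, ...) {
  cls <- table(factor(x$class, levels = c("indistinguishable", "slight",
                                          "favorable", "detrimental")))
  cat(sprintf("<position_profile> %d positions: %s\n", nrow(x),
              paste(names(cls), as.integer(cls), sep = " = ",
                    collapse = ", ")))
  invisible(x)
}
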