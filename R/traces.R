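#' Per-position kinetic trace
#'
#' The reaction progress of the substrate subpopulation modified at one
#' track position: `F = I(S1) / (I(S1) + I(S2))` per sampling time, where
#' I(S1) and I(S2) are the band intensities of that position in the unwound
#' supernatant and bead-recovered fractions.
#'
#' @param position 1-based track index (0 for the control trace).
#' @param times Sampling times in seconds.
#' @param F Fraction unwound per time, in `[0, 1]`; masked points are `NA`.
#' @param masked Logical vector flagging masked points (defaults to
#'   `is.na(F)`).
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(position, times, F, masked = NULL) {
  if (length(times) != length(F))
    stop("`times` and `F` must have the same length", call. = FALSE)
  masked <- masked %||% is.na(F)
  if (length(masked) != length(F))
    stop("`masked` must match `F` in length", call. = FALSE)
  ok <- !masked
  if (any(F[ok] < -1e-9 | F[ok] > 1 + 1e-9))
    stop("`F` values must lie in [0, 1]", call. = FALSE)
  structure(list(position = as.integer(position),
                 times = as.numeric(times),
                 F = pmin(pmax(as.numeric(F), 0), 1),
                 masked = as.logical(masked)),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> position %d, %d points (%d masked)\n",
              x$position, length(x$times), sum(x$masked)))
  invisible(x)
}

#' Per-position fraction-unwound traces from a gel dataset
#'
#' Computes `F = I(S1) / (I(S1) + I(S2))` for every track position and
#' sampling time.  Points whose total intensity is at or below `floor` are
#' masked (never zeroed or imputed); a zero total additionally triggers a
#' warning log.  The position-0 control readout, if present, is skipped
#' here (see [control_trace()]).
#'
#' @param dataset A [gel_dataset()].
#' @param floor Total-intensity masking floor (default 0: only empty band
#'   pairs are masked).
#' @param positions Optional subset of positions (e.g. an analysis window).
#' @return A list of [kinetic_trace()] objects, one per position.
#' @export
fraction_unwound <- function(dataset, floor = 0, positions = NULL) {
  stopifnot(inherits(dataset, "gel_dataset"))
  d <- dataset$data
  pos <- dataset_positions(dataset)
  if (!is.null(positions)) {
    missing_pos <- setdiff(positions, pos)
    if (length(missing_pos))
      stop("positions absent from the dataset: ",
           paste(missing_pos, collapse = ", "), call. = FALSE)
    pos <- sort(intersect(pos, positions))
  }
  times <- sort(unique(d$time_s))
  s1 <- d[d$fraction == "S1", ]
  s2 <- d[d$fraction == "S2", ]
  i1 <- matrix(s1$intensity[order(s1$position, s1$time_s)],
               nrow = length(times),
               dimnames = list(NULL, sort(unique(s1$position))))
  i2 <- matrix(s2$intensity[order(s2$position, s2$time_s)],
               nrow = length(times),
               dimnames = list(NULL, sort(unique(s2$position))))
  n_zero <- 0L
  out <- lapply(pos, function(p) {
    a <- i1[, as.character(p)]
    b <- i2[, as.character(p)]
    tot <- a + b
    mask <- tot <= floor
    n_zero <<- n_zero + sum(tot == 0)
    f <- ifelse(mask, NA_real_, a / ifelse(tot == 0, 1, tot))
    kinetic_trace(p, times, f, mask)
  })
  if (n_zero > 0L)
    tr_log("fraction_unwound: %d point(s) with zero total intensity were masked",
           n_zero)
  n_masked <- sum(vapply(out, function(tr) sum(tr$masked), integer(1)))
  if (n_masked > 0L)
    tr_log("fraction_unwound: %d masked point(s) in total", n_masked)
  names(out) <- pos
  out
}

#' Control trace of a gel dataset
#'
#' @param dataset A [gel_dataset()] containing the position-0 control
#'   readout.
#' @param floor Masking floor, as in [fraction_unwound()].
#' @return A [kinetic_trace()] with position 0.
#' @export
control_trace <- function(dataset, floor = 0) {
  stopifnot(inherits(dataset, "gel_dataset"))
  if (!0L %in% dataset$data$position)
    stop("dataset has no position-0 control readout", call. = FALSE)
  d <- dataset$data[dataset$data$position == 0L, ]
  times <- sort(unique(d$time_s))
  a <- d$intensity[d$fraction == "S1"][order(d$time_s[d$fraction == "S1"])]
  b <- d$intensity[d$fraction == "S2"][order(d$time_s[d$fraction == "S2"])]
  tot <- a + b
  mask <- tot <= floor
  f <- ifelse(mask, NA_real_, a / ifelse(tot == 0, 1, tot))
  kinetic_trace(0L, times, f, mask)
}
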