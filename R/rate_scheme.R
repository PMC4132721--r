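#' Sequential-step kinetic scheme for single-run duplex unwinding
#'
#' A `rate_scheme` describes the linear first-order reaction chain used to
#' model single-cycle helicase unwinding: a slow, irreversible activation of
#' the enzyme:substrate complex (rate `k_act`), followed by one
#' translocation/unwinding step per RNA nucleotide consumed.  At every step
#' the complex either advances (rate `k_U`) or dissociates irreversibly
#' (rate `k_D`); under single-run conditions (a trap prevents re-binding)
#' the dissociated state is absorbing, so the reaction amplitude reports the
#' product of the per-step processivities.
#'
#' @param k_act Activation rate in 1/s; must be a single positive number.
#' @param k_U,k_D Per-step forward and dissociation rates in 1/s.  Vectors
#'   are recycled to a common length, one element per translocation step; a
#'   scalar gives a homogeneous chain.
#' @param baseline_amplitude Fraction in `[0, 1]` of complexes competent at
#'   `t = 0` (carries any sub-maximal control amplitude that is not due to
#'   dissociation during translocation).
#'
#' @return An object of class `rate_scheme` with fields `k_act`, `k_U`,
#'   `k_D` and `baseline_amplitude`.
#' @seealso [uniform_rate_scheme()], [simulate_progress()],
#'   [total_amplitude()], [apply_penalties()]
#' @examples
#' sch <- rate_scheme(k_act = 0.01, k_U = 50, k_D = rep(0.5, 94))
#' total_amplitude(sch)
#' @export
rate_scheme <- function(k_act, k_U, k_D, baseline_amplitude = 1) {
  if (!is.numeric(k_act) || length(k_act) != 1L || !is.finite(k_act) ||
      k_act <= 0)
    stop("`k_act` must be a single positive rate (1/s)", call. = FALSE)
  n <- max(length(k_U), length(k_D))
  if (n < 1L)
    stop("a rate scheme needs at least one translocation step", call. = FALSE)
  k_U <- rep_len(as.numeric(k_U), n)
  k_D <- rep_len(as.numeric(k_D), n)
  if (anyNA(k_U) || anyNA(k_D) || any(k_U < 0) || any(k_D < 0) ||
      any(!is.finite(k_U)) || any(!is.finite(k_D)))
    stop("step rates must be finite and non-negative", call. = FALSE)
  bad <- which(k_U == 0 & k_D == 0)
  if (length(bad))
    stop("degenerate step(s) with k_U = k_D = 0: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is_prob(baseline_amplitude))
    stop("`baseline_amplitude` must be a single value in [0, 1]",
         call. = FALSE)
  structure(
    list(k_act = k_act, k_U = k_U, k_D = k_D,
         baseline_amplitude = as.numeric(baseline_amplitude)),
    class = "rate_scheme"
  )
}

#' Homogeneous rate scheme with package-default rates
#'
#' Convenience constructor for a chain in which every translocation step has
#' the same forward and dissociation rate.  The defaults are the package's
#' stated reference world: activation is ~5000-fold slower than stepping, so
#' unwinding kinetics are rate-limited by activation while the amplitude
#' reports cumulative processivity.
#'
#' @param n_steps Number of translocation steps (one per RNA nucleotide).
#' @inheritParams rate_scheme
#' @return A [rate_scheme()].
#' @export
uniform_rate_scheme <- function(n_steps, k_act = 0.01, k_U = 50, k_D = 0.5,
                                baseline_amplitude = 0.9) {
  if (!is_count(n_steps))
    stop("`n_steps` must be a positive integer", call. = FALSE)
  rate_scheme(k_act, rep(k_U, n_steps), rep(k_D, n_steps),
              baseline_amplitude)
}

#' @export
print.rate_scheme <- function(x, ...) {
  cat(sprintf(
    "<rate_scheme> %d step(s); k_act = %g /s; baseline amplitude = %g\n",
    n_steps(x), x$k_act, x$baseline_amplitude))
  cat(sprintf("  k_U: %s\n", summary_rates(x$k_U)))
  cat(sprintf("  k_D: %s\n", summary_rates(x$k_D)))
  cat(sprintf("  total amplitude: %.4f\n", total_amplitude(x)))
  invisible(x)
}

summary_rates <- function(r) {
  if (length(unique(r)) == 1L) sprintf("%g /s (all steps)", r[1])
  else sprintf("%g-%g /s (%d distinct values)", min(r), max(r),
               length(unique(r)))
}

#' Number of translocation steps in a scheme
#' @param scheme A [rate_scheme()].
#' @return Integer number of steps.
#' @export
n_steps <- function(scheme) {
  stopifnot(inherits(scheme, "rate_scheme"))
  length(scheme$k_U)
}

#' Single-step processivity
#'
#' Probability that the complex completes one translocation/unwinding step
#' before dissociating, `k_U / (k_U + k_D)`: the branching ratio of the
#' competing forward and dissociation pathways.
#'
#' @param k_U,k_D Non-negative rates (1/s); vectors are recycled.
#' @return Probability in `[0, 1]`, vectorized over steps.
#' @examples
#' step_processivity(3, 1)  # 0.75
#' @export
step_processivity <- function(k_U, k_D) {
  if (any(k_U < 0) || any(k_D < 0))
    stop("rates must be non-negative", call. = FALSE)
  tot <- k_U + k_D
  if (any(tot == 0))
    stop("degenerate step: k_U and k_D are both zero", call. = FALSE)
  k_U / tot
}

#' Asymptotic amplitude of the unwinding reaction
#'
#' The limit of the progress curve as t -> Inf: the baseline amplitude times
#' the product over steps of the per-step processivities
#' `k_U / (k_U + k_D)`.
#'
#' @param scheme A [rate_scheme()].
#' @return Probability in `[0, 1]`.
#' @export
total_amplitude <- function(scheme) {
  stopifnot(inherits(scheme, "rate_scheme"))
  scheme$baseline_amplitude * prod(step_processivity(scheme$k_U, scheme$k_D))
}

#' Single-analog modification penalty
#'
#' A multiplicative perturbation of the step that consumes one RNA track
#' position, representing incorporation of a ribose 2'-substituent analog
#' there.  Factors default to the package's per-analog table (see
#' [analog_penalty_factors()]); the parent phosphorothioate analog
#' (`"parent-alphaS"`) is always `(1, 1)`.
#'
#' @param position 1-based RNA track index.
#' @param analog Analog identifier, e.g. `"2'-deoxy"`, `"2'-OMe"`, `"2'-F"`,
#'   `"parent-alphaS"`.
#' @param kU_factor,kD_factor Non-negative multipliers applied to the step's
#'   `k_U` and `k_D`; `NULL` takes the per-analog default.
#' @return A one-row data frame with columns `position`, `analog`,
#'   `kU_factor`, `kD_factor`.
#' @export
modification_penalty <- function(position, analog = "2'-deoxy",
                                 kU_factor = NULL, kD_factor = NULL) {
  if (!is_count(position))
    stop("`position` must be a positive integer", call. = FALSE)
  def <- analog_penalty_factors(analog)
  kU_factor <- kU_factor %||% def[["kU_factor"]]
  kD_factor <- kD_factor %||% def[["kD_factor"]]
  if (!is.numeric(kU_factor) || kU_factor < 0 ||
      !is.numeric(kD_factor) || kD_factor < 0)
    stop("penalty factors must be non-negative", call. = FALSE)
  if (identical(analog, "parent-alphaS") &&
      (kU_factor != 1 || kD_factor != 1))
    stop("the parent-alphaS analog must carry factors (1, 1)", call. = FALSE)
  data.frame(position = as.integer(position), analog = analog,
             kU_factor = as.numeric(kU_factor),
             kD_factor = as.numeric(kD_factor),
             stringsAsFactors = FALSE)
}

# Default multiplicative penalties per analog class, applied to the step
# consuming a modified regulatory position.  kD_factor = 100 puts the
# penalized step's dissociation rate equal to its forward rate under the
# default scheme (k_U = 50, k_D = 0.5), i.e. penalized step processivity
# 0.5: escape from the vulnerable state and dissociation become equally
# likely when the key 2'-OH contact is missing.  The bulkier 2'-OMe group is
# four-fold worse (processivity 0.2, ~80% amplitude loss), the small 2'-F
# H-bond acceptor is comparable to 2'-deoxy, and the parent
# phosphorothioate is inert by construction.
.analog_factor_table <- list(
  "parent-alphaS" = list(kU_factor = 1, kD_factor = 1),
  "2'-deoxy"      = list(kU_factor = 1, kD_factor = 100),
  "2'-OMe"        = list(kU_factor = 1, kD_factor = 400),
  "2'-F"          = list(kU_factor = 1, kD_factor = 100)
)

#' Default penalty factors for a nucleotide analog class
#'
#' @param analog Analog identifier; unknown identifiers default to the inert
#'   `(1, 1)` pair so that user-supplied analogs must state their factors
#'   explicitly.
#' @return A list with elements `kU_factor` and `kD_factor`.
#' @export
analog_penalty_factors <- function(analog) {
  .analog_factor_table[[analog]] %||% list(kU_factor = 1, kD_factor = 1)
}

#' Map RNA track positions to translocation steps
#'
#' One translocation step consumes one RNA nucleotide; the mapping is the
#' identity shifted by a configurable track origin (the first position whose
#' consumption the scheme models).
#'
#' @param positions 1-based track positions.
#' @param origin Track position consumed by step 1 (default 1).
#' @return Integer step indices.
#' @export
position_to_step <- function(positions, origin = 1L) {
  as.integer(positions) - as.integer(origin) + 1L
}

#' Apply modification penalties to a rate scheme
#'
#' Returns a new scheme in which, for every penalty, the step consuming the
#' penalized position has its rates multiplied by the penalty factors.
#' Multiple penalties landing on the same step combine multiplicatively.
#' The input scheme is not modified.
#'
#' @param scheme A [rate_scheme()].
#' @param penalties A data frame with columns `position`, `kU_factor`,
#'   `kD_factor` (e.g. rbind-ed [modification_penalty()] rows), or `NULL` /
#'   zero rows for no perturbation.
#' @param origin Track origin passed to [position_to_step()].
#' @return A new [rate_scheme()].
#' @export
apply_penalties <- function(scheme, penalties, origin = 1L) {
  stopifnot(inherits(scheme, "rate_scheme"))
  penalties <- as_penalty_table(penalties)
  if (nrow(penalties) == 0L) return(scheme)
  steps <- position_to_step(penalties$position, origin)
  bad <- penalties$position[steps < 1L | steps > n_steps(scheme)]
  if (length(bad))
    stop("penalty position(s) outside the modeled track: ",
         paste(sort(unique(bad)), collapse = ", "), call. = FALSE)
  k_U <- scheme$k_U
  k_D <- scheme$k_D
  for (i in seq_along(steps)) {
    s <- steps[i]
    k_U[s] <- k_U[s] * penalties$kU_factor[i]
    k_D[s] <- k_D[s] * penalties$kD_factor[i]
  }
  rate_scheme(scheme$k_act, k_U, k_D, scheme$baseline_amplitude)
}

as_penalty_table <- function(penalties) {
  if (is.null(penalties))
    return(data.frame(position = integer(), analog = character(),
                      kU_factor = numeric(), kD_factor = numeric()))
  if (!is.data.frame(penalties) ||
      !all(c("position", "kU_factor", "kD_factor") %in% names(penalties)))
    stop("`penalties` must be a data frame with columns position, ",
         "kU_factor, kD_factor", call. = FALSE)
  if (any(penalties$kU_factor < 0) || any(penalties$kD_factor < 0))
    stop("penalty factors must be non-negative", call. = FALSE)
  penalties
}

#' Ring geometry of periodic regulatory positions
#'
#' Bookkeeping for the model in which a hexameric ring translocase passes
#' through a dissociation-prone "regulatory" state at periodic positions of
#' its RNA track: once per full cycle of the ring, i.e. every `period`
#' nucleotides, when the weak (non-RNA-bridged) subunit interface must
#' engage the incoming 3' nucleotide.  `period` is a free parameter, not
#' derived from `n_subunits` (the ~7-nt recurrence for a 6-subunit ring is
#' an empirical property, not arithmetic).
#'
#' @param n_subunits Number of ring subunits (default 6).
#' @param period Spacing in nucleotides between regulatory positions
#'   (default 7).
#' @param offset 1-based track index of the first regulatory position; must
#'   satisfy `1 <= offset <= period`.  Default 4 (mid-period phase; the
#'   phase is substrate-specific).
#' @return An object of class `regulatory_geometry`.
#' @export
regulatory_geometry <- function(n_subunits = 6L, period = 7L, offset = 4L) {
  if (!is_count(n_subunits) || !is_count(period) || !is_count(offset))
    stop("geometry parameters must be positive integers", call. = FALSE)
  if (offset > period)
    stop("`offset` must satisfy 1 <= offset <= period", call. = FALSE)
  structure(list(n_subunits = as.integer(n_subunits),
                 period = as.integer(period), offset = as.integer(offset)),
            class = "regulatory_geometry")
}

#' @export
print.regulatory_geometry <- function(x, ...) {
  cat(sprintf(
    "<regulatory_geometry> %d subunits; regulatory state every %d nt, first at position %d\n",
    x$n_subunits, x$period, x$offset))
  invisible(x)
}

#' Regulatory positions along a track
#'
#' @param geometry A [regulatory_geometry()].
#' @param track_length Track length in nucleotides.
#' @return Integer vector `offset, offset + period, ... <= track_length`.
#' @examples
#' regulatory_positions(regulatory_geometry(period = 7, offset = 4), 25)
#' @export
regulatory_positions <- function(geometry = regulatory_geometry(),
                                 track_length) {
  stopifnot(inherits(geometry, "regulatory_geometry"))
  if (!is_count(track_length))
    stop("`track_length` must be a positive integer", call. = FALSE)
  if (geometry$offset > track_length) return(integer(0))
  seq.int(geometry$offset, as.integer(track_length), by = geometry$period)
}

#' Penalty table for analogs planted at regulatory positions
#'
#' Builds the modification-penalty table describing a track in which a given
#' analog perturbs translocation only at the periodic regulatory positions
#' of a ring geometry (elsewhere the analog is kinetically inert).
#'
#' @inheritParams regulatory_positions
#' @param analog Analog identifier (see [analog_penalty_factors()]).
#' @param kU_factor,kD_factor Optional overrides of the per-analog defaults.
#' @return A penalty data frame usable by [apply_penalties()] and
#'   [analog_spec()].
#' @export
regulatory_penalty_table <- function(geometry = regulatory_geometry(),
                                     track_length,
                                     analog = "2'-deoxy",
                                     kU_factor = NULL, kD_factor = NULL) {
  pos <- regulatory_positions(geometry, track_length)
  if (length(pos) == 0L)
    return(as_penalty_table(NULL))
  do.call(rbind, lapply(pos, modification_penalty, analog = analog,
                        kU_factor = kU_factor, kD_factor = kD_factor))
}
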