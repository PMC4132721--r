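# Molecule-level simulation of the single-run unwinding experiment.
#
# Each molecule either completes the whole chain (with probability equal to
# the product of its per-step processivities, penalized where it carries a
# kinetically active analog) or dissociates and never unwinds.  Conditional
# on completion, the unwinding time is activation (Exp(k_act)) plus the
# chain passage time: the per-step dwell is Exp(k_U + k_D) irrespective of
# the branch taken (competing-risks property), so the passage time can be
# drawn as a Gamma for runs of identical unpenalized steps plus one
# exponential per penalized step.  This is exactly the distribution implied
# by the deterministic master equation solved by simulate_progress().

simulate_unwind_times <- function(scheme, pen, n_mol) {
  n <- n_steps(scheme)
  competent <- stats::runif(n_mol) < scheme$baseline_amplitude
  homogeneous <- length(unique(scheme$k_U)) == 1L &&
    length(unique(scheme$k_D)) == 1L
  if (homogeneous) {
    kU <- scheme$k_U[1]
    kD <- scheme$k_D[1]
    r0 <- kU + kD
    logp0 <- if (kU == 0) -Inf else log(kU / r0)
    n_pen <- tabulate(pen$molecule, nbins = n_mol)
    shape <- n - n_pen
    logP <- shape * logp0
    extra <- numeric(n_mol)
    if (nrow(pen)) {
      rp <- pen$kU_factor * kU + pen$kD_factor * kD
      logpp <- ifelse(rp > 0 & pen$kU_factor * kU > 0,
                      log(pen$kU_factor * kU / rp), -Inf)
      tpen <- stats::rexp(nrow(pen), rate = pmax(rp, 1e-300))
      agg <- rowsum(cbind(logpp = logpp, tpen = tpen), pen$molecule)
      mols <- as.integer(rownames(agg))
      logP[mols] <- logP[mols] + agg[, "logpp"]
      extra[mols] <- agg[, "tpen"]
    }
    completes <- competent & (log(stats::runif(n_mol)) < logP)
    gam <- numeric(n_mol)
    pos <- shape > 0
    if (any(pos))
      gam[pos] <- stats::rgamma(sum(pos), shape = shape[pos], rate = r0)
    Tm <- stats::rexp(n_mol, scheme$k_act) + gam + extra
  } else {
    pass <- competent
    Tm <- stats::rexp(n_mol, scheme$k_act)
    pen_by_step <- if (nrow(pen)) split(pen, pen$step) else list()
    for (s in seq_len(n)) {
      kU <- scheme$k_U[s]
      kD <- scheme$k_D[s]
      r0 <- kU + kD
      u <- stats::runif(n_mol)
      dwell <- stats::rexp(n_mol, r0)
      ok <- u < kU / r0
      ps <- pen_by_step[[as.character(s)]]
      if (!is.null(ps)) {
        rp <- ps$kU_factor * kU + ps$kD_factor * kD
        pp <- ifelse(rp > 0, ps$kU_factor * kU / rp, 0)
        ok[ps$molecule] <- u[ps$molecule] < pp
        dwell[ps$molecule] <- stats::rexp(nrow(ps), rate = pmax(rp, 1e-300))
      }
      pass <- pass & ok
      Tm <- Tm + dwell
    }
    completes <- pass
  }
  Tm[!completes] <- Inf
  Tm
}

lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

lane_factor <- function(sd) {
  if (sd == 0) return(1)
  stats::rlnorm(1, meanlog = -sd^2 / 2, sdlog = sd)
}

band_counts <- function(mods, keep_molecule, track_length) {
  sel <- keep_molecule[mods$molecule]
  tabulate(mods$position[sel], nbins = track_length)
}

#' Simulate a trNAIP sequencing-gel dataset
#'
#' Draws a randomly modified transcript library, runs every molecule
#' through the (penalty-adjusted) kinetic chain, partitions molecules into
#' the unwound supernatant (S1) and bead-retained (S2) fractions at each
#' sampling time, and reads out per-position band intensities: the number
#' of molecules in a fraction carrying an analog at position i, scaled by
#' the iodine cleavage efficiency and multiplied by lognormal band noise
#' and a per-lane loading factor.  A "Control" readout (total labeled RNA
#' per fraction, no iodine cleavage) is emitted as position 0.
#'
#' @param spec A [library_spec()].
#' @param base_scheme The unperturbed [rate_scheme()]; its number of steps
#'   must cover the track (`track_length - origin + 1` steps or more).
#' @param times Sampling times in seconds (positive, increasing); should
#'   span the rise and plateau of the control curve.
#' @param noise A [noise_model()]; `noise_model(0, 0)` turns noise off.
#' @param seed Integer seed; all randomness flows from it.
#' @param origin Track position consumed by step 1 of the scheme.
#' @return An object of class `gel_dataset`: list with `data` (long data
#'   frame `time_s`, `fraction`, `position`, `intensity`) and `metadata`.
#' @export
simulate_gel <- function(spec, base_scheme, times, noise = noise_model(),
                         seed = NULL, origin = 1L) {
  stopifnot(inherits(spec, "library_spec"),
            inherits(base_scheme, "rate_scheme"),
            inherits(noise, "noise_model"))
  if (spec$n_molecules < 1L) stop("empty library", call. = FALSE)
  if (!is.numeric(times) || !length(times) || any(times <= 0) ||
      any(diff(times) <= 0))
    stop("`times` must be positive and strictly increasing", call. = FALSE)
  last_step <- position_to_step(spec$track_length, origin)
  if (last_step > n_steps(base_scheme) || position_to_step(1L, origin) < 1L)
    stop("scheme does not cover the track: positions 1..", spec$track_length,
         " must map to steps 1..", n_steps(base_scheme), call. = FALSE)
  with_seed(seed, {
    lib <- sample_library(spec)
    pen <- penalized_pairs(lib, origin)
    Tm <- simulate_unwind_times(base_scheme, pen, spec$n_molecules)
    L <- spec$track_length
    rows <- vector("list", 2L * length(times))
    for (ti in seq_along(times)) {
      t <- times[ti]
      unw <- Tm <= t
      # one loading factor per suspension aliquot: the S1/S2 pair of a time
      # point is split from the same aliquot, so its loading error is
      # shared -- and cancels exactly in the ratio statistic F
      lf <- lane_factor(noise$lane_factor_sd)
      for (frac in c("S1", "S2")) {
        keep <- if (frac == "S1") unw else !unw
        counts <- band_counts(lib$mods, keep, L)
        band <- counts * spec$cleavage_efficiency *
          lognormal_factors(L, noise$band_cv) * lf
        ctrl <- sum(keep) * lognormal_factors(1L, noise$band_cv) * lf
        rows[[2L * (ti - 1L) + (frac == "S2") + 1L]] <- data.frame(
          time_s = t, fraction = frac, position = c(0L, seq_len(L)),
          intensity = c(ctrl, band))
      }
    }
    data <- do.call(rbind, rows)
    gel_dataset(data, metadata = list(
      kind = "trnaip", seed = seed,
      spec_hash = spec_hash(as.character(
        jsonlite::toJSON(strip_classes(spec), auto_unbox = TRUE,
                         null = "null", digits = NA))),
      n_molecules = spec$n_molecules, track_length = L, origin = origin,
      times = times, noise = unclass(noise),
      analogs = vapply(spec$analogs, `[[`, character(1), "id")))
  })
}

#' Simulate an endpoint NAIM selection
#'
#' Runs the library to the single time at which the unperturbed control
#' reaction reaches the requested absolute fraction unwound (`extent`,
#' located by bisection on the deterministic control curve), then reads out
#' band intensities of the selected pool (unwound molecules) and the
#' unselected pool (the input library).
#'
#' @inheritParams simulate_gel
#' @param extent Absolute fraction unwound at which the selection is
#'   performed, in `(0, asymptote)`; an extent at or above the control
#'   asymptote is an error naming the asymptote.
#' @return An object of class `naim_selection`: list with band tables
#'   `selected` and `unselected` (data frames `position`, `intensity`),
#'   the selection `time`, `extent`, and `metadata`.
#' @export
simulate_naim_selection <- function(spec, base_scheme, extent = 0.2,
                                    noise = noise_model(), seed = NULL,
                                    origin = 1L) {
  stopifnot(inherits(spec, "library_spec"),
            inherits(base_scheme, "rate_scheme"),
            inherits(noise, "noise_model"))
  if (!is.numeric(extent) || length(extent) != 1L || extent <= 0 ||
      extent >= 1)
    stop("`extent` must be in (0, 1)", call. = FALSE)
  t_sel <- time_at_extent(base_scheme, extent)
  with_seed(seed, {
    lib <- sample_library(spec)
    pen <- penalized_pairs(lib, origin)
    Tm <- simulate_unwind_times(base_scheme, pen, spec$n_molecules)
    unw <- Tm <= t_sel
    L <- spec$track_length
    pool <- function(keep) {
      counts <- band_counts(lib$mods, keep, L)
      lf <- lane_factor(noise$lane_factor_sd)
      data.frame(position = seq_len(L),
                 intensity = counts * spec$cleavage_efficiency *
                   lognormal_factors(L, noise$band_cv) * lf)
    }
    structure(list(
      selected = pool(unw),
      unselected = pool(rep(TRUE, spec$n_molecules)),
      time = t_sel, extent = extent,
      metadata = list(kind = "naim", seed = seed,
                      n_molecules = spec$n_molecules, track_length = L,
                      noise = unclass(noise))),
      class = "naim_selection")
  })
}

#' Simulate independent control experiments
#'
#' Generates `n_replicates` control kinetic traces: independent reactions
#' of the same combinatorial library whose total labeled RNA (no iodine
#' sequencing) is partitioned into S1/S2 at the same sampling times, read
#' out with the same densitometry noise, and converted to fraction-unwound
#' values.  The control is therefore the library-average progress curve --
#' exactly what an aliquot analyzed without sequencing reports -- so
#' per-position traces of kinetically inert positions match it even though
#' every molecule carries several scattered modifications.
#'
#' @inheritParams simulate_gel
#' @param n_replicates Number of independent controls (default 12).
#' @param origin Track origin, as in [simulate_gel()].
#' @return A list of `kinetic_trace` objects (position 0).
#' @export
simulate_control_replicates <- function(spec, base_scheme, times,
                                        noise = noise_model(),
                                        n_replicates = 12L, seed = NULL,
                                        origin = 1L) {
  stopifnot(inherits(spec, "library_spec"),
            inherits(base_scheme, "rate_scheme"))
  if (!is_count(n_replicates) || n_replicates < 1)
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(rep_i) {
      lib <- sample_library(spec)
      pen <- penalized_pairs(lib, origin)
      Tm <- simulate_unwind_times(base_scheme, pen, spec$n_molecules)
      f <- vapply(times, function(t) {
        n1 <- sum(Tm <= t)
        lf <- lane_factor(noise$lane_factor_sd)  # per aliquot, shared
        i1 <- n1 * lognormal_factors(1L, noise$band_cv) * lf
        i2 <- (spec$n_molecules - n1) * lognormal_factors(1L, noise$band_cv) * lf
        i1 / (i1 + i2)
      }, numeric(1))
      kinetic_trace(position = 0L, times = times, F = f)
    })
  })
}
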