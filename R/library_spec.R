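#' Analog description for a combinatorial transcript library
#'
#' Describes one phosphorothioate-tagged nucleotide analog doped into an in
#' vitro transcription: at every eligible track position, each transcript
#' independently carries the analog with probability `incorporation_prob`
#' (~5% in the emulated protocol, so most molecules carry a handful of
#' scattered modifications).
#'
#' @param id Analog identifier, e.g. `"2'-deoxy"`, `"2'-OMe"`, `"2'-F"`,
#'   `"parent-alphaS"`.
#' @param incorporation_prob Per-eligible-position Bernoulli probability of
#'   incorporation (default 0.05).
#' @param bases Optional subset of `c("A","C","G","U")`; when the library
#'   spec carries a sequence, incorporation is restricted to positions with
#'   these bases (base-specific NAIM sub-libraries).
#' @param penalties Kinetic consequences of incorporation: `NULL` (inert),
#'   a penalty data frame (`position`, `kU_factor`, `kD_factor`; positions
#'   absent from the table are inert), or a list
#'   `list(kU_factor =, kD_factor =)` applied at every eligible position
#'   (class-wide penalty).
#' @return An object of class `analog_spec`.
#' @export
analog_spec <- function(id, incorporation_prob = 0.05, bases = NULL,
                        penalties = NULL) {
  if (!is.character(id) || length(id) != 1L)
    stop("`id` must be a single string", call. = FALSE)
  if (!is_prob(incorporation_prob))
    stop("`incorporation_prob` must be in [0, 1]", call. = FALSE)
  if (!is.null(bases)) {
    bases <- toupper(bases)
    if (!all(bases %in% c("A", "C", "G", "U")))
      stop("`bases` must be a subset of A, C, G, U", call. = FALSE)
  }
  if (!is.null(penalties) && !is.data.frame(penalties)) {
    if (!is.list(penalties) ||
        !all(c("kU_factor", "kD_factor") %in% names(penalties)))
      stop("class-wide `penalties` must be list(kU_factor=, kD_factor=)",
           call. = FALSE)
  }
  structure(list(id = id, incorporation_prob = incorporation_prob,
                 bases = bases, penalties = penalties),
            class = "analog_spec")
}

#' Specification of a randomly modified transcript library
#'
#' The stand-in for the combinatorial substrate pool of an interference
#' experiment: `n_molecules` transcripts of length `track_length`, each
#' independently decorated with analog incorporations, to be reacted,
#' partitioned into unwound (S1) and bead-retained (S2) fractions, cleaved
#' with iodine at the phosphorothioate tags and read out as sequencing-gel
#' band intensities.
#'
#' @param track_length RNA track length in nucleotides.
#' @param n_molecules Number of transcripts in the pool (default 1e5).
#' @param analogs List of [analog_spec()] objects (typically one per
#'   library; multiple analogs are drawn independently).
#' @param sequence Optional base string of length `track_length` (required
#'   for base-restricted analogs); letters must be in A, C, G, U.
#' @param cleavage_efficiency Probability in `(0, 1]` that a
#'   phosphorothioate linkage is cut by the iodine treatment (default 0.9).
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(track_length, n_molecules = 1e5,
                         analogs = list(analog_spec("2'-deoxy")),
                         sequence = NULL, cleavage_efficiency = 0.9) {
  if (!is_count(track_length))
    stop("`track_length` must be a positive integer", call. = FALSE)
  if (!is_count(n_molecules))
    stop("`n_molecules` must be a positive integer", call. = FALSE)
  if (!is.list(analogs) || !length(analogs) ||
      !all(vapply(analogs, inherits, logical(1), "analog_spec")))
    stop("`analogs` must be a non-empty list of analog_spec objects",
         call. = FALSE)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    letters_ <- strsplit(sequence, "")[[1]]
    if (length(letters_) != track_length)
      stop("`sequence` length must equal `track_length`", call. = FALSE)
    if (!all(letters_ %in% c("A", "C", "G", "U")))
      stop("`sequence` contains letters outside {A, C, G, U}",
           call. = FALSE)
  }
  if (!is.numeric(cleavage_efficiency) || length(cleavage_efficiency) != 1L ||
      cleavage_efficiency <= 0 || cleavage_efficiency > 1)
    stop("`cleavage_efficiency` must be in (0, 1]", call. = FALSE)
  structure(list(track_length = as.integer(track_length),
                 n_molecules = as.integer(n_molecules),
                 analogs = analogs, sequence = sequence,
                 cleavage_efficiency = as.numeric(cleavage_efficiency)),
            class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf("<library_spec> %d molecules, %d-nt track, analogs: %s\n",
              x$n_molecules, x$track_length,
              paste(vapply(x$analogs, `[[`, character(1), "id"),
                    collapse = ", ")))
  invisible(x)
}

#' Densitometry noise model for synthetic gel bands
#'
#' Multiplicative lognormal noise on every band (coefficient of variation
#' `band_cv`) plus a shared per-lane loading factor (SD `lane_factor_sd` on
#' the log scale); both are mean-1 so that intensities stay unbiased.  This
#' is a standard error model for quantified sequencing gels.
#'
#' @param band_cv Per-band coefficient of variation (default 0.10).
#' @param lane_factor_sd Log-scale SD of the per-lane multiplier
#'   (default 0.05).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(band_cv = 0.10, lane_factor_sd = 0.05) {
  if (!is.numeric(band_cv) || band_cv < 0 ||
      !is.numeric(lane_factor_sd) || lane_factor_sd < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  structure(list(band_cv = as.numeric(band_cv),
                 lane_factor_sd = as.numeric(lane_factor_sd)),
            class = "noise_model")
}

eligible_positions <- function(spec, analog) {
  pos <- seq_len(spec$track_length)
  if (!is.null(analog$bases)) {
    if (is.null(spec$sequence))
      stop(sprintf(
        "analog '%s' is base-restricted but the library spec has no sequence",
        analog$id), call. = FALSE)
    letters_ <- strsplit(spec$sequence, "")[[1]]
    pos <- pos[letters_ %in% analog$bases]
  }
  pos
}

#' Draw the per-molecule modification sets of a library
#'
#' Every molecule independently carries each analog at each eligible
#' position with that analog's incorporation probability.
#'
#' @param spec A [library_spec()].
#' @param seed Integer seed (reproducible draws); `NULL` uses the current
#'   RNG state.
#' @return An object of class `mod_library`: list with `spec`,
#'   `n_molecules` and `mods`, a data frame with columns `molecule`,
#'   `position`, `analog` (one row per incorporation).
#' @export
sample_library <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "library_spec"))
  with_seed(seed, {
    parts <- lapply(spec$analogs, function(an) {
      pos <- eligible_positions(spec, an)
      if (length(pos) == 0L || an$incorporation_prob == 0)
        return(NULL)
      hits <- lapply(pos, function(p) {
        mol <- which(stats::runif(spec$n_molecules) < an$incorporation_prob)
        if (length(mol))
          data.frame(molecule = mol, position = p, analog = an$id,
                     stringsAsFactors = FALSE)
      })
      do.call(rbind, hits)
    })
    mods <- do.call(rbind, parts)
    if (is.null(mods))
      mods <- data.frame(molecule = integer(), position = integer(),
                         analog = character(), stringsAsFactors = FALSE)
    structure(list(spec = spec, n_molecules = spec$n_molecules, mods = mods),
              class = "mod_library")
  })
}

# Expand a library's analog penalty definitions into one table of
# per-(molecule, step) multiplicative factors, combining multiple penalties
# on the same step of the same molecule multiplicatively.
penalized_pairs <- function(lib, origin = 1L) {
  mods <- lib$mods
  if (nrow(mods) == 0L)
    return(data.frame(molecule = integer(), step = integer(),
                      kU_factor = numeric(), kD_factor = numeric()))
  specs <- lib$spec$analogs
  names(specs) <- vapply(specs, `[[`, character(1), "id")
  out <- lapply(split(mods, mods$analog), function(m) {
    an <- specs[[m$analog[1]]]
    pen <- an$penalties
    if (is.null(pen)) return(NULL)
    if (is.data.frame(pen)) {
      idx <- match(m$position, pen$position)
      keep <- !is.na(idx)
      if (!any(keep)) return(NULL)
      data.frame(molecule = m$molecule[keep],
                 step = position_to_step(m$position[keep], origin),
                 kU_factor = pen$kU_factor[idx[keep]],
                 kD_factor = pen$kD_factor[idx[keep]])
    } else {
      data.frame(molecule = m$molecule,
                 step = position_to_step(m$position, origin),
                 kU_factor = pen$kU_factor, kD_factor = pen$kD_factor)
    }
  })
  pp <- do.call(rbind, out)
  if (is.null(pp) || nrow(pp) == 0L)
    return(data.frame(molecule = integer(), step = integer(),
                      kU_factor = numeric(), kD_factor = numeric()))
  pp <- pp[pp$kU_factor != 1 | pp$kD_factor != 1, , drop = FALSE]
  if (nrow(pp) == 0L) return(pp)
  key <- paste(pp$molecule, pp$step)
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(cbind(kU_factor, kD_factor) ~ molecule + step,
                            data = pp, FUN = prod)
    pp <- agg
  }
  pp[order(pp$step, pp$molecule), , drop = FALSE]
}
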