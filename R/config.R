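#' Default run configuration
#'
#' The package's stated reference world for an end-to-end synthetic
#' experiment: a 118-nt track analyzed over the window 25-118 (94
#' positions), a homogeneous chain rate-limited by slow activation
#' (k_act = 0.01/s, k_U = 50/s, k_D = 0.5/s per step, baseline amplitude
#' 0.9), a 1e5-molecule library with ~5% 2'-deoxy incorporation whose
#' kinetic penalties act only at the periodic regulatory positions of the
#' default ring geometry, 10% band noise with 5% lane loading noise,
#' 12 sampling times spanning rise and plateau, endpoint NAIM selection at
#' an absolute extent of 0.2, significance bands at 1 and 2.5 SD and
#' |lambda| > 2.5, and 12 control replicates.
#'
#' @param seed Integer master seed; every random draw in the workflow
#'   derives from it.
#' @param out_dir Output directory for the command-line workflow.
#' @return An object of class `run_config` (a named list).
#' @export
default_run_config <- function(seed = 1L, out_dir = "trnaip-out") {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    scheme = list(k_act = 0.01, n_steps = 118L, kU = 50, kD = 0.5,
                  baseline_amplitude = 0.9),
    geometry = list(n_subunits = 6L, period = 7L, offset = 4L),
    library = list(
      track_length = 118L, n_molecules = 100000L,
      cleavage_efficiency = 0.9,
      analogs = list(list(id = "2'-deoxy", incorporation_prob = 0.05,
                          penalties = "regulatory"))),
    noise = list(band_cv = 0.10, lane_factor_sd = 0.05),
    times = c(5, 10, 20, 40, 60, 90, 120, 180, 240, 360, 480, 720),
    window = c(25L, 118L),
    thresholds = list(sd_bands = c(1, 2.5), lambda = 2.5),
    naim_extent = 0.2,
    n_control_replicates = 12L,
    origin = 1L
  )
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Checks presence and legality of every block and returns the config with
#' class `run_config`; a schema violation is an error listing the
#' offending keys.
#'
#' @param cfg A named list as produced by [default_run_config()] or read
#'   from JSON.
#' @return The validated `run_config`.
#' @export
validate_run_config <- function(cfg) {
  bad <- character()
  need <- c("seed", "scheme", "library", "noise", "times", "window",
            "thresholds", "naim_extent")
  bad <- c(bad, setdiff(need, names(cfg)))
  if (!length(bad)) {
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) bad <- c(bad, "seed")
    sch <- tryCatch(config_to_scheme(cfg$scheme), error = function(e) NULL)
    if (is.null(sch)) bad <- c(bad, "scheme")
    geo <- tryCatch(config_to_geometry(cfg$geometry), error = function(e) NULL)
    if (is.null(geo)) bad <- c(bad, "geometry")
    if (!is.null(sch) && !is.null(geo)) {
      lib <- tryCatch(config_to_library(cfg$library, geo),
                      error = function(e) NULL)
      if (is.null(lib)) bad <- c(bad, "library")
    }
    if (!is.numeric(cfg$times) || any(cfg$times <= 0) ||
        any(diff(cfg$times) <= 0)) bad <- c(bad, "times")
    if (!is.numeric(cfg$window) || length(cfg$window) != 2L ||
        cfg$window[1] > cfg$window[2] || cfg$window[1] < 1)
      bad <- c(bad, "window")
    thr <- cfg$thresholds
    if (!is.list(thr) || is.null(thr$sd_bands) || is.null(thr$lambda) ||
        length(thr$sd_bands) != 2L || any(thr$sd_bands <= 0) ||
        diff(thr$sd_bands) <= 0 || thr$lambda <= 0)
      bad <- c(bad, "thresholds")
    if (!is.numeric(cfg$naim_extent) || cfg$naim_extent <= 0 ||
        cfg$naim_extent >= 1) bad <- c(bad, "naim_extent")
    nm <- tryCatch(do.call(noise_model, as.list(cfg$noise)),
                   error = function(e) NULL)
    if (is.null(nm)) bad <- c(bad, "noise")
  }
  if (length(bad))
    stop("invalid run config; offending or missing key(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  cfg$origin <- as.integer(cfg$origin %||% 1L)
  cfg$n_control_replicates <- as.integer(cfg$n_control_replicates %||% 12L)
  cfg$out_dir <- cfg$out_dir %||% "trnaip-out"
  structure(cfg, class = "run_config")
}

#' Build model objects from config blocks
#'
#' `config_to_scheme` accepts either a compact homogeneous block
#' (`k_act`, `n_steps`, `kU`, `kD`, `baseline_amplitude`) or an explicit
#' `steps` list of `{kU, kD}` pairs.  `config_to_geometry` reads
#' `{n_subunits, period, offset}`.  `config_to_library` expands the analog
#' blocks; an analog's `penalties` entry may be `"regulatory"` (default
#' per-analog factors planted at the geometry's regulatory positions), a
#' class-wide `{kU_factor, kD_factor}` pair, a per-position table, or
#' absent (kinetically inert).
#'
#' @param block The corresponding sub-list of a run config.
#' @param geometry A [regulatory_geometry()] (for `config_to_library`).
#' @return A [rate_scheme()], [regulatory_geometry()] or [library_spec()].
#' @export
config_to_scheme <- function(block) {
  if (!is.null(block$steps)) {
    steps <- block$steps
    if (is.data.frame(steps)) steps <- split(steps, seq_len(nrow(steps)))
    kU <- vapply(steps, function(s) as.numeric(s$kU %||% s[["kU"]]),
                 numeric(1))
    kD <- vapply(steps, function(s) as.numeric(s$kD %||% s[["kD"]]),
                 numeric(1))
    rate_scheme(block$k_act, kU, kD,
                block$baseline_amplitude %||% 1)
  } else {
    uniform_rate_scheme(block$n_steps, k_act = block$k_act,
                        k_U = block$kU, k_D = block$kD,
                        baseline_amplitude = block$baseline_amplitude %||% 1)
  }
}

#' @rdname config_to_scheme
#' @export
config_to_geometry <- function(block) {
  if (is.null(block)) return(regulatory_geometry())
  regulatory_geometry(block$n_subunits %||% 6L, block$period %||% 7L,
                      block$offset %||% 4L)
}

#' @rdname config_to_scheme
#' @export
config_to_library <- function(block, geometry = regulatory_geometry()) {
  track_length <- block$track_length
  analogs <- lapply(block$analogs, function(an) {
    pen <- an$penalties
    if (identical(pen, "regulatory")) {
      pen <- regulatory_penalty_table(geometry, track_length,
                                      analog = an$id)
    } else if (is.list(pen) && !is.data.frame(pen) &&
               !is.null(pen$position)) {
      pen <- as.data.frame(pen)
    }
    analog_spec(an$id, an$incorporation_prob %||% 0.05,
                bases = unlist(an$bases), penalties = pen)
  })
  library_spec(track_length, block$n_molecules %||% 1e5, analogs,
               sequence = block$sequence,
               cleavage_efficiency = block$cleavage_efficiency %||% 0.9)
}

#' Serialize a rate scheme (and geometry) to a config block
#'
#' Inverse of [config_to_scheme()]: homogeneous chains are written in the
#' compact form, heterogeneous ones as an explicit `steps` list.
#'
#' @param scheme A [rate_scheme()].
#' @param geometry Optional [regulatory_geometry()] appended as a
#'   `geometry` block.
#' @return A named list serializable with [jsonlite::write_json()].
#' @export
scheme_to_config <- function(scheme, geometry = NULL) {
  stopifnot(inherits(scheme, "rate_scheme"))
  homog <- length(unique(scheme$k_U)) == 1L &&
    length(unique(scheme$k_D)) == 1L
  block <- if (homog)
    list(k_act = scheme$k_act, n_steps = n_steps(scheme),
         kU = scheme$k_U[1], kD = scheme$k_D[1],
         baseline_amplitude = scheme$baseline_amplitude)
  else
    list(k_act = scheme$k_act,
         steps = lapply(seq_len(n_steps(scheme)), function(i)
           list(kU = scheme$k_U[i], kD = scheme$k_D[i])),
         baseline_amplitude = scheme$baseline_amplitude)
  if (!is.null(geometry))
    block$geometry <- unclass(geometry)
  block
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @param cfg A `run_config`.
#' @return `read_run_config` returns a validated `run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
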