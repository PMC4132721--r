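#' Gel band-intensity dataset
#'
#' Container for quantified sequencing-gel band intensities indexed by
#' sampling time, fraction (`S1` unwound supernatant / `S2` bead-recovered)
#' and 1-based track position.  Position 0 is reserved for the "Control"
#' readout (total labeled RNA per fraction, no iodine cleavage).
#'
#' @param data Long-format data frame with columns `time_s`, `fraction`,
#'   `position`, `intensity` (all intensities non-negative; every
#'   (time, position) pair must be present in both fractions).
#' @param metadata Named list (seed, spec hash, noise parameters, ...).
#' @return An object of class `gel_dataset`.
#' @export
gel_dataset <- function(data, metadata = list()) {
  need <- c("time_s", "fraction", "position", "intensity")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("`data` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(data$fraction %in% c("S1", "S2")))
    stop("`fraction` must be 'S1' or 'S2'", call. = FALSE)
  if (any(data$intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  key1 <- with(data[data$fraction == "S1", ], paste(time_s, position))
  key2 <- with(data[data$fraction == "S2", ], paste(time_s, position))
  if (!setequal(key1, key2))
    stop("every (time, position) must be present in both fractions",
         call. = FALSE)
  data$position <- as.integer(data$position)
  rownames(data) <- NULL
  structure(list(data = data, metadata = metadata), class = "gel_dataset")
}

#' @export
print.gel_dataset <- function(x, ...) {
  pos <- setdiff(unique(x$data$position), 0L)
  cat(sprintf(
    "<gel_dataset> %d positions x %d times x 2 fractions (%d rows)%s\n",
    length(pos), length(unique(x$data$time_s)), nrow(x$data),
    if (0L %in% x$data$position) " + control readout" else ""))
  invisible(x)
}

#' Positions present in a gel dataset
#' @param dataset A [gel_dataset()].
#' @param include_control Keep the position-0 control rows?
#' @return Sorted integer positions.
#' @export
dataset_positions <- function(dataset, include_control = FALSE) {
  stopifnot(inherits(dataset, "gel_dataset"))
  pos <- sort(unique(dataset$data$position))
  if (!include_control) pos <- setdiff(pos, 0L)
  pos
}

tsv_header <- c(
  "# trnaip gel dataset (long format)",
  "# positions are 1-based along the transcript; position 0 = control readout (total RNA, no cleavage)",
  "# columns: time_s <tab> fraction (S1 = unwound supernatant, S2 = bead-recovered) <tab> position <tab> intensity")

#' Write / read a gel dataset as TSV (+ JSON metadata sidecar)
#'
#' The TSV carries a comment header stating the position convention;
#' metadata are written to `<path>.meta.json`.  Numeric values round-trip
#' exactly (shortest unique decimal representation).
#'
#' @param dataset A [gel_dataset()].
#' @param path Output TSV path.
#' @return `write_gel_tsv` returns `path` invisibly; `read_gel_tsv` returns
#'   a [gel_dataset()].
#' @export
write_gel_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "gel_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header, con)
  utils::write.table(dataset$data, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(dataset$metadata))
    jsonlite::write_json(dataset$metadata, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_gel_tsv
#' @export
read_gel_tsv <- function(path) {
  data <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  metadata <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  gel_dataset(data, metadata)
}

#' Write / read a per-position band table as TSV
#'
#' Band tables (columns `position`, `intensity`) hold the per-position
#' intensities of one NAIM pool (selected or unselected).
#'
#' @param table Data frame with columns `position` and `intensity`.
#' @param path TSV path.
#' @return `write_band_tsv` returns `path` invisibly; `read_band_tsv`
#'   returns the data frame.
#' @export
write_band_tsv <- function(table, path) {
  if (!all(c("position", "intensity") %in% names(table)))
    stop("band table needs columns position, intensity", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# trnaip band table; positions are 1-based along the transcript",
             con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_band_tsv
#' @export
read_band_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
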