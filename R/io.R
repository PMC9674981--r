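#' Read a two-channel stopped-flow trace from CSV
#'
#' Expects a comma-separated file with a header containing `time_s`,
#' `i405`, `i594` (case-insensitive; `time` and `t_s` are accepted
#' aliases for the time column). Rows with missing or non-finite values
#' and non-monotone time are rejected with the offending line numbers.
#'
#' @param path Path to the CSV file.
#' @param state Processing state to record on the trace (default
#'   `"raw"`).
#' @param meta Optional metadata list.
#' @return An [sf_trace()].
#' @export
read_trace <- function(path, state = "raw", meta = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- tolower(names(df))
  pick <- function(aliases, what) {
    i <- which(nm %in% aliases)
    if (length(i) == 0) stop("missing column ", what, " in ", path)
    df[[i[1]]]
  }
  time_s <- pick(c("time_s", "time", "t_s"), "time_s")
  i405 <- pick(c("i405", "intensity_405", "i_405"), "i405")
  i594 <- pick(c("i594", "intensity_594", "i_594"), "i594")
  bad <- !is.finite(time_s) | !is.finite(i405) | !is.finite(i594)
  if (any(bad))
    stop("non-finite values at line(s) ",
         paste(utils::head(which(bad) + 1, 10), collapse = ", "), " of ", path)
  if (any(diff(time_s) <= 0))
    stop("time not strictly increasing at line(s) ",
         paste(utils::head(which(diff(time_s) <= 0) + 2, 10), collapse = ", "),
         " of ", path)
  sf_trace(time_s, i405, i594, meta = meta, state = state)
}

#' Write a trace to CSV
#'
#' Columns `time_s, i405, i594`; round-trips through [read_trace()] at
#' full precision.
#'
#' @param trace An `sf_trace`.
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sf_trace"))
  utils::write.csv(format(as.data.frame(trace), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis result as versioned JSON
#'
#' Wraps any result record (a `ratio_fit`, `sf_calibration`,
#' `condition_ratio`, morphometry output, or plain list) in an envelope
#' with a schema version, the package version, the seed used, and MD5
#' hashes of any input files, then writes deterministic JSON (fixed key
#' order, no timestamps), so identical inputs give byte-identical files.
#'
#' @param record The result to serialize (lists/data.frames/atomics).
#' @param path Output path.
#' @param seed Seed used to produce the record (recorded, may be NULL).
#' @param inputs Optional character vector of input file paths to hash.
#' @return The envelope, invisibly.
#' @export
write_results <- function(record, path, seed = NULL, inputs = NULL) {
  hashes <- if (length(inputs)) {
    h <- tools::md5sum(inputs)
    as.list(stats::setNames(unname(h), basename(names(h))))
  } else NULL
  envelope <- list(
    schema_version = "1.0",
    software = paste0("vimscatter ",
                      as.character(utils::packageVersion("vimscatter"))),
    seed = seed,
    input_md5 = hashes,
    result = .jsonable(record))
  jsonlite::write_json(envelope, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(envelope)
}

# strip classes/attributes so jsonlite serializes predictably
.jsonable <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, .jsonable))
  x
}

#' Read a filament length table
#'
#' CSV with columns `time_s` and `length` plus a declared unit; nm
#' lengths are converted to ULF units via the inverse of
#' [ulf_to_length()] so downstream fits work in the units of the width
#' law.
#'
#' @param path Path to the CSV file.
#' @param unit `"ulf"` or `"nm"`.
#' @param geometry A [ulf_geometry()] (for nm conversion).
#' @return `data.frame(time_s, length_ulf)`.
#' @export
read_length_table <- function(path, unit = c("ulf", "nm"),
                              geometry = ulf_geometry()) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path)
  nm <- tolower(names(df))
  names(df) <- nm
  if (!all(c("time_s", "length") %in% nm))
    stop("length table needs columns time_s, length")
  if (any(!is.finite(df$length)) || any(df$length <= 0))
    stop("lengths must be finite and positive")
  len <- if (unit == "nm") length_to_ulf(df$length, geometry) else df$length
  data.frame(time_s = df$time_s, length_ulf = len)
}
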