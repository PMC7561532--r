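#' Write a fix table as a track CSV
#'
#' Timestamps are written as ISO-8601 UTC so files round-trip across
#' tools. Extra columns (e.g. `true_state`, `season`, `light`, `state`)
#' are preserved.
#'
#' @param fixes fix data.frame with columns `id, time, x, y` (+ extras).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(fixes, path) {
  out <- fixes
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  names(out)[names(out) == "time"] <- "timestamp"
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a track CSV
#'
#' Accepts `timestamp` (ISO-8601) or `time` columns; adds `source` and
#' `missing` columns when absent. Rows are ordered by animal then time.
#'
#' @param path CSV path.
#' @return fix data.frame with columns `id, time, x, y, source, missing`
#'   plus any extra columns present in the file.
#' @export
read_track_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("timestamp", "time"), names(d))[1]
  if (is.na(tcol)) stop("track CSV needs a 'timestamp' or 'time' column",
                        call. = FALSE)
  d$time <- as.POSIXct(d[[tcol]], tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                      "%Y-%m-%dT%H:%M:%OS",
                                      "%Y-%m-%d %H:%M:%OS"))
  if (tcol != "time") d[[tcol]] <- NULL
  if (is.null(d$source)) d$source <- "observed"
  if (is.null(d$missing)) d$missing <- is.na(d$x) | is.na(d$y)
  d[order(d$id, d$time), , drop = FALSE]
}
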