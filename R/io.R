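#' Read a channel-mean capture from CSV or JSON
#'
#' CSV: columns `t,red,green,blue` (t in seconds), with an optional
#' `# nominal_rate=60` comment line. JSON: object with `nominal_rate`, `t`,
#' `red`, `green`, `blue`. Non-monotone timestamps are rejected with the
#' offending line numbers.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @param nominal_rate Frame rate to assume when the file does not carry one.
#' @return A [channel_series()].
#' @export
read_channel_series <- function(path, format = c("auto", "csv", "json"),
                                nominal_rate = 60) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    j <- jsonlite::fromJSON(path)
    rate <- if (!is.null(j$nominal_rate)) j$nominal_rate else nominal_rate
    return(series_from_columns(j$t, j$red, j$green, j$blue, rate, path))
  }
  first <- readLines(path, n = 1)
  rate <- nominal_rate
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("nominal_rate=([0-9.]+)", first))[[1]]
    if (length(m) == 2) rate <- as.numeric(m[2])
  }
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("t", "red", "green", "blue")
  if (!all(need %in% names(d)))
    hs_invalid_input(sprintf("CSV must have columns %s",
                             paste(need, collapse = ", ")))
  series_from_columns(d$t, d$red, d$green, d$blue, rate, path)
}

series_from_columns <- function(t, red, green, blue, rate, path) {
  if (length(t) >= 2 && any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0) + 1L
    hs_invalid_input(sprintf(
      "%s: timestamps not strictly increasing at data row(s) %s",
      path, paste(utils::head(bad, 5), collapse = ", ")))
  }
  channel_series(t, red, green, blue, nominal_rate = rate)
}

#' Write a channel series to CSV or JSON
#'
#' @param series A [channel_series()].
#' @param path Output path; extension picks the format unless given.
#' @param format `"auto"`, `"csv"` or `"json"`.
#' @param digits Significant digits for CSV serialization (`NA` = full).
#' @return `path`, invisibly.
#' @export
write_channel_series <- function(series, path,
                                 format = c("auto", "csv", "json"),
                                 digits = NA) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    jsonlite::write_json(list(nominal_rate = series$nominal_rate,
                              t = series$t, red = series$red,
                              green = series$green, blue = series$blue),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# nominal_rate=%.10g", series$nominal_rate), con)
    d <- as.data.frame(series)
    if (!is.na(digits)) d[] <- lapply(d, signif, digits = digits)
    utils::write.csv(d, con, row.names = FALSE)
  }
  invisible(path)
}

#' Write a per-window heart-rate report
#'
#' One row per analysis window with per-channel and fused estimates,
#' confidences, the fusion source and the validity flag; CSV or JSON mirror.
#'
#' @param tc An [hr_timecourse()].
#' @param path Output path.
#' @param format `"auto"`, `"csv"` or `"json"`.
#' @param digits Significant digits for serialization (default 6).
#' @return `path`, invisibly.
#' @export
write_hr_windows <- function(tc, path, format = c("auto", "csv", "json"),
                             digits = 6) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  w <- tc$windows
  if (!is.na(digits)) {
    num <- vapply(w, is.numeric, logical(1))
    w[num] <- lapply(w[num], signif, digits = digits)
  }
  if (format == "json") {
    jsonlite::write_json(list(windows = w, retention = tc$retention,
                              cutoff = tc$config$cutoff),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(w, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a displacement track from CSV
#'
#' Columns `t,dx,dy`; a leading comment line declares the dialect and (for
#' the degrees dialect) the anchor, e.g.
#' `# dialect=degrees anchor=32.8801,-117.2340`.
#'
#' @param path File path.
#' @param dialect,anchor Overrides when the header does not declare them.
#' @param rate Samples per second.
#' @return A [displacement_track()].
#' @export
read_track_csv <- function(path, dialect = NULL, anchor = NULL, rate = 1) {
  first <- readLines(path, n = 1)
  if (grepl("^#", first)) {
    md <- regmatches(first, regexec("dialect=(\\w+)", first))[[1]]
    if (length(md) == 2 && is.null(dialect)) dialect <- md[2]
    ma <- regmatches(first,
                     regexec("anchor=(-?[0-9.]+),(-?[0-9.]+)", first))[[1]]
    if (length(ma) == 3 && is.null(anchor))
      anchor <- as.numeric(ma[2:3])
  }
  if (is.null(dialect)) dialect <- "meters"
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("dx", "dy") %in% names(d)))
    hs_invalid_input("track CSV must have columns dx, dy")
  displacement_track(d$dx, d$dy, dialect = dialect, anchor = anchor,
                     rate = rate)
}

#' Write a displacement track to CSV
#'
#' @param track A [displacement_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# dialect=%s%s", track$dialect,
                 if (!is.null(track$anchor))
                   sprintf(" anchor=%.10g,%.10g", track$anchor[1],
                           track$anchor[2]) else "")
  writeLines(hdr, con)
  utils::write.csv(data.frame(t = seq_along(track$dx) / track$rate,
                              dx = track$dx, dy = track$dy),
                   con, row.names = FALSE)
  invisible(path)
}
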