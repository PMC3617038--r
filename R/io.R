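TIME_FMT <- "%Y-%m-%d %H:%M:%S"

parse_time <- function(x, path, lines = NULL) {
  t <- as.POSIXct(as.character(x), tz = "UTC", format = TIME_FMT)
  bad <- which(is.na(t))
  if (length(bad)) {
    where <- if (is.null(lines)) bad[1] else lines[bad[1]]
    stop(sprintf("%s: unparsable timestamp at line %d", path, where),
         call. = FALSE)
  }
  t
}

#' Read a minute-epoch activity-count file
#'
#' Two dialects are auto-detected:
#' \describe{
#'   \item{device-export}{A header block delimited by lines of dashes
#'     (the ActiLife-style export), containing `Start Time HH:MM:SS`,
#'     `Start Date YYYY-MM-DD` and `Epoch Period (hh:mm:ss) 00:01:00`
#'     lines, followed by one count value per line.}
#'   \item{plain}{A headered CSV with columns `timestamp,counts` at a
#'     uniform minute grid.}
#' }
#' Counts must parse as non-negative numbers; violations are reported with
#' their line numbers.
#'
#' @param path File path.
#' @param subject_id Subject id to attach; defaults to the file name
#'   without extension.
#' @return An [epoch_series()].
#' @export
read_epoch_csv <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop(sprintf("%s: empty file", path), call. = FALSE)
  if (grepl("^-{4,}", lines[1])) {
    read_epoch_device(lines, path, subject_id)
  } else {
    read_epoch_plain(lines, path, subject_id)
  }
}

read_epoch_device <- function(lines, path, subject_id) {
  end <- which(grepl("^-{4,}", lines))[-1][1]
  if (is.na(end))
    stop(sprintf("%s: malformed header: no closing dashed line", path),
         call. = FALSE)
  header <- lines[2:(end - 1L)]
  grab <- function(pattern, what) {
    hit <- grep(pattern, header, value = TRUE)
    if (length(hit) != 1L)
      stop(sprintf("%s: malformed header: expected one '%s' line", path,
                   what), call. = FALSE)
    trimws(sub(pattern, "", hit[1]))
  }
  start_time <- grab("^Start Time\\s+", "Start Time")
  start_date <- grab("^Start Date\\s+", "Start Date")
  epoch <- grab("^Epoch Period \\(hh:mm:ss\\)\\s+", "Epoch Period")
  ep <- as.numeric(strsplit(epoch, ":")[[1]])
  if (length(ep) != 3L || any(is.na(ep)))
    stop(sprintf("%s: malformed header: bad epoch period '%s'", path, epoch),
         call. = FALSE)
  epoch_s <- ep[1] * 3600 + ep[2] * 60 + ep[3]
  start <- as.POSIXct(paste(start_date, start_time), tz = "UTC",
                      format = TIME_FMT)
  if (is.na(start))
    stop(sprintf("%s: malformed header: bad start date/time", path),
         call. = FALSE)
  body_idx <- (end + 1L):length(lines)
  body <- trimws(lines[body_idx])
  keep <- nzchar(body)
  body <- body[keep]; body_idx <- body_idx[keep]
  counts <- suppressWarnings(as.numeric(body))
  bad <- which(is.na(counts) | counts < 0)
  if (length(bad))
    stop(sprintf("%s: invalid count value '%s' at line %d", path,
                 body[bad[1]], body_idx[bad[1]]), call. = FALSE)
  epoch_series(subject_id, counts, start_time = start,
               epoch_length = epoch_s)
}

read_epoch_plain <- function(lines, path, subject_id) {
  d <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "counts") %in% names(d)))
    stop(sprintf("%s: expected columns timestamp,counts", path),
         call. = FALSE)
  ts <- parse_time(d$timestamp, path, lines = seq_len(nrow(d)) + 1L)
  counts <- suppressWarnings(as.numeric(d$counts))
  bad <- which(is.na(counts) | counts < 0)
  if (length(bad))
    stop(sprintf("%s: invalid count value '%s' at line %d", path,
                 d$counts[bad[1]], bad[1] + 1L), call. = FALSE)
  if (nrow(d) >= 2L) {
    gaps <- diff(as.numeric(ts))
    if (any(gaps != gaps[1]))
      stop(sprintf("%s: irregular timestamps at line %d", path,
                   which(gaps != gaps[1])[1] + 2L), call. = FALSE)
    epoch_s <- gaps[1]
  } else {
    epoch_s <- 60
  }
  epoch_series(subject_id, counts, start_time = ts[1],
               epoch_length = epoch_s)
}

#' Write an epoch series as plain CSV
#'
#' Plain `timestamp,counts` dialect, losslessly re-readable by
#' [read_epoch_csv()].
#'
#' @param series An [epoch_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  d <- data.frame(timestamp = format(epoch_timestamps(series), TIME_FMT),
                  counts = series$counts)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a minute-level heart-rate log
#'
#' CSV with `timestamp,hr` columns, one value per minute. Duplicate
#' timestamps are an error; missing minutes inside the covered range are
#' reported via a message and returned in the `"gaps"` attribute.
#'
#' @param path File path.
#' @return Data frame (`timestamp`, `hr`) of class `hr_series`, sorted by
#'   time, with attribute `gaps` (POSIXct vector of missing minutes).
#' @export
read_hr_log <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "hr") %in% names(d)))
    stop(sprintf("%s: expected columns timestamp,hr", path), call. = FALSE)
  ts <- parse_time(d$timestamp, path, lines = seq_len(nrow(d)) + 1L)
  if (anyDuplicated(ts))
    stop(sprintf("%s: duplicate timestamp %s", path,
                 format(ts[duplicated(ts)][1], TIME_FMT)), call. = FALSE)
  hr <- suppressWarnings(as.numeric(d$hr))
  if (anyNA(hr))
    stop(sprintf("%s: non-numeric hr at line %d", path,
                 which(is.na(hr))[1] + 1L), call. = FALSE)
  o <- order(ts)
  ts <- ts[o]; hr <- hr[o]
  grid <- seq(ts[1], ts[length(ts)], by = 60)
  gaps <- grid[!grid %in% ts]
  if (length(gaps))
    message(sprintf("%s: %d missing minute(s): %s", path, length(gaps),
                    paste(format(gaps, TIME_FMT), collapse = ", ")))
  out <- data.frame(timestamp = ts, hr = hr)
  class(out) <- c("hr_series", "data.frame")
  attr(out, "gaps") <- gaps
  out
}

#' Write a heart-rate log
#'
#' @param hr Data frame with `timestamp` (POSIXct) and `hr` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hr_log <- function(hr, path) {
  stopifnot(all(c("timestamp", "hr") %in% names(hr)))
  d <- data.frame(timestamp = format(hr$timestamp, TIME_FMT), hr = hr$hr)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align accelerometer and heart-rate clocks
#'
#' Applies a clock offset (seconds, added to the accelerometer timestamps)
#' and trims both series to their common minute grid — the in-software
#' equivalent of synchronizing device initialization time with the test
#' clock.
#'
#' @param hr An `hr_series` (see [read_hr_log()]) or data frame with
#'   `timestamp`, `hr`.
#' @param counts An [epoch_series()] at 60 s epochs.
#' @param offset Seconds to add to the accelerometer clock (default 0).
#' @return An object of class `aligned_series`: list with `timestamp`,
#'   `hr`, `counts` (equal-length, minute grid) and `offset_applied`.
#' @export
align_to_test_clock <- function(hr, counts, offset = 0) {
  stopifnot(inherits(counts, "epoch_series"))
  cts <- epoch_timestamps(counts) + offset
  common <- intersect(as.numeric(hr$timestamp), as.numeric(cts))
  if (length(common) == 0L)
    stop("alignment error: no overlapping minutes after offset",
         call. = FALSE)
  common <- sort(common)
  hi <- match(common, as.numeric(hr$timestamp))
  ci <- match(common, as.numeric(cts))
  structure(
    list(timestamp = as.POSIXct(common, origin = "1970-01-01", tz = "UTC"),
         hr = hr$hr[hi], counts = counts$counts[ci],
         offset_applied = offset),
    class = "aligned_series")
}

#' @export
print.aligned_series <- function(x, ...) {
  cat(sprintf("<aligned_series> %d common minute(s), offset %g s\n",
              length(x$timestamp), x$offset_applied))
  invisible(x)
}

#' Build a calibration session from aligned minute series
#'
#' Chunks an aligned HR/count stream into protocol stages (consecutive
#' blocks of `stage_minutes`, one per speed, stopping when the stream
#' ends) so that file-based data can enter [calibrate_subject()].
#'
#' @param aligned An [align_to_test_clock()] result.
#' @param profile A [subject_profile()].
#' @param protocol A [protocol_spec()].
#' @return A [calibration_session()].
#' @export
session_from_aligned <- function(aligned, profile,
                                 protocol = protocol_spec()) {
  stopifnot(inherits(aligned, "aligned_series"),
            inherits(profile, "subject_profile"))
  n <- length(aligned$hr)
  stages <- list()
  for (i in seq_along(protocol$speeds)) {
    from <- (i - 1L) * protocol$stage_minutes + 1L
    if (from > n) break
    to <- min(i * protocol$stage_minutes, n)
    stages <- c(stages, list(calibration_stage(
      protocol$speeds[i], aligned$hr[from:to], aligned$counts[from:to],
      planned_duration = protocol$stage_minutes)))
  }
  terminated <- n < length(protocol$speeds) * protocol$stage_minutes
  calibration_session(profile, stages, terminated_early = terminated,
                      termination_reason = if (terminated)
                        "stream shorter than full protocol" else
                        NA_character_)
}

#' Read subject profiles from CSV
#'
#' Columns: `subject_id, age, sex, height_cm, weight_kg, resting_hr,
#' max_hr, vo2max`.
#'
#' @param path File path.
#' @return List of [subject_profile()] objects.
#' @export
read_profile_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "height_cm", "weight_kg",
            "resting_hr", "max_hr", "vo2max")
  if (!all(need %in% names(d)))
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  lapply(seq_len(nrow(d)), function(i)
    subject_profile(as.character(d$subject_id[i]), d$age[i], d$sex[i],
                    d$height_cm[i], d$weight_kg[i], d$resting_hr[i],
                    d$max_hr[i], d$vo2max[i]))
}

#' Write per-subject cutpoint tables
#'
#' @param results List of [calibrate_subject()] results (or a single one).
#' @param path Output path.
#' @return `path`, invisibly. Columns: `subject_id, slope, intercept,
#'   orientation, r_squared, moderate_cut, vigorous_cut`.
#' @export
write_cutpoints_csv <- function(results, path) {
  if (inherits(results, "calibration_result")) results <- list(results)
  rows <- lapply(results, function(r)
    data.frame(subject_id = r$subject_id, slope = r$model$slope,
               intercept = r$model$intercept,
               orientation = r$model$orientation,
               r_squared = r$model$r_squared,
               moderate_cut = r$cutpoints$moderate_cut,
               vigorous_cut = r$cutpoints$vigorous_cut))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a cutpoint table
#'
#' @param path CSV written by [write_cutpoints_csv()].
#' @return Data frame.
#' @export
read_cutpoints_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "moderate_cut", "vigorous_cut")
  if (!all(need %in% names(d)))
    stop(sprintf("%s: expected at least columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  d
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (comments with `#`). Numeric values
#' are coerced; everything else stays character. Keys mirror
#' [simulation_config()] and [protocol_spec()] argument names.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("%s: bad config line '%s'", path, ln), call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}
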