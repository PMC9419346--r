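# Readers and writers for the device CSV dialects and the pipeline's own
# epoch/summary outputs. All pairs are lossless round trips on valid data;
# parsers reject (never silently repair) gap and overlap violations.

.AG_RULE <- paste(rep("-", 50), collapse = "")

#' Read an ActiGraph-style raw acceleration CSV
#'
#' Expects the conventional 10-line ActiGraph header block followed by a
#' column-name row and one row per sample. Both the "with timestamp column"
#' and "without" variants are accepted; a constant sampling rate is enforced
#' (any timestamp column must be monotone and consistent with the rate).
#'
#' @param path File path.
#' @param expected_rate Required sampling rate in Hz; a header declaring a
#'   different rate is an error.
#' @param date_format Header date convention: "ymd" (ISO, default), "mdy"
#'   or "dmy".
#' @return A [raw_stream()].
#' @export
read_actigraph_raw <- function(path, expected_rate = 30,
                               date_format = c("ymd", "mdy", "dmy")) {
  date_format <- match.arg(date_format)
  hdr <- readLines(path, n = 10)
  if (length(hdr) < 10 || !grepl("ActiGraph", hdr[1], ignore.case = TRUE))
    stop("malformed header: not an ActiGraph raw CSV")
  m <- regmatches(hdr[1], regexpr("at [0-9.]+ Hz", hdr[1]))
  if (!length(m)) stop("malformed header: sampling rate not declared")
  rate <- as.numeric(sub("at ([0-9.]+) Hz", "\\1", m))
  if (rate != expected_rate)
    stop(sprintf("rate mismatch: header declares %g Hz, expected %g Hz",
                 rate, expected_rate))
  get_field <- function(key) {
    ln <- grep(key, hdr, value = TRUE)
    if (!length(ln)) stop("malformed header: missing '", key, "'")
    trimws(sub(paste0(".*", key, "[: ]*"), "", ln[1]))
  }
  serial <- get_field("Serial Number")
  stime <- get_field("Start Time")
  sdate <- get_field("Start Date")
  start <- .parse_header_date(sdate, stime, date_format)

  body <- utils::read.csv(path, skip = 10, check.names = FALSE)
  cn <- tolower(names(body))
  acc_idx <- grep("accelerometer|axis", cn)
  if (length(acc_idx) != 3) stop("malformed body: expected 3 accelerometer columns")
  ts_idx <- grep("timestamp", cn)
  if (length(ts_idx)) {
    ts <- parse_time(body[[ts_idx[1]]])
    if (nrow(body) > 1) {
      dt <- diff(as.numeric(ts))
      if (any(dt <= 0)) stop("non-monotone timestamps")
      if (any(abs(dt - 1 / rate) > 1e-4))
        stop("gap detected: timestamps inconsistent with declared rate")
    }
    start <- ts[1]
  }
  raw_stream(start, rate, as.matrix(body[acc_idx]), device_id = serial)
}

.parse_header_date <- function(sdate, stime, date_format) {
  fmt <- switch(date_format, ymd = "%Y-%m-%d", mdy = "%m/%d/%Y",
                dmy = "%d/%m/%Y")
  d <- as.Date(sdate, format = fmt)
  if (is.na(d)) stop("malformed header: cannot parse start date '", sdate, "'")
  parse_time(paste(format(d), stime))
}

#' Write an ActiGraph-style raw acceleration CSV
#'
#' @param stream A [raw_stream()].
#' @param path Output path.
#' @param timestamps Include a per-row timestamp column.
#' @return `path`, invisibly.
#' @export
write_actigraph_raw <- function(stream, path, timestamps = FALSE) {
  hdr <- c(
    sprintf("%s Data File Created By ActiGraph GT3X+ ActiLife date format yyyy-MM-dd at %g Hz  Filter Normal %s",
            .AG_RULE, stream$rate_hz, .AG_RULE),
    paste("Serial Number:", stream$device_id),
    paste("Start Time", format(stream$start_time, "%H:%M:%S", tz = .TZ)),
    paste("Start Date", format(stream$start_time, "%Y-%m-%d", tz = .TZ)),
    "Epoch Period (hh:mm:ss) 00:00:00",
    "Download Time 00:00:00",
    "Download Date 1970-01-01",
    "Current Memory Address: 0",
    "Current Battery Voltage: 4.0     Mode = 12",
    .AG_RULE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(stream$data)
  names(df) <- c("Accelerometer X", "Accelerometer Y", "Accelerometer Z")
  if (timestamps) {
    ts <- stream$start_time + (seq_len(nrow(df)) - 1) / stream$rate_hz
    df <- cbind(Timestamp = format_time(ts, digits = 4), df)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ActiGraph-style 60-s epoch counts CSV
#'
#' Expects the 10-line header (declaring a 60-s epoch period) followed by
#' counts rows. The vertical-axis column is located through `column_map`;
#' by default the first column matching a known counts name is used.
#'
#' @param path File path.
#' @param column_map Candidate vertical-axis column names, first match wins.
#' @param date_format Header date convention as in [read_actigraph_raw()].
#' @return A [counts_stream()].
#' @export
read_actigraph_counts <- function(path,
                                  column_map = c("axis1", "activity", "counts",
                                                 "vertical"),
                                  date_format = c("ymd", "mdy", "dmy")) {
  date_format <- match.arg(date_format)
  hdr <- readLines(path, n = 10)
  if (length(hdr) < 10 || !grepl("ActiGraph", hdr[1], ignore.case = TRUE))
    stop("malformed header: not an ActiGraph counts CSV")
  ep_ln <- grep("Epoch Period", hdr, value = TRUE)
  if (!length(ep_ln)) stop("malformed header: missing epoch period")
  ep <- regmatches(ep_ln, regexpr("[0-9]{2}:[0-9]{2}:[0-9]{2}", ep_ln))
  ep_s <- sum(as.numeric(strsplit(ep, ":")[[1]]) * c(3600, 60, 1))
  if (ep_s != 60)
    stop("counts file declares a ", ep_s, "-s epoch; 60 s required")
  get_field <- function(key) {
    ln <- grep(key, hdr, value = TRUE)
    trimws(sub(paste0(".*", key, "[: ]*"), "", ln[1]))
  }
  start <- .parse_header_date(get_field("Start Date"), get_field("Start Time"),
                              date_format)
  body <- utils::read.csv(path, skip = 10, check.names = FALSE)
  cn <- tolower(names(body))
  hit <- which(cn %in% column_map)
  if (!length(hit)) hit <- grep(paste(column_map, collapse = "|"), cn)
  if (!length(hit)) stop("no counts column found (looked for: ",
                         paste(column_map, collapse = ", "), ")")
  counts_stream(start, body[[hit[1]]],
                extra = if (ncol(body) > 1) body[-hit[1]] else NULL)
}

#' Write an ActiGraph-style 60-s epoch counts CSV
#'
#' @param stream A [counts_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_actigraph_counts <- function(stream, path) {
  hdr <- c(
    sprintf("%s Data File Created By ActiGraph GT3X+ ActiLife date format yyyy-MM-dd  Filter Normal %s",
            .AG_RULE, .AG_RULE),
    "Serial Number: NEO0000000000",
    paste("Start Time", format(stream$start_time, "%H:%M:%S", tz = .TZ)),
    paste("Start Date", format(stream$start_time, "%Y-%m-%d", tz = .TZ)),
    "Epoch Period (hh:mm:ss) 00:01:00",
    "Download Time 00:00:00",
    "Download Date 1970-01-01",
    "Current Memory Address: 0",
    "Current Battery Voltage: 4.0     Mode = 12",
    .AG_RULE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(Axis1 = stream$counts), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an activPAL-style events CSV
#'
#' Classic events export: one row per posture interval with start time,
#' duration in seconds and an activity code (0 = sitting/lying, 1 =
#' standing, 2 = stepping). Codes 1 and 2 are collapsed to UPRIGHT; 0 maps
#' to SIT. Contiguity is validated; adjacent same-code events are kept
#' distinct (merging is a preprocessing concern).
#'
#' @param path File path.
#' @param provenance Passed to [posture_events()]; "device" enforces the
#'   10-s posture registration minimum.
#' @return A [posture_events()] list.
#' @export
read_activpal_events <- function(path, provenance = "device") {
  df <- utils::read.csv(path, check.names = FALSE)
  cn <- tolower(names(df))
  t_i <- grep("^time$|start", cn)[1]
  d_i <- grep("interval|duration", cn)[1]
  c_i <- grep("activitycode|activity code|^code$", cn)[1]
  if (anyNA(c(t_i, d_i, c_i))) stop("events file missing required columns")
  codes <- df[[c_i]]
  if (!all(codes %in% 0:2)) stop("unknown activity code: ",
                                 codes[!codes %in% 0:2][1])
  posture_events(parse_time(df[[t_i]]), as.numeric(df[[d_i]]),
                 ifelse(codes == 0, "SIT", "UPRIGHT"),
                 provenance = provenance)
}

#' Write an activPAL-style events CSV
#'
#' @param events A [posture_events()] list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activpal_events <- function(events, path) {
  df <- data.frame(
    Time = format_time(events$start_time),
    `Interval (s)` = sprintf("%.3f", events$duration_s),
    ActivityCode = ifelse(events$code == "SIT", 0L, 1L),
    check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read epoch-level posture predictions
#'
#' CSV with columns timestamp, label, probability; probabilities carry
#' enough digits for a lossless round trip at double precision.
#'
#' @param series An [epoch_series()].
#' @param path File path.
#' @return `write_epoch_predictions` returns `path` invisibly;
#'   `read_epoch_predictions` returns an [epoch_series()].
#' @export
write_epoch_predictions <- function(series, path) {
  probs <- series$probs
  df <- data.frame(
    timestamp = format_time(epoch_times(series)),
    label = series$labels,
    probability = if (is.null(probs)) rep(NA_real_, length(series$labels))
                  else probs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# epoch_s=", series$epoch_s, " source=", series$source),
             con)
  writeLines("timestamp,label,probability", con)
  writeLines(sprintf("%s,%s,%s", df$timestamp, df$label,
                     ifelse(is.na(df$probability), "",
                            sprintf("%.17g", df$probability))), con)
  invisible(path)
}

#' @rdname write_epoch_predictions
#' @export
read_epoch_predictions <- function(path) {
  meta <- readLines(path, n = 1)
  if (!grepl("^# epoch_s=", meta)) stop("missing epoch metadata line")
  epoch_s <- as.numeric(sub("^# epoch_s=([0-9]+).*", "\\1", meta))
  source <- sub(".*source=([a-z]+).*", "\\1", meta)
  df <- utils::read.csv(path, skip = 1)
  if (!all(df$label %in% c("SIT", "NONSIT", "UNWORN")))
    stop("label outside vocabulary")
  probs <- if (all(is.na(df$probability))) NULL else df$probability
  epoch_series(parse_time(df$timestamp[1]), epoch_s, df$label,
               probs = probs, source = source)
}

#' Write / read participant-season summary tables
#'
#' One row per participant-season with the six sedentary variables and
#' valid-day bookkeeping.
#'
#' @param summaries A data.frame as produced by
#'   [summarize_participant_season()] rows bound together.
#' @param path File path.
#' @return `path` invisibly, or the summary data.frame.
#' @export
write_summary_csv <- function(summaries, path) {
  cols <- c("participant", "season", "valid_days", "total_sed_min_day",
            "breaks_per_day", "min_day_bouts_ge30", "mean_bout_min",
            "usual_bout_min", "alpha", "source")
  missing <- setdiff(cols, names(summaries))
  if (length(missing)) stop("summary missing columns: ",
                            paste(missing, collapse = ", "))
  utils::write.csv(summaries[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
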