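#' Read a delimited trace file into a recording session
#'
#' Trace files are comma-delimited UTF-8 text with one header row. The time
#' column is named `t_s` (seconds, strictly increasing, uniform grid); every
#' other column is one channel named `side_muscle_channel`, e.g.
#' `right_TA_gyro_z` or `left_GC_semg_raw`. A `schema` may override the
#' name-based mapping for files with foreign headers.
#'
#' @param path Path to an existing CSV file.
#' @param schema Optional named list mapping a column name to a list with
#'   elements `side`, `muscle`, `channel` (and optionally `units`). Columns
#'   not in the schema fall back to name parsing.
#' @param fs Sampling rate in Hz, required when the file has no `t_s`
#'   column; otherwise inferred from the time grid.
#' @param resample_fs Optional target rate; when given, all channels are
#'   linearly interpolated onto a uniform grid at this rate at load time so
#'   that the whole session shares one `fs`.
#' @param annotations Optional [annotation_set()] (or path to an annotation
#'   CSV readable by [read_annotations()]) attached to the session.
#' @return A [recording_session()]; the original column order is kept in
#'   `meta$column_order`.
#' @export
read_trace_file <- function(path, schema = NULL, fs = NULL,
                            resample_fs = NULL, annotations = NULL) {
  if (!file.exists(path))
    stop("read_trace_file: no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (anyDuplicated(header))
    stop("read_trace_file: schema error: duplicated column name '",
         header[duplicated(header)][1], "'", call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) < 1L)
    stop("read_trace_file: format error: file has no data rows",
         call. = FALSE)
  if (any(vapply(df, function(col) anyNA(col) || !is.numeric(col),
                 logical(1))))
    stop("read_trace_file: format error: non-numeric or missing cells",
         call. = FALSE)

  t0 <- 0
  if ("t_s" %in% names(df)) {
    t <- df[["t_s"]]
    dt <- diff(t)
    if (length(dt) && any(dt <= 0))
      stop("read_trace_file: format error: time column not strictly ",
           "increasing", call. = FALSE)
    if (length(dt)) {
      fs_file <- 1 / stats::median(dt)
      if (length(dt) > 1 && max(abs(dt - stats::median(dt))) >
            0.01 * stats::median(dt))
        stop("read_trace_file: format error: time grid is not uniform",
             call. = FALSE)
    } else {
      if (is.null(fs))
        stop("read_trace_file: single-row file needs an explicit fs",
             call. = FALSE)
      fs_file <- fs
    }
    t0 <- t[1]
    df_sig <- df[setdiff(names(df), "t_s")]
  } else {
    if (is.null(fs))
      stop("read_trace_file: schema error: no 't_s' column and no fs given",
           call. = FALSE)
    fs_file <- fs
    df_sig <- df
  }
  if (length(df_sig) == 0L)
    stop("read_trace_file: schema error: no signal columns", call. = FALSE)

  parse_col <- function(nm) {
    if (!is.null(schema) && !is.null(schema[[nm]])) {
      sc <- schema[[nm]]
      if (is.null(sc$side) || is.null(sc$muscle) || is.null(sc$channel))
        stop("read_trace_file: schema error: entry for '", nm,
             "' needs side, muscle, channel", call. = FALSE)
      return(list(side = sc$side, muscle = sc$muscle, channel = sc$channel,
                  units = if (is.null(sc$units)) "" else sc$units))
    }
    m <- regmatches(nm, regexec(
      "^(left|right)_(TA|GC|none)_(gyro_z|semg_raw|semg_envelope|semg_type|fused)$",
      nm))[[1]]
    if (length(m) != 4L)
      stop("read_trace_file: schema error: cannot map column '", nm,
           "' to (side, muscle, channel)", call. = FALSE)
    list(side = m[2], muscle = m[3], channel = m[4], units = "")
  }

  traces <- lapply(names(df_sig), function(nm) {
    p <- parse_col(nm)
    v <- df_sig[[nm]]
    fs_use <- fs_file
    t0_use <- t0
    if (!is.null(resample_fs) && abs(resample_fs - fs_file) > 1e-9) {
      n_out <- max(2L, as.integer(floor((length(v) - 1) / fs_file *
                                          resample_fs)) + 1L)
      t_in <- t0 + (seq_along(v) - 1) / fs_file
      t_out <- t0 + (seq_len(n_out) - 1) / resample_fs
      v <- stats::approx(t_in, v, xout = t_out, rule = 2)$y
      fs_use <- resample_fs
    }
    signal_trace(v, fs_use, channel = p$channel, side = p$side,
                 muscle = p$muscle, units = p$units, t0 = t0_use)
  })

  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (is.null(annotations)) annotations <- annotation_set()
  recording_session(traces, annotations,
                    meta = list(column_order = names(df_sig),
                                source_path = path))
}

#' Write a recording session to a delimited trace file
#'
#' Inverse of [read_trace_file()]: one `t_s` column plus one column per
#' trace, named `side_muscle_channel`, with enough digits (15 significant)
#' for a round trip faithful to about 1e-12 relative precision.
#'
#' @param session A [recording_session()] with at least one trace.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_file <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  if (length(session$traces) == 0L)
    stop("write_trace_file: session has no traces", call. = FALSE)
  tr1 <- session$traces[[1]]
  cols <- c(list(t_s = trace_times(tr1)),
            lapply(session$traces, `[[`, "values"))
  df <- as.data.frame(cols, check.names = FALSE)
  ord <- session$meta$column_order
  if (!is.null(ord) && setequal(ord, names(session$traces)))
    df <- df[c("t_s", ord)]
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("write_trace_file: cannot open '", path, "' for writing",
         call. = FALSE))
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, function(col)
    sprintf("%.15g", col)), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read an interval annotation file
#'
#' Annotation files are CSV with header `start_s,end_s,label`.
#'
#' @param path Path to the CSV.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    stop("read_annotations: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("start_s", "end_s", "label") %in% names(df)))
    stop("read_annotations: header must be start_s,end_s,label",
         call. = FALSE)
  annotation_set(df$start_s, df$end_s, df$label)
}

#' Write an interval annotation file
#'
#' @param ann An [annotation_set()] (header-only file when empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  validate_annotations(ann)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("write_annotations: cannot open '", path, "' for writing",
         call. = FALSE))
  on.exit(close(con))
  writeLines("start_s,end_s,label", con)
  if (nrow(ann))
    writeLines(sprintf("%.15g,%.15g,%s", ann$start_s, ann$end_s, ann$label),
               con)
  invisible(path)
}
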