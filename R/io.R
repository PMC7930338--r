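# Reading beat-time / rhythm annotations and the package's tabular outputs.
# All times leave this module in seconds; sample indices never escape it.

#' Typed error helpers
#' @noRd
.format_error <- function(msg) {
  stop(errorCondition(msg, class = c("rgg_format_error", "error", "condition")))
}

#' @noRd
.data_error <- function(msg) {
  stop(errorCondition(msg, class = c("rgg_data_error", "error", "condition")))
}

# Rhythm labels seen across PhysioNet Holter databases (aux strings with the
# leading "(" removed).  Unknown labels are kept verbatim with a warning.
.known_rhythm_labels <- c(
  "AF", "AFIB", "AFL", "N", "NSR", "SBR", "B", "BII", "T", "VT", "SVTA",
  "AB", "IVR", "P", "PREX", "J", "NOD", "VFL", "AVB", "PAC"
)

#' Normalize a rhythm label
#'
#' Strips the PhysioNet aux-string prefix `"("` and maps the atrial
#' fibrillation synonyms `"(AFIB"`, `"AFIB"`, `"AF"` to `"AF"`.
#'
#' @param x character vector of raw labels.
#' @return character vector of normalized labels.
#' @export
normalize_rhythm_label <- function(x) {
  x <- sub("^\\(", "", as.character(x))
  x[x %in% c("AFIB", "AF")] <- "AF"
  unknown <- setdiff(unique(x), .known_rhythm_labels)
  if (length(unknown) > 0L) {
    warning("unknown rhythm label(s) kept verbatim: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  x
}

#' Beat-time container
#'
#' Strictly increasing beat occurrence times in seconds from record start.
#'
#' @param times numeric vector of beat times, seconds, strictly increasing,
#'   all non-negative.
#' @param record_id opaque record identifier.
#' @return an object of class `beat_times`.
#' @export
beat_times <- function(times, record_id = "record") {
  times <- as.numeric(times)
  if (anyNA(times)) .data_error("beat times contain NA")
  if (length(times) > 0L && any(times < 0)) .data_error("beat times must be >= 0")
  if (length(times) > 1L) {
    bad <- which(diff(times) <= 0)
    if (length(bad) > 0L) {
      .data_error(sprintf("beat times not strictly increasing at index %d", bad[1L] + 1L))
    }
  }
  structure(list(times = times, record_id = as.character(record_id)[1L]),
            class = "beat_times")
}

#' @export
print.beat_times <- function(x, ...) {
  cat(sprintf("<beat_times> record '%s': %d beats", x$record_id, length(x$times)))
  if (length(x$times) > 0L) {
    cat(sprintf(", t = [%.3f, %.3f] s", x$times[1L], x$times[length(x$times)]))
  }
  cat("\n")
  invisible(x)
}

#' RR-interval series
#'
#' Inter-beat intervals in seconds.  `timestamps[i]` is the occurrence time of
#' the beat that terminates interval `i`.
#'
#' @param intervals numeric vector of RR intervals, seconds, all positive.
#' @param timestamps numeric vector, same length, strictly increasing.
#' @param record_id opaque record identifier.
#' @return an object of class `rr_series`.
#' @export
rr_series <- function(intervals, timestamps, record_id = "record") {
  intervals <- as.numeric(intervals)
  timestamps <- as.numeric(timestamps)
  if (length(intervals) != length(timestamps)) {
    .data_error("intervals and timestamps must have equal length")
  }
  if (length(intervals) > 0L && any(intervals <= 0)) {
    .data_error("all RR intervals must be > 0")
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    .data_error("timestamps must be strictly increasing")
  }
  structure(list(intervals = intervals, timestamps = timestamps,
                 record_id = as.character(record_id)[1L]),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> record '%s': %d intervals", x$record_id,
              length(x$intervals)))
  if (length(x$intervals) > 0L) {
    cat(sprintf(", mean RR %.3f s, span %.1f s", mean(x$intervals),
                x$timestamps[length(x$timestamps)]))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Derive an RR-interval series from beat times
#'
#' Consecutive beat times are subtracted to yield inter-beat intervals;
#' interval `i` is stamped with the time of its terminating beat.
#'
#' @param beats a [beat_times] object.
#' @return an [rr_series] of length `max(0, n_beats - 1)`.
#' @export
rr_from_beats <- function(beats) {
  stopifnot(inherits(beats, "beat_times"))
  n <- length(beats$times)
  if (n < 2L) {
    return(rr_series(numeric(0), numeric(0), beats$record_id))
  }
  rr_series(diff(beats$times), beats$times[-1L], beats$record_id)
}

# ---------------------------------------------------------------------------
# WFDB (MIT-format) annotation files.
#
# The format is a stream of 16-bit little-endian words; the top 6 bits are an
# annotation type code and the low 10 bits a time increment in samples.
# Pseudo-annotation codes: 59 = SKIP (next two words hold a 32-bit time
# increment, high word first), 60/61/62 = NUM/SUB/CHN (ignored here),
# 63 = AUX (low bits give the byte count of an aux string, padded to even
# length, attached to the most recent annotation).  A zero word ends the file.

.wfdb_beat_codes <- c(1:13, 25L, 34L, 35L, 38L)
.WFDB_RHYTHM <- 28L

#' Parse a WFDB annotation file into a raw annotation table
#' @return data.frame with columns sample, code, aux
#' @noRd
.parse_wfdb_annotations <- function(path) {
  raw <- tryCatch(readBin(path, "raw", n = file.info(path)$size),
                  error = function(e) .format_error(paste("cannot read", path)))
  n <- length(raw)
  if (n %% 2L != 0L) .format_error("WFDB annotation file has odd byte count")
  ints <- as.integer(raw)
  out_sample <- integer(0)
  out_code <- integer(0)
  out_aux <- character(0)
  t <- 0
  i <- 1L
  pending_skip <- 0
  while (i + 1L <= n) {
    word <- ints[i] + 256L * ints[i + 1L]
    i <- i + 2L
    code <- word %/% 1024L
    delta <- word %% 1024L
    if (code == 0L && delta == 0L) break
    if (code == 59L) {          # SKIP: 32-bit increment in the next two words
      if (i + 3L > n) .format_error("truncated SKIP in WFDB annotation file")
      hi <- ints[i] + 256L * ints[i + 1L]
      lo <- ints[i + 2L] + 256L * ints[i + 3L]
      i <- i + 4L
      pending_skip <- pending_skip + hi * 65536 + lo
    } else if (code == 63L) {   # AUX string attached to previous annotation
      nb <- delta
      nread <- nb + (nb %% 2L)
      if (i + nread - 1L > n) .format_error("truncated AUX in WFDB annotation file")
      bytes <- raw[i:(i + nb - 1L)]
      bytes <- bytes[!bytes %in% as.raw(c(0L, 255L))]
      s <- rawToChar(bytes)
      i <- i + nread
      if (length(out_aux) > 0L) out_aux[length(out_aux)] <- s
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM / SUB / CHN: no time content
    } else {
      t <- t + delta + pending_skip
      pending_skip <- 0
      out_sample <- c(out_sample, t)
      out_code <- c(out_code, code)
      out_aux <- c(out_aux, "")
    }
  }
  data.frame(sample = out_sample, code = out_code, aux = out_aux,
             stringsAsFactors = FALSE)
}

#' Read beat annotations
#'
#' Reads beat occurrence times from either a simple CSV (beat times in
#' seconds, comma- or newline-separated) or a binary WFDB (MIT-format)
#' annotation file, in which case the sampling frequency `fs` is required to
#' convert sample indices to seconds.  Times are sorted and duplicate beat
#' times collapsed.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"wfdb"`.
#' @param fs sampling frequency in Hz; required for `dialect = "wfdb"`.
#' @param record_id identifier stored on the result; defaults to the file
#'   base name.
#' @return a [beat_times] object, times in seconds.
#' @export
read_beat_annotations <- function(path, dialect = c("csv", "wfdb"), fs = NULL,
                                  record_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .format_error(paste("no such file:", path))
  if (is.null(record_id)) {
    record_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (dialect == "csv") {
    times <- tryCatch(
      scan(path, what = numeric(), sep = ",", quiet = TRUE),
      error = function(e) .format_error(sprintf("cannot parse '%s' as beat-time CSV: %s",
                                                path, conditionMessage(e))),
      warning = function(w) .format_error(sprintf("cannot parse '%s' as beat-time CSV",
                                                  path)))
    if (anyNA(times)) .format_error(sprintf("non-numeric beat time in '%s'", path))
  } else {
    if (is.null(fs) || !is.numeric(fs) || fs <= 0) {
      .format_error("sampling frequency 'fs' required for the wfdb dialect")
    }
    ann <- .parse_wfdb_annotations(path)
    times <- ann$sample[ann$code %in% .wfdb_beat_codes] / fs
  }
  beat_times(sort(unique(times)), record_id)
}

#' Close a rhythm-change event stream into labeled segments
#'
#' @param times event times (seconds), temporally ordered.
#' @param labels rhythm label at each event (normalized via
#'   [normalize_rhythm_label]).
#' @param record_end time at which the final open segment is closed, seconds.
#' @return data.frame of class `rhythm_segments` with columns
#'   `start`, `end`, `label`.
#' @export
segments_from_events <- function(times, labels, record_end) {
  times <- as.numeric(times)
  if (length(times) == 0L) .data_error("no rhythm events")
  if (is.unsorted(times, strictly = FALSE)) {
    .data_error("rhythm events must be in temporal order")
  }
  if (record_end <= times[length(times)]) {
    .data_error("record_end must exceed the last event time")
  }
  seg <- data.frame(start = times,
                    end = c(times[-1L], record_end),
                    label = normalize_rhythm_label(labels),
                    stringsAsFactors = FALSE)
  seg <- seg[seg$end > seg$start, , drop = FALSE]
  rownames(seg) <- NULL
  rhythm_segments(seg)
}

#' Rhythm-segment table constructor/validator
#'
#' @param seg data.frame with numeric `start`, `end` (seconds) and character
#'   `label` columns; segments must be non-overlapping.
#' @return the validated data.frame with class `rhythm_segments` prepended.
#' @export
rhythm_segments <- function(seg) {
  stopifnot(is.data.frame(seg), all(c("start", "end", "label") %in% names(seg)))
  if (any(seg$start >= seg$end)) .data_error("segment start must precede end")
  o <- order(seg$start)
  seg <- seg[o, , drop = FALSE]
  if (nrow(seg) > 1L &&
      any(seg$start[-1L] < seg$end[-nrow(seg)] - 1e-9)) {
    .data_error("rhythm segments overlap")
  }
  rownames(seg) <- NULL
  class(seg) <- unique(c("rhythm_segments", class(seg)))
  seg
}

#' Read rhythm annotations as labeled segments
#'
#' CSV dialect: one segment per row, `start,end,label` (seconds).  WFDB
#' dialect: rhythm-change annotations (aux strings such as `"(AFIB"`,
#' `"(N"`) are converted into closed segments; the final segment is closed at
#' `record_end` if supplied, otherwise at the last beat time of `beats`
#' (flagged with attribute `closed_at_last_beat`).
#'
#' @param path file path.
#' @param dialect `"csv"` or `"wfdb"`.
#' @param fs sampling frequency, Hz (wfdb dialect).
#' @param record_end record duration in seconds, if known.
#' @param beats optional [beat_times] used to infer `record_end`.
#' @return a `rhythm_segments` data.frame.
#' @export
read_rhythm_segments <- function(path, dialect = c("csv", "wfdb"), fs = NULL,
                                 record_end = NULL, beats = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .format_error(paste("no such file:", path))
  if (dialect == "csv") {
    df <- tryCatch(
      utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE),
      error = function(e) .format_error(sprintf("cannot parse '%s' as segment CSV", path)))
    if (ncol(df) != 3L) {
      .format_error(sprintf("segment CSV '%s' must have 3 columns (start,end,label)", path))
    }
    names(df) <- c("start", "end", "label")
    if (!is.numeric(df$start) || !is.numeric(df$end)) {
      .format_error(sprintf("non-numeric segment bounds in '%s'", path))
    }
    df$label <- normalize_rhythm_label(df$label)
    return(rhythm_segments(df))
  }
  if (is.null(fs) || !is.numeric(fs) || fs <= 0) {
    .format_error("sampling frequency 'fs' required for the wfdb dialect")
  }
  ann <- .parse_wfdb_annotations(path)
  rhy <- ann[ann$code == .WFDB_RHYTHM & nzchar(ann$aux), , drop = FALSE]
  if (nrow(rhy) == 0L) .data_error(sprintf("no rhythm annotations in '%s'", path))
  closed_at_last_beat <- FALSE
  if (is.null(record_end)) {
    if (!is.null(beats)) {
      stopifnot(inherits(beats, "beat_times"))
      record_end <- beats$times[length(beats$times)]
      closed_at_last_beat <- TRUE
    } else {
      .data_error("record_end or beats needed to close the final rhythm segment")
    }
  }
  seg <- segments_from_events(rhy$sample / fs, rhy$aux, record_end)
  attr(seg, "closed_at_last_beat") <- closed_at_last_beat
  seg
}

# ---------------------------------------------------------------------------
# Window-index tables (the RGG's row type and the classifier's features).

.index_table_cols <- c("record_id", "window_start_beat", "window_end_beat",
                       "t_start", "t_end", "variability", "normality",
                       "mean_rr", "label")

#' Write a window-index table to CSV
#'
#' Numeric columns are written with 17 significant digits so that
#' `read_index_table(write_index_table(x))` round-trips exactly.
#'
#' @param records data.frame with the window-index schema (see
#'   [compute_indices]).
#' @param path output path.
#' @export
write_index_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.index_table_cols, names(records))
  if (length(missing_cols) > 0L) {
    .format_error(paste("index table missing column(s):",
                        paste(missing_cols, collapse = ", ")))
  }
  out <- records[, .index_table_cols, drop = FALSE]
  for (cn in c("t_start", "t_end", "variability", "normality", "mean_rr")) {
    out[[cn]] <- sprintf("%.17g", out[[cn]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a window-index table from CSV
#'
#' @param path CSV written by [write_index_table].
#' @return data.frame with the window-index schema.
#' @export
read_index_table <- function(path) {
  if (!file.exists(path)) .format_error(paste("no such file:", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) .format_error(sprintf("cannot parse '%s' as index CSV", path)))
  missing_cols <- setdiff(.index_table_cols, names(df))
  if (length(missing_cols) > 0L) {
    .format_error(paste("index table missing column(s):",
                        paste(missing_cols, collapse = ", ")))
  }
  df <- df[, .index_table_cols, drop = FALSE]
  df$record_id <- as.character(df$record_id)
  df$label <- as.character(df$label)
  for (cn in c("window_start_beat", "window_end_beat")) {
    df[[cn]] <- as.integer(df[[cn]])
  }
  for (cn in c("t_start", "t_end", "variability", "normality", "mean_rr")) {
    df[[cn]] <- as.numeric(df[[cn]])
  }
  df
}
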