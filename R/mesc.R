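# The modified entropy scale (MESC) and sliding estimation windows.

#' MESC series of a given order
#'
#' The MESC of order 0 is the RR-interval series itself; the MESC of order n
#' is the series of differences between consecutive MESC values of order
#' n - 1.  Equivalently, value i of the order-n series is the alternating
#' binomial combination `sum_k (-1)^k choose(n, k) rr[i + n - k]`.
#'
#' @param rr an [rr_series].
#' @param order non-negative integer.
#' @return object of class `mesc_series`: list with `values` (seconds),
#'   `order`, `record_id`.  Length is `max(0, length(rr) - order)`; if the
#'   series is too short an empty result is returned with a warning.
#' @export
mesc <- function(rr, order = 1L) {
  stopifnot(inherits(rr, "rr_series"))
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || order < 0L) {
    stop("order must be a single non-negative integer", call. = FALSE)
  }
  v <- rr$intervals
  if (length(v) <= order && order > 0L) {
    warning(sprintf("RR series of length %d too short for MESC order %d",
                    length(v), order), call. = FALSE)
    v <- numeric(0)
  } else if (order > 0L) {
    v <- diff(v, differences = order)
  }
  structure(list(values = v, order = order, record_id = rr$record_id),
            class = "mesc_series")
}

#' @export
print.mesc_series <- function(x, ...) {
  cat(sprintf("<mesc_series> order %d, record '%s': %d values\n",
              x$order, x$record_id, length(x$values)))
  invisible(x)
}

#' @export
length.mesc_series <- function(x) length(x$values)

#' @export
as.numeric.mesc_series <- function(x, ...) x$values

#' Build overlapping estimation windows over an RR series
#'
#' Windows are half-open runs of `window_length` consecutive RR intervals
#' starting at beat indices 0, `stride`, `2*stride`, ...; a final partial
#' window is discarded.  `t_start` is the onset time of the window's first
#' interval and `t_end` the time of its last terminating beat.
#'
#' @param rr an [rr_series].
#' @param window_length window length W in beats (>= 2).
#' @param stride step between window starts in beats (1..W).
#' @return data.frame with columns `start_beat` (0-based), `end_beat`
#'   (exclusive), `t_start`, `t_end`, `label` (`NA` until [label_windows]).
#' @export
make_windows <- function(rr, window_length = 150L, stride = 30L) {
  stopifnot(inherits(rr, "rr_series"))
  window_length <- as.integer(window_length)
  stride <- as.integer(stride)
  if (window_length < 2L) stop("window_length must be >= 2", call. = FALSE)
  if (stride < 1L || stride > window_length) {
    stop("stride must be in 1..window_length", call. = FALSE)
  }
  n <- length(rr$intervals)
  if (n < window_length) {
    return(data.frame(start_beat = integer(0), end_beat = integer(0),
                      t_start = numeric(0), t_end = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  starts <- seq.int(0L, n - window_length, by = stride)
  ends <- starts + window_length
  data.frame(
    start_beat = starts,
    end_beat = ends,
    t_start = rr$timestamps[starts + 1L] - rr$intervals[starts + 1L],
    t_end = rr$timestamps[ends],
    label = NA_character_,
    stringsAsFactors = FALSE)
}

#' Label estimation windows from rhythm segments
#'
#' A window wholly inside AF segments is labeled `"AF"`, wholly inside
#' non-AF segments `"non-AF"`; a window spanning a rhythm boundary, or lying
#' outside all segments, is `"ambiguous"` (downstream consumers discard it).
#'
#' @param windows data.frame from [make_windows].
#' @param segments a `rhythm_segments` data.frame (non-overlapping).
#' @param eps tolerance in seconds for containment at segment seams.
#' @return `windows` with the `label` column filled.
#' @export
label_windows <- function(windows, segments, eps = 1e-9) {
  segments <- rhythm_segments(as.data.frame(segments))
  if (nrow(windows) == 0L) return(windows)
  # segments are sorted by start; locate each window endpoint's segment
  i1 <- findInterval(windows$t_start + eps, segments$start)
  i2 <- findInterval(windows$t_end - eps, segments$start)
  lab <- rep("ambiguous", nrow(windows))
  same <- i1 == i2 & i1 >= 1L
  inside <- same
  inside[same] <- windows$t_start[same] >= segments$start[i1[same]] - eps &
    windows$t_end[same] <= segments$end[i1[same]] + eps
  lab[inside] <- ifelse(segments$label[i1[inside]] == "AF", "AF", "non-AF")
  outside <- i1 < 1L | windows$t_start > segments$end[nrow(segments)] + eps
  if (any(outside)) {
    warning(sprintf("%d window(s) outside all rhythm segments marked ambiguous",
                    sum(outside)), call. = FALSE)
  }
  windows$label <- lab
  windows
}
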