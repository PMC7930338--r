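# The regularogram: per-window index scatter plots and rectangle-based
# AF-burden estimation.

#' Build a regularogram from a window-index table
#'
#' Each non-ambiguous estimation window contributes one point; x is the
#' variability index, y the normality index, and (for `dims = 3`) z the mean
#' RR of the window.
#'
#' @param records window-index data.frame from [compute_indices] (ambiguous
#'   windows must already be absent).
#' @param dims 2 or 3.
#' @return object of class `rgg`: list with `points` (data.frame), `dims`,
#'   `record_id`.
#' @export
build_rgg <- function(records, dims = 2L) {
  stopifnot(is.data.frame(records))
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3", call. = FALSE)
  if (nrow(records) == 0L) stop("no windows to plot", call. = FALSE)
  if (any(records$label %in% "ambiguous")) {
    stop("ambiguous windows must be removed before building an RGG",
         call. = FALSE)
  }
  cols <- c("variability", "normality")
  if (dims == 3L) cols <- c(cols, "mean_rr")
  pts <- records[, cols, drop = FALSE]
  pts$label <- if ("label" %in% names(records)) records$label else NA_character_
  structure(list(points = pts, dims = dims,
                 record_id = paste(unique(records$record_id), collapse = "+")),
            class = "rgg")
}

#' @export
print.rgg <- function(x, ...) {
  cat(sprintf("<rgg> %d-D, record '%s': %d windows\n", x$dims, x$record_id,
              nrow(x$points)))
  if (!all(is.na(x$points$label))) {
    print(table(x$points$label))
  }
  invisible(x)
}

.rgg_palette <- c("AF" = "#d62728", "non-AF" = "#1f77b4")

#' @noRd
.rgg_colors <- function(labels) {
  if (all(is.na(labels))) return(rep("#333333", length(labels)))
  cols <- .rgg_palette[labels]
  cols[is.na(cols)] <- "#7f7f7f"
  cols
}

#' Plot a regularogram
#'
#' 2-D regularograms use base graphics; 3-D ones (variability, normality,
#' mean RR) use [lattice::cloud].  Points are color-coded by label when
#' labels are present.
#'
#' @param x an `rgg` object.
#' @param main plot title.
#' @param cex point size.
#' @param ... passed to the underlying plotting function.
#' @export
plot.rgg <- function(x, main = sprintf("Regularogram: %s", x$record_id),
                     cex = 0.6, ...) {
  cols <- .rgg_colors(x$points$label)
  has_labels <- !all(is.na(x$points$label))
  if (x$dims == 2L) {
    graphics::plot(x$points$variability, x$points$normality, col = cols,
                   pch = 16, cex = cex, xlab = "Variability (s)",
                   ylab = "Normality", main = main,
                   ylim = c(0, 1), ...)
    if (has_labels) {
      labs <- sort(unique(x$points$label))
      graphics::legend("bottomright", legend = labs,
                       col = .rgg_colors(labs), pch = 16, bty = "n")
    }
  } else {
    p <- lattice::cloud(mean_rr ~ variability * normality, data = x$points,
                        col = cols, pch = 16, cex = cex, main = main,
                        xlab = "Variability (s)", ylab = "Normality",
                        zlab = "Mean RR (s)", ...)
    print(p)
  }
  invisible(x)
}

#' Render a regularogram to an image file
#'
#' The output format follows the file extension (`.svg` or `.png`); given
#' identical data and options the output is deterministic.
#'
#' @param rgg an `rgg` object.
#' @param path output path ending in `.svg` or `.png`.
#' @param width,height device size in inches.
#' @param ... passed to [plot.rgg].
#' @return `path`, invisibly.
#' @export
render_rgg <- function(rgg, path, width = 7, height = 6, ...) {
  stopifnot(inherits(rgg, "rgg"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(rgg, ...)
  invisible(path)
}

#' Rectangular zone on the regularogram plane
#'
#' @param v_min,v_max variability bounds, seconds.
#' @param n_min,n_max normality bounds, unitless.
#' @return object of class `zone_rect`.
#' @export
zone_rect <- function(v_min, v_max, n_min, n_max) {
  stopifnot(is.numeric(v_min), is.numeric(v_max),
            is.numeric(n_min), is.numeric(n_max))
  if (v_min >= v_max || n_min >= n_max) {
    stop("zone rectangle must satisfy v_min < v_max and n_min < n_max",
         call. = FALSE)
  }
  structure(list(v_min = v_min, v_max = v_max, n_min = n_min, n_max = n_max),
            class = "zone_rect")
}

#' Estimate AF burden from a marked rectangle
#'
#' Fraction of non-ambiguous estimation windows whose (variability,
#' normality) point lies inside the closed rectangle; with
#' `time_weighted = TRUE` windows are weighted by their duration instead.
#'
#' @param records window-index data.frame.
#' @param rect a [zone_rect].
#' @param time_weighted weight windows by `t_end - t_start`?
#' @return fraction in `[0, 1]`.
#' @export
estimate_burden <- function(records, rect, time_weighted = FALSE) {
  stopifnot(is.data.frame(records), inherits(rect, "zone_rect"))
  if (nrow(records) == 0L) stop("no windows", call. = FALSE)
  inside <- records$variability >= rect$v_min &
    records$variability <= rect$v_max &
    records$normality >= rect$n_min &
    records$normality <= rect$n_max
  if (time_weighted) {
    w <- records$t_end - records$t_start
    sum(w[inside]) / sum(w)
  } else {
    mean(inside)
  }
}

#' Mean absolute burden-estimation error, in percent
#'
#' @param estimates per-record estimated AF burdens (fractions).
#' @param truths per-record annotated AF window fractions.
#' @return mean absolute error as a percentage.
#' @export
burden_error <- function(estimates, truths) {
  estimates <- as.numeric(estimates)
  truths <- as.numeric(truths)
  if (length(estimates) != length(truths) || length(estimates) == 0L) {
    stop("estimates and truths must be equal-length, non-empty", call. = FALSE)
  }
  100 * mean(abs(estimates - truths))
}
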