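# Per-window variability / normality / mean indices and the
# Kolmogorov-Smirnov machinery behind the normality index.

#' Variability index: distribution width of the windowed MESC
#'
#' Implemented as the sample standard deviation (n - 1 denominator); a robust
#' alternative (interquartile range) is available via `estimator = "iqr"`.
#' Scale-equivariant: `variability(c * x) == abs(c) * variability(x)`.
#'
#' @param mesc_values numeric vector of MESC values from one window (>= 2).
#' @param estimator `"sd"` (default) or `"iqr"`.
#' @return non-negative scalar, seconds.
#' @export
variability <- function(mesc_values, estimator = c("sd", "iqr")) {
  estimator <- match.arg(estimator)
  x <- as.numeric(mesc_values)
  if (length(x) < 2L) stop("variability needs at least 2 values", call. = FALSE)
  switch(estimator, sd = stats::sd(x), iqr = stats::IQR(x))
}

#' Exact one-sample Kolmogorov-Smirnov statistic
#'
#' `D = sup_x |F_n(x) - F(x)|`, evaluated as the maximum over sorted sample
#' points of both one-sided gaps `|i/n - F(x_(i))|` and `|(i-1)/n - F(x_(i))|`.
#'
#' @param sample non-empty numeric vector.
#' @param reference_cdf vectorized distribution function mapping into `[0,1]`.
#' @return D in `[0, 1]`.
#' @export
ks_statistic_exact <- function(sample, reference_cdf = stats::pnorm) {
  x <- sort(as.numeric(sample))
  n <- length(x)
  if (n == 0L) stop("empty sample", call. = FALSE)
  Fx <- reference_cdf(x)
  i <- seq_len(n)
  max(pmax(abs(i / n - Fx), abs((i - 1) / n - Fx)))
}

#' Fast binned Kolmogorov-Smirnov estimator
#'
#' Single-pass estimator: the sample is counted into `grid_size`
#' equal-probability bins of the reference distribution and the cumulative
#' bin fractions are compared with the reference CDF at the bin edges.  No
#' sorting is required and `|D_fast - D_exact| <= 1/grid_size` always
#' (the estimator never exceeds the exact statistic).
#'
#' @param sample non-empty numeric vector.
#' @param reference_cdf vectorized distribution function (used only when
#'   `reference_quantile` must be derived numerically).
#' @param grid_size number of probability bins (>= 8).
#' @param reference_quantile quantile function of the reference distribution;
#'   defaults to [stats::qnorm].  If `NULL`, bin edges are obtained by
#'   numerically inverting `reference_cdf`.
#' @return approximate D in `[0, 1]`.
#' @export
ks_statistic_fast <- function(sample, reference_cdf = stats::pnorm,
                              grid_size = 32L,
                              reference_quantile = stats::qnorm) {
  x <- as.numeric(sample)
  n <- length(x)
  if (n == 0L) stop("empty sample", call. = FALSE)
  grid_size <- as.integer(grid_size)
  if (grid_size < 8L) stop("grid_size must be >= 8", call. = FALSE)
  p <- seq_len(grid_size - 1L) / grid_size
  if (is.null(reference_quantile)) {
    edges <- .invert_cdf(reference_cdf, p, x)
  } else {
    edges <- reference_quantile(p)
  }
  # bins (e[j-1], e[j]]: cumulative counts give the empirical CDF at edges
  counts <- tabulate(findInterval(x, edges, left.open = TRUE) + 1L,
                     nbins = grid_size)
  max(abs(cumsum(counts[-grid_size]) / n - p))
}

#' Numeric inversion of a CDF at probabilities p (fallback path)
#' @noRd
.invert_cdf <- function(cdf, p, sample) {
  lo <- min(sample) - 1
  hi <- max(sample) + 1
  while (cdf(lo) > min(p)) lo <- lo - 2 * (hi - lo)
  while (cdf(hi) < max(p)) hi <- hi + 2 * (hi - lo)
  vapply(p, function(pi) {
    stats::uniroot(function(q) cdf(q) - pi, lower = lo, upper = hi,
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Normality index: closeness of the windowed MESC to a Gaussian
#'
#' The window's MESC values are standardized by their own sample mean and
#' standard deviation and compared against the standard normal distribution;
#' the index is `1 - D` where `D` is the Kolmogorov-Smirnov distance.  A
#' zero-variance (perfectly regular) window returns 0, the extreme opposite
#' of irregular irregularity.  Invariant under affine rescaling of the input.
#'
#' @param mesc_values numeric vector of MESC values from one window (>= 8).
#' @param ks_mode `"fast"` (binned estimator, default) or `"exact"`.
#' @param ks_grid_size bins for the fast estimator.
#' @return unitless value in `[0, 1]`; high for AF-like random changes.
#' @export
normality <- function(mesc_values, ks_mode = c("fast", "exact"),
                      ks_grid_size = 32L) {
  ks_mode <- match.arg(ks_mode)
  x <- as.numeric(mesc_values)
  if (length(x) < 8L) stop("normality needs at least 8 values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) return(0)
  z <- (x - mean(x)) / s
  D <- if (ks_mode == "exact") {
    ks_statistic_exact(z, stats::pnorm)
  } else {
    ks_statistic_fast(z, stats::pnorm, grid_size = ks_grid_size)
  }
  1 - D
}

#' Mean index: arithmetic mean of the order-0 MESC (the RR intervals)
#'
#' Addresses the tachycardic tendency of AF: rapid episodes have a low mean
#' RR regardless of their irregularity.
#'
#' @param rr_window numeric vector of RR intervals from one window (>= 1).
#' @return mean RR in seconds.
#' @export
mean_index <- function(rr_window) {
  x <- as.numeric(rr_window)
  if (length(x) == 0L) stop("empty window", call. = FALSE)
  mean(x)
}

#' Index-computation configuration
#'
#' @param mesc_order MESC order used for variability/normality (default 1).
#' @param window_length estimation-window length in beats (default 150).
#' @param stride step between window starts in beats (default 30).
#' @param variability_estimator `"sd"` or `"iqr"`.
#' @param ks_mode `"fast"` or `"exact"`.
#' @param ks_grid_size bins for the fast KS estimator (default 32).
#' @return a validated list of class `index_config`.
#' @export
index_config <- function(mesc_order = 1L, window_length = 150L, stride = 30L,
                         variability_estimator = c("sd", "iqr"),
                         ks_mode = c("fast", "exact"), ks_grid_size = 32L) {
  cfg <- list(
    mesc_order = as.integer(mesc_order),
    window_length = as.integer(window_length),
    stride = as.integer(stride),
    variability_estimator = match.arg(variability_estimator),
    ks_mode = match.arg(ks_mode),
    ks_grid_size = as.integer(ks_grid_size))
  if (cfg$mesc_order < 0L) stop("mesc_order must be >= 0", call. = FALSE)
  if (cfg$window_length < cfg$mesc_order + 8L) {
    stop("window_length must be >= mesc_order + 8 for the normality index",
         call. = FALSE)
  }
  if (cfg$stride < 1L || cfg$stride > cfg$window_length) {
    stop("stride must be in 1..window_length", call. = FALSE)
  }
  structure(cfg, class = "index_config")
}

#' Compute the per-window index table of a record
#'
#' Builds overlapping estimation windows, labels them from the rhythm
#' segments, discards ambiguously labeled windows, and computes for each
#' remaining window the variability and normality of the order-n MESC and
#' the mean of the order-0 MESC (the RR intervals).
#'
#' @param rr an [rr_series].
#' @param segments a `rhythm_segments` data.frame.
#' @param config an [index_config].
#' @return data.frame with columns `record_id`, `window_start_beat`,
#'   `window_end_beat`, `t_start`, `t_end`, `variability`, `normality`,
#'   `mean_rr`, `label` (`"AF"` / `"non-AF"`); one row per non-ambiguous
#'   window.
#' @export
compute_indices <- function(rr, segments, config = index_config()) {
  stopifnot(inherits(rr, "rr_series"), inherits(config, "index_config"))
  w <- make_windows(rr, config$window_length, config$stride)
  w <- label_windows(w, segments)
  w <- w[w$label != "ambiguous", , drop = FALSE]
  n_w <- nrow(w)
  m <- mesc(rr, config$mesc_order)$values
  ord <- config$mesc_order
  W <- config$window_length
  vr <- numeric(n_w)
  nr <- numeric(n_w)
  mu <- numeric(n_w)
  for (k in seq_len(n_w)) {
    s <- w$start_beat[k]                  # 0-based
    mv <- m[(s + 1L):(s + W - ord)]
    vr[k] <- variability(mv, config$variability_estimator)
    nr[k] <- normality(mv, config$ks_mode, config$ks_grid_size)
    mu[k] <- mean_index(rr$intervals[(s + 1L):(s + W)])
  }
  data.frame(
    record_id = rep(rr$record_id, n_w),
    window_start_beat = w$start_beat,
    window_end_beat = w$end_beat,
    t_start = w$t_start,
    t_end = w$t_end,
    variability = vr,
    normality = nr,
    mean_rr = mu,
    label = w$label,
    stringsAsFactors = FALSE)
}
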