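# Seeded synthetic RR-interval generator with ground-truth rhythm segments.
#
# The generator targets the distributional structure the indices assume:
# AF as a clipped, mean-reverting Gaussian random walk on RR (so the order-1
# MESC is approximately normal), sinus rhythm as a respiratory sinusoid plus
# jitter, and the regularly-irregular rhythms (bigeminy, trigeminy, AV
# block, premature complexes) as superpositions of a few regular rhythms.

.rr_clip <- c(0.25, 2.5)   # physiologic RR bounds, seconds

#' Rhythm profile for the synthetic generator
#'
#' Kinds and their parameters (all times in seconds):
#' * `"AF"`: `mesc_sd` (sd of the beat-to-beat random step; the order-1 MESC
#'   sd), `reversion` (mean-reversion coefficient per beat).
#' * `"NSR"`: `resp_amplitude`, `resp_period_beats`, `jitter_sd`.
#' * `"bigeminy"`: `short_rr`, `long_rr`, `jitter_sd` (period-2 alternation).
#' * `"trigeminy"`: `normal_rr`, `short_rr`, `long_rr`, `jitter_sd`
#'   (period-3 pattern).
#' * `"av_block"`: NSR parameters plus `drop_probability`; a dropped beat
#'   merges its two adjacent intervals.
#' * `"pac"`: NSR parameters plus `pac_rate` and `coupling_fraction`; a
#'   premature interval `coupling_fraction * mean_rr` is followed by a
#'   compensatory pause.
#'
#' @param kind one of `"AF"`, `"NSR"`, `"bigeminy"`, `"trigeminy"`,
#'   `"av_block"`, `"pac"`.
#' @param mean_rr mean RR in seconds (0.3 to 2.0); kind-specific default.
#' @param ... kind-specific parameters overriding the defaults above.
#' @return object of class `rhythm_profile`.
#' @export
rhythm_profile <- function(kind = c("AF", "NSR", "bigeminy", "trigeminy",
                                    "av_block", "pac"),
                           mean_rr = NULL, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    AF = list(mean_rr = 0.55, mesc_sd = 0.10, reversion = 0.25),
    NSR = list(mean_rr = 0.85, resp_amplitude = 0.025, resp_period_beats = 5,
               jitter_sd = 0.01),
    bigeminy = list(short_rr = 0.5, long_rr = 1.0, jitter_sd = 0.01),
    trigeminy = list(normal_rr = 0.8, short_rr = 0.5, long_rr = 1.1,
                     jitter_sd = 0.01),
    av_block = list(mean_rr = 0.85, resp_amplitude = 0.025,
                    resp_period_beats = 5, jitter_sd = 0.01,
                    drop_probability = 0.1),
    pac = list(mean_rr = 0.85, resp_amplitude = 0.025, resp_period_beats = 5,
               jitter_sd = 0.01, pac_rate = 0.05, coupling_fraction = 0.6))
  p <- utils::modifyList(defaults, list(...))
  if (!is.null(mean_rr)) p$mean_rr <- mean_rr
  if (kind == "bigeminy") p$mean_rr <- (p$short_rr + p$long_rr) / 2
  if (kind == "trigeminy") p$mean_rr <- mean(c(p$normal_rr, p$short_rr, p$long_rr))
  if (p$mean_rr < 0.3 || p$mean_rr > 2.0) {
    stop("mean_rr must lie in [0.3, 2.0] s", call. = FALSE)
  }
  sds <- p[names(p) %in% c("mesc_sd", "jitter_sd", "resp_amplitude")]
  if (any(unlist(sds) < 0)) stop("spread parameters must be >= 0", call. = FALSE)
  probs <- p[names(p) %in% c("drop_probability", "pac_rate", "coupling_fraction")]
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(c(list(kind = kind), p), class = "rhythm_profile")
}

#' Ground-truth label written by a profile
#' @noRd
.profile_label <- function(kind) {
  switch(kind, AF = "AF", NSR = "N", bigeminy = "B", trigeminy = "T",
         av_block = "AVB", pac = "PAC")
}

#' Generate one rhythm segment of RR intervals
#'
#' Uses the current RNG state unless `seed` is given.  All intervals are
#' clipped to the physiologic bounds 0.25 to 2.5 s.
#'
#' @param profile a [rhythm_profile].
#' @param n_beats number of RR intervals to generate (>= 2).
#' @param seed optional integer seed.
#' @return numeric vector of RR intervals, seconds.
#' @export
gen_segment <- function(profile, n_beats, seed = NULL) {
  stopifnot(inherits(profile, "rhythm_profile"))
  n_beats <- as.integer(n_beats)
  if (n_beats < 2L) stop("n_beats must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- profile
  rr <- switch(p$kind,
    AF = {
      phi <- 1 - p$reversion
      eps <- stats::rnorm(n_beats, 0, p$mesc_sd)
      init <- if (phi < 1 && p$mesc_sd > 0) {
        stats::rnorm(1, 0, p$mesc_sd / sqrt(1 - phi^2))
      } else 0
      dev <- as.numeric(stats::filter(eps, phi, method = "recursive",
                                      init = init))
      p$mean_rr + dev
    },
    NSR = .nsr_rr(p, n_beats),
    bigeminy = rep_len(c(p$short_rr, p$long_rr), n_beats) +
      stats::rnorm(n_beats, 0, p$jitter_sd),
    trigeminy = rep_len(c(p$normal_rr, p$short_rr, p$long_rr), n_beats) +
      stats::rnorm(n_beats, 0, p$jitter_sd),
    av_block = {
      # generate surplus sinus beats, drop beats, re-difference the times
      p_keep <- max(1 - p$drop_probability, 0.05)
      rr2 <- numeric(0)
      while (length(rr2) < n_beats) {
        n_gen <- ceiling((n_beats + 20) / p_keep * 1.2) + 50L
        base <- .nsr_rr(p, n_gen)
        times <- cumsum(c(0, base))
        keep <- c(TRUE, stats::runif(n_gen) >= p$drop_probability)
        rr2 <- c(rr2, diff(times[keep]))
      }
      rr2[seq_len(n_beats)]
    },
    pac = {
      base <- .nsr_rr(p, n_beats)
      is_pac <- stats::runif(n_beats) < p$pac_rate
      is_pac[n_beats] <- FALSE
      is_pac[which(is_pac[-n_beats]) + 1L] <- FALSE  # no back-to-back PACs
      for (i in which(is_pac)) {
        base[i] <- p$coupling_fraction * p$mean_rr
        base[i + 1L] <- (2 - p$coupling_fraction) * p$mean_rr  # compensatory
      }
      base
    })
  pmin(pmax(rr, .rr_clip[1L]), .rr_clip[2L])
}

#' Sinus-rhythm RR: respiratory sinusoid plus Gaussian jitter
#' @noRd
.nsr_rr <- function(p, n) {
  i <- seq_len(n)
  p$mean_rr + p$resp_amplitude * sin(2 * pi * i / p$resp_period_beats) +
    stats::rnorm(n, 0, p$jitter_sd)
}

#' Generate a full synthetic record with ground-truth segments
#'
#' Concatenates rhythm segments; ground-truth segment boundaries are placed
#' at the temporal seams of the cumulative beat times.  The same seed always
#' reproduces the identical record.
#'
#' @param profile_sequence list of `list(profile = <rhythm_profile>,
#'   n_beats = <int>)` entries.
#' @param seed integer seed.
#' @param record_id identifier.
#' @return object of class `synthetic_record`: list with `rr`
#'   ([rr_series]), `segments` (`rhythm_segments` ground truth),
#'   `profile_sequence`, `seed`.
#' @export
gen_record <- function(profile_sequence, seed = 1L, record_id = "synthetic") {
  stopifnot(length(profile_sequence) >= 1L)
  set.seed(seed)
  .gen_record_core(profile_sequence, record_id, seed)
}

#' @noRd
.gen_record_core <- function(profile_sequence, record_id, seed) {
  chunks <- lapply(profile_sequence, function(ps) {
    gen_segment(ps$profile, ps$n_beats)
  })
  durations <- vapply(chunks, sum, numeric(1))
  bounds <- cumsum(c(0, durations))
  seg <- data.frame(
    start = bounds[-length(bounds)],
    end = bounds[-1L],
    label = vapply(profile_sequence,
                   function(ps) .profile_label(ps$profile$kind), character(1)),
    stringsAsFactors = FALSE)
  intervals <- unlist(chunks)
  rr <- rr_series(intervals, cumsum(intervals), record_id)
  structure(list(rr = rr, segments = rhythm_segments(seg),
                 profile_sequence = profile_sequence, seed = seed),
            class = "synthetic_record")
}

#' @export
print.synthetic_record <- function(x, ...) {
  cat(sprintf("<synthetic_record> '%s': %d beats, %d segment(s), seed %d\n",
              x$rr$record_id, length(x$rr$intervals), nrow(x$segments),
              x$seed))
  print(table(x$segments$label))
  invisible(x)
}

#' The generator's designed AF zone on the regularogram plane
#'
#' The rectangle that, by construction of the default synthetic cohort,
#' contains AF windows and excludes sinus-rhythm windows (low variability)
#' and bigeminy/trigeminy windows (low normality).  Used as the
#' "known-truth" marked rectangle in burden experiments.
#'
#' @return a [zone_rect].
#' @export
synthetic_af_zone <- function() {
  zone_rect(v_min = 0.04, v_max = 1.0, n_min = 0.75, n_max = 1.0)
}

#' Generate a synthetic cohort of paroxysmal-AF records
#'
#' Per-patient parameters are drawn once per record so that inter-patient
#' variability exists: AF mean RR ~ U(0.5, 0.75) s and MESC sd ~
#' U(0.06, 0.09) s (AF is tachycardic on average, but the mean-rate ranges
#' overlap sinus rhythm, as in physiology); sinus mean RR ~
#' U(0.70, 1.0) s, respiratory amplitude ~ U(0.010, 0.025) s, respiratory
#' period 4-7 beats, jitter sd ~ U(0.005, 0.012) s.  The AF burden is drawn
#' from `af_burden_range` and split over 2-5 episodes interleaved with
#' sinus blocks.  An ectopy block (bigeminy / trigeminy / none, cycling
#' deterministically over the patient index so every cohort contains each
#' kind) replaces part of one sinus block.  Deterministic per seed.
#'
#' @param n_patients number of records (>= 2).
#' @param af_burden_range range the per-record AF time fraction is drawn
#'   from.
#' @param seed integer seed.
#' @param beats_per_record total beats per record.
#' @param id_prefix prefix of the generated record ids (keep cohorts
#'   id-disjoint by using different prefixes).
#' @return list of `synthetic_record`s; each carries its parameter draws in
#'   attribute `params`.
#' @export
gen_cohort <- function(n_patients = 20L, af_burden_range = c(0.05, 0.95),
                       seed = 1L, beats_per_record = 8000L,
                       id_prefix = "synth") {
  n_patients <- as.integer(n_patients)
  if (n_patients < 2L) stop("n_patients must be >= 2", call. = FALSE)
  stopifnot(length(af_burden_range) == 2L,
            af_burden_range[1L] >= 0, af_burden_range[2L] <= 1,
            af_burden_range[1L] < af_burden_range[2L])
  set.seed(seed)
  record_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
  ectopy_cycle <- c("bigeminy", "trigeminy", "none")
  lapply(seq_len(n_patients), function(i) {
    set.seed(record_seeds[i])
    burden <- stats::runif(1, af_burden_range[1L], af_burden_range[2L])
    af_prof <- rhythm_profile("AF",
                              mean_rr = stats::runif(1, 0.5, 0.75),
                              mesc_sd = stats::runif(1, 0.06, 0.09))
    nsr_prof <- rhythm_profile("NSR",
                               mean_rr = stats::runif(1, 0.70, 1.0),
                               resp_amplitude = stats::runif(1, 0.010, 0.025),
                               resp_period_beats = sample(4:7, 1),
                               jitter_sd = stats::runif(1, 0.005, 0.012))
    total <- beats_per_record
    af_total <- round(burden * total)
    nsr_total <- total - af_total
    n_ep <- max(1L, min(sample(2:5, 1), af_total %/% 150L))
    af_lens <- .split_beats(af_total, n_ep)
    nsr_lens <- .split_beats(nsr_total, n_ep + 1L)
    seqs <- list()
    for (e in seq_len(n_ep + 1L)) {
      if (nsr_lens[e] >= 2L) {
        seqs[[length(seqs) + 1L]] <- list(profile = nsr_prof,
                                          n_beats = nsr_lens[e])
      }
      if (e <= n_ep && af_lens[e] >= 2L) {
        seqs[[length(seqs) + 1L]] <- list(profile = af_prof,
                                          n_beats = af_lens[e])
      }
    }
    # carve an ectopy block out of the first sufficiently long sinus block
    ect_kind <- ectopy_cycle[(i - 1L) %% length(ectopy_cycle) + 1L]
    if (ect_kind != "none") {
      for (s in seq_along(seqs)) {
        if (seqs[[s]]$profile$kind == "NSR" && seqs[[s]]$n_beats >= 1000L) {
          block <- as.integer(round(0.25 * seqs[[s]]$n_beats))
          seqs[[s]]$n_beats <- seqs[[s]]$n_beats - block
          seqs <- append(seqs, list(list(profile = rhythm_profile(ect_kind),
                                         n_beats = block)), after = s)
          break
        }
      }
    }
    rec <- .gen_record_core(seqs, sprintf("%s-%03d", id_prefix, i),
                            record_seeds[i])
    attr(rec, "params") <- list(burden = burden, af = af_prof,
                                nsr = nsr_prof, ectopy = ect_kind)
    rec
  })
}

#' Split n beats into k parts with random proportions (each >= ~10%)
#' @noRd
.split_beats <- function(n, k) {
  if (k == 1L) return(n)
  w <- stats::runif(k, 0.5, 1.5)
  lens <- floor(n * w / sum(w))
  lens[1L] <- lens[1L] + (n - sum(lens))
  as.integer(lens)
}

#' Write a synthetic record in the CSV dialects the readers consume
#'
#' Emits `<prefix>_beats.csv` (beat times in seconds, one per row, with the
#' record-start beat at 0) and `<prefix>_segments.csv` (`start,end,label`
#' rows).
#'
#' @param record a `synthetic_record`.
#' @param prefix output path prefix.
#' @return named character vector of the two paths, invisibly.
#' @export
write_synthetic_record <- function(record, prefix) {
  stopifnot(inherits(record, "synthetic_record"))
  beats_path <- paste0(prefix, "_beats.csv")
  seg_path <- paste0(prefix, "_segments.csv")
  beats <- c(0, record$rr$timestamps)
  writeLines(sprintf("%.17g", beats), beats_path)
  seg <- record$segments
  writeLines(sprintf("%.17g,%.17g,%s", seg$start, seg$end, seg$label),
             seg_path)
  invisible(c(beats = beats_path, segments = seg_path))
}
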