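# Shared fixture builders (all fixtures are generated in code at test time).

# Minimal MIT-format annotation writer: 16-bit little-endian words, top 6
# bits = type code, low 10 bits = sample delta; SKIP (59) escapes deltas
# >= 1024; AUX (63) attaches a string to the preceding annotation.
write_wfdb_ann <- function(path, samples, codes, aux = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  put_word <- function(w) writeBin(as.raw(c(w %% 256L, w %/% 256L)), con)
  prev <- 0L
  for (i in seq_along(samples)) {
    delta <- samples[i] - prev
    prev <- samples[i]
    if (delta >= 1024L) {
      put_word(59L * 1024L)                 # SKIP, I = 0
      put_word(delta %/% 65536L)            # high word
      put_word(delta %% 65536L)             # low word
      delta <- 0L
    }
    put_word(codes[i] * 1024L + delta)
    if (!is.null(aux) && nzchar(aux[i])) {
      b <- charToRaw(aux[i])
      put_word(63L * 1024L + length(b))
      writeBin(b, con)
      if (length(b) %% 2L == 1L) writeBin(as.raw(0L), con)
    }
  }
  put_word(0L)                              # EOF
  invisible(path)
}

# RR series with timestamps at the cumulative sums.
make_rr <- function(values, record_id = "rr") {
  rr_series(values, cumsum(values), record_id)
}

# Single-rhythm rr_series + full-cover segment table for a profile kind.
single_rhythm_record <- function(kind, n_beats = 2000, seed = 1, ...) {
  set.seed(seed)
  v <- gen_segment(rhythm_profile(kind, ...), n_beats)
  list(rr = make_rr(v, paste0(kind, seed)),
       segments = rhythm_segments(data.frame(
         start = 0, end = sum(v) + 1,
         label = switch(kind, AF = "AF", NSR = "N", bigeminy = "B",
                        trigeminy = "T", av_block = "AVB", pac = "PAC"))))
}

# Fine-grained rhythm label of each (non-ambiguous) window in an index
# table, looked up from the record's ground-truth segments.
fine_window_labels <- function(tab, segments) {
  segments <- as.data.frame(segments)
  segments$label[findInterval(tab$t_start + 1e-9, segments$start)]
}
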