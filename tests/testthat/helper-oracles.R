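# Independent oracles and fixture builders shared across the test files.

# Exhaustive segment-enumeration drop detector, written independently of the
# incremental state machine in the package: walks the trace, maintains the
# prior maximum by explicit scanning, and for each sub-threshold excursion
# enumerates its full extent to find the trough.
oracle_detect_drops <- function(a, thr = 0.30) {
  n <- length(a)
  events <- list()
  max_val <- a[1]
  max_step <- 1L
  j <- 2L
  while (j <= n) {
    if (max_val > 0 && a[j] <= (1 - thr) * max_val) {
      k <- j + 1L
      while (k <= n && a[k] <= (1 - thr) * max_val) k <- k + 1L
      seg <- a[j:(k - 1L)]
      trough_step <- j - 1L + which.min(seg)
      trough_val <- min(seg)
      events[[length(events) + 1L]] <- data.frame(
        peak_step = max_step, trough_step = trough_step,
        peak_uv = max_val, trough_uv = trough_val,
        relative_drop = 1 - trough_val / max_val,
        drop_db = 20 * log10(max_val / max(trough_val,
                                           .Machine$double.xmin)))
      if (k <= n && a[k] >= max_val) {
        max_val <- a[k]
        max_step <- k
      }
      j <- k + 1L
    } else {
      if (a[j] > max_val) {
        max_val <- a[j]
        max_step <- j
      }
      j <- j + 1L
    }
  }
  if (length(events) == 0L) {
    return(data.frame(peak_step = integer(0), trough_step = integer(0),
                      peak_uv = numeric(0), trough_uv = numeric(0),
                      relative_drop = numeric(0), drop_db = numeric(0)))
  }
  do.call(rbind, events)
}

# Random positive amplitude trace (multiplicative random walk with
# occasional sharp drops) for property tests.
random_trace <- function(n = 20) {
  a <- numeric(n)
  a[1] <- stats::runif(1, 2, 15)
  for (i in 2:n) {
    step <- if (stats::runif(1) < 0.15) {
      stats::runif(1, 0.3, 0.7)   # sharp drop
    } else {
      exp(stats::rnorm(1, 0.03, 0.12))
    }
    a[i] <- a[i - 1] * step
  }
  a
}

# Build a two-frequency insertion_trace directly from amplitude vectors.
make_trace <- function(a250, a500 = a250) {
  insertion_trace(list("250" = a250, "500" = a500))
}

# Single-frequency trace helper (column amp_500 only).
make_trace_500 <- function(a500) {
  insertion_trace(list("500" = a500))
}

# Near-flat excitation: space constants so large the tonotopic profile is
# constant to ~1e-8 relative over an insertion, isolating scripted
# attenuations from the tonotopic slope.
flat_excitation <- function(peak_uv = 10) {
  excitation_params(peak_uv = peak_uv, basal_space_deg = 1e10,
                    apical_space_deg = 1e10, peak_offset_deg = 0)
}

# Pure-tone analysis window (cycle-aligned) built from first principles.
pure_tone_window <- function(amp_uv, freq_hz, n_cycles, fs_hz = 20000,
                             phase = 0) {
  n <- round(n_cycles * fs_hz / freq_hz)
  amp_uv * sin(2 * pi * freq_hz * (seq_len(n) - 1) / fs_hz + phase)
}
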