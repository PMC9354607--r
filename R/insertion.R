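# Insertion-trajectory metrics: per-step CM traces, drop detection, drop
# magnitude/count, pattern typing, and the trauma-vs-CF-crossing call.

trace_col <- function(trace, freq, what = "amp") {
  col <- paste0(what, "_", freq)
  if (!col %in% names(trace)) {
    stop(sprintf("trace has no %d-Hz `%s` column", freq, what), call. = FALSE)
  }
  trace[[col]]
}

#' Construct an insertion trace from per-step amplitudes
#'
#' Low-level constructor used both by the waveform pipeline
#' ([build_insertion_trace()]) and by amplitude-level simulation.
#'
#' @param amplitudes Named list mapping frequency (e.g. `"250"`, `"500"`) to
#'   a numeric vector of per-step CM amplitudes (microvolts, >= 0).
#' @param significant Optional named list of logical vectors (same shape);
#'   defaults to all `TRUE`.
#' @param step Optional step indices (default `1:n`).
#' @return Data frame of class `insertion_trace` with columns `step`,
#'   `amp_<freq>` and `sig_<freq>`.
#' @export
insertion_trace <- function(amplitudes, significant = NULL, step = NULL) {
  stopifnot(is.list(amplitudes), length(amplitudes) >= 1)
  n <- length(amplitudes[[1]])
  if (any(vapply(amplitudes, length, 1L) != n)) {
    stop("amplitude vectors differ in length", call. = FALSE)
  }
  if (any(unlist(amplitudes) < 0)) {
    stop("amplitudes must be >= 0", call. = FALSE)
  }
  if (is.null(step)) step <- seq_len(n)
  if (is.unsorted(step, strictly = TRUE)) {
    stop("`step` must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(step = as.integer(step))
  for (f in names(amplitudes)) {
    out[[paste0("amp_", f)]] <- as.numeric(amplitudes[[f]])
    sig <- if (is.null(significant)) rep(TRUE, n) else significant[[f]]
    out[[paste0("sig_", f)]] <- as.logical(sig)
  }
  class(out) <- c("insertion_trace", "data.frame")
  out
}

#' Build an insertion trace from phase-pair recordings
#'
#' Applies the full single-step pipeline -- difference curve, ongoing
#' window, spectral amplitude -- to every insertion step and stimulus
#' frequency, and flags each amplitude against the 3-SD noise floor
#' estimated from the run's stimulus-free pairs. Steps containing
#' non-finite samples are excluded with a warning.
#'
#' @param x An `insertion_simulation` (see [simulate_insertion()]) or a list
#'   with elements `steps`, `noise_pairs`, `fs_hz`, `prestim_ms` in the same
#'   shape.
#' @return An `insertion_trace` data frame (see [insertion_trace()]) with an
#'   attribute `noise_floor` (per-frequency floor mean/sd).
#' @export
build_insertion_trace <- function(x) {
  steps <- x$steps
  if (length(steps) < 1L) stop("no insertion steps", call. = FALSE)
  fs <- x$fs_hz
  prestim <- x$prestim_ms
  freqs <- names(steps[[1]])

  analyze_pair <- function(pair) {
    curve <- difference_curve(pair$cond, pair$rare)
    win <- ongoing_window(curve, pair$cond$stimulus, fs, prestim)
    spectral_amplitude(win, fs, pair$cond$stimulus$freq_hz)
  }

  floors <- lapply(freqs, function(f) {
    if (is.null(x$noise_pairs) || length(x$noise_pairs) < 5L) {
      return(list(mean_uv = 0, sd_uv = 0))
    }
    wins <- lapply(x$noise_pairs, function(np) {
      pair <- np[[f]]
      ongoing_window(difference_curve(pair$cond, pair$rare),
                     pair$cond$stimulus, fs, prestim)
    })
    estimate_noise_floor(wins, fs, as.numeric(f))
  })
  names(floors) <- freqs

  ok <- vapply(steps, function(st) {
    all(vapply(st, function(pair) {
      all(is.finite(pair$cond$samples)) && all(is.finite(pair$rare$samples))
    }, logical(1)))
  }, logical(1))
  if (any(!ok)) {
    warning(sprintf("excluding %d step(s) with non-finite samples: %s",
                    sum(!ok), paste(which(!ok), collapse = ", ")),
            call. = FALSE)
  }
  kept <- which(ok)

  amps <- lapply(freqs, function(f) {
    vapply(steps[kept], function(st) analyze_pair(st[[f]]), numeric(1))
  })
  names(amps) <- freqs
  sig <- lapply(freqs, function(f) {
    is_significant(amps[[f]], floors[[f]])
  })
  names(sig) <- freqs

  out <- insertion_trace(amps, sig, step = kept)
  attr(out, "noise_floor") <- floors
  out
}

# Incremental running-maximum drop detector on a bare amplitude vector.
# An event opens when the amplitude falls to <= (1 - rel_threshold) of the
# running maximum, tracks its minimum, and closes when the amplitude
# recovers above that bound (or the trace ends).
detect_drops_vec <- function(a, rel_threshold = 0.30) {
  n <- length(a)
  empty <- data.frame(peak_step = integer(0), trough_step = integer(0),
                      peak_uv = numeric(0), trough_uv = numeric(0),
                      relative_drop = numeric(0), drop_db = numeric(0))
  if (n < 2L) stop("need at least 2 steps to detect drops", call. = FALSE)
  if (all(a == 0)) {
    warning("all-zero trace: no drops detectable", call. = FALSE)
    return(empty)
  }
  events <- list()
  runmax <- a[1]
  runmax_step <- 1L
  in_event <- FALSE
  peak_val <- peak_step <- trough_val <- trough_step <- NULL
  close_event <- function() {
    events[[length(events) + 1L]] <<- data.frame(
      peak_step = peak_step, trough_step = trough_step,
      peak_uv = peak_val, trough_uv = trough_val,
      relative_drop = 1 - trough_val / peak_val,
      drop_db = 20 * log10(peak_val / max(trough_val, .Machine$double.xmin)))
  }
  for (i in 2:n) {
    if (!in_event) {
      if (runmax > 0 && a[i] <= (1 - rel_threshold) * runmax) {
        in_event <- TRUE
        peak_val <- runmax; peak_step <- runmax_step
        trough_val <- a[i]; trough_step <- i
      } else if (a[i] > runmax) {
        runmax <- a[i]; runmax_step <- i
      }
    } else {
      if (a[i] > (1 - rel_threshold) * peak_val) {
        close_event()
        in_event <- FALSE
        if (a[i] >= runmax) {
          runmax <- a[i]; runmax_step <- i
        }
      } else if (a[i] < trough_val) {
        trough_val <- a[i]; trough_step <- i
      }
    }
  }
  if (in_event) close_event()
  if (length(events) == 0L) return(empty)
  do.call(rbind, events)
}

#' Detect CM amplitude drops along an insertion trace
#'
#' A drop is significant when the amplitude falls by at least
#' `rel_threshold` (default 30%) of a prior maximum. The detector keeps a
#' running maximum; an event opens when the amplitude falls to or below
#' `(1 - rel_threshold)` times that maximum, closes at the local minimum
#' once the amplitude recovers above the bound (recovery re-arms the
#' detector, so repeated drop/recovery cycles yield separate events), and
#' events are disjoint in step ranges.
#'
#' @param trace An [insertion_trace()].
#' @param freq Stimulus frequency whose trace to scan (250 or 500).
#' @param rel_threshold Relative drop criterion (default 0.30).
#' @return Data frame of drop events: `freq_hz`, `peak_step`, `trough_step`
#'   (trace step indices), `peak_uv`, `trough_uv`, `relative_drop`
#'   (`1 - trough/peak`, >= `rel_threshold`), `drop_db`
#'   (`20*log10(peak/trough)`).
#' @export
detect_drops <- function(trace, freq, rel_threshold = 0.30) {
  a <- trace_col(trace, freq)
  ev <- detect_drops_vec(a, rel_threshold)
  # map row positions back to recorded step indices
  if (nrow(ev) > 0) {
    ev$peak_step <- trace$step[ev$peak_step]
    ev$trough_step <- trace$step[ev$trough_step]
  }
  cbind(freq_hz = rep(as.numeric(freq), nrow(ev)), ev)
}

# Largest peak-to-post-peak drop (dB) on a bare amplitude vector.
largest_drop_db_vec <- function(a) {
  imax <- which.max(a)  # earliest maximum on ties
  n <- length(a)
  if (imax == n) return(0)
  trough <- min(a[(imax + 1L):n])
  if (trough <= 0) {
    warning("post-peak amplitude reaches 0; drop magnitude unbounded",
            call. = FALSE)
    return(Inf)
  }
  20 * log10(a[imax] / trough)
}

#' Largest CM drop from the insertion peak, in dB
#'
#' The change in amplitude from the global maximum of the trace to the
#' minimum over all later steps, `20*log10(max / post-max min)`; 0 when the
#' maximum sits at the final step. Ties for the maximum resolve to the
#' earliest step.
#'
#' @inheritParams detect_drops
#' @return Drop magnitude in dB re the peak (>= 0).
#' @export
largest_drop_db <- function(trace, freq) {
  a <- trace_col(trace, freq)
  if (length(a) < 2L) stop("need at least 2 steps", call. = FALSE)
  largest_drop_db_vec(a)
}

#' Count CM drops exceeding an absolute decrement
#'
#' Counts detected drop events whose absolute peak-to-trough decrement
#' strictly exceeds `min_abs_uv` (default 2 uV).
#'
#' @inheritParams detect_drops
#' @param min_abs_uv Absolute decrement threshold in microvolts (strict
#'   inequality).
#' @return Integer count.
#' @export
count_drops <- function(trace, freq, min_abs_uv = 2.0, rel_threshold = 0.30) {
  ev <- detect_drops(trace, freq, rel_threshold)
  sum(ev$peak_uv - ev$trough_uv > min_abs_uv)
}

#' Classify the insertion pattern (Type A/B/C)
#'
#' Quantifies the classic qualitative insertion-trajectory types:
#' * **A** -- overall increase from start to completion: final >=
#'   `(1+tol)` x start, with the global maximum in the final 20% of steps or
#'   the final amplitude within `tol` of the maximum.
#' * **B** -- maximum at the start with subsequent decrease: global maximum
#'   within the first 10% of steps and final <= `(1-tol)` x start.
#' * **C** -- similar start and end with an interior maximum exceeding both
#'   ends by more than `tol`.
#'
#' Rules are tested in the order C, B, A; a trace satisfying none is
#' assigned the nearest rule (smallest total relative violation) with a
#' warning.
#'
#' @inheritParams detect_drops
#' @param tol Relative tolerance quantifying "overall increase" / "similar
#'   amplitude" (default 0.20).
#' @return Character label, one of `"A"`, `"B"`, `"C"`.
#' @export
classify_pattern <- function(trace, freq, tol = 0.20) {
  a <- trace_col(trace, freq)
  n <- length(a)
  if (n < 3L) stop("need at least 3 steps to classify a pattern",
                   call. = FALSE)
  start <- a[1]; final <- a[n]
  mx <- max(a); imx <- which.max(a)
  eps <- .Machine$double.eps
  denom <- max(start, eps)

  is_c <- abs(final - start) <= tol * start &&
    imx > 1L && imx < n &&
    mx > (1 + tol) * start && mx > (1 + tol) * final
  if (is_c) return("C")
  is_b <- imx <= max(1L, ceiling(0.1 * n)) && final <= start * (1 - tol)
  if (is_b) return("B")
  is_a <- final >= start * (1 + tol) &&
    (imx >= ceiling(0.8 * n) || final >= (1 - tol) * mx)
  if (is_a) return("A")

  # nearest rule: total relative violation of each rule's conditions
  viol_c <- max(0, (abs(final - start) - tol * start) / denom) +
    (if (imx > 1L && imx < n) 0 else 1) +
    max(0, ((1 + tol) * start - mx) / max(mx, eps)) +
    max(0, ((1 + tol) * final - mx) / max(mx, eps))
  viol_b <- (if (imx <= max(1L, ceiling(0.1 * n))) 0 else 1) +
    max(0, (final - start * (1 - tol)) / denom)
  viol_a <- max(0, (start * (1 + tol) - final) / denom) +
    min((if (imx >= ceiling(0.8 * n)) 0 else 1),
        max(0, ((1 - tol) * mx - final) / max(mx, eps)))
  scores <- c(C = viol_c, B = viol_b, A = viol_a)
  label <- names(scores)[which.min(scores)]
  warning(sprintf("trace fits no pattern rule exactly; nearest is Type %s",
                  label), call. = FALSE)
  label
}

#' Final amplitude as a percentage of the insertion maximum
#'
#' @inheritParams detect_drops
#' @return `100 * final / max` (percent); `NA` with a warning if the
#'   maximum is 0.
#' @export
final_over_max <- function(trace, freq) {
  a <- trace_col(trace, freq)
  if (length(a) < 1L) stop("empty trace", call. = FALSE)
  mx <- max(a)
  if (mx == 0) {
    warning("maximum amplitude is 0; final/max undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * a[length(a)] / mx
}

#' Classify 500-Hz drop events as trauma vs CF crossing
#'
#' Uses the two-frequency paradigm: a 500-Hz drop that is synchronous with a
#' 250-Hz drop (event step ranges overlapping within `sync_window_steps`)
#' indicates basilar-membrane trauma, since trauma attenuates both
#' frequencies together; a 500-Hz drop over which the 250-Hz amplitude keeps
#' rising (non-negative least-squares slope across the event span) indicates
#' the apical electrode passing the 500-Hz CF place; anything else is
#' indeterminate.
#'
#' @param trace An [insertion_trace()] containing both `amp_250` and
#'   `amp_500` columns.
#' @param sync_window_steps Step tolerance for calling two events
#'   synchronous (default 2).
#' @param rel_threshold Drop criterion passed to [detect_drops()].
#' @return The 500-Hz drop-event data frame with an added `label` column
#'   (`"trauma"`, `"cf_crossing"`, or `"indeterminate"`).
#' @export
classify_drop_cause <- function(trace, sync_window_steps = 2,
                                rel_threshold = 0.30) {
  if (!"amp_500" %in% names(trace)) {
    stop("trace has no 500-Hz amplitudes", call. = FALSE)
  }
  ev500 <- detect_drops(trace, 500, rel_threshold)
  if (!"amp_250" %in% names(trace)) {
    warning("single-frequency trace: drop causes indeterminate",
            call. = FALSE)
    ev500$label <- rep("indeterminate", nrow(ev500))
    return(ev500)
  }
  ev250 <- detect_drops(trace, 250, rel_threshold)
  a250 <- trace_col(trace, 250)

  label_one <- function(ps, ts) {
    if (nrow(ev250) > 0) {
      sync <- any(ev250$peak_step <= ts + sync_window_steps &
                    ev250$trough_step >= ps - sync_window_steps)
      if (sync) return("trauma")
    }
    span <- which(trace$step >= ps & trace$step <= ts)
    slope <- stats::coef(stats::lm(a250[span] ~ span))[2]
    if (is.finite(slope) && slope >= 0) "cf_crossing" else "indeterminate"
  }
  ev500$label <- if (nrow(ev500) > 0) {
    mapply(label_one, ev500$peak_step, ev500$trough_step)
  } else {
    character(0)
  }
  ev500
}

#' Per-frequency insertion-trajectory metrics
#'
#' Summarises an insertion trace into the standard trajectory feature set:
#' drop count (> `min_abs_uv` decrement), largest drop (dB), starting CM
#' amplitude, final/max percentage, and pattern type, per stimulus
#' frequency.
#'
#' @inheritParams detect_drops
#' @param min_abs_uv Absolute decrement threshold for the drop count.
#' @return Data frame with one row per frequency: `freq_hz`, `n_drops`,
#'   `largest_drop_db`, `start_amp_uv`, `final_over_max_pct`, `pattern`.
#' @export
insertion_metrics <- function(trace, rel_threshold = 0.30, min_abs_uv = 2.0) {
  freqs <- sub("^amp_", "", grep("^amp_", names(trace), value = TRUE))
  rows <- lapply(freqs, function(f) {
    fn <- as.numeric(f)
    a <- trace_col(trace, f)
    data.frame(
      freq_hz = fn,
      n_drops = count_drops(trace, f, min_abs_uv, rel_threshold),
      largest_drop_db = largest_drop_db(trace, f),
      start_amp_uv = a[1],
      final_over_max_pct = final_over_max(trace, f),
      pattern = classify_pattern(trace, f)
    )
  })
  do.call(rbind, rows)
}
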