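#' Multichannel electrogram recording
#'
#' Container for a channels x samples voltage matrix with sampling metadata.
#'
#' @param samples Numeric matrix, channels in rows, mV.
#' @param fs Sampling rate (Hz).
#' @param channel_ids Character vector aligned with rows.
#' @param filter_band Optional `(lo, hi)` Hz already applied.
#' @param t0_ms Time of the first sample (ms).
#' @return Object of class `egm_recording`.
#' @export
egm_recording <- function(samples, fs, channel_ids = NULL, filter_band = NULL,
                          t0_ms = 0) {
  samples <- as.matrix(samples)
  if (!is_scalar_number(fs) || fs <= 0) {
    stop_fibmap("`fs` must be a positive number.", "fibmap_invalid_argument")
  }
  if (any(!is.finite(samples))) {
    stop_fibmap("Recording contains non-finite samples.", "fibmap_invalid_argument")
  }
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(nrow(samples)))
  if (anyDuplicated(channel_ids) || length(channel_ids) != nrow(samples)) {
    stop_fibmap("`channel_ids` must be unique, one per row.", "fibmap_invalid_argument")
  }
  structure(list(samples = samples, fs = fs, channel_ids = as.character(channel_ids),
                 filter_band = filter_band, t0_ms = t0_ms),
            class = "egm_recording")
}

#' @export
print.egm_recording <- function(x, ...) {
  cat(sprintf("<egm_recording> %d channels x %d samples @ %g Hz (%.0f ms)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs * 1000))
  invisible(x)
}

# Sample times in ms.
rec_times <- function(rec) rec$t0_ms + (seq_len(ncol(rec$samples)) - 1L) / rec$fs * 1000

#' @export
as_tibble.egm_recording <- function(x, ...) {
  t_ms <- rec_times(x)
  tibble::tibble(
    channel_id = rep(x$channel_ids, each = length(t_ms)),
    t_ms = rep(t_ms, times = length(x$channel_ids)),
    v_mv = as.vector(t(x$samples))
  )
}

#' @export
tidy.egm_recording <- function(x, ...) as_tibble.egm_recording(x, ...)

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering so activation timing is
#' not skewed by group delay. The channel mean is removed first, which makes
#' DC rejection exact even on short windows. When `hi` equals the Nyquist
#' frequency only the high-pass stage runs (the clinical 0.05-500 Hz band at a
#' 1 kHz sampling rate is exactly this case).
#'
#' @param rec An `egm_recording`.
#' @param lo,hi Band edges in Hz; `0 <= lo < hi <= fs/2`.
#' @param order_hp,order_lp Butterworth orders of the two stages.
#' @return A filtered `egm_recording` with `filter_band` updated.
#' @export
bandpass <- function(rec, lo = 0.05, hi = 500, order_hp = 2L, order_lp = 8L) {
  nyq <- rec$fs / 2
  if (!is_scalar_number(lo) || !is_scalar_number(hi) || lo < 0 || lo >= hi || hi > nyq) {
    stop_fibmap(sprintf("Band edges must satisfy 0 <= lo < hi <= fs/2 = %g Hz.", nyq),
                "fibmap_invalid_argument")
  }
  x <- rec$samples - rowMeans(rec$samples)
  if (lo > 0) {
    flt <- signal::butter(order_hp, lo / nyq, type = "high")
    x <- t(apply(x, 1, function(s) signal::filtfilt(flt, s)))
  }
  if (hi < nyq) {
    flt <- signal::butter(order_lp, hi / nyq, type = "low")
    x <- t(apply(x, 1, function(s) signal::filtfilt(flt, s)))
  }
  egm_recording(x, rec$fs, rec$channel_ids, filter_band = c(lo, hi),
                t0_ms = rec$t0_ms)
}

#' Detect activation times from unipolar electrograms
#'
#' Local activation is marked where the detection signal has a local maximum
#' exceeding a threshold, with a refractory lockout enforced by forward scan
#' (an accepted event suppresses later candidates within `lockout_ms`). Two
#' detection operators are offered: `"deflection"` (default) marks the sharp
#' negative deflection of the electrogram (peaks of `-V`), which is the
#' intrinsic-deflection criterion for unipolar signals; `"slope"` marks peaks
#' of `-dV/dt`. Either signal is first detrended with a short moving mean
#' (`detrend_ms`) so slow repolarization far-field does not trigger.
#'
#' The default threshold adapts per channel to continuously active
#' fibrillatory signals: the larger of `threshold_k` times the quiet-window
#' noise level (10th percentile of the rolling RMS) and `peak_frac` times the
#' robust peak height (98th percentile of the positive detection signal); the
#' second term keeps smaller secondary (repolarization far-field) lobes of a
#' continuously active signal below threshold.
#'
#' @param rec An `egm_recording`.
#' @param slope_threshold_mv_ms Fixed threshold (units of the detection
#'   signal), or `NULL` for the adaptive per-channel default.
#' @param lockout_ms Minimum spacing between detected events (ms).
#' @param operator `"deflection"` or `"slope"`.
#' @param threshold_k Multiplier on the quiet-window noise sd.
#' @param peak_frac Fraction of the robust peak height.
#' @param detrend_ms Moving-mean detrend window (ms); 0 disables.
#' @return An activation series: tibble `channel_id`, `time_ms`, sorted within
#'   channel, with class `activation_series`. Flat channels yield no rows.
#' @export
detect_activations <- function(rec, slope_threshold_mv_ms = NULL,
                               lockout_ms = 50,
                               operator = c("deflection", "slope"),
                               threshold_k = 3, peak_frac = 0.5,
                               detrend_ms = 40) {
  operator <- match.arg(operator)
  if (!is_scalar_number(lockout_ms) || lockout_ms <= 0) {
    stop_fibmap("`lockout_ms` must be positive.", "fibmap_invalid_argument")
  }
  t_ms <- rec_times(rec)
  dt_ms <- 1000 / rec$fs
  lockout_n <- max(1L, round(lockout_ms / dt_ms))
  rows <- lapply(seq_len(nrow(rec$samples)), function(ch) {
    v <- rec$samples[ch, ]
    if (operator == "deflection") {
      s <- -v
      offset <- 0
    } else {
      s <- -diff(v) / dt_ms
      offset <- dt_ms / 2
    }
    if (all(abs(s - mean(s)) < 1e-12)) return(NULL)
    if (detrend_ms > 0) s <- s - moving_mean(s, round(detrend_ms / dt_ms))
    thr <- slope_threshold_mv_ms %||% adaptive_threshold(s, threshold_k, peak_frac)
    if (thr <= 0) thr <- 1e-9
    n <- length(s)
    peak <- which(s > thr &
                    s >= c(-Inf, s[-n]) &
                    s > c(s[-1], -Inf))
    if (!length(peak)) return(NULL)
    kept <- integer()
    last <- -Inf
    for (p in peak) {
      if (p - last >= lockout_n) {
        kept <- c(kept, p)
        last <- p
      }
    }
    tibble::tibble(channel_id = rec$channel_ids[ch], time_ms = t_ms[kept] + offset)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) out <- tibble::tibble(channel_id = character(), time_ms = numeric())
  new_activation_series(out)
}

# Larger of k x quiet-window noise sd and peak_frac x robust peak height.
adaptive_threshold <- function(s, k = 3, peak_frac = 0.5, rms_win = 21L) {
  ms <- as.numeric(stats::filter(s^2, rep(1 / rms_win, rms_win), sides = 2))
  quiet_sd <- sqrt(quantile(ms, 0.1, na.rm = TRUE, names = FALSE))
  pos <- s[s > 0]
  pk <- if (length(pos)) quantile(pos, 0.98, names = FALSE) else 0
  max(k * quiet_sd, peak_frac * pk)
}

new_activation_series <- function(tb) {
  tb <- dplyr::arrange(tibble::as_tibble(tb), .data$channel_id, .data$time_ms)
  class(tb) <- c("activation_series", class(tb))
  tb
}

#' Restitution curve for physiologic interval filtering
#'
#' Recovery (action-potential duration) as a function of the preceding
#' diastolic interval, from MAP-style measurements. With no points the curve
#' is flat: recovery equals `min_apd_ms`, the minimum human atrial
#' repolarization time (100-110 ms).
#'
#' @param di_ms,apd_ms Optional paired vectors: strictly increasing diastolic
#'   intervals and non-decreasing APDs (ms).
#' @param min_apd_ms Floor on the recovery time (ms).
#' @return Object of class `restitution_curve`.
#' @export
restitution_curve <- function(di_ms = NULL, apd_ms = NULL, min_apd_ms = 100) {
  if (xor(is.null(di_ms), is.null(apd_ms))) {
    stop_fibmap("Provide both `di_ms` and `apd_ms`, or neither.", "fibmap_invalid_argument")
  }
  if (!is.null(di_ms)) {
    if (length(di_ms) != length(apd_ms) || !length(di_ms)) {
      stop_fibmap("`di_ms` and `apd_ms` must be non-empty and the same length.",
                  "fibmap_invalid_argument")
    }
    if (any(diff(di_ms) <= 0)) {
      stop_fibmap("`di_ms` must be strictly increasing.", "fibmap_invalid_argument")
    }
    if (any(diff(apd_ms) < 0)) {
      stop_fibmap("`apd_ms` must be non-decreasing in DI.", "fibmap_invalid_argument")
    }
  }
  structure(list(di_ms = di_ms, apd_ms = apd_ms, min_apd_ms = min_apd_ms),
            class = "restitution_curve")
}

#' Recovery time predicted at a diastolic interval
#'
#' Monotone linear interpolation of the restitution table (constant beyond its
#' range), floored at `min_apd_ms`; flat `min_apd_ms` when the curve has no
#' points.
#'
#' @param curve A [restitution_curve()].
#' @param di_ms Diastolic interval(s), ms.
#' @return Recovery time(s), ms.
#' @export
recovery_time <- function(curve, di_ms) {
  if (is.null(curve$di_ms)) return(rep(curve$min_apd_ms, length(di_ms)))
  pmax(curve$min_apd_ms,
       approx(curve$di_ms, curve$apd_ms, xout = di_ms, rule = 2)$y)
}

#' Discard physiologically impossible activation intervals
#'
#' Forward scan per channel: an event whose interval from the last accepted
#' event is shorter than the recovery time predicted by the restitution curve
#' is discarded (the earlier event of a too-close pair is kept, and subsequent
#' intervals are re-evaluated against the last accepted event). With the
#' default flat curve the rule is simply "no interval below `min_apd_ms`".
#' The operation is idempotent and its output is a subset of its input.
#'
#' @param series An activation series (tibble `channel_id`, `time_ms`).
#' @param curve A [restitution_curve()].
#' @return Filtered activation series.
#' @export
restitution_filter <- function(series, curve = restitution_curve()) {
  if (!inherits(curve, "restitution_curve")) {
    stop_fibmap("`curve` must be a restitution_curve.", "fibmap_invalid_argument")
  }
  filtered <- series |>
    dplyr::group_by(.data$channel_id) |>
    dplyr::group_modify(function(df, key) {
      keep <- restitution_scan(sort(df$time_ms), curve)
      tibble::tibble(time_ms = keep)
    }) |>
    dplyr::ungroup()
  new_activation_series(filtered[, c("channel_id", "time_ms")])
}

# Forward scan of one channel's sorted event times. State: the last accepted
# time and the APD attributed to the last accepted event (starts at the
# curve floor). DI feeding the curve = preceding accepted interval minus the
# APD of the event opening that interval.
restitution_scan <- function(times, curve) {
  if (length(times) <= 1L) return(times)
  kept <- times[1]
  apd_last <- curve$min_apd_ms
  for (t in times[-1]) {
    interval <- t - kept[length(kept)]
    di <- interval - apd_last
    if (interval >= recovery_time(curve, di)) {
      kept <- c(kept, t)
      apd_last <- recovery_time(curve, max(di, 0))
    }
  }
  kept
}

#' Cycle-length statistics and epoch comparison
#'
#' Pools successive activation intervals per channel; optionally compares two
#' epochs the way procedural AF slowing is reported: percent change
#' `100 * (CL_after - CL_before) / CL_before`.
#'
#' @param series An activation series.
#' @param channels Optional character vector restricting the channels used.
#' @param epochs Optional list `list(before = c(t0, t1), after = c(t0, t1))`
#'   in ms.
#' @return One-row tibble: `mean_cl_ms`, `median_cl_ms`, `n_intervals`, and
#'   (with epochs) `cl_before_ms`, `cl_after_ms`, `pct_change`. Channels with
#'   fewer than 2 events contribute nothing; if no channel has 2 events all
#'   values are `NA` and `undefined_cl` is `TRUE`.
#' @export
cycle_length_stats <- function(series, channels = NULL, epochs = NULL) {
  df <- series
  if (!is.null(channels)) df <- df[df$channel_id %in% channels, ]
  ivals <- function(d) {
    d |>
      dplyr::group_by(.data$channel_id) |>
      dplyr::filter(dplyr::n() >= 2) |>
      dplyr::summarise(iv = list(diff(sort(.data$time_ms))), .groups = "drop") |>
      dplyr::pull(.data$iv) |>
      unlist()
  }
  all_iv <- ivals(df)
  out <- tibble::tibble(
    mean_cl_ms = if (length(all_iv)) mean(all_iv) else NA_real_,
    median_cl_ms = if (length(all_iv)) median(all_iv) else NA_real_,
    n_intervals = length(all_iv),
    undefined_cl = !length(all_iv)
  )
  if (!is.null(epochs)) {
    bi <- ivals(df[df$time_ms >= epochs$before[1] & df$time_ms < epochs$before[2], ])
    ai <- ivals(df[df$time_ms >= epochs$after[1] & df$time_ms < epochs$after[2], ])
    out$cl_before_ms <- if (length(bi)) mean(bi) else NA_real_
    out$cl_after_ms <- if (length(ai)) mean(ai) else NA_real_
    out$pct_change <- 100 * (out$cl_after_ms - out$cl_before_ms) / out$cl_before_ms
  }
  out
}

#' Write / read an activation series CSV (`channel_id,time_ms`)
#'
#' @param series Activation series tibble.
#' @param path File path.
#' @return `read_activations()` returns an activation series.
#' @export
write_activations <- function(series, path) {
  utils::write.csv(as.data.frame(series[, c("channel_id", "time_ms")]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activations
#' @export
read_activations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("channel_id", "time_ms") %in% names(df))) {
    stop_fibmap("Activation CSV needs columns channel_id,time_ms.", "fibmap_invalid_argument")
  }
  new_activation_series(df)
}
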