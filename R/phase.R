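#' Instantaneous phase of each electrogram channel
#'
#' Phase is the angle of the analytic signal (FFT half-spectrum construction
#' of the Hilbert transform) of each channel. By default the channel is first
#' detrended by subtracting a moving mean over one dominant cycle length,
#' which stabilizes the analytic signal against the slow baseline wander that
#' survives a 0.05 Hz high-pass; set `detrend = "none"` to transform the raw
#' signal. Zero-variance channels get an undefined-phase flag (all-`NA` row).
#'
#' @param rec An `egm_recording`.
#' @param detrend `"moving_mean"` or `"none"`.
#' @return Object of class `phase_series`: list with `phase` (channels x
#'   samples matrix, values in `(-pi, pi]`), `fs`, `channel_ids`, `t_ms`,
#'   `undefined` (logical per channel).
#' @export
instantaneous_phase <- function(rec, detrend = c("moving_mean", "none")) {
  detrend <- match.arg(detrend)
  n <- ncol(rec$samples)
  phase <- matrix(NA_real_, nrow(rec$samples), n)
  undefined <- logical(nrow(rec$samples))
  for (ch in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ch, ]
    if (detrend == "moving_mean") {
      w <- dominant_period_samples(x, rec$fs)
      if (is.finite(w)) x <- x - moving_mean(x, w)
    }
    x <- x - mean(x)
    if (sd(x) < 1e-12) {
      undefined[ch] <- TRUE
      next
    }
    phase[ch, ] <- Arg(analytic_signal(x))
  }
  phase[phase <= -pi] <- pi
  structure(list(phase = phase, fs = rec$fs, channel_ids = rec$channel_ids,
                 t_ms = rec_times(rec), undefined = undefined),
            class = "phase_series")
}

# Analytic signal via the FFT half-spectrum method.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Centered moving mean with edge padding by reflection.
moving_mean <- function(x, w) {
  w <- max(3L, as.integer(w))
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) %/% 2L
  half <- min(half, length(x) - 1L)
  w <- 2L * half + 1L
  xp <- c(rev(x[seq_len(half)]), x, rev(x[length(x) - seq_len(half) + 1L]))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[half + seq_along(x)]
}

# Dominant cycle length of a channel in samples (spectral peak in 2.5-20 Hz).
dominant_period_samples <- function(x, fs, f_lo = 2.5, f_hi = 20) {
  n <- length(x)
  x <- x - mean(x)
  if (sd(x) < 1e-12) return(NA_real_)
  P <- Mod(fft(x))^2
  freq <- (seq_len(n) - 1L) * fs / n
  band <- which(freq >= f_lo & freq <= f_hi)
  if (!length(band)) return(NA_real_)
  fpk <- freq[band[which.max(P[band])]]
  fs / fpk
}

#' Dominant frequency / cycle length of a recording
#'
#' Spectral dominant frequency per channel (power-spectrum peak in the
#' fibrillatory band) and the implied cycle length.
#'
#' @param rec An `egm_recording`.
#' @param f_lo,f_hi Search band (Hz).
#' @return Tibble `channel_id`, `dominant_freq_hz`, `cycle_length_ms`.
#' @export
dominant_frequency <- function(rec, f_lo = 2.5, f_hi = 20) {
  per <- vapply(seq_len(nrow(rec$samples)), function(ch) {
    dominant_period_samples(rec$samples[ch, ], rec$fs, f_lo, f_hi)
  }, numeric(1))
  tibble::tibble(channel_id = rec$channel_ids,
                 dominant_freq_hz = rec$fs / per,
                 cycle_length_ms = per / rec$fs * 1000)
}

#' Phase field on the analysis grid
#'
#' Interpolates channel phases to the raster on the unit-circle embedding:
#' cos and sin are interpolated separately and recombined by `atan2`, so the
#' +/-pi wrap never corrupts the field. Never interpolate raw angles.
#'
#' @param phases A `phase_series` (or a numeric vector of per-channel phases
#'   for a single instant).
#' @param geom An `electrode_grid`.
#' @param grid An `analysis_grid`; default 1 mm over `geom`.
#' @param at_ms Times (ms) at which fields are built (nearest sample is used);
#'   ignored when `phases` is a plain vector.
#' @return A `phase_map`: list with `grid`, `phi` (`nu x nv x length(at_ms)`
#'   array, `(-pi, pi]` or `NA` outside the hull), `t_ms`, `interior` (logical
#'   matrix: nodes with a full plaquette neighbourhood inside the hull).
#' @export
phase_field <- function(phases, geom, grid = NULL, at_ms = NULL) {
  if (is.null(grid)) grid <- analysis_grid(geom)
  if (is.numeric(phases) && is.null(dim(phases))) {
    pm <- matrix(phases, nrow = nrow(geom), ncol = 1L)
    t_ms <- 0
  } else {
    stopifnot(inherits(phases, "phase_series"))
    if (is.null(at_ms)) at_ms <- phases$t_ms
    idx <- vapply(at_ms, function(tt) which.min(abs(phases$t_ms - tt)), integer(1))
    pm <- phases$phase[, idx, drop = FALSE]
    t_ms <- phases$t_ms[idx]
  }
  ok <- rowSums(!is.finite(pm)) == 0
  if (sum(ok) < 3) {
    stop_fibmap("Phase defined on fewer than 3 channels.", "fibmap_insufficient_data")
  }
  nu <- grid$nu; nv <- grid$nv
  phi <- array(NA_real_, dim = c(nu, nv, ncol(pm)))
  for (s in seq_len(ncol(pm))) {
    fc <- interpolate_to_grid(ifelse(ok, cos(pm[, s]), NA), geom, grid)$values
    fs_ <- interpolate_to_grid(ifelse(ok, sin(pm[, s]), NA), geom, grid)$values
    ph <- atan2(fs_, fc)
    ph[ph <= -pi] <- pi
    phi[, , s] <- ph
  }
  defined <- is.finite(phi[, , 1])
  structure(list(grid = grid, phi = phi, t_ms = t_ms, defined = defined),
            class = "phase_map")
}

#' Construct a phase map from raw phase values
#'
#' Low-level constructor for users who already hold a phase field (e.g. from
#' another mapping system or a synthetic screen); values are wrapped to
#' `(-pi, pi]`.
#'
#' @param grid An `analysis_grid`.
#' @param phi Numeric `nu x nv` matrix or `nu x nv x nt` array of phases.
#' @param t_ms Frame times (ms), one per slice of `phi`.
#' @return A `phase_map`.
#' @export
phase_map <- function(grid, phi, t_ms = NULL) {
  if (length(dim(phi)) == 2L) phi <- array(phi, dim = c(dim(phi), 1L))
  if (is.null(t_ms)) t_ms <- seq_len(dim(phi)[3]) - 1
  if (dim(phi)[1] != grid$nu || dim(phi)[2] != grid$nv ||
      dim(phi)[3] != length(t_ms)) {
    stop_fibmap("`phi` must be nu x nv x length(t_ms).", "fibmap_invalid_argument")
  }
  phi <- wrap_phase(phi)
  phi[phi <= -pi] <- pi
  structure(list(grid = grid, phi = phi, t_ms = t_ms,
                 defined = is.finite(phi[, , 1])),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d nodes, %d frames\n",
              x$grid$nu, x$grid$nv, length(x$t_ms)))
  invisible(x)
}

#' Detect phase singularities by plaquette topological charge
#'
#' For every elementary 2 x 2 plaquette of the phase field, the four wrapped
#' successive phase differences around the loop are summed; a sum of +/-2 pi
#' (in practice `|sum| > pi`) marks a phase singularity of charge
#' `round(sum / 2 pi)` at the plaquette centre. Plaquettes touching the edge
#' of the defined region are flagged `boundary = TRUE` (interpolation-edge
#' artifacts) and are excluded from tracking by default.
#'
#' @param pmap A `phase_map`.
#' @param t_ms Times at which to detect; default all frames in the map.
#' @return Tibble `t_ms`, `u_cm`, `v_cm`, `charge`, `boundary`.
#' @export
detect_phase_singularities <- function(pmap, t_ms = NULL) {
  if (is.null(t_ms)) t_ms <- pmap$t_ms
  g <- pmap$grid
  out <- lapply(t_ms, function(tt) {
    s <- which.min(abs(pmap$t_ms - tt))
    ph <- pmap$phi[, , s]
    ev <- plaquette_charges(ph)
    if (!nrow(ev)) return(NULL)
    tibble::tibble(t_ms = pmap$t_ms[s],
                   u_cm = g$u[ev$i] + g$du / 2,
                   v_cm = g$v[ev$j] + g$dv / 2,
                   charge = ev$charge,
                   boundary = ev$boundary)
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(t_ms = numeric(), u_cm = numeric(), v_cm = numeric(),
                          charge = integer(), boundary = logical())
  }
  res
}

# Plaquette loop sums on one phase frame. Returns i, j (lower-left node),
# charge, boundary flag.
plaquette_charges <- function(ph) {
  nu <- nrow(ph); nv <- ncol(ph)
  i <- seq_len(nu - 1L); j <- seq_len(nv - 1L)
  p00 <- ph[i, j, drop = FALSE]; p10 <- ph[i + 1L, j, drop = FALSE]
  p11 <- ph[i + 1L, j + 1L, drop = FALSE]; p01 <- ph[i, j + 1L, drop = FALSE]
  s <- phase_diff(p10, p00) + phase_diff(p11, p10) +
       phase_diff(p01, p11) + phase_diff(p00, p01)
  hit <- which(is.finite(s) & abs(s) > pi, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(data.frame(i = integer(), j = integer(), charge = integer(),
                      boundary = logical()))
  }
  def <- is.finite(ph)
  # a plaquette is interior if the 4x4 node neighbourhood around it is defined
  interior <- vapply(seq_len(nrow(hit)), function(r) {
    ii <- hit[r, 1]; jj <- hit[r, 2]
    ri <- max(1L, ii - 1L):min(nu, ii + 2L)
    rj <- max(1L, jj - 1L):min(nv, jj + 2L)
    all(def[ri, rj]) && ii > 1L && jj > 1L && ii + 2L <= nu && jj + 2L <= nv
  }, logical(1))
  data.frame(i = hit[, 1], j = hit[, 2],
             charge = as.integer(round(s[hit] / (2 * pi))),
             boundary = !interior)
}

#' Winding number of the phase along a closed node path
#'
#' Reference implementation of the loop integral of the phase gradient: the
#' sum of wrapped phase differences along the path, divided by 2 pi and
#' rounded. Used as the brute-force oracle against which plaquette detection
#' is checked.
#'
#' @param pmap A `phase_map` (or a bare phase matrix).
#' @param path Integer matrix with columns `i`, `j` of node indices; must be
#'   closed (first row equals last row) and on defined nodes.
#' @param t_ms Frame time when `pmap` is a `phase_map` (default first frame).
#' @return Integer winding number.
#' @export
winding_number_oracle <- function(pmap, path, t_ms = NULL) {
  ph <- if (inherits(pmap, "phase_map")) {
    s <- if (is.null(t_ms)) 1L else which.min(abs(pmap$t_ms - t_ms))
    pmap$phi[, , s]
  } else {
    pmap
  }
  path <- as.matrix(path)
  if (nrow(path) < 3 || any(path[1, ] != path[nrow(path), ])) {
    stop_fibmap("`path` must be a closed loop (first node repeated at the end).",
                "fibmap_invalid_argument")
  }
  vals <- ph[path]
  if (any(!is.finite(vals))) {
    stop_fibmap("Path crosses undefined nodes.", "fibmap_invalid_argument")
  }
  total <- sum(phase_diff(vals[-1], vals[-length(vals)]))
  as.integer(round(total / (2 * pi)))
}

#' Export phase-singularity events as CSV
#'
#' Columns `t_ms,u_cm,v_cm,charge,boundary`.
#'
#' @param events Event tibble from [detect_phase_singularities()].
#' @param path File path.
#' @export
write_singularities <- function(events, path) {
  utils::write.csv(as.data.frame(events[, c("t_ms", "u_cm", "v_cm", "charge", "boundary")]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
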