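#' Tissue model parameters for the excitable-medium simulator
#'
#' Parameters for a two-variable cubic excitation/recovery (Aliev-Panfilov
#' form) sheet used to generate ground-truth episodes. Defaults are tuned so a
#' sustained spiral has a period in the 150-250 ms range typical of human AF
#' cycle lengths, and so one spiral turn fits the default 4 x 4 cm sheet.
#'
#' @param domain_cm Side length of the square sheet (cm).
#' @param nodes Fine-grid nodes per side.
#' @param diffusion_cm2_ms Voltage diffusion coefficient (cm^2/ms).
#' @param k,a,eps0,mu1,mu2 Dimensionless local-kinetics constants.
#' @param tau_ms Milliseconds per dimensionless kinetics time unit.
#' @param dt_ms Euler time step (ms); must satisfy the diffusion stability
#'   bound `dt <= h^2 / (4 D)`. Default picks half the bound, capped at 0.1 ms.
#' @return Object of class `tissue_params`.
#' @export
tissue_params <- function(domain_cm = 4, nodes = 128L,
                          diffusion_cm2_ms = 3.5e-4,
                          k = 8, a = 0.1, eps0 = 0.05, mu1 = 0.2, mu2 = 0.3,
                          tau_ms = 7.1, dt_ms = NULL) {
  if (any(c(domain_cm, nodes, diffusion_cm2_ms, k, tau_ms) <= 0)) {
    stop_fibmap("Tissue parameters must be positive.", "fibmap_invalid_argument")
  }
  h <- domain_cm / nodes
  cfl <- h^2 / (4 * diffusion_cm2_ms)
  if (is.null(dt_ms)) dt_ms <- min(0.1, cfl / 2)
  if (dt_ms > cfl) {
    stop_fibmap(sprintf("dt = %.3g ms violates the stability bound h^2/(4D) = %.3g ms.",
                        dt_ms, cfl), "fibmap_invalid_argument")
  }
  structure(list(domain_cm = domain_cm, nodes = as.integer(nodes), h_cm = h,
                 diffusion_cm2_ms = diffusion_cm2_ms, k = k, a = a, eps0 = eps0,
                 mu1 = mu1, mu2 = mu2, tau_ms = tau_ms, dt_ms = dt_ms),
            class = "tissue_params")
}

new_state_movie <- function(res, params, stim_nodes = integer()) {
  nf <- res$n_frames
  V <- array(res$movie, dim = c(params$nodes, params$nodes, nf))
  structure(list(V = V, t_ms = res$frame_t, params = params,
                 h_cm = params$h_cm, domain_cm = params$domain_cm,
                 stim_nodes = as.integer(stim_nodes) + 1L),
            class = "state_movie")
}

#' @export
print.state_movie <- function(x, ...) {
  cat(sprintf("<state_movie> %d x %d nodes, %d frames, t = [%.0f, %.0f] ms\n",
              dim(x$V)[1], dim(x$V)[2], dim(x$V)[3], min(x$t_ms), max(x$t_ms)))
  invisible(x)
}

# Node-centre coordinate of fine-grid index i (1-based) in cm.
node_coord <- function(i, h) (i - 0.5) * h

ap_step <- function(params, V, r, duration_ms, record_every_ms = 1,
                    a_mod_amp = 0, a_mod_period = 0,
                    stim_nodes = integer(), stim_period = 0, stim_start = 0,
                    stim_dur = 0, stim_amp = 0, t0 = 0) {
  n_steps <- round(duration_ms / params$dt_ms)
  rec_every <- max(1L, round(record_every_ms / params$dt_ms))
  .ap_run(params$nodes, params$nodes, params$h_cm, params$diffusion_cm2_ms,
          params$dt_ms, as.integer(n_steps), as.integer(rec_every),
          params$k, params$a, params$eps0, params$mu1, params$mu2, params$tau_ms,
          as.numeric(V), as.numeric(r),
          a_mod_amp, a_mod_period,
          as.integer(stim_nodes), stim_period, stim_start, stim_dur, stim_amp, t0)
}

#' Simulate a spiral-wave (rotor) episode
#'
#' Initiates a spiral by the classic broken-wavefront (S1 with a cross-field
#' reset) protocol, then records the transmembrane field at 1 ms frames. The
#' true rotor tip path is recovered afterwards with [true_tip_trajectory()].
#' `meander_level` modulates tissue excitability periodically, making the tip
#' wander over a bounded migration locus.
#'
#' @param params A [tissue_params()] object.
#' @param duration_ms Recorded episode length (ms) after spiral initiation;
#'   must cover at least three rotations.
#' @param meander_level Amplitude of the periodic excitability modulation
#'   (0 = stable spiral; 0.1-0.5 = increasing meander).
#' @param seed Integer seed (the PDE is deterministic; the seed is carried to
#'   downstream stochastic stages such as electrogram noise).
#' @return List of class `sim_episode` with elements `movie` (class
#'   `state_movie`) and `truth` (class `ground_truth`).
#' @export
simulate_spiral <- function(params = tissue_params(), duration_ms = 2000,
                            meander_level = 0, seed = 1L) {
  n <- params$nodes
  V <- matrix(0, n, n); r <- matrix(0, n, n)
  # S1: plane wave from the left edge.
  stim_cols <- seq_len(3L)
  stim_nodes0 <- as.vector(outer(stim_cols - 1L, (seq_len(n) - 1L) * n, `+`))
  res <- ap_step(params, V, r, duration_ms = 5, record_every_ms = 5,
                 stim_nodes = stim_nodes0, stim_period = 1e9, stim_start = 0,
                 stim_dur = 5, stim_amp = 3)
  V <- res$V; r <- res$r; t_now <- 5
  # Advance until the front reaches ~60% of the domain width.
  probe_col <- round(0.6 * n)
  repeat {
    res <- ap_step(params, V, r, duration_ms = 5, record_every_ms = 5, t0 = t_now)
    V <- res$V; r <- res$r; t_now <- t_now + 5
    Vm <- matrix(V, n, n)
    if (max(Vm[probe_col, ]) > 0.5) break
    if (t_now > 2000) {
      stop_fibmap("S1 wavefront never crossed the sheet; parameters unexcitable.",
                  "fibmap_simulation_failure")
    }
  }
  # S2 cross-field reset: wipe the lower half so the broken end curls up.
  Vm <- matrix(V, n, n); rm_ <- matrix(r, n, n)
  half <- seq_len(floor(n / 2))
  Vm[, half] <- 0
  # Let the spiral establish itself before recording.
  res <- ap_step(params, Vm, rm_, duration_ms = 300, record_every_ms = 10,
                 t0 = t_now)
  V <- res$V; r <- res$r; t_now <- t_now + 300
  mod_period <- if (meander_level > 0) 450 else 0
  res <- ap_step(params, V, r, duration_ms = duration_ms, record_every_ms = 1,
                 a_mod_amp = meander_level, a_mod_period = mod_period, t0 = 0)
  movie <- new_state_movie(res, params, stim_nodes0)
  if (max(movie$V[, , dim(movie$V)[3]]) < 0.2) {
    stop_fibmap("Spiral died before the end of the episode.", "fibmap_simulation_failure")
  }
  tips <- true_tip_trajectory(movie)
  period <- movie_dominant_period(movie)
  truth <- structure(list(kind = "spiral", tip_path = tips, origin = NULL,
                          cycle_length_ms = NULL, period_ms = period,
                          meander_level = meander_level, seed = as.integer(seed)),
                     class = "ground_truth")
  structure(list(movie = movie, truth = truth), class = "sim_episode")
}

#' Simulate a repetitive focal-source episode
#'
#' Point pacing at `origin` emits concentric target waves at the requested
#' cycle length, emulating a repetitive focal beat.
#'
#' @inheritParams simulate_spiral
#' @param origin `(u, v)` stimulus site in cm; must lie inside the sheet.
#' @param cycle_length_ms Pacing interval (ms); values at or below tissue
#'   refractoriness produce 2:1 capture, which is recorded as a warning flag in
#'   the returned truth.
#' @return As [simulate_spiral()]; `truth$origin` is the stimulus site.
#' @export
simulate_focal <- function(params = tissue_params(), origin = NULL,
                           cycle_length_ms = 220, duration_ms = 2000, seed = 1L) {
  n <- params$nodes
  L <- params$domain_cm
  if (is.null(origin)) origin <- c(L / 2, L / 2)
  if (any(origin <= 0) || any(origin >= L)) {
    stop_fibmap("Focal origin must lie strictly inside the sheet.",
                "fibmap_invalid_argument")
  }
  ctr <- pmin(pmax(round(origin / params$h_cm + 0.5), 1L), n)
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  d <- sqrt((node_coord(ij$i, params$h_cm) - origin[1])^2 +
            (node_coord(ij$j, params$h_cm) - origin[2])^2)
  stim_nodes <- which(d <= max(2.5 * params$h_cm, 0.08)) - 1L
  V <- matrix(0, n, n); r <- matrix(0, n, n)
  res <- ap_step(params, V, r, duration_ms = duration_ms, record_every_ms = 1,
                 stim_nodes = stim_nodes, stim_period = cycle_length_ms,
                 stim_start = 10, stim_dur = 5, stim_amp = 3, t0 = 0)
  movie <- new_state_movie(res, params, stim_nodes)
  # Check capture at a probe two-fifths of the way to the boundary.
  probe <- pmin(pmax(ctr + round(0.15 * n), 2L), n - 1L)
  act <- upstroke_times(movie$V[probe[1], probe[2], ], movie$t_ms)
  capture_warning <- length(act) >= 2 && median(diff(act)) > 1.5 * cycle_length_ms
  period <- if (length(act) >= 2) median(diff(act)) else cycle_length_ms
  truth <- structure(list(kind = "focal", tip_path = NULL,
                          origin = origin, cycle_length_ms = cycle_length_ms,
                          period_ms = period, capture_warning = capture_warning,
                          seed = as.integer(seed)),
                     class = "ground_truth")
  structure(list(movie = movie, truth = truth), class = "sim_episode")
}

#' Simulate a plane-wave episode
#'
#' Periodic pacing of one sheet edge produces parallel wavefronts sweeping the
#' sheet; the ground truth records propagation direction and a conduction
#' velocity measured from the fine-grid activation times themselves. The
#' default pacing interval (450 ms) exceeds the sheet-crossing time so each
#' wavefront clears the sheet before the next is launched and per-cycle
#' isochronal windows are unaliased.
#'
#' @inheritParams simulate_focal
#' @return As [simulate_spiral()]; `truth$speed_cm_s` and `truth$direction`
#'   describe the wave.
#' @export
simulate_planewave <- function(params = tissue_params(), cycle_length_ms = 450,
                               duration_ms = 1500, seed = 1L) {
  n <- params$nodes
  stim_nodes <- as.vector(outer(seq_len(3L) - 1L, (seq_len(n) - 1L) * n, `+`))
  V <- matrix(0, n, n); r <- matrix(0, n, n)
  res <- ap_step(params, V, r, duration_ms = duration_ms, record_every_ms = 1,
                 stim_nodes = stim_nodes, stim_period = cycle_length_ms,
                 stim_start = 10, stim_dur = 5, stim_amp = 3, t0 = 0)
  movie <- new_state_movie(res, params, stim_nodes)
  # CV from first-activation times along the mid row.
  jmid <- round(n / 2)
  iseq <- seq(round(0.2 * n), round(0.8 * n))
  at <- vapply(iseq, function(i) {
    a <- upstroke_times(movie$V[i, jmid, ], movie$t_ms)
    if (length(a)) a[1] else NA_real_
  }, numeric(1))
  uu <- node_coord(iseq, params$h_cm)
  fit <- lm(at ~ uu)
  speed <- 1000 / abs(coef(fit)[2])  # ms/cm slope -> cm/s
  truth <- structure(list(kind = "planewave", tip_path = NULL, origin = NULL,
                          cycle_length_ms = cycle_length_ms,
                          period_ms = cycle_length_ms,
                          speed_cm_s = unname(speed), direction = c(1, 0),
                          seed = as.integer(seed)),
                     class = "ground_truth")
  structure(list(movie = movie, truth = truth), class = "sim_episode")
}

# Times of upward crossings of V = thr.
upstroke_times <- function(v, t, thr = 0.5) {
  idx <- which(v[-1] >= thr & v[-length(v)] < thr)
  t[idx + 1L]
}

# Dominant period (ms) of a movie from upstroke intervals at probe nodes.
movie_dominant_period <- function(movie, n_probes = 5) {
  n <- dim(movie$V)[1]
  pos <- round(seq(0.2, 0.8, length.out = n_probes) * n)
  per <- unlist(lapply(pos, function(p) {
    a <- upstroke_times(movie$V[p, p, ], movie$t_ms)
    if (length(a) >= 3) diff(a) else numeric()
  }))
  if (!length(per)) return(NA_real_)
  median(per)
}

#' True spiral-tip trajectory from a state movie
#'
#' Standard isoline-intersection tip definition: per frame pair, the tip is
#' where the `V = v_iso` contour at frame t intersects the same contour at
#' frame t+dt. Serves as the independent ground-truth oracle against which
#' phase-singularity tracking is validated.
#'
#' @param movie A `state_movie`.
#' @param v_iso Iso-potential level defining the wavefront.
#' @param frame_stride Analyze every `frame_stride`-th frame pair.
#' @return Tibble `t_ms`, `u_cm`, `v_cm` (possibly zero rows).
#' @export
true_tip_trajectory <- function(movie, v_iso = 0.5, frame_stride = 5L) {
  dims <- dim(movie$V)
  if (dims[3] < 2) stop_fibmap("Movie needs at least 2 frames.", "fibmap_invalid_argument")
  h <- movie$h_cm
  out <- vector("list", 0L)
  frames <- seq(1L, dims[3] - 1L, by = frame_stride)
  for (f in frames) {
    tips <- frame_tips(movie$V[, , f], movie$V[, , f + 1L], v_iso, h)
    if (nrow(tips)) {
      tips$t_ms <- movie$t_ms[f]
      out[[length(out) + 1L]] <- tips
    }
  }
  if (!length(out)) {
    return(tibble::tibble(t_ms = numeric(), u_cm = numeric(), v_cm = numeric()))
  }
  res <- dplyr::bind_rows(out)
  tibble::as_tibble(res[, c("t_ms", "u_cm", "v_cm")])
}

# Intersections of the f = 0 and g = 0 isolines within grid cells, where
# f = V1 - iso, g = V2 - iso. Local planar approximation per mixed-sign cell.
frame_tips <- function(V1, V2, v_iso, h) {
  f <- V1 - v_iso; g <- V2 - v_iso
  nx <- nrow(f); ny <- ncol(f)
  i <- seq_len(nx - 1L); j <- seq_len(ny - 1L)
  f00 <- f[i, j]; f10 <- f[i + 1L, j]; f01 <- f[i, j + 1L]; f11 <- f[i + 1L, j + 1L]
  g00 <- g[i, j]; g10 <- g[i + 1L, j]; g01 <- g[i, j + 1L]; g11 <- g[i + 1L, j + 1L]
  mixed <- function(a, b, c, d) {
    mx <- pmax(a, b, c, d); mn <- pmin(a, b, c, d)
    mx > 0 & mn < 0
  }
  cand <- which(mixed(f00, f10, f01, f11) & mixed(g00, g10, g01, g11), arr.ind = TRUE)
  if (!nrow(cand)) {
    return(data.frame(u_cm = numeric(), v_cm = numeric()))
  }
  ii <- cand[, 1]; jj <- cand[, 2]
  lin <- cbind(ii, jj)
  # planar least-squares through the 4 corners: z ~ z0 + zu*x + zv*y
  pf0 <- (f00[lin] + f10[lin] + f01[lin] + f11[lin]) / 4
  pfu <- (f10[lin] + f11[lin] - f00[lin] - f01[lin]) / 2
  pfv <- (f01[lin] + f11[lin] - f00[lin] - f10[lin]) / 2
  pg0 <- (g00[lin] + g10[lin] + g01[lin] + g11[lin]) / 4
  pgu <- (g10[lin] + g11[lin] - g00[lin] - g01[lin]) / 2
  pgv <- (g01[lin] + g11[lin] - g00[lin] - g10[lin]) / 2
  det <- pfu * pgv - pfv * pgu
  ok <- abs(det) > 1e-12
  # solve for offsets from cell centre (x, y in [-0.5, 0.5])
  x <- (-pf0 * pgv + pfv * pg0) / det
  y <- (-pfu * pg0 + pf0 * pgu) / det
  keep <- ok & abs(x) <= 0.75 & abs(y) <= 0.75
  if (!any(keep)) {
    return(data.frame(u_cm = numeric(), v_cm = numeric()))
  }
  data.frame(u_cm = (ii[keep] + x[keep]) * h,
             v_cm = (jj[keep] + y[keep]) * h)
}

#' Sample pseudo-unipolar electrograms at basket electrodes
#'
#' Each channel is a distance-weighted (1/r, r floored at one node spacing)
#' sum of -dV/dt over tissue nodes, tapered by a Gaussian sensing volume of
#' scale `sensing_radius_cm` (about one electrode pitch) so that, as for a
#' physical unipolar contact electrode, local tissue dominates while nearby
#' activity still contributes the characteristic biphasic far field. The
#' result is resampled to 1 kHz, with optional additive white noise.
#'
#' @param movie A `state_movie`.
#' @param geom An `electrode_grid`; all electrodes must lie inside the sheet.
#' @param noise_sd_mv White-noise standard deviation (mV).
#' @param farfield_gain Overall gain applied to the far-field sum.
#' @param sensing_radius_cm Gaussian taper scale of the sensing volume (cm).
#' @param seed Seed for the noise realization.
#' @return An `egm_recording` (see [egm_recording()]) at 1 kHz.
#' @export
sample_electrograms <- function(movie, geom, noise_sd_mv = 0, farfield_gain = 1,
                                sensing_radius_cm = 0.5, seed = 1L) {
  L <- movie$domain_cm
  if (any(geom$u_cm < 0 | geom$u_cm > L | geom$v_cm < 0 | geom$v_cm > L)) {
    stop_fibmap("All electrodes must lie inside the simulated sheet.",
                "fibmap_invalid_geometry")
  }
  n <- dim(movie$V)[1]
  h <- movie$h_cm
  nf <- dim(movie$V)[3]
  node_u <- node_coord(seq_len(n), h)
  # weight matrix: channels x nodes (column-major over the fine grid)
  gu <- rep(node_u, times = n)
  gv <- rep(node_u, each = n)
  W <- matrix(0, nrow(geom), n * n)
  for (c in seq_len(nrow(geom))) {
    r <- sqrt((gu - geom$u_cm[c])^2 + (gv - geom$v_cm[c])^2)
    W[c, ] <- exp(-r^2 / (2 * sensing_radius_cm^2)) / pmax(r, h)
  }
  W <- W * (h^2) * farfield_gain * 50  # node-area weight; gain for ~mV scale
  # pacing-artifact blanking: stimulated nodes carry the injected current, not
  # propagated membrane activity, and are excluded (as clinical systems blank
  # the pacing site)
  if (length(movie$stim_nodes)) W[, movie$stim_nodes] <- 0
  dt <- diff(movie$t_ms[1:2])
  Vm <- matrix(movie$V, n * n, nf)
  dVdt <- (Vm[, -1, drop = FALSE] - Vm[, -nf, drop = FALSE]) / dt
  sig <- -(W %*% dVdt)
  t_mid <- (movie$t_ms[-1] + movie$t_ms[-nf]) / 2
  # resample to a regular 1 kHz clock
  t_out <- seq(ceiling(min(t_mid)), floor(max(t_mid)), by = 1)
  samples <- t(apply(sig, 1, function(s) approx(t_mid, s, xout = t_out)$y))
  if (noise_sd_mv > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(length(samples), 0, noise_sd_mv),
                                    nrow = nrow(samples)))
    samples <- samples + noise
  }
  egm_recording(samples, fs = 1000, channel_ids = geom$channel_id,
                t0_ms = t_out[1])
}

#' Assemble a complete simulated episode
#'
#' Convenience wrapper: runs the requested episode kind, samples electrograms
#' on a basket geometry, and bundles recording, geometry and ground truth.
#'
#' @param kind `"spiral"`, `"focal"` or `"planewave"`.
#' @param params A [tissue_params()].
#' @param geom Electrode grid; default [basket_geometry()] seeded from `seed`.
#' @param duration_ms Episode length in ms.
#' @param noise_sd_mv Electrogram noise (mV).
#' @param seed Master seed for the episode.
#' @param ... Passed to the episode simulator (`meander_level`, `origin`,
#'   `cycle_length_ms`, ...).
#' @return List of class `simulated_episode`: `recording`, `geom`, `truth`,
#'   `movie`, `seed`.
#' @export
simulate_episode <- function(kind = c("spiral", "focal", "planewave"),
                             params = tissue_params(), geom = NULL,
                             duration_ms = 2000, noise_sd_mv = 0, seed = 1L, ...) {
  kind <- match.arg(kind)
  if (is.null(geom)) geom <- basket_geometry(jitter_seed = derive_seed(seed, "geometry"))
  ep <- switch(kind,
    spiral = simulate_spiral(params, duration_ms = duration_ms, seed = seed, ...),
    focal = simulate_focal(params, duration_ms = duration_ms, seed = seed, ...),
    planewave = simulate_planewave(params, duration_ms = duration_ms, seed = seed, ...))
  rec <- sample_electrograms(ep$movie, geom, noise_sd_mv = noise_sd_mv,
                             seed = derive_seed(seed, "egm_noise"))
  structure(list(recording = rec, geom = geom, truth = ep$truth,
                 movie = ep$movie, seed = as.integer(seed)),
            class = "simulated_episode")
}
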