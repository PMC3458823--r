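test_that("tissue parameters enforce the diffusion stability bound", {
  p <- tissue_params()
  expect_lte(p$dt_ms, p$h_cm^2 / (4 * p$diffusion_cm2_ms))
  expect_error(tissue_params(dt_ms = 10), class = "fibmap_invalid_argument")
  expect_error(tissue_params(diffusion_cm2_ms = -1), class = "fibmap_invalid_argument")
})

test_that("stable spiral stays confined and keeps a fibrillatory period", {
  ep <- fx_spiral()
  tp <- ep$truth$tip_path
  expect_gt(nrow(tp), 100)
  # final-half tip point set confined to a small disc
  late <- tp[tp$t_ms > max(tp$t_ms) / 2, ]
  expect_lt(max(stats::dist(cbind(late$u_cm, late$v_cm))), 0.5)
  # period in the human AF cycle-length range
  expect_gt(ep$truth$period_ms, 150)
  expect_lt(ep$truth$period_ms, 250)
  # state stays in physiologic bounds
  expect_gt(min(ep$movie$V), -0.2)
  expect_lt(max(ep$movie$V), 1.1)
})

test_that("simulation is deterministic for a fixed seed", {
  p <- tissue_params()
  a <- simulate_planewave(p, duration_ms = 500, seed = 5)
  b <- simulate_planewave(p, duration_ms = 500, seed = 5)
  expect_identical(a$movie$V, b$movie$V)
})

test_that("plane-wave movie has no persistent spiral tips", {
  ep <- fx_plane()
  tips <- true_tip_trajectory(ep$movie)
  frames <- length(unique(ep$movie$t_ms))
  # at most transient boundary artifacts: tips in under 2% of frames
  expect_lt(length(unique(tips$t_ms)) / frames, 0.02)
})

test_that("tip oracle recovers the centre of an analytic rotating vortex", {
  # phase-rotation movie: V = cos(theta - omega t + r / pitch)
  n <- 101; h <- 0.04
  x <- ((seq_len(n)) - 0.5) * h
  ctr <- c(2.02, 1.98)
  U <- matrix(x, n, n); Vv <- matrix(x, n, n, byrow = TRUE)
  th <- atan2(Vv - ctr[2], U - ctr[1])
  r <- sqrt((U - ctr[1])^2 + (Vv - ctr[2])^2)
  frames <- lapply(seq(0, 0.9, by = 0.1), function(ft) {
    cos(th - 2 * pi * ft + r / 0.3)
  })
  movie <- structure(list(V = array(unlist(frames), dim = c(n, n, length(frames))),
                          t_ms = seq_along(frames) * 10, h_cm = h, domain_cm = n * h,
                          params = NULL),
                     class = "state_movie")
  tips <- true_tip_trajectory(movie, v_iso = 0, frame_stride = 1L)
  expect_gt(nrow(tips), 0)
  d <- sqrt((tips$u_cm - ctr[1])^2 + (tips$v_cm - ctr[2])^2)
  # at least one tip per frame within one fine-grid node of the true centre
  per_frame <- tapply(d, tips$t_ms, min)
  expect_true(all(per_frame <= sqrt(2) * h))
})

test_that("tip oracle returns nothing on a uniform field", {
  movie <- structure(list(V = array(0.3, dim = c(20, 20, 3)), t_ms = 1:3,
                          h_cm = 0.1, domain_cm = 2, params = NULL),
                     class = "state_movie")
  expect_equal(nrow(true_tip_trajectory(movie, frame_stride = 1L)), 0)
})

test_that("focal episode emits one wavefront per pacing cycle at plane-wave speed", {
  ep <- fx_focal()
  tr <- ep$truth
  expect_equal(tr$period_ms, tr$cycle_length_ms, tolerance = 0.05)
  expect_false(tr$capture_warning)

  # activation time ~ distance / CV, with CV from an independent 1-D cable run
  p <- ep$movie$params
  act_cable <- fibmap:::.ap_run_cable(400L, p$h_cm, p$diffusion_cm2_ms, p$dt_ms,
                                      as.integer(600 / p$dt_ms),
                                      p$k, p$a, p$eps0, p$mu1, p$mu2, p$tau_ms,
                                      5L, 3, 5)
  sel <- 100:300
  cv_cable <- 1 / (stats::coef(stats::lm(act_cable[sel] ~ sel))[[2]] / p$h_cm) # cm/ms
  mov <- ep$movie
  org <- tr$origin
  probe_r <- c(0.6, 0.9, 1.2)
  for (rr in probe_r) {
    i <- round((org[1] + rr) / mov$h_cm + 0.5)
    j <- round(org[2] / mov$h_cm + 0.5)
    at <- fibmap:::upstroke_times(mov$V[i, j, ], mov$t_ms)[1]
    i0 <- round(org[1] / mov$h_cm + 0.5)
    at0 <- fibmap:::upstroke_times(mov$V[i0, j, ], mov$t_ms)[1]
    expected <- rr / cv_cable
    expect_equal(at - at0, expected, tolerance = 0.35,
                 label = sprintf("radial delay at %.1f cm", rr))
  }
})

test_that("electrogram sampling is local, ordered, and noise-additive", {
  ep <- fx_plane()
  rec <- ep$recording
  expect_equal(rec$fs, 1000)
  expect_equal(nrow(rec$samples), 64L)

  # deflection times ordered along the propagation direction (+u)
  acts <- detect_activations(rec)
  first <- acts |>
    dplyr::group_by(channel_id) |>
    dplyr::summarise(t = min(time_ms), .groups = "drop")
  geom <- ep$geom
  first$u <- geom$u_cm[match(first$channel_id, geom$channel_id)]
  expect_gt(stats::cor(first$u, first$t, method = "spearman"), 0.95)

  # same seed: noisy - noiseless = pure stored noise realization
  clean <- sample_electrograms(ep$movie, geom, noise_sd_mv = 0, seed = 11)
  noisy <- sample_electrograms(ep$movie, geom, noise_sd_mv = 0.05, seed = 11)
  diffm <- noisy$samples - clean$samples
  expect_equal(sd(as.vector(diffm)), 0.05, tolerance = 0.02)
  noisy2 <- sample_electrograms(ep$movie, geom, noise_sd_mv = 0.05, seed = 11)
  expect_identical(noisy$samples, noisy2$samples)

  expect_error(
    sample_electrograms(ep$movie, basket_geometry(sheet_extent = c(9, 9))),
    class = "fibmap_invalid_geometry")
})

test_that("electrogram dominant frequency matches the simulated period", {
  for (ep in list(fx_spiral(), fx_focal())) {
    df <- dominant_frequency(ep$recording)
    med_cl <- stats::median(df$cycle_length_ms, na.rm = TRUE)
    expect_equal(med_cl, ep$truth$period_ms, tolerance = 0.05)
  }
})

test_that("time refinement leaves the solution essentially unchanged", {
  p1 <- tissue_params(dt_ms = 0.04)
  p2 <- tissue_params(dt_ms = 0.02)
  a <- simulate_planewave(p1, duration_ms = 300, seed = 1)
  b <- simulate_planewave(p2, duration_ms = 300, seed = 1)
  fa <- a$movie$V[, , dim(a$movie$V)[3]]
  fb <- b$movie$V[, , dim(b$movie$V)[3]]
  expect_lt(sqrt(mean((fa - fb)^2)), 0.01 * max(abs(fb)))
})

test_that("episode bundles round-trip through the plain-text format", {
  ep <- fx_plane()
  dir <- withr::local_tempdir()
  write_episode(ep, dir)
  back <- read_episode(dir)
  expect_equal(back$recording$samples, ep$recording$samples, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$geom$u_cm, ep$geom$u_cm, tolerance = 1e-12)
  expect_equal(back$truth$kind, "planewave")
  expect_equal(back$truth$speed_cm_s, ep$truth$speed_cm_s, tolerance = 1e-9)
})
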