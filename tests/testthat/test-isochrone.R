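# Synthetic activation series: channels activate at T(u, v) per cycle.
plane_series <- function(geom, cv_cm_s = 40, cycles = 1, cl = 250, angle = 0) {
  slo <- 1000 / cv_cm_s  # ms/cm
  d <- geom$u_cm * cos(angle) + geom$v_cm * sin(angle)
  dplyr::bind_rows(lapply(seq_len(cycles) - 1L, function(k) {
    tibble::tibble(channel_id = geom$channel_id, time_ms = k * cl + slo * (d - min(d)) + 5)
  }))
}

test_that("plane-wave isochrones are parallel straight lines", {
  geom <- basket_geometry(jitter_seed = 2)
  s <- plane_series(geom, cv_cm_s = 40, angle = 0.4)
  m <- build_isochrone_map(s, geom, window = c(0, 250))
  tb <- tidy(m)
  fit <- stats::lm(value ~ u_cm + v_cm, data = tb)
  expect_lt(sqrt(mean(fit$residuals^2)), 1)  # ms; well under one grid-step delay
})

test_that("sparse windows raise insufficient-data errors", {
  geom <- basket_geometry()
  s <- tibble::tibble(channel_id = geom$channel_id[1], time_ms = 10)
  expect_error(build_isochrone_map(s, geom, window = c(0, 250)),
               class = "fibmap_insufficient_data")
})

test_that("isochronal map on a focal episode matches fine-grid truth times", {
  ep <- fx_focal()
  acts <- restitution_filter(detect_activations(ep$recording))
  wins <- segment_cycles(acts)
  wi <- max(2L, nrow(wins) %/% 2)
  m <- build_isochrone_map(acts, ep$geom, c(wins$t0_ms[wi], wins$t1_ms[wi]))
  tb <- tidy(m)
  mov <- ep$movie
  errs <- vapply(seq_len(nrow(tb)), function(r) {
    i <- round(tb$u_cm[r] / mov$h_cm + 0.5)
    j <- round(tb$v_cm[r] / mov$h_cm + 0.5)
    tru <- fibmap:::upstroke_times(mov$V[i, j, ], mov$t_ms)
    if (!length(tru)) return(NA_real_)
    min(abs(tru - tb$value[r]))
  }, numeric(1))
  expect_lte(stats::median(errs, na.rm = TRUE), 5)
})

test_that("propagation field recovers closed-form plane-wave direction and speed", {
  geom <- basket_geometry(jitter_seed = 2)
  g <- analysis_grid(geom, spacing_cm = 0.1)
  # T = u / 0.04 ms (40 cm/s along +u), constructed directly on the raster
  T_ <- matrix(rep(g$u / 0.04, times = g$nv), g$nu, g$nv)
  m <- fibmap:::new_grid_field(g, T_, class = "isochrone_map")
  f <- propagation_field(m)
  expect_true(all(abs(f$du - 1) < 1e-9))
  expect_true(all(abs(f$dv) < 1e-9))
  expect_true(all(abs(f$speed_cm_s - 40) < 1e-6))

  const <- fibmap:::new_grid_field(g, matrix(5, g$nu, g$nv), class = "isochrone_map")
  expect_equal(nrow(propagation_field(const)), 0)
})

test_that("direction winding around a rotating map's pivot is one full turn", {
  geom <- basket_geometry(jitter_seed = 2)
  g <- analysis_grid(geom, spacing_cm = 0.1)
  ctr <- c(2, 2)
  U <- matrix(g$u, g$nu, g$nv); Vv <- matrix(g$v, g$nu, g$nv, byrow = TRUE)
  period <- 200
  T_ <- (atan2(Vv - ctr[2], U - ctr[1]) + pi) / (2 * pi) * period
  f <- propagation_field(fibmap:::new_grid_field(g, T_, class = "isochrone_map"),
                         min_grad_ms_cm = 1)
  # walk a ring around the pivot and accumulate direction-angle changes;
  # ring nodes on the activation-time branch cut (where the raster gradient
  # is an artifact of the 0/period wrap, visible as an outlying speed) are
  # skipped -- the remaining loop still closes
  ring <- seq(0, 2 * pi, length.out = 33)[-33]
  picks <- vapply(ring, function(a) {
    pu <- ctr[1] + 0.8 * cos(a); pv <- ctr[2] + 0.8 * sin(a)
    which.min((f$u_cm - pu)^2 + (f$v_cm - pv)^2)
  }, integer(1))
  spd <- f$speed_cm_s[picks]
  ok <- spd < 3 * stats::median(spd) & spd > stats::median(spd) / 3
  angs <- atan2(f$dv[picks[ok]], f$du[picks[ok]])
  dw <- fibmap:::phase_diff(angs[c(2:length(angs), 1)], angs)
  expect_equal(abs(sum(dw)), 2 * pi, tolerance = 0.5)
})

test_that("plane-fit conduction velocity is exact and rotation invariant", {
  geom <- basket_geometry(jitter_seed = 2)
  for (ang in c(0, 37 * pi / 180)) {
    s <- plane_series(geom, cv_cm_s = 40, angle = ang)
    m <- build_isochrone_map(s, geom, window = c(0, 250))
    cv <- estimate_cv_planewave(m)
    expect_equal(cv$cv_cm_s, 40, tolerance = 0.01)
    expect_true(cv$planar)
  }
})

test_that("plane-wave CV estimated from electrograms matches simulator truth", {
  ep <- fx_plane()
  acts <- restitution_filter(detect_activations(ep$recording))
  # window spanning one complete sheet crossing: open it just before the
  # second front enters the mapped region
  starts <- acts |>
    dplyr::group_by(channel_id) |>
    dplyr::summarise(t1 = sort(time_ms)[2], .groups = "drop")
  t0 <- min(starts$t1, na.rm = TRUE) - 5
  m <- build_isochrone_map(acts, ep$geom, c(t0, t0 + 445))
  cv <- suppressWarnings(estimate_cv_planewave(m))
  expect_equal(cv$cv_cm_s, ep$truth$speed_cm_s, tolerance = 0.1)
})

test_that("a curved map carries a not-planar warning", {
  geom <- basket_geometry(jitter_seed = 2)
  g <- analysis_grid(geom, spacing_cm = 0.1)
  U <- matrix(g$u, g$nu, g$nv)
  bump <- fibmap:::new_grid_field(g, 100 * sin(U * 3), class = "isochrone_map")
  expect_warning(estimate_cv_planewave(bump), class = "fibmap_not_planar")
})

test_that("direction recurrence hits its closed-form extremes", {
  geom <- basket_geometry(jitter_seed = 2)
  s <- plane_series(geom, cycles = 4, angle = 0.3)
  maps <- lapply(0:3, function(k) {
    build_isochrone_map(s, geom, window = c(k * 250, (k + 1) * 250))
  })
  r <- direction_recurrence(maps)
  vals <- r$values[is.finite(r$values)]
  expect_gt(length(vals), 100)
  expect_equal(vals, rep(1, length(vals)), tolerance = 1e-6)

  # alternating 180 degrees: synthetic direction fields
  g <- attr(propagation_field(maps[[1]]), "grid")
  mk <- function(sgn) {
    f <- propagation_field(maps[[1]])
    f$du <- sgn * f$du; f$dv <- sgn * f$dv
    f
  }
  alt <- direction_recurrence(list(mk(1), mk(-1), mk(1), mk(-1)))
  vals <- alt$values[is.finite(alt$values)]
  expect_equal(vals, rep(-1, length(vals)), tolerance = 1e-9)
})

test_that("recurrence of random directions concentrates near zero", {
  geom <- basket_geometry(jitter_seed = 2)
  base <- plane_series(geom, cycles = 1)
  m0 <- build_isochrone_map(base, geom, window = c(0, 250))
  f0 <- propagation_field(m0)
  set.seed(17)
  fields <- lapply(seq_len(200), function(k) {
    f <- f0
    a <- stats::runif(nrow(f), 0, 2 * pi)
    f$du <- cos(a); f$dv <- sin(a)
    f
  })
  r <- direction_recurrence(fields)
  vals <- r$values[is.finite(r$values)]
  expect_gte(mean(abs(vals) < 0.2), 0.95)

  # invariance under a global rotation of every cycle's directions
  rot <- 0.7
  fields_rot <- lapply(fields, function(f) {
    du <- f$du * cos(rot) - f$dv * sin(rot)
    dv <- f$du * sin(rot) + f$dv * cos(rot)
    f$du <- du; f$dv <- dv
    f
  })
  r2 <- direction_recurrence(fields_rot)
  expect_equal(r2$values, r$values, tolerance = 1e-9)
})
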