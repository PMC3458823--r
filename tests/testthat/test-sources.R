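ev_tbl <- function(t, u, v, charge = 1L, boundary = FALSE) {
  tibble::tibble(t_ms = t, u_cm = u, v_cm = v, charge = as.integer(charge),
                 boundary = boundary)
}

combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

test_that("linking joins a stationary vortex and separates distant ones", {
  tt <- seq(0, 900, by = 30)
  one <- ev_tbl(tt, 2 + 0.01 * sin(tt), 2 + 0.01 * cos(tt))
  tracks <- link_singularities(one)
  expect_length(tracks, 1L)
  expect_equal(nrow(tracks[[1]]$samples), length(tt))
  expect_equal(tracks[[1]]$chirality, 1L)

  two <- dplyr::bind_rows(ev_tbl(tt, 0.5, 2), ev_tbl(tt, 3.5, 2, charge = -1L))
  tracks <- link_singularities(two, max_jump_cm = 1)
  expect_length(tracks, 2L)
  expect_true(all(vapply(tracks, function(tr) nrow(tr$samples), integer(1)) == length(tt)))
  chir <- sort(vapply(tracks, function(tr) tr$chirality, numeric(1)))
  expect_equal(chir, c(-1, 1))
})

test_that("tracks close after a gap and opposite chirality never merges", {
  tt <- seq(0, 300, by = 30)
  gap <- ev_tbl(c(tt, tt + 600), 2, 2)
  tracks <- link_singularities(gap, max_gap_ms = 90)
  expect_length(tracks, 2L)

  flip <- dplyr::bind_rows(ev_tbl(tt, 2, 2, charge = 1L),
                           ev_tbl(tt + 330, 2, 2, charge = -1L))
  tracks <- link_singularities(flip, max_gap_ms = 90)
  expect_length(tracks, 2L)
})

test_that("greedy linking equals exhaustive optimal assignment when unambiguous", {
  # events form well-separated clusters (> 2 x max_jump apart): any sane
  # assignment is the same partition; oracle = per-slab optimal assignment by
  # full permutation search
  set.seed(41)
  max_jump <- 0.5
  for (trial in seq_len(25)) {
    k <- sample(2:4, 1)
    centers <- cbind(stats::runif(k, 0, 10), stats::runif(k, 0, 10))
    while (k > 1 && min(stats::dist(centers)) < 2.5 * max_jump) {
      centers <- cbind(stats::runif(k, 0, 10), stats::runif(k, 0, 10))
    }
    tt <- seq(0, 300, by = 30)
    ev <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      ev_tbl(tt, centers[i, 1] + stats::runif(length(tt), -0.1, 0.1),
             centers[i, 2] + stats::runif(length(tt), -0.1, 0.1))
    }))
    ev <- ev[order(ev$t_ms, ev$u_cm), ]
    tracks <- link_singularities(ev, max_jump_cm = max_jump)
    expect_length(tracks, k)

    # oracle: per consecutive slab pair, optimal one-to-one assignment
    slabs <- split(ev, ev$t_ms)
    assign_ok <- TRUE
    for (si in seq_len(length(slabs) - 1)) {
      a <- slabs[[si]]; b <- slabs[[si + 1]]
      perms <- combinat_perms(nrow(b))
      costs <- vapply(seq_len(nrow(perms)), function(p) {
        sum(sqrt((a$u_cm - b$u_cm[perms[p, ]])^2 + (a$v_cm - b$v_cm[perms[p, ]])^2))
      }, numeric(1))
      best <- perms[which.min(costs), ]
      # greedy track membership must match the optimal pairing
      for (i in seq_len(nrow(a))) {
        tr_a <- which(vapply(tracks, function(tr) {
          any(tr$samples$t_ms == a$t_ms[i] & tr$samples$u_cm == a$u_cm[i])
        }, logical(1)))
        tr_b <- which(vapply(tracks, function(tr) {
          any(tr$samples$t_ms == b$t_ms[best[i]] & tr$samples$u_cm == b$u_cm[best[i]])
        }, logical(1)))
        if (!identical(tr_a, tr_b)) assign_ok <- FALSE
      }
    }
    expect_true(assign_ok)
  }
})

test_that("outlier removal drops isolated extreme points only", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  circ <- tibble::tibble(t_ms = seq_along(th) * 30,
                         u_cm = 2 + 0.5 * cos(th), v_cm = 2 + 0.5 * sin(th))
  tr <- fibmap:::new_source_track(circ, "rotor", 1)
  spiked <- circ
  spiked$u_cm[20] <- 2 + 10 * 0.5  # ten radii out
  tr_sp <- fibmap:::new_source_track(spiked, "rotor", 1)
  cleaned <- remove_outlier_points(tr_sp)
  expect_equal(nrow(cleaned$samples), nrow(circ) - 1L)
  expect_false(any(cleaned$samples$u_cm > 4))

  expect_identical(remove_outlier_points(tr)$samples, tr$samples)

  short <- fibmap:::new_source_track(circ[1:3, ], "rotor", 1)
  expect_warning(out <- remove_outlier_points(short), class = "fibmap_short_track")
  expect_identical(out$samples, short$samples)
})

test_that("outlier removal matches a brute-force audit of its own rule", {
  set.seed(57)
  for (trial in seq_len(50)) {
    n <- sample(8:30, 1)
    u <- 2 + cumsum(stats::rnorm(n, 0, 0.05))
    v <- 2 + cumsum(stats::rnorm(n, 0, 0.05))
    n_out <- sample(0:2, 1)
    idx <- sample(n, n_out)
    u[idx] <- u[idx] + sample(c(-1, 1), n_out, TRUE) * stats::runif(n_out, 3, 5)
    tr <- fibmap:::new_source_track(
      tibble::tibble(t_ms = seq_len(n) * 30, u_cm = u, v_cm = v), "rotor", 1)
    cleaned <- suppressWarnings(remove_outlier_points(tr, k = 5))
    # independent leave-one-out audit: per point, distance to the nearest of
    # all other points, computed pairwise from scratch
    nn <- vapply(seq_len(n), function(i) {
      min(sqrt((u[i] - u[-i])^2 + (v[i] - v[-i])^2))
    }, numeric(1))
    flag <- nn > 5 * max(stats::median(nn), 1e-9)
    want <- if (sum(flag) > 0.2 * n) seq_len(n) else which(!flag)
    expect_equal(cleaned$samples$u_cm, u[want])
  }
})

test_that("smoothed locus is C2, interpolating, and linear on collinear input", {
  line <- tibble::tibble(t_ms = 1:6 * 30,
                         u_cm = seq(1, 2, length.out = 6),
                         v_cm = seq(2, 4, length.out = 6))
  cur <- smooth_locus(fibmap:::new_source_track(line, "rotor", 1))
  xy <- evaluate_locus(cur, 200)
  d <- abs((xy[, 2] - 2) / 2 - (xy[, 1] - 1))  # v-2 = 2 (u-1) along the segment
  expect_lt(max(d), 1e-9)

  two <- smooth_locus(cbind(c(0, 1), c(0, 1)))
  xy <- evaluate_locus(two, 50)
  expect_equal(xy[, 1], xy[, 2], tolerance = 1e-12)

  set.seed(8)
  for (trial in 1:10) {
    n <- sample(5:15, 1)
    pts <- cbind(cumsum(stats::runif(n, 0.1, 0.5)), stats::rnorm(n))
    cur <- smooth_locus(pts)
    # interpolation through every knot
    ku <- cur$fu(cur$knots_s); kv <- cur$fv(cur$knots_s)
    expect_equal(ku, pts[, 1], tolerance = 1e-9)
    expect_equal(kv, pts[, 2], tolerance = 1e-9)
    # first/second derivative continuity at interior knots by finite differences
    scale <- max(stats::dist(pts))
    eps <- 1e-5
    for (k in cur$knots_s[-c(1, length(cur$knots_s))]) {
      for (f in list(cur$fu, cur$fv)) {
        d1l <- (f(k) - f(k - eps)) / eps
        d1r <- (f(k + eps) - f(k)) / eps
        expect_lt(abs(d1r - d1l) / scale, 1e-3)
        d2l <- (f(k) - 2 * f(k - eps) + f(k - 2 * eps)) / eps^2
        d2r <- (f(k + 2 * eps) - 2 * f(k + eps) + f(k)) / eps^2
        expect_lt(abs(d2r - d2l) / scale, 1)
      }
    }
  }
})

test_that("locus area matches known hulls and a brute-force oracle", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circle <- cbind(cos(th), sin(th))
  expect_equal(locus_area(circle), pi, tolerance = 0.01)

  expect_equal(locus_area(cbind(1:5, 2 * (1:5))), 0)
  expect_equal(locus_area(cbind(1, 1)), 0)

  # O(n^3) oracle: find hull edges by testing every directed pair for
  # one-sidedness, order them by angle, apply the shoelace formula
  brute_hull_area <- function(pts) {
    n <- nrow(pts)
    if (n < 3) return(0)
    edges <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      rel <- (pts[, 1] - pts[i, 1]) * (pts[j, 2] - pts[i, 2]) -
             (pts[, 2] - pts[i, 2]) * (pts[j, 1] - pts[i, 1])
      if (all(rel <= 1e-12)) edges[[length(edges) + 1L]] <- c(i, j)
    }
    if (!length(edges)) return(0)
    vs <- unique(unlist(edges))
    hp <- pts[vs, , drop = FALSE]
    ctr <- colMeans(hp)
    ord <- order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1]))
    h <- hp[ord, , drop = FALSE]
    abs(sum(h[, 1] * c(h[-1, 2], h[1, 2]) - c(h[-1, 1], h[1, 1]) * h[, 2])) / 2
  }
  set.seed(12)
  for (trial in seq_len(100)) {
    n <- sample(3:40, 1)
    pts <- cbind(stats::rnorm(n), stats::rnorm(n))
    expect_equal(locus_area(pts), brute_hull_area(pts), tolerance = 1e-9)
  }

  # rigid motions leave the area unchanged
  pts <- cbind(stats::rnorm(20), stats::rnorm(20))
  a0 <- locus_area(pts)
  R <- matrix(c(cos(1.1), sin(1.1), -sin(1.1), cos(1.1)), 2)
  expect_equal(locus_area(sweep(pts %*% R, 2, c(5, -3), `+`)), a0, tolerance = 1e-9)
})

test_that("concurrent-source counting uses span overlap", {
  tr <- function(t0, t1, kind = "rotor") {
    fibmap:::new_source_track(tibble::tibble(t_ms = c(t0, t1), u_cm = 1:2, v_cm = 1:2),
                              kind, 1)
  }
  expect_equal(count_concurrent_sources(list(tr(0, 1000)), c(200, 800)), 1L)
  expect_equal(count_concurrent_sources(list(tr(0, 1000), tr(500, 1500, "focal")),
                                        c(600, 900)), 2L)
  expect_equal(count_concurrent_sources(list(tr(0, 100)), c(200, 800)), 0L)
})

test_that("conservation metric matches closed-form hull arithmetic", {
  sq <- function(x0) cbind(x0 + c(0, 1, 1, 0), c(0, 0, 1, 1))
  same <- conservation_metric(sq(0), sq(0))
  expect_equal(same$centroid_distance_cm, 0)
  expect_equal(same$overlap, 1, tolerance = 1e-9)

  far <- conservation_metric(sq(0), sq(20))
  expect_equal(far$overlap, 0)
  expect_equal(far$centroid_distance_cm, 20)

  off <- conservation_metric(sq(0), sq(0.5))
  expect_equal(off$overlap, 0.5 / 1.5, tolerance = 1e-9)

  # degenerate loci get buffered and flagged
  dg <- conservation_metric(cbind(c(1, 1), c(1, 1)), cbind(c(1.05, 1.05), c(1, 1)))
  expect_true(dg$buffered)
  expect_gte(dg$overlap, 0)
})

test_that("predicted wavelength reproduces the published bound and is bilinear", {
  expect_equal(predicted_wavelength(100, 40), 40)
  expect_equal(predicted_wavelength(110, 40), 44)
  for (r in c(0.001, 1, 50, 200)) for (cv in c(0.5, 10, 40)) {
    expect_equal(predicted_wavelength(r, cv), r * cv / 100, tolerance = 1e-12)
  }
  expect_error(predicted_wavelength(0, 40), class = "fibmap_invalid_argument")
  expect_error(predicted_wavelength(100, -1), class = "fibmap_invalid_argument")
})

test_that("rotor classification needs sustained rotation", {
  rep_s <- fx_report("spiral")
  tracks <- attr(rep_s, "tracks")
  pmap <- attr(rep_s, "phase_map")
  main <- tracks[[which.max(vapply(tracks, function(t) nrow(t$samples), integer(1)))]]
  cls <- classify_rotor(main, pmap)
  expect_true(cls$is_rotor)
  expect_gte(cls$n_rotations, 4)

  # truncated to roughly half a rotation: not a rotor at the default threshold
  period <- attr(rep_s, "episode")$truth$period_ms
  half <- main
  keep <- half$samples$t_ms <= half$samples$t_ms[1] + period / 2
  half$samples <- half$samples[keep, ]
  half$time_span <- range(half$samples$t_ms)
  cls2 <- classify_rotor(half, pmap)
  expect_false(cls2$is_rotor)
})

test_that("focal detection localizes the origin and rejects other patterns", {
  rep_f <- fx_report("focal")
  focal <- attr(rep_f, "focal_tracks")
  expect_length(focal, 1L)
  org <- attr(rep_f, "episode")$truth$origin
  est <- c(stats::median(focal[[1]]$samples$u_cm), stats::median(focal[[1]]$samples$v_cm))
  expect_lt(sqrt(sum((est - org)^2)), 1.0)

  rep_p <- fx_report("plane")
  expect_length(attr(rep_p, "focal_tracks"), 0L)
  rep_s <- fx_report("spiral")
  expect_length(attr(rep_s, "focal_tracks"), 0L)
})

test_that("episode kinds yield mutually exclusive source classifications", {
  rs <- fx_report("spiral")
  expect_true(all(rs$sources$kind == "rotor"))
  expect_gte(rs$n_sources, 1)
  rf <- fx_report("focal")
  expect_true(all(rf$sources$kind == "focal"))
  expect_equal(rf$n_sources, 1L)
  rp <- fx_report("plane")
  expect_equal(rp$n_sources, 0L)
})

test_that("tracked rotor locus contains the truth tip cloud at comparable scale", {
  rep_s <- analyze_episode(fx_spiral_meander(), list(kind = "spiral"))
  tracks <- attr(rep_s, "tracks")
  main <- tracks[[which.max(vapply(tracks, function(t) nrow(t$samples), integer(1)))]]
  locus <- evaluate_locus(smooth_locus(main), 1024)
  hull <- fibmap:::hull_polygon(locus)
  tp <- fx_spiral_meander()$truth$tip_path
  tp <- tp[tp$t_ms >= main$time_span[1] & tp$t_ms <= main$time_span[2], ]
  inside <- fibmap:::points_in_hull(tp$u_cm, tp$v_cm, rbind(hull, hull[1, ]))
  expect_gte(mean(inside), 0.8)
  # areas within a factor of two
  a_track <- locus_area(locus)
  a_truth <- locus_area(cbind(tp$u_cm, tp$v_cm))
  expect_lt(a_track / a_truth, 2)
  expect_gt(a_track / a_truth, 0.5)
})
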