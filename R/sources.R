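#' Link phase-singularity events into provisional rotor tracks
#'
#' Greedy nearest-neighbour linking per time slab: events at successive
#' analysis times are joined to the nearest open track of the same chirality
#' within `max_jump_cm`; tracks missing a match for longer than `max_gap_ms`
#' are closed. Boundary-flagged events are excluded by default.
#'
#' @param events Event tibble (`t_ms`, `u_cm`, `v_cm`, `charge`, `boundary`),
#'   time-sorted, typically detected every 25-45 ms.
#' @param max_jump_cm Maximum per-step displacement of a source centre.
#' @param max_gap_ms Gap after which a track is closed.
#' @param include_boundary Keep boundary-flagged events?
#' @return A `source_track_set`: list of `source_track` objects (kind
#'   `"rotor"`, provisional), each with `samples` (tibble `t_ms`, `u_cm`,
#'   `v_cm`), `chirality`, `kind`, `time_span`.
#' @export
link_singularities <- function(events, max_jump_cm = 1, max_gap_ms = 90,
                               include_boundary = FALSE) {
  ev <- events
  if (!include_boundary && "boundary" %in% names(ev)) ev <- ev[!ev$boundary, ]
  ev <- ev[order(ev$t_ms), ]
  tracks <- list()   # open: list(samples rows, chirality, last_t)
  closed <- list()
  for (tt in unique(ev$t_ms)) {
    slab <- ev[ev$t_ms == tt, ]
    # close stale tracks
    if (length(tracks)) {
      stale <- vapply(tracks, function(tr) tt - tr$last_t > max_gap_ms, logical(1))
      closed <- c(closed, tracks[stale])
      tracks <- tracks[!stale]
    }
    unmatched <- rep(TRUE, nrow(slab))
    if (length(tracks) && nrow(slab)) {
      # candidate pairs ordered by distance, same chirality
      last_pos <- t(vapply(tracks, function(tr) {
        c(tr$samples$u_cm[nrow(tr$samples)], tr$samples$v_cm[nrow(tr$samples)])
      }, numeric(2)))
      chir <- vapply(tracks, function(tr) tr$chirality, numeric(1))
      cand <- expand.grid(trk = seq_along(tracks), evt = seq_len(nrow(slab)))
      cand$d <- sqrt((last_pos[cand$trk, 1] - slab$u_cm[cand$evt])^2 +
                     (last_pos[cand$trk, 2] - slab$v_cm[cand$evt])^2)
      cand <- cand[cand$d <= max_jump_cm & chir[cand$trk] == slab$charge[cand$evt], ]
      cand <- cand[order(cand$d), ]
      used_trk <- logical(length(tracks))
      for (r in seq_len(nrow(cand))) {
        ti <- cand$trk[r]; ei <- cand$evt[r]
        if (used_trk[ti] || !unmatched[ei]) next
        tracks[[ti]]$samples <- rbind(tracks[[ti]]$samples,
                                      slab[ei, c("t_ms", "u_cm", "v_cm")])
        tracks[[ti]]$last_t <- tt
        used_trk[ti] <- TRUE
        unmatched[ei] <- FALSE
      }
    }
    for (ei in which(unmatched)) {
      tracks[[length(tracks) + 1L]] <- list(
        samples = slab[ei, c("t_ms", "u_cm", "v_cm")],
        chirality = slab$charge[ei], last_t = tt)
    }
  }
  closed <- c(closed, tracks)
  out <- lapply(closed, function(tr) {
    new_source_track(tibble::as_tibble(tr$samples), kind = "rotor",
                     chirality = tr$chirality)
  })
  # stable order: by start time, then u
  ord <- order(vapply(out, function(tr) tr$time_span[1], numeric(1)),
               vapply(out, function(tr) tr$samples$u_cm[1], numeric(1)))
  structure(out[ord], class = "source_track_set")
}

new_source_track <- function(samples, kind, chirality = NA_real_) {
  samples <- samples[order(samples$t_ms), ]
  structure(list(kind = kind, samples = tibble::as_tibble(samples),
                 chirality = chirality,
                 time_span = range(samples$t_ms)),
            class = "source_track")
}

#' @export
print.source_track <- function(x, ...) {
  cat(sprintf("<source_track> %s, %d samples, t = [%.0f, %.0f] ms, chirality %s\n",
              x$kind, nrow(x$samples), x$time_span[1], x$time_span[2],
              if (is.na(x$chirality)) "n/a" else sprintf("%+d", x$chirality)))
  invisible(x)
}

#' @export
print.source_track_set <- function(x, ...) {
  cat(sprintf("<source_track_set> %d track(s)\n", length(x)))
  for (tr in x) print(tr)
  invisible(x)
}

#' Remove isolated extreme outlying points from a track
#'
#' Interpolation errors occasionally throw a singularity far from the true
#' migration locus. A sample is an isolated extreme outlier when its
#' leave-one-out nearest-neighbour distance exceeds `k` times the median
#' nearest-neighbour distance of the track. At most 20% of samples may be
#' removed; if the rule would drop more, the track is returned unchanged with
#' a warning. Tracks with fewer than 4 samples are returned unchanged with a
#' warning.
#'
#' @param track A `source_track`.
#' @param k Outlyingness multiplier (default 5).
#' @return The cleaned `source_track` (never gains points).
#' @export
remove_outlier_points <- function(track, k = 5) {
  n <- nrow(track$samples)
  if (n < 4L) {
    warn("Track has fewer than 4 samples; outlier removal skipped.",
         class = "fibmap_short_track")
    return(track)
  }
  keep <- !outlier_flags(track$samples$u_cm, track$samples$v_cm, k)
  if (sum(!keep) > 0.2 * n) {
    warn("Outlier rule would drop more than 20% of samples; keeping all.",
         class = "fibmap_outlier_overflow")
    return(track)
  }
  new_source_track(track$samples[keep, ], track$kind, track$chirality)
}

# The removal rule: leave-one-out nearest-neighbour distance per point,
# flagged when > k * median of those distances.
outlier_flags <- function(u, v, k = 5) {
  dm <- as.matrix(stats::dist(cbind(u, v)))
  diag(dm) <- Inf
  nn <- apply(dm, 1, min)
  nn > k * max(median(nn), 1e-9)
}

#' Smooth a migration locus with a C2 piecewise-cubic curve
#'
#' Fits chord-length-parameterized natural cubic splines through the retained
#' tip samples -- a piecewise third-order (Bezier-equivalent) curve whose
#' first and second derivatives are continuous at every interior knot and
#' which passes through every sample exactly. Consecutive duplicate points
#' are collapsed before fitting; two points give the straight segment.
#'
#' @param track A `source_track` (or a 2-column matrix / data frame of
#'   `u_cm`, `v_cm`).
#' @return Object of class `locus_curve`: functions `fu(s)`, `fv(s)` over
#'   arc parameter `s` in `[0, s_max]`, plus `knots_s` and the knot points.
#' @export
smooth_locus <- function(track) {
  pts <- locus_points(track)
  # collapse consecutive duplicates
  if (nrow(pts) > 1) {
    d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    pts <- pts[c(TRUE, d > 1e-12), , drop = FALSE]
  }
  if (nrow(pts) < 2) {
    stop_fibmap("Need at least 2 distinct points to smooth a locus.",
                "fibmap_invalid_argument")
  }
  s <- c(0, cumsum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)))
  if (nrow(pts) == 2) {
    fu <- stats::approxfun(s, pts[, 1]); fv <- stats::approxfun(s, pts[, 2])
  } else {
    fu <- splinefun(s, pts[, 1], method = "natural")
    fv <- splinefun(s, pts[, 2], method = "natural")
  }
  structure(list(fu = fu, fv = fv, knots_s = s, points = pts),
            class = "locus_curve")
}

locus_points <- function(x) {
  if (inherits(x, "source_track")) {
    cbind(x$samples$u_cm, x$samples$v_cm)
  } else if (inherits(x, "locus_curve")) {
    evaluate_locus(x, 512L)
  } else {
    m <- as.matrix(as.data.frame(x))
    storage.mode(m) <- "double"
    m[, 1:2, drop = FALSE]
  }
}

#' Evaluate a smoothed locus at evenly spaced arc parameters
#'
#' @param curve A `locus_curve`.
#' @param n Number of evaluation points.
#' @return `n x 2` matrix of `(u, v)`.
#' @export
evaluate_locus <- function(curve, n = 256L) {
  s <- seq(0, max(curve$knots_s), length.out = n)
  cbind(curve$fu(s), curve$fv(s))
}

#' Migration-locus area
#'
#' Area of the convex hull of the (smoothed) locus, in cm^2. Degenerate loci
#' (fewer than 3 distinct points, or collinear) have area 0.
#'
#' @param x A `locus_curve`, `source_track`, or matrix / data frame of points.
#' @return Area in cm^2.
#' @export
locus_area <- function(x) {
  pts <- locus_points(x)
  convex_hull_area(pts)
}

# Shoelace area of the convex hull of a point set.
convex_hull_area <- function(pts) {
  pts <- unique(pts[complete.cases(pts), , drop = FALSE])
  if (nrow(pts) < 3) return(0)
  idx <- grDevices::chull(pts)
  if (length(idx) < 3) return(0)
  h <- pts[idx, , drop = FALSE]
  polygon_area(h)
}

polygon_area <- function(h) {
  n <- nrow(h)
  i2 <- c(2:n, 1)
  abs(sum(h[, 1] * h[i2, 2] - h[i2, 1] * h[, 2])) / 2
}

#' Classify a track as a rotor by sustained rotation
#'
#' Rotation is measured from the phase field itself: probe nodes on a ring
#' around the track centroid have their phase time series unwrapped over the
#' track's time span; the rotation count is the mean total phase progression
#' across probes divided by 2 pi. A track is a rotor when it completes at
#' least `min_rotations` full rotations without a sampling gap longer than
#' `max_gap_ms`.
#'
#' @param track A `source_track`.
#' @param pmap The `phase_map` the track was detected on (frames covering the
#'   track's span).
#' @param min_rotations Minimum full rotations (default 2).
#' @param max_gap_ms Maximum tolerated gap between track samples.
#' @param probe_radius_cm Ring radius for the probe nodes.
#' @return One-row tibble `is_rotor`, `n_rotations`, `chirality`.
#' @export
classify_rotor <- function(track, pmap, min_rotations = 2, max_gap_ms = 90,
                           probe_radius_cm = 0.8) {
  g <- pmap$grid
  ctr <- c(median(track$samples$u_cm), median(track$samples$v_cm))
  span <- track$time_span
  sel <- which(pmap$t_ms >= span[1] & pmap$t_ms <= span[2])
  gaps_ok <- nrow(track$samples) >= 2 &&
    max(diff(sort(track$samples$t_ms))) <= max_gap_ms
  if (length(sel) < 3) {
    return(tibble::tibble(is_rotor = FALSE, n_rotations = 0,
                          chirality = track$chirality))
  }
  ang <- seq(0, 2 * pi, length.out = 9L)[-9L]
  prog <- vapply(ang, function(a) {
    pu <- ctr[1] + probe_radius_cm * cos(a)
    pv <- ctr[2] + probe_radius_cm * sin(a)
    iu <- which.min(abs(g$u - pu)); iv <- which.min(abs(g$v - pv))
    series <- pmap$phi[iu, iv, sel]
    if (any(!is.finite(series))) return(NA_real_)
    d <- phase_diff(series[-1], series[-length(series)])
    sum(d)
  }, numeric(1))
  prog <- prog[is.finite(prog)]
  if (!length(prog)) {
    return(tibble::tibble(is_rotor = FALSE, n_rotations = 0,
                          chirality = track$chirality))
  }
  n_rot <- abs(mean(prog)) / (2 * pi)
  tibble::tibble(is_rotor = gaps_ok && n_rot >= min_rotations,
                 n_rotations = n_rot, chirality = track$chirality)
}

#' Detect repetitive focal sources from per-cycle isochronal maps
#'
#' A focal origin candidate in one cycle is an interior grid node that is a
#' local minimum of activation time and from which time increases
#' monotonically along all 8 grid rays for at least `ray_length_cm`.
#' Candidates recurring within `max_jump_cm` across at least `min_repeats`
#' consecutive cycles form a focal track.
#'
#' @param maps List of per-cycle `isochrone_map`s on a common grid.
#' @param min_repeats Minimum consecutive cycles (default 2).
#' @param max_jump_cm Maximum origin movement between cycles.
#' @param ray_length_cm Required monotone-radiation distance (about two
#'   electrode spacings).
#' @return A `source_track_set` of focal tracks (possibly empty).
#' @export
detect_focal_sources <- function(maps, min_repeats = 2L, max_jump_cm = 1,
                                 ray_length_cm = 1) {
  if (length(maps) < min_repeats) {
    stop_fibmap(sprintf("Need at least %d mapped cycles.", min_repeats),
                "fibmap_insufficient_data")
  }
  origins <- lapply(seq_along(maps), function(ci) {
    m <- maps[[ci]]
    cand <- focal_candidates(m$values, m$grid, ray_length_cm)
    if (!nrow(cand)) return(NULL)
    cand$cycle <- ci
    cand$t_ms <- mean(m$window %||% c(0, 0))
    cand
  })
  origins <- dplyr::bind_rows(origins)
  if (is.null(origins) || !nrow(origins)) return(structure(list(), class = "source_track_set"))
  # chain origins over consecutive cycles, greedy nearest within max_jump
  chains <- list()
  open <- list()
  for (ci in sort(unique(origins$cycle))) {
    slab <- origins[origins$cycle == ci, ]
    matched_ev <- rep(FALSE, nrow(slab))
    if (length(open)) {
      last_pos <- t(vapply(open, function(o) unlist(o$pos), numeric(2)))
      cand <- expand.grid(ch = seq_along(open), evt = seq_len(nrow(slab)))
      cand$d <- sqrt((last_pos[cand$ch, 1] - slab$u_cm[cand$evt])^2 +
                     (last_pos[cand$ch, 2] - slab$v_cm[cand$evt])^2)
      ok_gap <- vapply(open, function(o) ci - o$last_cycle == 1L, logical(1))
      cand <- cand[cand$d <= max_jump_cm & ok_gap[cand$ch], ]
      cand <- cand[order(cand$d), ]
      used <- logical(length(open))
      for (r in seq_len(nrow(cand))) {
        ch <- cand$ch[r]; ei <- cand$evt[r]
        if (used[ch] || matched_ev[ei]) next
        open[[ch]]$rows <- rbind(open[[ch]]$rows, slab[ei, ])
        open[[ch]]$pos <- list(slab$u_cm[ei], slab$v_cm[ei])
        open[[ch]]$last_cycle <- ci
        used[ch] <- TRUE
        matched_ev[ei] <- TRUE
      }
      done <- vapply(open, function(o) ci - o$last_cycle >= 1L, logical(1))
      chains <- c(chains, open[done])
      open <- open[!done]
    }
    for (ei in which(!matched_ev)) {
      open[[length(open) + 1L]] <- list(rows = slab[ei, ],
                                        pos = list(slab$u_cm[ei], slab$v_cm[ei]),
                                        last_cycle = ci)
    }
  }
  chains <- c(chains, open)
  keep <- Filter(function(o) nrow(o$rows) >= min_repeats, chains)
  out <- lapply(keep, function(o) {
    tr <- new_source_track(tibble::as_tibble(o$rows[, c("t_ms", "u_cm", "v_cm")]),
                           kind = "focal", chirality = NA_real_)
    tr$n_beats <- nrow(o$rows)
    tr
  })
  structure(out, class = "source_track_set")
}

# Interior local minima with monotone radiation along 8 grid rays.
focal_candidates <- function(T_, grid, ray_length_cm) {
  nu <- nrow(T_); nv <- ncol(T_)
  steps <- max(2L, ceiling(ray_length_cm / grid$du))
  dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  res <- list()
  for (i in 2:(nu - 1L)) {
    for (j in 2:(nv - 1L)) {
      t0 <- T_[i, j]
      if (!is.finite(t0)) next
      nb <- T_[cbind(i + dirs[, 1], j + dirs[, 2])]
      if (any(!is.finite(nb)) || any(nb < t0)) next
      ok <- TRUE
      for (d in seq_len(8)) {
        prev <- t0
        for (s in seq_len(steps)) {
          ii <- i + s * dirs[d, 1]; jj <- j + s * dirs[d, 2]
          if (ii < 1 || ii > nu || jj < 1 || jj > nv || !is.finite(T_[ii, jj])) {
            ok <- FALSE; break
          }
          if (T_[ii, jj] < prev - 1e-9) { ok <- FALSE; break }
          prev <- T_[ii, jj]
        }
        if (!ok) break
      }
      if (ok) res[[length(res) + 1L]] <- data.frame(u_cm = grid$u[i], v_cm = grid$v[j],
                                                    t_at_origin = t0)
    }
  }
  if (!length(res)) {
    return(data.frame(u_cm = numeric(), v_cm = numeric(), t_at_origin = numeric()))
  }
  cand <- dplyr::bind_rows(res)
  # collapse a plateau of candidates to its centroid
  if (nrow(cand) > 1) {
    cl <- cluster_points(cand$u_cm, cand$v_cm, eps = 3 * grid$du)
    cand <- cand |>
      dplyr::mutate(cl = cl) |>
      dplyr::group_by(.data$cl) |>
      dplyr::summarise(u_cm = mean(.data$u_cm), v_cm = mean(.data$v_cm),
                       t_at_origin = min(.data$t_at_origin), .groups = "drop") |>
      dplyr::select(-dplyr::any_of("cl"))
  }
  cand
}

# Single-linkage clustering by distance threshold (small n).
cluster_points <- function(u, v, eps) {
  n <- length(u)
  if (n == 1L) return(1L)
  d <- as.matrix(stats::dist(cbind(u, v)))
  cl <- stats::cutree(stats::hclust(stats::as.dist(d), method = "single"), h = eps)
  cl
}

#' Number of sources concurrent with a time window
#'
#' @param tracks A `source_track_set` (or list of tracks).
#' @param window `(t0, t1)` ms.
#' @return Integer count of tracks whose time span overlaps the window.
#' @export
count_concurrent_sources <- function(tracks, window) {
  sum(vapply(tracks, function(tr) {
    tr$time_span[1] <= window[2] && tr$time_span[2] >= window[1]
  }, logical(1)))
}

#' Spatial conservation between two maps of the same source
#'
#' Quantifies whether a source re-mapped later sits where it was: centroid
#' distance between the two migration loci and the fractional overlap
#' (intersection over union) of their convex hulls. Degenerate (zero-area)
#' loci are buffered by 1 mm and flagged.
#'
#' @param track_a,track_b `source_track`s (or point matrices).
#' @param elapsed_min Optional minutes between the two maps, echoed in the
#'   report.
#' @return One-row tibble `centroid_distance_cm`, `overlap`, `elapsed_min`,
#'   `buffered`.
#' @export
conservation_metric <- function(track_a, track_b, elapsed_min = NA_real_) {
  pa <- locus_points(track_a); pb <- locus_points(track_b)
  if (!nrow(pa) || !nrow(pb)) {
    stop_fibmap("Both tracks must be non-empty.", "fibmap_invalid_argument")
  }
  ca <- colMeans(pa); cb <- colMeans(pb)
  buffered <- FALSE
  ha <- hull_polygon(pa); hb <- hull_polygon(pb)
  if (is.null(ha) || is.null(hb)) {
    buffered <- TRUE
    pa <- buffer_points(pa, 0.1); pb <- buffer_points(pb, 0.1)
    ha <- hull_polygon(pa); hb <- hull_polygon(pb)
  }
  ai <- convex_intersection_area(ha, hb)
  aa <- polygon_area(ha); ab <- polygon_area(hb)
  overlap <- if (aa + ab - ai > 0) ai / (aa + ab - ai) else 0
  tibble::tibble(centroid_distance_cm = sqrt(sum((ca - cb)^2)),
                 overlap = overlap, elapsed_min = elapsed_min,
                 buffered = buffered)
}

hull_polygon <- function(pts) {
  pts <- unique(pts[complete.cases(pts), , drop = FALSE])
  if (nrow(pts) < 3) return(NULL)
  idx <- grDevices::chull(pts)
  if (length(idx) < 3) return(NULL)
  h <- pts[idx, , drop = FALSE]
  if (polygon_area(h) < 1e-12) return(NULL)
  h
}

buffer_points <- function(pts, r) {
  offs <- rbind(c(r, 0), c(-r, 0), c(0, r), c(0, -r), c(r, r), c(r, -r),
                c(-r, r), c(-r, -r))
  do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    sweep(offs, 2, pts[i, ], `+`)
  }))
}

# Sutherland-Hodgman clipping of convex polygon `subject` by convex `clip`;
# both open (no repeated last vertex). Returns intersection area.
convex_intersection_area <- function(subject, clip) {
  # ensure CCW orientation of clip
  if (signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  n <- nrow(clip)
  for (e in seq_len(n)) {
    if (is.null(out) || nrow(out) < 3) return(0)
    a <- clip[e, ]; b <- clip[if (e == n) 1L else e + 1L, ]
    inp <- out
    out <- NULL
    m <- nrow(inp)
    side <- (b[1] - a[1]) * (inp[, 2] - a[2]) - (b[2] - a[2]) * (inp[, 1] - a[1])
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      ci <- side[i] >= -1e-12; cj <- side[j] >= -1e-12
      if (ci) out <- rbind(out, inp[i, ])
      if (xor(ci, cj)) {
        t <- side[i] / (side[i] - side[j])
        out <- rbind(out, inp[i, ] + t * (inp[j, ] - inp[i, ]))
      }
    }
  }
  if (is.null(out) || nrow(out) < 3) return(0)
  polygon_area(out)
}

signed_area <- function(h) {
  n <- nrow(h)
  i2 <- c(2:n, 1)
  sum(h[, 1] * h[i2, 2] - h[i2, 1] * h[, 2]) / 2
}

#' Minimum reentrant wavelength
#'
#' Wavelength = repolarization time x conduction velocity, the shortest path
#' length able to sustain re-entry. With the minimum human atrial
#' repolarization time (100 ms) and the slowest dynamic conduction velocity
#' (40 cm/s) this gives the 40 mm lower bound that a basket's electrode pitch
#' must (and does) resolve.
#'
#' @param repolarization_ms Repolarization (recovery) time, ms.
#' @param cv_cm_s Conduction velocity, cm/s.
#' @return Wavelength in mm.
#' @examples
#' predicted_wavelength(100, 40) # 40 mm
#' @export
predicted_wavelength <- function(repolarization_ms, cv_cm_s) {
  if (any(!is.finite(repolarization_ms)) || any(!is.finite(cv_cm_s)) ||
      any(repolarization_ms <= 0) || any(cv_cm_s <= 0)) {
    stop_fibmap("Both arguments must be positive.", "fibmap_invalid_argument")
  }
  repolarization_ms * cv_cm_s / 100
}

#' Summarise a set of source tracks
#'
#' @param x A `source_track_set`.
#' @param ... Unused.
#' @return Tibble, one row per track: kind, chirality, sample count, span,
#'   locus area.
#' @export
tidy.source_track_set <- function(x, ...) {
  if (!length(x)) {
    return(tibble::tibble(track = integer(), kind = character(),
                          chirality = numeric(), n_samples = integer(),
                          t_start_ms = numeric(), t_end_ms = numeric(),
                          locus_area_cm2 = numeric()))
  }
  dplyr::bind_rows(lapply(seq_along(x), function(i) {
    tr <- x[[i]]
    tibble::tibble(track = i, kind = tr$kind, chirality = tr$chirality,
                   n_samples = nrow(tr$samples),
                   t_start_ms = tr$time_span[1], t_end_ms = tr$time_span[2],
                   locus_area_cm2 = locus_area(tr))
  }))
}

#' Export tracks as JSON
#'
#' One object per track: kind, chirality, samples, hull vertices, area.
#'
#' @param tracks A `source_track_set`.
#' @param path File path.
#' @export
write_tracks <- function(tracks, path) {
  obj <- lapply(tracks, function(tr) {
    h <- hull_polygon(cbind(tr$samples$u_cm, tr$samples$v_cm))
    list(kind = tr$kind,
         chirality = if (is.na(tr$chirality)) NULL else tr$chirality,
         samples = as.data.frame(tr$samples),
         hull = if (is.null(h)) NULL else as.data.frame(h),
         area_cm2 = locus_area(tr),
         time_span_ms = tr$time_span)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
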