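#' Segment a recording into activation cycles
#'
#' Picks the most regular channel (lowest coefficient of variation of its
#' activation intervals, requiring at least 3 events) as the reference and
#' anchors one window per reference activation, each of the local median cycle
#' length. The window phase is then aligned to the diastolic gap: activation
#' times folded modulo the cycle length concentrate in the active part of the
#' cycle, and windows open at the least-active phase, so one window holds one
#' complete propagation cycle rather than cutting a wavefront in half.
#'
#' @param series An activation series.
#' @param max_cycles Optional cap on the number of windows returned.
#' @return Tibble `cycle`, `t0_ms`, `t1_ms` plus attributes
#'   `reference_channel` and `cycle_length_ms`.
#' @export
segment_cycles <- function(series, max_cycles = NULL) {
  stats <- series |>
    dplyr::group_by(.data$channel_id) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::summarise(cv = sd(diff(.data$time_ms)) / mean(diff(.data$time_ms)),
                     .groups = "drop")
  if (!nrow(stats)) {
    stop_fibmap("No channel has 3 or more activations; cannot segment cycles.",
                "fibmap_insufficient_data")
  }
  ref <- stats$channel_id[which.min(stats$cv)]
  tt <- sort(series$time_ms[series$channel_id == ref])
  cl <- median(diff(tt))
  # diastolic-gap alignment: fold all activations mod cl, find the phase bin
  # with least activity (ties: first), and shift window starts onto it
  nb <- 24L
  folded <- series$time_ms %% cl
  counts <- tabulate(pmin(floor(folded / cl * nb) + 1L, nb), nbins = nb)
  # centre of the longest circular run of least-active bins
  is_min <- counts == min(counts)
  ext <- rep(is_min, 2L)
  run_len <- 0L; best_len <- 0L; best_end <- 1L
  for (i in seq_along(ext)) {
    run_len <- if (ext[i]) run_len + 1L else 0L
    if (run_len > best_len && run_len <= nb) {
      best_len <- run_len; best_end <- i
    }
  }
  gap_bin <- ((best_end - (best_len - 1L) / 2 - 1L) %% nb) + 1
  gap_phase <- (gap_bin - 0.5) / nb * cl
  ref_phase <- median(tt %% cl)
  delta <- (ref_phase - gap_phase) %% cl
  t0 <- tt[-length(tt)] - delta
  wins <- tibble::tibble(cycle = seq_along(t0), t0_ms = t0, t1_ms = t0 + cl)
  if (!is.null(max_cycles)) wins <- wins[seq_len(min(nrow(wins), max_cycles)), ]
  attr(wins, "reference_channel") <- ref
  attr(wins, "cycle_length_ms") <- cl
  wins
}

#' Per-cycle isochronal activation map
#'
#' Takes each channel's first activation inside the window and interpolates
#' the activation times onto the analysis grid. Nodes outside the electrode
#' hull (no bracketing data) are missing -- the "non-activated, diastole"
#' region of a clinical isochronal display.
#'
#' @param series An activation series.
#' @param geom An `electrode_grid`.
#' @param window `(t0, t1)` ms.
#' @param grid An `analysis_grid`; default 1 mm over `geom`.
#' @param method Interpolation method, see [interpolate_to_grid()].
#' @return An `isochrone_map` (subclass of `grid_field`) with `window`.
#' @export
build_isochrone_map <- function(series, geom, window, grid = NULL,
                                method = "linear") {
  if (is.null(grid)) grid <- analysis_grid(geom)
  first_act <- series |>
    dplyr::filter(.data$time_ms >= window[1], .data$time_ms < window[2]) |>
    dplyr::group_by(.data$channel_id) |>
    dplyr::summarise(time_ms = min(.data$time_ms), .groups = "drop")
  vals <- first_act$time_ms[match(geom$channel_id, first_act$channel_id)]
  if (sum(is.finite(vals)) < 3) {
    stop_fibmap("Fewer than 3 channels activated in the window.",
                "fibmap_insufficient_data")
  }
  fld <- interpolate_to_grid(vals, geom, grid, method = method)
  fld$window <- window
  class(fld) <- c("isochrone_map", class(fld))
  fld
}

#' Propagation-direction vector field from an isochronal map
#'
#' Direction of propagation is the unit gradient of activation time (the wave
#' moves toward later activation); speed is the inverse gradient magnitude,
#' in cm/s. Nodes where the gradient is undefined (missing neighbours, or
#' magnitude below `min_grad_ms_cm`) are dropped.
#'
#' @param map An `isochrone_map` (any `grid_field` of times works).
#' @param min_grad_ms_cm Gradient-magnitude tolerance (ms/cm) below which
#'   direction is considered undefined.
#' @return A `direction_field`: tibble `u_cm`, `v_cm`, `du`, `dv`,
#'   `speed_cm_s` with unit `(du, dv)`.
#' @export
propagation_field <- function(map, min_grad_ms_cm = 1e-6) {
  g <- map$grid
  T_ <- map$values
  if (sum(is.finite(T_)) < 4) {
    stop_fibmap("Map needs at least a 2x2 block of defined nodes.",
                "fibmap_insufficient_data")
  }
  gu <- central_diff(T_, g$du, along = 1L)
  gv <- central_diff(T_, g$dv, along = 2L)
  mag <- sqrt(gu^2 + gv^2)
  ok <- is.finite(mag) & mag > min_grad_ms_cm
  idx <- which(ok, arr.ind = TRUE)
  out <- tibble::tibble(
    u_cm = g$u[idx[, 1]],
    v_cm = g$v[idx[, 2]],
    du = (gu[ok] / mag[ok]),
    dv = (gv[ok] / mag[ok]),
    speed_cm_s = 1000 / mag[ok]
  )
  class(out) <- c("direction_field", class(out))
  attr(out, "grid") <- g
  out
}

# Central differences with missing-data masking; one-sided at edges of the
# defined region.
central_diff <- function(M, h, along = 1L) {
  if (along == 2L) return(t(central_diff(t(M), h, along = 1L)))
  n <- nrow(M)
  up <- M[c(2:n, n), , drop = FALSE]    # i+1 (clamped)
  dn <- M[c(1, 1:(n - 1)), , drop = FALSE]  # i-1 (clamped)
  two_h <- matrix(2 * h, n, ncol(M))
  two_h[1, ] <- h; two_h[n, ] <- h
  d <- (up - dn) / two_h
  # fall back to one-sided where a neighbour is missing
  fwd <- (up - M) / h
  bwd <- (M - dn) / h
  d[!is.finite(d) & is.finite(fwd)] <- fwd[!is.finite(d) & is.finite(fwd)]
  d[!is.finite(d) & is.finite(bwd)] <- bwd[!is.finite(d) & is.finite(bwd)]
  d
}

#' Conduction velocity of a plane-wave map
#'
#' Least-squares plane fit `T = a u + b v + c` to the defined activation
#' times; speed is `1/sqrt(a^2+b^2)` converted to cm/s. A poor plane fit
#' (RMS residual above `residual_tol_ms`) flags the map as not planar.
#'
#' @param map An `isochrone_map`.
#' @param residual_tol_ms Tolerance for the planarity check (ms).
#' @return One-row tibble `cv_cm_s`, `direction_u`, `direction_v`,
#'   `rms_residual_ms`, `planar`. A not-planar map raises a warning.
#' @export
estimate_cv_planewave <- function(map, residual_tol_ms = 10) {
  tb <- tidy.grid_field(map)
  fit <- lm(value ~ u_cm + v_cm, data = tb)
  ab <- coef(fit)[c("u_cm", "v_cm")]
  rms <- sqrt(mean(fit$residuals^2))
  planar <- rms <= residual_tol_ms
  if (!planar) warn("Activation map is not plane-wave-like; CV estimate unreliable.",
                    class = "fibmap_not_planar")
  mag <- sqrt(sum(ab^2))
  tibble::tibble(cv_cm_s = 1000 / mag,
                 direction_u = unname(ab[1] / mag),
                 direction_v = unname(ab[2] / mag),
                 rms_residual_ms = rms, planar = planar)
}

#' Cycle-to-cycle directionality recurrence
#'
#' Per grid node, the mean cosine of the angle between propagation directions
#' in consecutive cycles -- 1 where the wave always comes the same way, -1
#' where it alternates by 180 degrees, near 0 where direction is random.
#'
#' @param maps List of per-cycle `isochrone_map`s on a common grid (or a list
#'   of `direction_field`s).
#' @return A `grid_field` of recurrence scores in `[-1, 1]`; nodes with
#'   directions defined in fewer than 2 consecutive-cycle pairs are missing.
#' @export
direction_recurrence <- function(maps) {
  if (length(maps) < 2) {
    stop_fibmap("Need at least 2 cycles.", "fibmap_invalid_argument")
  }
  fields <- lapply(maps, function(m) {
    if (inherits(m, "direction_field")) m else propagation_field(m)
  })
  g <- attr(fields[[1]], "grid")
  to_mat <- function(f) {
    DU <- matrix(NA_real_, g$nu, g$nv); DV <- DU
    iu <- round((f$u_cm - g$origin[1]) / g$du) + 1L
    iv <- round((f$v_cm - g$origin[2]) / g$dv) + 1L
    DU[cbind(iu, iv)] <- f$du
    DV[cbind(iu, iv)] <- f$dv
    list(DU = DU, DV = DV)
  }
  mats <- lapply(fields, to_mat)
  acc <- matrix(0, g$nu, g$nv)
  cnt <- matrix(0L, g$nu, g$nv)
  for (i in seq_len(length(mats) - 1L)) {
    a <- mats[[i]]; b <- mats[[i + 1L]]
    cosang <- a$DU * b$DU + a$DV * b$DV
    ok <- is.finite(cosang)
    acc[ok] <- acc[ok] + cosang[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  score <- acc / cnt
  score[cnt < 1L] <- NA_real_
  new_grid_field(g, pmin(pmax(score, -1), 1), class = "recurrence_field")
}

#' Write an isochrone raster as CSV (`u_cm,v_cm,t_ms`)
#'
#' @param map An `isochrone_map`.
#' @param path File path.
#' @export
write_isochrone_map <- function(map, path) {
  tb <- tidy.grid_field(map)
  names(tb)[3] <- "t_ms"
  utils::write.csv(as.data.frame(tb), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
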