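#' Basket electrode geometry on the unwrapped atrial sheet
#'
#' Builds the channel-to-coordinate table for a multi-spline basket catheter
#' laid out on a flat, unwrapped atrial sheet. The default emulates a 64-pole
#' basket (8 splines of 8 electrodes) covering a 4 x 4 cm sheet, with
#' electrodes roughly 5 mm apart along each spline and 5 mm between splines,
#' plus a small seeded jitter so the layout is irregular the way a deployed
#' basket is. Channel ids follow the clinical convention of a spline letter
#' (A, B, C, ...) plus electrode number, distal to proximal.
#'
#' @param spline_count Number of splines (columns of electrodes).
#' @param electrodes_per_spline Electrodes along each spline.
#' @param sheet_extent Length-2 numeric, extent of the unwrapped sheet in cm
#'   (`c(u, v)`).
#' @param atrium `"LA"` or `"RA"`; label only, the sheet math is identical.
#' @param jitter_seed Integer seed for the placement jitter; the layout is
#'   bit-reproducible given the seed.
#' @param jitter_cm Half-width of the uniform placement jitter in cm. Set to 0
#'   for a perfectly regular grid.
#'
#' @return A tibble of class `electrode_grid` with columns `channel_id`,
#'   `atrium`, `spline`, `electrode`, `u_cm`, `v_cm`, and attributes
#'   `spline_count`, `electrodes_per_spline`, `sheet_extent`.
#' @examples
#' geom <- basket_geometry()
#' nrow(geom) # 64 channels
#' @export
basket_geometry <- function(spline_count = 8L, electrodes_per_spline = 8L,
                            sheet_extent = c(4, 4), atrium = c("LA", "RA"),
                            jitter_seed = 0L, jitter_cm = 0.04) {
  atrium <- match.arg(atrium)
  if (!is_scalar_number(spline_count) || spline_count < 1 ||
      !is_scalar_number(electrodes_per_spline) || electrodes_per_spline < 1) {
    stop_fibmap("`spline_count` and `electrodes_per_spline` must be positive integers.",
                "fibmap_invalid_argument")
  }
  if (length(sheet_extent) != 2L || any(!is.finite(sheet_extent)) || any(sheet_extent <= 0)) {
    stop_fibmap("`sheet_extent` must be two positive numbers (cm).",
                "fibmap_invalid_argument")
  }
  spline_count <- as.integer(spline_count)
  electrodes_per_spline <- as.integer(electrodes_per_spline)

  du <- sheet_extent[1] / spline_count
  dv <- sheet_extent[2] / electrodes_per_spline

  with_seed(jitter_seed, {
    # Splines share one transverse offset (a spline is one physical wire);
    # electrodes jitter independently along the spline. Degenerate axes (a
    # single spline or single electrode) sit exactly at the sheet centre.
    ju <- if (spline_count > 1) stats::runif(spline_count, -jitter_cm, jitter_cm) else 0
    u_spline <- (seq_len(spline_count) - 0.5) * du + ju
    jv <- if (electrodes_per_spline > 1) {
      matrix(stats::runif(spline_count * electrodes_per_spline, -jitter_cm, jitter_cm),
             nrow = spline_count)
    } else {
      matrix(0, nrow = spline_count, ncol = 1L)
    }
  })

  spline_idx <- rep(seq_len(spline_count), each = electrodes_per_spline)
  elec_idx <- rep(seq_len(electrodes_per_spline), times = spline_count)
  u <- u_spline[spline_idx]
  v <- (elec_idx - 0.5) * dv + jv[cbind(spline_idx, elec_idx)]

  spline_letter <- make_spline_letters(spline_count)
  geom <- tibble::tibble(
    channel_id = paste0(spline_letter[spline_idx], elec_idx),
    atrium = atrium,
    spline = spline_idx,
    electrode = elec_idx,
    u_cm = u,
    v_cm = v
  )
  new_electrode_grid(geom, spline_count, electrodes_per_spline, sheet_extent)
}

make_spline_letters <- function(n) {
  base <- LETTERS
  if (n <= 26L) return(base[seq_len(n)])
  extra <- as.vector(outer(base, base, paste0))
  c(base, extra)[seq_len(n)]
}

new_electrode_grid <- function(geom, spline_count, electrodes_per_spline, sheet_extent) {
  geom <- tibble::as_tibble(geom)
  attr(geom, "spline_count") <- spline_count
  attr(geom, "electrodes_per_spline") <- electrodes_per_spline
  attr(geom, "sheet_extent") <- sheet_extent
  class(geom) <- c("electrode_grid", class(geom))
  validate_electrode_grid(geom)
  geom
}

validate_electrode_grid <- function(geom) {
  stopifnot(all(c("channel_id", "u_cm", "v_cm") %in% names(geom)))
  if (anyDuplicated(geom$channel_id)) {
    stop_fibmap("Duplicate channel ids in electrode grid.", "fibmap_invalid_argument")
  }
  if (any(!is.finite(geom$u_cm)) || any(!is.finite(geom$v_cm))) {
    stop_fibmap("Electrode coordinates must be finite.", "fibmap_invalid_argument")
  }
  if (anyDuplicated(round(cbind(geom$u_cm, geom$v_cm), 9))) {
    stop_fibmap("Two channels share one position.", "fibmap_invalid_argument")
  }
  invisible(geom)
}

#' Write / read an electrode geometry CSV
#'
#' Plain CSV with header `channel_id,atrium,spline,electrode,u_cm,v_cm`.
#'
#' @param geom An `electrode_grid`.
#' @param path File path.
#' @return `read_geometry()` returns an `electrode_grid` tibble.
#' @export
write_geometry <- function(geom, path) {
  utils::write.csv(
    as.data.frame(geom[, c("channel_id", "atrium", "spline", "electrode", "u_cm", "v_cm")]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel_id", "atrium", "spline", "electrode", "u_cm", "v_cm")
  if (!all(need %in% names(df))) {
    stop_fibmap("Geometry CSV must have columns channel_id,atrium,spline,electrode,u_cm,v_cm.",
                "fibmap_invalid_argument")
  }
  sc <- length(unique(df$spline))
  ep <- max(df$electrode)
  ext <- c(max(df$u_cm) + min(df$u_cm), max(df$v_cm) + min(df$v_cm))
  new_electrode_grid(df[need], sc, ep, ext)
}

#' Regular analysis grid covering an electrode array
#'
#' The raster on which interpolated activation-time and phase fields live.
#' Spacing defaults to 1 mm, well below the 4-10 mm electrode pitch.
#'
#' @param geom An `electrode_grid` (or any table with `u_cm`, `v_cm`).
#' @param spacing_cm Node spacing in cm (same in u and v).
#' @param margin_cm Extra margin beyond the electrode bounding box.
#' @return An object of class `analysis_grid`: list with `u`, `v` node
#'   coordinate vectors, `du`, `dv`, `nu`, `nv`, `origin`.
#' @export
analysis_grid <- function(geom, spacing_cm = 0.1, margin_cm = 0) {
  if (!is_scalar_number(spacing_cm) || spacing_cm <= 0) {
    stop_fibmap("`spacing_cm` must be a positive number.", "fibmap_invalid_argument")
  }
  u0 <- min(geom$u_cm) - margin_cm
  v0 <- min(geom$v_cm) - margin_cm
  nu <- max(2L, ceiling((max(geom$u_cm) + margin_cm - u0) / spacing_cm) + 1L)
  nv <- max(2L, ceiling((max(geom$v_cm) + margin_cm - v0) / spacing_cm) + 1L)
  structure(
    list(origin = c(u0, v0), du = spacing_cm, dv = spacing_cm,
         nu = nu, nv = nv,
         u = u0 + (seq_len(nu) - 1L) * spacing_cm,
         v = v0 + (seq_len(nv) - 1L) * spacing_cm),
    class = "analysis_grid")
}

#' @export
print.analysis_grid <- function(x, ...) {
  cat(sprintf("<analysis_grid> %d x %d nodes, %.3g cm spacing, origin (%.3g, %.3g) cm\n",
              x$nu, x$nv, x$du, x$origin[1], x$origin[2]))
  invisible(x)
}

# Convex hull of the electrodes as a closed polygon matrix (u, v).
electrode_hull <- function(geom) {
  pts <- cbind(geom$u_cm, geom$v_cm)
  idx <- grDevices::chull(pts)
  pts[c(idx, idx[1]), , drop = FALSE]
}

# Vectorized point-in-convex-polygon (polygon closed, CCW or CW).
points_in_hull <- function(u, v, hull, tol = 1e-9) {
  n <- nrow(hull) - 1L
  inside <- rep(TRUE, length(u))
  # consistent orientation sign
  area2 <- sum(hull[seq_len(n), 1] * hull[seq_len(n) + 1L, 2] -
               hull[seq_len(n) + 1L, 1] * hull[seq_len(n), 2])
  s <- sign(area2)
  if (s == 0) return(rep(FALSE, length(u)))
  for (i in seq_len(n)) {
    ex <- hull[i + 1L, 1] - hull[i, 1]
    ey <- hull[i + 1L, 2] - hull[i, 2]
    cr <- ex * (v - hull[i, 2]) - ey * (u - hull[i, 1])
    inside <- inside & (s * cr >= -tol)
  }
  inside
}

#' Interpolate per-channel values onto the analysis grid
#'
#' Scattered-to-raster interpolation from electrode positions to a regular
#' grid. The default is piecewise-linear (barycentric on a Delaunay
#' triangulation); `"nearest"` is offered for robustness checks. Nodes outside
#' the electrode convex hull are missing (`NA`), mirroring the non-activated /
#' uncovered region of a clinical map.
#'
#' @param values Numeric vector, one value per channel, in `geom` row order
#'   (NA allowed; those channels are dropped before interpolation).
#' @param geom An `electrode_grid`.
#' @param grid An `analysis_grid`.
#' @param method `"linear"` or `"nearest"`.
#' @return A `grid_field`: list with `grid` and `values` (`nu x nv` matrix,
#'   u indexing rows).
#' @export
interpolate_to_grid <- function(values, geom, grid, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (length(values) != nrow(geom)) {
    stop_fibmap("Need exactly one value per channel.", "fibmap_invalid_argument")
  }
  ok <- is.finite(values)
  u <- geom$u_cm[ok]; v <- geom$v_cm[ok]; z <- values[ok]
  if (sum(ok) < 3L) {
    stop_fibmap("Need at least 3 channels with finite values.", "fibmap_insufficient_data")
  }
  if (collinear_points(u, v)) {
    stop_fibmap("Electrode positions are collinear; planar interpolation is degenerate.",
                "fibmap_degenerate_geometry")
  }
  if (method == "linear") {
    res <- interp::interp(x = u, y = v, z = z, xo = grid$u, yo = grid$v,
                          method = "linear", output = "grid")
    vals <- res$z
  } else {
    gu <- rep(grid$u, times = grid$nv)
    gv <- rep(grid$v, each = grid$nu)
    d2 <- outer(gu, u, `-`)^2 + outer(gv, v, `-`)^2
    vals <- matrix(z[max.col(-d2, ties.method = "first")], grid$nu, grid$nv)
    hull <- electrode_hull(geom[ok, , drop = FALSE])
    vals[!points_in_hull(gu, gv, hull)] <- NA_real_
  }
  new_grid_field(grid, vals)
}

collinear_points <- function(u, v) {
  uc <- u - mean(u); vc <- v - mean(v)
  m <- cbind(uc, vc)
  sv <- svd(m, nu = 0, nv = 0)$d
  sv[2] < 1e-9 * max(sv[1], 1e-12)
}

new_grid_field <- function(grid, values, class = character()) {
  structure(list(grid = grid, values = values), class = c(class, "grid_field"))
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<%s> %d x %d nodes, %d defined\n", class(x)[1],
              x$grid$nu, x$grid$nv, sum(is.finite(x$values))))
  invisible(x)
}

#' Tidy a raster field into a long tibble
#'
#' @param x A `grid_field` (or subclass such as `isochrone_map`).
#' @param ... Unused.
#' @return Tibble with `u_cm`, `v_cm`, `value` (defined nodes only).
#' @export
tidy.grid_field <- function(x, ...) {
  g <- x$grid
  tb <- tibble::tibble(
    u_cm = rep(g$u, times = g$nv),
    v_cm = rep(g$v, each = g$nu),
    value = as.vector(x$values)
  )
  tb[is.finite(tb$value), ]
}

#' @export
as_tibble.grid_field <- function(x, ...) tidy.grid_field(x, ...)
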