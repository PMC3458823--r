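#' @importFrom ggplot2 ggplot aes geom_raster geom_point geom_path geom_line
#'   geom_segment scale_fill_viridis_c coord_equal labs facet_wrap autoplot
NULL

#' Plot a raster field (isochrone, phase frame, recurrence score)
#'
#' @param object A `grid_field` / `isochrone_map` / `recurrence_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grid_field <- function(object, ...) {
  tb <- tidy.grid_field(object)
  lab <- switch(class(object)[1],
                isochrone_map = "activation time (ms)",
                recurrence_field = "direction recurrence",
                "value")
  ggplot(tb, aes(x = .data$u_cm, y = .data$v_cm, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = lab) +
    coord_equal() +
    labs(x = "u (cm)", y = "v (cm)")
}

#' Plot stacked electrogram traces
#'
#' @param object An `egm_recording`.
#' @param channels Channel ids to show (default first 8).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.egm_recording <- function(object, channels = NULL, ...) {
  if (is.null(channels)) channels <- utils::head(object$channel_ids, 8)
  tb <- as_tibble.egm_recording(object)
  tb <- tb[tb$channel_id %in% channels, ]
  ggplot(tb, aes(x = .data$t_ms, y = .data$v_mv)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel_id, ncol = 1, strip.position = "left") +
    labs(x = "time (ms)", y = "voltage (mV)")
}

#' Plot one frame of a phase map with its singularities
#'
#' @param object A `phase_map`.
#' @param t_ms Frame time (default first frame).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phase_map <- function(object, t_ms = NULL, ...) {
  s <- if (is.null(t_ms)) 1L else which.min(abs(object$t_ms - t_ms))
  g <- object$grid
  tb <- tibble::tibble(u_cm = rep(g$u, times = g$nv),
                       v_cm = rep(g$v, each = g$nu),
                       phase = as.vector(object$phi[, , s]))
  tb <- tb[is.finite(tb$phase), ]
  ev <- detect_phase_singularities(object, t_ms = object$t_ms[s])
  p <- ggplot(tb, aes(x = .data$u_cm, y = .data$v_cm, fill = .data$phase)) +
    geom_raster() +
    scale_fill_viridis_c(name = "phase (rad)", limits = c(-pi, pi)) +
    coord_equal() +
    labs(x = "u (cm)", y = "v (cm)",
         title = sprintf("t = %.0f ms", object$t_ms[s]))
  if (nrow(ev)) {
    p <- p + geom_point(data = ev, aes(x = .data$u_cm, y = .data$v_cm),
                        inherit.aes = FALSE, colour = "white", size = 3, shape = 21,
                        fill = "black")
  }
  p
}

#' Plot source tracks with their smoothed migration loci
#'
#' @param object A `source_track_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.source_track_set <- function(object, ...) {
  if (!length(object)) {
    return(ggplot() + labs(x = "u (cm)", y = "v (cm)"))
  }
  pts <- dplyr::bind_rows(lapply(seq_along(object), function(i) {
    dplyr::mutate(object[[i]]$samples, track = factor(i),
                  kind = object[[i]]$kind)
  }))
  curves <- dplyr::bind_rows(lapply(seq_along(object), function(i) {
    tr <- object[[i]]
    if (nrow(unique(tr$samples[, c("u_cm", "v_cm")])) < 3) return(NULL)
    xy <- evaluate_locus(smooth_locus(tr))
    tibble::tibble(u_cm = xy[, 1], v_cm = xy[, 2], track = factor(i))
  }))
  p <- ggplot(pts, aes(x = .data$u_cm, y = .data$v_cm, colour = .data$track)) +
    geom_point(aes(shape = .data$kind), size = 2) +
    coord_equal() +
    labs(x = "u (cm)", y = "v (cm)")
  if (nrow(curves)) p <- p + geom_path(data = curves)
  p
}

#' Plot a propagation-direction field
#'
#' @param object A `direction_field`.
#' @param stride Show every `stride`-th node.
#' @param scale_cm Arrow length in cm.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.direction_field <- function(object, stride = 4L, scale_cm = 0.25, ...) {
  tb <- object[seq(1, nrow(object), by = stride), ]
  ggplot(tb, aes(x = .data$u_cm, y = .data$v_cm)) +
    geom_segment(aes(xend = .data$u_cm + scale_cm * .data$du,
                     yend = .data$v_cm + scale_cm * .data$dv,
                     colour = .data$speed_cm_s),
                 arrow = grid::arrow(length = grid::unit(0.1, "cm"))) +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "u (cm)", y = "v (cm)", colour = "CV (cm/s)")
}
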