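# Shared simulated fixtures, built once per test run and memoised.
# Episode parameters mirror the package defaults (2 s episodes, 64-pole
# basket on a 4 x 4 cm sheet); noiseless recordings unless a test adds noise.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

fx_spiral <- function() {
  fixture("spiral", function() {
    simulate_episode("spiral", duration_ms = 2000, noise_sd_mv = 0, seed = 101)
  })
}

fx_focal <- function() {
  fixture("focal", function() {
    simulate_episode("focal", duration_ms = 2000, noise_sd_mv = 0, seed = 102)
  })
}

fx_plane <- function() {
  fixture("plane", function() {
    simulate_episode("planewave", duration_ms = 1500, noise_sd_mv = 0, seed = 103)
  })
}

fx_spiral_meander <- function() {
  fixture("spiral_meander", function() {
    simulate_episode("spiral", duration_ms = 2000, noise_sd_mv = 0, seed = 104,
                     meander_level = 0.2)
  })
}

fx_report <- function(kind) {
  fixture(paste0("report_", kind), function() {
    ep <- switch(kind, spiral = fx_spiral(), focal = fx_focal(), plane = fx_plane())
    analyze_episode(ep, list(kind = ep$truth$kind))
  })
}

# Band-limited random phase screen: phase of a complex sum of a few random
# plane waves, guaranteed smooth at the node scale; contains vortices at the
# common zeros of the real and imaginary parts.
random_phase_screen <- function(n = 24, n_waves = 6, kmax = 2.5) {
  re <- matrix(0, n, n); im <- matrix(0, n, n)
  x <- seq(0, 1, length.out = n)
  for (w in seq_len(n_waves)) {
    kx <- stats::runif(1, -kmax, kmax) * 2 * pi
    ky <- stats::runif(1, -kmax, kmax) * 2 * pi
    ph <- stats::runif(2, 0, 2 * pi)
    amp <- stats::rexp(2)
    re <- re + amp[1] * cos(outer(kx * x, ky * x, `+`) + ph[1])
    im <- im + amp[2] * cos(outer(kx * x, ky * x, `+`) + ph[2])
  }
  atan2(im, re)
}

# Minimal analysis grid for synthetic screens (1 mm spacing).
screen_grid <- function(n = 24, spacing = 0.1) {
  geom <- tibble::tibble(u_cm = c(0, (n - 1) * spacing), v_cm = c(0, (n - 1) * spacing))
  g <- analysis_grid(geom, spacing_cm = spacing)
  stopifnot(g$nu >= n, g$nv >= n)
  g$nu <- n; g$nv <- n
  g$u <- g$u[seq_len(n)]; g$v <- g$v[seq_len(n)]
  g
}
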