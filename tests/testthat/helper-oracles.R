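# Independent oracles and shared fixtures for the test suite.

# Explicit fine-grid brute-force solver for the two-layer static-gel
# problem (forward Euler, harmonic-mean face diffusivities).  Kept fully
# independent of the package's implicit solver.
static_gel_explicit_oracle <- function(C0, D_gel, D_media, gel_mL, media_mL,
                                       well_d_mm, out_times_h, n_cells = 200) {
  A_m2 <- pi * (well_d_mm / 2)^2 * 1e-6
  h_gel <- gel_mL * 1e-6 / A_m2
  h_med <- media_mL * 1e-6 / A_m2
  L <- h_gel + h_med
  dz <- L / n_cells
  ng <- round(h_gel / L * n_cells)
  in_gel <- seq_len(n_cells) <= ng
  D <- ifelse(in_gel, D_gel, D_media)
  Dface <- 2 * D[-n_cells] * D[-1] / (D[-n_cells] + D[-1])
  dt <- 0.4 * dz^2 / max(D)
  nstep_out <- round(out_times_h * 3600 / dt)
  cv <- ifelse(in_gel, 0, C0)
  gel_means <- numeric(length(out_times_h))
  step <- 0L
  for (k in seq_along(out_times_h)) {
    while (step < nstep_out[k]) {
      flux <- Dface * diff(cv) / dz
      cv <- cv + dt / dz * (c(flux, 0) - c(0, flux))
      step <- step + 1L
    }
    gel_means[k] <- mean(cv[in_gel])
  }
  gel_means
}

# Dense log-grid search oracle for the constrained 4PL fit: grid over
# log(IC50) with the hill slope profiled out by a 1-D line search at each
# grid point, then two zoom stages around the minimum.
grid_search_4pl <- function(x, y, eff_lo, eff_hi) {
  profile_ssr <- function(le) {
    stats::optimize(function(lh) {
      p <- organodose:::pred_constrained(x, exp(le), exp(lh),
                                         eff_lo, eff_hi)
      sum((y - p)^2)
    }, interval = log(c(0.05, 20)), tol = 1e-9)$objective
  }
  scan <- function(le_grid) {
    s <- vapply(le_grid, profile_ssr, numeric(1))
    k <- which.min(s)
    c(le_grid[k], s[k], le_grid[max(1, k - 1)], le_grid[min(length(s), k + 1)])
  }
  xpos <- x[x > 0]
  b <- scan(seq(log(min(xpos)) - 3, log(max(xpos)) + 3, length.out = 250))
  b <- scan(seq(b[3], b[4], length.out = 80))
  b <- scan(seq(b[3], b[4], length.out = 60))
  le <- b[1]
  lh <- stats::optimize(function(lh) {
    p <- organodose:::pred_constrained(x, exp(le), exp(lh), eff_lo, eff_hi)
    sum((y - p)^2)
  }, interval = log(c(0.05, 20)), tol = 1e-9)$minimum
  list(ic50 = exp(le), hill = exp(lh), ssr = b[2])
}

# Analytic chord-area fraction of the circular well footprint within a
# lateral half-width `cut` of a central diameter, lumen excluded.
chord_region1_fraction <- function(well_d, cut, lumen_d) {
  R <- well_d / 2; u <- cut / R
  f <- (2 / pi) * (asin(u) + u * sqrt(1 - u^2))
  A <- pi * R^2; Al <- pi * (lumen_d / 2)^2
  (f * A - Al) / (A - Al)
}

# Shared expensive simulation results, computed once per test run.
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

default_bioreactor_run <- function() cached("bio_default",
  simulate_bioreactor(C0 = 1, duration = 168,
                      snapshot_times = c(24, 84, 168)))

default_static_run <- function() cached("static_default",
  simulate_static_gel(C0 = 2, duration = 168))

# small pipeline configuration: coarser grids, identical physics
fast_pipeline_config <- function() list(
  simulation = list(dx_mm = 0.4, dx_1d_mm = 0.1, dt_s = 300,
                    output_every_h = 0.5))
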