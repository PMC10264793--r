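#' Simulate drug exposure for organoids cultured directly in media
#'
#' In the media platform the drug is neither consumed nor added over the
#' treatment window, so the concentration seen by the organoids is constant
#' at the applied concentration for the whole duration.
#'
#' @param C0 applied concentration, uM.
#' @param duration duration in h.
#' @param sample_times optional vector of output times (h, strictly
#'   increasing, starting at 0); default is a 0.5 h cadence.
#' @return a `simulation_result` with a single region `"media"`.
#' @export
simulate_media <- function(C0, duration = 168, sample_times = NULL) {
  if (!is.numeric(C0) || length(C0) != 1 || !is.finite(C0) || C0 < 0)
    stop("C0 must be a single nonnegative concentration (uM)")
  times <- sample_times %||% seq(0, duration, by = 0.5)
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop("sample_times must be strictly increasing and start at 0")
  spec <- platform_spec("media")
  rm <- matrix(C0, length(times), 1, dimnames = list(NULL, "media"))
  vol <- spec$media_volume %||% NA_real_
  new_simulation_result(
    platform = "media", C0 = C0, times = times, region_means = rm,
    equilibrium_uM = C0, mass_nmol = rep(C0 * vol, length(times)),
    spec = spec, params = list())
}

#' Simulate static-gel drug transport (two-layer diffusion)
#'
#' One-dimensional two-layer model of the static hydrogel platform: a media
#' slab (initially at the applied concentration `C0`) over a gel slab
#' (initially drug free), no-flux at the top and bottom, concentration and
#' flux continuity at the interface, free-media diffusivity in the overlay
#' and the effective gel diffusivity below.  The closed system relaxes to the
#' mass-balance equilibrium `C0 * V_media / (V_media + V_gel)` -- with the
#' equal 1 mL volumes of the packaged preset, exactly 50% of the source
#' concentration.
#'
#' @param spec a `static_gel` [platform_spec()].
#' @param C0 applied media concentration, uM.
#' @param duration duration in h (default: the spec's duration).
#' @param D_gel optional override of the effective gel diffusivity (m^2/s),
#'   used by [calibrate_effective_diffusivity()].
#' @param dx_mm,dt_s,out_every_h numerical controls (defaults from the
#'   packaged `simulation` settings: 0.05 mm, 60 s, 0.5 h).
#' @return a `simulation_result` with regions `"gel"`, `"media"`, `"total"`.
#' @examples
#' \donttest{
#' res <- simulate_static_gel(C0 = 2, duration = 48)
#' time_to_steady_state(res, "gel")  # ~24 h with the packaged D_gel
#' }
#' @export
simulate_static_gel <- function(spec = platform_spec("static_gel"), C0,
                                duration = NULL, D_gel = NULL,
                                dx_mm = NULL, dt_s = NULL, out_every_h = NULL) {
  stopifnot(inherits(spec, "platform_spec"))
  if (spec$kind != "static_gel") stop("spec$kind must be 'static_gel'")
  if (!is.numeric(C0) || C0 < 0) stop("C0 must be nonnegative (uM)")
  sim <- platform_defaults()$simulation
  dx_mm <- dx_mm %||% sim$dx_1d_mm
  dt_s <- dt_s %||% sim$dt_s
  out_every_h <- out_every_h %||% sim$output_every_h
  duration <- duration %||% spec$duration
  D_gel <- D_gel %||% spec$D_gel

  geo <- derive_geometry(spec)
  A_m2 <- geo$well_area * MM2_TO_M2
  ng <- max(2L, round(geo$gel_height / dx_mm))
  nm <- max(2L, round(geo$media_height / dx_mm))
  dzg <- geo$gel_height / ng * MM_TO_M
  dzm <- geo$media_height / nm * MM_TO_M
  n <- ng + nm
  in_gel <- c(rep(TRUE, ng), rep(FALSE, nm))     # cell 1 = well floor
  dz <- ifelse(in_gel, dzg, dzm)
  D <- ifelse(in_gel, D_gel, spec$D_media)
  V <- dz * A_m2
  # series half-cell resistances give flux continuity at the interface
  G <- A_m2 / ((dz[-n] / 2) / D[-n] + (dz[-1] / 2) / D[-1])
  sys <- list(V_m3 = V, ii = seq_len(n - 1), jj = seq_len(n - 1) + 1L, gg = G)
  V_mL <- V / ML_TO_M3
  regions <- list(
    gel = list(idx = which(in_gel), w = V_mL[in_gel]),
    media = list(idx = which(!in_gel), w = V_mL[!in_gel]),
    total = list(idx = seq_len(n), w = V_mL))
  run <- fv_run(sys, c0 = ifelse(in_gel, 0, C0), duration_h = duration,
                dt_s = dt_s, out_every_h = out_every_h, regions = regions)
  eq <- C0 * spec$media_volume / (spec$media_volume + spec$gel_volume)
  new_simulation_result(
    platform = "static_gel", C0 = C0, times = run$times,
    region_means = run$region_means, equilibrium_uM = eq,
    mass_nmol = run$mass_nmol, spec = spec, geometry = geo,
    params = list(dx_mm = dx_mm, dt_s = dt_s, out_every_h = out_every_h,
                  D_gel = D_gel))
}

#' Simulate bioreactor drug transport (reservoir-coupled diffusion)
#'
#' Diffusion of the drug from a perfused channel into the surrounding
#' hydrogel of the multi-well bioreactor.  The channel lumen is treated as
#' well mixed at the instantaneous reservoir concentration (the lumen
#' residence time at 22 uL/min is ~4 min, far below the multi-day gel
#' diffusion scale), so it imposes a Dirichlet boundary; the recirculating
#' reservoir obeys `V_res dC_res/dt = -J(t)` with `J` the total diffusive
#' flux across the lumen wall.  Outer walls and the gel surface are no-flux,
#' gel initially drug free, reservoir at `C0`.  Advection in the gel is
#' neglected (interstitial Peclet number << 1; see [peclet_number()]).
#'
#' The default `"2d_cross_section"` mode solves the plane perpendicular to
#' the channel axis; each grid column is extruded along the axis by the chord
#' length of the circular well footprint at that lateral position (rescaled
#' so the gel cells sum to the gel volume), which preserves both the region
#' volume split of the circular footprint and exact mass balance.  `"3d"`
#' runs a coarse three-dimensional discretization of the cylindrical well for
#' consistency checks.
#'
#' @param spec a `bioreactor` [platform_spec()].
#' @param C0 applied (reservoir) concentration, uM.
#' @param duration duration in h.
#' @param mode `"2d_cross_section"` (default) or `"3d"`.
#' @param dx_mm,dt_s,out_every_h numerical controls; defaults 0.2 mm / 60 s /
#'   0.5 h in 2-D and 0.65 mm / 300 s / 0.5 h in 3-D.
#' @param snapshot_times optional times (h) at which to keep the full
#'   concentration field.
#' @return a `simulation_result` with regions `"region1"` (gel within the
#'   region cut distance of the channel axis), `"region2"` (the rest),
#'   `"total"` and `"reservoir"`.
#' @export
simulate_bioreactor <- function(spec = platform_spec("bioreactor"), C0,
                                duration = NULL,
                                mode = c("2d_cross_section", "3d"),
                                dx_mm = NULL, dt_s = NULL, out_every_h = NULL,
                                snapshot_times = NULL) {
  stopifnot(inherits(spec, "platform_spec"))
  if (spec$kind != "bioreactor") stop("spec$kind must be 'bioreactor'")
  if (!is.numeric(C0) || C0 < 0) stop("C0 must be nonnegative (uM)")
  mode <- match.arg(mode)
  sim <- platform_defaults()$simulation
  dx_mm <- dx_mm %||% if (mode == "3d") sim$dx_3d_mm else sim$dx_mm
  dt_s <- dt_s %||% if (mode == "3d") sim$dt_3d_s else sim$dt_s
  out_every_h <- out_every_h %||% sim$output_every_h
  duration <- duration %||% spec$duration

  grid <- bioreactor_grid(spec, dx_mm = dx_mm, mode = mode)
  sysr <- bioreactor_system(spec, grid)
  masks <- region_masks(grid, spec)
  gel_idx <- sysr$gel_index            # cell index within state vector
  w <- grid$vol_mL[sysr$gel_cells]     # per-gel-cell volume, mL
  in1 <- masks$region1[sysr$gel_cells]
  nres <- length(sysr$sys$V_m3)
  regions <- list(
    region1 = list(idx = gel_idx[in1], w = w[in1]),
    region2 = list(idx = gel_idx[!in1], w = w[!in1]),
    total = list(idx = gel_idx, w = w),
    reservoir = list(idx = nres, w = 1))
  c0 <- c(rep(0, nres - 1L), C0)
  run <- fv_run(sysr$sys, c0 = c0, duration_h = duration, dt_s = dt_s,
                out_every_h = out_every_h, regions = regions,
                snapshot_times = snapshot_times)
  eq <- C0 * spec$media_volume / (spec$media_volume + spec$gel_volume)
  snaps <- lapply(run$snapshots, function(s)
    concentration_field(grid, gel_values = s$state[gel_idx],
                        lumen_value = s$state[nres], time_h = s$time_h))
  new_simulation_result(
    platform = "bioreactor", C0 = C0, times = run$times,
    region_means = run$region_means, equilibrium_uM = eq,
    mass_nmol = run$mass_nmol, spec = spec,
    geometry = derive_geometry(spec), grid = grid, snapshots = snaps,
    params = list(mode = mode, dx_mm = dx_mm, dt_s = dt_s,
                  out_every_h = out_every_h, D_gel = spec$D_gel))
}

#' Build the labeled simulation grid for the bioreactor
#'
#' Uniform rectangular grid over the gel cross-section (2-D mode: lateral x
#' by vertical y; 3-D mode adds the channel-axis direction z).  Cells are
#' labeled `gel`, `lumen` (inside the channel) or, in 3-D, `outside` (outside
#' the circular well footprint).  Per-cell volumes in mL include the 2-D
#' chord-length extrusion and are rescaled so the gel cells sum exactly to
#' the spec's gel volume.
#'
#' @param spec a `bioreactor` [platform_spec()].
#' @param dx_mm grid spacing, mm.
#' @param mode `"2d_cross_section"` or `"3d"`.
#' @return an object of class `transport_grid`.
#' @export
bioreactor_grid <- function(spec, dx_mm = 0.2, mode = "2d_cross_section") {
  geo <- derive_geometry(spec)
  Wd <- spec$well_diameter; Hg <- geo$gel_height
  nx <- max(4L, round(Wd / dx_mm)); ny <- max(4L, round(Hg / dx_mm))
  dx <- Wd / nx; dy <- Hg / ny
  xs <- (seq_len(nx) - 0.5) * dx; ys <- (seq_len(ny) - 0.5) * dy
  xc <- Wd / 2; yc <- geo$channel_axis_height
  rl <- spec$channel_diameter / 2; R <- Wd / 2
  if (mode == "2d_cross_section") {
    X <- matrix(xs, nx, ny); Y <- matrix(ys, nx, ny, byrow = TRUE)
    lumen <- (X - xc)^2 + (Y - yc)^2 <= rl^2
    if (!any(lumen)) stop("grid too coarse to resolve the channel lumen")
    labels <- matrix("gel", nx, ny); labels[lumen] <- "lumen"
    chord <- 2 * sqrt(pmax(0, R^2 - (xs - xc)^2))  # axis extrusion, mm
    vol_raw <- dx * dy * matrix(chord, nx, ny)     # mm^3
    s <- spec$gel_volume * 1e3 / sum(vol_raw[!lumen])
    vol_mL <- vol_raw * s * MM3_TO_ML
    g <- list(mode = mode, dx = dx, dy = dy, x = xs, y = ys,
              labels = labels, vol_mL = vol_mL,
              extrusion_mm = chord * s, extrusion_scale = s,
              lat_mm = abs(X - xc), xc = xc, yc = yc,
              channel_radius = rl, well_radius = R)
  } else {
    nz <- nx; dz <- dx; zs <- xs
    lab <- array("gel", c(nx, ny, nz))
    foot_out <- outer((xs - xc)^2, (zs - xc)^2, "+") > R^2   # x-z footprint
    lum_xy <- outer((xs - xc)^2, (ys - yc)^2, "+") <= rl^2   # x-y circle
    for (j in seq_len(ny)) { sl <- lab[, j, ]
      sl[foot_out] <- "outside"; lab[, j, ] <- sl }
    for (k in seq_len(nz)) { sl <- lab[, , k]
      sl[lum_xy & sl == "gel"] <- "lumen"; lab[, , k] <- sl }
    if (!any(lab == "lumen")) stop("grid too coarse to resolve the channel lumen")
    vol_raw <- array(dx * dy * dz, c(nx, ny, nz))
    vol_raw[lab != "gel"] <- 0
    s <- spec$gel_volume * 1e3 / sum(vol_raw)
    vol_mL <- vol_raw * s * MM3_TO_ML
    g <- list(mode = mode, dx = dx, dy = dy, dz = dz, x = xs, y = ys, z = zs,
              labels = lab, vol_mL = vol_mL, vol_scale = s,
              lat_mm = array(rep(abs(xs - xc), ny * nz), c(nx, ny, nz)),
              xc = xc, yc = yc, channel_radius = rl, well_radius = R)
  }
  structure(g, class = "transport_grid")
}

# Assemble the finite-volume system (cells + reservoir node) for a grid.
# Face conductances use the half-cell series formula; faces adjacent to the
# lumen see only the gel-side half cell (Dirichlet wall at the face).
bioreactor_system <- function(spec, grid) {
  D <- spec$D_gel
  if (grid$mode == "2d_cross_section") {
    nx <- length(grid$x); ny <- length(grid$y)
    gel <- grid$labels == "gel"
    idx <- matrix(0L, nx, ny); idx[gel] <- seq_len(sum(gel))
    nres <- sum(gel) + 1L
    s <- grid$extrusion_scale; R <- grid$well_radius; xc <- grid$xc
    dx_m <- grid$dx * MM_TO_M; dy_m <- grid$dy * MM_TO_M
    ii <- jj <- integer(0); gg <- numeric(0)
    # x-direction faces: area = dy * extrusion at the face
    xf <- grid$x[-nx] + grid$dx / 2
    Lf <- 2 * sqrt(pmax(0, R^2 - (xf - xc)^2)) * s        # mm
    a <- which(gel[-nx, , drop = FALSE] & gel[-1, , drop = FALSE],
               arr.ind = TRUE)
    if (nrow(a)) {
      G <- D * (dy_m * Lf[a[, 1]] * MM_TO_M) / dx_m
      ii <- c(ii, idx[a]); jj <- c(jj, idx[cbind(a[, 1] + 1L, a[, 2])])
      gg <- c(gg, G)
    }
    lum <- grid$labels == "lumen"
    for (shift in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      # gel cell whose neighbor in `shift` direction is lumen
      nb <- shift_mask(lum, shift)
      cand <- which(gel & nb, arr.ind = TRUE)
      if (!nrow(cand)) next
      if (shift[1] != 0) {
        xface <- grid$x[cand[, 1]] + shift[1] * grid$dx / 2
        Lface <- 2 * sqrt(pmax(0, R^2 - (xface - xc)^2)) * s
        G <- 2 * D * (dy_m * Lface * MM_TO_M) / dx_m
      } else {
        Lcol <- 2 * sqrt(pmax(0, R^2 - (grid$x[cand[, 1]] - xc)^2)) * s
        G <- 2 * D * (dx_m * Lcol * MM_TO_M) / dy_m
      }
      ii <- c(ii, idx[cand]); jj <- c(jj, rep(nres, nrow(cand)))
      gg <- c(gg, G)
    }
    b <- which(gel[, -ny, drop = FALSE] & gel[, -1, drop = FALSE],
               arr.ind = TRUE)
    if (nrow(b)) {
      Lcol <- 2 * sqrt(pmax(0, R^2 - (grid$x[b[, 1]] - xc)^2)) * s
      G <- D * (dx_m * Lcol * MM_TO_M) / dy_m
      ii <- c(ii, idx[b]); jj <- c(jj, idx[cbind(b[, 1], b[, 2] + 1L)])
      gg <- c(gg, G)
    }
    V <- c(grid$vol_mL[gel] * ML_TO_M3, spec$media_volume * ML_TO_M3)
    list(sys = list(V_m3 = V, ii = ii, jj = jj, gg = gg),
         gel_cells = which(gel), gel_index = seq_len(sum(gel)),
         reservoir_index = nres)
  } else {
    lab <- grid$labels
    gel <- lab == "gel"; lum <- lab == "lumen"
    dims <- dim(lab)
    idx <- array(0L, dims); idx[gel] <- seq_len(sum(gel))
    nres <- sum(gel) + 1L
    d_m <- c(grid$dx, grid$dy, grid$dz) * MM_TO_M
    areas <- c(d_m[2] * d_m[3], d_m[1] * d_m[3], d_m[1] * d_m[2])
    ii <- jj <- integer(0); gg <- numeric(0)
    for (ax in 1:3) {
      n_ax <- dims[ax]
      lo <- slice_drop(gel, ax, 1L, n_ax - 1L)
      hi <- slice_drop(gel, ax, 2L, n_ax)
      a <- which(lo & hi, arr.ind = TRUE)
      if (nrow(a)) {
        a2 <- a; a2[, ax] <- a2[, ax] + 1L
        G <- rep(D * areas[ax] / d_m[ax], nrow(a))
        ii <- c(ii, idx[a]); jj <- c(jj, idx[a2]); gg <- c(gg, G)
      }
      for (dd in c(1L, -1L)) {
        cand <- which(gel & arr_shift(lum, ax, dd), arr.ind = TRUE)
        if (!nrow(cand)) next
        G <- rep(2 * D * areas[ax] / d_m[ax], nrow(cand))
        ii <- c(ii, idx[cand]); jj <- c(jj, rep(nres, nrow(cand)))
        gg <- c(gg, G)
      }
    }
    V <- c(grid$vol_mL[gel] * ML_TO_M3, spec$media_volume * ML_TO_M3)
    list(sys = list(V_m3 = V, ii = ii, jj = jj, gg = gg),
         gel_cells = which(gel), gel_index = seq_len(sum(gel)),
         reservoir_index = nres)
  }
}

# logical mask shifted so that TRUE marks cells whose neighbor at +shift is
# TRUE in `m` (2-D matrices)
shift_mask <- function(m, shift) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(FALSE, nx, ny)
  xi <- seq_len(nx) + shift[1]; yi <- seq_len(ny) + shift[2]
  okx <- xi >= 1 & xi <= nx; oky <- yi >= 1 & yi <= ny
  out[okx, oky] <- m[xi[okx], yi[oky]]
  out
}

# take a sub-array along axis `ax` from index a..b, keeping dimensions
slice_drop <- function(arr, ax, a, b) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[ax]] <- a:b
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# TRUE where the neighbor at +d along axis `ax` is TRUE in `m` (3-D arrays)
arr_shift <- function(m, ax, d) {
  out <- array(FALSE, dim(m)); n <- dim(m)[ax]
  src <- seq_len(n) + d; ok <- src >= 1 & src <= n
  idx_out <- rep(list(quote(expr = )), 3); idx_in <- idx_out
  idx_out[[ax]] <- which(ok); idx_in[[ax]] <- src[ok]
  part <- do.call(`[`, c(list(m), idx_in, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), idx_out, list(value = part)))
}

#' Assemble a labeled concentration field snapshot
#'
#' @param grid a [bioreactor_grid()] `transport_grid`.
#' @param gel_values concentrations (uM) for the gel cells, in grid order.
#' @param lumen_value reservoir concentration carried by the lumen cells, uM.
#' @param time_h snapshot time, h.
#' @return object of class `concentration_field`: `values` (uM, `NA` outside
#'   the domain), `labels`, `vol_mL`, `spacing_mm`, `time_h`.
#' @export
concentration_field <- function(grid, gel_values, lumen_value, time_h) {
  vals <- grid$vol_mL * NA_real_
  vals[grid$labels == "gel"] <- gel_values
  vals[grid$labels == "lumen"] <- lumen_value
  structure(list(values = vals, labels = grid$labels, vol_mL = grid$vol_mL,
                 spacing_mm = grid$dx, time_h = time_h, grid = grid),
            class = "concentration_field")
}

new_simulation_result <- function(platform, C0, times, region_means,
                                  equilibrium_uM, mass_nmol, spec,
                                  geometry = NULL, grid = NULL,
                                  snapshots = list(), params = list()) {
  structure(list(platform = platform, C0 = C0, times = times,
                 region_means = region_means,
                 equilibrium_uM = equilibrium_uM, mass_nmol = mass_nmol,
                 spec = spec, geometry = geometry, grid = grid,
                 snapshots = snapshots, params = params),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result: ", x$platform,
      if (!is.null(x$params$mode)) paste0(" (", x$params$mode, ")"),
      ">\n", sep = "")
  cat("  C0 = ", x$C0, " uM, ", length(x$times), " samples over ",
      max(x$times), " h\n", sep = "")
  last <- x$region_means[nrow(x$region_means), , drop = TRUE]
  cat("  final region means (uM): ",
      paste(names(last), signif(last, 4), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract the exposure history of one region
#'
#' @param result a `simulation_result`.
#' @param region region name (e.g. `"gel"`, `"region1"`, `"reservoir"`).
#' @return data frame (`time_h`, `mean_uM`) of class `exposure_history`, with
#'   the region name, applied concentration and equilibrium as attributes.
#' @export
exposure_history <- function(result, region) {
  stopifnot(inherits(result, "simulation_result"))
  if (!region %in% colnames(result$region_means))
    stop("unknown region '", region, "'; available: ",
         paste(colnames(result$region_means), collapse = ", "))
  h <- data.frame(time_h = result$times,
                  mean_uM = result$region_means[, region])
  attr(h, "region") <- region
  attr(h, "C0") <- result$C0
  attr(h, "equilibrium_uM") <- result$equilibrium_uM
  class(h) <- c("exposure_history", "data.frame")
  h
}

#' @export
as.data.frame.simulation_result <- function(x, ...) {
  regions <- colnames(x$region_means)
  do.call(rbind, lapply(regions, function(r)
    data.frame(platform = x$platform, region = r, time_h = x$times,
               mean_uM = x$region_means[, r],
               fraction_of_applied = if (x$C0 > 0)
                 100 * x$region_means[, r] / x$C0 else NA_real_)))
}
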