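#' Time for a region to reach steady state
#'
#' Steady state is defined as the region mean coming within a fraction
#' `1 - threshold` of the closed-system equilibrium concentration (default:
#' within 5%).  The equilibrium is the mass-balance value stored in the
#' simulation result (e.g. `C0 * V_media / (V_media + V_gel)` for the static
#' gel).
#'
#' @param result a `simulation_result`.
#' @param region region name.
#' @param threshold steady-state threshold as a fraction of equilibrium
#'   (default 0.95, i.e. within 5%).
#' @return first output time (h) at which the criterion holds; `Inf` if it is
#'   never reached within the simulated duration.
#' @export
time_to_steady_state <- function(result, region, threshold = 0.95) {
  h <- exposure_history(result, region)
  eq <- result$equilibrium_uM
  if (eq == 0) {
    i <- which(h$mean_uM == 0)[1]
  } else {
    i <- which(abs(h$mean_uM - eq) <= (1 - threshold) * eq)[1]
  }
  if (is.na(i)) Inf else h$time_h[i]
}

#' Calibrate the effective gel diffusivity from the static-gel kinetics
#'
#' The effective diffusivity of the drug in the hydrogel is not an input of
#' this package; it is fixed by requiring that the two-layer static-gel model
#' reach steady state (within `1 - threshold` of equilibrium) at
#' `target_time` -- 24 h by default.  The search is a bisection on log10(D):
#' because the output cadence quantizes the steady-state time, the bisection
#' brackets the plateau of diffusivities whose steady-state time equals the
#' target and returns its (geometric) midpoint.
#'
#' The packaged default `D_gel` in `platform_defaults()` is the frozen output
#' of this routine at its defaults and is used unchanged for all bioreactor
#' predictions.
#'
#' @param spec a `static_gel` [platform_spec()].
#' @param target_time target steady-state time, h.
#' @param threshold steady-state threshold (see [time_to_steady_state()]).
#' @param bracket search bracket for D, m^2/s.
#' @param tol relative tolerance on the achieved steady-state time.
#' @param dx_mm,dt_s,out_every_h numerical controls passed to
#'   [simulate_static_gel()].
#' @return calibrated diffusivity, m^2/s.
#' @export
calibrate_effective_diffusivity <- function(spec = platform_spec("static_gel"),
                                            target_time = 24,
                                            threshold = 0.95,
                                            bracket = c(1e-12, 1e-9),
                                            tol = 0.02,
                                            dx_mm = NULL, dt_s = NULL,
                                            out_every_h = 0.5) {
  if (!is.numeric(target_time) || target_time <= 0)
    stop("target_time must be > 0")
  dur <- max(3 * target_time, 48)
  tss <- function(D) {
    res <- simulate_static_gel(spec, C0 = 1, duration = dur, D_gel = D,
                               dx_mm = dx_mm, dt_s = dt_s,
                               out_every_h = out_every_h)
    time_to_steady_state(res, "gel", threshold)
  }
  if (!(tss(bracket[1]) > target_time && tss(bracket[2]) < target_time))
    stop("calibration error: target time ", target_time,
         " h not bracketed by D in [", bracket[1], ", ", bracket[2], "] m^2/s")
  # smallest D whose (quantized) steady-state time is <= t_edge
  edge <- function(t_edge) {
    lo <- log10(bracket[1]); hi <- log10(bracket[2])
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (tss(10^mid) > t_edge + 1e-9) lo <- mid else hi <- mid
      if (hi - lo < 5e-5) break
    }
    10^hi
  }
  D <- sqrt(edge(target_time) * edge(target_time - out_every_h))
  achieved <- tss(D)
  if (!is.finite(achieved) || abs(achieved - target_time) > tol * target_time)
    stop("calibration error: achieved steady-state time ", achieved,
         " h outside ", 100 * tol, "% of target ", target_time, " h")
  D
}

#' Darcy (superficial) velocity in a porous medium
#'
#' `v = kappa * grad(P) / mu`.  With hydrogel-scale permeabilities the
#' interstitial velocity in the perfused bioreactor gel is of order 1 nm/s,
#' orders of magnitude below physiologic interstitial flow -- the basis for
#' neglecting advection in the transport model.
#'
#' @param permeability medium permeability, m^2.
#' @param viscosity dynamic viscosity, Pa s.
#' @param pressure_gradient pressure gradient magnitude, Pa/m.
#' @return velocity, m/s.
#' @export
darcy_velocity <- function(permeability, viscosity, pressure_gradient) {
  if (any(c(permeability, viscosity) <= 0) || any(pressure_gradient < 0))
    stop("permeability and viscosity must be > 0; pressure gradient >= 0")
  permeability * pressure_gradient / viscosity
}

#' Peclet number
#'
#' Ratio of advective to diffusive transport, `Pe = v L / D`.  At the
#' bioreactor's interstitial velocity scale (~0.5 nm/s) and the 4.5 mm
#' region scale, Pe is of order 1e-2, justifying the diffusion-only model.
#'
#' @param velocity fluid velocity, m/s.
#' @param length_scale characteristic length, m.
#' @param D diffusivity, m^2/s.
#' @return dimensionless Peclet number.
#' @export
peclet_number <- function(velocity, length_scale, D) {
  if (any(D <= 0)) stop("D must be > 0")
  if (any(velocity < 0) || any(length_scale < 0))
    stop("velocity and length_scale must be >= 0")
  velocity * length_scale / D
}
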