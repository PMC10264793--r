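# Shared finite-volume machinery for the diffusion solvers.
#
# A system is a graph of cells: per-cell solute capacities V (m^3) and a list
# of conductances G = D * A_face / dist (m^3/s) between cell pairs.  An
# optional well-mixed reservoir is just one more node with capacity V_res.
# Backward-Euler stepping solves (V/dt + L) c^{n+1} = (V/dt) c^n with L the
# (symmetric, zero-row-sum) graph Laplacian, so total mass sum(V*c) is
# conserved to solver tolerance and the scheme is unconditionally stable and
# monotone (an M-matrix): concentrations stay nonnegative.

fv_laplacian <- function(n, ii, jj, gg) {
  off <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(-gg, -gg),
                              dims = c(n, n))
  off + Matrix::Diagonal(n, -Matrix::colSums(off))
}

# sys: list(V_m3, ii, jj, gg); regions: named list(idx, w) with w in mL
# returns times (h), region-mean matrix, mass trace (nmol), snapshots
fv_run <- function(sys, c0, duration_h, dt_s, out_every_h,
                   regions, snapshot_times = NULL) {
  n <- length(sys$V_m3)
  stopifnot(length(c0) == n)
  L <- fv_laplacian(n, sys$ii, sys$jj, sys$gg)
  Vdt <- sys$V_m3 / dt_s
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Matrix::Diagonal(n, Vdt) + L),
                         LDL = FALSE)
  nstep <- round(duration_h * H_TO_S / dt_s)
  per_out <- round(out_every_h * H_TO_S / dt_s)
  if (per_out < 1 || nstep %% per_out != 0)
    stop("output cadence must be a multiple of the time step and divide the duration")
  times <- seq(0, duration_h, by = out_every_h)
  V_mL <- sys$V_m3 / ML_TO_M3
  rmean <- function(cv) vapply(regions, function(r)
    sum(cv[r$idx] * r$w) / sum(r$w), numeric(1))
  out <- matrix(NA_real_, length(times), length(regions),
                dimnames = list(NULL, names(regions)))
  mass <- numeric(length(times))
  out[1, ] <- rmean(c0); mass[1] <- sum(c0 * V_mL)
  snaps <- list()
  snap_steps <- if (length(snapshot_times))
    round(snapshot_times * H_TO_S / dt_s) else integer(0)
  cv <- c0; k <- 2L
  for (s in seq_len(nstep)) {
    cv <- as.numeric(Matrix::solve(ch, Vdt * cv, system = "A"))
    if (s %% per_out == 0) {
      out[k, ] <- rmean(cv); mass[k] <- sum(cv * V_mL); k <- k + 1L
    }
    if (s %in% snap_steps) snaps[[length(snaps) + 1L]] <-
      list(time_h = s * dt_s / H_TO_S, state = cv)
  }
  list(times = times, region_means = out, mass_nmol = mass,
       final_state = cv, snapshots = snaps)
}
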