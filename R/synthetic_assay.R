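#' Ground-truth parameters for the synthetic assay generator
#'
#' @param condition condition name.
#' @param ic50_true true midpoint concentration, uM (> 0).
#' @param hill_true true hill slope.
#' @param signal_scale raw signal at zero dose (a.u. for luminescence).
#' @param noise_cv replicate coefficient of variation (multiplicative
#'   log-normal noise); 0 for noiseless data.
#' @param seed integer seed making the generator a pure function of its
#'   parameters.
#' @return an object of class `assay_truth`.
#' @export
assay_truth <- function(condition, ic50_true, hill_true = 1,
                        signal_scale = 1e4, noise_cv = 0.1, seed = 1L) {
  stopifnot(ic50_true > 0, hill_true > 0, noise_cv >= 0, signal_scale > 0)
  structure(list(condition = condition, ic50_true = ic50_true,
                 hill_true = hill_true, signal_scale = signal_scale,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "assay_truth")
}

#' Packaged ground-truth presets per culture condition
#'
#' Midpoint concentrations reported for patient-derived colorectal-cancer
#' liver-metastasis organoids treated with 5-FU in each platform, used as
#' generator ground truth: viability IC50s of 3.387 uM (media), 33.96 uM
#' (static gel), 22.6 / 69.8 uM (bioreactor regions 1 / 2), and day-7
#' lactate EC50s of 2.87 / 13.65 / 54.33 uM (media / static gel /
#' bioreactor).  Hill slopes are not reported and default to 1.
#'
#' @param noise_cv,seed passed to [assay_truth()].
#' @return list with elements `viability` and `lactate`, each a named list
#'   of [assay_truth()] objects.
#' @export
assay_truth_presets <- function(noise_cv = 0.1, seed = 1L) {
  mk <- function(cond, val, s_off)
    assay_truth(cond, val, hill_true = 1, noise_cv = noise_cv,
                seed = seed + s_off)
  list(
    viability = list(
      media = mk("media", 3.387, 101L),
      static_gel = mk("static_gel", 33.96, 102L),
      bioreactor_region1 = mk("bioreactor_region1", 22.6, 103L),
      bioreactor_region2 = mk("bioreactor_region2", 69.8, 104L)),
    lactate = list(
      media = mk("media", 2.87, 201L),
      static_gel = mk("static_gel", 13.65, 202L),
      bioreactor = mk("bioreactor", 54.33, 203L)))
}

# mean-preserving multiplicative log-normal noise with the given CV
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sg <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sg^2 / 2, sg))
}

#' Generate synthetic endpoint viability signals
#'
#' Emulates a CellTiter-Glo-like endpoint luminescence readout: mean signal
#' `signal_scale / (1 + (x / IC50)^hill)` at effective dose `x` (bottom 0),
#' with mean-preserving multiplicative log-normal replicate noise of the
#' truth's CV.  Deterministic given `(truth, doses, n_replicates)`.
#'
#' @param truth an [assay_truth()].
#' @param effective_doses effective concentrations, uM (>= 2 values).
#' @param applied_doses optional applied concentrations backing the
#'   effective ones (defaults to the effective doses).
#' @param n_replicates replicates per dose.
#' @return an [assay_table()].
#' @export
generate_viability <- function(truth, effective_doses, applied_doses = NULL,
                               n_replicates = 4) {
  stopifnot(inherits(truth, "assay_truth"))
  if (length(effective_doses) < 2) stop("need at least 2 doses")
  applied_doses <- applied_doses %||% effective_doses
  m <- truth$signal_scale *
    hill_unit(effective_doses, truth$ic50_true, truth$hill_true)
  sig <- withr::with_seed(truth$seed, {
    matrix(rep(m, n_replicates) *
             lognormal_noise(length(m) * n_replicates, truth$noise_cv),
           nrow = length(m))
  })
  assay_table(condition = truth$condition, doses = applied_doses,
              effective_doses = effective_doses, signals = sig)
}

#' Lactate accumulation model parameters
#'
#' Minimal growth-with-inhibition harness behind the synthetic lactate time
#' series: a viable-cell trajectory `N(t) = n0 exp(r t (1 - E(t)))` where
#' `E` is a Hill function (midpoint `ec50_true`, slope `hill_true`) of the
#' cumulative average drug exposure to date, and cumulative lactate is
#' `secretion_rate * integral of N` plus a dose-independent pre-treatment
#' baseline.  It reproduces the qualitative structure of the experimental
#' readout (identical day-0 values, dose separation emerging from day 2)
#' without claiming pharmacodynamic realism.
#'
#' @param ec50_true midpoint of the inhibition Hill curve, uM.
#' @param hill_true Hill slope of the inhibition curve (default 2: metabolic
#'   output separates sharply between the highest and lowest doses).
#' @param n0 initial viable-cell equivalents.
#' @param growth_rate uninhibited specific growth rate, 1/day (default 0.1:
#'   roughly one doubling over the weeklong treatment, typical of
#'   slow-growing organoid cultures embedded in a dense hydrogel).
#' @param secretion_rate lactate secreted per cell-equivalent per day, uM.
#' @param pre_days days of pre-treatment culture contributing the
#'   dose-independent day-0 baseline.
#' @param noise_cv replicate CV (multiplicative log-normal).
#' @param seed integer seed.
#' @return an object of class `lactate_model_params`.
#' @export
lactate_model_params <- function(ec50_true, hill_true = 2, n0 = 1000,
                                 growth_rate = 0.1, secretion_rate = 0.08,
                                 pre_days = 1, noise_cv = 0.05, seed = 1L) {
  stopifnot(ec50_true > 0, hill_true > 0, n0 >= 0, growth_rate >= 0,
            secretion_rate >= 0, pre_days >= 0, noise_cv >= 0)
  structure(list(ec50_true = ec50_true, hill_true = hill_true, n0 = n0,
                 growth_rate = growth_rate, secretion_rate = secretion_rate,
                 pre_days = pre_days, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "lactate_model_params")
}

#' Generate synthetic cumulative lactate time series
#'
#' For each applied dose, the viable-cell trajectory is inhibited by the
#' Hill of the *cumulative* average exposure to date (so dose separation
#' accumulates over the week), and reported lactate at each sampling day is
#' the integrated secretion plus the pre-treatment baseline, with
#' multiplicative replicate noise.  Day-0 values are dose independent by
#' construction.
#'
#' @param params a [lactate_model_params()].
#' @param effective_dose_histories named list (one entry per applied dose) of
#'   exposure histories (`time_h`, `mean_uM`), or a numeric vector of
#'   constant effective doses.
#' @param applied_doses applied concentrations, uM, aligned with the
#'   histories (defaults to the names/values of the histories).
#' @param days sampling days (default `c(0, 2, 4, 7)`).
#' @param n_replicates replicates per dose and day.
#' @return named list of [assay_table()]s, one per day (`day0`, `day2`,
#'   ...); each table's `effective_uM` is the exposure at that day.
#' @export
generate_lactate_timeseries <- function(params, effective_dose_histories,
                                        applied_doses = NULL,
                                        days = c(0, 2, 4, 7),
                                        n_replicates = 4) {
  stopifnot(inherits(params, "lactate_model_params"))
  if (is.numeric(effective_dose_histories)) {
    applied_doses <- applied_doses %||% effective_dose_histories
    effective_dose_histories <- lapply(effective_dose_histories, function(d)
      data.frame(time_h = c(0, max(days) * 24), mean_uM = d))
  }
  ndose <- length(effective_dose_histories)
  applied_doses <- applied_doses %||% as.numeric(names(effective_dose_histories))
  stopifnot(length(applied_doses) == ndose, !anyNA(applied_doses))
  span_ok <- vapply(effective_dose_histories, function(h)
    max(h$time_h) >= max(days) * 24, logical(1))
  if (!all(span_ok)) stop("histories must cover the sampled day span")

  tg <- seq(0, max(days), by = 0.05)                      # days
  per_dose <- lapply(effective_dose_histories, function(h) {
    conc <- stats::approx(h$time_h / 24, h$mean_uM, tg, rule = 2)$y
    cum <- c(0, cumsum((head(conc, -1) + tail(conc, -1)) / 2 * diff(tg)))
    cum_avg <- ifelse(tg > 0, cum / tg, conc[1])          # uM, to-date mean
    E <- 1 - hill_unit(cum_avg, params$ec50_true, params$hill_true)
    N <- params$n0 * exp(params$growth_rate * tg * (1 - E))
    intN <- c(0, cumsum((head(N, -1) + tail(N, -1)) / 2 * diff(tg)))
    baseline <- params$secretion_rate * params$n0 * params$pre_days
    stats::approx(tg, baseline + params$secretion_rate * intN, days)$y
  })
  lact <- do.call(rbind, per_dose)                        # dose x day, uM
  eff_at_day <- vapply(effective_dose_histories, function(h)
    stats::approx(h$time_h / 24, h$mean_uM, days, rule = 2)$y,
    numeric(length(days)))
  eff_at_day <- matrix(eff_at_day, nrow = length(days))

  noise <- withr::with_seed(params$seed,
    array(lognormal_noise(ndose * length(days) * n_replicates,
                          params$noise_cv),
          dim = c(ndose, length(days), n_replicates)))
  out <- lapply(seq_along(days), function(di) {
    sig <- lact[, di] * noise[, di, , drop = TRUE]
    sig <- matrix(sig, nrow = ndose)
    assay_table(condition = paste0("day", days[di]), doses = applied_doses,
                effective_doses = eff_at_day[di, ], signals = sig)
  })
  names(out) <- paste0("day", days)
  out
}

#' Generate synthetic organoid shape measurements
#'
#' Emulates day-7 brightfield morphometrics: areas are log-normal with a
#' platform-specific location (organoids in media form larger, more
#' irregular clusters than the hydrogel-embedded platforms), circularity is
#' Beta-distributed in (0, 1], and the perimeter is derived from the sampled
#' area and circularity (`P = sqrt(4 pi A / c)`), so every generated shape
#' has a valid circularity by construction.
#'
#' @param platform `"media"`, `"static_gel"` or `"bioreactor"`.
#' @param n number of organoids.
#' @param seed integer seed.
#' @return data frame with columns `platform`, `area_mm2`, `perimeter_mm`,
#'   `circularity`.
#' @export
generate_organoid_shapes <- function(platform = c("media", "static_gel",
                                                  "bioreactor"),
                                     n, seed = 1L) {
  platform <- match.arg(platform)
  stopifnot(n >= 1)
  par <- switch(platform,
    media = list(meanlog = log(0.40), sdlog = 0.7, ca = 5, cb = 3.2),
    static_gel = list(meanlog = log(0.06), sdlog = 0.5, ca = 10, cb = 2.2),
    bioreactor = list(meanlog = log(0.08), sdlog = 0.5, ca = 10, cb = 2.5))
  withr::with_seed(seed, {
    area <- stats::rlnorm(n, par$meanlog, par$sdlog)
    circ <- pmin(1, pmax(1e-3, stats::rbeta(n, par$ca, par$cb)))
    data.frame(platform = platform, area_mm2 = area,
               perimeter_mm = sqrt(4 * pi * area / circ),
               circularity = circ)
  })
}
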