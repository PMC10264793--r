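#' Assemble a dose-response assay table
#'
#' An `assay_table` holds endpoint signals (luminescence viability counts or
#' lactate concentrations) for one condition: one row per replicate per
#' applied dose, together with the *effective* dose -- the simulated mean
#' concentration actually experienced in that platform/region (equal to the
#' applied dose for the media condition).
#'
#' @param condition condition name (e.g. `"media"`, `"bioreactor_region1"`).
#' @param doses applied concentrations, uM (recycled across replicates).
#' @param effective_doses effective concentrations, uM, same length/order as
#'   `doses`; defaults to `doses`.
#' @param signals matrix or vector of signals: either `length(doses) x n`
#'   replicate matrix or a vector aligned with `doses`.
#' @param data alternatively, a long data frame with columns `condition`,
#'   `applied_uM`, `effective_uM`, `replicate`, `signal`.
#' @return an object of class `assay_table` (a long-format data frame).
#' @export
assay_table <- function(condition = NULL, doses = NULL,
                        effective_doses = NULL, signals = NULL, data = NULL) {
  if (is.null(data)) {
    stopifnot(!is.null(condition), !is.null(doses), !is.null(signals))
    effective_doses <- effective_doses %||% doses
    stopifnot(length(effective_doses) == length(doses))
    if (is.matrix(signals)) {
      stopifnot(nrow(signals) == length(doses))
      data <- data.frame(
        condition = condition,
        applied_uM = rep(doses, ncol(signals)),
        effective_uM = rep(effective_doses, ncol(signals)),
        replicate = rep(seq_len(ncol(signals)), each = length(doses)),
        signal = as.vector(signals))
    } else {
      stopifnot(length(signals) == length(doses))
      data <- data.frame(condition = condition, applied_uM = doses,
                         effective_uM = effective_doses,
                         replicate = stats::ave(doses, doses, FUN = seq_along),
                         signal = signals)
    }
  }
  need <- c("condition", "applied_uM", "effective_uM", "replicate", "signal")
  if (!all(need %in% names(data)))
    stop("assay data must have columns: ", paste(need, collapse = ", "))
  data <- data[order(data$applied_uM, data$replicate), , drop = FALSE]
  rownames(data) <- NULL
  if (length(unique(data$applied_uM[data$applied_uM > 0])) < 2)
    stop("need at least 2 distinct nonzero applied doses")
  if (any(!is.finite(data$signal))) stop("signals must be finite")
  class(data) <- c("assay_table", "data.frame")
  data
}

#' Read an assay table from CSV
#'
#' Expects columns `condition, applied_uM, effective_uM, replicate, signal`.
#' @param path CSV file path.
#' @return an [assay_table()].
#' @export
read_assay_csv <- function(path) assay_table(data = utils::read.csv(path))

#' Min/max normalization of assay signals
#'
#' Normalizes signals to the replicate means at the lowest and highest
#' applied drug concentrations: `(s - mean_highest) / (mean_lowest -
#' mean_highest)`, so the mean signal at the lowest dose maps to 1 and at the
#' highest dose to 0.  The anchors are stored as attributes; fits account for
#' the fact that the anchors are extreme-dose means rather than true
#' asymptotes (see [fit_4pl()]).
#'
#' @param table an [assay_table()].
#' @return the table with an added `signal_norm` column and normalization
#'   attributes.
#' @export
normalize_min_max <- function(table) {
  stopifnot(inherits(table, "assay_table"))
  dlo <- min(table$applied_uM); dhi <- max(table$applied_uM)
  mlo <- mean(table$signal[table$applied_uM == dlo])
  mhi <- mean(table$signal[table$applied_uM == dhi])
  if (isTRUE(all.equal(mlo, mhi)))
    stop("normalization error: lowest- and highest-dose mean signals are equal")
  table$signal_norm <- (table$signal - mhi) / (mlo - mhi)
  attr(table, "anchors") <- list(
    dose_lo = dlo, dose_hi = dhi,
    eff_lo = table$effective_uM[match(dlo, table$applied_uM)],
    eff_hi = table$effective_uM[match(dhi, table$applied_uM)],
    mean_lo = mlo, mean_hi = mhi)
  table
}

# unit-amplitude Hill decay: 1 at x = 0, 1/2 at x = e
hill_unit <- function(x, e, h) ifelse(x <= 0, 1, 1 / (1 + (x / e)^h))

# constrained model prediction: the 4PL with top/bottom fixed at 1/0 is
# passed through the same min/max map as the data (anchored at the model
# values at the extreme effective doses), so a noiseless table generated
# from the model is recovered exactly.
pred_constrained <- function(x, e, h, eff_lo, eff_hi) {
  g <- hill_unit(x, e, h)
  glo <- hill_unit(eff_lo, e, h); ghi <- hill_unit(eff_hi, e, h)
  (g - ghi) / (glo - ghi)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL `y = bottom + (top - bottom) / (1 +
#' (x / IC50)^hill)` to min/max-normalized signals against the effective
#' doses, with `IC50` and `hill` optimized on the log scale.  With
#' `fix_top_bottom = TRUE` (default, the constrained normalize-then-fit
#' workflow) top/bottom are fixed at 1/0 and the model curve is passed
#' through the same min/max normalization as the data, which removes the
#' bias from anchoring the normalization at extreme-dose means; with
#' `FALSE`, top and bottom are free parameters.
#'
#' The 95% confidence interval is asymptotic on log(IC50)
#' (back-transformed).  All replicates enter individually; `df = n -
#' n_free_params`.
#'
#' @param table an [assay_table()]; normalized automatically if needed.
#' @param fix_top_bottom fix top = 1, bottom = 0 (default `TRUE`).
#' @param label reported parameter label, `"IC50"` or `"EC50"`.
#' @return object of class `fit_4pl`: fields `ic50`, `hill`, `ci95_low`,
#'   `ci95_high`, `ssr`, `df`, `converged`, `top`, `bottom`, `label`.
#' @examples
#' truth <- assay_truth("media", ic50_true = 25, noise_cv = 0)
#' tab <- generate_viability(truth, effective_doses = c(0, 1, 5, 25, 100, 150))
#' fit_4pl(tab)$ic50  # 25
#' @export
fit_4pl <- function(table, fix_top_bottom = TRUE, label = "IC50") {
  stopifnot(inherits(table, "assay_table"))
  if (is.null(table$signal_norm)) table <- normalize_min_max(table)
  an <- attr(table, "anchors")
  x <- table$effective_uM; y <- table$signal_norm
  npar <- if (fix_top_bottom) 2L else 4L
  if (length(y) <= npar)
    stop("fewer data points (", length(y), ") than free parameters + 1")
  if (length(unique(x[x > 0])) < 2)
    stop("need at least 2 distinct nonzero effective doses to fit")
  xpos <- x[x > 0]
  start <- c(log_e = log(exp(mean(log(xpos)))), log_h = 0)
  if (!fix_top_bottom) start <- c(bottom = 0, span = 1, start)
  resid_fun <- if (fix_top_bottom) {
    function(p) y - pred_constrained(x, exp(p[["log_e"]]), exp(p[["log_h"]]),
                                     an$eff_lo, an$eff_hi)
  } else {
    function(p) y - (p[["bottom"]] +
                       p[["span"]] * hill_unit(x, exp(p[["log_e"]]),
                                               exp(p[["log_h"]])))
  }
  lower <- rep(-Inf, npar); upper <- rep(Inf, npar)
  names(lower) <- names(upper) <- names(start)
  lower[c("log_e", "log_h")] <- c(log(min(xpos)) - log(1e4), log(0.05))
  upper[c("log_e", "log_h")] <- c(log(max(xpos)) + log(1e4), log(20))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fun,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  ssr <- sum(fit$fvec^2); df <- length(y) - npar
  # Asymptotic SE on log(IC50).  For the constrained fit the variance is
  # taken from the free top/bottom (affine-nuisance) refit so that noise in
  # the min/max normalization anchors is propagated into the interval --
  # the same nuisance treatment the F test uses.
  ci_info <- tryCatch({
    if (fix_top_bottom && length(y) > 5) {
      r4 <- function(q) y - (q[["bottom"]] +
                               q[["span"]] * hill_unit(x, exp(q[["log_e"]]),
                                                       exp(q[["log_h"]])))
      f4 <- minpack.lm::nls.lm(
        par = c(bottom = 0, span = 1, p),
        fn = r4, control = minpack.lm::nls.lm.control(maxiter = 500))
      J <- num_jacobian(r4, f4$par)
      df_ci <- length(y) - 4L
      covm <- solve(crossprod(J)) * sum(f4$fvec^2) / df_ci
      list(se = sqrt(covm[3, 3]), df = df_ci)
    } else {
      J <- num_jacobian(resid_fun, p)
      covm <- solve(crossprod(J)) * ssr / df
      k <- which(names(p) == "log_e")
      list(se = sqrt(covm[k, k]), df = df)
    }
  }, error = function(e) list(se = NA_real_, df = df))
  se_log_e <- ci_info$se
  ic50 <- exp(p[["log_e"]])
  ci <- if (is.finite(se_log_e))
    exp(p[["log_e"]] + c(-1, 1) * stats::qt(0.975, ci_info$df) * se_log_e)
  else c(NA_real_, NA_real_)
  structure(list(
    ic50 = ic50, hill = exp(p[["log_h"]]),
    ci95_low = ci[1], ci95_high = ci[2], se_log_ic50 = se_log_e,
    ssr = ssr, df = df,
    converged = fit$info %in% 1:4,
    top = if (fix_top_bottom) 1 else p[["bottom"]] + p[["span"]],
    bottom = if (fix_top_bottom) 0 else p[["bottom"]],
    fix_top_bottom = fix_top_bottom,
    label = label, n = length(y), condition = table$condition[1],
    info = fit$message), class = "fit_4pl")
}

num_jacobian <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(NA_real_, length(f0), length(p))
  for (k in seq_along(p)) {
    pk <- p; pk[k] <- pk[k] + eps
    J[, k] <- (f(pk) - f0) / eps
  }
  J
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat("<", x$label, " fit: ", x$condition, ">\n", sep = "")
  cat(sprintf("  %s = %.4g uM  (95%% CI %.4g - %.4g), hill = %.3g\n",
              x$label, x$ic50, x$ci95_low, x$ci95_high, x$hill))
  cat(sprintf("  SSR = %.4g on %d df; converged: %s\n", x$ssr, x$df,
              x$converged))
  invisible(x)
}

#' Fit an EC50 from a day-7 lactate table
#'
#' Lactate readouts decrease with dose like the viability signal, so the
#' same min/max normalization and constrained 4PL machinery applies; the
#' midpoint is reported as an EC50.
#'
#' @param day7_lactate an [assay_table()] of day-7 lactate concentrations.
#' @param ... passed to [fit_4pl()].
#' @return a `fit_4pl` object with label `"EC50"`.
#' @export
fit_ec50_lactate <- function(day7_lactate, ...) {
  fit_4pl(day7_lactate, label = "EC50", ...)
}

#' Compare two dose-response curves with the extra sum-of-squares F test
#'
#' Nested-model comparison of the IC50s (log scale) of two conditions.  The
#' null model fits both tables with a single shared log(IC50); the
#' alternative gives each table its own.  Both models share the hill slope
#' and give each table its own top/bottom (scale/offset) nuisance
#' parameters, so that noise in the min/max normalization anchors is not
#' mistaken for a curve shift.  `F = ((SSR0 - SSR1)/1) / (SSR1/df1)` with
#' `df1 = n_total - 7`.
#'
#' @param tableA,tableB normalized [assay_table()]s (normalized automatically
#'   if needed).
#' @return list with `F`, `p`, `df_num`, `df_den`, per-condition IC50s under
#'   the alternative, and both SSRs.
#' @export
compare_ic50_f_test <- function(tableA, tableB) {
  prep <- function(tb) {
    if (is.null(tb$signal_norm)) tb <- normalize_min_max(tb)
    tb
  }
  tableA <- prep(tableA); tableB <- prep(tableB)
  xA <- tableA$effective_uM; yA <- tableA$signal_norm
  xB <- tableB$effective_uM; yB <- tableB$signal_norm
  n <- length(yA) + length(yB)
  if (n <= 7) stop("too few points for the nested comparison")
  resid2 <- function(a, b, e, h, x, y) y - (a + b * hill_unit(x, e, h))
  start_e <- log(exp(mean(log(c(xA[xA > 0], xB[xB > 0])))))
  f0 <- minpack.lm::nls.lm(
    par = c(aA = 0, bA = 1, aB = 0, bB = 1, log_e = start_e, log_h = 0),
    fn = function(p) c(
      resid2(p[["aA"]], p[["bA"]], exp(p[["log_e"]]), exp(p[["log_h"]]), xA, yA),
      resid2(p[["aB"]], p[["bB"]], exp(p[["log_e"]]), exp(p[["log_h"]]), xB, yB)),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p0 <- f0$par
  f1 <- minpack.lm::nls.lm(
    par = c(aA = p0[["aA"]], bA = p0[["bA"]], aB = p0[["aB"]], bB = p0[["bB"]],
            log_eA = p0[["log_e"]], log_eB = p0[["log_e"]],
            log_h = p0[["log_h"]]),
    fn = function(p) c(
      resid2(p[["aA"]], p[["bA"]], exp(p[["log_eA"]]), exp(p[["log_h"]]), xA, yA),
      resid2(p[["aB"]], p[["bB"]], exp(p[["log_eB"]]), exp(p[["log_h"]]), xB, yB)),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  ssr0 <- sum(f0$fvec^2); ssr1 <- sum(f1$fvec^2)
  if (!is.finite(ssr0) || !is.finite(ssr1))
    stop("degenerate fits in F-test comparison")
  df_den <- n - 7L
  Fstat <- max(0, (ssr0 - ssr1)) / (ssr1 / df_den)
  list(F = Fstat, p = stats::pf(Fstat, 1, df_den, lower.tail = FALSE),
       df_num = 1L, df_den = df_den,
       ic50_A = exp(f1$par[["log_eA"]]), ic50_B = exp(f1$par[["log_eB"]]),
       shared_hill = exp(f1$par[["log_h"]]),
       ssr_null = ssr0, ssr_alt = ssr1)
}
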