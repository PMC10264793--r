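test_that("min/max normalization anchors extreme-dose means at 1 and 0", {
  tab <- assay_table(condition = "demo", doses = c(0, 1, 10, 100),
                     signals = matrix(c(10000, 10000, 7000, 4000, 5500, 5500,
                                        1000, 1000), 4, 2, byrow = TRUE))
  nt <- normalize_min_max(tab)
  expect_equal(mean(nt$signal_norm[nt$applied_uM == 0]), 1)
  expect_equal(mean(nt$signal_norm[nt$applied_uM == 100]), 0)
  expect_equal(nt$signal_norm[nt$applied_uM == 10][1], 0.5)
  # monotone-decreasing dose means stay monotone after normalization
  means <- tapply(nt$signal_norm, nt$applied_uM, mean)
  expect_true(all(diff(means) <= 0))

  flat <- assay_table(condition = "flat", doses = c(0, 1, 10, 100),
                      signals = rep(5, 4))
  expect_error(normalize_min_max(flat), "normalization error")
})

test_that("noiseless 4PL data are recovered to optimizer tolerance", {
  truth <- assay_truth("demo", ic50_true = 25, hill_true = 1, noise_cv = 0)
  tab <- generate_viability(truth, effective_doses = c(0, 1, 5, 25, 100, 150))
  fit <- fit_4pl(tab)
  expect_equal(fit$ic50, 25, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$df, 24 - 2)
  expect_true(fit$ci95_low <= fit$ic50 && fit$ic50 <= fit$ci95_high)
})

test_that("packaged media-condition truth round-trips through the fit", {
  presets <- assay_truth_presets(noise_cv = 0)
  tab <- generate_viability(presets$viability$media,
                            effective_doses = c(0, 1, 5, 25, 100, 150))
  expect_equal(fit_4pl(tab)$ic50, 3.387, tolerance = 1e-6)
})

test_that("the optimizer agrees with a dense grid-search oracle", {
  doses <- c(0, 2, 10, 50, 200, 300)
  set.seed(42)
  for (i in 1:20) {
    truth <- assay_truth("grid", ic50_true = exp(runif(1, log(3), log(90))),
                         hill_true = exp(runif(1, log(0.6), log(1.8))),
                         noise_cv = 0.1, seed = 5000 + i)
    tab <- normalize_min_max(generate_viability(truth, doses))
    an <- attr(tab, "anchors")
    fit <- fit_4pl(tab)
    oracle <- grid_search_4pl(tab$effective_uM, tab$signal_norm,
                              an$eff_lo, an$eff_hi)
    expect_equal(fit$ic50, oracle$ic50, tolerance = 0.01)
    expect_lte(fit$ssr, oracle$ssr * (1 + 1e-6))
  }
})

test_that("IC50 estimates are monotone in the true IC50 (noiseless)", {
  doses <- c(0, 4, 20, 100, 400, 600)
  truths <- c(5, 15, 40, 90, 200)
  est <- vapply(truths, function(e) {
    tab <- generate_viability(assay_truth("m", e, noise_cv = 0), doses)
    fit_4pl(tab)$ic50
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_equal(est, truths, tolerance = 1e-5)
})

test_that("normalized fits are invariant to the raw signal scale", {
  truth <- assay_truth("s", 30, noise_cv = 0.1, seed = 77)
  tab <- generate_viability(truth, c(0, 4, 20, 100, 400, 600))
  tab37 <- tab; tab37$signal <- tab$signal * 37
  f1 <- fit_4pl(tab); f2 <- fit_4pl(tab37)
  expect_equal(f1$ic50, f2$ic50, tolerance = 1e-6)
  expect_equal(f1$ci95_low, f2$ci95_low, tolerance = 1e-6)
  tb <- generate_viability(assay_truth("s2", 30, noise_cv = 0.1, seed = 78),
                           c(0, 4, 20, 100, 400, 600))
  tb37 <- tb; tb37$signal <- tb$signal * 37
  c1 <- compare_ic50_f_test(tab, tb)
  c2 <- compare_ic50_f_test(tab37, tb37)
  expect_equal(c1$p, c2$p, tolerance = 1e-9)
})

test_that("media-condition fits against applied and effective doses agree", {
  truth <- assay_truth("media", 3.387, noise_cv = 0.1, seed = 9)
  doses <- c(0, 1, 5, 25, 100, 150)
  t_eff <- generate_viability(truth, effective_doses = doses,
                              applied_doses = doses)
  f_eff <- fit_4pl(t_eff)
  t_app <- t_eff; t_app$effective_uM <- t_app$applied_uM
  expect_equal(fit_4pl(t_app)$ic50, f_eff$ic50, tolerance = 1e-12)
})

test_that("comparing a table with itself yields F ~ 0, p ~ 1", {
  tab <- generate_viability(assay_truth("x", 30, noise_cv = 0.1, seed = 3),
                            c(0, 4, 20, 100, 400, 600))
  cmp <- compare_ic50_f_test(tab, tab)
  expect_lt(cmp$F, 1e-4)
  expect_gt(cmp$p, 0.99)
  expect_equal(cmp$df_num, 1L)
})

test_that("the F test separates the two bioreactor-region truths", {
  doses <- c(0, 4, 20, 100, 400, 600)
  rej <- 0L; n_sim <- 500L
  for (i in seq_len(n_sim)) {
    tA <- generate_viability(assay_truth("r1", 22.6, noise_cv = 0.1,
                                         seed = 10000 + i), doses)
    tB <- generate_viability(assay_truth("r2", 69.8, noise_cv = 0.1,
                                         seed = 20000 + i), doses)
    if (compare_ic50_f_test(tA, tB)$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_sim, 0.80)
})

test_that("free-asymptote fit variant recovers affine-shifted curves", {
  doses <- c(0, 1, 5, 25, 100, 150)
  truth <- assay_truth("fa", 25, noise_cv = 0)
  tab <- generate_viability(truth, doses)
  fit <- fit_4pl(tab, fix_top_bottom = FALSE)
  expect_equal(fit$ic50, 25, tolerance = 1e-4)
  expect_equal(fit$top, 1, tolerance = 0.05)
  expect_equal(fit$df, 24 - 4)
})

test_that("lactate EC50 fits recover the packaged presets (noiseless)", {
  presets <- assay_truth_presets(noise_cv = 0)
  pan_bio <- c(0, 4, 20, 100, 400, 600)
  tab <- generate_viability(presets$lactate$bioreactor, pan_bio)
  f <- fit_ec50_lactate(tab)
  expect_equal(f$ic50, 54.33, tolerance = 1e-6)
  expect_equal(f$label, "EC50")
  pan_sg <- c(0, 2, 10, 50, 200, 300)
  f2 <- fit_ec50_lactate(generate_viability(presets$lactate$static_gel, pan_sg))
  expect_equal(f2$ic50, 13.65, tolerance = 1e-6)
})

test_that("fits with too few informative doses are rejected", {
  tab <- assay_table(condition = "tiny", doses = c(0, 1, 10),
                     signals = c(100, 50, 10))
  expect_error(fit_4pl(tab, fix_top_bottom = FALSE), "fewer data points")
  lac <- assay_table(condition = "day0", doses = c(0, 4, 20, 100),
                     effective_doses = rep(0, 4),
                     signals = matrix(80 + rnorm(8), 4))
  expect_error(fit_4pl(lac), "effective doses")
})
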