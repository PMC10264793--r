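test_that("viability generator is exact at zero noise and seed-deterministic", {
  truth <- assay_truth("demo", 33.96, noise_cv = 0)
  doses <- c(0, 2, 10, 50, 200, 300)
  tab <- generate_viability(truth, doses)
  mean_curve <- 1e4 / (1 + (doses / 33.96))
  mean_curve[doses == 0] <- 1e4
  got <- tapply(tab$signal, tab$applied_uM, mean)
  expect_equal(as.numeric(got), mean_curve, tolerance = 1e-12)

  noisy <- assay_truth("demo", 33.96, noise_cv = 0.1, seed = 123)
  t1 <- generate_viability(noisy, doses)
  t2 <- generate_viability(noisy, doses)
  expect_identical(t1, t2)
  t3 <- generate_viability(assay_truth("demo", 33.96, noise_cv = 0.1,
                                       seed = 124), doses)
  expect_false(identical(t1$signal, t3$signal))
  # generator does not disturb the global RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_viability(noisy, doses)); b <- runif(1)
  expect_identical(a, b)
})

test_that("fitted IC50 covers the truth across seeded noisy replicates", {
  doses <- c(0, 2, 10, 50, 200, 300)
  hits <- 0L; n_sim <- 200L
  for (i in seq_len(n_sim)) {
    truth <- assay_truth("sg", 33.96, noise_cv = 0.1, seed = 40000 + i)
    fit <- fit_4pl(generate_viability(truth, doses, n_replicates = 4))
    if (fit$ci95_low <= 33.96 && 33.96 <= fit$ci95_high) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.90)
})

test_that("lactate series are dose-independent at day 0 and grow without drug", {
  pars <- lactate_model_params(54.33, noise_cv = 0)
  tabs <- generate_lactate_timeseries(pars, c(0, 4, 20, 100, 400, 600))
  expect_named(tabs, c("day0", "day2", "day4", "day7"))
  d0 <- tabs$day0
  expect_equal(diff(range(d0$signal)), 0)
  zero_dose <- vapply(tabs, function(tb)
    tb$signal[tb$applied_uM == 0][1], numeric(1))
  expect_true(all(diff(zero_dose) > 0))
  # high doses secrete less than low doses from day 2 onward
  for (d in c("day2", "day4", "day7")) {
    m <- tapply(tabs[[d]]$signal, tabs[[d]]$applied_uM, mean)
    expect_true(all(diff(m) <= 1e-12), info = d)
  }
  t2 <- generate_lactate_timeseries(pars, c(0, 4, 20, 100, 400, 600))
  expect_identical(tabs, t2)
})

test_that("day-7 lactate tables recover the preset EC50 within 15%", {
  pan <- c(0, 4, 20, 100, 400, 600)
  # noiseless: the only distortion is the mild nonlinearity of cumulative
  # secretion in the inhibition fraction
  pars0 <- lactate_model_params(54.33, noise_cv = 0)
  f0 <- fit_ec50_lactate(generate_lactate_timeseries(pars0, pan)$day7)
  expect_equal(f0$ic50, 54.33, tolerance = 0.15)
  # CV 5% replicate noise: the estimate distribution is wide (the dose
  # effect rides on a large secretion baseline), but its median stays
  # within 15% of the preset across seeded runs
  est <- vapply(seq_len(200), function(i) {
    pars <- lactate_model_params(54.33, noise_cv = 0.05, seed = 60000 + i)
    tabs <- generate_lactate_timeseries(pars, pan)
    fit_ec50_lactate(tabs$day7)$ic50
  }, numeric(1))
  expect_equal(stats::median(est), 54.33, tolerance = 0.15)
})

test_that("lactate inhibition follows the cumulative exposure history", {
  pars <- lactate_model_params(50, noise_cv = 0)
  # ramping exposure reaching 100 uM at day 7 delivers less cumulative dose
  # than a constant 100 uM, so late-day lactate is higher
  ramp <- data.frame(time_h = c(0, 168), mean_uM = c(0, 100))
  const <- data.frame(time_h = c(0, 168), mean_uM = c(100, 100))
  tabs <- generate_lactate_timeseries(pars, list(ramp, const),
                                      applied_doses = c(100, 100.1))
  d7 <- tabs$day7
  expect_gt(d7$signal[d7$applied_uM == 100][1],
            d7$signal[d7$applied_uM == 100.1][1])
  expect_error(
    generate_lactate_timeseries(pars,
      list(data.frame(time_h = c(0, 24), mean_uM = 1)),
      applied_doses = 1),
    "span")
})

test_that("organoid shape generator respects its own construction", {
  shp <- generate_organoid_shapes("media", 1000, seed = 5)
  circ <- circularity(shp$area_mm2, shp$perimeter_mm)
  expect_true(all(circ > 0 & circ <= 1 + 1e-12))
  expect_equal(as.numeric(circ), shp$circularity, tolerance = 1e-12)
  expect_identical(shp, generate_organoid_shapes("media", 1000, seed = 5))

  bio <- generate_organoid_shapes("bioreactor", 1000, seed = 5)
  gel <- generate_organoid_shapes("static_gel", 1000, seed = 5)
  expect_gt(mean(shp$area_mm2), mean(bio$area_mm2))
  expect_gt(mean(shp$area_mm2), mean(gel$area_mm2))
  # media clusters are more irregular (lower circularity)
  expect_lt(mean(shp$circularity), mean(bio$circularity))
  expect_error(generate_organoid_shapes("media", 0), "n >= 1")
})
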