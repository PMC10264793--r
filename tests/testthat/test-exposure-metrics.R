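test_that("region masks split the gel into near-equal volumes", {
  spec <- platform_spec("bioreactor")
  grid <- bioreactor_grid(spec, dx_mm = 0.2)
  masks <- region_masks(grid, spec)
  gel <- grid$labels == "gel"
  # exact partition of the gel cells
  expect_true(all(xor(masks$region1[gel], masks$region2[gel])))
  expect_false(any(masks$region1 & masks$region2))
  expect_false(any((masks$region1 | masks$region2) & !gel))
  v1 <- sum(grid$vol_mL[masks$region1])
  v2 <- sum(grid$vol_mL[masks$region2])
  expect_equal(v1 + v2, spec$gel_volume, tolerance = 1e-9)
  # chord-area integral oracle (lumen excluded): ~49.9% / 50.1%
  oracle <- chord_region1_fraction(22.1, 4.5, 2.272)
  expect_equal(oracle, 0.4985, tolerance = 1e-3)
  expect_equal(v1 / (v1 + v2), oracle, tolerance = 0.035)
  # wall convention shifts the cut outward
  mw <- region_masks(grid, spec, from = "wall")
  expect_gt(sum(grid$vol_mL[mw$region1]), v1)
})

test_that("degenerate region cuts are rejected", {
  spec <- platform_spec("bioreactor")
  grid <- bioreactor_grid(spec, dx_mm = 0.4)
  expect_error(region_masks(grid, cut_mm = 12), "degenerate")
  # the cell column on the channel axis keeps region 1 nonempty even for a
  # vanishing cut, so only the region-2 side can degenerate
  m <- region_masks(grid, cut_mm = 1e-6)
  expect_true(any(m$region1) && any(m$region2))
})

test_that("region_mean is an exact volume-weighted average", {
  spec <- platform_spec("bioreactor")
  grid <- bioreactor_grid(spec, dx_mm = 0.5)
  gel <- grid$labels == "gel"
  # uniform field
  f <- concentration_field(grid, gel_values = rep(7, sum(gel)),
                           lumen_value = 7, time_h = 0)
  masks <- region_masks(grid, spec)
  expect_equal(region_mean(f, masks$region1), 7)
  expect_equal(region_mean(f, masks$region2), 7)
  # linear-in-x field vs direct sum
  X <- matrix(grid$x, length(grid$x), length(grid$y))
  f2 <- concentration_field(grid, gel_values = X[gel], lumen_value = 0,
                            time_h = 0)
  direct <- sum(X[masks$region1] * grid$vol_mL[masks$region1]) /
    sum(grid$vol_mL[masks$region1])
  expect_equal(region_mean(f2, masks$region1), direct, tolerance = 1e-12)
  # single cell
  one <- masks$region1 & FALSE
  one[which(masks$region1)[1]] <- TRUE
  expect_equal(region_mean(f2, one), X[which(masks$region1)[1]])
  expect_error(region_mean(f2, one & FALSE), "empty mask")
})

test_that("trapezoidal AUC matches closed forms and is additive/linear", {
  const <- data.frame(time_h = seq(0, 168, 0.5), mean_uM = 1)
  expect_equal(auc_trapezoid(const), 168)
  ramp <- data.frame(time_h = seq(0, 168, 0.5),
                     mean_uM = seq(0, 2, length.out = 337))
  expect_equal(auc_trapezoid(ramp), 168)
  zero <- data.frame(time_h = 0:168, mean_uM = 0)
  expect_equal(auc_trapezoid(zero), 0)
  # additivity at an interior sample and at an interpolated point
  h <- data.frame(time_h = seq(0, 10, 0.5), mean_uM = sqrt(seq(0, 10, 0.5)))
  expect_equal(auc_trapezoid(h, 0, 4) + auc_trapezoid(h, 4, 10),
               auc_trapezoid(h, 0, 10))
  expect_equal(auc_trapezoid(h, 0, 3.25) + auc_trapezoid(h, 3.25, 10),
               auc_trapezoid(h, 0, 10))
  h2 <- h; h2$mean_uM <- 5 * h$mean_uM
  expect_equal(auc_trapezoid(h2), 5 * auc_trapezoid(h))
  expect_error(auc_trapezoid(h, 0, 12), "outside the sampled span")
  expect_error(auc_trapezoid(h, 5, 5), "t_start")
})

test_that("fraction of applied follows the simulated histories", {
  res <- default_bioreactor_run()
  h1 <- exposure_history(res, "region1")
  h2 <- exposure_history(res, "region2")
  expect_gt(fraction_of_applied(h1, res$C0, 168),
            fraction_of_applied(h2, res$C0, 168))
  expect_error(fraction_of_applied(h1, 0, 168), "C0")
  expect_error(fraction_of_applied(h1, 1, 1000), "span")

  st <- default_static_run()
  expect_equal(fraction_of_applied(exposure_history(st, "gel"), st$C0, 168),
               50, tolerance = 0.01)
})

test_that("region1 cumulative exposure dominates region2", {
  res <- default_bioreactor_run()
  expect_gt(auc_trapezoid(exposure_history(res, "region1")),
            auc_trapezoid(exposure_history(res, "region2")))
})

test_that("circularity matches closed forms for analytic shapes", {
  expect_equal(circularity(pi, 2 * pi), 1, ignore_attr = TRUE)
  expect_equal(circularity(1, 4), pi / 4, ignore_attr = TRUE)
  # ellipse series: circularity < 1, decreasing with eccentricity
  per_ellipse <- function(a, b) {
    f <- function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
    4 * stats::integrate(f, 0, pi / 2, rel.tol = 1e-10)$value
  }
  cs <- vapply(c(1.5, 2, 3, 5), function(a)
    as.numeric(circularity(pi * a, per_ellipse(a, 1))), numeric(1))
  expect_true(all(cs < 1))
  expect_true(all(diff(cs) < 0))
  # noisy measurements slightly above 1 are flagged, not dropped
  flagged <- circularity(pi * 1.01, 2 * pi)
  expect_true(attr(flagged, "clipped"))
  expect_error(circularity(0, 1), "must be")
  expect_error(circularity(1, 0), "must be")
})

test_that("dose_metrics summarizes AUC, day-7 mean and fraction", {
  res <- default_bioreactor_run()
  m <- dose_metrics(res)
  expect_setequal(m$region, c("region1", "region2", "total"))
  r1 <- m[m$region == "region1", ]
  expect_equal(r1$day7_mean_uM,
               res$region_means[nrow(res$region_means), "region1"],
               ignore_attr = TRUE)
  expect_equal(r1$fraction_pct, 100 * r1$day7_mean_uM / res$C0)
  expect_true(all(m$auc_uMh >= 0))
})
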