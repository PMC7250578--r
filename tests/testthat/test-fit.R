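self_generated <- function(params, days = seq(0, 12, 2), ...) {
  tr <- simulate_population(params, "II", days = max(days), step = min(diff(days)), ...)
  idx <- match(days, tr$time)
  tibble::tibble(day = days,
                 extra_fraction = extra_centrosome_fraction(tr[idx, ]))
}

test_that("noiseless self-generated data recovers the generating (v, r_S)", {
  for (preset in c("dld1", "rpe1_p53ko")) {
    pr <- centro_preset(preset)
    obs <- self_generated(pr)
    fit <- fit_time_course(obs, pr, free = c("v", "r_S"))
    expect_lt(abs(fit$estimate["v"] - pr$v), 0.02)
    expect_lt(abs(fit$estimate["r_S"] - pr$r_S), 0.02)
    expect_lt(fit$loss, 1e-10)
  }
})

test_that("the fit is invariant to row order and rejects ill-posed input", {
  pr <- centro_preset("dld1")
  obs <- self_generated(pr)
  fit1 <- fit_time_course(obs, pr, free = c("v", "r_S"))
  fit2 <- fit_time_course(obs[sample.int(nrow(obs)), ], pr,
                          free = c("v", "r_S"))
  expect_equal(fit1$estimate, fit2$estimate, tolerance = 1e-8)
  expect_equal(fit1$loss, fit2$loss, tolerance = 1e-8)
  expect_error(fit_time_course(obs[1, ], pr, free = c("v", "r_S")),
               "Ill-posed")
  expect_error(fit_time_course(obs, pr, free = "nonsense"), "subset")
})

test_that("every multi-start refinement lands on the same optimum", {
  pr <- centro_preset("dld1")
  obs <- self_generated(pr)
  fit <- fit_time_course(obs, pr, free = c("v", "r_S"), n_starts = 5)
  # all refined losses agree at the identifiable design (7 time points)
  expect_lt(max(fit$start_losses) - min(fit$start_losses), 1e-3)
})

test_that("goodness of fit reports residual scale; broom methods tidy it", {
  pr <- centro_preset("dld1")
  obs <- self_generated(pr)
  fit <- fit_time_course(obs, pr, free = c("v", "r_S"))
  gof <- goodness_of_fit(fit, obs)
  expect_lt(gof$rms, 1e-5)
  expect_error(goodness_of_fit(fit, dplyr::mutate(obs, extra_fraction = 0.5)),
               "match")
  td <- tidy(fit)
  expect_equal(td$parameter, c("v", "r_S"))
  expect_true(all(td$estimate >= td$lower & td$estimate <= td$upper))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 7)
  expect_equal(nrow(augment(fit)), 7)
})

test_that("binomially noised self-fits have residuals on the sampling scale", {
  pr <- centro_preset("dld1")
  obs <- self_generated(pr)
  set.seed(5)
  n <- 300
  noised <- dplyr::mutate(obs,
    extra_fraction = rbinom(dplyr::n(), n, extra_fraction) / n,
    n_cells = n)
  fit <- fit_time_course(noised, pr, free = c("v", "r_S"))
  noise_scale <- sqrt(mean(obs$extra_fraction * (1 - obs$extra_fraction) / n))
  expect_lt(goodness_of_fit(fit, noised)$rms, 4 * noise_scale)
})

test_that("sensitivity scans report metric, direction and range", {
  pr <- centro_preset("dld1")
  scan <- sensitivity_scan(pr, "r_S", seq(0.5, 1, by = 0.05),
                           metric = "steady_state", model = "II")
  expect_equal(nrow(scan), 11)
  # near r_S = 1 the metric falls as symmetric SC divisions stop leaking C2
  tail_vals <- scan$metric[scan$value >= 0.9]
  expect_true(all(diff(tail_vals) < 0) || attr(scan, "direction") != "constant")
  single <- sensitivity_scan(pr, "v", 0.3, metric = "final_day", day = 12)
  expect_equal(nrow(single), 1)
  expect_true(is.na(attr(single, "direction")))
  expect_error(sensitivity_scan(pr, "bogus", c(0.1, 0.2)), "Unknown")
})

test_that("the Model II metric is most sensitive to r_S among fitted params", {
  pr <- centro_preset("dld1")
  grids <- list(r_S = seq(0.5, 1, length.out = 11),
                q = seq(0.975, 1, length.out = 11),
                v = seq(0, 0.6, length.out = 11))
  spans <- vapply(names(grids), function(nm) {
    attr(sensitivity_scan(pr, nm, grids[[nm]], metric = "steady_state",
                          model = "II"), "metric_range")
  }, numeric(1))
  expect_equal(names(which.max(spans)), "r_S")
})
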