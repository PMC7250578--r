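dld1 <- centro_preset("dld1")
rpe1 <- centro_preset("rpe1_p53ko")

test_that("rate matrices carry the model coefficients", {
  P2 <- build_rate_matrix(dld1, "II")
  expect_equal(dim(P2), c(4, 4))
  expect_equal(P2["C2", "C2"], 1.2 * 0.95)   # b_C2 (2q - 1) - d_C2 = 1.14
  expect_equal(P2["SC", "C2"], 1.2 * 0.025 * 0.22)
  expect_equal(P2["C6", "C6"], -1.5)
  # v = 0 collapses Model II onto Model I term by term
  pr0 <- population_params(b_C2 = 1.2, b_C4 = 1, q = 0.975,
                           p_bipolar = 0.33, r = 0.5, fs = 0.4,
                           d_C4 = 0.5, d_C6 = 1.5, v = 0, r_S = 0.93)
  P1 <- build_rate_matrix(pr0, "I")
  P2v0 <- build_rate_matrix(pr0, "II")
  sub <- P2v0[c("C2", "C4", "C6"), c("C2", "C4", "C6")]
  expect_equal(sub, P1, ignore_attr = TRUE)
  # no cytokinesis failure -> no flux from C2 into C4
  pr1 <- population_params(b_C2 = 1, b_C4 = 1, q = 1, p_bipolar = 1,
                           r = 1, fs = 1)
  expect_equal(build_rate_matrix(pr1, "I")["C4", "C2"], 0)
})

test_that("day-0 states split extra-centrosome cells by the SC probability", {
  expect_equal(initial_state(dld1, alpha = 1, total = 7, model = "II"),
               c(C2 = 7, C4 = 0, SC = 0, C6 = 0))
  expect_equal(initial_state(dld1, model = "II"),
               c(C2 = 0.10, C4 = 0.702, SC = 0.198, C6 = 0))
  expect_equal(initial_state(rpe1, model = "II"),
               c(C2 = 0.127, C4 = 0.59364, SC = 0.27936, C6 = 0))
  expect_equal(initial_state(dld1, model = "I"),
               c(C2 = 0.10, C4 = 0.90, C6 = 0))
  expect_equal(initial_state(dld1, model = "II", sc_seeding = "none"),
               c(C2 = 0.10, C4 = 0.90, SC = 0, C6 = 0))
})

test_that("integration matches closed forms and the adaptive integrator", {
  # one-type system dX/dt = bX
  b <- 0.7
  P <- matrix(b, 1, 1, dimnames = list("C2", "C2"))
  tr <- integrate_population(P, c(C2 = 1), times = c(0, 1))
  expect_equal(tr$C2[2], exp(b), tolerance = 1e-10)
  # zero matrix: constant trajectory
  P0 <- matrix(0, 2, 2, dimnames = list(c("C2", "C4"), c("C2", "C4")))
  tr0 <- integrate_population(P0, c(C2 = 2, C4 = 3), times = 0:5)
  expect_true(all(tr0$C2 == 2) && all(tr0$C4 == 3))
  # matrix exponential vs lsoda on the full Model II system
  P2 <- build_rate_matrix(dld1, "II")
  x0 <- initial_state(dld1, model = "II")
  t_expm <- integrate_population(P2, x0, times = 0:12, method = "expm")
  t_ode <- integrate_population(P2, x0, times = 0:12, method = "ode")
  a <- as.matrix(t_expm[-1])
  b <- as.matrix(t_ode[-1])
  rel <- abs(a - b) / pmax(abs(a), abs(b), 1e-6)
  expect_lt(max(rel), 1e-8)
  expect_error(integrate_population(P2, x0, times = c(0, 2, 1)), "increasing")
})

test_that("fractions normalize, sum to one, and satisfy the fraction ODE", {
  P2 <- build_rate_matrix(dld1, "II")
  x0 <- initial_state(dld1, model = "II")
  tr <- integrate_population(P2, x0, times = seq(0, 12, 0.5))
  fr <- population_fractions(tr)
  fcols <- paste0("f_", c("C2", "C4", "SC", "C6"))
  expect_true(all(abs(rowSums(fr[fcols]) - 1) < 1e-9))
  # independent route: integrate the nonlinear fraction ODE directly
  oracle <- integrate_fraction_ode(P2, as.numeric(x0), seq(0, 12, 0.5))
  expect_lt(max(abs(as.matrix(fr[fcols]) - oracle)), 1e-6)
  # degenerate cases
  one <- population_fractions(tibble::tibble(time = 0, C2 = 0, C4 = 5,
                                             SC = 0, C6 = 0))
  expect_equal(as.numeric(one[fcols]), c(0, 1, 0, 0))
  eq <- population_fractions(tibble::tibble(time = 0, C2 = 1, C4 = 1,
                                            SC = 1, C6 = 1))
  expect_equal(as.numeric(eq[fcols]), rep(0.25, 4))
  expect_error(population_fractions(tibble::tibble(time = 0, C2 = 0, C4 = 0,
                                                   SC = 0, C6 = 0)),
               "positive")
})

test_that("extra-centrosome fraction and SC share read out correctly", {
  expect_equal(extra_centrosome_fraction(c(C2 = 1, C4 = 0, SC = 0, C6 = 0)), 0)
  d0 <- initial_state(dld1, model = "II")
  expect_equal(extra_centrosome_fraction(d0), 0.90)
  expect_equal(sc_share_of_extra(d0), 0.22)   # equals v by construction
  tr <- simulate_population(dld1, "II", days = 12, step = 1)
  extra <- extra_centrosome_fraction(tr)
  expect_lt(extra[13], 0.5)                    # far below the day-0 90%
  expect_equal(sc_share_of_extra(c(C2 = 1, C4 = 0, SC = 2, C6 = 0)), 1)
  expect_error(sc_share_of_extra(c(C2 = 1, C4 = 0, SC = 0, C6 = 0)), "extra")
  # convention switch: excluding C6 can only lower the fraction
  expect_true(all(extra_centrosome_fraction(tr, include_C6 = FALSE) <= extra))
})

test_that("Model II with v = 0 and no SC seeding reproduces Model I", {
  pr <- population_params(b_C2 = 1.2, b_C4 = 1, q = 0.975, p_bipolar = 0.33,
                          r = 0.5, fs = 0.4, d_C4 = 0.5, d_C6 = 1.5,
                          v = 0, r_S = 0.93)
  t1 <- integrate_population(build_rate_matrix(pr, "I"),
                             c(C2 = 0.1, C4 = 0.9, C6 = 0), times = 0:12)
  t2 <- integrate_population(build_rate_matrix(pr, "II"),
                             c(C2 = 0.1, C4 = 0.9, SC = 0, C6 = 0),
                             times = 0:12)
  for (st in c("C2", "C4", "C6")) {
    rel <- abs(t2[[st]] - t1[[st]]) / pmax(abs(t1[[st]]), 1e-300)
    expect_lt(max(rel[t1[[st]] > 0]), 1e-10)
  }
  expect_true(all(t2$SC == 0))
})

test_that("pure growth is exactly exponential and abundances stay non-negative", {
  pr <- population_params(b_C2 = 0.9, b_C4 = 1, q = 1, p_bipolar = 1, r = 1,
                          fs = 1)
  tr <- integrate_population(build_rate_matrix(pr, "I"),
                             c(C2 = 1, C4 = 1, C6 = 0), times = 0:5)
  expect_equal(tr$C2, exp(0.9 * (0:5)), tolerance = 1e-10)
  expect_equal(tr$C4, exp(1 * (0:5)), tolerance = 1e-10)
  set.seed(101)
  for (i in 1:10) {
    pr <- random_valid_params()
    tr <- simulate_population(pr, "II", alpha = 0.1, days = 12, step = 0.5)
    expect_true(all(as.matrix(tr[c("C2", "C4", "SC", "C6")]) > -1e-12))
  }
})
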