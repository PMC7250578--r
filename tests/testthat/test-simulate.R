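dld1 <- centro_preset("dld1")

test_that("a population with all rates zero never changes", {
  frozen <- population_params(b_C2 = 0, b_C4 = 0, q = 0.975,
                              p_bipolar = 0.33, r = 0.5, fs = 0.4,
                              v = 0.22, r_S = 0.93)
  sim <- simulate_lineages(frozen, n0 = 100, alpha = 0.1, days = 5,
                           sample_days = 0:5, seed = 1)
  totals <- rowSums(sim[c("C2", "C4", "SC", "C6")])
  expect_true(all(totals == 100))
})

test_that("identical seeds reproduce counts and event logs exactly", {
  a <- simulate_lineages(dld1, n0 = 200, days = 2, sample_days = 0:2,
                         seed = 9, record_events = TRUE)
  b <- simulate_lineages(dld1, n0 = 200, days = 2, sample_days = 0:2,
                         seed = 9, record_events = TRUE)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "events"), attr(b, "events"))
})

test_that("event log daughters follow the fate tables", {
  sim <- simulate_lineages(dld1, n0 = 300, days = 2, sample_days = 0:2,
                           seed = 21, record_events = TRUE)
  ev <- attr(sim, "events")
  asym <- dplyr::filter(ev, kind == "bipolar-asymmetric")
  expect_true(all(asym$daughter1_type == "C2" & asym$daughter2_type == "C6"))
  expect_true(all(asym$cell_type %in% c("C4", "SC")))
  cf <- dplyr::filter(ev, kind == "cytokinesis-failure")
  expect_true(all(cf$cell_type == "C2"))
  expect_true(all(cf$daughter1_type %in% c("C4", "SC")))
  fatal <- dplyr::filter(ev, kind %in% c("multipolar-fatal", "death"))
  expect_true(all(is.na(fatal$daughter1_id) |
                    fatal$kind != "multipolar-fatal"))
  # ids are unique across daughters
  ids <- c(ev$daughter1_id, ev$daughter2_id)
  ids <- ids[!is.na(ids)]
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("ensemble means track the ODE fractions", {
  reps <- 40
  sim <- simulate_lineages(dld1, n0 = 2000, days = 2, sample_days = c(0, 2),
                           cap = 20000, replicates = reps, seed = 31)
  day2 <- dplyr::filter(sim, time == 2)
  fr <- as.matrix(day2[c("C2", "C4", "SC", "C6")]) /
    rowSums(day2[c("C2", "C4", "SC", "C6")])
  tr <- simulate_population(dld1, "II", days = 2, step = 1)
  target <- population_fractions(tr)[3, paste0("f_", c("C2", "C4", "SC", "C6"))]
  for (j in 1:4) {
    se <- stats::sd(fr[, j]) / sqrt(reps)
    expect_lt(abs(mean(fr[, j]) - as.numeric(target[j])), 3 * se + 1e-4)
  }
})

test_that("passaging subsampling leaves expected fractions unchanged", {
  reps <- 40
  capped <- simulate_lineages(dld1, n0 = 1000, days = 2,
                              sample_days = c(0, 2), cap = 1500,
                              replicates = reps, seed = 41)
  free <- simulate_lineages(dld1, n0 = 1000, days = 2, sample_days = c(0, 2),
                            cap = 10^7, replicates = reps, seed = 42)
  frac2 <- function(sim) {
    d <- dplyr::filter(sim, time == 2)
    extra_centrosome_fraction(d)
  }
  fc <- frac2(capped)
  ff <- frac2(free)
  pooled_se <- sqrt(stats::var(fc) / reps + stats::var(ff) / reps)
  expect_lt(abs(mean(fc) - mean(ff)), 4 * pooled_se)
})

test_that("binomial observation sampling behaves at the extremes", {
  tr <- tibble::tibble(time = 0:2, C2 = c(10, 10, 0), C4 = c(0, 0, 10),
                       SC = 0, C6 = 0)
  obs <- sample_observations(tr, 0:1, n = 50, seed = 2)
  expect_true(all(obs$extra_fraction == 0))
  obs2 <- sample_observations(tr, 2, n = 50, seed = 2)
  expect_equal(obs2$extra_fraction, 1)
  expect_identical(sample_observations(tr, 0:2, n = 30, seed = 8),
                   sample_observations(tr, 0:2, n = 30, seed = 8))
  expect_error(sample_observations(tr, 5, n = 30), "not in the trajectory")
  # consistency: large n concentrates on the truth
  tr2 <- tibble::tibble(time = 0, C2 = 3, C4 = 7, SC = 0, C6 = 0)
  big <- sample_observations(tr2, 0, n = 1e6, seed = 3)
  expect_lt(abs(big$extra_fraction - 0.7), 0.005)
})

test_that("karyotypes are copied in bipolar and conserved in multipolar divisions", {
  # chromatid conservation in the partition of a mixed karyotype
  set.seed(13)
  kv <- c(4L, 3L, 1L, 2L, 0L)
  for (p in c(3L, 4L)) {
    d <- centrodyn:::partition_karyotype(kv, p)
    expect_equal(unname(colSums(d)), 2L * kv)
    expect_true(all(d >= 0))
  }
  # no multipolar divisions: every cell keeps the full tetraploid count
  only_bipolar <- population_params(b_C2 = 1.2, b_C4 = 1, q = 0.975,
                                    p_bipolar = 1, r = 0.5, fs = 0.4,
                                    v = 0.22, r_S = 0.93)
  h <- simulate_karyotype_evolution(only_bipolar,
                                    karyotype_config(n_chromosome_types = 23,
                                                     ploidy = 4),
                                    n0 = 30, days = 3, cap = 500, seed = 4)
  expect_true(all(h$chromosome_count == 92))
})

test_that("nullisomy-lethal filtering culls the analytic fraction of daughters", {
  spec <- partition_spec(23, 4, 3)
  n <- 2e4
  sim <- simulate_partitions(spec, n, seed = 99)
  null_by_daughter <- dplyr::summarise(
    dplyr::group_by(sim, division, pole),
    any_null = any(copies == 0), .groups = "drop")
  frac <- mean(null_by_daughter$any_null)
  expected <- cell_event_prob(per_chromosome_prob(spec, "nullisomy"), 23)
  se <- sqrt(expected * (1 - expected) / (3 * n))
  expect_lt(abs(frac - expected), 4 * se)
  # surviving daughters of a lethal-filter run keep at least one copy of all
  h <- simulate_karyotype_evolution(dld1, karyotype_config(), n0 = 100,
                                    days = 2, cap = 1000, seed = 15)
  expect_true(all(h$chromosome_count >= 23))
})
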