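#' Fit free model parameters to an extra-centrosome time course
#'
#' Least-squares fit of selected model parameters to observed per-day
#' fractions of cells with supernumerary centrosomes. The objective is the
#' unweighted sum of squared residuals between the model's
#' extra-centrosome fraction and the observations; when per-day cell
#' counts are available, `weight_by_n = TRUE` switches to inverse-variance
#' weights `n / (f (1 - f))` from the binomial sampling variance.
#'
#' Optimization is deterministic: a regular multi-start grid
#' (`n_starts` points per free dimension across the bounds) is evaluated,
#' and bounded local refinement (`optim`, L-BFGS-B) is run from every grid
#' point; the best refined optimum is returned.
#'
#' @param data A data frame with columns `day` and `extra_fraction`
#'   (optionally `n_cells`), e.g. from [read_time_course()] or
#'   [sample_observations()].
#' @param params A [population_params()] object supplying every parameter
#'   not being fitted.
#' @param free Character vector of parameters to fit, a subset of
#'   `c("v", "r_S", "b_C2", "b_C4", "q")`.
#' @param model `"I"` or `"II"`.
#' @param alpha Day-0 C2 fraction (defaults to the preset's value).
#' @param sc_seeding Day-0 SC seeding rule, see [initial_state()].
#' @param bounds A data frame like [fitting_ranges()] giving `parameter`,
#'   `lower`, `upper`; defaults to the published fitting ranges.
#' @param n_starts Grid points per free dimension for the multi-start.
#' @param weight_by_n Use binomial inverse-variance weights (requires
#'   `n_cells`)?
#' @param include_C6 Convention for the extra-centrosome observable, see
#'   [extra_centrosome_fraction()].
#' @return An object of class `centro_fit` with elements `estimate`,
#'   `loss`, `residuals` (tibble), `convergence`, `fixed`, `bounds`,
#'   `starts`. Supports [tidy()], [glance()] and [augment()].
#' @examples
#' params <- centro_preset("dld1")
#' obs <- simulate_population(params, "II", days = 12, step = 2) |>
#'   dplyr::mutate(extra_fraction = extra_centrosome_fraction(
#'     dplyr::pick(dplyr::everything()))) |>
#'   dplyr::transmute(day = time, extra_fraction)
#' fit_time_course(obs, params, free = c("v", "r_S"))
#' @export
fit_time_course <- function(data, params, free = c("v", "r_S"),
                            model = c("II", "I"), alpha = NULL,
                            sc_seeding = c("split_v", "none"),
                            bounds = fitting_ranges(), n_starts = 5,
                            weight_by_n = FALSE, include_C6 = TRUE) {
  stopifnot(inherits(params, "population_params"))
  model <- arg_match(model)
  sc_seeding <- arg_match(sc_seeding)
  allowed <- c("v", "r_S", "b_C2", "b_C4", "q")
  if (length(free) == 0 || !all(free %in% allowed)) {
    abort(paste0("`free` must be a non-empty subset of: ",
                 paste(allowed, collapse = ", "), "."))
  }
  if (!all(c("day", "extra_fraction") %in% names(data))) {
    abort("`data` must have columns `day` and `extra_fraction`.")
  }
  data <- dplyr::arrange(as_tibble(data), .data$day)
  if (nrow(data) < length(free)) {
    abort(sprintf(
      "Ill-posed fit: %d observation(s) for %d free parameter(s).",
      nrow(data), length(free)))
  }
  if (any(data$extra_fraction < 0 | data$extra_fraction > 1)) {
    abort("`extra_fraction` values must lie in [0, 1].")
  }
  bnd <- as_tibble(bounds)
  missing_b <- setdiff(free, bnd$parameter)
  if (length(missing_b) > 0) {
    abort(paste0("No bounds for parameter(s): ",
                 paste(missing_b, collapse = ", "), "."))
  }
  bnd <- bnd[match(free, bnd$parameter), ]
  if (any(bnd$lower > bnd$upper)) abort("Bounds must satisfy lower <= upper.")
  wts <- rep(1, nrow(data))
  if (weight_by_n) {
    if (!("n_cells" %in% names(data))) {
      abort("`weight_by_n = TRUE` requires an `n_cells` column.")
    }
    f <- pmin(pmax(data$extra_fraction, 1e-6), 1 - 1e-6)
    wts <- data$n_cells / (f * (1 - f))
  }
  if (is.null(alpha)) alpha <- attr(params, "alpha")
  if (is.null(alpha)) abort("`alpha` is required (no preset day-0 value).")

  base <- unclass(params)
  obs_days <- data$day
  loss_fn <- function(theta) {
    pr <- base
    pr[free] <- as.list(theta)
    pr <- structure(pr, class = "population_params")
    P <- build_rate_matrix(pr, model)
    x0 <- initial_state(pr, alpha = alpha, model = model,
                        sc_seeding = sc_seeding)
    ab <- matrix_exp_solve(P, as.numeric(x0), obs_days - obs_days[1])
    pred <- extra_centrosome_fraction(as_tibble(ab), include_C6 = include_C6)
    sum(wts * (pred - data$extra_fraction)^2)
  }

  grids <- purrr::map2(bnd$lower, bnd$upper,
                       function(lo, hi) seq(lo, hi, length.out = n_starts))
  starts <- as.matrix(expand.grid(grids))
  colnames(starts) <- free
  refined <- purrr::map(seq_len(nrow(starts)), function(i) {
    optim(starts[i, ], loss_fn, method = "L-BFGS-B",
          lower = bnd$lower, upper = bnd$upper,
          control = list(factr = 10, ndeps = rep(1e-5, length(free))))
  })
  losses <- purrr::map_dbl(refined, "value")
  best <- refined[[which.min(losses)]]
  est <- setNames(as.numeric(best$par), free)

  pr <- base
  pr[free] <- as.list(est)
  pr <- structure(pr, class = "population_params")
  P <- build_rate_matrix(pr, model)
  x0 <- initial_state(pr, alpha = alpha, model = model,
                      sc_seeding = sc_seeding)
  ab <- matrix_exp_solve(P, as.numeric(x0), obs_days - obs_days[1])
  fitted <- extra_centrosome_fraction(as_tibble(ab), include_C6 = include_C6)
  resid_tbl <- tibble(day = obs_days, observed = data$extra_fraction,
                      fitted = fitted,
                      residual = data$extra_fraction - fitted)

  structure(
    list(estimate = est, loss = best$value, residuals = resid_tbl,
         convergence = best$convergence,
         start_losses = losses,
         bounds = bnd,
         fixed = base[setdiff(names(base), free)],
         model = model, alpha = alpha, sc_seeding = sc_seeding,
         weight_by_n = weight_by_n, include_C6 = include_C6,
         params = pr, data = data),
    class = "centro_fit")
}

#' @method print centro_fit
#' @export
print.centro_fit <- function(x, ...) {
  cat(sprintf("<centro_fit> Model %s, %d observations, loss %.3e\n",
              x$model, nrow(x$residuals), x$loss))
  print(round(x$estimate, 4))
  invisible(x)
}

#' @export
tidy.centro_fit <- function(x, ...) {
  tibble(parameter = names(x$estimate), estimate = unname(x$estimate),
         lower = x$bounds$lower, upper = x$bounds$upper)
}

#' @export
glance.centro_fit <- function(x, ...) {
  tibble(loss = x$loss,
         rms = sqrt(mean(x$residuals$residual^2)),
         n_obs = nrow(x$residuals),
         n_free = length(x$estimate),
         convergence = x$convergence)
}

#' @export
augment.centro_fit <- function(x, ...) x$residuals

#' Residual summary of a fitted time course
#'
#' @param fit A `centro_fit` object.
#' @param data The dataset the fit was produced from (checked against the
#'   fit's recorded observations).
#' @return A list with `rms` (root-mean-square residual) and `residuals`
#'   (per-day tibble).
#' @export
goodness_of_fit <- function(fit, data) {
  stopifnot(inherits(fit, "centro_fit"))
  data <- dplyr::arrange(as_tibble(data), .data$day)
  if (!isTRUE(all.equal(data$day, fit$residuals$day)) ||
      !isTRUE(all.equal(data$extra_fraction, fit$residuals$observed))) {
    abort("`data` does not match the dataset this fit was produced from.")
  }
  list(rms = sqrt(mean(fit$residuals$residual^2)),
       residuals = fit$residuals)
}

#' Scan one parameter and record an extra-centrosome metric
#'
#' Evaluates, over a grid of values of one model parameter (all others held
#' fixed), either the steady-state extra-centrosome fraction (from the
#' leading eigenvector of the rate matrix) or the extra-centrosome fraction
#' at a fixed day of the integrated dynamics.
#'
#' @inheritParams fit_time_course
#' @param parameter Name of the parameter to scan.
#' @param grid Numeric vector of values for the scanned parameter.
#' @param metric `"steady_state"` or `"final_day"`.
#' @param day Evaluation day for `metric = "final_day"`.
#' @return A tibble of class `centro_sensitivity` with columns `parameter`,
#'   `value`, `metric`; attributes `metric_kind`, `direction` (monotone
#'   direction of the metric over the grid, `"increasing"`,
#'   `"decreasing"`, `"constant"` or `"non-monotone"`; `NA` for a single
#'   point) and `metric_range` (max - min of the metric).
#' @examples
#' sensitivity_scan(centro_preset("dld1"), "r_S", seq(0.5, 1, by = 0.05))
#' @export
sensitivity_scan <- function(params, parameter, grid,
                             metric = c("steady_state", "final_day"),
                             model = c("II", "I"), day = 12, alpha = NULL,
                             sc_seeding = c("split_v", "none"),
                             include_C6 = TRUE) {
  stopifnot(inherits(params, "population_params"))
  metric <- arg_match(metric)
  model <- arg_match(model)
  sc_seeding <- arg_match(sc_seeding)
  if (!parameter %in% names(unclass(params))) {
    abort(sprintf("Unknown model parameter '%s'.", parameter))
  }
  if (!is.numeric(grid) || length(grid) < 1) {
    abort("`grid` must be a non-empty numeric vector.")
  }
  if (is.null(alpha)) alpha <- attr(params, "alpha")
  base <- unclass(params)
  vals <- purrr::map_dbl(grid, function(g) {
    pr <- base
    pr[[parameter]] <- g
    validate_population_params(pr)
    pr <- structure(pr, class = "population_params")
    P <- build_rate_matrix(pr, model)
    if (metric == "steady_state") {
      fr <- steady_state(P)$fractions
      extra_centrosome_fraction(fr, include_C6 = include_C6)
    } else {
      if (is.null(alpha)) abort("`alpha` is required for the final-day metric.")
      x0 <- initial_state(pr, alpha = alpha, model = model,
                          sc_seeding = sc_seeding)
      ab <- matrix_exp_solve(P, as.numeric(x0), c(0, day))
      extra_centrosome_fraction(as_tibble(ab),
                                include_C6 = include_C6)[2]
    }
  })
  out <- tibble(parameter = parameter, value = grid, metric = vals)
  d <- diff(vals)
  direction <- if (length(d) == 0) {
    NA_character_
  } else if (all(d >= 0) && any(d > 0)) {
    "increasing"
  } else if (all(d <= 0) && any(d < 0)) {
    "decreasing"
  } else if (all(d == 0)) {
    "constant"
  } else {
    "non-monotone"
  }
  class(out) <- c("centro_sensitivity", class(out))
  attr(out, "metric_kind") <- metric
  attr(out, "direction") <- direction
  attr(out, "metric_range") <- diff(range(vals))
  out
}
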