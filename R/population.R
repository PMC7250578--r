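#' Coefficient matrix of the centrosome-class ODE system
#'
#' Builds the constant coefficient matrix `P` of the linear system
#' `dX/dt = P X` describing the abundances of centrosome classes.
#' Model I tracks (C2, C4, C6):
#' \preformatted{
#'   dC2/dt = b_C2 (2q - 1) C2 + b_C4 p (1 - r) C4            - d_C2 C2
#'   dC4/dt = b_C2 (1 - q) C2 + b_C4 (2pr + (1-p) fs - 1) C4  - d_C4 C4
#'   dC6/dt =                   b_C4 p (1 - r) C4             - d_C6 C6
#' }
#' Model II adds super-clustering (SC) cells, with states
#' (C2, C4, SC, C6): a cytokinesis failure of a C2 cell yields an SC cell
#' with probability `v` (a C4 cell otherwise); SC cells divide at the C2
#' rate, symmetrically (SC + SC) with probability `r_S` and asymmetrically
#' (C2 + C6) otherwise, and die at the C2 death rate. Setting `v = 0`
#' decouples SC, and the (C2, C4, C6) block reduces exactly to Model I.
#'
#' @param params A [population_params()] object.
#' @param model `"I"` or `"II"`.
#' @return A square numeric matrix (3x3 for Model I, 4x4 for Model II) with
#'   state labels as dimnames and attributes `model` and `params`.
#' @examples
#' build_rate_matrix(centro_preset("dld1"), model = "II")
#' @export
build_rate_matrix <- function(params, model = c("II", "I")) {
  stopifnot(inherits(params, "population_params"))
  model <- arg_match(model)
  b2 <- params$b_C2; b4 <- params$b_C4; q <- params$q
  p <- params$p_bipolar; r <- params$r; fs <- params$fs
  d2 <- params$d_C2; d4 <- params$d_C4; d6 <- params$d_C6
  g4 <- b4 * (2 * p * r + (1 - p) * fs - 1) - d4   # net C4 self-term
  if (model == "I") {
    P <- rbind(
      c(b2 * (2 * q - 1) - d2, b4 * p * (1 - r), 0),
      c(b2 * (1 - q),          g4,               0),
      c(0,                     b4 * p * (1 - r), -d6))
    states <- c("C2", "C4", "C6")
  } else {
    v <- params$v; rS <- params$r_S
    P <- rbind(
      c(b2 * (2 * q - 1) - d2,  b4 * p * (1 - r), b2 * (1 - rS),       0),
      c(b2 * (1 - q) * (1 - v), g4,               0,                   0),
      c(b2 * (1 - q) * v,       0,                b2 * (2 * rS - 1) - d2, 0),
      c(0,                      b4 * p * (1 - r), b2 * (1 - rS),       -d6))
    states <- c("C2", "C4", "SC", "C6")
  }
  dimnames(P) <- list(states, states)
  attr(P, "model") <- model
  attr(P, "params") <- params
  P
}

#' Initial abundances of the centrosome classes
#'
#' Day-0 condition for the induced-tetraploidization experiment: a fraction
#' `alpha` of cells escaped the cytokinesis block and remain C2; the rest
#' carry supernumerary centrosomes. Under Model II the default seeding rule
#' splits the day-0 extra-centrosome cells into SC with probability `v` and
#' C4 otherwise, because the day-0 population was created by one induced
#' cytokinesis-failure event and `v` is the probability such an event yields
#' an SC cell; set `sc_seeding = "none"` to start all of them as C4. C6
#' starts at zero.
#'
#' @param params A [population_params()] object.
#' @param alpha Fraction of normal (C2) cells at day 0, in \[0, 1\].
#'   Defaults to the preset's recorded value if `params` carries one.
#' @param total Total initial population (default 1, i.e. fractions).
#' @param model `"I"` or `"II"`.
#' @param sc_seeding `"split_v"` (default, Model II) or `"none"`.
#' @return A named numeric state vector ordered as the rate matrix.
#' @examples
#' initial_state(centro_preset("dld1"), model = "II")
#' @export
initial_state <- function(params, alpha = NULL, total = 1,
                          model = c("II", "I"),
                          sc_seeding = c("split_v", "none")) {
  stopifnot(inherits(params, "population_params"))
  model <- arg_match(model)
  sc_seeding <- arg_match(sc_seeding)
  if (is.null(alpha)) alpha <- attr(params, "alpha")
  if (is.null(alpha)) abort("`alpha` is required when `params` has no preset day-0 value.")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].")
  }
  if (!is.numeric(total) || total <= 0) abort("`total` must be positive.")
  extra <- (1 - alpha) * total
  if (model == "I") {
    c(C2 = alpha * total, C4 = extra, C6 = 0)
  } else {
    v_eff <- if (sc_seeding == "split_v") params$v else 0
    c(C2 = alpha * total, C4 = (1 - v_eff) * extra, SC = v_eff * extra,
      C6 = 0)
  }
}

# exp(P t) x0 for many times via eigen-decomposition; falls back to
# Matrix::expm when P is numerically defective.
matrix_exp_solve <- function(P, x0, times) {
  n <- nrow(P)
  e <- eigen(P)
  use_eigen <- is.finite(rcond(e$vectors)) && rcond(e$vectors) > 1e-10
  out <- matrix(NA_real_, nrow = length(times), ncol = n)
  if (use_eigen) {
    c0 <- solve(e$vectors, x0 + 0i)
    for (i in seq_along(times)) {
      out[i, ] <- Re(e$vectors %*% (exp(e$values * times[i]) * c0))
    }
  } else {
    for (i in seq_along(times)) {
      out[i, ] <- as.numeric(Matrix::expm(P * times[i]) %*% x0)
    }
  }
  colnames(out) <- rownames(P)
  out
}

#' Integrate the centrosome-class ODE system
#'
#' Solves `dX/dt = P X` from `state0` over `times`. The default method is
#' the matrix exponential (exact for a linear constant-coefficient system,
#' evaluated by eigen-decomposition); `method = "ode"` integrates the same
#' system with `deSolve::lsoda` (absolute tolerance 1e-10, relative 1e-8)
#' and is kept as an independent cross-check.
#'
#' @param rate_matrix A matrix from [build_rate_matrix()] (or any square
#'   matrix whose rows/columns are labelled states).
#' @param state0 Named initial state vector matching the matrix states.
#' @param times Increasing numeric vector of output times (days); the first
#'   entry is the initial time.
#' @param method `"expm"` (default) or `"ode"`.
#' @return A `centro_trajectory`: a tibble with column `time` and one
#'   abundance column per state.
#' @examples
#' P <- build_rate_matrix(centro_preset("dld1"), "II")
#' x0 <- initial_state(centro_preset("dld1"), model = "II")
#' integrate_population(P, x0, times = 0:12)
#' @export
integrate_population <- function(rate_matrix, state0, times,
                                 method = c("expm", "ode")) {
  method <- arg_match(method)
  if (!is.matrix(rate_matrix) || nrow(rate_matrix) != ncol(rate_matrix)) {
    abort("`rate_matrix` must be a square matrix.")
  }
  if (any(!is.finite(rate_matrix))) abort("`rate_matrix` has non-finite entries.")
  states <- rownames(rate_matrix)
  if (!is.null(names(state0))) state0 <- state0[states]
  if (length(state0) != nrow(rate_matrix) || any(!is.finite(state0))) {
    abort("`state0` must be a finite vector matching the matrix states.")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.")
  }
  t0 <- times[1]
  if (method == "expm") {
    ab <- matrix_exp_solve(rate_matrix, as.numeric(state0), times - t0)
  } else {
    if (!requireNamespace("deSolve", quietly = TRUE)) {
      abort("method = \"ode\" requires the 'deSolve' package.")
    }
    deriv <- function(t, y, parms) list(as.numeric(rate_matrix %*% y))
    sol <- deSolve::lsoda(as.numeric(state0), times, deriv, parms = NULL,
                          atol = 1e-12, rtol = 1e-10)
    ab <- unname(sol[, -1, drop = FALSE])
    colnames(ab) <- states
  }
  out <- as_tibble(ab)
  out <- dplyr::bind_cols(tibble(time = times), out)
  class(out) <- c("centro_trajectory", class(out))
  attr(out, "model") <- attr(rate_matrix, "model")
  attr(out, "params") <- attr(rate_matrix, "params")
  out
}

#' Simulate the deterministic centrosome-class dynamics
#'
#' One-call wrapper: builds the rate matrix and day-0 state from a
#' parameter set and integrates over a regular time grid.
#'
#' @inheritParams build_rate_matrix
#' @inheritParams initial_state
#' @param days Horizon in days.
#' @param step Output step in days.
#' @inheritParams integrate_population
#' @return A `centro_trajectory` tibble (see [integrate_population()]).
#' @examples
#' simulate_population(centro_preset("dld1"), model = "II", days = 12)
#' @export
simulate_population <- function(params, model = c("II", "I"), alpha = NULL,
                                total = 1, days = 12, step = 0.1,
                                sc_seeding = c("split_v", "none"),
                                method = c("expm", "ode")) {
  model <- arg_match(model)
  P <- build_rate_matrix(params, model)
  x0 <- initial_state(params, alpha = alpha, total = total, model = model,
                      sc_seeding = sc_seeding)
  integrate_population(P, x0, times = seq(0, days, by = step),
                       method = method)
}

state_columns <- function(x) intersect(c("C2", "C4", "SC", "C6"), names(x))

#' Per-type fractions along a trajectory
#'
#' Normalizes abundances to fractions `f_i(t) = X_i(t) / sum_j X_j(t)` and
#' records the total population.
#'
#' @param trajectory A `centro_trajectory` tibble (or any data frame with a
#'   `time` column and abundance columns among C2, C4, SC, C6).
#' @return A tibble with `time`, one `f_<state>` column per state, and
#'   `total`.
#' @export
population_fractions <- function(trajectory) {
  cols <- state_columns(trajectory)
  if (length(cols) == 0) abort("No state columns (C2, C4, SC, C6) found.")
  ab <- as.matrix(trajectory[cols])
  total <- rowSums(ab)
  if (any(total <= 0)) abort("Total population must be positive at all times.")
  f <- ab / total
  colnames(f) <- paste0("f_", cols)
  dplyr::bind_cols(tibble(time = trajectory$time), as_tibble(f),
                   tibble(total = total))
}

#' Fraction of cells with supernumerary centrosomes
#'
#' The observable scored in the time-course experiments: the fraction of
#' cells with more than the normal centrosome number. By default C6 cells
#' are included (any cell with extra centrosomes); the published convention
#' is not stated, so `include_C6 = FALSE` is also supported (C6 cells are a
#' negligible share under the fitted parameters, so the two conventions are
#' nearly identical).
#'
#' @param x A trajectory/fraction data frame with state columns, or a named
#'   state vector.
#' @param include_C6 Count C6 cells as extra-centrosome cells?
#' @return A numeric vector (one value per row/state).
#' @export
extra_centrosome_fraction <- function(x, include_C6 = TRUE) {
  if (is.numeric(x) && !is.null(names(x))) x <- as_tibble(as.list(x))
  cols <- state_columns(x)
  if (!all(c("C2", "C4") %in% cols)) abort("Need at least C2 and C4 columns.")
  ab <- as.matrix(x[cols])
  total <- rowSums(ab)
  if (any(total <= 0)) abort("Total population must be positive.")
  extra_cols <- setdiff(cols, c("C2", if (!include_C6) "C6"))
  unname(rowSums(ab[, extra_cols, drop = FALSE]) / total)
}

#' Share of extra-centrosome cells that are super-clustering cells
#'
#' Among cells with supernumerary centrosomes (C4 + SC + C6), the fraction
#' that are SC cells — the model's prediction for the composition of the
#' surviving extra-centrosome population.
#'
#' @param x A trajectory/fraction data frame with state columns (including
#'   SC), or a named state vector.
#' @return A numeric vector (one value per row/state).
#' @export
sc_share_of_extra <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) x <- as_tibble(as.list(x))
  cols <- state_columns(x)
  if (!("SC" %in% cols)) abort("`x` has no SC column (Model II states).")
  ab <- as.matrix(x[cols])
  extra <- rowSums(ab[, setdiff(cols, "C2"), drop = FALSE])
  if (any(extra <= 0)) abort("No extra-centrosome cells present.")
  unname(ab[, "SC"] / extra)
}
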