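# Independent oracles used across the suite. These deliberately avoid the
# package's own closed-form code paths.

# Exhaustive enumeration of sister-pair pole assignments for one chromosome
# type: returns the exact integer count of assignments in which pole 1
# receives c chromatids, for c = 0..k. Denominator is choose(p, 2)^k.
enumerate_pole1_counts <- function(k, p) {
  pairs <- utils::combn(p, 2)
  grid <- expand.grid(rep(list(seq_len(ncol(pairs))), k))
  cnt <- apply(as.matrix(grid), 1, function(row) {
    sum(pairs[, row, drop = FALSE] == 1)
  })
  tabulate(cnt + 1L, nbins = k + 1L)
}

# Integrate the nonlinear fraction ODE f' = P f - (1' P f) f directly
# (independent route to the normalized-abundance fractions).
integrate_fraction_ode <- function(P, f0, times) {
  colsum <- colSums(P)
  deriv <- function(t, f, parms) {
    list(as.numeric(P %*% f) - sum(colsum * f) * f)
  }
  sol <- deSolve::lsoda(f0, times, deriv, parms = NULL,
                        atol = 1e-12, rtol = 1e-10)
  unname(sol[, -1, drop = FALSE])
}

# Random valid parameter sets with a clearly separated leading eigenvalue
# (so fraction convergence at a 200-day horizon is well-posed).
random_valid_params <- function(min_gap = 0.08) {
  repeat {
    pr <- population_params(
      b_C2 = runif(1, 0.6, 1.2), b_C4 = runif(1, 0.4, 1),
      q = runif(1, 0.9, 1), p_bipolar = runif(1, 0.1, 0.9),
      r = runif(1, 0.1, 0.9), fs = runif(1, 0, 1),
      d_C2 = runif(1, 0, 0.2), d_C4 = runif(1, 0, 1),
      d_C6 = runif(1, 0.5, 2), v = runif(1, 0, 0.6),
      r_S = runif(1, 0.5, 0.99))
    P <- build_rate_matrix(pr, "II")
    ss <- tryCatch(steady_state(P), error = function(e) NULL)
    if (!is.null(ss) && ss$spectral_gap > min_gap &&
        all(ss$fractions > -1e-12)) {
      return(pr)
    }
  }
}
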