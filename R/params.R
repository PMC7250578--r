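#' Rate and probability constants of the centrosome-evolution models
#'
#' Bundles every constant of the population models into one validated
#' object. Cell classes are labelled by mitotic centrosome number: C2
#' (normal), C4 (doubled, from cytokinesis failure), C6 (tripled, from
#' asymmetric clustering), and SC ("super-clustering" C4 cells that cluster
#' their extra centrosomes with high efficiency and divide bipolarly).
#' Model I tracks (C2, C4, C6); Model II adds SC and the parameters `v`
#' and `r_S`, which Model I ignores.
#'
#' @param b_C2 Division rate of C2 (and SC) cells, per day.
#' @param b_C4 Division rate of C4 cells, per day.
#' @param q Probability that a C2 cell divides normally; `1 - q` is the
#'   probability of spontaneous cytokinesis failure.
#' @param p_bipolar Probability that a C4 cell divides bipolarly (the
#'   population model's `p`; multipolar otherwise).
#' @param r Probability that a bipolar C4 division clusters centrosomes
#'   symmetrically (two C4 daughters); asymmetric clustering (`1 - r`)
#'   yields one C2 and one C6 daughter.
#' @param fs Probability that the C4 daughter of a multipolar C4 division
#'   survives (one combined constant; its factors are never used
#'   separately).
#' @param d_C2,d_C4,d_C6 Death rates of C2/SC, C4, and C6 cells, per day.
#' @param v Probability that a cytokinesis-failure event yields an SC cell
#'   (Model II only).
#' @param r_S Probability that an SC cell divides symmetrically (SC + SC);
#'   otherwise C2 + C6 (Model II only).
#'
#' @return An object of class `population_params` (a named list).
#' @seealso [centro_preset()] for published parameter sets.
#' @export
population_params <- function(b_C2, b_C4, q, p_bipolar, r, fs,
                              d_C2 = 0, d_C4 = 0, d_C6 = 0,
                              v = 0, r_S = 1) {
  x <- list(b_C2 = b_C2, b_C4 = b_C4, q = q, p_bipolar = p_bipolar, r = r,
            fs = fs, d_C2 = d_C2, d_C4 = d_C4, d_C6 = d_C6, v = v, r_S = r_S)
  validate_population_params(x)
  structure(x, class = "population_params")
}

validate_population_params <- function(x) {
  rates <- c("b_C2", "b_C4", "d_C2", "d_C4", "d_C6")
  probs <- c("q", "p_bipolar", "r", "fs", "v", "r_S")
  for (nm in c(rates, probs)) {
    val <- x[[nm]]
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val)) {
      abort(sprintf("Parameter `%s` must be a single finite number.", nm))
    }
  }
  for (nm in rates) {
    if (x[[nm]] < 0) abort(sprintf("Rate `%s` must be >= 0.", nm))
  }
  for (nm in probs) {
    if (x[[nm]] < 0 || x[[nm]] > 1) {
      abort(sprintf("Probability `%s` must lie in [0, 1].", nm))
    }
  }
  invisible(x)
}

#' @method print population_params
#' @export
print.population_params <- function(x, ...) {
  cat("<population_params>\n")
  print(tibble(parameter = names(x), value = unlist(x, use.names = FALSE)),
        n = length(x))
  invisible(x)
}

#' Published parameter presets for DLD-1 and RPE-1 p53-null cells
#'
#' Named parameter sets carrying the published per-day rates and
#' probabilities for the two cell lines in which tetraploidization was
#' induced, verbatim: division and death rates from growth and death
#' curves, division-mode probabilities from fixed- and live-cell scoring,
#' and the Model II constants `v` and `r_S` from data fitting.
#'
#' Alongside the rate constants, each preset records the observed day-0
#' fraction of cells with supernumerary centrosomes right after the induced
#' cytokinesis-failure event (90% for DLD-1, 87.3% for RPE-1 p53-null), as
#' attribute `alpha`: the complementary fraction of normal (C2) cells, 0.10
#' and 0.127 respectively.
#'
#' @param name `"dld1"` or `"rpe1_p53ko"`.
#' @return A [population_params()] object with attribute `alpha`.
#' @examples
#' centro_preset("dld1")
#' attr(centro_preset("rpe1_p53ko"), "alpha")
#' @export
centro_preset <- function(name = c("dld1", "rpe1_p53ko")) {
  name <- arg_match(name)
  out <- switch(name,
    dld1 = population_params(
      b_C2 = 1.2, b_C4 = 1, q = 0.975, p_bipolar = 0.33, r = 0.5,
      fs = 0.4, d_C2 = 0, d_C4 = 0.5, d_C6 = 1.5, v = 0.22, r_S = 0.93),
    rpe1_p53ko = population_params(
      b_C2 = 0.94, b_C4 = 0.6, q = 0.975, p_bipolar = 0.25, r = 0.7,
      fs = 0.7, d_C2 = 0, d_C4 = 0.12, d_C6 = 1.5, v = 0.32, r_S = 0.90)
  )
  attr(out, "alpha") <- switch(name, dld1 = 0.10, rpe1_p53ko = 0.127)
  attr(out, "preset") <- name
  out
}

#' Default fitting ranges for the free parameters
#'
#' Bounds used for data fitting of the free model parameters; parameters
#' not listed here are held fixed at their preset values.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
fitting_ranges <- function() {
  tibble(
    parameter = c("v", "r_S", "b_C2", "b_C4", "q"),
    lower = c(0, 0.5, 0.8, 0.6, 0.975),
    upper = c(0.6, 1, 1.2, 1, 1)
  )
}

#' Load model parameters from a preset name or a configuration file
#'
#' A configuration file may be YAML (`.yml`/`.yaml`) or two-column CSV
#' (`parameter,value`). Fields present in the file override the base
#' preset (default `"dld1"` or the file's own `preset` field); all other
#' fields keep their preset values.
#'
#' @param source A preset name (see [centro_preset()]) or a path to a
#'   configuration file.
#' @param base Base preset merged under a configuration file.
#' @return A [population_params()] object.
#' @export
load_params <- function(source, base = "dld1") {
  if (source %in% c("dld1", "rpe1_p53ko")) {
    return(centro_preset(source))
  }
  if (!file.exists(source)) {
    abort(sprintf("Unknown preset or missing file: '%s'.", source))
  }
  vals <- if (grepl("\\.ya?ml$", source, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML configuration requires the 'yaml' package.")
    }
    yaml::read_yaml(source)
  } else {
    df <- readr::read_csv(source, show_col_types = FALSE, comment = "#")
    if (!all(c("parameter", "value") %in% names(df))) {
      abort("Parameter CSV must have columns `parameter` and `value`.")
    }
    setNames(as.list(df$value), df$parameter)
  }
  if (!is.null(vals$preset)) {
    base <- vals$preset
    vals$preset <- NULL
  }
  out <- unclass(centro_preset(base))
  extra <- setdiff(names(vals), c(names(out), "alpha"))
  if (length(extra) > 0) {
    abort(paste0("Unknown parameter(s) in file: ",
                 paste(extra, collapse = ", "), "."))
  }
  alpha <- attr(centro_preset(base), "alpha")
  if (!is.null(vals$alpha)) {
    alpha <- as.numeric(vals$alpha)
    vals$alpha <- NULL
  }
  out[names(vals)] <- lapply(vals, as.numeric)
  validate_population_params(out)
  out <- structure(out, class = "population_params")
  attr(out, "alpha") <- alpha
  out
}
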