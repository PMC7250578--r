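#' Stochastic lineage simulation of the centrosome-class dynamics
#'
#' Exact continuous-time (Gillespie) simulation of the branching process
#' whose mean-field limit is the linear ODE system: each cell of class i
#' waits exponential times for division (rate `b_i`) and death (rate
#' `d_i`); division outcomes are drawn from the model's fate table
#' (`q`, `v`, `p_bipolar`, `r`, `fs`, `r_S`); C6 cells only die (their
#' eventual multipolar divisions are folded into `d_C6`). Whenever the
#' population exceeds `cap`, it is uniformly subsampled back to `cap`
#' (passaging), which bounds memory and compute while leaving expected
#' class fractions unchanged.
#'
#' @inheritParams build_rate_matrix
#' @param n0 Initial total population size.
#' @param alpha Day-0 C2 fraction (defaults to the preset's value); the
#'   initial class counts are the rounded deterministic split of
#'   [initial_state()].
#' @param days Simulation horizon in days.
#' @param sample_days Days at which class counts are recorded (defaults to
#'   every half day up to `days`).
#' @param cap Population cap triggering passaging (default 20000).
#' @param replicates Number of independent replicates.
#' @param seed Optional integer seed set once before the first replicate;
#'   replicates consume one RNG stream sequentially, so a run is fully
#'   reproducible from the root seed.
#' @param sc_seeding Day-0 SC seeding rule, see [initial_state()].
#' @param record_events Keep a per-event lineage log (cell ids, event kind,
#'   daughter ids/types)? Intended for small runs; the log grows with every
#'   event.
#' @param max_events Guard on the number of events per replicate.
#' @return A tibble with columns `replicate`, `time`, `C2`, `C4`, `SC`,
#'   `C6`, `extinct`. When `record_events = TRUE`, attribute `"events"`
#'   holds a tibble with columns `replicate`, `time`, `cell_id`,
#'   `cell_type`, `kind` (`bipolar-symmetric`, `bipolar-asymmetric`,
#'   `multipolar-survive`, `multipolar-fatal`, `cytokinesis-failure`,
#'   `death`), `daughter1_id`, `daughter1_type`, `daughter2_id`,
#'   `daughter2_type`.
#' @examples
#' simulate_lineages(centro_preset("dld1"), n0 = 500, days = 2,
#'                   sample_days = 0:2, seed = 1)
#' @export
simulate_lineages <- function(params, model = c("II", "I"), n0 = 5000,
                              alpha = NULL, days = 12, sample_days = NULL,
                              cap = 20000, replicates = 1, seed = NULL,
                              sc_seeding = c("split_v", "none"),
                              record_events = FALSE, max_events = 1e8) {
  stopifnot(inherits(params, "population_params"))
  model <- arg_match(model)
  sc_seeding <- arg_match(sc_seeding)
  if (!is.numeric(n0) || n0 < 1) abort("`n0` must be a positive integer.")
  if (cap < n0) abort("`cap` must be at least `n0`.")
  if (is.null(sample_days)) sample_days <- seq(0, days, by = 0.5)
  if (any(sample_days < 0) || any(sample_days > days)) {
    abort("`sample_days` must lie within [0, days].")
  }
  sample_days <- sort(unique(sample_days))
  if (!is.null(seed)) set.seed(seed)

  x0 <- initial_state(params, alpha = alpha, total = n0, model = "II",
                      sc_seeding = if (model == "II") sc_seeding else "none")
  init <- round(x0)
  init["C2"] <- n0 - sum(init[c("C4", "SC", "C6")])

  ev_kinds <- c("bipolar-symmetric", "bipolar-asymmetric",
                "multipolar-survive", "multipolar-fatal",
                "cytokinesis-failure", "death")
  types <- c("C2", "C4", "SC", "C6")

  runs <- purrr::map(seq_len(replicates), function(rep) {
    res <- gillespie_core(as.integer(init), unclass(params),
                          model2 = (model == "II"),
                          sample_times = as.numeric(sample_days),
                          cap = as.integer(cap),
                          record_events = record_events,
                          max_events = max_events)
    counts <- res$counts
    colnames(counts) <- types
    tb <- dplyr::bind_cols(
      tibble(replicate = rep, time = sample_days),
      as_tibble(counts))
    tb$extinct <- res$extinct
    ev <- NULL
    if (record_events) {
      ev <- as_tibble(res$events)
      ev$kind <- ev_kinds[ev$kind]
      ev$cell_type <- types[ev$cell_type]
      ev$daughter1_type <- ifelse(ev$daughter1_type == 0, NA_character_,
                                  types[pmax(ev$daughter1_type, 1)])
      ev$daughter2_type <- ifelse(ev$daughter2_type == 0, NA_character_,
                                  types[pmax(ev$daughter2_type, 1)])
      ev$daughter1_id[ev$daughter1_id < 0] <- NA_integer_
      ev$daughter2_id[ev$daughter2_id < 0] <- NA_integer_
      ev <- dplyr::bind_cols(tibble(replicate = rep(rep, nrow(ev))), ev)
    }
    list(counts = tb, events = ev)
  })
  out <- dplyr::bind_rows(purrr::map(runs, "counts"))
  if (record_events) {
    attr(out, "events") <- dplyr::bind_rows(purrr::map(runs, "events"))
  }
  class(out) <- c("centro_counts", class(out))
  attr(out, "model") <- model
  attr(out, "params") <- params
  out
}

#' Binomial observation sampling of a simulated time course
#'
#' Emulates the experimental read-out: on each sampling day, `n` cells are
#' scored and the number with supernumerary centrosomes is
#' `Binomial(n, true fraction)`. The true fraction is taken from the
#' trajectory (simulated counts or deterministic abundances) at that day.
#'
#' @param trajectory A data frame with a `time` column and state columns
#'   (C2, C4, SC, C6), e.g. from [simulate_lineages()] (one replicate) or
#'   [integrate_population()].
#' @param sample_days Days to observe; each must be present in
#'   `trajectory$time`.
#' @param n Cells scored per day.
#' @param seed Optional integer seed.
#' @param cell_line Label recorded in the output.
#' @param include_C6 Observable convention, see
#'   [extra_centrosome_fraction()].
#' @return A tibble with columns `cell_line`, `day`, `extra_fraction`,
#'   `n_cells` — the time-course format accepted by [fit_time_course()].
#' @export
sample_observations <- function(trajectory, sample_days, n, seed = NULL,
                                cell_line = "synthetic",
                                include_C6 = TRUE) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a positive integer.")
  }
  if ("replicate" %in% names(trajectory) &&
      length(unique(trajectory$replicate)) > 1) {
    abort("`trajectory` must be a single replicate.")
  }
  idx <- match(sample_days, trajectory$time)
  if (anyNA(idx)) {
    abort(sprintf("Sampling day(s) not in the trajectory: %s.",
                  paste(sample_days[is.na(idx)], collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  truth <- extra_centrosome_fraction(trajectory[idx, ],
                                     include_C6 = include_C6)
  tibble(
    cell_line = cell_line,
    day = sample_days,
    extra_fraction = rbinom(length(truth), size = n, prob = truth) / n,
    n_cells = as.integer(n)
  )
}

# Partition one karyotype (copy-number vector) across p poles: each
# chromosome with c copies contributes c sister pairs, each assigned to a
# uniformly random unordered pair of distinct poles. Returns a p x M matrix
# of daughter copy numbers; columns sum to 2 * copies.
partition_karyotype <- function(copies, n_poles) {
  m <- length(copies)
  out <- matrix(0L, nrow = n_poles, ncol = m)
  pairs <- utils::combn(n_poles, 2)
  total_pairs <- sum(copies)
  if (total_pairs == 0) return(out)
  idx <- sample.int(ncol(pairs), total_pairs, replace = TRUE)
  chr <- rep.int(seq_len(m), copies)
  for (side in 1:2) {
    pole <- pairs[side, idx]
    out <- out + matrix(tabulate((chr - 1L) * n_poles + pole,
                                 nbins = m * n_poles),
                        nrow = n_poles, ncol = m)
  }
  out
}

#' Karyotype configuration for the multipolar branch of the lineage model
#'
#' @param n_chromosome_types Number of nonhomologous chromosome types.
#' @param ploidy Initial copies per chromosome (4 for newly tetraploid
#'   cells).
#' @param tripolar_prob Probability that a multipolar division is tripolar
#'   (tetrapolar otherwise). Both occur at comparable frequency in newly
#'   formed tetraploid cells, hence the 50:50 default.
#' @param nullisomy_lethal Remove daughters missing all copies of any
#'   chromosome? Nullisomic cells cannot proliferate.
#' @param monosomy_survival Survival probability of a daughter bearing at
#'   least one monosomy (only certain monosomies are lethal, so the default
#'   is 1; set lower to impose a penalty).
#' @return An object of class `karyotype_config`.
#' @export
karyotype_config <- function(n_chromosome_types = 23, ploidy = 4,
                             tripolar_prob = 0.5, nullisomy_lethal = TRUE,
                             monosomy_survival = 1) {
  if (tripolar_prob < 0 || tripolar_prob > 1 ||
      monosomy_survival < 0 || monosomy_survival > 1) {
    abort("Probabilities must lie in [0, 1].")
  }
  spec <- partition_spec(n_chromosome_types, ploidy, 3) # validates M, k
  structure(
    list(n_chromosome_types = spec$n_chromosome_types,
         ploidy = spec$ploidy,
         tripolar_prob = tripolar_prob,
         nullisomy_lethal = nullisomy_lethal,
         monosomy_survival = monosomy_survival),
    class = "karyotype_config")
}

#' Simulate karyotype evolution in a newly tetraploid population
#'
#' Couples the lineage fate rules to the chromosome-partitioning model:
#' every cell divides at rate `b_C4` and dies at rate `d_C4`
#' (continuous-time, exact scheduling). A division is bipolar with
#' probability `p_bipolar`, in which case both daughters inherit the
#' mother's karyotype unchanged (no missegregation in bipolar divisions);
#' otherwise it is multipolar (tripolar or tetrapolar per
#' `kconfig$tripolar_prob`) and each daughter's karyotype is drawn by
#' random sister-pair partitioning of every chromosome. Daughters failing
#' the viability rule (nullisomy lethal; optional monosomy penalty) are
#' removed. The population is uniformly subsampled to `cap` when it grows
#' beyond it.
#'
#' @inheritParams simulate_lineages
#' @param kconfig A [karyotype_config()].
#' @param n0 Initial number of (tetraploid) cells.
#' @param sample_days Days at which chromosome-count histograms are taken
#'   (default integer days).
#' @param cap Population cap (passaging).
#' @return A tibble with columns `day`, `chromosome_count`, `n_cells`
#'   (per-day histogram of total chromosomes per cell). Attribute
#'   `"extinct"` flags an extinct population.
#' @examples
#' simulate_karyotype_evolution(centro_preset("dld1"),
#'   karyotype_config(ploidy = 4), n0 = 20, days = 2, seed = 1)
#' @export
simulate_karyotype_evolution <- function(params, kconfig = karyotype_config(),
                                         n0 = 200, days = 6,
                                         sample_days = NULL, cap = 2000,
                                         seed = NULL) {
  stopifnot(inherits(params, "population_params"),
            inherits(kconfig, "karyotype_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sample_days)) sample_days <- 0:floor(days)
  sample_days <- sort(unique(sample_days))
  if (any(sample_days < 0) || any(sample_days > days)) {
    abort("`sample_days` must lie within [0, days].")
  }
  m <- kconfig$n_chromosome_types
  K <- matrix(as.integer(kconfig$ploidy), nrow = n0, ncol = m)
  b <- params$b_C4
  d <- params$d_C4
  t <- 0
  si <- 1
  hists <- vector("list", length(sample_days))
  take_hist <- function(K, day) {
    cnt <- table(rowSums(K))
    tibble(day = day,
           chromosome_count = as.integer(names(cnt)),
           n_cells = as.integer(cnt))
  }
  viable <- function(kv) {
    if (kconfig$nullisomy_lethal && any(kv == 0)) return(FALSE)
    if (any(kv == 1) && kconfig$monosomy_survival < 1) {
      return(runif(1) < kconfig$monosomy_survival)
    }
    TRUE
  }
  while (t < days && nrow(K) > 0) {
    rate <- (b + d) * nrow(K)
    t <- t + stats::rexp(1, rate)
    while (si <= length(sample_days) && sample_days[si] <= t) {
      hists[[si]] <- take_hist(K, sample_days[si])
      si <- si + 1
    }
    if (t >= days) break
    i <- sample.int(nrow(K), 1)
    if (runif(1) < d / (b + d)) {
      K <- K[-i, , drop = FALSE]
      next
    }
    if (runif(1) < params$p_bipolar) {
      K <- rbind(K, K[i, , drop = FALSE])   # bipolar: faithful copy
    } else {
      p_poles <- if (runif(1) < kconfig$tripolar_prob) 3L else 4L
      daughters <- partition_karyotype(K[i, ], p_poles)
      keep <- vapply(seq_len(p_poles),
                     function(j) viable(daughters[j, ]), logical(1))
      K <- rbind(K[-i, , drop = FALSE], daughters[keep, , drop = FALSE])
    }
    if (nrow(K) > cap) K <- K[sample.int(nrow(K), cap), , drop = FALSE]
  }
  while (si <= length(sample_days)) {
    if (nrow(K) > 0) hists[[si]] <- take_hist(K, sample_days[si])
    si <- si + 1
  }
  out <- dplyr::bind_rows(hists)
  attr(out, "extinct") <- nrow(K) == 0
  out
}
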