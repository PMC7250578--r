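#' Specify the geometry of a multipolar division
#'
#' A partition specification describes one cell division in the random
#' chromosome-partitioning model: a mother cell carrying `ploidy` replicated
#' copies (sister-chromatid pairs) of each of `n_chromosome_types`
#' nonhomologous chromosomes divides with `n_poles` spindle poles. Sister
#' chromatids of each pair always go to two *different* poles (missegregation
#' during bipolar division is ignored); which pair of poles receives them is
#' uniform over all unordered pole pairs, independently for every chromatid
#' pair and every chromosome type.
#'
#' @param n_chromosome_types Number of nonhomologous chromosome types
#'   (23 for human cells).
#' @param ploidy Number of replicated copies of each chromosome in the mother
#'   cell, i.e. sister-chromatid pairs per chromosome type (4 for a tetraploid
#'   mother).
#' @param n_poles Number of spindle poles, at least 2 (2 = bipolar,
#'   3 = tripolar, 4 = tetrapolar).
#'
#' @return An object of class `partition_spec`.
#' @examples
#' tripolar_4n <- partition_spec(n_chromosome_types = 23, ploidy = 4, n_poles = 3)
#' per_chromosome_prob(tripolar_4n, "nullisomy")
#' @export
partition_spec <- function(n_chromosome_types = 23, ploidy = 4, n_poles = 3) {
  stopifnot(length(n_chromosome_types) == 1, length(ploidy) == 1,
            length(n_poles) == 1)
  if (!is.numeric(n_chromosome_types) || n_chromosome_types < 1 ||
      n_chromosome_types != round(n_chromosome_types)) {
    abort("`n_chromosome_types` must be a positive integer.")
  }
  if (!is.numeric(ploidy) || ploidy < 1 || ploidy != round(ploidy)) {
    abort("`ploidy` must be a positive integer.")
  }
  if (!is.numeric(n_poles) || n_poles < 2 || n_poles != round(n_poles)) {
    abort("`n_poles` must be an integer >= 2.")
  }
  structure(
    list(n_chromosome_types = as.integer(n_chromosome_types),
         ploidy = as.integer(ploidy),
         n_poles = as.integer(n_poles)),
    class = "partition_spec"
  )
}

#' @method print partition_spec
#' @export
print.partition_spec <- function(x, ...) {
  cat(sprintf(
    "<partition_spec> %d chromosome types, ploidy %d, %d poles\n",
    x$n_chromosome_types, x$ploidy, x$n_poles))
  invisible(x)
}

#' Number of equally likely sister-pair pole assignments per chromosome
#'
#' Each of the `ploidy` sister-chromatid pairs of one chromosome type can be
#' assigned to any unordered pair of distinct poles, so one chromosome type
#' has `choose(n_poles, 2)^ploidy` equally likely assignments.
#'
#' @param spec A [partition_spec()].
#' @return A positive number (integer-valued).
#' @examples
#' count_partitions(partition_spec(ploidy = 4, n_poles = 3)) # 3^4 = 81
#' @export
count_partitions <- function(spec) {
  stopifnot(inherits(spec, "partition_spec"))
  choose(spec$n_poles, 2)^spec$ploidy
}

#' Per-chromosome probabilities of nullisomy and monosomy at one pole
#'
#' Closed-form probabilities that a *given* pole (equivalently, the daughter
#' cell formed around it) receives zero chromatids (nullisomy) or exactly one
#' chromatid (monosomy) of one chromosome type, under uniform random
#' partitioning of sister-chromatid pairs to pole pairs. With `k = ploidy`
#' and `p = n_poles`:
#' \deqn{P(\mathrm{nullisomy}) = ((p-2)/p)^k}
#' \deqn{P(\mathrm{monosomy}) = 2k(p-2)^{k-1}/p^k}
#' The two events are mutually exclusive for one chromosome, so
#' `"either"` is their sum. All three are zero for a bipolar division
#' (`p = 2`), where the forced sister split gives every pole exactly `k`
#' chromatids.
#'
#' Note this is the probability for a *given* daughter cell, not for the
#' division as a whole (no factor `p`). The returned value is the binomial
#' parameter often written `q_event`; it is unrelated to the population
#' model's `q` (probability of normal division of a C2 cell).
#'
#' @param spec A [partition_spec()].
#' @param event One of `"nullisomy"`, `"monosomy"`, `"either"`.
#' @return A probability.
#' @examples
#' spec <- partition_spec(ploidy = 4, n_poles = 3)
#' per_chromosome_prob(spec, "nullisomy") # 1/81
#' per_chromosome_prob(spec, "monosomy")  # 8/81
#' per_chromosome_prob(spec, "either")    # 1/9
#' @export
per_chromosome_prob <- function(spec,
                                event = c("nullisomy", "monosomy", "either")) {
  stopifnot(inherits(spec, "partition_spec"))
  event <- arg_match(event)
  k <- spec$ploidy
  p <- spec$n_poles
  switch(event,
    nullisomy = ((p - 2) / p)^k,
    monosomy  = 2 * k * (p - 2)^(k - 1) / p^k,
    either    = ((p - 2)^k + 2 * k * (p - 2)^(k - 1)) / p^k
  )
}

#' Probability that a daughter cell is affected for at least one chromosome
#'
#' Chromosome types partition independently, so the probability that a
#' daughter cell bears the event (nullisomy, monosomy, or either) for at
#' least one of `n_chromosome_types` chromosomes is
#' `1 - (1 - per_chromosome_prob)^M`.
#'
#' @param per_chromosome_prob Per-chromosome event probability in \[0, 1\],
#'   e.g. from [per_chromosome_prob()].
#' @param n_chromosome_types Number of chromosome types `M`.
#' @return A probability.
#' @examples
#' spec <- partition_spec(ploidy = 4, n_poles = 3)
#' cell_event_prob(per_chromosome_prob(spec, "nullisomy"), 23)
#' @export
cell_event_prob <- function(per_chromosome_prob, n_chromosome_types) {
  if (!is.numeric(per_chromosome_prob) ||
      any(per_chromosome_prob < 0 | per_chromosome_prob > 1)) {
    abort("`per_chromosome_prob` must lie in [0, 1].")
  }
  if (!is.numeric(n_chromosome_types) || any(n_chromosome_types < 1) ||
      any(n_chromosome_types != round(n_chromosome_types))) {
    abort("`n_chromosome_types` must be a positive integer.")
  }
  1 - (1 - per_chromosome_prob)^n_chromosome_types
}

#' Per-chromosome and per-cell event probabilities as a tibble
#'
#' Convenience summary of all three events for one division geometry.
#'
#' @param spec A [partition_spec()].
#' @return A tibble with columns `event`, `per_chromosome_prob`, `cell_prob`.
#' @export
partition_event_probs <- function(spec) {
  stopifnot(inherits(spec, "partition_spec"))
  events <- c("nullisomy", "monosomy", "either")
  qs <- vapply(events, function(e) per_chromosome_prob(spec, e), numeric(1))
  tibble(
    event = events,
    per_chromosome_prob = unname(qs),
    cell_prob = cell_event_prob(unname(qs), spec$n_chromosome_types)
  )
}

#' Distribution of the number of affected chromosomes in a daughter cell
#'
#' Chromosome types are independent and identically distributed under the
#' partitioning model, so the number of chromosomes affected by the event in
#' one daughter cell follows a binomial law `B(M, q_event)`, with `q_event`
#' the per-chromosome probability.
#'
#' @inheritParams per_chromosome_prob
#' @return A tibble with columns `n_affected` (0..M), `probability`, plus
#'   attributes `event` and `per_chromosome_prob`.
#' @examples
#' event_count_distribution(partition_spec(ploidy = 4, n_poles = 3), "nullisomy")
#' @export
event_count_distribution <- function(spec,
                                     event = c("nullisomy", "monosomy",
                                               "either")) {
  stopifnot(inherits(spec, "partition_spec"))
  event <- arg_match(event)
  q <- per_chromosome_prob(spec, event)
  m <- spec$n_chromosome_types
  out <- tibble(
    n_affected = 0:m,
    probability = dbinom(0:m, size = m, prob = q)
  )
  attr(out, "event") <- event
  attr(out, "per_chromosome_prob") <- q
  out
}

# Draw partition outcomes for n independent chromosome types (or divisions):
# returns an n x p integer matrix of chromatid counts per pole. Each of the
# k sister pairs goes to a uniformly random unordered pair of distinct poles.
draw_partition_counts <- function(n, k, p) {
  pairs <- utils::combn(p, 2)            # 2 x choose(p, 2)
  n_pairs <- ncol(pairs)
  idx <- sample.int(n_pairs, n * k, replace = TRUE)
  row_of <- rep(seq_len(n), each = k)
  counts <- matrix(0L, nrow = n, ncol = p)
  # accumulate one chromatid at each pole of the chosen pair
  for (side in 1:2) {
    pole <- pairs[side, idx]
    tab <- tabulate((row_of - 1L) * p + pole, nbins = n * p)
    counts <- counts + matrix(tab, nrow = n, ncol = p, byrow = TRUE)
  }
  counts
}

#' Simulate random chromosome partitioning in multipolar divisions
#'
#' Monte-Carlo oracle for the closed-form probabilities: simulates
#' `n_divisions` independent divisions under the partitioning rules of
#' [partition_spec()] and reports the chromatid copy number each pole
#' (daughter cell) receives for each chromosome type. Within one division
#' the copy numbers of each chromosome type sum to `2 * ploidy` across
#' poles (chromatid conservation).
#'
#' @param spec A [partition_spec()].
#' @param n_divisions Number of independent divisions to simulate.
#' @param seed Optional integer seed set before simulation for
#'   reproducibility.
#' @return A tibble with columns `division`, `chromosome`, `pole`, `copies`.
#' @examples
#' simulate_partitions(partition_spec(1, 4, 3), n_divisions = 2, seed = 1)
#' @export
simulate_partitions <- function(spec, n_divisions, seed = NULL) {
  stopifnot(inherits(spec, "partition_spec"))
  if (!is.numeric(n_divisions) || length(n_divisions) != 1 ||
      n_divisions < 1 || n_divisions != round(n_divisions)) {
    abort("`n_divisions` must be a positive integer.")
  }
  if (!is.null(seed)) set.seed(seed)
  m <- spec$n_chromosome_types
  k <- spec$ploidy
  p <- spec$n_poles
  n <- as.integer(n_divisions)
  counts <- draw_partition_counts(n * m, k, p)   # rows: division-major, chr within
  tibble(
    division = rep(rep(seq_len(n), each = m), each = p),
    chromosome = rep(rep(seq_len(m), times = n), each = p),
    pole = rep(seq_len(p), times = n * m),
    copies = as.integer(t(counts))
  )
}
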