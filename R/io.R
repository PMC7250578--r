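#' Read an extra-centrosome time course from CSV
#'
#' Expects columns `cell_line`, `day`, `extra_fraction` and optionally
#' `n_cells`; lines starting with `#` are treated as metadata comments.
#' Rows are validated (fractions in \[0, 1\], days unique per cell line,
#' positive integer cell counts) and returned sorted by day.
#'
#' @param path Path to a CSV file.
#' @return A tibble with the validated time course.
#' @export
read_time_course <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("cell_line", "day", "extra_fraction")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", "), "."))
  }
  bad <- which(df$extra_fraction < 0 | df$extra_fraction > 1)
  if (length(bad) > 0) {
    abort(sprintf("`extra_fraction` outside [0, 1] at row(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  dup <- df |>
    dplyr::count(.data$cell_line, .data$day) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate day(s) within a cell line: %s.",
                  paste(unique(dup$day), collapse = ", ")))
  }
  if ("n_cells" %in% names(df)) {
    badn <- which(df$n_cells <= 0 | df$n_cells != round(df$n_cells))
    if (length(badn) > 0) {
      abort(sprintf("`n_cells` must be positive integers; bad row(s): %s.",
                    paste(badn, collapse = ", ")))
    }
  }
  dplyr::arrange(df, .data$cell_line, .data$day)
}

metadata_header <- function(seed = NULL, params = NULL) {
  lines <- c(
    sprintf("# centrodyn %s",
            as.character(utils::packageVersion("centrodyn"))),
    sprintf("# written %s", format(Sys.time(), "%Y-%m-%d")))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %s", seed))
  if (!is.null(params)) {
    lines <- c(lines, paste0(
      "# params: ",
      paste(sprintf("%s=%g", names(unclass(params)),
                    unlist(unclass(params))), collapse = " ")))
  }
  lines
}

#' Write a time course or trajectory to a self-describing CSV
#'
#' Writes the table with `#`-prefixed metadata header lines recording the
#' package version and, when supplied, the seed and full parameter set.
#' Columns are written in their current (deterministic) order with 12
#' significant digits, so write-then-read round-trips are lossless at that
#' precision.
#'
#' @param x A data frame (time course, trajectory, fractions, ...).
#' @param path Output path.
#' @param seed Optional seed to record in the header.
#' @param params Optional [population_params()] to record in the header.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(x, path, seed = NULL, params = NULL) {
  if (is.null(params)) params <- attr(x, "params")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(metadata_header(seed = seed, params = params), con)
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(col) signif(col, 12))
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a trajectory with fractions and derived observables
#'
#' Augments a trajectory with per-type fractions, the extra-centrosome
#' fraction, and (Model II) the SC share among extra-centrosome cells,
#' then writes it with [write_time_course()]. A consistency check verifies
#' the fraction columns sum to 1 within 1e-9 on every row.
#'
#' @param trajectory A `centro_trajectory` tibble.
#' @param path Output path.
#' @inheritParams write_time_course
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, seed = NULL, params = NULL) {
  fr <- population_fractions(trajectory)
  fcols <- grep("^f_", names(fr), value = TRUE)
  stopifnot(all(abs(rowSums(fr[fcols]) - 1) < 1e-9))
  out <- dplyr::bind_cols(
    trajectory, fr[fcols],
    tibble(extra_fraction = extra_centrosome_fraction(trajectory)))
  if ("SC" %in% names(trajectory)) {
    out$sc_share_of_extra <- sc_share_of_extra(trajectory)
  }
  write_time_course(out, path, seed = seed, params = params)
}
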