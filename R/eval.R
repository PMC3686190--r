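#' Random calibration/evaluation split
#'
#' Disjoint, exhaustive, seed-reproducible split of occurrence records; the
#' calibration set gets `round(n * fraction)` rows.
#'
#' @param occurrences a tibble of occurrence records.
#' @param fraction calibration fraction in (0, 1); default 0.70.
#' @param seed RNG seed.
#' @return A list with tibbles `calibration` and `evaluation`.
#' @export
split_occurrences <- function(occurrences, fraction = 0.70, seed = 1) {
  n <- nrow(occurrences)
  if (n < 2) stop("need at least 2 records to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  }
  n_cal <- round(n * fraction)
  idx <- withr::with_seed(seed, sample.int(n, n_cal))
  list(calibration = occurrences[sort(idx), , drop = FALSE],
       evaluation = occurrences[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Presence-background AUC
#'
#' Rank-based area under the ROC curve: the probability that a random
#' presence point outscores a random background point, ties counting one
#' half. Invariant under strictly monotone transforms of the scores.
#'
#' @param presence,background numeric score vectors (non-empty).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence, background) {
  np <- length(presence); nb <- length(background)
  if (np == 0 || nb == 0) {
    stop("presence and background scores must be non-empty", call. = FALSE)
  }
  r <- rank(c(presence, background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Median habitat similarity index
#'
#' @param scores non-empty numeric vector of HSI scores.
#' @return The sample median.
#' @export
median_hsi <- function(scores) {
  if (length(scores) == 0) stop("`scores` must be non-empty", call. = FALSE)
  stats::median(scores)
}

#' HSI threshold covering a fraction of leks
#'
#' The lower empirical quantile (inverse-ECDF, type 1) of the lek HSI
#' scores at probability `1 - coverage`, so that at least `coverage` of the
#' leks have HSI at or above the returned value.
#'
#' @param lek_hsi non-empty numeric vector of lek HSI scores.
#' @param coverage target fraction of leks above the threshold, in (0, 1);
#'   default 0.90.
#' @return The threshold HSI value.
#' @export
hsi_threshold <- function(lek_hsi, coverage = 0.90) {
  if (length(lek_hsi) == 0) stop("`lek_hsi` must be non-empty", call. = FALSE)
  if (coverage <= 0 || coverage >= 1) {
    stop("`coverage` must be in (0, 1)", call. = FALSE)
  }
  stats::quantile(lek_hsi, probs = 1 - coverage, type = 1, names = FALSE)
}

#' Dose-response curve of HSI against an environmental variable
#'
#' Bins the study-area range of a variable into `n_bins` equal-width bins
#' and summarizes, per bin, the mean and SD of HSI over in-mask cells and
#' the proportion of leks falling in the bin. Mirrors the classic
#' dose-response display: study-area mean HSI with a +/- 1 SD band and lek
#' proportion bars.
#'
#' @param variable_grid matrix (or [eco_raster]) of the variable over the
#'   study area; `NA` outside.
#' @param hsi_raster matrix or [eco_raster] of HSI values, aligned.
#' @param lek_values the variable's values at lek locations.
#' @param n_bins number of bins (>= 2); default 20.
#' @param lek_hsi optional lek HSI scores used to annotate the curve with
#'   the coverage threshold.
#' @param coverage coverage for the threshold annotation.
#' @return An `eco_dose_response` tibble: `bin, lower, upper, mid,
#'   mean_hsi, sd_hsi, n_cells, lek_prop, empty`, with attributes
#'   `hsi_threshold` and `variable`.
#' @export
dose_response <- function(variable_grid, hsi_raster, lek_values,
                          n_bins = 20, lek_hsi = NULL, coverage = 0.90,
                          variable = "variable") {
  v <- as.vector(as_values_matrix(variable_grid))
  h <- as.vector(as_values_matrix(hsi_raster))
  if (length(v) != length(h)) {
    stop("variable and HSI grids must be aligned", call. = FALSE)
  }
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  ok <- !is.na(v) & !is.na(h)
  rng <- range(v[ok])
  if (diff(rng) <= 0) {
    stop("variable has a degenerate range over the study area",
         call. = FALSE)
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin_of <- function(x) {
    b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    b[x < rng[1] | x > rng[2]] <- NA_integer_
    b
  }
  cell_bin <- bin_of(v[ok])
  lek_bin <- bin_of(lek_values)
  cells <- tibble::tibble(bin = cell_bin, hsi = h[ok]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_hsi = mean(.data$hsi),
                     sd_hsi = stats::sd(.data$hsi),
                     n_cells = dplyr::n(), .groups = "drop")
  out <- tibble::tibble(bin = seq_len(n_bins),
                        lower = edges[-length(edges)],
                        upper = edges[-1]) |>
    dplyr::mutate(mid = (.data$lower + .data$upper) / 2) |>
    dplyr::left_join(cells, by = "bin") |>
    dplyr::mutate(
      n_cells = dplyr::coalesce(.data$n_cells, 0L),
      sd_hsi = dplyr::if_else(.data$n_cells == 1L, 0, .data$sd_hsi),
      lek_prop = as.numeric(
        tabulate(lek_bin[!is.na(lek_bin)], n_bins)) / length(lek_values),
      empty = .data$n_cells == 0L
    )
  attr(out, "variable") <- variable
  attr(out, "hsi_threshold") <-
    if (is.null(lek_hsi)) NA_real_ else hsi_threshold(lek_hsi, coverage)
  class(out) <- c("eco_dose_response", class(out))
  out
}

#' Variable importance for the ecological-minimum partition
#'
#' Per variable: the absolute loading on the boundary partition `k`, the
#' aggregate tail loading `sqrt(sum_{j >= k} e_{j,i}^2)`, and the Spearman
#' correlation between the variable and the HSI scores. A variable is
#' flagged important when its boundary loading exceeds
#' `loading_threshold` and its absolute correlation exceeds `cor_floor`.
#'
#' @param model a fitted, partition-selected model.
#' @param hsi_scores HSI scores aligned with the table rows.
#' @param table a variable table holding the model's variables.
#' @param loading_threshold flag threshold on `|loading_k|`; default 0.3.
#' @param cor_floor flag floor on `|spearman|`; default 0.3.
#' @return A tibble: `variable, loading_k, loading_tail, spearman,
#'   important`.
#' @export
variable_importance <- function(model, hsi_scores, table,
                                loading_threshold = 0.3, cor_floor = 0.3) {
  if (is.na(model$k_selected)) {
    stop("select a boundary partition first", call. = FALSE)
  }
  X <- as.matrix(table[model$variables])
  if (nrow(X) != length(hsi_scores)) {
    stop("`hsi_scores` must align with the table rows", call. = FALSE)
  }
  p <- length(model$eigvals)
  k <- model$k_selected
  tail_cols <- model$eigvecs[, k:p, drop = FALSE]
  rho <- apply(X, 2, function(col) {
    suppressWarnings(stats::cor(col, hsi_scores, method = "spearman"))
  })
  tibble::tibble(
    variable = model$variables,
    loading_k = abs(model$eigvecs[, k]),
    loading_tail = sqrt(rowSums(tail_cols^2)),
    spearman = as.numeric(rho),
    important = .data$loading_k > loading_threshold &
      abs(.data$spearman) > cor_floor
  )
}

#' Per-variable group summaries (active / historic / study area)
#'
#' Mean, standard error, range, and normal-approximation 95% confidence
#' interval (`mean +/- 1.96 SE`) for every variable in every group.
#'
#' @param groups named list of variable tables (e.g. `active`, `historic`,
#'   `study_area`).
#' @param variables variable columns; default from the first table.
#' @return A long tibble: `group, variable, n, mean, se, min, max,
#'   ci_lower, ci_upper`.
#' @export
group_summary <- function(groups, variables = NULL) {
  if (!is.list(groups) || is.null(names(groups))) {
    stop("`groups` must be a named list of tables", call. = FALSE)
  }
  for (nm in names(groups)) {
    if (is.null(groups[[nm]]) || nrow(groups[[nm]]) == 0) {
      stop("empty group: ", nm, call. = FALSE)
    }
  }
  variables <- variable_columns(groups[[1]], variables)
  purrr::imap_dfr(groups, function(tab, nm) {
    tab |>
      dplyr::select(dplyr::all_of(variables)) |>
      tidyr::pivot_longer(dplyr::everything(), names_to = "variable") |>
      dplyr::group_by(.data$variable) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean = mean(.data$value),
        se = stats::sd(.data$value) / sqrt(dplyr::n()),
        min = min(.data$value),
        max = max(.data$value),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        se = dplyr::if_else(is.na(.data$se), 0, .data$se),
        ci_lower = mean - 1.96 * .data$se,
        ci_upper = mean + 1.96 * .data$se,
        group = nm, .before = 1
      )
  })
}
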