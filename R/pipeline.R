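#' Default demonstration configuration
#'
#' The stock synthetic study: a 64 x 64 grid of 1-km cells with 10
#' spatially autocorrelated variables, a planted niche with 2 minimum
#' directions (SD 0.1 against 1.0 on the free subspace), 8 populations of
#' unequal size summing to 500 leks, 99 historic locations, 500 background
#' points,
#' a 70/30 calibration/evaluation split, and a 1000-iteration bootstrap
#' capped at 25 leks per population.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @return A named list consumable by [run_pipeline()].
#' @export
demo_config <- function(seed = 7) {
  list(
    seed = as.integer(seed),
    n_rows = 64, n_cols = 64, cell_km = 1,
    p = 10, corr_length = 3,
    m = 2, sigma_min = 0.1, sigma_free = 1.0, presence_quantile = 0.25,
    n_pops = 8, leks_per_pop = c(100, 85, 75, 65, 55, 45, 40, 35),
    spread_cells = 5,
    count_meanlog = 2.3, count_sdlog = 1,
    n_historic = 99, n_background = 500,
    split_fraction = 0.70,
    n_boot = 1000, pop_cap = 25,
    k = NULL, eigval_threshold = 1.0, k_policy = "auc",
    n_bins = 20, coverage = 0.90, dose_variables = 2,
    connectivity = TRUE, neighborhood = 8, r_max = 1e5, hsi_floor = 1e-5,
    resistance_method = "reciprocal"
  )
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the [demo_config()] defaults.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(demo_config(), user)
}

pipeline_seed <- function(config, offset) {
  (config$seed + offset * 10007L) %% 2147483647L
}

#' Run the full synthetic analysis pipeline
#'
#' Simulate a landscape with a planted niche, extract the variable table,
#' split, fit the bootstrap-averaged partition model, select the boundary
#' partition, map the HSI, evaluate (AUC, median HSI, coverage threshold,
#' dose-response, variable importance, group summaries), and solve the
#' circuit-theory connectivity model. Every stage is seeded from
#' `config$seed`, so the pipeline is a pure function of the configuration;
#' with `out_dir` set, all tables, the model and the rasters are written to
#' disk.
#'
#' @param config a configuration list; see [demo_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress progress messages.
#' @return A list bundling every intermediate and final artifact: the
#'   stack, occurrence tables, fitted `model`, `diagnostics`, `hsi` raster,
#'   `evaluation` summary tibble, `dose` curves, `importance`,
#'   `group_summary`, and (unless disabled) `resistance` and `current`.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  say("simulate: ", config$n_rows, " x ", config$n_cols, " grid, p = ",
      config$p)
  lc <- stage("simulate", landscape_config(
    config$n_rows, config$n_cols, config$cell_km, config$p,
    config$corr_length, seed = pipeline_seed(config, 1)))
  niche <- stage("simulate", planted_niche(
    p = config$p, m = config$m, sigma_min = config$sigma_min,
    sigma_free = config$sigma_free,
    presence_quantile = config$presence_quantile,
    seed = pipeline_seed(config, 2)))
  layout <- stage("simulate", population_layout(
    lc, n_pops = config$n_pops, spread_cells = config$spread_cells,
    leks_per_pop = config$leks_per_pop,
    count_meanlog = config$count_meanlog, count_sdlog = config$count_sdlog,
    seed = pipeline_seed(config, 3)))
  stack <- stage("simulate", gen_env_stack(lc, niche, layout))
  occurrences <- stage("simulate", gen_occurrences(
    stack, niche, layout, seed = pipeline_seed(config, 4)))
  historic <- stage("simulate", gen_historic(
    stack, niche, config$n_historic, seed = pipeline_seed(config, 5)))
  background <- stage("simulate", sample_background(
    stack, config$n_background, seed = pipeline_seed(config, 6)))

  say("extract: variable tables")
  tab_occ <- stage("extract", extract_table(stack, occurrences))
  tab_hist <- stage("extract", extract_table(stack, historic))
  tab_bg <- stage("extract", extract_table(stack, background))

  say("split: calibration fraction ", config$split_fraction)
  halves <- stage("split", split_occurrences(
    tab_occ, config$split_fraction, seed = pipeline_seed(config, 7)))

  say("fit: ", config$n_boot, " bootstrap iterations, cap ",
      config$pop_cap)
  model <- stage("fit", bootstrap_fit(
    halves$calibration, n_boot = config$n_boot, pop_cap = config$pop_cap,
    seed = pipeline_seed(config, 8)))

  diagnostics <- stage("diagnostics", partition_diagnostics(
    model, halves$calibration, halves$evaluation, tab_hist, tab_bg))
  k <- config$k
  if (is.null(k)) {
    k <- stage("diagnostics", choose_k(diagnostics,
                                       threshold = config$eigval_threshold,
                                       policy = config$k_policy))
  }
  model <- stage("fit", select_partition(model, k = k))
  say("fit: selected boundary partition k = ", model$k_selected)

  say("map: HSI raster")
  hsi_map <- stage("map", map_hsi(stack, model))

  say("evaluate")
  sc_cal <- stage("evaluate", score_table(halves$calibration, model))
  sc_eval <- stage("evaluate", score_table(halves$evaluation, model))
  sc_hist <- stage("evaluate", score_table(tab_hist, model))
  sc_bg <- stage("evaluate", score_table(tab_bg, model))
  sc_all <- stage("evaluate", score_table(tab_occ, model))
  evaluation <- tibble::tibble(
    k_selected = model$k_selected,
    df = model$df,
    auc_evaluation = auc(sc_eval$hsi, sc_bg$hsi),
    median_hsi_calibration = median_hsi(sc_cal$hsi),
    median_hsi_evaluation = median_hsi(sc_eval$hsi),
    median_hsi_historic = median_hsi(sc_hist$hsi),
    hsi_threshold = hsi_threshold(sc_all$hsi, config$coverage),
    coverage = config$coverage,
    orth_dev = model$orth_dev
  )

  dose_vars <- model$variables[seq_len(min(config$dose_variables,
                                           length(model$variables)))]
  dose <- stage("dose_response", purrr::map(
    stats::setNames(dose_vars, dose_vars),
    function(v) dose_response(stack$layers[[v]], hsi_map,
                              lek_values = tab_occ[[v]],
                              n_bins = config$n_bins,
                              lek_hsi = sc_all$hsi,
                              coverage = config$coverage, variable = v)))

  importance <- stage("importance", variable_importance(
    model, sc_all$hsi, tab_occ))
  groups <- stage("group_summary", group_summary(list(
    active = tab_occ, historic = tab_hist, study_area = tab_bg)))

  resistance <- current <- NULL
  if (isTRUE(config$connectivity)) {
    say("connect: ", nrow(occurrences), " source iterations, ",
        config$neighborhood, "-neighborhood")
    resistance <- stage("connect", resistance_from_hsi(
      hsi_map, r_max = config$r_max, hsi_floor = config$hsi_floor,
      method = config$resistance_method))
    graph <- stage("connect", build_graph(resistance,
                                          config$neighborhood))
    current <- stage("connect", solve_all_to_one(graph, occurrences))
  }

  out <- list(
    config = config, stack = stack, niche = niche, layout = layout,
    occurrences = occurrences, historic = historic, background = background,
    calibration = halves$calibration, evaluation_set = halves$evaluation,
    model = model, diagnostics = diagnostics, hsi = hsi_map,
    scores = list(calibration = sc_cal, evaluation = sc_eval,
                  historic = sc_hist, background = sc_bg, active = sc_all),
    evaluation = evaluation, dose = dose, importance = importance,
    group_summary = groups, resistance = resistance, current = current
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
  jsonlite::write_json(result$config,
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  w(result$occurrences, "occurrences.csv")
  w(result$historic, "historic.csv")
  w(result$background, "background.csv")
  w(result$diagnostics, "diagnostics.csv")
  w(result$evaluation, "evaluation.csv")
  w(result$importance, "importance.csv")
  w(result$group_summary, "group_summary.csv")
  for (nm in names(result$dose)) {
    w(result$dose[[nm]], sprintf("dose_response_%s.csv", nm))
  }
  write_model(result$model, file.path(out_dir, "model.json"))
  write_ascii_grid(result$hsi, file.path(out_dir, "hsi.asc"))
  if (!is.null(result$resistance)) {
    write_ascii_grid(result$resistance, file.path(out_dir, "resistance.asc"))
    write_ascii_grid(result$current$raster,
                     file.path(out_dir, "current.asc"))
    w(result$current$per_source, "current_per_source.csv")
  }
  invisible(out_dir)
}
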