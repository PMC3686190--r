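# Shared small fixtures, built in code. Sizes are kept small so the whole
# suite stays fast; the heavier end-to-end checks live in test-acceptance.R.

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- landscape_config(48, 48, cell_km = 1, p = 6, corr_length = 2,
                              seed = 11)
      niche <- planted_niche(p = 6, m = 2, sigma_min = 0.1, sigma_free = 1,
                             presence_quantile = 0.3, seed = 12)
      layout <- population_layout(cfg, n_pops = 4, spread_cells = 4,
                                  leks_per_pop = c(30, 25, 20, 15),
                                  seed = 13)
      stack <- gen_env_stack(cfg, niche, layout)
      occ <- gen_occurrences(stack, niche, layout, seed = 14)
      cache <<- list(cfg = cfg, niche = niche, layout = layout,
                     stack = stack, occ = occ,
                     tab = extract_table(stack, occ))
    }
    cache
  }
})

# iid standard-normal variable table with bookkeeping columns
random_table <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    colnames(X) <- sprintf("v%02d", seq_len(p))
    dplyr::bind_cols(
      tibble::tibble(x_km = seq_len(n) + 0.5, y_km = 0.5,
                     row = 0L, col = seq_len(n) - 1L,
                     population = rep_len(1:4, n), count = 1,
                     status = "active"),
      tibble::as_tibble(X)
    )
  })
}

# uniform 1 x n resistance chain graph
chain_graph <- function(n, r = 1) {
  build_graph(matrix(r, 1, n), neighborhood = 4)
}

table1_path <- function() {
  system.file("extdata", "table1_eigenvalues.csv", package = "ecominima")
}
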