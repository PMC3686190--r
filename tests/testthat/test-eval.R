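test_that("splits are disjoint, exhaustive, reproducible and size-correct", {
  tab <- random_table(10, 3)
  sp <- split_occurrences(tab, 0.7, seed = 1)
  expect_equal(nrow(sp$calibration), 7)
  expect_equal(nrow(sp$evaluation), 3)
  both <- dplyr::bind_rows(sp$calibration, sp$evaluation)
  expect_equal(dplyr::arrange(both, col), tab)
  expect_identical(split_occurrences(tab, 0.7, seed = 1), sp)
  sp2 <- split_occurrences(tab, 0.3, seed = 5)
  expect_equal(nrow(sp2$calibration), nrow(sp$evaluation))
  expect_error(split_occurrences(tab, 1.2), "fraction")
  expect_error(split_occurrences(tab[1, ], 0.5), "at least 2")
})

test_that("auc matches pair enumeration, the tie rule, and pROC", {
  expect_equal(auc(rep(1, 5), rep(0, 7)), 1)
  expect_equal(auc(c(0.9, 0.8), c(0.85, 0.1)), 0.75)  # 3 wins of 4 pairs
  expect_equal(auc(c(0.5, 0.7), c(0.5, 0.2)), 0.875)  # 3 wins + 1 tie of 4
  withr::with_seed(3, {
    pres <- rnorm(300)
    bg <- rnorm(400)
  })
  expect_equal(auc(pres, bg), 0.5, tolerance = 0.1)
  # independent oracle on irregular scores
  expect_equal(auc(pres, bg),
               as.numeric(pROC::auc(pROC::roc(
                 response = c(rep(1, 300), rep(0, 400)),
                 predictor = c(pres, bg), quiet = TRUE,
                 direction = "<"))))
  expect_error(auc(numeric(0), bg), "non-empty")
})

test_that("auc is invariant under monotone transforms and complement-symmetric", {
  withr::with_seed(4, {
    a <- runif(50); b <- runif(60)
  })
  base <- auc(a, b)
  expect_equal(auc(qlogis(a), qlogis(b)), base)
  expect_equal(auc(a^3, b^3), base)
  expect_equal(auc(a, b) + auc(b, a), 1)
})

test_that("median_hsi is the sample median with an empty guard", {
  expect_equal(median_hsi(1), 1)
  expect_equal(median_hsi(c(0, 1)), 0.5)
  expect_equal(median_hsi(c(0.2, 0.8, 0.9)), 0.8)
  expect_error(median_hsi(numeric(0)), "non-empty")
})

test_that("hsi_threshold is the inverse-ECDF quantile covering the leks", {
  scores <- seq(0.1, 1, by = 0.1)
  expect_equal(hsi_threshold(scores, 0.9), 0.1)
  expect_equal(hsi_threshold(scores, 0.8), 0.2)
  expect_equal(hsi_threshold(scores, 1 - 1e-9), 0.1)
  expect_equal(hsi_threshold(rep(0.4, 9), 0.9), 0.4)
  withr::with_seed(5, {
    s <- runif(137)
  })
  for (cov in c(0.5, 0.75, 0.9)) {
    thr <- hsi_threshold(s, cov)
    expect_gte(mean(s >= thr), cov)
    expect_true(thr %in% s)   # an observed order statistic
  }
  expect_error(hsi_threshold(s, 1.5), "coverage")
})

test_that("dose-response bins summarize HSI and lek proportions", {
  v <- matrix(rep(seq(0, 1, length.out = 20), each = 20), 20, 20)
  h <- matrix(0.5, 20, 20)
  leks <- c(0.05, 0.06, 0.07)   # all in the first bin
  dr <- dose_response(v, h, leks, n_bins = 10)
  expect_equal(nrow(dr), 10)
  expect_equal(dr$mean_hsi, rep(0.5, 10))
  expect_equal(dr$sd_hsi, rep(0, 10))
  expect_equal(dr$lek_prop, c(1, rep(0, 9)))
  expect_equal(sum(dr$lek_prop), 1, tolerance = 1e-9)
  # uniform variable over 2 bins: cell counts within 1 of each other
  dr2 <- dose_response(v, h, leks, n_bins = 2)
  expect_lte(abs(diff(dr2$n_cells)), 1)
  expect_error(dose_response(matrix(1, 5, 5), matrix(0.5, 5, 5), 1),
               "degenerate")
  expect_error(dose_response(v, matrix(0.5, 3, 3), leks), "aligned")
})

test_that("dose-response threshold annotation uses lek coverage", {
  v <- matrix(runif(400), 20, 20)
  h <- matrix(runif(400), 20, 20)
  lek_hsi <- seq(0.1, 1, by = 0.1)
  dr <- dose_response(v, h, runif(10), n_bins = 5, lek_hsi = lek_hsi,
                      coverage = 0.9)
  expect_equal(attr(dr, "hsi_threshold"), 0.1)
})

test_that("variable importance flags strong loadings correlated with HSI", {
  w <- small_world()
  fit <- select_partition(fit_single(w$tab))
  sc <- score_table(w$tab, fit)
  imp <- variable_importance(fit, sc$hsi, w$tab)
  expect_named(imp,
               c("variable", "loading_k", "loading_tail", "spearman",
                 "important"))
  expect_equal(imp$loading_k, abs(fit$eigvecs[, fit$k_selected]))
  p <- length(fit$eigvals)
  expect_equal(imp$loading_tail,
               sqrt(rowSums(fit$eigvecs[, fit$k_selected:p]^2)))
  # HSI independent of a noise column: near-zero correlation, not flagged
  noise_tab <- dplyr::mutate(w$tab, var01 = withr::with_seed(1, runif(dplyr::n())))
  rho <- suppressWarnings(cor(noise_tab$var01, sc$hsi, method = "spearman"))
  expect_lt(abs(rho), 0.25)
  expect_error(variable_importance(fit, sc$hsi[-1], w$tab), "align")
})

test_that("importance flagging respects the 0.3 loading threshold", {
  tab <- random_table(50, 2, seed = 9)
  fit <- select_partition(fit_single(tab), k = 2)
  # construct a model whose boundary loadings straddle the threshold
  fit$eigvecs[, 2] <- c(sqrt(1 - 0.12^2), 0.12)   # loadings 0.99, 0.12
  hsi_scores <- as.numeric(scale(tab$v01))        # correlated with v01 only
  imp <- variable_importance(fit, hsi_scores, tab)
  expect_identical(imp$important, c(TRUE, FALSE))
})

test_that("group summaries report mean, SE and normal CIs per variable", {
  g <- list(
    active = tibble::tibble(v = c(0, 2), w = c(1, 1)),
    historic = tibble::tibble(v = c(5, 5, 5), w = c(2, 4, 6))
  )
  gs <- group_summary(g, variables = c("v", "w"))
  act_v <- gs[gs$group == "active" & gs$variable == "v", ]
  expect_equal(act_v$mean, 1)
  expect_equal(act_v$se, 1)             # sd sqrt(2), n = 2
  expect_equal(act_v$ci_lower, 1 - 1.96)
  hist_v <- gs[gs$group == "historic" & gs$variable == "v", ]
  expect_equal(hist_v$se, 0)
  expect_equal(hist_v$ci_upper - hist_v$ci_lower, 0)
  expect_equal(act_v[c("min", "max")], tibble::tibble(min = 0, max = 2))
  expect_error(group_summary(list(a = g$active[0, ])), "empty group")
})
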