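test_that("single fits match closed-form correlation eigenstructure", {
  # p = 2, known correlation r: eigenvalues are 1 + r and 1 - r
  withr::with_seed(1, {
    n <- 400
    a <- rnorm(n)
    b <- 0.8 * a + sqrt(1 - 0.8^2) * rnorm(n)
  })
  tab <- tibble::tibble(v1 = a, v2 = b)
  fit <- fit_single(tab, c("v1", "v2"))
  r <- cor(a, b)
  expect_equal(fit$eigvals, c(1 + r, 1 - r), tolerance = 1e-10)
  expect_equal(sum(fit$eigvals), 2, tolerance = 1e-6)

  # uncorrelated standardized data: eigenvalues near (1, 1)
  withr::with_seed(2, {
    tab2 <- tibble::tibble(v1 = rnorm(2000), v2 = rnorm(2000))
  })
  expect_equal(fit_single(tab2)$eigvals, c(1, 1), tolerance = 0.1)
})

test_that("fit_single rejects degenerate inputs by name", {
  tab <- random_table(30, 4)
  tab$v02 <- 1
  expect_error(fit_single(tab), "v02")
  expect_error(fit_single(random_table(4, 5)), "n > p")
  expect_error(fit_single(random_table(20, 3), c("v01", "nope")), "nope")
})

test_that("trace conservation and unit eigenvectors hold on random fits", {
  for (seed in 1:5) {
    tab <- random_table(60, 7, seed = seed)
    fit <- fit_single(tab)
    expect_equal(sum(fit$eigvals), 7, tolerance = 1e-6)
    expect_equal(colSums(fit$eigvecs^2), rep(1, 7), tolerance = 1e-10)
    expect_true(all(diff(fit$eigvals) <= 1e-9))
  }
})

test_that("partition contributions are additive to the direct Mahalanobis form", {
  tab <- random_table(200, 10, seed = 3)
  fit <- fit_single(tab)
  X <- as.matrix(tab[fit$variables])
  Rinv <- solve(cor(X))
  withr::with_seed(4, {
    Q <- matrix(rnorm(50 * 10, sd = 2), 50, 10)
  })
  for (i in seq_len(nrow(Q))) {
    x <- Q[i, ]
    z <- (x - fit$mu) / fit$sigma
    expect_equal(sum(partition_contributions(x, fit)),
                 drop(t(z) %*% Rinv %*% z), tolerance = 1e-8)
  }
  expect_equal(partition_contributions(as.numeric(fit$mu), fit),
               rep(0, 10))
  expect_error(partition_contributions(1:3, fit), "length")
})

test_that("d2_k conventions: tail sum, single partition, and bounds", {
  tab <- random_table(100, 6, seed = 5)
  fit <- fit_single(tab)
  x <- as.numeric(tab[7, fit$variables])
  ctr <- partition_contributions(x, fit)
  expect_equal(d2_k(x, fit, k = 1), sum(ctr))
  expect_equal(d2_k(x, fit, k = 6), ctr[6])
  expect_equal(d2_k(x, fit, k = 3), sum(ctr[3:6]))
  expect_equal(d2_k(x, fit, k = 4, mode = "single"), ctr[4])
  expect_equal(d2_k(as.numeric(fit$mu), fit, k = 2), 0)
  expect_error(d2_k(x, fit, k = 0), "1..p")
  expect_error(d2_k(x, fit, k = 7), "1..p")
})

test_that("HSI rescale is the chi-square upper tail: 1 at 0, monotone, correct quantile", {
  expect_equal(hsi(0, df = 3), 1)
  expect_equal(hsi(3.841, df = 1), 0.05, tolerance = 1e-3)
  d2 <- seq(0, 50, by = 0.25)
  h <- hsi(d2, df = 4)
  expect_true(all(diff(h) < 0))
  expect_lt(hsi(1e6, df = 4), 1e-12)
  expect_error(hsi(-1, df = 2), "non-negative")
  fit <- select_partition(fit_single(random_table(50, 4, 8)), k = 3)
  expect_equal(fit$df, 2)
  expect_equal(hsi(0, fit), 1)
})

test_that("bootstrap with full samples reproduces the single fit", {
  tab <- random_table(60, 5, seed = 6)
  # cap above every population size and a single iteration: no resampling
  bf <- bootstrap_fit(tab, n_boot = 1, pop_cap = 100, seed = 1)
  sf <- fit_single(tab)
  expect_equal(bf$eigvals, sf$eigvals, tolerance = 1e-12)
  expect_equal(abs(bf$eigvecs), abs(sf$eigvecs), tolerance = 1e-12)
  expect_equal(bf$mu, sf$mu)
  # several iterations of the full sample: still the single fit
  bf5 <- bootstrap_fit(tab, n_boot = 5, pop_cap = 100, seed = 2)
  expect_equal(bf5$eigvals, sf$eigvals, tolerance = 1e-12)
  expect_lt(bf5$orth_dev, 1e-10)
})

test_that("bootstrap averaging agrees with an independent subsample-mean oracle", {
  tab <- random_table(1000, 6, seed = 7)
  bf1 <- bootstrap_fit(tab, n_boot = 200, pop_cap = 25, seed = 11)
  bf2 <- bootstrap_fit(tab, n_boot = 200, pop_cap = 25, seed = 22)
  expect_false(identical(bf1$eigvals, bf2$eigvals))
  # oracle: mean of sorted correlation eigenvalues over independent
  # per-population subsamples, computed directly
  pops <- split(seq_len(nrow(tab)), tab$population)
  oracle <- withr::with_seed(99, {
    draws <- replicate(200, {
      idx <- unlist(lapply(pops, function(ii) ii[sample.int(length(ii), 25)]))
      sort(eigen(cor(as.matrix(tab[idx, sprintf("v%02d", 1:6)])),
                 symmetric = TRUE, only.values = TRUE)$values,
           decreasing = TRUE)
    })
    list(mean = rowMeans(draws),
         se = apply(draws, 1, sd) / sqrt(ncol(draws)))
  })
  tol <- 6 * oracle$se
  expect_true(all(abs(bf1$eigvals - oracle$mean) < tol))
  expect_true(all(abs(bf2$eigvals - oracle$mean) < tol))
  expect_equal(sum(bf1$eigvals), 6, tolerance = 1e-8)
})

test_that("planted minimum directions are recovered from generated data", {
  w <- small_world()
  fit <- fit_single(w$tab)
  expect_equal(sort(fit$eigvals)[1:2], c(0, 0), tolerance = 0.05)
  cosines <- principal_angle_cosines(minimum_directions(fit, 2),
                                     w$niche$B_min)
  expect_true(all(cosines >= 0.9))
})

test_that("select_partition applies the eigenvalue <= 1 rule and sets df", {
  fit <- fit_single(w <- small_world()$tab)
  sel <- select_partition(fit)
  expect_equal(sel$k_selected, min(which(fit$eigvals <= 1)))
  expect_equal(sel$df, length(fit$eigvals) - sel$k_selected + 1)
  expect_error(select_partition(fit, k = 99), "1..p")
})

test_that("map_hsi honours the mean, nodata and the [0,1] range", {
  w <- small_world()
  fit <- select_partition(fit_single(w$tab), k = 5)
  hs <- map_hsi(w$stack, fit)
  v <- hs$values
  expect_true(all(is.na(v[w$stack$nodata_mask])))
  expect_true(all(v[!w$stack$nodata_mask] >= 0 &
                  v[!w$stack$nodata_mask] <= 1))
  # a stack equal to the fitted mean everywhere scores HSI 1 in-mask
  const <- lapply(seq_along(fit$mu), function(j) {
    m <- matrix(fit$mu[j], 10, 10)
  })
  names(const) <- fit$variables
  st1 <- env_stack(const)
  expect_true(all(map_hsi(st1, fit)$values == 1))
  st_missing <- env_stack(const[-1])
  expect_error(map_hsi(st_missing, fit), "var01")
})

test_that("partition diagnostics carry the eigenvalue ladder and per-k medians", {
  w <- small_world()
  fit <- fit_single(w$tab)
  halves <- split_occurrences(w$tab, 0.7, seed = 2)
  hist <- extract_table(w$stack, gen_historic(w$stack, w$niche, 30, 21))
  bg <- extract_table(w$stack, sample_background(w$stack, 80, 22))
  d <- partition_diagnostics(fit, halves$calibration, halves$evaluation,
                             hist, bg)
  expect_equal(d$eigval, fit$eigvals)
  expect_equal(d$delta_eigval[-1], -diff(fit$eigvals))
  expect_true(all(d$delta_eigval[-1] >= -1e-9))
  # identical point sets give identical median columns
  d2 <- partition_diagnostics(fit, halves$calibration, halves$calibration,
                              hist, bg)
  expect_equal(d2$median_hsi_calibration, d2$median_hsi_evaluation)
  expect_error(partition_diagnostics(fit, halves$calibration,
                                     halves$evaluation, hist[0, ], bg),
               "historic")
})

test_that("choose_k prefers the best-evaluating qualifying partition", {
  d <- tibble::tibble(k = 1:5, eigval = c(2, 1.4, 0.9, 0.5, 0.1),
                      auc_evaluation = c(0.9, 0.85, 0.7, 0.82, 0.75))
  expect_equal(choose_k(d, policy = "eigval"), 3)
  expect_equal(choose_k(d, policy = "auc"), 4)
  none <- dplyr::mutate(d, eigval = eigval + 10)
  expect_equal(choose_k(none, policy = "auc"), 5)
})

test_that("models round-trip through JSON and tidy/glance summarize them", {
  w <- small_world()
  fit <- select_partition(fit_single(w$tab))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f)
  back <- read_model(f)
  expect_equal(back$eigvals, fit$eigvals)
  expect_equal(back$eigvecs, fit$eigvecs, ignore_attr = TRUE)
  expect_equal(back$mu, fit$mu)
  expect_equal(back$k_selected, fit$k_selected)
  x <- as.numeric(w$tab[3, fit$variables])
  expect_equal(d2_k(x, back), d2_k(x, fit))

  td <- tidy(fit)
  expect_equal(td$eigval, fit$eigvals)
  expect_equal(sum(td$in_tail), fit$df)
  gl <- glance(fit)
  expect_equal(gl$eigval_sum, sum(fit$eigvals))
  expect_equal(gl$k_selected, fit$k_selected)
})
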