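OCCURRENCE_COLS <- c("x_km", "y_km", "row", "col", "population", "count",
                     "status")

variable_columns <- function(table, variables = NULL) {
  if (is.null(variables)) {
    variables <- setdiff(names(table), OCCURRENCE_COLS)
  }
  missing <- setdiff(variables, names(table))
  if (length(missing)) {
    stop("table lacks variable column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  variables
}

new_partition_model <- function(mu, sigma, eigvals, eigvecs, variables,
                                n, n_boot = 0L, pop_cap = NA_integer_,
                                seed = NA_integer_, orth_dev = 0,
                                d2_mode = "tail") {
  structure(
    list(mu = mu, sigma = sigma, eigvals = eigvals, eigvecs = eigvecs,
         variables = variables, n = n, k_selected = NA_integer_,
         df = NA_real_, n_boot = n_boot, pop_cap = pop_cap, seed = seed,
         orth_dev = orth_dev, d2_mode = d2_mode),
    class = "eco_partition_model"
  )
}

#' Fit a partitioned Mahalanobis distance model (single fit)
#'
#' Computes the occurrence means and SDs, standardizes, and
#' eigen-decomposes the p x p correlation matrix of the occurrence data.
#' Eigenvalues are returned in descending order with unit eigenvectors;
#' partitions are orthogonal and additive, summing to the full-rank
#' Mahalanobis distance.
#'
#' @param table a variable table (e.g. from [extract_table()]): occurrence
#'   bookkeeping columns plus `p` numeric variables.
#' @param variables variable column names; default every non-bookkeeping
#'   column.
#' @return An `eco_partition_model`; call [select_partition()] to set the
#'   boundary partition before computing HSI.
#' @export
fit_single <- function(table, variables = NULL) {
  variables <- variable_columns(table, variables)
  X <- as.matrix(table[variables])
  n <- nrow(X); p <- ncol(X)
  if (n <= p) {
    stop(sprintf("need n > p occurrences (n = %d, p = %d)", n, p),
         call. = FALSE)
  }
  mu <- colMeans(X)
  sigma <- apply(X, 2, stats::sd)
  const <- sigma <= 0 | !is.finite(sigma)
  if (any(const)) {
    stop("constant variable(s): ", paste(variables[const], collapse = ", "),
         call. = FALSE)
  }
  R <- stats::cor(X)
  ed <- eigen(R, symmetric = TRUE)
  new_partition_model(
    mu = stats::setNames(mu, variables),
    sigma = stats::setNames(sigma, variables),
    eigvals = ed$values,
    eigvecs = ed$vectors,
    variables = variables, n = n
  )
}

#' Bootstrap-averaged, sign-corrected partition model
#'
#' Per iteration, at most `pop_cap` occurrences are drawn from each
#' population (without replacement by default), a single model is fitted,
#' components are matched across iterations by eigenvalue rank, and
#' eigenvector signs are aligned to a running mean reference (a column is
#' flipped when its dot product with the reference is negative). The final
#' model is the element-wise mean of the per-iteration means, SDs,
#' eigenvalues and eigenvectors; averaged eigenvectors are renormalized to
#' unit length and the residual orthogonality deviation
#' `max |e_i . e_j|, i != j` is stored in `$orth_dev`.
#'
#' @inheritParams fit_single
#' @param population_col column holding the population id.
#' @param n_boot number of bootstrap iterations.
#' @param pop_cap per-population cap on occurrences per iteration.
#' @param seed RNG seed.
#' @param replace sample populations with replacement instead of
#'   subsampling without replacement.
#' @return An `eco_partition_model` with bootstrap metadata.
#' @export
bootstrap_fit <- function(table, variables = NULL,
                          population_col = "population",
                          n_boot = 1000, pop_cap = 25, seed = 1,
                          replace = FALSE) {
  variables <- variable_columns(table, variables)
  if (!population_col %in% names(table)) {
    stop("missing population column '", population_col, "'", call. = FALSE)
  }
  pops <- split(seq_len(nrow(table)), table[[population_col]])
  p <- length(variables)
  withr::with_seed(seed, {
    sum_mu <- sum_sigma <- numeric(p)
    sum_vals <- numeric(p)
    sum_vecs <- matrix(0, p, p)
    ref <- NULL
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(pops, function(ii) {
        if (replace) {
          ii[sample.int(length(ii), min(length(ii), pop_cap),
                        replace = TRUE)]
        } else if (length(ii) > pop_cap) {
          ii[sample.int(length(ii), pop_cap)]
        } else ii
      }), use.names = FALSE)
      fit <- fit_single(table[idx, , drop = FALSE], variables)
      V <- fit$eigvecs
      if (is.null(ref)) {
        ref <- V
      } else {
        flip <- colSums(V * ref) < 0
        V[, flip] <- -V[, flip]
      }
      sum_mu <- sum_mu + fit$mu
      sum_sigma <- sum_sigma + fit$sigma
      sum_vals <- sum_vals + fit$eigvals
      sum_vecs <- sum_vecs + V
      ref <- sum_vecs / b      # running mean reference for sign alignment
    }
    vecs <- sum_vecs / n_boot
    vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), `/`)
    G <- abs(crossprod(vecs)); diag(G) <- 0
    new_partition_model(
      mu = sum_mu / n_boot, sigma = sum_sigma / n_boot,
      eigvals = sum_vals / n_boot, eigvecs = vecs,
      variables = variables, n = nrow(table),
      n_boot = as.integer(n_boot), pop_cap = as.integer(pop_cap),
      seed = as.integer(seed), orth_dev = max(G)
    )
  })
}

#' Select the boundary partition
#'
#' Default rule: the smallest `k` whose eigenvalue is at most
#' `threshold` (1.0) — partitions with eigenvalues <= 1 explain little
#' variance and represent the invariant, "ecological minimum" relationships.
#' The chi-square degrees of freedom for the HSI rescale are set to the
#' number of summed partitions, `p - k + 1` (or 1 in single-partition mode).
#'
#' @param model an `eco_partition_model`.
#' @param k explicit boundary partition; overrides the rule.
#' @param threshold eigenvalue threshold for the default rule.
#' @return The model with `k_selected` and `df` set.
#' @export
select_partition <- function(model, k = NULL, threshold = 1.0) {
  p <- length(model$eigvals)
  if (is.null(k)) {
    below <- which(model$eigvals <= threshold)
    k <- if (length(below)) min(below) else p
  }
  if (k < 1 || k > p) stop("`k` must be in 1..p", call. = FALSE)
  model$k_selected <- as.integer(k)
  model$df <- if (identical(model$d2_mode, "tail")) p - k + 1 else 1
  model
}

#' Per-partition contributions to the Mahalanobis distance
#'
#' For a raw variable vector `x`: standardize `z = (x - mu) / sigma`, then
#' `c_j = (e_j . z)^2 / lambda_j`. The contributions are orthogonal and sum
#' to the full-rank distance `z' R^{-1} z`.
#'
#' @param x length-p raw variable vector (order of `model$variables`).
#' @param model a fitted `eco_partition_model`.
#' @return Length-p numeric vector of contributions.
#' @export
partition_contributions <- function(x, model) {
  p <- length(model$mu)
  if (length(x) != p) {
    stop(sprintf("`x` must have length %d", p), call. = FALSE)
  }
  z <- (x - model$mu) / model$sigma
  lam <- pmax(model$eigvals, 1e-10)
  if (any(model$eigvals < 1e-10)) {
    warning("eigenvalue(s) below 1e-10 floored in partition contributions")
  }
  as.numeric((crossprod(model$eigvecs, z))^2 / lam)
}

# Vectorized contributions: rows of X are points; returns n x p matrix.
contributions_matrix <- function(X, model) {
  Z <- sweep(sweep(X, 2, model$mu), 2, model$sigma, `/`)
  lam <- pmax(model$eigvals, 1e-10)
  sweep((Z %*% model$eigvecs)^2, 2, lam, `/`)
}

#' Reduced-rank distance D2(k)
#'
#' In the default `"tail"` convention, `D2(k)` sums partitions `k..p` — the
#' minimum-variance tail of the partition ladder, so `k = 1` recovers the
#' full-rank distance. The `"single"` convention returns partition `k`
#' alone.
#'
#' @inheritParams partition_contributions
#' @param k boundary partition in 1..p; defaults to `model$k_selected`.
#' @param mode `"tail"` (default) or `"single"`.
#' @return Scalar distance (>= 0).
#' @export
d2_k <- function(x, model, k = model$k_selected,
                 mode = model$d2_mode) {
  p <- length(model$eigvals)
  if (is.na(k) || k < 1 || k > p) stop("`k` must be in 1..p", call. = FALSE)
  ctr <- partition_contributions(x, model)
  if (identical(mode, "tail")) sum(ctr[k:p]) else ctr[k]
}

d2_k_matrix <- function(X, model, k = model$k_selected,
                        mode = model$d2_mode) {
  p <- length(model$eigvals)
  if (is.na(k) || k < 1 || k > p) stop("`k` must be in 1..p", call. = FALSE)
  C <- contributions_matrix(X, model)
  if (identical(mode, "tail")) {
    rowSums(C[, k:p, drop = FALSE])
  } else {
    C[, k]
  }
}

#' Habitat similarity index from a reduced-rank distance
#'
#' Rescales `D2` to \[0, 1\]: 1 means conditions identical to the mean
#' habitat vector, values near 0 very dissimilar conditions. The default
#' rescale is the upper-tail probability of a chi-square distribution with
#' `df = p - k + 1` degrees of freedom (the number of summed partitions),
#' which is strictly decreasing in `D2` and exactly 1 at `D2 = 0`.
#'
#' @param d2 non-negative distance(s).
#' @param model a fitted, partition-selected model (supplies `df`); or pass
#'   `df` directly.
#' @param df chi-square degrees of freedom; overrides the model.
#' @return HSI value(s) in \[0, 1\].
#' @export
hsi <- function(d2, model = NULL, df = NULL) {
  if (any(d2 < 0)) stop("`d2` must be non-negative", call. = FALSE)
  if (is.null(df)) {
    if (is.null(model) || is.na(model$df)) {
      stop("provide a partition-selected model or `df`", call. = FALSE)
    }
    df <- model$df
  }
  stats::pchisq(d2, df = df, lower.tail = FALSE)
}

#' Score a variable table with the model
#'
#' @param table a variable table holding the model's variables.
#' @param model a fitted, partition-selected model.
#' @param k boundary partition (default `model$k_selected`).
#' @return The table with `d2` and `hsi` columns appended.
#' @export
score_table <- function(table, model, k = model$k_selected) {
  X <- as.matrix(table[model$variables])
  d2 <- d2_k_matrix(X, model, k)
  dplyr::mutate(tibble::as_tibble(table), d2 = d2,
                hsi = hsi(d2, df = chisq_df(model, k)))
}

chisq_df <- function(model, k) {
  p <- length(model$eigvals)
  if (identical(model$d2_mode, "tail")) p - k + 1 else 1
}

#' Map the habitat similarity index over a raster stack
#'
#' Assembles the model's variable vector per non-nodata cell (point values
#' and focal summaries per the extraction spec), computes `D2(k)` and the
#' HSI; nodata is preserved.
#'
#' @param stack an [env_stack] providing every model variable.
#' @param model a fitted, partition-selected model.
#' @param spec an [extraction_spec] mapping model variables to layers;
#'   default point-samples layers named like the variables.
#' @param k boundary partition (default `model$k_selected`).
#' @return An [eco_raster] of HSI values in \[0, 1\].
#' @export
map_hsi <- function(stack, model, spec = NULL, k = model$k_selected) {
  if (is.null(spec)) spec <- extraction_spec(model$variables)
  missing <- setdiff(model$variables, spec$variable)
  if (length(missing)) {
    stop("extraction spec lacks model variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  spec <- spec[match(model$variables, spec$variable), , drop = FALSE]
  grids <- derived_grids(stack, spec)
  keep <- !as.vector(stack$nodata_mask)
  X <- vapply(grids, as.vector, numeric(length(stack$nodata_mask)))
  ok <- keep & stats::complete.cases(X)
  vals <- rep(NA_real_, length(keep))
  if (any(ok)) {
    d2 <- d2_k_matrix(X[ok, , drop = FALSE], model, k)
    vals[ok] <- hsi(d2, df = chisq_df(model, k))
  }
  eco_raster(matrix(vals, nrow(stack$nodata_mask), ncol(stack$nodata_mask)),
             stack$cell_km)
}

#' Partition-selection diagnostics
#'
#' For every candidate boundary partition `k`, the eigenvalue, the adjacent
#' eigenvalue difference, the median HSI of the calibration, evaluation and
#' historic sets, and the AUC of evaluation leks against background points.
#'
#' @param model a fitted `eco_partition_model`.
#' @param calibration,evaluation,historic,background variable tables with
#'   the model's variables.
#' @return An `eco_partition_diagnostics` tibble with one row per `k`.
#' @export
partition_diagnostics <- function(model, calibration, evaluation, historic,
                                  background) {
  sets <- list(calibration = calibration, evaluation = evaluation,
               historic = historic, background = background)
  for (nm in names(sets)) {
    if (is.null(sets[[nm]]) || nrow(sets[[nm]]) == 0) {
      stop("empty point set: ", nm, call. = FALSE)
    }
  }
  p <- length(model$eigvals)
  mats <- purrr::map(sets, ~ as.matrix(.x[model$variables]))
  per_k <- purrr::map_dfr(seq_len(p), function(k) {
    df <- chisq_df(model, k)
    h <- purrr::map(mats, ~ hsi(d2_k_matrix(.x, model, k), df = df))
    tibble::tibble(
      k = k,
      eigval = model$eigvals[k],
      delta_eigval = if (k == 1) NA_real_ else
        model$eigvals[k - 1] - model$eigvals[k],
      median_hsi_calibration = stats::median(h$calibration),
      median_hsi_evaluation = stats::median(h$evaluation),
      median_hsi_historic = stats::median(h$historic),
      auc_evaluation = auc(h$evaluation, h$background)
    )
  })
  class(per_k) <- c("eco_partition_diagnostics", class(per_k))
  per_k
}

#' Choose the boundary partition from diagnostics
#'
#' Mirrors the multi-criteria selection used in practice: candidates are
#' the partitions whose eigenvalue is at most `threshold` (the invariant,
#' low-variance partitions), and among them the partition with the best
#' evaluation AUC is chosen. With `policy = "eigval"` the smallest
#' candidate `k` is taken regardless of performance.
#'
#' @param diagnostics an `eco_partition_diagnostics` tibble.
#' @param threshold eigenvalue ceiling for candidate partitions.
#' @param policy `"auc"` (default) or `"eigval"`.
#' @return The chosen boundary partition `k`.
#' @export
choose_k <- function(diagnostics, threshold = 1.0,
                     policy = c("auc", "eigval")) {
  policy <- match.arg(policy)
  cand <- diagnostics$k[diagnostics$eigval <= threshold]
  if (length(cand) == 0) cand <- max(diagnostics$k)
  if (policy == "eigval") return(min(cand))
  rows <- diagnostics[diagnostics$k %in% cand, ]
  rows$k[which.max(rows$auc_evaluation)]
}

#' @export
print.eco_partition_model <- function(x, ...) {
  p <- length(x$eigvals)
  cat(sprintf("<eco_partition_model> p = %d variables, n = %d occurrences\n",
              p, x$n))
  if (x$n_boot > 0) {
    cat(sprintf("  bootstrap: %d iterations, population cap %d, seed %d; orthogonality deviation %.2e\n",
                x$n_boot, x$pop_cap, x$seed, x$orth_dev))
  }
  cat("  eigenvalues:", paste(sprintf("%.3g", x$eigvals), collapse = " "), "\n")
  if (!is.na(x$k_selected)) {
    cat(sprintf("  boundary partition k = %d (%s mode, chi-square df = %g)\n",
                x$k_selected, x$d2_mode, x$df))
  } else {
    cat("  boundary partition not yet selected (see select_partition)\n")
  }
  invisible(x)
}

#' Tidy a fitted partition model
#'
#' One row per partition: the eigenvalue, adjacent eigenvalue difference,
#' and whether the partition lies in the selected minimum-variance tail.
#'
#' @param x an `eco_partition_model`.
#' @param ... unused.
#' @return A tibble with columns `partition`, `eigval`, `delta_eigval`,
#'   `in_tail`.
#' @export
tidy.eco_partition_model <- function(x, ...) {
  p <- length(x$eigvals)
  tibble::tibble(
    partition = seq_len(p),
    eigval = x$eigvals,
    delta_eigval = c(NA_real_, -diff(x$eigvals)),
    in_tail = if (is.na(x$k_selected)) NA else seq_len(p) >= x$k_selected
  )
}

#' Glance at a fitted partition model
#'
#' @inheritParams tidy.eco_partition_model
#' @return A one-row tibble of model-level summaries.
#' @export
glance.eco_partition_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = length(x$eigvals), k_selected = x$k_selected,
    df = x$df, n_boot = x$n_boot, pop_cap = x$pop_cap,
    eigval_sum = sum(x$eigvals), orth_dev = x$orth_dev
  )
}

#' Serialize / restore a partition model as JSON
#'
#' @param model an `eco_partition_model`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_model` returns the model.
#' @export
write_model <- function(model, path) {
  obj <- model
  obj$eigvecs <- unclass(obj$eigvecs)
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- new_partition_model(
    mu = stats::setNames(obj$mu, obj$variables),
    sigma = stats::setNames(obj$sigma, obj$variables),
    eigvals = obj$eigvals, eigvecs = obj$eigvecs,
    variables = obj$variables, n = obj$n, n_boot = obj$n_boot,
    pop_cap = obj$pop_cap, seed = obj$seed, orth_dev = obj$orth_dev,
    d2_mode = obj$d2_mode
  )
  m$k_selected <- obj$k_selected
  m$df <- obj$df
  m
}

#' Principal-angle cosines between two subspaces
#'
#' Singular values of `Q_A' Q_B` for orthonormal bases of the column spans:
#' all 1 for identical subspaces, 0 for orthogonal ones.
#'
#' @param A,B matrices whose columns span the subspaces.
#' @return Decreasing vector of cosines, length `min(ncol(A), ncol(B))`.
#' @export
principal_angle_cosines <- function(A, B) {
  qa <- qr.Q(qr(as.matrix(A)))
  qb <- qr.Q(qr(as.matrix(B)))
  sv <- svd(crossprod(qa, qb))$d
  pmin(sv, 1)
}

#' Raw-space minimum directions of a fitted model
#'
#' Eigenvectors live in standardized (z) space; the raw-space functional of
#' partition `j` is `diag(1/sigma) e_j`, normalized. Returns the directions
#' of the `m` smallest-eigenvalue partitions for comparison with a planted
#' minimum subspace.
#'
#' @param model a fitted `eco_partition_model`.
#' @param m number of minimum directions.
#' @return A `p x m` matrix with unit columns.
#' @export
minimum_directions <- function(model, m) {
  p <- length(model$eigvals)
  cols <- seq.int(p - m + 1L, p)
  V <- model$eigvecs[, cols, drop = FALSE] / model$sigma
  sweep(V, 2, sqrt(colSums(V^2)), `/`)
}
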