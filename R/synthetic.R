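#' Landscape configuration for the synthetic generator
#'
#' @param n_rows,n_cols grid dimensions in cells (>= 16).
#' @param cell_km cell edge length in km.
#' @param p number of environmental variables (>= 3).
#' @param corr_length spatial autocorrelation range in cells (Gaussian
#'   smoothing scale); 0 gives white noise.
#' @param seed RNG seed for the raster fields.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(n_rows = 64, n_cols = 64, cell_km = 1, p = 10,
                             corr_length = 3, seed = 1) {
  if (n_rows < 16 || n_cols < 16) {
    stop("grid must be at least 16 x 16 cells", call. = FALSE)
  }
  if (p < 3) stop("`p` must be at least 3", call. = FALSE)
  if (cell_km <= 0) stop("`cell_km` must be positive", call. = FALSE)
  if (corr_length < 0) stop("`corr_length` must be >= 0", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_km = cell_km, p = as.integer(p),
                 corr_length = corr_length, seed = as.integer(seed)),
            class = "landscape_config")
}

#' Planted ecological niche
#'
#' Defines the ground truth that the partitioned-distance model should
#' recover: a mean environmental vector `mu` at suitable sites, `m`
#' orthonormal "minimum" directions along which suitable sites vary little
#' (`sigma_min`), and a larger spread `sigma_free` on the orthogonal
#' complement. Occurrences are only drawn from the best `presence_quantile`
#' of cells ranked by the quadratic form in the minimum directions.
#'
#' @param p number of environmental variables.
#' @param m number of minimum directions (< p).
#' @param mu length-`p` mean vector at suitable sites.
#' @param B_min `p x m` matrix with orthonormal columns; random (QR of a
#'   Gaussian matrix) when `NULL`.
#' @param sigma_min length-`m` (or scalar) SDs along the minimum directions.
#' @param sigma_free scalar SD on the orthogonal complement; must exceed
#'   every `sigma_min`.
#' @param presence_quantile fraction of best cells eligible for occurrence.
#' @param seed seed used when `B_min` is generated.
#' @return A `planted_niche` list.
#' @export
planted_niche <- function(p, m = 2, mu = rep(0, p), B_min = NULL,
                          sigma_min = 0.1, sigma_free = 1,
                          presence_quantile = 0.25, seed = 1) {
  if (m >= p) stop("`m` must be smaller than `p`", call. = FALSE)
  if (length(mu) != p) stop("`mu` must have length p", call. = FALSE)
  sigma_min <- rep_len(sigma_min, m)
  if (length(sigma_free) != 1L || any(sigma_min >= sigma_free)) {
    stop("every `sigma_min` must be smaller than the scalar `sigma_free`",
         call. = FALSE)
  }
  if (presence_quantile <= 0 || presence_quantile > 1) {
    stop("`presence_quantile` must be in (0, 1]", call. = FALSE)
  }
  if (is.null(B_min)) {
    B_min <- withr::with_seed(seed, {
      qr.Q(qr(matrix(stats::rnorm(p * m), p, m)))
    })
  }
  G <- crossprod(B_min)
  if (max(abs(G - diag(m))) > 1e-10) {
    stop("columns of `B_min` must be orthonormal", call. = FALSE)
  }
  structure(list(mu = mu, B_min = B_min, sigma_min = sigma_min,
                 sigma_free = sigma_free,
                 presence_quantile = presence_quantile),
            class = "planted_niche")
}

#' Population layout for synthetic occurrences
#'
#' Population centers are placed inside the elliptical study area with a
#' minimum mutual separation; lek counts per population and lognormal
#' parameters for per-lek male counts complete the layout.
#'
#' @param config a [landscape_config].
#' @param n_pops number of populations (>= 1).
#' @param centers optional `n_pops x 2` matrix of 0-based (row, col) centers.
#' @param spread_cells within-population dispersion (Gaussian SD, cells).
#' @param leks_per_pop integer vector of lek counts, recycled to `n_pops`.
#' @param count_meanlog,count_sdlog lognormal parameters for mean annual
#'   male counts (rounded up to >= 1).
#' @param seed seed for center placement.
#' @return A `population_layout` list.
#' @export
population_layout <- function(config, n_pops = 10, centers = NULL,
                              spread_cells = 6, leks_per_pop = 50,
                              count_meanlog = 2.3, count_sdlog = 1,
                              seed = 1) {
  if (n_pops < 1) stop("`n_pops` must be >= 1", call. = FALSE)
  leks_per_pop <- rep_len(as.integer(leks_per_pop), n_pops)
  if (any(leks_per_pop < 1)) {
    stop("every `leks_per_pop` entry must be >= 1", call. = FALSE)
  }
  if (is.null(centers)) {
    centers <- withr::with_seed(seed, {
      place_centers(config, n_pops, margin = 0.65)
    })
  }
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (any(centers[, 1] < 0 | centers[, 1] >= config$n_rows |
          centers[, 2] < 0 | centers[, 2] >= config$n_cols)) {
    stop("population centers must lie inside the grid", call. = FALSE)
  }
  structure(list(n_pops = as.integer(n_pops), centers = centers,
                 spread_cells = spread_cells, leks_per_pop = leks_per_pop,
                 count_meanlog = count_meanlog, count_sdlog = count_sdlog),
            class = "population_layout")
}

# Rejection-sample centers inside the study ellipse, biased apart.
place_centers <- function(config, n_pops, margin = 0.65) {
  cr <- config$n_rows / 2; cc <- config$n_cols / 2
  a <- 0.45 * config$n_rows; b <- 0.45 * config$n_cols
  min_sep <- margin * 2 * sqrt(a * b / max(1, n_pops))
  centers <- matrix(NA_real_, n_pops, 2)
  placed <- 0L
  for (attempt in seq_len(20000L)) {
    r <- stats::runif(1, 0, config$n_rows)
    c <- stats::runif(1, 0, config$n_cols)
    if (((r - cr) / (margin * a))^2 + ((c - cc) / (margin * b))^2 > 1) next
    if (placed > 0L) {
      d <- sqrt((centers[seq_len(placed), 1] - r)^2 +
                (centers[seq_len(placed), 2] - c)^2)
      if (min(d) < min_sep) next
    }
    placed <- placed + 1L
    centers[placed, ] <- c(r, c)
    if (placed == n_pops) break
  }
  if (placed < n_pops) {
    # relax separation rather than fail on crowded layouts
    for (i in seq.int(placed + 1L, n_pops)) {
      repeat {
        r <- stats::runif(1, 0, config$n_rows)
        c <- stats::runif(1, 0, config$n_cols)
        if (((r - cr) / (margin * a))^2 + ((c - cc) / (margin * b))^2 <= 1) break
      }
      centers[i, ] <- c(r, c)
    }
  }
  centers
}

# Separable Gaussian smoothing with edge renormalization (rows then cols).
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  band <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    idx <- seq_len(n)
    S <- outer(idx, idx, function(i, j) {
      w <- exp(-((i - j)^2) / (2 * sigma^2))
      w * (abs(i - j) <= r)
    })
    S / rowSums(S)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

study_area_mask <- function(config) {
  # TRUE inside the elliptical study area
  r <- (seq_len(config$n_rows) - 0.5)
  c <- (seq_len(config$n_cols) - 0.5)
  cr <- config$n_rows / 2; cc <- config$n_cols / 2
  a <- 0.45 * config$n_rows; b <- 0.45 * config$n_cols
  outer(r, c, function(rr, cc2) ((rr - cr) / a)^2 + ((cc2 - cc) / b)^2 <= 1)
}

suitable_mask <- function(config, layout, suitable_radius_cells) {
  rows <- seq_len(config$n_rows) - 0.5
  cols <- seq_len(config$n_cols) - 0.5
  if (is.null(layout)) {
    cr <- config$n_rows / 2; cc <- config$n_cols / 2
    rad <- 0.35 * min(config$n_rows, config$n_cols)
    return(outer(rows, cols,
                 function(r, c) (r - cr)^2 + (c - cc)^2 <= rad^2))
  }
  if (is.null(suitable_radius_cells)) {
    # habitat patches are limiting: cover roughly a third of the study
    # area rather than blanketing it
    suitable_radius_cells <- 1.5 * layout$spread_cells
  }
  m <- matrix(FALSE, config$n_rows, config$n_cols)
  for (i in seq_len(layout$n_pops)) {
    ctr <- layout$centers[i, ]
    d2 <- outer(rows, cols,
                function(r, c) (r - ctr[1])^2 + (c - ctr[2])^2)
    m <- m | (d2 <= suitable_radius_cells^2)
  }
  m
}

#' Generate a synthetic environmental stack with a planted niche
#'
#' Each layer is spatially autocorrelated noise (white noise smoothed with a
#' Gaussian kernel of scale `corr_length`, then rescaled to unit variance).
#' Inside a "suitable" region — cells within a radius of the population
#' centers, or a central disk when no layout is given — the multivariate
#' field is re-expressed as `mu + sigma_free * (I - BB')x + B diag(sigma_min)
#' B'x`, so that projections of `(x - mu)` onto the minimum directions have
#' SD `sigma_min` while the orthogonal complement keeps SD `sigma_free`.
#' Cells outside an elliptical study-area mask are nodata.
#'
#' @param config a [landscape_config].
#' @param niche a [planted_niche] with `p` matching `config$p`.
#' @param layout optional [population_layout] defining the suitable region.
#' @param suitable_radius_cells radius of the suitable habitat patch around
#'   each center; defaults to `1.5 * layout$spread_cells`, sized so habitat
#'   remains a limited fraction of the study area.
#' @return An [env_stack] of `p` continuous layers named `var01 ... varNN`,
#'   with attributes `suitable` (logical matrix) and `config`.
#' @export
gen_env_stack <- function(config, niche, layout = NULL,
                          suitable_radius_cells = NULL) {
  stopifnot(inherits(config, "landscape_config"),
            inherits(niche, "planted_niche"))
  p <- config$p
  if (nrow(niche$B_min) != p || length(niche$mu) != p) {
    stop("niche dimension does not match `config$p`", call. = FALSE)
  }
  nr <- config$n_rows; nc <- config$n_cols
  fields <- withr::with_seed(config$seed, {
    lapply(seq_len(p), function(j) {
      f <- matrix(stats::rnorm(nr * nc), nr, nc)
      f <- smooth_gaussian(f, config$corr_length)
      (f - mean(f)) / stats::sd(f)
    })
  })
  X <- vapply(fields, as.vector, numeric(nr * nc))   # cells x p
  suit <- suitable_mask(config, layout, suitable_radius_cells)
  sv <- as.vector(suit)
  B <- niche$B_min
  proj <- X[sv, , drop = FALSE] %*% B                # cells x m
  free_part <- X[sv, , drop = FALSE] - proj %*% t(B)
  X[sv, ] <- matrix(niche$mu, sum(sv), p, byrow = TRUE) +
    niche$sigma_free * free_part +
    proj %*% (niche$sigma_min * t(B))
  mask <- study_area_mask(config)
  layers <- lapply(seq_len(p), function(j) {
    m <- matrix(X[, j], nr, nc)
    m[!mask] <- NA_real_
    m
  })
  names(layers) <- sprintf("var%02d", seq_len(p))
  out <- env_stack(layers, cell_km = config$cell_km,
                   nodata_mask = !mask, layer_kinds = "continuous")
  attr(out, "suitable") <- suit
  attr(out, "config") <- config
  out
}

#' True niche membership statistic
#'
#' The quadratic form `||B_min' (x - mu)||^2` evaluated per cell from the
#' stack's layers (point values). Small values mean the cell sits close to
#' the planted minimum subspace; this is the ground-truth suitability used
#' to place occurrences and historic locations.
#'
#' @param stack an [env_stack] whose layers are the `p` variables.
#' @param niche the [planted_niche] that generated the stack.
#' @return A matrix of the statistic, `NA` at nodata cells.
#' @export
niche_membership <- function(stack, niche) {
  p <- length(stack$layers)
  if (nrow(niche$B_min) != p) {
    stop("niche dimension does not match the stack", call. = FALSE)
  }
  X <- vapply(stack$layers, as.vector, numeric(length(stack$nodata_mask)))
  Z <- sweep(X, 2, niche$mu) %*% niche$B_min
  q <- rowSums(Z^2)
  matrix(q, nrow(stack$nodata_mask), ncol(stack$nodata_mask))
}

occurrence_tibble <- function(rows0, cols0, population, count, status,
                              cell_km) {
  tibble::tibble(
    x_km = (cols0 + 0.5) * cell_km,
    y_km = (rows0 + 0.5) * cell_km,
    row = as.integer(rows0),
    col = as.integer(cols0),
    population = population,
    count = count,
    status = status
  )
}

#' Generate occurrence (lek) locations
#'
#' Leks are sampled without replacement near each population center, from
#' cells in the best `presence_quantile` of the true niche-membership
#' statistic over the study area, with Gaussian distance weights
#' `exp(-d^2 / (2 spread^2))`. Each lek receives its population id, a
#' lognormal mean annual male count (rounded up to >= 1), and status
#' `"active"`. Cells are unique across all populations.
#'
#' @param stack an [env_stack] from [gen_env_stack()].
#' @param niche the [planted_niche] used to generate the stack.
#' @param layout a [population_layout].
#' @param seed RNG seed.
#' @return An occurrence tibble with columns
#'   `x_km, y_km, row, col, population, count, status`.
#' @export
gen_occurrences <- function(stack, niche, layout, seed = 1) {
  q <- niche_membership(stack, niche)
  in_mask <- !stack$nodata_mask
  qthr <- stats::quantile(q[in_mask], niche$presence_quantile, names = FALSE)
  eligible <- in_mask & !is.na(q) & q <= qthr
  nr <- nrow(q); nc <- ncol(q)
  rows0 <- (row(q) - 1)[eligible]
  cols0 <- (col(q) - 1)[eligible]
  withr::with_seed(seed, {
    taken <- integer(0)
    out <- vector("list", layout$n_pops)
    for (i in seq_len(layout$n_pops)) {
      ctr <- layout$centers[i, ]
      d2 <- (rows0 + 0.5 - ctr[1])^2 + (cols0 + 0.5 - ctr[2])^2
      local <- which(d2 <= (3 * layout$spread_cells)^2)
      local <- setdiff(local, taken)
      need <- layout$leks_per_pop[i]
      if (length(local) < need) {
        stop(sprintf(
          "population %d: requested %d leks but only %d eligible cells",
          i, need, length(local)), call. = FALSE)
      }
      w <- exp(-d2[local] / (2 * layout$spread_cells^2))
      pick <- local[sample.int(length(local), need, prob = w)]
      taken <- c(taken, pick)
      counts <- pmax(1, ceiling(stats::rlnorm(need, layout$count_meanlog,
                                              layout$count_sdlog)))
      out[[i]] <- occurrence_tibble(rows0[pick], cols0[pick],
                                    population = i, count = counts,
                                    status = "active", stack$cell_km)
    }
    dplyr::bind_rows(out)
  })
}

#' Generate historic (extirpated) locations
#'
#' Samples `n` cells uniformly from the worst decile of the true
#' niche-membership statistic — environments far from the planted minimum
#' subspace — with status `"historic"` and count 0.
#'
#' @inheritParams gen_occurrences
#' @param n number of historic locations (>= 1).
#' @return An occurrence tibble (population `NA`).
#' @export
gen_historic <- function(stack, niche, n, seed = 1) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  q <- niche_membership(stack, niche)
  in_mask <- !stack$nodata_mask
  qthr <- stats::quantile(q[in_mask], 0.9, names = FALSE)
  worst <- in_mask & !is.na(q) & q >= qthr
  idx <- which(worst)
  if (n > length(idx)) {
    stop(sprintf("requested %d historic locations but only %d cells in the worst decile",
                 n, length(idx)), call. = FALSE)
  }
  withr::with_seed(seed, {
    pick <- idx[sample.int(length(idx), n)]
    occurrence_tibble((row(q) - 1)[pick], (col(q) - 1)[pick],
                      population = NA_integer_, count = 0L,
                      status = "historic", stack$cell_km)
  })
}

#' Sample background cells uniformly from the study area
#'
#' @param stack an [env_stack].
#' @param n number of background points.
#' @param seed RNG seed.
#' @return An occurrence-shaped tibble with status `"background"`.
#' @export
sample_background <- function(stack, n, seed = 1) {
  idx <- which(!stack$nodata_mask)
  if (n > length(idx)) stop("`n` exceeds the number of in-mask cells",
                            call. = FALSE)
  withr::with_seed(seed, {
    pick <- idx[sample.int(length(idx), n)]
    m <- stack$nodata_mask
    occurrence_tibble((row(m) - 1)[pick], (col(m) - 1)[pick],
                      population = NA_integer_, count = 0L,
                      status = "background", stack$cell_km)
  })
}

#' Write / read occurrence tables
#'
#' CSV with header `x_km,y_km,row,col,population,count,status`.
#'
#' @param occurrences an occurrence tibble.
#' @param path CSV path.
#' @return `path` invisibly; `read_occurrences` returns the tibble.
#' @export
write_occurrences <- function(occurrences, path) {
  readr::write_csv(occurrences, path)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    x_km = "d", y_km = "d", row = "i", col = "i",
                    population = "i", count = "d", status = "c"))
}
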