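#' Circular focal window offsets
#'
#' Integer (dr, dc) offsets whose center-to-center distance is at most
#' `radius_km`; ties at exactly the radius are included, so a 5-km window on
#' a 1-km grid has 81 cells.
#'
#' @param radius_km window radius in km (>= 0).
#' @param cell_km cell edge length in km.
#' @return A tibble with integer columns `dr`, `dc`; always contains (0, 0).
#' @export
circular_window <- function(radius_km, cell_km = 1) {
  if (radius_km < 0) stop("`radius_km` must be >= 0", call. = FALSE)
  r_cells <- floor(radius_km / cell_km + 1e-9)
  off <- expand.grid(dr = -r_cells:r_cells, dc = -r_cells:r_cells)
  keep <- sqrt(off$dr^2 + off$dc^2) * cell_km <= radius_km + 1e-9
  tibble::tibble(dr = as.integer(off$dr[keep]),
                 dc = as.integer(off$dc[keep]))
}

# Shift a matrix by (dr, dc), padding with NA.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  r_lo <- max(1, 1 - dr); r_hi <- min(nr, nr - dr)
  c_lo <- max(1, 1 - dc); c_hi <- min(nc, nc - dc)
  if (r_lo <= r_hi && c_lo <= c_hi) {
    out[r_lo:r_hi, c_lo:c_hi] <- m[(r_lo:r_hi) + dr, (c_lo:c_hi) + dc]
  }
  out
}

# Focal sum and count of non-NA cells over a circular window.
focal_sum_count <- function(m, window) {
  s <- matrix(0, nrow(m), ncol(m))
  n <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(window))) {
    sh <- shift_matrix(m, window$dr[i], window$dc[i])
    ok <- !is.na(sh)
    s[ok] <- s[ok] + sh[ok]
    n <- n + ok
  }
  list(sum = s, count = n)
}

#' Focal mean of a fraction layer over a circular window
#'
#' Per cell, the mean of the layer over in-window, non-nodata cells; windows
#' are truncated at the grid edge and at nodata. Output is nodata where the
#' center cell is nodata.
#'
#' @param stack an [env_stack].
#' @param layer layer name (kind `"fraction"` or `"continuous"`).
#' @param radius_km window radius in km.
#' @return A matrix of focal means.
#' @export
focal_fraction <- function(stack, layer, radius_km) {
  m <- stack_layer(stack, layer)
  w <- circular_window(radius_km, stack$cell_km)
  sc <- focal_sum_count(m, w)
  out <- sc$sum / sc$count
  out[sc$count == 0] <- NA_real_
  out[stack$nodata_mask] <- NA_real_
  out
}

#' Focal linear-feature density over a circular window
#'
#' The layer holds km of linear feature per cell; the density is the window
#' total divided by the window area (non-nodata cell count times
#' `cell_km^2`), in km per square km.
#'
#' @inheritParams focal_fraction
#' @param layer layer name of kind `"density_length"`.
#' @return A matrix of densities (km/km^2).
#' @export
focal_density <- function(stack, layer, radius_km) {
  m <- stack_layer(stack, layer)
  if (!identical(unname(stack$layer_kinds[layer]), "density_length")) {
    stop("layer '", layer, "' is not of kind 'density_length'", call. = FALSE)
  }
  w <- circular_window(radius_km, stack$cell_km)
  sc <- focal_sum_count(m, w)
  out <- sc$sum / (sc$count * stack$cell_km^2)
  out[sc$count == 0] <- NA_real_
  out[stack$nodata_mask] <- NA_real_
  out
}

# Horn 3x3 gradient components; row 1 is north, columns increase eastward.
horn_gradients <- function(dem, cell_km) {
  if (nrow(dem) < 3 || ncol(dem) < 3) {
    stop("DEM must be at least 3 x 3", call. = FALSE)
  }
  sh <- function(dr, dc) shift_matrix(dem, dr, dc)
  n <- sh(-1, 0); s <- sh(1, 0); e <- sh(0, 1); w <- sh(0, -1)
  ne <- sh(-1, 1); nw <- sh(-1, -1); se <- sh(1, 1); sw <- sh(1, -1)
  dzdx <- ((ne + 2 * e + se) - (nw + 2 * w + sw)) / (8 * cell_km)
  dzdy <- ((ne + 2 * n + nw) - (se + 2 * s + sw)) / (8 * cell_km)  # northward
  list(dzdx = dzdx, dzdy = dzdy)
}

#' Slope and aspect from a DEM (Horn stencil)
#'
#' Slope in degrees; aspect in degrees clockwise from north, pointing
#' downslope, `NA` (flagged) on flat cells and at the grid border where the
#' 3x3 stencil is incomplete. Elevation is taken in the same length unit as
#' `cell_km`.
#'
#' @param dem elevation matrix.
#' @param cell_km cell edge length.
#' @return A matrix of degrees.
#' @export
slope_deg <- function(dem, cell_km = 1) {
  g <- horn_gradients(dem, cell_km)
  atan(sqrt(g$dzdx^2 + g$dzdy^2)) * 180 / pi
}

#' @rdname slope_deg
#' @export
aspect_deg <- function(dem, cell_km = 1) {
  g <- horn_gradients(dem, cell_km)
  asp <- (atan2(-g$dzdx, -g$dzdy) * 180 / pi) %% 360
  asp[g$dzdx == 0 & g$dzdy == 0] <- NA_real_   # flat: aspect undefined
  asp
}

#' Vector ruggedness measure (VRM)
#'
#' Terrain heterogeneity as 1 minus the magnitude of the resultant of unit
#' surface normals `(sin t sin a, sin t cos a, cos t)` over a square window:
#' 0 for parallel normals (flat or uniformly tilted terrain), approaching 1
#' for maximally dispersed normals. Flat cells have a well-defined vertical
#' normal (0, 0, 1) and contribute it regardless of their undefined aspect;
#' cells with missing slope are excluded with the window count reduced.
#'
#' @param slope slope matrix in degrees.
#' @param aspect aspect matrix in degrees (NA allowed on flat cells).
#' @param window_cells odd window edge length in cells (>= 3).
#' @return A matrix of VRM values in \[0, 1\].
#' @export
vrm <- function(slope, aspect, window_cells = 3) {
  if (!all(dim(slope) == dim(aspect))) {
    stop("slope and aspect grids must have the same shape", call. = FALSE)
  }
  if (window_cells < 3 || window_cells %% 2 == 0) {
    stop("`window_cells` must be an odd number >= 3", call. = FALSE)
  }
  th <- slope * pi / 180
  al <- aspect * pi / 180
  flat <- !is.na(th) & th == 0
  al[flat] <- 0                       # sin(0) * anything = 0 anyway
  x <- sin(th) * sin(al)
  y <- sin(th) * cos(al)
  z <- cos(th)
  bad <- is.na(x) | is.na(y) | is.na(z)
  x[bad] <- 0; y[bad] <- 0; z[bad] <- 0
  half <- (window_cells - 1) / 2
  w <- expand.grid(dr = -half:half, dc = -half:half)
  sx <- matrix(0, nrow(th), ncol(th)); sy <- sx; sz <- sx; n <- sx
  for (i in seq_len(nrow(w))) {
    sx <- sx + shift_fill0(x, w$dr[i], w$dc[i])
    sy <- sy + shift_fill0(y, w$dr[i], w$dc[i])
    sz <- sz + shift_fill0(z, w$dr[i], w$dc[i])
    n <- n + shift_fill0((!bad) * 1, w$dr[i], w$dc[i])
  }
  out <- 1 - sqrt(sx^2 + sy^2 + sz^2) / n
  out[n == 0] <- NA_real_
  pmin(pmax(out, 0), 1)
}

shift_fill0 <- function(m, dr, dc) {
  out <- shift_matrix(m, dr, dc)
  out[is.na(out)] <- 0
  out
}

#' Extraction specification for the variable table
#'
#' One row per derived variable: the source layer, the summary
#' (`"point"`, `"fraction"` for a focal mean, or `"density"` for a focal
#' linear density), and the window radius in km (ignored for `"point"`).
#'
#' @param variable output column names; default the layer names.
#' @param layer source layer names.
#' @param summary summary type per variable.
#' @param radius_km window radius per variable.
#' @return A tibble usable as the `spec` of [extract_table()] / [map_hsi()].
#' @export
extraction_spec <- function(layer, summary = "point", radius_km = 0,
                            variable = layer) {
  tibble::tibble(variable = variable, layer = layer,
                 summary = rep_len(summary, length(layer)),
                 radius_km = rep_len(radius_km, length(layer)))
}

# Materialize every derived-variable grid named by an extraction spec.
derived_grids <- function(stack, spec) {
  purrr::pmap(spec, function(variable, layer, summary, radius_km) {
    switch(summary,
      point = stack_layer(stack, layer),
      fraction = focal_fraction(stack, layer, radius_km),
      density = focal_density(stack, layer, radius_km),
      stop("unknown summary type: '", summary, "'", call. = FALSE)
    )
  }) |> stats::setNames(spec$variable)
}

#' Build the n x p variable table at occurrence locations
#'
#' Point-sampled variables are read at the occurrence cell; landscape
#' variables are read from precomputed focal grids. Rows touching nodata in
#' any variable are dropped with a message reporting the count.
#'
#' @param stack an [env_stack].
#' @param occurrences an occurrence tibble with 0-based `row`, `col`.
#' @param spec an [extraction_spec]; default: point-sample every layer.
#' @return A tibble: the occurrence columns followed by the `p` variables,
#'   with attribute `provenance` (the spec) and `n_dropped`.
#' @export
extract_table <- function(stack, occurrences, spec = NULL) {
  if (is.null(spec)) spec <- extraction_spec(names(stack$layers))
  nr <- nrow(stack$nodata_mask); nc <- ncol(stack$nodata_mask)
  bad <- occurrences$row < 0 | occurrences$row >= nr |
         occurrences$col < 0 | occurrences$col >= nc
  if (any(bad)) {
    stop("occurrences outside the grid at rows: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  grids <- derived_grids(stack, spec)
  idx <- cbind(occurrences$row + 1L, occurrences$col + 1L)
  vals <- purrr::map(grids, ~ .x[idx])
  tab <- dplyr::bind_cols(occurrences, tibble::as_tibble(vals))
  keep <- stats::complete.cases(tab[spec$variable])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " occurrence row(s) dropped for nodata")
  }
  out <- tab[keep, , drop = FALSE]
  attr(out, "provenance") <- spec
  attr(out, "n_dropped") <- n_dropped
  out
}
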