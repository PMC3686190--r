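#' Matrix-backed single-band raster
#'
#' A minimal raster container: a numeric matrix of cell values (`NA` marks
#' nodata) plus the cell edge length in kilometres. Row 1 is the northern
#' (top) edge; cells are addressed by 0-based `(row, col)` with cell centers
#' at `(row + 0.5, col + 0.5) * cell_km`.
#'
#' @param values numeric matrix; `NA` entries are nodata.
#' @param cell_km cell edge length in km (> 0).
#' @return An object of class `eco_raster`.
#' @export
eco_raster <- function(values, cell_km = 1) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cell_km) || length(cell_km) != 1L || cell_km <= 0) {
    stop("`cell_km` must be a single positive number", call. = FALSE)
  }
  structure(list(values = values, cell_km = cell_km), class = "eco_raster")
}

#' @export
print.eco_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<eco_raster> %d x %d cells, cell %.3g km, %d nodata\n",
              nrow(v), ncol(v), x$cell_km, sum(is.na(v))))
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat(sprintf("  range [%.4g, %.4g]\n", min(fin), max(fin)))
  }
  invisible(x)
}

#' @export
dim.eco_raster <- function(x) dim(x$values)

as_values_matrix <- function(x) {
  if (inherits(x, "eco_raster")) x$values else if (is.matrix(x)) x else
    stop("expected an eco_raster or matrix", call. = FALSE)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header followed by rows of values, top row first.
#'
#' @param path file path.
#' @return An [eco_raster]; `cellsize` is interpreted as km.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]])) stop("missing header field: ", key, call. = FALSE)
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    stop(sprintf("expected %d values, found %d",
                 hdr$nrows * hdr$ncols, length(vals)), call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  eco_raster(m, cell_km = hdr$cellsize)
}

#' Write an ESRI ASCII grid
#'
#' @param raster an [eco_raster] or numeric matrix.
#' @param path output path.
#' @param cell_km cell size when `raster` is a bare matrix.
#' @param nodata_value value written for `NA` cells.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, cell_km = 1,
                             nodata_value = -9999, digits = 8) {
  if (inherits(raster, "eco_raster")) {
    m <- raster$values
    cell_km <- raster$cell_km
  } else {
    m <- raster
  }
  m[is.na(m)] <- nodata_value
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.10g", cell_km),
    sprintf("NODATA_value %.10g", nodata_value)
  )
  body <- apply(m, 1L, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Aligned multi-layer environmental raster stack
#'
#' Bundles equal-shape layers with a shared nodata mask, cell size, and a
#' kind tag per layer (`"continuous"`, `"fraction"`, or `"density_length"`;
#' density layers hold km of linear feature per cell).
#'
#' @param layers named list of equal-shape numeric matrices.
#' @param cell_km cell edge length (km).
#' @param nodata_mask logical matrix, `TRUE` where nodata; defaults to cells
#'   that are `NA` in any layer.
#' @param layer_kinds character vector (recycled) or named vector matching
#'   `layers`.
#' @return An object of class `eco_env_stack`.
#' @export
env_stack <- function(layers, cell_km = 1, nodata_mask = NULL,
                      layer_kinds = "continuous") {
  if (!is.list(layers) || is.null(names(layers)) || any(names(layers) == "")) {
    stop("`layers` must be a named list of matrices", call. = FALSE)
  }
  dims <- lapply(layers, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("all layers must share the same shape", call. = FALSE)
  }
  if (cell_km <= 0) stop("`cell_km` must be positive", call. = FALSE)
  if (is.null(nodata_mask)) {
    nodata_mask <- Reduce(`|`, lapply(layers, is.na))
  }
  if (length(layer_kinds) == 1L) {
    layer_kinds <- stats::setNames(rep(layer_kinds, length(layers)),
                                   names(layers))
  }
  bad <- setdiff(layer_kinds, c("continuous", "fraction", "density_length"))
  if (length(bad)) stop("unknown layer kind: ", bad[1], call. = FALSE)
  for (nm in names(layers)) {
    if (identical(unname(layer_kinds[nm]), "fraction")) {
      v <- layers[[nm]][!nodata_mask]
      if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE)) {
        stop("fraction layer '", nm, "' has values outside [0, 1]",
             call. = FALSE)
      }
    }
    layers[[nm]][nodata_mask] <- NA_real_
  }
  structure(
    list(layers = layers, nodata_mask = nodata_mask, cell_km = cell_km,
         layer_kinds = layer_kinds),
    class = "eco_env_stack"
  )
}

#' @export
print.eco_env_stack <- function(x, ...) {
  d <- dim(x$nodata_mask)
  cat(sprintf("<eco_env_stack> %d layers on a %d x %d grid (%.3g km cells), %d nodata cells\n",
              length(x$layers), d[1], d[2], x$cell_km, sum(x$nodata_mask)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eco_env_stack <- function(x) dim(x$nodata_mask)

stack_layer <- function(stack, name) {
  if (!name %in% names(stack$layers)) {
    stop("unknown layer name: '", name, "'", call. = FALSE)
  }
  stack$layers[[name]]
}

#' Write an environmental stack to disk
#'
#' One ESRI ASCII grid per layer plus a JSON manifest recording layer names,
#' kinds, grid shape and cell size.
#'
#' @param stack an [env_stack].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_env_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(stack$layers)) {
    f <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(eco_raster(stack$layers[[nm]], stack$cell_km), f)
    files[nm] <- basename(f)
  }
  manifest <- list(
    layers = as.list(files),
    layer_kinds = as.list(stack$layer_kinds),
    n_rows = nrow(stack$nodata_mask), n_cols = ncol(stack$nodata_mask),
    cell_km = stack$cell_km
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

#' Read an environmental stack written by [write_env_stack()]
#'
#' @param dir directory containing `manifest.json` and the per-layer grids.
#' @return An [env_stack].
#' @export
read_env_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  layers <- lapply(manifest$layers, function(f) {
    read_ascii_grid(file.path(dir, f))$values
  })
  env_stack(layers, cell_km = manifest$cell_km,
            layer_kinds = unlist(manifest$layer_kinds))
}
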