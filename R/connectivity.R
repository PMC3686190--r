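#' Resistance surface from a habitat similarity raster
#'
#' Movement resistance is the reciprocal of the HSI with a floor,
#' `r = 1 / max(HSI, hsi_floor)`, clamped to `[1, r_max]`, so HSI 1 gives
#' resistance 1 and HSI 0 gives `r_max` (default 100,000). Cells outside
#' the historic range mask are set to exactly `r_max` to damp boundary
#' effects; nodata is preserved. A linear rescale of `1/HSI` onto
#' `[1, r_max]` is available as `method = "linear"`.
#'
#' @param hsi_raster an [eco_raster] or matrix of HSI values in \[0, 1\].
#' @param range_mask optional logical matrix, `TRUE` inside the historic
#'   range; cells outside get `r_max`.
#' @param r_max maximum resistance; default 100000.
#' @param hsi_floor floor applied to HSI before inversion; default 1e-5.
#' @param method `"reciprocal"` (default) or `"linear"`.
#' @return An [eco_raster] of resistance values in `[1, r_max]`.
#' @export
resistance_from_hsi <- function(hsi_raster, range_mask = NULL,
                                r_max = 1e5, hsi_floor = 1e-5,
                                method = c("reciprocal", "linear")) {
  method <- match.arg(method)
  m <- as_values_matrix(hsi_raster)
  cell_km <- if (inherits(hsi_raster, "eco_raster")) hsi_raster$cell_km else 1
  fin <- !is.na(m)
  if (any(m[fin] < -1e-12 | m[fin] > 1 + 1e-12)) {
    stop("HSI values must lie in [0, 1]", call. = FALSE)
  }
  inv <- 1 / pmax(m, hsi_floor)
  r <- if (method == "reciprocal") {
    pmin(pmax(inv, 1), r_max)
  } else {
    lo <- 1; hi <- 1 / hsi_floor
    1 + (pmin(pmax(inv, lo), hi) - lo) / (hi - lo) * (r_max - 1)
  }
  if (!is.null(range_mask)) {
    if (!all(dim(range_mask) == dim(m))) {
      stop("`range_mask` must match the raster shape", call. = FALSE)
    }
    r[!range_mask & fin] <- r_max
  }
  eco_raster(r, cell_km)
}

#' Build the cell-conductance graph of a resistance raster
#'
#' Nodes are the non-nodata cells; edges connect 4- or 8-neighbours with
#' conductance `g = 1 / (d * (r_i + r_j) / 2)` where `d` is 1 for
#' orthogonal and `sqrt(2)` for diagonal neighbours (cell units).
#'
#' @param resistance an [eco_raster] or matrix of resistances (`NA` =
#'   nodata).
#' @param neighborhood 4 or 8.
#' @return An `eco_circuit_graph`: node index grid, edge table
#'   (`i, j, conductance`), and dimensions.
#' @export
build_graph <- function(resistance, neighborhood = 8) {
  if (!neighborhood %in% c(4, 8)) {
    stop("`neighborhood` must be 4 or 8", call. = FALSE)
  }
  m <- as_values_matrix(resistance)
  ok <- !is.na(m)
  n_nodes <- sum(ok)
  if (n_nodes < 2) stop("need at least 2 in-mask cells", call. = FALSE)
  node_id <- matrix(NA_integer_, nrow(m), ncol(m))
  node_id[ok] <- seq_len(n_nodes)
  offsets <- list(c(0L, 1L), c(1L, 0L))
  dists <- c(1, 1)
  if (neighborhood == 8) {
    offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
    dists <- c(dists, sqrt(2), sqrt(2))
  }
  edges <- purrr::map2_dfr(offsets, dists, function(off, d) {
    a <- node_id
    b <- shift_matrix(node_id * 1.0, off[1], off[2])
    ra <- m
    rb <- shift_matrix(m, off[1], off[2])
    keep <- !is.na(a) & !is.na(b)
    tibble::tibble(
      i = as.integer(a[keep]),
      j = as.integer(b[keep]),
      conductance = 1 / (d * (ra[keep] + rb[keep]) / 2)
    )
  })
  structure(
    list(node_id = node_id, n_nodes = n_nodes, edges = edges,
         neighborhood = neighborhood, dim = dim(m)),
    class = "eco_circuit_graph"
  )
}

#' @export
print.eco_circuit_graph <- function(x, ...) {
  cat(sprintf("<eco_circuit_graph> %d nodes, %d edges, %d-neighborhood on a %d x %d grid\n",
              x$n_nodes, nrow(x$edges), x$neighborhood, x$dim[1], x$dim[2]))
  invisible(x)
}

graph_laplacian <- function(graph) {
  e <- graph$edges
  n <- graph$n_nodes
  A <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                            x = c(e$conductance, e$conductance),
                            dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(A)) - A
}

graph_components <- function(graph) {
  g <- igraph::graph_from_edgelist(cbind(graph$edges$i, graph$edges$j),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, graph$n_nodes - igraph::vcount(g)))
  igraph::components(g)$membership
}

# Solve voltages with `grounds` fixed at 0 and injections `b` elsewhere.
solve_grounded <- function(L, grounds, b, tol = 1e-10) {
  n <- nrow(L)
  keep <- setdiff(seq_len(n), grounds)
  Lk <- L[keep, keep, drop = FALSE]
  bk <- b[keep]
  v <- rep(0, n)
  sol <- as.numeric(Matrix::solve(Lk, bk))
  res <- as.numeric(Lk %*% sol - bk)
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(bk^2)), 1e-300)
  if (!is.finite(rel) || rel > tol) {
    stop(sprintf("linear solve did not reach the %g relative residual (got %g)",
                 tol, rel), call. = FALSE)
  }
  v[keep] <- sol
  v
}

node_cells <- function(graph, rows0, cols0) {
  ids <- graph$node_id[cbind(rows0 + 1L, cols0 + 1L)]
  if (any(is.na(ids))) {
    stop("source cell(s) fall on nodata: rows ",
         paste(which(is.na(ids)), collapse = ", "), call. = FALSE)
  }
  ids
}

#' Iterative all-to-one circuit solves with weighted sources
#'
#' Each source cell is activated in turn: its amplitude (mean annual male
#' count) is injected while every other source cell is grounded at zero
#' voltage, the reduced Laplacian system is solved to a 1e-10 relative
#' residual, and per-node currents are accumulated over all iterations.
#' Node current is half the sum of absolute incident branch currents for
#' interior nodes, the injected amplitude at the active source, and the
#' absorbed current at grounds. Sources disconnected from every ground are
#' skipped with a warning.
#'
#' @param graph an `eco_circuit_graph` from [build_graph()].
#' @param sources a tibble with 0-based `row`, `col` and a positive
#'   amplitude column (`count`); cells must be unique and in-mask.
#' @param amplitude_col name of the amplitude column; default `"count"`.
#' @return An `eco_current_map`: the cumulative current raster (`$raster`)
#'   and a per-source provenance tibble (`$per_source` with the injected
#'   and absorbed current and the solve residual).
#' @export
solve_all_to_one <- function(graph, sources, amplitude_col = "count") {
  amp <- sources[[amplitude_col]]
  if (is.null(amp) || any(amp <= 0)) {
    stop("source amplitudes must be positive", call. = FALSE)
  }
  ids <- node_cells(graph, sources$row, sources$col)
  if (anyDuplicated(ids)) stop("source cells must be unique", call. = FALSE)
  if (length(ids) < 2) stop("need at least 2 source cells", call. = FALSE)
  L <- graph_laplacian(graph)
  comp <- graph_components(graph)
  e <- graph$edges
  cum <- rep(0, graph$n_nodes)
  prov <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    src <- ids[s]
    grounds <- ids[-s]
    reachable <- grounds[comp[grounds] == comp[src]]
    if (length(reachable) == 0) {
      warning(sprintf("source %d disconnected from all grounds; skipped", s))
      prov[[s]] <- tibble::tibble(source = s, amplitude = amp[s],
                                  absorbed = NA_real_, residual = NA_real_,
                                  skipped = TRUE)
      next
    }
    b <- rep(0, graph$n_nodes)
    b[src] <- amp[s]
    v <- solve_grounded(L, grounds, b)
    bc <- e$conductance * (v[e$i] - v[e$j])
    node_cur <- rep(0, graph$n_nodes)
    abs_flow <- abs(bc)
    for_i <- rowsum(abs_flow, e$i)
    for_j <- rowsum(abs_flow, e$j)
    node_cur[as.integer(rownames(for_i))] <- for_i[, 1]
    jj <- as.integer(rownames(for_j))
    node_cur[jj] <- node_cur[jj] + for_j[, 1]
    node_cur <- node_cur / 2
    # grounds: absorbed (signed inflow); source: injected amplitude
    inflow <- rep(0, graph$n_nodes)
    net_i <- rowsum(bc, e$i); net_j <- rowsum(bc, e$j)
    inflow[as.integer(rownames(net_i))] <- -net_i[, 1]
    jj <- as.integer(rownames(net_j))
    inflow[jj] <- inflow[jj] + net_j[, 1]
    node_cur[grounds] <- pmax(inflow[grounds], 0)
    node_cur[src] <- amp[s]
    cum <- cum + node_cur
    absorbed <- sum(inflow[grounds])
    res <- abs(absorbed - amp[s]) / amp[s]
    prov[[s]] <- tibble::tibble(source = s, amplitude = amp[s],
                                absorbed = absorbed, residual = res,
                                skipped = FALSE)
  }
  out_m <- matrix(NA_real_, graph$dim[1], graph$dim[2])
  out_m[!is.na(graph$node_id)] <- cum[graph$node_id[!is.na(graph$node_id)]]
  structure(
    list(raster = eco_raster(out_m),
         per_source = dplyr::bind_rows(prov)),
    class = "eco_current_map"
  )
}

#' @export
print.eco_current_map <- function(x, ...) {
  ps <- x$per_source
  cat(sprintf("<eco_current_map> %d source iterations (%d skipped)\n",
              nrow(ps), sum(ps$skipped)))
  print(x$raster)
  invisible(x)
}

#' Effective resistance between two cells
#'
#' Grounds `b`, injects unit current at `a`, and returns the voltage at
#' `a` — the two-terminal effective resistance of the conductance graph.
#'
#' @param graph an `eco_circuit_graph`.
#' @param a,b 0-based `(row, col)` pairs (length-2 vectors) or node ids.
#' @return Effective resistance (scalar).
#' @export
effective_resistance <- function(graph, a, b) {
  as_node <- function(x) {
    if (length(x) == 2) node_cells(graph, x[1], x[2]) else as.integer(x)
  }
  na <- as_node(a); nb <- as_node(b)
  if (na == nb) stop("`a` and `b` must differ", call. = FALSE)
  comp <- graph_components(graph)
  if (comp[na] != comp[nb]) {
    stop("terminals are disconnected", call. = FALSE)
  }
  L <- graph_laplacian(graph)
  bb <- rep(0, graph$n_nodes)
  bb[na] <- 1
  v <- solve_grounded(L, nb, bb)
  v[na]
}
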