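#' Assemble lattice layers into a spatiotemporal graph
#'
#' Links a time-ordered list of per-layer lattice graphs with directed,
#' zero-weight temporal edges from each unmasked cell to its homologous cell
#' in the immediately younger layer. By default homology is the identity map
#' (a cell stays put); per-pair homology maps (e.g. from a plate-rotation
#' model) redirect the temporal edges. A temporal edge is skipped when either
#' endpoint is masked; assembly fails if any consecutive layer pair would be
#' left with no temporal edge at all, because time could then not pass
#' through the graph.
#'
#' @param layers List of `lattice_layer`, ordered strictly oldest to
#'   youngest by age.
#' @param grids The matching list of `elevation_grid` objects.
#' @param homology_maps Optional list (length `length(layers) - 1`) of
#'   data.frames with 0-based columns `row_from, col_from, row_to, col_to`
#'   (see [read_homology_maps()]); `NULL` entries mean identity.
#' @return A `spacetime_graph` holding the layers, the global directed
#'   igraph, the unique horizontal edge table and the temporal edge table.
#' @export
assemble_spacetime <- function(layers, grids, homology_maps = NULL) {
  nl <- length(layers)
  if (nl != length(grids)) stop("layers and grids must have equal length", call. = FALSE)
  ages <- vapply(grids, function(g) g$age_ma, numeric(1))
  if (nl > 1 && any(diff(ages) >= 0)) {
    stop("layer ages must strictly decrease (oldest first)", call. = FALSE)
  }
  if (!is.null(homology_maps) && length(homology_maps) != max(nl - 1, 0)) {
    stop("need one homology map (or NULL) per consecutive layer pair", call. = FALSE)
  }

  # global vertex table; vid = row number
  per_layer_n <- vapply(layers, function(l) nrow(l$vertices), integer(1))
  offsets <- cumsum(c(0L, utils::head(per_layer_n, -1)))
  vertex_df <- do.call(rbind, lapply(seq_len(nl), function(i) {
    v <- layers[[i]]$vertices
    data.frame(layer = i, cell = v$cell, lon = v$lon, lat = v$lat,
               elevation_m = v$elevation_m)
  }))
  vertex_df$vid <- seq_len(nrow(vertex_df))

  # per-layer lookup: 0-based cell id + 1 -> global vid (NA if masked)
  cell2vid <- lapply(seq_len(nl), function(i) {
    g <- grids[[i]]
    lk <- rep(NA_integer_, g$nrows * g$ncols)
    lk[layers[[i]]$vertices$cell + 1L] <- offsets[i] + seq_len(per_layer_n[i])
    lk
  })

  hedges <- do.call(rbind, lapply(seq_len(nl), function(i) {
    e <- layers[[i]]$edges
    if (nrow(e) == 0) return(NULL)
    data.frame(layer = i, from_cell = e$from, to_cell = e$to,
               from_vid = cell2vid[[i]][e$from + 1L], to_vid = cell2vid[[i]][e$to + 1L],
               topo_km = e$weight_km, is_island_link = e$is_island_link)
  }))
  if (is.null(hedges)) hedges <- data.frame(layer = integer(0), from_cell = integer(0),
                                            to_cell = integer(0), from_vid = integer(0),
                                            to_vid = integer(0), topo_km = numeric(0),
                                            is_island_link = logical(0))

  tedges <- NULL
  if (nl > 1) {
    tedges <- do.call(rbind, lapply(seq_len(nl - 1), function(i) {
      src_cells <- layers[[i]]$vertices$cell
      map <- if (!is.null(homology_maps)) homology_maps[[i]] else NULL
      dst_cells <- apply_homology(src_cells, map, grids[[i]], grids[[i + 1]])
      ok <- !is.na(dst_cells)
      dst_vid <- rep(NA_integer_, length(src_cells))
      dst_vid[ok] <- cell2vid[[i + 1]][dst_cells[ok] + 1L]
      keep <- ok & !is.na(dst_vid)
      if (!any(keep)) {
        stop(sprintf("no temporal edges between layers %g Ma and %g Ma: time cannot pass",
                     ages[i], ages[i + 1]), call. = FALSE)
      }
      data.frame(layer_from = i,
                 from_cell = src_cells[keep], to_cell = dst_cells[keep],
                 from_vid = cell2vid[[i]][src_cells[keep] + 1L], to_vid = dst_vid[keep])
    }))
  } else {
    tedges <- data.frame(layer_from = integer(0), from_cell = integer(0),
                         to_cell = integer(0), from_vid = integer(0), to_vid = integer(0))
  }

  # directed igraph: horizontal edges in both directions, temporal one way
  nh <- nrow(hedges)
  edf <- rbind(
    data.frame(from = hedges$from_vid, to = hedges$to_vid,
               hedge_id = seq_len(nh), type = rep("horizontal", nh)),
    data.frame(from = hedges$to_vid, to = hedges$from_vid,
               hedge_id = seq_len(nh), type = rep("horizontal", nh)),
    data.frame(from = tedges$from_vid, to = tedges$to_vid,
               hedge_id = rep(NA_integer_, nrow(tedges)),
               type = rep("temporal", nrow(tedges))))
  g <- igraph::graph_from_data_frame(
    edf, directed = TRUE,
    vertices = data.frame(name = vertex_df$vid))

  structure(
    list(layers = layers, grids = grids, ages = ages, n_layers = nl,
         offsets = offsets, cell2vid = cell2vid, vertex_df = vertex_df,
         hedges = hedges, tedges = tedges, igraph = g,
         edge_hid = edf$hedge_id, edge_type = edf$type),
    class = "spacetime_graph")
}

#' @export
print.spacetime_graph <- function(x, ...) {
  cat(sprintf("<spacetime_graph> %d layers (%g-%g Ma), %d vertices, %d horizontal + %d temporal edges\n",
              x$n_layers, x$ages[1], x$ages[x$n_layers],
              nrow(x$vertex_df), nrow(x$hedges), nrow(x$tedges)))
  invisible(x)
}

#' Build a spatiotemporal graph straight from elevation grids
#'
#' Convenience wrapper: builds each layer's lattice, optionally links
#' islands, and assembles the temporal stack.
#'
#' @inheritParams build_lattice
#' @inheritParams link_islands
#' @param grids List of `elevation_grid`, oldest first.
#' @param link_degree Island link degree (`0` = no linking, `1` = MST, `k`
#'   = k-nearest; see [link_islands()]).
#' @param homology_maps Optional per-pair homology maps.
#' @return A `spacetime_graph`.
#' @export
spacetime_graph <- function(grids, adjacency = c("queen", "rook"),
                            wrap_antimeridian = TRUE, radius_km = 6371,
                            link_degree = 1, cap_by_voronoi = FALSE,
                            weight_multiplier = 1, homology_maps = NULL) {
  adjacency <- match.arg(adjacency)
  layers <- lapply(grids, build_lattice, adjacency = adjacency,
                   wrap_antimeridian = wrap_antimeridian, radius_km = radius_km)
  if (link_degree >= 1) {
    layers <- lapply(layers, link_islands, degree = link_degree,
                     cap_by_voronoi = cap_by_voronoi, radius_km = radius_km,
                     weight_multiplier = weight_multiplier)
  }
  assemble_spacetime(layers, grids, homology_maps)
}

# map 0-based source cells through an (optional) homology table; NA when a
# cell has no image (it drops off the grid)
apply_homology <- function(src_cells, map, grid_from, grid_to) {
  if (is.null(map)) {
    if (grid_from$nrows != grid_to$nrows || grid_from$ncols != grid_to$ncols) {
      stop("identity homology requires equal grid dimensions", call. = FALSE)
    }
    return(src_cells)
  }
  need <- c("row_from", "col_from", "row_to", "col_to")
  if (!all(need %in% names(map))) {
    stop("homology map needs columns row_from, col_from, row_to, col_to", call. = FALSE)
  }
  from_id <- rc_to_cell(grid_from, map$row_from, map$col_from)
  to_id <- rc_to_cell(grid_to, map$row_to, map$col_to)
  idx <- match(src_cells, from_id)
  out <- to_id[idx]
  out
}

#' Read per-layer-pair homology maps
#'
#' Delimited text with header `layer_from_age_ma, row_from, col_from,
#' row_to, col_to` (0-based rows/cols). Rows are grouped by
#' `layer_from_age_ma` and matched to consecutive layer pairs by the older
#' layer's age.
#'
#' @param path File path.
#' @param ages Layer ages of the target stack (oldest first).
#' @return A list of data.frames (or NULL for pairs without entries),
#'   suitable for [assemble_spacetime()].
#' @export
read_homology_maps <- function(path, ages) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("layer_from_age_ma", "row_from", "col_from", "row_to", "col_to")
  if (!all(need %in% names(tab))) {
    stop(sprintf("homology file needs columns: %s", paste(need, collapse = ", ")), call. = FALSE)
  }
  lapply(seq_len(length(ages) - 1), function(i) {
    sub <- tab[abs(tab$layer_from_age_ma - ages[i]) < 1e-9, , drop = FALSE]
    if (nrow(sub) == 0) NULL else sub
  })
}

#' Map an absolute age onto a layer index
#'
#' Layer intervals are delimited by midpoints between consecutive layer
#' ages, closed at the older end; ages outside the span of the stack (older
#' than the oldest layer age or younger than the youngest) are an error.
#'
#' @param ages Layer ages in Ma, strictly decreasing.
#' @param age_ma Query age.
#' @return Integer layer index (1 = oldest).
#' @export
layer_for_age <- function(ages, age_ma) {
  n <- length(ages)
  if (age_ma > ages[1] + 1e-9 || age_ma < ages[n] - 1e-9) {
    stop(sprintf("age %g Ma is outside the stack span [%g, %g] Ma",
                 age_ma, ages[n], ages[1]), call. = FALSE)
  }
  if (n == 1) return(1L)
  bounds <- (ages[-n] + ages[-1]) / 2  # older -> younger midpoints
  for (i in seq_len(n - 1)) {
    # layer i+1's interval is closed at its older bound, so age == bounds[i]
    # belongs to the younger layer i+1
    if (age_ma > bounds[i]) return(i)
  }
  n
}

# vid lookup for (layer, 0-based cell); NA if masked
st_vid <- function(graph, layer, cell) {
  graph$cell2vid[[layer]][cell + 1L]
}
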