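#' Space-time anchor for a tree node
#'
#' A node's geographic point estimate with an absolute age. [resolve_anchor()]
#' snaps it onto the graph: the age picks the layer (closed-at-older-end
#' intervals, see [layer_for_age()]) and the point snaps to the nearest land
#' cell of that layer.
#'
#' @param node_id Node label.
#' @param lon,lat Coordinates in degrees.
#' @param age_ma Absolute age in Ma.
#' @return A `spacetime_anchor`.
#' @export
anchor <- function(node_id, lon, lat, age_ma) {
  check_lonlat(matrix(c(lon, lat), ncol = 2))
  structure(list(node_id = as.character(node_id), lon = lon, lat = lat,
                 age_ma = age_ma, layer = NA_integer_, cell = NA_integer_,
                 vid = NA_integer_),
            class = "spacetime_anchor")
}

#' Resolve an anchor onto a spatiotemporal graph
#'
#' @param a A `spacetime_anchor`.
#' @param graph A `spacetime_graph`.
#' @return The anchor with `layer`, `cell` and `vid` filled in.
#' @export
resolve_anchor <- function(a, graph) {
  a$layer <- layer_for_age(graph$ages, a$age_ma)
  a$cell <- snap_to_land(c(a$lon, a$lat), graph$grids[[a$layer]])
  a$vid <- st_vid(graph, a$layer, a$cell)
  if (is.na(a$vid)) stop("anchor snapped to a masked cell (internal error)", call. = FALSE)
  a
}

# directed edge weights aligned with the igraph edge order
directed_weights <- function(graph, weights = NULL) {
  hid <- graph$edge_hid
  w <- numeric(length(hid))
  hvals <- if (is.null(weights)) graph$hedges$topo_km else weights$compound
  horiz <- !is.na(hid)
  w[horiz] <- hvals[hid[horiz]]
  w  # temporal edges stay 0
}

#' Least-cost path between two space-time anchors
#'
#' Dijkstra's algorithm over the directed spatiotemporal graph, respecting
#' temporal edge direction (a path can never revisit an older layer). Among
#' equal-cost paths the result is made deterministic by minimizing hop
#' count and then taking the lexicographically smallest vertex-id sequence.
#'
#' @param graph A `spacetime_graph`.
#' @param weights Optional `edge_weights` (per-branch compound weights);
#'   `NULL` searches on the base topographic weights.
#' @param start,end `spacetime_anchor`s (resolved or not); the start must
#'   not be younger than the end.
#' @param branch_id Label attached to the returned path.
#' @return A `dispersal_path`: ordered `(layer, cell)` vertex table with
#'   coordinates and layer ages, the compound search cost, and
#'   `geographic_length_km` measured from the base topographic weights
#'   (temporal steps contribute zero).
#' @export
least_cost_path <- function(graph, weights = NULL, start, end, branch_id = NA_character_) {
  start <- resolve_anchor(start, graph)
  end <- resolve_anchor(end, graph)
  if (start$age_ma < end$age_ma) {
    stop("start anchor must not be younger than end anchor", call. = FALSE)
  }
  if (start$layer > end$layer) {
    stop("start anchor resolved to a younger layer than the end anchor", call. = FALSE)
  }

  if (start$vid == end$vid) {
    return(make_path(graph, start$vid, cost = 0, branch_id = branch_id))
  }

  g <- graph$igraph
  w <- directed_weights(graph, weights)
  ds <- as.numeric(igraph::distances(g, v = start$vid, mode = "out", weights = w,
                                     algorithm = "dijkstra"))
  cost <- ds[end$vid]
  if (!is.finite(cost)) {
    stop(no_route_message(graph, ds, start, end), call. = FALSE)
  }
  dt <- as.numeric(igraph::distances(g, v = end$vid, mode = "in", weights = w,
                                     algorithm = "dijkstra"))

  # shortest-path DAG: directed edges with ds[u] + w + dt[v] == cost
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  tol <- 1e-9 * max(1, abs(cost))
  on_dag <- is.finite(ds[ends[, 1]]) & is.finite(dt[ends[, 2]]) &
    abs(ds[ends[, 1]] + w + dt[ends[, 2]] - cost) <= tol
  dag_from <- ends[on_dag, 1]; dag_to <- ends[on_dag, 2]

  vseq <- lexicographic_min_hop_walk(dag_from, dag_to, start$vid, end$vid)
  make_path(graph, vseq, cost = cost, branch_id = branch_id)
}

# min-hop BFS towards `end` over the DAG edge list, then a greedy walk from
# `start` taking, at each step, the smallest-id successor that still allows
# a minimum-hop completion
lexicographic_min_hop_walk <- function(dag_from, dag_to, start, end) {
  verts <- sort(unique(c(dag_from, dag_to, start, end)))
  idx <- function(v) match(v, verts)
  nf <- idx(dag_from); nt <- idx(dag_to)
  n <- length(verts)
  hops <- rep(NA_integer_, n)
  hops[idx(end)] <- 0L
  in_adj <- split(nf, nt)       # predecessors by node
  out_adj <- split(nt, nf)      # successors by node
  frontier <- idx(end)
  h <- 0L
  while (length(frontier)) {
    h <- h + 1L
    preds <- unique(unlist(in_adj[as.character(frontier)], use.names = FALSE))
    preds <- preds[!is.na(preds)]
    preds <- preds[is.na(hops[preds])]
    hops[preds] <- h
    frontier <- preds
  }
  cur <- idx(start)
  if (is.na(hops[cur])) stop("internal error: start not connected in shortest-path DAG", call. = FALSE)
  walk <- verts[cur]
  while (cur != idx(end)) {
    succ <- out_adj[[as.character(cur)]]
    succ <- succ[!is.na(hops[succ]) & hops[succ] == hops[cur] - 1L]
    nxt <- succ[which.min(verts[succ])]
    walk <- c(walk, verts[nxt])
    cur <- nxt
  }
  walk
}

no_route_message <- function(graph, ds, start, end) {
  reached_layers <- graph$vertex_df$layer[is.finite(ds)]
  maxl <- max(reached_layers)
  if (maxl < end$layer) {
    sprintf("no route from node %s to node %s: no usable temporal edge between layers %g Ma and %g Ma",
            start$node_id, end$node_id, graph$ages[maxl], graph$ages[maxl + 1])
  } else {
    sprintf("no route from node %s to node %s: layer %g Ma is spatially disconnected",
            start$node_id, end$node_id, graph$ages[end$layer])
  }
}

make_path <- function(graph, vseq, cost, branch_id) {
  v <- graph$vertex_df[vseq, , drop = FALSE]
  steps <- data.frame(step = seq_along(vseq) - 1L, layer = v$layer, cell = v$cell,
                      lon = v$lon, lat = v$lat,
                      layer_age_ma = graph$ages[v$layer])
  structure(list(branch_id = branch_id, vertices = steps,
                 compound_cost = cost,
                 geographic_length_km = measure_path_km(graph, steps)),
            class = "dispersal_path")
}

#' @export
print.dispersal_path <- function(x, ...) {
  cat(sprintf("<dispersal_path> %s: %d steps, %.1f km, search cost %.4g\n",
              x$branch_id, nrow(x$vertices) - 1, x$geographic_length_km, x$compound_cost))
  invisible(x)
}

# sum of base topographic weights over horizontal steps
measure_path_km <- function(graph, steps) {
  n <- nrow(steps)
  if (n < 2) return(0)
  i <- seq_len(n - 1)
  horiz <- steps$layer[i] == steps$layer[i + 1]
  if (!any(horiz)) return(0)
  a <- pmin(steps$cell[i], steps$cell[i + 1])[horiz]
  b <- pmax(steps$cell[i], steps$cell[i + 1])[horiz]
  want <- paste(steps$layer[i][horiz], a, b)
  have <- with(graph$hedges,
               paste(layer, pmin(from_cell, to_cell), pmax(from_cell, to_cell)))
  hit <- match(want, have)
  if (anyNA(hit)) stop("path step is not a graph edge", call. = FALSE)
  sum(graph$hedges$topo_km[hit])
}

#' Geographic length of a dispersal path
#'
#' Sum of the base topographic edge weights along the path's horizontal
#' steps, regardless of the (possibly climate-compounded) weights the search
#' used. Temporal steps contribute zero.
#'
#' @param path A `dispersal_path`.
#' @return Length in km.
#' @export
path_geographic_length <- function(path) {
  path$geographic_length_km
}

#' Dispersal rate of a branch
#'
#' @param path A `dispersal_path`.
#' @param branch_duration_myr Branch duration in Myr, `> 0`.
#' @return Rate in km/Myr.
#' @export
dispersal_rate <- function(path, branch_duration_myr) {
  if (!is.numeric(branch_duration_myr) || branch_duration_myr <= 0) {
    stop("branch duration must be positive", call. = FALSE)
  }
  path$geographic_length_km / branch_duration_myr
}

#' Climatic conditions along a path, projected into climate space
#'
#' One selected-variable vector per visited vertex, read from that vertex's
#' layer and projected through the fitted climate space; output order
#' matches path order.
#'
#' @param path A `dispersal_path`.
#' @param bioclim_stack List of `bioclim_grid`, one per graph layer.
#' @param selected_variables Variable names (default: the pca's).
#' @param pca A `climate_pca`.
#' @return Matrix of PC coordinates, one row per path vertex.
#' @export
sample_path_conditions <- function(path, bioclim_stack,
                                   selected_variables = pca$variable_names, pca) {
  v <- path$vertices
  cond <- matrix(NA_real_, nrow(v), length(selected_variables),
                 dimnames = list(NULL, selected_variables))
  for (i in seq_len(nrow(v))) {
    row <- bioclim_stack[[v$layer[i]]]$variables[v$cell[i] + 1L, selected_variables]
    if (anyNA(row)) {
      stop(sprintf("missing climate at layer %d, cell %d", v$layer[i], v$cell[i]), call. = FALSE)
    }
    cond[i, ] <- row
  }
  project(pca, cond)
}
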