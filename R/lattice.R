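#' Build the lattice graph of one elevation layer
#'
#' Converts an elevation raster to an undirected lattice graph: one vertex
#' per unmasked cell and one edge per adjacent unmasked pair, weighted by the
#' elevation-adjusted great-circle distance between cell centres. Queen's
#' case (8-neighbour) adds the diagonals to rook's case (4-neighbour). For
#' global grids the last and first columns are adjacent across the
#' antimeridian; there is never wraparound across the poles.
#'
#' @param grid An `elevation_grid`.
#' @param adjacency `"queen"` (default, 8 neighbours) or `"rook"` (4).
#' @param wrap_antimeridian Connect the first and last columns. Only applied
#'   when the grid spans 360 degrees.
#' @param radius_km Sphere radius for edge weights.
#' @return A `lattice_layer`: vertex table (0-based `cell`, `row`, `col`,
#'   `lon`, `lat`, `elevation_m`) and canonical edge table (`from < to`,
#'   sorted), plus island membership filled in by [find_islands()].
#' @export
build_lattice <- function(grid, adjacency = c("queen", "rook"),
                          wrap_antimeridian = TRUE, radius_km = 6371) {
  adjacency <- match.arg(adjacency)
  wrap <- wrap_antimeridian && is_global_grid(grid)
  nr <- grid$nrows; nc <- grid$ncols
  land <- which(!t(grid$mask)) - 1L
  land <- sort(land)

  layer <- structure(
    list(age_ma = grid$age_ma, cell_size_deg = grid$cell_size_deg,
         dim = c(nr, nc), grid = grid,
         vertices = NULL, edges = NULL, membership = NULL),
    class = "lattice_layer")

  if (length(land) == 0) {
    warning("grid is fully masked: empty lattice layer", call. = FALSE)
    layer$vertices <- data.frame(cell = integer(0), row = integer(0), col = integer(0),
                                 lon = numeric(0), lat = numeric(0), elevation_m = numeric(0))
    layer$edges <- empty_edge_table()
    layer$membership <- integer(0)
    return(layer)
  }

  rc <- cell_to_rc(grid, land)
  ctr <- cell_center(grid, land)
  elev <- grid$elevations[cbind(rc[, "row"] + 1L, rc[, "col"] + 1L)]
  layer$vertices <- data.frame(cell = as.integer(land),
                               row = as.integer(rc[, "row"]), col = as.integer(rc[, "col"]),
                               lon = ctr[, "lon"], lat = ctr[, "lat"], elevation_m = elev)

  offsets <- list(c(0L, 1L), c(1L, 0L))             # E, S
  if (adjacency == "queen") offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))  # SE, SW

  unmasked_flag <- !t(grid$mask)  # index by cell id + 1 (row-major)
  efrom <- integer(0); eto <- integer(0)
  for (off in offsets) {
    r2 <- rc[, "row"] + off[1]
    c2 <- rc[, "col"] + off[2]
    if (wrap) c2 <- c2 %% nc
    ok <- r2 >= 0 & r2 < nr & c2 >= 0 & c2 < nc
    if (!any(ok)) next
    nb <- rc_to_cell(grid, r2[ok], c2[ok])
    src <- land[ok]
    keep <- unmasked_flag[nb + 1L] & nb != src
    efrom <- c(efrom, src[keep]); eto <- c(eto, nb[keep])
  }

  if (length(efrom)) {
    a <- pmin(efrom, eto); b <- pmax(efrom, eto)
    key <- as.numeric(a) * (nr * nc) + as.numeric(b)
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
    o <- order(a, b)
    a <- a[o]; b <- b[o]
    pa <- cell_center(grid, a); pb <- cell_center(grid, b)
    gc <- geosphere::distHaversine(pa, pb, r = radius_km)
    rca <- cell_to_rc(grid, a); rcb <- cell_to_rc(grid, b)
    ea <- grid$elevations[cbind(rca[, "row"] + 1L, rca[, "col"] + 1L)]
    eb <- grid$elevations[cbind(rcb[, "row"] + 1L, rcb[, "col"] + 1L)]
    w <- elevation_adjusted_distance(gc, ea, eb)
    layer$edges <- data.frame(from = as.integer(a), to = as.integer(b),
                              weight_km = w, is_island_link = FALSE)
  } else {
    layer$edges <- empty_edge_table()
  }
  layer$membership <- layer_membership(layer)
  layer
}

empty_edge_table <- function() {
  data.frame(from = integer(0), to = integer(0),
             weight_km = numeric(0), is_island_link = logical(0))
}

#' @export
print.lattice_layer <- function(x, ...) {
  cat(sprintf("<lattice_layer> age %g Ma: %d vertices, %d edges (%d island links), %d island(s)\n",
              x$age_ma, nrow(x$vertices), nrow(x$edges),
              sum(x$edges$is_island_link), n_islands(x)))
  invisible(x)
}

layer_membership <- function(layer) {
  cells <- layer$vertices$cell
  if (length(cells) == 0) return(integer(0))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(layer$edges$from), to = as.character(layer$edges$to)),
    directed = FALSE, vertices = data.frame(name = as.character(cells)))
  comp <- igraph::components(g)
  memb <- comp$membership[as.character(cells)]
  # renumber components deterministically by their smallest cell id
  first <- tapply(cells, memb, min)
  rank <- rank(first)
  out <- as.integer(rank[as.character(memb)])
  names(out) <- as.character(cells)
  out
}

n_islands <- function(layer) {
  if (length(layer$membership) == 0) 0L else max(layer$membership)
}

#' Partition a lattice layer into connected components ("islands")
#'
#' @param layer A `lattice_layer`.
#' @return A list of integer vectors of 0-based cell ids, one per connected
#'   component, ordered by each component's smallest cell id.
#' @export
find_islands <- function(layer) {
  memb <- layer_membership(layer)
  cells <- layer$vertices$cell
  unname(split(cells, memb))
}

#' Link disconnected islands of a lattice layer
#'
#' With `degree = 1`, islands are iteratively merged by the single globally
#' closest inter-island vertex pair until the layer is one component: a
#' minimum spanning tree over islands with `n_islands - 1` link edges. With
#' `degree = k > 1`, up to k closest cross-island vertex pairs are added per
#' island pair; if `cap_by_voronoi` is set, island pairs whose shortest
#' great-circle link segment passes through a third island's cells are not
#' linked (no edges crossing other landmasses). Link edges are flagged
#' `is_island_link = TRUE` and weighted by great-circle distance times
#' `weight_multiplier` with no elevation term (the gap is open ocean).
#'
#' @param layer A `lattice_layer`.
#' @param degree Positive integer; 1 gives MST behaviour.
#' @param cap_by_voronoi Drop island pairs whose link segment intersects a
#'   third island (only meaningful for `degree > 1`).
#' @param radius_km Sphere radius.
#' @param weight_multiplier Multiplier on island-link weights (default 1).
#' @return The layer with link edges appended and a single component when
#'   `degree = 1`. A single-island layer is returned unchanged.
#' @export
link_islands <- function(layer, degree = 1, cap_by_voronoi = FALSE,
                         radius_km = 6371, weight_multiplier = 1) {
  if (degree < 1) stop("degree must be >= 1", call. = FALSE)
  if (n_islands(layer) <= 1) return(layer)

  cells <- layer$vertices$cell
  coords <- as.matrix(layer$vertices[, c("lon", "lat")])
  memb <- layer$membership

  new_edges <- if (degree == 1) {
    mst_links(cells, coords, memb, radius_km)
  } else {
    knn_links(cells, coords, memb, degree, cap_by_voronoi, layer, radius_km)
  }
  if (nrow(new_edges)) {
    new_edges$weight_km <- new_edges$weight_km * weight_multiplier
    edges <- rbind(layer$edges, new_edges)
    o <- order(edges$from, edges$to, edges$is_island_link)
    layer$edges <- edges[o, , drop = FALSE]
    rownames(layer$edges) <- NULL
    layer$membership <- layer_membership(layer)
  }
  layer
}

# closest cross-component pair, exhaustive over member cells
closest_pair <- function(cells, coords, ia, ib, radius_km) {
  best <- list(d = Inf)
  cb <- coords[ib, , drop = FALSE]
  for (k in seq_along(ia)) {
    d <- geosphere::distHaversine(coords[ia[k], , drop = FALSE], cb, r = radius_km)
    j <- which.min(d)
    if (d[j] < best$d - 1e-12 ||
        (abs(d[j] - best$d) <= 1e-12 && tie_smaller(cells[ia[k]], cells[ib[j]], best))) {
      best <- list(d = d[j], a = cells[ia[k]], b = cells[ib[j]])
    }
  }
  best
}

tie_smaller <- function(a, b, best) {
  lo <- min(a, b); hi <- max(a, b)
  blo <- min(best$a, best$b); bhi <- max(best$a, best$b)
  lo < blo || (lo == blo && hi < bhi)
}

mst_links <- function(cells, coords, memb, radius_km) {
  comps <- split(seq_along(cells), memb)
  edges <- empty_edge_table()
  while (length(comps) > 1) {
    best <- list(d = Inf)
    for (i in seq_len(length(comps) - 1)) {
      for (j in (i + 1):length(comps)) {
        cand <- closest_pair(cells, coords, comps[[i]], comps[[j]], radius_km)
        if (cand$d < best$d - 1e-12 ||
            (abs(cand$d - best$d) <= 1e-12 && tie_smaller(cand$a, cand$b, best))) {
          best <- cand; best$i <- i; best$j <- j
        }
      }
    }
    edges <- rbind(edges, data.frame(from = min(best$a, best$b), to = max(best$a, best$b),
                                     weight_km = best$d, is_island_link = TRUE))
    comps[[best$i]] <- c(comps[[best$i]], comps[[best$j]])
    comps[[best$j]] <- NULL
  }
  edges
}

knn_links <- function(cells, coords, memb, degree, cap_by_voronoi, layer, radius_km) {
  ncomp <- max(memb)
  edges <- empty_edge_table()
  for (i in seq_len(ncomp - 1)) {
    for (j in (i + 1):ncomp) {
      ia <- which(memb == i); ib <- which(memb == j)
      d <- geosphere::distm(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE],
                            fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = radius_km))
      ord <- order(d)
      if (cap_by_voronoi) {
        k1 <- arrayInd(ord[1], dim(d))
        if (segment_hits_other_island(coords[ia[k1[1]], ], coords[ib[k1[2]], ],
                                      layer, exclude = c(i, j))) next
      }
      take <- utils::head(ord, degree)
      idx <- arrayInd(take, dim(d))
      a <- cells[ia[idx[, 1]]]; b <- cells[ib[idx[, 2]]]
      edges <- rbind(edges, data.frame(from = pmin(a, b), to = pmax(a, b),
                                       weight_km = d[take], is_island_link = TRUE))
    }
  }
  edges
}

# sample the great-circle segment at cell resolution and test whether any
# sample lands in a cell belonging to an island other than the linked pair
segment_hits_other_island <- function(p1, p2, layer, exclude) {
  grid <- layer$grid
  gc_km <- geosphere::distHaversine(matrix(p1, ncol = 2), matrix(p2, ncol = 2), r = 6371)
  step_km <- grid$cell_size_deg * 111.2 / 2
  n <- max(2, ceiling(gc_km / step_km))
  pts <- geosphere::gcIntermediate(p1, p2, n = n, addStartEnd = FALSE)
  hit_cells <- containing_cell(grid, pts[, 1], pts[, 2])
  memb <- layer$membership[as.character(hit_cells)]
  any(!is.na(memb) & !(memb %in% exclude))
}
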