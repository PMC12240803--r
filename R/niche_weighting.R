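#' Niche trajectory between ancestor and descendant in climate space
#'
#' The straight parametric segment through the two niche positions in full
#' PC space, modelling the ancestor-to-descendant niche shift as gradual
#' change. Coincident endpoints degenerate to a point target.
#'
#' @param ancestor_pc,descendant_pc Numeric PC coordinate vectors of equal
#'   length.
#' @param clamp Clamp residual projections to the segment (default `TRUE`):
#'   niche states beyond either endpoint are penalized by distance to the
#'   nearer endpoint rather than to the infinite line.
#' @return A `branch_niche_line`.
#' @export
branch_niche_line <- function(ancestor_pc, descendant_pc, clamp = TRUE) {
  a <- as.numeric(ancestor_pc); d <- as.numeric(descendant_pc)
  if (length(a) != length(d)) {
    stop("ancestor and descendant PC vectors must have equal dimension", call. = FALSE)
  }
  structure(list(ancestor_pc = a, descendant_pc = d,
                 direction = d - a, len2 = sum((d - a)^2),
                 clamp_to_segment = isTRUE(clamp)),
            class = "branch_niche_line")
}

#' Squared residual distance from a climate-space point to a niche line
#'
#' The Euclidean distance from the point to its (optionally clamped)
#' orthogonal projection on the line, squared: deviations from the niche
#' optimum are penalized quadratically.
#'
#' @param point_pc Numeric PC vector, or a matrix of points (rows).
#' @param line A `branch_niche_line`.
#' @return Squared distance(s), `>= 0`; zero iff the point lies on the
#'   (clamped) line.
#' @export
climate_residual_weight <- function(point_pc, line) {
  if (is.null(dim(point_pc))) point_pc <- matrix(point_pc, nrow = 1)
  p <- as.matrix(point_pc)
  if (ncol(p) != length(line$ancestor_pc)) {
    stop("point dimensionality does not match the niche line", call. = FALSE)
  }
  rel <- sweep(p, 2, line$ancestor_pc, "-")
  if (line$len2 == 0) {
    return(rowSums(rel^2))
  }
  t <- as.numeric(rel %*% line$direction) / line$len2
  if (line$clamp_to_segment) t <- pmin(pmax(t, 0), 1)
  proj <- outer(t, line$direction)
  rowSums((rel - proj)^2)
}

#' Rescale values linearly to the unit interval
#'
#' `(v - min) / (max - min)`. A constant nonzero input maps to all ones (the
#' multiplicative identity, so a degenerate weight component drops out of
#' the compound product); a constant all-zero input maps to all zeros so
#' that exactly-zero weights stay zero.
#'
#' @param values Finite numeric vector.
#' @return Values in `[0, 1]`.
#' @export
rescale_unit <- function(values) {
  if (length(values) == 0) return(numeric(0))
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(rep(if (rng[1] == 0) 0 else 1, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Mean selected-variable climate vector of graph edges
#'
#' The climatic condition attributed to an edge is the arithmetic mean of
#' the selected BIOCLIM variables at its two endpoint cells. Horizontal
#' edges use their own layer's climate; temporal edges mix the two layers'
#' values for the homologous cells.
#'
#' @param graph A `spacetime_graph`.
#' @param bioclim_stack List of `bioclim_grid`, one per layer.
#' @param selected_variables Variable names.
#' @param edges Optional subset of rows of `graph$hedges` (default all).
#' @return Matrix: one row per horizontal edge, one column per variable.
#' @export
edge_climate_matrix <- function(graph, bioclim_stack, selected_variables,
                                edges = graph$hedges) {
  if (length(bioclim_stack) != graph$n_layers) {
    stop("bioclim_stack must have one layer per graph layer", call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(edges), length(selected_variables),
                dimnames = list(NULL, selected_variables))
  for (li in unique(edges$layer)) {
    idx <- which(edges$layer == li)
    vars <- bioclim_stack[[li]]$variables
    a <- vars[edges$from_cell[idx] + 1L, selected_variables, drop = FALSE]
    b <- vars[edges$to_cell[idx] + 1L, selected_variables, drop = FALSE]
    if (anyNA(a) || anyNA(b)) {
      bad <- idx[which(rowSums(is.na(a)) + rowSums(is.na(b)) > 0)][1]
      stop(sprintf("missing climate at layer %d, cells %d/%d", li,
                   edges$from_cell[bad], edges$to_cell[bad]), call. = FALSE)
    }
    out[idx, ] <- (a + b) / 2
  }
  out
}

#' Climate vector of a single edge (convenience scalar form)
#'
#' @inheritParams edge_climate_matrix
#' @param layer Layer index of the edge (for a temporal edge, the older
#'   layer; supply `layer_to` for the younger endpoint).
#' @param from_cell,to_cell 0-based endpoint cell ids.
#' @param layer_to Layer of `to_cell` (defaults to `layer`: horizontal edge).
#' @return Named numeric vector of variable means.
#' @export
edge_climate_vector <- function(graph, bioclim_stack, selected_variables,
                                layer, from_cell, to_cell, layer_to = layer) {
  va <- bioclim_stack[[layer]]$variables[from_cell + 1L, selected_variables]
  vb <- bioclim_stack[[layer_to]]$variables[to_cell + 1L, selected_variables]
  if (anyNA(va) || anyNA(vb)) {
    stop(sprintf("missing climate at layer %d cell %d or layer %d cell %d",
                 layer, from_cell, layer_to, to_cell), call. = FALSE)
  }
  (va + vb) / 2
}

#' Compound per-branch edge weights
#'
#' For every horizontal edge: the squared residual of the edge's mean
#' climate (projected into PC space) to the branch's niche line, and the
#' topographic distance, are each rescaled to `[0, 1]` over the graph's
#' full weight set and multiplied. Because that set includes the
#' zero-weight temporal edges its minimum is zero, so rescaling divides by
#' the maximum; this keeps least-cost routes invariant under the rescaling
#' (a min-shift would re-rank path totals by hop count) and makes a
#' constant nonzero component the multiplicative identity while exact
#' zeros stay zero. Temporal edges always cost zero. The graph's base
#' topographic weights are never modified; each branch gets a fresh weight
#' set.
#'
#' @param graph A `spacetime_graph`.
#' @param bioclim_stack List of `bioclim_grid`, one per layer.
#' @param pca A fitted `climate_pca`.
#' @param line A `branch_niche_line` for the branch.
#' @param selected_variables Variables defining the climate space (default:
#'   the pca's variables).
#' @return An `edge_weights` set aligned row-for-row with `graph$hedges`:
#'   `topographic_km`, `climatic_raw` (squared residuals) and `compound`.
#' @export
compound_weights <- function(graph, bioclim_stack, pca, line,
                             selected_variables = pca$variable_names) {
  clim <- edge_climate_matrix(graph, bioclim_stack, selected_variables)
  pc <- project(pca, clim)
  raw <- climate_residual_weight(pc, line)
  structure(
    list(topographic_km = graph$hedges$topo_km,
         climatic_raw = raw,
         compound = rescale_zero_anchored(raw) *
           rescale_zero_anchored(graph$hedges$topo_km)),
    class = "edge_weights")
}

# [0,1] rescaling over a weight set whose minimum is zero (the temporal
# edges): divide by the maximum; all-zero input stays zero
rescale_zero_anchored <- function(values) {
  m <- max(values)
  if (m == 0) return(rep(0, length(values)))
  values / m
}

#' Export an edge weight set as an audit table
#'
#' @param graph A `spacetime_graph`.
#' @param weights An `edge_weights` from [compound_weights()].
#' @return Data.frame (layer, cell_from, cell_to, is_island_link,
#'   topographic_km, climatic_raw, compound).
#' @export
edge_weight_table <- function(graph, weights) {
  data.frame(layer = graph$hedges$layer,
             cell_from = graph$hedges$from_cell,
             cell_to = graph$hedges$to_cell,
             is_island_link = graph$hedges$is_island_link,
             topographic_km = weights$topographic_km,
             climatic_raw = weights$climatic_raw,
             compound = weights$compound)
}
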