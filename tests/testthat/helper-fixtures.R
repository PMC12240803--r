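# in-code fixtures shared across test files

# grid from an elevation matrix, 10-degree cells, non-global by default
toy_grid <- function(elev, age_ma = 100, cell = 10, mask = NULL,
                     lon_min = 0, lat_max = nrow(as.matrix(elev)) * cell / 2) {
  elevation_grid(as.matrix(elev), age_ma = age_ma, cell_size_deg = cell,
                 mask = mask, lon_min = lon_min, lat_max = lat_max)
}

# all-land n x m grid at constant elevation
land_grid <- function(nr = 3, nc = 3, age_ma = 100, elev = 100, cell = 10) {
  toy_grid(matrix(elev, nr, nc), age_ma = age_ma, cell = cell)
}

# constant climatology (ncell x 12 matrices)
constant_climatology <- function(grid, t = 20, p = 10) {
  n <- grid$nrows * grid$ncols
  monthly_climatology(tmax = matrix(t, n, 12), tmin = matrix(t, n, 12),
                      precip = matrix(p, n, 12), age_ma = grid$age_ma, grid = grid)
}

# independent per-cell BIOCLIM oracle: plain loops, no shared code with
# compute_bioclim's vectorized path
bioclim_oracle_cell <- function(tmx, tmn, pr) {
  tav <- (tmx + tmn) / 2
  q <- function(x, m) sum(x[((m - 1 + 0:2) %% 12) + 1])
  qt <- sapply(1:12, function(m) q(tav, m) / 3)
  qp <- sapply(1:12, function(m) q(pr, m))
  b5 <- max(tmx); b6 <- min(tmn); b7 <- b5 - b6
  b2 <- mean(tmx - tmn); b12 <- sum(pr)
  c(bio1 = mean(tav), bio2 = b2, bio3 = 100 * b2 / b7, bio4 = 100 * sd(tav),
    bio5 = b5, bio6 = b6, bio7 = b7,
    bio8 = qt[which.max(qp)], bio9 = qt[which.min(qp)],
    bio10 = qt[which.max(qt)], bio11 = qt[which.min(qt)],
    bio12 = b12, bio13 = max(pr), bio14 = min(pr),
    bio15 = 100 * sd(pr) / (1 + b12 / 12),
    bio16 = qp[which.max(qp)], bio17 = qp[which.min(qp)],
    bio18 = qp[which.max(qt)], bio19 = qp[which.min(qt)])
}

# brute-force minimum cost over all directed simple walks (with pruning);
# independent of igraph. edges: data.frame(from, to, w), directed.
brute_force_min_cost <- function(edges, start, end) {
  best <- Inf
  adj <- split(seq_len(nrow(edges)), edges$from)
  recur <- function(v, cost, visited) {
    if (cost >= best) return()
    if (v == end) { best <<- cost; return() }
    for (ei in adj[[as.character(v)]]) {
      u <- edges$to[ei]
      if (u %in% visited) next
      recur(u, cost + edges$w[ei], c(visited, u))
    }
  }
  recur(start, 0, start)
  best
}

# directed edge list (both directions for horizontal, one for temporal) of a
# spacetime graph under a given weight set
directed_edge_table <- function(graph, weights = NULL) {
  h <- graph$hedges
  wv <- if (is.null(weights)) h$topo_km else weights$compound
  rbind(data.frame(from = h$from_vid, to = h$to_vid, w = wv),
        data.frame(from = h$to_vid, to = h$from_vid, w = wv),
        data.frame(from = graph$tedges$from_vid, to = graph$tedges$to_vid,
                   w = rep(0, nrow(graph$tedges))))
}

# small random spacetime graph for oracle tests: random masks, random
# elevations, guaranteed assemblable (shared land cell across layers)
random_spacetime <- function(seed, nr = 3, nc = 3, n_layers = 2) {
  set.seed(seed)
  repeat {
    grids <- lapply(seq_len(n_layers), function(i) {
      elev <- matrix(runif(nr * nc, -500, 1500), nr, nc)
      elev[2, 2] <- abs(elev[2, 2]) + 1  # keep one shared land cell
      toy_grid(elev, age_ma = 100 - 10 * (i - 1), cell = 10)
    })
    g <- tryCatch(spacetime_graph(grids, adjacency = "queen", link_degree = 1),
                  error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(g) && nrow(g$vertex_df) <= 24) return(g)
    nr2 <- nr  # re-draw with same dims until constraints hold
  }
}

# all permutations of a small vector (tip-age assignment oracle)
combinat_perms <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- combinat_perms(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}
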