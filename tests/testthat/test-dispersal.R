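test_that("identical anchors give the zero path", {
  g <- land_grid(3, 3, age_ma = 100)
  st <- spacetime_graph(list(g))
  a <- anchor("x", 15, 5, 100)
  p <- least_cost_path(st, NULL, a, a)
  expect_equal(nrow(p$vertices), 1)
  expect_equal(p$compound_cost, 0)
  expect_equal(path_geographic_length(p), 0)
})

test_that("corner-to-corner LCP on a uniform rook lattice matches brute force", {
  g <- land_grid(3, 3, age_ma = 100)
  lay <- build_lattice(g, adjacency = "rook", wrap_antimeridian = FALSE)
  st <- assemble_spacetime(list(lay), list(g))
  start <- anchor("a", as.numeric(cell_center(g, 0))[1], as.numeric(cell_center(g, 0))[2], 100)
  end <- anchor("b", as.numeric(cell_center(g, 8))[1], as.numeric(cell_center(g, 8))[2], 100)
  p <- least_cost_path(st, NULL, start, end)
  expect_equal(nrow(p$vertices), 5)  # 4 hops
  edges <- directed_edge_table(st)
  oracle <- brute_force_min_cost(edges, st$cell2vid[[1]][1], st$cell2vid[[1]][9])
  expect_equal(p$compound_cost, oracle, tolerance = 1e-12)
})

test_that("two islands joined by an MST link route through the flagged edge", {
  elev <- matrix(c(100, 100, -10, -10, 100, 100), 1, 6)
  g <- toy_grid(elev, lat_max = 5, age_ma = 50)
  st <- spacetime_graph(list(g), link_degree = 1)
  a <- anchor("a", 5, 0, 50)    # west island
  b <- anchor("b", 55, 0, 50)   # east island
  p <- least_cost_path(st, NULL, a, b)
  link <- st$hedges[st$hedges$is_island_link, ]
  cells <- p$vertices$cell
  crossed <- any(vapply(seq_len(length(cells) - 1), function(i) {
    all(sort(c(cells[i], cells[i + 1])) == sort(c(link$from_cell, link$to_cell)))
  }, logical(1)))
  expect_true(crossed)
})

test_that("geographic length sums base topographic weights only", {
  fx <- random_spacetime(31)
  v1 <- fx$vertex_df$vid[1]
  vend <- fx$vertex_df$vid[nrow(fx$vertex_df)]
  a1 <- fx$vertex_df[fx$vertex_df$vid == v1, ]
  a2 <- fx$vertex_df[fx$vertex_df$vid == vend, ]
  p <- least_cost_path(fx, NULL,
                       anchor("a", a1$lon, a1$lat, fx$ages[a1$layer]),
                       anchor("b", a2$lon, a2$lat, fx$ages[a2$layer]))
  # manual resum from the edge table
  v <- p$vertices
  manual <- 0
  for (i in seq_len(nrow(v) - 1)) {
    if (v$layer[i] == v$layer[i + 1]) {
      h <- fx$hedges
      hit <- which(h$layer == v$layer[i] &
                     pmin(h$from_cell, h$to_cell) == min(v$cell[i], v$cell[i + 1]) &
                     pmax(h$from_cell, h$to_cell) == max(v$cell[i], v$cell[i + 1]))
      manual <- manual + h$topo_km[hit]
    }
  }
  expect_equal(path_geographic_length(p), manual)
  # single-vertex and two-cell cases
  expect_equal(dispersal_rate(p, 5), path_geographic_length(p) / 5)
  expect_error(dispersal_rate(p, 0), "positive")
})

test_that("LCP cost equals exhaustive enumeration on random small graphs", {
  for (seed in 1:25) {
    fx <- random_spacetime(seed)
    set.seed(seed + 500)
    # random positive weights stand in for compound weights
    w <- structure(list(topographic_km = fx$hedges$topo_km,
                        climatic_raw = runif(nrow(fx$hedges)),
                        compound = runif(nrow(fx$hedges))), class = "edge_weights")
    vids <- fx$vertex_df$vid
    from <- fx$vertex_df[fx$vertex_df$layer == 1, ][1, ]
    cand <- fx$vertex_df[fx$vertex_df$layer == fx$n_layers, ]
    to <- cand[nrow(cand), ]
    p <- least_cost_path(fx, w,
                         anchor("a", from$lon, from$lat, fx$ages[1]),
                         anchor("b", to$lon, to$lat, fx$ages[fx$n_layers]))
    oracle <- brute_force_min_cost(directed_edge_table(fx, w), from$vid, to$vid)
    expect_equal(p$compound_cost, oracle, tolerance = 1e-10)
  }
})

test_that("equal-cost ties resolve to fewest hops then lexicographic order", {
  # uniform 2x2 all-land single layer: two 2-hop corner routes tie exactly
  g <- land_grid(2, 2, age_ma = 10, cell = 10)
  lay <- build_lattice(g, adjacency = "rook", wrap_antimeridian = FALSE)
  # force exact symmetric weights to create a tie
  lay$edges$weight_km <- rep(1, nrow(lay$edges))
  st <- assemble_spacetime(list(lay), list(g))
  ctr0 <- as.numeric(cell_center(g, 0)); ctr3 <- as.numeric(cell_center(g, 3))
  p <- least_cost_path(st, NULL, anchor("a", ctr0[1], ctr0[2], 10),
                       anchor("b", ctr3[1], ctr3[2], 10))
  # routes 0-1-3 and 0-2-3 tie at cost 2 and 2 hops; lexicographic picks 0-1-3
  expect_equal(p$vertices$cell, c(0L, 1L, 3L))
  # rerun is byte-identical (determinism)
  p2 <- least_cost_path(st, NULL, anchor("a", ctr0[1], ctr0[2], 10),
                        anchor("b", ctr3[1], ctr3[2], 10))
  expect_identical(p$vertices, p2$vertices)
})

test_that("paths never revisit older layers and searches respect time direction", {
  fx <- random_spacetime(77, n_layers = 3)
  set.seed(99)
  for (i in 1:30) {
    vdf <- fx$vertex_df
    from <- vdf[sample(nrow(vdf), 1), ]
    cand <- vdf[vdf$layer >= from$layer, ]
    to <- cand[sample(nrow(cand), 1), ]
    p <- tryCatch(least_cost_path(
      fx, NULL, anchor("a", from$lon, from$lat, fx$ages[from$layer]),
      anchor("b", to$lon, to$lat, fx$ages[to$layer])),
      error = function(e) NULL)
    if (is.null(p)) next
    expect_true(all(diff(p$vertices$layer) >= 0))
    expect_gte(p$vertices$layer[1], from$layer)
  }
  # an ancestor younger than the descendant is refused outright
  v1 <- fx$vertex_df[fx$vertex_df$layer == 1, ][1, ]
  v3 <- fx$vertex_df[fx$vertex_df$layer == 3, ][1, ]
  expect_error(least_cost_path(fx, NULL,
                               anchor("a", v3$lon, v3$lat, fx$ages[3]),
                               anchor("b", v1$lon, v1$lat, fx$ages[1])),
               "younger")
})

test_that("disconnected targets raise a no-route error naming the blockage", {
  # two single-cell islands, no link edges
  elev <- matrix(c(100, -10, 100), 1, 3)
  g <- toy_grid(elev, lat_max = 5, age_ma = 10)
  st <- spacetime_graph(list(g), link_degree = 0)
  expect_error(least_cost_path(st, NULL, anchor("a", 5, 0, 10),
                               anchor("b", 25, 0, 10)),
               "spatially disconnected")
})

test_that("changing search weights never changes how a fixed path is measured", {
  fx <- weighting_fixture <- random_spacetime(12)
  vdf <- fx$vertex_df
  from <- vdf[1, ]; to <- vdf[nrow(vdf), ]
  p1 <- least_cost_path(fx, NULL, anchor("a", from$lon, from$lat, fx$ages[from$layer]),
                        anchor("b", to$lon, to$lat, fx$ages[to$layer]))
  # re-measure p1's vertex sequence under a different weight regime: the
  # geographic length is a property of the sequence alone
  relen <- tardis:::measure_path_km(fx, p1$vertices)
  expect_equal(relen, p1$geographic_length_km)
})

test_that("path conditions project each visited cell in order", {
  g1 <- land_grid(2, 3, age_ma = 100)
  g2 <- land_grid(2, 3, age_ma = 90)
  n <- 6
  tv <- seq(0, 25, length.out = n)
  mk <- function(g, shift) compute_bioclim(monthly_climatology(
    tmax = matrix(tv + shift + 5, n, 12), tmin = matrix(tv + shift - 5, n, 12),
    precip = matrix(seq(40, 90, length.out = n), n, 12),
    age_ma = g$age_ma, grid = g))
  stack <- list(mk(g1, 0), mk(g2, 3))
  st <- spacetime_graph(list(g1, g2))
  cond <- rbind(stack[[1]]$variables[, c("bio1", "bio12")],
                stack[[2]]$variables[, c("bio1", "bio12")])
  pca <- fit_pca(cond)
  c0 <- as.numeric(cell_center(g1, 0)); c5 <- as.numeric(cell_center(g2, 5))
  p <- least_cost_path(st, NULL, anchor("a", c0[1], c0[2], 100),
                       anchor("b", c5[1], c5[2], 90))
  pc <- sample_path_conditions(p, stack, pca$variable_names, pca)
  expect_equal(nrow(pc), nrow(p$vertices))
  # manual lookup for each step
  for (i in seq_len(nrow(pc))) {
    manual <- project(pca, stack[[p$vertices$layer[i]]]$variables[
      p$vertices$cell[i] + 1, c("bio1", "bio12")])
    expect_equal(pc[i, ], manual[1, ], tolerance = 1e-12)
  }
  # uniform climate gives identical projected points
  ustack <- list(compute_bioclim(constant_climatology(g1)),
                 compute_bioclim(constant_climatology(g2)))
  upc <- sample_path_conditions(p, ustack, pca$variable_names, pca)
  expect_equal(max(apply(upc, 2, function(x) diff(range(x)))), 0)
})
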