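test_that("niche lines pass through both endpoints with zero residual", {
  ln <- branch_niche_line(c(0, 0), c(1, 0))
  expect_equal(climate_residual_weight(c(0, 0), ln), 0)
  expect_equal(climate_residual_weight(c(1, 0), ln), 0)
  expect_equal(climate_residual_weight(c(0.5, 0), ln), 0)
  # coincident endpoints: point target
  pt <- branch_niche_line(c(2, 3), c(2, 3))
  expect_equal(climate_residual_weight(c(2, 3), pt), 0)
  expect_equal(climate_residual_weight(c(2, 4), pt), 1)
  expect_error(branch_niche_line(c(0, 0), c(1, 2, 3)), "equal dimension")
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(4); d <- rnorm(4)
    ln <- branch_niche_line(a, d)
    expect_equal(climate_residual_weight(a, ln), 0, tolerance = 1e-12)
    expect_equal(climate_residual_weight(d, ln), 0, tolerance = 1e-12)
  }
})

test_that("residuals are squared distances, clamped to the segment when asked", {
  ln <- branch_niche_line(c(0, 0), c(4, 0))
  expect_equal(climate_residual_weight(c(2, 2), ln), 4)      # offset 2 -> 2^2
  # beyond the descendant end at distance 3 from it
  expect_equal(climate_residual_weight(c(7, 0), ln), 9)
  expect_equal(climate_residual_weight(c(4 + 3 / sqrt(2), 3 / sqrt(2)), ln), 9,
               tolerance = 1e-12)
  # unclamped: residual is to the infinite line
  ln_inf <- branch_niche_line(c(0, 0), c(4, 0), clamp = FALSE)
  expect_equal(climate_residual_weight(c(7, 0), ln_inf), 0)
  expect_equal(climate_residual_weight(c(7, 2), ln_inf), 4)
})

test_that("rescale_unit maps to [0,1] with stated degenerate conventions", {
  expect_equal(rescale_unit(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(rescale_unit(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(rescale_unit(c(0, 0, 0)), c(0, 0, 0))
  set.seed(2)
  v <- rnorm(50)
  r <- rescale_unit(v)
  expect_equal(r[which.min(v)], 0)
  expect_equal(r[which.max(v)], 1)
  expect_true(all(r >= 0 & r <= 1))
  expect_error(rescale_unit(c(1, NA)), "finite")
  expect_error(rescale_unit(c(1, Inf)), "finite")
})

# shared scaffolding: two-layer stack with spatially varying climate
weighting_fixture <- function(t_field = NULL) {
  g1 <- land_grid(2, 3, age_ma = 100)
  g2 <- land_grid(2, 3, age_ma = 90)
  n <- 6
  mk <- function(g, tvals, pvals) {
    compute_bioclim(monthly_climatology(
      tmax = matrix(tvals + 5, n, 12), tmin = matrix(tvals - 5, n, 12),
      precip = matrix(pvals, n, 12) + matrix(c(0, 5, 0, 9, 0, 3, 0, 2, 0, 7, 0, 4),
                                             n, 12, byrow = TRUE),
      age_ma = g$age_ma, grid = g))
  }
  tv <- if (is.null(t_field)) seq(0, 25, length.out = n) else t_field
  pv <- seq(40, 140, length.out = n)
  list(graph = spacetime_graph(list(g1, g2), link_degree = 1),
       stack = list(mk(g1, tv, pv), mk(g2, tv + 2, pv - 10)))
}

test_that("edge climate is the mean of endpoint cells", {
  fx <- weighting_fixture()
  vars <- c("bio1", "bio12")
  m <- edge_climate_matrix(fx$graph, fx$stack, vars)
  h <- fx$graph$hedges
  for (i in c(1, 3, nrow(h))) {
    a <- fx$stack[[h$layer[i]]]$variables[h$from_cell[i] + 1, vars]
    b <- fx$stack[[h$layer[i]]]$variables[h$to_cell[i] + 1, vars]
    expect_equal(unname(m[i, ]), unname((a + b) / 2))
  }
  # temporal edge form mixes the two layers
  v <- edge_climate_vector(fx$graph, fx$stack, vars, layer = 1,
                           from_cell = 0, to_cell = 0, layer_to = 2)
  expect_equal(unname(v),
               unname((fx$stack[[1]]$variables[1, vars] +
                         fx$stack[[2]]$variables[1, vars]) / 2))
})

test_that("compound weights combine rescaled climate residuals and topography", {
  fx <- weighting_fixture()
  vars <- c("bio1", "bio12")
  cond <- rbind(fx$stack[[1]]$variables[, vars], fx$stack[[2]]$variables[, vars])
  pca <- fit_pca(cond)
  line <- branch_niche_line(project(pca, cond[1, ])[1, ], project(pca, cond[6, ])[1, ])
  before <- fx$graph$hedges$topo_km
  w <- compound_weights(fx$graph, fx$stack, pca, line)
  # non-mutation of the base weights
  expect_identical(fx$graph$hedges$topo_km, before)
  expect_identical(w$topographic_km, before)
  # hand recomputation, edge by edge
  m <- edge_climate_matrix(fx$graph, fx$stack, pca$variable_names)
  raw <- climate_residual_weight(project(pca, m), line)
  expect_equal(w$climatic_raw, raw)
  expect_equal(w$compound, tardis:::rescale_zero_anchored(raw) *
                 tardis:::rescale_zero_anchored(before))
  expect_true(all(w$compound >= 0 & w$compound <= 1))
})

test_that("degenerate weighting cases behave as stated", {
  # uniform climate: compound reduces to rescaled topography
  g1 <- toy_grid(matrix(c(0, 500, 1500, 100, 2000, 50), 2, 3), age_ma = 100)
  g2 <- toy_grid(matrix(c(0, 500, 1500, 100, 2000, 50), 2, 3), age_ma = 90)
  stack <- list(compute_bioclim(constant_climatology(g1, t = 20, p = 50)),
                compute_bioclim(constant_climatology(g2, t = 20, p = 50)))
  graph <- spacetime_graph(list(g1, g2), link_degree = 1)
  set.seed(6)
  train <- cbind(bio1 = rnorm(10, 20), bio12 = rnorm(10, 600, 50))
  pca <- fit_pca(train)
  line <- branch_niche_line(project(pca, train[1, ])[1, ], project(pca, train[2, ])[1, ])
  w <- compound_weights(graph, stack, pca, line)
  expect_equal(w$compound, tardis:::rescale_zero_anchored(graph$hedges$topo_km))
  # every edge on the niche line: all compound weights exactly zero
  # the niche target is the (uniform) edge climate itself, projected through
  # the same route the weighting uses
  edge_pc <- project(pca, edge_climate_matrix(graph, stack, pca$variable_names))
  pp <- edge_pc[1, ]
  line0 <- branch_niche_line(pp, pp)
  w0 <- compound_weights(graph, stack, pca, line0)
  expect_true(all(w0$climatic_raw == 0))
  expect_equal(w0$compound, rep(0, nrow(graph$hedges)))
})

test_that("compound ordering is invariant to topographic rescaling and monotone in residuals", {
  fx <- weighting_fixture()
  vars <- c("bio1", "bio12")
  cond <- rbind(fx$stack[[1]]$variables[, vars], fx$stack[[2]]$variables[, vars])
  pca <- fit_pca(cond)
  line <- branch_niche_line(project(pca, cond[2, ])[1, ], project(pca, cond[5, ])[1, ])
  w1 <- compound_weights(fx$graph, fx$stack, pca, line)
  g2 <- fx$graph
  g2$hedges$topo_km <- g2$hedges$topo_km * 7.3
  w2 <- compound_weights(g2, fx$stack, pca, line)
  # rescaling absorbs the constant entirely, so the edge ordering (and the
  # values themselves up to rounding) are unchanged
  expect_equal(w1$compound, w2$compound)
  # increasing one edge's residual (via direct recomputation) cannot lower
  # its compound weight
  raw <- w1$climatic_raw
  bumped <- raw; bumped[3] <- bumped[3] + diff(range(raw))
  cw_before <- tardis:::rescale_zero_anchored(raw)[3] *
    tardis:::rescale_zero_anchored(fx$graph$hedges$topo_km)[3]
  cw_after <- tardis:::rescale_zero_anchored(bumped)[3] *
    tardis:::rescale_zero_anchored(fx$graph$hedges$topo_km)[3]
  expect_gte(cw_after, cw_before)
})
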