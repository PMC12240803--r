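#' @name synthetic_fixtures
#' @title Seeded synthetic landscapes, climatologies and phylogeographies
#' @description Generators for every input the pipeline consumes, with known
#'   ground truth: smooth random terrain stacks thresholded to a target land
#'   fraction, analytic monthly climatologies (latitudinal gradient +
#'   seasonal sinusoid with opposite hemispheric phase, tropical and
#'   midlatitude precipitation belts), and birth-death trees with
#'   land-restricted Brownian dispersal and Brownian climate traits. A seed
#'   fully determines all outputs; the caller's RNG state is untouched.
NULL

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# smooth random field on the grid: sum of low-frequency cosine waves,
# periodic in longitude so global grids wrap cleanly
smooth_field <- function(nrows, ncols, k = 12) {
  lon <- matrix(rep((seq_len(ncols) - 0.5) / ncols, each = nrows), nrows)
  lat <- matrix(rep((seq_len(nrows) - 0.5) / nrows, ncols), nrows)
  z <- matrix(0, nrows, ncols)
  for (i in seq_len(k)) {
    f1 <- sample(0:3, 1); f2 <- sample(0:3, 1)
    if (f1 == 0 && f2 == 0) f1 <- 1
    amp <- stats::rnorm(1, 0, 1 / sqrt(i))
    phase <- stats::runif(1, 0, 2 * pi)
    z <- z + amp * cos(2 * pi * (f1 * lon + f2 * lat) + phase)
  }
  z
}

#' Generate a time-ordered stack of synthetic elevation grids
#'
#' Smooth random terrain thresholded so each layer hits the requested land
#' fraction (up to cell discreteness); consecutive layers share most of
#' their field (AR(1) drift) so homologous land cells persist through time.
#'
#' @param seed Integer seed.
#' @param nrows,ncols Grid dimensions (default 18 x 36: a 10-degree global
#'   grid).
#' @param ages Layer ages in Ma, strictly decreasing, oldest first.
#' @param land_fraction Target fraction of unmasked cells, in (0, 1).
#' @param drift AR(1) persistence of the terrain field between layers
#'   (1 = static landscape).
#' @param relief_m Maximum land elevation (m); ocean floors slope to -4000 m.
#' @return List of `elevation_grid` (oldest first).
#' @export
make_dem_stack <- function(seed = 1, nrows = 18, ncols = 36,
                           ages = c(255, 245, 235, 225),
                           land_fraction = 0.3, drift = 0.9, relief_m = 2000) {
  if (land_fraction <= 0 || land_fraction >= 1) {
    stop("land_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  if (length(ages) < 1 || (length(ages) > 1 && any(diff(ages) >= 0))) {
    stop("ages must be strictly decreasing, oldest first", call. = FALSE)
  }
  cell <- 360 / ncols
  with_seed(seed, {
    z <- smooth_field(nrows, ncols)
    grids <- vector("list", length(ages))
    for (i in seq_along(ages)) {
      if (i > 1) {
        z <- drift * z + sqrt(1 - drift^2) * smooth_field(nrows, ncols)
      }
      thr <- stats::quantile(z, 1 - land_fraction, names = FALSE)
      land <- z > thr
      elev <- matrix(0, nrows, ncols)
      span_up <- max(z[land] - thr, 1e-6)
      elev[land] <- (z[land] - thr) / span_up * relief_m
      span_dn <- max(thr - min(z), 1e-6)
      elev[!land] <- (z[!land] - thr) / span_dn * 4000
      grids[[i]] <- elevation_grid(elev, age_ma = ages[i], cell_size_deg = cell,
                                   mask = !land, lon_min = -180, lat_max = 90)
    }
    grids
  })
}

#' Generate an analytic monthly climatology for a grid
#'
#' Temperature is a latitudinal gradient, lapse-rate adjusted over land,
#' plus a seasonal sinusoid whose amplitude grows linearly with latitude
#' and whose phase is opposite between hemispheres (July peak in the
#' north). Precipitation combines a tropical peak, midlatitude belts, a
#' mild wet-season modulation, and optional Gaussian noise, clamped at
#' zero. With `noise_sd = 0` all fields are exactly reproducible analytic
#' functions of latitude, elevation and month.
#'
#' @param grid An `elevation_grid`.
#' @param seed Integer seed (only the precipitation noise consumes it).
#' @param t_eq Equatorial annual mean temperature (deg C).
#' @param equator_pole_dt Equator-to-pole temperature difference (deg C).
#' @param lapse_c_per_km Lapse rate applied to land elevation (deg C/km).
#' @param seasonal_amp Seasonal half-amplitude at the poles (deg C).
#' @param diurnal_range tmax - tmin (deg C, constant).
#' @param p_tropical,p_belt Peak precipitation of the tropical band and the
#'   midlatitude belts (mm/month).
#' @param noise_sd Gaussian noise sd on monthly precipitation (mm/month).
#' @return A `monthly_climatology`.
#' @export
make_monthly_climatology <- function(grid, seed = 1, t_eq = 28,
                                     equator_pole_dt = 45, lapse_c_per_km = 6.5,
                                     seasonal_amp = 18, diurnal_range = 10,
                                     p_tropical = 220, p_belt = 90, noise_sd = 5) {
  nc <- grid$ncols; nr <- grid$nrows
  cells <- seq_len(nr * nc) - 1L
  ctr <- cell_center(grid, cells)
  lat <- ctr[, "lat"]
  rc <- cell_to_rc(grid, cells)
  elev <- pmax(grid$elevations[cbind(rc[, "row"] + 1L, rc[, "col"] + 1L)], 0)
  months <- 1:12
  base_t <- t_eq - equator_pole_dt * (lat / 90)^2 - lapse_c_per_km * elev / 1000
  seas <- outer(seasonal_amp * lat / 90, cos(2 * pi * (months - 7) / 12))
  tavg <- base_t + seas
  # diurnal range grows with latitude and elevation (continentality proxy)
  diurnal <- diurnal_range * (0.5 + abs(lat) / 90) + 2 * elev / 1000
  tmax <- tavg + diurnal / 2
  tmin <- tavg - diurnal / 2

  base_p <- p_tropical * exp(-(lat / 15)^2) + p_belt * exp(-((abs(lat) - 50) / 12)^2)
  wet_season <- 1 + 0.3 * outer(sign(lat), cos(2 * pi * (months - 7) / 12))
  precip <- base_p * wet_season
  if (noise_sd > 0) {
    precip <- precip + with_seed(seed, matrix(stats::rnorm(length(precip), 0, noise_sd),
                                              nrow(precip)))
  }
  precip <- pmax(precip, 0)
  monthly_climatology(tmax = tmax, tmin = tmin, precip = precip,
                      age_ma = grid$age_ma, grid = grid)
}

#' Simulate a fossil phylogeography with known ground truth
#'
#' Forward birth-death simulation from the oldest layer age to the
#' youngest (extinct lineages become fossil-like tips, so the tree is not
#' ultrametric), pruned deterministically to `n_tips`. Node locations
#' follow a Brownian walk on the sphere restricted to land by rejection
#' sampling against each node's layer mask (after 200 rejected proposals
#' the point snaps to the nearest land cell). Climate traits evolve by
#' Brownian motion with known root states and rates.
#'
#' @param n_tips Number of tips to keep.
#' @param seed Integer seed.
#' @param grids Elevation stack (oldest first) constraining the walk.
#' @param origin `c(lon, lat)` of the root; must lie on (or is snapped to)
#'   land in the oldest layer.
#' @param birth,death Per-lineage rates (events/Myr).
#' @param dispersal_sigma_km Brownian dispersal scale (km per sqrt(Myr)).
#' @param trait_roots Named numeric vector of trait root states.
#' @param trait_rates Matching Brownian rate(s) (variance per Myr).
#' @return List: `tree` (a `timetree`), `anchors` (node_id, lon, lat,
#'   age_ma for every node), `traits` (all-node matrix), `tip_traits`,
#'   and `truth` (the generating parameters).
#' @export
simulate_phylogeography <- function(n_tips = 32, seed = 1, grids,
                                    origin = NULL,
                                    birth = 0.25, death = 0.1,
                                    dispersal_sigma_km = 400,
                                    trait_roots = c(temp = 20, precip = 100),
                                    trait_rates = c(temp = 2, precip = 40)) {
  ages <- vapply(grids, function(g) g$age_ma, numeric(1))
  root_age <- ages[1]; end_age <- ages[length(ages)]
  with_seed(seed, {
    phy <- NULL
    for (try in seq_len(200)) {
      cand <- sim_bd_newick(root_age - end_age, birth, death, max_tips = 12 * n_tips)
      if (!is.null(cand) && ape::Ntip(cand) >= n_tips) { phy <- cand; break }
    }
    if (is.null(phy)) {
      stop("birth-death simulation failed to reach the requested tip count", call. = FALSE)
    }
    if (ape::Ntip(phy) > n_tips) {
      drop <- utils::tail(phy$tip.label[order(as.integer(sub("^t", "", phy$tip.label)))],
                          ape::Ntip(phy) - n_tips)
      phy <- ape::drop.tip(phy, drop)
    }
    tree <- timetree(phy)
    # absolute calendar: the root sits at the oldest layer age by construction
    depths <- ape::node.depth.edgelength(phy)
    tree$ages <- stats::setNames(root_age - depths,
                                 c(phy$tip.label, tree$phy$node.label))
    tree$root_age_ma <- root_age
    tree$durations_myr <- unname(tree$ages[phy$edge[, 1]] - tree$ages[phy$edge[, 2]])

    if (is.null(origin)) origin <- default_origin(grids[[1]])
    oc <- snap_to_land(origin, grids[[1]])
    origin <- as.numeric(cell_center(grids[[1]], oc))

    ntip <- ape::Ntip(phy)
    nn <- ntip + phy$Nnode
    loc <- matrix(NA_real_, nn, 2)
    traits <- matrix(NA_real_, nn, length(trait_roots),
                     dimnames = list(NULL, names(trait_roots)))
    root <- ntip + 1L
    loc[root, ] <- origin
    traits[root, ] <- trait_roots
    e <- phy$edge[order(depths[phy$edge[, 2]]), , drop = FALSE]  # preorder-ish
    for (k in seq_len(nrow(e))) {
      par <- e[k, 1]; ch <- e[k, 2]
      dt <- max(tree$ages[par] - tree$ages[ch], 1e-8)
      li <- layer_for_age(ages, min(max(tree$ages[ch], end_age), root_age))
      loc[ch, ] <- bm_step_on_land(loc[par, ], dispersal_sigma_km * sqrt(dt), grids[[li]])
      traits[ch, ] <- traits[par, ] + stats::rnorm(length(trait_roots), 0,
                                                   sqrt(trait_rates * dt))
    }
    labels <- c(phy$tip.label, tree$phy$node.label)
    rownames(loc) <- labels
    rownames(traits) <- labels
    anchors <- data.frame(node_id = labels, lon = loc[, 1], lat = loc[, 2],
                          age_ma = unname(tree$ages))
    list(tree = tree, anchors = anchors, traits = traits,
         tip_traits = traits[seq_len(ntip), , drop = FALSE],
         truth = list(origin = origin, birth = birth, death = death,
                      dispersal_sigma_km = dispersal_sigma_km,
                      trait_roots = trait_roots, trait_rates = trait_rates))
  })
}

default_origin <- function(grid) {
  land <- which(!t(grid$mask)) - 1L
  ctr <- cell_center(grid, land)
  # most central land cell (closest to the land centroid)
  c0 <- point_summary(ctr)
  as.numeric(ctr[which.min(geosphere::distHaversine(matrix(c0, ncol = 2), ctr)), ])
}

# forward birth-death simulation returning an ape phylo (fossil tips kept)
sim_bd_newick <- function(span_myr, birth, death, max_tips) {
  node_env <- new.env()
  node_env$n_tips <- 0
  grow <- function(t_remaining) {
    if (node_env$n_tips > max_tips) return(NULL)
    wait <- stats::rexp(1, birth + death)
    if (wait >= t_remaining) {
      node_env$n_tips <- node_env$n_tips + 1
      return(sprintf("t%d:%.8f", node_env$n_tips, t_remaining))
    }
    if (stats::runif(1) < birth / (birth + death)) {
      left <- grow(t_remaining - wait)
      right <- grow(t_remaining - wait)
      if (is.null(left) || is.null(right)) return(NULL)
      sprintf("(%s,%s):%.8f", left, right, wait)
    } else {
      node_env$n_tips <- node_env$n_tips + 1
      sprintf("t%d:%.8f", node_env$n_tips, wait)
    }
  }
  # root: require an initial split so the tree has >= 2 tips
  wait <- stats::rexp(1, birth)
  if (wait >= span_myr) return(NULL)
  left <- grow(span_myr - wait)
  right <- grow(span_myr - wait)
  if (is.null(left) || is.null(right)) return(NULL)
  txt <- sprintf("(%s,%s):%.8f;", left, right, wait)
  ape::read.tree(text = txt)
}

# one Brownian displacement restricted to land
bm_step_on_land <- function(p, sigma_km, grid) {
  for (i in seq_len(200)) {
    d_km <- abs(stats::rnorm(1, 0, sigma_km))
    brg <- stats::runif(1, 0, 360)
    q <- geosphere::destPoint(p, brg, d_km * 1000, r = 6371000)
    q <- c(((q[1, 1] + 180) %% 360) - 180, q[1, 2])
    cell <- containing_cell(grid, q[1], q[2])
    rc <- cell_to_rc(grid, cell)
    if (!grid$mask[rc[1, "row"] + 1L, rc[1, "col"] + 1L]) return(q)
  }
  as.numeric(cell_center(grid, snap_to_land(p, grid)))
}

#' Generate the complete synthetic study fixture
#'
#' One call producing everything the pipeline needs: the DEM stack, one
#' monthly climatology per layer, the simulated tree and anchors. The
#' defaults give a 10-degree global grid with 4 layers spanning 255-225 Ma
#' and a 32-tip tree.
#'
#' @param seed Integer seed driving all stages (split deterministically).
#' @param n_tips Tree size.
#' @param ... Passed to [make_dem_stack()].
#' @return List: `grids`, `climatologies`, `bioclim` (computed stack),
#'   `sim` (tree/anchors/traits/truth).
#' @export
simulate_fixture <- function(seed = 1, n_tips = 32, ...) {
  grids <- make_dem_stack(seed = seed, ...)
  climatologies <- lapply(seq_along(grids), function(i) {
    make_monthly_climatology(grids[[i]], seed = seed + 1000 + i)
  })
  bioclim <- lapply(climatologies, compute_bioclim)
  sim <- simulate_phylogeography(n_tips = n_tips, seed = seed + 2000, grids = grids)
  list(grids = grids, climatologies = climatologies, bioclim = bioclim, sim = sim)
}
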