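#' Read a node anchor table
#'
#' Delimited file (comma, header row) with columns `node_id, age_ma, lon,
#' lat` for point anchors, or `node_id, lon, lat` repeated per row for
#' posterior samples (`posterior = TRUE`, duplicates allowed).
#'
#' @param path File path.
#' @param posterior Expect posterior samples rather than unique points.
#' @return Validated data.frame.
#' @export
read_anchor_table <- function(path, posterior = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- if (posterior) c("node_id", "lon", "lat") else c("node_id", "age_ma", "lon", "lat")
  if (!all(need %in% names(tab))) {
    stop(sprintf("anchor table needs columns: %s", paste(need, collapse = ", ")), call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    line <- i + 1  # header is line 1
    if (anyNA(tab[i, need])) stop(sprintf("line %d: missing value", line), call. = FALSE)
    if (tab$lon[i] < -180 || tab$lon[i] > 180) {
      stop(sprintf("line %d: longitude %g out of range", line, tab$lon[i]), call. = FALSE)
    }
    if (tab$lat[i] < -90 || tab$lat[i] > 90) {
      stop(sprintf("line %d: latitude %g out of range", line, tab$lat[i]), call. = FALSE)
    }
  }
  if (!posterior && anyDuplicated(tab$node_id)) {
    dup <- tab$node_id[duplicated(tab$node_id)][1]
    stop(sprintf("duplicate node id '%s' in anchor table", dup), call. = FALSE)
  }
  tab
}

#' Export land-sea masks for external geographic ancestral-state software
#'
#' Nearest-neighbour upscales each layer's binary mask by an integer factor
#' and writes (a) an ESRI ASCII grid and (b) a plain-text dialect with one
#' row of 0/1 characters per latitude band (0 = traversable land,
#' 1 = masked), one pair of files per layer, named by age.
#'
#' @param grids List of `elevation_grid`.
#' @param out_dir Output directory (created if needed).
#' @param upscale_factor Positive integer block-replication factor.
#' @return Character vector of files written, invisibly.
#' @export
export_landsea_masks <- function(grids, out_dir, upscale_factor = 2) {
  if (upscale_factor < 1 || upscale_factor != round(upscale_factor)) {
    stop("upscale_factor must be a positive integer", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (g in grids) {
    up <- upscale_mask(g, upscale_factor)
    base <- file.path(out_dir, sprintf("mask_%gMa", g$age_ma))
    write_ascii_grid(up, paste0(base, ".asc"), values = "mask")
    writeLines(apply(up$mask * 1, 1, paste, collapse = ""), paste0(base, ".txt"))
    files <- c(files, paste0(base, ".asc"), paste0(base, ".txt"))
  }
  invisible(files)
}

upscale_mask <- function(grid, f) {
  idx_r <- rep(seq_len(grid$nrows), each = f)
  idx_c <- rep(seq_len(grid$ncols), each = f)
  elevation_grid(grid$elevations[idx_r, idx_c, drop = FALSE],
                 age_ma = grid$age_ma, cell_size_deg = grid$cell_size_deg / f,
                 mask = grid$mask[idx_r, idx_c, drop = FALSE],
                 lon_min = grid$lon_min, lat_max = grid$lat_max)
}

#' Run the full dispersal and disparity pipeline
#'
#' Orchestrates the stages in order: BIOCLIM computation, variable
#' selection, PCA climate space from tip conditions, ML ancestral climate
#' states, spatiotemporal graph assembly, per-branch compound weighting and
#' least-cost paths, dispersal rates, and the three disparity series
#' (ML-state based; anchor-location based; dispersal-path based). All
#' randomness flows from `config$seed`. Outputs are deterministic for a
#' fixed config, and every table carries a provenance header line with the
#' seed and config hash.
#'
#' @param config A named list (or path to a YAML file) with entries: either
#'   `simulate: {seed, n_tips, ...}` to generate the synthetic fixture, or
#'   paths `dem_manifest`, `climatology_manifest`, `tree`, `anchors`
#'   (+ optional `homology_maps`); optional `adjacency` ("queen"/"rook"),
#'   `link_degree`, `island_weight_multiplier`, `height_threshold`,
#'   `drop_list`, `clamp`, `step_myr`, `bin_myr`, `n_boot`, `seed`,
#'   `out_dir`.
#' @return Invisible list with all intermediate objects (`graph`, `pca`,
#'   `paths`, `rates`, `disparity`, ...); side effect: tables written under
#'   `out_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_defaults(config)
  validate_config(cfg)

  inputs <- load_pipeline_inputs(cfg)
  grids <- inputs$grids
  bioclim <- inputs$bioclim
  tree <- inputs$tree
  anchors <- inputs$anchors

  # climate space from tip conditions at tip anchor locations
  tips <- tree$phy$tip.label
  tip_anchor <- anchors[match(tips, anchors$node_id), , drop = FALSE]
  if (anyNA(tip_anchor$node_id)) stop("pipeline: anchors missing for some tips", call. = FALSE)
  tip_pts <- data.frame(entity = tip_anchor$node_id, lon = tip_anchor$lon,
                        lat = tip_anchor$lat, age_ma = tip_anchor$age_ma)
  cond_long <- extract_conditions_at_points(bioclim, tip_pts)
  cond <- long_to_matrix(cond_long)
  # variables constant across tips carry no information for the climate
  # space (common when few tips share coarse grid cells); exclude them
  # before redundancy clustering
  sds <- apply(cond, 2, stats::sd)
  uninformative <- colnames(cond)[is.na(sds) | sds == 0]
  selected <- select_variables(cond[, setdiff(colnames(cond), uninformative),
                                    drop = FALSE],
                               height_threshold = cfg$height_threshold,
                               drop_list = cfg$drop_list)
  pca <- fit_pca(cond[, selected, drop = FALSE])

  # ML ancestral climate states and node positions in climate space
  states <- ml_ancestral_states(tree, cond[tips, selected, drop = FALSE])
  node_mat <- states_to_matrix(states)
  node_pc <- project(pca, node_mat[, selected, drop = FALSE])
  rownames(node_pc) <- rownames(node_mat)

  # spatiotemporal graph
  graph <- spacetime_graph(grids, adjacency = cfg$adjacency,
                           link_degree = cfg$link_degree,
                           weight_multiplier = cfg$island_weight_multiplier,
                           homology_maps = inputs$homology_maps)

  # per-branch compound weights and least-cost paths
  pairs <- branch_anchor_pairs(tree, anchors)
  paths <- vector("list", nrow(pairs))
  rates <- data.frame(branch_id = pairs$branch_id,
                      length_km = NA_real_, duration_myr = pairs$duration_myr,
                      rate_km_per_myr = NA_real_, cost = NA_real_, hops = NA_integer_)
  for (b in seq_len(nrow(pairs))) {
    line <- branch_niche_line(node_pc[pairs$ancestor[b], ],
                              node_pc[pairs$descendant[b], ], clamp = cfg$clamp)
    w <- compound_weights(graph, bioclim, pca, line)
    pa <- anchor(pairs$ancestor[b], pairs$anc_lon[b], pairs$anc_lat[b], pairs$anc_age_ma[b])
    pd <- anchor(pairs$descendant[b], pairs$dec_lon[b], pairs$dec_lat[b], pairs$dec_age_ma[b])
    path <- least_cost_path(graph, w, pa, pd, branch_id = pairs$branch_id[b])
    paths[[b]] <- path
    rates$length_km[b] <- path$geographic_length_km
    rates$rate_km_per_myr[b] <- if (pairs$duration_myr[b] > 0) {
      path$geographic_length_km / pairs$duration_myr[b]
    } else 0
    rates$cost[b] <- path$compound_cost
    rates$hops[b] <- nrow(path$vertices) - 1L
  }

  disparity <- pipeline_disparity(cfg, tree, states, pca, anchors, bioclim,
                                  paths, pairs, selected)

  result <- list(config = cfg, grids = grids, bioclim = bioclim, tree = tree,
                 anchors = anchors, conditions = cond, selected_variables = selected,
                 pca = pca, states = states, node_pc = node_pc, graph = graph,
                 pairs = pairs, paths = paths, rates = rates, disparity = disparity)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, cfg)
  invisible(result)
}

pipeline_defaults <- function(config) {
  defaults <- list(adjacency = "queen", link_degree = 1,
                   island_weight_multiplier = 1, height_threshold = 0.3,
                   drop_list = "bio3", clamp = TRUE, step_myr = 0.1,
                   bin_myr = 2, n_boot = 100, seed = 1, out_dir = NULL)
  utils::modifyList(defaults, config)
}

validate_config <- function(cfg) {
  if (is.null(cfg$simulate)) {
    for (k in c("dem_manifest", "climatology_manifest", "tree", "anchors")) {
      if (is.null(cfg[[k]])) {
        stop(sprintf("config error: '%s' is required (or supply 'simulate')", k), call. = FALSE)
      }
      if (!file.exists(cfg[[k]])) {
        stop(sprintf("config error: file not found: %s", cfg[[k]]), call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    fx <- do.call(simulate_fixture, sim_args)
    return(list(grids = fx$grids, bioclim = fx$bioclim, tree = fx$sim$tree,
                anchors = fx$sim$anchors, homology_maps = NULL))
  }
  grids <- read_dem_manifest(cfg$dem_manifest)
  clim <- read_climatology_manifest(cfg$climatology_manifest, grids)
  bioclim <- lapply(clim, compute_bioclim)
  tree <- read_timetree(cfg$tree)
  anchors <- read_anchor_table(cfg$anchors)
  ages <- vapply(grids, function(g) g$age_ma, numeric(1))
  hmaps <- if (!is.null(cfg$homology_maps)) read_homology_maps(cfg$homology_maps, ages)
  list(grids = grids, bioclim = bioclim, tree = tree, anchors = anchors,
       homology_maps = hmaps)
}

#' Read a climatology manifest into monthly climatologies
#'
#' CSV with columns `age_ma, variable (tmax|tmin|precip), month, path`;
#' each path is an ESRI ASCII grid for that variable and month.
#'
#' @param manifest_path Path to the manifest.
#' @param grids The matching elevation stack (for ages and geometry).
#' @return List of `monthly_climatology`, one per layer.
#' @export
read_climatology_manifest <- function(manifest_path, grids) {
  tab <- utils::read.csv(manifest_path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("age_ma", "variable", "month", "path")
  if (!all(need %in% names(tab))) {
    stop(sprintf("climatology manifest needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  lapply(grids, function(g) {
    sub <- tab[abs(tab$age_ma - g$age_ma) < 1e-9, , drop = FALSE]
    read_var <- function(v) {
      rows <- sub[sub$variable == v, , drop = FALSE]
      if (nrow(rows) != 12) {
        stop(sprintf("layer %g Ma: expected 12 months of %s, found %d",
                     g$age_ma, v, nrow(rows)), call. = FALSE)
      }
      rows <- rows[order(rows$month), , drop = FALSE]
      lapply(rows$path, function(p) {
        if (!file.exists(p)) p <- file.path(base, p)
        read_ascii_grid(p, age_ma = g$age_ma)$elevations
      })
    }
    monthly_climatology(read_var("tmax"), read_var("tmin"), read_var("precip"),
                        age_ma = g$age_ma, grid = g)
  })
}

long_to_matrix <- function(cond_long) {
  ents <- unique(cond_long$entity)
  vars <- unique(cond_long$variable)
  m <- matrix(NA_real_, length(ents), length(vars), dimnames = list(ents, vars))
  m[cbind(match(cond_long$entity, ents), match(cond_long$variable, vars))] <- cond_long$mean
  m
}

states_to_matrix <- function(states) {
  nodes <- unique(states$node)
  vars <- unique(states$variable)
  m <- matrix(NA_real_, length(nodes), length(vars), dimnames = list(nodes, vars))
  m[cbind(match(states$node, nodes), match(states$variable, vars))] <- states$estimate
  m
}

# the three disparity datasets mirroring the three tolerance-estimate sets
pipeline_disparity <- function(cfg, tree, states, pca, anchors, bioclim,
                               paths, pairs, selected) {
  # (1) ML states (tips + nodes), interpolated along branches
  interp_ml <- interpolate_lineage_states(tree, states, step_myr = cfg$step_myr)
  d1 <- interp_to_pc(interp_ml, pca)

  # (2) conditions measured at anchor locations, interpolated along branches
  pts <- data.frame(entity = anchors$node_id, lon = anchors$lon,
                    lat = anchors$lat, age_ma = clamp_ages(anchors$age_ma, bioclim))
  loc_long <- extract_conditions_at_points(bioclim, pts, variables = selected)
  loc_states <- data.frame(node = loc_long$entity, variable = loc_long$variable,
                           age_ma = anchors$age_ma[match(loc_long$entity, anchors$node_id)],
                           estimate = loc_long$mean)
  interp_loc <- interpolate_lineage_states(tree, loc_states, step_myr = cfg$step_myr)
  d2 <- interp_to_pc(interp_loc, pca)

  # (3) conditions along the dispersal paths, timed linearly along each path
  pc_list <- list(); t_list <- list()
  for (b in seq_along(paths)) {
    pc <- sample_path_conditions(paths[[b]], bioclim, selected, pca)
    ns <- nrow(pc)
    tt <- seq(pairs$anc_age_ma[b], pairs$dec_age_ma[b], length.out = ns)
    pc_list[[b]] <- pc; t_list[[b]] <- tt
  }
  d3 <- list(times = unlist(t_list), pc = do.call(rbind, pc_list))

  mk <- function(d) bin_bootstrap_series(d$times, d$pc, bin_myr = cfg$bin_myr,
                                         n_boot = cfg$n_boot, seed = cfg$seed)
  list(ml_states = mk(d1), anchor_locations = mk(d2), dispersal_paths = mk(d3))
}

clamp_ages <- function(ages_ma, bioclim) {
  ages <- vapply(bioclim, function(b) b$age_ma, numeric(1))
  pmin(pmax(ages_ma, min(ages)), max(ages))
}

interp_to_pc <- function(interp, pca) {
  # interpolation emits identical (branch, time) sequences per variable, so
  # the long table pivots by simple column binding
  vars <- unique(interp$variable)
  sub1 <- interp[interp$variable == vars[1], , drop = FALSE]
  m <- vapply(vars, function(v) interp$value[interp$variable == v],
              numeric(nrow(sub1)))
  colnames(m) <- vars
  list(times = sub1$time_ma, pc = project(pca, m))
}

write_pipeline_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  prov <- sprintf("# tardis provenance: seed=%d config=%s", cfg$seed, hash)
  wr <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    con <- file(path, "w")
    writeLines(prov, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  wr(result$rates, "rates.csv")
  wr(data.frame(variable = result$selected_variables), "selected_variables.csv")
  wr(as.data.frame(result$conditions), "tip_conditions.csv")
  wr(result$states, "node_states.csv")
  wr(result$disparity$ml_states, "disparity_ml_states.csv")
  wr(result$disparity$anchor_locations, "disparity_anchor_locations.csv")
  wr(result$disparity$dispersal_paths, "disparity_dispersal_paths.csv")
  verts <- do.call(rbind, lapply(result$paths, function(p) {
    cbind(branch_id = p$branch_id, p$vertices)
  }))
  wr(verts, "path_vertices.csv")
  write_paths_geojson(result$paths, file.path(cfg$out_dir, "paths.geojson"))
  jsonlite::write_json(list(seed = cfg$seed, config_hash = hash),
                       file.path(cfg$out_dir, "provenance.json"), auto_unbox = TRUE)
  invisible(cfg$out_dir)
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

#' Write dispersal paths as GeoJSON LineStrings
#'
#' One feature per contiguous same-layer segment of each path, with branch
#' id and layer age as properties.
#'
#' @param paths List of `dispersal_path`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_paths_geojson <- function(paths, path) {
  features <- list()
  for (p in paths) {
    v <- p$vertices
    seg_id <- cumsum(c(1, diff(v$layer) != 0))
    for (s in unique(seg_id)) {
      sub <- v[seg_id == s, , drop = FALSE]
      if (nrow(sub) < 2) next
      features[[length(features) + 1]] <- list(
        type = "Feature",
        properties = list(branch_id = p$branch_id,
                          layer_age_ma = sub$layer_age_ma[1]),
        geometry = list(type = "LineString",
                        coordinates = unname(lapply(seq_len(nrow(sub)), function(i) {
                          c(sub$lon[i], sub$lat[i])
                        }))))
    }
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
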