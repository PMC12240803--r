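#' Read a time-scaled tree and compute absolute node ages
#'
#' Parses Newick (with branch lengths in Myr) via ape and converts relative
#' depths to absolute ages in Ma by holding one tip at a known age. By
#' default the deepest tip (the one at the maximum root-to-tip distance) is
#' held at `anchor_age_ma`; name a different tip to anchor elsewhere.
#' Polytomies are preserved; internal nodes without labels receive labels
#' `n<k>` so anchor tables can refer to them.
#'
#' @param newick Newick string or path to a file containing one.
#' @param anchor_tip Tip label held at a known age; `NULL` = deepest tip.
#' @param anchor_age_ma Absolute age of the anchor tip (Ma).
#' @return A `timetree`: the `phylo` object plus `ages` (named, tips then
#'   internal nodes in ape numbering) and per-edge `durations_myr`.
#' @export
read_timetree <- function(newick, anchor_tip = NULL, anchor_age_ma = 0) {
  phy <- if (file.exists(newick[1]) && !grepl("\\(", newick[1])) {
    ape::read.tree(newick)
  } else {
    ape::read.tree(text = newick)
  }
  if (is.null(phy$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(phy$edge.length < 0)) stop("negative branch lengths are not allowed", call. = FALSE)
  timetree(phy, anchor_tip, anchor_age_ma)
}

#' Construct a timetree from an existing phylo object
#'
#' @inheritParams read_timetree
#' @param phy An ape `phylo` with branch lengths.
#' @return A `timetree`.
#' @export
timetree <- function(phy, anchor_tip = NULL, anchor_age_ma = 0) {
  ntip <- ape::Ntip(phy)
  if (is.null(phy$node.label) || any(phy$node.label == "")) {
    phy$node.label <- paste0("n", seq_len(phy$Nnode))
  }
  depths <- ape::node.depth.edgelength(phy)  # distance from root
  if (is.null(anchor_tip)) {
    anchor_idx <- which.max(depths[seq_len(ntip)])
  } else {
    anchor_idx <- match(anchor_tip, phy$tip.label)
    if (is.na(anchor_idx)) stop(sprintf("anchor tip '%s' not in tree", anchor_tip), call. = FALSE)
  }
  root_age <- anchor_age_ma + depths[anchor_idx]
  ages <- root_age - depths
  names(ages) <- c(phy$tip.label, phy$node.label)
  durations <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  structure(list(phy = phy, ages = ages, durations_myr = unname(durations),
                 root_age_ma = root_age),
            class = "timetree")
}

#' @export
print.timetree <- function(x, ...) {
  cat(sprintf("<timetree> %d tips, %d internal nodes, root age %.2f Ma\n",
              ape::Ntip(x$phy), x$phy$Nnode, x$root_age_ma))
  invisible(x)
}

node_label <- function(tree, num) {
  ntip <- ape::Ntip(tree$phy)
  ifelse(num <= ntip, tree$phy$tip.label[num], tree$phy$node.label[num - ntip])
}

#' Pair anchors along every branch of a tree
#'
#' @param tree A `timetree`.
#' @param anchors Data.frame with columns `node_id`, `lon`, `lat` and
#'   optional `age_ma` (defaults to the tree's node ages). Every tree node
#'   (tips and internal) must be present exactly once.
#' @return Data.frame, one row per branch: ancestor/descendant ids,
#'   coordinates, ages, and `duration_myr`.
#' @export
branch_anchor_pairs <- function(tree, anchors) {
  phy <- tree$phy
  labels <- c(phy$tip.label, phy$node.label)
  hit <- match(labels, anchors$node_id)
  if (anyNA(hit)) {
    stop(sprintf("missing anchor(s) for node(s): %s",
                 paste(utils::head(labels[is.na(hit)], 5), collapse = ", ")), call. = FALSE)
  }
  age <- if (!is.null(anchors$age_ma)) anchors$age_ma[hit] else unname(tree$ages)
  e <- phy$edge
  data.frame(
    branch_id = paste0(labels[e[, 1]], "->", labels[e[, 2]]),
    ancestor = labels[e[, 1]], descendant = labels[e[, 2]],
    anc_lon = anchors$lon[hit][e[, 1]], anc_lat = anchors$lat[hit][e[, 1]],
    anc_age_ma = age[e[, 1]],
    dec_lon = anchors$lon[hit][e[, 2]], dec_lat = anchors$lat[hit][e[, 2]],
    dec_age_ma = age[e[, 2]],
    duration_myr = age[e[, 1]] - age[e[, 2]])
}

#' Maximum-likelihood Brownian ancestral states with confidence intervals
#'
#' Per-variable generalized least squares on the Brownian-motion tree
#' covariance: the root estimate is the GLS mean, internal nodes are the
#' conditional expectations given the tips, and normal-theory 95% intervals
#' use the REML rate estimate with the prediction variance accounting for
#' root uncertainty. For a two-tip tree with equal branch lengths the root
#' is the tip mean. Tips appear in the output with their observed states
#' and zero-width intervals.
#'
#' @param tree A `timetree` with positive branch durations.
#' @param tip_states Named numeric vector (one variable), or a tips x
#'   variables matrix/data.frame with row names matching tip labels.
#' @return Data.frame (node, variable, age_ma, estimate, lo95, hi95).
#' @export
ml_ancestral_states <- function(tree, tip_states) {
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  if (any(tree$durations_myr <= 0)) {
    stop("all branch durations must be positive (collapse zero-length branches first)",
         call. = FALSE)
  }
  if (is.null(dim(tip_states))) {
    tip_states <- matrix(tip_states, ncol = 1,
                         dimnames = list(names(tip_states), "state"))
  }
  tip_states <- as.matrix(tip_states)
  if (is.null(rownames(tip_states))) rownames(tip_states) <- phy$tip.label
  miss <- setdiff(phy$tip.label, rownames(tip_states))
  if (length(miss)) stop(sprintf("missing tip state(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  y_all <- tip_states[phy$tip.label, , drop = FALSE]

  C <- ape::vcv(phy)                       # tip covariance (shared root paths)
  Ci <- solve(C)
  one <- rep(1, ntip)
  denom <- sum(Ci)                         # 1' C^-1 1

  depths <- ape::node.depth.edgelength(phy)
  mrca_all <- ape::mrca(phy, full = TRUE)
  internal <- ntip + seq_len(phy$Nnode)
  # shared path length between each internal node and each tip
  S <- matrix(depths[mrca_all[internal, seq_len(ntip)]], nrow = phy$Nnode)
  v_node <- depths[internal]

  out <- lapply(colnames(y_all), function(var) {
    y <- y_all[, var]
    mu <- sum(Ci %*% y) / denom
    resid <- y - mu
    sig2 <- as.numeric(t(resid) %*% Ci %*% resid) / (ntip - 1)  # REML rate
    CiR <- Ci %*% resid
    est <- mu + as.numeric(S %*% CiR)
    CiS <- Ci %*% t(S)                      # ntip x Nnode
    quad <- colSums(t(S) * CiS)             # s' C^-1 s per node
    root_term <- (1 - colSums(CiS))^2 / denom
    pv <- sig2 * pmax(v_node - quad + root_term, 0)
    half <- stats::qnorm(0.975) * sqrt(pv)
    rbind(
      data.frame(node = phy$tip.label, variable = var,
                 age_ma = unname(tree$ages[seq_len(ntip)]),
                 estimate = unname(y), lo95 = unname(y), hi95 = unname(y)),
      data.frame(node = phy$node.label, variable = var,
                 age_ma = unname(tree$ages[internal]),
                 estimate = est, lo95 = est - half, hi95 = est + half))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Linearly interpolate node states along every branch
#'
#' Along each branch the state table is interpolated at fixed time steps
#' from the older endpoint, with the younger endpoint appended when the step
#' does not land on it exactly; both endpoints are always present. When the
#' step divides the duration the sample count is
#' `floor(duration / step) + 1`.
#'
#' @param tree A `timetree`.
#' @param states A node state table as returned by [ml_ancestral_states()]
#'   (long form: node, variable, age_ma, estimate).
#' @param step_myr Time step (default 0.1 Myr).
#' @return Data.frame (branch_id, variable, time_ma, value).
#' @export
interpolate_lineage_states <- function(tree, states, step_myr = 0.1) {
  if (step_myr <= 0) stop("step_myr must be positive", call. = FALSE)
  phy <- tree$phy
  labels <- c(phy$tip.label, phy$node.label)
  e <- phy$edge
  out <- vector("list", nrow(e) * length(unique(states$variable)))
  k <- 0
  for (var in unique(states$variable)) {
    sub <- states[states$variable == var, ]
    val <- stats::setNames(sub$estimate, sub$node)
    for (b in seq_len(nrow(e))) {
      anc <- labels[e[b, 1]]; dec <- labels[e[b, 2]]
      t0 <- tree$ages[e[b, 1]]; t1 <- tree$ages[e[b, 2]]
      times <- branch_time_grid(t0, t1, step_myr)
      frac <- if (t0 == t1) rep(0, length(times)) else (t0 - times) / (t0 - t1)
      k <- k + 1
      out[[k]] <- data.frame(branch_id = paste0(anc, "->", dec), variable = var,
                             time_ma = times,
                             value = val[[anc]] + frac * (val[[dec]] - val[[anc]]))
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

branch_time_grid <- function(older_ma, younger_ma, step_myr) {
  d <- older_ma - younger_ma
  n <- floor(d / step_myr + 1e-9) + 1
  times <- older_ma - (seq_len(n) - 1) * step_myr
  if (times[n] > younger_ma + 1e-9) times <- c(times, younger_ma)
  times
}

#' Summarize posterior samples of a geographic origin
#'
#' Bins posterior (lon, lat) samples on a regular grid (default 1 degree),
#' smooths the 2-D histogram with a Gaussian kernel (Silverman's rule per
#' marginal by default), and reports the highest-density cell centre, the
#' marginal 95% highest-density intervals, and whether the smoothed surface
#' has a single local maximum (unimodality).
#'
#' @param samples Two-column matrix/data.frame of (lon, lat) samples.
#' @param grid_deg Bin size in degrees.
#' @param bandwidth_deg Gaussian kernel sd in degrees (length 1 or 2 for
#'   lon/lat); `NULL` = Silverman's rule per marginal.
#' @return List: `mode` (lon/lat of peak cell centre), `lon_hpd95`,
#'   `lat_hpd95`, `unimodal`, and the smoothed `density` matrix.
#' @export
summarize_origin_posterior <- function(samples, grid_deg = 1, bandwidth_deg = NULL) {
  m <- to_coord_matrix(samples)
  check_lonlat(m)
  if (nrow(m) < 1) stop("at least one sample required", call. = FALSE)
  lon_breaks <- seq(-180, 180, by = grid_deg)
  lat_breaks <- seq(-90, 90, by = grid_deg)
  ix <- pmin(pmax(findInterval(m[, 1], lon_breaks, rightmost.closed = TRUE), 1),
             length(lon_breaks) - 1)
  iy <- pmin(pmax(findInterval(m[, 2], lat_breaks, rightmost.closed = TRUE), 1),
             length(lat_breaks) - 1)
  h <- matrix(0, length(lat_breaks) - 1, length(lon_breaks) - 1)
  for (k in seq_len(nrow(m))) h[iy[k], ix[k]] <- h[iy[k], ix[k]] + 1

  if (is.null(bandwidth_deg)) {
    bw <- c(silverman_bw(m[, 1]), silverman_bw(m[, 2]))
  } else {
    bw <- rep(bandwidth_deg, length.out = 2)
  }
  bw_cells <- pmax(bw / grid_deg, 1e-6)
  sm <- gauss_smooth_2d(h, bw_cells[1], bw_cells[2], wrap_x = TRUE)

  peak <- arrayInd(which.max(sm), dim(sm))
  mode <- c(lon = lon_breaks[peak[2]] + grid_deg / 2,
            lat = lat_breaks[peak[1]] + grid_deg / 2)
  list(mode = mode,
       lon_hpd95 = marginal_hpd(colSums(sm), lon_breaks),
       lat_hpd95 = marginal_hpd(rowSums(sm), lat_breaks),
       unimodal = count_local_maxima(sm, wrap_x = TRUE) <= 1,
       density = sm)
}

silverman_bw <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  # degenerate samples: effectively unsmoothed so the histogram stays a spike
  if (is.na(s) || s == 0) return(1e-6)
  spread <- min(s, stats::IQR(x) / 1.349)
  if (spread == 0) spread <- s
  0.9 * spread * n^(-1 / 5)
}

# separable Gaussian smoothing of a histogram matrix; x (columns) optionally
# wraps (longitudes), y (rows) truncates at the poles
gauss_smooth_2d <- function(h, sx, sy, wrap_x = FALSE) {
  kern <- function(s) {
    r <- max(1, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k / sum(k)
  }
  kx <- kern(sx); ky <- kern(sy)
  sm <- apply(h, 2, conv_1d, k = ky, wrap = FALSE)        # smooth down columns (lat)
  sm <- t(apply(sm, 1, conv_1d, k = kx, wrap = wrap_x))   # smooth along rows (lon)
  sm
}

conv_1d <- function(x, k, wrap) {
  n <- length(x); r <- (length(k) - 1) / 2
  if (wrap) {
    xx <- c(utils::tail(x, r), x, utils::head(x, r))
    out <- stats::filter(xx, k, sides = 2)[(r + 1):(r + n)]
  } else {
    xx <- c(rep(0, r), x, rep(0, r))
    out <- stats::filter(xx, k, sides = 2)[(r + 1):(r + n)]
    # renormalize truncated mass at the edges
    w <- stats::filter(c(rep(0, r), rep(1, n), rep(0, r)), k, sides = 2)[(r + 1):(r + n)]
    out <- out / w
  }
  as.numeric(out)
}

marginal_hpd <- function(dens, breaks, level = 0.95) {
  total <- sum(dens)
  if (total == 0) return(c(NA_real_, NA_real_))
  o <- order(dens, decreasing = TRUE)
  k <- which(cumsum(dens[o]) >= total * level - 1e-12)[1]  # smallest HPD bin set
  need <- sort(o[seq_len(k)])
  c(breaks[need[1]], breaks[need[length(need)] + 1])
}

count_local_maxima <- function(m, wrap_x = FALSE, eps = 1e-12) {
  nr <- nrow(m); nc <- ncol(m)
  cnt <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- m[i, j]
      if (v <= eps) next
      is_max <- TRUE
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (wrap_x) jj <- ((jj - 1) %% nc) + 1
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (m[ii, jj] > v + eps) { is_max <- FALSE; break }
        # ties on a plateau: count only the first (lowest index) cell
        if (abs(m[ii, jj] - v) <= eps && (ii < i || (ii == i && jj < j))) {
          is_max <- FALSE; break
        }
      }
      if (is_max) cnt <- cnt + 1
    }
  }
  cnt
}

#' Stratigraphic consistency index
#'
#' Fraction of internal nodes (root excluded) whose oldest descendant first
#' appearance is not older than the oldest first appearance of its sister
#' lineage (for polytomies, all other children of the parent).
#'
#' @param tree A `timetree` or ape `phylo`.
#' @param tip_first_ages Named numeric vector of first-appearance ages (Ma)
#'   for every tip.
#' @return SCI in `[0, 1]`.
#' @export
stratigraphic_consistency_index <- function(tree, tip_first_ages) {
  phy <- if (inherits(tree, "timetree")) tree$phy else tree
  ntip <- ape::Ntip(phy)
  fad <- tip_first_ages[phy$tip.label]
  if (anyNA(fad)) stop("missing first-appearance age(s)", call. = FALSE)
  oldest <- oldest_descendant_fad(phy, fad)
  root <- ntip + 1L
  internal <- setdiff(ntip + seq_len(phy$Nnode), root)
  if (length(internal) == 0) return(NA_real_)
  consistent <- vapply(internal, function(nd) {
    parent <- phy$edge[phy$edge[, 2] == nd, 1]
    sibs <- setdiff(phy$edge[phy$edge[, 1] == parent, 2], nd)
    oldest[nd] <= max(oldest[sibs]) + 1e-12
  }, logical(1))
  mean(consistent)
}

# oldest descendant FAD for every node (tips = own FAD), by postorder
oldest_descendant_fad <- function(phy, fad) {
  ntip <- ape::Ntip(phy)
  oldest <- numeric(ntip + phy$Nnode)
  oldest[seq_len(ntip)] <- fad
  e <- phy$edge[ape::postorder(phy), , drop = FALSE]
  for (k in seq_len(nrow(e))) {
    oldest[e[k, 1]] <- max(oldest[e[k, 1]], oldest[e[k, 2]])
  }
  oldest
}

#' Gap excess ratio
#'
#' `GER = 1 - (MIG - G_min) / (G_max - G_min)` where MIG is the minimum
#' implied ghost-lineage gap of the observed topology (internal node ages
#' set to the oldest descendant first appearance), `G_min` is the range of
#' first-appearance ages (the smallest MIG any topology can achieve) and
#' `G_max = sum(oldest FAD - FAD_i)` (the largest, realized by nesting the
#' oldest tip deepest). Equals 1 when the topology implies the least
#' possible ghost range.
#'
#' @inheritParams stratigraphic_consistency_index
#' @return GER in `[0, 1]`; 1 (with a warning) when all tips share one age.
#' @export
gap_excess_ratio <- function(tree, tip_first_ages) {
  phy <- if (inherits(tree, "timetree")) tree$phy else tree
  fad <- tip_first_ages[phy$tip.label]
  if (anyNA(fad)) stop("missing first-appearance age(s)", call. = FALSE)
  mig <- minimum_implied_gap(phy, fad)
  g_min <- max(fad) - min(fad)
  g_max <- sum(max(fad) - fad)
  if (g_max - g_min < 1e-12) {
    warning("all tip ages equal: GER undefined, returning 1 by convention", call. = FALSE)
    return(1)
  }
  1 - (mig - g_min) / (g_max - g_min)
}

#' Minimum implied ghost-lineage gap of a topology
#'
#' Sum over all branches of (parent age - child age) with every internal
#' node dated to the oldest first appearance among its descendants.
#'
#' @inheritParams stratigraphic_consistency_index
#' @return Total ghost range in Myr.
#' @export
minimum_implied_gap <- function(tree, tip_first_ages) {
  phy <- if (inherits(tree, "timetree")) tree$phy else tree
  fad <- tip_first_ages[phy$tip.label]
  oldest <- oldest_descendant_fad(phy, fad)
  sum(oldest[phy$edge[, 1]] - oldest[phy$edge[, 2]])
}
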