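#' Fit the PCA climate space from sampled conditions
#'
#' Columns are centred and scaled to unit variance before the decomposition
#' (the variables are in incommensurable units) and all axes are retained,
#' so pairwise distances among scores equal distances among standardized
#' inputs.
#'
#' @param conditions Numeric samples x variables matrix/data.frame.
#' @return A `climate_pca`: `variable_names`, `centers`, `scales`,
#'   `rotation` (orthonormal loadings), `scores` (training projections) and
#'   `explained_variance` per axis (summing to the number of variables up to
#'   numerical tolerance).
#' @export
fit_pca <- function(conditions) {
  x <- as.matrix(conditions)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- colnames(x)[sds == 0 | is.na(sds)]
    stop(sprintf("zero-variance column(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  structure(
    list(variable_names = colnames(x),
         centers = p$center, scales = p$scale,
         rotation = p$rotation, scores = p$x,
         explained_variance = p$sdev^2),
    class = "climate_pca")
}

#' @export
print.climate_pca <- function(x, ...) {
  pct <- 100 * x$explained_variance / sum(x$explained_variance)
  cat(sprintf("<climate_pca> %d variables, %d samples; PC1 %.1f%%, PC2 %.1f%%\n",
              length(x$variable_names), nrow(x$scores), pct[1],
              if (length(pct) > 1) pct[2] else 0))
  invisible(x)
}

#' Project points into a fitted climate space
#'
#' Applies `(point - centers) / scales %*% rotation`. The map is linear in
#' the standardized coordinates, so midpoints project to midpoints.
#'
#' @param pca A `climate_pca`.
#' @param point Numeric vector over the pca's variables, or a matrix with
#'   one point per row (columns matched by name when present).
#' @return Matrix of PC coordinates (one row per point).
#' @export
project <- function(pca, point) {
  if (is.null(dim(point))) point <- matrix(point, nrow = 1, dimnames = list(NULL, names(point)))
  point <- as.matrix(point)
  if (!is.null(colnames(point))) {
    missing <- setdiff(pca$variable_names, colnames(point))
    if (length(missing)) {
      stop(sprintf("point lacks variable(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
    }
    point <- point[, pca$variable_names, drop = FALSE]
  } else if (ncol(point) != length(pca$variable_names)) {
    stop(sprintf("point has %d values but the climate space has %d variables",
                 ncol(point), length(pca$variable_names)), call. = FALSE)
  }
  z <- sweep(sweep(point, 2, pca$centers, "-"), 2, pca$scales, "/")
  z %*% pca$rotation
}

#' Sample climatic conditions at dated geographic points
#'
#' Each point is assigned to the layer whose age interval contains its age
#' (see [layer_for_age()]), snapped to the nearest land cell, and the
#' selected variables are read from that cell. Per entity the variables are
#' summarized as the weighted mean and weighted percentile 95% interval,
#' with weights proportional to the supplied sample density.
#'
#' @param bioclim_stack List of `bioclim_grid` (oldest first, with grids).
#' @param points Data.frame with columns `entity`, `lon`, `lat`, `age_ma`
#'   and optional `weight` (default 1).
#' @param variables Variable names to extract (default all 19).
#' @return Data.frame (entity, variable, mean, lo95, hi95, n).
#' @export
extract_conditions_at_points <- function(bioclim_stack, points,
                                         variables = bioclim_names()) {
  stopifnot(is.data.frame(points))
  need <- c("entity", "lon", "lat", "age_ma")
  if (!all(need %in% names(points))) {
    stop(sprintf("points needs columns: %s", paste(need, collapse = ", ")), call. = FALSE)
  }
  if (is.null(points$weight)) points$weight <- 1
  ages <- vapply(bioclim_stack, function(b) b$age_ma, numeric(1))
  vals <- condition_matrix_at_points(bioclim_stack, points, variables, ages)
  out <- do.call(rbind, lapply(split(seq_len(nrow(points)), points$entity), function(idx) {
    w <- points$weight[idx]
    sub <- vals[idx, , drop = FALSE]
    data.frame(entity = points$entity[idx[1]], variable = variables,
               mean = apply(sub, 2, weighted_mean, w = w),
               lo95 = apply(sub, 2, weighted_quantile, w = w, p = 0.025),
               hi95 = apply(sub, 2, weighted_quantile, w = w, p = 0.975),
               n = length(idx), row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

condition_matrix_at_points <- function(bioclim_stack, points, variables, ages) {
  vals <- matrix(NA_real_, nrow(points), length(variables),
                 dimnames = list(NULL, variables))
  for (i in seq_len(nrow(points))) {
    li <- layer_for_age(ages, points$age_ma[i])
    bc <- bioclim_stack[[li]]
    if (is.null(bc$grid)) stop("bioclim layer lacks grid geometry", call. = FALSE)
    cell <- snap_to_land(c(points$lon[i], points$lat[i]), bc$grid)
    row <- bc$variables[cell + 1L, variables]
    if (anyNA(row)) {
      stop(sprintf("missing climate at layer %g Ma, cell %d", bc$age_ma, cell), call. = FALSE)
    }
    vals[i, ] <- row
  }
  vals
}

weighted_mean <- function(x, w) sum(x * w) / sum(w)

# inverse-CDF weighted quantile
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= p - 1e-12)[1]]
}
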