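#' Monthly climatology for one layer
#'
#' Twelve months of maximum temperature, minimum temperature and
#' precipitation on the same grid geometry as the paired elevation layer.
#'
#' @param tmax,tmin Lists of 12 matrices (deg C) or `ncell x 12` matrices.
#' @param precip As above, mm/month, non-negative.
#' @param age_ma Layer age (Ma).
#' @param grid Optional `elevation_grid` giving the geometry.
#' @return A `monthly_climatology` with `ncell x 12` matrices (cells in
#'   0-based row-major order).
#' @export
monthly_climatology <- function(tmax, tmin, precip, age_ma, grid = NULL) {
  tmax <- months_to_matrix(tmax); tmin <- months_to_matrix(tmin)
  precip <- months_to_matrix(precip)
  if (ncol(tmax) != 12 || ncol(tmin) != 12 || ncol(precip) != 12) {
    stop("need exactly 12 months of tmax, tmin and precip", call. = FALSE)
  }
  if (nrow(tmax) != nrow(tmin) || nrow(tmax) != nrow(precip)) {
    stop("tmax, tmin and precip must cover the same cells", call. = FALSE)
  }
  if (any(tmax < tmin)) stop("tmax must be >= tmin in every cell and month", call. = FALSE)
  if (any(precip < 0)) stop("precip must be non-negative", call. = FALSE)
  structure(list(tmax = tmax, tmin = tmin, precip = precip,
                 age_ma = age_ma, grid = grid),
            class = "monthly_climatology")
}

# accept list of 12 matrices (row 1 = north) or an ncell x 12 matrix
months_to_matrix <- function(x) {
  if (is.list(x)) {
    cols <- lapply(x, function(m) as.numeric(t(m)))  # row-major flatten
    x <- do.call(cbind, cols)
  }
  as.matrix(x)
}

#' Compute the 19 BIOCLIM variables from a monthly climatology
#'
#' Standard ANUCLIM-convention bioclimatic variables. Monthly mean
#' temperature is `(tmax + tmin) / 2`. Quarters are consecutive 3-month
#' windows with December-January wraparound; ties for the
#' warmest/coldest/wettest/driest quarter are broken by the earliest start
#' month. Seasonality (bio4, bio15) uses the sample (n-1) standard deviation.
#' bio3 (isothermality) is NaN where bio7 is zero.
#'
#' @param clim A `monthly_climatology`.
#' @param sd_population Use the population (n) instead of the sample (n-1)
#'   standard deviation in bio4/bio15.
#' @return A `bioclim_grid`: `ncell x 19` matrix with columns `bio1..bio19`,
#'   plus the layer age and grid geometry.
#' @export
compute_bioclim <- function(clim, sd_population = FALSE) {
  if (!inherits(clim, "monthly_climatology")) {
    stop("clim must be a monthly_climatology", call. = FALSE)
  }
  tmax <- clim$tmax; tmin <- clim$tmin; prec <- clim$precip
  tavg <- (tmax + tmin) / 2
  n <- nrow(tavg)
  denom <- if (sd_population) 12 else 11

  row_sd <- function(m) sqrt(rowSums((m - rowMeans(m))^2) / denom)
  row_max <- function(m) do.call(pmax, as.data.frame(m))
  row_min <- function(m) do.call(pmin, as.data.frame(m))

  # quarter sums/means: column q = months q, q+1, q+2 (wrapping)
  qsum <- function(m) {
    idx2 <- c(2:12, 1); idx3 <- c(3:12, 1, 2)
    m + m[, idx2, drop = FALSE] + m[, idx3, drop = FALSE]
  }
  qt <- qsum(tavg) / 3     # quarterly mean temperature
  qp <- qsum(prec)         # quarterly precipitation totals

  # which.max/min over rows, first (earliest start month) wins ties
  arg_row <- function(m, maxim = TRUE) {
    f <- if (maxim) which.max else which.min
    apply(m, 1, f)
  }
  pick <- function(m, j) m[cbind(seq_len(n), j)]

  wetq <- arg_row(qp, TRUE); dryq <- arg_row(qp, FALSE)
  warmq <- arg_row(qt, TRUE); coldq <- arg_row(qt, FALSE)

  bio <- matrix(NA_real_, n, 19, dimnames = list(NULL, paste0("bio", 1:19)))
  bio[, 1] <- rowMeans(tavg)
  bio[, 2] <- rowMeans(tmax - tmin)
  bio[, 5] <- row_max(tmax)
  bio[, 6] <- row_min(tmin)
  bio[, 7] <- bio[, 5] - bio[, 6]
  bio[, 3] <- 100 * bio[, 2] / bio[, 7]
  bio[, 4] <- 100 * row_sd(tavg)
  bio[, 8] <- pick(qt, wetq)
  bio[, 9] <- pick(qt, dryq)
  bio[, 10] <- pick(qt, warmq)
  bio[, 11] <- pick(qt, coldq)
  bio[, 12] <- rowSums(prec)
  bio[, 13] <- row_max(prec)
  bio[, 14] <- row_min(prec)
  bio[, 15] <- 100 * row_sd(prec) / (1 + bio[, 12] / 12)
  bio[, 16] <- pick(qp, wetq)
  bio[, 17] <- pick(qp, dryq)
  bio[, 18] <- pick(qp, warmq)
  bio[, 19] <- pick(qp, coldq)

  structure(list(variables = bio, age_ma = clim$age_ma, grid = clim$grid),
            class = "bioclim_grid")
}

#' @export
print.bioclim_grid <- function(x, ...) {
  cat(sprintf("<bioclim_grid> age %g Ma, %d cells x 19 variables\n",
              x$age_ma, nrow(x$variables)))
  invisible(x)
}

#' Names of the BIOCLIM variables
#'
#' @return Character vector `bio1..bio19` with long names as the `names`
#'   attribute.
#' @export
bioclim_names <- function() {
  long <- c("annual mean temperature", "mean diurnal range", "isothermality",
            "temperature seasonality", "max temperature of warmest month",
            "min temperature of coldest month", "temperature annual range",
            "mean temperature of wettest quarter", "mean temperature of driest quarter",
            "mean temperature of warmest quarter", "mean temperature of coldest quarter",
            "annual precipitation", "precipitation of wettest month",
            "precipitation of driest month", "precipitation seasonality",
            "precipitation of wettest quarter", "precipitation of driest quarter",
            "precipitation of warmest quarter", "precipitation of coldest quarter")
  stats::setNames(paste0("bio", 1:19), long)
}

#' Select a low-redundancy subset of BIOCLIM variables
#'
#' Clusters variables by `1 - Pearson r` distance with hierarchical
#' clustering, cuts the dendrogram at `height_threshold` (default 0.3,
#' i.e. r = 0.7), and keeps one representative per cluster. Monthly-scale
#' variables are preferred over quarterly ones to capture climatic extremes;
#' within the same preference class the lowest bio number wins. Variables in
#' `drop_list` are removed before clustering regardless of correlation
#' (default: bio3, isothermality).
#'
#' @param bioclim_at_samples Numeric samples x variables matrix/data.frame
#'   with bio names as columns.
#' @param height_threshold Dendrogram cut height in `1 - r` units.
#' @param drop_list Variables excluded unconditionally.
#' @param linkage Linkage method for [stats::hclust()].
#' @return Character vector of retained variable names (bio order).
#' @export
select_variables <- function(bioclim_at_samples, height_threshold = 0.3,
                             drop_list = "bio3", linkage = "complete") {
  x <- as.matrix(bioclim_at_samples)
  if (nrow(x) < 3) stop("need at least 3 samples to estimate correlations", call. = FALSE)
  x <- x[, setdiff(colnames(x), drop_list), drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- colnames(x)[sds == 0 | is.na(sds)]
    stop(sprintf("zero-variance variable(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  r <- stats::cor(x)
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  cl <- stats::cutree(hc, h = height_threshold)
  keep <- vapply(split(names(cl), cl), function(members) {
    members[order(variable_preference(members), bio_number(members))][1]
  }, character(1))
  keep <- keep[order(bio_number(keep))]
  unname(keep)
}

bio_number <- function(v) as.integer(sub("^bio", "", v))

# 1 = monthly-scale / annual summaries, 2 = quarterly composites
variable_preference <- function(v) {
  quarterly <- paste0("bio", c(8:11, 16:19))
  ifelse(v %in% quarterly, 2L, 1L)
}
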