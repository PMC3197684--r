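#' Standard water-column sampling depths
#'
#' The 13 depths (m) at which climatological mean annual temperatures are
#' taken, spanning the potential depth habitat of a thermocline-dwelling
#' foraminifer.
#' @export
water_column_depths <- function() {
  c(0, 10, 20, 30, 50, 75, 100, 125, 150, 250, 300, 400, 500)
}

# Great-circle central angle (degrees) between two points given in degrees.
.central_angle <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  ca <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon1 - lon2) * r)
  acos(pmin(1, pmax(-1, ca))) / r
}

.wrap_lon <- function(lon) ((lon + 180) %% 360) - 180

#' Interpolate a missing gridded temperature from its neighbors
#'
#' Fills one missing locality-by-depth value of a 1-degree gridded
#' temperature field from the (at most 8) cells immediately surrounding
#' the target cell (a 3x3-degree neighborhood), as the weighted average of
#' the available neighbor values.  The default weighting factor is the
#' inverse great-circle angular distance between cell centers, so diagonal
#' neighbors weigh relatively more at high latitude; `method = "flat"`
#' uses plane 1 / sqrt(2) degree distances instead.  Cells are identified
#' by the integer latitude/longitude of their south-west corner, values
#' sit at cell centers, and longitude wraps at +/-180.
#'
#' @param grid `data.frame` with columns `lat`, `lon` (integer SW
#'   corners), `depth` (m) and `temp` (deg C, `NA` = missing).
#' @param lat,lon,depth the target cell and depth.
#' @param method `"angular"` (default) or `"flat"`.
#' @return the interpolated temperature, or `NA` if all 8 neighbors are
#'   missing at that depth.
#' @export
interpolate_cell <- function(grid, lat, lon, depth,
                             method = c("angular", "flat")) {
  method <- match.arg(method)
  offs <- expand.grid(dlat = -1:1, dlon = -1:1)
  offs <- offs[!(offs$dlat == 0 & offs$dlon == 0), ]
  vals <- numeric(0)
  wts <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    nlat <- lat + offs$dlat[[k]]
    nlon <- .wrap_lon(lon + offs$dlon[[k]])
    hit <- grid$lat == nlat & grid$lon == nlon & grid$depth == depth
    v <- grid$temp[hit]
    if (length(v) == 1 && !is.na(v)) {
      w <- if (method == "angular") {
        1 / .central_angle(lat + 0.5, lon + 0.5, nlat + 0.5, nlon + 0.5)
      } else {
        1 / sqrt(offs$dlat[[k]]^2 + offs$dlon[[k]]^2)
      }
      vals <- c(vals, v)
      wts <- c(wts, w)
    }
  }
  if (!length(vals)) return(NA_real_)
  sum(vals * wts) / sum(wts)
}

#' Fill all missing values of a gridded temperature field
#'
#' Single-pass neighbor interpolation with [interpolate_cell()]: only
#' originally observed values feed interpolations (no cascading fill).
#' Cells whose 8 neighbors are all missing stay `NA` and are flagged.
#'
#' @inheritParams interpolate_cell
#' @return the grid with filled `temp` plus logical columns `interpolated`
#'   and `still_missing`.
#' @export
fill_missing_temperatures <- function(grid, method = c("angular", "flat")) {
  method <- match.arg(method)
  miss <- which(is.na(grid$temp))
  filled <- grid
  filled$interpolated <- FALSE
  filled$still_missing <- FALSE
  for (i in miss) {
    v <- interpolate_cell(grid, grid$lat[[i]], grid$lon[[i]], grid$depth[[i]],
                          method = method)
    if (is.na(v)) {
      filled$still_missing[[i]] <- TRUE
    } else {
      filled$temp[[i]] <- v
      filled$interpolated[[i]] <- TRUE
    }
  }
  filled
}

#' Correlation-matrix PCA of water-column temperatures
#'
#' Principal component analysis of the depth-temperature variables over
#' localities, on the correlation matrix (variables z-scored, eigenvalues
#' summing to the number of depths).  PC1 is sign-oriented to correlate
#' positively with the depth-mean temperature, so it reads as the mean
#' thermal state of the upper water column; higher components are
#' oriented so the deepest depth loads non-negatively.
#'
#' @param temps numeric matrix or data.frame, localities x depths, no
#'   missing values (interpolate first); column names identify depths.
#' @return list with `scores` (localities x components), `loadings`
#'   (correlations between depth variables and components),
#'   `variance_explained` (percent per component) and `eigenvalues`.
#' @export
thermal_pca <- function(temps) {
  temps <- as.matrix(temps)
  if (nrow(temps) <= ncol(temps))
    stop("need more localities than depth variables", call. = FALSE)
  if (anyNA(temps)) stop("missing temperatures: interpolate first", call. = FALSE)
  sds <- apply(temps, 2, sd)
  if (any(sds == 0))
    stop("constant temperature variable at depth ",
         paste(colnames(temps)[sds == 0], collapse = ", "), call. = FALSE)
  z <- scale(temps)
  r <- cor(temps)
  eig <- eigen(r, symmetric = TRUE)
  vecs <- eig$vectors
  scores <- z %*% vecs
  # deterministic sign conventions
  if (cor(scores[, 1], rowMeans(temps)) < 0) vecs[, 1] <- -vecs[, 1]
  for (k in 2:ncol(vecs)) {
    if (vecs[nrow(vecs), k] < 0) vecs[, k] <- -vecs[, k]
  }
  scores <- z %*% vecs
  loadings <- vecs %*% diag(sqrt(pmax(eig$values, 0)))
  dimnames(loadings) <- list(colnames(temps), paste0("PC", seq_len(ncol(vecs))))
  colnames(scores) <- paste0("PC", seq_len(ncol(vecs)))
  list(scores = scores, loadings = loadings,
       variance_explained = 100 * eig$values / sum(eig$values),
       eigenvalues = eig$values)
}

#' Binned least-squares regression of PC1 on sea surface temperature
#'
#' Localities are binned into 1 deg C SST intervals; the per-bin mean (and
#' SD) of the PC1 score is regressed by ordinary least squares on SST over
#' the stated interval.  Both predictors of interest are reported: bin
#' centers (primary) and per-bin mean SST.
#'
#' @param pc1 PC1 score per locality.
#' @param sst SST (10 m temperature, deg C) per locality.
#' @param sst_range interval of bin centers entering the regression;
#'   default `c(0, 25)`.
#' @return list with `bins` (`data.frame`: bin center, mean/sd of PC1,
#'   mean SST, n), `slope`, `intercept` (bin-center predictor), and
#'   `slope_binmean`, `intercept_binmean` (bin-mean-SST predictor).
#' @export
pc1_sst_regression <- function(pc1, sst, sst_range = c(0, 25)) {
  stopifnot(length(pc1) == length(sst))
  bin <- floor(sst)
  agg <- data.frame(
    center = sort(unique(bin)) + 0.5,
    pc1_mean = as.numeric(tapply(pc1, bin, mean)),
    pc1_sd = as.numeric(tapply(pc1, bin, sd)),
    sst_mean = as.numeric(tapply(sst, bin, mean)),
    n = as.integer(tapply(pc1, bin, length)),
    row.names = NULL
  )
  use <- agg$center >= sst_range[[1]] & agg$center <= sst_range[[2]]
  if (sum(use) < 3) stop("need at least 3 non-empty SST bins", call. = FALSE)
  fit_c <- lm(pc1_mean ~ center, data = agg[use, ])
  fit_m <- lm(pc1_mean ~ sst_mean, data = agg[use, ])
  list(bins = agg,
       slope = unname(coef(fit_c)[[2]]), intercept = unname(coef(fit_c)[[1]]),
       slope_binmean = unname(coef(fit_m)[[2]]),
       intercept_binmean = unname(coef(fit_m)[[1]]))
}

#' Occurrence statistics of a focal species in core-top assemblages
#'
#' Presence count and percentage over localities, and the mean and
#' 2.5th/97.5th-percentile interval of the focal species' relative
#' abundance among the localities where it is present.
#'
#' @param counts matrix or data.frame, localities x morpho-species counts.
#' @param focal column name of the focal species.
#' @return list: `n_localities`, `n_present`, `pct_present`,
#'   `mean_rel_abundance`, `ci_low`, `ci_high` (relative abundances as
#'   proportions).
#' @export
occurrence_stats <- function(counts, focal) {
  counts <- as.matrix(counts)
  if (!focal %in% colnames(counts))
    stop("focal species ", focal, " not in count table", call. = FALSE)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " locality(ies) with zero total count excluded")
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  rel <- counts[, focal] / tot
  pres <- rel > 0
  ci <- if (any(pres)) unname(quantile(rel[pres], c(0.025, 0.975), type = 7))
        else c(NA_real_, NA_real_)
  list(n_localities = length(rel), n_present = sum(pres),
       pct_present = 100 * mean(pres),
       mean_rel_abundance = if (any(pres)) mean(rel[pres]) else NA_real_,
       ci_low = ci[[1]], ci_high = ci[[2]])
}

#' Genotype boundary temperature from station occupancy
#'
#' The warm edge of the cold-water genotype (maximum SST over stations
#' bearing Type II) and the cold edge of the warm-water genotype (minimum
#' SST over stations bearing Type I) bracket the hydrographic front
#' separating the two; the overlap flag reports sympatry (warm edge
#' exceeding cold edge).
#'
#' @param stations `data.frame` with columns `sst`, `n_type1`, `n_type2`.
#' @return list: `warm_edge_type2`, `cold_edge_type1`, `overlap`.
#' @export
boundary_temperature <- function(stations) {
  stopifnot(all(c("sst", "n_type1", "n_type2") %in% names(stations)))
  s1 <- stations$sst[stations$n_type1 > 0]
  s2 <- stations$sst[stations$n_type2 > 0]
  if (!length(s1)) stop("no station bears Type I", call. = FALSE)
  if (!length(s2)) stop("no station bears Type II", call. = FALSE)
  warm2 <- max(s2)
  cold1 <- min(s1)
  list(warm_edge_type2 = warm2, cold_edge_type1 = cold1,
       overlap = warm2 > cold1)
}
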