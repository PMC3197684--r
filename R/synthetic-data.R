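#' Simulation configuration
#'
#' Parameters of the synthetic-data generators.  The divergence-rate
#' ordering `inter_type > intra_type >= intra_individual >= 0` mirrors the
#' structure of a pseudo-cryptic species pair: between-genotype distances
#' exceed within-genotype distances, which in turn are comparable to
#' intragenomic (clone) variation.
#'
#' @param seed integer seed governing every generator draw.
#' @param n_individuals_per_type individuals sequenced per genotype.
#' @param clones_per_individual cloned sequences per individual.
#' @param amplicon_length_its,amplicon_length_ssu amplicon lengths (bases).
#' @param inter_type_divergence,intra_type_divergence,intra_individual_divergence
#'   substitution rates (substitutions/site) separating the two genotype
#'   ancestors, individuals within a genotype, and clones within an
#'   individual.
#' @param n_stations number of plankton-tow stations.
#' @param front_sst_low,front_sst_high SST band (deg C) of the
#'   hydrographic front separating the genotypes.
#' @param grid_extent latitude half-width (degrees) of the 1-degree
#'   core-top grid (latitudes `-grid_extent ... grid_extent - 1`, 18
#'   longitude cells).
#' @param missing_cell_fraction fraction of locality-by-depth temperature
#'   couples masked missing.
#' @param n_specimens_per_group morphometric sample sizes; scalar or
#'   length-2 (north, south).
#' @param morpho_effect_size standardized mean difference of the
#'   size-normalized apertural length between the two groups.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_individuals_per_type = 20,
                       clones_per_individual = 3,
                       amplicon_length_its = 1000,
                       amplicon_length_ssu = 620,
                       inter_type_divergence = 0.05,
                       intra_type_divergence = 0.005,
                       intra_individual_divergence = 0.002,
                       n_stations = 40,
                       front_sst_low = 8,
                       front_sst_high = 12,
                       grid_extent = 65,
                       missing_cell_fraction = 0.0327,
                       n_specimens_per_group = c(154, 152),
                       morpho_effect_size = 0.825) {
  cfg <- list(seed = as.integer(seed),
              n_individuals_per_type = n_individuals_per_type,
              clones_per_individual = clones_per_individual,
              amplicon_length_its = amplicon_length_its,
              amplicon_length_ssu = amplicon_length_ssu,
              inter_type_divergence = inter_type_divergence,
              intra_type_divergence = intra_type_divergence,
              intra_individual_divergence = intra_individual_divergence,
              n_stations = n_stations,
              front_sst_low = front_sst_low,
              front_sst_high = front_sst_high,
              grid_extent = grid_extent,
              missing_cell_fraction = missing_cell_fraction,
              n_specimens_per_group = n_specimens_per_group,
              morpho_effect_size = morpho_effect_size)
  with(cfg, {
    if (!(inter_type_divergence > intra_type_divergence &&
          intra_type_divergence >= intra_individual_divergence &&
          intra_individual_divergence >= 0))
      stop("divergence ordering violated: need inter > intra >= intra-individual >= 0",
           call. = FALSE)
    if (n_individuals_per_type < 1 || clones_per_individual < 1)
      stop("counts must be >= 1", call. = FALSE)
    if (missing_cell_fraction < 0 || missing_cell_fraction > 1)
      stop("missing_cell_fraction must lie in [0, 1]", call. = FALSE)
    if (front_sst_low >= front_sst_high)
      stop("front_sst_low must be below front_sst_high", call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

.bases <- c("A", "C", "G", "T")

# Substitute each site independently with probability `rate`, always to a
# different base (Jukes-Cantor-style uniform substitution).
.mutate <- function(s, rate) {
  if (rate <= 0) return(s)
  hit <- which(runif(length(s)) < rate)
  if (length(hit)) {
    cur <- match(s[hit], .bases)
    s[hit] <- .bases[(cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
  }
  s
}

# Ablate CCWGG occurrences (W -> G gives the uncuttable CCGGG) at starts
# strictly below `before`; the A/T count strictly decreases, so this
# terminates.
.ablate_ccwgg <- function(s, before = length(s) + 1L) {
  repeat {
    txt <- paste(s, collapse = "")
    m <- gregexpr("(?=CC[AT]GG)", txt, perl = TRUE)[[1]]
    m <- m[m > 0 & m < before]
    if (!length(m)) return(s)
    s[m[[1]] + 2L] <- "G"
  }
}

#' Generate synthetic rDNA clone libraries for two genotypes
#'
#' Sequences evolve from a random ancestor by uniform substitution along a
#' genotype -> individual -> clone hierarchy.  The genotype-ancestor
#' divergence is set so the realized mean between-type p-distance matches
#' `inter_type_divergence` (the individual- and clone-level rates are
#' subtracted from the ancestor split).  A diagnostic CCWGG restriction
#' site is engineered into every Type I ITS amplicon (first occurrence at
#' 40% of the amplicon length) and ablated from every Type II ITS
#' amplicon, reproducing the cut/uncut RFLP contrast; SSU amplicons are
#' left untouched.
#'
#' @param config a [sim_config()].
#' @return seq_records `data.frame` (see [seq_records]) for both markers,
#'   with genotype labels in the `type` column.
#' @export
generate_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  anc_rate <- max(
    config$inter_type_divergence -
      2 * (config$intra_type_divergence + config$intra_individual_divergence),
    config$inter_type_divergence / 2)
  rows <- list()
  for (marker in c("ITS", "SSU")) {
    len <- if (marker == "ITS") config$amplicon_length_its else config$amplicon_length_ssu
    anc <- sample(.bases, len, replace = TRUE)
    type_anc <- list(I = anc, II = .mutate(anc, anc_rate))
    site_start <- max(1L, round(0.4 * len))
    for (type in c("I", "II")) {
      for (ind in seq_len(config$n_individuals_per_type)) {
        ind_seq <- .mutate(type_anc[[type]], config$intra_type_divergence)
        specimen <- sprintf("T%s_i%02d", type, ind)
        station <- sprintf("st%s%02d", type, (ind - 1L) %% 5L + 1L)
        for (cl in seq_len(config$clones_per_individual)) {
          s <- .mutate(ind_seq, config$intra_individual_divergence)
          if (marker == "ITS") {
            if (type == "I") {
              s[site_start:(site_start + 4L)] <- c("C", "C", "A", "G", "G")
              s <- .ablate_ccwgg(s, before = site_start)
            } else {
              s <- .ablate_ccwgg(s)
            }
          }
          rows[[length(rows) + 1L]] <- data.frame(
            id = sprintf("%s_T%s_i%02d_c%d", marker, type, ind, cl),
            specimen = specimen, station = station, marker = marker,
            type = type, seq = paste(s, collapse = ""),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic plankton-tow stations with allopatric genotypes
#'
#' Station SSTs are stratified across 2-22 deg C (so the front band is
#' always straddled); every individual at a station warmer than the front
#' band is Type I, everyone colder is Type II, and stations inside the
#' band fall on either side of a single seed-chosen cut temperature
#' within the band -- a strictly allopatric, SST-controlled occupancy.
#' Each station gets coordinates, a 0-250 m
#' temperature/fluorescence profile whose 10 m value equals the SST, and
#' genotype counts.
#'
#' @param config a [sim_config()].
#' @return list with `stations` (`data.frame`: station, lat, lon, sst,
#'   side, n_type1, n_type2) and `profiles` (`data.frame`: station,
#'   depth, temperature, fluorescence).
#' @export
generate_stations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_stations
  if (n == 0)
    return(list(stations = data.frame(station = character(0), lat = numeric(0),
                                      lon = numeric(0), sst = numeric(0),
                                      side = character(0), n_type1 = integer(0),
                                      n_type2 = integer(0)),
                profiles = data.frame(station = character(0), depth = numeric(0),
                                      temperature = numeric(0),
                                      fluorescence = numeric(0))))
  mids <- seq(2, 22, length.out = n + 1)
  mids <- (mids[-1] + mids[-(n + 1)]) / 2
  sst <- mids + runif(n, -0.1, 0.1)
  lo <- config$front_sst_low
  hi <- config$front_sst_high
  front_cut <- runif(1, lo, hi)
  is_type1 <- sst > front_cut
  n_ind <- 1L + rpois(n, 6)
  stations <- data.frame(
    station = sprintf("ST%02d", seq_len(n)),
    lat = -60 + 2.2 * sst + rnorm(n, 0, 1),
    lon = runif(n, -180, 180),
    sst = sst,
    side = ifelse(is_type1, "north", "south"),
    n_type1 = ifelse(is_type1, n_ind, 0L),
    n_type2 = ifelse(is_type1, 0L, n_ind),
    stringsAsFactors = FALSE)
  depths <- seq(0, 250, by = 10)
  profs <- list()
  for (i in seq_len(n)) {
    tdeep <- max(2, sst[[i]] - 8)
    temp <- ifelse(depths < 10, sst[[i]] + 0.2,
                   tdeep + (sst[[i]] - tdeep) * exp(-(depths - 10) / 60))
    fluo <- exp(-((depths - 50) / 30)^2) * (1 + 0.1 * rnorm(length(depths)))
    profs[[i]] <- data.frame(station = stations$station[[i]], depth = depths,
                             temperature = temp, fluorescence = fluo,
                             stringsAsFactors = FALSE)
  }
  list(stations = stations, profiles = do.call(rbind, profs))
}

#' Generate a synthetic core-top assemblage set and gridded temperatures
#'
#' Builds a 1-degree grid (latitudes `-grid_extent ... grid_extent - 1`,
#' 18 longitude cells) with 13 depth-temperatures per cell, smoothly
#' decreasing with latitude and monotone non-increasing with depth (an
#' exponential thermocline whose depth varies with position, injecting a
#' surface/subsurface contrast).  Exactly
#' `floor(missing_cell_fraction * n_cells * 13)` locality-by-depth values
#' are masked missing.  Each cell is a core-top locality with counts of 37
#' morpho-species; the focal species' relative abundance is flat in
#' temperate waters, decreases beyond a warm threshold, and drops to zero
#' in subpolar cold water.
#'
#' @param config a [sim_config()].
#' @return list with `coretops` (`data.frame`: locality, lat, lon, 13
#'   `t<depth>` columns carrying the mask as `NA`, 37 species-count
#'   columns), `grid` (`data.frame`: lat, lon, depth, temp with `NA` =
#'   missing), `n_masked`, and `focal` (the focal species column name).
#' @export
generate_coretop_grid <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  lats <- seq(-config$grid_extent, config$grid_extent - 1)
  lons <- 0:17
  cells <- expand.grid(lat = lats, lon = lons)
  n_cells <- nrow(cells)
  depths <- water_column_depths()
  phi <- cells$lat + 0.5
  sst <- -2 + 30 * cos(phi * pi / 180)^1.7 +
    0.3 * sin(2 * pi * (cells$lon + 0.5) / 18) + rnorm(n_cells, 0, 0.2)
  h <- pmax(30, 70 + 25 * sin(2 * pi * cells$lon / 18 + phi / 30) + rnorm(n_cells, 0, 5))
  tdeep <- 2
  temps <- outer(seq_len(n_cells), seq_along(depths), function(i, j) {
    tdeep + (sst[i] - tdeep) * exp(-depths[j] / h[i])
  })
  colnames(temps) <- paste0("t", depths)

  n_masked <- as.integer(config$missing_cell_fraction * n_cells *
                           length(depths))
  masked <- sample.int(n_cells * length(depths), n_masked)
  temps_masked <- temps
  temps_masked[masked] <- NA_real_

  grid <- data.frame(lat = rep(cells$lat, times = length(depths)),
                     lon = rep(cells$lon, times = length(depths)),
                     depth = rep(depths, each = n_cells),
                     temp = as.vector(temps_masked))

  p_focal <- ifelse(sst < 8, 0,
                    ifelse(sst <= 18, 0.12, 0.12 * exp(-0.35 * (sst - 18))))
  n_species <- 37L
  species <- c("G_inflata", sprintf("sp%02d", seq_len(n_species - 1L)))
  other_w <- exp(rnorm(n_species - 1L, 0, 0.8))
  sizes <- pmax(50L, round(exp(rnorm(n_cells, log(379), 0.38))))
  counts <- matrix(0L, n_cells, n_species, dimnames = list(NULL, species))
  for (i in seq_len(n_cells)) {
    prob <- c(p_focal[[i]], (1 - p_focal[[i]]) * other_w / sum(other_w))
    counts[i, ] <- rmultinom(1, sizes[[i]], prob)[, 1]
  }

  coretops <- cbind(
    data.frame(locality = sprintf("L%04d", seq_len(n_cells)),
               lat = cells$lat, lon = cells$lon, stringsAsFactors = FALSE),
    as.data.frame(temps_masked), as.data.frame(counts))
  list(coretops = coretops, grid = grid, n_masked = n_masked,
       focal = "G_inflata")
}

#' Generate two synthetic morphometric populations
#'
#' Log-normal shell sizes shared across the two groups; the
#' size-normalized apertural length (log aperture/chamber ratio) differs
#' between groups by `morpho_effect_size` standard deviations, with the
#' north group larger.  At the default calibration the two-group
#' discriminant classification accuracy at n = 154/152 sits near 66%.
#'
#' @param config a [sim_config()].
#' @return `data.frame` with columns `specimen`, `group`
#'   (`"north"`/`"south"`), `major_axis`, `chamber_axis`, `aperture_axis`
#'   (micrometers).
#' @export
generate_morphometry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  nn <- config$n_specimens_per_group
  if (length(nn) == 1) nn <- c(nn, nn)
  ratio_sd <- 0.18
  mu_base <- log(0.55)
  out <- list()
  for (k in 1:2) {
    grp <- c("north", "south")[[k]]
    mu <- mu_base + c(1, -1)[[k]] * config$morpho_effect_size * ratio_sd / 2
    n <- nn[[k]]
    major <- exp(rnorm(n, log(500), 0.15))
    chamber <- major * 0.45 * exp(rnorm(n, 0, 0.06))
    aperture <- chamber * exp(rnorm(n, mu, ratio_sd))
    out[[k]] <- data.frame(
      specimen = sprintf("%s%03d", substr(grp, 1, 1), seq_len(n)),
      group = grp, major_axis = major, chamber_axis = chamber,
      aperture_axis = aperture, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
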