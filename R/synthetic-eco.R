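# Synthetic ecological-factor rasters and site tables.
#
# Each numeric factor field is Gaussian-filtered white noise rescaled to
# the factor's range (the filter sigma, in cells, sets the spatial
# autocorrelation length); the categorical soil layer is a smoothed field
# cut into classes. Sample sites are drawn uniformly inside the extent
# and carry the raster values at their cells plus chemical contents
# generated as planted-coefficient linear responses to the standardized
# factors plus Gaussian noise.

#' Default value ranges of the ecological factors x1-x10
#'
#' Plausible ranges for a southwest-China mountain study region, used to
#' rescale the synthetic factor fields (units in the comments below).
#'
#' @return named list, factor id -> c(low, high).
#' @export
default_factor_ranges <- function() {
  list(x1 = c(200, 3500),    # elevation, m
       x2 = c(3000, 6500),   # active accumulated temperature, degC d
       x3 = c(900, 1800),    # sunshine duration, h
       x4 = c(8, 20),        # mean annual temperature, degC
       x5 = c(-8, 4),        # minimum temperature in January, degC
       x6 = c(-4, 10),       # average temperature in January, degC
       x7 = c(26, 36),       # maximum temperature in July, degC
       x8 = c(18, 28),       # average temperature in July, degC
       x9 = c(600, 1400),    # annual precipitation, mm
       x10 = c(55, 85))      # relative humidity, %
}

#' Default planted factor-content coefficients of the eco generator
#'
#' Signed effects of the standardized factors on each content; the signs
#' mirror the reported correlation directions and are the ground truth
#' that parameter-recovery tests check against.
#'
#' @return list with `oil` and `ether` named coefficient vectors.
#' @export
default_true_coefficients <- function() {
  # signed effects of the standardized factors on each content; signs
  # mirror the reported correlation directions (temperatures positive,
  # elevation/sunshine negative for oil; precipitation and humidity
  # positive for ether extract)
  list(
    oil = c(x1 = -0.5, x2 = 0.2, x3 = -0.4, x4 = 0.6, x5 = 1.0,
            x6 = 0.9, x7 = 0.9, x8 = 1.0, x9 = -0.4, x10 = 0.3),
    ether = c(x1 = -0.2, x2 = 0.1, x3 = -0.4, x4 = 1.2, x5 = 0.8,
              x6 = 1.0, x7 = -0.3, x8 = 0.4, x9 = 1.0, x10 = 0.7)
  )
}

#' Scenario for the synthetic ecological raster/site generator
#'
#' @param n_sites number of sample sites.
#' @param factor_ranges named list x1..x10 -> c(low, high), the value
#'   range each factor field is rescaled to (low < high).
#' @param true_coefficients list with `oil` and `ether` named coefficient
#'   vectors (effects of standardized factors on the contents).
#' @param noise_sd standard deviation of the content noise (>= 0).
#' @param raster_shape c(rows, cols) of all layers.
#' @param raster_origin c(xll, yll) in degrees.
#' @param cellsize cell size in degrees.
#' @param spatial_autocorrelation_length Gaussian-filter sigma in cells;
#'   0 gives spatially uncorrelated fields.
#' @param soil_classes integer codes of the categorical soil layer.
#' @param seed integer seed.
#' @return an `eco_scenario` list.
#' @export
eco_scenario <- function(n_sites = 40,
                         factor_ranges = default_factor_ranges(),
                         true_coefficients = default_true_coefficients(),
                         noise_sd = 0.5,
                         raster_shape = c(60, 80),
                         raster_origin = c(97, 26),
                         cellsize = 0.1,
                         spatial_autocorrelation_length = 5,
                         soil_classes = 1:4,
                         seed = 1) {
  if (n_sites < 2) stop("need at least 2 sites")
  for (f in names(factor_ranges)) {
    r <- factor_ranges[[f]]
    if (r[1] >= r[2]) stop("factor range must satisfy low < high for ", f)
  }
  if (cellsize <= 0) stop("cellsize must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_sites = as.integer(n_sites), factor_ranges = factor_ranges,
                 true_coefficients = true_coefficients, noise_sd = noise_sd,
                 raster_shape = as.integer(raster_shape),
                 raster_origin = raster_origin, cellsize = cellsize,
                 spatial_autocorrelation_length = spatial_autocorrelation_length,
                 soil_classes = soil_classes, seed = as.integer(seed)),
            class = "eco_scenario")
}

# separable Gaussian smoothing with edge renormalization
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  smooth_1d <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1, i - r); hi <- min(n, i + r)
      w <- k[(lo - i + r + 1):(hi - i + r + 1)]
      out[i] <- sum(v[lo:hi] * w) / sum(w)
    }
    out
  }
  m <- apply(m, 2, smooth_1d)
  t(apply(m, 1, smooth_1d))
}

rescale_to <- function(m, lo, hi) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  lo + (m - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Generate synthetic factor rasters, a soil raster and a site table
#'
#' @param scenario an [eco_scenario()].
#' @return list with `rasters` (named list of `eco_grid`, x1..x10),
#'   `soil` (categorical `eco_grid`, layer x11), and `sites` (data frame:
#'   site id, lon, lat, x1..x10, x11, volatile_oil, ether_extract).
#' @export
gen_eco_rasters <- function(scenario) {
  stopifnot(inherits(scenario, "eco_scenario"))
  set.seed(scenario$seed)
  nr <- scenario$raster_shape[1]; nc <- scenario$raster_shape[2]
  sig <- scenario$spatial_autocorrelation_length
  factors <- names(scenario$factor_ranges)
  rasters <- list()
  for (f in factors) {
    field <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sig)
    rng <- scenario$factor_ranges[[f]]
    rasters[[f]] <- eco_grid(rescale_to(field, rng[1], rng[2]),
                             scenario$raster_origin[1], scenario$raster_origin[2],
                             scenario$cellsize)
  }
  # physical consistency: January minimum <= January average,
  # July average <= July maximum
  if (all(c("x5", "x6") %in% factors)) {
    rasters$x5$values <- pmin(rasters$x5$values, rasters$x6$values)
  }
  if (all(c("x7", "x8") %in% factors)) {
    rasters$x8$values <- pmin(rasters$x8$values, rasters$x7$values)
  }
  soil_field <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sig)
  ncls <- length(scenario$soil_classes)
  cuts <- stats::quantile(soil_field, probs = seq(0, 1, length.out = ncls + 1))
  cuts[1] <- -Inf; cuts[ncls + 1] <- Inf
  soil_codes <- matrix(scenario$soil_classes[as.integer(cut(soil_field, cuts))],
                       nr, nc)
  soil <- eco_grid(soil_codes, scenario$raster_origin[1],
                   scenario$raster_origin[2], scenario$cellsize)
  ext <- grid_extent(soil)
  n <- scenario$n_sites
  lon <- stats::runif(n, ext["xmin"], ext["xmax"] - 1e-9)
  lat <- stats::runif(n, ext["ymin"], ext["ymax"] - 1e-9)
  X <- sapply(factors, function(f) extract_at(rasters[[f]], lon, lat))
  Xs <- scale(X)
  beta_oil <- scenario$true_coefficients$oil[factors]
  beta_eth <- scenario$true_coefficients$ether[factors]
  oil <- 9 + as.vector(Xs %*% beta_oil) + stats::rnorm(n, 0, scenario$noise_sd)
  eth <- 13 + as.vector(Xs %*% beta_eth) + stats::rnorm(n, 0, scenario$noise_sd)
  sites <- data.frame(site = sprintf("S%02d", seq_len(n)),
                      longitude = lon, latitude = lat,
                      X, x11 = extract_at(soil, lon, lat),
                      volatile_oil = pmax(0, oil), ether_extract = pmax(0, eth),
                      stringsAsFactors = FALSE)
  list(rasters = rasters, soil = soil, sites = sites)
}
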