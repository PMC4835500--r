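# Fuzzy environmental-envelope habitat suitability.
#
# Per numeric factor the envelope is the [min, max] of the values
# observed at the sample sites; membership is trapezoidal with a graded
# margin of width tau * (max - min) on each side, so tau = 0 recovers a
# crisp BIOCLIM-style box. The categorical soil layer matches the set of
# codes observed at the sites. The similarity index of a grid cell is
# the weighted mean (or minimum) of its factor memberships, scaled to
# 0-100; SI 95-100 is the conventional suitable-habitat band.

#' Build a fuzzy environmental envelope from sample sites
#'
#' @param sites data frame with the numeric factor columns and the
#'   categorical soil column; >= 2 rows, no missing factor values.
#' @param factors numeric factor column names (default x1..x10).
#' @param soil_col categorical soil column name (default x11); `NULL`
#'   for envelopes without a soil constraint.
#' @param tau tolerance fraction controlling the fuzzy margin (>= 0;
#'   default 0.1).
#' @param weights optional non-negative factor weights named by factor
#'   (soil weight under the soil column name); equal weights by default.
#'   VIP scores from the chemo-ecology stage are a natural choice.
#' @return object of class `fuzzy_envelope`: `bounds` (factor, lo, hi),
#'   `tau`, `soil_codes`, `weights`.
#' @export
build_envelope <- function(sites, factors = paste0("x", 1:10), soil_col = "x11",
                           tau = 0.1, weights = NULL) {
  if (nrow(sites) < 2) stop("need at least 2 sites")
  if (tau < 0) stop("tau must be >= 0")
  miss <- setdiff(c(factors, soil_col), names(sites))
  if (length(miss)) stop("missing factor column(s): ", paste(miss, collapse = ", "))
  vals <- as.matrix(sites[factors])
  if (anyNA(vals)) stop("missing factor value(s) at some site")
  bounds <- data.frame(factor = factors,
                       lo = apply(vals, 2, min),
                       hi = apply(vals, 2, max),
                       stringsAsFactors = FALSE)
  rownames(bounds) <- NULL
  soil_codes <- NULL
  if (!is.null(soil_col)) {
    if (anyNA(sites[[soil_col]])) stop("missing soil value(s) at some site")
    soil_codes <- sort(unique(sites[[soil_col]]))
  }
  all_names <- c(factors, soil_col)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(all_names)), all_names)
  } else {
    if (is.null(names(weights))) names(weights) <- all_names[seq_along(weights)]
    weights <- weights[all_names]
    weights[is.na(weights)] <- 1
    names(weights) <- all_names
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with at least one positive entry")
  }
  structure(list(bounds = bounds, tau = tau, soil_codes = soil_codes,
                 weights = weights),
            class = "fuzzy_envelope")
}

#' @export
print.fuzzy_envelope <- function(x, ...) {
  cat("fuzzy_envelope: tau =", x$tau, "\n")
  print(x$bounds)
  if (!is.null(x$soil_codes)) {
    cat("soil codes:", paste(x$soil_codes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Trapezoidal membership of a value in a factor envelope
#'
#' mu = 1 inside \[lo, hi\], decays linearly to 0 over a margin of
#' `tau * (hi - lo)` on each side (or `tau * |lo|` for a degenerate
#' envelope with hi = lo), and is 0 beyond. With `tau = 0` (or a zero
#' margin) the membership is crisp.
#'
#' @param value numeric vector (or matrix) of factor values.
#' @param lo,hi envelope bounds, lo <= hi.
#' @param tau tolerance fraction (>= 0).
#' @return membership values in \[0, 1\], same shape as `value`.
#' @export
membership <- function(value, lo, hi, tau = 0.1) {
  if (tau < 0) stop("tau must be >= 0")
  if (lo > hi) stop("lo must be <= hi")
  margin <- if (hi > lo) tau * (hi - lo) else tau * abs(lo)
  if (margin == 0) {
    mu <- ifelse(value >= lo & value <= hi, 1, 0)
  } else {
    mu <- ifelse(value >= lo & value <= hi, 1,
                 ifelse(value < lo, pmax(0, 1 - (lo - value) / margin),
                        pmax(0, 1 - (value - hi) / margin)))
  }
  mu[is.na(value)] <- NA
  mu
}

#' Gridded similarity index from a raster stack and an envelope
#'
#' Per cell, SI = 100 x the weighted mean (or minimum) of the factor
#' memberships, including the binary soil membership. A nodata cell in
#' any layer makes the cell nodata. With `soil = "hard"` the soil match
#' multiplies the numeric-factor SI instead of being averaged in.
#'
#' @param stack list with `rasters` (named list of `eco_grid`, one per
#'   envelope factor) and optionally `soil` (categorical `eco_grid`).
#' @param envelope a [build_envelope()] result.
#' @param combine `"mean"` (weighted arithmetic mean, default) or
#'   `"min"` (most limiting factor).
#' @param soil `"weighted"` (averaged like other factors, default) or
#'   `"hard"` (binary multiplier).
#' @return an `eco_grid` of SI values in \[0, 100\] (NA where any input
#'   layer is nodata).
#' @export
similarity_index <- function(stack, envelope, combine = c("mean", "min"),
                             soil = c("weighted", "hard")) {
  combine <- match.arg(combine)
  soil <- match.arg(soil)
  stopifnot(inherits(envelope, "fuzzy_envelope"))
  factors <- envelope$bounds$factor
  miss <- setdiff(factors, names(stack$rasters))
  if (length(miss)) stop("stack lacks raster(s): ", paste(miss, collapse = ", "))
  grids <- stack$rasters[factors]
  if (!is.null(envelope$soil_codes)) {
    if (is.null(stack$soil)) stop("envelope has a soil constraint but stack has no soil layer")
    grids <- c(grids, list(stack$soil))
  }
  ref <- check_aligned(grids)
  mus <- lapply(factors, function(f) {
    b <- envelope$bounds[envelope$bounds$factor == f, ]
    membership(grids[[f]]$values, b$lo, b$hi, envelope$tau)
  })
  w <- as.numeric(envelope$weights[factors])
  if (!is.null(envelope$soil_codes)) {
    soil_mu <- ifelse(is.na(stack$soil$values), NA,
                      as.numeric(stack$soil$values %in% envelope$soil_codes))
    soil_mu <- matrix(soil_mu, nrow(stack$soil$values), ncol(stack$soil$values))
    soil_w <- as.numeric(envelope$weights[length(envelope$weights)])
    if (soil == "weighted") {
      mus <- c(mus, list(soil_mu))
      w <- c(w, soil_w)
    }
  }
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  if (combine == "mean") {
    acc <- matrix(0, nr, nc)
    for (k in seq_along(mus)) acc <- acc + w[k] * mus[[k]]
    si <- 100 * acc / sum(w)
  } else {
    si <- matrix(1, nr, nc)
    for (k in seq_along(mus)) si <- pmin(si, mus[[k]])
    si <- 100 * si
  }
  if (!is.null(envelope$soil_codes) && soil == "hard") {
    si <- si * soil_mu
  }
  eco_grid(si, ref$xll, ref$yll, ref$cellsize, ref$nodata)
}

#' Mask of cells inside an SI band
#'
#' Both bounds inclusive; nodata cells are `FALSE`.
#'
#' @param si_grid `eco_grid` of similarity-index values.
#' @param lo,hi band bounds in percent, 0 <= lo <= hi <= 100.
#' @return logical matrix of the grid's shape.
#' @export
si_band_mask <- function(si_grid, lo = 95, hi = 100) {
  if (lo < 0 || hi > 100 || lo > hi) stop("need 0 <= lo <= hi <= 100")
  v <- si_grid$values
  m <- !is.na(v) & v >= lo & v <= hi
  m
}

#' Pairwise overlap of suitability masks
#'
#' For every pair of masks: the cellwise intersection and the overlap
#' fraction |A and B| / min(|A|, |B|) (NA when either mask is empty).
#'
#' @param masks named list of logical matrices of identical shape.
#' @return list with `pairs` (data frame: a, b, cells_a, cells_b,
#'   overlap_cells, fraction) and `intersections` (named list of logical
#'   matrices, `"a|b"`).
#' @export
overlay_intersection <- function(masks) {
  if (length(masks) < 2) stop("need at least 2 masks")
  dims <- lapply(masks, dim)
  if (!all(vapply(dims, identical, logical(1), y = dims[[1]]))) {
    stop("mask geometry mismatch")
  }
  nm <- names(masks)
  if (is.null(nm)) nm <- paste0("m", seq_along(masks))
  pairs <- utils::combn(seq_along(masks), 2)
  inter <- list()
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    ab <- masks[[i]] & masks[[j]]
    inter[[paste(nm[i], nm[j], sep = "|")]] <<- ab
    na_ <- sum(masks[[i]]); nb <- sum(masks[[j]])
    data.frame(a = nm[i], b = nm[j], cells_a = na_, cells_b = nb,
               overlap_cells = sum(ab),
               fraction = if (min(na_, nb) == 0) NA_real_ else sum(ab) / min(na_, nb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(pairs = out, intersections = inter)
}
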