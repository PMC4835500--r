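toy_stack <- function(nr = 5, nc = 5, seed = 1) {
  set.seed(seed)
  rasters <- lapply(setNames(nm = paste0("x", 1:10)), function(f) {
    eco_grid(matrix(runif(nr * nc, 0, 10), nr, nc), 100, 28, 0.1)
  })
  soil <- eco_grid(matrix(sample(1:3, nr * nc, TRUE), nr, nc), 100, 28, 0.1)
  list(rasters = rasters, soil = soil)
}

toy_sites <- function(stack, n = 6, seed = 2) {
  set.seed(seed)
  ext <- grid_extent(stack$soil)
  lon <- runif(n, ext["xmin"], ext["xmax"] - 1e-9)
  lat <- runif(n, ext["ymin"], ext["ymax"] - 1e-9)
  df <- data.frame(longitude = lon, latitude = lat)
  for (f in names(stack$rasters)) df[[f]] <- extract_at(stack$rasters[[f]], lon, lat)
  df$x11 <- extract_at(stack$soil, lon, lat)
  df
}

test_that("envelope bounds equal brute-force min/max and widen monotonically", {
  stack <- toy_stack()
  sites <- toy_sites(stack)
  env <- build_envelope(sites)
  for (k in seq_len(nrow(env$bounds))) {
    f <- env$bounds$factor[k]
    expect_equal(env$bounds$lo[k], min(sites[[f]]))
    expect_equal(env$bounds$hi[k], max(sites[[f]]))
  }
  expect_equal(env$soil_codes, sort(unique(sites$x11)))
  # adding a site never shrinks an envelope
  extra <- toy_sites(stack, n = 1, seed = 99)
  env2 <- build_envelope(rbind(sites, extra))
  expect_true(all(env2$bounds$lo <= env$bounds$lo))
  expect_true(all(env2$bounds$hi >= env$bounds$hi))
  # degenerate: all sites identical
  env3 <- build_envelope(sites[c(1, 1), ])
  expect_true(all(env3$bounds$lo == env3$bounds$hi))
  sites_na <- sites; sites_na$x3[2] <- NA
  expect_error(build_envelope(sites_na), "missing")
  expect_error(build_envelope(sites, tau = -0.1), "tau")
})

test_that("trapezoidal membership hits its anchor points", {
  expect_equal(membership(5, 2, 8, 0.1), 1)
  # 0.5 exactly halfway down the margin
  expect_equal(membership(2 - 0.1 * 6 / 2, 2, 8, 0.1), 0.5)
  expect_equal(membership(8 + 0.1 * 6 / 2, 2, 8, 0.1), 0.5)
  expect_equal(membership(-100, 2, 8, 0.1), 0)
  expect_equal(membership(100, 2, 8, 0.1), 0)
  # crisp when tau = 0
  expect_equal(membership(c(1.999, 2, 8, 8.001), 2, 8, 0), c(0, 1, 1, 0))
  # degenerate envelope uses tau*|lo| as margin
  expect_equal(membership(10, 10, 10, 0.1), 1)
  expect_equal(membership(10.5, 10, 10, 0.1), 0.5)
  expect_error(membership(1, 0, 1, -1), "tau")
})

test_that("similarity index: identity at sites, forced arithmetic, oracle", {
  stack <- toy_stack()
  sites <- toy_sites(stack)
  env <- build_envelope(sites, tau = 0.1)
  si <- similarity_index(stack, env)
  expect_true(all(si$values >= 0 & si$values <= 100, na.rm = TRUE))
  # every training site's cell scores exactly 100
  expect_equal(extract_at(si, sites$longitude, sites$latitude),
               rep(100, nrow(sites)))
  # full 5x5 brute-force recomputation
  expect_equal(si$values, oracle_si(stack, env), tolerance = 1e-12)
  # min-combination oracle too
  si_min <- similarity_index(stack, env, combine = "min")
  expect_equal(si_min$values, oracle_si(stack, env, combine = "min"),
               tolerance = 1e-12)
  expect_true(all(si_min$values <= si$values + 1e-9))
})

test_that("one factor fully outside among 11 equal weights gives 100*10/11", {
  stack <- toy_stack()
  sites <- toy_sites(stack)
  # push x1's envelope far away from every cell value
  sites$x1 <- sites$x1 + 1000
  env <- build_envelope(sites, tau = 0.1)
  for (f in paste0("x", 2:10)) {
    env$bounds[env$bounds$factor == f, c("lo", "hi")] <- c(-1e6, 1e6)
  }
  env$soil_codes <- 1:3
  si <- similarity_index(stack, env)
  expect_equal(unique(as.vector(si$values)), 100 * 10 / 11, tolerance = 1e-9)
})

test_that("nodata cells propagate and grid mismatches are errors", {
  stack <- toy_stack()
  stack$rasters$x2$values[1, 1] <- NA
  si <- similarity_index(stack, build_envelope(toy_sites(toy_stack())))
  expect_true(is.na(si$values[1, 1]))
  bad <- toy_stack(nr = 4)
  bad$rasters$x1 <- toy_stack(nr = 6)$rasters$x1
  expect_error(similarity_index(bad, build_envelope(toy_sites(toy_stack(nr = 4)))),
               "geometry")
})

test_that("equal-weight SI is invariant to factor ordering", {
  stack <- toy_stack()
  sites <- toy_sites(stack)
  env <- build_envelope(sites)
  si <- similarity_index(stack, env)
  perm <- c(paste0("x", 10:1))
  stack2 <- stack
  stack2$rasters <- stack$rasters[perm]
  env2 <- build_envelope(sites, factors = perm)
  si2 <- similarity_index(stack2, env2)
  expect_equal(si2$values, si$values, tolerance = 1e-12)
})

test_that("SI band masks: thresholding, nesting, band extremes", {
  stack <- toy_stack()
  si <- similarity_index(stack, build_envelope(toy_sites(stack)))
  m_all <- si_band_mask(si, 0, 100)
  expect_equal(m_all, !is.na(si$values))
  m95 <- si_band_mask(si, 95, 100)
  expect_equal(m95, !is.na(si$values) & si$values >= 95 & si$values <= 100)
  m97 <- si_band_mask(si, 97, 100)
  expect_true(all(m95[m97]))  # nested bands
  expect_error(si_band_mask(si, 80, 50), "lo <= hi")
})

test_that("spherical cell areas: closed form, additivity, empty mask", {
  g1 <- eco_grid(matrix(0, 1, 1), 0, 0, 0.1)
  expect_equal(mask_area_km2(matrix(TRUE, 1, 1), g1), 123.6, tolerance = 0.1 / 123.6)
  expect_equal(mask_area_km2(matrix(FALSE, 1, 1), g1), 0)
  g <- eco_grid(matrix(0, 4, 4), 102, 28, 0.25)
  set.seed(3)
  m <- matrix(sample(c(TRUE, FALSE), 16, TRUE), 4, 4)
  expect_equal(mask_area_km2(m, g),
               mask_area_km2(m & upper.tri(m, diag = TRUE), g) +
               mask_area_km2(m & !upper.tri(m, diag = TRUE), g),
               tolerance = 1e-12)
  # higher-latitude rows cover less area
  a <- row_cell_areas_km2(g)
  expect_true(all(diff(a) > 0))  # row 1 is northernmost
})

test_that("suitable area is monotone in tau and in the band lower bound", {
  eco <- small_eco(seed = 6)
  sites <- eco$sites
  areas_tau <- sapply(c(0, 0.1, 0.3), function(tau) {
    si <- similarity_index(eco, build_envelope(sites, tau = tau))
    mask_area_km2(si_band_mask(si, 95, 100), si)
  })
  expect_true(all(diff(areas_tau) >= 0))
  si <- similarity_index(eco, build_envelope(sites, tau = 0.1))
  areas_lo <- sapply(c(0, 50, 80, 95), function(lo) {
    mask_area_km2(si_band_mask(si, lo, 100), si)
  })
  expect_true(all(diff(areas_lo) <= 0))
})

test_that("tau = 0 with equal weights equals the crisp BIOCLIM box", {
  stack <- toy_stack(seed = 5)
  sites <- toy_sites(stack, seed = 6)
  env <- build_envelope(sites, tau = 0)
  si <- similarity_index(stack, env)
  inside <- matrix(TRUE, 5, 5)
  for (f in paste0("x", 1:10)) {
    b <- env$bounds[env$bounds$factor == f, ]
    inside <- inside & stack$rasters[[f]]$values >= b$lo &
      stack$rasters[[f]]$values <= b$hi
  }
  inside <- inside & matrix(stack$soil$values %in% env$soil_codes, 5, 5)
  expect_equal(si$values == 100, inside)
})

test_that("overlay fractions: identical, disjoint, planted niche scenario", {
  m1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  ov <- overlay_intersection(list(a = m1, b = m1))
  expect_equal(ov$pairs$fraction, 1)
  ov2 <- overlay_intersection(list(a = m1, b = !m1))
  expect_equal(ov2$pairs$fraction, 0)
  expect_error(overlay_intersection(list(m1, matrix(TRUE, 3, 3))), "mismatch")

  masks <- disjoint_niche_masks(seed = 1)
  ov3 <- overlay_intersection(masks)$pairs
  za <- ov3$a == "ZA" | ov3$b == "ZA"
  expect_true(all(ov3$fraction[za] < 0.05))
  expect_true(all(ov3$fraction[!za] >= 0.5))
})

test_that("region summaries conserve total area and match a groupby oracle", {
  g <- eco_grid(matrix(0, 10, 10), 100, 25, 0.2)
  set.seed(7)
  regions <- eco_grid(matrix(sample(1:4, 100, TRUE), 10, 10), 100, 25, 0.2)
  mask <- matrix(sample(c(TRUE, FALSE), 100, TRUE), 10, 10)
  rs <- region_summary(mask, regions)
  expect_equal(sum(rs$suitable_area_km2), mask_area_km2(mask, g), tolerance = 1e-9)
  # brute-force per-cell groupby
  areas <- matrix(row_cell_areas_km2(g), 10, 10)
  for (cd in 1:4) {
    sel <- mask & regions$values == cd
    expect_equal(rs$suitable_area_km2[rs$region == cd], sum(areas[sel]),
                 tolerance = 1e-12)
    expect_equal(rs$suitable_cells[rs$region == cd], sum(sel))
  }
  # single-region raster reduces to the plain mask area
  one <- eco_grid(matrix(1, 10, 10), 100, 25, 0.2)
  expect_equal(region_summary(mask, one)$suitable_area_km2,
               mask_area_km2(mask, g), tolerance = 1e-12)
  expect_error(region_summary(matrix(TRUE, 2, 2), regions), "mismatch")
})

test_that("ASCII grids round-trip through write and read", {
  g <- eco_grid(matrix(c(1.5, NA, 3, 4.25, 5, 6), 2, 3), 101.05, 27.3, 0.05)
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(g, f)
  back <- read_ascii_grid(f)
  expect_equal(back$values, g$values)
  expect_equal(c(back$xll, back$yll, back$cellsize), c(101.05, 27.3, 0.05))
  expect_true(same_geometry(g, back))
})
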