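# Shared scenario builders for the tests.

# the six cultivars plus the Toddalia-like outgroup (generator defaults)
default_set <- function(seed = 7, ...) {
  gen_barcode_set(barcode_scenario(seed = seed, ...))
}

# six cultivars only, no outgroup
two_species_scenario <- function(seed = 7, ...) {
  barcode_scenario(
    species_diagnostic_snps = list(
      "Z. bungeanum" = data.frame(position = c(105L, 191L, 197L, 203L),
                                  base = c("T", "C", "A", "G"),
                                  stringsAsFactors = FALSE)),
    cultivar_map = list("Z. armatum" = c("ZA1", "ZA2"),
                        "Z. bungeanum" = c("ZB1", "ZB2", "ZB3", "ZB4")),
    n_specimens_per_cultivar = 5,
    seed = seed, ...)
}

# small rasters keep the eco tests quick; the structure is unchanged
small_eco <- function(seed = 1, ...) {
  gen_eco_rasters(eco_scenario(raster_shape = c(25, 30), seed = seed, ...))
}

# disjoint-niche habitat scenario: a cool-niche group (Z. armatum-like)
# and three overlapping warm-niche subsets (Z. bungeanum cultivar-like),
# split on mean annual temperature quartiles
disjoint_niche_masks <- function(seed = 1, tau = 0.1, band = c(95, 100)) {
  eco <- gen_eco_rasters(eco_scenario(n_sites = 60, seed = seed))
  s <- eco$sites
  q <- stats::quantile(s$x4, c(0.25, 0.75))
  cool <- s[s$x4 <= q[1], ]
  warm <- s[s$x4 >= q[2], ]
  set.seed(seed)
  zb <- lapply(1:3, function(i) warm[sample(nrow(warm), ceiling(0.7 * nrow(warm))), ])
  groups <- c(list(ZA = cool), stats::setNames(zb, paste0("ZB", 1:3)))
  masks <- lapply(groups, function(g) {
    si <- similarity_index(eco, build_envelope(g, tau = tau))
    si_band_mask(si, band[1], band[2])
  })
  masks
}
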