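# Synthetic chemistry batch tables mirroring the layout of the packaged
# 47-batch field table, for pipeline tests that need more (or controlled)
# replication than the published data provide.

default_cultivar_means <- function() {
  # per-cultivar (oil %, ether %) means computed from the packaged table
  tab <- read_chem_table()
  s <- group_summary(tab, by = "abbreviation")
  means <- lapply(seq_len(nrow(s)), function(i) c(oil = s$mean_oil[i],
                                                  ether = s$mean_ether[i]))
  names(means) <- s$group
  means
}

#' Scenario for the synthetic chemistry-table generator
#'
#' @param n_batches_per_cultivar positive integer batches per cultivar.
#' @param cultivar_means named list, cultivar -> c(oil, ether) mean
#'   contents in percent; defaults to the per-cultivar means of the
#'   packaged batch table.
#' @param within_cultivar_sd within-cultivar standard deviation of both
#'   contents, in percent points (> 0, or 0 for noiseless tables).
#' @param seed integer seed.
#' @return a `chem_scenario` list.
#' @export
chem_scenario <- function(n_batches_per_cultivar = 8,
                          cultivar_means = NULL,
                          within_cultivar_sd = 1.5,
                          seed = 1) {
  if (is.null(cultivar_means)) cultivar_means <- default_cultivar_means()
  if (n_batches_per_cultivar < 1) stop("n_batches_per_cultivar must be positive")
  if (within_cultivar_sd < 0) stop("within_cultivar_sd must be >= 0")
  mv <- unlist(cultivar_means)
  if (any(!is.finite(mv)) || any(mv <= 0)) stop("cultivar means must be strictly positive")
  structure(list(n_batches_per_cultivar = as.integer(n_batches_per_cultivar),
                 cultivar_means = cultivar_means,
                 within_cultivar_sd = within_cultivar_sd,
                 seed = as.integer(seed)),
            class = "chem_scenario")
}

#' Generate a synthetic chemistry batch table
#'
#' One row per batch with the packaged table's column layout (species,
#' cultivar name, abbreviation, locality, longitude, latitude, contents).
#' Contents are Gaussian around the cultivar means, truncated at 0.
#' Deterministic given the scenario seed.
#'
#' @param scenario a [chem_scenario()].
#' @return data frame of batches.
#' @export
gen_chem_table <- function(scenario) {
  stopifnot(inherits(scenario, "chem_scenario"))
  set.seed(scenario$seed)
  cultivars <- names(scenario$cultivar_means)
  n <- scenario$n_batches_per_cultivar
  rows <- lapply(cultivars, function(cv) {
    mu <- scenario$cultivar_means[[cv]]
    sp <- if (grepl("^ZA", cv)) "Z. armatum" else if (grepl("^ZB", cv)) "Z. bungeanum" else cv
    data.frame(
      species = sp,
      cultivar_name = cv,
      abbreviation = cv,
      locality = paste0("Synthetic site ", cv, "-", seq_len(n)),
      longitude = round(stats::runif(n, 101.5, 104), 5),
      latitude = round(stats::runif(n, 27.5, 32.5), 5),
      volatile_oil = pmax(0, stats::rnorm(n, mu[1], scenario$within_cultivar_sd)),
      ether_extract = pmax(0, stats::rnorm(n, mu[2], scenario$within_cultivar_sd)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
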