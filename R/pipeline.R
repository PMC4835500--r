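# End-to-end orchestration: chem -> barcode -> ecology -> habitat, with a
# single user seed expanded into independent per-stage seeds so toggling
# one stage never shifts another stage's random stream. A JSON manifest
# records package version, configuration and MD5 hashes of every stage
# output; it contains no timestamps, so identical runs produce identical
# manifests.

stage_seed <- function(seed, stage) {
  offsets <- c(chem = 101L, barcode = 211L, ecology = 307L, habitat = 401L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param stages subset of `c("chem", "barcode", "ecology", "habitat")`.
#' @param chem_input CSV of batches; default is the packaged 47-batch
#'   table. Must exist at run start.
#' @param barcode_scenario a [barcode_scenario()]; default scenario with
#'   the stage seed.
#' @param eco_scenario an [eco_scenario()]; default scenario with the
#'   stage seed.
#' @param bootstrap bootstrap replicates for the NJ tree.
#' @param ncomp PLSR components.
#' @param tau fuzzy-envelope tolerance fraction.
#' @param band SI band c(lo, hi) in percent.
#' @param combine membership aggregation, `"mean"` or `"min"`.
#' @param soil soil handling, `"weighted"` or `"hard"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1,
                            stages = c("chem", "barcode", "ecology", "habitat"),
                            chem_input = table1_path(),
                            barcode_scenario = NULL,
                            eco_scenario = NULL,
                            bootstrap = 1000,
                            ncomp = 2,
                            tau = 0.1,
                            band = c(95, 100),
                            combine = "mean",
                            soil = "weighted") {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 chem_input = chem_input, barcode_scenario = barcode_scenario,
                 eco_scenario = eco_scenario, bootstrap = bootstrap,
                 ncomp = ncomp, tau = tau, band = band, combine = combine,
                 soil = soil),
            class = "pipeline_config")
}

write_stage_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages on provided or generated inputs and
#' writes per-stage outputs plus `manifest.json` into `out_dir`. Any
#' stage failure aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with `package_version`,
#'   `seed`, `parameters`, `outputs` holding relative paths and MD5
#'   hashes).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if ("chem" %in% config$stages && !file.exists(config$chem_input)) {
    stop("chem input not found: ", config$chem_input)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- function(f) file.path(config$out_dir, f)

  if ("chem" %in% config$stages) {
    run_stage("chem", function() {
      tab <- read_chem_table(config$chem_input)
      outputs <<- c(outputs,
        write_stage_csv(group_summary(tab, "species"), out("chem_species_summary.csv")),
        write_stage_csv(group_summary(tab, "abbreviation"), out("chem_cultivar_summary.csv")))
      an <- do.call(rbind, lapply(c("volatile_oil", "ether_extract"), function(v) {
        a <- one_way_anova(tab[[v]], tab$species)
        data.frame(content = v, F = a$F, df_between = a$df_between,
                   df_within = a$df_within, p = a$p)
      }))
      outputs <<- c(outputs, write_stage_csv(an, out("chem_anova_species.csv")))
      pc <- chem_pca(as.matrix(tab[c("volatile_oil", "ether_extract")]),
                     standardize = TRUE)
      sc <- data.frame(abbreviation = tab$abbreviation, species = tab$species,
                       pc$scores)
      outputs <<- c(outputs, write_stage_csv(sc, out("chem_pca_scores.csv")))
    })
  }

  if ("barcode" %in% config$stages) {
    run_stage("barcode", function() {
      scn <- config$barcode_scenario
      if (is.null(scn)) scn <- barcode_scenario(seed = stage_seed(config$seed, "barcode"))
      set <- gen_barcode_set(scn)
      outputs <<- c(outputs, write_alignment(set, out("barcode_alignment.fasta")))
      dm <- k2p_matrix(set)
      outputs <<- c(outputs, write_dist(dm, out("barcode_k2p.csv"), "csv"))
      outputs <<- c(outputs,
        write_stage_csv(gap_analysis(dm, "species"), out("barcode_gap.csv")),
        write_stage_csv(intra_range(dm, "cultivar"), out("barcode_intra_range.csv")),
        write_stage_csv(haplotype_collapse(set, "species")$counts,
                        out("barcode_haplotypes.csv")))
      diag <- diagnostic_sites(set, "species")
      diag_df <- do.call(rbind, lapply(names(diag), function(sp) {
        rbind(
          if (nrow(diag[[sp]]$variable_sites))
            cbind(group = sp, type = "variable", diag[[sp]]$variable_sites),
          if (nrow(diag[[sp]]$indel_sites))
            cbind(group = sp, type = "indel", diag[[sp]]$indel_sites))
      }))
      outputs <<- c(outputs, write_stage_csv(diag_df, out("barcode_diagnostic_sites.csv")))
      tr <- bootstrap_support(set, replicates = config$bootstrap,
                              seed = stage_seed(config$seed, "barcode"),
                              outgroup = set$id[set$species == "Toddalia asiatica"][1])
      ape::write.tree(tr, out("barcode_nj.nwk"))
      outputs <<- c(outputs, out("barcode_nj.nwk"))
    })
  }

  eco <- NULL
  if ("ecology" %in% config$stages || "habitat" %in% config$stages) {
    scn <- config$eco_scenario
    if (is.null(scn)) scn <- eco_scenario(seed = stage_seed(config$seed, "ecology"))
    eco <- gen_eco_rasters(scn)
  }

  if ("ecology" %in% config$stages) {
    run_stage("ecology", function() {
      outputs <<- c(outputs, write_stage_csv(eco$sites, out("eco_sites.csv")))
      for (resp in c("volatile_oil", "ether_extract")) {
        fit <- plsr_fit(eco$sites, resp, ncomp = config$ncomp)
        outputs <<- c(outputs,
          write_stage_csv(fit$classification,
                          out(paste0("plsr_", resp, ".csv"))))
      }
    })
  }

  if ("habitat" %in% config$stages) {
    run_stage("habitat", function() {
      # split sites at the median mean-annual-temperature into a warm and
      # a cool niche group, standing for the two species' niches
      warm <- eco$sites$x4 > stats::median(eco$sites$x4)
      groups <- list(warm = eco$sites[warm, ], cool = eco$sites[!warm, ])
      masks <- list()
      areas <- list()
      for (g in names(groups)) {
        env <- build_envelope(groups[[g]], tau = config$tau)
        si <- similarity_index(eco, env, combine = config$combine,
                               soil = config$soil)
        outputs <<- c(outputs,
                      write_ascii_grid(si, out(paste0("habitat_si_", g, ".asc"))))
        masks[[g]] <- si_band_mask(si, config$band[1], config$band[2])
        areas[[g]] <- data.frame(group = g,
                                 suitable_cells = sum(masks[[g]]),
                                 suitable_area_km2 = mask_area_km2(masks[[g]], si))
      }
      outputs <<- c(outputs,
        write_stage_csv(do.call(rbind, areas), out("habitat_areas.csv")),
        write_stage_csv(overlay_intersection(masks)$pairs, out("habitat_overlap.csv")))
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("zanthotools")),
    seed = config$seed,
    parameters = list(stages = config$stages, bootstrap = config$bootstrap,
                      ncomp = config$ncomp, tau = config$tau,
                      band = config$band, combine = config$combine,
                      soil = config$soil),
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
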