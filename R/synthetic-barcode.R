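# Synthetic ITS2 alignments with planted species-diagnostic structure.
#
# A single ancestral sequence (exact GC count at the target fraction) is
# shared by all species; each species then receives its planted
# substitutions, and indel-carrier species keep ancestral bases at their
# insert columns while every other species holds a gap there. Planted
# substitutions are realised as transitions whose ancestral state is the
# transition partner of the planted base, so species differ exactly at
# the planted positions and the realised GC stays at the target.

transition_partner <- function(b) {
  unname(c(A = "G", G = "A", C = "T", T = "C")[b])
}

default_snps <- function() {
  list(
    "Z. bungeanum" = data.frame(position = c(105L, 191L, 197L, 203L),
                                base = c("T", "C", "A", "G"),
                                stringsAsFactors = FALSE),
    "Toddalia asiatica" = data.frame(position = c(12L, 48L, 77L, 133L, 158L, 210L),
                                     base = c("A", "G", "T", "C", "A", "T"),
                                     stringsAsFactors = FALSE)
  )
}

default_indels <- function() list("Z. armatum" = c(29L, 165L, 215L))

default_cultivar_map <- function() {
  list("Z. armatum" = c("ZA1", "ZA2"),
       "Z. bungeanum" = c("ZB1", "ZB2", "ZB3", "ZB4"),
       "Toddalia asiatica" = "TA")
}

#' Scenario for the synthetic ITS2 alignment generator
#'
#' Defaults emulate the published marker: alignment length 225 within the
#' reported 222-227 bp span, GC near 70%, four Z. bungeanum-unique
#' substitution sites at alignment positions 105, 191, 197 and 203, three
#' Z. armatum-unique insert columns at 29, 165 and 215 (all other species
#' hold gaps there), plus a Toddalia asiatica outgroup with its own
#' private substitutions.
#'
#' @param seq_length alignment length in \[222, 227\].
#' @param gc_target target GC fraction of the ancestral sequence.
#' @param species_diagnostic_snps named list, species -> data frame with
#'   `position` (1-based) and `base` (the carrier's state).
#' @param species_diagnostic_indels named list, species -> integer insert
#'   positions (the named species carries bases; all others get gaps).
#' @param cultivar_map named list, species -> cultivar labels.
#' @param n_specimens_per_cultivar scalar or named vector of specimen
#'   counts per cultivar.
#' @param within_cultivar_divergence substitutions/site of specimen-level
#'   noise; scalar or named per-cultivar vector. 0 (default) makes all
#'   specimens of a species share one haplotype.
#' @param seed integer seed.
#' @return a `barcode_scenario` list.
#' @export
barcode_scenario <- function(seq_length = 225,
                             gc_target = 0.70,
                             species_diagnostic_snps = default_snps(),
                             species_diagnostic_indels = default_indels(),
                             cultivar_map = default_cultivar_map(),
                             n_specimens_per_cultivar = c(ZA1 = 5, ZA2 = 5,
                                                          ZB1 = 5, ZB2 = 5,
                                                          ZB3 = 5, ZB4 = 5,
                                                          TA = 3),
                             within_cultivar_divergence = 0,
                             seed = 1) {
  if (seq_length < 222 || seq_length > 227) stop("seq_length must be in [222, 227]")
  if (gc_target <= 0 || gc_target >= 1) stop("gc_target must be in (0, 1)")
  if (any(within_cultivar_divergence < 0)) stop("divergence must be >= 0")
  all_pos <- c(unlist(lapply(species_diagnostic_snps, `[[`, "position")),
               unlist(species_diagnostic_indels))
  if (length(all_pos)) {
    if (any(all_pos < 1 | all_pos > seq_length)) {
      stop("diagnostic positions must lie in [1, seq_length]")
    }
    if (anyDuplicated(all_pos)) {
      stop("diagnostic position collision between species")
    }
  }
  for (sp in names(species_diagnostic_snps)) {
    b <- species_diagnostic_snps[[sp]]$base
    if (any(!b %in% c("A", "C", "G", "T"))) stop("planted bases must be A/C/G/T")
  }
  structure(list(seq_length = as.integer(seq_length), gc_target = gc_target,
                 species_diagnostic_snps = species_diagnostic_snps,
                 species_diagnostic_indels = species_diagnostic_indels,
                 cultivar_map = cultivar_map,
                 n_specimens_per_cultivar = n_specimens_per_cultivar,
                 within_cultivar_divergence = within_cultivar_divergence,
                 seed = as.integer(seed)),
            class = "barcode_scenario")
}

per_cultivar_value <- function(x, cultivar, default = 0) {
  if (length(x) == 1 && is.null(names(x))) return(unname(x))
  if (!is.null(names(x)) && cultivar %in% names(x)) return(unname(x[[cultivar]]))
  default
}

#' Generate a synthetic aligned ITS2 sequence set
#'
#' @param scenario a [barcode_scenario()].
#' @return an [aligned_seq_set()]; empty when all specimen counts are 0.
#' @export
gen_barcode_set <- function(scenario) {
  stopifnot(inherits(scenario, "barcode_scenario"))
  set.seed(scenario$seed)
  L <- scenario$seq_length
  n_gc <- round(scenario$gc_target * L)
  pool <- c(sample(c("G", "C"), n_gc, replace = TRUE),
            sample(c("A", "T"), L - n_gc, replace = TRUE))
  anc <- sample(pool, L)
  # planted substitutions: ancestral state forced to the transition
  # partner of the planted base (preserves GC, differs from the carrier)
  for (sp in names(scenario$species_diagnostic_snps)) {
    df <- scenario$species_diagnostic_snps[[sp]]
    anc[df$position] <- transition_partner(df$base)
  }
  species_list <- names(scenario$cultivar_map)
  sp_seq <- lapply(species_list, function(sp) {
    s <- anc
    df <- scenario$species_diagnostic_snps[[sp]]
    if (!is.null(df)) s[df$position] <- df$base
    for (carrier in names(scenario$species_diagnostic_indels)) {
      if (carrier != sp) s[scenario$species_diagnostic_indels[[carrier]]] <- "-"
    }
    s
  })
  names(sp_seq) <- species_list
  fixed_pos <- c(unlist(lapply(scenario$species_diagnostic_snps, `[[`, "position")),
                 unlist(scenario$species_diagnostic_indels))
  free_pos <- setdiff(seq_len(L), fixed_pos)
  seqs <- character(0); sp_lab <- character(0); cv_lab <- character(0)
  id <- character(0)
  for (sp in species_list) {
    for (cv in scenario$cultivar_map[[sp]]) {
      n <- per_cultivar_value(scenario$n_specimens_per_cultivar, cv, 0)
      if (n < 1) next
      div <- per_cultivar_value(scenario$within_cultivar_divergence, cv, 0)
      for (k in seq_len(n)) {
        s <- sp_seq[[sp]]
        if (div > 0) {
          n_mut <- stats::rbinom(1, length(free_pos), div)
          if (n_mut > 0) {
            at <- sample(free_pos, n_mut)
            s[at] <- vapply(s[at], function(b) {
              sample(setdiff(c("A", "C", "G", "T"), b), 1)
            }, character(1))
          }
        }
        seqs <- c(seqs, paste(s, collapse = ""))
        sp_lab <- c(sp_lab, sp)
        cv_lab <- c(cv_lab, cv)
        id <- c(id, sprintf("%s_%02d", cv, k))
      }
    }
  }
  aligned_seq_set(seqs, sp_lab, cv_lab, id)
}
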