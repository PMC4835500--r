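#' Path to the packaged batch table of the 47 field-collected batches
#'
#' Locality, coordinates and measured volatile-oil / ether-extract contents
#' for 47 pericarp batches of six cultivars (ZA1, ZA2 of *Z. armatum*; ZB1 -
#' ZB4 of *Z. bungeanum*), as published. Coordinates are kept as the original
#' degree-minute-second strings, including their typographic irregularities.
#'
#' @return file path of the packaged CSV.
#' @export
table1_path <- function() {
  system.file("extdata", "table1.csv", package = "zanthotools", mustWork = TRUE)
}

#' Parse a degree-minute-second coordinate string to decimal degrees
#'
#' Tolerant of the mixed prime/double-prime notation found in field tables:
#' all numeric tokens are read in order as degrees, minutes, seconds
#' (missing trailing parts default to 0).
#'
#' @param x character vector like `"103°15′22.372″"`.
#' @return numeric decimal degrees.
#' @export
parse_dms <- function(x) {
  vapply(as.character(x), function(s) {
    tok <- regmatches(s, gregexpr("[0-9]*\\.?[0-9]+", s))[[1]]
    if (length(tok) == 0) return(NA_real_)
    v <- as.numeric(tok)
    length(v) <- 3
    v[is.na(v)] <- 0
    v[1] + v[2] / 60 + v[3] / 3600
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a chemistry batch table
#'
#' Reads a CSV in the packaged column layout (species, cultivar_name,
#' abbreviation, locality, longitude, latitude, volatile_oil, ether_extract),
#' converts DMS coordinates to decimal degrees, and derives the species from
#' the cultivar abbreviation prefix (ZA -> *Z. armatum*, ZB -> *Z. bungeanum*)
#' when the species column is absent.
#'
#' @param path CSV file; defaults to the packaged batch table.
#' @return data frame of batches with numeric `longitude`, `latitude`
#'   (decimal degrees) and contents in percent.
#' @export
read_chem_table <- function(path = table1_path()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("abbreviation", "volatile_oil", "ether_extract")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(tab$species)) {
    tab$species <- ifelse(grepl("^ZA", tab$abbreviation), "Z. armatum",
                          ifelse(grepl("^ZB", tab$abbreviation), "Z. bungeanum", NA))
  }
  if (any(tab$volatile_oil < 0) || any(tab$ether_extract < 0)) {
    stop("contents must be >= 0")
  }
  if (!is.numeric(tab$longitude)) tab$longitude <- parse_dms(tab$longitude)
  if (!is.numeric(tab$latitude)) tab$latitude <- parse_dms(tab$latitude)
  tab
}
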