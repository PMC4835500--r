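# Kimura 2-parameter distances with pairwise deletion.
#
# Sites holding a gap or N in either sequence of a pair are dropped for
# that pair only (pairwise deletion, the MEGA default). With P the
# transition fraction and Q the transversion fraction over the usable
# sites, d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]. When the log argument is
# non-positive the distance is saturated: it is returned as NA flagged by
# a "saturated" attribute, never as a silent NaN.

# core on integer-encoded vectors (A=1, G=2, C=3, T=4, missing=0);
# returns c(d, n_sites, P, Q) with d = NA when saturated
k2p_core <- function(a, b) {
  use <- a > 0L & b > 0L
  n <- sum(use)
  if (n == 0L) return(c(NA_real_, 0, NA_real_, NA_real_))
  a <- a[use]; b <- b[use]
  diff <- a != b
  # purines are codes 1-2, pyrimidines 3-4: a within-class difference is
  # a transition, a between-class difference a transversion
  ts <- sum(diff & ((a <= 2L) == (b <= 2L)))
  tv <- sum(diff) - ts
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1) - 0.25 * log(w2)
  c(d, n, P, Q)
}

encode_one <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], c("A", "G", "C", "T"),
        nomatch = 0L)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' @param seq_a,seq_b aligned sequences of equal length (characters over
#'   A, C, G, T, N, `-`).
#' @return the K2P distance in substitutions/site, with attributes
#'   `n_sites` (usable sites after pairwise deletion), `P` and `Q`
#'   (transition and transversion fractions). A saturated pair (log
#'   argument <= 0) returns `NA` with attribute `saturated = TRUE`.
#'   No usable sites at all is an error.
#' @examples
#' a <- paste(rep("A", 100), collapse = "")
#' b <- paste(c("G", rep("A", 99)), collapse = "")
#' k2p_distance(a, b)  # -0.5 * log(0.98) = 0.01010135
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must have equal aligned length")
  r <- k2p_core(encode_one(seq_a), encode_one(seq_b))
  if (r[2] == 0) stop("no usable sites after pairwise deletion")
  d <- r[1]
  attr(d, "n_sites") <- as.integer(r[2])
  attr(d, "P") <- r[3]
  attr(d, "Q") <- r[4]
  if (is.na(r[1])) attr(d, "saturated") <- TRUE
  d
}

#' K2P distance matrix for an aligned sequence set
#'
#' All pairwise distances under pairwise deletion. Saturated pairs are NA
#' in the matrix and listed in the `saturated` element.
#'
#' @param set an [aligned_seq_set()] with at least 2 records.
#' @return object of class `k2p_dist`: `d` (symmetric labelled matrix,
#'   zero diagonal), `n_sites` (usable-site counts), `labels`, `species`,
#'   `cultivar`, `saturated` (data frame of flagged pairs).
#' @export
k2p_matrix <- function(set) {
  stopifnot(inherits(set, "aligned_seq_set"))
  n <- length(set)
  if (n < 2) stop("need at least 2 sequences")
  im <- as_int_matrix(set)
  d <- matrix(0, n, n, dimnames = list(set$id, set$id))
  ns <- matrix(set$width, n, n, dimnames = list(set$id, set$id))
  sat <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- k2p_core(im[i, ], im[j, ])
      if (r[2] == 0) {
        stop("no usable sites between ", set$id[i], " and ", set$id[j])
      }
      d[i, j] <- d[j, i] <- r[1]
      ns[i, j] <- ns[j, i] <- r[2]
      if (is.na(r[1])) sat[[length(sat) + 1]] <- c(set$id[i], set$id[j])
    }
  }
  diag(ns) <- NA_integer_
  sat_df <- if (length(sat)) {
    data.frame(a = vapply(sat, `[`, "", 1), b = vapply(sat, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  }
  structure(list(d = d, n_sites = ns, labels = set$id,
                 species = set$species, cultivar = set$cultivar,
                 saturated = sat_df),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat("k2p_dist:", length(x$labels), "taxa")
  if (nrow(x$saturated)) cat(",", nrow(x$saturated), "saturated pair(s)")
  cat("\n")
  invisible(x)
}

# group labels aligned to a k2p_dist; `groups` may be "species",
# "cultivar", or a vector of labels in matrix order
resolve_groups <- function(dm, groups) {
  if (is.character(groups) && length(groups) == 1 &&
      groups %in% c("species", "cultivar")) {
    return(dm[[groups]])
  }
  if (length(groups) != length(dm$labels)) {
    stop("group labels must match the number of taxa")
  }
  as.character(groups)
}

#' Barcoding-gap analysis per species
#'
#' For each species: the maximum intraspecific K2P distance, the minimum
#' distance to any other species, and the barcoding-gap flag
#' (min interspecific > max intraspecific). Species represented by a
#' single specimen have an undefined intraspecific range and an NA flag.
#'
#' @param dm a [k2p_matrix()] result.
#' @param groups `"species"` (default), `"cultivar"`, or an explicit label
#'   vector.
#' @return data frame: `group`, `n`, `max_intra`, `min_inter`, `gap`.
#' @export
gap_analysis <- function(dm, groups = "species") {
  stopifnot(inherits(dm, "k2p_dist"))
  g <- resolve_groups(dm, groups)
  lev <- unique(g)
  if (length(lev) < 2) stop("need at least 2 species for a barcoding-gap analysis")
  if (anyNA(dm$d)) stop("distance matrix contains saturated (undefined) entries")
  res <- lapply(lev, function(sp) {
    inside <- which(g == sp)
    outside <- which(g != sp)
    max_intra <- if (length(inside) >= 2) {
      max(dm$d[inside, inside][upper.tri(matrix(0, length(inside), length(inside)))])
    } else NA_real_
    min_inter <- min(dm$d[inside, outside, drop = FALSE])
    data.frame(group = sp, n = length(inside), max_intra = max_intra,
               min_inter = min_inter,
               gap = if (is.na(max_intra)) NA else min_inter > max_intra,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Within-group distance range
#'
#' Minimum and maximum K2P distance over all pairs inside each group.
#' Singleton groups are flagged with NA ranges.
#'
#' @param dm a [k2p_matrix()] result.
#' @param groups `"species"`, `"cultivar"`, or an explicit label vector.
#' @return data frame: `group`, `n`, `min_intra`, `max_intra`.
#' @export
intra_range <- function(dm, groups = "cultivar") {
  stopifnot(inherits(dm, "k2p_dist"))
  g <- resolve_groups(dm, groups)
  lev <- unique(g)
  res <- lapply(lev, function(gr) {
    inside <- which(g == gr)
    if (length(inside) < 2) {
      return(data.frame(group = gr, n = length(inside),
                        min_intra = NA_real_, max_intra = NA_real_,
                        stringsAsFactors = FALSE))
    }
    dd <- dm$d[inside, inside][upper.tri(matrix(0, length(inside), length(inside)))]
    data.frame(group = gr, n = length(inside),
               min_intra = min(dd), max_intra = max(dd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a distance matrix as CSV or square PHYLIP
#'
#' @param dm a [k2p_matrix()] result.
#' @param path output file.
#' @param format `"csv"` (labelled square CSV) or `"phylip"` (square
#'   PHYLIP with a taxon-count header line).
#' @return `path`, invisibly.
#' @export
write_dist <- function(dm, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  stopifnot(inherits(dm, "k2p_dist"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(dm$d), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(dm$labels)), con)
    for (i in seq_along(dm$labels)) {
      writeLines(paste(formatC(dm$labels[i], width = -10),
                       paste(sprintf("%.8f", dm$d[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}
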