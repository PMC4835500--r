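#' Aligned sequence set with species and cultivar labels
#'
#' Container for an ITS2 (or any) alignment: equal-length sequences over
#' A, C, G, T, N and the gap character `-`, each carrying a specimen id,
#' a species label and a cultivar label. Ambiguity codes other than N are
#' rejected: the intended inputs are clean Sanger consensus sequences.
#'
#' @param seq character vector of aligned sequences (equal lengths).
#' @param species species label per sequence.
#' @param cultivar cultivar label per sequence.
#' @param id unique specimen ids; defaults to names of `seq` or `seq_<i>`.
#' @return object of class `aligned_seq_set` with fields `id`, `species`,
#'   `cultivar`, `seq` and `width` (alignment length).
#' @export
aligned_seq_set <- function(seq, species, cultivar, id = NULL) {
  nms <- names(seq)
  seq <- toupper(as.character(seq))
  n <- length(seq)
  if (is.null(id)) id <- if (!is.null(nms)) nms else paste0("seq_", seq_len(n))
  id <- as.character(id)
  species <- as.character(species)
  cultivar <- as.character(cultivar)
  if (length(species) != n || length(cultivar) != n || length(id) != n) {
    stop("seq, species, cultivar and id must have equal length")
  }
  if (anyDuplicated(id)) stop("sequence ids must be unique")
  width <- 0L
  if (n > 0) {
    lens <- nchar(seq)
    if (length(unique(lens)) != 1) stop("all aligned sequences must have equal length")
    width <- lens[1]
    bad <- grepl("[^ACGTN-]", seq)
    if (any(bad)) {
      stop("disallowed characters (only A,C,G,T,N,- accepted; no ambiguity codes) in: ",
           paste(id[bad], collapse = ", "))
    }
  }
  structure(list(id = id, species = species, cultivar = cultivar,
                 seq = unname(seq), width = as.integer(width)),
            class = "aligned_seq_set")
}

#' @export
length.aligned_seq_set <- function(x) length(x$seq)

#' @export
print.aligned_seq_set <- function(x, ...) {
  cat("aligned_seq_set:", length(x), "sequences, alignment width", x$width, "\n")
  if (length(x)) {
    tab <- table(x$species)
    cat("species:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset an aligned sequence set
#' @param x an `aligned_seq_set`.
#' @param i index vector (logical, integer or id character).
#' @param ... unused.
#' @export
`[.aligned_seq_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  aligned_seq_set(x$seq[i], x$species[i], x$cultivar[i], x$id[i])
}

#' Alignment as a character matrix (one column per site)
#' @param set an `aligned_seq_set`.
#' @return character matrix, rows named by specimen id.
#' @export
as_char_matrix <- function(set) {
  stopifnot(inherits(set, "aligned_seq_set"))
  if (length(set) == 0) {
    return(matrix(character(0), nrow = 0, ncol = set$width))
  }
  m <- do.call(rbind, strsplit(set$seq, "", fixed = TRUE))
  rownames(m) <- set$id
  m
}

# integer encoding used by the distance code: A=1, G=2, C=3, T=4,
# gap/N/other = 0 (treated as missing under pairwise deletion)
as_int_matrix <- function(set) {
  m <- as_char_matrix(set)
  im <- matrix(match(m, c("A", "G", "C", "T"), nomatch = 0L), nrow = nrow(m))
  rownames(im) <- rownames(m)
  im
}

#' Write an aligned sequence set to FASTA
#'
#' Headers are `id|species|cultivar` so the labels survive a round trip
#' through [read_alignment()].
#'
#' @param set an `aligned_seq_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(set, path) {
  stopifnot(inherits(set, "aligned_seq_set"))
  hdr <- paste(set$id, set$species, set$cultivar, sep = "|")
  bin <- ape::as.DNAbin(as_char_matrix(set))
  rownames(bin) <- hdr
  ape::write.FASTA(bin, path)
  invisible(path)
}

#' Read an aligned FASTA into an `aligned_seq_set`
#'
#' Headers of the form `id|species|cultivar` restore the labels; plain
#' headers yield empty species/cultivar labels.
#'
#' @param path aligned FASTA file.
#' @return an `aligned_seq_set`.
#' @export
read_alignment <- function(path) {
  bin <- ape::read.FASTA(path)
  if (length(bin) == 0) return(aligned_seq_set(character(0), character(0), character(0)))
  m <- as.character(as.matrix(bin))
  seqs <- toupper(apply(m, 1, paste, collapse = ""))
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  id <- vapply(parts, `[`, "", 1)
  species <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
  cultivar <- vapply(parts, function(p) if (length(p) >= 3) p[3] else "", "")
  aligned_seq_set(unname(seqs), species, cultivar, id)
}

#' Alignment statistics: ungapped lengths and GC content
#'
#' Per-record ungapped length (A/C/G/T/N characters) and GC percentage
#' computed over unambiguous bases (A/C/G/T) only.
#'
#' @param set an `aligned_seq_set`.
#' @return list with `per_record` (id, ungapped_length, gc_percent),
#'   `length_range` (min, max) and `mean_gc` (percent).
#' @export
seq_stats <- function(set) {
  stopifnot(inherits(set, "aligned_seq_set"))
  if (length(set) == 0) stop("empty sequence set")
  m <- as_char_matrix(set)
  ungapped <- rowSums(m != "-")
  acgt <- apply(m, 1, function(r) sum(r %in% c("A", "C", "G", "T")))
  gc <- apply(m, 1, function(r) sum(r %in% c("G", "C")))
  gc_pct <- 100 * gc / acgt
  list(
    per_record = data.frame(id = set$id, ungapped_length = as.integer(ungapped),
                            gc_percent = gc_pct, stringsAsFactors = FALSE),
    length_range = range(ungapped),
    mean_gc = mean(gc_pct)
  )
}

#' Collapse identical sequences into haplotypes per group
#'
#' Sequences are compared after uppercasing; N is treated as a distinct
#' state, so two sequences differing only by an N are different haplotypes.
#'
#' @param set an `aligned_seq_set`.
#' @param within grouping key: `"species"` or `"cultivar"`.
#' @return list with `counts` (data frame: group, n_specimens,
#'   n_haplotypes) and `haplotype` (integer haplotype index per specimen,
#'   numbered within the whole set).
#' @export
haplotype_collapse <- function(set, within = c("species", "cultivar")) {
  within <- match.arg(within)
  stopifnot(inherits(set, "aligned_seq_set"))
  if (length(set) == 0) stop("empty sequence set")
  hap <- match(set$seq, unique(set$seq))
  g <- factor(set[[within]])
  counts <- data.frame(
    group = levels(g),
    n_specimens = as.integer(tabulate(g)),
    n_haplotypes = as.integer(tapply(hap, g, function(h) length(unique(h)))),
    stringsAsFactors = FALSE
  )
  rownames(counts) <- NULL
  list(counts = counts, haplotype = hap)
}
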