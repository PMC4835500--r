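# Saitou-Nei neighbor joining with deterministic tie-breaking.
#
# At each step the pair (i, j) minimising
#   Q(i, j) = (r - 2) d(i, j) - R_i - R_j
# is joined (r = number of active nodes, R_i = row sum). Ties are broken
# on the lowest (i, j) index pair in current active order, so the output
# is a pure function of the input matrix. Negative branch lengths are
# clamped to 0 with the excess transferred to the sister branch
# (Kuhner-Felsenstein style), keeping path lengths between taxa intact.

quote_label <- function(x) {
  need <- grepl("[^A-Za-z0-9_.\\-]", x)
  x[need] <- paste0("'", gsub("'", "_", x[need]), "'")
  x
}

fmt_bl <- function(x) sprintf("%.12g", x + 0)  # `+ 0` folds -0 into 0

nj_newick <- function(D, labels) {
  r <- nrow(D)
  nw <- quote_label(labels)
  while (r > 3) {
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    m <- min(Q)
    hits <- which(Q == m, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
    new_nw <- sprintf("(%s:%s,%s:%s)", nw[i], fmt_bl(vi), nw[j], fmt_bl(vj))
    dn <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn), c(dn, 0))
    nw <- c(nw[keep], new_nw)
    r <- r - 1
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  sprintf("(%s:%s,%s:%s,%s:%s);", nw[1], fmt_bl(v[1]), nw[2], fmt_bl(v[2]),
          nw[3], fmt_bl(v[3]))
}

as_dist_matrix <- function(dm) {
  if (inherits(dm, "k2p_dist")) return(dm$d)
  if (inherits(dm, "dist")) return(as.matrix(dm))
  as.matrix(dm)
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param dm a [k2p_matrix()] result, a `dist` object, or a symmetric
#'   labelled matrix with at least 3 taxa and finite entries.
#' @param outgroup optional taxon label(s); when given, the tree is rooted
#'   on that clade via [ape::root()].
#' @return an [ape::phylo] tree (unrooted unless `outgroup` is supplied)
#'   with branch lengths in substitutions/site.
#' @export
nj_tree <- function(dm, outgroup = NULL) {
  D <- as_dist_matrix(dm)
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (any(!is.finite(D))) {
    stop("distance matrix has undefined entries; resolve saturated pairs first")
  }
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  tr <- ape::read.tree(text = nj_newick(D, labels))
  if (!is.null(outgroup)) {
    missing <- setdiff(outgroup, tr$tip.label)
    if (length(missing)) stop("outgroup not in tree: ", paste(missing, collapse = ", "))
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Alignment columns are resampled with replacement `replicates` times;
#' each replicate is run through [k2p_matrix()] and [nj_tree()], and the
#' support of each internal bipartition of the full-alignment tree is the
#' percentage of successful replicates containing it. Replicates whose
#' resampled alignment yields an undefined distance are skipped and
#' counted in the `skipped` attribute.
#'
#' @param set an [aligned_seq_set()].
#' @param replicates number of bootstrap resamples (>= 1).
#' @param seed integer seed making the resampling deterministic.
#' @param outgroup optional label(s) to root the reported tree on.
#' @return the full-data NJ tree with `node.label` holding bootstrap
#'   percentages (root label empty), plus attributes `skipped` and
#'   `n_used`.
#' @export
bootstrap_support <- function(set, replicates = 1000, seed = 1, outgroup = NULL) {
  stopifnot(inherits(set, "aligned_seq_set"))
  if (replicates < 1) stop("replicates must be >= 1")
  main <- nj_tree(k2p_matrix(set))
  im <- as_int_matrix(set)
  L <- ncol(im)
  n <- nrow(im)
  set.seed(as.integer(seed))
  boot <- vector("list", replicates)
  used <- 0L
  skipped <- 0L
  # identical rows (shared haplotypes) give identical distances; collapse
  # them once so each replicate only computes distinct-pair distances
  key <- apply(im, 1, paste, collapse = "")
  uidx <- which(!duplicated(key))
  map <- match(key, key[uidx])
  nu <- length(uidx)
  for (b in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    Mb <- im[uidx, cols, drop = FALSE]
    Du <- matrix(0, nu, nu)
    bad <- FALSE
    if (nu > 1) {
      for (i in seq_len(nu - 1)) {
        for (j in (i + 1):nu) {
          r <- k2p_core(Mb[i, ], Mb[j, ])
          if (r[2] == 0 || is.na(r[1])) { bad <- TRUE; break }
          Du[i, j] <- Du[j, i] <- r[1]
        }
        if (bad) break
      }
    }
    if (bad) { skipped <- skipped + 1L; next }
    D <- Du[map, map, drop = FALSE]
    dimnames(D) <- list(set$id, set$id)
    used <- used + 1L
    boot[[used]] <- ape::read.tree(text = nj_newick(D, set$id))
  }
  if (used == 0) stop("all bootstrap replicates failed")
  boot <- boot[seq_len(used)]
  class(boot) <- "multiPhylo"
  counts <- ape::prop.clades(main, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / used)
  # node 1 is the basal trichotomy of the unrooted tree, not a bipartition
  support[1] <- NA
  main$node.label <- ifelse(is.na(support), "", as.character(support))
  if (!is.null(outgroup)) {
    main <- ape::root(main, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  attr(main, "skipped") <- skipped
  attr(main, "n_used") <- used
  main
}

#' Diagnostic variable sites and indel sites per group
#'
#' A site (1-based alignment column) is diagnostic for a group when the
#' group is fixed for one state (a base or the gap) that occurs in no
#' other group. N is treated as missing and ignored; a group observed
#' only as N at a column is not fixed there. A diagnostic site is
#' reported as an *indel* site when the distinguishing contrast involves
#' the gap state (the group is fixed for a gap, or carries a base where
#' every other group is fixed for gaps -- the insert-carrier case);
#' otherwise it is a *variable* (substitution) site.
#'
#' @param set an [aligned_seq_set()].
#' @param group_key `"species"` or `"cultivar"`.
#' @return object of class `diagnostic_report`: a named list per group,
#'   each with `variable_sites` and `indel_sites` data frames
#'   (`position`, `state`).
#' @export
diagnostic_sites <- function(set, group_key = c("species", "cultivar")) {
  group_key <- match.arg(group_key)
  stopifnot(inherits(set, "aligned_seq_set"))
  g <- set[[group_key]]
  lev <- unique(g)
  if (length(lev) < 2) stop("need at least 2 groups")
  m <- as_char_matrix(set)
  report <- lapply(lev, function(x) {
    list(variable_sites = data.frame(position = integer(0), state = character(0),
                                     stringsAsFactors = FALSE),
         indel_sites = data.frame(position = integer(0), state = character(0),
                                  stringsAsFactors = FALSE))
  })
  names(report) <- lev
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    states <- lapply(lev, function(sp) setdiff(unique(col[g == sp]), "N"))
    names(states) <- lev
    for (sp in lev) {
      s <- states[[sp]]
      if (length(s) != 1) next
      others <- unique(unlist(states[setdiff(lev, sp)]))
      if (length(others) == 0 || s %in% others) next
      is_indel <- s == "-" || all(others == "-")
      row <- data.frame(position = j, state = s, stringsAsFactors = FALSE)
      slot <- if (is_indel) "indel_sites" else "variable_sites"
      report[[sp]][[slot]] <- rbind(report[[sp]][[slot]], row)
    }
  }
  structure(report, class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  for (sp in names(x)) {
    cat(sp, ": ", nrow(x[[sp]]$variable_sites), " variable site(s)",
        if (nrow(x[[sp]]$variable_sites))
          paste0(" [", paste(x[[sp]]$variable_sites$position, collapse = ", "), "]"),
        ", ", nrow(x[[sp]]$indel_sites), " indel site(s)",
        if (nrow(x[[sp]]$indel_sites))
          paste0(" [", paste(x[[sp]]$indel_sites$position, collapse = ", "), "]"),
        "\n", sep = "")
  }
  invisible(x)
}
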