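# Independent brute-force oracles, deliberately written without reusing
# any package internals.

# K2P by explicit per-site comparison with a lookup of the six
# transition pairs, counting usable sites directly.
oracle_k2p <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  transitions <- c("AG", "GA", "CT", "TC")
  n <- 0; ts <- 0; tv <- 0
  for (i in seq_along(av)) {
    x <- av[i]; y <- bv[i]
    if (!x %in% c("A", "C", "G", "T") || !y %in% c("A", "C", "G", "T")) next
    n <- n + 1
    if (x != y) {
      if (paste0(x, y) %in% transitions) ts <- ts + 1 else tv <- tv + 1
    }
  }
  P <- ts / n; Q <- tv / n
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# all within-group pairwise K2P values via the oracle
oracle_intra <- function(seqs, groups, group) {
  idx <- which(groups == group)
  if (length(idx) < 2) return(numeric(0))
  pairs <- utils::combn(idx, 2)
  apply(pairs, 2, function(ij) oracle_k2p(seqs[ij[1]], seqs[ij[2]]))
}

# diagnostic-site scan: per column, a group fixed for a state absent in
# every other group (N ignored)
oracle_diagnostic <- function(seqs, groups) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  lev <- unique(groups)
  out <- list()
  for (sp in lev) out[[sp]] <- integer(0)
  for (j in seq_len(ncol(m))) {
    for (sp in lev) {
      mine <- setdiff(unique(m[groups == sp, j]), "N")
      rest <- setdiff(unique(m[groups != sp, j]), "N")
      if (length(mine) == 1 && length(rest) >= 1 && !(mine %in% rest)) {
        out[[sp]] <- c(out[[sp]], j)
      }
    }
  }
  out
}

# random additive tree -> patristic distance matrix (for NJ recovery)
random_additive_case <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.05, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# bootstrap support of the bipartition separating `tips` from the rest,
# matched by label sets rather than node numbering
support_of_split <- function(tree, tips) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  all_tips <- tree$tip.label
  for (k in seq_along(parts)) {
    s <- labs[parts[[k]]]
    if (setequal(s, tips) || setequal(s, setdiff(all_tips, tips))) {
      lab <- tree$node.label[k]
      return(suppressWarnings(as.numeric(lab)))
    }
  }
  NA_real_
}

# per-cell similarity index recomputed cell by cell from first principles
oracle_si <- function(stack, env, combine = "mean") {
  factors <- env$bounds$factor
  nr <- nrow(stack$soil$values); nc <- ncol(stack$soil$values)
  si <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      mus <- numeric(0); ws <- numeric(0)
      bad <- FALSE
      for (f in factors) {
        v <- stack$rasters[[f]]$values[i, j]
        if (is.na(v)) { bad <- TRUE; break }
        b <- env$bounds[env$bounds$factor == f, ]
        margin <- if (b$hi > b$lo) env$tau * (b$hi - b$lo) else env$tau * abs(b$lo)
        mu <- if (v >= b$lo && v <= b$hi) 1
              else if (margin == 0) 0
              else if (v < b$lo) max(0, 1 - (b$lo - v) / margin)
              else max(0, 1 - (v - b$hi) / margin)
        mus <- c(mus, mu); ws <- c(ws, env$weights[[f]])
      }
      if (bad) next
      sv <- stack$soil$values[i, j]
      if (is.na(sv)) next
      mus <- c(mus, as.numeric(sv %in% env$soil_codes))
      ws <- c(ws, env$weights[[length(env$weights)]])
      si[i, j] <- if (combine == "mean") 100 * sum(ws * mus) / sum(ws)
                  else 100 * min(mus)
    }
  }
  si
}
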