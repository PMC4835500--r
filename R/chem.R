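#' Round half away from zero
#'
#' Commercial rounding used for all reported percentages: ties go away from
#' zero (so 12.775 -> 12.78), unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Volatile-oil content from a steam-distillation measurement
#'
#' Content T = V / M x 100, the distilled oil volume as a percentage of the
#' dry sample mass (protocol mass 20.00 g per batch).
#'
#' @param V volatile-oil volume in mL.
#' @param M sample mass in g; must be positive.
#' @return content in percent.
#' @examples
#' volatile_oil_content(V = 1.498, M = 20)  # 7.49
#' @export
volatile_oil_content <- function(V, M) {
  if (any(!is.finite(M)) || any(M <= 0)) stop("sample mass M must be positive")
  if (any(!is.finite(V)) || any(V < 0)) stop("oil volume V must be >= 0")
  V / M * 100
}

#' Non-volatile ether-extract content from a Soxhlet measurement
#'
#' Content X = (m2 - m1) * 100 / m0 * 100 / (100 - H): the extract mass as a
#' percentage of sample mass, corrected to dry mass by the water content H.
#'
#' @param m0 sample mass in g; must be positive.
#' @param m1 receiving-flask mass in g.
#' @param m2 flask-plus-extract mass in g; must be >= m1.
#' @param H water content of the sample in percent, in \[0, 100).
#' @return content in percent.
#' @examples
#' ether_extract_content(m0 = 2, m1 = 50, m2 = 50.18, H = 10)  # 10
#' @export
ether_extract_content <- function(m0, m1, m2, H = 0) {
  if (any(!is.finite(m0)) || any(m0 <= 0)) stop("sample mass m0 must be positive")
  if (any(m2 < m1)) stop("flask-plus-extract mass m2 must be >= flask mass m1")
  if (any(H < 0 | H >= 100)) stop("water content H must be in [0, 100)")
  (m2 - m1) * 100 / m0 * 100 / (100 - H)
}

#' Per-group content summary
#'
#' Arithmetic means of volatile-oil and ether-extract contents per cultivar
#' or per species, reported both at full precision and rounded to 2 decimals
#' (half away from zero), the precision of the source tables.
#'
#' @param batches data frame of batches with columns `volatile_oil`,
#'   `ether_extract` and the grouping column.
#' @param by grouping column: `"species"` or `"abbreviation"` (cultivar).
#' @return data frame with one row per group: `group`, `n`, `mean_oil`,
#'   `mean_ether`, `mean_oil_2dp`, `mean_ether_2dp`.
#' @export
group_summary <- function(batches, by = c("species", "abbreviation")) {
  by <- match.arg(by)
  if (!is.data.frame(batches) || nrow(batches) == 0) {
    stop("`batches` must be a non-empty data frame")
  }
  need <- c(by, "volatile_oil", "ether_extract")
  miss <- setdiff(need, names(batches))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  g <- factor(batches[[by]])
  if (nlevels(g) == 0) stop("no groups present")
  out <- data.frame(
    group      = levels(g),
    n          = as.integer(tabulate(g)),
    mean_oil   = as.numeric(tapply(batches$volatile_oil, g, mean)),
    mean_ether = as.numeric(tapply(batches$ether_extract, g, mean)),
    stringsAsFactors = FALSE
  )
  out$mean_oil_2dp <- round_half_up(out$mean_oil, 2)
  out$mean_ether_2dp <- round_half_up(out$mean_ether, 2)
  rownames(out) <- NULL
  out
}

#' One-way analysis of variance
#'
#' Classic between/within sum-of-squares decomposition via [stats::aov()].
#' The degenerate all-identical case returns F = 0, p = 1 rather than an
#' error, so screening loops over many variables need no special casing.
#'
#' @param values numeric response (one content variable, batch level).
#' @param groups group labels, same length as `values`.
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(values, groups) {
  if (length(values) != length(groups)) stop("values and groups differ in length")
  ok <- is.finite(values)
  if (!all(ok)) stop("values must be finite")
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (max(tabulate(g)) < 2) stop("at least one group needs >= 2 values")
  df_b <- nlevels(g) - 1L
  df_w <- length(values) - nlevels(g)
  if (max(values) == min(values)) {
    return(list(F = 0, df_between = df_b, df_within = df_w, p = 1))
  }
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  list(
    F = tab[["F value"]][1],
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    p = tab[["Pr(>F)"]][1]
  )
}

#' Principal component analysis of a content matrix
#'
#' Singular-value decomposition of the column-centered (and optionally
#' unit-scaled) batches x features matrix. Components are ordered by
#' decreasing variance; each loading vector's sign is fixed so its
#' largest-magnitude entry is positive, making scores reproducible across
#' platforms.
#'
#' @param x numeric matrix or data frame, batches in rows.
#' @param standardize scale columns to unit variance? Constant columns are
#'   rejected when `TRUE`.
#' @param ncomp number of components to keep; defaults to the matrix rank.
#' @return object of class `chem_pca`: `scores`, `loadings`,
#'   `explained_variance` (fractions summing to 1 over all components),
#'   `sdev`, `center`, `scale`.
#' @export
chem_pca <- function(x, standardize = TRUE, ncomp = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (nrow(x) < 2 || ncol(x) < 1) stop("need >= 2 batches and >= 1 feature")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  scl <- rep(1, ncol(x))
  if (standardize) {
    scl <- apply(x, 2, stats::sd)
    if (any(scl == 0)) {
      stop("constant column(s) cannot be standardized: ",
           paste(colnames(x)[scl == 0], collapse = ", "))
    }
    xc <- sweep(xc, 2, scl, "/")
  }
  sv <- svd(xc)
  pos <- sv$d > max(sv$d[1], 0) * 1e-12
  rank <- sum(pos)
  if (is.null(ncomp)) ncomp <- rank
  if (ncomp > rank) stop("requested ", ncomp, " components but rank is ", rank)
  ev <- sv$d^2 / sum(sv$d^2)
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*% diag(sv$d[seq_len(ncomp)], ncomp)
  # sign convention: largest-|loading| entry positive per component
  for (a in seq_len(ncomp)) {
    k <- which.max(abs(loadings[, a]))
    if (loadings[k, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncomp)))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(ncomp)))
  structure(list(
    scores = scores, loadings = loadings,
    explained_variance = ev, sdev = sv$d / sqrt(nrow(x) - 1),
    center = ctr, scale = if (standardize) scl else NULL
  ), class = "chem_pca")
}

#' @export
print.chem_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "observations,", ncol(x$scores), "components kept\n")
  cat("explained variance:",
      paste0(round(100 * x$explained_variance, 1), "%", collapse = ", "), "\n")
  invisible(x)
}
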