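# NIPALS partial least squares regression (single response) with VIP
# scores, implemented from first principles. Per component a: weight
# w_a = X'y / ||X'y||, score t_a = X w_a, X-loading p_a = X't_a / t_a't_a,
# y-loading q_a = y't_a / t_a't_a, then X and y are deflated. The
# standardized coefficient vector is b = W (P'W)^{-1} q, and
# SSY_a = q_a^2 t_a't_a is the response variance captured by component a.

#' Column-standardize a matrix, keeping the transform
#'
#' @param x numeric matrix or data frame (>= 2 rows).
#' @return matrix with attributes `center` and `scale`; every column has
#'   mean 0 and sd 1. A zero-variance column is an error naming the
#'   column.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    bad <- colnames(x)[scl == 0]
    if (is.null(bad)) bad <- which(scl == 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  out <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Invert [standardize_columns()]
#' @param z standardized matrix carrying `center`/`scale` attributes.
#' @return matrix on the original scale.
#' @export
unstandardize_columns <- function(z) {
  sweep(sweep(as.matrix(z), 2, attr(z, "scale"), "*"), 2, attr(z, "center"), "+")
}

#' Fit a single-response PLSR model by NIPALS
#'
#' `X` and `y` are expected standardized (see [standardize_columns()]);
#' coefficients and VIP scores are then directly comparable across
#' factors. The number of components must not exceed the rank of `X`.
#'
#' @param X standardized predictor matrix, sites x p.
#' @param y standardized response vector.
#' @param ncomp number of latent components A.
#' @param tol residual tolerance of the inner NIPALS iteration.
#' @param max_iter inner iteration cap; non-convergence is an error
#'   naming the component.
#' @return object of class `plsr_model`: `W` (p x A weights, unit
#'   columns), `P` (X-loadings), `q` (y-loadings), `scores` (T),
#'   `coefficients` (standardized b, length p), `ssy` (per-component
#'   explained response sum of squares), `vip`, `ncomp`, `p`.
#' @export
nipals_plsr <- function(X, y, ncomp = 2, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree")
  if (p < 1) stop("need at least one predictor")
  rk <- qr(X)$rank
  if (ncomp > rk) stop("ncomp (", ncomp, ") exceeds rank(X) = ", rk)
  fac <- colnames(X)
  if (is.null(fac)) fac <- paste0("x", seq_len(p))
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  ssy <- numeric(ncomp)
  Xd <- X; yd <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    if (sqrt(sum(w^2)) < tol) {
      stop("NIPALS failed to converge at component ", a,
           ": no remaining covariance between X and y")
    }
    w <- w / sqrt(sum(w^2))
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      tt <- as.vector(Xd %*% w)
      if (sqrt(sum((tt - t_old)^2)) < tol) break
      t_old <- tt
      # single-response NIPALS: the weight update is stationary after
      # one pass; the loop guards the general contract
      if (it == max_iter) {
        stop("NIPALS failed to converge at component ", a)
      }
    }
    tt2 <- sum(tt^2)
    pa <- as.vector(crossprod(Xd, tt)) / tt2
    qa <- sum(yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, pa)
    yd <- yd - tt * qa
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- tt
    q[a] <- qa
    ssy[a] <- qa^2 * tt2
  }
  b <- as.vector(W %*% solve(crossprod(P, W), q))
  names(b) <- fac
  rownames(W) <- rownames(P) <- fac
  model <- structure(list(W = W, P = P, q = q, scores = Tm,
                          coefficients = b, ssy = ssy,
                          ncomp = ncomp, p = p, factors = fac),
                     class = "plsr_model")
  model$vip <- vip_scores(model)
  model
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("NIPALS PLSR:", x$p, "predictors,", x$ncomp, "component(s)\n")
  print(round(rbind(coefficient = x$coefficients, VIP = x$vip), 4))
  invisible(x)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a(w_ja^2 * SSY_a) / sum_a(SSY_a))`; the squares
#' of the VIP scores average to 1 across predictors.
#'
#' @param model a fitted [nipals_plsr()] model.
#' @return named numeric vector of VIP scores, one per predictor.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  tot <- sum(model$ssy)
  if (tot <= 0) stop("zero total explained response variance; VIP undefined")
  v <- sqrt(model$p * as.vector(model$W^2 %*% model$ssy) / tot)
  names(v) <- model$factors
  v
}

#' Three-tier ecological-factor classification from VIP scores
#'
#' VIP > 1: most significant; 0.5 <= VIP <= 1: significant; VIP < 0.5:
#' unimportant. Boundary values (exactly 1 or 0.5) fall in the lower
#' tier. The coefficient supplies the direction of the association.
#'
#' @param vip per-factor VIP scores.
#' @param coefficients per-factor standardized regression coefficients.
#' @return data frame: `factor`, `vip`, `coefficient`, `sign`, `tier`
#'   (factor with levels most significant / significant / unimportant).
#' @export
classify_factors <- function(vip, coefficients) {
  if (length(vip) != length(coefficients)) {
    stop("vip and coefficients must have equal length")
  }
  fac <- names(vip)
  if (is.null(fac)) fac <- paste0("x", seq_along(vip))
  tier <- ifelse(vip > 1, "most significant",
                 ifelse(vip >= 0.5, "significant", "unimportant"))
  data.frame(factor = fac, vip = as.numeric(vip),
             coefficient = as.numeric(coefficients),
             sign = ifelse(coefficients >= 0, "+", "-"),
             tier = factor(tier, levels = c("most significant", "significant",
                                            "unimportant")),
             stringsAsFactors = FALSE)
}

#' Choose the number of PLSR components by leave-one-out CV
#'
#' Minimises the leave-one-out predicted residual sum of squares
#' (PRESS) over 1..`max_comp` components.
#'
#' @param X standardized predictor matrix.
#' @param y standardized response.
#' @param max_comp largest A to consider (capped at rank(X) and n - 2).
#' @return list with `ncomp` (the PRESS-minimising A) and `press`.
#' @export
select_ncomp_loo <- function(X, y, max_comp = 4) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  max_comp <- min(max_comp, qr(X)$rank, n - 2)
  press <- numeric(max_comp)
  for (a in seq_len(max_comp)) {
    err <- vapply(seq_len(n), function(i) {
      fit <- nipals_plsr(X[-i, , drop = FALSE], y[-i], ncomp = a)
      y[i] - sum(X[i, ] * fit$coefficients)
    }, numeric(1))
    press[a] <- sum(err^2)
  }
  list(ncomp = which.min(press), press = press)
}

#' Fit one PLSR model per response from a site-factor table
#'
#' Convenience wrapper: standardizes the chosen factor columns and the
#' response, fits [nipals_plsr()], and classifies the factors.
#'
#' @param sites data frame holding factor columns and the response.
#' @param response column name, e.g. `"volatile_oil"`.
#' @param factors predictor column names (default x1..x10; the
#'   categorical soil layer x11 is excluded from regression by design).
#' @param ncomp number of components (default 2).
#' @return list with `model`, `classification`.
#' @export
plsr_fit <- function(sites, response, factors = paste0("x", 1:10), ncomp = 2) {
  miss <- setdiff(c(factors, response), names(sites))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  X <- standardize_columns(as.matrix(sites[factors]))
  y <- as.numeric(scale(sites[[response]]))
  model <- nipals_plsr(X, y, ncomp = ncomp)
  list(model = model,
       classification = classify_factors(model$vip, model$coefficients))
}
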