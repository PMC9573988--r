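# Keep only the `keep` largest-magnitude entries of w (hard sparsity),
# ties broken by earliest index for determinism.
.sparsify <- function(w, keep) {
  p <- length(w)
  if (is.null(keep) || keep >= p) return(w)
  ord <- order(-abs(w), seq_len(p))
  w[ord[(keep + 1):p]] <- 0
  w
}

#' Standardize a feature matrix to an omics block
#'
#' Centers every feature to mean zero and scales it to unit variance, the
#' form required by [plsFit()] and [buildNetwork()]. Features with zero
#' variance on the given samples are dropped with a warning.
#'
#' @param x numeric matrix, samples x features, no missing values; must have
#'   column names (feature ids) and row names (sample ids).
#' @return standardized numeric matrix.
#' @export
omicsBlock <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("omicsBlock: missing values not allowed")
  if (is.null(colnames(x)) || is.null(rownames(x)))
    stop("omicsBlock: feature and sample names required")
  s <- apply(x, 2, stats::sd)
  if (any(s == 0)) {
    warning("omicsBlock: dropping zero-variance features: ",
            paste(colnames(x)[s == 0], collapse = ", "))
    x <- x[, s > 0, drop = FALSE]
    s <- s[s > 0]
  }
  scale(x, center = TRUE, scale = s)[, , drop = FALSE]
}

#' Fit a (sparse) partial least squares model between two blocks
#'
#' Sequential NIPALS fit: for each component, paired weight vectors are
#' iterated to maximize the covariance between the X- and Y-projections.
#' Optional per-component hard sparsity retains only the keepX/keepY
#' largest-magnitude weight entries (zeroing the rest before
#' renormalization), giving the penalized variant used for sparse multi-
#' omics integration. After each component X is deflated by its fitted
#' loading and Y by its regression on the score (regression mode), which
#' makes the score vectors mutually orthogonal.
#'
#' @param X,Y standardized numeric matrices (see [omicsBlock()]) with the
#'   same samples in the same order.
#' @param ncomp number of components H (default 3); silently limited by the
#'   rank bound min(ncol(X), n - 1) with a warning, and truncated early if a
#'   block is exhausted.
#' @param keepX,keepY optional integer vectors (recycled to H) of variables
#'   kept per component; NULL keeps all.
#' @return A [PLSFit-class].
#' @export
plsFit <- function(X, Y, ncomp = 3L, keepX = NULL, keepY = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ncomp >= 1L)
  if (anyNA(X) || anyNA(Y)) stop("plsFit: missing values not allowed")
  n <- nrow(X)
  if (any(apply(X, 2, stats::sd) == 0) || any(apply(Y, 2, stats::sd) == 0))
    stop("plsFit: zero-variance feature in a block")
  Hmax <- min(ncol(X), n - 1L)
  H <- as.integer(ncomp)
  if (H > Hmax) {
    warning("plsFit: ncomp exceeds rank bound, truncated to ", Hmax)
    H <- Hmax
  }
  kx <- if (is.null(keepX)) rep(ncol(X), H) else rep_len(keepX, H)
  ky <- if (is.null(keepY)) rep(ncol(Y), H) else rep_len(keepY, H)
  Xc <- X; Yc <- Y
  scores <- matrix(0, n, H)
  xw <- matrix(0, ncol(X), H, dimnames = list(colnames(X), NULL))
  yw <- matrix(0, ncol(Y), H, dimnames = list(colnames(Y), NULL))
  xl <- xw; yl <- yw
  h <- 0L
  tol <- 1e-12
  for (comp in seq_len(H)) {
    if (sum(Xc^2) < tol || sum(Yc^2) < tol) break
    u <- Yc[, which.max(colSums(Yc^2))]
    tOld <- rep(0, n)
    w <- rep(0, ncol(X))
    tvec <- rep(0, n)
    for (it in seq_len(500L)) {
      w <- drop(crossprod(Xc, u))
      w <- .sparsify(w, kx[comp])
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      tvec <- drop(Xc %*% w)
      cv <- drop(crossprod(Yc, tvec))
      cv <- .sparsify(cv, ky[comp])
      ncv <- sqrt(sum(cv^2))
      if (ncv < tol) break
      cv <- cv / ncv
      u <- drop(Yc %*% cv)
      if (sqrt(sum((tvec - tOld)^2)) < 1e-12 * max(1, sqrt(sum(tvec^2))))
        break
      tOld <- tvec
    }
    if (sqrt(sum(w^2)) < tol || sum(tvec^2) < tol) break
    tt <- drop(crossprod(tvec))
    pvec <- drop(crossprod(Xc, tvec)) / tt
    bvec <- drop(crossprod(Yc, tvec)) / tt
    Xc <- Xc - tcrossprod(tvec, pvec)
    Yc <- Yc - tcrossprod(tvec, bvec)
    h <- comp
    scores[, comp] <- tvec
    xw[, comp] <- w
    yw[, comp] <- cv
    xl[, comp] <- pvec
    yl[, comp] <- bvec
  }
  if (h == 0L) stop("plsFit: no component could be extracted")
  if (h < H)
    warning("plsFit: component extraction stopped after ", h,
            " components (block exhausted)")
  idx <- seq_len(h)
  new("PLSFit", scores = scores[, idx, drop = FALSE],
      xWeights = xw[, idx, drop = FALSE],
      yWeights = yw[, idx, drop = FALSE],
      xLoadings = xl[, idx, drop = FALSE],
      yLoadings = yl[, idx, drop = FALSE],
      ncomp = h, keepX = as.integer(kx[idx]), keepY = as.integer(ky[idx]))
}

#' Component-based similarity (association) matrix
#'
#' Reconstructs the cross-block association from the latent scores:
#' \deqn{s_{ij} = \sum_{h=1}^{H} cor(x_i, t_h)\, cor(y_j, t_h)}
#' Because the scores are mutually orthogonal, Bessel's inequality plus
#' Cauchy-Schwarz guarantee |s_ij| <= 1. With full-rank components and no
#' sparsity, each centered feature lies in the span of the scores and s_ij
#' equals the Pearson correlation cor(x_i, y_j) exactly.
#'
#' @param fit A [PLSFit-class] produced from \code{X}, \code{Y}.
#' @param X,Y the standardized blocks the fit was produced from.
#' @return numeric matrix of s_ij, rows = X features, columns = Y features.
#' @export
similarityMatrix <- function(fit, X, Y) {
  stopifnot(is(fit, "PLSFit"))
  Tm <- fit@scores
  Cx <- suppressWarnings(stats::cor(X, Tm))
  Cy <- suppressWarnings(stats::cor(Y, Tm))
  Cx[is.na(Cx)] <- 0
  Cy[is.na(Cy)] <- 0
  s <- Cx %*% t(Cy)
  dimnames(s) <- list(colnames(X), colnames(Y))
  s
}

#' P-value of an association score
#'
#' Treats the component similarity s like a correlation coefficient:
#' two-sided p-value from \code{t = s * sqrt((n - 2) / (1 - s^2))} on
#' Student's t with n - 2 degrees of freedom; |s| = 1 gives p = 0.
#'
#' @param s numeric (scalar, vector or matrix) with |s| <= 1.
#' @param n sample count, at least 3.
#' @return p-values with the same shape as \code{s}.
#' @examples
#' edgeSignificance(0.1, 348)   # ~0.0624
#' @export
edgeSignificance <- function(s, n) {
  if (n < 3) stop("edgeSignificance: need at least 3 samples")
  if (any(abs(s) > 1 + 1e-9)) stop("edgeSignificance: |s| must be <= 1")
  s <- pmin(pmax(s, -1), 1)
  p <- ifelse(abs(s) >= 1, 0,
              2 * stats::pt(abs(s) * sqrt((n - 2) / (1 - s^2)),
                            df = n - 2, lower.tail = FALSE))
  if (is.matrix(s)) {
    p <- matrix(p, nrow(s), ncol(s), dimnames = dimnames(s))
  }
  p
}
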