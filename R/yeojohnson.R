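#' Yeo-Johnson power transformation
#'
#' The Yeo-Johnson family extends the Box-Cox power transform to variables
#' taking negative values, and is used here to Gaussianize metabolite
#' abundances before network integration:
#' \deqn{\psi(y,\lambda)=\begin{cases}
#'   ((y+1)^\lambda - 1)/\lambda          & y \ge 0, \lambda \ne 0\\
#'   \log(y+1)                             & y \ge 0, \lambda = 0\\
#'   -((-y+1)^{2-\lambda}-1)/(2-\lambda)   & y < 0, \lambda \ne 2\\
#'   -\log(-y+1)                           & y < 0, \lambda = 2
#' \end{cases}}
#' The transform is strictly increasing in y for every lambda.
#'
#' @param y numeric vector, finite.
#' @param lambda numeric(1), power parameter.
#' @return Transformed numeric vector of the same length.
#' @examples
#' yeoJohnson(c(-2, 0, 3), 1)    # identity
#' yeoJohnson(exp(1) - 1, 0)     # log(e) = 1
#' @export
yeoJohnson <- function(y, lambda) {
  if (any(!is.finite(y))) stop("yeoJohnson: input values must be finite")
  stopifnot(length(lambda) == 1L, is.finite(lambda))
  out <- numeric(length(y))
  pos <- y >= 0
  if (abs(lambda) > .Machine$double.eps^0.5) {
    out[pos] <- (exp(lambda * log1p(y[pos])) - 1) / lambda
  } else {
    out[pos] <- log1p(y[pos])
  }
  if (abs(lambda - 2) > .Machine$double.eps^0.5) {
    out[!pos] <- -(exp((2 - lambda) * log1p(-y[!pos])) - 1) / (2 - lambda)
  } else {
    out[!pos] <- -log1p(-y[!pos])
  }
  out
}

#' Inverse Yeo-Johnson transformation
#'
#' @param z numeric vector on the transformed scale.
#' @param lambda numeric(1), power parameter used by the forward transform.
#' @return numeric vector on the original scale. Values outside the
#'   attainable range of the forward transform (possible for lambda < 0 on
#'   the positive branch, lambda > 2 on the negative branch) are an error.
#' @export
yeoJohnsonInverse <- function(z, lambda) {
  stopifnot(length(lambda) == 1L, is.finite(lambda))
  out <- numeric(length(z))
  pos <- z >= 0
  if (abs(lambda) > .Machine$double.eps^0.5) {
    arg <- lambda * z[pos] + 1
    if (any(arg <= 0)) stop("yeoJohnsonInverse: value outside transform range")
    out[pos] <- expm1(log(arg) / lambda)
  } else {
    out[pos] <- expm1(z[pos])
  }
  if (abs(lambda - 2) > .Machine$double.eps^0.5) {
    arg <- -(2 - lambda) * z[!pos] + 1
    if (any(arg <= 0)) stop("yeoJohnsonInverse: value outside transform range")
    out[!pos] <- -expm1(log(arg) / (2 - lambda))
  } else {
    out[!pos] <- -expm1(-z[!pos])
  }
  out
}

# Gaussian profile log-likelihood of lambda (up to constants):
#   l(lambda) = -(n/2) log sigma^2(lambda) + (lambda-1) sum sign(y) log(|y|+1)
.yjLogLik <- function(y, lambda) {
  z <- yeoJohnson(y, lambda)
  n <- length(y)
  s2 <- sum((z - mean(z))^2) / n
  if (s2 <= 0) return(-Inf)
  -(n / 2) * log(s2) + (lambda - 1) * sum(sign(y) * log1p(abs(y)))
}

#' Fit the Yeo-Johnson transform by maximum likelihood
#'
#' Finds the power parameter lambda maximizing the Gaussian profile
#' log-likelihood over lambda in [-5, 5] by bounded scalar minimization
#' (tolerance 1e-6; near-exact ties resolved toward lambda = 1, the
#' identity), then records the mean and standard deviation of the
#' transformed values so that [applyYeoJohnson()] standardizes to zero mean
#' and unit variance.
#'
#' @param y numeric vector with at least 3 distinct finite values.
#' @return A [YeoJohnsonParams-class] object.
#' @examples
#' p <- fitYeoJohnson(rexp(200))
#' z <- applyYeoJohnson(rexp(200), p)
#' @export
fitYeoJohnson <- function(y) {
  if (any(!is.finite(y))) stop("fitYeoJohnson: input values must be finite")
  if (length(unique(y)) < 3L)
    stop("fitYeoJohnson: need at least 3 distinct values (constant or near-constant input)")
  opt <- stats::optimize(function(l) -.yjLogLik(y, l),
                         interval = c(-5, 5), tol = 1e-6)
  lambda <- opt$minimum
  # tie-break toward the identity transform
  if (-.yjLogLik(y, 1) <= opt$objective + 1e-8) lambda <- 1
  z <- yeoJohnson(y, lambda)
  s <- stats::sd(z)
  if (!is.finite(s) || s <= 0)
    stop("fitYeoJohnson: transformed values have zero variance")
  new("YeoJohnsonParams", lambda = lambda, center = mean(z), scale = s)
}

#' Apply fitted Yeo-Johnson parameters
#'
#' Transforms, centers and scales new values with the parameters learned by
#' [fitYeoJohnson()]. On the training data itself the result has mean 0 and
#' variance 1 (up to floating point).
#'
#' @param y numeric vector, finite.
#' @param params A [YeoJohnsonParams-class].
#' @return standardized transformed vector.
#' @export
applyYeoJohnson <- function(y, params) {
  stopifnot(is(params, "YeoJohnsonParams"))
  (yeoJohnson(y, params@lambda) - params@center) / params@scale
}
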