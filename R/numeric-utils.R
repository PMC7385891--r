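# Low-level numeric helpers shared across the package. All ordinal-variable
# machinery works on the latent standard-normal scale, so most of what lives
# here is normal-distribution plumbing.

# 64-point Gauss-Legendre nodes/weights on [-1, 1], computed once at load via
# the Golub-Welsch eigenvalue method (no quadrature package in Imports).
.gl64 <- local({
  n <- 64L
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1L, ]^2))
})

#' Bivariate standard normal CDF
#'
#' `P(X <= a, Y <= b)` for standard normal `(X, Y)` with correlation `rho`.
#' Uses the one-dimensional reduction
#' `integral over x <= a of dnorm(x) * pnorm((b - rho x)/sqrt(1-rho^2))`
#' evaluated by fixed 64-point Gauss-Legendre quadrature, vectorised over
#' `(a, b)` pairs. Accuracy is ample for likelihood work at `|rho| <= 0.999`.
#'
#' @param a,b upper limits (vectors, recycled to common length).
#' @param rho scalar correlation in `[-1, 1]`.
#' @return vector of probabilities.
#' @export
pbvnorm <- function(a, b, rho) {
  stopifnot(length(rho) == 1L, is.finite(rho), rho >= -1, rho <= 1)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (rho == 0) return(stats::pnorm(a) * stats::pnorm(b))
  if (rho == 1) return(stats::pnorm(pmin(a, b)))
  if (rho == -1) return(pmax(stats::pnorm(a) + stats::pnorm(b) - 1, 0))
  # integrate the narrower margin for better node placement
  swap <- abs(b) < abs(a)
  if (any(swap)) {
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  lo <- -8.5
  out <- numeric(n)
  live <- a > lo
  if (any(live)) {
    ai <- pmin(a[live], 8.5)
    bi <- b[live]
    s <- sqrt(1 - rho^2)
    panel <- function(l, u) {
      half <- pmax(u - l, 0) / 2
      mid <- (u + l) / 2
      z <- outer(half, .gl64$nodes) + mid
      f <- stats::dnorm(z) * stats::pnorm((bi - rho * z) / s)
      half * as.vector(f %*% .gl64$weights)
    }
    if (abs(rho) > 0.9) {
      # inner pnorm has a sharp transition near x = b/rho: split there
      x0 <- pmin(pmax(bi / rho, lo), ai)
      out[live] <- panel(rep(lo, length(ai)), x0) + panel(x0, ai)
    } else {
      out[live] <- panel(rep(lo, length(ai)), ai)
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Truncated standard normal draws by inverse CDF
#'
#' Draws `x ~ N(0,1)` conditioned on `lo < x <= hi`, elementwise. Rejection
#' free; used for the data-augmentation step of the Gibbs sampler.
#'
#' @param n number of draws (must equal length of `lo`/`hi` after recycling).
#' @param lo,hi interval bounds (may be `-Inf`/`Inf`).
#' @return numeric vector of draws.
#' @export
rtruncnorm_std <- function(n, lo, hi) {
  plo <- stats::pnorm(rep_len(lo, n))
  phi <- stats::pnorm(rep_len(hi, n))
  u <- plo + stats::runif(n) * (phi - plo)
  # clamp away from 0/1 so qnorm stays finite
  x <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  pmin(pmax(x, rep_len(lo, n) + 1e-10), rep_len(hi, n))
}

#' General truncated normal draws
#'
#' Draws from `N(mean, sd^2)` conditioned on `lo < x <= hi`, elementwise.
#'
#' @param n number of draws.
#' @param mean,sd location and scale (vectors, recycled).
#' @param lo,hi interval bounds.
#' @return numeric vector of draws.
#' @export
rtruncnorm <- function(n, mean, sd, lo, hi) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  rep_len(mean, n) + sd * rtruncnorm_std(n, (rep_len(lo, n) - mean) / sd,
                                         (rep_len(hi, n) - mean) / sd)
}

#' Mean of a truncated standard normal
#'
#' `E[X | lo < X <= hi]` for standard normal X; vectorised.
#' @param lo,hi interval bounds.
#' @export
truncnorm_mean <- function(lo, hi) {
  d <- stats::pnorm(hi) - stats::pnorm(lo)
  ifelse(d <= 0, 0, (stats::dnorm(lo) - stats::dnorm(hi)) / d)
}

# inverse-gamma draws: X ~ IG(shape, rate) iff 1/X ~ Gamma(shape, rate)
rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

# multivariate normal draw(s): one draw if mu is a vector, else row-wise for
# a mean matrix (common covariance)
rmvnorm_chol <- function(mu, Sigma) {
  L <- chol(Sigma)
  if (is.matrix(mu)) {
    z <- matrix(stats::rnorm(nrow(mu) * ncol(mu)), nrow(mu))
    mu + z %*% L
  } else {
    drop(mu + stats::rnorm(length(mu)) %*% L)
  }
}

#' Repair a symmetric matrix to positive definiteness
#'
#' Eigenvalue clipping: eigenvalues below `eps` are raised to `eps`. Used on
#' hybrid polychoric/polyserial matrices, which are not guaranteed PSD.
#'
#' @param S symmetric matrix.
#' @param eps clipping floor (default `1e-6`).
#' @return list with `mat` (repaired matrix, dimnames kept) and `delta`
#'   (Frobenius norm of the perturbation).
#' @export
psd_repair <- function(S, eps = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= eps)) return(list(mat = S, delta = 0))
  v <- pmax(e$values, eps)
  M <- e$vectors %*% (v * t(e$vectors))
  dimnames(M) <- dimnames(S)
  M <- (M + t(M)) / 2
  list(mat = M, delta = sqrt(sum((M - S)^2)))
}

# log multivariate gamma function
lmvgamma <- function(a, d) {
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

#' Wishart log-likelihood of a sample covariance matrix
#'
#' Log density of `W = (n-1) * S` under a Wishart with `n - 1` degrees of
#' freedom and scale `Sigma`, the parametrisation with
#' `E[W] = (n-1) Sigma`, i.e. `E[S] = Sigma`. This
#' convention is fixed package-wide so log-likelihood values are comparable
#' across fits and selection steps.
#'
#' @param S sample covariance matrix (d x d).
#' @param Sigma model-implied covariance matrix (d x d, positive definite).
#' @param n sample size (must exceed d).
#' @return scalar log density.
#' @export
wishart_loglik <- function(S, Sigma, n) {
  d <- nrow(S)
  stopifnot(ncol(S) == d, all(dim(Sigma) == d), n > d)
  nu <- n - 1
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) stop("implied covariance is not positive definite", call. = FALSE)
  W <- nu * S
  eW <- determinant(W, logarithm = TRUE)
  if (eW$sign <= 0) stop("sample covariance must be positive definite", call. = FALSE)
  logdetW <- as.numeric(eW$modulus)
  logdetV <- 2 * sum(log(diag(R)))                 # V = Sigma
  # V^{-1} W = Sigma^{-1} * nu * S
  trVinvW <- nu * sum(backsolve(R, backsolve(R, S, transpose = TRUE))[cbind(1:d, 1:d)])
  (nu - d - 1) / 2 * logdetW - trVinvW / 2 -
    nu * d / 2 * log(2) - nu / 2 * logdetV - lmvgamma(nu / 2, d)
}

# quiet logical: finite positive-definiteness test via chol
is_pd <- function(S) !is.null(tryCatch(chol(S), error = function(e) NULL))
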