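#' Symmetric matrix power via eigendecomposition
#'
#' Computes `M^exponent` for a symmetric positive semi-definite matrix through
#' its spectral decomposition, clipping small negative eigenvalues (round-off)
#' at zero. The two exponents needed for standardization and for the
#' mean-augmented statistic are `-1/2` (inverse square root, used to whiten an
#' expression block) and `+1/2` (the unique symmetric PSD square root).
#'
#' @param m A symmetric numeric matrix (checked to relative tolerance 1e-10).
#' @param exponent Real exponent; `-1/2` and `1/2` are the supported use
#'   cases. Negative exponents require `m` to be numerically full rank.
#' @param rank_tol Relative eigenvalue tolerance: eigenvalues below
#'   `rank_tol * max(eigenvalue)` are treated as zero.
#' @return A symmetric matrix of the same dimension.
#' @examples
#' s <- crossprod(matrix(rnorm(30), 10, 3))
#' r <- sym_matrix_power(s, 1/2)
#' max(abs(r %*% r - s))   # ~ 1e-12
#' @export
sym_matrix_power <- function(m, exponent, rank_tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("'m' must be a square matrix", call. = FALSE)
  }
  scale <- max(1, max(abs(m)))
  if (max(abs(m - t(m))) > 1e-10 * scale) {
    stop("'m' is not symmetric (relative tolerance 1e-10)", call. = FALSE)
  }
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ev <- e$values
  thresh <- rank_tol * max(ev, 0)
  if (exponent < 0) {
    r <- sum(ev > thresh)
    if (r < length(ev)) {
      stop(sprintf(
        "matrix is singular at relative tolerance %g (rank %d < %d); %s",
        rank_tol, r, length(ev),
        "use shrinkage standardization or the unstandardized statistics"
      ), call. = FALSE)
    }
  }
  ev <- pmax(ev, 0)
  pow <- ifelse(ev > 0, ev^exponent, 0)
  out <- e$vectors %*% (pow * t(e$vectors))
  (out + t(out)) / 2
}

#' Analytic shrinkage covariance estimate
#'
#' Schaefer-Strimmer style shrinkage of the sample correlation matrix toward
#' the identity (equivalently, of the covariance toward its own diagonal),
#' with the shrinkage intensity chosen by the closed-form estimate
#' \deqn{\lambda = \sum_{i \ne j} \widehat{Var}(r_{ij}) / \sum_{i \ne j} r_{ij}^2,}
#' clipped to `[0, 1]`. The result is positive definite whenever
#' `lambda > 0` and every gene has positive variance, which makes it a usable
#' standardization target when the sample covariance is singular (p >= n).
#'
#' @param x Numeric matrix, samples in rows, genes in columns (n x p), n >= 3.
#' @param divisor `"n"` (maximum likelihood) or `"n-1"` for the variances on
#'   the diagonal of the returned covariance; the intensity estimate itself
#'   always uses the standard unbiased-correlation formulas.
#' @return A list with components `sigma` (p x p shrunk covariance) and
#'   `lambda` (the intensity actually used).
#' @export
shrinkage_cov <- function(x, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 3) stop("shrinkage covariance needs at least 3 samples", call. = FALSE)
  v <- apply(x, 2, stats::var)                     # divisor n-1
  if (any(v <= 0)) {
    stop(sprintf("gene(s) with zero variance: %s",
                 paste(colnames(x)[v <= 0], collapse = ", ")), call. = FALSE)
  }
  xs <- scale(x, center = TRUE, scale = sqrt(v))
  r <- crossprod(xs) / (n - 1)
  # var-hat of r_ij from the products w_kij = xs_ki * xs_kj:
  #   n / (n-1)^3 * sum_k (w_kij - mean_k w_kij)^2
  m1 <- crossprod(xs) / n
  m2 <- crossprod(xs^2) / n
  var_r <- n^2 / (n - 1)^3 * (m2 - m1^2)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom > 0) sum(var_r[off]) / denom else 1
  lambda <- min(1, max(0, lambda))
  r_shrunk <- (1 - lambda) * r
  diag(r_shrunk) <- 1
  vv <- if (divisor == "n") v * (n - 1) / n else v
  sdv <- sqrt(vv)
  sigma <- r_shrunk * tcrossprod(sdv)
  list(sigma = sigma, lambda = lambda)
}

# ML (divisor n) or unbiased (n-1) covariance of a samples-x-genes matrix.
.pooled_cov <- function(x, divisor = "n") {
  n <- nrow(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr, check.margin = FALSE)
  div <- if (divisor == "n") n else n - 1L
  crossprod(xc) / div
}
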