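#' Standardize an expression block
#'
#' Centers the samples-by-genes matrix and, depending on `mode`, whitens it so
#' that the pooled covariance is (close to) the identity. Row `i` of the
#' result is `W (x_i - xbar)` where `W` is the transform:
#'
#' * `"exact"` — `W = S^{-1/2}` with `S` the pooled sample covariance; the
#'   standardized data then have pooled covariance exactly `I_p`. Requires a
#'   numerically nonsingular `S` (in practice `n > p`).
#' * `"shrinkage"` — `W = S*^{-1/2}` with `S*` the analytic shrinkage estimate
#'   from [shrinkage_cov()]; always available, pooled covariance of the result
#'   is approximately `I_p`.
#' * `"identity"` (alias `"none"`) — `W = I`, centering only; used by the
#'   unstandardized statistics T* and V*.
#' * `"auto"` — `"exact"` when the pooled covariance is numerically
#'   nonsingular, otherwise `"shrinkage"` (a message records the fallback).
#'
#' @param x Numeric matrix, samples in rows, genes in columns; no missing
#'   values.
#' @param mode One of `"auto"`, `"exact"`, `"shrinkage"`, `"identity"`,
#'   `"none"`.
#' @param divisor Covariance divisor convention, `"n"` (default) or `"n-1"`,
#'   applied consistently to the pooled and (downstream) within-slice
#'   covariances.
#' @param quiet Suppress the message emitted when `"auto"` falls back to
#'   shrinkage.
#' @return An object of class `"sdr_standardized"`: a list with `values`
#'   (n x p centered/whitened matrix), `transform`, `center`, `mode` (the mode
#'   actually used), `pooled_cov` (`I_p` for exact/shrinkage, the sample
#'   covariance for identity), `divisor`, and `lambda` (shrinkage intensity,
#'   `NA` otherwise).
#' @export
standardize_expression <- function(x,
                                   mode = c("auto", "exact", "shrinkage",
                                            "identity", "none"),
                                   divisor = c("n", "n-1"),
                                   quiet = FALSE) {
  mode <- match.arg(mode)
  divisor <- match.arg(divisor)
  x <- .check_expression(x)
  n <- nrow(x)
  p <- ncol(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr, check.margin = FALSE)
  s <- crossprod(xc) / (if (divisor == "n") n else n - 1L)
  lambda <- NA_real_

  if (mode == "auto") {
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    mode <- if (min(ev) > 1e-10 * max(ev, 0)) "exact" else "shrinkage"
    if (mode == "shrinkage" && !quiet) {
      message("pooled covariance numerically singular (p >= n?); ",
              "using shrinkage standardization")
    }
  }
  if (mode == "none") mode <- "identity"

  if (mode == "exact") {
    w <- tryCatch(sym_matrix_power(s, -1 / 2), error = function(e) {
      stop("exact standardization failed: ", conditionMessage(e),
           call. = FALSE)
    })
    values <- xc %*% w
    pooled <- diag(p)
  } else if (mode == "shrinkage") {
    sh <- shrinkage_cov(x, divisor = divisor)
    lambda <- sh$lambda
    w <- sym_matrix_power(sh$sigma, -1 / 2)
    values <- xc %*% w
    pooled <- diag(p)
  } else {
    w <- diag(p)
    values <- xc
    pooled <- s
  }
  dimnames(values) <- dimnames(x)
  structure(
    list(values = values, transform = w, center = ctr, mode = mode,
         pooled_cov = pooled, divisor = divisor, lambda = lambda),
    class = "sdr_standardized"
  )
}

# Validate an expression block: numeric matrix, n >= 2, p >= 1, complete,
# unique ids when named. Accepts data.frames of numeric columns.
.check_expression <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression data must be a numeric matrix (samples x genes)",
         call. = FALSE)
  }
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (ncol(x) < 1L) stop("need at least 1 gene", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)
    bad <- utils::head(bad, 5L)
    stop("missing/non-finite expression values at (sample, gene): ",
         paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " "),
         call. = FALSE)
  }
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x))) {
    stop("duplicate gene identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x))) {
    stop("duplicate sample identifiers", call. = FALSE)
  }
  x
}
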