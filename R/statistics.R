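#' Within-slice first and second moments
#'
#' Computes the per-slice mean vectors and within-slice covariance matrices of
#' a (standardized or merely centered) expression block, with the same divisor
#' convention as the pooled covariance, so that a single slice containing the
#' whole sample reproduces the pooled moments exactly.
#'
#' @param z An `"sdr_standardized"` object from [standardize_expression()], or
#'   a plain centered numeric matrix (then taken as identity mode).
#' @param partition An `"sdr_slices"` object with one label per sample.
#' @return An object of class `"sdr_slice_moments"`: list with `means`
#'   (H x p), `covariances` (p x p x H array), `proportions`, `sizes`, `H`,
#'   `pooled_cov`, `mode` and `divisor`.
#' @export
slice_moments <- function(z, partition) {
  if (is.matrix(z)) {
    z <- structure(list(values = z, mode = "identity",
                        pooled_cov = .pooled_cov(z), divisor = "n"),
                   class = "sdr_standardized")
  }
  stopifnot(inherits(z, "sdr_standardized"), inherits(partition, "sdr_slices"))
  zm <- z$values
  n <- nrow(zm)
  p <- ncol(zm)
  if (length(partition$labels) != n) {
    stop("partition labels do not match the number of samples", call. = FALSE)
  }
  if (any(partition$sizes < 2L)) {
    stop("degenerate slice of size < 2", call. = FALSE)
  }
  H <- partition$H
  means <- matrix(0, H, p)
  covs <- array(0, c(p, p, H))
  idx <- split(seq_len(n), partition$labels)
  for (s in seq_len(H)) {
    zs <- zm[idx[[s]], , drop = FALSE]
    ns <- nrow(zs)
    ms <- colMeans(zs)
    zc <- sweep(zs, 2L, ms, check.margin = FALSE)
    div <- if (z$divisor == "n") ns else ns - 1L
    means[s, ] <- ms
    covs[, , s] <- crossprod(zc) / div
  }
  structure(
    list(means = means, covariances = covs,
         proportions = partition$proportions, sizes = partition$sizes,
         H = H, pooled_cov = z$pooled_cov, mode = z$mode,
         divisor = z$divisor),
    class = "sdr_slice_moments"
  )
}

#' SAVE marginal-dimension statistic T
#'
#' The sliced average variance estimation test statistic for the null of no
#' association (structural dimension zero),
#' \deqn{T = \sum_s \hat p_s \, \mathrm{tr}(\hat\Sigma_{Z|s} - I_p)^2
#'         = \sum_s \hat p_s \sum_i \sum_j (\hat\sigma_{ij|s} - \sigma_{ij})^2,}
#' together with its per-gene decomposition
#' \eqn{T_i = \sum_s \hat p_s \sum_j (\hat\sigma_{ij|s} - \sigma_{ij})^2},
#' which satisfies \eqn{\sum_i T_i = T}.
#'
#' @param m An `"sdr_slice_moments"` object computed from standardized data
#'   (pooled covariance equal to the identity).
#' @return List with `value` (nonnegative scalar) and `gene_contributions`
#'   (length-p vector summing to `value`).
#' @export
statistic_T <- function(m) {
  .check_moments(m)
  p <- ncol(m$means)
  if (max(abs(m$pooled_cov - diag(p))) > 1e-6) {
    stop("slice moments were not computed from standardized data ",
         "(pooled covariance differs from the identity); use statistic_T_star",
         call. = FALSE)
  }
  .stat_T_core(m, diag(p))
}

#' Unstandardized statistic T*
#'
#' Variant of [statistic_T()] that skips standardization: within-slice
#' covariances of the raw (centered) expressions are compared with the pooled
#' sample covariance,
#' \eqn{T^* = \sum_s \hat p_s \, \mathrm{tr}(\hat\Sigma_{X|s} - \hat\Sigma_X)^2}.
#' Useful when the pooled covariance is singular (p >= n).
#'
#' @param m Slice moments computed in identity (centering-only) mode.
#' @return List with `value` and `gene_contributions`.
#' @export
statistic_T_star <- function(m) {
  .check_moments(m)
  .stat_T_core(m, m$pooled_cov)
}

.stat_T_core <- function(m, pooled) {
  p <- ncol(m$means)
  gene <- numeric(p)
  for (s in seq_len(m$H)) {
    d <- m$covariances[, , s] - pooled
    gene <- gene + m$proportions[s] * rowSums(d * d)
  }
  list(value = sum(gene), gene_contributions = gene)
}

#' Mean-augmented SAVE statistic V
#'
#' Modification of [statistic_T()] that puts more weight on mean perturbation
#' across slices:
#' \deqn{V = \sum_s \hat p_s \, \mathrm{tr}\{(\hat\Sigma_{Z|s}^{1/2} - I_p)^2
#'           + \bar Z_s \bar Z_s^T\},}
#' where \eqn{\mathrm{tr}(\bar Z_s \bar Z_s^T) = \lVert \bar Z_s \rVert^2}.
#' Within-slice covariance square roots are taken after clipping round-off
#' negative eigenvalues at zero.
#'
#' @inheritParams statistic_T
#' @return Nonnegative scalar.
#' @export
statistic_V <- function(m) {
  .check_moments(m)
  p <- ncol(m$means)
  if (max(abs(m$pooled_cov - diag(p))) > 1e-6) {
    stop("slice moments were not computed from standardized data ",
         "(pooled covariance differs from the identity); use statistic_V_star",
         call. = FALSE)
  }
  v <- 0
  for (s in seq_len(m$H)) {
    ev <- .psd_eigenvalues(m$covariances[, , s])
    v <- v + m$proportions[s] *
      (sum((sqrt(ev) - 1)^2) + sum(m$means[s, ]^2))
  }
  v
}

#' Unstandardized statistic V*
#'
#' Analogue of [statistic_V()] without standardization: pooled quantities
#' replace the identity and the zero vector,
#' \deqn{V^* = \sum_s \hat p_s \, \mathrm{tr}\{(\hat\Sigma_{X|s}^{1/2} -
#'   \hat\Sigma_X^{1/2})^2 + (\bar X_s - \bar X)(\bar X_s - \bar X)^T\}.}
#'
#' @param m Slice moments computed in identity (centering-only) mode; the
#'   stored means are then already the centered slice means
#'   \eqn{\bar X_s - \bar X}.
#' @return Nonnegative scalar.
#' @export
statistic_V_star <- function(m) {
  .check_moments(m)
  pooled_sqrt <- sym_matrix_power(m$pooled_cov, 1 / 2)
  v <- 0
  for (s in seq_len(m$H)) {
    a <- .psd_sqrt(m$covariances[, , s])
    d <- a - pooled_sqrt
    v <- v + m$proportions[s] * (sum(d * d) + sum(m$means[s, ]^2))
  }
  v
}

.check_moments <- function(m) {
  if (!inherits(m, "sdr_slice_moments")) {
    stop("expected an 'sdr_slice_moments' object", call. = FALSE)
  }
  for (s in seq_len(m$H)) {
    cs <- m$covariances[, , s]
    if (max(abs(cs - t(cs))) > 1e-12 * max(1, max(abs(cs)))) {
      stop("within-slice covariance is not symmetric", call. = FALSE)
    }
  }
  invisible(m)
}

# Eigenvalues of a PSD matrix, clipped at zero; violations beyond round-off
# are an error.
.psd_eigenvalues <- function(cs) {
  ev <- eigen(cs, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * max(1, abs(ev[1]))
  if (min(ev) < -tol) {
    stop("within-slice covariance has a substantially negative eigenvalue",
         call. = FALSE)
  }
  pmax(ev, 0)
}

.psd_sqrt <- function(cs) {
  e <- eigen((cs + t(cs)) / 2, symmetric = TRUE)
  tol <- 1e-10 * max(1, abs(e$values[1]))
  if (min(e$values) < -tol) {
    stop("within-slice covariance has a substantially negative eigenvalue",
         call. = FALSE)
  }
  ev <- pmax(e$values, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

# ---- fast path used by the permutation engine ------------------------------
#
# Computes any subset of the four statistics for one label assignment without
# building moments objects. `pooled` is the comparison matrix (identity for
# T/V on standardized data, the pooled sample covariance for T*/V*);
# `pooled_is_identity` enables the Gram-matrix eigenvalue shortcut for V:
# the nonzero eigenvalues of crossprod(Zc)/div equal those of
# tcrossprod(Zc)/div, and each exactly-zero eigenvalue contributes
# (sqrt(0)-1)^2 = 1 to tr((S^{1/2}-I)^2).
.stats_for_labels <- function(zm, labels, H, proportions, stats,
                              pooled, pooled_sqrt = NULL,
                              divisor = "n", gene_level = FALSE) {
  p <- ncol(zm)
  n <- nrow(zm)
  pooled_is_identity <- is.null(dim(pooled))  # pooled given as NULL => I
  want_T <- any(stats %in% c("T", "Tstar"))
  want_V <- "V" %in% stats
  want_Vs <- "Vstar" %in% stats
  tval <- 0
  vval <- 0
  vsval <- 0
  gene <- if (gene_level) numeric(p) else NULL
  idx <- split(seq_len(n), labels)
  for (s in seq_len(H)) {
    zs <- zm[idx[[s]], , drop = FALSE]
    ns <- nrow(zs)
    ms <- colMeans(zs)
    zc <- sweep(zs, 2L, ms, check.margin = FALSE)
    div <- if (divisor == "n") ns else ns - 1L
    ph <- proportions[s]
    cs <- NULL
    if (want_T || want_Vs || (want_V && !pooled_is_identity)) {
      cs <- crossprod(zc) / div
    }
    if (want_T) {
      d <- if (pooled_is_identity) {
        dd <- cs
        diag(dd) <- diag(dd) - 1
        dd
      } else cs - pooled
      if (gene_level) {
        g <- rowSums(d * d)
        gene <- gene + ph * g
        tval <- tval + ph * sum(g)
      } else {
        tval <- tval + ph * sum(d * d)
      }
    }
    if (want_V) {
      if (pooled_is_identity && p > ns) {
        ev <- eigen(tcrossprod(zc) / div, symmetric = TRUE,
                    only.values = TRUE)$values
        ev <- pmax(ev, 0)
        trpart <- sum((sqrt(ev) - 1)^2) + (p - ns)
      } else if (pooled_is_identity) {
        ev <- pmax(eigen(cs %||% (crossprod(zc) / div), symmetric = TRUE,
                         only.values = TRUE)$values, 0)
        trpart <- sum((sqrt(ev) - 1)^2)
      } else {
        a <- .psd_sqrt(cs)
        dmat <- a - pooled_sqrt
        trpart <- sum(dmat * dmat)
      }
      vval <- vval + ph * (trpart + sum(ms^2))
    }
    if (want_Vs) {
      a <- .psd_sqrt(cs)
      dmat <- a - pooled_sqrt
      vsval <- vsval + ph * (sum(dmat * dmat) + sum(ms^2))
    }
  }
  out <- c(T = if ("T" %in% stats) tval else NA_real_,
           Tstar = if ("Tstar" %in% stats) tval else NA_real_,
           V = if (want_V) vval else NA_real_,
           Vstar = if (want_Vs) vsval else NA_real_)
  list(values = out[stats], gene = gene)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
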