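#' Simulation scenarios for SDR gene set tests
#'
#' Constructors for the three multivariate-normal study designs used to
#' calibrate and benchmark the tests: a two-group (binary phenotype)
#' differential-coexpression design, a three-class block-diagonal design, and
#' a continuous-phenotype regression design with linear or exponential link.
#' Each returns a classed scenario object; draw datasets from it with
#' [simulate()] and estimate rejection rates with [estimate_size_power()].
#'
#' @details
#' **Binary design.** Two groups of `n/2` samples from `MVN(0, Sigma_1)` and
#' `MVN(0, Sigma_2)`. `Sigma_1` is the identity (homogeneous) or a diagonal
#' matrix of variances drawn from `U(1, 5)` (heterogeneous). Under the null
#' `Sigma_2 = Sigma_1`; under the alternative the first `gamma * p` genes are
#' equi-correlated at `rho` in group 2 and, in the heterogeneous case, group-2
#' variances are redrawn from `U(1, 5)` independently of group 1. Covariances
#' are assembled as `D^{1/2} R D^{1/2}` (variances first, correlation matrix,
#' then scaling).
#'
#' **Three-class design.** Three groups of `n/3` samples. All variances are
#' `U(1, 5)` draws; `Sigma_1` is diagonal while `Sigma_2` and `Sigma_3` are
#' block-diagonal with four blocks of size `p/4`; within every block the first
#' `gamma * p/4` genes are equi-correlated at `rho` in `Sigma_2` and the last
#' `gamma * p/4` in `Sigma_3`, so the coexpressed positions differ between the
#' two non-null classes.
#'
#' **Continuous design.** `X ~ MVN(0, Sigma_X)` with unit variances, an
#' equi-correlated block on genes `1..p1`, an AR-type block
#' (`rho^|i-j|`) on genes `p1+1..2p1`, and zeros elsewhere. Under the null
#' `Y ~ N(0, 1)` independent of `X`; under the alternatives
#' `Y | x ~ N(x'beta, 1)` (linear) or `N(exp(x'beta), 1)` (nonlinear), where
#' `beta` has ten nonzero entries: five positions drawn at random from the
#' first block with `beta_j ~ N(nu, |nu|)` (variance `|nu|`) and five from the
#' second block with `beta_j ~ N(-nu, |nu|)`; `nu = 0` gives `beta = 0`
#' exactly. The selected positions are redrawn per replicate and recorded in
#' the `beta` attribute of the phenotype.
#'
#' @param n Total sample size (even for binary, divisible by 3 for
#'   three-class).
#' @param p Gene set size (divisible by 4 for three-class).
#' @param variance `"homogeneous"` or `"heterogeneous"` group-1 variances
#'   (binary design).
#' @param gamma Proportion of coexpressed genes, in `(0, 1]`.
#' @param rho Inter-gene correlation, in `[0, 1)`.
#' @param null If `TRUE`, the binary design uses `Sigma_2 = Sigma_1` (no
#'   association).
#' @param p1 Size of the correlated blocks in the continuous design
#'   (`2 * p1 <= p`).
#' @param link `"null"`, `"linear"` or `"nonlinear"` phenotype model
#'   (continuous design).
#' @param nu Effect scale in `[0, 2]` for the regression coefficients.
#' @return An object of class `c("sdr_scenario_binary", "sdr_scenario")`
#'   (respectively `_threeclass`, `_continuous`).
#' @name sdr_scenarios
NULL

#' @rdname sdr_scenarios
#' @export
binary_scenario <- function(n = 20, p = 20,
                            variance = c("homogeneous", "heterogeneous"),
                            gamma = 1, rho = 0, null = FALSE) {
  variance <- match.arg(variance)
  n <- as.integer(n); p <- as.integer(p)
  if (n < 4L || n %% 2L != 0L) stop("n must be even and >= 4", call. = FALSE)
  if (p < 1L) stop("p must be >= 1", call. = FALSE)
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  structure(list(n = n, p = p, variance = variance, gamma = gamma,
                 rho = rho, null = isTRUE(null)),
            class = c("sdr_scenario_binary", "sdr_scenario"))
}

#' @rdname sdr_scenarios
#' @export
threeclass_scenario <- function(n = 30, p = 20, gamma = 0.8, rho = 0.5) {
  n <- as.integer(n); p <- as.integer(p)
  if (n < 6L || n %% 3L != 0L) {
    stop("n must be divisible by 3 and >= 6", call. = FALSE)
  }
  if (p %% 4L != 0L) stop("p must be divisible by 4", call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  structure(list(n = n, p = p, gamma = gamma, rho = rho),
            class = c("sdr_scenario_threeclass", "sdr_scenario"))
}

#' @rdname sdr_scenarios
#' @export
continuous_scenario <- function(n = 20, p = 20, p1 = 5, rho = 0,
                                link = c("null", "linear", "nonlinear"),
                                nu = 0) {
  link <- match.arg(link)
  n <- as.integer(n); p <- as.integer(p); p1 <- as.integer(p1)
  if (2L * p1 > p) stop("need 2 * p1 <= p", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (nu < 0 || nu > 2) stop("nu must be in [0, 2]", call. = FALSE)
  structure(list(n = n, p = p, p1 = p1, rho = rho, link = link, nu = nu),
            class = c("sdr_scenario_continuous", "sdr_scenario"))
}

#' @export
print.sdr_scenario <- function(x, ...) {
  kind <- sub("sdr_scenario_", "", class(x)[1])
  cat("SDR simulation scenario:", kind, "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

# ---- covariance builders ---------------------------------------------------

# Equi-correlation matrix on the first k of p genes (zeros elsewhere
# off-diagonal), scaled by variances: Sigma = D^{1/2} R D^{1/2}.
.equicorr_sigma <- function(p, k, rho, variances) {
  r <- diag(p)
  if (k >= 2L && rho != 0) {
    r[seq_len(k), seq_len(k)] <- rho
    diag(r) <- 1
  }
  sdv <- sqrt(variances)
  r * tcrossprod(sdv)
}

# Block-diagonal correlation for the three-class design: four blocks of size
# p/4; within each block positions `pos` (indices within the block) are
# equi-correlated at rho.
.block_sigma <- function(p, pos, rho, variances) {
  r <- diag(p)
  bs <- p %/% 4L
  for (b in seq_len(4L)) {
    off <- (b - 1L) * bs
    idx <- off + pos
    if (length(idx) >= 2L && rho != 0) {
      r[idx, idx] <- rho
      diag(r) <- 1
    }
  }
  sdv <- sqrt(variances)
  r * tcrossprod(sdv)
}

# Piecewise correlation of the continuous design: unit diagonal,
# equi-correlated genes 1..p1, AR(rho^|i-j|) genes p1+1..2p1, zero elsewhere.
.continuous_sigma <- function(p, p1, rho) {
  s <- diag(p)
  if (p1 >= 2L && rho != 0) {
    b1 <- seq_len(p1)
    s[b1, b1] <- rho
    b2 <- (p1 + 1L):(2L * p1)
    s[b2, b2] <- rho^abs(outer(b2, b2, `-`))
    diag(s) <- 1
  }
  s
}

# MVN draw via Cholesky; errors if sigma is not positive definite.
.rmvn <- function(n, sigma) {
  r <- tryCatch(chol(sigma), error = function(e) {
    stop("scenario covariance is not positive definite", call. = FALSE)
  })
  matrix(stats::rnorm(n * ncol(sigma)), n, ncol(sigma)) %*% r
}

# ---- simulate() methods ----------------------------------------------------

#' Draw a dataset from a simulation scenario
#'
#' `simulate()` methods for the scenario objects of [sdr_scenarios]. One
#' replicate is a list with components `x` (expression matrix, samples by
#' genes) and `y` (phenotype vector); the covariance matrices actually used
#' are attached as the `"sigma"` attribute and, for the continuous design, the
#' regression coefficients as the `"beta"` attribute.
#'
#' @param object A scenario object.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed; `NULL` continues the session RNG stream.
#' @param ... Unused.
#' @return For `nsim = 1` a single replicate list; otherwise a list of
#'   replicates.
#' @export
simulate.sdr_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  reps <- replicate(nsim, .simulate_one(object), simplify = FALSE)
  if (nsim == 1L) reps[[1L]] else reps
}

.simulate_one <- function(sc) {
  if (inherits(sc, "sdr_scenario_binary")) return(.simulate_binary(sc))
  if (inherits(sc, "sdr_scenario_threeclass")) return(.simulate_threeclass(sc))
  if (inherits(sc, "sdr_scenario_continuous")) return(.simulate_continuous(sc))
  stop("unknown scenario class", call. = FALSE)
}

.simulate_binary <- function(sc) {
  p <- sc$p
  half <- sc$n %/% 2L
  v1 <- if (sc$variance == "homogeneous") rep(1, p) else stats::runif(p, 1, 5)
  sigma1 <- diag(v1, nrow = p)
  if (sc$null) {
    sigma2 <- sigma1
  } else {
    v2 <- if (sc$variance == "homogeneous") rep(1, p) else stats::runif(p, 1, 5)
    k <- as.integer(round(sc$gamma * p))
    sigma2 <- .equicorr_sigma(p, k, sc$rho, v2)
  }
  x <- rbind(.rmvn(half, sigma1), .rmvn(half, sigma2))
  y <- rep(c(1L, 2L), each = half)
  .dataset(x, y, sigma = list(sigma1, sigma2))
}

.simulate_threeclass <- function(sc) {
  p <- sc$p
  third <- sc$n %/% 3L
  bs <- p %/% 4L
  k <- as.integer(round(sc$gamma * bs))
  sigma1 <- diag(stats::runif(p, 1, 5), nrow = p)
  pos2 <- if (k >= 1L) seq_len(k) else integer()
  pos3 <- if (k >= 1L) (bs - k + 1L):bs else integer()
  sigma2 <- .block_sigma(p, pos2, sc$rho, stats::runif(p, 1, 5))
  sigma3 <- .block_sigma(p, pos3, sc$rho, stats::runif(p, 1, 5))
  x <- rbind(.rmvn(third, sigma1), .rmvn(third, sigma2), .rmvn(third, sigma3))
  y <- rep(1:3, each = third)
  .dataset(x, y, sigma = list(sigma1, sigma2, sigma3))
}

.simulate_continuous <- function(sc) {
  sigma <- .continuous_sigma(sc$p, sc$p1, sc$rho)
  x <- .rmvn(sc$n, sigma)
  beta <- numeric(sc$p)
  if (sc$link != "null" && sc$nu > 0) {
    j1 <- sample(seq_len(sc$p1), 5L)
    j2 <- sample((sc$p1 + 1L):(2L * sc$p1), 5L)
    beta[j1] <- stats::rnorm(5L, mean = sc$nu, sd = sqrt(sc$nu))
    beta[j2] <- stats::rnorm(5L, mean = -sc$nu, sd = sqrt(sc$nu))
  }
  eta <- drop(x %*% beta)
  y <- switch(sc$link,
              null = stats::rnorm(sc$n),
              linear = stats::rnorm(sc$n, mean = eta),
              nonlinear = stats::rnorm(sc$n, mean = exp(eta)))
  out <- .dataset(x, y, sigma = list(sigma))
  attr(out$y, "beta") <- beta
  out
}

.dataset <- function(x, y, sigma) {
  colnames(x) <- paste0("g", seq_len(ncol(x)))
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  names(y) <- rownames(x)
  out <- list(x = x, y = y)
  attr(out, "sigma") <- sigma
  out
}

# ---- size / power harness --------------------------------------------------

#' Empirical type I error / power of the SDR tests
#'
#' Replicates a scenario `n_datasets` times, runs the permutation test(s) on
#' every replicate, and reports the empirical rejection rate at level `alpha`
#' with its binomial standard error. Several statistics can be evaluated on
#' the same replicates (and the same permutation streams), which mirrors how
#' competing rows of a calibration table are produced.
#'
#' @param scenario A scenario object from [sdr_scenarios].
#' @param statistic Character vector among `"T"`, `"V"`, `"Tstar"`, `"Vstar"`.
#' @param n_datasets Number of replicate datasets (>= 100 recommended).
#' @param n_perm Permutations per dataset.
#' @param alpha Significance level(s).
#' @param seed Master seed; per-replicate data and permutation seeds are
#'   derived from it, so results are reproducible and independent of any
#'   chunking.
#' @param slices,standardize,divisor Passed to the test; see [sdr_test()].
#' @return An object of class `"sdr_power"`: a data frame with one row per
#'   (statistic, alpha) holding `rejection_rate` and `se`, plus the matrix of
#'   p-values in attribute `"p_values"`.
#' @examples
#' sc <- binary_scenario(n = 20, p = 5, null = TRUE)
#' estimate_size_power(sc, "T", n_datasets = 20, n_perm = 99, seed = 1)
#' @export
estimate_size_power <- function(scenario, statistic = "T",
                                n_datasets = 1000L, n_perm = 1000L,
                                alpha = 0.05, seed = 1L, slices = NULL,
                                standardize = "auto",
                                divisor = c("n", "n-1")) {
  stopifnot(inherits(scenario, "sdr_scenario"))
  divisor <- match.arg(divisor)
  statistic <- match.arg(statistic, c("T", "V", "Tstar", "Vstar"),
                         several.ok = TRUE)
  n_datasets <- as.integer(n_datasets)
  starred <- all(statistic %in% c("Tstar", "Vstar"))
  if (!starred && any(statistic %in% c("Tstar", "Vstar"))) {
    stop("cannot mix standardized and starred statistics in one run",
         call. = FALSE)
  }
  mode <- if (starred) "none" else standardize

  set.seed(seed)
  seeds <- matrix(sample.int(2147483646L, 2L * n_datasets), ncol = 2L)
  ptype <- if (inherits(scenario, "sdr_scenario_continuous"))
    "continuous" else "categorical"

  pvals <- matrix(NA_real_, n_datasets, length(statistic),
                  dimnames = list(NULL, statistic))
  for (d in seq_len(n_datasets)) {
    dat <- simulate(scenario, seed = seeds[d, 1L])
    part <- make_slices(dat$y, slices = slices, type = ptype, quiet = TRUE)
    std <- standardize_expression(dat$x, mode = mode, divisor = divisor,
                                  quiet = TRUE)
    eng <- .perm_engine(std, part, stats = statistic, n_perm = n_perm,
                        seed = seeds[d, 2L], gene_level = FALSE)
    for (st in statistic) {
      obs <- eng$observed[[st]]
      pvals[d, st] <- (1 + sum(eng$perm[, st] >= obs)) / (n_perm + 1)
    }
  }
  grid <- expand.grid(statistic = statistic, alpha = alpha,
                      stringsAsFactors = FALSE)
  grid$rejection_rate <- mapply(function(st, a) mean(pvals[, st] <= a),
                                grid$statistic, grid$alpha)
  grid$se <- sqrt(grid$rejection_rate * (1 - grid$rejection_rate) /
                    n_datasets)
  grid$n_datasets <- n_datasets
  grid$n_perm <- n_perm
  attr(grid, "p_values") <- pvals
  attr(grid, "seed") <- seed
  class(grid) <- c("sdr_power", "data.frame")
  grid
}

#' @export
print.sdr_power <- function(x, ...) {
  cat("Empirical rejection rates (permutation SDR tests)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Binomial calibration band for an empirical rejection rate
#'
#' Closed-form standard error and normal-approximation confidence limits for
#' an empirical rate estimated from `n_reps` independent replicates when the
#' true rate is `p`: with 1000 replicates at `p = 0.05` the standard error is
#' 0.0069 and the upper 97.5% limit about 0.064; at `p = 0.01` the upper
#' limit is about 0.016.
#'
#' @param p True rate.
#' @param n_reps Number of replicates.
#' @param conf Two-sided confidence level (default 0.95).
#' @return Named vector with `se`, `lower`, `upper`.
#' @export
rejection_band <- function(p = 0.05, n_reps = 1000, conf = 0.95) {
  se <- sqrt(p * (1 - p) / n_reps)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(se = se, lower = p - z * se, upper = p + z * se)
}
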