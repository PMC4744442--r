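test_that("single-slice moments reproduce pooled moments; T and V vanish", {
  set.seed(7)
  x <- matrix(rnorm(12 * 3), 12, 3)
  std <- standardize_expression(x, "exact")
  part <- structure(list(labels = rep(1L, 12), H = 1L, sizes = 12L,
                         proportions = 1), class = "sdr_slices")
  m <- slice_moments(std, part)
  expect_lt(max(abs(m$means)), 1e-10)
  expect_lt(max(abs(m$covariances[, , 1] - diag(3))), 1e-8)
  expect_lt(statistic_T(m)$value, 1e-16)
  expect_lt(statistic_V(m), 1e-16)

  # unstandardized variants vanish too (slice = pooled sample)
  mi <- slice_moments(standardize_expression(x, "identity"), part)
  expect_lt(statistic_T_star(mi)$value, 1e-16)
  expect_lt(statistic_V_star(mi), 1e-16)
})

test_that("duplicated blocks give identical slice moments", {
  set.seed(8)
  blk <- matrix(rnorm(9), 3, 3)
  z <- structure(list(values = rbind(blk, blk), mode = "identity",
                      pooled_cov = slow_cov(rbind(blk, blk)), divisor = "n"),
                 class = "sdr_standardized")
  part <- structure(list(labels = rep(1:2, each = 3), H = 2L,
                         sizes = c(3L, 3L), proportions = c(0.5, 0.5)),
                    class = "sdr_slices")
  m <- slice_moments(z, part)
  expect_equal(m$means[1, ], m$means[2, ])
  expect_equal(m$covariances[, , 1], m$covariances[, , 2])
})

test_that("slice moments match a direct per-slice loop", {
  set.seed(9)
  z <- matrix(rnorm(10 * 3), 10, 3)
  labels <- rep(1:2, each = 5)
  zc <- sweep(z, 2, colMeans(z))
  std <- standardize_expression(z, "identity")
  part <- structure(list(labels = labels, H = 2L, sizes = c(5L, 5L),
                         proportions = c(0.5, 0.5)), class = "sdr_slices")
  m <- slice_moments(std, part)
  for (s in 1:2) {
    zs <- zc[labels == s, ]
    expect_equal(m$means[s, ], colMeans(zs), tolerance = 1e-12)
    expect_equal(m$covariances[, , s], slow_cov(zs), tolerance = 1e-12)
  }
})

test_that("scalar closed forms for T and V", {
  # p = 1, H = 2, phat = (.5,.5), slice variances (1.2, .8) -> T = 0.04
  m <- structure(list(means = matrix(0, 2, 1),
                      covariances = array(c(1.2, 0.8), c(1, 1, 2)),
                      proportions = c(0.5, 0.5), sizes = c(5L, 5L), H = 2L,
                      pooled_cov = diag(1), mode = "exact", divisor = "n"),
                 class = "sdr_slice_moments")
  expect_equal(statistic_T(m)$value, 0.04, tolerance = 1e-12)
  # variances (4,1), means (.3,-.3) -> V = .5*((2-1)^2+.09) + .5*(0+.09) = .59
  m$covariances <- array(c(4, 1), c(1, 1, 2))
  m$means <- matrix(c(0.3, -0.3), 2, 1)
  expect_equal(statistic_V(m), 0.59, tolerance = 1e-12)
})

test_that("matrix forms match brute-force oracles on small instances", {
  set.seed(10)
  for (case in 1:8) {
    n <- sample(6:12, 1)
    p <- sample(2:4, 1)
    H <- sample(2:3, 1)
    if (n < 2 * H + p) next
    x <- matrix(rnorm(n * p), n, p)
    labels <- sort(rep_len(seq_len(H), n))
    part <- sdrgsa:::.new_slices(labels, H)

    std <- standardize_expression(x, "exact")
    m <- slice_moments(std, part)
    oracle <- slow_slice_stats(std$values, labels, diag(p))
    tt <- statistic_T(m)
    expect_equal(tt$value, oracle$T, tolerance = 1e-10)
    expect_equal(tt$gene_contributions, oracle$Ti, tolerance = 1e-10)
    # sqrt(lambda) is non-Lipschitz at 0: rank-deficient slice covariances
    # (slice size <= p) only admit sqrt(eps)-level agreement for V
    v_tol <- if (min(part$sizes) > p) 1e-10 else 1e-7
    expect_equal(statistic_V(m), oracle$V, tolerance = v_tol)

    stdi <- standardize_expression(x, "identity")
    mi <- slice_moments(stdi, part)
    oraclei <- slow_slice_stats(stdi$values, labels, slow_cov(x))
    tsi <- statistic_T_star(mi)
    expect_equal(tsi$value, oraclei$T, tolerance = 1e-10)
    expect_equal(tsi$gene_contributions, oraclei$Ti, tolerance = 1e-10)
    expect_equal(statistic_V_star(mi), oraclei$Vstar, tolerance = v_tol)
  }
})

test_that("fast label path agrees with the moments path, incl. Gram branch", {
  set.seed(12)
  # p > slice size exercises the Gram-matrix eigenvalue shortcut for V
  x <- matrix(rnorm(14 * 20), 14, 20)
  std <- standardize_expression(x, "shrinkage")
  labels <- rep(1:2, each = 7)
  part <- sdrgsa:::.new_slices(labels, 2L)
  m <- slice_moments(std, part)
  f <- sdrgsa:::.stats_for_labels(std$values, labels, 2L, part$proportions,
                                  c("T", "V"), NULL, NULL, "n", TRUE)
  expect_equal(unname(f$values["T"]), statistic_T(m)$value, tolerance = 1e-10)
  # Gram-matrix eigenvalues agree with the p x p route to ~1e-8 relative
  expect_equal(unname(f$values["V"]), statistic_V(m), tolerance = 1e-7)
  expect_equal(f$gene, statistic_T(m)$gene_contributions, tolerance = 1e-10)

  # starred path
  stdi <- standardize_expression(x, "identity")
  mi <- slice_moments(stdi, part)
  ps <- sym_matrix_power(stdi$pooled_cov, 1 / 2)
  fs <- sdrgsa:::.stats_for_labels(stdi$values, labels, 2L, part$proportions,
                                   c("Tstar", "Vstar"), stdi$pooled_cov, ps,
                                   "n", FALSE)
  expect_equal(unname(fs$values["Tstar"]), statistic_T_star(mi)$value,
               tolerance = 1e-10)
  expect_equal(unname(fs$values["Vstar"]), statistic_V_star(mi),
               tolerance = 1e-10)
})

test_that("statistics are nonnegative and T decomposes over genes", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    p <- sample(2:6, 1)
    x <- matrix(rnorm(n * p), n, p)
    H <- 2L
    labels <- rep_len(1:2, n)
    part <- sdrgsa:::.new_slices(labels, H)
    std <- standardize_expression(x, if (p < n - 2) "exact" else "shrinkage")
    m <- slice_moments(std, part)
    tt <- statistic_T(m)
    expect_gte(tt$value, 0)
    expect_true(all(tt$gene_contributions >= 0))
    expect_equal(sum(tt$gene_contributions), tt$value,
                 tolerance = 1e-12 * max(1, tt$value))
    expect_gte(statistic_V(m), 0)
  }
})

test_that("T and V are invariant under affine maps of the expressions", {
  set.seed(14)
  n <- 25; p <- 4
  x <- matrix(rnorm(n * p), n, p)
  a <- matrix(rnorm(p * p), p, p) + diag(p)       # invertible w.h.p.
  b <- rnorm(p)
  xa <- x %*% t(a) + matrix(b, n, p, byrow = TRUE)
  labels <- rep_len(1:2, n)
  part <- sdrgsa:::.new_slices(labels, 2L)
  m1 <- slice_moments(standardize_expression(x, "exact"), part)
  m2 <- slice_moments(standardize_expression(xa, "exact"), part)
  expect_equal(statistic_T(m1)$value, statistic_T(m2)$value,
               tolerance = 1e-8)
  expect_equal(statistic_V(m1), statistic_V(m2), tolerance = 1e-8)
})

test_that("gene reordering permutes contributions without changing totals", {
  set.seed(15)
  x <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  perm <- c(3, 1, 5, 2, 4)
  labels <- rep(1:2, each = 10)
  part <- sdrgsa:::.new_slices(labels, 2L)
  m1 <- slice_moments(standardize_expression(x, "exact"), part)
  m2 <- slice_moments(standardize_expression(x[, perm], "exact"), part)
  t1 <- statistic_T(m1); t2 <- statistic_T(m2)
  expect_equal(t1$value, t2$value, tolerance = 1e-10)
  expect_equal(t1$gene_contributions[perm], t2$gene_contributions,
               tolerance = 1e-10)
  expect_equal(statistic_V(m1), statistic_V(m2), tolerance = 1e-10)

  mi1 <- slice_moments(standardize_expression(x, "identity"), part)
  mi2 <- slice_moments(standardize_expression(x[, perm], "identity"), part)
  expect_equal(statistic_T_star(mi1)$value, statistic_T_star(mi2)$value,
               tolerance = 1e-10)
  expect_equal(statistic_V_star(mi1), statistic_V_star(mi2),
               tolerance = 1e-10)
})

test_that("starred statistics coincide with T/V on pre-standardized data", {
  set.seed(16)
  x <- matrix(rnorm(18 * 4), 18, 4)
  z <- standardize_expression(x, "exact")$values   # now Sigma_X = I exactly
  labels <- rep_len(1:3, 18)
  part <- sdrgsa:::.new_slices(labels, 3L)
  m_std <- slice_moments(standardize_expression(z, "exact"), part)
  m_id <- slice_moments(standardize_expression(z, "identity"), part)
  expect_equal(statistic_T_star(m_id)$value, statistic_T(m_std)$value,
               tolerance = 1e-10)
  expect_equal(statistic_V_star(m_id), statistic_V(m_std), tolerance = 1e-10)
})

test_that("statistic contract: T/V refuse unstandardized moments", {
  set.seed(17)
  x <- matrix(rnorm(20 * 3), 20, 3) * 3
  part <- sdrgsa:::.new_slices(rep(1:2, each = 10), 2L)
  mi <- slice_moments(standardize_expression(x, "identity"), part)
  expect_error(statistic_T(mi), "statistic_T_star")
  expect_error(statistic_V(mi), "statistic_V_star")
})

test_that("null expectation of T shrinks as n grows at fixed H and p", {
  set.seed(18)
  mean_T <- function(n, reps = 300) {
    vals <- replicate(reps, {
      x <- matrix(rnorm(n * 3), n, 3)
      part <- sdrgsa:::.new_slices(rep_len(1:2, n), 2L)
      statistic_T(slice_moments(standardize_expression(x, "exact"), part))$value
    })
    mean(vals)
  }
  m_small <- mean_T(16)
  m_large <- mean_T(64)
  expect_lt(m_large, m_small / 2)
})
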