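test_that("binary scenario draws the advertised group structure", {
  sc <- binary_scenario(n = 20, p = 20, variance = "homogeneous", null = TRUE)
  dat <- simulate(sc, seed = 41)
  expect_identical(dim(dat$x), c(20L, 20L))
  expect_identical(as.vector(table(dat$y)), c(10L, 10L))
  sig <- attr(dat, "sigma")
  expect_equal(sig[[1]], diag(20))
  expect_equal(sig[[2]], sig[[1]])
})

test_that("gamma = 1 with rho = 0 changes only the diagonal", {
  sc <- binary_scenario(n = 20, p = 8, variance = "heterogeneous",
                        gamma = 1, rho = 0)
  dat <- simulate(sc, seed = 42)
  sig <- attr(dat, "sigma")
  expect_true(all(diag(sig[[1]]) >= 1 & diag(sig[[1]]) <= 5))
  expect_false(isTRUE(all.equal(diag(sig[[1]]), diag(sig[[2]]))))
  expect_equal(sig[[2]] - diag(diag(sig[[2]])), matrix(0, 8, 8))
})

test_that("binary covariance construction matches its moment oracle", {
  sc <- binary_scenario(n = 100000, p = 8, variance = "heterogeneous",
                        gamma = 0.5, rho = 0.6)
  dat <- simulate(sc, seed = 43)
  sig2 <- attr(dat, "sigma")[[2]]
  # constructed correlation: first gamma*p = 4 genes equicorrelated at .6
  r2 <- stats::cov2cor(sig2)
  expect_equal(r2[1:4, 1:4][upper.tri(diag(4))], rep(0.6, 6))
  expect_equal(r2[5:8, 1:4], matrix(0, 4, 4), ignore_attr = TRUE)
  emp <- slow_cov_fast(dat$x[dat$y == 2L, ])
  expect_lt(max(abs(emp - sig2)), 0.15)
  emp1 <- slow_cov_fast(dat$x[dat$y == 1L, ])
  expect_lt(max(abs(emp1 - attr(dat, "sigma")[[1]])), 0.15)
})

test_that("three-class design places correlated genes block-wise", {
  sc <- threeclass_scenario(n = 30, p = 20, gamma = 0.8, rho = 0.5)
  dat <- simulate(sc, seed = 44)
  sig <- attr(dat, "sigma")
  expect_identical(as.vector(table(dat$y)), rep(10L, 3))
  r2 <- stats::cov2cor(sig[[2]])
  r3 <- stats::cov2cor(sig[[3]])
  # blocks of size 5, 4 correlated genes per block (first for class 2,
  # last for class 3)
  expect_equal(r2[1:4, 1:4][upper.tri(diag(4))], rep(0.5, 6))
  expect_equal(r3[2:5, 2:5][upper.tri(diag(4))], rep(0.5, 6))
  expect_equal(r2[1:5, 6:10], matrix(0, 5, 5), ignore_attr = TRUE)
  # Sigma_1 diagonal; gamma = 0 degenerates to an all-diagonal null design
  expect_equal(sig[[1]], diag(diag(sig[[1]])))
  sc0 <- threeclass_scenario(n = 30, p = 20, gamma = 0, rho = 0.5)
  sig0 <- attr(simulate(sc0, seed = 45), "sigma")
  expect_equal(sig0[[2]], diag(diag(sig0[[2]])))
  expect_equal(sig0[[3]], diag(diag(sig0[[3]])))
})

test_that("continuous covariance matches the piecewise definition", {
  sc <- continuous_scenario(n = 10, p = 10, p1 = 3, rho = 0.6)
  sig <- attr(simulate(sc, seed = 46), "sigma")[[1]]
  direct <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    direct[i, j] <- if (i == j) 1
      else if (i <= 3 && j <= 3) 0.6
      else if (i >= 4 && i <= 6 && j >= 4 && j <= 6) 0.6^abs(i - j)
      else 0
  }
  expect_equal(sig, direct)
  # rho = 0 gives the identity
  sc0 <- continuous_scenario(n = 20, p = 20, p1 = 5, rho = 0)
  expect_equal(attr(simulate(sc0, seed = 47), "sigma")[[1]], diag(20))
})

test_that("continuous links behave as specified", {
  # null link: phenotype independent of every gene
  sc <- continuous_scenario(n = 20000, p = 4, p1 = 2, rho = 0.3,
                            link = "null")
  dat <- simulate(sc, seed = 48)
  expect_lt(max(abs(cor(dat$x, dat$y))), 0.03)
  expect_equal(attr(dat$y, "beta"), rep(0, 4))

  # alternative: exactly 10 nonzero coefficients, 5 per block, signs by block
  sca <- continuous_scenario(n = 30, p = 40, p1 = 12, rho = 0.3,
                             link = "linear", nu = 1.5)
  beta <- attr(simulate(sca, seed = 49)$y, "beta")
  expect_identical(sum(beta != 0), 10L)
  expect_identical(sum(beta[1:12] != 0), 5L)
  expect_identical(sum(beta[13:24] != 0), 5L)
  expect_true(all(beta[25:40] == 0))
  # nu = 0 collapses the alternative onto the null
  sc0 <- continuous_scenario(n = 10, p = 20, p1 = 5, link = "linear", nu = 0)
  expect_equal(attr(simulate(sc0, seed = 50)$y, "beta"), rep(0, 20))
})

test_that("scenario invariants are enforced at construction", {
  expect_error(binary_scenario(n = 21), "even")
  expect_error(binary_scenario(rho = 1), "rho")
  expect_error(threeclass_scenario(n = 31), "divisible by 3")
  expect_error(threeclass_scenario(p = 18), "divisible by 4")
  expect_error(continuous_scenario(p = 8, p1 = 5), "2 \\* p1")
})

test_that("replicates are reproducible and generated covariances are PD", {
  sc <- binary_scenario(n = 12, p = 6, variance = "heterogeneous",
                        gamma = 0.5, rho = 0.8)
  d1 <- simulate(sc, seed = 51)
  d2 <- simulate(sc, seed = 51)
  expect_identical(d1$x, d2$x)
  reps <- simulate(sc, nsim = 5, seed = 52)
  for (r in reps) {
    for (s in attr(r, "sigma")) {
      expect_gt(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
})

test_that("size/power harness reports rates with binomial errors", {
  sc <- binary_scenario(n = 16, p = 4, null = TRUE)
  res <- estimate_size_power(sc, c("T", "V"), n_datasets = 40, n_perm = 99,
                             alpha = c(0, 0.5), seed = 9)
  expect_identical(nrow(res), 4L)
  r0 <- res$rejection_rate[res$alpha == 0]
  expect_true(all(r0 == 0))          # p-values are >= 1/(B+1) > 0
  expect_equal(res$se,
               sqrt(res$rejection_rate * (1 - res$rejection_rate) / 40))
  res2 <- estimate_size_power(sc, c("T", "V"), n_datasets = 40, n_perm = 99,
                              alpha = c(0, 0.5), seed = 9)
  expect_identical(res$rejection_rate, res2$rejection_rate)
})
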