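test_that("jackknife coefficients match the published closed forms", {
  jack1 <- function(S, f, t) S + (t - 1) / t * f[1]
  jack2 <- function(S, f, t)
    S + (2 * t - 3) / t * f[1] - (t - 2)^2 / (t * (t - 1)) * f[2]
  jack3 <- function(S, f, t)
    S + (3 * t - 6) / t * f[1] -
    (3 * t^2 - 15 * t + 19) / (t * (t - 1)) * f[2] +
    (t - 3)^3 / (t * (t - 1) * (t - 2)) * f[3]
  set.seed(5)
  for (t in c(4, 5, 7, 10)) {
    f <- rpois(t, 3)
    f[1] <- f[1] + 1                 # ensure captures exist
    S <- sum(f)
    est <- jackknifeMh(f, t = t, order = 1)
    expect_equal(est$Nhat, jack1(S, f, t), tolerance = 1e-10)
    expect_equal(jackknifeMh(f, t = t, order = 2)$Nhat,
                 max(jack2(S, f, t), S), tolerance = 1e-10)
    expect_equal(jackknifeMh(f, t = t, order = 3)$Nhat,
                 max(jack3(S, f, t), S), tolerance = 1e-10)
  }
})

test_that("first-order jackknife agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(9)
  # occasions-by-individuals incidence, the richness analogue of captures
  m <- matrix(rbinom(7 * 40, 1, 0.3), nrow = 40, ncol = 7)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  fc <- frequencyCounts(m)
  pool <- vegan::specpool(t(m))
  expect_equal(jackknifeMh(fc, order = 1)$Nhat, pool$jack1,
               tolerance = 1e-9)
})

test_that("worked frequency examples", {
  est <- jackknifeMh(c(3, 2, 1), t = 3, order = 1)
  expect_equal(est$Nhat, 8, tolerance = 1e-12)   # 6 + (2/3)*3
  # every animal caught on every occasion: no singletons, no correction
  all7 <- jackknifeMh(c(0, 0, 0, 0, 0, 0, 12), t = 7, order = 1)
  expect_equal(all7$Nhat, 12)
})

test_that("the estimate never falls below the observed count", {
  set.seed(21)
  for (i in 1:30) {
    t <- sample(3:10, 1)
    f <- rpois(t, 2)
    if (sum(f) == 0) f[sample.int(t, 1)] <- 1
    S <- sum(f)
    for (k in seq_len(min(5, t - 1)))
      expect_gte(jackknifeMh(f, t = t, order = k)$Nhat, S)
    expect_gte(jackknifeMh(f, t = t)$Nhat, S)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(jackknifeMh(c(1, 1), t = 1), "two trapping occasions")
  expect_error(jackknifeMh(rep(0, 5), t = 5), "no captures")
  expect_error(jackknifeMh(c(3, 2, 1), t = 3, order = 4), "order")
})

test_that("first-order jackknife is calibrated at p = 1/t", {
  # at per-occasion capture probability 1/t the first-order correction is
  # unbiased for homogeneous capture; the estimate should sit within 3 SE
  set.seed(33)
  N <- 1000; t <- 7; p <- 1 / t
  ni <- rbinom(N, t, p)
  f <- tabulate(ni[ni > 0], nbins = t)
  est <- jackknifeMh(f, t = t, order = 1)
  expect_lt(abs(est$Nhat - N), 3 * est$se)
})

test_that("auto order selection reports its interpolation", {
  set.seed(4)
  ni <- rbinom(300, 7, rbeta(300, 1.5, 4))
  f <- tabulate(ni[ni > 0], nbins = 7)
  est <- jackknifeMh(f, t = 7)
  expect_true(est$order >= 1 && est$order <= 5)
  expect_true(est$interpolation >= 0 && est$interpolation < 1)
  expect_equal(nrow(est$estimates), 5)
  expect_true(all(diff(est$estimates$order) == 1))
})

test_that("abundance converts to density over the enclosure area", {
  expect_equal(densityFromAbundance(120), 30)
  expect_equal(densityFromAbundance(120, areaHa = 2), 60)
  expect_error(densityFromAbundance(120, areaHa = 0), "positive")
})
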