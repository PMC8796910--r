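test_that("simulation replays are deterministic under a fixed seed", {
  cfg <- simConfig(seed = 11, nFounders = 60, horizonMonths = 18)
  p1 <- simulatePopulation(cfg)
  p2 <- simulatePopulation(cfg)
  expect_identical(p1, p2)
  ch1 <- simulateTrapping(p1, cfg, months = 1:6)
  ch2 <- simulateTrapping(p2, cfg, months = 1:6)
  expect_identical(SummarizedExperiment::assay(ch1, "captures"),
                   SummarizedExperiment::assay(ch2, "captures"))
  # a different seed produces a different history
  p3 <- simulatePopulation(simConfig(seed = 12, nFounders = 60,
                                     horizonMonths = 18))
  expect_false(identical(p1$deathMonth, p3$deathMonth))
})

test_that("survival-only dynamics match the binomial expectation", {
  cfg <- simConfig(seed = 2, nFounders = 1000, horizonMonths = 12,
                   monthlySurvival = list(
                     female = c(juvenile = 0.9, adult = 0.9),
                     male = c(juvenile = 0.9, adult = 0.9)),
                   monthlyBreedingProb = 0, lateBreedingProb = 0)
  pop <- simulatePopulation(cfg)
  expect_equal(nrow(pop), 1000)            # no births
  survivors <- sum(is.na(pop$deathMonth))
  expected <- 1000 * 0.9^12
  sdv <- sqrt(1000 * 0.9^12 * (1 - 0.9^12))
  expect_lt(abs(survivors - expected), 3 * sdv)
})

test_that("the litter-size distribution hits the observed mean on 1..7", {
  cfg <- simConfig()
  expect_equal(sum(cfg@litterProb), 1, tolerance = 1e-12)
  expect_equal(sum((1:7) * cfg@litterProb), 4.57, tolerance = 1e-9)
  set.seed(3)
  draws <- sample.int(7, 1e4, replace = TRUE, prob = cfg@litterProb)
  expect_true(all(draws >= 1 & draws <= 7))
  expect_lt(abs(mean(draws) - 4.57), 3 * sd(draws) / sqrt(1e4))
})

test_that("trapping matches the analytic capture expectation", {
  # static adult population, one session: expected distinct captures is
  # N * (1 - E[(1-p)^t]) with p ~ Beta(a, b), E[(1-p)^t] = B(a, b+t)/B(a, b)
  cfg <- simConfig(seed = 5, nFounders = 2000, horizonMonths = 1,
                   monthlySurvival = list(
                     female = c(juvenile = 1, adult = 1),
                     male = c(juvenile = 1, adult = 1)),
                   monthlyBreedingProb = 0, lateBreedingProb = 0)
  pop <- simulatePopulation(cfg)
  ch <- simulateTrapping(pop, cfg, months = 1)
  fc <- frequencyCounts(ch, session = 1)
  a <- cfg@captureShape[1]; b <- cfg@captureShape[2]; t <- fc$t
  pMiss <- beta(a, b + t) / beta(a, b)
  expected <- 2000 * (1 - pMiss)
  sdv <- sqrt(2000 * pMiss * (1 - pMiss))
  expect_lt(abs(fc$S - expected), 3 * sdv)
  # capture-history invariants hold by construction (validity ran)
  expect_s4_class(ch, "CaptureHistory")
})

test_that("triple-catch aggregation recovers the true monthly survival", {
  cfg <- simConfig(seed = 8, nFounders = 2000, horizonMonths = 3,
                   monthlySurvival = list(
                     female = c(juvenile = 0.7, adult = 0.7),
                     male = c(juvenile = 0.7, adult = 0.7)),
                   monthlyBreedingProb = 0, lateBreedingProb = 0)
  pop <- simulatePopulation(cfg)
  ch <- simulateTrapping(pop, cfg, months = 1:3)
  rec <- tripleCatchFromHistory(ch, sessions = 1:3)
  expect_true(rec$R13 <= rec$B1)
  expect_lt(abs(rec$Shat - 0.7), 0.06)
})

test_that("known-age cohorts reproduce the configured survivorship curve", {
  cfg <- simConfig(seed = 14, nFounders = 400, horizonMonths = 36)
  pop <- simulatePopulation(cfg)
  cc <- knownAgeCohort(pop, sex = "female", bornBy = 6)
  alive <- aliveCounts(cc)
  n0 <- alive[1]
  expect_gt(n0, 100)
  sJ <- cfg@monthlySurvival$female[["juvenile"]]
  sA <- cfg@monthlySurvival$female[["adult"]]
  for (k in 1:min(4, length(alive) - 1)) {
    lTrue <- sJ^3 * sA^(3 * (k - 1))
    sdv <- sqrt(n0 * lTrue * (1 - lTrue))
    expect_lt(abs(alive[k + 1] - n0 * lTrue), 3 * sdv + 1)
  }
})

test_that("male-biased mortality produces a female-biased adult population", {
  cfg <- simConfig(seed = 20, nFounders = 600, horizonMonths = 24)
  pop <- simulatePopulation(cfg)
  adultAt <- function(m) !is.na(pop$birthMonth) & (m - pop$birthMonth) >= 3 &
    pop$birthMonth <= m & (is.na(pop$deathMonth) | pop$deathMonth >= m)
  sexAt <- pop$sex[adultAt(24)]
  expect_gt(sum(sexAt == "female"), sum(sexAt == "male"))
})

test_that("growth series are reproducible and fit back to their generator", {
  cfg0 <- simConfig(seed = 6, growthNoiseSD = 0)
  g0 <- simulateGrowthSeries(cfg0, nSubjects = 3)
  expect_equal(g0$mass,
               rep(growthClosedForm(seq(0, 1, 0.02), cfg0@growth, 0.01), 3),
               tolerance = 1e-12)
  fit0 <- fitGrowthModel(g0)
  ab <- growthConstants(fit0$params)
  expect_lt(abs(ab["a"] / 6.5266 - 1), 0.01)
  expect_lt(abs(ab["b"] / 12.1787 - 1), 0.01)

  cfgN <- simConfig(seed = 6, growthNoiseSD = 0.02)
  gN <- simulateGrowthSeries(cfgN, nSubjects = 50)
  fitN <- fitGrowthModel(gN)
  abN <- growthConstants(fitN$params)
  expect_lt(abs(abN["a"] / 6.5266 - 1), 0.05)
  expect_lt(abs(abN["b"] / 12.1787 - 1), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(monthlySurvival = list(
    female = c(juvenile = 1.2, adult = 0.5),
    male = c(juvenile = 0.8, adult = 0.5))), "survival")
  expect_error(simConfig(litterProb = rep(0.2, 5)), "litterProb")
  expect_error(simConfig(growthNoiseSD = -0.1), "growthNoiseSD")
  cfg <- simConfig(horizonMonths = 6)
  pop <- simulatePopulation(cfg)
  expect_error(simulateTrapping(pop, cfg, months = 1:12), "horizon")
})
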