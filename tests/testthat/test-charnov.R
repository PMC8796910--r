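test_that("survival to maturity: hazard and empirical modes", {
  expect_equal(survivalToMaturity(Zbar = 0, alphaMonths = 12), 1)
  expect_equal(survivalToMaturity(Zbar = 0.1, alphaMonths = 12),
               exp(-1.2), tolerance = 1e-12)
  # empirical: female survivorship entering the first reproductive class
  lt <- buildLifeTable(CohortCounts(femaleCounts(), sex = "female"))
  S <- survivalToMaturity(lx = lx(lt), alphaClass = 4, mode = "empirical")
  expect_equal(S, 0.1558, tolerance = 1e-3)   # tabulated as 0.156
  expect_error(survivalToMaturity(Zbar = -1, alphaMonths = 12),
               "non-negative")
})

test_that("S falls with harsher juvenile mortality and later maturity", {
  zs <- seq(0, 0.5, by = 0.1)
  expect_true(all(diff(vapply(zs, survivalToMaturity, 1,
                              alphaMonths = 12)) < 0))
  as <- c(3, 6, 12, 24)
  expect_true(all(diff(vapply(as, function(a)
    survivalToMaturity(Zbar = 0.1, alphaMonths = a), 1)) < 0))
})

test_that("hazard averaging converts class mortality to monthly rates", {
  expect_equal(meanJuvenileHazard(0.5, classWidth = 3),
               -log(0.5) / 3, tolerance = 1e-12)
  expect_equal(meanJuvenileHazard(c(0.3, 0.3)), -log(0.7) / 3,
               tolerance = 1e-12)
  expect_error(meanJuvenileHazard(1), "\\[0, 1\\)")
})

test_that("adult residence time matches brute-force integration oracles", {
  # piecewise-linear survivorship: trapezoid sum computed longhand
  l <- c(1, 0.7, 0.4, 0.1)
  longhand <- 3 * ((1 + 0.7) / 2 + (0.7 + 0.4) / 2 + (0.4 + 0.1) / 2 +
                   0.1 / 2)
  expect_equal(adultLifeExpectancy(l, alphaClass = 1, classWidth = 3),
               longhand, tolerance = 1e-12)
  # one adult class: survivorship S then extinction within the class
  expect_equal(adultLifeExpectancy(c(1, 0.2), alphaClass = 2,
                                   classWidth = 3), 1.5)
  # smooth exponential decline: class-width trapezoid vs fine-grid Riemann
  z <- 0.12
  ages <- seq(0, 60, by = 3)
  l <- exp(-z * ages)
  fine <- seq(0, 60, by = 0.001)
  riemann <- sum(exp(-z * fine)) * 0.001
  expect_equal(adultLifeExpectancy(l, alphaClass = 1, classWidth = 3),
               riemann, tolerance = 0.02)
  # invariant to rescaling the survivorship series
  expect_equal(adultLifeExpectancy(1000 * l, 1, 3),
               adultLifeExpectancy(l, 1, 3), tolerance = 1e-12)
})

test_that("reproductive effort is the reproduction-weighted mean of Cx", {
  expect_equal(reproductiveEffort(c(0.5, 0.3, 0.1), c(1, 2, 1), 0.07),
               0.07, tolerance = 1e-12)
  expect_equal(reproductiveEffort(c(0.4, 0.2), c(1, 2), c(0.1, 0.3)),
               0.2, tolerance = 1e-12)   # equal weights 0.4*1 = 0.2*2
  expect_error(reproductiveEffort(c(1, 1), c(0, 0), 0.1), "zero total")
})

test_that("the 2R0 identity holds on internally consistent schedules", {
  # single adult class, fertility chosen so total offspring mass over the
  # adult phase equals offspring count times independence mass
  S <- 0.2; cw <- 3; c0 <- 0.05; I <- 50; m <- 150
  ch <- charnovInvariantSet(lx = c(1, S), mx = c(0, c0 * cw * m / (4 * I)),
                            alphaClass = 2, alphaMonths = 12, Cx = c0,
                            I = I, mAdult = m, classWidth = cw)
  expect_lt(ch$residual2R0, 1e-10)

  # multi-class schedule: pass the R0 the identity implies and check the
  # residual is computed consistently from the same components
  lxs <- c(1, 0.6, 0.3, 0.15, 0.05)
  mxs <- c(0, 0, 1.2, 0.8, 0.2)
  S2 <- 0.3; Eres <- adultLifeExpectancy(lxs, 3, cw)
  C2 <- reproductiveEffort(lxs[3:5], mxs[3:5], 0.04)
  R0c <- lxs[3] * C2 * Eres * m / (2 * I)
  ch2 <- charnovInvariantSet(lxs, mxs, alphaClass = 3, alphaMonths = 9,
                             Cx = 0.04, I = I, mAdult = m, classWidth = cw,
                             R0 = R0c)
  expect_lt(ch2$residual2R0, 1e-10)
})

test_that("the pika schedules land inside the published invariant bands", {
  lt <- buildLifeTable(CohortCounts(femaleCounts(), sex = "female"))
  mxs <- fertilitySchedule(
    readFecundity(pikaExtdata("fecundity_female.tsv")))$mx
  traits <- pikaTraits()
  litter <- traitValue("litter_size_mean", "female")
  litsYr <- traitValue("litters_per_year", "female")
  w0 <- traitValue("weaning_mass_g", "pooled")
  wAdult <- traitValue("adult_mass_g", "pooled")
  CxMonthly <- litter * litsYr * w0 / wAdult / 12
  ch <- charnovInvariantSet(lx(lt), mxs, alphaClass = 4, alphaMonths = 12,
                            Cx = CxMonthly,
                            I = traitValue("independence_mass_g"),
                            mAdult = wAdult)
  expect_equal(ch$EoverAlpha, 1.35, tolerance = 0.15 / 1.35)
  expect_equal(ch$CE, 1.7, tolerance = 0.2 / 1.7)
  expect_equal(ch$IoverM, 0.3348, tolerance = 1e-3)
})
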