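test_that("cohort life table reproduces the published male and female columns", {
  ltM <- buildLifeTable(CohortCounts(maleCounts(), sex = "male"))
  expect_equal(qx(ltM)[1], 112 / 228, tolerance = 1e-12)
  expect_equal(round(qx(ltM)[1], 4), 0.4912)
  expect_equal(round(lx(ltM)[2], 4), 0.5088)

  ltF <- buildLifeTable(CohortCounts(femaleCounts(), sex = "female"))
  expect_equal(round(qx(ltF)[1], 4), 0.5156)
  expect_equal(round(lx(ltF)[4], 4), 0.1558)   # survivorship entering 9-12
})

test_that("deaths always sum to the radix and lx tracks the empirical fraction", {
  set.seed(42)
  for (i in 1:20) {
    alive <- randomCohort()
    for (radix in c(1, 1000)) {
      lt <- buildLifeTable(CohortCounts(alive), radix = radix)
      expect_equal(sum(dx(lt)), radix, tolerance = 1e-9)
      expect_equal(lx(lt) / radix, alive / alive[1], tolerance = 1e-12)
      expect_true(all(qx(lt) >= 0 & qx(lt) <= 1))
      expect_true(all(diff(Tx(lt)) <= 1e-9))
      expect_true(all(ex(lt) >= 0))
    }
  }
})

test_that("a single-class cohort is absorbed by its terminal class", {
  lt <- buildLifeTable(CohortCounts(50))
  expect_equal(qx(lt), 1)
  expect_equal(lx(lt), 1)
  expect_equal(dx(lt), 1)          # radix scale
  expect_equal(Lx(lt), 0.5)
  expect_equal(ex(lt), 0.5)        # class units: midpoint of terminal class
})

test_that("midpoint person-time matches the published radix-1000 table", {
  tb <- femaleExpectancyTable()
  lt <- lifeTableFromLx(tb$lx, sex = "female")
  # midpoint of the 3-6 class: (487.18 + 347.62) / 2
  expect_equal(Lx(lt)[2], 417.40, tolerance = 1e-6)
  # rows 2+ of the published Lx column follow the midpoint rule
  expect_equal(Lx(lt)[-1], tb$Lx[-1], tolerance = 2e-4)
  # the published first-row Lx (782.46) does not; midpoint gives
  # (1000 + 487.18) / 2
  expect_equal(Lx(lt)[1], 743.59, tolerance = 1e-6)
})

test_that("accumulating a published Lx column reproduces its totals", {
  tb <- femaleExpectancyTable()
  lt <- lifeTableFromLx(tb$lx, sex = "female", Lx = tb$Lx)
  expect_equal(Tx(lt)[1], 2113.69, tolerance = 1e-6)
  expect_equal(ex(lt)[1], 2.11, tolerance = 1e-2)   # class units
  expect_equal(Tx(lt), rev(cumsum(rev(tb$Lx))), tolerance = 1e-9)
})

test_that("life expectancy under constant class survival matches the geometric closed form", {
  for (s in c(0.5, 0.8)) {
    k <- 10
    alive <- round(4096 * s^(0:(k - 1)))
    lt <- buildLifeTable(CohortCounts(alive))
    # telescoped midpoint sum: e0 = sum(s^x) - 1/2, computed independently
    oracle <- sum((alive / alive[1])) - 0.5
    expect_equal(ex(lt)[1], oracle, tolerance = 1e-9)
  }
})

test_that("average mortality matches the printed mortality columns", {
  am <- averageMortality(buildLifeTable(CohortCounts(maleCounts(),
                                                     sex = "male")))
  expect_equal(unname(am["mean"]), 0.44617, tolerance = 1e-4)
  expect_equal(unname(am["n"]), 9)

  af <- averageMortality(buildLifeTable(CohortCounts(femaleCounts(),
                                                     sex = "female")))
  expect_equal(unname(af["mean"]), 0.42529, tolerance = 1e-4)
  expect_equal(unname(af["n"]), 10)

  flat <- buildLifeTable(CohortCounts(c(1000, 700, 490, 343)))
  amf <- averageMortality(flat)
  expect_equal(unname(amf["mean"]), 0.3, tolerance = 1e-9)
  expect_equal(unname(amf["sd"]), 0, tolerance = 1e-9)
})

test_that("invalid cohorts are rejected with informative errors", {
  expect_error(CohortCounts(integer(0)), "empty")
  expect_error(CohortCounts(c(100, 120, 50)), "class 0 -> 1")
  expect_error(CohortCounts(c(100, 0, 0)), "broken cohort")
  expect_error(buildLifeTable(CohortCounts(c(10, 5)), radix = -1),
               "radix")
  expect_error(averageMortality(buildLifeTable(CohortCounts(50))),
               "no defined qx")
})

test_that("life tables survive a write/read round trip", {
  lt <- buildLifeTable(CohortCounts(maleCounts(), sex = "male"),
                       radix = 1000)
  path <- tempfile(fileext = ".tsv")
  writeLifeTable(lt, path)
  back <- read.delim(path)
  expect_equal(back$lx, lx(lt), tolerance = 1e-9)
  expect_equal(back$ex, ex(lt), tolerance = 1e-9)
  expect_equal(parseAgeBounds(back$age)$lo, (0:9) * 3)
})
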