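#' Configuration of the individual-based mark-recapture simulator
#'
#' Holds every parameter of the synthetic population: monthly age- and
#' sex-specific survival, the pulse-breeding calendar, the litter-size
#' distribution, the neonate sex ratio, the heterogeneous per-occasion
#' capture-probability distribution, the trapping design, and the growth
#' model used for simulated weighing series. Defaults reproduce the
#' studied alpine-meadow pika population: juvenile monthly survival 0.80
#' (about one half of a cohort clears its first 3-month class), adult
#' monthly survival 0.68 for females and 0.58 for males, two litters per
#' female per season with 96% of litters in April-June and the rest in
#' July-August, litter sizes `1 + Binomial(6, 0.595)` (support 1-7, mean
#' 4.57), an even neonate sex ratio, and per-occasion capture
#' probabilities drawn once per individual from a right-skewed
#' `Beta(1.5, 4)` (mean about 0.27) to exercise capture heterogeneity.
#'
#' @slot seed Integer seed; all randomness flows from it.
#' @slot nFounders Founder adults (even sex split).
#' @slot monthlySurvival Named list `female`/`male`, each
#'   `c(juvenile = , adult = )` monthly survival probabilities.
#' @slot juvenileMonths Age (months) below which the juvenile survival and
#'   capture rules apply.
#' @slot maturityMonths Age at first reproduction, months.
#' @slot breedingMonths Calendar months of the main breeding pulse.
#' @slot lateBreedingMonths Calendar months of the minor late pulse.
#' @slot monthlyBreedingProb Per-female litter probability in a main
#'   breeding month (2/3 of 0.96 by default, so a season yields on average
#'   two litters, at least a month apart).
#' @slot lateBreedingProb Per-female litter probability in a late month.
#' @slot litterProb Probabilities of litter sizes 1..7.
#' @slot neonateFemaleFraction Probability a neonate is female.
#' @slot captureShape Beta shape parameters of the per-individual
#'   per-occasion capture probability.
#' @slot occasionsPerSession Trap days per monthly session.
#' @slot horizonMonths Simulated duration in months (month 1 is April,
#'   the start of the breeding season).
#' @slot growth A [GrowthParams-class] for simulated growth series.
#' @slot growthNoiseSD Relative (multiplicative) measurement noise of
#'   simulated masses.
#' @seealso [simConfig()], [simulatePopulation()]
#' @export
setClass("SimConfig",
  representation(seed = "integer", nFounders = "integer",
                 monthlySurvival = "list", juvenileMonths = "numeric",
                 maturityMonths = "numeric", breedingMonths = "integer",
                 lateBreedingMonths = "integer",
                 monthlyBreedingProb = "numeric",
                 lateBreedingProb = "numeric", litterProb = "numeric",
                 neonateFemaleFraction = "numeric",
                 captureShape = "numeric", occasionsPerSession = "integer",
                 horizonMonths = "integer", growth = "GrowthParams",
                 growthNoiseSD = "numeric")
)

setValidity("SimConfig", function(object) {
  msg <- character()
  sv <- unlist(object@monthlySurvival)
  if (!all(c("female", "male") %in% names(object@monthlySurvival)))
    msg <- c(msg, "monthlySurvival needs 'female' and 'male' entries")
  if (any(sv < 0 | sv > 1)) msg <- c(msg, "survival probabilities not in [0,1]")
  if (length(object@litterProb) != 7L || any(object@litterProb < 0) ||
      abs(sum(object@litterProb) - 1) > 1e-8)
    msg <- c(msg, "litterProb must be 7 probabilities summing to 1")
  p <- c(object@monthlyBreedingProb, object@lateBreedingProb,
         object@neonateFemaleFraction)
  if (any(p < 0 | p > 1)) msg <- c(msg, "breeding/sex probabilities not in [0,1]")
  if (object@growthNoiseSD < 0) msg <- c(msg, "growthNoiseSD must be >= 0")
  if (any(object@captureShape <= 0)) msg <- c(msg, "captureShape must be positive")
  if (object@horizonMonths < 1L) msg <- c(msg, "horizonMonths must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param seed,nFounders,monthlySurvival,juvenileMonths,maturityMonths
#'   See slots.
#' @param breedingMonths,lateBreedingMonths,monthlyBreedingProb,lateBreedingProb
#'   See slots.
#' @param litterProb,neonateFemaleFraction,captureShape,occasionsPerSession
#'   See slots.
#' @param horizonMonths,growth,growthNoiseSD See slots.
#' @export
simConfig <- function(seed = 1L,
                      nFounders = 200L,
                      monthlySurvival = list(
                        female = c(juvenile = 0.80, adult = 0.68),
                        male = c(juvenile = 0.80, adult = 0.58)),
                      juvenileMonths = 3,
                      maturityMonths = 12,
                      breedingMonths = 4:6,
                      lateBreedingMonths = 7:8,
                      monthlyBreedingProb = 2 / 3 * 0.96,
                      lateBreedingProb = 0.04,
                      litterProb = stats::dbinom(0:6, 6, 0.595),
                      neonateFemaleFraction = 0.5,
                      captureShape = c(1.5, 4),
                      occasionsPerSession = 7L,
                      horizonMonths = 36L,
                      growth = GrowthParams(6.5266, 12.1787),
                      growthNoiseSD = 0.02) {
  new("SimConfig", seed = as.integer(seed), nFounders = as.integer(nFounders),
      monthlySurvival = monthlySurvival, juvenileMonths = juvenileMonths,
      maturityMonths = maturityMonths,
      breedingMonths = as.integer(breedingMonths),
      lateBreedingMonths = as.integer(lateBreedingMonths),
      monthlyBreedingProb = monthlyBreedingProb,
      lateBreedingProb = lateBreedingProb, litterProb = litterProb,
      neonateFemaleFraction = neonateFemaleFraction,
      captureShape = captureShape,
      occasionsPerSession = as.integer(occasionsPerSession),
      horizonMonths = as.integer(horizonMonths), growth = growth,
      growthNoiseSD = growthNoiseSD)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d founders, %d months, seed %d\n",
    object@nFounders, object@horizonMonths, object@seed))
})

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate an individual-based pika population
#'
#' Monthly time step. Each month, mature females litter according to the
#' breeding calendar (main-pulse months with `monthlyBreedingProb`, late
#' months with `lateBreedingProb`; litters of one female always fall in
#' distinct months, hence at least one month apart), neonates receive a
#' sex, and every individual survives the month with its (sex, age-class)
#' probability. Month 1 is April. Replays are deterministic under a fixed
#' config seed.
#'
#' @param cfg A [SimConfig-class].
#' @return data.frame with one row per individual ever alive: `id`, `sex`,
#'   `birthMonth` (non-positive for founders, so founders are adults at
#'   month 1), `deathMonth` (`NA` when alive at the horizon), and
#'   `founder`.
#' @examples
#' pop <- simulatePopulation(simConfig(seed = 7, nFounders = 50,
#'                                     horizonMonths = 12))
#' @export
simulatePopulation <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  withLocalSeed(cfg@seed, {
    n0 <- cfg@nFounders
    sex <- rep(c("female", "male"), length.out = n0)
    birth <- rep.int(as.integer(1 - cfg@maturityMonths), n0)
    death <- rep(NA_integer_, n0)
    founder <- rep(TRUE, n0)
    for (m in seq_len(cfg@horizonMonths)) {
      alive <- which(is.na(death) & birth <= m)
      if (!length(alive)) break
      moy <- (m - 1L) %% 12L + 4L      # month 1 is April
      moy <- (moy - 1L) %% 12L + 1L
      pBreed <- if (moy %in% cfg@breedingMonths) cfg@monthlyBreedingProb
                else if (moy %in% cfg@lateBreedingMonths) cfg@lateBreedingProb
                else 0
      if (pBreed > 0) {
        mothers <- alive[sex[alive] == "female" &
                         (m - birth[alive]) >= cfg@maturityMonths]
        if (length(mothers)) {
          litters <- mothers[stats::runif(length(mothers)) < pBreed]
          if (length(litters)) {
            sizes <- sample.int(7L, length(litters), replace = TRUE,
                                prob = cfg@litterProb)
            nNew <- sum(sizes)
            newSex <- ifelse(
              stats::runif(nNew) < cfg@neonateFemaleFraction,
              "female", "male")
            sex <- c(sex, newSex)
            birth <- c(birth, rep.int(m, nNew))
            death <- c(death, rep(NA_integer_, nNew))
            founder <- c(founder, rep(FALSE, nNew))
          }
        }
      }
      alive <- which(is.na(death) & birth <= m)
      age <- m - birth[alive]
      isF <- sex[alive] == "female"
      isJ <- age < cfg@juvenileMonths
      svF <- cfg@monthlySurvival$female
      svM <- cfg@monthlySurvival$male
      sRate <- ifelse(isF,
                      ifelse(isJ, svF[["juvenile"]], svF[["adult"]]),
                      ifelse(isJ, svM[["juvenile"]], svM[["adult"]]))
      dies <- stats::runif(length(alive)) >= sRate
      death[alive[dies]] <- m
      if (length(sex) > 2e6)
        stop("population exploded beyond 2e6 individuals; check survival")
    }
    data.frame(id = seq_along(sex), sex = sex, birthMonth = birth,
               deathMonth = death, founder = founder)
  })
}

#' Simulate monthly trapping of a simulated population
#'
#' Every individual draws a lifetime per-occasion capture probability from
#' the configured Beta distribution; each monthly session has
#' `occasionsPerSession` trap days, and an individual present that month
#' (weaned: at least one month old; not yet dead) is caught on each
#' occasion independently with its own probability. Marks are permanent.
#' The trapping stream is seeded from the config seed (offset by one), so
#' population and trapping are independently reproducible.
#'
#' @param pop Population event log from [simulatePopulation()].
#' @param cfg The [SimConfig-class] used to generate it.
#' @param months Integer vector of session months (default every month of
#'   the horizon).
#' @return A [CaptureHistory-class]; individuals never available for
#'   capture are kept as all-zero rows. The row metadata `knownAge` flags
#'   individuals first captured while younger than `juvenileMonths`.
#' @export
simulateTrapping <- function(pop, cfg, months = NULL) {
  stopifnot(is(cfg, "SimConfig"))
  if (is.null(months)) months <- seq_len(cfg@horizonMonths)
  if (any(months > cfg@horizonMonths))
    stop("trapping months extend beyond the simulated horizon")
  withLocalSeed(cfg@seed + 1L, {
    n <- nrow(pop)
    pcap <- stats::rbeta(n, cfg@captureShape[1], cfg@captureShape[2])
    occ <- cfg@occasionsPerSession
    caps <- matrix(0L, n, length(months) * occ)
    dm <- ifelse(is.na(pop$deathMonth), Inf, pop$deathMonth)
    for (j in seq_along(months)) {
      m <- months[j]
      avail <- pop$birthMonth + 1 <= m & dm >= m
      cols <- (j - 1L) * occ + seq_len(occ)
      caps[avail, cols] <- stats::rbinom(sum(avail) * occ, 1L, pcap[avail])
    }
    monthCol <- rep(months, each = occ)
    firstCapCol <- apply(caps == 1L, 1L, function(z) which(z)[1])
    firstMonth <- monthCol[firstCapCol]
    knownAge <- !is.na(firstMonth) &
      (firstMonth - pop$birthMonth) < cfg@juvenileMonths
    CaptureHistory(caps,
                   sex = pop$sex, birthMonth = pop$birthMonth,
                   deathMonth = pop$deathMonth, knownAge = knownAge,
                   session = monthCol, month = monthCol,
                   occasion = rep(seq_len(occ), length(months)))
  })
}

#' Known-age cohort counts from a simulated population
#'
#' Builds a [CohortCounts-class] from individuals born during the
#' simulation whose full lifetime was observed (the dynamic-life-table
#' analogue of juveniles first caught young and followed to death).
#' Censored individuals (alive at the horizon) are excluded.
#'
#' @param pop Population event log from [simulatePopulation()].
#' @param sex `"female"`, `"male"` or `"pooled"`.
#' @param classWidth Age-class width in months.
#' @param ch Optional [CaptureHistory-class]: restrict to individuals
#'   flagged `knownAge` (caught as juveniles) rather than using the full
#'   truth record.
#' @param bornBy Only individuals born up to this month enter the cohort;
#'   restricting the birth window keeps right-censoring negligible when
#'   the horizon is much longer than a lifetime.
#' @return A [CohortCounts-class].
#' @export
knownAgeCohort <- function(pop, sex = "pooled", classWidth = 3, ch = NULL,
                           bornBy = Inf) {
  keep <- pop$birthMonth >= 1 & pop$birthMonth <= bornBy &
    !is.na(pop$deathMonth)
  if (sex != "pooled") keep <- keep & pop$sex == sex
  if (!is.null(ch)) {
    ka <- SummarizedExperiment::rowData(ch)$knownAge
    keep <- keep & ka
  }
  life <- pop$deathMonth[keep] - pop$birthMonth[keep]
  if (!length(life)) stop("no complete known-age lifetimes in simulation")
  nClasses <- max(life %/% classWidth) + 1L
  alive <- vapply(seq_len(nClasses) - 1L,
                  function(k) sum(life >= k * classWidth), integer(1))
  CohortCounts(alive, sex = sex, classWidth = classWidth)
}

#' Aggregate a capture history into a triple-catch record
#'
#' Counts captures over three sessions: `B1`, `B2` are individuals caught
#' in the first and second session; `R13` and `R23` those caught in the
#' first (resp. second) session that were recaptured in the third.
#'
#' @param ch A [CaptureHistory-class].
#' @param sessions Three session identifiers, in chronological order.
#' @param sex Optional filter (`"female"`/`"male"`).
#' @return data.frame with one row: `B1`, `R13`, `B2`, `R23` and the
#'   computed `Shat` (NA when undefined).
#' @export
tripleCatchFromHistory <- function(ch, sessions, sex = NULL) {
  stopifnot(is(ch, "CaptureHistory"))
  if (length(sessions) != 3L) stop("exactly three sessions required")
  cd <- SummarizedExperiment::colData(ch)
  m <- SummarizedExperiment::assay(ch, "captures")
  if (!is.null(sex)) m <- m[SummarizedExperiment::rowData(ch)$sex == sex, ,
                            drop = FALSE]
  caughtIn <- vapply(sessions, function(s)
    rowSums(m[, cd$session == s, drop = FALSE]) > 0, logical(nrow(m)))
  B1 <- sum(caughtIn[, 1]); B2 <- sum(caughtIn[, 2])
  R13 <- sum(caughtIn[, 1] & caughtIn[, 3])
  R23 <- sum(caughtIn[, 2] & caughtIn[, 3])
  Shat <- suppressWarnings(
    tripleCatchSurvival(B1, R13, B2, R23, undefinedAsNA = TRUE))
  data.frame(B1 = B1, R13 = R13, B2 = B2, R23 = R23, Shat = Shat)
}

#' Simulate daily-weighing growth series
#'
#' Masses follow the configured closed-form growth trajectory with
#' multiplicative Gaussian measurement noise, one series per subject.
#'
#' @param cfg A [SimConfig-class] (uses its `growth` parameters, noise SD
#'   and seed, offset by two from the population stream).
#' @param nSubjects Number of subjects.
#' @param times Measurement ages (model time units).
#' @param m0 Initial mass (model mass units).
#' @return data.frame with columns `subject`, `age`, `mass`.
#' @export
simulateGrowthSeries <- function(cfg, nSubjects,
                                 times = seq(0, 1, by = 0.02), m0 = 0.01) {
  stopifnot(is(cfg, "SimConfig"))
  if (nSubjects < 1) stop("need at least one subject")
  withLocalSeed(cfg@seed + 2L, {
    mu <- growthClosedForm(times, cfg@growth, m0)
    do.call(rbind, lapply(seq_len(nSubjects), function(s) {
      noise <- 1 + stats::rnorm(length(times), 0, cfg@growthNoiseSD)
      data.frame(subject = s, age = times, mass = pmax(mu * noise, 1e-12))
    }))
  })
}
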