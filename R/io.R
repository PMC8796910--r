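#' Path to a packaged demographic table
#'
#' The package ships the published plateau pika demographic tables from a
#' three-year (1989-1991) mark-recapture study of an enclosed alpine-meadow
#' population as UTF-8 tab-separated files:
#'
#' * `life_table_male.tsv`, `life_table_female.tsv` - known-age cohort
#'   life tables (counts, printed `lx`, `qx`, `ex`).
#' * `expectancy_female_radix1000.tsv`, `expectancy_male_radix1000.tsv` -
#'   radix-1000 life-expectancy tables with printed `Lx`, `Tx`, `ex`.
#' * `adult_triple_catch.tsv`, `juvenile_triple_catch.tsv` - monthly
#'   triple-catch session counts by sex with the printed estimates.
#' * `fecundity_female.tsv` - age-specific fecundity records.
#' * `reproductive_value_female.tsv` - survivorship, fertility and printed
#'   reproductive values.
#' * `vital_rates_mammals.tsv` - the 65-species comparative vital-rates
#'   table (46 complete rows); missing values marked with a filled circle.
#' * `life_history_traits.tsv` - summary trait means (masses, ages).
#'
#' @param file File name within the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Full path (or a vector of available file names).
#' @examples
#' pikaExtdata()
#' readVitalRates(pikaExtdata("vital_rates_mammals.tsv"))[1:3, 1:4]
#' @export
pikaExtdata <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "pikaDemog")))
  path <- system.file("extdata", file, package = "pikaDemog")
  if (path == "") stop("no packaged table called '", file, "'")
  path
}

# shared delimited-text reader: UTF-8, schema check with a useful error,
# configurable missing-value markers
readDemographyTable <- function(path, required, sep = "\t",
                                na = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, na.strings = na,
                          fileEncoding = "UTF-8", check.names = FALSE,
                          strip.white = TRUE)
  if (!nrow(tb)) stop("empty table: ", path)
  missing <- setdiff(required, names(tb))
  if (length(missing))
    stop("schema mismatch in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  tb
}

#' Parse age-class labels into numeric bounds
#'
#' Accepts labels like `"0-3"` (en-dash or plain hyphen); classes are
#' half-open `[lo, hi)` months.
#'
#' @param labels Character vector of class labels.
#' @return data.frame with `lo` and `hi` in months.
#' @examples
#' parseAgeBounds(c("0-3", "3-6"))
#' @export
parseAgeBounds <- function(labels) {
  parts <- strsplit(gsub("\u2013", "-", as.character(labels)), "-",
                    fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("unparseable age label(s): ",
         paste(labels[bad], collapse = ", "))
  lo <- as.numeric(vapply(parts, `[`, "", 1L))
  hi <- as.numeric(vapply(parts, `[`, "", 2L))
  if (anyNA(lo) || anyNA(hi) || any(hi <= lo))
    stop("age labels must be numeric increasing ranges")
  data.frame(lo = lo, hi = hi)
}

#' Read a growth series table
#'
#' Expects columns `subject`, `age`, `mass`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return data.frame suitable for [fitGrowthModel()].
#' @export
readGrowthSeries <- function(path, sep = "\t") {
  readDemographyTable(path, c("subject", "age", "mass"), sep = sep)
}

#' Run the full demographic analysis pipeline
#'
#' Chains the pipeline stages on a set of input tables (the packaged study
#' tables by default): cohort life tables for each sex, triple-catch
#' survival summaries, the fertility and reproductive-value schedules, the
#' net reproductive rate, the multi-species fitness ranking, and the
#' tempo classification. Any stage failure is re-raised with the stage
#' name attached.
#'
#' @param cohortMale,cohortFemale Paths to known-age cohort tables.
#' @param tripleCatch Path to the adult triple-catch table.
#' @param fecundity Path to the fecundity table.
#' @param reproValue Path to a survivorship/fertility schedule with
#'   columns `lx`, `mx` (and optionally a published `lxmx`); set `NULL`
#'   to derive the schedule from the female life table and the fertility
#'   schedule instead.
#' @param vitalRates Path to the multi-species vital-rates table.
#' @param radix Radix of the reported life tables.
#' @param daughterFraction Passed to [fertilitySchedule()].
#' @param alphaYears Age at first reproduction in years, for the tempo
#'   statistic.
#' @param averageFertility Average fertility used for the tempo statistic;
#'   defaults to the survivorship-weighted mean of the nonzero fertility
#'   classes.
#' @param outDir Optional directory; when given, result tables are written
#'   there as TSV.
#'
#' @return A list with elements `lifeTables` (per sex), `survival` (per
#'   sex mean/sum), `fertility`, `reproductiveValue`, `R0`, `ranking`,
#'   `tempo`, and `summary` (named key numbers).
#' @examples
#' rep <- runPipeline()
#' rep$summary
#' @export
runPipeline <- function(cohortMale = pikaExtdata("life_table_male.tsv"),
                        cohortFemale = pikaExtdata("life_table_female.tsv"),
                        tripleCatch = pikaExtdata("adult_triple_catch.tsv"),
                        fecundity = pikaExtdata("fecundity_female.tsv"),
                        reproValue =
                          pikaExtdata("reproductive_value_female.tsv"),
                        vitalRates = pikaExtdata("vital_rates_mammals.tsv"),
                        radix = 1000, daughterFraction = 0.5,
                        alphaYears = 1, averageFertility = NULL,
                        outDir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  lts <- stage("life_table", {
    list(male = buildLifeTable(readCohortCounts(cohortMale, sex = "male"),
                               radix = radix),
         female = buildLifeTable(readCohortCounts(cohortFemale,
                                                  sex = "female"),
                                 radix = radix))
  })
  surv <- stage("capture_survival", {
    tc <- readTripleCatch(tripleCatch)
    bySex <- split(tc, if ("sex" %in% names(tc)) tc$sex else "pooled")
    lapply(bySex, function(d)
      suppressWarnings(meanPeriodicSurvival(d))[c("mean", "sum", "n")])
  })
  fert <- stage("reproduction", {
    fertilitySchedule(readFecundity(fecundity),
                      daughterFraction = daughterFraction)
  })
  rv <- stage("reproduction", {
    if (!is.null(reproValue)) {
      sched <- readDemographyTable(reproValue, c("lx", "mx"))
      reproductiveValueSchedule(sched$lx, sched$mx,
                                lxmx = sched[["lxmx"]])
    } else {
      lxF <- lx(lts$female)
      k <- min(length(lxF), nrow(fert))
      reproductiveValueSchedule(lxF[seq_len(k)], fert$mx[seq_len(k)])
    }
  })
  R0 <- stage("reproduction",
              netReproductiveRate(rv$lx, rv$mx, lxmx = rv$lxmx))
  ranking <- stage("fitness_tempo", {
    rankVitalRates(readVitalRates(vitalRates))
  })
  if (is.null(averageFertility)) {
    nz <- rv$mx > 0
    averageFertility <- sum(rv$lxmx[nz]) / sum(rv$lx[nz])
  }
  tempo <- stage("fitness_tempo",
                 tempoClassification(averageFertility, alphaYears))
  pikaRow <- ranking[grepl("curzoniae", ranking$species), , drop = FALSE]
  summary <- c(
    q0_male = unname(qx(lts$male)[1]),
    V_21_24 = if (nrow(rv) >= 8) rv$Vx[8] else NA_real_,
    q0_female = unname(qx(lts$female)[1]),
    mean_S_adult = unname(surv[[1]]$mean),
    R0 = R0,
    r_pika = if (nrow(pikaRow)) pikaRow$r[1] else NA_real_,
    rank_pika = if (nrow(pikaRow)) pikaRow$rank[1] else NA_real_,
    tempo_T = tempo$T[1]
  )
  out <- list(lifeTables = lts, survival = surv, fertility = fert,
              reproductiveValue = rv, R0 = R0, ranking = ranking,
              tempo = tempo, summary = summary)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeLifeTable(lts$male, file.path(outDir, "life_table_male_out.tsv"))
    writeLifeTable(lts$female,
                   file.path(outDir, "life_table_female_out.tsv"))
    write.table(fert, file.path(outDir, "fertility_schedule.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rv, file.path(outDir, "reproductive_value.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ranking, file.path(outDir, "fitness_ranking.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(key = names(summary), value = summary),
                file.path(outDir, "summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
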