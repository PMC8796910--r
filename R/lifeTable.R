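#' Build a dynamic (cohort) life table from known-age counts
#'
#' Constructs the classical cohort life table. Survivorship is the empirical
#' fraction still alive, scaled to the radix: `lx = alive[x]/alive[1] *
#' radix`. Deaths are successive differences, with the whole remaining
#' cohort dying inside the terminal class, so `sum(dx)` equals the radix
#' exactly. Within-class mortality is `qx = dx/lx`.
#'
#' Person-time columns use the midpoint rule: `Lx = (lx + lx[x+1])/2`, and
#' for the terminal class `Lx = lx/2` (deaths spread evenly over one class
#' width). `Tx` is the tail sum of `Lx` and `ex = Tx/lx`, reported in
#' class-width units; multiply by [classWidth()] for months. A published
#' `Lx` column can be substituted via the `Lx` argument, in which case `Tx`
#' and `ex` are derived from it unchanged.
#'
#' @param counts A [CohortCounts-class] object.
#' @param radix Scaling base for `lx` (1 by default; 1000 is the common
#'   presentation scale).
#' @param Lx Optional numeric vector overriding the midpoint `Lx` column
#'   (same length as the counts, on the radix scale).
#' @param expectancy If `FALSE`, the `Lx`, `Tx`, `ex` columns are left `NA`.
#'
#' @return A [LifeTable-class] object.
#' @examples
#' cc <- CohortCounts(c(228, 116, 51, 35, 22, 11, 5, 3, 2, 1), sex = "male")
#' lt <- buildLifeTable(cc)
#' qx(lt)[1]   # 112/228 = 0.4912
#' @seealso [lifeExpectancyColumns()], [averageMortality()]
#' @export
buildLifeTable <- function(counts, radix = 1, Lx = NULL, expectancy = TRUE) {
  stopifnot(is(counts, "CohortCounts"))
  validObject(counts)
  if (radix <= 0) stop("radix must be positive")
  alive <- counts@alive
  n <- length(alive)
  lxv <- alive / alive[1] * radix
  dcounts <- c(-diff(alive), alive[n])
  dxv <- dcounts / alive[1] * radix
  qxv <- dcounts / alive
  w <- counts@classWidth
  tb <- data.frame(
    age_lo = (seq_len(n) - 1) * w,
    age_hi = seq_len(n) * w,
    alive = alive,
    lx = lxv, dx = dxv, qx = qxv,
    Lx = NA_real_, Tx = NA_real_, ex = NA_real_
  )
  lt <- new("LifeTable", table = tb, radix = radix, classWidth = w,
            sex = counts@sex)
  if (expectancy) lt <- lifeExpectancyColumns(lt, Lx = Lx)
  lt
}

#' Fill the person-time and life-expectancy columns of a life table
#'
#' `Lx` is the person-time lived within each class in class-width units
#' (midpoint rule, terminal class `lx/2`), `Tx` the person-time at and
#' beyond the class, and `ex = Tx/lx` the remaining life expectancy in
#' class-width units.
#'
#' @param lt A [LifeTable-class] with the `lx` column present.
#' @param Lx Optional replacement `Lx` column (e.g. a published one); `Tx`
#'   and `ex` are then accumulated from it as given.
#'
#' @return The [LifeTable-class] with `Lx`, `Tx`, `ex` filled.
#' @export
lifeExpectancyColumns <- function(lt, Lx = NULL) {
  stopifnot(is(lt, "LifeTable"))
  lxv <- lt@table$lx
  n <- length(lxv)
  if (any(lxv == 0 & rev(cummax(rev(lxv))) > 0))
    stop("lx drops to zero before a class with survivors (broken cohort)")
  if (is.null(Lx)) {
    Lx <- c((lxv[-n] + lxv[-1]) / 2, lxv[n] / 2)
  } else {
    if (length(Lx) != n) stop("supplied Lx has wrong length")
  }
  Txv <- rev(cumsum(rev(Lx)))
  lt@table$Lx <- Lx
  lt@table$Tx <- Txv
  lt@table$ex <- Txv / lxv
  validObject(lt)
  lt
}

#' Build a life table from a published survivorship column
#'
#' Published life tables often print `lx` on a radix scale (per 1000)
#' without the underlying counts. This constructor rebuilds the remaining
#' columns from `lx` alone: `dx` as successive differences (terminal class
#' absorbs the remainder), `qx = dx/lx`, and the person-time columns by
#' the same midpoint rule as [buildLifeTable()].
#'
#' @param lxValues Non-increasing positive survivorship values; the first
#'   element is taken as the radix.
#' @param sex,classWidth As in [CohortCounts()].
#' @param Lx,expectancy As in [buildLifeTable()].
#' @return A [LifeTable-class].
#' @export
lifeTableFromLx <- function(lxValues, sex = "pooled", classWidth = 3,
                            Lx = NULL, expectancy = TRUE) {
  if (!length(lxValues)) stop("empty survivorship series")
  if (any(lxValues <= 0)) stop("lx must be positive (broken cohort)")
  up <- which(diff(lxValues) > 0)
  if (length(up))
    stop("lx increases at age class ", up[1] - 1L, " -> ", up[1])
  n <- length(lxValues)
  dxv <- c(-diff(lxValues), lxValues[n])
  tb <- data.frame(
    age_lo = (seq_len(n) - 1) * classWidth,
    age_hi = seq_len(n) * classWidth,
    alive = NA_integer_,
    lx = lxValues, dx = dxv, qx = dxv / lxValues,
    Lx = NA_real_, Tx = NA_real_, ex = NA_real_
  )
  lt <- new("LifeTable", table = tb, radix = lxValues[1],
            classWidth = classWidth, sex = sex)
  if (expectancy) lt <- lifeExpectancyColumns(lt, Lx = Lx)
  lt
}

#' Mean and spread of age-specific mortality
#'
#' Arithmetic mean and sample standard deviation of the `qx` column. The
#' terminal class has `qx = 1` by construction (everyone left dies in it),
#' so it is excluded by default.
#'
#' @param lt A [LifeTable-class].
#' @param excludeTerminal Drop the final class from the average (default
#'   `TRUE`).
#'
#' @return Named numeric vector `c(mean, sd, n)`.
#' @examples
#' lt <- buildLifeTable(CohortCounts(c(228, 116, 51, 35, 22, 11, 5, 3, 2, 1),
#'                                   sex = "male"))
#' averageMortality(lt)["mean"]   # 0.4462
#' @export
averageMortality <- function(lt, excludeTerminal = TRUE) {
  stopifnot(is(lt, "LifeTable"))
  q <- lt@table$qx
  if (excludeTerminal) q <- q[-length(q)]
  q <- q[!is.na(q)]
  if (!length(q)) stop("no defined qx values")
  c(mean = mean(q), sd = stats::sd(q), n = length(q))
}

#' Read known-age cohort counts from a delimited text file
#'
#' Expects a header with at least the columns `age` (class label such as
#' `"0-3"`, en-dash accepted) and `alive`. An optional `sex` column (single
#' value) sets the sex label.
#'
#' @param path File path (TSV by default).
#' @param sex Sex label; taken from the file's `sex` column when present.
#' @param classWidth Age-class width in months.
#' @param sep Field separator.
#' @return A [CohortCounts-class] object.
#' @export
readCohortCounts <- function(path, sex = "pooled", classWidth = 3,
                             sep = "\t") {
  tb <- readDemographyTable(path, c("age", "alive"), sep = sep)
  if ("sex" %in% names(tb) && length(unique(tb$sex)) == 1L)
    sex <- as.character(tb$sex[1])
  CohortCounts(tb$alive, sex = sex, classWidth = classWidth)
}

#' Write a life table as delimited text
#'
#' Columns follow the conventional presentation order: age label, `alive`,
#' `lx`, `dx`, `qx`, `Lx`, `Tx`, `ex`.
#'
#' @param lt A [LifeTable-class].
#' @param path Output file path.
#' @param sep Field separator (tab by default).
#' @return `path`, invisibly.
#' @export
writeLifeTable <- function(lt, path, sep = "\t") {
  stopifnot(is(lt, "LifeTable"))
  tb <- lt@table
  out <- data.frame(age = paste0(tb$age_lo, "-", tb$age_hi), tb[-(1:2)])
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
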