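#' @import methods
#' @importFrom stats lm coef rbinom rbeta rnorm runif sd setNames qchisq
#'   pchisq complete.cases
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
NULL

#' Known-age cohort counts for one sex
#'
#' Counts of known-age individuals (first captured as juveniles and followed
#' for life) alive at the start of each age class. Age classes are half-open
#' intervals `[x, x + classWidth)` months wide, three months by default.
#'
#' @slot sex Label: `"female"`, `"male"` or `"pooled"`.
#' @slot classWidth Width of one age class in months.
#' @slot alive Integer vector, individuals alive at the start of each class.
#'   Must be positive and non-increasing; the whole cohort dies within the
#'   terminal class.
#'
#' @seealso [CohortCounts()], [buildLifeTable()]
#' @export
setClass("CohortCounts",
  representation(sex = "character", classWidth = "numeric", alive = "integer"),
  prototype(sex = "pooled", classWidth = 3)
)

setValidity("CohortCounts", function(object) {
  msg <- character()
  if (!object@sex %in% c("female", "male", "pooled"))
    msg <- c(msg, "sex must be 'female', 'male' or 'pooled'")
  if (length(object@classWidth) != 1L || object@classWidth <= 0)
    msg <- c(msg, "classWidth must be a single positive number")
  if (length(object@alive) == 0L)
    msg <- c(msg, "alive counts are empty")
  else {
    if (any(object@alive <= 0L))
      msg <- c(msg, "alive counts must be positive (broken cohort)")
    up <- which(diff(object@alive) > 0L)
    if (length(up))
      msg <- c(msg, sprintf(
        "alive counts increase at age class %d -> %d", up[1] - 1L, up[1]))
    if (length(object@alive) && object@alive[1] <= 0L)
      msg <- c(msg, "first age class must contain at least one individual")
  }
  if (length(msg)) msg else TRUE
})

#' Construct known-age cohort counts
#'
#' @param alive Positive, non-increasing integer vector: individuals alive at
#'   the start of each age class.
#' @param sex `"female"`, `"male"` or `"pooled"`.
#' @param classWidth Age-class width in months (default 3).
#'
#' @return A [CohortCounts-class] object.
#' @examples
#' CohortCounts(c(228, 116, 51, 35, 22, 11, 5, 3, 2, 1), sex = "male")
#' @export
CohortCounts <- function(alive, sex = "pooled", classWidth = 3) {
  if (length(alive) == 0L) stop("alive counts are empty")
  if (any(is.na(alive))) stop("alive counts contain NA")
  if (any(abs(alive - round(alive)) > 1e-8))
    stop("alive counts must be whole numbers")
  new("CohortCounts", alive = as.integer(round(alive)), sex = sex,
      classWidth = classWidth)
}

setMethod("show", "CohortCounts", function(object) {
  cat("CohortCounts:", length(object@alive), "age classes,",
      object@classWidth, "months each, sex =", object@sex, "\n")
  cat("  alive:", paste(object@alive, collapse = " "), "\n")
})

#' Cohort life table
#'
#' Per age class: survivorship `lx` (on the radix scale), deaths `dx`,
#' within-class mortality `qx`, person-time lived `Lx`, remaining person-time
#' `Tx`, and remaining life expectancy `ex` in class-width units.
#'
#' @slot table data.frame with columns `age_lo`, `age_hi` (months), `alive`,
#'   `lx`, `dx`, `qx`, `Lx`, `Tx`, `ex`.
#' @slot radix Scaling base of `lx` (1 or 1000, typically).
#' @slot classWidth Age-class width in months.
#' @slot sex Sex label carried over from the cohort.
#'
#' @seealso [buildLifeTable()], [averageMortality()]
#' @export
setClass("LifeTable",
  representation(table = "data.frame", radix = "numeric",
                 classWidth = "numeric", sex = "character")
)

setValidity("LifeTable", function(object) {
  tb <- object@table
  need <- c("age_lo", "age_hi", "lx", "dx", "qx")
  if (!all(need %in% names(tb)))
    return(paste("table lacks columns:",
                 paste(setdiff(need, names(tb)), collapse = ", ")))
  if (object@radix <= 0) return("radix must be positive")
  if (any(diff(tb$lx) > 1e-9)) return("lx must be non-increasing")
  if (any(tb$qx < -1e-9 | tb$qx > 1 + 1e-9, na.rm = TRUE))
    return("qx must lie in [0, 1]")
  TRUE
})

setMethod("show", "LifeTable", function(object) {
  cat(sprintf("LifeTable (%s): %d classes of %g months, radix %g\n",
              object@sex, nrow(object@table), object@classWidth,
              object@radix))
  print(format(object@table, digits = 4), row.names = FALSE)
})

#' @describeIn LifeTable-class Coerce the life table to a plain data.frame.
#' @param x,row.names,optional,... passed on from the generic.
#' @export
as.data.frame.LifeTable <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  x@table
}

#' Ontogenetic growth model parameters
#'
#' Parameters of the growth law `dm/dt = a * m^0.75 - b * m`: `a` is the
#' taxon-level anabolic constant (mass^0.25 per unit time) and `b` the
#' cell-maintenance constant (per unit time). The implied asymptotic mass is
#' `(a/b)^4`. Units are carried as labels because the constants are only
#' meaningful jointly with the mass scale of the data they were fitted to.
#'
#' @slot a Anabolic constant, positive.
#' @slot b Maintenance constant, positive.
#' @slot massUnit,timeUnit Unit labels.
#'
#' @seealso [growthClosedForm()], [fitGrowthModel()]
#' @export
setClass("GrowthParams",
  representation(a = "numeric", b = "numeric", massUnit = "character",
                 timeUnit = "character"),
  prototype(massUnit = "model", timeUnit = "model")
)

setValidity("GrowthParams", function(object) {
  if (length(object@a) != 1L || length(object@b) != 1L)
    return("a and b must be single numbers")
  if (!is.finite(object@a) || object@a <= 0) return("a must be positive")
  if (!is.finite(object@b) || object@b <= 0) return("b must be positive")
  TRUE
})

#' @rdname GrowthParams-class
#' @param a,b Positive growth constants.
#' @param massUnit,timeUnit Unit labels (defaults `"model"`).
#' @export
GrowthParams <- function(a, b, massUnit = "model", timeUnit = "model") {
  new("GrowthParams", a = a, b = b, massUnit = massUnit, timeUnit = timeUnit)
}

setMethod("show", "GrowthParams", function(object) {
  cat(sprintf(
    "GrowthParams: a = %.4f, b = %.4f (asymptote (a/b)^4 = %.5g %s)\n",
    object@a, object@b, (object@a / object@b)^4, object@massUnit))
})

#' Capture-history matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a binary
#' individuals-by-occasions capture matrix in the `"captures"` assay.
#' Row metadata carries per-individual covariates (`sex`, `birthMonth`,
#' `deathMonth`, `knownAge`); column metadata identifies the trapping
#' `session` (a month index), the calendar `month`, and the `occasion`
#' (trap day) within the session.
#'
#' @seealso [CaptureHistory()], [simulateTrapping()], [frequencyCounts()],
#'   [tripleCatchFromHistory()]
#' @export
setClass("CaptureHistory", contains = "SummarizedExperiment")

setValidity("CaptureHistory", function(object) {
  if (!"captures" %in% SummarizedExperiment::assayNames(object))
    return("assay 'captures' is missing")
  m <- SummarizedExperiment::assay(object, "captures")
  if (!all(m %in% c(0L, 1L))) return("captures must be binary")
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  needR <- c("sex", "birthMonth", "deathMonth", "knownAge")
  needC <- c("session", "month", "occasion")
  if (!all(needR %in% names(rd)))
    return(paste("rowData lacks:", paste(setdiff(needR, names(rd)),
                                         collapse = ", ")))
  if (!all(needC %in% names(cd)))
    return(paste("colData lacks:", paste(setdiff(needC, names(cd)),
                                         collapse = ", ")))
  dm <- ifelse(is.na(rd$deathMonth), Inf, rd$deathMonth)
  if (any(m == 1L & outer(dm, cd$month, `<`)))
    return("captures recorded after death")
  if (any(m == 1L & outer(rd$birthMonth, cd$month, `>`)))
    return("captures recorded before birth")
  TRUE
})

#' Construct a capture history
#'
#' @param captures Binary matrix, individuals in rows, trap occasions in
#'   columns.
#' @param sex Character vector per individual.
#' @param birthMonth,deathMonth Integer month indices; `deathMonth` is `NA`
#'   for individuals alive at the end of observation.
#' @param knownAge Logical: first captured as a juvenile, so age is known.
#' @param session,month,occasion Integer vectors per column: session index,
#'   calendar month index, and trap day within session.
#'
#' @return A [CaptureHistory-class] object.
#' @export
CaptureHistory <- function(captures, sex, birthMonth, deathMonth, knownAge,
                           session, month, occasion) {
  captures <- as.matrix(captures)
  storage.mode(captures) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(captures = captures),
    rowData = S4Vectors::DataFrame(sex = sex, birthMonth = birthMonth,
                                   deathMonth = deathMonth,
                                   knownAge = knownAge),
    colData = S4Vectors::DataFrame(session = session, month = month,
                                   occasion = occasion)
  )
  new("CaptureHistory", se)
}

setMethod("show", "CaptureHistory", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf(
    "CaptureHistory: %d individuals x %d occasions in %d sessions\n",
    nrow(object), ncol(object), length(unique(cd$session))))
})
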