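#' Triple-catch survival estimator
#'
#' Estimates per-interval survival from three consecutive trapping sessions:
#' `Shat = (B2 * R13) / (B1 * (R23 - 1))`, where `B1`, `B2` are the numbers
#' captured in sessions I and II, and `R13`, `R23` the numbers marked in
#' session I (resp. II) that were recaptured in session III. With monthly
#' sessions this is a monthly survival rate.
#'
#' The estimator is undefined when `B1 = 0` or `R23 <= 1`. Sampling noise
#' can push `Shat` above 1; such values are returned as-is with a warning
#' (never clipped), so simulation studies see the estimator's raw behaviour.
#'
#' @param B1,R13,B2,R23 Non-negative integer counts (vectorised). `R13`
#'   cannot exceed `B1`.
#' @param undefinedAsNA If `TRUE`, undefined records yield `NA` with a
#'   warning instead of an error (used when averaging over many records).
#'
#' @return Numeric vector of survival estimates.
#' @examples
#' tripleCatchSurvival(B1 = 10, R13 = 5, B2 = 85, R23 = 79)   # 0.5449
#' @seealso [meanPeriodicSurvival()], [tripleCatchFromHistory()]
#' @export
tripleCatchSurvival <- function(B1, R13, B2, R23, undefinedAsNA = FALSE) {
  counts <- cbind(B1, R13, B2, R23)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (any(R13 > B1, na.rm = TRUE)) stop("R13 cannot exceed B1")
  und <- is.na(B1) | is.na(R23) | B1 == 0 | R23 <= 1
  if (any(und)) {
    if (!undefinedAsNA)
      stop("survival estimate undefined: needs B1 > 0 and R23 > 1")
    warning(sum(und), " record(s) with undefined estimate skipped")
  }
  s <- ifelse(und, NA_real_, (B2 * R13) / (B1 * (R23 - 1)))
  if (any(s > 1, na.rm = TRUE))
    warning("estimate(s) exceed 1 (reported unclipped): ",
            paste(format(s[!is.na(s) & s > 1], digits = 4), collapse = ", "))
  s
}

#' Mean periodic survival over a set of triple-catch records
#'
#' Averages survival estimates over records, skipping undefined ones (with
#' a warning) and reporting the running sum alongside the mean.
#'
#' @param x Either a numeric vector of survival estimates, or a data.frame
#'   with columns `B1`, `R13`, `B2`, `R23` from which estimates are
#'   computed.
#'
#' @return A list with `mean`, `sum`, `n` (records used) and the individual
#'   `estimates` (NA where undefined).
#' @examples
#' rec <- data.frame(B1 = c(10, 27), R13 = c(5, 22),
#'                   B2 = c(85, 35), R23 = c(79, 34))
#' meanPeriodicSurvival(rec)$mean
#' @export
meanPeriodicSurvival <- function(x) {
  if (is.data.frame(x)) {
    need <- c("B1", "R13", "B2", "R23")
    if (!all(need %in% names(x)))
      stop("data.frame needs columns ", paste(need, collapse = ", "))
    est <- suppressWarnings(
      tripleCatchSurvival(x$B1, x$R13, x$B2, x$R23, undefinedAsNA = TRUE))
    if (anyNA(est))
      warning(sum(is.na(est)), " undefined record(s) excluded from the mean")
  } else {
    est <- as.numeric(x)
  }
  ok <- !is.na(est)
  if (!any(ok)) stop("all survival estimates are undefined")
  list(mean = mean(est[ok]), sum = sum(est[ok]), n = sum(ok),
       estimates = est)
}

#' Read triple-catch session records from delimited text
#'
#' Expects columns `B1`, `R13`, `B2`, `R23`; any additional label columns
#' (`year`, `month`, `sex`, ...) are kept. A `Shat` column with the
#' computed estimates is appended.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return data.frame of records with appended `Shat`.
#' @export
readTripleCatch <- function(path, sep = "\t") {
  tb <- readDemographyTable(path, c("B1", "R13", "B2", "R23"), sep = sep)
  tb$Shat <- suppressWarnings(
    tripleCatchSurvival(tb$B1, tb$R13, tb$B2, tb$R23, undefinedAsNA = TRUE))
  tb
}
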