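#' Composite fitness index from fecundity and monthly mortalities
#'
#' A fecundity-minus-mortality balance over a 12-month horizon, used to
#' compare population growth potential across mammal species:
#' \deqn{r = b\,\frac{1 - 2Z + Z^{13}}{1 - Z} - M\,\frac{1 - M^{12}}{1 - M}}
#' where `b` is annual fecundity (daughters-equivalent per female per
#' year), `Z` monthly juvenile mortality and `M` monthly adult mortality.
#' The closed form is the geometric-series collapse of
#' `b * (1 - sum(Z^k)) - sum(M^k)` over `k = 1..12` months; the horizon is
#' exposed as a parameter but defaults to 12 months, which yields the
#' printed exponents 13 and 12. With `Z = M = 0` the index reduces to `b`.
#'
#' @param b Annual fecundity, non-negative (vectorised).
#' @param Z,M Monthly juvenile and adult mortality in `[0, 1)`. `NA`
#'   propagates to an `NA` result (missing vital rates are never treated as
#'   zero).
#' @param horizonMonths Mortality horizon in months (default 12).
#'
#' @return Numeric vector of fitness indices (may be negative).
#' @examples
#' fitnessIndex(b = 2.10, Z = 0.418, M = 0.324)   # 0.1125, plateau pika
#' fitnessIndex(b = 2.73, Z = 0.157, M = 0.047)   # 2.1722, American pika
#' @seealso [rankVitalRates()], [tempoClassification()]
#' @export
fitnessIndex <- function(b, Z, M, horizonMonths = 12) {
  if (any(b < 0, na.rm = TRUE)) stop("b must be non-negative")
  if (any(Z >= 1 | M >= 1, na.rm = TRUE))
    stop("Z = 1 or M = 1 makes the index singular")
  if (any(Z < 0 | M < 0, na.rm = TRUE)) stop("mortalities must be in [0, 1)")
  h <- horizonMonths
  b * (1 - 2 * Z + Z^(h + 1)) / (1 - Z) - M * (1 - M^h) / (1 - M)
}

#' Classify life-history tempo on the fast-slow continuum
#'
#' The tempo statistic is `T = F / alpha` (average fertility over age at
#' first reproduction in years). Species with `T > 0.60` are "fast"
#' (early maturity, short life, high fertility), `T < 0.15` "slow", and
#' otherwise intermediate.
#'
#' @param F Average fertility, non-negative (vectorised).
#' @param alpha Age at first reproduction in years, positive.
#' @param fast,slow Classification thresholds (defaults 0.60 and 0.15).
#'
#' @return A data.frame with columns `T` and `tempo`.
#' @examples
#' tempoClassification(F = 1.972, alpha = 1)   # fast
#' @export
tempoClassification <- function(F, alpha, fast = 0.60, slow = 0.15) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  if (any(F < 0)) stop("F must be non-negative")
  if (slow >= fast) stop("thresholds must satisfy slow < fast")
  T <- F / alpha
  tempo <- ifelse(T > fast, "fast", ifelse(T < slow, "slow", "intermediate"))
  data.frame(T = T, tempo = tempo)
}

#' Rank a multi-species vital-rates table by fitness index
#'
#' Computes the fitness index for every species with complete `b`, `Z`, `M`
#' and ranks species in descending order of `r`. Species with missing vital
#' rates get `NA` for both `r` and `rank` (they are flagged, never
#' zero-filled).
#'
#' @param vitals data.frame with columns `b`, `Z`, `M` (one row per
#'   species); other columns are carried through.
#' @param horizonMonths Passed to [fitnessIndex()].
#'
#' @return The table with appended columns `r` and `rank` (1 = highest
#'   fitness).
#' @examples
#' vr <- readVitalRates(pikaExtdata("vital_rates_mammals.tsv"))
#' rk <- rankVitalRates(vr)
#' rk[rk$species == "Ochotona curzoniae", c("r", "rank")]
#' @export
rankVitalRates <- function(vitals, horizonMonths = 12) {
  if (!nrow(vitals)) {
    vitals$r <- numeric(0)
    vitals$rank <- integer(0)
    return(vitals)
  }
  need <- c("b", "Z", "M")
  if (!all(need %in% names(vitals)))
    stop("vital-rates table needs columns ", paste(need, collapse = ", "))
  vitals$r <- fitnessIndex(vitals$b, vitals$Z, vitals$M,
                           horizonMonths = horizonMonths)
  vitals$rank <- as.integer(rank(-vitals$r, ties.method = "min",
                                 na.last = "keep"))
  vitals
}

#' Read a multi-species vital-rates table
#'
#' Expects columns `species`, `LS`, `lits_per_year`, `b`, `delta`,
#' `S_alpha`, `Z`, `M` and optionally a published `r` column, which is
#' renamed `r_printed` so that [rankVitalRates()] can append a freshly
#' computed `r`. Missing values are marked with a filled circle or an empty
#' field by convention.
#'
#' @param path File path.
#' @param sep Field separator.
#' @param naMarkers Strings treated as missing (default the filled-circle
#'   marker and the empty string).
#' @return data.frame, one row per species.
#' @export
readVitalRates <- function(path, sep = "\t",
                           naMarkers = c("\u25cf", "", "NA")) {
  tb <- readDemographyTable(path, c("species", "b", "Z", "M"), sep = sep,
                            na = naMarkers)
  if ("r" %in% names(tb)) names(tb)[names(tb) == "r"] <- "r_printed"
  tb
}
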