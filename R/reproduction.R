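#' Age-specific fertility schedule from fecundity records
#'
#' For each age class, total offspring is `pregnant * meanLitter` and
#' fertility is the number of daughters per female alive in the class:
#' `mx = total * daughterFraction / n`. The daughter fraction defaults to
#' one half (the conventional 1:1 primary sex ratio), even when the
#' observed neonate ratio deviates slightly.
#'
#' @param records data.frame with columns `n_x` (females alive in class),
#'   `B_x` (pregnant females) and `mean_litter` (mean litter size); extra
#'   columns (age labels, pivotal ages) are carried through.
#' @param daughterFraction Proportion of offspring that are daughters, in
#'   (0, 1]; default 0.5.
#'
#' @return The input data.frame with appended columns `total_offspring`,
#'   `female_offspring` and `mx`.
#' @examples
#' fertilitySchedule(data.frame(n_x = 55, B_x = 41, mean_litter = 4.83))$mx
#' # 1.800
#' @export
fertilitySchedule <- function(records, daughterFraction = 0.5) {
  need <- c("n_x", "B_x", "mean_litter")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "))
  if (daughterFraction <= 0 || daughterFraction > 1)
    stop("daughterFraction must be in (0, 1]")
  with(records, {
    if (any(n_x == 0 & B_x > 0)) stop("n_x = 0 with pregnant females present")
    if (any(B_x > n_x)) stop("pregnant females exceed females alive")
    if (any(B_x < 0) || any(mean_litter < 0)) stop("negative fecundity input")
  })
  tot <- records$B_x * records$mean_litter
  fem <- tot * daughterFraction
  records$total_offspring <- tot
  records$female_offspring <- fem
  records$mx <- ifelse(records$n_x == 0, 0, fem / records$n_x)
  records
}

#' Fisherian reproductive value by age class
#'
#' Reproductive value is the expected present plus future daughter
#' production of a female currently in class `x`, discounted by her
#' survivorship:
#' `Vx = mx + sum(l[t] * m[t], t > x) / l[x]`.
#' The residual reproductive value is the future-only part, `Vx - mx`.
#' Sums run over discrete age classes; `Vx` is invariant to rescaling the
#' survivorship series by a constant (radix independence).
#'
#' @param lx Survivorship series (any radix).
#' @param mx Fertility series (daughters per female per class), same length.
#' @param lxmx Optional replacement for the product `lx * mx`, for working
#'   from a published reproduction column that was rounded independently
#'   of its factors.
#'
#' @return data.frame with `lx`, `mx`, `lxmx`, `Vx`, `RRVx`.
#' @examples
#' v <- reproductiveValueSchedule(lx = c(1000, 63.83, 53.19, 21.28),
#'                                mx = c(0, 2.645, 2.032, 1.250))
#' @export
reproductiveValueSchedule <- function(lx, mx, lxmx = NULL) {
  if (length(lx) != length(mx)) stop("lx and mx have different lengths")
  if (any(mx < 0)) stop("mx must be non-negative")
  n <- length(lx)
  if (is.null(lxmx)) lxmx <- lx * mx
  else if (length(lxmx) != n) stop("lxmx has wrong length")
  future <- rev(cumsum(rev(lxmx))) - lxmx   # sum over t > x
  if (any(lx == 0 & future > 0))
    stop("lx = 0 with nonzero future reproduction")
  Vx <- mx + ifelse(future == 0, 0, future / lx)
  data.frame(lx = lx, mx = mx, lxmx = lxmx, Vx = Vx, RRVx = Vx - mx)
}

#' Net reproductive rate
#'
#' `R0 = sum(lx * mx)` with the survivorship series normalised to
#' `lx[1] = 1`: the expected number of daughters a newborn female produces
#' over her lifetime. When the first class has `mx = 0`, `R0` equals the
#' reproductive value at birth `V0` (an algebraic identity).
#'
#' @param lx Survivorship series (normalised internally).
#' @param mx Fertility series, same length.
#' @param lxmx Optional published `lx * mx` column used in place of the
#'   product (normalised by `lx[1]` as well).
#' @return The net reproductive rate, a single number.
#' @export
netReproductiveRate <- function(lx, mx, lxmx = NULL) {
  if (length(lx) != length(mx)) stop("lx and mx have different lengths")
  if (lx[1] <= 0) stop("lx[1] must be positive")
  if (is.null(lxmx)) lxmx <- lx * mx
  else if (length(lxmx) != length(lx)) stop("lxmx has wrong length")
  sum(lxmx / lx[1])
}

#' Read a fecundity table from delimited text
#'
#' Expects columns `n_x`, `B_x`, `mean_litter` (plus optional labels).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return data.frame of fecundity records.
#' @export
readFecundity <- function(path, sep = "\t") {
  readDemographyTable(path, c("n_x", "B_x", "mean_litter"), sep = sep)
}
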