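#' Mean instantaneous juvenile mortality per month
#'
#' Converts per-class mortality probabilities to instantaneous (log-hazard)
#' rates, `-log(1 - q) / classWidth` per month, and averages them over the
#' juvenile classes. This is the hazard entering the exponential
#' survival-to-maturity formula.
#'
#' @param q Per-class mortality probabilities of the juvenile classes.
#' @param classWidth Class width in months (default 3).
#' @return Mean instantaneous mortality per month.
#' @export
meanJuvenileHazard <- function(q, classWidth = 3) {
  if (any(q < 0 | q >= 1)) stop("q must be in [0, 1)")
  mean(-log(1 - q) / classWidth)
}

#' Survivorship to first reproduction
#'
#' Either the hazard form `S = exp(-Zbar * alpha)` (integrated
#' instantaneous juvenile mortality), or the empirical form `S = l[alpha] /
#' l[1]` read straight off a survivorship series.
#'
#' @param Zbar Mean instantaneous juvenile mortality per month (hazard
#'   mode).
#' @param alphaMonths Age at first reproduction in months (hazard mode).
#' @param lx Survivorship series (empirical mode).
#' @param alphaClass Index of the first reproductive class in `lx`
#'   (empirical mode).
#' @param mode `"hazard"` or `"empirical"`.
#' @return Survival probability in (0, 1].
#' @examples
#' survivalToMaturity(Zbar = 0.1, alphaMonths = 12)      # exp(-1.2)
#' @export
survivalToMaturity <- function(Zbar = NULL, alphaMonths = NULL, lx = NULL,
                               alphaClass = NULL,
                               mode = c("hazard", "empirical")) {
  mode <- match.arg(mode)
  if (mode == "hazard") {
    if (is.null(Zbar) || is.null(alphaMonths))
      stop("hazard mode needs Zbar and alphaMonths")
    if (Zbar < 0) stop("Zbar must be non-negative")
    if (alphaMonths <= 0) stop("alphaMonths must be positive")
    exp(-Zbar * alphaMonths)
  } else {
    if (is.null(lx) || is.null(alphaClass))
      stop("empirical mode needs lx and alphaClass")
    if (alphaClass < 1 || alphaClass > length(lx)) stop("alphaClass out of range")
    lx[alphaClass] / lx[1]
  }
}

#' Adult residence time (conditional on reaching maturity)
#'
#' The trapezoid discretisation of the integral of the adult survivorship
#' curve normalised at maturity, `integral of l(x)/S dx` over ages at and
#' beyond the first reproductive class: the expected number of months an
#' individual that reaches maturity still has to live. Survivorship is
#' assumed to decline linearly to zero across the terminal class, so the
#' last class contributes half a class width times its survivorship.
#' Rescaling `lx` by any constant leaves the result unchanged (the
#' maturity normalisation cancels).
#'
#' @param lx Survivorship series over all age classes (any radix).
#' @param alphaClass Index of the first adult (reproductive) class.
#' @param classWidth Class width in months.
#' @return Residence time in months.
#' @seealso [charnovInvariantSet()], which converts this residence time
#'   into an adult life span measured from birth.
#' @export
adultLifeExpectancy <- function(lx, alphaClass, classWidth = 3) {
  if (alphaClass < 1 || alphaClass > length(lx))
    stop("alphaClass out of range")
  l <- lx[alphaClass:length(lx)]
  if (!length(l) || l[1] <= 0) stop("no surviving adults at maturity")
  l <- l / l[1]
  n <- length(l)
  trap <- if (n > 1) sum((l[-1] + l[-n]) / 2) else 0
  classWidth * (trap + l[n] / 2)
}

#' Mass-normalised reproductive effort
#'
#' The survivorship-and-fertility weighted mean of the age-specific effort
#' schedule: `C = sum(l * m * Cx) / sum(l * m)` over adult classes, the
#' discrete form of the ratio-of-integrals definition (mass devoted to
#' reproduction per unit time per unit adult body mass). A constant `Cx`
#' is returned unchanged, whatever the weights.
#'
#' @param lx,mx Aligned survivorship and fertility series.
#' @param Cx Age-specific reproductive effort per unit mass per unit time;
#'   a scalar is recycled.
#' @return The weighted mean effort `C` (same time unit as `Cx`).
#' @export
reproductiveEffort <- function(lx, mx, Cx) {
  if (length(lx) != length(mx)) stop("lx and mx lengths differ")
  if (length(Cx) == 1L) Cx <- rep(Cx, length(lx))
  if (length(Cx) != length(lx)) stop("Cx length mismatch")
  w <- lx * mx
  if (sum(w) <= 0) stop("zero total reproduction: effort undefined")
  sum(w * Cx) / sum(w)
}

#' Charnov's dimensionless life-history invariant set
#'
#' Computes the classic dimensionless triple for a female schedule:
#' `E/alpha` (adult life span over age at maturity), `C * E` (lifetime
#' reproductive effort) and `I/m` (offspring independence mass over adult
#' mass), together with the relative residual of the identity
#' `2 * R0 = S * C * E_res * m / I`, where `E_res` is the adult residence
#' time (the integral of `l/S` beyond maturity) and `S` the survivorship
#' to maturity. Internally consistent schedules satisfy the identity to
#' machine precision.
#'
#' The adult life span `E` entering the two ratios is measured from birth:
#' `alphaMonths` plus the residence time from [adultLifeExpectancy()]. The
#' identity residual instead uses the residence time itself, which is the
#' form in which the identity is exact dimensionally (total offspring mass
#' produced over the adult phase equals offspring count times independence
#' mass).
#'
#' @param lx,mx Full survivorship and fertility series (all age classes).
#' @param alphaClass Index of the first reproductive class.
#' @param alphaMonths Age at first reproduction in months.
#' @param Cx Reproductive effort schedule per month per unit mass (scalar
#'   recycled).
#' @param I Offspring mass at independence (grams).
#' @param mAdult Average adult body mass (grams).
#' @param classWidth Class width in months.
#' @param R0 Net reproductive rate; computed from `lx`, `mx` via
#'   [netReproductiveRate()] when omitted.
#'
#' @return List with `EoverAlpha`, `CE`, `IoverM`, `residual2R0`
#'   (relative), and the components `S`, `Eres` (months), `E` (months,
#'   from birth), `C` (per month), `R0`.
#' @examples
#' # a one-adult-class schedule built to satisfy the identity exactly
#' S <- 0.2; cw <- 3; c0 <- 0.05; I <- 50; m <- 150
#' ch <- charnovInvariantSet(lx = c(1, S), mx = c(0, c0 * cw * m / (4 * I)),
#'                           alphaClass = 2, alphaMonths = 12, Cx = c0,
#'                           I = I, mAdult = m, classWidth = cw)
#' ch$residual2R0   # ~ 0
#' @export
charnovInvariantSet <- function(lx, mx, alphaClass, alphaMonths, Cx, I,
                                mAdult, classWidth = 3, R0 = NULL) {
  if (I <= 0 || mAdult <= 0) stop("masses must be positive")
  if (alphaMonths <= 0) stop("alphaMonths must be positive")
  S <- survivalToMaturity(lx = lx, alphaClass = alphaClass,
                          mode = "empirical")
  Eres <- adultLifeExpectancy(lx, alphaClass, classWidth)
  adult <- alphaClass:length(lx)
  C <- reproductiveEffort(lx[adult], mx[adult],
                          if (length(Cx) == 1L) Cx else Cx[adult])
  if (is.null(R0)) R0 <- netReproductiveRate(lx, mx)
  E <- alphaMonths + Eres
  rhs <- S * C * Eres * mAdult / I
  residual <- if (R0 > 0) abs(2 * R0 - rhs) / (2 * R0) else abs(rhs)
  list(EoverAlpha = E / alphaMonths, CE = C * E, IoverM = I / mAdult,
       residual2R0 = residual,
       S = S, Eres = Eres, E = E, C = C, R0 = R0)
}
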