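#' Capture-frequency counts from a capture matrix
#'
#' Tabulates `f[k]`, the number of distinct individuals captured exactly
#' `k` times, from a binary individuals-by-occasions matrix or from one
#' session of a [CaptureHistory-class].
#'
#' @param x Binary matrix (individuals x occasions) or a
#'   [CaptureHistory-class].
#' @param session For a capture history: which session (month index) to
#'   tabulate.
#' @return List with `t` (occasions), `f` (length-`t` frequency vector)
#'   and `S` (distinct individuals caught, `sum(f)`).
#' @export
frequencyCounts <- function(x, session = NULL) {
  if (is(x, "CaptureHistory")) {
    cd <- SummarizedExperiment::colData(x)
    if (is.null(session)) session <- cd$session[1]
    m <- SummarizedExperiment::assay(x, "captures")[, cd$session == session,
                                                    drop = FALSE]
  } else {
    m <- as.matrix(x)
  }
  t <- ncol(m)
  ni <- rowSums(m)
  f <- tabulate(ni[ni > 0], nbins = t)
  list(t = t, f = f, S = sum(f))
}

# Coefficients a[i, k] of the order-k Burnham-Overton jackknife
# Nhat_k = sum_i a[i,k] * f[i], derived from the defining generalized
# jackknife: Nhat_k = sum_{j=0..k} (-1)^j choose(k,j) (t-j)^k / k! * E_j,
# where E_j is the expected distinct count over random subsets of t-j
# occasions, E_j = sum_i f_i (1 - choose(t-i, j-i)/choose(t, j)).
jackknifeCoefficients <- function(t, k) {
  vapply(seq_len(t), function(i) {
    sum(vapply(0:k, function(j) {
      miss <- if (j < i) 0 else choose(t - i, j - i) / choose(t, j)
      (-1)^j * choose(k, j) * (t - j)^k / factorial(k) * (1 - miss)
    }, numeric(1)))
  }, numeric(1))
}

#' Jackknife abundance estimator for heterogeneous capture (model Mh)
#'
#' The Burnham-Overton jackknife corrects the naive distinct-capture count
#' `S` for individuals never caught, using the capture-frequency counts
#' `f[1..t]` and allowing every individual its own capture probability.
#' Estimates of orders 1 to `min(5, t - 1)` are computed from the
#' generalized-jackknife coefficients; with `order = "auto"` the order is
#' chosen by the sequential difference test: the first order whose
#' difference from the next is not significant (chi-square, `alphaTest`) is
#' selected, and the reported estimate interpolates linearly (in the test
#' statistic) between that order and the next, so the estimate moves
#' smoothly as the evidence for a higher order grows. Estimates are
#' floored at `S`, so `Nhat >= S` always.
#'
#' @param f Frequency vector (`f[k]` = individuals caught exactly `k`
#'   times) or the list returned by [frequencyCounts()].
#' @param t Number of trapping occasions (taken from `f` when it is a
#'   [frequencyCounts()] list; otherwise defaults to `length(f)`).
#' @param order `"auto"` or an integer order 1-5.
#' @param alphaTest Significance level of the sequential test.
#'
#' @return List with `Nhat`, `se`, `order` (selected order),
#'   `interpolation` (weight on the next order, 0 when none), and
#'   `estimates`, a data.frame of all orders with `Nhat`, `se`, `chisq`,
#'   `p` of the difference test against the next order.
#' @examples
#' jackknifeMh(c(3, 2, 1), t = 3, order = 1)$Nhat   # 6 + (2/3)*3 = 8
#' @seealso [densityFromAbundance()]
#' @export
jackknifeMh <- function(f, t = NULL, order = "auto", alphaTest = 0.05) {
  if (is.list(f) && all(c("t", "f") %in% names(f))) {
    t <- f$t
    f <- f$f
  }
  if (is.null(t)) t <- length(f)
  if (t < 2) stop("need at least two trapping occasions")
  if (length(f) < t) f <- c(f, rep(0, t - length(f)))
  if (any(f < 0)) stop("frequencies must be non-negative")
  S <- sum(f)
  if (S == 0) stop("no captures: abundance undefined")
  kmax <- min(5L, t - 1L)
  A <- vapply(seq_len(kmax), function(k) jackknifeCoefficients(t, k),
              numeric(t))
  Nk <- pmax(colSums(A * f), S)
  sek <- sqrt(pmax(colSums(A^2 * f) - Nk, 0))
  chisq <- p <- rep(NA_real_, kmax)
  for (k in seq_len(kmax - 1L)) {
    bcoef <- A[, k + 1L] - A[, k]
    d <- Nk[k + 1L] - Nk[k]
    v <- S / max(S - 1, 1) * (sum(bcoef^2 * f) - d^2 / S)
    chisq[k] <- if (v > 0) d^2 / v else Inf
    p[k] <- stats::pchisq(chisq[k], df = 1, lower.tail = FALSE)
  }
  crit <- stats::qchisq(1 - alphaTest, df = 1)
  if (identical(order, "auto")) {
    sel <- kmax
    w <- 0
    for (k in seq_len(kmax - 1L)) {
      if (chisq[k] < crit) {
        sel <- k
        w <- chisq[k] / crit
        break
      }
    }
    Nhat <- if (sel < kmax) (1 - w) * Nk[sel] + w * Nk[sel + 1L] else Nk[sel]
    se <- if (sel < kmax) (1 - w) * sek[sel] + w * sek[sel + 1L] else sek[sel]
  } else {
    sel <- as.integer(order)
    if (sel < 1L || sel > kmax) stop("order must be in 1..", kmax)
    w <- 0
    Nhat <- Nk[sel]
    se <- sek[sel]
  }
  list(Nhat = Nhat, se = se, order = sel, interpolation = w,
       estimates = data.frame(order = seq_len(kmax), Nhat = Nk, se = sek,
                              chisq = chisq, p = p))
}

#' Convert an abundance estimate to a density
#'
#' @param Nhat Abundance estimate.
#' @param areaHa Sampled area in hectares (default the 4-ha study
#'   enclosure).
#' @return Individuals per hectare.
#' @export
densityFromAbundance <- function(Nhat, areaHa = 4) {
  if (areaHa <= 0) stop("area must be positive")
  Nhat / areaHa
}
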