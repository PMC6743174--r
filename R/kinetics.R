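#' Kinetic parameters of MNase digestion at one locus
#'
#' Bundles the three parameters of the consecutive first-order reaction chain
#' B -> N -> 0 that describes MNase digestion of chromatin at a genomic locus:
#' nucleosome occupancy \code{O} (fraction of cells carrying a nucleosome
#' there, possibly on an arbitrary scale before calibration), the release rate
#' constant \code{k1} (chromatin accessibility) and the decay rate constant
#' \code{k2} (over-digestion of free mononucleosomes). Rates are per minute at
#' the experiment's fixed enzyme concentration, which is absorbed into them.
#'
#' @param O nucleosome occupancy, a nonnegative number.
#' @param k1 release rate constant, strictly positive.
#' @param k2 decay rate constant, nonnegative (0 means mononucleosomes are
#'   never destroyed and the count curve is monotone).
#' @return An object of class \code{"digestion_params"}.
#' @examples
#' p <- digestion_params(O = 1, k1 = 1, k2 = 0.1)
#' apparent_occupancy(seq(0, 10, by = 0.5), p)
#' @export
digestion_params <- function(O, k1, k2) {
  stopifnot(length(O) == 1L, length(k1) == 1L, length(k2) == 1L)
  if (!is.finite(O) || O < 0) stop("O must be finite and >= 0")
  if (!is.finite(k1) || k1 <= 0) stop("k1 must be finite and > 0")
  if (!is.finite(k2) || k2 < 0) stop("k2 must be finite and >= 0")
  structure(list(O = as.numeric(O), k1 = as.numeric(k1), k2 = as.numeric(k2)),
            class = "digestion_params")
}

#' @export
print.digestion_params <- function(x, ...) {
  cat(sprintf("Digestion kinetics: O = %.4g, k1 = %.4g/min, k2 = %.4g/min\n",
              x$O, x$k1, x$k2))
  invisible(x)
}

# Accept a digestion_params, a named list, or a named numeric vector.
as_dp <- function(p) {
  if (inherits(p, "digestion_params")) return(p)
  if (is.numeric(p) && !is.null(names(p))) p <- as.list(p)
  if (is.list(p) && all(c("O", "k1", "k2") %in% names(p)))
    return(digestion_params(p$O, p$k1, p$k2))
  stop("expected a digestion_params object or named (O, k1, k2)")
}

check_d <- function(d) {
  if (!is.numeric(d) || anyNA(d) || any(d < 0))
    stop("digestion level d must be nonnegative")
  as.numeric(d)
}

# TRUE when k1 and k2 are too close for the two-exponential form to be
# numerically stable (relative threshold eps).
degenerate_rates <- function(k1, k2, eps) abs(k1 - k2) < eps * max(k1, k2)

#' Fraction of nucleosomes still bound to chromatin
#'
#' Closed-form solution f_B(d) = exp(-k1 d) of d[B]/dt = -k1 [E] [B], as a
#' function of the digestion level d = [E] t. Equals 1 at d = 0 and decays
#' monotonically to 0.
#'
#' @param d digestion level(s) (enzyme concentration x time, in minutes at the
#'   reference enzyme concentration); nonnegative.
#' @param params a \code{\link{digestion_params}} object (or named vector).
#' @return Numeric vector of fractions in [0, 1], one per element of \code{d}.
#' @export
bound_fraction <- function(d, params) {
  p <- as_dp(params)
  d <- check_d(d)
  exp(-p$k1 * d)
}

#' Apparent occupancy: free mononucleosome count per cell
#'
#' Closed-form number of intact free mononucleosomes per cell, N(d)/C, under
#' the consecutive reaction B -> N -> 0:
#' \deqn{N(d)/C = O \frac{k_1}{k_1 - k_2} (e^{-k_2 d} - e^{-k_1 d})}
#' with the limiting form \eqn{O k_1 d e^{-k_1 d}} when k1 and k2 coincide
#' (within relative tolerance \code{eps}). Zero at d = 0, rises to a single
#' maximum at \code{\link{time_of_maximum}}, and vanishes again as
#' over-digestion destroys all nucleosomes.
#'
#' @inheritParams bound_fraction
#' @param eps relative closeness threshold on |k1 - k2| below which the
#'   degenerate (equal-rates) limiting form is used.
#' @return Numeric vector of nonnegative apparent occupancies, never
#'   exceeding \code{O}.
#' @export
apparent_occupancy <- function(d, params, eps = 1e-8) {
  p <- as_dp(params)
  d <- check_d(d)
  if (degenerate_rates(p$k1, p$k2, eps)) {
    k <- p$k1
    p$O * k * d * exp(-k * d)
  } else {
    p$O * p$k1 / (p$k1 - p$k2) * (exp(-p$k2 * d) - exp(-p$k1 * d))
  }
}

#' Digestion level at which the mononucleosome count peaks
#'
#' Solves the stationarity condition of the apparent occupancy: the count is
#' maximal when the rate of nucleosome release equals the rate of nucleosome
#' decay, k1 exp(-k1 d) = k2 exp(-k2 d), giving
#' d* = log(k1/k2) / (k1 - k2), with limit 1/k1 for equal rates. For k2 = 0
#' the curve is monotone increasing and \code{Inf} is returned.
#'
#' @inheritParams apparent_occupancy
#' @return A single digestion level (minutes); \code{Inf} when k2 = 0.
#' @export
time_of_maximum <- function(params, eps = 1e-8) {
  p <- as_dp(params)
  if (p$k2 == 0) return(Inf)
  if (degenerate_rates(p$k1, p$k2, eps)) return(1 / p$k1)
  log(p$k1 / p$k2) / (p$k1 - p$k2)
}

# Derivative dN/dd of the apparent occupancy (per cell), vectorized over d.
apparent_occupancy_deriv <- function(d, params, eps = 1e-8) {
  p <- as_dp(params)
  d <- check_d(d)
  if (degenerate_rates(p$k1, p$k2, eps)) {
    k <- p$k1
    p$O * k * exp(-k * d) * (1 - k * d)
  } else {
    p$O * p$k1 / (p$k1 - p$k2) *
      (p$k1 * exp(-p$k1 * d) - p$k2 * exp(-p$k2 * d))
  }
}

#' Model-implied MNase accessibility score along the digestion
#'
#' The MACC accessibility score is the negative slope of counts against log
#' enzyme dose. On the kinetic model curve the instantaneous analogue is
#' -dN/d(log d) = -d dN/dd. It is negative while counts still rise with
#' digestion (before \code{\link{time_of_maximum}}), zero at the maximum and
#' positive afterwards — every locus passes from "inaccessible" to
#' "accessible" as digestion proceeds.
#'
#' @param d digestion level(s), strictly positive.
#' @inheritParams apparent_occupancy
#' @return Numeric vector of instantaneous scores.
#' @export
macc_model_score <- function(d, params, eps = 1e-8) {
  if (!is.numeric(d) || anyNA(d) || any(d <= 0))
    stop("macc_model_score requires d > 0")
  -d * apparent_occupancy_deriv(d, params, eps = eps)
}

#' Fit the MACC accessibility score from an MNase titration
#'
#' Ordinary least squares of fragment counts on the natural log of the enzyme
#' dose, N = a log(E) + b. The MACC score is the negative fitted slope,
#' MACC = -a: loci whose counts rise with enzyme (a > 0) score negative and
#' are labelled inaccessible, loci whose counts fall score positive
#' (accessible).
#'
#' @param counts nonnegative fragment counts, one per titration point.
#' @param enzyme_levels strictly positive enzyme doses (at least two
#'   distinct).
#' @return An object of class \code{"macc_fit"}: list with slope \code{a},
#'   intercept \code{b}, score \code{macc} and \code{label} in
#'   \code{c("accessible", "inaccessible", "neutral")}.
#' @examples
#' fit_macc(c(10, 20, 30), c(1, 2, 4))  # counts rise: inaccessible
#' @export
fit_macc <- function(counts, enzyme_levels) {
  if (length(counts) != length(enzyme_levels))
    stop("counts and enzyme_levels must have equal length")
  if (any(enzyme_levels <= 0)) stop("enzyme levels must be > 0")
  if (length(unique(enzyme_levels)) < 2)
    stop("need at least 2 distinct enzyme levels")
  fit <- stats::lm(counts ~ log(enzyme_levels))
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  # flat titrations give a slope of zero up to machine rounding
  if (abs(a) < sqrt(.Machine$double.eps) * max(1, abs(b))) a <- 0
  macc <- -a
  label <- if (macc > 0) "accessible" else if (macc < 0) "inaccessible" else "neutral"
  structure(list(a = a, b = b, macc = macc, label = label), class = "macc_fit")
}

#' @export
print.macc_fit <- function(x, ...) {
  cat(sprintf("MACC fit: slope a = %.4g, intercept b = %.4g, MACC = %.4g (%s)\n",
              x$a, x$b, x$macc, x$label))
  invisible(x)
}
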