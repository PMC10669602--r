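#' Fractional extent of oxygen exchange
#'
#' Container pairing the fractional extent X (fraction of the four Pi
#' oxygens that carry the heavy label, 0--1) with the equivalent mean
#' 18O/P ratio (`4 * X`, 0--4).
#'
#' @param X Fraction in `[0, 1]` (vectorised).
#' @return An object of class `fractional_extent` with fields `X` and
#'   `o18_per_p`.
#' @export
fractional_extent <- function(X) {
  if (!is.numeric(X) || length(X) < 1L || anyNA(X)) {
    stop_domain("`X` must be numeric and non-missing")
  }
  if (any(X < 0 | X > 1)) {
    stop_domain("fractional extent X must lie in [0, 1]")
  }
  structure(list(X = as.numeric(X), o18_per_p = 4 * as.numeric(X)),
            class = "fractional_extent")
}

#' @export
print.fractional_extent <- function(x, ...) {
  cat("Fractional extent of oxygen exchange\n")
  print(data.frame(X = x$X, o18_per_p = x$o18_per_p))
  invisible(x)
}

#' Extent of oxygen exchange after a dimensionless exposure kt
#'
#' First-order uptake law for the exchange of Pi oxygens with water
#' oxygens at apparent rate constant k over exposure time t. Only the
#' product `kt` enters; with initial fraction `Xi` the solution of
#' `dX/dt = k (1 - X)` is
#' \deqn{X = 1 - (1 - X_i) e^{-kt}.}
#' The hydrolysis stoichiometry (one of the four oxygens of each released
#' Pi comes from a water molecule) fixes the default `Xi = 0.25`.
#'
#' @param kt Dimensionless exposure `k * t`, non-negative (vectorised).
#' @param Xi Initial labeled fraction, in `[0, 1)`.
#' @return A [fractional_extent()].
#' @examples
#' extent_from_kt(0)$X          # 0.25, the stoichiometric floor
#' extent_from_kt(log(3))$X     # 0.75
#' @export
extent_from_kt <- function(kt, Xi = 0.25) {
  if (!is.numeric(kt) || length(kt) < 1L || anyNA(kt)) {
    stop_domain("`kt` must be numeric and non-missing")
  }
  if (any(kt < 0)) stop_domain("`kt` must be non-negative")
  check_scalar_number(Xi, "Xi", lower = 0)
  if (Xi >= 1) stop_domain("`Xi` must lie in [0, 1)")
  fractional_extent(1 - (1 - Xi) * exp(-kt))
}

#' Invert the uptake law: kt from a measured extent
#'
#' With the hydrolysis initial condition `Xi = 0.25` the uptake law reads
#' `ln[0.75 / (1 - X)] = kt`; this returns that logarithm. Extents below
#' 0.25 would imply a negative exchange time and are rejected. Extents
#' within 1e-12 of 1 are clamped (with a warning) before taking the
#' logarithm, since measured 18O/P near 4 produces a near-singular
#' transform.
#'
#' @param X Fractional extent in `[0.25, 1)`, or a [fractional_extent()]
#'   (vectorised).
#' @return Dimensionless `kt`, same length as `X`.
#' @examples
#' kt_from_extent(0.75)                 # log(3)
#' kt_from_extent(extent_from_kt(2))    # 2
#' @export
kt_from_extent <- function(X) {
  if (inherits(X, "fractional_extent")) X <- X$X
  if (!is.numeric(X) || length(X) < 1L || anyNA(X)) {
    stop_domain("`X` must be numeric and non-missing")
  }
  if (any(X < 0.25)) {
    stop_domain(sprintf(
      "extent X = %g is below the stoichiometric floor 0.25 (implies negative exchange time)",
      min(X)
    ))
  }
  if (any(X >= 1)) stop_domain("extent X must be < 1")
  hi <- X > 1 - 1e-12
  if (any(hi)) {
    warning("extent within 1e-12 of 1 clamped before log transform",
            call. = FALSE)
    X[hi] <- 1 - 1e-12
  }
  log(0.75 / (1 - X))
}

#' Extent via the exchange-before-hydrolysis pathway
#'
#' When the label exchange happens on the gamma-phosphoryl group before
#' the bond-cleavage step, three quarters of the final Pi oxygens come
#' from the pre-hydrolysis pool (extent `1 - exp(-kt)` from a zero
#' initial fraction) and one quarter is contributed by the water oxygen
#' incorporated in the hydrolysis step itself:
#' \deqn{X = \tfrac{3}{4}\,(1 - e^{-kt}) + \tfrac{1}{4}.}
#' This equals [extent_from_kt()] with `Xi = 0.25` identically -- the
#' observed extent does not depend on the order of the exchange and
#' hydrolysis steps.
#'
#' @inheritParams extent_from_kt
#' @return A [fractional_extent()].
#' @export
extent_prehydrolysis_pathway <- function(kt) {
  if (!is.numeric(kt) || length(kt) < 1L || anyNA(kt)) {
    stop_domain("`kt` must be numeric and non-missing")
  }
  if (any(kt < 0)) stop_domain("`kt` must be non-negative")
  X_before <- 1 - exp(-kt)
  fractional_extent(0.75 * X_before + 0.25)
}

#' Convert between fractional extent and the 18O/P ratio
#'
#' The measured observable is the mean number of labeled oxygens per
#' released Pi (18O/P, 0--4); the fractional extent is that mean divided
#' by the four oxygens of phosphate.
#'
#' @param X Fractional extent in `[0, 1]` (vectorised).
#' @param o18_per_p Mean labeled oxygens per Pi, in `[0, 4]` (vectorised).
#' @return `extent_to_o18_per_p`: the 18O/P ratio; `o18_per_p_to_extent`:
#'   the fractional extent.
#' @examples
#' extent_to_o18_per_p(0.525)   # 2.10
#' o18_per_p_to_extent(1.85)    # 0.4625
#' @export
extent_to_o18_per_p <- function(X) {
  if (inherits(X, "fractional_extent")) X <- X$X
  if (!is.numeric(X) || anyNA(X) || any(X < 0 | X > 1)) {
    stop_domain("`X` must lie in [0, 1]")
  }
  4 * X
}

#' @rdname extent_to_o18_per_p
#' @export
o18_per_p_to_extent <- function(o18_per_p) {
  if (!is.numeric(o18_per_p) || anyNA(o18_per_p) ||
      any(o18_per_p < 0 | o18_per_p > 4)) {
    stop_domain("`o18_per_p` must lie in [0, 4]")
  }
  o18_per_p / 4
}

#' Stoichiometric initial fraction of labeled Pi oxygens
#'
#' During hydrolysis exactly one of the four oxygen atoms of each released
#' Pi is incorporated from medium water; when the water carries the heavy
#' label this fixes the pre-exchange labeled fraction of Pi at
#' `n_water / n_oxygens = 1/4`.
#'
#' @param n_oxygens Oxygen atoms per Pi (4).
#' @param n_water Water oxygens incorporated per hydrolysis event (1).
#' @return The initial fraction, 0.25 by default.
#' @export
hydrolysis_initial_fraction <- function(n_oxygens = 4L, n_water = 1L) {
  check_scalar_number(n_oxygens, "n_oxygens", lower = 1)
  check_scalar_number(n_water, "n_water", lower = 0, upper = n_oxygens)
  n_water / n_oxygens
}

#' Total exchange time available per released Pi
#'
#' The time a Pi (or the gamma-phosphoryl of bound ATP) spends exposed to
#' exchange at one catalytic site per hydrolysis cycle is the reciprocal
#' of the steady-state velocity; when `n` sites mediate exchange
#' simultaneously the effective exposure is `n / velocity`.
#'
#' @param velocity Steady-state hydrolysis velocity, mol Pi per mol
#'   enzyme per second, `> 0` (vectorised).
#' @param n Number of simultaneously exchanging sites, 1, 2 or 3.
#' @return Exchange time in seconds.
#' @examples
#' per_site_time(650)        # fastest turnover measured
#' per_site_time(3.5, n = 2) # 4/7 s
#' @export
per_site_time <- function(velocity, n = 1L) {
  if (!is.numeric(velocity) || length(velocity) < 1L || anyNA(velocity)) {
    stop_domain("`velocity` must be numeric and non-missing")
  }
  if (any(velocity <= 0)) stop_domain("`velocity` must be positive")
  if (!is.numeric(n) || length(n) != 1L || !(n %in% c(1, 2, 3))) {
    stop_domain("`n` must be 1, 2 or 3")
  }
  n / velocity
}

#' Closed-form isotopomer distribution after Poisson-chain washout
#'
#' Label washout from the gamma-phosphoryl group of ATP into unlabeled
#' water proceeds as a chain of first-order exchange events, each
#' removing one heavy label, all at the same apparent rate constant k
#' (so the event count over an exposure `t` is Poisson with mean `kt`).
#' Writing `A1..A4` for the percentages with 3, 2, 1, 0 labels, the
#' mass-action system integrates to
#' \deqn{A_1 = A_{10} e^{-kt}}
#' \deqn{A_2 = A_{10} kt\, e^{-kt} + A_{20} e^{-kt}}
#' \deqn{A_3 = A_{10} (kt)^2 e^{-kt}/2 + A_{20} kt\, e^{-kt} + A_{30} e^{-kt}}
#' with the zero-label class taken by the normalisation closure
#' `A4 = 100 - A1 - A2 - A3` (the chain is absorbing at zero labels).
#'
#' @param initial Starting [label_distribution()] of the gamma-phosphoryl
#'   group.
#' @param kt Dimensionless exposure `k * t`, non-negative scalar.
#' @return The evolved [label_distribution()].
#' @examples
#' init <- label_distribution(57, 17, 2, 24)
#' isotopomer_distribution(init, 0)      # unchanged
#' isotopomer_distribution(init, 5.25)   # long-time washout
#' @export
isotopomer_distribution <- function(initial, kt) {
  initial <- as_label_distribution(initial)
  check_scalar_number(kt, "kt", lower = 0)
  ekt <- exp(-kt)
  a10 <- initial[["p3"]]; a20 <- initial[["p2"]]; a30 <- initial[["p1"]]
  p3 <- a10 * ekt
  p2 <- (a10 * kt + a20) * ekt
  p1 <- (a10 * kt^2 / 2 + a20 * kt + a30) * ekt
  p0 <- 100 - p3 - p2 - p1
  label_distribution(p3, p2, p1, p0)
}

# Vectorised washout: rows = kt values, columns p3..p0 (percent).
# Used by selection, pipelines and plots; same closed forms as above.
washout_curve <- function(initial, kt) {
  initial <- as_label_distribution(initial)
  if (!is.numeric(kt) || anyNA(kt) || any(kt < 0)) {
    stop_domain("`kt` must be a non-negative numeric vector")
  }
  ekt <- exp(-kt)
  a10 <- initial[["p3"]]; a20 <- initial[["p2"]]; a30 <- initial[["p1"]]
  p3 <- a10 * ekt
  p2 <- (a10 * kt + a20) * ekt
  p1 <- (a10 * kt^2 / 2 + a20 * kt + a30) * ekt
  cbind(kt = kt, p3 = p3, p2 = p2, p1 = p1, p0 = 100 - p3 - p2 - p1)
}
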