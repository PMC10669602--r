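#' Isotopomer label distribution of phosphate species
#'
#' An isotopomer distribution records the percentage of Pi (or of the
#' gamma-phosphoryl group of ATP) carrying exactly 3, 2, 1, or 0 heavy
#' (\eqn{^{18}}O) oxygen atoms, as resolved by GC-MS of derivatised
#' phosphate. Percentages are stored on the 0--100 scale used throughout
#' the oxygen-exchange literature and must sum to 100.
#'
#' A four-label (\eqn{^{18}}O\eqn{_4}) channel is accepted on input for
#' completeness (it exists as a GC-MS mass channel) but must be zero to
#' within `p4_tol`: the washout theory starts from the gamma-phosphoryl
#' group, which carries at most three exchangeable oxygens.
#'
#' @param p3,p2,p1,p0 Percentages (0--100) of species with 3, 2, 1, 0
#'   labeled oxygens.
#' @param p4 Percentage in the four-label channel; must not exceed
#'   `p4_tol`.
#' @param normalize If `TRUE`, a total within `sum_tol` of 100 is rescaled
#'   exactly to 100 (measurement-rounding convenience used by the table
#'   reader). If `FALSE` (default) the components must already sum to 100
#'   to within relative 1e-9.
#' @param sum_tol Absolute tolerance on the total when `normalize = TRUE`.
#' @param p4_tol Validation tolerance for the four-label channel.
#'
#' @return An object of class `label_distribution`: a named numeric vector
#'   with components `p3`, `p2`, `p1`, `p0`.
#' @examples
#' label_distribution(57, 17, 2, 24)   # measured gamma-phosphoryl input
#' label_distribution(100, 0, 0, 0)
#' @export
label_distribution <- function(p3, p2, p1, p0, p4 = 0,
                               normalize = FALSE, sum_tol = 0.5,
                               p4_tol = 0.5) {
  p <- c(p3 = p3, p2 = p2, p1 = p1, p0 = p0)
  if (!is.numeric(p) || length(p) != 4L || anyNA(p)) {
    stop_validation("all four components must be non-missing numbers")
  }
  if (any(p < 0)) {
    stop_validation("label percentages must be non-negative")
  }
  if (!is.numeric(p4) || length(p4) != 1L || is.na(p4) || p4 < 0) {
    stop_validation("`p4` must be a single non-negative number")
  }
  if (p4 > p4_tol) {
    stop_validation(sprintf(
      "four-label channel p4 = %g exceeds tolerance %g; the washout model has no 18O4 state",
      p4, p4_tol
    ))
  }
  total <- sum(p)
  if (normalize) {
    if (abs(total - 100) > sum_tol) {
      stop_validation(sprintf(
        "components sum to %g; must be within %g of 100", total, sum_tol
      ))
    }
    p <- p / total * 100
  } else if (abs(total - 100) > 1e-9 * 100) {
    stop_validation(sprintf(
      "components sum to %.10g; must equal 100 (use normalize = TRUE for rounded data)",
      total
    ))
  }
  structure(as.numeric(p), names = names(p), class = "label_distribution")
}

#' Coerce a length-4 numeric vector to a label distribution
#'
#' @param x Numeric vector `(p3, p2, p1, p0)` or a `label_distribution`.
#' @param ... Passed on to [label_distribution()].
#' @return A `label_distribution`.
#' @export
as_label_distribution <- function(x, ...) {
  if (inherits(x, "label_distribution")) return(x)
  if (!is.numeric(x) || length(x) != 4L) {
    stop_validation("expected a label_distribution or a numeric vector of length 4")
  }
  label_distribution(x[[1]], x[[2]], x[[3]], x[[4]], ...)
}

#' @export
print.label_distribution <- function(x, digits = 4, ...) {
  cat("Isotopomer distribution (% of Pi species)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Mean number of labeled oxygens per Pi implied by a distribution
#'
#' First moment of the isotopomer distribution: `(3 p3 + 2 p2 + p1) / 100`,
#' in labeled oxygens per Pi, between 0 and 3. This is the washout-side
#' counterpart of the measured 18O/P ratio.
#'
#' @param dist A [label_distribution()].
#' @return Mean labels per Pi (0--3).
#' @examples
#' mean_label_count(label_distribution(57, 17, 2, 24))  # 2.07
#' @export
mean_label_count <- function(dist) {
  dist <- as_label_distribution(dist)
  unname((3 * dist[["p3"]] + 2 * dist[["p2"]] + dist[["p1"]]) / 100)
}
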