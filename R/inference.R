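#' Estimate the apparent oxygen-exchange rate constant
#'
#' Fits the linearised uptake law to per-condition observations of
#' steady-state velocity and measured 18O/P ratio. For each observation
#' the extent `X = o18_per_p / 4` is transformed to
#' `y = ln[0.75 / (1 - X)]` and regressed on the exchange time
#' `t = n / velocity` by ordinary least squares. Because the uptake law
#' has no intercept, the default regression is constrained through the
#' origin and the reported R-squared is computed about the origin
#' (`1 - SS_res / sum(y^2)`); a free-intercept mode is available for
#' diagnostics.
#'
#' @param observations Data frame with numeric columns `velocity_per_s`
#'   and `o18_per_p` (as produced by [read_observations()] or
#'   [simulate_dataset()]).
#' @param n Site-count multiplier applied to `1/velocity`: a single value
#'   or one value per observation. The default 1 matches the convention
#'   of plotting extent against the reciprocal velocity; site
#'   multiplicity is handled downstream by [select_site_count()].
#' @param intercept If `TRUE`, fit a free intercept (diagnostic mode).
#' @param o18_max Saturation ceiling of the 18O/P measurement. Ratios
#'   above it sit at the resolution limit of the isotopomer assay (whose
#'   largest resolvable reading is about 3.98 of a possible 4), carry no
#'   usable information about `kt`, and are excluded with a warning
#'   before the log transform.
#' @return An object of class `oxex_fit` with `estimates` (named vector,
#'   `k` and optionally `intercept`), `std_errors`, `r_squared`,
#'   `residuals`, `fitted`, and the transformed data.
#' @examples
#' v <- exp(seq(log(3.5), log(650), length.out = 15))
#' obs <- data.frame(velocity_per_s = v,
#'                   o18_per_p = 4 * extent_from_kt(10.5 / v)$X)
#' fit_rate_constant(obs)
#' @export
fit_rate_constant <- function(observations, n = 1, intercept = FALSE,
                              o18_max = 3.98) {
  obs <- as.data.frame(observations)
  for (col in c("velocity_per_s", "o18_per_p")) {
    if (is.null(obs[[col]]) || !is.numeric(obs[[col]])) {
      stop_usage(sprintf("`observations` must contain numeric column `%s`", col))
    }
  }
  if (nrow(obs) < 2L) stop_usage("need at least 2 observations to fit k")
  if (anyNA(obs$velocity_per_s) || anyNA(obs$o18_per_p)) {
    stop_validation("velocity and o18_per_p must be non-missing for every row")
  }
  if (any(obs$velocity_per_s <= 0)) {
    stop_domain(sprintf("non-positive velocity in row %d",
                        which(obs$velocity_per_s <= 0)[1]))
  }
  if (!length(n) %in% c(1L, nrow(obs)) || !all(n %in% c(1, 2, 3))) {
    stop_usage("`n` must be 1, 2 or 3, scalar or one value per observation")
  }
  saturated <- obs$o18_per_p > o18_max
  if (any(saturated)) {
    warning(sprintf(
      "%d observation(s) with o18_per_p > %g excluded: saturated beyond the assay's resolution",
      sum(saturated), o18_max
    ), call. = FALSE)
    obs <- obs[!saturated, , drop = FALSE]
    if (length(n) > 1L) n <- n[!saturated]
    if (nrow(obs) < 2L) {
      stop_fit("fewer than 2 unsaturated observations remain")
    }
  }
  X <- o18_per_p_to_extent(obs$o18_per_p)
  bad <- which(X < 0.25)
  if (length(bad)) {
    stop_domain(sprintf(
      "row %d: o18_per_p = %g implies extent %g below the 0.25 floor",
      bad[1], obs$o18_per_p[bad[1]], X[bad[1]]
    ))
  }
  y <- kt_from_extent(X)
  t <- n / obs$velocity_per_s
  if (diff(range(t)) == 0) {
    stop_fit("singular design: all exchange times are equal")
  }
  fit <- if (intercept) stats::lm(y ~ t) else stats::lm(y ~ 0 + t)
  # summary.lm warns on exact (noiseless) fits; the zero SE is meaningful here
  sm <- suppressWarnings(summary(fit))
  coefs <- stats::coef(sm)
  k_hat <- coefs["t", "Estimate"]
  k_se <- coefs["t", "Std. Error"]
  estimates <- c(k = unname(k_hat))
  std_errors <- c(k = unname(k_se))
  if (intercept) {
    estimates["intercept"] <- coefs["(Intercept)", "Estimate"]
    std_errors["intercept"] <- coefs["(Intercept)", "Std. Error"]
    r2 <- sm$r.squared
  } else {
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum(y^2)
  }
  structure(list(
    model = "rate_constant",
    estimates = estimates,
    std_errors = std_errors,
    r_squared = r2,
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    data = data.frame(t = t, y = y),
    intercept = intercept
  ), class = "oxex_fit")
}

#' @export
print.oxex_fit <- function(x, digits = 4, ...) {
  cat(sprintf("oxex fit: %s\n", x$model))
  est <- cbind(estimate = x$estimates, std_error = x$std_errors)
  print(round(est, digits))
  cat(sprintf("R-squared%s: %.6g  (n = %d)\n",
              if (identical(x$intercept, FALSE)) " (about origin)" else "",
              x$r_squared, length(x$residuals)))
  invisible(x)
}

#' Select the number of simultaneously exchanging catalytic sites
#'
#' Compares a measured isotopomer distribution against the closed-form
#' washout prediction for each candidate site count n, where the
#' predicted exposure is `kt = k * n / velocity`. The discrepancy is the
#' sum of squared differences over the four percentage components (or,
#' optionally, a Pearson chi-square statistic on molecule counts). The
#' candidate with the smallest discrepancy wins; exact ties are broken
#' toward the smaller n (parsimony) and flagged.
#'
#' @param velocity Steady-state velocity (1/s); `Inf` is accepted and
#'   represents the degenerate no-exchange limit `kt = 0`.
#' @param distribution Measured [label_distribution()] of the released Pi.
#' @param k Apparent exchange rate constant (1/s), `> 0`.
#' @param initial Initial gamma-phosphoryl [label_distribution()].
#' @param candidates Candidate site counts, a non-empty subset of 1:3.
#' @param criterion `"sse"` (percentage scale, default) or `"chisq"`
#'   (requires `n_molecules`).
#' @param n_molecules Number of Pi molecules behind the measured
#'   distribution; needed only for `criterion = "chisq"`.
#' @param tie_tol Absolute tolerance under which discrepancies count as
#'   tied.
#' @return A list with `n_selected`, `score` (named per-candidate
#'   discrepancies), `criterion`, and `tie`.
#' @examples
#' init <- label_distribution(57, 17, 2, 24)
#' obs <- isotopomer_distribution(init, 10.5 * 2 / 4)  # exact n = 2 data
#' select_site_count(4, obs, k = 10.5, initial = init)
#' @export
select_site_count <- function(velocity, distribution, k, initial,
                              candidates = c(1L, 2L, 3L),
                              criterion = c("sse", "chisq"),
                              n_molecules = NULL, tie_tol = 1e-9) {
  criterion <- match.arg(criterion)
  if (length(candidates) == 0) stop_usage("`candidates` must be non-empty")
  if (!all(candidates %in% c(1, 2, 3)) || anyDuplicated(candidates)) {
    stop_usage("`candidates` must be a subset of {1, 2, 3} without duplicates")
  }
  check_scalar_number(velocity, "velocity", allow_infinite = TRUE)
  if (velocity <= 0) stop_domain("`velocity` must be positive")
  check_scalar_number(k, "k")
  if (k <= 0) stop_domain("`k` must be positive")
  distribution <- as_label_distribution(distribution)
  initial <- as_label_distribution(initial)
  candidates <- sort(as.integer(candidates))

  score <- vapply(candidates, function(nc) {
    kt <- k * nc / velocity
    pred <- isotopomer_distribution(initial, kt)
    if (criterion == "sse") {
      sum((unclass(distribution) - unclass(pred))^2)
    } else {
      if (is.null(n_molecules)) {
        stop_usage("`n_molecules` is required for criterion = \"chisq\"")
      }
      observed <- unclass(distribution) / 100 * n_molecules
      expected <- pmax(unclass(pred) / 100 * n_molecules, .Machine$double.eps)
      sum((observed - expected)^2 / expected)
    }
  }, numeric(1))
  names(score) <- paste0("n", candidates)

  best <- min(score)
  tied <- which(score - best <= tie_tol)
  list(
    n_selected = candidates[tied[1]],   # candidates sorted: parsimony
    score = score,
    criterion = criterion,
    tie = length(tied) > 1L
  )
}

#' Locate the transition between short-time and long-time exchange regimes
#'
#' Runs [select_site_count()] on every observation carrying a measured
#' distribution, orders the observations by exchange time `1/velocity`,
#' and reports the midpoint between the largest time labelled n = 3 and
#' the smallest time labelled n = 2, together with the bracketing ATP
#' concentrations. A time-ordered label sequence that goes back up from
#' 2 to 3 sites is physically unexpected and is reported as a warning
#' (with the full label vector returned), not an error.
#'
#' @param observations Data frame with columns `velocity_per_s`,
#'   `p3_pct`, `p2_pct`, `p1_pct`, `p0_pct` and optionally `atp_conc_uM`.
#' @inheritParams select_site_count
#' @return A list with `transition` (`TRUE`/`FALSE`), `transition_time_s`
#'   (midpoint, `NA` if no transition), `bracket_time_s`,
#'   `bracket_atp_uM`, and the per-observation table `labels`.
#' @export
detect_transition <- function(observations, k, initial,
                              candidates = c(1L, 2L, 3L),
                              criterion = c("sse", "chisq"),
                              n_molecules = NULL) {
  criterion <- match.arg(criterion)
  obs <- as.data.frame(observations)
  needed <- c("velocity_per_s", "p3_pct", "p2_pct", "p1_pct", "p0_pct")
  missing_cols <- setdiff(needed, names(obs))
  if (length(missing_cols)) {
    stop_usage(sprintf(
      "observations lack distribution columns needed for site selection: %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(obs) < 2L) stop_usage("need at least 2 observations")

  n_hat <- vapply(seq_len(nrow(obs)), function(i) {
    dist <- label_distribution(obs$p3_pct[i], obs$p2_pct[i],
                               obs$p1_pct[i], obs$p0_pct[i],
                               normalize = TRUE)
    select_site_count(obs$velocity_per_s[i], dist, k, initial,
                      candidates = candidates, criterion = criterion,
                      n_molecules = n_molecules)$n_selected
  }, integer(1))

  t <- 1 / obs$velocity_per_s
  ord <- order(t)
  labels <- data.frame(
    time_s = t[ord],
    atp_conc_uM = if (!is.null(obs$atp_conc_uM)) obs$atp_conc_uM[ord] else NA_real_,
    n = n_hat[ord]
  )
  if (is.unsorted(rev(labels$n))) {
    warning(sprintf(
      "site-count labels are not monotone non-increasing in time: %s",
      paste(labels$n, collapse = " ")
    ), call. = FALSE)
  }
  has3 <- any(labels$n == 3)
  has2 <- any(labels$n == 2)
  if (!has3 || !has2) {
    return(list(transition = FALSE, transition_time_s = NA_real_,
                bracket_time_s = c(NA_real_, NA_real_),
                bracket_atp_uM = c(NA_real_, NA_real_), labels = labels))
  }
  t3 <- max(labels$time_s[labels$n == 3])
  t2 <- min(labels$time_s[labels$n == 2])
  i3 <- which(labels$time_s == t3 & labels$n == 3)[1]
  i2 <- which(labels$time_s == t2 & labels$n == 2)[1]
  list(
    transition = TRUE,
    transition_time_s = (t3 + t2) / 2,
    bracket_time_s = c(t3, t2),
    bracket_atp_uM = c(labels$atp_conc_uM[i3], labels$atp_conc_uM[i2]),
    labels = labels
  )
}

#' Fit Michaelis-Menten parameters to steady-state velocities
#'
#' Nonlinear least squares of `v = Vmax * S / (Km + S)`, with starting
#' values from the double-reciprocal (Lineweaver-Burk) linearisation.
#' Used for activity normalisation of occupancy plots; it recovers the
#' generating parameters exactly on noiseless inputs.
#'
#' @param atp_conc_uM Substrate concentrations (uM), `> 0`.
#' @param velocity_per_s Velocities (1/s), `> 0`; same length.
#' @return An `oxex_fit` with estimates `Vmax` (1/s) and `Km` (uM),
#'   standard errors, conventional R-squared and residuals. A saturated
#'   design (all `S >> Km`) is not an error but shows up as a large
#'   standard error on `Km`.
#' @examples
#' S <- c(0.11, 1, 10, 99, 500, 5000)
#' fit_michaelis_menten(S, 640 * S / (99 + S))
#' @export
fit_michaelis_menten <- function(atp_conc_uM, velocity_per_s) {
  S <- as.numeric(atp_conc_uM)
  v <- as.numeric(velocity_per_s)
  if (length(S) != length(v)) stop_usage("inputs must have equal length")
  if (length(S) < 3L) stop_usage("need at least 3 (S, v) pairs")
  if (anyNA(S) || anyNA(v) || any(S <= 0) || any(v <= 0)) {
    stop_domain("all concentrations and velocities must be positive")
  }
  # Lineweaver-Burk start: 1/v = 1/Vmax + (Km/Vmax) * 1/S
  lb <- stats::lm(I(1 / v) ~ I(1 / S))
  vmax0 <- 1 / stats::coef(lb)[[1]]
  km0 <- stats::coef(lb)[[2]] * vmax0
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(v)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(S)

  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 0, Km = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop_fit(sprintf(
        "Michaelis-Menten fit failed to converge (start Vmax = %.3g, Km = %.3g): %s",
        vmax0, km0, conditionMessage(e)
      ))
    }
  )
  sm <- summary(fit)
  co <- stats::coef(sm)
  res <- unname(stats::residuals(fit))
  r2 <- 1 - sum(res^2) / sum((v - mean(v))^2)
  structure(list(
    model = "michaelis_menten",
    estimates = c(Vmax = co["Vmax", "Estimate"], Km = co["Km", "Estimate"]),
    std_errors = c(Vmax = co["Vmax", "Std. Error"], Km = co["Km", "Std. Error"]),
    r_squared = r2,
    residuals = res,
    fitted = unname(stats::fitted(fit)),
    data = data.frame(atp_conc_uM = S, velocity_per_s = v),
    intercept = NA
  ), class = "oxex_fit")
}
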