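#' Configuration for the stochastic exchange simulator
#'
#' Bundles the generating conditions for synthetic oxygen-exchange
#' datasets: the apparent exchange rate constant, the initial
#' gamma-phosphoryl label distribution, the substrate grid and the
#' Michaelis-Menten constants that map concentration to velocity, the
#' site-count rule (three exchanging sites at short per-site hydrolysis
#' times, two at long times, with a hard switch at 33 ms), and the
#' molecule count that sets the multinomial GC-MS counting noise.
#'
#' @param k Apparent exchange rate constant (1/s).
#' @param initial Initial [label_distribution()] of the gamma-phosphoryl
#'   group.
#' @param atp_concs Substrate concentrations (uM); defaults to 12 points
#'   log-spaced over 0.11--5000 uM.
#' @param vmax,km Michaelis-Menten constants (1/s, uM).
#' @param switch_time Per-site hydrolysis time (s) below which three
#'   sites exchange simultaneously; at or above it, two.
#' @param n_rule Optional function `t -> n` overriding the default hard
#'   switch.
#' @param molecules_per_condition Simulated Pi molecules per condition.
#' @param o18_source `"uptake"` (default): the 18O/P column is simulated
#'   from the per-oxygen uptake law at exposure `k / v`, matching the
#'   convention of regressing extent on the reciprocal velocity;
#'   `"washout"`: the column is the mean label count of the sampled
#'   washout distribution (0--3 scale).
#' @param seed Integer seed; the simulator is fully reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(k = 10.5,
                              initial = label_distribution(57, 17, 2, 24),
                              atp_concs = 10^seq(log10(0.11), log10(5000),
                                                 length.out = 12),
                              vmax = 640, km = 99,
                              switch_time = 0.033,
                              n_rule = NULL,
                              molecules_per_condition = 1e4,
                              o18_source = c("uptake", "washout"),
                              seed = 1L) {
  check_scalar_number(k, "k"); if (k <= 0) stop_domain("`k` must be positive")
  check_scalar_number(vmax, "vmax"); if (vmax <= 0) stop_domain("`vmax` must be positive")
  check_scalar_number(km, "km"); if (km <= 0) stop_domain("`km` must be positive")
  check_scalar_number(switch_time, "switch_time")
  if (switch_time <= 0) stop_domain("`switch_time` must be positive")
  check_scalar_number(molecules_per_condition, "molecules_per_condition", lower = 1)
  if (!is.numeric(atp_concs) || length(atp_concs) < 1L || any(atp_concs <= 0)) {
    stop_domain("`atp_concs` must be positive concentrations")
  }
  if (!is.null(n_rule) && !is.function(n_rule)) {
    stop_usage("`n_rule` must be NULL or a function of the per-site time")
  }
  structure(list(
    k = k,
    initial = as_label_distribution(initial),
    atp_concs = as.numeric(atp_concs),
    vmax = vmax, km = km,
    switch_time = switch_time,
    n_rule = n_rule,
    molecules_per_condition = as.integer(molecules_per_condition),
    o18_source = match.arg(o18_source),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Washout of heavy labels from single molecules
#'
#' Simulates the Poisson event chain for molecules starting with
#' `labels0` heavy oxygens: over a dimensionless exposure `kt` the number
#' of exchange events is Poisson with mean `kt`, each event removes one
#' label, and the zero-label state is absorbing.
#'
#' @param labels0 Integer label counts in `{0, 1, 2, 3}` (vectorised; one
#'   molecule per element).
#' @param kt Dimensionless exposure, `>= 0`.
#' @return Integer vector of final label counts.
#' @examples
#' set.seed(1)
#' table(simulate_molecule_washout(rep(3L, 1000), kt = 1))
#' @export
simulate_molecule_washout <- function(labels0, kt) {
  if (!is.numeric(labels0) || anyNA(labels0) ||
      any(labels0 != as.integer(labels0)) || any(labels0 < 0 | labels0 > 3)) {
    stop_domain("`labels0` must contain integers in {0, 1, 2, 3}")
  }
  check_scalar_number(kt, "kt", lower = 0)
  events <- stats::rpois(length(labels0), lambda = kt)
  as.integer(pmax(0L, as.integer(labels0) - events))
}

#' Sampled isotopomer distribution of a washed-out population
#'
#' Draws `n_molecules` starting label counts from the initial
#' distribution (multinomial), evolves each molecule with
#' [simulate_molecule_washout()], and tabulates the resulting percentages
#' -- a molecule-level emulation of a GC-MS measurement whose expectation
#' is the closed-form [isotopomer_distribution()].
#'
#' @param initial Initial [label_distribution()].
#' @param kt Dimensionless exposure, `>= 0`.
#' @param n_molecules Number of simulated Pi molecules, `>= 1`.
#' @return A list with `distribution` (the sampled
#'   [label_distribution()]), `counts` (named molecule counts for 3, 2,
#'   1, 0 labels), and `n_molecules`.
#' @examples
#' set.seed(1)
#' simulate_population(label_distribution(57, 17, 2, 24), 0.5, 1e4)$distribution
#' @export
simulate_population <- function(initial, kt, n_molecules) {
  initial <- as_label_distribution(initial)
  check_scalar_number(n_molecules, "n_molecules", lower = 1)
  n_molecules <- as.integer(n_molecules)
  start_counts <- as.vector(stats::rmultinom(1, n_molecules,
                                             prob = unclass(initial) / 100))
  labels0 <- rep(3:0, times = start_counts)
  final <- simulate_molecule_washout(labels0, kt)
  counts <- vapply(3:0, function(l) sum(final == l), integer(1))
  names(counts) <- c("p3", "p2", "p1", "p0")
  pct <- counts / n_molecules * 100
  list(
    distribution = label_distribution(pct[["p3"]], pct[["p2"]],
                                      pct[["p1"]], pct[["p0"]],
                                      normalize = TRUE),
    counts = counts,
    n_molecules = n_molecules
  )
}

#' Sampled fractional extent in the uptake configuration
#'
#' Emulates label uptake from heavy water into released Pi: every Pi
#' carries one labeled oxygen from the hydrolysis step itself, and each
#' of the remaining three oxygens exchanges independently with
#' probability `1 - exp(-kt)`, so the per-molecule label count is
#' `1 + Binomial(3, 1 - exp(-kt))` and the expected extent is
#' `1 - 0.75 exp(-kt)`.
#'
#' @inheritParams simulate_population
#' @return A [fractional_extent()] (population mean over the simulated
#'   molecules).
#' @examples
#' set.seed(1)
#' simulate_uptake_extent(1, 1e5)$X   # near 1 - 0.75 * exp(-1)
#' @export
simulate_uptake_extent <- function(kt, n_molecules) {
  check_scalar_number(kt, "kt", lower = 0)
  check_scalar_number(n_molecules, "n_molecules", lower = 1)
  n_molecules <- as.integer(n_molecules)
  labels <- 1L + stats::rbinom(n_molecules, 3L, 1 - exp(-kt))
  fractional_extent(mean(labels) / 4)
}

#' Simulate a full oxygen-exchange dataset
#'
#' For every substrate concentration in the configuration: the velocity
#' follows the Michaelis-Menten law, the per-site hydrolysis time is its
#' reciprocal, the site count comes from the switch rule, the washout
#' exposure is `k * n / v`, and the isotopomer distribution is sampled at
#' the configured molecule count. The 18O/P column is simulated per the
#' configured `o18_source` (see [simulation_config()]). Ground truth
#' (per-site time, site count, exposures) travels alongside the
#' observations for recovery scoring.
#'
#' @param config A [simulation_config()].
#' @return An object of class `oxex_dataset`: a list with `observations`
#'   (data frame with columns `atp_conc_uM`, `velocity_per_s`,
#'   `o18_per_p`, `p3_pct` ... `p0_pct`), `truth` (data frame with
#'   `t_per_site_s`, `n`, `kt_washout`, `kt_uptake`), and `config`.
#' @examples
#' ds <- simulate_dataset(simulation_config(atp_concs = c(3, 5), seed = 1))
#' ds$truth$n
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_usage("`config` must be a simulation_config")
  }
  set.seed(config$seed)
  n_rule <- config$n_rule %||%
    function(t) if (t < config$switch_time) 3L else 2L

  rows <- lapply(config$atp_concs, function(S) {
    v <- config$vmax * S / (config$km + S)
    t <- 1 / v
    n <- as.integer(n_rule(t))
    kt_washout <- config$k * n * t
    kt_uptake <- config$k * t
    pop <- simulate_population(config$initial, kt_washout,
                               config$molecules_per_condition)
    o18 <- if (config$o18_source == "uptake") {
      simulate_uptake_extent(kt_uptake, config$molecules_per_condition)$o18_per_p
    } else {
      mean_label_count(pop$distribution)
    }
    d <- unclass(pop$distribution)
    list(
      obs = data.frame(atp_conc_uM = S, velocity_per_s = v, o18_per_p = o18,
                       p3_pct = d[["p3"]], p2_pct = d[["p2"]],
                       p1_pct = d[["p1"]], p0_pct = d[["p0"]]),
      truth = data.frame(t_per_site_s = t, n = n,
                         kt_washout = kt_washout, kt_uptake = kt_uptake)
    )
  })
  structure(list(
    observations = do.call(rbind, lapply(rows, `[[`, "obs")),
    truth = do.call(rbind, lapply(rows, `[[`, "truth")),
    config = config
  ), class = "oxex_dataset")
}

#' @export
print.oxex_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated oxygen-exchange dataset: %d conditions, %d molecules each (seed %d)\n",
    nrow(x$observations), x$config$molecules_per_condition, x$config$seed))
  print(utils::head(cbind(x$observations, n_true = x$truth$n), 12))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
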