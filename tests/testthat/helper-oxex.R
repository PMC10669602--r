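# Shared fixtures and oracles for the oxex test-suite.

# Measured initial distribution of the gamma-phosphoryl label used in the
# intermediate-concentration experiments (sums to 100 exactly).
initial_gamma <- label_distribution(57, 17, 2, 24)

# Monte-Carlo standard error (percentage scale) of a sampled component.
mc_se_pct <- function(p_pct, n) {
  p <- p_pct / 100
  sqrt(p * (1 - p) / n) * 100
}

# Noiseless forward-model observations: extents from the uptake law at
# kt = k / v over a velocity grid.
forward_observations <- function(velocities, k = 10.5) {
  data.frame(
    velocity_per_s = velocities,
    o18_per_p = 4 * extent_from_kt(k / velocities)$X
  )
}

# Velocities over five decades of ATP via the Michaelis-Menten law.
mm_velocities <- function(n_points = 20, vmax = 640, km = 99,
                          s_min = 0.11, s_max = 5000) {
  S <- 10^seq(log10(s_min), log10(s_max), length.out = n_points)
  list(S = S, v = vmax * S / (km + S))
}
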