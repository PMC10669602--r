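test_that("single-molecule washout respects its degenerate limits", {
  set.seed(1)
  expect_equal(simulate_molecule_washout(c(3L, 2L, 1L, 0L), 0),
               c(3L, 2L, 1L, 0L))
  expect_equal(simulate_molecule_washout(rep(0L, 100), 5), rep(0L, 100))
  expect_error(simulate_molecule_washout(4L, 1), class = "oxex_domain_error")
  expect_error(simulate_molecule_washout(3L, -1), class = "oxex_domain_error")
})

test_that("washout of fully labelled molecules matches the closed forms", {
  set.seed(2)
  N <- 1e6
  final <- simulate_molecule_washout(rep(3L, N), kt = 1)
  emp <- vapply(3:0, function(l) mean(final == l) * 100, numeric(1))
  theory <- unclass(isotopomer_distribution(label_distribution(100, 0, 0, 0), 1))
  for (i in 1:4) {
    se <- max(mc_se_pct(theory[i], N), 1e-12)
    expect_lt(abs(emp[i] - theory[i]), 3 * se)
  }
})

test_that("population sampling reproduces the closed-form distribution", {
  set.seed(3)
  N <- 1e6
  pop <- simulate_population(initial_gamma, 0.4568, N)
  theory <- unclass(isotopomer_distribution(initial_gamma, 0.4568))
  for (comp in c("p3", "p2", "p1", "p0")) {
    se <- mc_se_pct(theory[[comp]], N)
    expect_lt(abs(pop$distribution[[comp]] - theory[[comp]]), 3 * se)
  }
  expect_equal(sum(pop$counts), N)

  one <- simulate_population(initial_gamma, 0.3, 1)
  expect_equal(sort(unname(unclass(one$distribution))), c(0, 0, 0, 100))
})

test_that("sampled distributions pass a goodness-of-fit screen across kt", {
  set.seed(42)
  N <- 1e5
  kt_grid <- seq(0.05, 6, length.out = 20)
  pvals <- vapply(kt_grid, function(kt) {
    pop <- simulate_population(initial_gamma, kt, N)
    expected <- unclass(isotopomer_distribution(initial_gamma, kt)) / 100
    keep <- expected > 1e-12
    stat <- sum((pop$counts[keep] - N * expected[keep])^2 /
                  (N * expected[keep]))
    pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("uptake simulation matches the uptake closed form", {
  expect_equal(simulate_uptake_extent(0, 1000)$X, 0.25)
  set.seed(4)
  expect_gt(simulate_uptake_extent(30, 1e4)$X, 0.999)

  N <- 1e6
  sim <- simulate_uptake_extent(1, N)
  theory <- 1 - 0.75 * exp(-1)
  p <- 1 - exp(-1)
  se_X <- sqrt(3 * p * (1 - p) / N) / 4   # per-molecule labels are 1 + Bin(3, p)
  expect_lt(abs(sim$X - theory), 3 * se_X)
})

test_that("dataset generation applies the regime switch rule", {
  ds <- simulate_dataset(simulation_config(atp_concs = c(3, 5), seed = 1))
  # with Vmax = 640 and Km = 99: t(3 uM) = 53 ms > 33 ms, t(5 uM) = 32.5 ms
  expect_equal(ds$truth$n, c(2L, 3L))
  expect_equal(ds$observations$velocity_per_s,
               640 * c(3, 5) / (99 + c(3, 5)))
  expect_equal(ds$truth$kt_washout,
               10.5 * ds$truth$n * ds$truth$t_per_site_s)
})

test_that("dataset generation is deterministic in the seed", {
  cfg <- simulation_config(seed = 123)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$observations, b$observations)
  c <- simulate_dataset(simulation_config(seed = 124))
  expect_false(identical(a$observations, c$observations))
})

test_that("washout-mode 18O/P equals the sampled mean label count", {
  ds <- simulate_dataset(simulation_config(atp_concs = c(1, 100), seed = 9,
                                           o18_source = "washout"))
  implied <- (3 * ds$observations$p3_pct + 2 * ds$observations$p2_pct +
                ds$observations$p1_pct) / 100
  expect_equal(ds$observations$o18_per_p, implied)
})

test_that("simulated 18O/P converges to the uptake law at large N", {
  ds <- simulate_dataset(simulation_config(atp_concs = c(10, 1000),
                                           molecules_per_condition = 1e6,
                                           seed = 6))
  expected <- 4 * extent_from_kt(ds$truth$kt_uptake)$X
  p <- 1 - exp(-ds$truth$kt_uptake)
  se <- sqrt(3 * p * (1 - p) / 1e6)   # on the 18O/P scale
  expect_true(all(abs(ds$observations$o18_per_p - expected) < 3 * se))
})

test_that("the full pipeline recovers k and the site labels", {
  ds <- simulate_dataset(simulation_config(seed = 1))
  # the lowest concentrations saturate the 18O/P assay and are excluded
  fit <- suppressWarnings(fit_rate_constant(ds$observations))
  expect_lt(abs(fit$estimates[["k"]] - 10.5) / 10.5, 0.05)

  hits <- 0L; total <- 0L
  for (s in 1:100) {
    ds_s <- simulate_dataset(simulation_config(seed = s))
    n_hat <- vapply(seq_len(nrow(ds_s$observations)), function(i) {
      o <- ds_s$observations[i, ]
      d <- label_distribution(o$p3_pct, o$p2_pct, o$p1_pct, o$p0_pct,
                              normalize = TRUE)
      select_site_count(o$velocity_per_s, d, 10.5, initial_gamma,
                        candidates = c(2L, 3L))$n_selected
    }, integer(1))
    hits <- hits + sum(n_hat == ds_s$truth$n)
    total <- total + nrow(ds_s$observations)
  }
  expect_gte(hits / total, 0.95)
})

test_that("simulation config validates its fields", {
  expect_error(simulation_config(k = -1), class = "oxex_domain_error")
  expect_error(simulation_config(vmax = 0), class = "oxex_domain_error")
  expect_error(simulation_config(molecules_per_condition = 0),
               class = "oxex_domain_error")
  expect_error(simulation_config(n_rule = "three"),
               class = "oxex_usage_error")
})
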