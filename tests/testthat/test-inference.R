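test_that("zero-intercept regression recovers the generating slope exactly", {
  v <- exp(seq(log(3.5), log(650), length.out = 15))
  fit <- fit_rate_constant(forward_observations(v, k = 10.5))
  expect_equal(unname(fit$estimates[["k"]]), 10.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_length(fit$residuals, 15)
})

test_that("two points determine the slope through the origin", {
  obs <- data.frame(
    velocity_per_s = c(10, 5),   # t = 0.1, 0.2
    o18_per_p = 4 * extent_from_kt(c(1.05, 2.10))$X
  )
  fit <- fit_rate_constant(obs)
  expect_equal(unname(fit$estimates[["k"]]), 10.5, tolerance = 1e-10)
})

test_that("rate constant is recovered within 5% under counting noise", {
  set.seed(1)
  v <- exp(seq(log(3.5), log(650), length.out = 15))
  o18 <- vapply(v, function(vi)
    simulate_uptake_extent(10.5 / vi, 1e4)$o18_per_p, numeric(1))
  fit <- fit_rate_constant(data.frame(velocity_per_s = v, o18_per_p = o18))
  expect_lt(abs(fit$estimates[["k"]] - 10.5) / 10.5, 0.05)
})

test_that("free-intercept diagnostic mode reports a conventional R-squared", {
  v <- exp(seq(log(3.5), log(650), length.out = 10))
  fit <- fit_rate_constant(forward_observations(v), intercept = TRUE)
  expect_equal(unname(fit$estimates[["k"]]), 10.5, tolerance = 1e-8)
  expect_equal(unname(fit$estimates[["intercept"]]), 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("rate fit rejects bad designs and names offending records", {
  obs <- forward_observations(c(10, 5))
  obs$o18_per_p[2] <- 0.8   # extent 0.2, below the floor
  expect_error(fit_rate_constant(obs), "row 2", class = "oxex_domain_error")
  expect_error(fit_rate_constant(forward_observations(c(10, 10))),
               class = "oxex_fit_error")
  expect_error(fit_rate_constant(forward_observations(10)),
               class = "oxex_usage_error")
})

test_that("saturated 18O/P readings are excluded before the log transform", {
  v <- c(0.5, 0.7, exp(seq(log(3.5), log(650), length.out = 10)))
  obs <- forward_observations(v, k = 10.5)   # first two are above 3.98
  expect_warning(fit <- fit_rate_constant(obs), "saturated")
  expect_equal(unname(fit$estimates[["k"]]), 10.5, tolerance = 1e-9)
  expect_length(fit$residuals, 10)
  # everything saturated -> nothing to fit
  expect_warning(
    expect_error(fit_rate_constant(forward_observations(c(0.5, 0.7))),
                 class = "oxex_fit_error"),
    "saturated")
})

test_that("site count is recovered from simulator output in both regimes", {
  k <- 10.5
  set.seed(1)
  long_time <- simulate_population(initial_gamma, k * 2 / 4, 1e4)
  sel2 <- select_site_count(4, long_time$distribution, k, initial_gamma)
  expect_identical(sel2$n_selected, 2L)
  expect_false(sel2$tie)

  short_time <- simulate_population(initial_gamma, k * 3 / 200, 1e4)
  sel3 <- select_site_count(200, short_time$distribution, k, initial_gamma)
  expect_identical(sel3$n_selected, 3L)
  expect_lt(sel3$score[["n3"]], sel3$score[["n2"]])
})

test_that("no-exchange observation ties all candidates and picks n = 1", {
  sel <- select_site_count(Inf, initial_gamma, 10.5, initial_gamma)
  expect_true(sel$tie)
  expect_identical(sel$n_selected, 1L)
  expect_equal(unname(sel$score), rep(0, 3))
})

test_that("selection accuracy does not degrade as molecule counts grow", {
  k <- 10.5
  cases <- list(list(v = 4, n = 2L), list(v = 200, n = 3L))
  accuracy <- sapply(c(1e2, 1e3, 1e4), function(N) {
    set.seed(20)
    hits <- 0L; total <- 0L
    for (s in 1:100) {
      for (cs in cases) {
        pop <- simulate_population(initial_gamma, k * cs$n / cs$v, N)
        sel <- select_site_count(cs$v, pop$distribution, k, initial_gamma)
        hits <- hits + (sel$n_selected == cs$n)
        total <- total + 1L
      }
    }
    hits / total
  })
  expect_true(all(diff(accuracy) >= 0))
  expect_equal(accuracy[3], 1)
})

test_that("chi-square criterion agrees with SSE on well-separated cases", {
  set.seed(3)
  pop <- simulate_population(initial_gamma, 10.5 * 2 / 4, 1e4)
  sse <- select_site_count(4, pop$distribution, 10.5, initial_gamma)
  chi <- select_site_count(4, pop$distribution, 10.5, initial_gamma,
                           criterion = "chisq", n_molecules = 1e4)
  expect_identical(sse$n_selected, chi$n_selected)
  expect_error(
    select_site_count(4, pop$distribution, 10.5, initial_gamma,
                      criterion = "chisq"),
    class = "oxex_usage_error")
  expect_error(
    select_site_count(4, pop$distribution, 10.5, initial_gamma,
                      candidates = integer(0)),
    class = "oxex_usage_error")
})

test_that("transition detection brackets the regime switch", {
  ds <- simulate_dataset(simulation_config(seed = 4))
  res <- detect_transition(ds$observations, 10.5, initial_gamma)
  expect_true(res$transition)
  expect_lte(res$bracket_time_s[1], 0.033)
  expect_gte(res$bracket_time_s[2], 0.033)
  expect_equal(res$transition_time_s, mean(res$bracket_time_s))
})

test_that("transition midpoint is arithmetic on the bracketing times", {
  mk_obs <- function(v, n) {
    d <- isotopomer_distribution(initial_gamma, 10.5 * n / v)
    data.frame(atp_conc_uM = if (n == 3) 100 else 1, velocity_per_s = v,
               p3_pct = d[["p3"]], p2_pct = d[["p2"]],
               p1_pct = d[["p1"]], p0_pct = d[["p0"]])
  }
  obs <- rbind(mk_obs(200, 3), mk_obs(4, 2))   # 5 ms and 250 ms
  res <- detect_transition(obs, 10.5, initial_gamma)
  expect_equal(res$transition_time_s, 0.1275)
  expect_equal(res$bracket_time_s, c(0.005, 0.25))
  expect_equal(res$bracket_atp_uM, c(100, 1))
})

test_that("uniform-regime series reports no transition", {
  obs <- do.call(rbind, lapply(c(3, 4, 6), function(v) {
    d <- isotopomer_distribution(initial_gamma, 10.5 * 2 / v)
    data.frame(atp_conc_uM = v, velocity_per_s = v,
               p3_pct = d[["p3"]], p2_pct = d[["p2"]],
               p1_pct = d[["p1"]], p0_pct = d[["p0"]])
  }))
  res <- detect_transition(obs, 10.5, initial_gamma)
  expect_false(res$transition)
  expect_true(is.na(res$transition_time_s))
})

test_that("non-monotone site labels raise a warning, not an error", {
  mk_obs <- function(v, n) {
    d <- isotopomer_distribution(initial_gamma, 10.5 * n / v)
    data.frame(atp_conc_uM = v, velocity_per_s = v,
               p3_pct = d[["p3"]], p2_pct = d[["p2"]],
               p1_pct = d[["p1"]], p0_pct = d[["p0"]])
  }
  obs <- rbind(mk_obs(200, 3), mk_obs(50, 2), mk_obs(4, 3))
  expect_warning(res <- detect_transition(obs, 10.5, initial_gamma),
                 "not monotone")
  expect_equal(nrow(res$labels), 3)
})

test_that("Michaelis-Menten fit recovers generating constants exactly", {
  grid <- mm_velocities(12)
  fit <- fit_michaelis_menten(grid$S, grid$v)
  expect_equal(unname(fit$estimates[["Vmax"]]), 640, tolerance = 1e-6)
  expect_equal(unname(fit$estimates[["Km"]]), 99, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("half-maximal velocity occurs at S = Km", {
  S <- c(10, 99, 1000)
  v <- 640 * S / (99 + S)
  expect_equal(v[2], 320)
  fit <- fit_michaelis_menten(S, v)
  expect_equal(unname(fit$estimates[["Km"]]), 99, tolerance = 1e-6)
})

test_that("saturated designs leave Km poorly identified", {
  S <- c(5e4, 7e4, 1e5, 2e5)   # all far above Km
  set.seed(5)
  v <- 640 * S / (99 + S) * (1 + rnorm(4, sd = 1e-3))
  fit <- fit_michaelis_menten(S, v)
  expect_gt(fit$std_errors[["Km"]] / max(fit$estimates[["Km"]], 1), 0.5)
})

test_that("Michaelis-Menten fit is scale-equivariant in velocity", {
  grid <- mm_velocities(10)
  f1 <- fit_michaelis_menten(grid$S, grid$v)
  f2 <- fit_michaelis_menten(grid$S, 3.7 * grid$v)
  expect_equal(unname(f2$estimates[["Vmax"]]),
               3.7 * unname(f1$estimates[["Vmax"]]), tolerance = 1e-6)
  expect_equal(unname(f2$estimates[["Km"]]),
               unname(f1$estimates[["Km"]]), tolerance = 1e-6)
})

test_that("Michaelis-Menten fit validates its inputs", {
  expect_error(fit_michaelis_menten(c(1, 2), c(1, 2)),
               class = "oxex_usage_error")
  expect_error(fit_michaelis_menten(c(1, 2, -1), c(1, 2, 3)),
               class = "oxex_domain_error")
})
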