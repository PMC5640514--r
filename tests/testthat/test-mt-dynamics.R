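# Dynamic instability: growth law, catastrophe law, conservation, renewal

test_that("growth speed follows the force- and pool-attenuated law", {
  expect_equal(growth_speed(0.2, 0, 1.5, 0, 500), 0.2)
  expect_equal(growth_speed(0.2, 1.5, 1.5, 0, 500), 0.2 * exp(-1))
  expect_equal(growth_speed(0.2, 0, 1.5, 500, 500), 0)      # exhausted pool
  expect_equal(growth_speed(0.2, -3, 1.5, 0, 500), 0.2)     # pushing force clamped
  # monotone decreasing in force and in pool usage
  f <- seq(0, 10, 0.5)
  v <- vapply(f, function(ff) growth_speed(0.2, ff, 1.5, 100, 500), 0)
  expect_true(all(diff(v) < 0))
  expect_true(all(v >= 0 & v <= 0.2))
})

test_that("catastrophe rate interpolates between stalled and free limits", {
  expect_equal(catastrophe_rate(0.2, 0.2, 600, 30), 1 / 600)
  expect_equal(catastrophe_rate(0, 0.2, 600, 30), 1 / 30)
  expect_equal(catastrophe_rate(0.1, 0.2, 600, 30), 1 / 315)
  v <- seq(0, 0.2, 0.01)
  r <- vapply(v, function(vv) catastrophe_rate(vv, 0.2, 600, 30), 0)
  expect_true(all(diff(r) <= 0))
  expect_error(catastrophe_rate(0.1, 0.2, 600, 0), "t_stalled")
})

test_that("tubulin is conserved and rescue never happens over 1e4 steps", {
  p <- simulation_params(duration = 100)   # 1e4 steps at dt = 0.01
  res <- simulate_myotube("control", params = p, duration = 100, seed = 8,
                          frame_stride = 1e5)
  expect_lt(res$diagnostics[["max_conservation_error"]], 1e-6)
  expect_identical(unname(res$events[["rescues"]]), 0)
  expect_lte(res$pool$L_polymerized, res$pool$L_max)
  expect_gt(res$events[["nucleations"]], 0)
})

test_that("nucleation is horizontal with balanced +x/-x directions", {
  p <- simulation_params(duration = 60, nucleation_rate = 0.2,
                         tubulin_pool_Lmax = 1e5,
                         n_dynein_per_nucleus = 0, n_kif5b_per_nucleus = 0,
                         n_map4 = 0, n_map7kif5b = 0)
  tot_p <- 0; tot_m <- 0
  for (sd in 1:4) {
    res <- simulate_myotube("control", params = p, duration = 60, seed = sd,
                            frame_stride = 1e5)
    tot_p <- tot_p + res$events[["nucleations_plus_x"]]
    tot_m <- tot_m + res$events[["nucleations_minus_x"]]
  }
  n <- tot_p + tot_m
  expect_gt(n, 100)
  # binomial 3 sigma around 1/2
  expect_lt(abs(tot_p / n - 0.5), 3 * sqrt(0.25 / n))
  # with zero angular spread and no obstacles, fibers stay exactly
  # horizontal (single nucleus so that nothing deflects young fibers)
  p0 <- simulation_params(duration = 5, temperature_kT = 0,
                          nucleation_rate = 0.2, nucleation_angle_sd = 0,
                          nucleus_count = 9,
                          n_dynein_per_nucleus = 0, n_kif5b_per_nucleus = 0,
                          n_map4 = 0, n_map7kif5b = 0)
  st <- initialize_state("control", p0, seed = 2)
  st$bodies <- st$bodies[1, ]; st$bodies$x <- 0; st$bodies$y <- 0
  st$bodies$drag <- 1e9    # pinned, so anchored fiber bases cannot drift
  st$sites <- st$sites[st$sites$body == 1, ]
  # short horizon: fibers are still short, so steric deflection of the
  # shared body is negligible and every fiber is horizontal
  res <- run_simulation(st, duration = 0.5, frame_stride = 1e6, seed = 2)
  expect_gt(length(res$mts$y), 2)
  yr <- vapply(res$mts$y, function(v) diff(range(v)), 0)
  # fibers that grow into their own nucleus are deflected sterically;
  # the unobstructed majority must be exactly horizontal
  expect_lt(median(yr), 1e-9)
  expect_gt(mean(yr < 1e-9), 0.4)
})

test_that("per-nucleus MT cap is enforced by the nucleation sites", {
  p <- simulation_params(duration = 120, nucleation_rate = 1,
                         max_mts_per_nucleus = 4, tubulin_pool_Lmax = 1e5,
                         n_dynein_per_nucleus = 0, n_kif5b_per_nucleus = 0,
                         n_map4 = 0, n_map7kif5b = 0)
  res <- simulate_myotube("control", params = p, duration = 120, seed = 3,
                          frame_stride = 1e5)
  st <- initialize_state("control", p, seed = 3)
  host <- st$sites$body[res$mts$site]
  expect_true(all(table(host) <= 4))
})

test_that("steady-state lengths match an event-driven renewal oracle", {
  # constant catastrophe rate (stalled == free), huge pool, no forces:
  # the engine should reproduce the two-state renewal process
  t_cat <- 50; v_g <- 0.2; v_s <- 0.4; r_nuc <- 0.02; t_end <- 300
  p <- simulation_params(duration = t_end, v_grow0 = v_g, v_shrink = v_s,
                         cat_time_free = t_cat, cat_time_stalled = t_cat,
                         nucleation_rate = r_nuc, tubulin_pool_Lmax = 1e6,
                         nucleus_count = 9,
                         n_dynein_per_nucleus = 0, n_kif5b_per_nucleus = 0,
                         n_map4 = 0, n_map7kif5b = 0, temperature_kT = 0)
  lens <- c()
  for (sd in 1:15) {
    # a single nucleus at the center of the large domain: no obstacles,
    # so growth is genuinely unloaded
    st <- initialize_state("control", p, seed = 600 + sd)
    st$bodies <- st$bodies[1, ]; st$bodies$x <- 0; st$bodies$y <- 0
    st$sites <- st$sites[st$sites$body == 1, ]
    res <- run_simulation(st, duration = t_end, frame_stride = 1e6)
    lens <- c(lens, res$mts$length)
  }
  set.seed(77)
  oracle <- na.omit(replicate(2000, renewal_lengths_oracle(
    v_g, v_s, 1 / t_cat, r_nuc, t_end, t_end)))
  se <- sqrt(var(lens) / length(lens) + var(oracle) / length(oracle))
  expect_gt(length(lens), 100)
  expect_lt(abs(mean(lens) - mean(oracle)), 3 * se + 0.05 * mean(oracle))
})
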