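# Motors and crosslinkers: force-velocity, Hookean pairs, kinetics, sliding

test_that("linear force-velocity with stall and clamping", {
  expect_equal(motor_velocity(0, 0.8, 5), 0.8)
  expect_equal(motor_velocity(5, 0.8, 5), 0)
  expect_equal(motor_velocity(2.5, 0.8, 5), 0.4)
  expect_equal(motor_velocity(50, 0.8, 5), 0)     # super-stall: no walking back
  expect_equal(motor_velocity(-3, 0.8, 5), 0.8)   # assisting: capped at v0
  expect_error(motor_velocity(1, 0.8, 0), "f_stall")
})

test_that("connector spring force pair is Hookean, equal and opposite", {
  f <- connector_forces(c(0, 0), c(0.1, 0), 100)
  expect_equal(f$f1, c(10, 0))
  expect_equal(f$f2, c(-10, 0))
  expect_equal(connector_forces(c(3, 2), c(3, 2), 50)$f1, c(0, 0))
  spc <- connector_species()
  expect_setequal(spc$name, c("dynein", "kif5b", "map4", "map7kif5b"))
  expect_equal(spc$v0[spc$name == "map4"], 0)
  expect_equal(spc$direction[spc$name == "dynein"], -1)
})

test_that("bound fraction of a saturated head matches k_on/(k_on+k_off)", {
  set.seed(55)
  fb <- myospread:::cpp_bound_fraction_toy(5, 0.5, 0.01, 2e5)
  expect_lt(abs(fb - 5 / 5.5), 0.03)
  # and through the full engine: one anchored motor with a fiber always in
  # reach spends about the same fraction of time bound
  p <- simulation_params(.overrides = list(
    nucleus_count = 9, temperature_kT = 0, nucleation_rate = 0,
    n_map4 = 0, n_map7kif5b = 0,
    n_dynein_per_nucleus = 0, n_kif5b_per_nucleus = 0,
    cat_time_free = 1e9, cat_time_stalled = 1e9, kif5b_v0 = 0,
    kif5b_f_unbind = Inf))
  st <- initialize_state("control", p, seed = 1)
  st$bodies <- st$bodies[1, ]; st$bodies$x <- 0; st$bodies$y <- 0
  st$bodies$drag <- 1e9                      # pinned
  st$sites <- st$sites[0, ]; st$links <- st$links[0, ]
  st$anchors <- data.frame(body = 1, angle = pi / 2, species = "kif5b")
  st$mts <- data.frame(site = 0, x = -20, y = 4.02, dir_x = 1, dir_y = 0,
                       length = 40, state = "growing")
  st$pool$L_max <- 40; st$pool$L_polymerized <- 40
  set.seed(56)
  res <- run_simulation(st, duration = 300, frame_stride = 1e6)
  expect_lt(abs(res$diagnostics[["mean_anchor_bound"]] - 5 / 5.5), 0.1)
})

test_that("equidistant fibers are tie-broken toward the lowest MT id", {
  p <- simulation_params(.overrides = list(
    nucleus_count = 9, temperature_kT = 0, nucleation_rate = 0,
    n_map4 = 0, n_map7kif5b = 0,
    n_dynein_per_nucleus = 0, n_kif5b_per_nucleus = 0,
    cat_time_free = 1e9, cat_time_stalled = 1e9,
    kif5b_v0 = 0, kif5b_k_off = 0, kif5b_f_unbind = Inf))
  st <- initialize_state("control", p, seed = 1)
  # a tiny pinned body so that neither fiber touches it: the anchor sits at
  # (0, 1/64) and the fibers pass at binary-exact distances +-1/32
  st$bodies <- st$bodies[1, ]; st$bodies$x <- 0; st$bodies$y <- 0
  st$bodies$radius <- 1 / 64
  st$bodies$drag <- 1e9
  st$sites <- st$sites[0, ]; st$links <- st$links[0, ]
  st$anchors <- data.frame(body = 1, angle = pi / 2, species = "kif5b")
  st$mts <- data.frame(site = c(0, 0), x = c(-20, -20),
                       y = c(1 / 64 + 1 / 32, 1 / 64 - 1 / 32),
                       dir_x = 1, dir_y = 0, length = 40, state = "growing")
  st$pool$L_max <- 80; st$pool$L_polymerized <- 80
  res <- run_simulation(st, duration = 5, frame_stride = 1e6, seed = 2)
  expect_equal(res$connectors_detail$anchor_mt, 1L)
})

test_that("kinesin transports a nucleus toward the plus end, dynein toward the minus end", {
  base <- list(nucleus_count = 9, temperature_kT = 0, nucleation_rate = 0,
               n_map4 = 0, n_map7kif5b = 0,
               n_dynein_per_nucleus = 0, n_kif5b_per_nucleus = 0,
               cat_time_free = 1e9, cat_time_stalled = 1e9)
  toy <- function(species) {
    p <- simulation_params(.overrides = base)
    st <- initialize_state("control", p, seed = 1)
    st$bodies <- st$bodies[1, ]; st$bodies$x <- 0; st$bodies$y <- 0
    st$sites <- st$sites[0, ]; st$links <- st$links[0, ]
    st$anchors <- data.frame(body = 1, angle = pi / 2, species = species)
    st$mts <- data.frame(site = 0, x = -20, y = 4.02, dir_x = 1, dir_y = 0,
                         length = 40, state = "growing")
    st$pool$L_max <- 40; st$pool$L_polymerized <- 40
    run_simulation(st, duration = 30, frame_stride = 1e6, seed = 3)$bodies$x
  }
  expect_gt(toy("kif5b"), 0.5)    # toward the fiber plus end (+x)
  expect_lt(toy("dynein"), -0.5)  # toward the minus end (-x)
})

test_that("NE dynein pulls a nucleus toward the minus end anchored at a neighbour", {
  p <- simulation_params(.overrides = list(
    nucleus_count = 2, temperature_kT = 0, nucleation_rate = 0,
    n_map4 = 0, n_map7kif5b = 0,
    n_dynein_per_nucleus = 0, n_kif5b_per_nucleus = 0,
    cat_time_free = 1e9, cat_time_stalled = 1e9))
  st <- suppressMessages(initialize_state("control", p, seed = 1))
  st$bodies <- st$bodies[1:2, ]
  st$bodies$x <- c(-10, 10); st$bodies$y <- c(0, 0)
  # fiber nucleated at the top of B, growing over the top of A where a
  # single dynein is anchored (grazing contact, no steric conflict)
  st$sites <- data.frame(body = 2, angle = pi / 2, active = FALSE)
  st$anchors <- data.frame(body = 1, angle = pi / 2, species = "dynein")
  st$links <- st$links[0, ]
  st$mts <- data.frame(site = 1, x = 10, y = 4, dir_x = -1, dir_y = 0,
                       length = 20.05, state = "growing")
  st$pool$L_max <- 20.05; st$pool$L_polymerized <- 20.05
  res <- run_simulation(st, duration = 30, frame_stride = 1e6, seed = 4)
  dA <- res$bodies$x[1] - (-10)
  expect_gt(dA, 0.3)   # A moves toward B (the fiber's minus end)
})

test_that("motile crosslinkers slide antiparallel fibers apart; passive ones hold parallel fibers", {
  p <- simulation_params(.overrides = list(
    nucleus_count = 9, temperature_kT = 0, nucleation_rate = 0,
    n_map4 = 0, n_map7kif5b = 0,
    n_dynein_per_nucleus = 0, n_kif5b_per_nucleus = 0,
    cat_time_free = 1e9, cat_time_stalled = 1e9))
  sliding <- function(link_species, antiparallel) {
    st <- initialize_state("control", p, seed = 1)
    st$bodies <- st$bodies[0, ]; st$sites <- st$sites[0, ]
    st$anchors <- st$anchors[0, ]
    st$links <- data.frame(species = link_species,
                           x = c(-1, 0, 1), y = 0.01)
    if (antiparallel)
      st$mts <- data.frame(site = c(0, 0), x = c(-15, 15), y = c(0, 0.02),
                           dir_x = c(1, -1), dir_y = 0, length = 30,
                           state = "growing")
    else
      st$mts <- data.frame(site = c(0, 0), x = c(-15, -15), y = c(0, 0.02),
                           dir_x = c(1, 1), dir_y = 0, length = 30,
                           state = "growing")
    st$pool$L_max <- 60; st$pool$L_polymerized <- 60
    res <- run_simulation(st, duration = 40, frame_stride = 1e6, seed = 5)
    minus_x <- vapply(res$mts$x, `[`, 0, 1)
    list(sep = abs(minus_x[2] - minus_x[1]), res = res)
  }
  init_anti <- 30
  out <- sliding("map7kif5b", TRUE)
  expect_gt(out$sep, init_anti + 2)      # antiparallel pair driven apart
  out2 <- sliding("map4", FALSE)
  expect_lt(abs(out2$sep - 0), 0.5)      # passive crosslink: no sliding
})
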