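# Langevin mechanics: diffusion, drift, confinement, sterics, stability

# single free nucleus in a large domain, nothing else
free_body_state <- function(p, seed) {
  st <- initialize_state("control", p, seed = seed)
  st$bodies <- st$bodies[1, ]; st$bodies$x <- 0; st$bodies$y <- 0
  st$sites <- st$sites[0, ]; st$anchors <- st$anchors[0, ]
  st$links <- st$links[0, ]
  st
}

bare_params <- function(...) {
  simulation_params(.overrides = utils::modifyList(
    list(nucleus_count = 9, nucleation_rate = 0,
         n_dynein_per_nucleus = 0, n_kif5b_per_nucleus = 0,
         n_map4 = 0, n_map7kif5b = 0), list(...)))
}

test_that("free-body MSD matches the Stokes-Einstein prediction", {
  # the 10^3-replicate 5% version runs with the acceptance checks; this is
  # a faster smoke test of the same law
  p <- bare_params()
  st <- free_body_state(p, 1)
  tt <- 5; n <- 500
  set.seed(123)
  d2 <- replicate(n, {
    res <- run_simulation(st, duration = tt, frame_stride = 1e6)
    res$bodies$x^2 + res$bodies$y^2
  })
  D <- p$temperature_kT / st$bodies$drag[1]
  expect_lt(abs(mean(d2) / (4 * D * tt) - 1), 0.1)
})

test_that("drift under constant force matches F t / gamma", {
  p <- bare_params(external_fx = 0.5, external_fy = -0.2)
  st <- free_body_state(p, 1)
  tt <- 10; n <- 60
  set.seed(124)
  xs <- replicate(n, unlist(run_simulation(st, duration = tt,
                                           frame_stride = 1e6)$bodies[c("x", "y")]))
  g <- st$bodies$drag[1]
  se <- sqrt(2 * (p$temperature_kT / g) * tt / n)   # SEM of the mean position
  expect_lt(abs(mean(xs[1, ]) - 0.5 * tt / g), 3 * se)
  expect_lt(abs(mean(xs[2, ]) - (-0.2) * tt / g), 3 * se)
  # deterministic rest: kT = 0 and no force -> exactly no motion
  p0 <- bare_params(temperature_kT = 0)
  st0 <- free_body_state(p0, 1)
  res0 <- run_simulation(st0, duration = 5, frame_stride = 1e6)
  expect_identical(res0$bodies$x, st0$bodies$x)
  expect_identical(res0$bodies$y, st0$bodies$y)
})

test_that("confinement force is zero inside and linear toward the nearest boundary point", {
  d <- make_domain(5)
  expect_equal(confinement_force(c(0, 0), d, 100), c(0, 0))
  expect_equal(confinement_force(c(d$a - 0.01, 0), d, 100), c(0, 0))
  # outside along the major axis: magnitude k * penetration, direction -x
  f <- confinement_force(c(d$a + 2, 0), d, 100)
  expect_equal(f, c(-200, 0), tolerance = 1e-6)
  # generic outside point vs an independent 1D-minimization oracle
  pt <- c(d$a * 0.9, d$b * 1.4)
  np <- ellipse_nearest_point(pt, d$a, d$b)
  oracle <- optimize(function(th) {
    (d$a * cos(th) - pt[1])^2 + (d$b * sin(th) - pt[2])^2
  }, c(0, pi / 2), tol = 1e-12)
  onp <- c(d$a * cos(oracle$minimum), d$b * sin(oracle$minimum))
  expect_equal(np, onp, tolerance = 1e-6)
  f2 <- confinement_force(pt, d, 100)
  expect_equal(f2, 100 * (onp - pt), tolerance = 1e-5)
  # a body touching the reduced boundary feels no force
  r <- 4
  expect_equal(confinement_force(c(d$a - r, 0), d, 100, radius = r), c(0, 0))
})

test_that("steric force is a linear equal-and-opposite contact repulsion", {
  s0 <- steric_force(c(0, 0), 4, c(8, 0), 4, 100)
  expect_equal(s0$fA, c(0, 0))                       # exactly touching
  s1 <- steric_force(c(0, 0), 4, c(7.9, 0), 4, 100)  # 0.1 um overlap
  expect_equal(s1$fA, c(-10, 0))
  expect_equal(s1$fB, c(10, 0))
  expect_equal(s1$fA, -s1$fB)
  # coincident centers: deterministic +x fallback
  s2 <- steric_force(c(1, 1), 2, c(1, 1), 2, 50)
  expect_equal(s2$fB / sqrt(sum(s2$fB^2)), c(1, 0))
})

test_that("crossing fibers exert no steric force on each other", {
  p <- bare_params(temperature_kT = 0, cat_time_free = 1e9,
                   cat_time_stalled = 1e9)
  st <- initialize_state("control", p, seed = 1)
  st$bodies <- st$bodies[0, ]; st$sites <- st$sites[0, ]
  st$anchors <- st$anchors[0, ]; st$links <- st$links[0, ]
  # one horizontal, one oblique fiber crossing at the origin, both well
  # inside the domain
  st$mts <- data.frame(site = c(0, 0), x = c(-10, -5), y = c(0, -2.5),
                       dir_x = c(1, 0.8944272), dir_y = c(0, 0.4472136),
                       length = c(20, 11.18034), state = "growing")
  st$pool$L_max <- 31.18034; st$pool$L_polymerized <- 31.18034  # frozen
  res <- run_simulation(st, duration = 5, frame_stride = 1e6)
  for (i in 1:2) {
    n <- length(res$mts$x[[i]])
    # interior vertices sit at multiples of the segment rest length, the
    # tip vertex carries the remainder
    arcs <- pmin(2 * (seq_len(n) - 1), st$mts$length[i])
    expect_equal(res$mts$x[[i]], st$mts$x[i] + st$mts$dir_x[i] * arcs,
                 tolerance = 1e-2)
    expect_equal(res$mts$y[[i]], st$mts$y[i] + st$mts$dir_y[i] * arcs,
                 tolerance = 1e-2)
  }
})

test_that("internal forces balance to machine tolerance", {
  res <- simulate_myotube("control",
                          params = simulation_params(duration = 20),
                          duration = 20, seed = 9, frame_stride = 1e5)
  expect_lt(res$diagnostics[["max_net_internal_force"]], 1e-8)
})

test_that("a light tracer samples the accessible region without drift", {
  p <- bare_params(viscosity = 0.02)
  st <- initialize_state("control", p, seed = 5)
  st$bodies <- st$bodies[1, ]; st$bodies$x <- 0; st$bodies$y <- 0
  st$bodies$radius <- 0.2
  st$bodies$drag <- 6 * pi * p$viscosity * 0.2
  st$sites <- st$sites[0, ]; st$anchors <- st$anchors[0, ]
  st$links <- st$links[0, ]
  st$domain$a <- 6; st$domain$b <- 3
  set.seed(321)
  res <- run_simulation(st, duration = 1200, frame_stride = 100)
  x <- res$frames[-(1:200), 2]; y <- res$frames[-(1:200), 3]
  # no spurious drift and both halves visited (coarse, autocorrelation-aware)
  expect_lt(abs(mean(x)), 2)
  expect_gt(mean(x > 0), 0.15); expect_lt(mean(x > 0), 0.85)
  # stays essentially inside the (reduced) ellipse
  q <- (x / (6 - 0.2))^2 + (y / (3 - 0.2))^2
  expect_lt(mean(q > 1.1), 0.01)
})

test_that("halving dt leaves the ensemble-mean SF statistically unchanged", {
  sf_at <- function(dt) {
    p <- simulation_params(dt = dt, duration = 60)
    vapply(1:6, function(sd)
      simulate_myotube("control", params = p, duration = 60,
                       seed = 700 + sd, frame_stride = 1e6)$sf, 0)
  }
  a <- sf_at(0.01); b <- sf_at(0.005)
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * se + 0.02)
})
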