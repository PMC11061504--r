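# Hill-type MTU model: characteristic curves, geometry, equilibrium,
# activation-rate bounds, parameter perturbation.

test_that("tendon curve is calibrated: zero at zero strain, slope k at 4%", {
  expect_identical(tendon_force_norm(0, 35), 0)
  # closed form at the calibration strain
  expect_equal(tendon_force_norm(0.04, 35), 1 - exp(-1.4), tolerance = 1e-12)
  for (k in c(14, 20, 27.5, 35)) {
    slope <- (tendon_force_norm(0.04 + 1e-6, k) -
                tendon_force_norm(0.04 - 1e-6, k)) / 2e-6
    expect_equal(slope, k, tolerance = 1e-6)
  }
  # strictly increasing
  eps <- seq(-0.02, 0.09, by = 0.005)
  expect_true(all(diff(tendon_force_norm(eps, 35)) > 0))
  expect_error(tendon_force_norm(NaN, 35), "non-finite")
  expect_error(tendon_force_norm(0.02, -3), "k_tendon")
})

test_that("tendon curve inversion round-trips to 1e-10", {
  set.seed(1)
  for (i in 1:100) {
    k <- runif(1, 14, 35)
    f <- runif(1, 0, 3.5)
    expect_equal(tendon_force_norm(tendon_strain_from_force(f, k), k), f,
                 tolerance = 1e-10)
  }
})

test_that("active force-length: unit peak at optimum, small outside", {
  expect_equal(active_force_length(1), 1, tolerance = 0.01)
  expect_lt(active_force_length(0.5), 0.3)
  grid <- seq(0.3, 2, by = 0.001)
  v <- active_force_length(grid)
  expect_true(all(v >= 0 & v <= 1.001))
  expect_lt(abs(grid[which.max(v)] - 1), 0.05)
  # descending-limb monotonicity by dense sampling
  desc <- active_force_length(seq(1.1, 1.8, by = 0.01))
  expect_true(all(diff(desc) < 0))
  expect_lt(active_force_length(1.4), active_force_length(1.1))
  expect_error(active_force_length(-1), "> 0")
})

test_that("passive force-length: slack at optimum, 1 at the strain limit", {
  expect_lt(abs(passive_force_length(1)), 0.02)
  expect_true(all(abs(passive_force_length(seq(0.4, 1, by = 0.05))) <= 0.02))
  expect_equal(passive_force_length(1.6), 1, tolerance = 1e-12)
  up <- passive_force_length(seq(1, 1.8, by = 0.01))
  expect_true(all(diff(up) > 0))
  expect_gt(passive_force_length(1.3), passive_force_length(1.1))
  expect_lt(passive_force_length(1.3), passive_force_length(1.5))
})

test_that("force-velocity: isometric 1, vanishing at max shortening", {
  expect_equal(force_velocity(0), 1, tolerance = 0.01)
  expect_lte(force_velocity(-1), 0.05)
  expect_gte(force_velocity(0.5), force_velocity(0))
  v <- force_velocity(seq(-1, 1, by = 0.01))
  expect_true(all(diff(v) > 0))      # monotone increasing
  expect_true(all(v <= 1.8))         # bounded eccentric plateau
})

test_that("curves are C1: analytic derivatives match central differences", {
  dl <- seq(0.45, 1.9, by = 0.05)
  fd <- (active_force_length(dl + 1e-6) -
           active_force_length(dl - 1e-6)) / 2e-6
  expect_equal(hillmc:::active_force_length_d(dl), fd, tolerance = 1e-4)
  fd <- (passive_force_length(dl + 1e-6) -
           passive_force_length(dl - 1e-6)) / 2e-6
  expect_equal(hillmc:::passive_force_length_d(dl), fd, tolerance = 1e-4)
  vv <- seq(-1.2, 1.2, by = 0.05)
  fd <- (force_velocity(vv + 1e-6) - force_velocity(vv - 1e-6)) / 2e-6
  expect_equal(hillmc:::force_velocity_d(vv), fd, tolerance = 1e-4)
})

test_that("pennation geometry", {
  expect_identical(pennation_angle(1.3, 0), 0)
  a0 <- 15 * pi / 180
  expect_equal(pennation_angle(1, a0), a0, tolerance = 1e-12)
  expect_equal(pennation_angle(2, 30 * pi / 180), asin(0.25),
               tolerance = 1e-12)
  expect_error(pennation_angle(0.2, 30 * pi / 180, name = "vasti"),
               "vasti")
  # clamp: cos(angle) never below 0.1
  expect_lte(pennation_angle(1.0001, 80 * pi / 180), acos(0.1))
})

test_that("fiber state from tendon force", {
  p <- mtu_parameters("m", 1000, 0.1, 10 * pi / 180, 1, 35, 0.25, 0.5)
  fs <- fiber_state_from_tendon_force(0, 0.33, p)
  expect_equal(fs$tendon_length, p$l_tendon_slack)
  # force on the calibrated curve at 4% strain implies 4% elongation
  f04 <- tendon_force_norm(0.04, 35)
  fs4 <- fiber_state_from_tendon_force(f04, 0.36, p)
  expect_equal(fs4$tendon_length, 1.04 * p$l_tendon_slack,
               tolerance = 1e-12)
  # round trip through the forward curve
  set.seed(2)
  for (i in 1:100) {
    f <- runif(1, 0, 3)
    fs <- fiber_state_from_tendon_force(f, 0.40, p)
    strain <- fs$tendon_length / p$l_tendon_slack - 1
    expect_equal(tendon_force_norm(strain, p$k_tendon), f,
                 tolerance = 1e-10)
  }
  expect_error(fiber_state_from_tendon_force(3, 0.20, p), "fiber")
})

test_that("Hill equilibrium residual: slack, root-finding, monotonicity", {
  p <- mtu_parameters("m", 1000, 0.1, 5 * pi / 180, 1, 35, 0.25, 0.5)
  # fully slack MTU: a = 0, F = 0, fiber below optimal
  lmtu_slack <- 0.25 + 0.09   # fiber ~0.9 normalized
  r <- hill_equilibrium_residual(
    list(activation = 0, tendon_force_norm = 0),
    list(activation_rate = 0, tendon_force_rate = 0),
    lmtu_slack, 0, p)
  expect_lt(abs(r), 0.02)
  # isometric roots match scalar root-finding to 1e-8 (oracle equivalence)
  set.seed(3)
  for (i in 1:100) {
    a <- runif(1, 0.1, 1)
    lmtu <- 0.25 + runif(1, 0.08, 0.12)
    res <- function(f) hill_equilibrium_residual(
      list(activation = a, tendon_force_norm = f),
      list(activation_rate = 0, tendon_force_rate = 0), lmtu, 0, p)
    root <- stats::uniroot(res, c(0, 3.5), tol = 1e-13)$root
    expect_lt(abs(res(root)), 1e-8)
    # more activation than the equilibrium supports => negative residual
    expect_lt(hill_equilibrium_residual(
      list(activation = min(1, a + 0.1), tendon_force_norm = root),
      list(activation_rate = 0, tendon_force_rate = 0), lmtu, 0, p), 0)
  }
})

test_that("activation-rate bounds and the first-order response limit", {
  expect_equal(activation_rate_bounds(1)$max_rate, 0)
  expect_equal(activation_rate_bounds(0)$min_rate, 0)
  b <- activation_rate_bounds(0.5)
  expect_equal(b$min_rate, -0.5 / 0.06, tolerance = 1e-12)
  expect_equal(b$max_rate, 0.5 / 0.015, tolerance = 1e-12)
  expect_error(activation_rate_bounds(1.2), "activation")
  # integrating a_dot = (1 - a)/t_a from 0 reproduces 1 - exp(-t/t_a)
  ta <- 0.015
  out <- radau_integrate(function(t, x) (1 - x) / ta, 0, t_end = 0.06,
                         n_mesh = 20, degree = 3)
  expect_equal(out$state[, 1], 1 - exp(-out$time / ta), tolerance = 1e-6)
})

test_that("apply_perturbation is multiplicative and leaves slack length", {
  p <- mtu_parameters("m", 1000, 0.1, 10 * pi / 180, 1, 35, 0.25, 0.5)
  same <- apply_perturbation(p, group_perturbation())
  expect_equal(unclass(same), unclass(p))
  weak <- apply_perturbation(p, group_perturbation(mif_pct = 40))
  expect_equal(weak$f_max, 400)
  compl <- apply_perturbation(p, group_perturbation(tc_pct = 40))
  expect_equal(compl$k_tendon, 14)
  # recalibration: perturbed curve still zero at zero strain, slope 14 at 4%
  expect_identical(tendon_force_norm(0, compl$k_tendon), 0)
  slope <- (tendon_force_norm(0.0401, 14) -
              tendon_force_norm(0.0399, 14)) / 2e-4
  expect_equal(slope, 14, tolerance = 1e-4)
  # OFL perturbation does not rescale the stored absolute v_max
  short <- apply_perturbation(p, group_perturbation(ofl_pct = 60))
  expect_equal(short$v_max, p$v_max)
  expect_equal(short$l_tendon_slack, p$l_tendon_slack)
  # multiplicative composition: 80% then 50% equals 40% once (within bounds
  # checks disabled for the intermediate step)
  p80 <- apply_perturbation(p, group_perturbation(mif_pct = 80))
  p40a <- apply_perturbation(p80, group_perturbation(mif_pct = 50),
                             bounds = NULL)
  p40b <- apply_perturbation(p, group_perturbation(mif_pct = 40))
  expect_equal(p40a$f_max, p40b$f_max, tolerance = 1e-12)
  expect_error(apply_perturbation(p, group_perturbation(mif_pct = 20)),
               "outside bounds")
})
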