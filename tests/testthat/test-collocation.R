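# Radau scheme, cost terms, transcription bookkeeping, and the solver.

test_that("Radau scheme: points, quadrature and differentiation exactness", {
  s1 <- radau_scheme(1)
  expect_equal(s1$points, 1)
  expect_equal(s1$weights, 1)
  s3 <- radau_scheme(3)
  expect_equal(s3$points, c((1 + (-1 - sqrt(6)) / 5) / 2,
                            (1 + (-1 + sqrt(6)) / 5) / 2, 1),
               tolerance = 1e-12)
  expect_equal(sum(s3$weights * s3$points^2), 1 / 3, tolerance = 1e-12)
  for (d in 1:5) {
    s <- radau_scheme(d)
    expect_equal(sum(s$weights), 1, tolerance = 1e-12)
    # quadrature exact to degree 2d - 2
    for (pow in 0:max(0, 2 * d - 2)) {
      expect_equal(sum(s$weights * s$points^pow), 1 / (pow + 1),
                   tolerance = 1e-12)
    }
    # differentiation exact on tau^d
    vals <- c(0, s$points)^d
    expect_equal(as.numeric(s$diff_matrix %*% vals), d * s$points^(d - 1),
                 tolerance = 1e-10)
  }
  expect_error(radau_scheme(0), "degree")
  expect_error(radau_scheme(10), "degree")
})

test_that("cost terms match closed-form integrals", {
  # one MTU, PV = 1, a = 1 for 3 s
  qw <- rep(3 / 30, 30)
  expect_equal(effort_term(matrix(1, 30, 1), 1, qw), 3)
  expect_equal(effort_term(matrix(0, 30, 2), c(0.4, 0.6), qw), 0)
  # PV swap invariance for equal activations
  a2 <- matrix(0.5, 30, 2)
  expect_equal(effort_term(a2, c(0.3, 0.7), qw),
               effort_term(a2, c(0.7, 0.3), qw))
  # reserve: tau_scaled = 1 for 0.5 s, w = 1
  qh <- rep(0.5 / 10, 10)
  expect_equal(reserve_term(matrix(1, 10, 1), qh, 1), 0.5)
  expect_equal(reserve_term(matrix(1, 10, 1), qh, 2),
               2 * reserve_term(matrix(1, 10, 1), qh, 1))
  expect_equal(reserve_term(matrix(0, 10, 3), qh), 0)
  # control: adot = 2, ftdot = 0, 1 s, w = 1 -> 4
  q1 <- rep(1 / 20, 20)
  expect_equal(control_term(matrix(2, 20, 1), matrix(0, 20, 1), q1, 1), 4)
  expect_equal(control_term(matrix(-2, 20, 1), matrix(0, 20, 1), q1, 1), 4)
  expect_equal(control_term(matrix(0, 20, 1), matrix(0, 20, 1), q1, 1), 0)
})

test_that("transcription counts match a hand enumeration on a toy problem", {
  m <- toy_model()
  kin <- isokinetic_kinematics(30, n_samples = 5)
  ref <- oracle_post_reference(m, p_baseline(), kin,
                               activations = c(knee_extensor = 0.5,
                                               knee_flexor = 0,
                                               non_knee = 0))
  st <- ocp_settings(n_mesh_intervals = 2, poly_degree = 1)
  nlp <- transcribe(m, ref, st)
  # hand count: 1 MTU, 1 coordinate, 2 intervals, degree 1
  # states: 2 vars x 1 MTU x 2 points x 2 intervals = 8
  # controls: 2 x 1 x 1 x 2 = 4; reserves: 1 x 1 x 2 = 2
  expect_equal(nlp$counts$n_var, 14)
  expect_equal(nlp$counts$dynamics_eq, 4)
  expect_equal(nlp$counts$continuity_eq, 2)
  expect_equal(nlp$counts$moment_balance_eq, 2)
  expect_equal(nlp$counts$hill_eq, 2)
  expect_equal(nlp$counts$rate_ineq, 4)
  expect_equal(nlp$counts$n_constraints, 14)
  con <- nlp$constraints(rep(0, nlp$n_var))
  expect_length(con$value, 14)
  # default settings transcribe to 50 mesh intervals
  nlp50 <- transcribe(m, ref, ocp_settings())
  expect_equal(nlp50$counts$n_mesh_intervals, 50)
  # unscaling a scaled reserve of +-1 gives +-25 N m
  x <- rep(0, nlp$n_var)
  x[nlp$idx(1, "res")] <- 1
  expect_equal(nlp$unscale(x)$res[, , 1][1], 25)
  x[nlp$idx(1, "res")] <- -1
  expect_equal(nlp$unscale(x)$res[, , 1][1], -25)
  expect_true(all(nlp$lower == -1) && all(nlp$upper == 1))
})

test_that("analytic gradient of the reduced objective matches FD", {
  m <- small_model()
  ref <- small_pre_ref()
  st <- ocp_settings(n_mesh_intervals = 2, poly_degree = 2)
  rn <- hillmc:::.reduced_nlp(m, ref, st)
  set.seed(42)
  nz <- length(rn$lower)
  z <- runif(nz, 0.05, 0.8)
  z[(rn$N * rn$nm + 1):nz] <- runif(rn$nm, 0.05, 0.9)
  u <- rn$unpack(z)
  g0 <- rn$ineq(rn$fwd(u$Fg, u$a0))
  lam <- lapply(g0, function(x) matrix(runif(length(x), 0, 2),
                                       nrow(x), ncol(x)))
  og <- rn$make_obj(lam, rho = 50)
  gr_a <- og$gr(z)
  eps <- 1e-6
  gr_fd <- vapply(seq_len(nz), function(i) {
    zp <- z; zm <- z
    zp[i] <- zp[i] + eps; zm[i] <- zm[i] - eps
    (og$fn(zp) - og$fn(zm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(gr_a - gr_fd) / pmax(1, abs(gr_fd))), 1e-4)
})

test_that("self-consistent tracking converges with tiny reserves", {
  m <- small_model()
  ref <- small_pre_ref()
  sol <- solve_tracking_ocp(m, ref, fast_settings())
  expect_identical(sol$status, "converged")
  # self-generated reference is attainable: small peak reserve. (The < 1%
  # acceptance bound applies to the 40-MTU default model, where per-muscle
  # volume fractions -- and hence the effort price of a marginal N m -- are
  # an order of magnitude smaller; see test-acceptance.R.)
  expect_lt(max(abs(sol$reserve_knee)), 0.07 * max(abs(ref$moment_Nm)))
  expect_true(all(sol$activation >= -1e-3 & sol$activation <= 1 + 1e-3))
  # objective recomposes exactly from the trajectories (Eq. J = sum of terms)
  s <- sol$settings
  J <- effort_term(sol$activation,
                   vapply(m$mtus, function(x) x$params$volume_fraction,
                          numeric(1)), sol$quadrature) +
    reserve_term(sol$reserves / s$reserve_bound, sol$quadrature,
                 s$w_reserve) +
    control_term(sol$activation_rate * s$t_act,
                 sol$tendon_force_rate / s$rate_bound_tf, sol$quadrature,
                 s$w_control)
  expect_equal(J, sol$objective, tolerance = 1e-10)
})

test_that("solution satisfies the full NLP equalities and moment balance", {
  m <- small_model()
  ref <- small_pre_ref()
  st <- fast_settings()
  sol <- solve_tracking_ocp(m, ref, st)
  nlp <- transcribe(m, ref, st)
  x <- solution_to_nlp_x(nlp, sol)
  expect_equal(nlp$objective(x), sol$objective, tolerance = 1e-10)
  con <- nlp$constraints(x)
  eq <- con$value[con$upper == 0 & is.finite(con$lower)]
  expect_lt(max(abs(eq)), 1e-8)
  # moment balance within 10x solver tolerance, unscaled N m
  expect_lt(sol$moment_residual, 10 * st$constraint_tol)
  # inequality violations within the solver tolerance
  ineqv <- con$value[!is.finite(con$lower)]
  expect_lt(max(ineqv), st$constraint_tol)
})

test_that("mesh refinement leaves the converged objective nearly unchanged", {
  m <- small_model()
  ref <- small_pre_ref()
  s4 <- solve_tracking_ocp(m, ref, ocp_settings(n_mesh_intervals = 4,
                                                max_iter = 4000))
  s8 <- solve_tracking_ocp(m, ref, ocp_settings(n_mesh_intervals = 8,
                                                max_iter = 4000))
  expect_identical(s4$status, "converged")
  expect_identical(s8$status, "converged")
  expect_lt(abs(s8$objective - s4$objective) / s4$objective, 0.01)
})

test_that("solver is deterministic for identical inputs", {
  m <- small_model()
  ref <- small_pre_ref()
  s1 <- solve_tracking_ocp(m, ref, fast_settings())
  s2 <- solve_tracking_ocp(m, ref, fast_settings())
  expect_identical(s1$objective, s2$objective)
  expect_identical(s1$reserve_knee, s2$reserve_knee)
})

test_that("an unattainable reference saturates the knee reserve and fails", {
  m <- small_model()
  ref <- small_pre_ref()
  big <- ref
  big$moment_Nm <- rep(10 * max(ref$moment_Nm), nrow(ref))
  sol <- solve_tracking_ocp(m, big, fast_settings())
  expect_identical(sol$status, "failed")
  expect_gte(max(abs(sol$reserve_knee)), sol$settings$reserve_bound)
  expect_false(classify_feasibility(sol, big)$feasible)
})

test_that("feasibility rule is pointwise at 9% with converged status", {
  mref <- c(100, 80, 60)
  expect_true(classify_feasibility(stub_solution(c(0, 0, 0), mref),
                                   NULL)$feasible)
  # 9.5% of the reference at a single sample: infeasible
  cls <- classify_feasibility(stub_solution(c(0, 0.095 * 80, 0)[c(1, 2, 3)],
                                            mref), NULL)
  expect_false(cls$feasible)
  expect_equal(cls$max_reserve_pct, 9.5, tolerance = 1e-10)
  # exactly at the threshold: feasible
  expect_true(classify_feasibility(stub_solution(c(9, 7.2, 5.4), mref),
                                   NULL)$feasible)
  # failed solves are never feasible, reserves notwithstanding
  expect_false(classify_feasibility(stub_solution(c(0, 0, 0), mref,
                                                  status = "failed"),
                                    NULL)$feasible)
  # floor guards the percentage near zero reference
  cls2 <- classify_feasibility(stub_solution(c(0.5), c(0.01)), NULL,
                               floor_Nm = 1)
  expect_equal(cls2$max_reserve_pct, 50)
})
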