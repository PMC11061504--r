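# Shared fixtures, built lazily and cached for the whole test run.
.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# small model: fast solves for solver-level properties
small_model <- function() {
  fixture("small_model", function() {
    build_default_model(n_extensors = 2, n_flexors = 2, n_non_knee = 3,
                        seed = 3)
  })
}

default_model <- function() {
  fixture("default_model", function() build_default_model(seed = 1))
}

p_baseline <- function() {
  stats::setNames(rep(100, 15), perturbation_names())
}

# ground-truth perturbation used for all recovery checks: a plausibly
# deconditioned individual (weakened extensors, mildly shortened fibers,
# more compliant tendons)
p_star <- function() {
  stats::setNames(c(55, 90, 85, 110, 70,
                    75, 85, 90, 100, 70,
                    75, 85, 90, 100, 70), perturbation_names())
}

small_pre_ref <- function() {
  fixture("small_pre_ref", function() {
    oracle_post_reference(small_model(), p_baseline(),
                          isokinetic_kinematics(30, n_samples = 21),
                          condition = "pre")
  })
}

# solver settings for fast module-level tests
fast_settings <- function(...) {
  ocp_settings(n_mesh_intervals = 4, max_iter = 1500, ...)
}

# campaign-scale settings (documented desk-scale reduction of the production
# 50-interval mesh; the mesh-refinement test shows objective insensitivity)
campaign_settings <- function(...) {
  ocp_settings(n_mesh_intervals = 5, max_iter = 900, ...)
}

# a synthetic collocation_solution stub for classifier edge cases
stub_solution <- function(reserve, mref, status = "converged") {
  structure(list(status = status, reserve_knee = reserve, Mref_knee = mref),
            class = "collocation_solution")
}

# hand-built single-coordinate, single-MTU toy model for hand counting
toy_model <- function() {
  params <- mtu_parameters("toy", f_max = 2000, l_opt = 0.1,
                           alpha_opt = 0, v_max = 1, k_tendon = 35,
                           l_tendon_slack = 0.25, volume_fraction = 1)
  poly <- mtu_poly(const = 0.25 + 0.07,
                   terms = list(knee_flexion = c(0.04)),
                   range = list(knee_flexion = c(0, pi / 2)))
  structure(list(coordinates = "knee_flexion",
                 moving_coordinate = "knee_flexion",
                 posture = c(),
                 mtus = list(list(name = "toy", params = params,
                                  poly = poly, group = "knee_extensor")),
                 seed = 0), class = "limb_model")
}
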