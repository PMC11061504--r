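#' Reference knee-moment profiles (synthetic-data stage)
#'
#' Reference net knee extension moments are built the way the framework's
#' source data were: a measured anchor moment at 30 deg knee flexion is
#' multiplied by a normative angle-profile expressed as fractions of the
#' 30 deg value (tabulated at 10 deg intervals) and interpolated onto the
#' isokinetic kinematics grid. The literature anchors and fraction tables
#' are not public, so [default_scenario()] generates clearly-labelled
#' synthetic stand-ins, and [oracle_post_reference()] generates references
#' that are attainable by construction from a known ground-truth
#' perturbation (enabling parameter-recovery testing).
#'
#' @name reference-gen
NULL

#' Isokinetic knee-extension kinematics
#'
#' Knee flexion angle from `start` to `end` degrees at constant angular
#' speed: the flexion coordinate decreases, so its angular velocity is
#' `-angular_velocity`.
#'
#' @param angular_velocity Angular speed (deg/s, > 0).
#' @param start,end Start/end knee flexion angles (deg).
#' @param n_samples Number of time samples.
#' @return A `coordinate_trajectory`: list with `name`, `time` (s), `angle`
#'   (rad) and `angular_velocity` (rad/s, constant).
#' @export
isokinetic_kinematics <- function(angular_velocity, start = 90, end = 0,
                                  n_samples = 61) {
  stopifnot(angular_velocity > 0, start > end, n_samples >= 2)
  duration <- (start - end) / angular_velocity
  time <- seq(0, duration, length.out = n_samples)
  angle_deg <- start - angular_velocity * time
  structure(list(name = "knee_flexion",
                 time = time,
                 angle = angle_deg * pi / 180,
                 angular_velocity = rep(-angular_velocity * pi / 180,
                                        n_samples),
                 speed_deg_s = angular_velocity,
                 duration = duration),
            class = "coordinate_trajectory")
}

#' Normative moment fractions relative to 30 deg flexion
#'
#' @param angle_deg Angles (deg), must include 30.
#' @param moment Raw normative moments at those angles (any consistent
#'   unit).
#' @return Data frame (`angle_deg`, `moment_fraction`) with the 30 deg entry
#'   exactly 1.
#' @export
fractions_from_normative <- function(angle_deg, moment) {
  stopifnot(length(angle_deg) == length(moment))
  i30 <- which(abs(angle_deg - 30) < 1e-9)
  if (length(i30) != 1 || moment[i30] == 0) {
    stop("normative table must contain a single nonzero entry at 30 deg",
         call. = FALSE)
  }
  data.frame(angle_deg = angle_deg, moment_fraction = moment / moment[i30])
}

#' Build a reference moment profile from an anchor and fraction table
#'
#' `moment(angle) = anchor * fraction(angle)`, with the fraction table
#' interpolated by a monotone (shape-preserving) cubic through the tabulated
#' knots, evaluated on the kinematics grid. The value at 30 deg equals the
#' anchor exactly.
#'
#' @param moment_at_30deg Anchor moment (N m, > 0) at 30 deg knee flexion.
#' @param fractions Fraction table from [fractions_from_normative()].
#' @param kinematics An [isokinetic_kinematics()] trajectory.
#' @param condition `"pre"` or `"post"`.
#' @return A `moment_profile` data frame with columns `time_s`, `angle_deg`,
#'   `moment_Nm` and attributes `condition`, `angular_velocity`.
#' @export
build_reference <- function(moment_at_30deg, fractions, kinematics,
                            condition = "pre") {
  stopifnot(moment_at_30deg > 0)
  o <- order(fractions$angle_deg)
  f <- stats::splinefun(fractions$angle_deg[o], fractions$moment_fraction[o],
                        method = "monoH.FC")
  angle_deg <- kinematics$angle * 180 / pi
  df <- data.frame(time_s = kinematics$time,
                   angle_deg = angle_deg,
                   moment_Nm = moment_at_30deg * f(angle_deg))
  structure(df, condition = condition,
            angular_velocity = kinematics$speed_deg_s,
            class = c("moment_profile", "data.frame"))
}

#' Synthetic pre/post reference scenario
#'
#' Deterministic-given-seed stand-in for the unavailable bed-rest anchors
#' and normative fraction table: a bell-shaped angle profile peaking near
#' 60-70 deg flexion, pre anchors of ~190-230 N m at 30 deg/s, smaller
#' anchors at 180 deg/s, and post-unloading anchors reduced by ~32-42%.
#'
#' @param seed Integer seed.
#' @param n_samples Samples per profile.
#' @return List with `fractions` (table), `anchors` (named list) and
#'   `profiles` (named list `pre_30`, `post_30`, `pre_180`, `post_180`).
#' @export
default_scenario <- function(seed = 1, n_samples = 61) {
  .with_seed(seed, {
    peak <- runif(1, 60, 70)
    width <- runif(1, 50, 65)
    ang <- seq(90, 0, by = -10)
    raw <- exp(-((ang - peak) / width)^2)
    fractions <- fractions_from_normative(ang, raw)
    pre30 <- runif(1, 190, 230)
    ratio180 <- runif(1, 0.68, 0.78)
    red30 <- runif(1, 0.58, 0.68)   # post/pre multiplier (32-42% reduction)
    red180 <- runif(1, 0.60, 0.70)
    anchors <- list(pre_30 = pre30, post_30 = pre30 * red30,
                    pre_180 = pre30 * ratio180,
                    post_180 = pre30 * ratio180 * red180)
    k30 <- isokinetic_kinematics(30, n_samples = n_samples)
    k180 <- isokinetic_kinematics(180, n_samples = n_samples)
    profiles <- list(
      pre_30 = build_reference(anchors$pre_30, fractions, k30, "pre"),
      post_30 = build_reference(anchors$post_30, fractions, k30, "post"),
      pre_180 = build_reference(anchors$pre_180, fractions, k180, "pre"),
      post_180 = build_reference(anchors$post_180, fractions, k180, "post"))
    list(fractions = fractions, anchors = anchors, profiles = profiles,
         seed = seed)
  })
}

# quasi-static tendon force for one MTU at fixed activation: scalar
# root-find of the Hill residual with zero tendon-force-rate
.quasistatic_force <- function(params, l_mtu, v_mtu, activation,
                               ft_max = 3.5, label = "") {
  res <- function(ft) {
    hill_equilibrium_residual(
      state = list(activation = activation, tendon_force_norm = ft),
      controls = list(activation_rate = 0, tendon_force_rate = 0),
      mtu_length = l_mtu, mtu_velocity = v_mtu, params = params)
  }
  r0 <- res(0)
  if (r0 >= 0) return(0)
  if (res(ft_max) < 0) {
    stop("equilibrium root not bracketed for MTU '", params$name, "' ",
         label, call. = FALSE)
  }
  stats::uniroot(res, c(0, ft_max), tol = 1e-12)$root
}

#' Oracle reference profile from a known ground-truth perturbation
#'
#' Applies a known perturbation to the model, fixes the group activations,
#' solves the quasi-static Hill equilibrium (zero tendon-force-rate, scalar
#' root-find per MTU per sample) along the prescribed kinematics, and
#' returns the resulting net knee extension moment. By construction the
#' profile is attainable by the perturbed model, so the true perturbation
#' lies inside the feasible set -- the basis of all parameter-recovery
#' checks.
#'
#' @param model A `limb_model`.
#' @param true_perturbation Named 15-vector of percentages
#'   (`KE_MIF` ... `NK_TC`, see [perturbation_names()]); 100 = baseline.
#' @param kinematics An [isokinetic_kinematics()] trajectory.
#' @param activations Named group activations in `[0, 1]`.
#' @param condition Condition label for the profile.
#' @return A `moment_profile` (see [build_reference()]).
#' @export
oracle_post_reference <- function(model, true_perturbation,
                                  kinematics,
                                  activations = c(knee_extensor = 0.9,
                                                  knee_flexor = 0.05,
                                                  non_knee = 0.1),
                                  condition = "post") {
  if (any(activations < 0 | activations > 1)) {
    stop("activations must be in [0, 1]", call. = FALSE)
  }
  pmap <- expand_to_mtus(true_perturbation, model)
  nt <- length(kinematics$time)
  moment <- numeric(nt)
  for (j in seq_along(model$mtus)) {
    m <- model$mtus[[j]]
    pp <- apply_perturbation(m$params, pmap[[j]])
    act <- activations[[m$group]]
    ang <- list(knee_flexion = kinematics$angle,
                hip_flexion = rep(model$posture[["hip_flexion"]], nt),
                ankle_flexion = rep(model$posture[["ankle_flexion"]], nt))
    lmtu <- mtu_length(m$poly, ang)
    vmtu <- mtu_velocity(m$poly, ang,
                         list(knee_flexion = kinematics$angular_velocity))
    arm <- moment_arm(m$poly, ang, "knee_flexion")
    if (all(arm == 0)) next  # non-knee MTUs do not load the knee
    ft <- vapply(seq_len(nt), function(i) {
      .quasistatic_force(pp, lmtu[i], vmtu[i], act,
                         label = sprintf("at t=%.3f s", kinematics$time[i]))
    }, numeric(1))
    moment <- moment + arm * pp$f_max * ft
  }
  df <- data.frame(time_s = kinematics$time,
                   angle_deg = kinematics$angle * 180 / pi,
                   moment_Nm = moment)
  structure(df, condition = condition,
            angular_velocity = kinematics$speed_deg_s,
            class = c("moment_profile", "data.frame"))
}

#' Write / read a moment profile as CSV with a JSON sidecar
#'
#' The CSV has header `time_s,angle_deg,moment_Nm`; condition and angular
#' velocity metadata go to `<path>.json`.
#'
#' @param profile A `moment_profile`.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[c("time_s", "angle_deg",
                                            "moment_Nm")],
                   path, row.names = FALSE)
  meta <- list(condition = attr(profile, "condition"),
               angular_velocity = attr(profile, "angular_velocity"))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::fromJSON(sidecar)
  } else {
    list(condition = NA_character_, angular_velocity = NA_real_)
  }
  structure(df, condition = meta$condition,
            angular_velocity = meta$angular_velocity,
            class = c("moment_profile", "data.frame"))
}
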