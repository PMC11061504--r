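#' Polynomial MTU kinematics and the synthetic right-leg model
#'
#' MTU lengths are additive polynomials of the joint angles (degree <= 4 per
#' coordinate). Moment arms and MTU velocities follow by differentiation.
#'
#' Sign convention (knee): the knee coordinate is the flexion angle
#' `theta in [0, pi/2]`; the isokinetic extension motion runs 90 deg -> 0 deg
#' so `theta_dot < 0`. The knee moment arm is reported in the
#' extension-positive sense, `r = d l / d theta_flex`: an extensor has
#' `r > 0`, shortens during the extension motion, and contributes a positive
#' (extension) moment `r * F` under tension. Equivalently this is
#' `-dl/dangle` with the angle measured in the extension-positive sense.
#'
#' @name limb-model
NULL

.poly_check_angles <- function(poly, angles) {
  for (nm in names(poly$terms)) {
    rng <- poly$range[[nm]]
    if (!is.null(rng) && !is.null(angles[[nm]])) {
      q <- angles[[nm]]
      if (any(q < rng[1] - 1e-9 | q > rng[2] + 1e-9)) {
        warning("angle for coordinate '", nm,
                "' outside polynomial validity range; extrapolating",
                call. = FALSE)
      }
    }
  }
}

#' Create an MTU kinematics polynomial
#'
#' @param const Constant term (m).
#' @param terms Named list, one entry per coordinate, each a numeric vector
#'   of coefficients for powers 1..degree (degree <= 4) of that coordinate's
#'   angle (rad).
#' @param range Named list of validity ranges (length-2 numeric) per
#'   coordinate.
#' @return Object of class `mtu_poly`.
#' @export
mtu_poly <- function(const, terms = list(), range = list()) {
  stopifnot(is.numeric(const), length(const) == 1)
  for (cf in terms) {
    stopifnot(is.numeric(cf), length(cf) >= 1, length(cf) <= 4)
  }
  structure(list(const = const, terms = terms, range = range),
            class = "mtu_poly")
}

#' Evaluate MTU length
#'
#' @param poly An [mtu_poly()] object.
#' @param angles Named list/vector of joint angles (rad).
#' @return MTU length (m).
#' @export
mtu_length <- function(poly, angles) {
  angles <- as.list(angles)
  .poly_check_angles(poly, angles)
  out <- poly$const
  for (nm in names(poly$terms)) {
    q <- angles[[nm]]
    if (is.null(q)) stop("missing angle for coordinate '", nm, "'",
                         call. = FALSE)
    cf <- poly$terms[[nm]]
    out <- out + drop(outer(q, seq_along(cf), "^") %*% cf)
  }
  out
}

#' Moment arm about a coordinate
#'
#' `r = d l / d q` with the knee sign convention described in
#' [limb-model]: positive knee arm = extensor = positive extension moment.
#'
#' @inheritParams mtu_length
#' @param coordinate Coordinate name.
#' @return Moment arm (m); 0 for an MTU that does not span the coordinate.
#' @export
moment_arm <- function(poly, angles, coordinate) {
  angles <- as.list(angles)
  cf <- poly$terms[[coordinate]]
  if (is.null(cf)) {
    return(rep(0, length(angles[[coordinate]] %||% 1)))
  }
  .poly_check_angles(poly, angles[coordinate])
  q <- angles[[coordinate]]
  dcf <- cf * seq_along(cf)
  drop(outer(q, seq_along(cf) - 1, "^") %*% dcf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' MTU lengthening velocity
#'
#' Chain rule over all spanned coordinates:
#' `v = sum_coord (dl/dq) * q_dot`.
#'
#' @inheritParams mtu_length
#' @param angular_velocities Named list/vector of joint angular velocities
#'   (rad/s).
#' @return MTU velocity (m/s), positive = lengthening.
#' @export
mtu_velocity <- function(poly, angles, angular_velocities) {
  angular_velocities <- as.list(angular_velocities)
  out <- 0
  for (nm in names(poly$terms)) {
    qd <- angular_velocities[[nm]] %||% 0
    out <- out + moment_arm(poly, angles, nm) * qd
  }
  out
}

#' Maximum isometric force from muscle volume
#'
#' `F_max = specific_tension * (volume / l_opt)` (physiological
#' cross-sectional area times specific tension).
#'
#' @param volume Muscle volume (cm^3).
#' @param l_opt Optimal fiber length (cm).
#' @param specific_tension Specific tension (N/cm^2, default 60 as in the
#'   source simulation framework).
#' @return Maximum isometric force (N).
#' @export
scale_max_isometric_force <- function(volume, l_opt, specific_tension = 60) {
  if (any(volume <= 0) || any(l_opt <= 0) || any(specific_tension <= 0)) {
    stop("volume, l_opt and specific_tension must be > 0", call. = FALSE)
  }
  specific_tension * volume / l_opt
}

#' Classify MTUs into knee extensors, knee flexors and non-knee muscles
#'
#' Mean knee moment arm over the 90 deg -> 0 deg motion: > +1 mm is a knee
#' extensor, < -1 mm a knee flexor, otherwise non-knee. Grouping depends
#' only on geometry, never on strength.
#'
#' @param model A model from [build_default_model()] (or same structure).
#' @param n_grid Angle grid resolution for the mean.
#' @return Named character vector, one of `knee_extensor`, `knee_flexor`,
#'   `non_knee` per MTU.
#' @export
classify_muscle_groups <- function(model, n_grid = 19) {
  th <- seq(0, pi / 2, length.out = n_grid)
  vapply(model$mtus, function(m) {
    arm <- mean(moment_arm(m$poly, list(knee_flexion = th), "knee_flexion"))
    if (arm > 1e-3) "knee_extensor"
    else if (arm < -1e-3) "knee_flexor"
    else "non_knee"
  }, character(1))
}

#' Net joint moment from tendon forces
#'
#' `M = sum_j r_j(q) * F_j` about the named coordinate (extension-positive
#' at the knee).
#'
#' @param model Limb model.
#' @param tendon_forces Numeric vector of tendon forces (N, >= 0), one per
#'   MTU in model order.
#' @param angles Named list of joint angles (rad).
#' @param coordinate Coordinate name.
#' @return Net moment (N m).
#' @export
net_joint_moment <- function(model, tendon_forces, angles,
                             coordinate = "knee_flexion") {
  if (length(tendon_forces) != length(model$mtus)) {
    stop("need one tendon force per MTU", call. = FALSE)
  }
  arms <- vapply(model$mtus,
                 function(m) moment_arm(m$poly, angles, coordinate)[1],
                 numeric(1))
  sum(arms * tendon_forces)
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# horizontal (along-tendon) extent of a fiber of normalized length lnorm
.fiber_horiz <- function(lnorm, l_opt, alpha_opt) {
  l_opt * sqrt(lnorm^2 - sin(alpha_opt)^2)
}

#' Build the default synthetic right-leg model
#'
#' A deterministic-given-seed synthetic stand-in for a scaled
#' musculoskeletal model: 40 Hill-type MTUs by default, grouped into knee
#' extensors, knee flexors and non-knee (hip/ankle) muscles. Coordinates are
#' hip flexion (fixed at 60 deg), knee flexion (the moving coordinate, range
#' 0..90 deg) and ankle flexion (fixed neutral). Knee extensors operate on
#' the ascending limb/plateau of the force-length curve over the seated
#' 90 deg -> 0 deg motion and knee flexors on the plateau/descending limb;
#' their moment arms are drawn from documented plausible ranges (extensors
#' ~2-5 cm, flexors ~2-4 cm). This is a labelled synthetic construction, not
#' fitted polynomials from any real model.
#'
#' @param n_extensors,n_flexors,n_non_knee Group sizes (default 4 + 8 + 28 =
#'   40 MTUs).
#' @param seed Integer seed; the same seed yields an identical model.
#' @param specific_tension N/cm^2 used to scale maximum isometric forces.
#' @return A `limb_model` list with `coordinates`, `posture` (fixed angles),
#'   and `mtus` (each with `params`, `poly`, `group`).
#' @export
build_default_model <- function(n_extensors = 4, n_flexors = 8,
                                n_non_knee = 28, seed = 1,
                                specific_tension = 60) {
  stopifnot(n_extensors >= 1, n_flexors >= 1, n_non_knee >= 1)
  .with_seed(seed, {
    theta_max <- pi / 2
    posture <- c(hip_flexion = pi / 3, ankle_flexion = 0)
    krange <- list(knee_flexion = c(0, theta_max))
    mtus <- list()
    add <- function(name, l_opt, alpha_opt, l_ts, volume, poly) {
      mtus[[length(mtus) + 1]] <<- list(
        name = name, l_opt = l_opt, alpha_opt = alpha_opt, l_ts = l_ts,
        volume = volume, poly = poly)
    }
    for (i in seq_len(n_extensors)) {
      l_opt <- runif(1, 0.10, 0.13)
      alpha <- runif(1, 0, 18) * pi / 180
      l_ts <- runif(1, 0.22, 0.32)
      l0 <- runif(1, 0.65, 0.78)     # slack-tendon normalized length at 0 deg
      l90 <- runif(1, 1.02, 1.15)    # ... at 90 deg flexion
      delta <- .fiber_horiz(l90, l_opt, alpha) - .fiber_horiz(l0, l_opt, alpha)
      s <- runif(1, -0.2, 0.2)
      r0 <- delta / (theta_max + s * theta_max^2 / 2)
      poly <- mtu_poly(const = l_ts + .fiber_horiz(l0, l_opt, alpha),
                       terms = list(knee_flexion = c(r0, s * r0 / 2)),
                       range = krange)
      add(sprintf("ke%02d", i), l_opt, alpha, l_ts, runif(1, 380, 520), poly)
    }
    for (i in seq_len(n_flexors)) {
      l_opt <- runif(1, 0.08, 0.11)
      alpha <- runif(1, 0, 15) * pi / 180
      l_ts <- runif(1, 0.18, 0.30)
      l0 <- runif(1, 1.08, 1.20)
      l90 <- runif(1, 0.68, 0.80)
      delta <- .fiber_horiz(l0, l_opt, alpha) - .fiber_horiz(l90, l_opt, alpha)
      s <- runif(1, -0.2, 0.2)
      r0 <- delta / (theta_max + s * theta_max^2 / 2)
      poly <- mtu_poly(const = l_ts + .fiber_horiz(l0, l_opt, alpha),
                       terms = list(knee_flexion = c(-r0, -s * r0 / 2)),
                       range = krange)
      add(sprintf("kf%02d", i), l_opt, alpha, l_ts, runif(1, 150, 260), poly)
    }
    for (i in seq_len(n_non_knee)) {
      coord <- if (i %% 2 == 1) "hip_flexion" else "ankle_flexion"
      q0 <- posture[[coord]]
      l_opt <- runif(1, 0.06, 0.13)
      alpha <- runif(1, 0, 20) * pi / 180
      l_ts <- runif(1, 0.10, 0.35)
      ltgt <- runif(1, 0.95, 1.10)
      # alternate agonist/antagonist arms with a mild systematic imbalance so
      # uniform passive force increases do not fully cancel in the balance
      sgn <- if (i %% 4 %in% c(0, 1)) 1 else -1
      am <- sgn * runif(1, 0.025, 0.05) * (1 + 0.15 * sgn)
      c2 <- runif(1, -0.02, 0.02)
      c1 <- am - 2 * c2 * q0
      const <- l_ts + .fiber_horiz(ltgt, l_opt, alpha) - (c1 * q0 + c2 * q0^2)
      poly <- mtu_poly(const = const,
                       terms = stats::setNames(list(c(c1, c2)), coord),
                       range = stats::setNames(list(q0 + c(-0.4, 0.4)), coord))
      add(sprintf("nk%02d", i), l_opt, alpha, l_ts, runif(1, 80, 220), poly)
    }
    vols <- vapply(mtus, `[[`, numeric(1), "volume")
    vfrac <- vols / sum(vols)
    model_mtus <- lapply(seq_along(mtus), function(j) {
      m <- mtus[[j]]
      params <- mtu_parameters(
        name = m$name,
        f_max = scale_max_isometric_force(m$volume, m$l_opt * 100,
                                          specific_tension),
        l_opt = m$l_opt, alpha_opt = m$alpha_opt, v_max = 10 * m$l_opt,
        k_tendon = 35, l_tendon_slack = m$l_ts, volume_fraction = vfrac[j])
      list(name = m$name, params = params, poly = m$poly, group = NA)
    })
    model <- structure(list(
      coordinates = c("hip_flexion", "knee_flexion", "ankle_flexion"),
      moving_coordinate = "knee_flexion",
      posture = posture,
      mtus = model_mtus,
      seed = seed), class = "limb_model")
    groups <- classify_muscle_groups(model)
    for (j in seq_along(model$mtus)) model$mtus[[j]]$group <- groups[j]
    model
  })
}

#' @export
print.limb_model <- function(x, ...) {
  g <- vapply(x$mtus, `[[`, character(1), "group")
  cat(sprintf(
    "Synthetic right-leg model: %d MTUs (%d knee extensors, %d knee flexors, %d non-knee), seed %d\n",
    length(x$mtus), sum(g == "knee_extensor"), sum(g == "knee_flexor"),
    sum(g == "non_knee"), x$seed))
  invisible(x)
}

#' Serialize a limb model to JSON
#'
#' @param model A `limb_model`.
#' @param path File path; `NULL` returns the JSON string.
#' @return `path` (invisibly) or the JSON string.
#' @export
write_model_json <- function(model, path = NULL) {
  obj <- list(
    coordinates = model$coordinates,
    moving_coordinate = model$moving_coordinate,
    posture = as.list(model$posture),
    seed = model$seed,
    mtus = lapply(model$mtus, function(m) {
      list(name = m$name, group = m$group,
           params = unclass(m$params)[-1],
           poly = list(const = m$poly$const, terms = m$poly$terms,
                       range = m$poly$range))
    }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a limb model from JSON
#'
#' @param path File path (or a JSON string).
#' @return A `limb_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mtus <- lapply(obj$mtus, function(m) {
    p <- m$params
    list(name = m$name,
         params = mtu_parameters(m$name, p$f_max, p$l_opt, p$alpha_opt,
                                 p$v_max, p$k_tendon, p$l_tendon_slack,
                                 p$volume_fraction),
         poly = mtu_poly(m$poly$const,
                         lapply(m$poly$terms, unlist),
                         lapply(m$poly$range, unlist)),
         group = m$group)
  })
  structure(list(coordinates = unlist(obj$coordinates),
                 moving_coordinate = obj$moving_coordinate,
                 posture = unlist(obj$posture),
                 mtus = mtus, seed = obj$seed), class = "limb_model")
}

#' Export knee moment arms versus angle as CSV
#'
#' @param model A `limb_model`.
#' @param path Output CSV path.
#' @param n_grid Number of knee angles (90 deg -> 0 deg).
#' @return `path` invisibly.
#' @export
export_moment_arms <- function(model, path, n_grid = 19) {
  th <- seq(pi / 2, 0, length.out = n_grid)
  df <- data.frame(angle_deg = th * 180 / pi)
  for (m in model$mtus) {
    df[[m$name]] <- moment_arm(m$poly, list(knee_flexion = th),
                               "knee_flexion")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
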