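#' Characteristic curves of the Hill-type muscle-tendon unit
#'
#' Normalized force-length, force-velocity, passive and tendon curves in the
#' tendon-force-state formulation of De Groote et al. (2016). The source
#' simulation framework fixes a single calibration constraint -- the tendon
#' force-strain curve has gradient `k_tendon` (baseline 35) at 4% strain --
#' which the tendon curve here satisfies exactly by construction. All curve
#' coefficients are package constants surfaced through
#' [hill_curve_constants()], not claims about any particular source model.
#'
#' @name hill-curves
NULL

# Active force-length: sum of three Gaussians (De Groote et al. 2016, eq. S2).
.FL_B <- matrix(c(
  0.815, 1.055,  0.162, 0.0633,
  0.433, 0.717, -0.030, 0.200,
  0.100, 1.000,  0.354, 0.000
), nrow = 3, byrow = TRUE)  # columns: magnitude, center, width, width slope

# Passive force-length shape and strain limit.
.PAS_KPE <- 4
.PAS_E0 <- 0.6

# Force-velocity (arsinh form), De Groote et al. (2016, eq. S6).
.FV_D <- c(d1 = -0.318, d2 = -8.149, d3 = -0.374, d4 = 0.886)

#' Curve constants used by the package
#'
#' @return Named list with the active force-length Gaussian coefficients
#'   (`fl_gaussians`), passive shape (`kpe`) and strain limit (`e0`), and the
#'   force-velocity coefficients (`fv`).
#' @export
hill_curve_constants <- function() {
  list(fl_gaussians = .FL_B, kpe = .PAS_KPE, e0 = .PAS_E0, fv = .FV_D)
}

.check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("non-finite ", what, call. = FALSE)
  }
  invisible(x)
}

#' Normalized tendon force-strain curve
#'
#' `f_t(strain) = c * (exp(k_tendon * strain) - 1)` with
#' `c = exp(-0.04 * k_tendon)`, so the force is zero at zero strain and the
#' slope at 4% strain equals `k_tendon` exactly (baseline 35). Strictly
#' increasing in strain.
#'
#' @param strain Tendon strain (dimensionless, `> -1`).
#' @param k_tendon Dimensionless stiffness shape parameter (`> 0`).
#' @return Normalized tendon force (force / maximum isometric force).
#' @export
tendon_force_norm <- function(strain, k_tendon) {
  .check_finite(strain, "strain")
  .check_finite(k_tendon, "k_tendon")
  if (any(k_tendon <= 0)) stop("k_tendon must be > 0", call. = FALSE)
  if (any(strain <= -1)) stop("strain must be > -1", call. = FALSE)
  exp(-0.04 * k_tendon) * (exp(k_tendon * strain) - 1)
}

#' Invert the calibrated tendon curve
#'
#' @param force_norm Normalized tendon force (`>= 0`).
#' @param k_tendon Stiffness shape parameter.
#' @return Strain such that [tendon_force_norm()] reproduces `force_norm`.
#' @export
tendon_strain_from_force <- function(force_norm, k_tendon) {
  .check_finite(force_norm, "force_norm")
  if (any(force_norm < 0)) stop("force_norm must be >= 0", call. = FALSE)
  log(force_norm / exp(-0.04 * k_tendon) + 1) / k_tendon
}

# d f_t / d strain
tendon_force_slope <- function(strain, k_tendon) {
  exp(-0.04 * k_tendon) * k_tendon * exp(k_tendon * strain)
}

#' Active force-length curve
#'
#' Sum of three Gaussians; maximum of ~1 at the optimal fiber length, decaying
#' towards zero outside roughly \[0.4, 1.8\] optimal lengths.
#'
#' @param fib_len_norm Fiber length / optimal fiber length (`> 0`).
#' @return Dimensionless active scaling factor.
#' @export
active_force_length <- function(fib_len_norm) {
  .check_finite(fib_len_norm, "fib_len_norm")
  if (any(fib_len_norm <= 0)) stop("fib_len_norm must be > 0", call. = FALSE)
  b <- .FL_B
  out <- 0
  for (i in seq_len(nrow(b))) {
    den <- b[i, 3] + b[i, 4] * fib_len_norm
    out <- out + b[i, 1] * exp(-0.5 * (fib_len_norm - b[i, 2])^2 / den^2)
  }
  out
}

# d f_act / d l_norm
active_force_length_d <- function(l) {
  b <- .FL_B
  out <- 0
  for (i in seq_len(nrow(b))) {
    den <- b[i, 3] + b[i, 4] * l
    u <- (l - b[i, 2]) / den
    g <- b[i, 1] * exp(-0.5 * u^2)
    # du/dl = (den - (l - center) * width_slope)/den^2
    dudl <- (den - (l - b[i, 2]) * b[i, 4]) / den^2
    out <- out - g * u * dudl
  }
  out
}

#' Passive force-length curve
#'
#' Exponential parallel-elastic curve, zero (slightly negative) at and below
#' the optimal length and normalized to 1 at the strain limit
#' (fiber length 1.6 optimal lengths).
#'
#' @inheritParams active_force_length
#' @return Normalized passive force.
#' @export
passive_force_length <- function(fib_len_norm) {
  .check_finite(fib_len_norm, "fib_len_norm")
  if (any(fib_len_norm <= 0)) stop("fib_len_norm must be > 0", call. = FALSE)
  (exp(.PAS_KPE * (fib_len_norm - 1) / .PAS_E0) - 1) / (exp(.PAS_KPE) - 1)
}

passive_force_length_d <- function(l) {
  (.PAS_KPE / .PAS_E0) * exp(.PAS_KPE * (l - 1) / .PAS_E0) / (exp(.PAS_KPE) - 1)
}

#' Force-velocity curve
#'
#' Logarithmic (arsinh) form; 1 at zero velocity, approaching 0 at maximal
#' shortening (`fib_vel_norm = -1`), monotone non-decreasing with a bounded
#' eccentric plateau on the physiological domain.
#'
#' @param fib_vel_norm Fiber velocity / maximum shortening velocity, signed
#'   (shortening negative).
#' @return Dimensionless velocity scaling factor.
#' @export
force_velocity <- function(fib_vel_norm) {
  .check_finite(fib_vel_norm, "fib_vel_norm")
  d <- .FV_D
  d[["d1"]] * asinh(d[["d2"]] * fib_vel_norm + d[["d3"]]) + d[["d4"]]
}

force_velocity_d <- function(v) {
  d <- .FV_D
  u <- d[["d2"]] * v + d[["d3"]]
  d[["d1"]] * d[["d2"]] / sqrt(u^2 + 1)
}
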