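#' Muscle-tendon unit parameters
#'
#' Container for one MTU's Hill-model parameters: the five perturbable
#' parameters (maximum isometric force, optimal fiber length, pennation angle
#' at optimal fiber length, maximum shortening velocity, tendon stiffness
#' shape) plus tendon slack length and the MTU's fraction of total muscle
#' volume.
#'
#' @param name MTU name.
#' @param f_max Maximum isometric force (N, > 0).
#' @param l_opt Optimal fiber length (m, > 0).
#' @param alpha_opt Pennation angle at optimal fiber length (rad, in
#'   `[0, pi/2)`).
#' @param v_max Maximum shortening velocity (m/s, > 0; baseline convention is
#'   ten optimal fiber lengths per second).
#' @param k_tendon Dimensionless tendon stiffness shape (> 0; baseline 35,
#'   giving the tendon curve slope 35 at 4% strain).
#' @param l_tendon_slack Tendon slack length (m, > 0).
#' @param volume_fraction MTU volume / total muscle volume (in `[0, 1]`).
#' @return An object of class `mtu_parameters`.
#' @export
mtu_parameters <- function(name, f_max, l_opt, alpha_opt, v_max,
                           k_tendon, l_tendon_slack, volume_fraction) {
  stopifnot(is.character(name), length(name) == 1)
  num <- c(f_max = f_max, l_opt = l_opt, alpha_opt = alpha_opt,
           v_max = v_max, k_tendon = k_tendon,
           l_tendon_slack = l_tendon_slack,
           volume_fraction = volume_fraction)
  .check_finite(num, paste0("parameter for MTU '", name, "'"))
  if (f_max <= 0 || l_opt <= 0 || v_max <= 0 || k_tendon <= 0 ||
      l_tendon_slack <= 0) {
    stop("f_max, l_opt, v_max, k_tendon, l_tendon_slack must be > 0 (MTU '",
         name, "')", call. = FALSE)
  }
  if (alpha_opt < 0 || alpha_opt >= pi / 2) {
    stop("alpha_opt must be in [0, pi/2) (MTU '", name, "')", call. = FALSE)
  }
  if (volume_fraction < 0 || volume_fraction > 1) {
    stop("volume_fraction must be in [0, 1] (MTU '", name, "')",
         call. = FALSE)
  }
  structure(list(name = name, f_max = f_max, l_opt = l_opt,
                 alpha_opt = alpha_opt, v_max = v_max, k_tendon = k_tendon,
                 l_tendon_slack = l_tendon_slack,
                 volume_fraction = volume_fraction),
            class = "mtu_parameters")
}

#' @export
print.mtu_parameters <- function(x, ...) {
  cat(sprintf(
    "MTU '%s': f_max %.1f N, l_opt %.3f m, alpha_opt %.1f deg, v_max %.3f m/s,\n          k_tendon %.1f, l_tendon_slack %.3f m, volume fraction %.4f\n",
    x$name, x$f_max, x$l_opt, x$alpha_opt * 180 / pi, x$v_max, x$k_tendon,
    x$l_tendon_slack, x$volume_fraction))
  invisible(x)
}

#' Pennation angle from normalized fiber length
#'
#' Constant-thickness pennation geometry:
#' `alpha = asin(sin(alpha_opt) / fib_len_norm)`, clamped so that
#' `cos(alpha) >= 0.1` (standard singularity guard; never active for
#' pennation angles within the physiological <= 20 degree range).
#'
#' @param fib_len_norm Normalized fiber length (> `sin(alpha_opt)`).
#' @param alpha_opt Pennation angle at optimal fiber length (rad).
#' @param name MTU name used in error messages.
#' @return Pennation angle (rad).
#' @export
pennation_angle <- function(fib_len_norm, alpha_opt, name = "MTU") {
  s <- sin(alpha_opt)
  if (any(fib_len_norm <= s)) {
    stop("pennation geometry unsolvable (fiber too short) for ", name,
         call. = FALSE)
  }
  a <- asin(s / fib_len_norm)
  amax <- acos(0.1)
  pmin(a, amax)
}

#' Fiber state implied by a normalized tendon force
#'
#' Inverts the calibrated tendon curve to recover tendon strain and length,
#' then solves the constant-thickness pennation geometry for the fiber.
#'
#' @param tendon_force_norm Normalized tendon force (>= 0).
#' @param mtu_length MTU origin-to-insertion length (m).
#' @param params An [mtu_parameters()] object.
#' @return List with `fib_len_norm`, `pennation` (rad), `tendon_length` (m),
#'   `fiber_length` (m).
#' @export
fiber_state_from_tendon_force <- function(tendon_force_norm, mtu_length,
                                          params) {
  if (any(tendon_force_norm < 0)) {
    stop("tendon_force_norm must be >= 0", call. = FALSE)
  }
  strain <- tendon_strain_from_force(tendon_force_norm, params$k_tendon)
  l_t <- params$l_tendon_slack * (1 + strain)
  h <- mtu_length - l_t          # fiber length projected along the tendon
  if (any(h <= 0)) {
    stop("negative implied fiber length for MTU '", params$name, "'",
         call. = FALSE)
  }
  w <- params$l_opt * sin(params$alpha_opt)   # constant muscle thickness
  l_m <- sqrt(h^2 + w^2)
  list(fib_len_norm = l_m / params$l_opt,
       pennation = atan2(w, h),
       tendon_length = l_t,
       fiber_length = l_m)
}

#' Hill-equilibrium residual
#'
#' `residual = F_t - (a * f_act(l) * f_v(v) + f_pas(l)) * cos(alpha)`, with
#' the fiber kinematics derived from the tendon force and its rate through
#' the inverted tendon curve and constant-thickness pennation. The residual
#' is zero exactly when the contractile + passive fiber force projected along
#' the tendon balances the tendon force.
#'
#' @param state List with `activation` and `tendon_force_norm`.
#' @param controls List with `activation_rate` and `tendon_force_rate`
#'   (only the tendon force rate enters the residual).
#' @param mtu_length,mtu_velocity MTU length (m) and lengthening velocity
#'   (m/s).
#' @param params An [mtu_parameters()] object.
#' @return Dimensionless residual.
#' @export
hill_equilibrium_residual <- function(state, controls, mtu_length,
                                      mtu_velocity, params) {
  fs <- fiber_state_from_tendon_force(state$tendon_force_norm, mtu_length,
                                      params)
  cosa <- cos(fs$pennation)
  # tendon lengthening rate from the force rate (chain rule through the
  # calibrated curve): eps_dot = Ft_dot / (k * (Ft + c))
  ct <- exp(-0.04 * params$k_tendon)
  eps_dot <- controls$tendon_force_rate /
    (params$k_tendon * (state$tendon_force_norm + ct))
  v_t <- params$l_tendon_slack * eps_dot
  v_m <- (mtu_velocity - v_t) * cosa
  v_norm <- v_m / params$v_max
  fl <- active_force_length(fs$fib_len_norm)
  fp <- passive_force_length(fs$fib_len_norm)
  fv <- force_velocity(v_norm)
  state$tendon_force_norm - (state$activation * fl * fv + fp) * cosa
}

#' Admissible activation-rate interval
#'
#' First-order excitation-activation dynamics expressed as inequality bounds
#' on the activation rate: activation time constant `t_a = 0.015` s,
#' deactivation time constant `t_d = 0.06` s.
#'
#' @param activation Activation in `[0, 1]`.
#' @param t_act,t_deact Activation and deactivation time constants (s).
#' @return List with `min_rate` and `max_rate` (1/s).
#' @export
activation_rate_bounds <- function(activation, t_act = 0.015,
                                   t_deact = 0.06) {
  if (any(activation < 0 | activation > 1)) {
    stop("activation must be in [0, 1]", call. = FALSE)
  }
  list(min_rate = -activation / t_deact,
       max_rate = (1 - activation) / t_act)
}

#' Group perturbation of MTU parameters
#'
#' Percentages of baseline (100 = unperturbed) for the five perturbable
#' parameters: maximum isometric force (MIF), optimal fiber length (OFL),
#' pennation angle at OFL (OPA), maximum shortening velocity (MSV), and
#' tendon compliance (TC).
#'
#' @param mif_pct,ofl_pct,opa_pct,msv_pct,tc_pct Percentages of baseline.
#' @return Object of class `group_perturbation`.
#' @export
group_perturbation <- function(mif_pct = 100, ofl_pct = 100, opa_pct = 100,
                               msv_pct = 100, tc_pct = 100) {
  p <- c(mif_pct = mif_pct, ofl_pct = ofl_pct, opa_pct = opa_pct,
         msv_pct = msv_pct, tc_pct = tc_pct)
  .check_finite(p, "perturbation percentage")
  structure(as.list(p), class = "group_perturbation")
}

#' Apply a group perturbation to MTU parameters
#'
#' Multiplies each of the five perturbable parameters by its percentage/100.
#' Tendon slack length is never perturbed (no evidence of adaptation to
#' unloading). The maximum shortening velocity is stored in absolute units
#' and scaled independently of the fiber-length perturbation. Perturbing the
#' tendon stiffness shape automatically re-calibrates the curve offset (the
#' offset is a function of `k_tendon`), so zero strain still gives zero
#' force.
#'
#' @param params An [mtu_parameters()] object.
#' @param p A [group_perturbation()] object.
#' @param bounds Optional [perturbation_bounds()] within which the
#'   percentages must lie; `NULL` skips the check.
#' @return Perturbed [mtu_parameters()] object.
#' @export
apply_perturbation <- function(params, p, bounds = perturbation_bounds()) {
  stopifnot(inherits(params, "mtu_parameters"),
            inherits(p, "group_perturbation"))
  if (!is.null(bounds)) {
    pct <- c(MIF = p$mif_pct, OFL = p$ofl_pct, OPA = p$opa_pct,
             MSV = p$msv_pct, TC = p$tc_pct)
    for (nm in names(pct)) {
      b <- bounds[[nm]]
      if (pct[[nm]] < b[1] || pct[[nm]] > b[2]) {
        stop(sprintf("%s perturbation %.1f%% outside bounds [%g, %g]",
                     nm, pct[[nm]], b[1], b[2]), call. = FALSE)
      }
    }
  }
  mtu_parameters(name = params$name,
                 f_max = params$f_max * p$mif_pct / 100,
                 l_opt = params$l_opt * p$ofl_pct / 100,
                 alpha_opt = params$alpha_opt * p$opa_pct / 100,
                 v_max = params$v_max * p$msv_pct / 100,
                 k_tendon = params$k_tendon * p$tc_pct / 100,
                 l_tendon_slack = params$l_tendon_slack,
                 volume_fraction = params$volume_fraction)
}
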