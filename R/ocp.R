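#' Tracking optimal control problem settings
#'
#' Defaults follow the source framework where printed (50 equally spaced
#' mesh intervals, third-order interval polynomials / four points per
#' interval, knee reserve bounded at +-25 N m and scaled to +-1, activation
#' time constants 0.015 / 0.06 s, 9% pointwise feasibility threshold) and
#' documented package choices elsewhere (cost weights, solver tolerances,
#' rate scalings).
#'
#' @param n_mesh_intervals Equally spaced mesh intervals (>= 1).
#' @param poly_degree Collocation points per interval (interval polynomials
#'   of this degree through `poly_degree + 1` points).
#' @param reserve_bound Reserve actuator bound (N m); scaled reserves live in
#'   `[-1, 1]`.
#' @param w_reserve,w_control Cost weights on the scaled reserve and control
#'   terms.
#' @param tol Solver convergence tolerance (relative objective change).
#' @param constraint_tol Maximum admitted constraint violation for a
#'   solution to count as converged.
#' @param max_iter Inner-iteration cap across the solve.
#' @param ft_max Upper bound on normalized tendon force states.
#' @param rate_bound_tf Scale/bound for the tendon-force-rate controls
#'   (1/s).
#' @param t_act,t_deact Activation/deactivation time constants (s).
#' @param init_activation,init_tendon_force Initial-guess state values used
#'   by the flat initializer.
#' @param init_method Initial-guess strategy for [solve_tracking_ocp()]:
#'   `"quasistatic"` (default; vectorized quasi-static warm start with a
#'   coarse extensor-activation line search) or `"flat"` (mid-range
#'   constants).
#' @param feasibility_threshold_pct Pointwise knee-reserve threshold (% of
#'   the reference moment).
#' @param reserve_floor_Nm Floor on `|M_ref|` when forming reserve
#'   percentages near full extension.
#' @return List of class `ocp_settings`.
#' @export
ocp_settings <- function(n_mesh_intervals = 50, poly_degree = 3,
                         reserve_bound = 25, w_reserve = 10,
                         w_control = 0.01, tol = 1e-4,
                         constraint_tol = 1e-3, max_iter = 3000,
                         ft_max = 3.5, rate_bound_tf = 50,
                         t_act = 0.015, t_deact = 0.06,
                         init_activation = 0.1, init_tendon_force = 0.2,
                         init_method = c("quasistatic", "flat"),
                         feasibility_threshold_pct = 9,
                         reserve_floor_Nm = 1) {
  stopifnot(n_mesh_intervals >= 1, poly_degree >= 1, reserve_bound > 0)
  init_method <- match.arg(init_method)
  structure(as.list(environment()), class = "ocp_settings")
}

# Assemble the discretized problem data shared by transcribe() and the
# solver: collocation grid, reference moments, MTU kinematics and parameter
# matrices at the collocation points.
.ocp_problem <- function(model, reference, settings) {
  sch <- radau_scheme(settings$poly_degree)
  d <- settings$poly_degree
  K <- settings$n_mesh_intervals
  M <- K * d                     # collocation points
  N <- M + 1                     # state grid (interval starts shared)
  duration <- max(reference$time_s)
  h <- duration / K
  tcol <- as.vector(vapply(seq_len(K),
                           function(k) (k - 1) * h + h * sch$points,
                           numeric(d)))
  # knee kinematics reconstructed from the (isokinetic) reference grid
  speed <- attr(reference, "angular_velocity")
  ang_fun <- stats::approxfun(reference$time_s, reference$angle_deg,
                              rule = 2)
  theta <- ang_fun(tcol) * pi / 180
  theta_dot <- rep(-speed * pi / 180, M)
  mom_fun <- stats::splinefun(reference$time_s, reference$moment_Nm,
                              method = "monoH.FC")
  coords <- model$coordinates
  nc <- length(coords)
  Mref <- matrix(0, M, nc, dimnames = list(NULL, coords))
  Mref[, model$moving_coordinate] <- mom_fun(tcol)
  nm <- length(model$mtus)
  angles <- list()
  for (cn in coords) {
    angles[[cn]] <- if (cn == model$moving_coordinate) theta
                    else rep(model$posture[[cn]], M)
  }
  qdots <- stats::setNames(as.list(rep(0, nc)), coords)
  qdots[[model$moving_coordinate]] <- theta_dot
  Lmtu <- Vmtu <- matrix(0, M, nm)
  ARM <- lapply(coords, function(cn) matrix(0, M, nm))
  names(ARM) <- coords
  par_vec <- function(f) vapply(model$mtus, function(m) f(m$params),
                                numeric(1))
  for (j in seq_len(nm)) {
    poly <- model$mtus[[j]]$poly
    Lmtu[, j] <- mtu_length(poly, angles)
    Vmtu[, j] <- mtu_velocity(poly, angles, qdots)
    for (cn in coords) ARM[[cn]][, j] <- moment_arm(poly, angles, cn)
  }
  # full-grid quantities (interval starts): first grid point at t = 0
  Bd <- matrix(0, M, N)
  for (k in seq_len(K)) {
    rows <- (k - 1) * d + seq_len(d)
    cols <- (k - 1) * d + seq_len(d + 1)
    Bd[rows, cols] <- sch$diff_matrix
  }
  qw <- rep(h * sch$weights, K)
  list(model = model, settings = settings, scheme = sch,
       d = d, K = K, M = M, N = N, h = h, duration = duration,
       tcol = tcol, coords = coords, nc = nc, nm = nm,
       Mref = Mref, Lmtu = Lmtu, Vmtu = Vmtu, ARM = ARM,
       Bd = Bd, qw = qw,
       fmax = par_vec(function(p) p$f_max),
       lopt = par_vec(function(p) p$l_opt),
       w_thick = par_vec(function(p) p$l_opt * sin(p$alpha_opt)),
       vmax = par_vec(function(p) p$v_max),
       kt = par_vec(function(p) p$k_tendon),
       ct = par_vec(function(p) exp(-0.04 * p$k_tendon)),
       lts = par_vec(function(p) p$l_tendon_slack),
       pv = par_vec(function(p) p$volume_fraction))
}

#' Volume-weighted squared-activation effort term
#'
#' `sum_j PV_j * integral(a_j^2 dt)` evaluated with the collocation
#' quadrature.
#'
#' @param activations Matrix (time x MTU) of activations at the collocation
#'   points.
#' @param volume_fractions Per-MTU volume fractions `PV_j`.
#' @param quadrature Time quadrature weights (length = rows of
#'   `activations`).
#' @return Dimensionless effort term.
#' @export
effort_term <- function(activations, volume_fractions, quadrature) {
  activations <- as.matrix(activations)
  stopifnot(nrow(activations) == length(quadrature),
            ncol(activations) == length(volume_fractions))
  sum(quadrature * (activations^2 %*% volume_fractions))
}

#' Squared-reserve cost term
#'
#' `w_reserve * sum_i integral(tau_scaled_i^2 dt)` over the actuated
#' coordinates, reserves in scaled (+-1) units.
#'
#' @param reserves Matrix (time x coordinate) of scaled reserves.
#' @param quadrature Time quadrature weights.
#' @param w_reserve Weight.
#' @return Dimensionless reserve term.
#' @export
reserve_term <- function(reserves, quadrature, w_reserve = 1) {
  reserves <- as.matrix(reserves)
  stopifnot(nrow(reserves) == length(quadrature))
  w_reserve * sum(quadrature * rowSums(reserves^2))
}

#' Squared-control cost term
#'
#' `w_control * (sum_j integral(tf_rate_j^2 dt) + sum_j
#' integral(act_rate_j^2 dt))` for whatever rate trajectories are supplied
#' (the solver applies it to the scaled rates).
#'
#' @param activation_rates,tendon_force_rates Matrices (time x MTU).
#' @param quadrature Time quadrature weights.
#' @param w_control Weight.
#' @return Dimensionless control term.
#' @export
control_term <- function(activation_rates, tendon_force_rates, quadrature,
                         w_control = 1) {
  activation_rates <- as.matrix(activation_rates)
  tendon_force_rates <- as.matrix(tendon_force_rates)
  stopifnot(nrow(activation_rates) == length(quadrature))
  w_control * (sum(quadrature * rowSums(tendon_force_rates^2)) +
                 sum(quadrature * rowSums(activation_rates^2)))
}

#' Classify a solved draw as feasible or infeasible
#'
#' Feasible iff the solve converged AND at every collocation time the knee
#' reserve magnitude is at most `threshold_pct`% of the reference moment
#' magnitude (a floor guards the percentage where the reference approaches
#' zero near full extension).
#'
#' @param solution A `collocation_solution` from [solve_tracking_ocp()].
#' @param reference The tracked post-unloading `moment_profile`.
#' @param threshold_pct Pointwise threshold (default 9).
#' @param floor_Nm Reference-magnitude floor (N m).
#' @return List with `feasible` and `max_reserve_pct`.
#' @export
classify_feasibility <- function(solution, reference, threshold_pct = 9,
                                 floor_Nm = 1) {
  mref <- solution$Mref_knee
  tau <- solution$reserve_knee
  pct <- 100 * abs(tau) / pmax(abs(mref), floor_Nm)
  list(feasible = identical(solution$status, "converged") &&
         all(pct <= threshold_pct),
       max_reserve_pct = max(pct))
}

#' Transcribe the tracking OCP into a nonlinear program
#'
#' Direct Legendre-Gauss-Radau transcription. The decision vector holds, per
#' mesh interval, the interval-start and collocation-point states (`a`,
#' normalized tendon force) per MTU, the controls (state rates) at the
#' collocation points, and the reserve controls per actuated coordinate; all
#' affinely scaled to `[-1, 1]`. Constraints: (i) collocation dynamics
#' equalities, (ii) inter-interval continuity equalities, (iii) moment
#' balance (knee tracks the reference, other coordinates balance zero) with
#' bounded reserves, (iv) Hill-equilibrium equalities per MTU, (v)
#' activation-rate inequalities.
#'
#' @param model A `limb_model`.
#' @param reference A `moment_profile` to track.
#' @param settings [ocp_settings()].
#' @return An `ocp_nlp` list: `n_var`, `lower`, `upper`, `objective(x)`,
#'   `constraints(x)`, constraint bounds `c_lower`/`c_upper`, `counts`,
#'   index helpers and the discretized `problem` data.
#' @export
transcribe <- function(model, reference, settings = ocp_settings()) {
  prob <- .ocp_problem(model, reference, settings)
  d <- prob$d; K <- prob$K; nm <- prob$nm; nc <- prob$nc; M <- prob$M
  s <- settings
  # layout per interval: [a states (d+1) x nm] [ft states (d+1) x nm]
  #                      [adot d x nm] [ftdot d x nm] [reserves d x nc]
  per_int <- 2 * nm * (d + 1) + 2 * nm * d + nc * d
  n_var <- K * per_int
  idx <- function(k, block) {
    base <- (k - 1) * per_int
    sizes <- c(a = nm * (d + 1), ft = nm * (d + 1), adot = nm * d,
               ftdot = nm * d, res = nc * d)
    off <- cumsum(c(0, sizes))[match(block, names(sizes))]
    base + off + seq_len(sizes[[block]])
  }
  rate_a <- 1 / s$t_act
  unscale <- function(x) {
    a <- array(0, c(d + 1, nm, K)); ft <- a
    adot <- array(0, c(d, nm, K)); ftdot <- adot
    res <- array(0, c(d, nc, K))
    for (k in seq_len(K)) {
      a[, , k] <- matrix((x[idx(k, "a")] + 1) / 2, d + 1, nm)
      ft[, , k] <- matrix((x[idx(k, "ft")] + 1) / 2 * s$ft_max, d + 1, nm)
      adot[, , k] <- matrix(x[idx(k, "adot")] * rate_a, d, nm)
      ftdot[, , k] <- matrix(x[idx(k, "ftdot")] * s$rate_bound_tf, d, nm)
      res[, , k] <- matrix(x[idx(k, "res")] * s$reserve_bound, d, nc)
    }
    list(a = a, ft = ft, adot = adot, ftdot = ftdot, res = res)
  }
  # collocation-point matrices (M x .) from the per-interval arrays
  colloc_mat <- function(arr3, nvals) {
    out <- matrix(0, M, nvals)
    for (k in seq_len(K)) {
      out[(k - 1) * d + seq_len(d), ] <- arr3[seq_len(d) + 1, , k,
                                              drop = FALSE][, , 1]
    }
    out
  }
  ctrl_mat <- function(arr3, nvals) {
    out <- matrix(0, M, nvals)
    for (k in seq_len(K)) out[(k - 1) * d + seq_len(d), ] <- arr3[, , k]
    out
  }
  lower <- rep(-1, n_var); upper <- rep(1, n_var)
  # normalized tendon force is non-negative: scaled lower bound -1 is 0 N
  objective <- function(x) {
    tr <- unscale(x)
    a_c <- colloc_mat(tr$a, nm)
    adot_c <- ctrl_mat(tr$adot, nm)
    ftdot_c <- ctrl_mat(tr$ftdot, nm)
    res_c <- ctrl_mat(tr$res, nc)
    effort_term(a_c, prob$pv, prob$qw) +
      reserve_term(res_c / s$reserve_bound, prob$qw, s$w_reserve) +
      control_term(adot_c * s$t_act, ftdot_c / s$rate_bound_tf, prob$qw,
                   s$w_control)
  }
  constraints <- function(x) {
    tr <- unscale(x)
    g_dyn <- g_cont <- g_mom <- g_hill <- g_rate <- numeric(0)
    h <- prob$h
    Dm <- prob$scheme$diff_matrix
    for (k in seq_len(K)) {
      sa <- tr$a[, , k, drop = FALSE][, , 1, drop = FALSE]
      sa <- matrix(sa, d + 1, nm)
      sf <- matrix(tr$ft[, , k], d + 1, nm)
      da <- Dm %*% sa / h
      df <- Dm %*% sf / h
      g_dyn <- c(g_dyn, as.numeric(da - matrix(tr$adot[, , k], d, nm)),
                 as.numeric(df - matrix(tr$ftdot[, , k], d, nm)))
      if (k < K) {
        g_cont <- c(g_cont,
                    as.numeric(tr$a[d + 1, , k] - tr$a[1, , k + 1]),
                    as.numeric(tr$ft[d + 1, , k] - tr$ft[1, , k + 1]))
      }
      rows <- (k - 1) * d + seq_len(d)
      fc <- matrix(tr$ft[seq_len(d) + 1, , k], d, nm)
      for (ci in seq_len(nc)) {
        cn <- prob$coords[ci]
        mom <- rowSums(prob$ARM[[cn]][rows, , drop = FALSE] *
                         sweep(fc, 2, prob$fmax, "*")) +
          matrix(tr$res[, , k], d, nc)[, ci]
        g_mom <- c(g_mom, mom - prob$Mref[rows, ci])
      }
      ac <- matrix(tr$a[seq_len(d) + 1, , k], d, nm)
      adk <- matrix(tr$adot[, , k], d, nm)
      fdk <- matrix(tr$ftdot[, , k], d, nm)
      for (j in seq_len(nm)) {
        p <- model$mtus[[j]]$params
        for (c in seq_len(d)) {
          pnt <- (k - 1) * d + c
          g_hill <- c(g_hill, hill_equilibrium_residual(
            state = list(activation = ac[c, j],
                         tendon_force_norm = fc[c, j]),
            controls = list(activation_rate = adk[c, j],
                            tendon_force_rate = fdk[c, j]),
            mtu_length = prob$Lmtu[pnt, j],
            mtu_velocity = prob$Vmtu[pnt, j], params = p))
        }
      }
      g_rate <- c(g_rate, as.numeric(adk - (1 - ac) / s$t_act),
                  as.numeric(-ac / s$t_deact - adk))
    }
    list(value = c(g_dyn, g_cont, g_mom, g_hill, g_rate),
         lower = c(rep(0, length(g_dyn) + length(g_cont) + length(g_mom) +
                         length(g_hill)),
                   rep(-Inf, length(g_rate))),
         upper = c(rep(0, length(g_dyn) + length(g_cont) + length(g_mom) +
                         length(g_hill)),
                   rep(0, length(g_rate))))
  }
  counts <- list(
    n_var = n_var,
    n_mesh_intervals = K,
    n_collocation_points = M,
    dynamics_eq = 2 * nm * M,
    continuity_eq = 2 * nm * (K - 1),
    moment_balance_eq = nc * M,
    hill_eq = nm * M,
    rate_ineq = 2 * nm * M)
  counts$n_constraints <- counts$dynamics_eq + counts$continuity_eq +
    counts$moment_balance_eq + counts$hill_eq + counts$rate_ineq
  structure(list(n_var = n_var, lower = lower, upper = upper,
                 objective = objective, constraints = constraints,
                 counts = counts, idx = idx, unscale = unscale,
                 problem = prob, model = model, reference = reference,
                 settings = settings),
            class = "ocp_nlp")
}

#' @export
print.ocp_nlp <- function(x, ...) {
  cat(sprintf(
    "Radau collocation NLP: %d variables, %d constraints (%d mesh intervals, degree %d, %d MTUs, %d coordinates)\n",
    x$counts$n_var, x$counts$n_constraints, x$counts$n_mesh_intervals,
    x$settings$poly_degree, x$problem$nm, x$problem$nc))
  invisible(x)
}
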