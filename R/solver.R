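#' Solve the tracking OCP
#'
#' Package-native reduced-space solver for the Radau collocation NLP (no
#' external interior-point solver is assumed). The normalized tendon forces
#' at the state grid plus the initial activations are the free variables;
#' the controls are eliminated through the collocation differentiation
#' matrix, the activations through the Hill-equilibrium identity, and the
#' reserves through the (hard) moment-balance equality. The remaining
#' inequality constraints -- activation bounds, activation-rate bounds and
#' reserve bounds -- are enforced by an augmented-Lagrangian outer loop
#' around `stats::optim(method = "L-BFGS-B")` with an analytic gradient.
#' Equality path constraints are therefore satisfied by construction
#' (verifiable post hoc through the full [transcribe()] constraint vector).
#'
#' Solver failures are data, not exceptions: infeasible draws are expected,
#' so a non-converged solve returns `status = "failed"` with full
#' diagnostics.
#'
#' @param model A `limb_model` (possibly perturbed).
#' @param reference `moment_profile` to track.
#' @param settings [ocp_settings()].
#' @param seed Recorded for reproducibility (the solve itself is
#'   deterministic given inputs and initial guess).
#' @param init Optional initial guess list with `ft` (grid x MTU matrix) and
#'   `a0` (per-MTU initial activations); default per
#'   `settings$init_method` (quasi-static warm start, or the flat mid-range
#'   guess).
#' @return A `collocation_solution` list: `status`, `objective`, `terms`
#'   (J_effort, J_reserves, J_controls), state/control trajectories on the
#'   collocation grid, `reserves` (N m, time x coordinate), `reserve_knee`,
#'   `Mref_knee`, `moment_residual` (max moment-balance residual, N m),
#'   `max_violation`, iteration counts, `seed` and the initial guess.
#' @export
solve_tracking_ocp <- function(model, reference, settings = ocp_settings(),
                               seed = NA_integer_, init = NULL) {
  rn <- .reduced_nlp(model, reference, settings)
  s <- settings
  if (is.null(init)) {
    init <- if (identical(s$init_method, "flat")) {
      list(ft = matrix(s$init_tendon_force, rn$N, rn$nm),
           a0 = rep(s$init_activation, rn$nm))
    } else {
      rn$quasistatic_init()
    }
  }
  z <- rn$pack(init$ft, init$a0)
  lam <- NULL
  rho <- 10
  viol_of <- function(g) max(vapply(g, function(x) max(0, max(x)),
                                    numeric(1)))
  prev_viol <- Inf
  total_iter <- 0L
  outer_max <- 12L
  inner_maxit <- max(50L, ceiling(s$max_iter / 8))
  converged <- FALSE
  last <- NULL
  for (outer in seq_len(outer_max)) {
    og <- rn$make_obj(lam, rho)
    opt <- stats::optim(z, og$fn, og$gr, method = "L-BFGS-B",
                        lower = rn$lower, upper = rn$upper,
                        control = list(maxit = inner_maxit, factr = 1e6,
                                       pgtol = 1e-9))
    z <- opt$par
    total_iter <- total_iter + opt$counts[[1]]
    last <- og$eval(z)
    viol <- viol_of(last$g)
    if (viol <= s$constraint_tol) { converged <- TRUE; break }
    lam <- og$update_multipliers(z)
    if (viol > 0.25 * prev_viol) rho <- min(rho * 10, 1e9)
    prev_viol <- viol
    if (total_iter >= s$max_iter) break
  }
  u <- rn$unpack(z)
  fw <- last$fw
  tobj <- last$terms
  prob <- rn$prob
  # honest moment-balance residual (zero by construction up to arithmetic)
  mom_res <- max(abs(vapply(seq_len(rn$nc), function(ci) {
    max(abs(rowSums(rn$ARMF[[ci]] * fw$Fc) + fw$tau[, ci] -
              prob$Mref[, ci]))
  }, numeric(1))))
  structure(list(
    status = if (converged) "converged" else "failed",
    objective = sum(tobj), terms = tobj,
    time = prob$tcol, quadrature = prob$qw,
    activation = fw$a, activation0 = u$a0,
    tendon_force_norm = u$Fg, tendon_force_colloc = fw$Fc,
    activation_rate = fw$adot, tendon_force_rate = fw$Fdot,
    reserves = fw$tau, reserve_knee = fw$tau[, rn$kneei],
    Mref_knee = prob$Mref[, rn$kneei],
    fiber_length_norm = fw$lnorm, fiber_velocity_norm = fw$vn,
    moment_residual = mom_res,
    max_violation = viol_of(last$g),
    iterations = total_iter, outer_iterations = outer,
    seed = seed, init = init, settings = settings),
    class = "collocation_solution")
}

# Reduced-space machinery: forward model, inequality sets, objective +
# analytic gradient factory, quasi-static initializer. Internal; tests use
# it to verify the gradient against finite differences.
.reduced_nlp <- function(model, reference, settings) {
  prob <- .ocp_problem(model, reference, settings)
  s <- settings
  M <- prob$M; N <- prob$N; nm <- prob$nm; nc <- prob$nc
  kneei <- match(model$moving_coordinate, prob$coords)
  rowm <- function(v) matrix(v, M, nm, byrow = TRUE)
  KT <- rowm(prob$kt); CT <- rowm(prob$ct); LTS <- rowm(prob$lts)
  W <- rowm(prob$w_thick); LOPT <- rowm(prob$lopt); VMX <- rowm(prob$vmax)
  FMX <- rowm(prob$fmax)
  ARMF <- lapply(prob$ARM, function(A) A * FMX)
  PVrow <- rowm(prob$pv)
  qw <- prob$qw
  Bd <- prob$Bd; h <- prob$h; BdT <- t(Bd)
  rb <- s$reserve_bound; ta <- s$t_act; td <- s$t_deact
  fwd <- function(Fg, a0) {
    Fc <- Fg[-1, , drop = FALSE]
    Fdot <- (Bd %*% Fg) / h
    eps <- log(Fc / CT + 1) / KT
    hh <- prob$Lmtu - LTS * (1 + eps)
    clamped <- hh < 1e-4
    hh[clamped] <- 1e-4
    lm <- sqrt(hh^2 + W^2)
    lnorm <- lm / LOPT
    cosa <- hh / lm
    epsdot <- Fdot / (KT * (Fc + CT))
    vt <- LTS * epsdot
    vn <- (prob$Vmtu - vt) * cosa / VMX
    fl <- active_force_length(lnorm)
    fp <- passive_force_length(lnorm)
    fv <- force_velocity(vn)
    den <- fl * fv
    num <- Fc / cosa - fp
    a <- num / den
    ag <- rbind(a0, a)
    adot <- (Bd %*% ag) / h
    tau <- matrix(0, M, nc)
    for (ci in seq_len(nc)) {
      tau[, ci] <- prob$Mref[, ci] - rowSums(ARMF[[ci]] * Fc)
    }
    list(Fc = Fc, Fdot = Fdot, hh = hh, clamped = clamped, lm = lm,
         lnorm = lnorm, cosa = cosa, epsdot = epsdot, vt = vt, vn = vn,
         fl = fl, fp = fp, fv = fv, den = den, num = num, a = a,
         adot = adot, tau = tau, taus = tau / rb)
  }
  ineq <- function(fw) {
    list(a_lo = -fw$a, a_hi = fw$a - 1,
         r_hi = fw$adot - (1 - fw$a) / ta,
         r_lo = -fw$a / td - fw$adot,
         t_hi = fw$taus - 1, t_lo = -fw$taus - 1)
  }
  true_obj <- function(fw) {
    c(J_effort = effort_term(fw$a, prob$pv, qw),
      J_reserves = reserve_term(fw$taus, qw, s$w_reserve),
      J_controls = control_term(fw$adot * ta, fw$Fdot / s$rate_bound_tf,
                                qw, s$w_control))
  }
  pack <- function(Fg, a0) c(as.numeric(Fg), a0)
  unpack <- function(z) list(Fg = matrix(z[seq_len(N * nm)], N, nm),
                             a0 = z[N * nm + seq_len(nm)])
  make_obj <- function(lam, rho) {
    eval_full <- function(z) {
      u <- unpack(z)
      fw <- fwd(u$Fg, u$a0)
      g <- ineq(fw)
      lamf <- lapply(names(g), function(nmk) {
        l <- lam[[nmk]]
        if (is.null(l)) 0 * g[[nmk]] else l
      })
      names(lamf) <- names(g)
      mm <- lapply(names(g),
                   function(nmk) pmax(lamf[[nmk]] + rho * g[[nmk]], 0))
      names(mm) <- names(g)
      al <- 0
      for (nmk in names(g)) {
        al <- al + (sum(mm[[nmk]]^2) - sum(lamf[[nmk]]^2)) / (2 * rho)
      }
      tobj <- true_obj(fw)
      J <- sum(tobj) + al
      # reverse pass
      ga <- 2 * qw * fw$a * PVrow - mm$a_lo + mm$a_hi +
        mm$r_hi / ta - mm$r_lo / td
      gadot <- 2 * s$w_control * qw * fw$adot * ta^2 + mm$r_hi - mm$r_lo
      gag <- (BdT %*% gadot) / h
      ga0 <- gag[1, ]
      ga <- ga + gag[-1, , drop = FALSE]
      depsdF <- 1 / (KT * (fw$Fc + CT))
      dhhdF <- -LTS * depsdF
      dhhdF[fw$clamped] <- 0
      dlmdF <- (fw$hh / fw$lm) * dhhdF
      dlndF <- dlmdF / LOPT
      dcosdF <- dhhdF * W^2 / fw$lm^3
      depsdotdF <- -fw$epsdot / (fw$Fc + CT)
      dvndF <- (-LTS * depsdotdF * fw$cosa +
                  (prob$Vmtu - fw$vt) * dcosdF) / VMX
      dvndFd <- -LTS * fw$cosa * depsdF / VMX
      fld <- active_force_length_d(fw$lnorm)
      fpd <- passive_force_length_d(fw$lnorm)
      fvd <- force_velocity_d(fw$vn)
      dnumdF <- 1 / fw$cosa - fw$Fc * dcosdF / fw$cosa^2 - fpd * dlndF
      ddendF <- fld * dlndF * fw$fv + fw$fl * fvd * dvndF
      dadF <- (dnumdF * fw$den - fw$num * ddendF) / fw$den^2
      dadFd <- -fw$num * fw$fl * fvd * dvndFd / fw$den^2
      gFdot <- 2 * s$w_control * qw * fw$Fdot / s$rate_bound_tf^2 +
        ga * dadFd
      gFc <- ga * dadF
      for (ci in seq_len(nc)) {
        gtau_s <- 2 * s$w_reserve * qw * fw$taus[, ci] +
          mm$t_hi[, ci] - mm$t_lo[, ci]
        gFc <- gFc - (ARMF[[ci]] / rb) * gtau_s
      }
      gF <- matrix(0, N, nm)
      gF[-1, ] <- gFc
      gF <- gF + (BdT %*% gFdot) / h
      list(value = J, grad = c(as.numeric(gF), ga0), fw = fw, g = g,
           terms = tobj)
    }
    cache <- new.env(parent = emptyenv())
    eval_cached <- function(z) {
      if (!is.null(cache$z) && identical(cache$z, z)) return(cache$res)
      res <- eval_full(z)
      cache$z <- z
      cache$res <- res
      res
    }
    list(fn = function(z) eval_cached(z)$value,
         gr = function(z) eval_cached(z)$grad,
         eval = eval_full,
         update_multipliers = function(z) {
           g <- eval_full(z)$g
           out <- lapply(names(g), function(nmk) {
             l <- lam[[nmk]]
             if (is.null(l)) l <- 0 * g[[nmk]]
             pmax(l + rho * g[[nmk]], 0)
           })
           names(out) <- names(g)
           out
         })
  }
  # vectorized quasi-static forces (zero tendon-force-rate) at fixed
  # activations: bisection on the Hill residual, all points at once
  qs_forces <- function(act_row) {
    ACT <- matrix(act_row, M, nm, byrow = TRUE)
    resid <- function(Fc) {
      eps <- log(Fc / CT + 1) / KT
      hh <- pmax(prob$Lmtu - LTS * (1 + eps), 1e-4)
      lm <- sqrt(hh^2 + W^2)
      lnorm <- lm / LOPT
      cosa <- hh / lm
      vn <- prob$Vmtu * cosa / VMX
      Fc - (ACT * active_force_length(lnorm) * force_velocity(vn) +
              passive_force_length(lnorm)) * cosa
    }
    lo <- matrix(0, M, nm)
    hi <- matrix(s$ft_max, M, nm)
    r0 <- resid(lo)
    for (i in 1:45) {
      mid <- (lo + hi) / 2
      rm <- resid(mid)
      take_hi <- rm < 0
      lo[take_hi] <- mid[take_hi]
      hi[!take_hi] <- mid[!take_hi]
    }
    mid <- (lo + hi) / 2
    mid[r0 >= 0] <- 0    # slack at zero force
    mid
  }
  quasistatic_init <- function() {
    groups <- vapply(model$mtus, `[[`, character(1), "group")
    base <- c(knee_extensor = 0.6, knee_flexor = 0.05, non_knee = 0.1)
    act <- unname(base[groups])
    kneeM <- function(Fc) rowSums(ARMF[[kneei]] * Fc)
    best <- NULL; best_err <- Inf; best_a <- base[["knee_extensor"]]
    for (ae in seq(0.15, 0.95, by = 0.1)) {
      act[groups == "knee_extensor"] <- ae
      Fc <- qs_forces(act)
      err <- mean(abs(kneeM(Fc) - prob$Mref[, kneei]))
      if (err < best_err) { best <- Fc; best_err <- err; best_a <- ae }
    }
    act[groups == "knee_extensor"] <- best_a
    list(ft = rbind(best[1, ], best), a0 = act)
  }
  list(prob = prob, M = M, N = N, nm = nm, nc = nc, kneei = kneei,
       ARMF = ARMF, fwd = fwd, ineq = ineq, true_obj = true_obj,
       pack = pack, unpack = unpack, make_obj = make_obj,
       quasistatic_init = quasistatic_init,
       lower = c(rep(0, N * nm), rep(0, nm)),
       upper = c(rep(s$ft_max, N * nm), rep(1, nm)))
}

#' @export
print.collocation_solution <- function(x, ...) {
  cat(sprintf(
    "Collocation solution: %s, J = %.4g (effort %.4g, reserves %.4g, controls %.4g)\n  max inequality violation %.2e, max |moment residual| %.2e N m, peak |knee reserve| %.2f N m\n",
    x$status, x$objective, x$terms[["J_effort"]], x$terms[["J_reserves"]],
    x$terms[["J_controls"]], x$max_violation, x$moment_residual,
    max(abs(x$reserve_knee))))
  invisible(x)
}

#' Pack a reduced-space solution into the full NLP decision vector
#'
#' Useful to evaluate the full [transcribe()] constraint vector on a
#' solution produced by [solve_tracking_ocp()] (equality residuals are zero
#' by construction; this provides the independent check).
#'
#' @param nlp An `ocp_nlp` from [transcribe()].
#' @param solution A `collocation_solution` (same model/reference/settings).
#' @return Scaled decision vector of length `nlp$n_var`.
#' @export
solution_to_nlp_x <- function(nlp, solution) {
  prob <- nlp$problem
  s <- nlp$settings
  d <- prob$d; K <- prob$K
  Fg <- solution$tendon_force_norm
  ag <- rbind(solution$activation0, solution$activation)
  x <- numeric(nlp$n_var)
  for (k in seq_len(K)) {
    gi <- (k - 1) * d + seq_len(d + 1)
    rows <- (k - 1) * d + seq_len(d)
    x[nlp$idx(k, "a")] <- as.numeric(2 * ag[gi, , drop = FALSE] - 1)
    x[nlp$idx(k, "ft")] <- as.numeric(2 * Fg[gi, , drop = FALSE] /
                                        s$ft_max - 1)
    x[nlp$idx(k, "adot")] <-
      as.numeric(solution$activation_rate[rows, , drop = FALSE] * s$t_act)
    x[nlp$idx(k, "ftdot")] <-
      as.numeric(solution$tendon_force_rate[rows, , drop = FALSE] /
                   s$rate_bound_tf)
    x[nlp$idx(k, "res")] <-
      as.numeric(solution$reserves[rows, , drop = FALSE] / s$reserve_bound)
  }
  x
}
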