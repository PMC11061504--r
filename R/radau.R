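#' Legendre-Gauss-Radau collocation scheme
#'
#' Flipped (right) Radau points on (0, 1] -- the roots of
#' `P_{d-1}(x) - P_d(x)` mapped from \[-1, 1\] -- with quadrature weights and
#' the differentiation matrix of the degree-`d` interpolating polynomial
#' through the interval start (tau = 0) plus the `d` collocation points.
#' The scheme includes the right endpoint (tau = 1), integrates polynomials
#' up to degree `2d - 2` exactly, and its differentiation matrix is exact for
#' polynomials up to degree `d`.
#'
#' @param degree Number of collocation points per mesh interval (1..9).
#' @return List with `points` (length `degree`, increasing, last is 1),
#'   `weights` (length `degree`), and `diff_matrix`
#'   (`degree` x `degree + 1`): row `c` gives the derivative of the
#'   interpolant at collocation point `c` as a linear combination of the
#'   values at `(0, points)`, per unit interval.
#' @export
radau_scheme <- function(degree) {
  if (!is.numeric(degree) || length(degree) != 1 || degree != round(degree) ||
      degree < 1 || degree > 9) {
    stop("degree must be an integer in 1..9", call. = FALSE)
  }
  d <- as.integer(degree)
  # Legendre coefficient vectors (monomial basis, increasing powers)
  leg <- vector("list", d + 1)
  leg[[1]] <- 1
  if (d >= 1) leg[[2]] <- c(0, 1)
  if (d >= 2) {
    for (n in 1:(d - 1)) {
      a <- c(0, leg[[n + 1]]) * (2 * n + 1)      # (2n+1) x P_n
      b <- c(leg[[n]], 0, 0) * n                 # n P_{n-1}
      leg[[n + 2]] <- (a - b[seq_along(a)]) / (n + 1)
    }
  }
  pm1 <- c(leg[[d]], 0)
  q <- pm1 - leg[[d + 1]]                        # P_{d-1} - P_d
  if (d == 1) {
    x <- 1
  } else {
    r <- polyroot(q)
    x <- sort(Re(r[abs(Im(r)) < 1e-8]))
    # polish with Newton on the real polynomial
    qd <- q[-1] * seq_len(length(q) - 1)
    pev <- function(cf, z) drop(outer(z, seq_along(cf) - 1, "^") %*% cf)
    for (i in 1:3) x <- x - pev(q, x) / pev(qd, x)
    x[length(x)] <- 1
  }
  tau <- (x + 1) / 2
  # Quadrature weights: exact integrals of the Lagrange basis on `tau`
  V <- outer(tau, seq_len(d) - 1, "^")           # d x d Vandermonde
  moments <- 1 / seq_len(d)                      # integral of t^(j-1) on [0,1]
  w <- drop(solve(t(V), moments))
  # Differentiation matrix on basis nodes (0, tau)
  nodes <- c(0, tau)
  Vb <- outer(nodes, seq_len(d + 1) - 1, "^")
  Ci <- solve(Vb)                                # column i: coeffs of L_i
  Dm <- matrix(0, d, d + 1)
  for (i in seq_len(d + 1)) {
    cf <- Ci[, i]
    dcf <- cf[-1] * seq_len(d)
    Dm[, i] <- drop(outer(tau, seq_len(d) - 1, "^") %*% dcf)
  }
  list(points = tau, weights = w, diff_matrix = Dm)
}

#' Integrate an ODE with Radau collocation
#'
#' Small fixed-mesh collocation integrator used as an independent check of
#' the collocation machinery (e.g. the closed-form first-order activation
#' response). Solves the per-interval collocation equations by Newton
#' iteration with a finite-difference Jacobian.
#'
#' @param deriv Function `(t, x) -> dx/dt` (x may be a vector).
#' @param x0 Initial state.
#' @param t_end End time (start is 0).
#' @param n_mesh Number of equal mesh intervals.
#' @param degree Collocation degree (see [radau_scheme()]).
#' @return List with `time` (mesh + collocation grid) and `state`
#'   (matrix, one row per grid time).
#' @export
radau_integrate <- function(deriv, x0, t_end, n_mesh = 20, degree = 3) {
  sch <- radau_scheme(degree)
  d <- degree
  h <- t_end / n_mesh
  ns <- length(x0)
  tgrid <- 0
  xgrid <- matrix(x0, nrow = 1)
  xk <- x0
  t0 <- 0
  for (k in seq_len(n_mesh)) {
    tc <- t0 + h * sch$points
    X <- matrix(rep(xk, each = d), nrow = d)     # d x ns unknowns
    resid <- function(Xm) {
      st <- rbind(matrix(xk, nrow = 1), Xm)
      dX <- sch$diff_matrix %*% st / h
      f <- vapply(seq_len(d),
                  function(c) as.numeric(deriv(tc[c], Xm[c, ])),
                  numeric(ns))
      f <- if (ns == 1) matrix(f, d, 1) else t(f)
      dX - f
    }
    for (it in 1:30) {
      R <- resid(X)
      if (max(abs(R)) < 1e-12) break
      n <- d * ns
      J <- matrix(0, n, n)
      eps <- 1e-7
      for (j in seq_len(n)) {
        Xp <- X
        Xp[j] <- Xp[j] + eps
        J[, j] <- as.numeric(resid(Xp) - R) / eps
      }
      X <- X - matrix(solve(J, as.numeric(R)), d, ns)
    }
    tgrid <- c(tgrid, tc)
    xgrid <- rbind(xgrid, X)
    xk <- X[d, ]
    t0 <- t0 + h
  }
  list(time = tgrid, state = xgrid)
}
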