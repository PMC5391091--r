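# Quasi-steady-state reduction for M = 2.  The slow variables are the
# methylation-level fractions xi = (xi0, xi2); the intra-level (binding)
# degrees of freedom are equilibrated out, which puts the free-enzyme
# concentrations and the Michaelis occupancy factors into the drift.

as_xi <- function(xi) {
  xi <- unname(as.numeric(xi))
  if (length(xi) != 2L || any(!is.finite(xi)))
    stop("xi must be a finite numeric 2-vector (xi0, xi2)")
  if (any(xi < -1e-12) || sum(xi) > 1 + 1e-12)
    stop("xi0, xi2 must lie in [0,1] with xi0 + xi2 <= 1")
  xi
}

#' Free enzyme concentrations
#'
#' Self-consistent free CheR and CheB concentrations given the level
#' fractions, from the enzyme conservation laws with the intra-level
#' populations equilibrated:
#' \deqn{R_f = R_0 K_r (L+K_L) / \{K_r(L+K_L) + A_0[K_L \xi_0 + L(1-\xi_2)]\}}
#' and the mirrored expression for \eqn{B_f} with
#' \eqn{K_L(1-\xi_0) + L\xi_2}.
#'
#' @param xi numeric 2-vector \code{c(xi0, xi2)}.
#' @param params a \code{\link{bl_params}} object (M = 2 semantics).
#' @return named numeric vector \code{c(Rf = , Bf = )} in uM.
#' @export
free_enzymes <- function(xi, params) {
  xi <- as_xi(xi)
  with(params, {
    s <- L + KL
    Rf <- R0 * Kr * s / (Kr * s + A0 * (KL * xi[1] + L * (1 - xi[2])))
    Bf <- B0 * Kb * s / (Kb * s + A0 * (KL * (1 - xi[1]) + L * xi[2]))
    c(Rf = Rf, Bf = Bf)
  })
}

# Free enzymes under the self-consistent *saturating* conservation law:
# Rf + A0 (Rf/(Rf+Kr)) u = R0 with u the inactive receptor weight, a
# quadratic in Rf (positive root).  This is the true deterministic limit
# of the discrete network; the closed form of free_enzymes() linearizes
# the occupancy inside the conservation law (valid for Rf << Kr).
free_enzymes_exact <- function(xi, params) {
  xi <- as_xi(xi)
  with(params, {
    s <- L + KL
    u <- (KL * xi[1] + L * (1 - xi[2])) / s        # inactive weight
    w <- (KL * (1 - xi[1]) + L * xi[2]) / s        # active weight
    root <- function(K, E0, subw) {
      b <- K + A0 * subw - E0
      (-b + sqrt(b^2 + 4 * K * E0)) / 2
    }
    c(Rf = root(Kr, R0, u), Bf = root(Kb, B0, w))
  })
}

# Michaelis occupancy factors of the two enzymes; "saturating" and
# "exact" use X/(X+K) (with Eq-5-style vs self-consistent free
# concentrations), "linearized" the small-X form X/K.
enzyme_factors <- function(fe, params, mode) {
  if (mode == "linearized")
    c(R = fe[["Rf"]] / params$Kr, B = fe[["Bf"]] / params$Kb)
  else
    c(R = fe[["Rf"]] / (fe[["Rf"]] + params$Kr),
      B = fe[["Bf"]] / (fe[["Bf"]] + params$Kb))
}

enzyme_concentrations <- function(xi, params, mode) {
  if (mode == "exact") free_enzymes_exact(xi, params)
  else free_enzymes(xi, params)
}

#' Drift of the level fractions
#'
#' The deterministic rates of change \eqn{(v_0, v_2)} of the fractions in
#' the lowest and highest methylation level:
#' \deqn{v_0 = \nu_b \tilde B \frac{K_L}{L+K_L}(1-\xi_0-\xi_2)
#'        - \nu_r \tilde R \xi_0}
#' \deqn{v_2 = \nu_r \tilde R \frac{L}{L+K_L}(1-\xi_0-\xi_2)
#'        - \nu_b \tilde B \xi_2}
#' where \eqn{\tilde R, \tilde B} are the enzyme Michaelis occupancy
#' factors evaluated at the self-consistent free concentrations
#' (\code{\link{free_enzymes}}).
#'
#' @param xi numeric 2-vector \code{c(xi0, xi2)}.
#' @param params a \code{\link{bl_params}} object.
#' @param mode \code{"saturating"} (full Michaelis factors with the
#'   closed-form free enzymes, default), \code{"linearized"} (the
#'   \code{Rf << Kr}, \code{Bf << Kb} form used by the analytical layer),
#'   or \code{"exact"} (full Michaelis factors with the self-consistent
#'   saturating enzyme conservation -- the deterministic limit of the
#'   simulated network).
#' @return numeric 2-vector \code{c(v0, v2)} (1/s).
#' @export
bl_drift <- function(xi, params, mode = c("saturating", "linearized", "exact")) {
  mode <- match.arg(mode)
  xi <- as_xi(xi)
  fe <- enzyme_concentrations(xi, params, mode)
  f <- enzyme_factors(fe, params, mode)
  with(params, {
    x1 <- 1 - xi[1] - xi[2]
    pL <- KL / (L + KL)
    c(v0 = nu_b * f[["B"]] * pL * x1 - nu_r * f[["R"]] * xi[1],
      v2 = nu_r * f[["R"]] * (1 - pL) * x1 - nu_b * f[["B"]] * xi[2])
  })
}

#' Diffusion coefficients of the level fractions
#'
#' Finite-copy-number noise strengths \eqn{(D_0, D_2)}: each equals
#' \eqn{1/(2N)} times the sum of the two opposing catalytic fluxes feeding
#' that coordinate, with \eqn{N} the total receptor number.
#'
#' @inheritParams bl_drift
#' @return numeric 2-vector \code{c(D0, D2)} (1/s).
#' @export
bl_diffusion <- function(xi, params, mode = c("saturating", "linearized", "exact")) {
  mode <- match.arg(mode)
  xi <- as_xi(xi)
  fe <- enzyme_concentrations(xi, params, mode)
  f <- enzyme_factors(fe, params, mode)
  N <- receptor_count(params)
  with(params, {
    x1 <- 1 - xi[1] - xi[2]
    pL <- KL / (L + KL)
    c(D0 = (nu_b * f[["B"]] * pL * x1 + nu_r * f[["R"]] * xi[1]) / (2 * N),
      D2 = (nu_r * f[["R"]] * (1 - pL) * x1 + nu_b * f[["B"]] * xi[2]) / (2 * N))
  })
}

#' Active fraction of receptors
#'
#' \deqn{\xi_a = \frac{1-\xi_0}{1+\ell} + \frac{\ell}{1+\ell}\xi_2}
#' with \eqn{\ell = L/K_L}: the unligated part of the intermediate level
#' plus the (always active) top level.
#'
#' @inheritParams bl_drift
#' @return scalar active fraction in [0, 1].
#' @export
active_fraction <- function(xi, params) {
  xi <- as_xi(xi)
  l <- ell(params)
  (1 - xi[1]) / (1 + l) + l * xi[2] / (1 + l)
}

#' Solve for the deterministic fixed point
#'
#' Finds the stationary point of the level-fraction drift by damped
#' self-consistent iteration.  At a zero of the drift the fractions obey
#' \eqn{\xi_0 = 1/[(1+\rho)(1+\rho\ell)]},
#' \eqn{\xi_2 = \rho^2 \ell/[(1+\rho)(1+\rho\ell)]} with
#' \eqn{\rho = \nu_r \tilde R/(\nu_b \tilde B)}; the iteration refreshes
#' the free-enzyme concentrations (and hence \eqn{\rho}) from the current
#' iterate with damping 0.5 until the update norm falls below \code{tol}.
#' If the iteration fails to converge the mean-field ODE is integrated to
#' stationarity (deSolve) and the iteration restarted from there.
#'
#' @param params a \code{\link{bl_params}} object.
#' @param mode \code{"saturating"} (default), \code{"linearized"} or
#'   \code{"exact"}; see \code{\link{bl_drift}}.
#' @param tol convergence tolerance on the damped update norm.
#' @param max_iter iteration cap before the ODE fall-back.
#' @return An object of class \code{bl_fixed_point}: list with \code{xi}
#'   (c(xi0, xi2)), \code{xi1}, \code{Rf}, \code{Bf}, \code{xi_a},
#'   \code{mode}, and \code{drift_norm} (must be < 1e-10).
#' @export
solve_fixed_point <- function(params, mode = c("saturating", "linearized", "exact"),
                              tol = 1e-12, max_iter = 10000L) {
  mode <- match.arg(mode)
  l <- ell(params)
  step <- function(xi) {
    fe <- enzyme_concentrations(xi, params, mode)
    f <- enzyme_factors(fe, params, mode)
    num_r <- params$nu_r * f[["R"]]
    num_b <- params$nu_b * f[["B"]]
    if (num_r == 0 && num_b == 0) return(xi)  # nu=0 or no enzymes: any xi stationary
    if (num_r == 0) return(c(1, 0))
    if (num_b == 0) return(if (l > 0) c(0, 1) else c(0, 0))
    rho <- num_r / num_b
    den <- (1 + rho) * (1 + rho * l)
    c(1 / den, rho^2 * l / den)
  }
  iterate <- function(xi) {
    for (i in seq_len(max_iter)) {
      xin <- 0.5 * xi + 0.5 * step(xi)
      if (max(abs(xin - xi)) < tol) return(list(xi = xin, ok = TRUE))
      xi <- xin
    }
    list(xi = xi, ok = FALSE)
  }
  res <- iterate(c(1, 0))
  if (!res$ok) {
    traj <- deSolve::ode(
      y = c(xi0 = 1, xi2 = 0), times = c(0, 10^(0:6)),
      func = function(t, y, p) list(bl_drift(y, params, mode)),
      parms = NULL, method = "lsoda",
      rtol = 1e-10, atol = 1e-12)
    res <- iterate(pmin(pmax(traj[nrow(traj), c("xi0", "xi2")], 0), 1))
    if (!res$ok)
      stop("fixed-point iteration did not converge; last iterate: ",
           paste(signif(res$xi, 8), collapse = ", "))
  }
  xi <- res$xi
  v <- bl_drift(xi, params, mode)
  fe <- enzyme_concentrations(xi, params, mode)
  structure(list(xi = c(xi0 = xi[1], xi2 = xi[2]), xi1 = 1 - sum(xi),
                 Rf = fe[["Rf"]], Bf = fe[["Bf"]],
                 xi_a = active_fraction(xi, params),
                 mode = mode, drift_norm = max(abs(v))),
            class = "bl_fixed_point")
}

#' @export
print.bl_fixed_point <- function(x, ...) {
  cat(sprintf("BL fixed point (%s): xi* = (%.6g, %.6g, %.6g), xi_a* = %.6g\n",
              x$mode, x$xi[1], x$xi1, x$xi[2], x$xi_a))
  cat(sprintf("  Rf* = %.6g uM, Bf* = %.6g uM, |drift| = %.2g\n",
              x$Rf, x$Bf, x$drift_norm))
  invisible(x)
}

#' Perfect-adaptation closed form for the stationary active fraction
#'
#' In the regime \eqn{R_f \ll K_r}, \eqn{B_f \ll K_b} the stationary
#' active fraction obeys a ligand-independent quadratic obtained from the
#' methylation/demethylation flux balance
#' \eqn{\nu_r (R_f/K_r)(1-\xi_a) = \nu_b (B_f/K_b)\xi_a} together with the
#' enzyme conservation laws
#' \eqn{R_f = R_0 K_r/[K_r + A_0(1-\xi_a)]},
#' \eqn{B_f = B_0 K_b/[K_b + A_0 \xi_a]}:
#' \deqn{A_0(\nu_b B_0 - \nu_r R_0)\,\xi_a^2
#'   + [\nu_r R_0 (A_0 - K_b) - \nu_b B_0 (K_r + A_0)]\,\xi_a
#'   + \nu_r R_0 K_b = 0.}
#' The root in [0, 1] is returned (at \eqn{\alpha = 1} the equation is
#' linear and gives \eqn{K_b/(K_b+K_r)}, independent of \eqn{A_0}).  The
#' result is checked against \code{\link{solve_fixed_point}} in
#' \code{"linearized"} mode, with which it agrees identically; a warning
#' is issued if the small-\eqn{R_f/B_f} regime assumption is violated at
#' the solution (\eqn{R_f^* > 0.05 K_r} or \eqn{B_f^* > 0.05 K_b}).
#'
#' @param params a \code{\link{bl_params}} object.
#' @return stationary active fraction \eqn{\xi_a^*} in [0, 1].
#' @export
perfect_adaptation_xa <- function(params) {
  with(params, {
    if (R0 == 0) return(0)
    a <- A0 * (nu_b * B0 - nu_r * R0)
    b <- nu_r * R0 * (A0 - Kb) - nu_b * B0 * (Kr + A0)
    cc <- nu_r * R0 * Kb
    if (abs(a) < 1e-14 * abs(b)) {
      root <- -cc / b
    } else {
      disc <- b^2 - 4 * a * cc
      if (disc < 0) stop("no real root: inconsistent parameters")
      # numerically stable pair of roots
      q <- -0.5 * (b + sign(b) * sqrt(disc))
      roots <- c(q / a, cc / q)
      inside <- roots[roots >= -1e-12 & roots <= 1 + 1e-12]
      if (!length(inside))
        stop("no root of the adaptation quadratic lies in [0,1]")
      root <- min(max(inside[1], 0), 1)
    }
    Rf <- R0 * Kr / (Kr + A0 * (1 - root))
    Bf <- B0 * Kb / (Kb + A0 * root)
    if (Rf > 0.05 * Kr || Bf > 0.05 * Kb)
      warning("Rf* or Bf* is not small compared to its dissociation ",
              "constant; the closed form is outside its regime of validity")
    root
  })
}

#' Zero-order ultrasensitivity limits of the level populations
#'
#' Limiting level populations \eqn{(\xi_0, \xi_1, \xi_2)} as the receptor
#' concentration \eqn{A_0 \to \infty}.  At vanishing ligand the population
#' is shared between levels 0 and 1 and jumps at \eqn{\alpha = 1}
#' (\eqn{\xi_0}: 1 for \eqn{\alpha < 1}, 0 above); at saturating ligand it
#' is shared between levels 1 and 2 with the jump carried by \eqn{\xi_2}.
#' At \eqn{\alpha = 1} the populations are indeterminate (critical point).
#'
#' @param params a \code{\link{bl_params}} object.
#' @param regime \code{"low_ligand"} (\eqn{\ell \to 0}) or
#'   \code{"high_ligand"} (\eqn{\ell \to \infty}).
#' @return list with \code{xi} (3-vector \code{c(xi0, xi1, xi2)} or NA at
#'   the critical point), \code{alpha}, and logical \code{critical}.
#' @export
zou_limits <- function(params, regime = c("low_ligand", "high_ligand")) {
  regime <- match.arg(regime)
  a <- zou_alpha(params)
  if (a == 1)
    return(list(xi = c(xi0 = NA_real_, xi1 = NA_real_, xi2 = NA_real_),
                alpha = a, critical = TRUE))
  xi <- if (regime == "low_ligand") {
    if (a < 1) c(1, 0, 0) else c(0, 1, 0)
  } else {
    if (a < 1) c(0, 1, 0) else c(0, 0, 1)
  }
  list(xi = c(xi0 = xi[1], xi1 = xi[2], xi2 = xi[3]),
       alpha = a, critical = FALSE)
}

#' Fixed-point sweep table
#'
#' Solves the fixed point over a grid of \code{R0}, \code{ell} and
#' \code{A0} values and tabulates the results; optionally written as CSV.
#'
#' @param params template \code{\link{bl_params}} object.
#' @param R0_grid,ell_grid,A0_grid numeric grids (each defaults to the
#'   template's single value).
#' @param mode passed to \code{\link{solve_fixed_point}}.
#' @param file optional CSV path.
#' @return data frame with columns R0, ell, A0, xi0, xi1, xi2, xi_a, Rf, Bf.
#' @export
sweep_fixed_points <- function(params, R0_grid = params$R0,
                               ell_grid = ell(params), A0_grid = params$A0,
                               mode = "saturating", file = NULL) {
  grid <- expand.grid(R0 = R0_grid, ell = ell_grid, A0 = A0_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    p <- update_params(params, R0 = g$R0, L = g$ell * params$KL, A0 = g$A0)
    fp <- solve_fixed_point(p, mode = mode)
    data.frame(R0 = g$R0, ell = g$ell, A0 = g$A0,
               xi0 = fp$xi[["xi0"]], xi1 = fp$xi1, xi2 = fp$xi[["xi2"]],
               xi_a = fp$xi_a, Rf = fp$Rf, Bf = fp$Bf)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
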