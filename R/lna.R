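# Linear-noise approximation around the deterministic fixed point.
# "simplified" mode evaluates the analytic partial derivatives of the
# linearized (Rf << Kr, Bf << Kb) drift -- the regime in which the slow
# dynamics is usually quoted -- at the matching linearized fixed point, so
# that (fp, beta, gamma) are exactly consistent and perfect-adaptation
# identities hold to machine precision.  "full" mode differentiates the
# saturating drift numerically at the saturating fixed point.

# analytic partials of the linearized drift, all evaluated at (xi, Rf, Bf)
simplified_partials <- function(xi, params) {
  with(params, {
    fe <- free_enzymes(xi, params)
    Rf <- fe[["Rf"]]; Bf <- fe[["Bf"]]
    s <- L + KL
    pL <- KL / s
    x1 <- 1 - xi[1] - xi[2]
    # direct partials at fixed free-enzyme concentrations
    dv_dxi <- matrix(c(
      -(nu_b * Bf / Kb * pL + nu_r * Rf / Kr),  -nu_b * Bf / Kb * pL,
      -nu_r * Rf / Kr * (1 - pL),               -(nu_r * Rf / Kr * (1 - pL) + nu_b * Bf / Kb)),
      nrow = 2, byrow = TRUE)
    dv_dRf <- c(-nu_r / Kr * xi[1],        nu_r / Kr * (1 - pL) * x1)
    dv_dBf <- c(nu_b / Kb * pL * x1,       -nu_b / Kb * xi[2])
    denR <- (Kr * s + A0 * (KL * xi[1] + L * (1 - xi[2])))^2
    denB <- (Kb * s + A0 * (KL * (1 - xi[1]) + L * xi[2]))^2
    dRf_dxi <- c(-R0 * Kr * s * A0 * KL / denR,  R0 * Kr * s * A0 * L / denR)
    dBf_dxi <- c(B0 * Kb * s * A0 * KL / denB,  -B0 * Kb * s * A0 * L / denB)
    dv_dL <- c(-nu_b * Bf / Kb * KL / s^2 * x1,
                nu_r * Rf / Kr * KL / s^2 * x1)
    dRf_dL <- -R0 * Kr * A0 * KL * x1 / denR
    dBf_dL <-  B0 * Kb * A0 * KL * x1 / denB
    list(dv_dxi = dv_dxi, dv_dRf = dv_dRf, dv_dBf = dv_dBf,
         dRf_dxi = dRf_dxi, dBf_dxi = dBf_dxi,
         dv_dL = dv_dL, dRf_dL = dRf_dL, dBf_dL = dBf_dL)
  })
}

numeric_jacobian <- function(f, x, rel_h = 1e-7) {
  n <- length(x)
  J <- matrix(0, length(f(x)), n)
  for (j in seq_len(n)) {
    h <- rel_h * max(abs(x[j]), 1e-3)
    xp <- x; xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Jacobian of the drift at the fixed point
#'
#' The relaxation matrix \eqn{\beta_{mn} = \partial v_m/\partial \xi_n}
#' evaluated at the fixed point, including the chain-rule contributions
#' through the free-enzyme concentrations:
#' \deqn{\beta_{mn} = \partial_{\xi_n} v_m
#'   + \partial_{R_f} v_m\, \partial_{\xi_n} R_f
#'   + \partial_{B_f} v_m\, \partial_{\xi_n} B_f.}
#' At a stable fixed point \eqn{\beta} is Hurwitz (eigenvalues with
#' negative real parts).
#'
#' @param fp a \code{\link{solve_fixed_point}} result.
#' @param params a \code{\link{bl_params}} object.
#' @param mode \code{"simplified"}: analytic partials of the linearized
#'   drift (default); \code{"full"}/\code{"exact"}: central-difference
#'   Jacobian of the saturating/exact drift (see \code{\link{bl_drift}}).
#' @return 2x2 matrix (1/s), rows/cols ordered (0, 2).
#' @export
beta_matrix <- function(fp, params, mode = c("simplified", "full", "exact")) {
  mode <- match.arg(mode)
  xi <- as.numeric(fp$xi)
  drift_of <- c(full = "saturating", exact = "exact")
  if (mode != "simplified")
    return(numeric_jacobian(function(x) bl_drift(x, params, drift_of[[mode]]), xi))
  p <- simplified_partials(xi, params)
  p$dv_dxi + outer(p$dv_dRf, p$dRf_dxi) + outer(p$dv_dBf, p$dBf_dxi)
}

#' Ligand sensitivity of the drift at the fixed point
#'
#' \eqn{\gamma_m = d v_m/d L} at the fixed point, including the
#' free-enzyme chain terms.  This is the coupling through which a
#' time-dependent ligand perturbation drives the level fractions.
#'
#' @inheritParams beta_matrix
#' @return numeric 2-vector (1/s/uM).
#' @export
gamma_vector <- function(fp, params, mode = c("simplified", "full", "exact")) {
  mode <- match.arg(mode)
  xi <- as.numeric(fp$xi)
  if (mode != "simplified") {
    drift_mode <- if (mode == "full") "saturating" else "exact"
    g <- numeric_jacobian(function(LL) {
      bl_drift(xi, update_params(params, L = LL[1]), drift_mode)
    }, params$L)
    return(as.numeric(g))
  }
  p <- simplified_partials(xi, params)
  as.numeric(p$dv_dL + p$dv_dRf * p$dRf_dL + p$dv_dBf * p$dBf_dL)
}

#' Stationary covariance of the level fractions
#'
#' Solves the stationary Lyapunov equation
#' \eqn{\beta\sigma + \sigma\beta^T + 2D = 0} for the 2x2 case in closed
#' form:
#' \deqn{\sigma_{00} = -[(\beta_{22}(\beta_{00}+\beta_{22})
#'   -\beta_{02}\beta_{20})D_0 + \beta_{02}^2 D_2]/\Delta}
#' \deqn{\sigma_{22} = -[\beta_{20}^2 D_0 + (\beta_{00}(\beta_{00}
#'   +\beta_{22})-\beta_{02}\beta_{20})D_2]/\Delta}
#' \deqn{\sigma_{02} = [\beta_{20}\beta_{22} D_0
#'   + \beta_{00}\beta_{02} D_2]/\Delta}
#' with \eqn{\Delta = (\beta_{00}+\beta_{22})
#' (\beta_{00}\beta_{22}-\beta_{02}\beta_{20})}.
#'
#' @param beta 2x2 Hurwitz relaxation matrix (\code{\link{beta_matrix}}).
#' @param Dstar numeric 2-vector of diffusion coefficients at the fixed
#'   point (\code{\link{bl_diffusion}}).
#' @return symmetric 2x2 covariance matrix of \code{(xi0', xi2')}.
#' @export
stationary_covariance <- function(beta, Dstar) {
  ev <- eigen(beta, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("beta is not Hurwitz (fixed point not stable); cannot solve ",
         "the stationary Lyapunov equation")
  b00 <- beta[1, 1]; b02 <- beta[1, 2]; b20 <- beta[2, 1]; b22 <- beta[2, 2]
  Delta <- (b00 + b22) * (b00 * b22 - b02 * b20)
  s00 <- -((b22 * (b00 + b22) - b02 * b20) * Dstar[1] + b02^2 * Dstar[2]) / Delta
  s22 <- -(b20^2 * Dstar[1] + (b00 * (b00 + b22) - b02 * b20) * Dstar[2]) / Delta
  s02 <- (b20 * b22 * Dstar[1] + b00 * b02 * Dstar[2]) / Delta
  matrix(c(s00, s02, s02, s22), 2, 2,
         dimnames = list(c("xi0", "xi2"), c("xi0", "xi2")))
}

#' Variance of the active fraction
#'
#' Propagates the level-fraction covariance to the activity:
#' \deqn{\sigma_a^2 = \frac{\sigma_{00} + \ell^2\sigma_{22}
#'   - 2\ell\sigma_{02}}{(1+\ell)^2}.}
#'
#' @param sigma 2x2 covariance from \code{\link{stationary_covariance}}.
#' @param params a \code{\link{bl_params}} object.
#' @return scalar variance (dimensionless).
#' @export
activity_variance <- function(sigma, params) {
  l <- ell(params)
  (sigma[1, 1] + l^2 * sigma[2, 2] - 2 * l * sigma[1, 2]) / (1 + l)^2
}

#' Linear-noise approximation at the fixed point
#'
#' Convenience wrapper: solves the fixed point (in the mode matching the
#' requested derivative scheme), assembles \eqn{\beta}, \eqn{\gamma}, the
#' diffusion vector, the stationary covariance and the activity variance.
#'
#' @param params a \code{\link{bl_params}} object.
#' @param mode \code{"simplified"} (analytic linearized layer, default),
#'   \code{"full"} (numerical derivatives of the saturating drift), or
#'   \code{"exact"} (numerical derivatives of the exact drift, the
#'   deterministic limit of the simulated network -- use this when
#'   comparing against stochastic simulations).
#' @param fp optional precomputed fixed point (must match \code{mode}).
#' @return An object of class \code{bl_lna}: list with \code{fp},
#'   \code{beta}, \code{gamma}, \code{Dstar}, \code{sigma},
#'   \code{sigma_a2}, \code{mode}.
#' @examples
#' res <- bl_lna(bl_params(R0 = 0.224, L = 2))
#' sqrt(res$sigma_a2)   # ~1e-2 near the ultrasensitive transition
#' @export
bl_lna <- function(params, mode = c("simplified", "full", "exact"), fp = NULL) {
  mode <- match.arg(mode)
  fp_mode <- switch(mode, simplified = "linearized", full = "saturating",
                    exact = "exact")
  if (is.null(fp)) fp <- solve_fixed_point(params, mode = fp_mode)
  beta <- beta_matrix(fp, params, mode)
  gamma <- gamma_vector(fp, params, mode)
  Dstar <- bl_diffusion(as.numeric(fp$xi), params, mode = fp_mode)
  sigma <- stationary_covariance(beta, Dstar)
  structure(list(fp = fp, beta = beta, gamma = gamma, Dstar = Dstar,
                 sigma = sigma,
                 sigma_a2 = activity_variance(sigma, params), mode = mode),
            class = "bl_lna")
}

#' @export
print.bl_lna <- function(x, ...) {
  cat(sprintf("BL linear-noise approximation (%s): xi_a* = %.6g, sigma_a = %.4g\n",
              x$mode, x$fp$xi_a, sqrt(x$sigma_a2)))
  cat("  beta eigenvalues:", paste(signif(eigen(x$beta, only.values = TRUE)$values, 4),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Activity-variance profile over enzyme and ligand grids
#'
#' For each (R0, ell) pair: fixed point, LNA, activity variance.  Also
#' reports, per ell, the R0 maximising the variance and the peak value.
#'
#' @param params template \code{\link{bl_params}} object.
#' @param R0_grid,ell_grid numeric grids (non-empty).
#' @param mode passed to \code{\link{bl_lna}}.
#' @return list with \code{table} (data frame R0, ell, A0, sigma00,
#'   sigma22, sigma02, sigma_a2; failed cells carried as NA) and
#'   \code{peaks} (data frame ell, R0_peak, sigma_a2_peak).
#' @export
variance_profile <- function(params, R0_grid, ell_grid, mode = "simplified") {
  stopifnot(length(R0_grid) > 0, length(ell_grid) > 0)
  grid <- expand.grid(R0 = R0_grid, ell = ell_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    out <- data.frame(R0 = g$R0, ell = g$ell, A0 = params$A0,
                      sigma00 = NA_real_, sigma22 = NA_real_,
                      sigma02 = NA_real_, sigma_a2 = NA_real_)
    res <- tryCatch({
      p <- update_params(params, R0 = g$R0, L = g$ell * params$KL)
      bl_lna(p, mode = mode)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      out$sigma00 <- res$sigma[1, 1]
      out$sigma22 <- res$sigma[2, 2]
      out$sigma02 <- res$sigma[1, 2]
      out$sigma_a2 <- res$sigma_a2
    }
    out
  })
  tab <- do.call(rbind, rows)
  peaks <- do.call(rbind, lapply(split(tab, tab$ell), function(d) {
    if (all(is.na(d$sigma_a2))) return(NULL)
    i <- which.max(d$sigma_a2)
    data.frame(ell = d$ell[1], R0_peak = d$R0[i],
               sigma_a2_peak = d$sigma_a2[i])
  }))
  rownames(peaks) <- NULL
  list(table = tab, peaks = peaks)
}
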