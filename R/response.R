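# Linear response of the mean activity and the motor clockwise bias to a
# time-dependent ligand perturbation.  The slow level fractions respond
# through the linearised dynamics d(dxi)/dt = beta dxi + gamma dL(t), and
# the activity carries in addition an instantaneous ligand-occupancy term.

#' Linear-response model at the operating point
#'
#' Assembles everything needed to evaluate the activity response
#' \eqn{\chi_a} and the clockwise-bias response \eqn{\chi_b}: the fixed
#' point, \eqn{\beta}, \eqn{\gamma} (from \code{\link{bl_lna}}), the two
#' relaxation rates \eqn{A, B} (minus the eigenvalues of \eqn{\beta}),
#' the CheY-P turnover rate and the motor operating point.
#'
#' @param params a \code{\link{bl_params}} object.
#' @param lambda_Y CheY-P dephosphorylation rate (1/s; default 30).
#' @param H motor Hill coefficient (default 20).
#' @param Pcw_star clockwise bias at the operating point (default 0.5).
#' @param mode passed to \code{\link{bl_lna}}.
#' @return object of class \code{bl_response_model} with fields
#'   \code{lna}, \code{A}, \code{B} (1/s; complex-conjugate pairs are kept
#'   complex and handled downstream), \code{lambda_Y}, \code{H},
#'   \code{Pcw_star}, \code{params}.
#' @export
response_model <- function(params, lambda_Y = 30, H = 20, Pcw_star = 0.5,
                           mode = "simplified") {
  lna <- bl_lna(params, mode = mode)
  b <- lna$beta
  tr <- b[1, 1] + b[2, 2]
  disc <- (b[1, 1] - b[2, 2])^2 + 4 * b[1, 2] * b[2, 1]
  sq <- sqrt(as.complex(disc))
  A <- -0.5 * (tr + sq)
  B <- -0.5 * (tr - sq)
  if (abs(Im(A)) < 1e-12 * max(1, abs(Re(A)))) { A <- Re(A); B <- Re(B) }
  structure(list(lna = lna, A = A, B = B, lambda_Y = lambda_Y, H = H,
                 Pcw_star = Pcw_star, params = params),
            class = "bl_response_model")
}

# chi_m(s) transforms (Laplace): numerators and common denominator
chi_m_laplace <- function(s, model) {
  b <- model$lna$beta; g <- model$lna$gamma
  d <- (s - b[1, 1]) * (s - b[2, 2]) - b[1, 2] * b[2, 1]
  c(chi0 = ((s - b[2, 2]) * g[1] + b[1, 2] * g[2]) / d,
    chi2 = (b[2, 1] * g[1] + (s - b[1, 1]) * g[2]) / d)
}

#' Laplace transform of the activity response function
#'
#' \deqn{\tilde\chi_a(s) = -\frac{K_L}{L+K_L}\tilde\chi_0(s)
#'   + \frac{L}{L+K_L}\tilde\chi_2(s)
#'   - \frac{K_L}{(L+K_L)^2}(1-\xi_0^*-\xi_2^*)}
#' where \eqn{\tilde\chi_m(s)} are the level-fraction responses with
#' poles at the eigenvalues of \eqn{\beta}.  Perfect adaptation makes
#' \eqn{\tilde\chi_a(0) = 0} (zero enclosed area).
#'
#' @param s Laplace frequency/frequencies (1/s); must avoid the poles
#'   \code{-A}, \code{-B}.
#' @param model a \code{\link{response_model}}.
#' @return \eqn{\tilde\chi_a(s)}, vectorised over \code{s}.
#' @export
chi_a_laplace <- function(s, model) {
  p <- model$params
  if (any(abs(s + model$A) < 1e-12) || any(abs(s + model$B) < 1e-12))
    stop("s coincides with a pole of the response function")
  fp <- model$lna$fp
  sKL <- p$L + p$KL
  vapply(s, function(si) {
    cm <- chi_m_laplace(si, model)
    Re(-p$KL / sKL * cm[["chi0"]] + p$L / sKL * cm[["chi2"]]) -
      p$KL / sKL^2 * (1 - fp$xi[["xi0"]] - fp$xi[["xi2"]])
  }, numeric(1))
}

#' Activity response to a small ligand step
#'
#' Integrates the linearised level dynamics for a step
#' \eqn{\delta L(t) = \delta L_s \Theta(t)} and assembles the activity
#' deviation, including the instantaneous ligand-occupancy term.  Perfect
#' adaptation returns the activity to baseline as \eqn{t \to \infty}.
#'
#' @param model a \code{\link{response_model}}.
#' @param dL_s step size (uM); should be small against \code{L + KL}.
#' @param t_grid times at which to report (s, >= 0).
#' @return data frame with \code{t}, \code{dxi0}, \code{dxi2},
#'   \code{dxi_a}.
#' @export
step_response <- function(model, dL_s, t_grid) {
  p <- model$params
  if (abs(dL_s) > 0.1 * (p$L + p$KL))
    warning("step size is not small compared to L + KL; ",
            "linear response may be inaccurate")
  b <- model$lna$beta; g <- model$lna$gamma
  fp <- model$lna$fp
  # dxi(t) = (e^{beta t} - I) beta^{-1} gamma dL_s; eval via eigendecomposition
  eg <- eigen(b)
  Vi <- solve(eg$vectors)
  binv_g <- solve(b, g)
  out <- t(vapply(t_grid, function(tt) {
    E <- eg$vectors %*% diag(exp(eg$values * tt), 2) %*% Vi
    Re((E - diag(2)) %*% binv_g) * dL_s
  }, numeric(2)))
  sKL <- p$L + p$KL
  dxi_a <- -p$KL / sKL * out[, 1] + p$L / sKL * out[, 2] -
    p$KL / sKL^2 * (1 - fp$xi[["xi0"]] - fp$xi[["xi2"]]) * dL_s
  data.frame(t = t_grid, dxi0 = out[, 1], dxi2 = out[, 2], dxi_a = dxi_a)
}

# partial-fraction coefficients of chi_b(t): chi_b(t) = C * (r_lam -
# c_inst) e^{-lam t} + C r_A e^{-A t} + C r_B e^{-B t}, derived from
# chi_b(s) = C * chi_a(s)/(s + lambda_Y) with chi_a from its Laplace form.
chi_b_coefficients <- function(model) {
  p <- model$params
  b <- model$lna$beta; g <- model$lna$gamma
  fp <- model$lna$fp
  A <- model$A; B <- model$B; lam <- model$lambda_Y
  sKL <- p$L + p$KL
  w0 <- -p$KL / sKL; w2 <- p$L / sKL
  # chi_0 + chi_2 weighted numerator: P s + Q over (s+A)(s+B)
  P <- w0 * g[1] + w2 * g[2]
  Q <- w0 * (-b[2, 2] * g[1] + b[1, 2] * g[2]) +
       w2 * (b[2, 1] * g[1] - b[1, 1] * g[2])
  c_inst <- p$KL / sKL^2 * (1 - fp$xi[["xi0"]] - fp$xi[["xi2"]])
  C <- model$H * model$lambda_Y / fp$xi_a * (1 - model$Pcw_star)
  r_A <- (-P * A + Q) / ((B - A) * (lam - A))
  r_B <- (-P * B + Q) / ((A - B) * (lam - B))
  r_lam <- (-P * lam + Q) / ((A - lam) * (B - lam))
  list(C = C, rates = c(lambda_Y = lam, A = A, B = B),
       coefs = c(C * (r_lam - c_inst), C * r_A, C * r_B))
}

#' Clockwise-bias response function
#'
#' The chemotactic response of the motor clockwise bias to a ligand
#' impulse: the activity response filtered through CheY-P turnover,
#' \deqn{\chi_b(t) = \frac{H\lambda_Y}{\xi_a^*}[1-P_{CW}(Y^*)]
#'   \int_0^t e^{-\lambda_Y(t-t')}\chi_a(t') dt',}
#' evaluated in closed form as a sum of three exponentials with rates
#' \eqn{\lambda_Y, A, B} (coefficients from partial fractions of
#' \eqn{\tilde\chi_a(s)/(s+\lambda_Y)}).  The curve is bilobed — a fast
#' positive lobe followed by a slow negative lobe — and encloses zero
#' area (perfect adaptation).  Degenerate rates (\eqn{A = B} or
#' \eqn{\lambda_Y \in \{A, B\}}) fall back to numerical convolution with a
#' message.  Complex-conjugate rate pairs are evaluated in complex
#' arithmetic; the real part is returned.
#'
#' @param t_grid times (s, >= 0).
#' @param model a \code{\link{response_model}}.
#' @return numeric vector \eqn{\chi_b(t)} on \code{t_grid}.
#' @export
chi_b_time <- function(t_grid, model) {
  A <- model$A; B <- model$B; lam <- model$lambda_Y
  degenerate <- abs(A - B) < 1e-10 * max(abs(A), abs(B)) ||
    min(abs(lam - A), abs(lam - B)) < 1e-10 * lam
  if (degenerate) {
    message("degenerate relaxation rates; using numerical convolution")
    return(chi_b_numeric(t_grid, model))
  }
  co <- chi_b_coefficients(model)
  vapply(t_grid, function(tt) {
    Re(sum(co$coefs * exp(-co$rates * tt)))
  }, numeric(1))
}

# numerical fall-back via the exact unit step response w(t):
# chi_a = w' (with its t=0 jump), and the CheY-P filter gives
# z(t) = int_0^t e^{-lam(t-t')} chi_a(t') dt' = w(t) - lam*u(t) with
# u' = -lam*u + w(t), u(0) = 0.  w is evaluated analytically, so the only
# numerical step is a one-dimensional linear ODE.
chi_b_numeric <- function(t_grid, model) {
  p <- model$params
  lam <- model$lambda_Y
  dLs <- 1e-6 * (p$L + p$KL)
  w <- function(tt) step_response(model, dLs, tt)$dxi_a / dLs
  C <- model$H * lam / model$lna$fp$xi_a * (1 - model$Pcw_star)
  tt <- sort(unique(c(0, t_grid)))
  sol <- deSolve::ode(y = c(u = 0), times = tt,
                      func = function(t, y, parms) list(-lam * y[1] + w(t)),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  u <- stats::approx(sol[, "time"], sol[, "u"], xout = t_grid, rule = 2)$y
  C * (w(t_grid) - lam * u)
}

#' Total area under the bias response
#'
#' Analytic integral \eqn{\int_0^\infty \chi_b(t)\,dt} of the closed-form
#' three-exponential response; zero (to round-off) under perfect
#' adaptation.
#'
#' @param model a \code{\link{response_model}}.
#' @return scalar area.
#' @export
chi_b_area <- function(model) {
  co <- chi_b_coefficients(model)
  Re(sum(co$coefs / co$rates))
}
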