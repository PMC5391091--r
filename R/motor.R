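# Downstream pathway: receptor activity -> CheY-P level -> flagellar-motor
# clockwise bias.  Active receptors phosphorylate CheY; CheY-P sets the
# motor's clockwise (tumble) bias through a steep Hill function, so
# receptor-level noise propagates into fluctuations of the bias.

#' Motor and CheY pathway parameters
#'
#' @param a_Y CheY phosphorylation rate by an active receptor (1/uM/s).
#' @param Y0 total CheY concentration (uM).
#' @param lambda_Y CheY-P dephosphorylation rate (1/s).
#' @param K_Y motor Hill constant (uM; default 3).
#' @param H Hill coefficient of the non-adapted motor (default 20).
#' @param H_a Hill coefficient of the adapted motor (default 10).
#' @param lambda_m motor adaptation rate (1/s; default 0.0167, i.e. a
#'   one-minute adaptation time).
#' @param lambda_xi decay rate of receptor-activity fluctuations (1/s;
#'   default 0, which saturates the CheY-P noise bound -- appropriate when
#'   activity fluctuations are slow compared to CheY-P turnover).  Set it
#'   from a simulated trajectory's \code{autocorr_rate} when available.
#' @return object of class \code{bl_motor_params}.
#' @export
motor_params <- function(a_Y = 3, Y0 = 18, lambda_Y = 14.15, K_Y = 3,
                         H = 20, H_a = 10, lambda_m = 0.0167,
                         lambda_xi = 0) {
  stopifnot(a_Y > 0, Y0 > 0, lambda_Y > 0, K_Y > 0, H > 1, H_a > 1,
            lambda_m >= 0, lambda_xi >= 0)
  structure(list(a_Y = a_Y, Y0 = Y0, lambda_Y = lambda_Y, K_Y = K_Y,
                 H = H, H_a = H_a, lambda_m = lambda_m,
                 lambda_xi = lambda_xi),
            class = "bl_motor_params")
}

#' Motor parameters from a literature set
#'
#' Builds \code{\link{motor_params}} from one of the published pathway
#' parameterisations (see \code{\link{literature_params}}).
#'
#' @inheritParams literature_params
#' @param ... overrides passed on to \code{\link{motor_params}}.
#' @return object of class \code{bl_motor_params}.
#' @export
motor_params_literature <- function(set = c("morton_firth", "rao", "kollmann"),
                                    ...) {
  lp <- literature_params(set)
  args <- list(a_Y = lp$a_Y, Y0 = lp$Y0, lambda_Y = lp$lambda_Y)
  override <- list(...)
  args[names(override)] <- override
  do.call(motor_params, args)
}

#' Mean steady-state CheY-P concentration
#'
#' With total CheY well above the phosphorylated pool, the balance of
#' phosphorylation by active receptors against dephosphorylation gives
#' \deqn{Y^* = a_Y Y_0 A_0 \xi_a^* / \lambda_Y.}
#'
#' @param params a \code{\link{bl_params}} object (supplies \code{A0}).
#' @param motor a \code{\link{motor_params}} object.
#' @param xi_a_star stationary active receptor fraction.
#' @return CheY-P concentration (uM).
#' @export
cheYp_mean <- function(params, motor, xi_a_star) {
  motor$a_Y * motor$Y0 * params$A0 * xi_a_star / motor$lambda_Y
}

#' CheY-P noise from receptor-activity noise
#'
#' Fluctuations in the active fraction with standard deviation
#' \eqn{\sigma_a} and correlation decay rate \eqn{\lambda_\xi} produce
#' \deqn{\sigma_Y = \frac{a_Y Y_0 A_0}
#'   {\sqrt{\lambda_Y(\lambda_Y+\lambda_\xi)}}\,\sigma_a,}
#' which saturates the bound \eqn{\sigma_Y \le a_Y Y_0 A_0 \sigma_a /
#' \lambda_Y} when \eqn{\lambda_\xi \ll \lambda_Y}.
#'
#' @param sigma_a standard deviation of the active fraction.
#' @param motor a \code{\link{motor_params}} object (uses
#'   \code{lambda_xi}).
#' @param params a \code{\link{bl_params}} object (supplies \code{A0}).
#' @return standard deviation of CheY-P (uM).
#' @export
sigma_Y_from_activity <- function(sigma_a, motor, params) {
  stopifnot(sigma_a >= 0)
  motor$a_Y * motor$Y0 * params$A0 * sigma_a /
    sqrt(motor$lambda_Y * (motor$lambda_Y + motor$lambda_xi))
}

#' Receptor-activity noise implied by a CheY-P noise range
#'
#' Inverts the saturated CheY-P noise relation at both interval
#' endpoints: \eqn{\sigma_a = \sigma_Y \lambda_Y/(a_Y Y_0 A_0)}.  With the
#' experimentally measured \eqn{\sigma_Y \in [0.09, 0.22]} uM this maps
#' the published pathway parameter sets onto activity-noise windows of
#' order \eqn{10^{-4}}--\eqn{10^{-2}}.
#'
#' @param sigma_Y_low,sigma_Y_high CheY-P standard deviation interval
#'   endpoints (uM, \code{0 <= low <= high}).
#' @param motor a \code{\link{motor_params}} object.
#' @param params a \code{\link{bl_params}} object (supplies \code{A0}).
#' @return numeric 2-vector \code{c(low, high)} of activity standard
#'   deviations.
#' @examples
#' mf <- motor_params_literature("morton_firth")
#' sigma_a_range(0.09, 0.22, mf, bl_params(A0 = 5))  # c(4.7e-3, 1.15e-2)
#' @export
sigma_a_range <- function(sigma_Y_low, sigma_Y_high, motor, params) {
  stopifnot(0 <= sigma_Y_low, sigma_Y_low <= sigma_Y_high)
  k <- motor$lambda_Y / (motor$a_Y * motor$Y0 * params$A0)
  c(low = sigma_Y_low * k, high = sigma_Y_high * k)
}

#' Clockwise bias of the flagellar motor
#'
#' Hill response of the motor to CheY-P:
#' \eqn{P_{CW}(Y) = Y^H/(Y^H + K_Y^H)}.
#'
#' @param Y CheY-P concentration(s) (uM, >= 0).
#' @param motor a \code{\link{motor_params}} object.
#' @param H Hill coefficient override (defaults to \code{motor$H}).
#' @return clockwise-spinning probability in [0, 1].
#' @export
cw_bias <- function(Y, motor, H = motor$H) {
  stopifnot(all(Y >= 0))
  # 1/(1 + y^-H) is overflow-safe for steep Hill coefficients
  1 / (1 + (Y / motor$K_Y)^(-H))
}

# derivative of the Hill bias with respect to Y, evaluated in log space so
# that very steep Hill coefficients do not overflow
cw_bias_slope <- function(Y, motor, H = motor$H) {
  y <- Y / motor$K_Y
  out <- numeric(length(y))
  pos <- y > 0
  ly <- log(y[pos])
  # log(1 + y^H) without forming y^H when it would overflow
  l1p <- ifelse(ly > 0, H * ly + log1p(exp(-H * ly)), log1p(exp(H * ly)))
  out[pos] <- exp(log(H) - log(motor$K_Y) + (H - 1) * ly - 2 * l1p)
  out
}

#' Clockwise-bias fluctuation from CheY-P noise
#'
#' Linear propagation of a CheY-P fluctuation of size \eqn{\sigma_Y}
#' through the motor Hill curve at operating point \eqn{\bar y = Y/K_Y}:
#' \deqn{\delta P_{CW} = \frac{H \bar y^{H-1}}{K_Y (1+\bar y^H)^2}
#'   \sigma_Y.}
#'
#' @param sigma_Y CheY-P standard deviation (uM).
#' @param ybar dimensionless operating point \eqn{Y/K_Y}.
#' @param motor a \code{\link{motor_params}} object.
#' @return standard deviation of the clockwise bias.
#' @seealso \code{\link{delta_pcw_bound}} for the supremum over operating
#'   points.
#' @export
delta_pcw <- function(sigma_Y, ybar, motor) {
  stopifnot(sigma_Y >= 0, ybar >= 0)
  cw_bias_slope(ybar * motor$K_Y, motor) * sigma_Y
}

#' Upper bound on the clockwise-bias fluctuation
#'
#' The slope factor \eqn{\bar y^{H-1}/(1+\bar y^H)^2} attains its single
#' maximum at \eqn{\tilde y = [(H-1)/(H+1)]^{1/H}}, approaching 1/4 for
#' large \eqn{H}; hence
#' \deqn{\delta P_{CW} \le \frac{H}{4 K_Y} \sigma_Y.}
#'
#' @inheritParams delta_pcw
#' @return list with \code{bound} (\eqn{H\sigma_Y/(4K_Y)}) and
#'   \code{ytilde} (the maximising operating point).
#' @examples
#' m <- motor_params(H = 20, K_Y = 3)
#' delta_pcw_bound(0.22, m)$bound  # 0.367
#' @export
delta_pcw_bound <- function(sigma_Y, motor) {
  stopifnot(sigma_Y >= 0)
  list(bound = motor$H * sigma_Y / (4 * motor$K_Y),
       ytilde = ((motor$H - 1) / (motor$H + 1))^(1 / motor$H))
}

#' Bias fluctuation corrected for motor-level adaptation
#'
#' The motor partially adapts to sustained CheY-P shifts over a time
#' \eqn{1/\lambda_m}; its linear response is an instantaneous non-adapted
#' term \eqn{\alpha_{na} = \partial_Y P_{CW}} (Hill coefficient \eqn{H})
#' plus a slow relaxation toward the adapted slope \eqn{\alpha_a} (Hill
#' coefficient \eqn{H_a}).  Filtering stationary CheY-P fluctuations of
#' size \eqn{\sigma_Y} through this response gives
#' \deqn{\delta P_{CW} = \sigma_Y\,\alpha_{na}\sqrt{1
#'   - \frac{\lambda_m}{\lambda_Y}\frac{\alpha_a}{\alpha_{na}}
#'     \left(1-\frac{\alpha_a}{\alpha_{na}}\right)},}
#' which reduces to \code{\link{delta_pcw}} when \eqn{\lambda_m = 0} or
#' \eqn{\alpha_a = \alpha_{na}}.  The correction is negligible where the
#' bracket stays near 1 (CheY-P in roughly the 2.5--4 uM sensitive
#' window).
#'
#' @param sigma_Y CheY-P standard deviation (uM).
#' @param Y CheY-P operating point (uM).
#' @param motor a \code{\link{motor_params}} object.
#' @return standard deviation of the clockwise bias.
#' @export
delta_pcw_adapted <- function(sigma_Y, Y, motor) {
  stopifnot(sigma_Y >= 0, Y >= 0)
  a_na <- cw_bias_slope(Y, motor, H = motor$H)
  a_a <- cw_bias_slope(Y, motor, H = motor$H_a)
  ratio <- a_a / a_na
  bracket <- 1 - (motor$lambda_m / motor$lambda_Y) * ratio * (1 - ratio)
  if (bracket < 0)
    stop("adaptation correction bracket is negative: inconsistent ",
         "motor parameters (lambda_m too large relative to lambda_Y)")
  sigma_Y * a_na * sqrt(bracket)
}
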