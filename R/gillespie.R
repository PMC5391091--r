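#' Simulation configuration
#'
#' @param seed integer RNG seed.
#' @param t_burn burn-in time discarded by \code{\link{summarize_trajectory}}
#'   (s).
#' @param t_total total simulated time (s), must exceed \code{t_burn}.
#' @param sample_dt observation interval (s).
#' @return object of class \code{bl_sim_config}.
#' @export
sim_config <- function(seed = 1L, t_burn = 500, t_total = 10500,
                       sample_dt = 0.5) {
  stopifnot(t_total > t_burn, t_burn >= 0, sample_dt > 0)
  structure(list(seed = as.integer(seed), t_burn = t_burn,
                 t_total = t_total, sample_dt = sample_dt),
            class = "bl_sim_config")
}

#' Exact stochastic simulation of the receptor network
#'
#' Runs the Gillespie direct method on the full reaction network.  All
#' receptors start unmethylated, unbound and inactive; free CheR/CheB
#' counts are \code{round(R0*conversion)} and \code{round(B0*conversion)};
#' the ligand enters as a fixed external concentration factor in the
#' binding propensities.  Trajectories are reproducible: the same seed
#' yields a bit-identical sample path.
#'
#' @param params a \code{\link{bl_params}} object.
#' @param config a \code{\link{sim_config}}.
#' @param network optional prebuilt \code{\link{build_network}} (must match
#'   \code{params}).
#' @return object of class \code{bl_trajectory}: list with \code{time},
#'   integer matrix \code{counts} (one column per species, free enzymes
#'   last), \code{xi_a} (active fraction per sample), \code{levels}
#'   (matrix of per-level receptor fractions), \code{network},
#'   \code{config}.
#' @examples
#' \donttest{
#' p <- bl_params(A0 = 5.3, R0 = 0.224, L = 0.02)
#' sim <- simulate_bl(p, sim_config(seed = 7, t_burn = 50, t_total = 250))
#' summarize_trajectory(sim)
#' }
#' @export
simulate_bl <- function(params, config = sim_config(),
                        network = build_network(params)) {
  rx <- network$reactions
  set.seed(config$seed)
  counts <- ssa_run(as.integer(network$init), as.numeric(rx$c),
                    as.integer(rx$r1) - 1L,
                    as.integer(ifelse(is.na(rx$r2), 0L, rx$r2)) - 1L,
                    as.integer(rx$p1) - 1L,
                    as.integer(ifelse(is.na(rx$p2), 0L, rx$p2)) - 1L,
                    config$t_total, config$sample_dt)
  colnames(counts) <- names(network$init)
  time <- (seq_len(nrow(counts)) - 1L) * config$sample_dt
  N <- receptor_count(params)
  act <- active_species(network)
  xi_a <- rowSums(counts[, act, drop = FALSE]) / N
  lv <- vapply(0:params$M, function(m) {
    nm <- network$species$name[network$species$level == m]
    rowSums(counts[, nm, drop = FALSE]) / N
  }, numeric(nrow(counts)))
  colnames(lv) <- paste0("m", 0:params$M)
  structure(list(time = time, counts = counts, xi_a = xi_a, levels = lv,
                 network = network, config = config, params = params),
            class = "bl_trajectory")
}

# exponential decay rate of the autocorrelation of a stationary series,
# by log-linear fit over the initial positive part of the ACF
fit_autocorr_rate <- function(x, dt, max_lag = min(length(x) %/% 4L, 4000L)) {
  if (stats::var(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # use lags up to where the ACF first drops below 0.05 (or turns negative)
  upto <- which(ac < 0.05)[1]
  if (is.na(upto)) upto <- length(ac)
  upto <- max(upto - 1L, 2L)
  lag <- seq_len(upto) - 1L
  y <- log(pmax(ac[seq_len(upto)], 1e-12))
  fit <- stats::lm.fit(cbind(1, lag), y)
  max(-fit$coefficients[2] / dt, 0)
}

#' Steady-state summary of a trajectory
#'
#' Discards the burn-in, then estimates the mean and variance of the
#' active fraction with autocorrelation-aware (blocking) standard errors,
#' the per-level mean fractions, and the exponential decay rate
#' \code{lambda_xi} of the activity autocorrelation.  Block length is set
#' from the fitted correlation time (at least 20 correlation times per
#' block where the series allows it).
#'
#' @param sim a \code{\link{simulate_bl}} result.
#' @param t_burn burn-in override (defaults to the trajectory's config).
#' @return object of class \code{bl_summary}: list with \code{mean_xi_a},
#'   \code{se_mean}, \code{var_xi_a}, \code{se_var}, \code{sd_xi_a},
#'   \code{mean_levels}, \code{autocorr_rate}, \code{n_samples},
#'   \code{n_blocks}.
#' @export
summarize_trajectory <- function(sim, t_burn = sim$config$t_burn) {
  keep <- sim$time >= t_burn
  if (!any(keep)) stop("trajectory shorter than the burn-in")
  x <- sim$xi_a[keep]
  n <- length(x)
  dt <- sim$config$sample_dt
  lam <- fit_autocorr_rate(x, dt)
  # block length: >= 20 correlation times, capped so >= 8 blocks remain
  blen <- if (is.finite(lam) && lam > 0) ceiling(20 / (lam * dt)) else n %/% 20L
  blen <- max(1L, min(blen, n %/% 8L))
  nb <- n %/% blen
  bm <- colMeans(matrix(x[seq_len(nb * blen)], nrow = blen))
  bv <- apply(matrix(x[seq_len(nb * blen)], nrow = blen), 2, stats::var)
  mean_xi <- mean(x)
  var_xi <- stats::var(x)
  # standard errors: blocking can undershoot when the window holds few
  # correlation times (blocks stay correlated), so take the larger of the
  # blocking estimate and the analytic Ornstein-Uhlenbeck forms
  # Var(mean) = 2 sigma^2 tau/T, Var(var) = 4 sigma^4 tau/T
  se_mean <- stats::sd(bm) / sqrt(nb)
  se_var <- stats::sd(bv) / sqrt(nb)
  Tspan <- n * dt
  if (is.finite(lam) && lam > 0) {
    se_mean <- max(se_mean, sqrt(2 * var_xi / (lam * Tspan)))
    se_var <- max(se_var, 2 * var_xi / sqrt(lam * Tspan))
  }
  neff <- if (is.finite(lam) && lam > 0) n * dt * lam else n
  if (neff < 100)
    warning("fewer than 100 effectively independent samples; ",
            "estimates are imprecise")
  ml <- colMeans(sim$levels[keep, , drop = FALSE])
  structure(list(mean_xi_a = mean_xi, se_mean = se_mean,
                 var_xi_a = var_xi, se_var = se_var,
                 sd_xi_a = sqrt(var_xi),
                 mean_levels = ml, autocorr_rate = lam,
                 n_samples = n, n_blocks = nb),
            class = "bl_summary")
}

#' @export
print.bl_summary <- function(x, ...) {
  cat(sprintf("steady state: <xi_a> = %.5f +/- %.5f, var = %.3g +/- %.3g (sd = %.4g)\n",
              x$mean_xi_a, x$se_mean, x$var_xi_a, x$se_var, x$sd_xi_a))
  cat("  mean level fractions:",
      paste(sprintf("%s=%.4f", names(x$mean_levels), x$mean_levels),
            collapse = ", "), "\n")
  cat(sprintf("  lambda_xi = %.4g 1/s, %d samples in %d blocks\n",
              x$autocorr_rate, x$n_samples, x$n_blocks))
  invisible(x)
}

#' Parameter sweep of stochastic simulations
#'
#' Runs one simulation per grid value of a single varied parameter and
#' tabulates the steady-state summaries.  Per-point seeds are derived
#' deterministically from the master seed in \code{config}.
#'
#' @param params template \code{\link{bl_params}}.
#' @param vary one of \code{"R0"}, \code{"ell"}, \code{"A0"}, \code{"M"}.
#' @param grid numeric vector of values for the varied parameter.
#' @param config a \code{\link{sim_config}}; its seed is the master seed.
#' @param k_minus,k_minus_p,k_d unbinding rates forwarded to
#'   \code{\link{kinetic_rates}} for every point (larger values push the
#'   network deeper into the fast-binding regime the reduction assumes,
#'   at proportional simulation cost).
#' @param file optional CSV output path.
#' @return data frame with the grid value, mean/var of the active fraction
#'   with standard errors, per-level means (columns \code{m0..}, padded
#'   with NA across different M), \code{lambda_xi} and the per-point seed.
#'   Failed points are kept as NA rows with the error message in
#'   \code{error}.
#' @export
sweep_ssa <- function(params, vary = c("R0", "ell", "A0", "M"), grid,
                      config = sim_config(), k_minus = 10, k_minus_p = 10,
                      k_d = 100, file = NULL) {
  vary <- match.arg(vary)
  stopifnot(length(grid) > 0)
  rows <- lapply(seq_along(grid), function(i) {
    seed_i <- (config$seed * 1009L + i * 9973L) %% .Machine$integer.max
    base <- data.frame(value = grid[i], seed = seed_i, error = NA_character_)
    names(base)[1] <- vary
    res <- tryCatch({
      p <- switch(vary,
        R0 = update_params(params, R0 = grid[i]),
        ell = update_params(params, L = grid[i] * params$KL),
        A0 = update_params(params, A0 = grid[i]),
        M = update_params(params, M = as.integer(grid[i])))
      cfg <- config; cfg$seed <- as.integer(seed_i)
      net <- build_network(p, kinetic_rates(p, k_minus = k_minus,
                                            k_minus_p = k_minus_p, k_d = k_d))
      s <- summarize_trajectory(simulate_bl(p, cfg, network = net))
      lev <- as.list(s$mean_levels)
      cbind(base,
            data.frame(mean_xi_a = s$mean_xi_a, se_mean = s$se_mean,
                       var_xi_a = s$var_xi_a, se_var = s$se_var,
                       lambda_xi = s$autocorr_rate),
            as.data.frame(lev))
    }, error = function(e) {
      base$error <- conditionMessage(e)
      base
    })
    res
  })
  # pad columns across rows (e.g. differing M)
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    r[cols]
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
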