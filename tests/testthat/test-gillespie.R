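test_that("simulation config validates its time windows", {
  expect_error(sim_config(t_burn = 100, t_total = 50), "t_total > t_burn")
  expect_error(sim_config(sample_dt = 0), "sample_dt")
})

test_that("trajectories are reproducible and conserve receptors", {
  p <- bl_params(A0 = 2, R0 = 0.224, L = 0.02)
  cfg <- sim_config(seed = 11, t_burn = 20, t_total = 120)
  s1 <- simulate_bl(p, cfg)
  s2 <- simulate_bl(p, cfg)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_bl(p, sim_config(seed = 12, t_burn = 20, t_total = 120))
  expect_false(identical(s1$counts, s3$counts))
  net <- build_network(p)
  tot <- rowSums(s1$counts[, net$species$name])
  expect_true(all(tot == receptor_count(p)))
  nR <- s1$counts[, "Rf"] + rowSums(s1$counts[, grep("\\.R$", colnames(s1$counts)), drop = FALSE])
  nB <- s1$counts[, "Bf"] + rowSums(s1$counts[, grep("\\.B$", colnames(s1$counts)), drop = FALSE])
  expect_true(all(nR == nR[1]) && all(nB == nB[1]))
  expect_true(all(s1$xi_a >= 0 & s1$xi_a <= 1))
  expect_true(all(abs(rowSums(s1$levels) - 1) < 1e-12))
})

test_that("no enzymes means a frozen all-unmethylated trajectory", {
  p <- bl_params(A0 = 2, R0 = 0, B0 = 1e-9, L = 0.02)
  net <- build_network(p)
  net$init["Bf"] <- 0L
  sim <- simulate_bl(p, sim_config(seed = 3, t_burn = 5, t_total = 60),
                     network = net)
  expect_true(all(sim$counts[, "m0"] == receptor_count(p)))
  expect_true(all(sim$xi_a == 0))
})

test_that("binding equilibria honour the dissociation constants", {
  # catalysis switched (effectively) off: each enzyme-receptor pair must
  # equilibrate to the occupancy set by its dissociation constant
  p <- bl_params(A0 = 5.3, R0 = 0.5, B0 = 0.5, L = 0,
                 nu_r = 1e-12, nu_b = 1e-12)
  net <- build_network(p, kinetic_rates(p, check = FALSE))
  # start with half the receptors at the top level so CheB has substrate
  N <- receptor_count(p)
  net$init["m0"] <- N %/% 2L
  net$init["m2a"] <- N - N %/% 2L
  sim <- simulate_bl(p, sim_config(seed = 5, t_burn = 50, t_total = 450),
                     network = net)
  keep <- sim$time >= 50
  # expected occupancy from mass action with free-enzyme depletion:
  # bound/free receptor ratio = [Ef]/K at the self-consistent [Ef]
  occR <- mean(sim$counts[keep, "m0.R"]) /
    (mean(sim$counts[keep, "m0.R"]) + mean(sim$counts[keep, "m0"]))
  Rf_mean <- mean(sim$counts[keep, "Rf"]) / p$conversion
  expect_equal(occR, Rf_mean / (Rf_mean + p$Kr), tolerance = 0.05)
  occB <- mean(sim$counts[keep, "m2a.B"]) /
    (mean(sim$counts[keep, "m2a.B"]) + mean(sim$counts[keep, "m2a"]))
  Bf_mean <- mean(sim$counts[keep, "Bf"]) / p$conversion
  expect_equal(occB, Bf_mean / (Bf_mean + p$Kb), tolerance = 0.05)
})

test_that("steady-state summary agrees with the analytical layer", {
  # at the critical point both enzymes are dilute (Rf << Kr, Bf << Kb),
  # where the quasi-steady-state reduction describes the network best
  p <- bl_params(A0 = 5.3, R0 = 0.224, L = 0.02)
  sim <- simulate_bl(p, sim_config(seed = 21, t_burn = 400, t_total = 2400))
  s <- suppressWarnings(summarize_trajectory(sim))
  lna <- bl_lna(p, mode = "exact")
  expect_lt(abs(s$mean_xi_a - lna$fp$xi_a), 3 * s$se_mean)
  expect_lt(abs(s$var_xi_a - lna$sigma_a2), 3 * s$se_var)
  expect_equal(sum(s$mean_levels), 1, tolerance = 1e-12)
  expect_gt(s$autocorr_rate, 0)
})

test_that("the mean active fraction does not depend on ligand level", {
  p <- bl_params(A0 = 5.3, R0 = 0.26)
  cfg <- sim_config(seed = 31, t_burn = 400, t_total = 1600)
  s_lo <- suppressWarnings(
    summarize_trajectory(simulate_bl(update_params(p, L = 0.002), cfg)))
  s_hi <- suppressWarnings(
    summarize_trajectory(simulate_bl(update_params(p, L = 200), cfg)))
  z <- (s_lo$mean_xi_a - s_hi$mean_xi_a) /
    sqrt(s_lo$se_mean^2 + s_hi$se_mean^2)
  expect_lt(abs(z), 3)
})

test_that("sweeps record failures without aborting and write CSV", {
  p <- bl_params(A0 = 2, R0 = 0.224, L = 0.02)
  f <- withr::local_tempfile(fileext = ".csv")
  cfg <- sim_config(seed = 8, t_burn = 10, t_total = 80)
  sw <- suppressWarnings(
    sweep_ssa(p, vary = "R0", grid = c(0.1, -1, 0.3), config = cfg, file = f))
  expect_identical(nrow(sw), 3L)
  expect_true(is.na(sw$error[1]) && !is.na(sw$error[2]) && is.na(sw$error[3]))
  expect_true(file.exists(f))
  # same master seed reproduces the sweep bit-identically
  sw2 <- suppressWarnings(
    sweep_ssa(p, vary = "R0", grid = c(0.1, -1, 0.3), config = cfg))
  expect_equal(sw[, setdiff(names(sw), "error")],
               sw2[, setdiff(names(sw2), "error")], tolerance = 0)
})
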