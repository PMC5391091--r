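test_that("beta matches a finite-difference Jacobian of the drift", {
  p <- table_params()
  for (mode in c("simplified", "full")) {
    drift_mode <- if (mode == "simplified") "linearized" else "saturating"
    fp <- solve_fixed_point(p, mode = drift_mode)
    beta <- beta_matrix(fp, p, mode = mode)
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- 1e-7
      xp <- as.numeric(fp$xi); xm <- xp
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      J[, j] <- (bl_drift(xp, p, drift_mode) - bl_drift(xm, p, drift_mode)) /
        (2 * h)
    }
    expect_equal(beta, J, tolerance = 1e-6)
    # stability at the default operating point
    expect_true(all(Re(eigen(beta, only.values = TRUE)$values) < 0))
  }
})

test_that("gamma matches a finite difference in ligand concentration", {
  p <- table_params()
  fp <- solve_fixed_point(p, mode = "linearized")
  g <- gamma_vector(fp, p)
  h <- 1e-6
  gd <- (bl_drift(as.numeric(fp$xi), update_params(p, L = p$L + h), "linearized") -
         bl_drift(as.numeric(fp$xi), update_params(p, L = p$L - h), "linearized")) /
    (2 * h)
  expect_equal(g, unname(gd), tolerance = 1e-6)
  # empty intermediate level: no direct ligand coupling
  p2 <- table_params()
  fp2 <- solve_fixed_point(p2, mode = "linearized")
  fp2$xi <- c(xi0 = 0.4, xi2 = 0.6)
  part <- blswitch:::simplified_partials(as.numeric(fp2$xi), p2)
  expect_equal(part$dv_dL, c(0, 0))
  # no catalysis, no response
  p0 <- update_params(p, nu_r = 1e-300, nu_b = 1e-300)
  fp0 <- solve_fixed_point(p0, mode = "linearized")
  expect_equal(gamma_vector(fp0, p0), c(0, 0), tolerance = 1e-290)
})

test_that("closed-form covariance solves the Lyapunov equation", {
  # decoupled Ornstein-Uhlenbeck limit
  beta <- diag(c(-2, -0.5))
  D <- c(0.3, 0.1)
  s <- stationary_covariance(beta, D)
  expect_equal(s, matrix(c(0.15, 0, 0, 0.2), 2, 2,
                         dimnames = dimnames(s)))
  # generic stable systems against an independent kronecker solve
  set.seed(404)
  n_ok <- 0
  while (n_ok < 100) {
    b <- matrix(rnorm(4, sd = 2), 2, 2)
    if (any(Re(eigen(b, only.values = TRUE)$values) >= -1e-3)) next
    n_ok <- n_ok + 1
    D <- runif(2, 0.01, 1)
    expect_equal(stationary_covariance(b, D), lyapunov_oracle(b, D),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # unstable input is refused
  expect_error(stationary_covariance(matrix(c(1, 0, 0, -1), 2, 2), c(1, 1)),
               "Hurwitz")
})

test_that("covariance matches a simulated linear SDE", {
  # Euler-Maruyama ensemble of the linearised dynamics, vectorised over
  # replicas; the stationary covariance must sit within 3 standard errors
  beta <- matrix(c(-1, 0.3, 0.2, -0.8), 2, 2, byrow = TRUE)
  D <- c(0.5, 0.3)
  target <- stationary_covariance(beta, D)
  set.seed(99)
  nrep <- 4000; dt <- 0.004; nstep <- 3000
  X <- matrix(0, 2, nrep)
  sq <- sqrt(2 * D * dt)
  samples <- list()
  for (k in seq_len(nstep)) {
    X <- X + beta %*% X * dt + sq * matrix(rnorm(2 * nrep), 2, nrep)
    if (k %in% c(2000, 2500, 3000)) samples[[length(samples) + 1]] <- X
  }
  S <- do.call(cbind, samples)
  est <- tcrossprod(S) / ncol(S)
  se <- sqrt(2 / ncol(S)) * sqrt(diag(target) %o% diag(target))
  expect_true(all(abs(est - target) < 3 * se + 0.01 * max(target)))
})

test_that("activity variance combines the covariances correctly", {
  p <- table_params()
  s <- matrix(c(3e-4, -5e-5, -5e-5, 2e-4), 2, 2)
  expect_equal(activity_variance(s, update_params(p, L = 0)), s[1, 1])
  expect_equal(activity_variance(s, update_params(p, L = 1e12)), s[2, 2],
               tolerance = 1e-9)
  sflat <- matrix(2e-4, 2, 2)
  l <- ell(p)
  expect_equal(activity_variance(sflat, p), 2e-4 * (1 - l)^2 / (1 + l)^2)
})

test_that("activity variance scales inversely with receptor number", {
  # conversion factors chosen so both receptor counts are exact integers
  p <- update_params(table_params(), conversion = 500)
  v1 <- bl_lna(p)$sigma_a2
  v2 <- bl_lna(update_params(p, conversion = 1000))$sigma_a2
  expect_equal(v2 / v1, 0.5, tolerance = 1e-6)
})

test_that("variance profile peaks at the critical point for every ligand level", {
  p <- table_params()
  R0g <- seq(0.19, 0.26, by = 0.005)
  vp <- variance_profile(p, R0g, c(0.2, 2, 20))
  expect_true(all(abs(vp$peaks$R0_peak - critical_R0(p)) <= 0.005 + 1e-12))
  # sigma00 peak decreasing in ell, sigma22 peak increasing,
  # sigma02 negative near the critical point
  by_ell <- split(vp$table, vp$table$ell)
  pk00 <- vapply(by_ell, function(d) max(d$sigma00), numeric(1))
  pk22 <- vapply(by_ell, function(d) max(d$sigma22), numeric(1))
  expect_true(all(diff(pk00) < 0))
  expect_true(all(diff(pk22) > 0))
  near_crit <- vp$table[abs(vp$table$R0 - critical_R0(p)) <= 0.01, ]
  expect_true(all(near_crit$sigma02 <= 0))
  # peak variance shrinks with receptor number at fixed ell
  pks <- vapply(c(5.3, 27.2), function(A0)
    variance_profile(update_params(p, A0 = A0), R0g, 20)$peaks$sigma_a2_peak,
    numeric(1))
  expect_lt(pks[2], pks[1])
})

test_that("activity noise stays near 1e-2 across ligand levels at the critical point", {
  p <- update_params(table_params(), R0 = critical_R0(table_params()))
  # the LNA of the simulated (saturating) kinetics; the simplified printed
  # layer overshoots this by the dropped O(Rf/Kr) terms near criticality
  for (l in c(0.02, 2, 2000)) {
    sa <- sqrt(bl_lna(update_params(p, L = l * p$KL), mode = "full")$sigma_a2)
    expect_gt(sa, 0.5e-2)
    expect_lt(sa, 2e-2)
  }
})
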