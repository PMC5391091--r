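# Shared fixtures: the default E. coli parameter set and a deterministic
# generator of random-but-valid parameter draws for property tests.

table_params <- function(...) bl_params(...)

random_params <- function(rng_seed) {
  set.seed(rng_seed)
  bl_params(
    A0 = runif(1, 4, 30),
    R0 = runif(1, 0.05, 0.6),
    B0 = runif(1, 0.1, 0.6),
    Kr = runif(1, 0.2, 1),
    Kb = runif(1, 0.2, 1),
    KL = runif(1, 0.05, 0.5),
    nu_r = runif(1, 0.2, 1.5),
    nu_b = runif(1, 0.2, 1.5),
    L = runif(1, 0, 10))
}

# independent generic Lyapunov solver (vectorised Kronecker form) used as
# the oracle against the closed-form stationary covariance
lyapunov_oracle <- function(beta, D) {
  K <- kronecker(diag(2), beta) + kronecker(beta, diag(2))
  matrix(solve(K, -2 * as.numeric(diag(D))), 2, 2)
}
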