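# blswitch

Zero-order ultrasensitivity and intrinsic noise in the Barkai–Leibler
(BL) model of *E. coli* chemotaxis receptors.

## The problem

Chemotaxis receptors in *E. coli* are methylated by CheR (which binds
only inactive receptors) and demethylated by CheB (which binds only
active ones); attractant binding inactivates the partially methylated
states. These rules give robust, perfect adaptation: the steady-state
kinase activity is independent of the ambient attractant level. Because
the antagonistic enzyme pair operates on a saturating receptor pool, the
circuit is also a covalent-modification cycle in the Goldbeter–Koshland
sense: the mean active fraction `ξ_a` switches ultrasensitively at

```
α = R0·νr / (B0·νb) = 1
```

and the *fluctuations* of `ξ_a` — which drive the flagellar motor's
run/tumble switching through CheY-P and a Hill response with coefficient
H ≈ 20 — peak at that transition. `blswitch` provides, for anyone
studying this circuit quantitatively:

* the full stochastic reaction network for any number of methylation
  sites `M` (4M conformations, 5M−1 reactions) and an exact Gillespie
  simulator (compiled, ~2×10⁷ events/s, bit-reproducible by seed);
* the quasi-steady-state reduction for `M = 2`: drift/diffusion of the
  level fractions, self-consistent free enzymes, fixed points, the
  ligand-independent closed form for `ξ_a*`, and the ultrasensitive
  limits;
* the linear-noise approximation: Jacobian, ligand sensitivity, Lyapunov
  covariance in closed form, and the activity variance
  `σ_a² = (σ00 + ℓ²σ22 − 2ℓσ02)/(1+ℓ)²`;
* linear response to time-dependent attractant changes, including the
  bilobed clockwise-bias response `χ_b(t)` in three-exponential closed
  form;
* the downstream pathway: CheY-P mean and noise, motor clockwise bias,
  the fluctuation bound `δP_CW ≤ H·σ_Y/(4K_Y)`, and the motor-adaptation
  correction, with the three standard literature parameter sets built in.

## Worked example

```r
library(blswitch)
p <- bl_params()          # E. coli set: B0=0.28, Kr=0.39, Kb=0.54, KL=0.1,
print(p)                  # nu_r=0.75, nu_b=0.6; A0=13.6 uM, ell=20
#> BL model parameters (M = 2 methylation sites)
#>   A0 = 13.6 uM (N = 8191 receptors), R0 = 0.224 uM, B0 = 0.28 uM
#>   Kr = 0.39, Kb = 0.54, KL = 0.1 uM; nu_r = 0.75, nu_b = 0.6 1/s
#>   L = 2 uM (ell = 20); alpha = 1

critical_R0(p)            # CheR level at the ultrasensitive transition
#> [1] 0.224

solve_fixed_point(p)      # deterministic steady state
#> BL fixed point (saturating): xi* = (0.0154519, 0.433357, 0.551191), xi_a* = 0.571827
#>   Rf* = 0.0140605 uM, Bf* = 0.01818 uM, |drift| = 7.9e-14

sqrt(bl_lna(p, mode = "exact")$sigma_a2)   # activity noise at the transition
#> [1] 0.01961525

sim <- simulate_bl(bl_params(A0 = 5.3, R0 = 0.224, L = 0.02),
                   sim_config(seed = 42, t_burn = 400, t_total = 2400))
summarize_trajectory(sim)
#> steady state: <xi_a> = 0.56699 +/- 0.00455, var = 0.000298 +/- 1.83e-05 (sd = 0.01727)
#>   mean level fractions: m0=0.3429, m1=0.5384, m2=0.1186
#>   lambda_xi = 0.003026 1/s, 4001 samples in 8 blocks
```

Reading this: at the critical CheR level the mean activity sits near
0.57 (and stays there across five decades of attractant — perfect
adaptation), while its standard deviation is of order 10⁻², the noise
level that, pushed through CheY-P, is large enough to move the motor's
clockwise bias appreciably:

```r
mot <- motor_params_literature("morton_firth")
sigma_a_range(0.09, 0.22, mot, bl_params(A0 = 5))  # activity noise implied
#>         low        high                            # by measured CheY-P noise
#> 0.004716667 0.011529630
delta_pcw_bound(0.22, motor_params(H = 20, K_Y = 3))$bound
#> [1] 0.3666667                                      # max CW-bias fluctuation
```

A thin command-line front end over the same functions lives in
`inst/cli/blswitch.R` (subcommands `simulate`, `sweep`, `lna`,
`response`, `motor`).

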