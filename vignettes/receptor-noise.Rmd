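---
title: "Ultrasensitivity and intrinsic noise in chemotaxis receptor methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasensitivity and intrinsic noise in chemotaxis receptor methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blswitch)
```

## The model

`blswitch` implements a stochastic version of the Barkai–Leibler (BL)
scheme for the methylation dynamics of *E. coli* chemotaxis receptors. A
receptor (in complex with CheW/CheA) carries `M` methylation sites and is,
at any instant, either kinase-active or inactive. Three rules generate the
dynamics:

* the methyltransferase CheR binds only *inactive* receptors and, once
  bound, methylates them at rate $\nu_r$;
* the methylesterase CheB binds only *active* receptors and demethylates
  them at rate $\nu_b$;
* attractant (ligand) binding inactivates a receptor at the intermediate
  methylation levels; the lowest level is always inactive, the highest
  always active.

Binding and unbinding (of both enzymes and ligand) are fast compared with
catalysis, so on the slow time scale each methylation level is an
equilibrated "module" and the state is summarised by the level fractions
$\xi_m$. Activity of level $m$ follows
$a_m(L) = a_m(0)\,K_m/(L+K_m)$ with the ideal conventions $K_0 = 0$ and
$K_M = \infty$. Two conventions for the intermediate levels are provided
(`activity_probability()`): the default **ligation split** ($a_m(0)=1$,
one active-unligated and one inactive-ligated conformation per
intermediate level, $K_m = K_L$), which is what the discrete reaction
network realises and what produces the standard conformation/reaction
counting ($4M$ species, $5M-1$ reactions); and an optional **graded**
convention $a_m(0)=m/M$. The two coincide for the quantities this package
computes at $M=2$; they differ for $M>2$, where the literature is not
internally consistent about the zero-ligand activity of intermediate
levels, and we treat the ligation split as canonical because it matches
that counting.

The antagonistic enzyme pair makes the scheme a covalent-modification
cycle in the sense of Goldbeter and Koshland: when the receptor pool
saturates both enzymes ($A_0 \to \infty$), the mean active fraction
switches ultrasensitively at the critical enzyme-activity ratio

$$\alpha = \frac{R_0\,\nu_r}{B_0\,\nu_b} = 1,$$

which for the default parameter set puts the critical CheR concentration
at `critical_R0(bl_params())` = 0.224 µM. In the limits $\ell = L/K_L \to
0$ and $\ell \to \infty$ the three-level ($M=2$) system reduces to two
different two-level Goldbeter–Koshland modules (`zou_limits()`).

## Parameters

`bl_params()` carries the full parameter set with these defaults (µM and
s⁻¹): $B_0 = 0.28$, $K_r = 0.39$, $K_b = 0.54$, $K_L = 0.1$,
$\nu_r = 0.75$, $\nu_b = 0.6$, cell volume $10^{-15}$ L (602.3 molecules
per µM), $A_0 = 13.6$, $R_0 = 0.224$ (the critical point) and $\ell = 20$.
These are the values commonly used for the aspartate receptor system;
$A_0$ is experimentally varied in the 5.3–27.2 µM range and $R_0$ over
10⁻²–10 µM to scan the transition, which the sweep helpers reproduce.
The dissociation constants fix only rate *ratios*; the individual off
rates default to $k_- = k'_- = 10\,\mathrm{s^{-1}}$ and
$k_d = 100\,\mathrm{s^{-1}}$ (`kinetic_rates()`), which keeps every
binding step at least an order of magnitude faster than catalysis (the
time-scale separation the reduction assumes) while keeping the exact
simulation affordable. All are overridable; the quasi-steady-state
observables are insensitive to them by construction.

## The quasi-steady-state layer and its three modes

Integrating out the fast binding degrees of freedom leaves a
two-dimensional drift for $(\xi_0,\xi_2)$ driven by the enzyme occupancy
factors and the self-consistent free-enzyme concentrations. Three
consistent closures are exposed, because they matter at different places:

* **saturating** (default for `bl_drift()`/`solve_fixed_point()`): full
  Michaelis factors $R_f/(R_f+K_r)$ with the closed-form free-enzyme
  expressions; this is the form in which the reduction is usually written;
* **linearized**: the $R_f \ll K_r$, $B_f \ll K_b$ form in which the
  analytic fixed point, Jacobian and ligand-sensitivity formulas are
  derived. `bl_lna(mode = "simplified")` evaluates those closed forms
  at the linearized fixed point so that the triple (fixed point, $\beta$,
  $\gamma$) is exactly self-consistent — this is what makes the
  perfect-adaptation identities below hold to machine precision;
* **exact**: full Michaelis factors *and* the saturating enzyme
  conservation law $R_f + A_0\,\tilde x(R_f) = R_0$ solved as a quadratic.
  This is the true deterministic limit of the simulated network and the
  right reference when comparing against the Gillespie simulator: at the
  default operating point $R_f^*/K_r \approx 0.04$, and above the critical
  point the dropped terms shift the mean by a few percent — clearly
  visible at simulation precision.

The fixed point is found by damped self-consistent iteration (damping 0.5,
tolerance $10^{-12}$ on the update norm) of the stationarity relations
$\xi_0 = 1/[(1+\rho)(1+\rho\ell)]$,
$\xi_2 = \rho^2\ell/[(1+\rho)(1+\rho\ell)]$ with
$\rho = \nu_r\tilde R/\nu_b\tilde B$ refreshed from the current iterate;
a `deSolve` integration of the mean-field equations is the fall-back for
the rare non-contracting cases, and the result always satisfies
$\|v(\xi^*)\| < 10^{-10}\,\mathrm{s^{-1}}$.

**Perfect adaptation.** In every mode the stationary active fraction
$\xi_a^* $ is independent of the ligand level — the structural property of
the BL rules. In the linearized regime it solves the ligand-free quadratic

$$A_0(\nu_bB_0-\nu_rR_0)\,\xi_a^{*2}
  + [\nu_rR_0(A_0-K_b)-\nu_bB_0(K_r+A_0)]\,\xi_a^*
  + \nu_rR_0K_b = 0,$$

re-derived here from the flux-balance and conservation relations (the
placement of $A_0$ on the quadratic coefficient is required by
dimensional consistency; `perfect_adaptation_xa()` is verified against the
solver rather than transcribed). At $\alpha = 1$ the root is
$K_b/(K_b+K_r)$, independent of $A_0$.

## Noise: linear-noise approximation

Fluctuations around the fixed point are Gaussian at leading order in
$1/N$ ($N = A_0 V$ receptors), with stationary covariance solving the
Lyapunov equation $\beta\sigma + \sigma\beta^T + 2D = 0$;
`stationary_covariance()` implements the 2×2 closed form and is tested
against an independent Kronecker-product solve and against simulated
linear SDE ensembles. The activity variance is

$$\sigma_a^2 = \frac{\sigma_{00} + \ell^2\sigma_{22} - 2\ell\sigma_{02}}
                    {(1+\ell)^2},$$

which peaks in $R_0$ at the ultrasensitive transition and scales as $1/N$.
Swept over ligand (`variance_profile()`), the peak-over-$R_0$ is a
non-monotonic function of $\ell$, shaped by the negative covariance
$\sigma_{02}$ between the two outer levels; with the default parameter
set the valley of the peak lies near $\ell \approx 1$–2: its continuous
minimum sits at $\ell \approx 0.9$, just below the coarse log-grid point
at 1, and the valley is shallow enough that anywhere in roughly
$\ell \in [1, 4]$ is consistent within its width. At
the critical point $\sigma_a \approx 1\text{–}2\times10^{-2}$ across at
least five decades of $\ell$.

## Exact stochastic simulation

`simulate_bl()` runs the Gillespie direct method on the full network
(compiled; roughly $2\times10^7$ events/s), with free CheR/CheB as
discrete molecules (`round(R0*conversion)` etc., at least one molecule),
ligand as a constant external concentration folded into the binding
propensity, and R's RNG so that a seed fixes the trajectory bit-for-bit.
All receptors start unmethylated, unbound and inactive. Catalytic
products enter the unligated conformation of the destination level;
under the fast-binding assumption the observables are insensitive to this
convention, but it is fixed and documented for reproducibility.

`summarize_trajectory()` discards the burn-in, fits the exponential decay
rate $\lambda_\xi$ of the activity autocorrelation, and reports
blocking standard errors (block length at least 20 correlation times when
the series allows it; a warning is issued below ~100 effective samples).
Near the critical point the slow relaxation rate is of order
$2\times10^{-3}\,\mathrm{s^{-1}}$ for $A_0 = 13.6$ µM, i.e. correlation
times of ~500 s. Two practical consequences, both sized into the test
suite as the package's own precision/cost trade-off: the burn-in must
cover many correlation times (4 000 s there — shorter burn-ins leave a
transient from the all-unmethylated start that visibly inflates the
variance), and variance estimation needs several $10^4$ s of simulated
time (12 000–44 000 s depending on how close the measured value sits to
the claim being tested; runs at smaller $A_0$, where relaxation is ~5×
faster, use proportionally less).

Two further facts about simulation-vs-theory comparisons, measured while
validating the package: (i) at the default off-rates the binding/catalysis
time-scale separation is only ~13×, and the simulated transition is
slightly smoother than the quasi-steady-state prediction (mean shifts up
to ~0.01 near enzyme saturation); raising the off-rates to
$k_- = 40\,\mathrm{s^{-1}}$, $k_d = 400\,\mathrm{s^{-1}}$ — the regime
the reduction actually assumes — removes the shift, which is why
`compare_lna_ssa()` exposes the off-rates and the agreement test runs
there. (ii) at $A_0 = 13.6$ µM the linear-noise variance underestimates
the simulated one by ~30–50% right at the critical point (fluctuations
there are large and the linearisation is at its weakest); at
$A_0 = 5.3$ µM prediction and simulation agree within errors.

What the simulator emulates — and what it does not: it is a well-mixed,
single-cell, fixed-ligand model. Receptor clustering and allosteric
coupling, CheB phosphorylation feedback, CheZ localisation, spatial
gradients and run-and-tumble motion are all outside its scope;
consequently, agreement between the simulator and the analytics validates
the reduction and the noise theory, not those omitted mechanisms, and
measured cellular noise can differ where clustering or enzyme
localisation matter.

## Linear response and the motor

For a small time-dependent ligand change, the mean activity responds
through the linearised dynamics plus an instantaneous ligand-occupancy
term; `chi_a_laplace()` gives the frequency-domain response with
$\tilde\chi_a(0) = 0$ (zero enclosed area — the response-function face of
perfect adaptation), and `step_response()` the time domain. The
clockwise-bias response `chi_b_time()` filters $\chi_a$ through CheY-P
turnover ($\lambda_Y = 30\,\mathrm{s^{-1}}$, Hill coefficient $H = 20$,
operating bias 0.5 by default) and is evaluated as a three-exponential
closed form whose coefficients are obtained here by partial fractions of
$\tilde\chi_a(s)/(s+\lambda_Y)$ (the residue denominators must be
$(A-\lambda_Y)(B-\lambda_Y)$ etc., with $-A$, $-B$ the eigenvalues of
$\beta$; complex-conjugate pairs are evaluated in complex arithmetic and
the real part returned, and degenerate rates fall back to a numerical
convolution). Sign convention: the curve is the response to a unit
*increase* in attractant, so the sharp early lobe is negative (ligation
suppresses activity and hence tumbling) and the slow methylation recovery
carries the opposite-signed late lobe; the total area is zero, and the
negative-lobe depth shrinks as the ambient ligand level grows.

The motor layer propagates activity noise downstream:
$Y^* = a_YY_0A_0\xi_a^*/\lambda_Y$,
$\sigma_Y = a_YY_0A_0\,\sigma_a/\sqrt{\lambda_Y(\lambda_Y+\lambda_\xi)}$
(saturating the slow-fluctuation bound at $\lambda_\xi = 0$, the default;
set `lambda_xi` from a fitted `autocorr_rate` to tighten it), the steep
Hill clockwise bias, and the fluctuation bound
$\delta P_{CW} \le H\sigma_Y/(4K_Y)$. That bound uses the asymptotic peak
value 1/4 of the Hill-slope factor; the exact maximum is
$(1/4)(1+O(H^{-2}))$ — 0.3% higher at $H=20$ — attained at
$\tilde y = [(H-1)/(H+1)]^{1/H}$, which is why the package exposes both
the bound and the exact slope (`delta_pcw()`). Motor-level adaptation
(rate $\lambda_m = 0.0167\,\mathrm{s^{-1}}$, adapted Hill coefficient
$H_a = 10$) modifies the fluctuation by a factor
$\sqrt{1-(\lambda_m/\lambda_Y)r(1-r)}$ with $r$ the adapted/non-adapted
slope ratio: within the sensitive CheY-P window (~2.5–4 µM) the correction
stays below 2%, and it grows outside it.

## Numerical choices, degenerate inputs, limitations

* $R_0 = 0$ (or a vanishing occupancy factor) short-circuits the
  fixed-point iteration to the appropriate boundary ($\xi = (1,0)$ etc.).
* A zero total propensity in the simulator is an absorbing state, not an
  error; remaining samples repeat the frozen state.
* Hill functions are evaluated in log space so $H$ in the thousands does
  not overflow.
* Finite-difference Jacobians use central differences with relative step
  $10^{-7}$.
* Per-point sweep seeds are derived affinely from the master seed, so a
  sweep is reproducible as a whole and each point individually.
* The analytic layer exists for $M = 2$ only; $M = 3, 4$ are simulation
  territory (their network construction and conservation laws are tested,
  and their qualitative behaviour — sharper mean transition, smaller
  variance for larger $M$ — matches the two-site analytics).
* The mean of the stochastic process differs from the deterministic fixed
  point at order $1/N$ and, in the strongly zero-order (enzyme-saturated)
  regime, by finite time-scale-separation corrections of order
  $\nu/k_-$; both are visible above the critical point at sub-percent
  statistics. The `exact` mode captures the deterministic part of this;
  the residual is a genuine limitation of any quasi-steady-state
  treatment.

## A worked pipeline

```{r pipeline, eval = FALSE}
p <- bl_params()                      # critical point, ell = 20
fp <- solve_fixed_point(p)            # xi_a* ~ 0.572 (saturating mode)
lna <- bl_lna(p, mode = "exact")      # sigma_a ~ 0.016 at N = 8191
sim <- simulate_bl(p, sim_config(seed = 1, t_burn = 1000, t_total = 7000))
summarize_trajectory(sim)             # mean/var with blocking SEs
m <- response_model(update_params(p, L = 0.02))
chi_b_time(c(0.1, 1, 10), m)          # bilobed bias response
mot <- motor_params_literature("morton_firth")
sigma_a_range(0.09, 0.22, mot, bl_params(A0 = 5))
```
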