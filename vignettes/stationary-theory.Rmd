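---
title: "Stationary theory of correlated colored-noise synchronization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stationary theory of correlated colored-noise synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(corrsync)
```

## The model

Two regularly firing neurons that share part of their synaptic input can
synchronize without any direct coupling. `corrsync` studies this mechanism
for *heterogeneous* pairs: oscillators that differ in their phase-response
curves (PRCs) and, slightly, in their firing frequencies, driven by
partially correlated low-pass-filtered (Ornstein-Uhlenbeck, OU) noise.

After phase reduction, each cell is a phase $\theta_j \in [0, 2\pi)$
advancing at unit speed and nudged by its input in proportion to its PRC
$\Delta_j(\theta)$:

$$
\theta_1' = 1 + \epsilon \Delta_1(\theta_1)\, z_x(t), \qquad
\theta_2' = 1 + \epsilon \Delta_2(\theta_2)\, z_y(t) + \epsilon^2 \omega ,
$$

where $z_x, z_y$ are OU processes with common time constant $\tau$ and
input correlation $c \in [0, 1]$, $\epsilon \ll 1$ is the noise magnitude,
and $\omega$ measures the frequency difference. The detuning enters at
order $\epsilon^2$ deliberately: the *variance* of the noise is
$O(\epsilon^2)$, so this is the regime in which synchronizing drive and
detuning compete; larger frequency differences preclude locking entirely.

Two conventions are worth stating explicitly because they fix every
numerical factor in the package:

* **PRC correlations are averaged, not integrated.** The phase functions
  $h_{nm}(\phi) = \frac{1}{2\pi}\int_0^{2\pi}
  \Delta_n(\theta)\Delta_m(\theta + \phi)\,d\theta$ carry a $1/2\pi$
  prefactor, so for $\Delta = -\sin\theta$, $h(\phi) = \cos(\phi)/2$.
* **The drive has $\tau$-independent power.** The OU process in the raw
  parameterization $x' = -x/\tau + \xi/\tau$ has stationary variance
  $1/(2\tau)$, which would make the input power collapse as the noise gets
  slower. The phase and biophysical simulators therefore drive with the
  variance-normalized process $z = \sqrt{\tau}\,x$ (variance $1/2$ for
  every $\tau$), and the analytical coefficients below are derived for
  that drive. At $\tau = 1$ the two parameterizations coincide. This
  choice is forced by the physics the package reproduces: with
  $\tau$-decaying input power there is no resonance of synchrony in
  $\tau$ for detuned pairs, whereas with fixed input power the
  detuning-to-transport ratio scales as $(1 + \tau^2)/\tau$ and is
  minimal at $\tau = 1$ — precisely the resonance the boundary value
  problem and the Monte Carlo simulations both exhibit.

## The stationary phase-difference density

The observable of interest is the stationary density $R(\phi)$ of the
phase difference $\phi = \theta_2 - \theta_1$. Averaging over the fast
phase and the noise turns the pair into a one-dimensional stationary
flux balance, a first-order periodic boundary value problem:

$$
\frac{d}{d\phi}\Big\{\big[c\,g(\phi) - C_1\big] R(\phi)\Big\}
 + \Big(\tfrac{2\omega}{\tau} - C_2\Big) R(\phi) = K,
\qquad \int_{-\pi}^{\pi} R = 1,
\qquad K = \frac{2\omega/\tau - C_2}{2\pi}.
$$

All coefficients are elementary integrals of the PRC pair and the noise
kernel:

* $g_{nm}(\phi)$ is $h_{nm}$ low-pass filtered by the OU
  autocorrelation: harmonic $k$ is multiplied by $1/(1 + k^2\tau^2)$
  (`filtered_correlation()`).
* $C_1 = g_{11}(0) + g_{22}(0)$ is the total filtered noise power
  transferred through the two PRCs, and $c\,g(\phi) = 2c\,g_{12}(\phi)$
  is the part coherent between the cells. $C_1 - c\,g(\phi) > 0$ is the
  phase-dependent diffusion (transport) coefficient; it degenerates only
  in the perfect-synchrony limit of identical cells at $c = 1$.
* $C_2 = 2(\nu_1 - \nu_2)$ with
  $\nu_j = \int_0^\infty h_{jj}'(s)\,\rho_\tau(s)\,ds$ is the asymmetry
  of the noise-induced frequency shifts; it vanishes for identical PRCs.
* $K$ is *not* free: integrating the equation over one period forces it,
  and `build_problem()` carries it as a consistency value.

Several consequences are built in as tests: for identical PRCs and
$\omega = 0$ the flux vanishes and
$R(\phi) = N / (C_1 - c\,g(\phi))$ in closed form, symmetric and peaked
at $\phi = 0$; for $\Delta = -\sin\theta$ this is the Poisson-kernel-like
density with order parameter $(1 - \sqrt{1 - c^2})/c$; for pure
first-harmonic PRCs with zero DC the density is independent of $\tau$
altogether; and $\epsilon$ appears nowhere, so Monte Carlo densities at
different noise amplitudes coincide to leading order.

`solve_density()` expands $R$ in Fourier harmonics; multiplication by the
transport coefficient is a convolution, so the BVP becomes a dense linear
system in harmonic space. The $k = 0$ row is the (automatically
satisfied) compatibility condition and is replaced by the normalization.
The solver refuses solutions whose ODE residual exceeds
$10^{-7}\max(1, \max|R|)$ or that dip below $-10^{-6}$: those indicate an
under-resolved or invalid problem and are never clipped into validity.
The default 128 harmonics are far more than the smooth coefficient
functions need; identical-pair solutions match the closed form at
machine precision.

## What the synchrony numbers mean

`order_parameter()` reports the modulus of the first circular moment
$OP = |{\textstyle\int} e^{i\phi} R(\phi)\,d\phi|$: 0 for a flat density,
1 for a delta peak, with circular variance $1 - OP$. The peak position is
the resultant angle $\mathrm{atan2}(S, C)$ rather than the argmax bin,
which is robust to binning noise. The zero-lag spike-time
cross-correlation implied by a density is $(R(0) - \frac{1}{2\pi})/2\pi$,
and at small $c$ it is linear in $c$ with slope (susceptibility)

$$
S = \frac{1}{2\pi}\Big(1 - \frac{1}{2\pi}\int_0^{2\pi}
     \frac{g(\phi)}{g(0)}\,d\phi\Big).
$$

Because the mean of $g$ is proportional to the squared DC component
$a_0^2$ of the PRC, *good synchronizers are cells whose PRC has small
mean*: for the exponential-sine family
$(\sin a - \sin(x + a))e^{C(x - 2\pi)}$ the optimum is at
$a = -\arctan C$. A counterintuitive corollary, which the small-$c$
expansion (`small_c_expansion()`) makes exact for first-harmonic PRCs, is
that a good-bad heterogeneous pair can out-synchronize the bad-bad
homogeneous pair at low correlations:

$$
OP_{jk} \propto \frac{c}{1 + (\tau^2 + 1)(\sin^2 a_j + \sin^2 a_k)},
$$

so $OP_{11} > OP_{12} > OP_{22}$ whenever $0 \le a_1 < a_2 \le \pi/2$.
At high correlations the ordering reverses in the sense that both
homogeneous pairs approach perfect synchrony while the heterogeneous
pair saturates (below $OP = 0.4$ for the standard double-sinusoidal
example pair).

```{r}
p1 <- prc_double_sine(0.1, 0.32)
p2 <- prc_double_sine(0.6, 0.3)
d <- solve_density(build_problem(p1, p2, tau = 1, c = 0.8, omega = 0))
order_parameter(d)
```

## The Morris-Lecar validation layer

The phase theory is validated against a conductance-based model: the
two-variable Morris-Lecar (ML) neuron, whose onset of firing can occur
through a Hopf bifurcation (PRC with a substantial negative lobe) or a
saddle-node on an invariant circle (SNIC; predominantly non-negative
PRC). The package ships both regimes tuned to a common period near
91.2 ms (`ml_hopf_params()`, `ml_snic_params()`; the SNIC current is
matched to the Hopf period with `ml_match_frequency()`, mirroring how
same-frequency heterogeneous pairs are constructed).

The chain of reductions is exercised end to end:

1. `find_limit_cycle()` integrates the deterministic cell (fixed-step
   RK4, transient 2000 ms), measures the period from upward 0 mV
   crossings, and resamples one cycle to 1024 points (closure below
   $10^{-6}$ of the cycle amplitude).
2. `adjoint_prc()` integrates the transposed-Jacobian system backward in
   time — backward integration contracts onto the unique periodic
   adjoint solution — normalizes $Z \cdot F$ to the phase speed
   $2\pi/T$, and returns the voltage component per unit injected charge
   density. A direct pulse oracle (`pulse_prc()`, 0.2 ms pulses) agrees
   within 1% of the PRC peak.
3. `hilbert_phase()` reconstructs phase from noisy voltage via the
   analytic signal, remapped through a monotone lookup built on the
   noise-free cycle so that phase advances uniformly in time. On a
   noise-free record covering whole periods the remapped phase is linear
   to ~0.01 rad; on records with a fractional trailing period, spectral
   leakage adds a small global wobble that is negligible for the long
   runs used for densities.
4. `ml_phase_difference_density()` runs the noisy pair end to end, and
   `ml_phase_model()` converts cycles plus noise settings into the
   equivalent phase-model inputs ($\tau$ in phase units is
   $2\pi\tau_{\mathrm{ms}}/T$; the effective noise magnitude is
   $\sigma T / 2\pi$ because both layers drive with unit-power colored
   noise).

For the heterogeneous Hopf-SNIC pair at $c = 0.8$, $\tau = 5$ ms the
three pipelines (biophysical + Hilbert phase, phase-reduced Monte Carlo
with adjoint PRCs, BVP with adjoint PRCs) agree in peak height within a
few percent and in peak location within about one histogram bin.

### Simulation scales and the cost of mixing

A practical lesson that shapes every default: the phase difference
relaxes on a time scale $\propto 1/(\epsilon^2 C_1)$. Halving the noise
amplitude quadruples the time needed for the same Monte Carlo accuracy,
and a finite histogram from an under-mixed run is dominated by a handful
of effectively independent samples — it can look like (and must not be
mistaken for) a genuinely different stationary density. The noise
amplitude for biophysical examples, $\sigma = 2\ \mu A/cm^2$, was chosen
once so the per-cycle phase kick stays weak (~0.2 rad, where densities
are amplitude-independent) while the pair still mixes within a few
hundred cycles; it is not printed with the original parameter sets.
Likewise the Monte Carlo checks of the theory use total times of
$10^5$–$3\times 10^5$ phase-time units with $\epsilon = 0.1$, and the
order-parameter spot checks average three seeds because a single run of
that length carries a few-percent error in OP.

## Synthetic data and its limits

Two generators stand in for experimental material, and both are
first-class, tested code:

* `synthetic_prc_table()` samples a parametric PRC on a uniform grid and
  adds Gaussian noise, emulating a PRC estimated from noisy spike-time
  measurements; it exercises the tabulated-PRC and exponential-sine
  fitting path (`fit_exp_sine()`, seed-averaged recovery of both
  parameters to 0.1 under 5%-of-peak noise).
* `heterogeneity_population_study()` runs the population-level analysis
  — classify each pair's "good synchronizer" by the area under the
  homogeneous OP-vs-$c$ curve, then ask whether heterogeneity enhances
  synchrony at low correlations ($c \le 0.3$ by default) — on synthetic
  PRC populations.

What these do *not* emulate: real PRC estimates carry correlated (not
white) measurement noise and trial-to-trial drift; real cells have
intrinsic noise that caps the achievable input correlation below 1; and
firing-rate differences in experiments are matched only approximately.
Passing tests on synthetic populations therefore demonstrate the
machinery and the qualitative phenomenon (enhancement occurs for some
pairs and not others), not the quantitative population statistics of any
particular recorded data set.

## Numerical choices, in brief

* Phase grids are uniform, half-open on $[0, 2\pi)$, power-of-two sized
  (default 256); densities live on $[-\pi, \pi)$ with the seam mapped to
  $-\pi$.
* Tabulated PRCs use periodic cubic splines (smoothness is needed for
  the derivative-sensitive $C_2$); the exponential-sine family is
  periodized by wrapping, accepting the jump at 0 since it serves as a
  fitting model only.
* The Langevin integrator is plain Euler-Maruyama on a shared grid for
  phases and noise (`dt = 0.05` by default, `0.02` where the tests need
  the discretization bias below the Monte Carlo error); the OU module
  also provides the exact exponential update as a cross-check.
* The exponential-sine fit initializes $a$ from the phase of the first
  Fourier harmonic and $C$ from the early/late log-magnitude ratio, then
  polishes by Levenberg-Marquardt; the $(\mathrm{scale}, a) \to
  (-\mathrm{scale}, a + \pi)$ ambiguity is resolved to positive scale.
* The peak angle uses the resultant-vector convention
  $\mathrm{atan2}(S, C)$; the argmax bin is reported nowhere.

## Known limitations

* The theory is leading-order in $\epsilon$: at $\epsilon \approx 1$ the
  Monte Carlo density distorts visibly near its peak (the tests document
  the regime where agreement holds).
* Exact $OP(\omega) = OP(-\omega)$ symmetry holds when the density's
  asymmetry enters only through $\omega$ (e.g. first-harmonic PRC
  pairs); pairs with differing higher harmonics break it at the
  $10^{-3}$ level through $C_2$ and the odd part of $g$.
* Only pairs are modeled — no populations of mutually coupled
  oscillators — and only OU (exponential-kernel) noise, although the
  filtered-correlation construction would accept any stationary kernel.
* The c = 1 homogeneous limit is a delta function; the BVP solver
  refuses it and the closed-form order parameter reports the limit
  instead.
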