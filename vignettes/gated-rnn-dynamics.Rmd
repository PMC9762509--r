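---
title: "Dynamics of gated recurrent networks: models, mean-field theory, and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics of gated recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gatedRNN)
```

## The model

The package simulates and analyses a continuous-time recurrent network of
`N` units whose interactions are both additive and multiplicative
(*gated*):

$$\dot h_i = \sigma_z(z_i)\,[-h_i + R_i] + I^h_i, \qquad
  R_i = \sum_j J^h_{ij}\,\phi(h_j)\,\sigma_r(r_j),$$
$$\tau_x \dot x_i = -x_i + \sum_j J^x_{ij}\,\phi(h_j) + I^x_i,
  \qquad x \in \{z, r\},$$

with activation $\phi(x) = \tanh(g_h x + \beta_h)$ and gates
$\sigma_\cdot(x) = [1 + e^{-\alpha_\cdot x + \beta_\cdot}]^{-1}$.  The
*update* gate $\sigma_z$ acts as a per-unit adaptive time constant; the
*output* gate $\sigma_r$ scales each unit's recurrent output.  All three
coupling matrices are independent with i.i.d. $N(0, 1/N)$ entries, so the
model is a disordered dynamical system whose large-`N` behaviour is
captured by mean-field theory.  Pinning both gates to 1
(`gate_override = list(z = 1, r = 1)`) recovers the classical additive
network $\dot x = -x + J\phi(x)$ with its transition to chaos at unit
effective gain; with the default gate biases and gains of zero the gates
sit at $1/2$, which rescales both time and coupling and moves the
transition of the gated network to $g_h = 2$.

Sign conventions follow the sigmoid exactly as written above.  Under this
convention the bias-free zero fixed point loses stability at
$g_h = 1 + e^{+\beta_r}$; we implement the convention literally and do not
flip bias signs.

## Numerical integration

Trajectories use fixed-step RK4 with `dt = 0.05` (all time constants are
O(1)); the Lyapunov machinery needs a fixed step, and a halving test is
part of the test suite.  Initial conditions default to i.i.d.
$N(0, 0.1^2)$ on all of $(h, z, r)$: small enough to stay in the basin of
the zero fixed point when it is stable, nonzero so the measure-zero fixed
point itself is avoided.  Where the analysis requires reaching a chaotic
set that coexists with the stable origin, initial conditions are drawn at
a scale comparable to the nonzero mean-field amplitude instead — small
initial conditions would be captured by the origin and the set would be
invisible.

An infinite gate gain is an explicit flag (`alpha_z = Inf`), never a large
float.  Because the Heaviside gate makes the vector field discontinuous,
ODE runs integrate it by default through the smooth surrogate gain
`surrogate_alpha = 100`; `infinite_gate = "heaviside"` integrates the
discontinuous field directly, which is what the reset experiment uses
(there, *exactly* frozen units are the point).  Exactly at a gate
threshold the gate value is $1/(1+e^\beta)$ — the finite-gain value — as a
deterministic tie rule.

All randomness derives from one root seed through named substreams
(couplings, initial conditions, inputs, trials), so every stochastic
experiment is bit-reproducible.

## Mean-field theory of fixed points

At a fixed point the recurrent field $h_i = \sum_j J^h_{ij}
\phi(h_j)\sigma_r(r_j)$ is Gaussian, and because the three coupling
matrices are independent the on-site correlations between $h$, $z$ and
$r$ vanish at large `N`.  The closure solved by `solve_fixed_point()` is

$$\Delta_z = \Delta_r = \langle\phi^2\rangle_{\Delta_h}, \qquad
  \Delta_h = \langle\phi^2\rangle_{\Delta_h}\,
             \langle\sigma_r^2\rangle_{\Delta_r},$$

iterated with damping 0.5 to tolerance $10^{-10}$.  Near the fold where
nontrivial solutions first appear the map's slope approaches 1 and the
iteration stalls; the solver then falls back to bracketing the largest
root of $\mathrm{map}(\Delta) - \Delta$ directly, which is what decides
branch existence in `alpha_r_fp_star()`.  (The plain damped iteration
prescribed initially misclassified the branch close to $g_h = 2$, where
the collapse toward zero is slower than any practical iteration budget —
this is the one place the implementation deviates from its first design.)

This closure was validated against simulation before any boundary curve
was trusted: at $g_h = 3$ the chaotic population variance
$\langle h^2\rangle$ at $N = 800$ agrees with the fixed-point $\Delta_h$
to under 2%, and the test suite holds two supercritical gains to within
15% at $N = 800$.

Gaussian averages use Gauss–Hermite quadrature with 201 nodes.  Two
non-obvious numerical points: (i) the $\mathrm{sech}^4(g_h h)$ integrand
that controls $\langle\phi'^2\rangle$ becomes strongly peaked at large
gain and is badly under-resolved below roughly 150 nodes — the
marginal-window boundary computed with a 101-node rule is off by 0.06 in
gain; (ii) the quadrature rule must be exactly antisymmetric, because the
binary-gate averages integrate step functions and an off-center node at
$10^{-16}$ silently loses the center weight (4 percentage points in
$\langle\sigma_z\rangle$).  Both are enforced and tested.

## Spectral theory of the instantaneous Jacobian

The $3N \times 3N$ Jacobian has the block structure assembled by
`instantaneous_jacobian()`; its support boundary in the complex plane is
predicted from the moment set by the spectral-curve equation

$$\langle\phi'^2\rangle \left( \langle\sigma_r^2\rangle +
  \frac{\langle\phi^2\rangle\langle\sigma_r'^2\rangle}{|1+\tau_r\lambda|^2}
  \right) \left\langle \frac{\sigma_z^2}{|\lambda + \sigma_z|^2}
  \right\rangle_z = 1.$$

`spectral_curve()` traces the zero level set on a 600×600 grid (the
imaginary grid is chosen to avoid the real segment $[-1, 0]$, where the
$z$-average has non-integrable poles at $-\sigma_z$) and refines the two
scalar diagnostics — the leading edge and the imaginary-axis intercept —
by bisection to $10^{-10}$.  The placement of the two squared-modulus
denominators is validated by a standing test: at the bias-free zero fixed
point the equation collapses to the circle $|\lambda + 1/2| = g_h/4$, so
the leading edge crosses the origin exactly at $g_h = 2$.

The $z$-average adapts to how the $z$ distribution is known: Gauss–Hermite
for a Gaussian $z$ field, a two-point law for the binary gate, the exact
point value at the zero fixed point, and a binned empirical average when
the moments come from a trajectory.

In the binary-gate limit ($\alpha_z = \infty$) the spectrum splits into an
extensive set of exact zero modes and a disk centered at $-1$ of radius
$\rho = \sqrt{a/2 + \sqrt{4b+a^2}/2}$,
$a = \langle\phi'^2\rangle\langle\sigma_z\rangle\langle\sigma_r^2\rangle$,
$b = \langle\phi'^2\rangle\langle\sigma_z\rangle\langle\phi^2\rangle
\langle\sigma_r'^2\rangle$; $\rho < 1$ is marginal stability.  The
limiting eigenvalue density of the `h` block is the mixture returned by
`limiting_density_infinite_alpha_z()`: mass $1-f_z$ at 0 (frozen units),
mass $f_z(1-f_h)$ at $-1$ (active units with saturated activation), and a
uniform disk of density $4/(\pi g_h^2)$ with radius
$(g_h/2)\sqrt{f_z f_h}$ centered at $-1$ — the circular law of the
active, unsaturated bulk, carrying exactly the remaining mass $f_z f_h$
(the $1/2$ is the closed output gate at $\alpha_r = 0$); it reduces to
the plain circular law at $f_z = f_h = 1$ and matches the empirical
near-zero cluster count to a few percent at $N = 800$.

## Lyapunov analysis

`lyapunov_spectrum()` implements the standard tangent-space method: `k`
tangent vectors are evolved with the instantaneous Jacobian alongside the
trajectory (both in the same augmented RK4 step, so the tangent flow sees
the Jacobian at the RK4 stage states), reorthonormalized by QR every time
unit, with exponents read off the averaged log diagonal of R.  Sum-rule
(trace), reorthonormalization-halving, and exact-linear-system tests pin
the machinery down to $10^{-3}$ per exponent.  `kaplan_yorke()` converts a
spectrum into the attractor-dimension bound
$D_A = M + \sum_{i\le M}\lambda_i / |\lambda_{M+1}|$.

The mean-field prediction for the maximal exponent is the growth-rate
eigenproblem solved by `dmft_lambda_max()`:

$$\left[(\langle\sigma_z\rangle+\kappa)^2 - \partial_\tau^2\right]
  \chi(\tau) = \langle\sigma_z\rangle^2\, C_{\phi'}(\tau)\,
  C_{\sigma_r}(\tau)\, \chi(\tau),$$

with correlators measured from a stationary run
(`measure_correlators()`), $-\partial_\tau^2$ as second differences on
the lag grid ($\tau \in [-20, 20]$, $\Delta\tau = 4\,dt$) and Dirichlet
ends.  The closure $\partial C_{\phi\sigma_r}/\partial C_h = C_{\phi'}
C_{\sigma_r}$ treats $(h, r)$ as jointly Gaussian with vanishing cross
covariance and applies Price's theorem to the $h$ variation; it is exact
only for `alpha_z = 0`, where the update gate is constant and the `h`
field Gaussian, and the function refuses other gains rather than return
an uncontrolled number.  Because $\kappa$ enters only through the scalar
factor $(\langle\sigma_z\rangle+\kappa)^2$, the quadratic eigenproblem
reduces in closed form to $\kappa_{\max} = -\langle\sigma_z\rangle +
\sqrt{\ell_{\max}}$ with $\ell_{\max}$ the top eigenvalue of the symmetric
discretized operator — the companion linearization one would use for a
general quadratic pencil collapses to this.  Two checks anchor the
construction: with both gates pinned to 1 it reduces to the classical
additive-network eigenproblem, and the time-rescaled gated network at
gate value $1/2$ maps onto the classical problem at effective gain
$g_h/2$, reproducing the $g_h = 2$ threshold.

## Phase diagram and the discontinuous transition

`classify_point()` labels a bias-free parameter point by combining the
zero-fixed-point criterion, nontrivial-MFT existence, a
large-initial-condition ensemble vote on $\lambda_{\max}$ (8 trials,
"positive" at $\ge 6$ exceeding $+0.02$), and the binary-gate disk radius
for the marginal overlay.  The dynamical transition in the output gate,
`alpha_r_dmft_star()`, is located by bisection of the vote.

At the sizes a single-CPU run affords, the transition region is blurred by
chaotic transients: trajectories near the threshold can sustain activity
for the whole observation window and then collapse.  The per-trial
collapse flag (terminal population variance below $10^{-8}$) separates the
two branches of $\lambda_{\max}$, and the jump size across the transition
is reported between the branch-conditioned means — trials that collapsed
sample the stable branch (the decay rate onto the zero fixed point,
$-1/2 + g_h/4$), sustained trials the chaotic-set branch.  This is the
finite-size estimator of the discontinuity; the unconditioned means blur
it at any affordable `N`.

Transient-time scaling (`transient_time_scaling()`) uses censored medians
of the collapse time; in the coexistence regime the median grows with `N`
while in the stable regime it is O(1) and size-independent.

## Static drive: suppression and induction of chaos

A quenched static drive can enter the model two ways, and they behave
differently:

* `input_mode = "additive_h"` — the literal $I^h$ term of the dynamical
  equations, outside the update gate.  At a fixed point this contributes
  $\sigma_h^2 \langle\sigma_z^{-2}\rangle$ to $\Delta_h$ (a factor 4 at
  `alpha_z = 0`), and in direct simulation at $\sigma_h = 0.5$ this form
  *suppresses* chaos at every parameter point we scanned, including the
  whole discontinuous-transition neighbourhood.

* `input_mode = "activation_bias"` (default) — a frozen per-unit offset
  inside the activation argument, $\phi = \tanh(g_h h + \beta_h + b_i)$,
  i.e. quenched random biases.  Activation averages then run over
  variance $\Delta_h + \sigma_h^2/g_h^2$ while $\Delta_h$ keeps its
  autonomous closure.  This is the drive under which the induced
  transition exists: it populates the $r$ field
  ($\Delta_r = \langle\phi^2\rangle > 0$), switches on the
  $\langle\sigma_r'^2\rangle$ term of the instability criterion, and at
  large `alpha_r` pulls the critical line below $g_h = 2$.

`biased_critical_line()` computes the critical locus for either mode from
the fixed-point criterion; `input_induced_chaos_scan()` measures the
simulated $\lambda_{\max}$ with and without the drive.  With
$\sigma_h = 0.5$ the scan at $(g_h, \alpha_r) = (1.9, 13)$, $N = 200$
flips a stable point to sustained chaos, while the fully chaotic point
$(3, 0)$ is stabilized — the same drive, opposite effects, exactly the
asymmetry the phase geometry predicts.  The input protocol type `"phi"`
exposes the bias drive to the integrator as a first-class input channel.

## Integrator and reset experiments

`integrator_experiment()` demonstrates the line-attractor function of the
marginal state (default $\alpha_z = 30$, $g_h = 3$): relax, extract a slow
Jacobian eigenvector, drive `h` along it for 10 time units, and track the
excess projection on the matching left eigenvector against a no-input
reference run.  Retention is the projection 50 time units after offset
relative to offset.  Selection details that matter in practice: the slow
mode is chosen from the near-zero cluster as a *collective* mode (highest
participation ratio of its `h` components) with a usable left–right
pairing — the nominally smallest eigenvalues are single-frozen-unit
directions with nearly defective pairings whose projections are numerical
noise.  The contrast ("non-aligned") input drives a well-separated fast
mode from the stable disk and is tracked through that mode's own left
eigenvector, for which the linear decay is exact; its amplitude is kept
small because large pulses flip marginal update gates and leave genuine
static offsets.  At these sizes the experiment is realization dependent
(the marginal state is fragile to gate flips); the packaged configuration
($N = 300$, seed 4) exhibits the clean contrast of retention above 0.85
for aligned drive versus below 0.1 for the fast-mode probe.

`reset_experiment()` erases the memory: either clamp the output gate to
zero for a window (the state decays at rate $\sigma_z$), or apply a
positive static pulse to the update gate.  The pulse shifts
$\langle\sigma_z\rangle$ above the marginal-stability bound, transiently
induces chaos, and scrambles the state; the projection of `h` on the
pre-reset state falls below 0.1 for supra-threshold pulses and stays
high for weak ones.  This experiment runs with the true Heaviside gate so
that frozen units are exactly frozen between pulses.

## Problem sizes and what the tests do (and do not) show

The package's own test battery runs networks of $N = 150$–800 and
windows of a few hundred time units: spectra and zero-mode counts at
$N = 600$–800, mean-field/Lyapunov agreement at $N = 500$–600, the
discontinuous-transition machinery at $N = 300$ with 5–6-vote ensembles,
and the functional experiments at $N = 300$.  These sizes reproduce the
analytic thresholds to the stated tolerances, but finite-size effects are
visible exactly where the theory says they should be: chaotic transients
blur the discontinuous transition, the marginal state is fragile to gate
flips, and single-realization $\lambda_{\max}$ estimates carry
$\pm 0.01$–0.02 noise.  Everything the generator produces is i.i.d.
Gaussian disorder — there is no structured connectivity, sparseness,
cell-type structure or noise process, so agreement here says nothing
about those features of real networks.

## Known limitations

* The mean-field growth rate is available only at `alpha_z = 0`; for
  switchlike update gates the `h` distribution is strongly non-Gaussian
  and the Price closure is wrong, so the function refuses rather than
  extrapolate.
* The two-time correlators are measured from simulation, not solved as a
  self-consistent functional equation; correlator-based predictions
  inherit simulation noise.
* The upper edge of the marginal window from the joint mean-field +
  disk-radius solve is $g_h \approx 6.55$ with this fixed-point closure
  (the value is quadrature-converged and oracle-checked); treat it as the
  package's prediction under the stated closure.
* Region semantics of the phase diagram are defined for the bias-free
  network; biased variants are exposed through the critical-line and
  drive-scan functions only.
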