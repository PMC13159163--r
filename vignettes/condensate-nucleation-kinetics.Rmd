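---
title: "Methods: nucleation kinetics of biomolecular condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleation kinetics of biomolecular condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(condnuc)
```

# The physical problem

Biomolecular condensates form by liquid-liquid phase separation of a
biomolecule-rich phase from a dilute solution. Two nucleation processes are
mirror images of each other across the same interface: condensates nucleate
in a supersaturated dilute solution, and *voids* (pockets of dilute phase)
nucleate inside a condensate that has been driven out of equilibrium, for
example by cooling a system with an upper critical solution temperature so
that the dense binodal concentration rises above the condensate's actual
concentration. Both processes are governed by the same dense-dilute
interfacial tension $\gamma$, which for condensates is of order
$\mu\mathrm{J\,m^{-2}}$ — five to six orders of magnitude below typical
protein-crystal tensions. This package quantifies that statement: it
implements the thermodynamics, the transport model and the classical
nucleation theory (CNT) rate expressions needed to turn void-count
experiments into estimates of $\gamma$, and to predict condensate
nucleation rates from $\gamma$.

# Thermodynamics

A binary Flory-Huggins model describes the polymer-solvent mixture through
the free energy per lattice site (in units of $k_BT$)

$$f(\phi,T) = \frac{\phi\ln\phi}{M} + (1-\phi)\ln(1-\phi)
  + \chi(T)\,\phi(1-\phi), \qquad \chi(T) = A + \frac{B}{T},$$

with effective chain length $M$, entropic interaction part $A$ and
enthalpic part $B$ (kelvin). Coexistence compositions
$(\phi_-,\phi_+)$ satisfy the common-tangent conditions; the critical point
has the closed form $\phi_c = 1/(1+\sqrt M)$,
$\chi_c = (1+1/\sqrt M)^2/2$. Mass concentrations and volume fractions are
interconverted through the solute density $\rho$ (`phi_from_conc()`), 1600
kg/m^3 for RNA and 1500 kg/m^3 in the cross-system atlas.

The package ships three fitted parameterisations for poly-rA RNA in 1 M KCl
(`fh_preset()`): $(M,A,B)$ = (1000, 0.31, 75.0 K), (2000, 0.23, 98.8 K) —
the reference set, with a critical temperature of 64.5 °C — and
(4000, 0.19, 110 K). The chain length is fixed by the user (the data cannot
identify it independently of $A,B$); `fit_phase_model()` estimates only
$(A,B)$ by least squares on measured coexistence concentrations, with equal
weighting of dense and dilute points by default and a dense-only mode,
since for long chains the dilute branch contributes almost nothing to the
squared-error surface.

## Binodal construction

`compute_binodal()` evaluates $f$ on a composition grid that is
log-spaced near $\phi = 0$ (down to $10^{-12}$; for $M = 2000$ the dilute
binodal sits at volume fractions of $10^{-5}$–$10^{-3}$ and a linear grid
misses it entirely) and linear above $\phi_c$, takes the lower convex hull
(the numerical form of the Gibbs double-tangent construction), and uses the
hull facet spanning $\phi_c$ to initialise a damped Newton iteration on the
two common-tangent equations in logit coordinates. Solutions satisfy both
conditions to $10^{-13}$ $k_BT$. Above $T_c$ the degenerate binodal
$\phi_- = \phi_+ = \phi_c$ is returned rather than an error, so temperature
sweeps are loop-safe. `binodal_curve()` marches a temperature grid from the
coldest point upward, warm-starting each Newton solve from its neighbour —
this is what makes the 0.003 °C supercooling sweeps cheap.

## Driving forces and their numerical form

For condensate nucleation the driving force per molecule is
$\Delta g_+ = -k_BT\ln S$ with $S = \phi/\phi_-(T)$. For void nucleation
it follows from comparing a control volume of dense phase at composition
$\phi$ with a void ($\phi_-$) plus concentrated dense phase ($\phi_+$),

$$\Delta g_- = [g(\phi_-) - g(\phi)] + K\,[g(\phi_+) - g(\phi)], \qquad
  g = \frac{fM}{\phi}, \qquad
  K = \frac{1/\phi - 1/\phi_-}{1/\phi_+ - 1/\phi},$$

which vanishes at both binodals and is negative in between. The two-term
form is *catastrophically ill-conditioned* near the dense binodal: $K$
diverges while the bracket it multiplies cancels to zero, and in a cooling
simulation the interface sits exactly at $\phi_+$, where a naive evaluation
returns pure rounding noise amplified by $K$ (we observed errors of six
orders of magnitude). The implementation therefore uses the algebraically
identical tangent-excess form

$$\Delta g_- = -M\,h(\phi)\,
  \frac{\phi_+-\phi_-}{\phi_-\,(\phi_+-\phi)}\,k_BT,\qquad
  h(\phi) = f(\phi) - f(\phi_-) - f'(\phi_-)(\phi-\phi_-) \ge 0,$$

derived by writing $f$ as its common tangent plus the non-negative excess
$h$; the $a$-dependent large terms cancel exactly. Compositions within a
relative $10^{-9}$ of either binodal are treated as at equilibrium (the
true driving force there is below $10^{-6}\,k_BT$ and irrelevant for any
rate).

# Classical nucleation theory

The stationary rate is assembled as the product
$J = \vartheta\, z f_c \rho_m e^{-W_c/k_BT}$ with the cluster work
$W(n) = \gamma(36\pi)^{1/3}v_m^{2/3}n^{2/3} + n\Delta g$, barrier
$W_c = (16\pi/3)\gamma^3 v_m^2/\Delta g^2$, Zeldovich factor
$z = \sqrt{-W''(n_c)/2\pi k_BT}$, diffusion-limited attachment frequency
$f_c = (48\pi^2 v_m)^{1/3} c D n_c^{1/3}$ and site density
$\rho_m = 1/v_m$. The product form is authoritative; the collapsed closed
form $J = \vartheta D c\,|\Delta g|\,v_m^{-1}(\gamma k_BT)^{-1/2}
e^{-W_c/k_BT}$ is a *verified identity* in the test suite (to $10^{-10}$
relative over $10^4$ random parameter sets), not an independent input —
this resolves the typographic ambiguity of the printed groupings. Molecular
volumes are $v_m = M_w/(N_A \hat c)$ with a single molecular weight
$M_w = 2500$ kg/mol for the polydisperse RNA.

Conventions: driving forces are stored signed (favourable = negative);
$J \equiv 0$ for $\Delta g \ge 0$; $\ln J$ is computed first and
exponentiated last, with underflow below $e^{-700}$ mapped to zero. For
voids the parent phase is dense ($c$ from the local condensate
concentration, $D_+$) and the nucleating phase dilute ($v_{m,-}$,
$\Delta g_-$); for condensates the roles swap ($c$ from the solution,
$D_- = 1000\,D_+$, $v_{m,+}$, $\Delta g_+$). $\vartheta$ is one shared
dimensionless prefactor; $\vartheta = 1$ is the physically expected value
for homogeneous volume-diffusion-limited nucleation and is the default in
the cross-system atlas.

# Transport: a cooling condensate

`simulate_condensate()` integrates spherical diffusion
$\partial_t c = D r^{-2}\partial_r(r^2\partial_r c)$ with the interface
node pinned to the dense binodal $c^*(T(t))$, a ghost-point symmetry
condition at the centre, and solute-mass conservation enforced by the
discrete shrinkage rule: whenever the mass on all but the outermost grid
point exceeds the initial mass, the outermost point is removed. Choices:

* **Implicit backward-Euler** stepping by default (tridiagonal Thomas
  solve). The explicit option aborts with a diagnostic when its stability
  limit $\Delta t \le \Delta r^2/6D$ is violated; for the measured
  $D_+ = 1.3\times10^{-13}$ m²/s that limit is milliseconds, which is why
  implicit stepping is the default.
* **Grid**: 500 intervals across $R_0$ by default. The shrinkage rule
  quantises the radius to whole shells, so the mass drift over a run is
  bounded by about one outer shell, $\sim 3/n_{grid}$; 500 points keep it
  below 1 % (measured 0.8 % for the reference run, converging as the grid
  refines). Tests and fits use 150 points with a 0.1 K time step, which
  changes expected void counts by ~1 % (verified by a refinement test).
* **Time step**: tied to the cooling rate (0.05 K per step) during the
  ramp; $\tau/400$ with $\tau = R_0^2/6D$ during the hold.
* **Termination**: the hold ends when the profile deviates from the final
  binodal value by less than $10^{-3}$ (relative, maximum over the grid) —
  the "equilibrated" criterion, unspecified in the source and fixed here
  once.
* Temperature is spatially uniform and $D$ temperature-independent.

# Void statistics and parameter estimation

The expected number of voids in one condensate is the space-time integral
$N = \int\!\!\int 4\pi r^2 J_{void}(c(r,t), T(t))\,dr\,dt$ over the
shrinking sphere (trapezoidal quadrature on the transport grid). Observed
counts are Poisson with mean $N$. The critical size $d_{crit}$ (where
$N = 1$) is found by bisection between 10 and 100 µm to 0.1 µm, using that
$N$ increases monotonically with size; the single-void band is delimited by
$N = 0.242$ and $N = 5.572$, constants adopted verbatim from the source
analysis (the upper value matches the exact Poisson 97.5 % bound for one
observed event; the lower does not match the standard 2.5 % bound and we
deliberately do not reinterpret it).

`fit_void_parameters()` estimates $(\gamma_0,\vartheta)$ by minimising
$\sum_k [\ln N(d_{crit,k})]^2$ over per-rate critical sizes, with
Nelder-Mead in $\log_{10}$ parameter space from a log-spaced multistart
grid. A key implementation point: the transport trajectory — and hence the
entire $\Delta g_-(r,t)$ field — does not depend on $(\gamma_0,\vartheta)$,
so each critical size is simulated once and every optimiser step only
re-evaluates the cheap algebraic rate field on the stored trajectory.

Two estimator refinements beyond the experimental convention are provided
and documented as such:

* `estimate_critical_sizes(method = "poisson")` replaces the mean size of
  single-void condensates by a per-rate maximum-likelihood estimate on the
  0/1/≥2 categories of *all* condensates (with $\ln N$ locally linear in
  $\ln d$; the any-void indicator under this model is exactly a
  complementary-log-log GLM, which provides the initial values). With the
  steep $N(d)$ of the reference parameterisation only a handful of
  condensates per rate fall in the single-void window, and the
  single-void mean is accordingly noisy.
* `fit_void_parameters_mle()` skips the critical-size compression entirely
  and maximises the Poisson category likelihood of the raw records. This
  removes most of the strong sampling correlation between $\gamma_0$ and
  $\vartheta$ that the critical-size objective exhibits (both parameters
  shift $N$, and only the weak rate-dependence of the barrier separates
  them); in repeated synthetic studies it recovers $\gamma_0$ several
  times more precisely at the same experimental size. The critical-size
  route remains the default because it is the convention of the
  experimental analysis being emulated.

# Condensate-nucleation predictions

`supercooling_curve()` sweeps the temperature below a reference $T_{ref}$
(40 °C) at 0.003 °C resolution. The solution composition is taken to *be*
the dilute binodal at $T_{ref}$, so $S(T) = \phi_-(T_{ref})/\phi_-(T)$ and
$J = 0$ at zero supercooling; the measured solution concentration
(0.82 mg/mL) enters only the kinetic prefactor. (Taking the measured
concentration as the composition instead would put the solution far above
the model binodal already at $T_{ref}$ and produce astronomically large
rates at $\Delta T = 0$, contradicting the observed reversible
appearance/disappearance of condensates around the reference; this is the
one place where we follow the source's methods text rather than a more
literal reading.) The dense-phase molecular volume and any
temperature-dependent tension are re-evaluated at every grid temperature.

`delta_g_min()` inverts $J(\gamma, \Delta g) = 10^{12}\,
\mathrm{m^{-3}s^{-1}}$ — one nucleus per 100 s per nanolitre, the named
relevance threshold — for the driving force, by bracketed root finding on
$\ln J$, under the shared atlas reference set (1 mg/mL, 300 K, solute
density 1.5 g/mL, $D = 10^{-10}$ m²/s, dense volume fraction 0.2 for
condensates and 0.5 for solids, $\vartheta = 1$). `cell_nuclei()` converts
a rate into an expected per-cell count $N = J V \Delta t$ with
$\Delta t = d^2/6D$ the diffusive depletion time of a 60 µm cell.

# The synthetic world

All experiment-shaped inputs are generated with known ground truth:

* **Binodal points**: both phases at 20–60 °C in 5 °C steps, 5 % relative
  Gaussian noise by default.
* **Void-count studies**: condensate diameters log-uniform over 10–100 µm
  (the observed size window), 100 condensates per rate (the experiments
  report "more than 50" per rate), cooling rates 0.5/1/2/5 K/min from 55
  to 36 °C, counts Poisson-drawn from the exact model $N(d)$ (simulated on
  a 12-point diameter grid per rate and monotone-spline-interpolated in
  $\ln N$–$\ln d$; with the very steep $N(d)$ of this system, coarser
  interpolation produces a ln-scale model error that the shallow
  $(\gamma_0,\vartheta)$ likelihood ridge amplifies into a severe
  parameter bias, so the grid density is part of the stated analysis). Ground truth $(\gamma_0,\vartheta) =
  (1.8\,\mu\mathrm{J\,m^{-2}},\,1.5\times10^{-10})$ with the constant
  tension form — the values fitted in the source experiment; under this
  package's thermodynamics they place the critical sizes at 15–45 µm
  across the four rates, squarely in the observed window.
* **FRAP traces / fusion events**: exact single-exponential curves with
  multiplicative noise; truths $\tau = d^2/16D$ and
  $\tau = (d_1+d_2)/2v$ recorded alongside.

What a green end-to-end test establishes: that the pipeline's transport,
rate integral, Poisson statistics and optimiser are mutually consistent and
statistically calibrated — not that the physical model is correct for any
real system, and not the published parameter values themselves, which are
not reproducible from printed data alone. The generators also idealise
reality: no size-dependent detection limits, no void-void interaction, no
optical censoring of small voids, monodisperse $M_w$.

The tension atlas shipped in `inst/extdata/tension_atlas_synthetic.csv` is
a clearly labelled *synthetic stand-in*: system names follow published
condensate/solid systems but tensions and molecular weights are
representative order-of-magnitude values (condensates 0.2–200 µJ/m²,
solids 0.4–12 mJ/m², the insulin range following the published 2–12 mJ/m²).
Conclusions drawn from it are ordering statements, not system-specific
values.

# Measurement reduction

FRAP recovery and fusion relaxation are single-exponential fits; both use
variable projection (amplitudes are linear for fixed $\tau$, so only
$\ln\tau$ is optimised by a grid scan plus golden-section polish), which is
exact on noiseless data. The diffusivity follows as $D = d^2/(16\tau)$ with
the prefactor 16 adopted verbatim. The printed capillary-velocity relation
"$v = \gamma/\eta = 2\tau_{fusion}/(d_1+d_2)$" is dimensionally
inconsistent as typeset (it has units of s/m); the implementation uses the
standard estimator $v = (d_1+d_2)/(2\tau_{fusion})$. Viscosity follows from
Stokes-Einstein, $\eta = k_BT/(6\pi D R_h)$, with the hydrodynamic radius
bounded by 5 and 20 nm; note that for $D = 1.3\times10^{-13}$ m²/s and
$R_h = 20$ nm this gives $\eta \approx 0.09$ Pa s, which combined with
measured capillary velocities reproduces tensions of order 0.1–1 µJ/m².

# Known limitations

* The dilute binodal of the $M = 2000$ parameterisation falls steeply with
  temperature; at 36 °C it predicts 0.08 mg/mL, likely below what the
  underlying measurements could resolve. All void-nucleation quantities
  inherit this extrapolation through $v_{m,-}$.
* The critical-size fit's $(\gamma_0,\vartheta)$ ridge means $\vartheta$ is
  only order-of-magnitude identifiable from critical sizes alone.
* No viscoelasticity, no void-void interaction, no post-nucleation
  feedback on the concentration field, no multi-component thermodynamics,
  no time-lag (non-stationary) nucleation corrections.
* Above-critical tension forms are undefined above $T_c$ by construction;
  calls there are domain errors rather than extrapolations.
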