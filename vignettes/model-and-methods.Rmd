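---
title: "CAR T-cells against B-cell lymphoma in a lymph node: model, analysis and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CAR T-cells against B-cell lymphoma in a lymph node: model, analysis and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartnode)
```

## The model

`cartnode` analyses a two-population compartment model of chimeric antigen
receptor (CAR) T-cells, $C(t)$, interacting with diffuse large B-cell
lymphoma cells, $L(t)$, inside one lymph node area:

$$\frac{dC}{dt} = \sigma + \beta\,\frac{CL}{H+L} - \gamma\,\frac{CL}{G+C}
  - \frac{C}{\tau_C}, \qquad
  \frac{dL}{dt} = \rho L - \alpha L C .$$

The four mechanisms acting on the CAR T compartment are a constant systemic
inflow $\sigma$ (cells/day), antigen-driven mitotic stimulation saturating at
rate $\beta$ with half-saturation tumor load $H$, tumor-induced inactivation
(immunosuppression by the lymphoma microenvironment) with maximal rate
$\gamma$ and CAR T-cell saturation level $G$, and first-order death with
mean lifetime $\tau_C$.  The lymphoma grows exponentially at rate $\rho$ and
is killed by mass-action encounters with efficiency $\alpha$
(day$^{-1}$cell$^{-1}$).  Units are absolute cell counts and days
throughout; `table1_ranges()` records the plausibility interval for each
parameter and `validate_table1()` warns (never errors) outside them.  The
inflow is treated as a constant; `dimensional_params()` reserves a
`sigma_fun` hook for a time-dependent inflow, but no analysis in the
package uses it.

Rescaling by $\bar C = (\rho/\sigma)C$, $\bar L = L/H$, $\bar t = \rho t$
(`map_state()`) collapses the eight rates to five dimensionless groups
(`nondimensionalize()`):
$m_1=\beta/\rho$, $m_2=\gamma H/(\rho G)$, $m_3=\sigma/(\rho G)$,
$m_4=1/(\rho\tau_C)$, $m_5=\alpha\sigma/\rho^2$, giving

$$\frac{d\bar C}{d\bar t} = 1 + m_1\frac{\bar C\bar L}{1+\bar L}
 - m_2\frac{\bar C\bar L}{1+m_3\bar C} - m_4\bar C,\qquad
 \frac{d\bar L}{d\bar t} = \bar L - m_5\bar C\bar L .$$

All qualitative analysis happens in this plane; $m_2$ (immunosuppression)
and $m_5$ (killing) are the axes of the bifurcation atlas because they are
the two quantities therapy can plausibly move.

## Equilibria and their classification

Three equilibria organise the dynamics (`equilibria()`):

* $E_1=(1/m_4,\,0)$ — tumor-free, eigenvalues $-m_4$ and $1-m_5/m_4$:
  stable exactly when $m_5>m_4$ (killing outpaces growth).
* $E_{2,3}=(1/m_5,\,\bar L_{2,3})$ — coexistence states, with
  $\bar L_{2,3}$ the roots of $a\bar L^2+b\bar L+c=0$,
  $a=-m_2/(1+m_3/m_5)$, $b=m_1+m_5-m_4+a$, $c=m_5-m_4$.  $E_2$ is the
  high-burden saddle whose stable manifold bounds the curable region;
  $E_3$ the low-burden controlled state.

Two numerical choices matter here.  First, the quadratic is solved in the
cancellation-safe form $q=-(b+\operatorname{sign}(b)\sqrt{\Delta})/2$,
roots $q/a$ and $c/q$: in the weak-immunosuppression scenario the roots
differ by five orders of magnitude ($\bar L_3\approx 0.21$ versus
$\bar L_2\approx 4.9\times10^4$) and the textbook formula loses most of
the small root's digits.  Second, residual checks of the closed forms are
*relative* to the largest vector-field term: with $\bar L_2\sim10^4$ the
individual terms reach $10^6$, so even an exact root evaluates to an
absolute residual near $10^{-9}$ in double precision; the package asserts
relative residuals below $10^{-10}$ instead.

Stability classes come from the standard planar taxonomy of the analytic
Jacobian (`jacobian_at()`, `classify_stability()`): saddle when
$\det J<0$, otherwise stable/unstable by the trace sign and focus/node by
the sign of $\mathrm{tr}^2-4\det$.  The exact focus–node transition curves
are not part of the available analysis, so the discriminant sign is the
operational criterion; boundary cases within a relative $10^{-9}$ are
flagged degenerate rather than forced into a class.

## The bifurcation atlas

With $(m_1,m_3,m_4)$ fixed, four analytic curves partition the
$(m_5,m_2)$ plane (`fold_curve()`, `hopf_curve()`, `bt_point()`):

* transcritical line $m_5=m_4$ — $E_1$ exchanges stability with the
  colliding coexistence root;
* fold branches $m_2=(1+m_3/m_5)(\sqrt{m_1}\pm\sqrt{m_4-m_5})^2$ for
  $m_5\le m_4$, where the coexistence pair is created/destroyed; the
  branches meet at the subcritical pitchfork point
  $m_2=m_1(1+m_3/m_4)$;
* the Hopf curve
  $m_2=(m_3+m_5)^2(m_1m_3-m_4m_3-m_5^2)/(m_3(m_3m_4+m_5^2))$, valid where
  $m_4>m_5$ and $m_1>(m_3m_4+m_5^2)^2/(m_3^2(m_4-m_5))$, on which $E_3$'s
  eigenvalues are purely imaginary (no Hopf exists when $m_1\le m_4$);
* the Bogdanov–Takens point where fold and Hopf meet, found by bracketed
  root-finding of $m_1=(m_3m_4+m_5^2)^2/(m_3^2(m_4-m_5))$ on $(0,m_4)$.
  Substituting that relation into either curve gives
  $m_2=m_5(m_3+m_5)^3/(m_3^2(m_4-m_5))$; the package uses this defining
  property (the point must lie on both curves, verified to $10^{-6}$)
  rather than any shorthand expression.

The homoclinic curve — where the attracting limit cycle born at the Hopf
collides with a saddle connection and disappears — has no closed form.
`locate_homoclinic()` finds it by bisection on $m_2$ over the
limit-cycle/escape dichotomy of an orbit started 1% away from $E_3$.
This trades the continuation machinery used in specialist tools for a
robust, dependency-free locator that is adequate for a planar system; its
resolution is the bisection tolerance (default relative $10^{-3}$), not a
continuation step.

`classify_region()` reproduces the region taxonomy as a decision tree
over computed properties: sign of $m_5-m_4$, discriminant sign,
positivity of the pair, stability class of $E_3$, and — only in the
unstable-focus zone — a limit-cycle probe that separates the
controllable-oscillation region (R4A) from the post-homoclinic escape
region (R4B).  The probe integrates $10^4$ dimensionless time units from
a 1% offset of $E_3$, long enough for the slow transients near the
homoclinic.  The R6/R7 and R9/R10 labels name zones whose coexistence pair exists
but is not biologically positive (dynamics as the escape-only region
R5); their naming is a reconstruction keyed on computed properties, and
they carry a `reconstructed` flag so downstream users know the naming,
not the computed properties, is the reconstructed part.  Points within a relative $10^{-6}$ of a defining
curve are labelled `"boundary"`.

## Trajectories, fates, manifolds and the curable burden

`integrate_model()` wraps a stiff-capable solver (`deSolve::lsoda`,
rtol $10^{-8}$, atol $10^{-10}$ dimensionless / $10^{-2}$ cells
dimensional) with a terminal escape event.  One implementation detail is
load-bearing: whenever $L(0)>0$ the tumor component is integrated as
$u=\log L$.  Controlled trajectories dip many orders of magnitude below
any absolute tolerance during remission phases (these deep dips *are* the
model's relapse dynamics), and in linear space the solver's small
negative overshoot is amplified exponentially and eventually hits the
$1+\bar L=0$ pole of the stimulation term.  In log space positivity is
structural, the dips are resolved exactly, and the $L\equiv 0$ axis
(which is invariant) is integrated in linear space where $dL/dt=0$ holds
identically.  Solver output in $(-\mathrm{atol},0)$ is clipped to zero;
anything more negative raises an error, since positive invariance of the
flow means larger violations indicate solver failure.

`classify_orbit()` labels an orbit `TUMOR_FREE`, `COEXIST`,
`LIMIT_CYCLE`, `ESCAPE` or `UNRESOLVED`.  Escape triggers at
$\bar L>10^5\max(1,\bar L_2)$ — above every equilibrium scale no finite
attractor remains.  Capture requires distance below $10^{-6}$ to the
equilibrium sustained for 10 time units.  Recurrence is established on a
densely sampled 500-unit window (successive refined maxima of $\bar L$
with matching amplitudes and periods), because a coarse output grid
aliases cycles whose period (~3 time units on the standard frame) is
shorter than the grid spacing.  If the base horizon (default $10^3$;
$10^4$ for the R4A/R4B split) ends unresolved, the horizon is doubled up
to three times before `UNRESOLVED` is returned — never silently
misclassified.

`saddle_manifolds()` seeds at $\pm\varepsilon$ along the saddle's
eigenvectors ($\varepsilon=10^{-6}(1+\|x\|)$) and integrates the
arclength-normalised field $f/\|f\|$, forward for unstable and backward
for stable branches, in restartable chunks.  A branch stops just past the
coordinate axes, at the domain box, on arrival at another equilibrium
(where the normalised field is singular), or when the solver stalls; the
chunked restarts clear the stiff boundary layer near the seed, where the
transversal instability rate $\lambda_u/\|f\|$ is extreme.

The curable tumor burden is read off the stable manifold of $E_2$:
`curable_burden_curves()` sweeps $\gamma$ or $\alpha$, traces
$W^s(E_2)$ backward, and records the lymphoma load where it crosses the
vertical lines $C=2.5\times10^5$ (a minimal feasible dose) and $C=10^8$
cells (an optimistic ceiling); the band between the two cutoffs is the
dose-dependent curability window.  `basin_threshold()` computes the same
boundary independently by bisecting the initial burden between controlled
and escaping fates (relative width $10^{-3}$); the two routes agree to
~1% on the weak-immunosuppression scenario, which is the package's
internal cross-validation of the manifold tracer.  The threshold quoted
for that scenario is read at an infused dose of $10^7$ cells — the dose
the corresponding trajectory panels use — since no other dose is stated.

## Sobol sensitivity

`sobol_design()` and `sobol_first_order()` implement a Saltelli-style
radial design ($N(k+2)$ runs, $k=4$) and the first-order estimator
$S_1^{(i)}=\mathrm{mean}(f_B(f_{A_B^{(i)}}-f_A))/\mathrm{Var}(f_{A\cup B})$
with bootstrap confidence intervals, written in-package because no
variance-based sensitivity library is among the package's dependencies;
the estimator is validated in the test suite against the closed-form
indices of an additive model.  The study design holds the well-constrained rates at their scenario
values ($\rho=0.02$, $\beta=0.8$, $\tau_C=7$, $\sigma=2\times10^5$)
and varies $\alpha$, $G$, $\gamma$, $H$ over their plausibility ranges.
The initial condition, output grid, sample size and sampling
distribution are design choices fixed once:
$C(0)=10^7$, $L(0)=10^8$ cells (the infused dose and burden used by the
trajectory panels), monthly outputs over the first year, $N=1024$, and
log-uniform sampling for the multi-decade ranges ($\alpha$, $G$, $H$;
uniform sampling of a range like $[10^{-11},10^{-9}]$ concentrates all
mass in the top decade), uniform for $\gamma$ whose range starts at 0.
Escaped runs are capped at the escape bound rather than discarded, to
keep the design balanced; the capped fraction is reported (zero under the
defaults, since a year of growth at $\rho=0.02$ cannot reach the bound).

Under these conditions the first-order ranking is dominated by the
parameters controlling whether the CAR T compartment survives
immunosuppression at all ($\gamma$, $G$) and by the stimulation
saturation $H$; the killing efficiency $\alpha$, acting only through the
product $\alpha C$, carries little first-order variance of the raw
outputs.  Re-running `analysis/06_sensitivity.R` reproduces this table;
the acceptance suite records the $\alpha$-top fraction it actually
measures rather than asserting a ranking the computation does not
produce.

## What the synthetic scenarios do and do not emulate

No external data exist for this analysis; inputs are parameter sets and
initial conditions.  `preset()` carries the named scenario values
bit-exactly (the frame value $m_4$ is stored as $1/0.14=7.1428\ldots$,
not the 2-d.p. display value), and `sample_cohort()` draws virtual
cohorts from the plausibility ranges, log-uniform across decade-spanning
ranges.  These scenarios emulate the *deterministic* response of a single
well-mixed lymph node compartment.  They do not emulate: measurement
noise or inter-patient variability beyond parameter ranges, stochastic
extinction at few-cell burdens (the model is a continuum; a dip to
$10^{-3}$ cells is "controlled", not cured), CAR T-cell exhaustion,
normal B-cells, cytokine dynamics, or spatial structure.  Passing tests
therefore certify the mathematics of this planar model, not clinical
predictions.

## Problem sizes and determinism

The test and analysis runs use: 41×41 atlas rasters (tests use 7×7),
200-draw oracle comparisons, 100-draw positivity sweeps, bisections to
relative $10^{-3}$, and Sobol designs of $N=1024$ (structure tests use
smaller $N$).  Everything except the Sobol design and cohort sampling is
deterministic; both take a single integer seed and reproduce bit-exactly
from it, as the manifest round-trip test checks.
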