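---
title: "Modeling the mitochondrial reticulum on a centrosomal microtubule array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the mitochondrial reticulum on a centrosomal microtubule array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoreticulum)
```

## The model in one page

Mitochondria in most animal cells form a partially connected network (the
chondriome) that is continuously remodeled by fission and fusion while the
organelles ride on microtubules (MTs). `mitoreticulum` couples three layers
of an idealized, spherically symmetric cell whose MTs are grafted at a
central centrosome:

1. **Cytoskeleton.** Each MT is a freely rotating chain (FRC): bonds of
   fixed length $a$ at a fixed bond angle $\theta$ with uniform torsion,
   giving the worm-like-chain (WLC) persistence length
   $L_p = 2a/\theta^2$. Grafted-end directions are uniform on the sphere.
2. **Densities.** Exploiting spherical symmetry, everything is radially
   resolved. The analytic layer provides the end-to-end distance density
   $P(r,\rho)$ of a semiflexible chain section of contour length $\rho$,
   the motor-biased occupancy $\varepsilon(\rho,\psi)$ of MT contour by
   mitochondria, the shell densities
   $Q_j(r) = n_f\int_r^L P(r,\rho)\,\varepsilon^j(\rho)\,d\rho$
   ($j = 0,1,2$), and the occupied-crossing density
   $S_{jj}(r) = Q_j(r)\int Q_j(\xi)\,A(\xi,r)/(4\pi\xi^2)\,d\xi$
   with the spherical-cap factor $A$ over $|\xi - r|\le\sigma$.
3. **Graph dynamics.** The reticulum is a graph of fixed-length edges
   (0.2 µm, the organelle diameter) whose nodes have degree 1 (free end),
   2 (bulk) or 3 (branch). Tip-to-tip fusion and its reverse (bulk
   fission), and tip-to-side fusion and its reverse (branch fission),
   run at ratios $\alpha_1(r)$, $\alpha_2(r)$ set by the cytoskeleton.
   The steady state solves $u_2 = \tfrac{\alpha_1}{2}u_1^2$,
   $u_3 = \alpha_2 u_1 u_2$, $u_1 + 2u_2 + 3u_3 = 2Q_1$ per shell; the
   same reactions drive an exact event-driven (Gillespie) agent-based
   simulation that additionally yields cluster-level statistics.

The reference configuration (the package defaults, `mito_config()`) is a
cell of radius $L = 16$ µm with $n_f = 200$ MTs of $L_p = 32$ µm,
$\sigma = 0.2$ µm, total reticulum length $M = 1$ mm distributed on the
contour interval $[0.5, 15]$ µm, balanced motors ($\psi = 0$), and shells
of width $\Delta r = 0.01L$.

```{r reference}
mito_config()
```

## Parameters that matter

| parameter | meaning | unit | default |
|---|---|---|---|
| `n_fibers` | MTs grafted at the centrosome | — | 200 |
| `L` | MT contour length = cell radius | µm | 16 |
| `Lp` | persistence length | µm | 32 |
| `a` | FRC bond length | µm | 0.02 |
| `sigma` | proximity threshold (organelle diameter) | µm | 0.2 |
| `edge_length` | mitochondrial graph edge | µm | 0.2 |
| `M` | total mitochondrial length | µm | 1000 |
| `l1`, `l2` | occupancy window on the contour | µm | 0.5, 15 |
| `psi` | drift-to-diffusion ratio of MT transport | 1/µm | 0 |
| `gamma` | fusion-to-fission propensity ratio | — | 0.1 |
| `dr` | radial shell width | µm | 0.16 |

`psi` deserves a note on units: the occupancy solves
$\psi\varepsilon - d\varepsilon/d\rho = 0$, so $\psi$ carries 1/µm; the
biases explored in the package ($\pm 0.2$/µm) change the occupancy by a
factor $e^{0.2\,(l_2-l_1)} \approx 18$ across the contour window, enough
to move the chondriome between perinuclear and peripheral clustering.

## The end-to-end density and its two branches

$P(r,\rho)$ is evaluated in the weakly bending (semiflexible) regime from
the stored-length variable $\eta = 1 - r/\rho$ and stiffness
$\kappa = L_p/\rho$. Two exact resummations of the same distribution are
used: an exponential series for $r \le 0.9\rho$ and a Hermite-polynomial
form for $r > 0.9\rho$, which converge quickly on complementary sides of
the split and join continuously (this is tested to $10^{-5}$). For very
stiff sections the series is also used below the split once
$\kappa\eta > 25$, where both branches have decayed to zero but the
Hermite sum would need impractically many terms to cancel to it. Series
terms are capped at 200 with a convergence check that warns on failure.

The truncated weak-bending form integrates to one only approximately
(0.996 at $L/L_p = 1.6$), so the density is always renormalized by
$Z(\kappa) = \int_0^1 g(\eta;\kappa)\,d\eta$, a universal function of the
stiffness that is computed by piecewise adaptive quadrature resolving the
$O(1/6\kappa)$ peak and cached as a spline in $\log\kappa$.

Radial-density integrals run in $\eta$ rather than $\rho$: at small radii
the integrand is a spike of width $\sim r^2/(6L_p)$ next to $\rho = r$
which blind adaptive quadrature can miss entirely; the substitution plus
geometric subdivision of the integration range makes the quadrature
robust at the stated tolerance ($10^{-8}$ relative).

The approximation is quantitatively reliable for $L/L_p \lesssim 1$. The
package's own validation (`recipe_density_validation()`) regenerates
explicit FRC arrays and compares $Q_0/n_f$ and $S_{00}/n_f^2$ with the
analytic curves on the shell grid; because the Monte Carlo histogram
measures shell averages, the analytic curves are shell-averaged too
(3-point Gauss rule) — comparing bin means against bin-center values
misstates the steeply curved tail by several percent. At Monte Carlo
precision of order 0.1% (100 seeds × 300 fibers), small systematic
residuals of the leading-order form — a fraction of a percent in the
curve body, a few percent in the extreme tail, where the discrete chain
and the continuum limit genuinely differ — become statistically visible;
they are far below the resolution at which the analytic and simulated
curves are indistinguishable when plotted.

Near the centrosome the crossing formula needs one geometric amendment:
when the proximity ball at $r < \sigma$ swallows an entire sphere of
radius $\xi \le \sigma - r$, the overlap is the full sphere area
$4\pi\xi^2$ rather than a cap. Crossing statistics are still only
compared to simulation for $r > 4\sigma$: closer to the centrosome,
convergences of three and more fibers — outside the two-fiber scope of
the model — dominate the geometry.

## Occupancy and the carrying capacity

$\varepsilon(\rho)$ is a coverage fraction, zero outside $[l_1, l_2]$,
uniform for $\psi = 0$ and exponential otherwise, normalized so that
$n_f\int\varepsilon = M$. Normalization can push
$\max\varepsilon$ above one — the requested mass then exceeds what the
cytoskeleton can carry at that bias. At the reference mass the strongest
biases considered ($\psi = \pm 0.2$/µm) overshoot marginally
($\max\varepsilon = 1.058$ at the window edge). A hard failure would
make exactly those regimes uncomputable, so the default flags the
overshoot as a warning ("overloaded cytoskeleton"); `capacity = "error"`
enforces strictness, and the profile is never clipped, because clipping
would silently destroy mass conservation ($\int Q_1\,dr = M$, which is
tested to $10^{-3}$ and holds to $10^{-8}$).

## The rate fields

Tip-to-tip fusion is supported by any fusion-competent apposition of two
organelles — pairs superimposed on one fiber ($Q_2$) and occupied
crossings ($S_{11}$) — while branching requires two proximal fibers and
is limited by occupied crossings alone. The package therefore uses

$$\alpha_1(r) = \gamma\,\chi\,\bigl(w\,Q_2(r) + S_{11}(r)\bigr), \qquad
  \alpha_2(r) = \gamma\,\chi\,S_{11}(r),$$

with weight $w = 1$ and a single scale constant $\chi$ (`rate_scale`).
An alternative intensive normalization by $Q_1(r)^p$ is exposed
(`q1_exponent`); it is kept at $p = 0$ because normalizing by $Q_1^2$
suppresses branching by four orders of magnitude at the reference
density, leaving no branching-dominated perinuclear zone, no partition
border and no supercluster at any $\gamma$ — it cannot produce the
radial structure the model exists to describe.

$\chi$ is the one genuinely free constant. It is calibrated once against
the reference phenomenology: with $\chi = 0.25$ the mean segment length
at mid-cell peaks at $\gamma^{\max} \approx 0.1$ — the physiological
fusion–fission balance — at about 1 µm, rising towards the periphery.
The calibration is a model-level choice, not a fit to data, and all
structural conclusions (unimodality of $s(\gamma)$, node-fraction
crossover, monotone growth of the partition border with $\gamma$, the
$\psi$-driven reversal of radial clustering) are insensitive to its
exact value. A known consequence of this rate form is that the innermost
shells, where crossings are dense, have segments shorter (0.3–0.6 µm at
$\gamma = 0.1$) than the micrometer-scale perinuclear segments reported
for real cells; the branching-to-sequential balance very close to the
centrosome is the least constrained part of the model.

```{r steady, eval = FALSE}
cfg <- mito_config()
profiles <- density_profiles(cfg)
ss <- solve_radial_steady_state(cfg, gamma = 0.1, profiles = profiles)
partition_border(ss)   # ~1.7 um at gamma = 0.1
```

## Stochastic layer

Each radial shell is simulated as an independent well-mixed reaction
system (there is no transport of nodes between shells at steady state —
consistent with solving shells independently in the deterministic
layer). Three choices the continuous model does not dictate:

* **Edge allocation.** Shell $i$ receives edges in proportion to
  $Q_1(r_i)\Delta r$, rounded by largest remainder so the total is
  exactly `round(M / edge_length)` = 5000 edges: the simulated graph
  carries exactly 1 mm of reticulum, before and after any number of
  events (fission and fusion conserve edges).
* **Volume scaling.** Bimolecular propensities are divided by
  $\Omega = n/Q_1(r)$, which makes count-level mass action match the
  density-level shell equations; ensemble means at $n = 5000$ edges
  agree with the deterministic solution to within Monte Carlo error
  (tested at 3 standard errors over 100 runs).
* **Self-loops.** Fusing the two ends of a single edge onto each other
  would create a loop below the graph's resolution and is excluded —
  exactly, by subtracting the forbidden pair counts ($n_{\rm iso}$
  isolated edges; $n_{\rm mix}$ edges with endpoint degrees {1,2}) from
  the propensities, not by rejection alone. Cycles spanning two or more
  edges are allowed.

Equilibration follows "burn in, then verify": a burn-in of 20 events per
edge, then a comparison of the first and second half of the sampling
window (u1/u2 snapshot means at the 95% level), doubling the burn-in up
to twice more if a trend remains. Each ensemble run is recorded once
after equilibration; cluster statistics aggregate those final states.

The engine is validated against two independent oracles: the exhaustive
continuous-time Markov chain of all reachable graph states for systems of
up to 4 edges (exact linear solve of the stationary law; χ² on
time-spaced samples), and long-time ODE integration of the mass-action
system (`deSolve`) for the deterministic shells.

## What the generator emulates — and what it does not

The cytoskeleton Monte Carlo and the shell ensembles are the package's
synthetic data: they realize exactly the study conditions above
(spherical symmetry, equal fiber lengths, static fibers, fixed total
mass). Passing tests therefore demonstrate internal consistency of the
model chain — analytic densities against explicit fiber arrays,
deterministic against stochastic dynamics — under those idealizations.
They do not show that a real cell obeys the model: MT dynamic
instability, non-spherical geometry, organelle transport between shells
during remodeling, ER-assisted fission, and finite fiber thickness
(beyond the negligibility argument for 25-nm MTs at σ = 200 nm) are all
outside scope.

## Problem sizes used by the test-suite

The suite exercises the full reference scale where the claim demands it
(100-seed × 300-fiber density validation; 5000-edge stochastic runs;
100-run ensembles) and scaled-down systems elsewhere (tens to hundreds
of edges, 2–4-edge oracle systems, 120–300 chains for stiffness
recovery), chosen so the whole suite completes in well under half an
hour on a single core.

## Known limitations

* The analytic $P(r,\rho)$ is leading-order weak bending; beyond
  $L/L_p \approx 1$ (e.g. $L_p = 10$ µm at $L = 16$ µm) it remains a
  shape approximation with percent-level body errors and larger tail
  errors, and the package treats it as such in its validation recipe.
* The rate-field normalization and scale are model choices calibrated to
  reference behavior (see above); absolute values of $\gamma$ are
  therefore meaningful relative to this package's convention, not
  transferable to other parameterizations.
* Near-centrosome shells mix two-fiber and higher-order crossing
  geometry; quantities there are reported but not validated.
* Shells are statistically independent; spatial correlations of the
  reticulum across shell boundaries (one cluster spanning shells) are
  not represented — cluster statistics are per-shell.
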