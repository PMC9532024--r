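---
title: "Modelling collateral flow and permeable thrombi with collatflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling collateral flow and permeable thrombi with collatflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`collatflow` simulates steady-state cerebral blood flow on synthetic
vascular networks during health and acute ischaemic stroke. This
vignette is the package's account of the science: the model and its
assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, the numerical choices, and the limitations.

## The flow model

Blood is treated as an incompressible Newtonian fluid at steady state —
every variable is the average over a heartbeat, so pulsatility, wave
propagation and time-dependent autoregulation are outside the model. On
a graph of short vessel segments the nodal pressures satisfy Kirchhoff
mass balance, $\sum_j G_{ij}(P_i - P_j) = Q_i$, a weighted graph
Laplacian system solved by sparse LU decomposition. The segment
conductance is

$$G = \frac{\pi r^4}{2(\zeta + 2)\mu L},$$

where $\zeta$ encodes the axial velocity profile: $\zeta = 2$ recovers
the parabolic Poiseuille profile ($R = 8\mu L/\pi r^4$), while the
default $\zeta = 9$ represents the blunter profile observed in cerebral
arteries and arterioles. The profile is assumed uniform across the
network; how it really varies along the vascular tree is not well
characterised, which is a modelling assumption rather than a fitted
quantity.

Vessels are linearly elastic thin-walled tubes,

$$P = P_0 + \frac{Eh}{r_0^2(1-\nu^2)}(r - r_0),$$

with Poisson ratio $\nu = 0.5$ (incompressible wall), Young's modulus
1.6 MPa for cerebral vessels (larger systemic vessels carry their own
moduli in the systemic table), and a wall thickness
$h = r_0(a e^{b r_0} + c e^{d r_0})$ from an empirical fit to human
measurements ($a = 0.2802$, $b = -0.5053\,\mathrm{mm^{-1}}$,
$c = 0.1324$, $d = -0.01114\,\mathrm{mm^{-1}}$). The implied
distensibility $(dA/dP)/A$ is of order $10^{-6}\,\mathrm{Pa^{-1}}$ at
the 0.2 mm pial radius, consistent with clinical measurements — the
vessels are stiff enough that the elastic coupling converges in a few
fixed-point iterations, but compliant enough that radii respond to the
pressure field.

$P_0$ is the reference (diastolic) pressure at which $r = r_0$; the
package defaults it to 80 mmHg as a configuration scalar
(`solver.reference_pressure_Pa`).

### Boundary conditions and calibration

The heart inlet must satisfy two conditions at once: pressure
$p_{in} = 12\,500$ Pa and cardiac output $Q_{in} = 100$ ml/s. The
venous side is a fixed $p_{out} = 666$ Pa behind every outlet. The free
parameter is a single common factor on all outlet resistances:
`calibrate_network()` pins the inlet pressure, solves the full
compliant system, and rescales all outlet resistances by the ratio of
simulated to target inlet flow until the flow matches to $10^{-6}$
relative (typically about five rescalings). The pressure condition then
holds exactly by construction. Calibration runs once, on the healthy
network, before autoregulation — stroke runs reuse the calibrated
resistances as their starting point and are never re-calibrated.

### Autoregulation

Each penetrating-artery outlet aims at an equal share of cerebral flow,
$q = Q_{brain}/N_{total}$ with $Q_{brain} = 12.5$ ml/s. After each full
elastic solve, every outlet resistance is updated synchronously to
$R = (P_i - p_{out})/q$ and clamped to $[P_{low}/q,\; P_{upp}/q]$ with
$P_{low} = 10$ mmHg and $P_{upp} = 100$ mmHg — the limits of maximal
dilation and constriction. The loop stops when the largest relative
update falls below $10^{-6}$; because the check runs *before* the
update, the reported flows, pressures and resistances are mutually
consistent, and every unclamped outlet provably sits within the
tolerance of its set-point. An optional damping factor (default 1,
automatically halved if the residual stalls) stabilises oscillatory
cases without moving the fixed point. Whether clamping is applied
before or after the linear solve within an iteration only affects the
iteration count, not the fixed point.

### The thrombus

A permeable thrombus is a Darcy porous medium: integrated over a span
of length $L$ and lumen area $A = \pi r_0^2$,
$R_{thrombus} = \mu L/(\kappa A)$. The total resistance of the
clot-bearing vessel is the series sum $R_T = R_{thrombus} + R_{vessel}$,
and the package deliberately treats the whole host vessel as a single
rigid hydraulic element of resistance $R_T$ (distributed over its
discretized segments in proportion to length). This makes the central
collapse property exact: pressure drop and through-flow depend on
$(\kappa, L)$ only through $R_T$, so a short impermeable clot and a
long permeable one with equal $R_T$ are indistinguishable — which is
also why the patient inversion can only ever recover an *effective*
permeability. A fully occluding clot ($\kappa = 0$) removes the
proximal segment's conductance entirely (no large-but-finite
resistance, avoiding conditioning artifacts); the remaining flowless
segments keep a rigid conductance so their interior nodes stay
hydraulically tied to the distal pressure rather than floating.

The critical resistance scale at which a clot begins to matter is set
by the downstream microcirculatory resistance it competes with. In
interface units this is of order $10^3$ Pa s/ml on the study network —
numerically the same magnitude as $10^9$ Pa s m$^{-3}$, and the package
reports resistances in Pa s/ml while converting exactly (1 Pa s/ml =
$10^6$ Pa s m$^{-3}$) rather than hard-coding any threshold.

### Infarct volume

An outlet is infarcted when its fractional flow change
$\Delta Q = (Q_{healthy} - Q_{stroke})/Q_{healthy}$ reaches the
perfusion threshold 0.4 — i.e. at most 60% of its healthy flow remains;
the tie is counted as infarcted. The infarct volume is the affected
share of brain volume, $IV = V_{brain} \cdot N_{infarcted}/N_{total}$
with $V_{brain} = 1390$ ml. The threshold is a penumbra-style proxy,
not a mechanistic tissue-death model; the healthy baseline is always
recomputed on the same network realization (paired per outlet), never
shared across seeds.

## The synthetic vasculature

The generator emulates the *topology* of a patient-derived cerebral
network without any imaging data:

* **Pial surface** — the dual graph of a uniformly triangulated sphere
  (subdivided icosahedron): one node per triangle, so the pial mesh is
  hexagonal with every node of degree 3. All pial vessels have the
  0.2 mm reference radius. The sphere radius defaults to 50 mm.
* **Territories** — fixed angular sectors approximating the eight major
  perfusion territories (left/right ACA, MCA, PCA, cerebellum,
  brainstem). Pial vessels whose endpoints straddle two territories are
  the leptomeningeal collateral candidates; a collateral score
  $p \in [0,1]$ keeps each candidate independently with probability
  $p$, resampled per seed.
* **Feeding trees** — per territory, a Murray-law bifurcating tree
  ($r_{parent}^3 = r_1^3 + r_2^3$, split fractions proportional to the
  pial-node count served by each branch, branch length = 10 radii)
  built by recursive spatial bisection of the territory's pial nodes,
  terminating at one pial node per leaf or at the 0.25 mm terminal
  radius, whichever comes first (the radius tie terminates,
  inclusively, for determinism).
* **Systemic tree** — a small surrogate table of large arteries (heart
  to circle of Willis) with literature-typical radii, lengths and
  moduli, shipped as `systemic_vessels_synthetic.csv` and
  user-overridable. Its absolute resistances are non-critical because
  boundary calibration rescales all outlet resistances anyway. Circle
  of Willis variants are not modelled. The right-MCA root vessel
  (`root_R-MCA`, 1.4 mm radius, 30 mm) is the default occlusion site.
* **Outlets** — one penetrating artery per pial node, modelled as a
  lumped resistance element to the pinned venous pressure. A published
  "penetrating artery density of 1 mm$^{-1}$" has ambiguous units, so
  the outlet count is exposed directly instead: `surface_resolution`
  $k$ gives $20 \cdot 4^k$ outlets (1280 at the default $k = 3$).

Every vessel is discretized to at least three nodes and at most 2.5 mm
per segment before solving.

### What desk scale does and does not show

Patient-derived meshes carry on the order of $10^5$ outlets; the
package's study network carries 1280 and its property-check networks 80
to 320. Physics that survives this scaling — boundary calibration,
set-point autoregulation, the $R_T$ collapse, monotone responses to
permeability and collateral density, and the inversion round-trip — is
what the test suite verifies. What does *not* survive is the absolute
collateral efficacy: per-outlet demand $q$ grows as $1/N_{total}$
shrinks while pial vessel resistance per edge falls only slowly, so on
the 80-outlet surface collaterals cannot rescue any outlet, on 320
outlets they begin to differentiate, and on 1280 outlets a full
occlusion spans a clean monotone infarct range (about 160 ml down to
100 ml across collateral scores). Published patient-scale per-grade
infarct volumes and calibrated collateral probabilities therefore
cannot be reproduced here; they ship as a documented reference table
(`collateral_grade_targets()`) and serve as default targets for
`calibrate_collateral_probability()`, which re-derives the probability
mapping for whatever mesh it is given. For the same reason, passing
tests on synthetic spheres says nothing about anatomical realism —
territory shapes, vessel tortuosity and collateral heterogeneity are
all idealised.

## Patient-measurement inversion

The measured flow through an occlusion is $Q = \epsilon A_{MCA}
L/\Delta t$ (void fraction × contralateral lumen area × thrombus length
/ transit time). Per collateral grade, `build_response_curve()`
tabulates the simulated mean flow through the clot over a resistance
grid spanning $10^2$–$10^9$ Pa s/ml (15 knots, averaged over seeds with
collaterals resampled; 5 seeds by default), together with the pressure
drop, the infarct volume, and a fully-occluding reference run.
Inversion interpolates log–log between knots; measured flows above the
healthy branch are clamped to it with a per-patient warning, zero void
fraction maps to the fully-occluding branch, and permeability follows
exactly as $\kappa = \mu L/(A(R_T - R_{vessel}))$. The flow–resistance
curve flattens at both ends (healthy plateau, occlusive tail
$Q \approx \Delta p_{max}/R_T$), so inversion is best conditioned in
the transition region — which is where clinically plausible
measurements land.

A synthetic cohort generator stands in for clinical measurement tables:
log-uniform transit times 1–30 s, uniform void fractions 0–0.5,
thrombus lengths 3–28 mm (the clinically observed range), lumen areas
3–8 mm², reproducible under a seed; 44 patients mirrors the cohort size
the measurement pipeline was designed around.

## Numerical choices

* Internal units are strict SI (Pa, m, m³/s); interfaces speak mm,
  mmHg, ml/s, Pa s/ml with exact constants (1 mmHg = 133.322 Pa).
  Blood viscosity is 3.5 mPa s.
* Elastic fixed point: under-relaxation 0.7 on radius updates;
  convergence when the relative pressure change (infinity-norm ratio,
  configurable to component-wise) is below $10^{-6}$. The converged
  answer is relaxation-independent (tested).
* Radii update from the mean of the segment's endpoint pressures;
  velocities use the mean-radius cross-section.
* Outlet resistances are initialized at the autoregulation set-point
  $(p_{in}-p_{out})/q$; the initialization is erased by calibration
  (tested from perturbed starts).
* Degenerate inputs fail loudly: a component with no pressure boundary
  names its nodes, a collapsing radius names its segments, unknown
  configuration keys and all violated invariants are reported at once.
* Problem sizes in the shipped tests: resolution 3 (1280 outlets,
  ~12 500 segments) for study-scale boundary and autoregulation checks,
  resolutions 1–2 for per-thrombus properties, 20 forward-simulated
  patients for the inversion round-trip (median $|\Delta \log_{10}
  \kappa|$ well under 0.15), 50-node random graphs against a dense
  solver oracle at $10^{-10}$.

## Limitations

Steady-state only; Newtonian rheology; no thrombolysis or clot
mechanics (permeability is effective and homogeneous); no circle of
Willis variants; the infarct threshold is a static penumbra proxy; the
synthetic sphere is a topological, not anatomical, stand-in; collateral
efficacy depends on mesh resolution, so probability-to-grade mappings
must be re-calibrated per mesh.
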