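---
title: "Coupled mesh–meshless soft-tissue cutting: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled mesh-meshless soft-tissue cutting: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuecut)
```

## The model

Surgical cutting changes topology, which is where purely mesh-based soft-tissue
models struggle (remeshing, sliver elements, instability) and where purely
meshless models struggle instead with boundary conditions and surface
rendering. `tissuecut` implements a coupled representation:

* the **surface** is a triangle mesh carrying the visible incision, modelled
  with two quadratic Bézier curves;
* the **interior** is a cloud of meshless *point elements* deformed by
  moving-least-squares (MLS) displacement-gradient elasticity;
* **virtual points**, interpolated on the incision boundary, tie the two
  together: they carry the surface opening into the meshless solve as
  prescribed (Dirichlet-style) displacements and are never rendered.

### Surface incision

A cutting path is a sequence of surface vertices. The chord runs from the
first path vertex `A` to the last, `B`. All vertices of triangles touching the
path form the cutting-affected region; they are split into a positive and a
negative side by the sign of $((B-A)\times(P-A))\cdot \hat n$, with $\hat n$
the patch normal (points exactly on the chord count as positive — a fixed tie
rule). The farthest point on each side becomes the middle control point of a
quadratic Bézier curve through `A` and `B`:

$$P(t) = (1-t)^2 P_0 + 2t(1-t)P_1 + t^2 P_2, \qquad t \in [0,1].$$

The two sampled curves bound the wound. `remesh_incision()` realizes the
opening by vertex duplication — the standard idiom in cutting simulation:
interior path vertices are split into left/right copies assigned by triangle
centroid side, the copies are moved onto the sampled curves, and remaining
curve samples are inserted by fanning the adjacent boundary triangle from its
opposite vertex. Chain parameters are snapped to sample parameters so the
final free boundary *is* the sampled polyline, in order. Degenerate (chordal)
curves skip sample insertion, leaving the closed chord as the boundary.

Collision detection against a physical tool is out of scope; the cutting path
is extracted analytically by intersecting the blade plane with the surface
edges, snapping each crossing to its nearest endpoint, and keeping vertices
under the blade segment and above the cutting depth.

### Level-set classification

The scalpel is a tip $P$, a handle point $P'$ and a vertical direction
$\hat v$. The blade plane contains $P$, $P'$ with normal
$\hat n_b = \widehat{(P'-P)\times\hat v}$; the vertical plane sits at the cut
depth with normal $-\hat v$. Both are tracked as signed-distance level sets.
Because the blade moves rigidly, re-computing signed distances from the
current pose solves the advection equation $\varphi_t + v\cdot\nabla\varphi=0$
exactly; a grid-based upwind solver exists only as a test oracle. Points at
height $\psi \le 0$ relative to the vertical plane are *unaffected* and are
skipped entirely by the solver (their state is bit-identical across steps —
this is the model's efficiency contract). Above it, the blade-plane sign
yields the `+` and `−` flaps; $\varphi = 0$ goes to `+` (tie rule). The
reported $\psi$ is the height above the vertical plane measured along
$+\hat v$, so "affected" is always $\psi > 0$.

### Meshless elasticity

Displacement gradients are estimated per point from weighted neighbor
differences with the compact kernel $\omega(r) = (1-(r/h)^2)^3$ for $r<h$
(a Wendland-type polynomial: smooth, cheap and standard; the formulation
itself leaves the weight open). With rest offsets $d_{ij} = x_j - x_i$ and moment matrix
$M_i = \sum_j \omega_{ij} d_{ij} d_{ij}^T$,

$$\nabla u_i = M_i^{-1}\sum_j (u_j - u_i)\, d_{ij}\, \omega_{ij},$$

which reproduces affine fields exactly — the module's primary oracle. Strain
is Green's tensor $\varepsilon = \tfrac12(\nabla U + \nabla U^T + \nabla U^T
\nabla U)$; the quadratic term is chosen in the form that vanishes under
rigid rotation, which is the physically required reading. Stress is the
single-parameter Hookean law $\sigma = E\varepsilon$. Forces use the per-point
matrix $B_i = -2 v_i (\nabla U_i + I)\,\sigma_i\, M_i^{-1}$ distributed over
neighbor pairs, $f_j \mathrel{+}= B_i d_{ij}\omega_{ij}$,
$f_i \mathrel{-}= B_i d_{ij}\omega_{ij}$. The sign conventions are fixed so
that elastic forces oppose the deformation (restoring) — this matches the
Müller-style point-based elasticity the formulation derives from, and makes
the pairwise terms exactly antisymmetric, so linear momentum is conserved to
round-off in free runs.

Integration is explicit Euler with optional per-step velocity damping $c$:
$\dot U \leftarrow (1-c)(\dot U + \Delta t\, f/m)$,
$U \leftarrow U + \Delta t\,\dot U$, and current positions are always
*rest + displacement* so no drift accumulates. The undamped integrator is
conditionally stable only; damping is an artifact extension (default 0).

### Coupling and cutting the continuum

Virtual points are placed at uniform interpolation weights on each sampled
incision polyline edge, tagged `+`/`−` by curve. Their prescribed
displacement is $\pm s(t)\,\kappa\,\hat n_b$ where $s(t)$ is half the local
separation of the two curves and $\kappa$ the `opening_scale`; the two sides
are exact opposites at matched parameters, so the prescription is
self-balancing and vanishes for degenerate cuts. How incision width maps to
the prescribed opening is a genuinely open design point; the half-separation
rule makes the interior opening track the surface incision by construction.

One further ingredient is required that the continuum formulation leaves
implicit: the blade separates the flaps, so neighbor pairs crossing the cut
must be severed (`sever_cut_pairs()`), otherwise the intact continuum
elastically resists the prescribed opening and the wound pulls shut (easily
demonstrated on a symmetric slab). Pairs involving unaffected points are
kept, hinging the flaps at the intact tissue below the cutting depth. Moment
matrices of pruned neighborhoods are rebuilt, and points left with fewer than
4 neighbors become rigid.

Virtual points are constraints, not matter: they are excluded from momentum
bookkeeping, never integrated, and regenerated per scalpel pose.

### Force feedback

Measured cutting forces oscillate around a downtrending value, so the
computed force is modulated by $\Gamma(t,d) = e^{-at}\sin(bt)\,k d$ with a
linear depth factor (defaults $a = 1\,\mathrm{s^{-1}}$,
$b = 2\pi\,\mathrm{rad\,s^{-1}}$, $k = 1$, chosen to show a visible ~1 Hz
oscillation in demo runs; these are free parameters of the model). The recorded feedback
series takes the reaction forces accumulated at the virtual points — the
wound boundary is what the blade feels — and scales them by $\Gamma$. The
published empirical porcine-liver fit
$f(x) = a_1 e^{-((x-b_1)/c_1)^2} + a_2 e^{-((x-b_2)/c_2)^2}$ with
$a_1=15.29$, $b_1=3.164$, $c_1=0.2933$, $a_2=27.69$, $b_2=3.288$, $c_2=1.746$
is included for comparison, along with the RMSE error measure
$\sqrt{\sum_i (f_i - f_i^*)^2 / N}$.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `E` | force/mm² | 1 | single material stiffness; only sets the force scale |
| `h` | mm | 2.2 × spacing | ≥ 10 interior neighbors on a lattice |
| `dt` | s | 0.01 | comfortably below the explicit stability bound at the defaults |
| `damping` | — | 0 (solver), 0.3 (demo) | quasi-static tissue response, suppresses ringing |
| `density` | g/mm³ | 1 | masses `density × spacing³`; free parameter |
| `samples_per_curve` | — | 16 | incision smoothness |
| `per_edge` | — | 1 | virtual points per boundary edge |
| `opening_scale` | — | 1 (demo 0.5) | maps curve separation to prescribed opening |
| `steps_per_pose` | — | 10 | fixed-iteration realization of the bounded search |

## Synthetic geometry

"Equal-distance interpolation" of the interior is realized as an axis-aligned
lattice clipped to the solid (box: inclusive of faces, anchored at the
minimum corner; ellipsoid: centred), matching the regular point pattern such
reconstructions show. Box surfaces default to the minimal 12-triangle
triangulation; `surface_segments` subdivides each face so cutting paths exist
on synthetic models. A 250 × 150 × 50 mm box at spacing 12 mm gives ~1365
interior points — the order of the reconstructed-liver point budget (508
triangles / 1526 points); the generator treats those counts as descriptive,
not reproducible, since no interior spacing accompanies them.

What the generators do *not* emulate: organ-shaped boundaries with curvature
(the ellipsoid is a crude stand-in), inhomogeneous or anisotropic material,
viscoelasticity, and contact with a physical tool. Passing tests therefore
show internal consistency of the algorithms at desk scale, not biomechanical
fidelity on real organs.

## Numerical choices and degenerate inputs

* Moment matrices with condition number above 1e8 get Tikhonov
  regularization $\epsilon I$, $\epsilon = 10^{-9}\,\mathrm{tr}(M)/3$, and are
  flagged; points with fewer than 4 neighbors are rigid (zero gradient).
* Tie rules, all documented and tested: on-chord points are positive;
  equidistant control-point candidates take the lowest index; $\varphi = 0$
  classifies as `+`; points exactly on the vertical plane are unaffected;
  plane-crossing snaps prefer the lower-index endpoint.
* Empty path → no-op cut; degenerate curves → boundary stays the chord;
  zero depth → zero affected points and a bit-identical no-op step.
* Non-finite forces abort with the offending point index rather than
  propagating NaNs.

## Study sizes and stability of the kinetic norm

The shipped property suite runs at desk scale, chosen to exercise every code
path at tight tolerances: clouds of 200–2000 points for affine reproduction,
a 1000-point lattice for momentum conservation (100 steps), a 343-point
lattice for energy decay (500 steps), and straight-cut sessions on a 64-point
box with a 3×3-subdivided surface (15 poses × 20 steps). A full session runs
in under a second.

On damping: with $c > 0$ and *no elastic input* (uniform drift), the kinetic
norm $\sum_i m_i\|\dot U_i\|^2$ contracts by exactly $(1-c)^2$ per step —
strictly monotone. For deforming initial motion, individual modes exchange
kinetic and elastic energy; even overdamped modes pass their kinetic energy
through zero and rebound, so pointwise monotonicity is not a theorem. What
holds robustly — and what a damped-iteration stability analysis actually
bounds — is domination by the initial value; the suite asserts
strict monotone decay for the drift state and boundedness plus >95%
dissipation for a smooth deforming field.

## Known limitations

* Linear single-parameter constitutive law; no anisotropy, viscoelasticity
  or incompressibility constraint.
* Explicit integration is conditionally stable; the package does not pick
  `dt` automatically.
* Remeshing assumes a simple, non-self-intersecting, edge-connected path;
  paths that skip across non-adjacent vertices leave that interval's
  boundary at the chord.
* One blade; no bleeding, suturing, or rendering — file export only.
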