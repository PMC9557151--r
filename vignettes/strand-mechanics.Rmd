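---
title: "Strand mechanics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand mechanics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandmech)
```

Claudins polymerize into tight-junction strands — linear polymers of
tetrameric ion channels running through the membranes of adjoining cells.
How stiff such a strand is in the membrane plane, and how single residues on
the third transmembrane helix (TM3) change that stiffness, are questions one
answers from simulation trajectories with a small set of geometric
estimators. This vignette documents the models behind each estimator in this
package, the tunable parameters, and the choices made where the design was
genuinely open.

## The strand as a 2D worm-like chain

A strand is reduced to one point per tetramer (the center of mass of its
four claudins), projected into the membrane plane. For the resulting
discrete polymer with points $\vec r_i$ the tangent at an interior point is
the central difference

$$\vec\tau_i = \frac{\vec r_{i+1}-\vec r_{i-1}}{|\vec r_{i+1}-\vec r_{i-1}|},
\qquad \phi_i = \operatorname{atan2}(\tau_{i,y}, \tau_{i,x}),$$

the local contour fragment is
$\delta s_i = \tfrac12(|\vec r_{i+1}-\vec r_i| + |\vec r_i-\vec r_{i-1}|)$,
and $\delta s$ is the flat (count-weighted) average of all $\delta s_i$ over
positions and frames. For a two-dimensional worm-like chain the tangent
correlation decays as

$$\langle\cos(\phi(s)-\phi(0))\rangle = e^{-s/2l_p},$$

with the factor of two in the denominator specific to two dimensions (in 3D
it is absent; the package hardcodes the 2D convention because the strand is
confined to the membrane plane). `fit_persistence_length()` regresses
$\ln C(k)$ on $s = k\,\delta s$ and reports $l_p = -1/(2\,\text{slope})$.

Three estimator choices deserve a record:

* **Pooling.** $C(k)$ is a single ensemble average: cosines of angle
  differences are pooled over all position pairs at lag $k$ and all frames,
  and the logarithm is taken once, of the pooled mean. Pooling maximizes
  the sample count at large lags, where pairs are scarce.
* **Prefix selection.** The fitted range is the longest lag prefix
  $k = 1..K$ (with $K \ge 3$) whose ordinary-least-squares fit reaches
  $R^2 \ge 0.95$. Lags where $C(k) \le 0$ terminate the usable range (the
  log is undefined); if no prefix reaches the cutoff the three-lag fit is
  reported with a `"r2 below cutoff"` flag rather than silently passing.
  A non-negative slope is flagged `"no measurable decay"` with $l_p$ unset —
  the infinitely stiff limit is an answer, not an error.
* **Free intercept.** The central-difference tangent at point $i$ is the
  bisector of the two adjacent segment headings, so for the Gaussian chain
  the variance of $\phi_{i+k}-\phi_i$ is $\sigma^2(k-\tfrac12)$, not
  $\sigma^2 k$: discretization shifts $\ln C$ by a constant
  $+\sigma^2/4$ independent of $k$. A free intercept absorbs this shift
  exactly; forcing the line through zero would fold it into the slope and
  bias $l_p$. Only the slope is interpreted.

Tangent angles appear exclusively inside cosines of differences, so no
angle unwrapping is needed anywhere.

## Local curvature

Curvature at position $i$ is $1/r_i$ with $r_i$ the radius of the
least-squares circle through the window $i-5..i+5$ (half-width
configurable). The fit is the algebraic (Kåsa) one — the linear normal
equations of $x^2+y^2 = ax+by+c$ — matching a "least-squares linear
regression" prescription; geometric (orthogonal-distance) refinement is
deliberately omitted. The two optima agree to well under 1% on windows
covering a substantial arc, and the suite verifies this against a
brute-force grid minimizer; on shallow arcs they genuinely separate, which
is a property of the estimators, not a bug.

Near-straight windows make the $3\times3$ normal matrix ill-conditioned;
beyond a condition-number cutoff (default $10^{10}$) the window is flagged
degenerate and its curvature recorded as **zero** — a straight segment has
zero curvature, not undefined curvature.

End handling: positions closer than the window half-width to either end
cannot be fitted, so a 44-point trace with half-width 5 yields positions
$i = 6..39$ (34 values). An independent `end_exclude` knob can widen the
excluded zone (it is effective only beyond the half-width); the default is
the explicit $i$-range rule. Curvature is reported in $\mu m^{-1}$
($\times 1000$ from the internal nm$^{-1}$).

## Helix tilt and bend

Local helix axes come from the bisector construction on each window of four
consecutive C$\alpha$ atoms: with $B_2 = (P_1-P_2)+(P_3-P_2)$ and
$B_3 = (P_2-P_3)+(P_4-P_3)$ both perpendicular to the local axis, the local
axis is $\widehat{B_2\times B_3}$, sign-aligned from the first toward the
last residue; the global axis is the normalized mean of the local axes.
This is a direction-only simplification of the full axis algorithm (origin
refinement omitted) — tilt and bend need directions only, and on ideal
generated helices the recovered axis is exact to numerical precision.
Tilt is $\arccos|\hat a\cdot\hat n|$, folded into $[0^\circ, 90^\circ]$
because the helix direction along its axis is arbitrary; the membrane
normal defaults to $+z$.

The bend angle at an apex residue (TM3's residue 134) is the angle at its
C$\alpha$ between the chords to the C$\alpha$ of the two end residues (123
cytoplasmic, 141 extracellular). One geometric subtlety matters: on an
ideal helix of radius 2.3 Å the chord from the apex to an end residue is
parallel to the helix axis only when the arm spans a whole number of
helical turns ($\Delta n \cdot 100^\circ \equiv 0 \pmod{360^\circ}$).
With the 123/134/141 residues the arms span fractional turns, both chords
carry the same radial offset, and a perfectly straight helix reads
$\approx 173^\circ$, not $180^\circ$ — consistent with straight
transmembrane helices being reported near $168^\circ$ rather than at the
geometric maximum. The recovery tests therefore use full-turn arms
(18 residues = 5 turns per side), where the generator's imposed kink
$\chi$ maps to a bend of exactly $180^\circ-\chi$; the fractional-turn
offset is itself asserted as a documented property.

RMSD uses the standard SVD superposition with the determinant correction
against improper rotations, and is checked against a dense rotation-grid
minimizer.

## Contacts and occupancy

Interface distances are per-frame minimum heavy-atom distances between two
resolved atom subsets. Occupancy is the fraction of *sampled* frames at or
under the cutoff, matching the "% of simulation time" reporting convention.
Default cutoffs are the conventional MD-analysis values — salt bridge 4.0 Å
between side-chain N/O, generic side-chain contact 4.5 Å, hydrogen bond
3.5 Å donor–acceptor heavy-atom distance with no angle term (united-atom and
coarse models may lack hydrogens) — all configurable per interface. The
claudin-15 preset names both residue spellings found in the literature for
two interfaces (M68/S68 with F146, and L58/L48 with R79) as separate labels
rather than guessing which is intended. Side-by-side adjacency comes from
the declared row order in the grouping, never from geometry.

## The synthetic world

Every estimator is validated on generated data whose governing parameter is
known by construction:

* **Worm-like chains** — segment headings follow
  $\phi_{i+1} = \phi_i + \varepsilon_i$,
  $\varepsilon_i \sim N(0, \delta s/l_p)$; this variance identity *is* the
  generator's definition of $l_p$, and makes the heading correlation
  $e^{-k\delta s/2l_p}$ exact in expectation. Defaults (44 points,
  $\delta s = 3$ nm, $l_p \in \{50, 150, 590\}$ nm, 10,000 frames) mirror
  the regime of the longest simulated strands and the flexible-vs-stiff
  contrast of interest. Frames are independent draws — the estimator treats
  frames as samples of a pooled ensemble average — with an optional AR(1)
  `mixing` parameter to impose frame-to-frame correlation for robustness
  checks.
* **Kinked helices** — ideal cylinder helices (rise 1.5 Å, twist
  100°/residue, radius 2.3 Å) with the post-kink segment rigidly rotated by
  the kink angle about an in-plane axis through the kink residue, plus
  optional Gaussian coordinate noise.
* **Contact series** — a two-state mixture: bound ($N(4.0, 0.5^2)$ Å) with
  probability $p$, unbound ($N(8.5, 0.8^2)$ Å) otherwise, emulating the
  loose (extended tail to ~10 Å, $p \approx 0.82$) versus tight (compact,
  $p \approx 0.95$) interface distributions.
* **Strand fixtures** — toy structures whose tetramer centers of mass
  reproduce a supplied 2D backbone exactly (monomer and atom offsets sum to
  zero), writable to PDB, for end-to-end I/O → analysis verification.

What a green suite establishes: the estimators recover the generators'
ground truth (persistence length within 10% at 10,000 frames, kink within
2°, occupancy within 2%), the correlation machinery matches its closed
form, and the algebraic fits match brute-force oracles. What it does not
establish: the values any *real* strand trajectory would give. The
generators have no temporal autocorrelation by default, no excluded volume,
no coupling between curvature and contacts, and no membrane; conclusions
about claudin biology require actual trajectories fed through the same
pipeline.

## Practical limits and I/O

Structures are read from fixed-column PDB; monomers are assigned from an
explicit sidecar when given, else segment ids when present and finer than
chain ids (replicated strands exceed the one-character chain alphabet), else
chain ids. Trajectory frames enter through an in-memory pluggable reader
(a list of coordinate matrices or a `function(i)`); binary trajectory
formats (DCD/XTC) need an external conversion step, which is the main
practical limitation. Frame sampling is nearest-frame at a configured
interval (default 60 ps) with optional trailing windows (e.g. last 100 ns).
All angle summaries use the sample (n−1) standard deviation, stated in the
outputs.
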