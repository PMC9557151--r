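# strandmech

Mechanics of claudin tight-junction strands from simulation trajectories.

Tight-junction strands are linear polymers of claudin ion channels in the
membranes of adjoining epithelial cells. Their lateral flexibility — how
readily a strand arcs and bends in the membrane plane — is a mechanical
property one can read off equilibrium trajectories, and single residues on
the third transmembrane helix (TM3) can change it severalfold. `strandmech`
provides the estimators for that analysis, for anyone working with
coarse-grained or atomistic membrane-protein polymer simulations:

* **Persistence length** of a strand treated as a discrete 2D worm-like
  chain: tangent angles from central differences of the tetramer-center
  trace, the pooled correlation function
  `⟨cos(φ(s) − φ(0))⟩ = exp(−s / 2 l_p)`, and an R²-gated log-linear fit
  with `l_p = −1/(2·slope)` (the factor 2 is the 2D convention).
* **Local curvature** as the reciprocal radius of algebraic (Kåsa)
  least-squares circles over sliding 11-point windows, with end exclusion
  and degenerate (straight) windows counted as zero curvature.
* **Helix geometry**: HELANAL-style local axes from 4-Cα windows, tilt
  against the membrane normal, and the chord bend angle at an apex residue
  (e.g. TM3 residue 134 toward residues 123/141).
* **Superposition RMSD** (Kabsch) for per-monomer / per-pair / per-tetramer
  stability series.
* **Contacts**: minimum heavy-atom distance series for named residue
  interfaces (a claudin-15 preset covers the K155–N148 salt bridge,
  R79–F65/L58, M68/S68–F146, S67–E157 and β4–β4), occupancy fractions under
  configurable cutoffs, and distance distributions with tail quantiles.
* **Synthetic generators** — worm-like chains, kinked helices, two-state
  contact series, PDB-writable toy strands — whose ground truth makes every
  stage verifiable without microsecond trajectories.

## Worked example

Generate a stiff strand ensemble (persistence length 590 nm, 44 tetramer
centers at 3 nm spacing) and recover its persistence length:

```r
library(strandmech)

ens <- generate_wlc_ensemble(wlc_params(n_points = 44, ds = 3.0, lp = 590,
                                        n_frames = 2000, seed = 590))
res <- persistence_pipeline(ens, k_max = 15, r2_cutoff = 0.95)
res$estimate
#> Persistence length: 586.6 nm  (delta_s = 3 nm, R2 = 1.0000, 15 lags, 2000 frames)

cp <- curvature_pipeline(ens, half_width = 5)
round(cp$summary$mean, 1)   # mean local curvature, um^-1
#> [1] 13.6
```

The fitted 586.6 nm agrees with the generator's 590 nm to under 1%; the
44-point traces give curvature at positions i = 6..39 (34 windows per
frame), and the stiff chain's mean curvature (~14 μm⁻¹) is roughly half
that of a flexible 150 nm chain (~25 μm⁻¹) — stiffness and mean curvature
are two views of the same bending rigidity.

The numbered drivers under `analysis/` run the full workflow on the
synthetic worlds — simulation (`01`), persistence length (`02`), curvature
(`03`), helix bend/tilt (`04`), contact occupancy (`05`) — and write their
tables under `results/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's ground-truth recoveries from scratch: the
worm-like-chain pipeline at l_p = 50/150/590 nm (including one full
PDB-write → reload → analysis round trip), helix-kink recovery under
coordinate noise, and contact-occupancy recovery, printing each comparison
and writing its JSON output to `--out`.

## Documentation

`vignettes/strand-mechanics.Rmd` documents the models, the estimator
choices (pooling, fit-prefix selection, free intercept, degeneracy
handling, chord-offset geometry of the bend angle) and what the synthetic
world does and does not establish.
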