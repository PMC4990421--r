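---
title: "Multi-resolution flexible fitting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution flexible fitting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

Flexible fitting by biased molecular dynamics (MDFF) refines an atomic or
coarse-grained model into a cryo-EM density map by adding a map-derived
potential to the model's internal energy,

$$U_{\mathrm{total}} = U_{\mathrm{MD}} + U_{\mathrm{EM}} + U_{\mathrm{SS}},$$

and letting thermostatted dynamics settle the model into the density.  The
map enters through a per-voxel fitting potential

$$V(\mathbf r) = \begin{cases}
  \zeta\left[1 - \dfrac{\Phi(\mathbf r) - \Phi_{\mathrm{thr}}}
       {\Phi_{\max} - \Phi_{\mathrm{thr}}}\right]
  & \Phi(\mathbf r) \ge \Phi_{\mathrm{thr}},\\[4pt]
  \zeta & \Phi(\mathbf r) < \Phi_{\mathrm{thr}},
\end{cases}$$

so that density maxima are energy minima ($V = 0$), sub-threshold noise is a
flat plateau of height $\zeta$, and $V$ is continuous at the threshold.  A
commonly printed form of this expression omits the "$1 -$" term; taken
literally it would make density maxima energy *maxima*, so `mapfit`
implements the sign-inverted, threshold-continuous form above (the raw form
is quoted in `?potential_from_map`).  Coupled beads contribute
$U_{\mathrm{EM}} = \sum_i w_i V(\mathbf r_i)$ with weight $w_i$ equal to the
bead mass by default; forces are the exact gradient of the trilinear
interpolant of $V$.

At better than ~5 Å resolution the fitting potential becomes rugged and
direct MDFF is easily trapped.  The two multi-resolution protocols address
this:

* **Cascade fitting** (`run_cmdff`) refines sequentially against a ladder
  of maps blurred with decreasing Gaussian half-widths
  $\sigma_1 > \sigma_2 > \dots > \sigma_L = 0$, each stage seeding the next.
* **Resolution exchange** (`run_remdff`) runs one replica per rung and
  swaps $\sigma$ (and the associated potential) between neighbouring
  replicas with the Metropolis probability
  $p = \min\!\big(1, e^{-\Delta/k_BT}\big)$, where
  $\Delta = E(x_i,\sigma_j) + E(x_j,\sigma_i) - E(x_i,\sigma_i) -
  E(x_j,\sigma_j)$.  Internal and restraint energies cancel in $\Delta$, a
  property the test suite asserts to $10^{-10}$.

Both protocols end with an annealed re-refinement (`anneal_refine`): map
coupling raised to $\zeta = 1$, temperature ramped 300 K → 0 K, then a 0 K
hold and an energy minimisation.

### How the blur ladder is built

The rung potentials are Gaussian blurs **of the fitting potential itself**
(holding the plateau fixed by blurring $V - \zeta$), not potentials re-derived
from a blurred density.  The two constructions differ importantly: re-deriving
from a blurred density renormalises every rung to the full $[0, \zeta]$ range,
which restores full-strength gradients at every rung but makes the energies of
neighbouring rungs differ by tens of $k_BT$ on a small system — measured on the
packaged fixture, the mean Metropolis $\Delta$ per neighbour pair was 19–73
kcal/mol, and no exchange is ever accepted.  Blurring the potential keeps
neighbouring rungs energetically close (blur only smooths $V$), at the cost of
shallower wells on the blurred rungs.  It is also the construction under which
the width-composition rule holds exactly: blurring a Gaussian well of width
$s$ by $\sigma$ gives a well of width $\sqrt{s^2 + \sigma^2}$.

## The coarse-grained internal energy

`mapfit` replaces the all-atom force field with a structure-based
(Gō-like) one-bead-per-residue model built from a reference conformation
(`build_topology`): harmonic bonds, angles and cosine dihedrals at their
reference values, 10–12 native contacts between pairs separated by at least
three positions within 8 Å, and a soft $r^{-12}$ excluded volume for the
rest.  The reference conformation is therefore an exact stationary point of
its own topology (asserted to $10^{-6}$ kcal/mol/Å in the tests).  Fitting
protocols build the topology from the **search** model, so deformation
toward the map genuinely works against the model's internal energy.

This is the central scale-down of the package, and one parameter choice in
it matters beyond aesthetics.  In an all-atom model the internal force
field is far stiffer, per atom, than the grid potential, so thermal
fluctuations of each atom are map-independent and the exchange criterion
compares *conformations*, not well widths.  The surrogate must reproduce
that separation of scales: with full coupling ($\zeta = 1$, $w = 110$ amu,
rendering width $s \approx 1.3$ Å) the per-bead curvature of the map term
is roughly $\zeta w / s^2 \approx 60$ kcal/mol/Å².  The defaults
(`topology_params()`: bond 100 kcal/mol/Å², angle 40 kcal/mol/rad²,
dihedral 2 kcal/mol, contact depth 5 kcal/mol, giving a per-bead contact
curvature above that figure) keep internal stiffness dominant.  With
markedly softer constants the entropic well-width mismatch between rungs
drives swap acceptance to zero and resolution exchange degenerates into
independent fixed-blur runs.

Secondary-structure restraints (`assign_ss_restraints`) are harmonic terms
on all pseudo-dihedrals and 1–4 distances inside contiguous helix/strand
segments, at their assignment-time values with $k = 2$ — a deliberately
simple stand-in for the production restraint potentials of the original
all-atom implementations, which are not reproduced here.

## Dynamics, units and numerics

* Units: Å, kcal/mol, amu, fs, Kelvin; $k_B = 0.0019872$ kcal/mol/K.
  Internally time is handled in AKMA units (48.88821 fs).
* Integrator: BAOAB-splitting Langevin dynamics; with zero friction it
  reduces to velocity Verlet and conserves energy to better than $10^{-4}$
  relative over $10^4$ steps at 1 fs.  Defaults: 5 fs timestep, 1 ps$^{-1}$
  friction, 300 K.
* All randomness flows from R's RNG, so a fixed seed reproduces a
  trajectory bitwise.  A single RNG stream serves all beads.
* Map forces use the trilinear interpolant's exact gradient, which is
  discontinuous across voxel faces; force-consistency tests therefore
  sample states away from cell boundaries.
* Blurring and sharpening are periodic Fourier-space transfer functions
  ($e^{-2\pi^2\sigma^2 s^2}$ and $e^{-B s^2/4}$) on the map's own grid.
  This makes mass conservation, the blur semigroup, blur/sharpen
  commutation and the blur↔sharpen inverse all exact; the rendering
  utilities pad maps by ≥ 8 Å so wrap-around between opposite faces is
  negligible.  A zero-pad-and-crop alternative was rejected because the
  cropped mass loss violates those identities near the boundary.
* Per-stage duration is adaptive: dynamics run until the RMSD of recent
  frames to their window mean has a range below 0.1 Å over a 200-frame
  window, with a hard cap (default 12 000 steps per stage).  On strongly
  blurred rungs thermal wander can keep the detector from firing, in which
  case the cap applies and the stage is flagged (`converged = FALSE` in
  the stage records) — a convergence warning, not an error.  Resolution
  exchange instead monitors every replica's total energy and stops when
  all are trend-free (slope indistinguishable from noise over the window),
  the behaviour described for the original protocol, where exchanges
  naturally cease as the ensemble settles.
* `anneal_refine` guarantees a non-increasing total energy: in the rare
  case the annealed candidate ends above the starting energy, the
  minimised start is returned instead.

## Choice of final model

Cascade fitting returns the annealed end structure.  Resolution exchange
returns the **best-fit member of the replica ensemble** — each replica's
end structure scored by global cross-correlation, the winner annealed
against the unblurred map.  Restricting extraction to whichever replica
happens to hold $\sigma = 0$ at the end would misreport the method
whenever late-run swap acceptance is low: a mid-ladder replica routinely
reaches sub-Å accuracy while the $\sigma = 0$ holder is still trapped, and
ensemble-sorting by quality indicators is how the protocol is described in
its original account.

## The synthetic fixtures

The generators in `make_toy_dimer`, `displace_conformer`, `make_halfmaps`
and `make_localres_map` emulate the benchmark scenarios at desk scale:

* **Toy dimer** — two idealised three-helix domains (60 residues each,
  standard Cα helix geometry, 14 Å axis spacing) joined by a 4-residue
  linker: 124 beads, ~70 Å extent.  The 14 Å spacing is chosen so that a
  5 Å blur still leaves lobed, orientation-locking density; with tighter
  bundles the blurred blob becomes nearly featureless and a 124-bead
  domain reorients thermally, something the megadalton systems the method
  was built for do not do.
* **Displaced conformers** — `hinge` mode rotates domain B about a bending
  axis perpendicular to the inter-domain direction (the seed sets the
  azimuth), with the angle solved by bisection to hit a prescribed RMSD
  within ±0.2 Å; a twist about the inter-domain axis is deliberately
  excluded because it scrambles helix register, which a closed→open hinge
  motion does not do.  `heat` mode takes snapshots from 1000 K unbiased
  dynamics; `local` mode confines a rigid displacement to a named region.
* **Half-maps** — one rendered signal plus two independent Gaussian noise
  fields, for overfitting checks.
* **Local-resolution fixture** — per-bead rendering widths follow a radial
  profile (3 Å core degrading linearly to a 6 Å shell), with a companion
  volume storing the nominal resolution per voxel.

Maps are rendered with each bead as a Gaussian whose full width at half
maximum equals the nominal resolution ($s = R/2.355$); any fixed
convention works for self-consistent analyses, and this one is used
everywhere.  The noise threshold $\Phi_{\mathrm{thr}}$ defaults to the 5th
percentile of the strictly positive voxels and is recomputed per map.

What these fixtures do *not* emulate: real experimental noise spectra
(solvent, CTF), sidechain chemistry, map anisotropy, or masking artefacts.
Passing the packaged checks shows the machinery behaves correctly at toy
scale, not that the protocol parameters transfer untouched to a particular
experimental map.

### Problem sizes

The packaged study conditions are the 124-bead dimer fitted into its 3 Å,
1 Å-voxel map from a 7 Å hinge-displaced start (ladder 5…0 Å in 1 Å
steps, $\zeta = 0.3$, 300 K), with medians over five dynamics seeds; these
sizes let a full cascade run finish in well under a minute on one CPU
while still exhibiting the phenomenon of interest (direct fitting fails
from the same start in the large majority of paired seeds).  One caveat
is stated rather than hidden: the first-stage (σ = 5 Å) result is a
thermal snapshot, and the RMSD spread inside a 5 Å-blurred potential is
several tenths of an Ångström for a 124-bead system at 300 K, so
stage-end values scatter over roughly 1.6–2.3 Å across seeds.

Two validation fixtures carry their own calibration logic.  The
sharpening-scan fixture adds white noise (sd 0.05, ~1.5% of the map peak)
before blurring by σ* = 1.2 Å: without noise the over-sharpening branch of
the RMSF parabola never rises (there is nothing for sharpening to
amplify), and the Guinier comparison measures the blur-induced falloff
relative to the noise-free rendering's own Gaussian-bead decay — the
synthetic analogue of referencing expected molecular-transform amplitudes,
as experimental sharpening does.  The half-map overfit control couples the
model to the *noise* of half-map 1 after light smoothing (1.5 Å): raw
single-voxel speckle has neither followable minima nor power in the
5–10 Å band in which the integrated-FSC indicator is scored.

## Validation metrics

* `gcc`/`lcc` — Pearson correlation between the map and the model rendered
  on its grid, over the union of above-threshold voxels (locally
  restricted to 5 Å spheres for LCC; the sphere radius is a local choice,
  as the original account does not state its mask).
* `fsc`, `integrated_fsc` — Fourier shell correlation on shells one
  reciprocal-grid unit wide, and its trapezoidal integral over a stated
  resolution range in Å (an FSC pinned at 1 over [5, 10] Å integrates to
  5 Å, matching the printed magnitudes of the original analyses).
* `halfmap_crossvalidate` — integrated FSC of the fitted model against the
  fitting half-map versus the held-out half-map; the difference is the
  overfitting indicator.
* `rmsf_profile` — per-bead fluctuation about the window-averaged
  positions (default: trailing 80% of frames), with no superposition
  because the map fixes the frame.
* `bfactor_from_rmsf` — $B = \tfrac{8\pi^2}{3}\,\mathrm{RMSF}^2$ with the
  exact constant 26.3189… (printed worked examples elsewhere imply ≈26.0;
  the exact constant is used here).
* `guinier_bfactor` — least-squares slope of log spherically averaged
  Fourier amplitude against $s^2$, $B = -4 \times$ slope.
* `sharpen_scan` — overall RMSF of a short fixed-seed fitting run as a
  function of the map's sharpening B-factor.  The curve is parabolic: too
  little sharpening leaves a blurred, shallow potential; too much
  amplifies noise until the normalised potential's wells flatten.  On a
  blur-degraded noisy fixture the minimum coincides with the Guinier
  estimate within one grid step, the coincidence the RMSF-based
  B-factor-selection argument rests on.

## Known limitations

* Coarse-grained beads cannot express sidechain fit; EMRinger- or
  MolProbity-style model-quality scores are out of scope.
* Orthorhombic grids only; no symmetry handling; local-resolution volumes
  are consumed, never computed.
* Swap acceptance between sharp rungs drops as replicas specialise;
  best-ensemble extraction compensates, but ladder mixing on large, stiff
  systems would benefit from finer rung spacing (the 0.5 Å half-step
  ladder, `make_schedule(5, 0.5)`).
* Steepest-descent minimisation is robust but slow near flat minima; the
  annealed re-refinement compensates in the protocols.
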