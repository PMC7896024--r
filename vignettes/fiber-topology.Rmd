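---
title: "Modeling the topology of two-start chromatin fibers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the topology of two-start chromatin fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In eukaryotic nuclei, DNA is wrapped ~1.65 left-handed superhelical turns
around histone octamers, and the resulting nucleosome chains fold into
two-start ("zigzag") fibers in which nucleosome i stacks face-to-face on
nucleosome i±2. The DNA of such a fiber has a well-defined topology: for a
closed chain, the linking-number change relative to relaxed B-DNA decomposes
as dLk = dTw + Wr, where dTw is the excess duplex twist and Wr is the writhe
of the duplex axis (the Gauss double integral of the space curve over
itself). A long-standing puzzle ("the linking number paradox") is that the
wrap alone suggests about -1.65 turns per nucleosome while topological
measurements on minichromosomes historically gave about -1.

fibertopo builds base-pair-resolution coarse-grained models of regular
nucleosome arrays, scores them with an elastic + stacking + excluded-volume
energy, finds energetically optimal regular two-start fibers as a function
of the free linker length L, samples thermal ensembles by Metropolis Monte
Carlo, and computes the observables these models are tested against. Its
central reproducible result is that two-start fibers fall into two
topological families controlled by the linker-length class: L near 10n bp
gives the T2 fold with dLk per nucleosome near -1.5, while L near 10n+5
gives the T1 fold near -1.0, because adding half a helical turn of linker
rotates the setting of successive nucleosomes by ~180 degrees (a cis-like
to trans-like flip).

## Geometry

DNA is represented at rigid base-pair resolution. Each base pair carries an
orthonormal frame; successive frames are related by six step parameters
(tilt, roll, twist in degrees; shift, slide, rise in nm) under the mid-step
compounding convention: the step rotation is
Rz(Tw/2 - phi) Ry(Gamma) Rz(Tw/2 + phi) with bend magnitude
Gamma = sqrt(tilt^2 + roll^2) and phase phi = atan2(tilt, roll), and the
displacement is applied in the half-rotated mid-step frame. The relaxed
reference step is twist 34.3 degrees (10.5 bp/turn), rise 0.34 nm, all other
parameters zero; every dTw in the package is measured against a chain of
these steps.

The nucleosome core is `L_NCP` base pairs (147 generically; 146 for arrays
built on the "601" positioning sequence) placed on a left-handed superhelix
of radius 4.18 nm and pitch 2.39 nm, wrapping 1.65 turns (1.64 for 146 bp),
following the crystallographic core-particle geometry. Frames along the
wrap are parallel-transported with an imposed twist of 34.3 degrees per
step, so the wrapped DNA is torsionally relaxed and the core's entire
topological contribution is writhe; closing a single core with a distant
return path gives Wr close to -1.4. We fix full wrapping; partial
unwrapping is not modeled, and the tolerance on per-nucleosome dLk absorbs
the difference.

A fiber is assembled by placing rigid copies of the core template connected
by linkers. A linker with L free base pairs carries L + 1 steps (core exit
-> L linker bp -> next core entry), which makes the base-pair bookkeeping
come out at n * L_NCP + (n - 1) * L for an open n-mer and keeps
NRL = L_NCP + L exact.

## Topology

Writhe is computed by the discrete Gauss double integral over ordered
segment pairs with the exact per-pair solid-angle formula (the arcsine
form); a second, independent formulation via two spherical-triangle solid
angles is provided as a cross-check, and both are validated against a
planar circle (0), Fuller's closed form for tight toroidal solenoids
(|Wr| = N (1 - sin alpha)), and a refinement oracle on the trefoil. Twist is
the exact ribbon twist of the material frame about the tangent (parallel
transport plus residual rotation), which is the quantity that pairs with
the Gauss writhe in Lk = Tw + Wr; for straight relaxed linkers it coincides
with the summed step twist.

Open fibers are closed the way flanking plasmid DNA would close them: both
termini are extended along their local tangents and then joined by a planar
half-ellipse far from the fiber body (apex clearance at least three fiber
diameters, widened on retry). The tangential extensions matter: closing
end-to-end directly short-circuits the phase of the terminal wraps and
underestimates |Wr| by roughly 0.4 turns for a single core. End effects of
the closure are cancelled by reporting the per-nucleosome dLk as the slope
of dLk against array size (n = 4, 6, 8 by default); for circular chains
dLk/n is used directly. Both routes agree to better than 0.05 per
nucleosome for regular fibers.

## Energy model

Three terms score a conformation:

* **Linker elasticity.** Harmonic in the step-parameter deviations,
  E = 1/2 (s - s0)' K (s - s0) per step, with a diagonal default stiffness
  matched to persistence lengths: tilt/roll 0.043 kT/deg^2 (bending
  persistence ~50 nm), twist 0.06 kT/deg^2, displacements 50 kT/nm^2. This
  declared harmonic parameterization stands in for knowledge-based DNA
  potentials; it is deliberately simple and config-overridable with a full
  6x6 matrix.
* **Stacking.** An attractive face-to-face well between cores,
  -depth * exp(-(d - d0)^2 / 2w^2) * |cos(theta)| in the center distance d
  and the angle theta between superhelical axes, cut off at d0 + 3w.
  Defaults: depth 18 kT, d0 = 7.0 nm, w = 0.5 nm. Two calibrations were
  made once, and for stated reasons: (i) d0 = 7.0 nm is the closest
  (i, i+2) approach the rigid fully-wrapped core geometry affords at an
  elastic cost a well can repay (pulling centers to 5.7 nm would cost
  140-240 kT of linker elasticity); (ii) depth 18 kT is the smallest round
  value at which the compact stacked two-start folds are global minima of
  the total energy across the nucleosome repeat lengths studied here.
  The well acts only between cores at sequence separation |i - j| >= 2:
  the faces of sequence neighbors are occluded by the linker DNA entering
  and exiting between them. Without this occlusion rule the model's global
  optima are one-start solenoids with adjacent cores glued face-to-face,
  outside the two-start structural family.
* **Excluded volume.** Hard-core: non-adjacent core cylinders (radius
  5.5 nm, half-height 2.75 nm, realized as a center-plus-ring sphere
  covering) must not overlap, linker bp centers may not penetrate foreign
  core cylinders, and segments of distinct linkers may not approach below
  twice the DNA radius (1 nm). Sequence-neighbor cores are exempt from the
  cylinder test - idealized parallel rigid cylinders of a compact zigzag
  formally graze where real, tilted nucleosomes do not - but their centers
  must stay above a stereochemical floor of 6.5 nm, below which real cores
  would interpenetrate regardless of tilt.

## Finding optimal regular fibers

A regular fiber shares one linker step-parameter set, so nucleosome i+1
follows from nucleosome i by a fixed screw transform and the search space
is six-dimensional. The landscape couples a quadratic elastic term to a
short-ranged well, which defeats plain descent from the relaxed geometry
(there is no gradient across the plateau between relaxed and contact, and
the valley toward contact is strongly curved). Each start is therefore
optimized in two phases: a guided-compaction phase replaces the well by a
long-ranged harmonic pull of the (i, i+2) center distances toward the
stacking distance plus an axis-alignment term, and a polish phase descends
on the true energy with excluded volume as a hard wall. Both phases run a
shrinking-step coordinate descent and an L-BFGS-B refinement and keep the
better result. Because the guided landscape is chaotic, trajectory
diversity is what reaches the distinct basins: three deterministic
pipelines (a target-distance homotopy from the relaxed seed and from two
rotational-phase seeds, plus a weak-pull quasi-Newton path) are combined
with seeded random starts whose pull stiffness, target and alignment
weight are themselves drawn from the RNG.

The shared linker step is bounded by crystallographically motivated
distortion ranges (tilt/roll within 10 degrees, twist within 3 degrees of
relaxed, displacements within 0.3 nm, rise 0.24-0.44 nm). The twist band
admits the rotational-setting fine-tuning the compact folds need while
capping uniform rewinding of the linker. Converged minima are
deduplicated (energy within 0.5 kT, per-nucleosome dLk within 0.05),
restricted to the fiber class (dLk per nucleosome in [-2.5, 0): the
left-handed wrap makes fiber dLk strictly negative, and nothing in the
two-start family links more than ~2 turns per nucleosome - folds outside
this interval are coiled columns or contorted near-clash states), labeled
T1/T2 by the -1.25 threshold (the midpoint of the two families), and
sorted by energy.

## Monte Carlo

`mc_sample()` runs Metropolis on the linker degrees of freedom: each
elementary move perturbs one randomly chosen parameter of one step of one
linker by a symmetric uniform proposal (default half-widths 3 degrees /
0.03 nm), so detailed balance holds; regularity is not enforced and each
linker fluctuates independently while cores stay rigid; excluded-volume
violations are rejected outright. The first 20% of snapshots are discarded
from observables. Identical seeds give bit-identical trajectories. The
equipartition check (harmonic-only system, variance of each linker
coordinate equal to kT/k) recovers the twist stiffness to within 5% at
2e5 moves.

## Observables

* **Fragment-length distribution (FLD).** For each fragment length n (nt,
  equal to the bp separation), the mean over bp pairs (i, i+n) of
  exp(-d/lambda) in the 3-D distance d, with lambda = 4.0 nm - the
  exponential decay of radiation-induced correlated break frequencies.
  Distances use bp origins (duplex axis); the strand-level offset is
  absorbed into lambda's effective value. Peaks are detected after a 5-nt
  centered moving average with a prominence threshold of 5% of the dynamic
  range. For the optimal T2 fiber at NRL 187 the profile shows the two
  zigzag maxima in the 250-400 nt window near 280 and 360 nt, produced by
  the (i, i+1) gyre contacts across the two stacks and the (i, i+2)
  linker-linker proximity, respectively.
* **Contacts, stacking fraction, flip-out.** Close contacts are core pairs
  within 11 nm (one core diameter), binned by sequence offset; a
  nucleosome is stacked when a partner at |i-j| >= 2 lies within the
  stacking well cutoff with axes aligned beyond |cos| = 0.7; a core is
  flipped out when it lies more than 1.5 fiber-axis radii from the local
  fiber axis (line fit through a 5-nucleosome sliding window).
* **Sedimentation.** Kirkwood's double-sum bead model on core centers,
  s/s_mono = 1 + (2 R_eff / n) sum(1/d_ij), with s_mono = 11.1 S and
  R_eff = 5.5 nm.

## What the model reproduces, and what it does not

At its defaults the package reproduces, at desk scale: the two-family
topology (optimal dLk per nucleosome ~ -1.58 at L = 20 and ~ -1.09 at
L = 25); the measured topology of circular "601" arrays (~ -1.53 at NRL 167
vs the measured -1.4, ~ -1.04 at NRL 172 vs -0.9); the two FLD maxima of
the compact T2 fiber at NRL 187 (~277 and ~364 nt); the higher thermal
stacking of T2 versus T1 arrays and the corresponding sedimentation
ordering.

Known limitations, stated plainly:

* The harmonic persistence-length elasticity is stiffer against the
  collective deformations of fiber compaction than knowledge-based DNA
  potentials. Two consequences follow. First, compact stacked folds
  require a deep stacking well to be global minima, and at 1 kT such
  ensembles barely unstack: thermal stacking fractions of compact T2
  arrays stay near 100% rather than the ~60% seen with softer potentials,
  while the T1 arrays (whose optimal fold here is loose) build up
  intermediate fractions through spontaneous transient stacking (roughly
  30-65%, growing with run length and varying with seed, against a ~30%
  reference under softer potentials). The T2-T1 ordering and a gap of at
  least 15 percentage points are robust across seeds. Second, the compact
  T2 branch stays energetically optimal
  further across each 10-bp linker decade than under a knowledge-based
  potential, so the linker scan's most negative per-nucleosome dLk reaches
  about -2.1 (near L = 48) rather than -1.7.
* The stacking well is orientationally coarse (|cos| of the axis angle);
  it does not resolve gyre-level contact registry, which is why
  intermediate rotational settings can stack here that a surface-resolved
  model would reject.
* No linker histones, no sequence-dependent step equilibria, no
  electrostatics or salt dependence, no nucleosome unwrapping or sliding
  moves, and no modeling of the closing plasmid beyond an ideal distant
  return path.
* The synthetic conditions are idealized: uniform linker lengths, identical
  cores, and a single shared template. Passing tests on these conditions
  shows the machinery is correct under the stated model; it does not show
  that real chromatin with heterogeneous spacing behaves quantitatively
  this way.

## Numerical choices

Writhe uses the exact per-segment-pair solid angle (no quadrature error;
discretization at bp resolution converges to well below 0.02). Degenerate
(touching/intersecting) segment pairs are reported as errors rather than
silently skipped. Frames are re-orthogonalized during compounding so drift
never reaches 1e-9. Angles are degrees at every interface and radians
internally; lengths are nm; PDB export converts to Angstrom. Problem sizes
used throughout the shipped tests and the acceptance script - 8-mer arrays
for optimization, 12-mers for observables, 2e5-move MC with three seeds,
and a 2-bp-stride linker scan - were chosen so the whole analysis runs on
a laptop-class single core in well under an hour.

## Worked example

```{r example}
library(fibertopo)

spec <- fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 8)
opt <- optimize_regular_fiber(spec, starts = 50, seed = 1)
opt[[1]]
#> optimal T2 fiber: L = 20 bp, dLk/nucleosome = -1.584, E = -17.99 kT

fib12 <- assemble_fiber(fiber_spec(L = 40, L_NCP = 147, n_nucleosomes = 12),
                        optimize_regular_fiber(
                          fiber_spec(L = 40, L_NCP = 147, n_nucleosomes = 8,
                                     family_hint = "T2"),
                          starts = 50, seed = 1)[[1]]$linker_step)
detect_peaks(fld_profile(fib12, lambda_nm = 4, range = c(250, 400)))
#>   position    height prominence
#> 1      277 0.1963436  0.1236426
#> 2      364 0.2156235  0.1497111
```
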