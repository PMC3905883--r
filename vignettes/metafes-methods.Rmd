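---
title: "Metadynamics unbinding landscapes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metadynamics unbinding landscapes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metafes)
```

## The model

`metafes` analyses ligand unbinding on a free-energy surface (FES) spanned
by two collective variables: the mass-weighted center-of-mass distance
between the ligand and the binding-site bases (nm), and a coordination
number counting ligand–base atomic contacts. The coordination number is a
smooth pair sum

$$\mathrm{CN} = \sum_{i \in A}\sum_{j \in B} \frac{1 - x_{ij}^{\,n}}{1 - x_{ij}^{\,m}},
\qquad x_{ij} = \frac{r_{ij} - d_0}{r_0},$$

with the convention that pairs at $r \le d_0$ contribute the limiting
value 1. The offset $d_0$ is placed at the first peak of the radial
ligand–base atom-pair distance distribution and $r_0$ at its full width at
half maximum, so the switching function turns off exactly where the
contact shell of the equilibrated complex ends. The exponents are not
derivable from the distribution; we use the common rational-switching
defaults $n = 6$, $m = 12$ (configurable). Near $x = 1$ the expression has
a removable singularity; a first-order expansion around $n/m$ is used when
$|x - 1| < 10^{-6}$.

Metadynamics adds a history-dependent bias
$V(\mathbf{s},t) = \sum_k w_k \exp\!\big(-\sum_d (s_d - c_{k,d})^2 / 2\sigma_d^2\big)$
built from Gaussian hills deposited at the visited CV point at a fixed
pace. The FES estimate is $F(\mathbf{s}) = -V(\mathbf{s}, t_{\mathrm{end}})$,
scaled by $\gamma/(\gamma-1)$ in the well-tempered variant, and shifted so
its global minimum is zero. Production-style parameters are hills of
1.0 kJ/mol deposited every 0.5 ps (one per 250 frames of 2 fs), a
contact-CV width of 50, a 500 × 500 reconstruction grid, and truncation of
the hill stream at the first time the distance CV reaches 4.0 nm — the
point where the ligand no longer contacts the complex, after which further
hills describe the irrelevant unbound region. Both standard (constant
height) and well-tempered (damped height
$w = w_0 e^{-V/k_B(\gamma-1)T}$) deposition are implemented; standard is
the default and $\gamma$ defaults to 10. The distance-CV hill width
defaults to 0.05 nm, a value on the scale of the bound basin's thermal
width.

Internal units are nm, kJ/mol, ps and amu throughout;
$k_B = 0.008314463\ \mathrm{kJ\,mol^{-1}K^{-1}}$.

## The sampler

Because the package targets method validation rather than all-atom
simulation, the dynamics on a landscape is a Langevin particle in CV
space, integrated with the BAOAB splitting (accurate configurational
averages at large time steps) with reflecting walls at the CV domain
boundary. The potential gradient and the accumulated bias live on fine
grids (4001 nodes in 1-D, 451 × 451 in 2-D) and are linearly
interpolated; each deposited hill is added to the bias tables over an
8-sigma window. All randomness flows through R's RNG, so a seed makes the
entire run — trajectory and hills — bit-identical.

Two sampler parameters matter and are worth stating explicitly:

* **Friction.** Metadynamics estimates are only reliable when deposition
  is quasi-static — the CV must relax within a deposition period. For the
  1-D double-well validation we run overdamped (friction 50 ps⁻¹ at unit
  mass), which makes the intra-well relaxation time comparable to the
  0.5 ps pace; at low friction the walker crosses the barrier ballistically
  before the well has genuinely filled and the recovered barrier is biased
  low by several kJ/mol. The general-purpose default remains 1 ps⁻¹.
* **Per-CV masses.** The two CVs have stiffnesses differing by orders of
  magnitude (the contact coordinate's transverse curvature is
  ~0.002 kJ/mol per contact²), so a common mass cannot make both relax
  within the pace. `run_metadynamics()` therefore accepts one fictitious
  mass per CV; the 2-D study protocol uses (5, 10⁻⁴) amu with friction
  20 ps⁻¹, which puts both relaxation times at or below the pace while
  keeping the Kramers prefactor for unassisted barrier crossing small.

The 2-D synthetic runs sample at 100 K. This is a property of the toy
study conditions, not of the method: the reference all-atom systems have
unbinding barriers that are large multiples of $k_BT$ at 300 K, while the
toy landscape's 10–30 kJ/mol barriers would be only 4–12 $k_BT$ at 300 K
and the ligand would hop out thermally before the bias had filled the
bound basin. Sampling at 100 K restores the barrier ≫ $k_BT$ regime the
method assumes.

## The synthetic unbinding landscape

`make_unbinding_landscape()` builds
$V(d, c) = f(d) + \tfrac{1}{2} k_c\,(c - c_0(d))^2$ on
$d \in [0, 4.5]$ nm, $c \in [0, 400]$ contacts, with $k_c = 0.002$. The
valley profile $f$ is a chain of quintic smoothsteps through fixed knots:
a bound basin B at $d = 0.3$ (energy 0, valley at 300 contacts), the main
transition state Ts at $d = 1.0$ (energy = the requested barrier, exactly,
because smoothsteps are flat at their knots and the transverse term
vanishes on the valley), an intermediate I at $d = 1.6$ nm and ~20
contacts, an exit barrier Ts_out at $d = 2.1$, and an exit channel that
slopes down to $0.1 \times$ barrier and is exactly constant over the last
0.2 nm. Energy levels follow the depth parameters: I sits
`depths["I"]` below Ts and Ts_out at `depths["B"] − depths["I"]`; the
defaults scale with the barrier (1.5× and 0.75×) so that a barrier sweep
rescales the landscape self-similarly. Geometries in which the
intermediate, the exit barrier or the bound state would degenerate are
rejected.

Two constructions are deliberate. First, the valley-center transitions of
$c_0(d)$ are confined to intervals where $f$ has solid slope; a steep
valley crossing a flat stretch of $f$ would create rows of spurious strict
grid minima along the valley wall, and placing the transitions inside the
sloped segments provably avoids them — the exact landscape has exactly two
strict grid minima at any tested resolution. Second, the exit channel is a
genuine downhill slope rather than a long flat shelf: on a shelf the
walker lingers diffusively and deposits enough bias to turn the exit into
the apparent global minimum of the reconstruction.

## Estimators on reconstructed surfaces

Reconstruction is the exact Gaussian summation over all hills at every
grid node (no tail truncation; the per-hill term factorizes per
dimension, so 500 × 500 × tens of thousands of hills is unproblematic).
Off-node queries use bilinear interpolation. Two post-processing estimators
address the noise of finite-height deposition:

* `fes_time_average()` averages the cumulative-hill FES over checkpoints
  in the last half of the run. On an overfilled standard-metadynamics
  landscape the instantaneous estimate oscillates around the FES with an
  amplitude of a few hill heights; time-averaging removes most of it. The
  double-well validation (20,000 hills, three seeds) recovers the
  20 kJ/mol barrier within 1 $k_BT$ with this estimator.
* `fes_smooth()` filters the surface with a Gaussian at the hill widths.
  A metadynamics FES carries no information below the hill width, so this
  suppresses the deposition sawtooth without touching genuine basins.
  Minima counting and state labelling in the pipeline run on the smoothed
  surface.

Basin analysis follows the grid-search convention: a node is a minimum
when strictly lower than its 8 neighbors (boundary nodes compare the
neighbors they have); every node descends to the lowest strictly-lower
neighbor until it reaches a minimum (ties break on a fixed neighbor
order); frames are assigned to the basin of their nearest node when their
interpolated free energy is within 20 kJ/mol of the basin minimum, and
are otherwise unassigned, as are frames outside the grid. On exactly flat
plateaus strict descent can stall; such nodes are reported unassigned
rather than invented into a basin (this cannot occur on generic
reconstructed surfaces).

The minimum-energy path between two basins minimizes the maximum free
energy along the 8-connected path (the minimax criterion), with ties
broken by the lower path integral of energy. The saddle is found on the
minimum spanning tree of the grid graph under the edge weight
$\max(F_u, F_v)$ — the MST path between any two nodes is a minimax path —
and the reported path is then the lowest energy-integral route through
the region at or below the saddle. The profile is reported against the
normalized arc length $s \in [0, 1]$ measured in grid-index space, and
the activation energy is $F(\mathrm{saddle}) - F(\mathrm{start})$.

Reconstructed surfaces carry shallow spurious dips whose depth is on the
hill-height scale. We separate them from genuine basins by topographic
prominence — the height of the lowest saddle separating a minimum from
any lower minimum — computed pairwise on the same MST. Minima with
prominence ≥ 4 kJ/mol (several hill heights, well below the ≥ 7 kJ/mol
prominence of the shallowest genuine basin under the default conditions)
count as deep; shallower ones are merged into the significant basin they
connect to most easily. For barrier sweeps where a shallow intermediate
may hover near the detection threshold, `cv_point_barrier()` measures the
minimax barrier between the generator's known bound and intermediate
locations, referenced to the reconstructed bound-basin floor — no basin
detection involved, and immune to which basin the reconstruction happens
to overfill into its global minimum. The reported sweep value is the mean
of eight replicate runs, since a single first-escape estimate spreads by
several kJ/mol (the waiting time for the final crossing is roughly
exponential, and hills keep piling into the bound basin while it lasts).
`escape_barrier()` (minimax from the reconstruction's global minimum to
the exit channel) is the matching one-call probe when the bound basin is
known to dominate.

## Mock complexes and structural statistics

`default_mock_spec()` builds a ~60 pseudo-atom stand-in for a
protein–DNA–drug ternary complex: a ligand between the ±1 base groups,
bases at positions −2…+2 on an intact and a scissile strand, and four
residues carrying hydrogen-bond donors. The generator places each declared
donor/acceptor pair in hydrogen-bond geometry (donor–acceptor 0.30 nm,
colinear D–H–A, D–H 0.10 nm) with exactly its state's Bernoulli
probability and in broken geometry (0.60 nm) otherwise — safely inside and
outside any sensible cutoff — and jitters every atom with its isotropic
Gaussian sigma. Atoms whose geometry is overridden by a pair keep a tight
sigma (0.005 nm) so the Bernoulli occupancy is not smeared across the
detection cutoff; the scissile +1/+2 bases get a larger sigma (0.04 nm) to
emulate a mobile cleavage site. The default occupancy table includes a
0.49-probability residue→ligand bond present only in the bound state, a
transition-state-only bond, and stable residue→base bonds; the default
state sequence is bound-state-heavy (7512/22/631 frames), mirroring the
frame budget of an equilibrium-state analysis. Frame stride metadata is
0.5 ps.

What the mock does *not* emulate: real geometry (no helical DNA, no
side-chain chemistry), correlated motions, state-dependent conformational
change of the ligand beyond its H-bond pattern, and competition between
donors for one acceptor. Tests passing on the mock therefore certify the
*operators* (counting, filtering, weighting, clustering logic), not the
biology of any particular complex.

The structural operators follow the conventions of the standard trajectory
tools: hydrogen bonds use the geometric criterion D–A ≤ 0.35 nm and
∠H–D–A ≤ 30°; percentages of existence are per state over the frames
assigned to that state, with rows kept only when some state exceeds 25%
strictly. RMSF is the mass-weighted per-residue fluctuation about the
per-atom time mean; frames are least-squares superposed onto the first
frame by default since rigid-body drift otherwise dominates (`fit =
FALSE` restores the raw definition, which is translation-invariant but
not rotation-invariant). RMSD uses mass-weighted Kabsch superposition
(rotations via SVD with a determinant correction; selections of fewer
than 3 non-collinear atoms are rejected). gromos clustering greedily takes
the frame with the most neighbors within the RMSD cutoff (ties to the
lowest index) as a cluster with those neighbors, removes them and
repeats; cluster sizes are therefore non-increasing, and each cluster's
representative is its medoid. The gromos cutoff defaults to 0.1 nm. The
nick width is the COM distance between the pooled −1 and +1 base groups.

## Problem sizes and determinism

The shipped validation workload is sized for a desk machine: 5 × 10⁶
integrator steps per double-well seed (20,000 hills), 4 × 10⁶ steps per
2-D unbinding run (~150–1300 hills before escape), a 500 × 500 production
grid with 300 × 300 grids in the replicate sweep, 10⁶-step equipartition
checks, ~8000-frame mocks, and 10⁵-sample switching-function fits. Every
stochastic stage takes an explicit seed, sub-seeds are derived
deterministically per stage, and `generate_mock_trajectory()` restores the
caller's RNG state, so identical configurations reproduce outputs
byte-for-byte.

## Known limitations

* The engine handles 1 or 2 CVs; no path CVs, torsions, multiple walkers
  or on-the-fly reweighting estimators.
* No periodic-boundary minimum-image convention: toy systems are
  non-periodic (flagged in the configuration for future extension).
* First-escape FES estimates carry a systematic few-kJ/mol distortion
  (underfill of late-visited regions, overfill of the bound basin while
  waiting for the crossing); the sweep therefore reports replicate means
  and treats single-run activation energies as ±20% figures.
* Error bars on the FES (e.g. block averaging over the hill stream) are
  out of scope.
* Sub-basins within a super-basin are reported per-minimum; no merging
  rule beyond the prominence threshold is applied.
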