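---
title: "Methods: landscapes, networks and pockets from enhanced-sampling trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscapes, networks and pockets from enhanced-sampling trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allostera)
```

This vignette explains the models behind each stage of the package, the
parameters that matter, what the synthetic generators do and do not emulate,
and the numerical choices made where the design was genuinely open. The goal
of the toolkit is to characterise *conformational selection*: how a binding
partner shifts the population of pre-existing active-site conformations —
here phrased through two substrate pockets whose accessibility is tracked by
two collective variables — and through which residue paths that allosteric
signal travels.

## Dual-boost acceleration and reweighting

Enhanced sampling is modelled with the dual-boost scheme. Whenever the total
potential energy $V(r)$ falls below a reference $E_P$, the simulation runs on
the modified surface $V^*(r) = V(r) + \Delta V(r)$ with

$$\Delta V = \frac{(E_P - V)^2}{\alpha_P + E_P - V}
           + \frac{(E_D - V_D)^2}{\alpha_D + E_D - V_D},$$

each term active only below its reference; $V_D$ is a designated
dihedral-like component of the energy (zero for 1D toys). The form has two
properties the tests assert numerically: $\Delta V \ge 0$ with
$V^* = V$ exactly at and above the references, and $C^1$ continuity at the
threshold ($\Delta V \to 0$ *and* $d\Delta V/dV \to 0$ as $V \to E_P^-$), so
forces stay continuous. Below threshold the force is damped by the factor
$\alpha^2/(\alpha + E - V)^2 \in (0, 1)$ — barriers flatten but minima are
never inverted.

Reference parameters are deliberately plain configuration
(`amd_params()`): production values are system-specific and typically tuned
after preliminary runs, so the package never hard-codes them. For toy
surfaces `amd_params_from_prerun()` offers the common heuristic
$E = \langle V\rangle + 4\,\mathrm{sd}(V)$, $\alpha = \mathrm{sd}(V)$ from a
short unboosted pre-run.

The integrator (`run_langevin()`) is *overdamped* (position) Langevin with
Euler–Maruyama updates rather than velocity Verlet: only equilibrium
sampling matters for landscape work, and the overdamped chain samples
$\exp(-V^*/kT)$ exactly up to an $O(k\,\Delta t/2\gamma)$ discretisation
factor, which the equipartition test budgets for. $k_B = 0.0019872$
kcal/mol/K throughout and 300 K is the default temperature, so
$kT = 0.596$ kcal/mol.

Reweighting (`reweight_profile()`) accumulates the Boltzmann factor
$e^{\Delta V / kT}$ per bin and reports $F = -kT\log(\text{weight})$,
min-shifted. With $\Delta V \equiv 0$ it is bit-identical to the unweighted
histogram. Weights are accumulated in log space (shift by
$\max \Delta V$) so large boosts cannot overflow. On desk-scale toys the
reweighted boosted profile recovers the analytic free energy of a harmonic
well within 0.15 kcal/mol and a constructed 1.0 kcal/mol two-well asymmetry
within 0.2 kcal/mol; on large biomolecular systems the exponential
reweighting is notoriously noisy, which is why landscape analysis below
defaults to *unweighted* surfaces and treats them as comparative estimates.

## Free-energy landscapes and conformational states

`build_fel()` bins a two-CV series on a regular grid (default 0.3 Å for both
CVs, the value at which the minima positions and populations are stable in
the convergence checks) and sets $F = -kT \log(n_{bin}/N)$, shifted so the
global minimum is zero — the zero-reference convention is the global
minimum, a choice the shift-invariance tests make explicit. Ranges are taken
from the data with half-bin padding, which means bins straddling the edge of
the sampled support are only partially covered; flatness assertions in the
tests therefore evaluate interior bins.

Bins with fewer than `min_count = 5` samples are *masked* rather than given
a pseudo-count: a pseudo-count floor would decorate the landscape rim with
spurious shallow minima, whereas masked bins simply cannot host minima or
carry paths.

`find_minima()` reports valid bins strictly lower than all valid
8-neighbours, then merges minima lying within `merge_radius = 0.6` Å (two
default bins) of a deeper minimum — sampling noise on a wide basin otherwise
splits it into sibling pits. Basin populations come from steepest-descent
assignment of every valid bin. `classify_states()` applies fixed
accessibility thresholds: cap pocket open at CV1 > 10 Å, cofactor pocket
open at CV2 > 11 Å, closed below 9 Å and 10 Å. Because the open thresholds
and closed bounds do not meet, frames in the 9–10 / 10–11 Å bands get an
explicit `intermediate` label instead of a forced assignment; every frame
receives exactly one label and the fractions sum to 1.

`barrier_height()` reads a barrier as a transition-state (saddle) height:
the minimax path value — over all 8-connected paths through valid bins, the
smallest possible maximum of $F$ along the way — minus the endpoint free
energy. A sum-of-energies cost would grow with path length and stop meaning
a saddle. The minimax value is symmetric in the endpoints, so the barrier is
reported from *both* sides (`barrier_from`, `barrier_to`); which one is
"the" barrier depends on which basin the transition leaves, and both
readings are returned rather than guessed. Masked bins are impassable and a
disconnected landscape is an error, not a zero.

`fel_convergence()` rebuilds the surface from leading fractions
(0.25/0.5/0.75/1) of the series and at bin sizes 0.2–0.5 Å, comparing minima
counts and positions and the RMS $F$ difference against the full-data
reference; `converged` requires the two largest fractions to agree in minima
count with positions shifting less than one bin.

## Residue networks and communities

`cross_correlation()` computes the normalised fluctuation covariance
$C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}$ of
per-residue anchor atoms (Cα when present) after two-pass mean-structure
superposition, so rigid-body motion never masquerades as correlation.
Zero-variance residues are flagged and their rows masked.

`contact_network()` draws an edge when the minimum heavy-atom distance
between two residues is below 4.5 Å in at least 75 % of frames (the
comparison is `>=`: "at least" read literally, and the tests pin the
boundary case). Sequence-adjacent pairs ($|i-j| \le 1$) are excluded —
backbone neighbours are trivially in contact and would wash out the
dendrogram — with the span configurable. Edge *length* defaults to
$-\log|C_{ij}|$, the standard dynamical-network convention (strong coupling
= short edge), clamped to $[10^{-4}, 20]$ so perfect or vanishing
correlations stay finite; uniform lengths are available when correlation
weighting is not wanted, since a purely contact-based network is also a
defensible reading.

`girvan_newman()` iteratively removes the edge with the highest weighted
shortest-path betweenness, recomputing betweenness after every removal, and
returns the nested partition maximising modularity on the original graph.
Modularity weights are the edge affinities $e^{-\text{length}}$ (i.e.
$|C_{ij}|$ under the default weighting), so the two weight senses — length
for paths, affinity for cohesion — stay consistent. Ties in the maximum
betweenness are broken by the lexicographically smallest residue pair,
making runs bit-reproducible. `community_graph()` aggregates the betweenness
of edges crossing each community pair into the *cumulative betweenness*, the
quantity drawn as inter-community edge width (node radii scale with
$\sqrt{\text{size}}$ so area tracks residue count).

Betweenness and modularity evaluation are delegated to igraph; the
Girvan–Newman loop, tie-breaking and coarse-graining are this package's.
The test suite checks betweenness against brute-force path enumeration and
the selected partition against exhaustive modularity search on small graphs
— noting that GN is restricted to its dendrogram, so on adversarial graphs
the exhaustive optimum may not be reachable; the suite requires GN never to
claim *more* than the optimum and to reach it on structured cases.

## Pocket volumes

`build_reference_envelope()` voxelises (default 1 Å spacing) the region
within the maximum probe radius of defining coordinates (bound-ligand atoms
or seed points) over reference snapshots (default 2000, capped at the
trajectory length), removing voxels buried in protein in more than 95 % of
snapshots. `pocket_volume_frame()` then throws uniform Monte-Carlo points
(default 10 000) into the envelope and classifies each as pocket interior
when:

1. it lies outside all atoms but within `r_max = 6` Å of the nearest
   surface (clearance above `r_max` means bulk solvent, not pocket);
2. some *empty probe sphere* with radius in $[1.2, 6]$ Å contains it. The
   lower bound is the nominal minimum probe radius (3 Å) relaxed by a slack
   of 1.8 Å; the containment test walks a trial centre away from the
   nearest atom (up to four steps) until an empty sphere of admissible
   radius covers the point. The naive alternative — requiring the point's
   own clearance to exceed the minimum radius — would carve away a rind of
   that thickness along every pocket wall and underestimate an analytic
   spherical cavity by tens of percent, which is inconsistent with what a
   probe-sphere (alpha-sphere) volume means;
3. it is *buried*: at least half of the 26 lattice ray directions hit an
   atom within 8 Å. This separates enclosed pockets from open exterior
   dimples; both thresholds are configuration.

Volume = envelope volume × interior fraction; it can never exceed the
envelope, and a frame with no atoms returns the full envelope volume (a
fully open envelope). Atom radii default to a uniform 1.7 Å unless the
topology carries per-atom values. Frame $f$ of a series uses seed
`seed + f - 1`, so frames are independently reproducible. The Monte-Carlo
standard error contracts as $1/\sqrt{\text{iterations}}$, which the suite
verifies by doubling.

## Synthetic data: what it emulates, and what it does not

The generators provide every input class with known answers, emulating the
statistical structure of enhanced-sampling trajectories at desk scale:

* `gen_cv_series()` draws a Markov state chain (resampling move with
  probability `switch_prob`, stationary distribution exactly the state
  weights) with axis-aligned Gaussian emissions. Markov switching — not
  i.i.d. draws — gives the series realistic autocorrelation so
  convergence-with-sampling tests are meaningful. No CV1–CV2 covariance is
  modelled: the basins being emulated are roughly isotropic, and a
  covariance extension would not change any recovery contract.
* `gen_bead_trajectory()` mixes a shared block factor (weight $\sqrt\rho$)
  with independent noise so within-block displacement correlations are
  $\rho$ and cross-block correlations vanish. Scheduled contacts place the
  pair at exactly the contact distance in a deterministic, evenly spread
  set of frames — occupancy thresholds can then be tested exactly, at the
  cost that a scheduled frame overrides the second bead's own displacement.
  Community-recovery fixtures therefore use *geometric* bridges (clusters
  whose rest geometry keeps exactly one inter-block pair in permanent
  contact) so correlations stay untouched.
* `gen_cavity_system()` builds concentric golden-spiral bead shells tangent
  to an analytic spherical cavity ($V = \tfrac43\pi r^3$), or a solid
  cluster for the zero-cavity reference.
* `make_potential()` provides harmonic, 1D double-well (exact saddle
  `barrier` above the minima at `tilt = 0`) and 2D two-well forms, plus an
  optional cosine dihedral-like channel; `sample_potential_2d()` draws
  Boltzmann samples by Metropolis Monte Carlo.

Every generator takes a mandatory seed and is a pure function of
(spec, seed). What passing tests on these fixtures shows is that the
*analysis machinery* is correct at its contracts; they do not establish
anything about force fields, solvent, all-atom detail, or the physical
realism of any particular protein's landscape.

## Problem sizes and determinism

The validation experiments run at sizes chosen to keep statistical error
comfortably inside each tolerance on a single CPU: landscape recovery uses
1–2 × 10⁵ CV samples (sampling error of a minimum position ≈
$\sigma/\sqrt{N w}$, far below the 1.5-bin tolerance), barrier recovery
5 × 10⁵ Metropolis samples, Langevin checks 2 × 10⁴–2 × 10⁵ steps at
timesteps 0.005–0.02 (stability limit of the steepest toy force), bead
systems 400–2000 frames, and pocket estimates 2000–10 000 Monte-Carlo
points per frame. All randomness flows through explicit seeds; pipeline
stages derive their seeds from the single global seed by fixed offsets, and
identical configurations reproduce identical output hashes in the run
manifest.

## Known limitations

* Unweighted landscapes are comparative estimates, not equilibrium free
  energies; the reweighted mode is exact only in the small-boost regime.
* The minimax barrier is a lower bound on the true saddle when the saddle
  region is under-sampled enough to be masked (the path then detours) and
  is biased low by up to roughly half a bin of discretisation.
* Girvan–Newman explores only its own dendrogram of nested partitions;
  modularity is maximised within that family.
* The pocket estimator is a probe-sphere volume on a fixed envelope — it
  does not discover pockets ab initio, score druggability, or aim for
  parity with any external cavity-detection binary.
* The PDB/DCD readers cover the clean subset the pipeline emits
  (no insertion codes; first altloc only; single segment), by design.
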