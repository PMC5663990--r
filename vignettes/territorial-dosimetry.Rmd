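---
title: "Territorial partition-model dosimetry for Y-90 radioembolization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Territorial partition-model dosimetry for Y-90 radioembolization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirtpartition)
```

## The problem

Selective internal radiation therapy (SIRT) delivers yttrium-90-loaded
microspheres through the hepatic artery. Planning has to answer one
question — how much activity to administer — under two safety constraints
(mean dose to normal liver and to the lungs, which receive whatever
activity shunts through the hepatic circulation) and one efficacy goal
(enough dose to the tumors). The pre-therapy Tc-99m MAA SPECT/CT provides
a surrogate image of where the microspheres will lodge; counts in that
image act as relative activity weights.

The classical MIRD partition model (PM) splits the body into three
compartments — lung, normal liver, tumor — and assumes activity is uniform
inside each. That assumption is weakest exactly where it matters: the
normal liver is large, and its perfusion is anything but uniform. This
package implements a territorial model (TM) that keeps the partition-model
mathematics but partitions the normal liver into *arterial territories*
(one per supplying artery branch), gives every disconnected tumor its own
partition, and excludes an 11-mm shell around tumors — the maximum Y-90
beta range, and roughly twice the SPECT resolution — from normal liver so
that tumor spill-out does not masquerade as normal-liver uptake.

## Dose model

All dosimetry rests on the single-compartment MIRD relation. An activity
$A$ (GBq) decaying completely in a mass $m$ (kg) deposits

$$ D = k \frac{A}{m}, \qquad
   k = \langle E\rangle \frac{T_{1/2}}{\ln 2}
     = 49.38~\mathrm{Gy\,kg\,GBq^{-1}}, $$

with $\langle E\rangle = 0.9267$ MeV per transition and
$T_{1/2} = 64.04$ h. `dose_constants()` evaluates $k$ at full precision
(49.38305…); 49.38 is only the conventional rounded display value.

With lung shunt fraction $L = c_L / (c_L + c_{NL} + c_T)$ and
tumor-to-normal concentration ratio
$T/N = (c_T/m_T)/(c_{NL}/m_{NL})$ estimated from image counts $c$, the
classical doses are

$$ D_L = \frac{k A_0}{m_L} L, \qquad
   D_{NL} = \frac{k A_0 (1-L)}{m_{NL} + (T/N)\, m_T}, \qquad
   D_T = (T/N)\, D_{NL}. $$

The territorial generalization replaces the two liver compartments with an
arbitrary partition set $\Sigma$. Writing $f_i = A_i / \sum_{j\in\Sigma} A_j$
for the fractional uptake of partition $i$ (estimated by its count share),

$$ D_i = \frac{k A_0 (1-L)}{m_i} f_i . $$

For $\Sigma = \{NL, T\}$ this reduces algebraically to the classical
equations — the package asserts that identity to $10^{-10}$ relative over
randomized inputs, and also the energy balance
$\sum_i D_i m_i = k A_0 (1-L)$.

## Arterial territories

`skeletonize_vessels()` thins a binary artery mask to a single-voxel-wide
centerline by sequential removal of simple points under (26,6) digital
topology, with six directional subiterations and retention of curve
endpoints. `build_centerline_graph()` classifies skeleton voxels by
neighbor count (1 = endpoint, ≥ 3 = ramification), merges touching
ramification voxels into one bifurcation node, and traces junction-free
chains into branch polylines in world millimetres. Two clean-up steps make
the result a usable tree:

* **Cycle breaking.** Thinning artifacts can close small loops; the
  maximum-length spanning tree is kept, i.e. the shortest cycle edge is
  dropped, with a warning.
* **Spur pruning.** Junctions of tubes more than a couple of voxels wide
  sprout short terminal spurs. Terminal branches shorter than two voxel
  diagonals hanging off a junction are removed and the resulting
  pass-through nodes merged. The threshold comes from the geometry of the
  artifact (spurs are at most about two voxels long); real branches at
  clinical scales are an order of magnitude longer.

`assign_territories()` then labels every liver voxel with the branch whose
centerline is nearest in anisotropy-aware Euclidean distance (polylines
densified to ≤ 1 mm so the discretization error stays below voxel size;
distance ties go to the lowest branch id). Distances are always computed
in millimetres — on a typical CT grid of 0.98 × 0.98 × 5 mm, voxel-index
distances would be badly wrong. Grouping branches into named territories
is deliberately decoupled from anatomy: `group_branches()` either takes an
explicit map or groups by the subtree rooted at a chosen generation.
Classical segmental anatomy can be emulated by an explicit map when the
operator knows which branch feeds which segment.

One design point deserves a note. Branches *above* the grouping generation
(the shared trunk) must land in some territory. Assigning them by branch
id made the result depend on the arbitrary numbering a skeleton trace
produces, so the trunk instead joins its *dominant* descendant subtree —
the one with the greatest total centerline length — with ids only as a
tie-break. This is invariant under relabeling and keeps ground-truth
comparisons meaningful.

A hard guarantee, tested voxel-wise: territories are exhaustive and
mutually exclusive over the liver region, and they exactly match a
brute-force nearest-point scan on grids up to $32^3$.

## Counts, margins, masses

`partition_counts()` turns a count image plus masks into a partition
table: one lung row, one row per territory, one row per 26-connected tumor
component, and one row for the 11-mm margin shell. Three choices matter:

* **Margin disposition.** By default the margin is its own
  `excluded_margin` partition: its counts stay in the liver-side activity
  balance (so the shunt fraction and the energy balance are unaffected)
  but contribute to no normal-liver or tumor dose and to no planning
  constraint. Merging the shell into the tumors, or dropping it entirely,
  are available alternatives (`margin_policy()`); merging is hard to
  defend when tumor doses computed with and without the margin should
  barely differ, and dropping breaks activity conservation, so neither is
  the default.
* **Count capture (`capture_mm`).** The imaging point spread pushes
  counts just outside organ masks. With `capture_mm > 0`, background
  voxels within that distance of a partition contribute their counts to
  the nearest partition — the volumetric analogue of the generous regions
  drawn in clinical shunt quantification. Masses always come from the
  anatomical masks. In the phantom studies 10 mm (about four times the
  PSF sigma) recovers spilled counts while the lung-liver separation
  keeps capture regions disjoint.
* **Masses.** Volume × density with a uniform 1.05 kg/L default. A single
  configurable density is used for all partitions, including lung; users
  with CT-derived lung masses can substitute them directly in the table.

Counts are booked exactly once: partition sums plus the background
remainder always equal the image total, an identity the tests assert with
integer exactness.

## Activity planning

Every dose above is linear in $A_0$, so threshold-constrained planning
(`plan_activity()`) inverts in closed form, with no root finding:
$A_0 = \min(A_0^{NL}, A_0^{L})$ where $A_0^{NL}$ puts the mean
normal-liver dose at its limit (mass-weighted mean over territories,
equivalent to the pooled normal-liver dose; an unweighted mean is
available) and $A_0^{L}$ puts the lung dose at its limit. Two published
threshold presets are built in: T1 = (lung 25 Gy, normal liver 70 Gy,
tumor > 100 Gy) and T2 = (25, 40, > 100). The tumor minimum is a reported
flag, never a constraint — a plan that underdoses the tumor is still a
plan, and flagging matches how the thresholds are used clinically. An
optional maximum-tumor-dose cap can be enabled (`tumor_max_Gy`) for cases
where an unconstrained plan would deliver several hundred gray to a small
tumor; it is off by default.

Under the classical model the margin partition is folded back into normal
liver before inversion — the PM has no margin concept — so a single
partition table supports both models. Two consequences follow directly
from the algebra and are verified on phantoms:

* When the lung limit binds, PM and TM invert the same equation and
  prescribe *identical* activities.
* When the liver limit binds and the tumor is hot, excluding the (hot)
  margin lowers the normal-liver fractional uptake more than its mass, so
  TM prescribes *more* activity than PM, and at fixed activity the
  margin-excluded normal-liver dose is strictly lower.

`bsa_activity()` implements the empirical body-surface-area prescription
$A = 0.20247\,h^{0.725} w^{0.425} - 0.2 + V_T/V_{total}$; it depends only
on patient size and tumor volume fraction, never on counts, and is
reported alongside the models by `compare_models()`.

## The synthetic phantom

No patient data ships with the package; `build_phantom()` generates
everything the chain needs, deterministically per seed:

* an ellipsoidal liver and a lung slab on a 64³ grid of 4.795-mm
  isotropic voxels (the resolution of a typical MAA SPECT);
* a recursive bifurcating arterial tree grown from an inlet inside the
  liver (per-branch random angles and lengths, tapered per generation,
  clipped to the liver), rasterized with its radii into a vessel mask;
* spherical tumors (default: one of 20 mm radius);
* a ground-truth activity density — uniform in normal liver, `true_TN`
  (default 6) times higher in tumors, lung scaled to a `true_lung_shunt`
  (default 0.1) share of total activity;
* a count image: activity normalized to 2 × 10⁶ expected counts, blurred
  with a 6-mm-FWHM Gaussian (the reconstruction point spread of the
  emulated SPECT protocol), then Poisson-sampled.

The blur uses zero padding with the organs kept well away from the grid
boundary, so convolution conserves counts to 10⁻⁶ relative — the property
that makes count bookkeeping exact downstream. The lung slab sits ≥ 30 mm
above the liver; anatomically the diaphragm separation is smaller, but
the gap guarantees that blurred counts from one organ cannot enter the
other's capture region, which is what lets the phantom isolate estimator
bias from geometric cross-talk.

What the phantom does *not* emulate: projection/reconstruction physics
(no sinograms, attenuation, or scatter — the Gaussian stands in for the
reconstructed resolution), respiratory motion, microsphere discreteness,
heterogeneous intra-tumor uptake, and registration error between masks.
Passing phantom tests therefore validates the *algorithmic* chain — count
bookkeeping, geometry, closed-form inversions — not the clinical accuracy
of MAA as a microsphere surrogate.

Deliberate phantom-recovery properties, all under fixed seeds:

* noiseless, unblurred counts return the true shunt fraction and T/N to
  10⁻⁶;
* with blur and Poisson noise, the shunt estimate averaged over 100 seeds
  stays within 3 binomial standard errors of one acquisition;
* spill-out biases the blurred T/N estimate strictly toward 1 (between 1
  and the true ratio for the default 20-mm tumor) — the very effect the
  11-mm margin is designed to absorb;
* territory labels recovered from the rasterized, re-skeletonized vessel
  mask agree with the ground-truth labels on ≥ 95 % of voxels.

## Numerical choices

* **Thinning parity.** Six-subiteration thinning of an *even*-width tube
  collapses it (there is no central voxel plane to converge to); a
  voxel-centered (odd-width) tube yields an exact axis centerline. This
  matches the behavior of the standard 3-D thinning implementations and
  is why centerline accuracy is assessed on voxel-centered tubes.
* **Distance transforms** use the separable lower-envelope algorithm with
  anisotropic spacing — exact center-to-center distances, linear cost.
* **Tie-breaks** are deterministic everywhere: lowest branch id for
  equidistant centerlines, first-encountered component in labeling.
* **Zero activity** in a partition gives fractional uptake 0 by limit, no
  division; zero masses with nonzero counts are hard errors.
* **Degenerate inputs**: empty masks error; multi-component vessel masks
  are reduced to the largest component with a warning; a margin that
  swallows the whole normal liver is an error rather than a silent empty
  partition.
* Internal arithmetic is full precision; rounding to two decimals happens
  only in printed reports.

## Problem sizes

The shipped tests and the acceptance script run the full chain on 64³
phantoms (about 20 000 liver voxels, 2 × 10⁶ counts), brute-force oracle
comparisons on 32³ grids, and 100-seed noise ensembles — sizes chosen so
the whole suite exercises every code path in a few minutes on one core
while keeping the Poisson noise floor well below the tolerances being
asserted.

## Limitations

The model inherits every limitation of partition dosimetry: uniform
uptake within each partition, counts as activity surrogates without
partial-volume correction, and reliance on the MAA distribution as a
microsphere surrogate. Territory accuracy is bounded by the vessel
segmentation it is given — contrast timing, resolution and noise enter
upstream of this package. Voxel-level dose kernels and Monte Carlo
transport are intentionally out of scope: the package computes
partition-mean doses and renders them as piecewise-constant maps.
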