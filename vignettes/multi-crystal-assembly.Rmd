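---
title: "Assembling diffraction data from many partial microcrystal wedges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling diffraction data from many partial microcrystal wedges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalmerge)
```

## Why assemble wedges at all

A microcrystal survives only a short rotation range in the beam, so each
crystal yields a *partial* dataset — here modelled as a 20° wedge divided
into frames — that is individually far from complete. Solving a structure
from such material means pooling on the order of a hundred wedges, and the
pooling is only as good as three decisions: which crystals belong
together (non-isomorphism), how each wedge is brought onto a common
intensity scale, and which crystals or frames should be discarded
outright. `xtalmerge` implements that pipeline end to end and, because raw
data of this kind is rarely deposited, ships a simulator whose ground
truth makes every stage falsifiable.

## The data model

Observations are SHELX-style records `(h, k, l, I, σ, frame)` plus a
per-crystal sidecar (unit cell, wedge start/width, wavelength, space
group). Symmetry is handled through explicit operator lists for the
built-in groups P1, P2₁, C2, P2₁2₁2₁ and P4₃2₁2 (arbitrary groups can be
supplied as operator lists). The canonical asymmetric-unit representative
of an orbit is the lexicographically largest index among all rotation
images (and Friedel mates when merged) — a convention that needs no
per-group boundary tables, is idempotent, and is stable across software
versions. Systematic absences come from the operator criterion (an index
fixed by a rotation whose translational phase shift is non-integral),
which reproduces the textbook screw-axis and centring rules and feeds the
completeness denominators.

## The scaling model

Each scaling group $j$ (a crystal, or a frame when per-frame scaling is
on — frames inherit their crystal's B and contribute only a scale) relates
its observations to the merged means by

$$ I_{obs}(h, j) \approx k_j \, e^{-2 B_j s^2 / 4} \, \langle I(h)
\rangle, \qquad s = 1/d . $$

The fit alternates inverse-variance merging of currently corrected
intensities with per-crystal weighted least squares, where $k$ has a
closed form given $B$ and $B$ is refined by 1-D minimisation on
$[-60, 60]$ Å². Convergence is declared when the largest relative
parameter shift drops below $10^{-6}$ (cap 100 iterations). The overall
scale and B origin are not identifiable from relative data, so the gauge
$\overline{\log k} = 0$, $\overline{B} = 0$ is imposed after every sweep;
consequently a constant rescaling of one crystal's data is absorbed into
the scales and only shifts the merged set by one global factor. The fit
refuses collections whose crystal graph (edges = pairs sharing at least
`min_common` unique reflections, default 20) is disconnected, naming the
components, since relative scales across disconnected components would be
meaningless.

Merging is the standard inverse-variance weighted mean per canonical
index, with $\sigma_{merged} = (\sum \sigma_i^{-2})^{-1/2}$ and the
agreement statistics in their multiplicity-corrected forms (R_merge,
R_meas with $\sqrt{n/(n-1)}$, R_pim with $\sqrt{1/(n-1)}$), computed over
multiply observed reflections. Shells partition $(d_{max}, d_{min}]$ with
equal volume in $1/d^3$ (default 10 shells). Empty or singly-observed
shells report `NA`, never fabricated zeros.

CC1/2 is the Pearson correlation of merged means over two balanced random
half-subsets of each multiply observed reflection. The half-split
assignment is derived from a content hash of each observation (indices,
frame, quantised intensity) mixed with the seeded split stream, rather
than from positions in memory: this keeps CC1/2 invariant under
observation reordering and crystal relabeling while still giving
independent splits across seeds — with `n_splits > 1` the mean and sd
over splits are reported, and a single split lies within a few sd of the
mean. The anomalous correlation CC_anom applies the same half-split
machinery to the Friedel differences $\Delta I = \langle I^+ \rangle -
\langle I^- \rangle$ of rotation-canonical pairs and requires a
Friedel-unmerged space group; shells with fewer than 3 usable pairs are
`NA`.

## Grouping by unit-cell variation

Cells are clustered on their six parameters after centring and division
by a *common* scale — the largest per-parameter standard deviation across
the population (angle weight configurable). The obvious alternative,
per-parameter standardization, whitens every jittering parameter to unit
variance; a genuine shift confined to one axis (the typical
non-isomorphism signature, e.g. a shrunken *a* axis) then drowns in the
remaining axes, and we verified numerically that populations separated by
five jitter sigma in *a* become inseparable under it. The common-scale
variant keeps the relative magnitudes of variation — which carry the
signal — while making lengths and angles commensurable. Average-linkage
agglomerative clustering is cut at `max_groups` (default 20) or at a
height; crystals farther than `reject_z` (default 3) standardized units
from their group centroid are rejected. Ties are broken by input order,
so the grouping is deterministic and permutation of the input only
permutes labels.

At five-sigma separation an individual crystal can still land past the
midpoint between two populations (probability $\Phi(-2.5) \approx 0.006$
per crystal); such draws are intrinsically unclassifiable, so
label-perfect recovery of every crystal on every seed is not a property
any metric can guarantee — the `validation_clustering_ari()` benchmark
reports the per-seed adjusted Rand indices so near-misses are visible.

## Group selection, ranking and iterative rejection

Groups are merged independently; only groups with overall completeness
strictly above the gate (default 0.90) are considered further. Among
those, the winner is ranked by overall CC1/2, then completeness, then
number of uniques, then group id. The historical arbiter for such a
choice is the refined R_free of each candidate dataset; refinement
requires phases and a model and is deliberately out of scope here, so
merged-data quality stands as the proxy and the report says so.

Rejection is greedy steepest ascent on the objective (overall CC1/2, or
overall CC_anom for anomalous-signal work): refit scales, evaluate the
objective with each crystal left out, accept the best removal if it
improves the objective by more than `tol` (default 0.001 absolute),
repeat; then the same loop at frame level within the surviving crystals.
Floors (`min_crystals = 3`, `min_frames_per_crystal = 2`) prevent
degenerate emptying. Every candidate evaluation is recorded and the trace
of accepted removals is monotone in the objective by construction — an
auditable alternative to batch z-score rejection. Leave-one-out refits
warm-start from the incumbent model, which keeps the loop at seconds per
iteration for tens of crystals. The objective is averaged over `n_splits`
(default 8) seeded half-splits so that split noise, not data quality,
does not drive removals at the default tolerance.

## The simulator and what it does not model

The generator assigns every observable symmetry image of every unique
reflection an independent uniform diffraction angle in $[0, 360)$ and
records the images inside each crystal's wedge, binned into frames.
True intensities follow the acentric Wilson law (exponential with mean
$\Sigma_0 e^{-B_W s^2/2}$); per-crystal scales and B offsets are uniform
on configurable ranges; noise is Gaussian with variance $I +
\text{noise\_floor}$ (Poisson-like plus background), negative recorded
intensities are kept, and $\sigma$ is the model sd. Outlier crystals draw
from a second intensity set built as $Z = \mu + \rho (X - \mu) +
\sqrt{1-\rho^2}(Y - \mu)$ — correlation $\rho$ with the truth at the same
resolution-dependent mean — and/or carry a systematic cell shift; the two
defects are independently switchable so the cell-clustering and
intensity-rejection stages can be probed separately. Anomalous signal
adds $\pm \Delta I/2$ by Friedel class with $|\Delta I| =$
`anom_fraction` $\times I$; the reference intensities always live on
Friedel-merged uniques, since mates share one structure-factor modulus
apart from that signal.

Deliberately not modelled: diffraction geometry (no Ewald-sphere ray
tracing — wedge membership is a uniform-angle abstraction that preserves
partiality statistics and multiplicity growth, not orientation
correlations), spot shape, absorption, radiation damage, and centric
intensity statistics (all reflections draw from the acentric law).
Passing tests therefore demonstrate the pipeline's statistical machinery,
not detector-level realism.

Defaults mirror the acquisition this package models: 20° wedges (10
frames), Wilson $\Sigma_0 = 100$, $B_W = 20$ Å², scale range $[0.5, 2]$,
B range $[0, 20]$ Å², noise floor 25, cell jitter 0.05 Å lengths / 0.02°
angles, and a P2₁2₁2₁ test cell of 25 × 30 × 35 Å at $d_{min} = 3$ Å —
the cell is kept deliberately small so simulations and leave-one-out
loops run in seconds; the real crystal forms' cells and intensity
statistics are not published, so these are declared package choices, as
are the clustering cap of 20 groups and the 0.90 completeness gate which
follow the multi-crystal workflow this package reimplements.

## Numerical choices and degenerate inputs

Resolution cutoffs carry a $10^{-9}$ relative epsilon so reflections on
the limit are kept regardless of floating-point route. Single-resolution
degenerate inputs widen $d_{max}$ by $10^{-6}$ relative to form one
shell. Closed-form scale estimates are floored at $10^{-9}$ to keep
$k > 0$; B search is bounded to $[-60, 60]$ Å². The merged reflection
table is sorted (decreasing d, then h, k, l) so output is deterministic
whatever the input order. Ties in alt-loc occupancy resolve to the
alphabetically first conformer. Sub-seeds for simulation streams, splits
and benchmark repeats are derived from the master seed by fixed integer
arithmetic below $2^{31}$.

## Companion modules

**Cleavage mapping.** Digestion cuts C-terminal to explicit sites or to a
residue class (K/R for metacaspase-type self-cleavage, F/Y/W for
chymotryptic sub-digestion), with 1-based inclusive numbering. Fragments
tile the parent exactly; masses are sums of the standard average and
monoisotopic residue tables plus one water, so any fragment set balances
against the parent to machine precision plus one water per cut.
Missed-cleavage variants are reported separately to preserve the tiling
invariant. The calcium-regime substrate model applies the elicitor-release
cut (after Arg69) always and the N-terminal Arg6/Arg7 cuts only at high
calcium, and only where the named residue really is K/R — so double
mutants lose the high-calcium cuts, matching the biochemical control this
models. The real protein sequences are not redistributed: deterministic
synthetic stand-ins with the documented residue classes at every named
position (and no stray K/R) make site-specific behaviour fully
determined.

**Structure geometry.** A fixed-column PDB reader (per-line diagnostics,
occupancy-based alt-loc resolution) feeds chain counting with a
20-residue polymer filter, unique-selection atom distances,
missing-residue gap detection, and a catalytic-dyad report that measures
His NE2/ND1 and Cys SG (or mutant CB) against the scissile carbonyl
carbon and marks the closest pair per side — because which atom pair
underlies a quoted dyad distance is usually unstated. Deposited
coordinate files are not bundled; a synthetic stand-in generator writes a
model with the documented gross features (two chains, a 3.2 Å dyad
geometry, residues 153–210 missing) to exercise the measurement code, and
an independent reader (bio3d) cross-checks coordinates in the tests.

## Validation benchmarks

Three exported harnesses drive the acceptance checks:
`validation_scaling_recovery()` (30 wedges; RMS relative scale error and
RMS B error after gauge alignment), `validation_rejection_efficacy()`
(20 clean + 4 half-decorrelated crystals over 10 seeds; outliers/clean
removed, monotonicity of the accepted trace) and
`validation_clustering_ari()` (two populations at five-sigma cell
separation). `scripts/acceptance.R` runs them together with the
brute-force completeness cross-check, the merge identities, the digestion
conservation sweep and a full 132-wedge assembly, and writes every
measured number as JSON.

## Known limitations

No reindexing/indexing-ambiguity resolution between indexing solutions;
no error-model refinement (SDfac/SDadd) or French–Wilson truncation
(negative merged intensities are reported as is); no binary MTZ/XDS
input; refinement-based figures of merit (R_free) are out of scope, so
group ranking rests on merged-data quality alone; and the simulator's
uniform-angle wedge abstraction means completeness patterns lack the
systematic blind regions real goniometry can produce.
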