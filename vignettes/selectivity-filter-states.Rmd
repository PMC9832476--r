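---
title: "Selectivity-filter state analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selectivity-filter state analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfstate)
```

## The problem

The selectivity filter (SF) of a potassium channel is a narrow stack of
backbone carbonyl oxygens, contributed by all four subunits, that forms five
K⁺ binding sites conventionally labelled S0 (extracellular) to S4
(intracellular). Each site is delineated by two rings of four oxygen atoms,
eight atoms in total. Which sites are occupied, how intact each site's
oxygen cage is, and whether ions and water reach the intracellular cavity
below the filter together define the functional state of the pore — in
particular the distinction between a conductive filter, a centrally
constricted (closed) filter, and a filter whose extracellular sites have
widened and effectively dissolved.

`sfstate` turns multi-frame coordinate sets of such a pore into a per-frame
feature vector built on one primitive, classifies frames into ion-
configuration states, and characterises those states. Everything downstream
of file parsing rests on a single smooth counting device, described next.

## The coordination number

For a probe point $i$ and an atom selection, the coordination number is

$$
C_i \;=\; \sum_{j} \frac{1 - (d_{ij}/d_c)^6}{1 - (d_{ij}/d_c)^{12}}
\;=\; \sum_{j} \frac{1}{1 + (d_{ij}/d_c)^6},
$$

where $d_{ij}$ is the distance from the probe to atom $j$ and $d_c$ a
cutoff. Each atom contributes a value that decays smoothly from 1 at the
probe to 0 far away, passing through exactly $1/2$ at $d_c$. The rational
$6/12$ form is the standard switching function of collective-variable
analyses. The naive quotient is $0/0$ at $d = d_c$; the implementation
evaluates only the reduced form $1/(1+x^6)$, which is continuous and
strictly monotone, and the test suite checks continuity at the cutoff to
$10^{-9}$ and equivalence with a brute-force per-atom loop to $10^{-9}$ on
random systems.

Two cutoffs are used, and both defaults are deliberate:

* $d_c = 1.4\,$Å for **K⁺ site occupancy** — roughly half the axial length
  of one binding site, so the sum over all potassium ions evaluated at a
  site center approaches 1 when an ion is centred there and 0 when the site
  is empty;
* $d_c = 3.2\,$Å for **oxygen coordination and hydration** — about the
  radius of the first hydration shell of K⁺, so the sum over all oxygen
  atoms counts the cage of carbonyl/water oxygens available to an ion.

Site centers are the unweighted mean of the eight delineating oxygens,
recomputed per frame.

## Cavity profiling

The intracellular cavity is probed along the pore axis on a segment
starting 2 Å below the lower boundary of S4 (the mean axial position of the
bottom oxygen ring) and extending 20 Å toward the intracellular side.
The axis is the topology's `pore_axis` (the z axis by default; trajectories
are assumed axis-aligned, which is how production systems are commonly
built). Two summaries are taken per frame:

* **cavity K⁺ presence** — the *maximum* of the potassium coordination
  profile over the segment. The maximum makes the estimate independent of
  where along the axis the ion sits; the test suite translates a single
  on-axis ion across the segment and requires the estimate to stay within
  1% of 1.
* **cavity hydration** — the *minimum* of the oxygen coordination profile.
  The minimum is the right summary because the question is whether any
  stretch of the axis lacks water; a continuous column scores well above 4
  at every point, while a planted 7 Å gap drops the minimum below 1.

The probe spacing is not a physically determined quantity; 0.5 Å (41 points
over 20 Å) is fine enough that the max/min summaries are insensitive to the
grid (the z-independence check above holds to well under 1%), and it is
configurable.

Dwell events generalise the per-frame presence estimate to residence times:
an ion is "inside" while its axial projection lies within the segment and
its radial distance from the axis is at most 1.4 Å. Excursions of at most
two consecutive frames do not split an event (saved frames are sparse
relative to barrier recrossings; the tolerance is configurable), the exit
frame is exclusive, and durations are `(exit − entry) × frame_interval`.
Events longer than 10 ns count as stable binding.

## Geometry metrics

Opposite-subunit ("diagonal") distances are the standard readout of filter
diameter. Given the four copies of an atom, the two diagonal pairs are
identified by farthest-neighbour matching — each atom pairs with the
farthest of the remaining three — rather than by chain-label convention, so
arbitrarily labelled assemblies work. The reported value is the mean of the
two diagonals (for a perfect four-fold ring this equals twice the radial
distance from the axis). Distance tables report mean ± SD over frames at
full precision; one decimal is conventional for display.

The SF backbone RMSD compares mapped residues (default backbone atom set
{N, CA, C, O}, overridable — "backbone" is convention-dependent) across all
four subunits against a reference structure. Whether such an RMSD should be
computed after an optimal rigid-body superposition or in a common
axis-aligned frame is genuinely open — both conventions appear in the
literature and neither is privileged here. Both modes are provided
(`superpose = TRUE` is the default; with `superpose = FALSE` the measure is
translation-covariant, e.g. a uniform (1,1,1) Å shift gives exactly
$\sqrt3$).

## State clustering

Frames are clustered on the five S0–S4 K⁺ occupancies only. Ion
configurations are a natural state coordinate: an ion in S2 is incompatible
with a centrally constricted filter, and configurations map directly onto
the states visited during conduction. The cavity and oxygen-coordination
features are *descriptive* — they characterise clusters after the fact but
do not enter the metric.

Clustering is agglomerative with Euclidean distance and Ward linkage
(`stats::hclust(method = "ward.D2")`, the Ward variant consistent with
unsquared Euclidean input). The number of clusters is chosen by the maximum
of the mean silhouette width over a candidate range (default 2–15,
configurable); ties break toward the smaller k for parsimony. A maximal
silhouette below 0.25 triggers a low-confidence warning. Note that the
silhouette is scale-invariant, so a single tight Gaussian blob does *not*
score near zero when split — genuinely structureless (e.g. uniform) feature
clouds do, and that is what the warning is calibrated against.

Because the exact silhouette is quadratic in the number of frames, scoring
is performed on a stratified random subsample when the input exceeds 20,000
rows (fixed seed; exact mode simply means staying under the cap). The
dendrogram itself is also capped, with overflow rows assigned to the
nearest cluster centroid; at the frame counts used in this package's tests
and acceptance runs everything is exact.

Cluster summaries report, per cluster: probability (fraction of frames),
mean and first/third quartiles of each of the 12 features
(linear-interpolation quantiles, `stats::quantile` type 7 — a documented
convention choice), and a representative frame chosen as the feature-space
medoid, the member minimising the summed distance to its cluster. The
medoid is a deterministic, outlier-robust choice for "a representative
snapshot".

When several replica trajectories of one system are analysed, the default
is to pool all replicas into one feature matrix while retaining per-row
(replica, frame) provenance, so states rare in any single replica can still
form clusters.

## The synthetic generator

`synthetic_spec()` / `generate_ensemble()` build a pseudo-atom filter: six
stacked rings of four oxygens (plus Cα pseudo-atoms on the carbonyl rings),
K⁺ ions, and a water column in the cavity. This is *not* a protein model —
it is the minimal geometry for which every metric above has a known ground
truth. Defaults encode the study conditions the package is meant to
emulate:

* `frame_interval = 0.01` ns (coordinates saved every 10 ps);
* ring separation 2.8 Å, consistent with the occupancy cutoff being half a
  site length;
* conductive boundary-ring diameters 5.1/4.7/4.7/4.5 Å top to bottom — the
  crystallographic conductive-filter values for the Y78-, G77-, V76- and
  T75-like rings — with the S0 top ring at 5.1 Å and the hydroxyl ring at
  4.5 Å;
* Cα rings 3.4 Å wider in diameter than their oxygen rings, which places
  the conductive Gly-ring Cα diagonal at 8.1 Å;
* the **widened** state inflates the S0/S1 boundary ring by +4 Å diameter
  (the magnitude seen at the extracellular entrance of inactivation-prone
  filters); this pushes the oxygen coordination of S0 and S1 below 5 while
  leaving S3/S4 within 5%, which is exactly the cluster-characterisation
  logic the package applies to real data;
* the **constricted** state scales the two S2-bounding rings by 5.5/8.1,
  the Cα-diagonal ratio between the closed and conductive filter;
* isotropic, uncorrelated Gaussian noise per atom per frame, default
  σ = 0.1 Å — the simplest perturbation that exercises the statistics
  (real thermal motion is correlated and anisotropic; see limitations);
* the water column spans the probe segment with 1.4 Å axial spacing and
  extends a few Å past both ends, because the physical cavity connects to
  bulk water and a column truncated at the probe boundary would fake a
  hydration deficit at the segment ends.

Ion schedules are either explicit per-frame configuration indices or draws
from a configuration pool with given weights; `plant_ion_dwell()` adds a
cavity ion resident for exactly `ceiling(duration/frame_interval)`
consecutive frames. Everything is reproducible bit-for-bit from the seed,
and noise-free ensembles are exactly four-fold symmetric.

What passing tests on this generator do **not** show: that the feature set
separates states in real trajectories with correlated dynamics, partial
occupancies, off-axis ions, or protein oxygens competing with water. The
generator validates the *machinery* (the estimators recover planted truth);
scientific conclusions on real systems still require the real systems.

`reference_structures()` returns paired noise-free conductive/constricted
single frames. These are synthetic idealisations built from published
filter dimensions, not deposited experimental coordinates, and they are
labelled as such wherever they appear.

## Numerical choices and degenerate inputs

* The switching function is never evaluated in its $0/0$ form. Note two
  floating-point plateaus: below $d \approx 0.3 d_c$, $(d/d_c)^6$
  underflows against 1, and deep in the tail neighbouring doubles coincide;
  strict monotonicity holds everywhere the value is resolvable.
* Empty atom selections give coordination 0 by contract rather than an
  error; an all-empty feature column is legal input to clustering.
* `exit_frame` of dwell events is exclusive, making the duration formula
  exact for both the "1001 frames at 0.01 ns = 10.01 ns" and the
  "500 frames = 5 ns" arithmetic.
* Cluster-count candidates must lie in $[2, n-1]$; `k = n` is allowed in
  `cluster_frames()` (singletons) but not in selection.
* Distances are kept at full precision internally; display rounding is the
  caller's concern.
* Problem sizes in the shipped tests and acceptance study — 5,000-frame
  ensembles, 20 seeded replicates, candidate range 2–10 — were chosen so
  the planted-recovery statistics are stable (recovery is 20/20 with
  centroid separations ≥ 10 feature-σ) while the full study completes in a
  few minutes on one core.

## Known limitations

* No XTC reader: trajectories are consumed as DCD or multi-model PDB
  (plus single-structure PDB); convert upstream if needed.
* The pore axis is taken from the topology (default z), not estimated from
  the coordinates; heavily tilted or drifting pores should be aligned
  first.
* Subunit assignment relies on chain identifiers; single-chain asymmetric
  units must be expanded to the biological assembly by the user, since
  opposite-subunit distances on a monomer are meaningless.
* The silhouette criterion inherits the usual bias of favouring compact,
  equally scaled clusters; heavily imbalanced state populations can shift
  the selected k.
* Author residue numbering is used verbatim throughout; there is no
  renumbering or alignment beyond the explicit residue map.
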