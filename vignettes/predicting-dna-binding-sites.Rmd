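---
title: "Predicting DNA-binding sites from protein structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA-binding sites from protein structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdnasite)
```

# The problem and the model

Protein--DNA recognition leaves detectable marks on a protein surface:
binding residues are more evolutionarily conserved than the rest of the
surface, enriched in positively charged and polar amino acids (to
counterbalance the DNA phosphate charge), and sit in characteristic
geometric environments -- locally protruding side chains inserted into the
grooves, or globally concave channels in enzymes that envelop the double
helix. `pdnasite` turns these three signals into a patch predictor.

Every surface residue receives four descriptors, all in $[0,1]$:

* **cons** -- evolutionary conservation. Either supplied per residue from
  a file, or computed by a tree-trace calculation: for each phylogenetic
  tree built on a subsample of the sequence alignment, the trace of a
  position is the topological level (leaf $=0$, root $=L$) of the highest
  ancestor whose whole subtree conserves the query amino acid, normalised
  by $L$; traces are averaged over trees.
* **prop** -- the amino acid's propensity to occur at protein--DNA
  interfaces, linearly scaled so the most interface-prone residue
  (arginine) maps to 1.
* **cv_local**, **cv_global** -- circular variance at radii
  $r_c = 12$ Å and $100$ Å. For atom $i$,
  $\mathrm{CV}(i) = 1 - \tfrac{1}{n_i}\left\lVert\sum_{j \ne i,\ r_{ij}
  \le r_c} \hat r_{ij}\right\rVert$, averaged per residue. Values near 0
  mark protruding positions, values near 1 buried ones; the 100 Å radius
  spans essentially any protein, so cv_global locates a residue relative
  to the whole molecule.

Three scoring schemes combine pairs of descriptors; each is a sum of two
terms in $[0,1]$, so scores live in $[0,2]$:

| scheme | seed / extension | outer layer | intended target |
|--------|------------------|-------------|-----------------|
| SC1 | cons + prop | cons + (1 − cv_local) | generic conserved sites |
| SC2 | cons + cv_global | cons + prop | enveloping (polymerase-like) sites |
| SC3 | prop + (1 − cv_local) | same | sites without a conservation signal |

The seed and extension layers deliberately share one formula: in
experimental interfaces the innermost two layers (see below) can exchange
their spatial positions, so the predictor must not commit to which one it
finds first. SC3 uses a single combination for all three layers; no
outer-layer variant exists for it by design.

# Reference interfaces: support, core, rim

Experimental interfaces are extracted from bound complexes by computing
each protein residue's relative accessibility twice -- in the complex
(rasa_dna) and with nucleic atoms deleted (rasa_free) -- and keeping
residues with $\Delta$rasa $= $ rasa_free $-$ rasa_dna $> 0$. With the
25 % exposure threshold this yields three layers: *support* (buried in
both contexts), *core* (exposed without DNA, buried with it), *rim*
(exposed in both). The predictor's seed / extension / outer layers
approximate support / core / rim. Atomic contacts (strictly below 5 Å)
are split into DNA-backbone and DNA-base contacts; the sugar C1' counts
as backbone under the standard phosphodiester convention (the partition
table is configurable since conventions differ at this atom).

# The clustering procedure

The anticipated interface fraction for a surface of $x$ residues is
$f(x) = 2.66/x + 0.03$; the expected residue count is $f(x)\,x$ rounded
half-up, floored at 3 so the 1--2-residue patch filter cannot void tiny
proteins.

1. **Seeds.** The candidate pool is the top third of the expected count,
   ranked by seed-layer score (ties broken by higher conservation, then
   chain and residue number, so the whole procedure is bit-for-bit
   deterministic). Seeds are the connected components of the pool in the
   residue adjacency graph (minimal heavy-atom distance $\le 5$ Å).
   Components of 1--2 residues are discarded here only when a component of
   3 or more exists; otherwise they are retained for extension and judged
   by the final filter.
2. **Pocket avoidance.** Small-ligand pockets are conserved and deeply
   buried, and would otherwise capture the seeds. If a seed's fraction of
   highly buried residues (cv_local $> 0.9$) exceeds 20 % under SC1 or
   30 % under SC2, seed detection restarts once with all highly buried
   surface residues excluded from every candidate pool. SC3 selects
   protruding residues and never needs the check.
3. **Extension.** The highest-ranked unassigned neighbour of any patch is
   admitted while it remains inside the extension pool (top two thirds of
   the expected count) and its score stays above `score_clus` (default
   0.7) times the current patch mean. Patches that touch through an
   admitted residue are merged and keep both seeds.
4. **Outer layer.** The same loop under the outer-layer formula, with a
   pool of the full expected count; growth stops when the prediction
   reaches the expected size.
5. **Relaxation.** If the completed pass predicts less than 70 % of the
   expected size, all three steps are re-run once with pools enlarged by
   1.5 and admission floors lowered by 10 % -- still far stricter than
   unbounded admission.
6. **Filtering.** Patches of 1--2 residues are always removed. If the
   prediction still exceeds 70 % of the expected size, patches are tested
   smallest-first against the 95th percentile of a random-patch null and
   removed while they fall below it, stopping at the 70 % mark or when
   every remaining patch passes.

**Cluster-mean floor.** The admission floor is applied to the candidate's
score *relative to the patch mean recomputed under the active layer's
formula*. The two layers of a scheme score on different effective scales
(e.g. SC1's outer formula replaces prop by $1-$cv_local); comparing a
candidate's outer score against a mean of seed scores would freeze the
outer layer on proteins whose interfaces are propensity-rich, so the
floor always compares like with like.

**Random-patch null.** The null size distribution is built by drawing,
1000 times (seeded), a random surface subset of the seed-pool size and
recording the largest connected component. This asks exactly the question
the filter needs answered: how large a patch does unstructured selection
of the same intensity produce on this surface?

# Scheme selection and the two-round mode

SC1 seeds are always computed first. If their mean conservation is below
0.3 (or no seeds exist), the protein is treated as carrying no usable
conservation signal and SC3 runs. Otherwise, seeds lying in a distinctly
concave region (mean cv_global $> 0.6$) without strongly favourable
chemistry (mean prop $< 0.9$) switch the procedure to SC2; in all other
cases SC1 proceeds. The three decision statistics are recorded in the
prediction's trace so every automated choice is auditable.

The *complete* mode adds a second clustering round with the complementary
scheme -- SC3 after SC1/SC2, SC1 after SC3 -- to pick up sub-regions whose
signal the first scheme is blind to (e.g. poorly conserved,
sequence-specific parts of a binding site). Round-2 residues already
predicted in round 1 are reported once, with the overlap noted on the
round-2 patch.

The *iterative* mode repeats the prediction $N$ times (seeded
`seed + run − 1`); randomness enters only through the alignment
subsampling of the conservation calculation and the filter null. A
residue's detection probability is detections$/N$, and the consensus
prediction keeps residues detected at least $k$ times, as connected
components, with layer labels set by majority vote (ties resolved toward
the inner layer). Raising $k$ can only shrink the prediction; the choice
of $k$ trades sensitivity (low $k$) for precision (high $k$) and is left
to the user.

# Evaluation

Predictions are scored against reference interfaces with the six standard
measures (sensitivity, positive predictive value, specificity, accuracy,
F1, Matthews correlation), reported multiplied by 100. A zero denominator
leaves the affected measure undefined rather than silently zero. The
evaluation universe defaults to the surface residues of the evaluated
structure -- binding is a surface phenomenon and the expected-size model
is surface-based -- but an all-residue universe is available. For paired
method comparisons, normality of the paired differences is assessed with
the Anderson--Darling test, routing to a paired t-test or a Wilcoxon
signed-rank test (significance at $p < 0.05$); with fewer than 8 pairs the
Anderson--Darling statistic is unavailable and the Wilcoxon branch is used
directly.

A per-protein "best patch or combination" evaluation mode scores every
scheme's output and reports the maximum-F1 entry
(`evaluate_best_scheme()`).

# Numerical choices

* **Accessibility engine.** Shrake--Rupley sphere sampling with a
  deterministic golden-spiral lattice (240 points per atom by default,
  probe 1.4 Å), van der Waals radii by element, and the theoretical
  per-amino-acid maxima of Tien et al. (2013) as the rASA reference.
  Absolute areas differ by a few percent from slice-based engines, so
  support/core/rim counts on real data can shift slightly depending on
  the reference table; the 25 % thresholds and all internal comparisons
  are self-consistent.
* **Surface residues** are those with rASA $\ge 5$ % (inclusive). The
  threshold is a package choice -- interface definitions in the
  literature rarely state one -- and is configurable.
* **$\Delta$rasa tolerance.** Interface membership requires
  $\Delta$rasa $> 10^{-3}$ percentage points, suppressing the sampling
  quantisation of the area engine.
* **Neighbour cutoff in the circular variance** is inclusive
  ($\le r_c$); the difference from a strict inequality is measure-zero.
  Atoms with no neighbour inside $r_c$ have undefined CV and are dropped
  from the residue mean.
* **Propensity table.** The shipped table is a synthetic stand-in
  reproducing the range (0--2.534, arginine maximal) and qualitative
  ordering of published protein--DNA propensity scales; supply a
  published scale via `read_propensities(path)` for production use.
* **Pool fractions** (1/3, 2/3, 1 × expected count) follow from the
  observation that seeds cover about a third of experimental interfaces;
  they, the admission floor, the relaxation factors and the filter
  percentile are all plain config parameters (`pdna_config()`).

# What the synthetic fixtures emulate

`make_pseudo_protein()` builds seeded, deterministic pseudo-proteins:
residues are small rigid atom clusters on a spherical shell (with an
optional conserved, propensity-biased planted patch carrying a radial
conservation gradient, as real binding sites have more conserved centres
than edges), on a shell pierced by a cylindrical channel whose lining is
globally buried (cv_global $> 0.6$ -- the enveloping-enzyme geometry), or
on helix-like curves. Optional extras: fully buried single-atom residues
enclosed in atom cages (their accessible area is exactly zero, giving
closed-form burial truth), and a deep conserved pocket -- a pit of
arginines reachable only through a long narrow chimney, so its residues
combine cv_local $> 0.9$ with probe accessibility. `make_bound_pair()`
adds a DNA pseudo-strand with canonical backbone/base atom names directly
over the planted patch, so interface extraction has construction-time
truth. `make_alignment()` evolves sequences down a random tree with
per-branch mutations outside the designated conserved columns.

These fixtures provide geometry and signals with known ground truth; they
are not physically realistic proteins. Passing the planted-recovery tests
demonstrates that the ranking, clustering, routing and filtering machinery
behaves as specified under clean contrasts (0.4+ between plant and
background); it does not measure performance on real structures, where
conservation is noisy, propensity contrasts are weaker and surfaces are
irregular. Test problem sizes -- 150-residue fixtures, 20 replicates per
property, 10-run consensus on an 80-residue fixture -- were chosen as the
smallest sizes at which the patch machinery (pool sizes 3--7, multi-patch
filtering) is exercised non-trivially.

# Known limitations

* The tree-trace conservation is a simplified re-implementation: homolog
  retrieval and Gibbs-like sequence sampling are replaced by uniform
  random subsampling of a user-supplied alignment. File-based scores are
  the fidelity path when a full evolutionary pipeline is available.
* mmCIF input, multi-model NMR ensembles and ligand typing beyond
  protein/nucleic/other are out of scope; only the first PDB model is
  read.
* The exact threshold values of the original three-step clustering are
  not published in full; the pool fractions and floors used here are
  principled defaults exposed in the configuration, not calibrated
  constants.
* RNA chains are treated exactly like DNA throughout; no RNA-specific
  features are used.
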