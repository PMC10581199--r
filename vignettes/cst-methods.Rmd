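---
title: "Chemical shift transfer: models, generators, and the assignment engine"
author: "cstransfer package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical shift transfer: models, generators, and the assignment engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cstransfer)
```

## The problem

Assigning protein NMR resonances de novo requires spectra with enough
information content to pin every chemical shift from database statistics
alone.  When an assigned *source* protein similar to the *target* exists — a
homolog, a mutant, the apo form of a complex, the same protein at another
temperature or pH — its shift list can seed the assignment of the target,
cutting the spectra requirement to a minimal set: the two 2D HSQCs
([1H,15N] and [1H,13C]) and the two 3D [1H,1H]-NOESYs (15N- and
13C-resolved).  This package implements that *chemical shift transfer*
(CST) workflow end to end:

1. **Transfer** (`localAlign`, `buildMapping`, `reindexShifts`,
   `buildSearchSpaces`): align the source to the target sequence, keep only
   columns where the residue types are identical, relabel the source shifts
   with target numbering, and build one *search space* per expected target
   atom — a center (ppm) and width (ppm).  Atoms not covered by the
   transfer fall back to per-(residue type, atom) database statistics.
2. **Assignment** (`assignShifts`): a simplified combinatorial engine maps
   expected peaks to measured peaks inside the search spaces, over many
   stochastic replicates, and takes a majority consensus per atom.
3. **Evaluation** (`accuracy`, `improvementRatio`): correctness against a
   reference list under per-nucleus tolerances, with backbone / sidechain /
   amide breakdowns and transfer-vs-de-novo ratios.
4. **Benchmark generators** (`randomPerturb`, `structurePerturb`,
   `simulatePeakLists`): controlled source/target divergence and synthetic
   peak lists, so the whole workflow is testable at desk scale without any
   experimental data.

## Search-space model

For atom $i$ the search space is a center $\mu_i$ and width $\sigma_i$.
With transfer, $\mu_i$ is the (reindexed) source shift and

$$\sigma_i = \max(\mathrm{floor}(\mathrm{nucleus}), w_i),$$

where $w_i$ is, in order of precedence: a per-atom sigma supplied by a
perturbation experiment; $c_\mathrm{CST}\cdot\sigma_i^\mathrm{stats}$ in
parametric mode; or a fixed per-nucleus width (reference setting 0.09 ppm
for 1H, 1.2 ppm for 13C/15N).  Without transfer, $\mu_i, \sigma_i$ are the
statistics mean and standard deviation.  Two floor conventions appear in
the workflow and both are available via `cstFloors()`: 0.04/0.4/0.4 ppm
(1H/13C/15N; random-perturbation experiments and the idealized reference)
and 0.03/0.4/0.4 ppm (structure-based perturbation and homolog
selection).  `idealizedSpaces()` is the upper-bound reference: the
target's own shifts as centers with floor widths.

The width is interpreted both as the scale of the initialization
distribution and, multiplied by the hard-window factor $k$ (default 3), as
an absolute acceptance window: no measured peak farther than $k\sigma_i$
from the center in any dimension is ever considered for atom $i$.  Whether
an engine should treat the width as a soft scale or a hard window is
genuinely open; we chose "both" because it makes the hard-window invariant
cheap to verify and the initialization density natural.

## Homolog qualification

Candidate source/target pairs are ranked by the local-alignment score
normalized by the target's self-alignment score (`normalizedScore`), and
by the fraction of aligned source shifts within 0.03/0.4 ppm of the target
reference (`fractionCorrectAligned`).  The selection predicate
(`selectHomologPairs`) keeps pairs with normalized score strictly above
0.8 and fraction at least 0.5.  Alignment uses BLOSUM62 with affine gaps,
gap open 10 and gap extension 0.5 — expensive to open, cheap to extend, so
optima have few wide gaps separating long aligned stretches.  These
parameters are configurable (`alignParams`); the defaults are this
package's choice, and ties between equal-scoring alignments are broken by
the dynamic program's fixed traceback, so runs are reproducible.

## Perturbation generators

Both generators add independent Gaussian noise
$\Delta_i \sim N(0, \sigma_i^2)$ to a reference shift list and report the
per-atom $\sigma_i$ (which the transfer step may then use as its width).

**Random mode** (`randomPerturb`): exactly $\mathrm{round}(pN)$ atoms
(round half up, for exact testability) drawn uniformly at random receive
noise with $\sigma_i = c\,\sigma_i^\mathrm{stats}$, $c \in \{0.2, 0.5,
1.0\}$ and $p \in \{0.2, 0.5, 1.0\}$ in the benchmark grid.  The subset is
drawn once per seed.

**Structure mode** (`structurePerturb`): residues near chosen
*perturbation centers* are perturbed, emulating localized changes such as
ligand binding or point mutations.  For residue $i$ with backbone amide
nitrogen $N_i$, the decay factor is the count of centers $g_j$ with
$\lVert N_i - N_{g_j}\rVert \le x_0$ (a step function), normalized by the
maximum count over the protein so $e_i' \in [0,1]$, and
$\sigma_i = e_i'\,c\,\sigma_i^\mathrm{stats}$.  Test-case sampling
(`sampleStructureSpecs`) draws $x_0 \sim U(5, 25)$ Å, the number of
centers uniformly from $\{1..10\}$ (the distribution over 1–10 is not
specified more precisely anywhere we know of; uniform is the neutral
choice, and a weight vector can be supplied), and center positions without
replacement.  Residues missing amide-N coordinates inherit $e_i' = 0$ with
a warning.  Noise is independent across atoms; real shift perturbations
are correlated within residues, which this deliberately statistical model
ignores.

## Peak simulation

`expectedPeaks()` enumerates, per spectrum type: one (H, N) peak per
non-proline residue from position 2; one (H, C) peak per bonded
proton–carbon pair; and for the NOESYs, each anchor proton against every
other proton of residues under the contact rule.  The default
*sequential* contact rule (intra-residue plus adjacent residues) needs no
structure; a *structure* rule (amide-N distance ≤ `dmax`, default 5 Å) is
available when coordinates exist.  `simulateMeasured()` emits retained
expected peaks at the true shifts plus per-nucleus Gaussian jitter
(defaults 0.01 ppm 1H, 0.1 ppm 13C/15N — inside the floors, so tolerances
dominate jitter), omits each with probability `missingProb`, and adds
Poisson(`artifactRate` × true peaks) spurious peaks uniform over the
occupied bounding box.  "Realistic" test settings in this package use
`missingProb = 0.1`, `artifactRate = 0.2`.

What the simulator does *not* model: lineshapes and intensities, peak
overlap/merging, solvent artifacts, spectrometer-dependent referencing
errors, and correlated omissions (e.g. whole broadened spin systems).
Passing tests therefore demonstrate internal consistency of the workflow
under idealized peak picking, not performance on experimental spectra.

## The assignment engine

The engine is an intentionally simplified stand-in for full
assignment software: it exists so the effect of search-space quality is
measurable end to end.  It is **not** a re-implementation of any published
scoring scheme.

* **State**: a many-to-one mapping from expected peaks to measured peaks of
  the same spectrum.  An atom's committed shift is the mean of the
  measured coordinates supporting it.
* **Hard constraints**: every matched coordinate lies within $k\sigma$ of
  its atom's center, and coordinates supporting one atom agree within the
  per-nucleus matching tolerance (defaults = the 0.04/0.4 floors).
* **Score**: $\sum_{\text{matched } e}\bigl[1 - \tfrac1{n_d}\sum_d
  \bigl(\tfrac{x_d - \mu_d}{k\sigma_d}\bigr)^2\bigr] - \lambda\,
  \tfrac{\#\text{unmatched}}{\#\text{expected}}$.  Deviations are measured
  from the search-space centers, not from the committed atom means: with
  center-based deviations the generating truth is the strict global
  optimum on noiseless data, whereas mean-based deviations are invariant
  under coupled swaps of symmetric atoms (e.g. the two HB protons of one
  CB) and would make exact truth recovery unattainable in principle.  This
  also makes move evaluation O(1).
* **Initialization**: expected peaks visited in random order; candidates
  sampled with weight $\exp(-\gamma\,\mathrm{dev})$ among those consistent
  with already-committed shifts ($\gamma$ = `initGreed`, default 50;
  $\gamma = 0$ recovers uniform sampling).  Near-greedy initialization is
  what prevents symmetric-atom swaps from locking in through the
  consistency constraint; replicate diversity comes from the visiting
  order and the annealing.
* **Optimization**: simulated annealing (geometric cooling, default 10
  iterations per expected peak) over three moves — reassign one peak
  (80%), swap two peaks (15%), unassign (5%) — followed by
  best-improvement polish sweeps at temperature zero.
* **Consensus**: per atom, replicate values are single-linkage clustered
  at the matching tolerance; the largest cluster's mean is the consensus,
  its size over the number of replicates the support, and assignments with
  support ≥ `sMin` (default 0.8) are flagged *strong*.  Ties prefer the
  tighter, then lower-ppm cluster.  The default of 20 replicates follows
  common practice for consensus assignment engines; benchmarks in this
  package use 4–5 replicates to keep grids tractable.

All randomness in the compiled core comes from a private Mersenne Twister
with explicit uniform mapping, so replicates are bit-reproducible across
platforms; R-level seeds are derived per stage from one master seed, so
paired experiment arms share peak lists without sharing optimization
randomness.

## Evaluation conventions

An atom is *correct* iff assigned and within the per-nucleus tolerance of
its reference shift.  The headline accuracy divides by all reference atoms
considered (unassigned counts as incorrect); the of-assigned variant is
reported alongside.  Atoms with no reference shift are excluded from the
denominator, and `simulatableAtoms()` restricts the denominator to atoms
that appear in at least one expected peak — atoms outside every peak
template (e.g. non-protonated sidechain nitrogens) cannot be assigned by
any engine run on these four spectrum types.  The backbone partition is
fixed as N, H, CA, HA(2/3), C, CB; amide = {N, H}.  Default accuracy
tolerances are 0.04/0.4 ppm, with the 0.03/0.4 alignment convention
selectable.  Pseudo-atoms (Q/M prefixed) are read verbatim but excluded
from assignment and evaluation.

## Synthetic study conditions

The packaged fixtures (`packagedProteins()`) are three 60-residue random-
sequence proteins whose reference shifts are drawn per atom from the
packaged statistics table, $x_i \sim N(\mu_i^\mathrm{stats},
\sigma_i^{\mathrm{stats}\,2})$.  The statistics table itself
(`loadStatTable()`, `inst/extdata/shift_stats_synthetic.tsv`) is
**synthetic**: field-typical means (random-coil-like) with
category-typical standard deviations (0.6 ppm amide 1H, ~0.32 ppm
aliphatic 1H, ~1.9 ppm aliphatic 13C, 4.2 ppm backbone 15N), covering
every expected atom of the 20 residues.  No value is tied to a database
release, so absolute accuracies here are not comparable to published
benchmark numbers; directions and orderings (transfer vs de novo, narrow
vs wide spaces) are the meaningful outputs.  Problem sizes used in the
tests — 60-residue proteins, 4–5 engine replicates, 4–10 seeds per trend —
are the package's chosen desk scale.

Independent-atom reference shifts also mean methyl protons get three
distinct values where real spectra show one degenerate peak; peak counts
are therefore somewhat inflated relative to real spectra of the same size.

## Numerical choices and degenerate inputs

* Widths are validated > 0; `max(floor, w)` keeps them bounded away from
  zero even for zero-sigma transfers.
* `round(p N)` uses round-half-up so perturbation counts are unambiguous.
* Empty peak lists yield an all-unmatched state; an empty transfer list
  yields an all-statistics search-space set; an empty aligned list makes
  the fraction-correct undefined and is signalled as an error.
* Decay normalization divides by the maximum count; if no residue is
  within the cutoff of any center (possible only when centers lack
  coordinates) all decays are zero.
* Measured peaks are canonically sorted before the engine runs, so results
  are invariant to input file order.
* The local-alignment score is floored at zero (the empty local alignment),
  matching the normalized-score clipping to [0, 1].

## Known limitations

The engine's accuracy on statistics-only (de novo) spaces is well below
what mature assignment software achieves on real spectra — it lacks
spin-system typing, triple-resonance connectivities and evolutionary
optimization.  Transfer-vs-de-novo ratios measured here are therefore
larger than those a production pipeline would report; only their direction
and ordering across conditions should be interpreted.  Triple-resonance
experiments (HNCO, HNCA, ...) are out of scope, as are peak picking from
raw spectra and any database crawling for homolog pairs.
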