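---
title: "abcscreen: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{abcscreen: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcscreen)
```

This vignette documents the models implemented in `abcscreen`, the
parameters that matter and why their defaults were chosen, what the
synthetic-data generators do and do not emulate, and the numerical
decisions taken where the design was genuinely open.

## Scientific setting

Type VII ABC transporters couple ATP binding and hydrolysis in cytoplasmic
nucleotide-binding domains to large conformational changes on the
periplasmic side of the bacterial inner membrane ("mechanotransmission").
Partner proteins define each system's biology, so a practical route to
characterizing an orphan transporter is: (i) co-fold it against a library
of candidate periplasmic partners and rank the predicted complexes, (ii)
corroborate the top candidate with inter-protein coevolution, (iii)
quantify the apo versus ATP-bound conformational change, (iv) ask whether
membrane simulations support the proposed substrate pathway, and (v)
characterize the partner enzyme's activity. `abcscreen` implements the
analysis layer of each step; structure prediction, coevolution inference
(CCMPred) and molecular dynamics engines are deliberately upstream and out
of scope — the package consumes their standard output formats.

## Complex scoring

**Interface contacts.** A contact is a cross-chain residue pair whose
representative atoms lie within a cutoff (default 8 Å). The representative
atom is Cβ, falling back to Cα for glycine; residues missing both are
skipped with a warning rather than failing the run, since predicted models
occasionally omit side chains. The cutoff and representative-atom rule
follow the published pDockQ definition.

**pDockQ.** The score is the published sigmoid calibration
(L = 0.724, k = 0.052, x₀ = 152.611, floor b = 0.018) of
x = mean-interface-pLDDT × log10(contact count). Per-residue pLDDT is read
from the B-factor column and averaged over each residue's atoms; the
structure must be explicitly flagged `predicted` — silently treating
crystallographic B-factors as confidences would be a category error, so
the function refuses instead. With zero contacts the score is the floor
0.018 and x is reported as 0.

**Clashscore.** A clash is a non-bonded heavy-atom pair with van der Waals
overlap ≥ 0.4 Å (radii: C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å; unknown
elements get 1.70 Å with a warning). The implementation is hydrogen-free:
predicted models carry no hydrogens, and adding them would import a
placement model the screen does not need — the screen consumes *relative*
plausibility. Consequently absolute values differ from hydrogen-aware
MolProbity clashscores; only the ranking is contractual. Bonded and
near-bonded pairs are excluded by a deterministic, connectivity-free rule:
same residue; backbone pairs C(i)–N(i+1), C(i)–CA(i+1), O(i)–N(i+1),
CA(i)–N(i+1) of sequence-adjacent residues; and any pair closer than
1.2 Å, which is treated as an unrecorded covalent bond. Neighbor search
uses a uniform cell grid (cell edge = the largest possible clash distance,
3.2 Å); the test suite and acceptance script verify the cell path against
an O(n²) brute force on random 500-atom structures.

**Ranking.** Candidates are ranked into Pareto fronts on (maximize pDockQ,
minimize clashscore); within a front, by pDockQ descending with ties
broken by candidate id, making output order deterministic. A "hit" flag
(front 1 and pDockQ > 0.5) is report-only: in practice the outlier is
picked by eye on the 2-D plane, and the flag merely reproduces that
reading.

## Coevolution Z-analysis

Coupling matrices are read in the CCMPred plain-matrix dialect (L rows of
L whitespace-separated floats), symmetrized as (M + Mᵀ)/2 (warning if
asymmetry exceeds 1e-6) with the diagonal forced to zero. For a
concatenated two-protein alignment partitioned at `len_a`, the inter-chain
block (len_a × len_b cells) is both the signal and the default background:
z = (raw − μ)/σ with μ, σ the mean and *population* standard deviation of
that block. Population rather than sample SD because the block is the
entire population of inter-chain cells, not a sample from it. Two open
choices are exposed behind flags rather than defaults: a whole-matrix
background (`background =` argument) and the average-product correction
(`apc_correct()`), since the standard workflow Z-scores the raw
inter-protein block directly. The annotation threshold default (z > 10)
matches the convention of reporting only far-outlier pairs; the
half-normal noise floor on realistic block sizes (~10³–10⁵ cells) reaches
z ≈ 5, so thresholds below ~6 admit background extremes.

## Conformational metrics

Reporter distances are named atom pairs (Cα default) evaluated per
structure; unresolvable addresses flag the row and the run continues, so a
batch over many deposited models cannot be derailed by one renumbered
chain. The package ships reporter tables for the transporter state
comparison (`nbd_gap_reporters()`, and TSV copies under `inst/extdata/`):
the Ser50–Ser148 gap between the two ATP-binding-cassette monomers and the
Leu403–Leu754 transmembrane pair. Because the deposited models do not
state which monomer contributes which serine at each site, both
cross-chain pairings are listed and reported.

State comparisons pair residues across structures by (chain, residue
number, insertion code) — no sequence alignment — then superpose the
mobile structure onto the reference over the Cα atoms of a selection and
report per-residue Cα displacements. The default superposition frame is
the chain with the most residues (the large transmembrane subunit), which
is the natural static core when the moving parts are the cassette dimers
and periplasmic domains; any explicit selection overrides it.
Superposition is a Kabsch fit (SVD with determinant correction, so the
rotation is always proper); sets with fewer than three pairs or collinear
geometry are rejected. The test suite checks the fit against an
independent quaternion-method oracle to 1e-6.

## Membrane-trajectory analytics

Trajectories are a GRO or PDB topology plus multi-model-PDB or DCD frames;
GRO coordinates (nm) are converted so everything downstream is Å and ns.
Atom roles (protein / lipid / solvent) are inferred from residue names and
are configuration, not heuristics: coarse-grained beads and atomistic
atoms are handled identically by naming the headgroup reference atom
(default `P`/`PO4`, the phosphate).

*Leaflets*: per frame, the bilayer midplane is the mean z of all lipid
headgroup reference atoms; a lipid is "upper" iff its headgroup is
strictly above the midplane (ties go lower, with a warning — a degenerate
flat system should be visible, not silently split).

*Residency*: a 30 × 30 grid of 2.5 Å bins (75 Å window) centered on the
time-averaged protein xy centroid, accumulated over every 10th frame by
default, matching the standard residency-plot construction. The grid
origin is not part of the convention, so centering on the protein centroid
makes grids comparable across runs; observations outside the window are
dropped *and counted*, and the conservation identity
`sum(counts) + dropped = observations` is asserted in tests. Density is
normalized to the per-grid maximum; when several grids must share a scale,
normalize to the global maximum externally — both conventions are used in
practice.

*Vertical traces* report a chosen lipid atom's z relative to the per-frame
midplane (default) or to the upper-leaflet headgroup plane (flag), since
either reference is defensible for an extraction event; positive z is the
periplasmic side.

*Contact propensity* is exact integer arithmetic: frames-in-contact /
frames-analyzed, with contact = any heavy-atom pair under 4 Å.

*RMSF/RMSD*: every frame is superposed onto the first frame over the
selection before measurement; RMSF is about the mean fitted position. For
isotropic Gaussian jitter of σ per coordinate the expected RMSF is σ√3;
the superposition absorbs six rigid degrees of freedom, which biases the
estimate down by ~3 % at the default selection size — within the 5 %
verification band used in the tests.

No periodic-boundary reconstruction is attempted beyond keeping lipids in
the primary box: the package is an analysis layer, and imaging policy
belongs to the simulation toolchain.

## Kinetics

Initial rates are ordinary least-squares slopes over an early window of
the progress curve. The window default — the first 20 % of points, minimum
5 — is a pragmatic compromise between staying in the linear regime and
retaining enough points for a stable slope; assays with a known linear
range should pass an explicit window. A paired blank on the identical time
grid is subtracted before fitting; mismatched grids are an error, not an
interpolation, because silent resampling hides pipetting/timing problems.

Michaelis–Menten fits use Levenberg–Marquardt nonlinear least squares with
Vmax₀ = max(v) and Km₀ = the concentration at the first rate ≥ Vmax₀/2 —
an initialization that is within a factor of ~2 of the optimum whenever
the grid brackets Km. Standard errors come from the Jacobian at the
optimum (asymptotic); no bootstrap by default. When the fitted Km falls
below the smallest tested concentration the fit is flagged
`upper_bound_regime` and `km_upper_bound = min(S)` is the only
interpretable number: a nanomolar-Km enzyme probed at micromolar substrate
is saturated everywhere, and reporting a point estimate would overstate
what the data contain. Wavelengths are metadata; conversion to molar units
is the caller's extinction-coefficient business.

Relative activities are group means as a percentage of a reference group's
mean, with standard deviations scaled by the same factor and replicate
counts reported — the layout of a wild-type-normalized mutational panel
(typically n = 6: two biological × three technical repeats).

## Synthetic data: what it does and does not show

Each generator is bit-deterministic under (parameters, seed), uses its own
seeded stream without touching the caller's RNG state, and emits a
manifest of planted truths that the analysis modules are tested against.

* `gen_complex` builds poly-alanine chains with exact planted contact
  counts (Cβ–Cβ at 6 Å, spacing chosen so no accidental pair enters the
  8 Å cutoff), exact clash counts (isolated Cβ–Cβ overlaps of ~0.9 Å), and
  stated pLDDT values; a ≤0.05 Å uniform jitter decorrelates seeds without
  crossing any threshold. Glycine substitution exercises the Cα fallback.
* `gen_coupling` fills the matrix with half-normal noise and sets planted
  inter-chain cells to μ + z·σ of the realized background. Because the
  planted cells subsequently join the background, realized z sits slightly
  below target (≈11 for a target of 12 on a 60 × 40 block) — recovery
  thresholds account for this.
* `gen_membrane_trajectory` plants a two-leaflet bead slab, a static
  protein cylinder, pocket-lining residues, an occupancy schedule for one
  tagged LysoPG, an optional linear extraction, and optional isotropic
  protein jitter. Default conditions mirror the simulation-analysis
  regime: 2.5 Å bins on a 30 × 30 grid, every-10th-frame striding, 4 Å
  contact cutoff, a 40 % pocket occupancy for recovery tests and a 15 Å
  extraction rise.
* `gen_progress_curves` draws rates from the Michaelis–Menten curve with
  Gaussian noise (truncated at zero). The recovery study uses 8
  log-spaced concentrations spanning 0.1–10×Km with noise σ = 5 % of Vmax
  over 100 seeds — a design any enzymology lab would recognize.

These generators plant *statistics, not physics*: no force fields, no
diffusion, no excluded volume, no MSA phylogeny. Passing tests therefore
demonstrate that the analysis code measures what it claims to measure on
data with known answers — they do not demonstrate that real membranes,
alignments or predicted models satisfy the generators' assumptions. In
particular, real coupling matrices carry entropic and phylogenetic biases
the half-normal background lacks (which is why the APC flag exists), and
real trajectories have correlated frames where the generator's are
independent.

## Problem sizes and runtime

The shipped test suite and acceptance script run on one CPU in well under
a minute each at the default sizes: 500-atom clash clouds (20 seeds),
60 × 40 coupling blocks (20 + 20 seeds), 100-frame membrane trajectories
(1000 frames for the RMSF calibration), and 100-seed kinetics recovery.
These sizes were chosen as the smallest at which each statistical check is
comfortably stable; every size is a parameter, and all analyses scale to
production inputs (thousands of atoms, 10³–10⁴ frames) without code
changes.

## Known limitations

* The clashscore is heavy-atom only and will not match hydrogen-aware
  MolProbity numbers; use it to rank, not to report absolute model
  quality.
* mmCIF support rides on `bio3d::read.cif` (beta upstream); exotic mmCIF
  dialects may need conversion to PDB first.
* No PAE-based interface scores (ipTM, pDockQ2): the inputs carry pLDDT
  only.
* Pocket geometry is treated qualitatively (reporter distances and
  residency), not volumetrically — no cavity detection.
* Progress-curve analysis is initial-rate only; integrated rate-equation
  (global) fitting is out of scope.
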