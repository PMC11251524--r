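---
title: "Methods: fluctuation metrics, landscapes, ion atmosphere and SHAPE processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluctuation metrics, landscapes, ion atmosphere and SHAPE processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboscape)
```

`riboscape` implements the analysis layer of a combined MD/SHAPE study of
a riboswitch aptamer: structural fluctuation metrics, principal-component
free-energy landscapes, ion-atmosphere statistics, and the processing of
capillary-electrophoresis SHAPE traces.  This vignette records the models
behind each stage, the tunable parameters with their defaults and
rationale, the numerical conventions, and what the synthetic generators
do and do not emulate.  Units throughout: coordinates in Å, times in ps,
diffusion coefficients in μm²/s (1 Å²/ns = 10 μm²/s), free energies in
kT.

## Structures, trajectories and regions

Structures use 1-based sequential residue indexing in the
crystal-structure numbering convention; the region map carries an
`offset` field for the alternative experimental numbering (the shipped
default uses −4, mapping C80 to C76).  The exact residue ranges of the
P1A/P1B/P2/P3/L2/L3/J12/J23/J31 partition are not fully determined by the
available anchors, so the default map interpolates between them — G34/G35
on P2, A42/G45/G46 on L2, C68/C69/A71 on L3, U74 on P3, C80 on J31, with
J31 two and J12 three residues wide (P1 is separated from P3 by two
residues and from P2 by three).  Any analysis accepts a user map loaded
from YAML, which is the supported way to impose an exact partition.

Trajectories are stored as F × A × 3 arrays with a constant frame
spacing `dt`; the plain-text frame format (`frame <i> time_ps <t>`
headers) requires uniform spacing within 1e-6 relative and a constant
atom count.  Periodic boxes are stored but frames are assumed pre-imaged
(molecule whole); no unwrapping is performed, because all metrics here
operate on whole-molecule coordinates.

## Superposition and fluctuation metrics

`kabsch_superpose()` computes the least-squares optimal proper rotation
via the SVD of the weighted cross-covariance, with the determinant
correction that excludes reflections.  Fewer than three atoms or a
collinear point set (second singular value below 1e-8 of the first)
is an error, since the rotation is then underdetermined.

RMSD follows the study protocol of *global fit, regional measurement*:
`rmsd_series()` takes separate `fit_selection` and `measure_selection`
arguments, superposes each frame on the fit selection (default: all
heavy atoms) and measures over the measurement selection without
re-fitting.  Both conventions found in the literature (regional fit or
global fit) are therefore reproducible by choosing the selections.
`rmsf_per_residue()` superposes onto the reference, then refines once
against the resulting mean structure before computing
RMSF = √⟨|r − ⟨r⟩|²⟩ per atom, averaged over each residue's heavy atoms;
for isotropic per-axis noise of standard deviation σ this converges to
σ√3, which is how the generator recovery tests are calibrated (within 5%
at 2000 frames).

Radius of gyration and stack centroids are **unweighted** (not
mass-weighted): element masses are not needed, the choice is stated, and
it is reproducible from coordinates alone.

Contacts: base pairs and hydrogen bonds are atom–atom distances (pair
convention: purine N1 against pyrimidine N3), stacks are distances
between base-atom-set centroids.  Default formed thresholds — 4.0 Å for
base pairs, 5.0 Å for stacks — are package conventions chosen at the
visible formed/broken separation of such distance traces, and are fields
of every `contact_spec()`, hence configurable per contact.  Hydrogen
bonds use the common geometric criterion: donor–acceptor heavy-atom
distance ≤ 3.5 Å, plus D–H…A angle ≥ 150° whenever hydrogens exist in
the structure; without hydrogens the criterion is distance-only.  The
shipped donor/acceptor table covers the four ribonucleotides plus
backbone and 2′-OH oxygens.  Regional counts are assigned by the donor
residue and scaled by the region's native-bond count; a region with no
native bonds gets flagged `NA` scales rather than an invented value.
Non-native bonds may replace native ones, so the scaled total may exceed
1 — by design.

## PCA landscapes and basins

`fit_pca()` uses the Cartesian coordinates of the selected heavy atoms
as the variable set, removes rigid-body motion by superposing all frames
onto an iterative mean (two passes; `superpose = FALSE` gives the raw
variant), then diagonalises the covariance matrix.  Eigenvector signs
follow a deterministic convention (largest-magnitude component
positive).  The covariance trace is reported in Å² and nm² as a scalar
disorder metric; `replica_trace()` provides both the per-replica and the
pooled-frame aggregation since either may be wanted for multi-replica
studies.

`free_energy_surface()` histograms the PC1–PC2 scores (default 50×50
bins spanning the data range ±5%; fixed for reproducibility,
configurable) and applies Boltzmann inversion F = −ln(n/n_max), so the
global minimum is 0 and empty bins are `NA`, never numeric infinity.
Temperature only labels the kT scale.

`count_basins()` is deliberately deterministic.  The raw counts are
mean-filtered over a `smoothing`-bin radius (default 1) *before*
re-inversion: in log space a 2-count bin beside 1-count bins reads as a
~0.7 kT feature, so unsmoothed Boltzmann inversion turns Poisson noise
into spurious kT-deep minima, while count-space smoothing suppresses
exactly that.  Minima are then found by a persistence sweep (occupied
bins added in increasing F; when catchments meet, the shallower
minimum's persistence is the merge level minus its depth) with
lexicographic tie-breaks.  Two filters define what counts as a basin:
persistence ≥ `depth_cutoff` (kT), and catchment population ≥
`min_mass` (default 1% of frames) — a "state" visited by less than 1%
of the sampling is read as noise, not metastability.  Disconnected
occupied components never merge; the barrier between the two deepest
basins is then reported as `Inf`, which is the honest statement that the
sampling never crossed.

## Ion atmosphere

For a window of length 1 ns starting at t₀, `windowed_msd()` averages
|r(t+τ) − r(t)|² over **all** ordered in-window pairs at lags τ of 1, 2
and 3 frame spacings (125 ps), and `fit_diffusion()` fits a line through
the origin following ⟨x²⟩ = 6Dt: D = Σ(τ·MSD)/(6Στ²).  Negative fitted
D (a finite-sample artifact) is clipped to zero and flagged so it cannot
silently pass a threshold test.  Window stride defaults to one window
(non-overlapping); an overlapping stride is available.

`detect_association_events()` runs a hysteresis state machine over the
D(t₀) series: an event opens at the first window with D below `d_on`
(default 10 μm²/s) and closes at the first later window with D above
`d_off` (default 100 μm²/s).  Residence time is measured between the
two window start times — the threshold definition fixes the crossings
but not the timestamp convention, so the package picks the window-start
convention and applies it consistently; events still open at the end of
a track are flagged censored.  The association site is the mean ion
coordinate over the event's frames; `cluster_sites()` merges event
sites by single linkage at 3 Å (order-independent by construction).

Bulk statistics: the bulk region is everything at least 15 Å from any
RNA atom; its volume comes from Monte-Carlo integration with a binomial
standard error (exact when there is no RNA).  Bulk concentration is the
per-frame bulk count over that volume, mean ± sd over frames (the
over-replica aggregation is a trivial outer loop).  A correction for
ion–ion interaction effects on the raw concentration is exposed as a
pluggable hook (`correction` argument) defaulting to the identity with
`correction_applied = FALSE`: the specific correction used in the
original analysis is not reproducible from the available description,
and the package does not guess silently.  The preferential interaction
coefficient is Γ = N_tot − c_bulk·V_ref per frame, averaged; `V_ref`
defaults to the full box volume, with a box-minus-excluded-volume mode
(Monte-Carlo volume within a configurable 3.5 Å of the RNA) available
because published Γ tables do not always state the convention.

## SHAPE trace processing

The pipeline is align → fit → integrate → assign → subtract → normalize
→ classify, with full provenance (shifts, factor, outlier set, negative
flags, convergence) kept in the result's metadata.

Alignment maximises integer-shift cross-correlation of mean-centred
channels (ties to the smaller magnitude; flat traces are an error).
Peak fitting is simultaneous nonlinear least squares
(Levenberg–Marquardt via `minpack.lm`, analytic Jacobian) of a constant
baseline plus one Gaussian per initial centre; a linear-drift baseline
is optional, constant is the default model.  Bounds: centres within two
ladder spacings of their initialisation, σ within [0.05, 2] × the median
spacing — at the well-resolved spacing of six peak widths the true σ is
spacing/6 ≈ 0.17 × spacing, so the lower bound must sit well below
that; a width beyond two spacings is indistinguishable from baseline.
Non-convergence keeps the current parameters and flags them rather than
failing the run.  Each fitted peak takes the nucleotide of the nearest
ladder peak (ties to the lower index; beyond two median spacings:
unassigned).

Blank subtraction is elementwise and **retains** negative results,
flagged as unanalyzable: flooring them would bias the normalization
factor.  Normalization implements the outlier-excluding 10% rule with
ceiling counts (n_out = ⌈0.1 n⌉ outliers excluded, factor = mean of the
top n_avg = ⌈0.1 (n − n_out)⌉ of the rest, everything including the
outliers divided by the factor); profiles with fewer than 10 analyzable
values are refused, since the rule's counts degenerate below that.
Classification thresholds default to the common 0.4 / 0.85 convention
(value < 0.4 low, ≤ 0.85 moderate, above high), configurable; reported
grayscale reactivity bins do not fix numeric boundaries, so a stated
convention is the reproducible choice.  Output is unsmoothed; a
moving-average utility is provided separately.

## Synthetic generators: what they emulate, and what not

All generators are deterministic under a fixed seed and return the
ground truth needed to score the estimators.

* `gen_fluctuation_trajectory()` — reference + per-region state offset +
  isotropic Gaussian noise, with a Markov switching process.  This
  emulates only the *statistical* structure of metastable conformational
  states (the two-state RMSD/landscape signature); it has no bonded
  geometry, no solvent, no correlated motion.  Landscape tests passing
  on it show the estimator chain is correct, not that real trajectories
  are two-state.
* `gen_ion_tracks()` — overdamped Brownian steps (per-axis sd √(2 D dt))
  with `d_free` outside and `d_trapped` inside trap spheres, reflecting
  box walls, exclusive trap occupancy (one ion per trap keeps the true
  residence intervals unambiguous), Poisson escape with mean dwell
  1/escape_rate, and a short detachment jump to 1.5 trap radii on
  escape so an escaped ion is not recaptured in the same frame.  Default
  study conditions for recovery runs: dt = 125 ps, 1-ns windows, mean
  dwell 10 ns, d_trapped = 5 μm²/s, and d_free = 400 μm²/s — a free
  hydrated cation diffuses at several hundred μm²/s, safely above the
  100 μm²/s dissociation threshold; a free diffusion at the threshold
  itself would make event closure ill-defined by construction.  No
  electrostatics, hydration shells or force-field physics.
* `gen_electropherogram()` — baseline + Σ Gaussians + white noise per
  channel, ladder peaks at every nucleotide.  Real traces add drift,
  peak tailing and mobility nonlinearity; the optional linear-drift
  baseline covers the first of these only.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use sizes chosen to give
stable statistics on a single CPU in minutes: 2000-frame trajectories on
a 24-residue scaffold for RMSF/landscape recoveries, ~1000 diffusion
windows and ~400 completed binding events for the ion recoveries, and
100-seed ensembles of six-peak traces for area recovery.  Tolerances
follow the estimator statistics: 5% for RMSF recovery, 30% for the
median windowed D (a three-lag fit in a 1-ns window is a noisy
estimator by design), 25% for mean residence time, 2% for the mean
relative peak-area error at amplitude-SNR 50 (the per-peak statistical
floor of the Gaussian fit at that SNR is ≈1.4%, so a worst-case bound
at 2% would be unattainable, while the mean sits near 1.2%).  Exact
identities (trace conservation, Γ = N in the all-shell construction,
the oscillating-track closed form D = a²/(21 dt), the 10-value
normalization enumeration) are asserted at machine precision or the
stated analytic tolerance.
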