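---
title: "Staggered-window DIA: design, demultiplexing and library evaluation with stagdia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staggered-window DIA: design, demultiplexing and library evaluation with stagdia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagdia)
```

## The problem

In data-independent acquisition (DIA) proteomics the instrument co-fragments
all precursors inside a wide isolation window, trading precursor selectivity
for complete, reproducible sampling. Two design ideas recover much of the
lost selectivity:

* **Staggered windows.** Two interleaved banks of isolation windows, offset
  by half a window width, are acquired in one ascending sweep. Because every
  half-width *bin* of precursor space is covered by two different windows,
  the overlapped signal can be demultiplexed onto bins of half the nominal
  window width.
* **Gas-phase fractionation (GPF).** Repeated injections each restrict the
  precursor range to a narrow segment, so the same cycle time buys much
  narrower windows (4 m/z instead of 24 m/z) within each segment. The
  segment runs are used to build a deep ion-chromatogram library which is
  then queried in single-shot wide-window runs.

`stagdia` implements this workflow end to end — scheme design, overlap
demultiplexing, library assembly with retention-time (iRT) calibration,
target–decoy scoring, top-3 label-free quantification, the
differential-expression filter cascade, and the library comparison metrics —
together with a ground-truthed synthetic data generator so that every stage
is testable without instrument data.

## Window geometry

`build_staggered_scheme(mz_min, mz_max, width)` places window lower edges
from `mz_min - width/2` to `mz_max` in steps of half a width, giving

\[ n = \frac{m/z_\max - m/z_\min}{\text{width}/2} + 2 \]

windows per cycle in two equal banks that alternate scan by scan. For the
canonical 400–1000 m/z range with 24 m/z windows this yields 52 windows
(26 per bank), and an MS1 survey scan is inserted after every 26 MS2 scans,
i.e. once per bank pass. The same rule gives 52 staggered 4 m/z windows on a
GPF segment with a 100 m/z unique span.

Demultiplexing bins are the half-width intervals tiling
`[mz_min, mz_max)`, plus one edge bin of half a width on each side. In this
geometry every in-range bin is covered by exactly two windows and exactly
two windows cover a single in-range bin each. The geometry is slightly
asymmetric at the extremes — the low edge bin is covered once (and is
directly solvable), the high edge bin twice, and the topmost window covers
only out-of-range bins — an unavoidable consequence of equal bank sizes;
`scheme_coverage()` therefore reports the demux-bin union
`[mz_min - w/2, mz_max + w/2)` as the analyzable range, and the simulator
and library assembly exclude precursors outside it.

Window edges can be snapped into peptide *forbidden zones*: tryptic
precursor m/z values cluster on the averagine grid with spacing
Δ = 1.00045475 per nominal mass, so edges are moved to the nearest
`(k + 0.25)·Δ/z` (default z = 2), shifting an edge by at most `Δ/(2z)` ≈
0.25 Th. Snapping perturbs only the physical edges; demultiplexing always
uses the nominal geometry.

```{r}
sch <- build_staggered_scheme(400, 1000, 24)
sch
build_gpf_plan(400, 1000, 6, 2, 4)
```

Offline high-pH fractions are pooled round-robin
(`plan_concatenation(18, 6)`: pool 1 receives fractions 1, 7, 13), which
concatenates early, middle and late eluters and keeps the high-pH and low-pH
separations orthogonal.

## Demultiplexing model

For each acquisition cycle, each window's fragment channels are brought to
the cycle's reference time by linear interpolation between that window's
bracketing measurements; channels are then grouped across windows by a
greedy m/z clustering at `tol_ppm` (default 10 ppm, centroids
intensity-weighted), and for each channel the per-bin intensities solve

\[ \min_{x \ge 0} \lVert A x - y \rVert^2 \]

where `A` is the window-to-bin incidence restricted to the bins of the
windows that observed the channel, and `y` holds the (interpolated) window
intensities — including informative zeros from covering windows that did not
observe the channel. Bins covered by a single window are solved directly.
The NNLS is a Lawson–Hanson active-set implementation with problem-scaled
tolerances; exactly tied measurements (both covering windows reading the
same value, the generic case in noiseless staggered data) are handled
without iteration-limit failures. If the active-set solve fails on a
degenerate system the solver falls back to a ridge-regularized solution
(`ridge`, default 1e-6 of the dominant measurement) and clips negatives.

## The synthetic data generator

`generate_peptides()` digests random (or FASTA) proteins with tryptic
specificity (K/R, "/P" rule configurable, ≤ 2 missed cleavages), keeps
peptides of 7–35 residues, assigns charges 2–4, uniform iRT on [0, 100] and
log-normal protein/peptide abundances, and draws each precursor's fragment
relative intensities once from a symmetric Dirichlet(1) over all singly
charged b/y ions, keeping the 3–6 most intense fragments inside 300–1800
m/z. Cysteines carry the fixed carbamidomethyl modification.

`simulate_run()` plays a scheme over a gradient with Gaussian elution peaks
(defaults: cycle time 3180 ms, peak FWHM 17 s), an affine iRT→RT map
covering the central 80% of the gradient, optional per-run retention jitter,
Poisson-like shot noise (variance ∝ mean) and uniform chemical-noise peaks.
Two retention-time stamping modes exist: the default `rt_mode = "cycle"`
stamps all scans of a cycle with the cycle start time (an
instantaneous-cycle simplification under which demultiplexing is exact to
numerical precision), while `rt_mode = "spread"` spaces scans across the
cycle and exercises the cross-cycle interpolation (median relative demux
error of a few percent against a 17 s peak, as expected from linearizing a
Gaussian over ~3 s).

`simulate_two_group_study()` emulates a two-group clinical design (defaults
26 vs 22 samples, mirroring a normal vs impaired glucose tolerance cohort):
protein-level log-normal biological variation with CV `cv_within` shared by
all peptides of a protein, a planted log2 fold change (default 0.585, i.e. a
50% difference; random sign) in a fraction `frac_de` of proteins, a small
fragment-level measurement CV, and a detection floor that creates
missingness for the presence filter. The study is generated at the
quantification level (a long fragment-area table plus ground-truth
matrices); `materialize_runs = TRUE` additionally simulates full raw runs
per sample for small designs. The within-group CV is a free parameter, not
an estimate of any real cohort.

What the generator does **not** emulate: isotope envelopes, charge-state
interference between co-isolated precursors beyond shared fragment m/z,
peak-shape tailing, dynamic exclusion, and instrument duty-cycle effects.
Passing tests therefore demonstrate the correctness of the algorithms under
the stated model, not performance on real instrument data.

## Libraries, calibration and scoring

`assemble_library()` pools entries across fraction runs on the
(sequence, charge) key with per-entry provenance. Retention calibration fits
`rt = intercept + slope·irt` by least absolute deviations (IRLS; OLS below
5 anchors) on the most abundant detectable peptides. In *hybrid* mode the
calibration is refit on the unfractionated whole-sample runs, which removes
between-fraction retention drift from the residuals; the XIC extraction
window is `2·k·(residual SD)` (k = 3), floored at 0.5 min so a noiseless
calibration still yields a usable window. On synthetic data with
inter-fraction jitter the hybrid window is strictly narrower, and it is
never wider — the package's analogue of the observation that adding mixed
runs tightens retention alignment.

`score_and_fdr()` scores each entry as (cosine similarity between the
library fragment pattern and the observed fragment areas) × (mean pairwise
Pearson correlation of the fragment traces, clamped to [0, 1]). Decoys keep
the target's precursor coordinates but shift fragments by +10 Th per copy
and shuffle intensities; q-values come from target–decoy competition,
monotonized along the score ranking, with the universal 1% cutoff as
default. Ties break deterministically by entry key.

## Quantification and the filter cascade

`normalize_ms2()` equalizes per-sample median log2 fragment intensity to the
grand median (missing values untouched; all-missing samples flagged and left
unscaled). `rollup_top3()` takes the mean of the 3 most intense fragments
per peptide and the mean of the 3 most abundant peptides per protein — so
the roll-up is scale-equivariant by construction. The differential cascade
applies, in order: presence (≥ 50% of the samples of *each* group; the
per-group reading makes the subsequent fold change well defined), ≥ 2
distinct peptides, Benjamini–Hochberg q < 0.05 from Welch t-tests on log2
intensities (robust to the unequal group sizes/variances of a 26/22 design;
no imputation), and |log2 fold change| ≥ 0.585 = log2(1.5). A protein is
significant only if all four pass; proteins absent from an entire group are
excluded with a flag.

## Evaluation metrics

Per-run **completeness** (share of the replicate-union proteome seen in each
run), **library recovery** (share of library proteins identified),
**explained TIC** (share of MS2 ion current matched to accepted
identifications' fragments, counted only in windows covering the
precursor), CV distributions, Venn-style overlap regions at precursor /
peptide / protein level, protein rank curves on mean log10 intensity, and
cross-method Pearson correlation of log10 quantities on shared identifiers.
Peptide physicochemical properties use Kyte–Doolittle GRAVY and, for the
hydrophobicity index, the Eisenberg consensus scale by default (the scale is
an argument; radar values in `comparison_report()` are z-scored across
methods before export). Median XIC window width is reported per library
(one calibration per library, hence per precursor and per run coincide).

## Numerical choices and problem sizes

* Half-open m/z intervals everywhere, so bin tilings are unambiguous.
* Channel grouping is deterministic (sorted gap-splitting), hence
  idempotent at a fixed tolerance.
* NNLS tolerances scale with `max |A'y|`; the grid oracle in the test suite
  uses a fine grid for ≤ 3 bins and coarse-to-fine refinement for 4–6 bins.
* Test and acceptance simulations use reduced ranges and gradients (e.g.
  400–640 m/z, 4 min gradients, 8–20 synthetic proteins; 60 proteins and
  26/22 samples for the differential-expression checks over 20 seeds) —
  sizes chosen so the full suite exercises every stage in a few minutes
  while leaving Monte-Carlo margins far from the asserted bounds.
* The cycle time (3180 ms) and FWHM (17 s) defaults give ~5.3 points per
  FWHM; no points-per-peak target is asserted.

## Known limitations

* No mzML I/O: runs serialize to a lossless internal JSON; libraries to a
  transition-list TSV; schemes to CSV/JSON.
* Identification is library-driven only — there is no database search from
  spectra, and decoys are fragment-shift/shuffle constructs rather than
  mutated sequences.
* MS1-based quantification and MaxLFQ-style delayed normalization are out of
  scope; quantification is top-3 roll-up at MS2 level.
* The two-group test treats samples as independent; subject-level pairing
  can be emulated by averaging technical replicates upstream.
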