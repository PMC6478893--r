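---
title: "Mapping lipid binding sites on membrane proteins from coarse-grain trajectories"
author: "cglipidsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping lipid binding sites on membrane proteins from coarse-grain trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cglipidsite)
```

## The problem

Coarse-grain molecular dynamics makes millisecond-aggregate sampling of
protein–lipid encounters affordable, which is how sphingolipid binding
sites on β-barrel channels such as the voltage-dependent anion channel
(VDAC) have been located: a ceramide molecule diffusing in the outer
leaflet repeatedly visits a groove on the barrel wall, and the questions
are *where* it binds (which residues), *how long* it stays (residence
times), and *what volume* it prefers around the protein. This package
implements that post-processing pipeline — contact analysis, binding-event
kinetics, space-occupation analysis, and the attendant statistics — for
coarse-grain trajectories with named head-group beads (`AM1`/`AM2` for
ceramide, `ROH` for cholesterol, `PO4`/`NC3` for phosphatidylcholine),
plus a synthetic trajectory generator with exact ground-truth kinetics so
every stage can be validated without access to cluster-scale trajectory
archives.

## Contact analysis

`residue_contact_occupancy()` reports, per protein residue, the fraction
of frames with *any* head bead of the species within the contact cutoff
(default 7 Å, minimum image under orthorhombic periodic boundaries) of
*any* particle of that residue. Counting is any-molecule: simultaneous
contacts by two ligand copies count once, so occupancy is capped at 1
(1.0 = in contact for the entire analyzed time). `call_binding_site()`
applies a strict `>` threshold (default 15%, the background level of
non-site residues); ties at background are deliberately not called.
Occupancy is computed on the raw series — the majority filter described
below belongs to binding-duration analysis only.

## Binding events and residence times

A sharp single cutoff makes continuous residence times fragile: a ligand
drifting briefly past the threshold without leaving the site would split
one long event into several short ones. Event detection therefore uses a
deliberately redundant criterion (`raw_contact_series()`): a frame is
bound when head beads are within 8 Å of at least two of three residue
groups defined on the β-strands that form the site (defaults 58–60,
73–75, 81–83). Remaining one-or-two-frame flickers are removed by
`majority_smooth()`: a five-frame window voting with a three-frame
threshold, with edge-replication padding so constant series pass
unchanged and both ends are treated symmetrically (the edge rule is a
design choice; replication is the variant that cannot manufacture events
at the boundaries).

`extract_events()` turns maximal bound runs into events (duration = run
length × frame interval; one frame = one interval, 600 ps by default). A
run still bound at the final frame has an unknown duration and is
discarded (counted separately). Events already in contact at frame 0 are
*kept* by default — that is the published convention — and a
`drop_start_censored` flag exists to study the bias that choice carries.

`residence_time_distribution()` histograms durations on log-spaced bins
(8 per decade from one frame interval to the total time; the bin density
is a package choice, as no canonical width exists) with each event
contributing its *duration*, normalized by total simulation time: the sum
of all y-values is the fraction of system time spent bound, an identity
the tests enforce to 1e-12. When several runs are pooled,
`pool_residence_histograms()` normalizes each run by its own length
first, then pools with duration weights — the reading of per-run
normalization that keeps the summed-fraction identity for the pooled
ensemble.

Residence times are summarized by the time-weighted mean
$\sum d_i^2 / \sum d_i$ — the expected duration of the event in progress
at a random bound instant; for an exponential law with unbinding rate
$k_\mathrm{off}$ it equals $2/k_\mathrm{off}$.

## Space-occupation analysis

`align_protein_xy()` applies per frame the z-rotation plus xy-translation
(closed-form two-dimensional Kabsch fit on the protein particles) that
matches a reference frame; z is never touched, preserving the membrane
normal — a full 3-D superposition would tilt the bilayer frame and smear
the volume along z. `occupancy_volume()` then grids the box at 5 Å
(half-open cells anchored at the box corner, so a particle belongs to
exactly one cell; several heads in one cell count once, keeping values in
[0, 1]) and records per-cell occupied-frame fractions. The grid total
equals the time-averaged number of distinct occupied cells — the
conservation check used in the tests. `export_grid()` writes standard
OpenDX fields for contouring at the per-species iso levels (10% ceramide,
20% cholesterol). A linear molecule-count compensation of those levels is
available but off by default: the published per-species thresholds are
taken as authoritative, and linear scaling is only one reading of
count compensation.

## Statistics

`bootstrap_time_weighted_mean()` resamples events (the event, not the
frame, is the exchangeable unit) with replacement, 10,000 times by
default, and reports the percentile interval; BCa is available behind a
flag. A single seeded generator drives each invocation and the seed is
recorded, so reports are bit-reproducible. Be aware of a real limitation
the acceptance checks expose rather than hide: for the heavy-tailed ratio
statistic $\sum d^2/\sum d$ at $n = 50$ exponential durations, the 95%
percentile interval covers the true value in only ~80% of replicates
(BCa ~86%) — the statistic is dominated by the sample maximum, a known
hard case for the bootstrap. Intervals should be read as reproducible
summaries of resampling spread, not as exactly calibrated 95% coverage at
small n.

`compare_durations()` is the one-tailed, continuity-corrected
Mann–Whitney–Wilcoxon test (normal approximation with tie correction, as
in `stats::wilcox.test`); the tail is a required argument with no
default. An exact full-enumeration mode exists for
$n_a + n_b \le 12$ and is the oracle the approximation is tested
against: agreement is within 0.01 once both samples have three or more
values, but reaches 0.064 at 1-vs-3 splits — tiny samples should use the
exact mode.

## The synthetic generator: what it emulates and what it does not

`generate_synthetic_trajectory()` builds a static pseudo-barrel (57
single-bead residues in 19 three-residue columns on a 12 Å cylinder, the
three site groups on adjacent columns) in a 100 × 100 × 60 Å box with 16
ceramide-like head particles, frames every 600 ps. Binding is
*scheduled*, not emergent: a telegraph (two-state Markov) chain with
per-frame probabilities $k_\mathrm{on}\Delta t$ and
$k_\mathrm{off}\Delta t$ drives site occupation, bound runs are assigned
to ligands round-robin (one site, at most one ligand bound per frame, so
ground truth is unambiguous), the bound ligand sits at the site face with
sub-Å jitter, and free ligands random-walk in the membrane plane outside
an exclusion radius that keeps them > 12 Å from every site group.
Scheduling is the point: it yields exact ground truth for oracle tests,
which emergent dynamics cannot.

Three generator choices matter for interpreting test results:

* **Run lengths ≥ 3 frames.** Both bound and unbound runs are drawn from
  a shifted geometric law with minimum 3 frames, which makes the
  5-frame/3-vote filter provably the identity on the emitted series —
  the pipeline must then recover the schedule *exactly*, a much sharper
  test than approximate recovery. With symmetric rates the stationary
  bound fraction remains exactly $k_\mathrm{on}/(k_\mathrm{on}+k_\mathrm{off})$;
  with asymmetric rates the 2-frame shift introduces a small bias at fast
  switching (negligible when mean runs span thousands of frames).
  `generate_telegraph_series()` exposes `min_run = 1` for a plain chain,
  used when checking raw transition frequencies.
* **Rate regimes.** The default `kinetics_spec()` uses
  $k_\mathrm{on} = k_\mathrm{off} = 1\,\mu s^{-1}$ — microsecond
  residence at 600 ps frames, the regime the real system occupies.
  Geometric convergence tests (site occupancy within ±0.02–0.03 of the
  stationary fraction at $10^4$ frames) instead use fast symmetric
  switching ($400\,\mu s^{-1}$): the time-average of a two-state chain has
  variance $\approx 2 f(1-f)\tau_c/T$ with $\tau_c = 1/(k_\mathrm{on}+k_\mathrm{off})$,
  so at slow rates a 6 µs run simply cannot decorrelate enough to pin the
  fraction to ±0.02, whatever the implementation does. The fast-rate
  choice follows from that variance formula, not from tuning.
* **End-censoring bias is real and visible.** At
  $k_\mathrm{off} = 1\,\mu s^{-1}$ and $10^4$ frames (6 µs per ligand),
  discarding end-censored events length-biases the retained sample: for
  exponential durations observed in a window of length $T$ the retained
  time-weighted mean is $\mathbb{E}[d^2(T-d)]/\mathbb{E}[d(T-d)]$, about
  1.5 µs rather than $2/k_\mathrm{off} = 2$ µs at $T = 6$ µs. The
  kinetic-recovery checks at that window length measure exactly this
  bias (the recovered value sits near 1.5–1.6 µs); recovery of the
  analytic value to within the bootstrap CI requires
  $T \gg 1/k_\mathrm{off}$, which the long-run test (120 µs per ligand)
  demonstrates. Survival-analysis corrections for censoring are out of
  scope by design — the published convention is to discard.

What the generator does *not* emulate: lipid–lipid interactions, membrane
elasticity or curvature, competing ligands at one site, emergent binding
free energies, or protein flexibility (the barrel is rigid and the
"bilayer" is a geometric plane). Passing tests therefore certify the
*analysis machinery* — distances, smoothing, censoring, normalization,
gridding, statistics — not the realism of any force field.

## Numerical and interface choices

* Coordinates are stored in Å (cutoffs are quoted in Å); GRO input (nm)
  is converted on read. Boxes are restricted to orthorhombic — the
  bilayer systems of interest are rectangular, and this keeps the
  minimum image exact; triclinic input is rejected explicitly.
* Trajectory formats are multi-frame GRO (text) and DCD (read via bio3d;
  a minimal DCD writer is included so round-trips can be tested). Frame
  indexing is 0-based; the time of frame *i* is *i* × frame interval.
* Structure comparison (`barrel_rmsd()`) performs Kabsch superposition
  over an explicit index pairing supplied by the caller — typically from
  `pairing_from_alignment()` (global Needleman–Wunsch) — and never
  guesses correspondences; fewer than three pairs is a degeneracy error.
* Analysis problem sizes in the shipped tests and scripts (e.g. 2,000
  frames for the worked system, $10^4$-frame convergence checks, 500
  bootstrap-coverage replicates) were chosen so the whole suite runs on a
  laptop-scale core in a few minutes while keeping Monte-Carlo margins at
  3σ or better.

## Known limitations

* No survival-analysis treatment of censored events (see above); the
  censoring counts are reported so the bias is at least visible.
* The bootstrap intervals undercover for small heavy-tailed samples (see
  above).
* The occupancy grid is anchored to the box, not the protein; a site
  that happens to sit near a 5 Å cell boundary spreads its occupancy
  over the adjacent cells, which is why site-level checks sum the cell
  neighbourhood rather than reading a single cell.
* Role inference relies on bead/residue naming; non-Martini naming
  schemes need a custom `default_name_map()` edit.
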