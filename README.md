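# cglipidsite

Post-processing toolkit, in R, for locating and quantifying lipid binding
sites on membrane proteins from coarse-grain molecular dynamics
trajectories — the kind of analysis used to map a ceramide site on the
wall of VDAC β-barrel channels. It is organised as a package (all
computation in `R/`) plus a numbered analysis workflow (`analysis/`)
that exercises it end to end on synthetic trajectories with known
binding kinetics.

## What it computes

Given a trajectory with named head-group beads (`AM1`/`AM2` ceramide,
`ROH` cholesterol, `PO4`/`NC3` phosphocholine) and a protein:

* **Contact occupancy** — per residue, the fraction of frames with any
  head bead within 7 Å (minimum image); residues above the 15%
  background threshold are called as the binding site.
* **Binding events** — per ligand, frames within 8 Å of ≥ 2 of 3 site
  residue groups (defaults 58–60, 73–75, 81–83), majority-smoothed over
  a 5-frame window (3 votes), with events still bound at the last frame
  discarded as end-censored.
* **Residence-time distributions** — log-binned histograms where each
  event contributes its duration, normalized by total time, so
  Σy = fraction of time bound; summarized by the time-weighted mean
  Σd²/Σd (equal to 2/k_off for exponential residence), with 10,000-resample
  percentile bootstrap CIs and one-tailed continuity-corrected
  Mann–Whitney–Wilcoxon comparisons (exact enumeration for n ≤ 12).
* **Occupancy volumes** — after in-plane (z-rotation + xy) alignment of
  the protein, 5 Å occupancy grids exported as OpenDX fields for
  contouring at 10% (ceramide) / 20% (cholesterol) iso levels.
* **Synthetic ground truth** — a telegraph-process trajectory generator
  (static pseudo-barrel, 16 diffusing head particles, 600 ps frames)
  whose scheduled events the pipeline must recover exactly.

## Worked example

Running the workflow in order reproduces the numbers below
(`Rscript analysis/01_simulate.R` … `06_pipeline.R`; tables land in
`results/`, bulky trajectory files in `scratch/`):

```
$ Rscript analysis/01_simulate.R
system: 2000 frames x 73 particles (16 ligands)
scheduled binding events: 68 (0 end-censored)
stationary bound fraction (analytic): 0.500, realized: 0.507

$ Rscript analysis/02_contacts.R
residues above the 15% threshold: 59, 73, 74, 75, 82
all calls inside the scheduled site strands: TRUE
max occupancy 0.507 at residue 59 (scheduled bound fraction 0.507)

$ Rscript analysis/03_binding_kinetics.R
retained events: 68 (+0 end-censored discarded)
pipeline recovered the scheduled events exactly: TRUE
fraction of system time bound (sum of histogram y): 0.507
time-weighted mean residence: 14.7 ns, 95% CI [11.6, 17.3]

$ Rscript analysis/04_occupancy_volume.R
grid: 20 x 20 x 12 cells at 5 A
occupancy mass at the site: 0.508 (scheduled bound fraction 0.507)

$ Rscript analysis/05_stats.R
wild type:  270 events, TW mean 1.61 us, CI [1.40, 1.81]
weakened:   392 events, TW mean 0.52 us, CI [0.44, 0.60]
one-tailed MWW p (wild type > weakened): 6.51e-39
```

Reading the output: the contact profile flags exactly the residues lining
the scheduled site; the event pipeline reproduces the generator's
schedule event-for-event; the histogram identity (Σy = bound fraction)
holds on the written artifacts; and the two-condition comparison shows
how a four-fold faster unbinding rate (a stand-in for removing the
head-group-anchoring residue) collapses the time-weighted residence from
~1.6 µs toward 0.5 µs with an overwhelming rank-test significance. Note
the 1.61 µs wild-type estimate versus the analytic 2 µs: end-censoring
biases retained durations downward on finite runs, a bias discussed in
the methods vignette (`vignettes/lipid-site-mapping.Rmd`).

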