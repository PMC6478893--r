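# Shared by the analysis stages: the deterministic study system.
# Regenerated in memory when the stage-1 files are absent, so each stage
# can also run standalone.

suppressMessages(library(cglipidsite))

study_spec <- function() {
  kinetics_spec(k_on = 150, k_off = 150, n_frames = 2000,
                n_ligands = 16, seed = 20260920L)
}

load_study_system <- function() {
  topo <- "scratch/fixtures/study_topology.gro"
  traj <- "scratch/fixtures/study.gro"
  res <- generate_synthetic_trajectory(study_spec())
  if (file.exists(topo) && file.exists(traj)) {
    res$trajectory <- load_trajectory(topo, traj)
  }
  res
}
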