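# Shared study conditions for the analysis scripts. Everything is
# regenerated deterministically from these seeds, so each script can be run
# independently from the repository root:
#   Rscript analysis/01_simulate.R   (then 02, 03, ... in any order)

suppressMessages(library(oligotraj))

RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")
ROOT_SEED <- 20260923L

# Scaled-down coalescence studies: six peptides merging pairwise and then
# fully, with and without an equal count of lipids, three replicates each.
# 200 frames at 0.5 ns spacing (100 ns) keep every stage fast while still
# exercising transient dimer/trimer populations and a dissociation blip.
study_schedule <- function() {
  merge_schedule(
    events = list(list(time = 10, pair = c(1, 2)),
                  list(time = 20, pair = c(3, 4)),
                  list(time = 30, pair = c(5, 6)),
                  list(time = 40, pair = c(1, 3)),
                  list(time = 50, pair = c(1, 5))),
    blips = list(list(time = 70, duration = 0.5, split = 6)),
    n_peptides = 6)
}

study_conditions <- function() {
  list(control = list(n_lipids = 0, seeds = ROOT_SEED + 1:3),
       popc    = list(n_lipids = 6, seeds = ROOT_SEED + 11:13))
}

make_replicate <- function(condition, replicate) {
  cond <- study_conditions()[[condition]]
  make_aggregation_trajectory(
    6, study_schedule(), dt = 0.5, n_frames = 200,
    seed = cond$seeds[replicate], n_lipids = cond$n_lipids)
}

ensure_dir <- function(path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  path
}
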