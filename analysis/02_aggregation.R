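# Aggregation-state detection on the simulated replicates: per-frame N-mer
# partitions from 0.6 nm contact graphs, oligomer population tables, and
# stable-aggregation times (1 ns dwell tolerance), checked against the
# planted schedule.

source("analysis/00_common.R")
out <- ensure_dir(file.path(RESULTS, "aggregation"))

summary_rows <- list()
for (condition in names(study_conditions())) {
  for (rep in 1:3) {
    stem <- file.path(DATA_DIR, sprintf("%s_rep%d", condition, rep))
    sys <- load_system(paste0(stem, "_topology.json"),
                       paste0(stem, "_trajectory.txt"))
    tl <- aggregation_timeline(sys, cutoff = 0.6)
    pop <- nmer_population_timeseries(tl)
    t_agg <- aggregation_time(tl, dwell_tolerance = 1)
    write.csv(pop, file.path(out, sprintf("%s_rep%d_populations.csv",
                                          condition, rep)),
              row.names = FALSE)
    truth <- make_replicate(condition, rep)$truth
    exact <- mean(mapply(identical, tl$partitions,
                         truth$partition_timeline))
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      condition = condition, replicate = rep,
      aggregation_time_ns = t_agg,
      planted_time_ns = truth$aggregation_time,
      timeline_match_fraction = exact)
    cat(sprintf(
      "%s rep %d: t_agg %.1f ns (planted %.1f), timeline match %.0f%%\n",
      condition, rep, t_agg, truth$aggregation_time, 100 * exact))
  }
}
summary <- do.call(rbind, summary_rows)
write.csv(summary, file.path(out, "aggregation_summary.csv"),
          row.names = FALSE)
stopifnot(all(summary$timeline_match_fraction == 1),
          all(summary$aggregation_time_ns == summary$planted_time_ns))
cat("Every replicate's detected timeline equals the planted one,",
    "including bridging of the 0.5 ns dissociation blip at 70 ns.\n")
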