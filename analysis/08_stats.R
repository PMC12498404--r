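# Statistical framework in action: (a) size calibration of the
# subsample -> assumption-checked comparison -> FDR pipeline on true-null
# AR(1) series, and (b) a cross-condition comparison of oligomer
# eccentricity between the control and lipid-containing replicates.

source("analysis/00_common.R")
out <- ensure_dir(file.path(RESULTS, "stats"))

# (a) type-I error on a true null: 3 groups from one AR(1) process
# (rho = 0.9), series long relative to the ~19-frame correlation time
rej <- vapply(1:300, function(i) {
  d <- make_null_timeseries(3, 5e4, 0.9, seed = ROOT_SEED + 1000 + i)
  r <- compare_timeseries_groups(d, n = 100, seed = ROOT_SEED + 9000 + i)
  r$p_adjusted < 0.05
}, logical(1))
write.csv(data.frame(replicates = length(rej), rejection_rate = mean(rej)),
          file.path(out, "null_calibration.csv"), row.names = FALSE)
cat(sprintf("Null rejection rate: %.3f over %d replicates (nominal 0.05)\n",
            mean(rej), length(rej)))

# (b) eccentricity comparison, control vs popc, pooling replicate frames
# over the stable window and subsampling for independence
vals <- list()
for (condition in names(study_conditions())) {
  frames <- do.call(rbind, lapply(1:3, function(rep) {
    stem <- file.path(DATA_DIR, sprintf("%s_rep%d", condition, rep))
    sys <- load_system(paste0(stem, "_topology.json"),
                       paste0(stem, "_trajectory.txt"))
    shp <- shape_timeseries(sys)
    shp[shp$time >= 50, ]
  }))
  vals[[condition]] <- subsample_series(frames$e, 100,
                                        seed = ROOT_SEED + 77)
}
cmp <- compare_groups(c(vals$control, vals$popc),
                      rep(c("control", "popc"), each = 100))
res <- data.frame(test = cmp$test, statistic = cmp$statistic, p = cmp$p,
                  p_adjusted = fdr_adjust(cmp$p),
                  normal = cmp$assumptions$normal,
                  equal_var = cmp$assumptions$equal_var)
write.csv(res, file.path(out, "eccentricity_comparison.csv"),
          row.names = FALSE)
cat(sprintf("Eccentricity control vs popc: %s, p = %.3g (FDR %.3g)\n",
            cmp$test, cmp$p, res$p_adjusted))
cat("Note: both conditions share one placement geometry by design, so no\n",
    "difference is expected here; the comparison demonstrates the workflow.\n")
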