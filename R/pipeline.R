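# End-to-end orchestration: run every analysis stage on one or more
# systems and write the result tables, deterministically under one root
# seed.

#' Pipeline configuration
#'
#' @param systems Named list of `oligotraj_system` objects (one per
#'   condition/replicate), or a single system.
#' @param aggregation_cutoff Contact cutoff for N-mer detection, nm.
#' @param clustering_cutoff GROMOS RMSD cutoff, nm.
#' @param hbond_threshold,saltbridge_threshold Convergence thresholds, nm.
#' @param window Clustering window, ns.
#' @param averaging_range Shape-averaging time range, ns; `NULL` uses the
#'   full trajectory.
#' @param dwell_tolerance Dwell tolerance for stability calls, ns.
#' @param seed Root seed; all stage randomness derives from it.
#' @param out_dir Output directory for CSV/JSON tables.
#' @return A validated `run_config` list.
#' @export
run_config <- function(systems, aggregation_cutoff = 0.6,
                       clustering_cutoff = 0.3, hbond_threshold = 0.35,
                       saltbridge_threshold = 0.4, window = 200,
                       averaging_range = NULL, dwell_tolerance = 1,
                       seed = 1, out_dir = tempfile("oligotraj_run_")) {
  if (inherits(systems, "oligotraj_system")) {
    systems <- list(system1 = systems)
  }
  stopifnot(length(systems) >= 1,
            all(vapply(systems, inherits, logical(1), "oligotraj_system")))
  cutoffs <- c(aggregation_cutoff, clustering_cutoff, hbond_threshold,
               saltbridge_threshold)
  if (any(cutoffs <= 0) || window <= 0) {
    stop("cutoffs and window must be > 0")
  }
  if (!is.null(averaging_range)) {
    for (nm in names(systems)) {
      times <- frame_times(systems[[nm]])
      if (averaging_range[1] < times[1] ||
          averaging_range[1] > times[length(times)]) {
        stop(sprintf(
          "averaging range [%g, %g] outside trajectory span of %s",
          averaging_range[1], averaging_range[2], nm))
      }
    }
  }
  structure(list(systems = systems, aggregation_cutoff = aggregation_cutoff,
                 clustering_cutoff = clustering_cutoff,
                 hbond_threshold = hbond_threshold,
                 saltbridge_threshold = saltbridge_threshold,
                 window = window, averaging_range = averaging_range,
                 dwell_tolerance = dwell_tolerance, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

.write_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run every analysis stage end-to-end
#'
#' Per system: aggregation timeline and N-mer populations, per-frame shape
#' records and window-averaged summary, windowed GROMOS clustering,
#' residue-residue and (when lipids are present) residue-region
#' interaction maps, hydrogen-bond propensities (when hydrogens are
#' present), SASA and hydrophobic-SASA summaries. Outputs are CSV files
#' under the config's `out_dir` plus a JSON provenance record (config
#' hash, seed). Reruns with the same config are bit-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of per-system stage results (also
#'   written to disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (nm in names(config$systems)) {
    sys <- config$systems[[nm]]
    sdir <- file.path(config$out_dir, nm)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    stage <- "aggregation"
    res <- tryCatch({
      tl <- aggregation_timeline(sys, cutoff = config$aggregation_cutoff)
      pop <- nmer_population_timeseries(tl)
      agg_t <- aggregation_time(tl, config$dwell_tolerance)

      stage <- "shape"
      shp <- shape_timeseries(sys)
      rng <- if (is.null(config$averaging_range)) {
        range(frame_times(sys))
      } else config$averaging_range
      shp_sum <- shape_summary(shp, rng)

      stage <- "clustering"
      clu <- windowed_clustering(sys, window = config$window,
                                 cutoff = config$clustering_cutoff)

      stage <- "interactions"
      cst <- residue_contact_stats(sys, cutoff = config$aggregation_cutoff)
      imap <- interaction_frequency(cst, cutoff = config$aggregation_cutoff)
      rmap <- if (n_lipids(sys$topology) > 0) {
        region_interaction_map(sys, cutoff = config$aggregation_cutoff)
      } else NULL

      stage <- "hbonds"
      el <- .element_of(sys$topology$atoms$name)
      hb <- if (any(el == "H")) hbond_propensity(sys) else NULL

      stage <- "sasa"
      last <- sys$frames[[length(sys$frames)]]
      sasa <- shrake_rupley_sasa(last, sys$topology)
      hsasa <- hydrophobic_sasa(sasa)
      nsc <- normalized_solvent_contact(sasa)

      list(timeline = tl, populations = pop, aggregation_time = agg_t,
           shape = shp, shape_summary = shp_sum, clustering = clu,
           contact_stats = cst, interaction_map = imap,
           region_map = rmap, hbond_propensity = hb, sasa = sasa,
           hydrophobic_sasa = hsasa, normalized_contact = nsc)
    }, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed for system '%s': %s",
                   stage, nm, conditionMessage(e)))
    })

    .write_csv(res$populations, sdir, "nmer_populations.csv")
    .write_csv(data.frame(
      frame = seq_along(res$timeline$partitions),
      time = res$timeline$times,
      partition = vapply(res$timeline$partitions, function(p) {
        paste(vapply(p, paste, character(1), collapse = "+"),
              collapse = "|")
      }, character(1))), sdir, "aggregation_timeline.csv")
    .write_csv(res$shape, sdir, "shape_timeseries.csv")
    .write_csv(cbind(system = nm,
                     aggregation_time = res$aggregation_time,
                     res$shape_summary), sdir, "shape_summary.csv")
    .write_csv(data.frame(
      window_start = vapply(res$clustering, function(w) w$window[1],
                            numeric(1)),
      window_end = vapply(res$clustering, function(w) w$window[2],
                          numeric(1)),
      n_clusters = vapply(res$clustering,
                          function(w) length(w$result$clusters),
                          integer(1)),
      occupancy = vapply(res$clustering, function(w) w$result$occupancy,
                         numeric(1))), sdir, "clustering_summary.csv")
    .write_csv(as.data.frame(as.table(unclass(res$interaction_map)),
                             responseName = "frequency"),
               sdir, "interaction_map.csv")
    if (!is.null(res$region_map)) {
      .write_csv(as.data.frame(as.table(unclass(res$region_map)),
                               responseName = "frequency"),
                 sdir, "region_interaction_map.csv")
    }
    if (!is.null(res$hbond_propensity)) {
      .write_csv(res$hbond_propensity, sdir, "hbond_propensity.csv")
    }
    .write_csv(res$hydrophobic_sasa, sdir, "hydrophobic_sasa.csv")
    .write_csv(res$normalized_contact, sdir, "normalized_contact.csv")
    results[[nm]] <- res
  }

  # provenance: hash of the configuration (minus the in-memory systems)
  cfg_desc <- config[setdiff(names(config), "systems")]
  cfg_desc$systems <- lapply(config$systems, function(s) {
    list(n_atoms = nrow(s$topology$atoms), n_frames = length(s$frames))
  })
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(cfg_desc, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  jsonlite::write_json(
    list(config_md5 = unname(tools::md5sum(cfg_path)),
         seed = config$seed,
         package_version = as.character(utils::packageVersion("oligotraj"))),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE)
  invisible(results)
}

#' Pooled shape summary across replicates
#'
#' Per-replicate mean and sd plus a pooled row computed over the
#' concatenated frames of all replicates (frame-weighted, so replicates
#' with more frames weigh more). Eccentricity is also given formatted to
#' two decimals, the conventional reporting precision for this statistic.
#'
#' @param shapes Named list of per-replicate shape data.frames (from
#'   [shape_timeseries()]).
#' @param range Averaging time range, ns.
#' @return data.frame: one row per replicate plus a `pooled` row, columns
#'   `replicate`, `Rg_mean`, `Rg_sd`, `e_mean`, `e_sd`, `e_formatted`,
#'   `n_frames`.
#' @export
summarize_table <- function(shapes, range = c(500, 2000)) {
  stopifnot(length(shapes) >= 1)
  reps <- lapply(shapes, function(s) shape_summary(s, range))
  per <- do.call(rbind, reps)
  per <- cbind(replicate = names(shapes), per)
  all_frames <- do.call(rbind, lapply(shapes, function(s) {
    s[s$time >= range[1] & s$time <= range[2], ]
  }))
  pooled <- data.frame(replicate = "pooled",
                       Rg_mean = mean(all_frames$Rg),
                       Rg_sd = stats::sd(all_frames$Rg),
                       e_mean = mean(all_frames$e),
                       e_sd = stats::sd(all_frames$e),
                       n_frames = nrow(all_frames))
  out <- rbind(per, pooled)
  out$e_formatted <- sprintf("%.2f", out$e_mean)
  rownames(out) <- NULL
  out
}
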