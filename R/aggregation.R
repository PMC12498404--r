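# Aggregation-state detection. Each frame is reduced to a peptide-peptide
# minimum-distance matrix; a contact graph (edge when d < cutoff, strict)
# is built and its connected components define the N-mer partition.

#' Peptide-peptide minimum-distance matrix for one frame
#'
#' Entry (i, j) is the minimum over selected atom pairs of the
#' minimum-image distance between peptides i and j.
#'
#' @param frame An `oligotraj_frame`.
#' @param topology The matching topology (>= 2 peptide chains).
#' @param selection `"all-atom"` (default, matching GROMACS mindist
#'   conventions) or `"heavy-atom"`.
#' @return Symmetric matrix, nm, zero diagonal.
#' @export
peptide_min_distance_matrix <- function(frame, topology,
                                        selection = c("all-atom",
                                                      "heavy-atom")) {
  selection <- match.arg(selection)
  pep <- which(topology$chains$kind == "peptide")
  if (length(pep) < 2) stop("need at least 2 peptides")
  idx <- lapply(pep, function(i) {
    ai <- seq.int(topology$chains$first[i], topology$chains$end[i] - 1L)
    if (selection == "heavy-atom") {
      ai <- ai[.element_of(topology$atoms$name[ai]) != "H"]
    }
    ai
  })
  n <- length(pep)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    Ai <- frame$coordinates[idx[[i]], , drop = FALSE]
    for (j in (i + 1):n) {
      Bj <- frame$coordinates[idx[[j]], , drop = FALSE]
      dmat[i, j] <- dmat[j, i] <- min(.min_image_cross(Ai, Bj, frame$box))
    }
  }
  dmat
}

#' N-mer partition from a distance matrix
#'
#' Connected components of the graph whose edges join peptide pairs with
#' distance strictly below the cutoff. Transitive connectivity: A-B and
#' B-C in contact makes {A, B, C} one trimer even if A and C are far apart.
#'
#' @param dmat Symmetric nonnegative distance matrix, nm.
#' @param cutoff Contact cutoff, nm (default 0.6).
#' @return List of integer vectors (components, each sorted, ordered by
#'   smallest member).
#' @export
nmer_partition <- function(dmat, cutoff = 0.6) {
  stopifnot(is.matrix(dmat), nrow(dmat) == ncol(dmat),
            all(dmat >= 0), isTRUE(all.equal(dmat, t(dmat))))
  adj <- dmat < cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  .canonical_partition(split(seq_along(comp), comp))
}

#' Per-frame aggregation timeline of a system
#'
#' @param system An `oligotraj_system` with >= 2 peptides.
#' @param cutoff Contact cutoff, nm.
#' @param selection Atom selection mode, see
#'   [peptide_min_distance_matrix()].
#' @return An `aggregation_timeline`: list with `times` (ns) and
#'   `partitions` (per-frame component lists).
#' @export
aggregation_timeline <- function(system, cutoff = 0.6,
                                 selection = "all-atom") {
  partitions <- lapply(system$frames, function(f) {
    nmer_partition(peptide_min_distance_matrix(f, system$topology,
                                               selection), cutoff)
  })
  structure(list(times = frame_times(system), partitions = partitions,
                 n_peptides = n_peptides(system$topology)),
            class = "aggregation_timeline")
}

#' @export
print.aggregation_timeline <- function(x, ...) {
  sizes <- vapply(x$partitions, function(p) max(lengths(p)), integer(1))
  cat(sprintf("<aggregation timeline: %d frames, largest N-mer %d-%d>\n",
              length(x$partitions), min(sizes), max(sizes)))
  invisible(x)
}

#' N-mer population table
#'
#' For each frame, the count of components of each size. Sizes times
#' counts always sum to the number of peptides (mass conservation).
#'
#' @param timeline An `aggregation_timeline`.
#' @return data.frame with columns `time`, `size`, `count` (long format;
#'   zero counts omitted).
#' @export
nmer_population_timeseries <- function(timeline) {
  rows <- mapply(function(t, parts) {
    tab <- table(lengths(parts))
    data.frame(time = t, size = as.integer(names(tab)),
               count = as.integer(tab))
  }, timeline$times, timeline$partitions, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

# Bridge short FALSE-gaps in a logical series: a run of FALSE flanked by
# TRUE on both sides whose duration (n_frames * dt) is below the tolerance
# is flipped to TRUE.
.bridge_gaps <- function(flag, times, tolerance) {
  if (length(flag) < 3 || tolerance <= 0) return(flag)
  dt <- stats::median(diff(times))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] && k > 1 && k < length(r$values)) {
      if (r$lengths[k] * dt < tolerance) {
        flag[starts[k]:ends[k]] <- TRUE
      }
    }
  }
  flag
}

#' Time to stable, non-dissociating full aggregation
#'
#' Earliest time from which the full N-mer (all peptides in one component)
#' persists to the final frame, ignoring transient dissociation gaps
#' shorter than the dwell tolerance.
#'
#' @param timeline An `aggregation_timeline`.
#' @param dwell_tolerance Maximum transient dissociation duration to
#'   bridge, ns (default 1).
#' @return Aggregation time in ns, or `NA` if stable full aggregation is
#'   never reached.
#' @export
aggregation_time <- function(timeline, dwell_tolerance = 1) {
  full <- vapply(timeline$partitions, function(p) {
    length(p) == 1 && length(p[[1]]) == timeline$n_peptides
  }, logical(1))
  full <- .bridge_gaps(full, timeline$times, dwell_tolerance)
  n <- length(full)
  if (!full[n]) return(NA_real_)
  last_false <- max(c(0L, which(!full)))
  timeline$times[last_false + 1L]
}

#' Minimum-distance time series between two atom groups
#'
#' Per-frame minimum-image minimum distance between two named selections
#' (e.g. hydrophobic peptide residues vs lipid tails). The companion
#' [convergence_time()] applies the same dwell logic as
#' [aggregation_time()] to find when the series first drops below a
#' contact threshold and stays there.
#'
#' @param system An `oligotraj_system`.
#' @param groupA,groupB Integer atom index vectors (see [select_atoms()]).
#' @param nameA,nameB Labels for the two groups.
#' @return A data.frame with columns `time` and `min_distance`, with the
#'   group names in attributes `groupA` / `groupB`.
#' @export
group_min_distance_timeseries <- function(system, groupA, groupB,
                                          nameA = "groupA",
                                          nameB = "groupB") {
  if (length(groupA) == 0) stop("empty selection: ", nameA)
  if (length(groupB) == 0) stop("empty selection: ", nameB)
  if (length(intersect(groupA, groupB)) > 0) {
    stop("selections must be disjoint")
  }
  d <- vapply(system$frames, function(f) {
    min(.min_image_cross(f$coordinates[groupA, , drop = FALSE],
                         f$coordinates[groupB, , drop = FALSE], f$box))
  }, numeric(1))
  out <- data.frame(time = frame_times(system), min_distance = d)
  attr(out, "groupA") <- nameA
  attr(out, "groupB") <- nameB
  out
}

#' First time a distance series converges below a threshold
#'
#' @param series data.frame from [group_min_distance_timeseries()].
#' @param threshold Contact threshold, nm (0.35 for hydrogen bonds, 0.4
#'   for salt bridges are the conventional choices).
#' @param dwell_tolerance Gaps above threshold shorter than this (ns) are
#'   bridged.
#' @return Time in ns, or `NA` if the series never converges.
#' @export
convergence_time <- function(series, threshold, dwell_tolerance = 1) {
  below <- series$min_distance < threshold
  below <- .bridge_gaps(below, series$time, dwell_tolerance)
  n <- length(below)
  if (!below[n]) return(NA_real_)
  last_above <- max(c(0L, which(!below)))
  series$time[last_above + 1L]
}
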