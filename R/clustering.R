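# Optimal-superposition RMSD (Kabsch) and GROMOS (Daura) neighbor-count
# clustering over fixed time windows.

#' Least-squares RMSD after optimal superposition
#'
#' Kabsch algorithm: optimal translation (centroids) and proper rotation
#' (SVD with determinant correction, so no reflections), then the
#' (weighted) root-mean-square deviation.
#'
#' @param confA,confB n x 3 coordinate matrices, equal atom counts >= 3.
#' @param weights Optional per-atom weights (default uniform).
#' @return RMSD in the coordinate units (nm throughout this package).
#' @export
kabsch_rmsd <- function(confA, confB, weights = NULL) {
  confA <- as.matrix(confA); confB <- as.matrix(confB)
  if (!all(dim(confA) == dim(confB)) || ncol(confA) != 3) {
    stop("conformations must be equal-size n x 3 matrices")
  }
  n <- nrow(confA)
  if (n < 3) stop("need at least 3 atoms")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  w <- w / sum(w)
  A <- sweep(confA, 2, colSums(confA * w))
  B <- sweep(confB, 2, colSums(confB * w))
  sv <- svd(crossprod(B * w, A))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate (collinear) conformation: superposition is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diff <- A %*% R - B
  sqrt(sum(w * rowSums(diff^2)))
}

#' Pairwise RMSD matrix for a list of conformations
#'
#' @param conformations List of n x 3 matrices.
#' @param weights Optional per-atom weights.
#' @return Symmetric matrix of fitted RMSDs.
#' @export
rmsd_matrix <- function(conformations, weights = NULL) {
  n <- length(conformations)
  m <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- kabsch_rmsd(conformations[[i]],
                                          conformations[[j]], weights)
      }
    }
  }
  m
}

#' GROMOS (Daura) neighbor-count clustering
#'
#' Iteratively: count, for every remaining structure, its neighbors at
#' RMSD strictly below the cutoff; the structure with the most neighbors
#' becomes a cluster representative and is removed together with its
#' neighbors; repeat until no structures remain. Ties in the neighbor
#' count go to the lowest structure index. A structure is not its own
#' neighbor but always belongs to its own cluster.
#'
#' @param conformations List of n x 3 coordinate matrices, or a
#'   precomputed RMSD matrix.
#' @param cutoff Neighbor cutoff, nm (default 0.3).
#' @param weights Optional per-atom weights for the RMSD.
#' @return A `cluster_result`: list with `clusters` (each
#'   `list(representative =, members =)`, largest first; members include
#'   the representative), `sizes`, and `occupancy` (fraction of structures
#'   in the top cluster).
#' @export
gromos_cluster <- function(conformations, cutoff = 0.3, weights = NULL) {
  dmat <- if (is.matrix(conformations)) conformations
  else rmsd_matrix(conformations, weights)
  n <- nrow(dmat)
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining) > 0) {
    sub <- dmat[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub < cutoff) - 1L   # strict; exclude self
    center <- remaining[which.max(counts)] # which.max: first (lowest) wins
    members <- remaining[sub[match(center, remaining), ] < cutoff]
    members <- sort(unique(c(center, members)))
    clusters[[length(clusters) + 1L]] <-
      list(representative = center, members = members)
    remaining <- setdiff(remaining, members)
  }
  structure(list(clusters = clusters,
                 sizes = vapply(clusters, function(cl) length(cl$members),
                                integer(1)),
                 occupancy = length(clusters[[1]]$members) / n,
                 n = n, cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster result: %d structures, %d cluster(s), occupancy %.1f%%>\n",
    x$n, length(x$clusters), 100 * x$occupancy))
  invisible(x)
}

# Extract per-frame backbone coordinate matrices for clustering.
.backbone_conformations <- function(system, selection = NULL) {
  if (is.null(selection)) {
    selection <- select_atoms(system$topology, kind = "peptide",
                              backbone = TRUE)
    if (length(selection) == 0) {
      # bead models may carry only CA-like atoms; fall back to peptide atoms
      selection <- select_atoms(system$topology, kind = "peptide")
    }
  }
  lapply(system$frames,
         function(f) f$coordinates[selection, , drop = FALSE])
}

#' Windowed GROMOS clustering over a trajectory
#'
#' Splits the trajectory into consecutive non-overlapping windows (default
#' 200 ns) and clusters the peptide backbone conformations of each window.
#' Peptide chains are concatenated in chain order; no chain-permutation
#' minimization is attempted. A trailing partial window is dropped when it
#' holds fewer than half the frames of a full window.
#'
#' @param system An `oligotraj_system` (unwrapped).
#' @param window Window length, ns.
#' @param cutoff RMSD cutoff, nm.
#' @param selection Optional atom selection (default: peptide backbone).
#' @return List of per-window results: `list(window = c(start, end),
#'   frames =, result = cluster_result)`.
#' @export
windowed_clustering <- function(system, window = 200, cutoff = 0.3,
                                selection = NULL) {
  times <- frame_times(system)
  t0 <- times[1]
  idx <- floor((times - t0) / window)
  confs <- .backbone_conformations(system, selection)
  dt <- stats::median(diff(times))
  full_count <- window / dt
  out <- list()
  for (w in sort(unique(idx))) {
    fr <- which(idx == w)
    if (w == max(idx) && length(fr) < full_count / 2) next
    res <- gromos_cluster(confs[fr], cutoff = cutoff)
    # remap structure indices to frame ids
    res$clusters <- lapply(res$clusters, function(cl) {
      list(representative = fr[cl$representative], members = fr[cl$members])
    })
    out[[length(out) + 1L]] <-
      list(window = t0 + c(w, w + 1) * window, frames = fr, result = res)
  }
  out
}
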