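# Independent oracles used across tests. These are deliberately naive
# (brute force, exhaustive recounting, numeric minimization) and share no
# code with the package implementation.

# Minimum distance over all 27 periodic images, by enumeration.
brute27_distance <- function(p, q, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    img <- q + c(ix, iy, iz) * box
    best <- min(best, sqrt(sum((p - img)^2)))
  }
  best
}

# Connected components by breadth-first search on an adjacency matrix.
bfs_partition <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- c()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, integer(1)))]
}

# GROMOS clustering oracle: recompute every neighbor count from the full
# distance matrix at every step.
gromos_oracle <- function(dmat, cutoff) {
  remaining <- seq_len(nrow(dmat))
  out <- list()
  while (length(remaining)) {
    counts <- vapply(remaining, function(i) {
      sum(dmat[i, remaining] < cutoff) - 1L
    }, integer(1))
    center <- remaining[which(counts == max(counts))[1]]
    members <- remaining[dmat[center, remaining] < cutoff]
    members <- sort(unique(c(center, members)))
    out[[length(out) + 1L]] <- members
    remaining <- setdiff(remaining, members)
  }
  out
}

# Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, m * p[o[k]] / k)
    adj[o[k]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Accessible area of sphere 1 (radius R1, expanded) partially occluded by
# sphere 2 at center distance d: closed-form spherical cap.
two_sphere_accessible <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  if (d + R1 <= R2) return(0)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# Numeric least-squares superposition RMSD: minimize over three Euler
# angles after centroid alignment, with several random restarts.
rmsd_numeric_oracle <- function(A, B, n_starts = 8) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rx %*% Ry %*% Rz
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% rotmat(ang) - B)^2)))
  best <- Inf
  set.seed(42)
  starts <- rbind(c(0, 0, 0),
                  matrix(stats::runif(3 * (n_starts - 1), -pi, pi),
                         ncol = 3))
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Small toy topology: n single-bead "peptides" at given x positions.
bead_peptides <- function(x_positions, box = c(100, 100, 100)) {
  n <- length(x_positions)
  top <- topology(data.frame(
    name = "CA", chain = paste0("P", seq_len(n)), resid = 1L,
    resname = "GLY", stringsAsFactors = FALSE))
  f <- frame(cbind(x_positions, 0, 0) + 50, box)
  list(topology = top, frame = f)
}

# Canonical six-peptide merge schedule used in several tests.
demo_schedule <- function() {
  merge_schedule(
    events = list(list(time = 10, pair = c(1, 2)),
                  list(time = 20, pair = c(3, 4)),
                  list(time = 30, pair = c(5, 6)),
                  list(time = 40, pair = c(1, 3)),
                  list(time = 50, pair = c(1, 5))),
    n_peptides = 6)
}
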