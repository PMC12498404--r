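# Synthetic systems with planted ground truth. These generators script the
# geometry the analysis stages must recover (who is aggregated with whom,
# what shape a cloud has, which cluster a conformation came from, whether a
# hydrogen-bond geometry passes the criterion) without any force-field
# dynamics.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

.canonical_partition <- function(parts) {
  parts <- lapply(unname(parts), function(p) sort(unname(as.integer(p))))
  parts[order(vapply(parts, min, integer(1)))]
}

#' Scripted coalescence schedule
#'
#' Describes when peptide components merge on the way to the final
#' aggregate, plus optional short-lived dissociation "blips" used to test
#' dwell-tolerance bridging.
#'
#' @param events List of `list(time =, pair = c(i, j))`: at `time` (ns) the
#'   components containing peptides `i` and `j` merge. Must be
#'   time-ordered.
#' @param blips Optional list of `list(time =, duration =, split = ids)`:
#'   during `[time, time + duration)` the listed peptides transiently leave
#'   their component.
#' @param n_peptides Number of peptides the schedule applies to.
#' @return A `merge_schedule` object carrying the events, blips and the
#'   final partition implied by the events.
#' @export
merge_schedule <- function(events = list(), blips = list(), n_peptides) {
  times <- vapply(events, `[[`, numeric(1), "time")
  if (length(times) > 1 && any(diff(times) < 0)) {
    stop("merge events must be time-ordered")
  }
  for (ev in events) {
    if (any(ev$pair < 1 | ev$pair > n_peptides)) {
      stop("merge pair outside 1..n_peptides")
    }
  }
  final <- .schedule_partition(events, Inf, n_peptides)
  structure(list(events = events, blips = blips, n_peptides = n_peptides,
                 final_partition = final),
            class = "merge_schedule")
}

# Partition implied by all events with time <= t (blips not applied).
.schedule_partition <- function(events, t, n) {
  comp <- as.list(seq_len(n))
  for (ev in events) {
    if (ev$time > t) break
    ia <- which(vapply(comp, function(p) ev$pair[1] %in% p, logical(1)))
    ib <- which(vapply(comp, function(p) ev$pair[2] %in% p, logical(1)))
    if (ia != ib) {
      comp[[ia]] <- sort(c(comp[[ia]], comp[[ib]]))
      comp[[ib]] <- NULL
    }
  }
  .canonical_partition(comp)
}

# Partition at time t including active blips.
.schedule_partition_at <- function(schedule, t) {
  parts <- .schedule_partition(schedule$events, t, schedule$n_peptides)
  for (b in schedule$blips) {
    if (t >= b$time && t < b$time + b$duration) {
      split <- as.integer(b$split)
      parts <- unlist(lapply(parts, function(p) {
        inside <- intersect(p, split)
        rest <- setdiff(p, split)
        out <- list()
        if (length(rest)) out <- c(out, list(rest))
        if (length(inside)) out <- c(out, list(inside))
        out
      }), recursive = FALSE)
      parts <- .canonical_partition(parts)
    }
  }
  parts
}

#' Synthetic aggregation trajectory with planted partition timeline
#'
#' Builds a periodic system of rigid bead-chain peptides (plus, by default,
#' an equal count of four-bead POPC lipids) whose grouping follows a
#' scripted [merge_schedule()]. Peptides in the same ground-truth component
#' are stacked 0.4 nm apart (inter-peptide minimum distance < 0.45 nm);
#' distinct components sit on a coarse grid separated by well over 1.2 nm,
#' so a 0.6 nm contact cutoff recovers the planted partition exactly
#' regardless of the (small) Gaussian jitter.
#'
#' @param n_peptides Number of peptides (>= 2).
#' @param schedule A [merge_schedule()] for these peptides.
#' @param box Orthorhombic box edge lengths, nm.
#' @param noise_sigma Per-coordinate Gaussian jitter sd, nm (< 0.05).
#' @param dt Frame spacing, ns.
#' @param n_frames Number of frames.
#' @param seed RNG seed; output is deterministic given the seed.
#' @param n_lipids Number of lipid molecules (default equal to
#'   `n_peptides`, a 1:1 peptide:lipid ratio).
#' @param beads_per_peptide Beads per peptide chain.
#' @param residue_names Residue names for the beads (recycled).
#' @return `list(system =, truth =)` where `truth` has
#'   `partition_timeline` (per-frame list of components),
#'   `aggregation_time` (ns; `NA` if the schedule never fully merges) and
#'   `times`.
#' @export
make_aggregation_trajectory <- function(n_peptides, schedule,
                                        box = c(14, 14, 14),
                                        noise_sigma = 0.01, dt = 1,
                                        n_frames = 100, seed = 1,
                                        n_lipids = n_peptides,
                                        beads_per_peptide = 5,
                                        residue_names = c("LEU", "VAL",
                                                          "PHE", "PHE",
                                                          "ALA")) {
  stopifnot(n_peptides >= 2, inherits(schedule, "merge_schedule"),
            schedule$n_peptides == n_peptides, noise_sigma < 0.05)
  bond <- 0.35            # bead spacing along the chain, nm
  stack <- 0.40           # spacing between peptides in one component, nm
  extent_x <- bond * (beads_per_peptide - 1)
  extent_y <- stack * (n_peptides - 1)
  pitch <- max(extent_x, extent_y) + 3.0
  n_side <- ceiling(n_peptides^(1 / 3))
  span <- (n_side - 1) * pitch + max(extent_x, extent_y) + 1.5
  if (span > min(box)) {
    stop(sprintf(
      "separation constraints unsatisfiable: need %.1f nm, box edge %.1f nm",
      span, min(box)))
  }
  # fixed grid of component slots, indexed by the component's smallest member
  slot_xyz <- function(slot) {
    k <- slot - 1L
    (c(k %% n_side, (k %/% n_side) %% n_side, k %/% n_side^2) * pitch) + 1.5
  }

  resn <- rep_len(residue_names, beads_per_peptide)
  pep_atoms <- do.call(rbind, lapply(seq_len(n_peptides), function(p) {
    data.frame(name = "CA", chain = paste0("P", p),
               resid = seq_len(beads_per_peptide), resname = resn,
               stringsAsFactors = FALSE)
  }))
  lip_atoms <- if (n_lipids > 0) {
    do.call(rbind, lapply(seq_len(n_lipids), function(l) {
      data.frame(name = c("N", "P", "C1", "C316"),
                 chain = paste0("L", l), resid = 1L, resname = "POPC",
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  top <- topology(rbind(pep_atoms, lip_atoms))
  n_atoms <- nrow(top$atoms)

  times <- (seq_len(n_frames) - 1) * dt
  .with_seed(seed, {
    frames <- vector("list", n_frames)
    timeline <- vector("list", n_frames)
    for (fi in seq_len(n_frames)) {
      parts <- .schedule_partition_at(schedule, times[fi])
      timeline[[fi]] <- parts
      xyz <- matrix(0, n_atoms, 3)
      for (ci in seq_along(parts)) {
        comp <- parts[[ci]]
        base <- slot_xyz(min(comp))
        for (mi in seq_along(comp)) {
          p <- comp[mi]
          idx <- chain_atoms(top, paste0("P", p))
          xyz[idx, 1] <- base[1] + bond * (seq_len(beads_per_peptide) - 1)
          xyz[idx, 2] <- base[2] + stack * (mi - 1)
          xyz[idx, 3] <- base[3]
        }
      }
      if (n_lipids > 0) {
        lx <- seq(1, by = min(1.2, (box[1] - 2) / n_lipids),
                  length.out = n_lipids)
        for (l in seq_len(n_lipids)) {
          idx <- chain_atoms(top, paste0("L", l))
          xyz[idx, 1] <- lx[l]
          xyz[idx, 2] <- box[2] - 1.0
          xyz[idx, 3] <- box[3] - 1.0 - 0.3 * (seq_along(idx) - 1)
        }
      }
      xyz <- xyz + matrix(stats::rnorm(3 * n_atoms, 0, noise_sigma),
                          n_atoms, 3)
      frames[[fi]] <- frame(xyz, box, times[fi])
    }
    sys <- system_of(top, frames)
  })

  full <- length(schedule$final_partition) == 1 &&
    length(schedule$final_partition[[1]]) == n_peptides
  agg_time <- NA_real_
  if (full) {
    ev_times <- vapply(schedule$events, `[[`, numeric(1), "time")
    t_full <- if (length(ev_times)) max(ev_times) else 0
    cand <- times[times >= t_full]
    if (length(cand)) agg_time <- cand[1]
  }
  list(system = sys,
       truth = list(partition_timeline = lapply(timeline,
                                                .canonical_partition),
                    aggregation_time = agg_time, times = times))
}

#' Uniform ellipsoid point cloud with analytic shape parameters
#'
#' Samples points uniformly inside a solid ellipsoid with semi-axes
#' `a >= b >= c`. The analytic solid-ellipsoid moments are
#' \eqn{I_a = M(b^2+c^2)/5} (about the major axis), etc.; the analytic
#' eccentricity follows from those moments. After sampling, the cloud is
#' affinely standardized (centered, and linearly adjusted so its sample
#' second moments equal the analytic solid-ellipsoid values exactly): the
#' planted shape parameters then hold for the realized points, not merely
#' in expectation, which removes Monte-Carlo noise from the ground truth.
#'
#' @param semi_axes Numeric `(a, b, c)`, nm, non-increasing, positive.
#' @param n_points Number of points (>= 10).
#' @param total_mass Total mass, amu, split equally across points.
#' @param seed RNG seed.
#' @return `list(frame =, topology =, truth = list(moments =, e =))`.
#' @export
make_ellipsoid_cloud <- function(semi_axes, n_points, total_mass = 1,
                                 seed = 1) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0),
            !is.unsorted(rev(semi_axes)))
  if (n_points < 10) stop("n_points must be >= 10")
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  M <- total_mass
  xyz <- .with_seed(seed, {
    g <- matrix(stats::rnorm(3 * n_points), n_points, 3)
    u <- g / sqrt(rowSums(g^2))
    r <- stats::runif(n_points)^(1 / 3)
    sweep(u * r, 2, semi_axes, "*")
  })
  # standardize: exact zero mean and exact analytic second moments
  xyz <- sweep(xyz, 2, colMeans(xyz))
  S <- crossprod(xyz) / n_points
  target <- diag(semi_axes^2 / 5)
  A <- chol(target) %*% solve(t(chol(S)))
  xyz <- xyz %*% t(A)
  top <- topology(data.frame(
    name = "CA", chain = "P1", resid = 1L, resname = "GLY",
    mass = M / n_points, radius = 0.17, stringsAsFactors = FALSE
  )[rep(1, n_points), ])
  I <- sort(M / 5 * c(b^2 + cc^2, a^2 + cc^2, a^2 + b^2))
  e <- 1 - (I[1] + I[2] - I[3]) / (-I[1] + I[2] + I[3])
  list(frame = frame(xyz, rep(100 * max(semi_axes), 3), 0),
       topology = top,
       truth = list(moments = I, e = min(max(e, 0), 1)))
}

#' Conformational ensemble with planted cluster labels
#'
#' Generates `n_centers` template bead-chain structures whose pairwise
#' fitted RMSD is on the `separation` scale, then perturbs each template
#' with Gaussian noise so member-to-template RMSD is on the `spread` scale.
#' With a cutoff between the two scales, neighbor-count (GROMOS) clustering
#' recovers the planted labels.
#'
#' @param n_centers Number of cluster centers.
#' @param members_per_center Integer vector of member counts (length
#'   `n_centers`).
#' @param spread Within-cluster RMSD scale, nm (< separation / 3).
#' @param separation Between-cluster RMSD scale, nm.
#' @param seed RNG seed.
#' @param n_atoms Atoms per conformation.
#' @return `list(conformations = list of matrices, labels = integer
#'   vector)`; conformations are listed center by center, in
#'   `members_per_center` order.
#' @export
make_cluster_ensemble <- function(n_centers, members_per_center, spread,
                                  separation, seed = 1, n_atoms = 8) {
  stopifnot(length(members_per_center) == n_centers,
            spread < separation / 3)
  i0 <- seq_len(n_atoms) - 1
  sd_idx <- sqrt(mean((i0 - mean(i0))^2))
  templates <- lapply(seq_len(n_centers), function(k) {
    dx <- 0.5 + (k - 1) * separation / sd_idx
    cbind(i0 * dx, rep_len(c(0.2, -0.2), n_atoms), 0)
  })
  .with_seed(seed, {
    confs <- list(); labels <- integer(0)
    for (k in seq_len(n_centers)) {
      for (m in seq_len(members_per_center[k])) {
        confs[[length(confs) + 1L]] <- templates[[k]] +
          matrix(stats::rnorm(3 * n_atoms, 0, spread / sqrt(3)), n_atoms, 3)
        labels <- c(labels, k)
      }
    }
    list(conformations = confs, labels = labels)
  })
}

#' Hydrogen-bond geometry fixture
#'
#' Places a donor nitrogen, its hydrogen and an acceptor oxygen with an
#' exact donor--acceptor distance and an exact H--donor--acceptor angle, in
#' two separate residues (so the pair is not excluded as intra-residue).
#'
#' @param distance Donor--acceptor distance, Angstrom.
#' @param theta H--donor--acceptor angle, degrees (0 <= theta < 90).
#' @return `list(frame =, topology =)`.
#' @export
make_hbond_fixture <- function(distance, theta) {
  stopifnot(distance > 0, theta >= 0, theta < 90)
  d_nm <- distance / 10
  th <- theta * pi / 180
  donor <- c(5, 5, 5)
  hydrogen <- donor + 0.10 * c(cos(th), sin(th), 0)
  acceptor <- donor + c(d_nm, 0, 0)
  top <- topology(data.frame(
    name = c("N", "H", "O"), chain = "P1", resid = c(1L, 1L, 2L),
    resname = "SER", stringsAsFactors = FALSE))
  list(frame = frame(rbind(donor, hydrogen, acceptor), c(10, 10, 10), 0),
       topology = top)
}

#' FoldX SequenceDetail fixture text
#'
#' Emits a per-residue energy table in the whitespace-separated
#' SequenceDetail layout the parser accepts: one header line, then one row
#' per residue (`<resname> <chain> <number> <total energy>`), using the
#' canonical amyloid-beta(1-42) residue names.
#'
#' @param dg Named numeric vector: names are residue numbers (1-42),
#'   values are total energies (FoldX units).
#' @param chain Chain label.
#' @param path Optional output file; if given the text is written there.
#' @return Character vector of lines, invisibly if `path` is given.
#' @export
make_foldx_fixture <- function(dg, chain = "A", path = NULL) {
  resid <- as.integer(names(dg))
  if (anyNA(resid) || any(resid < 1 | resid > 42)) {
    stop("residue numbers must be 1..42")
  }
  seq3 <- ab42_sequence("three")
  lines <- c(
    "SequenceDetail output",
    sprintf("%s %s %d %.6f 0 0", seq3[resid], chain, resid, unname(dg)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Group-labelled AR(1) null time series
#'
#' All groups are drawn from one stationary AR(1) process with standard
#' normal marginals (a true null for group comparisons): x_t = rho x_{t-1}
#' + sqrt(1 - rho^2) eps_t.
#'
#' @param n_groups Number of groups.
#' @param length Series length per group.
#' @param autocorr Lag-1 autocorrelation rho, 0 <= rho < 1.
#' @param seed RNG seed.
#' @return data.frame with columns `group`, `time`, `value`.
#' @export
make_null_timeseries <- function(n_groups, length, autocorr = 0, seed = 1) {
  stopifnot(autocorr >= 0, autocorr < 1)
  .with_seed(seed, {
    rows <- lapply(seq_len(n_groups), function(g) {
      eps <- stats::rnorm(length, 0, sqrt(1 - autocorr^2))
      x0 <- stats::rnorm(1)   # stationary start
      x <- as.numeric(stats::filter(eps, autocorr, method = "recursive",
                                    init = x0))
      data.frame(group = paste0("g", g), time = seq_len(length), value = x)
    })
    do.call(rbind, rows)
  })
}
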