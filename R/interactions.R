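# Residue-residue and residue-lipid-region interaction frequency maps, and
# geometric hydrogen-bond detection.
#
# The interaction "frequency" for a residue pair compresses three
# observations into one number in [0, 1]:
#   (1) how many distinct molecule pairs ever show the contact,
#   (2) the fraction of frames the contact is present (averaged over the
#       molecule pairs that ever show it), and
#   (3) how tight the contact is when present (mean distance, relative to
#       the cutoff).
# The combination used here is multiplicative,
#   F = (pairs_observed / pairs_possible) * frame_fraction
#       * (1 - mean_contact_distance / cutoff),
# which preserves all three monotonicities (more pairs, more frames and
# tighter contacts each increase F) and is isolated in
# interaction_frequency() so it can be swapped out.

# Minimum distance between residue i atoms of chain a and residue j atoms
# of chain b across frames: helper returning a frames-long vector.
.residue_pair_min_dist <- function(system, idx_a, idx_b) {
  vapply(system$frames, function(f) {
    min(.min_image_cross(f$coordinates[idx_a, , drop = FALSE],
                         f$coordinates[idx_b, , drop = FALSE], f$box))
  }, numeric(1))
}

#' Per-residue-pair contact statistics across peptide pairs
#'
#' For each residue-position pair (i, j) and each unordered peptide pair,
#' a contact exists in a frame when the minimum-image distance between the
#' residues (taking the closer of the two i/j orientations) is below the
#' cutoff. Statistics returned per (i, j): the number of distinct peptide
#' pairs ever in contact, the mean (over those pairs) fraction of frames
#' in contact, and the mean contact distance conditional on contact.
#'
#' @param system An `oligotraj_system` with >= 2 peptides.
#' @param cutoff Contact cutoff, nm (default 0.6).
#' @return data.frame with columns `res_i`, `res_j` (i <= j),
#'   `n_pairs_possible`, `n_pairs_observed`, `mean_frame_fraction`,
#'   `mean_contact_distance` (0 when never in contact, by convention).
#' @export
residue_contact_stats <- function(system, cutoff = 0.6) {
  top <- system$topology
  pep <- which(top$chains$kind == "peptide")
  if (length(pep) < 2) stop("need at least 2 peptides")
  n_pep <- length(pep)
  n_res <- max(top$atoms$resid[unlist(lapply(pep, function(i) {
    seq.int(top$chains$first[i], top$chains$end[i] - 1L)
  }))])
  res_idx <- lapply(pep, function(ci) {
    atoms <- seq.int(top$chains$first[ci], top$chains$end[ci] - 1L)
    lapply(seq_len(n_res), function(r) atoms[top$atoms$resid[atoms] == r])
  })
  n_pairs_possible <- n_pep * (n_pep - 1) / 2
  out <- list()
  for (i in seq_len(n_res)) {
    for (j in i:n_res) {
      frac <- c(); dists <- c()
      for (a in seq_len(n_pep - 1)) {
        for (b in (a + 1):n_pep) {
          d1 <- .residue_pair_min_dist(system, res_idx[[a]][[i]],
                                       res_idx[[b]][[j]])
          d <- if (i == j) d1 else {
            pmin(d1, .residue_pair_min_dist(system, res_idx[[a]][[j]],
                                            res_idx[[b]][[i]]))
          }
          contact <- d < cutoff
          if (any(contact)) {
            frac <- c(frac, mean(contact))
            dists <- c(dists, d[contact])
          }
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        res_i = i, res_j = j,
        n_pairs_possible = n_pairs_possible,
        n_pairs_observed = length(frac),
        mean_frame_fraction = if (length(frac)) mean(frac) else 0,
        mean_contact_distance = if (length(dists)) mean(dists) else 0)
    }
  }
  do.call(rbind, out)
}

#' Weighted interaction-frequency map from contact statistics
#'
#' Applies the multiplicative weighting
#' `F = (n_observed / n_possible) * frame_fraction * (1 - mean_dist /
#' cutoff)` to per-pair contact statistics. F is 0 when a pair is never in
#' contact and lies in [0, 1] always.
#'
#' @param stats data.frame from [residue_contact_stats()] (or any table
#'   with the same columns).
#' @param cutoff The cutoff the statistics were computed with, nm.
#' @return An `interaction_map`: symmetric residue x residue matrix of
#'   frequencies in [0, 1], with residue positions as dimnames.
#' @export
interaction_frequency <- function(stats, cutoff = 0.6) {
  n_res <- max(stats$res_i, stats$res_j)
  F <- matrix(0, n_res, n_res,
              dimnames = list(seq_len(n_res), seq_len(n_res)))
  f <- with(stats, (n_pairs_observed / n_pairs_possible) *
              mean_frame_fraction *
              pmax(0, 1 - mean_contact_distance / cutoff))
  f[stats$n_pairs_observed == 0] <- 0
  for (k in seq_len(nrow(stats))) {
    F[stats$res_i[k], stats$res_j[k]] <- f[k]
    F[stats$res_j[k], stats$res_i[k]] <- f[k]
  }
  structure(F, class = c("interaction_map", "matrix"))
}

#' Residue-by-lipid-region interaction frequency map
#'
#' Same weighting as [interaction_frequency()], with (peptide, lipid)
#' molecule pairs in the role of peptide pairs and the contact evaluated
#' between a peptide residue and the atoms of one lipid region (choline,
#' phosphate, glycerol, tail).
#'
#' @param system An `oligotraj_system` containing lipid chains.
#' @param cutoff Contact cutoff, nm.
#' @return An `interaction_map` matrix: residues x 4 regions, values in
#'   [0, 1].
#' @export
region_interaction_map <- function(system, cutoff = 0.6) {
  top <- system$topology
  pep <- which(top$chains$kind == "peptide")
  lip <- which(top$chains$kind == "lipid")
  if (length(lip) == 0) stop("system contains no lipids")
  regions <- c("choline", "phosphate", "glycerol", "tail")
  n_res <- max(top$atoms$resid[unlist(lapply(pep, function(i) {
    seq.int(top$chains$first[i], top$chains$end[i] - 1L)
  }))])
  res_idx <- lapply(pep, function(ci) {
    atoms <- seq.int(top$chains$first[ci], top$chains$end[ci] - 1L)
    lapply(seq_len(n_res), function(r) atoms[top$atoms$resid[atoms] == r])
  })
  reg_idx <- lapply(lip, function(ci) {
    atoms <- seq.int(top$chains$first[ci], top$chains$end[ci] - 1L)
    lapply(regions, function(rg) atoms[top$atoms$region[atoms] == rg])
  })
  n_possible <- length(pep) * length(lip)
  F <- matrix(0, n_res, length(regions),
              dimnames = list(seq_len(n_res), regions))
  for (r in seq_len(n_res)) {
    for (g in seq_along(regions)) {
      frac <- c(); dists <- c()
      for (p in seq_along(pep)) {
        for (l in seq_along(lip)) {
          if (length(reg_idx[[l]][[g]]) == 0) next
          d <- .residue_pair_min_dist(system, res_idx[[p]][[r]],
                                      reg_idx[[l]][[g]])
          contact <- d < cutoff
          if (any(contact)) {
            frac <- c(frac, mean(contact))
            dists <- c(dists, d[contact])
          }
        }
      }
      if (length(frac)) {
        F[r, g] <- (length(frac) / n_possible) * mean(frac) *
          max(0, 1 - mean(dists) / cutoff)
      }
    }
  }
  structure(F, class = c("interaction_map", "matrix"))
}

#' Geometric hydrogen-bond detection
#'
#' A donor--hydrogen--acceptor triple forms a bond when the
#' donor--acceptor distance r (Angstrom) satisfies
#' `r < 3.3 - 0.00044 * theta^2`, with theta the hydrogen--donor--acceptor
#' angle in degrees. Donors are N/O atoms with a covalently bound hydrogen
#' (H within 1.2 Angstrom); acceptors are any other N/O. Pairs within one
#' residue are excluded.
#'
#' @param frame An `oligotraj_frame`.
#' @param topology The matching topology; must contain hydrogens.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices), `distance` (Angstrom) and `angle` (degrees); zero rows when
#'   no bond qualifies.
#' @export
detect_hbonds <- function(frame, topology) {
  el <- .element_of(topology$atoms$name)
  x <- frame$coordinates
  box <- frame$box
  h_idx <- which(el == "H")
  no_idx <- which(el %in% c("N", "O"))
  if (length(h_idx) == 0) {
    stop("topology contains no hydrogens; hydrogen-bond detection needs ",
         "an all-atom topology with explicit hydrogens")
  }
  # covalent donor for each hydrogen: nearest N/O within 0.12 nm
  dh <- .min_image_cross(x[no_idx, , drop = FALSE],
                         x[h_idx, , drop = FALSE], box)
  out <- list()
  for (hi in seq_along(h_idx)) {
    cand <- which(dh[, hi] < 0.12)
    if (length(cand) == 0) next
    donor <- no_idx[cand[which.min(dh[cand, hi])]]
    h <- h_idx[hi]
    for (acc in no_idx) {
      if (acc == donor) next
      same_res <- topology$atoms$chain[acc] == topology$atoms$chain[donor] &&
        topology$atoms$resid[acc] == topology$atoms$resid[donor]
      if (same_res) next
      r_nm <- minimum_image_distance(x[donor, ], x[acc, ], box)
      v1 <- x[h, ] - x[donor, ]
      v1 <- v1 - box * round(v1 / box)
      v2 <- x[acc, ] - x[donor, ]
      v2 <- v2 - box * round(v2 / box)
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      theta <- acos(min(max(cosang, -1), 1)) * 180 / pi
      r_ang <- 10 * r_nm
      if (theta < 90 && r_ang < 3.3 - 0.00044 * theta^2) {
        out[[length(out) + 1L]] <- data.frame(
          donor = donor, hydrogen = h, acceptor = acc,
          distance = r_ang, angle = theta)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  }
  do.call(rbind, out)
}

#' Per-residue hydrogen-bond propensity over a trajectory
#'
#' Counts, per residue position, bonds per frame (a bond is attributed to
#' both its donor and acceptor residue), averaged over the trajectory.
#'
#' @param system An `oligotraj_system` with hydrogens.
#' @return data.frame with columns `resid` and `bonds_per_frame`.
#' @export
hbond_propensity <- function(system) {
  top <- system$topology
  n_res <- max(top$atoms$resid)
  counts <- numeric(n_res)
  for (f in system$frames) {
    hb <- detect_hbonds(f, top)
    if (nrow(hb)) {
      for (k in seq_len(nrow(hb))) {
        counts[top$atoms$resid[hb$donor[k]]] <-
          counts[top$atoms$resid[hb$donor[k]]] + 1
        counts[top$atoms$resid[hb$acceptor[k]]] <-
          counts[top$atoms$resid[hb$acceptor[k]]] + 1
      }
    }
  }
  data.frame(resid = seq_len(n_res),
             bonds_per_frame = counts / length(system$frames))
}
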