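# Shape descriptors: mass-weighted radius of gyration, principal inertia
# moments and the inertia-tensor eccentricity.
#
# The eccentricity convention here treats the oligomer as an ellipsoid and
# orders the principal moments ascending (I1 <= I2 <= I3): the *major*
# (longest) axis carries the *smallest* moment, so I1 belongs to the major
# axis. With that ordering
#     e = 1 - (I1 + I2 - I3) / (-I1 + I2 + I3)
# lies in [0, 1]: 0 for a sphere, -> 1 for rods and thin discs.

.selection_xyz_mass <- function(frame, topology, selection) {
  if (is.null(selection)) selection <- seq_len(nrow(topology$atoms))
  if (length(selection) == 0) stop("empty atom selection")
  m <- topology$atoms$mass[selection]
  if (sum(m) <= 0) stop("zero total mass in selection")
  list(x = frame$coordinates[selection, , drop = FALSE], m = m)
}

#' Mass-weighted radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i \lVert r_i \rVert^2 / \sum_i m_i}} with
#' \eqn{r_i} taken relative to the selection's centre of mass. The molecule
#' (or aggregate) must already be whole; use [unwrap_molecule()] first for
#' wrapped trajectories.
#'
#' @param frame An `oligotraj_frame`.
#' @param topology The matching `oligotraj_topology`.
#' @param selection Integer atom indices (default: all atoms).
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(frame, topology, selection = NULL) {
  s <- .selection_xyz_mass(frame, topology, selection)
  com <- colSums(s$x * s$m) / sum(s$m)
  r2 <- rowSums(sweep(s$x, 2, com)^2)
  sqrt(sum(s$m * r2) / sum(s$m))
}

#' Principal moments of inertia
#'
#' Eigenvalues of the mass-weighted inertia tensor about the centre of
#' mass, sorted ascending. The smallest moment (`I1`) is the moment about
#' the major (longest) principal axis.
#'
#' @inheritParams radius_of_gyration
#' @return Numeric length-3 vector `(I1, I2, I3)` in amu nm^2, ascending.
#' @export
inertia_moments <- function(frame, topology, selection = NULL) {
  s <- .selection_xyz_mass(frame, topology, selection)
  com <- colSums(s$x * s$m) / sum(s$m)
  x <- sweep(s$x, 2, com)
  r2 <- rowSums(x^2)
  I <- diag(sum(s$m * r2), 3) - crossprod(x * sqrt(s$m))
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}

#' Inertia-tensor eccentricity
#'
#' \eqn{e = 1 - (I_1 + I_2 - I_3)/(-I_1 + I_2 + I_3)} for ascending
#' principal moments. Equals 0 for a sphere and approaches 1 for elongated
#' (rod) or flattened (disc) shapes.
#'
#' @param moments Numeric length-3 vector of principal moments, ascending
#'   (`I1 <= I2 <= I3`), all positive, satisfying `I3 <= I1 + I2` (a
#'   perpendicular-axis-type constraint any real mass distribution obeys).
#' @return Eccentricity in [0, 1].
#' @export
#' @examples
#' eccentricity(c(1, 1, 1))     # 0 (sphere)
#' eccentricity(c(0.4, 2, 2))   # 8/9 (3:1:1 solid ellipsoid)
eccentricity <- function(moments) {
  if (length(moments) != 3 || any(!is.finite(moments)) || any(moments <= 0)) {
    stop("moments must be three positive finite values")
  }
  if (is.unsorted(moments)) {
    stop("moments must be ascending (I1 <= I2 <= I3)")
  }
  tol <- 1e-9 * moments[3]
  if (moments[3] > moments[1] + moments[2] + tol) {
    stop("invalid moments: I3 > I1 + I2")
  }
  e <- 1 - (moments[1] + moments[2] - moments[3]) /
    (-moments[1] + moments[2] + moments[3])
  min(max(e, 0), 1)
}

#' Per-frame shape records for a selection
#'
#' Computes Rg, principal inertia moments and eccentricity for every frame.
#' By default the peptide-only selection is used, matching how oligomer
#' shape is normally reported; pass an explicit selection to include lipids.
#'
#' @param system An `oligotraj_system` (already unwrapped).
#' @param selection Atom indices; default all peptide atoms.
#' @return data.frame with columns `time`, `Rg`, `I1`, `I2`, `I3`, `e`.
#' @export
shape_timeseries <- function(system, selection = NULL) {
  if (is.null(selection)) {
    selection <- select_atoms(system$topology, kind = "peptide")
  }
  rows <- lapply(system$frames, function(f) {
    I <- inertia_moments(f, system$topology, selection)
    data.frame(time = f$time,
               Rg = radius_of_gyration(f, system$topology, selection),
               I1 = I[1], I2 = I[2], I3 = I[3],
               e = eccentricity(I))
  })
  do.call(rbind, rows)
}

#' Window-averaged shape summary
#'
#' Mean and standard deviation of Rg and eccentricity over a time range
#' (default 500-2000 ns, the post-aggregation window used for oligomer
#' shape tables).
#'
#' @param shape data.frame from [shape_timeseries()].
#' @param range Length-2 time range in ns, inclusive.
#' @return One-row data.frame: `Rg_mean`, `Rg_sd`, `e_mean`, `e_sd`,
#'   `n_frames`.
#' @export
shape_summary <- function(shape, range = c(500, 2000)) {
  sel <- shape$time >= range[1] & shape$time <= range[2]
  if (!any(sel)) stop("averaging range contains no frames")
  s <- shape[sel, ]
  data.frame(Rg_mean = mean(s$Rg), Rg_sd = stats::sd(s$Rg),
             e_mean = mean(s$e), e_sd = stats::sd(s$e),
             n_frames = sum(sel))
}
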