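# Shrake-Rupley solvent-accessible surface area with hydrophobic
# partitioning, and simplified-DSSP secondary-structure summaries.

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom accessible area by sphere-point quadrature: each atom is
#' expanded by the probe radius and covered with a deterministic
#' quasi-uniform point set; points falling inside any neighboring expanded
#' sphere are occluded. Areas are aggregated per residue and per chain.
#'
#' @param frame An `oligotraj_frame` (molecules whole; no periodic wrap is
#'   applied, SASA is computed on the coordinates as given).
#' @param topology Matching topology; every atom must carry a radius.
#' @param probe Probe (solvent) radius, nm (default 0.14, water).
#' @param n_points Quadrature points per atom (default 960).
#' @param selection Atom indices to include (default all).
#' @return A `sasa_record`: list with `atom_area` (nm^2 per selected
#'   atom), `residue` (data.frame chain, resid, resname, area),
#'   `chain` (data.frame chain_id, kind, area, n_heavy).
#' @export
shrake_rupley_sasa <- function(frame, topology, probe = 0.14,
                               n_points = 960, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(topology$atoms))
  radii <- topology$atoms$radius[selection]
  if (anyNA(radii)) {
    stop("missing radius for atom(s): ",
         paste(topology$atoms$name[selection][is.na(radii)], collapse = ", "))
  }
  x <- frame$coordinates[selection, , drop = FALSE]
  n <- length(selection)
  R <- radii + probe
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  # neighbor cutoff: two expanded spheres can overlap only within Ri + Rj
  maxR <- max(R)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(x) - x[i, ])^2))
    nb <- which(d < R[i] + maxR & seq_len(n) != i)
    nb <- nb[d[nb] < R[i] + R[nb]]
    p <- sweep(pts * R[i], 2, x[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(acc)) break
        dj2 <- colSums((t(p[acc, , drop = FALSE]) - x[j, ])^2)
        acc[acc] <- dj2 >= R[j]^2
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    area[i] <- 4 * pi * R[i]^2 * frac
  }
  a <- topology$atoms[selection, ]
  key <- paste(a$chain, a$resid)
  res_area <- tapply(area, key, sum)
  first <- !duplicated(key)
  residue <- data.frame(chain = a$chain[first], resid = a$resid[first],
                        resname = a$resname[first],
                        area = as.numeric(res_area[key[first]]),
                        stringsAsFactors = FALSE)
  heavy <- .element_of(a$name) != "H"
  ch_area <- tapply(area, a$chain, sum)
  ch_heavy <- tapply(heavy, a$chain, sum)
  cid <- names(ch_area)
  chain <- data.frame(
    chain_id = cid,
    kind = topology$chains$kind[match(cid, topology$chains$chain_id)],
    area = as.numeric(ch_area), n_heavy = as.integer(ch_heavy),
    stringsAsFactors = FALSE)
  structure(list(atom_area = area, residue = residue, chain = chain,
                 probe = probe, n_points = n_points),
            class = "sasa_record")
}

#' @export
print.sasa_record <- function(x, ...) {
  cat(sprintf("<SASA record: %d atoms, total %.3f nm^2>\n",
              length(x$atom_area), sum(x$atom_area)))
  invisible(x)
}

#' Hydrophobic SASA per peptide
#'
#' Sum of residue SASA over the hydrophobic residue set
#' (Ala, Val, Leu, Ile, Met, Phe) for each peptide chain.
#'
#' @param record A `sasa_record`.
#' @return data.frame with columns `chain_id` and `hydrophobic_area`
#'   (nm^2), one row per peptide chain.
#' @export
hydrophobic_sasa <- function(record) {
  hydro <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE")
  pep <- record$chain$chain_id[record$chain$kind == "peptide"]
  area <- vapply(pep, function(cid) {
    r <- record$residue
    sum(r$area[r$chain == cid & r$resname %in% hydro])
  }, numeric(1))
  data.frame(chain_id = pep, hydrophobic_area = as.numeric(area),
             stringsAsFactors = FALSE)
}

#' Size-normalized solvent contact per molecule
#'
#' Chain SASA divided by the chain's heavy-atom count, making solvent
#' exposure comparable between molecules of different size (peptides vs
#' lipids).
#'
#' @param record A `sasa_record`.
#' @return data.frame with columns `chain_id`, `kind`,
#'   `normalized_contact` (nm^2 per heavy atom).
#' @export
normalized_solvent_contact <- function(record) {
  data.frame(chain_id = record$chain$chain_id, kind = record$chain$kind,
             normalized_contact = record$chain$area /
               pmax(record$chain$n_heavy, 1),
             stringsAsFactors = FALSE)
}

#' Collapse an 8-state DSSP code to helix/strand/coil
#'
#' H, G, I (alpha-, 3-10- and pi-helix) map to helix; E, B (ladder and
#' bridge) to strand; T, S, C, and blank (turn, bend, loop, unassigned) to
#' coil.
#'
#' @param code Character vector of single DSSP letters.
#' @return Character vector in `{"helix", "strand", "coil"}`.
#' @export
simplify_dssp <- function(code) {
  map <- c(H = "helix", G = "helix", I = "helix",
           E = "strand", B = "strand",
           T = "coil", S = "coil", C = "coil", " " = "coil")
  out <- map[code]
  if (anyNA(out)) {
    stop("unknown DSSP code(s): ",
         paste(unique(code[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Read a frames-by-residues DSSP letter grid from text
#'
#' One line per frame, one DSSP letter per residue (no separators).
#'
#' @param path Text file path.
#' @return Character matrix (frames x residues).
#' @export
read_dssp_grid <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  widths <- nchar(lines)
  if (length(unique(widths)) != 1) {
    stop("ragged DSSP table: line widths ", paste(unique(widths),
                                                  collapse = ", "))
  }
  do.call(rbind, strsplit(lines, ""))
}

#' Secondary-structure content summary
#'
#' Per-residue probabilities of helix/strand/coil over frames, and
#' system-level percentages. When several replicate tables are given, the
#' system percentage uncertainty is the standard deviation over
#' replicates.
#'
#' @param code_table A frames x residues character matrix of DSSP codes,
#'   or a list of such matrices (replicates).
#' @return List with `per_residue` (data.frame resid, helix, strand,
#'   coil; probabilities summing to 1) and `system` (data.frame class,
#'   percent, sd).
#' @export
ss_content_summary <- function(code_table) {
  tables <- if (is.list(code_table)) code_table else list(code_table)
  n_res <- unique(vapply(tables, ncol, integer(1)))
  if (length(n_res) != 1) stop("replicate tables differ in residue count")
  simple <- lapply(tables, function(tab) {
    matrix(simplify_dssp(tab), nrow(tab), ncol(tab))
  })
  pooled <- do.call(rbind, simple)
  per_res <- data.frame(
    resid = seq_len(n_res),
    helix = colMeans(pooled == "helix"),
    strand = colMeans(pooled == "strand"),
    coil = colMeans(pooled == "coil"))
  pct <- vapply(simple, function(m) {
    c(helix = mean(m == "helix"), strand = mean(m == "strand"),
      coil = mean(m == "coil")) * 100
  }, numeric(3))
  system <- data.frame(
    class = rownames(pct),
    percent = rowMeans(pct),
    sd = if (ncol(pct) > 1) apply(pct, 1, stats::sd) else NA_real_)
  list(per_residue = per_res, system = system)
}
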