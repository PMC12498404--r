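# Canonical amino-acid names and element properties used throughout the
# package. Radii are Bondi-type van der Waals radii in nm; masses in amu.
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

.ELEMENTS <- data.frame(
  element = c("H", "C", "N", "O", "S", "P"),
  mass    = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974),
  radius  = c(0.120, 0.170, 0.155, 0.152, 0.180, 0.180),
  stringsAsFactors = FALSE
)

#' Canonical amyloid-beta (1-42) sequence
#'
#' The 42-residue amyloid-beta peptide sequence used for residue-class
#' assignments and hydrophobic-subset definitions.
#'
#' @param format `"one"` for one-letter codes, `"three"` for three-letter
#'   codes.
#' @return Character vector of length 42.
#' @export
#' @examples
#' ab42_sequence()[19] # "F"
ab42_sequence <- function(format = c("one", "three")) {
  format <- match.arg(format)
  one <- strsplit("DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA", "")[[1]]
  if (format == "one") return(one)
  .AA3[match(one, .AA1)]
}

.element_of <- function(atom_name) {
  # First alphabetic character of the atom name; CHARMM-style names put the
  # element first (CA, HB1, OD2, N, P).
  el <- toupper(substr(gsub("^[0-9]*", "", atom_name), 1, 1))
  bad <- !el %in% .ELEMENTS$element
  if (any(bad)) {
    stop("cannot infer element for atom name(s): ",
         paste(unique(atom_name[bad]), collapse = ", "))
  }
  el
}

.element_mass <- function(atom_name) {
  .ELEMENTS$mass[match(.element_of(atom_name), .ELEMENTS$element)]
}

.element_radius <- function(atom_name) {
  .ELEMENTS$radius[match(.element_of(atom_name), .ELEMENTS$element)]
}

# ---------------------------------------------------------------------------
# POPC region table

#' POPC atom-to-region assignment table
#'
#' Maps every atom of a POPC lipid (CHARMM36 atom naming, 134 atoms) to one
#' of the four headgroup/tail regions used in residue--lipid interaction
#' analysis: choline, phosphate, glycerol (including the two ester linkages)
#' and tail (both acyl chains). The table is a total partition: every atom
#' appears exactly once.
#'
#' @return A data.frame with columns `atom` and
#'   `region` (one of `"choline"`, `"phosphate"`, `"glycerol"`, `"tail"`).
#' @export
popc_region_table <- function() {
  choline <- c(
    "N", "C12", "H12A", "H12B", "C13", "H13A", "H13B", "H13C",
    "C14", "H14A", "H14B", "H14C", "C15", "H15A", "H15B", "H15C",
    "C11", "H11A", "H11B")
  phosphate <- c("P", "O11", "O12", "O13", "O14")
  glycerol <- c(
    "C1", "HA", "HB", "C2", "HS", "C3", "HX", "HY",
    "O21", "C21", "O22", "O31", "C31", "O32")
  # sn-2 oleoyl chain: C22..C218 with a 9-10 double bond; sn-1 palmitoyl
  # chain: C32..C316. Hydrogen naming follows CHARMM36 (R/S on sn-2, X/Y on
  # sn-1, T/Z on the terminal methyls, H91/H101 at the double bond).
  ole_c <- paste0("C2", 2:18)
  ole_h <- c(
    unlist(lapply(setdiff(2:17, c(9, 10)),
                  function(i) paste0("H", i, c("R", "S")))),
    "H91", "H101", "H18R", "H18S", "H18T")
  pal_c <- paste0("C3", 2:16)
  pal_h <- c(
    unlist(lapply(2:15, function(i) paste0("H", i, "X"))),
    unlist(lapply(2:15, function(i) paste0("H", i, "Y"))),
    "H16X", "H16Y", "H16Z")
  tail <- c(ole_c, ole_h, pal_c, pal_h)
  data.frame(
    atom = c(choline, phosphate, glycerol, tail),
    region = rep(c("choline", "phosphate", "glycerol", "tail"),
                 c(length(choline), length(phosphate), length(glycerol),
                   length(tail))),
    stringsAsFactors = FALSE)
}

#' Assign a lipid atom to its headgroup/tail region
#'
#' Deterministic total mapping from (residue name, atom name) to one of the
#' four POPC regions. Unknown atom names are an error, never guessed.
#'
#' @param residue_name Three(plus)-letter residue code; only `"POPC"` is
#'   supported.
#' @param atom_name Atom name(s) in the CHARMM36 convention.
#' @return Character vector of region labels, one per atom name.
#' @export
#' @examples
#' label_lipid_regions("POPC", "P")  # "phosphate"
#' label_lipid_regions("POPC", "N")  # "choline"
label_lipid_regions <- function(residue_name, atom_name) {
  if (!identical(toupper(residue_name), "POPC")) {
    stop("unsupported lipid residue: ", residue_name)
  }
  tab <- popc_region_table()
  idx <- match(atom_name, tab$atom)
  if (anyNA(idx)) {
    stop("unknown POPC atom name(s): ",
         paste(unique(atom_name[is.na(idx)]), collapse = ", "))
  }
  tab$region[idx]
}

# ---------------------------------------------------------------------------
# Topology / Frame / System

#' Build a topology from a per-atom table
#'
#' The topology holds one row per atom with chain membership, residue
#' numbering (1-based within each chain), masses (amu), van der Waals radii
#' (nm), backbone flags (N, CA, C, O of peptide chains) and, for lipid
#' atoms, the POPC region label. Chain kind is inferred from residue names:
#' `POPC` residues form lipid chains, the twenty amino acids form peptide
#' chains; any other residue name is an error.
#'
#' @param atoms data.frame with columns `name`, `chain`, `resid`, `resname`
#'   and optionally `mass`, `radius` (filled from element defaults when
#'   absent).
#' @return An object of class `oligotraj_topology` with components `atoms`
#'   (the completed per-atom table, plus `backbone` and `region` columns)
#'   and `chains` (one row per chain: `chain_id`, `kind`, `first`, `end` --
#'   a half-open atom index interval).
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "chain", "resid", "resname") %in% names(atoms)))
  atoms$name <- as.character(atoms$name)
  atoms$chain <- as.character(atoms$chain)
  atoms$resname <- toupper(as.character(atoms$resname))
  if (is.null(atoms$mass)) atoms$mass <- .element_mass(atoms$name)
  if (is.null(atoms$radius)) atoms$radius <- .element_radius(atoms$name)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    stop("all atom masses must be finite and > 0")
  }
  known <- atoms$resname %in% c(.AA3, "POPC")
  if (any(!known)) {
    stop("unknown residue name(s): ",
         paste(unique(atoms$resname[!known]), collapse = ", "))
  }

  # chains are maximal runs of equal chain id, in file order
  brk <- c(TRUE, atoms$chain[-1] != atoms$chain[-nrow(atoms)])
  first <- which(brk)
  end <- c(first[-1], nrow(atoms) + 1L)
  chain_id <- atoms$chain[first]
  if (anyDuplicated(chain_id)) {
    stop("chain ids must be contiguous; duplicated id(s): ",
         paste(unique(chain_id[duplicated(chain_id)]), collapse = ", "))
  }
  kind <- ifelse(atoms$resname[first] == "POPC", "lipid", "peptide")

  atoms$backbone <- atoms$name %in% c("N", "CA", "C", "O") &
    rep(kind, end - first) == "peptide"
  atoms$region <- NA_character_
  lip <- rep(kind, end - first) == "lipid"
  if (any(lip)) {
    atoms$region[lip] <- label_lipid_regions("POPC", atoms$name[lip])
  }

  structure(
    list(atoms = atoms,
         chains = data.frame(chain_id = chain_id, kind = kind,
                             first = first, end = end,
                             stringsAsFactors = FALSE)),
    class = "oligotraj_topology")
}

#' @export
print.oligotraj_topology <- function(x, ...) {
  cat(sprintf("<topology: %d atoms, %d peptide chain(s), %d lipid chain(s)>\n",
              nrow(x$atoms), n_peptides(x), n_lipids(x)))
  invisible(x)
}

#' Number of peptide / lipid chains in a topology
#' @param top An `oligotraj_topology`.
#' @return Integer count.
#' @export
n_peptides <- function(top) sum(top$chains$kind == "peptide")

#' @rdname n_peptides
#' @export
n_lipids <- function(top) sum(top$chains$kind == "lipid")

#' Atom indices of one chain
#' @param top An `oligotraj_topology`.
#' @param chain_id Chain label.
#' @return Integer vector of global atom indices.
#' @export
chain_atoms <- function(top, chain_id) {
  i <- match(chain_id, top$chains$chain_id)
  if (is.na(i)) stop("no such chain: ", chain_id)
  seq.int(top$chains$first[i], top$chains$end[i] - 1L)
}

#' Select atoms by chain kind, residue, atom name or element class
#'
#' @param top An `oligotraj_topology`.
#' @param kind Optional chain kind (`"peptide"` or `"lipid"`).
#' @param chains Optional chain ids.
#' @param resnames Optional residue names.
#' @param residues Optional residue numbers (1-based within chain).
#' @param names Optional atom names.
#' @param regions Optional lipid region labels.
#' @param backbone If `TRUE`, restrict to peptide backbone atoms.
#' @param heavy_only If `TRUE`, drop hydrogens.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(top, kind = NULL, chains = NULL, resnames = NULL,
                         residues = NULL, names = NULL, regions = NULL,
                         backbone = FALSE, heavy_only = FALSE) {
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(kind)) {
    ck <- rep(top$chains$kind, top$chains$end - top$chains$first)
    keep <- keep & ck %in% kind
  }
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  if (!is.null(resnames)) keep <- keep & a$resname %in% toupper(resnames)
  if (!is.null(residues)) keep <- keep & a$resid %in% residues
  if (!is.null(names)) keep <- keep & a$name %in% names
  if (!is.null(regions)) keep <- keep & !is.na(a$region) & a$region %in% regions
  if (backbone) keep <- keep & a$backbone
  if (heavy_only) keep <- keep & .element_of(a$name) != "H"
  which(keep)
}

#' Construct a trajectory frame
#'
#' @param coordinates Numeric n x 3 matrix, nm.
#' @param box Orthorhombic box edge lengths, nm (length 3). Triclinic boxes
#'   are rejected.
#' @param time Frame time, ns.
#' @return An `oligotraj_frame`.
#' @export
frame <- function(coordinates, box, time = 0) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3) stop("coordinates must be n x 3")
  if (length(box) != 3) {
    stop("box must be three orthorhombic edge lengths; ",
         "triclinic boxes are not supported")
  }
  if (any(box <= 0)) stop("box edges must be > 0")
  structure(list(coordinates = coordinates, box = as.numeric(box),
                 time = as.numeric(time)),
            class = "oligotraj_frame")
}

#' Assemble a system from a topology and frames
#'
#' @param topology An `oligotraj_topology`.
#' @param frames List of `oligotraj_frame` objects with strictly increasing
#'   times and coordinate counts matching the topology.
#' @return An `oligotraj_system`.
#' @export
system_of <- function(topology, frames) {
  stopifnot(inherits(topology, "oligotraj_topology"), length(frames) >= 1)
  n_atoms <- nrow(topology$atoms)
  for (f in frames) {
    if (nrow(f$coordinates) != n_atoms) {
      stop(sprintf("atom-count mismatch: topology has %d atoms, frame has %d",
                   n_atoms, nrow(f$coordinates)))
    }
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(topology = topology, frames = frames),
            class = "oligotraj_system")
}

#' @export
print.oligotraj_system <- function(x, ...) {
  times <- frame_times(x)
  cat(sprintf(
    "<system: %d atoms, %d peptides, %d lipids, %d frames (%.3g-%.3g ns)>\n",
    nrow(x$topology$atoms), n_peptides(x$topology), n_lipids(x$topology),
    length(x$frames), min(times), max(times)))
  invisible(x)
}

#' Frame times of a system
#' @param system An `oligotraj_system`.
#' @return Numeric vector, ns.
#' @export
frame_times <- function(system) {
  vapply(system$frames, `[[`, numeric(1), "time")
}

# ---------------------------------------------------------------------------
# Minimum image and unwrapping

#' Minimum-image distance between two points in an orthorhombic box
#'
#' @param p,q Numeric length-3 coordinates, nm.
#' @param box Orthorhombic box edge lengths, nm.
#' @return Distance in nm: the minimum over all periodic images.
#' @export
#' @examples
#' minimum_image_distance(c(0.2, 0, 0), c(9.9, 0, 0), c(10, 10, 10)) # 0.3
minimum_image_distance <- function(p, q, box) {
  if (any(box <= 0)) stop("box edges must be > 0")
  d <- p - q
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# Vectorized minimum-image pairwise distance matrix between coordinate sets
# A (n x 3) and B (m x 3). Internal workhorse for contacts and mindist.
.min_image_cross <- function(A, B, box) {
  n <- nrow(A); m <- nrow(B)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Unwrap a molecule across periodic boundaries
#'
#' Makes a molecule whole in every frame by walking its atoms in order and
#' choosing, for each atom, the periodic image closest to its predecessor.
#' Assumes consecutively listed atoms are bonded (true for the bead-chain
#' topologies this package generates and for typical MD atom orders).
#'
#' @param system An `oligotraj_system`.
#' @param chain_id Chain to unwrap.
#' @return A new system with the chain whole in every frame; the chain
#'   centroid may lie outside the primary cell.
#' @export
unwrap_molecule <- function(system, chain_id) {
  idx <- chain_atoms(system$topology, chain_id)
  for (fi in seq_along(system$frames)) {
    x <- system$frames[[fi]]$coordinates
    box <- system$frames[[fi]]$box
    xm <- x[idx, , drop = FALSE]
    if (nrow(xm) > 1) {
      for (k in 2:nrow(xm)) {
        d <- xm[k, ] - xm[k - 1, ]
        xm[k, ] <- xm[k, ] - box * round(d / box)
      }
    }
    ext <- apply(xm, 2, function(v) diff(range(v)))
    if (any(ext > box / 2)) {
      stop(sprintf("chain %s spans more than half the box after unwrapping",
                   chain_id))
    }
    x[idx, ] <- xm
    system$frames[[fi]]$coordinates <- x
  }
  system
}

#' Unwrap every chain of a system
#' @param system An `oligotraj_system`.
#' @return System with all chains whole.
#' @export
unwrap_all <- function(system) {
  for (cid in system$topology$chains$chain_id) {
    system <- unwrap_molecule(system, cid)
  }
  system
}

# ---------------------------------------------------------------------------
# Test-dialect IO (plain-text topology + trajectory, oracle-checkable)

#' Write a system in the plain-text test dialect
#'
#' The test dialect is a pair of text files: a JSON topology (chains with
#' per-atom name, mass, radius, residue number and name) and a trajectory of
#' whitespace-separated frames (`frame <time> <bx> <by> <bz>` followed by
#' one `x y z` row per atom). Numbers are written with 17 significant
#' digits, so load -> write -> load round-trips exactly.
#'
#' @param system An `oligotraj_system`.
#' @param topology_path,trajectory_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_system <- function(system, topology_path, trajectory_path) {
  top <- system$topology
  chains <- lapply(seq_len(nrow(top$chains)), function(i) {
    idx <- seq.int(top$chains$first[i], top$chains$end[i] - 1L)
    a <- top$atoms[idx, , drop = FALSE]
    list(chain_id = top$chains$chain_id[i],
         atoms = lapply(seq_len(nrow(a)), function(j) {
           list(name = a$name[j], mass = a$mass[j], radius = a$radius[j],
                resid = a$resid[j], resname = a$resname[j])
         }))
  })
  jsonlite::write_json(
    list(format = "oligotraj-topology", version = 1L, chains = chains),
    topology_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  con <- file(trajectory_path, "w")
  on.exit(close(con))
  writeLines(sprintf("oligotraj-trajectory 1 natoms %d", nrow(top$atoms)),
             con)
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  for (f in system$frames) {
    writeLines(paste("frame", fmt(f$time), paste(fmt(f$box), collapse = " ")),
               con)
    writeLines(paste(fmt(f$coordinates[, 1]), fmt(f$coordinates[, 2]),
                     fmt(f$coordinates[, 3])), con)
  }
  invisible(c(topology_path, trajectory_path))
}

.read_test_topology <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(j$format, "oligotraj-topology")) {
    stop("not an oligotraj test-dialect topology: ", path)
  }
  rows <- do.call(rbind, lapply(j$chains, function(ch) {
    do.call(rbind, lapply(ch$atoms, function(a) {
      data.frame(name = a$name, chain = ch$chain_id, resid = a$resid,
                 resname = a$resname, mass = a$mass, radius = a$radius,
                 stringsAsFactors = FALSE)
    }))
  }))
  topology(rows)
}

.read_test_trajectory <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE)
  if (length(tok) < 4 || tok[1] != "oligotraj-trajectory") {
    stop("not an oligotraj test-dialect trajectory: ", path)
  }
  n_atoms <- as.integer(tok[4])
  pos <- 5L
  frames <- list()
  while (pos <= length(tok)) {
    if (tok[pos] != "frame") stop("malformed trajectory near token ", pos)
    hdr <- as.numeric(tok[pos + 1:4])
    pos <- pos + 5L
    need <- 3L * n_atoms
    if (pos + need - 1L > length(tok)) {
      stop("truncated trajectory frame in ", path)
    }
    xyz <- matrix(as.numeric(tok[pos:(pos + need - 1L)]), ncol = 3,
                  byrow = TRUE)
    pos <- pos + need
    frames[[length(frames) + 1L]] <- frame(xyz, hdr[2:4], hdr[1])
  }
  frames
}

# ---------------------------------------------------------------------------
# Standard-dialect readers (PDB/GRO topologies, DCD trajectories)

.read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  boxline <- strsplit(trimws(lines[3 + n]), "\\s+")[[1]]
  if (length(boxline) > 3 && any(as.numeric(boxline[-(1:3)]) != 0)) {
    stop("triclinic boxes are not supported")
  }
  box <- as.numeric(boxline[1:3])
  resname <- toupper(trimws(substr(body, 6, 10)))
  name <- trimws(substr(body, 11, 15))
  x <- as.numeric(substr(body, 21, 28))
  y <- as.numeric(substr(body, 29, 36))
  z <- as.numeric(substr(body, 37, 44))
  resno <- as.integer(substr(body, 1, 5))
  # chains: contiguous residue runs; a new chain starts when the residue
  # number does not increase or the molecule type changes
  new_res <- c(TRUE, resno[-1] != resno[-n])
  is_lip <- resname == "POPC"
  new_chain <- c(TRUE, (resno[-1] < resno[-n]) | (is_lip[-1] != is_lip[-n]) |
                   (is_lip[-1] & new_res[-1]))
  chain <- paste0(ifelse(is_lip, "L", "P"), cumsum(new_chain))
  resid <- stats::ave(as.numeric(new_res), chain, FUN = cumsum)
  atoms <- data.frame(name = name, chain = chain, resid = as.integer(resid),
                      resname = resname, stringsAsFactors = FALSE)
  list(topology = topology(atoms), coords = cbind(x, y, z), box = box)
}

.read_pdb_topology <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  resname <- toupper(a$resid)
  new_res <- c(TRUE, a$resno[-1] != a$resno[-nrow(a)] |
                 chain[-1] != chain[-nrow(a)])
  resid <- stats::ave(as.numeric(new_res), chain, FUN = cumsum)
  atoms <- data.frame(name = a$elety, chain = chain,
                      resid = as.integer(resid), resname = resname,
                      stringsAsFactors = FALSE)
  list(topology = topology(atoms), coords = matrix(c(a$x, a$y, a$z),
                                                   ncol = 3) / 10)
}

#' Load a system from topology and trajectory files
#'
#' In the `test-dialect`, the topology is the package's JSON text format and
#' the trajectory its plain-text frame format (see [write_system()]). In the
#' `standard` dialect, the topology may be a GRO or PDB file and the
#' trajectory a DCD file (read via bio3d; lengths converted to nm assuming
#' DCD coordinates in Angstrom) or the plain-text trajectory format.
#'
#' @param topology_path,trajectory_path Input files. `trajectory_path` may
#'   be `NULL` in the standard dialect, in which case the single
#'   coordinate set in the topology file becomes one frame at t = 0 (GRO
#'   only; requires the GRO box).
#' @param dialect `"test-dialect"` or `"standard"`.
#' @param box Optional box edge lengths, nm; required for trajectory formats
#'   that do not store the box (DCD written without unit cell, PDB).
#' @return An `oligotraj_system`.
#' @export
load_system <- function(topology_path, trajectory_path = NULL,
                        dialect = c("test-dialect", "standard"),
                        box = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(topology_path)) stop("no such file: ", topology_path)
  if (dialect == "test-dialect") {
    top <- .read_test_topology(topology_path)
    frames <- .read_test_trajectory(trajectory_path)
  } else {
    ext <- tolower(tools::file_ext(topology_path))
    parsed <- switch(ext,
      gro = .read_gro(topology_path),
      pdb = .read_pdb_topology(topology_path),
      stop("unsupported topology format: .", ext))
    top <- parsed$topology
    if (is.null(trajectory_path)) {
      if (is.null(parsed$box) && is.null(box)) {
        stop("box required when the topology carries no box")
      }
      frames <- list(frame(parsed$coords,
                           if (is.null(box)) parsed$box else box, 0))
    } else {
      text <- tolower(tools::file_ext(trajectory_path))
      if (text == "dcd") {
        xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
        if (is.null(box)) stop("box required for DCD trajectories")
        frames <- lapply(seq_len(nrow(xyz)), function(i) {
          frame(matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10, box,
                time = i - 1)
        })
      } else {
        frames <- .read_test_trajectory(trajectory_path)
      }
    }
  }
  n_top <- nrow(top$atoms)
  n_trj <- nrow(frames[[1]]$coordinates)
  if (n_top != n_trj) {
    stop(sprintf(
      "atom-count mismatch: topology has %d atoms, trajectory has %d",
      n_top, n_trj))
  }
  system_of(top, frames)
}
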