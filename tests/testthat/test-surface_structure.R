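iso_atom <- function(radius = 0.16) {
  top <- topology(data.frame(name = "CA", chain = "P1", resid = 1L,
                             resname = "GLY", mass = 12, radius = radius))
  list(topology = top, frame = frame(matrix(c(5, 5, 5), 1), c(10, 10, 10)))
}

test_that("isolated-atom SASA matches the analytic sphere", {
  a <- iso_atom(0.16)
  rec <- shrake_rupley_sasa(a$frame, a$topology, probe = 0.14,
                            n_points = 960)
  expect_equal(rec$atom_area, 4 * pi * 0.30^2, tolerance = 1e-9)
  # quadrature converges with point count on a two-sphere problem
  top2 <- topology(data.frame(name = c("CA", "CA"), chain = "P1",
                              resid = 1:2, resname = "GLY", mass = 12,
                              radius = 0.16))
  f2 <- frame(rbind(c(5, 5, 5), c(5.35, 5, 5)), c(10, 10, 10))
  truth <- two_sphere_accessible(0.30, 0.30, 0.35)
  errs <- vapply(c(96, 960, 9600), function(np) {
    rec <- shrake_rupley_sasa(f2, top2, n_points = np)
    abs(rec$atom_area[1] - truth) / truth
  }, numeric(1))
  expect_lt(errs[2], 0.02)
  expect_lt(errs[3], errs[1])  # finer quadrature is more accurate
})

test_that("fully enclosed atoms have zero SASA", {
  top <- topology(data.frame(name = c("CA", "CA"), chain = "P1",
                             resid = 1:2, resname = "GLY", mass = 12,
                             radius = c(0.05, 1.0)))
  f <- frame(rbind(c(5, 5, 5), c(5.1, 5, 5)), c(10, 10, 10))
  rec <- shrake_rupley_sasa(f, top)
  expect_equal(rec$atom_area[1], 0)
})

test_that("SASA is invariant under rigid rotation", {
  set.seed(141)
  n <- 20
  top <- topology(data.frame(name = "CA", chain = "P1", resid = seq_len(n),
                             resname = "GLY", mass = 12,
                             radius = runif(n, 0.12, 0.18)))
  x <- matrix(rnorm(3 * n, 0, 0.3), n, 3) + 5
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  a1 <- sum(shrake_rupley_sasa(frame(x, c(10, 10, 10)), top)$atom_area)
  xr <- sweep(sweep(x, 2, c(5, 5, 5)) %*% R, 2, c(5, 5, 5), "+")
  a2 <- sum(shrake_rupley_sasa(frame(xr, c(10, 10, 10)), top)$atom_area)
  expect_equal(a1, a2, tolerance = 0.005)
})

test_that("hydrophobic SASA uses the canonical residue set", {
  # full-length peptide, residues far apart so every residue is exposed
  seq3 <- ab42_sequence("three")
  top <- topology(data.frame(name = "CA", chain = "P1", resid = 1:42,
                             resname = seq3, mass = 12, radius = 0.17))
  f <- frame(cbind(seq(1, by = 1.5, length.out = 42), 5, 5),
             c(100, 100, 100))
  rec <- shrake_rupley_sasa(f, top, n_points = 96)
  hyd <- hydrophobic_sasa(rec)
  per_res <- 4 * pi * (0.17 + 0.14)^2
  hydro_set <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE")
  n_hydro <- sum(seq3 %in% hydro_set)
  expect_equal(n_hydro, 19)  # A2,A21,A30,A42,V12,V18,V24,V36,V39,V40,
                             # L17,L34,I31,I32,I41,M35,F4,F19,F20
  expect_equal(hyd$hydrophobic_area, n_hydro * per_res, tolerance = 0.01)
  # linearity: doubling all residue areas doubles the hydrophobic total
  rec2 <- rec
  rec2$residue$area <- rec$residue$area * 2
  expect_equal(hydrophobic_sasa(rec2)$hydrophobic_area,
               2 * hyd$hydrophobic_area)
  # a peptide with no hydrophobic residues scores zero
  topg <- topology(data.frame(name = "CA", chain = "P1", resid = 1:3,
                              resname = "GLY", mass = 12, radius = 0.17))
  recg <- shrake_rupley_sasa(frame(cbind(1:3, 5, 5), c(50, 50, 50)), topg,
                             n_points = 96)
  expect_equal(hydrophobic_sasa(recg)$hydrophobic_area, 0)
})

test_that("normalized solvent contact is comparable across molecules", {
  # identical molecules get identical values
  top <- topology(data.frame(
    name = "CA", chain = rep(c("P1", "P2"), each = 2), resid = rep(1:2, 2),
    resname = "GLY", mass = 12, radius = 0.17))
  f <- frame(rbind(c(2, 5, 5), c(2.4, 5, 5), c(8, 5, 5), c(8.4, 5, 5)),
             c(20, 20, 20))
  nsc <- normalized_solvent_contact(shrake_rupley_sasa(f, top))
  expect_equal(nsc$normalized_contact[1], nsc$normalized_contact[2],
               tolerance = 1e-9)
  # a buried molecule scores below an exposed one
  top2 <- topology(data.frame(
    name = c("CA", rep("CA", 13)), chain = c("P1", rep("P2", 13)),
    resid = c(1L, seq_len(13)), resname = "GLY", mass = 12,
    radius = c(0.17, 0.6, rep(0.25, 12))))
  shell <- rbind(c(10, 5, 5),                  # exposed P1
                 c(5, 5, 5),                   # P2 core
                 c(5.55, 5, 5), c(4.45, 5, 5), # P2 shell around core
                 c(5, 5.55, 5), c(5, 4.45, 5),
                 c(5, 5, 5.55), c(5, 5, 4.45),
                 c(5.4, 5.4, 5.4), c(4.6, 4.6, 4.6),
                 c(5.4, 4.6, 5.4), c(4.6, 5.4, 4.6),
                 c(5.4, 5.4, 4.6), c(4.6, 4.6, 5.4))
  nsc2 <- normalized_solvent_contact(
    shrake_rupley_sasa(frame(shell, c(20, 20, 20)), top2))
  # normalized exposure: buried-core molecule < free single atom
  p1 <- nsc2$normalized_contact[nsc2$chain_id == "P1"]
  p2 <- nsc2$normalized_contact[nsc2$chain_id == "P2"]
  expect_lt(p2, p1)
})

test_that("DSSP simplification and content summaries", {
  expect_identical(simplify_dssp(c("H", "G", "I")), rep("helix", 3))
  expect_identical(simplify_dssp(c("E", "B")), rep("strand", 2))
  expect_identical(simplify_dssp(c("T", "S", "C", " ")), rep("coil", 4))
  expect_error(simplify_dssp("X"), "unknown DSSP")

  # all-coil table
  tab <- matrix("C", 10, 6)
  sc <- ss_content_summary(tab)
  expect_equal(sc$system$percent[sc$system$class == "coil"], 100)
  # strand block at residues 3-5 in every frame
  tab2 <- matrix("C", 8, 6)
  tab2[, 3:5] <- "E"
  sc2 <- ss_content_summary(tab2)
  expect_equal(sc2$per_residue$strand, c(0, 0, 1, 1, 1, 0))
  expect_equal(rowSums(sc2$per_residue[, c("helix", "strand", "coil")]),
               rep(1, 6))
  # replicate sd
  sc3 <- ss_content_summary(list(tab, tab2))
  expect_false(anyNA(sc3$system$sd))

  # ragged text grids are fatal
  p <- tempfile()
  writeLines(c("CCCC", "CCC"), p)
  expect_error(read_dssp_grid(p), "ragged")
  writeLines(c("CHEB", "HHEE"), p)
  g <- read_dssp_grid(p)
  expect_identical(dim(g), c(2L, 4L))
})
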