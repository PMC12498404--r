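test_that("minimum-image distance matches 27-image brute force", {
  expect_equal(minimum_image_distance(c(1, 2, 3), c(1, 2, 3), c(5, 5, 5)), 0)
  expect_equal(
    minimum_image_distance(c(0.2, 0, 0), c(9.9, 0, 0), c(10, 10, 10)), 0.3)
  set.seed(11)
  for (k in 1:1000) {
    box <- runif(3, 1, 20)
    p <- runif(3) * box   # inside the primary cell, where the 27-image
    q <- runif(3) * box   # enumeration is an exact oracle

    d <- minimum_image_distance(p, q, box)
    expect_equal(d, brute27_distance(p, q, box), tolerance = 1e-12)
    expect_equal(d, minimum_image_distance(q, p, box))
    expect_lte(d, sqrt(sum((box / 2)^2)) + 1e-12)
  }
})

test_that("unwrapping makes molecules whole across boundaries", {
  top <- topology(data.frame(name = "CA", chain = "P1", resid = 1:2,
                             resname = "GLY"))
  # split across the x boundary: images chosen 0.2 nm apart
  f <- frame(rbind(c(0.1, 5, 5), c(9.9, 5, 5)), c(10, 10, 10))
  sys <- system_of(top, list(f))
  un <- unwrap_molecule(sys, "P1")
  d <- un$frames[[1]]$coordinates[1, ] - un$frames[[1]]$coordinates[2, ]
  expect_equal(sqrt(sum(d^2)), 0.2, tolerance = 1e-12)

  # already-whole molecule is untouched
  f2 <- frame(rbind(c(5, 5, 5), c(5.3, 5, 5)), c(10, 10, 10))
  sys2 <- system_of(top, list(f2))
  expect_identical(unwrap_molecule(sys2, "P1")$frames[[1]]$coordinates,
                   f2$coordinates)

  # randomized wraps of a 5-bead chain: consecutive displacements < L/2
  top5 <- topology(data.frame(name = "CA", chain = "P1", resid = 1:5,
                              resname = "GLY"))
  set.seed(21)
  for (k in 1:50) {
    box <- c(8, 8, 8)
    base <- matrix(cumsum(c(7.8, runif(4, 0.2, 0.4))), ncol = 1)
    xyz <- cbind(as.numeric(base), runif(1, 0, 8), runif(1, 0, 8))
    wrapped <- xyz - floor(xyz / 8) * 8
    sysk <- system_of(top5, list(frame(wrapped, box)))
    unk <- unwrap_molecule(sysk, "P1")$frames[[1]]$coordinates
    steps <- abs(diff(unk))
    expect_true(all(steps < 4))
  }
})

test_that("POPC region labels are a total partition with correct anchors", {
  expect_identical(label_lipid_regions("POPC", "P"), "phosphate")
  expect_identical(label_lipid_regions("POPC", "N"), "choline")
  expect_identical(label_lipid_regions("POPC", "C218"), "tail")
  expect_identical(label_lipid_regions("POPC", "C316"), "tail")
  expect_identical(label_lipid_regions("POPC", "C1"), "glycerol")
  expect_error(label_lipid_regions("POPC", "XX9"), "unknown POPC atom")
  expect_error(label_lipid_regions("DPPC", "P"), "unsupported lipid")
  tab <- popc_region_table()
  expect_equal(anyDuplicated(tab$atom), 0)
  expect_setequal(unique(tab$region),
                  c("choline", "phosphate", "glycerol", "tail"))
  # full POPC topology gets complete region coverage
  lip <- topology(data.frame(name = tab$atom, chain = "L1", resid = 1L,
                             resname = "POPC"))
  expect_false(anyNA(lip$atoms$region))
  expect_identical(lip$chains$kind, "lipid")
})

test_that("test-dialect IO round-trips and validates atom counts", {
  top <- topology(data.frame(
    name = rep("CA", 4), chain = rep(c("P1", "P2"), each = 2),
    resid = rep(1:2, 2), resname = "ALA"))
  frames <- lapply(0:2, function(t) {
    frame(matrix(runif(12, 0, 9), 4, 3), c(10, 10, 10), t)
  })
  sys <- system_of(top, frames)
  tp <- tempfile(fileext = ".json"); tj <- tempfile(fileext = ".trj")
  write_system(sys, tp, tj)
  s2 <- load_system(tp, tj)
  expect_equal(n_peptides(s2$topology), 2)
  expect_length(s2$frames, 3)
  expect_equal(lapply(s2$frames, `[[`, "coordinates"),
               lapply(sys$frames, function(f) unname(f$coordinates)))
  # second round trip is bit-identical on disk
  tp2 <- tempfile(); tj2 <- tempfile()
  write_system(s2, tp2, tj2)
  expect_identical(readLines(tj), readLines(tj2))
  expect_identical(readLines(tp), readLines(tp2))

  # atom-count mismatch reports both counts
  bad <- topology(data.frame(name = rep("CA", 5),
                             chain = paste0("P", 1:5), resid = 1L,
                             resname = "ALA"))
  tb <- tempfile()
  write_system(system_of(bad, list(frame(matrix(0, 5, 3), c(5, 5, 5)))),
               tb, tempfile())
  expect_error(load_system(tb, tj), "atom-count mismatch.*5.*4")
})

test_that("unknown residue names and triclinic boxes are rejected", {
  expect_error(topology(data.frame(name = "CA", chain = "A", resid = 1,
                                   resname = "XYZ")), "XYZ")
  expect_error(frame(matrix(0, 1, 3), c(10, 10, 10, 1, 0, 0)),
               "triclinic")
})

test_that("GRO topologies load with inferred lipid chains", {
  gro <- c(
    "toy system", " 6",
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "ALA", "N", 1, 1.0, 1.0, 1.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "ALA", "CA", 2, 1.1, 1.0, 1.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 2, "GLY", "CA", 3, 1.3, 1.0, 1.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 3, "POPC", "P", 4, 3.0, 3.0, 3.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 3, "POPC", "N", 5, 3.2, 3.0, 3.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 3, "POPC", "C1", 6, 3.4, 3.0, 3.0),
    "   5.00000   5.00000   5.00000")
  path <- tempfile(fileext = ".gro")
  writeLines(gro, path)
  sys <- load_system(path, dialect = "standard")
  expect_equal(n_peptides(sys$topology), 1)
  expect_equal(n_lipids(sys$topology), 1)
  expect_equal(sys$frames[[1]]$box, c(5, 5, 5))
  expect_equal(unname(sys$frames[[1]]$coordinates[1, ]), c(1, 1, 1))
  expect_identical(
    sys$topology$atoms$region[sys$topology$atoms$name == "P"], "phosphate")
})
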