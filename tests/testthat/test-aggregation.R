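test_that("peptide minimum-distance matrices match brute-force geometry", {
  # single-bead peptides at hand-computed positions (box too large to wrap)
  toy <- bead_peptides(c(0, 0.5, 1.2))
  dmat <- peptide_min_distance_matrix(toy$frame, toy$topology)
  expect_equal(dmat[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(dmat[2, 3], 0.7, tolerance = 1e-12)
  expect_equal(dmat[1, 3], 1.2, tolerance = 1e-12)
  expect_equal(diag(dmat), rep(0, 3))

  # coincident peptides
  co <- bead_peptides(c(1, 1))
  expect_equal(peptide_min_distance_matrix(co$frame, co$topology)[1, 2], 0)

  # random multi-atom frames vs all-pairs brute force over images
  set.seed(31)
  top <- topology(data.frame(
    name = "CA", chain = rep(paste0("P", 1:4), each = 3),
    resid = rep(1:3, 4), resname = "GLY"))
  for (k in 1:20) {
    box <- runif(3, 2, 6)
    f <- frame(matrix(runif(36, 0, 6), 12, 3), box)
    dmat <- peptide_min_distance_matrix(f, top)
    for (i in 1:3) for (j in (i + 1):4) {
      ref <- Inf
      wrap <- function(x) x - floor(x / box) * box  # into the primary cell
      for (ai in ((i - 1) * 3 + 1):(i * 3)) {
        for (aj in ((j - 1) * 3 + 1):(j * 3)) {
          ref <- min(ref, brute27_distance(wrap(f$coordinates[ai, ]),
                                           wrap(f$coordinates[aj, ]), box))
        }
      }
      expect_equal(dmat[i, j], ref, tolerance = 1e-12)
    }
  }
})

test_that("N-mer partitions equal a BFS oracle and are transitive", {
  # transitive connectivity: A-B, B-C close, A-C far -> one trimer
  d <- matrix(c(0, 0.5, 1.2, 0.5, 0, 0.5, 1.2, 0.5, 0), 3, 3)
  expect_identical(nmer_partition(d, 0.6), list(1:3))

  # all pairs at the cutoff (strict inequality) -> singletons
  d2 <- matrix(0.6, 3, 3); diag(d2) <- 0
  expect_identical(nmer_partition(d2, 0.6), list(1L, 2L, 3L))

  set.seed(41)
  for (k in 1:200) {
    d <- matrix(runif(100, 0, 1.5), 10, 10)
    d <- (d + t(d)) / 2; diag(d) <- 0
    parts <- nmer_partition(d, 0.6)
    adj <- d < 0.6; diag(adj) <- FALSE
    expect_identical(parts, bfs_partition(adj))
  }
})

test_that("raising the cutoff never splits a component", {
  set.seed(51)
  for (k in 1:30) {
    d <- matrix(runif(64, 0, 1.5), 8, 8)
    d <- (d + t(d)) / 2; diag(d) <- 0
    lo <- nmer_partition(d, 0.4)
    hi <- nmer_partition(d, 0.9)
    for (comp in lo) {
      host <- vapply(hi, function(h) all(comp %in% h), logical(1))
      expect_equal(sum(host), 1)  # each low-cutoff component nests intact
    }
  }
})

test_that("population tables conserve peptide count and track schedules", {
  sch <- demo_schedule()
  tr <- make_aggregation_trajectory(6, sch, n_frames = 80, seed = 2)
  tl <- aggregation_timeline(tr$system)
  pop <- nmer_population_timeseries(tl)
  expect_true(all(tapply(pop$size * pop$count, pop$time, sum) == 6))
  # schedule-implied populations: two dimers + two monomers at 25 ns
  at25 <- pop[pop$time == 25, ]
  expect_identical(at25$count[order(at25$size)], c(2L, 2L))
  expect_identical(sort(at25$size), c(1L, 2L))
  expect_identical(pop$size[pop$time == 60], 6L)
  # all-singleton start
  expect_identical(pop$count[pop$time == 0], 6L)
})

test_that("aggregation time handles immediate, blipped and absent cases", {
  sch0 <- merge_schedule(events = list(list(time = 0, pair = c(1, 2))),
                         n_peptides = 2)
  tr0 <- make_aggregation_trajectory(2, sch0, n_frames = 10, seed = 1)
  tl0 <- aggregation_timeline(tr0$system)
  expect_equal(aggregation_time(tl0), 0)

  # full hexamer from 50 ns with one 0.5 ns blip at 70 ns, tolerance 1 ns
  schb <- merge_schedule(
    events = demo_schedule()$events,
    blips = list(list(time = 70, duration = 0.5, split = 6)),
    n_peptides = 6)
  trb <- make_aggregation_trajectory(6, schb, dt = 0.5, n_frames = 200,
                                     seed = 3)
  tlb <- aggregation_timeline(trb$system)
  expect_equal(aggregation_time(tlb, dwell_tolerance = 1), 50)
  # without bridging the blip pushes the stable point past 70 ns
  expect_gt(aggregation_time(tlb, dwell_tolerance = 1e-9), 70)

  # never fully aggregated
  schn <- merge_schedule(events = list(list(time = 5, pair = c(1, 2))),
                         n_peptides = 3)
  trn <- make_aggregation_trajectory(3, schn, n_frames = 20, seed = 4)
  expect_true(is.na(aggregation_time(aggregation_timeline(trn$system))))

  # detector reproduces the planted timeline frame-for-frame
  expect_true(all(mapply(identical, tlb$partitions,
                         trb$truth$partition_timeline)))
  expect_equal(aggregation_time(tlb, 1), trb$truth$aggregation_time)
})

test_that("group minimum-distance series and convergence behave", {
  top <- topology(data.frame(
    name = "CA", chain = c("P1", "P2"), resid = 1L, resname = "GLY"))
  # scripted approach: distance decreases 2.0 -> 0.2 then stays
  dists <- c(2, 1.5, 1, 0.6, 0.3, 0.2, 0.2, 0.2)
  frames <- lapply(seq_along(dists), function(i) {
    frame(rbind(c(5, 5, 5), c(5 + dists[i], 5, 5)), c(20, 20, 20), i - 1)
  })
  sys <- system_of(top, frames)
  ser <- group_min_distance_timeseries(sys, 1L, 2L, "A", "B")
  expect_equal(ser$min_distance, dists, tolerance = 1e-12)
  expect_true(all(diff(ser$min_distance) <= 0))
  expect_equal(convergence_time(ser, threshold = 0.4), 4)

  # overlapping groups in space give distance zero
  f0 <- frame(rbind(c(5, 5, 5), c(5, 5, 5)), c(20, 20, 20), 0)
  sys0 <- system_of(top, list(f0))
  expect_equal(
    group_min_distance_timeseries(sys0, 1L, 2L)$min_distance, 0)

  expect_error(group_min_distance_timeseries(sys, integer(0), 2L, "empty"),
               "empty")
  expect_error(group_min_distance_timeseries(sys, 1L, 1L), "disjoint")
})
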