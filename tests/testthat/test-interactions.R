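# Two-peptide fixture where residue 1 of P1 contacts residue 1 of P2 in a
# chosen fraction of frames, at a chosen contact distance.
contact_fixture <- function(contact_frames, n_frames, contact_d = 0.3,
                            apart_d = 2) {
  top <- topology(data.frame(
    name = "CA", chain = rep(c("P1", "P2"), each = 2),
    resid = rep(1:2, 2), resname = "GLY"))
  frames <- lapply(seq_len(n_frames), function(i) {
    d <- if (i %in% contact_frames) contact_d else apart_d
    frame(rbind(c(5, 5, 5), c(5, 6, 5),          # P1 res 1, 2
                c(5 + d, 5, 5), c(5 + d, 7, 5)), # P2 res 1, 2 (res 2 offset)
          c(20, 20, 20), i - 1)
  })
  system_of(top, frames)
}

test_that("residue contact statistics count pairs, frames and distances", {
  sys <- contact_fixture(1:5, 10, contact_d = 0.3)
  st <- residue_contact_stats(sys, cutoff = 0.6)
  r11 <- st[st$res_i == 1 & st$res_j == 1, ]
  expect_equal(r11$n_pairs_observed, 1)
  expect_equal(r11$n_pairs_possible, 1)
  expect_equal(r11$mean_frame_fraction, 0.5)
  expect_equal(r11$mean_contact_distance, 0.3, tolerance = 1e-12)
  # residue 2 sits 1 nm off-axis: contact distance sqrt(d^2+1) > 0.6 always
  r22 <- st[st$res_i == 2 & st$res_j == 2, ]
  expect_equal(r22$n_pairs_observed, 0)
  expect_equal(r22$mean_frame_fraction, 0)
  expect_equal(r22$mean_contact_distance, 0)  # convention: 0 when never

  # saturation: always in contact at 0.3
  sat <- contact_fixture(1:10, 10, contact_d = 0.3)
  st2 <- residue_contact_stats(sat, cutoff = 0.6)
  s11 <- st2[st2$res_i == 1 & st2$res_j == 1, ]
  expect_equal(s11$mean_frame_fraction, 1)
})

test_that("interaction frequency implements the multiplicative weighting", {
  # hand case: half of pairs, frame fraction 0.5, distance half the cutoff
  st <- data.frame(res_i = 1, res_j = 2, n_pairs_possible = 2,
                   n_pairs_observed = 1, mean_frame_fraction = 0.5,
                   mean_contact_distance = 0.3)
  F <- interaction_frequency(st, cutoff = 0.6)
  expect_equal(F[1, 2], 0.125)
  expect_equal(F[2, 1], 0.125)  # symmetric

  # saturation limit -> 1; no contact -> 0
  st_sat <- data.frame(res_i = 1, res_j = 1, n_pairs_possible = 3,
                       n_pairs_observed = 3, mean_frame_fraction = 1,
                       mean_contact_distance = 0)
  expect_equal(interaction_frequency(st_sat, 0.6)[1, 1], 1)
  st_no <- data.frame(res_i = 1, res_j = 1, n_pairs_possible = 3,
                      n_pairs_observed = 0, mean_frame_fraction = 0,
                      mean_contact_distance = 0)
  expect_equal(interaction_frequency(st_no, 0.6)[1, 1], 0)
})

test_that("interaction frequency bounds and monotonicities hold", {
  set.seed(121)
  base <- function(n_obs, frac, dist) {
    data.frame(res_i = 1, res_j = 2, n_pairs_possible = 10,
               n_pairs_observed = n_obs, mean_frame_fraction = frac,
               mean_contact_distance = dist)
  }
  for (k in 1:200) {
    n_obs <- sample(0:10, 1)
    frac <- if (n_obs == 0) 0 else runif(1)
    dist <- if (n_obs == 0) 0 else runif(1, 0, 0.6)
    F <- interaction_frequency(base(n_obs, frac, dist), 0.6)[1, 2]
    expect_gte(F, 0); expect_lte(F, 1)
    if (n_obs > 0) {
      # monotone nondecreasing in pair count and frame fraction
      expect_gte(interaction_frequency(base(min(n_obs + 1, 10), frac, dist),
                                       0.6)[1, 2], F)
      expect_gte(interaction_frequency(base(n_obs, min(frac * 1.1, 1), dist),
                                       0.6)[1, 2], F)
      # monotone nonincreasing in mean contact distance
      expect_lte(interaction_frequency(base(n_obs, frac,
                                            min(dist * 1.1, 0.6)),
                                       0.6)[1, 2], F)
    }
  }
})

test_that("residue x residue maps from trajectories are symmetric", {
  sch <- demo_schedule()
  tr <- make_aggregation_trajectory(6, sch, n_frames = 30, seed = 6)
  st <- residue_contact_stats(tr$system, cutoff = 0.6)
  F <- interaction_frequency(st, cutoff = 0.6)
  expect_equal(unclass(F), t(unclass(F)), tolerance = 1e-12)
  expect_true(all(F >= 0 & F <= 1))
})

test_that("region interaction maps resolve lipid regions", {
  # one peptide residue permanently adjacent to the phosphate bead
  top <- topology(data.frame(
    name = c("CA", "CA", "N", "P", "C1", "C316"),
    chain = c("P1", "P1", "L1", "L1", "L1", "L1"),
    resid = c(1L, 2L, 1L, 1L, 1L, 1L),
    resname = c("ARG", "GLY", "POPC", "POPC", "POPC", "POPC")))
  frames <- lapply(1:5, function(i) {
    frame(rbind(c(5, 5, 5), c(5, 8, 5),       # residues 1, 2
                c(9, 9, 9),                   # choline far
                c(5.3, 5, 5),                 # phosphate close to residue 1
                c(9, 9, 5), c(9, 5, 9)),      # glycerol, tail far
          c(20, 20, 20), i - 1)
  })
  sys <- system_of(top, frames)
  M <- region_interaction_map(sys, cutoff = 0.6)
  expect_gt(M["1", "phosphate"], 0.4)
  expect_equal(M["1", "choline"], 0)
  expect_equal(M["2", "tail"], 0)
  expect_true(all(M >= 0 & M <= 1))

  # lipid-free systems are an error
  sch <- merge_schedule(events = list(), n_peptides = 2)
  nolip <- make_aggregation_trajectory(2, sch, n_frames = 3, seed = 1,
                                       n_lipids = 0)
  expect_error(region_interaction_map(nolip$system), "no lipids")
})

test_that("hydrogen-bond criterion classifies planted geometries exactly", {
  inside <- make_hbond_fixture(3.0, 0)
  expect_equal(nrow(detect_hbonds(inside$frame, inside$topology)), 1)
  at30 <- make_hbond_fixture(3.2, 30)   # threshold 2.904 A at 30 degrees
  expect_equal(nrow(detect_hbonds(at30$frame, at30$topology)), 0)
  far <- make_hbond_fixture(3.4, 0)     # threshold 3.3 A at 0 degrees
  expect_equal(nrow(detect_hbonds(far$frame, far$topology)), 0)

  # grid straddling the criterion curve r = 3.3 - 0.00044 theta^2
  set.seed(131)
  for (k in 1:100) {
    theta <- runif(1, 0, 80)
    thresh <- 3.3 - 0.00044 * theta^2
    delta <- sample(c(-1, 1), 1) * runif(1, 0.01, 0.3)
    r <- thresh + delta
    if (r <= 0.5) next
    fx <- make_hbond_fixture(r, theta)
    hb <- detect_hbonds(fx$frame, fx$topology)
    expect_equal(nrow(hb), as.integer(delta < 0))
    if (nrow(hb)) {
      expect_equal(hb$distance, r, tolerance = 1e-8)
      expect_equal(hb$angle, theta, tolerance = 1e-6)
    }
  }

  # hydrogens absent -> informative error
  toy <- bead_peptides(c(0, 1))
  expect_error(detect_hbonds(toy$frame, toy$topology), "hydrogens")
})

test_that("hydrogen-bond propensity attributes bonds to both residues", {
  fx <- make_hbond_fixture(2.9, 10)
  sys <- system_of(fx$topology, list(fx$frame))
  prop <- hbond_propensity(sys)
  expect_equal(prop$bonds_per_frame, c(1, 1))  # donor res 1, acceptor res 2
})
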