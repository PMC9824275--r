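# Toy NP-fibril systems: placement, rigid-body trajectories, study design

small_np <- function() {
  assemble_nanoparticle(replicate_chains(build_chain("PP", 8, seed = 1), 2,
                                         box = 5, seed = 2), seed = 3)
}
small_fibril <- function() make_synthetic_fibril_unit(seed = 1)

test_that("interaction_matrix validates its inputs", {
  expect_s3_class(interaction_matrix(), "interaction_matrix")
  expect_error(interaction_matrix(affinity = c(hydrophobic = -1)),
               class = "invalid_argument")
  expect_error(interaction_matrix(screening_length = 0),
               class = "invalid_argument")
})

test_that("residue-specific affinity keys override class values", {
  fib <- small_fibril()
  ints <- interaction_matrix(affinity = c(hydrophobic = 1, polar = 0.3,
                                          charged = 0.2, K16 = 9))
  eps <- npfibril:::resolve_affinities(ints, fib)
  b <- fib$beads
  expect_equal(unique(eps[b$resno == 16]), 9)            # K16 override
  expect_equal(unique(eps[b$resno == 17]), 1)            # L17 hydrophobic
  expect_equal(unique(eps[b$resno == 15]), 0.3)          # Q15 polar
  expect_equal(unique(eps[b$resno == 22]), 0.2)          # E22 charged
  bare <- fib; bare$beads$class <- NULL
  expect_error(npfibril:::resolve_affinities(ints, bare),
               class = "configuration_error")
})

test_that("random placement lands in the spacing window, deterministically", {
  fib <- small_fibril(); np <- small_np()
  cfg <- place_nanoparticle_random(fib, np, min_spacing = 3, box = 14, seed = 7)
  expect_s3_class(cfg, "np_system")
  expect_gt(cfg$initial_gap, 3)
  expect_lte(cfg$initial_gap, 4.5)
  cfg2 <- place_nanoparticle_random(fib, np, min_spacing = 3, box = 14, seed = 7)
  expect_identical(cfg$np$beads, cfg2$np$beads)
  expect_error(place_nanoparticle_random(fib, np, min_spacing = 12, box = 14),
               class = "placement_error")
})

test_that("biased placement reaches the requested face at the requested gap", {
  fib <- small_fibril(); np <- small_np()
  side <- place_nanoparticle_biased(fib, np, "side", gap = 1, box = 14, seed = 1)
  expect_equal(side$initial_gap, 1, tolerance = 0.01)
  cen <- colMeans(as.matrix(side$np$beads[, c("x", "y", "z")])) - 7
  expect_lt(abs(cen[3]), max(abs(cen[1:2])))  # displaced off the axis

  fro <- place_nanoparticle_biased(fib, np, "frontal", gap = 1, box = 14, seed = 1)
  cenf <- colMeans(as.matrix(fro$np$beads[, c("x", "y", "z")])) - 7
  expect_gt(abs(cenf[3]), max(abs(cenf[1:2])))  # displaced along the axis
})

test_that("targeted placement sits over the target patch", {
  fib <- small_fibril(); np <- small_np()
  cfg <- place_nanoparticle_biased(fib, np, "side", gap = 1, box = 14,
                                   seed = 2, target_resno = 16:20)
  b <- cfg$fibril$beads
  sel <- b$resno %in% 16:20 & b$protofilament == 1
  patch <- colMeans(as.matrix(b[sel, c("x", "y", "z")]))
  cen <- colMeans(as.matrix(cfg$np$beads[, c("x", "y", "z")]))
  # the NP centroid projects onto the patch along the strand and the axis
  expect_lt(abs(cen[1] - patch[1]), 0.5)
  expect_lt(abs(cen[3] - patch[3]), 0.5)
})

test_that("trajectories are deterministic and respect the box", {
  fib <- small_fibril(); np <- small_np()
  cfg <- place_nanoparticle_random(fib, np, min_spacing = 3, box = 14, seed = 4)
  ints <- interaction_matrix(electrostatics = FALSE)
  t1 <- simulate_toy_trajectory(cfg, ints, n_frames = 10, seed = 5)
  t2 <- simulate_toy_trajectory(cfg, ints, n_frames = 10, seed = 5)
  expect_identical(t1$np_coords, t2$np_coords)
  expect_length(t1$times, 10)
  expect_equal(t1$times[1], 0)
  # centroid of every frame stays inside the box after rewrap
  for (f in 1:10) {
    cen <- colMeans(t1$np_coords[, , f])
    expect_true(all(cen >= 0 & cen <= 14))
  }
  expect_error(simulate_toy_trajectory(cfg, ints, n_frames = 1),
               class = "invalid_argument")
})

test_that("with zero temperature and zero wells the NP does not move", {
  fib <- small_fibril(); np <- small_np()
  cfg <- place_nanoparticle_random(fib, np, min_spacing = 3, box = 14, seed = 4)
  ints <- interaction_matrix(affinity = c(hydrophobic = 0, polar = 0,
                                          charged = 0),
                             electrostatics = FALSE, temperature = 0)
  tr <- simulate_toy_trajectory(cfg, ints, n_frames = 5, seed = 1)
  for (f in 2:5) expect_equal(tr$np_coords[, , f], tr$np_coords[, , 1])
})

test_that("the rigid body preserves its internal geometry exactly", {
  fib <- small_fibril(); np <- small_np()
  cfg <- place_nanoparticle_random(fib, np, min_spacing = 3, box = 14, seed = 4)
  tr <- simulate_toy_trajectory(cfg, interaction_matrix(), n_frames = 8,
                                seed = 6)
  d0 <- as.numeric(dist(tr$np_coords[, , 1]))
  for (f in c(4, 8))
    expect_equal(as.numeric(dist(tr$np_coords[, , f])), d0, tolerance = 1e-8)
})

test_that("the study design enumerates the 9 species and the fixture counts", {
  des <- study_design()
  expect_equal(nrow(des), 9)
  expect_equal(sum(des$charge_density == 0), 3)
  expect_equal(sum(des$charge_sign > 0), 3)
  expect_equal(sum(des$charge_sign < 0), 3)

  fx <- generate_study_fixtures(master_seed = 1, scale = 0.1, replicas = 1)
  expect_length(fx, 10)  # 9 species + 1 control
  expect_equal(vapply(fx, `[[`, "", "species")[10], "control")
  ctrl <- fx[[10]]$trajectory
  expect_equal(dim(ctrl$np_coords)[1], 0)
  s <- contact_summary(ctrl)
  expect_equal(s$contact_type, "none")
  expect_true(all(s$timeseries$total == 0))
  expect_error(generate_study_fixtures(scale = 0), class = "invalid_argument")
})
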