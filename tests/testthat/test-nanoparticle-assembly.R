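# Nanoparticle assembly, charge assignment, size estimation

make_small_system <- function(seed = 1) {
  replicate_chains(build_chain("PS", 10, seed = seed), 2, box = 6,
                   seed = seed + 100)
}

test_that("assembly is deterministic in the seed", {
  sys <- make_small_system()
  a <- assemble_nanoparticle(sys, seed = 9)
  b <- assemble_nanoparticle(sys, seed = 9)
  c <- assemble_nanoparticle(sys, seed = 10)
  expect_identical(a$beads, b$beads)
  expect_false(isTRUE(all.equal(a$beads$x, c$beads$x)))
})

test_that("eps = 0 with kT = 0 exerts no force at all", {
  sys <- make_small_system()
  p <- assembly_params(eps = 0, kT = 0, electrostatics = FALSE,
                       n_compress = 50, n_steps = 50, n_relax = 20)
  np <- assemble_nanoparticle(sys, params = p, seed = 1)
  fl <- npfibril:::flatten_system(sys)
  x0 <- as.matrix(fl$beads[, c("x", "y", "z")])
  x0 <- sweep(x0, 2, colMeans(x0))
  x1 <- as.matrix(np$beads[, c("x", "y", "z")])
  expect_equal(x1, x0, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a neutral collapse gives one cluster matching the BFS oracle", {
  np <- assemble_nanoparticle(make_small_system(), seed = 2)
  expect_equal(np$n_clusters, 1L)
  xyz <- as.matrix(np$beads[, c("x", "y", "z")])
  lab <- oracle_cluster_labels(xyz, 0.8)
  expect_equal(max(lab), np$n_clusters)
  # same partition, up to label names
  expect_equal(length(unique(paste(lab, np$cluster_labels))),
               length(unique(lab)))
})

test_that("cluster labelling kernel agrees with the oracle on point sets", {
  set.seed(11)
  for (k in 1:5) {
    pos <- matrix(runif(3 * 60, 0, 6), ncol = 3)
    fast <- npfibril:::cpp_cluster_labels(pos, 0.9)
    slow <- oracle_cluster_labels(pos, 0.9)
    expect_equal(max(fast), max(slow))
    expect_equal(length(unique(paste(fast, slow))), max(slow))
  }
})

test_that("assign_charges charges exactly round(density x monomers) carriers", {
  sys <- make_small_system()  # 20 monomers
  chg <- assign_charges(sys, 0.1, sign = 1, seed = 3)
  q <- unlist(lapply(chg$chains, function(c) c$beads$charge))
  expect_equal(sum(q), 2)             # round(0.1 * 20)
  expect_true(all(q %in% c(0, 1)))
  carriers <- unlist(lapply(chg$chains, function(c) c$beads$name[c$beads$charge != 0]))
  expect_true(all(carriers == "B"))   # PS backbone carries the charge

  neg <- assign_charges(sys, 0.5, sign = -1, seed = 3)
  qn <- unlist(lapply(neg$chains, function(c) c$beads$charge))
  expect_equal(sum(qn), -10)

  expect_error(assign_charges(sys, 1.2), class = "invalid_argument")
  expect_error(assign_charges(sys, -0.1), class = "invalid_argument")
  expect_error(assign_charges(build_chain("PS", 5), 0.1),
               class = "invalid_argument")
})

test_that("surface placement concentrates charge in the outer shell", {
  np <- assemble_nanoparticle(make_small_system(), seed = 4)
  surf <- assign_charges(np, 0.2, sign = 1, placement = "surface", seed = 5)
  unif <- assign_charges(np, 0.2, sign = 1, placement = "uniform", seed = 5)
  expect_equal(surf$total_charge, 4)
  fs <- charge_surface_fraction(surf, 0.5)
  fu <- charge_surface_fraction(unif, 0.5)
  expect_gte(fs, fu)
  expect_error(charge_surface_fraction(np, 0.5),
               class = "undefined_statistic")
})

test_that("estimate_diameter recovers a known ball and a known pair", {
  ball <- sample_ball(5000, radius = 3, seed = 8)
  d <- estimate_diameter(ball)
  expect_equal(d$diameter, 6, tolerance = 0.05)
  expect_lte(d$max_extent, 6.0000001)

  pair <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(estimate_diameter(pair)$max_extent, 4)
  expect_error(estimate_diameter(pair[1, , drop = FALSE]),
               class = "invalid_argument")
})

test_that("summary reports masses, diameter and cluster count", {
  np <- assemble_nanoparticle(make_small_system(), seed = 2)
  s <- summary(np)
  expect_equal(s$n_monomers, 20)
  expect_equal(s$chemical_mass_Da, 20 * 104.15)
  expect_equal(s$cg_mass_Da, sum(np$beads$mass))
  expect_equal(s$n_clusters, 1L)
  expect_output(print(s), "PS nanoparticle")
})
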