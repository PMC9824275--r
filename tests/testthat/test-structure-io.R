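# File formats, trajectories, reports and run configuration

test_that("GRO and XYZ round-trip within printed precision", {
  np <- assemble_nanoparticle(replicate_chains(build_chain("PS", 6, seed = 1),
                                               2, box = 5, seed = 2), seed = 3)
  doc <- as_structure_document(np)
  x0 <- as.matrix(doc$beads[, c("x", "y", "z")])

  g <- withr::local_tempfile(fileext = ".gro")
  write_structure(doc, g)
  rg <- read_structure(g)
  expect_lt(max(abs(as.matrix(rg$beads[, c("x", "y", "z")]) - x0)), 5.1e-4)
  expect_equal(rg$beads$name, doc$beads$name)
  expect_equal(rg$beads$resno, doc$beads$resno)

  x <- withr::local_tempfile(fileext = ".xyz")
  write_structure(doc, x)
  rx <- read_structure(x)
  expect_lt(max(abs(as.matrix(rx$beads[, c("x", "y", "z")]) - x0)), 5.1e-5)
  expect_equal(rx$beads$name, doc$beads$name)
})

test_that("PDB round-trips and agrees with a direct bio3d read", {
  fib <- make_synthetic_fibril_unit(seed = 1)
  doc <- as_structure_document(fib)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(doc, p)
  rp <- read_structure(p)
  x0 <- as.matrix(doc$beads[, c("x", "y", "z")])
  expect_lt(max(abs(as.matrix(rp$beads[, c("x", "y", "z")]) - x0)), 5.1e-5)
  expect_equal(rp$beads$resname, doc$beads$resname)
  expect_equal(rp$beads$chain, doc$beads$chain)

  raw <- bio3d::read.pdb(p, verbose = FALSE)
  expect_equal(rp$beads$x, raw$atom$x / 10)
  expect_equal(nrow(raw$atom), 336)
})

test_that("parse errors carry the file and the offending line", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("title", "10", "only one atom line"), f)
  expect_error(read_structure(f), "truncated", class = "parse_error")

  g <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("title", "1",
               "    1PS     B    1   x.xxx   0.000   0.000",
               "   5.0   5.0   5.0"), g)
  expect_error(read_structure(g), "line 3", class = "parse_error")

  x <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "cmt", "B 1.0 2.0 3.0", "B 1.0 2.0"), x)
  expect_error(read_structure(x), "line 4", class = "parse_error")

  expect_error(read_structure(file.path(tempdir(), "nope.gro")),
               class = "parse_error")
  d <- withr::local_tempfile(fileext = ".dat")
  writeLines("not a structure", d)
  expect_error(read_structure(d), class = "format_error")
})

test_that("chain letters are finite and overflow loudly", {
  expect_equal(npfibril:::chain_letter(c(1, 27, 53)), c("A", "a", "0"))
  expect_error(npfibril:::chain_letter(63), class = "encoding_error")
})

test_that("trajectory PDB round-trip preserves contact totals", {
  np <- assemble_nanoparticle(replicate_chains(build_chain("PP", 8, seed = 1),
                                               2, box = 5, seed = 2), seed = 3)
  fib <- make_synthetic_fibril_unit(seed = 1)
  cfg <- place_nanoparticle_biased(fib, np, "side", gap = 1, box = 14, seed = 4)
  tr <- simulate_toy_trajectory(cfg, interaction_matrix(electrostatics = FALSE),
                                n_frames = 5, seed = 5)

  p <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, p)
  expect_equal(length(grep("^MODEL", readLines(p))), 5)
  back <- read_trajectory(p)
  expect_s3_class(back, "np_trajectory")
  expect_equal(back$times, tr$times)
  expect_lt(max(abs(back$np_coords - tr$np_coords)), 5.1e-5)
  t1 <- contact_timeseries(tr)
  t2 <- contact_timeseries(back)
  expect_equal(t2$total, t1$total)
  expect_equal(t2[, c("hydrophobic", "polar", "charged")],
               t1[, c("hydrophobic", "polar", "charged")])

  x <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(tr, x)
  bx <- read_trajectory(x)
  expect_lt(max(abs(bx$np_coords - tr$np_coords)), 5.1e-5)

  # no manifest -> parse error
  nm <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, nm, manifest = FALSE)
  expect_error(read_trajectory(nm), class = "parse_error")
})

test_that("export_report writes byte-stable CSV/JSON", {
  np <- assemble_nanoparticle(replicate_chains(build_chain("PP", 8, seed = 1),
                                               2, box = 5, seed = 2), seed = 3)
  fib <- make_synthetic_fibril_unit(seed = 1)
  cfg <- place_nanoparticle_biased(fib, np, "side", gap = 1, box = 14, seed = 4)
  tr <- simulate_toy_trajectory(cfg, interaction_matrix(electrostatics = FALSE),
                                n_frames = 4, seed = 5)
  s <- contact_summary(tr)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_report(list(run1 = s), d1)
  export_report(list(run1 = s), d2)
  for (f in c("contacts.csv", "residue_profile.csv", "summary.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  j <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_named(j$systems, "run1")
  expect_true(j$systems$run1$contact_type %in% c("side", "frontal", "none"))

  # an empty summary list still yields valid zero-row tables
  d3 <- withr::local_tempdir()
  export_report(list(), d3)
  expect_equal(nrow(read.csv(file.path(d3, "contacts.csv"))), 0)
  expect_equal(nrow(read.csv(file.path(d3, "residue_profile.csv"))), 0)
})

test_that("run_config rejects unknown keys and hashes stably", {
  cfg <- run_config(replicas = 2L)
  expect_equal(cfg$replicas, 2L)
  expect_equal(cfg$cutoff, 0.8)
  expect_error(run_config(cutof = 0.9), class = "configuration_error")
  expect_error(run_config(0.9), class = "configuration_error")
  expect_identical(npfibril:::config_hash(cfg), npfibril:::config_hash(cfg))
  expect_false(identical(npfibril:::config_hash(cfg),
                         npfibril:::config_hash(run_config(replicas = 3L))))
})
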