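# Abeta42 fibril model: construction, annotation, faces, replication, I/O

test_that("the base unit is 8 chains x 42 residues with the right labels", {
  fib <- make_synthetic_fibril_unit(seed = 1)
  b <- fib$beads
  expect_equal(nrow(b), 336)
  expect_equal(sort(unique(b$chain)), 1:8)
  expect_equal(unname(table(b$chain)), rep(42L, 8), ignore_attr = TRUE)
  expect_equal(b$aa[b$chain == 1], strsplit(AB42_SEQUENCE, "")[[1]])
  expect_equal(sort(unique(b$layer)), 1:4)
  expect_equal(sort(unique(b$protofilament)), 1:2)
})

test_that("annotation gives net -3 e per chain from 6 acidic and 3 basic", {
  fib <- make_synthetic_fibril_unit(seed = 1)
  for (ch in 1:8) {
    cb <- fib$beads[fib$beads$chain == ch, ]
    expect_equal(sum(cb$charge), -3)
    expect_equal(sum(cb$aa %in% c("D", "E")), 6)
    expect_equal(sum(cb$aa %in% c("K", "R")), 3)
  }
  expect_true(all(fib$beads$class %in% c("hydrophobic", "polar", "charged")))
  expect_true(all((fibril <- fib$beads)$class[fibril$charge != 0] == "charged"))
})

test_that("KLVFF (16-20) lies on the exposed lateral edge of each protofilament", {
  fib <- make_synthetic_fibril_unit(seed = 1, jitter = 0)
  b <- fib$beads
  # protofilaments pack through their C-terminal strands: the N-terminal
  # strand carrying 16-20 must be the outermost row of each protofilament
  y1_n <- mean(b$y[b$protofilament == 1 & b$resno %in% 16:20])
  y1_c <- mean(b$y[b$protofilament == 1 & b$resno %in% 30:34])
  y2_n <- mean(b$y[b$protofilament == 2 & b$resno %in% 16:20])
  y2_c <- mean(b$y[b$protofilament == 2 & b$resno %in% 30:34])
  expect_lt(y1_n, y1_c)   # pf1 KLVFF row is below its C-terminal row
  expect_gt(y2_n, y2_c)   # pf2 is the C2 image above
  expect_lt(y1_c, y2_c)   # the two C-terminal rows form the interface
})

test_that("face definition partitions residues by terminal layers", {
  fib <- make_synthetic_fibril_unit(seed = 1)
  b <- fib$beads
  expect_true(all(b$face[b$layer %in% c(1, 4)] == "frontal"))
  expect_true(all(b$face[b$layer %in% c(2, 3)] == "side"))
  expect_equal(sum(b$face == "frontal"), 168)

  deeper <- define_faces(fib, depth = 2L)
  expect_true(all(deeper$beads$face == "frontal"))

  one_layer <- fib
  one_layer$beads <- one_layer$beads[one_layer$beads$layer == 1, ]
  expect_error(define_faces(one_layer), class = "degenerate_geometry")
})

test_that("replicating the unit 4x gives the 32-chain fibril", {
  unit <- make_synthetic_fibril_unit(seed = 1, jitter = 0)
  fib <- replicate_unit(unit, 4)
  b <- fib$beads
  expect_equal(length(unique(b$chain)), 32)
  expect_equal(nrow(b), 1344)
  expect_equal(sort(unique(b$layer)), 1:16)
  # z extent = 15 rises exactly (no jitter)
  expect_equal(max(b$z) - min(b$z), 15 * 0.48, tolerance = 1e-12)
  # faces are redefined on the full stack
  expect_true(all(b$face[b$layer %in% c(1, 16)] == "frontal"))
  expect_true(all(b$face[b$layer %in% 2:15] == "side"))

  expect_identical(replicate_unit(unit, 1), unit)
  expect_error(replicate_unit(unit, 0), class = "invalid_argument")
})

test_that("residue code translation round-trips and rejects unknowns", {
  aa <- strsplit(AB42_SEQUENCE, "")[[1]]
  expect_equal(npfibril:::aa3_to_1(npfibril:::aa1_to_3(aa)), aa)
  expect_error(npfibril:::aa1_to_3("X"), class = "annotation_error")
  expect_error(npfibril:::aa3_to_1("XYZ"), class = "annotation_error")
})

test_that("annotation table is complete and CSV-ready", {
  fib <- make_synthetic_fibril_unit(seed = 1)
  tab <- fibril_annotation_table(fib)
  expect_equal(nrow(tab), 336)
  expect_named(tab, c("chain", "layer", "index", "name", "class", "charge",
                      "face"))
  expect_equal(sum(tab$charge), -24)
})

test_that("load_base_unit round-trips GRO and PDB within printed precision", {
  unit <- make_synthetic_fibril_unit(seed = 1)
  x0 <- as.matrix(unit$beads[, c("x", "y", "z")])

  g <- withr::local_tempfile(fileext = ".gro")
  write_structure(unit, g)
  ug <- load_base_unit(g)
  expect_equal(length(unique(ug$beads$chain)), 8)
  expect_lt(max(abs(as.matrix(ug$beads[, c("x", "y", "z")]) - x0)), 5.1e-4)
  expect_equal(length(unique(ug$beads$layer)), 4)
  expect_gt(abs(ug$axis[3]), 0.99)  # recovered axis is the stacking z

  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(unit, p)
  up <- load_base_unit(p)
  expect_lt(max(abs(as.matrix(up$beads[, c("x", "y", "z")]) - x0)), 5.1e-5)
  expect_equal(up$beads$resname[up$beads$chain == 1], unit$beads$resname[unit$beads$chain == 1])
  expect_equal(up$rise, unit$rise, tolerance = 0.05)

  # a non-fibril structure is rejected with a model shape error
  np <- assemble_nanoparticle(replicate_chains(build_chain("PP", 5, seed = 1),
                                               2, box = 5, seed = 2), seed = 3)
  f <- withr::local_tempfile(fileext = ".gro")
  write_structure(np, f)
  expect_error(load_base_unit(f), class = "model_shape_error")
})
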