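# Contact analytics against hand-constructed micro-systems

# a trajectory with hand-placed NP bead positions per frame near a regular
# (jitter-free) fibril; np_positions is a list of m x 3 matrices
hand_trajectory <- function(np_positions, box = c(20, 20, 20)) {
  fib <- make_synthetic_fibril_unit(seed = 1, jitter = 0)
  m <- nrow(np_positions[[1]])
  arr <- array(NA_real_, c(m, 3, length(np_positions)))
  for (f in seq_along(np_positions)) arr[, , f] <- np_positions[[f]]
  structure(list(
    times = seq_along(np_positions) - 1,
    np_coords = arr, fibril = fib, np = NULL, box = box,
    component = list(np = nrow(fib$beads) + seq_len(m),
                     fibril = seq_len(nrow(fib$beads))),
    config = list()
  ), class = "np_trajectory")
}

test_that("contacts count residues, not bead pairs", {
  fib <- make_synthetic_fibril_unit(seed = 1, jitter = 0)
  target <- fib$beads[fib$beads$chain == 1 & fib$beads$resno == 10, ]
  p <- c(target$x, target$y, target$z)
  # two NP beads within the cutoff of residue 10 only: sequence neighbours
  # (0.35 nm apart) and the next layer (0.48 nm) stay outside 0.8 nm
  tr <- hand_trajectory(list(rbind(p + c(0, -0.75, 0),
                                   p + c(0.05, -0.75, 0))))
  rec <- contacts_in_frame(tr, 1)
  expect_equal(rec$resno, 10)          # one residue, not two bead pairs
  expect_equal(rec$chain, 1)
  expect_equal(rec$min_dist, 0.75)
  expect_equal(rec$class, "polar")     # Y10

  # just beyond the cutoff: no contact anywhere
  tr2 <- hand_trajectory(list(rbind(p + c(0, -0.801, 0))))
  expect_equal(nrow(contacts_in_frame(tr2, 1)), 0)
})

test_that("the cutoff boundary is closed (a pair exactly at 0.8 counts)", {
  fib <- matrix(0, 1, 3)
  np <- matrix(c(0.8, 0, 0), 1)
  d <- npfibril:::cpp_residue_min_dists(fib, 1L, 1L, np, c(-1, -1, -1), 0.8)
  expect_equal(d, 0.8)
  np2 <- matrix(c(0.8 + 1e-12, 0, 0), 1)
  d2 <- npfibril:::cpp_residue_min_dists(fib, 1L, 1L, np2, c(-1, -1, -1), 0.8)
  expect_identical(d2, Inf)
})

test_that("contacts are found through the periodic boundary", {
  fib <- make_synthetic_fibril_unit(seed = 1, jitter = 0)
  target <- fib$beads[fib$beads$chain == 1 & fib$beads$resno == 1, ]
  p <- c(target$x, target$y, target$z)
  box <- c(20, 20, 20)
  # the same physical point, one box length away in x
  tr <- hand_trajectory(list(rbind(p + c(20, 0, 0.3))), box = box)
  rec <- contacts_in_frame(tr, 1)
  expect_true(any(rec$resno == 1 & rec$chain == 1))
  expect_equal(rec$min_dist[rec$resno == 1 & rec$chain == 1], 0.3,
               tolerance = 1e-9)
})

test_that("an unannotated fibril is a configuration error", {
  tr <- hand_trajectory(list(matrix(c(100, 100, 100), 1)))
  tr$fibril$beads$face <- NULL
  expect_error(contacts_in_frame(tr, 1), class = "configuration_error")
})

test_that("class columns add up to the total each frame", {
  fib <- make_synthetic_fibril_unit(seed = 1, jitter = 0)
  cen <- colMeans(as.matrix(fib$beads[, c("x", "y", "z")]))
  set.seed(3)
  frames <- lapply(1:6, function(f)
    sweep(matrix(rnorm(9, sd = 1.5), 3), 2, cen, `+`))
  tr <- hand_trajectory(frames)
  ts <- contact_timeseries(tr)
  expect_equal(ts$total, ts$hydrophobic + ts$polar + ts$charged)
  expect_s3_class(ts, "contact_timeseries")
})

test_that("first_contact_time honours the persistence filter", {
  ser <- data.frame(time = 0:9, total = c(0, 1, 0, 1, 1, 1, 0, 0, 1, 1))
  expect_equal(first_contact_time(ser, 1), 1)
  expect_equal(first_contact_time(ser, 2), 3)
  expect_equal(first_contact_time(ser, 3), 3)
  expect_true(is.na(first_contact_time(ser, 4)))
  expect_true(is.na(first_contact_time(data.frame(time = 0:2, total = 0:0))))
  expect_error(first_contact_time(data.frame()), class = "invalid_argument")
  expect_error(first_contact_time(ser, 0), class = "invalid_argument")
})

test_that("residue frequency is 1 for an always-contacted position", {
  fib <- make_synthetic_fibril_unit(seed = 1, jitter = 0)
  target <- fib$beads[fib$beads$chain == 1 & fib$beads$resno == 10, ]
  p <- c(target$x, target$y, target$z)
  tr <- hand_trajectory(rep(list(rbind(p + c(0, -0.7, 0))), 5))
  freq <- residue_contact_frequency(tr)
  expect_equal(nrow(freq), 42)
  expect_equal(freq$frequency[freq$resno == 10], 1)
  expect_true(all(freq$frequency[!freq$resno %in% 9:11] == 0))

  per_chain <- residue_contact_frequency(tr, aggregate = "chain")
  expect_equal(nrow(per_chain), 336)
  expect_equal(per_chain$frequency[per_chain$chain == 1 &
                                     per_chain$resno == 10], 1)
  expect_true(all(per_chain$frequency[per_chain$chain != 1] == 0))
})

test_that("contact type classification follows the frontal threshold", {
  rec <- function(n_front, n_side)
    data.frame(face = c(rep("frontal", n_front), rep("side", n_side)),
               class = rep("polar", n_front + n_side))
  expect_equal(classify_contact_type(rec(6, 4)), "frontal")
  expect_equal(classify_contact_type(rec(5, 5)), "side")    # tie -> side
  expect_equal(classify_contact_type(rec(0, 10)), "side")
  expect_equal(classify_contact_type(rec(0, 0)), "none")
  expect_error(classify_contact_type(data.frame(class = "polar", x = 1)),
               class = "configuration_error")
})

test_that("class_breakdown validates and counts", {
  rec <- data.frame(class = c("polar", "polar", "charged"))
  expect_equal(class_breakdown(rec),
               c(hydrophobic = 0L, polar = 2L, charged = 1L))
  expect_error(class_breakdown(data.frame(class = "greasy")),
               class = "annotation_error")
  expect_error(class_breakdown("not a frame"), class = "invalid_argument")
})

test_that("contact_summary bundles consistent pieces", {
  fib <- make_synthetic_fibril_unit(seed = 1, jitter = 0)
  # chain 3 is layer 2, a side-face chain
  target <- fib$beads[fib$beads$chain == 3 & fib$beads$resno == 18, ]
  p <- c(target$x, target$y, target$z)
  far <- p + c(0, -5, 0)
  tr <- hand_trajectory(list(rbind(far), rbind(p + c(0, -0.7, 0)),
                             rbind(p + c(0, -0.7, 0))))
  s <- contact_summary(tr, persistence = 2)
  expect_s3_class(s, "contact_summary")
  expect_equal(s$first_contact, 1)
  expect_equal(s$contact_type, "side")
  expect_equal(sum(s$class_totals), sum(s$timeseries$total))
  expect_output(print(s), "side")
})
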