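# Independent pure-R oracles used to cross-check the C++ kernels and the
# closed-form geometry used in the shape tests. Deliberately simple and
# slow: plain loops, no shared code with the package internals.

# minimum-image component-wise displacement (box <= 0 disables wrapping)
oracle_min_image <- function(d, L) {
  if (any(L <= 0)) return(d)
  d - L * round(d / L)
}

# per-residue minimum bead-bead distance (Inf beyond cutoff), O(N^2),
# same wrap-then-minimum-image arithmetic as the kernels
oracle_residue_min_dists <- function(fib_xyz, resid, n_res, np_xyz, box,
                                     cutoff) {
  out <- rep(Inf, n_res)
  if (nrow(np_xyz) == 0 || nrow(fib_xyz) == 0) return(out)
  wrap <- function(p) {
    if (any(box <= 0)) return(p)
    sweep(p, 2, box, function(x, L) x - L * floor(x / L))
  }
  fw <- wrap(fib_xyz); nw <- wrap(np_xyz)
  c2 <- cutoff^2
  for (i in seq_len(nrow(fw))) {
    for (j in seq_len(nrow(nw))) {
      dd <- oracle_min_image(fw[i, ] - nw[j, ], box)
      d2 <- sum(dd^2)
      if (d2 <= c2) {
        d <- sqrt(d2)
        if (d < out[resid[i]]) out[resid[i]] <- d
      }
    }
  }
  out
}

# single-linkage clusters by breadth-first search on the <= cutoff graph
oracle_cluster_labels <- function(pos, cutoff) {
  n <- nrow(pos)
  lab <- integer(n)
  nxt <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      d <- sqrt(rowSums(sweep(pos, 2, pos[i, ])^2))
      nb <- which(d <= cutoff & lab == 0L)
      lab[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  lab
}

# inertia tensor of point masses about their centre of mass, plain loops
oracle_inertia <- function(coords, masses) {
  com <- colSums(coords * masses) / sum(masses)
  I <- matrix(0, 3, 3)
  for (k in seq_len(nrow(coords))) {
    d <- coords[k, ] - com
    I <- I + masses[k] * (sum(d^2) * diag(3) - outer(d, d))
  }
  I
}

# principal moments of a uniform solid ellipsoid with semi-axes (a, b, c)
# and total mass M: I = M/5 * (b^2+c^2, a^2+c^2, a^2+b^2)
oracle_ellipsoid_moments <- function(a, b, c, M = 1) {
  M / 5 * c(b^2 + c^2, a^2 + c^2, a^2 + b^2)
}

# number of connected components of a bead-bond graph
oracle_graph_components <- function(n_beads, bonds) {
  lab <- seq_len(n_beads)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(bonds))) {
      i <- bonds[e, 1]; j <- bonds[e, 2]
      m <- min(lab[i], lab[j])
      if (lab[i] != m || lab[j] != m) {
        lab[lab == lab[i] | lab == lab[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(lab))
}
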