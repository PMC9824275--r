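# Toy stochastic NP-fibril systems: random initial placement with a minimum
# spacing, rigid-body overdamped Langevin trajectories of the nanoparticle in
# the field of the fixed fibril, and the full study design (9 NP species x 8
# replicas + 8 NP-free controls = 80 systems) at desk scale.

#' Interaction matrix for the toy binding simulator
#'
#' Defines the short-range well depths between the nanoparticle and fibril
#' residues, keyed by residue class (`hydrophobic`, `polar`, `charged`) or by
#' specific residue (`"K16"`-style name+position keys override class values),
#' plus the electrostatic settings and reduced temperature. This is artifact
#' plumbing: it exists so that the generator can be steered to known binding
#' behaviour that the analysis operators must then recover.
#'
#' @param affinity named numeric vector of well depths (reduced energy >= 0)
#' @param electrostatics enable screened Coulomb between NP and fibril charges
#' @param coulomb_k Coulomb prefactor (reduced energy x nm / e^2)
#' @param screening_length Debye screening length, nm (> 0)
#' @param temperature reduced temperature of the Langevin bath
#' @param sigma LJ length scale, nm
#' @param rcut LJ cutoff, nm
#' @return list of class `interaction_matrix`
#' @export
interaction_matrix <- function(affinity = c(hydrophobic = 1, polar = 0.3,
                                            charged = 0.2),
                               electrostatics = TRUE,
                               coulomb_k = 2, screening_length = 1,
                               temperature = 0.3,
                               sigma = 0.47, rcut = 1.2) {
  if (any(affinity < 0))
    np_abort("invalid_argument", "well depths must be >= 0")
  if (screening_length <= 0)
    np_abort("invalid_argument", "screening length must be > 0")
  structure(as.list(environment()), class = "interaction_matrix")
}

#' Default material-specific affinities
#'
#' Qualitative, reduced-unit well depths chosen so the toy simulator mirrors
#' the observed chemistry: PS binds hydrophobic residues strongly with extra
#' affinity for the aromatic pair F19/F20 (ring stacking with styrene), PE
#' and PP bind hydrophobic residues without residue specificity.
#'
#' @param material `"PS"`, `"PE"` or `"PP"`
#' @return a named affinity vector usable in [interaction_matrix()]
#' @export
default_affinities <- function(material) {
  base <- c(hydrophobic = 1, polar = 0.3, charged = 0.2)
  if (material == "PS") c(base, F19 = 1.6, F20 = 1.6) else base
}

# resolve the per-fibril-bead well depth vector
resolve_affinities <- function(interactions, fibril) {
  b <- fibril$beads
  if (is.null(b$class))
    np_abort("configuration_error", "fibril must be annotated first")
  aff <- interactions$affinity
  eps <- rep(0, nrow(b))
  for (cl in c("hydrophobic", "polar", "charged"))
    if (cl %in% names(aff)) eps[b$class == cl] <- aff[[cl]]
  key <- paste0(b$aa, b$resno)
  special <- setdiff(names(aff), c("hydrophobic", "polar", "charged"))
  for (k in special) eps[key == k] <- aff[[k]]
  eps
}

#' Randomly place a nanoparticle near a fibril
#'
#' Centres the fibril in the periodic box, then draws uniform random
#' orientations and centroid positions for the NP until the minimum
#' bead-to-bead distance to the fibril (minimum image) lies in
#' `(min_spacing, max_spacing]` -- just outside the required spacing, the way
#' encounter simulations ring the nanoparticle around the fibril rather than
#' anywhere in the box. The NP is kept spatially contiguous; its centroid
#' lies inside the box.
#'
#' @param fibril an annotated `fibril_model`
#' @param np a `nanoparticle`
#' @param min_spacing required minimum NP-fibril bead distance, nm
#' @param max_spacing upper edge of the initial-gap window, nm (default
#'   `1.5 * min_spacing`)
#' @param box periodic box lengths, nm (length 1 or 3)
#' @param seed RNG seed
#' @param max_tries placement attempts before failing
#' @param replica replica identifier carried into reports
#' @return an object of class `np_system`: `fibril`, `np` (placed), `box`,
#'   `replica`, `seed`
#' @export
place_nanoparticle_random <- function(fibril, np, min_spacing = 4,
                                      box = c(20, 20, 20), seed = 1,
                                      max_spacing = 1.5 * min_spacing,
                                      max_tries = 2000, replica = 1L) {
  stopifnot(inherits(fibril, "fibril_model"), inherits(np, "nanoparticle"))
  box <- rep(as.numeric(box), length.out = 3)
  fib_xyz <- coords_matrix(fibril$beads)
  fib_xyz <- sweep(fib_xyz, 2, colMeans(fib_xyz))
  fib_xyz <- sweep(fib_xyz, 2, box / 2, `+`)
  fibril$beads <- set_coords(fibril$beads, fib_xyz)

  np_xyz0 <- coords_matrix(np$beads)
  np_xyz0 <- sweep(np_xyz0, 2, colMeans(np_xyz0))
  np_rad <- max(sqrt(rowSums(np_xyz0^2)))
  fib_ext <- max(sqrt(rowSums(sweep(fib_xyz, 2, box / 2)^2)))
  if (any(fib_ext + min_spacing + 2 * np_rad > box))
    np_abort("placement_error",
             "box too small to place the NP %g nm away from the fibril",
             min_spacing)

  placed <- with_seed(seed, {
    hit <- NULL
    for (t in seq_len(max_tries)) {
      R <- random_rotation()
      xyz <- np_xyz0 %*% t(R)
      cen <- runif(3) * box
      xyz <- sweep(xyz, 2, cen, `+`)
      gap <- cpp_min_pair(xyz, fib_xyz, box)$dist
      if (gap > min_spacing && gap <= max_spacing) {
        hit <- list(xyz = xyz, gap = gap)
        break
      }
    }
    hit
  })
  if (is.null(placed))
    np_abort("placement_error",
             "no placement with spacing > %g nm found in %d tries",
             min_spacing, max_tries)
  np$beads <- set_coords(np$beads, placed$xyz)
  structure(list(fibril = fibril, np = np, box = box,
                 initial_gap = placed$gap,
                 replica = as.integer(replica), seed = as.integer(seed)),
            class = "np_system")
}

#' @export
print.np_system <- function(x, ...) {
  cat(sprintf(
    "<np_system> %s NP (%d beads) + fibril (%d residues), box %s nm, gap %.2f nm\n",
    x$np$material, nrow(x$np$beads), nrow(x$fibril$beads),
    paste(signif(x$box, 3), collapse = " x "), x$initial_gap))
  invisible(x)
}

#' Place a nanoparticle near a chosen fibril face
#'
#' Steered variant of [place_nanoparticle_random()] used for
#' constructed-truth tests: the NP is dropped at a small surface gap either
#' off the lateral surface (`"side"`, perpendicular to the fibril axis, at a
#' random azimuth) or off one end (`"frontal"`, along the axis), so that a
#' binding trajectory started from it approaches the designated face first.
#'
#' @param fibril an annotated `fibril_model`
#' @param np a `nanoparticle`
#' @param face `"side"` or `"frontal"`
#' @param gap target NP-fibril surface gap, nm
#' @param box periodic box lengths, nm
#' @param seed RNG seed (orientation and azimuth)
#' @param target_resno optional sequence positions; for a side placement the
#'   NP is pushed out from the centroid of those residues along the local
#'   outward surface normal instead of from the box centre at a random
#'   azimuth
#' @param replica replica identifier
#' @return an `np_system`
#' @export
place_nanoparticle_biased <- function(fibril, np, face = c("side", "frontal"),
                                      gap = 1, box = c(20, 20, 20), seed = 1,
                                      target_resno = NULL, replica = 1L) {
  face <- match.arg(face)
  stopifnot(inherits(fibril, "fibril_model"), inherits(np, "nanoparticle"))
  box <- rep(as.numeric(box), length.out = 3)
  fib_xyz <- coords_matrix(fibril$beads)
  fib_xyz <- sweep(fib_xyz, 2, colMeans(fib_xyz))
  fib_xyz <- sweep(fib_xyz, 2, box / 2, `+`)
  fibril$beads <- set_coords(fibril$beads, fib_xyz)
  axis <- fibril$axis / sqrt(sum(fibril$axis^2))

  np_xyz0 <- coords_matrix(np$beads)
  np_xyz0 <- sweep(np_xyz0, 2, colMeans(np_xyz0))

  placed <- with_seed(seed, {
    R <- random_rotation()
    xyz <- np_xyz0 %*% t(R)
    origin <- box / 2
    if (face == "frontal") {
      dir <- axis * sample(c(-1, 1), 1)
    } else if (!is.null(target_resno)) {
      # drop the NP straight onto the designated patch: push out from the
      # patch centroid along its outward surface normal (perpendicular to
      # the fibril axis and to the strand direction). One protofilament
      # only, so the two symmetry-related patches do not cancel out.
      sel <- fibril$beads$resno %in% target_resno
      pf <- fibril$beads$protofilament
      if (!all(is.na(pf))) sel <- sel & !is.na(pf) & pf == pf[which(sel)[1]]
      patch <- fib_xyz[sel, , drop = FALSE]
      origin <- colMeans(patch)
      # in-plane strand direction: principal direction of the patch after
      # projecting out the fibril axis (the patch spans many layers, so its
      # raw principal direction would be the axis itself)
      d <- sweep(patch, 2, origin)
      d <- d - (d %*% axis) %*% t(axis)
      strand <- svd(d)$v[, 1]
      v <- origin - box / 2
      v <- v - sum(v * axis) * axis
      v <- v - sum(v * strand) * strand
      dir <- v / sqrt(sum(v^2))
    } else {
      # random direction perpendicular to the axis
      v <- rnorm(3)
      v <- v - sum(v * axis) * axis
      dir <- v / sqrt(sum(v^2))
    }
    # push the NP out along dir until the surface gap matches
    lo <- 0; hi <- max(box)
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      cand <- sweep(xyz, 2, origin + mid * dir, `+`)
      g <- cpp_min_pair(cand, fib_xyz, box)$dist
      if (g < gap) lo <- mid else hi <- mid
    }
    cand <- sweep(xyz, 2, origin + hi * dir, `+`)
    list(xyz = cand, gap = cpp_min_pair(cand, fib_xyz, box)$dist)
  })
  np$beads <- set_coords(np$beads, placed$xyz)
  structure(list(fibril = fibril, np = np, box = box,
                 initial_gap = placed$gap, steered_face = face,
                 replica = as.integer(replica), seed = as.integer(seed)),
            class = "np_system")
}

#' Simulate a toy rigid-body binding trajectory
#'
#' Propagates the nanoparticle as a rigid body with overdamped Langevin
#' dynamics (translation + rotation) in the field of the fixed fibril:
#' short-range attraction with per-residue well depths from the interaction
#' matrix plus screened Coulomb between NP bead charges and residue charges,
#' with minimum-image periodic boundaries. Frames are recorded every
#' `stride` steps and labelled in pseudo-ns (`frame time = step * dt`); no
#' physical time mapping is claimed.
#'
#' The free diffusion constant is `kT / gamma_t`. The default friction
#' `gamma_t = 1` is deliberately small: it compresses the slow diffusive
#' NP-fibril encounter (microseconds in solvent) onto the short pseudo-ns
#' trajectories generated here, so that binding events are observable at
#' desk scale. The rotational friction defaults to `gamma_t` times the mean
#' squared bead radius.
#'
#' @param config an [place_nanoparticle_random()] system
#' @param interactions an [interaction_matrix()]
#' @param n_frames number of recorded frames (>= 2; includes the initial one)
#' @param dt integration step, pseudo-ns
#' @param stride integration steps between recorded frames
#' @param gamma_t,gamma_r translational / rotational friction (reduced)
#' @param seed RNG seed
#' @return an object of class `np_trajectory`: `times`, `np_coords`
#'   (`n_np_beads x 3 x n_frames` array), `fibril`, `np`, `box`, `component`
#'   (bead index bookkeeping), `config`
#' @export
simulate_toy_trajectory <- function(config, interactions = interaction_matrix(),
                                    n_frames = 200, dt = 0.01, stride = 10,
                                    gamma_t = 1, gamma_r = NULL, seed = 1) {
  stopifnot(inherits(config, "np_system"),
            inherits(interactions, "interaction_matrix"))
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 2)
    np_abort("invalid_argument", "n_frames must be >= 2")
  n_frames <- as.integer(n_frames)

  fib_xyz <- coords_matrix(config$fibril$beads)
  fib_q <- as.numeric(config$fibril$beads$charge %||% rep(0, nrow(fib_xyz)))
  eps <- resolve_affinities(interactions, config$fibril)
  np_xyz <- coords_matrix(config$np$beads)
  np_q <- as.numeric(config$np$beads$charge)
  box <- config$box
  m <- nrow(np_xyz)
  cen <- colMeans(np_xyz)
  gamma_r <- gamma_r %||% (gamma_t * mean(rowSums(sweep(np_xyz, 2, cen)^2)))
  kT <- interactions$temperature
  ke <- if (interactions$electrostatics) interactions$coulomb_k else 0

  frames <- array(NA_real_, c(m, 3, n_frames))
  times <- numeric(n_frames)
  frames[, , 1] <- np_xyz
  with_seed(seed, {
    step_no <- 0L
    for (f in 2:n_frames) {
      for (s in seq_len(stride)) {
        step_no <- step_no + 1L
        cen <- colMeans(np_xyz)
        fr <- cpp_rigid_forces(np_xyz, np_q, fib_xyz, fib_q, eps,
                               interactions$sigma, interactions$rcut,
                               ke, interactions$screening_length, box, cen)
        if (!all(is.finite(fr$F)) || !all(is.finite(fr$tau)))
          np_abort("numerical_failure",
                   "non-finite forces at step %d (min NP-fibril distance %.3g nm)",
                   step_no, fr$min_dist)
        dR <- dt * fr$F / gamma_t
        dW <- dt * fr$tau / gamma_r
        # cap the deterministic drift for stability near the LJ core
        # (the thermal noise below is never clipped, so free diffusion is exact)
        nr <- sqrt(sum(dR^2)); if (nr > 0.1) dR <- dR * 0.1 / nr
        nw <- sqrt(sum(dW^2)); if (nw > 0.2) dW <- dW * 0.2 / nw
        if (kT > 0) {
          dR <- dR + sqrt(2 * kT * dt / gamma_t) * rnorm(3)
          dW <- dW + sqrt(2 * kT * dt / gamma_r) * rnorm(3)
        }
        R <- rotation_from_axis_angle(dW)
        np_xyz <- sweep(sweep(np_xyz, 2, cen) %*% t(R), 2, cen + dR, `+`)
        # re-wrap the whole particle when its centroid leaves the box
        cen2 <- cen + dR
        shift <- floor(cen2 / box) * box
        if (any(shift != 0)) np_xyz <- sweep(np_xyz, 2, shift)
      }
      frames[, , f] <- np_xyz
      times[f] <- step_no * dt
    }
  })
  structure(list(
    times = times, np_coords = frames, fibril = config$fibril,
    np = config$np, box = box,
    component = list(np = nrow(config$fibril$beads) + seq_len(m),
                     fibril = seq_len(nrow(config$fibril$beads))),
    config = list(replica = config$replica, seed = as.integer(seed),
                  dt = dt, stride = stride,
                  interactions = unclass(interactions))
  ), class = "np_trajectory")
}

#' @export
print.np_trajectory <- function(x, ...) {
  cat(sprintf(
    "<np_trajectory> %d frames over %.3g pseudo-ns: %d NP beads vs %d fibril residues\n",
    length(x$times), max(x$times), dim(x$np_coords)[1], nrow(x$fibril$beads)))
  invisible(x)
}

#' Full bead coordinates of one trajectory frame (fibril then NP)
#' @param traj an `np_trajectory`
#' @param frame frame index
#' @return a numeric matrix, one row per bead
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(inherits(traj, "np_trajectory"))
  if (frame < 1 || frame > length(traj$times))
    np_abort("invalid_argument", "frame index out of range")
  rbind(coords_matrix(traj$fibril$beads), traj$np_coords[, , frame])
}

# control "trajectory" for NP-free systems: static fibril, zero NP beads
control_trajectory <- function(fibril, box, n_frames, dt = 0.01, stride = 10,
                               replica = 1L) {
  structure(list(
    times = (seq_len(n_frames) - 1) * dt * stride,
    np_coords = array(NA_real_, c(0, 3, n_frames)),
    fibril = fibril, np = NULL, box = box,
    component = list(np = integer(0), fibril = seq_len(nrow(fibril$beads))),
    config = list(replica = as.integer(replica), seed = NA_integer_,
                  dt = dt, stride = stride, interactions = NULL)
  ), class = "np_trajectory")
}

#' The default study design: 9 NP species plus NP-free controls
#' @return data frame with columns `species`, `material`, `charge_density`,
#'   `charge_sign`
#' @export
study_design <- function() {
  data.frame(
    species = c("PS", "PE", "PP",
                "PS4+", "PS10+", "PS20+", "PS4-", "PS10-", "PS20-"),
    material = c("PS", "PE", "PP", rep("PS", 6)),
    charge_density = c(0, 0, 0, 0.04, 0.10, 0.20, 0.04, 0.10, 0.20),
    charge_sign = c(0, 0, 0, 1, 1, 1, -1, -1, -1),
    stringsAsFactors = FALSE
  )
}

#' Generate the full fixture suite of NP-fibril systems and toy trajectories
#'
#' Enumerates the study design (8 replicas for each of the 9 NP species plus
#' 8 NP-free controls: 80 systems) at desk scale: small nanoparticles, a
#' 2-repeat fibril and short trajectories, with every per-system seed derived
#' deterministically from `master_seed`. `scale` multiplies the frame count.
#'
#' @param master_seed master RNG seed
#' @param scale frame-count factor (> 0); `scale = 1` gives 20 frames/system
#' @param n_chains,n_monomers toy NP size (chains x monomers per chain)
#' @param fibril_repeats longitudinal fibril repeats
#' @param replicas replicas per species
#' @param box periodic box, nm
#' @param min_spacing initial NP-fibril spacing, nm
#' @return a list of entries, each with `species`, `replica`, `config`
#'   (`np_system` or NULL for controls) and `trajectory`
#' @export
generate_study_fixtures <- function(master_seed = 1, scale = 1,
                                    n_chains = 3, n_monomers = 20,
                                    fibril_repeats = 2, replicas = 8,
                                    box = c(20, 20, 20), min_spacing = 4) {
  if (!is.numeric(scale) || scale <= 0)
    np_abort("invalid_argument", "scale must be > 0")
  n_frames <- max(2L, as.integer(round(20 * scale)))
  design <- study_design()
  fibril <- replicate_unit(
    make_synthetic_fibril_unit(seed = derive_seed(master_seed, 0)),
    fibril_repeats)

  # one assembled neutral NP per material, reused across replicas
  nps <- list()
  for (mat in unique(design$material)) {
    sys <- replicate_chains(
      build_chain(mat, n_monomers, seed = derive_seed(master_seed, 1)),
      n_chains, box = 8, seed = derive_seed(master_seed, 2))
    nps[[mat]] <- assemble_nanoparticle(sys, seed = derive_seed(master_seed, 3))
  }

  out <- list()
  k <- 10L
  for (i in seq_len(nrow(design))) {
    sp <- design[i, ]
    np <- nps[[sp$material]]
    if (sp$charge_density > 0)
      np <- assign_charges(np, sp$charge_density, sp$charge_sign,
                           placement = "surface",
                           seed = derive_seed(master_seed, k))
    ints <- interaction_matrix(affinity = default_affinities(sp$material))
    for (r in seq_len(replicas)) {
      k <- k + 2L
      cfg <- place_nanoparticle_random(fibril, np, min_spacing, box,
                                       seed = derive_seed(master_seed, k),
                                       replica = r)
      traj <- simulate_toy_trajectory(cfg, ints, n_frames = n_frames,
                                      seed = derive_seed(master_seed, k + 1L))
      out[[length(out) + 1L]] <- list(species = sp$species, replica = r,
                                      config = cfg, trajectory = traj)
    }
  }
  for (r in seq_len(replicas)) {
    out[[length(out) + 1L]] <- list(
      species = "control", replica = r, config = NULL,
      trajectory = control_trajectory(fibril, box, n_frames, replica = r))
  }
  out
}
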