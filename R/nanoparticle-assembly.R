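# Collapse a dispersed multi-chain system into a compact spheroidal
# nanoparticle with overdamped Langevin dynamics under a short-range
# pairwise attraction (plus bonded springs and, when charges are present,
# Debye-screened Coulomb), followed by a zero-temperature relaxation.
# Reduced units throughout: lengths nm, energies in units of the attraction
# well depth, friction coefficient 1 per bead.

#' Assembly parameter set
#'
#' The collapse runs in three stages: a compression stage with a stronger
#' centroid-directed confinement that brings dispersed chains into one
#' droplet, a cohesion stage with weak confinement where the short-range
#' attraction consolidates the particle, and an unconfined zero-temperature
#' relaxation. Confinement constants are expressed in units of the attraction
#' well depth per nm^2 (they are scaled by `eps`), so with `eps = 0` the
#' surrogate exerts no force at all.
#'
#' @param eps nonbonded attraction well depth (reduced energy)
#' @param sigma nonbonded length scale, nm (one CG bead diameter)
#' @param rcut nonbonded cutoff, nm
#' @param k_bond bond spring constant (reduced energy / nm^2)
#' @param k_compress confinement during the compression stage (eps / nm^2)
#' @param k_confine confinement during the cohesion stage (eps / nm^2)
#' @param kT reduced temperature during the stochastic stages
#' @param dt integration step (reduced time)
#' @param n_compress compression steps
#' @param n_steps cohesion steps
#' @param n_relax unconfined zero-temperature relaxation steps
#' @param electrostatics enable screened Coulomb between charged beads
#' @param coulomb_k Coulomb prefactor (reduced energy x nm / e^2). The
#'   default 56 is the vacuum Coulomb constant e^2/(4 pi eps0) = 138.9
#'   kJ/mol nm expressed in well-depth units with eps taken as kT at 300 K
#'   (2.48 kJ/mol), so like-charge repulsion during the vacuum collapse has
#'   its physical strength relative to the cohesive attraction
#' @param screening_length Debye screening length, nm
#' @return a list of class `assembly_params`
#' @export
assembly_params <- function(eps = 1, sigma = 0.47, rcut = 1.2,
                            k_bond = 50, k_compress = 2, k_confine = 0.1,
                            kT = 0.2, dt = 0.002,
                            n_compress = 800, n_steps = 1200, n_relax = 400,
                            electrostatics = TRUE,
                            coulomb_k = 56, screening_length = 1) {
  structure(as.list(environment()), class = "assembly_params")
}

#' Assemble a multi-chain system into a nanoparticle
#'
#' Runs an overdamped Langevin collapse of the chain system under the toy
#' force field in `params`, then relaxes at zero temperature, and reports the
#' number of spatial clusters in the final structure (single-linkage at a
#' 0.8 nm neighbour cutoff). Highly charged systems may legitimately finish
#' fragmented (more than one cluster) when electrostatic repulsion beats the
#' short-range attraction; the cluster count is reported, not enforced.
#'
#' @param system a [replicate_chains()] result (or a single `polymer_chain`)
#' @param params an [assembly_params()] list
#' @param seed RNG seed for the thermal noise
#' @param cluster_cutoff neighbour cutoff for the final cluster count, nm
#' @return an object of class `nanoparticle`: `material`, `beads`
#'   (name/mass/charge/x/y/z), `bonds`, `bond_r0`, `monomer_of_bead`,
#'   `n_monomers`, `charge_density`, `total_charge`, `n_clusters`, `seed`
#' @export
assemble_nanoparticle <- function(system, params = assembly_params(), seed = 1,
                                  cluster_cutoff = 0.8) {
  if (inherits(system, "polymer_chain"))
    system <- structure(list(chains = list(system), box = rep(Inf, 3)),
                        class = "chain_system")
  stopifnot(inherits(system, "chain_system"))
  if (length(system$chains) == 0)
    np_abort("invalid_argument", "empty chain system")
  fl <- flatten_system(system)
  pos <- coords_matrix(fl$beads)
  pos <- sweep(pos, 2, colMeans(pos))
  bonds0 <- fl$bonds - 1L  # 0-based for the kernel
  q <- fl$beads$charge
  ke <- if (params$electrostatics && any(q != 0)) params$coulomb_k else 0
  n <- nrow(pos)

  step <- function(pos, kT, k_confine) {
    F <- cpp_pair_forces(pos, bonds0, fl$bond_r0, params$k_bond, q,
                         params$eps, params$sigma, params$rcut,
                         ke, params$screening_length, k_confine)
    if (!all(is.finite(F))) {
      mp <- cpp_min_pair(pos, pos + 0, c(-1, -1, -1))
      np_abort("numerical_failure",
               "non-finite forces during assembly (closest bead pair %d-%d)",
               mp$i, mp$j)
    }
    disp <- params$dt * F
    if (kT > 0)
      disp <- disp + sqrt(2 * kT * params$dt) *
        matrix(rnorm(3 * n), ncol = 3)
    # cap per-step displacement for stability of the steep LJ core
    dmax <- 0.1
    nr <- sqrt(rowSums(disp^2))
    too_far <- nr > dmax
    if (any(too_far)) disp[too_far, ] <- disp[too_far, ] * (dmax / nr[too_far])
    pos + disp
  }

  pos <- with_seed(seed, {
    for (s in seq_len(params$n_compress))
      pos <- step(pos, params$kT, params$eps * params$k_compress)
    for (s in seq_len(params$n_steps))
      pos <- step(pos, params$kT, params$eps * params$k_confine)
    for (s in seq_len(params$n_relax))
      pos <- step(pos, 0, 0)
    pos
  })
  pos <- sweep(pos, 2, colMeans(pos))
  beads <- set_coords(fl$beads, pos)
  labels <- cpp_cluster_labels(pos, cluster_cutoff)

  material <- system$chains[[1]]$material
  structure(list(
    material = material, beads = beads, bonds = fl$bonds, bond_r0 = fl$bond_r0,
    monomer_of_bead = fl$monomer_of_bead, chain_of_bead = fl$chain_of_bead,
    n_monomers = fl$n_monomers,
    mapping = system$chains[[1]]$mapping,
    charge_density = attr(system, "charge_density") %||% 0,
    total_charge = sum(beads$charge),
    n_clusters = max(labels), cluster_labels = labels,
    seed = as.integer(seed)
  ), class = "nanoparticle")
}

#' @export
print.nanoparticle <- function(x, ...) {
  d <- estimate_diameter(x)
  cat(sprintf(
    "<nanoparticle> %s: %d monomers, %d beads, total charge %+g e\n",
    x$material, x$n_monomers, nrow(x$beads), x$total_charge))
  cat(sprintf("  sphere-equivalent diameter %.2f nm (max extent %.2f nm), %d cluster(s)\n",
              d$diameter, d$max_extent, x$n_clusters))
  invisible(x)
}

#' @export
summary.nanoparticle <- function(object, ...) {
  m <- chemical_mass(object)
  d <- estimate_diameter(object)
  out <- list(material = object$material, n_monomers = object$n_monomers,
              n_beads = nrow(object$beads),
              chemical_mass_Da = m$chemical, cg_mass_Da = m$cg,
              total_charge_e = object$total_charge,
              charge_density = object$charge_density,
              diameter_nm = d$diameter, max_extent_nm = d$max_extent,
              n_clusters = object$n_clusters)
  class(out) <- "summary.nanoparticle"
  out
}

#' @export
print.summary.nanoparticle <- function(x, ...) {
  cat(sprintf("%s nanoparticle: %d monomers / %d beads\n", x$material,
              x$n_monomers, x$n_beads))
  cat(sprintf("  mass: %.1f kDa chemical, %.1f kDa CG beads\n",
              x$chemical_mass_Da / 1000, x$cg_mass_Da / 1000))
  cat(sprintf("  charge: %+g e (density %.0f%% of monomers)\n",
              x$total_charge_e, 100 * x$charge_density))
  cat(sprintf("  diameter: %.2f nm (max extent %.2f nm); clusters: %d\n",
              x$diameter_nm, x$max_extent_nm, x$n_clusters))
  invisible(x)
}

# carrier bead index for every chemical monomer (1..n_monomers)
carrier_beads <- function(obj) {
  chains <- if (inherits(obj, "chain_system")) obj$chains else list(obj)
  map <- chains[[1]]$mapping
  bpm <- nrow(map$bead_templates)
  out <- integer(0); off <- 0L
  for (ch in chains) {
    units <- ceiling(seq_len(ch$n_monomers) / map$monomers_per_bead)
    out <- c(out, off + (units - 1L) * bpm + map$charge_carrier)
    off <- off + nrow(ch$beads)
  }
  out
}

#' Assign monomer charges to a nanoparticle or chain system
#'
#' Charges exactly `round(density * n_monomers)` monomers (half away from
#' zero) with `sign` x 1 e on their designated carrier bead (the backbone
#' bead for PS). `placement = "uniform"` samples monomers uniformly;
#' `placement = "surface"` samples with probability proportional to the rank
#' of the carrier bead's distance from the centroid, concentrating charge at
#' the particle surface.
#'
#' @param np a `nanoparticle` or `chain_system`
#' @param density fraction of monomers to charge, in `[0, 1]`
#' @param sign `+1` or `-1`
#' @param placement `"uniform"` or `"surface"`
#' @param seed RNG seed for monomer sampling
#' @return the input object with updated bead charges, `charge_density` and
#'   `total_charge`
#' @export
assign_charges <- function(np, density, sign = 1,
                           placement = c("uniform", "surface"), seed = 1) {
  placement <- match.arg(placement)
  if (!is.numeric(density) || length(density) != 1L ||
      is.na(density) || density < 0 || density > 1)
    np_abort("invalid_argument", "charge density must be in [0, 1]")
  sign <- if (sign >= 0) 1 else -1

  is_np <- inherits(np, "nanoparticle")
  if (!is_np && !inherits(np, "chain_system"))
    np_abort("invalid_argument", "np must be a nanoparticle or chain_system")

  if (is_np) {
    n_mon <- np$n_monomers
    beads <- np$beads
    map <- np$mapping
    bpm <- nrow(map$bead_templates)
    # carrier bead of monomer m, using per-chain offsets recorded at flatten
    carrier <- integer(n_mon)
    mono <- 1L
    for (k in sort(unique(np$chain_of_bead))) {
      idx <- which(np$chain_of_bead == k)
      # monomer_of_bead stores first-monomer-of-unit; recover chain monomer count
      n_mon_ch <- max(np$monomer_of_bead[idx]) - min(np$monomer_of_bead[idx]) +
        map$monomers_per_bead
      u <- ceiling(seq_len(n_mon_ch) / map$monomers_per_bead)
      carrier[mono:(mono + n_mon_ch - 1L)] <-
        idx[1] - 1L + (u - 1L) * bpm + map$charge_carrier
      mono <- mono + n_mon_ch
    }
  } else {
    n_mon <- sum(vapply(np$chains, `[[`, 0L, "n_monomers"))
    fl <- flatten_system(np)
    beads <- fl$beads
    carrier <- carrier_beads(np)
  }

  n_charged <- as.integer(round_half_away(density * n_mon))
  beads$charge <- 0
  if (n_charged > 0) {
    chosen <- with_seed(seed, {
      if (placement == "uniform") {
        sample(n_mon, n_charged)
      } else {
        xyz <- coords_matrix(beads)
        cen <- colMeans(xyz)
        d <- sqrt(rowSums(sweep(xyz, 2, cen)^2))[carrier]
        sample(n_mon, n_charged, prob = rank(d))
      }
    })
    for (m in chosen) {
      b <- carrier[m]
      beads$charge[b] <- beads$charge[b] + sign
    }
  }

  if (is_np) {
    np$beads <- beads
    np$charge_density <- density
    np$total_charge <- sum(beads$charge)
    np
  } else {
    # write charges back into the per-chain bead tables
    off <- 0L
    for (k in seq_along(np$chains)) {
      nb <- nrow(np$chains[[k]]$beads)
      np$chains[[k]]$beads$charge <- beads$charge[off + seq_len(nb)]
      off <- off + nb
    }
    attr(np, "charge_density") <- density
    np
  }
}

#' Fraction of charged beads in the nanoparticle surface shell
#'
#' The surface shell is the set of beads whose distance from the NP centroid
#' is at least (max bead distance - `shell_thickness`). For charges
#' distributed uniformly through a solid ball the expected fraction is
#' 1 - (1 - t/R)^3; surface placement drives it toward 1.
#'
#' @param np a charged `nanoparticle`
#' @param shell_thickness shell depth from the outermost bead, nm
#' @return fraction of charged beads in the shell
#' @export
charge_surface_fraction <- function(np, shell_thickness) {
  stopifnot(inherits(np, "nanoparticle"))
  chg <- which(np$beads$charge != 0)
  if (length(chg) == 0)
    np_abort("undefined_statistic",
             "charge_surface_fraction is undefined for a neutral nanoparticle")
  xyz <- coords_matrix(np$beads)
  d <- sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2))
  mean(d[chg] >= max(d) - shell_thickness)
}

#' Sphere-equivalent diameter of a nanoparticle
#'
#' Reports `2 * sqrt(5/3) * Rg` (the diameter of the uniform solid sphere
#' with the same mass-weighted radius of gyration) together with the maximum
#' pairwise bead extent.
#'
#' @param np a `nanoparticle`, or a numeric coordinate matrix (nm)
#' @param masses optional bead masses when `np` is a matrix
#' @return list with `diameter` and `max_extent`, nm
#' @export
estimate_diameter <- function(np, masses = NULL) {
  if (inherits(np, "nanoparticle")) {
    xyz <- coords_matrix(np$beads)
    masses <- np$beads$mass
  } else {
    xyz <- as.matrix(np)
  }
  if (nrow(xyz) < 2)
    np_abort("invalid_argument", "need at least 2 beads to estimate a diameter")
  rg <- radius_of_gyration(xyz, masses)
  # max pairwise extent: exact for moderate bead counts, extreme-point subset
  # (convex-hull directions) for very large clouds
  pts <- xyz
  if (nrow(pts) > 3000) {
    dirs <- rbind(diag(3), -diag(3),
                  expand_signs(c(1, 1, 1)))
    idx <- unique(c(apply(pts %*% t(dirs), 2, which.max),
                    apply(pts %*% t(dirs), 2, which.min)))
    pts <- pts[idx, , drop = FALSE]
  }
  list(diameter = 2 * sqrt(5 / 3) * rg,
       max_extent = max(stats::dist(pts)))
}

expand_signs <- function(v) {
  s <- expand.grid(c(1, -1), c(1, -1), c(1, -1))
  as.matrix(s) * matrix(v, nrow(s), 3, byrow = TRUE)
}
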