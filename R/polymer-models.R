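# Coarse-grained mappings and linear-chain builders for the three commodity
# plastics (polystyrene, polyethylene, polypropylene). The mapping follows
# the usual 4-heavy-atoms-to-1-bead coarse-graining: PS monomers become one
# backbone bead plus a 3-bead phenyl ring, PE packs two C2H4 monomers into
# one bead, PP uses one (small) bead per monomer.

# chemical monomer molecular weights, Da
MONOMER_MASS <- c(PS = 104.15, PE = 28.05, PP = 42.08)

SUPPORTED_MATERIALS <- c("PS", "PE", "PP")

#' Default coarse-grained mapping for a polymer material
#'
#' Returns the bead template, intra-monomer bond topology and inter-monomer
#' link used to coarse-grain one chemical monomer of the given material.
#' Bead masses follow the usual CG convention of 72 Da for regular (4 heavy
#' atom) beads and 45 Da for small (ring / 3 heavy atom) beads.
#'
#' @param material one of `"PS"`, `"PE"`, `"PP"`
#' @param variant mapping variant; `"default"` gives the 4-bead styrene
#'   monomer (backbone + 3-bead ring), `"2bead"` a backbone + single-ring-bead
#'   alternative for PS
#' @return an object of class `cg_mapping` with fields `material`,
#'   `beads_per_monomer`, `monomers_per_bead`, `bead_templates` (data frame:
#'   name, mass, charge, radius), `bonds_within_monomer`, `bond_to_next`,
#'   `charge_carrier` (template index of the bead that receives a monomer
#'   charge) and `monomer_mass` (chemical, Da)
#' @examples
#' cg_mapping("PS")$beads_per_monomer  # 4
#' @export
cg_mapping <- function(material, variant = "default") {
  if (!is.character(material) || length(material) != 1L ||
      !(material %in% SUPPORTED_MATERIALS))
    np_abort("unsupported_material",
             "unsupported material '%s' (supported: %s)",
             as.character(material)[1], paste(SUPPORTED_MATERIALS, collapse = ", "))
  tmpl <- function(name, mass, charge, radius)
    data.frame(name = name, mass = mass, charge = charge, radius = radius,
               stringsAsFactors = FALSE)
  if (material == "PS" && variant == "default") {
    map <- list(
      material = "PS", beads_per_monomer = 4, monomers_per_bead = 1,
      bead_templates = tmpl(c("B", "R1", "R2", "R3"),
                            c(72, 45, 45, 45), c(0, 0, 0, 0),
                            c(0.235, 0.215, 0.215, 0.215)),
      bonds_within_monomer = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 2)),
      bond_to_next = c(1, 1), charge_carrier = 1L
    )
  } else if (material == "PS" && variant == "2bead") {
    map <- list(
      material = "PS", beads_per_monomer = 2, monomers_per_bead = 1,
      bead_templates = tmpl(c("B", "R"), c(72, 135), c(0, 0), c(0.235, 0.264)),
      bonds_within_monomer = rbind(c(1, 2)),
      bond_to_next = c(1, 1), charge_carrier = 1L
    )
  } else if (material == "PE") {
    # one bead per four backbone carbons = two C2H4 monomers per bead
    map <- list(
      material = "PE", beads_per_monomer = 0.5, monomers_per_bead = 2,
      bead_templates = tmpl("C", 72, 0, 0.235),
      bonds_within_monomer = matrix(integer(0), ncol = 2),
      bond_to_next = c(1, 1), charge_carrier = 1L
    )
  } else if (material == "PP") {
    map <- list(
      material = "PP", beads_per_monomer = 1, monomers_per_bead = 1,
      bead_templates = tmpl("C", 45, 0, 0.215),
      bonds_within_monomer = matrix(integer(0), ncol = 2),
      bond_to_next = c(1, 1), charge_carrier = 1L
    )
  } else {
    np_abort("invalid_argument", "unknown mapping variant '%s' for %s",
             variant, material)
  }
  map$monomer_mass <- unname(MONOMER_MASS[material])
  structure(map, class = "cg_mapping")
}

#' @export
print.cg_mapping <- function(x, ...) {
  cat(sprintf("CG mapping for %s: %g bead(s)/monomer, %d template bead(s)\n",
              x$material, x$beads_per_monomer, nrow(x$bead_templates)))
  print(x$bead_templates, row.names = FALSE)
  invisible(x)
}

# bead-group geometry for one coarse-grained repeat unit, local frame (nm)
monomer_geometry <- function(map, parity) {
  side <- if (parity %% 2 == 0) 1 else -1
  if (map$material == "PS" && map$beads_per_monomer == 4) {
    rbind(c(0, 0.05 * side, 0),
          c(0, 0.05 * side + 0.24 * side, 0),
          c(-0.11, 0.05 * side + 0.43 * side, 0),
          c(0.11, 0.05 * side + 0.43 * side, 0))
  } else if (map$material == "PS") {
    rbind(c(0, 0.05 * side, 0), c(0, 0.05 * side + 0.3 * side, 0))
  } else {
    rbind(c(0, 0.06 * side, 0))
  }
}

backbone_spacing <- function(map) {
  switch(map$material, PS = 0.26, PE = 0.47, PP = 0.30)
}

#' Build a linear coarse-grained polymer chain
#'
#' Builds an ideal zig-zag conformation of `n_monomers` chemical monomers of
#' the given material under its default CG mapping, then applies a
#' seed-derived random rigid rotation so that chains built with different
#' seeds start in different orientations. Bond rest lengths are taken from
#' the constructed geometry, so the initial conformation is relaxed.
#'
#' For polyethylene the mapping packs two monomers into one bead, so odd
#' monomer counts are rounded down to the next even count with a warning.
#'
#' @param material `"PS"`, `"PE"` or `"PP"`
#' @param n_monomers number of chemical monomers (>= 1)
#' @param seed RNG seed controlling the chain orientation
#' @param mapping optional `cg_mapping` overriding the default
#' @return an object of class `polymer_chain`: fields `material`,
#'   `n_monomers`, `beads` (data frame name/mass/charge/x/y/z),
#'   `bonds` (two-column index matrix), `bond_r0` (rest lengths, nm),
#'   `monomer_of_bead` (integer vector) and `mapping`
#' @examples
#' ch <- build_chain("PS", 50)
#' nrow(ch$beads)  # 200
#' @export
build_chain <- function(material, n_monomers, seed = 1, mapping = NULL) {
  map <- mapping %||% cg_mapping(material)
  if (!is.numeric(n_monomers) || length(n_monomers) != 1L || n_monomers < 1)
    np_abort("invalid_argument", "n_monomers must be a single count >= 1")
  n_monomers <- as.integer(n_monomers)
  if (map$monomers_per_bead == 2 && n_monomers %% 2 == 1) {
    warning(sprintf(
      "PE chains need an even monomer count; rounding %d down to %d",
      n_monomers, n_monomers - 1L))
    n_monomers <- n_monomers - 1L
    if (n_monomers < 1)
      np_abort("invalid_argument", "n_monomers too small for the PE mapping")
  }
  n_units <- n_monomers / map$monomers_per_bead  # CG repeat units along chain
  bpm <- nrow(map$bead_templates)
  dx <- backbone_spacing(map)

  beads <- vector("list", n_units)
  bonds <- list()
  monomer_of_bead <- integer(0)
  for (u in seq_len(n_units)) {
    local <- monomer_geometry(map, u)
    local[, 1] <- local[, 1] + (u - 1) * dx
    b <- map$bead_templates
    b$x <- local[, 1]; b$y <- local[, 2]; b$z <- local[, 3]
    beads[[u]] <- b
    off <- (u - 1) * bpm
    if (nrow(map$bonds_within_monomer))
      bonds[[length(bonds) + 1]] <- map$bonds_within_monomer + off
    if (u < n_units)
      bonds[[length(bonds) + 1]] <-
        matrix(c(off + map$bond_to_next[1], off + bpm + map$bond_to_next[2]),
               ncol = 2)
    # a CG unit may span several chemical monomers (PE); attribute beads to
    # the first monomer of the unit for charge bookkeeping
    monomer_of_bead <- c(monomer_of_bead,
                         rep((u - 1L) * map$monomers_per_bead + 1L, bpm))
  }
  beads <- do.call(rbind, beads)
  rownames(beads) <- NULL
  bonds <- do.call(rbind, bonds)
  storage.mode(bonds) <- "integer"

  xyz <- coords_matrix(beads)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  R <- with_seed(seed, random_rotation())
  xyz <- xyz %*% t(R)
  beads <- set_coords(beads, xyz)
  r0 <- sqrt(rowSums((xyz[bonds[, 1], , drop = FALSE] -
                      xyz[bonds[, 2], , drop = FALSE])^2))
  structure(list(
    material = map$material, n_monomers = n_monomers, beads = beads,
    bonds = bonds, bond_r0 = r0, monomer_of_bead = monomer_of_bead,
    mapping = map, seed = as.integer(seed)
  ), class = "polymer_chain")
}

#' @export
print.polymer_chain <- function(x, ...) {
  cat(sprintf("<polymer_chain> %s, %d monomers, %d beads, %d bonds\n",
              x$material, x$n_monomers, nrow(x$beads), nrow(x$bonds)))
  invisible(x)
}

#' Replicate a chain into a multi-chain starting system
#'
#' Places `n_copies` rigid copies of a chain at random positions and
#' orientations inside a cubic or rectangular box, rejecting placements in
#' which any two beads of different chains come closer than `clash` nm.
#'
#' @param chain a [build_chain()] result
#' @param n_copies number of copies (>= 1)
#' @param box box edge lengths, nm (length 1 or 3)
#' @param seed RNG seed
#' @param clash minimum allowed inter-chain bead distance, nm
#' @param max_tries placement attempts per copy before giving up
#' @return an object of class `chain_system`: `chains` (list of
#'   `polymer_chain`), `box` (length-3 numeric)
#' @export
replicate_chains <- function(chain, n_copies, box, seed = 1,
                             clash = 0.47, max_tries = 500) {
  stopifnot(inherits(chain, "polymer_chain"))
  if (!is.numeric(n_copies) || length(n_copies) != 1L || n_copies < 1)
    np_abort("invalid_argument", "n_copies must be a single count >= 1")
  n_copies <- as.integer(n_copies)
  box <- rep(as.numeric(box), length.out = 3)
  base <- coords_matrix(chain$beads)
  base <- sweep(base, 2, colMeans(base))
  ext <- 2 * max(sqrt(rowSums(base^2)))
  if (ext > sqrt(sum(box^2)))
    np_abort("packing_error",
             "box too small to host the chain (extent %.1f nm, box diagonal %.1f nm)",
             ext, sqrt(sum(box^2)))

  with_seed(seed, {
    placed <- list()
    all_coords <- NULL
    for (k in seq_len(n_copies)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        R <- random_rotation()
        xyz <- base %*% t(R)
        lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
        if (any(-lo > box - hi)) next  # this orientation cannot fit
        cen <- runif(3, -lo, box - hi)
        xyz <- sweep(xyz, 2, cen, `+`)
        if (is.null(all_coords) ||
            cpp_min_pair(xyz, all_coords, c(-1, -1, -1))$dist >= clash) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        np_abort("packing_error",
                 "could not place copy %d of %d without clashes after %d tries",
                 k, n_copies, max_tries)
      ch <- chain
      ch$beads <- set_coords(ch$beads, xyz)
      placed[[k]] <- ch
      all_coords <- rbind(all_coords, xyz)
    }
    structure(list(chains = placed, box = box, clash = clash,
                   seed = as.integer(seed)),
              class = "chain_system")
  })
}

#' @export
print.chain_system <- function(x, ...) {
  nb <- sum(vapply(x$chains, function(c) nrow(c$beads), 0L))
  cat(sprintf("<chain_system> %d x %s chain(s), %d beads, box %s nm\n",
              length(x$chains), x$chains[[1]]$material, nb,
              paste(signif(x$box, 3), collapse = " x ")))
  invisible(x)
}

#' Chemical and coarse-grained mass of a chain, system or nanoparticle
#'
#' The chemical mass is the monomer count times the monomer molecular weight
#' (PS 104.15, PE 28.05, PP 42.08 Da); the CG mass is the sum of bead masses,
#' which for standard CG bead masses is larger (the two conventions are both
#' reported and not forced to agree).
#'
#' @param x a `polymer_chain`, `chain_system` or `nanoparticle`
#' @return a list with elements `chemical` and `cg`, both in Da
#' @export
chemical_mass <- function(x) UseMethod("chemical_mass")

#' @export
chemical_mass.polymer_chain <- function(x) {
  if (nrow(x$beads) == 0)
    np_abort("invalid_argument", "chain has no beads")
  list(chemical = x$n_monomers * unname(MONOMER_MASS[x$material]),
       cg = sum(x$beads$mass))
}

#' @export
chemical_mass.chain_system <- function(x) {
  per <- lapply(x$chains, chemical_mass)
  list(chemical = sum(vapply(per, `[[`, 0, "chemical")),
       cg = sum(vapply(per, `[[`, 0, "cg")))
}

#' @export
chemical_mass.nanoparticle <- function(x) {
  if (nrow(x$beads) == 0)
    np_abort("invalid_argument", "nanoparticle has no beads")
  list(chemical = x$n_monomers * unname(MONOMER_MASS[x$material]),
       cg = sum(x$beads$mass))
}

# flatten a chain system into one bead table + topology (used by assembly)
flatten_system <- function(system) {
  beads <- list(); bonds <- list(); r0 <- list()
  monomer_of_bead <- integer(0); chain_of_bead <- integer(0)
  off <- 0L; mon_off <- 0L
  for (k in seq_along(system$chains)) {
    ch <- system$chains[[k]]
    beads[[k]] <- ch$beads
    bonds[[k]] <- ch$bonds + off
    r0[[k]] <- ch$bond_r0
    monomer_of_bead <- c(monomer_of_bead, ch$monomer_of_bead + mon_off)
    chain_of_bead <- c(chain_of_bead, rep(k, nrow(ch$beads)))
    off <- off + nrow(ch$beads)
    mon_off <- mon_off + ch$n_monomers
  }
  list(beads = do.call(rbind, beads), bonds = do.call(rbind, bonds),
       bond_r0 = unlist(r0), monomer_of_bead = monomer_of_bead,
       chain_of_bead = chain_of_bead, n_monomers = mon_off)
}
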