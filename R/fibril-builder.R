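# Coarse-grained Abeta42 cross-beta fibril model: an 8-chain base unit (two
# protofilaments x four stacked layers, one bead per residue at the backbone
# position), longitudinal replication, residue class/charge annotation and
# side/frontal face definition.

#' Canonical Abeta42 sequence (one-letter codes, positions 1..42)
#' @export
AB42_SEQUENCE <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

aa1_to_3 <- function(a) {
  i <- match(a, AA1)
  if (anyNA(i))
    np_abort("annotation_error", "unknown residue code(s): %s",
             paste(unique(a[is.na(i)]), collapse = ", "))
  AA3[i]
}

aa3_to_1 <- function(a) {
  i <- match(toupper(a), AA3)
  if (anyNA(i))
    np_abort("annotation_error", "unknown residue name(s): %s",
             paste(unique(a[is.na(i)]), collapse = ", "))
  AA1[i]
}

# default hydrophobic set; His is treated as uncharged-polar
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "P", "G")

# in-plane backbone trace for one 42-residue chain (nm): a beta-arch of two
# antiparallel strands (residues 1-20 and 23-42) joined by a tight turn at
# E22-D23, so the central hydrophobic KLVFF stretch (16-20) lies exposed on
# one lateral edge and the charged turn forms the corner of the fold
chain_trace <- function(spacing = 0.35, row_gap = 0.75) {
  xy <- matrix(0, 42, 2)
  for (i in 1:20) xy[i, ] <- c((i - 1) * spacing, 0)
  xy[21, ] <- c(19 * spacing + 0.30, 0.18)
  xy[22, ] <- c(19 * spacing + 0.30, row_gap - 0.18)
  for (i in 23:42) xy[i, ] <- c((42 - i) * spacing, row_gap)
  xy
}

#' Build the synthetic 8-chain Abeta42 fibril base unit
#'
#' Arranges 8 chains of 42 residues (one bead per residue at the backbone
#' position) as two C2-related protofilaments of four stacked layers with a
#' configurable cross-beta rise, annotates residue classes and charges, and
#' defines the side/frontal faces. The stacking direction (the fibril axis)
#' is the z axis at construction time.
#'
#' @param rise cross-beta layer spacing along the axis, nm
#' @param spacing in-plane distance between consecutive residues, nm
#' @param pf_gap lateral gap between the two protofilaments, nm
#' @param jitter s.d. of a small seeded positional jitter, nm (breaks exact
#'   geometric degeneracies; set 0 for a perfectly regular lattice)
#' @param seed RNG seed for the jitter
#' @return an object of class `fibril_model` with one row per residue bead:
#'   `chain`, `protofilament`, `layer`, `resno`, `resname`, `aa`, `x`, `y`,
#'   `z`, plus annotation columns `class`, `charge`, `face`
#' @examples
#' fib <- make_synthetic_fibril_unit()
#' nrow(fib$beads)  # 336 = 8 x 42
#' @export
make_synthetic_fibril_unit <- function(rise = 0.48, spacing = 0.35,
                                       pf_gap = 0.6, jitter = 0.02, seed = 1) {
  trace <- chain_trace(spacing)
  width <- max(trace[, 2]) - min(trace[, 2])
  aa <- strsplit(AB42_SEQUENCE, "")[[1]]
  rows <- list()
  for (layer in 1:4) {
    for (pf in 1:2) {
      xy <- trace
      if (pf == 2) {
        # C2 rotation about the fibril axis; the protofilaments pack through
        # their C-terminal (23-42) strands, leaving both KLVFF edges exposed
        xy[, 1] <- max(trace[, 1]) - xy[, 1]
        xy[, 2] <- (2 * width + pf_gap) - xy[, 2]
      }
      rows[[length(rows) + 1]] <- data.frame(
        chain = (layer - 1L) * 2L + pf,
        protofilament = pf, layer = layer,
        resno = 1:42, resname = aa1_to_3(aa), aa = aa,
        x = xy[, 1], y = xy[, 2], z = (layer - 1) * rise,
        stringsAsFactors = FALSE
      )
    }
  }
  beads <- do.call(rbind, rows)
  if (jitter > 0) {
    noise <- with_seed(seed, matrix(rnorm(3 * nrow(beads), sd = jitter),
                                    ncol = 3))
    beads$x <- beads$x + noise[, 1]
    beads$y <- beads$y + noise[, 2]
    beads$z <- beads$z + noise[, 3]
  }
  fib <- structure(list(
    beads = beads, axis = c(0, 0, 1), rise = rise,
    layers_per_unit = 4L, n_repeats = 1L, seed = as.integer(seed)
  ), class = "fibril_model")
  define_faces(annotate_residues(fib))
}

#' @export
print.fibril_model <- function(x, ...) {
  nl <- length(unique(x$beads$layer))
  cat(sprintf(
    "<fibril_model> %d chains x 42 residues (%d beads), %d layer(s), %d repeat(s)\n",
    length(unique(x$beads$chain)), nrow(x$beads), nl, x$n_repeats))
  if (!is.null(x$beads$charge))
    cat(sprintf("  total charge %+g e (%+g e per chain)\n",
                sum(x$beads$charge),
                sum(x$beads$charge) / length(unique(x$beads$chain))))
  invisible(x)
}

#' Annotate residue classes and side-chain charges
#'
#' Standard scheme: Asp/Glu carry -1 e, Lys/Arg +1 e (termini neutral, His
#' uncharged-polar); residues in the hydrophobic set are `hydrophobic`;
#' everything else `polar`. A residue is `charged` iff its charge is
#' non-zero. Annotation depends only on residue identity, never on
#' coordinates.
#'
#' @param fibril a `fibril_model`
#' @param hydrophobic one-letter codes treated as hydrophobic
#' @return the fibril with `class` and `charge` columns filled in
#' @export
annotate_residues <- function(fibril, hydrophobic = HYDROPHOBIC_AA) {
  stopifnot(inherits(fibril, "fibril_model"))
  aa <- fibril$beads$aa
  if (anyNA(match(aa, AA1)))
    np_abort("annotation_error", "unknown residue code(s): %s",
             paste(unique(aa[is.na(match(aa, AA1))]), collapse = ", "))
  charge <- ifelse(aa %in% c("D", "E"), -1L,
                   ifelse(aa %in% c("K", "R"), 1L, 0L))
  cls <- ifelse(charge != 0L, "charged",
                ifelse(aa %in% hydrophobic, "hydrophobic", "polar"))
  fibril$beads$class <- cls
  fibril$beads$charge <- charge
  fibril
}

#' Label the frontal and side faces of the fibril
#'
#' Frontal residues are all residues in the first and last `depth` layers
#' along the fibril axis (the growth faces); every other residue is on the
#' lateral (side) surface. The two labels partition the fibril.
#'
#' @param fibril a `fibril_model` with layer indices
#' @param depth how many terminal layers count as frontal
#' @return the fibril with a `face` column (`"frontal"` / `"side"`)
#' @export
define_faces <- function(fibril, depth = 1L) {
  stopifnot(inherits(fibril, "fibril_model"))
  layers <- fibril$beads$layer
  lo <- min(layers); hi <- max(layers)
  if (hi - lo + 1L < 2L)
    np_abort("degenerate_geometry",
             "face definition needs at least 2 layers (got %d)", hi - lo + 1L)
  frontal <- layers <= lo + depth - 1L | layers >= hi - depth + 1L
  fibril$beads$face <- ifelse(frontal, "frontal", "side")
  fibril$face_depth <- as.integer(depth)
  fibril
}

#' Replicate the fibril unit along its axis
#'
#' Stacks `n_repeats` copies of the unit, translating copy k by
#' `k * layers_per_unit * rise` along the fibril axis and extending the
#' layer and chain indices, so an 8-chain unit replicated 4 times gives a
#' 32-chain fibril.
#'
#' @param unit a `fibril_model`
#' @param n_repeats total number of copies (>= 1; 1 returns the unit)
#' @return the replicated `fibril_model`
#' @export
replicate_unit <- function(unit, n_repeats) {
  stopifnot(inherits(unit, "fibril_model"))
  if (!is.numeric(n_repeats) || length(n_repeats) != 1L || n_repeats < 1)
    np_abort("invalid_argument", "n_repeats must be a single count >= 1")
  n_repeats <- as.integer(n_repeats)
  if (n_repeats == 1L) return(unit)
  lpu <- unit$layers_per_unit
  n_chains <- length(unique(unit$beads$chain))
  shift <- unit$axis * lpu * unit$rise
  out <- vector("list", n_repeats)
  for (k in seq_len(n_repeats) - 1L) {
    b <- unit$beads
    b$x <- b$x + k * shift[1]
    b$y <- b$y + k * shift[2]
    b$z <- b$z + k * shift[3]
    b$layer <- b$layer + k * lpu
    b$chain <- b$chain + k * n_chains
    out[[k + 1L]] <- b
  }
  unit$beads <- do.call(rbind, out)
  unit$n_repeats <- n_repeats * unit$n_repeats
  define_faces(unit, depth = unit$face_depth %||% 1L)
}

#' Load a fibril base unit from a PDB or GRO file
#'
#' One bead per residue is taken at the backbone position (the `CA` or `BB`
#' atom when present, otherwise the first atom of the residue); coordinates
#' from PDB files are converted from Angstrom to nm. Chains must each have
#' exactly 42 residues and at least 8 such chains must be present (an
#' explicit `chain_selection` can pick which). GRO files carry no chain
#' identifiers, so chains are inferred from residue-number restarts.
#' Layers are inferred from the
#' stacking geometry: the axis is the displacement between the two closest
#' chain centroids (the cross-beta rise), and layers are grouped by their
#' projection onto it.
#'
#' @param path PDB/GRO file
#' @param chain_selection optional chain identifiers to keep (in file order)
#' @param format `"auto"`, `"pdb"` or `"gro"`
#' @return a `fibril_model`, annotated and with faces defined
#' @export
load_base_unit <- function(path, chain_selection = NULL, format = "auto") {
  doc <- read_structure(path, format)
  at <- doc$beads
  if (all(is.na(at$chain))) {
    # GRO carries no chain identifiers; a drop in the residue number marks
    # the start of the next molecule
    at$chain <- as.character(cumsum(c(TRUE, diff(at$resno) < 0)))
  }
  chains <- unique(at$chain)
  if (!is.null(chain_selection)) chains <- intersect(chains, chain_selection)
  keep <- list()
  for (ch in chains) {
    a <- at[at$chain == ch, , drop = FALSE]
    resnos <- unique(a$resno)
    if (length(resnos) != 42L) next
    rep_rows <- vapply(resnos, function(r) {
      rr <- which(a$resno == r)
      cand <- rr[a$name[rr] %in% c("CA", "BB")]
      if (length(cand)) cand[1] else rr[1]
    }, 0L)
    keep[[length(keep) + 1L]] <- a[rep_rows, , drop = FALSE]
  }
  if (length(keep) < 8L)
    np_abort("model_shape_error",
             "need at least 8 chains of 42 residues (found %d)", length(keep))
  keep <- keep[1:8]

  cent <- t(vapply(keep, function(a) colMeans(as.matrix(a[, c("x", "y", "z")])),
                   numeric(3)))
  dd <- as.matrix(stats::dist(cent)); diag(dd) <- Inf
  ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
  axis <- cent[ij[2], ] - cent[ij[1], ]
  axis <- axis / sqrt(sum(axis^2))
  proj <- as.numeric(cent %*% axis)
  rise <- min(dd)
  layer <- as.integer(round((proj - min(proj)) / rise)) + 1L

  rows <- list()
  for (k in seq_along(keep)) {
    a <- keep[[k]]
    aa <- aa3_to_1(a$resname)
    rows[[k]] <- data.frame(
      chain = k, protofilament = NA_integer_, layer = layer[k],
      resno = a$resno, resname = toupper(a$resname), aa = aa,
      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE
    )
  }
  fib <- structure(list(
    beads = do.call(rbind, rows), axis = axis, rise = rise,
    layers_per_unit = length(unique(layer)), n_repeats = 1L,
    seed = NA_integer_
  ), class = "fibril_model")
  define_faces(annotate_residues(fib))
}

#' Per-residue annotation table
#'
#' @param fibril an annotated `fibril_model`
#' @return a data frame (chain, layer, index, name, class, charge, face)
#'   suitable for CSV export
#' @export
fibril_annotation_table <- function(fibril) {
  stopifnot(inherits(fibril, "fibril_model"))
  b <- fibril$beads
  if (is.null(b$class) || is.null(b$face))
    np_abort("configuration_error", "fibril is not fully annotated")
  data.frame(chain = b$chain, layer = b$layer, index = b$resno,
             name = b$resname, class = b$class, charge = b$charge,
             face = b$face, stringsAsFactors = FALSE)
}

# net side-chain charge per chain (e)
chain_charges <- function(fibril) {
  tapply(fibril$beads$charge, fibril$beads$chain, sum)
}
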