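# Structure and trajectory I/O. Internal units are always nm (and pseudo-ns,
# Da, e); conversion happens only at the file boundary: PDB and XYZ files are
# written/read in Angstrom, GRO is nm-native. PDB files are read through
# bio3d; GRO and XYZ, which have no reader in the R stack, are parsed here
# with fixed-width/whitespace rules and line-numbered parse errors.

#' A minimal structure container for file I/O
#'
#' @param beads data frame with columns `name`, `resname`, `resno`, `chain`,
#'   `x`, `y`, `z` (coordinates in nm)
#' @param box box lengths in nm (length 3) or NULL
#' @param title free-text title line
#' @return an object of class `structure_document`
#' @export
structure_document <- function(beads, box = NULL, title = "npfibril structure") {
  need <- c("name", "resname", "resno", "chain", "x", "y", "z")
  miss <- setdiff(need, names(beads))
  if (length(miss))
    np_abort("invalid_argument", "beads lack column(s): %s",
             paste(miss, collapse = ", "))
  structure(list(beads = beads[, need], box = box, title = title),
            class = "structure_document")
}

#' @export
print.structure_document <- function(x, ...) {
  cat(sprintf("<structure_document> %d beads%s\n", nrow(x$beads),
              if (!is.null(x$box))
                sprintf(", box %s nm", paste(signif(x$box, 4), collapse = " x "))
              else ""))
  invisible(x)
}

#' Convert package objects to a structure document
#' @param x a `nanoparticle`, `fibril_model`, `chain_system` or `np_system`
#' @param ... unused
#' @return a [structure_document()]
#' @export
as_structure_document <- function(x, ...) UseMethod("as_structure_document")

#' @export
as_structure_document.structure_document <- function(x, ...) x

#' @export
as_structure_document.nanoparticle <- function(x, ...) {
  b <- x$beads
  structure_document(data.frame(
    name = b$name, resname = x$material, resno = x$monomer_of_bead,
    chain = chain_letter(x$chain_of_bead %||% rep(1L, nrow(b))),
    x = b$x, y = b$y, z = b$z, stringsAsFactors = FALSE
  ), title = sprintf("%s nanoparticle (%d monomers)", x$material, x$n_monomers))
}

#' @export
as_structure_document.fibril_model <- function(x, ...) {
  b <- x$beads
  structure_document(data.frame(
    name = "CA", resname = b$resname, resno = b$resno,
    chain = chain_letter(b$chain),
    x = b$x, y = b$y, z = b$z, stringsAsFactors = FALSE
  ), title = "CG amyloid fibril (one bead per residue)")
}

#' @export
as_structure_document.chain_system <- function(x, ...) {
  fl <- flatten_system(x)
  b <- fl$beads
  structure_document(data.frame(
    name = b$name, resname = x$chains[[1]]$material,
    resno = fl$monomer_of_bead, chain = chain_letter(fl$chain_of_bead),
    x = b$x, y = b$y, z = b$z, stringsAsFactors = FALSE
  ), box = x$box, title = "dispersed chain system")
}

#' @export
as_structure_document.np_system <- function(x, ...) {
  f <- as_structure_document(x$fibril)$beads
  n <- as_structure_document(x$np)$beads
  n$chain <- chain_letter(max(match(f$chain, CHAIN_CHARS)) +
                          match(n$chain, CHAIN_CHARS))
  structure_document(rbind(f, n), box = x$box, title = "NP-fibril system")
}

CHAIN_CHARS <- c(LETTERS, letters, as.character(0:9))

chain_letter <- function(i) {
  i <- as.integer(i)
  if (any(i > length(CHAIN_CHARS)))
    np_abort("encoding_error",
             "chain identifier space exhausted (%d chains, max %d)",
             max(i), length(CHAIN_CHARS))
  CHAIN_CHARS[i]
}

guess_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gro", "pdb", "xyz")) return(ext)
  np_abort("format_error", "cannot infer format from extension '%s'", ext)
}

#' Read a structure file (GRO, PDB or XYZ)
#'
#' Coordinates are converted to nm on reading (PDB and XYZ are Angstrom
#' formats, GRO is nm-native). For multi-model PDB files only the first
#' model is returned; use [read_trajectory()] for trajectories.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"gro"`, `"pdb"` or `"xyz"`
#' @return a [structure_document()]
#' @export
read_structure <- function(path, format = "auto") {
  if (!file.exists(path))
    np_abort("parse_error", "file not found: %s", path)
  format <- guess_format(path, format)
  switch(format,
         gro = read_gro(path),
         pdb = read_pdb_doc(path),
         xyz = read_xyz_doc(path),
         np_abort("format_error", "unknown format '%s'", format))
}

#' Write a structure file (GRO, PDB or XYZ)
#'
#' GRO is written with 3-decimal nm coordinates, PDB and XYZ with 3-decimal
#' Angstrom coordinates, so a write-read round trip preserves coordinates to
#' half of the last printed digit (5e-4 nm for GRO and XYZ/PDB alike).
#'
#' @param x a `structure_document` or any object with an
#'   [as_structure_document()] method
#' @param path output path
#' @param format `"auto"`, `"gro"`, `"pdb"` or `"xyz"`
#' @return `path`, invisibly
#' @export
write_structure <- function(x, path, format = "auto") {
  doc <- as_structure_document(x)
  format <- guess_format(path, format)
  lines <- switch(format,
                  gro = format_gro(doc),
                  pdb = c(format_pdb_header(doc), format_pdb_atoms(doc$beads), "END"),
                  xyz = format_xyz(doc$beads, doc$title),
                  np_abort("format_error", "unknown format '%s'", format))
  writeLines(lines, path)
  invisible(path)
}

# ---- GRO ----

format_gro <- function(doc) {
  b <- doc$beads
  box <- doc$box %||% c(0, 0, 0)
  c(doc$title,
    sprintf("%5d", nrow(b)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            b$resno %% 100000, substr(b$resname, 1, 5), substr(b$name, 1, 5),
            seq_len(nrow(b)) %% 100000, b$x, b$y, b$z),
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
}

read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3)
    np_abort("parse_error", "%s: truncated GRO file (only %d line(s))",
             path, length(lines))
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n))
    np_abort("parse_error", "%s line 2: expected an atom count, got '%s'",
             path, lines[2])
  if (length(lines) < n + 3)
    np_abort("parse_error", "%s line %d: file truncated (%d atoms declared)",
             path, length(lines), n)
  at <- lines[3:(2 + n)]
  fw <- function(s, a, b) substr(s, a, b)
  xs <- suppressWarnings(as.numeric(fw(at, 21, 28)))
  ys <- suppressWarnings(as.numeric(fw(at, 29, 36)))
  zs <- suppressWarnings(as.numeric(fw(at, 37, 44)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad))
    np_abort("parse_error", "%s line %d: malformed coordinate record '%s'",
             path, bad[1] + 2L, at[bad[1]])
  resno <- suppressWarnings(as.integer(fw(at, 1, 5)))
  if (anyNA(resno))
    np_abort("parse_error", "%s line %d: malformed residue number",
             path, which(is.na(resno))[1] + 2L)
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]]))
  structure_document(data.frame(
    name = trimws(fw(at, 11, 15)), resname = trimws(fw(at, 6, 10)),
    resno = resno, chain = NA_character_,
    x = xs, y = ys, z = zs, stringsAsFactors = FALSE
  ), box = if (length(box) >= 3 && !anyNA(box[1:3])) box[1:3] else NULL,
  title = lines[1])
}

# ---- PDB ----

format_pdb_header <- function(doc) {
  out <- sprintf("TITLE     %s", doc$title)
  if (!is.null(doc$box))
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                          doc$box[1] * 10, doc$box[2] * 10, doc$box[3] * 10,
                          90, 90, 90))
  out
}

format_pdb_atoms <- function(b) {
  ch <- ifelse(is.na(b$chain), "A", as.character(b$chain))
  if (any(nchar(ch) != 1L))
    np_abort("encoding_error", "PDB chain identifiers must be single characters")
  sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          seq_len(nrow(b)) %% 100000, substr(b$name, 1, 3),
          substr(b$resname, 1, 3), ch, b$resno %% 10000,
          b$x * 10, b$y * 10, b$z * 10, 1, 0)
}

read_pdb_doc <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e)
      np_abort("parse_error", "%s: PDB parse failure: %s",
               path, conditionMessage(e)),
    warning = function(w)
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)))
  a <- pdb$atom
  box <- NULL
  cr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cr)) {
    v <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15),
                                       substr(cr[1], 16, 24),
                                       substr(cr[1], 25, 33))))
    if (!anyNA(v) && all(v > 0)) box <- v / 10
  }
  structure_document(data.frame(
    name = a$elety, resname = a$resid, resno = a$resno,
    chain = a$chain, x = a$x / 10, y = a$y / 10, z = a$z / 10,
    stringsAsFactors = FALSE
  ), box = box, title = basename(path))
}

# ---- XYZ ----

format_xyz <- function(b, comment, coords = NULL) {
  xyz <- if (is.null(coords)) cbind(b$x, b$y, b$z) else coords
  c(sprintf("%d", nrow(b)), comment,
    sprintf("%-4s %12.3f %12.3f %12.3f",
            substr(b$name, 1, 4), xyz[, 1] * 10, xyz[, 2] * 10, xyz[, 3] * 10))
}

read_xyz_doc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2)
    np_abort("parse_error", "%s: truncated XYZ file", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n))
    np_abort("parse_error", "%s line 1: expected an atom count, got '%s'",
             path, lines[1])
  if (length(lines) < n + 2)
    np_abort("parse_error", "%s line %d: file truncated (%d atoms declared)",
             path, length(lines), n)
  at <- lines[3:(2 + n)]
  parts <- strsplit(trimws(at), "\\s+")
  bad <- which(vapply(parts, length, 0L) < 4)
  if (length(bad))
    np_abort("parse_error", "%s line %d: malformed XYZ record '%s'",
             path, bad[1] + 2L, at[bad[1]])
  m <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[2:4])),
                numeric(3)))
  bad <- which(apply(is.na(m), 1, any))
  if (length(bad))
    np_abort("parse_error", "%s line %d: non-numeric coordinates",
             path, bad[1] + 2L)
  structure_document(data.frame(
    name = vapply(parts, `[[`, "", 1L), resname = "UNK",
    resno = seq_len(n), chain = NA_character_,
    x = m[, 1] / 10, y = m[, 2] / 10, z = m[, 3] / 10,
    stringsAsFactors = FALSE
  ), title = lines[2])
}

# ---- trajectories ----

#' Write a trajectory as multi-model PDB or multi-frame XYZ with a manifest
#'
#' Each frame holds the full system (fibril then NP beads). A sidecar JSON
#' manifest (`<path>.json`) records the frame times, the periodic box and the
#' component index so the file pair is self-describing.
#'
#' @param traj an `np_trajectory`
#' @param path output path (`.pdb` or `.xyz`)
#' @param format `"auto"`, `"pdb"` or `"xyz"`
#' @param manifest write the sidecar JSON manifest
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path, format = "auto", manifest = TRUE) {
  stopifnot(inherits(traj, "np_trajectory"))
  format <- guess_format(path, format)
  fib <- coords_matrix(traj$fibril$beads)
  doc <- if (is.null(traj$np))
    as_structure_document(traj$fibril)
  else
    as_structure_document(structure(list(fibril = traj$fibril, np = traj$np,
                                         box = traj$box),
                                    class = "np_system"))
  b <- doc$beads
  n_frames <- length(traj$times)
  lines <- character(0)
  if (format == "pdb") {
    lines <- format_pdb_header(structure_document(b, box = traj$box,
                                                  title = "npfibril trajectory"))
    for (f in seq_len(n_frames)) {
      xyz <- rbind(fib, if (dim(traj$np_coords)[1]) traj$np_coords[, , f])
      bf <- b; bf$x <- xyz[, 1]; bf$y <- xyz[, 2]; bf$z <- xyz[, 3]
      lines <- c(lines, sprintf("MODEL %8d", f), format_pdb_atoms(bf), "ENDMDL")
    }
    lines <- c(lines, "END")
  } else if (format == "xyz") {
    for (f in seq_len(n_frames)) {
      xyz <- rbind(fib, if (dim(traj$np_coords)[1]) traj$np_coords[, , f])
      lines <- c(lines, format_xyz(b, sprintf("frame %d t= %g", f,
                                              traj$times[f]), xyz))
    }
  } else np_abort("format_error", "trajectories support pdb or xyz, not %s",
                  format)
  writeLines(lines, path)
  if (manifest) {
    jsonlite::write_json(list(
      n_frames = n_frames, times = traj$times, box = traj$box,
      component = traj$component, format = format,
      config = traj$config,
      fibril_beads = traj$fibril$beads, fibril_axis = traj$fibril$axis
    ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path trajectory file (`.pdb` or `.xyz`)
#' @param manifest path of the JSON manifest (default `<path>.json`)
#' @return an `np_trajectory` when the manifest carries the fibril bead
#'   annotation (manifests written by this package do); otherwise a plain
#'   list with `frames` (list of full coordinate matrices, nm), `times`,
#'   `box`, `component`
#' @export
read_trajectory <- function(path, manifest = paste0(path, ".json")) {
  if (!file.exists(manifest))
    np_abort("parse_error", "manifest not found: %s", manifest)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  format <- man$format %||% tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  if (format == "pdb") {
    starts <- grep("^MODEL", lines)
    ends <- grep("^ENDMDL", lines)
    if (length(starts) != length(ends) || length(starts) == 0)
      np_abort("parse_error", "%s: no complete MODEL/ENDMDL blocks", path)
    for (k in seq_along(starts)) {
      at <- lines[(starts[k] + 1):(ends[k] - 1)]
      at <- at[startsWith(at, "ATOM")]
      frames[[k]] <- cbind(as.numeric(substr(at, 31, 38)),
                           as.numeric(substr(at, 39, 46)),
                           as.numeric(substr(at, 47, 54))) / 10
    }
  } else if (format == "xyz") {
    i <- 1L
    while (i <= length(lines)) {
      n <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(n))
        np_abort("parse_error", "%s line %d: expected an atom count", path, i)
      at <- lines[(i + 2):(i + 1 + n)]
      parts <- strsplit(trimws(at), "\\s+")
      frames[[length(frames) + 1L]] <-
        t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))) / 10
      i <- i + 2L + n
    }
  } else np_abort("format_error", "unknown trajectory format '%s'", format)
  raw <- list(frames = frames, times = man$times, box = man$box,
              component = man$component)
  if (is.null(man$fibril_beads)) return(raw)

  np_idx <- man$component$np
  fib <- structure(list(beads = as.data.frame(man$fibril_beads),
                        axis = man$fibril_axis),
                   class = "fibril_model")
  np_coords <- array(NA_real_, c(length(np_idx), 3, length(frames)))
  for (f in seq_along(frames))
    np_coords[, , f] <- frames[[f]][np_idx, , drop = FALSE]
  structure(list(times = man$times, np_coords = np_coords,
                 fibril = fib, np = NULL, box = man$box,
                 component = man$component, config = man$config),
            class = "np_trajectory")
}
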