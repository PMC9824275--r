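# Contact analytics: a fibril residue is "in contact" in a frame when the
# minimum bead-centre distance (minimum image) between any of its beads and
# any NP bead is <= the cutoff (0.8 nm by default, closed boundary).
# "Number of contacts" counts residues in contact, not bead pairs.

CONTACT_CUTOFF_NM <- 0.8

contact_classes <- c("hydrophobic", "polar", "charged")

# min NP distance per fibril residue bead for one frame (Inf beyond cutoff)
residue_min_dists <- function(traj, frame, cutoff) {
  fib <- coords_matrix(traj$fibril$beads)
  np <- traj$np_coords[, , frame, drop = FALSE]
  dim(np) <- dim(np)[1:2]
  cpp_residue_min_dists(fib, seq_len(nrow(fib)), nrow(fib), np,
                        traj$box, cutoff)
}

#' Fibril residues in contact with the NP in one frame
#'
#' @param traj an `np_trajectory`
#' @param frame frame index
#' @param cutoff contact cutoff, nm (closed boundary: a pair exactly at the
#'   cutoff is in contact)
#' @return a data frame of contact records: `frame`, `chain`, `resno`,
#'   `resname`, `class`, `face`, `min_dist`
#' @export
contacts_in_frame <- function(traj, frame, cutoff = CONTACT_CUTOFF_NM) {
  stopifnot(inherits(traj, "np_trajectory"))
  if (!is.numeric(cutoff) || cutoff <= 0)
    np_abort("invalid_argument", "cutoff must be > 0")
  b <- traj$fibril$beads
  if (is.null(b$class) || is.null(b$face))
    np_abort("configuration_error",
             "fibril annotation/face masks missing; run annotate_residues() and define_faces()")
  if (length(traj$component$np) == 0)
    return(data.frame(frame = integer(0), chain = integer(0),
                      resno = integer(0), resname = character(0),
                      class = character(0), face = character(0),
                      min_dist = numeric(0), stringsAsFactors = FALSE))
  d <- residue_min_dists(traj, frame, cutoff)
  hit <- which(is.finite(d))
  data.frame(frame = rep(as.integer(frame), length(hit)),
             chain = b$chain[hit], resno = b$resno[hit],
             resname = b$resname[hit], class = b$class[hit],
             face = b$face[hit], min_dist = d[hit],
             stringsAsFactors = FALSE)
}

#' Class-resolved contact counts over a trajectory
#'
#' @param traj an `np_trajectory`
#' @param cutoff contact cutoff, nm
#' @return a data frame of class `contact_timeseries`: one row per frame with
#'   `frame`, `time`, `total`, `hydrophobic`, `polar`, `charged`
#' @export
contact_timeseries <- function(traj, cutoff = CONTACT_CUTOFF_NM) {
  stopifnot(inherits(traj, "np_trajectory"))
  n <- length(traj$times)
  if (n == 0) np_abort("invalid_argument", "empty trajectory")
  out <- data.frame(frame = seq_len(n), time = traj$times,
                    total = 0L, hydrophobic = 0L, polar = 0L, charged = 0L)
  for (f in seq_len(n)) {
    rec <- contacts_in_frame(traj, f, cutoff)
    out$total[f] <- nrow(rec)
    tab <- table(factor(rec$class, levels = contact_classes))
    out$hydrophobic[f] <- tab[["hydrophobic"]]
    out$polar[f] <- tab[["polar"]]
    out$charged[f] <- tab[["charged"]]
  }
  class(out) <- c("contact_timeseries", "data.frame")
  out
}

#' Time of first sustained contact
#'
#' Returns the time of the first frame that starts a run of at least
#' `persistence` consecutive frames with one or more contacts, or `NA` if no
#' such run exists. With `persistence = 1` this is the raw first contact.
#'
#' @param series a [contact_timeseries()] data frame (or any data frame with
#'   `time` and `total` columns)
#' @param persistence required run length in frames (>= 1)
#' @return first contact time (pseudo-ns) or `NA_real_`
#' @export
first_contact_time <- function(series, persistence = 1) {
  if (!is.data.frame(series) || nrow(series) == 0)
    np_abort("invalid_argument", "empty contact series")
  if (!is.numeric(persistence) || persistence < 1)
    np_abort("invalid_argument", "persistence must be >= 1")
  persistence <- as.integer(persistence)
  has <- series$total > 0
  r <- rle(has)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= persistence)
  if (length(ok) == 0) return(NA_real_)
  series$time[starts[ok[1]]]
}

#' Per-residue contact frequency
#'
#' Fraction of frames in which each residue is in contact with the NP,
#' aggregated per sequence position (a position counts as contacting in a
#' frame when any of the chains is in contact at that position) or reported
#' per chain instance.
#'
#' @param traj an `np_trajectory`
#' @param cutoff contact cutoff, nm
#' @param aggregate `"position"` (default) or `"chain"`
#' @return a data frame with `resno`, `resname`, `frequency` (and `chain`
#'   when `aggregate = "chain"`)
#' @export
residue_contact_frequency <- function(traj, cutoff = CONTACT_CUTOFF_NM,
                                      aggregate = c("position", "chain")) {
  stopifnot(inherits(traj, "np_trajectory"))
  aggregate <- match.arg(aggregate)
  n <- length(traj$times)
  if (n == 0) np_abort("invalid_argument", "empty trajectory")
  b <- traj$fibril$beads
  if (aggregate == "position") {
    counts <- setNames(numeric(42), 1:42)
    for (f in seq_len(n)) {
      rec <- contacts_in_frame(traj, f, cutoff)
      pos <- unique(rec$resno)
      counts[pos] <- counts[pos] + 1
    }
    aa <- b$resname[match(1:42, b$resno)]
    data.frame(resno = 1:42, resname = aa, frequency = unname(counts) / n,
               stringsAsFactors = FALSE)
  } else {
    key <- paste(b$chain, b$resno)
    counts <- setNames(numeric(length(key)), key)
    for (f in seq_len(n)) {
      rec <- contacts_in_frame(traj, f, cutoff)
      k <- paste(rec$chain, rec$resno)
      counts[k] <- counts[k] + 1
    }
    data.frame(chain = b$chain, resno = b$resno, resname = b$resname,
               frequency = unname(counts) / n, stringsAsFactors = FALSE)
  }
}

#' Classify the contact type of a trajectory as side, frontal or none
#'
#' Pools all contact events (residue-frame pairs) from the first contact
#' frame onward; the trajectory is `"frontal"` when the fraction of events on
#' frontal-face residues exceeds `threshold`, `"side"` otherwise (ties break
#' to side, the modal outcome for lateral binding), and `"none"` when no
#' contact is ever observed.
#'
#' @param traj an `np_trajectory` (or a pooled contact-record data frame with
#'   a `face` column)
#' @param threshold frontal fraction above which the label is frontal
#' @param cutoff contact cutoff, nm (trajectory input only)
#' @return `"side"`, `"frontal"` or `"none"`
#' @export
classify_contact_type <- function(traj, threshold = 0.5,
                                  cutoff = CONTACT_CUTOFF_NM) {
  if (inherits(traj, "np_trajectory")) {
    b <- traj$fibril$beads
    if (is.null(b$face))
      np_abort("configuration_error", "face masks are not defined")
    recs <- lapply(seq_along(traj$times), contacts_in_frame,
                   traj = traj, cutoff = cutoff)
    first <- which(vapply(recs, nrow, 0L) > 0)
    if (length(first) == 0) return("none")
    rec <- do.call(rbind, recs[first[1]:length(recs)])
  } else {
    rec <- traj
    if (is.null(rec$face))
      np_abort("configuration_error", "face masks are not defined")
    if (nrow(rec) == 0) return("none")
  }
  frontal_frac <- mean(rec$face == "frontal")
  if (frontal_frac > threshold) "frontal" else "side"
}

#' Contact counts by residue class
#'
#' @param records a contact-record data frame (from [contacts_in_frame()] or
#'   pooled over frames)
#' @return named integer vector with counts for hydrophobic, polar, charged
#' @export
class_breakdown <- function(records) {
  if (!is.data.frame(records))
    np_abort("invalid_argument", "records must be a data frame")
  if (nrow(records) > 0 &&
      (is.null(records$class) || anyNA(records$class) ||
       !all(records$class %in% contact_classes)))
    np_abort("annotation_error", "records carry missing or unknown residue classes")
  tab <- table(factor(records$class, levels = contact_classes))
  setNames(as.integer(tab), contact_classes)
}

#' Full contact summary of one trajectory
#'
#' Bundles the per-frame class-resolved counts, the per-position contact
#' frequencies, the first-contact time and the side/frontal/none label.
#'
#' @param traj an `np_trajectory`
#' @param cutoff contact cutoff, nm
#' @param persistence first-contact persistence filter, frames
#' @param threshold frontal classification threshold
#' @return an object of class `contact_summary`
#' @export
contact_summary <- function(traj, cutoff = CONTACT_CUTOFF_NM,
                            persistence = 1, threshold = 0.5) {
  series <- contact_timeseries(traj, cutoff)
  structure(list(
    timeseries = series,
    residue_frequency = residue_contact_frequency(traj, cutoff),
    first_contact = first_contact_time(series, persistence),
    contact_type = classify_contact_type(traj, threshold, cutoff),
    class_totals = c(hydrophobic = sum(series$hydrophobic),
                     polar = sum(series$polar),
                     charged = sum(series$charged)),
    cutoff = cutoff, persistence = persistence, threshold = threshold
  ), class = "contact_summary")
}

#' @export
print.contact_summary <- function(x, ...) {
  cat(sprintf("<contact_summary> type: %s; first contact: %s\n",
              x$contact_type,
              if (is.na(x$first_contact)) "never"
              else sprintf("%.3g pseudo-ns", x$first_contact)))
  cat(sprintf("  pooled class events: hydrophobic %d, polar %d, charged %d\n",
              x$class_totals[["hydrophobic"]], x$class_totals[["polar"]],
              x$class_totals[["charged"]]))
  top <- head(x$residue_frequency[order(-x$residue_frequency$frequency), ], 5)
  if (any(top$frequency > 0)) {
    cat("  most-contacted positions:",
        paste(sprintf("%s%d (%.0f%%)", aa3_to_1(top$resname), top$resno,
                      100 * top$frequency), collapse = ", "), "\n")
  }
  invisible(x)
}
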