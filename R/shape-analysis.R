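# Moments of inertia, lowest-MOI alignment and the shape factor
# SF = 1 - Ix / ((Iy + Iz) / 2), where Ix is the smallest principal moment
# after aligning its axis to x. SF is 0 for a uniform sphere and exactly 1
# for a collinear (one-dimensional) bead arrangement, and lies in [0, 1]
# whenever Ix is the minimum moment.

inertia_tensor <- function(coords, masses) {
  com <- colSums(coords * masses) / sum(masses)
  d <- sweep(coords, 2, com)
  r2 <- rowSums(d^2)
  I <- diag(c(sum(masses * r2), sum(masses * r2), sum(masses * r2)))
  for (a in 1:3) for (b in 1:3)
    I[a, b] <- I[a, b] - sum(masses * d[, a] * d[, b])
  I
}

#' Principal moments of inertia
#'
#' Eigen-decomposition of the inertia tensor about the centre of mass, with
#' point masses (no per-bead inertia). Moments are returned in ascending
#' order together with their axes (columns of `axes`).
#'
#' @param coords bead coordinate matrix (nm) or an object with beads
#'   (`nanoparticle`, `fibril_model`)
#' @param masses bead masses, Da (default: bead masses of the object, or unit
#'   masses for a plain matrix)
#' @return list with `moments` (ascending, mass nm^2) and `axes` (3x3,
#'   columns are the principal axes)
#' @export
principal_moments <- function(coords, masses = NULL) {
  xm <- resolve_coords_masses(coords, masses)
  coords <- xm$coords; masses <- xm$masses
  if (nrow(coords) < 1)
    np_abort("invalid_argument", "need at least one bead")
  if (sum(masses) <= 0)
    np_abort("invalid_argument", "total mass must be > 0")
  I <- inertia_tensor(coords, masses)
  e <- eigen(I, symmetric = TRUE)
  ord <- order(e$values)
  list(moments = e$values[ord], axes = e$vectors[, ord, drop = FALSE])
}

resolve_coords_masses <- function(coords, masses) {
  if (inherits(coords, "nanoparticle") || inherits(coords, "fibril_model")) {
    obj <- coords
    coords <- coords_matrix(obj$beads)
    if (is.null(masses)) masses <- obj$beads$mass %||% rep(1, nrow(coords))
  } else {
    coords <- as.matrix(coords)
    if (is.null(masses)) masses <- rep(1, nrow(coords))
  }
  list(coords = coords, masses = as.numeric(masses))
}

#' Align the lowest-moment principal axis with x
#'
#' Rigid rotation (about the centre of mass) that maps the principal axis of
#' the smallest moment of inertia onto x, the middle one onto y and the
#' largest onto z. Degenerate (equal-moment) cases are resolved
#' deterministically: eigenvectors are taken in ascending-moment order and
#' each axis sign is fixed so that the bead with the largest absolute
#' projection projects positively; the third axis completes a right-handed
#' frame.
#'
#' @inheritParams principal_moments
#' @return the rotated coordinate matrix (centre of mass preserved)
#' @export
align_lowest_moi_to_x <- function(coords, masses = NULL) {
  xm <- resolve_coords_masses(coords, masses)
  coords <- xm$coords; masses <- xm$masses
  pm <- principal_moments(coords, masses)
  com <- colSums(coords * masses) / sum(masses)
  d <- sweep(coords, 2, com)
  ax <- pm$axes
  for (j in 1:2) {
    proj <- d %*% ax[, j]
    i <- which.max(abs(proj))
    if (proj[i] < 0) ax[, j] <- -ax[, j]
  }
  ax[, 3] <- c(ax[2, 1] * ax[3, 2] - ax[3, 1] * ax[2, 2],
               ax[3, 1] * ax[1, 2] - ax[1, 1] * ax[3, 2],
               ax[1, 1] * ax[2, 2] - ax[2, 1] * ax[1, 2])
  sweep(d %*% ax, 2, com, `+`)
}

#' Shape factor of a bead cloud
#'
#' `SF = 1 - Ix / ((Iy + Iz) / 2)` with `Ix <= Iy <= Iz` the principal
#' moments of inertia after lowest-MOI alignment: 0 for a perfectly round
#' particle, 1 for a one-dimensional rod.
#'
#' @inheritParams principal_moments
#' @return the shape factor (dimensionless, in `[0, 1]`)
#' @examples
#' shape_factor(cbind(1:100, 0, 0))  # collinear beads: exactly 1
#' @export
shape_factor <- function(coords, masses = NULL) {
  xm <- resolve_coords_masses(coords, masses)
  if (nrow(xm$coords) < 2)
    np_abort("invalid_argument", "need at least 2 beads")
  pm <- principal_moments(xm$coords, xm$masses)
  if (pm$moments[3] <= 0)
    np_abort("degenerate_geometry", "all beads are collocated")
  1 - pm$moments[1] / ((pm$moments[2] + pm$moments[3]) / 2)
}

#' Shape factor along a trajectory
#'
#' Computes the principal moments and shape factor of the nanoparticle beads
#' in each requested frame. With `frames = "ends"` only the first and last
#' frames are reported (the start/end comparison of interest for a rigid or
#' slowly deforming particle).
#'
#' @param traj an `np_trajectory`
#' @param frames `"ends"`, `"all"`, or an integer vector of frame indices
#' @return a data frame with `frame`, `time`, `Ix`, `Iy`, `Iz`, `SF`
#' @export
shape_timeseries <- function(traj, frames = c("ends", "all")) {
  stopifnot(inherits(traj, "np_trajectory"))
  if (dim(traj$np_coords)[1] == 0)
    np_abort("invalid_argument", "trajectory has no nanoparticle beads")
  if (is.character(frames)) {
    frames <- match.arg(frames)
    idx <- if (frames == "ends") c(1L, length(traj$times))
           else seq_along(traj$times)
  } else idx <- as.integer(frames)
  masses <- traj$np$beads$mass
  out <- data.frame(frame = idx, time = traj$times[idx],
                    Ix = NA_real_, Iy = NA_real_, Iz = NA_real_,
                    SF = NA_real_)
  for (r in seq_along(idx)) {
    xyz <- traj$np_coords[, , idx[r]]
    pm <- principal_moments(xyz, masses)
    out$Ix[r] <- pm$moments[1]; out$Iy[r] <- pm$moments[2]
    out$Iz[r] <- pm$moments[3]
    out$SF[r] <- 1 - pm$moments[1] / ((pm$moments[2] + pm$moments[3]) / 2)
  }
  out
}
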