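# Internal helpers: classed errors, seed handling, small geometry utilities.

np_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "npfibril_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    np_abort("invalid_argument", "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-task child seed from a master seed
#'
#' Deterministic arithmetic derivation (no RNG involved) so that fixture
#' suites can hand every subsystem its own reproducible stream. Results stay
#' in `[1, 2^31 - 2]`.
#'
#' @param master single integer master seed
#' @param k task index (non-negative integer)
#' @return a single integer seed
#' @export
derive_seed <- function(master, k) {
  m <- 2147483629  # large prime < 2^31
  x <- (as.numeric(master) %% m) * 48271 %% m
  x <- (x + as.numeric(k) * 1000003 + 12345) %% m
  as.integer(x + 1)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Uniform random rotation matrix (draws from the caller's RNG stream).
random_rotation <- function() {
  # quaternion method (Shoemake); uniform over SO(3)
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_to_mat(q)
}

quat_to_mat <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rotation_from_axis_angle <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-14) return(diag(3))
  k <- v / theta
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

centroid <- function(x) colMeans(x)

# mass-weighted radius of gyration
radius_of_gyration <- function(coords, masses = NULL) {
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  com <- colSums(coords * masses) / sum(masses)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

coords_matrix <- function(beads) as.matrix(beads[, c("x", "y", "z")])

set_coords <- function(beads, m) {
  beads$x <- m[, 1]; beads$y <- m[, 2]; beads$z <- m[, 3]
  beads
}

#' Sample points uniformly in a solid ball
#'
#' Convenience generator used for geometric calibration of the shape and
#' diameter estimators (a uniform ball has known closed-form moments).
#'
#' @param n number of points
#' @param radius ball radius (nm)
#' @param seed RNG seed
#' @return an `n x 3` matrix of coordinates
#' @export
sample_ball <- function(n, radius = 1, seed = 1) {
  with_seed(seed, {
    m <- matrix(rnorm(3 * n), ncol = 3)
    m <- m / sqrt(rowSums(m^2))
    r <- radius * runif(n)^(1 / 3)
    m * r
  })
}
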