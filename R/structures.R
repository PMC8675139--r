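## Core in-memory types: molecular configurations (a snapshot of atoms with
## optional energy/force labels) and local atomic environments (a center atom
## plus displacement vectors to its neighbors inside the outer cutoff).
## Molecules in vacuum only: neighbor lists are brute-force O(N^2) pair scans,
## free boundary conditions, no periodic images.

#' Atomic configuration
#'
#' A molecule snapshot: chemical elements, Cartesian positions (Angstrom) and
#' optional labels (total energy in eV, per-atom forces in eV/Angstrom).
#'
#' @param elements character vector of element symbols.
#' @param positions numeric `N x 3` matrix, Angstrom.
#' @param energy optional total energy label (eV).
#' @param forces optional `N x 3` force label matrix (eV/Angstrom).
#' @param info optional named list of free-form metadata.
#' @return object of class `"atomic_config"`.
#' @export
atomic_configuration <- function(elements, positions, energy = NULL,
                                 forces = NULL, info = list()) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  if (length(elements) != n) stop("elements and positions disagree in length")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (n > 1) {
    d <- dist(positions)
    if (any(d == 0)) stop("coincident atoms (zero pairwise distance)")
  }
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    storage.mode(forces) <- "double"
    if (!all(dim(forces) == c(n, 3))) {
      stop("forces must be an N x 3 matrix matching the atom count")
    }
  }
  if (!is.null(energy)) {
    stopifnot(is.numeric(energy), length(energy) == 1L, is.finite(energy))
    energy <- as.numeric(energy)
  }
  structure(list(elements = as.character(elements), positions = positions,
                 energy = energy, forces = forces, info = info),
            class = "atomic_config")
}

#' @export
print.atomic_config <- function(x, ...) {
  cat(sprintf("Atomic configuration: %d atoms (%s)%s%s\n",
              length(x$elements),
              paste(names(table(x$elements)), table(x$elements),
                    sep = "", collapse = " "),
              if (!is.null(x$energy)) sprintf(", E = %.6f eV", x$energy) else "",
              if (!is.null(x$forces)) ", forces labeled" else ""))
  invisible(x)
}

#' Number of atoms
#' @param config an [atomic_configuration()].
#' @return integer atom count.
#' @export
n_atoms <- function(config) length(config$elements)

#' Atomic environment
#'
#' The local neighborhood of one atom: its element, the elements of its
#' neighbors, and displacement vectors `r_j - r_i` (Angstrom). All neighbor
#' distances must be positive and (by construction from a neighbor list) at
#' most the outer cutoff.
#'
#' @param center_element element symbol of the central atom.
#' @param neighbor_elements character vector for the neighbors.
#' @param displacements `m x 3` matrix of displacement vectors.
#' @param neighbor_index optional original atom indices of the neighbors
#'   (used for force assembly).
#' @return object of class `"atomic_env"`.
#' @export
atomic_environment <- function(center_element, neighbor_elements,
                               displacements, neighbor_index = NULL) {
  displacements <- matrix(as.numeric(displacements),
                          ncol = 3,
                          nrow = length(neighbor_elements))
  if (length(neighbor_elements) > 0) {
    d2 <- rowSums(displacements^2)
    if (any(d2 == 0)) stop("coincident neighbor (zero displacement)")
  }
  structure(list(center_element = as.character(center_element),
                 neighbor_elements = as.character(neighbor_elements),
                 displacements = displacements,
                 neighbor_index = neighbor_index),
            class = "atomic_env")
}

#' Neighbor list and atomic environments of a configuration
#'
#' Builds, for every atom, the environment of neighbors within `r_cut` by a
#' brute-force pair scan (molecules in vacuum; no periodic images).
#'
#' @param config an [atomic_configuration()].
#' @param r_cut cutoff radius (Angstrom).
#' @return list of [atomic_environment()] objects, one per atom.
#' @export
configuration_environments <- function(config, r_cut) {
  pos <- config$positions
  n <- nrow(pos)
  envs <- vector("list", n)
  if (n == 1) {
    envs[[1]] <- atomic_environment(config$elements[1], character(0),
                                    matrix(0, 0, 3), integer(0))
    return(envs)
  }
  d2 <- as.matrix(dist(pos))^2
  rc2 <- r_cut^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] <= rc2 & seq_len(n) != i)
    disp <- if (length(nb)) {
      pos[nb, , drop = FALSE] - matrix(pos[i, ], length(nb), 3, byrow = TRUE)
    } else {
      matrix(0, 0, 3)
    }
    envs[[i]] <- atomic_environment(config$elements[i], config$elements[nb],
                                    disp, nb)
  }
  envs
}

## --- small geometry helpers -------------------------------------------------

#' Random rotation (or reflection) matrix
#'
#' Draws a Haar-distributed orthogonal 3x3 matrix; with `proper = TRUE` the
#' determinant is forced to +1, otherwise the sign is random (full O(3)).
#' Used by the invariance test-suite.
#'
#' @param proper restrict to SO(3)?
#' @return 3x3 orthogonal matrix.
#' @export
random_rotation <- function(proper = FALSE) {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (proper && det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Apply a rigid rotation to a configuration or environment
#' @param x an [atomic_configuration()] or [atomic_environment()].
#' @param Q 3x3 orthogonal matrix.
#' @return object of the same class with rotated coordinates.
#' @export
rotate_structure <- function(x, Q) {
  if (inherits(x, "atomic_config")) {
    atomic_configuration(x$elements, x$positions %*% t(Q),
                         energy = x$energy,
                         forces = if (!is.null(x$forces)) x$forces %*% t(Q),
                         info = x$info)
  } else if (inherits(x, "atomic_env")) {
    atomic_environment(x$center_element, x$neighbor_elements,
                       x$displacements %*% t(Q), x$neighbor_index)
  } else {
    stop("rotate_structure: unsupported object")
  }
}

## signed dihedral angle (radians, (-pi, pi]) and its analytic gradient
## wrt the four atom positions (rows of a 4 x 3 matrix)
.dihedral_angle <- function(p1, p2, p3, p4, grad = FALSE) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  nb2 <- sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / nb2
  phi <- atan2(sum(m1 * n2), sum(n1 * n2))
  if (!grad) return(phi)
  g1 <- nb2 / sum(n1^2) * n1
  g4 <- -nb2 / sum(n2^2) * n2
  tt <- sum(b1 * b2) / sum(b2^2)
  ss <- sum(b3 * b2) / sum(b2^2)
  g2 <- -(1 + tt) * g1 + ss * g4
  g3 <- tt * g1 - (1 + ss) * g4
  list(phi = phi, grad = rbind(g1, g2, g3, g4))
}

#' Signed dihedral angle
#'
#' IUPAC signed dihedral in degrees, range (-180, 180].
#'
#' @param config an [atomic_configuration()].
#' @param idx integer 4-vector of atom indices.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(config, idx) {
  stopifnot(length(idx) == 4)
  p <- config$positions
  phi <- .dihedral_angle(p[idx[1], ], p[idx[2], ], p[idx[3], ], p[idx[4], ])
  deg <- phi * 180 / pi
  if (deg <= -180) deg <- deg + 360
  deg
}
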