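## Projection of the neighborhood density onto the one-particle basis
## phi_{znlm}(r_ij) = R_n(|r_ij|) Y_lm(r_ij / |r_ij|), per element channel z.
## The atomic base A_{z_i v} is the single sum of phi over neighbors of the
## matching element; its per-neighbor gradients feed force assembly.

## Flat index over the one-particle labels v = (z, n, l, m):
##   v = ((iz - 1) * n_max + (n - 1)) * (l_max + 1)^2 + l^2 + l + m + 1
## where iz is the position of z in the declared element set.
.v_index <- function(iz, n, l, m, n_max, l_max) {
  nlm <- (l_max + 1L)^2
  ((iz - 1L) * n_max + (n - 1L)) * nlm + l^2 + l + m + 1L
}

.n_v <- function(n_elements, n_max, l_max) {
  n_elements * n_max * (l_max + 1L)^2
}

#' One-particle basis at a single displacement
#'
#' Evaluates `phi_{znlm}(r) = R_n(|r|) Y_lm(r-hat)` for all `(n, l, m)` with
#' `l <= l_max`, in the element channel of the given neighbor (all other
#' channels are zero), together with the gradient with respect to the
#' displacement vector.
#'
#' @param displacement length-3 vector (Angstrom), nonzero.
#' @param element element symbol of the neighbor.
#' @param spec a [radial_spec()].
#' @param polys matching [build_orthogonal_polynomials()].
#' @param l_max maximum angular degree.
#' @param elements declared element set of the model.
#' @return list with `phi` (length `n_elements * n_max * (l_max+1)^2`) and
#'   `grad` (`3 x length(phi)` matrix).
#' @export
evaluate_one_particle_basis <- function(displacement, element, spec, polys,
                                        l_max, elements) {
  env <- atomic_environment(elements[1], element,
                            matrix(displacement, 1, 3))
  pr <- .project_env(env, spec, polys, l_max, elements)
  list(phi = pr$A, grad = matrix(pr$dA[1, , ], nrow = 3))
}

## Core per-environment projection. Returns
##   A  : numeric n_v
##   dA : array (n_neigh, 3, n_v), gradient of A wrt each neighbor position
.project_env <- function(env, spec, polys, l_max, elements) {
  n_max <- spec$n_max
  nv <- .n_v(length(elements), n_max, l_max)
  m <- length(env$neighbor_elements)
  A <- numeric(nv)
  dA <- array(0, c(m, 3, nv))
  if (m == 0) return(list(A = A, dA = dA))
  iz <- match(env$neighbor_elements, elements)
  if (anyNA(iz)) {
    stop("environment contains element(s) not declared in the model: ",
         paste(unique(env$neighbor_elements[is.na(iz)]), collapse = ", "))
  }
  ## canonical neighbor order: the sum over neighbors is accumulated in a
  ## deterministic order, so permuting the input neighbor list leaves A (and
  ## everything downstream) bit-identical; gradients are mapped back to the
  ## input order below
  ord <- order(iz, env$displacements[, 1], env$displacements[, 2],
               env$displacements[, 3])
  iz <- iz[ord]
  disp <- env$displacements[ord, , drop = FALSE]
  r <- sqrt(rowSums(disp^2))
  rb <- evaluate_radial_basis(r, spec, polys)
  sh <- real_spherical_harmonics(disp, l_max, grad = TRUE)
  nlm <- (l_max + 1L)^2
  u <- disp / r  # unit vectors, rows
  for (nn in seq_len(n_max)) {
    Rn <- rb$R[, nn]
    dRn <- rb$dR[, nn]
    ## phi_j = Rn_j * Y_j,lm ; dphi_j = dRn_j * u_j * Y + Rn_j * dY
    base <- (iz - 1L) * n_max * nlm + (nn - 1L) * nlm
    for (j in seq_len(m)) {
      cols <- base[j] + seq_len(nlm)
      A[cols] <- A[cols] + Rn[j] * sh$Y[j, ]
      jo <- ord[j]   # gradient row in the caller's neighbor order
      for (d in 1:3) {
        dA[jo, d, cols] <- dRn[j] * u[j, d] * sh$Y[j, ] + Rn[j] * sh$dY[j, d, ]
      }
    }
  }
  list(A = A, dA = dA)
}

#' Project the neighborhood density onto the one-particle basis
#'
#' Forms the atomic base `A_{z_i v} = sum_j phi_v(r_ij)` (the single sum over
#' neighbors of the matching element channel) and its per-neighbor gradients.
#'
#' @param env an [atomic_environment()].
#' @inheritParams evaluate_one_particle_basis
#' @return object of class `"atomic_base"`: list with `A` (values over the
#'   flat multi-index), `dA` (`n_neigh x 3 x n_v` gradient array), and the
#'   index metadata (`elements`, `n_max`, `l_max`).
#' @export
project_density <- function(env, spec, polys, l_max, elements) {
  pr <- .project_env(env, spec, polys, l_max, elements)
  structure(list(A = pr$A, dA = pr$dA, elements = elements,
                 n_max = spec$n_max, l_max = as.integer(l_max)),
            class = "atomic_base")
}
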