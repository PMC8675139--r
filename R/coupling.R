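## Generalized coupling coefficients for O(3)-invariant contractions of
## products of real spherical harmonics, obtained numerically: the invariant
## subspace of the tensor-product rotation action is the common fixed space of
## a few generic rotations (plus inversion, which restricts to even total l).
## This avoids error-prone real-harmonic Clebsch-Gordan bookkeeping; the
## random-rotation invariance tests certify correctness independently of any
## convention.

## Wigner-D matrix of a 3x3 orthogonal Q in the real-harmonic convention of
## real_spherical_harmonics(): Y_l(Q u) = D_l(Q) Y_l(u). Solved exactly (to
## machine precision) from a fixed deterministic set of sample directions.
.wigner_d_real <- function(l, Q) {
  if (l == 0) return(matrix(1, 1, 1))
  k <- 2L * (2L * l + 1L) + 4L
  ## deterministic, reasonably uniform directions (Fibonacci sphere)
  i <- seq_len(k)
  zs <- 1 - 2 * (i - 0.5) / k
  th <- acos(pmin(1, pmax(-1, zs)))
  ph <- i * pi * (3 - sqrt(5))
  U <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  cols <- l^2 + l + ((-l):l) + 1L
  Y0 <- real_spherical_harmonics(U, l, grad = FALSE)$Y[, cols, drop = FALSE]
  Y1 <- real_spherical_harmonics(U %*% t(Q), l, grad = FALSE)$Y[, cols,
                                                                drop = FALSE]
  ## Y1 = Y0 %*% t(D)
  t(qr.solve(Y0, Y1))
}

## Deterministic "generic" rotations used for the invariance constraints.
.coupling_rotations <- function() {
  rot <- function(axis, angle) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2],
                  -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  }
  list(rot(c(0.32, -0.85, 0.41), 1.0471),
       rot(c(-0.74, 0.12, 0.66), 2.2214),
       rot(c(0.55, 0.61, -0.57), 0.7321))
}

## Orthonormal basis (columns) of the space of invariant coupling tensors for
## an l-sequence (l_1, ..., l_nu), as vectors of length prod(2 l_t + 1) in
## row-major order over (m_1, ..., m_nu) (m_1 slowest). May have 0 columns.
.invariant_couplings <- function(ls) {
  nu <- length(ls)
  dims <- 2L * ls + 1L
  P <- prod(dims)
  if (sum(ls) %% 2 == 1) return(matrix(0, P, 0))  # inversion kills odd total l
  if (nu == 1) {
    if (ls[1] == 0) return(matrix(1, 1, 1)) else return(matrix(0, P, 0))
  }
  rots <- .coupling_rotations()
  M <- matrix(0, 0, P)
  for (Q in rots) {
    K <- matrix(1, 1, 1)
    for (t in seq_len(nu)) K <- kronecker(K, .wigner_d_real(ls[t], Q))
    M <- rbind(M, K - diag(P))
  }
  sv <- svd(M, nu = 0, nv = P)
  keep <- sv$d < 1e-8 * max(sv$d, 1)
  ## svd() returns d of length min(nrow, P) = P here (nrow >= P)
  V <- sv$v[, keep, drop = FALSE]
  V
}

## Decode flat tensor index p (1..prod(dims)) to the m-combination, with the
## first factor slowest (consistent with kronecker()).
.decode_m <- function(p, ls) {
  dims <- 2L * ls + 1L
  nu <- length(ls)
  out <- integer(nu)
  p0 <- p - 1L
  for (t in nu:1) {
    out[t] <- p0 %% dims[t]
    p0 <- p0 %/% dims[t]
  }
  out - ls  # shift 0..2l -> -l..l
}

## Permutation of flat tensor indices induced by permuting factors `perm`
## (valid only when the permuted dims coincide, i.e. equal l's are swapped).
.tensor_perm <- function(ls, perm) {
  dims <- 2L * ls + 1L
  P <- prod(dims)
  arr <- array(seq_len(P), dim = rev(dims))       # first factor slowest
  ap <- aperm(arr, rev(length(ls) + 1 - perm))
  ## Map: new flat index -> old flat index. Build by permuting the array of
  ## indices laid out in kronecker order.
  as.vector(ap)
}

## Symmetrize invariant coupling columns over permutations of identical
## factor groups, then re-orthonormalize; returns matrix with possibly fewer
## columns.
.symmetrize_couplings <- function(V, ls, groups) {
  if (ncol(V) == 0) return(V)
  perms <- .group_permutations(groups, length(ls))
  if (length(perms) > 1) {
    W <- matrix(0, nrow(V), ncol(V))
    for (pr in perms) {
      idx <- .tensor_perm(ls, pr)
      W <- W + V[idx, , drop = FALSE]
    }
    W <- W / length(perms)
    sv <- svd(W)
    keep <- sv$d > 1e-10 * max(sv$d, 1e-300)
    V <- sv$u[, keep, drop = FALSE]
  }
  V
}

## All permutations of 1..nu that permute only within identical-factor groups.
## `groups` is an integer vector of group labels per slot.
.group_permutations <- function(groups, nu) {
  perm_list <- list(seq_len(nu))
  for (g in unique(groups)) {
    slots <- which(groups == g)
    if (length(slots) < 2) next
    ps <- .all_perms(length(slots))
    new_list <- list()
    for (base in perm_list) {
      for (p in ps) {
        q <- base
        q[slots] <- base[slots][p]
        new_list[[length(new_list) + 1L]] <- q
      }
    }
    perm_list <- new_list
  }
  perm_list
}

.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- .all_perms(n - 1L)
    for (r in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[r])
  }
  out
}
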