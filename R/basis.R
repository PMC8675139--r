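## The symmetric (B-) basis: enumerate candidate A-products by correlation
## order and polynomial degree, symmetrize them over O(3) into invariant
## B-functions via numerically solved coupling coefficients, prune linear
## dependencies by a rank-revealing factorization on sample environments, and
## evaluate values and gradients through the density trick (cost linear in
## the neighbor count, independent of correlation order).

#' Basis selection parameters
#'
#' The three truncation parameters of the ACE basis: maximum correlation
#' order `nu_max`, per-order polynomial degree caps `D_nu^max` (with degree
#' `D = sum_t n_t + w_Y l_t`), and the radial/angular trade-off weight `w_Y`.
#'
#' @param elements declared element set (character vector).
#' @param nu_max maximum correlation order. Default: 4 for up to three
#'   distinct elements, 3 for four or more.
#' @param degree_caps numeric vector of length `nu_max`, degree cap per
#'   correlation order.
#' @param w_Y angular degree weight (default 2).
#' @return object of class `"basis_selection"`.
#' @export
basis_selection <- function(elements,
                            nu_max = if (length(elements) <= 3) 4L else 3L,
                            degree_caps = rep(8, nu_max),
                            w_Y = 2) {
  elements <- as.character(elements)
  if (length(elements) == 0) stop("empty element set")
  if (anyDuplicated(elements)) stop("duplicated elements in selection")
  nu_max <- as.integer(nu_max)
  if (nu_max < 1) stop("nu_max must be >= 1")
  if (length(degree_caps) == 1) degree_caps <- rep(degree_caps, nu_max)
  if (length(degree_caps) != nu_max) {
    stop("degree_caps must have one entry per correlation order")
  }
  if (any(degree_caps <= 0)) stop("degree caps must be positive")
  structure(list(elements = elements, nu_max = nu_max,
                 degree_caps = as.numeric(degree_caps), w_Y = w_Y),
            class = "basis_selection")
}

## l_max implied by the degree caps: l_max = floor(max_nu D_nu^max / w_Y)
.l_max_of <- function(selection) {
  as.integer(floor(max(selection$degree_caps) / selection$w_Y))
}

## The single-factor index table: all (iz, n, l) with n + w_Y l <= max cap,
## ordered lexicographically (the canonical factor order, m excluded).
.factor_table <- function(selection, n_max) {
  wy <- selection$w_Y
  dmax <- max(selection$degree_caps)
  lmax <- .l_max_of(selection)
  rows <- list()
  for (iz in seq_along(selection$elements)) {
    for (n in seq_len(n_max)) {
      for (l in 0:lmax) {
        d <- n + wy * l
        if (d <= dmax) rows[[length(rows) + 1L]] <- c(iz, n, l, d)
      }
    }
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("iz", "n", "l", "deg")
  tab
}

## Enumerate canonical (sorted, nondecreasing factor-index) skeletons:
## tuples of rows of the factor table with nu <= nu_max and degree within the
## per-order caps. Returns a list of integer vectors (factor-table rows).
.enumerate_skeletons <- function(selection, n_max) {
  tab <- .factor_table(selection, n_max)
  caps <- selection$degree_caps
  numax <- selection$nu_max
  out <- list()
  recurse <- function(prefix, last, deg) {
    len <- length(prefix)
    if (len > 0 && deg <= caps[len]) out[[length(out) + 1L]] <<- prefix
    if (len == numax) return()
    maxrest <- max(caps[(len + 1L):numax])
    for (idx in last:nrow(tab)) {
      nd <- deg + tab[idx, "deg"]
      if (nd <= maxrest) recurse(c(prefix, idx), idx, nd)
    }
  }
  recurse(integer(0), 1L, 0)
  out
}

#' Enumerate candidate A-product specifications
#'
#' All canonical products of one-particle basis functions with correlation
#' order at most `nu_max` and polynomial degree `D = sum_t (n_t + w_Y l_t)`
#' at most `D_nu^max`, m-resolved and deduplicated under the canonical factor
#' order (lexicographic on `(z, n, l, m)`).
#'
#' @param selection a [basis_selection()].
#' @param n_max number of radial functions.
#' @return list of product specs; each is a matrix with columns
#'   `iz, n, l, m` and one row per factor, rows canonically sorted, plus
#'   attributes `nu` and `degree`.
#' @export
enumerate_product_specs <- function(selection, n_max) {
  tab <- .factor_table(selection, n_max)
  skels <- .enumerate_skeletons(selection, n_max)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (sk in skels) {
    rows <- tab[sk, , drop = FALSE]
    ls <- rows[, "l"]
    mgrid <- do.call(expand.grid, lapply(ls, function(l) (-l):l))
    for (g in seq_len(nrow(mgrid))) {
      mat <- cbind(rows[, c("iz", "n", "l"), drop = FALSE],
                   m = as.integer(mgrid[g, ]))
      ord <- order(mat[, 1], mat[, 2], mat[, 3], mat[, 4])
      mat <- mat[ord, , drop = FALSE]
      key <- paste(t(mat), collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      attr(mat, "nu") <- nrow(mat)
      attr(mat, "degree") <- sum(mat[, "n"] + selection$w_Y * mat[, "l"])
      out[[length(out) + 1L]] <- mat
    }
  }
  out
}

## cache environment for invariant coupling blocks, keyed by the l-sequence
## and the identical-factor grouping pattern
.coupling_cache <- new.env(parent = emptyenv())

## Invariant couplings for a skeleton: rows (iz, n, l). Returns a matrix of
## coupling columns over the m-combinations (possibly 0 columns).
.skeleton_couplings <- function(skel_rows) {
  ls <- as.integer(skel_rows[, "l"])
  key_rows <- paste(skel_rows[, "iz"], skel_rows[, "n"], skel_rows[, "l"],
                    sep = ":")
  groups <- match(key_rows, unique(key_rows))
  key <- paste(paste(ls, collapse = ","), paste(groups, collapse = ","),
               sep = "|")
  hit <- .coupling_cache[[key]]
  if (!is.null(hit)) return(hit)
  V <- .invariant_couplings(ls)
  V <- .symmetrize_couplings(V, ls, groups)
  .coupling_cache[[key]] <- V
  V
}

#' Symmetrize an A-product into O(3)-invariant basis functions
#'
#' For the `(z, n, l)` skeleton of the given product specification, returns a
#' spanning set of all rotation- and reflection-invariant couplings over the
#' factors' m-indices. The list is empty when no invariant exists (odd total
#' l, or angular momenta that cannot couple to a scalar).
#'
#' @param spec a product spec as returned by [enumerate_product_specs()]
#'   (only the `(z, n, l)` part is used), or any matrix with columns
#'   `iz, n, l`.
#' @return list of symmetric basis functions; each is a list with fields
#'   `nu`, `skeleton` (the `(iz, n, l)` rows) and `coupling` (matrix with
#'   columns `m_1..m_nu` and `coeff`, entries below 1e-12 dropped).
#' @export
symmetrize <- function(spec) {
  rows <- spec[, c("iz", "n", "l"), drop = FALSE]
  V <- .skeleton_couplings(rows)
  if (ncol(V) == 0) return(list())
  ls <- as.integer(rows[, "l"])
  out <- vector("list", ncol(V))
  for (k in seq_len(ncol(V))) {
    v <- V[, k]
    nz <- which(abs(v) > 1e-12)
    mcomb <- t(vapply(nz, .decode_m, integer(length(ls)), ls = ls))
    if (length(ls) == 1) mcomb <- matrix(mcomb, ncol = 1)
    coupling <- cbind(mcomb, coeff = v[nz])
    colnames(coupling) <- c(paste0("m_", seq_along(ls)), "coeff")
    out[[k]] <- list(nu = length(ls), skeleton = rows, coupling = coupling)
  }
  out
}

## ---------------------------------------------------------------------------
## basis assembly

## Build the flattened evaluation tables for a list of symmetric basis
## functions: ENT (entries x nu_max matrix of flat A indices, 0-padded),
## coeff, fid (function id per entry).
.flatten_functions <- function(funs, n_max, l_max, nu_max) {
  n_entries <- sum(vapply(funs, function(f) nrow(f$coupling), integer(1)))
  ENT <- matrix(0L, n_entries, nu_max)
  coeff <- numeric(n_entries)
  fid <- integer(n_entries)
  pos <- 0L
  for (k in seq_along(funs)) {
    f <- funs[[k]]
    cp <- f$coupling
    ne <- nrow(cp)
    rowsidx <- pos + seq_len(ne)
    for (t in seq_len(f$nu)) {
      ENT[rowsidx, t] <- .v_index(f$skeleton[t, "iz"], f$skeleton[t, "n"],
                                  f$skeleton[t, "l"], cp[, t],
                                  n_max, l_max)
    }
    coeff[rowsidx] <- cp[, "coeff"]
    fid[rowsidx] <- k
    pos <- pos + ne
  }
  list(ENT = ENT, coeff = coeff, fid = fid, n_fun = length(funs))
}

## Evaluate many basis functions from a precomputed atomic base vector A.
.eval_funs_from_A <- function(flat, A) {
  Apad <- c(1, A)
  P <- flat$coeff
  for (t in seq_len(ncol(flat$ENT))) P <- P * Apad[flat$ENT[, t] + 1L]
  B <- numeric(flat$n_fun)
  agg <- rowsum(P, flat$fid)
  B[as.integer(rownames(agg))] <- agg[, 1]
  B
}

#' Construct a pruned, linearly independent ACE basis
#'
#' Runs the full basis pipeline: enumerate candidate skeletons under the
#' selection's truncation, solve for O(3)-invariant couplings, and remove
#' linear dependencies by a rank-revealing factorization of the candidate
#' evaluation matrix on randomly sampled environments (at least 3x
#' oversampling, fixed documented seed).
#'
#' @param selection a [basis_selection()].
#' @param radial a [radial_spec()].
#' @param prune_tol relative singular-value threshold for dependency removal.
#' @param prune_seed RNG seed used to draw the sample environments.
#' @param sample_envs optional list of environments to use for pruning in
#'   place of the internally sampled ones.
#' @return object of class `"ace_basis"`.
#' @export
ace_basis <- function(selection, radial, prune_tol = 1e-10,
                      prune_seed = 20210521L, sample_envs = NULL) {
  stopifnot(inherits(selection, "basis_selection"),
            inherits(radial, "radial_spec"))
  l_max <- .l_max_of(selection)
  polys <- build_orthogonal_polynomials(radial,
                                        degree_max = max(radial$n_max, 8L))
  skels <- .enumerate_skeletons(selection, radial$n_max)
  tab <- .factor_table(selection, radial$n_max)
  candidates <- list()
  for (sk in skels) {
    rows <- tab[sk, c("iz", "n", "l"), drop = FALSE]
    fs <- symmetrize(rows)
    candidates <- c(candidates, fs)
  }
  if (length(candidates) == 0) stop("basis selection produced no candidates")
  flat_cand <- .flatten_functions(candidates, radial$n_max, l_max,
                                  selection$nu_max)
  ## sample environments for pruning
  n_env <- 3L * length(candidates)
  if (is.null(sample_envs)) {
    sample_envs <- withr::with_seed(prune_seed, {
      lapply(seq_len(n_env), function(i) {
        .random_env(selection$elements, radial)
      })
    })
  }
  if (length(sample_envs) < 3L * length(candidates)) {
    stop("insufficient sample environments for dependency pruning ",
         "(need at least 3x the candidate count)")
  }
  M <- matrix(0, length(sample_envs), length(candidates))
  for (e in seq_along(sample_envs)) {
    A <- .project_env(sample_envs[[e]], radial, polys, l_max,
                      selection$elements)$A
    M[e, ] <- .eval_funs_from_A(flat_cand, A)
  }
  keep <- .rank_prune(M, prune_tol)
  funs <- candidates[keep]
  flat <- .flatten_functions(funs, radial$n_max, l_max, selection$nu_max)
  structure(list(
    selection = selection, radial = radial, polys = polys,
    elements = selection$elements, l_max = l_max,
    functions = funs, flat = flat, n_fun = length(funs),
    n_v = .n_v(length(selection$elements), radial$n_max, l_max),
    provenance = list(prune_tol = prune_tol, prune_seed = prune_seed,
                      n_candidates = length(candidates),
                      n_sample_envs = length(sample_envs))),
    class = "ace_basis")
}

#' @export
print.ace_basis <- function(x, ...) {
  nus <- vapply(x$functions, function(f) f$nu, integer(1))
  cat(sprintf("ACE basis: %d invariant functions (from %d candidates)\n",
              x$n_fun, x$provenance$n_candidates))
  cat("  by correlation order:",
      paste(sprintf("nu=%d: %d", sort(unique(nus)), table(nus)),
            collapse = ", "), "\n")
  cat(sprintf("  elements {%s}, n_max = %d, l_max = %d, r_out = %.2f A\n",
              paste(x$elements, collapse = ","), x$radial$n_max, x$l_max,
              x$radial$r_out))
  invisible(x)
}

## Column subset selection: normalize columns, drop (near-)zero ones, rank by
## singular values at relative threshold `tol`, subset by pivoted QR. Returns
## indices of a maximal linearly independent subset, in original order.
.rank_prune <- function(M, tol) {
  nrm <- sqrt(colSums(M^2))
  nz <- which(nrm > 1e-300 & nrm > max(nrm) * 1e-14)
  if (length(nz) == 0) stop("all candidate basis functions vanish on samples")
  Ms <- M[, nz, drop = FALSE] / rep(nrm[nz], each = nrow(M))
  sv <- svd(Ms, nu = 0, nv = 0)$d
  rank <- sum(sv > tol * sv[1])
  qrp <- qr(Ms, LAPACK = TRUE)
  keep <- sort(nz[qrp$pivot[seq_len(rank)]])
  keep
}

#' Remove linear dependencies among candidate basis functions
#'
#' Selects a maximal linearly independent subset of the candidates by a
#' rank-revealing factorization of their evaluation matrix on sample
#' environments.
#'
#' @param candidates list of symmetric basis functions (as from
#'   [symmetrize()]).
#' @param sample_envs list of [atomic_environment()]s, at least 3 times as
#'   many as candidates.
#' @param radial a [radial_spec()]; `polys`, `l_max`, `elements` as in the
#'   basis pipeline.
#' @param polys orthogonal polynomial set.
#' @param l_max maximum angular degree.
#' @param elements declared element set.
#' @param tol relative singular-value threshold.
#' @return integer indices of the retained candidates.
#' @export
remove_linear_dependencies <- function(candidates, sample_envs, radial,
                                       polys, l_max, elements,
                                       tol = 1e-10) {
  if (length(sample_envs) < 3L * length(candidates)) {
    stop("insufficient sample environments ",
         "(need at least 3x the candidate count)")
  }
  nu_max <- max(vapply(candidates, function(f) f$nu, integer(1)))
  flat <- .flatten_functions(candidates, radial$n_max, l_max, nu_max)
  M <- matrix(0, length(sample_envs), length(candidates))
  for (e in seq_along(sample_envs)) {
    A <- .project_env(sample_envs[[e]], radial, polys, l_max, elements)$A
    M[e, ] <- .eval_funs_from_A(flat, A)
  }
  .rank_prune(M, tol)
}

## random environment generator used for pruning (and tests)
.random_env <- function(elements, radial, n_min = 2L, n_max_neigh = 8L) {
  m <- sample(n_min:n_max_neigh, 1)
  els <- sample(elements, m, replace = TRUE)
  lo <- radial$r_in + 0.05 * (radial$r_out - radial$r_in)
  hi <- radial$r_out * 0.97
  r <- stats::runif(m, lo, hi)
  u <- matrix(stats::rnorm(3 * m), m, 3)
  u <- u / sqrt(rowSums(u^2))
  atomic_environment(sample(elements, 1), els, u * r)
}

#' Evaluate the symmetric basis on an environment
#'
#' Computes all B-values via the density trick: project the density once
#' (cost linear in the neighbor count), then contract cached A-products with
#' the sparse coupling coefficients.
#'
#' @param env an [atomic_environment()].
#' @param basis an [ace_basis()].
#' @param A optionally a precomputed [project_density()] result.
#' @return numeric vector of length `basis$n_fun`.
#' @export
evaluate_basis <- function(env, basis, A = NULL) {
  if (!env$center_element %in% basis$elements ||
      !all(env$neighbor_elements %in% basis$elements)) {
    stop("environment elements are not declared in the basis")
  }
  if (is.null(A)) {
    A <- project_density(env, basis$radial, basis$polys, basis$l_max,
                         basis$elements)
  }
  .eval_funs_from_A(basis$flat, A$A)
}

#' Evaluate basis values and gradients on an environment
#'
#' Analytic gradients of every B-function with respect to each neighbor
#' position, by the product rule over the A-products.
#'
#' @inheritParams evaluate_basis
#' @return list with `B` (length `n_fun`) and `dB`
#'   (`n_fun x n_neigh x 3` array of per-neighbor gradients).
#' @export
evaluate_basis_gradients <- function(env, basis, A = NULL) {
  if (is.null(A)) {
    A <- project_density(env, basis$radial, basis$polys, basis$l_max,
                         basis$elements)
  }
  flat <- basis$flat
  Apad <- c(1, A$A)
  nu_max <- ncol(flat$ENT)
  ne <- length(flat$coeff)
  vals <- matrix(1, ne, nu_max)
  for (t in seq_len(nu_max)) vals[, t] <- Apad[flat$ENT[, t] + 1L]
  prodv <- flat$coeff
  for (t in seq_len(nu_max)) prodv <- prodv * vals[, t]
  B <- numeric(flat$n_fun)
  agg <- rowsum(prodv, flat$fid)
  B[as.integer(rownames(agg))] <- agg[, 1]

  m <- length(env$neighbor_elements)
  if (m == 0) {
    return(list(B = B, dB = array(0, c(flat$n_fun, 0, 3))))
  }
  ## W[k, v] = sum over entries of k and slots t with index v of the
  ## leave-one-out product
  iacc <- integer(0); jacc <- integer(0); wacc <- numeric(0)
  for (t in seq_len(nu_max)) {
    j <- flat$ENT[, t]
    act <- which(j > 0L)
    if (length(act) == 0) next
    loo <- flat$coeff[act]
    for (s in seq_len(nu_max)) {
      if (s != t) loo <- loo * vals[act, s]
    }
    iacc <- c(iacc, flat$fid[act])
    jacc <- c(jacc, j[act])
    wacc <- c(wacc, loo)
  }
  key <- (as.numeric(jacc) - 1) * flat$n_fun + iacc
  agg2 <- rowsum(wacc, key)
  keyv <- as.numeric(rownames(agg2))
  jv <- floor((keyv - 1) / flat$n_fun) + 1
  iv <- keyv - (jv - 1) * flat$n_fun
  W <- matrix(0, flat$n_fun, basis$n_v)
  W[cbind(iv, jv)] <- agg2[, 1]
  ## dB[k, j, d] = sum_v W[k, v] dA[j, d, v]
  DA <- matrix(A$dA, nrow = m * 3, ncol = basis$n_v)  # (j,d) x v
  dBmat <- W %*% t(DA)                                # n_fun x (j,d)
  dB <- array(dBmat, c(flat$n_fun, m, 3))
  list(B = B, dB = dB)
}

#' Brute-force correlation oracle
#'
#' Evaluates an A-product by the explicit sum over *ordered* neighbor tuples
#' (repeated indices included, i.e. with the self-interaction terms that the
#' density trick produces). Exponential cost in the correlation order; used
#' as an independent oracle on small environments only.
#'
#' @param env an [atomic_environment()] with at most 8 neighbors.
#' @param spec a product spec (matrix with columns `iz, n, l, m`).
#' @param radial a [radial_spec()].
#' @param polys orthogonal polynomial set.
#' @param l_max maximum angular degree.
#' @param elements declared element set.
#' @return the scalar product value.
#' @export
brute_force_correlation <- function(env, spec, radial, polys, l_max,
                                    elements) {
  m <- length(env$neighbor_elements)
  if (m > 8) stop("brute-force oracle refuses environments with > 8 neighbors")
  nu <- nrow(spec)
  if (m == 0) return(0)
  ## per-neighbor phi values for the nu required one-particle functions
  phi <- matrix(0, m, nu)
  iz_n <- match(env$neighbor_elements, elements)
  r <- sqrt(rowSums(env$displacements^2))
  rb <- evaluate_radial_basis(r, radial, polys)
  sh <- real_spherical_harmonics(env$displacements, l_max, grad = FALSE)
  for (t in seq_len(nu)) {
    ycol <- spec[t, "l"]^2 + spec[t, "l"] + spec[t, "m"] + 1L
    phi[, t] <- ifelse(iz_n == spec[t, "iz"],
                       rb$R[, spec[t, "n"]] * sh$Y[, ycol], 0)
  }
  ## explicit sum over all m^nu ordered tuples: build every tuple product
  ## individually (outer products), then sum
  prods <- 1
  for (t in seq_len(nu)) prods <- as.vector(outer(prods, phi[, t]))
  sum(prods)
}

#' SOAP-style power spectrum features
#'
#' An independent implementation of the rotationally invariant power
#' spectrum: `p_{(z1 n1)(z2 n2) l} = sum_m A_{z1 n1 l m} A_{z2 n2 l m}`,
#' computed here *without* the atomic base or any coupling coefficients, by
#' the explicit double sum over neighbor pairs using the Legendre addition
#' theorem. Serves as the cross-check that the span of the two-correlation
#' (three-body) ACE invariants coincides with the power spectrum.
#'
#' @param env an [atomic_environment()].
#' @param radial a [radial_spec()].
#' @param polys orthogonal polynomial set.
#' @param l_max maximum angular degree.
#' @param elements declared element set.
#' @return named numeric vector of power-spectrum features.
#' @export
power_spectrum <- function(env, radial, polys, l_max, elements) {
  n_max <- radial$n_max
  chan <- expand.grid(iz1 = seq_along(elements), n1 = seq_len(n_max),
                      iz2 = seq_along(elements), n2 = seq_len(n_max),
                      l = 0:l_max)
  chan <- chan[order(chan$l, chan$iz1, chan$n1, chan$iz2, chan$n2), ]
  chan <- chan[with(chan, iz1 * n_max + n1 <= iz2 * n_max + n2), ]
  m <- length(env$neighbor_elements)
  vals <- numeric(nrow(chan))
  names(vals) <- with(chan, paste0("p[", elements[iz1], n1, ",",
                                   elements[iz2], n2, ",l", l, "]"))
  if (m == 0) return(vals)
  iz_n <- match(env$neighbor_elements, elements)
  r <- sqrt(rowSums(env$displacements^2))
  u <- env$displacements / r
  rb <- evaluate_radial_basis(r, radial, polys)
  cosg <- u %*% t(u)
  ## Legendre polynomials P_l(cos gamma) for all pairs, by recursion
  Pl <- vector("list", l_max + 1L)
  Pl[[1]] <- matrix(1, m, m)
  if (l_max >= 1) Pl[[2]] <- cosg
  if (l_max >= 2) {
    for (l in 2:l_max) {
      Pl[[l + 1]] <- ((2 * l - 1) * cosg * Pl[[l]] - (l - 1) * Pl[[l - 1]]) / l
    }
  }
  for (k in seq_len(nrow(chan))) {
    z1 <- chan$iz1[k]; z2 <- chan$iz2[k]
    a <- ifelse(iz_n == z1, rb$R[, chan$n1[k]], 0)
    b <- ifelse(iz_n == z2, rb$R[, chan$n2[k]], 0)
    l <- chan$l[k]
    vals[k] <- (2 * l + 1) / (4 * pi) * sum(outer(a, b) * Pl[[l + 1]])
  }
  attr(vals, "channels") <- chan
  vals
}
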