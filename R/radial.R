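## Radial basis machinery: the one-dimensional transform x(r), the inner/outer
## cutoff envelope, and orthogonal polynomials p_n built by a Stieltjes
## three-term recursion against Gauss-Legendre quadrature, so that the radial
## functions R_n(r) = p_n(x(r)) f_cut(r) are orthonormal in x-coordinates.
##
## The transform is x_raw(r) = ((1 + r0)/(1 + r))^q, which amplifies the effect
## of neighbors close to the central atom, followed by an affine
## standardization x = (x_raw - mu)/sigma under the measure
## f_cut(r)^2 |dx/dr| dr. The standardization plus envelope amplitude
## normalization make that measure have mass 1, mean 0 and variance 1 in x, so
## that p_0(x) = 1 and p_1(x) = x are themselves the first two orthonormal
## polynomials and the whole set {R_n} is orthonormal.

#' Radial basis specification
#'
#' Defines the one-dimensional radial channel of an ACE model: inner and outer
#' cutoffs, the number of radial functions, the radial transform and the cutoff
#' envelope. The constructor precomputes (by quadrature) the affine
#' standardization of the transform and the envelope amplitude under which the
#' induced measure is normalized; these constants are part of the spec and make
#' every downstream quantity deterministic.
#'
#' @param r_in inner cutoff (Angstrom). The multibody radial functions vanish
#'   for `r <= r_in`, excluding the short-range region where training data is
#'   scarce; short-range repulsion is carried by the auxiliary pair basis
#'   instead (see [pair_cutoff_envelope()]).
#' @param r_out outer cutoff (Angstrom); the model's interaction range.
#' @param n_max number of radial functions (`n = 1..n_max`).
#' @param r0 length scale of the radial transform (Angstrom); about a typical
#'   bond length.
#' @param q exponent of the radial transform; larger values put more
#'   resolution at short range.
#' @param p_in,p_out envelope exponents at the inner and outer cutoff (both
#'   must be >= 2 so that value and first derivative vanish there).
#' @param quadrature_points number of Gauss-Legendre points used for
#'   orthogonalization (must be at least `4 * n_max`).
#' @return an object of class `"radial_spec"`.
#' @export
radial_spec <- function(r_in = 0.8, r_out = 5.0, n_max = 6,
                        r0 = 1.5, q = 2, p_in = 2, p_out = 2,
                        quadrature_points = 2000) {
  stopifnot(is.numeric(r_in), is.numeric(r_out), length(r_in) == 1L,
            length(r_out) == 1L)
  if (!(r_in > 0 && r_in < r_out)) {
    stop("invalid radial spec: need 0 < r_in < r_out")
  }
  if (n_max < 1) stop("invalid radial spec: n_max must be >= 1")
  if (p_in < 2 || p_out < 2) {
    stop("envelope exponents must be >= 2 for C^1 continuity at the cutoffs")
  }
  if (quadrature_points < 4 * n_max) {
    stop("quadrature_points must be at least 4 * n_max")
  }
  spec <- structure(
    list(r_in = r_in, r_out = r_out, n_max = as.integer(n_max),
         r0 = r0, q = q, p_in = p_in, p_out = p_out,
         quadrature_points = as.integer(quadrature_points),
         mu = 0, sigma = 1, env_amp = 1),
    class = "radial_spec")
  ## quadrature for the standardization constants
  gl <- pracma::gaussLegendre(quadrature_points, r_in, r_out)
  xr <- .x_raw(gl$x, spec)
  dxr <- abs(.x_raw_deriv(gl$x, spec))
  fhat <- .envelope_raw(gl$x, spec)
  w <- fhat^2 * dxr * gl$w
  m0 <- sum(w)
  if (!is.finite(m0) || m0 <= 0) stop("degenerate radial measure")
  mu0 <- sum(xr * w) / m0
  sig0 <- sqrt(sum((xr - mu0)^2 * w) / m0)
  if (!is.finite(sig0) || sig0 <= 0) stop("degenerate radial measure")
  spec$mu <- mu0
  spec$sigma <- sig0
  spec$env_amp <- sqrt(sig0 / m0)
  spec
}

#' @export
print.radial_spec <- function(x, ...) {
  cat(sprintf("Radial spec: n_max = %d, r_in = %.3f A, r_out = %.3f A\n",
              x$n_max, x$r_in, x$r_out))
  cat(sprintf("  transform ((1+r0)/(1+r))^q standardized: r0 = %.3f, q = %g\n",
              x$r0, x$q))
  cat(sprintf("  envelope exponents (%g, %g), quadrature %d points\n",
              x$p_in, x$p_out, x$quadrature_points))
  invisible(x)
}

## raw (unstandardized) transform and its derivative
.x_raw <- function(r, spec) ((1 + spec$r0) / (1 + r))^spec$q

.x_raw_deriv <- function(r, spec) {
  -spec$q * (1 + spec$r0)^spec$q * (1 + r)^(-spec$q - 1)
}

## unnormalized two-sided envelope, maximum value 1
.envelope_raw <- function(r, spec) {
  out <- numeric(length(r))
  inside <- r > spec$r_in & r < spec$r_out
  if (any(inside)) {
    ri <- spec$r_in; ro <- spec$r_out
    rstar <- (spec$p_in * ro + spec$p_out * ri) / (spec$p_in + spec$p_out)
    nrm <- (rstar - ri)^spec$p_in * (ro - rstar)^spec$p_out
    rr <- r[inside]
    out[inside] <- (rr - ri)^spec$p_in * (ro - rr)^spec$p_out / nrm
  }
  out
}

.envelope_raw_deriv <- function(r, spec) {
  out <- numeric(length(r))
  inside <- r > spec$r_in & r < spec$r_out
  if (any(inside)) {
    ri <- spec$r_in; ro <- spec$r_out
    rstar <- (spec$p_in * ro + spec$p_out * ri) / (spec$p_in + spec$p_out)
    nrm <- (rstar - ri)^spec$p_in * (ro - rstar)^spec$p_out
    rr <- r[inside]
    a <- (rr - ri)^spec$p_in
    b <- (ro - rr)^spec$p_out
    da <- spec$p_in * (rr - ri)^(spec$p_in - 1)
    db <- -spec$p_out * (ro - rr)^(spec$p_out - 1)
    out[inside] <- (da * b + a * db) / nrm
  }
  out
}

#' Radial transform
#'
#' The standardized one-dimensional radial transform x(r): the algebraic form
#' `((1 + r0)/(1 + r))^q` (which amplifies the effect of neighbors closer to
#' the central atom) followed by the affine standardization stored in the
#' spec. Strictly monotone (decreasing) in r.
#'
#' @param r radial distance(s), Angstrom, `r >= 0`.
#' @param spec a [radial_spec()].
#' @param deriv if `TRUE`, also return `dx/dr`.
#' @return numeric vector `x`, or a list `(x, dx)` when `deriv = TRUE`.
#' @export
radial_transform <- function(r, spec, deriv = FALSE) {
  if (any(r < 0)) stop("radial_transform: r must be non-negative")
  x <- (.x_raw(r, spec) - spec$mu) / spec$sigma
  if (!deriv) return(x)
  list(x = x, dx = .x_raw_deriv(r, spec) / spec$sigma)
}

#' Cutoff envelope for the multibody radial basis
#'
#' Two-sided envelope with both an inner and an outer cutoff: zero (with zero
#' first derivative) outside `(r_in, r_out)`, smooth inside. The amplitude is
#' the normalization constant fixed by the spec so that the radial basis is
#' orthonormal.
#'
#' @inheritParams radial_transform
#' @return envelope values (and derivatives when `deriv = TRUE`).
#' @export
cutoff_envelope <- function(r, spec, deriv = FALSE) {
  if (any(r < 0)) stop("cutoff_envelope: r must be non-negative")
  f <- spec$env_amp * .envelope_raw(r, spec)
  if (!deriv) return(f)
  list(f = f, df = spec$env_amp * .envelope_raw_deriv(r, spec))
}

#' Cutoff envelope for the auxiliary pair basis
#'
#' One-sided envelope `(1 - r/r_out)^2` used by the two-body repulsion basis:
#' it has no inner cutoff (so the pair basis stays active as r -> 0 and can
#' carry short-range repulsion) and goes to zero with zero slope at `r_out`.
#'
#' @inheritParams radial_transform
#' @return envelope values (and derivatives when `deriv = TRUE`).
#' @export
pair_cutoff_envelope <- function(r, spec, deriv = FALSE) {
  if (any(r < 0)) stop("pair_cutoff_envelope: r must be non-negative")
  f <- numeric(length(r))
  df <- numeric(length(r))
  inside <- r < spec$r_out
  u <- 1 - r[inside] / spec$r_out
  f[inside] <- u^2
  df[inside] <- -2 * u / spec$r_out
  if (!deriv) return(f)
  list(f = f, df = df)
}

#' Build the orthogonal polynomial set
#'
#' Constructs the three-term recursion coefficients of the polynomials p_n by
#' a Stieltjes procedure against Gauss-Legendre quadrature, under the measure
#' in which the radial functions `R_n(r) = p_n(x(r)) f_cut(r)` are orthonormal
#' in x-coordinates. Because the measure is standardized (see [radial_spec()]),
#' the recursion yields `p_0(x) = 1` and `p_1(x) = x` exactly (to quadrature
#' accuracy).
#'
#' @param spec a [radial_spec()].
#' @param degree_max highest polynomial degree needed (defaults to
#'   `spec$n_max`; the auxiliary pair basis may require more).
#' @return an object of class `"ortho_polys"` with fields `alpha`, `beta`
#'   (recursion coefficients) and `degree_max`.
#' @export
build_orthogonal_polynomials <- function(spec, degree_max = spec$n_max) {
  stopifnot(inherits(spec, "radial_spec"))
  if (spec$quadrature_points < 4 * spec$n_max) {
    stop("quadrature_points must be at least 4 * n_max")
  }
  K <- as.integer(degree_max)
  gl <- pracma::gaussLegendre(spec$quadrature_points, spec$r_in, spec$r_out)
  tr <- radial_transform(gl$x, spec, deriv = TRUE)
  fc <- cutoff_envelope(gl$x, spec)
  w <- fc^2 * abs(tr$dx) * gl$w
  x <- tr$x
  ## orthonormal Stieltjes recursion:
  ## beta[k+1] p_{k+1} = (x - alpha[k]) p_k - beta[k] p_{k-1}
  alpha <- numeric(K)
  beta <- numeric(K)
  pkm1 <- numeric(length(x))
  pk <- rep(1 / sqrt(sum(w)), length(x))
  for (k in seq_len(K)) {
    alpha[k] <- sum(w * x * pk^2)
    q <- (x - alpha[k]) * pk - (if (k > 1) beta[k - 1] * pkm1 else 0)
    b <- sqrt(sum(w * q^2))
    if (!is.finite(b) || b < 1e-12) {
      stop("quadrature-rank failure: radial measure degenerate at degree ", k)
    }
    beta[k] <- b
    pkm1 <- pk
    pk <- q / b
  }
  structure(list(alpha = alpha, beta = beta, degree_max = K),
            class = "ortho_polys")
}

## Evaluate p_n(x) (and optionally dp_n/dx) for n = 0..degree via the stored
## recursion; x may be a vector. Returns matrices length(x) x (degree+1).
.eval_ortho_polys <- function(x, polys, degree = polys$degree_max,
                              deriv = FALSE) {
  K <- degree
  if (K > polys$degree_max) stop("polynomial degree exceeds the built set")
  n <- length(x)
  P <- matrix(0, n, K + 1)
  P[, 1] <- 1
  if (deriv) D <- matrix(0, n, K + 1)
  if (K >= 1) {
    for (k in 1:K) {
      pkm1 <- if (k > 1) P[, k - 1] else numeric(n)
      P[, k + 1] <- ((x - polys$alpha[k]) * P[, k] -
                       (if (k > 1) polys$beta[k - 1] * pkm1 else 0)) /
        polys$beta[k]
      if (deriv) {
        dkm1 <- if (k > 1) D[, k - 1] else numeric(n)
        D[, k + 1] <- (P[, k] + (x - polys$alpha[k]) * D[, k] -
                         (if (k > 1) polys$beta[k - 1] * dkm1 else 0)) /
          polys$beta[k]
      }
    }
  }
  if (deriv) list(P = P, D = D) else P
}

#' Evaluate the radial basis
#'
#' Radial functions `R_n(r) = p_n(x(r)) f_cut(r)` for `n = 1..n_max`, with
#' analytic derivatives `dR_n/dr` by the chain rule. Both vanish identically
#' for `r >= r_out` (and for `r <= r_in`, by the two-sided envelope).
#'
#' @param r radial distances (Angstrom), `r >= 0`.
#' @param spec a [radial_spec()].
#' @param polys the matching [build_orthogonal_polynomials()] set.
#' @return list with matrices `R` and `dR`, `length(r)` rows and `n_max`
#'   columns.
#' @export
evaluate_radial_basis <- function(r, spec, polys) {
  if (any(r < 0)) stop("evaluate_radial_basis: r must be non-negative")
  n <- length(r)
  R <- matrix(0, n, spec$n_max)
  dR <- matrix(0, n, spec$n_max)
  inside <- r > spec$r_in & r < spec$r_out
  if (any(inside)) {
    tr <- radial_transform(r[inside], spec, deriv = TRUE)
    fc <- cutoff_envelope(r[inside], spec, deriv = TRUE)
    pe <- .eval_ortho_polys(tr$x, polys, degree = spec$n_max, deriv = TRUE)
    for (nn in seq_len(spec$n_max)) {
      p <- pe$P[, nn + 1]
      dp <- pe$D[, nn + 1]
      R[inside, nn] <- p * fc$f
      dR[inside, nn] <- dp * tr$dx * fc$f + p * fc$df
    }
  }
  list(R = R, dR = dR)
}

## Auxiliary pair radial basis: same transform and polynomials, pair envelope.
## Returns R (length(r) x degree) and dR. Degrees n = 1..degree.
.evaluate_pair_radial <- function(r, spec, polys, degree) {
  if (any(r < 0)) stop("pair radial basis: r must be non-negative")
  n <- length(r)
  R <- matrix(0, n, degree)
  dR <- matrix(0, n, degree)
  inside <- r < spec$r_out
  if (any(inside)) {
    tr <- radial_transform(r[inside], spec, deriv = TRUE)
    fc <- pair_cutoff_envelope(r[inside], spec, deriv = TRUE)
    pe <- .eval_ortho_polys(tr$x, polys, degree = degree, deriv = TRUE)
    for (nn in seq_len(degree)) {
      p <- pe$P[, nn + 1]
      dp <- pe$D[, nn + 1]
      R[inside, nn] <- p * fc$f
      dR[inside, nn] <- dp * tr$dx * fc$f + p * fc$df
    }
  }
  list(R = R, dR = dR)
}
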