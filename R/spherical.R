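## Real spherical harmonics, orthonormal on the unit sphere, Condon-Shortley
## phase omitted. Convention (theta polar, phi azimuth):
##   Y_l0  = sqrt((2l+1)/4pi) P_l(cos theta)
##   Y_lm  = sqrt(2) sqrt((2l+1)/4pi (l-m)!/(l+m)!) P_l^m(cos theta) cos(m phi)
##   Y_l-m = same with sin(m phi),  m > 0, P_l^m without the (-1)^m phase.
## Evaluated via regular solid-harmonic recursions in Cartesian coordinates,
## which are smooth everywhere away from the origin (no pole problems), with
## analytic gradients with respect to the *unnormalized* input vector.
## All downstream invariants are convention-independent; the fixed convention
## here makes the numerically solved coupling coefficients unambiguous.

#' Real spherical harmonics with gradients
#'
#' Evaluates all real spherical harmonics with `l <= l_max` at one or more
#' directions, together with their gradients with respect to the unnormalized
#' input vector(s). Columns are ordered by the flat index `l^2 + l + m + 1`.
#'
#' @param u a length-3 vector or an `n x 3` matrix of nonzero vectors
#'   (normalized internally).
#' @param l_max maximum angular degree.
#' @param grad if `TRUE` (default) also return gradients.
#' @return list with `Y` (`n x (l_max+1)^2`) and, when requested, `dY`
#'   (`n x 3 x (l_max+1)^2` array).
#' @export
real_spherical_harmonics <- function(u, l_max, grad = TRUE) {
  if (is.null(dim(u))) u <- matrix(u, 1, 3)
  stopifnot(ncol(u) == 3)
  n <- nrow(u)
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  r2 <- x^2 + y^2 + z^2
  if (any(r2 == 0)) stop("real_spherical_harmonics: zero vector")
  r <- sqrt(r2)
  L <- as.integer(l_max)
  nlm <- (L + 1L)^2
  Y <- matrix(0, n, nlm)
  if (grad) dY <- array(0, c(n, 3, nlm))

  ## azimuthal polynomials c_m + i s_m = (x + i y)^m
  cs <- vector("list", L + 1L); sn <- vector("list", L + 1L)
  cs[[1]] <- rep(1, n); sn[[1]] <- rep(0, n)
  if (L >= 1) {
    for (m in 1:L) {
      cs[[m + 1]] <- x * cs[[m]] - y * sn[[m]]
      sn[[m + 1]] <- x * sn[[m]] + y * cs[[m]]
    }
  }

  ## Q_l^m(z, r^2): scaled associated-Legendre part (degree l - m in z),
  ## with value and partials wrt z and r^2 carried through the recursion.
  Qv <- vector("list", L + 1L)
  Qz <- vector("list", L + 1L)
  Qr <- vector("list", L + 1L)
  for (l in 0:L) {
    Qv[[l + 1]] <- vector("list", l + 1L)
    Qz[[l + 1]] <- vector("list", l + 1L)
    Qr[[l + 1]] <- vector("list", l + 1L)
  }
  Qv[[1]][[1]] <- rep(1, n); Qz[[1]][[1]] <- rep(0, n); Qr[[1]][[1]] <- rep(0, n)
  if (L >= 1) {
    for (l in 1:L) {
      ## m = l
      Qv[[l + 1]][[l + 1]] <- (2 * l - 1) * Qv[[l]][[l]]
      Qz[[l + 1]][[l + 1]] <- (2 * l - 1) * Qz[[l]][[l]]
      Qr[[l + 1]][[l + 1]] <- (2 * l - 1) * Qr[[l]][[l]]
      ## m = l - 1
      Qv[[l + 1]][[l]] <- (2 * l - 1) * z * Qv[[l]][[l]]
      Qz[[l + 1]][[l]] <- (2 * l - 1) * (Qv[[l]][[l]] + z * Qz[[l]][[l]])
      Qr[[l + 1]][[l]] <- (2 * l - 1) * z * Qr[[l]][[l]]
      if (l >= 2) {
        for (m in (l - 2):0) {
          a <- 2 * l - 1
          b <- l - 1 + m
          d <- l - m
          Qv[[l + 1]][[m + 1]] <-
            (a * z * Qv[[l]][[m + 1]] - b * r2 * Qv[[l - 1]][[m + 1]]) / d
          Qz[[l + 1]][[m + 1]] <-
            (a * (Qv[[l]][[m + 1]] + z * Qz[[l]][[m + 1]]) -
               b * r2 * Qz[[l - 1]][[m + 1]]) / d
          Qr[[l + 1]][[m + 1]] <-
            (a * z * Qr[[l]][[m + 1]] -
               b * (Qv[[l - 1]][[m + 1]] + r2 * Qr[[l - 1]][[m + 1]])) / d
        }
      }
    }
  }

  for (l in 0:L) {
    rl <- r^(-l)
    for (m in (-l):l) {
      mm <- abs(m)
      N <- if (mm == 0) {
        sqrt((2 * l + 1) / (4 * pi))
      } else {
        sqrt(2) * sqrt((2 * l + 1) / (4 * pi) *
                         exp(lfactorial(l - mm) - lfactorial(l + mm)))
      }
      Q <- Qv[[l + 1]][[mm + 1]]
      dQz <- Qz[[l + 1]][[mm + 1]]
      dQr <- Qr[[l + 1]][[mm + 1]]
      if (m >= 0) {
        trig <- cs[[mm + 1]]
        dtx <- if (mm > 0) mm * cs[[mm]] else numeric(n)
        dty <- if (mm > 0) -mm * sn[[mm]] else numeric(n)
      } else {
        trig <- sn[[mm + 1]]
        dtx <- mm * sn[[mm]]
        dty <- mm * cs[[mm]]
      }
      S <- Q * trig
      col <- l^2 + l + m + 1L
      Y[, col] <- N * S * rl
      if (grad) {
        dSx <- dQr * 2 * x * trig + Q * dtx
        dSy <- dQr * 2 * y * trig + Q * dty
        dSz <- (dQz + dQr * 2 * z) * trig
        f <- l * S * r^(-l - 2)
        dY[, 1, col] <- N * (dSx * rl - f * x)
        dY[, 2, col] <- N * (dSy * rl - f * y)
        dY[, 3, col] <- N * (dSz * rl - f * z)
      }
    }
  }
  if (grad) list(Y = Y, dY = dY) else list(Y = Y)
}
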