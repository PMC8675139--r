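## Synthetic labeled data: analytic, body-ordered reference potentials
## (Morse pairs on the bond graph plus harmonic angle bending, or a "planted"
## linear ACE model with known coefficients) and samplers that emulate the
## statistical structure of force-field training sets — thermally perturbed
## molecular geometries with energy/force labels. These stand in for
## electronic-structure labels so that fitting and evaluation are testable
## end to end with no external data.

#' Analytic reference potential
#'
#' Builds a deterministic reference calculator for a template molecule.
#'
#' `"morse_pairs_plus_harmonic_angles"`: Morse interactions
#' `D_e ((1 - exp(-a (r - r_e)))^2 - 1)` on every bond of the template's
#' covalent bond graph, plus harmonic bending `k_theta (theta - theta_0)^2`
#' on every bonded angle. Equilibrium values are taken from the template;
#' stiffnesses are drawn (seeded) from documented ranges so different bonds
#' are distinguishable. The potential has *no* dihedral dependence.
#'
#' `"planted_ace"`: a linear ACE model with coefficients drawn (seeded) from
#' a smoothness-weighted normal distribution within a stated basis — the
#' backbone of exact parameter-recovery tests.
#'
#' @param template an [atomic_configuration()] defining topology (and, for
#'   `planted_ace`, the element set).
#' @param kind `"morse_pairs_plus_harmonic_angles"` or `"planted_ace"`.
#' @param params named list. For the Morse kind: optional `D_e`, `a`,
#'   `k_theta` (scalars or per-term vectors), `jitter` (logical, default
#'   TRUE: draw per-term values from ranges D_e in (3.5, 5) eV, a in
#'   (1.8, 2.2) 1/A, k_theta in (2.5, 3.5) eV/rad^2). For `planted_ace`:
#'   `basis` (an [ace_basis()], required), `coef_scale` (default 0.1 eV),
#'   `pair_degree` (default 6), `e0` (named one-body energies, default 0).
#' @param seed integer seed (all randomness flows from it).
#' @return for the Morse kind, an object of class `"ace_reference"`; for
#'   `planted_ace`, a `"linear_ace"` model. Both implement
#'   [potential_energy()] and [potential_forces()].
#' @export
make_reference_potential <- function(template,
                                     kind = c("morse_pairs_plus_harmonic_angles",
                                              "planted_ace"),
                                     params = list(), seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "planted_ace") {
    basis <- params$basis
    if (is.null(basis)) stop("planted_ace requires params$basis")
    scale <- params$coef_scale %||% 0.1
    pair_degree <- params$pair_degree %||% 6L
    model <- linear_ace_model(basis, pair_degree = pair_degree)
    gam <- smoothness_prior(model, p = 2)
    nb <- length(model$coefficients)
    withr::with_seed(as.integer(seed), {
      v <- stats::rnorm(length(gam)) * scale / gam
      model <- .coef_unpack(model, v)
    })
    e0 <- params$e0 %||% stats::setNames(numeric(length(basis$elements)),
                                         basis$elements)
    model$one_body <- e0[basis$elements]
    model$one_body_strategy <- "isolated_atom"
    return(model)
  }
  bonds <- .bond_list(template)
  if (is.null(bonds) || nrow(bonds) == 0) stop("template has no bonds")
  d <- as.matrix(dist(template$positions))
  r_e <- d[bonds]
  nb <- nrow(bonds)
  ## angles: every pair of bonds sharing an atom (vertex in the middle)
  angles <- list()
  for (v in seq_len(n_atoms(template))) {
    nbrs <- sort(unique(c(bonds[bonds[, 1] == v, 2], bonds[bonds[, 2] == v, 1])))
    if (length(nbrs) >= 2) {
      cmb <- utils::combn(nbrs, 2)
      for (cidx in seq_len(ncol(cmb))) {
        angles[[length(angles) + 1L]] <- c(cmb[1, cidx], v, cmb[2, cidx])
      }
    }
  }
  angles <- do.call(rbind, angles)
  na <- if (is.null(angles)) 0L else nrow(angles)
  jitter <- params$jitter %||% TRUE
  withr::with_seed(as.integer(seed), {
    D_e <- params$D_e %||% (if (jitter) stats::runif(nb, 3.5, 5) else rep(4, nb))
    a <- params$a %||% (if (jitter) stats::runif(nb, 1.8, 2.2) else rep(2, nb))
    k_th <- params$k_theta %||%
      (if (jitter && na > 0) stats::runif(na, 2.5, 3.5) else rep(3, na))
  })
  theta0 <- if (na > 0) {
    vapply(seq_len(na), function(t) {
      .angle_value(template$positions, angles[t, ])$theta
    }, numeric(1))
  } else {
    numeric(0)
  }
  structure(list(kind = kind, bonds = bonds,
                 D_e = rep_len(D_e, nb), a = rep_len(a, nb), r_e = r_e,
                 angles = angles, k_theta = rep_len(k_th, max(na, 0L)),
                 theta0 = theta0, seed = as.integer(seed),
                 elements = unique(template$elements)),
            class = "ace_reference")
}

## bond angle at vertex idx[2] with gradient wrt the three positions
.angle_value <- function(pos, idx, grad = FALSE) {
  u <- pos[idx[1], ] - pos[idx[2], ]
  w <- pos[idx[3], ] - pos[idx[2], ]
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  uh <- u / nu; wh <- w / nw
  ct <- max(-1, min(1, sum(uh * wh)))
  theta <- acos(ct)
  if (!grad) return(list(theta = theta))
  st <- sqrt(max(1 - ct^2, 1e-24))
  g1 <- (ct * uh - wh) / (nu * st)
  g3 <- (ct * wh - uh) / (nw * st)
  list(theta = theta, g1 = g1, g2 = -(g1 + g3), g3 = g3)
}

#' @export
potential_energy.ace_reference <- function(object, config, ...) {
  potential_energy_forces(object, config)$energy
}

#' @export
potential_forces.ace_reference <- function(object, config, ...) {
  potential_energy_forces(object, config)$forces
}

#' @export
potential_energy_forces.ace_reference <- function(object, config, ...) {
  pos <- config$positions
  n <- nrow(pos)
  e <- 0
  f <- matrix(0, n, 3)
  for (b in seq_len(nrow(object$bonds))) {
    i <- object$bonds[b, 1]; j <- object$bonds[b, 2]
    dv <- pos[j, ] - pos[i, ]
    r <- sqrt(sum(dv^2))
    ex <- exp(-object$a[b] * (r - object$r_e[b]))
    e <- e + object$D_e[b] * ((1 - ex)^2 - 1)
    dEdr <- 2 * object$D_e[b] * (1 - ex) * object$a[b] * ex
    g <- dEdr * dv / r
    f[i, ] <- f[i, ] + g
    f[j, ] <- f[j, ] - g
  }
  if (!is.null(object$angles) && length(object$theta0) > 0) {
    for (t in seq_len(nrow(object$angles))) {
      idx <- object$angles[t, ]
      av <- .angle_value(pos, idx, grad = TRUE)
      dth <- av$theta - object$theta0[t]
      e <- e + object$k_theta[t] * dth^2
      co <- 2 * object$k_theta[t] * dth
      f[idx[1], ] <- f[idx[1], ] - co * av$g1
      f[idx[2], ] <- f[idx[2], ] - co * av$g2
      f[idx[3], ] <- f[idx[3], ] - co * av$g3
    }
  }
  list(energy = e, forces = f)
}

#' @export
print.ace_reference <- function(x, ...) {
  cat(sprintf("Analytic reference potential (%s): %d bonds, %d angles\n",
              x$kind, nrow(x$bonds),
              if (is.null(x$angles)) 0L else nrow(x$angles)))
  invisible(x)
}

#' Toy molecule fixtures
#'
#' A small library of programmatically constructed molecular geometries used
#' throughout the tests and examples: a CO diatomic, a bent water molecule,
#' a benzene-like six-ring, and a 12-atom propanol-like chain with three
#' named rotatable dihedrals (`info$dihedrals`).
#'
#' @return named list of [atomic_configuration()]s:
#'   `diatomic`, `triatomic`, `ring6`, `chain`.
#' @export
make_toy_molecules <- function() {
  out <- list()
  ## CO diatomic
  out$diatomic <- atomic_configuration(
    c("C", "O"), rbind(c(0, 0, 0), c(1.128, 0, 0)))
  ## bent water
  ang <- 104.52 * pi / 180
  out$triatomic <- atomic_configuration(
    c("O", "H", "H"),
    rbind(c(0, 0, 0),
          0.9572 * c(1, 0, 0),
          0.9572 * c(cos(ang), sin(ang), 0)))
  ## benzene-like six-ring (C6H6)
  th <- (0:5) * pi / 3
  rc <- 1.397; rh <- rc + 1.084
  out$ring6 <- atomic_configuration(
    rep(c("C", "H"), each = 6),
    rbind(cbind(rc * cos(th), rc * sin(th), 0),
          cbind(rh * cos(th), rh * sin(th), 0)))
  ## propanol-like chain CH3-CH2-CH2-OH
  tz <- 35.26439 * pi / 180   # half the tetrahedral supplement
  da <- c(cos(tz), sin(tz), 0)
  db <- c(cos(tz), -sin(tz), 0)
  C1 <- c(0, 0, 0)
  C2 <- C1 + 1.53 * da
  C3 <- C2 + 1.53 * db
  O  <- C3 + 1.43 * da
  HO <- O + 0.96 * db
  ## methyl hydrogens on C1 (tetrahedral around the C1->C2 direction)
  tet_h <- function(center, u, bond, phis, e1, e2) {
    t(vapply(phis, function(phi) {
      dir <- -u / 3 + (2 * sqrt(2) / 3) * (cos(phi) * e1 + sin(phi) * e2)
      center + bond * dir
    }, numeric(3)))
  }
  orth <- function(u) {
    e1 <- c(-u[2], u[1], 0)
    if (sqrt(sum(e1^2)) < 1e-8) e1 <- c(1, 0, 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    list(e1 = e1, e2 = e2)
  }
  oc1 <- orth(da)
  H1 <- tet_h(C1, da, 1.09, c(0, 2 * pi / 3, 4 * pi / 3), oc1$e1, oc1$e2)
  ## methylene hydrogens: in the plane bisecting the two backbone bonds,
  ## tilted +/- out of plane
  ch2_h <- function(center, nb1, nb2, bond = 1.09) {
    u <- (nb1 - center); u <- u / sqrt(sum(u^2))
    w <- (nb2 - center); w <- w / sqrt(sum(w^2))
    s <- -(u + w); s <- s / sqrt(sum(s^2))
    nrm <- c(u[2] * w[3] - u[3] * w[2],
             u[3] * w[1] - u[1] * w[3],
             u[1] * w[2] - u[2] * w[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    rbind(center + bond * (0.5774 * s + 0.8165 * nrm),
          center + bond * (0.5774 * s - 0.8165 * nrm))
  }
  H2 <- ch2_h(C2, C1, C3)
  H3 <- ch2_h(C3, C2, O)
  chain_pos <- rbind(C1, C2, C3, O, H1, H2, H3, HO)
  chain_el <- c("C", "C", "C", "O", rep("H", 3), rep("H", 2), rep("H", 2), "H")
  out$chain <- atomic_configuration(
    chain_el, chain_pos,
    info = list(dihedrals = list(
      about_C1_C2 = c(5L, 1L, 2L, 3L),
      about_C2_C3 = c(1L, 2L, 3L, 4L),
      about_C3_O = c(2L, 3L, 4L, 12L))))
  out
}

#' Sample labeled configurations
#'
#' Generates `n` configurations around a template and labels each with the
#' reference potential's energy and forces. Two regimes mirror typical
#' training-set construction: `"gaussian_displace"` perturbs every Cartesian
#' coordinate with i.i.d. normal noise of the given standard deviation
#' (near-equilibrium sampling), `"md_sample"` subsamples seeded Langevin
#' trajectories on the reference at one or several temperatures (stratified
#' across temperatures when several are given — the barrier-crossing
#' regime).
#'
#' @param template an [atomic_configuration()].
#' @param reference a calculator providing labels.
#' @param n number of configurations.
#' @param mode `"gaussian_displace"` or `"md_sample"`.
#' @param scale displacement standard deviation (Angstrom) for
#'   `gaussian_displace`.
#' @param temperature temperature(s) in K for `md_sample`.
#' @param seed integer seed; all randomness flows from it.
#' @param n_equil,stride MD-protocol parameters for `md_sample`.
#' @param timestep,friction MD integrator parameters.
#' @return list of labeled configurations; attribute `"metadata"` records
#'   generator kind, parameters and seed.
#' @export
sample_configurations <- function(template, reference, n,
                                  mode = c("gaussian_displace", "md_sample"),
                                  scale = 0.05, temperature = 300,
                                  seed = 1L, n_equil = 200L, stride = 20L,
                                  timestep = 0.5, friction = 0.1) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  label <- function(cfg) {
    ef <- potential_energy_forces(reference, cfg)
    if (!is.finite(ef$energy) || !all(is.finite(ef$forces))) return(NULL)
    atomic_configuration(cfg$elements, cfg$positions,
                         energy = ef$energy, forces = ef$forces)
  }
  out <- vector("list", n)
  if (mode == "gaussian_displace") {
    withr::with_seed(as.integer(seed), {
      for (i in seq_len(n)) {
        cfg_l <- NULL
        for (try in 1:100) {
          pos <- template$positions +
            matrix(stats::rnorm(3 * n_atoms(template), sd = scale),
                   n_atoms(template), 3)
          if (n_atoms(template) > 1 && min(dist(pos)) < 0.5) next
          cfg_l <- label(atomic_configuration(template$elements, pos))
          if (!is.null(cfg_l)) break
        }
        if (is.null(cfg_l)) stop("failed to sample a valid configuration")
        out[[i]] <- cfg_l
      }
    })
  } else {
    temps <- rep_len(temperature, length(temperature))
    per <- diff(round(seq(0, n, length.out = length(temps) + 1)))
    i <- 0L
    for (ti in seq_along(temps)) {
      if (per[ti] == 0) next
      samp <- sample_md_protocol(reference, template, temps[ti],
                                 timestep = timestep, friction = friction,
                                 seed = as.integer(seed) + ti,
                                 n_equil = n_equil, n_samples = per[ti],
                                 stride = stride)
      if (length(samp) < per[ti]) {
        stop("MD sampling terminated before collecting enough configurations")
      }
      for (s in samp) {
        i <- i + 1L
        out[[i]] <- label(s)
      }
    }
  }
  attr(out, "metadata") <- list(mode = mode, scale = scale,
                                temperature = temperature, seed = seed,
                                n = n)
  out
}
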