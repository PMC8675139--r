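## Beyond-RMSE evaluation battery: test-set error metrics, geometry
## relaxation, normal-mode analysis (finite-difference Hessian of analytic
## forces), constrained dihedral scans, rigid bond scans, and seeded Langevin
## molecular dynamics with hole detection. Everything operates through the
## generic calculator interface (potential_energy / potential_forces), so the
## same battery runs on fitted ACE models and on the analytic reference
## potentials.

#' Energy and force error metrics
#'
#' Energy errors are per atom (each configuration's energy residual divided
#' by its atom count); force errors are over all Cartesian components.
#'
#' @param object a calculator (fitted model or reference potential).
#' @param test_set list of labeled [atomic_configuration()]s.
#' @param units `"meV"` (default; meV and meV/Angstrom) or `"eV"`.
#' @return list with `energy_mae`, `energy_rmse`, `force_mae`, `force_rmse`,
#'   `n_configs`, `n_force_components`.
#' @export
error_metrics <- function(object, test_set, units = c("meV", "eV")) {
  units <- match.arg(units)
  de <- numeric(0)
  df <- numeric(0)
  for (cfg in test_set) {
    if (is.null(cfg$energy) && is.null(cfg$forces)) {
      stop("error_metrics: unlabeled configuration in the test set")
    }
    if (!is.null(cfg$energy)) {
      de <- c(de, (potential_energy(object, cfg) - cfg$energy) / n_atoms(cfg))
    }
    if (!is.null(cfg$forces)) {
      df <- c(df, as.vector(potential_forces(object, cfg) - cfg$forces))
    }
  }
  s <- if (units == "meV") 1000 else 1
  list(energy_mae = s * mean(abs(de)),
       energy_rmse = s * sqrt(mean(de^2)),
       force_mae = if (length(df)) s * mean(abs(df)) else NA_real_,
       force_rmse = if (length(df)) s * sqrt(mean(df^2)) else NA_real_,
       n_configs = length(test_set), n_force_components = length(df))
}

## flatten / unflatten positions (row-major over atoms)
.pos_vec <- function(pos) as.vector(t(pos))
.vec_pos <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Relax a geometry
#'
#' Quasi-Newton (BFGS) energy minimization with analytic forces, down to a
#' maximum force component below `force_tol`. Deterministic from a fixed
#' start.
#'
#' @param object a calculator.
#' @param config starting [atomic_configuration()].
#' @param force_tol convergence threshold on the maximum force component
#'   (eV/Angstrom).
#' @param max_steps iteration cap (over BFGS restarts).
#' @return the relaxed configuration; `info$converged` flags success and
#'   `info$max_force` records the residual force.
#' @export
relax_geometry <- function(object, config, force_tol = 1e-4,
                           max_steps = 2000L) {
  els <- config$elements
  fn <- function(v) {
    potential_energy(object, atomic_configuration(els, .vec_pos(v)))
  }
  gr <- function(v) {
    -.pos_vec(potential_forces(object, atomic_configuration(els, .vec_pos(v))))
  }
  v <- .pos_vec(config$positions)
  steps <- 0L
  mf_prev <- Inf
  repeat {
    opt <- stats::optim(v, fn, gr, method = "BFGS",
                        control = list(maxit = 200L, reltol = 1e-16,
                                       abstol = 1e-16))
    v <- opt$par
    steps <- steps + opt$counts[["function"]]
    mf <- max(abs(gr(v)))
    if (mf <= force_tol || steps >= max_steps || mf >= mf_prev) break
    mf_prev <- mf
  }
  ## backtracking gradient-descent polish for the last digits, where BFGS
  ## restarts stagnate; near the floating-point floor of the energy the line
  ## search falls back to reducing the force norm itself
  it <- 0L
  while (mf > force_tol && it < 1000L) {
    it <- it + 1L
    g <- gr(v)
    e0 <- fn(v)
    gn2 <- sum(g^2)
    step <- 0.05 / max(1, max(abs(g)))
    improved <- FALSE
    while (step >= 1e-14) {
      v1 <- v - step * g
      if (fn(v1) <= e0 - 1e-4 * step * gn2) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) {
      step <- 0.05 / max(1, max(abs(g)))
      while (step >= 1e-14) {
        v1 <- v - step * g
        if (sum(gr(v1)^2) < gn2) { improved <- TRUE; break }
        step <- step / 2
      }
    }
    if (!improved) break
    v <- v1
    mf <- max(abs(gr(v)))
  }
  out <- atomic_configuration(els, .vec_pos(v))
  out$info$converged <- mf <= force_tol
  out$info$max_force <- mf
  out$info$energy <- fn(v)
  out
}

#' Normal-mode analysis
#'
#' Mass-weighted Hessian by central finite differences of the analytic
#' forces (step `h`, symmetrized), diagonalized to vibrational frequencies
#' in reciprocal centimeters. Negative Hessian eigenvalues are reported as
#' imaginary frequencies (negative sign in `frequencies`, flagged).
#'
#' @param object a calculator.
#' @param config a relaxed [atomic_configuration()]; a warning is issued (and
#'   the result flagged) if the maximum force exceeds `1e-4` eV/Angstrom.
#' @param h finite-difference displacement (Angstrom).
#' @param zero_tol modes with `|frequency|` below this (cm^-1) are counted as
#'   the translational/rotational null space.
#' @return object of class `"normal_modes"`: `frequencies` (cm^-1, sorted
#'   ascending), `modes` (mass-weighted eigenvectors, columns),
#'   `n_zero_modes`, `imaginary` flags, `relaxed` flag.
#' @export
normal_modes <- function(object, config, h = 0.005, zero_tol = 1.0) {
  n <- n_atoms(config)
  f0 <- potential_forces(object, config)
  relaxed <- max(abs(f0)) <= 1e-4
  if (!relaxed) {
    warning(sprintf(
      "normal_modes: input not relaxed (max |F| = %.3g eV/A); proceeding",
      max(abs(f0))))
  }
  els <- config$elements
  H <- matrix(0, 3 * n, 3 * n)
  pos <- config$positions
  for (a in seq_len(n)) {
    for (d in 1:3) {
      pp <- pos; pp[a, d] <- pp[a, d] + h
      fp <- potential_forces(object, atomic_configuration(els, pp))
      pm <- pos; pm[a, d] <- pm[a, d] - h
      fm <- potential_forces(object, atomic_configuration(els, pm))
      ## H[.., col] = d^2 E / dx dx_col = -dF/dx_col
      H[, (a - 1) * 3 + d] <- -.pos_vec(fp - fm) / (2 * h)
    }
  }
  H <- (H + t(H)) / 2
  m <- rep(atomic_masses(els), each = 3)
  Hw <- H / sqrt(outer(m, m))
  ## project out rigid-body translations and rotations (Eckart conditions)
  ## so the 3N-6 (3N-5) internal modes are not contaminated by the
  ## finite-difference anharmonicity picked up along the null directions
  V <- .rigid_body_basis(pos, atomic_masses(els))
  Hw <- Hw - V %*% (t(V) %*% Hw)
  Hw <- Hw - (Hw %*% V) %*% t(V)
  Hw <- (Hw + t(Hw)) / 2
  eig <- eigen(Hw, symmetric = TRUE)
  lam <- rev(eig$values)              # ascending
  vec <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  freq <- sign(lam) * sqrt(abs(lam)) * .ace_freq_cm
  structure(list(frequencies = freq, modes = vec,
                 n_zero_modes = sum(abs(freq) < zero_tol),
                 imaginary = freq < -zero_tol,
                 relaxed = relaxed, h = h),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  fin <- x$frequencies[abs(x$frequencies) >= 1]
  cat(sprintf("Normal modes: %d finite frequencies, %d near-zero modes%s\n",
              length(fin), x$n_zero_modes,
              if (any(x$imaginary)) sprintf(" (%d imaginary!)",
                                            sum(x$imaginary)) else ""))
  cat("  frequencies (cm^-1):",
      paste(sprintf("%.1f", fin), collapse = ", "), "\n")
  invisible(x)
}

## orthonormal basis (columns) of mass-weighted rigid-body displacements:
## 3 translations plus 3 (2 for linear molecules) infinitesimal rotations
.rigid_body_basis <- function(pos, masses) {
  n <- nrow(pos)
  sm <- sqrt(masses)
  com <- colSums(pos * masses) / sum(masses)
  rel <- sweep(pos, 2, com)
  cols <- list()
  for (d in 1:3) {
    v <- matrix(0, n, 3); v[, d] <- 1
    cols[[length(cols) + 1L]] <- as.vector(t(v * sm))
  }
  ex <- diag(3)
  for (d in 1:3) {
    v <- t(apply(rel, 1, function(r) c(r[2] * ex[d, 3] - r[3] * ex[d, 2],
                                       r[3] * ex[d, 1] - r[1] * ex[d, 3],
                                       r[1] * ex[d, 2] - r[2] * ex[d, 1])))
    cols[[length(cols) + 1L]] <- as.vector(t(v * sm))
  }
  M <- do.call(cbind, cols)
  qrm <- qr(M)
  rank <- sum(abs(diag(qr.R(qrm))) > 1e-8 * max(abs(diag(qr.R(qrm)))))
  qr.Q(qrm)[, seq_len(rank), drop = FALSE]
}

## --- scan helpers -----------------------------------------------------------

.covalent_radii <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
                     Br = 1.20, I = 1.39)

## bonded pairs by covalent-radius criterion (1.3 x sum of radii)
.bond_list <- function(config, scale = 1.3) {
  n <- n_atoms(config)
  if (n < 2) return(matrix(0L, 0, 2))
  rad <- .covalent_radii[config$elements]
  rad[is.na(rad)] <- 0.8
  d <- as.matrix(dist(config$positions))
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] <= scale * (rad[i] + rad[j])) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  do.call(rbind, out)
}

## atoms on the idx3-side of the bond idx2-idx3 (connected component after
## removing the bond), including idx3
.dihedral_moving_set <- function(config, idx) {
  bonds <- .bond_list(config)
  adj <- vector("list", n_atoms(config))
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    if ((i == idx[2] && j == idx[3]) || (i == idx[3] && j == idx[2])) next
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n_atoms(config))
  queue <- idx[3]
  seen[idx[3]] <- TRUE
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    for (b in adj[[a]]) {
      if (!seen[b]) { seen[b] <- TRUE; queue <- c(queue, b) }
    }
  }
  if (seen[idx[2]]) {
    stop("dihedral scan: the bond is part of a ring; cannot split the molecule")
  }
  which(seen)
}

## rotate the moving set about the idx2->idx3 axis so that the dihedral
## equals target_deg exactly
.set_dihedral <- function(config, idx, target_deg, moving) {
  rotate_by <- function(pos, ang) {
    axis <- pos[idx[3], ] - pos[idx[2], ]
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2],
                  -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    ctr <- pos[idx[2], ]
    pos[moving, ] <- sweep(sweep(pos[moving, , drop = FALSE], 2, ctr) %*% t(R),
                           2, ctr, "+")
    pos
  }
  wrap <- function(x) ((x + 180) %% 360) - 180
  cur <- dihedral_angle(config, idx)
  dphi <- wrap(target_deg - cur) * pi / 180
  pos1 <- rotate_by(config$positions, dphi)
  c1 <- atomic_configuration(config$elements, pos1)
  if (abs(wrap(dihedral_angle(c1, idx) - target_deg)) > 1e-6) {
    pos1 <- rotate_by(config$positions, -dphi)
    c1 <- atomic_configuration(config$elements, pos1)
  }
  c1
}

#' Constrained dihedral scan
#'
#' At each grid angle, minimizes the energy subject to the fixed dihedral:
#' a stiff harmonic restraint drives a BFGS minimization, the dihedral is
#' then restored exactly by rotation about the bond, and a projected-gradient
#' polish (forces projected onto the constraint tangent space) finishes the
#' point. Points are chained along the grid. Energies are reported relative
#' to the scan minimum.
#'
#' @param object a calculator.
#' @param config starting [atomic_configuration()].
#' @param dihedral integer 4-vector of atom indices.
#' @param grid target angles in degrees, within (-180, 180].
#' @param restrain_k restraint stiffness (eV/rad^2).
#' @param force_tol convergence threshold on the projected force
#'   (eV/Angstrom).
#' @param maxiter polish iteration cap per point.
#' @return object of class `"ace_scan"` with columns `coordinate` (degrees),
#'   `energy` (eV, relative to the scan minimum) and `converged`.
#' @export
dihedral_scan <- function(object, config, dihedral, grid,
                          restrain_k = 1000, force_tol = 1e-4,
                          maxiter = 300L) {
  stopifnot(length(dihedral) == 4)
  if (any(grid < -180 | grid > 180)) {
    stop("grid angles must lie in [-180, 180]")
  }
  wrap <- function(x) ((x + 180) %% 360) - 180
  moving <- .dihedral_moving_set(config, dihedral)
  els <- config$elements
  energies <- numeric(length(grid))
  converged <- logical(length(grid))
  current <- config
  phi_grad <- function(pos) {
    dh <- .dihedral_angle(pos[dihedral[1], ], pos[dihedral[2], ],
                          pos[dihedral[3], ], pos[dihedral[4], ], grad = TRUE)
    g <- matrix(0, nrow(pos), 3)
    g[dihedral, ] <- dh$grad
    list(phi = dh$phi * 180 / pi, grad = .pos_vec(g))
  }
  for (gi in seq_along(grid)) {
    target <- grid[gi]
    start <- .set_dihedral(current, dihedral, target, moving)
    ## stage 1: restrained BFGS
    fn <- function(v) {
      cfg <- atomic_configuration(els, .vec_pos(v))
      pg <- phi_grad(cfg$positions)
      potential_energy(object, cfg) +
        restrain_k * (wrap(pg$phi - target) * pi / 180)^2
    }
    gr <- function(v) {
      cfg <- atomic_configuration(els, .vec_pos(v))
      pg <- phi_grad(cfg$positions)
      -.pos_vec(potential_forces(object, cfg)) +
        2 * restrain_k * (wrap(pg$phi - target) * pi / 180) * pg$grad
    }
    opt <- stats::optim(.pos_vec(start$positions), fn, gr, method = "BFGS",
                        control = list(maxit = 500L, reltol = 1e-16))
    cfg <- .set_dihedral(atomic_configuration(els, .vec_pos(opt$par)),
                         dihedral, target, moving)
    ## stage 2: projected-gradient polish with exact restoration
    ok <- FALSE
    for (it in seq_len(maxiter)) {
      ef <- potential_energy_forces(object, cfg)
      g <- -.pos_vec(ef$forces)
      pg <- phi_grad(cfg$positions)
      gt <- g - sum(g * pg$grad) / sum(pg$grad^2) * pg$grad
      if (max(abs(gt)) <= force_tol) { ok <- TRUE; break }
      step <- 0.05 / max(1, max(abs(gt)))
      e0 <- ef$energy
      repeat {
        trial <- .set_dihedral(
          atomic_configuration(els,
                               .vec_pos(.pos_vec(cfg$positions) - step * gt)),
          dihedral, target, moving)
        e1 <- potential_energy(object, trial)
        if (e1 <= e0 - 1e-4 * step * sum(gt^2) || step < 1e-10) break
        step <- step / 2
      }
      if (step < 1e-10) { ok <- max(abs(gt)) <= 10 * force_tol; break }
      cfg <- trial
    }
    energies[gi] <- potential_energy(object, cfg)
    converged[gi] <- ok &&
      abs(wrap(dihedral_angle(cfg, dihedral) - target)) <= 0.1
    current <- cfg
  }
  structure(list(coordinate = grid, energy = energies - min(energies),
                 converged = converged, type = "dihedral",
                 dihedral = dihedral),
            class = "ace_scan")
}

#' Rigid bond scan
#'
#' Displaces the second atom of the pair along the bond direction to each
#' requested distance, all other degrees of freedom fixed, and records the
#' energy.
#'
#' @param object a calculator.
#' @param config an [atomic_configuration()].
#' @param pair integer 2-vector `(i, j)`: atom j is moved along the i->j
#'   direction.
#' @param distances target bond lengths (Angstrom, > 0).
#' @return object of class `"ace_scan"` (energies relative to the scan
#'   minimum; `info` keeps the absolute energies).
#' @export
bond_scan <- function(object, config, pair, distances) {
  stopifnot(length(pair) == 2)
  if (any(distances <= 0)) stop("bond distances must be positive")
  p1 <- config$positions[pair[1], ]
  p2 <- config$positions[pair[2], ]
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  energies <- vapply(distances, function(d) {
    pos <- config$positions
    pos[pair[2], ] <- p1 + d * u
    potential_energy(object, atomic_configuration(config$elements, pos))
  }, numeric(1))
  structure(list(coordinate = distances, energy = energies - min(energies),
                 converged = rep(TRUE, length(distances)),
                 type = "bond", pair = pair,
                 absolute_energy = energies),
            class = "ace_scan")
}

#' @export
print.ace_scan <- function(x, ...) {
  cat(sprintf("%s scan, %d points, barrier %.4f eV%s\n",
              x$type, length(x$coordinate), max(x$energy),
              if (!all(x$converged)) sprintf(" (%d unconverged)",
                                             sum(!x$converged)) else ""))
  invisible(x)
}

#' @export
plot.ace_scan <- function(x, ...) {
  xl <- if (x$type == "dihedral") "dihedral (degrees)" else "distance (A)"
  graphics::plot(x$coordinate, x$energy, type = "b", xlab = xl,
                 ylab = "energy (eV)", ...)
  invisible(x)
}

## --- molecular dynamics -----------------------------------------------------

#' Langevin molecular dynamics
#'
#' BAOAB-splitting Langevin integrator with a fixed seed (bit-reproducible
#' trajectories). Every step is monitored for "holes" in the potential: the
#' run terminates, flagged, when the potential energy drops more than
#' `hole_floor` below the starting energy or when any pair distance falls
#' below `min_distance` (defaults to the model's inner cutoff).
#'
#' @param object a calculator.
#' @param config starting [atomic_configuration()].
#' @param temperature target temperature (K).
#' @param timestep time step in femtoseconds.
#' @param n_steps number of steps.
#' @param friction Langevin friction (1/fs); `0` disables the thermostat
#'   (velocity Verlet limit).
#' @param seed integer RNG seed.
#' @param sample_every record every k-th frame (the starting frame is always
#'   recorded).
#' @param hole_floor energy drop (eV) below the starting potential energy
#'   that triggers hole detection.
#' @param min_distance pair-distance floor (Angstrom).
#' @param velocities optional starting velocities (Angstrom per internal time
#'   unit); drawn from the Maxwell-Boltzmann distribution when `NULL`.
#' @return object of class `"ace_md"`: recorded `frames` (configurations),
#'   `potential`/`kinetic` energy traces (eV, every step), `time_fs`,
#'   `terminated` flag and `reason`.
#' @export
run_langevin_md <- function(object, config, temperature, timestep = 0.3,
                            n_steps = 1000L, friction = 0.01, seed = 1L,
                            sample_every = 1L, hole_floor = 10,
                            min_distance = NULL, velocities = NULL) {
  stopifnot(temperature >= 0, timestep > 0, n_steps >= 1)
  if (is.null(min_distance)) {
    min_distance <- if (inherits(object, "linear_ace")) {
      object$basis$radial$r_in
    } else {
      0.3
    }
  }
  kT <- .ace_const$kB * temperature
  m <- atomic_masses(config$elements)
  n <- n_atoms(config)
  dt <- timestep / .ace_time_fs          # internal time units
  gam <- friction * .ace_time_fs         # per internal time unit
  c1 <- exp(-gam * dt)
  c2 <- sqrt(pmax(0, kT * (1 - c1^2)) / m)
  withr::with_seed(as.integer(seed), {
    pos <- config$positions
    v <- if (is.null(velocities)) {
      matrix(stats::rnorm(3 * n), n, 3) * sqrt(kT / m)
    } else {
      velocities
    }
    ef <- potential_energy_forces(object, config)
    e_start <- ef$energy
    pot <- numeric(n_steps); kin <- numeric(n_steps)
    frames <- list(config)
    terminated <- FALSE; reason <- NA_character_; done <- 0L
    for (s in seq_len(n_steps)) {
      a <- ef$forces / m
      v <- v + 0.5 * dt * a                       # B
      pos <- pos + 0.5 * dt * v                   # A
      if (friction > 0) {
        v <- c1 * v + matrix(stats::rnorm(3 * n), n, 3) * c2   # O
      }
      pos <- pos + 0.5 * dt * v                   # A
      cfg <- atomic_configuration(config$elements, pos)
      ef <- potential_energy_forces(object, cfg)
      if (!all(is.finite(ef$forces)) || !is.finite(ef$energy)) {
        terminated <- TRUE; reason <- "non-finite energy or force"
        done <- s; break
      }
      v <- v + 0.5 * dt * ef$forces / m           # B
      pot[s] <- ef$energy
      kin[s] <- 0.5 * sum(m * rowSums(v^2))
      done <- s
      if (s %% sample_every == 0L) {
        frames[[length(frames) + 1L]] <- cfg
      }
      if (ef$energy < e_start - hole_floor) {
        terminated <- TRUE; reason <- "potential energy hole"; break
      }
      if (n > 1 && min(dist(pos)) < min_distance) {
        terminated <- TRUE; reason <- "pair distance below inner cutoff"
        break
      }
    }
    structure(list(frames = frames, potential = pot[seq_len(done)],
                   kinetic = kin[seq_len(done)],
                   time_fs = seq_len(done) * timestep,
                   terminated = terminated, reason = reason,
                   n_steps_done = done, temperature = temperature,
                   timestep = timestep, friction = friction, seed = seed),
              class = "ace_md")
  })
}

#' @export
print.ace_md <- function(x, ...) {
  cat(sprintf("Langevin MD: %d steps at %g K (dt = %g fs)%s\n",
              x$n_steps_done, x$temperature, x$timestep,
              if (x$terminated) paste0(" -- TERMINATED: ", x$reason) else ""))
  if (x$n_steps_done > 0) {
    cat(sprintf("  mean potential %.4f eV, mean kinetic %.4f eV\n",
                mean(x$potential), mean(x$kinetic)))
  }
  invisible(x)
}

#' Equilibrate-then-sample MD protocol
#'
#' Runs seeded Langevin dynamics, discards an equilibration segment, then
#' collects samples a fixed number of steps apart (the protocol used to
#' build temperature-transfer test sets).
#'
#' @inheritParams run_langevin_md
#' @param n_equil equilibration steps discarded before sampling.
#' @param n_samples number of configurations to collect.
#' @param stride steps between samples.
#' @return list of sampled [atomic_configuration()]s (unlabeled); attribute
#'   `"md"` carries the underlying `"ace_md"` run.
#' @export
sample_md_protocol <- function(object, config, temperature, timestep = 0.3,
                               friction = 0.05, seed = 1L,
                               n_equil = 500L, n_samples = 10L,
                               stride = 200L) {
  total <- n_equil + n_samples * stride
  md <- run_langevin_md(object, config, temperature, timestep = timestep,
                        n_steps = total, friction = friction, seed = seed,
                        sample_every = 1L)
  if (md$terminated) {
    warning("MD terminated early (", md$reason, "); returning ",
            "the samples collected before termination")
  }
  idx <- n_equil + seq_len(n_samples) * stride
  idx <- idx[idx <= md$n_steps_done]
  out <- md$frames[idx + 1L]   # frames[1] is the start
  attr(out, "md") <- md
  out
}

#' Simulate configurations from a fitted model
#'
#' Draws thermal samples from the model's own potential-energy surface via
#' the seeded Langevin equilibrate-then-sample protocol.
#'
#' @param object a fitted `"linear_ace"` model.
#' @param nsim number of configurations.
#' @param seed integer seed.
#' @param config starting [atomic_configuration()].
#' @param temperature temperature (K).
#' @param ... further arguments passed to [sample_md_protocol()].
#' @return list of sampled configurations.
#' @export
simulate.linear_ace <- function(object, nsim = 10, seed = 1L, config,
                                temperature = 300, ...) {
  sample_md_protocol(object, config, temperature, seed = seed,
                     n_samples = nsim, ...)
}
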