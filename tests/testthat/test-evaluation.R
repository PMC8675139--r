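test_that("error metrics follow their definitions", {
  mols <- fixture("mols")
  ref <- make_reference_potential(mols$triatomic, seed = 2)
  data <- sample_configurations(mols$triatomic, ref, n = 15, scale = 0.05,
                                seed = 5)
  ## the labeling model predicts its own labels exactly
  met <- error_metrics(ref, data)
  expect_equal(met$energy_mae, 0)
  expect_equal(met$force_rmse, 0)
  ## a constant-zero model: energy MAE = mean |E| / N, in meV
  zero <- structure(list(), class = "zero_model")
  assign("potential_energy.zero_model",
         function(object, config, ...) 0, envir = globalenv())
  assign("potential_forces.zero_model",
         function(object, config, ...) matrix(0, n_atoms(config), 3),
         envir = globalenv())
  on.exit(rm("potential_energy.zero_model", "potential_forces.zero_model",
             envir = globalenv()))
  metz <- error_metrics(zero, data)
  expect_rel_error(metz$energy_mae,
                   1000 * mean(abs(vapply(data, `[[`, numeric(1), "energy"))) /
                     3, 1e-12)
  expect_lte(metz$energy_mae, metz$energy_rmse)
  expect_lte(metz$force_mae, metz$force_rmse)
  expect_error(error_metrics(ref, list(
    atomic_configuration("H", matrix(0, 1, 3)))), "unlabeled")
})

test_that("geometry relaxation descends to the known minimum", {
  mols <- fixture("mols")
  ref <- make_reference_potential(mols$diatomic, params = list(jitter = FALSE),
                                  seed = 1)
  ## start away from equilibrium: converges to the Morse minimum r_e
  start <- atomic_configuration(c("C", "O"),
                                rbind(c(0, 0, 0), c(1.45, 0.1, 0)))
  e_start <- potential_energy(ref, start)
  rel <- relax_geometry(ref, start, force_tol = 1e-6)
  expect_true(rel$info$converged)
  expect_lt(abs(dist(rel$positions) - ref$r_e[1]), 1e-6)
  expect_lte(rel$info$energy, e_start)
  ## starting at a stationary point returns it unchanged (within tolerance)
  rel2 <- relax_geometry(ref, rel, force_tol = 1e-6)
  expect_lt(max(abs(rel2$positions - rel$positions)), 1e-6)
})

test_that("normal modes reproduce the closed-form diatomic frequency", {
  mols <- fixture("mols")
  ref <- make_reference_potential(mols$diatomic, params = list(jitter = FALSE),
                                  seed = 1)
  rel <- relax_geometry(ref, mols$diatomic, force_tol = 1e-8)
  nm <- normal_modes(ref, rel)
  fin <- nm$frequencies[abs(nm$frequencies) >= 1]
  expect_length(fin, 1)
  expect_identical(nm$n_zero_modes, 5L)  # linear molecule: 3N - 5 = 1 finite
  k <- 2 * ref$D_e[1] * ref$a[1]^2       # Morse curvature at the minimum
  mu <- prod(atomic_masses(c("C", "O"))) / sum(atomic_masses(c("C", "O")))
  expect_rel_error(fin, sqrt(k / mu) * acemol:::.ace_freq_cm, 1e-3)
  ## mass-weighted eigenvectors are orthonormal
  M <- crossprod(nm$modes)
  expect_lt(max(abs(M - diag(nrow(M)))), 1e-10)
})

test_that("a bent triatomic has 3N-6 finite and 6 near-zero modes", {
  mols <- fixture("mols")
  ref <- make_reference_potential(mols$triatomic, seed = 2)
  rel <- relax_geometry(ref, mols$triatomic, force_tol = 1e-8)
  nm <- normal_modes(ref, rel)
  expect_identical(sum(abs(nm$frequencies) >= 1), 3L)
  expect_identical(nm$n_zero_modes, 6L)
  expect_false(any(nm$imaginary))
  ## frequencies are orientation-independent (FD step reduced so that the
  ## finite-difference truncation error does not mask the comparison)
  nmf <- normal_modes(ref, rel, h = 1e-3)
  Q <- withr::with_seed(9, random_rotation())
  nmr <- normal_modes(ref, rotate_structure(rel, Q), h = 1e-3)
  expect_lt(max(abs(sort(nmf$frequencies[abs(nmf$frequencies) >= 1]) -
                      sort(nmr$frequencies[abs(nmr$frequencies) >= 1]))),
            0.01)
  ## unrelaxed input warns and flags
  bent <- atomic_configuration(mols$triatomic$elements,
                               mols$triatomic$positions +
                                 matrix(c(0.1, 0, 0, 0, 0.1, 0, 0, 0, 0),
                                        3, 3))
  expect_warning(nmu <- normal_modes(ref, bent), "not relaxed")
  expect_false(nmu$relaxed)
})

test_that("dihedral scans are flat, periodic and anchored at equilibrium", {
  mols <- fixture("mols")
  ## Morse + angles has no dihedral dependence: profile flat to 1e-8 eV
  ref <- make_reference_potential(mols$chain, seed = 4)
  dih <- mols$chain$info$dihedrals$about_C2_C3
  sc <- dihedral_scan(ref, mols$chain, dih,
                      grid = c(-120, -60, 0, 60, 120, 180))
  expect_true(all(sc$converged))
  expect_lt(max(sc$energy), 1e-8)
  ## a potential with genuine dihedral dependence: +/-180 degrees coincide
  tm <- torsion_model(ref, dih)
  sc2 <- dihedral_scan(tm, mols$chain, dih, grid = c(-180, 180))
  expect_lt(abs(diff(sc2$energy)), 1e-8)
  ## the unconstrained equilibrium dihedral scans to zero
  relc <- relax_geometry(tm, mols$chain, force_tol = 1e-7)
  phi0 <- dihedral_angle(relc, dih)
  sc3 <- dihedral_scan(tm, relc, dih, grid = phi0)
  expect_lt(abs(sc3$energy), 1e-8)
  expect_error(dihedral_scan(ref, mols$chain, dih, grid = 200), "180")
})

test_that("bond scans plateau beyond the cutoff and match Morse exactly", {
  mols <- fixture("mols")
  refd <- make_reference_potential(mols$diatomic, params = list(jitter = FALSE),
                                   seed = 1)
  dists <- seq(0.9, 5.5, by = 0.25)
  sc <- bond_scan(refd, mols$diatomic, c(1, 2), dists)
  closed <- refd$D_e[1] * ((1 - exp(-refd$a[1] * (dists - refd$r_e[1])))^2 - 1)
  expect_lt(max(abs(sc$absolute_energy - closed)), 1e-10)
  ## ACE model with isolated-atom one-body terms: dissociation plateau
  planted <- fixture("planted_cho")
  rs <- planted$basis$radial
  co <- atomic_configuration(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
  far <- seq(rs$r_out + 0.5, rs$r_out + 2.5, by = 0.5)
  sc2 <- bond_scan(planted, co, c(1, 2), far)
  expect_lt(max(abs(diff(sc2$absolute_energy))), 1e-10)
  expect_equal(sc2$absolute_energy[1],
               unname(planted$one_body["C"] + planted$one_body["O"]),
               tolerance = 1e-12)
  expect_error(bond_scan(refd, mols$diatomic, c(1, 2), c(-1, 2)), "positive")
})

test_that("Langevin MD is seeded, symplectic at zero friction, thermal", {
  mols <- fixture("mols")
  ref <- make_reference_potential(mols$triatomic, seed = 2)
  md1 <- run_langevin_md(ref, mols$triatomic, 300, timestep = 0.3,
                         n_steps = 150, friction = 0.05, seed = 7)
  md2 <- run_langevin_md(ref, mols$triatomic, 300, timestep = 0.3,
                         n_steps = 150, friction = 0.05, seed = 7)
  expect_identical(md1$frames[[151]]$positions, md2$frames[[151]]$positions)
  expect_identical(md1$potential, md2$potential)
  ## zero friction: velocity-Verlet limit conserves energy
  rel <- relax_geometry(ref, mols$triatomic, force_tol = 1e-8)
  md3 <- run_langevin_md(ref, rel, 300, timestep = 0.1, n_steps = 1000,
                         friction = 0, seed = 3)
  etot <- md3$potential + md3$kinetic
  expect_lt(max(etot) - min(etot), 1e-5)
  ## equipartition: mean kinetic energy ~ (3N/2) kT under the thermostat
  md4 <- run_langevin_md(ref, rel, 400, timestep = 0.3, n_steps = 20000,
                         friction = 0.2, seed = 5)
  keexp <- 1.5 * 3 * 8.617333262e-5 * 400
  expect_rel_error(mean(md4$kinetic[-(1:2000)]), keexp, 0.05)
})

test_that("MD hole detection terminates runs that leave the physical region", {
  mols <- fixture("mols")
  ref <- make_reference_potential(mols$diatomic, params = list(jitter = FALSE),
                                  seed = 1)
  ## a tight distance floor must trip immediately at moderate temperature
  md <- run_langevin_md(ref, mols$diatomic, 600, timestep = 0.5,
                        n_steps = 2000, friction = 0.02, seed = 11,
                        min_distance = 1.1)
  expect_true(md$terminated)
  expect_match(md$reason, "distance")
  expect_lt(md$n_steps_done, 2000)
})

test_that("the equilibrate-then-sample protocol returns spaced samples", {
  mols <- fixture("mols")
  ref <- make_reference_potential(mols$triatomic, seed = 2)
  samp <- sample_md_protocol(ref, mols$triatomic, 300, seed = 13,
                             n_equil = 100, n_samples = 5, stride = 50)
  expect_length(samp, 5)
  expect_s3_class(samp[[5]], "atomic_config")
  md <- attr(samp, "md")
  expect_identical(md$n_steps_done, 100L + 5L * 50L)
})
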