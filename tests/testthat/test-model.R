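test_that("site energy reduces to the one-body term and is linear in c", {
  planted <- fixture("planted_cho")
  env0 <- atomic_environment("O", character(0), matrix(0, 0, 3))
  expect_identical(site_energy(planted, env0), unname(planted$one_body["O"]))
  withr::with_seed(12, {
    env <- rand_env(c("C", "H", "O"), planted$basis$radial, 3, 6)
  })
  e1 <- site_energy(planted, env) - planted$one_body[env$center_element]
  m2 <- acemol:::.coef_unpack(planted, 2 * acemol:::.coef_pack(planted))
  e2 <- site_energy(m2, env) - m2$one_body[env$center_element]
  expect_equal(unname(e2), unname(2 * e1), tolerance = 1e-12)
  ## manual dot product against independently evaluated B values (model
  ## without the pair block, so the multibody term is the whole site energy)
  ring <- fixture("ring_setup")
  withr::with_seed(15, {
    envc <- rand_env("C", ring$rs, 3, 6)
  })
  B <- evaluate_basis(envc, ring$basis)
  manual <- sum(B * ring$planted$coefficients[, 1])
  expect_equal(unname(site_energy(ring$planted, envc)),
               unname(ring$planted$one_body["C"] + manual),
               tolerance = 1e-14)
})

test_that("total energy respects the isometries and isolated-atom limit", {
  planted <- fixture("planted_cho")
  mols <- fixture("mols")
  cfg <- mols$chain
  e0 <- potential_energy(planted, cfg)
  ## translation
  shifted <- atomic_configuration(cfg$elements, cfg$positions + 17.3)
  expect_lt(abs(potential_energy(planted, shifted) - e0), 1e-12)
  ## rotation and reflection
  withr::with_seed(13, {
    for (k in 1:3) {
      Q <- random_rotation()
      expect_lt(abs(potential_energy(planted, rotate_structure(cfg, Q)) - e0),
                1e-10)
    }
  })
  ## permutation of identical atoms (swap two hydrogens)
  perm <- seq_len(n_atoms(cfg)); perm[c(5, 6)] <- c(6, 5)
  pcfg <- atomic_configuration(cfg$elements[perm], cfg$positions[perm, ])
  expect_lt(abs(potential_energy(planted, pcfg) - e0), 1e-12)
  ## a single isolated atom evaluates to its one-body energy
  iso <- atomic_configuration("C", matrix(0, 1, 3))
  expect_identical(potential_energy(planted, iso),
                   unname(planted$one_body["C"]))
  expect_identical(max(abs(potential_forces(planted, iso))), 0)
  expect_error(potential_energy(planted,
                                atomic_configuration("N", matrix(0, 1, 3))),
               "not declared")
})

test_that("forces are the exact negative gradient with zero net force", {
  planted <- fixture("planted_cho")
  withr::with_seed(14, {
    cfg <- rand_config(5)
    ef <- potential_energy_forces(planted, cfg)
    expect_lt(max(abs(colSums(ef$forces))), 1e-10)
    h <- 1e-5
    maxdev <- 0
    for (a in seq_len(5)) {
      for (d in 1:3) {
        pp <- cfg$positions; pp[a, d] <- pp[a, d] + h
        pm <- cfg$positions; pm[a, d] <- pm[a, d] - h
        fd <- (potential_energy(planted,
                                atomic_configuration(cfg$elements, pp)) -
                 potential_energy(planted,
                                  atomic_configuration(cfg$elements, pm))) /
          (2 * h)
        maxdev <- max(maxdev, abs(fd + ef$forces[a, d]))
      }
    }
    expect_lt(maxdev, 1e-6)
  })
})

test_that("energies are strictly local and fragments separate exactly", {
  planted <- fixture("planted_cho")
  mols <- fixture("mols")
  rs <- planted$basis$radial
  pos <- mols$chain$positions
  els <- mols$chain$elements
  frag <- c(4L, 12L)
  pos2 <- pos
  pos2[frag, ] <- pos2[frag, ] + matrix(c(50, 0, 0), 2, 3, byrow = TRUE)
  e_all <- potential_energy(planted, atomic_configuration(els, pos2))
  e_a <- potential_energy(planted,
                          atomic_configuration(els[-frag], pos[-frag, ]))
  e_b <- potential_energy(planted,
                          atomic_configuration(els[frag], pos[frag, ]))
  expect_identical(e_all, e_a + e_b)
  ## perturbing an atom beyond 2 r_out leaves a site energy bit-identical
  envs1 <- configuration_environments(atomic_configuration(els, pos2),
                                      rs$r_out)
  pos3 <- pos2; pos3[4, ] <- pos3[4, ] + 0.37
  envs2 <- configuration_environments(atomic_configuration(els, pos3),
                                      rs$r_out)
  expect_identical(site_energy(planted, envs1[[1]]),
                   site_energy(planted, envs2[[1]]))
})

test_that("the three one-body strategies behave as specified", {
  mols <- fixture("mols")
  bs <- fixture("basis_oh")
  ref <- make_reference_potential(mols$triatomic, seed = 2)
  data <- sample_configurations(mols$triatomic, ref, n = 40, scale = 0.05,
                                seed = 5)
  ## isolated_atom: dissociation limit equals the sum of one-body energies
  e0 <- c(O = -75.0, H = -0.5)
  fitE <- ace_fit(data, bs, one_body = "isolated_atom", e0 = e0,
                  fitcfg = fit_config(lambda = 1e-6))
  apart <- atomic_configuration(c("O", "H", "H"),
                                rbind(c(0, 0, 0), c(100, 0, 0),
                                      c(0, 100, 0)))
  expect_equal(potential_energy(fitE, apart), sum(e0[c("O", "H", "H")]),
               tolerance = 1e-12)
  ## training_average: constant per-atom energy datasets are centered exactly
  same <- lapply(1:5, function(i) {
    atomic_configuration(mols$triatomic$elements,
                         mols$triatomic$positions + 10 * i,
                         energy = 3 * 1.5)
  })
  m <- set_one_body_term(linear_ace_model(bs), "training_average",
                         dataset = same)
  expect_equal(unname(m$one_body), c(1.5, 1.5))
  resid <- vapply(same, function(cfg) {
    potential_energy(m, cfg) - cfg$energy
  }, numeric(1))
  expect_lt(abs(mean(resid)), 1e-12)
  ## forces_only_shift zeroes the mean signed per-atom energy residual
  fitF <- ace_fit(data, bs, one_body = "forces_only_shift",
                  fitcfg = fit_config(lambda = 1e-6))
  residF <- vapply(data, function(cfg) {
    (cfg$energy - potential_energy(fitF, cfg)) / n_atoms(cfg)
  }, numeric(1))
  expect_lt(abs(mean(residF)), 1e-10)
  expect_error(set_one_body_term(linear_ace_model(bs), "isolated_atom"),
               "requires")
})
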