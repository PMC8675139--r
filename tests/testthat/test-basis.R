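test_that("product-spec enumeration matches the hand count and is canonical", {
  sel <- basis_selection("C", nu_max = 1, degree_caps = 3, w_Y = 2)
  sp <- enumerate_product_specs(sel, n_max = 3)
  ## {n + 2l <= 3} = (1,0),(2,0),(3,0) with m = 0 and (1,1) with m in -1..1
  expect_length(sp, 6)
  nl <- t(vapply(sp, function(m) m[1, c("n", "l")], numeric(2)))
  expect_setequal(paste(nl[, 1], nl[, 2]),
                  c("1 0", "2 0", "3 0", "1 1", "1 1", "1 1"))
  ## canonical sorting: permuted factor orders give identical specs
  selc <- basis_selection(c("C", "H"), nu_max = 2, degree_caps = c(4, 4))
  sp2 <- enumerate_product_specs(selc, n_max = 2)
  keys <- vapply(sp2, function(m) paste(t(m), collapse = ","), character(1))
  expect_false(anyDuplicated(keys) > 0)
  ## monotone truncation: nu_max = 2 list contains the nu_max = 1 list
  sp1 <- enumerate_product_specs(
    basis_selection(c("C", "H"), nu_max = 1, degree_caps = 4), n_max = 2)
  keys1 <- vapply(sp1, function(m) paste(t(m), collapse = ","), character(1))
  expect_true(all(keys1 %in% keys))
  expect_error(basis_selection(character(0)), "empty element")
})

test_that("symmetrization returns exactly the invariant couplings", {
  ## nu = 1: l = 0 survives the rotation average, l > 0 is annihilated
  sk0 <- cbind(iz = 1L, n = 1L, l = 0L)
  fs <- symmetrize(sk0)
  expect_length(fs, 1)
  expect_equal(unname(abs(fs[[1]]$coupling[, "coeff"])), 1)
  expect_length(symmetrize(cbind(iz = 1L, n = 1L, l = 1L)), 0)
  ## nu = 2: l1 != l2 cannot couple to a scalar; l1 = l2 gives one invariant
  expect_length(symmetrize(cbind(iz = 1L, n = c(1L, 1L), l = c(1L, 2L))), 0)
  fs2 <- symmetrize(cbind(iz = 1L, n = c(1L, 2L), l = c(2L, 2L)))
  expect_length(fs2, 1)
  expect_equal(nrow(fs2[[1]]$coupling), 5)  # one entry per m
})

test_that("every symmetrized function is O(3)-invariant on random input", {
  rs <- fixture("rs_small")
  bs <- fixture("basis_cho3")
  withr::with_seed(21, {
    for (rep in 1:5) {
      env <- rand_env(c("C", "H", "O"), rs)
      B0 <- evaluate_basis(env, bs)
      for (k in 1:20) {
        Q <- random_rotation()  # full O(3): improper with probability 1/2
        B1 <- evaluate_basis(rotate_structure(env, Q), bs)
        expect_lt(max(abs(B1 - B0)), 1e-10)
      }
    }
  })
})

test_that("dependency pruning removes duplicates and zeros, rank is stable", {
  rs <- fixture("rs_small")
  sel <- basis_selection(c("C", "H"), nu_max = 2, degree_caps = c(5, 4))
  skels <- acemol:::.enumerate_skeletons(sel, rs$n_max)
  tab <- acemol:::.factor_table(sel, rs$n_max)
  cands <- list()
  for (sk in skels) {
    cands <- c(cands, symmetrize(tab[sk, c("iz", "n", "l"), drop = FALSE]))
  }
  ## inject an exact duplicate and a zero function
  dup <- cands[[3]]
  zero <- cands[[1]]
  zero$coupling[, "coeff"] <- 0
  cands2 <- c(cands, list(dup, zero))
  po <- build_orthogonal_polynomials(rs)
  envs <- withr::with_seed(31, lapply(seq_len(3 * length(cands2)),
                                      function(i) rand_env(c("C", "H"), rs)))
  keep <- remove_linear_dependencies(cands2, envs, rs, po,
                                     acemol:::.l_max_of(sel), c("C", "H"))
  expect_length(keep, length(cands))           # duplicate + zero removed
  envs2 <- withr::with_seed(32, lapply(seq_len(3 * length(cands2)),
                                       function(i) rand_env(c("C", "H"), rs)))
  keep2 <- remove_linear_dependencies(cands2, envs2, rs, po,
                                      acemol:::.l_max_of(sel), c("C", "H"))
  expect_identical(length(keep), length(keep2))  # rank reproducible
  expect_error(remove_linear_dependencies(cands2, envs[1:3], rs, po,
                                          acemol:::.l_max_of(sel),
                                          c("C", "H")),
               "insufficient")
})

test_that("basis evaluation is permutation-invariant and local", {
  rs <- fixture("rs_small")
  bs <- fixture("basis_cho3")
  withr::with_seed(41, {
    env <- rand_env(c("C", "H", "O"), rs, 5, 8)
    perm <- sample(length(env$neighbor_elements))
    env2 <- atomic_environment(env$center_element,
                               env$neighbor_elements[perm],
                               env$displacements[perm, ])
    expect_identical(evaluate_basis(env, bs), evaluate_basis(env2, bs))
    ## empty environment: all nu >= 1 functions vanish
    env0 <- atomic_environment("C", character(0), matrix(0, 0, 3))
    expect_identical(max(abs(evaluate_basis(env0, bs))), 0)
  })
  expect_error(evaluate_basis(
    atomic_environment("N", "H", matrix(c(1, 0, 0), 1, 3)), bs),
    "not declared")
})

test_that("basis gradients match finite differences and respect the cutoff", {
  rs <- fixture("rs_small")
  bs <- fixture("basis_cho3")
  withr::with_seed(51, {
    env <- rand_env(c("C", "H", "O"), rs, 3, 6)
    bg <- evaluate_basis_gradients(env, bs)
    h <- 1e-6
    maxdev <- 0
    for (j in seq_along(env$neighbor_elements)) {
      for (d in 1:3) {
        dp <- env$displacements; dp[j, d] <- dp[j, d] + h
        dm <- env$displacements; dm[j, d] <- dm[j, d] - h
        Bp <- evaluate_basis(atomic_environment(env$center_element,
                                                env$neighbor_elements, dp), bs)
        Bm <- evaluate_basis(atomic_environment(env$center_element,
                                                env$neighbor_elements, dm), bs)
        maxdev <- max(maxdev, max(abs((Bp - Bm) / (2 * h) - bg$dB[, j, d])))
      }
    }
    expect_lt(maxdev, 1e-6)
    ## a neighbor beyond r_out contributes a zero gradient block
    envf <- atomic_environment("C", c("H", "H"),
                               rbind(c(1.5, 0, 0), c(rs$r_out + 1, 0, 0)))
    bgf <- evaluate_basis_gradients(envf, bs)
    expect_identical(max(abs(bgf$dB[, 2, ])), 0)
  })
})

test_that("density-trick products equal the explicit ordered-tuple sum", {
  rs <- fixture("rs_small")
  bs <- fixture("basis_ch2")
  po <- bs$polys
  sel <- basis_selection(c("C", "H"), nu_max = 3, degree_caps = c(5, 4, 4))
  specs <- enumerate_product_specs(sel, n_max = 2)
  withr::with_seed(61, {
    for (rep in 1:10) {
      env <- rand_env(c("C", "H"), rs, 1, 6)
      A <- project_density(env, rs, po, bs$l_max, c("C", "H"))
      for (sp in specs[seq(1, length(specs), by = 7)]) {
        direct <- 1
        for (t in seq_len(nrow(sp))) {
          direct <- direct * A$A[acemol:::.v_index(sp[t, "iz"], sp[t, "n"],
                                                   sp[t, "l"], sp[t, "m"],
                                                   rs$n_max, bs$l_max)]
        }
        oracle <- brute_force_correlation(env, sp, rs, po, bs$l_max,
                                          c("C", "H"))
        expect_lt(abs(direct - oracle), 1e-12)
      }
    }
    ## single neighbor, nu = 2: the only tuple is the self-pair
    env1 <- atomic_environment("C", "H", matrix(c(1.4, 0.3, -0.2), 1, 3))
    sp <- cbind(iz = 2L, n = c(1L, 1L), l = 0L, m = 0L)
    phi <- evaluate_one_particle_basis(c(1.4, 0.3, -0.2), "H", rs, po,
                                       bs$l_max, c("C", "H"))
    i <- acemol:::.v_index(2L, 1L, 0L, 0L, rs$n_max, bs$l_max)
    expect_equal(brute_force_correlation(env1, sp, rs, po, bs$l_max,
                                         c("C", "H")),
                 phi$phi[i]^2, tolerance = 1e-14)
    ## empty environment sums to zero
    env0 <- atomic_environment("C", character(0), matrix(0, 0, 3))
    expect_identical(brute_force_correlation(env0, sp, rs, po, bs$l_max,
                                             c("C", "H")), 0)
  })
  bigenv <- atomic_environment("C", rep("H", 9),
                               cbind(seq(1, 2.6, by = 0.2), 0.5, 0.2))
  expect_error(brute_force_correlation(bigenv, sp, rs, po, bs$l_max,
                                       c("C", "H")), "refuses")
})

test_that("two-correlation invariants span the SOAP power spectrum", {
  rs <- fixture("rs_small")
  bs <- fixture("basis_ch2")
  nus <- vapply(bs$functions, function(f) f$nu, integer(1))
  nenv <- 120
  withr::with_seed(71, {
    XB <- matrix(0, nenv, bs$n_fun)
    XP <- NULL
    for (e in seq_len(nenv)) {
      env <- rand_env(c("C", "H"), rs, 2, 6)
      XB[e, ] <- evaluate_basis(env, bs)
      ps <- power_spectrum(env, rs, bs$polys, bs$l_max, c("C", "H"))
      if (is.null(XP)) {
        XP <- matrix(0, nenv, length(ps))
        chan <- attr(ps, "channels")
      }
      XP[e, ] <- ps
    }
  })
  ## same truncation on both sides: D = n1 + n2 + w_Y (l1 + l2) <= cap
  keep <- chan$n1 + chan$n2 + 2 * 2 * chan$l <= bs$selection$degree_caps[2]
  expect_identical(sum(keep), sum(nus == 2))
  proj_resid <- function(Y, X) {
    qx <- qr(X)
    max(vapply(seq_len(ncol(Y)), function(j) {
      y <- Y[, j]
      sqrt(sum((y - qr.fitted(qx, y))^2)) / max(sqrt(sum(y^2)), 1e-300)
    }, numeric(1)))
  }
  expect_lt(proj_resid(XP[, keep], XB), 1e-10)
  expect_lt(proj_resid(XB[, nus == 2, drop = FALSE], XP[, keep]), 1e-10)
})

test_that("moving a neighbor across r_out keeps B and dB continuous", {
  rs <- fixture("rs_small")
  bs <- fixture("basis_cho3")
  mk <- function(r) atomic_environment("C", c("H", "O"),
                                       rbind(c(1.2, 0.4, 0), c(r, 0, 0)))
  h <- 1e-7
  Bin <- evaluate_basis(mk(rs$r_out - h), bs)
  Bout <- evaluate_basis(mk(rs$r_out + h), bs)
  expect_lt(max(abs(Bin - Bout)), 1e-10)
  gin <- evaluate_basis_gradients(mk(rs$r_out - h), bs)$dB[, 2, ]
  expect_lt(max(abs(gin)), 1e-5)
})
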