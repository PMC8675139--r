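## small synthetic fit problems reused across solver tests
make_problem <- function(A, b, gamma) {
  structure(list(design = A, targets = b, gamma = gamma,
                 fitcfg = fit_config(lambda = 0)),
            class = "fit_problem")
}

test_that("design assembly has the right shape and reproduces the loss", {
  mols <- fixture("mols")
  bs <- fixture("basis_oh")
  ref <- make_reference_potential(mols$triatomic, seed = 2)
  data <- sample_configurations(mols$triatomic, ref, n = 2, scale = 0.05,
                                seed = 5)
  model <- linear_ace_model(bs, one_body_strategy = "training_average")
  fc <- fit_config(energy_weight = 0.7, force_weight = 1.3)
  pb <- assemble_design_matrix(model, data, fc)
  expect_identical(nrow(pb$design), 2L * (1L + 9L))   # 2 x (1 + 3*3) rows
  ## || Psi c - t ||^2 equals the directly evaluated loss for arbitrary c
  withr::with_seed(77, {
    cvec <- rnorm(ncol(pb$design), sd = 0.01)
  })
  m2 <- acemol:::.coef_unpack(pb$model, cvec)
  direct <- ace_loss(m2, data, fc)
  assembled <- sum((pb$design %*% cvec - pb$targets)^2)
  expect_rel_error(assembled, direct, 1e-10)
  ## zero energy weight removes the energy rows
  pb0 <- assemble_design_matrix(model, data,
                                fit_config(energy_weight = 0,
                                           force_weight = 1))
  expect_identical(nrow(pb0$design), 18L)
  expect_true(all(pb0$row_info$kind == "force"))
  ## unlabeled config with nonzero weight is a data error
  bare <- atomic_configuration(mols$triatomic$elements,
                               mols$triatomic$positions)
  expect_error(assemble_design_matrix(model, list(bare), fit_config()),
               "label")
})

test_that("the smoothness prior is positive and monotone in degree", {
  bs <- fixture("basis_cho3")
  model <- linear_ace_model(bs)
  g <- smoothness_prior(model, p = 2)
  expect_true(all(g > 0))
  expect_length(g, acemol:::.n_coef(model))
  ## entries nondecreasing in l: compare same-skeleton pairs differing in l_1
  funs <- bs$functions
  key <- vapply(funs, function(f) {
    paste(f$nu, paste(f$skeleton[, "n"], collapse = ","))
  }, character(1))
  gfun <- g[seq_along(funs)]
  checked <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    l1 <- vapply(idx, function(i) sum(funs[[i]]$skeleton[, "l"]), numeric(1))
    ord <- order(l1)
    expect_true(all(diff(gfun[idx][ord]) >= -1e-12))
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
  ## p = 0 limit: the entry depends only on the correlation order (2 nu)
  g0 <- smoothness_prior(model, p = 0)
  nus <- vapply(funs, function(f) f$nu, integer(1))
  expect_equal(g0[seq_along(funs)], 2 * nus, ignore_attr = TRUE)
})

test_that("LSQR solves the regularized problem along the lambda path", {
  withr::with_seed(101, {
    A <- matrix(rnorm(200 * 30), 200, 30)
    x0 <- rnorm(30)
    b <- as.vector(A %*% x0) + rnorm(200, sd = 0.1)
    g <- runif(30, 0.5, 2)
  })
  pb <- make_problem(A, b, g)
  ols <- qr.solve(A, b)
  expect_lt(max(abs(solve_tychonov_lsqr(pb, 0)$coefficients - ols)), 1e-8)
  ## noiseless full-rank recovery at tiny lambda
  pb2 <- make_problem(A, as.vector(A %*% x0), g)
  xr <- solve_tychonov_lsqr(pb2, 1e-12)$coefficients
  expect_lt(sqrt(sum((xr - x0)^2)) / sqrt(sum(x0^2)), 1e-6)
  ## residual nondecreasing, prior norm nonincreasing over the lambda grid
  path <- vapply(c(0, 1e-4, 1e-2, 1), function(l) {
    cc <- solve_tychonov_lsqr(pb, l)$coefficients
    c(sqrt(sum((A %*% cc - b)^2)), sqrt(sum((g * cc)^2)))
  }, numeric(2))
  expect_true(all(diff(path[1, ]) >= -1e-9))
  expect_true(all(diff(path[2, ]) <= 1e-9))
})

test_that("RRQR truncates, handles rank deficiency, and matches OLS", {
  withr::with_seed(102, {
    A <- matrix(rnorm(120 * 20), 120, 20)
    x0 <- rnorm(20)
    b <- as.vector(A %*% x0) + rnorm(120, sd = 0.05)
    g <- runif(20, 0.5, 2)
  })
  pb <- make_problem(A, b, g)
  ols <- qr.solve(A, b)
  expect_lt(max(abs(solve_rrqr(pb, 1e-13)$coefficients - ols)), 1e-8)
  ## exact duplicate column: finite solution, predictions = min-norm solution
  A2 <- cbind(A, A[, 1])
  pb2 <- make_problem(A2, b, c(g, g[1]))
  c2 <- solve_rrqr(pb2, 1e-10)$coefficients
  sv <- svd(A2)
  keep <- sv$d > 1e-10 * sv$d[1]
  pinv <- sv$v[, keep] %*% ((t(sv$u[, keep]) %*% b) / sv$d[keep])
  expect_lt(max(abs(A2 %*% c2 - A2 %*% pinv)), 1e-8)
  ## truncation beyond the largest singular value wipes everything out
  expect_identical(solve_rrqr(pb, 2 * max(svd(A)$d))$coefficients,
                   rep(0, 20))
  ## the two solvers agree in their exact limits
  expect_lt(max(abs(solve_tychonov_lsqr(pb, 0)$coefficients -
                      solve_rrqr(pb, 1e-13)$coefficients)), 1e-6)
})

test_that("refitting data from a model in the same basis recovers it", {
  rg <- fixture("ring_setup")
  data <- sample_configurations(rg$ring, rg$planted, n = 120, scale = 0.06,
                                seed = 11)
  fit <- ace_fit(data[1:100], rg$basis, one_body = "isolated_atom",
                 e0 = c(C = 0), pair_degree = 0L,
                 fitcfg = fit_config(lambda = 1e-12))
  expect_identical(fit$diagnostics$effective_rank, fit$diagnostics$n_cols)
  cv0 <- acemol:::.coef_pack(rg$planted)
  cv1 <- acemol:::.coef_pack(fit)
  expect_lt(sqrt(sum((cv1 - cv0)^2)) / sqrt(sum(cv0^2)), 1e-6)
  met <- error_metrics(fit, data[101:120], units = "eV")
  expect_lt(met$energy_rmse, 1e-10)
  expect_lt(met$force_rmse, 1e-9)
})

test_that("an empty basis degenerates to one-body terms only", {
  mols <- fixture("mols")
  rs <- radial_spec(r_in = 0.7, r_out = 3.5, n_max = 1)
  bs1 <- ace_basis(basis_selection(c("O", "H"), nu_max = 1, degree_caps = 1),
                   rs)
  expect_identical(bs1$n_fun, 2L)  # one l = 0 channel per element
  ref <- make_reference_potential(mols$triatomic, seed = 2)
  data <- sample_configurations(mols$triatomic, ref, n = 10, scale = 0.03,
                                seed = 9)
  model <- linear_ace_model(bs1, one_body_strategy = "training_average",
                            pair_degree = 0L)
  model <- set_one_body_term(model, "training_average", dataset = data)
  model$coefficients[] <- 0
  resid <- vapply(data, function(cfg) {
    cfg$energy - potential_energy(model, cfg)
  }, numeric(1))
  centered <- vapply(data, function(cfg) {
    cfg$energy - sum(model$one_body[cfg$elements])
  }, numeric(1))
  expect_equal(resid, centered, tolerance = 1e-14)
})
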