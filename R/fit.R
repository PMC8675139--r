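## Regularized linear least-squares fitting of ACE models to energies and
## forces. The loss is
##   L(c) = sum_X wE_X^2 (E(c;X) - E_ref,X)^2
##        + sum_X wF_X^2 sum_k |F_k(c;X) - F_ref,k,X|^2   ( + lambda^2 |Gamma c|^2 )
## written as ||Psi c - t||^2 with one energy row per configuration and three
## force rows per atom. Two solvers: damped LSQR on the augmented system
## [Psi; lambda Gamma], and rank-revealing pivoted QR on the preconditioned
## system Psi Gamma^-1 with singular values truncated below a tolerance.

#' Fit configuration
#'
#' Weights and regularization settings for [assemble_design_matrix()] /
#' [ace_fit()]. Per-configuration overrides are read from
#' `config$info$energy_weight` / `config$info$force_weight` when present.
#'
#' @param energy_weight default energy weight per configuration (1/eV).
#' @param force_weight default force weight per component (Angstrom/eV).
#' @param p smoothness order of the regularization prior (exponent).
#' @param lambda Tychonov strength, or the RRQR truncation tolerance.
#' @param solver `"auto"` (RRQR when rows >= 1.2 x columns, else LSQR),
#'   `"lsqr_tychonov"` or `"rrqr"`.
#' @param seed integer seed recorded with the fit.
#' @return object of class `"fit_config"`.
#' @export
fit_config <- function(energy_weight = 1, force_weight = 1, p = 2,
                       lambda = 1e-8, solver = c("auto", "lsqr_tychonov",
                                                 "rrqr"),
                       seed = 1L) {
  solver <- match.arg(solver)
  if (energy_weight < 0 || force_weight < 0) stop("weights must be >= 0")
  if (energy_weight == 0 && force_weight == 0) {
    stop("at least one of the energy and force weights must be positive")
  }
  if (lambda < 0) stop("lambda must be >= 0")
  if (p < 0) stop("smoothness order p must be >= 0")
  structure(list(energy_weight = energy_weight, force_weight = force_weight,
                 p = p, lambda = lambda, solver = solver,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Smoothness regularization prior
#'
#' Diagonal entries of the regularizer Gamma: a rough estimate of the size of
#' the p-th derivative of each basis function,
#' `Gamma_vv = sum_t (n_t^p + l_t^p)` over the factors of the invariant
#' (pair-basis columns use their polynomial degree `n^p`). High-degree basis
#' functions are scaled down, encouraging a smooth potential.
#'
#' @param model a `"linear_ace"` model (template or fitted): supplies the
#'   basis and the pair-block layout.
#' @param p smoothness order (>= 0).
#' @return numeric vector, one strictly positive entry per linear
#'   coefficient, in the packed coefficient order.
#' @export
smoothness_prior <- function(model, p = 2) {
  if (p < 0) stop("p must be >= 0")
  basis <- model$basis
  gfun <- vapply(basis$functions, function(f) {
    sum(f$skeleton[, "n"]^p + f$skeleton[, "l"]^p)
  }, numeric(1))
  k <- length(basis$elements)
  gb <- rep(gfun, times = k)
  gp <- rep(seq_len(model$pair_degree)^p, times = ncol(model$pair_coefficients))
  g <- c(gb, gp)
  ## l = 0 contributes 0^p; entries stay positive because n >= 1, but guard
  ## against a pathological all-zero entry anyway
  pmax(g, .Machine$double.eps)
}

#' Assemble the least-squares system
#'
#' Builds the design matrix, target vector and regularizer from a labeled
#' dataset. Energy rows are per-configuration feature sums scaled by the
#' energy weight (one-body contributions subtracted from the targets
#' according to the strategy; energy rows are omitted entirely for
#' force-only fits); force rows are negative feature gradients scaled by the
#' force weight.
#'
#' @param model a `"linear_ace"` template carrying basis and one-body
#'   strategy (for `"isolated_atom"` the `one_body` values must already be
#'   set).
#' @param dataset list of labeled [atomic_configuration()]s.
#' @param fitcfg a [fit_config()].
#' @return object of class `"fit_problem"`: `design`, `targets`, `gamma`,
#'   `row_info`, and the (possibly updated) `model` template.
#' @export
assemble_design_matrix <- function(model, dataset, fitcfg = fit_config()) {
  stopifnot(inherits(model, "linear_ace"))
  if (length(dataset) == 0) stop("empty dataset")
  strategy <- model$one_body_strategy
  use_energy <- fitcfg$energy_weight > 0 && strategy != "forces_only_shift"
  if (strategy == "training_average") {
    model <- set_one_body_term(model, "training_average", dataset = dataset)
  }
  rows <- list(); targ <- list(); rinfo <- list()
  for (ci in seq_along(dataset)) {
    cfg <- dataset[[ci]]
    wE <- cfg$info$energy_weight %||% fitcfg$energy_weight
    wF <- cfg$info$force_weight %||% fitcfg$force_weight
    need_grad <- wF > 0 && !is.null(cfg$forces)
    cf <- .config_features(cfg, model, grad = need_grad)
    if (use_energy && wE > 0) {
      if (is.null(cfg$energy)) {
        stop("configuration ", ci,
             " has no energy label but a nonzero energy weight")
      }
      e_off <- sum(model$one_body[cfg$elements])
      rows[[length(rows) + 1L]] <- wE * cf$f
      targ[[length(targ) + 1L]] <- wE * (cfg$energy - e_off)
      rinfo[[length(rinfo) + 1L]] <-
        data.frame(config = ci, kind = "energy", n_atoms = n_atoms(cfg))
    }
    if (need_grad) {
      rows[[length(rows) + 1L]] <- -wF * cf$G
      targ[[length(targ) + 1L]] <- wF * as.vector(t(cfg$forces))
      rinfo[[length(rinfo) + 1L]] <-
        data.frame(config = ci, kind = "force", n_atoms = n_atoms(cfg))
    } else if (wF > 0 && is.null(cfg$forces) && !use_energy) {
      stop("configuration ", ci, " has no usable label")
    }
  }
  if (length(rows) == 0) stop("no observations assembled")
  design <- do.call(rbind, lapply(rows, function(r) {
    if (is.matrix(r)) r else matrix(r, 1)
  }))
  structure(list(design = design, targets = unlist(targ),
                 gamma = smoothness_prior(model, fitcfg$p),
                 row_info = do.call(rbind, rinfo),
                 model = model, fitcfg = fitcfg),
            class = "fit_problem")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Direct loss evaluation
#'
#' Computes the weighted least-squares loss directly from model predictions
#' (without the design matrix); the assembled system satisfies
#' `||Psi c - t||^2 == ace_loss(model with coefficients c, ...)`.
#'
#' @param model a `"linear_ace"` model with coefficients set.
#' @param dataset labeled configurations.
#' @param fitcfg a [fit_config()].
#' @return scalar loss value.
#' @export
ace_loss <- function(model, dataset, fitcfg = fit_config()) {
  total <- 0
  use_energy <- fitcfg$energy_weight > 0 &&
    model$one_body_strategy != "forces_only_shift"
  for (cfg in dataset) {
    wE <- cfg$info$energy_weight %||% fitcfg$energy_weight
    wF <- cfg$info$force_weight %||% fitcfg$force_weight
    if (use_energy && wE > 0 && !is.null(cfg$energy)) {
      total <- total + wE^2 * (potential_energy(model, cfg) - cfg$energy)^2
    }
    if (wF > 0 && !is.null(cfg$forces)) {
      total <- total +
        wF^2 * sum((potential_forces(model, cfg) - cfg$forces)^2)
    }
  }
  total
}

## ---------------------------------------------------------------------------
## solvers

## Paige-Saunders LSQR for min ||A x - b||^2 + lambda^2 ||G x||^2 with
## diagonal G, via the augmented operator [A; lambda G]. Deterministic,
## fixed tolerances.
.lsqr <- function(A, b, lambda = 0, G = NULL, atol = 1e-14, btol = 1e-14,
                  itnlim = NULL) {
  n <- ncol(A)
  if (is.null(G)) G <- rep(1, n)
  if (is.null(itnlim)) itnlim <- max(10L * n, 200L)
  damp <- lambda * G
  matvec <- function(x) c(A %*% x, damp * x)
  rmatvec <- function(u) as.vector(crossprod(A, u[seq_len(nrow(A))])) +
    damp * u[nrow(A) + seq_len(n)]
  bb <- c(b, numeric(n))
  x <- numeric(n)
  u <- bb; beta <- sqrt(sum(u^2))
  if (beta == 0) return(list(x = x, converged = TRUE, itn = 0L))
  u <- u / beta
  v <- rmatvec(u); alpha <- sqrt(sum(v^2))
  if (alpha == 0) return(list(x = x, converged = TRUE, itn = 0L))
  v <- v / alpha
  w <- v
  phibar <- beta; rhobar <- alpha
  normb <- beta
  normAtr <- alpha * beta
  converged <- FALSE
  itn <- 0L
  while (itn < itnlim) {
    itn <- itn + 1L
    u <- matvec(v) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) u <- u / beta
    v <- rmatvec(u) - beta * v
    alpha <- sqrt(sum(v^2))
    if (alpha > 0) v <- v / alpha
    rho <- sqrt(rhobar^2 + beta^2)
    cs <- rhobar / rho; sn <- beta / rho
    theta <- sn * alpha
    rhobar <- -cs * alpha
    phi <- cs * phibar
    phibar <- sn * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    normAtr <- phibar * alpha * abs(cs)
    if (phibar <= btol * normb || normAtr <= atol * max(normb, 1)) {
      converged <- TRUE
      break
    }
    if (alpha == 0 || beta == 0) { converged <- TRUE; break }
  }
  list(x = x, converged = converged, itn = itn)
}

#' Solve the fit problem by Tychonov-regularized LSQR
#'
#' Minimizes `||Psi c - t||^2 + lambda^2 ||Gamma c||^2` with the iterative
#' LSQR solver on the augmented system. Deterministic (fixed iteration cap
#' and tolerances).
#'
#' @param problem a `"fit_problem"` from [assemble_design_matrix()].
#' @param lambda Tychonov strength (>= 0); defaults to the problem's
#'   fit configuration.
#' @return list with `coefficients` (packed vector), `effective_rank`
#'   (= number of columns for this solver), `converged`, `iterations`.
#' @export
solve_tychonov_lsqr <- function(problem, lambda = NULL) {
  lambda <- lambda %||% problem$fitcfg$lambda
  if (lambda < 0) stop("lambda must be >= 0")
  sol <- .lsqr(problem$design, problem$targets, lambda, problem$gamma)
  if (!sol$converged) {
    warning("LSQR did not converge within the iteration cap; ",
            "returning the best iterate")
  }
  list(coefficients = sol$x, effective_rank = ncol(problem$design),
       converged = sol$converged, iterations = sol$itn)
}

#' Solve the fit problem by rank-revealing QR
#'
#' Solves the preconditioned system `Psi Gamma^-1` by pivoted (rank-revealing)
#' QR, truncating diagonal values below the tolerance, and maps the solution
#' back through `Gamma^-1`. No Tychonov term.
#'
#' @param problem a `"fit_problem"`.
#' @param tol_lambda truncation tolerance (>= 0); defaults to the problem's
#'   fit configuration.
#' @return list with `coefficients`, `effective_rank`, `converged = TRUE`.
#' @export
solve_rrqr <- function(problem, tol_lambda = NULL) {
  tol_lambda <- tol_lambda %||% problem$fitcfg$lambda
  if (tol_lambda < 0) stop("tolerance must be >= 0")
  A <- problem$design
  G <- problem$gamma
  As <- sweep(A, 2, G, "/")
  qrp <- qr(As, LAPACK = TRUE)
  R <- qr.R(qrp)
  dvals <- abs(diag(R))
  rank <- sum(dvals > max(tol_lambda, 0) & dvals > 0)
  n <- ncol(A)
  d <- numeric(n)
  if (rank > 0) {
    qtb <- qr.qty(qrp, problem$targets)[seq_len(rank)]
    y <- backsolve(R[seq_len(rank), seq_len(rank), drop = FALSE], qtb)
    d[qrp$pivot[seq_len(rank)]] <- y
  }
  list(coefficients = d / G, effective_rank = rank, converged = TRUE)
}

## ---------------------------------------------------------------------------
## top-level fit

#' Fit a linear ACE force field
#'
#' The main model-fitting entry point: builds the least-squares system from
#' labeled configurations (energies and/or forces), applies the smoothness
#' prior, solves with the configured solver, sets the one-body term, and
#' returns a fitted `"linear_ace"` model with training diagnostics.
#'
#' @param dataset list of labeled [atomic_configuration()]s (e.g. from
#'   [sample_configurations()] or [read_extxyz()]).
#' @param basis an [ace_basis()].
#' @param one_body one of `"isolated_atom"` (requires `e0`),
#'   `"training_average"`, `"forces_only_shift"`.
#' @param e0 named vector of isolated-atom energies (eV), for
#'   `one_body = "isolated_atom"`.
#' @param pair_degree polynomial degree of the auxiliary pair basis.
#' @param fitcfg a [fit_config()] (weights, smoothness order, lambda,
#'   solver).
#' @return a fitted `"linear_ace"` model; see [predict.linear_ace()],
#'   [summary.linear_ace()], [error_metrics()].
#' @examples
#' \donttest{
#' mols <- make_toy_molecules()
#' ref <- make_reference_potential(mols$triatomic, seed = 7)
#' data <- sample_configurations(mols$triatomic, ref, n = 80, scale = 0.04,
#'                               seed = 11)
#' rs <- radial_spec(r_in = 0.7, r_out = 4.0, n_max = 4)
#' bs <- ace_basis(basis_selection(c("O", "H"), nu_max = 2,
#'                                 degree_caps = c(6, 5)), rs)
#' fit <- ace_fit(data, bs, one_body = "training_average")
#' print(fit)
#' }
#' @export
ace_fit <- function(dataset, basis,
                    one_body = c("training_average", "isolated_atom",
                                 "forces_only_shift"),
                    e0 = NULL, pair_degree = 6L,
                    fitcfg = fit_config()) {
  one_body <- match.arg(one_body)
  model <- linear_ace_model(basis, pair_degree = pair_degree,
                            one_body_strategy = one_body)
  if (one_body == "isolated_atom") {
    model <- set_one_body_term(model, "isolated_atom", values = e0)
  }
  problem <- assemble_design_matrix(model, dataset, fitcfg)
  model <- problem$model  # one_body may have been populated (training_average)
  solver <- fitcfg$solver
  if (solver == "auto") {
    solver <- if (nrow(problem$design) >= 1.2 * ncol(problem$design)) {
      "rrqr"
    } else {
      "lsqr_tychonov"
    }
  }
  sol <- if (solver == "rrqr") solve_rrqr(problem) else
    solve_tychonov_lsqr(problem)
  model <- .coef_unpack(model, sol$coefficients)
  if (one_body == "forces_only_shift") {
    model <- set_one_body_term(model, "forces_only_shift", dataset = dataset)
  }
  model$fit_config <- fitcfg
  res <- problem$targets - as.vector(problem$design %*% sol$coefficients)
  met <- error_metrics(model, dataset, units = "eV")
  model$diagnostics <- list(
    solver = solver, lambda = fitcfg$lambda,
    effective_rank = sol$effective_rank,
    residual_norm = sqrt(sum(res^2)),
    n_rows = nrow(problem$design), n_cols = ncol(problem$design),
    energy_rmse = met$energy_rmse, energy_mae = met$energy_mae,
    force_rmse = met$force_rmse, force_mae = met$force_mae,
    converged = sol$converged, seed = fitcfg$seed,
    train_energy = vapply(dataset, function(cfg) cfg$energy %||% NA_real_,
                          numeric(1)),
    train_energy_pred = vapply(dataset,
                               function(cfg) potential_energy(model, cfg),
                               numeric(1)),
    train_n_atoms = vapply(dataset, n_atoms, integer(1)))
  model
}

#' @export
coef.linear_ace <- function(object, ...) {
  list(basis = object$coefficients, pair = object$pair_coefficients,
       one_body = object$one_body)
}

#' Predict energies and forces for new configurations
#'
#' @param object a fitted `"linear_ace"` model.
#' @param newdata an [atomic_configuration()] or a list of them.
#' @param type `"energy"`, `"forces"` or `"both"`.
#' @param ... unused.
#' @return for a single configuration, the energy (eV), force matrix, or a
#'   list of both; for a list input, a list of such results.
#' @export
predict.linear_ace <- function(object, newdata,
                               type = c("energy", "forces", "both"), ...) {
  type <- match.arg(type)
  one <- function(cfg) {
    switch(type,
           energy = potential_energy(object, cfg),
           forces = potential_forces(object, cfg),
           both = potential_energy_forces(object, cfg))
  }
  if (inherits(newdata, "atomic_config")) return(one(newdata))
  lapply(newdata, one)
}

#' @export
fitted.linear_ace <- function(object, ...) {
  object$diagnostics$train_energy_pred
}

#' @export
residuals.linear_ace <- function(object, ...) {
  d <- object$diagnostics
  d$train_energy - d$train_energy_pred
}

#' @export
summary.linear_ace <- function(object, ...) {
  d <- object$diagnostics
  out <- list(
    n_basis = object$basis$n_fun,
    n_coefficients = .n_coef(object),
    elements = object$basis$elements,
    one_body = object$one_body,
    one_body_strategy = object$one_body_strategy,
    diagnostics = d)
  class(out) <- "summary.linear_ace"
  out
}

#' @export
print.summary.linear_ace <- function(x, ...) {
  cat("Linear ACE force field\n")
  cat(sprintf("  %d invariant basis functions, %d linear coefficients\n",
              x$n_basis, x$n_coefficients))
  cat(sprintf("  one-body (%s): %s\n", x$one_body_strategy,
              paste(sprintf("%s = %.4f eV", names(x$one_body), x$one_body),
                    collapse = ", ")))
  d <- x$diagnostics
  if (!is.null(d)) {
    cat(sprintf("  solver %s (lambda = %g), effective rank %d of %d columns\n",
                d$solver, d$lambda, d$effective_rank, d$n_cols))
    cat(sprintf("  train energy RMSE %.4f meV/atom, MAE %.4f meV/atom\n",
                d$energy_rmse * 1000, d$energy_mae * 1000))
    cat(sprintf("  train force  RMSE %.4f meV/A,   MAE %.4f meV/A\n",
                d$force_rmse * 1000, d$force_mae * 1000))
  }
  invisible(x)
}

#' Parity plot of training energies
#'
#' @param x a fitted `"linear_ace"` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.linear_ace <- function(x, ...) {
  d <- x$diagnostics
  if (is.null(d) || all(is.na(d$train_energy))) {
    stop("no stored training energies to plot")
  }
  e <- d$train_energy / d$train_n_atoms
  p <- d$train_energy_pred / d$train_n_atoms
  graphics::plot(e, p, xlab = "reference energy (eV/atom)",
                 ylab = "model energy (eV/atom)",
                 main = "Training-set energy parity", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
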