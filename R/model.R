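## The linear ACE energy model. A site energy is
##   E_i = E0(z_i) + c[, z_i] . B(env_i) + c_pair . g(env_i)
## where B are the invariant basis functions, and g is the small auxiliary
## two-body basis (same transform and polynomials, one-sided pair envelope)
## that carries short-range repulsion. The total energy is the sum of site
## energies; forces are the exact negative gradient, assembled from analytic
## basis gradients including cross-site contributions.

#' Calculator interface: potential energy
#'
#' Generic energy evaluator implemented by fitted ACE models
#' ([ace_fit()], [linear_ace_model()]) and by the analytic reference
#' potentials of the synthetic-data module.
#'
#' @param object a calculator (e.g. `"linear_ace"` or `"ace_reference"`).
#' @param config an [atomic_configuration()].
#' @param ... passed on to methods.
#' @return total potential energy in eV.
#' @export
potential_energy <- function(object, config, ...) UseMethod("potential_energy")

#' Calculator interface: forces
#'
#' @inheritParams potential_energy
#' @return `N x 3` matrix of forces (eV/Angstrom).
#' @export
potential_forces <- function(object, config, ...) UseMethod("potential_forces")

#' Calculator interface: energy and forces in one pass
#'
#' @inheritParams potential_energy
#' @return list with `energy` (eV) and `forces` (`N x 3`, eV/Angstrom).
#' @export
potential_energy_forces <- function(object, config, ...) {
  UseMethod("potential_energy_forces")
}

#' @export
potential_energy_forces.default <- function(object, config, ...) {
  list(energy = potential_energy(object, config, ...),
       forces = potential_forces(object, config, ...))
}

## ---------------------------------------------------------------------------

## unordered element-pair channel index matrix (k x k, symmetric)
.pair_index_matrix <- function(k) {
  P <- matrix(0L, k, k)
  idx <- 0L
  for (i in seq_len(k)) {
    for (j in i:k) {
      idx <- idx + 1L
      P[i, j] <- idx
      P[j, i] <- idx
    }
  }
  P
}

#' Construct a linear ACE model
#'
#' Assembles a model object from a basis and coefficient values. Mostly used
#' internally by [ace_fit()] and by the synthetic-data generator (planted
#' models); coefficients default to zero.
#'
#' @param basis an [ace_basis()].
#' @param coefficients `n_fun x n_elements` matrix of linear coefficients
#'   (one column per center element).
#' @param pair_coefficients `pair_degree x n_pairs` matrix for the auxiliary
#'   two-body basis (`n_pairs = k(k+1)/2` unordered element pairs).
#' @param one_body named numeric vector of per-element one-body energies (eV).
#' @param one_body_strategy one of `"isolated_atom"`, `"training_average"`,
#'   `"forces_only_shift"`.
#' @param pair_degree polynomial degree of the auxiliary pair basis.
#' @return object of class `"linear_ace"`.
#' @export
linear_ace_model <- function(basis, coefficients = NULL,
                             pair_coefficients = NULL,
                             one_body = NULL,
                             one_body_strategy = "isolated_atom",
                             pair_degree = 6L) {
  stopifnot(inherits(basis, "ace_basis"))
  k <- length(basis$elements)
  np <- k * (k + 1L) / 2L
  pair_degree <- as.integer(pair_degree)
  if (pair_degree > basis$polys$degree_max) {
    stop("pair_degree exceeds the degree of the built polynomial set")
  }
  if (is.null(coefficients)) coefficients <- matrix(0, basis$n_fun, k)
  coefficients <- as.matrix(coefficients)
  if (!all(dim(coefficients) == c(basis$n_fun, k))) {
    stop("coefficient matrix must be n_fun x n_elements")
  }
  if (is.null(pair_coefficients)) pair_coefficients <- matrix(0, pair_degree, np)
  pair_coefficients <- as.matrix(pair_coefficients)
  if (!all(dim(pair_coefficients) == c(pair_degree, np))) {
    stop("pair coefficient matrix must be pair_degree x n_pairs")
  }
  if (is.null(one_body)) {
    one_body <- stats::setNames(numeric(k), basis$elements)
  }
  if (!all(basis$elements %in% names(one_body))) {
    stop("one_body must be defined for every declared element")
  }
  one_body <- one_body[basis$elements]
  one_body_strategy <- match.arg(one_body_strategy,
                                 c("isolated_atom", "training_average",
                                   "forces_only_shift"))
  structure(list(basis = basis, coefficients = coefficients,
                 pair_coefficients = pair_coefficients,
                 pair_degree = pair_degree,
                 pair_index = .pair_index_matrix(k),
                 one_body = one_body,
                 one_body_strategy = one_body_strategy,
                 diagnostics = NULL, fit_config = NULL),
            class = "linear_ace")
}

## number of linear coefficients (excluding one-body terms)
.n_coef <- function(model) {
  length(model$coefficients) + length(model$pair_coefficients)
}

## pack/unpack the full linear coefficient vector
## layout: [n_fun x n_elem column-major] then [pair_degree x n_pairs]
.coef_pack <- function(model) {
  c(as.vector(model$coefficients), as.vector(model$pair_coefficients))
}

.coef_unpack <- function(model, v) {
  nb <- length(model$coefficients)
  model$coefficients <- matrix(v[seq_len(nb)], nrow(model$coefficients),
                               ncol(model$coefficients))
  model$pair_coefficients <- matrix(v[-seq_len(nb)],
                                    nrow(model$pair_coefficients),
                                    ncol(model$pair_coefficients))
  model
}

## Per-environment features and gradients for both blocks.
## Returns f (length n_col), and (optionally) df: array (m, 3, n_col) of
## gradients wrt neighbor positions (center gradient = -colSums).
.env_features <- function(env, model, grad = FALSE) {
  basis <- model$basis
  k <- length(basis$elements)
  nb <- basis$n_fun
  ncolb <- nb * k
  npair <- ncol(model$pair_coefficients)
  nd <- model$pair_degree
  ncols <- ncolb + nd * npair
  izc <- match(env$center_element, basis$elements)
  if (is.na(izc)) {
    stop("center element not declared in the model: ", env$center_element)
  }
  m <- length(env$neighbor_elements)
  f <- numeric(ncols)
  bcols <- (izc - 1L) * nb + seq_len(nb)
  if (!grad) {
    B <- evaluate_basis(env, basis)
    f[bcols] <- B
  } else {
    bg <- evaluate_basis_gradients(env, basis)
    f[bcols] <- bg$B
    df <- array(0, c(m, 3, ncols))
    if (m > 0) {
      for (d in 1:3) df[, d, bcols] <- t(bg$dB[, , d])
    }
  }
  if (m > 0) {
    izn <- match(env$neighbor_elements, basis$elements)
    r <- sqrt(rowSums(env$displacements^2))
    pr <- .evaluate_pair_radial(r, basis$radial, basis$polys, nd)
    pidx <- model$pair_index[cbind(rep(izc, m), izn)]
    u <- env$displacements / r
    for (j in seq_len(m)) {
      cols <- ncolb + (pidx[j] - 1L) * nd + seq_len(nd)
      f[cols] <- f[cols] + pr$R[j, ]
      if (grad) {
        for (d in 1:3) {
          df[j, d, cols] <- df[j, d, cols] + pr$dR[j, ] * u[j, d]
        }
      }
    }
  }
  if (grad) list(f = f, df = if (m > 0) df else array(0, c(0, 3, ncols)))
  else list(f = f)
}

## Whole-configuration features: f (n_col) and G (3N x n_col) with
## G[(a-1)*3 + d, c] = d f_c / d position[a, d]. Energy = sum(one_body) + f.c;
## forces = -matrix(G %*% coef).
.config_features <- function(config, model, grad = FALSE) {
  envs <- configuration_environments(config, model$basis$radial$r_out)
  n <- n_atoms(config)
  ncols <- .n_coef(model)
  f <- numeric(ncols)
  G <- if (grad) matrix(0, 3L * n, ncols) else NULL
  for (i in seq_len(n)) {
    ef <- .env_features(envs[[i]], model, grad = grad)
    f <- f + ef$f
    if (grad) {
      m <- length(envs[[i]]$neighbor_elements)
      if (m > 0) {
        ctr_rows <- (i - 1L) * 3L + 1:3
        for (d in 1:3) {
          dfd <- ef$df[, d, , drop = FALSE]
          dim(dfd) <- c(m, ncols)
          nbr <- envs[[i]]$neighbor_index
          rows <- (nbr - 1L) * 3L + d
          ## accumulate: same neighbor can appear once only per env
          G[rows, ] <- G[rows, , drop = FALSE] + dfd
          G[ctr_rows[d], ] <- G[ctr_rows[d], ] - colSums(dfd)
        }
      }
    }
  }
  list(f = f, G = G)
}

#' Site energy
#'
#' Energy contribution of one atomic environment:
#' `E_i = E0(z_i) + c . B(env) + c_pair . g(env)`.
#'
#' @param model a `"linear_ace"` model.
#' @param env an [atomic_environment()].
#' @return site energy in eV.
#' @export
site_energy <- function(model, env) {
  ef <- .env_features(env, model, grad = FALSE)
  unname(model$one_body[env$center_element] + sum(ef$f * .coef_pack(model)))
}

#' Total energy of a configuration
#'
#' Sum of site energies over all atoms, with environments built at the outer
#' cutoff.
#'
#' @param model a `"linear_ace"` model.
#' @param config an [atomic_configuration()].
#' @return total energy in eV.
#' @export
total_energy <- function(model, config) {
  potential_energy(model, config)
}

#' @export
potential_energy.linear_ace <- function(object, config, ...) {
  cf <- .config_features(config, object, grad = FALSE)
  sum(object$one_body[config$elements]) + sum(cf$f * .coef_pack(object))
}

#' Forces of a linear ACE model
#'
#' Exact negative gradient of the total energy, including cross-site
#' contributions (every atom appears in its neighbors' environments).
#'
#' @inheritParams total_energy
#' @return `N x 3` force matrix (eV/Angstrom).
#' @export
forces <- function(model, config) potential_forces(model, config)

#' @export
potential_forces.linear_ace <- function(object, config, ...) {
  potential_energy_forces(object, config)$forces
}

#' @export
potential_energy_forces.linear_ace <- function(object, config, ...) {
  cf <- .config_features(config, object, grad = TRUE)
  cv <- .coef_pack(object)
  e <- sum(object$one_body[config$elements]) + sum(cf$f * cv)
  g <- as.vector(cf$G %*% cv)
  list(energy = e, forces = matrix(-g, n_atoms(config), 3, byrow = TRUE))
}

#' Set the one-body term of a model
#'
#' The three strategies for the element-wise constant energies: supplied
#' isolated-atom energies (correct dissociation limit), the training-set
#' average energy per atom (zero-mean fitted model), or — for force-only
#' fits — a single constant per atom chosen after the coefficient fit to
#' zero the mean signed per-atom training energy residual.
#'
#' @param model a `"linear_ace"` model.
#' @param strategy `"isolated_atom"`, `"training_average"` or
#'   `"forces_only_shift"`.
#' @param values named vector of isolated-atom energies (eV), required for
#'   `"isolated_atom"`.
#' @param dataset list of labeled [atomic_configuration()]s, required for the
#'   other two strategies.
#' @return the model with `one_body` populated.
#' @export
set_one_body_term <- function(model, strategy, values = NULL, dataset = NULL) {
  strategy <- match.arg(strategy, c("isolated_atom", "training_average",
                                    "forces_only_shift"))
  els <- model$basis$elements
  if (strategy == "isolated_atom") {
    if (is.null(values) || !all(els %in% names(values))) {
      stop("isolated_atom strategy requires energies for every element")
    }
    model$one_body <- values[els]
  } else {
    if (is.null(dataset) || length(dataset) == 0) {
      stop(strategy, " strategy requires a labeled dataset")
    }
    en <- vapply(dataset, function(cfg) {
      if (is.null(cfg$energy)) stop("dataset contains unlabeled energies")
      cfg$energy
    }, numeric(1))
    nat <- vapply(dataset, n_atoms, integer(1))
    if (strategy == "training_average") {
      ebar <- mean(en / nat)
      model$one_body <- stats::setNames(rep(ebar, length(els)), els)
    } else {
      ## forces_only_shift: per-atom constant = mean signed per-atom residual
      ## of the already-fitted coefficients (one-body set to zero first)
      model$one_body <- stats::setNames(rep(0, length(els)), els)
      pred <- vapply(dataset, function(cfg) potential_energy(model, cfg),
                     numeric(1))
      delta <- mean((en - pred) / nat)
      model$one_body <- stats::setNames(rep(delta, length(els)), els)
    }
  }
  model$one_body_strategy <- strategy
  model
}

#' @export
print.linear_ace <- function(x, ...) {
  cat("Linear ACE force field\n")
  cat(sprintf("  elements {%s}; %d invariant basis functions x %d elements",
              paste(x$basis$elements, collapse = ","), x$basis$n_fun,
              length(x$basis$elements)))
  cat(sprintf(" + %d pair coefficients\n", length(x$pair_coefficients)))
  cat(sprintf("  r_out = %.2f A, nu_max = %d, one-body: %s\n",
              x$basis$radial$r_out, x$basis$selection$nu_max,
              x$one_body_strategy))
  if (!is.null(x$diagnostics)) {
    d <- x$diagnostics
    cat(sprintf(
      "  train: energy RMSE %.3f meV/atom, force RMSE %.3f meV/A (rank %d)\n",
      d$energy_rmse * 1000, d$force_rmse * 1000, d$effective_rank))
  }
  invisible(x)
}
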