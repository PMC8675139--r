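## Shared fixtures, memoized so expensive basis builds run once per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!is.null(.fixtures[[name]])) return(.fixtures[[name]])
  val <- switch(
    name,
    mols = make_toy_molecules(),
    rs_small = radial_spec(r_in = 0.7, r_out = 4.0, n_max = 3),
    ## two-correlation C/H basis used by density-trick and power-spectrum
    ## checks
    basis_ch2 = ace_basis(
      basis_selection(c("C", "H"), nu_max = 2, degree_caps = c(8, 8)),
      fixture("rs_small")),
    ## three-correlation C/H/O basis for model-level tests
    basis_cho3 = ace_basis(
      basis_selection(c("C", "H", "O"), nu_max = 3, degree_caps = c(6, 5, 4)),
      fixture("rs_small")),
    ## O/H basis for fits of the bent triatomic
    basis_oh = ace_basis(
      basis_selection(c("O", "H"), nu_max = 3, degree_caps = c(6, 5, 4)),
      radial_spec(r_in = 0.7, r_out = 3.5, n_max = 3)),
    ## planted C/H/O model on the small basis (with pair block)
    planted_cho = make_reference_potential(
      fixture("mols")$chain, kind = "planted_ace",
      params = list(basis = fixture("basis_cho3"), coef_scale = 0.05,
                    e0 = c(C = -5, H = -2, O = -7)),
      seed = 8),
    ## single-element carbon-ring recovery problem: distribution-matched
    ## pruning environments, planted model, labeled data
    ring_setup = local({
      mols <- fixture("mols")
      ring <- atomic_configuration(rep("C", 6),
                                   mols$ring6$positions[1:6, ])
      rs <- radial_spec(r_in = 0.7, r_out = 4.0, n_max = 3)
      sel <- basis_selection("C", nu_max = 3, degree_caps = c(8, 6, 5))
      envs <- withr::with_seed(42, {
        out <- list()
        for (i in 1:120) {
          pos <- ring$positions + matrix(rnorm(18, sd = 0.06), 6, 3)
          out <- c(out, configuration_environments(
            atomic_configuration(rep("C", 6), pos), rs$r_out))
        }
        out
      })
      basis <- ace_basis(sel, rs, sample_envs = envs)
      planted <- make_reference_potential(
        ring, kind = "planted_ace",
        params = list(basis = basis, pair_degree = 0L), seed = 5)
      list(ring = ring, rs = rs, basis = basis, planted = planted)
    }),
    stop("unknown fixture: ", name))
  .fixtures[[name]] <- val
  val
}

## random environment drawing from the full radial support
rand_env <- function(elements, rs, n_min = 2L, n_max_neigh = 8L) {
  m <- sample(n_min:n_max_neigh, 1)
  els <- sample(elements, m, replace = TRUE)
  r <- runif(m, rs$r_in + 0.05 * (rs$r_out - rs$r_in), rs$r_out * 0.97)
  u <- matrix(rnorm(3 * m), m, 3)
  u <- u / sqrt(rowSums(u^2))
  atomic_environment(sample(elements, 1), els, u * r)
}

## random well-separated molecular configuration (for force checks)
rand_config <- function(n, elements = c("C", "H", "O"), box = 4.5,
                        min_dist = 1.0) {
  repeat {
    pos <- matrix(runif(3 * n, 0, box), n, 3)
    if (n == 1 || min(dist(pos)) >= min_dist) break
  }
  atomic_configuration(sample(elements, n, replace = TRUE), pos)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}

## bounded test calculator with explicit dihedral dependence: a Morse/angle
## reference plus a single cosine torsion term (phase-shifted so the torsional
## minimum is away from +/-180 degrees)
torsion_model <- function(base, dihedral, k = 0.3, phase = 0.7) {
  structure(list(base = base, dih = dihedral, k = k, phase = phase),
            class = "torsion_model")
}

potential_energy.torsion_model <- function(object, config, ...) {
  d <- object$dih
  p <- config$positions
  phi <- acemol:::.dihedral_angle(p[d[1], ], p[d[2], ], p[d[3], ], p[d[4], ])
  potential_energy(object$base, config) +
    object$k * (1 + cos(phi + object$phase))
}

potential_forces.torsion_model <- function(object, config, ...) {
  d <- object$dih
  p <- config$positions
  dh <- acemol:::.dihedral_angle(p[d[1], ], p[d[2], ], p[d[3], ], p[d[4], ],
                                 grad = TRUE)
  f <- potential_forces(object$base, config)
  f[d, ] <- f[d, ] + object$k * sin(dh$phi + object$phase) * dh$grad
  f
}

registerS3method("potential_energy", "torsion_model",
                 potential_energy.torsion_model,
                 envir = asNamespace("acemol"))
registerS3method("potential_forces", "torsion_model",
                 potential_forces.torsion_model,
                 envir = asNamespace("acemol"))
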