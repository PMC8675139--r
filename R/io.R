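## File formats: multi-frame extended XYZ (positions in Angstrom, total
## energy in eV on the comment line, per-atom forces in eV/Angstrom), and a
## JSON model archive with full provenance and a checksum over the
## coefficient block. All numeric output at 17 significant digits, which
## round-trips IEEE doubles exactly.

## tokenize an extxyz comment line into a named list of key=value pairs,
## honoring double quotes
.parse_kv <- function(line) {
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_:-]*)=("([^"]*)"|[^ ]+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  starts <- as.vector(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    tok <- substr(line, starts[i], starts[i] + lens[i] - 1)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    if (startsWith(val, '"')) val <- substr(val, 2, nchar(val) - 1)
    out[[key]] <- val
  }
  out
}

#' Read a multi-frame extended-XYZ file
#'
#' Parses extended XYZ: per frame, an atom count, a comment line with
#' `key=value` pairs (a `Properties=...` column descriptor, and optionally a
#' total energy under `energy=`), and one line per atom. Recognized columns:
#' `species` (S:1), `pos` (R:3) and `forces`/`force` (R:3); other declared
#' columns are skipped. Malformed frames raise an error naming the frame and
#' line.
#'
#' @param path input file.
#' @return list of [atomic_configuration()]s.
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  ## drop trailing blank lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  configs <- list()
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1) {
      stop(sprintf("frame %d (line %d): invalid atom count '%s'",
                   frame, pos, lines[pos]))
    }
    if (pos + 1L + nat > length(lines) + 0L && pos + nat > length(lines)) {
      stop(sprintf("frame %d (line %d): file truncated (%d atom lines needed)",
                   frame, pos, nat))
    }
    kv <- .parse_kv(lines[pos + 1L])
    props <- kv[["Properties"]] %||% kv[["properties"]] %||%
      "species:S:1:pos:R:3"
    pf <- strsplit(props, ":", fixed = TRUE)[[1]]
    if (length(pf) %% 3 != 0) {
      stop(sprintf("frame %d (line %d): malformed Properties '%s'",
                   frame, pos + 1L, props))
    }
    pnames <- pf[seq(1, length(pf), 3)]
    pwidth <- as.integer(pf[seq(3, length(pf), 3)])
    col <- 1L
    colmap <- list()
    for (i in seq_along(pnames)) {
      colmap[[pnames[i]]] <- col:(col + pwidth[i] - 1L)
      col <- col + pwidth[i]
    }
    ncol_expected <- col - 1L
    if (is.null(colmap[["species"]]) || is.null(colmap[["pos"]])) {
      stop(sprintf("frame %d: Properties must declare species and pos", frame))
    }
    body <- lines[pos + 1L + seq_len(nat)]
    if (anyNA(body)) {
      stop(sprintf("frame %d (line %d): atom count disagrees with the body",
                   frame, pos))
    }
    toks <- strsplit(trimws(body), "[ \t]+")
    nt <- lengths(toks)
    if (any(nt < ncol_expected)) {
      bad <- which(nt < ncol_expected)[1]
      stop(sprintf("frame %d (line %d): expected %d columns, found %d",
                   frame, pos + 1L + bad, ncol_expected, nt[bad]))
    }
    tm <- do.call(rbind, toks)
    elements <- tm[, colmap[["species"]][1]]
    posm <- matrix(as.numeric(tm[, colmap[["pos"]]]), nat, 3)
    if (anyNA(posm)) {
      stop(sprintf("frame %d: non-numeric position entries", frame))
    }
    fcols <- colmap[["forces"]] %||% colmap[["force"]]
    forcem <- NULL
    if (!is.null(fcols)) {
      forcem <- matrix(as.numeric(tm[, fcols]), nat, 3)
      if (anyNA(forcem)) {
        stop(sprintf("frame %d: non-numeric force entries", frame))
      }
    }
    ekey <- kv[["energy"]] %||% kv[["Energy"]]
    energy <- if (!is.null(ekey)) as.numeric(ekey) else NULL
    configs[[frame]] <- atomic_configuration(elements, posm,
                                             energy = energy,
                                             forces = forcem)
    pos <- pos + 2L + nat
  }
  configs
}

#' Write configurations as extended XYZ
#'
#' Standard-conformant multi-frame extended XYZ, numeric fields at 17
#' significant digits (lossless for doubles). Energy labels go on the
#' comment line (`energy=`); force labels become per-atom columns.
#'
#' @param configs a list of [atomic_configuration()]s (or a single one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(configs, path) {
  if (inherits(configs, "atomic_config")) configs <- list(configs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in configs) {
    n <- n_atoms(cfg)
    has_f <- !is.null(cfg$forces)
    props <- paste0("species:S:1:pos:R:3", if (has_f) ":forces:R:3")
    comment <- paste0("Properties=", props,
                      if (!is.null(cfg$energy)) {
                        sprintf(" energy=%.17g", cfg$energy)
                      })
    writeLines(c(as.character(n), comment), con)
    for (i in seq_len(n)) {
      fields <- c(cfg$elements[i], sprintf("%.17g", cfg$positions[i, ]),
                  if (has_f) sprintf("%.17g", cfg$forces[i, ]))
      writeLines(paste(fields, collapse = " "), con)
    }
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## model archive

.ARCHIVE_VERSION <- 1L

.coef_checksum <- function(payload) {
  js <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Save a linear ACE model
#'
#' Writes a structured JSON archive: format version, radial spec (including
#' the precomputed standardization constants and recursion coefficients),
#' basis selection with full provenance (pruning seed and tolerance),
#' coupling coefficients, coefficient vectors at 17 significant digits, the
#' one-body map, fit diagnostics, and an md5 checksum over the coefficient
#' block. The round trip is lossless: a loaded model predicts bit-identical
#' energies.
#'
#' @param model a `"linear_ace"` model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "linear_ace"))
  basis <- model$basis
  funs <- lapply(basis$functions, function(f) {
    list(nu = f$nu,
         skeleton = unname(f$skeleton[, c("iz", "n", "l"), drop = FALSE]),
         coupling = unname(f$coupling))
  })
  coefs <- list(coefficients = unname(model$coefficients),
                pair_coefficients = unname(model$pair_coefficients),
                one_body = as.numeric(model$one_body))
  archive <- list(
    format_version = .ARCHIVE_VERSION,
    radial = unclass(basis$radial),
    polys = unclass(basis$polys),
    selection = unclass(basis$selection),
    l_max = basis$l_max,
    provenance = basis$provenance,
    functions = funs,
    pair_degree = model$pair_degree,
    one_body_elements = names(model$one_body),
    one_body_strategy = model$one_body_strategy,
    coefficient_block = coefs,
    checksum = .coef_checksum(coefs),
    diagnostics = model$diagnostics[c("solver", "lambda", "effective_rank",
                                      "residual_norm", "n_rows", "n_cols",
                                      "energy_rmse", "force_rmse", "seed")])
  jsonlite::write_json(archive, path, digits = I(17), auto_unbox = TRUE,
                       pretty = FALSE, null = "null")
  invisible(path)
}

#' Load a linear ACE model
#'
#' Reads a [save_model()] archive, verifying the format version and the
#' coefficient checksum, and reconstructs the model (including the basis
#' evaluation tables) without re-running any numerical construction, so the
#' loaded model is bit-identical to the saved one.
#'
#' @param path archive file.
#' @return a `"linear_ace"` model.
#' @export
load_model <- function(path) {
  arc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(arc$format_version) ||
      arc$format_version != .ARCHIVE_VERSION) {
    stop("unknown model archive format_version: ",
         arc$format_version %||% "<missing>")
  }
  coefs <- list(
    coefficients = matrix(arc$coefficient_block$coefficients,
                          nrow = NROW(arc$coefficient_block$coefficients)),
    pair_coefficients = matrix(arc$coefficient_block$pair_coefficients,
                               nrow = NROW(arc$coefficient_block$pair_coefficients)),
    one_body = arc$coefficient_block$one_body)
  check_payload <- list(coefficients = unname(coefs$coefficients),
                        pair_coefficients = unname(coefs$pair_coefficients),
                        one_body = as.numeric(coefs$one_body))
  if (!identical(unname(.coef_checksum(check_payload)),
                 unname(arc$checksum))) {
    stop("model archive checksum failure: coefficient block corrupted")
  }
  spec <- structure(arc$radial, class = "radial_spec")
  spec$n_max <- as.integer(spec$n_max)
  spec$quadrature_points <- as.integer(spec$quadrature_points)
  polys <- structure(arc$polys, class = "ortho_polys")
  selection <- structure(arc$selection, class = "basis_selection")
  selection$nu_max <- as.integer(selection$nu_max)
  funs_raw <- arc$functions
  getfun <- function(i) {
    if (is.data.frame(funs_raw)) {
      list(nu = funs_raw$nu[i], skeleton = funs_raw$skeleton[[i]],
           coupling = funs_raw$coupling[[i]])
    } else {
      funs_raw[[i]]
    }
  }
  nfun <- if (is.data.frame(funs_raw)) nrow(funs_raw) else length(funs_raw)
  funs <- vector("list", nfun)
  for (i in seq_len(nfun)) {
    fr <- getfun(i)
    skel <- matrix(as.numeric(unlist(fr$skeleton)), ncol = 3)
    colnames(skel) <- c("iz", "n", "l")
    cp <- matrix(as.numeric(unlist(fr$coupling)), ncol = fr$nu + 1L)
    colnames(cp) <- c(paste0("m_", seq_len(fr$nu)), "coeff")
    funs[[i]] <- list(nu = as.integer(fr$nu), skeleton = skel, coupling = cp)
  }
  l_max <- as.integer(arc$l_max)
  flat <- .flatten_functions(funs, spec$n_max, l_max, selection$nu_max)
  basis <- structure(list(
    selection = selection, radial = spec, polys = polys,
    elements = selection$elements, l_max = l_max,
    functions = funs, flat = flat, n_fun = nfun,
    n_v = .n_v(length(selection$elements), spec$n_max, l_max),
    provenance = arc$provenance), class = "ace_basis")
  model <- linear_ace_model(basis,
                            coefficients = coefs$coefficients,
                            pair_coefficients = coefs$pair_coefficients,
                            one_body = stats::setNames(coefs$one_body,
                                                       arc$one_body_elements),
                            one_body_strategy = arc$one_body_strategy,
                            pair_degree = as.integer(arc$pair_degree))
  model$diagnostics <- arc$diagnostics
  model
}
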