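#' Normal-mode basis
#'
#' Bundle of ground-state normal-mode frequencies in the dimensionless
#' coordinate convention, with optional mode labels and C_s irrep tags.
#'
#' @param frequencies Numeric vector of vibrational quanta (eV), all > 0.
#' @param labels Optional character vector of mode labels.
#' @param symmetry Optional character vector of per-mode irreps
#'   (`"a'"` totally symmetric, `"a''"` antisymmetric).
#' @return An object of class `normal_modes`.
#' @export
normal_modes <- function(frequencies, labels = NULL, symmetry = NULL) {
  frequencies <- as.numeric(frequencies)
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("all normal-mode frequencies must be finite and strictly positive", call. = FALSE)
  }
  f <- length(frequencies)
  if (!is.null(labels) && length(labels) != f) {
    stop("`labels` must have one entry per mode (", f, ")", call. = FALSE)
  }
  if (!is.null(symmetry)) {
    if (length(symmetry) != f) {
      stop("`symmetry` must have one entry per mode (", f, ")", call. = FALSE)
    }
    bad <- setdiff(unique(symmetry), c("a'", "a''"))
    if (length(bad) > 0) {
      stop("unknown mode irrep label(s): ", paste(bad, collapse = ", "),
           " (expected \"a'\" or \"a''\")", call. = FALSE)
    }
  }
  structure(
    list(n_modes = f, frequencies = frequencies, labels = labels, symmetry = symmetry),
    class = "normal_modes"
  )
}

#' Diabatic-state metadata table
#'
#' @param label Character vector of unique state labels, e.g. `"T(pipi*1)"`,
#'   `"A(La)"`, `"A->T CT"`.
#' @param character Electronic character, one of `"LE_pipi"`, `"LE_npi"`, `"CT"`.
#' @param symmetry State irrep, `"A'"` or `"A''"`.
#' @param fragment Fragment tag (chromophore the excitation lives on; for CT
#'   states, conventionally `"donor->acceptor"`).
#' @param oscillator_strength Non-negative oscillator strengths.
#' @return A tibble with one row per diabatic state.
#' @export
lvc_states <- function(label, character = "LE_pipi", symmetry = "A'",
                       fragment = NA_character_, oscillator_strength = 0) {
  n <- length(label)
  if (anyDuplicated(label)) stop("state labels must be unique", call. = FALSE)
  character <- rep_len(character, n)
  symmetry <- rep_len(symmetry, n)
  fragment <- rep_len(fragment, n)
  oscillator_strength <- rep_len(as.numeric(oscillator_strength), n)
  bad <- setdiff(unique(character), c("LE_pipi", "LE_npi", "CT"))
  if (length(bad) > 0) {
    stop("unknown electronic character(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(symmetry), c("A'", "A''"))
  if (length(bad) > 0) {
    stop("unknown state irrep(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(oscillator_strength < 0)) {
    stop("oscillator strengths must be >= 0", call. = FALSE)
  }
  tibble::tibble(
    label = as.character(label), fragment = fragment, character = character,
    symmetry = symmetry, oscillator_strength = oscillator_strength
  )
}

#' Linear vibronic coupling model
#'
#' An LVC model couples N diabatic electronic states through a potential that
#' is harmonic (with the common ground-state frequencies) plus linear along
#' every dimensionless normal coordinate:
#' \deqn{V_{ii}(q) = E^D_{ii}(0) + \tfrac12 \sum_\alpha \omega_\alpha q_\alpha^2
#'   + \lambda_{ii} \cdot q, \qquad
#'   V_{ij}(q) = E^D_{ij}(0) + \lambda_{ij} \cdot q .}
#' The constant off-diagonal couplings \eqn{E^D_{ij}(0)} are nonzero whenever
#' the diabatic states differ from the adiabatic states at the reference
#' geometry (fragment-based diabatic states).
#'
#' When both state and mode irreps are available, the C_s selection rule is
#' checked: \eqn{\lambda_{ij,\alpha}} may be nonzero only if
#' irrep(i) x irrep(j) x irrep(alpha) is totally symmetric, and constant
#' couplings only between states of the same irrep.
#'
#' @param modes A [normal_modes()] object.
#' @param states A tibble from [lvc_states()] (N rows).
#' @param constant_matrix Symmetric N x N matrix (eV): diagonal holds the
#'   diabatic energies at the reference geometry, off-diagonal the constant
#'   electronic couplings.
#' @param couplings N x N x F array (eV): `couplings[i, i, ]` are the
#'   intra-state energy gradients, `couplings[i, j, ]` (i != j) the linear
#'   inter-state couplings, symmetric in i <-> j.
#' @param check_symmetry How to react to selection-rule violations when irreps
#'   are present: `"warn"` (default), `"error"`, or `"none"`.
#' @param provenance Optional list of diagnostics attached by the
#'   parametrization pipeline (reference weights, completeness, strategy).
#' @return An object of class `lvc_model`.
#' @seealso [potential_matrix()], [adiabatic_energies()], [diabatic_minimum()],
#'   [reorganization_energy()], [build_lvc_model()]
#' @export
lvc_model <- function(modes, states, constant_matrix, couplings = NULL,
                      check_symmetry = c("warn", "error", "none"),
                      provenance = NULL) {
  check_symmetry <- match.arg(check_symmetry)
  stopifnot(inherits(modes, "normal_modes"))
  states <- as_lvc_states(states)
  n <- nrow(states)
  f <- modes$n_modes
  constant_matrix <- as.matrix(constant_matrix)
  if (nrow(constant_matrix) != n || ncol(constant_matrix) != n) {
    stop("`constant_matrix` must be ", n, " x ", n, call. = FALSE)
  }
  if (max(abs(constant_matrix - t(constant_matrix))) > 1e-12) {
    stop("`constant_matrix` must be symmetric to 1e-12", call. = FALSE)
  }
  constant_matrix <- (constant_matrix + t(constant_matrix)) / 2
  if (is.null(couplings)) couplings <- array(0, dim = c(n, n, f))
  couplings <- as_coupling_array(couplings, n, f)
  sym_err <- max(abs(couplings - aperm(couplings, c(2, 1, 3))), 0)
  if (sym_err > 1e-12) {
    stop("coupling vectors must be symmetric in i <-> j (max asymmetry ",
         format(sym_err), ")", call. = FALSE)
  }
  couplings <- (couplings + aperm(couplings, c(2, 1, 3))) / 2
  model <- structure(
    list(modes = modes, states = states, constant_matrix = constant_matrix,
         couplings = couplings, provenance = provenance),
    class = "lvc_model"
  )
  if (check_symmetry != "none" && !is.null(modes$symmetry)) {
    viol <- symmetry_violations(model)
    if (nrow(viol) > 0) {
      msg <- paste0(nrow(viol), " coupling element(s) violate the C_s selection rule, ",
                    "largest |value| = ", format(max(abs(viol$value))), " eV")
      if (check_symmetry == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  model
}

as_lvc_states <- function(states) {
  if (is.character(states)) return(lvc_states(states))
  states <- tibble::as_tibble(states)
  needed <- c("label", "fragment", "character", "symmetry", "oscillator_strength")
  missing_cols <- setdiff(needed, names(states))
  if ("label" %in% missing_cols) stop("states table needs a `label` column", call. = FALSE)
  if ("fragment" %in% missing_cols) states$fragment <- NA_character_
  if ("character" %in% missing_cols) states$character <- "LE_pipi"
  if ("symmetry" %in% missing_cols) states$symmetry <- "A'"
  if ("oscillator_strength" %in% missing_cols) states$oscillator_strength <- 0
  lvc_states(states$label, states$character, states$symmetry,
             states$fragment, states$oscillator_strength)
}

as_coupling_array <- function(couplings, n, f) {
  couplings <- as.array(couplings)
  if (length(dim(couplings)) != 3 || !all(dim(couplings) == c(n, n, f))) {
    stop("`couplings` must be an ", n, " x ", n, " x ", f, " array", call. = FALSE)
  }
  storage.mode(couplings) <- "double"
  couplings
}

# Selection-rule audit: lambda_{ij,alpha} transforms as
# irrep(i) x irrep(j) x irrep(alpha); in C_s the product is totally symmetric
# iff an even number of the three is antisymmetric.
symmetry_violations <- function(model, tol = 0) {
  n <- n_states(model)
  f <- model$modes$n_modes
  st_odd <- model$states$symmetry == "A''"
  md_odd <- model$modes$symmetry == "a''"
  out <- list()
  for (a in seq_len(f)) {
    forbidden <- outer(st_odd, st_odd, function(i, j) xor(xor(i, j), md_odd[a]))
    bad <- which(forbidden & abs(model$couplings[, , a]) > tol, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        i = bad[, 1], j = bad[, 2], mode = a,
        value = model$couplings[, , a][bad]
      )
    }
  }
  # constant couplings only between states of equal irrep
  forb0 <- outer(st_odd, st_odd, xor)
  diag(forb0) <- FALSE
  bad0 <- which(forb0 & abs(model$constant_matrix) > tol, arr.ind = TRUE)
  if (nrow(bad0) > 0) {
    out[[length(out) + 1]] <- tibble::tibble(
      i = bad0[, 1], j = bad0[, 2], mode = 0L,
      value = model$constant_matrix[bad0]
    )
  }
  if (length(out) == 0) {
    tibble::tibble(i = integer(), j = integer(), mode = integer(), value = numeric())
  } else {
    dplyr::bind_rows(out)
  }
}

#' @export
print.lvc_model <- function(x, ...) {
  cat("<lvc_model> ", n_states(x), " diabatic states, ",
      x$modes$n_modes, " modes\n", sep = "")
  cat("  diabatic energies at q = 0 (eV): ",
      paste(format(round(diag(x$constant_matrix), 3)), collapse = " "), "\n", sep = "")
  if (!is.null(x$provenance$strategy)) {
    cat("  parametrized with strategy: ", x$provenance$strategy, "\n", sep = "")
  }
  invisible(x)
}

#' Number of states / modes of an LVC model
#' @param model An `lvc_model`.
#' @return Integer count.
#' @export
n_states <- function(model) nrow(model$states)

#' @rdname n_states
#' @export
n_modes <- function(model) model$modes$n_modes

#' Diabatic potential matrix at a nuclear geometry
#'
#' Evaluates the N x N diabatic potential of the LVC model at dimensionless
#' coordinates `q`: harmonic plus gradient terms on the diagonal, constant
#' plus linear couplings off-diagonal.
#'
#' @param model An [lvc_model()].
#' @param q Numeric vector of length `n_modes(model)`.
#' @return Symmetric N x N matrix in eV.
#' @export
potential_matrix <- function(model, q) {
  q <- as.numeric(q)
  f <- n_modes(model)
  if (length(q) != f) {
    stop("`q` has length ", length(q), " but the model has ", f, " modes", call. = FALSE)
  }
  n <- n_states(model)
  v <- model$constant_matrix
  if (f > 0) {
    lin <- matrix(matrix(model$couplings, n * n, f) %*% q, n, n)
    v <- v + lin
    v <- v + diag(rep(0.5 * sum(model$modes$frequencies * q^2), n), n)
  }
  (v + t(v)) / 2
}

#' Adiabatic energies of an LVC model
#'
#' Diagonalizes the diabatic potential matrix at `q`. Eigenvalues are returned
#' in ascending order; eigenvectors are column-normalized with the sign fixed
#' so the largest-magnitude component of each column is positive (first such
#' component on ties), making weight tables reproducible.
#'
#' @inheritParams potential_matrix
#' @param return_vectors If `TRUE`, return a list with `values` and `vectors`.
#' @return Numeric vector of N eigenvalues (eV), or a list when
#'   `return_vectors = TRUE`.
#' @export
adiabatic_energies <- function(model, q = numeric(n_modes(model)),
                               return_vectors = FALSE) {
  v <- potential_matrix(model, q)
  e <- eigen(v, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  if (!return_vectors) return(values)
  vectors <- fix_eigenvector_signs(e$vectors[, ord, drop = FALSE])
  list(values = values, vectors = vectors)
}

fix_eigenvector_signs <- function(u) {
  for (k in seq_len(ncol(u))) {
    piv <- which.max(abs(u[, k]))
    if (u[piv, k] < 0) u[, k] <- -u[, k]
  }
  u
}

#' Diabatic-state minimum
#'
#' Closed-form minimum of the i-th diagonal diabatic surface:
#' \eqn{q_{min,\alpha} = -\lambda_{ii,\alpha}/\omega_\alpha},
#' \eqn{E_{min} = E^D_{ii}(0) - \frac12 \sum_\alpha \lambda_{ii,\alpha}^2/\omega_\alpha}.
#'
#' @inheritParams potential_matrix
#' @param i State index (1-based) or state label.
#' @return List with `q_min` (length-F vector) and `E_min` (eV).
#' @export
diabatic_minimum <- function(model, i) {
  i <- resolve_state(model, i)
  lam <- model$couplings[i, i, ]
  w <- model$modes$frequencies
  q_min <- if (n_modes(model) > 0) -lam / w else numeric(0)
  e_min <- model$constant_matrix[i, i] - 0.5 * sum(lam^2 / w)
  list(q_min = q_min, E_min = e_min)
}

#' Reorganization energy of a diabatic state
#'
#' Energy released relaxing from the vertical (reference) geometry to the
#' state's own minimum: \eqn{\frac12\sum_\alpha \lambda_{ii,\alpha}^2/\omega_\alpha}.
#'
#' @inheritParams diabatic_minimum
#' @return Reorganization energy in eV.
#' @export
reorganization_energy <- function(model, i) {
  i <- resolve_state(model, i)
  lam <- model$couplings[i, i, ]
  0.5 * sum(lam^2 / model$modes$frequencies)
}

resolve_state <- function(model, i) {
  if (is.character(i)) {
    k <- match(i, model$states$label)
    if (is.na(k)) {
      stop("unknown state label \"", i, "\"; available: ",
           paste(model$states$label, collapse = ", "), call. = FALSE)
    }
    return(k)
  }
  i <- as.integer(i)
  if (is.na(i) || i < 1 || i > n_states(model)) {
    stop("state index must be in 1..", n_states(model), call. = FALSE)
  }
  i
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an LVC model into a per-state table
#'
#' @param x An `lvc_model`.
#' @param ... Unused.
#' @return Tibble with state metadata, vertical diabatic energy, minimum
#'   energy and reorganization energy (all eV).
#' @method tidy lvc_model
#' @export
tidy.lvc_model <- function(x, ...) {
  n <- n_states(x)
  mins <- purrr::map(seq_len(n), ~ diabatic_minimum(x, .x))
  dplyr::mutate(
    x$states,
    energy_vertical = diag(x$constant_matrix),
    energy_minimum = purrr::map_dbl(mins, "E_min"),
    reorganization = purrr::map_dbl(seq_len(n), ~ reorganization_energy(x, .x))
  )
}

#' @rdname tidy.lvc_model
#' @method glance lvc_model
#' @export
glance.lvc_model <- function(x, ...) {
  tibble::tibble(
    n_states = n_states(x),
    n_modes = n_modes(x),
    n_bright = sum(x$states$oscillator_strength > 0),
    min_frequency = if (n_modes(x) > 0) min(x$modes$frequencies) else NA_real_,
    max_frequency = if (n_modes(x) > 0) max(x$modes$frequencies) else NA_real_,
    max_reorganization = max(purrr::map_dbl(seq_len(n_states(x)),
                                            ~ reorganization_energy(x, .x)))
  )
}
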