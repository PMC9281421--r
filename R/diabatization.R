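#' Electronic-structure record at one geometry
#'
#' Container for the output of an excited-state calculation at a single
#' nuclear geometry: adiabatic energies of the lowest M states and the overlap
#' matrix between the N reference states and those adiabatic states,
#' \eqn{S_{im} = \langle R_i | a_m \rangle}. The reference states need not be
#' fully spanned by the M adiabatic states, so row norms of S may be below 1;
#' they must not exceed 1 (beyond numerical tolerance).
#'
#' @param geometry_tag Character tag, e.g. `"FC"`, `"m3+"`, `"m3-"`.
#' @param q Dimensionless coordinates of the geometry (length F).
#' @param adiabatic_energies Numeric vector of M energies (eV), ascending.
#' @param overlap N x M numeric matrix.
#' @param oscillator_strengths Optional length-M vector.
#' @param strategy Optional provenance tag for how the reference states were
#'   built (`"St"`, `"FrD"`, `"FrD_MMref"`, ...).
#' @param tol Tolerance on row norms exceeding 1.
#' @return An object of class `es_record`.
#' @export
es_record <- function(geometry_tag, q, adiabatic_energies, overlap,
                      oscillator_strengths = NULL, strategy = NULL,
                      tol = 1e-8) {
  overlap <- as.matrix(overlap)
  m <- length(adiabatic_energies)
  if (ncol(overlap) != m) {
    stop("overlap has ", ncol(overlap), " columns but ", m,
         " adiabatic energies were given", call. = FALSE)
  }
  rn <- rowSums(overlap^2)
  if (any(rn > 1 + tol)) {
    stop("overlap row norm exceeds 1 for reference state(s) ",
         paste(which(rn > 1 + tol), collapse = ", "), call. = FALSE)
  }
  structure(
    list(geometry_tag = as.character(geometry_tag), q = as.numeric(q),
         adiabatic_energies = as.numeric(adiabatic_energies),
         overlap = overlap, oscillator_strengths = oscillator_strengths,
         strategy = strategy),
    class = "es_record"
  )
}

#' @export
print.es_record <- function(x, ...) {
  cat("<es_record> geometry ", x$geometry_tag, ": ",
      nrow(x$overlap), " reference x ", ncol(x$overlap), " adiabatic states\n",
      sep = "")
  invisible(x)
}

#' Loewdin (symmetric) orthonormalization of an overlap matrix
#'
#' Computes \eqn{D = (S S^T)^{-1/2} S}, the row-orthonormal matrix closest to
#' S in Frobenius norm. Applied to the reference/adiabatic overlap matrix it
#' yields the expansion of diabatic states in the adiabatic basis that
#' resembles the reference states as closely as possible.
#'
#' The inverse square root is taken through the eigen-decomposition of
#' \eqn{S S^T}; an eigenvalue below `rank_tol` means some reference state is
#' (numerically) outside the span of the adiabatic set and raises an error
#' naming that state rather than regularizing silently.
#'
#' @param S N x M overlap matrix, M >= N.
#' @param rank_tol Eigenvalue floor for \eqn{S S^T} (default 1e-10; the
#'   corresponding singular-value floor is 1e-5).
#' @return N x M matrix with orthonormal rows.
#' @export
lowdin_transform <- function(S, rank_tol = 1e-10) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (ncol(S) < n) {
    stop("overlap matrix must have at least as many columns (adiabatic states) ",
         "as rows (reference states)", call. = FALSE)
  }
  gram <- S %*% t(S)
  e <- eigen((gram + t(gram)) / 2, symmetric = TRUE)
  if (any(e$values < rank_tol)) {
    # identify which reference state dominates the deficient direction
    k <- which.min(e$values)
    ref <- which.max(abs(e$vectors[, k]))
    stop("overlap matrix is rank deficient (eigenvalue ", format(e$values[k]),
         " of S S^T below ", format(rank_tol), "); reference state ", ref,
         " is not spanned by the adiabatic set", call. = FALSE)
  }
  inv_sqrt <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  inv_sqrt %*% S
}

#' Diabatic Hamiltonian from a transformation matrix
#'
#' \eqn{H^D = D \,\mathrm{diag}(E^A)\, D^T}: rotates the diagonal matrix of
#' adiabatic energies into the diabatic basis. With `D` from
#' [lowdin_transform()] the diagonal gives the diabatic energies
#' \eqn{E^D_{ii}} and the off-diagonal the electronic couplings
#' \eqn{E^D_{ij}} at that geometry.
#'
#' @param D N x M matrix with orthonormal rows.
#' @param E_adiabatic Numeric vector of M adiabatic energies (eV).
#' @return Symmetric N x N matrix (eV).
#' @export
diabatic_hamiltonian <- function(D, E_adiabatic) {
  D <- as.matrix(D)
  if (ncol(D) != length(E_adiabatic)) {
    stop("`D` has ", ncol(D), " columns but ", length(E_adiabatic),
         " adiabatic energies were given", call. = FALSE)
  }
  h <- D %*% (E_adiabatic * t(D))
  (h + t(h)) / 2
}

#' Reference weights of adiabatic states
#'
#' For each adiabatic state m, the weight of the best-matching reference
#' state: \eqn{W_m = \max_i S_{im}^2}. Values near 1 justify labelling the
#' adiabatic state by that reference character.
#'
#' @param S N x M overlap matrix.
#' @return Numeric vector of M weights in \[0, 1\].
#' @export
reference_weights <- function(S) {
  S <- as.matrix(S)
  apply(S^2, 2, max)
}

#' Completeness of the reference states in the adiabatic set
#'
#' Row norms \eqn{\sum_m S_{im}^2}; below 1 when the adiabatic set is
#' truncated and does not fully span reference state i.
#'
#' @inheritParams reference_weights
#' @return Numeric vector of N row norms.
#' @export
reference_completeness <- function(S) {
  rowSums(as.matrix(S)^2)
}

#' Align diabatization phases against a reference transformation
#'
#' Flips the sign of each row of `D` so that its inner product with the
#' corresponding row of `D_ref` is non-negative; used to undo arbitrary
#' reference-state phase flips between electronic-structure runs. A warning
#' is raised when an aligned inner product is still small in magnitude
#' (< 0.5), which signals possible reordering of diabatic character between
#' the two transformations.
#'
#' Caveat: the comparison is between row *coordinates*, which live in the
#' adiabatic basis of each geometry. Between different geometries those bases
#' coincide only approximately; when near-degenerate adiabatic states rotate
#' strongly under a small displacement the inner products lose meaning. The
#' parametrization pipeline therefore aligns signs on the (basis-invariant)
#' diabatic Hamiltonians instead — see [align_hamiltonian_signs()] — and this
#' row-space alignment is intended for transformations sharing one geometry
#' or very similar bases.
#'
#' @param D,D_ref Matrices of identical shape.
#' @return `D` with per-row sign flips applied.
#' @export
phase_align <- function(D, D_ref) {
  D <- as.matrix(D); D_ref <- as.matrix(D_ref)
  if (!all(dim(D) == dim(D_ref))) {
    stop("`D` and `D_ref` must have identical shapes", call. = FALSE)
  }
  ip <- rowSums(D * D_ref)
  flip <- ifelse(ip < 0, -1, 1)
  if (any(abs(ip) < 0.5)) {
    warning("phase alignment found |row inner product| < 0.5 for row(s) ",
            paste(which(abs(ip) < 0.5), collapse = ", "),
            "; diabatic states may have reordered", call. = FALSE)
  }
  D * flip
}

#' Align diabatic-state signs between two diabatic Hamiltonians
#'
#' A sign flip of diabatic state i flips row and column i of the diabatic
#' Hamiltonian (off-diagonal elements only). This helper finds the sign
#' vector s (first entry fixed to +1) maximizing
#' \eqn{\sum_{i \ne j} s_i s_j H_{ij} H^{ref}_{ij}} by iterated greedy
#' sweeps, and returns `H` with the flips applied — the representation of
#' the same Hamiltonian in the reference sign convention. Unlike row-space
#' phase alignment this comparison is invariant under any rotation of the
#' underlying adiabatic basis, so it remains valid between displaced
#' geometries. States whose reference couplings are all (numerically) zero
#' carry no sign evidence and are left unflipped.
#'
#' @param H,H_ref Symmetric matrices of identical shape (eV).
#' @param tol Evidence threshold below which a state's sign is left alone.
#' @return `H` with row/column sign flips applied.
#' @export
align_hamiltonian_signs <- function(H, H_ref, tol = 1e-12) {
  n <- nrow(H)
  s <- rep(1, n)
  w <- H * H_ref
  diag(w) <- 0
  for (sweep in 1:4) {
    changed <- FALSE
    for (i in seq(2, length.out = max(n - 1, 0))) {
      evidence <- sum(s[-i] * w[i, -i])
      if (abs(evidence) > tol && sign(evidence) != s[i]) {
        s[i] <- sign(evidence)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  H * tcrossprod(s)
}

#' Diabatize one electronic-structure record
#'
#' Runs the overlap-based diabatization at a single geometry: Loewdin
#' orthonormalization of the overlap matrix, rotation of the adiabatic
#' energies into the diabatic basis, and the weight/completeness diagnostics.
#'
#' For the standard (St) strategy the reference states are the lowest N
#' adiabatic states themselves: S is the N x M identity block, D = S, and the
#' diabatic Hamiltonian is exactly diagonal.
#'
#' @param record An [es_record()].
#' @param n_states Number of diabatic states N. Defaults to `nrow(overlap)`;
#'   required for `strategy = "St"`.
#' @param strategy `"overlap"` (default; use the record's overlap matrix,
#'   covering both fragment-based conventions) or `"St"` (identity reference
#'   on the lowest N adiabatic states).
#' @return A list of class `diabatization_result`: `D`, `H_diabatic`,
#'   `weights`, `completeness`, `geometry_tag`, `q`.
#' @export
diabatize_record <- function(record, n_states = NULL,
                             strategy = c("overlap", "St")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(record, "es_record"))
  m <- length(record$adiabatic_energies)
  if (strategy == "St") {
    if (is.null(n_states)) {
      stop("`n_states` must be given for the St strategy", call. = FALSE)
    }
    S <- cbind(diag(n_states), matrix(0, n_states, m - n_states))
  } else {
    S <- record$overlap
    if (!is.null(n_states) && n_states != nrow(S)) {
      stop("record carries ", nrow(S), " reference states but n_states = ",
           n_states, call. = FALSE)
    }
  }
  D <- lowdin_transform(S)
  structure(
    list(D = D,
         H_diabatic = diabatic_hamiltonian(D, record$adiabatic_energies),
         weights = reference_weights(S),
         completeness = reference_completeness(S),
         geometry_tag = record$geometry_tag,
         q = record$q),
    class = "diabatization_result"
  )
}

#' @export
print.diabatization_result <- function(x, ...) {
  cat("<diabatization_result> geometry ", x$geometry_tag, "\n", sep = "")
  cat("  diabatic energies (eV): ",
      paste(format(round(diag(x$H_diabatic), 3)), collapse = " "), "\n", sep = "")
  cat("  min completeness: ", format(round(min(x$completeness), 4)), "\n", sep = "")
  invisible(x)
}
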