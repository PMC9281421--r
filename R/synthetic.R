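#' Seeded ground-truth LVC model generator
#'
#' Builds a reproducible LVC model with the structure typical of a
#' hydrogen-bonded purine/pyrimidine pair in C_s symmetry: bright pipi* local
#' excitations, dark npi* states, and an inter-fragment charge-transfer state
#' whose reorganization energy is by construction the largest (CT states
#' couple strongly to the intramolecular relaxation, with reorganization
#' energies around 1.2 eV versus 0.25-0.6 eV for the local excitations).
#' Frequencies span 0.01-0.4 eV and all couplings respect the C_s selection
#' rules: gradients only along totally-symmetric (a') modes, linear couplings
#' between A'/A'' states only through a'' modes, and constant couplings only
#' within an irrep block.
#'
#' With the default 12-state template the state characters, irreps,
#' oscillator strengths and vertical energies correspond to the low-lying
#' singlet manifold of an adenine-thymine Watson-Crick pair (two bright
#' adenine pipi* states La/Lb, the lowest thymine pipi*, five npi* states, the
#' adenine-to-thymine CT and three higher pipi* states).
#'
#' @param n_states Number of diabatic states (default 12).
#' @param n_modes Number of normal modes (default 10).
#' @param character_template Optional tibble with columns `label`, `fragment`,
#'   `character`, `symmetry`, `oscillator_strength`, `energy`; defaults to the
#'   built-in AT-like 12-state template (recycled/truncated to `n_states`).
#' @param seed Integer seed; the same seed always yields the same model.
#' @param coupling_scale Standard deviation of the constant inter-state
#'   couplings (eV, default 0.03) and scale of the linear inter-state
#'   couplings (half of it per mode).
#' @return An [lvc_model()].
#' @export
make_truth_model <- function(n_states = 12, n_modes = 10,
                             character_template = NULL, seed = 1,
                             coupling_scale = 0.03) {
  stopifnot(n_states >= 1, n_modes >= 1)
  tpl <- character_template %||% at_state_template()
  idx <- rep_len(seq_len(nrow(tpl)), n_states)
  tpl <- tpl[idx, ]
  if (anyDuplicated(tpl$label)) {
    tpl$label <- make.unique(tpl$label, sep = "#")
  }
  withr::with_seed(as.integer(seed), {
    # modes: at least one totally-symmetric mode so every state has a gradient
    freq <- sort(stats::runif(n_modes, 0.01, 0.4))
    sym <- sample(c("a'", "a''"), n_modes, replace = TRUE, prob = c(0.65, 0.35))
    sym[1] <- "a'"
    modes <- normal_modes(freq, symmetry = sym)
    a1 <- which(sym == "a'")

    states <- lvc_states(tpl$label, tpl$character, tpl$symmetry,
                         tpl$fragment, tpl$oscillator_strength)
    energy <- tpl$energy + stats::rnorm(n_states, sd = 0.02)

    reorg_range <- function(ch) switch(ch,
      LE_pipi = c(0.25, 0.40), LE_npi = c(0.40, 0.60), CT = c(1.1, 1.3))
    couplings <- array(0, dim = c(n_states, n_states, n_modes))
    for (i in seq_len(n_states)) {
      rr <- reorg_range(states$character[i])
      target <- stats::runif(1, rr[1], rr[2])
      direction <- stats::rnorm(length(a1))
      direction <- direction / sqrt(sum(direction^2))
      # scale so that 0.5 * sum(lambda^2 / omega) equals the drawn target
      lam <- direction * sqrt(freq[a1])          # unit reorg contribution shape
      lam <- lam * sqrt(2 * target / sum(lam^2 / freq[a1]))
      couplings[i, i, a1] <- lam
    }
    st_odd <- states$symmetry == "A''"
    md_odd <- sym == "a''"
    constant <- diag(energy)
    for (i in seq_len(n_states - 1)) {
      for (j in seq((i + 1), n_states)) {
        if (st_odd[i] == st_odd[j]) {
          constant[i, j] <- constant[j, i] <- stats::rnorm(1, sd = coupling_scale)
        }
        allowed <- which(md_odd == xor(st_odd[i], st_odd[j]))
        if (length(allowed) > 0) {
          lam_ij <- stats::rnorm(length(allowed), sd = coupling_scale / 2)
          couplings[i, j, allowed] <- couplings[j, i, allowed] <- lam_ij
        }
      }
    }
    lvc_model(modes, states, constant, couplings, check_symmetry = "error")
  })
}

at_state_template <- function() {
  tibble::tibble(
    label = c("T(pipi*1)", "T(nOpi*1)", "A(La)", "A(Lb)", "A(nNpi*1)",
              "A->T(CT)", "A(nNpi*2)", "T(nOpi*2)", "A(nNpi*3)",
              "T(pipi*2)", "T(pipi*3)", "A(pipi*3)"),
    fragment = c("T", "T", "A", "A", "A", "A->T", "A", "T", "A", "T", "T", "A"),
    character = c("LE_pipi", "LE_npi", "LE_pipi", "LE_pipi", "LE_npi", "CT",
                  "LE_npi", "LE_npi", "LE_npi", "LE_pipi", "LE_pipi", "LE_pipi"),
    symmetry = c("A'", "A''", "A'", "A'", "A''", "A'",
                 "A''", "A''", "A''", "A'", "A'", "A'"),
    oscillator_strength = c(0.204, 0, 0.126, 0.203, 0, 0.003,
                            0, 0, 0.003, 0.017, 0.296, 0.268),
    energy = c(5.32, 5.36, 5.45, 5.56, 5.66, 6.08,
               6.14, 6.44, 6.61, 6.63, 6.73, 6.81)
  )
}

#' Synthetic-backend specification
#'
#' Couples a hidden ground-truth LVC model to the imperfection knobs of the
#' emulated electronic-structure layer: truncation of the adiabatic set to M
#' states, a seeded orthogonal mixing of the reference states (emulating
#' reference states that are not eigenstates of the full system), per-state
#' embedding shifts (emulating a molecular-mechanics description of the
#' surrounding fragments in the reference-state definition), and the choice of
#' reference convention.
#'
#' @param truth The ground-truth [lvc_model()].
#' @param n_adiabatic_out `"all"` or an integer M <= N: how many adiabatic
#'   states the backend reports.
#' @param reference_mixing_angle Rotation angle (rad, in \[0, pi/4)) of a
#'   seeded orthogonal perturbation applied to the reference states within
#'   same-irrep blocks; 0 means perfect references.
#' @param embedding_shift Optional per-state energy shifts (eV) added to the
#'   truth constant matrix before re-diagonalizing to define the reference
#'   states (the truth surfaces themselves are untouched).
#' @param reference_type `"diabatic"` (references are the truth diabatic
#'   states; fragment-style conventions) or `"adiabatic_fc"` (references are
#'   the adiabatic states at q = 0; standard-LVC convention).
#' @param seed Integer seed for the mixing perturbation.
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(truth, n_adiabatic_out = "all",
                       reference_mixing_angle = 0, embedding_shift = NULL,
                       reference_type = c("diabatic", "adiabatic_fc"),
                       seed = 1) {
  stopifnot(inherits(truth, "lvc_model"))
  reference_type <- match.arg(reference_type)
  n <- n_states(truth)
  m <- if (identical(n_adiabatic_out, "all")) n else as.integer(n_adiabatic_out)
  if (m < 1 || m > n) stop("`n_adiabatic_out` must be in 1..", n, call. = FALSE)
  if (reference_mixing_angle < 0 || reference_mixing_angle >= pi / 4) {
    stop("`reference_mixing_angle` must be in [0, pi/4)", call. = FALSE)
  }
  if (!is.null(embedding_shift) && length(embedding_shift) != n) {
    stop("`embedding_shift` needs one entry per state", call. = FALSE)
  }
  structure(
    list(truth = truth, n_adiabatic_out = m,
         reference_mixing_angle = reference_mixing_angle,
         embedding_shift = embedding_shift, reference_type = reference_type,
         seed = as.integer(seed)),
    class = "truth_spec"
  )
}

# Reference states expressed in the truth diabatic basis (orthogonal N x N,
# columns = reference vectors).
reference_matrix <- function(spec) {
  truth <- spec$truth
  n <- n_states(truth)
  if (spec$reference_type == "adiabatic_fc") {
    e <- eigen(truth$constant_matrix, symmetric = TRUE)
    base <- fix_eigenvector_signs(e$vectors[, order(e$values), drop = FALSE])
  } else if (!is.null(spec$embedding_shift)) {
    shifted <- truth$constant_matrix + diag(spec$embedding_shift, n)
    e <- eigen(shifted, symmetric = TRUE)
    u <- fix_eigenvector_signs(e$vectors[, order(e$values), drop = FALSE])
    # assign each reference to the diabatic state it overlaps most, keeping
    # the fragment labels meaningful
    assign <- apply(abs(u), 2, which.max)
    if (anyDuplicated(assign) == 0) u <- u[, order(assign), drop = FALSE]
    base <- u
  } else {
    base <- diag(n)
  }
  theta <- spec$reference_mixing_angle
  if (theta > 0) {
    st_odd <- truth$states$symmetry == "A''"
    k <- withr::with_seed(spec$seed, {
      a <- matrix(stats::rnorm(n * n), n, n)
      a[outer(st_odd, st_odd, xor)] <- 0  # mix only within an irrep block
      a - t(a)
    })
    nrm <- max(svd(k, nu = 0, nv = 0)$d)
    if (nrm > 0) {
      rot <- as.matrix(Matrix::expm((theta / nrm) * k))
      base <- base %*% rot
    }
  }
  base
}

#' Generate a synthetic electronic-structure record
#'
#' Emulates one excited-state calculation: diagonalizes the ground-truth
#' potential at `q`, reports the lowest M adiabatic energies, and forms the
#' reference/adiabatic overlap matrix \eqn{S_{im} = \langle R_i | a_m\rangle}
#' in the truth diabatic basis. With perfect references and M = N the record
#' is an exact faithful image of the truth; truncation (M < N) leaves the
#' reference states incompletely spanned, and mixing/embedding imperfections
#' lower the reference weights below 1.
#'
#' @param spec A [truth_spec()].
#' @param q Dimensionless coordinates (length `n_modes(truth)`).
#' @param geometry_tag Tag stored on the record (default from `q`).
#' @return An [es_record()].
#' @export
generate_record <- function(spec, q, geometry_tag = NULL) {
  stopifnot(inherits(spec, "truth_spec"))
  truth <- spec$truth
  v <- potential_matrix(truth, q)
  e <- eigen(v, symmetric = TRUE)
  ord <- order(e$values)
  u <- fix_eigenvector_signs(e$vectors[, ord, drop = FALSE])
  vals <- e$values[ord]
  m <- spec$n_adiabatic_out
  r <- reference_matrix(spec)
  s <- t(r) %*% u[, seq_len(m), drop = FALSE]
  f_dia <- truth$states$oscillator_strength
  f_adia <- as.numeric(t(u[, seq_len(m), drop = FALSE]^2) %*% f_dia)
  if (is.null(geometry_tag)) {
    geometry_tag <- if (all(q == 0)) "FC" else paste0("q[", paste(signif(q, 6), collapse = ","), "]")
  }
  es_record(geometry_tag, q, vals[seq_len(m)], s,
            oscillator_strengths = f_adia,
            strategy = if (spec$reference_type == "adiabatic_fc") "St" else "FrD")
}

#' Generate the full record set for a displacement protocol
#'
#' @param spec A [truth_spec()].
#' @param protocol A [displacement_grid()] protocol over the truth's modes.
#' @return Named list of [es_record()]s, one per protocol geometry.
#' @export
generate_records <- function(spec, protocol) {
  stopifnot(inherits(protocol, "displacement_protocol"))
  tags <- protocol$plan$geometry_tag
  out <- purrr::map(tags, function(tag) {
    generate_record(spec, protocol_q(protocol, tag), geometry_tag = tag)
  })
  stats::setNames(out, tags)
}
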