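#' Finite-difference displacement protocol
#'
#' Generates the 2F + 1 geometries used to extract linear couplings: the
#' reference point plus displacements of each dimensionless normal coordinate
#' by +/- Delta_alpha. Tags are deterministic: `"FC"`, `"m<alpha>+"`,
#' `"m<alpha>-"`.
#'
#' @param modes A [normal_modes()] object.
#' @param delta Positive step, scalar or one value per mode (default 0.1).
#' @return An object of class `displacement_protocol`: tibble `plan`
#'   (`geometry_tag`, `mode`, `sign`) and the step vector `deltas`; the
#'   q-vectors are available through `protocol_q()`.
#' @export
displacement_grid <- function(modes, delta = 0.1) {
  stopifnot(inherits(modes, "normal_modes"))
  f <- modes$n_modes
  deltas <- rep_len(as.numeric(delta), f)
  if (any(!is.finite(deltas)) || any(deltas <= 0)) {
    stop("displacement steps must be strictly positive", call. = FALSE)
  }
  plan <- tibble::tibble(
    geometry_tag = c("FC", as.vector(rbind(paste0("m", seq_len(f), "+"),
                                           paste0("m", seq_len(f), "-")))),
    mode = c(NA_integer_, rep(seq_len(f), each = 2)),
    sign = c(NA_real_, rep(c(1, -1), f))
  )
  structure(list(plan = plan, deltas = deltas, n_modes = f),
            class = "displacement_protocol")
}

#' Geometry of a protocol entry
#'
#' @param protocol A [displacement_grid()] protocol.
#' @param geometry_tag One of the protocol's tags.
#' @return Dimensionless q vector of length F.
#' @export
protocol_q <- function(protocol, geometry_tag) {
  row <- match(geometry_tag, protocol$plan$geometry_tag)
  if (is.na(row)) stop("unknown geometry tag \"", geometry_tag, "\"", call. = FALSE)
  q <- numeric(protocol$n_modes)
  mode <- protocol$plan$mode[row]
  if (!is.na(mode)) q[mode] <- protocol$plan$sign[row] * protocol$deltas[mode]
  q
}

#' @export
print.displacement_protocol <- function(x, ...) {
  cat("<displacement_protocol> ", nrow(x$plan), " geometries over ",
      x$n_modes, " modes, steps ",
      paste(format(unique(x$deltas)), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Linear couplings by central finite differences
#'
#' \deqn{\lambda_{ij,\alpha} = \frac{H^D_{ij}(+\Delta_\alpha) -
#'   H^D_{ij}(-\Delta_\alpha)}{2\Delta_\alpha}.}
#' The harmonic contribution \eqn{\tfrac12\omega_\alpha\Delta^2} to the
#' diagonal is even in the displacement and cancels exactly, so on an exactly
#' linear-plus-harmonic potential the central difference is exact.
#'
#' @param H_plus,H_minus Lists of F phase-aligned diabatic Hamiltonians, one
#'   per mode, at +Delta and -Delta.
#' @param protocol The [displacement_grid()] protocol used.
#' @return N x N x F coupling array (eV), symmetric in i <-> j.
#' @export
finite_difference_couplings <- function(H_plus, H_minus, protocol) {
  f <- protocol$n_modes
  if (length(H_plus) != f || length(H_minus) != f) {
    stop("need one +Delta and one -Delta Hamiltonian per mode (", f, ")", call. = FALSE)
  }
  n <- nrow(H_plus[[1]])
  lam <- array(0, dim = c(n, n, f))
  for (a in seq_len(f)) {
    lam[, , a] <- (H_plus[[a]] - H_minus[[a]]) / (2 * protocol$deltas[a])
    lam[, , a] <- (lam[, , a] + t(lam[, , a])) / 2
  }
  lam
}

#' Curvature diagnostic for the linear vibronic model
#'
#' The LVC ansatz requires every diagonal diabatic surface to carry exactly
#' the ground-state harmonic curvature and the couplings to be exactly linear.
#' The central second difference
#' \eqn{[H_{ij}(+\Delta) + H_{ij}(-\Delta) - 2 H_{ij}(0)]/\Delta^2}
#' therefore must equal \eqn{\omega_\alpha} on the diagonal and 0
#' off-diagonal; deviations flag anharmonicity or nonlinear couplings in the
#' underlying electronic structure.
#'
#' @inheritParams finite_difference_couplings
#' @param H_fc Diabatic Hamiltonian at the reference geometry.
#' @param modes The [normal_modes()] basis.
#' @param threshold Flag deviations larger than this (eV; default 0.01).
#' @return Tibble with one row per mode: worst diagonal deviation from
#'   omega_alpha, worst off-diagonal deviation from 0, and a logical flag.
#' @export
lvc_validity_diagnostic <- function(H_plus, H_minus, H_fc, modes, protocol,
                                    threshold = 0.01) {
  f <- protocol$n_modes
  rows <- purrr::map(seq_len(f), function(a) {
    curv <- (H_plus[[a]] + H_minus[[a]] - 2 * H_fc) / protocol$deltas[a]^2
    diag_dev <- max(abs(diag(curv) - modes$frequencies[a]))
    off <- curv; diag(off) <- 0
    off_dev <- max(abs(off), 0)
    tibble::tibble(mode = a, frequency = modes$frequencies[a],
                   diag_curvature_dev = diag_dev, offdiag_curvature_dev = off_dev)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, flagged = .data$diag_curvature_dev > threshold |
                  .data$offdiag_curvature_dev > threshold)
}

#' Build an LVC model from electronic-structure records
#'
#' Orchestrates the full parametrization: diabatize every record
#' ([lowdin_transform()] + [diabatic_hamiltonian()]), phase-align each
#' displaced transformation against the reference-point one, and extract the
#' linear couplings by central finite differences. The constant matrix is the
#' diabatic Hamiltonian at the reference geometry; reference weights and
#' completeness at the reference point are attached as provenance together
#' with the per-mode curvature diagnostic.
#'
#' Strategies: `"FrD"` and `"FrD_MMref"` both consume the overlap matrices
#' carried by the records (they differ only in how the backend defined the
#' reference states); `"St"` takes the lowest `n_states` adiabatic states as
#' the diabatic basis, so the constant off-diagonal couplings are exactly
#' zero.
#'
#' @param records List of [es_record()]s covering the protocol (tags `"FC"`,
#'   `"m<alpha>+"`, `"m<alpha>-"`).
#' @param modes The [normal_modes()] basis (ground-state frequencies).
#' @param n_states Number of diabatic states N.
#' @param strategy `"FrD"`, `"FrD_MMref"` or `"St"`.
#' @param protocol Optional [displacement_grid()]; defaults to steps of
#'   `delta` on every mode.
#' @param delta Displacement step used when `protocol` is not given.
#' @param states Optional state metadata ([lvc_states()] tibble) for the
#'   resulting model.
#' @param completeness_warn Warn when any reference-state completeness at the
#'   reference geometry falls below this (default 0.8).
#' @return An [lvc_model()] with provenance (`strategy`, `weights_fc`,
#'   `completeness_fc`, `diagnostic`, `diabatizations`).
#' @export
build_lvc_model <- function(records, modes, n_states,
                            strategy = c("FrD", "FrD_MMref", "St"),
                            protocol = NULL, delta = 0.1, states = NULL,
                            completeness_warn = 0.8) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(modes, "normal_modes"))
  if (is.null(protocol)) protocol <- displacement_grid(modes, delta)
  f <- modes$n_modes
  tags <- purrr::map_chr(records, "geometry_tag")
  ms <- unique(purrr::map_int(records, ~ length(.x$adiabatic_energies)))
  if (length(ms) != 1) {
    stop("records carry inconsistent numbers of adiabatic states: ",
         paste(ms, collapse = ", "), call. = FALSE)
  }
  get_record <- function(tag) {
    k <- match(tag, tags)
    if (is.na(k)) {
      if (tag == "FC") stop("missing reference-point record (tag \"FC\")", call. = FALSE)
      stop("missing displaced record for geometry \"", tag, "\" (mode ",
           sub("^m([0-9]+).*$", "\\1", tag), ", sign ",
           substring(tag, nchar(tag)), ")", call. = FALSE)
    }
    records[[k]]
  }
  # For the standard strategy the diabatic states coincide with the lowest N
  # adiabatic states at the reference geometry: S("FC") is the identity block
  # and the constant couplings vanish exactly. Displaced geometries still use
  # the records' overlaps (references = reference-point adiabatic states).
  dstrat_fc <- if (strategy == "St") "St" else "overlap"
  dia_fc <- diabatize_record(get_record("FC"), n_states = n_states, strategy = dstrat_fc)
  dia_plus <- vector("list", f); dia_minus <- vector("list", f)
  for (a in seq_len(f)) {
    dp <- diabatize_record(get_record(paste0("m", a, "+")), n_states, "overlap")
    dm <- diabatize_record(get_record(paste0("m", a, "-")), n_states, "overlap")
    # undo possible reference-phase flips against the reference-point
    # diabatization (never the neighbouring geometry, so sign drift cannot
    # accumulate); alignment works on the diabatic Hamiltonians because row
    # coordinates of D at different geometries live in different adiabatic
    # bases and are not comparable near avoided crossings
    dp$H_diabatic <- align_hamiltonian_signs(dp$H_diabatic, dia_fc$H_diabatic)
    dm$H_diabatic <- align_hamiltonian_signs(dm$H_diabatic, dia_fc$H_diabatic)
    dia_plus[[a]] <- dp; dia_minus[[a]] <- dm
  }
  h_plus <- purrr::map(dia_plus, "H_diabatic")
  h_minus <- purrr::map(dia_minus, "H_diabatic")
  lam <- finite_difference_couplings(h_plus, h_minus, protocol)
  diag_tbl <- lvc_validity_diagnostic(h_plus, h_minus, dia_fc$H_diabatic,
                                      modes, protocol)
  low <- which(dia_fc$completeness < completeness_warn)
  if (length(low) > 0) {
    warning("reference-state completeness below ", completeness_warn,
            " at the reference geometry for state(s) ",
            paste(low, collapse = ", "), call. = FALSE)
  }
  if (is.null(states)) {
    # diabatic oscillator strengths from the adiabatic ones at the reference
    # point: f^D_i = sum_m D_im^2 f^A_m (squared-rotation estimate)
    f_fc <- get_record("FC")$oscillator_strengths
    f_dia <- if (is.null(f_fc)) 0 else as.numeric(dia_fc$D^2 %*% f_fc)
    states <- lvc_states(paste0("D", seq_len(n_states)),
                         oscillator_strength = pmax(f_dia, 0))
  }
  constant <- dia_fc$H_diabatic
  if (strategy == "St") {
    constant[row(constant) != col(constant)] <- 0
  }
  lvc_model(
    modes = modes, states = states, constant_matrix = constant, couplings = lam,
    check_symmetry = "none",
    provenance = list(
      strategy = strategy,
      n_adiabatic = ms,
      delta = protocol$deltas,
      weights_fc = dia_fc$weights,
      completeness_fc = dia_fc$completeness,
      diagnostic = diag_tbl,
      diabatization_fc = dia_fc
    )
  )
}
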