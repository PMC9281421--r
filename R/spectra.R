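#' Nonadiabatic absorption spectrum from autocorrelation functions
#'
#' Builds the vibronic absorption spectrum from the autocorrelation functions
#' of wavepacket propagations started on each bright diabatic state. The
#' lineshape of each contribution is
#' \deqn{I_b(E) \propto f_b \, \mathrm{Re}\!\int_0^{T} C_b(t)\, g(t)\,
#'   e^{i (E + E_{ZPE}) t/\hbar}\, dt,}
#' where \eqn{C_b(t) = \langle\psi_b(0)|\psi_b(t)\rangle}, \eqn{f_b} is the
#' oscillator strength of the initially excited diabatic state,
#' \eqn{E_{ZPE} = \tfrac12\sum_\alpha\omega_\alpha} references energies to
#' the vibrational ground level of S0, and \eqn{g(t) =
#' \exp(-\sigma^2 t^2/2\hbar^2)} is the time-domain conjugate of a Gaussian
#' whose energy-domain half width at half maximum is `hwhm` (so a stick line
#' becomes a Gaussian of exactly that HWHM). The total spectrum is the
#' pointwise sum of the per-initial-state contributions.
#'
#' @param trajectories One [propagate()] result or a list of them, one per
#'   bright initial state. Each must have been started from a single diabatic
#'   state (as [initial_wavepacket()] does).
#' @param hwhm Gaussian half width at half maximum in eV (default 0.04).
#' @param shift Rigid shift added to the energy axis (eV, default 0) for
#'   comparison with experiment; purely presentational.
#' @param energy_grid Energies (eV) at which to evaluate the spectrum;
#'   defaults to a 2 meV grid spanning the bright verticals +/- 1.5 eV.
#' @param e_prefactor If `TRUE`, multiply each contribution by the photon
#'   energy E (transition-dipole vs oscillator-strength weighting); off by
#'   default and recorded in the metadata.
#' @param normalize `"total_max"` (default) scales so the total curve peaks
#'   at 1 and clamps negative transform ringing at 0; `"none"` returns the
#'   raw transform.
#' @param min_damping_spans Error unless the time grid covers at least this
#'   many damping times \eqn{\hbar/\sigma} (default 4; shorter grids cannot
#'   resolve the requested broadening).
#' @return An object of class `lvc_spectrum`: tibble `data` (energy, one
#'   column per initial state, `total`) plus `metadata`.
#' @export
absorption_spectrum <- function(trajectories, hwhm = 0.04, shift = 0,
                                energy_grid = NULL, e_prefactor = FALSE,
                                normalize = c("total_max", "none"),
                                min_damping_spans = 4) {
  normalize <- match.arg(normalize)
  if (inherits(trajectories, "lvc_propagation")) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1,
            all(purrr::map_lgl(trajectories, inherits, "lvc_propagation")))
  if (hwhm <= 0) stop("`hwhm` must be > 0", call. = FALSE)
  sigma <- hwhm / sqrt(2 * log(2))
  tau <- hbar_ev_fs / sigma
  model <- trajectories[[1]]$model

  labels <- purrr::map_chr(trajectories, function(tr) {
    colnames(tr$populations)[tr$metadata$initial_state]
  })
  f_b <- purrr::map_dbl(trajectories, function(tr) {
    tr$model$states$oscillator_strength[tr$metadata$initial_state]
  })
  verticals <- purrr::map_dbl(trajectories, function(tr) {
    diag(tr$model$constant_matrix)[tr$metadata$initial_state]
  })
  for (tr in trajectories) {
    t_cov <- tr$times[length(tr$times)]
    if (t_cov < min_damping_spans * tau) {
      stop("time grid covers ", format(round(t_cov, 1)), " fs but the ",
           format(hwhm), " eV broadening needs t_final >= ",
           format(round(min_damping_spans * tau, 1)), " fs", call. = FALSE)
    }
  }
  if (is.null(energy_grid)) {
    energy_grid <- seq(min(verticals) - 1.5, max(verticals) + 1.5, by = 0.002)
  }
  e_zpe <- 0.5 * sum(model$modes$frequencies)

  contribs <- purrr::map(trajectories, function(tr) {
    tt <- tr$times
    damped <- tr$autocorrelation * exp(-(sigma * tt)^2 / (2 * hbar_ev_fs^2))
    # trapezoid weights on the (uniform or not) time grid
    w <- diff(c(tt[1], tt)) / 2 + c(diff(tt) / 2, 0)
    fourier_re(damped * w, tt, energy_grid + e_zpe)
  })
  raw <- purrr::map2(contribs, f_b, function(curve, f) f * curve)
  if (e_prefactor) raw <- purrr::map(raw, function(curve) curve * energy_grid)
  total <- Reduce(`+`, raw)
  if (normalize == "total_max") {
    peak <- max(total)
    if (peak <= 0) stop("total spectrum is non-positive on this grid", call. = FALSE)
    raw <- purrr::map(raw, function(curve) pmax(curve / peak, 0))
    total <- Reduce(`+`, raw)
    # clamping can only raise the total; rescale so the maximum is exactly 1
    raw <- purrr::map(raw, function(curve) curve / max(total))
    total <- total / max(total)
  }
  data <- tibble::as_tibble(stats::setNames(raw, make.unique(labels)))
  data <- dplyr::bind_cols(tibble::tibble(energy = energy_grid + shift), data)
  data$total <- total
  structure(
    list(data = data,
         metadata = list(hwhm = hwhm, sigma = sigma, shift = shift,
                         e_prefactor = e_prefactor, normalize = normalize,
                         zpe = e_zpe, oscillator_strengths = f_b,
                         initial_states = labels)),
    class = "lvc_spectrum"
  )
}

# Re sum_t x_t exp(i E t / hbar), chunked over the energy grid to bound the
# size of the phase matrix
fourier_re <- function(x, times, energies, chunk = 512) {
  out <- numeric(length(energies))
  for (start in seq(1, length(energies), by = chunk)) {
    idx <- start:min(start + chunk - 1, length(energies))
    phase <- exp(1i * outer(energies[idx], times) / hbar_ev_fs)
    out[idx] <- Re(phase %*% x)
  }
  out
}

#' @export
print.lvc_spectrum <- function(x, ...) {
  cat("<lvc_spectrum> ", nrow(x$data), " energies, contributions: ",
      paste(x$metadata$initial_states, collapse = ", "),
      " (hwhm ", x$metadata$hwhm, " eV)\n", sep = "")
  invisible(x)
}

#' Tidy a spectrum into long format
#'
#' @param x An `lvc_spectrum`.
#' @param ... Unused.
#' @return Tibble with `energy`, `component` (initial state or `"total"`),
#'   `intensity`.
#' @method tidy lvc_spectrum
#' @export
tidy.lvc_spectrum <- function(x, ...) {
  tidyr::pivot_longer(x$data, -"energy", names_to = "component",
                      values_to = "intensity")
}

#' @rdname tidy.lvc_spectrum
#' @method glance lvc_spectrum
#' @export
glance.lvc_spectrum <- function(x, ...) {
  tot <- x$data$total
  tibble::tibble(
    peak_energy = x$data$energy[which.max(tot)],
    peak_intensity = max(tot),
    hwhm = x$metadata$hwhm,
    shift = x$metadata$shift,
    n_contributions = length(x$metadata$initial_states)
  )
}
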