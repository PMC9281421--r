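# Unit conventions used throughout: energies and vibrational quanta in eV,
# dimensionless (frequency-weighted) normal-mode coordinates, time in fs.

#' Reduced Planck constant in eV fs
#'
#' The package works in eV / femtosecond / dimensionless-coordinate units;
#' `hbar_ev_fs` converts between energy and angular frequency.
#'
#' @format A length-one numeric, 0.6582119569 eV fs.
#' @export
hbar_ev_fs <- 0.6582119569
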