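#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot diabatic populations over time
#'
#' @param object An [propagate()] result.
#' @param states Optional subset of state labels to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lvc_propagation
#' @export
autoplot.lvc_propagation <- function(object, states = NULL, ...) {
  df <- diabatic_populations(object)
  if (!is.null(states)) df <- dplyr::filter(df, .data$state %in% states)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$population,
                                   colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (fs)", y = "diabatic population", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot diabatic potential-surface expectations over time
#'
#' @inheritParams autoplot.lvc_propagation
#' @param object An [propagate()] result.
#' @return A ggplot object.
#' @export
plot_pes_expectations <- function(object, states = NULL, ...) {
  df <- pes_expectations(object)
  if (!is.null(states)) df <- dplyr::filter(df, .data$state %in% states)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$pes_expectation,
                                   colour = .data$state)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (fs)", y = "diabatic PES expectation (eV)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an absorption spectrum with its per-state contributions
#'
#' @param object An [absorption_spectrum()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lvc_spectrum
#' @export
autoplot.lvc_spectrum <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$energy, y = .data$intensity,
                                   colour = .data$component,
                                   linetype = .data$component == "total")) +
    ggplot2::geom_line(show.legend = c(colour = TRUE, linetype = FALSE)) +
    ggplot2::labs(x = "energy (eV)", y = "intensity (normalized)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot reference weights of the adiabatic states at the reference geometry
#'
#' Bar chart of \eqn{W_m = \max_i S_{im}^2} from a parametrized model's
#' provenance; weights near 1 indicate adiabatic states that are well
#' represented by a single reference (diabatic) character.
#'
#' @param model An [lvc_model()] built by [build_lvc_model()].
#' @return A ggplot object.
#' @export
plot_reference_weights <- function(model) {
  w <- model$provenance$weights_fc
  if (is.null(w)) stop("model carries no reference weights (was it built by build_lvc_model()?)", call. = FALSE)
  df <- tibble::tibble(adiabatic_state = seq_along(w), weight = w)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$adiabatic_state, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "adiabatic state", y = expression(W[m])) +
    ggplot2::theme_minimal()
}
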