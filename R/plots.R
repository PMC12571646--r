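# ggplot2 views of the result types. Each takes the tidy result table
# produced by the corresponding analysis function.

#' Plot windowed PPII content traces
#'
#' One trace per chain (or per repeat, when given a pooled per-repeat
#' table).
#'
#' @param windowed Output of [ppii_windowed_content()] or
#'   [ppii_per_repeat()].
#' @return A ggplot.
#' @export
plot_ppii_timecourse <- function(windowed) {
  windowed <- as_tibble(windowed)
  colour_var <- if ("chain" %in% names(windowed)) "chain" else "segment"
  ggplot(windowed, aes(x = .data$time_ns, y = .data$fraction, colour = .data[[colour_var]])) +
    geom_line() +
    geom_point(size = 0.8) +
    facet_wrap(~segment) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(
      x = "time (ns)", y = "PPII fraction",
      title = "Windowed PPII helical content"
    ) +
    theme_minimal()
}

#' Plot the mean per-residue PPII population profile
#'
#' @param per_residue Output of [ppii_per_residue()].
#' @return A ggplot.
#' @export
plot_ppii_profile <- function(per_residue) {
  per_residue <- as_tibble(per_residue)
  ggplot(
    dplyr::filter(per_residue, !is.na(.data$mean_fraction)),
    aes(x = .data$residue_index, y = .data$mean_fraction)
  ) +
    geom_col(aes(fill = .data$chain), position = "dodge") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(
      x = "residue", y = "mean PPII population",
      title = "Per-residue PPII population (whole run)"
    ) +
    theme_minimal()
}

#' Plot far-UV CD spectra
#'
#' @param spectra CD spectrum tibble (several temperatures allowed).
#' @return A ggplot.
#' @export
plot_cd_spectra <- function(spectra) {
  spectra <- as_tibble(spectra)
  p <- ggplot(spectra, aes(x = .data$wavelength_nm, y = .data$mre))
  if ("temperature_C" %in% names(spectra)) {
    p <- p + geom_line(aes(colour = factor(.data$temperature_C))) +
      labs(colour = "T (C)")
  } else {
    p <- p + geom_line()
  }
  p +
    geom_hline(yintercept = 0, linetype = "dotted") +
    labs(
      x = "wavelength (nm)",
      y = expression("[" * theta * "] (deg cm"^2 * " dmol"^-1 * ")"),
      title = "Far-UV CD spectra"
    ) +
    theme_minimal()
}

#' @rdname fit_melt
#' @param object A `melt_fit`.
#' @export
autoplot.melt_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$temperature_C, y = .data$mre)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$slope, colour = "blue") +
    labs(
      x = "temperature (C)",
      y = expression("[" * theta * "] (deg cm"^2 * " dmol"^-1 * ")"),
      title = sprintf(
        "[theta] = %.4g %+.4g T(C),  R = %.3f",
        object$intercept, object$slope, object$r
      )
    ) +
    theme_minimal()
}

#' Plot secondary shifts and couplings with residue classes
#'
#' Bar plot of 13Ca secondary shifts coloured by assigned class, with the
#' coupling band overlaid on a secondary axis when couplings are present.
#'
#' @param classed Output of [classify_residues()].
#' @param criteria The [class_criteria()] used (drawn as guide lines).
#' @return A ggplot.
#' @export
plot_shift_classes <- function(classed, criteria = class_criteria()) {
  classed <- as_tibble(classed)
  ggplot(classed, aes(x = .data$residue_index, y = .data$dca_ppm, fill = .data$class)) +
    geom_col() +
    geom_hline(yintercept = c(criteria$dca_alpha_min, criteria$dca_beta_max), linetype = "dashed") +
    geom_hline(yintercept = c(-criteria$dca_coil_band, criteria$dca_coil_band), linetype = "dotted") +
    labs(
      x = "residue", y = expression(Delta * delta * " "^13 * "C" * alpha * " (ppm)"),
      title = "Secondary chemical shifts and residue classes"
    ) +
    theme_minimal()
}
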