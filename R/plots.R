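# autoplot() methods for the package's result types (ggplot2).

#' Plot a stress sweep
#'
#' Normalised per-gene expression versus stressor uptake rate, one panel
#' per expression layer.
#'
#' @param object A `stress_sweep` (normalised with [normalize_profiles()]
#'   first; raw fluxes are normalised on the fly otherwise).
#' @param genes Optional subset of genes to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stress_sweep <- function(object, genes = NULL, ...) {
  if (!"norm_transcription" %in% names(object$profiles)) {
    object <- normalize_profiles(object)
  }
  d <- object$profiles |>
    tidyr::pivot_longer(c("norm_transcription", "norm_translation"),
                        names_to = "layer", values_to = "fraction") |>
    mutate(layer = sub("norm_", "", .data$layer))
  if (!is.null(genes)) d <- d[d$gene %in% genes, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$rate, .data$fraction,
                                  colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~layer) +
    ggplot2::labs(x = sprintf("%s uptake rate (mmol/gDW/h)", object$metabolite),
                  y = "fraction of maximum flux") +
    ggplot2::theme_minimal()
}

#' Plot flux-sample principal components
#'
#' Scores of the first two principal components, coloured by condition.
#'
#' @param object An `me_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.me_pca <- function(object, ...) {
  v <- object$variance$variance_fraction
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$condition)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * v[1]),
                  y = sprintf("PC2 (%.0f%%)", 100 * v[2])) +
    ggplot2::theme_minimal()
}

#' Plot a flux comparison
#'
#' Paired log10 fluxes of two solutions with the identity line.
#'
#' @param object A `flux_comparison` from [compare_solutions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flux_comparison <- function(object, ...) {
  r2 <- attr(object, "r_squared")
  ggplot2::ggplot(object, ggplot2::aes(.data$log10_a, .data$log10_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "log10 flux (model A)", y = "log10 flux (model B)",
                  subtitle = sprintf("R² = %.3f", r2)) +
    ggplot2::theme_minimal()
}

#' Plot a kinetics fit
#'
#' Observed points and the fitted exponential (growth fits) or the product
#' accumulation curve (secretion fits).
#'
#' @param object A `kinetics_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetics_fit <- function(object, ...) {
  d <- object$data
  if (object$type == "growth") {
    ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$biomass)) +
      ggplot2::geom_point() +
      ggplot2::geom_function(
        fun = function(t) exp(object$intercept + object$mu * t),
        colour = "steelblue") +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "time (h)", y = "biomass (g/L)",
                    subtitle = sprintf("mu = %.3f 1/h, R² = %.3f",
                                       object$mu, object$r_squared)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$product)) +
      ggplot2::geom_point() +
      ggplot2::geom_line(alpha = 0.5) +
      ggplot2::labs(x = "time (h)", y = "product concentration",
                    subtitle = sprintf("nu = %.4g per gDW per h", object$nu)) +
      ggplot2::theme_minimal()
  }
}

#' Plot composition versus sensitivity
#'
#' Molar fraction against predicted sensitivity with the trimmed
#' regression line; outliers are flagged.
#'
#' @param object A `composition_sensitivity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.composition_sensitivity <- function(object, ...) {
  ft <- object$fit_trimmed
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$molar_fraction, .data$sensitivity)) +
    ggplot2::geom_abline(slope = ft$slope, intercept = ft$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$aa), vjust = -0.6, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "molar fraction in protein", y = "sensitivity",
                  subtitle = sprintf("trimmed fit: R² = %.2f, p = %.3g",
                                     ft$r_squared, ft$p_value)) +
    ggplot2::theme_minimal()
}
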