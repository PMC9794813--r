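# broom-style tidiers for the package's result objects.

#' Tidiers for model results
#'
#' [tidy()] returns the per-observation table of a result object (fluxes,
#' samples, loadings, fitted terms); [glance()] returns its one-row
#' summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name tidy_minime
NULL

#' @rdname tidy_minime
#' @export
tidy.kinetics_fit <- function(x, ...) {
  if (x$type == "growth") {
    tibble(term = c("mu", "intercept"),
           estimate = c(x$mu, x$intercept))
  } else {
    tibble(term = "nu", estimate = x$nu)
  }
}

#' @rdname tidy_minime
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble(mu = x$mu, nu = x$nu, r_squared = x$r_squared, n = x$n,
         window_lo = x$window[1], window_hi = x$window[2])
}

#' @rdname tidy_minime
#' @export
tidy.sample_set <- function(x, ...) {
  as_tibble(x$fluxes) |>
    mutate(sample = x$meta$sample, .before = 1) |>
    tidyr::pivot_longer(-"sample", names_to = "reaction", values_to = "flux") |>
    mutate(condition = x$condition)
}

#' @rdname tidy_minime
#' @export
glance.sample_set <- function(x, ...) {
  tibble(n = nrow(x$fluxes), reactions = ncol(x$fluxes),
         condition = x$condition, seed = x$seed)
}

#' @rdname tidy_minime
#' @export
tidy.me_pca <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"reaction", names_to = "component",
                      values_to = "loading")
}

#' @rdname tidy_minime
#' @export
glance.me_pca <- function(x, ...) {
  tibble(pc1_variance = x$variance$variance_fraction[1],
         pc2_variance = x$variance$variance_fraction[2],
         n = nrow(x$scores))
}

#' @rdname tidy_minime
#' @export
tidy.sensitivity_result <- function(x, ...) {
  tibble(term = c("x_bar_high", "x_bar_low", "r_high", "r_low", "sensitivity"),
         estimate = c(x$x_bar_high, x$x_bar_low, x$r_high, x$r_low,
                      x$sensitivity))
}

#' @rdname tidy_minime
#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble(sensitivity = x$sensitivity, p_value = x$p_value,
         n_high = x$n_high, n_low = x$n_low, reaction = x$reaction)
}

#' @rdname tidy_minime
#' @export
tidy.stress_sweep <- function(x, ...) {
  x$profiles
}

#' @rdname tidy_minime
#' @export
glance.stress_sweep <- function(x, ...) {
  tibble(metabolite = x$metabolite, n_rates = nrow(x$growth),
         n_feasible = sum(x$growth$feasible))
}

#' @rdname tidy_minime
#' @export
tidy.composition_sensitivity <- function(x, ...) x$data

#' @rdname tidy_minime
#' @export
glance.composition_sensitivity <- function(x, ...) {
  bind_rows(
    mutate(x$fit_all, fit = "all", .before = 1),
    mutate(x$fit_trimmed, fit = "trimmed", .before = 1)
  )
}
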