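# Protein-secretion analysis: batch-kinetics estimation, activity
# conversion, near-optimal and forced-overexpression flux sampling, PCA of
# flux samples, and amino-acid sensitivity of secretion.

#' Estimate growth rate from a biomass time course
#'
#' Fits the linearised exponential-growth model `log(X) = mu*t + k` by least
#' squares over the exponential window (natural logarithm, so `mu` is in
#' 1/h).
#'
#' @param tc Tibble with columns `time` (h) and `biomass` (g/L).
#' @param window Optional `c(t_min, t_max)` restricting the fit window.
#' @return A `kinetics_fit` with `mu`, `intercept`, `r_squared`.
#' @export
estimate_growth_rate <- function(tc, window = NULL) {
  d <- as_tibble(tc)
  if (!all(c("time", "biomass") %in% names(d))) {
    abort("time course needs `time` and `biomass` columns")
  }
  if (is.unsorted(d$time, strictly = TRUE)) abort("times must be strictly increasing")
  if (!is.null(window)) d <- d[d$time >= window[1] & d$time <= window[2], ]
  if (nrow(d) < 3) abort("need at least 3 points in the fit window")
  if (any(d$biomass <= 0)) abort("non-positive biomass in the fit window")
  fit <- lm(log(biomass) ~ time, data = d)
  structure(list(
    mu = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared, nu = NA_real_,
    window = range(d$time), n = nrow(d), data = d, type = "growth"
  ), class = "kinetics_fit")
}

#' Estimate secretion rate from product and biomass time courses
#'
#' Computes `nu = (C_f - C_0) / integral(X dt)` with trapezoidal quadrature
#' of the biomass curve over the shared time window; `nu` has the units of
#' product per biomass per hour.
#'
#' @param tc_biomass Tibble with `time`, `biomass`.
#' @param tc_product Tibble with `time`, `product` on the same time grid.
#' @return A `kinetics_fit` with `nu`.
#' @export
estimate_secretion_rate <- function(tc_biomass, tc_product) {
  X <- as_tibble(tc_biomass); C <- as_tibble(tc_product)
  if (!all(c("time", "biomass") %in% names(X)) ||
      !all(c("time", "product") %in% names(C))) {
    abort("need `time`+`biomass` and `time`+`product` columns")
  }
  if (nrow(X) != nrow(C) || max(abs(X$time - C$time)) > 1e-9) {
    abort("time grids are not aligned")
  }
  integral <- pracma::trapz(X$time, X$biomass)
  if (abs(integral) < 1e-12) abort("biomass integral is zero")
  nu <- (C$product[nrow(C)] - C$product[1]) / integral
  structure(list(
    mu = NA_real_, intercept = NA_real_, r_squared = NA_real_, nu = nu,
    window = range(X$time), n = nrow(X),
    data = mutate(X, product = C$product), type = "secretion"
  ), class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("<kinetics_fit>", x$type, "\n")
  if (x$type == "growth") {
    cat(sprintf("  mu = %.4f 1/h, intercept = %.4f, R^2 = %.4f (n = %d)\n",
                x$mu, x$intercept, x$r_squared, x$n))
  } else {
    cat(sprintf("  nu = %.6g per gDW per h over [%g, %g] h (n = %d)\n",
                x$nu, x$window[1], x$window[2], x$n))
  }
  invisible(x)
}

#' Convert enzyme activity to concentration
#'
#' Converts an activity `A` (mU/mL) to a mass-concentration range (mg/mL)
#' using a specific-activity range (U/mg): `C = (A/1000)/SA` at each range
#' endpoint; with a molecular weight (g/mol, e.g. from [peptide_mw()]) the
#' molar concentration (mmol/L) is added.
#'
#' @param activity Activity in mU/mL (non-negative).
#' @param specific_activity_range Two positive values, U/mg.
#' @param molecular_weight Optional protein molecular weight, g/mol.
#' @return Tibble with one row per specific-activity endpoint:
#'   `specific_activity`, `concentration_mg_ml`, and optionally
#'   `concentration_mmol_l`.
#' @export
activity_to_concentration <- function(activity, specific_activity_range = c(153.7, 245),
                                      molecular_weight = NULL) {
  stopifnot_scalar_number(activity, "activity", min = 0)
  if (any(specific_activity_range <= 0)) abort("specific activity must be positive")
  sa <- sort(specific_activity_range)
  out <- tibble(
    specific_activity = sa,
    concentration_mg_ml = (activity / 1000) / sa
  )
  if (!is.null(molecular_weight)) {
    out$concentration_mmol_l <- out$concentration_mg_ml / molecular_weight * 1000
  }
  out
}

#' Exchange-flux envelopes between two conditions
#'
#' For every exchange reaction, the interval spanned by the fluxes of two
#' condition solutions (e.g. low- and high-secretion solves) — the ranges
#' within which exchange bounds are randomised during sampling.
#'
#' @param model An `me_model`.
#' @param conditions List of two feasible `flux_solution`s.
#' @return Tibble with `reaction`, `lo`, `hi`.
#' @export
feasible_exchange_bounds <- function(model, conditions) {
  if (length(conditions) != 2 ||
      !all(vapply(conditions, function(s) s$status == "feasible", logical(1)))) {
    abort("`conditions` must be two feasible solutions")
  }
  ex <- exchange_reactions(model)
  va <- conditions[[1]]$fluxes[ex$reaction]
  vb <- conditions[[2]]$fluxes[ex$reaction]
  tibble(reaction = ex$reaction, lo = pmin(va, vb), hi = pmax(va, vb))
}

new_sample_set <- function(fluxes, meta, model, seed, condition) {
  structure(list(
    fluxes = fluxes, meta = meta,
    reactions = model$reactions[, c("id", "base_id", "rtype", "subsystem")],
    seed = seed, condition = condition
  ), class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples x %d reactions (%s, seed %d)\n",
              nrow(x$fluxes), ncol(x$fluxes), x$condition, x$seed))
  invisible(x)
}

#' Sample the near-optimal solution space
#'
#' Draws `n` feasible flux vectors with growth between `growth_frac` and
#' 100% of the optimal growth rate: for each sample a growth rate is drawn
#' uniformly in that range, and exchange bounds are set to uniform draws
#' within the envelopes spanned by the optimal and `growth_frac`-optimal
#' solutions. Infeasible draws are retried up to `max_retries` per sample.
#'
#' @param model An `me_model` that grows.
#' @param growth_frac Lower growth fraction (0 < frac <= 1), default 0.9.
#' @param n Number of samples, default 100.
#' @param seed Integer seed; identical seeds give identical sample sets.
#' @param max_retries Retry budget per sample.
#' @return A `sample_set` (matrix of `n` flux vectors with metadata).
#' @export
sample_solution_space <- function(model, growth_frac = 0.9, n = 100, seed = 1,
                                  max_retries = 25) {
  if (growth_frac <= 0 || growth_frac > 1) abort("growth_frac must be in (0, 1]")
  gr <- maximize_growth(model)
  mu_hi <- gr$mu_star
  mu_lo <- growth_frac * mu_hi
  sol_lo <- solve_at_mu(model, mu_lo)
  env <- feasible_exchange_bounds(model, list(sol_lo, gr$solution))
  env <- env[env$hi - env$lo > 1e-9, ]
  with_local_seed(seed, {
    fluxes <- matrix(NA_real_, n, nrow(model$reactions),
                     dimnames = list(NULL, model$reactions$id))
    mus <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        mu_i <- stats::runif(1, mu_lo, mu_hi)
        ms <- model
        for (k in seq_len(nrow(env))) {
          ms <- set_bounds(ms, env$reaction[k],
                           lower = stats::runif(1, env$lo[k], env$hi[k]))
        }
        sol <- solve_at_mu(ms, mu_i)
        if (sol$status == "feasible") {
          fluxes[i, ] <- sol$fluxes
          mus[i] <- mu_i
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort(sprintf(
          "sampling failed after %d retries; binding exchanges: %s",
          max_retries, paste(env$reaction, collapse = ", ")))
      }
    }
    new_sample_set(fluxes, tibble(sample = seq_len(n), mu = mus),
                   model, seed, sprintf("near-optimal (>=%d%%)",
                                        round(100 * growth_frac)))
  })
}

#' Sample forced overexpression of a secreted protein
#'
#' Fixes the growth rate and forces the secretion flux to uniform draws in
#' `[secretion_lo, secretion_hi]`, collecting the resulting flux vectors —
#' the in-silico overexpression experiment that isolates the effect of
#' secretion from growth.
#'
#' @param model An `me_model`.
#' @param mu_fixed Fixed growth rate (1/h).
#' @param secretion_lo,secretion_hi Secretion flux range, mmol/gDW/h.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param secretion_reaction Reaction id carrying the secretion flux
#'   (defaults to the translocation reaction of the spec's reporter gene).
#' @return A `sample_set`.
#' @export
sample_overexpression <- function(model, mu_fixed, secretion_lo, secretion_hi,
                                  n = 100, seed = 1,
                                  secretion_reaction = NULL) {
  secretion_reaction <- secretion_reaction %||%
    paste0("TLOC_", model$spec$motifs$reporter_gene)
  if (secretion_hi < secretion_lo) abort("secretion_hi must be >= secretion_lo")
  base <- set_bounds(model, secretion_reaction,
                     lower = secretion_lo, upper = secretion_lo)
  if (solve_at_mu(base, mu_fixed)$status != "feasible") {
    abort("model infeasible at mu_fixed with secretion_lo")
  }
  hi_test <- set_bounds(model, secretion_reaction,
                        lower = secretion_hi, upper = secretion_hi)
  if (solve_at_mu(hi_test, mu_fixed)$status != "feasible") {
    max_sec <- maximize_flux(model, mu_fixed, secretion_reaction, "max")
    abort(sprintf(
      "infeasible at secretion_hi = %g; maximum feasible secretion is about %g",
      secretion_hi, max_sec))
  }
  with_local_seed(seed, {
    fluxes <- matrix(NA_real_, n, nrow(model$reactions),
                     dimnames = list(NULL, model$reactions$id))
    rs <- stats::runif(n, secretion_lo, secretion_hi)
    for (i in seq_len(n)) {
      ms <- set_bounds(model, secretion_reaction, lower = rs[i], upper = rs[i])
      sol <- solve_at_mu(ms, mu_fixed)
      if (sol$status != "feasible") {
        abort(sprintf("infeasible at forced secretion %g", rs[i]))
      }
      fluxes[i, ] <- sol$fluxes
    }
    new_sample_set(fluxes, tibble(sample = seq_len(n), mu = mu_fixed,
                                  secretion = rs),
                   model, seed, "forced overexpression")
  })
}

#' Principal component analysis of flux samples
#'
#' Drops constant-flux reactions, z-scores the rest, and runs PCA. Reports
#' orthonormal loadings, variance-explained fractions, and
#' subsystem-averaged absolute loadings for the first two components.
#'
#' @param samples A `sample_set` or a list of them (conditions are pooled
#'   and labelled).
#' @return An `me_pca`: list with `scores`, `loadings`, `variance`,
#'   `subsystem_loadings`, and the underlying `prcomp` object.
#' @export
pca_fluxes <- function(samples) {
  if (inherits(samples, "sample_set")) samples <- list(samples)
  X <- do.call(rbind, lapply(samples, function(s) s$fluxes))
  condition <- unlist(lapply(samples, function(s) rep(s$condition, nrow(s$fluxes))))
  if (nrow(X) < 3) abort("need at least 3 samples")
  keep <- apply(X, 2, sd) > 1e-12
  if (sum(keep) < 2) abort("fewer than 2 non-constant reactions; PCA undefined")
  Z <- scale(X[, keep, drop = FALSE])
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  loadings <- as_tibble(pc$rotation[, seq_len(min(5, ncol(pc$rotation))), drop = FALSE],
                        rownames = "reaction")
  rx <- samples[[1]]$reactions
  sub_load <- loadings |>
    left_join(rx, by = c(reaction = "id")) |>
    group_by(.data$subsystem) |>
    summarise(across(dplyr::starts_with("PC"), ~ mean(abs(.x))), .groups = "drop")
  structure(list(
    scores = bind_cols(tibble(condition = condition),
                       as_tibble(pc$x[, 1:min(5, ncol(pc$x)), drop = FALSE])),
    loadings = loadings,
    variance = tibble(component = paste0("PC", seq_along(var_frac)),
                      variance_fraction = var_frac),
    subsystem_loadings = sub_load,
    prcomp = pc
  ), class = "me_pca")
}

#' @export
print.me_pca <- function(x, ...) {
  v <- x$variance$variance_fraction
  cat(sprintf("<me_pca> %d samples, %d reactions; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), nrow(x$loadings), 100 * v[1], 100 * v[2]))
  invisible(x)
}

#' Amino-acid sensitivity of secretion
#'
#' The ratio of the change in a synthesis flux to the change in secretion
#' rate between two sampled conditions:
#' `(x_bar_high - x_bar_low) / (r_high - r_low)`, in mmol amino acid per
#' mmol secreted protein. Outliers are removed from each synthesis-flux
#' distribution (beyond mean +/- z_crit*SD, one pass) before the means are
#' taken; a two-sided two-sample t test assesses the separation.
#'
#' @param set_low,set_high `sample_set`s at the low/high secretion
#'   condition.
#' @param synthesis_reaction Base id of the synthesis reaction.
#' @param r_low,r_high Secretion rates of the two conditions (must differ);
#'   defaults to the mean forced secretion recorded in each set.
#' @param conf Confidence level for outlier exclusion (default 95%).
#' @return A `sensitivity_result`.
#' @export
sensitivity <- function(set_low, set_high, synthesis_reaction,
                        r_low = NULL, r_high = NULL, conf = 0.95) {
  xs <- function(s) {
    idx <- which(s$reactions$base_id == synthesis_reaction)
    if (length(idx) == 0) abort(sprintf("unknown reaction '%s'", synthesis_reaction))
    rowSums(s$fluxes[, idx, drop = FALSE])
  }
  r_low <- r_low %||% mean(set_low$meta$secretion)
  r_high <- r_high %||% mean(set_high$meta$secretion)
  if (!is.finite(r_low) || !is.finite(r_high) || r_high == r_low) {
    abort("secretion rates of the two conditions must be distinct")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  trim <- function(x) {
    if (sd(x) == 0) return(x)
    x[abs(x - mean(x)) <= z * sd(x)]
  }
  xl <- trim(xs(set_low)); xh <- trim(xs(set_high))
  if (length(xl) == 0 || length(xh) == 0) abort("outlier filtering removed all samples")
  p <- if (sd(xl) == 0 && sd(xh) == 0) {
    if (isTRUE(all.equal(mean(xl), mean(xh)))) 1 else 0
  } else {
    t.test(xh, xl)$p.value
  }
  structure(list(
    x_bar_high = mean(xh), x_bar_low = mean(xl),
    r_high = r_high, r_low = r_low,
    sensitivity = (mean(xh) - mean(xl)) / (r_high - r_low),
    p_value = p, n_high = length(xh), n_low = length(xl),
    reaction = synthesis_reaction
  ), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %s: %.4g mmol per mmol secreted (p = %.3g)\n",
              x$reaction, x$sensitivity, x$p_value))
  invisible(x)
}

#' Regress amino-acid sensitivity on protein composition
#'
#' Computes the molar fraction of each amino acid in the protein sequence
#' and regresses predicted sensitivities on those fractions, with and
#' without outliers (points whose externally studentised residual exceeds
#' the 95% critical value are excluded and the model refit).
#'
#' @param protein_sequence One-letter amino-acid string of the protein.
#' @param sensitivities Named numeric vector (one-letter codes) of
#'   predicted sensitivities; needs at least 3 amino acids.
#' @return A `composition_sensitivity` list: `data` (aa, molar_fraction,
#'   sensitivity, outlier), `fit_all` and `fit_trimmed` (r_squared,
#'   p_value, slope, intercept, n).
#' @export
composition_vs_sensitivity <- function(protein_sequence, sensitivities) {
  if (length(sensitivities) < 3) abort("need sensitivities for at least 3 amino acids")
  counts <- aa_counts(protein_sequence)
  frac <- counts / sum(counts)
  aa <- names(sensitivities)
  d <- tibble(
    aa = aa,
    molar_fraction = as.numeric(frac[aa]),
    sensitivity = as.numeric(sensitivities)
  )
  d$molar_fraction[is.na(d$molar_fraction)] <- 0
  if (sd(d$molar_fraction) < 1e-12) abort("degenerate composition variance")
  summarize_fit <- function(fit, n) {
    s <- summary(fit)
    tibble(r_squared = s$r.squared,
           p_value = s$coefficients[2, 4],
           slope = coef(fit)[[2]], intercept = coef(fit)[[1]], n = n)
  }
  fit0 <- lm(sensitivity ~ molar_fraction, data = d)
  # externally studentised residuals at the 95% level; an exact fit has no
  # outliers by definition
  rs <- suppressWarnings(stats::rstudent(fit0))
  res <- stats::residuals(fit0)
  crit <- stats::qt(0.975, df = max(nrow(d) - 3, 1))
  # a non-finite studentised residual with a real raw residual means the
  # remaining points fit perfectly without this one - the clearest outlier
  d$outlier <- (is.finite(rs) & abs(rs) > crit) |
    (!is.finite(rs) & abs(res) > 1e-8)
  if (summary(fit0)$sigma < 1e-12) d$outlier <- rep(FALSE, nrow(d))
  trimmed <- d[!d$outlier, ]
  fit1 <- if (nrow(trimmed) >= 3 && sd(trimmed$molar_fraction) > 1e-12) {
    lm(sensitivity ~ molar_fraction, data = trimmed)
  } else fit0
  structure(list(
    data = d,
    fit_all = summarize_fit(fit0, nrow(d)),
    fit_trimmed = summarize_fit(fit1, nrow(trimmed)),
    models = list(all = fit0, trimmed = fit1)
  ), class = "composition_sensitivity")
}
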