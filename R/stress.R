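# Stress simulation: uncoupled stressor influx (ethanol diffusion, sodium
# under salt stress), folate damage, expression profiling, amino-acid demand
# attribution and differential-expression scoring.

#' Simulate uncoupled uptake of a stressor
#'
#' Forces the stressor's exchange to exactly the given influx rate (lower
#' and upper bound at `-rate`) with no transporter-expression coupling —
#' influx happens by diffusion or leak reactions that carry no enzyme
#' coupling — while any export remains coupled to the synthesis of its
#' transporter. All other exchanges are unchanged. The stressed model is
#' solved to optimal growth.
#'
#' @param model An `me_model`.
#' @param metabolite_id Extracellular stressor metabolite id.
#' @param rate Forced influx rate, mmol/gDW/h (non-negative).
#' @return List with `growth` (a `growth_result`), `solution` (the flux
#'   solution at optimal growth) and `model` (the stressed model).
#' @export
simulate_uncoupled_uptake <- function(model, metabolite_id, rate) {
  stopifnot_scalar_number(rate, "rate", min = 0)
  ex <- exchange_of(model, metabolite_id)
  ms <- set_bounds(model, ex, lower = -rate, upper = if (rate > 0) -rate else NULL)
  gr <- tryCatch(maximize_growth(ms), error = function(e) {
    abort(sprintf(
      "stress-infeasible: no growth possible at %s influx %g (limiting bracket [0, %g])",
      metabolite_id, rate, rate), class = "minime_stress_infeasible")
  })
  list(growth = gr, solution = gr$solution, model = ms)
}

#' Sweep a stressor over a series of uptake rates
#'
#' Runs [simulate_uncoupled_uptake()] at each rate, recording per-gene
#' transcription/translation fluxes and any tracked reaction fluxes
#' (summed over coupled copies by base id). Per-rate infeasibilities are
#' recorded and the sweep continues.
#'
#' @param model An `me_model`.
#' @param metabolite_id Stressor metabolite id.
#' @param rates Strictly increasing uptake rates.
#' @param tracked Character vector of base reaction ids whose net flux is
#'   recorded per rate.
#' @return A `stress_sweep`: list with `profiles` (long tibble: rate, gene,
#'   transcription, translation), `tracked` (tibble: rate, reaction, flux),
#'   `growth` (tibble: rate, mu_star, feasible), `metabolite`.
#' @export
sweep_stressor <- function(model, metabolite_id, rates, tracked = character()) {
  if (is.unsorted(rates, strictly = TRUE)) {
    abort("`rates` must be strictly increasing")
  }
  profiles <- list(); trk <- list(); growth <- list()
  for (r in rates) {
    sim <- tryCatch(simulate_uncoupled_uptake(model, metabolite_id, r),
                    error = function(e) e)
    if (inherits(sim, "error")) {
      growth[[length(growth) + 1]] <- tibble(rate = r, mu_star = NA_real_,
                                             feasible = FALSE)
      next
    }
    growth[[length(growth) + 1]] <- tibble(rate = r, mu_star = sim$growth$mu_star,
                                           feasible = TRUE)
    profiles[[length(profiles) + 1]] <-
      expression_fluxes(sim$model, sim$solution) |> mutate(rate = r)
    for (id in tracked) {
      trk[[length(trk) + 1]] <- tibble(
        rate = r, reaction = id,
        flux = flux_through(sim$model, sim$solution, id)
      )
    }
  }
  structure(list(
    profiles = if (length(profiles)) bind_rows(profiles) else
      tibble(gene = character(), transcription = numeric(),
             translation = numeric(), rate = numeric()),
    tracked = if (length(trk)) bind_rows(trk) else
      tibble(rate = numeric(), reaction = character(), flux = numeric()),
    growth = bind_rows(growth),
    metabolite = metabolite_id
  ), class = "stress_sweep")
}

#' Simulate folate damage
#'
#' Adds a forced demand consuming the folate analog at exactly
#' `damage_rate` and solves to optimal growth; at steady state the folate
#' synthesis pathway must increase its flux by exactly the damage rate.
#'
#' @param model An `me_model` containing the folate species.
#' @param damage_rate Damage drain, mmol/gDW/h.
#' @param folate_species Folate species id.
#' @return List with `growth`, `solution`, `model` (as
#'   [simulate_uncoupled_uptake()]).
#' @export
simulate_folate_damage <- function(model, damage_rate,
                                   folate_species = "fol_c") {
  stopifnot_scalar_number(damage_rate, "damage_rate", min = 0)
  ms <- add_demand_reaction(model, folate_species, id = "DM_folate_damage",
                            lower = damage_rate, upper = damage_rate)
  gr <- tryCatch(maximize_growth(ms), error = function(e) {
    abort(sprintf(
      "folate damage %g exceeds the maximum sustainable rate (bracket [0, %g])",
      damage_rate, damage_rate), class = "minime_stress_infeasible")
  })
  list(growth = gr, solution = gr$solution, model = ms)
}

#' Normalise expression profiles across a sweep
#'
#' Divides each gene's transcription and translation series by its maximum
#' across the sweep, so profiles are comparable fractions of the maximal
#' value in the dataset; all-zero series stay zero.
#'
#' @param sweep A `stress_sweep`.
#' @return The sweep with `norm_transcription` and `norm_translation`
#'   columns added to `$profiles`.
#' @export
normalize_profiles <- function(sweep) {
  if (nrow(sweep$profiles) == 0) abort("empty sweep")
  norm0 <- function(x) {
    m <- max(x)
    if (m <= 0) rep(0, length(x)) else x / m
  }
  sweep$profiles <- sweep$profiles |>
    group_by(.data$gene) |>
    mutate(norm_transcription = norm0(.data$transcription),
           norm_translation = norm0(.data$translation)) |>
    ungroup()
  sweep
}

#' Attribute an amino-acid demand change to proteins
#'
#' Between a baseline and a stressed solution, attributes the change in one
#' amino acid's total synthesis flux to individual proteins: each protein's
#' contribution is the change in (translation flux times the count of the
#' amino acid in its mature product), divided by the change in total
#' synthesis. Expression-machinery proteins appear as their own rows. When
#' the amino acid's only sinks are tRNA charging and translation the
#' fractions sum to one exactly.
#'
#' @param model An `me_model`.
#' @param sol_base,sol_stress Feasible flux solutions from the same model
#'   structure.
#' @param amino_acid One-letter code.
#' @return An `attribution_table` tibble: `gene`, `aa_count`,
#'   `delta_demand`, `fraction`, sorted by decreasing fraction.
#' @export
attribute_amino_acid_demand <- function(model, sol_base, sol_stress, amino_acid) {
  spec <- model$spec
  if (!amino_acid %in% spec$amino_acids) {
    abort(sprintf("amino acid '%s' is not modeled", amino_acid))
  }
  aa_row <- aa_species(amino_acid)
  production <- function(sol) {
    col <- model$S0[aa_row, ]
    sum(pmax(col, 0) * sol$fluxes)
  }
  d_total <- production(sol_stress) - production(sol_base)
  if (abs(d_total) < 1e-15) {
    abort("total amino-acid synthesis change is zero; attribution undefined",
          class = "minime_undefined")
  }
  prot <- spec$genes$id[spec$genes$product_kind == "protein"]
  rows <- lapply(prot, function(g) {
    cnt <- gene_composition(spec, g)[[amino_acid]]
    tl <- paste0("TL_", g)
    dd <- (sol_stress$fluxes[[tl]] - sol_base$fluxes[[tl]]) * cnt
    tibble(gene = g, aa_count = cnt, delta_demand = dd)
  })
  out <- bind_rows(rows) |>
    mutate(fraction = .data$delta_demand / d_total) |>
    arrange(desc(.data$fraction))
  attr(out, "delta_total") <- d_total
  class(out) <- c("attribution_table", class(out))
  out
}

#' Differential-expression calls between two conditions
#'
#' Calls a gene up- or down-regulated when the relative change of its
#' expression flux exceeds `epsilon`, and unchanged otherwise. A gene with
#' zero baseline flux is called up if its stressed flux is positive.
#'
#' @param profile_base,profile_stress Per-gene expression tibbles (as from
#'   [expression_fluxes()] via a sweep's `$profiles`), sharing a gene set.
#' @param epsilon Relative-change threshold (default 5%).
#' @param layer `"transcription"` or `"translation"`.
#' @return A tibble: `gene`, `base`, `stress`, `rel_change`, `call`.
#' @export
differential_expression_calls <- function(profile_base, profile_stress,
                                          epsilon = 0.05,
                                          layer = c("transcription", "translation")) {
  layer <- match.arg(layer)
  shared <- intersect(profile_base$gene, profile_stress$gene)
  if (length(shared) == 0) abort("no shared genes")
  b <- setNames(profile_base[[layer]], profile_base$gene)[shared]
  s <- setNames(profile_stress[[layer]], profile_stress$gene)[shared]
  rel <- ifelse(b > 0, (s - b) / b, ifelse(s > 0, Inf, 0))
  tibble(
    gene = shared, base = unname(b), stress = unname(s),
    rel_change = unname(rel),
    call = dplyr::case_when(rel > epsilon ~ "up",
                            rel < -epsilon ~ "down",
                            TRUE ~ "unchanged")
  )
}

#' Score differential-expression calls against a reference
#'
#' Accuracy is the fraction of reference-differentially-expressed genes
#' whose direction is reproduced, reported overall, by direction, and by
#' subsystem when the reference provides one.
#'
#' @param calls Output of [differential_expression_calls()].
#' @param reference Tibble with `gene`, `call` (up/down/unchanged) and
#'   optionally `subsystem`.
#' @return List of tibbles: `overall`, `by_direction`, `by_subsystem`
#'   (NULL without subsystem labels).
#' @export
score_de <- function(calls, reference) {
  joined <- inner_join(calls, reference, by = "gene",
                       suffix = c("_pred", "_ref"))
  changed <- joined |> filter(.data$call_ref %in% c("up", "down"))
  if (nrow(changed) == 0) abort("reference contains no differentially expressed genes")
  acc <- function(d) tibble(n = nrow(d),
                            accuracy = mean(d$call_pred == d$call_ref))
  overall <- acc(changed)
  by_dir <- changed |> group_by(direction = .data$call_ref) |>
    summarise(n = dplyr::n(),
              accuracy = mean(.data$call_pred == .data$call_ref),
              .groups = "drop")
  by_sub <- NULL
  if ("subsystem" %in% names(reference)) {
    by_sub <- changed |> group_by(.data$subsystem) |>
      summarise(n = dplyr::n(),
                accuracy = mean(.data$call_pred == .data$call_ref),
                .groups = "drop")
  }
  list(overall = overall, by_direction = by_dir, by_subsystem = by_sub)
}
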