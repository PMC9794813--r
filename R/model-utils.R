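# Small model-editing and flux-accounting helpers shared by the screening,
# stress and secretion modules.

#' Set flux bounds on a model reaction
#'
#' Sets constant bounds (the mu-dependent part is cleared) on one reaction,
#' identified by exact id or by base id (in which case all split/coupled
#' members are updated; the lower bound is then applied to the first member
#' only, which matters for forced exchanges).
#'
#' @param model An `me_model`.
#' @param reaction Reaction id (exact or base id).
#' @param lower,upper New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction, lower = NULL, upper = NULL) {
  idx <- which(model$reactions$id == reaction)
  if (length(idx) == 0) idx <- which(model$reactions$base_id == reaction)
  if (length(idx) == 0) abort(sprintf("unknown reaction '%s'", reaction))
  if (!is.null(lower)) {
    model$reactions$lb_const[idx] <- lower
    model$reactions$lb_mu[idx] <- 0
  }
  if (!is.null(upper)) {
    model$reactions$ub_const[idx] <- upper
    model$reactions$ub_mu[idx] <- 0
  }
  model
}

#' Exchange reactions of a model
#'
#' @param model An `me_model`.
#' @param carbon_only Keep only exchanges of carbon-containing metabolites.
#' @return Tibble with `reaction`, `metabolite`, `lower`, `upper`.
#' @export
exchange_reactions <- function(model, carbon_only = FALSE) {
  ex <- model$reactions[model$reactions$rtype == "exchange", ]
  met <- vapply(ex$id, function(id) {
    col <- model$S0[, id]
    rownames(model$S0)[which(col != 0)][1]
  }, character(1))
  out <- tibble(reaction = ex$id, metabolite = unname(met),
                lower = ex$lb_const, upper = ex$ub_const)
  if (carbon_only) {
    fo <- parse_formulas(model$spec$metabolites)
    has_c <- vapply(out$metabolite, function(m) {
      f <- fo[[m]]
      !is.null(f) && !is.na(f["C"]) && f["C"] > 0
    }, logical(1))
    out <- out[has_c, ]
  }
  out
}

# exchange reaction id for a metabolite id
exchange_of <- function(model, metabolite_id) {
  ex <- exchange_reactions(model)
  id <- ex$reaction[ex$metabolite == metabolite_id]
  if (length(id) != 1) {
    abort(sprintf("metabolite '%s' has no (unique) exchange reaction", metabolite_id))
  }
  id
}

#' Total flux through a base reaction
#'
#' Sums the fluxes of every member (split directions, per-enzyme copies) of
#' a base reaction id in a flux solution.
#'
#' @param model An `me_model`.
#' @param solution A feasible `flux_solution`.
#' @param base_id Base reaction id (e.g. a core-reaction id).
#' @param net Subtract reverse-direction members (net flux) instead of
#'   summing magnitudes.
#' @return Numeric flux.
#' @export
flux_through <- function(model, solution, base_id, net = TRUE) {
  if (solution$status != "feasible") abort("solution is not feasible")
  idx <- which(model$reactions$base_id == base_id)
  if (length(idx) == 0) abort(sprintf("unknown base reaction '%s'", base_id))
  v <- solution$fluxes[idx]
  if (net) {
    sign <- ifelse(grepl("_REV(_|$)", model$reactions$id[idx]), -1, 1)
    sum(v * sign)
  } else {
    sum(v)
  }
}

#' Add a demand reaction to a model
#'
#' Appends a reaction consuming one unit of `species` per unit flux, with
#' constant bounds. Used e.g. to impose a folate-damage drain.
#'
#' @param model An `me_model`.
#' @param species Species id to consume.
#' @param id Reaction id; default `DM_<species>_forced`.
#' @param lower,upper Flux bounds.
#' @return The modified model.
#' @export
add_demand_reaction <- function(model, species, id = NULL, lower = 0, upper = 0) {
  id <- id %||% paste0("DM_", species, "_forced")
  if (id %in% model$reactions$id) abort(sprintf("reaction '%s' already exists", id))
  if (!species %in% rownames(model$S0)) abort(sprintf("unknown species '%s'", species))
  newcol <- matrix(0, nrow(model$S0), 1, dimnames = list(rownames(model$S0), id))
  newcol[species, 1] <- -1
  model$S0 <- cbind(model$S0, newcol)
  model$S1 <- cbind(model$S1, 0 * newcol)
  model$coupling_const <- cbind(model$coupling_const, 0 * newcol)
  model$coupling_mu <- cbind(model$coupling_mu, 0 * newcol)
  model$reactions <- bind_rows(model$reactions, tibble(
    id = id, base_id = id, rtype = "demand", subsystem = "forced_demand",
    gene_id = NA_character_, complex_id = NA_character_,
    lb_const = lower, lb_mu = 0, ub_const = upper, ub_mu = 0
  ))
  model
}

# per-gene expression fluxes (transcription summed over containing TUs,
# translation) from a solved model
expression_fluxes <- function(model, solution) {
  prot <- model$spec$genes$id[model$spec$genes$product_kind == "protein"]
  tus <- model$spec$transcription_units
  tx_of <- setNames(rep(0, length(prot)), prot)
  for (i in seq_len(nrow(tus))) {
    fx <- solution$fluxes[[paste0("TX_", tus$id[i])]]
    for (g in intersect(tus$gene_ids[[i]], prot)) tx_of[g] <- tx_of[g] + fx
  }
  tl_of <- vapply(prot, function(g) solution$fluxes[[paste0("TL_", g)]], numeric(1))
  tibble(gene = prot, transcription = unname(tx_of), translation = unname(tl_of))
}
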