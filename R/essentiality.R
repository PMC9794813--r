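# Gene-essentiality and carbon-substrate screening with confusion-matrix
# scoring.

#' Genome-wide single-knockout essentiality screen
#'
#' Knocks out each gene in turn (closing its translation reaction) and calls
#' it essential when the knockout cannot grow: maximum growth below
#' `threshold`. By monotonicity of feasibility in the growth rate this is
#' equivalent to LP infeasibility at `mu = threshold`, which is what the
#' default fast mode tests with a single LP per gene; `mode = "full"` runs
#' the complete bisection per knockout and reports `mu_star`.
#'
#' @param model An `me_model` whose wild type grows.
#' @param gene_ids Genes to screen; defaults to all protein-coding genes.
#' @param threshold Zero-growth threshold (1/h); default ten times the
#'   default bisection tolerance.
#' @param mode `"feasibility"` (one LP per gene) or `"full"` (bisection).
#' @return A tibble with `gene`, `essential` (logical), `call`, and (in
#'   full mode) `mu_star`.
#' @export
essentiality_screen <- function(model, gene_ids = NULL,
                                threshold = 1e-5,
                                mode = c("feasibility", "full")) {
  mode <- match.arg(mode)
  gene_ids <- gene_ids %||%
    model$spec$genes$id[model$spec$genes$product_kind == "protein"]
  wt <- solve_at_mu(model, threshold)
  if (wt$status != "feasible") {
    abort("wild-type model does not grow at the zero-growth threshold")
  }
  rows <- lapply(gene_ids, function(g) {
    km <- knockout_gene(model, g)
    if (mode == "feasibility") {
      ess <- solve_at_mu(km, threshold)$status != "feasible"
      tibble(gene = g, essential = ess, mu_star = NA_real_)
    } else {
      mu <- tryCatch(maximize_growth(km)$mu_star, error = function(e) 0)
      tibble(gene = g, essential = mu < threshold, mu_star = mu)
    }
  })
  out <- bind_rows(rows) |>
    mutate(call = ifelse(.data$essential, "essential", "non_essential"))
  if (mode == "feasibility") out$mu_star <- NULL
  out
}

#' Double-knockout growth
#'
#' Utility for redundancy analysis: closes two translation reactions and
#' returns the maximum growth rate.
#'
#' @param model An `me_model`.
#' @param gene_a,gene_b Protein-coding gene ids.
#' @return Maximum growth rate (1/h) of the double knockout.
#' @export
double_knockout <- function(model, gene_a, gene_b) {
  km <- knockout_gene(knockout_gene(model, gene_a), gene_b)
  tryCatch(maximize_growth(km)$mu_star, error = function(e) 0)
}

#' Score binary predictions against a truth set
#'
#' Builds the confusion matrix over the shared keys and computes the
#' standard scores: true positive rate TP/(TP+FN), true negative rate
#' TN/(TN+FP), false discovery rate FP/(FP+TP), precision TP/(TP+FP), the
#' Matthews correlation coefficient with the conventional square-rooted
#' denominator, and (when `database_size` is given) coverage, the fraction
#' of database genes represented in the model. Zero denominators yield `NA`
#' (undefined), never 0.
#'
#' @param pred,truth Named logical vectors (`TRUE` = positive/essential),
#'   or two-column data frames (id, call) where the call is logical or the
#'   strings `"essential"`/`"non_essential"`.
#' @param database_size Total genes in the reference database (for
#'   coverage); the numerator is the number of scored genes unless
#'   `model_genes` is given.
#' @param model_genes Optional numerator for coverage.
#' @return List with `confusion` (tibble: TP, FP, TN, FN) and `scores`
#'   (tibble: TPR, TNR, FDR, MCC, Precision, Coverage).
#' @export
score_predictions <- function(pred, truth, database_size = NULL,
                              model_genes = NULL) {
  pred <- as_call_vector(pred)
  truth <- as_call_vector(truth)
  if (!setequal(names(pred), names(truth))) {
    abort("prediction and truth must cover the same gene set")
  }
  truth <- truth[names(pred)]
  TP <- sum(pred & truth); FP <- sum(pred & !truth)
  TN <- sum(!pred & !truth); FN <- sum(!pred & truth)
  if (TP + FP + TN + FN == 0) abort("empty prediction set")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  scores <- tibble(
    TPR = div(TP, TP + FN),
    TNR = div(TN, TN + FP),
    FDR = div(FP, FP + TP),
    MCC = if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den,
    Precision = div(TP, TP + FP),
    Coverage = if (is.null(database_size)) NA_real_ else
      (model_genes %||% length(pred)) / database_size
  )
  list(confusion = tibble(TP = TP, FP = FP, TN = TN, FN = FN), scores = scores)
}

as_call_vector <- function(x) {
  if (is.data.frame(x)) {
    keys <- x[[1]]
    val <- x[[if ("essential" %in% names(x)) "essential" else 2]]
    x <- setNames(val, keys)
  }
  nm <- names(x)
  if (is.character(x)) x <- x %in% c("essential", "TRUE", "yes", "growth")
  x <- as.logical(x)
  names(x) <- nm %||% as.character(seq_along(x))
  x
}

#' Carbon-substrate growth screen
#'
#' For each substrate: closes the uptake of every carbon-containing
#' exchange metabolite, opens the substrate's exchange at `uptake_rate`,
#' and calls growth when the maximum growth rate exceeds `threshold`.
#' Substrates without an exchange reaction produce a per-row error record
#' and the screen continues. When a reference call set is supplied the
#' screen is scored with [score_predictions()].
#'
#' @param model An `me_model`.
#' @param substrates Metabolite ids (extracellular).
#' @param uptake_rate Uptake bound magnitude, mmol/gDW/h.
#' @param threshold Zero-growth threshold (1/h).
#' @param reference Optional named logical vector of reference growth calls.
#' @return A tibble with `substrate`, `growth`, `mu_star`, `error`; when a
#'   reference is given, the score list is attached as attribute
#'   `"scores"`.
#' @export
carbon_screen <- function(model, substrates, uptake_rate = 5,
                          threshold = 1e-5, reference = NULL) {
  carbon_ex <- exchange_reactions(model, carbon_only = TRUE)
  closed <- model
  for (rx in carbon_ex$reaction) closed <- set_bounds(closed, rx, lower = 0)
  rows <- lapply(substrates, function(s) {
    ex <- tryCatch(exchange_of(model, s), error = function(e) NA_character_)
    if (is.na(ex)) {
      return(tibble(substrate = s, growth = NA, mu_star = NA_real_,
                    error = "no exchange reaction"))
    }
    ms <- set_bounds(closed, ex, lower = -abs(uptake_rate))
    mu <- tryCatch(maximize_growth(ms)$mu_star, error = function(e) 0)
    tibble(substrate = s, growth = mu > threshold, mu_star = mu,
           error = NA_character_)
  })
  out <- bind_rows(rows)
  if (!is.null(reference)) {
    ok <- !is.na(out$growth)
    pred <- setNames(out$growth[ok], out$substrate[ok])
    attr(out, "scores") <- score_predictions(pred, reference[names(pred)])
  }
  out
}
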