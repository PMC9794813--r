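#' Validate an organism specification
#'
#' Checks internal consistency of an organism spec: unique identifiers,
#' dangling references, flux-bound ordering, coding-sequence invariants
#' (start/stop codons, no internal stops, length divisible by three),
#' transcription-unit/gene sequence containment, elemental balance of fully
#' annotated non-exchange core reactions, machinery-role completeness, and
#' biomass fractions summing to one. Always returns a report (never throws);
#' an empty report means the spec is internally consistent.
#'
#' @param spec An `organism_spec`.
#' @return A `validation_report`: a tibble with columns `code`, `message`
#'   and `context`, one row per violated invariant.
#' @export
validate_spec <- function(spec) {
  findings <- list()
  say <- function(code, message, context = NA_character_) {
    findings[[length(findings) + 1]] <<- tibble(code = code, message = message,
                                                context = context)
  }

  dup <- function(ids, what) {
    d <- unique(ids[duplicated(ids)])
    for (x in d) say("duplicate_id", sprintf("duplicate %s id", what), x)
  }
  dup(spec$metabolites$id, "metabolite")
  dup(spec$core_reactions$id, "reaction")
  dup(spec$genes$id, "gene")
  dup(spec$transcription_units$id, "transcription unit")
  dup(spec$complexes$id, "complex")

  bad_comp <- !spec$metabolites$compartment %in% c("cytosol", "membrane", "extracellular")
  for (x in spec$metabolites$id[bad_comp]) {
    say("bad_compartment", "compartment must be cytosol/membrane/extracellular", x)
  }

  met_ids <- spec$metabolites$id
  formulas <- parse_formulas(spec$metabolites)
  for (i in seq_len(nrow(spec$core_reactions))) {
    r <- spec$core_reactions[i, ]
    st <- r$stoichiometry[[1]]
    missing <- setdiff(names(st), met_ids)
    for (m in missing) {
      say("dangling_reference", sprintf("reaction '%s' references unknown metabolite", r$id), m)
    }
    if (r$lower_bound > r$upper_bound) {
      say("bad_bounds", "lower bound exceeds upper bound", r$id)
    }
    if (length(missing) == 0 && r$subsystem != "exchange") {
      fs <- formulas[names(st)]
      if (!any(vapply(fs, is.null, logical(1)))) {
        elements <- unique(unlist(lapply(fs, names)))
        for (el in elements) {
          bal <- sum(st * vapply(fs, function(f) {
            v <- unname(f[el])
            if (length(v) == 0 || is.na(v)) 0 else v
          }, numeric(1)))
          if (abs(bal) > 1e-9) {
            say("mass_imbalance",
                sprintf("element %s does not balance (net %+g) in reaction '%s'",
                        el, bal, r$id), r$id)
          }
        }
      }
    }
  }

  prot <- spec$genes[spec$genes$product_kind == "protein", ]
  for (i in seq_len(nrow(prot))) {
    g <- prot[i, ]
    ok <- tryCatch({
      translate_cds(g$nucleotide_sequence)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) say("bad_coding_sequence", ok, g$id)
  }

  gene_ids <- spec$genes$id
  seq_of <- setNames(spec$genes$nucleotide_sequence, gene_ids)
  for (i in seq_len(nrow(spec$transcription_units))) {
    u <- spec$transcription_units[i, ]
    gs <- u$gene_ids[[1]]
    if (length(gs) == 0) say("empty_tu", "transcription unit has no genes", u$id)
    for (g in setdiff(gs, gene_ids)) {
      say("dangling_reference", sprintf("transcription unit '%s' references unknown gene", u$id), g)
    }
    for (g in intersect(gs, gene_ids)) {
      if (!grepl(seq_of[[g]], u$sequence, fixed = TRUE)) {
        say("tu_sequence_mismatch",
            sprintf("gene '%s' sequence is not contained in unit '%s'", g, u$id), u$id)
      }
    }
  }

  prot_ids <- prot$id
  for (i in seq_len(nrow(spec$complexes))) {
    cx <- spec$complexes[i, ]
    su <- cx$subunit_stoichiometry[[1]]
    for (g in setdiff(names(su), prot_ids)) {
      say("dangling_reference",
          sprintf("complex '%s' subunit is not a protein-coding gene", cx$id), g)
    }
    if (any(su < 1)) say("bad_stoichiometry", "subunit stoichiometry below 1", cx$id)
    mods <- cx$modifications[[1]]
    for (m in names(mods)) {
      known <- m %in% met_ids ||
        (grepl("^(rrna|mrna|protein)_", m) &&
           sub("^(rrna|mrna|protein)_", "", m) %in% gene_ids)
      if (!known) {
        say("dangling_reference",
            sprintf("complex '%s' modification references unknown species", cx$id), m)
      }
    }
  }

  for (i in seq_len(nrow(spec$enzyme_assignments))) {
    a <- spec$enzyme_assignments[i, ]
    if (!a$reaction_id %in% spec$core_reactions$id) {
      say("dangling_reference", "enzyme assignment references unknown reaction", a$reaction_id)
    }
    if (!a$complex_id %in% spec$complexes$id) {
      say("dangling_reference", "enzyme assignment references unknown complex", a$complex_id)
    }
    if (!is.finite(a$keff) || a$keff <= 0) {
      say("bad_keff", "keff must be positive", paste(a$reaction_id, a$complex_id))
    }
  }

  for (i in seq_len(nrow(spec$translocations))) {
    tr <- spec$translocations[i, ]
    if (!tr$gene_id %in% prot_ids) {
      say("dangling_reference", "translocation references unknown protein gene", tr$gene_id)
    }
    if (tr$destination != "cytosol" && tr$pathway == "none") {
      say("bad_translocation", "non-cytosolic destination requires a pathway", tr$gene_id)
    }
  }

  required_roles <- c("rna_polymerase", "ribosome", "degradosome",
                      paste0("trna_synthetase:", aa3(spec$amino_acids)))
  for (role in setdiff(required_roles, names(spec$machinery_roles))) {
    say("missing_machinery", "machinery role is not assigned", role)
  }
  for (cx in setdiff(unname(spec$machinery_roles), spec$complexes$id)) {
    say("dangling_reference", "machinery role references unknown complex", cx)
  }

  if (abs(sum(spec$biomass_composition) - 1) > 1e-9) {
    say("bad_biomass", sprintf("biomass fractions sum to %.12f, not 1",
                               sum(spec$biomass_composition)))
  }

  report <- if (length(findings)) bind_rows(findings) else
    tibble(code = character(), message = character(), context = character())
  class(report) <- c("validation_report", class(report))
  report
}

# parse formula strings like "C6" / "C9N2" into named vectors; NULL when absent
parse_formulas <- function(metabolites) {
  out <- lapply(metabolites$formula, function(f) {
    if (is.na(f) || f == "") return(NULL)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, m)[[1]]
    parts <- parts[parts != ""]
    el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
    ct <- sub("^[A-Z][a-z]?", "", parts)
    ct[ct == ""] <- "1"
    setNames(as.numeric(ct), el)
  })
  setNames(out, metabolites$id)
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<validation_report> no findings; spec is internally consistent\n")
  } else {
    cat(sprintf("<validation_report> %d finding(s)\n", nrow(x)))
    NextMethod()
  }
  invisible(x)
}
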