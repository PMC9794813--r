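# Assembly of a model of metabolism and gene expression (ME model) from an
# organism spec. Stoichiometric coefficients are functions of the growth rate
# mu, restricted to the linear form a + b*mu: enzyme usage couplings are
# mu/keff, mRNA usage is (mu + k_deg)/k_rate, and biomass-component dilution
# is fraction*mu. Substituting a numeric mu therefore yields an ordinary
# linear program.

#' Growth-rate-dependent coefficient
#'
#' A scalar coefficient of the form `constant + mu_linear * mu`, evaluable at
#' any growth rate `mu >= 0` (finite at `mu = 0`). This covers all coupling
#' forms used in the model: constants, enzyme usage `mu/keff`, and ratio
#' forms `(a + b*mu)/c`.
#'
#' @param constant Constant part.
#' @param mu_linear Coefficient of mu.
#' @return A `mu_coefficient` object.
#' @export
mu_coefficient <- function(constant = 0, mu_linear = 0) {
  structure(c(constant = constant, mu_linear = mu_linear),
            class = "mu_coefficient")
}

#' Evaluate a growth-rate-dependent coefficient
#'
#' @param x A [mu_coefficient()].
#' @param mu Growth rate (1/h), non-negative.
#' @return Numeric value `constant + mu_linear * mu`.
#' @export
eval_mu <- function(x, mu) {
  stopifnot_scalar_number(mu, "mu", min = 0)
  unname(x[["constant"]] + x[["mu_linear"]] * mu)
}

# ---- internal reaction construction ---------------------------------------

new_me_rxn <- function(id, rtype, subsystem = rtype, lb = c(0, 0),
                       ub = c(NA, 0), gene_id = NA_character_,
                       complex_id = NA_character_, base_id = id) {
  list(id = id, rtype = rtype, subsystem = subsystem,
       stoich_const = numeric(), stoich_mu = numeric(),
       coup_const = numeric(), coup_mu = numeric(),
       lb = lb, ub = ub, gene_id = gene_id, complex_id = complex_id,
       base_id = base_id)
}

# add a stoichiometric term; coupling terms are tracked separately so that
# decouple_model() can strip them
add_term <- function(r, species, const = 0, mu = 0, coupling = FALSE) {
  tgt_c <- if (coupling) "coup_const" else "stoich_const"
  tgt_m <- if (coupling) "coup_mu" else "stoich_mu"
  r[[tgt_c]][species] <- (r[[tgt_c]][species] %|0|% 0) + const
  r[[tgt_m]][species] <- (r[[tgt_m]][species] %|0|% 0) + mu
  r
}

`%|0|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

rxn_stoich <- function(r, include_coupling = TRUE) {
  sp <- union(names(r$stoich_const), if (include_coupling) names(r$coup_const))
  const <- setNames(rep(0, length(sp)), sp)
  mu <- const
  const[names(r$stoich_const)] <- r$stoich_const
  mu[names(r$stoich_mu)] <- const[names(r$stoich_mu)] * 0 + r$stoich_mu
  if (include_coupling && length(r$coup_const)) {
    const[names(r$coup_const)] <- const[names(r$coup_const)] + r$coup_const
    mu[names(r$coup_mu)] <- mu[names(r$coup_mu)] + r$coup_mu
  }
  list(constant = const, mu_linear = mu)
}

# ---- spec lookups ----------------------------------------------------------

resolve_row <- function(tbl, x, what) {
  if (is.character(x)) {
    row <- tbl[tbl$id == x, ]
    if (nrow(row) != 1) abort(sprintf("unknown %s '%s'", what, x))
    row
  } else x
}

gene_row <- function(spec, g) resolve_row(spec$genes, g, "gene")

# residue body of a protein gene (vector of one-letter codes, initiator
# excised when flagged) and total chain length including the initiator
gene_peptide <- function(spec, gene) {
  g <- gene_row(spec, gene)
  if (g$product_kind != "protein") abort(sprintf("gene '%s' is not protein-coding", g$id))
  mature <- translate_cds(g$nucleotide_sequence, cleave_start = g$cleaved_start_residue)
  list(mature = strsplit(mature, "")[[1]],
       n_residues = nchar(g$nucleotide_sequence) / 3 - 1)
}

trna_species <- function(aa1) paste0("trna_", aa3(aa1))
charged_trna_species <- function(aa1) paste0("chtrna_", aa3(aa1))
aa_species <- function(aa1) paste0(aa3(aa1), "_c")

gene_product_species <- function(spec, gene_id) {
  tr <- spec$translocations
  dest <- tr$destination[tr$gene_id == gene_id]
  if (length(dest) == 1 && dest != "cytosol") {
    paste0("processed_", gene_id, "_", dest)
  } else {
    paste0("protein_", gene_id)
  }
}

machinery_complex <- function(spec, role) {
  cx <- spec$machinery_roles[role]
  if (is.na(cx)) abort(sprintf("machinery role '%s' is not assigned", role))
  unname(cx)
}

# nt mass in g/mmol (average nucleotide 340 g/mol)
.NT_MASS <- 0.34

# ---- builders (one exported function per reaction class) -------------------

#' Build the transcription reaction of a transcription unit
#'
#' Consumes nucleoside triphosphates in the exact counts of the unit
#' sequence, couples RNA polymerase usage at `mu * length / rate` (i.e.
#' `mu/keff` with an effective polymerase turnover of `rate/length`
#' transcripts per hour), and produces one RNA species per member gene:
#' mRNA for protein-coding genes, and stable RNA (tRNA/rRNA, credited to the
#' RNA biomass component) otherwise.
#'
#' @param tu Transcription-unit id or one-row tibble.
#' @param spec An `organism_spec`.
#' @return An internal ME-reaction object.
#' @export
build_transcription_reaction <- function(tu, spec) {
  u <- resolve_row(spec$transcription_units, tu, "transcription unit")
  if (is.na(u$sigma_factor) || !nzchar(u$sigma_factor)) {
    abort(sprintf("transcription unit '%s' has no sigma factor", u$id))
  }
  rnap <- machinery_complex(spec, "rna_polymerase")
  r <- new_me_rxn(paste0("TX_", u$id), "transcription")
  counts <- nt_counts(u$sequence)
  for (nt in names(counts)) {
    sp <- paste0("ntp_", if (nt == "T") "u" else tolower(nt))
    if (counts[[nt]] > 0) r <- add_term(r, sp, const = -counts[[nt]])
  }
  r <- add_term(r, rnap, mu = -nchar(u$sequence) / spec$global_rates$transcription_rate_per_nt,
                coupling = TRUE)
  for (g in u$gene_ids[[1]]) {
    row <- gene_row(spec, g)
    if (row$product_kind == "protein") {
      r <- add_term(r, paste0("mrna_", g), const = 1)
    } else {
      sp <- if (row$product_kind == "rRNA") paste0("rrna_", g) else
        trna_species(names(spec$trna_gene_of)[spec$trna_gene_of == g])
      r <- add_term(r, sp, const = 1)
      r <- add_term(r, "rna_biomass",
                    const = nchar(row$nucleotide_sequence) * .NT_MASS)
    }
  }
  r
}

#' Build the translation reaction of a protein-coding gene
#'
#' Consumes one charged tRNA per codon of the mature product (returning the
#' uncharged tRNA), energy per residue, ribosome usage at
#' `mu * length / rate`, and mRNA at `(mu + k_deg)/k_rate`; the degraded
#' share of the consumed mRNA (`k_deg/k_rate`) is emitted as a
#' degraded-mRNA species that the RNA-degradation demand reactions must
#' process. Produces the translated protein, honouring N-terminal
#' methionine excision when the gene is flagged.
#'
#' @param gene Gene id or one-row tibble (must be protein-coding).
#' @inheritParams build_transcription_reaction
#' @export
build_translation_reaction <- function(gene, spec) {
  g <- gene_row(spec, gene)
  pep <- gene_peptide(spec, g)
  gr <- spec$global_rates
  ribo <- machinery_complex(spec, "ribosome")
  r <- new_me_rxn(paste0("TL_", g$id), "translation", gene_id = g$id)
  counts <- table(pep$mature)
  for (aa in names(counts)) {
    n <- as.numeric(counts[[aa]])
    r <- add_term(r, charged_trna_species(aa), const = -n)
    r <- add_term(r, trna_species(aa), const = n)
  }
  r <- add_term(r, "atp_c", const = -gr$translation_atp_per_residue * pep$n_residues)
  r <- add_term(r, ribo, mu = -pep$n_residues / gr$translation_rate_per_residue,
                coupling = TRUE)
  kdeg <- gr$mrna_degradation_rate
  krate <- gr$mrna_translation_capacity
  r <- add_term(r, paste0("mrna_", g$id), const = -kdeg / krate, mu = -1 / krate,
                coupling = TRUE)
  r <- add_term(r, paste0("degmrna_", g$id), const = kdeg / krate, coupling = TRUE)
  r <- add_term(r, paste0("protein_", g$id), const = 1)
  if (g$id %in% (spec$biomass_protein_genes %||% character())) {
    r <- add_term(r, "protein_biomass", const = peptide_mw(paste(pep$mature, collapse = "")) / 1000)
  }
  r
}

#' Build a complex-formation reaction
#'
#' Consumes processed (post-translocation) or translated protein subunits in
#' the declared stoichiometry plus any modification cofactors, and produces
#' one unit of the complex species.
#'
#' @param cplx Complex id or one-row tibble.
#' @inheritParams build_transcription_reaction
#' @export
build_complex_formation <- function(cplx, spec) {
  cx <- resolve_row(spec$complexes, cplx, "complex")
  r <- new_me_rxn(paste0("CF_", cx$id), "complex_formation", complex_id = cx$id)
  su <- cx$subunit_stoichiometry[[1]]
  for (g in names(su)) {
    if (!g %in% spec$genes$id[spec$genes$product_kind == "protein"]) {
      abort(sprintf("complex '%s': missing protein subunit '%s'", cx$id, g))
    }
    r <- add_term(r, gene_product_species(spec, g), const = -su[[g]])
  }
  mods <- cx$modifications[[1]]
  for (m in names(mods)) r <- add_term(r, m, const = -mods[[m]])
  add_term(r, cx$id, const = 1)
}

#' Build a tRNA-charging reaction
#'
#' Consumes the free amino acid, its uncharged tRNA and energy, couples the
#' assigned aminoacyl-tRNA synthetase at `mu/keff`, and produces the charged
#' tRNA species.
#'
#' @param amino_acid One-letter amino-acid code.
#' @inheritParams build_transcription_reaction
#' @export
build_trna_charging <- function(amino_acid, spec) {
  syn <- machinery_complex(spec, paste0("trna_synthetase:", aa3(amino_acid)))
  gr <- spec$global_rates
  r <- new_me_rxn(paste0("CHG_", aa3(amino_acid)), "trna_charging")
  r <- add_term(r, aa_species(amino_acid), const = -1)
  r <- add_term(r, trna_species(amino_acid), const = -1)
  r <- add_term(r, "atp_c", const = -gr$charging_atp)
  r <- add_term(r, syn, mu = -1 / gr$keff_synthetase, coupling = TRUE)
  add_term(r, charged_trna_species(amino_acid), const = 1)
}

#' Couple an enzyme to a reaction
#'
#' Adds consumption of the catalysing complex with coefficient `mu/keff` per
#' unit reaction flux — the coupling constraint linking enzyme synthesis to
#' catalysed flux. Exchange and demand reactions stay uncoupled.
#'
#' @param rxn An internal ME-reaction object (an irreversible-direction
#'   member).
#' @param assignment One row of the spec's enzyme-assignment table.
#' @export
couple_enzyme <- function(rxn, assignment) {
  if (rxn$rtype %in% c("exchange", "demand")) {
    abort(sprintf("reaction '%s' (%s) must stay uncoupled", rxn$id, rxn$rtype))
  }
  if (!is.finite(assignment$keff) || assignment$keff <= 0) abort("keff must be positive")
  rxn <- add_term(rxn, assignment$complex_id, mu = -1 / assignment$keff,
                  coupling = TRUE)
  rxn$complex_id <- assignment$complex_id
  rxn
}

#' Build a translocation reaction
#'
#' Converts a cytosolic translated protein into its destination-compartment
#' processed form, with an energy cost proportional to chain length. The
#' post-translational secretion pathways (`sec_srp`, `tat`) additionally
#' consume the translocase complex at `mu/keff`; co-translational membrane
#' insertion (`srp`) is handled by the translating ribosome and carries only
#' the energy cost. The processed species is what complex formation (and
#' hence catalysis) uses, so a secreted enzyme is only active after
#' translocation.
#'
#' @param gene Gene id or row.
#' @param assignment One row of the spec's translocation table.
#' @inheritParams build_transcription_reaction
#' @export
add_translocation <- function(gene, assignment, spec) {
  g <- gene_row(spec, gene)
  if (assignment$destination == "cytosol") {
    abort(sprintf("gene '%s' is cytosolic; no translocation needed", g$id))
  }
  if (assignment$pathway == "none") {
    abort(sprintf("gene '%s' has a non-cytosolic destination but no pathway", g$id))
  }
  pep <- gene_peptide(spec, g)
  gr <- spec$global_rates
  r <- new_me_rxn(paste0("TLOC_", g$id), "translocation", gene_id = g$id)
  r <- add_term(r, paste0("protein_", g$id), const = -1)
  r <- add_term(r, "atp_c", const = -gr$translocation_atp_per_residue * pep$n_residues)
  if (assignment$pathway %in% c("sec_srp", "tat")) {
    tloc <- spec$translocase_complex %||% abort("no translocase complex declared")
    r <- add_term(r, tloc, mu = -1 / gr$keff_translocase, coupling = TRUE)
  }
  add_term(r, paste0("processed_", g$id, "_", assignment$destination), const = 1)
}

# ---- assembly --------------------------------------------------------------

#' Assemble a model of metabolism and gene expression
#'
#' Expands an organism spec into the full reaction network: metabolic and
#' exchange reactions (reversible ones split into forward/reverse members
#' with non-negative bounds, one coupled copy per enzyme assignment),
#' transcription, translation, translocation, complex formation, tRNA
#' charging, RNA-degradation and turnover demand reactions, and the
#' biomass-dilution objective whose component coefficients scale with mu.
#'
#' @param spec A validated `organism_spec`.
#' @return An object of class `me_model`.
#' @export
assemble_me_model <- function(spec) {
  report <- validate_spec(spec)
  if (nrow(report) > 0) {
    abort(sprintf("spec fails validation with %d finding(s); see validate_spec()",
                  nrow(report)))
  }
  BIG <- spec$config$default_flux_bound %||% 1000
  rxns <- list()
  push <- function(r) rxns[[length(rxns) + 1]] <<- r

  # core reactions: split + couple
  asg <- spec$enzyme_assignments
  for (i in seq_len(nrow(spec$core_reactions))) {
    cr <- spec$core_reactions[i, ]
    st <- cr$stoichiometry[[1]]
    rtype <- if (cr$subsystem == "exchange") "exchange" else "metabolic"
    directions <- list()
    if (cr$reversible) {
      fwd <- new_me_rxn(paste0(cr$id, "_FWD"), rtype, cr$subsystem,
                        lb = c(0, 0), ub = c(cr$upper_bound, 0), base_id = cr$id)
      rev <- new_me_rxn(paste0(cr$id, "_REV"), rtype, cr$subsystem,
                        lb = c(0, 0), ub = c(-cr$lower_bound, 0), base_id = cr$id)
      for (m in names(st)) {
        fwd <- add_term(fwd, m, const = st[[m]])
        rev <- add_term(rev, m, const = -st[[m]])
      }
      directions <- list(fwd, rev)
    } else {
      r <- new_me_rxn(cr$id, rtype, cr$subsystem,
                      lb = c(cr$lower_bound, 0), ub = c(cr$upper_bound, 0))
      for (m in names(st)) r <- add_term(r, m, const = st[[m]])
      directions <- list(r)
    }
    mine <- asg[asg$reaction_id == cr$id, ]
    if (nrow(mine) == 0 || rtype == "exchange") {
      for (d in directions) push(d)
    } else {
      for (d in directions) {
        for (j in seq_len(nrow(mine))) {
          cpy <- d
          cpy$id <- paste0(d$id, "_", mine$complex_id[j])
          push(couple_enzyme(cpy, mine[j, ]))
        }
      }
    }
  }

  # expression layer
  for (i in seq_len(nrow(spec$transcription_units))) {
    push(build_transcription_reaction(spec$transcription_units[i, ], spec))
  }
  prot <- spec$genes[spec$genes$product_kind == "protein", ]
  gr <- spec$global_rates
  deg_cx <- machinery_complex(spec, "degradosome")
  for (i in seq_len(nrow(prot))) {
    g <- prot[i, ]
    push(build_translation_reaction(g, spec))
    # whole-mRNA turnover (excess transcript decay) ...
    turn <- new_me_rxn(paste0("DM_mrna_", g$id), "demand", "rna_degradation",
                       gene_id = g$id)
    turn <- add_term(turn, paste0("mrna_", g$id), const = -1)
    turn <- add_term(turn, paste0("degmrna_", g$id), const = 1)
    push(turn)
    # ... and degradosome-coupled recycling of degraded mRNA to NMPs
    dr <- new_me_rxn(paste0("DEG_mrna_", g$id), "demand", "rna_degradation",
                     gene_id = g$id)
    dr <- add_term(dr, paste0("degmrna_", g$id), const = -1)
    counts <- nt_counts(g$nucleotide_sequence)
    for (nt in names(counts)) {
      sp <- paste0("nmp_", if (nt == "T") "u" else tolower(nt))
      if (counts[[nt]] > 0) dr <- add_term(dr, sp, const = counts[[nt]])
    }
    dr <- add_term(dr, deg_cx, mu = -1 / gr$keff_degradosome, coupling = TRUE)
    push(dr)
    # free-protein turnover pool (translated protein not used in complexes)
    dp <- new_me_rxn(paste0("DM_protein_", g$id), "demand", "protein_turnover",
                     gene_id = g$id)
    push(add_term(dp, paste0("protein_", g$id), const = -1))
  }
  tr <- spec$translocations[spec$translocations$destination != "cytosol", ]
  for (i in seq_len(nrow(tr))) {
    push(add_translocation(tr$gene_id[i], tr[i, ], spec))
  }
  for (i in seq_len(nrow(spec$complexes))) {
    push(build_complex_formation(spec$complexes[i, ], spec))
  }
  for (aa in spec$amino_acids) push(build_trna_charging(aa, spec))
  # stable-RNA turnover pools
  rrna_genes <- spec$genes$id[spec$genes$product_kind == "rRNA"]
  stable <- c(paste0("rrna_", rrna_genes), trna_species(spec$amino_acids))
  for (sp in stable) {
    d <- new_me_rxn(paste0("DM_", sp), "demand", "rna_turnover")
    push(add_term(d, sp, const = -1))
  }
  # biomass dilution objective: component consumption scales with mu
  bm <- new_me_rxn("biomass_dilution", "biomass_dilution", "biomass",
                   lb = c(1, 0), ub = c(1, 0))
  comp_species <- c(protein = "protein_biomass", rna = "rna_biomass",
                    other = "other_biomass")
  for (k in names(spec$biomass_composition)) {
    bm <- add_term(bm, comp_species[[k]], mu = -spec$biomass_composition[[k]])
  }
  push(bm)

  finalize_me_model(rxns, spec, BIG)
}

finalize_me_model <- function(rxns, spec, BIG) {
  ids <- map_chr(rxns, "id")
  if (anyDuplicated(ids)) abort("internal error: duplicate reaction ids in assembly")
  all_species <- sort(unique(unlist(lapply(rxns, function(r)
    union(names(r$stoich_const), names(r$coup_const))))))
  n <- length(rxns)
  m <- length(all_species)
  S0 <- matrix(0, m, n, dimnames = list(all_species, ids))
  S1 <- S0
  C0 <- S0
  C1 <- S0
  lb0 <- numeric(n); lb1 <- numeric(n); ub0 <- numeric(n); ub1 <- numeric(n)
  for (j in seq_len(n)) {
    r <- rxns[[j]]
    if (length(r$stoich_const)) S0[names(r$stoich_const), j] <- r$stoich_const
    if (length(r$stoich_mu)) S1[names(r$stoich_mu), j] <- r$stoich_mu
    if (length(r$coup_const)) C0[names(r$coup_const), j] <- r$coup_const
    if (length(r$coup_mu)) C1[names(r$coup_mu), j] <- r$coup_mu
    lb0[j] <- r$lb[1]; lb1[j] <- r$lb[2]
    ub0[j] <- if (is.na(r$ub[1])) BIG else r$ub[1]
    ub1[j] <- r$ub[2]
  }
  species <- tibble(id = all_species, stype = classify_species(all_species, spec))
  reactions <- tibble(
    id = ids,
    base_id = map_chr(rxns, "base_id"),
    rtype = map_chr(rxns, "rtype"),
    subsystem = map_chr(rxns, "subsystem"),
    gene_id = map_chr(rxns, function(r) r$gene_id %||% NA_character_),
    complex_id = map_chr(rxns, function(r) r$complex_id %||% NA_character_),
    lb_const = lb0, lb_mu = lb1, ub_const = ub0, ub_mu = ub1
  )
  model <- list(
    species = species,
    reactions = reactions,
    S0 = S0 + C0, S1 = S1 + C1,
    coupling_const = C0, coupling_mu = C1,
    objective = "biomass_dilution",
    coupled = TRUE,
    spec = spec,
    spec_hash = rlang::hash(spec[c("metabolites", "core_reactions", "genes",
                                   "transcription_units", "complexes",
                                   "enzyme_assignments", "translocations")])
  )
  class(model) <- "me_model"
  model
}

classify_species <- function(ids, spec) {
  constraint <- spec$metabolites$id[spec$metabolites$category == "constraint_component"]
  dplyr::case_when(
    ids %in% constraint ~ "constraint",
    ids %in% spec$metabolites$id ~ "metabolite",
    ids %in% spec$complexes$id ~ "complex",
    grepl("^(ch)?trna_", ids) ~ "generic_trna",
    grepl("^(mrna|degmrna|rrna)_", ids) ~ "transcribed_gene",
    grepl("^protein_", ids) ~ "translated_gene",
    grepl("^processed_", ids) ~ "processed_protein",
    TRUE ~ "other"
  )
}

#' Remove expression coupling from a model
#'
#' Returns an M-model-like variant with every growth-rate coupling
#' coefficient (enzyme, ribosome, polymerase, synthetase, translocase,
#' degradosome and mRNA usage) removed. Expression reactions are retained
#' but free of machinery cost; catalysis no longer consumes enzymes. Used
#' for the loop-suppression and flux-comparison contrasts. Idempotent.
#'
#' @param model An `me_model`.
#' @return The decoupled `me_model` (`$coupled` is `FALSE`).
#' @export
decouple_model <- function(model) {
  if (!model$coupled) return(model)
  model$S0 <- model$S0 - model$coupling_const
  model$S1 <- model$S1 - model$coupling_mu
  model$coupling_const[] <- 0
  model$coupling_mu[] <- 0
  model$coupled <- FALSE
  model
}

#' Census of a model by reaction and species type
#'
#' @param model An `me_model`.
#' @return A list of two tibbles: `reactions` (counts by `rtype`) and
#'   `species` (counts by `stype`).
#' @export
me_census <- function(model) {
  list(
    reactions = count(model$reactions, .data$rtype, name = "n"),
    species = count(model$species, .data$stype, name = "n")
  )
}

#' @export
print.me_model <- function(x, ...) {
  cat("<me_model>", if (!x$coupled) "(decoupled)", "\n")
  cat("  species:  ", nrow(x$species), "\n")
  cat("  reactions:", nrow(x$reactions), "\n")
  cat("  objective:", x$objective, "\n")
  invisible(x)
}
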