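#' Configuration for the synthetic mini-cell organism
#'
#' The mini-cell is a seeded, internally consistent organism specification
#' that emulates, at desk scale, the structures a genome-scale model of
#' metabolism and gene expression (ME model) assumes: a minimal metabolic
#' core (carbon uptake, precursors, amino acids, nucleotides, energy), an
#' expression layer (RNA polymerase, ribosome, tRNA synthetase, RNA
#' degradosome), a secreted reporter enzyme that hydrolyses an extracellular
#' polymer into the carbon source (an amylase/starch analog), an
#' alcohol-degradation path with an acetate exporter (ethanol-stress analog),
#' and sodium import/export (salt-stress analog).
#'
#' Every gene essential by construction (the sole carbon transporter, the
#' sole route from carbon to each biomass requirement, and all
#' expression-machinery subunits) is recorded in the generated spec as ground
#' truth, so downstream screens can be validated without trusting the solver.
#'
#' @param amino_acids One-letter codes of the amino acids modeled explicitly;
#'   the rest of the proteome is lumped into these.
#' @param glucose_uptake Maximum glucose uptake rate, mmol/gDW/h.
#' @param keff_primary,keff_secondary Effective enzyme turnover rates (1/h)
#'   for primary- and secondary-metabolism assignments (two-tier scheme).
#' @param keff_translocase Effective translocation turnover rate (1/h).
#' @param mrna_degradation_rate mRNA decay rate constant (1/h).
#' @param translation_rate_per_residue Ribosome elongation capacity,
#'   residues/h per ribosome.
#' @param transcription_rate_per_nt RNA polymerase capacity, nt/h per enzyme.
#' @param mrna_translation_capacity Translation events per mRNA per hour used
#'   in the mRNA coupling coefficient.
#' @param translation_atp_per_residue,charging_atp,translocation_atp_per_residue
#'   Energy costs (mmol ATP per residue / per charging event / per residue
#'   translocated).
#' @param biomass_composition Named fractions (must sum to 1) of biomass mass
#'   assigned to the `protein`, `rna` and `other` constraint components.
#' @param reporter_composition Named integer counts (one-letter codes) of the
#'   mature secreted reporter enzyme; this is the planted ground truth for
#'   the secretion sensitivity analysis.
#' @param exporter_trp Number of tryptophans in the acetate exporter; drives
#'   the tryptophan upregulation motif under ethanol stress.
#' @param membrane_amylase_cys Number of cysteines in the membrane-bound
#'   amylase; its displacement by forced reporter secretion plants a
#'   negative cysteine sensitivity of exactly this magnitude.
#' @param bulk_protein_length Residue length of the bulk-proteome pseudo-gene
#'   that supplies the protein fraction of biomass.
#' @param enzyme_protein_length Residue length of generic enzyme genes.
#' @param codon_usage Optional named numeric weights over codons; uniform
#'   within each amino acid's codon set by default.
#' @param add_isozyme Add a redundant isozyme for the glycolysis step
#'   (renders that step's genes individually non-essential).
#' @param include_futile_cycle Embed a thermodynamically impossible two-step
#'   futile loop used for the loop-suppression analysis.
#' @param default_flux_bound Upper flux bound, mmol/gDW/h.
#' @return A `minicell_config` list.
#' @export
minicell_config <- function(amino_acids = c("A", "G", "K", "W", "C"),
                            glucose_uptake = 5,
                            keff_primary = 36000,
                            keff_secondary = 3600,
                            keff_translocase = 3600,
                            mrna_degradation_rate = 8,
                            translation_rate_per_residue = 43200,
                            transcription_rate_per_nt = 36000,
                            mrna_translation_capacity = 40,
                            translation_atp_per_residue = 2,
                            charging_atp = 2,
                            translocation_atp_per_residue = 0.1,
                            biomass_composition = c(protein = 0.55, rna = 0.20, other = 0.25),
                            reporter_composition = c(A = 8, G = 4, K = 4, W = 2, C = 0),
                            exporter_trp = 8,
                            membrane_amylase_cys = 5,
                            bulk_protein_length = 200,
                            enzyme_protein_length = 60,
                            codon_usage = NULL,
                            add_isozyme = FALSE,
                            include_futile_cycle = TRUE,
                            default_flux_bound = 1000) {
  cfg <- list(
    amino_acids = amino_acids,
    glucose_uptake = glucose_uptake,
    keff_primary = keff_primary,
    keff_secondary = keff_secondary,
    keff_translocase = keff_translocase,
    mrna_degradation_rate = mrna_degradation_rate,
    translation_rate_per_residue = translation_rate_per_residue,
    transcription_rate_per_nt = transcription_rate_per_nt,
    mrna_translation_capacity = mrna_translation_capacity,
    translation_atp_per_residue = translation_atp_per_residue,
    charging_atp = charging_atp,
    translocation_atp_per_residue = translocation_atp_per_residue,
    biomass_composition = biomass_composition,
    reporter_composition = reporter_composition,
    exporter_trp = exporter_trp,
    membrane_amylase_cys = membrane_amylase_cys,
    bulk_protein_length = bulk_protein_length,
    enzyme_protein_length = enzyme_protein_length,
    codon_usage = codon_usage,
    add_isozyme = add_isozyme,
    include_futile_cycle = include_futile_cycle,
    default_flux_bound = default_flux_bound
  )
  class(cfg) <- "minicell_config"
  validate_minicell_config(cfg)
  cfg
}

validate_minicell_config <- function(cfg) {
  if (length(cfg$amino_acids) == 0) {
    abort("configuration error: no amino acids modeled but protein genes requested")
  }
  if (!all(cfg$amino_acids %in% names(.AA_NAME))) {
    abort("configuration error: unknown amino-acid code in `amino_acids`")
  }
  rc <- cfg$reporter_composition
  if (is.null(names(rc)) || !all(names(rc) %in% cfg$amino_acids)) {
    abort("configuration error: reporter composition must be named over `amino_acids`")
  }
  if (any(rc < 0) || sum(rc) == 0) {
    abort("configuration error: reporter composition must be non-negative with a positive total")
  }
  bc <- cfg$biomass_composition
  if (!setequal(names(bc), c("protein", "rna", "other")) || abs(sum(bc) - 1) > 1e-9) {
    abort("configuration error: biomass fractions must cover protein/rna/other and sum to 1")
  }
  for (nm in c("glucose_uptake", "keff_primary", "keff_secondary", "keff_translocase",
               "mrna_degradation_rate", "translation_rate_per_residue",
               "transcription_rate_per_nt", "mrna_translation_capacity",
               "bulk_protein_length", "enzyme_protein_length", "default_flux_bound")) {
    stopifnot_scalar_number(cfg[[nm]], nm, min = 1e-12)
  }
  invisible(cfg)
}

# three-letter species name for a one-letter code
aa3 <- function(aa) unname(.AA_NAME[aa])

# Draw a codon for amino acid `aa` using the configured usage weights
# (uniform within the amino acid's codon set by default).
draw_codon <- function(aa, codon_usage = NULL) {
  cods <- codons_for(aa)
  if (!is.null(codon_usage)) {
    w <- codon_usage[cods]
    w[is.na(w)] <- 0
    if (sum(w) > 0) return(sample(cods, 1, prob = w))
  }
  sample(cods, 1)
}

# Reverse-translate a body (vector of one-letter residues) into a CDS with
# start and stop codons.
reverse_translate <- function(body, codon_usage = NULL) {
  cods <- vapply(body, draw_codon, character(1), codon_usage = codon_usage)
  paste0(.START_CODON, paste(cods, collapse = ""), sample(.STOP_CODONS, 1))
}

# body residues for a gene given explicit counts (exact composition)
body_from_counts <- function(counts) {
  body <- rep(names(counts), counts)
  if (length(body) > 1) body <- sample(body) else body
}

# random body of length L over `aas`, each amino acid present at least once
random_body <- function(L, aas, weights) {
  if (L < length(aas)) abort("protein length shorter than the amino-acid alphabet")
  body <- c(aas, sample(aas, L - length(aas), replace = TRUE, prob = weights))
  sample(body)
}

#' Generate a seeded mini-cell organism specification
#'
#' Produces a complete, internally consistent [organism spec][validate_spec]
#' with byte-identical output for identical `(config, seed)`. See
#' [minicell_config()] for what the organism contains. The returned spec
#' records its ground truth under `$ground_truth`: the essential-by-
#' construction gene set, the non-essential gene set, and the reporter
#' enzyme's mature amino-acid composition.
#'
#' @param config A [minicell_config()].
#' @param seed Integer seed; the generator restores the caller's RNG state.
#' @return An object of class `organism_spec`.
#' @export
generate_minicell <- function(config = minicell_config(), seed = 1) {
  validate_minicell_config(config)
  with_local_seed(seed, build_minicell(config, seed))
}

build_minicell <- function(cfg, seed) {
  aas <- cfg$amino_acids
  aan <- aa3(aas)
  BIG <- cfg$default_flux_bound
  # generic composition weights: tryptophan and cysteine rare (as in real
  # proteomes), the rest uniform
  w <- rep(1, length(aas))
  w[aas == "W"] <- 0.12
  w[aas == "C"] <- 0.25
  w <- w / sum(w)

  ## ---- metabolites -------------------------------------------------------
  met <- function(id, name, compartment, formula = NA_character_,
                  category = "metabolite") {
    tibble(id = id, name = name, compartment = compartment,
           formula = formula, category = category)
  }
  aa_mets <- purrr::map2_dfr(aan, aas, function(n3, a1) {
    met(paste0(n3, "_c"), paste(n3, "(free amino acid)"), "cytosol",
        paste0("C", .AA_CARBON[[a1]]))
  })
  metabolites <- bind_rows(
    met("glc_e", "glucose (external)", "extracellular", "C6"),
    met("glc_c", "glucose", "cytosol", "C6"),
    met("starch_e", "starch unit (external)", "extracellular", "C6"),
    met("prec_c", "carbon precursor", "cytosol", "C3"),
    met("atp_c", "energy equivalent", "cytosol"),
    met("co2_c", "CO2", "cytosol", "C1"),
    met("co2_e", "CO2 (external)", "extracellular", "C1"),
    met("chor_c", "chorismate analog", "cytosol", "C11"),
    met("fol_c", "folate analog", "cytosol", "C11"),
    aa_mets,
    bind_rows(lapply(c("a", "c", "g", "u"), function(x) bind_rows(
      met(paste0("ntp_", x), paste0("NTP (", toupper(x), ")"), "cytosol", "C9"),
      met(paste0("nmp_", x), paste0("NMP (", toupper(x), ")"), "cytosol", "C9")
    ))),
    met("etoh_e", "ethanol (external)", "extracellular", "C2"),
    met("etoh_c", "ethanol", "cytosol", "C2"),
    met("acald_c", "acetaldehyde", "cytosol", "C2"),
    met("ac_c", "acetate", "cytosol", "C2"),
    met("ac_e", "acetate (external)", "extracellular", "C2"),
    met("na_e", "sodium (external)", "extracellular"),
    met("na_c", "sodium", "cytosol"),
    met("na_x", "sodium (exported pool)", "extracellular"),
    if (cfg$include_futile_cycle) met("floop_c", "futile-loop carrier", "cytosol", "C3"),
    met("protein_biomass", "protein biomass component", "cytosol",
        category = "constraint_component"),
    met("rna_biomass", "RNA biomass component", "cytosol",
        category = "constraint_component"),
    met("other_biomass", "other biomass component", "cytosol",
        category = "constraint_component")
  )

  ## ---- core reactions ----------------------------------------------------
  rxn <- function(id, stoich, subsystem, lb = 0, ub = BIG, reversible = FALSE) {
    tibble(id = id, stoichiometry = list(stoich), reversible = reversible,
           lower_bound = lb, upper_bound = ub, subsystem = subsystem)
  }
  aa_syn <- list(
    A = c(prec_c = -1, atp_c = -1, ala_c = 1),
    G = c(prec_c = -1, atp_c = -1, gly_c = 1, co2_c = 1),
    K = c(prec_c = -2, atp_c = -2, lys_c = 1),
    C = c(prec_c = -1, atp_c = -2, cys_c = 1),
    W = NULL # via chorismate, below
  )
  aa_syn_rxns <- bind_rows(lapply(aas, function(a) {
    if (a == "W") {
      bind_rows(
        rxn("TRPS1", c(prec_c = -4, atp_c = -2, chor_c = 1, co2_c = 1),
            "amino_acid_synthesis"),
        rxn("TRPS2", c(chor_c = -1, atp_c = -2, trp_c = 1), "amino_acid_synthesis")
      )
    } else if (!is.null(aa_syn[[a]])) {
      rxn(paste0(toupper(aa3(a)), "S"), aa_syn[[a]], "amino_acid_synthesis")
    } else {
      # amino acids outside the default alphabet: direct lumped synthesis
      st <- c(-ceiling(.AA_CARBON[[a]] / 3), -1, 1)
      names(st) <- c("prec_c", "atp_c", paste0(aa3(a), "_c"))
      rxn(paste0(toupper(aa3(a)), "S"), st, "amino_acid_synthesis")
    }
  }))
  ntp_rxns <- bind_rows(lapply(c("a", "c", "g", "u"), function(x) bind_rows(
    rxn(paste0("NTPS_", toupper(x)),
        setNames(c(-3, -2, 1), c("prec_c", "atp_c", paste0("ntp_", x))),
        "nucleotide_synthesis"),
    rxn(paste0("NMPK_", toupper(x)),
        setNames(c(-1, -2, 1), c(paste0("nmp_", x), "atp_c", paste0("ntp_", x))),
        "nucleotide_synthesis")
  )))
  core_reactions <- bind_rows(
    rxn("EX_glc_e", c(glc_e = -1), "exchange", lb = -cfg$glucose_uptake),
    rxn("EX_starch_e", c(starch_e = -1), "exchange", lb = 0),
    rxn("EX_etoh_e", c(etoh_e = -1), "exchange", lb = 0),
    rxn("EX_ac_e", c(ac_e = -1), "exchange", lb = 0),
    rxn("EX_na_e", c(na_e = -1), "exchange", lb = 0),
    rxn("EX_na_x", c(na_x = -1), "exchange", lb = 0),
    rxn("EX_co2_e", c(co2_e = -1), "exchange", lb = 0),
    rxn("GLCt", c(glc_e = -1, glc_c = 1), "transport"),
    rxn("GLYC", c(glc_c = -1, prec_c = 2), "glycolysis"),
    rxn("RESP", c(prec_c = -1, co2_c = 3, atp_c = 12), "energy"),
    rxn("CO2t", c(co2_c = -1, co2_e = 1), "transport", lb = -BIG, reversible = TRUE),
    aa_syn_rxns,
    rxn("FOLS", c(chor_c = -1, atp_c = -2, fol_c = 1), "folate_synthesis"),
    ntp_rxns,
    rxn("OTHSYN", c(prec_c = -1, atp_c = -2, other_biomass = 0.1),
        "biomass_precursor"),
    rxn("ETOHt", c(etoh_e = -1, etoh_c = 1), "transport"),
    rxn("ADH", c(etoh_c = -1, acald_c = 1), "ethanol_degradation"),
    rxn("ALD", c(acald_c = -1, ac_c = 1), "ethanol_degradation"),
    rxn("ACt", c(ac_c = -1, ac_e = 1), "transport"),
    rxn("NAt_leak", c(na_e = -1, na_c = 1), "transport"),
    # export pumps against the forced influx; the exported pool is tracked
    # separately so a forced net-uptake exchange stays feasible
    rxn("NAt_out", c(na_c = -1, atp_c = -2, na_x = 1), "transport"),
    rxn("AMYL", c(starch_e = -1, glc_e = 1), "starch_hydrolysis"),
    if (cfg$include_futile_cycle) bind_rows(
      rxn("FUT1", c(prec_c = -1, atp_c = -1, floop_c = 1), "futile_cycle"),
      rxn("FUT2", c(floop_c = -1, prec_c = 1, atp_c = 1), "futile_cycle")
    )
  )

  ## ---- genes -------------------------------------------------------------
  Lz <- cfg$enzyme_protein_length
  # exporter composition: fixed tryptophan load, remainder spread
  exporter_counts <- local({
    rest <- Lz - cfg$exporter_trp - 4
    cts <- setNames(rep(0L, length(aas)), aas)
    cts["W"] <- cfg$exporter_trp
    if ("C" %in% aas) cts["C"] <- 4L
    main <- setdiff(aas, c("W", "C"))
    cts[main] <- rest %/% length(main)
    cts[main[1]] <- cts[main[1]] + rest %% length(main)
    cts
  })
  bulk_counts <- local({
    Lb <- cfg$bulk_protein_length
    cts <- setNames(rep(0L, length(aas)), aas)
    cts["W"] <- max(1L, round(0.03 * Lb))
    if ("C" %in% aas) cts["C"] <- max(1L, round(0.07 * Lb))
    main <- setdiff(aas, c("W", "C"))
    rest <- Lb - sum(cts)
    cts[main] <- rest %/% length(main)
    cts[main[1]] <- cts[main[1]] + rest %% length(main)
    cts
  })
  reporter_counts <- local({
    cts <- setNames(rep(0L, length(aas)), aas)
    cts[names(cfg$reporter_composition)] <- as.integer(cfg$reporter_composition)
    cts
  })
  amyc_counts <- local({
    cts <- setNames(rep(0L, length(aas)), aas)
    cts["C"] <- as.integer(cfg$membrane_amylase_cys)
    cts
  })

  enzyme_gene_ids <- c("ptsG", "enzA", if (cfg$add_isozyme) "enzB", "ametA",
                       "trpB", "cysE", "folE", "ntpA", "atpA", "adhA", "aldX",
                       "natE", "secY", "rpoA", "rpsA", "rnjA", "synS")
  gene_bodies <- c(
    setNames(lapply(enzyme_gene_ids, function(g) random_body(Lz, aas, w)),
             enzyme_gene_ids),
    list(ywcA = body_from_counts(exporter_counts),
         amyE = body_from_counts(reporter_counts),
         amyC = body_from_counts(amyc_counts),
         bulkP = body_from_counts(bulk_counts))
  )
  protein_gene_ids <- names(gene_bodies)
  genes_protein <- tibble(
    id = protein_gene_ids,
    nucleotide_sequence = unname(map_chr(gene_bodies, reverse_translate,
                                         codon_usage = cfg$codon_usage)),
    product_kind = "protein",
    cleaved_start_residue = TRUE
  )
  random_rna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                  collapse = "")
  genes_rna <- bind_rows(
    tibble(id = "rrnA", nucleotide_sequence = random_rna(120),
           product_kind = "rRNA", cleaved_start_residue = FALSE),
    tibble(id = paste0("trn", toupper(substr(aan, 1, 1)), substr(aan, 2, 3)),
           nucleotide_sequence = map_chr(rep(30, length(aan)), random_rna),
           product_kind = "tRNA", cleaved_start_residue = FALSE)
  )
  genes <- bind_rows(genes_protein, genes_rna)
  trna_gene_of <- setNames(genes_rna$id[-1], aas)

  ## ---- transcription units ----------------------------------------------
  seq_of <- setNames(genes$nucleotide_sequence, genes$id)
  tu <- function(id, gene_ids) {
    seq <- paste(seq_of[gene_ids], collapse = "")
    tibble(id = id, gene_ids = list(gene_ids), sequence = seq,
           sigma_factor = "sigA")
  }
  operons <- list(
    TU_adhA_aldX = c("adhA", "aldX"),
    TU_trpB_folE = c("trpB", "folE")
  )
  mono <- setdiff(genes$id, unlist(operons))
  transcription_units <- bind_rows(
    bind_rows(purrr::imap(operons, function(gs, id) tu(id, gs))),
    bind_rows(lapply(mono, function(g) tu(paste0("TU_", g), g)))
  )

  ## ---- complexes ---------------------------------------------------------
  cplx <- function(id, subunits, modifications = list()) {
    tibble(id = id, subunit_stoichiometry = list(subunits),
           modifications = list(modifications))
  }
  monomer_ids <- setdiff(protein_gene_ids, c("ptsG", "atpA", "rpsA", "bulkP"))
  complexes <- bind_rows(
    cplx("ptsG_cplx", c(ptsG = 2L)),
    cplx("atpA_cplx", c(atpA = 1L), list(atp_c = 1)),
    cplx("ribosome_cplx", c(rpsA = 3L), list(rrna_rrnA = 1)),
    bind_rows(lapply(monomer_ids, function(g)
      cplx(paste0(g, "_cplx"), setNames(1L, g))))
  )

  ## ---- enzyme assignments ------------------------------------------------
  asg <- function(reaction_id, complex_id, tier) {
    tibble(reaction_id = reaction_id, complex_id = complex_id,
           keff = if (tier == "primary") cfg$keff_primary else cfg$keff_secondary,
           tier = tier)
  }
  primary_map <- c(
    GLYC = "enzA_cplx", RESP = "atpA_cplx",
    NTPS_A = "ntpA_cplx", NTPS_C = "ntpA_cplx", NTPS_G = "ntpA_cplx",
    NTPS_U = "ntpA_cplx", NMPK_A = "ntpA_cplx", NMPK_C = "ntpA_cplx",
    NMPK_G = "ntpA_cplx", NMPK_U = "ntpA_cplx", OTHSYN = "ametA_cplx"
  )
  primary_map <- primary_map[names(primary_map) %in% core_reactions$id]
  secondary_map <- c(
    GLCt = "ptsG_cplx",
    ALAS = "ametA_cplx", GLYS = "ametA_cplx", LYSS = "ametA_cplx",
    TRPS1 = "trpB_cplx", TRPS2 = "trpB_cplx", CYSS = "cysE_cplx",
    ADH = "adhA_cplx", ALD = "aldX_cplx", ACt = "ywcA_cplx",
    NAt_out = "natE_cplx", FOLS = "folE_cplx",
    if (cfg$include_futile_cycle) c(FUT1 = "adhA_cplx", FUT2 = "aldX_cplx")
  )
  enzyme_assignments <- bind_rows(
    bind_rows(purrr::imap(as.list(primary_map), function(cx, rx) asg(rx, cx, "primary"))),
    bind_rows(purrr::imap(as.list(secondary_map), function(cx, rx) asg(rx, cx, "secondary"))),
    asg("AMYL", "amyE_cplx", "secondary"),
    asg("AMYL", "amyC_cplx", "secondary"),
    if (cfg$add_isozyme) asg("GLYC", "enzB_cplx", "primary")
  )

  ## ---- translocation -----------------------------------------------------
  membrane_genes <- c("ptsG", "ywcA", "natE", "secY", "amyC")
  translocations <- tibble(id = protein_gene_ids) |>
    transmute(gene_id = .data$id,
              pathway = case_when(.data$id == "amyE" ~ "sec_srp",
                                  .data$id %in% membrane_genes ~ "srp",
                                  TRUE ~ "none"),
              destination = case_when(.data$id == "amyE" ~ "extracellular",
                                      .data$id %in% membrane_genes ~ "membrane",
                                      TRUE ~ "cytosol"))

  ## ---- machinery roles, ground truth -------------------------------------
  machinery_roles <- c(
    rna_polymerase = "rpoA_cplx",
    ribosome = "ribosome_cplx",
    degradosome = "rnjA_cplx",
    setNames(rep("synS_cplx", length(aas)), paste0("trna_synthetase:", aan))
  )
  essential <- c("ptsG", if (!cfg$add_isozyme) "enzA", "ametA", "trpB", "cysE",
                 "ntpA", "atpA", "rpoA", "rpsA", "rnjA", "synS", "bulkP")
  nonessential <- setdiff(protein_gene_ids, essential)

  spec <- list(
    metabolites = metabolites,
    core_reactions = core_reactions,
    genes = genes,
    transcription_units = transcription_units,
    complexes = complexes,
    enzyme_assignments = enzyme_assignments,
    translocations = translocations,
    machinery_roles = machinery_roles,
    biomass_composition = cfg$biomass_composition,
    global_rates = c(cfg[c("mrna_degradation_rate", "translation_rate_per_residue",
                           "transcription_rate_per_nt", "mrna_translation_capacity",
                           "translation_atp_per_residue", "charging_atp",
                           "translocation_atp_per_residue", "keff_translocase")],
                     list(keff_synthetase = cfg$keff_secondary,
                          keff_degradosome = 36)),
    translocase_complex = "secY_cplx",
    biomass_protein_genes = "bulkP",
    amino_acids = aas,
    trna_gene_of = trna_gene_of,
    motifs = list(
      reporter_gene = "amyE",
      reporter_composition = reporter_counts,
      membrane_amylase_gene = "amyC",
      carbon_exchange = "EX_glc_e",
      polymer_exchange = "EX_starch_e",
      ethanol_metabolite = "etoh_e",
      sodium_metabolite = "na_e",
      folate_metabolite = "fol_c",
      acetate_exporter_gene = "ywcA",
      tryptophan_synthesis = "TRPS2",
      cysteine_synthesis = "CYSS",
      futile_cycle = if (cfg$include_futile_cycle) c("FUT1", "FUT2") else character(),
      bulk_protein_gene = "bulkP"
    ),
    ground_truth = list(
      essential_genes = sort(essential),
      nonessential_genes = sort(nonessential),
      reporter_composition = reporter_counts
    ),
    config = cfg,
    seed = as.integer(seed)
  )
  class(spec) <- "organism_spec"
  spec
}

#' @export
print.organism_spec <- function(x, ...) {
  cat("<organism_spec>\n")
  cat("  metabolites:         ", nrow(x$metabolites), "\n")
  cat("  core reactions:      ", nrow(x$core_reactions), "\n")
  cat("  genes:               ", nrow(x$genes),
      sprintf("(%d protein-coding)\n", sum(x$genes$product_kind == "protein")))
  cat("  transcription units: ", nrow(x$transcription_units), "\n")
  cat("  complexes:           ", nrow(x$complexes), "\n")
  cat("  enzyme assignments:  ", nrow(x$enzyme_assignments), "\n")
  invisible(x)
}

#' Mature amino-acid composition of a protein gene
#'
#' @param spec An `organism_spec`.
#' @param gene_id Protein-coding gene id.
#' @return Named integer counts over the spec's amino-acid alphabet.
#' @export
gene_composition <- function(spec, gene_id) {
  g <- spec$genes[spec$genes$id == gene_id, ]
  if (nrow(g) != 1 || g$product_kind != "protein") {
    abort(sprintf("unknown protein gene '%s'", gene_id))
  }
  pep <- translate_cds(g$nucleotide_sequence, cleave_start = g$cleaved_start_residue)
  aa_counts(pep, alphabet = spec$amino_acids)
}
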