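# Shared fixtures, built once per test run (lazy, memoised).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

default_spec <- function() memo("spec", generate_minicell(minicell_config(), seed = 7))

default_model <- function() memo("model", assemble_me_model(default_spec()))

default_growth <- function() memo("growth", maximize_growth(default_model()))

# glucose closed, starch open: the secretion condition
starch_model <- function() memo("starch", {
  m <- set_bounds(default_model(), "EX_glc_e", lower = 0)
  set_bounds(m, "EX_starch_e", lower = -3)
})

starch_growth <- function() memo("starch_growth", maximize_growth(starch_model()))

isozyme_model <- function() memo("isozyme", {
  spec <- generate_minicell(minicell_config(add_isozyme = TRUE), seed = 7)
  list(spec = spec, model = assemble_me_model(spec))
})

# A hand-built minimal spec over {M, G, K} for builder unit examples;
# not solvable, only buildable.
toy_spec <- function() memo("toy", {
  genes <- tibble::tibble(
    id = c("pepA", "pepB"),
    # both encode Met-Gly-Lys; pepB undergoes N-terminal excision
    nucleotide_sequence = c("ATGGGTAAATAA", "ATGGGTAAATAA"),
    product_kind = "protein",
    cleaved_start_residue = c(FALSE, TRUE)
  )
  tus <- tibble::tibble(
    id = "TU_pep",
    gene_ids = list(c("pepA", "pepB")),
    sequence = paste0(genes$nucleotide_sequence, collapse = ""),
    sigma_factor = "sigA"
  )
  cplx <- tibble::tibble(
    id = "toy_cplx",
    subunit_stoichiometry = list(c(pepA = 1L)),
    modifications = list(list())
  )
  spec <- list(
    metabolites = tibble::tibble(id = character(), name = character(),
                                 compartment = character(), formula = character(),
                                 category = character()),
    core_reactions = tibble::tibble(),
    genes = genes,
    transcription_units = tus,
    complexes = cplx,
    enzyme_assignments = tibble::tibble(),
    translocations = tibble::tibble(gene_id = genes$id, pathway = "none",
                                    destination = "cytosol"),
    machinery_roles = c(rna_polymerase = "toy_cplx", ribosome = "toy_cplx",
                        degradosome = "toy_cplx",
                        `trna_synthetase:met` = "toy_cplx",
                        `trna_synthetase:gly` = "toy_cplx",
                        `trna_synthetase:lys` = "toy_cplx"),
    biomass_composition = c(protein = 0.6, rna = 0.2, other = 0.2),
    global_rates = list(mrna_degradation_rate = 8,
                        translation_rate_per_residue = 43200,
                        transcription_rate_per_nt = 36000,
                        mrna_translation_capacity = 40,
                        translation_atp_per_residue = 2, charging_atp = 2,
                        translocation_atp_per_residue = 0.1,
                        keff_translocase = 3600, keff_synthetase = 3600,
                        keff_degradosome = 36),
    amino_acids = c("M", "G", "K"),
    trna_gene_of = c(M = "trnMet", G = "trnGly", K = "trnLys"),
    translocase_complex = "toy_cplx",
    biomass_protein_genes = character(),
    motifs = list(),
    config = minicell_config(),
    seed = 1L
  )
  class(spec) <- "organism_spec"
  spec
})

# stoichiometry of an internal ME-reaction object at a given mu
rxn_coeff <- function(r, species, mu = NULL) {
  const <- (r$stoich_const[species] %||% 0)
  if (is.na(const)) const <- 0
  muc <- r$stoich_mu[species]; if (length(muc) == 0 || is.na(muc)) muc <- 0
  cc <- r$coup_const[species]; if (length(cc) == 0 || is.na(cc)) cc <- 0
  cm <- r$coup_mu[species]; if (length(cm) == 0 || is.na(cm)) cm <- 0
  if (is.null(mu)) c(constant = unname(const + cc), mu_linear = unname(muc + cm))
  else unname(const + cc + mu * (muc + cm))
}

`%||%` <- rlang::`%||%`
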