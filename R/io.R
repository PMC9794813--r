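# Serialization: organism specs as a directory of delimited text tables
# plus one structured config file; ME models as a COBRAme-style JSON
# dialect in which every stoichiometric coefficient is a
# {constant, mu_linear} record. Both round-trip losslessly.

#' Write an organism spec to a directory of text tables
#'
#' One TSV per table (list columns in long form) plus `config.json` for
#' the scalar structure (machinery roles, biomass composition, rates,
#' ground truth, generator config). Writing is deterministic: identical
#' specs produce byte-identical directories.
#'
#' @param spec An `organism_spec`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_organism_spec <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(dir, name), progress = FALSE)
  w(spec$metabolites, "metabolites.tsv")
  cr <- spec$core_reactions
  w(cr[, c("id", "reversible", "lower_bound", "upper_bound", "subsystem")],
    "core_reactions.tsv")
  st <- purrr::map2_dfr(cr$id, cr$stoichiometry, function(id, s) {
    tibble(reaction_id = id, metabolite_id = names(s), coefficient = unname(s))
  })
  w(st, "core_reaction_stoichiometry.tsv")
  w(spec$genes, "genes.tsv")
  tus <- spec$transcription_units
  w(tibble(id = tus$id,
           gene_ids = map_chr(tus$gene_ids, paste, collapse = ";"),
           sequence = tus$sequence, sigma_factor = tus$sigma_factor),
    "transcription_units.tsv")
  cx <- spec$complexes
  w(purrr::map2_dfr(cx$id, cx$subunit_stoichiometry, function(id, s) {
    tibble(complex_id = id, gene_id = names(s), stoichiometry = unname(s))
  }), "complex_subunits.tsv")
  mods <- purrr::map2_dfr(cx$id, cx$modifications, function(id, m) {
    if (length(m) == 0) return(NULL)
    tibble(complex_id = id, species_id = names(m), count = as.numeric(unlist(m)))
  })
  if (nrow(mods) == 0) {
    mods <- tibble(complex_id = character(), species_id = character(),
                   count = numeric())
  }
  w(mods, "complex_modifications.tsv")
  w(spec$enzyme_assignments, "enzyme_assignments.tsv")
  w(spec$translocations, "translocations.tsv")
  cfg <- spec$config
  class(cfg) <- NULL
  jsonlite::write_json(list(
    machinery_roles = as.list(spec$machinery_roles),
    biomass_composition = as.list(spec$biomass_composition),
    global_rates = spec$global_rates,
    amino_acids = spec$amino_acids,
    trna_gene_of = as.list(spec$trna_gene_of),
    translocase_complex = spec$translocase_complex,
    biomass_protein_genes = spec$biomass_protein_genes,
    motifs = spec$motifs,
    ground_truth = spec$ground_truth,
    config = cfg,
    seed = spec$seed
  ), file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE, null = "null")
  invisible(dir)
}

#' Read an organism spec from a directory
#'
#' Inverse of [write_organism_spec()]; the round trip is lossless.
#'
#' @param dir Directory written by [write_organism_spec()].
#' @return An `organism_spec`.
#' @export
read_organism_spec <- function(dir) {
  r <- function(name, types) {
    readr::read_tsv(file.path(dir, name), col_types = types, progress = FALSE)
  }
  metabolites <- r("metabolites.tsv", "ccccc")
  crh <- r("core_reactions.tsv", "clddc")
  st <- r("core_reaction_stoichiometry.tsv", "ccd")
  stoich <- lapply(crh$id, function(id) {
    rows <- st[st$reaction_id == id, ]
    setNames(rows$coefficient, rows$metabolite_id)
  })
  core_reactions <- mutate(crh, stoichiometry = stoich,
                           .after = "id")
  genes <- r("genes.tsv", "cccl")
  tuh <- r("transcription_units.tsv", "cccc")
  transcription_units <- tibble(
    id = tuh$id,
    gene_ids = strsplit(tuh$gene_ids, ";", fixed = TRUE),
    sequence = tuh$sequence, sigma_factor = tuh$sigma_factor
  )
  su <- r("complex_subunits.tsv", "ccd")
  mo <- r("complex_modifications.tsv", "ccd")
  cids <- unique(su$complex_id)
  complexes <- tibble(
    id = cids,
    subunit_stoichiometry = lapply(cids, function(id) {
      rows <- su[su$complex_id == id, ]
      setNames(as.integer(rows$stoichiometry), rows$gene_id)
    }),
    modifications = lapply(cids, function(id) {
      rows <- mo[mo$complex_id == id, ]
      if (nrow(rows) == 0) list() else as.list(setNames(rows$count, rows$species_id))
    })
  )
  enzyme_assignments <- r("enzyme_assignments.tsv", "ccdc")
  translocations <- r("translocations.tsv", "ccc")
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- cfg$config
  config$reporter_composition <- unlist(config$reporter_composition)
  config$biomass_composition <- unlist(config$biomass_composition)
  if (is.null(config$codon_usage)) config["codon_usage"] <- list(NULL)
  class(config) <- "minicell_config"
  gt <- cfg$ground_truth
  gt$reporter_composition <- unlist(gt$reporter_composition)
  motifs <- cfg$motifs
  motifs$reporter_composition <- unlist(motifs$reporter_composition)
  spec <- list(
    metabolites = metabolites,
    core_reactions = core_reactions,
    genes = genes,
    transcription_units = transcription_units,
    complexes = complexes,
    enzyme_assignments = enzyme_assignments,
    translocations = translocations,
    machinery_roles = unlist(cfg$machinery_roles),
    biomass_composition = unlist(cfg$biomass_composition),
    global_rates = cfg$global_rates,
    amino_acids = cfg$amino_acids,
    trna_gene_of = unlist(cfg$trna_gene_of),
    translocase_complex = cfg$translocase_complex,
    biomass_protein_genes = cfg$biomass_protein_genes,
    motifs = motifs,
    ground_truth = gt,
    config = config,
    seed = cfg$seed
  )
  class(spec) <- "organism_spec"
  spec
}

# ---- ME-model JSON dialect -------------------------------------------------

coef_record <- function(const, mu) {
  out <- list()
  if (const != 0) out$constant <- const
  if (mu != 0) out$mu_linear <- mu
  if (length(out) == 0) out$constant <- 0
  out
}

#' Write an ME model to COBRAme-style JSON
#'
#' Species, reactions and bounds with every coefficient encoded as a
#' `{constant, mu_linear}` record (coupling terms kept in a separate
#' `coupling` block per reaction so the decoupled variant is recoverable).
#' The format is versioned (`minime-me-json/1`) and files round-trip
#' byte-identically through [read_me_model()] + [write_me_model()].
#'
#' @param model An `me_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_me_model <- function(model, path) {
  rx <- model$reactions
  reactions <- lapply(seq_len(nrow(rx)), function(j) {
    stoich_c <- model$S0[, j] - model$coupling_const[, j]
    stoich_m <- model$S1[, j] - model$coupling_mu[, j]
    coup_c <- model$coupling_const[, j]
    coup_m <- model$coupling_mu[, j]
    sp <- rownames(model$S0)
    nz <- which(stoich_c != 0 | stoich_m != 0)
    nzc <- which(coup_c != 0 | coup_m != 0)
    out <- list(
      id = rx$id[j], base_id = rx$base_id[j], rtype = rx$rtype[j],
      subsystem = rx$subsystem[j],
      lower_bound = coef_record(rx$lb_const[j], rx$lb_mu[j]),
      upper_bound = coef_record(rx$ub_const[j], rx$ub_mu[j]),
      stoichiometry = setNames(
        lapply(nz, function(i) coef_record(stoich_c[i], stoich_m[i])), sp[nz])
    )
    if (!is.na(rx$gene_id[j])) out$gene_id <- rx$gene_id[j]
    if (!is.na(rx$complex_id[j])) out$complex_id <- rx$complex_id[j]
    if (length(nzc)) {
      out$coupling <- setNames(
        lapply(nzc, function(i) coef_record(coup_c[i], coup_m[i])), sp[nzc])
    }
    out
  })
  jsonlite::write_json(list(
    format = "minime-me-json/1",
    objective = model$objective,
    coupled = model$coupled,
    spec_hash = model$spec_hash,
    species = purrr::map2(model$species$id, model$species$stype,
                          function(id, st) list(id = id, stype = st)),
    reactions = reactions
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

parse_coef <- function(rec, where, warnings) {
  known <- c("constant", "mu_linear")
  extra <- setdiff(names(rec), known)
  if (length(extra)) {
    abort(sprintf("unsupported coefficient construct %s in %s",
                  paste(extra, collapse = "/"), where),
          class = "minime_unsupported_construct")
  }
  c(rec$constant %||% 0, rec$mu_linear %||% 0)
}

#' Read an ME model from COBRAme-style JSON
#'
#' Inverse of [write_me_model()]. Unknown coefficient-expression forms
#' raise an explicit unsupported-construct error; unknown top-level reaction
#' fields are collected as warnings, never silently dropped. The returned
#' model carries no organism spec (`$spec` is `NULL`); spec-dependent
#' analyses need the spec loaded separately.
#'
#' @param path Path to a model JSON file.
#' @return An `me_model`.
#' @export
read_me_model <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "minime-me-json/1")) {
    abort(sprintf("unrecognised model format '%s'", doc$format %||% "<missing>"))
  }
  sp_ids <- map_chr(doc$species, "id")
  rx_ids <- map_chr(doc$reactions, "id")
  m <- length(sp_ids); n <- length(rx_ids)
  S0 <- matrix(0, m, n, dimnames = list(sp_ids, rx_ids))
  S1 <- S0; C0 <- S0; C1 <- S0
  lb0 <- numeric(n); lb1 <- numeric(n); ub0 <- numeric(n); ub1 <- numeric(n)
  warnings <- character()
  known_fields <- c("id", "base_id", "rtype", "subsystem", "lower_bound",
                    "upper_bound", "stoichiometry", "coupling", "gene_id",
                    "complex_id")
  for (j in seq_len(n)) {
    r <- doc$reactions[[j]]
    extra <- setdiff(names(r), known_fields)
    if (length(extra)) {
      warnings <- c(warnings, sprintf("reaction '%s': unsupported field(s) %s",
                                      r$id, paste(extra, collapse = ", ")))
    }
    lbc <- parse_coef(r$lower_bound, r$id); ubc <- parse_coef(r$upper_bound, r$id)
    lb0[j] <- lbc[1]; lb1[j] <- lbc[2]; ub0[j] <- ubc[1]; ub1[j] <- ubc[2]
    for (spn in names(r$stoichiometry)) {
      cf <- parse_coef(r$stoichiometry[[spn]], r$id)
      S0[spn, j] <- S0[spn, j] + cf[1]
      S1[spn, j] <- S1[spn, j] + cf[2]
    }
    for (spn in names(r$coupling)) {
      cf <- parse_coef(r$coupling[[spn]], r$id)
      C0[spn, j] <- C0[spn, j] + cf[1]
      C1[spn, j] <- C1[spn, j] + cf[2]
      S0[spn, j] <- S0[spn, j] + cf[1]
      S1[spn, j] <- S1[spn, j] + cf[2]
    }
  }
  reactions <- tibble(
    id = rx_ids,
    base_id = map_chr(doc$reactions, function(r) r$base_id %||% r$id),
    rtype = map_chr(doc$reactions, "rtype"),
    subsystem = map_chr(doc$reactions, function(r) r$subsystem %||% r$rtype),
    gene_id = map_chr(doc$reactions, function(r) r$gene_id %||% NA_character_),
    complex_id = map_chr(doc$reactions, function(r) r$complex_id %||% NA_character_),
    lb_const = lb0, lb_mu = lb1, ub_const = ub0, ub_mu = ub1
  )
  model <- list(
    species = tibble(id = sp_ids, stype = map_chr(doc$species, "stype")),
    reactions = reactions,
    S0 = S0, S1 = S1, coupling_const = C0, coupling_mu = C1,
    objective = doc$objective,
    coupled = isTRUE(doc$coupled),
    spec = NULL,
    spec_hash = doc$spec_hash
  )
  if (length(warnings)) attr(model, "warnings") <- warnings
  class(model) <- "me_model"
  model
}

#' Load a model file with a census record
#'
#' Reads a COBRAme-style JSON model and reports its census: number of
#' genes (distinct gene associations), reactions and species, plus any
#' unsupported constructs collected as warnings.
#'
#' @param path Path to a model JSON file.
#' @return List with `model`, `record` (tibble: genes, reactions, species,
#'   dialect) and `warnings` (character).
#' @export
read_cobrame_json <- function(path) {
  model <- read_me_model(path)
  genes <- unique(stats::na.omit(model$reactions$gene_id))
  record <- tibble(
    genes = length(genes),
    reactions = nrow(model$reactions),
    species = nrow(model$species),
    dialect = "minime-me-json/1"
  )
  list(model = model, record = record,
       warnings = attr(model, "warnings") %||% character())
}

#' Write a flux solution to a delimited file
#'
#' Two-column TSV (reaction id, flux).
#'
#' @param solution A feasible `flux_solution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flux_solution <- function(solution, path) {
  readr::write_tsv(tidy(solution), path, progress = FALSE)
  invisible(path)
}
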