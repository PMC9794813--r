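test_that("mu coefficients evaluate linearly and finitely at zero", {
  x <- mu_coefficient(0.2, 3)
  expect_equal(eval_mu(x, 0), 0.2)
  expect_equal(eval_mu(x, 0.5), 1.7)
  expect_error(eval_mu(x, -1), "mu")
})

test_that("transcription consumes the unit's nucleotides and couples the polymerase", {
  spec <- toy_spec()
  r <- build_transcription_reaction("TU_pep", spec)
  counts <- table(strsplit(spec$transcription_units$sequence[1], "")[[1]])
  expect_equal(rxn_coeff(r, "ntp_a")[["constant"]], -unname(counts[["A"]]))
  expect_equal(rxn_coeff(r, "ntp_g")[["constant"]], -unname(counts[["G"]]))
  expect_equal(rxn_coeff(r, "ntp_u")[["constant"]], -unname(counts[["T"]]))
  # one mRNA per member gene
  expect_equal(rxn_coeff(r, "mrna_pepA")[["constant"]], 1)
  expect_equal(rxn_coeff(r, "mrna_pepB")[["constant"]], 1)
  # polymerase coupling vanishes at mu = 0 and scales with unit length
  expect_equal(rxn_coeff(r, "toy_cplx", mu = 0), 0)
  len <- nchar(spec$transcription_units$sequence[1])
  expect_equal(rxn_coeff(r, "toy_cplx", mu = 0.3),
               -0.3 * len / spec$global_rates$transcription_rate_per_nt)
})

test_that("translation consumes charged tRNA per codon and honours excision", {
  spec <- toy_spec()
  # pepA: Met-Gly-Lys, no excision
  r <- build_translation_reaction("pepA", spec)
  for (aa in c("met", "gly", "lys")) {
    expect_equal(rxn_coeff(r, paste0("chtrna_", aa))[["constant"]], -1)
    expect_equal(rxn_coeff(r, paste0("trna_", aa))[["constant"]], 1)
  }
  expect_equal(rxn_coeff(r, "protein_pepA")[["constant"]], 1)
  # pepB: initiator methionine excised; the mature product has no Met
  r2 <- build_translation_reaction("pepB", spec)
  expect_equal(rxn_coeff(r2, "chtrna_met")[["constant"]], 0)
  expect_equal(rxn_coeff(r2, "chtrna_gly")[["constant"]], -1)
  expect_equal(translate_cds(spec$genes$nucleotide_sequence[2], cleave_start = TRUE),
               "GK")
  # energy cost scales with full chain length (3 residues)
  expect_equal(rxn_coeff(r, "atp_c")[["constant"]],
               -spec$global_rates$translation_atp_per_residue * 3)
})

test_that("the mRNA coupling coefficient increases with growth rate", {
  spec <- toy_spec()
  r <- build_translation_reaction("pepA", spec)
  c1 <- rxn_coeff(r, "mrna_pepA", mu = 0.1)
  c2 <- rxn_coeff(r, "mrna_pepA", mu = 0.5)
  expect_lt(c2, c1)  # consumption coefficients are negative: more consumed
  expect_gt(abs(c2), abs(c1))
  gr <- spec$global_rates
  expect_equal(c1, -(0.1 + gr$mrna_degradation_rate) / gr$mrna_translation_capacity)
})

test_that("complex formation consumes subunits and modification cofactors", {
  spec <- default_spec()
  # ptsG is a homodimer
  r <- build_complex_formation("ptsG_cplx", spec)
  expect_equal(rxn_coeff(r, "processed_ptsG_membrane")[["constant"]], -2)
  expect_equal(rxn_coeff(r, "ptsG_cplx")[["constant"]], 1)
  # atpA carries one cofactor modification
  r2 <- build_complex_formation("atpA_cplx", spec)
  expect_equal(rxn_coeff(r2, "atp_c")[["constant"]], -1)
  # the ribosome consumes its rRNA as a modification
  r3 <- build_complex_formation("ribosome_cplx", spec)
  expect_equal(rxn_coeff(r3, "rrna_rrnA")[["constant"]], -1)
  expect_equal(rxn_coeff(r3, "protein_rpsA")[["constant"]], -3)
})

test_that("tRNA charging couples the synthetase with mu/keff", {
  spec <- default_spec()
  r <- build_trna_charging("A", spec)
  expect_equal(rxn_coeff(r, "ala_c")[["constant"]], -1)
  expect_equal(rxn_coeff(r, "chtrna_ala")[["constant"]], 1)
  expect_equal(rxn_coeff(r, "synS_cplx", mu = 0), 0)
  # doubling keff halves the coupling coefficient at fixed mu
  spec2 <- spec
  spec2$global_rates$keff_synthetase <- 2 * spec$global_rates$keff_synthetase
  r2 <- build_trna_charging("A", spec2)
  expect_equal(rxn_coeff(r2, "synS_cplx", mu = 0.4),
               rxn_coeff(r, "synS_cplx", mu = 0.4) / 2)
})

test_that("enzyme coupling adds mu/keff complex usage and refuses exchanges", {
  asg <- tibble::tibble(reaction_id = "X", complex_id = "cpx", keff = 234000,
                        tier = "primary")
  r <- minime:::new_me_rxn("X", "metabolic")
  rc <- couple_enzyme(r, asg[1, ])
  expect_equal(rxn_coeff(rc, "cpx", mu = 0.45), -0.45 / 234000)
  expect_equal(rxn_coeff(rc, "cpx", mu = 0.45), -1.923e-6, tolerance = 1e-4)
  expect_equal(rxn_coeff(rc, "cpx", mu = 0), 0)
  ex <- minime:::new_me_rxn("EX_x", "exchange")
  expect_error(couple_enzyme(ex, asg[1, ]), "uncoupled")
})

test_that("translocation gates the secreted reporter and prices chain length", {
  spec <- default_spec()
  tr <- spec$translocations
  amye <- tr[tr$gene_id == "amyE", ]
  r <- add_translocation("amyE", amye, spec)
  expect_equal(rxn_coeff(r, "protein_amyE")[["constant"]], -1)
  expect_equal(rxn_coeff(r, "processed_amyE_extracellular")[["constant"]], 1)
  # secreted pathway couples the translocase; membrane srp insertion does not
  expect_lt(rxn_coeff(r, "secY_cplx", mu = 0.3), 0)
  ptsg <- tr[tr$gene_id == "ptsG", ]
  r2 <- add_translocation("ptsG", ptsg, spec)
  expect_equal(rxn_coeff(r2, "secY_cplx", mu = 0.3), 0)
  # energy cost is linear in chain length
  n_amye <- nchar(spec$genes$nucleotide_sequence[spec$genes$id == "amyE"]) / 3 - 1
  expect_equal(rxn_coeff(r, "atp_c")[["constant"]],
               -spec$global_rates$translocation_atp_per_residue * n_amye)
  # errors: cytosolic gene, missing pathway
  expect_error(add_translocation("bulkP", tr[tr$gene_id == "bulkP", ], spec),
               "cytosolic")
  bad <- amye; bad$pathway <- "none"
  expect_error(add_translocation("amyE", bad, spec), "pathway")
})

test_that("assembly census matches the spec and is deterministic", {
  spec <- default_spec()
  m <- default_model()
  census <- me_census(m)$reactions
  n_of <- function(t) census$n[census$rtype == t]
  expect_equal(n_of("transcription"), nrow(spec$transcription_units))
  expect_equal(n_of("translation"), sum(spec$genes$product_kind == "protein"))
  expect_equal(n_of("complex_formation"), nrow(spec$complexes))
  expect_equal(n_of("trna_charging"), length(spec$amino_acids))
  # one degradation demand per mRNA species routes nucleotides back as NMPs
  deg <- m$reactions[grepl("^DEG_mrna_", m$reactions$id), ]
  expect_equal(nrow(deg), sum(spec$genes$product_kind == "protein"))
  m2 <- assemble_me_model(spec)
  expect_identical(m$S0, m2$S0)
  expect_identical(m$S1, m2$S1)
  expect_identical(m$spec_hash, m2$spec_hash)
})

test_that("reversible core reactions split into non-negative members", {
  m <- default_model()
  rx <- m$reactions
  fwd <- rx[rx$id == "CO2t_FWD", ]; rev <- rx[rx$id == "CO2t_REV", ]
  expect_equal(nrow(fwd), 1); expect_equal(nrow(rev), 1)
  expect_equal(fwd$lb_const, 0); expect_equal(rev$lb_const, 0)
  expect_gt(fwd$ub_const, 0); expect_gt(rev$ub_const, 0)
  # opposite stoichiometry
  expect_equal(m$S0[, "CO2t_FWD"], -m$S0[, "CO2t_REV"])
})

test_that("all coupling coefficients vanish at mu = 0 and grow with mu", {
  m <- default_model()
  c0 <- m$coupling_const + 0 * m$coupling_mu
  # machinery couplings have no constant part except the mRNA terms
  mrna_rows <- grepl("^(mrna|degmrna)_", rownames(c0))
  expect_true(all(c0[!mrna_rows, ] == 0))
  # and the mu part never decreases consumption magnitude
  expect_true(all(m$coupling_mu[!mrna_rows, ] <= 0))
})

test_that("decoupling is idempotent and relaxes growth", {
  m <- default_model()
  md <- decouple_model(m)
  expect_false(md$coupled)
  expect_identical(md$S0, decouple_model(md)$S0)
  mu_c <- default_growth()$mu_star
  mu_d <- maximize_growth(md)$mu_star
  expect_gte(mu_d, mu_c)
})
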