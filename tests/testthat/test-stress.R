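test_that("zero stressor rate reproduces the baseline solution", {
  m <- default_model()
  base <- simulate_uncoupled_uptake(m, "etoh_e", 0)
  gr <- default_growth()
  expect_equal(base$growth$mu_star, gr$mu_star)
  expect_equal(base$solution$fluxes, gr$solution$fluxes, tolerance = 1e-8)
})

test_that("forced ethanol influx is conserved through the degradation path", {
  m <- default_model()
  st <- simulate_uncoupled_uptake(m, "etoh_e", 0.5)
  expect_equal(flux_through(m, st$solution, "ADH"), 0.5, tolerance = 1e-7)
  expect_equal(flux_through(m, st$solution, "ALD"), 0.5, tolerance = 1e-7)
  expect_equal(flux_through(m, st$solution, "ACt"), 0.5, tolerance = 1e-7)
  expect_equal(st$solution$fluxes[["EX_ac_e"]], 0.5, tolerance = 1e-7)
})

test_that("sodium influx forces coupled export and exporter expression", {
  m <- default_model()
  base <- simulate_uncoupled_uptake(m, "na_e", 0)
  st <- simulate_uncoupled_uptake(m, "na_e", 2)
  expect_equal(flux_through(m, st$solution, "NAt_out"), 2, tolerance = 1e-6)
  tl_base <- base$solution$fluxes[["TL_natE"]]
  tl_st <- st$solution$fluxes[["TL_natE"]]
  expect_gt(tl_st, tl_base + 1e-6)
})

test_that("tryptophan synthesis rises monotonically with ethanol in the coupled model only", {
  rates <- seq(0, 0.5, by = 0.1)
  sw <- sweep_stressor(default_model(), "etoh_e", rates, tracked = "TRPS2")
  trp <- sw$tracked$flux[order(sw$tracked$rate)]
  expect_length(trp, length(rates))
  expect_false(is.unsorted(trp))
  expect_gt(trp[length(trp)], trp[1])
  # the decoupled (M-like) model shows no variation at all
  swd <- sweep_stressor(decouple_model(default_model()), "etoh_e", rates,
                        tracked = "TRPS2")
  expect_lt(diff(range(swd$tracked$flux)), 1e-8)
})

test_that("total amino-acid synthesis never increases under salt stress", {
  m <- default_model()
  rates <- c(0, 1, 2, 4)
  syn <- vapply(rates, function(r) {
    s <- simulate_uncoupled_uptake(m, "na_e", r)$solution
    sum(vapply(c("ALAS", "GLYS", "LYSS", "TRPS2", "CYSS"),
               function(rx) flux_through(m, s, rx), numeric(1)))
  }, numeric(1))
  expect_false(is.unsorted(rev(syn)))
})

test_that("empty rate lists and unsorted rates are handled", {
  m <- default_model()
  sw <- sweep_stressor(m, "etoh_e", numeric(0))
  expect_equal(nrow(sw$profiles), 0)
  expect_error(sweep_stressor(m, "etoh_e", c(0.2, 0.1)), "increasing")
})

test_that("folate damage drains the pathway at exactly the forced rate", {
  m <- default_model()
  fd <- simulate_folate_damage(m, 0.02)
  expect_equal(flux_through(fd$model, fd$solution, "FOLS"), 0.02, tolerance = 1e-8)
  # zero damage is the baseline
  fd0 <- simulate_folate_damage(m, 0)
  expect_equal(fd0$growth$mu_star, default_growth()$mu_star)
  # transcription of the shared chorismate-branch unit rises with damage
  base_tx <- expression_fluxes(m, fd0$solution)
  dmg_tx <- expression_fluxes(fd$model, fd$solution)
  expect_gt(dmg_tx$transcription[dmg_tx$gene == "trpB"],
            base_tx$transcription[base_tx$gene == "trpB"])
  expect_gt(dmg_tx$translation[dmg_tx$gene == "folE"],
            base_tx$translation[base_tx$gene == "folE"])
})

test_that("profile normalisation maps series to fractions of their maximum", {
  sweep <- structure(list(
    profiles = tibble::tibble(
      gene = rep(c("a", "b", "c"), each = 3),
      rate = rep(1:3, 3),
      transcription = c(2, 4, 8, 5, 5, 5, 0, 0, 0),
      translation = c(1, 2, 4, 0, 0, 0, 3, 3, 3)
    ),
    tracked = tibble::tibble(), growth = tibble::tibble(), metabolite = "x"
  ), class = "stress_sweep")
  ns <- normalize_profiles(sweep)$profiles
  expect_equal(ns$norm_transcription[ns$gene == "a"], c(0.25, 0.5, 1))
  expect_equal(ns$norm_transcription[ns$gene == "b"], c(1, 1, 1))
  expect_equal(ns$norm_transcription[ns$gene == "c"], c(0, 0, 0))
  expect_equal(ns$norm_translation[ns$gene == "c"], c(1, 1, 1))
})

test_that("amino-acid demand attribution is conservative and well-ordered", {
  m <- default_model()
  base <- simulate_uncoupled_uptake(m, "etoh_e", 0)
  st <- simulate_uncoupled_uptake(m, "etoh_e", 0.5)
  at <- attribute_amino_acid_demand(m, base$solution, st$solution, "W")
  expect_equal(sum(at$fraction), 1, tolerance = 1e-9)
  # the tryptophan-rich acetate exporter dominates the increment
  expect_equal(at$gene[1], "ywcA")
  expect_gt(at$fraction[1], 0.5)
  # machinery proteins appear as their own rows
  expect_true(all(c("rpoA", "rpsA", "synS") %in% at$gene))
  expect_error(attribute_amino_acid_demand(m, base$solution, base$solution, "W"),
               "undefined")
})

test_that("attribution assigns everything to a single changing protein", {
  m <- default_model()
  base <- simulate_uncoupled_uptake(m, "etoh_e", 0)
  # doctor a stressed solution where only the reporter's translation moved
  st <- base$solution
  st$fluxes[["TL_amyE"]] <- st$fluxes[["TL_amyE"]] + 1e-3
  comp <- gene_composition(m$spec, "amyE")
  # mirror the extra synthesis in the tryptophan production flux
  st$fluxes[["TRPS2_trpB_cplx"]] <- st$fluxes[["TRPS2_trpB_cplx"]] +
    1e-3 * comp[["W"]]
  at <- attribute_amino_acid_demand(m, base$solution, st, "W")
  expect_equal(at$fraction[at$gene == "amyE"], 1, tolerance = 1e-9)
  expect_equal(sum(at$fraction), 1, tolerance = 1e-9)
})

test_that("differential-expression calls and scoring behave on constructed tables", {
  base <- tibble::tibble(gene = c("a", "b", "c", "d"),
                         transcription = c(1, 1, 1, 0),
                         translation = c(1, 1, 1, 0))
  stress <- tibble::tibble(gene = c("a", "b", "c", "d"),
                           transcription = c(1.5, 0.6, 1.01, 0.5),
                           translation = c(1, 1, 1, 0))
  calls <- differential_expression_calls(base, stress, epsilon = 0.05)
  expect_equal(setNames(calls$call, calls$gene),
               c(a = "up", b = "down", c = "unchanged", d = "up"))
  # reference equal to predictions: accuracy 1 everywhere
  ref <- dplyr::transmute(calls, gene, call, subsystem = c("s1", "s1", "s2", "s2"))
  sc <- score_de(calls, ref)
  expect_equal(sc$overall$accuracy, 1)
  expect_true(all(sc$by_direction$accuracy == 1))
  expect_true(all(sc$by_subsystem$accuracy == 1))
  # half-agreeing reference
  ref2 <- ref
  ref2$call <- c("up", "up", "unchanged", "down")
  sc2 <- score_de(calls, ref2)
  expect_equal(sc2$overall$accuracy, 1 / 3)
  # epsilon larger than any change: everything unchanged, accuracy over
  # reference-changed genes only
  calls3 <- differential_expression_calls(base, stress, epsilon = 10)
  expect_true(all(calls3$call[calls3$gene != "d"] == "unchanged"))
  sc3 <- score_de(calls3, ref)
  expect_equal(sc3$overall$n, 3)
})
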