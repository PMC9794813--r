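test_that("mu substitution evaluates coefficients and is linear in mu", {
  m <- default_model()
  lp0 <- substitute_mu(m, 0)
  # at mu = 0 the matrix has no machinery coupling left (M-like),
  # except the constant mRNA-degradation terms
  coup0 <- m$coupling_mu * 0.2
  lp2 <- substitute_mu(m, 0.2)
  lp4 <- substitute_mu(m, 0.4)
  delta2 <- lp2$S - lp0$S
  delta4 <- lp4$S - lp0$S
  expect_equal(delta4, 2 * delta2)
  # spot-check three coupling entries against hand evaluation
  spec <- m$spec
  expect_equal(lp2$S["ptsG_cplx", "GLCt_ptsG_cplx"], -0.2 / spec$config$keff_secondary)
  expect_equal(lp2$S["enzA_cplx", "GLYC_enzA_cplx"], -0.2 / spec$config$keff_primary)
  expect_equal(lp2$S["synS_cplx", "CHG_ala"], -0.2 / spec$global_rates$keff_synthetase)
  expect_error(substitute_mu(m, -0.1), "mu")
})

test_that("feasibility detects closed and forced infeasible problems", {
  m <- default_model()
  # everything closed at mu 0: the zero flux vector (with the biomass
  # dilution pseudo-flux) is feasible
  closed <- m
  for (rx in exchange_reactions(m)$reaction) closed <- set_bounds(closed, rx, lower = 0)
  s0 <- solve_at_mu(closed, 0)
  expect_equal(s0$status, "feasible")
  expect_true(all(abs(s0$fluxes[names(s0$fluxes) != "biomass_dilution"]) < 1e-9))
  # demanding uptake of a closed nutrient is infeasible
  forced <- set_bounds(m, "EX_etoh_e", lower = -0.5, upper = -0.5)
  forced <- set_bounds(forced, "ADH", upper = 0)
  expect_equal(solve_at_mu(forced, 0.1)$status, "infeasible")
  # far above the optimum the model is infeasible
  expect_equal(solve_at_mu(m, 1.9)$status, "infeasible")
})

test_that("feasible solutions satisfy steady state and bounds within tolerance", {
  m <- default_model()
  s <- solve_at_mu(m, 0.3)
  lp <- substitute_mu(m, 0.3)
  expect_lte(max(abs(lp$S %*% s$fluxes)), 1e-9)
  expect_true(all(s$fluxes >= lp$lb - 1e-9))
  expect_true(all(s$fluxes <= lp$ub + 1e-9))
})

test_that("bisection finds the maximum growth rate within tolerance of the grid oracle", {
  gr <- default_growth()
  oracle <- grid_search_growth(default_model())
  expect_lte(abs(gr$mu_star - oracle$mu_star), 2e-6)
  expect_lte(gr$bracket[2] - gr$bracket[1], 2e-6)
  expect_lte(gr$iterations, ceiling(log2(2 / 1e-6)) + 2)
})

test_that("closing all carbon uptake drives growth to zero", {
  m <- default_model()
  closed <- m
  for (rx in exchange_reactions(m, carbon_only = TRUE)$reaction) {
    closed <- set_bounds(closed, rx, lower = 0)
  }
  expect_equal(maximize_growth(closed)$mu_star, 0)
})

test_that("halving the tolerance refines the bracket without losing the optimum", {
  m <- default_model()
  g1 <- maximize_growth(m, tol = 4e-6)
  g2 <- maximize_growth(m, tol = 2e-6)
  expect_lte(g1$bracket[2] - g1$bracket[1], 8e-6)
  expect_lte(g2$bracket[2] - g2$bracket[1], 4e-6)
  # the finer optimum lies inside the coarser bracket
  expect_gte(g2$mu_star, g1$bracket[1] - 1e-12)
  expect_lte(g2$mu_star, g1$bracket[2] + 1e-12)
})

test_that("feasibility is monotone in mu", {
  m <- default_model()
  mus <- seq(0, 1, by = 0.1)
  feas <- vapply(mus, function(mu) solve_at_mu(m, mu)$status == "feasible",
                 logical(1))
  expect_false(is.unsorted(rev(feas)))  # TRUE..TRUE FALSE..FALSE
})

test_that("knockouts never increase growth and kill by construction", {
  m <- default_model()
  wt <- default_growth()$mu_star
  # sole carbon transporter and a ribosome subunit are lethal
  expect_equal(maximize_growth(knockout_gene(m, "ptsG"))$mu_star, 0)
  expect_equal(maximize_growth(knockout_gene(m, "rpsA"))$mu_star, 0)
  # a non-essential knockout cannot exceed the wild type
  for (g in c("amyE", "natE")) {
    expect_lte(maximize_growth(knockout_gene(m, g))$mu_star, wt + 2e-6)
  }
  expect_error(knockout_gene(m, "nosuchgene"), "unknown")
})

test_that("an isozyme pair is individually dispensable but jointly lethal", {
  fx <- isozyme_model()
  wt <- maximize_growth(fx$model)$mu_star
  mu_a <- maximize_growth(knockout_gene(fx$model, "enzA"))$mu_star
  expect_equal(mu_a, wt, tolerance = 1e-4)
  expect_lt(double_knockout(fx$model, "enzA", "enzB"), 1e-5)
})

test_that("flux comparison reports squared Pearson correlation", {
  sol <- function(v) structure(list(fluxes = v, status = "feasible",
                                    mu = 0.1, residual = 0),
                               class = "flux_solution")
  a <- sol(c(r1 = 1, r2 = 2, r3 = 3))
  cmp <- compare_solutions(a, a)
  expect_equal(glance(cmp)$r_squared, 1)
  b <- sol(c(r1 = 1, r2 = 2, r3 = 3) * c(1.1, 0.9, 1.2))
  cmp2 <- compare_solutions(a, b)
  expect_equal(glance(cmp2)$r_squared,
               cor(log10(a$fluxes), log10(b$fluxes))^2)
  # zeros are excluded
  c3 <- sol(c(r1 = 1, r2 = 0, r3 = 3))
  expect_equal(nrow(compare_solutions(a, c3)), 2)
  expect_error(compare_solutions(a, sol(c(x = 1))), "no shared")
})

test_that("the futile cycle flags the largest coupled/decoupled discrepancy", {
  m <- default_model()
  md <- decouple_model(m)
  mu <- default_growth()$mu_star
  fc <- maximize_flux(m, mu, "FUT1_adhA_cplx", "max", tol = 1e-2)
  fd <- maximize_flux(md, mu, "FUT1_adhA_cplx", "max", tol = 1e-2)
  expect_gte(fd, 100 * max(fc, 1e-9))
})
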