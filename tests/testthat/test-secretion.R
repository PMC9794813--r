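test_that("growth-rate estimation recovers exact exponentials", {
  tc <- tibble::tibble(time = 0:5, biomass = 0.05 * exp(0.2 * (0:5)))
  fit <- suppressWarnings(estimate_growth_rate(tc))
  expect_equal(fit$mu, 0.2, tolerance = 1e-12)
  expect_equal(fit$intercept, log(0.05), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  # constant biomass: zero growth
  fit0 <- suppressWarnings(
    estimate_growth_rate(tibble::tibble(time = 0:4, biomass = rep(2, 5))))
  expect_equal(fit0$mu, 0)
  expect_error(estimate_growth_rate(tibble::tibble(time = 0:1, biomass = c(1, 2))),
               "3 points")
  expect_error(estimate_growth_rate(tibble::tibble(time = 0:3, biomass = c(1, -1, 1, 1))),
               "non-positive")
})

test_that("growth-rate estimation is robust to mild multiplicative noise", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    t <- seq(0, 5, length.out = 8)
    X <- 0.05 * exp(0.2 * t) * exp(stats::rnorm(8, sd = 0.01))
    abs(estimate_growth_rate(tibble::tibble(time = t, biomass = X))$mu - 0.2) / 0.2
  }, numeric(1))
  expect_true(all(errs < 0.05))
})

test_that("secretion-rate estimation matches closed forms", {
  # constant biomass: nu = (Cf - C0) / (X * T)
  tX <- tibble::tibble(time = seq(0, 10, 1), biomass = 1)
  tC <- tibble::tibble(time = tX$time, product = seq(0, 5, 0.5))
  expect_equal(estimate_secretion_rate(tX, tC)$nu, 0.5, tolerance = 1e-12)
  # exponential biomass, closed-form integral, trapezoid error < 1e-3
  t <- seq(0, 5, length.out = 50)
  tX2 <- tibble::tibble(time = t, biomass = exp(0.2 * t))
  cf <- 0.5 * (exp(0.2 * 5) - 1) / 0.2
  tC2 <- tibble::tibble(time = t, product = c(0, rep(cf, 49)))
  tC2$product <- cf * (exp(0.2 * t) - 1) / (exp(0.2 * 5) - 1)  # any path; endpoints matter
  fit <- estimate_secretion_rate(tX2, tC2)
  expect_equal(fit$nu, 0.5, tolerance = 1e-3)
  # constant product: zero secretion
  tC3 <- tibble::tibble(time = t, product = rep(1, 50))
  expect_equal(estimate_secretion_rate(tX2, tC3)$nu, 0)
  expect_error(estimate_secretion_rate(tX2[1:10, ], tC3), "aligned")
})

test_that("activity converts to concentration across the specific-activity range", {
  out <- activity_to_concentration(245000)
  expect_equal(out$concentration_mg_ml[out$specific_activity == 245], 1.0)
  out2 <- activity_to_concentration(1537, c(153.7, 245))
  expect_equal(out2$concentration_mg_ml[out2$specific_activity == 153.7], 0.01)
  expect_lt(out$concentration_mg_ml[2], out$concentration_mg_ml[1])
  # molar conversion from the mature protein sequence
  mw <- peptide_mw("AAAAAAAAGGGGKKKKWW")
  out3 <- activity_to_concentration(245000, molecular_weight = mw)
  expect_equal(out3$concentration_mmol_l,
               out3$concentration_mg_ml / mw * 1000)
  expect_error(activity_to_concentration(100, c(0, 10)), "positive")
})

test_that("exchange envelopes span both condition solutions", {
  m <- starch_model()
  gr <- starch_growth()
  lo <- solve_at_mu(m, 0.9 * gr$mu_star)
  env <- feasible_exchange_bounds(m, list(lo, gr$solution))
  expect_true(all(env$lo <= env$hi))
  va <- lo$fluxes[env$reaction]; vb <- gr$solution$fluxes[env$reaction]
  expect_true(all(va >= env$lo - 1e-12 & va <= env$hi + 1e-12))
  expect_true(all(vb >= env$lo - 1e-12 & vb <= env$hi + 1e-12))
  # identical conditions give degenerate intervals
  env2 <- feasible_exchange_bounds(m, list(lo, lo))
  expect_true(all(env2$hi - env2$lo == 0))
})

test_that("near-optimal sampling honours its growth contract and seed", {
  m <- starch_model()
  gr <- starch_growth()
  ss <- sample_solution_space(m, growth_frac = 0.9, n = 15, seed = 31)
  expect_equal(nrow(ss$fluxes), 15)
  expect_true(all(ss$meta$mu >= 0.9 * gr$mu_star - 1e-9))
  expect_true(all(ss$meta$mu <= gr$mu_star + 1e-9))
  ss2 <- sample_solution_space(m, growth_frac = 0.9, n = 15, seed = 31)
  expect_identical(ss$fluxes, ss2$fluxes)
  # secretion flux across samples stays within the endpoint span (loosely)
  sec <- ss$fluxes[, "TLOC_amyE"]
  expect_true(all(sec >= 0))
})

test_that("forced overexpression reproduces the planted sensitivities", {
  m <- starch_model()
  mu_fix <- round(0.9 * starch_growth()$mu_star, 3)
  lo <- sample_overexpression(m, mu_fix, 1e-5, 2e-5, n = 40, seed = 11)
  hi <- sample_overexpression(m, mu_fix, 6e-5, 8e-5, n = 40, seed = 12)
  # same-seed reproducibility
  lo2 <- sample_overexpression(m, mu_fix, 1e-5, 2e-5, n = 40, seed = 11)
  expect_identical(lo$fluxes, lo2$fluxes)
  comp <- m$spec$ground_truth$reporter_composition
  planted <- c(ALAS = comp[["A"]], GLYS = comp[["G"]], LYSS = comp[["K"]],
               TRPS2 = comp[["W"]])
  for (rx in names(planted)) {
    s <- sensitivity(lo, hi, rx)
    expect_equal(s$sensitivity, planted[[rx]], tolerance = 0.1)
    expect_lt(s$p_value, 1e-6)
  }
  # the cysteine-rich membrane amylase is displaced: planted negative slope
  s_cys <- sensitivity(lo, hi, "CYSS")
  expect_equal(s_cys$sensitivity,
               -m$spec$config$membrane_amylase_cys, tolerance = 0.1)
  # amino-acid synthesis is non-decreasing in forced secretion for
  # reporter amino acids (regression over pooled samples)
  x <- c(lo$meta$secretion, hi$meta$secretion)
  y <- c(rowSums(lo$fluxes[, lo$reactions$base_id == "ALAS", drop = FALSE]),
         rowSums(hi$fluxes[, hi$reactions$base_id == "ALAS", drop = FALSE]))
  expect_gt(coef(lm(y ~ x))[[2]], 0)
})

test_that("overexpression sampling rejects an unreachable secretion range", {
  m <- starch_model()
  mu_fix <- round(0.9 * starch_growth()$mu_star, 3)
  expect_error(sample_overexpression(m, mu_fix, 1e-5, 1, n = 3, seed = 1),
               "maximum feasible secretion")
  expect_error(sample_overexpression(m, mu_fix, 0.5, 1, n = 3, seed = 1),
               "secretion_lo")
})

test_that("the sensitivity formula and degenerate cases are exact", {
  fake <- function(vals, r) {
    structure(list(
      fluxes = matrix(vals, ncol = 1, dimnames = list(NULL, "SYN")),
      meta = tibble::tibble(sample = seq_along(vals), mu = 0.1, secretion = r),
      reactions = tibble::tibble(id = "SYN", base_id = "SYN", rtype = "metabolic",
                                 subsystem = "s"),
      seed = 1, condition = "fake"
    ), class = "sample_set")
  }
  lo <- fake(rep(1, 10), 1); hi <- fake(rep(2, 10), 3)
  s <- sensitivity(lo, hi, "SYN")
  expect_equal(s$sensitivity, 0.5)
  # identical distributions: zero sensitivity, p about 1
  s0 <- sensitivity(fake(rep(1, 10), 1), fake(rep(1, 10), 3), "SYN")
  expect_equal(s0$sensitivity, 0)
  expect_equal(s0$p_value, 1)
  expect_error(sensitivity(lo, fake(rep(2, 10), 1), "SYN"), "distinct")
})

test_that("outliers beyond the confidence band are removed before averaging", {
  set.seed(9)
  vals <- c(rnorm(50, 10, 0.1), 50)  # one gross outlier
  fake <- structure(list(
    fluxes = matrix(vals, ncol = 1, dimnames = list(NULL, "SYN")),
    meta = tibble::tibble(sample = seq_along(vals), mu = 0.1, secretion = 1),
    reactions = tibble::tibble(id = "SYN", base_id = "SYN", rtype = "metabolic",
                               subsystem = "s"),
    seed = 1, condition = "fake"
  ), class = "sample_set")
  base <- structure(fake, class = "sample_set")
  base$fluxes <- matrix(rnorm(51, 5, 0.1), ncol = 1,
                        dimnames = list(NULL, "SYN"))
  base$meta$secretion <- 0
  s <- sensitivity(base, fake, "SYN")
  expect_equal(s$n_high, 50)          # the outlier is gone
  expect_equal(s$x_bar_high, 10, tolerance = 0.01)
})

test_that("PCA separates constructed clusters with orthonormal loadings", {
  set.seed(4)
  mk <- function(center, label) {
    fx <- cbind(matrix(rnorm(30 * 5, center, 0.05), 30, 5),
                matrix(1, 30, 2))  # two constant reactions to drop
    colnames(fx) <- paste0("r", 1:7)
    structure(list(
      fluxes = fx,
      meta = tibble::tibble(sample = 1:30, mu = 0.1),
      reactions = tibble::tibble(id = paste0("r", 1:7),
                                 base_id = paste0("r", 1:7),
                                 rtype = "metabolic",
                                 subsystem = rep(c("s1", "s2"), c(4, 3))),
      seed = 1, condition = label
    ), class = "sample_set")
  }
  sets <- list(mk(0, "low"), mk(5, "high"))
  pca <- pca_fluxes(sets)
  expect_gt(pca$variance$variance_fraction[1], 0.9)
  # PC1 separates the two conditions
  sc <- pca$scores
  expect_true(max(sc$PC1[sc$condition == "low"]) <
                min(sc$PC1[sc$condition == "high"]) ||
              min(sc$PC1[sc$condition == "low"]) >
                max(sc$PC1[sc$condition == "high"]))
  # loadings orthonormal, variance fractions a partition
  L <- as.matrix(pca$loadings[, -1])
  expect_equal(t(L) %*% L, diag(ncol(L)), tolerance = 1e-9, ignore_attr = TRUE)
  expect_lte(sum(pca$variance$variance_fraction), 1 + 1e-12)
  # invariance under reaction reordering (up to sign)
  perm <- c(3, 1, 2, 5, 4, 7, 6)
  sets_p <- lapply(sets, function(s) {
    s$fluxes <- s$fluxes[, perm]
    s$reactions <- s$reactions[perm, ]
    s
  })
  pca_p <- pca_fluxes(sets_p)
  expect_equal(pca_p$variance$variance_fraction,
               pca$variance$variance_fraction, tolerance = 1e-9)
  expect_equal(abs(pca_p$scores$PC1), abs(pca$scores$PC1), tolerance = 1e-9)
})

test_that("composition-sensitivity regression finds planted structure", {
  pep <- paste(rep(c("A", "G", "K", "W", "C"), c(4, 3, 1, 1, 1)), collapse = "")
  counts <- c(A = 4, G = 3, K = 1, W = 1, C = 1)
  frac <- counts / 10
  expect_equal(sum(frac), 1)
  # sensitivities exactly proportional to molar fraction: R^2 = 1
  sens <- 7 * frac
  cv <- suppressWarnings(composition_vs_sensitivity(pep, sens))
  expect_equal(cv$fit_all$r_squared, 1, tolerance = 1e-12)
  expect_equal(cv$fit_all$slope, 7, tolerance = 1e-9)
  # a planted gross outlier is flagged and excluded from the trimmed fit
  sens2 <- sens; sens2[["C"]] <- 5
  cv2 <- suppressWarnings(composition_vs_sensitivity(pep, sens2))
  expect_true(cv2$data$outlier[cv2$data$aa == "C"])
  expect_equal(cv2$fit_trimmed$n, 4)
  expect_equal(cv2$fit_trimmed$slope, 7, tolerance = 1e-6)
  expect_error(composition_vs_sensitivity(pep, sens[1:2]), "at least 3")
})
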