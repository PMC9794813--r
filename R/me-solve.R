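# Solving a mu-substituted ME model.
#
# At a fixed growth rate mu the model is the linear feasibility problem
# {S(mu) v = 0, lb(mu) <= v <= ub(mu)}. Feasibility is tested by finding the
# minimum-norm feasible point with a strictly convex quadratic program
# (Goldfarb-Idnani, quadprog); this doubles as the deterministic secondary
# objective that stabilises reported flux vectors. Growth maximisation is a
# binary search over mu against this feasibility oracle; linear maximisation
# of a single flux is a binary search on that flux's lower bound.

#' Substitute a growth rate into a model
#'
#' Evaluates every growth-rate-dependent coefficient and bound at `mu`,
#' yielding an ordinary linear problem `S v = 0` with finite bounds.
#'
#' @param model An `me_model`.
#' @param mu Growth rate (1/h), non-negative.
#' @return A `linear_problem` list with elements `S`, `lb`, `ub`, `b`, `mu`.
#' @export
substitute_mu <- function(model, mu) {
  stopifnot_scalar_number(mu, "mu", min = 0)
  lp <- list(
    S = model$S0 + mu * model$S1,
    lb = model$reactions$lb_const + mu * model$reactions$lb_mu,
    ub = model$reactions$ub_const + mu * model$reactions$ub_mu,
    b = rep(0, nrow(model$S0)),
    reaction_ids = model$reactions$id,
    species_ids = model$species$id,
    mu = mu
  )
  names(lp$lb) <- names(lp$ub) <- lp$reaction_ids
  class(lp) <- "linear_problem"
  lp
}

#' Test feasibility of a linear problem
#'
#' Returns the minimum-norm feasible flux vector when the problem is
#' feasible, or an infeasible-status solution otherwise. A post-solve
#' residual check (`|S v - b| <= feas_tol` componentwise) guards against
#' silent numerical failure; residual violations are raised as numerical
#' errors, distinct from infeasibility.
#'
#' @param lp A [substitute_mu()] result.
#' @param feas_tol Feasibility tolerance on the steady-state residual.
#' @return A `flux_solution` with fields `fluxes`, `status`
#'   (`"feasible"`/`"infeasible"`), `mu`, `residual`.
#' @export
check_feasible <- function(lp, feas_tol = 1e-9) {
  n <- length(lp$lb)
  lb <- lp$lb; ub <- lp$ub
  if (any(lb > ub + feas_tol)) {
    return(new_flux_solution(NULL, "infeasible", lp))
  }

  # -- presolve: propagate structural zeros ---------------------------------
  # A species with no remaining producer forces all its consumers to zero
  # (and vice versa). Iterating to a fixpoint prunes the flux-incapable
  # block (e.g. everything downstream of a knocked-out translation), which
  # both detects many infeasibilities outright and removes the degenerate
  # zero-bound structure that active-set QP solvers handle poorly.
  S <- lp$S
  b <- lp$b
  repeat {
    # structural signs are exact: the matrix is constructed, not measured,
    # and quadprog enforces the equalities exactly, so even a tiny coupling
    # coefficient makes a species row live
    pos <- (S > 0) ; neg <- (S < 0)
    can_up <- ub > 0             # can carry positive flux
    can_dn <- lb < 0             # can carry negative flux
    no_prod <- (rowSums(pos[, can_up, drop = FALSE]) +
                  rowSums(neg[, can_dn, drop = FALSE])) == 0
    no_cons <- (rowSums(neg[, can_up, drop = FALSE]) +
                  rowSums(pos[, can_dn, drop = FALSE])) == 0
    # fixed inflow from eliminated variables must be absorbable
    if (any(no_prod & b < -feas_tol) || any(no_cons & b > feas_tol)) {
      return(new_flux_solution(NULL, "infeasible", lp))
    }
    changed <- FALSE
    dead_rows <- which((no_prod | no_cons) & abs(b) <= feas_tol)
    for (i in dead_rows) {
      # all sign-capable participants of a dead row must vanish
      js <- which((pos[i, ] | neg[i, ]) & (can_up | can_dn))
      for (j in js) {
        if (lb[j] > feas_tol || ub[j] < -feas_tol) {
          return(new_flux_solution(NULL, "infeasible", lp))
        }
        if (ub[j] > 0) { ub[j] <- 0; changed <- TRUE }
        if (lb[j] < 0) { lb[j] <- 0; changed <- TRUE }
      }
    }
    if (!changed) break
  }

  fixed <- which(ub - lb < 1e-12)
  free <- setdiff(seq_len(n), fixed)
  vfix <- (lb + ub)[fixed] / 2
  if (length(fixed)) b <- b - as.vector(S[, fixed, drop = FALSE] %*% vfix)
  Sf <- S[, free, drop = FALSE]
  empty <- rowSums(abs(Sf)) == 0
  if (any(empty & abs(b) > feas_tol)) {
    return(new_flux_solution(NULL, "infeasible", lp))
  }
  Sf <- Sf[!empty, , drop = FALSE]
  b2 <- b[!empty]
  nf <- length(free)
  assemble <- function(vfree) {
    v <- numeric(n)
    v[free] <- vfree
    v[fixed] <- vfix
    v <- pmin(pmax(v, lp$lb - feas_tol), lp$ub + feas_tol)
    names(v) <- lp$reaction_ids
    v
  }
  if (nf == 0) {
    v <- assemble(numeric(0))
    resid <- max(abs(lp$S %*% v - lp$b), 0)
    status <- if (resid <= feas_tol) "feasible" else "infeasible"
    return(new_flux_solution(v, status, lp, resid))
  }
  sc <- pmax(apply(abs(Sf), 1, max), 1e-12)
  fit <- tryCatch(
    quadprog::solve.QP(
      Dmat = diag(nf), dvec = rep(0, nf),
      Amat = cbind(t(Sf / sc), diag(nf), -diag(nf)),
      bvec = c(b2 / sc, lb[free], -ub[free]),
      meq = nrow(Sf)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    msg <- conditionMessage(fit)
    if (grepl("constraints are inconsistent", msg)) {
      return(new_flux_solution(NULL, "infeasible", lp))
    }
    abort(sprintf("LP solver failure (numerical error, not infeasibility): %s", msg),
          class = "minime_numerical_error")
  }
  v <- assemble(fit$solution)
  resid <- max(abs(lp$S %*% v - lp$b))
  if (resid > sqrt(feas_tol)) {
    abort(sprintf("solver returned residual %.3e above tolerance", resid),
          class = "minime_numerical_error")
  }
  new_flux_solution(v, "feasible", lp, resid)
}

new_flux_solution <- function(fluxes, status, lp, residual = NA_real_) {
  structure(list(fluxes = fluxes, status = status, mu = lp$mu,
                 residual = residual),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status: %s, mu = %g", x$status, x$mu))
  if (x$status == "feasible") {
    cat(sprintf(", %d reactions, residual %.2e", length(x$fluxes), x$residual))
  }
  cat("\n")
  invisible(x)
}

#' Solve a model at a fixed growth rate
#'
#' Convenience wrapper: [substitute_mu()] then [check_feasible()].
#'
#' @inheritParams substitute_mu
#' @inheritParams check_feasible
#' @export
solve_at_mu <- function(model, mu, feas_tol = 1e-9) {
  check_feasible(substitute_mu(model, mu), feas_tol = feas_tol)
}

#' Maximise growth rate by binary search
#'
#' Finds the maximum feasible growth rate by bisection over the feasibility
#' oracle: a candidate mu is substituted into all symbolic coefficients and
#' the resulting linear program is tested for feasibility. Relies on the
#' (empirically asserted) monotonicity of feasibility in mu.
#'
#' @param model An `me_model`.
#' @param mu_min,mu_max Search bracket (1/h).
#' @param tol Bracket half-width at termination (1/h).
#' @param feas_tol Feasibility tolerance passed to [check_feasible()].
#' @return A `growth_result`: `mu_star`, `bracket` (feasible lo, infeasible
#'   hi), `solution` (flux solution at `mu_star`), `iterations`.
#' @export
maximize_growth <- function(model, mu_min = 0, mu_max = 2, tol = 1e-6,
                            feas_tol = 1e-9) {
  stopifnot_scalar_number(tol, "tol", min = 1e-15)
  lo_sol <- solve_at_mu(model, mu_min, feas_tol)
  if (lo_sol$status != "feasible") {
    abort(sprintf("no growth: model infeasible at mu_min = %g", mu_min))
  }
  hi_sol <- solve_at_mu(model, mu_max, feas_tol)
  if (hi_sol$status == "feasible") {
    warn(sprintf("bracket saturated: model still feasible at mu_max = %g", mu_max))
    return(structure(list(mu_star = mu_max, bracket = c(mu_max, mu_max),
                          solution = hi_sol, iterations = 2L),
                     class = "growth_result"))
  }
  lo <- mu_min; hi <- mu_max
  iters <- 2L
  best <- lo_sol
  while (hi - lo > 2 * tol) {
    mid <- (lo + hi) / 2
    sol <- solve_at_mu(model, mid, feas_tol)
    iters <- iters + 1L
    if (sol$status == "feasible") {
      lo <- mid; best <- sol
    } else {
      hi <- mid
    }
  }
  structure(list(mu_star = lo, bracket = c(lo, hi), solution = best,
                 iterations = iters),
            class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat(sprintf("<growth_result> mu* = %.6f 1/h (bracket [%.6f, %.6f], %d LP solves)\n",
              x$mu_star, x$bracket[1], x$bracket[2], x$iterations))
  invisible(x)
}

#' Maximise growth rate by staged dense grid search
#'
#' Reference method used to cross-check [maximize_growth()]: scans a dense
#' mu grid for the feasible/infeasible transition, then refines the grid
#' around the transition until the step reaches `tol/2`. Shares only the
#' feasibility oracle with the bisection path, not its search trajectory.
#'
#' @inheritParams maximize_growth
#' @param refine Grid-shrink factor per stage.
#' @return List with `mu_star`, `solves` (number of LP feasibility tests).
#' @export
grid_search_growth <- function(model, mu_min = 0, mu_max = 2, tol = 1e-6,
                               refine = 20, feas_tol = 1e-9) {
  lo <- mu_min; hi <- mu_max
  solves <- 0L
  step <- (hi - lo) / 40
  repeat {
    grid <- seq(lo, hi, by = step)
    feas <- rep(NA, length(grid))
    last_ok <- NA
    for (i in seq_along(grid)) {
      s <- solve_at_mu(model, grid[i], feas_tol)
      solves <- solves + 1L
      feas[i] <- s$status == "feasible"
      if (feas[i]) last_ok <- i else break
    }
    if (is.na(last_ok)) {
      abort(sprintf("no growth: model infeasible at mu = %g", grid[1]))
    }
    lo <- grid[last_ok]
    hi <- if (last_ok < length(grid)) grid[last_ok + 1] else hi
    if (step <= tol / 2) break
    step <- max(step / refine, tol / 2)
  }
  list(mu_star = lo, solves = solves)
}

#' Knock out a gene
#'
#' Models a single-gene knockout by closing the gene's translation reaction
#' (bounds set to zero); everything else is untouched.
#'
#' @param model An `me_model`.
#' @param gene_id Protein-coding gene id.
#' @return The modified model.
#' @export
knockout_gene <- function(model, gene_id) {
  idx <- which(model$reactions$id == paste0("TL_", gene_id))
  if (length(idx) != 1) abort(sprintf("unknown protein-coding gene '%s'", gene_id))
  model$reactions$lb_const[idx] <- 0
  model$reactions$lb_mu[idx] <- 0
  model$reactions$ub_const[idx] <- 0
  model$reactions$ub_mu[idx] <- 0
  model
}

#' Maximise or minimise one flux at fixed growth rate
#'
#' Flux-variability-style query: binary search on the reaction's bound
#' against the LP feasibility oracle.
#'
#' @param model An `me_model`.
#' @param mu Growth rate at which to query.
#' @param reaction Reaction id.
#' @param direction `"max"` or `"min"`.
#' @param tol Absolute tolerance on the returned optimum.
#' @return The optimal flux value (within `tol`).
#' @export
maximize_flux <- function(model, mu, reaction, direction = c("max", "min"),
                          tol = 1e-3, feas_tol = 1e-9) {
  direction <- match.arg(direction)
  lp <- substitute_mu(model, mu)
  j <- which(lp$reaction_ids == reaction)
  if (length(j) != 1) abort(sprintf("unknown reaction '%s'", reaction))
  base <- check_feasible(lp, feas_tol)
  if (base$status != "feasible") abort("model infeasible at the requested mu")
  lo <- base$fluxes[[j]]
  hi <- if (direction == "max") lp$ub[[j]] else lp$lb[[j]]
  probe <- function(t) {
    lp2 <- lp
    if (direction == "max") lp2$lb[j] <- t else lp2$ub[j] <- t
    check_feasible(lp2, feas_tol)$status == "feasible"
  }
  if (probe(hi)) return(hi)
  while (abs(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    if (probe(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Compare two flux solutions on shared reactions
#'
#' Pairs log10 fluxes of the shared reactions (values below
#' `zero_threshold` in either solution are excluded) and reports the
#' squared Pearson correlation, the comparison used to contrast coupled and
#' decoupled model variants.
#'
#' @param sol_a,sol_b Feasible `flux_solution` objects.
#' @param shared_reactions Reaction ids to compare; defaults to the
#'   intersection of the two flux vectors' names.
#' @param zero_threshold Fluxes at or below this magnitude count as zero.
#' @return A `flux_comparison` tibble (`reaction`, `flux_a`, `flux_b`,
#'   `log10_a`, `log10_b`, `abs_log_diff`) with the correlation available
#'   via [glance()].
#' @export
compare_solutions <- function(sol_a, sol_b, shared_reactions = NULL,
                              zero_threshold = 1e-9) {
  if (sol_a$status != "feasible" || sol_b$status != "feasible") {
    abort("both solutions must be feasible")
  }
  shared <- shared_reactions %||% intersect(names(sol_a$fluxes), names(sol_b$fluxes))
  if (length(shared) == 0) abort("no shared reactions to compare")
  a <- abs(sol_a$fluxes[shared])
  b <- abs(sol_b$fluxes[shared])
  keep <- a > zero_threshold & b > zero_threshold
  out <- tibble(
    reaction = shared[keep],
    flux_a = a[keep], flux_b = b[keep],
    log10_a = log10(a[keep]), log10_b = log10(b[keep])
  ) |>
    mutate(abs_log_diff = abs(.data$log10_a - .data$log10_b)) |>
    arrange(desc(.data$abs_log_diff))
  r2 <- if (nrow(out) >= 2 && sd(out$log10_a) > 0 && sd(out$log10_b) > 0) {
    cor(out$log10_a, out$log10_b)^2
  } else if (nrow(out) >= 1 && all(out$log10_a == out$log10_b)) 1 else NA_real_
  attr(out, "r_squared") <- r2
  class(out) <- c("flux_comparison", class(out))
  out
}

#' @export
glance.flux_comparison <- function(x, ...) {
  tibble(r_squared = attr(x, "r_squared"), n = nrow(x))
}

#' @rdname tidy_minime
#' @export
tidy.flux_solution <- function(x, ...) {
  if (x$status != "feasible") return(tibble(reaction = character(), flux = numeric()))
  tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' @rdname tidy_minime
#' @export
glance.growth_result <- function(x, ...) {
  tibble(mu_star = x$mu_star, bracket_lo = x$bracket[1],
         bracket_hi = x$bracket[2], iterations = x$iterations)
}
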