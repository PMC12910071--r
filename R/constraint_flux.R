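# ---------------------------------------------------------------------------
# Solver layer: FBA, alpha-suboptimal FVA, ACHR flux sampling, pFBA and the
# maximal-NADH-capacity procedure.
# ---------------------------------------------------------------------------

new_flux_solution <- function(fluxes, objective_value, status, method) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status, method = method),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> %s: status=%s, objective=%g\n",
              x$method, x$status,
              if (is.na(x$objective_value)) NA else x$objective_value))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the linear objective `c^T v` subject to steady state
#' (`S v = 0`) and box bounds. Infeasible or iteration-limited solves are
#' reported in `status`, never silently zeroed.
#'
#' @param model A validated `"gem"` object.
#' @param objective Optional named objective override (reaction id ->
#'   coefficient); defaults to the model's objective.
#' @param maximize Logical; maximize (default) or minimize.
#' @return A `"flux_solution"`: named `fluxes`, `objective_value`, `status`.
#' @export
run_fba <- function(model, objective = NULL, maximize = TRUE) {
  validate_gem(model)
  parts <- lp_parts(model)
  obj <- objective_vector(model, objective)
  res <- solve_lp(obj, parts$S, parts$lb, parts$ub, maximize = maximize)
  new_flux_solution(
    fluxes = if (res$status == "optimal") setNames(res$x, parts$ids) else
      setNames(rep(NA_real_, length(parts$ids)), parts$ids),
    objective_value = res$objective, status = res$status, method = "fba")
}

#' Flux variability analysis
#'
#' For each reaction, minimizes and maximizes its flux subject to steady
#' state, bounds, and the optimality constraint `c^T v >= alpha * z_opt`,
#' where `z_opt` is the common FBA optimum. `alpha = 1` pins the objective at
#' its optimum; `alpha = 0` drops the constraint entirely.
#'
#' @param model A `"gem"` object.
#' @param alpha Optimality fraction in `[0, 1]`; the default 0.9 allows a
#'   small deviation from optimality so near-optimal alternatives are
#'   explored.
#' @param reactions Optional subset of reaction ids (default: all).
#' @param objective Optional objective override.
#' @param keep_solutions Keep the per-solve flux vectors (used as sampler
#'   warm-up points).
#' @return A `"fva_result"`: `data.frame(reaction, min, max)` in `$ranges`,
#'   plus `alpha`, `z_opt` and optionally `solutions` (n_rxn x n_solves).
#' @export
run_fva <- function(model, alpha = 0.9, reactions = NULL, objective = NULL,
                    keep_solutions = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1)
  validate_gem(model)
  parts <- lp_parts(model)
  has_obj <- length(model$objective) > 0 || !is.null(objective)
  A_ge <- NULL; b_ge <- NULL; z_opt <- NA_real_
  if (has_obj) {
    obj <- objective_vector(model, objective)
    base <- solve_lp(obj, parts$S, parts$lb, parts$ub, maximize = TRUE)
    if (base$status != "optimal")
      stop("base FBA problem is ", base$status, "; FVA aborted")
    z_opt <- base$objective
    if (alpha > 0) {
      A_ge <- matrix(obj, nrow = 1)
      b_ge <- alpha * z_opt
    }
  }
  if (is.null(reactions)) reactions <- parts$ids
  idx <- rxn_index(model, reactions)
  n <- length(parts$ids)
  ranges <- data.frame(reaction = reactions,
                       min = NA_real_, max = NA_real_,
                       stringsAsFactors = FALSE)
  sols <- if (keep_solutions)
    matrix(NA_real_, nrow = n, ncol = 2L * length(idx),
           dimnames = list(parts$ids, NULL)) else NULL
  for (k in seq_along(idx)) {
    e <- numeric(n); e[idx[k]] <- 1
    lo <- solve_lp(e, parts$S, parts$lb, parts$ub, maximize = FALSE,
                   A_ge = A_ge, b_ge = b_ge)
    hi <- solve_lp(e, parts$S, parts$lb, parts$ub, maximize = TRUE,
                   A_ge = A_ge, b_ge = b_ge)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem not optimal for reaction ", reactions[k])
    ranges$min[k] <- lo$objective
    ranges$max[k] <- hi$objective
    if (keep_solutions) {
      sols[, 2 * k - 1] <- lo$x
      sols[, 2 * k] <- hi$x
    }
  }
  # numerical guard: min can exceed max by solver tolerance only
  sw <- ranges$min > ranges$max
  if (any(sw)) {
    mid <- (ranges$min[sw] + ranges$max[sw]) / 2
    ranges$min[sw] <- ranges$max[sw] <- mid
  }
  structure(list(ranges = ranges, alpha = alpha, z_opt = z_opt,
                 solutions = sols),
            class = "fva_result")
}

#' @export
print.fva_result <- function(x, ...) {
  cat(sprintf("<fva_result> %d reactions, alpha=%g, z_opt=%g\n",
              nrow(x$ranges), x$alpha, x$z_opt))
  invisible(x)
}

#' Hit-and-run flux sampling
#'
#' Draws points from the steady-state flux polytope with an
#' artificial-centering hit-and-run chain. Reaction bounds are first replaced
#' by the FVA minimum/maximum fluxes (the conventional tightening before
#' sampling); warm-up points are the FVA extreme-point solutions, so every
#' chain state lies in the steady-state affine subspace by construction, and
#' states are re-projected onto it at every collected sample to keep
#' numerical drift below tolerance.
#'
#' @param model A `"gem"` object.
#' @param fva Optional `"fva_result"` run with `keep_solutions = TRUE`; when
#'   missing it is computed at `alpha`.
#' @param n_samples Number of samples (the full-scale convention is 10,000;
#'   scale down for small studies).
#' @param seed Integer seed; the chain is reproducible bit-for-bit.
#' @param thinning Chain steps between collected samples.
#' @param alpha Optimality fraction for the implicit FVA when `fva` is NULL.
#' @return A `"flux_sample_set"`: `samples` (n_samples x n_reactions),
#'   `n`, per-reaction `stats` (mean, var, median), `seed`.
#' @export
sample_fluxes <- function(model, fva = NULL, n_samples = 1000, seed,
                          thinning = 100, alpha = 0.9) {
  stopifnot(n_samples >= 1)
  if (missing(seed)) stop("sampling requires an explicit seed")
  validate_gem(model)
  if (is.null(fva)) {
    fva <- run_fva(model, alpha = alpha, keep_solutions = TRUE)
  }
  if (is.null(fva$solutions))
    stop("fva must be run with keep_solutions = TRUE to provide warm-up points")
  ids <- model$reactions$id
  stopifnot(identical(fva$ranges$reaction, ids))
  lb <- fva$ranges$min
  ub <- fva$ranges$max

  span <- ub - lb
  if (all(span <= 1e-9)) {
    warning("flux polytope is a single point; returning identical samples")
    pt <- (lb + ub) / 2
    samples <- matrix(rep(pt, each = n_samples), nrow = n_samples,
                      dimnames = list(NULL, ids))
  } else {
    S <- as.matrix(stoich_matrix(model))
    # projection onto the null space of S (for drift control)
    sv <- svd(S)
    pos <- sv$d > max(dim(S)) * max(sv$d, 1e-12) * 1e-12
    V1 <- sv$v[, pos, drop = FALSE]
    proj <- diag(length(ids)) - V1 %*% t(V1)
    warm <- fva$solutions
    set.seed(as.integer(seed))
    samples <- achr_sample(warm, lb, ub, as.integer(n_samples),
                           as.integer(thinning), proj)
    colnames(samples) <- ids
  }
  structure(list(samples = samples, n = n_samples,
                 stats = data.frame(
                   reaction = ids,
                   mean = colMeans(samples),
                   var = apply(samples, 2, var),
                   median = apply(samples, 2, median),
                   stringsAsFactors = FALSE, row.names = NULL),
                 seed = seed, alpha = fva$alpha),
            class = "flux_sample_set")
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat(sprintf("<flux_sample_set> %d samples x %d reactions (seed %s)\n",
              x$n, ncol(x$samples), format(x$seed)))
  invisible(x)
}

#' Median fluxes of a sample set
#'
#' The median sampled flux is the representative flux value used by all
#' downstream differential comparisons.
#'
#' @param samples A `"flux_sample_set"`.
#' @return Named numeric vector of per-reaction medians.
#' @export
median_fluxes <- function(samples) {
  setNames(samples$stats$median, samples$stats$reaction)
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP: the objective is first optimized by FBA, then, on the
#' irreversible-split network with the objective pinned at its optimum, the
#' total flux `sum_j v_irrev,j` is minimized. Net fluxes are mapped back via
#' the split mapping.
#'
#' @param model A `"gem"` object.
#' @param objective Optional objective override.
#' @param gene_associated_only Minimize only over gene-associated reactions
#'   (classic variant) instead of all reactions (default `FALSE`).
#' @return A `"flux_solution"` with net `fluxes`; attribute `total_flux`
#'   holds the minimized total.
#' @export
run_pfba <- function(model, objective = NULL, gene_associated_only = FALSE) {
  validate_gem(model)
  fba <- run_fba(model, objective = objective)
  if (fba$status != "optimal")
    stop("FBA stage of pFBA is ", fba$status)
  obj_named <- if (is.null(objective)) model$objective else objective

  split <- to_irreversible(model)
  sm <- split$model
  # pin the objective at its FBA optimum: c^T v >= z and c^T v <= z
  parts <- lp_parts(sm)
  obj_full <- objective_vector(sm, obj_named[names(obj_named) %in% parts$ids])
  # reverse partners of objective reactions carry -coefficient
  for (i in seq_len(nrow(split$mapping))) {
    m <- split$mapping[i, ]
    if (m$id %in% names(obj_named) && !is.na(m$reverse)) {
      obj_full[match(m$reverse, parts$ids)] <- -obj_named[[m$id]]
    }
    if (m$id %in% names(obj_named) && m$flipped) {
      obj_full[match(m$forward, parts$ids)] <- -obj_named[[m$id]]
    }
  }
  w <- rep(1, length(parts$ids))
  if (gene_associated_only) w <- as.numeric(sm$reactions$gpr != "")
  z <- fba$objective_value
  res <- solve_lp(w, rbind(parts$S, obj_full), parts$lb, parts$ub,
                  maximize = FALSE,
                  beq = c(numeric(nrow(parts$S)), z))
  if (res$status != "optimal")
    stop("pFBA minimization stage is ", res$status)
  v_split <- setNames(res$x, parts$ids)
  v_net <- net_fluxes(v_split, split$mapping)
  out <- new_flux_solution(fluxes = v_net,
                           objective_value = z,
                           status = "optimal", method = "pfba")
  attr(out, "total_flux") <- sum(w * res$x)
  out
}

#' Maximal NADH production capacity
#'
#' Adds nothing itself: the artificial NADH demand reaction must already be
#' present (see [add_demand_reaction()] / [nadh_demand_spec()]). The biomass
#' objective is first optimized by FBA; the biomass lower bound is then fixed
#' at `fraction` of that optimum and pFBA is performed maximizing the demand
#' reaction. The capacity is the demand flux.
#'
#' @param model A `"gem"` object containing the demand reaction.
#' @param demand_id Reaction id of the NADH demand.
#' @param biomass_id Reaction id of the biomass objective.
#' @param fraction Fraction of the biomass optimum enforced as a lower bound
#'   (default 0.5).
#' @return List with `capacity` (demand flux) and `solution` (the pFBA
#'   `"flux_solution"`).
#' @export
nadh_max_capacity <- function(model, demand_id, biomass_id, fraction = 0.5) {
  stopifnot(fraction >= 0, fraction <= 1)
  rxn_index(model, c(demand_id, biomass_id))
  fba <- run_fba(model, objective = setNames(1, biomass_id))
  if (fba$status != "optimal")
    stop("biomass FBA is ", fba$status, "; cannot evaluate NADH capacity")
  m2 <- set_bounds(model, biomass_id, lower = fraction * fba$objective_value)
  m2$objective <- setNames(1, demand_id)
  sol <- tryCatch(run_pfba(m2),
                  error = function(e)
                    stop("NADH capacity stage infeasible at fraction ",
                         fraction, ": ", conditionMessage(e)))
  list(capacity = unname(sol$fluxes[demand_id]), solution = sol)
}

#' Mass-balance residual of a flux vector
#'
#' @param model A `"gem"` object.
#' @param fluxes Named flux vector.
#' @return `max |S v|`, the worst steady-state violation.
#' @export
mass_balance_residual <- function(model, fluxes) {
  S <- stoich_matrix(model)
  v <- fluxes[colnames(S)]
  max(abs(as.vector(S %*% v)))
}
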