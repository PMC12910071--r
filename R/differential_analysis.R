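# ---------------------------------------------------------------------------
# Condition-comparison statistics: cross-method differential-flux consensus,
# reaction- and pathway-level two-sample Z-tests, and flux sensitivity
# coefficients.
# ---------------------------------------------------------------------------

direction_call <- function(delta, threshold) {
  ifelse(delta > threshold, "increased",
         ifelse(delta < -threshold, "decreased", "unchanged"))
}

#' Cross-method differential-flux consensus
#'
#' Compares per-reaction fluxes between a reference and a perturbed
#' condition for each of the three methods (FBA, pFBA, FVA-sampling
#' medians), calls each reaction increased/decreased/unchanged per method by
#' a flux-difference threshold, and forms the consensus sets of reactions on
#' which all methods agree.
#'
#' @param ref,cond Named lists of per-method named flux vectors; names must
#'   include the same methods on both sides (conventionally `fba`, `pfba`,
#'   `sampling`). Sampling is represented by median fluxes.
#' @param threshold Flux-difference threshold (default 1, adjustable for
#'   stringency).
#' @return A `"differential_flux_result"`: `table` with per-method deltas
#'   and direction calls plus `consensus`; `sets$increased` / `sets$decreased`
#'   hold the consensus reaction ids; `membership` is the UpSet-style
#'   per-method call matrix.
#' @export
differential_fluxes <- function(ref, cond, threshold = 1) {
  methods <- names(ref)
  stopifnot(length(methods) >= 1, setequal(methods, names(cond)))
  universe <- names(ref[[1]])
  for (m in methods) {
    if (!setequal(names(ref[[m]]), universe) ||
        !setequal(names(cond[[m]]), universe)) {
      diff <- union(setdiff(names(cond[[m]]), universe),
                    union(setdiff(names(ref[[m]]), universe),
                          setdiff(universe, union(names(ref[[m]]),
                                                  names(cond[[m]])))))
      stop("reaction universes differ across methods/conditions: ",
           paste(head(diff, 10), collapse = ", "))
    }
  }
  tab <- data.frame(reaction = universe, stringsAsFactors = FALSE)
  dirs <- matrix("", nrow = length(universe), ncol = length(methods),
                 dimnames = list(universe, methods))
  for (m in methods) {
    delta <- cond[[m]][universe] - ref[[m]][universe]
    tab[[paste0("delta_", m)]] <- unname(delta)
    dirs[, m] <- direction_call(unname(delta), threshold)
    tab[[paste0("dir_", m)]] <- dirs[, m]
  }
  agree <- function(lab) rowSums(dirs == lab) == length(methods)
  consensus <- rep("none", length(universe))
  consensus[agree("increased")] <- "increased"
  consensus[agree("decreased")] <- "decreased"
  tab$consensus <- consensus
  structure(list(table = tab,
                 sets = list(increased = universe[consensus == "increased"],
                             decreased = universe[consensus == "decreased"]),
                 membership = dirs, threshold = threshold),
            class = "differential_flux_result")
}

#' Two-sample Z-test on sampled fluxes
#'
#' Per reaction, `Z = (mean_cond - mean_ref) / sqrt(var_cond/n_cond +
#' var_ref/n_ref)` with two-tailed p-values from the standard normal CDF and
#' multiple-testing correction over the tested subset only. Zero pooled
#' variance with equal means yields `Z = 0, p = 1`; with unequal means the
#' p-value is 0 and the row is flagged degenerate.
#'
#' @param samples_ref,samples_cond `"flux_sample_set"` objects.
#' @param reactions Optional subset of reaction ids to test (default: all
#'   shared reactions).
#' @param correction `"bonferroni"` (the reaction-level convention) or
#'   `"bh"`.
#' @return `data.frame(reaction, mean_ref, mean_cond, delta, log2fc, Z, p,
#'   p_adj, degenerate)`.
#' @export
flux_z_test <- function(samples_ref, samples_cond, reactions = NULL,
                        correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  sr <- samples_ref$stats; sc <- samples_cond$stats
  shared <- intersect(sr$reaction, sc$reaction)
  if (is.null(reactions)) reactions <- shared
  missing <- setdiff(reactions, shared)
  if (length(missing)) stop("reactions absent from a sample set: ",
                            paste(head(missing, 10), collapse = ", "))
  stopifnot(samples_ref$n >= 2, samples_cond$n >= 2)
  ir <- match(reactions, sr$reaction); ic <- match(reactions, sc$reaction)
  se <- sqrt(sc$var[ic] / samples_cond$n + sr$var[ir] / samples_ref$n)
  delta <- sc$mean[ic] - sr$mean[ir]
  z <- ifelse(se > 0, delta / se, ifelse(abs(delta) < 1e-12, 0, Inf * sign(delta)))
  degenerate <- se == 0 & abs(delta) >= 1e-12
  p <- ifelse(is.finite(z), 2 * pnorm(-abs(z)), 0)
  p[se == 0 & !degenerate] <- 1
  data.frame(reaction = reactions,
             mean_ref = sr$mean[ir], mean_cond = sc$mean[ic],
             delta = delta,
             log2fc = log2_ratio(sc$mean[ic], sr$mean[ir]),
             Z = z, p = p,
             p_adj = p.adjust(p, method = if (correction == "bh") "BH"
                              else "bonferroni"),
             degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

# log2 fold change with signed-infinity sentinel for zero denominators
log2_ratio <- function(num, den) {
  out <- ifelse(den != 0, suppressWarnings(log2(num / den)), NA_real_)
  zero_den <- den == 0
  out[zero_den & num > 0] <- Inf
  out[zero_den & num < 0] <- -Inf
  out[zero_den & num == 0] <- 0
  out
}

#' Reactions carrying a given cofactor
#'
#' Convenience selector for e.g. NAD(H)-dependent reactions: reactions whose
#' stoichiometry involves any of the listed metabolite ids.
#'
#' @param model A `"gem"` object.
#' @param metabolite_ids Cofactor metabolite ids (all compartments).
#' @return Character vector of reaction ids.
#' @export
cofactor_reactions <- function(model, metabolite_ids) {
  keep <- vapply(model$stoichiometry,
                 function(s) any(names(s) %in% metabolite_ids), logical(1))
  model$reactions$id[keep]
}

#' Active subset of reactions
#'
#' A reaction is active when its median |flux| exceeds `zero_tol` in at
#' least one of the supplied sample sets.
#'
#' @param sample_sets List of `"flux_sample_set"` objects.
#' @param reactions Candidate reaction ids.
#' @param zero_tol Flux-magnitude tolerance (default 1e-6).
#' @return Character vector of active reaction ids.
#' @export
active_reactions <- function(sample_sets, reactions = NULL, zero_tol = 1e-6) {
  meds <- lapply(sample_sets, median_fluxes)
  if (is.null(reactions)) reactions <- names(meds[[1]])
  act <- Reduce(`|`, lapply(meds, function(m) abs(m[reactions]) > zero_tol))
  reactions[act]
}

#' Flux sensitivity analysis
#'
#' Quantifies the control of individual target reactions (e.g. glycolytic
#' steps) over a pathway output flux, analogously to flux control
#' coefficients. The baseline flux of each reaction is its median from
#' FVA-sampling; the output is the total consumption flux of
#' `output_metabolite` (summed over all consuming reactions). Each target is
#' perturbed by clamping both bounds to `level x baseline` (fixing the
#' flux), FVA-sampling is re-run, and the normalized sensitivity coefficient
#' `S_i = (delta v_out / delta v_i) * (v_i_base / v_out_base)` is computed
#' per level; `mean |S_i|` across levels summarizes each reaction.
#'
#' @param model A `"gem"` object.
#' @param target_reactions Reaction ids to perturb.
#' @param output_metabolite Metabolite id whose total consumption is the
#'   pathway output proxy (e.g. cytosolic pyruvate).
#' @param levels Perturbation levels as fractions of baseline (the default
#'   set 0.95/0.90/0.70/0.50 corresponds to 5-50% perturbation magnitudes).
#' @param n_samples Samples per FVA-sampling run.
#' @param seed Integer seed.
#' @param alpha FVA optimality fraction.
#' @param zero_tol Tolerance below which a baseline flux is reported as
#'   not-applicable.
#' @return A `"sensitivity_result"`: `table` with one row per
#'   (reaction, level) holding baseline/perturbed output and `S`;
#'   `summary` with `mean_abs_S` per reaction; `consumers` lists the
#'   output-consuming reactions.
#' @export
sensitivity_analysis <- function(model, target_reactions, output_metabolite,
                                 levels = c(0.95, 0.90, 0.70, 0.50),
                                 n_samples = 1000, seed = 1, alpha = 0.9,
                                 zero_tol = 1e-6) {
  validate_gem(model)
  rxn_index(model, target_reactions)
  met_index(model, output_metabolite)
  consumers <- consuming_reactions(model, output_metabolite)
  if (!length(consumers))
    stop("no reaction can consume ", output_metabolite)

  base_fva <- run_fva(model, alpha = alpha, keep_solutions = TRUE)
  base_samp <- sample_fluxes(model, base_fva, n_samples = n_samples,
                             seed = seed)
  base_med <- median_fluxes(base_samp)
  v_out_base <- consumption_flux(model, base_med, output_metabolite)

  rows <- list()
  for (ri in seq_along(target_reactions)) {
    rid <- target_reactions[ri]
    v_base <- base_med[[rid]]
    for (li in seq_along(levels)) {
      lev <- levels[li]
      if (abs(v_base) <= zero_tol) {
        rows[[length(rows) + 1L]] <- data.frame(
          reaction = rid, level = lev, baseline = v_base,
          output_baseline = v_out_base, output_perturbed = NA_real_,
          S = NA_real_, applicable = FALSE, stringsAsFactors = FALSE)
        next
      }
      target_flux <- lev * v_base
      m2 <- set_bounds(model, rid, lower = target_flux, upper = target_flux)
      pert <- tryCatch({
        fva2 <- run_fva(m2, alpha = alpha, keep_solutions = TRUE)
        samp2 <- sample_fluxes(m2, fva2, n_samples = n_samples,
                               seed = seed + 1000L * ri + li)
        median_fluxes(samp2)
      }, error = function(e) NULL)
      if (is.null(pert)) {
        rows[[length(rows) + 1L]] <- data.frame(
          reaction = rid, level = lev, baseline = v_base,
          output_baseline = v_out_base, output_perturbed = NA_real_,
          S = NA_real_, applicable = FALSE, stringsAsFactors = FALSE)
        next
      }
      v_out_pert <- consumption_flux(model, pert, output_metabolite)
      dv_i <- pert[[rid]] - v_base
      dv_out <- v_out_pert - v_out_base
      S <- if (abs(dv_i) <= zero_tol || abs(v_out_base) <= zero_tol) NA_real_
           else (dv_out / dv_i) * (v_base / v_out_base)
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = rid, level = lev, baseline = v_base,
        output_baseline = v_out_base, output_perturbed = v_out_pert,
        S = S, applicable = TRUE, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$reaction), function(d) {
    data.frame(reaction = d$reaction[1],
               mean_abs_S = mean(abs(d$S), na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(-summ$mean_abs_S), ]
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ, consumers = consumers,
                 levels = levels, output_metabolite = output_metabolite),
            class = "sensitivity_result")
}

#' Reactions structurally able to consume a metabolite
#' @param model A `"gem"` object.
#' @param metabolite Metabolite id.
#' @return Reaction ids with a negative coefficient and positive capacity,
#'   or a positive coefficient and reverse capacity.
#' @export
consuming_reactions <- function(model, metabolite) {
  ids <- model$reactions$id
  keep <- vapply(seq_along(ids), function(i) {
    s <- model$stoichiometry[[i]]
    cf <- s[metabolite]
    if (is.na(cf)) return(FALSE)
    (cf < 0 && model$reactions$upper_bound[i] > 0) ||
      (cf > 0 && model$reactions$lower_bound[i] < 0)
  }, logical(1))
  ids[keep]
}

# total consumption of `metabolite` at the flux vector `v`:
# sum over reactions of max(-coef * v, 0)
consumption_flux <- function(model, v, metabolite) {
  tot <- 0
  for (i in seq_along(model$stoichiometry)) {
    cf <- model$stoichiometry[[i]][metabolite]
    if (is.na(cf)) next
    rate <- -cf * v[[model$reactions$id[i]]]
    if (rate > 0) tot <- tot + rate
  }
  tot
}

#' Per-sample pathway fluxes
#'
#' Pathway flux `V_i` is the average of non-zero flux magnitudes over the
#' pathway's member reactions (fluxes with `|v| <= zero_tol` are excluded
#' from the mean; an all-zero pathway sample scores 0 and is flagged).
#'
#' @param samples A `"flux_sample_set"` or a single named flux vector (e.g.
#'   a pFBA solution's fluxes).
#' @param pathway_map Named list: pathway -> member reaction ids.
#' @param zero_tol Zero-flux tolerance.
#' @return Matrix (samples x pathways) for sample sets, or a named vector
#'   for a single flux vector; attribute `"all_zero"` flags pathways with no
#'   active member anywhere. Empty pathways are skipped with a warning.
#' @export
pathway_fluxes <- function(samples, pathway_map, zero_tol = 1e-6) {
  single <- !inherits(samples, "flux_sample_set")
  mat <- if (single) matrix(samples, nrow = 1,
                            dimnames = list(NULL, names(samples)))
         else samples$samples
  empty <- lengths(pathway_map) == 0 |
    !vapply(pathway_map, function(m) any(m %in% colnames(mat)), logical(1))
  if (any(empty)) {
    warning("skipping pathway(s) with no member in the flux table: ",
            paste(names(pathway_map)[empty], collapse = ", "))
    pathway_map <- pathway_map[!empty]
  }
  out <- vapply(pathway_map, function(members) {
    sub <- abs(mat[, intersect(members, colnames(mat)), drop = FALSE])
    sub[sub <= zero_tol] <- NA
    v <- rowMeans(sub, na.rm = TRUE)
    v[is.nan(v)] <- 0
    v
  }, numeric(nrow(mat)))
  if (nrow(mat) == 1) out <- matrix(out, nrow = 1,
                                    dimnames = list(NULL, names(pathway_map)))
  attr(out, "all_zero") <- names(pathway_map)[colSums(out != 0) == 0]
  if (single) out <- structure(out[1, ], all_zero = attr(out, "all_zero"))
  out
}

#' Pathway-level two-sample Z-test
#'
#' Applies the sampled-flux Z statistic to per-sample pathway fluxes. For
#' single-solution inputs (pFBA) only the log2 fold change is reported and
#' no test is performed.
#'
#' @param Vi_ref,Vi_cond Per-sample pathway-flux matrices from
#'   [pathway_fluxes()] (or single-row matrices / named vectors for pFBA).
#' @param correction `"bh"` (default) or `"bonferroni"`.
#' @return A `"pathway_flux_result"` data frame: pathway, mean fluxes,
#'   `log2fc`, and where testable `Z`, `p`, `p_adj`.
#' @export
pathway_z_test <- function(Vi_ref, Vi_cond, correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  if (is.null(dim(Vi_ref))) Vi_ref <- matrix(Vi_ref, nrow = 1,
                                             dimnames = list(NULL, names(Vi_ref)))
  if (is.null(dim(Vi_cond))) Vi_cond <- matrix(Vi_cond, nrow = 1,
                                               dimnames = list(NULL, names(Vi_cond)))
  shared <- intersect(colnames(Vi_ref), colnames(Vi_cond))
  if (!length(shared)) stop("no shared pathways between conditions")
  nr <- nrow(Vi_ref); nc <- nrow(Vi_cond)
  mr <- colMeans(Vi_ref[, shared, drop = FALSE])
  mc <- colMeans(Vi_cond[, shared, drop = FALSE])
  out <- data.frame(pathway = shared, mean_ref = unname(mr),
                    mean_cond = unname(mc),
                    log2fc = log2_ratio(unname(mc), unname(mr)),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (nr >= 2 && nc >= 2) {
    vr <- apply(Vi_ref[, shared, drop = FALSE], 2, var)
    vc <- apply(Vi_cond[, shared, drop = FALSE], 2, var)
    se <- sqrt(vc / nc + vr / nr)
    delta <- mc - mr
    z <- ifelse(se > 0, delta / se,
                ifelse(abs(delta) < 1e-12, 0, Inf * sign(delta)))
    p <- ifelse(is.finite(z), 2 * pnorm(-abs(z)), 0)
    p[se == 0 & abs(delta) < 1e-12] <- 1
    out$Z <- unname(z)
    out$p <- unname(p)
    out$p_adj <- p.adjust(out$p, method = if (correction == "bh") "BH"
                          else "bonferroni")
  }
  class(out) <- c("pathway_flux_result", "data.frame")
  out
}

#' Pathway map from model subsystems
#'
#' @param model A `"gem"` object.
#' @param drop Subsystem labels to exclude (default: empty label).
#' @return Named list subsystem -> reaction ids.
#' @export
subsystem_pathway_map <- function(model, drop = "") {
  ss <- model$reactions$subsystem
  keep <- !(ss %in% drop)
  split(model$reactions$id[keep], ss[keep])
}
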