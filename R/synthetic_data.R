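# ---------------------------------------------------------------------------
# Synthetic data generators: compartmentalized toy GEMs with a glycolysis-like
# chain, TCA-like cycle and NAD(H) cofactor coupling; model families with
# planted partitions; metabolomics and isotopomer tables with planted truth.
# All generators are seed-deterministic.
# ---------------------------------------------------------------------------

#' Generate a compartmentalized toy metabolic model
#'
#' Builds a small mass-balanced model emulating central carbon metabolism: a
#' linear glycolysis-like chain in the cytosol (optionally NAD(H)-coupled at
#' a designated "GAPDH" step), a TCA-like cycle in the mitochondrion whose
#' turns reduce mitochondrial NAD+, cofactor re-oxidation reactions, a
#' biomass drain on the terminal chain metabolite, an alternative secretion
#' route for the terminal metabolite, and optionally a futile two-reaction
#' cycle (which FBA may use but pFBA never does). Every internal metabolite
#' is both produced and consumed and the biomass FBA optimum equals the
#' uptake bound.
#'
#' @param chain_length Number of metabolites in the linear chain (>= 2).
#' @param cycle_length Number of cycle metabolites (0 disables the
#'   mitochondrial part).
#' @param compartments Subset of `c("c", "m")`; the cycle requires `"m"`.
#' @param cofactor_coupling Couple the designated chain step (and the first
#'   two cycle steps) to NAD+/NADH pairs.
#' @param n_parallel_paths Number of parallel copies of the chain step
#'   `bypass_step` (1 = plain chain).
#' @param bypass_step Index of the chain step to duplicate (default: step
#'   after the coupled one).
#' @param uptake_bound Upper bound of substrate uptake (flux units).
#' @param secretion Include the alternative terminal-metabolite secretion
#'   route.
#' @param futile_cycle Include a zero-gain internal loop.
#' @param seed Integer seed (recorded; generation itself is deterministic
#'   given the config).
#' @return List with `model` (a `"gem"`) and `truth` (a list recording the
#'   coupled step id, chain/cycle reaction ids, NADH yields and the planted
#'   bottleneck candidate).
#' @export
make_toy_gem <- function(chain_length = 5, cycle_length = 4,
                         compartments = c("c", "m"),
                         cofactor_coupling = TRUE,
                         n_parallel_paths = 1, bypass_step = NULL,
                         uptake_bound = 10, secretion = TRUE,
                         futile_cycle = FALSE, seed = 1) {
  stopifnot(chain_length >= 2, n_parallel_paths >= 1)
  has_m <- "m" %in% compartments && cycle_length >= 2
  k <- chain_length
  chain_ids <- c("glc", paste0("gi", seq_len(max(0, k - 2))), "pyr")
  met <- function(base, cmp) paste0(base, "[", cmp, "]")

  mets <- data.frame(id = met(chain_ids, "c"),
                     name = chain_ids, compartment = "c",
                     formula = NA_character_, stringsAsFactors = FALSE)
  add_met <- function(base, cmp) {
    mets <<- rbind(mets, data.frame(id = met(base, cmp), name = base,
                                    compartment = cmp, formula = NA_character_,
                                    stringsAsFactors = FALSE))
  }
  rxn_rows <- list(); stoich <- list()
  add_rxn <- function(id, st, lb = 0, ub = 1000, gpr = "", subsystem = "") {
    rxn_rows[[length(rxn_rows) + 1L]] <<-
      data.frame(id = id, name = id, lower_bound = lb, upper_bound = ub,
                 gpr = gpr, subsystem = subsystem, ec_number = "",
                 stringsAsFactors = FALSE)
    stoich[[id]] <<- st
  }

  coupled_step <- if (cofactor_coupling) max(1L, ceiling((k - 1) / 2)) else NA
  if (is.null(bypass_step))
    bypass_step <- if (!is.na(coupled_step)) min(coupled_step + 1L, k - 1L) else 1L
  if (cofactor_coupling) { add_met("nad", "c"); add_met("nadh", "c") }

  add_rxn("EX_glc", setNames(1, met("glc", "c")), lb = 0, ub = uptake_bound,
          subsystem = "Exchange")
  chain_rxn_ids <- character(k - 1)
  for (i in seq_len(k - 1)) {
    st <- setNames(c(-1, 1), met(chain_ids[c(i, i + 1)], "c"))
    gid <- if (!is.na(coupled_step) && i == coupled_step) "GAPDH"
           else sprintf("GLY%d", i)
    if (!is.na(coupled_step) && i == coupled_step)
      st <- c(st, setNames(c(-1, 1), c(met("nad", "c"), met("nadh", "c"))))
    add_rxn(gid, st, gpr = sprintf("g%d", i), subsystem = "Glycolysis")
    chain_rxn_ids[i] <- gid
    if (i == bypass_step && n_parallel_paths > 1) {
      for (p in seq_len(n_parallel_paths - 1)) {
        add_rxn(sprintf("%s_alt%d", gid, p),
                setNames(c(-1, 1), met(chain_ids[c(i, i + 1)], "c")),
                gpr = sprintf("g%d_alt%d", i, p), subsystem = "Glycolysis")
      }
    }
  }
  if (cofactor_coupling)
    add_rxn("NOXc", setNames(c(-1, 1), c(met("nadh", "c"), met("nad", "c"))),
            subsystem = "Redox")

  n_mito_nadh <- 0L
  if (has_m) {
    add_met("pyr", "m")
    cyc <- paste0("tca", seq_len(cycle_length))
    for (b in cyc) add_met(b, "m")
    add_met("co2", "m")
    if (cofactor_coupling) { add_met("nad", "m"); add_met("nadh", "m") }
    add_rxn("T_pyr", setNames(c(-1, 1), c(met("pyr", "c"), met("pyr", "m"))),
            subsystem = "Transport")
    n_mito_nadh <- if (cofactor_coupling) min(2L, cycle_length - 1L) else 0L
    for (i in seq_len(cycle_length)) {
      from <- met(cyc[i], "m")
      to <- met(cyc[if (i < cycle_length) i + 1 else 1], "m")
      st <- setNames(c(-1, 1), c(from, to))
      if (i == 1) st <- c(st, setNames(-1, met("pyr", "m")))
      if (i == cycle_length) st <- c(st, setNames(1, met("co2", "m")))
      if (cofactor_coupling && i <= n_mito_nadh)
        st <- c(st, setNames(c(-1, 1), c(met("nad", "m"), met("nadh", "m"))))
      add_rxn(sprintf("TCA%d", i), st, gpr = sprintf("t%d", i),
              subsystem = "TCA cycle")
    }
    add_rxn("EX_co2", setNames(-1, met("co2", "m")), subsystem = "Exchange")
    if (cofactor_coupling)
      add_rxn("NOXm", setNames(c(-1, 1), c(met("nadh", "m"), met("nad", "m"))),
              subsystem = "Redox")
  }

  add_met("biomass", "c")
  add_rxn("BIOMASS", setNames(c(-1, 1), c(met("pyr", "c"), met("biomass", "c"))),
          subsystem = "Biomass")
  add_rxn("EX_biomass", setNames(-1, met("biomass", "c")), subsystem = "Exchange")
  if (secretion) {
    add_met("byp", "c")
    add_rxn("ALT", setNames(c(-1, 1), c(met("pyr", "c"), met("byp", "c"))),
            subsystem = "Overflow")
    add_rxn("EX_byp", setNames(-1, met("byp", "c")), subsystem = "Exchange")
  }
  if (futile_cycle) {
    add_met("fcx", "c")
    mid <- met(chain_ids[2], "c")
    add_rxn("FC1", setNames(c(-1, 1), c(mid, met("fcx", "c"))),
            subsystem = "Futile")
    add_rxn("FC2", setNames(c(-1, 1), c(met("fcx", "c"), mid)),
            subsystem = "Futile")
  }

  model <- new_gem(id = sprintf("toy_gem_seed%d", seed),
                   metabolites = mets,
                   reactions = do.call(rbind, rxn_rows),
                   stoichiometry = stoich,
                   objective = c(BIOMASS = 1),
                   default_bound = 1000)
  fba <- run_fba(model)
  if (fba$status != "optimal" || fba$objective_value <= 1e-9)
    stop("generated toy model has no feasible nonzero biomass ",
         "(status ", fba$status, ")")
  truth <- list(
    bottleneck = if (!is.na(coupled_step)) chain_rxn_ids[coupled_step]
                 else chain_rxn_ids[1],
    chain_reactions = chain_rxn_ids,
    cycle_reactions = if (has_m) sprintf("TCA%d", seq_len(cycle_length))
                      else character(0),
    uptake_bound = uptake_bound,
    cytosolic_nadh_per_substrate = if (cofactor_coupling) 1L else 0L,
    mito_nadh_per_pyruvate = n_mito_nadh,
    seed = seed)
  list(model = model, truth = truth)
}

#' Generate a family of structurally related models
#'
#' Starts from a common base toy model augmented with a pool of accessory
#' reactions, then creates `n_families` families by deleting disjoint blocks
#' of `between_effect` accessory reactions per family, plus `within_noise`
#' random single-reaction deletions per model from a separate noise pool.
#' The planted partition is returned as ground truth.
#'
#' @param n_models Total number of models (split as evenly as possible).
#' @param n_families Number of planted families.
#' @param between_effect Accessory reactions deleted per family block.
#' @param within_noise Random accessory deletions per model.
#' @param noise_pool Size of the shared noise pool.
#' @param seed Integer seed.
#' @param ... Passed to [make_toy_gem()] for the base model.
#' @return List with `models` (named list of `"gem"`), `truth` (family
#'   assignment and per-family deleted blocks).
#' @export
make_model_family <- function(n_models = 8, n_families = 2,
                              between_effect = 10, within_noise = 1,
                              noise_pool = max(4L * within_noise, 8L),
                              seed = 1, ...) {
  stopifnot(n_models >= 2, n_families >= 2)
  if (between_effect <= within_noise)
    warning("between_effect <= within_noise: partition recovery not guaranteed")
  set.seed(as.integer(seed))
  base <- make_toy_gem(seed = seed, ...)$model

  n_acc <- n_families * between_effect + noise_pool
  m <- base
  mets <- m$metabolites; reactions <- m$reactions; stoich <- m$stoichiometry
  acc_ids <- sprintf("ACC%03d", seq_len(n_acc))
  for (j in seq_len(n_acc)) {
    aid <- sprintf("accm%03d", j)
    mets <- rbind(mets, data.frame(id = paste0(aid, "[c]"), name = aid,
                                   compartment = "c", formula = NA_character_,
                                   stringsAsFactors = FALSE))
    reactions <- rbind(reactions,
                       data.frame(id = acc_ids[j], name = acc_ids[j],
                                  lower_bound = 0, upper_bound = 1000,
                                  gpr = "", subsystem = "Accessory",
                                  ec_number = "", is_exchange = FALSE,
                                  is_demand = FALSE, stringsAsFactors = FALSE),
                       data.frame(id = paste0("EX_", acc_ids[j]),
                                  name = paste0("EX_", acc_ids[j]),
                                  lower_bound = 0, upper_bound = 1000,
                                  gpr = "", subsystem = "Exchange",
                                  ec_number = "", is_exchange = TRUE,
                                  is_demand = TRUE, stringsAsFactors = FALSE))
    stoich[[acc_ids[j]]] <- setNames(c(-1, 1), c("glc[c]", paste0(aid, "[c]")))
    stoich[[paste0("EX_", acc_ids[j])]] <- setNames(-1, paste0(aid, "[c]"))
  }
  augmented <- new_gem(id = "family_base", metabolites = mets,
                       reactions = reactions, stoichiometry = stoich,
                       objective = base$objective,
                       default_bound = base$default_bound)

  blocks <- split(acc_ids[seq_len(n_families * between_effect)],
                  rep(seq_len(n_families), each = between_effect))
  pool <- acc_ids[(n_families * between_effect + 1):n_acc]
  fam <- rep_len(seq_len(n_families), n_models)
  models <- vector("list", n_models)
  names(models) <- sprintf("model%02d_f%d", seq_len(n_models), fam)
  for (i in seq_len(n_models)) {
    drop <- blocks[[fam[i]]]
    if (within_noise > 0)
      drop <- c(drop, sample(pool, within_noise))
    mi <- remove_reaction(augmented, drop)
    mi$id <- names(models)[i]
    models[[i]] <- mi
  }
  list(models = models,
       truth = list(family = setNames(fam, names(models)),
                    blocks = blocks, noise_pool = pool, seed = seed))
}

#' Simulate a grouped metabolomics intensity table
#'
#' Log-normal feature intensities with planted group-specific enrichment:
#' selected features are shifted upward by `effect` log2 units in their
#' group. Features carry pathway annotations such that the planted features
#' of each group concentrate in designated pathways, so over-representation
#' analysis can recover them.
#'
#' @param groups Character vector of group names (the regional design uses
#'   four regions with n = 4).
#' @param n_per_group Samples per group (>= 2).
#' @param n_features Total number of features.
#' @param n_pathways Number of annotation pathways (features are split
#'   evenly).
#' @param n_enriched_per_group Planted enriched features per group.
#' @param effect Log2 shift of planted features in their group.
#' @param noise_sd SD of the log2-scale noise (multiplicative log-normal).
#' @param seed Integer seed.
#' @return List with `table` (an `"omics_table"`: `intensities`
#'   features x samples, `features` annotation frame, `groups` per sample)
#'   and `truth` (planted feature ids and pathway per group).
#' @export
simulate_metabolomics <- function(groups = c("thorax", "head", "gut", "abdomen"),
                                  n_per_group = 4, n_features = 60,
                                  n_pathways = 10, n_enriched_per_group = 5,
                                  effect = 2, noise_sd = 0.25, seed = 1) {
  stopifnot(n_per_group >= 2,
            length(groups) * n_enriched_per_group <= n_features)
  set.seed(as.integer(seed))
  feat_ids <- sprintf("met%03d", seq_len(n_features))
  pathway <- sprintf("path%02d", rep_len(seq_len(n_pathways), n_features))
  # planted features for group g live in pathway g (recycled)
  planted <- list(); taken <- character(0)
  for (gi in seq_along(groups)) {
    pw <- sprintf("path%02d", ((gi - 1) %% n_pathways) + 1)
    cand <- setdiff(feat_ids[pathway == pw], taken)
    extra <- setdiff(feat_ids, c(taken, cand))
    sel <- c(cand, extra)[seq_len(n_enriched_per_group)]
    planted[[groups[gi]]] <- sel
    taken <- c(taken, sel)
  }
  sample_groups <- rep(groups, each = n_per_group)
  sample_ids <- paste0(sample_groups, "_", sequence(rep(n_per_group,
                                                        length(groups))))
  base <- runif(n_features, 8, 14)   # log2 baseline abundance
  logi <- matrix(rep(base, length(sample_ids)), nrow = n_features)
  for (g in groups) {
    idx <- match(planted[[g]], feat_ids)
    logi[idx, sample_groups == g] <- logi[idx, sample_groups == g] + effect
  }
  logi <- logi + matrix(rnorm(length(logi), 0, noise_sd), nrow = n_features)
  intensities <- 2^logi
  dimnames(intensities) <- list(feat_ids, sample_ids)
  table <- structure(list(
    intensities = intensities,
    features = data.frame(id = feat_ids, pathway = pathway,
                          stringsAsFactors = FALSE),
    groups = setNames(sample_groups, sample_ids)),
    class = "omics_table")
  list(table = table,
       truth = list(planted = planted,
                    planted_pathways = setNames(
                      sprintf("path%02d", ((seq_along(groups) - 1) %% n_pathways) + 1),
                      groups),
                    effect = effect, noise_sd = noise_sd, seed = seed))
}

#' Simulate an isotopomer labeling table with a planted bottleneck
#'
#' Steady-state bookkeeping (not an ODE simulator): metabolites along an
#' ordered chain carry a labeled isotopomer whose fractional abundance is
#' attenuated by `bottleneck_scale` downstream of the planted bottleneck in
#' the perturbed condition, while upstream pool intensities are inflated.
#' A tracer reference metabolite (fully labeled substrate) is included for
#' normalization.
#'
#' @param chain Ordered metabolite names, upstream to downstream.
#' @param bottleneck_after Index: metabolites after this position are
#'   downstream of the bottleneck.
#' @param bottleneck_scale Attenuation factor in the perturbed condition
#'   (1 = no bottleneck).
#' @param conditions Two condition labels (reference first).
#' @param n_per_group Replicates per condition.
#' @param labeled_isotopomer Name of the labeled species (e.g. `"M+3"`).
#' @param tracer Metabolite/isotopomer used as the tracer reference
#'   (e.g. glucose `"M+6"`).
#' @param base_fraction Labeled fraction upstream (before attenuation).
#' @param noise_sd SD of multiplicative log-normal intensity noise.
#' @param seed Integer seed.
#' @return List with `table` (an `"isotopomer_table"` long data frame:
#'   metabolite, isotopomer, condition, sample, intensity; attribute
#'   `tracer`) and `truth`.
#' @export
simulate_labeling <- function(chain = c("g6p", "f16bp", "gap", "bpg", "pyr"),
                              bottleneck_after = 3, bottleneck_scale = 0.1,
                              conditions = c("NSD", "HSD"), n_per_group = 6,
                              labeled_isotopomer = "M+3",
                              tracer = c(metabolite = "glc", isotopomer = "M+6"),
                              base_fraction = 0.6, noise_sd = 0.05, seed = 1) {
  stopifnot(length(conditions) == 2, bottleneck_after >= 1,
            bottleneck_after <= length(chain))
  set.seed(as.integer(seed))
  rows <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    scale <- if (ci == 2) bottleneck_scale else 1
    for (s in seq_len(n_per_group)) {
      sample_id <- paste0(cond, "_", s)
      # tracer reference: fully labeled substrate pool
      pool <- 1000 * rlnorm(1, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = tracer[["metabolite"]],
        isotopomer = c("M+0", tracer[["isotopomer"]]),
        condition = cond, sample = sample_id,
        intensity = c(0.05, 0.95) * pool, stringsAsFactors = FALSE)
      for (mi in seq_along(chain)) {
        downstream <- mi > bottleneck_after
        frac <- base_fraction * (if (downstream) scale else 1)
        # upstream pools accumulate when the bottleneck is active
        pool_m <- 500 * (if (!downstream && ci == 2) 1.25 else 1) *
          (if (downstream && ci == 2) scale else 1) * rlnorm(1, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite = chain[mi],
          isotopomer = c("M+0", labeled_isotopomer),
          condition = cond, sample = sample_id,
          intensity = c(1 - frac, frac) * pool_m, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- structure(tab, class = c("isotopomer_table", "data.frame"))
  attr(tab, "tracer") <- tracer
  list(table = tab,
       truth = list(chain = chain, bottleneck_after = bottleneck_after,
                    bottleneck_scale = bottleneck_scale,
                    labeled_isotopomer = labeled_isotopomer, seed = seed))
}
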