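# ---------------------------------------------------------------------------
# Conditioned models: declarative constraint specifications (diet/condition
# bound overrides, directionality updates, artificial demand reactions,
# undetected-exchange scaling) applied to a base model.
# ---------------------------------------------------------------------------

#' Declare a condition specification
#'
#' A declarative description of how to condition a base model, e.g. encoding
#' a high-sugar-diet state as tightened uptake bounds plus directionality
#' updates and auxiliary demand reactions. Application order is fixed:
#' directionality updates, then bound overrides, then demand additions, then
#' exchange scaling, so overlapping edits are reproducible.
#'
#' @param bound_overrides `data.frame(reaction, lower, upper)`; `NA` keeps
#'   the current bound.
#' @param directionality `data.frame(reaction, direction)` with direction in
#'   `forward_only`, `reverse_only`, `reversible`.
#' @param demands List of demand specs from [demand_spec()].
#' @param undetected_exchange_scale Fraction in `(0, 1]` applied to the upper
#'   bounds of exchanges of undetected metabolites (the conventional value
#'   0.1 scales them to one tenth of the default); `NULL` disables scaling.
#' @param detected_metabolites Metabolite ids whose exchanges stay untouched.
#' @param notes Free-text evidence notes carried as metadata.
#' @return A `"condition_spec"` object.
#' @export
condition_spec <- function(bound_overrides = NULL, directionality = NULL,
                           demands = list(), undetected_exchange_scale = NULL,
                           detected_metabolites = character(0), notes = NULL) {
  if (!is.null(undetected_exchange_scale))
    stopifnot(undetected_exchange_scale > 0, undetected_exchange_scale <= 1)
  if (!is.null(directionality))
    stopifnot(all(directionality$direction %in%
                    c("forward_only", "reverse_only", "reversible")))
  structure(list(bound_overrides = bound_overrides,
                 directionality = directionality,
                 demands = demands,
                 undetected_exchange_scale = undetected_exchange_scale,
                 detected_metabolites = detected_metabolites,
                 notes = notes),
            class = "condition_spec")
}

#' Declare an artificial demand reaction
#'
#' @param id Reaction id for the new demand.
#' @param stoichiometry Named numeric vector (metabolite id -> signed
#'   coefficient); at least one reactant (negative) and, for
#'   conversion-style demands such as cofactor turnover, products
#'   (positive). A pure sink (`X -> `) is allowed.
#' @param lower_bound,upper_bound Flux bounds.
#' @return A `"demand_spec"` object.
#' @export
demand_spec <- function(id, stoichiometry, lower_bound = 0,
                        upper_bound = 1000) {
  stopifnot(length(stoichiometry) >= 1, any(stoichiometry < 0))
  structure(list(id = id, stoichiometry = stoichiometry,
                 lower_bound = lower_bound, upper_bound = upper_bound),
            class = "demand_spec")
}

#' Compartment-spanning NADH demand specification
#'
#' Builds the artificial total-NADH-turnover demand `NADH -> NAD+ (+ H+)`
#' summed over the model's NAD(H)-carrying compartments (cytosol,
#' mitochondria, peroxisome where present), used to probe the network's
#' maximal NADH production capacity.
#'
#' @param model A `"gem"` object.
#' @param nadh,nad,h Base metabolite names (compartment suffixes are
#'   appended); `h` entries are included only when present in the model.
#' @param id Reaction id of the demand.
#' @return A `"demand_spec"`.
#' @export
nadh_demand_spec <- function(model, nadh = "nadh", nad = "nad", h = "h",
                             id = "DM_nadh_total") {
  mets <- model$metabolites$id
  comps <- intersect(c("c", "m", "p"), unique(model$metabolites$compartment))
  st <- numeric(0)
  for (cm in comps) {
    nid <- paste0(nadh, "[", cm, "]")
    oid <- paste0(nad, "[", cm, "]")
    hid <- paste0(h, "[", cm, "]")
    if (nid %in% mets && oid %in% mets) {
      st[nid] <- -1
      st[oid] <- +1
      if (hid %in% mets) st[hid] <- +1
    }
  }
  if (!length(st))
    stop("no NADH/NAD+ pair found in any of compartments ",
         paste(comps, collapse = ", "))
  demand_spec(id, st)
}

#' Add a demand reaction to a model
#'
#' @param model A `"gem"` object.
#' @param spec A `"demand_spec"`.
#' @return A new validated model with the reaction appended.
#' @export
add_demand_reaction <- function(model, spec) {
  stopifnot(inherits(spec, "demand_spec"))
  missing <- setdiff(names(spec$stoichiometry), model$metabolites$id)
  if (length(missing))
    stop("demand reaction references missing metabolite(s): ",
         paste(missing, collapse = ", "))
  if (spec$id %in% model$reactions$id)
    stop("reaction id already present: ", spec$id)
  row <- data.frame(id = spec$id, name = spec$id,
                    lower_bound = spec$lower_bound,
                    upper_bound = spec$upper_bound,
                    gpr = "", subsystem = "Artificial demand", ec_number = "",
                    is_exchange = FALSE, is_demand = FALSE,
                    stringsAsFactors = FALSE)
  model$reactions <- rbind(model$reactions, row)
  model$stoichiometry[[spec$id]] <- spec$stoichiometry
  new_gem(id = model$id, metabolites = model$metabolites,
          reactions = model$reactions, stoichiometry = model$stoichiometry,
          genes = model$genes, objective = model$objective,
          compartments = model$compartments,
          default_bound = model$default_bound)
}

#' Remove a reaction from a model
#'
#' @param model A `"gem"` object.
#' @param id Reaction id(s) to drop.
#' @return A new validated model.
#' @export
remove_reaction <- function(model, id) {
  i <- rxn_index(model, id)
  model$reactions <- model$reactions[-i, , drop = FALSE]
  model$stoichiometry <- model$stoichiometry[-i]
  model$objective <- model$objective[setdiff(names(model$objective), id)]
  new_gem(id = model$id, metabolites = model$metabolites,
          reactions = model$reactions, stoichiometry = model$stoichiometry,
          genes = model$genes, objective = model$objective,
          compartments = model$compartments,
          default_bound = model$default_bound)
}

#' Scale exchange bounds of undetected metabolites
#'
#' Every exchange reaction whose metabolite is not in `detected` has its
#' upper bound multiplied by `factor` (the conventional choice 0.1 reduces
#' them to one tenth of the default upper bound); detected exchanges are
#' untouched.
#'
#' @param model A `"gem"` object.
#' @param detected Metabolite ids considered detected; an empty vector
#'   scales all exchanges (a message is emitted).
#' @param factor Fraction in `(0, 1]`.
#' @return A new model.
#' @export
scale_undetected_exchanges <- function(model, detected, factor) {
  stopifnot(factor > 0, factor <= 1)
  if (factor == 1) return(model)
  ex_met <- exchange_metabolites(model)
  if (!length(detected))
    message("empty detected list: scaling all ", length(ex_met), " exchanges")
  target <- names(ex_met)[!(ex_met %in% detected)]
  i <- rxn_index(model, target)
  model$reactions$upper_bound[i] <- model$reactions$upper_bound[i] * factor
  model
}

#' Apply a condition specification to a model
#'
#' Purely functional: returns a new conditioned model, leaving the input
#' unmodified, with edits applied in the fixed order directionality ->
#' bound overrides -> demand additions -> exchange scaling. An audit log of
#' every changed bound is attached as attribute `"audit"` (a
#' `data.frame(reaction, old_lb, old_ub, new_lb, new_ub, rule)`).
#'
#' @param model A validated `"gem"` object.
#' @param spec A `"condition_spec"`.
#' @return The conditioned model.
#' @export
apply_condition <- function(model, spec) {
  stopifnot(inherits(spec, "condition_spec"))
  validate_gem(model)
  audit <- list()
  log_change <- function(m_old, m_new, rule) {
    ch <- which(m_old$reactions$lower_bound != m_new$reactions$lower_bound |
                  m_old$reactions$upper_bound != m_new$reactions$upper_bound)
    if (!length(ch)) return(NULL)
    data.frame(reaction = m_old$reactions$id[ch],
               old_lb = m_old$reactions$lower_bound[ch],
               old_ub = m_old$reactions$upper_bound[ch],
               new_lb = m_new$reactions$lower_bound[ch],
               new_ub = m_new$reactions$upper_bound[ch],
               rule = rule, stringsAsFactors = FALSE)
  }

  m <- model
  if (!is.null(spec$directionality)) {
    prev <- m
    for (i in seq_len(nrow(spec$directionality))) {
      rid <- spec$directionality$reaction[i]
      j <- rxn_index(m, rid)
      dir <- spec$directionality$direction[i]
      lb <- m$reactions$lower_bound[j]; ub <- m$reactions$upper_bound[j]
      if (dir == "forward_only") {
        m$reactions$lower_bound[j] <- max(lb, 0)
        m$reactions$upper_bound[j] <- max(ub, 0)
      } else if (dir == "reverse_only") {
        m$reactions$upper_bound[j] <- min(ub, 0)
        m$reactions$lower_bound[j] <- min(lb, 0)
      } else {
        m$reactions$lower_bound[j] <- min(lb, -m$default_bound)
        m$reactions$upper_bound[j] <- max(ub, m$default_bound)
      }
    }
    audit[["directionality"]] <- log_change(prev, m, "directionality")
  }
  if (!is.null(spec$bound_overrides)) {
    prev <- m
    bo <- spec$bound_overrides
    for (i in seq_len(nrow(bo))) {
      m <- set_bounds(m, bo$reaction[i],
                      lower = if ("lower" %in% names(bo)) bo$lower[i] else NA,
                      upper = if ("upper" %in% names(bo)) bo$upper[i] else NA)
    }
    audit[["bounds"]] <- log_change(prev, m, "bound_override")
  }
  for (d in spec$demands) m <- add_demand_reaction(m, d)
  if (!is.null(spec$undetected_exchange_scale)) {
    prev <- m
    m <- scale_undetected_exchanges(m, spec$detected_metabolites,
                                    spec$undetected_exchange_scale)
    audit[["scaling"]] <- log_change(prev, m, "exchange_scaling")
  }
  validate_gem(m)
  attr(m, "audit") <- do.call(rbind, audit)
  m
}

#' Read a condition specification from YAML
#'
#' The YAML schema mirrors the constraint-table convention: top-level keys
#' `bound_overrides` (list of reaction/lower/upper), `directionality`
#' (reaction/direction), `demands` (id/stoichiometry/lower_bound/upper_bound),
#' `undetected_exchange_scale`, `detected_metabolites`, `notes`.
#'
#' @param path YAML file path.
#' @return A `"condition_spec"`.
#' @export
read_condition_spec <- function(path) {
  y <- yaml::read_yaml(path)
  as_df <- function(x, cols) {
    if (is.null(x)) return(NULL)
    df <- do.call(rbind, lapply(x, function(r) {
      r <- r[cols[cols %in% names(r)]]
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)
    }))
    df
  }
  demands <- lapply(y$demands, function(d)
    demand_spec(d$id, unlist(d$stoichiometry),
                lower_bound = if (is.null(d$lower_bound)) 0 else d$lower_bound,
                upper_bound = if (is.null(d$upper_bound)) 1000 else d$upper_bound))
  condition_spec(
    bound_overrides = as_df(y$bound_overrides, c("reaction", "lower", "upper")),
    directionality = as_df(y$directionality, c("reaction", "direction")),
    demands = demands,
    undetected_exchange_scale = y$undetected_exchange_scale,
    detected_metabolites = unlist(y$detected_metabolites),
    notes = y$notes)
}
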