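#' @useDynLib gemdiff, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median var sd pnorm p.adjust cor.test phyper fisher.test
#'   aov cutree hclust dist rnorm runif rlnorm setNames t.test lm coef ave
#' @importFrom utils head read.delim write.table
NULL

# ---------------------------------------------------------------------------
# Core data structures
#
# A genome-scale metabolic model (GEM) is held as a plain S3 list:
#   metabolites:  data.frame(id, name, compartment, formula)
#   reactions:    data.frame(id, name, lower_bound, upper_bound, gpr,
#                            subsystem, ec_number, is_exchange, is_demand)
#   stoichiometry: named list, one named numeric vector per reaction
#                  (metabolite id -> signed coefficient)
#   genes:        character vector of gene ids
#   objective:    named numeric (reaction id -> objective coefficient)
#   compartments: named character (code -> name)
#   default_bound: magnitude used for unspecified bounds
# ---------------------------------------------------------------------------

#' Construct a metabolic model
#'
#' Builds and validates a genome-scale metabolic model from its parts. Most
#' users will obtain models from [read_gem()] or [make_toy_gem()] instead.
#'
#' @param id Model identifier.
#' @param metabolites `data.frame` with at least an `id` column; optional
#'   `name`, `compartment`, `formula`. Missing compartments are parsed from a
#'   trailing `[x]` suffix of the metabolite id; ids without a suffix are
#'   assigned compartment `"c"` with a warning.
#' @param reactions `data.frame` with at least an `id` column; optional
#'   `name`, `lower_bound`, `upper_bound`, `gpr`, `subsystem`, `ec_number`.
#'   Unspecified bounds are filled with `c(-default_bound, default_bound)`.
#' @param stoichiometry Named list (one element per reaction id) of named
#'   numeric vectors mapping metabolite ids to signed coefficients.
#' @param genes Character vector of gene ids; defaults to genes mentioned in
#'   the GPR rules.
#' @param objective Named numeric vector of objective coefficients keyed by
#'   reaction id.
#' @param compartments Named character vector (code -> name). Defaults to the
#'   codes seen in the metabolites.
#' @param default_bound Flux magnitude substituted for unspecified bounds.
#'   The conventional value 1000 marks a computational convention, not a
#'   measured limit.
#' @return An object of class `"gem"`.
#' @export
new_gem <- function(id, metabolites, reactions, stoichiometry,
                    genes = NULL, objective = numeric(0),
                    compartments = NULL, default_bound = 1000) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(metabolites), "id" %in% names(reactions))

  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- NA_character_
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  missing_cmp <- is.na(metabolites$compartment) | metabolites$compartment == ""
  if (any(missing_cmp)) {
    parsed <- parse_compartment(metabolites$id[missing_cmp])
    if (anyNA(parsed)) {
      warning("metabolite id(s) without [compartment] suffix assigned to 'c': ",
              paste(head(metabolites$id[missing_cmp][is.na(parsed)], 5),
                    collapse = ", "))
      parsed[is.na(parsed)] <- "c"
    }
    metabolites$compartment[missing_cmp] <- parsed
  }

  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$lower_bound)) reactions$lower_bound <- NA_real_
  if (is.null(reactions$upper_bound)) reactions$upper_bound <- NA_real_
  reactions$lower_bound[is.na(reactions$lower_bound)] <- -default_bound
  reactions$upper_bound[is.na(reactions$upper_bound)] <- default_bound
  for (col in c("gpr", "subsystem", "ec_number")) {
    if (is.null(reactions[[col]])) reactions[[col]] <- ""
    reactions[[col]][is.na(reactions[[col]])] <- ""
  }

  stoichiometry <- stoichiometry[reactions$id]
  n_met <- vapply(stoichiometry, length, integer(1))
  reactions$is_exchange <- n_met == 1L
  reactions$is_demand <- reactions$is_exchange &
    vapply(stoichiometry, function(s) s[1] < 0, logical(1)) &
    reactions$lower_bound >= 0
  rownames(metabolites) <- rownames(reactions) <- NULL

  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  }
  if (is.null(compartments)) {
    codes <- sort(unique(metabolites$compartment))
    compartments <- setNames(codes, codes)
  }
  model <- structure(list(
    id = as.character(id),
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stoichiometry,
    genes = as.character(genes),
    objective = objective,
    compartments = compartments,
    default_bound = default_bound
  ), class = "gem")
  validate_gem(model)
  model
}

parse_compartment <- function(ids) {
  out <- rep(NA_character_, length(ids))
  hit <- grepl("\\[([A-Za-z])\\]$", ids)
  out[hit] <- sub(".*\\[([A-Za-z])\\]$", "\\1", ids[hit])
  out
}

gpr_genes <- function(rule) {
  if (is.na(rule) || rule == "") return(character(0))
  toks <- strsplit(gsub("[()]", " ", rule), "\\s+")[[1]]
  setdiff(toks[toks != ""], c("and", "or", "AND", "OR"))
}

#' Evaluate a gene-protein-reaction rule
#'
#' Boolean evaluation of a GPR string against a set of present genes:
#' `or` means any gene suffices, `and` requires all.
#'
#' @param rule GPR string, genes joined by `and`/`or` with parentheses.
#' @param present Character vector of present gene ids.
#' @return Logical; `TRUE` for an empty rule (non-gene-associated reactions
#'   are always available).
#' @export
eval_gpr <- function(rule, present) {
  if (is.na(rule) || rule == "") return(TRUE)
  expr <- gsub("\\bAND\\b", "&&", gsub("\\bOR\\b", "||", rule, ignore.case = FALSE))
  expr <- gsub("\\band\\b", "&&", gsub("\\bor\\b", "||", expr))
  genes <- gpr_genes(rule)
  env <- new.env(parent = emptyenv())
  for (g in genes) assign(g, g %in% present, envir = env)
  # gene ids may not be syntactic names; substitute with logical literals
  for (g in genes[order(nchar(genes), decreasing = TRUE)]) {
    expr <- gsub(paste0("(?<![A-Za-z0-9_.])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", g),
                        "(?![A-Za-z0-9_.])"),
                 if (g %in% present) "TRUE" else "FALSE", expr, perl = TRUE)
  }
  isTRUE(eval(parse(text = expr)))
}

#' Validate a metabolic model
#'
#' Checks referential integrity (every metabolite referenced by a reaction is
#' declared, GPR genes are listed, objective reactions exist), bound sanity
#' (`lower_bound <= upper_bound`), non-empty stoichiometries and unique ids.
#'
#' @param model A `"gem"` object.
#' @return The model, invisibly; errors describe the offending element.
#' @export
validate_gem <- function(model) {
  stopifnot(inherits(model, "gem"))
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  if (anyDuplicated(mets)) stop("duplicate metabolite id: ",
                                mets[duplicated(mets)][1])
  if (anyDuplicated(rxns)) stop("duplicate reaction id: ",
                                rxns[duplicated(rxns)][1])
  if (!identical(names(model$stoichiometry), rxns))
    stop("stoichiometry list is not aligned with reactions")
  empty <- lengths(model$stoichiometry) == 0
  if (any(empty)) stop("reaction with empty stoichiometry: ",
                       rxns[empty][1])
  referenced <- unique(unlist(lapply(model$stoichiometry, names)))
  dangling <- setdiff(referenced, mets)
  if (length(dangling))
    stop("reaction references undeclared metabolite(s): ",
         paste(dangling, collapse = ", "))
  bad <- model$reactions$lower_bound > model$reactions$upper_bound
  if (any(bad)) stop("lower_bound > upper_bound for reaction: ",
                     rxns[bad][1])
  gpr_g <- unique(unlist(lapply(model$reactions$gpr, gpr_genes)))
  missing_g <- setdiff(gpr_g, model$genes)
  if (length(missing_g))
    stop("GPR references gene(s) absent from gene list: ",
         paste(missing_g, collapse = ", "))
  if (length(model$objective)) {
    bad_obj <- setdiff(names(model$objective), rxns)
    if (length(bad_obj))
      stop("objective references unknown reaction(s): ",
           paste(bad_obj, collapse = ", "))
  }
  bad_cmp <- setdiff(unique(model$metabolites$compartment),
                     names(model$compartments))
  if (length(bad_cmp))
    stop("metabolite compartment code(s) not declared: ",
         paste(bad_cmp, collapse = ", "))
  invisible(model)
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("<gem> %s: %d metabolites, %d reactions, %d genes\n",
              x$id, nrow(x$metabolites), nrow(x$reactions), length(x$genes)))
  if (length(x$objective))
    cat("objective:", paste(sprintf("%g*%s", x$objective, names(x$objective)),
                            collapse = " + "), "\n")
  invisible(x)
}

#' Number of reactions / metabolites
#' @param model A `"gem"` object.
#' @return Integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

# ---------------------------------------------------------------------------
# Readers / writers
# ---------------------------------------------------------------------------

#' Read a metabolic model
#'
#' Reads a COBRA-community-style JSON model or an SBML Level 3 (fbc) file and
#' maps it into the package's model type. Unspecified bounds are filled with
#' `+- default_bound`; the objective is taken from the file when present.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"json"` or `"sbml"`.
#' @param default_bound Bound magnitude for unspecified bounds.
#' @return A validated `"gem"` object.
#' @export
read_gem <- function(path, format = c("auto", "json", "sbml"),
                     default_bound = 1000) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format,
         json = read_gem_json(path, default_bound),
         sbml = read_gem_sbml(path, default_bound))
}

read_gem_json <- function(path, default_bound = 1000) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$reactions) || is.null(doc$metabolites))
    stop("JSON model is missing 'reactions' or 'metabolites' arrays: ", path)
  get_chr <- function(x, key, default = NA_character_) {
    v <- x[[key]]
    if (is.null(v)) default else as.character(v)
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = get_chr(m, "id"),
               name = get_chr(m, "name"),
               compartment = get_chr(m, "compartment"),
               formula = get_chr(m, "formula"),
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    # the community files spell the pathway key either 'subsystem' or 'subSystems'
    subsys <- r$subsystem
    if (is.null(subsys)) subsys <- r$subSystems
    if (is.list(subsys)) subsys <- paste(unlist(subsys), collapse = "; ")
    data.frame(id = get_chr(r, "id"),
               name = get_chr(r, "name"),
               lower_bound = if (is.null(r$lower_bound)) NA_real_ else as.numeric(r$lower_bound),
               upper_bound = if (is.null(r$upper_bound)) NA_real_ else as.numeric(r$upper_bound),
               gpr = get_chr(r, "gene_reaction_rule", ""),
               subsystem = if (is.null(subsys)) "" else as.character(subsys),
               ec_number = get_chr(r, "ec_number", ""),
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(doc$reactions, function(r) {
    s <- unlist(r$metabolites)
    if (is.null(s)) stop("reaction without metabolites in JSON model: ", r$id)
    storage.mode(s) <- "double"
    s
  })
  names(stoich) <- rxns$id
  objective <- numeric(0)
  oc <- vapply(doc$reactions, function(r)
    if (is.null(r$objective_coefficient)) 0 else as.numeric(r$objective_coefficient),
    numeric(1))
  if (any(oc != 0)) objective <- setNames(oc[oc != 0], rxns$id[oc != 0])
  genes <- vapply(doc$genes, function(g)
    if (is.list(g)) as.character(g$id) else as.character(g), character(1))
  new_gem(id = if (is.null(doc$id)) basename(path) else doc$id,
          metabolites = mets, reactions = rxns, stoichiometry = stoich,
          genes = if (length(genes)) genes else NULL,
          objective = objective, default_bound = default_bound)
}

#' Write a metabolic model as COBRA-style JSON
#'
#' The JSON dialect round-trips: `read_gem(write_gem(m))` reproduces `m`
#' field for field.
#'
#' @param model A `"gem"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gem <- function(model, path) {
  validate_gem(model)
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    s <- model$stoichiometry[[i]]
    list(id = r$id, name = r$name,
         metabolites = as.list(s),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene_reaction_rule = r$gpr,
         subsystem = r$subsystem,
         ec_number = r$ec_number,
         objective_coefficient =
           if (r$id %in% names(model$objective)) unname(model$objective[r$id]) else 0)
  })
  doc <- list(id = model$id,
              metabolites = mets,
              reactions = rxns,
              genes = lapply(model$genes, function(g) list(id = g)),
              compartments = as.list(model$compartments),
              default_bound = model$default_bound)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_gem_sbml <- function(path, default_bound = 1000) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path, ": ",
                                           conditionMessage(e)))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  model_node <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  if (is.na(xml2::xml_name(model_node))) stop("no <model> element in ", path)

  params <- xml2::xml_find_all(doc, ".//sbml:listOfParameters/sbml:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(doc, ".//sbml:listOfSpecies/sbml:species", ns)
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  mets <- data.frame(id = xml2::xml_attr(sp, "id"),
                     name = xml2::xml_attr(sp, "name"),
                     compartment = xml2::xml_attr(sp, "compartment"),
                     formula = NA_character_,
                     stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  mets <- mets[!boundary, , drop = FALSE]

  rnodes <- xml2::xml_find_all(doc, ".//sbml:listOfReactions/sbml:reaction", ns)
  if (!length(rnodes)) stop("no reactions in SBML model: ", path)
  parse_side <- function(rn, tag, sign) {
    refs <- xml2::xml_find_all(
      rn, paste0("./sbml:", tag, "/sbml:speciesReference"), ns)
    if (!length(refs)) return(numeric(0))
    st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    st[is.na(st)] <- 1
    setNames(sign * st, xml2::xml_attr(refs, "species"))
  }
  rxn_list <- lapply(rnodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    rev <- !(xml2::xml_attr(rn, "reversible") %in% c("false", "0"))
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]]
          else if (rev) NA_real_ else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]] else NA_real_
    s <- c(parse_side(rn, "listOfReactants", -1), parse_side(rn, "listOfProducts", +1))
    gpr_nodes <- xml2::xml_find_all(rn, ".//fbc:geneProductRef", ns)
    gpr <- ""
    if (length(gpr_nodes)) {
      ors <- xml2::xml_find_all(rn, ".//fbc:or", ns)
      refs <- xml2::xml_attr(gpr_nodes, "geneProduct")
      gpr <- paste(refs, collapse = if (length(ors)) " or " else " and ")
    }
    list(row = data.frame(id = id,
                          name = if (is.na(xml2::xml_attr(rn, "name"))) id
                                 else xml2::xml_attr(rn, "name"),
                          lower_bound = lb, upper_bound = ub, gpr = gpr,
                          subsystem = "", ec_number = "",
                          stringsAsFactors = FALSE),
         stoich = s)
  })
  rxns <- do.call(rbind, lapply(rxn_list, `[[`, "row"))
  stoich <- lapply(rxn_list, `[[`, "stoich")
  names(stoich) <- rxns$id
  # drop references to boundary species
  keep_ids <- mets$id
  stoich <- lapply(stoich, function(s) s[names(s) %in% keep_ids])
  if (any(lengths(stoich) == 0))
    stop("SBML reaction reduced to empty stoichiometry after removing ",
         "boundary species: ", rxns$id[lengths(stoich) == 0][1])

  obj_nodes <- xml2::xml_find_all(
    doc, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  objective <- numeric(0)
  if (length(obj_nodes)) {
    cf <- as.numeric(xml2::xml_attr(obj_nodes, "coefficient"))
    cf[is.na(cf)] <- 1
    objective <- setNames(cf, xml2::xml_attr(obj_nodes, "reaction"))
  }
  gp <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- xml2::xml_attr(gp, "id")
  comps <- xml2::xml_find_all(doc, ".//sbml:listOfCompartments/sbml:compartment", ns)
  compartments <- setNames(xml2::xml_attr(comps, "name"), xml2::xml_attr(comps, "id"))
  compartments[is.na(compartments)] <- names(compartments)[is.na(compartments)]
  new_gem(id = xml2::xml_attr(model_node, "id"),
          metabolites = mets, reactions = rxns, stoichiometry = stoich,
          genes = if (length(genes)) genes else NULL,
          objective = objective,
          compartments = if (length(compartments)) compartments else NULL,
          default_bound = default_bound)
}

# ---------------------------------------------------------------------------
# Matrix construction and model transforms
# ---------------------------------------------------------------------------

#' Build the stoichiometric matrix
#'
#' Returns the m x n sparse stoichiometric matrix S with metabolite ids as
#' row names and reaction ids as column names. Column j reproduces reaction
#' j's stoichiometry exactly; structural zeros are omitted from storage.
#'
#' @param model A validated `"gem"` object.
#' @return A `Matrix::dgCMatrix`.
#' @export
stoich_matrix <- function(model) {
  validate_gem(model)
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  i <- unlist(lapply(model$stoichiometry, function(s) match(names(s), mets)))
  j <- rep(seq_along(rxns), lengths(model$stoichiometry))
  x <- unlist(model$stoichiometry, use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Split reversible reactions
#'
#' Converts the model to an equivalent irreversible form: every reversible
#' reaction (`lower_bound < 0 < upper_bound`) is split into a forward and a
#' reverse non-negative reaction; reactions that can only run backwards
#' (`upper_bound <= 0`) are flipped. Net flux is reconstructed as
#' `forward - reverse` via the returned mapping.
#'
#' @param model A `"gem"` object.
#' @return A list with `model` (the split model) and `mapping`, a
#'   `data.frame(id, forward, reverse, flipped)` where `reverse` is `NA` for
#'   unsplit reactions.
#' @export
to_irreversible <- function(model) {
  validate_gem(model)
  rx <- model$reactions
  new_rows <- list(); new_stoich <- list()
  map <- data.frame(id = rx$id, forward = rx$id, reverse = NA_character_,
                    flipped = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    s <- model$stoichiometry[[i]]
    if (r$lower_bound >= 0) {
      new_rows[[length(new_rows) + 1L]] <- r
      new_stoich[[r$id]] <- s
    } else if (r$upper_bound <= 0) {
      r2 <- r
      r2$lower_bound <- -r$upper_bound
      r2$upper_bound <- -r$lower_bound
      new_rows[[length(new_rows) + 1L]] <- r2
      new_stoich[[r$id]] <- -s
      map$flipped[i] <- TRUE
    } else {
      fwd <- r; fwd$lower_bound <- 0
      rev <- r
      rev$id <- paste0(r$id, "_rev")
      rev$lower_bound <- 0
      rev$upper_bound <- -r$lower_bound
      new_rows[[length(new_rows) + 1L]] <- fwd
      new_rows[[length(new_rows) + 1L]] <- rev
      new_stoich[[fwd$id]] <- s
      new_stoich[[rev$id]] <- -s
      map$reverse[i] <- rev$id
    }
  }
  reactions <- do.call(rbind, new_rows)
  objective <- model$objective
  split_model <- new_gem(id = paste0(model$id, "_irrev"),
                         metabolites = model$metabolites,
                         reactions = reactions,
                         stoichiometry = new_stoich,
                         genes = model$genes,
                         objective = objective,
                         compartments = model$compartments,
                         default_bound = model$default_bound)
  list(model = split_model, mapping = map)
}

#' Net fluxes from an irreversible-split solution
#'
#' @param fluxes Named flux vector on the split model.
#' @param mapping Mapping returned by [to_irreversible()].
#' @return Named net flux vector on the original reaction ids.
#' @export
net_fluxes <- function(fluxes, mapping) {
  out <- numeric(nrow(mapping))
  names(out) <- mapping$id
  for (i in seq_len(nrow(mapping))) {
    v <- fluxes[[mapping$forward[i]]]
    if (!is.na(mapping$reverse[i])) v <- v - fluxes[[mapping$reverse[i]]]
    if (mapping$flipped[i]) v <- -v
    out[i] <- v
  }
  out
}

#' Binary reaction presence vector
#'
#' @param model A `"gem"` object.
#' @param reaction_universe Non-empty character vector of reaction ids.
#' @return Integer 0/1 vector named by the universe; 1 where the model
#'   contains the reaction.
#' @export
presence_vector <- function(model, reaction_universe) {
  if (!length(reaction_universe)) stop("reaction universe is empty")
  setNames(as.integer(reaction_universe %in% model$reactions$id),
           reaction_universe)
}

#' Binary reaction presence matrix across models
#'
#' Rows are the union reaction universe, columns the models; entries are 0/1
#' presence indicators.
#'
#' @param models Named list of `"gem"` objects.
#' @param universe Optional reaction universe; defaults to the union of all
#'   model reaction sets.
#' @return Integer matrix (reactions x models).
#' @export
presence_matrix <- function(models, universe = NULL) {
  stopifnot(length(models) >= 1)
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- paste0("model", seq_along(models))
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(models, function(m) m$reactions$id))))
  vapply(models, presence_vector, integer(length(universe)),
         reaction_universe = universe)
}

# small shared helpers ------------------------------------------------------

rxn_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction id(s): ",
                     paste(id[is.na(i)], collapse = ", "))
  i
}

met_index <- function(model, id) {
  i <- match(id, model$metabolites$id)
  if (anyNA(i)) stop("unknown metabolite id(s): ",
                     paste(id[is.na(i)], collapse = ", "))
  i
}

#' Set reaction bounds
#'
#' @param model A `"gem"` object.
#' @param id Reaction id(s).
#' @param lower,upper New bounds (recycled); `NA` keeps the current value.
#' @return Modified model.
#' @export
set_bounds <- function(model, id, lower = NA, upper = NA) {
  i <- rxn_index(model, id)
  lower <- rep_len(lower, length(i)); upper <- rep_len(upper, length(i))
  lb <- model$reactions$lower_bound[i]
  ub <- model$reactions$upper_bound[i]
  lb[!is.na(lower)] <- lower[!is.na(lower)]
  ub[!is.na(upper)] <- upper[!is.na(upper)]
  if (any(lb > ub))
    stop("bound override violates lower <= upper for reaction: ",
         id[which(lb > ub)[1]])
  model$reactions$lower_bound[i] <- lb
  model$reactions$upper_bound[i] <- ub
  model
}

#' Exchange reactions of a model
#'
#' Exchange (boundary) reactions touch exactly one metabolite.
#'
#' @param model A `"gem"` object.
#' @return Character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[model$reactions$is_exchange]
}

#' Metabolite touched by each exchange reaction
#' @param model A `"gem"` object.
#' @return Named character vector (reaction id -> metabolite id).
#' @export
exchange_metabolites <- function(model) {
  ex <- exchange_reactions(model)
  setNames(vapply(model$stoichiometry[ex], function(s) names(s)[1], character(1)),
           ex)
}
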