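# ---------------------------------------------------------------------------
# Cross-model structural comparison and functional capability testing:
# Hamming similarity, hierarchical clustering, cluster-overlap Jaccard,
# subsystem coverage deviation, metabolic-task feasibility, Fisher
# association, and a CPM utility for expression-based comparisons.
# ---------------------------------------------------------------------------

#' Hamming similarity between models
#'
#' From a binary presence matrix, the pairwise distance is the count of
#' differing entries and the similarity is `1 - distance / universe size`.
#'
#' @param P Binary presence matrix (reactions x models) from
#'   [presence_matrix()].
#' @return List with `distance` and `similarity` (models x models; the
#'   similarity has unit diagonal).
#' @export
hamming_similarity <- function(P) {
  stopifnot(ncol(P) >= 2, all(P %in% c(0, 1)))
  n <- nrow(P)
  # for 0/1 columns, differing entries = x + y - 2xy summed
  cross <- crossprod(P)
  ones <- colSums(P)
  d <- outer(ones, ones, "+") - 2 * cross
  d <- as.matrix(d)
  list(distance = d, similarity = 1 - d / n)
}

#' Hierarchical clustering of models by reaction content
#'
#' Average-linkage agglomerative clustering on Euclidean distances between
#' the binary presence columns (for 0/1 vectors the Euclidean distance is
#' `sqrt(Hamming)`), cut at `k` clusters.
#'
#' @param P Binary presence matrix (reactions x models).
#' @param k Number of clusters (`1 <= k <= ncol(P)`).
#' @return A `"cluster_assignment"`: named integer labels (contiguous
#'   `1..k`), plus `k`, `linkage`, `distance` and the `hclust` tree.
#' @export
hierarchical_clusters <- function(P, k) {
  if (k < 1) stop("k must be >= 1")
  stopifnot(k <= ncol(P))
  hc <- hclust(dist(t(P), method = "euclidean"), method = "average")
  raw <- cutree(hc, k = k)
  labels <- as.integer(factor(raw, levels = unique(raw)))
  structure(list(labels = setNames(labels, colnames(P)), k = k,
                 linkage = "average", distance = "euclidean", tree = hc),
            class = "cluster_assignment")
}

#' Cluster assignment from explicit labels
#' @param labels Named vector (model -> cluster label).
#' @return A `"cluster_assignment"`.
#' @export
cluster_assignment <- function(labels) {
  lab <- as.integer(factor(labels, levels = unique(labels)))
  structure(list(labels = setNames(lab, names(labels)),
                 k = length(unique(lab)),
                 linkage = NA_character_, distance = NA_character_,
                 tree = NULL),
            class = "cluster_assignment")
}

#' Jaccard overlap between two clusterings
#'
#' For matched cluster pairs, `J = |intersection| / |union|` of member
#' models. Pairs are matched greedily by maximum overlap unless clusters
#' share names. Groups listed in `merge_map` (e.g. one tissue class spread
#' over several clusters) have their indices averaged into one reported
#' value.
#'
#' @param A,B `"cluster_assignment"` objects over the same model universe.
#' @param merge_map Optional named list: group name -> cluster labels of A
#'   to merge in the report.
#' @return `data.frame(cluster_A, cluster_B, jaccard)`; merged groups are
#'   appended with `cluster_A` set to the group name.
#' @export
cluster_jaccard <- function(A, B, merge_map = NULL) {
  ua <- names(A$labels); ub <- names(B$labels)
  if (!setequal(ua, ub)) stop("cluster assignments cover different models")
  membersA <- split(ua, A$labels[ua])
  membersB <- split(ub, B$labels[ub])
  jac <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  Jm <- outer(seq_along(membersA), seq_along(membersB),
              Vectorize(function(i, j) jac(membersA[[i]], membersB[[j]])))
  rows <- list()
  free_a <- seq_along(membersA); free_b <- seq_along(membersB)
  Jw <- Jm
  while (length(free_a) && length(free_b)) {
    best <- which(Jw == max(Jw), arr.ind = TRUE)[1, ]
    i <- free_a[best[1]]; j <- free_b[best[2]]
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_A = names(membersA)[i], cluster_B = names(membersB)[j],
      jaccard = Jm[i, j], stringsAsFactors = FALSE)
    free_a <- setdiff(free_a, i); free_b <- setdiff(free_b, j)
    Jw <- Jm[free_a, free_b, drop = FALSE]
    if (!length(Jw)) break
  }
  out <- do.call(rbind, rows)
  if (!is.null(merge_map)) {
    for (g in names(merge_map)) {
      sel <- out$cluster_A %in% as.character(merge_map[[g]])
      if (any(sel)) {
        out <- rbind(out, data.frame(cluster_A = g, cluster_B = NA_character_,
                                     jaccard = mean(out$jaccard[sel]),
                                     stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Subsystem coverage deviation across models
#'
#' Subsystem coverage (SC) is the number of a model's reactions in each
#' subsystem; the percent deviation is `(SC - SC_mean) / SC_mean * 100` with
#' `SC_mean` the mean coverage across models. Reactions without a subsystem
#' are bucketed as `"Unannotated"`.
#'
#' @param models Named list of `"gem"` objects.
#' @param min_reactions,min_pct_dev Display rule: keep subsystems with at
#'   least `min_reactions` reactions (in some model) and at least one model
#'   deviating by more than `min_pct_dev` percent (the defaults 15 and 50
#'   reproduce the conventional display filter).
#' @return List with `table` (model, subsystem, SC, SC_mean, pct_diff) and
#'   `display` (the filtered subset).
#' @export
subsystem_coverage <- function(models, min_reactions = 15, min_pct_dev = 50) {
  stopifnot(length(models) >= 1)
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  counts <- lapply(models, function(m) {
    ss <- m$reactions$subsystem
    ss[ss == ""] <- "Unannotated"
    table(ss)
  })
  subsystems <- sort(unique(unlist(lapply(counts, names))))
  SC <- sapply(counts, function(ct) {
    v <- as.integer(ct[subsystems]); v[is.na(v)] <- 0L; v
  })
  rownames(SC) <- subsystems
  SC_mean <- rowMeans(SC)
  tab <- data.frame(
    model = rep(colnames(SC), each = nrow(SC)),
    subsystem = rep(subsystems, ncol(SC)),
    SC = as.vector(SC),
    SC_mean = rep(SC_mean, ncol(SC)),
    stringsAsFactors = FALSE)
  tab$pct_diff <- ifelse(tab$SC_mean > 0,
                         (tab$SC - tab$SC_mean) / tab$SC_mean * 100,
                         0)
  keep <- vapply(subsystems, function(s) {
    rowsel <- tab$subsystem == s
    max(tab$SC[rowsel]) >= min_reactions &&
      any(abs(tab$pct_diff[rowsel]) > min_pct_dev)
  }, logical(1))
  list(table = tab, display = tab[tab$subsystem %in% subsystems[keep], ])
}

#' Define a metabolic task
#'
#' A feasibility query: can the network convert the input metabolites into
#' the outputs with every other exchange closed?
#'
#' @param id Task id.
#' @param inputs Named numeric vector: metabolite id -> maximum uptake.
#' @param outputs Named numeric vector: metabolite id -> minimum required
#'   production.
#' @param description,system,subsystem Optional annotation labels.
#' @return A `"metabolic_task"` object.
#' @export
metabolic_task <- function(id, inputs, outputs, description = "",
                           system = "", subsystem = "") {
  if (!length(inputs) || !length(outputs))
    stop("malformed task ", id, ": inputs and outputs must be non-empty")
  if (is.null(names(inputs)) || is.null(names(outputs)))
    stop("malformed task ", id, ": inputs/outputs must be named by metabolite")
  structure(list(id = id, inputs = inputs, outputs = outputs,
                 description = description, system = system,
                 subsystem = subsystem),
            class = "metabolic_task")
}

#' Read metabolic tasks from YAML
#'
#' Schema: a list of entries with `id`, `inputs` (map metabolite -> max
#' uptake), `outputs` (map metabolite -> min production), optional
#' `description`, `system`, `subsystem`.
#'
#' @param path YAML file path.
#' @return List of `"metabolic_task"` objects.
#' @export
read_tasks <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(t)
    metabolic_task(t$id, unlist(t$inputs), unlist(t$outputs),
                   description = if (is.null(t$description)) "" else t$description,
                   system = if (is.null(t$system)) "" else t$system,
                   subsystem = if (is.null(t$subsystem)) "" else t$subsystem))
}

#' Check metabolic-task feasibility
#'
#' For each task: all exchange reactions are closed, temporary uptake
#' reactions are added for the task inputs (bounded by the stated maximum)
#' and sink reactions for the outputs (with the stated minimum production as
#' a lower bound), and LP feasibility is tested. A task whose required
#' metabolite is absent from the model fails with reason
#' `"missing metabolite"`. Passing tasks attach a feasible witness flux
#' vector that satisfies mass balance.
#'
#' @param model A `"gem"` object.
#' @param tasks List of `"metabolic_task"` objects.
#' @return `data.frame(task, passed, reason)`; witnesses in attribute
#'   `"witness"` (a named list of flux vectors on the augmented model).
#' @export
check_tasks <- function(model, tasks) {
  validate_gem(model)
  ok <- vapply(tasks, inherits, logical(1), "metabolic_task")
  if (!all(ok)) stop("not a metabolic_task: element ", which(!ok)[1])
  out <- data.frame(task = vapply(tasks, `[[`, character(1), "id"),
                    passed = FALSE, reason = "", stringsAsFactors = FALSE)
  witnesses <- list()
  closed <- model
  ex <- exchange_reactions(closed)
  if (length(ex)) closed <- set_bounds(closed, ex, lower = 0, upper = 0)
  for (ti in seq_along(tasks)) {
    task <- tasks[[ti]]
    if (!inherits(task, "metabolic_task")) stop("not a metabolic_task")
    need <- c(names(task$inputs), names(task$outputs))
    absent <- setdiff(need, model$metabolites$id)
    if (length(absent)) {
      out$reason[ti] <- paste0("missing metabolite: ",
                               paste(absent, collapse = ", "))
      next
    }
    m <- closed
    for (met in names(task$inputs)) {
      row <- data.frame(id = paste0("TASK_IN_", met), name = "task uptake",
                        lower_bound = 0, upper_bound = task$inputs[[met]],
                        gpr = "", subsystem = "Task", ec_number = "",
                        is_exchange = TRUE, is_demand = FALSE,
                        stringsAsFactors = FALSE)
      m$reactions <- rbind(m$reactions, row)
      m$stoichiometry[[row$id]] <- setNames(1, met)
    }
    for (met in names(task$outputs)) {
      row <- data.frame(id = paste0("TASK_OUT_", met), name = "task sink",
                        lower_bound = task$outputs[[met]], upper_bound = 1e6,
                        gpr = "", subsystem = "Task", ec_number = "",
                        is_exchange = TRUE, is_demand = TRUE,
                        stringsAsFactors = FALSE)
      m$reactions <- rbind(m$reactions, row)
      m$stoichiometry[[row$id]] <- setNames(-1, met)
    }
    m <- new_gem(id = m$id, metabolites = m$metabolites,
                 reactions = m$reactions, stoichiometry = m$stoichiometry,
                 genes = m$genes, objective = numeric(0),
                 compartments = m$compartments,
                 default_bound = m$default_bound)
    parts <- lp_parts(m)
    obj <- numeric(length(parts$ids))
    obj[match(paste0("TASK_OUT_", names(task$outputs)), parts$ids)] <- 1
    res <- solve_lp(obj, parts$S, parts$lb, parts$ub, maximize = TRUE)
    if (res$status == "optimal") {
      out$passed[ti] <- TRUE
      witnesses[[task$id]] <- setNames(res$x, parts$ids)
    } else {
      out$reason[ti] <- "infeasible"
    }
  }
  attr(out, "witness") <- witnesses
  out
}

#' Task pass/fail matrix across models
#'
#' @param models Named list of `"gem"` objects.
#' @param tasks List of `"metabolic_task"` objects.
#' @return Binary matrix (models x tasks).
#' @export
task_matrix <- function(models, tasks) {
  res <- t(vapply(models, function(m) as.integer(check_tasks(m, tasks)$passed),
                  integer(length(tasks))))
  colnames(res) <- vapply(tasks, `[[`, character(1), "id")
  res
}

#' Fisher association between models and metabolic systems
#'
#' For each (model, system) pair, builds the 2x2 table of the model's passes
#' in the system vs elsewhere against the pooled passes of the other models,
#' and applies a two-sided Fisher exact test with BH adjustment. Tables with
#' an empty margin report `p = 1` and are flagged degenerate.
#'
#' @param task_results Binary models x tasks matrix from [task_matrix()].
#' @param systems Named character vector: task id -> system label (>= 2
#'   systems).
#' @return `data.frame(model, system, odds_ratio, p, p_adj, degenerate)`.
#' @export
fisher_association <- function(task_results, systems) {
  tasks <- colnames(task_results)
  systems <- systems[tasks]
  if (length(unique(systems)) < 2) stop("need at least 2 systems")
  models <- rownames(task_results)
  rows <- list()
  for (mdl in models) {
    for (sys in unique(systems)) {
      in_sys <- systems == sys
      a <- sum(task_results[mdl, in_sys])
      b <- sum(task_results[mdl, !in_sys])
      others <- task_results[setdiff(models, mdl), , drop = FALSE]
      c_ <- sum(others[, in_sys])
      d <- sum(others[, !in_sys])
      tabm <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
      degenerate <- any(rowSums(tabm) == 0) || any(colSums(tabm) == 0)
      if (degenerate) {
        rows[[length(rows) + 1L]] <- data.frame(
          model = mdl, system = sys, odds_ratio = NA_real_, p = 1,
          degenerate = TRUE, stringsAsFactors = FALSE)
      } else {
        ft <- fisher.test(tabm, alternative = "two.sided")
        rows[[length(rows) + 1L]] <- data.frame(
          model = mdl, system = sys,
          odds_ratio = unname(ft$estimate), p = ft$p.value,
          degenerate = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("model", "system", "odds_ratio", "p", "p_adj", "degenerate")]
}

#' Counts-per-million normalization
#'
#' `counts / library size * 1e6`, the normalization used to prepare
#' pseudo-bulk expression for model comparison; genes at or above
#' `threshold` CPM (default 1) are flagged expressed.
#'
#' @param counts Gene x sample count matrix.
#' @param threshold Expression threshold in CPM units.
#' @return List with `cpm` matrix and `expressed` logical matrix.
#' @export
cpm_normalize <- function(counts, threshold = 1) {
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("zero library size in column(s): ",
                              paste(which(libsize == 0), collapse = ", "))
  cpm <- sweep(counts, 2, libsize, "/") * 1e6
  list(cpm = cpm, expressed = cpm >= threshold)
}
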