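# ---------------------------------------------------------------------------
# Omics-side statistics: differential feature calls, hypergeometric ORA with
# BH correction, weighted Jaccard pathway overlap with bootstrap, isotopomer
# fractional-labeling normalization, and flux<->measurement correlation.
# ---------------------------------------------------------------------------

#' Differential feature calls on an intensity table
#'
#' Two-group contrasts use the log2 fold change of group means and a
#' two-sided Welch t-test. Multi-group ("one vs rest") contrasts compare
#' each group against the mean of the other groups with a one-way ANOVA
#' p-value per feature. Significance presets mirror common uses:
#' `"default"` (`|log2FC| > 0.5`, adjusted p < 0.05), `"strict"`
#' (`log2FC > 2`, raw p < 0.05); per-group overrides can relax the fold
#'-change cut (e.g. a low-coverage group using `log2FC > 0`).
#'
#' @param table An `"omics_table"` (see [simulate_metabolomics()]) or a list
#'   with `intensities` (features x samples) and `groups` (named by sample).
#' @param group Group to contrast (vs `other` or vs the rest).
#' @param other Optional second group for a two-group contrast; `NULL`
#'   contrasts `group` against all remaining samples with ANOVA.
#' @param lfc_cut Log2 fold-change cut.
#' @param p_cut P-value cut (applied to `p_adj` when `adjust = "bh"`).
#' @param adjust `"bh"` or `"none"`.
#' @return `data.frame(feature, log2fc, p, p_adj, significant)`.
#' @export
differential_features <- function(table, group, other = NULL,
                                  lfc_cut = 0.5, p_cut = 0.05,
                                  adjust = c("bh", "none")) {
  adjust <- match.arg(adjust)
  X <- log2(table$intensities)
  grp <- table$groups[colnames(X)]
  if (sum(grp == group) < 2) stop("need >= 2 samples in group ", group)
  in_g <- grp == group
  in_o <- if (is.null(other)) !in_g else grp == other
  if (sum(in_o) < 2) stop("need >= 2 samples in the comparison group")

  lfc <- rowMeans(X[, in_g, drop = FALSE]) - rowMeans(X[, in_o, drop = FALSE])
  if (is.null(other) && length(unique(grp)) > 2) {
    # one-vs-rest fold change with one-way ANOVA p across all groups
    p <- apply(X, 1, function(x) {
      fit <- aov(x ~ factor(grp))
      summary(fit)[[1]][["Pr(>F)"]][1]
    })
  } else {
    p <- apply(X, 1, function(x) {
      a <- x[in_g]; b <- x[in_o]
      if (sd(a) == 0 && sd(b) == 0) {
        return(if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0)
      }
      t.test(a, b)$p.value
    })
  }
  p_adj <- if (adjust == "bh") p.adjust(p, "BH") else p
  crit <- if (adjust == "bh") p_adj else p
  data.frame(feature = rownames(X), log2fc = unname(lfc),
             p = unname(p), p_adj = unname(p_adj),
             significant = unname(lfc > lfc_cut & crit < p_cut),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test per pathway, with pathway member
#' sets intersected with the detected-feature universe before testing, and
#' BH adjustment across the tested pathways. The enrichment ratio is
#' observed / expected overlap.
#'
#' @param hits Significant feature ids (must be a subset of `universe`).
#' @param universe All detected feature ids (the background).
#' @param pathway_db Named list: pathway -> member feature ids.
#' @param q_cut Significance threshold on the adjusted p-value.
#' @return An `"ora_result"` data frame: pathway, overlap, pathway_size,
#'   universe_size, n_hits, enrichment_ratio, p, p_adj, significant.
#' @export
ora_hypergeometric <- function(hits, universe, pathway_db, q_cut = 0.05) {
  hits <- unique(hits); universe <- unique(universe)
  if (!all(hits %in% universe))
    stop("hits must be a subset of the universe")
  N <- length(universe); n <- length(hits)
  rows <- lapply(names(pathway_db), function(pw) {
    members <- intersect(pathway_db[[pw]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, hits))
    p <- if (n == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expected <- n * K / N
    data.frame(pathway = pw, overlap = k, pathway_size = K,
               universe_size = N, n_hits = n,
               enrichment_ratio = if (expected > 0) k / expected else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pathway overlaps the universe")
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < q_cut
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Build a significance-weighted pathway set
#'
#' Weights are `-log10(q)` normalized to sum to 1 over the set. A set whose
#' weights are all 0 (every q = 1) falls back to uniform weights with a
#' notice. With `q` omitted, uniform weights `1/n` are assigned (the
#' convention for model-derived sets without significance values).
#'
#' @param pathways Pathway ids.
#' @param q Optional adjusted p-values aligned with `pathways`.
#' @return An `"enriched_pathway_set"`: data frame (pathway, weight), the
#'   weights summing to 1 (empty sets allowed).
#' @export
enriched_pathway_set <- function(pathways, q = NULL) {
  pathways <- as.character(pathways)
  if (anyDuplicated(pathways)) {
    keep <- !duplicated(pathways)
    if (!is.null(q)) q <- q[keep]
    pathways <- pathways[keep]
  }
  if (!length(pathways)) {
    out <- data.frame(pathway = character(0), weight = numeric(0))
  } else if (is.null(q)) {
    out <- data.frame(pathway = pathways, weight = 1 / length(pathways),
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(length(q) == length(pathways), all(q >= 0), all(q <= 1))
    w <- -log10(pmax(q, 1e-300))
    if (sum(w) == 0) {
      message("all q-values are 1; falling back to uniform weights")
      w <- rep(1, length(w))
    }
    out <- data.frame(pathway = pathways, weight = w / sum(w),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("enriched_pathway_set", "data.frame")
  out
}

#' GEM-side enriched pathways by reaction content
#'
#' For each model, a pathway is called enriched when its reaction count in
#' that model exceeds the median count of that pathway across all models
#' (per-pathway-across-models median; `per_model_median = TRUE` switches to
#' the per-model-across-pathways alternative).
#'
#' @param models Named list of `"gem"` objects.
#' @param per_model_median Alternative median convention flag.
#' @return Named list of `"enriched_pathway_set"` (uniform weights) per
#'   model.
#' @export
gem_enriched_pathways <- function(models, per_model_median = FALSE) {
  cov <- subsystem_coverage(models, min_reactions = 0, min_pct_dev = -1)$table
  out <- list()
  for (mdl in unique(cov$model)) {
    sub <- cov[cov$model == mdl, ]
    if (per_model_median) {
      med <- median(sub$SC[sub$SC > 0])
      sel <- sub$subsystem[sub$SC > med]
    } else {
      sel <- vapply(seq_len(nrow(sub)), function(i) {
        s <- sub$subsystem[i]
        sub$SC[i] > median(cov$SC[cov$subsystem == s])
      }, logical(1))
      sel <- sub$subsystem[sel]
    }
    out[[mdl]] <- enriched_pathway_set(sel)
  }
  out
}

#' Weighted Jaccard index between enriched pathway sets
#'
#' `J_w(A, B) = sum_{i in A int B} min(w_A(i), w_B(i)) /
#'  sum_{i in A un B} max(w_A(i), w_B(i))`, with weight 0 outside a set.
#' Under uniform equal-size weights this reduces to the plain Jaccard
#' index. Two empty sets score 0 with a warning.
#'
#' @param A,B `"enriched_pathway_set"` objects.
#' @return Numeric in `[0, 1]`.
#' @export
weighted_jaccard <- function(A, B) {
  all_pw <- union(A$pathway, B$pathway)
  if (!length(all_pw)) {
    warning("both pathway sets are empty; weighted Jaccard defined as 0")
    return(0)
  }
  wa <- setNames(rep(0, length(all_pw)), all_pw)
  wb <- wa
  wa[A$pathway] <- A$weight
  wb[B$pathway] <- B$weight
  sum(pmin(wa, wb)) / sum(pmax(wa, wb))
}

#' Bootstrap distribution of the weighted Jaccard index
#'
#' Resamples the experimentally enriched pathways (with replacement),
#' recomputes the significance weights and the index against a fixed
#' model-derived set per replicate. With several source regions, a one-way
#' ANOVA over the bootstrap replicates is followed by Bonferroni-corrected
#' pairwise tests against a declared reference region.
#'
#' @param A_source `data.frame(pathway, q)` of experimentally enriched
#'   pathways, or a named list of such frames (one per region).
#' @param B Fixed `"enriched_pathway_set"` (model side).
#' @param n_boot Bootstrap replicates (the full-scale convention is
#'   10,000).
#' @param seed Integer seed.
#' @param reference Reference region name (required for the group
#'   comparison).
#' @return For a single source: list with `point`, `replicates`, `mean`,
#'   `sd`, `degenerate`. For multiple: additionally `anova_p` and
#'   `pairwise` (vs the reference, Bonferroni-adjusted).
#' @export
bootstrap_weighted_jaccard <- function(A_source, B, n_boot = 1000, seed = 1,
                                       reference = NULL) {
  stopifnot(n_boot >= 1)
  set.seed(as.integer(seed))
  wb <- setNames(B$weight, B$pathway)
  wj_agg <- function(wa) {
    all_pw <- union(names(wa), names(wb))
    a <- setNames(rep(0, length(all_pw)), all_pw); b <- a
    a[names(wa)] <- wa; b[names(wb)] <- wb
    sum(pmin(a, b)) / sum(pmax(a, b))
  }
  boot_one <- function(src) {
    stopifnot(all(c("pathway", "q") %in% names(src)))
    point <- weighted_jaccard(enriched_pathway_set(src$pathway, src$q), B)
    w_raw <- -log10(pmax(src$q, 1e-300))
    if (sum(w_raw) == 0) w_raw <- rep(1, length(w_raw))
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(src), replace = TRUE)
      w <- w_raw[idx] / sum(w_raw[idx])
      # duplicates keep their resampled weight mass (summed per pathway)
      wa <- tapply(w, src$pathway[idx], sum)
      wj_agg(wa)
    }, numeric(1))
    list(point = point, replicates = reps, mean = mean(reps), sd = sd(reps),
         degenerate = nrow(src) < 2 || sd(reps) == 0)
  }
  if (is.data.frame(A_source)) return(boot_one(A_source))

  res <- lapply(A_source, boot_one)
  reps <- unlist(lapply(res, `[[`, "replicates"))
  region <- factor(rep(names(res), each = n_boot))
  fit <- aov(reps ~ region)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  pairwise <- NULL
  if (!is.null(reference)) {
    stopifnot(reference %in% names(res))
    others <- setdiff(names(res), reference)
    praw <- vapply(others, function(g)
      t.test(res[[reference]]$replicates, res[[g]]$replicates)$p.value,
      numeric(1))
    pairwise <- data.frame(region = others, p = praw,
                           p_adj = pmin(praw * length(others), 1),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  c(res, list(anova_p = anova_p, pairwise = pairwise))
}

#' Fractional labeling normalization of an isotopomer table
#'
#' Per metabolite and sample: the fractional labeling of each mass
#' isotopomer is its intensity over the metabolite's summed isotopomer
#' intensities (fractions sum to 1). The normalized value divides by the
#' tracer-reference fraction of the same sample (e.g. glucose M+6), and the
#' scaled value divides by the control-group mean of the normalized value,
#' so control-group scaled values average to 1 by construction. Samples
#' with zero tracer fraction are excluded with a warning.
#'
#' @param table An `"isotopomer_table"` long data frame (metabolite,
#'   isotopomer, condition, sample, intensity).
#' @param tracer_ref Character vector `c(metabolite, isotopomer)`; defaults
#'   to the table's `tracer` attribute.
#' @param control_group Control condition label used for scaling.
#' @return Long data frame with `fraction`, `normalized`, `scaled` columns.
#' @export
fractional_labeling <- function(table, tracer_ref = attr(table, "tracer"),
                                control_group) {
  stopifnot(length(tracer_ref) >= 2)
  df <- as.data.frame(table)
  stopifnot(all(df$intensity >= 0))
  tot <- stats::ave(df$intensity, df$metabolite, df$sample, FUN = sum)
  df$fraction <- ifelse(tot > 0, df$intensity / tot, 0)

  tr <- df[df$metabolite == tracer_ref[[1]] &
             df$isotopomer == tracer_ref[[2]], c("sample", "fraction")]
  if (!nrow(tr)) stop("tracer reference not found: ",
                      paste(tracer_ref, collapse = " "))
  trf <- setNames(tr$fraction, tr$sample)
  missing_tracer <- setdiff(unique(df$sample), names(trf))
  if (length(missing_tracer))
    stop("tracer reference missing in sample(s): ",
         paste(missing_tracer, collapse = ", "))
  bad <- names(trf)[trf == 0]
  if (length(bad)) {
    warning("zero tracer fraction; excluding sample(s): ",
            paste(bad, collapse = ", "))
    df <- df[!(df$sample %in% bad), ]
    trf <- trf[setdiff(names(trf), bad)]
  }
  df$normalized <- df$fraction / trf[df$sample]

  ctrl <- df$condition == control_group
  if (!any(ctrl)) stop("control group not present: ", control_group)
  key <- paste(df$metabolite, df$isotopomer)
  ctrl_mean <- tapply(df$normalized[ctrl], key[ctrl], mean)
  df$scaled <- df$normalized / as.numeric(ctrl_mean[key])
  rownames(df) <- NULL
  df
}

#' Correlation between relative fluxes and measurements
#'
#' Maps each reaction's condition/reference flux ratio to a measured
#' feature ratio through an explicit reaction -> feature mapping (never
#' inferred), and reports the Pearson correlation with a two-sided test and
#' the fitted least-squares line.
#'
#' @param flux_ratios Named numeric: reaction -> relative flux
#'   (condition / reference).
#' @param mapping Named character: reaction -> measured feature id.
#' @param measurements Named numeric: feature -> relative measurement.
#' @return List with `r`, `p`, `n`, `fit` (intercept, slope) and the paired
#'   `data`; `r` is `NA` with reason `"constant input"` when either vector
#'   is constant.
#' @export
flux_measurement_correlation <- function(flux_ratios, mapping, measurements) {
  rxns <- intersect(names(flux_ratios), names(mapping))
  feats <- mapping[rxns]
  keep <- feats %in% names(measurements)
  rxns <- rxns[keep]; feats <- feats[keep]
  if (length(rxns) < 3)
    stop("mapping must cover at least 3 reactions with measurements")
  x <- unname(flux_ratios[rxns]); y <- unname(measurements[feats])
  dat <- data.frame(reaction = rxns, feature = unname(feats), flux_ratio = x,
                    measurement = y, stringsAsFactors = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), fit = NULL,
                data = dat, reason = "constant input"))
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       fit = c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2])),
       data = dat)
}
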