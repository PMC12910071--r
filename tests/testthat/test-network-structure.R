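test_that("Hamming similarity counts differing reactions and is metric", {
  fam <- make_model_family(n_models = 4, between_effect = 2, within_noise = 0,
                           seed = 1)
  P <- presence_matrix(fam$models)
  hs <- hamming_similarity(P)
  expect_equal(diag(hs$distance), rep(0, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(hs$distance))
  expect_equal(diag(hs$similarity), rep(1, 4), ignore_attr = TRUE)
  # same family, no noise: identical; across families: 2 * block size
  expect_equal(hs$distance["model01_f1", "model03_f1"], 0)
  expect_equal(hs$distance["model01_f1", "model02_f2"], 4)

  # triangle inequality over random binary models
  set.seed(42)
  for (rep in 1:20) {
    M <- matrix(rbinom(30, 1, 0.5), nrow = 10, ncol = 3,
                dimnames = list(paste0("r", 1:10), c("x", "y", "z")))
    d <- hamming_similarity(M)$distance
    expect_lte(d["x", "z"], d["x", "y"] + d["y", "z"])
  }

  # Euclidean distance on binary columns is sqrt(Hamming)
  expect_equal(as.matrix(dist(t(P)))^2, hs$distance,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("hierarchical clustering recovers planted families and edge cases", {
  fam <- make_model_family(n_models = 8, between_effect = 10, within_noise = 1,
                           seed = 2)
  P <- presence_matrix(fam$models)
  cl <- hierarchical_clusters(P, k = 2)
  truth <- cluster_assignment(fam$truth$family)
  jac <- cluster_jaccard(cl, truth)
  expect_equal(jac$jaccard, rep(1, 2))

  # k = number of models: singletons
  cl_all <- hierarchical_clusters(P, k = ncol(P))
  expect_equal(sort(unique(cl_all$labels)), seq_len(ncol(P)))
  expect_error(hierarchical_clusters(P, k = 0), "k must be")
})

test_that("cluster Jaccard matches enumeration and merge averaging", {
  a <- cluster_assignment(c(m1 = 1, m2 = 1, m3 = 2, m4 = 2))
  expect_equal(cluster_jaccard(a, a)$jaccard, c(1, 1))
  # completely crossed 2+2 partitions: every matched pair overlaps 1 of 3
  b <- cluster_assignment(c(m1 = 1, m2 = 2, m3 = 1, m4 = 2))
  expect_equal(cluster_jaccard(a, b)$jaccard, c(1 / 3, 1 / 3))
  # merge map averages the indices of a group split over clusters
  cj <- cluster_jaccard(a, b, merge_map = list(glia = c(1, 2)))
  expect_equal(cj$jaccard[cj$cluster_A == "glia"], 1 / 3)
  expect_error(cluster_jaccard(a, cluster_assignment(c(x = 1, y = 2))),
               "different models")
})

test_that("subsystem coverage deviation follows its formula and display rule", {
  mk <- function(id, n_extra) {
    base <- chain_model(k = 3)
    if (n_extra > 0) {
      mets <- base$metabolites
      rx <- base$reactions[, 1:7]
      st <- base$stoichiometry
      for (i in seq_len(n_extra)) {
        rid <- sprintf("EXTRA%02d", i)
        rx <- rbind(rx, data.frame(id = rid, name = rid, lower_bound = 0,
                                   upper_bound = 1000, gpr = "",
                                   subsystem = "Bulk", ec_number = ""))
        st[[rid]] <- c("glc[c]" = 1)
      }
      base <- new_gem(id, mets, rx, st, objective = base$objective)
    }
    base
  }
  models <- list(a = mk("a", 10), b = mk("b", 20), c = mk("c", 30))
  sc <- subsystem_coverage(models, min_reactions = 15, min_pct_dev = 40)
  bulk <- sc$table[sc$table$subsystem == "Bulk", ]
  expect_equal(bulk$SC_mean, rep(20, 3))
  expect_equal(sort(bulk$pct_diff), c(-50, 0, 50))
  expect_true("Bulk" %in% sc$display$subsystem)
  expect_false("Glycolysis" %in% sc$display$subsystem)  # equal everywhere
})

test_that("task feasibility respects directionality, absence, and attaches witnesses", {
  m <- chain_model(k = 3, uptake = 10)
  t_fwd <- metabolic_task("fwd", inputs = c("glc[c]" = 10),
                          outputs = c("pyr[c]" = 1))
  t_rev <- metabolic_task("rev", inputs = c("pyr[c]" = 10),
                          outputs = c("glc[c]" = 1))
  t_missing <- metabolic_task("missing", inputs = c("unobtainium[c]" = 1),
                              outputs = c("pyr[c]" = 1))
  res <- check_tasks(m, list(t_fwd, t_rev, t_missing))
  expect_equal(res$passed, c(TRUE, FALSE, FALSE))
  expect_match(res$reason[3], "missing metabolite")
  w <- attr(res, "witness")$fwd
  expect_gte(w[["TASK_OUT_pyr[c]"]], 1 - 1e-9)
  # the witness is exchange-closed and mass balanced on the augmented network
  expect_equal(w[["EX_glc"]], 0)
  expect_error(check_tasks(m, list("not a task")), "not a metabolic_task")
  expect_error(metabolic_task("bad", inputs = numeric(0), outputs = c(x = 1)),
               "non-empty")
})

test_that("Fisher association matches the hypergeometric tail oracle", {
  # model passing all and only system-X tasks vs others passing none
  tm <- matrix(c(1, 1, 1, 0, 0, 0,
                 0, 0, 0, 0, 0, 0,
                 0, 0, 0, 0, 0, 0), nrow = 3, byrow = TRUE,
               dimnames = list(c("m1", "m2", "m3"), paste0("t", 1:6)))
  systems <- setNames(rep(c("X", "Y"), each = 3), paste0("t", 1:6))
  fa <- fisher_association(tm, systems)
  # degenerate margins (other models pass nothing) are flagged, p = 1
  expect_true(all(fa$degenerate[fa$model %in% c("m2", "m3")] |
                    fa$p[fa$model %in% c("m2", "m3")] == 1))

  # uniform pass pattern: all p = 1
  tu <- matrix(1, 3, 6, dimnames = dimnames(tm))
  fu <- fisher_association(tu, systems)
  expect_true(all(fu$p == 1))

  # hand 2x2 table (3,1;1,3) against the exact enumeration of the tail
  tm2 <- rbind(m1 = c(1, 1, 1, 0, 1, 0, 0, 0),
               m2 = c(0, 0, 0, 1, 0, 1, 1, 1))
  colnames(tm2) <- paste0("t", 1:8)
  sys2 <- setNames(rep(c("X", "Y"), each = 4), paste0("t", 1:8))
  fa2 <- fisher_association(tm2, sys2)
  # m1 in X: a=3,b=1,c=1,d=3 -> two-sided Fisher p by enumeration:
  # P(k) = C(4,k) C(4,4-k) / C(8,4); two-sided = sum of P(k) <= P(3)
  pk <- choose(4, 0:4) * choose(4, 4 - (0:4)) / choose(8, 4)
  p_expected <- sum(pk[pk <= pk[4] + 1e-12])
  expect_equal(fa2$p[fa2$model == "m1" & fa2$system == "X"], p_expected,
               tolerance = 1e-12)
  expect_true(all(fa2$p_adj >= fa2$p - 1e-15))
})

test_that("CPM normalization scales by library size and thresholds at 1", {
  counts <- matrix(c(10, 90, 0, 50, 50, 0), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  res <- cpm_normalize(counts, threshold = 1)
  expect_equal(colSums(res$cpm), c(s1 = 1e6, s2 = 1e6))
  expect_equal(res$cpm["g1", "s1"], 0.1 * 1e6)
  expect_false(res$expressed["g3", "s1"])
  expect_error(cpm_normalize(matrix(0, 2, 1)), "zero library size")
})
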