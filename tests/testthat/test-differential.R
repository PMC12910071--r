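run_three_methods <- function(model, n_samples = 300, seed = 5) {
  fba <- run_fba(model)
  pfba <- run_pfba(model)
  fva <- run_fva(model, alpha = 0.9, keep_solutions = TRUE)
  samp <- suppressWarnings(
    sample_fluxes(model, fva, n_samples = n_samples, seed = seed))
  list(fba = fba$fluxes, pfba = pfba$fluxes, sampling = median_fluxes(samp))
}

test_that("identical conditions produce no consensus calls", {
  m <- make_toy_gem(seed = 6)$model
  res <- run_three_methods(m)
  d <- differential_fluxes(res, res, threshold = 1)
  expect_true(all(d$table$consensus == "none"))
  expect_length(d$sets$decreased, 0)
  expect_length(d$sets$increased, 0)
})

test_that("a planted bottleneck and its obligate chain land in the decreased consensus", {
  tg <- make_toy_gem(seed = 7)
  m <- tg$model
  cond <- apply_condition(m, condition_spec(
    bound_overrides = data.frame(reaction = tg$truth$bottleneck,
                                 lower = NA, upper = 1)))
  ref <- run_three_methods(m, seed = 7)
  hsd <- run_three_methods(cond, seed = 17)
  d <- differential_fluxes(ref, hsd, threshold = 1)
  expect_true(tg$truth$bottleneck %in% d$sets$decreased)
  expect_true(all(tg$truth$chain_reactions %in% d$sets$decreased))
  expect_false(any(d$sets$increased %in% tg$truth$chain_reactions))
})

test_that("consensus sets shrink monotonically as the threshold rises", {
  tg <- make_toy_gem(seed = 8)
  m <- tg$model
  cond <- apply_condition(m, condition_spec(
    bound_overrides = data.frame(reaction = tg$truth$bottleneck,
                                 lower = NA, upper = 1)))
  ref <- run_three_methods(m, seed = 8)
  hsd <- run_three_methods(cond, seed = 18)
  prev_dec <- NULL; prev_inc <- NULL
  for (th in c(0.5, 1, 2, 5)) {
    d <- differential_fluxes(ref, hsd, threshold = th)
    if (!is.null(prev_dec)) {
      expect_true(all(d$sets$decreased %in% prev_dec))
      expect_true(all(d$sets$increased %in% prev_inc))
    }
    prev_dec <- d$sets$decreased; prev_inc <- d$sets$increased
  }
})

test_that("universe mismatches across conditions are an error", {
  m <- make_toy_gem(seed = 6)$model
  res <- run_three_methods(m)
  res2 <- lapply(res, function(v) v[-1])
  expect_error(differential_fluxes(res, res2, threshold = 1), "universes differ")
})

test_that("the flux Z statistic matches its closed form and edge conventions", {
  stats_ref <- data.frame(reaction = c("r1", "r2", "r3"),
                          mean = c(5, 5, 2), var = c(1, 1, 0), median = c(5, 5, 2))
  stats_cond <- data.frame(reaction = c("r1", "r2", "r3"),
                           mean = c(5, 6, 2), var = c(1, 1, 0), median = c(5, 6, 2))
  zt <- flux_z_test(mk_sample_set(stats_ref, 100), mk_sample_set(stats_cond, 100),
                    correction = "bonferroni")
  # equal means: Z = 0, p = 1 (any variance)
  expect_equal(zt$Z[zt$reaction == "r1"], 0)
  expect_equal(zt$p[zt$reaction == "r1"], 1)
  # delta 1, var 1/1, n 100/100: Z = 1/sqrt(0.02)
  expect_equal(zt$Z[zt$reaction == "r2"], 1 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(zt$p[zt$reaction == "r2"],
               2 * pnorm(-1 / sqrt(0.02)), tolerance = 1e-12)
  # zero variance, equal means: Z = 0, p = 1, not degenerate
  expect_equal(zt$p[zt$reaction == "r3"], 1)
  expect_false(zt$degenerate[zt$reaction == "r3"])
  expect_true(all(zt$p_adj >= zt$p - 1e-15))

  # zero variance with unequal means is flagged degenerate with p = 0
  stats_cond2 <- stats_cond
  stats_cond2$mean[3] <- 4; stats_cond2$median[3] <- 4
  zt2 <- flux_z_test(mk_sample_set(stats_ref, 100), mk_sample_set(stats_cond2, 100))
  expect_true(zt2$degenerate[zt2$reaction == "r3"])
  expect_equal(zt2$p[zt2$reaction == "r3"], 0)

  # antisymmetry under swapping conditions; p invariant
  zt3 <- flux_z_test(mk_sample_set(stats_cond, 100), mk_sample_set(stats_ref, 100))
  expect_equal(zt3$Z, -zt$Z)
  expect_equal(zt3$p, zt$p)
})

test_that("Z tests on sampled toy conditions flag the NAD(H)-dependent bottleneck", {
  tg <- make_toy_gem(seed = 9)
  m <- tg$model
  cond <- apply_condition(m, condition_spec(
    bound_overrides = data.frame(reaction = tg$truth$bottleneck,
                                 lower = NA, upper = 1)))
  s_ref <- sample_fluxes(m, n_samples = 400, seed = 9)
  s_cond <- sample_fluxes(cond, n_samples = 400, seed = 19)
  nadh_rxns <- cofactor_reactions(m, c("nadh[c]", "nadh[m]"))
  act <- active_reactions(list(s_ref, s_cond), nadh_rxns)
  expect_true(tg$truth$bottleneck %in% act)
  zt <- flux_z_test(s_ref, s_cond, reactions = act, correction = "bonferroni")
  row <- zt[zt$reaction == tg$truth$bottleneck, ]
  expect_lt(row$Z, 0)
  expect_lt(row$p_adj, 0.01)
})

test_that("sensitivity is 1 on a strict chain and 0 behind a full-capacity bypass", {
  # the compensation property is structural; evaluated at full optimality
  # (alpha = 1) where the output flux is pinned and the property is exact
  cm <- chain_model(k = 4, uptake = 10)
  targets <- grep("^GLY", cm$reactions$id, value = TRUE)
  sens <- suppressWarnings(sensitivity_analysis(
    cm, targets, "pyr[c]", levels = c(0.95, 0.5),
    n_samples = 200, seed = 3, alpha = 1))
  expect_true(all(abs(sens$table$S - 1) < 0.05))

  bm <- bypass_model(k = 4, step = 2, uptake = 10)
  bys <- grep("_alt", bm$reactions$id, value = TRUE)
  target <- sub("_alt1", "", bys)
  sens2 <- suppressWarnings(sensitivity_analysis(
    bm, target, "pyr[c]", levels = c(0.95, 0.5),
    n_samples = 500, seed = 3, alpha = 1))
  expect_true(all(abs(sens2$table$S) < 0.05))
})

test_that("zero-baseline targets are reported not-applicable", {
  cm <- chain_model(k = 3, uptake = 10)
  # a dead-end side reaction that can never carry flux
  mets <- rbind(cm$metabolites,
                data.frame(id = "dead[c]", name = "dead", compartment = "c",
                           formula = NA_character_))
  rx <- rbind(cm$reactions[, c("id", "name", "lower_bound", "upper_bound",
                               "gpr", "subsystem", "ec_number")],
              data.frame(id = "DEAD", name = "DEAD", lower_bound = 0,
                         upper_bound = 1000, gpr = "", subsystem = "",
                         ec_number = ""))
  st <- c(cm$stoichiometry, list(DEAD = c("glc[c]" = -1, "dead[c]" = 1)))
  m <- new_gem("dead_toy", mets, rx, st, objective = cm$objective)
  sens <- suppressWarnings(sensitivity_analysis(
    m, "DEAD", "pyr[c]", levels = 0.5, n_samples = 100, seed = 1))
  expect_false(any(sens$table$applicable))
  expect_true(all(is.na(sens$table$S)))
})

test_that("pathway flux is the mean of non-zero magnitudes and tests behave", {
  # hand application: fluxes {3, -3, 0} -> mean(|3|, |-3|) = 3
  samples <- matrix(c(3, -3, 0, 5, 5, 5), nrow = 2, byrow = TRUE,
                    dimnames = list(NULL, c("a", "b", "c")))
  ss <- structure(list(samples = samples, n = 2,
                       stats = data.frame(reaction = c("a", "b", "c"),
                                          mean = colMeans(samples),
                                          var = apply(samples, 2, var),
                                          median = apply(samples, 2, median))),
                  class = "flux_sample_set")
  V <- pathway_fluxes(ss, list(P = c("a", "b", "c"), Q = c("a")))
  expect_equal(unname(V[1, "P"]), 3)
  expect_equal(unname(V[2, "P"]), 5)
  expect_equal(unname(V[, "Q"]), c(3, 5))
  expect_warning(pathway_fluxes(ss, list(E = character(0), P = "a")), "skipping")

  # singleton pathway equals the reaction's |median flux|
  m <- make_toy_gem(seed = 10)$model
  samp <- sample_fluxes(m, n_samples = 300, seed = 10)
  V1 <- pathway_fluxes(samp, list(single = "GAPDH"))
  expect_equal(median(V1[, "single"]), abs(median_fluxes(samp)[["GAPDH"]]),
               tolerance = 1e-9)

  # identical inputs: Z = 0; doubled deterministic flux: log2fc = 1
  pz <- pathway_z_test(V, V)
  expect_equal(pz$Z, c(0, 0))
  p1 <- pathway_fluxes(setNames(c(2, 4), c("a", "b")), list(P = c("a", "b")))
  p2 <- pathway_fluxes(setNames(c(4, 8), c("a", "b")), list(P = c("a", "b")))
  pz2 <- pathway_z_test(p1, p2)
  expect_equal(pz2$log2fc, 1)
  expect_null(pz2$Z)  # single solutions: no statistical test
})

test_that("a planted pathway knock-down is recovered as the most negative log2fc", {
  tg <- make_toy_gem(seed = 11)
  m <- tg$model
  # choke the cycle entry: the TCA-like pathway (and its obligate transporter)
  # collapses while glycolysis is rerouted and stays near its baseline
  cond <- apply_condition(m, condition_spec(
    bound_overrides = data.frame(reaction = "TCA1", lower = NA, upper = 0.02)))
  pmap <- subsystem_pathway_map(m, drop = c("", "Exchange"))
  s_ref <- sample_fluxes(m, n_samples = 400, seed = 11)
  s_cond <- sample_fluxes(cond, n_samples = 400, seed = 21)
  pz <- pathway_z_test(pathway_fluxes(s_ref, pmap),
                       pathway_fluxes(s_cond, pmap))
  worst <- pz$pathway[which.min(pz$log2fc)]
  expect_true(worst %in% c("TCA cycle", "Transport"))
  expect_lt(pz$log2fc[pz$pathway == "TCA cycle"], -2)
  expect_lt(pz$Z[pz$pathway == "TCA cycle"], 0)
  expect_lt(abs(pz$log2fc[pz$pathway == "Glycolysis"]), 0.5)
})
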