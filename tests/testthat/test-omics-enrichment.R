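test_that("differential feature calls recover planted effects and not nulls", {
  sim <- simulate_metabolomics(groups = c("g1", "g2"), n_per_group = 4,
                               n_features = 40, n_enriched_per_group = 4,
                               effect = 2, noise_sd = 0.25, seed = 5)
  df <- differential_features(sim$table, "g1", "g2",
                              lfc_cut = 0.5, p_cut = 0.05)
  planted <- sim$truth$planted$g1
  expect_true(all(planted %in% df$feature[df$significant]))

  # identical groups: nothing called
  null_sim <- simulate_metabolomics(groups = c("g1", "g2"), n_per_group = 4,
                                    n_features = 40, n_enriched_per_group = 0,
                                    effect = 0, noise_sd = 0.25, seed = 6)
  df0 <- differential_features(null_sim$table, "g1", "g2")
  expect_equal(sum(df0$significant), 0)
  expect_lt(max(abs(df0$log2fc)), 1)

  # multi-group one-vs-rest contrast with ANOVA p
  sim4 <- simulate_metabolomics(n_per_group = 3, seed = 7)
  d4 <- differential_features(sim4$table, "thorax", lfc_cut = 0.5, p_cut = 0.05)
  expect_true(all(sim4$truth$planted$thorax %in% d4$feature[d4$significant]))
})

test_that("hypergeometric ORA equals the exact combinatorial tail", {
  # universe == pathway: enrichment impossible, p = 1
  db1 <- list(all = paste0("f", 1:12))
  o1 <- ora_hypergeometric(paste0("f", 1:3), paste0("f", 1:12), db1)
  expect_equal(o1$p, 1)

  # universe 20, pathway 5, hits 5, overlap 5 -> p = 1 / C(20,5)
  uni <- paste0("f", 1:20)
  db2 <- list(pw = uni[1:5])
  o2 <- ora_hypergeometric(uni[1:5], uni, db2)
  expect_equal(o2$p, 1 / choose(20, 5), tolerance = 1e-12)

  # oracle equivalence on random small universes (<= 25 features)
  set.seed(1)
  for (rep in 1:25) {
    N <- sample(8:25, 1)
    uni <- paste0("f", seq_len(N))
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    members <- sample(uni, K)
    hits <- sample(uni, n)
    k_obs <- length(intersect(members, hits))
    got <- ora_hypergeometric(hits, uni, list(pw = members))
    # closed-form tail: sum_j>=k C(K,j) C(N-K,n-j) / C(N,n)
    j <- k_obs:min(K, n)
    p_oracle <- sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
    expect_equal(got$p, p_oracle, tolerance = 1e-10)
    expect_equal(got$enrichment_ratio, k_obs / (n * K / N), tolerance = 1e-12)
  }

  # empty hits: all p = 1; BH keeps p_adj >= p
  o3 <- ora_hypergeometric(character(0), uni, list(pw = uni[1:5]))
  expect_equal(o3$p, 1)
  expect_error(ora_hypergeometric("not_in_universe", uni, db2), "subset")
})

test_that("ORA on simulated regional metabolomics recovers the planted pathway", {
  sim <- simulate_metabolomics(n_per_group = 4, effect = 2.5, seed = 8)
  calls <- differential_features(sim$table, "thorax", lfc_cut = 0.5,
                                 p_cut = 0.05)
  db <- split(sim$table$features$id, sim$table$features$pathway)
  ora <- ora_hypergeometric(calls$feature[calls$significant],
                            sim$table$features$id, db)
  expect_equal(ora$pathway[1], unname(sim$truth$planted_pathways["thorax"]))
  expect_true(ora$significant[1])
})

test_that("weighted Jaccard obeys its identities, bounds and monotonicity", {
  A <- enriched_pathway_set(c("p1", "p2", "p3"), q = c(0.01, 0.02, 0.03))
  expect_equal(weighted_jaccard(A, A), 1)
  B <- enriched_pathway_set(c("q1", "q2"))
  expect_equal(weighted_jaccard(A, B), 0)
  expect_warning(
    expect_equal(weighted_jaccard(enriched_pathway_set(character(0)),
                                  enriched_pathway_set(character(0))), 0),
    "empty")

  # uniform weights, equal sizes: reduces to plain Jaccard
  U1 <- enriched_pathway_set(c("a", "b", "c", "d"))
  U2 <- enriched_pathway_set(c("c", "d", "e", "f"))
  expect_equal(weighted_jaccard(U1, U2), 2 / 6, tolerance = 1e-12)

  # moving weight from a shared to an unshared pathway never increases J
  A1 <- structure(data.frame(pathway = c("s", "u"), weight = c(0.7, 0.3)),
                  class = c("enriched_pathway_set", "data.frame"))
  A2 <- structure(data.frame(pathway = c("s", "u"), weight = c(0.5, 0.5)),
                  class = c("enriched_pathway_set", "data.frame"))
  Bf <- enriched_pathway_set("s")
  expect_gte(weighted_jaccard(A1, Bf), weighted_jaccard(A2, Bf))

  # weights normalize to 1 and q = 1 everywhere falls back to uniform
  expect_equal(sum(A$weight), 1)
  expect_message(Aq1 <- enriched_pathway_set(c("x", "y"), q = c(1, 1)),
                 "uniform")
  expect_equal(Aq1$weight, c(0.5, 0.5))
})

test_that("bootstrap weighted Jaccard is reproducible with sane dispersion", {
  src <- data.frame(pathway = paste0("p", 1:8),
                    q = c(0.001, 0.01, 0.02, 0.03, 0.2, 0.4, 0.6, 0.9))
  B <- enriched_pathway_set(paste0("p", c(1:4, 9:10)))
  b1 <- bootstrap_weighted_jaccard(src, B, n_boot = 400, seed = 3)
  b2 <- bootstrap_weighted_jaccard(src, B, n_boot = 400, seed = 3)
  expect_identical(b1$replicates, b2$replicates)
  expect_false(b1$degenerate)
  # replicates are valid indices; set-valued resampling shifts the
  # distribution below the point estimate (each replicate misses part of
  # the set), so the mean bounds the point from below
  expect_true(all(b1$replicates >= 0 & b1$replicates <= 1))
  expect_lte(b1$mean, b1$point)

  # single-pathway source: degenerate distribution flagged
  b3 <- bootstrap_weighted_jaccard(data.frame(pathway = "p1", q = 0.01),
                                   enriched_pathway_set("p1"),
                                   n_boot = 50, seed = 1)
  expect_true(b3$degenerate)
  expect_equal(unique(b3$replicates), 1)

  # multi-region comparison: matched region wins, reference tests reported
  regions <- list(
    thorax = data.frame(pathway = paste0("p", 1:6),
                        q = c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1)),
    head = data.frame(pathway = paste0("x", 1:5),
                      q = c(0.01, 0.02, 0.03, 0.04, 0.05)))
  Bm <- enriched_pathway_set(paste0("p", 1:6))
  mb <- bootstrap_weighted_jaccard(regions, Bm, n_boot = 200, seed = 4,
                                   reference = "thorax")
  expect_gt(mb$thorax$mean, mb$head$mean)
  expect_lt(mb$anova_p, 0.001)
  expect_equal(mb$pairwise$region, "head")
  expect_lt(mb$pairwise$p_adj, 0.001)
})

test_that("fractional labeling normalizes, references the tracer, and scales", {
  sim <- simulate_labeling(seed = 2)
  fl <- fractional_labeling(sim$table, control_group = "NSD")
  # fractions sum to 1 per metabolite and sample
  sums <- tapply(fl$fraction, paste(fl$metabolite, fl$sample), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  # control-group scaled values average to 1 per (metabolite, isotopomer)
  ctrl <- fl[fl$condition == "NSD", ]
  means <- tapply(ctrl$scaled, paste(ctrl$metabolite, ctrl$isotopomer), mean)
  expect_equal(as.numeric(means), rep(1, length(means)), tolerance = 1e-12)

  # hand arithmetic: M+0 = 75, M+3 = 25 -> fraction 0.25
  tab <- data.frame(
    metabolite = c("glc", "glc", "m", "m"),
    isotopomer = c("M+0", "M+6", "M+0", "M+3"),
    condition = "NSD", sample = "s1",
    intensity = c(10, 90, 75, 25))
  f2 <- fractional_labeling(tab, tracer_ref = c("glc", "M+6"),
                            control_group = "NSD")
  expect_equal(f2$fraction[f2$metabolite == "m" & f2$isotopomer == "M+3"], 0.25)
  expect_equal(f2$normalized[f2$metabolite == "m" & f2$isotopomer == "M+3"],
               0.25 / 0.9)

  # zero tracer fraction excludes the sample with a warning
  tab2 <- rbind(tab, data.frame(metabolite = c("glc", "m"),
                                isotopomer = c("M+6", "M+3"),
                                condition = "NSD", sample = "s2",
                                intensity = c(0, 10)))
  expect_warning(f3 <- fractional_labeling(tab2, c("glc", "M+6"), "NSD"),
                 "zero tracer")
  expect_false("s2" %in% f3$sample)
})

test_that("the labeling simulator plants a recoverable bottleneck attenuation", {
  sim <- simulate_labeling(bottleneck_scale = 0.1, noise_sd = 0.02, seed = 9)
  fl <- fractional_labeling(sim$table, control_group = "NSD")
  lab <- fl[fl$isotopomer == "M+3", ]
  down <- sim$truth$chain[(sim$truth$bottleneck_after + 1):length(sim$truth$chain)]
  hsd_down <- lab$scaled[lab$condition == "HSD" & lab$metabolite %in% down]
  hsd_up <- lab$scaled[lab$condition == "HSD" & !lab$metabolite %in% down &
                         lab$metabolite %in% sim$truth$chain]
  expect_lt(mean(hsd_down) / mean(hsd_up), 0.2)
})

test_that("flux-measurement correlation matches the closed-form Pearson r", {
  flux <- setNames(c(1, 2, 3, 4, 5), paste0("r", 1:5))
  mapping <- setNames(paste0("f", 1:5), paste0("r", 1:5))
  meas_up <- setNames(c(1, 2, 3, 4, 5), paste0("f", 1:5))
  expect_equal(flux_measurement_correlation(flux, mapping, meas_up)$r, 1)
  expect_equal(flux_measurement_correlation(flux, mapping, -meas_up)$r, -1)

  set.seed(10)
  x <- rnorm(8); y <- rnorm(8)
  res <- flux_measurement_correlation(setNames(x, paste0("r", 1:8)),
                                      setNames(paste0("f", 1:8), paste0("r", 1:8)),
                                      setNames(y, paste0("f", 1:8)))
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  t_stat <- r_oracle * sqrt(6 / (1 - r_oracle^2))
  expect_equal(res$p, 2 * pt(-abs(t_stat), df = 6), tolerance = 1e-12)

  const <- flux_measurement_correlation(
    setNames(rep(1, 4), paste0("r", 1:4)),
    setNames(paste0("f", 1:4), paste0("r", 1:4)),
    setNames(1:4, paste0("f", 1:4)))
  expect_true(is.na(const$r))
  expect_equal(const$reason, "constant input")
  expect_error(flux_measurement_correlation(flux[1:2], mapping, meas_up),
               "at least 3")
})
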