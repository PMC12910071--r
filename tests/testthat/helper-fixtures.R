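# Fixture models built in code.

# Plain linear chain: EX -> A -> ... -> biomass, every flux forced equal.
chain_model <- function(k = 4, uptake = 10) {
  make_toy_gem(chain_length = k, cycle_length = 0, compartments = "c",
               cofactor_coupling = FALSE, secretion = FALSE,
               uptake_bound = uptake, seed = 1)$model
}

# Chain with a full-capacity parallel copy of one step.
bypass_model <- function(k = 4, step = 2, uptake = 10) {
  make_toy_gem(chain_length = k, cycle_length = 0, compartments = "c",
               cofactor_coupling = FALSE, secretion = FALSE,
               n_parallel_paths = 2, bypass_step = step,
               uptake_bound = uptake, seed = 1)$model
}

# Hand-built 5-metabolite x 7-reaction branched network with a known
# feasible flux vector (used for S.v = 0 checks and oracle comparisons):
#   EX_A -> A; A -> B; A -> C; B -> D; C -> D; D -> E(biomass); EX_E
branched_model <- function(uptake = 6) {
  mets <- data.frame(id = paste0(c("A", "B", "C", "D", "E"), "[c]"),
                     compartment = "c", stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("EX_A", "AB", "AC", "BD", "CD", "DE", "EX_E"),
    lower_bound = 0,
    upper_bound = c(uptake, 1000, 1000, 1000, 1000, 1000, 1000),
    stringsAsFactors = FALSE)
  st <- list(
    EX_A = c("A[c]" = 1),
    AB = c("A[c]" = -1, "B[c]" = 1),
    AC = c("A[c]" = -1, "C[c]" = 1),
    BD = c("B[c]" = -1, "D[c]" = 1),
    CD = c("C[c]" = -1, "D[c]" = 1),
    DE = c("D[c]" = -1, "E[c]" = 1),
    EX_E = c("E[c]" = -1))
  new_gem("branched", mets, rx, st, objective = c(DE = 1))
}

mk_sample_set <- function(stats_df, n) {
  structure(list(stats = stats_df, n = n, samples = NULL, seed = NA),
            class = "flux_sample_set")
}
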