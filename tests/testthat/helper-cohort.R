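# Shared builders for small simulated cohorts used across test files.

# Long-format rho table for one category with per-tissue high/low values.
make_rho <- function(high, low, category = "secreted") {
  tissues <- names(high)
  rbind(
    data.frame(tissue = tissues, stratum = "high", category = category,
               rho = unname(high), stringsAsFactors = FALSE),
    data.frame(tissue = tissues, stratum = "low", category = category,
               rho = unname(low[tissues]), stringsAsFactors = FALSE))
}

# Compact cohort configuration: one category, uniform availability.
quick_config <- function(n = 100, seed = 1,
                         peripheral = c("adipose_subcutaneous",
                                        "skeletal_muscle"),
                         availability = 1,
                         rho_high = NULL, rho_low = NULL,
                         n_category = 12, n_target = 12,
                         n_signature = 6, n_background = 5,
                         estrogen_effect = 1, high_fraction = 0.5) {
  tissues <- c("hypothalamus", peripheral)
  if (is.null(rho_high)) {
    rho_high <- setNames(rep(0, length(peripheral)), peripheral)
  }
  if (is.null(rho_low)) {
    rho_low <- setNames(rep(0, length(peripheral)), peripheral)
  }
  avail <- setNames(rep(availability, length(tissues)), tissues)
  avail["hypothalamus"] <- 1
  simulation_config(
    n_individuals = n, tissues = tissues, availability = avail,
    estrogen_effect = estrogen_effect, high_fraction = high_fraction,
    rho = make_rho(rho_high, rho_low),
    n_genes = c(signature = n_signature, category = n_category,
                target = n_target, background = n_background),
    seed = seed)
}

# Fraction of individuals whose inferred median-split bin matches the
# latent state, running the full signature-scoring path.
bin_recovery_accuracy <- function(config) {
  sim <- simulate_cohort(config)
  signature <- make_annotations(config)$gene_sets[[1]]
  z <- suppressMessages(lapply(sim$tissues, zscore_gene_set,
                               signature = signature))
  states <- suppressMessages(bin_individuals(score_individuals(z)))
  truth <- sim$truth$estrogen_state[states$individual]
  mean(states$bin == unname(truth))
}

# Records for the generating pairs of one tissue, using the latent truth
# strata (isolates the correlation stage from state inference).
truth_pair_records <- function(sim, tissue, category = "secreted") {
  pairs <- unique(sim$truth$pairing[
    sim$truth$pairing$tissue == tissue &
      sim$truth$pairing$category == category,
    c("peripheral_gene", "target_gene")])
  set <- gene_set(toupper(category),
                  unique(pairs$peripheral_gene), category)
  suppressMessages(cross_tissue_correlations(
    sim$tissues[[tissue]], sim$tissues$hypothalamus, set,
    targets = unique(pairs$target_gene),
    states = states_from_truth(sim$truth),
    pairing = "matched", pairs = pairs))
}
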