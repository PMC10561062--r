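test_that("invalid configurations are rejected naming the field", {
  expect_error(simulation_config(n_individuals = 1), "n_individuals")
  expect_error(simulation_config(tissues = c("adipose_subcutaneous")),
               "hypothalamus")
  expect_error(simulation_config(
    availability = c(hypothalamus = 1, adipose_subcutaneous = 1.2,
                     adipose_visceral = 0.5, skeletal_muscle = 0.5,
                     stomach = 0.5, small_intestine = 0.5)),
    "availability")
  expect_error(simulation_config(high_fraction = 0), "high_fraction")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  bad_rho <- default_rho_table()
  bad_rho$rho[1] <- 1
  expect_error(simulation_config(rho = bad_rho), "rho")
  expect_error(simulation_config(
    n_genes = c(signature = 0, category = 5, target = 5, background = 5)),
    "n_genes")
})

test_that("identical configs give identical cohorts, truth and annotations", {
  cfg <- quick_config(n = 40, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$tissues$hypothalamus$values,
                   b$tissues$hypothalamus$values)
  expect_identical(a$truth, b$truth)
  expect_identical(make_annotations(cfg), make_annotations(cfg))
  # a different seed changes the draw
  c2 <- simulate_cohort(quick_config(n = 40, seed = 6))
  expect_false(identical(a$tissues$hypothalamus$values,
                         c2$tissues$hypothalamus$values))
})

test_that("generated pair correlations recover the configured rho", {
  # one strong/null contrast, checked stratum by stratum over 20 seeds
  per_seed <- sapply(1:20, function(s) {
    cfg <- quick_config(n = 500, seed = s,
                        peripheral = "adipose_subcutaneous",
                        rho_high = c(adipose_subcutaneous = 0.5),
                        rho_low = c(adipose_subcutaneous = 0),
                        n_category = 4, n_target = 4)
    sim <- simulate_cohort(cfg)
    state <- sim$truth$estrogen_state
    pair <- sim$truth$pairing[1, ]
    x <- sim$tissues$adipose_subcutaneous$values[pair$peripheral_gene, ]
    y <- sim$tissues$hypothalamus$values[pair$target_gene, ]
    c(high = cor(x[state == "high"], y[state == "high"]),
      low = cor(x[state == "low"], y[state == "low"]))
  })
  # single-seed spread and cross-seed mean fidelity
  expect_true(all(abs(per_seed["high", ] - 0.5) < 0.12))
  expect_true(all(abs(per_seed["low", ] - 0.0) < 0.12))
  expect_lt(abs(mean(per_seed["high", ]) - 0.5), 0.05)
  expect_lt(abs(mean(per_seed["low", ])), 0.05)
})

test_that("signature shift and availability match their configuration", {
  gaps <- sapply(1:3, function(s) {
    cfg <- quick_config(n = 500, seed = s, availability = 0.6,
                        estrogen_effect = 1)
    sim_s <- simulate_cohort(cfg)
    state_s <- sim_s$truth$estrogen_state
    sig <- grep("^SIG", sim_s$tissues$hypothalamus$genes, value = TRUE)
    vals <- sim_s$tissues$hypothalamus$values[sig, ]
    mean(vals[, state_s == "high"]) - mean(vals[, state_s == "low"])
  })
  expect_lt(abs(mean(gaps) - 1), 0.1)
  cfg <- quick_config(n = 500, seed = 3, availability = 0.6)
  sim <- simulate_cohort(cfg)

  # availability: binomial 99% bounds around 0.6
  mask <- sim$truth$availability
  expect_true(all(mask[, "hypothalamus"]))
  for (t in c("adipose_subcutaneous", "skeletal_muscle")) {
    obs <- mean(mask[, t])
    half <- qnorm(0.995) * sqrt(0.6 * 0.4 / nrow(mask))
    expect_gt(obs, 0.6 - half)
    expect_lt(obs, 0.6 + half)
  }
  # full availability => all-true mask
  sim_full <- simulate_cohort(quick_config(n = 30, seed = 1,
                                           availability = 1))
  expect_true(all(sim_full$truth$availability))
})

test_that("expression matrices omit unavailable individuals", {
  cfg <- quick_config(n = 80, seed = 9, availability = 0.5)
  sim <- simulate_cohort(cfg)
  mask <- sim$truth$availability
  for (t in names(sim$tissues)) {
    expect_identical(sim$tissues[[t]]$individuals,
                     rownames(mask)[mask[, t]])
  }
  # pairing genes exist in the emitted matrices
  p <- sim$truth$pairing
  expect_true(all(p$peripheral_gene %in%
                    unlist(lapply(sim$tissues[unique(p$tissue)],
                                  `[[`, "genes"))))
  expect_true(all(p$target_gene %in% sim$tissues$hypothalamus$genes))
})

test_that("neuron count simulation places the reference at its quantile", {
  nc <- simulate_neuron_counts(1000, n_samples = 6,
                               reference_quantile = 0.5, seed = 2)
  kept <- filter_high_expressed(nc)
  expect_gt(length(kept), 450)
  expect_lt(length(kept), 550)
  expect_false("Gfap" %in% kept)

  # reproducibility and single-sample degenerate case
  nc2 <- simulate_neuron_counts(1000, n_samples = 6,
                                reference_quantile = 0.5, seed = 2)
  expect_identical(nc$counts, nc2$counts)
  nc1 <- simulate_neuron_counts(50, n_samples = 1,
                                reference_quantile = 0.5, seed = 4)
  expect_identical(ncol(nc1$counts), 1L)
  expect_type(filter_high_expressed(nc1), "character")

  # forced-high genes end up above the reference nearly always
  nch <- simulate_neuron_counts(200, seed = 5,
                                gene_names = sprintf("G%03d", 1:200),
                                high_genes = sprintf("G%03d", 1:20))
  expect_gt(mean(sprintf("G%03d", 1:20) %in% filter_high_expressed(nch)),
            0.9)
  expect_error(simulate_neuron_counts(1), "n_genes")
  expect_error(simulate_neuron_counts(10, reference_quantile = 1),
               "reference_quantile")
})

test_that("annotations are disjoint, cover the pairing and map orthologs", {
  cfg <- simulation_config(n_individuals = 50, seed = 8,
                           unmapped_fraction = 0.25)
  ann <- make_annotations(cfg)
  expect_length(ann$gene_sets, 5)
  kinds <- vapply(ann$gene_sets, `[[`, character(1), "category_kind")
  expect_setequal(kinds, c("signature", "secreted", "ligand",
                           "peptide_hormone", "feeding"))
  members <- lapply(ann$gene_sets[kinds != "signature"], `[[`, "genes")
  expect_identical(anyDuplicated(unlist(members)), 0L)

  # every pairing gene sits in exactly one category set
  sim <- simulate_cohort(cfg)
  counts <- sapply(unique(sim$truth$pairing$peripheral_gene), function(g) {
    sum(vapply(members, function(m) g %in% m, logical(1)))
  })
  expect_true(all(counts == 1))

  # unmapped fraction: 8 targets, 25% unmapped -> 6 mapped
  expect_length(ann$orthologs$entries, 6)
  # mouse-style casing maps back to the human namespace
  expect_true(all(unlist(ann$orthologs$entries) %in%
                    sprintf("TGT%03d", 1:8)))
})
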