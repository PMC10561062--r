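test_that("stratified records recover the generating correlations", {
  med <- sapply(1:10, function(s) {
    cfg <- quick_config(n = 300, seed = s,
                        peripheral = "adipose_subcutaneous",
                        availability = 0.8,
                        rho_high = c(adipose_subcutaneous = 0.5),
                        rho_low = c(adipose_subcutaneous = 0),
                        n_category = 10, n_target = 10)
    sim <- simulate_cohort(cfg)
    recs <- truth_pair_records(sim, "adipose_subcutaneous")
    c(high = median(recs$r[recs$stratum == "high"]),
      low = median(recs$r[recs$stratum == "low"]))
  })
  expect_lt(abs(median(med["high", ]) - 0.5), 0.08)
  expect_lt(abs(median(med["low", ])), 0.08)
})

test_that("record tables satisfy the type invariants and are deterministic", {
  cfg <- quick_config(n = 80, seed = 12,
                      rho_high = c(adipose_subcutaneous = 0.4,
                                   skeletal_muscle = 0),
                      rho_low = c(adipose_subcutaneous = 0,
                                  skeletal_muscle = 0.4))
  sim <- simulate_cohort(cfg)
  set <- gene_set("SECRETED_PROTEINS",
                  grep("^SECR", sim$tissues$adipose_subcutaneous$genes,
                       value = TRUE), "secreted")
  targets <- grep("^TGT", sim$tissues$hypothalamus$genes, value = TRUE)
  states <- states_from_truth(sim$truth)
  recs <- cross_tissue_correlations(sim$tissues$adipose_subcutaneous,
                                    sim$tissues$hypothalamus, set,
                                    targets, states)
  expect_true(all(abs(recs$r) <= 1))
  expect_true(all(recs$n >= 3))
  expect_true(all(recs$p >= 0 & recs$p <= 1))
  expect_setequal(unique(recs$stratum), c("high", "low"))
  expect_identical(nrow(recs), 2L * 12L * 12L)
  # no randomness in this module
  recs2 <- cross_tissue_correlations(sim$tissues$adipose_subcutaneous,
                                     sim$tissues$hypothalamus, set,
                                     targets, states)
  expect_identical(recs, recs2)
  # TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_records(recs, path)
  expect_equal(read_records(path), recs, tolerance = 1e-12)
})

test_that("pair universe policies behave as documented", {
  cfg <- quick_config(n = 60, seed = 3, n_category = 6, n_target = 6)
  sim <- simulate_cohort(cfg)
  set <- gene_set("S", grep("^SECR", sim$tissues$skeletal_muscle$genes,
                            value = TRUE), "secreted")
  targets <- grep("^TGT", sim$tissues$hypothalamus$genes, value = TRUE)
  states <- states_from_truth(sim$truth)
  # cap truncates deterministically in sorted order
  capped <- suppressMessages(cross_tissue_correlations(
    sim$tissues$skeletal_muscle, sim$tissues$hypothalamus, set, targets,
    states, max_pairs = 10))
  expect_identical(nrow(capped), 20L)  # 10 pairs x 2 strata
  full <- cross_tissue_correlations(
    sim$tissues$skeletal_muscle, sim$tissues$hypothalamus, set, targets,
    states)
  key <- function(d) paste(d$peripheral_gene, d$target_gene, d$stratum)
  expect_true(all(key(capped) %in% key(full)))
  # matched policy restricts to the supplied pairs
  pairs <- unique(sim$truth$pairing[
    sim$truth$pairing$tissue == "skeletal_muscle" &
      sim$truth$pairing$category == "secreted",
    c("peripheral_gene", "target_gene")])
  matched <- cross_tissue_correlations(
    sim$tissues$skeletal_muscle, sim$tissues$hypothalamus, set, targets,
    states, pairing = "matched", pairs = pairs)
  expect_identical(nrow(matched), 2L * nrow(pairs))
})

test_that("empty overlaps and degenerate strata are handled explicitly", {
  cfg <- quick_config(n = 40, seed = 2)
  sim <- simulate_cohort(cfg)
  targets <- grep("^TGT", sim$tissues$hypothalamus$genes, value = TRUE)
  states <- states_from_truth(sim$truth)
  # category set disjoint from peripheral genes -> empty, logged
  expect_message(
    empty <- cross_tissue_correlations(
      sim$tissues$skeletal_muscle, sim$tissues$hypothalamus,
      gene_set("X", c("NOT_A_GENE")), targets, states),
    "no overlapping")
  expect_identical(nrow(empty), 0L)
  # all-high states: the low stratum has zero matched individuals
  all_high <- states
  all_high$bin <- "high"
  set <- gene_set("S", grep("^SECR", sim$tissues$skeletal_muscle$genes,
                            value = TRUE), "secreted")
  expect_error(
    cross_tissue_correlations(sim$tissues$skeletal_muscle,
                              sim$tissues$hypothalamus, set, targets,
                              all_high),
    "stratum 'low'")
})

test_that("the tissue screen drops sparse and null tissues with reasons", {
  # deterministic insufficient-matching drop
  recs <- data.frame(tissue = "small_intestine", category = "secreted",
                     peripheral_gene = "A", target_gene = "B",
                     stratum = c("high", "low"), r = c(0.1, 0.2),
                     n = c(12L, 40L), p = c(0.5, 0.1),
                     method = "bicor", stringsAsFactors = FALSE)
  screen <- screen_tissues(list(small_intestine = recs), min_n = 30)
  expect_identical(screen$kept, character(0))
  expect_identical(screen$dropped$reason, "insufficient matching")
  # empty record set is an insufficient-matching drop too
  screen0 <- screen_tissues(list(gone = recs[0, ]))
  expect_identical(screen0$dropped$reason, "insufficient matching")

  # null-generated tissue dropped, signal tissue kept, across seeds
  outcomes <- sapply(1:10, function(s) {
    cfg <- quick_config(n = 160, seed = 40 + s, availability = 1,
                        peripheral = c("adipose_subcutaneous",
                                       "skeletal_muscle"),
                        rho_high = c(adipose_subcutaneous = 0.5,
                                     skeletal_muscle = 0),
                        rho_low = c(adipose_subcutaneous = 0.5,
                                    skeletal_muscle = 0),
                        n_category = 10, n_target = 10)
    sim <- simulate_cohort(cfg)
    by_tissue <- list(
      adipose_subcutaneous = truth_pair_records(sim,
                                                "adipose_subcutaneous"),
      skeletal_muscle = truth_pair_records(sim, "skeletal_muscle"))
    screen <- screen_tissues(by_tissue, min_n = 30,
                             min_sig_fraction = 0.05, alpha = 0.05)
    c(signal_kept = "adipose_subcutaneous" %in% screen$kept,
      null_dropped = "skeletal_muscle" %in% screen$dropped$tissue)
  })
  expect_gte(mean(outcomes["signal_kept", ]), 0.95)
  expect_gte(mean(outcomes["null_dropped", ]), 0.8)
})
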