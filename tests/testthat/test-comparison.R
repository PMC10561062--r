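fake_records <- function(tissue, stratum, r,
                         category = "secreted") {
  data.frame(tissue = tissue, category = category,
             peripheral_gene = sprintf("P%03d", seq_along(r)),
             target_gene = sprintf("T%03d", seq_along(r)),
             stratum = stratum, r = r, n = 50L,
             p = correlation_pvalue(pmax(-0.999, pmin(0.999, r)), 50),
             method = "bicor", stringsAsFactors = FALSE)
}

test_that("the omnibus rank test matches a hand-ranked oracle", {
  # identical value multisets in two groups: H = 0, p = 1
  recs <- rbind(fake_records("adipose", "high", c(0.1, 0.2, 0.3)),
                fake_records("adipose", "low", c(0.3, 0.1, 0.2)))
  kw <- kw_across_groups(recs)
  expect_equal(kw$H, 0, tolerance = 1e-12)
  expect_equal(kw$p, 1)
  expect_identical(kw$df, 1L)

  # three small groups with ties against the oracle
  vals <- list(c(0.12, -0.31, 0.12, 0.55, 0.02),
               c(-0.02, 0.40, 0.21, 0.21, -0.15),
               c(0.60, 0.31, 0.44, 0.02, 0.70))
  recs3 <- rbind(fake_records("t1", "high", vals[[1]]),
                 fake_records("t2", "high", vals[[2]]),
                 fake_records("t3", "high", vals[[3]]))
  kw3 <- kw_across_groups(recs3)
  expect_equal(kw3$H,
               kw_oracle(unlist(vals), rep(1:3, each = 5)),
               tolerance = 1e-10)
  expect_identical(kw3$df, 2L)
  # group table bookkeeping: df = non-empty groups - 1
  expect_identical(nrow(kw3$groups), 3L)
  expect_error(kw_across_groups(fake_records("t1", "high", c(0.1, 0.2))),
               "2 non-empty")
})

test_that("the omnibus test is invariant under monotone transforms", {
  set.seed(31)
  recs <- rbind(fake_records("a", "high", rnorm(15)),
                fake_records("a", "low", rnorm(15) + 0.3),
                fake_records("b", "high", rnorm(15)),
                fake_records("b", "low", rnorm(15)))
  h1 <- kw_across_groups(recs)$H
  recs$r <- tanh(3 * recs$r) # strictly monotone
  expect_equal(kw_across_groups(recs)$H, h1, tolerance = 1e-10)
})

test_that("welch contrast matches its closed form and flags direction", {
  a <- c(0.42, 0.11, 0.35, 0.28)
  b <- c(0.05, -0.12, 0.19, 0.02)
  recs <- rbind(fake_records("adipose", "high", a),
                fake_records("adipose", "low", b))
  ct <- contrast_high_vs_low(recs, "adipose")
  oracle <- welch_oracle(a, b)
  expect_equal(ct$statistic, oracle$t, tolerance = 1e-10)
  expect_equal(ct$p, oracle$p, tolerance = 1e-10)
  expect_identical(ct$direction, "high>low")

  # identical strata: p = 1, direction none (both methods)
  same <- rbind(fake_records("adipose", "high", a),
                fake_records("adipose", "low", a))
  for (m in c("welch_t", "rank_sum")) {
    ct0 <- contrast_high_vs_low(same, "adipose", m)
    expect_equal(ct0$p, 1)
    expect_identical(ct0$direction, "none")
  }
  expect_error(contrast_high_vs_low(recs[recs$stratum == "high", ],
                                    "adipose"), "'low'")
})

test_that("a shifted stratum is detected with adjusted significance", {
  hits <- sapply(1:100, function(s) {
    set.seed(600 + s)
    recs <- rbind(fake_records("adipose", "high", rnorm(100, 0.3, 0.2)),
                  fake_records("adipose", "low", rnorm(100, 0.0, 0.2)),
                  fake_records("muscle", "high", rnorm(100, 0, 0.2)),
                  fake_records("muscle", "low", rnorm(100, 0, 0.2)))
    res <- compare_category(recs)
    row <- res$contrasts[res$contrasts$tissue == "adipose", ]
    row$direction == "high>low" && row$adjusted_p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("profile similarity aligns strata by record key", {
  set.seed(9)
  high <- fake_records("adipose", "high", rnorm(20))
  low <- high
  low$stratum <- "low"
  expect_equal(profile_similarity(high, low)$r, 1.0)
  neg <- low
  neg$r <- -neg$r
  expect_equal(profile_similarity(high, neg)$r, -1.0)
  # unmatched keys dropped and counted
  extra <- fake_records("muscle", "low", rnorm(5))
  expect_message(ps <- profile_similarity(high, rbind(low, extra)),
                 "dropped 5")
  expect_identical(ps$n_pairs, 20L)
  expect_error(profile_similarity(high[1:2, ], low[1:2, ]),
               "fewer than 3")
})

test_that("comparison results keep their bookkeeping invariants", {
  set.seed(13)
  recs <- rbind(fake_records("adipose", "high", rnorm(30, 0.3, 0.15)),
                fake_records("adipose", "low", rnorm(30, 0, 0.15)),
                fake_records("stomach", "high", rnorm(30, 0, 0.15)),
                fake_records("stomach", "low", rnorm(30, 0.2, 0.15)))
  res <- compare_category(recs)
  expect_identical(res$df, nrow(res$groups) - 1L)
  expect_true(all(res$contrasts$adjusted_p >= res$contrasts$raw_p))
  expect_error(compare_category(rbind(
    recs, fake_records("adipose", "high", 0.1, category = "ligand"))),
    "several categories")
})

test_that("run summaries round-trip through JSON", {
  set.seed(21)
  recs <- rbind(fake_records("adipose", "high", rnorm(25, 0.2, 0.1)),
                fake_records("adipose", "low", rnorm(25, 0, 0.1)))
  res <- compare_category(recs)
  screen <- screen_tissues(list(adipose = recs), min_n = 10)
  summary <- summarize_run(list(res), screen = screen,
                           config = list(seed = 5), all_records = recs)
  path <- withr::local_tempfile(fileext = ".json")
  write_summary(summary, path)
  back <- read_summary(path)
  expect_equal(back$n_categories, 1L)
  expect_equal(back$categories$secreted$omnibus_H, res$omnibus_H,
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$categories$secreted$contrasts),
               res$contrasts, tolerance = 1e-12)
  expect_equal(back$categories$secreted$profile_similarity$r,
               res$profile_similarity$r, tolerance = 1e-12)
  expect_equal(back$config_echo$seed, 5L)
  # text rendering mentions every contrast exactly once
  txt <- render_summary_text(summary)
  expect_identical(sum(grepl("adipose:", txt)), 1L)
  # empty summary is still valid
  empty <- summarize_run(list())
  expect_identical(empty$n_categories, 0L)
  write_summary(empty, path)
  expect_equal(read_summary(path)$n_categories, 0L)
})
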