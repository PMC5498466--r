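make_tab <- function(values, conds, reps = 2L, genes = NULL) {
  # values: named list gene -> vector over samples (length conds*reps)
  samples <- expand.grid(replicate = seq_len(reps), condition = conds,
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_r%d", samples$condition, samples$replicate)
  m <- do.call(rbind, values)
  rownames(m) <- names(values)
  colnames(m) <- samples$sample
  expression_table(m, samples[, c("sample", "condition", "replicate")],
                   control = conds[1])
}

test_that("growth rate follows the logarithmic-change formula", {
  expect_equal(growth_rate(1e6, 1e6, 0, 24), 0)
  expect_equal(growth_rate(5e5, 1e6, 0, 24), log(2) / 24)
  # frozen calculator oracle: (ln 3.5e6 - ln 1e6)/72 = ln(3.5)/72
  expect_equal(growth_rate(1e6, 3.5e6, 0, 72), 0.0173994857,
               tolerance = 1e-7)
  expect_error(growth_rate(0, 1e6, 0, 24), "positive")
  expect_error(growth_rate(1e6, 2e6, 24, 24), "exceed")

  d <- data.frame(time_h = c(0, 24, 48), cells_per_ml = c(1e6, 2e6, 8e6))
  gr <- growth_rate_series(d)
  expect_equal(gr$mu_per_h, c(log(2) / 24, log(4) / 24))
})

test_that("log2 fold change is pseudocount-stabilized", {
  vals <- c(list(flat = c(100, 100, 100, 100),
                 up4 = c(1000, 1000, 4000, 4000),
                 zero = c(0, 0, 0, 0)),
            stats::setNames(replicate(6, c(100, 100, 100, 100),
                                      simplify = FALSE),
                            sprintf("bg%d", 1:6)))
  tab <- make_tab(vals, conds = c("control", "stress"))
  expect_equal(log2_fold_change(tab, "flat", "stress"), 0)
  expect_equal(log2_fold_change(tab, "up4", "stress", normalize = FALSE),
               2, tolerance = 0.001)
  expect_equal(log2_fold_change(tab, "zero", "stress"), 0)
  expect_error(log2_fold_change(tab, "nope", "stress"), "absent")
  expect_error(log2_fold_change(tab, "flat", "nope"), "absent")
})

test_that("median-ratio normalization is robust to a strongly shifted minority", {
  # 20 flat genes + 1 gene up 16x: total-count scaling drags flat genes
  # down; median-ratio must keep them flat.
  vals <- c(list(big = c(500, 500, 8000, 8000)),
            stats::setNames(replicate(20, c(100, 100, 100, 100),
                                      simplify = FALSE),
                            sprintf("f%02d", 1:20)))
  tab <- make_tab(vals, conds = c("control", "stress"))
  expect_equal(log2_fold_change(tab, "f01", "stress", normalize = TRUE), 0,
               tolerance = 0.02)
  lfc_total <- log2((mean(normalize_counts(tab, "total")["f01", 3:4]) + 0.5) /
                    (mean(normalize_counts(tab, "total")["f01", 1:2]) + 0.5))
  expect_lt(lfc_total, -0.5)
})

test_that("permutation test: exhaustive enumeration cases", {
  # identical groups -> every arrangement ties -> p = 1
  tab <- make_tab(list(g = rep(50, 6)), conds = c("control", "s"),
                  reps = 3L)
  r <- permutation_significance(tab, "g", "s")
  expect_true(r$exhaustive)
  expect_equal(r$n_arrangements, 20)
  expect_equal(r$p_value, 1.0)

  # 3v3 with no overlap: only the observed labeling and its mirror are as
  # extreme -> p = 2/20 (hand-enumerated oracle)
  tab2 <- make_tab(list(g = c(10, 11, 12, 100, 110, 120)),
                   conds = c("control", "s"), reps = 3L)
  r2 <- permutation_significance(tab2, "g", "s", normalize = FALSE)
  expect_equal(r2$p_value, 2 / 20)

  # invariance to replicate ordering
  tab3 <- make_tab(list(g = c(12, 11, 10, 120, 100, 110)),
                   conds = c("control", "s"), reps = 3L)
  expect_equal(permutation_significance(tab3, "g", "s",
                                        normalize = FALSE)$p_value,
               r2$p_value)

  # too few replicates -> explicit refusal
  tab4 <- make_tab(list(g = c(10, 100)), conds = c("control", "s"),
                   reps = 1L)
  expect_error(permutation_significance(tab4, "g", "s"),
               "insufficient replication")
})

test_that("sampled permutations are seeded and reproducible", {
  set.seed(99)
  vals <- list(g = c(rnorm(8, 100, 5), rnorm(8, 160, 5)))
  tab <- make_tab(vals, conds = c("control", "s"), reps = 8L)
  r1 <- permutation_significance(tab, "g", "s", n_perm = 500, seed = 42,
                                 normalize = FALSE)
  r2 <- permutation_significance(tab, "g", "s", n_perm = 500, seed = 42,
                                 normalize = FALSE)
  expect_false(r1$exhaustive)
  expect_identical(r1$p_value, r2$p_value)
  expect_lte(r1$p_value, 0.05)
})

test_that("classification thresholds and statuses behave as specified", {
  mk <- function(t_stress, a_stress) {
    make_tab(list(T1 = c(1000, 1000, t_stress, t_stress),
                  A1 = c(1000, 1000, a_stress, a_stress),
                  f1 = c(500, 500, 500, 500),
                  f2 = c(200, 200, 200, 200),
                  f3 = c(800, 800, 800, 800)),
             conds = c("control", "Zn"))
  }
  pairs <- data.frame(pair_rank = 1L, toxin = "T1", antitoxin = "A1",
                      stringsAsFactors = FALSE)
  # 10.6-fold up toxin, flat antitoxin -> toxin-up
  calls <- classify_pairs(mk(10600, 1000), pairs)
  expect_equal(calls$status, "toxin-up")
  expect_true(is.na(calls$significant))  # 2v2: permutation floor > alpha
  expect_gt(calls$ta_ratio, 5)
  # all flat -> none
  expect_equal(classify_pairs(mk(1000, 1000), pairs)$status, "none")
  # 1.9-fold -> below threshold -> none
  expect_equal(classify_pairs(mk(1900, 1000), pairs)$status, "none")
  # toxin up + antitoxin down -> both
  expect_equal(classify_pairs(mk(4000, 250), pairs)$status, "both")
  # antitoxin down only
  expect_equal(classify_pairs(mk(1000, 250), pairs)$status,
               "antitoxin-down")
})

test_that("ta_ratio increases with toxin expression at fixed antitoxin", {
  pairs <- data.frame(pair_rank = 1L, toxin = "T1", antitoxin = "A1",
                      stringsAsFactors = FALSE)
  ratios <- vapply(c(500, 1000, 4000, 12000), function(tx) {
    tab <- make_tab(list(T1 = c(500, 500, tx, tx),
                         A1 = c(400, 400, 400, 400)),
                    conds = c("control", "Zn"))
    classify_pairs(tab, pairs, normalize = FALSE)$ta_ratio
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("expression tables round-trip through TSV", {
  refs <- demo_refs()
  sim <- generate_genome(refs, n_pairs = 2, n_decoys = 5, divergence = 0,
                         seed = 3)
  tab <- generate_expression(sim, seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_expression_files(tab, dir)
  back <- read_expression(paths["counts"], paths["samples"])
  expect_equal(back$counts, tab$counts)
  expect_equal(back$samples$condition, tab$samples$condition)
})
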