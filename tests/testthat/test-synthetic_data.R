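test_that("mutate_protein hits the exact divergence and is seeded", {
  s <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  expect_identical(mutate_protein(s, 0, seed = 1), s)
  m1 <- mutate_protein(s, 0.2, seed = 1)
  m2 <- mutate_protein(s, 0.2, seed = 1)
  m3 <- mutate_protein(s, 0.2, seed = 2)
  hamming <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_identical(m1, m2)
  expect_false(m1 == m3)
  expect_equal(hamming(s, m1), 20L)
  expect_equal(hamming(s, m3), 20L)
  expect_error(mutate_protein(s, 1, seed = 1), "divergence")
})

test_that("generated genomes are deterministic and coordinate-consistent", {
  refs <- demo_refs()
  s1 <- generate_genome(refs, n_pairs = 4, n_decoys = 20,
                        divergence = 0.1, seed = 5)
  s2 <- generate_genome(refs, n_pairs = 4, n_decoys = 20,
                        divergence = 0.1, seed = 5)
  expect_identical(s1$features, s2$features)
  expect_identical(s1$truth, s2$truth)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genome_files(s1, d1); write_genome_files(s2, d2)
  for (f in c("proteins.faa", "genes.gff3", "truth_pairs.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  # truth ids all exist in the annotation; coordinates valid
  expect_true(all(c(s1$truth$pairs$toxin, s1$truth$pairs$antitoxin,
                    s1$truth$decoys$gene_id) %in% s1$features$gene_id))
  expect_equal(nrow(s1$features), 4 * 2 + 20)
  validate_features <- tascreen:::validate_features
  expect_silent(validate_features(s1$features))

  # planted intergenic distances are realized on the chromosome
  fx <- s1$features
  for (k in seq_len(nrow(s1$truth$pairs))) {
    tr <- s1$truth$pairs[k, ]
    g1 <- fx[fx$gene_id %in% c(tr$toxin, tr$antitoxin), ]
    g1 <- g1[order(g1$start), ]
    expect_equal(g1$start[2] - g1$end[1] - 1L, tr$intergenic_nt)
  }
})

test_that("overlap_choices of -3 makes every planted pair coupled", {
  refs <- demo_refs()
  sim <- generate_genome(refs, n_pairs = 5, n_decoys = 0, divergence = 0,
                         overlap_choices = -3L, seed = 6)
  m <- screen_metrics(sim, demo_clusters())
  expect_equal(m$recall, 1.0)
  expect_true(all(m$pairs$coupled))
  expect_true(all(m$pairs$intergenic_nt == -3L))
})

test_that("zero-divergence screens close the loop: full recall, no false pairs", {
  refs <- demo_refs()
  sim <- generate_genome(refs, n_pairs = 3, n_decoys = 40, divergence = 0,
                         seed = 8)
  m <- screen_metrics(sim, demo_clusters())
  expect_equal(m$recall, 1.0)
  expect_equal(m$precision, 1.0)
  expect_equal(m$n_called, 3L)
  # adversarial decoys present and none of them paired
  expect_gte(nrow(sim$truth$decoys), 40L)
  expect_true(any(grepl("wrong_strand", sim$truth$decoys$decoy_type)))
  paired <- c(m$pairs$toxin, m$pairs$antitoxin)
  expect_length(intersect(paired, sim$truth$decoys$gene_id), 0L)
})

test_that("recall degrades monotonically with divergence", {
  refs <- demo_refs()
  cl <- demo_clusters()
  rec <- vapply(c(0, 0.3, 0.6), function(dv) {
    mean(vapply(1:8, function(s) {
      sim <- generate_genome(refs, n_pairs = 10, n_decoys = 10,
                             divergence = dv, seed = 100 + s)
      screen_metrics(sim, cl)$recall
    }, 0))
  }, 0)
  expect_equal(rec[1], 1.0)
  expect_true(all(diff(rec) <= 1e-9))
})

test_that("expression generator recovers scenario fold changes at low dispersion", {
  refs <- demo_refs()
  sim <- generate_genome(refs, n_pairs = 2, n_decoys = 10, divergence = 0,
                         seed = 9)
  tab <- generate_expression(sim, dispersion = 0.0001, n_reps = 50,
                             baseline_mean = 5000, seed = 10)
  sc <- default_stress_scenario()
  for (k in seq_len(nrow(sim$truth$pairs))) {
    tox <- sim$truth$pairs$toxin[k]
    for (i in seq_len(nrow(sc))) {
      fc <- 2^log2_fold_change(tab, tox, sc$condition[i],
                               normalize = FALSE)
      expect_equal(fc, sc$toxin_mult[i], tolerance = 0.05)
    }
  }

  # all-1 scenario -> classify reports none
  flat <- default_stress_scenario()
  flat$toxin_mult <- flat$antitoxin_mult <- 1
  tab2 <- generate_expression(sim, scenario = flat, seed = 11)
  pairs <- data.frame(pair_rank = seq_len(nrow(sim$truth$pairs)),
                      toxin = sim$truth$pairs$toxin,
                      antitoxin = sim$truth$pairs$antitoxin,
                      stringsAsFactors = FALSE)
  expect_true(all(classify_pairs(tab2, pairs)$status == "none"))

  # determinism
  expect_identical(generate_expression(sim, seed = 12)$counts,
                   generate_expression(sim, seed = 12)$counts)
  expect_error(generate_expression(sim, dispersion = -1), "dispersion")
})
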