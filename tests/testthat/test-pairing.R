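test_that("intergenic distance follows 1-based inclusive arithmetic", {
  a <- list(contig = "c", start = 1, end = 300)
  expect_identical(intergenic_distance(a, list(contig = "c", start = 304,
                                               end = 600)), 3L)
  expect_identical(intergenic_distance(a, list(contig = "c", start = 298,
                                               end = 600)), -3L)
  expect_identical(intergenic_distance(a, list(contig = "c", start = 301,
                                               end = 600)), 0L)
  expect_error(intergenic_distance(a, list(contig = "d", start = 304,
                                           end = 600)), "contigs")
  expect_error(intergenic_distance(list(contig = "c", start = 500,
                                        end = 600), a), "leftmost")
})

test_that("co-directed overlapping toxin/antitoxin pair is called and coupled", {
  f <- rbind(feat("tox", 100, 400, "+"), feat("ant", 398, 650, "+"))
  a <- rbind(asg("tox", "relE", "toxin"), asg("ant", "relB", "antitoxin"))
  p <- find_ta_pairs(f, a)
  expect_equal(nrow(p), 1L)
  expect_identical(p$intergenic_nt, -3L)
  expect_true(p$coupled)
  expect_false(p$antitoxin_upstream)  # toxin is leftmost on + strand
  expect_equal(p$pair_rank, 1L)
})

test_that("opposite strands, same family, and distance violations never pair", {
  a <- rbind(asg("tox", "relE", "toxin"), asg("ant", "relB", "antitoxin"))
  # opposite strands
  f <- rbind(feat("tox", 100, 400, "+"), feat("ant", 398, 650, "-"))
  expect_equal(nrow(find_ta_pairs(f, a)), 0L)
  # same family label on both genes
  f2 <- rbind(feat("tox", 100, 400, "+"), feat("ant", 398, 650, "+"))
  a2 <- rbind(asg("tox", "relE", "toxin"), asg("ant", "relE", "antitoxin"))
  expect_equal(nrow(find_ta_pairs(f2, a2)), 0L)
  # same role on both genes
  a3 <- rbind(asg("tox", "relE", "toxin"), asg("ant", "mazF", "toxin"))
  expect_equal(nrow(find_ta_pairs(f2, a3)), 0L)
  # gap beyond threshold
  f3 <- rbind(feat("tox", 100, 400, "+"), feat("ant", 700, 950, "+"))
  expect_equal(nrow(find_ta_pairs(f3, a)), 0L)
  expect_equal(nrow(find_ta_pairs(f3, a, max_intergenic_nt = 500)), 1L)
})

test_that("triplet resolves greedily to the nearest partner", {
  # antitoxin--toxin--antitoxin, gaps 5 nt and 2 nt: toxin pairs with the
  # 2-nt neighbor; the other antitoxin stays unpaired.
  f <- rbind(feat("antA", 100, 300, "+"), feat("tox", 306, 500, "+"),
             feat("antB", 503, 700, "+"))
  a <- rbind(asg("antA", "relB", "antitoxin"), asg("tox", "relE", "toxin"),
             asg("antB", "phd", "antitoxin"))
  # oracle: enumerate all legal pairings; matching maximizing greedy rule
  cands <- list(c("antA", "tox", 5L), c("tox", "antB", 2L))
  expect_equal(order(vapply(cands, function(x) as.integer(x[3]), 0L))[1],
               2L)
  p <- find_ta_pairs(f, a)
  expect_equal(nrow(p), 1L)
  expect_equal(p$toxin, "tox")
  expect_equal(p$antitoxin, "antB")
  expect_identical(p$intergenic_nt, 2L)
  expect_true(p$antitoxin_upstream == FALSE)
})

test_that("minus-strand pairs get transcription-relative upstream labels", {
  # on '-', transcription runs right to left: the rightmost gene is
  # upstream. Canonical operon: antitoxin upstream.
  f <- rbind(feat("tox", 100, 400, "-"), feat("ant", 403, 650, "-"))
  a <- rbind(asg("tox", "relE", "toxin"), asg("ant", "relB", "antitoxin"))
  p <- find_ta_pairs(f, a)
  expect_equal(nrow(p), 1L)
  expect_true(p$antitoxin_upstream)
})

test_that("pair calls are a matching and reflection-invariant", {
  refs <- demo_refs()
  sim <- generate_genome(refs, n_pairs = 6, n_decoys = 30, divergence = 0,
                         seed = 91)
  m <- screen_metrics(sim, demo_clusters())
  p <- m$pairs
  expect_equal(anyDuplicated(c(p$toxin, p$antitoxin)), 0L)

  # reflect coordinates and flip strands: same pairs, same orientation
  # labels (upstream is transcription-relative, preserved by reflection)
  L <- max(sim$features$end) + 1000L
  rf <- sim$features
  new_start <- L - rf$end + 1L
  rf$end <- L - rf$start + 1L
  rf$start <- new_start
  rf$strand <- ifelse(rf$strand == "+", "-", "+")
  a <- assign_family(rf, demo_clusters())
  p2 <- find_ta_pairs(rf, a)
  key <- function(x) paste(x$toxin, x$antitoxin, x$antitoxin_upstream)
  expect_setequal(key(p), key(p2))
  expect_identical(sort(p$intergenic_nt), sort(p2$intergenic_nt))
})

test_that("operon report merges physchem and flags pI asymmetry", {
  f <- rbind(feat("tox", 100, 400, "+", protein = strrep("KRAGLIK", 10)),
             feat("ant", 399, 650, "+", protein = strrep("DEAGLSD", 10)))
  a <- rbind(asg("tox", "relE", "toxin"), asg("ant", "relB", "antitoxin"))
  p <- find_ta_pairs(f, a)
  pc <- physchem_summary(f)
  rep <- operon_report(p, pc, f)
  expect_equal(nrow(rep), 1L)
  expect_true(rep$pi_asymmetric)     # poly-basic toxin vs poly-acidic anti
  expect_true(rep$coupled)           # -2 nt overlap
  expect_identical(rep$intergenic_nt, -2L)
  expect_error(operon_report(p, pc[pc$gene_id != "ant", ], f), "ant")

  # empty pair list -> header-only report
  expect_equal(nrow(operon_report(p[0, ], pc, f)), 0L)
})

test_that("pairs GFF3 track spans both genes", {
  f <- rbind(feat("tox", 100, 400, "+"), feat("ant", 398, 650, "+"))
  a <- rbind(asg("tox", "relE", "toxin"), asg("ant", "relB", "antitoxin"))
  p <- find_ta_pairs(f, a)
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_pairs_gff3(p, f, tmp)
  lines <- readLines(tmp)
  expect_equal(lines[1], "##gff-version 3")
  body <- strsplit(lines[length(lines)], "\t")[[1]]
  expect_equal(as.integer(body[4:5]), c(100L, 650L))
  expect_equal(body[3], "operon")
})
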