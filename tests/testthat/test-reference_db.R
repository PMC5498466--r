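test_that("reference FASTA parsing validates headers and records", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1|relE|toxin", strrep("ARNDKLMW", 10),
               ">a1|relB|antitoxin", strrep("DEGSLIVT", 9)), tmp)
  refs <- read_ta_references(tmp)
  expect_equal(refs$record_id, c("t1", "a1"))
  expect_equal(refs$role, c("toxin", "antitoxin"))
  expect_equal(nchar(refs$sequence), c(80L, 72L))

  # missing role token
  writeLines(c(">t1|relE", strrep("ARNDKLMW", 10)), tmp)
  expect_error(read_ta_references(tmp), "malformed header")

  # duplicate id
  writeLines(c(">t1|relE|toxin", strrep("ARNDKLMW", 10),
               ">t1|relE|toxin", strrep("ARNDKLMW", 10)), tmp)
  expect_error(read_ta_references(tmp), "duplicate")

  # role inconsistent within family
  writeLines(c(">t1|relE|toxin", strrep("ARNDKLMW", 10),
               ">t2|relE|antitoxin", strrep("ARNDKLMW", 10)), tmp)
  expect_error(read_ta_references(tmp), "mixes")

  # length bounds
  writeLines(c(">t1|relE|toxin", "ARNDKLMW"), tmp)
  expect_error(read_ta_references(tmp), "length")
})

test_that("CRLF and wrapped sequence lines parse identically to plain LF", {
  seqs <- c(strrep("ARNDKLMWCE", 9), strrep("DEGSLIVTQH", 8))
  lf <- withr::local_tempfile(fileext = ".fasta")
  crlf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1|relE|toxin", seqs[1], ">a1|relB|antitoxin", seqs[2]),
             lf)
  wrapped <- unlist(lapply(seqs, function(s)
    substring(s, seq(1, nchar(s), 30), pmin(seq(30, nchar(s) + 29, 30),
                                            nchar(s)))))
  con <- file(crlf, "wb")
  writeBin(charToRaw(paste0(paste(
    c(">t1|relE|toxin", wrapped[1:3], ">a1|relB|antitoxin", wrapped[4:6]),
    collapse = "\r\n"), "\r\n")), con)
  close(con)
  expect_identical(read_ta_references(lf), read_ta_references(crlf))
})

test_that("clustering links by coverage and score density, single linkage", {
  # A/B share 3 of 4 50-aa blocks, B/C share 3, A/C share only 2 (< 75%
  # coverage of the shorter), so {A,B,C} must merge via B (single linkage)
  # even though A-C alone would not link.
  set.seed(42)
  blocks <- random_aa(6, 50)
  A <- paste(blocks[1:4], collapse = "")
  B <- paste(blocks[2:5], collapse = "")
  C <- paste(blocks[3:6], collapse = "")
  rec <- data.frame(record_id = c("A", "B", "C"), family = "relE",
                    role = "toxin", sequence = c(A, B, C),
                    stringsAsFactors = FALSE)

  # oracle: brute-force pairwise linkage + transitive closure
  link <- function(x, y) {
    h <- align_local(x, y)
    h$coverage_shorter >= 0.75 && h$bit_score / h$aln_length >= 1.0
  }
  expect_true(link(A, B) && link(B, C) && !link(A, C))

  cl <- cluster_references(rec)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_setequal(cl$record_id, c("A", "B", "C"))
  # representative: longest (all equal) -> lexicographically smallest id
  expect_equal(cl$record_id[cl$is_representative], "A")
})

test_that("identical sequences cluster; unrelated roles/records do not", {
  s <- strrep("ARNDKLMWCE", 9)
  rec <- data.frame(
    record_id = c("x1", "x2", "y1"), family = c("relE", "relE", "mazE"),
    role = c("toxin", "toxin", "antitoxin"),
    sequence = c(s, s, strrep("DEGSLIVTQH", 8)), stringsAsFactors = FALSE)
  cl <- cluster_references(rec)
  expect_equal(length(unique(cl$cluster_id)), 2L)
  expect_equal(sort(table(cl$cluster_id), decreasing = TRUE)[[1]], 2L)

  # identical sequence but different role must NOT link (role authoritative)
  rec2 <- data.frame(record_id = c("x1", "y1"), family = c("relE", "relB"),
                     role = c("toxin", "antitoxin"), sequence = c(s, s),
                     stringsAsFactors = FALSE)
  cl2 <- cluster_references(rec2)
  expect_equal(length(unique(cl2$cluster_id)), 2L)
})

test_that("clustering is a partition, order-invariant, and idempotent on representatives", {
  refs <- demo_refs()
  cl <- demo_clusters()
  # partition
  expect_setequal(cl$record_id, refs$record_id)
  expect_equal(anyDuplicated(cl$record_id), 0L)
  expect_equal(sum(cl$is_representative),
               length(unique(cl$cluster_id)))

  # permutation invariance (membership and representative choice)
  set.seed(7)
  perm <- refs[sample(nrow(refs)), , drop = FALSE]
  clp <- cluster_references(perm)
  key <- function(x) {
    sp <- split(x$record_id, x$cluster_id)
    unname(sort(vapply(sp, function(v) paste(sort(v), collapse = ","), "")))
  }
  expect_identical(key(cl), key(clp))
  expect_setequal(cl$record_id[cl$is_representative],
                  clp$record_id[clp$is_representative])

  # representatives re-cluster to singletons
  reps <- cl[cl$is_representative, , drop = FALSE]
  reps <- data.frame(record_id = reps$record_id, family = reps$family,
                     role = reps$role, sequence = reps$sequence,
                     stringsAsFactors = FALSE)
  clr <- cluster_references(reps)
  expect_equal(length(unique(clr$cluster_id)), nrow(reps))
})

test_that("empty reference set is rejected and cluster TSV round-trips", {
  expect_error(cluster_references(demo_refs()[0, ]), "empty")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_clusters_tsv(demo_clusters(), tmp, header = "unit test")
  back <- read.table(tmp, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(back), nrow(demo_clusters()))
  expect_true(startsWith(readLines(tmp, n = 1), "#"))
})
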