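# Synthetic genomes, annotations and expression tables with known ground
# truth, so every pipeline stage is testable without external downloads.
# Architecture emulated: compact co-directed antitoxin-toxin operons with
# 1-3 nt ORF overlaps, buried among decoy genes that exercise the pairing
# rule's negative cases.

.cognate_families <- data.frame(
  toxin = c("relE", "mazF", "yoeB", "vapC", "doc"),
  antitoxin = c("relB", "mazE", "yefM", "vapB", "phd"),
  stringsAsFactors = FALSE)

#' Mutate a protein to a target divergence
#'
#' Substitutes exactly `round(divergence * nchar(seq))` positions, each to
#' a different residue drawn from the background frequency table
#' ([aa_background()], renormalized to exclude the incumbent residue).
#' Substitution-only (no indels), so planted identity stays interpretable.
#' Deterministic for a given seed.
#'
#' @param seq Protein sequence.
#' @param divergence Target substituted fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return Mutated protein sequence (same length).
#' @export
mutate_protein <- function(seq, divergence, seed) {
  if (divergence < 0 || divergence >= 1)
    stop("`divergence` must lie in [0, 1)")
  ch <- check_protein(seq, allow_x = FALSE)
  n_sub <- round(divergence * length(ch))
  if (n_sub == 0L) return(seq)
  bg <- aa_background()
  with_seed(seed, {
    pos <- sample(length(ch), n_sub)
    for (p in pos) {
      alt <- bg[names(bg) != ch[p]]
      ch[p] <- sample(names(alt), 1L, prob = alt / sum(alt))
    }
  })
  paste(ch, collapse = "")
}

random_protein <- function(len) {
  bg <- aa_background()
  paste(sample(names(bg), len, replace = TRUE, prob = bg), collapse = "")
}

# Pick one reference record of the given family; error if absent.
.pick_ref <- function(refs, family) {
  cand <- which(refs$family == family)
  if (!length(cand)) stop(sprintf("no reference record for family '%s'",
                                  family))
  cand[sample.int(length(cand), 1L)]
}

#' Generate a synthetic annotated genome with planted TA operons
#'
#' Plants `n_pairs` co-directed antitoxin-toxin operons (antitoxin upstream
#' in transcription direction, intergenic distances drawn from
#' `overlap_choices`) among `n_decoys` decoy genes on a single contig.
#' The decoy set deliberately includes the pairing rule's negative cases:
#' lone TA homologs (10%), divergently oriented toxin/antitoxin neighbors
#' (10% of genes), co-directed same-role neighbors (10%), co-directed
#' toxin/antitoxin pairs separated by more than the adjacency threshold
#' (10%), and random proteins (the remainder). Planted and decoy TA
#' proteins are mutated copies of reference exemplars at the requested
#' divergence. Consecutive transcription units are separated by 200-2000 nt
#' so only planted operons satisfy the adjacency rule.
#'
#' @param refs Reference records ([read_ta_references()]); must contain the
#'   canonical cognate families (relB/relE, mazE/mazF, yefM/yoeB,
#'   vapB/vapC, phd/doc).
#' @param n_pairs Number of planted operons (>= 0).
#' @param n_decoys Number of decoy genes.
#' @param divergence Fraction of substituted positions in planted/decoy TA
#'   proteins.
#' @param overlap_choices Intergenic distances (nt; negative = ORF overlap)
#'   sampled per planted operon.
#' @param seed Integer seed; the same seed reproduces the simulation
#'   byte-identically.
#' @param contig Contig name.
#' @return List of class `"ta_simulation"`: `features` (GeneFeature data
#'   frame incl. proteins), `truth` (list with `pairs` and `decoys` data
#'   frames), `seed`, `params`.
#' @export
generate_genome <- function(refs, n_pairs, n_decoys = 0L,
                            divergence = 0,
                            overlap_choices = c(-1L, -2L, -3L, 0L, 10L,
                                                50L),
                            seed = 1L, contig = "chr1") {
  if (n_pairs < 0) stop("`n_pairs` must be non-negative")
  if (n_decoys < 0) stop("`n_decoys` must be non-negative")
  validate_ta_references(refs)

  with_seed(seed, {
    units <- list()
    truth_pairs <- list()
    decoys <- list()
    mut_seed <- function() sample.int(2^31 - 1L, 1L)

    # planted operons
    for (k in seq_len(n_pairs)) {
      fam <- .cognate_families[sample.int(nrow(.cognate_families), 1L), ]
      ti <- .pick_ref(refs, fam$toxin)
      ai <- .pick_ref(refs, fam$antitoxin)
      tox_seq <- mutate_protein(refs$sequence[ti], divergence, mut_seed())
      ant_seq <- mutate_protein(refs$sequence[ai], divergence, mut_seed())
      gap <- sample(overlap_choices, 1L)
      strand <- sample(c("+", "-"), 1L)
      tox_id <- sprintf("TOX_%03d", k)
      ant_id <- sprintf("ANT_%03d", k)
      # antitoxin upstream in transcription direction
      genes <- if (strand == "+")
        list(list(id = ant_id, seq = ant_seq),
             list(id = tox_id, seq = tox_seq))
      else
        list(list(id = tox_id, seq = tox_seq),
             list(id = ant_id, seq = ant_seq))
      units[[length(units) + 1L]] <- list(genes = genes, gaps = gap,
                                          strands = c(strand, strand))
      truth_pairs[[length(truth_pairs) + 1L]] <- data.frame(
        toxin = tox_id, antitoxin = ant_id, toxin_family = fam$toxin,
        antitoxin_family = fam$antitoxin, intergenic_nt = as.integer(gap),
        strand = strand, contig = contig, stringsAsFactors = FALSE)
    }

    # decoy allocation
    n_lone <- round(0.10 * n_decoys)
    n_ws <- round(0.05 * n_decoys)    # wrong-strand pairs (2 genes each)
    n_sr <- round(0.05 * n_decoys)    # same-role pairs
    n_far <- round(0.05 * n_decoys)   # distant pairs
    n_rand <- n_decoys - n_lone - 2L * (n_ws + n_sr + n_far)
    if (n_rand < 0) { n_rand <- n_decoys; n_lone <- n_ws <- n_sr <- n_far <- 0L }
    did <- 0L
    next_id <- function(tag) {
      did <<- did + 1L
      sprintf("DEC_%03d_%s", did, tag)
    }
    ta_homolog <- function(role) {
      i <- .pick_ref(refs, sample(refs$family[refs$role == role], 1L))
      mutate_protein(refs$sequence[i], divergence, mut_seed())
    }
    add_decoy <- function(id, type) {
      decoys[[length(decoys) + 1L]] <<- data.frame(
        gene_id = id, decoy_type = type, stringsAsFactors = FALSE)
    }

    for (k in seq_len(n_lone)) {
      role <- sample(c("toxin", "antitoxin"), 1L)
      id <- next_id("lone")
      units[[length(units) + 1L]] <- list(
        genes = list(list(id = id, seq = ta_homolog(role))),
        gaps = integer(0), strands = sample(c("+", "-"), 1L))
      add_decoy(id, paste0("lone_", role))
    }
    for (k in seq_len(n_ws)) {
      id1 <- next_id("ws"); id2 <- next_id("ws")
      units[[length(units) + 1L]] <- list(
        genes = list(list(id = id1, seq = ta_homolog("antitoxin")),
                     list(id = id2, seq = ta_homolog("toxin"))),
        gaps = sample(c(-2L, 0L, 10L, 30L), 1L), strands = c("+", "-"))
      add_decoy(id1, "wrong_strand_pair"); add_decoy(id2, "wrong_strand_pair")
    }
    for (k in seq_len(n_sr)) {
      role <- sample(c("toxin", "antitoxin"), 1L)
      fams <- sample(unique(refs$family[refs$role == role]), 2L)
      s <- sample(c("+", "-"), 1L)
      id1 <- next_id("sr"); id2 <- next_id("sr")
      units[[length(units) + 1L]] <- list(
        genes = list(
          list(id = id1, seq = mutate_protein(
            refs$sequence[.pick_ref(refs, fams[1L])], divergence,
            mut_seed())),
          list(id = id2, seq = mutate_protein(
            refs$sequence[.pick_ref(refs, fams[2L])], divergence,
            mut_seed()))),
        gaps = sample(c(0L, 10L, 30L), 1L), strands = c(s, s))
      add_decoy(id1, paste0("same_role_", role))
      add_decoy(id2, paste0("same_role_", role))
    }
    for (k in seq_len(n_far)) {
      s <- sample(c("+", "-"), 1L)
      id1 <- next_id("far"); id2 <- next_id("far")
      units[[length(units) + 1L]] <- list(
        genes = list(list(id = id1, seq = ta_homolog("antitoxin")),
                     list(id = id2, seq = ta_homolog("toxin"))),
        gaps = sample(300:800, 1L), strands = c(s, s))
      add_decoy(id1, "distant_pair"); add_decoy(id2, "distant_pair")
    }
    for (k in seq_len(n_rand)) {
      id <- next_id("rnd")
      units[[length(units) + 1L]] <- list(
        genes = list(list(id = id, seq = random_protein(sample(60:250, 1L)))),
        gaps = integer(0), strands = sample(c("+", "-"), 1L))
      add_decoy(id, "random")
    }

    # shuffle transcription units and lay out coordinates
    units <- units[sample.int(length(units))]
    rows <- list()
    pos <- 1L
    for (u in units) {
      pos <- pos + sample(200:2000, 1L)  # inter-unit spacer > adjacency max
      for (gi in seq_along(u$genes)) {
        g <- u$genes[[gi]]
        len_nt <- 3L * (nchar(g$seq) + 1L)
        strand <- if (length(u$strands) == 1L) u$strands else u$strands[gi]
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g$id, contig = contig, start = pos,
          end = pos + len_nt - 1L, strand = strand, protein = g$seq,
          stringsAsFactors = FALSE)
        pos <- pos + len_nt
        if (gi < length(u$genes)) pos <- pos + u$gaps[gi]
      }
    }
    features <- do.call(rbind, rows)
    features <- features[order(features$contig, features$start,
                               features$end, features$gene_id), ,
                         drop = FALSE]
    rownames(features) <- NULL
    validate_features(features)

    structure(list(
      features = features,
      truth = list(
        pairs = if (length(truth_pairs)) do.call(rbind, truth_pairs)
                else data.frame(),
        decoys = if (length(decoys)) do.call(rbind, decoys)
                 else data.frame()),
      seed = as.integer(seed),
      params = list(n_pairs = n_pairs, n_decoys = n_decoys,
                    divergence = divergence,
                    overlap_choices = overlap_choices, contig = contig)),
      class = "ta_simulation")
  })
}

#' @export
print.ta_simulation <- function(x, ...) {
  cat(sprintf(
    "ta_simulation: %d genes on %s; %d planted TA pairs, %d decoys (seed %d)\n",
    nrow(x$features), x$params$contig, nrow(x$truth$pairs),
    nrow(x$truth$decoys), x$seed))
  invisible(x)
}

#' Write a simulated genome to standard files
#'
#' Emits `proteins.faa`, `genes.gff3`, `truth_pairs.tsv` and
#' `truth_decoys.tsv` into `dir`.
#'
#' @param sim A `ta_simulation` from [generate_genome()].
#' @param dir Output directory (created if needed).
#' @param header Optional provenance comment lines for the text outputs.
#' @return Invisibly, a named vector of the paths written.
#' @export
write_genome_files <- function(sim, dir, header = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_faa <- file.path(dir, "proteins.faa")
  p_gff <- file.path(dir, "genes.gff3")
  p_tru <- file.path(dir, "truth_pairs.tsv")
  p_dec <- file.path(dir, "truth_decoys.tsv")
  write_protein_fasta(sim$features$gene_id, sim$features$protein, p_faa)
  write_gff3(sim$features, p_gff, header = header)
  write_tsv_with_header(sim$truth$pairs, p_tru, header)
  write_tsv_with_header(sim$truth$decoys, p_dec, header)
  invisible(c(proteins = p_faa, gff3 = p_gff, truth_pairs = p_tru,
              truth_decoys = p_dec))
}

#' Default stress-expression scenario
#'
#' Per-condition multipliers applied to planted toxin and antitoxin genes,
#' anchored to the published CB0101 observations: toxin up 2.3-fold under
#' nitrogen depletion, 3.1-fold under phosphate depletion and 10.6-fold
#' under zinc toxicity; antitoxin down 2.5-fold under nitrogen depletion.
#'
#' @return Data frame: `condition`, `toxin_mult`, `antitoxin_mult`.
#' @export
default_stress_scenario <- function() {
  data.frame(condition = c("N-", "P-", "Zn"),
             toxin_mult = c(2.3, 3.1, 10.6),
             antitoxin_mult = c(1 / 2.5, 1, 1),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic expression table for a simulated genome
#'
#' Negative-binomial counts with gene-specific log-normal baselines.
#' Planted toxin and antitoxin genes are scaled by the scenario's
#' per-condition fold changes; all other genes stay at baseline.
#'
#' @param sim A `ta_simulation` from [generate_genome()].
#' @param scenario Effect table (see [default_stress_scenario()]); all
#'   multipliers must be positive.
#' @param dispersion Negative-binomial dispersion `alpha` in
#'   `Var = mu + alpha * mu^2`; `0` gives Poisson counts.
#' @param n_reps Replicates per condition (control included).
#' @param baseline_mean Geometric-mean baseline expression per gene.
#' @param seed Integer seed.
#' @return An [expression_table()] with conditions `control` plus the
#'   scenario's.
#' @export
generate_expression <- function(sim, scenario = default_stress_scenario(),
                                dispersion = 0.1, n_reps = 3L,
                                baseline_mean = 200, seed = 1L) {
  if (any(scenario$toxin_mult <= 0) || any(scenario$antitoxin_mult <= 0))
    stop("scenario multipliers must be positive")
  if (dispersion < 0) stop("`dispersion` must be non-negative")
  genes <- sim$features$gene_id
  conds <- c("control", scenario$condition)
  with_seed(seed, {
    base <- stats::rlnorm(length(genes), meanlog = log(baseline_mean),
                          sdlog = 0.5)
    names(base) <- genes
    mult <- matrix(1, nrow = length(genes), ncol = length(conds),
                   dimnames = list(genes, conds))
    if (nrow(sim$truth$pairs)) {
      for (i in seq_len(nrow(scenario))) {
        mult[sim$truth$pairs$toxin, scenario$condition[i]] <-
          scenario$toxin_mult[i]
        mult[sim$truth$pairs$antitoxin, scenario$condition[i]] <-
          scenario$antitoxin_mult[i]
      }
    }
    samples <- expand.grid(replicate = seq_len(n_reps), condition = conds,
                           stringsAsFactors = FALSE)
    samples$sample <- sprintf("%s_r%d", samples$condition,
                              samples$replicate)
    counts <- matrix(0, nrow = length(genes), ncol = nrow(samples),
                     dimnames = list(genes, samples$sample))
    for (s in seq_len(nrow(samples))) {
      mu <- base * mult[, samples$condition[s]]
      counts[, s] <- if (dispersion == 0) stats::rpois(length(mu), mu)
        else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    expression_table(counts, samples[, c("sample", "condition",
                                         "replicate")],
                     control = "control")
  })
}

#' Write an expression table to TSV files
#'
#' @param tab An [expression_table()].
#' @param dir Output directory.
#' @param header Optional provenance comment lines.
#' @return Invisibly, named vector of paths (`counts`, `samples`).
#' @export
write_expression_files <- function(tab, dir, header = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_cnt <- file.path(dir, "counts.tsv")
  p_map <- file.path(dir, "samples.tsv")
  cnt <- data.frame(gene_id = rownames(tab$counts), tab$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_with_header(cnt, p_cnt, header)
  write_tsv_with_header(tab$samples, p_map, header)
  invisible(c(counts = p_cnt, samples = p_map))
}
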