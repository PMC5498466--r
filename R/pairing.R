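# TA operon calling: turn per-gene family assignments plus genome
# coordinates into toxin-antitoxin pair calls, and summarize operon
# architecture.

#' Intergenic distance between two features
#'
#' Number of nucleotides strictly between two 1-based inclusive features on
#' the same contig, taking the leftmost (`a`) first: `b$start - a$end - 1`.
#' Negative values are overlap lengths; 0 means abutting.
#'
#' @param a,b Single-row feature data frames or lists with `contig`,
#'   `start`, `end`. `a$start` must not exceed `b$start`.
#' @return Integer distance (negative = overlap).
#' @examples
#' intergenic_distance(list(contig = "c", start = 1, end = 300),
#'                     list(contig = "c", start = 298, end = 600))  # -3
#' @export
intergenic_distance <- function(a, b) {
  if (a$contig != b$contig)
    stop("features lie on different contigs")
  if (a$start > b$start)
    stop("`a` must be the leftmost feature (order by start)")
  as.integer(b$start - a$end - 1L)
}

#' Call TA pairs from assignments and coordinates
#'
#' Implements the adjacency rule: co-directed genes at adjacent chromosome
#' locations, one an assigned toxin and the other an assigned antitoxin of
#' a different family, are recorded as a TA pair. "Adjacent" is
#' operationalized as consecutive annotated genes (when
#' `require_no_intervening`) with intergenic distance at most
#' `max_intergenic_nt`. Each gene joins at most one pair; conflicts (e.g.
#' an antitoxin-toxin-antitoxin triplet) are resolved greedily by smallest
#' intergenic distance, ties by leftmost upstream start.
#'
#' @param features Feature data frame (see [read_genome()]).
#' @param assignments Data frame from [assign_family()].
#' @param max_intergenic_nt Maximum nucleotides between partners (overlaps
#'   always qualify).
#' @param require_no_intervening If TRUE (default) partners must be
#'   consecutive annotated genes on their contig; if FALSE any co-directed
#'   toxin/antitoxin within range may pair across intervening genes.
#' @return Data frame of `TAPairCandidate`s sorted by (contig, upstream
#'   start): `pair_rank`, `contig`, `toxin`, `antitoxin`, `toxin_family`,
#'   `antitoxin_family`, `strand`, `intergenic_nt`, `antitoxin_upstream`,
#'   `coupled` (1-3 nt ORF overlap), `in_island` (NA until
#'   [annotate_pairs_with_islands()]). Zero rows when nothing qualifies.
#' @export
find_ta_pairs <- function(features, assignments, max_intergenic_nt = 150L,
                          require_no_intervening = TRUE) {
  validate_features(features)
  f <- merge(features, assignments[, c("gene_id", "family", "role")],
             by = "gene_id", all.x = TRUE, sort = FALSE)
  f$role[is.na(f$role)] <- "unassigned"
  f <- f[order(f$contig, f$start, f$end, f$gene_id), , drop = FALSE]
  rownames(f) <- NULL

  cand <- list()
  for (ct in unique(f$contig)) {
    fc <- f[f$contig == ct, , drop = FALSE]
    n <- nrow(fc)
    if (n < 2L) next
    for (i in 1:(n - 1L)) {
      jmax <- if (require_no_intervening) i + 1L else n
      for (j in (i + 1L):jmax) {
        gap <- as.integer(fc$start[j] - fc$end[i] - 1L)
        if (gap > max_intergenic_nt) break
        if (fc$strand[i] != fc$strand[j]) next
        ri <- fc$role[i]; rj <- fc$role[j]
        if (!((ri == "toxin" && rj == "antitoxin") ||
              (ri == "antitoxin" && rj == "toxin"))) next
        if (fc$family[i] == fc$family[j]) next
        tox <- if (ri == "toxin") i else j
        ant <- if (ri == "toxin") j else i
        # upstream in transcription direction
        up <- if (fc$strand[i] == "+") i else j
        cand[[length(cand) + 1L]] <- data.frame(
          contig = ct, toxin = fc$gene_id[tox], antitoxin = fc$gene_id[ant],
          toxin_family = fc$family[tox], antitoxin_family = fc$family[ant],
          strand = fc$strand[i], intergenic_nt = gap,
          antitoxin_upstream = (up == ant), upstream_start = fc$start[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(.empty_pairs())
  cand <- do.call(rbind, cand)

  # greedy matching: smallest gap first, ties by leftmost upstream start
  cand <- cand[order(cand$intergenic_nt, cand$upstream_start,
                     cand$contig), , drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cand$toxin[k] %in% used || cand$antitoxin[k] %in% used) next
    keep[k] <- TRUE
    used <- c(used, cand$toxin[k], cand$antitoxin[k])
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$contig, out$upstream_start), , drop = FALSE]
  out$coupled <- out$intergenic_nt %in% c(-1L, -2L, -3L)
  out$in_island <- NA
  out$pair_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("pair_rank", "contig", "toxin", "antitoxin", "toxin_family",
          "antitoxin_family", "strand", "intergenic_nt",
          "antitoxin_upstream", "coupled", "in_island", "upstream_start")]
}

.empty_pairs <- function() {
  data.frame(pair_rank = integer(0), contig = character(0),
             toxin = character(0), antitoxin = character(0),
             toxin_family = character(0), antitoxin_family = character(0),
             strand = character(0), intergenic_nt = integer(0),
             antitoxin_upstream = logical(0), coupled = logical(0),
             in_island = logical(0), upstream_start = integer(0),
             stringsAsFactors = FALSE)
}

#' Operon architecture report
#'
#' One row per called pair merging coordinates, intergenic architecture and
#' physicochemical properties of both partners, including the
#' basic-toxin/acidic-antitoxin asymmetry flag.
#'
#' @param pairs Data frame from [find_ta_pairs()] (optionally island
#'   annotated).
#' @param physchem Data frame from [physchem_summary()] covering all pair
#'   members.
#' @param features Feature data frame with the pair members' coordinates.
#' @return Data frame, one row per pair.
#' @export
operon_report <- function(pairs, physchem, features) {
  need <- unique(c(pairs$toxin, pairs$antitoxin))
  miss <- setdiff(need, physchem$gene_id)
  if (length(miss))
    stop(sprintf("missing physchem entry for gene(s): %s",
                 paste(miss, collapse = ", ")))
  miss2 <- setdiff(need, features$gene_id)
  if (length(miss2))
    stop(sprintf("missing feature entry for gene(s): %s",
                 paste(miss2, collapse = ", ")))
  tp <- physchem[match(pairs$toxin, physchem$gene_id), , drop = FALSE]
  ap <- physchem[match(pairs$antitoxin, physchem$gene_id), , drop = FALSE]
  tf <- features[match(pairs$toxin, features$gene_id), , drop = FALSE]
  af <- features[match(pairs$antitoxin, features$gene_id), , drop = FALSE]
  data.frame(
    pair_rank = pairs$pair_rank, contig = pairs$contig,
    toxin = pairs$toxin, toxin_family = pairs$toxin_family,
    antitoxin = pairs$antitoxin, antitoxin_family = pairs$antitoxin_family,
    strand = pairs$strand,
    toxin_start = tf$start, toxin_end = tf$end,
    antitoxin_start = af$start, antitoxin_end = af$end,
    intergenic_nt = pairs$intergenic_nt, coupled = pairs$coupled,
    antitoxin_upstream = pairs$antitoxin_upstream,
    toxin_length_aa = tp$length_aa, antitoxin_length_aa = ap$length_aa,
    toxin_mw_da = tp$mw_da, antitoxin_mw_da = ap$mw_da,
    toxin_pi = tp$pi, antitoxin_pi = ap$pi,
    pi_asymmetric = pi_asymmetry(tp$pi, ap$pi),
    in_island = pairs$in_island,
    stringsAsFactors = FALSE)
}

#' Write called pairs as TSV
#'
#' @param pairs Data frame from [find_ta_pairs()] or [operon_report()].
#' @param path Output path.
#' @param header Optional provenance comment lines.
#' @return Invisibly, `path`.
#' @export
write_pairs_tsv <- function(pairs, path, header = character()) {
  drop <- intersect("upstream_start", names(pairs))
  write_tsv_with_header(pairs[, setdiff(names(pairs), drop)], path, header)
}

#' Write called pairs as a GFF3 operon track
#'
#' One `operon` feature per pair spanning both genes.
#'
#' @param pairs Data frame from [find_ta_pairs()].
#' @param features Feature table with member coordinates.
#' @param path Output path.
#' @param header Optional provenance comment lines.
#' @return Invisibly, `path`.
#' @export
write_pairs_gff3 <- function(pairs, features, path, header = character()) {
  tf <- features[match(pairs$toxin, features$gene_id), , drop = FALSE]
  af <- features[match(pairs$antitoxin, features$gene_id), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(header)) writeLines(paste0("# ", header), con)
  if (nrow(pairs)) {
    lines <- sprintf(
      "%s\ttascreen\toperon\t%d\t%d\t.\t%s\t.\tID=TA_pair_%d;toxin=%s;antitoxin=%s;toxin_family=%s;antitoxin_family=%s;coupled=%s",
      pairs$contig, pmin(tf$start, af$start), pmax(tf$end, af$end),
      pairs$strand, pairs$pair_rank, pairs$toxin, pairs$antitoxin,
      pairs$toxin_family, pairs$antitoxin_family,
      tolower(pairs$coupled))
    writeLines(lines, con)
  }
  invisible(path)
}
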