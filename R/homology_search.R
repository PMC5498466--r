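# Local protein alignment, Karlin-Altschul statistics, and family
# assignment by best hit. This replaces an external BLAST step so the
# screen has no runtime dependency on a search tool; externally computed
# tabular hits can still be imported (read_hit_table).

encode_protein <- function(seq, sub, what = "sequence") {
  ch <- check_protein(seq, allow_x = TRUE, what = what)
  match(ch, rownames(sub)) - 1L
}

#' Karlin-Altschul bit score
#'
#' Converts a raw alignment score S to bits: `(lambda * S - ln K) / ln 2`.
#' Defaults are the standard gapped BLOSUM62 constants (gap open 11,
#' extend 1).
#'
#' @param raw_score Integer raw alignment score(s).
#' @param K,lam Karlin-Altschul parameters.
#' @return Numeric bit score(s).
#' @export
bit_score <- function(raw_score, K = 0.041, lam = 0.267) {
  (lam * raw_score - log(K)) / log(2)
}

#' Karlin-Altschul E-value
#'
#' Expected number of local alignments scoring at least `raw_score` between
#' a query of length `m` and a database of `n` residues under the
#' Karlin-Altschul null: `E = K * m * n * exp(-lambda * S)`. No edge-effect
#' correction is applied; `K` and `lambda` are configuration, not estimated
#' from the scoring system.
#'
#' @param raw_score Raw alignment score(s).
#' @param m Query length in residues (> 0).
#' @param n Database size in residues (> 0).
#' @param K,lam Karlin-Altschul parameters.
#' @return Non-negative numeric E-value(s).
#' @examples
#' evalue(50, m = 100, n = 1e4)
#' @export
evalue <- function(raw_score, m, n, K = 0.041, lam = 0.267) {
  if (any(m <= 0) || any(n <= 0))
    stop("`m` and `n` must be positive residue counts")
  K * m * n * exp(-lam * raw_score)
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman alignment with affine gaps (a gap of length k costs
#' `gap_open + k * gap_extend`). Identity and query coverage are computed
#' from one optimal traceback that prefers diagonal over up over left moves.
#' Residue `X` is accepted and scores 0 against everything; any other
#' non-standard residue is an error.
#'
#' @param a,b Protein sequences (single strings). `a` is the query.
#' @param matrix Substitution matrix with residue dimnames
#'   (default [blosum62()]).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param K,lam Karlin-Altschul parameters used for the bit score and
#'   E-value of this single comparison (database size `n = nchar(b)`).
#' @param query_id,target_id Optional labels carried into the hit.
#' @return A list of class `"ta_hit"`: `query_id`, `target_id`,
#'   `raw_score`, `bit_score`, `e_value`, `identity`, `coverage_query`,
#'   `aln_length`, plus 1-based alignment bounds `qstart/qend/tstart/tend`.
#' @examples
#' hit <- align_local("HEAGAWGHEE", "PAWHEAE")
#' hit$raw_score
#' @export
align_local <- function(a, b, matrix = blosum62(), gap_open = 11,
                        gap_extend = 1, K = 0.041, lam = 0.267,
                        query_id = NA_character_, target_id = NA_character_) {
  if (gap_open < 0 || gap_extend < 0)
    stop("gap penalties must be non-negative costs")
  ai <- encode_protein(a, matrix, "query sequence")
  bi <- encode_protein(b, matrix, "target sequence")
  r <- .sw_align_cpp(ai, bi, matrix, as.integer(gap_open),
                     as.integer(gap_extend))
  hit <- list(
    query_id = query_id, target_id = target_id,
    raw_score = r$score,
    bit_score = bit_score(r$score, K, lam),
    e_value = evalue(r$score, m = length(ai), n = length(bi), K = K,
                     lam = lam),
    identity = if (r$aln_length > 0) r$matches / r$aln_length else NA_real_,
    coverage_query = r$q_aligned / length(ai),
    coverage_shorter = if (length(ai) <= length(bi))
      r$q_aligned / length(ai) else r$t_aligned / length(bi),
    aln_length = r$aln_length, matches = r$matches,
    qstart = r$qstart, qend = r$qend, tstart = r$tstart, tend = r$tend)
  class(hit) <- "ta_hit"
  hit
}

#' @export
print.ta_hit <- function(x, ...) {
  cat(sprintf(
    "local alignment %s vs %s: raw %d, %.1f bits, E = %.3g, id %.1f%%, len %d\n",
    x$query_id, x$target_id, x$raw_score, x$bit_score, x$e_value,
    100 * x$identity, x$aln_length))
  invisible(x)
}

#' Assign genome proteins to TA families by best hit
#'
#' Aligns each protein against every cluster representative, keeps hits with
#' E-value at or below `e_cutoff` (database size `n` = total residues across
#' representatives), and assigns the family and role of the highest
#' bit-score hit. Ties are broken by lower E-value, then higher identity,
#' then lexicographically smallest representative id. Proteins with no
#' qualifying hit are `unassigned`.
#'
#' @param genes A `GeneFeature` data frame (see [read_genome()]) or any data
#'   frame with `gene_id` and `protein` columns.
#' @param clusters Reference clusters from [cluster_references()] (the
#'   member table, with sequences).
#' @param e_cutoff E-value cutoff for a qualifying hit.
#' @param matrix,gap_open,gap_extend,K,lam Alignment parameters, see
#'   [align_local()].
#' @return Data frame with one row per gene: `gene_id`, `family`, `role`
#'   (`"toxin"`, `"antitoxin"` or `"unassigned"`), `representative`,
#'   `raw_score`, `bit_score`, `e_value`, `identity`, `coverage_query`.
#' @export
assign_family <- function(genes, clusters, e_cutoff = 0.01,
                          matrix = blosum62(), gap_open = 11,
                          gap_extend = 1, K = 0.041, lam = 0.267) {
  stopifnot(is.data.frame(genes), all(c("gene_id", "protein") %in%
                                        names(genes)))
  reps <- clusters[clusters$is_representative, , drop = FALSE]
  if (nrow(reps) == 0L) stop("cluster set has no representatives")
  reps <- reps[order(reps$record_id), , drop = FALSE]
  n_db <- sum(nchar(reps$sequence))
  rep_enc <- lapply(reps$sequence, encode_protein, sub = matrix)
  q_enc <- lapply(seq_len(nrow(genes)), function(g)
    encode_protein(genes$protein[g], matrix,
                   sprintf("protein of %s", genes$gene_id[g])))
  qlen <- lengths(q_enc)
  aln <- .sw_align_many_cpp(q_enc, rep_enc, matrix, as.integer(gap_open),
                            as.integer(gap_extend))

  out <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    best <- NULL
    for (r in seq_len(nrow(reps))) {
      s <- aln$score[g, r]
      ev <- evalue(s, m = qlen[g], n = n_db, K = K, lam = lam)
      if (ev > e_cutoff) next
      al <- aln$aln_length[g, r]
      cand <- list(score = s, e = ev,
                   id = if (al > 0) aln$matches[g, r] / al else 0,
                   cov = aln$q_aligned[g, r] / qlen[g],
                   rep = reps$record_id[r],
                   family = reps$family[r], role = reps$role[r])
      if (is.null(best) ||
          cand$score > best$score ||
          (cand$score == best$score && cand$e < best$e) ||
          (cand$score == best$score && cand$e == best$e &&
             cand$id > best$id))
        best <- cand
      # equal on all criteria: keep earlier (lexicographically smaller) rep
    }
    out[[g]] <- if (is.null(best)) {
      data.frame(gene_id = genes$gene_id[g], family = NA_character_,
                 role = "unassigned", representative = NA_character_,
                 raw_score = NA_integer_, bit_score = NA_real_,
                 e_value = NA_real_, identity = NA_real_,
                 coverage_query = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = genes$gene_id[g], family = best$family,
                 role = best$role, representative = best$rep,
                 raw_score = best$score,
                 bit_score = bit_score(best$score, K, lam),
                 e_value = best$e, identity = best$id,
                 coverage_query = best$cov, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Import an external tabular hit file
#'
#' Reads the conventional 12-column tab-separated hit format (query, target,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' tstart, tend, evalue, bitscore) so results from an external search tool
#' can be fed into [assignments_from_hits()] in place of the internal
#' aligner.
#'
#' @param path Path to the tabular file (no header; `#` comments ignored).
#' @return Data frame with standardized column names.
#' @export
read_hit_table <- function(path) {
  cols <- c("query", "target", "pident", "length", "mismatches", "gapopens",
            "qstart", "qend", "tstart", "tend", "evalue", "bitscore")
  x <- utils::read.table(path, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(x) != 12L)
    stop(sprintf("expected 12 tab-separated columns, found %d", ncol(x)))
  names(x) <- cols
  x
}

#' Family assignment from an imported hit table
#'
#' Applies the same best-hit rule as [assign_family()] (highest bit score,
#' then lowest E-value, then highest identity, then lexicographic target id)
#' to externally computed hits.
#'
#' @param hits Data frame from [read_hit_table()].
#' @param clusters Cluster member table mapping representative
#'   `record_id` to `family` and `role`.
#' @param e_cutoff E-value cutoff.
#' @return Data frame as in [assign_family()] (alignment-detail columns
#'   limited to what the tabular format carries).
#' @export
assignments_from_hits <- function(hits, clusters, e_cutoff = 0.01) {
  reps <- clusters[clusters$is_representative, , drop = FALSE]
  if (nrow(reps) == 0L) stop("cluster set has no representatives")
  keep <- hits[hits$evalue <= e_cutoff &
                 hits$target %in% reps$record_id, , drop = FALSE]
  keep <- keep[order(keep$query, -keep$bitscore, keep$evalue,
                     -keep$pident, keep$target), , drop = FALSE]
  best <- keep[!duplicated(keep$query), , drop = FALSE]
  fam <- reps$family[match(best$target, reps$record_id)]
  role <- reps$role[match(best$target, reps$record_id)]
  data.frame(gene_id = best$query, family = fam, role = role,
             representative = best$target, raw_score = NA_integer_,
             bit_score = best$bitscore, e_value = best$evalue,
             identity = best$pident / 100,
             coverage_query = NA_real_, stringsAsFactors = FALSE)
}

#' Write family assignments as TSV
#'
#' @param assignments Data frame from [assign_family()].
#' @param path Output path.
#' @param header Optional provenance comment lines (without leading `#`).
#' @return Invisibly, `path`.
#' @export
write_assignments_tsv <- function(assignments, path, header = character()) {
  write_tsv_with_header(assignments, path, header)
}
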