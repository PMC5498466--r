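# Reference toxin/antitoxin set: loading, validation, and single-linkage
# family clustering with representative selection.

.valid_roles <- c("toxin", "antitoxin")

#' Load a reference TA protein set
#'
#' Reads a FASTA file whose headers carry record id, family and role as
#' `>{id}{sep}{family}{sep}{toxin|antitoxin}` (default separator `|`).
#' Sequences may be wrapped over multiple lines; CRLF line endings are
#' handled. Records are validated: unique ids, role one of
#' `toxin`/`antitoxin`, role consistent within a family label, sequence
#' length between 20 and 400 residues over the standard alphabet (plus X).
#'
#' @param path Path to the FASTA file.
#' @param sep Header field separator (a fixed string, default `"|"`).
#' @return Data frame of `TAFamilyRecord`s: `record_id`, `family`, `role`,
#'   `sequence`, in file order.
#' @examples
#' refs <- read_ta_references(demo_reference_path())
#' table(refs$role)
#' @export
read_ta_references <- function(path, sep = "|") {
  if (!file.exists(path)) stop(sprintf("reference FASTA not found: %s", path))
  fa <- Biostrings::readAAStringSet(path)
  if (length(fa) == 0L) stop("reference FASTA contains no records")
  parts <- strsplit(names(fa), sep, fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 3L)
  if (length(bad))
    stop(sprintf("malformed header (expected id%sfamily%srole): '%s'",
                 sep, sep, names(fa)[bad[1L]]))
  rec <- data.frame(
    record_id = trimws(vapply(parts, `[`, "", 1L)),
    family = trimws(vapply(parts, `[`, "", 2L)),
    role = trimws(vapply(parts, `[`, "", 3L)),
    sequence = toupper(as.character(fa)),
    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  validate_ta_references(rec)
  rec
}

validate_ta_references <- function(rec) {
  dup <- rec$record_id[duplicated(rec$record_id)]
  if (length(dup))
    stop(sprintf("duplicate record_id in reference set: %s",
                 paste(unique(dup), collapse = ", ")))
  badrole <- !rec$role %in% .valid_roles
  if (any(badrole))
    stop(sprintf("record '%s' has invalid role '%s' (want toxin/antitoxin)",
                 rec$record_id[badrole][1L], rec$role[badrole][1L]))
  len <- nchar(rec$sequence)
  badlen <- len < 20L | len > 400L
  if (any(badlen))
    stop(sprintf("record '%s' has sequence length %d (allowed 20..400)",
                 rec$record_id[badlen][1L], len[badlen][1L]))
  for (i in seq_len(nrow(rec)))
    check_protein(rec$sequence[i], allow_x = TRUE,
                  what = sprintf("sequence of '%s'", rec$record_id[i]))
  mixed <- tapply(rec$role, rec$family, function(r) length(unique(r)) > 1L)
  if (any(mixed))
    stop(sprintf("family '%s' mixes toxin and antitoxin records",
                 names(mixed)[mixed][1L]))
  invisible(rec)
}

#' Cluster reference records into families
#'
#' Single-linkage clustering of the reference set: two records link iff a
#' local alignment ([align_local()]) covers at least `length_coverage` of
#' the shorter sequence and carries at least `score_density` bits per
#' aligned position. Records of different roles never link (role is
#' authoritative metadata, never inferred from sequence). The cluster
#' representative is the longest member, ties broken by lexicographically
#' smallest `record_id`.
#'
#' The coverage/score-density thresholds mirror the conventions of classic
#' greedy sequence clusterers; `coverage_on = "both"` additionally requires
#' the coverage on the longer sequence.
#'
#' @param records Data frame from [read_ta_references()].
#' @param length_coverage Minimum aligned fraction of the (shorter)
#'   sequence, in (0, 1].
#' @param score_density Minimum bit score per aligned column.
#' @param coverage_on `"shorter"` (default) or `"both"`.
#' @param matrix,gap_open,gap_extend,K,lam Alignment parameters.
#' @return Data frame with one row per record: `cluster_id`, `record_id`,
#'   `family`, `role`, `sequence`, `is_representative`. Clusters are
#'   numbered `C001`, `C002`, ... by order of their first member.
#' @export
cluster_references <- function(records, length_coverage = 0.75,
                               score_density = 1.0,
                               coverage_on = c("shorter", "both"),
                               matrix = blosum62(), gap_open = 11,
                               gap_extend = 1, K = 0.041, lam = 0.267) {
  if (is.null(records) || nrow(records) == 0L)
    stop("empty reference set")
  if (length_coverage <= 0 || length_coverage > 1)
    stop("`length_coverage` must be in (0, 1]")
  coverage_on <- match.arg(coverage_on)
  validate_ta_references(records)

  n <- nrow(records)
  enc <- lapply(records$sequence, encode_protein, sub = matrix)
  lens <- lengths(enc)
  # order-independent linkage: evaluate all unordered pairs on sorted ids
  ord <- order(records$record_id)
  adj_from <- integer(0); adj_to <- integer(0)
  if (n > 1L) {
    for (ii in 1:(n - 1L)) {
      for (jj in (ii + 1L):n) {
        i <- ord[ii]; j <- ord[jj]
        if (records$role[i] != records$role[j]) next
        a <- .sw_align_cpp(enc[[i]], enc[[j]], matrix,
                           as.integer(gap_open), as.integer(gap_extend))
        if (a$aln_length == 0L) next
        cov_s <- if (lens[i] <= lens[j]) a$q_aligned / lens[i]
                 else a$t_aligned / lens[j]
        cov_l <- if (lens[i] <= lens[j]) a$t_aligned / lens[j]
                 else a$q_aligned / lens[i]
        cov_ok <- cov_s >= length_coverage &&
          (coverage_on == "shorter" || cov_l >= length_coverage)
        dens <- bit_score(a$score, K, lam) / a$aln_length
        if (cov_ok && dens >= score_density) {
          adj_from <- c(adj_from, i); adj_to <- c(adj_to, j)
        }
      }
    }
  }
  g <- igraph::make_graph(rbind(adj_from, adj_to), n = n, directed = FALSE)
  comp <- igraph::components(g)$membership

  # order-invariant cluster numbering: by lexicographically smallest member
  first <- tapply(records$record_id, comp, min)
  renum <- rank(first)
  cid <- sprintf("C%03d", renum[as.character(comp)])

  is_rep <- logical(n)
  for (cl in unique(comp)) {
    mem <- which(comp == cl)
    mx <- mem[nchar(records$sequence[mem]) ==
                max(nchar(records$sequence[mem]))]
    is_rep[mx[order(records$record_id[mx])][1L]] <- TRUE
  }
  fam <- records$family
  out <- data.frame(cluster_id = cid, record_id = records$record_id,
                    family = fam, role = records$role,
                    sequence = records$sequence,
                    is_representative = is_rep, stringsAsFactors = FALSE)
  mixedfam <- tapply(out$family, out$cluster_id,
                     function(f) length(unique(f)) > 1L)
  if (any(mixedfam))
    warning(sprintf("cluster(s) %s link records from different families",
                    paste(names(mixedfam)[mixedfam], collapse = ", ")))
  out[order(out$cluster_id, out$record_id), , drop = FALSE]
}

#' Path of the bundled synthetic reference set
#'
#' The package ships a small synthetic demonstration reference: exemplars of
#' the canonical type II families (relB/relE, mazE/mazF, yefM/yoeB,
#' vapB/vapC, phd/doc) generated with realistic lengths and with the
#' basic-toxin / acidic-antitoxin compositional bias typical of these
#' proteins. They are stand-ins, not database sequences; any user FASTA
#' with `id|family|role` headers can be used instead.
#'
#' @return Path to `ta_reference_synthetic.fasta`.
#' @export
demo_reference_path <- function() {
  system.file("extdata", "ta_reference_synthetic.fasta",
              package = "tascreen", mustWork = TRUE)
}

#' Write reference clusters as TSV
#'
#' @param clusters Data frame from [cluster_references()].
#' @param path Output path.
#' @param header Optional provenance comment lines.
#' @return Invisibly, `path`.
#' @export
write_clusters_tsv <- function(clusters, path, header = character()) {
  cols <- c("cluster_id", "record_id", "family", "role",
            "is_representative")
  write_tsv_with_header(clusters[, cols], path, header)
}
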