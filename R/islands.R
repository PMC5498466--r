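# Simplified genomic-island context: maximal runs of non-core genes
# spanning more than a minimum length. Stands in for composition-based
# island callers; the core/non-core designation is user input.

#' Call genomic islands from a core-gene designation
#'
#' Genomic islands are modeled as large regions (strictly more than
#' `min_island_length` nucleotides, default 8 kb) of contiguous non-core
#' genes. Genes are taken in coordinate order per contig; every maximal run
#' of genes absent from `core_gene_ids` whose genomic span (first start to
#' last end) exceeds the threshold becomes one island.
#'
#' @param features Feature data frame (see [read_genome()]).
#' @param core_gene_ids Character vector of core (conserved) gene ids; must
#'   be a subset of the feature ids.
#' @param min_island_length Minimum span in nt; the comparison is strict
#'   (a span of exactly `min_island_length` is excluded).
#' @return Data frame of `IslandInterval`s: `contig`, `start`, `end`,
#'   `length_nt`, `n_genes`, sorted and disjoint.
#' @export
call_islands <- function(features, core_gene_ids,
                         min_island_length = 8000L) {
  validate_features(features)
  stray <- setdiff(core_gene_ids, features$gene_id)
  if (length(stray))
    stop(sprintf("core gene id(s) not in annotation: %s",
                 paste(utils::head(stray, 5), collapse = ", ")))
  f <- features[order(features$contig, features$start, features$end), ,
                drop = FALSE]
  out <- list()
  for (ct in unique(f$contig)) {
    fc <- f[f$contig == ct, , drop = FALSE]
    noncore <- !(fc$gene_id %in% core_gene_ids)
    r <- rle(noncore)
    stop_i <- cumsum(r$lengths)
    start_i <- stop_i - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      s <- fc$start[start_i[k]]
      e <- max(fc$end[start_i[k]:stop_i[k]])
      span <- e - s + 1L
      if (span > min_island_length)
        out[[length(out) + 1L]] <- data.frame(
          contig = ct, start = s, end = e, length_nt = span,
          n_genes = stop_i[k] - start_i[k] + 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), length_nt = integer(0),
                      n_genes = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Flag pairs inside genomic islands
#'
#' Sets `in_island` TRUE iff both genes of a pair lie fully within a single
#' island interval; pairs straddling an island boundary are FALSE.
#'
#' @param pairs Data frame from [find_ta_pairs()].
#' @param islands Data frame from [call_islands()].
#' @param features Feature table with member coordinates.
#' @return `pairs` with `in_island` filled in.
#' @export
annotate_pairs_with_islands <- function(pairs, islands, features) {
  if (nrow(pairs) == 0L) return(pairs)
  tf <- features[match(pairs$toxin, features$gene_id), , drop = FALSE]
  af <- features[match(pairs$antitoxin, features$gene_id), , drop = FALSE]
  lo <- pmin(tf$start, af$start)
  hi <- pmax(tf$end, af$end)
  pairs$in_island <- vapply(seq_len(nrow(pairs)), function(k) {
    any(islands$contig == pairs$contig[k] & islands$start <= lo[k] &
          islands$end >= hi[k])
  }, logical(1))
  pairs
}

#' Read a core-gene list (one id per line)
#'
#' @param path Text file, one gene id per line; blank lines and `#`
#'   comments ignored.
#' @return Character vector of ids.
#' @export
read_core_genes <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write islands as BED
#'
#' Converts the 1-based inclusive island intervals to BED's 0-based
#' half-open convention (`chromStart = start - 1`, `chromEnd = end`).
#'
#' @param islands Data frame from [call_islands()].
#' @param path Output path.
#' @param header Optional provenance comment lines.
#' @return Invisibly, `path`.
#' @export
write_islands_bed <- function(islands, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  if (nrow(islands))
    writeLines(sprintf("%s\t%d\t%d\tisland_%d", islands$contig,
                       islands$start - 1L, islands$end,
                       seq_len(nrow(islands))), con)
  invisible(path)
}
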