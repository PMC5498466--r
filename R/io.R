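# Readers/writers for the pipeline's external formats: protein FASTA,
# GFF3 gene coordinates, and headered TSV tables.

write_tsv_with_header <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an annotated genome (GFF3 + protein FASTA)
#'
#' Builds the `GeneFeature` table the pairing stage consumes: one row per
#' annotated gene with 1-based inclusive coordinates, strand, and protein
#' sequence. Coordinates come from the GFF3 `CDS` (fallback `gene`)
#' features; proteins are matched by the GFF3 `ID` attribute against FASTA
#' record names.
#'
#' @param gff3 Path to a GFF3 file.
#' @param fasta Path to the matching protein FASTA (names = gene ids; text
#'   after the first whitespace is ignored).
#' @return Data frame: `gene_id`, `contig`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `protein`; sorted by (contig, start).
#' @export
read_genome <- function(gff3, fasta) {
  if (!file.exists(gff3)) stop(sprintf("GFF3 not found: %s", gff3))
  if (!file.exists(fasta)) stop(sprintf("FASTA not found: %s", fasta))
  gr <- rtracklayer::import(gff3, format = "gff3")
  keep <- as.character(gr$type) %in% c("CDS", "gene")
  if (any(as.character(gr$type) == "CDS"))
    keep <- as.character(gr$type) == "CDS"
  gr <- gr[keep]
  if (length(gr) == 0L) stop(sprintf("no CDS/gene features in %s", gff3))
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids))
    stop(sprintf("GFF3 features must carry an ID attribute (%s)", gff3))
  fa <- Biostrings::readAAStringSet(fasta)
  names(fa) <- sub("\\s.*$", "", names(fa))
  miss <- setdiff(ids, names(fa))
  if (length(miss))
    stop(sprintf("no protein sequence for gene(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  feats <- data.frame(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein = as.character(fa[ids]),
    stringsAsFactors = FALSE)
  if (any(!feats$strand %in% c("+", "-")))
    stop("all features must be stranded (+/-)")
  validate_features(feats)
  feats[order(feats$contig, feats$start, feats$end, feats$gene_id), ,
        drop = FALSE]
}

#' Read an annotated genome from a tabular annotation
#'
#' Alternative to [read_genome()] for inputs without GFF3: a TSV with
#' columns `gene_id`, `contig`, `start`, `end`, `strand` plus a protein
#' FASTA keyed by `gene_id`.
#'
#' @param tsv Path to the annotation TSV.
#' @param fasta Path to the protein FASTA.
#' @return As [read_genome()].
#' @export
read_genome_tsv <- function(tsv, fasta) {
  x <- read_tsv_table(tsv)
  need <- c("gene_id", "contig", "start", "end", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(sprintf("annotation TSV lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  fa <- Biostrings::readAAStringSet(fasta)
  names(fa) <- sub("\\s.*$", "", names(fa))
  absent <- setdiff(x$gene_id, names(fa))
  if (length(absent))
    stop(sprintf("no protein sequence for gene(s): %s",
                 paste(utils::head(absent, 5), collapse = ", ")))
  feats <- data.frame(gene_id = x$gene_id, contig = as.character(x$contig),
                      start = as.integer(x$start), end = as.integer(x$end),
                      strand = x$strand,
                      protein = as.character(fa[x$gene_id]),
                      stringsAsFactors = FALSE)
  validate_features(feats)
  feats[order(feats$contig, feats$start, feats$end, feats$gene_id), ,
        drop = FALSE]
}

validate_features <- function(feats) {
  stopifnot(is.data.frame(feats))
  need <- c("gene_id", "contig", "start", "end", "strand")
  miss <- setdiff(need, names(feats))
  if (length(miss))
    stop(sprintf("feature table lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(feats$gene_id))
    stop("duplicate gene_id in feature table")
  if (any(feats$start < 1L) || any(feats$end < feats$start))
    stop("coordinates must satisfy 1 <= start <= end")
  if (any(!feats$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(feats)
}

#' Write a feature table as GFF3
#'
#' Emits one `CDS` line per gene with an `ID` attribute, 1-based inclusive
#' coordinates per the GFF3 specification.
#'
#' @param feats Feature data frame (see [read_genome()]).
#' @param path Output path.
#' @param header Optional provenance comment lines (after `##gff-version`).
#' @param type Feature type column value.
#' @param source Source column value.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(feats, path, header = character(), type = "CDS",
                       source = "tascreen") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(header)) writeLines(paste0("# ", header), con)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t0\tID=%s",
                   feats$contig, source, type, feats$start, feats$end,
                   feats$strand, feats$gene_id)
  writeLines(lines, con)
  invisible(path)
}

#' Write proteins as FASTA
#'
#' @param ids Record names.
#' @param seqs Protein sequences (same length as `ids`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_protein_fasta <- function(ids, seqs, path, width = 70L) {
  fa <- Biostrings::AAStringSet(seqs)
  names(fa) <- ids
  Biostrings::writeXStringSet(fa, path, width = width)
  invisible(path)
}
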