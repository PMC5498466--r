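# End-to-end genome screen: family assignment -> pair calling ->
# physicochemical and island annotation, per genome, with a cross-genome
# summary. Mirrors a survey over many assembled genomes.

.default_config <- function() {
  list(reference = NULL, genomes = NULL, gff3 = NULL, proteins = NULL,
       genome_name = "genome", annotation_tsv = NULL, core_genes = NULL,
       out_dir = "tascreen_out", e_cutoff = 0.01, max_intergenic = 150,
       length_coverage = 0.75, score_density = 1.0,
       min_island_length = 8000, gap_open = 11, gap_extend = 1,
       karlin_k = 0.041, karlin_lambda = 0.267, seed = 1,
       pka_table = "EMBOSS")
}

#' Read a flat key-value configuration file
#'
#' Grammar: one `key = value` pair per line; blank lines and lines starting
#' with `#` are ignored; values are taken verbatim after trimming. Known
#' numeric keys are coerced. Unknown keys are an error (catches typos).
#'
#' @param path Path to the config file.
#' @return Named list of options merged over the package defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3L]
  if (length(bad))
    stop(sprintf("config line is not 'key = value': '%s'", bad[1L]))
  opts <- stats::setNames(
    lapply(kv, function(m) trimws(m[3L])),
    vapply(kv, function(m) trimws(m[2L]), ""))
  merge_config(opts)
}

merge_config <- function(opts, base = .default_config()) {
  unknown <- setdiff(names(opts), names(base))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")))
  numeric_keys <- c("e_cutoff", "max_intergenic", "length_coverage",
                    "score_density", "min_island_length", "gap_open",
                    "gap_extend", "karlin_k", "karlin_lambda", "seed")
  for (k in names(opts)) {
    v <- opts[[k]]
    base[[k]] <- if (k %in% numeric_keys) as.numeric(v) else v
  }
  base
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # output location does not alter the science; exclude it so the same
  # analysis written elsewhere hashes identically
  keys <- sort(setdiff(names(config), "out_dir"))
  writeLines(sprintf("%s=%s", keys,
                     vapply(config[keys], function(v)
                       paste(format(v), collapse = ","), "")), tmp)
  unname(tools::md5sum(tmp))
}

run_header <- function(config) {
  c(sprintf("tascreen %s",
            as.character(utils::packageVersion("tascreen"))),
    sprintf("config_sha: %s", config_hash(config)),
    sprintf("seed: %d", as.integer(config$seed)))
}

# Screen a single in-memory genome against prepared clusters.
screen_features <- function(features, clusters, config = .default_config()) {
  asg <- assign_family(features, clusters, e_cutoff = config$e_cutoff,
                       gap_open = config$gap_open,
                       gap_extend = config$gap_extend, K = config$karlin_k,
                       lam = config$karlin_lambda)
  pairs <- find_ta_pairs(features, asg,
                         max_intergenic_nt = config$max_intergenic)
  list(assignments = asg, pairs = pairs)
}

#' Run the full TA screen from a configuration
#'
#' Loads and clusters the reference set, then for each genome assigns
#' families, calls TA pairs, computes physicochemical summaries for pair
#' members, annotates genomic islands when a core-gene list is supplied,
#' and writes per-genome TSV/GFF3 outputs plus a cross-genome summary
#' (`summary.tsv`: genome, n_genes, n_toxin_hits, n_antitoxin_hits,
#' n_pairs, status). Every output carries a header with the tool version,
#' config hash and seed, so a rerun from the same config is
#' byte-identical.
#'
#' A failure in one genome is logged and isolated; remaining genomes are
#' still processed.
#'
#' Config keys (see [read_config()]): `reference` (FASTA, required);
#' either `genomes` (manifest TSV with columns `genome`, `gff3`, `faa` and
#' optional `core_genes`) or a single genome via `gff3` + `proteins`
#' (+ optional `core_genes`, `genome_name`); `out_dir`; thresholds
#' `e_cutoff`, `max_intergenic`, `length_coverage`, `score_density`,
#' `min_island_length`, `gap_open`, `gap_extend`, `karlin_k`,
#' `karlin_lambda`; `pka_table`; `seed`.
#'
#' @param config Path to a config file or a named list of options.
#' @return Invisibly, a list with `summary` (data frame), `results` (per
#'   genome: assignments, pairs, report), and `status` (0 = success, 2 =
#'   partial: at least one genome failed).
#' @export
run_screen <- function(config) {
  cfg <- if (is.character(config)) read_config(config)
         else merge_config(config)
  if (is.null(cfg$reference))
    stop("config must name a `reference` FASTA")
  if (is.null(cfg$genomes) && (is.null(cfg$gff3) || is.null(cfg$proteins)))
    stop("config must name `genomes` (manifest TSV) or `gff3` + `proteins`")
  if (!file.exists(cfg$reference))
    stop(sprintf("reference FASTA not found: %s", cfg$reference))

  manifest <- if (!is.null(cfg$genomes)) {
    m <- read_tsv_table(cfg$genomes)
    need <- c("genome", "gff3", "faa")
    if (!all(need %in% names(m)))
      stop("genome manifest needs columns: genome, gff3, faa")
    if (!"core_genes" %in% names(m)) m$core_genes <- NA_character_
    m
  } else {
    data.frame(genome = cfg$genome_name, gff3 = cfg$gff3,
               faa = cfg$proteins,
               core_genes = if (is.null(cfg$core_genes)) NA_character_
                            else cfg$core_genes,
               stringsAsFactors = FALSE)
  }
  missing_in <- unlist(lapply(seq_len(nrow(manifest)), function(i)
    Filter(function(p) !is.na(p) && nzchar(p) && !file.exists(p),
           c(manifest$gff3[i], manifest$faa[i], manifest$core_genes[i]))))
  if (length(missing_in))
    stop(sprintf("input file(s) not found: %s",
                 paste(missing_in, collapse = ", ")))

  hdr <- run_header(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  refs <- read_ta_references(cfg$reference)
  clusters <- cluster_references(refs,
                                 length_coverage = cfg$length_coverage,
                                 score_density = cfg$score_density,
                                 gap_open = cfg$gap_open,
                                 gap_extend = cfg$gap_extend,
                                 K = cfg$karlin_k, lam = cfg$karlin_lambda)
  write_clusters_tsv(clusters, file.path(cfg$out_dir, "clusters.tsv"), hdr)

  results <- list()
  summary_rows <- list()
  status <- 0L
  for (i in seq_len(nrow(manifest))) {
    gname <- manifest$genome[i]
    res <- tryCatch({
      feats <- read_genome(manifest$gff3[i], manifest$faa[i])
      sc <- screen_features(feats, clusters, cfg)
      pairs <- sc$pairs
      members <- unique(c(pairs$toxin, pairs$antitoxin))
      if (!is.na(manifest$core_genes[i]) &&
          nzchar(manifest$core_genes[i])) {
        core <- read_core_genes(manifest$core_genes[i])
        isl <- call_islands(feats, core,
                            min_island_length = cfg$min_island_length)
        pairs <- annotate_pairs_with_islands(pairs, isl, feats)
        write_islands_bed(isl, file.path(
          cfg$out_dir, sprintf("%s.islands.bed", gname)), hdr)
      }
      report <- if (nrow(pairs)) {
        pc <- physchem_summary(
          feats[feats$gene_id %in% members, , drop = FALSE],
          pka_table = cfg$pka_table)
        operon_report(pairs, pc, feats)
      } else .empty_report()
      gdir <- function(suffix) file.path(cfg$out_dir,
                                         sprintf("%s.%s", gname, suffix))
      write_assignments_tsv(sc$assignments, gdir("assignments.tsv"), hdr)
      write_pairs_tsv(pairs, gdir("pairs.tsv"), hdr)
      write_pairs_gff3(pairs, feats, gdir("pairs.gff3"), hdr)
      write_tsv_with_header(report, gdir("operon_report.tsv"), hdr)
      list(genome = gname, features = feats, assignments = sc$assignments,
           pairs = pairs, report = report)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("genome '%s' failed: %s", gname,
                      conditionMessage(res)), call. = FALSE)
      status <- 2L
      summary_rows[[i]] <- data.frame(
        genome = gname, n_genes = NA_integer_, n_toxin_hits = NA_integer_,
        n_antitoxin_hits = NA_integer_, n_pairs = NA_integer_,
        status = "failed", stringsAsFactors = FALSE)
    } else {
      results[[gname]] <- res
      summary_rows[[i]] <- data.frame(
        genome = gname, n_genes = nrow(res$features),
        n_toxin_hits = sum(res$assignments$role == "toxin"),
        n_antitoxin_hits = sum(res$assignments$role == "antitoxin"),
        n_pairs = nrow(res$pairs), status = "ok", stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, summary_rows)
  write_tsv_with_header(summary, file.path(cfg$out_dir, "summary.tsv"),
                        hdr)
  invisible(list(summary = summary, results = results, status = status,
                 config = cfg))
}

.empty_report <- function() {
  data.frame(pair_rank = integer(0), contig = character(0),
             toxin = character(0), toxin_family = character(0),
             antitoxin = character(0), antitoxin_family = character(0),
             strand = character(0), toxin_start = integer(0),
             toxin_end = integer(0), antitoxin_start = integer(0),
             antitoxin_end = integer(0), intergenic_nt = integer(0),
             coupled = logical(0), antitoxin_upstream = logical(0),
             toxin_length_aa = integer(0), antitoxin_length_aa = integer(0),
             toxin_mw_da = numeric(0), antitoxin_mw_da = numeric(0),
             toxin_pi = numeric(0), antitoxin_pi = numeric(0),
             pi_asymmetric = logical(0), in_island = logical(0),
             stringsAsFactors = FALSE)
}
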