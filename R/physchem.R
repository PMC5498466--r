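# Sequence-derived protein properties used to characterize TA candidates:
# length, average molecular weight, isoelectric point, charge asymmetry.

#' Average molecular mass of a protein
#'
#' Sum of average (isotope-weighted) residue masses plus one water
#' (18.01528 Da), matching the "molecular weight prediction" convention of
#' standard proteomics servers. Monoisotopic masses are not used. `X` is
#' not allowed here because it has no defined mass.
#'
#' @param seq Protein sequence(s); character vector.
#' @return Numeric vector of masses in daltons.
#' @examples
#' average_mass("G")  # glycine free amino acid, 75.07 Da
#' @export
average_mass <- function(seq) {
  vapply(seq, function(s) {
    ch <- check_protein(s, allow_x = FALSE)
    sum(.residue_mass[ch]) + .water_mass
  }, 0, USE.NAMES = FALSE)
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R). Positive groups contribute
#' `+1 / (1 + 10^(ph - pKa))`, negative groups `-1 / (1 + 10^(pKa - ph))`.
#' Cysteines are treated as free (no disulfide correction).
#'
#' @param seq A single protein sequence.
#' @param ph pH value(s) in `[0, 14]`; vectorized.
#' @param pka_table `"EMBOSS"` (default) or `"Bjellqvist"` (simplified).
#' @return Numeric net charge, one value per `ph`.
#' @export
charge_at_ph <- function(seq, ph, pka_table = "EMBOSS") {
  if (!pka_table %in% names(.pka_tables))
    stop(sprintf("unknown pKa table '%s' (available: %s)", pka_table,
                 paste(names(.pka_tables), collapse = ", ")))
  if (any(ph < 0 | ph > 14)) stop("`ph` must lie in [0, 14]")
  ch <- check_protein(seq, allow_x = TRUE)
  tab <- .pka_tables[[pka_table]]
  counts_pos <- vapply(names(tab$positive), function(r) sum(ch == r), 0)
  counts_neg <- vapply(names(tab$negative), function(r) sum(ch == r), 0)
  vapply(ph, function(p) {
    pos <- 1 / (1 + 10^(p - tab$nterm)) +
      sum(counts_pos / (1 + 10^(p - tab$positive)))
    neg <- 1 / (1 + 10^(tab$cterm - p)) +
      sum(counts_neg / (1 + 10^(tab$negative - p)))
    pos - neg
  }, 0)
}

#' Isoelectric point of a protein
#'
#' The pH at which [charge_at_ph()] is zero, found by bisection on
#' `[0, 14]` to `|charge| < tol` (default `1e-4`) or `max_iter` halvings.
#' Charge is strictly decreasing in pH, so the root is unique.
#'
#' @param seq Protein sequence(s); character vector.
#' @param pka_table Passed to [charge_at_ph()].
#' @param tol Charge tolerance at convergence.
#' @param max_iter Maximum bisection iterations.
#' @return Numeric pI value(s) in pH units.
#' @export
isoelectric_point <- function(seq, pka_table = "EMBOSS", tol = 1e-4,
                              max_iter = 100L) {
  vapply(seq, function(s) {
    lo <- 0; hi <- 14
    for (i in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      q <- charge_at_ph(s, mid, pka_table)
      if (abs(q) < tol) return(mid)
      if (q > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, 0, USE.NAMES = FALSE)
}

#' Toxin/antitoxin isoelectric-point asymmetry
#'
#' TRUE iff the toxin is basic (pI above `basic_above`) and the antitoxin
#' acidic (pI below `acidic_below`) - the charge complementarity typical of
#' tightly binding type II TA partners. Both inequalities are strict.
#'
#' @param toxin_pi,antitoxin_pi Numeric pI values (vectorized).
#' @param basic_above,acidic_below Thresholds in pH units (default 7).
#' @return Logical vector.
#' @export
pi_asymmetry <- function(toxin_pi, antitoxin_pi, basic_above = 7,
                         acidic_below = 7) {
  toxin_pi > basic_above & antitoxin_pi < acidic_below
}

#' Physicochemical summary per gene
#'
#' @param genes Data frame with `gene_id` and `protein` columns.
#' @param pka_table Passed to [isoelectric_point()].
#' @return Data frame: `gene_id`, `length_aa`, `mw_da`, `pi`,
#'   `net_charge_ph7`.
#' @export
physchem_summary <- function(genes, pka_table = "EMBOSS") {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "protein") %in% names(genes)))
  data.frame(
    gene_id = genes$gene_id,
    length_aa = nchar(genes$protein),
    mw_da = average_mass(genes$protein),
    pi = isoelectric_point(genes$protein, pka_table = pka_table),
    net_charge_ph7 = vapply(genes$protein, charge_at_ph, 0, ph = 7,
                            pka_table = pka_table, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Write per-protein physicochemical table as TSV
#'
#' @param physchem Data frame from [physchem_summary()].
#' @param path Output path.
#' @param header Optional provenance comment lines.
#' @return Invisibly, `path`.
#' @export
write_physchem_tsv <- function(physchem, path, header = character()) {
  write_tsv_with_header(physchem, path, header)
}
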