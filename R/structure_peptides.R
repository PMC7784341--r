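## Secondary-structure association of pausing scores and the
## mass-spectrometry peptide positional-enrichment test.

#' Preprocess alpha-helix annotations
#'
#' Adjacent helices without a gap are concatenated first
#' (`(a,b),(b+1,c) -> (a,c)`; overlapping intervals are merged the same
#' way), then helices of 4 residues or fewer are removed.  Idempotent.
#'
#' @param annotations helix table (`gene_id`, `start`, `end`), 1-based
#'   inclusive residue intervals.
#' @param min_len helices of this many residues or fewer are dropped
#'   after concatenation (default 4).
#' @return Cleaned helix table.
#' @export
preprocess_helices <- function(annotations, min_len = 4L) {
  dt <- as.data.table(annotations)[order(gene_id, start)]
  merged <- dt[, {
    s <- start; e <- end
    ms <- s[1]; me <- e[1]
    out_s <- integer(0); out_e <- integer(0)
    if (.N > 1L) for (i in 2L:.N) {
      if (s[i] <= me + 1L) {
        me <- max(me, e[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
    .(start = c(out_s, ms), end = c(out_e, me))
  }, by = gene_id]
  merged[end - start + 1L > min_len][order(gene_id, start)]
}

#' Amino-acid occurrence in gaps versus helices
#'
#' Every residue of every annotated protein (stop codon excluded) is
#' assigned to a helix or to a gap; counts are tallied per amino acid
#' and the gap:helix occurrence ratio returned.  Amino acids that
#' prefer gaps (high ratio) are the helix breakers.
#'
#' @param transcripts transcript table.
#' @param helices helix table, normally after [preprocess_helices()].
#' @return `data.table(aa, n_gap, n_helix, ratio)`; `ratio` is `NaN`
#'   when the helix count is zero.
#' @export
aa_gap_helix_ratio <- function(transcripts, helices) {
  hx <- as.data.table(helices)
  genes <- intersect(unique(hx$gene_id), transcripts$gene_id)
  if (length(genes) == 0L) stop("no annotated gene found in transcripts")
  tal <- rbindlist(lapply(genes, function(g) {
    n_res <- transcripts[g, n_codons, on = "gene_id"] - 1L
    res <- strsplit(substr(transcripts[g, aa_seq, on = "gene_id"],
                           1L, n_res), "", fixed = TRUE)[[1]]
    in_helix <- rep(FALSE, n_res)
    iv <- hx[gene_id == g]
    for (i in seq_len(nrow(iv)))
      in_helix[iv$start[i]:min(iv$end[i], n_res)] <- TRUE
    data.table(aa = res, helix = in_helix)
  }))
  out <- tal[, .(n_gap = sum(!helix), n_helix = sum(helix)), by = aa]
  out <- merge(data.table(aa = .amino_acids()), out, by = "aa", all.x = TRUE)
  out[is.na(n_gap), `:=`(n_gap = 0L, n_helix = 0L)]
  out[, ratio := ifelse(n_helix > 0, n_gap / n_helix, NaN)]
  out[order(aa)]
}

#' Regress a per-amino-acid feature on pausing scores
#'
#' Ordinary least squares of `feature ~ score` across the 20 amino
#' acids, with the two-sided slope p value and a Kolmogorov-Smirnov
#' test of the residuals against a fitted normal distribution.
#'
#' @param scores named numeric vector of per-amino-acid pausing scores.
#' @param feature named numeric vector of the property to predict
#'   (e.g. gap:helix ratio, or helix-termination ddG); matched to
#'   `scores` by name.
#' @return List with `slope`, `intercept`, `p_value`, `ks_p`, `n` and
#'   the `lm` fit.
#' @export
regress_score_vs_feature <- function(scores, feature) {
  common <- intersect(names(scores), names(feature))
  if (length(common) < 3L) stop("fewer than 3 amino acids in common")
  x <- scores[common]; y <- feature[common]
  ok <- is.finite(x) & is.finite(y)
  fit <- stats::lm(y[ok] ~ x[ok])
  cf <- summary(fit)$coefficients
  r <- stats::residuals(fit)
  ks <- suppressWarnings(
    stats::ks.test(r, "pnorm", mean = mean(r), sd = stats::sd(r)))
  list(slope = unname(cf[2, 1]), intercept = unname(cf[1, 1]),
       p_value = unname(cf[2, 4]), ks_p = ks$p.value, n = sum(ok),
       fit = fit)
}

#' In-silico tryptic digestion
#'
#' Cleaves after every lysine or arginine (trypsin/P: no proline
#' exception), zero missed cleavages; the resulting peptides
#' concatenate exactly to the input.
#'
#' @param proteins named character vector of protein sequences, or a
#'   transcript table (the trailing stop is removed).
#' @return `data.table(protein_id, start, end, sequence)` with 1-based
#'   residue coordinates.
#' @export
tryptic_digest <- function(proteins) {
  if (is.data.frame(proteins)) {
    seqs <- sub("\\*$", "", proteins$aa_seq)
    names(seqs) <- proteins$gene_id
  } else {
    seqs <- proteins
    if (is.null(names(seqs))) stop("protein sequences must be named")
  }
  rbindlist(lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    n <- nchar(s)
    cut_after <- which(strsplit(s, "", fixed = TRUE)[[1]] %in% c("K", "R"))
    ends <- unique(c(cut_after, n))
    starts <- c(1L, head(ends, -1L) + 1L)
    data.table(protein_id = id, start = starts, end = ends,
               sequence = substring(s, starts, ends))
  }))
}

#' Positional enrichment of observed peptides in protein N-halves
#'
#' Tests whether observed (MS-detected) peptides concentrate in the
#' first half of their proteins, the signature of nascent chains caught
#' mid-translation.  Per protein, observed peptides are split by
#' whether the N-terminal residue lies in the first half (residue index
#' `<= floor(n/2)`; the middle residue of an odd-length protein falls
#' in the second half) and compared with the same split of the
#' zero-missed-cleavage theoretical tryptic digest, aggregated across
#' proteins as a Mantel-Haenszel common odds ratio.
#'
#' @param observed_peptides `data.table(protein_id, start)` of detected
#'   peptides (1-based N-terminal residue).
#' @param proteins named character vector of protein sequences or a
#'   transcript table.
#' @return List with `common_or`, `p_value`, `n_strata` and the
#'   per-protein `strata` table.
#' @export
peptide_half_enrichment <- function(observed_peptides, proteins) {
  obs <- as.data.table(observed_peptides)
  theo <- tryptic_digest(proteins)
  plen <- theo[, .(n = max(end)), by = protein_id]
  obs <- merge(obs, plen, by = "protein_id")
  if (nrow(obs) == 0L) stop("no observed peptide matches a protein")
  obs[, first_half := start <= n %/% 2L]
  theo <- merge(theo, plen, by = "protein_id")
  theo[, first_half := start <= n %/% 2L]
  strata <- merge(
    obs[, .(a = sum(first_half), b = sum(!first_half)), by = protein_id],
    theo[, .(c = sum(first_half), d = sum(!first_half)), by = protein_id],
    by = "protein_id")
  list(common_or = mh_common_or(strata),
       p_value = mh_test_p(strata),
       n_strata = nrow(strata),
       strata = strata[])
}
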