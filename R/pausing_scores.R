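## Pausing scores: gene-stratified Mantel-Haenszel common odds ratios of
## a sequence feature at a ribosome site in footprint-defined positions
## versus a background (mRNA-seq pseudo-sites or the gene's own codon /
## amino-acid composition).
##
## All score functions funnel through one engine operating on sparse
## per-gene feature counts, so the A-site (64 codons), P-site (20 amino
## acids) and exit-tunnel (8000 amino-acid 3-mers, codon 3-mers) scores
## share the same statistics and the same zero-stratum policy as
## mh_common_or()/mh_test_p().

#' Gene-stratified odds-ratio scores for a feature family
#'
#' Workhorse behind the site-specific scoring functions.  Both inputs
#' are sparse per-gene feature counts; genes present in only one of the
#' two are uninformative about a ratio and are dropped.  For each
#' feature, each shared gene contributes the 2x2 table (reads with the
#' feature / without, foreground / background) and the Mantel-Haenszel
#' common odds ratio, chi-squared p value and family-wise q value are
#' returned.
#'
#' @param fg foreground counts: `data.table(gene_id, feature, n)`.
#' @param bg background counts, same layout.
#' @param features character vector of features to report; features with
#'   no counts anywhere get `NaN` scores.
#' @param qmode multiple-testing mode passed to [qvalues()].
#' @return `data.table(feature, score, p, q, n_strata)`, one row per
#'   feature; `n_strata` counts the shared genes where the feature was
#'   seen in foreground or background.
#' @export
score_features <- function(fg, bg, features, qmode = c("bh", "storey")) {
  qmode <- match.arg(qmode)
  fg <- as.data.table(fg)[, .(a = sum(n)), by = .(gene_id, feature)]
  bg <- as.data.table(bg)[, .(cc = sum(n)), by = .(gene_id, feature)]
  ftot <- fg[, .(ftot = sum(a)), by = gene_id]
  btot <- bg[, .(btot = sum(cc)), by = gene_id]
  genes <- intersect(ftot[ftot > 0, gene_id], btot[btot > 0, gene_id])
  if (length(genes) == 0L)
    stop("foreground and background share no genes with reads")
  cells <- merge(fg[gene_id %in% genes], bg[gene_id %in% genes],
                 by = c("gene_id", "feature"), all = TRUE)
  cells[is.na(a), a := 0]
  cells[is.na(cc), cc := 0]
  cells <- merge(cells, ftot, by = "gene_id")
  cells <- merge(cells, btot, by = "gene_id")
  ## doubles: the variance term n^2 (n - 1) overflows integers
  cells[, `:=`(a = as.numeric(a), cc = as.numeric(cc),
               ftot = as.numeric(ftot), btot = as.numeric(btot))]
  cells[, `:=`(b = ftot - a, d = btot - cc, n = ftot + btot)]
  ## Mantel-Haenszel sums; strata absent from `cells` for a feature have
  ## a = cc = 0 there and contribute nothing to any term.
  res <- cells[, .(
    or_num = sum(a * d / n),
    or_den = sum(b * cc / n),
    sum_a = sum(a),
    sum_e = sum(ftot * (a + cc) / n),
    sum_v = sum(ifelse(n > 1,
                       ftot * btot * (a + cc) * (b + d) / (n^2 * (n - 1)),
                       0)),
    n_strata = sum(a + cc > 0)
  ), by = feature]
  res[, score := fifelse(or_den > 0, or_num / or_den,
                         fifelse(or_num > 0, Inf, NaN))]
  res[, p := {
    dev <- pmax(abs(sum_a - sum_e) - 0.5, 0)
    fifelse(sum_v > 0, stats::pchisq(dev^2 / sum_v, 1L, lower.tail = FALSE),
            NaN)
  }]
  out <- merge(data.table(feature = features), res, by = "feature",
               all.x = TRUE)
  out[is.na(score), `:=`(score = NaN, p = NaN, n_strata = 0L)]
  out[, q := qvalues(fifelse(is.nan(p), NA_real_, p), method = qmode)]
  out[, .(feature, score, p, q, n_strata)][order(feature)]
}

#' Pseudo-assign mRNA-seq reads as monosome footprints
#'
#' The background for pausing scores: 28-29 nt mRNA-seq fragments are
#' given a pseudo A-site by the very offset rules applied to 28-29 nt
#' monosome footprints; other lengths are excluded.
#'
#' @param mrna_records mRNA-seq footprint table.
#' @param transcripts transcript table.
#' @return Assigned footprint table ([assign_footprints()]).
#' @export
mrna_pseudo_assign <- function(mrna_records, transcripts) {
  dt <- as.data.table(mrna_records)[length %in% c(28L, 29L)]
  assign_footprints(dt, transcripts)
}

## codon (3-nt string) at a 1-based codon index, vectorized over rows
.codon_at <- function(assigned, transcripts, index_col) {
  dt <- merge(as.data.table(assigned), transcripts[, .(gene_id, cds_seq)],
              by = "gene_id", sort = FALSE)
  i <- dt[[index_col]]
  substr(dt$cds_seq, 3L * (i - 1L) + 1L, 3L * i)
}

.aa_at <- function(assigned, transcripts, index_col) {
  dt <- merge(as.data.table(assigned), transcripts[, .(gene_id, aa_seq)],
              by = "gene_id", sort = FALSE)
  i <- dt[[index_col]]
  substr(dt$aa_seq, i, i)
}

#' A-site codon pausing scores
#'
#' For each of the 64 codons, its enrichment at the A-site of the
#' (leading) ribosome in the foreground footprints over the background,
#' as a gene-stratified common odds ratio.  Scores significantly above 1
#' flag slow decoding (or, for stop codons, slow ribosome release).
#'
#' @param fg assigned foreground footprints (disome or monosome).
#' @param bg background: pseudo-assigned mRNA reads
#'   ([mrna_pseudo_assign()]) or a composition background
#'   ([composition_background()] at `level = "codon"`).
#' @param transcripts transcript table.
#' @param qmode multiple-testing mode.
#' @return `data.table(feature, score, p, q, n_strata)`, 64 rows.
#' @export
asite_codon_scores <- function(fg, bg, transcripts, qmode = "bh") {
  fgc <- .site_feature_counts(fg, transcripts, "a_site_codon", "codon")
  bgc <- .as_feature_counts(bg, transcripts, "a_site_codon", "codon")
  score_features(fgc, bgc, features = names(.genetic_code()), qmode = qmode)
}

#' P-site amino-acid pausing scores
#'
#' As [asite_codon_scores()] but for the amino acid at the P-site of the
#' (leading) ribosome; sites without a defined P-site are excluded and
#' stop is not a feature.  Scores above 1 flag slow peptide-bond
#' formation from that amino acid.
#'
#' @inheritParams asite_codon_scores
#' @return `data.table(feature, score, p, q, n_strata)`, 20 rows.
#' @export
psite_aa_scores <- function(fg, bg, transcripts, qmode = "bh") {
  fgc <- .site_feature_counts(fg, transcripts, "p_site_codon", "aa")
  bgc <- .as_feature_counts(bg, transcripts, "p_site_codon", "aa")
  score_features(fgc, bgc, features = .amino_acids(), qmode = qmode)
}

## Turn an assigned-footprint table into (gene, feature, n) counts for a
## single-site feature (codon or amino acid at a site column).
.site_feature_counts <- function(assigned, transcripts, index_col, level) {
  dt <- as.data.table(assigned)
  dt <- dt[!is.na(dt[[index_col]])]
  feat <- if (level == "codon") .codon_at(dt, transcripts, index_col)
          else .aa_at(dt, transcripts, index_col)
  dt <- dt[, .(gene_id, count)]
  dt[, feature := feat]
  if (level == "aa") dt <- dt[feature != "*"]
  dt[, .(n = sum(count)), by = .(gene_id, feature)]
}

## Backgrounds may arrive either as assigned reads or as precomputed
## (gene_id, feature, n) composition counts; dispatch on the columns.
.as_feature_counts <- function(bg, transcripts, index_col, level) {
  dt <- as.data.table(bg)
  if (all(c("feature", "n") %in% names(dt))) return(dt)
  .site_feature_counts(dt, transcripts, index_col, level)
}

#' Exit-tunnel 3-mer pausing scores
#'
#' For every amino-acid 3-mer, its enrichment in the nascent-peptide
#' region upstream of the P-site of the paused (leading) ribosome.  At
#' each site a 3-residue window slides one residue per step across the
#' region consisting of the P-site residue and the `upstream` residues
#' before it (21 residues, 19 windows, by default); window counts are
#' summed over all sites of a gene, the same windows are enumerated at
#' the background pseudo-sites, and the common odds ratio is taken
#' across genes.  The foreground should be position-collapsed
#' ([collapse_positions()]) to control read pile-up "hitchhiking".
#'
#' @inheritParams asite_codon_scores
#' @param fg collapsed assigned foreground footprints.
#' @param upstream number of residues upstream of the P-site in the
#'   region (default 20).
#' @param include_psite include the P-site residue itself in the region
#'   (default `TRUE`, giving a 21-residue region; `FALSE` gives the
#'   strict 20-residue version).
#' @return `data.table(feature, score, p, q, n_strata)`, 8000 rows.
#' @export
tunnel_kmer_scores <- function(fg, bg, transcripts, upstream = 20L,
                               include_psite = TRUE, qmode = "bh") {
  fgw <- tunnel_windows(fg, transcripts, level = "aa", upstream = upstream,
                        include_psite = include_psite)
  bgw <- if (all(c("feature", "n") %in% names(as.data.table(bg))))
    as.data.table(bg)
  else tunnel_windows(bg, transcripts, level = "aa", upstream = upstream,
                      include_psite = include_psite)
  aa <- .amino_acids()
  feats <- as.vector(outer(as.vector(outer(aa, aa, paste0)), aa, paste0))
  score_features(fgw, bgw, features = sort(feats), qmode = qmode)
}

#' Exit-tunnel codon 3-mer pausing scores
#'
#' Identical windowing to [tunnel_kmer_scores()] but on codon triplets
#' (reported as 9-nt strings), which separates synonymous codon
#' combinations that the amino-acid-level score merges.  Features are
#' reported sparsely (those observed in foreground or background), and
#' each feature's relative abundance in the background is included.
#'
#' @inheritParams tunnel_kmer_scores
#' @return `data.table(feature, score, p, q, n_strata, bg_freq)`.
#' @export
tunnel_codon_kmer_scores <- function(fg, bg, transcripts, upstream = 20L,
                                     include_psite = TRUE, qmode = "bh") {
  fgw <- tunnel_windows(fg, transcripts, level = "codon", upstream = upstream,
                        include_psite = include_psite)
  bgw <- if (all(c("feature", "n") %in% names(as.data.table(bg))))
    as.data.table(bg)
  else tunnel_windows(bg, transcripts, level = "codon", upstream = upstream,
                      include_psite = include_psite)
  feats <- sort(union(unique(fgw$feature), unique(bgw$feature)))
  out <- score_features(fgw, bgw, features = feats, qmode = qmode)
  freq <- bgw[, .(bg_n = sum(n)), by = feature]
  out[, bg_freq := 0]
  out[freq, bg_freq := i.bg_n / sum(freq$bg_n), on = "feature"]
  out[]
}

#' Enumerate exit-tunnel windows at assigned sites
#'
#' @param assigned assigned footprint (site) table.
#' @param transcripts transcript table.
#' @param level `"aa"` for amino-acid 3-mers, `"codon"` for codon
#'   triplets (9-nt strings).
#' @param k window size in residues (default 3).
#' @param upstream residues upstream of the P-site in the region.
#' @param include_psite include the P-site residue in the region.
#' @return `data.table(gene_id, feature, n)`; sites whose region is
#'   shorter than `k` contribute only their available windows.
#' @export
tunnel_windows <- function(assigned, transcripts, level = c("aa", "codon"),
                           k = 3L, upstream = 20L, include_psite = TRUE) {
  level <- match.arg(level)
  dt <- as.data.table(assigned)[!is.na(p_site_codon)]
  if (nrow(dt) == 0L)
    return(data.table(gene_id = character(), feature = character(),
                      n = integer()))
  seqcol <- if (level == "aa") "aa_seq" else "cds_seq"
  dt <- merge(dt, transcripts[, c("gene_id", seqcol), with = FALSE],
              by = "gene_id", sort = FALSE)
  hi <- if (include_psite) dt$p_site_codon else dt$p_site_codon - 1L
  lo <- pmax(1L, dt$p_site_codon - upstream)
  width <- hi - lo + 1L
  nwin <- pmax(width - k + 1L, 0L)
  keep <- nwin > 0L
  dt <- dt[keep]; lo <- lo[keep]; nwin <- nwin[keep]
  if (nrow(dt) == 0L)
    return(data.table(gene_id = character(), feature = character(),
                      n = integer()))
  ## expand each site into its windows
  rows <- rep(seq_len(nrow(dt)), nwin)
  wstart <- lo[rows] + (sequence(nwin) - 1L)   # residue index of window start
  seqs <- dt[[seqcol]][rows]
  feat <- if (level == "aa") {
    substr(seqs, wstart, wstart + k - 1L)
  } else {
    substr(seqs, 3L * (wstart - 1L) + 1L, 3L * (wstart + k - 1L))
  }
  out <- data.table(gene_id = dt$gene_id[rows], feature = feat,
                    n = dt$count[rows])
  out[, .(n = sum(n)), by = .(gene_id, feature)]
}

#' Gene-composition background counts
#'
#' An alternative to the mRNA-seq background: the raw occurrence counts
#' of each feature in each gene's own sequence.
#'
#' @param transcripts transcript table.
#' @param level `"codon"` (all codons, stop included), `"aa"` (residues,
#'   stop excluded), `"kmer"` (overlapping amino-acid 3-mers) or
#'   `"codon_kmer"` (overlapping codon triplets, stop codon excluded).
#' @return `data.table(gene_id, feature, n)` usable as `bg` in the
#'   scoring functions.
#' @export
composition_background <- function(transcripts,
                                   level = c("codon", "aa", "kmer",
                                             "codon_kmer")) {
  level <- match.arg(level)
  tx <- as.data.table(transcripts)
  per_gene <- function(gene_id, cds, aaseq, nc) {
    switch(level,
      codon = substring(cds, 3L * (seq_len(nc) - 1L) + 1L, 3L * seq_len(nc)),
      aa = strsplit(substr(aaseq, 1L, nc - 1L), "", fixed = TRUE)[[1]],
      kmer = if (nc - 1L >= 3L)
        substring(substr(aaseq, 1L, nc - 1L), seq_len(nc - 3L),
                  seq_len(nc - 3L) + 2L) else character(0),
      codon_kmer = if (nc - 1L >= 3L)
        substring(cds, 3L * (seq_len(nc - 3L) - 1L) + 1L,
                  3L * (seq_len(nc - 3L) + 2L)) else character(0)
    )
  }
  out <- tx[, {
    f <- per_gene(gene_id, cds_seq, aa_seq, n_codons)
    as.data.table(table(feature = f))
  }, by = gene_id]
  setnames(out, "N", "n")
  out[, n := as.integer(n)]
  out[]
}
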