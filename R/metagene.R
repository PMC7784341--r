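## Metagene profiles, pause calling, monosome/disome pause overlap, and
## the density correlation between monosome occupancy and collision
## frequency.

#' Motif-anchored 5'-end metagene profile
#'
#' Aggregates footprint 5'-end abundance (RPM) around every occurrence
#' of a set of anchor codons; the first nucleotide of the anchor codon
#' is offset 0.  Anchors whose window leaves the CDS are excluded to
#' avoid edge bias.  With pauses planted so the leading-ribosome A-site
#' sits on the anchors, the profile peaks at -45 nt for in-frame 58-nt
#' disome footprints and at -15 nt for 28-nt monosome footprints.
#'
#' @param records footprint table (raw 5'-end positions).
#' @param transcripts transcript table.
#' @param anchor_codons character vector of anchor codons (e.g.
#'   `c("CAC", "CAT")` for histidine).
#' @param window integer `c(lo, hi)` of offsets (nt) relative to the
#'   anchor first nucleotide.
#' @return `data.table(offset, value, n_anchors)` where `value` is mean
#'   RPM per anchor; attribute `n_anchors` gives the anchor count.
#' @export
motif_anchored_profile <- function(records, transcripts, anchor_codons,
                                   window = c(-60L, 30L)) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  dt <- as.data.table(records)
  if (!"count" %in% names(dt)) dt[, count := 1L]
  total <- sum(dt$count)
  offsets <- seq.int(window[1], window[2])

  ## anchor positions: 0-based first nt of each anchor-codon occurrence
  anchors <- transcripts[, {
    cods <- substring(cds_seq, 3L * (seq_len(n_codons) - 1L) + 1L,
                      3L * seq_len(n_codons))
    idx <- which(cods %in% anchor_codons)
    a0 <- 3L * (idx - 1L)
    keep <- a0 + window[1] >= 0L & a0 + window[2] <= 3L * n_codons - 1L
    .(anchor0 = a0[keep])
  }, by = gene_id]
  n_anchors <- nrow(anchors)
  if (n_anchors == 0L) stop("no anchor occurrence fits the window")

  hits <- merge(anchors, dt[, .(gene_id, pos5, count)], by = "gene_id",
                allow.cartesian = TRUE)
  hits <- hits[pos5 - anchor0 >= window[1] & pos5 - anchor0 <= window[2]]
  prof <- hits[, .(value = sum(count) * 1e6 / total),
               by = .(offset = pos5 - anchor0)]
  out <- merge(data.table(offset = offsets), prof, by = "offset", all.x = TRUE)
  out[is.na(value), value := 0]
  out[, value := value / n_anchors]
  out[, n_anchors := n_anchors]
  setattr(out, "n_anchors", n_anchors)
  out[]
}

#' Length-normalized CDS metagene profile
#'
#' Maps each footprint's (leading) A-site to a bin of the normalized CDS
#' (`floor(rel_pos * n_bins)`), normalizes each gene's profile to mean 1
#' and averages across genes; genes below `min_count` reads are
#' excluded.  A rising profile toward the 3' end is the collision
#' "inverse ramp"; a terminal spike reflects slow termination.
#'
#' @param assigned assigned footprint table.
#' @param transcripts transcript table.
#' @param n_bins number of bins (default 50).
#' @param min_count minimum reads for a gene to contribute (default 1).
#' @return `data.table(bin, value, n_genes)` with `bin` in 1..n_bins.
#' @export
normalized_cds_profile <- function(assigned, transcripts, n_bins = 50L,
                                   min_count = 1L) {
  dt <- merge(as.data.table(assigned),
              transcripts[, .(gene_id, n_codons)], by = "gene_id")
  dt <- dt[, if (sum(count) >= min_count) .SD, by = gene_id]
  if (nrow(dt) == 0L) stop("no gene passes min_count")
  dt[, bin := pmin(as.integer(floor((a_site_codon - 1L) / n_codons * n_bins))
                   + 1L, n_bins)]
  per_gene <- dt[, .(n = sum(count)), by = .(gene_id, bin)]
  totals <- per_gene[, .(tot = sum(n)), by = gene_id]
  per_gene <- merge(per_gene, totals, by = "gene_id")
  ## gene profile normalized to mean 1 across bins: value = n / (tot/n_bins)
  per_gene[, value := n / (tot / n_bins)]
  n_genes <- length(unique(per_gene$gene_id))
  prof <- per_gene[, .(value = sum(value) / n_genes), by = bin]
  out <- merge(data.table(bin = seq_len(n_bins)), prof, by = "bin",
               all.x = TRUE)
  out[is.na(value), value := 0]
  out[, n_genes := n_genes]
  out[]
}

#' Start-proximal disome 5'-end occupancy
#'
#' Per-nucleotide 5'-end density over the first `n_nt` nt of the CDS,
#' summed across genes, and the first position with any signal.  Under
#' the steric initiation model no disome 5'-end can fall within the
#' first 9 nt of the open reading frame.
#'
#' @param records footprint table.
#' @param transcripts transcript table (genes shorter than `n_nt` are
#'   still counted over their full length).
#' @param n_nt how many 5'-terminal nucleotides to profile (default 60).
#' @return `data.table(position, density)` (1-based nt; density in RPM)
#'   with attribute `first_nonzero` (1-based, `NA` when all zero).
#' @export
start_proximal_occupancy <- function(records, transcripts, n_nt = 60L) {
  dt <- as.data.table(records)
  if (!"count" %in% names(dt)) dt[, count := 1L]
  total <- sum(dt$count)
  prof <- dt[pos5 < n_nt, .(density = sum(count) * 1e6 / total),
             by = .(position = pos5 + 1L)]
  out <- merge(data.table(position = seq_len(n_nt)), prof, by = "position",
               all.x = TRUE)
  out[is.na(density), density := 0]
  fz <- out[density > 0, position]
  setattr(out, "first_nonzero", if (length(fz)) min(fz) else NA_integer_)
  out[]
}

#' Call translational pauses
#'
#' A codon site is a pause when its (leading-ribosome) A-site footprint
#' abundance is strictly greater than the gene's mean abundance, with
#' the mean taken over all codon positions of the CDS (zeros included).
#'
#' @param assigned assigned footprint table.
#' @param transcripts transcript table.
#' @param source label stored with the pauses (`"monosome"` /
#'   `"disome"`).
#' @return `data.table(gene_id, codon, source, abundance, gene_mean)`.
#' @export
call_pauses <- function(assigned, transcripts, source = "disome") {
  sites <- as.data.table(assigned)[, .(abundance = sum(count)),
                                   by = .(gene_id, codon = a_site_codon)]
  sites <- merge(sites, transcripts[, .(gene_id, n_codons)], by = "gene_id")
  totals <- sites[, .(gene_mean = sum(abundance) / n_codons[1]), by = gene_id]
  sites <- merge(sites, totals, by = "gene_id")
  out <- sites[abundance > gene_mean,
               .(gene_id, codon, source = source, abundance, gene_mean)]
  out[order(gene_id, codon)]
}

#' Overlap of monosome and disome pauses
#'
#' A pause is shared when the A-site of a monosome footprint coincides
#' with the A-site of the leading ribosome of a disome footprint (same
#' gene and codon).
#'
#' @param mono_pauses,di_pauses pause tables ([call_pauses()]).
#' @return Named integer vector `c(mono_only, shared, di_only)`.
#' @export
pause_overlap <- function(mono_pauses, di_pauses) {
  m <- unique(as.data.table(mono_pauses)[, .(gene_id, codon)])
  d <- unique(as.data.table(di_pauses)[, .(gene_id, codon)])
  shared <- nrow(merge(m, d, by = c("gene_id", "codon")))
  c(mono_only = nrow(m) - shared, shared = shared, di_only = nrow(d) - shared)
}

#' Correlation of ribosome density and collision frequency
#'
#' Per gene, monosome density and collision (disome) frequency are each
#' expressed per mRNA per unit length, `count / (mRNA count x CDS
#' length)`; genes without mRNA reads are excluded and the Spearman rank
#' correlation across genes is returned.
#'
#' @param mono,di,mrna footprint tables (raw or assigned).
#' @param transcripts transcript table.
#' @return List with `rho`, `p_value`, `n` and the per-gene `densities`
#'   table.
#' @export
density_correlation <- function(mono, di, mrna, transcripts) {
  cnt <- function(x) as.data.table(x)[, .(n = sum(count)), by = gene_id]
  tab <- Reduce(function(a, b) merge(a, b, by = "gene_id", all = TRUE),
                list(cnt(mono), cnt(di), cnt(mrna)))
  setnames(tab, c("gene_id", "n_mono", "n_di", "n_mrna"))
  for (col in c("n_mono", "n_di", "n_mrna"))
    tab[is.na(get(col)), (col) := 0]
  tab <- merge(tab, transcripts[, .(gene_id, n_codons)], by = "gene_id")
  tab <- tab[n_mrna > 0]
  if (nrow(tab) < 3L) stop("fewer than 3 genes with mRNA reads")
  tab[, `:=`(mono_density = n_mono / (n_mrna * 3 * n_codons),
             di_density = n_di / (n_mrna * 3 * n_codons))]
  ct <- suppressWarnings(
    stats::cor.test(tab$mono_density, tab$di_density, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(tab),
       densities = tab[])
}
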