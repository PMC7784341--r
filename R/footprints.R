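## Footprint classification and ribosome-site assignment.
##
## Length classes: 28/29 nt monosomes and three disome conformations,
## 53/54 nt (leading A-site open), 58/59 nt (leading A-site occupied,
## 2-nt inter-ribosome gap) and 61/62 nt (one extra codon in the gap).
## Within each class, the even length is the canonical fragment; the odd
## length carries one extra nucleotide left by RNase trimming, at the
## 3'-end when the read is in frame 0 and at the 5'-end when in frame 2.
## Odd-length frame-1 reads have no defined A-site and are dropped.

.LENGTH_CLASSES <- c("MONO_28_29", "DI_53_54", "DI_58_59", "DI_61_62", "OTHER")

## 0-based offset from the 5'-end to the first A-site nucleotide of the
## (leading) ribosome, for the in-frame 58-nt reference conformation and
## its frame shifts: frame 0 -> 45 (1-based nts 46-48), frame 1 -> 44
## (45-47), frame 2 -> 46 (47-49).  Other classes are the same rule
## shifted by a class delta: 0 for 53/54 (3'-trimmed, same 5' geometry),
## +3 for 61/62 (extra codon between the ribosomes), -30 for 28/29 (no
## trailing ribosome).
.FRAME_OFFSET <- c(`0` = 45L, `1` = 44L, `2` = 46L)

.class_delta <- function(length) {
  out <- rep(NA_integer_, base::length(length))
  out[length %in% c(53L, 54L, 58L, 59L)] <- 0L
  out[length %in% c(61L, 62L)] <- 3L
  out[length %in% c(28L, 29L)] <- -30L
  out
}

#' Classify a footprint by length
#'
#' @param length footprint length(s) in nt (`>= 20`).
#' @param frame optional reading frame of the 5'-end (0/1/2); recorded on
#'   assigned footprints but not needed for classification.
#' @return Character vector over `MONO_28_29`, `DI_53_54`, `DI_58_59`,
#'   `DI_61_62`, `OTHER`.
#' @export
classify_footprint <- function(length, frame = NULL) {
  length <- as.integer(length)
  out <- rep("OTHER", base::length(length))
  out[length %in% c(28L, 29L)] <- "MONO_28_29"
  out[length %in% c(53L, 54L)] <- "DI_53_54"
  out[length %in% c(58L, 59L)] <- "DI_58_59"
  out[length %in% c(61L, 62L)] <- "DI_61_62"
  out
}

#' A-site offset of the (leading) ribosome
#'
#' Returns the 0-based offset from the footprint 5'-end to the first
#' nucleotide of the A-site of the (leading) ribosome, or `NA` when the
#' length/frame combination has no defined rule (odd lengths in frame 1,
#' and any length outside the defined classes).
#'
#' @param length footprint length(s) in nt.
#' @param frame 5'-end reading frame(s), `pos5 %% 3`.
#' @return Integer vector of offsets (`NA` = undefined; callers drop the
#'   read).
#' @examples
#' a_site_offset(58, 0)  # 45, i.e. 1-based nts 46-48
#' a_site_offset(28, 0)  # 15, i.e. 1-based nts 16-18
#' a_site_offset(61, 0)  # 48: one extra codon between the ribosomes
#' a_site_offset(53, 0)  # 45: same 5' geometry as the 58-nt class
#' a_site_offset(59, 1)  # NA: undefined
#' @export
a_site_offset <- function(length, frame) {
  nmax <- max(base::length(length), base::length(frame))
  length <- rep_len(as.integer(length), nmax)
  frame <- rep_len(as.integer(frame), nmax)
  if (any(!frame %in% 0:2)) stop("frame must be 0, 1 or 2")
  off <- unname(.FRAME_OFFSET[as.character(frame)]) + .class_delta(length)
  ## the longer member of each class carries the 1-nt RNase remnant; its
  ## frame-1 reads have no defined rule and are dropped
  off[length %in% c(29L, 54L, 59L, 62L) & frame == 1L] <- NA_integer_
  as.integer(off)
}

#' Assign leading-ribosome A/P-sites to footprints
#'
#' Classifies each record, computes its frame (`pos5 %% 3`) and applies
#' the length/frame offset rule; reads in class `OTHER`, with undefined
#' offsets, or whose A-site falls outside the CDS are dropped (counts
#' reported in the `dropped` attribute).
#'
#' @param records footprint table (`gene_id`, `pos5`, `length`, `umi`,
#'   `count`).
#' @param transcripts transcript table ([transcript_set()]).
#' @param drop_undefined drop `OTHER`/undefined reads silently (default);
#'   `FALSE` raises an error if any are present.
#' @return `data.table` with columns `gene_id`, `pos5`, `length`,
#'   `length_class`, `frame`, `a_site_codon` (1-based), `p_site_codon`
#'   (`NA` when the A-site is the first codon), `umi`, `count`; attribute
#'   `dropped` holds read counts dropped as undefined / out-of-CDS.
#' @export
assign_footprints <- function(records, transcripts, drop_undefined = TRUE) {
  dt <- as.data.table(records)
  if (!"count" %in% names(dt)) dt[, count := 1L]
  if (!"umi" %in% names(dt)) dt[, umi := NA_character_]
  unknown <- setdiff(unique(dt$gene_id), transcripts$gene_id)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(head(unknown, 10L), collapse = ", "))
  dt[, frame := as.integer(pos5 %% 3L)]
  dt[, length_class := classify_footprint(length)]
  off <- a_site_offset(dt$length, dt$frame)
  off[dt$length_class == "OTHER"] <- NA_integer_
  n_undefined <- sum(dt$count[is.na(off)])
  if (!drop_undefined && n_undefined > 0L)
    stop(n_undefined, " read(s) have no defined A-site rule")
  keep <- !is.na(off)
  dt <- dt[keep]
  ## offsets are congruent to -frame mod 3, so the division is exact
  dt[, a_site_codon := as.integer((pos5 + off[keep]) %/% 3L + 1L)]
  dt[, p_site_codon := ifelse(a_site_codon > 1L, a_site_codon - 1L,
                              NA_integer_)]
  nc <- transcripts[dt$gene_id, n_codons, on = "gene_id"]
  out_of_cds <- dt$a_site_codon < 1L | dt$a_site_codon > nc
  n_out <- sum(dt$count[out_of_cds])
  dt <- dt[!out_of_cds]
  out <- dt[, .(gene_id, pos5, length, length_class, frame,
                a_site_codon, p_site_codon, umi, count)]
  setattr(out, "dropped",
          c(undefined = n_undefined, out_of_cds = n_out))
  out[]
}

#' Collapse PCR duplicates by UMI
#'
#' Reads sharing the same gene, 5'-end position, length and UMI are
#' counted once; records lacking a UMI pass through unchanged.
#' Idempotent.
#'
#' @param records footprint table with a `umi` column.
#' @return Deduplicated footprint table.
#' @export
dedup_umi <- function(records) {
  dt <- as.data.table(records)
  if (!"umi" %in% names(dt)) return(dt)
  no_umi <- dt[is.na(umi)]
  with_umi <- unique(dt[!is.na(umi)], by = c("gene_id", "pos5", "length", "umi"))
  if (nrow(with_umi)) with_umi[, count := 1L]
  rbind(no_umi, with_umi)[order(gene_id, pos5, length)]
}

#' Collapse stacked reads to one per position
#'
#' Combines multiple reads mapped to the same position (same gene,
#' leading A-site codon and length class) into a single read, the
#' control for the "hitchhiking" inflation of exit-tunnel k-mer counts
#' by pile-ups at one pause.  Idempotent.
#'
#' @param assigned assigned footprint table ([assign_footprints()]).
#' @return One record per `(gene_id, a_site_codon, length_class)` with
#'   `count = 1`.
#' @export
collapse_positions <- function(assigned) {
  dt <- as.data.table(assigned)
  out <- unique(dt, by = c("gene_id", "a_site_codon", "length_class"))
  out[, count := 1L]
  out[order(gene_id, a_site_codon)]
}

#' Monosome-matched disome downsampling depth
#'
#' Converts a monosome library size into the disome depth matching the
#' monosome:disome population ratio, rounding half away from zero.
#'
#' @param n_monosome number of monosome footprints defining translated
#'   genes.
#' @param ratio monosome:disome population ratio (32.6 in fast-growing
#'   yeast).
#' @return Integer target disome depth, `round(n_monosome / ratio)`.
#' @examples
#' downsample_count(589461, 32.6)  # 18082
#' @export
downsample_count <- function(n_monosome, ratio) {
  stopifnot(n_monosome >= 0, ratio > 0)
  as.integer(.round_half_away(n_monosome / ratio))
}

#' Downsample disome reads to a target depth
#'
#' Count-weighted sampling without replacement: records are expanded to
#' unit reads, `target_n` of them are kept, and the table is
#' re-aggregated.  Deterministic under a fixed seed.
#'
#' @param assigned assigned (or raw) footprint table with a `count`
#'   column.
#' @param target_n number of reads to keep; must not exceed the total.
#' @param seed optional RNG seed.
#' @return Downsampled table with the same columns; total count is
#'   exactly `target_n`.
#' @export
downsample_disomes <- function(assigned, target_n, seed = NULL) {
  dt <- as.data.table(assigned)
  total <- sum(dt$count)
  if (target_n > total)
    stop("target_n (", target_n, ") exceeds total reads (", total, ")")
  if (target_n == total) return(dt)
  units <- dt[rep(seq_len(.N), count)]
  units[, count := 1L]
  keep <- .with_seed(seed, sample.int(nrow(units), target_n))
  sub <- units[keep]
  grp <- setdiff(names(sub), "count")
  sub[, .(count = as.integer(sum(count))), by = grp]
}

#' Length-by-frame footprint histogram
#'
#' @param records footprint table.
#' @return `data.table` with columns `length`, `frame`, `count` and
#'   `rpm` (reads per million mapped reads in the library).
#' @export
length_frame_histogram <- function(records) {
  dt <- as.data.table(records)
  if (!"count" %in% names(dt)) dt[, count := 1L]
  total <- sum(dt$count)
  out <- dt[, .(count = sum(count)), by = .(length, frame = pos5 %% 3L)]
  out[, rpm := count * 1e6 / total]
  out[order(length, frame)]
}
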