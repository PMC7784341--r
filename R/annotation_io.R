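## Input/output: CDS sequences, footprint tables, helix annotations,
## ortholog maps, helix-termination propensity tables, result writers.
##
## Conventions: footprint 5'-end positions (`pos5`) are 0-based offsets
## within the CDS; codon/residue indices are 1-based.  CDS sequences are
## expected to include the stop codon (the stop-codon A-site analyses
## depend on it); a warning is raised when the final codon is not a stop.

#' Build an indexed transcript table from CDS sequences
#'
#' @param gene_id character vector of gene identifiers (unique).
#' @param cds_seq character vector of CDS nucleotide sequences (A/C/G/T,
#'   length divisible by 3, stop codon included).
#' @return A `data.table` with columns `gene_id`, `cds_seq`, `n_codons`
#'   (CDS length / 3, stop codon counted) and `aa_seq` (amino acids, `*`
#'   for stop).
#' @export
transcript_set <- function(gene_id, cds_seq) {
  stopifnot(length(gene_id) == length(cds_seq))
  if (anyDuplicated(gene_id))
    stop("duplicated gene ids: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  cds_seq <- toupper(cds_seq)
  if (any(grepl("[^ACGT]", cds_seq)))
    stop("CDS sequences must contain only A/C/G/T")
  if (any(nchar(cds_seq) %% 3L != 0L))
    stop("CDS lengths must be divisible by 3")
  if (any(nchar(cds_seq) < 6L))
    stop("CDS must contain at least two codons")
  tx <- data.table(gene_id = as.character(gene_id), cds_seq = cds_seq,
                   n_codons = nchar(cds_seq) %/% 3L)
  tx[, aa_seq := .translate_cds(cds_seq)]
  last <- substring(tx$cds_seq, nchar(tx$cds_seq) - 2L)
  if (any(!last %in% .stop_codons()))
    warning("final codon is not TAA/TAG/TGA for: ",
            paste(head(tx$gene_id[!last %in% .stop_codons()], 5L),
                  collapse = ", "))
  setkey(tx, gene_id)
  tx[]
}

#' Load CDS sequences from a FASTA file
#'
#' One record per gene; records whose length is not divisible by 3 or that
#' contain non-ACGT characters are reported and skipped.  Lowercase
#' sequences are accepted and upper-cased.
#'
#' @param path path to a FASTA file of CDS sequences (stop codon included).
#' @return A transcript table, see [transcript_set()].
#' @export
load_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- toupper(as.character(seqs))
  bad <- nchar(chars) %% 3L != 0L | nchar(chars) < 6L | grepl("[^ACGT]", chars)
  if (any(bad))
    warning(sum(bad), " record(s) skipped (length not divisible by 3, ",
            "too short, or non-ACGT): ",
            paste(head(ids[bad], 5L), collapse = ", "))
  if (all(bad)) stop("no valid CDS records in ", path)
  transcript_set(ids[!bad], chars[!bad])
}

#' Write a transcript table to FASTA
#'
#' @param transcripts a transcript table ([transcript_set()]).
#' @param path output path.
#' @export
write_cds_fasta <- function(transcripts, path) {
  x <- Biostrings::DNAStringSet(transcripts$cds_seq)
  names(x) <- transcripts$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.fp_cols <- c("gene_id", "pos5", "length", "umi", "count")

#' Load an aligned footprint table
#'
#' Tab-separated with header `gene_id pos5 length umi count`; `umi` and
#' `count` are optional (`count` defaults to 1).  `pos5` is the 0-based
#' 5'-end offset within the CDS.  Rows violating the record invariants
#' (`pos5 >= 0`, `length >= 20`, `count >= 0`, and `pos5` inside the CDS
#' when `transcripts` is supplied) are rejected with their row numbers
#' logged in a warning.  Footprints for gene ids absent from
#' `transcripts` raise an error listing the offenders.
#'
#' @param path path to the table.
#' @param transcripts optional transcript table used to validate gene ids
#'   and positions.
#' @return A `data.table` with columns `gene_id`, `pos5`, `length`, `umi`
#'   (`NA` when absent) and `count`.
#' @export
load_footprint_table <- function(path, transcripts = NULL) {
  if (!file.exists(path)) stop("cannot read footprint table: ", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  missing_cols <- setdiff(c("gene_id", "pos5", "length"), names(dt))
  if (length(missing_cols))
    stop("footprint table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"umi" %in% names(dt)) dt[, umi := NA_character_]
  if (!"count" %in% names(dt)) dt[, count := 1L]
  dt[is.na(count), count := 1L]
  dt <- dt[, .(gene_id = as.character(gene_id), pos5 = as.integer(pos5),
               length = as.integer(length), umi = as.character(umi),
               count = as.integer(count))]
  footprint_records(dt, transcripts = transcripts, source = path)
}

## Validate a footprint record table; shared by load_footprint_table and
## in-memory construction.
#' @rdname load_footprint_table
#' @param records an in-memory footprint table to validate.
#' @param source label used in messages.
#' @export
footprint_records <- function(records, transcripts = NULL, source = "records") {
  dt <- as.data.table(records)
  for (col in c("umi", "count"))
    if (!col %in% names(dt)) dt[, (col) := if (col == "umi") NA_character_ else 1L]
  bad <- !(.is_count(dt$pos5) & .is_count(dt$count) &
             !is.na(dt$length) & dt$length >= 20L)
  if (!is.null(transcripts)) {
    unknown <- setdiff(unique(dt$gene_id), transcripts$gene_id)
    if (length(unknown))
      stop("unknown gene id(s) in ", source, ": ",
           paste(head(unknown, 10L), collapse = ", "))
    L <- transcripts[dt$gene_id, 3L * n_codons, on = "gene_id"]
    bad <- bad | (!is.na(dt$pos5) & dt$pos5 >= L)
  }
  if (any(bad))
    warning(sum(bad), " row(s) rejected in ", source, " (rows ",
            paste(head(which(bad), 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ..." else "", ")")
  dt[!bad][, .(gene_id, pos5, length, umi, count)]
}

#' Write a footprint (or assigned-footprint) table
#'
#' Tab-separated with a header row; the complement of
#' [load_footprint_table()] for round-tripping.
#'
#' @param records a footprint table.
#' @param path output path.
#' @export
write_footprint_table <- function(records, path) {
  fwrite(as.data.table(records), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Load alpha-helix interval annotations
#'
#' Tab-separated `gene_id start end` with 1-based inclusive residue
#' coordinates.  See [preprocess_helices()] for the concatenate-and-filter
#' preprocessing applied before helix/gap analyses.
#'
#' @param path path to the annotation table.
#' @param transcripts optional transcript table; intervals must then end at
#'   or before residue `n_codons - 1` (the stop codon is not a residue).
#' @return `data.table` with columns `gene_id`, `start`, `end`.
#' @export
load_helix_annotation <- function(path, transcripts = NULL) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = "gene_id"))
  if (!all(c("gene_id", "start", "end") %in% names(dt)))
    stop("helix annotation needs columns gene_id, start, end")
  dt[, `:=`(start = as.integer(start), end = as.integer(end))]
  if (any(is.na(dt$start) | is.na(dt$end) | dt$start < 1L | dt$end < dt$start))
    stop("malformed helix interval(s): need 1 <= start <= end")
  if (!is.null(transcripts)) {
    nc <- transcripts[dt$gene_id, n_codons, on = "gene_id"]
    if (anyNA(nc)) stop("unknown gene id(s) in helix annotation")
    if (any(dt$end > nc - 1L))
      stop("helix interval(s) extend beyond the last residue")
  }
  dt[]
}

#' Load an ortholog alignment map
#'
#' Tab-separated `gene_a gene_b res_a res_b`, one row per aligned residue
#' pair (1-based).  Within each gene pair the aligned pairs must be
#' strictly increasing in both coordinates.
#'
#' @param path path to the map table.
#' @return `data.table` with columns `gene_a`, `gene_b`, `res_a`, `res_b`.
#' @export
load_ortholog_map <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("gene_a", "gene_b")))
  if (!all(c("gene_a", "gene_b", "res_a", "res_b") %in% names(dt)))
    stop("ortholog map needs columns gene_a, gene_b, res_a, res_b")
  dt[, `:=`(res_a = as.integer(res_a), res_b = as.integer(res_b))]
  ortholog_map(dt)
}

#' @rdname load_ortholog_map
#' @param maps an in-memory map table to validate.
#' @export
ortholog_map <- function(maps) {
  dt <- as.data.table(maps)
  if (any(is.na(dt$res_a) | is.na(dt$res_b) | dt$res_a < 1L | dt$res_b < 1L))
    stop("residue indices must be positive integers")
  ok <- dt[, .(ok = all(diff(res_a) > 0L) && all(diff(res_b) > 0L)),
           by = .(gene_a, gene_b)]
  if (any(!ok$ok))
    stop("aligned pairs out of order for gene pair(s): ",
         paste(head(paste(ok$gene_a[!ok$ok], ok$gene_b[!ok$ok], sep = "/"),
                    5L), collapse = ", "))
  dt[]
}

#' Load a per-amino-acid helix-termination propensity table
#'
#' Tab-separated `aa ddG` (delta-delta-G relative to alanine, kJ/mol);
#' exactly the 20 standard amino acids are required.
#'
#' @param path path to the table.
#' @return Named numeric vector of ddG values, names are one-letter amino
#'   acid codes.
#' @export
load_propensity_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  if (!all(c("aa", "ddG") %in% names(dt)))
    stop("propensity table needs columns aa, ddG")
  if (!setequal(dt$aa, .amino_acids()) || nrow(dt) != 20L)
    stop("propensity table must contain exactly the 20 standard amino acids")
  stats::setNames(as.numeric(dt$ddG), dt$aa)
}

#' Write a result table (tab-separated, 1-based positions)
#'
#' @param x a `data.frame`/`data.table` of results.
#' @param path output path.
#' @export
write_result_table <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
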