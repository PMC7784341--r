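## Small shared helpers.

#' @keywords internal
#' @noRd
.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' @keywords internal
#' @noRd
.sense_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc != "*"]
}

#' @keywords internal
#' @noRd
.stop_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc == "*"]
}

#' @keywords internal
#' @noRd
.amino_acids <- function() sort(unique(.genetic_code()[.genetic_code() != "*"]))

## Translate CDS nucleotide strings (must be multiples of 3, ACGT only)
## to amino-acid strings, '*' for stop codons.
#' @keywords internal
#' @noRd
.translate_cds <- function(seqs) {
  if (length(seqs) == 0L) return(character(0))
  as.character(Biostrings::translate(Biostrings::DNAStringSet(seqs),
                                     no.init.codon = TRUE))
}

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## state; when seed is NULL the current RNG stream is used.
#' @keywords internal
#' @noRd
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

## Round half away from zero (round() rounds half to even).
#' @keywords internal
#' @noRd
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @keywords internal
#' @noRd
.is_count <- function(x) is.numeric(x) & !is.na(x) & x >= 0 & x == floor(x)
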