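## Shared in-code fixtures.

library(data.table)

## Three tiny hand-checkable transcripts (stop codon included).
tiny_transcripts <- function() {
  transcript_set(
    gene_id = c("g1", "g2", "g3"),
    cds_seq = c(
      "ATGAAATAA",                                  # M K *
      paste0("ATG", strrep("GAA", 30), "TGA"),      # M E x30 *
      paste0("ATG", strrep("CCT", 10), "CATCAC", strrep("AAG", 10), "TAG")
    ))
}

## A footprint record table built in code.
fp <- function(gene_id, pos5, length, umi = NA_character_, count = 1L) {
  data.table(gene_id = gene_id, pos5 = as.integer(pos5),
             length = as.integer(length), umi = umi,
             count = as.integer(count))
}

## Plant a footprint whose leading-ribosome A-site is `codon`.
plant <- function(gene_id, codon, length, frame = 0L, count = 1L) {
  off <- a_site_offset(length, frame)
  stopifnot(!is.na(off))
  fp(gene_id, 3L * (codon - 1L) - off, length, count = count)
}

## Independent brute-force Mantel-Haenszel oracle: plain loops over the
## textbook formulas, no shared code with the package engine.
brute_mh_or <- function(strata) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(strata))) {
    a <- strata$a[i]; b <- strata$b[i]; c <- strata$c[i]; d <- strata$d[i]
    n <- a + b + c + d
    if ((a + b) == 0 || (c + d) == 0 || n == 0) next
    num <- num + a * d / n
    den <- den + b * c / n
  }
  if (den > 0) num / den else if (num > 0) Inf else NaN
}

brute_mh_p <- function(strata) {
  sa <- 0; se <- 0; sv <- 0
  for (i in seq_len(nrow(strata))) {
    a <- strata$a[i]; b <- strata$b[i]; c <- strata$c[i]; d <- strata$d[i]
    n <- a + b + c + d
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0 ||
        n <= 1) next
    sa <- sa + a
    se <- se + (a + b) * (a + c) / n
    sv <- sv + (a + b) * (c + d) * (a + c) * (b + d) / (n^2 * (n - 1))
  }
  if (sv == 0) return(NaN)
  stats::pchisq(max(abs(sa - se) - 0.5, 0)^2 / sv, 1, lower.tail = FALSE)
}
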