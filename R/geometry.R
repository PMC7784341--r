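## Closed-form ribosome geometry: disome footprint-length decomposition,
## monosome/disome population arithmetic, steric spacing at initiation,
## and the trisome 5'-end offset.
##
## An elongating 80S ribosome with an occupied A-site protects 28 nt of
## mRNA; with an open A-site it protects 23 nt.  Two collided ribosomes
## are spaced by a 2-nt gap (or 5 nt when one extra codon separates
## them), which decomposes the observed disome footprint lengths:
## 28 + 2 + 28 = 58, 28 + 5 + 28 = 61, 28 + 2 + 23 = 53.

#' Ribosome geometry model
#'
#' @param mono_occupied_len nt protected by a ribosome with an occupied
#'   A-site (28).
#' @param mono_open_len nt protected with an open A-site (23).
#' @param gap_short short inter-ribosome gap, nt (2).
#' @param gap_long long gap with one extra codon between ribosomes, nt
#'   (5).
#' @param ssu_total nt occupied by the small subunit during subunit
#'   joining (37).
#' @param ssu_downstream_of_start of those, nt downstream of the start
#'   codon (22).
#' @param elong_downstream_of_start nt occupied downstream of the start
#'   codon by an elongating ribosome with the start codon in its P-site
#'   (13).
#' @param codon_step nt per elongation step (3).
#' @return A `geometry_model` list.
#' @export
geometry_model <- function(mono_occupied_len = 28L, mono_open_len = 23L,
                           gap_short = 2L, gap_long = 5L, ssu_total = 37L,
                           ssu_downstream_of_start = 22L,
                           elong_downstream_of_start = 13L,
                           codon_step = 3L) {
  m <- list(mono_occupied_len = mono_occupied_len,
            mono_open_len = mono_open_len,
            gap_short = gap_short, gap_long = gap_long,
            ssu_total = ssu_total,
            ssu_downstream_of_start = ssu_downstream_of_start,
            elong_downstream_of_start = elong_downstream_of_start,
            codon_step = codon_step)
  if (any(unlist(m) <= 0)) stop("all geometry parameters must be positive")
  if (gap_short >= gap_long) stop("gap_short must be smaller than gap_long")
  structure(m, class = "geometry_model")
}

#' @export
print.geometry_model <- function(x, ...) {
  cat("Ribosome geometry model (nt):\n")
  for (nm in names(x)) cat(sprintf("  %-26s %d\n", nm, x[[nm]]))
  cat(sprintf("  disome lengths: occupied/short %d, occupied/long %d, open/short %d\n",
              disome_length(x, "occupied", "short"),
              disome_length(x, "occupied", "long"),
              disome_length(x, "open", "short")))
  invisible(x)
}

#' Disome footprint length from ribosome states
#'
#' Trailing ribosome (occupied A-site) + gap + leading ribosome (28 nt
#' when its A-site is occupied, 23 nt when open).
#'
#' @param model a [geometry_model()].
#' @param leading_state `"occupied"` or `"open"` A-site of the leading
#'   ribosome.
#' @param gap `"short"` (2 nt) or `"long"` (5 nt, one extra codon).
#' @return Footprint length in nt (58, 61, 53 or 56 for the default
#'   model).
#' @export
disome_length <- function(model = geometry_model(),
                          leading_state = c("occupied", "open"),
                          gap = c("short", "long")) {
  leading_state <- match.arg(leading_state)
  gap <- match.arg(gap)
  model$mono_occupied_len +
    (if (gap == "short") model$gap_short else model$gap_long) +
    (if (leading_state == "occupied") model$mono_occupied_len
     else model$mono_open_len)
}

#' Monosome/disome population arithmetic
#'
#' From the monosome:disome area ratio of a polysome profile: the
#' population ratio of monosomes to ribosomes-in-disomes is twice the
#' area ratio (a disome holds two ribosomes), and the fraction of
#' ribosomes trapped in disomes is `1 / (area_ratio + 1)`.
#'
#' @param area_ratio monosome:disome area ratio (16.3 in fast-growing
#'   yeast).
#' @return List with `population_ratio` and `ribosome_fraction`.
#' @examples
#' disome_fraction(16.3)  # ratio 32.6, fraction 0.058
#' @export
disome_fraction <- function(area_ratio) {
  stopifnot(area_ratio > 0)
  list(population_ratio = 2 * area_ratio,
       ribosome_fraction = 1 / (area_ratio + 1))
}

#' Minimum inter-ribosome distance at initiation
#'
#' The joining small subunit reaches `ssu_downstream_of_start` nt past
#' the start codon, so the 5'-end of the leading ribosome must lie at
#' least that far plus the short gap downstream; an elongating ribosome
#' with the start codon at its P-site occupies only
#' `elong_downstream_of_start` nt.  The difference (11 nt by default) is
#' the minimum distance between an initiating and the preceding
#' elongating ribosome, clipped at zero.
#'
#' @param model a [geometry_model()].
#' @return Minimum distance in nt.
#' @export
initiation_min_gap <- function(model = geometry_model()) {
  max(model$ssu_downstream_of_start + model$gap_short -
        model$elong_downstream_of_start, 0L)
}

#' Elongation steps needed to collide
#'
#' Number of codon steps the trailing ribosome must take to close an
#' initial gap down to the collision (short) gap, the leading ribosome
#' staying still: `ceiling((initial_gap - gap_short) / codon_step)`,
#' never negative.  From the 11-nt initiation gap this is 3 moves.
#'
#' @param model a [geometry_model()].
#' @param initial_gap starting inter-ribosome distance in nt.
#' @return Integer number of moves.
#' @export
moves_to_collide <- function(model = geometry_model(), initial_gap) {
  max(as.integer(ceiling((initial_gap - model$gap_short) /
                           model$codon_step)), 0L)
}

#' Trisome 5'-end offset upstream of the stop codon
#'
#' A trisome queued at the stop codon places the disome-like 5'-end one
#' ribosome spacing upstream of the 58-nt disome 5'-end: the 45-nt
#' A-site offset of a 58-nt disome plus one occupied ribosome plus the
#' gap, ~75 nt upstream of the stop codon by default.
#'
#' @param model a [geometry_model()].
#' @param gap `"short"` or `"long"` spacing of the extra ribosome.
#' @return Offset in nt.
#' @export
trisome_5p_offset <- function(model = geometry_model(),
                              gap = c("short", "long")) {
  gap <- match.arg(gap)
  a_site_offset(58L, 0L) + model$mono_occupied_len +
    (if (gap == "short") model$gap_short else model$gap_long)
}
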