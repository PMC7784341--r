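## Cross-species conservation of pause sites: projection through
## ortholog alignments, nearest-pause distances, and a permutation test
## that preserves the per-gene pause counts.

#' Project pause sites between species
#'
#' Maps species-b pauses (gene, leading-ribosome A-site residue) into
#' species-a residue coordinates through the aligned residue pairs of an
#' ortholog map; pauses at unaligned residues are dropped and counted.
#'
#' @param pauses_b `data.table(gene_id, residue)` in species-b
#'   coordinates.
#' @param maps ortholog map table (`gene_a`, `gene_b`, `res_a`,
#'   `res_b`), see [load_ortholog_map()].
#' @return `data.table(gene_id, residue)` in species-a coordinates;
#'   attribute `n_dropped` counts unprojectable pauses.
#' @export
project_pauses <- function(pauses_b, maps) {
  pb <- as.data.table(pauses_b)
  mp <- as.data.table(maps)
  hit <- merge(pb, mp, by.x = c("gene_id", "residue"),
               by.y = c("gene_b", "res_b"))
  out <- hit[, .(gene_id = gene_a, residue = res_a)]
  setattr(out, "n_dropped", nrow(pb) - nrow(hit))
  out[order(gene_id, residue)]
}

#' Distance to the nearest projected pause
#'
#' For each species-a pause, the residue distance `d` to the closest
#' projected species-b pause in the same gene; `Inf` when the gene has
#' no projected pause.  `d = 0` means the collision occurs at the
#' orthologous position in both species.
#'
#' @param pauses_a `data.table(gene_id, residue)` in species-a
#'   coordinates.
#' @param projected_b projected pauses ([project_pauses()]).
#' @return `data.table(gene_id, residue, d)`.
#' @export
pause_distance <- function(pauses_a, projected_b) {
  pa <- as.data.table(pauses_a)
  pb <- as.data.table(projected_b)
  pa[, idx := .I]
  hit <- merge(pa, pb[, .(gene_id, res_b2 = residue)], by = "gene_id",
               allow.cartesian = TRUE)
  dmin <- hit[, .(d = as.numeric(min(abs(residue - res_b2)))), by = idx]
  out <- merge(pa, dmin, by = "idx", all.x = TRUE)
  out[is.na(d), d := Inf]
  out[order(idx), .(gene_id, residue, d)]
}

#' Permutation test for pause conservation
#'
#' Observed statistic: the fraction of species-a pauses lying at
#' distance `d = 0` from a projected species-b pause.  The null redraws,
#' for each species-b gene, the same number of pause positions uniformly
#' without replacement over the gene's residues, reprojects and
#' recomputes the fraction; the empirical p value uses the add-one
#' convention `(1 + #(null >= observed)) / (1 + n_perm)`, so it is never
#' zero.  Species-a pauses in genes without an ortholog map are excluded
#' from the denominator; pauses whose ortholog has no projected pause
#' count as non-conserved.
#'
#' @param pauses_a species-a pauses (`gene_id`, `residue`).
#' @param pauses_b species-b pauses (`gene_id`, `residue`).
#' @param maps ortholog map table.
#' @param gene_lengths_b `data.table(gene_id, n_residues)` for species-b
#'   genes carrying pauses.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional RNG seed.
#' @return List with `d` (per-pause distances for the retained species-a
#'   pauses), `observed_fraction`, `null_fractions` (length `n_perm`),
#'   `p_value`, and `n_pauses`.
#' @export
permutation_null <- function(pauses_a, pauses_b, maps, gene_lengths_b,
                             n_perm = 10000L, seed = NULL) {
  pa <- as.data.table(pauses_a)
  pb <- as.data.table(pauses_b)
  mp <- as.data.table(maps)
  gl <- as.data.table(gene_lengths_b)

  ## restrict species-a pauses to genes having an ortholog map
  pa <- pa[gene_id %in% unique(mp$gene_a)]
  if (nrow(pa) == 0L) stop("no species-a pause lies in a mapped gene")

  d_obs <- pause_distance(pa, project_pauses(pb, mp))
  obs <- mean(d_obs$d == 0)

  ## per species-b gene: pause count, residue count, and an alignment
  ## lookup res_b -> encoded species-a position (NA when unaligned)
  counts <- pb[, .(k = .N), by = gene_id]
  counts <- merge(counts, gl, by = "gene_id")
  if (any(counts$k > counts$n_residues))
    stop("gene(s) with more pauses than residues")
  a_genes <- sort(unique(mp$gene_a))
  code <- function(g, r) match(g, a_genes) * 1e7 + r
  lookup <- lapply(seq_len(nrow(counts)), function(i) {
    g <- counts$gene_id[i]
    m <- mp[gene_b == g]
    v <- rep(NA_integer_, counts$n_residues[i])
    if (nrow(m)) v[m$res_b] <- code(m$gene_a, m$res_a)
    v
  })
  pa_keys <- code(pa$gene_id, pa$residue)
  ks <- counts$k
  ls <- counts$n_residues

  null_frac <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(j) {
      proj <- unlist(lapply(seq_along(ks), function(i) {
        v <- lookup[[i]][sample.int(ls[i], ks[i])]
        v[!is.na(v)]
      }), use.names = FALSE)
      mean(pa_keys %in% proj)
    }, numeric(1))
  })
  p <- (1 + sum(null_frac >= obs)) / (1 + n_perm)
  list(d = d_obs, observed_fraction = obs, null_fractions = null_frac,
       p_value = p, n_pauses = nrow(pa))
}
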