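## Synthetic ribosome traffic: random transcriptomes and
## monosome/disome/mRNA footprint libraries with known dwell-time
## structure, so every pipeline stage can be validated against ground
## truth without external data.
##
## Per-codon dwell weights are the product of the multipliers that apply
## at a position (codon at the A-site, amino acid at the P-site,
## amino-acid or codon 3-mer anywhere in the exit-tunnel region, stop
## codon at the A-site).  Monosome A-sites are sampled proportional to
## dwell; disome leading A-sites follow the collision model: "excess",
## a unit stochastic-collision baseline plus the pause-induced excess
## (weight 1 + (dwell - 1) = dwell, so an injected multiplier m gives an
## asymptotic odds ratio of ~m against a uniform background), or
## "power" (weight dwell^alpha) for stress tests.  Footprints are
## emitted by inverting the offset rules, so re-assignment recovers the
## planted A-site exactly.

#' Simulation configuration
#'
#' @param n_genes number of genes.
#' @param mean_codons,sd_log_codons,min_codons,max_codons log-normal
#'   CDS-length distribution (in codons, stop included), clipped.
#' @param codon_weights named sampling weights over the 61 sense codons
#'   (default uniform).
#' @param expr_sd_log log-sd of the per-gene expression weights
#'   (log-normal, default 1).
#' @param multipliers dwell multipliers: a list with any of
#'   `codon_asite` (named, codon -> multiplier), `aa_psite` (named,
#'   amino acid -> multiplier), `aa_tunnel` (named, aa 3-mer ->
#'   multiplier), `codon_tunnel` (named, 9-nt codon 3-mer ->
#'   multiplier), `stop_asite` (scalar).  All default to 1.
#' @param collision_model `"excess"` (default) or `"power"`.
#' @param alpha exponent for the power collision model.
#' @param disome_class_weights mixture over disome classes, named
#'   `"53"`, `"58"`, `"61"`; defaults to the rich-medium composition
#'   (10.9% 53-nt, with 61-nt more abundant than 58-nt).
#' @param canonical_length_frac fraction of reads emitted at the canonical
#'   even length of their class (the rest carry the odd-length 1-nt
#'   RNase remnant).
#' @param mono_length_weights mixture over monosome lengths `"28"`,
#'   `"29"` (28-nt dominant).
#' @param frame_noise fraction of reads emitted in a non-zero frame
#'   (via the defined 5'-end shifts), exercising the frame-dependent
#'   offset rules.
#' @param steric forbid disome 5'-ends within the first 9 nt of the CDS
#'   (the initiation steric-exclusion model).
#' @param mono_depth,di_depth,mrna_depth library sizes (reads).
#' @param tunnel_upstream residues upstream of the P-site scanned for
#'   tunnel multipliers (default 20, matching the scoring window).
#' @param seed RNG seed; all generator functions are deterministic
#'   given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 50L, mean_codons = 350, sd_log_codons = 0.35,
                       min_codons = 120L, max_codons = 1000L,
                       codon_weights = NULL, expr_sd_log = 1,
                       multipliers = list(), collision_model = c("excess", "power"),
                       alpha = 1, disome_class_weights = c(`53` = 0.109,
                                                           `58` = 0.40,
                                                           `61` = 0.491),
                       canonical_length_frac = 0.7,
                       mono_length_weights = c(`28` = 0.75, `29` = 0.25),
                       frame_noise = 0.1, steric = FALSE,
                       mono_depth = 50000L, di_depth = 20000L,
                       mrna_depth = 50000L, tunnel_upstream = 20L,
                       seed = 1L) {
  collision_model <- match.arg(collision_model)
  if (is.null(codon_weights))
    codon_weights <- stats::setNames(rep(1, 61), .sense_codons())
  stopifnot(all(codon_weights >= 0), sum(codon_weights) > 0)
  mult <- list(codon_asite = NULL, aa_psite = NULL, aa_tunnel = NULL,
               codon_tunnel = NULL, stop_asite = 1)
  mult[names(multipliers)] <- multipliers
  for (m in mult) if (!is.null(m) && any(m <= 0))
    stop("dwell multipliers must be positive")
  w <- disome_class_weights / sum(disome_class_weights)
  stopifnot(setequal(names(w), c("53", "58", "61")))
  structure(list(
    n_genes = as.integer(n_genes), mean_codons = mean_codons,
    sd_log_codons = sd_log_codons, min_codons = as.integer(min_codons),
    max_codons = as.integer(max_codons), codon_weights = codon_weights,
    expr_sd_log = expr_sd_log, multipliers = mult,
    collision_model = collision_model, alpha = alpha,
    disome_class_weights = w,
    canonical_length_frac = canonical_length_frac,
    mono_length_weights = mono_length_weights / sum(mono_length_weights),
    frame_noise = frame_noise, steric = isTRUE(steric),
    mono_depth = as.integer(mono_depth), di_depth = as.integer(di_depth),
    mrna_depth = as.integer(mrna_depth),
    tunnel_upstream = as.integer(tunnel_upstream),
    seed = as.integer(seed)), class = "sim_config")
}

#' Generate a random transcriptome
#'
#' Random CDSs drawn from the codon-usage weights, ATG first, a stop
#' codon last; reproducible under the config seed.
#'
#' @param config a [sim_config()].
#' @return A transcript table ([transcript_set()]).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    nc <- pmin(pmax(round(stats::rlnorm(config$n_genes,
                                        log(config$mean_codons),
                                        config$sd_log_codons)),
                    config$min_codons), config$max_codons)
    sense <- names(config$codon_weights)
    pw <- config$codon_weights / sum(config$codon_weights)
    stops <- .stop_codons()
    seqs <- vapply(nc, function(k) {
      body <- sample(sense, k - 2L, replace = TRUE, prob = pw)
      paste0("ATG", paste(body, collapse = ""),
             sample(stops, 1L))
    }, character(1))
    transcript_set(sprintf("g%04d", seq_len(config$n_genes)), seqs)
  })
}

## Per-gene dwell-weight vectors over A-site codon positions.
#' Dwell weights implied by a configuration
#'
#' @param transcripts transcript table.
#' @param config a [sim_config()].
#' @return Named list (by gene) of per-codon dwell weights for the
#'   A-site position.
#' @export
dwell_weights <- function(transcripts, config) {
  m <- config$multipliers
  up <- config$tunnel_upstream
  out <- lapply(seq_len(nrow(transcripts)), function(i) {
    nc <- transcripts$n_codons[i]
    cds <- transcripts$cds_seq[i]
    aas <- transcripts$aa_seq[i]
    cods <- substring(cds, 3L * (seq_len(nc) - 1L) + 1L, 3L * seq_len(nc))
    w <- rep(1, nc)
    if (!is.null(m$codon_asite)) {
      hit <- m$codon_asite[cods]
      w <- w * ifelse(is.na(hit), 1, hit)
    }
    if (!is.null(m$aa_psite)) {
      paa <- c(NA, strsplit(aas, "", fixed = TRUE)[[1]][seq_len(nc - 1L)])
      hit <- m$aa_psite[paa]
      w <- w * ifelse(is.na(hit), 1, hit)
    }
    if (!is.null(m$aa_tunnel) || !is.null(m$codon_tunnel)) {
      for (i2 in seq_len(nc)) {
        p <- i2 - 1L
        if (p < 3L) next
        lo <- max(1L, p - up)
        if (!is.null(m$aa_tunnel)) {
          reg <- substr(aas, lo, p)
          for (k in names(m$aa_tunnel))
            if (grepl(k, reg, fixed = TRUE)) w[i2] <- w[i2] * m$aa_tunnel[[k]]
        }
        if (!is.null(m$codon_tunnel)) {
          regc <- substring(cds, 3L * (lo:(p - 2L) - 1L) + 1L,
                            3L * (lo:(p - 2L) + 2L))
          for (k in names(m$codon_tunnel))
            if (k %in% regc) w[i2] <- w[i2] * m$codon_tunnel[[k]]
        }
      }
    }
    if (!is.null(m$stop_asite) && m$stop_asite != 1)
      w[nc] <- w[nc] * m$stop_asite
    unname(w)
  })
  names(out) <- transcripts$gene_id
  out
}

## The defined (length, frame) variants of each footprint family, with
## the probability structure even/odd x canonical/shifted.
.emission_variants <- function(canonical_len, canonical_frac, frame_noise) {
  long_len <- canonical_len + 1L
  data.table(
    length = c(canonical_len, canonical_len, canonical_len, long_len, long_len),
    frame = c(0L, 1L, 2L, 0L, 2L),
    prob = c(canonical_frac * (1 - frame_noise),
             canonical_frac * frame_noise / 2,
             canonical_frac * frame_noise / 2,
             (1 - canonical_frac) * (1 - frame_noise),
             (1 - canonical_frac) * frame_noise)
  )
}

#' Simulate monosome, disome and mRNA footprint libraries
#'
#' Samples (gene, A-site) positions according to expression and dwell
#' weights, then emits footprint 5'-ends by inverting the offset rules
#' so that [assign_footprints()] recovers the planted A-site codon for
#' every read.  A-sites are restricted to codons where every emitted
#' length/frame variant keeps the 5'-end inside the CDS (plus the 9-nt
#' steric exclusion when `steric = TRUE`).  mRNA reads are uniform over
#' positions with lengths 28-29.  Library depths match the config
#' exactly.
#'
#' @param transcripts transcript table (normally
#'   [generate_transcriptome()]).
#' @param config a [sim_config()].
#' @return List with footprint tables `mono`, `di`, `mrna` and `truth`
#'   (a `sim_truth` list: injected multipliers, per-gene expression
#'   weights and expected read shares, and the config).
#' @export
simulate_libraries <- function(transcripts, config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed + 1L, {
    dw <- dwell_weights(transcripts, config)
    expr <- stats::rlnorm(nrow(transcripts), 0, config$expr_sd_log)
    ngenes <- nrow(transcripts)
    ncod <- transcripts$n_codons

    di_w <- switch(config$collision_model,
                   excess = lapply(dw, function(w) 1 + (w - 1)),
                   power = lapply(dw, function(w) w^config$alpha))

    classes <- as.integer(names(config$disome_class_weights))
    ## max 0-based offset over emitted disome variants: the odd length
    ## (class + 1) in frame 2 of the largest class present
    max_off_di <- max(vapply(classes[config$disome_class_weights > 0],
                             function(cl) a_site_offset(cl + 1L, 2L),
                             integer(1)))
    min_pos5_di <- if (config$steric) 9L else 0L
    imin_di <- as.integer(ceiling((max_off_di + min_pos5_di) / 3)) + 1L
    max_off_mono <- a_site_offset(29L, 2L)   # 16
    imin_mono <- as.integer(ceiling(max_off_mono / 3)) + 1L

    sample_sites <- function(weights, imin, depth) {
      cells <- rbindlist(lapply(seq_len(ngenes), function(g) {
        if (ncod[g] < imin) return(NULL)
        i <- imin:ncod[g]
        data.table(gene = g, codon = i, weight = expr[g] * weights[[g]][i])
      }))
      pick <- sample.int(nrow(cells), depth, replace = TRUE,
                         prob = cells$weight)
      cells[pick, .(gene, codon)]
    }

    emit <- function(sites, variants) {
      v <- sample.int(nrow(variants), nrow(sites), replace = TRUE,
                      prob = variants$prob)
      len <- variants$length[v]
      frm <- variants$frame[v]
      off <- a_site_offset(len, frm)
      data.table(gene_id = transcripts$gene_id[sites$gene],
                 pos5 = 3L * (sites$codon - 1L) - off,
                 length = len, umi = NA_character_, count = 1L)
    }

    aggregate <- function(dt)
      dt[, .(count = as.integer(sum(count))),
         by = .(gene_id, pos5, length, umi)][order(gene_id, pos5, length)]

    ## disome variants: mixture over classes, then even/odd and frame
    di_variants <- rbindlist(lapply(classes, function(cl) {
      v <- .emission_variants(cl, config$canonical_length_frac,
                              config$frame_noise)
      v[, prob := prob * config$disome_class_weights[[as.character(cl)]]]
      v
    }))
    mono_variants <- .emission_variants(
      28L,
      canonical_frac = config$mono_length_weights[["28"]],
      frame_noise = config$frame_noise)

    di_sites <- sample_sites(di_w, imin_di, config$di_depth)
    di <- aggregate(emit(di_sites, di_variants))
    mono_sites <- sample_sites(dw, imin_mono, config$mono_depth)
    mono <- aggregate(emit(mono_sites, mono_variants))

    ## mRNA: gene ~ expr x length, 5'-end position uniform.  Sheared
    ## mRNA fragments are not confined to the CDS, so 5'-ends run up to
    ## pos5 = L - 17 (the largest giving a pseudo A-site inside the
    ## CDS), letting the background cover every codon up to the stop.
    mlen <- sample(c(28L, 29L), config$mrna_depth, replace = TRUE,
                   prob = config$mono_length_weights)
    g <- sample.int(ngenes, config$mrna_depth, replace = TRUE,
                    prob = expr * ncod)
    maxp <- 3L * ncod[g] - 17L
    mpos <- as.integer(floor(stats::runif(config$mrna_depth) * (maxp + 1L)))
    mrna <- aggregate(data.table(gene_id = transcripts$gene_id[g],
                                 pos5 = mpos, length = mlen,
                                 umi = NA_character_, count = 1L))

    share <- vapply(seq_len(ngenes), function(g2)
      if (ncod[g2] < imin_di) 0 else
        expr[g2] * sum(di_w[[g2]][imin_di:ncod[g2]]), numeric(1))
    truth <- structure(list(
      multipliers = config$multipliers,
      expr = stats::setNames(expr, transcripts$gene_id),
      expected_di_share = stats::setNames(share / sum(share),
                                          transcripts$gene_id),
      dwell = dw, config = config), class = "sim_truth")
    list(mono = mono, di = di, mrna = mrna, truth = truth)
  })
}

#' Simulate paired-species pause sets with known conservation
#'
#' Two species with orthologous genes of equal residue length and an
#' (optionally gapped) identity alignment; species-b pauses are placed
#' uniformly, and a configurable fraction of species-a pauses is copied
#' onto the orthologous positions of species-b pauses, the rest placed
#' uniformly elsewhere.
#'
#' @param n_genes number of ortholog pairs.
#' @param n_residues residues per protein.
#' @param pauses_per_gene pauses per gene in each species.
#' @param aligned_frac fraction of residues covered by the alignment
#'   (unaligned columns are removed at random).
#' @param copy_fraction fraction of species-a pauses copied from
#'   orthologous species-b pause positions.
#' @param seed RNG seed.
#' @return List with `pauses_a`, `pauses_b`, `maps`, `gene_lengths_b`
#'   and `truth` (the copy fraction).
#' @export
simulate_pause_conservation <- function(n_genes = 40L, n_residues = 200L,
                                        pauses_per_gene = 5L,
                                        aligned_frac = 1, copy_fraction = 0.5,
                                        seed = 1L) {
  .with_seed(seed, {
    ga <- sprintf("ya%03d", seq_len(n_genes))
    gb <- sprintf("hb%03d", seq_len(n_genes))
    maps <- rbindlist(lapply(seq_len(n_genes), function(i) {
      keep <- sort(sample.int(n_residues,
                              max(1L, round(aligned_frac * n_residues))))
      data.table(gene_a = ga[i], gene_b = gb[i], res_a = keep, res_b = keep)
    }))
    pauses_b <- rbindlist(lapply(seq_len(n_genes), function(i)
      data.table(gene_id = gb[i],
                 residue = sort(sample.int(n_residues, pauses_per_gene)))))
    pauses_a <- rbindlist(lapply(seq_len(n_genes), function(i) {
      pb <- pauses_b[gene_id == gb[i], residue]
      aligned <- maps[gene_b == gb[i], res_b]
      copyable <- intersect(pb, aligned)
      n_copy <- min(round(copy_fraction * pauses_per_gene),
                    length(copyable))
      copied <- copyable[sample.int(length(copyable), n_copy)]
      rest <- sample(setdiff(seq_len(n_residues), copied),
                     pauses_per_gene - n_copy)
      data.table(gene_id = ga[i], residue = sort(c(copied, rest)))
    }))
    list(pauses_a = pauses_a, pauses_b = pauses_b, maps = maps,
         gene_lengths_b = data.table(gene_id = gb,
                                     n_residues = n_residues),
         truth = list(copy_fraction = copy_fraction))
  })
}
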