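test_that("motif-anchored profiles peak at the class-specific offsets", {
  ## plant His-codon pauses; 58-nt disome 5'-ends peak 45 nt upstream,
  ## 28-nt monosome 5'-ends 15 nt upstream
  cfg <- sim_config(n_genes = 10, di_depth = 2e4, mono_depth = 2e4,
                    mrna_depth = 1000, seed = 9, frame_noise = 0,
                    canonical_length_frac = 1,
                    disome_class_weights = c(`53` = 0, `58` = 1, `61` = 0),
                    mono_length_weights = c(`28` = 1, `29` = 0),
                    multipliers = list(codon_asite = c(CAC = 40, CAT = 40)))
  tx <- generate_transcriptome(cfg)
  sim <- simulate_libraries(tx, cfg)
  di <- motif_anchored_profile(sim$di, tx, c("CAC", "CAT"), c(-60L, 10L))
  expect_equal(di[which.max(value), offset], -45L)
  mono <- motif_anchored_profile(sim$mono, tx, c("CAC", "CAT"), c(-30L, 10L))
  expect_equal(mono[which.max(value), offset], -15L)
  ## 30-nt spacing between the two peaks: one in-frame ribosome
  expect_equal(di[which.max(value), offset] - mono[which.max(value), offset],
               -30L)
})

test_that("uniform coverage gives a flat profile and profiles are linear", {
  ## mRNA fragments: 5'-ends uniform over positions and frames
  cfg <- sim_config(n_genes = 10, di_depth = 1000, mono_depth = 1000,
                    mrna_depth = 1e5, seed = 10)
  tx <- generate_transcriptome(cfg)
  sim <- simulate_libraries(tx, cfg)
  prof <- motif_anchored_profile(sim$mrna, tx, c("CAC", "CAT"), c(-30L, 0L))
  expect_lt(max(prof$value) / min(prof$value), 1.3)
  ## linearity: profile of a split library sums to the whole
  half1 <- sim$di[seq(1, .N, by = 2)]
  half2 <- sim$di[seq(2, .N, by = 2)]
  w <- c(-20L, 20L)
  p_all <- motif_anchored_profile(sim$di, tx, "CAC", w)
  p1 <- motif_anchored_profile(half1, tx, "CAC", w)
  p2 <- motif_anchored_profile(half2, tx, "CAC", w)
  ## un-normalize RPM (per-library totals differ), compare raw sums
  raw <- function(p, tot) p$value * tot / 1e6
  expect_equal(raw(p_all, sum(sim$di$count)),
               raw(p1, sum(half1$count)) + raw(p2, sum(half2$count)),
               tolerance = 1e-9)
})

test_that("normalized CDS profile detects terminal enrichment", {
  cfg <- sim_config(n_genes = 12, di_depth = 3e4, mono_depth = 1000,
                    mrna_depth = 1000, seed = 11,
                    multipliers = list(stop_asite = 12))
  tx <- generate_transcriptome(cfg)
  sim <- simulate_libraries(tx, cfg)
  prof <- normalized_cds_profile(assign_footprints(sim$di, tx), tx,
                                 n_bins = 25L)
  expect_equal(which.max(prof$value), 25L)
  ## flat without the stop multiplier
  cfg0 <- sim_config(n_genes = 12, di_depth = 3e4, mono_depth = 1000,
                     mrna_depth = 1000, seed = 11)
  sim0 <- simulate_libraries(tx, cfg0)
  prof0 <- normalized_cds_profile(assign_footprints(sim0$di, tx), tx,
                                  n_bins = 25L)
  ## the first bins are depleted: disome leading A-sites cannot sit in
  ## the 5'-terminal codons
  inner <- prof0[bin > 4]
  expect_lt(max(inner$value), 1.3)
  expect_gt(min(inner$value), 0.7)
})

test_that("first-half concentration doubles the first-half bin mass", {
  tx <- transcript_set("g", paste0("ATG", strrep("GCT", 97), "TAA"))
  recs <- data.table::rbindlist(lapply(seq(20, 45), function(cd)
    plant("g", cd, 58)))
  prof <- normalized_cds_profile(assign_footprints(recs, tx), tx,
                                 n_bins = 10L)
  expect_equal(sum(prof$value[1:5]), 10, tolerance = 1e-9)
  expect_equal(sum(prof$value[6:10]), 0)
})

test_that("start-proximal occupancy reflects the steric exclusion", {
  cfg <- sim_config(n_genes = 10, di_depth = 2e4, mono_depth = 1000,
                    mrna_depth = 1000, seed = 12, steric = TRUE)
  tx <- generate_transcriptome(cfg)
  sim <- simulate_libraries(tx, cfg)
  occ <- start_proximal_occupancy(sim$di, tx, n_nt = 60L)
  expect_true(all(occ[position <= 9, density] == 0))
  expect_gte(attr(occ, "first_nonzero"), 10L)
  ## without the constraint 5'-ends reach the first positions
  cfg0 <- sim_config(n_genes = 10, di_depth = 2e4, mono_depth = 1000,
                     mrna_depth = 1000, seed = 12, steric = FALSE)
  sim0 <- simulate_libraries(tx, cfg0)
  occ0 <- start_proximal_occupancy(sim0$di, tx, n_nt = 60L)
  expect_lt(attr(occ0, "first_nonzero"), 10L)
})

test_that("pause calling applies the strict gene-mean threshold", {
  tx <- transcript_set("g", "ATGGCTTAA")   # 3 codons
  ## counts (0, 0, 10): mean 10/3, only codon 3 qualifies
  pz <- call_pauses(assign_footprints(plant("g", 3, 28, count = 10L), tx), tx)
  expect_equal(pz$codon, 3L)
  expect_equal(pz$abundance, 10L)
  ## uniform counts over every codon never exceed the mean
  tx2 <- transcript_set("g", paste0("ATG", strrep("GCT", 28), "TAA"))
  asg <- data.table(gene_id = "g", a_site_codon = 1:30, count = 2L)
  expect_equal(nrow(call_pauses(asg, tx2)), 0L)
  ## all-zero gene: empty
  expect_equal(nrow(call_pauses(asg[0], tx2)), 0L)
  ## partial uniform coverage: sites above the zero-inclusive mean
  part <- assign_footprints(
    data.table::rbindlist(lapply(7:30, function(cd) plant("g", cd, 28))),
    tx2)
  pz <- call_pauses(part, tx2)
  expect_equal(nrow(pz), 24L)   # mean 24/30 < 1, every covered site
  expect_true(all(pz$abundance > 0))
  expect_lte(nrow(pz), nrow(unique(part[, .(gene_id, a_site_codon)])))
})

test_that("pause overlap partitions shared and unique sites", {
  m <- data.table(gene_id = c("g1", "g1", "g2"), codon = c(5L, 9L, 3L))
  d <- data.table(gene_id = c("g1", "g2", "g2"), codon = c(5L, 3L, 8L))
  expect_equal(pause_overlap(m, d),
               c(mono_only = 1L, shared = 2L, di_only = 1L))
  expect_equal(unname(pause_overlap(m, m)), c(0L, 3L, 0L))
  disjoint <- data.table(gene_id = "g9", codon = 1L)
  expect_equal(unname(pause_overlap(m, disjoint)[["shared"]]), 0L)
})

test_that("planted pause overlap matches its construction fraction", {
  set.seed(33)
  genes <- sprintf("g%02d", 1:30)
  mono <- data.table(gene_id = rep(genes, each = 10),
                     codon = as.integer(rep(seq(10, 100, by = 10), 30)))
  ## disome pauses: half copied from monosome pauses, half elsewhere
  pick <- sample(nrow(mono), 150)
  di <- rbind(mono[pick],
              data.table(gene_id = rep(genes, each = 5),
                         codon = as.integer(rep(103:107, 30))))
  ov <- pause_overlap(mono, di)
  frac <- ov[["shared"]] / (ov[["shared"]] + ov[["di_only"]])
  expect_equal(frac, 0.5, tolerance = 0.1)
})

test_that("density correlation tracks coupling between libraries", {
  tx <- transcript_set(sprintf("g%02d", 1:20),
                       rep(paste0("ATG", strrep("GCT", 60), "TAA"), 20))
  mrna <- data.table(gene_id = tx$gene_id, pos5 = 0L, length = 28L,
                     umi = NA_character_, count = 50L)
  mono_counts <- as.integer(round(seq(10, 200, length.out = 20)))
  mono <- data.table(gene_id = tx$gene_id, pos5 = 30L, length = 28L,
                     umi = NA_character_, count = mono_counts)
  di_prop <- data.table(gene_id = tx$gene_id, pos5 = 30L, length = 58L,
                        umi = NA_character_, count = mono_counts * 2L)
  res <- density_correlation(mono, di_prop, mrna, tx)
  expect_equal(res$rho, 1)
  expect_equal(res$n, 20L)
  ## anti-proportional collision load flips the sign
  di_anti <- data.table::copy(di_prop)[, count := rev(count)]
  expect_equal(density_correlation(mono, di_anti, mrna, tx)$rho, -1)
})
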