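test_that("mRNA pseudo-assignment mirrors the monosome offset rules", {
  tx <- tiny_transcripts()
  rec <- rbind(fp("g2", 0, 28),   # pseudo A-site codon (0+15)/3+1 = 6
               fp("g2", 0, 30),   # not 28-29 nt: excluded
               fp("g2", 3, 28))
  ps <- mrna_pseudo_assign(rec, tx)
  expect_equal(nrow(ps), 2L)
  expect_equal(ps$a_site_codon, c(6L, 7L))
  ## identical to assign_footprints on the same 28-29 nt records
  direct <- assign_footprints(rec[length %in% c(28, 29)], tx)
  expect_equal(as.data.frame(ps), as.data.frame(direct))
})

test_that("single-gene A-site score reduces to the plain odds ratio", {
  tx <- transcript_set("g", paste0("ATG", strrep("GAA", 50),
                                   strrep("GCT", 50), "TAA"))
  ## fg: 20 reads on a GAA codon, 80 elsewhere; bg: 10 vs 90
  fg <- rbind(plant("g", 10, 58, count = 20L),
              plant("g", 60, 58, count = 80L))
  bg <- rbind(plant("g", 12, 28, count = 10L),
              plant("g", 70, 28, count = 90L))
  sc <- asite_codon_scores(assign_footprints(fg, tx),
                           assign_footprints(bg, tx), tx)
  expect_equal(sc[feature == "GAA", score], 2.25)
  expect_equal(sc[feature == "GCT", score], 1 / 2.25)
  expect_equal(sc[feature == "GAA", n_strata], 1L)
  ## features absent from the data come back NaN
  expect_true(is.nan(sc[feature == "TTT", score]))
})

test_that("self-background identity: fg == bg gives score 1 everywhere", {
  cfg <- sim_config(n_genes = 8, di_depth = 4000, mono_depth = 1000,
                    mrna_depth = 1000, seed = 3)
  tx <- generate_transcriptome(cfg)
  asg <- assign_footprints(simulate_libraries(tx, cfg)$di, tx)
  for (scores in list(asite_codon_scores(asg, asg, tx),
                      psite_aa_scores(asg, asg, tx))) {
    seen <- scores[!is.nan(score)]
    expect_true(all(abs(seen$score - 1) < 1e-12))
  }
  kt <- tunnel_kmer_scores(collapse_positions(asg),
                           collapse_positions(asg), tx)
  expect_true(all(abs(kt[!is.nan(score), score] - 1) < 1e-12))
})

test_that("swapping foreground and background inverts every score", {
  cfg <- sim_config(n_genes = 6, di_depth = 3000, mono_depth = 3000,
                    mrna_depth = 3000, seed = 5)
  tx <- generate_transcriptome(cfg)
  sim <- simulate_libraries(tx, cfg)
  fg <- assign_footprints(sim$di, tx)
  bg <- mrna_pseudo_assign(sim$mrna, tx)
  ab <- asite_codon_scores(fg, bg, tx)
  ba <- asite_codon_scores(bg, fg, tx)
  both <- merge(ab[is.finite(score) & score > 0],
                ba[is.finite(score) & score > 0], by = "feature")
  expect_gt(nrow(both), 30)
  expect_equal(both$score.x, 1 / both$score.y, tolerance = 1e-9)
})

test_that("injected dwell multipliers are recovered across sites", {
  ## P-site proline enrichment
  cfg <- sim_config(n_genes = 15, di_depth = 5e4, mrna_depth = 1e5,
                    mono_depth = 1000, seed = 21, frame_noise = 0.1,
                    multipliers = list(aa_psite = c(P = 5)))
  tx <- generate_transcriptome(cfg)
  sim <- simulate_libraries(tx, cfg)
  ps <- psite_aa_scores(assign_footprints(sim$di, tx),
                        mrna_pseudo_assign(sim$mrna, tx), tx)
  expect_equal(ps[feature == "P", score], 5, tolerance = 0.2)
  expect_lt(ps[feature == "P", q], 0.01)
  others <- ps[feature != "P" & !is.nan(score), score]
  expect_true(all(others > 0.7 & others < 1.35))

  ## exit-tunnel triple-lysine enrichment.  Lysine-rich codon usage
  ## makes KKK common enough to measure; read depth is kept well below
  ## the number of codon positions so that the position collapse
  ## (hitchhiking control) does not saturate the signal away.
  cw <- setNames(rep(1, 61), ribocollide:::.sense_codons())
  cw["AAG"] <- 3   # lysine common enough to measure, rare enough that
                   # boosted sites stay a small share of all windows
  cfg2 <- sim_config(n_genes = 40, di_depth = 12000, mrna_depth = 1.2e5,
                     mono_depth = 1000, seed = 22, codon_weights = cw,
                     multipliers = list(aa_tunnel = c(KKK = 8)))
  tx2 <- generate_transcriptome(cfg2)
  sim2 <- simulate_libraries(tx2, cfg2)
  fg2 <- assign_footprints(sim2$di, tx2)
  bg2 <- mrna_pseudo_assign(sim2$mrna, tx2)
  ## uncollapsed reads recover the multiplier up to the window-count
  ## attenuation (boosted sites also inflate the non-KKK window cell)
  kt_raw <- tunnel_kmer_scores(fg2, bg2, tx2)
  expect_equal(kt_raw[feature == "KKK", score], 8, tolerance = 0.3)
  expect_lt(kt_raw[feature == "KKK", q], 1e-6)
  ## collapsed (hitchhiking-controlled) scores keep KKK on top
  kt <- tunnel_kmer_scores(collapse_positions(fg2), bg2, tx2)
  ranked <- kt[is.finite(score) & n_strata >= 3][order(-score)]
  expect_equal(ranked$feature[1], "KKK")
  expect_gt(kt[feature == "KKK", score], 1.3)
})

test_that("tunnel windows enumerate the sliding 3-mers of the region", {
  ## gene: M then 30 K, P-site at codon 25 -> region codons 4..25 (22
  ## residues is clipped to 21: 5..25), all K -> 19 KKK windows
  tx <- transcript_set("g", paste0("ATG", strrep("AAG", 30), "TAA"))
  site <- plant("g", 26, 58)
  w <- tunnel_windows(assign_footprints(site, tx), tx, level = "aa")
  expect_equal(w[feature == "KKK", n], 19L)
  ## strict 20-residue region drops one window
  w20 <- tunnel_windows(assign_footprints(site, tx), tx, level = "aa",
                        include_psite = FALSE)
  expect_equal(w20[feature == "KKK", n], 18L)
  ## near the start the window truncates instead of vanishing
  early <- plant("g", 6, 28)   # P-site codon 5, region 1..5: MKKKK
  we <- tunnel_windows(assign_footprints(early, tx), tx, level = "aa")
  expect_equal(we[, sum(n)], 3L)
  expect_equal(we[feature == "MKK", n], 1L)
  expect_equal(we[feature == "KKK", n], 2L)
  ## codon-level windows distinguish synonymous triplets
  wc <- tunnel_windows(assign_footprints(site, tx), tx, level = "codon")
  expect_equal(wc[feature == "AAGAAGAAG", n], 19L)
})

test_that("codon-level tunnel scores separate synonymous lysine runs", {
  ## two genes: one AAG-run, one AAA-run; pauses planted only after the
  ## AAG run
  tx <- transcript_set(c("gA", "gB"),
                       c(paste0("ATG", strrep("GCT", 30), strrep("AAG", 6),
                                strrep("GCT", 30), "TAA"),
                         paste0("ATG", strrep("GCT", 30), strrep("AAA", 6),
                                strrep("GCT", 30), "TAA")))
  ## gA pause just downstream of its AAG run (in the tunnel); gB pause
  ## far from its AAA run
  fg <- rbind(plant("gA", 40, 58, count = 30L),
              plant("gB", 65, 58, count = 30L))
  bg <- data.table::rbindlist(lapply(c("gA", "gB"), function(g)
    data.table::rbindlist(lapply(seq(8, 65, by = 2), function(cd)
      plant(g, cd, 28)))))
  res <- tunnel_codon_kmer_scores(collapse_positions(assign_footprints(fg, tx)),
                                  assign_footprints(bg, tx), tx)
  aag <- res[feature == "AAGAAGAAG"]
  aaa <- res[feature == "AAAAAAAAA"]
  expect_gt(aag$score, 1)
  expect_true(is.nan(aaa$score) || aaa$score < aag$score)
  expect_true(all(res$bg_freq >= 0) && abs(sum(res$bg_freq) - 1) < 1e-9)
  ## while the amino-acid-level operation merges them
  resaa <- tunnel_kmer_scores(collapse_positions(assign_footprints(fg, tx)),
                              assign_footprints(bg, tx), tx)
  expect_gt(resaa[feature == "KKK", score], 1)
})

test_that("composition background counts features per gene", {
  tx <- tiny_transcripts()
  cb <- composition_background(tx, level = "codon")
  expect_equal(cb[gene_id == "g1" & feature == "AAA", n], 1L)
  expect_equal(cb[gene_id == "g1", sum(n)], 3L)
  aab <- composition_background(tx, level = "aa")
  expect_equal(aab[gene_id == "g1", sum(n)], 2L)   # stop excluded
  expect_equal(aab[gene_id == "g2" & feature == "E", n], 30L)
  km <- composition_background(tx, level = "kmer")
  expect_equal(km[gene_id == "g2" & feature == "EEE", n], 28L)
  ## composition and mRNA backgrounds recover the same score spectrum
  ## when dwell times vary across codons
  cfg <- sim_config(n_genes = 12, di_depth = 4e4, mrna_depth = 8e4,
                    mono_depth = 1000, seed = 31,
                    multipliers = list(codon_asite = c(GAA = 5, CCG = 3,
                                                       TTT = 2)))
  tx2 <- generate_transcriptome(cfg)
  sim <- simulate_libraries(tx2, cfg)
  asg <- assign_footprints(sim$di, tx2)
  s_mrna <- asite_codon_scores(asg, mrna_pseudo_assign(sim$mrna, tx2), tx2)
  s_comp <- asite_codon_scores(asg, composition_background(tx2, "codon"), tx2)
  both <- merge(s_mrna, s_comp, by = "feature")
  both <- both[is.finite(score.x) & is.finite(score.y)]
  expect_gt(cor(both$score.x, both$score.y, method = "spearman"), 0.6)
  expect_equal(both[feature == "GAA", score.y], 5, tolerance = 0.25)
})
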