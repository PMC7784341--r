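---
title: "Quantifying ribosome collisions from disome footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ribosome collisions from disome footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocollide)
library(data.table)
```

## The measurement

When a translating ribosome pauses, the next ribosome in line can run
into it.  The collided pair protects a single RNase-I-resistant mRNA
fragment roughly twice the length of a single ribosome footprint.
Disome-seq sequences those fragments; this package turns the aligned
footprints into codon-resolution collision maps and into per-feature
*pausing scores*.

The footprint length itself reports the conformation of the pair.  With
an occupied A-site a yeast ribosome protects ~28 nt, with an open A-site
~23 nt, and the collided pair sits either 2 nt or 5 nt (one extra codon)
apart.  That decomposes the observed disome classes:

* 28 + 2 + 28 = **58 nt** — leading A-site occupied, tight stack;
* 28 + 5 + 28 = **61 nt** — one extra codon between the ribosomes;
* 28 + 2 + 23 = **53 nt** — leading A-site open (e.g. waiting for a
  ternary complex or a release factor).

Each class also appears one nucleotide longer (29/54/59/62 nt) when
RNase trimming leaves a remnant nucleotide.  `geometry_model()` holds
these constants and derives the downstream quantities (the 11-nt minimum
inter-ribosome distance at initiation, the three elongation moves needed
to collide from it, and the ~75-nt trisome 5'-end offset upstream of
stop codons).

## A-site assignment

All downstream analyses hinge on placing the A-site of the *leading*
(paused) ribosome from the fragment 5'-end.  For an in-frame 58-nt
fragment the A-site occupies nucleotides 46–48; reads in frames +1/+2
shift by ∓1 nt (nts 45–47 / 47–49), because the 5'-end moved during
digestion while the ribosome did not.  The 53/54-nt classes share the
58/59-nt rule (they are 3'-trimmed), the 61/62-nt classes add one codon
(+3 nt), and 28/29-nt monosome footprints subtract one ribosome
(−30 nt), giving the familiar monosome A-site at nts 16–18.  The
odd-length frame-1 combination is geometrically ambiguous; those reads
are dropped rather than guessed (`a_site_offset()` returns `NA`).

```{r offsets}
rbind(mono_28 = a_site_offset(28, 0:2),
      di_58   = a_site_offset(58, 0:2),
      di_61   = a_site_offset(61, 0:2))
```

`assign_footprints()` applies these rules, records the length class and
frame, and reports dropped reads.  Because every defined offset is
congruent to `-frame (mod 3)`, the A-site codon index is always exact.

## Pausing scores

The pausing score of a sequence feature is a gene-stratified
Mantel-Haenszel common odds ratio.  For each gene a 2×2 table counts
foreground reads with/without the feature at the site of interest
against background reads split the same way, and the common odds ratio
across genes

$$\widehat{OR}_{MH} = \frac{\sum_g a_g d_g / n_g}{\sum_g b_g c_g / n_g}$$

is the score; the P value comes from the Mantel-Haenszel chi-squared
test with a 0.5 continuity correction.  Stratifying by gene controls
for expression and composition differences between genes; the
background (28–29 nt mRNA-seq fragments pushed through the *same*
monosome offset rules, or optionally the gene's own codon/amino-acid
composition via `composition_background()`) controls for library
biases and within-gene composition.

Three sites are scored:

* **A-site codons** (64 features, `asite_codon_scores()`): slow
  decoding; stop codons score the release step.
* **P-site amino acids** (20 features, `psite_aa_scores()`): slow
  peptide-bond formation (proline, glycine, ...).
* **Exit-tunnel 3-mers** (8000 amino-acid 3-mers,
  `tunnel_kmer_scores()`; codon triplets via
  `tunnel_codon_kmer_scores()`): interactions of the nascent peptide
  with the tunnel, e.g. polylysine.  A 3-residue window slides across
  the region made of the P-site residue plus the 20 residues upstream
  (21 residues, 19 windows); window counts are summed per gene.

Design choices worth knowing:

* *Zero strata.*  Genes with no foreground or no background reads carry
  no ratio information and are dropped from both the estimator and the
  test.  No continuity correction enters the estimator itself, so a
  score of, say, 2 really is "twice the odds".
* *Region definition.*  The tunnel region includes the P-site residue
  (21 residues); `include_psite = FALSE` gives the strict 20-residue
  variant.  Sites within the first 21 codons contribute their truncated
  windows rather than being excluded, which keeps counts and avoids a
  5'-bias in short genes.
* *Hitchhiking.*  Many reads stacked at one strong pause would inflate
  every 3-mer in that window.  `collapse_positions()` keeps one read
  per (gene, A-site codon, length class) before tunnel scoring.  This
  control has a cost: when read depth approaches the number of codon
  positions, collapsing saturates and attenuates true enrichments, so
  tunnel scores are best read as rankings at high depth.  Window-based
  scores are also intrinsically attenuated when the feature is common,
  because boosted sites contribute to the "other windows" cell as well.
* *Multiple testing.*  `qvalues()` defaults to Benjamini-Hochberg; a
  Storey-type mode (`method = "storey"`, lambda grid 0.05–0.95 with a
  smoothing spline for $\pi_0$) is provided and flagged in the result.
* *Length classes.*  The 58/59 and 61/62 classes are pooled by default
  for scoring (their pausing signals are nearly identical); the 53/54
  class can be scored separately since it reflects an open A-site.

## Metagene analyses and pause calling

`motif_anchored_profile()` aggregates footprint 5'-end RPM around
anchor codons; with pauses planted on histidine codons the disome
profile peaks 45 nt upstream and the monosome profile 15 nt upstream —
30 nt apart, exactly one stacked in-frame ribosome.
`normalized_cds_profile()` bins leading A-sites along the
length-normalized CDS after scaling each gene to mean 1; rising density
toward the 3'-end (the "inverse ramp") and a terminal spike are the
signatures of initiation-side steric exclusion and slow termination.
`start_proximal_occupancy()` inspects the first nucleotides of the ORF,
where the steric model predicts no disome 5'-end before nt 10.

`call_pauses()` marks codon sites whose footprint abundance strictly
exceeds the gene mean, with the mean taken over *all* codon positions
including zeros — the conservative reading of a per-gene mean.
`pause_overlap()` intersects monosome- and disome-derived pauses by
(gene, codon), and `density_correlation()` relates per-gene monosome
density and collision frequency (both per mRNA per unit CDS length,
genes without mRNA reads excluded) by Spearman correlation.

## Cross-species conservation

`project_pauses()` carries species-b pauses through an ortholog
alignment into species-a residue coordinates; `pause_distance()` takes
per-pause nearest distances (d = 0 means the collision sits at the
orthologous residue).  `permutation_null()` keeps each gene's pause
count fixed, redraws positions uniformly without replacement, and
reports the empirical P value with the add-one convention
`(1 + #(null ≥ obs)) / (1 + n_perm)`, which can never return zero —
consistent with reporting "P < 1/n_perm" at full depth.  Pauses in
genes lacking an ortholog map are excluded from the denominator;
pauses whose ortholog simply has no pause count as non-conserved.

## Secondary structure and nascent-chain peptides

`preprocess_helices()` first concatenates abutting helix annotations,
then removes helices of ≤ 4 residues; concatenation must precede
filtering or real long helices split by annotation artifacts would be
lost.  `aa_gap_helix_ratio()` tallies every residue of annotated
proteins into helix or gap, and `regress_score_vs_feature()` relates
P-site pausing scores to the gap:helix ratio or to helix-termination
propensities (ΔΔG), with a KS normality check on the residuals.

`tryptic_digest()` implements trypsin/P (cleave after every K/R, no
proline exception, zero missed cleavages) and
`peptide_half_enrichment()` asks whether observed MS peptides
concentrate in protein N-terminal halves — the signature of nascent
chains — against the theoretical digest, using the same MH engine.
The half boundary is `floor(n/2)`; the middle residue of an odd-length
protein counts as second half.

## The simulator and what passing tests mean

`sim_config()` / `generate_transcriptome()` / `simulate_libraries()`
produce a random transcriptome (ATG first, stop last, codon usage
configurable) and monosome/disome/mRNA libraries with known per-codon
dwell structure.  Dwell weights multiply per applicable feature (codon
at the A-site, amino acid at the P-site, 3-mer in the tunnel region,
stop at the A-site).  Disome emission uses an "excess" model by
default — a unit baseline of stochastic collisions plus the
pause-induced excess, giving emission weight `1 + (dwell − 1)` — so an
injected multiplier *m* is recovered as an odds ratio of ≈ *m* against
the uniform mRNA background, which is what makes recovery tests
interpretable; a `dwell^alpha` model is available for stress tests.
Footprints are emitted by inverting the offset rules (all five
length-class variants, frame noise included), so re-assignment recovers
every planted A-site exactly; library depths are exact.

Default conditions mirror the rich-medium libraries: disome class
mixture 10.9% / 40% / 49.1% (53/58/61 nt, the 61-nt class most
abundant), 28-nt-dominant monosomes, 70% canonical lengths, 10% frame
noise, log-normal expression (sd(log) = 1) and CDS lengths around 350
codons.  A-site positions are sampled only where every emitted variant
keeps the 5'-end inside the CDS, so the first ~17 codons of each gene
carry no disome signal (and `steric = TRUE` additionally excludes
5'-ends before nt 10); profile analyses should ignore those bins.
mRNA 5'-ends run to `L − 17` so the pseudo-site background covers every
codon up to and including the stop.

The simulator emulates dwell-time structure, not sequencing chemistry:
no ligation or amplification bias, no sequence errors, no UMI
structure, no 3-nt periodicity artifacts beyond frame noise, and
collisions are emitted independently per read rather than from an
explicit multi-ribosome traffic process.  Passing recovery tests
therefore validates the *inference machinery* — offsets, counting,
stratified estimation — not robustness to real-library artifacts.

Numerical conventions used throughout: `pos5` is 0-based within the
CDS, codon/residue indices are 1-based; report writers emit 1-based
positions.  Monosome-matched downsampling rounds half away from zero
(`downsample_count(589461, 32.6)` = 18082) and samples unit reads
without replacement, respecting count multiplicity.  Problem sizes in
the test suite (10–60 genes, 10³–10⁵ reads, 199 permutations × 200
trials) were chosen so each statistical check has adequate resolution
at interactive runtimes.

## Known limitations

* Footprint tables must already be CDS-aligned; genome alignment, GFF
  and BAM ingestion are out of scope (adapters welcome).
* Offset rules are fixed, not learned from data; species with other
  footprint geometries need a different rule table.
* The MH test is asymptotic; with very few informative strata an exact
  conditional test would be preferable and is not provided.
* `disome_fraction()` and the geometry arithmetic are closed-form
  bookkeeping, not a traffic model; no TASEP-style dynamics are
  implied.
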