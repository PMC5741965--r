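---
title: "Segmenting inbred genomes into High Variability Regions and prioritising them by regulatory conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HVR methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Two inbred strains derived from a common stock share most of their genome
identical by descent. Variants called against a common reference therefore
cluster: long stretches carry almost none that are strain-specific, and the
divergent haplotype blocks carry many. `hvrscan` formalises this as a
two-state segmentation of 10 kb windows driven by the density of
*strain-specific variants* (SSVs).

**SSV definition.** Against the reference alone, an SSV is any position
where the query carries an allele different from the reference base.
Against a control strain, the baseline becomes the union of the reference
base and the control's called alleles at that position (a position the
control does not mention is treated as reference-like). Subtracting the
control removes the variation the two phenotypically different strains
share, which by assumption cannot explain their difference. Heterozygous
calls are retained; only A/C/G/T alleles are considered (indels and
symbolic alleles are skipped with a warning).

**Smoothing.** Raw 10 kb window counts `n_x` are noisy at block edges and
inside blocks. The pipeline uses a triangular floating mean with
half-width `k` (default 3):

$$s_x = \frac{\sum_{i=-k}^{k} n_{x+i}\,(k-|i|)}{\sum_{i=-k}^{k} (k-|i|)}$$

The denominator is fixed at `k^2` (9 for k = 3) everywhere, with windows
beyond the chromosome ends contributing zero. Two consequences worth
knowing: a constant interior track is a fixed point, and total mass is
conserved on any track whose terminal `k` windows are zero (edge windows
otherwise leak mass into the padding — we follow the printed formula rather
than renormalising at the edges). The weight at `|i| = k` is zero, so the
kernel effectively spans `2k - 1` windows.

**Threshold.** Genome-wide, the smoothed density is bimodal: a large
low-density mode (IBD segments) and a high-density mode (divergent blocks).
The threshold is the centre of the lowest-count histogram bin strictly
between the two largest local maxima of the binned distribution (unit-width
bins by default, configurable). When no two separated maxima exist, a
fallback override is returned; its default of 3 variants / 10 kb is the
value the method's source analyses obtained in all three strain-versus-
reference comparisons. Windows with `s_x > t` are HVR-like, `s_x <= t`
LVR-like (the boundary value is LVR-like: "greater than" is strict). Only
maximal runs of at least 3 same-label windows become regions; unmappable
windows (mean MAPQ <= 30 and/or mean coverage >= 100, again in runs of
>= 3) are excluded and break runs.

**Conservation Enrichment.** A rat peak of a transcription factor is
*conserved* when it overlaps (>= 1 bp) a same-factor peak of at least one
comparison species, all in rat coordinates (projection is out of scope —
comparison peaks arrive pre-projected). Each HVR gets a per-factor CE
score. The method's source defines CE in two incompatible ways — conserved
peaks per 10 kb of HVR (its Methods) and the conserved fraction of
overlapping peaks (its Results). Both are implemented
(`mode = "density_per_10kb"` (default) and `mode = "fraction"`); the
discrepancy is deliberately preserved as configuration rather than silently
resolved. Subsets are nested by construction: `ALL` ⊇ `W_TFBS` ⊇ `CE>0` ⊇
… ⊇ `CE>0.8`, and `NTF>=1` ⊇ `NTF>=2` ⊇ `NTF>=3` (an HVR enters `CE>t`
when *any* factor's CE exceeds `t`, and `NTF>=m` when at least `m`
distinct factors have a conserved peak in it).

**Permutation test.** HVRs cluster along chromosomes, and nearby HVRs are
not independent. The null model therefore relocates *clusters* (HVRs merged
single-linkage within 1 Mb) as rigid units: a chromosome is drawn with
probability proportional to its length among chromosomes long enough to
hold the cluster span, the start is uniform over valid positions, and
member offsets are preserved. Relocated clusters may overlap each other and
may land anywhere, including unmappable regions — the source's shuffling
stated no exclusions, so none are applied by default (an exclusion mask is
available and off by default). Significance is the two-tailed empirical

$$p = \frac{\mathrm{card}\left(|EV - \overline{EV}| \ge |OV - \overline{EV}|\right) + 1}{N + 1}$$

applied exactly as printed (centred on the mean of the null sample, no
continuity correction), with floor `1/(N+1)` — `1e-4` at the default
N = 10,000. All placement randomness is drawn up front from one seeded
stream, so the null sample is independent of evaluation order and
reproducible.

**Gene-level interpretation.** Expressed genes are those with FPKM
strictly > 1. A promoter is assigned to a gene when the TSS overlaps the
promoter or lies within 5 kb downstream of its 3' end *in the gene's
orientation* (the source is silent on strandedness; the gene-centric
reading is the biologically standard one, and `stranded = FALSE` restores
the symmetric rule); any promoter near several TSSs, or gene near several
promoters, is discarded entirely (one-to-one rule). Coding consequences
come from a minimal codon-table classifier over the standard genetic code:
the novel allele is substituted at the transcript-oriented CDS position and
the affected codon retranslated; severity is
stop_gained = stop_lost > missense > synonymous > non_coding, most severe
across transcripts. This replaces a full consequence predictor and ignores
splice, UTR and regulatory terms by design. Disease enrichment is a 2x2
Fisher's exact test of candidate versus background genes (both mapped
through one-to-one orthology); the source does not state sidedness, so the
two-sided p is the headline number and the one-sided enrichment p is
reported alongside. The odds ratio reported is the sample cross-product
`ad/bc`, flagged when degenerate.

## The synthetic world

`simulation_config()` defaults describe the world the acceptance suite
runs on; they were chosen once, before any acceptance run, and are not
tuned:

* 5 chromosomes x 10 Mb, 10 kb windows (5,000 windows), matching the
  stated desk-scale genome.
* Candidate high blocks: window-aligned, length 5 + Geometric (mean 10
  windows ~ 100 kb, the average HVR size implied by the source's 232 Mb /
  2319 HVRs), separated by gaps of 20 + Geometric (mean 90 windows), i.e.
  ~10% of the genome in blocks versus the source's 7–8.5%. The 5-window
  floor keeps every planted block comfortably above the 3-window run rule,
  so ground-truth recovery is exact rather than ambiguous at edges.
* Four strains — three queries and one control — each carrying a candidate
  block with probability 0.6, independently; member strains share one
  block-variant draw (identity by descent), which is what makes
  query-versus-control subtraction meaningful.
* Per-window SSV counts: Poisson, `lambda_high = 15` inside a strain's
  blocks and `lambda_low = 0.5` elsewhere. The source does not state the
  within-HVR count distribution; Poisson is an assumption, noted as such.
  Its in-HVR density (~15/10 kb from Table-level numbers) fixes
  `lambda_high`. 5% of variants are emitted heterozygous (the source kept
  its ~5% het calls). The reference base is a deterministic function of
  position, so independently drawn variants at one site always agree.
* Peaks: Poisson mean 5 per factor per block, widths 200–600 bp, conserved
  with a per-block probability (default cycling 0.1–0.9 so CE subsets are
  non-trivial); conserved peaks are emitted identically in 1–2 comparison
  species. Background peaks (1/Mb, 50% conserved) land outside blocks.
  Comparison species carry *only* the conserved rat peaks — species-private
  peaks would be inert to the conservation annotation, so they are not
  simulated.
* Unmappable stretches: ~2% of windows in runs of 3–6, planted disjoint
  from candidate blocks so recovery scoring is unambiguous; their
  MAPQ/coverage tracks trip the <= 30 / >= 100 criteria in mixed modes.
* Expression: log-normal FPKM (meanlog 0.7, sdlog 1.5, ~65% of genes above
  the FPKM > 1 cutoff); 10% of genes flagged DE, half drawn from genes
  overlapping the strain's private blocks. GWAS points: 50% inside blocks.
  Disease map: background rate 0.11 (the source's obesity background,
  425/3865), planted odds ratio 2.5 on genes overlapping the first query's
  private blocks.

What the generator does **not** emulate: linkage and mutation-spectrum
structure within blocks, read-level artefacts (no FASTQ/BAM), overlapping
gene models' shared genomic sequence (each gene carries its own CDS
sequence in the model table — an extension of the gene TSV that avoids
shipping a genome FASTA), species-private peaks, and any real rat
coordinates. A green test therefore establishes that the *algorithms*
recover what was planted under the stated statistical structure — not that
the biological conclusions of any particular study reproduce.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; VCF positions are 1-based
  and converted at the I/O boundary. A 1-based position `p` belongs to
  window `floor((p-1)/w)`, so position 10,000 is the last base of the first
  10 kb window.
* The short terminal window counts as a full window for labelling (the
  simplest consistent rule; the source is silent).
* Thresholding ties: when several bins between the two modes share the
  minimum count, the middle tied bin's centre is returned.
* Zero SSVs: summary percentages report 0 with `undefined_pct = TRUE`
  rather than NaN. CE of an HVR with no peaks is 0 in both modes. A
  `mean_score` permutation statistic with no intersecting element is
  flagged undefined (NA observed; null draws with no element are treated as
  0 with a warning).
* Fisher tables with a zero margin report a degenerate odds ratio flag
  rather than Inf propagating silently.
* Permutation determinism: any two runs with the same seed yield the
  identical EV multiset; per-run placements are pre-drawn, so the test is
  parallelisable by contract.

## Calibration and verification design

The test suite pairs every non-trivial operation with an independent
oracle: naive double-loop interval overlap, gap-merge clustering by linear
scan, exhaustive promoter-boundary enumeration, all 576 codon
substitutions against Biostrings' genetic code, hypergeometric enumeration
for Fisher p-values, and a replay of the permutation seed stream scored by
the naive overlap oracle. The permutation test's calibration is checked
under a uniform null (400 trials of N = 1000 on a 5 x 10 Mb genome, 2000
uniform points, 20 isolated 40 kb HVRs) against the exact binomial 99%
band around 0.05; the point-count statistic was chosen for its wide
support, since heavy ties make the two-tailed empirical p conservative.

## Known limitations

* The consequence classifier handles SNVs in CDS only — no splice-site,
  UTR, start-loss or regulatory terms; premature-stop context is not
  checked against transcript completeness.
* The valley threshold assumes genuine bimodality; near-unimodal inputs
  fall back to the override (logged), and the choice of histogram bin width
  is the open knob.
* Cluster shuffling approximates uniform whole-genome placement; clusters
  longer than every chromosome are an error, and chromosome-edge effects
  mean base-level coverage of shuffled clusters is not perfectly uniform.
* With few clusters the permutation null has limited resolution regardless
  of N; the attainable minimum p is `1/(N+1)` only when the observation is
  strictly the most extreme value.
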