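---
title: "Screening morpholino off-targets and quantifying knockdown readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening morpholino off-targets and quantifying knockdown readouts}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moscreen)
```

## The problem

Morpholino antisense oligomers (MOs) are 25-mer synthetic oligos that knock
down a zebrafish gene either by occluding the translation start region of
the mature mRNA (ATG MOs) or by masking a splice site on the pre-mRNA
(splice MOs). Because a 25-mer tolerates a handful of mismatches and still
hybridizes, every MO design has to be screened for *off-target* sites:
places elsewhere in the transcriptome where a fragment of the MO could bind
and act the same way. `moscreen` implements that screen as an explicit,
reproducible decision tree, together with the quantitative readouts used to
evaluate a knockdown experiment (ordinal phenotype scores, maximum
fluorescence intensity as a proteinuria proxy, one-way ANOVA with Tukey
multiple comparisons, and delta-delta-Ct knockdown efficiency), and a
global-alignment module for human-zebrafish ortholog comparison.

## The decision tree

Candidate sites come from an exhaustive ungapped scan (below). Each site
then passes through four ordered rules:

1. **Named gene.** Only hits whose genomic footprint overlaps a `gene`
   feature carrying a Name (or ID) attribute are examined further.
2. **Orientation.** The probe must be antisense-compatible with the RNA;
   a sense-orientation match cannot hybridize to the transcript.
3. **Mechanism.** The position must allow morpholino-like action:
   *translation blocking* when the site overlaps the 5'UTR or the 25 nt
   window starting at the A of the annotated start codon (transcript
   coordinates), else *splice blocking* when, on the pre-mRNA, the site
   spans an exon-intron junction, overlaps the first or last 5 nt of an
   intron, or the 2 nt of an exon adjacent to an intron.
4. **Duplex stability.** A surviving hit whose duplex melting temperature
   is below 70 degC may still be excluded; a Tm of exactly 70 is retained,
   because the exclusion rule is strictly "below".

Every rule is evaluated for every site, so reports always show the full
trail; the final status is the first failing rule
(`excluded_step1` ... `excludable_step4`) or `confirmed_offtarget`.
`excludable` (not `excluded`) at rule 4 reflects that the Tm rule is
discretionary in practice.

Three conventions were genuinely open and are fixed as follows:

* **Overlap, not containment,** triggers the 25/5/2 nt windows: a MO that
  partially covers the start-codon window still blocks the scanning
  ribosome, so requiring full containment would under-call.
* **Exon-edge windows** apply only to exon ends adjacent to an intron;
  transcript termini are not splice sites.
* **Translation precedence** when a site qualifies for both mechanisms
  (the report still records the full trail).
* **Multi-isoform genes:** a site is classified per transcript and
  `consolidate_verdicts()` reports the most severe verdict at gene level
  (confirmed > excludable at the Tm rule > positionally excluded), which
  makes the screen conservative.

## Candidate scanning

The original screen used a BLAST search; `moscreen` replaces it with an
exhaustive scan of every window of every molecule, which dominates any
BLAST parameterization and needs no external service. A window is a
candidate when the reverse complement of the probe aligns ungapped with at
most `max_mismatches = 5` mismatches and a longest perfect run of at least
`min_perfect_run = 12` nt; windows matching the probe itself are reported
with sense-incompatible orientation and feed rule 2. Hybridization of a
morpholino is not gapped in practice, so no indels are modelled; the "MO
fragment" is represented by the maximal ungapped aligned span rather than
by explicit sub-fragments, which yields the same hit set with simpler
semantics.

Scanning covers, per transcript, the mature mRNA (spliced) and the
pre-mRNA (full gene span, because splice-blocking sites are intronic or
junctional by definition), and additionally each contig in both match
senses so that candidate sites *outside* annotated genes exist for rule 1
to reject. Hits with identical genomic footprints are de-duplicated in
favour of mature > pre-mRNA > contig-level records; contig-level hits that
fall entirely inside a gene span are delegated to the molecule scans.

Coordinates are 1-based inclusive throughout, in memory and on disk,
matching the GFF3 convention and R's native indexing; molecule coordinates
run 5' to 3' in transcript orientation.

## The melting-temperature model

The vendor's Tm algorithm used for the original 70 degC rule is proprietary
and unpublished, so the package substitutes a fully specified two-state
nearest-neighbor model:

$$T_m = \frac{1000\,\Delta H}{\Delta S + R \ln(C_T/4)} - 273.15
      + 16.6\,\log_{10}[\mathrm{Na}^+] - 5\,n_{\mathrm{mismatch}}$$

with $\Delta H$ in kcal/mol and $\Delta S$ in cal/(mol K) summed over
dinucleotide stacks plus an initiation term, $R = 1.987$ cal/(mol K),
total strand concentration $C_T = 0.25\,\mu M$ and monovalent cation
concentration 0.1 M by default. The stacking table is a DNA:RNA-hybrid
style parameter set with two deliberate adjustments:

* enthalpies are raised by about 7% relative to typical hybrid values,
  reflecting the higher affinity of the uncharged, conformationally
  preorganized morpholino backbone — under the defaults a well-designed
  perfect-match 25-mer melts at roughly 75-90 degC, the regime in which a
  70 degC cut-off meaningfully separates solid from weakened duplexes;
* the table is reverse-complement symmetric, so a duplex melts at the same
  temperature whichever strand the fragment is read from (a physical
  symmetry a hybrid-asymmetric table would violate).

Mismatches are charged a flat, configurable 5 degC each rather than
re-parameterizing all mismatch stacks; with the 5-mismatch scan ceiling
this spans a 25 degC range, which is what the screen needs from the rule.
Absolute Tm values are therefore model-dependent; the 70 degC threshold is
honoured exactly, and every parameter (`tm_parameters()`) is configurable.

## Global alignment for ortholog comparison

`global_align()` is a quadratic-space Gotoh implementation with affine gap
penalties. A gap of length $L$ costs $\mathrm{open} + (L-1)\,\mathrm{ext}$
(the opening column carries the open penalty). Defaults mirror the EMBOSS
stretcher web tool the field uses for such comparisons: BLOSUM62 with gap
open 12 / extend 2 for proteins, the full DNA matrix (+5/−4,
ambiguity-aware by set-averaging) with 16/4 for nucleotides. Identity
counts equal residues, similarity counts columns with a positive
substitution score, gaps counts gap columns, all over the alignment
length — the stretcher reporting convention. Traceback ties are broken
deterministically: diagonal, then gap-in-b, then gap-in-a. Ambiguity codes
score through the matrix and are never errors. Reproducing any published
ortholog percentage exactly also requires the exact sequence versions the
original comparison used; the module takes sequences from files only and
never fetches them.

## Readout statistics

* `tabulate_phenotypes()` tallies the ordinal P1 (physiological) to P4
  (severe edema/pericardial effusion) grades plus deaths per group.
  Dead larvae appear only here: they are excluded from fluorescence and
  ANOVA inputs, since a dead larva has no meaningful circulating-reporter
  readout.
* `max_fluorescence_intensity()` is the maximum gray value over a binary
  region-of-interest mask (the retinal vessel plexus in the motivating
  assay); segmentation itself is out of scope, the mask is an input.
* `anova_oneway()` and `tukey_hsd()` use the classical between/within
  decomposition (via `lm`) and the Tukey-Kramer statistic
  $q = |\bar y_i - \bar y_j| / \sqrt{(\mathrm{MSW}/2)(1/n_i + 1/n_j)}$
  with adjusted p from the studentized-range distribution (`ptukey`,
  itself numerical integration, cross-checked in the test suite against an
  independent quadrature of the studentized-range CDF to 1e-6).
  Significance tiers follow the star convention
  (\*, \*\*, \*\*\*, \*\*\*\* at 0.05/0.01/0.001/0.0001).
* `knockdown_efficiency()` implements delta-delta-Ct with the standard
  assumption of equal amplification efficiencies:
  $\Delta Ct = Ct_{target} - Ct_{ref}$ per sample, fold change
  $2^{-\Delta\Delta Ct}$, efficiency $(1-\mathrm{fold})\times 100\%$.

## The synthetic test bed

`sim_config()` / `generate_genome()` / `plant_offtargets()` build a toy
genome (about 6-12 kb by default: 6 genes, 2-4 exons each, introns of
80-150 nt, exons of 120-250 nt, 5'UTRs of 30-60 nt, GC 0.40-0.60, strands
alternating) and plant, per truth class, 5 binding sites with exact labels:

| truth class          | construction                                   | expected outcome   |
|----------------------|------------------------------------------------|--------------------|
| intergenic           | antisense window in a spacer, >=30 nt from genes | excluded at rule 1 |
| wrong_orientation    | probe equals the transcript window (sense)     | excluded at rule 2 |
| translation_blocking | antisense window over the start-codon window   | confirmed          |
| splice_blocking      | antisense window across a donor junction       | confirmed          |
| positional_null      | antisense, mid-exon, Tm >= 70, no window overlap | excluded at rule 3 |
| low_tm               | acceptor-junction window, probe mutated until scan-level Tm < 70 | excludable at rule 4 |

`positional_null` exists so that rule 3 has dedicated negative cases:
inside a named gene, orientation-compatible and thermodynamically solid,
but overlapping neither the start-codon window, the 5'UTR, nor any
junction window. Probes are derived from their windows (reverse complement
for antisense classes), window bases are re-drawn until the perfect-duplex
Tm lies in 75-86 degC (start codons and GT..AG dinucleotides held fixed),
and `low_tm` probes receive 2-4 clustered mutations so the per-mismatch
penalty pulls the scan-level Tm below threshold while the perfect run
stays >= 13 nt. After planting, the genome is re-scanned with every probe
and the draw is rejected and retried whenever any probe hits anything
beyond its planted footprint — the ground-truth table is exact by
construction, not by expectation.

What the generator does *not* emulate: repeats and low-complexity
sequence, GC isochores, realistic intron/exon length distributions,
multi-isoform genes (those are exercised by a hand-written two-isoform
fixture in the test suite), and genome scale. Passing the planted-truth
test therefore shows that the decision logic is correct, not that the
screen's thresholds are well-calibrated for a real transcriptome.

`generate_readout_tables()` emulates the experiment's readout structure:
multinomial phenotype grades, MFI drawn from a normal truncated at zero,
and qPCR Ct values consistent with each group's true fold change under the
delta-delta-Ct model (reference Ct around 15 cycles, per-channel
measurement noise 0.25 cycles, gene-specific baseline delta-Ct drawn once).
The default group set carries true knockdown fractions of 0.30, 0.33, 0.32
and 0.81 — the efficiency scale reported for the four splice MOs that
motivated these tools — so parameter-recovery tests run at realistic
effect sizes.

## Numerical choices and problem sizes

* Tm exactly at threshold is retained (rule 4 excludes strictly below).
* Scan merge rule: overlapping candidate windows of one orientation keep
  the fewest-mismatch placement, leftmost on ties.
* Alignment traceback tie-break: diagonal, then consume-a, then consume-b.
* Tukey p-values agree with an independent quadrature oracle to 1e-6
  (observed agreement is ~1e-13); ANOVA identities (F = t² for two groups,
  exact SS decomposition) hold to 1e-9 relative.
* The test suite runs the planted-truth check on seeds 1-20 (600 planted
  sites), the alignment-enumeration check on 500 random pairs of length
  <= 7 (where exhaustive path enumeration is feasible), knockdown recovery
  over 200 generated tables at n = 6 replicates, and the monotonicity
  suite (wider windows or lower Tm cut never lose confirmed hits) over 50
  genomes; `scripts/acceptance.R` recomputes scaled versions of the same
  quantities in a few minutes on one CPU. These sizes are the package's
  own choice of a thorough-but-quick regression net.

## Known limitations

* The screen classifies positions; it does not rank confirmed hits or
  model RNA secondary-structure accessibility.
* The Tm model is two-state with a flat mismatch penalty; it is not a
  thermodynamic ensemble and its absolute values should not be compared
  across different parameter tables.
* GFF3 is the only annotation dialect (unambiguous Parent linkage); GTF,
  BAM/VCF and compressed random access are out of scope.
* Gene-level consolidation takes the most severe isoform verdict; no
  attempt is made to weight isoform expression.
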