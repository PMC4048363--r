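---
title: "plantmir: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plantmir: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`plantmir` implements the classical small-RNA-sequencing workflow for
annotating plant miRNAs: collapse sequencer reads into unique tags, map them
perfectly to a genome, remove repeat/rRNA/tRNA-associated tags, fold the
genomic context of each surviving tag, test the fold against the
miRNA/miRNA* duplex criteria, and profile the accepted miRNAs across
tissues, against other genomes, and against degradome (PARE) libraries for
target validation. This vignette records the model, the tunable parameters,
and the design decisions made where the field's conventions leave room.

## Preprocessing

Raw reads are trimmed at the leftmost exact match to a prefix of the 3'
adapter; a match must cover at least 8 adapter nucleotides or reach the read
end. No mismatches are tolerated, which keeps trimming deterministic and is
consistent with the perfect-match mapping used downstream. Reads containing
non-ACGT characters are discarded (counted in the log). Inserts of 18-30 nt
(the sequenced size range; configurable as `keep_len`) are collapsed into
tags with per-library counts; mapping and locus discovery later restrict to
18-26 nt (`map_len`). Library summaries report distinct tags, total reads,
the per-library singleton fraction (singletons are defined within each
library, not across the union), and the 20-24 nt abundance fraction.

## Locus discovery

All thresholds live in `pipeline_config()`:

| parameter | default | meaning |
|---|---|---|
| `max_genome_hits` | 500 | tags with *more* than this many perfect genomic hits are repeat-associated (strict: exactly 500 is kept) |
| `mature_len` | 20-24 nt | candidate mature length |
| `min_reads_one_lib` | 20 | mature count must *exceed* this in at least one library |
| `min_reads_either` | 5 | mature count must *exceed* this in at least two libraries (waived for single-library data) |
| `max_duplex_mismatch` | 4 | mature bases unpaired to the opposite arm |
| `max_bulge_events`, `max_bulge_len` | 1, 2 | asymmetric bulges within the duplex |
| `overhang` | 2 | required 3' overhang of the miRNA/miRNA* duplex |
| `dominance_min`, `dominance_window` | 0.70, 20 nt | read dominance around the mature 5' end |
| `flank_lengths` | 50, 100, 150, 200 | genomic windows folded around a hit |

Windows are folded with ViennaRNA's `RNAfold` when the binary is on the
PATH (the default thermodynamic engine); otherwise a built-in Nussinov
base-pair-maximisation fold (Watson-Crick plus G:U, minimum hairpin loop 3
nt, surrogate energy = minus the pair count) is used. The smallest flank
window whose fold passes the structural criteria is reported.

**Duplex evaluation.** From the dot-bracket pairing table and the mature
span `[m1, m2]`, the star span is `[partner(m2 - 2), partner(m1) + 2]` —
the Dicer geometry that leaves 2-nt 3' overhangs on both strands. Unpaired
anchor positions are extrapolated from the nearest paired mature base
assuming a locally ungapped helix. Mature spans that are entirely unpaired,
pair into themselves, or pair to both sides (i.e. cross the terminal loop)
are rejected as `no_hairpin`. Mismatches are the mature bases unpaired to
the opposite arm; note that the mature 3' terminus legitimately pairs
*below* the inferred star span (the lower stem), so mismatch counting is by
pairing status, not by star-interval membership. Bulges are asymmetries
(`|gap_mature - gap_star|`) between consecutive paired mature positions.

**The overhang criterion is read-based.** On a hairpin whose stem extends
below the duplex, the inferred star span has 2-nt overhangs *by
construction*: structure alone cannot violate the criterion. The package
therefore checks it against observed star reads: if a tag's 5' end maps
within `star_search_slop` (4 nt) of the canonical star 5' position, the
realised overhang is `2 + (observed - canonical)` and must equal 2.
Without star reads the canonical star is assumed and the criterion passes,
as in standard annotation practice where miRNA* evidence is corroborating
rather than mandatory.

**Rejection reasons** follow the fixed order length, count, no_hairpin,
overhang, mismatches, bulge, dominance; structural diagnoses are taken from
the smallest window that yields a valid hairpin evaluation (larger windows
can re-fold a defective stem into a different defect class, so the smallest
informative window is authoritative, mirroring the smallest-window rule for
acceptances). The two read-count gates (>20 in one library, >5 in at least
two) are deliberately kept as independent configurable thresholds but share
the reason code `count`.

Each genomic hit of a tag is evaluated independently, so a multi-mapping
tag can found several accepted loci (as expected for homoeologous copies in
polyploids). One consequence on synthetic data: a *perfectly* paired stem is
its own inverted repeat, so the mature tag also maps — and can be accepted —
at the star arm on the opposite strand. Real precursors almost always carry
mismatches that break this symmetry; the planted-truth metrics are therefore
recall and per-locus reason accuracy, not precision over all acceptances.

## Conservation

A mature miRNA is present in another species when it has a perfect genomic
match and a ±200 bp (`conservation_flank`) window around some hit refolds
into a hairpin passing the structural criteria; read-count criteria are
waived since no sequencing data exist for other species. Lineage classes
over the panel (Arabidopsis, soybean | rice, maize, sorghum, barley,
Brachypodium) are assigned by precedence: any dicot => `broadly_conserved`;
none => `wheat_specific`; all monocots => `monocot_wide`; barley only =>
`wheat_barley`; any other pattern within the BEP clade
(barley/Brachypodium/rice) => `bep_clade`. The five-class scheme is not a
partition of all 128 presence patterns, so the remainder (patterns reaching
maize or sorghum without covering all monocots and without dicots) is
assigned `monocot_wide` to keep the classifier total; the choice is tested
exhaustively against an independent decision table.

## Degradome target calling

Target alignments use the Allen/CleaveLand-style penalty table: mismatch or
gap 1.0, G:U wobble 0.5, penalties doubled at miRNA positions 2-13 from the
5' end, at most one single-nucleotide bulge per alignment (windowed
exhaustive search stays fast with that bound), and an acceptance threshold
of 4.5. The predicted cleavage site is the transcript position paired with
miRNA position 10; an event requires at least 5 degradome read 5' ends at
the site (a ±1 nt tolerance is available but off by default, and the site
is not required to be the transcript-wide profile maximum). Cleavage
regions are classified against the longest ATG-initiated, stop-terminated
forward-frame ORF of at least 70 codons (the ATG counts as a codon; a
stop-to-stop convention would be an alternative, but ATG-initiation is
deterministic and matches how coding regions are annotated on ESTs).
Targets are unique (family, transcript) pairs; targets-per-family is
reported to one decimal place.

## Expression

Counts are normalised to RP10M (`count / mapped total x 1e7`). Group
comparisons use a two-sided Welch t test on `log10(x + 1)`; clustering uses
average-linkage agglomeration on `1 - Pearson correlation` of
`log2(RP10M + 1)` (row z-scoring optional, off by default), with undefined
correlations from constant rows placed at maximal distance. The
tissue-preferential rule is this package's operationalisation — the
literature rarely states one numerically: *preferential* means mean RP10M in
the target tissues ≥ 10 (`on_threshold`) and ≥ 10x (`fold_threshold`) the
maximum outside; *specific* additionally caps the outside maximum at 1
(`off_threshold`); *silenced* is the mirror image. All three thresholds are
configurable, and published tissue-specific counts should not be expected to
reproduce under any particular setting.

## The synthetic-data generator

The generator exists to give every criterion a planted positive and a
planted negative. Background genomes are i.i.d. uniform nucleotides — the
simplest null that does not fold into qualifying hairpins by chance at
these lengths. Precursors are built stem-outward from the desired duplex:
mature arm, 6-nt stem extension, an 8-nt A/C loop (unpairable against A/C
tails), the star arm as a reverse complement carrying non-pairing
substitutions (one per designed mismatch, spaced 3 nt apart) and optional
star-side bulge insertions flanked by A/C mature bases, then a 2-nt A/C
tail forming the star 3' overhang. Each construct is folded and verified to
reproduce the requested duplex statistics (the rare draw broken by an
off-design minimum-free-energy fold is redrawn), and verified once more in
its genomic context with the smallest discovery window, re-jittering the
local flank if needed — so truth labels round-trip by construction, for any
seed.

Planted read stacks realise a dominance target (0.85 for passing loci, 0.60
for dominance violations) by binomial sampling between the mature tag and
six offset "ragged-processing" fillers within ±15 nt; star reads are
planted at 6-15 copies (below the count gate) at the canonical star
position, or shifted 2 nt to a blunt duplex for overhang-violation loci.
Count-violation loci get 7-18 mature reads per library (failing the >20
gate while passing the >5 gate, so the count reason is unambiguous). The
default panel is three tissue libraries at depths 160/130/110 reads per
locus; seed-related tissues carry a 22-nt-enriched size mix and the others
a 21-nt-enriched mix, with 24-nt reads dominating everywhere, mimicking
plant small RNA populations. A 30-nt repeat unit planted in 501 tandem
copies trips the strict >500 copy filter, and a 120-nt rRNA-like locus
(shipped as the decoy catalogue) exercises the annotation filter.

Degradome truth plants one perfect 21-nt binding site in the 3' UTR of each
600-nt transcript carrying a 75-codon ORF, with exactly `peak_reads` 20-nt
reads starting at the position opposite miRNA position 10 (degradome read
length is not standardised in the literature; 20 nt is a typical PARE tag)
and count-1 background reads scattered at least 10 nt away.

What the generator does **not** emulate: sequencing errors, adapter
variants, quality-score structure, homoeologous subgenomes, 24-nt
heterochromatic siRNA clusters, expression correlation between loci, and
realistic transcriptome complexity. Passing the planted-truth suites
therefore demonstrates that the decision logic implements the stated
criteria exactly — not that the criteria themselves are optimally tuned for
real polyploid data.

## Problem sizes and numerical notes

The standard validation suites use a 40 + 60 locus genome (~65 kb), three
libraries, 40 degradome transcripts of 600 nt, and a 60 x 11 expression
matrix — sizes chosen so the whole suite folds, maps and scores in a couple
of minutes on a laptop while every criterion still has 10+ planted cases.
Score comparisons against the 4.5 threshold use a 1e-9 slack to absorb
floating-point accumulation of 0.5-unit penalties. The Nussinov traceback
prefers leaving a base unpaired and otherwise pairs with the smallest
admissible partner, making structures deterministic. Hierarchical
clustering inherits `stats::hclust`'s deterministic tie handling (input
order). All generator entry points take an integer seed and restore the
caller's RNG state.
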