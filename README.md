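# plantmir

Annotation of plant microRNAs from high-throughput small RNA sequencing,
with degradome-based target validation and tissue expression profiling.

Plant miRNA catalogues are built from deep small-RNA libraries by a
now-classical procedure: collapse reads into unique tags, map them
perfectly to the genome, discard repeat/rRNA/tRNA-associated tags, fold the
genomic context of each remaining tag, and accept a locus only when the
fold supports a genuine miRNA/miRNA* duplex backed by the read stack.
`plantmir` implements that procedure end to end for bulk plant small RNA
studies (its defaults follow a hexaploid wheat multi-tissue design), plus
the downstream analyses such studies report: cross-species conservation
classes, degradome (PARE) cleavage-site calling with t-plots, and RP10M
expression matrices with hierarchical clustering. A seeded synthetic-data
generator plants hairpin loci, decoys, read stacks and degradome peaks with
labelled truth, so every rule in the pipeline is testable against known
answers.

## The annotation criteria

A candidate tag of 20–24 nt founds a miRNA locus when:

1. the miRNA and miRNA\* derive from opposite stem arms and form a duplex
   with two-nucleotide 3' overhangs (checked against observed star reads
   when present; the inferred star span is
   `[partner(m2−2), partner(m1)+2]` from the pairing table);
2. at most 4 mature bases are unpaired to the opposite arm;
3. asymmetric bulges in the duplex are limited to one event of at most 2 nt;
4. the mature tag covers at least 70% of all reads with 5' ends within
   ±20 nt of its start site;
5. read support exceeds 20 reads in at least one library and 5 reads in at
   least two.

Tags with more than 500 perfect genomic hits or matching a decoy
ncRNA/repeat catalogue are removed first. Degradome targets use
Allen/CleaveLand-style scoring (mismatch/gap 1, G:U 0.5, doubled at miRNA
positions 2–13, threshold 4.5) and require ≥5 degradome read 5' ends at the
transcript position paired with miRNA position 10. Every threshold is a
field of `pipeline_config()`.

## Worked example

Simulate a small study with four clean loci and two planted criterion
violations, run discovery, and compare against the planted truth:

```r
library(plantmir)

spec <- simulation_spec(n_pass_loci = 4L,
                        n_fail_loci = c(mismatches = 1L, dominance = 1L),
                        seed = 42L)
sg  <- make_synthetic_genome(spec)
sim <- simulate_srna_libraries(sg)
res <- call_mirna_loci(sim$tag_counts, sg$genome, decoys = sg$decoys)

truth <- sg$truth[kind == "mirna_locus"]
calls <- merge(truth, res$candidates,
               by.x = c("mature_seq", "seq_id", "start"),
               by.y = c("sequence", "seq_id", "start"))
calls[order(locus_id),
      .(locus_id, violated_criterion, status, reason, flank, mismatches,
        round_dom = round(dominance, 2))]
```

```
   locus_id violated_criterion   status     reason flank mismatches round_dom
1: locus001               none accepted       <NA>    50          0      0.84
2: locus002               none accepted       <NA>    50          0      0.82
3: locus003          dominance rejected  dominance    50          0      0.60
4: locus004         mismatches rejected mismatches    NA         NA        NA
5: locus005               none accepted       <NA>    50          0      0.88
6: locus006               none accepted       <NA>    50          0      0.86
```

All four clean loci are accepted from the smallest (50 nt) flank window
with fully paired duplexes and ~85% read dominance; the locus planted with
60% dominance is rejected for exactly that criterion, and the locus whose
star arm carries five non-pairing substitutions is rejected for
`mismatches`. The same objects feed the rest of the pipeline:
`summarize_libraries()` / `size_class_profile()` for library statistics,
`profile_conservation()` for lineage classes, `score_target_alignment()` +
`build_degradome_profiles()` + `call_cleavage_events()` for targets, and
`normalize_rp10m()` + `call_tissue_preferential()` + `cluster_expression()`
for expression. A command-line wrapper covering the same stages is
installed at `system.file("cli", "plantmir", package = "plantmir")`.

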