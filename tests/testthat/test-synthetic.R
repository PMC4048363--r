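test_that("hairpin construction realises the requested duplex exactly", {
  set.seed(14)
  cases <- list(c(21, 0, 0), c(21, 2, 0), c(24, 4, 0), c(21, 0, 1),
                c(21, 0, 3), c(20, 5, 0))
  for (cs in cases) {
    hp <- make_hairpin_locus(cs[1], cs[2], cs[3])
    ev <- evaluate_duplex(hp$structure, c(1L, cs[1]))
    expect_true(ev$ok)
    expect_equal(ev$stats$mismatches, cs[2])
    expect_equal(ev$stats$max_bulge_len, cs[3])
    expect_equal(ev$stats$overhang_3p, 2L)
    # the star reads are verbatim substrings of the precursor
    expect_true(grepl(hp$star_read, hp$precursor, fixed = TRUE))
    expect_true(grepl(hp$star_read_blunt, hp$precursor, fixed = TRUE))
  }
  expect_error(make_hairpin_locus(20, 6, 0), "infeasible")
  expect_error(make_hairpin_locus(10), "18-26")
})

test_that("the generator is byte-deterministic under a fixed seed", {
  spec <- simulation_spec(n_pass_loci = 3L,
                          n_fail_loci = c(mismatches = 1L), seed = 33L)
  a <- make_synthetic_genome(spec)
  b <- make_synthetic_genome(spec)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  ra <- simulate_srna_libraries(a)
  rb <- simulate_srna_libraries(b)
  expect_identical(ra$tag_counts, rb$tag_counts)
})

test_that("planted spans contain their sequences and do not overlap", {
  spec <- simulation_spec(n_pass_loci = 4L,
                          n_fail_loci = c(dominance = 2L), seed = 10L)
  sg <- make_synthetic_genome(spec)
  tr <- sg$truth[sg$truth$kind == "mirna_locus"]
  gs <- sg$genome[[1]]
  for (i in seq_len(nrow(tr))) {
    span <- substr(gs, tr$start[i] + 1L, tr$end[i])
    if (tr$strand[i] == "-")
      span <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(span)))
    expect_equal(span, tr$mature_seq[i])
  }
  o <- order(sg$truth$start)
  expect_true(all(sg$truth$end[o][-nrow(sg$truth)] <=
                    sg$truth$start[o][-1]))
  expect_false(grepl("[^ACGT]", gs))
})

test_that("the repeat decoy trips the copy filter by exactly its copy number", {
  spec <- simulation_spec(n_pass_loci = 0L, n_fail_loci = c(count = 0L),
                          decoy_repeat_copies = 501L, seed = 6L)
  sg <- make_synthetic_genome(spec)
  h <- map_tags_exact(sg$repeat_tag, sg$genome)
  expect_equal(sum(h$strand == "+"), 501L)
  expect_equal(nrow(sg$truth[sg$truth$kind == "mirna_locus"]), 0L)
})

test_that("configured genome length is honoured and validated", {
  spec <- simulation_spec(n_pass_loci = 2L, n_fail_loci = c(count = 0L),
                          genome_length = 40000L, seed = 9L)
  sg <- make_synthetic_genome(spec)
  expect_equal(nchar(sg$genome[[1]]), 40000L)
  expect_error(make_synthetic_genome(
    simulation_spec(n_pass_loci = 2L, n_fail_loci = c(count = 0L),
                    genome_length = 1000L, seed = 9L)), "too small")
})

test_that("simulated libraries realise the dominance target", {
  sim <- small_sim(seed = 77L, n_pass = 5L, n_each = 0L)
  hits <- map_tags_exact(sim$sim$tag_counts$sequence, sim$sg$genome)
  libs <- setdiff(names(sim$sim$tag_counts), "sequence")
  cnt <- rowSums(as.matrix(sim$sim$tag_counts[, libs, with = FALSE]))
  names(cnt) <- sim$sim$tag_counts$sequence
  stacks <- hits[, c("tag", "seq_id", "strand", "fivep"), with = FALSE]
  stacks[, count := cnt[tag]]
  for (lc in Filter(function(l) !is.null(l$start), sim$sg$loci)) {
    fivep <- if (lc$strand == "+") lc$start else lc$end - 1L
    d <- compute_read_dominance(
      stacks[seq_id == lc$seq_id & strand == lc$strand], lc$mature, fivep)
    expect_true(abs(d - lc$dominance) <= 0.05,
                info = paste(lc$locus_id, round(d, 3)))
  }
})

test_that("a zero-depth library stays listed but contributes no reads", {
  libs <- default_libraries(depths = c(SH = 150, SR = 0))
  spec <- simulation_spec(n_pass_loci = 2L, n_fail_loci = c(count = 0L),
                          libraries = libs, seed = 12L)
  sg <- make_synthetic_genome(spec)
  sim <- simulate_srna_libraries(sg)
  expect_true("SR" %in% names(sim$tag_counts))
  expect_equal(sum(sim$tag_counts$SR), 0L)
  expect_error(simulate_srna_libraries(sg, libraries = list()), "empty")
})

test_that("reads are substrings of the genome or its reverse complement", {
  sim <- small_sim(seed = 55L, n_pass = 3L, n_each = 1L)
  gs <- sim$sg$genome[[1]]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gs)))
  seqs <- sim$sim$tag_counts$sequence
  ok <- vapply(seqs, function(s)
    grepl(s, gs, fixed = TRUE) || grepl(s, rc, fixed = TRUE), logical(1))
  expect_true(all(ok))
})

test_that("degradome truth plants peaks exactly opposite miRNA position 10", {
  ds <- simulate_degradome_truth(
    data.frame(transcript_id = c("t1", "t2", "t3"),
               peak_reads = c(6L, 4L, 0L)), seed = 4L)
  profs <- build_degradome_profiles(ds$reads, ds$transcripts)
  expect_equal(profs[["t1"]][ds$truth$site[1]], 6L)
  expect_equal(profs[["t2"]][ds$truth$site[2]], 4L)
  expect_equal(profs[["t3"]][ds$truth$site[3]], 0L)
  expect_equal(ds$truth$expected_pass, c(TRUE, FALSE, FALSE))
  # site = binding end - 9: the planted perfect alignment points at it
  al <- score_target_alignment(ds$mirnas[[1]], ds$transcripts[["t1"]])
  expect_true(any(al$score == 0 & al$site == ds$truth$site[1]))
})

test_that("expression simulation plants recoverable profiles", {
  ep <- simulate_expression_profiles(seed = 13L)
  expect_equal(dim(ep$counts), c(60L, 11L))
  rp <- normalize_rp10m(ep$counts, ep$totals)
  spec_rows <- ep$truth$class == "specific"
  expect_true(all(rowMeans(rp[spec_rows, ep$target]) >= 10))
  outside <- setdiff(colnames(rp), ep$target)
  expect_true(all(rp[spec_rows, outside] <= 1))
})
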