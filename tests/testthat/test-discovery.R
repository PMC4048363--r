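test_that("exact mapping agrees with a brute-force scan on both strands", {
  g <- c(chr1 = "AAGGTTCCAAGG")
  h <- map_tags_exact("AAGG", g)
  expect_equal(h$start, c(0L, 8L))
  expect_equal(h$strand, c("+", "+"))
  # CCTT maps as reverse complement of AAGG
  h2 <- map_tags_exact("CCTT", g)
  expect_equal(h2$strand, c("-", "-"))
  expect_equal(sort(h2$start), c(0L, 8L))
  # mismatching tag yields nothing
  expect_equal(nrow(map_tags_exact("AACG", g)), 0L)
  set.seed(8)
  gs <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  for (i in 1:5) {
    st <- sample(380, 1)
    tag <- substr(gs, st, st + 19)
    want <- oracle_scan(tag, gs)
    got <- map_tags_exact(tag, c(chr1 = gs))
    expect_equal(nrow(got), length(want))
    expect_setequal(paste(got$start, got$strand),
                    sapply(want, paste, collapse = " "))
  }
  expect_error(map_tags_exact("ACGN", g), "non-ACGT")
})

test_that("copy-number filter is strict at 500 and decoys are dropped", {
  tag_lo <- strrep("AT", 10)
  hits <- data.table::data.table(
    tag = c(rep("T500", 500), rep("T501", 501)),
    seq_id = "chr1", start = 0L, end = 20L, strand = "+", fivep = 0L)
  f <- filter_tags(c("T500", "T501", tag_lo), hits)
  expect_true(f$retained[f$tag == "T500"])
  expect_equal(f$reason[f$tag == "T501"], "high_copy")
  decoy <- paste0("GGG", tag_lo, "CCC")
  f2 <- filter_tags(tag_lo, hits[0], decoys = decoy)
  expect_equal(f2$reason, "annotated")
  # reverse-complement containment also counts
  f3 <- filter_tags(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tag_lo))),
    hits[0], decoys = decoy)
  expect_equal(f3$reason, "annotated")
})

test_that("candidate windows are clipped and strand-resolved", {
  set.seed(3)
  gs <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  g <- c(chr1 = gs)
  w <- extract_candidate_windows(
    list(seq_id = "chr1", start = 1000L, end = 1021L, strand = "+"), g, 100L)
  expect_equal(c(w$wstart, w$wend), c(900L, 1121L))
  expect_equal(substr(w$sequence, w$mature_start, w$mature_end),
               substr(gs, 1001, 1021))
  wc <- extract_candidate_windows(
    list(seq_id = "chr1", start = 10L, end = 31L, strand = "+"), g, 100L)
  expect_equal(c(wc$wstart, wc$wend), c(0L, 131L))
  # minus strand: mature tag reads 5'->3' in the window
  tag <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gs, 1001, 1021))))
  wm <- extract_candidate_windows(
    list(seq_id = "chr1", start = 1000L, end = 1021L, strand = "-"), g, 50L)
  expect_equal(substr(wm$sequence, wm$mature_start, wm$mature_end), tag)
})

test_that("read dominance follows the 70% rule with its strict boundary", {
  stack <- data.table::data.table(
    tag = c("M", "A", "B"), fivep = c(100L, 95L, 110L), count = c(70L, 20L, 10L))
  expect_equal(compute_read_dominance(stack, "M", 100L), 0.70)
  stack$count <- c(69L, 21L, 10L)
  expect_equal(compute_read_dominance(stack, "M", 100L), 0.69)
  one <- data.table::data.table(tag = "M", fivep = 100L, count = 5L)
  expect_equal(compute_read_dominance(one, "M", 100L), 1)
  far <- data.table::data.table(tag = "X", fivep = 200L, count = 5L)
  expect_true(is.na(compute_read_dominance(far, "M", 100L)))
  expect_error(compute_read_dominance(far[0], "M", 100L), "empty")
})

sim <- small_sim(seed = 42L)
res <- call_mirna_loci(sim$sim$tag_counts, sim$sg$genome, decoys = sim$sg$decoys)

test_that("planted loci round-trip with their designed pass/fail labels", {
  m <- truth_vs_candidates(sim$sg, res$candidates)
  expect_equal(nrow(m), nrow(sim$sg$truth[sim$sg$truth$kind == "mirna_locus"]))
  pass <- m[m$expected_pass == TRUE]
  fail <- m[m$expected_pass == FALSE]
  expect_true(all(pass$status == "accepted"))
  expect_equal(fail$reason, fail$violated_criterion)
  # decoy tags were removed before candidate evaluation
  expect_equal(res$filtered$reason[res$filtered$tag == sim$sg$repeat_tag],
               "high_copy")
  expect_equal(res$filtered$reason[res$filtered$tag == sim$sg$rrna_tag],
               "annotated")
})

test_that("accepted loci report hairpin evidence consistent with the config", {
  acc <- res$candidates[res$candidates$status == "accepted"]
  cfg <- pipeline_config()
  expect_true(all(acc$mismatches <= cfg$max_duplex_mismatch))
  expect_true(all(acc$bulge_events <= cfg$max_bulge_events))
  expect_true(all(acc$max_bulge_len <= cfg$max_bulge_len))
  expect_true(all(acc$overhang_3p == 2L))
  expect_true(all(acc$dominance >= cfg$dominance_min))
  expect_true(all(nchar(acc$sequence) >= 20 & nchar(acc$sequence) <= 24))
  expect_true(all(acc$flank %in% cfg$flank_lengths))
  # structures parse and mature spans sit inside their windows
  for (i in seq_len(nrow(acc))) {
    expect_silent(pairing_table(acc$structure[i]))
    expect_equal(substr(acc$precursor[i], acc$mature_start[i], acc$mature_end[i]),
                 acc$sequence[i])
  }
})

test_that("tightening thresholds never enlarges the accepted set", {
  strict_dom <- call_mirna_loci(sim$sim$tag_counts, sim$sg$genome,
                                decoys = sim$sg$decoys,
                                config = pipeline_config(dominance_min = 0.9))
  strict_mm <- call_mirna_loci(sim$sim$tag_counts, sim$sg$genome,
                               decoys = sim$sg$decoys,
                               config = pipeline_config(max_duplex_mismatch = 1L))
  key <- function(x) {
    a <- x$candidates[x$candidates$status == "accepted"]
    paste(a$sequence, a$seq_id, a$start)
  }
  expect_true(all(key(strict_dom) %in% key(res)))
  expect_true(all(key(strict_mm) %in% key(res)))
})

test_that("discovery is strand-symmetric", {
  g <- sim$sg$genome
  grc <- stats::setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g[[1]]))), names(g))
  res_rc <- call_mirna_loci(sim$sim$tag_counts, grc, decoys = sim$sg$decoys)
  key <- function(x) sort(unique(
    x$candidates$sequence[x$candidates$status == "accepted"]))
  expect_equal(key(res_rc), key(res))
})
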