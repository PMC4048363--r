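# helper: a perfect target window for a miRNA, plus targeted edits
rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
edit_at <- function(window, mir_pos, base) {
  # replace the transcript base paired with miRNA position mir_pos
  idx <- nchar(window) - mir_pos + 1L
  substr(window, idx, idx) <- base
  window
}

set.seed(17)
mir <- paste0("TG", paste(sample(c("A", "C", "G", "T"), 17, TRUE), collapse = ""),
              "CA")
substr(mir, 5, 5) <- "G"    # wobble-capable base inside the core region
substr(mir, 18, 18) <- "G"  # wobble-capable base outside the core region

test_that("alignment scoring follows the penalty table", {
  w0 <- rc(mir)
  a0 <- score_target_alignment(mir, w0)
  expect_equal(a0$score[1], 0)
  expect_equal(c(a0$start[1], a0$end[1]), c(1L, 21L))
  expect_equal(a0$site[1], 21L - 9L)
  # G:U wobble opposite miRNA position 5 (core, doubled): 0.5 x 2 = 1.0
  w_gu <- edit_at(w0, 5L, "T")
  expect_equal(score_target_alignment(mir, w_gu)$score[1], 1.0)
  # mismatch at position 16 (outside the core): 1.0
  m16 <- substr(mir, 16, 16)
  bad16 <- c(A = "C", C = "A", G = "A", T = "C")[[m16]]
  w_mm <- edit_at(w0, 16L, bad16)
  expect_equal(score_target_alignment(mir, w_mm)$score[1], 1.0)
  # both edits accumulate
  expect_equal(score_target_alignment(mir, edit_at(w_gu, 16L, bad16))$score[1], 2.0)
  # transcript shorter than the miRNA: no result
  expect_equal(nrow(score_target_alignment(mir, "ACGT")), 0L)
})

test_that("the 4.5 threshold is inclusive and 5.0 is excluded", {
  w0 <- rc(mir)
  mk_bad <- function(p) c(A = "C", C = "A", G = "A", T = "C")[[substr(mir, p, p)]]
  # two core mismatches (2.0 each) = 4.0; one outer G:U (0.5) = 4.5
  w45 <- edit_at(edit_at(w0, 3L, mk_bad(3)), 8L, mk_bad(8))
  w45 <- edit_at(w45, 18L, "T")   # G:U against miRNA position 18
  a <- score_target_alignment(mir, w45)
  expect_true(any(abs(a$score - 4.5) < 1e-9))
  # three core mismatches = 6.0 > 4.5: excluded
  w60 <- edit_at(edit_at(edit_at(w0, 3L, mk_bad(3)), 8L, mk_bad(8)), 12L, mk_bad(12))
  expect_equal(nrow(score_target_alignment(mir, w60)), 0L)
})

test_that("every single substitution scores exactly its penalty-table value", {
  w0 <- rc(mir)
  for (p in 1:21) {
    t0 <- substr(w0, 22 - p, 22 - p)
    for (b in setdiff(c("A", "C", "G", "T"), t0)) {
      w <- edit_at(w0, p, b)
      got <- score_target_alignment(mir, w)
      got <- got[got$start == 1L & got$gaps == 0L]
      expect_equal(got$score, oracle_target_score(mir, w),
                   info = paste("pos", p, "base", b))
    }
  }
})

test_that("score is complement-invariant for Watson-Crick/mismatch duplexes", {
  w0 <- rc(mir)
  bad <- c(A = "C", C = "A", G = "A", T = "C")
  w <- edit_at(edit_at(w0, 4L, bad[[substr(mir, 4, 4)]]), 15L,
               bad[[substr(mir, 15, 15)]])
  s1 <- score_target_alignment(mir, w)$score[1]
  s2 <- score_target_alignment(chartr("ACGT", "TGCA", mir),
                               chartr("ACGT", "TGCA", w))$score[1]
  expect_equal(s1, s2)
})

test_that("degradome profiles count 5' ends, conserving read mass", {
  set.seed(23)
  tx <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  reads <- data.frame(sequence = substr(tx, 111, 130), count = 6L)
  prof <- build_degradome_profile(reads, tx)
  expect_equal(prof[111], 6L)
  expect_equal(sum(prof), 6L)
  expect_equal(sum(build_degradome_profile(
    data.frame(sequence = strrep("A", 20), count = 3L), tx)), 0L)
  # a read matching twice is counted at both positions
  unit <- substr(tx, 1, 20)
  tx2 <- paste0(tx, unit)
  prof2 <- build_degradome_profile(data.frame(sequence = unit, count = 2L), tx2)
  expect_equal(which(prof2 > 0), c(1L, 201L))
  expect_equal(sum(prof2), 4L)
  # batched builder agrees
  expect_equal(build_degradome_profiles(reads, c(t1 = tx))[["t1"]], prof)
})

test_that("cleavage events require 5 reads exactly opposite miRNA position 10", {
  al <- data.table::data.table(mirna_id = "m1", transcript_id = "t1",
                               start = 100L, end = 120L, score = 0.5,
                               site = 111L)
  prof <- integer(300); prof[111] <- 6L
  ev <- call_cleavage_events(al, list(t1 = prof))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$read_count, 6L)
  prof[111] <- 4L
  expect_equal(nrow(call_cleavage_events(al, list(t1 = prof))), 0L)
  # a large peak away from the predicted site does not validate it
  prof[111] <- 0L; prof[141] <- 50L
  expect_equal(nrow(call_cleavage_events(al, list(t1 = prof))), 0L)
  # site outside the transcript: skipped with a warning
  al$site <- 400L
  expect_warning(ev2 <- call_cleavage_events(al, list(t1 = prof)), "outside")
  expect_equal(nrow(ev2), 0L)
})

test_that("ORF discovery and cleavage-region labels follow the reference ORF", {
  # single unambiguous ORF: the only G in the transcript is in its ATG
  utr5 <- strrep("CA", 50)
  orf <- paste0("ATG", strrep("ACC", 74), "TAA")           # 75 codons, 101-328
  utr3 <- strrep("AC", 75)
  tx <- paste0(utr5, orf, utr3)
  orfs <- find_orfs(tx)
  expect_equal(nrow(orfs), 1L)
  expect_equal(c(orfs$start, orfs$end, orfs$aa), c(101L, 328L, 75L))
  ev <- data.table::data.table(
    mirna_id = "m", transcript_id = "t", site = c(50L, 200L, 328L, 400L),
    read_count = 9L, score = 0, start = 1L, end = 21L)
  lab <- classify_cleavage_regions(ev, c(t = tx))
  expect_equal(lab$region, c("FIVE_UTR", "ORF", "ORF", "THREE_UTR"))
  # ORFs below the codon threshold (ATG included) never qualify
  short_tx <- paste0(utr5, "ATG", strrep("ACC", 68), "TAA", utr3)  # 69 codons
  expect_equal(nrow(find_orfs(short_tx)), 0L)
  expect_equal(nrow(find_orfs(paste0(utr5, "ATG", strrep("ACC", 69), "TAA"))), 1L)
  lab2 <- classify_cleavage_regions(ev, c(t = strrep("TAA", 100)))
  expect_true(all(lab2$region == "UNKNOWN"))
})

test_that("target summaries reproduce targets-per-family arithmetic", {
  mk_events <- function(n_targets, n_families) {
    per <- rep(n_targets %/% n_families, n_families)
    per[seq_len(n_targets %% n_families)] <- per[seq_len(n_targets %% n_families)] + 1L
    data.table::data.table(
      family = rep(sprintf("f%03d", seq_len(n_families)), per),
      transcript_id = sprintf("tx%04d", seq_len(n_targets)))
  }
  s <- summarize_target_results(mk_events(524L, 124L))
  expect_equal(s$n_targets, 524L)
  expect_equal(s$targets_per_family, 4.2)
  expect_equal(round(summarize_target_results(mk_events(122L, 17L))$targets_per_family), 7)
  expect_equal(round(summarize_target_results(mk_events(71L, 17L))$targets_per_family), 4)
  ev <- mk_events(5L, 2L)
  ev$region <- c("ORF", "ORF", "THREE_UTR", "THREE_UTR", "FIVE_UTR")
  s2 <- summarize_target_results(ev)
  expect_equal(unname(s2$region_fractions[c("ORF", "THREE_UTR", "FIVE_UTR")]),
               c(0.4, 0.4, 0.2))
  expect_error(summarize_target_results(ev[0]), "no events")
})
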