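test_that("RP10M normalization scales by mapped totals", {
  m <- matrix(c(5, 10), 1, 2, dimnames = list("m1", c("A", "B")))
  rp <- normalize_rp10m(m, c(A = 5e6, B = 5e6))
  expect_equal(unname(rp[1, ]), c(10, 20))
  # doubling counts and totals leaves the matrix unchanged
  expect_equal(normalize_rp10m(2 * m, c(A = 1e7, B = 1e7)), rp)
  # within-library ratios are conserved
  m2 <- matrix(c(3, 9, 2, 8), 2, 2, dimnames = list(c("a", "b"), c("A", "B")))
  rp2 <- normalize_rp10m(m2, c(A = 123456, B = 7e5))
  expect_equal(rp2["a", ] / rp2["b", ], m2["a", ] / m2["b", ])
  expect_error(normalize_rp10m(m, c(A = 5e6)), "missing mapped totals")
  expect_error(normalize_rp10m(m, c(A = 5e6, B = 0)), "positive")
})

test_that("a full tag set sums to ten million per library after RP10M", {
  sim <- small_sim(seed = 31L, n_pass = 3L, n_each = 0L)
  libs <- setdiff(names(sim$sim$tag_counts), "sequence")
  counts <- as.matrix(sim$sim$tag_counts[, libs, with = FALSE])
  rownames(counts) <- sim$sim$tag_counts$sequence
  rp <- normalize_rp10m(counts, colSums(counts))
  expect_equal(unname(colSums(rp)), rep(1e7, length(libs)))
})

test_that("group abundance test is a Welch t on log10(x + 1)", {
  expect_equal(group_abundance_test(c(3, 3, 3), c(3, 3, 3)),
               list(t = 0, p = 1, df = NA_real_))
  a <- c(100, 110, 90, 105); b <- c(1, 1.2, 0.8, 1.1)
  got <- group_abundance_test(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_lt(got$p, 0.01)
  sw <- group_abundance_test(b, a)
  expect_equal(sw$t, -got$t)
  expect_equal(sw$p, got$p)
})

test_that("tissue-preferential rule arithmetic and monotonicity", {
  rp <- rbind(spec1 = c(GRA8 = 100, GRA15 = 100, SH = 0.5, SR = 0.5),
              pref1 = c(100, 100, 5, 2),
              weak  = c(100, 100, 20, 20),
              zero  = c(0, 0, 0, 0),
              sil1  = c(0.5, 0.2, 80, 90))
  lab <- call_tissue_preferential(rp, c("GRA8", "GRA15"))
  expect_equal(lab$specific, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(lab$preferential, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(lab$silenced, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # raising the fold threshold never adds labels
  for (f in c(20, 50, 200)) {
    lab_f <- call_tissue_preferential(rp, c("GRA8", "GRA15"),
                                      config = pipeline_config(fold_threshold = f))
    expect_true(all(!lab_f$preferential | lab$preferential))
    expect_true(all(!lab_f$specific | lab$specific))
  }
  expect_error(call_tissue_preferential(rp, character(0)), "non-empty")
  expect_error(call_tissue_preferential(rp, colnames(rp)), "not cover all")
})

test_that("planted grain-specific profiles are recovered exactly", {
  ep <- simulate_expression_profiles(seed = 19L)
  rp <- normalize_rp10m(ep$counts, ep$totals)
  lab <- call_tissue_preferential(rp, ep$target)
  expect_equal(lab$specific, ep$truth$class == "specific")
  expect_equal(lab$silenced, ep$truth$class == "silenced")
})

test_that("5' nucleotide bias fractions are hand-countable and normalised", {
  seqs <- c(paste0("A", strrep("C", 23)), paste0("A", strrep("G", 23)),
            paste0("A", strrep("T", 23)),
            paste0("T", strrep("C", 20)), paste0("T", strrep("G", 20)),
            paste0("A", strrep("T", 20)))
  b <- first_nucleotide_bias(seqs)
  expect_equal(b$fraction[b$length == 24 & b$base == "A"], 1)
  expect_equal(b$fraction[b$length == 21 & b$base == "U"], 2 / 3)
  expect_equal(b$fraction[b$length == 21 & b$base == "A"], 1 / 3)
  expect_equal(sum(b$fraction[b$length == 21]), 1)
  bw <- first_nucleotide_bias(seqs, counts = c(1, 1, 1, 8, 1, 1),
                              weighted = TRUE)
  expect_equal(bw$fraction[bw$length == 21 & bw$base == "U"], 0.9)
})

test_that("clustering groups identical columns and planted blocks", {
  ep <- simulate_expression_profiles(seed = 23L)
  rp <- normalize_rp10m(ep$counts, ep$totals)
  cl <- cluster_expression(rp)
  # the grain libraries form one subtree (adjacent leaves)
  pos <- match(ep$target, cl$col_order)
  expect_equal(abs(diff(sort(pos))), 1L)
  # identical columns merge at height 0
  m <- cbind(rp[, 1, drop = FALSE], dup = rp[, 1], rp[, 2:3])
  colnames(m)[1] <- "orig"
  cl2 <- cluster_expression(m)
  h <- cl2$col_hclust
  first <- which.min(h$height)
  expect_equal(sort(colnames(m)[-h$merge[first, ]]), c("dup", "orig"))
  expect_equal(h$height[first], 0, tolerance = 1e-12)
  # row permutation does not change the column dendrogram
  cl3 <- cluster_expression(rp[rev(seq_len(nrow(rp))), ])
  expect_equal(cl3$col_newick, cl$col_newick)
  expect_error(cluster_expression(rp[1, , drop = FALSE]), "at least 2")
  # newick strings parse
  expect_s3_class(ape::read.tree(text = cl$row_newick), "phylo")
})
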