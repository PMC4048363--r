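# Independent oracles used to cross-check the implementation. These are
# deliberately written as direct transcriptions of the definitions (brute
# force where possible), separate from the package's code paths.

# pairing table by innermost-pair elimination on the string
oracle_pairing <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  p <- integer(length(ch))
  work <- ch
  repeat {
    open <- which(work == "(")
    if (!length(open)) break
    done <- FALSE
    for (i in open) {
      rest <- which(work == ")" | work == "(")
      rest <- rest[rest > i]
      if (length(rest) && work[rest[1]] == ")") {
        j <- rest[1]
        p[i] <- j; p[j] <- i
        work[c(i, j)] <- "."
        done <- TRUE
        break
      }
    }
    if (!done) stop("unbalanced structure")
  }
  p
}

# duplex statistics recomputed from the definitions
oracle_duplex <- function(structure, m1, m2) {
  p <- oracle_pairing(structure)
  n <- nchar(structure)
  fail <- list(ok = FALSE)
  paired <- which(p[m1:m2] > 0) + m1 - 1L
  if (!length(paired)) return(fail)
  partners <- p[paired]
  if (any(partners >= m1 & partners <= m2)) return(fail)
  right <- partners > m2
  if (any(right) && any(!right)) return(fail)
  anchors <- paired[paired <= m2 - 2L]
  j1 <- if (length(anchors)) max(anchors) else min(paired)
  j2 <- min(paired)
  lo <- p[j1] - ((m2 - 2L) - j1)
  hi <- p[j2] + (j2 - m1) + 2L
  if (lo < 1L || hi > n || lo >= hi) return(fail)
  if (lo <= m2 && hi >= m1) return(fail)
  mism <- sum(p[m1:m2] == 0)
  events <- 0L; maxlen <- 0L
  if (length(paired) > 1) {
    for (k in 1:(length(paired) - 1L)) {
      gm <- paired[k + 1L] - paired[k] - 1L
      gs <- p[paired[k]] - p[paired[k + 1L]] - 1L
      if (gm != gs) {
        events <- events + 1L
        maxlen <- max(maxlen, abs(gm - gs))
      }
    }
  }
  list(ok = TRUE, star = c(lo, hi), mismatches = mism,
       bulge_events = events, max_bulge_len = maxlen)
}

# brute-force exact matcher, both strands
oracle_scan <- function(tag, genome_string) {
  hits <- list()
  n <- nchar(genome_string); L <- nchar(tag)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
  for (i in seq_len(n - L + 1L)) {
    w <- substr(genome_string, i, i + L - 1L)
    if (w == tag) hits[[length(hits) + 1L]] <- c(i - 1L, "+")
    if (w == rc) hits[[length(hits) + 1L]] <- c(i - 1L, "-")
  }
  hits
}

# per-position penalty table scoring of an ungapped miRNA:target duplex;
# window given 5'->3' on the transcript, miRNA position 1 = its 5' end
oracle_target_score <- function(mirna, window) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- strsplit(mirna, "")[[1]]
  t <- rev(strsplit(window, "")[[1]])   # transcript base opposite position p
  stopifnot(length(m) == length(t))
  score <- 0
  for (pp in seq_along(m)) {
    w <- if (pp >= 2 && pp <= 13) 2 else 1
    if (comp[[m[pp]]] == t[pp]) next
    wob <- (m[pp] == "G" && t[pp] == "T") || (m[pp] == "T" && t[pp] == "G")
    score <- score + w * (if (wob) 0.5 else 1.0)
  }
  score
}

# closed-form Welch t on log10(x + 1)
oracle_welch <- function(a, b) {
  la <- log10(a + 1); lb <- log10(b + 1)
  va <- var(la) / length(la); vb <- var(lb) / length(lb)
  t <- (mean(la) - mean(lb)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(la) - 1) + vb^2 / (length(lb) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, p = p)
}

# independent lineage decision table over the 7-species panel
oracle_lineage <- function(pres) {
  dic <- c("arabidopsis", "soybean")
  mono <- c("rice", "maize", "sorghum", "barley", "brachypodium")
  bep <- c("barley", "brachypodium", "rice")
  on <- names(pres)[pres]
  if (length(intersect(on, dic)) > 0) return("broadly_conserved")
  if (length(on) == 0) return("wheat_specific")
  if (length(setdiff(mono, on)) == 0) return("monocot_wide")
  if (length(on) == 1 && on == "barley") return("wheat_barley")
  if (length(setdiff(on, bep)) == 0) return("bep_clade")
  "monocot_wide"
}

panel_species <- c("arabidopsis", "soybean", "rice", "maize", "sorghum",
                   "barley", "brachypodium")

# small discovery simulation shared by several tests
small_sim <- function(seed = 42L, n_pass = 6L, n_each = 2L) {
  spec <- simulation_spec(
    n_pass_loci = n_pass,
    n_fail_loci = c(length = n_each, count = n_each, overhang = n_each,
                    mismatches = n_each, bulge = n_each, dominance = n_each),
    seed = seed)
  sg <- make_synthetic_genome(spec)
  sim <- simulate_srna_libraries(sg)
  list(sg = sg, sim = sim)
}

truth_vs_candidates <- function(sg, candidates) {
  tr <- sg$truth[sg$truth$kind == "mirna_locus"]
  merge(tr, candidates,
        by.x = c("mature_seq", "seq_id", "start"),
        by.y = c("sequence", "seq_id", "start"))
}
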