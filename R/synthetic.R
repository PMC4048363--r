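# Synthetic study generator: plants hairpin miRNA loci (optionally violating
# a chosen annotation criterion), decoy repeat/rRNA loci, tissue-structured
# read libraries and degradome 5'-end peaks, with a labelled truth table.

#' Simulation specification
#'
#' @param n_pass_loci number of loci designed to pass every criterion.
#' @param n_fail_loci named integer vector of control loci per violated
#'   criterion; names from `length`, `count`, `overhang`, `mismatches`,
#'   `bulge`, `dominance`.
#' @param libraries list of library specs, see [default_libraries()].
#' @param genome_length optional genome size (bp); computed from the content
#'   when `NULL`.
#' @param decoy_repeat_copies tandem copies of the planted repeat unit
#'   (default 501, one more than the copy-number filter threshold).
#' @param decoy_repeat_unit_len repeat unit length (nt).
#' @param spacing distance between planted locus starts (bp).
#' @param seed integer seed fixing all randomness.
#'
#' @return list of class `plantmir_simspec`.
#' @export
simulation_spec <- function(n_pass_loci = 40L,
                            n_fail_loci = c(length = 10L, count = 10L,
                                            overhang = 10L, mismatches = 10L,
                                            bulge = 10L, dominance = 10L),
                            libraries = default_libraries(),
                            genome_length = NULL,
                            decoy_repeat_copies = 501L,
                            decoy_repeat_unit_len = 30L,
                            spacing = 400L,
                            seed = 1L) {
  stopifnot(n_pass_loci >= 0, all(n_fail_loci >= 0), spacing >= 250,
            length(libraries) >= 1)
  ok <- names(n_fail_loci) %in% c("length", "count", "overhang",
                                  "mismatches", "bulge", "dominance")
  if (!all(ok)) stop("unknown violated criterion: ",
                     paste(names(n_fail_loci)[!ok], collapse = ", "))
  for (lib in libraries) {
    stopifnot(!is.null(lib$library_id), lib$depth >= 0,
              lib$dominance >= 0, lib$dominance <= 1)
  }
  out <- list(n_pass_loci = as.integer(n_pass_loci),
              n_fail_loci = n_fail_loci, libraries = libraries,
              genome_length = genome_length,
              decoy_repeat_copies = as.integer(decoy_repeat_copies),
              decoy_repeat_unit_len = as.integer(decoy_repeat_unit_len),
              spacing = as.integer(spacing), seed = as.integer(seed))
  class(out) <- "plantmir_simspec"
  out
}

#' Default synthetic library panel
#'
#' Three tissue libraries (shoot, root, developing grain). Seed-related
#' tissues carry a size-class mix enriched for 22-nt reads, the others for
#' 21-nt reads; 24-nt reads dominate everywhere, as in plant small RNA
#' populations.
#'
#' @param depths read-stack depth per planted locus, per library.
#' @param n_background number of random background tags per library.
#' @return list of library specs.
#' @export
default_libraries <- function(depths = c(SH = 160, SR = 130, GRA8 = 110),
                              n_background = 150L) {
  mix_nonseed <- c(18, 10, 12, 50, 25, 12, 60)  # lengths 18,19,20,21,22,23,24
  mix_seed    <- c(18, 10, 12, 25, 50, 12, 70)
  lens <- c(18:24, 25:30)
  mk <- function(w) {
    m <- c(w, c(6, 8, 4, 3, 2, 2))
    stats::setNames(m / sum(m), lens)
  }
  lapply(names(depths), function(id) {
    list(library_id = id, depth = unname(depths[id]),
         dominance = 0.85,
         size_mix = if (id %in% c("DG", "GSE", "GRA8", "GRA15"))
           mk(mix_seed) else mk(mix_nonseed),
         n_background = as.integer(n_background))
  })
}

.mm_sub <- c(A = "C", C = "A", G = "A", T = "C")  # non-pairing partner

#' Construct a hairpin precursor with a prescribed duplex configuration
#'
#' Builds the precursor stem-outward from the desired miRNA/miRNA* duplex:
#' the mature arm, a short stem extension, an unpairable loop, the star arm
#' (a reverse complement carrying the requested number of non-pairing
#' substitutions and an optional star-side bulge insertion) and a 2-nt tail
#' that forms the star's 3' overhang. The construct is folded and checked so
#' that [evaluate_duplex()] on the result reports exactly the requested
#' configuration; the rare random draw broken by an off-design fold is
#' redrawn.
#'
#' @param mature_len mature length in nt (18-26).
#' @param mismatches number of mature bases left unpaired (0-5 typical).
#' @param bulge_len size of a single star-side asymmetric bulge (0 = none).
#' @param loop_len terminal loop length.
#' @param stem_ext stem extension between the mature 3' end and the loop.
#' @param engine folding engine (see [fold_rna()]).
#' @param max_tries redraw budget before failing.
#'
#' @return list with `precursor`, `mature`, `structure`, `energy`,
#'   `star_span` (1-based on the precursor), `star_read` (canonical, 2-nt
#'   3' overhangs) and `star_read_blunt` (shifted so the duplex is blunt;
#'   used to plant overhang violations).
#' @export
make_hairpin_locus <- function(mature_len = 21L, mismatches = 0L,
                               bulge_len = 0L, loop_len = 8L, stem_ext = 6L,
                               engine = "auto", max_tries = 50L) {
  mature_len <- as.integer(mature_len)
  if (mature_len < 18L || mature_len > 26L)
    stop("mature length must be in 18-26 nt")
  mm_slots <- seq(4L, mature_len - 4L, by = 3L)
  if (mismatches > length(mm_slots))
    stop("infeasible: ", mismatches, " mismatches do not fit in a ",
         mature_len, "-nt mature span")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (try in seq_len(max_tries)) {
    mature <- sample(DNA_BASES, mature_len, replace = TRUE)
    b <- mature_len %/% 2L
    if (bulge_len > 0L)
      mature[(b - 1L):(b + 2L)] <- sample(c("A", "C"), 4L, replace = TRUE)
    star <- rev(unname(comp[mature]))
    if (mismatches > 0L) {
      for (i in mm_slots[seq_len(mismatches)])
        star[mature_len - i + 1L] <- .mm_sub[[mature[i]]]
    }
    if (bulge_len > 0L)
      star <- append(star, rep("A", bulge_len), after = mature_len - b)
    d <- random_dna(stem_ext)
    loop <- random_dna(loop_len, bases = c("A", "C"))
    tail2 <- random_dna(2L, bases = c("A", "C"))
    precursor <- paste0(paste(mature, collapse = ""), d, loop, revcomp(d),
                        paste(star, collapse = ""), tail2)
    fold <- fold_rna(precursor, engine = engine)
    ev <- evaluate_duplex(fold$structure, c(1L, mature_len))
    ok <- ev$ok && ev$stats$mismatches == mismatches &&
      ev$stats$bulge_events == as.integer(bulge_len > 0L) &&
      ev$stats$max_bulge_len == bulge_len &&
      ev$star_span[1] >= 3L && ev$star_span[2] <= nchar(precursor)
    if (ok) {
      return(list(precursor = precursor,
                  mature = paste(mature, collapse = ""),
                  mature_len = mature_len, mismatches = mismatches,
                  bulge_len = bulge_len, structure = fold$structure,
                  energy = fold$energy, star_span = ev$star_span,
                  star_read = substr(precursor, ev$star_span[1], ev$star_span[2]),
                  star_read_blunt = substr(precursor, ev$star_span[1] - 2L,
                                           ev$star_span[2] - 2L)))
    }
  }
  stop("could not realise the requested duplex configuration in ",
       max_tries, " draws (infeasible specification?)")
}

.locus_plan <- function(sim) {
  plans <- list()
  add <- function(violated, n, maker) {
    for (i in seq_len(n)) plans[[length(plans) + 1L]] <<- maker(i, violated)
  }
  add("none", sim$n_pass_loci, function(i, v) {
    list(violated = v, mature_len = sample(c(20L, 21L, 21L, 21L, 22L, 24L), 1L),
         mismatches = if (i %% 7L == 0L) 2L else 0L,
         bulge_len = if (i %% 9L == 0L) 1L else 0L,
         dominance = 0.85, count_profile = "high", star_mode = "canonical")
  })
  makers <- list(
    length = function(i, v) list(violated = v, mature_len = 19L,
      mismatches = 0L, bulge_len = 0L, dominance = 0.85,
      count_profile = "high", star_mode = "canonical"),
    count = function(i, v) list(violated = v, mature_len = 21L,
      mismatches = 0L, bulge_len = 0L, dominance = 0.85,
      count_profile = "low", star_mode = "canonical"),
    overhang = function(i, v) list(violated = v, mature_len = 21L,
      mismatches = 0L, bulge_len = 0L, dominance = 0.85,
      count_profile = "high", star_mode = "blunt"),
    mismatches = function(i, v) list(violated = v, mature_len = 21L,
      mismatches = 5L, bulge_len = 0L, dominance = 0.85,
      count_profile = "high", star_mode = "canonical"),
    bulge = function(i, v) list(violated = v, mature_len = 21L,
      mismatches = 0L, bulge_len = 3L, dominance = 0.85,
      count_profile = "high", star_mode = "canonical"),
    dominance = function(i, v) list(violated = v, mature_len = 21L,
      mismatches = 0L, bulge_len = 0L, dominance = 0.60,
      count_profile = "high", star_mode = "canonical"))
  for (v in names(sim$n_fail_loci))
    add(v, sim$n_fail_loci[[v]], makers[[v]])
  plans
}

#' Generate a synthetic genome with planted miRNA loci, decoys and truth
#'
#' The background is i.i.d. uniform nucleotides. Hairpin precursors built by
#' [make_hairpin_locus()] are planted at regularly spaced, jittered,
#' non-overlapping positions on random strands; a tandem repeat region of
#' `decoy_repeat_copies` unit copies trips the genomic copy-number filter,
#' and a single rRNA-like decoy locus (whose sequence is returned as the
#' decoy catalogue) exercises the annotation filter. Each planted locus is
#' re-checked in its genomic context (the smallest discovery window is
#' folded and evaluated) so that its truth label is guaranteed to
#' round-trip through the discovery module.
#'
#' @param sim a [simulation_spec()].
#' @param config a [pipeline_config()] (folding engine etc.).
#'
#' @return list with `genome` (named character), `truth` (data.table:
#'   `locus_id`, `kind`, `seq_id`, `start`, `end` (0-based half-open),
#'   `strand`, `mature_seq`, `violated_criterion`, `expected_pass`), `loci`
#'   (placement + read-planting details), `decoys`, `repeat_tag`,
#'   `rrna_tag`, and the `spec`.
#' @export
make_synthetic_genome <- function(sim, config = NULL) {
  stopifnot(inherits(sim, "plantmir_simspec"))
  config <- as_config(config)
  with_seed(sim$seed, {
    plans <- .locus_plan(sim)
    n <- length(plans)
    if (n) plans <- plans[sample.int(n)]
    loci <- lapply(plans, function(pl) {
      hp <- make_hairpin_locus(pl$mature_len, pl$mismatches, pl$bulge_len,
                               engine = config$fold_engine)
      c(pl, hp)
    })
    spacing <- sim$spacing
    loci_region <- n * spacing + 200L
    rep_len <- sim$decoy_repeat_copies * sim$decoy_repeat_unit_len
    gl <- loci_region + rep_len + 120L + 1200L
    if (!is.null(sim$genome_length)) {
      if (sim$genome_length < gl)
        stop("genome_length ", sim$genome_length,
             " too small for the planted content (needs >= ", gl, ")")
      gl <- as.integer(sim$genome_length)
    }
    gvec <- sample(DNA_BASES, gl, replace = TRUE)

    place <- function(seqs, at) { # at: 0-based start
      s <- strsplit(seqs, "")[[1]]
      gvec[(at + 1L):(at + length(s))] <<- s
      at
    }
    truth <- list()
    if (n) for (i in seq_len(n)) {
      lc <- loci[[i]]
      plen <- nchar(lc$precursor)
      pos <- 100L + (i - 1L) * spacing + sample.int(spacing - plen - 150L, 1L)
      strand <- sample(c("+", "-"), 1L)
      inserted <- if (strand == "+") lc$precursor else revcomp(lc$precursor)
      place(inserted, pos)
      if (strand == "+") {
        mstart <- pos; mend <- pos + lc$mature_len
      } else {
        mend <- pos + plen; mstart <- mend - lc$mature_len
      }
      loci[[i]]$seq_id <- "chr1"
      loci[[i]]$pstart <- pos; loci[[i]]$pend <- pos + plen
      loci[[i]]$start <- mstart; loci[[i]]$end <- mend
      loci[[i]]$strand <- strand
      loci[[i]]$locus_id <- sprintf("locus%03d", i)
      truth[[i]] <- data.table::data.table(
        locus_id = loci[[i]]$locus_id, kind = "mirna_locus", seq_id = "chr1",
        start = mstart, end = mend, strand = strand,
        mature_seq = lc$mature, violated_criterion = lc$violated,
        expected_pass = identical(lc$violated, "none"))
    }
    # repeat decoy region (tandem)
    rep_unit <- random_dna(sim$decoy_repeat_unit_len)
    rep_start <- loci_region + 200L
    place(paste(rep(rep_unit, sim$decoy_repeat_copies), collapse = ""), rep_start)
    repeat_tag <- substr(rep_unit, 1L, 21L)
    truth[[length(truth) + 1L]] <- data.table::data.table(
      locus_id = "decoy_repeat1", kind = "decoy_repeat", seq_id = "chr1",
      start = rep_start, end = rep_start + rep_len, strand = "+",
      mature_seq = repeat_tag, violated_criterion = "none",
      expected_pass = FALSE)
    # rRNA-like decoy locus, sequence shipped as the decoy catalogue
    rrna <- random_dna(120L)
    rrna_start <- rep_start + rep_len + 400L
    place(rrna, rrna_start)
    rrna_tag <- substr(rrna, 40L, 60L)
    truth[[length(truth) + 1L]] <- data.table::data.table(
      locus_id = "decoy_rrna1", kind = "decoy_rrna", seq_id = "chr1",
      start = rrna_start, end = rrna_start + 120L, strand = "+",
      mature_seq = rrna_tag, violated_criterion = "none",
      expected_pass = FALSE)

    genome <- c(chr1 = paste(gvec, collapse = ""))

    # context check: the fold of the smallest discovery window must realise
    # the designed duplex; re-jitter the local flank on the rare disruption.
    if (n) for (i in seq_len(n)) {
      lc <- loci[[i]]
      want_mm <- lc$mismatches; want_bl <- lc$bulge_len
      for (rep_try in 0:10) {
        hit <- list(seq_id = "chr1", start = lc$start, end = lc$end,
                    strand = lc$strand)
        w <- extract_candidate_windows(hit, genome, config$flank_lengths[1])
        fold <- fold_rna(w$sequence, engine = config$fold_engine)
        ev <- evaluate_duplex(fold$structure, c(w$mature_start, w$mature_end))
        ok <- ev$ok && ev$stats$mismatches == want_mm &&
          ev$stats$bulge_events == as.integer(want_bl > 0L) &&
          ev$stats$max_bulge_len == want_bl
        if (ok) break
        if (rep_try == 10L)
          stop("could not stabilise locus ", lc$locus_id, " in its context")
        for (side in c(-1L, 1L)) {
          rng <- if (side < 0L) (lc$pstart - 60L):(lc$pstart - 1L)
                 else (lc$pend + 1L):(lc$pend + 60L)
          rng <- rng[rng >= 1L & rng <= gl] # 1-based here
          gvec[rng] <- sample(DNA_BASES, length(rng), replace = TRUE)
        }
        genome <- c(chr1 = paste(gvec, collapse = ""))
      }
    }

    list(genome = genome, truth = data.table::rbindlist(truth),
         loci = loci, decoys = c(rrna_decoy_1 = rrna),
         repeat_tag = repeat_tag, rrna_tag = rrna_tag, spec = sim)
  })
}

# strand-resolved genomic substring whose biological 5' end sits at `fivep`
.read_at <- function(genome_vec, fivep, len, strand) {
  if (strand == "+") {
    paste(genome_vec[(fivep + 1L):(fivep + len)], collapse = "")
  } else {
    revcomp(paste(genome_vec[(fivep - len + 2L):(fivep + 1L)], collapse = ""))
  }
}

#' Simulate small RNA read libraries over a synthetic genome
#'
#' For each planted miRNA locus and each library, draws a read stack in the
#' +/-20 nt dominance window: the mature tag with probability equal to the
#' locus's dominance target, and offset "ragged-processing" filler tags
#' otherwise; star reads (canonical, or blunt-shifted for overhang-violation
#' loci) are planted at low abundance on the star arm. Loci violating the
#' read-count criterion instead get 7-18 mature reads per library. Decoy and
#' random background reads complete each library.
#'
#' @param sim_genome result of [make_synthetic_genome()].
#' @param libraries library specs (defaults to those in the simulation spec).
#' @param seed seed for the read-sampling stage.
#' @param config a [pipeline_config()].
#'
#' @return list with `tag_counts` (data.table: `sequence` plus one count
#'   column per library), `reads` (long data.table: `library_id`, `sequence`,
#'   `count`) and `libraries`.
#' @export
simulate_srna_libraries <- function(sim_genome,
                                    libraries = sim_genome$spec$libraries,
                                    seed = sim_genome$spec$seed + 1000L,
                                    config = NULL) {
  if (!length(libraries)) stop("empty library specification")
  config <- as_config(config)
  gvec <- strsplit(sim_genome$genome[[1]], "")[[1]]
  gl <- length(gvec)
  mloci <- Filter(function(l) !is.null(l$start), sim_genome$loci)
  with_seed(seed, {
    rows <- list()
    addr <- function(lib, seqs, counts) {
      keep <- counts > 0
      if (!any(keep)) return(invisible())
      rows[[length(rows) + 1L]] <<- data.table::data.table(
        library_id = lib, sequence = seqs[keep], count = as.integer(counts[keep]))
    }
    mature_starts <- vapply(mloci, function(l)
      if (l$strand == "+") l$start else l$end - 1L, integer(1))
    for (lib in libraries) {
      id <- lib$library_id
      if (lib$depth == 0) next
      for (lc in mloci) {
        fivep <- if (lc$strand == "+") lc$start else lc$end - 1L
        if (lc$count_profile == "low") {
          addr(id, lc$mature, sample(7:18, 1L))
          n_fill <- 5L
        } else {
          total <- max(120L, stats::rpois(1L, lib$depth))
          d <- lc$dominance
          m <- stats::rbinom(1L, total, d)
          addr(id, lc$mature, m)
          n_fill <- total - m
        }
        if (n_fill > 0L) {
          offs <- sample(c(-15:-3, 3:15), 6L)
          lens <- pmin(24L, pmax(19L, lc$mature_len + sample(-1:1, 6L, TRUE)))
          alloc <- as.integer(stats::rmultinom(1L, n_fill, rep(1, 6L)))
          fseq <- vapply(seq_len(6L), function(k)
            .read_at(gvec, fivep + offs[k], lens[k], lc$strand), character(1))
          addr(id, fseq, alloc)
        }
        star <- if (lc$star_mode == "blunt") lc$star_read_blunt else lc$star_read
        addr(id, star, sample(6:15, 1L))
      }
      # decoy-derived reads
      addr(id, sim_genome$repeat_tag, sample(30:60, 1L))
      addr(id, sim_genome$rrna_tag, sample(20:40, 1L))
      # random background
      nb <- lib$n_background
      if (nb > 0L) {
        lens <- as.integer(sample(names(lib$size_mix), nb, TRUE, lib$size_mix))
        pos <- integer(nb)
        for (k in seq_len(nb)) {
          repeat {
            p <- sample.int(gl - 40L, 1L)
            if (!length(mature_starts) ||
                min(abs(p - mature_starts)) > 60L) break
          }
          pos[k] <- p
        }
        bseq <- vapply(seq_len(nb), function(k)
          .read_at(gvec, pos[k], lens[k], "+"), character(1))
        addr(id, bseq, sample(c(1L, 1L, 1L, 2L, 3L), nb, TRUE))
      }
    }
    reads <- data.table::rbindlist(rows)
    reads <- reads[, list(count = sum(count)), by = c("library_id", "sequence")]
    wide <- data.table::dcast(reads, sequence ~ library_id,
                              value.var = "count", fill = 0L)
    # keep all configured libraries as columns, even empty ones
    for (lib in libraries) {
      if (!lib$library_id %in% names(wide))
        wide[, (lib$library_id) := 0L]
    }
    list(tag_counts = wide, reads = reads, libraries = libraries)
  })
}

#' Expand collapsed reads to raw sequencer reads with a 3' adapter
#'
#' Each tag is replicated by its count and concatenated with the adapter,
#' truncated to `read_len` (shorter inserts keep a partial adapter that
#' reaches the read end, as on a real sequencer).
#'
#' @param lib_reads data.table with `sequence` and `count` (one library).
#' @param adapter 3' adapter sequence.
#' @param read_len raw read length.
#' @return character vector of raw reads.
#' @export
as_raw_reads <- function(lib_reads, adapter = pipeline_config()$adapter,
                         read_len = 36L) {
  raw <- paste0(rep(lib_reads$sequence, lib_reads$count), adapter)
  substr(raw, 1L, read_len)
}

#' Simulate degradome (PARE) truth: transcripts, miRNAs and 5'-end reads
#'
#' Each record plants one miRNA binding site (a perfect reverse complement
#' of a random 21-nt miRNA) in the 3' UTR of a transcript carrying a 75-codon
#' ORF, and `peak_reads` degradome reads (20 nt) whose 5' ends sit exactly at
#' the transcript position paired with miRNA position 10. Background reads
#' of count 1 are scattered away from the site.
#'
#' @param site_specs data.frame with columns `transcript_id` and
#'   `peak_reads`; one row per planted site.
#' @param seed integer seed.
#' @param transcript_len transcript length (nt).
#' @param n_background background degradome reads per transcript.
#'
#' @return list with `mirnas` (named character), `transcripts` (named
#'   character), `reads` (data.table `sequence`, `count`) and `truth`
#'   (`mirna_id`, `transcript_id`, `site`, `peak_reads`, `expected_pass`).
#' @export
simulate_degradome_truth <- function(site_specs, seed = 1L,
                                     transcript_len = 600L,
                                     n_background = 25L) {
  stopifnot(all(c("transcript_id", "peak_reads") %in% names(site_specs)))
  min_reads <- pipeline_config()$min_degradome_reads
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L,
                  paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  with_seed(seed, {
    mirnas <- character(0); transcripts <- character(0)
    reads <- list(); truth <- list()
    for (i in seq_len(nrow(site_specs))) {
      tid <- site_specs$transcript_id[i]
      k <- site_specs$peak_reads[i]
      mir <- random_dna(21L)
      mid <- sprintf("mir%03d", i)
      utr5 <- random_dna(100L)
      orf <- paste0("ATG", paste(sample(codons, 74L, TRUE), collapse = ""), "TAA")
      utr3 <- random_dna(transcript_len - 100L - nchar(orf))
      tx <- paste0(utr5, orf, utr3)
      bind_start <- 420L
      bind_end <- bind_start + 20L
      substr(tx, bind_start, bind_end) <- revcomp(mir)
      site <- bind_end - 9L
      if (bind_end > nchar(tx)) stop("binding span outside transcript")
      if (k > 0L)
        reads[[length(reads) + 1L]] <- data.table::data.table(
          sequence = substr(tx, site, site + 19L), count = as.integer(k))
      if (n_background > 0L) {
        pos <- sample(setdiff(seq_len(nchar(tx) - 20L),
                              (site - 10L):(site + 10L)), n_background)
        reads[[length(reads) + 1L]] <- data.table::data.table(
          sequence = vapply(pos, function(p) substr(tx, p, p + 19L),
                            character(1)), count = 1L)
      }
      mirnas[mid] <- mir
      transcripts[tid] <- tx
      truth[[length(truth) + 1L]] <- data.table::data.table(
        mirna_id = mid, transcript_id = tid, site = site,
        peak_reads = as.integer(k), expected_pass = k >= min_reads)
    }
    reads <- data.table::rbindlist(reads)
    reads <- reads[, list(count = sum(count)), by = "sequence"]
    list(mirnas = mirnas, transcripts = transcripts, reads = reads,
         truth = data.table::rbindlist(truth))
  })
}

#' Convenience wrapper: a degradome validation suite with planted truth
#'
#' @param n_pass number of sites with peaks of at least 5 reads.
#' @param n_fail number of control sites with 4-read peaks.
#' @param seed integer seed.
#' @return see [simulate_degradome_truth()].
#' @export
simulate_degradome_study <- function(n_pass = 30L, n_fail = 10L, seed = 1L) {
  peaks <- with_seed(seed,
    c(sample(5:20, n_pass, replace = TRUE), rep(4L, n_fail)))
  site_specs <- data.frame(
    transcript_id = sprintf("tx%03d", seq_len(n_pass + n_fail)),
    peak_reads = peaks)
  simulate_degradome_truth(site_specs, seed = seed + 1L)
}

#' Simulate a tissue expression count matrix with planted profiles
#'
#' Plants grain-specific rows (high in the target tissues, zero outside),
#' grain-silenced rows (zero in the target tissues, expressed outside) and
#' broadly expressed rows, on the standard 11-tissue wheat panel.
#'
#' @param n_broad,n_specific,n_silenced row counts per planted class.
#' @param libraries library (tissue) ids.
#' @param target target tissue set for the specific/silenced classes.
#' @param totals per-library mapped read totals.
#' @param seed integer seed.
#'
#' @return list with `counts` (integer matrix, miRNAs x libraries),
#'   `totals` (named), `truth` (`mirna_id`, `class`) and `target`.
#' @export
simulate_expression_profiles <- function(n_broad = 48L, n_specific = 8L,
                                         n_silenced = 4L,
                                         libraries = c("DG", "GSE", "SH", "SL",
                                                       "SR", "SJ", "YS5", "YS15",
                                                       "FL", "GRA8", "GRA15"),
                                         target = c("GRA8", "GRA15"),
                                         totals = 2e6, seed = 1L) {
  stopifnot(all(target %in% libraries))
  nl <- length(libraries)
  tot <- stats::setNames(rep(totals, nl), libraries)
  with_seed(seed, {
    n <- n_broad + n_specific + n_silenced
    cls <- c(rep("broad", n_broad), rep("specific", n_specific),
             rep("silenced", n_silenced))
    counts <- matrix(0L, n, nl, dimnames = list(sprintf("mir%03d", 1:n),
                                                libraries))
    scale <- totals / 1e7  # counts per RP10M unit
    in_t <- libraries %in% target
    for (i in seq_len(n)) {
      rp <- numeric(nl)
      if (cls[i] == "broad") {
        rp <- stats::rlnorm(1, log(50), 0.8) * stats::rlnorm(nl, 0, 0.4)
      } else if (cls[i] == "specific") {
        rp[in_t] <- stats::runif(1, 150, 500) * stats::rlnorm(sum(in_t), 0, 0.2)
      } else {
        rp[!in_t] <- stats::runif(1, 50, 150) *
          stats::rlnorm(nl - sum(in_t), 0, 0.2)
      }
      cnt <- stats::rpois(nl, rp * scale)
      if (cls[i] != "broad") cnt[cnt > 0] <- pmax(cnt[cnt > 0], 5L)
      counts[i, ] <- as.integer(cnt)
    }
    list(counts = counts, totals = tot,
         truth = data.table::data.table(mirna_id = rownames(counts),
                                        class = cls),
         target = target)
  })
}
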