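#' Map small RNA tags to a genome by exact matching
#'
#' Finds every perfect occurrence of each tag on the forward strand and of
#' its reverse complement on the reverse strand. Coordinates are 0-based
#' half-open on the forward strand of the reference.
#'
#' @param tags character vector of tag sequences (A/C/G/T).
#' @param genome named character vector or `Biostrings::DNAStringSet`.
#'
#' @return A `data.table` with columns `tag`, `seq_id`, `start`, `end`,
#'   `strand` and `fivep` (the genomic coordinate of the biological 5' end).
#' @export
map_tags_exact <- function(tags, genome) {
  tags <- normalize_seq(tags)
  check_dna(tags, "tag")
  g <- if (inherits(genome, "DNAStringSet")) genome
       else Biostrings::DNAStringSet(normalize_seq(genome))
  if (is.null(names(g))) names(g) <- paste0("seq", seq_along(g))
  out <- vector("list", 0L)
  utags <- unique(tags)
  widths <- nchar(utags)
  for (w in sort(unique(widths))) {
    tw <- utags[widths == w]
    pd_fwd <- Biostrings::PDict(Biostrings::DNAStringSet(tw))
    pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(tw)))
    for (chr in names(g)) {
      for (str in c("+", "-")) {
        pd <- if (str == "+") pd_fwd else pd_rev
        mi <- Biostrings::matchPDict(pd, g[[chr]])
        n <- S4Vectors::elementNROWS(mi)
        if (!sum(n)) next
        st <- BiocGenerics::unlist(BiocGenerics::start(mi), use.names = FALSE)
        out[[length(out) + 1L]] <- data.table::data.table(
          tag = rep(tw, n),
          seq_id = chr,
          start = st - 1L,
          end = st - 1L + w,
          strand = str)
      }
    }
  }
  hits <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(tag = character(0), seq_id = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0))
  hits[, "fivep" := ifelse(hits$strand == "+", hits$start, hits$end - 1L)]
  data.table::setkeyv(hits, c("seq_id", "strand", "fivep"))
  hits[]
}

#' Filter mapped tags by genomic copy number and decoy annotation
#'
#' Tags with more than `max_genome_hits` perfect genomic hits are treated as
#' repeat-associated siRNAs (reason `high_copy`); tags contained verbatim (or
#' as reverse complement) in any decoy sequence (rRNA/tRNA/repeat catalogues)
#' are dropped with reason `annotated`. The copy-number threshold is strict:
#' exactly `max_genome_hits` hits is retained.
#'
#' @param tags character vector of tag sequences.
#' @param hits result of [map_tags_exact()] for these tags.
#' @param decoys optional character vector (or `DNAStringSet`) of decoy
#'   sequences.
#' @param config a [pipeline_config()].
#'
#' @return `data.table` with columns `tag`, `n_hits`, `retained`, `reason`.
#' @export
filter_tags <- function(tags, hits, decoys = NULL, config = NULL) {
  config <- as_config(config)
  tags <- unique(normalize_seq(tags))
  cnt <- hits[, list(n_hits = .N), by = "tag"]
  res <- data.table::data.table(tag = tags)
  res <- merge(res, cnt, by = "tag", all.x = TRUE, sort = FALSE)
  res[is.na(res$n_hits), "n_hits" := 0L]
  res[, "reason" := NA_character_]
  res[res$n_hits > config$max_genome_hits, "reason" := "high_copy"]
  if (!is.null(decoys) && length(decoys)) {
    dec <- if (inherits(decoys, "DNAStringSet")) decoys
           else Biostrings::DNAStringSet(normalize_seq(as.character(decoys)))
    subj <- c(dec, Biostrings::reverseComplement(dec))
    open <- which(is.na(res$reason))
    if (length(open)) {
      ann <- vapply(res$tag[open], function(tg) {
        any(Biostrings::vcountPattern(tg, subj) > 0L)
      }, logical(1))
      res[open[ann], "reason" := "annotated"]
    }
  }
  res[, "retained" := is.na(res$reason)]
  res[]
}

#' Extract candidate precursor windows around a genomic hit
#'
#' For each flank length, returns the genomic window `[start - flank,
#' end + flank)` clipped at the sequence ends, strand-resolved so that the
#' mature tag reads 5' to 3' within the returned window sequence.
#'
#' @param hit list or one-row data.frame with `seq_id`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @param genome named character vector or `DNAStringSet`.
#' @param flanks integer vector of flank lengths (nt).
#'
#' @return data.frame with `flank`, `wstart`, `wend` (genomic, 0-based
#'   half-open), `sequence`, and the 1-based `mature_start`/`mature_end`
#'   within the window.
#' @export
extract_candidate_windows <- function(hit, genome, flanks = c(50L, 100L, 150L, 200L)) {
  g <- if (inherits(genome, "DNAStringSet")) genome
       else Biostrings::DNAStringSet(normalize_seq(genome))
  if (is.null(names(g))) names(g) <- paste0("seq", seq_along(g))
  chr_len <- Biostrings::width(g)[match(hit$seq_id, names(g))]
  len <- hit$end - hit$start
  out <- lapply(flanks, function(f) {
    ws <- max(0L, hit$start - f)
    we <- min(chr_len, hit$end + f)
    s <- as.character(Biostrings::subseq(g[[hit$seq_id]], ws + 1L, we))
    if (hit$strand == "+") {
      ms <- hit$start - ws + 1L
    } else {
      s <- revcomp(s)
      ms <- we - hit$end + 1L
    }
    data.frame(flank = f, wstart = ws, wend = we, sequence = s,
               mature_start = ms, mature_end = ms + len - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Evaluate the miRNA/miRNA* duplex on a folded hairpin
#'
#' Given a dot-bracket structure and the mature span, derives the star span
#' from the pairing table under Dicer geometry (`star = [partner(m2 - 2),
#' partner(m1) + 2]`, yielding 2-nt 3' overhangs on both strands) and
#' computes duplex statistics: the number of mature bases not paired to the
#' opposite arm (mismatches), asymmetric bulge events and their maximum
#' size, and the 3' overhang. When no star reads are observed the overhang
#' is 2 by construction; pass the observed star span (window coordinates)
#' via `observed_star` to measure the realised overhang of a sequenced
#' miRNA* instead.
#'
#' Unpaired anchor positions are extrapolated from the nearest paired mature
#' base assuming a locally ungapped helix.
#'
#' @param structure dot-bracket string.
#' @param mature_span integer vector `c(start, end)`, 1-based inclusive on
#'   the folded sequence.
#' @param observed_star optional `c(start, end)` of a star read, 1-based on
#'   the folded sequence.
#'
#' @return list with `ok` (logical), `reason` (`"no_hairpin"` or NA),
#'   `arm` (`"5p"`/`"3p"`), `star_span`, and `stats` (mismatches,
#'   bulge_events, max_bulge_len, overhang_3p).
#' @export
evaluate_duplex <- function(structure, mature_span, observed_star = NULL) {
  n <- nchar(structure)
  m1 <- as.integer(mature_span[1]); m2 <- as.integer(mature_span[2])
  stopifnot(m1 >= 1, m2 <= n, m1 < m2)
  p <- pairing_table(structure)
  reject <- function() list(ok = FALSE, reason = "no_hairpin", arm = NA_character_,
                            star_span = c(NA_integer_, NA_integer_),
                            stats = list(mismatches = NA_integer_,
                                         bulge_events = NA_integer_,
                                         max_bulge_len = NA_integer_,
                                         overhang_3p = NA_integer_))
  mp <- p[m1:m2]
  idx <- (m1:m2)[mp > 0]
  if (!length(idx)) return(reject())
  partners <- p[idx]
  if (any(partners >= m1 & partners <= m2)) return(reject())   # pairs into itself
  if (any(partners > m2) && any(partners < m1)) return(reject()) # spans the loop
  arm <- if (all(partners > m2)) "5p" else "3p"

  j2 <- min(idx)
  cand <- idx[idx <= m2 - 2L]
  j1 <- if (length(cand)) max(cand) else min(idx)
  star_lo <- p[j1] - ((m2 - 2L) - j1)
  star_hi <- p[j2] + (j2 - m1) + 2L
  if (star_lo < 1L || star_hi > n || star_lo >= star_hi) return(reject())
  if (star_lo <= m2 && star_hi >= m1) return(reject())          # overlaps mature

  # after the side-consistency checks every paired mature base pairs into
  # the opposite arm, so mismatches are the unpaired mature bases
  mismatches <- sum(mp == 0)

  dup <- idx
  bulge_events <- 0L; max_bulge_len <- 0L
  if (length(dup) >= 2) {
    for (k in seq_len(length(dup) - 1L)) {
      i <- dup[k]; j <- dup[k + 1L]
      gm <- j - i - 1L
      gs <- p[i] - p[j] - 1L
      if (gm != gs) {
        bulge_events <- bulge_events + 1L
        max_bulge_len <- max(max_bulge_len, abs(gm - gs))
      }
    }
  }
  overhang <- 2L
  if (!is.null(observed_star))
    overhang <- 2L + (as.integer(observed_star[1]) - star_lo)
  list(ok = TRUE, reason = NA_character_, arm = arm,
       star_span = c(star_lo, star_hi),
       stats = list(mismatches = as.integer(mismatches),
                    bulge_events = bulge_events,
                    max_bulge_len = max_bulge_len,
                    overhang_3p = overhang))
}

#' Read dominance of a mature tag within its locus window
#'
#' Fraction of all reads whose biological 5' ends fall within
#' `window` nt of the mature 5' end that belong to the mature tag itself,
#' summed over libraries.
#'
#' @param stack data.frame with columns `tag`, `fivep` (genomic coordinate
#'   of the 5' end) and `count`.
#' @param mature_tag the mature sequence.
#' @param mature_fivep genomic 5'-end coordinate of the mature tag.
#' @param window half-width of the window in nt (default 20).
#'
#' @return fraction in `[0, 1]`, or `NA` if no reads fall in the window.
#' @export
compute_read_dominance <- function(stack, mature_tag, mature_fivep, window = 20L) {
  if (!nrow(stack)) stop("empty read stack")
  inw <- abs(stack$fivep - mature_fivep) <= window
  tot <- sum(stack$count[inw])
  if (tot == 0) return(NA_real_)
  sum(stack$count[inw & stack$tag == mature_tag]) / tot
}

#' Call miRNA loci from collapsed tags and a genome
#'
#' Applies the full annotation procedure: exact mapping, copy-number and
#' decoy filters, the mature length (20-24 nt) and read-count gates (more
#' than 20 reads in at least one library; more than 5 reads in at least two
#' libraries), hairpin folding over increasing flank windows, miRNA/miRNA*
#' duplex criteria (2-nt 3' overhang checked against observed star reads
#' when present, at most 4 mismatched mature bases, at most one asymmetric
#' bulge of at most 2 nt) and at least 70% read dominance within +/-20 nt.
#' Rejected candidates carry the first failed criterion in the fixed order
#' length, count, no_hairpin, overhang, mismatches, bulge, dominance.
#'
#' Every genomic locus of a tag is evaluated independently, so one tag can
#' found several accepted loci. The smallest flank window that yields a
#' qualifying hairpin is reported.
#'
#' @param tag_counts data.frame/data.table with a `sequence` column and one
#'   numeric count column per library.
#' @param genome named character vector or `DNAStringSet`.
#' @param decoys optional decoy sequences for [filter_tags()].
#' @param config a [pipeline_config()].
#'
#' @return list with `candidates` (per tag x locus table with status,
#'   reason, duplex statistics, structure) and `filtered` (the
#'   [filter_tags()] table). Accepted loci are `candidates[status ==
#'   "accepted"]`.
#' @export
call_mirna_loci <- function(tag_counts, genome, decoys = NULL, config = NULL) {
  config <- as_config(config)
  tc <- data.table::as.data.table(tag_counts)
  stopifnot("sequence" %in% names(tc))
  libs <- setdiff(names(tc), "sequence")
  if (!length(libs)) stop("tag_counts must have at least one library column")
  tc[, "sequence" := normalize_seq(tc$sequence)]
  cm <- as.matrix(tc[, libs, with = FALSE])
  rownames(cm) <- tc$sequence
  lens <- nchar(tc$sequence)

  mappable <- lens >= config$map_len[1] & lens <= config$map_len[2] &
    !grepl("[^ACGT]", tc$sequence)
  hits <- map_tags_exact(tc$sequence[mappable], genome)
  filt <- filter_tags(tc$sequence[mappable], hits, decoys, config)
  kept <- filt$tag[filt$retained]
  hits_kept <- hits[hits$tag %in% kept]
  # read stacks from retained tags only (cleaned data)
  total_cnt <- rowSums(cm)
  stacks <- hits_kept[, c("tag", "seq_id", "strand", "fivep"), with = FALSE]
  stacks[, "count" := total_cnt[stacks$tag]]

  g <- if (inherits(genome, "DNAStringSet")) genome
       else Biostrings::DNAStringSet(normalize_seq(genome))
  if (is.null(names(g))) names(g) <- paste0("seq", seq_along(g))

  n_over20 <- rowSums(cm > config$min_reads_one_lib)
  n_over5 <- rowSums(cm > config$min_reads_either)
  need_two <- length(libs) >= 2L

  cand_rows <- list()
  for (tg in intersect(kept, tc$sequence)) {
    L <- nchar(tg)
    th <- hits_kept[hits_kept$tag == tg]
    if (!nrow(th)) next
    base <- list(sequence = tg, length = L,
                 total_reads = unname(total_cnt[tg]),
                 max_lib_reads = max(cm[tg, ]))
    emit <- function(hit_row, status, reason, extra = list()) {
      row <- c(base,
               list(seq_id = hit_row$seq_id, start = hit_row$start,
                    end = hit_row$end, strand = hit_row$strand,
                    status = status, reason = reason),
               extra)
      cand_rows[[length(cand_rows) + 1L]] <<- row
    }
    if (L < config$mature_len[1] || L > config$mature_len[2]) {
      for (hi in seq_len(nrow(th))) emit(th[hi], "rejected", "length")
      next
    }
    if (n_over20[match(tg, tc$sequence)] < 1L ||
        (need_two && n_over5[match(tg, tc$sequence)] < 2L)) {
      for (hi in seq_len(nrow(th))) emit(th[hi], "rejected", "count")
      next
    }
    for (hi in seq_len(nrow(th))) {
      hit <- th[hi]
      wins <- extract_candidate_windows(hit, g, sort(config$flank_lengths))
      first_fail <- NA_character_   # diagnosis of the smallest foldable window
      pass <- NULL
      for (wi in seq_len(nrow(wins))) {
        w <- wins[wi, ]
        fold <- fold_rna(w$sequence, engine = config$fold_engine,
                         min_loop = config$fold_min_loop)
        ev <- evaluate_duplex(fold$structure, c(w$mature_start, w$mature_end))
        if (!ev$ok) next
        # observed star reads near the canonical star 5' end
        star_fivep <- if (hit$strand == "+") w$wstart + ev$star_span[1] - 1L
                      else w$wend - ev$star_span[1]
        near <- stacks[stacks$seq_id == hit$seq_id & stacks$strand == hit$strand &
                       abs(stacks$fivep - star_fivep) <= config$star_search_slop &
                       stacks$tag != tg]
        overhang <- 2L
        star_tag <- NA_character_
        if (nrow(near)) {
          near <- near[which.max(near$count)]
          if (near$count >= config$min_star_reads) {
            star_tag <- near$tag
            obs_lo <- if (hit$strand == "+") near$fivep - w$wstart + 1L
                      else w$wend - near$fivep
            overhang <- 2L + (obs_lo - ev$star_span[1])
          }
        }
        st <- ev$stats
        fail <- if (overhang != config$overhang) "overhang"
          else if (st$mismatches > config$max_duplex_mismatch) "mismatches"
          else if (st$bulge_events > config$max_bulge_events ||
                   st$max_bulge_len > config$max_bulge_len) "bulge"
          else NA_character_
        if (is.na(fail)) {
          pass <- list(w = w, fold = fold, ev = ev, overhang = overhang,
                       star_tag = star_tag)
          break
        }
        if (is.na(first_fail)) first_fail <- fail
      }
      hairpin_extra <- function(pz) list(
        flank = pz$w$flank, window_start = pz$w$wstart, window_end = pz$w$wend,
        precursor = pz$w$sequence, structure = pz$fold$structure,
        energy = pz$fold$energy, arm = pz$ev$arm,
        mature_start = pz$w$mature_start, mature_end = pz$w$mature_end,
        star_start = pz$ev$star_span[1], star_end = pz$ev$star_span[2],
        mismatches = pz$ev$stats$mismatches,
        bulge_events = pz$ev$stats$bulge_events,
        max_bulge_len = pz$ev$stats$max_bulge_len,
        overhang_3p = pz$overhang, star_tag = pz$star_tag)
      if (is.null(pass)) {
        emit(hit, "rejected",
             if (is.na(first_fail)) "no_hairpin" else first_fail)
        next
      }
      dom <- compute_read_dominance(
        stacks[stacks$seq_id == hit$seq_id & stacks$strand == hit$strand],
        tg, hit$fivep, config$dominance_window)
      extra <- c(hairpin_extra(pass), list(dominance = dom))
      if (is.na(dom) || dom < config$dominance_min) {
        emit(hit, "rejected", "dominance", extra)
      } else {
        emit(hit, "accepted", NA_character_, extra)
      }
    }
  }
  candidates <- data.table::rbindlist(cand_rows, fill = TRUE)
  if (nrow(candidates)) data.table::setorderv(candidates, c("seq_id", "start"))
  list(candidates = candidates, filtered = filt, config = config)
}
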