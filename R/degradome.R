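#' Score miRNA:transcript alignments (Allen/CleaveLand-style)
#'
#' Slides the miRNA along the transcript in antisense orientation and scores
#' each window: mismatches and gaps cost 1, G:U wobbles 0.5, with penalties
#' doubled at miRNA positions 2-13 from the 5' end; at most one
#' single-nucleotide bulge per alignment. Windows scoring at most
#' `target_score_max` (default 4.5) are returned, sorted by score.
#'
#' @param mirna a single mature miRNA sequence (20-24 nt).
#' @param transcript a single transcript sequence.
#' @param config a [pipeline_config()].
#'
#' @return data.table with `start`, `end` (1-based inclusive binding span on
#'   the transcript), `score`, `site` (transcript position paired with
#'   miRNA position 10), `mismatches`, `gu_pairs`, `gaps`, `states`
#'   (per-miRNA-position codes: M match, X mismatch, G wobble, - gapped).
#' @export
score_target_alignment <- function(mirna, transcript, config = NULL) {
  config <- as_config(config)
  mirna <- normalize_seq(mirna)
  transcript <- normalize_seq(transcript)
  check_dna(c(mirna, transcript), "alignment input")
  L <- nchar(mirna)
  if (L < 18L || L > 26L) stop("miRNA length out of range: ", L)
  if (nchar(transcript) < L)
    return(data.table::data.table(start = integer(0), end = integer(0),
                                  score = numeric(0), site = integer(0),
                                  mismatches = integer(0), gu_pairs = integer(0),
                                  gaps = integer(0), states = character(0)))
  df <- .target_scan_cpp(mirna, transcript, config$target_score_max,
                         config$mismatch_penalty, config$gu_penalty,
                         config$gap_penalty, config$core_region[1],
                         config$core_region[2], config$max_gap)
  dt <- data.table::as.data.table(df)
  data.table::setorderv(dt, c("score", "start"))
  dt[]
}

#' Degradome 5'-end profile of a transcript (t-plot data)
#'
#' Maps degradome reads to the transcript by exact matching and counts read
#' 5' ends per position; reads mapping several times are counted at every
#' position.
#'
#' @param reads data.frame with `sequence` and `count` (collapsed degradome
#'   tags), or a character vector of raw reads.
#' @param transcript a single transcript sequence.
#' @return integer vector of length `nchar(transcript)`; entry i is the
#'   number of read 5' ends at position i.
#' @export
build_degradome_profile <- function(reads, transcript) {
  transcript <- normalize_seq(transcript)
  if (is.character(reads)) {
    reads <- data.table::as.data.table(table(sequence = reads))
    names(reads)[2] <- "count"
  }
  prof <- integer(nchar(transcript))
  subject <- Biostrings::DNAString(transcript)
  seqs <- normalize_seq(reads$sequence)
  cnts <- as.integer(reads$count)
  widths <- nchar(seqs)
  for (w in unique(widths)) {
    sel <- widths == w
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[sel]))
    mi <- Biostrings::matchPDict(pd, subject)
    n <- S4Vectors::elementNROWS(mi)
    if (!sum(n)) next
    st <- BiocGenerics::unlist(BiocGenerics::start(mi), use.names = FALSE)
    add <- rep(cnts[sel], n)
    for (k in seq_along(st)) prof[st[k]] <- prof[st[k]] + add[k]
  }
  prof
}

#' Degradome 5'-end profiles for a set of transcripts
#'
#' Same as [build_degradome_profile()] but builds the read dictionary once,
#' which is much faster for many transcripts.
#'
#' @param reads data.frame with `sequence` and `count`.
#' @param transcripts named character vector of transcript sequences.
#' @return named list of per-position 5'-end count vectors.
#' @export
build_degradome_profiles <- function(reads, transcripts) {
  seqs <- normalize_seq(reads$sequence)
  cnts <- as.integer(reads$count)
  widths <- nchar(seqs)
  # match against one concatenated subject (transcripts separated by N
  # spacers, which no read can span), then map hits back per transcript
  txs <- normalize_seq(unname(transcripts))
  spacer <- strrep("N", max(widths) + 1L)
  subject <- Biostrings::DNAString(paste(txs, collapse = spacer))
  offsets <- cumsum(c(0L, utils::head(nchar(txs) + nchar(spacer), -1L)))
  out <- lapply(nchar(txs), integer)
  names(out) <- names(transcripts)
  for (w in unique(widths)) {
    sel <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[sel]))
    mi <- Biostrings::matchPDict(pd, subject)
    n <- S4Vectors::elementNROWS(mi)
    if (!sum(n)) next
    st <- BiocGenerics::unlist(BiocGenerics::start(mi), use.names = FALSE)
    add <- rep(cnts[sel], n)
    ti <- findInterval(st, offsets + 1L)
    pos <- st - offsets[ti]
    for (k in seq_along(st))
      out[[ti[k]]][pos[k]] <- out[[ti[k]]][pos[k]] + add[k]
  }
  out
}

#' Call degradome-supported cleavage events
#'
#' For each target alignment the predicted cleavage site is the transcript
#' position paired with miRNA position 10; an event is emitted when the
#' degradome 5'-end profile carries at least `min_degradome_reads` (default
#' 5) reads at the site (optionally within +/- `site_tolerance` nt).
#'
#' @param alignments data.table of alignments (from
#'   [score_target_alignment()]) with added `mirna_id` and `transcript_id`
#'   columns, or a list of such tables.
#' @param profiles named list of per-transcript profiles (from
#'   [build_degradome_profile()]).
#' @param config a [pipeline_config()].
#'
#' @return data.table: `mirna_id`, `transcript_id`, `site`, `read_count`,
#'   `score`, `start`, `end`.
#' @export
call_cleavage_events <- function(alignments, profiles, config = NULL) {
  config <- as_config(config)
  if (is.list(alignments) && !is.data.frame(alignments))
    alignments <- data.table::rbindlist(alignments, fill = TRUE)
  alignments <- data.table::as.data.table(alignments)
  out <- list()
  for (i in seq_len(nrow(alignments))) {
    al <- alignments[i]
    prof <- profiles[[al$transcript_id]]
    if (is.null(prof)) next
    if (al$site < 1L || al$site > length(prof)) {
      warning("cleavage site outside transcript for ", al$transcript_id,
              "; alignment skipped")
      next
    }
    tol <- config$site_tolerance
    lo <- max(1L, al$site - tol); hi <- min(length(prof), al$site + tol)
    rc <- max(prof[lo:hi])
    if (rc >= config$min_degradome_reads)
      out[[length(out) + 1L]] <- data.table::data.table(
        mirna_id = al$mirna_id, transcript_id = al$transcript_id,
        site = al$site, read_count = rc, score = al$score,
        start = al$start, end = al$end)
  }
  if (!length(out))
    return(data.table::data.table(mirna_id = character(0),
                                  transcript_id = character(0),
                                  site = integer(0), read_count = integer(0),
                                  score = numeric(0), start = integer(0),
                                  end = integer(0)))
  ev <- data.table::rbindlist(out)
  # one event per site: keep the best-scoring supporting alignment
  data.table::setorderv(ev, c("mirna_id", "transcript_id", "site", "score"))
  unique(ev, by = c("mirna_id", "transcript_id", "site"))
}

#' Find ATG-initiated ORFs in the three forward frames
#'
#' @param transcript transcript sequence (5' to 3').
#' @param min_aa minimum ORF length in codons, stop excluded (default 70).
#' @return data.table: `start`, `end` (1-based inclusive, stop codon
#'   included), `frame`, `aa` (codons before the stop).
#' @export
find_orfs <- function(transcript, min_aa = 70L) {
  transcript <- normalize_seq(transcript)
  n <- nchar(transcript)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (frame in 0:2) {
    starts <- seq(frame + 1L, n - 2L, by = 3L)
    codons <- substring(transcript, starts, starts + 2L)
    is_stop <- codons %in% stops
    i <- 1L
    while (i <= length(codons)) {
      if (codons[i] == "ATG") {
        j <- i
        while (j <= length(codons) && !is_stop[j]) j <- j + 1L
        if (j <= length(codons)) {           # stop-terminated
          aa <- j - i
          if (aa >= min_aa)
            out[[length(out) + 1L]] <- data.table::data.table(
              start = starts[i], end = starts[j] + 2L, frame = frame, aa = aa)
          i <- j + 1L
        } else i <- i + 1L
      } else i <- i + 1L
    }
  }
  if (!length(out))
    return(data.table::data.table(start = integer(0), end = integer(0),
                                  frame = integer(0), aa = integer(0)))
  data.table::rbindlist(out)
}

#' Classify cleavage sites relative to the reference ORF
#'
#' The reference ORF is the longest qualifying ORF of the transcript; sites
#' upstream of its start codon are `FIVE_UTR`, sites within the ORF
#' (including the stop codon) are `ORF`, sites downstream are `THREE_UTR`.
#' Transcripts with no qualifying ORF yield `UNKNOWN`.
#'
#' @param events cleavage events (see [call_cleavage_events()]).
#' @param transcripts named character vector of transcript sequences.
#' @param config a [pipeline_config()] (`orf_min_aa`).
#' @return the events table with an added `region` column.
#' @export
classify_cleavage_regions <- function(events, transcripts, config = NULL) {
  config <- as_config(config)
  events <- data.table::as.data.table(events)
  region <- character(nrow(events))
  for (tid in unique(events$transcript_id)) {
    orfs <- find_orfs(transcripts[[tid]], config$orf_min_aa)
    sel <- which(events$transcript_id == tid)
    if (!nrow(orfs)) { region[sel] <- "UNKNOWN"; next }
    ref <- orfs[which.max(orfs$aa)]
    s <- events$site[sel]
    region[sel] <- ifelse(s < ref$start, "FIVE_UTR",
                          ifelse(s <= ref$end, "ORF", "THREE_UTR"))
  }
  events[, "region" := region]
  events[]
}

#' Summarise target-calling results per miRNA family
#'
#' Counts unique (family, transcript) pairs as targets, reports the number
#' of targets per family with at least one target (to one decimal place) and
#' the fraction of events per region.
#'
#' @param events cleavage events with a `family` column (and optionally
#'   `region`).
#' @return list with `n_targets`, `n_families`, `targets_per_family` and
#'   `region_fractions`.
#' @export
summarize_target_results <- function(events) {
  events <- data.table::as.data.table(events)
  if (!nrow(events)) stop("no events to summarise")
  stopifnot(all(c("family", "transcript_id") %in% names(events)))
  pairs <- unique(events[, c("family", "transcript_id"), with = FALSE])
  n_targets <- nrow(pairs)
  n_families <- length(unique(pairs$family))
  ratio <- round(n_targets / n_families, 1)
  rf <- NULL
  if ("region" %in% names(events)) {
    tb <- table(events$region)
    rf <- as.numeric(tb) / sum(tb)
    names(rf) <- names(tb)
  }
  list(n_targets = n_targets, n_families = n_families,
       targets_per_family = ratio, region_fractions = rf)
}

#' Base-graphics t-plot of a degradome profile
#'
#' @param profile per-position 5'-end counts (see
#'   [build_degradome_profile()]).
#' @param site optional cleavage site to highlight.
#' @param main plot title.
#' @return invisibly, the profile.
#' @export
plot_tplot <- function(profile, site = NULL, main = "t-plot") {
  graphics::plot(seq_along(profile), profile, type = "h",
                 xlab = "transcript position", ylab = "degradome 5' ends",
                 main = main)
  if (!is.null(site))
    graphics::points(site, profile[site], col = "red", pch = 17)
  invisible(profile)
}
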