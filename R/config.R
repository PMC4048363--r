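#' Pipeline configuration
#'
#' Collects every numeric threshold used across the pipeline. Defaults follow
#' the classical plant miRNA annotation criteria: perfect-match mapping of
#' 18-26 nt tags, removal of tags with more than 500 genomic hits or matching
#' decoy ncRNA/repeat sequences, mature length 20-24 nt, more than 20 reads in
#' at least one library and more than 5 reads in at least two libraries,
#' miRNA/miRNA* duplex with 2-nt 3' overhangs, at most 4 mismatched miRNA
#' bases and at most one asymmetric bulge of at most 2 nt, and at least 70%
#' read dominance within +/-20 nt of the mature 5' end. Degradome settings:
#' alignment score at most 4.5, at least 5 degradome reads at the cleavage
#' site (opposite miRNA position 10), ORFs of at least 70 codons.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A list of class `plantmir_config`.
#' @export
#'
#' @examples
#' cfg <- pipeline_config(dominance_min = 0.8)
#' cfg$dominance_min
pipeline_config <- function(...) {
  cfg <- list(
    # preprocessing
    adapter          = "TCGTATGCCGTCTTCTGCTTG",
    adapter_min_overlap = 8L,
    keep_len         = c(18L, 30L),
    # mapping / filters
    map_len          = c(18L, 26L),
    max_genome_hits  = 500L,
    # mature / locus calling
    mature_len       = c(20L, 24L),
    min_reads_one_lib = 20L,   # strict: count must exceed this in >=1 library
    min_reads_either  = 5L,    # strict: count must exceed this in >=2 libraries
    max_duplex_mismatch = 4L,
    overhang         = 2L,
    max_bulge_len    = 2L,
    max_bulge_events = 1L,
    dominance_min    = 0.70,
    dominance_window = 20L,
    flank_lengths    = c(50L, 100L, 150L, 200L),
    star_search_slop = 4L,
    min_star_reads   = 1L,
    fold_engine      = "auto",
    fold_min_loop    = 3L,
    # conservation
    variant_max_mismatch = 2L,
    conservation_flank   = 200L,
    # degradome / targets
    target_score_max    = 4.5,
    min_degradome_reads = 5L,
    site_tolerance      = 0L,
    orf_min_aa          = 70L,
    mismatch_penalty    = 1.0,
    gu_penalty          = 0.5,
    gap_penalty         = 1.0,
    core_region         = c(2L, 13L),
    max_gap             = 1L,
    # expression
    on_threshold   = 10,
    off_threshold  = 1,
    fold_threshold = 10
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$max_genome_hits > 0, cfg$dominance_min > 0,
            cfg$target_score_max > 0, cfg$min_degradome_reads > 0)
  class(cfg) <- "plantmir_config"
  cfg
}

as_config <- function(config) {
  if (is.null(config)) return(pipeline_config())
  if (inherits(config, "plantmir_config")) return(config)
  do.call(pipeline_config, as.list(config))
}
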