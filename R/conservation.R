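#' Classify mature miRNAs against a known-miRNA catalog
#'
#' A mature sequence is `known` when identical to a catalog entry, a
#' `variant` when some equal-length entry is within `max_mismatch` Hamming
#' distance (the minimum distance is reported), and `novel` otherwise.
#'
#' @param mature character vector of mature sequences.
#' @param catalog named character vector (e.g. read from a miRBase-style
#'   FASTA) of known mature sequences.
#' @param max_mismatch maximum Hamming distance for a variant call.
#'
#' @return data.table: `sequence`, `status` (`known`/`variant`/`novel`),
#'   `mismatches` (0 for known, min distance for variants, NA for novel),
#'   `closest` (catalog id).
#' @export
classify_against_catalog <- function(mature, catalog, max_mismatch = 2L) {
  mature <- normalize_seq(mature)
  if (!length(catalog)) {
    message("empty catalog: all sequences reported as novel")
    return(data.table::data.table(sequence = mature, status = "novel",
                                  mismatches = NA_integer_,
                                  closest = NA_character_))
  }
  catalog <- stats::setNames(normalize_seq(catalog),
                             names(catalog) %||% paste0("cat", seq_along(catalog)))
  catlen <- nchar(catalog)
  res <- lapply(mature, function(m) {
    exact <- which(catalog == m)
    if (length(exact))
      return(list(status = "known", mismatches = 0L,
                  closest = names(catalog)[exact[1]]))
    same <- which(catlen == nchar(m))
    if (length(same)) {
      mv <- strsplit(m, "")[[1]]
      d <- vapply(catalog[same], function(cseq)
        sum(strsplit(cseq, "")[[1]] != mv), integer(1))
      k <- which.min(d)
      if (d[k] <= max_mismatch)
        return(list(status = "variant", mismatches = unname(d[k]),
                    closest = names(catalog)[same[k]]))
    }
    list(status = "novel", mismatches = NA_integer_, closest = NA_character_)
  })
  data.table::data.table(
    sequence = mature,
    status = vapply(res, `[[`, "", "status"),
    mismatches = vapply(res, `[[`, NA_integer_, "mismatches"),
    closest = vapply(res, `[[`, NA_character_, "closest"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Is a mature miRNA present (with a qualifying precursor) in a genome?
#'
#' A mature sequence counts as present in another species when it matches
#' the genome perfectly and at least one window of `flank` nt on each side
#' of a hit folds into a hairpin passing the structural duplex criteria
#' (2-nt 3' overhang by construction, mismatch and bulge limits); read-count
#' criteria are waived since no sequencing data exist for the other species.
#'
#' @param mature a single mature sequence.
#' @param genome named character vector or `DNAStringSet`.
#' @param config a [pipeline_config()] (`conservation_flank`, duplex limits).
#' @return logical.
#' @export
assess_species_presence <- function(mature, genome, config = NULL) {
  config <- as_config(config)
  mature <- normalize_seq(mature)
  hits <- map_tags_exact(mature, genome)
  if (!nrow(hits)) return(FALSE)
  for (hi in seq_len(nrow(hits))) {
    w <- extract_candidate_windows(as.list(hits[hi]), genome,
                                   config$conservation_flank)
    fold <- fold_rna(w$sequence, engine = config$fold_engine,
                     min_loop = config$fold_min_loop)
    ev <- evaluate_duplex(fold$structure, c(w$mature_start, w$mature_end))
    if (!ev$ok) next
    st <- ev$stats
    if (st$mismatches <= config$max_duplex_mismatch &&
        st$bulge_events <= config$max_bulge_events &&
        st$max_bulge_len <= config$max_bulge_len)
      return(TRUE)
  }
  FALSE
}

#' Default species panel for lineage classification
#'
#' Dicot outgroups (Arabidopsis, soybean), the full monocot panel and the
#' BEP-clade members surveyed alongside wheat (barley, Brachypodium, rice).
#' @return list with `dicots`, `monocots`, `bep`.
#' @export
species_panel <- function() {
  list(dicots = c("arabidopsis", "soybean"),
       monocots = c("rice", "maize", "sorghum", "barley", "brachypodium"),
       bep = c("barley", "brachypodium", "rice"))
}

#' Classify the evolutionary lineage of a miRNA from its presence profile
#'
#' Deterministic, total classification of a presence/absence vector over the
#' species panel, in precedence order: present in any dicot =>
#' `broadly_conserved`; absent everywhere => `wheat_specific`; present in
#' all monocots => `monocot_wide`; present in barley only => `wheat_barley`;
#' any other pattern confined to the BEP clade (barley/Brachypodium/rice) =>
#' `bep_clade`; remaining patterns (reaching maize or sorghum without
#' covering all monocots) => `monocot_wide`.
#'
#' @param presence named logical vector over the panel species.
#' @param panel species sets, see [species_panel()].
#' @return one of `wheat_specific`, `wheat_barley`, `bep_clade`,
#'   `monocot_wide`, `broadly_conserved`.
#' @export
classify_lineage <- function(presence, panel = species_panel()) {
  species <- c(panel$dicots, panel$monocots)
  unknown <- setdiff(names(presence), species)
  if (length(unknown)) stop("unknown species id: ",
                            paste(unknown, collapse = ", "))
  missing <- setdiff(species, names(presence))
  if (length(missing)) stop("presence not evaluated for: ",
                            paste(missing, collapse = ", "))
  pres <- names(presence)[presence]
  if (any(pres %in% panel$dicots)) return("broadly_conserved")
  if (!length(pres)) return("wheat_specific")
  if (all(panel$monocots %in% pres)) return("monocot_wide")
  if (identical(pres, "barley")) return("wheat_barley")
  if (all(pres %in% panel$bep)) return("bep_clade")
  "monocot_wide"
}

#' Build presence profiles and lineage classes against a genome panel
#'
#' @param mature named character vector of mature sequences.
#' @param genomes named list of genomes (named character vectors or
#'   `DNAStringSet`), names matching the species panel.
#' @param config a [pipeline_config()].
#' @param panel species sets, see [species_panel()].
#' @return data.table with `mirna_id`, one 0/1 column per species and
#'   `lineage_class`. Species without a supplied genome are scored absent.
#' @export
profile_conservation <- function(mature, genomes, config = NULL,
                                 panel = species_panel()) {
  config <- as_config(config)
  species <- c(panel$dicots, panel$monocots)
  ids <- names(mature) %||% sprintf("mir%03d", seq_along(mature))
  rows <- lapply(seq_along(mature), function(i) {
    pres <- stats::setNames(rep(FALSE, length(species)), species)
    for (sp in intersect(species, names(genomes)))
      pres[sp] <- assess_species_presence(mature[i], genomes[[sp]], config)
    row <- c(list(mirna_id = ids[i]), as.list(as.integer(pres)),
             list(lineage_class = classify_lineage(pres, panel)))
    names(row) <- c("mirna_id", species, "lineage_class")
    row
  })
  data.table::rbindlist(rows)
}
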