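#' Trim a 3' adapter from raw reads
#'
#' The insert is the read prefix before the leftmost exact match to a prefix
#' of the adapter; a match must either cover at least `min_overlap` adapter
#' nucleotides or extend to the read end. No mismatches are tolerated.
#'
#' @param reads character vector of raw reads.
#' @param adapter adapter sequence.
#' @param min_overlap minimum adapter overlap for an internal match.
#' @return character vector of inserts (possibly zero-length strings).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 8L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  n <- nchar(reads)
  cut <- n + 1L                       # trim position (adapter start), none found
  alen <- nchar(adapter)
  maxn <- if (length(n)) max(n) else 0L
  for (i in seq_len(maxn)) {
    open <- cut > n & i <= n          # still untrimmed, position exists
    if (!any(open)) break
    m <- pmin(alen, n - i + 1L)
    cand <- open & (m >= min_overlap | i + m - 1L == n)
    if (!any(cand)) next
    hit <- cand & substring(reads, i, i + m - 1L) == substring(adapter, 1L, m)
    cut[hit] <- i
  }
  substr(reads, 1L, cut - 1L)
}

#' Preprocess raw small RNA reads into collapsed tags
#'
#' Trims the 3' adapter ([trim_adapter()]), discards reads containing
#' non-ACGT characters (counted in the log) and inserts outside the length
#' bounds, and collapses identical inserts into tags with per-library
#' counts.
#'
#' @param raw_reads named list: one character vector of raw reads per
#'   library.
#' @param adapter adapter sequence.
#' @param len_bounds inclusive insert length bounds (default 18-30 nt).
#' @param min_overlap adapter overlap, see [trim_adapter()].
#'
#' @return list with `tags` (data.table: `sequence` plus one count column
#'   per library) and `log` (per-library counts of input, N-discarded,
#'   length-discarded and retained reads).
#' @export
preprocess_reads <- function(raw_reads, adapter = pipeline_config()$adapter,
                             len_bounds = c(18L, 30L), min_overlap = 8L) {
  stopifnot(is.list(raw_reads), length(raw_reads) >= 1,
            !is.null(names(raw_reads)))
  stopifnot(len_bounds[1] >= 15L, len_bounds[2] <= 35L)
  rows <- list(); logs <- list()
  for (lib in names(raw_reads)) {
    reads <- toupper(raw_reads[[lib]])
    if (!length(reads)) stop("library '", lib, "' has no reads")
    badn <- grepl("[^ACGT]", reads)
    ins <- trim_adapter(reads[!badn], adapter, min_overlap)
    L <- nchar(ins)
    inlen <- L >= len_bounds[1] & L <= len_bounds[2]
    kept <- ins[inlen]
    logs[[lib]] <- data.table::data.table(
      library_id = lib, input = length(reads), n_discarded = sum(badn),
      length_discarded = sum(!inlen), retained = length(kept))
    if (length(kept))
      rows[[lib]] <- data.table::data.table(library_id = lib, sequence = kept)
  }
  long <- data.table::rbindlist(rows)
  long <- long[, list(count = .N), by = c("library_id", "sequence")]
  tags <- data.table::dcast(long, sequence ~ library_id,
                            value.var = "count", fill = 0L)
  for (lib in names(raw_reads))
    if (!lib %in% names(tags)) tags[, (lib) := 0L]
  list(tags = tags, log = data.table::rbindlist(logs))
}

#' Per-library tag summaries
#'
#' Computes, for each library, the number of distinct tags, the total read
#' count, the singleton fraction (tags seen exactly once in that library,
#' over distinct tags) and the fraction of reads 20-24 nt long, plus a
#' per-length histogram.
#'
#' @param tags data.table with `sequence` and one count column per library.
#' @param lengths length range to tabulate.
#'
#' @return list with `per_library` (data.table: `library_id`, `distinct`,
#'   `total`, `singleton_fraction`, `frac_20_24`), `histogram`
#'   (`library_id`, `length`, `distinct`, `total`) and `grand`
#'   (`grand_total`, `grand_distinct`).
#' @export
summarize_libraries <- function(tags, lengths = 18:30) {
  tags <- data.table::as.data.table(tags)
  libs <- setdiff(names(tags), "sequence")
  if (!length(libs)) stop("no library columns")
  L <- nchar(tags$sequence)
  per <- list(); hist <- list()
  for (lib in libs) {
    cnt <- tags[[lib]]
    pres <- cnt > 0
    if (!any(pres)) stop("library '", lib, "' has zero reads")
    total <- sum(cnt)
    distinct <- sum(pres)
    per[[lib]] <- data.table::data.table(
      library_id = lib, distinct = distinct, total = total,
      singleton_fraction = sum(cnt == 1L) / distinct,
      frac_20_24 = sum(cnt[L >= 20 & L <= 24]) / total)
    hist[[lib]] <- data.table::data.table(
      library_id = lib, length = lengths,
      distinct = vapply(lengths, function(l) sum(pres & L == l), integer(1)),
      total = vapply(lengths, function(l) sum(cnt[L == l]), numeric(1)))
  }
  per <- data.table::rbindlist(per)
  list(per_library = per, histogram = data.table::rbindlist(hist),
       grand = data.table::data.table(
         grand_total = sum(per$total),
         grand_distinct = sum(rowSums(tags[, libs, with = FALSE]) > 0)))
}

#' Combine published per-library summaries into grand totals
#'
#' For summary tables where only the per-library statistics are available
#' (not the tags themselves), the grand total is the exact integer sum of
#' the per-library totals.
#'
#' @param per_library data.frame with columns `library_id`, `distinct`,
#'   `total`.
#' @return data.table with `n_libraries`, `grand_total`, `sum_distinct`.
#' @export
combine_library_summaries <- function(per_library) {
  stopifnot(all(c("library_id", "total") %in% names(per_library)))
  data.table::data.table(
    n_libraries = nrow(per_library),
    grand_total = sum(as.numeric(per_library$total)),
    sum_distinct = if ("distinct" %in% names(per_library))
      sum(as.numeric(per_library$distinct)) else NA_real_)
}

#' Size-class profile of a tag set
#'
#' Per library, the fraction of distinct tags and the fraction of total
#' reads at each length; both distributions sum to 1 over the tabulated
#' range.
#'
#' @param tags data.table with `sequence` and one count column per library.
#' @param lengths lengths to tabulate (default 18-30 nt).
#' @return data.table: `library_id`, `length`, `distinct_fraction`,
#'   `abundance_fraction`.
#' @export
size_class_profile <- function(tags, lengths = 18:30) {
  s <- summarize_libraries(tags, lengths)
  h <- merge(s$histogram, s$per_library[, c("library_id", "distinct", "total")],
             by = "library_id", suffixes = c("", "_all"))
  data.table::data.table(
    library_id = h$library_id, length = h$length,
    distinct_fraction = h$distinct / h$distinct_all,
    abundance_fraction = h$total / h$total_all)
}
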