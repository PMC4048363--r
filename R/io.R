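# File-format readers and writers (FASTA/FASTQ/collapsed FASTA, GFF3,
# Vienna dot-bracket, TSV, run manifest).

#' Read sequences from FASTA/FASTQ, including the collapsed-FASTA dialect
#'
#' Format is auto-detected from the first character (`@` = FASTQ, `>` =
#' FASTA). Collapsed-FASTA headers of the form `id_x<count>` yield per-record
#' counts (1 otherwise). Sequences are uppercased and U converted to T.
#'
#' @param path input file.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return data.table: `id`, `sequence`, `count`.
#' @export
parse_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1L), 1L, 1L)
    format <- if (first == "@") "fastq" else if (first == ">") "fasta" else
      stop("cannot detect format of ", path, " (line 1)")
  }
  if (format == "fastq") .validate_fastq(path)
  ss <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("malformed ", format, " in ", path, ": ",
                             conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- normalize_seq(as.character(ss))
  cnt <- rep(1L, length(ss))
  m <- regmatches(ids, regexpr("_x[0-9]+$", ids))
  has <- grepl("_x[0-9]+$", ids)
  cnt[has] <- as.integer(sub("_x", "", m))
  data.table::data.table(id = ids, sequence = seqs, count = cnt)
}

# structural check of 4-line FASTQ records, with line numbers on failure
.validate_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed fastq in ", path, ": truncated record at line ",
         length(lines))
  hdr <- seq(1L, length(lines), by = 4L)
  bad <- hdr[!startsWith(lines[hdr], "@")]
  if (length(bad)) stop("malformed fastq in ", path, ": line ", bad[1])
  sep <- hdr + 2L
  bad <- sep[!startsWith(lines[sep], "+")]
  if (length(bad)) stop("malformed fastq in ", path, ": line ", bad[1])
  mism <- hdr[nchar(lines[hdr + 1L]) != nchar(lines[hdr + 3L])]
  if (length(mism))
    stop("malformed fastq in ", path,
         ": sequence/quality length mismatch at line ", mism[1])
  invisible(TRUE)
}

#' Write collapsed FASTA (`>id_x<count>` dialect)
#'
#' @param reads data.frame with `sequence` and `count`.
#' @param path output file.
#' @param prefix tag id prefix.
#' @return the path, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path, prefix = "tag") {
  lines <- paste0(">", prefix, seq_len(nrow(reads)), "_x", reads$count, "\n",
                  reads$sequence)
  writeLines(lines, path)
  invisible(path)
}

#' Write raw reads as FASTQ (Phred+33, constant quality "I")
#'
#' @param reads character vector of raw reads.
#' @param path output file.
#' @param prefix read id prefix.
#' @return the path, invisibly.
#' @export
write_fastq_reads <- function(reads, path, prefix = "read") {
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  lines <- paste0("@", prefix, seq_along(reads), "\n", reads, "\n+\n", qual)
  writeLines(lines, path)
  invisible(path)
}

#' Write accepted miRNA loci (or truth records) as GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 is written 1-based
#' inclusive via `rtracklayer`.
#'
#' @param loci data.frame with `seq_id`, `start`, `end` (0-based half-open),
#'   `strand` and an id column (`locus_id` or `sequence`).
#' @param path output file.
#' @param type GFF3 feature type.
#' @return the path, invisibly.
#' @export
write_loci_gff3 <- function(loci, path, type = "miRNA_primary_transcript") {
  loci <- as.data.frame(loci)
  ids <- if ("locus_id" %in% names(loci)) loci$locus_id
         else sprintf("mir_locus%03d", seq_len(nrow(loci)))
  gr <- GenomicRanges::GRanges(
    seqnames = loci$seq_id,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand)
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$ID <- ids
  if ("sequence" %in% names(loci)) S4Vectors::mcols(gr)$mature <- loci$sequence
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write hairpins in Vienna dot-bracket format
#'
#' Each record is a header line, the sequence, and the structure with the
#' energy in parentheses.
#'
#' @param ids,sequences,structures,energies parallel vectors.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_vienna <- function(ids, sequences, structures, energies, path) {
  lines <- paste0(">", ids, "\n", sequences, "\n", structures,
                  sprintf(" (%.2f)", energies))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest (config snapshot, input digests, seed, counts)
#'
#' @param path output JSON file.
#' @param config the [pipeline_config()] used.
#' @param inputs character vector of input file paths (md5-digested).
#' @param seed the seed used.
#' @param counts named list/vector of per-stage record counts.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config, inputs = character(0),
                               seed = NA_integer_, counts = list()) {
  manifest <- list(
    tool = "plantmir",
    version = as.character(utils::packageVersion("plantmir")),
    seed = seed,
    config = unclass(config),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    counts = counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
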