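#' Normalize raw counts to reads per ten million mapped reads (RP10M)
#'
#' @param counts numeric matrix, miRNAs x libraries.
#' @param totals named numeric vector of per-library mapped read totals
#'   (must cover every column; all positive).
#' @return numeric matrix of RP10M values.
#' @export
normalize_rp10m <- function(counts, totals) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have library column names")
  miss <- setdiff(colnames(counts), names(totals))
  if (length(miss)) stop("missing mapped totals for: ",
                         paste(miss, collapse = ", "))
  tt <- totals[colnames(counts)]
  if (any(!is.finite(tt)) || any(tt <= 0)) stop("mapped totals must be positive")
  sweep(counts, 2, tt, "/") * 1e7
}

#' Welch two-sample test on log-transformed abundances
#'
#' Compares two groups of (RP10M) values on the log10(x + 1) scale with a
#' two-sided Welch t test. Degenerate input (zero variance in both groups
#' with equal means) returns t = 0, p = 1.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with `t`, `p`, `df`.
#' @export
group_abundance_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  la <- log10(a + 1); lb <- log10(b + 1)
  if (stats::var(la) == 0 && stats::var(lb) == 0) {
    if (mean(la) == mean(lb)) return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mean(la) - mean(lb)) * Inf, p = 0, df = NA_real_))
  }
  tt <- stats::t.test(la, lb, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Call tissue-preferential, tissue-specific and tissue-silenced miRNAs
#'
#' With RP10M matrix rows as miRNAs: `preferential` requires mean abundance
#' in the target tissue set of at least `on_threshold` and at least
#' `fold_threshold` times the maximum outside; `specific` additionally
#' requires the maximum outside to stay at or below `off_threshold`;
#' `silenced` requires abundance at or below `off_threshold` throughout the
#' target set and at least `on_threshold` somewhere else.
#'
#' @param rp10m normalized matrix (see [normalize_rp10m()]).
#' @param target character vector of target library ids (non-empty, proper
#'   subset of the columns).
#' @param config a [pipeline_config()] (`on_threshold`, `off_threshold`,
#'   `fold_threshold`).
#' @return data.table: `mirna_id`, `mean_target`, `max_other`,
#'   `preferential`, `specific`, `silenced`.
#' @export
call_tissue_preferential <- function(rp10m, target, config = NULL) {
  config <- as_config(config)
  rp10m <- as.matrix(rp10m)
  if (!length(target) || !all(target %in% colnames(rp10m)))
    stop("target set must be a non-empty subset of the libraries")
  other <- setdiff(colnames(rp10m), target)
  if (!length(other)) stop("target set must not cover all libraries")
  mt <- rowMeans(rp10m[, target, drop = FALSE])
  mo <- apply(rp10m[, other, drop = FALSE], 1, max)
  maxt <- apply(rp10m[, target, drop = FALSE], 1, max)
  on_other <- apply(rp10m[, other, drop = FALSE], 1, max)
  pref <- mt >= config$on_threshold & mt >= config$fold_threshold * mo
  spec <- pref & mo <= config$off_threshold
  sil <- maxt <= config$off_threshold & on_other >= config$on_threshold
  ids <- rownames(rp10m) %||% sprintf("mir%03d", seq_len(nrow(rp10m)))
  data.table::data.table(mirna_id = ids, mean_target = mt, max_other = mo,
                         preferential = pref, specific = spec, silenced = sil)
}

#' 5' nucleotide bias per length class
#'
#' Fraction of A/C/G/U at the first position of mature sequences, per
#' length, on unique sequences (default) or weighted by abundance.
#'
#' @param sequences character vector of mature sequences.
#' @param counts optional abundances for weighting.
#' @param weighted use abundance weighting.
#' @return data.table: `length`, `base` (A/C/G/U), `fraction`.
#' @export
first_nucleotide_bias <- function(sequences, counts = NULL, weighted = FALSE) {
  if (!length(sequences)) stop("no sequences")
  sequences <- normalize_seq(sequences)
  w <- if (weighted) {
    if (is.null(counts)) stop("weighted = TRUE requires counts")
    as.numeric(counts)
  } else rep(1, length(sequences))
  L <- nchar(sequences)
  first <- substr(sequences, 1, 1)
  out <- list()
  for (len in sort(unique(L))) {
    sel <- L == len
    tot <- sum(w[sel])
    for (b in DNA_BASES) {
      out[[length(out) + 1L]] <- data.table::data.table(
        length = len, base = ifelse(b == "T", "U", b),
        fraction = sum(w[sel & first == b]) / tot)
    }
  }
  data.table::rbindlist(out)
}

#' Hierarchical clustering of an expression matrix
#'
#' Agglomerative (average linkage) clustering of rows and columns with
#' distance 1 - Pearson correlation on log2(RP10M + 1); rows or columns with
#' zero variance (undefined correlation) are placed at maximal distance,
#' with a message. Optionally rows are z-scored first. Leaf order is
#' deterministic (ties resolved by input order, as in [stats::hclust()]).
#'
#' @param rp10m normalized matrix with at least 2 rows and 2 columns.
#' @param row_zscore z-score rows before clustering.
#' @return list with `row_hclust`, `col_hclust`, `row_order`, `col_order`,
#'   `row_newick`, `col_newick`.
#' @export
cluster_expression <- function(rp10m, row_zscore = FALSE) {
  m <- log2(as.matrix(rp10m) + 1)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 rows and 2 columns")
  if (is.null(rownames(m))) rownames(m) <- sprintf("r%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%d", seq_len(ncol(m)))
  if (row_zscore) {
    sd <- apply(m, 1, stats::sd)
    m <- (m - rowMeans(m)) / ifelse(sd == 0, 1, sd)
  }
  cordist <- function(x) {
    cc <- suppressWarnings(stats::cor(t(x)))
    if (anyNA(cc)) {
      message("constant rows/columns: correlation undefined, distance set to maximum")
      cc[is.na(cc)] <- -1
    }
    stats::as.dist(1 - cc)
  }
  rh <- stats::hclust(cordist(m), method = "average")
  ch <- stats::hclust(cordist(t(m)), method = "average")
  list(row_hclust = rh, col_hclust = ch,
       row_order = rownames(m)[rh$order], col_order = colnames(m)[ch$order],
       row_newick = ape::write.tree(ape::as.phylo(rh)),
       col_newick = ape::write.tree(ape::as.phylo(ch)))
}
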