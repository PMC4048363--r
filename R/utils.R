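# Shared small helpers.

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(what, " contains non-ACGT characters: ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  invisible(x)
}

normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

random_dna <- function(n, bases = DNA_BASES, prob = NULL) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parse a dot-bracket structure into a pairing table
#'
#' @param structure dot-bracket string (balanced, nested).
#' @return Integer vector `p` of the same length; `p[i]` is the 1-based
#'   partner of position `i`, or 0 when unpaired.
#' @export
#' @examples
#' pairing_table("((..))")
pairing_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  p <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced structure at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    } else if (ch[i] != ".") {
      stop("invalid structure character '", ch[i], "'")
    }
  }
  if (length(stack)) stop("unbalanced structure: ", length(stack), " open bracket(s)")
  p
}
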