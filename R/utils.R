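#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()] that works
#' on plain character vectors (the package's working currency).
#'
#' @param x Character vector of DNA sequences (`ACGTN` alphabet).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGAT"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("invalid alphabet: ", what, " contains characters outside ACGTN",
         call. = FALSE)
  }
  invisible(x)
}

# sample one index from a named probability vector
sample_class <- function(probs, n = 1L) {
  sample(names(probs), n, replace = TRUE, prob = unname(probs))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
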