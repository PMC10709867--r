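#' Alignment scoring scheme
#'
#' Parameters of the three-part junction aligner.  Within each arm the
#' aligner uses affine gaps (a gap of length k scores
#' `gap_open + k * gap_extend`); unmapped middle bases at the junction score
#' `insertion_base_penalty` each; the left and right read parts may share up
#' to `max_overlap` read bases to capture staggered-cut overhangs and
#' junction microhomology; each retained read part must be at least
#' `min_anchor` nt.  Reads whose best decomposition scores below
#' `min_score_frac * match * nchar(read)` are reported unmapped.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0); `N` always scores as a mismatch.
#' @param gap_open,gap_extend Affine gap scores (<= 0).
#' @param insertion_base_penalty Score per unmapped middle base (<= 0).
#'   Must stay milder per base than a gap (`|gap_open + k*gap_extend|`) so
#'   junction insertions are reported as unmapped middle sequence rather
#'   than as gaps inside an arm.  Note a substitution error on the
#'   junction-adjacent base scores better as a 1-bp deletion plus 1-bp
#'   insertion than as a mismatch; at realistic error rates this affects of
#'   order 2% of reads and stays within binomial noise of class counts.
#' @param max_overlap Maximum left/right read-part overlap (nt).  The
#'   default of 3 matches the staggered-cleavage overhang window (1-3 nt 5'
#'   overhangs at positions -4 to -6); it also keeps the overlap score gain
#'   below the minimum gap penalty, so overlap is never used to buy gaps.
#' @param min_anchor Minimum read-part length (nt).
#' @param min_score_frac Mapped-read score threshold as a fraction of the
#'   perfect-match score.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap_open = -4L,
                           gap_extend = -1L, insertion_base_penalty = -1L,
                           max_overlap = 3L, min_anchor = 15L,
                           min_score_frac = 0.6) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            insertion_base_penalty <= 0, max_overlap >= 0, min_anchor >= 1)
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         insertion_base_penalty = as.integer(insertion_base_penalty),
         max_overlap = as.integer(max_overlap),
         min_anchor = as.integer(min_anchor),
         min_score_frac = min_score_frac),
    class = "scoring_scheme")
}

#' Align reads to a junctional reference by three-part decomposition
#'
#' Each read is split into a left part aligned to the upstream arm, a
#' possibly empty unmapped middle insertion, and a right part aligned to the
#' downstream arm.  Each part is aligned globally in the read and locally in
#' its arm (both arm ends free); the distances from the junction-proximal
#' alignment ends to the junction are reported as `del_up` and `del_down`.
#' The split indices are optimized jointly with the per-part alignments, and
#' the two parts may overlap by up to `max_overlap` read bases (overlap bases
#' are scored in both arms, so a single retained copy of junction-flanking
#' homology counts for both).  Score ties are broken in favor of the smallest
#' middle insertion, then the smallest `del_up + del_down`, then the largest
#' overlap, then the leftmost split.
#'
#' @param reads Character vector of reads (ACGTN), optionally named; or a
#'   tibble with columns `read_id` and `seq` as produced by [read_fastq()].
#' @param ref A [build_junction_reference()] object.
#' @param scheme A [scoring_scheme()].
#' @return A tibble with one row per read: split indices `i`/`j` (0-based,
#'   the left part is `read[0,i)` and the right part `read[j,len)`),
#'   `overlap_len`, `middle_insertion`, `del_up`, `del_down`, arm intervals
#'   (0-based half-open), `score`, `strand` and `mapped`.
#' @export
align_junction <- function(reads, ref, scheme = scoring_scheme()) {
  stopifnot(inherits(ref, "junction_reference"))
  reads <- as_read_tibble(reads)
  check_dna(reads$seq, "read")
  too_short <- nchar(reads$seq) < 2L * scheme$min_anchor
  if (any(too_short)) stop("read too short", call. = FALSE)

  res <- purrr::map(reads$seq, function(s) {
    hit <- split_align_cpp(s, ref$upstream_arm, ref$downstream_arm,
                           scheme$match, scheme$mismatch,
                           -scheme$gap_open, -scheme$gap_extend,
                           -scheme$insertion_base_penalty,
                           scheme$max_overlap, scheme$min_anchor)
    hit$middle_insertion <-
      if (hit$j > hit$i) substr(s, hit$i + 1L, hit$j) else ""
    hit
  })

  out <- tibble(
    read_id = reads$read_id,
    strand = "+",
    i = purrr::map_int(res, "i"),
    j = purrr::map_int(res, "j"),
    overlap_len = purrr::map_int(res, "overlap_len"),
    middle_insertion = purrr::map_chr(res, "middle_insertion"),
    del_up = purrr::map_int(res, "del_up"),
    del_down = purrr::map_int(res, "del_down"),
    up_start = purrr::map_int(res, "up_start"),
    up_end = purrr::map_int(res, "up_end"),
    down_start = purrr::map_int(res, "down_start"),
    down_end = purrr::map_int(res, "down_end"),
    score = purrr::map_dbl(res, "score")
  )
  out$mapped <- out$score >= scheme$min_score_frac * scheme$match * nchar(reads$seq)
  out
}

#' Align reads on both strands and keep the better orientation
#'
#' Runs [align_junction()] on each read and on its reverse complement and
#' reports the higher-scoring decomposition, annotated with the strand.
#' Ties prefer the forward strand.
#'
#' @inheritParams align_junction
#' @return As [align_junction()], with `strand` set to `"+"` or `"-"`.
#' @export
align_both_strands <- function(reads, ref, scheme = scoring_scheme()) {
  reads <- as_read_tibble(reads)
  fwd <- align_junction(reads, ref, scheme)
  rev <- align_junction(dplyr::mutate(reads, seq = revcomp(.data$seq)), ref, scheme)
  use_rev <- rev$score > fwd$score
  out <- fwd
  out[use_rev, ] <- rev[use_rev, ]
  out$strand[use_rev] <- "-"
  out
}

#' Exhaustive-split oracle aligner
#'
#' Independent reference implementation used to validate [align_junction()]:
#' enumerates every admissible split pair `(i, j)` and scores each part with
#' [Biostrings::pairwiseAlignment()] (`type = "global-local"`: read part
#' global, arm ends free), then maximizes the combined score exactly as the
#' production aligner defines it.  Intended for short reads only.
#'
#' @inheritParams align_junction
#' @param read A single read (character scalar), at most `max_len` nt.
#' @param max_len Guard against combinatorial blow-up.
#' @return A one-row tibble with `score`, `i`, `j`.
#' @export
brute_force_align <- function(read, ref, scheme = scoring_scheme(),
                              max_len = 60L) {
  stopifnot(length(read) == 1)
  check_dna(read, "read")
  if (nchar(read) > max_len) stop("oracle size exceeded", call. = FALSE)
  R <- nchar(read)
  if (R < 2L * scheme$min_anchor) stop("read too short", call. = FALSE)

  mat <- oracle_substitution_matrix(scheme)
  part_scores <- function(parts, arm) {
    # pairwiseAlignment costs are positive; gap of length k costs open + k*ext
    as.numeric(Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(parts), arm, type = "global-local",
      substitutionMatrix = mat,
      gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend,
      scoreOnly = TRUE))
  }
  is_ <- scheme$min_anchor:R
  js <- 0:(R - scheme$min_anchor)
  lsc <- part_scores(substring(read, 1L, is_), ref$upstream_arm)
  rsc <- part_scores(substring(read, js + 1L, R), ref$downstream_arm)

  best <- -Inf; bi <- NA_integer_; bj <- NA_integer_
  for (a in seq_along(is_)) {
    i <- is_[a]
    for (b in seq_along(js)) {
      j <- js[b]
      if (i - j > scheme$max_overlap) next
      mid <- max(0L, j - i)
      sc <- lsc[a] + rsc[b] + scheme$insertion_base_penalty * mid
      if (sc > best) { best <- sc; bi <- i; bj <- j }
    }
  }
  tibble(score = best, i = bi, j = bj)
}

oracle_substitution_matrix <- function(scheme) {
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(scheme$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- scheme$match
  mat["N", "N"] <- scheme$mismatch # N never matches, not even itself
  mat
}

as_read_tibble <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "seq") %in% names(reads)))
    return(tibble(read_id = as.character(reads$read_id), seq = reads$seq))
  }
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  tibble(read_id = ids, seq = unname(reads))
}
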