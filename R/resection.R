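#' Map reads as two segments against a reference window
#'
#' LAM-HTGTS-style junction mapping: each read is decomposed into a 5' bait
#' segment and a 3' prey segment, both fit-aligned against the supplied
#' reference window on either strand (the bait segment is taken on the
#' forward strand; the prey segment is tried forward and reverse).  The
#' higher-scoring strand combination is reported with reference coordinates
#' (0-based, half-open, forward strand).
#'
#' @param reads Character vector or `read_id`/`seq` tibble.
#' @param ref_seq Reference window (forward strand) containing the expected
#'   cuts; not a genome index — supply the locus window.
#' @param scheme A [scoring_scheme()]; `max_overlap` is forced to 0 here —
#'   segment overlap is a staggered-cleavage concept that has no meaning for
#'   two-segment genome-window mapping, and disabling it makes junction
#'   boundaries resolve to the leftmost (canonical) placement.
#' @return Tibble with one row per read: `seg1_start`, `seg1_end`,
#'   `seg1_strand`, `seg2_start`, `seg2_end`, `seg2_strand`, `score`,
#'   `mapped`.
#' @export
map_read_segments <- function(reads, ref_seq, scheme = scoring_scheme()) {
  reads <- as_read_tibble(reads)
  check_dna(ref_seq, "reference window")
  scheme$max_overlap <- 0L
  W <- nchar(ref_seq)
  ref_fwd <- structure(
    list(kind = "single_cut", label = "fwd", upstream_arm = ref_seq,
         downstream_arm = ref_seq, junction = W),
    class = "junction_reference")
  ref_rev <- ref_fwd
  ref_rev$downstream_arm <- revcomp(ref_seq)
  ref_rev$label <- "rev"

  fwd <- align_junction(reads, ref_fwd, scheme)
  rev <- align_junction(reads, ref_rev, scheme)
  use_rev <- rev$score > fwd$score

  out <- tibble(
    read_id = reads$read_id,
    seg1_start = fwd$up_start,
    seg1_end = fwd$up_end,
    seg1_strand = "+",
    seg2_start = dplyr::if_else(use_rev, W - rev$down_end, fwd$down_start),
    seg2_end = dplyr::if_else(use_rev, W - rev$down_start, fwd$down_end),
    seg2_strand = dplyr::if_else(use_rev, "-", "+"),
    score = dplyr::if_else(use_rev, rev$score, fwd$score)
  )
  out$seg1_start[use_rev] <- rev$up_start[use_rev]
  out$seg1_end[use_rev] <- rev$up_end[use_rev]
  out$mapped <- out$score >= scheme$min_score_frac * scheme$match * nchar(reads$seq)
  out
}

#' Classify two-segment mappings by order and strand
#'
#' Large resections during DNA-fragment deletion require the second (prey)
#' segment to map strictly downstream of the first (bait) segment with both
#' on the forward strand; a prey segment on the reverse strand indicates a
#' large resection during DNA-fragment inversion.  Everything else is
#' unclassified.
#'
#' @param mappings Tibble from [map_read_segments()].
#' @param expected_cuts Numeric length-2: the bait and prey blunt-cut
#'   coordinates (0-based inter-base) in the reference window, used to
#'   compute `resected_nt` — the total distance from the expected cuts to
#'   the observed junction-side boundaries.
#' @return The input with `resection_class` and `resected_nt` columns.
#' @export
classify_resection <- function(mappings, expected_cuts) {
  stopifnot(length(expected_cuts) == 2)
  m <- as_tibble(mappings)
  if (any(!m$mapped)) {
    # classification below marks these unclassified; a lone unmapped segment
    # in a single-row call is a caller error
    if (nrow(m) == 1) stop("incomplete mapping", call. = FALSE)
  }
  c_bait <- expected_cuts[1]; c_prey <- expected_cuts[2]
  m$resection_class <- dplyr::case_when(
    !m$mapped ~ "unclassified",
    m$seg1_strand == "+" & m$seg2_strand == "+" &
      m$seg2_start > m$seg1_end ~ "deletion_type",
    m$seg1_strand == "+" & m$seg2_strand == "-" ~ "inversion_type",
    TRUE ~ "unclassified"
  )
  m$resected_nt <- dplyr::case_when(
    m$resection_class == "deletion_type" ~
      pmax(0, c_bait - m$seg1_end) + pmax(0, m$seg2_start - c_prey),
    m$resection_class == "inversion_type" ~
      pmax(0, c_bait - m$seg1_end) + pmax(0, c_prey - m$seg2_end),
    TRUE ~ NA_real_
  )
  m
}

#' Fraction of large-resection reads in a library
#'
#' The ratio of reads classified as deletion- or inversion-type with more
#' than `threshold` resected nt to the total number of reads.
#'
#' @param classified Tibble from [classify_resection()].
#' @param total_reads Total reads in the library.
#' @param threshold Minimum resected nt to count as a large resection.
#' @return A fraction in `[0, 1]`.
#' @export
resection_fraction <- function(classified, total_reads,
                               threshold = LARGE_RESECTION_NT) {
  if (total_reads <= 0) stop("empty library", call. = FALSE)
  if (total_reads < nrow(classified)) stop("inconsistent totals", call. = FALSE)
  hits <- classified$resection_class %in% c("deletion_type", "inversion_type") &
    !is.na(classified$resected_nt) & classified$resected_nt > threshold
  sum(hits) / total_reads
}

#' Simulate a LAM-HTGTS-style resection library
#'
#' Generates reads from a reference window with two cuts: `none` reads span
#' the bait cut without rearrangement, `deletion` reads join the bait
#' segment to sequence `resected` nt beyond the prey cut on the forward
#' strand, and `inversion` reads join it to the reverse complement of the
#' fragment end resected by the same amount.
#'
#' @param ref_seq Reference window (>= 2 * `seg_len` + max resection + cut
#'   span).
#' @param cuts Numeric length-2 bait/prey cut coordinates (0-based).
#' @param n_reads Number of reads.
#' @param mixture Named probabilities over `none`, `deletion`, `inversion`.
#' @param resection_range Range of resected nt for rearranged reads.
#' @param seg_len Bait/prey segment length (nt).
#' @param seed RNG seed.
#' @return List with `reads` and `truth` tibbles.
#' @export
simulate_resection_library <- function(ref_seq, cuts, n_reads = 1000L,
                                       mixture = c(none = 0.98, deletion = 0.01,
                                                   inversion = 0.01),
                                       resection_range = c(101L, 150L),
                                       seg_len = 60L, seed = 1L) {
  if (abs(sum(mixture) - 1) > 1e-9) stop("invalid mixture", call. = FALSE)
  W <- nchar(ref_seq)
  c1 <- cuts[1]; c2 <- cuts[2]
  stopifnot(c1 >= seg_len, c2 + resection_range[2] + seg_len <= W,
            c2 - resection_range[2] - seg_len >= 0)
  set.seed(seed)
  classes <- sample_class(mixture, n_reads)
  # note: when the bait tail happens to match the sequence just left of the
  # prey start, the reported junction slides left; the slide moves one base
  # between the bait-shortfall and prey-excess terms of resected_nt, whose
  # sum — the value recorded here — is invariant
  rows <- purrr::map(seq_len(n_reads), function(idx) {
    cls <- classes[idx]
    bait <- substr(ref_seq, c1 - seg_len + 1L, c1)
    if (cls == "none") {
      seq <- paste0(bait, substr(ref_seq, c1 + 1L, c1 + seg_len))
      r <- 0L
    } else {
      r <- sample(resection_range[1]:resection_range[2], 1L)
      if (cls == "deletion") {
        prey <- substr(ref_seq, c2 + r + 1L, c2 + r + seg_len)
      } else {
        prey <- revcomp(substr(ref_seq, c2 - r - seg_len + 1L, c2 - r))
      }
      seq <- paste0(bait, prey)
    }
    list(cls = cls, r = as.integer(r), seq = seq)
  })
  ids <- sprintf("res%06d", seq_len(n_reads))
  list(
    reads = tibble(read_id = ids, seq = purrr::map_chr(rows, "seq"),
                   qual = strrep("I", nchar(purrr::map_chr(rows, "seq")))),
    truth = tibble(read_id = ids,
                   sim_class = purrr::map_chr(rows, "cls"),
                   resected_nt = purrr::map_int(rows, "r"))
  )
}
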