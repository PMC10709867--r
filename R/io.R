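#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (gzip-compressed accepted).
#' @return Tibble with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = sub(" .*", "", names(x)),
    seq = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with `read_id`, `seq` and optionally `qual`
#'   (constant Q40 `"I"` otherwise).
#' @param path Output path; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual %||% strrep("I", nchar(reads$seq))
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Demultiplex reads by barcode prefix
#'
#' Assigns each read to the sample whose barcode matches the read prefix
#' (exactly by default, or within one mismatch when `max_mismatch = 1` and
#' the nearest barcode is unique), trims the barcode, and routes everything
#' else to the `"undetermined"` bin.
#'
#' @param reads Tibble with `read_id`, `seq` (and optionally `qual`).
#' @param manifest Tibble with columns `sample` and `barcode` (all barcodes
#'   the same length, unique).
#' @param max_mismatch 0 or 1 allowed barcode mismatches.
#' @return The reads tibble with a `sample` column and barcodes trimmed
#'   from `seq` (and `qual`) for assigned reads.
#' @export
demultiplex <- function(reads, manifest, max_mismatch = 0L) {
  stopifnot(all(c("sample", "barcode") %in% names(manifest)),
            max_mismatch %in% c(0L, 1L))
  bc <- manifest$barcode
  if (anyDuplicated(bc)) stop("manifest conflict", call. = FALSE)
  blen <- unique(nchar(bc))
  if (length(blen) != 1) stop("barcodes must share one length", call. = FALSE)

  prefixes <- substr(reads$seq, 1L, blen)
  assign_one <- function(prefix) {
    d <- hamming_to(prefix, bc)
    hits <- which(d <= max_mismatch)
    if (length(hits) == 1) return(hits)
    if (length(hits) > 1) {
      best <- hits[d[hits] == min(d[hits])]
      if (length(best) == 1) return(best) # unique nearest
    }
    NA_integer_
  }
  idx <- vapply(prefixes, assign_one, integer(1), USE.NAMES = FALSE)

  out <- reads
  out$sample <- dplyr::if_else(is.na(idx), "undetermined", manifest$sample[idx])
  keep <- !is.na(idx)
  out$seq[keep] <- substr(out$seq[keep], blen + 1L, nchar(out$seq[keep]))
  if ("qual" %in% names(out)) {
    out$qual[keep] <- substr(out$qual[keep], blen + 1L, nchar(out$qual[keep]))
  }
  out
}

hamming_to <- function(prefix, barcodes) {
  pc <- strsplit(prefix, NULL)[[1]]
  vapply(strsplit(barcodes, NULL), function(b) sum(b != pc[seq_along(b)]), 0)
}

#' Merge a read pair by best ungapped overlap
#'
#' Naive paired-end merging: read 2 is reverse-complemented and slid over
#' read 1; the suffix/prefix overlap with the most matches is accepted when
#' it is at least `min_overlap` nt with a mismatch fraction of at most
#' `max_mismatch_frac`.  Disagreements inside the overlap are resolved by
#' the higher base quality.
#'
#' @param read1,read2 Sequences (character scalars); `read2` in sequencer
#'   orientation (it is reverse-complemented here).
#' @param qual1,qual2 Phred+33 quality strings (optional; defaults favor
#'   read 1).
#' @param min_overlap Minimum acceptable overlap (nt).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap.
#' @return The merged sequence, or `NA_character_` when no acceptable
#'   overlap exists (failure is a value, not an error).
#' @export
merge_pairs <- function(read1, read2, qual1 = NULL, qual2 = NULL,
                        min_overlap = 10L, max_mismatch_frac = 0.1) {
  r2 <- revcomp(read2)
  q2 <- if (!is.null(qual2)) reverse_chars(qual2) else strrep("!", nchar(r2))
  q1 <- qual1 %||% strrep("I", nchar(read1))
  l1 <- nchar(read1); l2 <- nchar(r2)
  if (min(l1, l2) < min_overlap) return(NA_character_)

  best_o <- 0L; best_matches <- -1L
  for (o in seq.int(min(l1, l2), min_overlap)) {
    s1 <- substr(read1, l1 - o + 1L, l1)
    s2 <- substr(r2, 1L, o)
    m <- sum(strsplit(s1, NULL)[[1]] == strsplit(s2, NULL)[[1]])
    if (m > best_matches && (o - m) / o <= max_mismatch_frac) {
      best_matches <- m; best_o <- o
    }
  }
  if (best_o < min_overlap) return(NA_character_)

  o <- best_o
  c1 <- strsplit(substr(read1, l1 - o + 1L, l1), NULL)[[1]]
  c2 <- strsplit(substr(r2, 1L, o), NULL)[[1]]
  p1 <- utf8ToInt(substr(q1, l1 - o + 1L, l1))
  p2 <- utf8ToInt(substr(q2, 1L, o))
  cons <- ifelse(c1 == c2, c1, ifelse(p1 >= p2, c1, c2))
  paste0(substr(read1, 1L, l1 - o),
         paste(cons, collapse = ""),
         substr(r2, o + 1L, l2))
}

#' Run the junction-analysis pipeline for a multiplexed library
#'
#' Demultiplexes reads by barcode, aligns each sample's reads to its
#' junctional reference on both strands, classifies the outcomes, and
#' tallies per-sample frequencies.  Deterministic given its inputs.
#'
#' @param reads Tibble with `read_id`, `seq` (and `qual`), e.g. from
#'   [read_fastq()].
#' @param manifest Tibble with columns `sample`, `barcode`, `ref_label`.
#' @param refs Named list of [build_junction_reference()] objects covering
#'   every `ref_label`.
#' @param scheme A [scoring_scheme()].
#' @param max_mismatch Barcode mismatches allowed (see [demultiplex()]).
#' @return List with `tallies` (one [glance()] row per sample), `outcomes`
#'   (per-read classification, all samples), `tally_objects`, and `log`
#'   (per-stage read counts).
#' @export
run_pipeline <- function(reads, manifest, refs, scheme = scoring_scheme(),
                         max_mismatch = 0L) {
  stopifnot(all(c("sample", "barcode", "ref_label") %in% names(manifest)))
  missing_refs <- setdiff(manifest$ref_label, names(refs))
  if (length(missing_refs) > 0) {
    stop("manifest references unknown reference label(s): ",
         paste(missing_refs, collapse = ", "), call. = FALSE)
  }
  if (nrow(reads) == 0) {
    empty <- tibble(sample = manifest$sample, total_reads = 0L,
                    junction_reads = 0L, repaired_fraction = NA_real_)
    return(list(tallies = empty, outcomes = tibble(), tally_objects = list(),
                log = tibble(stage = "input", reads = 0L)))
  }

  demuxed <- demultiplex(reads, manifest, max_mismatch)
  log <- tibble(stage = c("input", "assigned"),
                reads = c(nrow(reads), sum(demuxed$sample != "undetermined")))

  per_sample <- manifest |>
    dplyr::rowwise() |>
    dplyr::group_split() |>
    purrr::map(function(row) {
      sub <- demuxed[demuxed$sample == row$sample, ]
      ref <- refs[[row$ref_label]]
      if (nrow(sub) == 0) {
        return(list(sample = row$sample,
                    tally = tally_outcomes(
                      classify_outcomes(empty_alignment(), ref), 0L),
                    outcomes = tibble()))
      }
      usable <- sub[nchar(sub$seq) >= 2L * scheme$min_anchor, ]
      al <- if (nrow(usable) > 0) align_both_strands(usable, ref, scheme)
            else empty_alignment()
      out <- classify_outcomes(al, ref)
      out$sample <- rep(row$sample, nrow(out))
      list(sample = row$sample,
           tally = tally_outcomes(out, total_reads = nrow(sub)),
           outcomes = out)
    })

  tallies <- purrr::map(per_sample, function(p) {
    dplyr::mutate(glance(p$tally), sample = p$sample, .before = 1)
  }) |> bind_rows()

  list(
    tallies = tallies,
    outcomes = purrr::map(per_sample, "outcomes") |> bind_rows(),
    tally_objects = setNames(purrr::map(per_sample, "tally"),
                             purrr::map_chr(per_sample, "sample")),
    log = log
  )
}

empty_alignment <- function() {
  tibble(read_id = character(0), strand = character(0), i = integer(0),
         j = integer(0), overlap_len = integer(0),
         middle_insertion = character(0), del_up = integer(0),
         del_down = integer(0), up_start = integer(0), up_end = integer(0),
         down_start = integer(0), down_end = integer(0),
         score = numeric(0), mapped = logical(0))
}

#' Write a tally to TSV and JSON
#'
#' @param tally A [tally_outcomes()] object.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return `tally`, invisibly.
#' @export
write_tally <- function(tally, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(tidy(tally), tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(summary = as.list(glance(tally)),
           categories = tally$categories,
           del_bins = tally$del_bins),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tally)
}

#' Read a pipeline configuration file
#'
#' YAML with optional keys `scoring` (any [scoring_scheme()] argument) and
#' `pipeline` (`max_mismatch`, `large_resection_nt`); missing keys fall
#' back to package defaults.
#'
#' @param path YAML path.
#' @return List with `scheme` and `pipeline`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path) %||% list()
  scheme <- do.call(scoring_scheme, cfg$scoring %||% list())
  pipeline <- utils::modifyList(
    list(max_mismatch = 0L, large_resection_nt = LARGE_RESECTION_NT),
    cfg$pipeline %||% list())
  list(scheme = scheme, pipeline = pipeline)
}
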