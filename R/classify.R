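#' Test whether an insertion matches a predicted staggered-cut fill-in
#'
#' A 1-3 nt insertion is *templated* when it equals the sequence duplicated
#' by fill-in of a k-nt 5' overhang of either junction-side guide, i.e. the
#' bases at PAM-relative positions -4 to -(3+k).  Because the orientation of
#' the duplicated bases at inversion/duplication junctions is not defined a
#' priori, the comparison accepts the predicted overhang in either reading
#' order on either strand.
#'
#' @param insertion Inserted sequence (character scalar, >= 1 nt).
#' @param ref A [build_junction_reference()] object.
#' @return A list with `templated` (logical), `k` (matched overhang length,
#'   0 when untemplated), and `matched` (`"up"`, `"down"` or `NA`).
#' @export
is_templated_insertion <- function(insertion, ref) {
  stopifnot(length(insertion) == 1)
  k <- nchar(insertion)
  if (k < 1L) stop("insertion must be non-empty", call. = FALSE)
  if (k > 3L) return(list(templated = FALSE, k = 0L, matched = NA_character_))
  for (side in c("up", "down")) {
    g <- ref$guides[[side]]
    if (k > g$max_overhang) next
    ov <- predicted_overhang(g, k)
    variants <- unique(c(ov, reverse_chars(ov), revcomp(ov), revcomp(reverse_chars(ov))))
    if (insertion %in% variants) {
      return(list(templated = TRUE, k = as.integer(k), matched = side))
    }
  }
  list(templated = FALSE, k = 0L, matched = NA_character_)
}

reverse_chars <- function(x) {
  vapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Classify junction alignments into repair-outcome categories
#'
#' Converts the output of [align_junction()] / [align_both_strands()] into
#' the four junctional repair-outcome groups: `precise` (no inserted or
#' deleted bases), `deletion`, `insertion`, and `indel`; unmapped reads are
#' labeled `unmapped`.  Overlap bases (junction-flanking homology present
#' once in the read but attributable to both arms) are counted as deleted
#' sequence and attributed to the downstream arm (left-aligned retention),
#' so `del_total` is the physical number of missing bases.  Deletion sizes
#' are binned as 1 bp, 2-20 bp, 21-100 bp and >100 bp (large resection), and
#' deleted positions are reported PAM-relative per arm (e.g. -4, -5, -6 for
#' junction-adjacent staggered-overhang positions).
#'
#' @param alignments Tibble from [align_junction()] or
#'   [align_both_strands()].
#' @param ref The [build_junction_reference()] the reads were aligned to.
#' @param large_resection_nt Deletions longer than this are binned `">100"`
#'   and counted as large resections.
#' @return The input tibble with columns `category`, `del_total`, `del_bin`,
#'   `ins_len`, `templated`, `templated_k`, and a list-column
#'   `del_positions`.
#' @export
classify_outcomes <- function(alignments, ref,
                              large_resection_nt = LARGE_RESECTION_NT) {
  stopifnot(inherits(ref, "junction_reference"))
  al <- as_tibble(alignments)
  # fold overlap into the downstream deletion: the read retains one copy of
  # the shared junction sequence, attributed to the upstream arm
  del_dn_eff <- al$del_down + al$overlap_len
  del_total <- al$del_up + del_dn_eff
  ins_len <- nchar(al$middle_insertion)

  tmpl <- purrr::map(al$middle_insertion, function(ins) {
    if (nchar(ins) >= 1L) is_templated_insertion(ins, ref)
    else list(templated = FALSE, k = 0L)
  })

  al$category <- dplyr::case_when(
    !al$mapped ~ "unmapped",
    del_total == 0L & ins_len == 0L ~ "precise",
    del_total > 0L & ins_len == 0L ~ "deletion",
    del_total == 0L & ins_len > 0L ~ "insertion",
    TRUE ~ "indel"
  )
  al$del_total <- dplyr::if_else(al$mapped, del_total, NA_integer_)
  al$del_bin <- del_size_bin(al$del_total, large_resection_nt)
  al$ins_len <- dplyr::if_else(al$mapped, ins_len, NA_integer_)
  al$templated <- purrr::map_lgl(tmpl, "templated") & al$mapped
  al$templated_k <- dplyr::if_else(al$mapped, purrr::map_int(tmpl, "k"), NA_integer_)
  al$del_positions <- purrr::pmap(
    list(al$del_up, del_dn_eff, al$mapped),
    function(du, dd, ok) {
      if (!ok) return(integer(0))
      c(utils::head(ref$arm_pam$up, du), utils::head(ref$arm_pam$down, dd))
    })
  al
}

del_size_bin <- function(del_total, large_resection_nt = LARGE_RESECTION_NT) {
  dplyr::case_when(
    is.na(del_total) | del_total == 0L ~ NA_character_,
    del_total == 1L ~ "1",
    del_total <= 20L ~ "2-20",
    del_total <= large_resection_nt ~ "21-100",
    TRUE ~ ">100"
  )
}

#' Profile of deleted PAM-relative positions
#'
#' Tabulates which PAM-relative positions were removed among small (1-3 bp
#' by default) deletions — the signature of staggered Cas9 cleavage is a
#' strong bias toward positions -4, -5 and -6 upstream of the PAM.
#'
#' @param outcomes Tibble from [classify_outcomes()].
#' @param max_del Only deletions of at most this many nt contribute.
#' @return A tibble with columns `position` and `count`, sorted by position.
#' @export
deletion_position_profile <- function(outcomes, max_del = 3L) {
  keep <- outcomes$category == "deletion" &
    !is.na(outcomes$del_total) &
    outcomes$del_total >= 1L & outcomes$del_total <= max_del
  pos <- unlist(outcomes$del_positions[keep])
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0) {
    return(tibble(position = integer(0), count = integer(0)))
  }
  tibble(position = pos) |>
    dplyr::count(.data$position, name = "count") |>
    dplyr::arrange(.data$position)
}

#' Tally outcome categories and deletion-size bins for one library
#'
#' Computes per-library counts and frequencies: category frequencies among
#' junction (mapped) reads, deletion-size bin frequencies, the repaired
#' fraction (junction reads / total reads), and the large-resection fraction
#' (deletions > 100 nt / total reads).
#'
#' @param outcomes Tibble from [classify_outcomes()] for one library.
#' @param total_reads Total reads in the library (>= number of mapped
#'   reads); defaults to `nrow(outcomes)`.
#' @return An object of class `junction_tally` with [tidy()] and [glance()]
#'   methods.
#' @export
tally_outcomes <- function(outcomes, total_reads = nrow(outcomes)) {
  mapped <- outcomes[outcomes$category != "unmapped", ]
  junction_reads <- nrow(mapped)
  if (total_reads < junction_reads) stop("inconsistent totals", call. = FALSE)

  cats <- c("precise", "deletion", "insertion", "indel")
  cat_counts <- table(factor(mapped$category, levels = cats))
  categories <- tibble(
    category = cats,
    count = as.integer(cat_counts),
    frequency = if (junction_reads > 0) as.integer(cat_counts) / junction_reads else 0
  )

  bins <- c("1", "2-20", "21-100", ">100")
  bin_counts <- table(factor(mapped$del_bin[mapped$category == "deletion"], levels = bins))
  del_bins <- tibble(
    del_bin = bins,
    count = as.integer(bin_counts),
    frequency = if (junction_reads > 0) as.integer(bin_counts) / junction_reads else 0
  )

  large <- sum(mapped$category == "deletion" & mapped$del_bin == ">100", na.rm = TRUE)
  templated_ins <- sum(mapped$category == "insertion" & mapped$templated, na.rm = TRUE)

  structure(
    list(total_reads = as.integer(total_reads),
         junction_reads = as.integer(junction_reads),
         categories = categories,
         del_bins = del_bins,
         templated_insertions = as.integer(templated_ins),
         repaired_fraction = junction_reads / total_reads,
         large_resection_fraction = large / total_reads),
    class = "junction_tally")
}

#' @export
print.junction_tally <- function(x, ...) {
  cat(sprintf("<junction_tally> %d junction / %d total reads (repaired %.3f)\n",
              x$junction_reads, x$total_reads, x$repaired_fraction))
  print(x$categories)
  cat("deletion sizes:\n")
  print(x$del_bins)
  invisible(x)
}

#' @rdname tally_outcomes
#' @param x A `junction_tally`.
#' @param ... Unused.
#' @export
tidy.junction_tally <- function(x, ...) {
  bind_rows(
    dplyr::mutate(x$categories, term = .data$category, .keep = "unused"),
    dplyr::mutate(x$del_bins, term = paste0("deletion ", .data$del_bin),
                  .keep = "unused")
  ) |>
    dplyr::select("term", "count", "frequency")
}

#' @rdname tally_outcomes
#' @export
glance.junction_tally <- function(x, ...) {
  tibble(
    total_reads = x$total_reads,
    junction_reads = x$junction_reads,
    repaired_fraction = x$repaired_fraction,
    precise_fraction = x$categories$frequency[x$categories$category == "precise"],
    templated_insertions = x$templated_insertions,
    large_resection_fraction = x$large_resection_fraction
  )
}
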