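#' Locate a guide and its blunt cleavage position on a reference segment
#'
#' SpCas9 cleaves between the -3 and -4 protospacer positions upstream of the
#' PAM (counting -1 as the PAM-proximal base).  Coordinates here are 0-based
#' and cuts are inter-base: a cut at coordinate `c` falls between segment
#' positions `c - 1` and `c` (0-based).
#'
#' @param segment Reference segment (forward strand, character scalar).
#' @param protospacer Protospacer sequence, 5'->3' on the protospacer strand
#'   (typically 20 nt).
#' @param pam PAM sequence on the protospacer strand (3 nt, NGG).
#' @param strand `"+"` if the protospacer strand is the segment's forward
#'   strand, `"-"` otherwise.
#' @return Inter-base cut coordinate on the segment's forward strand
#'   (0-based integer).
#' @export
#' @examples
#' seg <- paste0("AAAT", "GACCGGGGACCCATGTATG", "TGG", "CCCA")
#' blunt_cut_position(seg, "GACCGGGGACCCATGTATG", "TGG", "+")
blunt_cut_position <- function(segment, protospacer, pam, strand = c("+", "-")) {
  strand <- match.arg(strand)
  check_dna(segment, "segment")
  check_dna(protospacer, "protospacer")
  if (!grepl("^[ACGT]GG$", pam)) {
    stop("unsupported PAM: only 3-nt NGG PAMs are accepted", call. = FALSE)
  }
  site <- if (strand == "+") paste0(protospacer, pam) else revcomp(paste0(protospacer, pam))
  hits <- gregexpr(site, segment, fixed = TRUE)[[1]]
  if (hits[1] == -1) stop("guide not found", call. = FALSE)
  if (length(hits) > 1) stop("ambiguous guide placement", call. = FALSE)
  start0 <- hits[1] - 1L # 0-based start of the matched site
  if (strand == "+") {
    pam_start <- start0 + nchar(protospacer)
    pam_start - 3L
  } else {
    # site = revcomp(pam) ++ revcomp(protospacer); cut 3 nt right of the
    # reverse-complement PAM end
    start0 + 3L + 3L
  }
}

#' Define a guide site on a reference segment
#'
#' Bundles a protospacer/PAM occurrence with its blunt cut coordinate and the
#' staggered-cleavage overhang window.  Cas9 cleavage is modeled as blunt at
#' the -3|-4 boundary, with optional 1-3 nt 5' overhangs reaching positions
#' -4 to -6 upstream of the PAM.
#'
#' @inheritParams blunt_cut_position
#' @param label Free-text guide name.
#' @param max_overhang Maximum staggered-cleavage overhang modeled (0-3 nt).
#' @return An object of class `guide_site`.
#' @export
guide_site <- function(label, segment, protospacer, pam, strand = c("+", "-"),
                       max_overhang = 3L) {
  strand <- match.arg(strand)
  max_overhang <- as.integer(max_overhang)
  stopifnot(max_overhang >= 0L, max_overhang <= 3L)
  cut <- blunt_cut_position(segment, protospacer, pam, strand)
  seg_len <- nchar(segment)
  if (cut < max_overhang || cut > seg_len - max_overhang) {
    stop("cut site too close to the segment edge for the overhang window",
         call. = FALSE)
  }
  site <- if (strand == "+") paste0(protospacer, pam) else revcomp(paste0(protospacer, pam))
  start0 <- regexpr(site, segment, fixed = TRUE)[1] - 1L
  structure(
    list(label = label, protospacer = protospacer, pam = pam, strand = strand,
         cut_blunt = cut, max_overhang = max_overhang,
         site_start = start0, seg_len = seg_len),
    class = "guide_site")
}

#' @export
print.guide_site <- function(x, ...) {
  cat(sprintf("<guide_site> %s  %s-%s (%s)  blunt cut @ %d  max overhang %d nt\n",
              x$label, x$protospacer, x$pam, x$strand, x$cut_blunt,
              x$max_overhang))
  invisible(x)
}

#' Sequence duplicated by fill-in of a staggered Cas9 cut
#'
#' A k-nt 5' overhang spans PAM-relative positions -4 to -(3+k); cellular
#' fill-in duplicates those bases, producing a templated insertion at the
#' ligation junction.  The overhang is returned 5'->3' on the protospacer
#' strand (PAM-distal base first); the outcome classifier compares insertions
#' against both reading orders and both strands.
#'
#' @param guide A [guide_site()].
#' @param k Overhang length, 1 to `guide$max_overhang`.
#' @return Character scalar of length `k`.
#' @export
predicted_overhang <- function(guide, k) {
  stopifnot(inherits(guide, "guide_site"))
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 1L || k > guide$max_overhang) {
    stop("overhang length unsupported", call. = FALSE)
  }
  len <- nchar(guide$protospacer)
  substr(guide$protospacer, len - 2L - k, len - 3L)
}

# PAM-relative position of a 0-based forward coordinate x for a guide.
# Protospacer positions are -1 (PAM-proximal) .. -len; PAM positions +1..+3;
# anything else is NA.
pam_relative_position <- function(guide, x) {
  len <- nchar(guide$protospacer)
  if (guide$strand == "+") {
    p0 <- guide$site_start + len # pam start
    dplyr::case_when(
      x >= guide$site_start & x < p0 ~ x - p0,
      x >= p0 & x < p0 + 3L ~ x - p0 + 1L,
      TRUE ~ NA_integer_
    )
  } else {
    q0 <- guide$site_start # start of revcomp(pam)
    dplyr::case_when(
      x >= q0 + 3L & x < q0 + 3L + len ~ (q0 + 2L) - x,
      x >= q0 & x < q0 + 3L ~ (q0 + 3L) - x,
      TRUE ~ NA_integer_
    )
  }
}

# positions of the `depth` arm bases adjacent to the junction, walking away
# from it; coords0 is the forward coordinate of the junction-adjacent base
# and step the forward-coordinate increment per base walked.
arm_pam_positions <- function(guide, coord0, step, depth = 10L) {
  coords <- coord0 + step * (seq_len(depth) - 1L)
  pam_relative_position(guide, coords)
}

#' Build the junctional reference for one rearrangement type
#'
#' Concatenates the two post-cleavage arms predicted by a dual-sgRNA
#' rearrangement: `deletion` joins the upstream flank of the first cut to the
#' downstream flank of the second; `inversion_up` / `inversion_down` join a
#' flank to the reverse complement of the inverted internal fragment at the
#' upstream / downstream junction; `duplication` is the tandem head-to-tail
#' junction of the duplicated fragment; `single_cut` is the re-ligated single
#' cut.  Arms are trimmed to `arm_window` nt so that amplicon-sized reads
#' (< 290 bp) are fully covered.
#'
#' @param upstream_segment,downstream_segment Forward-strand reference
#'   segments carrying the two guides (pass one segment twice for cuts on the
#'   same amplified locus; `downstream_segment` defaults to
#'   `upstream_segment`).
#' @param guide_up,guide_down [guide_site()] objects located on the
#'   respective segments.  `guide_down` defaults to `guide_up` for
#'   `kind = "single_cut"`.
#' @param kind One of `"deletion"`, `"inversion_up"`, `"inversion_down"`,
#'   `"duplication"`, `"single_cut"`.
#' @param arm_window Maximum arm length retained on each side of the junction
#'   (nt).
#' @param min_arm Minimum arm length required (anchor length), nt.
#' @param label Optional reference label.
#' @return An object of class `junction_reference`: upstream/downstream arm
#'   sequences, the junction coordinate (`= nchar(upstream_arm)` in the
#'   concatenated reference), the guides, and per-arm PAM-relative positions
#'   of the junction-adjacent bases (used to profile deleted positions).
#' @export
build_junction_reference <- function(upstream_segment,
                                     downstream_segment = upstream_segment,
                                     guide_up,
                                     guide_down = guide_up,
                                     kind = c("deletion", "inversion_up",
                                              "inversion_down", "duplication",
                                              "single_cut"),
                                     arm_window = 150L,
                                     min_arm = 15L,
                                     label = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(guide_up, "guide_site"), inherits(guide_down, "guide_site"))
  check_dna(upstream_segment, "upstream segment")
  check_dna(downstream_segment, "downstream segment")
  cu <- guide_up$cut_blunt
  cd <- guide_down$cut_blunt

  left_flank <- function(seg, c) substr(seg, max(1L, c - arm_window + 1L), c)
  right_flank <- function(seg, c) substr(seg, c + 1L, min(nchar(seg), c + arm_window))

  arms <- switch(kind,
    deletion = list(
      up = left_flank(upstream_segment, cu), up_guide = guide_up,
      up_coord0 = cu - 1L, up_step = -1L,
      down = right_flank(downstream_segment, cd), down_guide = guide_down,
      down_coord0 = cd, down_step = 1L),
    inversion_up = list(
      up = left_flank(upstream_segment, cu), up_guide = guide_up,
      up_coord0 = cu - 1L, up_step = -1L,
      down = revcomp(left_flank(downstream_segment, cd)), down_guide = guide_down,
      down_coord0 = cd - 1L, down_step = -1L),
    inversion_down = list(
      up = revcomp(right_flank(upstream_segment, cu)), up_guide = guide_up,
      up_coord0 = cu, up_step = 1L,
      down = right_flank(downstream_segment, cd), down_guide = guide_down,
      down_coord0 = cd, down_step = 1L),
    duplication = list(
      up = left_flank(downstream_segment, cd), up_guide = guide_down,
      up_coord0 = cd - 1L, up_step = -1L,
      down = right_flank(upstream_segment, cu), down_guide = guide_up,
      down_coord0 = cu, down_step = 1L),
    single_cut = list(
      up = left_flank(upstream_segment, cu), up_guide = guide_up,
      up_coord0 = cu - 1L, up_step = -1L,
      down = right_flank(upstream_segment, cu), down_guide = guide_up,
      down_coord0 = cu, down_step = 1L)
  )

  if (nchar(arms$up) < min_arm || nchar(arms$down) < min_arm) {
    stop("arm too short", call. = FALSE)
  }

  structure(
    list(kind = kind,
         label = label %||% paste0(kind, ":", guide_up$label),
         upstream_arm = arms$up,
         downstream_arm = arms$down,
         junction = nchar(arms$up),
         guides = list(up = arms$up_guide, down = arms$down_guide),
         arm_pam = list(
           up = arm_pam_positions(arms$up_guide, arms$up_coord0, arms$up_step),
           down = arm_pam_positions(arms$down_guide, arms$down_coord0, arms$down_step))),
    class = "junction_reference")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.junction_reference <- function(x, ...) {
  cat(sprintf("<junction_reference> %s (%s)\n", x$label, x$kind))
  cat(sprintf("  arms: %d + %d nt, junction @ %d\n",
              nchar(x$upstream_arm), nchar(x$downstream_arm), x$junction))
  cat(sprintf("  guides: %s / %s\n", x$guides$up$label, x$guides$down$label))
  invisible(x)
}

# full predicted sequence of the junctional reference
reference_sequence <- function(ref) {
  paste0(ref$upstream_arm, ref$downstream_arm)
}

#' Read guide/junction definitions from a TSV plus reference FASTA
#'
#' The TSV has columns `label`, `segment_fasta_id`, `protospacer`, `pam`,
#' `strand`, `kind`.  Rows sharing a `label` define one junction: a single
#' row is a `single_cut`, a pair of rows (upstream guide first) defines the
#' rearrangement named in `kind`.
#'
#' @param tsv_path Path to the definition table.
#' @param fasta_path Path to the reference segments (FASTA).
#' @param ... Passed on to [build_junction_reference()] (e.g. `arm_window`).
#' @return Named list of `junction_reference` objects.
#' @export
read_guide_table <- function(tsv_path, fasta_path, ...) {
  defs <- readr::read_tsv(tsv_path, col_types = readr::cols(.default = "c"))
  needed <- c("label", "segment_fasta_id", "protospacer", "pam", "strand", "kind")
  if (!all(needed %in% names(defs))) {
    stop("definition table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  segs <- Biostrings::readDNAStringSet(fasta_path)
  seg_of <- function(id) {
    if (!id %in% names(segs)) stop("unknown segment id: ", id, call. = FALSE)
    as.character(segs[[id]])
  }
  defs |>
    dplyr::group_by(.data$label) |>
    dplyr::group_split() |>
    purrr::map(function(rows) {
      g1 <- guide_site(rows$label[1], seg_of(rows$segment_fasta_id[1]),
                       rows$protospacer[1], rows$pam[1], rows$strand[1])
      if (nrow(rows) == 1) {
        build_junction_reference(seg_of(rows$segment_fasta_id[1]),
                                 guide_up = g1, kind = "single_cut",
                                 label = rows$label[1], ...)
      } else {
        g2 <- guide_site(paste0(rows$label[2], "_dn"),
                         seg_of(rows$segment_fasta_id[2]),
                         rows$protospacer[2], rows$pam[2], rows$strand[2])
        build_junction_reference(seg_of(rows$segment_fasta_id[1]),
                                 seg_of(rows$segment_fasta_id[2]),
                                 g1, g2, kind = rows$kind[1],
                                 label = rows$label[1], ...)
      }
    }) |>
    (\(x) setNames(x, purrr::map_chr(x, "label")))()
}
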