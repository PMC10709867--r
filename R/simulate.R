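#' Synthetic dual-guide locus
#'
#' Generates a random locus pair with an embedded PAM-out guide
#' configuration: the upstream guide on the forward strand of the upstream
#' segment and the downstream guide on the reverse strand of the downstream
#' segment, so that at a rearrangement junction both arms present the
#' staggered-overhang positions (-4, -5, -6) adjacent to the junction — the
#' common dual-sgRNA deletion design.
#'
#' @param seed RNG seed.
#' @param seg_len Segment length (nt).
#' @return List with `up_segment`, `down_segment`, `guide_up`, `guide_down`.
#' @export
synthetic_locus <- function(seed = 1L, seg_len = 400L) {
  stopifnot(seg_len >= 250L)
  set.seed(seed)
  up <- strsplit(random_dna(seg_len), NULL)[[1]]
  dn <- strsplit(random_dna(seg_len), NULL)[[1]]
  s0 <- 150L # 0-based protospacer start on the upstream segment (+ strand)
  up[(s0 + 22L):(s0 + 23L)] <- c("G", "G") # NGG PAM
  q0 <- 180L # 0-based start of revcomp(PAM) on the downstream segment (- strand)
  dn[(q0 + 1L):(q0 + 2L)] <- c("C", "C")
  up_seg <- paste(up, collapse = "")
  dn_seg <- paste(dn, collapse = "")
  proto_up <- substr(up_seg, s0 + 1L, s0 + 20L)
  pam_up <- substr(up_seg, s0 + 21L, s0 + 23L)
  proto_dn <- revcomp(substr(dn_seg, q0 + 4L, q0 + 23L))
  pam_dn <- revcomp(substr(dn_seg, q0 + 1L, q0 + 3L))
  list(
    up_segment = up_seg,
    down_segment = dn_seg,
    guide_up = guide_site("sg1", up_seg, proto_up, pam_up, "+"),
    guide_down = guide_site("sg2", dn_seg, proto_dn, pam_dn, "-")
  )
}

#' Simulation configuration for a junctional amplicon library
#'
#' Defines the ground-truth outcome mixture applied at the junction of a
#' [build_junction_reference()]:
#' `precise` ligations; `del1` staggered end-loss deletions removing
#' `del1_k_probs`-distributed 1-3 junction-adjacent bases from a random arm;
#' `del_mmej` microhomology-mediated deletions of size
#' `up_offset + down_offset + mh_len`; `ins_templated` fill-in duplications
#' of the 1-3 junction-adjacent overhang bases; `ins_random` untemplated
#' insertions; and `large_resection` deletions > 100 nt.  Substitution
#' sequencing errors are applied per base at `error_rate`.
#'
#' @param ref A [build_junction_reference()].
#' @param mixture Named probabilities over the outcome classes above;
#'   must sum to 1.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param read_len Amplicon window length (nt, <= 280 so reads never exceed
#'   290 nt even with insertions).
#' @param n_reads Number of reads.
#' @param seed RNG seed; the simulator is fully deterministic given the
#'   seed.
#' @param del1_k_probs Distribution of end-loss sizes (names "1","2","3").
#' @param ins_templated_k_probs Distribution of fill-in overhang lengths.
#' @param mmej_mh_probs Distribution of microhomology lengths (names are
#'   lengths).
#' @param mmej_offset_max Maximum per-side offset of the microhomology from
#'   the cut (nt).
#' @param ins_random_max Maximum untemplated insertion length (nt).
#' @param resection_range Inclusive range of large-resection sizes (nt,
#'   > 100).
#' @return A `sim_config` list.
#' @export
sim_config <- function(ref,
                       mixture = c(precise = 0.35, del1 = 0.15,
                                   del_mmej = 0.27, ins_templated = 0.12,
                                   ins_random = 0.06, large_resection = 0.05),
                       error_rate = 0.001,
                       read_len = 240L,
                       n_reads = 5000L,
                       seed = 1L,
                       del1_k_probs = c(`1` = 1),
                       ins_templated_k_probs = c(`1` = 0.5, `2` = 0.3, `3` = 0.2),
                       mmej_mh_probs = c(`2` = 0.5, `3` = 0.3, `4` = 0.2),
                       mmej_offset_max = 12L,
                       ins_random_max = 6L,
                       resection_range = c(101L, 160L)) {
  stopifnot(inherits(ref, "junction_reference"))
  known <- c("precise", "del1", "del_mmej", "ins_templated", "ins_random",
             "large_resection")
  if (!all(names(mixture) %in% known)) {
    stop("unknown mixture class: ",
         paste(setdiff(names(mixture), known), collapse = ", "), call. = FALSE)
  }
  if (abs(sum(mixture) - 1) > 1e-9) stop("invalid mixture", call. = FALSE)
  stopifnot(error_rate >= 0, error_rate < 1, read_len <= 280L,
            resection_range[1] > LARGE_RESECTION_NT)
  structure(
    list(ref = ref, mixture = mixture, error_rate = error_rate,
         read_len = as.integer(read_len), n_reads = as.integer(n_reads),
         seed = as.integer(seed), del1_k_probs = del1_k_probs,
         ins_templated_k_probs = ins_templated_k_probs,
         mmej_mh_probs = mmej_mh_probs,
         mmej_offset_max = as.integer(mmej_offset_max),
         ins_random_max = as.integer(ins_random_max),
         resection_range = as.integer(resection_range)),
    class = "sim_config")
}

# amplicon-window read around the junction after applying an event
make_junction_read <- function(ref, d_up, d_down, ins, read_len) {
  up_kept <- substr(ref$upstream_arm, 1L, nchar(ref$upstream_arm) - d_up)
  dn_kept <- substr(ref$downstream_arm, d_down + 1L, nchar(ref$downstream_arm))
  hw_up <- min(nchar(up_kept), read_len %/% 2L)
  hw_dn <- min(nchar(dn_kept), read_len - hw_up)
  paste0(
    substr(up_kept, nchar(up_kept) - hw_up + 1L, nchar(up_kept)),
    ins,
    substr(dn_kept, 1L, hw_dn))
}

# arms whose junction-adjacent base is the -4 overhang position; staggered
# end events (del1, templated fill-in) are drawn from these sides
overhang_sides <- function(ref) {
  sides <- c("up", "down")
  ok <- vapply(sides, function(s) {
    isTRUE(ref$arm_pam[[s]][1] == -4L)
  }, logical(1))
  if (any(ok)) sides[ok] else "up"
}

sample_int_probs <- function(probs) as.integer(sample_class(probs))

#' Simulate a junctional amplicon library with ground truth
#'
#' Draws an outcome class per read from the configured mixture, applies it
#' at the junction of the reference, windows the result to amplicon size,
#' applies substitution errors, and emits reads plus a truth table.  The
#' truth table records the expected outcome category, total deletion size,
#' insertion sequence, and templated flag (evaluated with
#' [is_templated_insertion()], so that chance collisions of random
#' insertions with predicted overhangs are labeled as what the classifier
#' should call them).
#'
#' @param config A [sim_config()].
#' @return List with `reads` (tibble: `read_id`, `seq`, `qual`) and `truth`
#'   (tibble: `read_id`, `sim_class`, `category`, `del_total`, `del_up`,
#'   `del_down`, `ins_seq`, `ins_len`, `templated`, `templated_k`,
#'   `resected_nt`).
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ref <- config$ref
  set.seed(config$seed)
  Lu <- nchar(ref$upstream_arm); Ld <- nchar(ref$downstream_arm)
  classes <- sample_class(config$mixture, config$n_reads)
  ov_sides <- overhang_sides(ref)

  rows <- purrr::map(seq_len(config$n_reads), function(idx) {
    cls <- classes[idx]
    d_up <- 0L; d_down <- 0L; ins <- ""
    if (cls == "del1") {
      k <- sample_int_probs(config$del1_k_probs)
      side <- sample(ov_sides, 1L)
      if (side == "up") d_up <- k else d_down <- k
    } else if (cls == "del_mmej") {
      mh <- sample_int_probs(config$mmej_mh_probs)
      d_up <- sample(0:config$mmej_offset_max, 1L)
      d_down <- sample(0:config$mmej_offset_max, 1L) + mh
    } else if (cls == "ins_templated") {
      k <- sample_int_probs(config$ins_templated_k_probs)
      side <- sample(ov_sides, 1L)
      ins <- if (side == "up") {
        substr(ref$upstream_arm, Lu - k + 1L, Lu)
      } else {
        substr(ref$downstream_arm, 1L, k)
      }
    } else if (cls == "ins_random") {
      len <- sample(seq_len(config$ins_random_max), 1L)
      ins <- random_dna(len)
    } else if (cls == "large_resection") {
      r <- sample(config$resection_range[1]:config$resection_range[2], 1L)
      lo <- max(0L, r - (Ld - 20L))
      hi <- min(r, Lu - 20L)
      d_up <- sample(lo:hi, 1L)
      d_down <- r - d_up
    }
    seq <- make_junction_read(ref, d_up, d_down, ins, config$read_len)
    tmpl <- if (nchar(ins) >= 1L) is_templated_insertion(ins, ref)
            else list(templated = FALSE, k = 0L)
    list(cls = cls, d_up = d_up, d_down = d_down, ins = ins, seq = seq,
         templated = tmpl$templated, templated_k = tmpl$k)
  })

  seqs <- purrr::map_chr(rows, "seq")
  if (config$error_rate > 0) seqs <- add_substitution_errors(seqs, config$error_rate)
  stopifnot(all(nchar(seqs) <= 290L))

  ids <- sprintf("sim%06d", seq_len(config$n_reads))
  d_up <- purrr::map_int(rows, "d_up"); d_down <- purrr::map_int(rows, "d_down")
  ins <- purrr::map_chr(rows, "ins")
  truth <- tibble(
    read_id = ids,
    sim_class = purrr::map_chr(rows, "cls"),
    category = dplyr::case_when(
      purrr::map_chr(rows, "cls") == "precise" ~ "precise",
      purrr::map_chr(rows, "cls") %in% c("del1", "del_mmej", "large_resection") ~ "deletion",
      TRUE ~ "insertion"
    ),
    del_total = d_up + d_down,
    del_up = d_up,
    del_down = d_down,
    ins_seq = ins,
    ins_len = nchar(ins),
    templated = purrr::map_lgl(rows, "templated"),
    templated_k = purrr::map_int(rows, "templated_k"),
    resected_nt = dplyr::if_else(purrr::map_chr(rows, "cls") == "large_resection",
                                 d_up + d_down, 0L)
  )
  list(
    reads = tibble(read_id = ids, seq = seqs,
                   qual = strrep("I", nchar(seqs))),
    truth = truth
  )
}

add_substitution_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0) return(s)
    ch <- strsplit(s, NULL)[[1]]
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Construct a single MMEJ-deletion read
#'
#' Emits the read produced when end resection exposes two copies of an
#' `mh_len`-nt microhomology — one ending `up_offset` nt upstream of the
#' cut, one starting `down_offset` nt downstream — and annealing deletes
#' everything between them plus one copy.  The retained copy is the
#' upstream one (deletions are reported left-aligned), so the read removes
#' `up_offset` nt of the upstream arm and `down_offset + mh_len` nt of the
#' downstream arm: `del_total = up_offset + down_offset + mh_len`.
#'
#' @param ref A [build_junction_reference()]; for a read that genuinely
#'   carries homology (and so exercises the aligner's overlap capture) the
#'   arms must already contain the matching copies — see
#'   [plant_microhomology()].
#' @param mh_len Microhomology length (nt, >= 0; 0 gives a plain deletion).
#' @param up_offset,down_offset Distances from the cut to the two copies
#'   (nt, >= 0).
#' @param read_len Amplicon window (nt).
#' @return List with `seq` and `del_total`.
#' @export
simulate_mmej_deletion <- function(ref, mh_len, up_offset, down_offset,
                                   read_len = 240L) {
  stopifnot(inherits(ref, "junction_reference"),
            mh_len >= 0, up_offset >= 0, down_offset >= 0)
  Lu <- nchar(ref$upstream_arm); Ld <- nchar(ref$downstream_arm)
  if (up_offset + mh_len > Lu - 15L || down_offset + mh_len > Ld - 15L) {
    stop("offset out of range", call. = FALSE)
  }
  d_up <- as.integer(up_offset)
  d_down <- as.integer(down_offset + mh_len)
  list(seq = make_junction_read(ref, d_up, d_down, "", read_len),
       del_total = d_up + d_down)
}

#' Plant a shared microhomology into both arms of a reference
#'
#' Overwrites `mh_len` nt ending `up_offset` nt before the junction on the
#' upstream arm and starting `down_offset` nt after it on the downstream
#' arm with the same sequence, so that MMEJ deletion reads built between the
#' copies carry genuine junction-flanking homology.
#'
#' @inheritParams simulate_mmej_deletion
#' @param mh_seq The microhomology sequence (random if `NULL`).
#' @return A modified `junction_reference`.
#' @export
plant_microhomology <- function(ref, mh_len, up_offset, down_offset,
                                mh_seq = NULL) {
  stopifnot(mh_len >= 1)
  mh_seq <- mh_seq %||% random_dna(mh_len)
  stopifnot(nchar(mh_seq) == mh_len)
  Lu <- nchar(ref$upstream_arm); Ld <- nchar(ref$downstream_arm)
  if (up_offset + mh_len > Lu || down_offset + mh_len > Ld) {
    stop("offset out of range", call. = FALSE)
  }
  up <- ref$upstream_arm
  substr(up, Lu - up_offset - mh_len + 1L, Lu - up_offset) <- mh_seq
  dn <- ref$downstream_arm
  substr(dn, down_offset + 1L, down_offset + mh_len) <- mh_seq
  ref$upstream_arm <- up
  ref$downstream_arm <- dn
  ref$junction <- nchar(up)
  ref
}
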