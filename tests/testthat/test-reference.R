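test_that("blunt cut falls between the -3 and -4 protospacer positions", {
  proto <- "GACCGGGGACCCATGTATG" # 19 nt also allowed; cut is PAM-anchored
  seg <- paste0("AAAT", proto, "TGG", "CCCA")
  # PAM starts at 0-based 23; cut 3 nt left of it
  expect_identical(blunt_cut_position(seg, proto, "TGG", "+"), 20L)

  # same guide on the minus strand: cut 3 nt right of the revcomp PAM end
  seg_m <- revcomp(seg)
  q0 <- regexpr(revcomp("TGG"), substr(seg_m, 1, 10), fixed = TRUE)[1] - 1L
  expect_identical(blunt_cut_position(seg_m, proto, "TGG", "-"), q0 + 6L)

  # a 60-nt random segment with a 20-nt protospacer+NGG embedded at offset 25
  set.seed(1)
  ch <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  proto20 <- paste(ch[26:45], collapse = "")
  ch[47:48] <- c("G", "G")
  seg60 <- paste(ch, collapse = "")
  pam <- substr(seg60, 46, 48)
  expect_identical(blunt_cut_position(seg60, proto20, pam, "+"), 25L + 17L)
})

test_that("guide placement errors are reported", {
  proto <- "GACCGGGGACCCATGTATG"
  seg <- paste0("AAAT", proto, "TGG", "CCCA")
  expect_error(blunt_cut_position(seg, "TTTTTTTTTTTTTTTTTTT", "TGG", "+"),
               "guide not found")
  seg2 <- paste0(seg, seg)
  expect_error(blunt_cut_position(seg2, proto, "TGG", "+"),
               "ambiguous guide placement")
  expect_error(blunt_cut_position(seg, proto, "TAA", "+"), "PAM")
})

test_that("predicted overhang reads off the -4..-6 window, 5'->3'", {
  m <- mecp2_guides()
  # MeCP2-1 protospacer CATACATGGGTCCCCGGTCA: -4 = G, -5 = G, -6 = C
  expect_identical(predicted_overhang(m$g1, 1), "G")
  expect_identical(predicted_overhang(m$g1, 2), "GG")
  expect_identical(predicted_overhang(m$g1, 3), "CGG")
  expect_identical(predicted_overhang(m$g2, 1), "G")
  expect_error(predicted_overhang(m$g1, 0), "overhang length unsupported")
  expect_error(predicted_overhang(m$g1, 4), "overhang length unsupported")
})

test_that("overhang is a fixed-offset protospacer substring with a mirrored
           reverse complement on the opposite strand", {
  loc <- fixture_locus()
  for (k in 1:3) {
    ov_up <- predicted_overhang(loc$guide_up, k)
    expect_identical(
      ov_up,
      substr(loc$guide_up$protospacer, 20 - 2 - k, 20 - 3))
    # minus-strand guide: the forward-strand bases just right of the cut are
    # the reverse complement of the protospacer-strand overhang
    ov_dn <- predicted_overhang(loc$guide_down, k)
    cut <- loc$guide_down$cut_blunt
    fwd <- substr(loc$down_segment, cut + 1, cut + k)
    expect_identical(fwd, revcomp(ov_dn))
  }
})

test_that("junction references assemble each rearrangement geometry", {
  loc <- fixture_locus()
  cu <- loc$guide_up$cut_blunt
  cd <- loc$guide_down$cut_blunt

  del <- build_junction_reference(loc$up_segment, loc$down_segment,
                                  loc$guide_up, loc$guide_down, "deletion")
  expect_identical(nchar(del$upstream_arm), 150L)
  expect_identical(del$junction, 150L)
  expect_identical(del$upstream_arm, substr(loc$up_segment, cu - 149, cu))
  expect_identical(del$downstream_arm, substr(loc$down_segment, cd + 1, cd + 150))

  inv <- build_junction_reference(loc$up_segment, loc$down_segment,
                                  loc$guide_up, loc$guide_down, "inversion_up")
  expect_identical(inv$downstream_arm,
                   revcomp(substr(loc$down_segment, cd - 149, cd)))

  inv_dn <- build_junction_reference(loc$up_segment, loc$down_segment,
                                     loc$guide_up, loc$guide_down, "inversion_down")
  expect_identical(inv_dn$upstream_arm,
                   revcomp(substr(loc$up_segment, cu + 1, cu + 150)))

  dup <- build_junction_reference(loc$up_segment, loc$down_segment,
                                  loc$guide_up, loc$guide_down, "duplication")
  expect_identical(dup$upstream_arm, substr(loc$down_segment, cd - 149, cd))
  expect_identical(dup$downstream_arm, substr(loc$up_segment, cu + 1, cu + 150))

  sc <- build_junction_reference(loc$up_segment, guide_up = loc$guide_up,
                                 kind = "single_cut")
  expect_identical(paste0(sc$upstream_arm, sc$downstream_arm),
                   substr(loc$up_segment, cu - 149, cu + 150))
})

test_that("a deletion junction with both cuts on the same coordinate reduces
           to the single-cut reference", {
  loc <- fixture_locus()
  del <- build_junction_reference(loc$up_segment, loc$up_segment,
                                  loc$guide_up, loc$guide_up, "deletion")
  sc <- build_junction_reference(loc$up_segment, guide_up = loc$guide_up,
                                 kind = "single_cut")
  expect_identical(del$upstream_arm, sc$upstream_arm)
  expect_identical(del$downstream_arm, sc$downstream_arm)
})

test_that("reference construction is idempotent and guards short arms", {
  loc <- fixture_locus()
  a <- fixture_ref("deletion")
  b <- build_junction_reference(loc$up_segment, loc$down_segment,
                                loc$guide_up, loc$guide_down, "deletion")
  expect_identical(a$upstream_arm, b$upstream_arm)
  expect_identical(a$arm_pam, b$arm_pam)

  # a cut 22 nt into its segment cannot supply a 30-nt upstream arm
  set.seed(4)
  edge_seg <- paste0(
    paste(sample(c("A", "C", "G", "T"), 5, TRUE), collapse = ""),
    loc$guide_up$protospacer, "AGG",
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""))
  g <- guide_site("edge", edge_seg, loc$guide_up$protospacer, "AGG", "+")
  expect_error(
    build_junction_reference(edge_seg, loc$down_segment, g, loc$guide_down,
                             "deletion", min_arm = 30),
    "arm too short")
})

test_that("PAM-out junction arms expose -4, -5, -6 adjacent to the junction", {
  ref <- fixture_ref("deletion")
  expect_identical(ref$arm_pam$up[1:3], c(-4L, -5L, -6L))
  expect_identical(ref$arm_pam$down[1:3], c(-4L, -5L, -6L))
})

test_that("guide tables round-trip through TSV + FASTA", {
  loc <- fixture_locus()
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(up = loc$up_segment, dn = loc$down_segment)), fa)
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    label = c("mazdel", "mazdel"),
    segment_fasta_id = c("up", "dn"),
    protospacer = c(loc$guide_up$protospacer, loc$guide_down$protospacer),
    pam = c(loc$guide_up$pam, loc$guide_down$pam),
    strand = c("+", "-"),
    kind = c("deletion", "deletion")), tsv)
  refs <- read_guide_table(tsv, fa)
  expect_named(refs, "mazdel")
  expect_identical(refs$mazdel$upstream_arm, fixture_ref("deletion")$upstream_arm)
})
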