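# shared fixtures: one synthetic PAM-out dual-guide locus and its deletion
# junction reference, built once per test run
.fixture_env <- new.env(parent = emptyenv())

fixture_locus <- function() {
  if (is.null(.fixture_env$locus)) .fixture_env$locus <- synthetic_locus(seed = 1)
  .fixture_env$locus
}

fixture_ref <- function(kind = "deletion") {
  key <- paste0("ref_", kind)
  if (is.null(.fixture_env[[key]])) {
    loc <- fixture_locus()
    .fixture_env[[key]] <- build_junction_reference(
      loc$up_segment, loc$down_segment, loc$guide_up, loc$guide_down, kind)
  }
  .fixture_env[[key]]
}

# read constructed from reference arms with programmed edits
junction_read <- function(ref, del_up = 0, del_down = 0, ins = "",
                          anchor = 40) {
  U <- ref$upstream_arm; D <- ref$downstream_arm
  paste0(
    substr(U, nchar(U) - anchor - del_up + 1, nchar(U) - del_up),
    ins,
    substr(D, del_down + 1, del_down + anchor))
}

# guides printed for the MeCP2 locus (first/second cut protospacers)
mecp2_guides <- function() {
  proto1 <- "CATACATGGGTCCCCGGTCA"
  proto2 <- "TTGAAGTGCGACTCATGCTG"
  seg1 <- paste0(strrep("T", 40), proto1, "TGG", strrep("A", 40))
  seg2 <- paste0(strrep("G", 40), proto2, "AGG", strrep("C", 40))
  list(
    g1 = guide_site("MeCP2-1", seg1, proto1, "TGG", "+"),
    g2 = guide_site("MeCP2-2", seg2, proto2, "AGG", "+"),
    seg1 = seg1, seg2 = seg2)
}
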