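test_that("precise ligation reads decompose with empty middle and no deletion", {
  ref <- fixture_ref("deletion")
  al <- align_junction(junction_read(ref), ref)
  expect_identical(al$score, 80)
  expect_identical(al$middle_insertion, "")
  expect_identical(al$del_up, 0L)
  expect_identical(al$del_down, 0L)
  expect_identical(al$overlap_len, 0L)
  expect_true(al$mapped)
})

test_that("junction insertions and arm-side deletions are recovered", {
  ref <- fixture_ref("deletion")
  minus4 <- substr(ref$upstream_arm, nchar(ref$upstream_arm),
                   nchar(ref$upstream_arm))
  al_ins <- align_junction(junction_read(ref, ins = minus4), ref)
  expect_identical(al_ins$middle_insertion, minus4)
  expect_identical(al_ins$del_up + al_ins$del_down + al_ins$overlap_len, 0L)

  al_del <- align_junction(junction_read(ref, del_down = 5), ref)
  expect_identical(al_del$middle_insertion, "")
  expect_identical(al_del$del_up + al_del$del_down + al_del$overlap_len, 5L)
})

test_that("aligner matches the exhaustive-split oracle across edit types", {
  ref <- fixture_ref("deletion")
  scheme <- scoring_scheme()
  set.seed(13)
  cases <- list()
  for (du in 0:4) for (dd in 0:4) {
    cases[[length(cases) + 1]] <- junction_read(ref, du, dd, anchor = 20)
  }
  for (insn in 1:3) {
    for (r in 1:5) {
      cases[[length(cases) + 1]] <- junction_read(
        ref, ins = paste(sample(c("A", "C", "G", "T"), insn, TRUE), collapse = ""),
        anchor = 20)
    }
  }
  # mutated reads (2% per-base substitutions)
  for (r in 1:20) {
    rd <- junction_read(ref, sample(0:3, 1), sample(0:3, 1), anchor = 20)
    ch <- strsplit(rd, NULL)[[1]]
    hit <- which(runif(length(ch)) < 0.02)
    if (length(hit) > 0) ch[hit] <- sample(c("A", "C", "G", "T"), length(hit), TRUE)
    cases[[length(cases) + 1]] <- paste(ch, collapse = "")
  }
  for (rd in cases) {
    expect_equal(align_junction(rd, ref, scheme)$score,
                 brute_force_align(rd, ref, scheme)$score)
  }
})

test_that("overlap captures junction-flanking microhomology without
           inflating the deletion", {
  ref <- plant_microhomology(fixture_ref("deletion"), mh_len = 2,
                             up_offset = 0, down_offset = 0, mh_seq = "CA")
  mm <- simulate_mmej_deletion(ref, mh_len = 2, up_offset = 0, down_offset = 0,
                               read_len = 80)
  al <- align_junction(mm$seq, ref)
  expect_identical(al$overlap_len, 2L)
  expect_identical(al$del_up, 0L)
  expect_identical(al$del_down, 0L)
  out <- classify_outcomes(al, ref)
  expect_identical(out$del_total, 2L)
})

test_that("alignment is invariant to reverse complementing the read", {
  ref <- fixture_ref("deletion")
  rd <- junction_read(ref, del_up = 2, ins = "")
  fwd <- align_both_strands(rd, ref)
  rev <- align_both_strands(revcomp(rd), ref)
  expect_identical(fwd$strand, "+")
  expect_identical(rev$strand, "-")
  expect_identical(fwd$del_up, rev$del_up)
  expect_identical(fwd$del_down, rev$del_down)
  expect_identical(fwd$middle_insertion, rev$middle_insertion)
  expect_identical(fwd$score, rev$score)
})

test_that("unrelated reads fall below the mapping threshold", {
  ref <- fixture_ref("deletion")
  set.seed(7)
  rd <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  al <- align_both_strands(rd, ref)
  expect_false(al$mapped)
})

test_that("appending matched anchor bases never decreases the score", {
  ref <- fixture_ref("deletion")
  scores <- vapply(seq(16, 60, by = 4), function(anchor) {
    align_junction(junction_read(ref, del_down = 1, anchor = anchor), ref)$score
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("degenerate inputs are rejected", {
  ref <- fixture_ref("deletion")
  expect_error(align_junction(strrep("A", 20), ref), "read too short")
  expect_error(align_junction(strrep("ACGTX", 20), ref), "invalid alphabet")
  expect_error(brute_force_align(junction_read(ref, anchor = 40), ref),
               "oracle size exceeded")
})

test_that("N bases never score as matches", {
  ref <- fixture_ref("deletion")
  clean <- junction_read(ref)
  noisy <- sub("^.", "N", clean)
  a <- align_junction(clean, ref)
  b <- align_junction(noisy, ref)
  expect_equal(a$score - b$score, 3) # match (+1) became mismatch (-2)
})
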