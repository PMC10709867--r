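classified_read <- function(ref, ...) {
  classify_outcomes(align_both_strands(junction_read(ref, ...), ref), ref)
}

test_that("outcome categories follow the four-group definitions", {
  ref <- fixture_ref("deletion")
  expect_identical(classified_read(ref)$category, "precise")
  expect_identical(classified_read(ref, del_up = 1)$category, "deletion")
  expect_identical(classified_read(ref, ins = "AG")$category, "insertion")
  expect_identical(classified_read(ref, del_up = 2, del_down = 1,
                                   ins = "AG")$category, "indel")

  out <- classified_read(ref, del_up = 1)
  expect_identical(out$del_bin, "1")
  expect_identical(out$del_positions[[1]], -4L)
})

test_that("deletion-size bins split exactly at 1, 20, 100", {
  expect_identical(
    junctionr:::del_size_bin(c(0L, 1L, 2L, 20L, 21L, 100L, 101L, 250L)),
    c(NA, "1", "2-20", "2-20", "21-100", "21-100", ">100", ">100"))
})

test_that("templated insertions match predicted overhangs from either guide
           in either orientation", {
  ref <- fixture_ref("deletion")
  for (k in 1:3) {
    ov <- predicted_overhang(ref$guides$up, k)
    expect_true(is_templated_insertion(ov, ref)$templated)
    expect_identical(is_templated_insertion(ov, ref)$k, k)
    expect_true(is_templated_insertion(revcomp(ov), ref)$templated)
    # the physically inserted forward-strand copy for the minus-strand guide
    dn <- substr(ref$downstream_arm, 1, k)
    expect_true(is_templated_insertion(dn, ref)$templated)
  }
  expect_false(is_templated_insertion("ACGT", ref)$templated)
})

test_that("insertions matching no guide overhang are untemplated", {
  # both MeCP2 guides have G at -4 (and C as its complement); A can never be
  # a 1-bp templated insertion at their junction
  m <- mecp2_guides()
  ref <- build_junction_reference(m$seg1, m$seg2, m$g1, m$g2, "deletion",
                                  arm_window = 40)
  r <- is_templated_insertion("A", ref)
  expect_false(r$templated)
  expect_identical(r$k, 0L)
  expect_true(is_templated_insertion("G", ref)$templated)
})

test_that("deleted positions profile concentrates where bases were removed", {
  ref <- fixture_ref("deletion")
  only_precise <- classified_read(ref)
  expect_identical(nrow(deletion_position_profile(only_precise)), 0L)

  two <- classified_read(ref, del_up = 2)
  prof <- deletion_position_profile(two)
  expect_identical(prof$position, c(-5L, -4L))
  expect_identical(prof$count, c(1L, 1L))
})

test_that("simulated staggered-end libraries put the deleted bases at
           -4, -5, -6", {
  ref <- fixture_ref("deletion")
  cfg <- sim_config(ref, mixture = c(del1 = 1), error_rate = 0,
                    n_reads = 600, seed = 5,
                    del1_k_probs = c(`1` = 0.5, `2` = 0.3, `3` = 0.2))
  sim <- simulate_library(cfg)
  out <- classify_outcomes(align_both_strands(sim$reads, ref), ref)
  prof <- deletion_position_profile(out)
  frac <- sum(prof$count[prof$position %in% c(-4L, -5L, -6L)]) / sum(prof$count)
  expect_gte(frac, 0.9)
})

test_that("tallies count and normalize the outcome mixture", {
  ref <- fixture_ref("deletion")
  outcomes <- dplyr::bind_rows(
    purrr::map(1:2, ~ classified_read(ref)),
    classified_read(ref, del_up = 1),
    classified_read(ref, ins = "ACGTAG")
  )
  tl <- tally_outcomes(outcomes, total_reads = 8)
  expect_identical(tl$junction_reads, 4L)
  expect_equal(tl$repaired_fraction, 0.5)
  expect_equal(sum(tl$categories$frequency), 1)
  expect_equal(tl$categories$frequency[tl$categories$category == "precise"], 0.5)
  expect_equal(tl$large_resection_fraction, 0)

  expect_error(tally_outcomes(outcomes, total_reads = 3), "inconsistent totals")

  td <- tidy(tl)
  expect_true(all(c("term", "count", "frequency") %in% names(td)))
  gl <- glance(tl)
  expect_identical(gl$total_reads, 8L)
})

test_that("an all-unmapped library tallies zero repaired fraction", {
  ref <- fixture_ref("deletion")
  set.seed(7)
  junk <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  }, "")
  out <- classify_outcomes(align_both_strands(junk, ref), ref)
  tl <- tally_outcomes(out, total_reads = 100)
  expect_identical(tl$junction_reads, 0L)
  expect_equal(tl$repaired_fraction, 0)
})

test_that("category frequencies form a distribution on simulated libraries", {
  ref <- fixture_ref("deletion")
  sim <- simulate_library(sim_config(ref, n_reads = 400, seed = 11,
                                     error_rate = 0.01))
  out <- classify_outcomes(align_both_strands(sim$reads, ref), ref)
  tl <- tally_outcomes(out)
  expect_equal(sum(tl$categories$frequency), 1)
  expect_true(all(tl$categories$frequency >= 0))
  expect_lte(tl$repaired_fraction, 1)
})
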