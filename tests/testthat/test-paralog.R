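test_that("position map enumerates mutually non-gap columns", {
  aln <- c(S = "ACDEFGHIKL", T = "ACDEFGHIKL")
  map <- build_position_map(aln, "S", "T")
  expect_equal(map$source_position, 1:10)
  expect_equal(map$target_position, 1:10)

  aln2 <- c(a = "AC-GT", b = "ACAGT")
  map2 <- build_position_map(aln2, "a", "b")
  expect_equal(map2$source_position, c(1, 2, 3, 4))
  expect_equal(map2$target_position, c(1, 2, 4, 5))
})

test_that("map construction validates identifiers and row lengths", {
  aln <- c(a = "ACGT", b = "ACG")
  expect_error(build_position_map(aln, "a", "b"), class = "setphen_format_error")
  expect_error(build_position_map(c(a = "ACGT", b = "ACGT"), "a", "zz"),
               class = "setphen_format_error")
})

test_that("variant transfer distinguishes mapped, gap and already-substituted cases", {
  aln <- c(src = "ACDEF", tgt = "AC-EF")
  map <- build_position_map(aln, "src", "tgt")
  # gap column
  gap <- transfer_variant(map, list(ref_aa = "D", position = 3, alt_aa = "N"))
  expect_equal(gap$status, "UnmappedGap")
  # mapped
  ok <- transfer_variant(map, list(ref_aa = "E", position = 4, alt_aa = "K"))
  expect_equal(ok$status, "Mapped")
  expect_equal(ok$target_position, 3)
  expect_equal(ok$target_variant, "E3K")
  # already substituted: target already carries the alternate identity
  aln2 <- c(src = "ACDEF", tgt = "ACEEF")
  map2 <- build_position_map(aln2, "src", "tgt")
  ex <- transfer_variant(map2, list(ref_aa = "D", position = 3, alt_aa = "E"))
  expect_equal(ex$status, "ExcludedAlreadySubstituted")
  # reference mismatch is a warning status, not an error
  mm <- transfer_variant(map, list(ref_aa = "Q", position = 4, alt_aa = "K"))
  expect_equal(mm$status, "RefMismatch")
  expect_error(transfer_variant(map, list(ref_aa = "A", position = 99, alt_aa = "C")),
               class = "setphen_argument_error")
})

test_that("generated fixture alignment reproduces the full paralog annotation column", {
  pairs <- table1_pairs()
  aln <- gen_paralog_alignment(pairs, source_id = "KMT2D", target_id = "KMT2C",
                               seed = 42)
  map <- build_position_map(aln, "KMT2D", "KMT2C")
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    transfer_variant(map, list(ref_aa = pairs$source_res[k],
                               position = pairs$source_pos[k],
                               alt_aa = pairs$alt[k]))
  })
  status <- vapply(res, `[[`, character(1), "status")
  excluded <- pairs$source_variant[status == "ExcludedAlreadySubstituted"]
  expect_equal(excluded, "D5489E")
  mapped <- status == "Mapped"
  expect_equal(sum(mapped), 19L)
  got <- vapply(res[mapped], `[[`, character(1), "target_variant")
  expect_equal(got, pairs$annotation[mapped])
  # constant offset of 626 in this region
  offs <- vapply(res[mapped], `[[`, numeric(1), "target_position")
  expect_true(all(pairs$source_pos[mapped] - offs == 626))
})

test_that("mapped positions are strictly monotone and round-trip", {
  pairs <- table1_pairs()
  aln <- gen_paralog_alignment(pairs, source_id = "KMT2D", target_id = "KMT2C",
                               seed = 7)
  map <- build_position_map(aln, "KMT2D", "KMT2C")
  expect_true(all(diff(map$source_position) > 0))
  expect_true(all(diff(map$target_position) > 0))
  back <- build_position_map(aln, "KMT2C", "KMT2D")
  idx <- match(map$target_position, back$source_position)
  expect_equal(back$target_position[idx], map$source_position)
})

test_that("filler seed changes sequences but never the mapped pairs", {
  pairs <- table1_pairs()
  a1 <- gen_paralog_alignment(pairs, seed = 1)
  a2 <- gen_paralog_alignment(pairs, seed = 2)
  expect_false(identical(unname(a1), unname(a2)))
  m1 <- build_position_map(a1, "SOURCE", "TARGET")
  m2 <- build_position_map(a2, "SOURCE", "TARGET")
  k1 <- m1[m1$source_position %in% pairs$source_pos, c("source_position", "target_position")]
  k2 <- m2[m2$source_position %in% pairs$source_pos, c("source_position", "target_position")]
  expect_equal(k1, k2)
})

test_that("percent identity follows the one-gap-in-denominator convention", {
  expect_equal(percent_identity(c(a = "ACGT", b = "ACGT")), 100.0)
  expect_equal(percent_identity(c(a = "ACGT", b = "ACGA")), 75.0)
  expect_equal(percent_identity(c(a = "AC-T", b = "ACGT")), 75.0)
  expect_error(percent_identity(c(a = "ACGT", b = "ACGT"), region = c(9, 12)),
               class = "setphen_argument_error")
})
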