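test_that("identity and similarity compute positionwise fractions with errors on bad input", {
  expect_equal(aa_identity("ARDA", "ARDA"), 1)
  expect_equal(aa_identity("ARDA", "ARDG"), 0.75)
  expect_error(aa_identity("ARDA", "ARD"), "equal length")
  expect_error(aa_identity("", ""), "non-empty")

  expect_equal(aa_similarity("KRDA", "RKDA"), 1) # K/R share the basic group
  expect_equal(aa_similarity("ARDA", "ARDG"), 1) # A/G share the aliphatic group
  expect_error(aa_similarity("ARBA", "ARDA"), "alphabet")

  # vectorised with scalar recycling
  expect_equal(aa_identity(c("AA", "AC"), "AA"), c(1, 0.5))
})

test_that("identity never exceeds similarity on random pairs", {
  withr::with_seed(7, {
    for (i in 1:300) {
      len <- sample(4:25, 1)
      a <- random_cdr3(len)
      b <- random_cdr3(len)
      expect_lte(aa_identity(a, b), aa_similarity(a, b))
    }
  })
})

test_that("motif search returns all 0-based offsets including overlaps and wildcards", {
  expect_equal(find_motif("ARGGYYGMDV", "GYY"), 3L)
  expect_equal(find_motif("GYYGYY", "GYY"), c(0L, 3L))
  expect_equal(find_motif("AAAA", "AA"), c(0L, 1L, 2L)) # overlapping hits
  expect_equal(find_motif("ARGAYYGMDV", "GXY"), 2L) # G at 2, wildcard A, Y at 4
  expect_equal(find_motif("ARD", "KGYY"), integer(0)) # motif longer than CDR3
  expect_error(find_motif("ARD", ""), "non-empty")
})

test_that("standard matching enforces clan, length, thresholds and exact motif offset", {
  catalog <- toy_catalog()
  t1 <- catalog[1, ] # IGHV1-69/IGHV1-2, clan I, ARDKGYYDSWFDP, KGYY @ 3
  self <- list(v_call = "IGHV1-69*01", cdr3_aa = "ARDKGYYDSWFDP")
  hit <- match_standard(self, t1)
  expect_equal(hit$match_type, "standard")
  expect_equal(hit$identity, 1)
  expect_equal(hit$similarity, 1)
  expect_equal(hit$length_delta, 0L)

  # one residue shorter: equal-length criterion fails
  shorter <- list(v_call = "IGHV1-69", cdr3_aa = "ARKGYYDSWFDP")
  expect_null(match_standard(shorter, t1))
  # motif present only one position right of the subset offset
  shifted <- list(v_call = "IGHV1-69", cdr3_aa = "ARDAKGYYSWFDP")
  expect_equal(find_motif(shifted$cdr3_aa, t1$motif), 4L)
  expect_null(match_standard(shifted, t1))
  # wrong clan, everything else identical
  wrong_clan <- list(v_call = "IGHV3-23", cdr3_aa = "ARDKGYYDSWFDP")
  expect_null(match_standard(wrong_clan, t1))
  # similarity below 70%: keep motif, replace the rest with far-group residues
  far <- vapply(strsplit("ARDKGYYDSWFDP", "")[[1]], far_residue, character(1))
  far[4:7] <- strsplit("KGYY", "")[[1]]
  dissimilar <- list(v_call = "IGHV1-69", cdr3_aa = paste(far, collapse = ""))
  expect_null(match_standard(dissimilar, t1))
})

test_that("satellite matching tolerates length and offset deviations up to 2", {
  catalog <- toy_catalog()
  t1 <- catalog[1, ]
  # two residues longer, motif shifted +2: satellite but not standard
  longer <- list(v_call = "IGHV1-2", cdr3_aa = "ARDAAKGYYDSWFDP")
  expect_null(match_standard(longer, t1))
  hit <- match_satellite(longer, t1)
  expect_equal(hit$match_type, "satellite")
  expect_equal(hit$length_delta, 2L)
  expect_equal(hit$offset_delta, 2L)
  # three residues longer: bound exceeded
  longest <- list(v_call = "IGHV1-2", cdr3_aa = "ARDAAAKGYYDSWFDP")
  expect_null(match_satellite(longest, t1))
  # offset +3 at equal length: no satellite
  shifted3 <- list(v_call = "IGHV1-69", cdr3_aa = "AAARDAKGYYWFD")
  expect_equal(find_motif(shifted3$cdr3_aa, t1$motif), 6L)
  expect_null(match_satellite(shifted3, t1))
})

test_that("offset ties resolve to the more negative delta", {
  # motif at offsets 1 and 5 around subset offset 3: |1-3| == |5-3|
  expect_equal(best_offset_delta(c(1L, 5L), 3L, 2L), -2L)
  expect_equal(best_offset_delta(c(2L, 4L), 3L, 2L), -1L)
  expect_equal(best_offset_delta(c(3L, 5L), 3L, 2L), 0L)
  expect_equal(best_offset_delta(c(0L, 6L), 3L, 2L), NA_integer_)
})

test_that("a standard match implies a satellite match for the same subset", {
  catalog <- toy_catalog()
  withr::with_seed(11, {
    for (i in 1:200) {
      s <- catalog[sample(nrow(catalog), 1), ]
      chars <- strsplit(s$consensus_cdr3, "")[[1]]
      free <- setdiff(
        seq_along(chars),
        (s$motif_offset + 1):(s$motif_offset + nchar(s$motif))
      )
      mutate_at <- free[stats::runif(length(free)) < 0.3]
      for (p in mutate_at) chars[p] <- sample(AA20, 1)
      r <- list(
        v_call = sample(s$ighv_genes[[1]], 1),
        cdr3_aa = paste(chars, collapse = "")
      )
      std <- match_standard(r, s)
      if (!is.null(std)) {
        sat <- match_satellite(r, s)
        expect_false(is.null(sat))
        expect_equal(sat$subset_id, std$subset_id)
      }
    }
  })
})
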