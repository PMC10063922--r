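test_that("mutation-status classification uses the >= cutoff rule", {
  expect_equal(classify_shm(c(1, 0.98, 0.9799, 0.95)), c("U", "U", "M", "M"))
  expect_equal(classify_shm(NA_real_), NA_character_)
  expect_equal(classify_shm(0.95, cutoff = 0.9), "U")
  expect_error(classify_shm(1.2), "is.na")
})

fake_assignments <- function(n_total, n_standard = 0, n_satellite = 0,
                             population = "NAIVE", sample_id = "S1") {
  tibble::tibble(
    sample_id = sample_id,
    population = population,
    sequence_key = sprintf("%s_%s_k%05d", sample_id, population, seq_len(n_total)),
    match_type = c(
      rep("standard", n_standard), rep("satellite", n_satellite),
      rep("none", n_total - n_standard - n_satellite)
    ),
    subset_id = ifelse(
      seq_len(n_total) <= n_standard + n_satellite, "T1", NA_character_
    )
  )
}

test_that("population summaries compute unique totals and frequencies", {
  s <- summarize_populations(fake_assignments(1000, n_standard = 1))
  expect_equal(s$total_unique, 1000)
  expect_equal(s$freq_standard, 0.001)
  expect_equal(s$freq_satellite, 0)
  # no matches at all
  s0 <- summarize_populations(fake_assignments(50))
  expect_equal(s0$freq_standard, 0)
  expect_equal(s0$freq_satellite, 0)
  # missing population labels are pooled under "unlabeled"
  x <- fake_assignments(10)
  x$population <- NA_character_
  expect_warning(su <- summarize_populations(x), "unlabeled")
  expect_equal(su$population, "unlabeled")
})

test_that("concordance profiles are fractions over known-SHM assignments only", {
  x <- tibble::tibble(
    sample_id = "S1",
    population = rep(c("NAIVE", "MEM"), each = 4),
    sequence_key = sprintf("k%d", 1:8),
    subset_id = "T1",
    match_type = "standard",
    shm_class = c("U", "U", "U", "U", "U", "M", NA, NA),
    concordant_shm = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, NA, NA)
  )
  p <- concordance_profiles(x)
  expect_equal(p$concordance[p$population == "NAIVE"], 1)
  expect_equal(p$concordance[p$population == "MEM"], 0.5)
  # the unknown-SHM row is excluded from the denominator
  expect_equal(p$n[p$population == "MEM"], 2)
  expect_true(all(p$concordance >= 0 & p$concordance <= 1))
})

test_that("pattern grouping recovers planted separation and handles edge cases", {
  two_same <- tibble::tibble(
    subset_id = rep(c("A", "B"), each = 2),
    mutation_class = "U",
    population = rep(c("NAIVE", "MEM"), 2),
    n = 10,
    concordance = c(0.9, 0.1, 0.9, 0.1)
  )
  g <- group_patterns(two_same, k = 1)
  expect_equal(unique(g$pattern_id), "P1")
  g2 <- group_patterns(two_same, k = 2)
  expect_equal(dplyr::n_distinct(g2$pattern_id), 2)
  expect_error(group_patterns(two_same, k = 3), "exceeds")

  # three well-separated planted patterns
  planted <- tidyr::expand_grid(
    subset_id = sprintf("S%d", 1:6),
    population = c("TRANS", "NAIVE", "rcMZ", "MEM")
  )
  profile_of <- c(S1 = 1, S2 = 1, S3 = 2, S4 = 2, S5 = 3, S6 = 3)
  shapes <- list(c(0.95, 0.95, 0.9, 0.9), c(0.9, 0.9, 0.3, 0.1), c(0.1, 0.1, 0.5, 0.9))
  withr::with_seed(3, {
    planted$concordance <- purrr::map2_dbl(
      planted$subset_id, rep(1:4, 6),
      function(s, pi) min(1, max(0, shapes[[profile_of[[s]]]][pi] + stats::runif(1, -0.03, 0.03)))
    )
  })
  planted$mutation_class <- "U"
  planted$n <- 50
  g3 <- group_patterns(planted, k = 3)
  grouping <- dplyr::distinct(tibble::as_tibble(g3)[, c("subset_id", "pattern_id")])
  expect_equal(dplyr::n_distinct(g3$pattern_id), 3)
  expect_equal(
    unname(split(grouping$subset_id, grouping$pattern_id)[["P1"]]),
    c("S1", "S2")
  )
})

test_that("light-chain concordance checks restriction by allele-stripped gene", {
  catalog <- toy_catalog() # T2 restricted to IGLV3-21, T1 unrestricted
  cells <- tibble::tibble(
    cell_id = c("c1", "c2", "c3"),
    population = "MEM",
    heavy_v_call = c("IGHV3-21*01", "IGHV3-21*01", "IGHV1-69*01"),
    heavy_j_call = "IGHJ4",
    heavy_junction_aa = c("CARDANGMDVW", "CARDANGMDVW", "CARDKGYYDSWFDPW"),
    heavy_cdr3_aa = c("ARDANGMDV", "ARDANGMDV", "ARDKGYYDSWFDP"),
    heavy_v_identity = 1,
    light_chain = c("L", "K", "K"),
    light_v_call = c("IGLV3-21*02", "IGKV4-1*01", "IGKV1-5*03"),
    light_j_call = "IGKJ2",
    light_junction_aa = "CQQYNSYPW"
  )
  per_cell <- light_chain_concordance(cells, catalog, aggregate = FALSE)
  expect_equal(
    per_cell$status[match(c("c1", "c2", "c3"), per_cell$cell_id)],
    c("concordant", "discordant", "no_restriction")
  )
  agg <- light_chain_concordance(cells, catalog)
  t2 <- agg[agg$subset_id == "T2", ]
  expect_equal(t2$n_concordant, 1)
  expect_equal(t2$n_discordant, 1)
  expect_equal(agg$n_no_restriction[agg$subset_id == "T1"], 1)
})

test_that("Kruskal-Wallis H matches the hand-computed rank statistic", {
  df <- data.frame(
    v = c(1, 2, 3, 10, 11, 12),
    g = rep(c("a", "b"), each = 3)
  )
  kw <- kw_frequency_test(df, v, g)
  # ranks 1..6, R1 = 6, R2 = 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 27/7
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(kw$df, 1)
  # Dunn z: (2 - 5) / sqrt(3.5 * (1/3 + 1/3))
  expect_equal(tidy(kw)$z, -3 / sqrt(3.5 * 2 / 3), tolerance = 1e-12)
  expect_equal(nrow(tidy(kw)), 1)
  g <- glance(kw)
  expect_equal(g$statistic, kw$statistic)
  expect_equal(g$n_groups, 2)
})

test_that("Kruskal-Wallis is null on identical groups and errors on one group", {
  df <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  kw <- kw_frequency_test(df, v, g)
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p.value, 1)
  expect_error(
    kw_frequency_test(data.frame(v = 1:3, g = "a"), v, g),
    "at least 2"
  )
})

test_that("Dunn post-hoc covers all pairs with Holm-adjusted p-values", {
  withr::with_seed(9, {
    df <- data.frame(
      v = c(rnorm(8), rnorm(8, 3), rnorm(8)),
      g = rep(c("a", "b", "c"), each = 8)
    )
  })
  kw <- kw_frequency_test(df, v, g)
  ph <- tidy(kw)
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p.adj >= ph$p.value))
  expect_true(all(ph$p.adj <= 1))
})
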