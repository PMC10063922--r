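small_config <- function(seed = 7, n_unique = 2000, planting = NULL,
                         shm_rate = 0, tdt_on = TRUE, population = "NAIVE") {
  sim_config(
    seed = seed, n_samples = 1,
    populations = data.frame(
      population = population, n_unique = n_unique,
      shm_rate = shm_rate, tdt_on = tdt_on
    ),
    planting = planting %||% data.frame(
      subset_id = c("T1", "T2"), tier = c("standard", "satellite"),
      frequency = c(0.005, 0.01), shm_perturb = 0
    )
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical seeds reproduce the simulation bit for bit", {
  s1 <- simulate_repertoire(small_config(seed = 99), toy_catalog())
  s2 <- simulate_repertoire(small_config(seed = 99), toy_catalog())
  expect_identical(s1$rearrangements, s2$rearrangements)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_repertoire(small_config(seed = 100), toy_catalog())
  expect_false(identical(s1$rearrangements, s3$rearrangements))
})

test_that("planted counts match the configured frequencies", {
  sim <- simulate_repertoire(small_config(n_unique = 4000), toy_catalog())
  expect_equal(nrow(sim$rearrangements), 4000)
  expect_equal(sum(sim$truth$tier == "standard"), round(4000 * 0.005))
  expect_equal(sum(sim$truth$tier == "satellite"), round(4000 * 0.01))
  # planted clonotypes are distinct
  expect_equal(anyDuplicated(sim$truth$sequence_key), 0)
})

test_that("every planted clonotype satisfies exactly its requested tier", {
  catalog <- toy_catalog()
  sim <- simulate_repertoire(small_config(n_unique = 1500), catalog)
  rearr <- sim$rearrangements
  for (t in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[t, ]
    row <- rearr[rearr$sequence_id == tr$sequence_id, ]
    s <- catalog[catalog$subset_id == tr$subset_id, ]
    std <- match_standard(row, s)
    if (tr$tier == "standard") {
      expect_false(is.null(std))
    } else {
      # satellites must not be standard for any subset
      for (si in seq_len(nrow(catalog))) {
        expect_null(match_standard(row, catalog[si, ]))
      }
      expect_false(is.null(match_satellite(row, s)))
    }
  }
})

test_that("switching TdT off strictly lowers junctional diversity", {
  on <- simulate_repertoire(
    small_config(seed = 31, planting = data.frame(
      subset_id = character(), tier = character(),
      frequency = numeric(), shm_perturb = numeric()
    )),
    toy_catalog()
  )
  off <- simulate_repertoire(
    small_config(seed = 31, tdt_on = FALSE, planting = data.frame(
      subset_id = character(), tier = character(),
      frequency = numeric(), shm_perturb = numeric()
    )),
    toy_catalog()
  )
  div <- function(sim) {
    c(
      distinct = dplyr::n_distinct(sim$rearrangements$junction_aa) /
        nrow(sim$rearrangements),
      len_sd = stats::sd(nchar(sim$rearrangements$cdr3_aa))
    )
  }
  expect_lt(div(off)["distinct"], div(on)["distinct"])
  expect_lt(div(off)["len_sd"], div(on)["len_sd"])
})

test_that("germline identity follows the population SHM rate", {
  naive <- simulate_repertoire(small_config(shm_rate = 0), toy_catalog())
  expect_true(all(naive$rearrangements$v_identity == 1))
  mem <- simulate_repertoire(
    small_config(shm_rate = 0.06, population = "MEM"), toy_catalog()
  )
  expect_equal(mean(mem$rearrangements$v_identity), 0.94, tolerance = 0.005)
  expect_gt(mean(classify_shm(mem$rearrangements$v_identity) == "M"), 0.99)
})

test_that("corruption respects the rate and protected motif windows", {
  catalog <- toy_catalog()
  sim <- simulate_repertoire(small_config(n_unique = 300), catalog)
  expect_identical(corrupt_repertoire(sim$rearrangements, 0), sim$rearrangements)
  withr::with_seed(17, {
    hard <- corrupt_repertoire(sim$rearrangements, 0.999999)
  })
  # essentially every unprotected residue substituted
  bg <- !sim$rearrangements$sequence_id %in% sim$truth$sequence_id
  expect_true(all(
    mapply(oracle_identity, hard$cdr3_aa[bg], sim$rearrangements$cdr3_aa[bg]) == 0
  ))
  # protected plants keep their motif intact
  withr::with_seed(18, {
    prot <- corrupt_repertoire(sim$rearrangements, 0.5,
      truth = sim$truth, catalog = catalog
    )
  })
  for (t in seq_len(nrow(sim$truth))) {
    s <- catalog[catalog$subset_id == sim$truth$subset_id[t], ]
    cdr3 <- prot$cdr3_aa[prot$sequence_id == sim$truth$sequence_id[t]]
    expect_gt(length(find_motif(cdr3, s$motif)), 0)
  }
})

test_that("standard-plant recovery degrades monotonically with corruption", {
  catalog <- toy_catalog()
  cfg <- small_config(
    seed = 12, n_unique = 3000,
    planting = data.frame(
      subset_id = "T1", tier = "standard", frequency = 0.02, shm_perturb = 0
    )
  )
  sim <- simulate_repertoire(cfg, catalog)
  recovery <- vapply(c(0, 0.05, 0.15, 0.4), function(rate) {
    x <- if (rate == 0) {
      sim$rearrangements
    } else {
      withr::with_seed(1000 + round(rate * 100), {
        corrupt_repertoire(sim$rearrangements, rate,
          truth = sim$truth, catalog = catalog
        )
      })
    }
    a <- tibble::as_tibble(assign_stereotypes(x, catalog))
    hits <- dplyr::semi_join(
      a[a$match_type == "standard" & a$subset_id == "T1", ],
      sim$truth,
      by = "sequence_key"
    )
    nrow(hits) / nrow(sim$truth)
  }, numeric(1))
  expect_equal(recovery[1], 1)
  expect_true(all(diff(recovery) <= 0))
  expect_lt(recovery[4], recovery[1])
})

test_that("invalid configurations are rejected", {
  expect_error(
    sim_config(planting = data.frame(
      subset_id = "T1", tier = "standard", frequency = 1.2, shm_perturb = 0
    )),
    "frequencies"
  )
  expect_error(
    sim_config(planting = data.frame(
      subset_id = "T1", tier = "weird", frequency = 0.1, shm_perturb = 0
    )),
    "tier"
  )
  cfg <- small_config(planting = data.frame(
    subset_id = "NOPE", tier = "standard", frequency = 0.01, shm_perturb = 0
  ))
  expect_error(simulate_repertoire(cfg, toy_catalog()), "absent from catalog")
})
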