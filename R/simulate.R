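# Seeded synthetic AIRR repertoires with the statistical structure the
# analysis assumes: multi-donor, multi-subpopulation design, per-population
# SHM rates, TdT-dependent junctional diversity, and stereotype / satellite
# sequences planted at controlled frequencies with a ground-truth table.
#
# Junctions are generated at the amino-acid level (V tail + N additions +
# D core + N additions + J tail between the conserved C/W anchors); germline
# V identity is book-kept on a nominal 300-nt V segment under a uniform
# per-site substitution model. The matching criteria operate on the aa CDR3
# and v_identity only, so no nucleotide-level realism beyond that is
# attempted (no SHM hotspots, no biophysical V(D)J model).

V_NT_SITES <- 300L

default_gene_usage <- function() {
  list(
    v = tibble::tibble(
      gene = c(
        "IGHV1-2", "IGHV1-18", "IGHV1-69", "IGHV5-51", "IGHV7-4-1",
        "IGHV2-5", "IGHV4-34", "IGHV4-39", "IGHV4-59", "IGHV6-1",
        "IGHV3-7", "IGHV3-21", "IGHV3-23", "IGHV3-30", "IGHV3-48"
      ),
      prob = c(
        0.05, 0.04, 0.07, 0.04, 0.01,
        0.03, 0.07, 0.05, 0.05, 0.02,
        0.08, 0.08, 0.15, 0.14, 0.12
      )
    ),
    d = tibble::tibble(
      gene = c(
        "IGHD1-26", "IGHD2-2", "IGHD3-10", "IGHD3-22",
        "IGHD4-17", "IGHD5-12", "IGHD6-19"
      ),
      core = c("SGGSY", "DIVVV", "YYYGSG", "YYDSSG", "DYGDY", "GYSGY", "SSGWY"),
      prob = c(0.15, 0.1, 0.2, 0.15, 0.15, 0.1, 0.15)
    ),
    j = tibble::tibble(
      gene = c("IGHJ1", "IGHJ2", "IGHJ3", "IGHJ4", "IGHJ5", "IGHJ6"),
      tail = c("FQH", "WYFDL", "AFDV", "FDY", "NWFDS", "YYGMDV"),
      prob = c(0.03, 0.05, 0.1, 0.42, 0.1, 0.3)
    )
  )
}

default_sim_populations <- function() {
  tibble::tibble(
    population = c("TRANS", "NAIVE", "rcMZ", "MEM", "DN"),
    n_unique = c(4000L, 12000L, 6000L, 8000L, 3000L),
    shm_rate = c(0, 0, 0.04, 0.06, 0.05),
    tdt_on = TRUE
  )
}

default_sim_planting <- function() {
  tibble::tibble(
    subset_id = rep(c("T1", "T2", "T3"), 2),
    tier = rep(c("standard", "satellite"), each = 3),
    frequency = c(4e-4, 3e-4, 3e-4, 4e-3, 3e-3, 3e-3),
    shm_perturb = 0
  )
}

#' Configuration for a synthetic repertoire
#'
#' Bundles and validates the generator parameters. The defaults describe
#' the study conditions the package targets: several donors; transitional
#' and naive populations without somatic hypermutation and
#' antigen-experienced populations (rcMZ, MEM, DN) with per-site SHM rates
#' of 4-6%; TdT active (neonatal cord-blood-like repertoires are emulated
#' by `tdt_on = FALSE`, which removes non-templated junction additions);
#' standard plants totalling 1e-3 and satellite plants totalling 1e-2 of
#' each population's unique sequences, in the 10:1 satellite:standard
#' proportion seen in normal repertoires.
#'
#' @param seed Integer seed; runs are bit-for-bit reproducible given it.
#' @param n_samples Number of donors.
#' @param populations Data frame with `population`, `n_unique` (unique
#'   sequences per donor), `shm_rate` (per-site substitution probability on
#'   the V segment), `tdt_on` (logical).
#' @param planting Data frame with `subset_id`, `tier` (`"standard"` /
#'   `"satellite"`), `frequency` (per population) and `shm_perturb`
#'   (per-residue amino-acid perturbation applied to planted CDR3s).
#' @param gene_usage Optional list of `v`, `d`, `j` usage tables (see
#'   package source for the default layout).
#' @param cdr3_length_distribution Optional data frame (`length`, `prob`)
#'   overriding the compositional junction model for background sequences.
#' @return A validated list of class `sls_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 3L,
                       populations = default_sim_populations(),
                       planting = default_sim_planting(),
                       gene_usage = NULL,
                       cdr3_length_distribution = NULL) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1, !is.na(seed))
  populations <- tibble::as_tibble(populations)
  stopifnot(all(c("population", "n_unique", "shm_rate", "tdt_on") %in% names(populations)))
  populations$n_unique <- as.integer(populations$n_unique)
  if (any(populations$n_unique < 1) ||
    any(populations$shm_rate < 0 | populations$shm_rate > 1)) {
    stop("invalid `populations`: n_unique must be >= 1 and shm_rate in [0, 1]",
      call. = FALSE
    )
  }
  planting <- tibble::as_tibble(planting)
  if (nrow(planting) > 0) {
    stopifnot(all(c("subset_id", "tier", "frequency", "shm_perturb") %in% names(planting)))
    if (any(!planting$tier %in% c("standard", "satellite"))) {
      stop("planting tier must be \"standard\" or \"satellite\"", call. = FALSE)
    }
    if (any(planting$frequency < 0 | planting$frequency > 1) ||
      sum(planting$frequency) > 1) {
      stop("planting frequencies must lie in [0, 1] and sum to at most 1 per population",
        call. = FALSE
      )
    }
    if (any(planting$shm_perturb < 0 | planting$shm_perturb >= 1)) {
      stop("shm_perturb must lie in [0, 1)", call. = FALSE)
    }
  }
  structure(
    list(
      seed = seed, n_samples = as.integer(n_samples),
      populations = populations, planting = planting,
      gene_usage = gene_usage %||% default_gene_usage(),
      cdr3_length_distribution = cdr3_length_distribution
    ),
    class = "sls_sim_config"
  )
}

#' Simulate an annotated repertoire with planted CLL-SLS
#'
#' Generates background rearrangements from the configured gene usage and
#' junction model, plants standard stereotype and satellite sequences at the
#' configured per-population frequencies, and returns the repertoire
#' together with a ground-truth table of every planted clonotype.
#'
#' Standard plants start from the subset consensus CDR3 and receive
#' junctional variation at non-motif positions by conservative
#' (same-similarity-group) substitutions — keeping every plant a distinct
#' clonotype, as quasi-identical stereotyped sequences are across donors —
#' then the optional `shm_perturb` amino-acid noise; each plant is re-checked
#' against the full standard criteria (and re-sampled otherwise). Satellite
#' plants additionally receive a 1-2 residue CDR3 length edit and/or motif
#' offset shift within the satellite tolerances and are verified to satisfy
#' the satellite but not the standard criteria for any subset.
#'
#' @param config An [sim_config()].
#' @param catalog An [subset_catalog()] containing all planted subsets.
#' @param clan_map,groups,association Matching conventions used for plant
#'   verification; keep in sync with the values later given to
#'   [assign_stereotypes()].
#' @return A list of class `sls_simulation` with elements `rearrangements`
#'   (AIRR-shaped tibble), `truth` (tibble: `sample_id`, `population`,
#'   `sequence_id`, `sequence_key`, `subset_id`, `tier`) and `config`.
#' @examples
#' cfg <- sim_config(seed = 7, n_samples = 1,
#'   populations = data.frame(population = "NAIVE", n_unique = 1000,
#'     shm_rate = 0, tdt_on = TRUE))
#' sim <- simulate_repertoire(cfg, toy_catalog())
#' nrow(sim$rearrangements)
#' @export
simulate_repertoire <- function(config, catalog,
                                clan_map = default_clan_map(),
                                groups = default_similarity_groups(),
                                association = NULL) {
  stopifnot(inherits(config, "sls_sim_config"), inherits(catalog, "sls_catalog"))
  missing_subsets <- setdiff(config$planting$subset_id, catalog$subset_id)
  if (length(missing_subsets) > 0) {
    stop("planted subset(s) absent from catalog: ",
      paste(missing_subsets, collapse = ", "),
      call. = FALSE
    )
  }
  for (sid in unique(config$planting$subset_id)) {
    s <- catalog[catalog$subset_id == sid, ]
    if (!motif_matches_at(s$consensus_cdr3, s$motif, s$motif_offset)) {
      stop("cannot plant subset ", sid,
        ": its consensus CDR3 does not carry the motif at motif_offset",
        call. = FALSE
      )
    }
  }
  codes <- residue_group_codes(groups)

  withr::with_seed(config$seed, {
    used_keys <- new.env(parent = emptyenv())
    samples <- paste0("S", seq_len(config$n_samples))
    parts <- list()
    truth_parts <- list()
    for (sample_id in samples) {
      for (pi in seq_len(nrow(config$populations))) {
        pop <- config$populations[pi, ]
        plants <- list()
        truths <- list()
        if (nrow(config$planting) > 0) {
          for (ki in seq_len(nrow(config$planting))) {
            pl <- config$planting[ki, ]
            n_k <- round(pop$n_unique * pl$frequency)
            if (n_k == 0) next
            s <- catalog[catalog$subset_id == pl$subset_id, ]
            p <- make_plants(
              s, pl$tier, n_k, pl$shm_perturb, catalog, clan_map, codes,
              association, config$gene_usage, used_keys
            )
            plants[[length(plants) + 1]] <- p
            truths[[length(truths) + 1]] <- tibble::tibble(
              junction_aa = p$junction_aa, v_call = p$v_call, j_call = p$j_call,
              subset_id = pl$subset_id, tier = pl$tier
            )
          }
        }
        plants <- dplyr::bind_rows(plants)
        n_bg <- pop$n_unique - nrow(plants)
        bg <- make_background(n_bg, pop, config$gene_usage, config$cdr3_length_distribution)
        block <- dplyr::bind_rows(plants, bg)
        block$v_identity <- 1 - stats::rbinom(nrow(block), V_NT_SITES, pop$shm_rate) / V_NT_SITES
        block$sample_id <- sample_id
        block$population <- pop$population
        block$sequence_id <- sprintf(
          "%s_%s_%06d", sample_id, pop$population, seq_len(nrow(block))
        )
        parts[[length(parts) + 1]] <- block
        if (length(truths) > 0) {
          tr <- dplyr::bind_rows(truths)
          tr$sample_id <- sample_id
          tr$population <- pop$population
          tr$sequence_id <- block$sequence_id[seq_len(nrow(tr))]
          truth_parts[[length(truth_parts) + 1]] <- tr
        }
      }
    }
    rearr <- dplyr::bind_rows(parts)
    rearr <- tibble::tibble(
      sequence_id = rearr$sequence_id,
      sample_id = rearr$sample_id,
      population = rearr$population,
      chain = "H",
      v_call = rearr$v_call,
      d_call = rearr$d_call,
      j_call = rearr$j_call,
      junction_aa = rearr$junction_aa,
      cdr3_aa = substr(rearr$junction_aa, 2, nchar(rearr$junction_aa) - 1),
      v_identity = rearr$v_identity,
      isotype = NA_character_,
      productive = TRUE
    )
    truth <- if (length(truth_parts) > 0) {
      dplyr::bind_rows(truth_parts) |>
        dplyr::mutate(sequence_key = unique_key(.data$v_call, .data$j_call, .data$junction_aa)) |>
        dplyr::select(
          "sample_id", "population", "sequence_id", "sequence_key",
          "subset_id", "tier"
        )
    } else {
      tibble::tibble(
        sample_id = character(), population = character(),
        sequence_id = character(), sequence_key = character(),
        subset_id = character(), tier = character()
      )
    }
    structure(
      list(rearrangements = rearr, truth = truth, config = config),
      class = "sls_simulation"
    )
  })
}

random_aa <- function(n) {
  if (n <= 0) {
    return("")
  }
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

make_background <- function(n, pop, gene_usage, length_dist) {
  if (n <= 0) {
    return(tibble::tibble(
      v_call = character(), d_call = character(), j_call = character(),
      junction_aa = character()
    ))
  }
  v <- sample(gene_usage$v$gene, n, replace = TRUE, prob = gene_usage$v$prob)
  di <- sample(nrow(gene_usage$d), n, replace = TRUE, prob = gene_usage$d$prob)
  ji <- sample(nrow(gene_usage$j), n, replace = TRUE, prob = gene_usage$j$prob)
  tails <- gene_usage$j$tail[ji]
  if (is.null(length_dist)) {
    # compositional model: V tail "AR" + N1 + D core + N2 + J tail, with
    # non-templated N additions only when TdT is on
    n1 <- if (pop$tdt_on) pmin(stats::rpois(n, 1.5), 6L) else integer(n)
    n2 <- if (pop$tdt_on) pmin(stats::rpois(n, 1.5), 6L) else integer(n)
    cdr3 <- paste0(
      "AR",
      vapply(n1, random_aa, character(1)),
      gene_usage$d$core[di],
      vapply(n2, random_aa, character(1)),
      tails
    )
  } else {
    L <- sample(length_dist$length, n, replace = TRUE, prob = length_dist$prob)
    cdr3 <- vapply(seq_len(n), function(i) {
      mid <- max(L[i] - 2L - nchar(tails[i]), 0L)
      out <- paste0("AR", random_aa(mid), tails[i])
      substr(out, 1, L[i])
    }, character(1))
  }
  tibble::tibble(
    v_call = paste0(v, "*01"),
    d_call = paste0(gene_usage$d$gene[di], "*01"),
    j_call = paste0(gene_usage$j$gene[ji], "*01"),
    junction_aa = paste0("C", cdr3, "W")
  )
}

# Conservative junctional variation: substitute free (non-motif) positions,
# each with probability p_sub, by another residue of the same similarity
# group (keeps similarity to the consensus at 1).
vary_same_group <- function(chars, free_idx, codes, p_sub = 0.35) {
  groups_by_code <- split(names(codes), codes)
  for (i in free_idx) {
    if (stats::runif(1) < p_sub) {
      members <- groups_by_code[[as.character(codes[[chars[i]]])]]
      chars[i] <- sample(members, 1)
    }
  }
  chars
}

perturb_any <- function(chars, rate) {
  if (rate <= 0) {
    return(chars)
  }
  hit <- stats::runif(length(chars)) < rate
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1)
  }
  chars
}

# sample() that never expands a scalar x into 1:x
resample <- function(x, size = 1) x[sample.int(length(x), size)]

# One structural satellite edit of the consensus: returns list(chars, offset)
# with |length delta| in 1..2 and |offset delta| <= 2, motif untouched.
satellite_edit <- function(cons_chars, motif_offset, motif_len) {
  L <- length(cons_chars)
  pre <- motif_offset # residues before the motif (0-based offset)
  post <- L - motif_offset - motif_len
  moves <- list()
  for (k in 1:2) {
    moves[[length(moves) + 1]] <- list(op = "ins_pre", k = k)
    if (pre >= k) moves[[length(moves) + 1]] <- list(op = "del_pre", k = k)
    moves[[length(moves) + 1]] <- list(op = "ins_post", k = k)
    if (post >= k) moves[[length(moves) + 1]] <- list(op = "del_post", k = k)
  }
  mv <- moves[[sample.int(length(moves), 1)]]
  k <- mv$k
  if (mv$op == "ins_pre") {
    at <- resample(0:pre) # insert before the motif
    chars <- append(cons_chars, sample(AA_ALPHABET, k, replace = TRUE), after = at)
    offset <- motif_offset + k
  } else if (mv$op == "del_pre") {
    del <- resample(seq_len(pre), k) # delete from the prefix
    chars <- cons_chars[-del]
    offset <- motif_offset - k
  } else if (mv$op == "ins_post") {
    at <- resample((motif_offset + motif_len):L)
    chars <- append(cons_chars, sample(AA_ALPHABET, k, replace = TRUE), after = at)
    offset <- motif_offset
  } else {
    del <- motif_offset + motif_len + resample(seq_len(post), k)
    chars <- cons_chars[-del]
    offset <- motif_offset
  }
  list(chars = chars, offset = offset)
}

make_plants <- function(s, tier, n, shm_perturb, catalog, clan_map, codes,
                        association, gene_usage, used_keys,
                        max_tries = 200L) {
  cons_chars <- strsplit(s$consensus_cdr3, "")[[1]]
  motif_len <- nchar(s$motif)
  j_genes <- gene_usage$j$gene
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      v_gene <- sample(s$ighv_genes[[1]], 1)
      j_gene <- sample(j_genes, 1)
      if (tier == "standard") {
        free_idx <- setdiff(seq_along(cons_chars), (s$motif_offset + 1):(s$motif_offset + motif_len))
        chars <- vary_same_group(cons_chars, free_idx, codes)
      } else {
        ed <- satellite_edit(cons_chars, s$motif_offset, motif_len)
        free_idx <- setdiff(seq_along(ed$chars), (ed$offset + 1):(ed$offset + motif_len))
        chars <- vary_same_group(ed$chars, free_idx, codes)
      }
      chars <- perturb_any(chars, shm_perturb)
      cdr3 <- paste(chars, collapse = "")
      r <- list(v_call = v_gene, cdr3_aa = cdr3)
      if (plant_is_valid(r, s, tier, catalog, clan_map, codes, association)) {
        key <- unique_key(v_gene, j_gene, paste0("C", cdr3, "W"))
        if (is.null(used_keys[[key]])) {
          used_keys[[key]] <- TRUE
          out[[i]] <- tibble::tibble(
            v_call = paste0(v_gene, "*01"),
            d_call = NA_character_,
            j_call = paste0(j_gene, "*01"),
            junction_aa = paste0("C", cdr3, "W")
          )
          ok <- TRUE
          break
        }
      }
    }
    if (!ok) {
      stop(sprintf(
        "could not generate a valid %s plant for subset %s after %d tries",
        tier, s$subset_id, max_tries
      ), call. = FALSE)
    }
  }
  dplyr::bind_rows(out)
}

# A plant is valid when the best match across the whole catalog is the
# requested subset at the requested tier.
plant_is_valid <- function(r, s, tier, catalog, clan_map, codes, association) {
  groups <- split(names(codes), codes) # reconstitute grouping for predicates
  std <- purrr::map(seq_len(nrow(catalog)), function(si) {
    match_standard(r, catalog[si, ], clan_map, groups)
  })
  std <- dplyr::bind_rows(std)
  if (tier == "standard") {
    if (nrow(std) == 0) {
      return(FALSE)
    }
    best <- std[order(-std$similarity, -std$identity, std$subset_id), ][1, ]
    return(best$subset_id == s$subset_id)
  }
  if (nrow(std) > 0) {
    return(FALSE)
  }
  sat <- purrr::map(seq_len(nrow(catalog)), function(si) {
    match_satellite(r, catalog[si, ], clan_map, groups, association)
  })
  sat <- dplyr::bind_rows(sat)
  if (nrow(sat) == 0) {
    return(FALSE)
  }
  best <- sat[order(-sat$similarity, -sat$identity, sat$subset_id), ][1, ]
  best$subset_id == s$subset_id
}

#' Randomly corrupt CDR3 residues of a repertoire
#'
#' Robustness instrument: substitutes each CDR3 residue independently with
#' probability `rate` by a different residue. When `truth` and `catalog` are
#' given, the planted motif windows are protected so that corruption
#' degrades the identity/similarity criteria rather than trivially deleting
#' the motif.
#'
#' @param rearrangements A rearrangement tibble.
#' @param rate Per-residue substitution probability in \[0, 1).
#' @param truth,catalog Optional simulation truth table and catalog used to
#'   locate planted motif windows.
#' @return The rearrangement tibble with corrupted `cdr3_aa`/`junction_aa`.
#' @export
corrupt_repertoire <- function(rearrangements, rate, truth = NULL, catalog = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) {
    return(rearrangements)
  }
  x <- rearrangements
  protect <- rep(list(integer(0)), nrow(x))
  if (!is.null(truth) && !is.null(catalog) && nrow(truth) > 0) {
    idx <- match(truth$sequence_id, x$sequence_id)
    for (t in seq_len(nrow(truth))) {
      i <- idx[t]
      if (is.na(i)) next
      s <- catalog[catalog$subset_id == truth$subset_id[t], ]
      offs <- find_motif(x$cdr3_aa[i], s$motif)
      if (length(offs) == 0) next
      o <- offs[order(abs(offs - s$motif_offset))][1]
      protect[[i]] <- (o + 1):(o + nchar(s$motif))
    }
  }
  x$cdr3_aa <- vapply(seq_len(nrow(x)), function(i) {
    chars <- strsplit(x$cdr3_aa[i], "")[[1]]
    free <- setdiff(seq_along(chars), protect[[i]])
    hit <- free[stats::runif(length(free)) < rate]
    for (p in hit) chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
    paste(chars, collapse = "")
  }, character(1))
  x$junction_aa <- paste0("C", x$cdr3_aa, "W")
  x
}

#' Write a simulation to disk
#'
#' Writes the rearrangements as AIRR TSV and the truth table as TSV.
#'
#' @param sim An [simulate_repertoire()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the two paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  airr_path <- file.path(dir, "rearrangements.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  write_airr(sim$rearrangements, airr_path)
  readr::write_tsv(sim$truth, truth_path)
  invisible(c(airr_path, truth_path))
}

#' @export
print.sls_simulation <- function(x, ...) {
  cat(sprintf(
    "Synthetic repertoire: %d rearrangements, %d donors, %d populations, %d planted clonotypes (seed %d)\n",
    nrow(x$rearrangements), x$config$n_samples,
    nrow(x$config$populations), nrow(x$truth), x$config$seed
  ))
  invisible(x)
}
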