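# Repertoire-scale stereotype assignment. The per-sequence predicates in
# matching.R define the criteria; this file applies them, vectorised, to
# every unique clonotype of an annotated repertoire and resolves the
# standard-over-satellite precedence and multi-subset ties.

#' Assign rearrangements to stereotyped CLL subsets
#'
#' The core pipeline step: collapses heavy-chain rearrangements to unique
#' clonotypes (see [collapse_rearrangements()]), tests every clonotype
#' against every catalog subset under the standard criteria, and tests the
#' clonotypes left unmatched under the satellite criteria. A clonotype with
#' a standard match is never also counted as a satellite (the two tiers are
#' disjoint). A clonotype matching several subsets within one tier is
#' resolved by highest similarity, then highest identity, then
#' lexicographic `subset_id`; the number of such ties is reported with a
#' message and kept in the `ties` attribute.
#'
#' @param rearrangements Tibble of annotated rearrangements ([read_airr()]
#'   or [simulate_repertoire()] output). Non-heavy chains are dropped.
#' @param catalog An [subset_catalog()].
#' @param clan_map Family-to-clan table.
#' @param groups Similarity grouping (see [default_similarity_groups()]).
#' @param association Optional extra clan-association pairs for the
#'   satellite tier; `NULL` means associated = same clan.
#' @param identity_min,similarity_min Standard-tier thresholds (0.5 / 0.7).
#' @param max_length_delta,max_offset_delta Satellite tolerances (2 / 2).
#' @param shm_cutoff Germline V identity at or above which a sequence is
#'   classed IGHV-unmutated (`"U"`); default 0.98.
#' @param key_type Clonotype key level, `"aa"` (default) or `"nt"`.
#' @return A tibble of class `sls_assignments`, one row per
#'   (sample, population, clonotype): `sequence_key`, `v_call`, `j_call`,
#'   `cdr3_aa`, `v_identity`, `n_copies`, `subset_id`, `match_type`
#'   (`"standard"`, `"satellite"` or `"none"`), `identity`, `similarity`,
#'   `length_delta`, `offset_delta`, `shm_class` (`"U"`/`"M"`/NA) and
#'   `concordant_shm` (does `shm_class` equal the matched subset's canonical
#'   class; NA for unmatched or unknown-SHM rows).
#' @examples
#' catalog <- toy_catalog()
#' sim <- simulate_repertoire(sim_config(seed = 1, n_samples = 1,
#'   populations = data.frame(population = "NAIVE", n_unique = 500,
#'     shm_rate = 0, tdt_on = TRUE)), catalog)
#' assign_stereotypes(sim$rearrangements, catalog)
#' @export
assign_stereotypes <- function(rearrangements, catalog,
                               clan_map = default_clan_map(),
                               groups = default_similarity_groups(),
                               association = NULL,
                               identity_min = 0.5, similarity_min = 0.7,
                               max_length_delta = 2L, max_offset_delta = 2L,
                               shm_cutoff = 0.98,
                               key_type = c("aa", "nt")) {
  key_type <- match.arg(key_type)
  stopifnot(inherits(catalog, "sls_catalog"), nrow(catalog) > 0)
  codes <- residue_group_codes(groups)

  heavy <- dplyr::filter(rearrangements, chain_of_v_call(.data$v_call) == "H")
  if (nrow(heavy) < nrow(rearrangements)) {
    message(sprintf(
      "assign_stereotypes: dropped %d non-heavy-chain row(s)",
      nrow(rearrangements) - nrow(heavy)
    ))
  }
  collapsed <- collapse_rearrangements(heavy, key_type)
  if (nrow(collapsed) == 0) {
    return(empty_assignments(catalog))
  }

  keys <- collapsed |>
    dplyr::distinct(.data$sequence_key, .keep_all = TRUE) |>
    dplyr::arrange(.data$sequence_key)
  keys$clan <- clan_of(keys$v_call, clan_map)
  keys$cdr3_len <- nchar(keys$cdr3_aa)

  standard <- match_tier_standard(keys, catalog, codes, identity_min, similarity_min)
  satellite_keys <- keys[!keys$sequence_key %in% standard$sequence_key, , drop = FALSE]
  satellite <- match_tier_satellite(
    satellite_keys, catalog, codes, association,
    max_length_delta, max_offset_delta
  )

  picked <- dplyr::bind_rows(standard, satellite)
  ties <- attr(standard, "ties") + attr(satellite, "ties")
  if (ties > 0) {
    message(sprintf(
      "assign_stereotypes: %d clonotype(s) matched multiple subsets in one tier; ties broken by similarity, then identity, then subset_id",
      ties
    ))
  }

  out <- collapsed |>
    dplyr::left_join(picked, by = "sequence_key") |>
    dplyr::mutate(
      match_type = dplyr::coalesce(.data$match_type, "none"),
      shm_class = classify_shm(.data$v_identity, cutoff = shm_cutoff)
    ) |>
    dplyr::left_join(
      tibble::tibble(
        subset_id = catalog$subset_id,
        subset_class = catalog$mutation_class
      ),
      by = "subset_id"
    ) |>
    dplyr::mutate(
      concordant_shm = ifelse(
        .data$match_type == "none" | is.na(.data$shm_class),
        NA, .data$shm_class == .data$subset_class
      ),
      subset_class = NULL
    ) |>
    dplyr::select(
      "sample_id", "population", "sequence_key", "v_call", "j_call",
      "junction_aa", "cdr3_aa", "v_identity", "n_copies", "subset_id",
      "match_type", "identity", "similarity", "length_delta", "offset_delta",
      "shm_class", "concordant_shm"
    ) |>
    dplyr::arrange(.data$sample_id, .data$population, .data$sequence_key)

  class(out) <- c("sls_assignments", class(out))
  attr(out, "catalog") <- catalog
  attr(out, "ties") <- ties
  attr(out, "params") <- list(
    identity_min = identity_min, similarity_min = similarity_min,
    max_length_delta = max_length_delta, max_offset_delta = max_offset_delta,
    shm_cutoff = shm_cutoff, key_type = key_type
  )
  out
}

empty_assignments <- function(catalog) {
  out <- tibble::tibble(
    sample_id = character(), population = character(), sequence_key = character(),
    v_call = character(), j_call = character(), junction_aa = character(),
    cdr3_aa = character(), v_identity = numeric(), n_copies = integer(),
    subset_id = character(), match_type = character(), identity = numeric(),
    similarity = numeric(), length_delta = integer(), offset_delta = integer(),
    shm_class = character(), concordant_shm = logical()
  )
  class(out) <- c("sls_assignments", class(out))
  attr(out, "catalog") <- catalog
  attr(out, "ties") <- 0L
  out
}

# Identity and similarity of many equal-length CDR3s against one consensus.
score_against_consensus <- function(cdr3s, consensus, codes) {
  n <- length(cdr3s)
  if (n == 0) {
    return(list(identity = numeric(0), similarity = numeric(0)))
  }
  len <- nchar(consensus)
  m <- matrix(unlist(strsplit(cdr3s, ""), use.names = FALSE), nrow = len)
  cons <- strsplit(consensus, "")[[1]]
  eq <- m == cons
  code_m <- matrix(codes[m], nrow = len)
  code_eq <- code_m == codes[cons]
  list(identity = colMeans(eq), similarity = colMeans(code_eq))
}

match_tier_standard <- function(keys, catalog, codes, identity_min, similarity_min) {
  hits <- purrr::map(seq_len(nrow(catalog)), function(si) {
    s <- catalog[si, ]
    idx <- which(keys$clan == s$clan & keys$cdr3_len == s$cdr3_length)
    if (length(idx) == 0) {
      return(NULL)
    }
    cands <- keys$cdr3_aa[idx]
    sc <- score_against_consensus(cands, s$consensus_cdr3, codes)
    window <- substr(cands, s$motif_offset + 1, s$motif_offset + nchar(s$motif))
    motif_ok <- grepl(paste0("^", motif_regex(s$motif), "$"), window)
    ok <- sc$identity >= identity_min & sc$similarity >= similarity_min & motif_ok
    if (!any(ok)) {
      return(NULL)
    }
    tibble::tibble(
      sequence_key = keys$sequence_key[idx][ok],
      subset_id = s$subset_id, match_type = "standard",
      identity = sc$identity[ok], similarity = sc$similarity[ok],
      length_delta = 0L, offset_delta = 0L
    )
  })
  pick_best(dplyr::bind_rows(hits))
}

match_tier_satellite <- function(keys, catalog, codes, association,
                                 max_length_delta, max_offset_delta) {
  hits <- purrr::map(seq_len(nrow(catalog)), function(si) {
    s <- catalog[si, ]
    idx <- which(
      clans_associated(keys$clan, s$clan, association) &
        abs(keys$cdr3_len - s$cdr3_length) <= max_length_delta
    )
    if (length(idx) == 0) {
      return(NULL)
    }
    cands <- keys$cdr3_aa[idx]
    offsets <- find_motif_all(cands, s$motif)
    delta <- vapply(offsets, best_offset_delta, integer(1),
      motif_offset = s$motif_offset, max_offset_delta = max_offset_delta
    )
    ok <- which(!is.na(delta))
    if (length(ok) == 0) {
      return(NULL)
    }
    scores <- vapply(ok, function(i) {
      anchored_scores(cands[i], s$consensus_cdr3, delta[i], codes)
    }, c(identity = 0, similarity = 0))
    tibble::tibble(
      sequence_key = keys$sequence_key[idx][ok],
      subset_id = s$subset_id, match_type = "satellite",
      identity = scores["identity", ], similarity = scores["similarity", ],
      length_delta = keys$cdr3_len[idx][ok] - s$cdr3_length,
      offset_delta = delta[ok]
    )
  })
  pick_best(dplyr::bind_rows(hits))
}

# Resolve multi-subset matches within a tier; count ties in attr "ties".
pick_best <- function(hits) {
  if (nrow(hits) == 0) {
    out <- tibble::tibble(
      sequence_key = character(), subset_id = character(),
      match_type = character(), identity = numeric(), similarity = numeric(),
      length_delta = integer(), offset_delta = integer()
    )
    attr(out, "ties") <- 0L
    return(out)
  }
  n_multi <- sum(table(hits$sequence_key) > 1)
  out <- hits |>
    dplyr::arrange(
      .data$sequence_key, dplyr::desc(.data$similarity),
      dplyr::desc(.data$identity), .data$subset_id
    ) |>
    dplyr::distinct(.data$sequence_key, .keep_all = TRUE)
  attr(out, "ties") <- n_multi
  out
}

#' Write an assignment table as TSV
#'
#' @param assignments An `sls_assignments` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  readr::write_tsv(tibble::as_tibble(assignments), path)
  invisible(path)
}
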