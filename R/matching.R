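# Core VH CDR3 comparison primitives and the per-sequence standard /
# satellite matching predicates. The criteria implemented here ARE the
# method: a rearrangement is a standard stereotype match when it (i) uses an
# IGHV gene of the subset's phylogenetic clan, (ii) reaches >= 50% amino-acid
# identity and >= 70% similarity to the subset consensus VH CDR3, (iii) has
# the same VH CDR3 length, and (iv) carries the subset motif at the identical
# offset. The satellite tier relaxes this to phylogenetically associated IGHV
# genes, a CDR3 length difference of at most 2 residues, and the motif at an
# offset within +/- 2 of the subset's.

check_equal_length_pair <- function(a, b) {
  if (length(a) != length(b)) {
    if (length(a) == 1) a <- rep(a, length(b))
    else if (length(b) == 1) b <- rep(b, length(a))
    else stop("`a` and `b` must have the same length", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("sequences must not be NA", call. = FALSE)
  if (any(nchar(a) == 0)) stop("sequences must be non-empty", call. = FALSE)
  if (any(nchar(a) != nchar(b))) {
    stop("sequences in a pair must have equal length", call. = FALSE)
  }
  list(a = a, b = b)
}

#' Amino-acid identity between equal-length sequences
#'
#' Fraction of aligned positions carrying the identical residue. Both
#' arguments are vectorised pairwise (with recycling of a scalar).
#'
#' @param a,b Character vectors of equal-length amino-acid sequences.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' aa_identity("ARDA", "ARDG")
#' @export
aa_identity <- function(a, b) {
  p <- check_equal_length_pair(a, b)
  purrr::map2_dbl(strsplit(p$a, ""), strsplit(p$b, ""), ~ mean(.x == .y))
}

#' Amino-acid similarity between equal-length sequences
#'
#' Fraction of aligned positions whose residues are identical or fall in the
#' same conservative-substitution group; always at least [aa_identity()].
#'
#' @inheritParams aa_identity
#' @param groups Residue grouping partitioning the 20 amino acids, as from
#'   [default_similarity_groups()].
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' aa_similarity("KRDA", "RKDA") # K and R share the basic group
#' @export
aa_similarity <- function(a, b, groups = default_similarity_groups()) {
  p <- check_equal_length_pair(a, b)
  codes <- residue_group_codes(groups)
  purrr::map2_dbl(strsplit(p$a, ""), strsplit(p$b, ""), function(ra, rb) {
    ca <- codes[ra]
    cb <- codes[rb]
    if (anyNA(ca) || anyNA(cb)) {
      stop("residue outside the 20-letter amino-acid alphabet", call. = FALSE)
    }
    mean(ca == cb)
  })
}

#' Find all offsets of a motif within a CDR3
#'
#' Returns every 0-based offset at which `motif` matches `cdr3`, including
#' overlapping occurrences. `"X"` in the motif matches any residue. A motif
#' longer than the CDR3 yields an empty result.
#'
#' @param cdr3 A single amino-acid CDR3 string.
#' @param motif Amino-acid motif, possibly with `X` wildcards.
#' @return Integer vector of 0-based offsets (possibly empty).
#' @examples
#' find_motif("GYYGYY", "GYY")
#' find_motif("ARGAYYGMDV", "GXY")
#' @export
find_motif <- function(cdr3, motif) {
  stopifnot(length(cdr3) == 1, length(motif) == 1)
  if (is.na(motif) || nchar(motif) == 0) stop("`motif` must be non-empty", call. = FALSE)
  if (nchar(motif) > nchar(cdr3)) {
    return(integer(0))
  }
  hits <- gregexpr(paste0("(?=", motif_regex(motif), ")"), cdr3, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
}

# Vectorised overlapping motif search: list of 0-based offset vectors.
find_motif_all <- function(cdr3s, motif) {
  hits <- gregexpr(paste0("(?=", motif_regex(motif), ")"), cdr3s, perl = TRUE)
  lapply(hits, function(h) if (h[1] == -1) integer(0) else as.integer(h) - 1L)
}

# From candidate motif offsets, the satellite offset delta: minimal |delta|
# within the tolerance, ties resolved toward the more negative delta.
best_offset_delta <- function(offsets, motif_offset, max_offset_delta) {
  if (length(offsets) == 0) {
    return(NA_integer_)
  }
  delta <- offsets - motif_offset
  delta <- delta[abs(delta) <= max_offset_delta]
  if (length(delta) == 0) {
    return(NA_integer_)
  }
  delta <- delta[order(abs(delta), delta)]
  delta[1]
}

# Identity/similarity on the motif-anchored overlap of two CDR3s that may
# differ in length: the query is shifted by `offset_delta` so the motifs
# align, and only positions present in both sequences are compared.
anchored_scores <- function(cdr3, consensus, offset_delta, group_codes) {
  q <- strsplit(cdr3, "")[[1]]
  s <- strsplit(consensus, "")[[1]]
  # query position i aligns with consensus position i - offset_delta
  qi <- seq_along(q)
  si <- qi - offset_delta
  keep <- si >= 1 & si <= length(s)
  if (!any(keep)) {
    return(c(identity = 0, similarity = 0))
  }
  qr <- q[qi[keep]]
  sr <- s[si[keep]]
  c(
    identity = mean(qr == sr),
    similarity = mean(group_codes[qr] == group_codes[sr])
  )
}

#' Match one rearrangement against one subset (standard criteria)
#'
#' Applies the four standard criteria of a query heavy-chain CDR3 against a
#' single subset definition. Intended for inspection of single sequences;
#' use [assign_stereotypes()] for whole repertoires.
#'
#' @param rearrangement A list or one-row data frame with at least `v_call`
#'   and `cdr3_aa` (or `junction_aa`).
#' @param subset One row of an [subset_catalog()] (as list or one-row tibble).
#' @param clan_map Family-to-clan table.
#' @param groups Similarity grouping.
#' @param identity_min,similarity_min Criterion thresholds (defaults 0.5 and
#'   0.7).
#' @return A one-row tibble (`subset_id`, `match_type = "standard"`,
#'   `identity`, `similarity`, `length_delta = 0`, `offset_delta = 0`) or
#'   `NULL` when any criterion fails.
#' @export
match_standard <- function(rearrangement, subset, clan_map = default_clan_map(),
                           groups = default_similarity_groups(),
                           identity_min = 0.5, similarity_min = 0.7) {
  subset <- as.list(subset)
  cdr3 <- rearrangement_cdr3(rearrangement)
  if (clan_of(rearrangement$v_call[[1]], clan_map) != subset$clan) {
    return(NULL)
  }
  if (nchar(cdr3) != subset$cdr3_length) {
    return(NULL)
  }
  id <- aa_identity(cdr3, subset$consensus_cdr3)
  sim <- aa_similarity(cdr3, subset$consensus_cdr3, groups)
  if (id < identity_min || sim < similarity_min) {
    return(NULL)
  }
  if (!subset$motif_offset %in% find_motif(cdr3, subset$motif)) {
    return(NULL)
  }
  tibble::tibble(
    subset_id = subset$subset_id, match_type = "standard",
    identity = id, similarity = sim,
    length_delta = 0L, offset_delta = 0L
  )
}

#' Match one rearrangement against one subset (satellite criteria)
#'
#' Applies the satellite criteria: phylogenetically associated IGHV genes
#' (same clan by default), CDR3 length within 2 residues of the subset's,
#' and the subset motif present at an offset within 2 of the subset's. No
#' identity/similarity thresholds apply at this tier; the scores are still
#' recorded, computed over the motif-anchored overlap when lengths differ.
#'
#' @inheritParams match_standard
#' @param association Optional extra clan-association pairs (two-column data
#'   frame); `NULL` means associated = same clan.
#' @param max_length_delta,max_offset_delta Satellite tolerances (default 2).
#' @return A one-row tibble with `match_type = "satellite"`, the recorded
#'   scores and the signed `length_delta`, `offset_delta`, or `NULL`.
#' @export
match_satellite <- function(rearrangement, subset, clan_map = default_clan_map(),
                            groups = default_similarity_groups(),
                            association = NULL,
                            max_length_delta = 2L, max_offset_delta = 2L) {
  subset <- as.list(subset)
  cdr3 <- rearrangement_cdr3(rearrangement)
  clan <- clan_of(rearrangement$v_call[[1]], clan_map)
  if (!clans_associated(clan, subset$clan, association)) {
    return(NULL)
  }
  length_delta <- nchar(cdr3) - subset$cdr3_length
  if (abs(length_delta) > max_length_delta) {
    return(NULL)
  }
  offsets <- find_motif(cdr3, subset$motif)
  offset_delta <- best_offset_delta(offsets, subset$motif_offset, max_offset_delta)
  if (is.na(offset_delta)) {
    return(NULL)
  }
  codes <- residue_group_codes(groups)
  scores <- anchored_scores(cdr3, subset$consensus_cdr3, offset_delta, codes)
  tibble::tibble(
    subset_id = subset$subset_id, match_type = "satellite",
    identity = unname(scores["identity"]), similarity = unname(scores["similarity"]),
    length_delta = as.integer(length_delta), offset_delta = as.integer(offset_delta)
  )
}

rearrangement_cdr3 <- function(r) {
  if (!is.null(r$cdr3_aa) && !is.na(r$cdr3_aa[[1]])) {
    return(r$cdr3_aa[[1]])
  }
  j <- r$junction_aa[[1]]
  substr(j, 2, nchar(j) - 1)
}
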