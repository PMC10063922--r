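# Downstream quantification: per-population CLL-SLS frequencies, IGHV
# mutation-status concordance with the subsets' canonical U/M classes,
# concordance-pattern grouping, heavy/light pairing restriction, and the
# nonparametric group comparisons used on the frequency tables.

#' Classify IGHV mutation status from germline V identity
#'
#' A rearrangement is IGHV-unmutated (`"U"`) when its nucleotide germline V
#' identity is at or above `cutoff`, else mutated (`"M"`). The default
#' cutoff of 0.98 (98% germline identity) is the convention universally used
#' for CLL; the boundary value itself is classed `"U"`. Missing identities
#' return NA ("unknown") and are excluded from concordance analyses.
#'
#' @param v_identity Numeric vector of germline V identities in \[0, 1\].
#' @param cutoff Classification threshold, default 0.98.
#' @return Character vector of `"U"`, `"M"` or NA.
#' @examples
#' classify_shm(c(1, 0.98, 0.95, NA))
#' @export
classify_shm <- function(v_identity, cutoff = 0.98) {
  stopifnot(all(is.na(v_identity) | (v_identity >= 0 & v_identity <= 1)))
  ifelse(is.na(v_identity), NA_character_,
    ifelse(v_identity >= cutoff, "U", "M")
  )
}

#' Per-sample, per-population CLL-SLS summary
#'
#' Counts unique clonotypes per sample and B-cell subpopulation and the
#' standard / satellite CLL-SLS among them; frequencies are fractions of the
#' unique-clonotype total (multiply by 100 for the percent scale used in
#' reports). Rows with no population label are grouped under `"unlabeled"`
#' with a warning.
#'
#' @param assignments An [assign_stereotypes()] result.
#' @return A tibble of class `sls_population_summary` with columns
#'   `sample_id`, `population`, `total_unique`, `n_standard`, `n_satellite`,
#'   `freq_standard`, `freq_satellite`.
#' @export
summarize_populations <- function(assignments) {
  x <- tibble::as_tibble(assignments)
  if (anyNA(x$population)) {
    warning("rearrangements without a population label grouped under \"unlabeled\"",
      call. = FALSE
    )
    x$population[is.na(x$population)] <- "unlabeled"
  }
  out <- x |>
    dplyr::group_by(.data$sample_id, .data$population) |>
    dplyr::summarise(
      total_unique = dplyr::n(),
      n_standard = sum(.data$match_type == "standard"),
      n_satellite = sum(.data$match_type == "satellite"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      freq_standard = .data$n_standard / .data$total_unique,
      freq_satellite = .data$n_satellite / .data$total_unique
    )
  class(out) <- c("sls_population_summary", class(out))
  out
}

#' Distribution of CLL-SLS across subsets
#'
#' Counts matched clonotypes per subset within one tier — the data behind
#' per-tissue subset pie charts — either pooled or per population.
#'
#' @param assignments An [assign_stereotypes()] result.
#' @param tier `"standard"` or `"satellite"`.
#' @param by_population Split counts by population (default pooled).
#' @return A tibble with `subset_id`, `n`, and `fraction` of the tier total
#'   (per population when `by_population`).
#' @export
subset_distribution <- function(assignments, tier = c("standard", "satellite"),
                                by_population = FALSE) {
  tier <- match.arg(tier)
  x <- dplyr::filter(tibble::as_tibble(assignments), .data$match_type == tier)
  grp <- if (by_population) c("population", "subset_id") else "subset_id"
  x |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), name = "n") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(grp, "subset_id")))) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' IGHV mutation-status concordance profiles
#'
#' For each matched subset and population, the fraction of assigned CLL-SLS
#' whose own IGHV mutation status (from [classify_shm()]) matches the
#' subset's canonical U/M class. Clonotypes with unknown SHM status are
#' excluded from both numerator and denominator.
#'
#' @param assignments An [assign_stereotypes()] result.
#' @param tier Which match tier to profile (default `"standard"`).
#' @return A tibble of class `sls_concordance`: `subset_id`,
#'   `mutation_class`, `population`, `n` (clonotypes with known SHM status)
#'   and `concordance` in \[0, 1\].
#' @export
concordance_profiles <- function(assignments, tier = "standard") {
  catalog <- attr(assignments, "catalog")
  x <- tibble::as_tibble(assignments) |>
    dplyr::filter(.data$match_type == tier, !is.na(.data$concordant_shm))
  out <- x |>
    dplyr::group_by(.data$subset_id, .data$population) |>
    dplyr::summarise(
      n = dplyr::n(),
      concordance = mean(.data$concordant_shm),
      .groups = "drop"
    )
  if (!is.null(catalog)) {
    out <- dplyr::left_join(
      out,
      tibble::tibble(subset_id = catalog$subset_id, mutation_class = catalog$mutation_class),
      by = "subset_id"
    )
  } else {
    out$mutation_class <- NA_character_
  }
  out <- dplyr::select(
    out, "subset_id", "mutation_class", "population", "n", "concordance"
  )
  class(out) <- c("sls_concordance", class(out))
  out
}

#' Group subsets by their concordance pattern across populations
#'
#' Stereotyped subsets can be grouped by how their mutation-status
#' concordance varies across B-cell subpopulations. Profiles are arranged as
#' a subset-by-population matrix of concordance fractions (missing
#' combinations filled with 0) and grouped by agglomerative hierarchical
#' clustering (Euclidean distance, average linkage) cut at `k` groups; the
#' result is deterministic given the input.
#'
#' @param profiles A [concordance_profiles()] result.
#' @param k Number of pattern groups; must not exceed the number of subsets.
#' @return `profiles` with an added `pattern_id` column (`"P1"`, `"P2"`, ...,
#'   numbered in order of first appearance), of class `sls_patterns`.
#' @export
group_patterns <- function(profiles, k) {
  wide <- tibble::as_tibble(profiles) |>
    dplyr::select("subset_id", "population", "concordance") |>
    tidyr::pivot_wider(
      names_from = "population", values_from = "concordance", values_fill = 0
    )
  if (k > nrow(wide)) {
    stop(sprintf(
      "k = %d exceeds the number of subsets with profiles (%d)", k, nrow(wide)
    ), call. = FALSE)
  }
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$subset_id
  cl <- if (nrow(mat) == 1) {
    stats::setNames(1L, rownames(mat))
  } else {
    stats::cutree(stats::hclust(stats::dist(mat), method = "average"), k = k)
  }
  # stable labels: number patterns by first appearance in subset_id order
  first_seen <- unique(cl[order(names(cl))])
  labels <- stats::setNames(paste0("P", seq_along(first_seen)), first_seen)
  out <- tibble::as_tibble(profiles)
  out$pattern_id <- unname(labels[as.character(cl[out$subset_id])])
  class(out) <- c("sls_patterns", class(out))
  out
}

#' Heavy/light-chain pairing concordance with subset restrictions
#'
#' Several stereotyped subsets near-obligately pair their heavy chain with a
#' specific light-chain V gene (e.g. IGLV3-21). Given paired single cells,
#' this assigns the heavy chains to subsets and checks each assigned cell's
#' light-chain V gene against the matched subset's restriction
#' (allele-stripped equality).
#'
#' @param cells A [read_paired_cells()] tibble.
#' @param catalog An [subset_catalog()].
#' @param ... Passed on to [assign_stereotypes()] for the heavy chains.
#' @param aggregate Return per-subset x population counts (default); set
#'   `FALSE` for the per-cell table.
#' @return Aggregated: a tibble with `subset_id`, `population`,
#'   `light_restriction`, `n_concordant`, `n_discordant`,
#'   `n_no_restriction`. Per-cell: `cell_id`, `population`, `subset_id`,
#'   `match_type`, `light_v_gene`, `status` in
#'   `"concordant"`/`"discordant"`/`"no_restriction"`.
#' @export
light_chain_concordance <- function(cells, catalog, ..., aggregate = TRUE) {
  heavy <- cells |>
    dplyr::transmute(
      sequence_id = .data$cell_id, sample_id = .data$cell_id,
      population = .data$population, chain = "H", v_call = .data$heavy_v_call,
      d_call = NA_character_, j_call = .data$heavy_j_call,
      junction_aa = .data$heavy_junction_aa, cdr3_aa = .data$heavy_cdr3_aa,
      v_identity = .data$heavy_v_identity, isotype = NA_character_,
      productive = TRUE
    )
  assigned <- assign_stereotypes(heavy, catalog, ...) |>
    tibble::as_tibble() |>
    dplyr::select("sample_id", "subset_id", "match_type") |>
    dplyr::rename(cell_id = "sample_id")
  per_cell <- cells |>
    dplyr::left_join(assigned, by = "cell_id") |>
    dplyr::filter(.data$match_type != "none") |>
    dplyr::left_join(
      tibble::tibble(
        subset_id = catalog$subset_id,
        light_restriction = catalog$light_chain_gene
      ),
      by = "subset_id"
    ) |>
    dplyr::mutate(
      light_v_gene = strip_allele(.data$light_v_call),
      status = dplyr::case_when(
        is.na(.data$light_restriction) ~ "no_restriction",
        .data$light_v_gene == strip_allele(.data$light_restriction) ~ "concordant",
        TRUE ~ "discordant"
      )
    ) |>
    dplyr::select(
      "cell_id", "population", "subset_id", "match_type",
      "light_v_gene", "light_restriction", "status"
    )
  if (!aggregate) {
    return(per_cell)
  }
  per_cell |>
    dplyr::group_by(.data$subset_id, .data$population, .data$light_restriction) |>
    dplyr::summarise(
      n_concordant = sum(.data$status == "concordant"),
      n_discordant = sum(.data$status == "discordant"),
      n_no_restriction = sum(.data$status == "no_restriction"),
      .groups = "drop"
    )
}

#' Kruskal-Wallis comparison of frequencies across groups
#'
#' Rank-based comparison of a frequency (or any numeric) column across
#' groups — the test used throughout for comparing CLL-SLS frequencies
#' among B-cell subpopulations. The H statistic and chi-square p-value come
#' from [stats::kruskal.test()] (tie-corrected); Dunn-type pairwise z-tests
#' on the pooled ranks, with multiplicity control (Holm by default), provide
#' the post-hoc comparisons.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the measured value and the
#'   group label.
#' @param posthoc Compute pairwise Dunn comparisons (default TRUE).
#' @param p_adjust Adjustment method for the pairwise p-values; any method
#'   of [stats::p.adjust()] (default `"holm"`).
#' @return An object of class `sls_kw` with `statistic`, `df`, `p.value`,
#'   `n`, and a `posthoc` tibble (`group1`, `group2`, `z`, `p.value`,
#'   `p.adj`). [generics::tidy()] returns the pairwise table,
#'   [generics::glance()] the one-row test summary.
#' @examples
#' df <- data.frame(
#'   freq = c(1, 2, 3, 10, 11, 12),
#'   pop = rep(c("NAIVE", "MEM"), each = 3)
#' )
#' kw_frequency_test(df, freq, pop)
#' @export
kw_frequency_test <- function(data, value, group, posthoc = TRUE,
                              p_adjust = "holm") {
  value <- rlang::eval_tidy(rlang::enquo(value), data)
  group <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(value) & !is.na(group)
  value <- value[keep]
  group <- group[keep]
  if (dplyr::n_distinct(group) < 2) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  kt <- stats::kruskal.test(value, factor(group))
  res <- list(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p.value = kt$p.value,
    n = length(value),
    groups = sort(unique(group)),
    method = "Kruskal-Wallis rank sum test",
    p_adjust = p_adjust
  )
  if (posthoc) {
    res$posthoc <- dunn_posthoc(value, group, p_adjust)
  }
  structure(res, class = "sls_kw")
}

# Dunn (1964) pairwise z-tests on the pooled ranks with tie correction.
dunn_posthoc <- function(value, group, p_adjust = "holm") {
  r <- rank(value)
  N <- length(value)
  ties <- table(value)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  mean_ranks <- tapply(r, group, mean)
  ns <- tapply(r, group, length)
  gs <- sort(names(mean_ranks))
  pairs <- utils::combn(gs, 2)
  z <- apply(pairs, 2, function(p) {
    (mean_ranks[[p[1]]] - mean_ranks[[p[2]]]) /
      sqrt(s2 * (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ], z = z,
    p.value = p, p.adj = stats::p.adjust(p, method = p_adjust)
  )
}

#' @export
print.sls_kw <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf(
    "H = %.4g, df = %d, p = %.4g (n = %d, %d groups)\n",
    x$statistic, x$df, x$p.value, x$n, length(x$groups)
  ))
  if (!is.null(x$posthoc)) {
    cat("Pairwise Dunn comparisons (", x$p_adjust, "-adjusted):\n", sep = "")
    print(x$posthoc, ...)
  }
  invisible(x)
}
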