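# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the pairwise comparisons of a Kruskal-Wallis result
#'
#' @param x An `sls_kw` object from [kw_frequency_test()].
#' @param ... Unused.
#' @return A tibble of pairwise Dunn comparisons (`group1`, `group2`, `z`,
#'   `p.value`, `p.adj`), or a zero-row tibble when `posthoc = FALSE` was
#'   used.
#' @export
tidy.sls_kw <- function(x, ...) {
  x$posthoc %||% tibble::tibble(
    group1 = character(), group2 = character(), z = numeric(),
    p.value = numeric(), p.adj = numeric()
  )
}

#' One-row summary of a Kruskal-Wallis result
#'
#' @inheritParams tidy.sls_kw
#' @return A one-row tibble: `statistic` (H), `df`, `p.value`, `n`,
#'   `n_groups`, `method`.
#' @export
glance.sls_kw <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p.value = x$p.value,
    n = x$n, n_groups = length(x$groups), method = x$method
  )
}

#' One-row summary of an assignment table
#'
#' @param x An `sls_assignments` tibble.
#' @param ... Unused.
#' @return A one-row tibble with clonotype and match-tier totals and the
#'   overall standard/satellite frequencies.
#' @export
glance.sls_assignments <- function(x, ...) {
  tbl <- tibble::as_tibble(x)
  n <- nrow(tbl)
  n_std <- sum(tbl$match_type == "standard")
  n_sat <- sum(tbl$match_type == "satellite")
  tibble::tibble(
    n_clonotypes = n,
    n_standard = n_std,
    n_satellite = n_sat,
    freq_standard = ifelse(n == 0, NA_real_, n_std / n),
    freq_satellite = ifelse(n == 0, NA_real_, n_sat / n),
    ties = attr(x, "ties") %||% NA_integer_
  )
}
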