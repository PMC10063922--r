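# Reading/writing annotated rearrangements in the AIRR Rearrangement TSV
# layout, plus uniqueness keys and paired single-cell contig ingestion.
# The package consumes already-annotated output (pRESTO/IMGT- or Cell
# Ranger-style upstream); no raw-read processing happens here.

airr_required_cols <- c("sequence_id", "v_call", "j_call", "junction_aa", "productive")

as_logical_flag <- function(x) {
  if (is.logical(x)) {
    return(x)
  }
  tolower(as.character(x)) %in% c("t", "true", "1", "yes")
}

chain_of_v_call <- function(v_call) {
  dplyr::case_when(
    stringr::str_starts(v_call, "IGHV") ~ "H",
    stringr::str_starts(v_call, "IGKV") ~ "K",
    stringr::str_starts(v_call, "IGLV") ~ "L",
    TRUE ~ NA_character_
  )
}

#' Read an AIRR rearrangement TSV
#'
#' Reads a tab-separated rearrangement table using the AIRR standard column
#' names. Required columns: `sequence_id`, `v_call`, `j_call`, `junction_aa`,
#' `productive`. Optional columns (`d_call`, `v_identity`, `isotype`,
#' `sample_id`, `population`, `junction`) are carried through when present.
#' Non-productive rows and rows whose amino-acid junction is missing, contains
#' a stop codon (`*`) or frame-shift placeholder, or is shorter than 4
#' residues are dropped, with a message reporting the counts. The CDR3 is
#' derived as the junction minus its conserved first (C) and last (W/F)
#' anchor residues, and `v_identity` given in percent is normalised to a
#' fraction.
#'
#' @param path Path to the TSV (may be gzip-compressed).
#' @param sample_col,population_col Names of the columns holding the sample
#'   and B-cell subpopulation labels (AIRR files vary); renamed to
#'   `sample_id` / `population` on read.
#' @return A tibble with one row per retained rearrangement: `sequence_id`,
#'   `sample_id`, `population`, `chain`, `v_call`, `d_call`, `j_call`,
#'   `junction_aa`, `cdr3_aa`, `v_identity`, `isotype`, `productive`.
#' @export
read_airr <- function(path, sample_col = "sample_id", population_col = "population") {
  if (!file.exists(path)) stop("AIRR file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (nrow(x) == 0) {
    warning("empty AIRR file: ", path, call. = FALSE)
    return(empty_rearrangements())
  }
  if (sample_col %in% names(x)) x <- dplyr::rename(x, sample_id = !!sample_col)
  if (population_col %in% names(x)) x <- dplyr::rename(x, population = !!population_col)
  missing_cols <- setdiff(airr_required_cols, names(x))
  if (length(missing_cols) > 0) {
    stop("AIRR file is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in c("d_call", "v_identity", "isotype", "sample_id", "population")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  x$productive <- as_logical_flag(x$productive)

  n0 <- nrow(x)
  x <- dplyr::filter(x, .data$productive)
  n_nonprod <- n0 - nrow(x)
  bad_junction <- is.na(x$junction_aa) | x$junction_aa == "" |
    stringr::str_detect(x$junction_aa, "[*_]") |
    nchar(x$junction_aa) < 4
  n_badj <- sum(bad_junction)
  x <- x[!bad_junction, , drop = FALSE]
  if (n_nonprod + n_badj > 0) {
    message(sprintf(
      "read_airr: dropped %d non-productive and %d junction-defective row(s); %d retained",
      n_nonprod, n_badj, nrow(x)
    ))
  }

  v_identity <- suppressWarnings(as.numeric(x$v_identity))
  # tolerate percent-scale germline identities
  v_identity <- ifelse(!is.na(v_identity) & v_identity > 1, v_identity / 100, v_identity)
  if (any(!is.na(v_identity) & (v_identity < 0 | v_identity > 1))) {
    stop("v_identity outside [0, 1] after percent normalisation", call. = FALSE)
  }

  tibble::tibble(
    sequence_id = x$sequence_id,
    sample_id = x$sample_id,
    population = x$population,
    chain = chain_of_v_call(x$v_call),
    v_call = x$v_call,
    d_call = x$d_call,
    j_call = x$j_call,
    junction_aa = x$junction_aa,
    cdr3_aa = substr(x$junction_aa, 2, nchar(x$junction_aa) - 1),
    v_identity = v_identity,
    isotype = x$isotype,
    productive = x$productive
  )
}

empty_rearrangements <- function() {
  tibble::tibble(
    sequence_id = character(), sample_id = character(), population = character(),
    chain = character(), v_call = character(), d_call = character(),
    j_call = character(), junction_aa = character(), cdr3_aa = character(),
    v_identity = numeric(), isotype = character(), productive = logical()
  )
}

#' Write rearrangements as AIRR TSV
#'
#' @param x A rearrangement tibble as returned by [read_airr()] or
#'   [simulate_repertoire()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Uniqueness key of a rearrangement
#'
#' Rearrangements are counted once per distinct clonotype. The default key
#' is the allele-stripped V gene, allele-stripped J gene and the amino-acid
#' junction; set `key_type = "nt"` to key on the nucleotide junction instead
#' (requires a `junction` column).
#'
#' @param v_call,j_call,junction Character vectors (recycled together).
#' @return Character vector of keys.
#' @examples
#' unique_key("IGHV1-69*01", "IGHJ6*02", "CARDKGYYDSWFDPW")
#' @export
unique_key <- function(v_call, j_call, junction) {
  paste(strip_allele(v_call), strip_allele(j_call), junction, sep = "|")
}

#' Collapse rearrangements to unique clonotypes
#'
#' Adds a `sequence_key` column and collapses duplicate keys within each
#' sample and population, averaging `v_identity` over the collapsed copies
#' (order-independent). Collapsing is idempotent.
#'
#' @param x Rearrangement tibble.
#' @param key_type `"aa"` (default) keys on the amino-acid junction; `"nt"`
#'   on the nucleotide junction (`junction` column).
#' @return A tibble with one row per (sample_id, population, sequence_key),
#'   carrying an `n_copies` count of the collapsed rows.
#' @export
collapse_rearrangements <- function(x, key_type = c("aa", "nt")) {
  key_type <- match.arg(key_type)
  junction <- if (key_type == "aa") {
    x$junction_aa
  } else {
    if (!"junction" %in% names(x)) {
      stop("key_type \"nt\" requires a `junction` column", call. = FALSE)
    }
    x$junction
  }
  x$sequence_key <- unique_key(x$v_call, x$j_call, junction)
  if (!"n_copies" %in% names(x)) x$n_copies <- 1L
  if (nrow(x) == 0) {
    out <- x[, c(
      "sample_id", "population", "sequence_key", "sequence_id", "chain",
      "v_call", "d_call", "j_call", "junction_aa", "cdr3_aa", "v_identity",
      "n_copies"
    )]
    return(tibble::as_tibble(out))
  }
  x <- x[order(x$sample_id, x$population, x$sequence_key, x$sequence_id,
    method = "radix"
  ), ]
  grp <- paste(x$sample_id, x$population, x$sequence_key, sep = "\r")
  f <- factor(grp, levels = unique(grp))
  v_n <- as.vector(rowsum(as.numeric(!is.na(x$v_identity)), f))
  v_sum <- as.vector(rowsum(ifelse(is.na(x$v_identity), 0, x$v_identity), f))
  first <- !duplicated(grp)
  out <- x[first, ]
  out$v_call <- strip_allele(out$v_call)
  out$j_call <- strip_allele(out$j_call)
  out$v_identity <- ifelse(v_n == 0, NA_real_, v_sum / pmax(v_n, 1))
  out$n_copies <- as.integer(rowsum(as.numeric(x$n_copies), f))
  tibble::as_tibble(out[, c(
    "sample_id", "population", "sequence_key", "sequence_id", "chain",
    "v_call", "d_call", "j_call", "junction_aa", "cdr3_aa", "v_identity",
    "n_copies"
  )])
}

#' Read a paired heavy/light single-cell contig table
#'
#' Ingests a 10x `filtered_contig_annotations`-style table (CSV or TSV;
#' columns `barcode`, `chain` (`IGH`/`IGK`/`IGL`), `v_gene`, `j_gene`,
#' `cdr3` and `productive`; AIRR-style names `cell_id`, `v_call`, `j_call`,
#' `junction_aa` are also accepted). Only cells with exactly one productive
#' heavy and exactly one productive light contig are retained; the counts of
#' dropped cells are reported with a message.
#'
#' @param path Path to the contig table.
#' @param population Optional population label applied to all cells when the
#'   table has no `population` column.
#' @return A tibble with one row per retained cell: `cell_id`, `population`,
#'   heavy-chain fields (`heavy_v_call`, `heavy_j_call`, `heavy_junction_aa`,
#'   `heavy_cdr3_aa`, `heavy_v_identity`) and light-chain fields
#'   (`light_chain`, `light_v_call`, `light_j_call`, `light_junction_aa`).
#' @export
read_paired_cells <- function(path, population = NULL) {
  if (!file.exists(path)) stop("contig file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  aliases <- c(
    barcode = "cell_id", v_gene = "v_call", j_gene = "j_call",
    cdr3 = "junction_aa"
  )
  for (old in names(aliases)) {
    if (old %in% names(x) && !aliases[[old]] %in% names(x)) {
      names(x)[names(x) == old] <- aliases[[old]]
    }
  }
  needed <- c("cell_id", "chain", "v_call", "j_call", "junction_aa", "productive")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("contig table is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"population" %in% names(x)) {
    x$population <- population %||% NA_character_
  }
  if (!"v_identity" %in% names(x)) x$v_identity <- NA_character_
  x$productive <- as_logical_flag(x$productive)
  x$chain <- dplyr::recode(x$chain, IGH = "H", IGK = "K", IGL = "L", .default = x$chain)
  x <- dplyr::filter(x, .data$productive, .data$chain %in% c("H", "K", "L"))
  x$v_identity <- suppressWarnings(as.numeric(x$v_identity))
  x$v_identity <- ifelse(!is.na(x$v_identity) & x$v_identity > 1,
    x$v_identity / 100, x$v_identity
  )

  counts <- x |>
    dplyr::count(.data$cell_id, heavy = .data$chain == "H") |>
    tidyr::pivot_wider(
      names_from = "heavy", values_from = "n", values_fill = 0L,
      names_prefix = "h"
    )
  if (!"hTRUE" %in% names(counts)) counts$hTRUE <- 0L
  if (!"hFALSE" %in% names(counts)) counts$hFALSE <- 0L
  keep <- counts$cell_id[counts$hTRUE == 1L & counts$hFALSE == 1L]
  n_dropped <- dplyr::n_distinct(x$cell_id) - length(keep)
  if (n_dropped > 0) {
    message(sprintf(
      "read_paired_cells: dropped %d cell(s) without exactly one productive heavy and one light contig",
      n_dropped
    ))
  }
  x <- dplyr::filter(x, .data$cell_id %in% keep)
  heavy <- dplyr::filter(x, .data$chain == "H")
  light <- dplyr::filter(x, .data$chain != "H")
  dplyr::inner_join(
    heavy |>
      dplyr::transmute(
        cell_id = .data$cell_id, population = .data$population,
        heavy_v_call = .data$v_call, heavy_j_call = .data$j_call,
        heavy_junction_aa = .data$junction_aa,
        heavy_cdr3_aa = substr(.data$junction_aa, 2, nchar(.data$junction_aa) - 1),
        heavy_v_identity = .data$v_identity
      ),
    light |>
      dplyr::transmute(
        cell_id = .data$cell_id, light_chain = .data$chain,
        light_v_call = .data$v_call, light_j_call = .data$j_call,
        light_junction_aa = .data$junction_aa
      ),
    by = "cell_id"
  ) |>
    dplyr::arrange(.data$cell_id)
}
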