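#' @importFrom rlang .data
NULL

# The 20 standard amino acids; "X" is additionally allowed in motifs as a
# wildcard position.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Default IGHV phylogenetic clan map
#'
#' Maps the seven human IGHV gene families to the three deep phylogenetic
#' clans under the standard immunogenetic convention:
#' clan I = IGHV1/IGHV5/IGHV7, clan II = IGHV2/IGHV4/IGHV6, clan III = IGHV3.
#' Standard stereotype matching requires the query and the subset to share a
#' clan; satellite matching requires "phylogenetically associated" genes,
#' which defaults to the same-clan relation (see [assign_stereotypes()]).
#'
#' @return A tibble with columns `family` (e.g. `"IGHV1"`) and `clan`
#'   (`"I"`, `"II"` or `"III"`).
#' @examples
#' default_clan_map()
#' @export
default_clan_map <- function() {
  tibble::tibble(
    family = paste0("IGHV", 1:7),
    clan = c("I", "II", "III", "II", "I", "II", "I")
  )
}

#' Default amino-acid similarity groups
#'
#' Partition of the 20 residues into conservative-substitution classes used
#' by [aa_similarity()]: two residues count as similar when identical or in
#' the same group. The partition follows standard physicochemical classes
#' (small/aliphatic, aromatic, sulfur-containing, hydroxyl, basic,
#' acidic/amide, proline); it is fully configurable wherever similarity is
#' computed.
#'
#' @return A named list of character vectors partitioning the 20 amino acids.
#' @examples
#' default_similarity_groups()
#' @export
default_similarity_groups <- function() {
  list(
    aliphatic = c("G", "A", "V", "L", "I"),
    aromatic  = c("F", "Y", "W"),
    sulfur    = c("C", "M"),
    hydroxyl  = c("S", "T"),
    basic     = c("K", "R", "H"),
    acidic    = c("D", "E", "N", "Q"),
    proline   = "P"
  )
}

# Named integer vector: residue -> group index. Validates the partition.
residue_group_codes <- function(groups = default_similarity_groups()) {
  residues <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(residues) || !setequal(residues, AA_ALPHABET)) {
    stop("`groups` must partition the 20 standard amino acids", call. = FALSE)
  }
  codes <- rep.int(seq_along(groups), lengths(groups))
  names(codes) <- residues
  codes
}

# Strip IMGT allele suffix ("*01") and keep the first call of a
# comma-separated ambiguous gene call.
strip_allele <- function(call) {
  stringr::str_remove(stringr::str_split_i(call, ",", 1), "\\*.*$")
}

ighv_family <- function(v_call) {
  fam <- stringr::str_match(v_call, "^(IGHV[1-7])[-/S0-9]")[, 2]
  # tolerate a bare family name such as "IGHV3"
  bare <- is.na(fam) & stringr::str_detect(v_call, "^IGHV[1-7]$")
  fam[bare] <- v_call[bare]
  fam
}

#' IGHV phylogenetic clan of a heavy-chain V gene
#'
#' Looks up the clan of an IGHV gene from its family; allele suffixes
#' (`"*01"`) are ignored.
#'
#' @param v_call Character vector of IGHV gene names, e.g. `"IGHV1-69*01"`.
#' @param clan_map Family-to-clan table, as from [default_clan_map()].
#' @return Character vector of clan labels (`"I"`, `"II"`, `"III"`).
#' @examples
#' clan_of(c("IGHV1-69*01", "IGHV3-21"))
#' @export
clan_of <- function(v_call, clan_map = default_clan_map()) {
  fam <- ighv_family(strip_allele(v_call))
  if (anyNA(fam)) {
    bad <- unique(v_call[is.na(fam)])
    stop(
      "not an IGHV gene (families IGHV1-IGHV7): ",
      paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  clan <- clan_map$clan[match(fam, clan_map$family)]
  if (anyNA(clan)) {
    stop("IGHV family missing from `clan_map`: ",
      paste(unique(fam[is.na(clan)]), collapse = ", "),
      call. = FALSE
    )
  }
  clan
}

# Are two clans "phylogenetically associated"? The default relation is
# same-clan; `association` may instead be a two-column data frame of
# unordered associated clan pairs (e.g. data.frame(a = "I", b = "II")).
clans_associated <- function(clan_a, clan_b, association = NULL) {
  same <- clan_a == clan_b
  if (is.null(association)) {
    return(same)
  }
  pairs <- paste(
    pmin(clan_a, clan_b), pmax(clan_a, clan_b)
  )
  extra <- paste(
    pmin(association[[1]], association[[2]]),
    pmax(association[[1]], association[[2]])
  )
  same | pairs %in% extra
}

catalog_columns <- c(
  "subset_id", "ighv_genes", "cdr3_length", "consensus_cdr3",
  "motif", "motif_offset", "mutation_class", "light_chain_gene"
)

#' Build a validated stereotyped-subset catalog
#'
#' A catalog row defines one stereotyped CLL subset: the IGHV genes its
#' clones use (all from one phylogenetic clan), the subset consensus VH CDR3
#' (IMGT CDR3, i.e. junction without the conserved C and W/F anchors), the
#' subset-specific amino-acid motif with its 0-based offset within the CDR3,
#' the subset's canonical IGHV mutation class (`"U"` unmutated / `"M"`
#' mutated), and an optional light-chain gene restriction.
#'
#' @param x A data frame with columns `subset_id`, `ighv_genes` (character
#'   with comma-separated genes, or a list column), `cdr3_length`,
#'   `consensus_cdr3`, `motif` (may contain `"X"` wildcards), `motif_offset`
#'   (0-based), `mutation_class` (`"U"`/`"M"`), and optionally
#'   `light_chain_gene` (NA when the subset has no known restriction).
#' @param clan_map Family-to-clan table used to derive and check each
#'   subset's clan.
#' @return A tibble of class `sls_catalog` with a list column `ighv_genes`
#'   and a derived `clan` column.
#' @seealso [read_subset_catalog()], [toy_catalog()]
#' @export
subset_catalog <- function(x, clan_map = default_clan_map()) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(setdiff(catalog_columns, "light_chain_gene"), names(x))
  if (length(missing_cols) > 0) {
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"light_chain_gene" %in% names(x)) x$light_chain_gene <- NA_character_
  if (!is.list(x$ighv_genes)) {
    x$ighv_genes <- stringr::str_split(x$ighv_genes, "\\s*,\\s*")
  }
  x$subset_id <- as.character(x$subset_id)
  x$cdr3_length <- as.integer(x$cdr3_length)
  x$motif_offset <- as.integer(x$motif_offset)
  x$light_chain_gene <- as.character(x$light_chain_gene)

  if (anyDuplicated(x$subset_id)) {
    stop("duplicated subset_id: ",
      paste(unique(x$subset_id[duplicated(x$subset_id)]), collapse = ", "),
      call. = FALSE
    )
  }

  stated_clan <- if ("clan" %in% names(x)) as.character(x$clan) else rep(NA_character_, nrow(x))

  fail <- function(i, field, why) {
    stop(sprintf("catalog row %d (subset_id %s), field `%s`: %s",
      i, x$subset_id[i], field, why
    ), call. = FALSE)
  }
  clans <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    cons <- x$consensus_cdr3[i]
    if (is.na(cons) || !all(strsplit(cons, "")[[1]] %in% AA_ALPHABET)) {
      fail(i, "consensus_cdr3", "contains a non-standard residue")
    }
    if (nchar(cons) != x$cdr3_length[i]) {
      fail(i, "consensus_cdr3", sprintf(
        "length %d does not equal cdr3_length %d", nchar(cons), x$cdr3_length[i]
      ))
    }
    mot <- x$motif[i]
    if (is.na(mot) || nchar(mot) == 0 ||
      !all(strsplit(mot, "")[[1]] %in% c(AA_ALPHABET, "X"))) {
      fail(i, "motif", "must be non-empty amino acids plus optional X wildcards")
    }
    if (is.na(x$motif_offset[i]) || x$motif_offset[i] < 0) {
      fail(i, "motif_offset", "must be a non-negative integer")
    }
    if (x$motif_offset[i] + nchar(mot) > x$cdr3_length[i]) {
      fail(i, "motif_offset", "motif extends beyond the CDR3")
    }
    if (!x$mutation_class[i] %in% c("U", "M")) {
      fail(i, "mutation_class", "must be \"U\" or \"M\"")
    }
    genes <- x$ighv_genes[[i]]
    if (length(genes) == 0) fail(i, "ighv_genes", "must list at least one IGHV gene")
    gene_clans <- tryCatch(clan_of(genes, clan_map), error = function(e) {
      fail(i, "ighv_genes", conditionMessage(e))
    })
    if (length(unique(gene_clans)) > 1) {
      fail(i, "ighv_genes", "genes span more than one phylogenetic clan")
    }
    clans[i] <- gene_clans[1]
    if (!is.na(stated_clan[i]) && !identical(stated_clan[i], clans[i])) {
      fail(i, "clan", sprintf(
        "stated clan %s disagrees with gene-derived clan %s", stated_clan[i], clans[i]
      ))
    }
    if (!motif_matches_at(cons, mot, x$motif_offset[i])) {
      warning(sprintf(
        "catalog row %d (subset_id %s): motif does not match the consensus CDR3 at motif_offset",
        i, x$subset_id[i]
      ), call. = FALSE)
    }
  }
  x$clan <- clans
  out <- x[, c(
    "subset_id", "ighv_genes", "clan", "cdr3_length", "consensus_cdr3",
    "motif", "motif_offset", "mutation_class", "light_chain_gene"
  )]
  class(out) <- c("sls_catalog", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Does `motif` (with X wildcards) match `cdr3` at 0-based `offset`?
motif_matches_at <- function(cdr3, motif, offset) {
  if (offset < 0 || offset + nchar(motif) > nchar(cdr3)) {
    return(FALSE)
  }
  window <- substr(cdr3, offset + 1, offset + nchar(motif))
  grepl(paste0("^", motif_regex(motif), "$"), window)
}

motif_regex <- function(motif) gsub("X", ".", motif, fixed = TRUE)

#' Read a stereotyped-subset catalog from a TSV file
#'
#' The catalog file is tab-separated with one row per subset and columns
#' `subset_id`, `ighv_genes` (comma-separated), `cdr3_length`,
#' `consensus_cdr3`, `motif`, `motif_offset` (0-based), `mutation_class`
#' (`U`/`M`) and optionally `light_chain_gene`. Extra columns (such as a
#' `provenance` note) are ignored. All rows are validated; malformed rows
#' raise an error naming the row and field.
#'
#' @inheritParams subset_catalog
#' @param path Path to the catalog TSV.
#' @return A validated `sls_catalog` tibble.
#' @examples
#' path <- system.file("extdata", "toy_subset_catalog.tsv", package = "cllsls")
#' read_subset_catalog(path)
#' @export
read_subset_catalog <- function(path, clan_map = default_clan_map()) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  subset_catalog(raw, clan_map = clan_map)
}

#' Write a subset catalog to TSV
#'
#' Inverse of [read_subset_catalog()]: `read_subset_catalog(write_subset_catalog(x, p))`
#' recovers `x`.
#'
#' @param catalog An `sls_catalog` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subset_catalog <- function(catalog, path) {
  out <- tibble::as_tibble(catalog)
  out$ighv_genes <- purrr::map_chr(out$ighv_genes, paste, collapse = ",")
  out$clan <- NULL # derived on read
  readr::write_tsv(out, path)
  invisible(path)
}

#' Toy subset catalog used in examples and tests
#'
#' Three fully synthetic stereotyped subsets, one per IGHV clan, with
#' realistic 4-residue motifs (one containing an `X` wildcard) and both
#' mutation classes represented. The consensus CDR3s and motifs are
#' invented; only the shape of the definitions mirrors real catalogs.
#'
#' @return An `sls_catalog` tibble with three subsets.
#' @examples
#' toy_catalog()
#' @export
toy_catalog <- function() {
  subset_catalog(tibble::tibble(
    subset_id = c("T1", "T2", "T3"),
    ighv_genes = list(
      c("IGHV1-69", "IGHV1-2"),
      c("IGHV3-21", "IGHV3-23"),
      c("IGHV4-34", "IGHV4-39")
    ),
    cdr3_length = c(13L, 9L, 16L),
    consensus_cdr3 = c("ARDKGYYDSWFDP", "ARDANGMDV", "ARGYGDYWGSYRFDYY"),
    motif = c("KGYY", "NGMD", "WGXYR"),
    motif_offset = c(3L, 4L, 7L),
    mutation_class = c("U", "M", "M"),
    light_chain_gene = c(NA, "IGLV3-21", "IGKV2-30")
  ))
}
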