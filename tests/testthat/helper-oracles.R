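# Independent brute-force implementations of the CDR3 comparison primitives,
# written as plain position loops so they share no code path with the
# package, plus small fixture builders.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

oracle_identity <- function(a, b) {
  n <- nchar(a)
  hits <- 0L
  for (i in seq_len(n)) {
    if (substr(a, i, i) == substr(b, i, i)) hits <- hits + 1L
  }
  hits / n
}

oracle_group_of <- function(residue, groups) {
  for (g in seq_along(groups)) {
    if (residue %in% groups[[g]]) {
      return(g)
    }
  }
  stop("residue not in any group: ", residue)
}

oracle_similarity <- function(a, b, groups = default_similarity_groups()) {
  n <- nchar(a)
  hits <- 0L
  for (i in seq_len(n)) {
    ra <- substr(a, i, i)
    rb <- substr(b, i, i)
    if (ra == rb || oracle_group_of(ra, groups) == oracle_group_of(rb, groups)) {
      hits <- hits + 1L
    }
  }
  hits / n
}

oracle_find_motif <- function(cdr3, motif) {
  n <- nchar(cdr3)
  m <- nchar(motif)
  out <- integer(0)
  if (m > n) {
    return(out)
  }
  for (off in 0:(n - m)) {
    ok <- TRUE
    for (i in seq_len(m)) {
      mc <- substr(motif, i, i)
      if (mc != "X" && mc != substr(cdr3, off + i, off + i)) {
        ok <- FALSE
        break
      }
    }
    if (ok) out <- c(out, off)
  }
  out
}

random_cdr3 <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

# Minimal AIRR-shaped rearrangement tibble around a set of heavy CDR3s.
make_rearrangements <- function(cdr3_aa, v_call, j_call = "IGHJ4*01",
                                sample_id = "S1", population = "NAIVE",
                                v_identity = 1) {
  n <- length(cdr3_aa)
  tibble::tibble(
    sequence_id = sprintf("seq%04d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    population = rep_len(population, n),
    chain = "H",
    v_call = rep_len(v_call, n),
    d_call = NA_character_,
    j_call = rep_len(j_call, n),
    junction_aa = paste0("C", cdr3_aa, "W"),
    cdr3_aa = cdr3_aa,
    v_identity = rep_len(v_identity, n),
    isotype = NA_character_,
    productive = TRUE
  )
}

write_airr_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A residue guaranteed to sit in a different similarity group (drives both
# identity and similarity down at that position).
far_residue <- function(residue, groups = default_similarity_groups()) {
  g <- oracle_group_of(residue, groups)
  far_group <- if (g == 2) 5 else 2 # aromatic <-> basic
  groups[[far_group]][1]
}
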