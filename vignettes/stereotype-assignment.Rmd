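---
title: "Assigning CLL stereotype-like sequences in normal B-cell repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning CLL stereotype-like sequences in normal B-cell repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cllsls)
library(dplyr)
```

## The problem

A large fraction of chronic lymphocytic leukemia (CLL) clones carry
"stereotyped" B-cell receptors: heavy-chain VH CDR3s so similar across
patients that they define numbered subsets (#1, #2, #4, ...), each with a
characteristic IGHV gene usage, CDR3 length, amino-acid motif and canonical
IGHV mutation status (U-CLL unmutated / M-CLL mutated). Because many
stereotyped receptors are autoreactive, an obvious question is whether
B cells carrying such receptors also exist in healthy donors — and, if so,
whether tolerance checkpoints remove them during development. Answering it
requires scanning annotated repertoires (cord blood, bone marrow
subpopulations sorted along the developmental axis, peripheral-blood
subsets) for rearrangements that satisfy the stereotype criteria:
"CLL stereotype-like sequences" (CLL-SLS).

`cllsls` implements that computation as a reusable pipeline: a validated
subset catalog, AIRR-format ingestion, the matching engine, the downstream
population statistics, and a seeded synthetic-repertoire generator that
provides ground truth for every stage.

## The matching criteria

A heavy-chain clonotype is a **standard** CLL-SLS for subset $s$ when all
four criteria hold:

1. its IGHV gene belongs to the same phylogenetic clan as $s$'s genes;
2. its CDR3 reaches $\ge 50\%$ amino-acid identity **and** $\ge 70\%$
   similarity to $s$'s consensus CDR3;
3. its CDR3 has exactly $s$'s CDR3 length;
4. it carries $s$'s subset-specific motif at the identical 0-based offset.

A clonotype without any standard match is a **satellite** CLL-SLS for $s$
when:

1. its IGHV gene is phylogenetically associated with $s$'s clan;
2. its CDR3 length differs from $s$'s by at most 2 residues;
3. it carries the motif at an offset within $\pm 2$ of $s$'s.

The two tiers are disjoint by construction: a standard match is never also
counted as a satellite. Identity and similarity thresholds belong to the
standard tier only; at the satellite tier the scores are still recorded but
do not gate the decision — the published satellite parameters are
implemented literally.

Identity is the fraction of aligned positions with the identical residue.
Similarity additionally accepts substitutions within conservative residue
groups. The grouping is nowhere fixed by the matching criteria themselves,
so the package defaults to standard physicochemical classes —
$\{G,A,V,L,I\}$, $\{F,Y,W\}$, $\{C,M\}$, $\{S,T\}$, $\{K,R,H\}$,
$\{D,E,N,Q\}$, $\{P\}$ — and exposes the partition as an argument
everywhere it is used. Motifs may contain `X` wildcard positions, which
match any residue, because published subset motifs contain degenerate
positions.

Two conventions are stated once and used everywhere:

* **Coordinates.** The CDR3 is the IMGT junction minus its conserved anchors
  (C104 and W118/F118); motif offsets are 0-based within that CDR3.
* **Clans.** Clan I = IGHV1/5/7, clan II = IGHV2/4/6, clan III = IGHV3 — the
  standard immunogenetic clan convention. "Phylogenetically associated"
  defaults to *same clan*; whether the original satellite definition used a
  finer gene-level association is not recoverable from the published
  criteria, so the relation is configurable (`association` argument) and
  same-clan is the documented default.

## Resolution rules the criteria leave open

* **Uniqueness.** Frequencies count unique clonotypes. The key is
  (allele-stripped V gene, allele-stripped J gene, amino-acid junction),
  collapsed within each sample and population. Amino-acid-level collapsing
  is conservative with respect to sequencing error; a nucleotide-junction
  key is available (`key_type = "nt"`).
* **Multi-subset ties.** A clonotype matching several subsets within a tier
  is resolved by highest similarity, then highest identity, then
  lexicographic subset id. The rule is deterministic and the number of ties
  is reported and retained on the result.
* **Satellite scores at unequal lengths.** When the query and consensus
  CDR3s differ in length, identity/similarity are computed on the
  motif-anchored overlap: the query is shifted by the matched offset delta
  and only positions present in both sequences are compared.
* **Offset ties.** If the motif occurs at several offsets within the $\pm 2$
  tolerance, the smallest $|\Delta|$ wins; exact ties go to the more
  negative delta.
* **Determinism.** Assignment output is independent of input row order:
  clonotypes are collapsed and sorted (byte-order) before matching.

## Mutation status and downstream statistics

`classify_shm()` calls a rearrangement IGHV-unmutated (`U`) when its
germline V nucleotide identity is $\ge$ 98%, the convention universally
used in CLL; the criteria themselves never state a threshold, so the cutoff
is an explicit argument and the boundary value classifies as `U`. Rows
without a germline identity take part in matching but are excluded from
concordance analyses.

`summarize_populations()` computes per-donor, per-population unique totals
and CLL-SLS frequencies (fractions of unique clonotypes; multiply by 100
for the percent scale used in reports). Donor-level values are kept
separate so that cross-population comparisons can be run on per-donor
points; averages over donors are unweighted.

`concordance_profiles()` gives, per subset and population, the fraction of
assigned CLL-SLS whose own U/M status matches the subset's canonical class.
`group_patterns()` groups those profiles across populations by hierarchical
clustering (Euclidean distance, average linkage) cut at a user-chosen `k`.
The published pattern groupings of this kind are presented graphically
without an algorithm; clustering the concordance vectors is a reproducible
stand-in, not a claim of identity with any eyeballed grouping, and `k` is
deliberately a user decision.

`light_chain_concordance()` checks paired single cells against the
catalog's light-chain restrictions (e.g. subsets that always pair with
IGLV3-21) by allele-stripped gene equality, reporting concordant,
discordant and no-restriction cells per subset and population.

`kw_frequency_test()` wraps the tie-corrected Kruskal-Wallis H test for
comparing frequencies across populations and adds Dunn-type pairwise
z-tests on the pooled ranks. Multiplicity control for the pairwise tests
defaults to Holm — a uniform, assumption-free default (one published
analysis in this area used Holm-Sidak with ANOVA; Holm is kept for
uniformity and the method is an argument).

## The subset catalog

Catalogs are external, user-editable TSV files validated on load
(`read_subset_catalog()`): consensus length must equal the stated CDR3
length, the motif must fit inside the CDR3 and (warning otherwise) match
the consensus at its offset, genes must map to one clan, subset ids must be
unique. The package ships two files:

* `toy_subset_catalog.tsv` — three fully synthetic subsets, one per clan,
  used by all tests and examples;
* `cll_subset_catalog_synthetic.tsv` — a starter skeleton for real,
  named CLL subsets. Gene usage, mutation class and light-chain
  restrictions follow the literature where published, but the consensus
  CDR3s and motifs are **synthetic placeholders** (the real definitions
  live in cohort-derived references that print no reusable table); every
  row carries a provenance note. Replace this file with a real catalog for
  production use. No test depends on it.

## What the generator emulates — and what it does not

`simulate_repertoire()` produces AIRR-shaped repertoires with the
statistical structure the analysis assumes:

* **Design.** Multiple donors; per-population unique-sequence counts; the
  defaults describe transitional/naive populations without somatic
  hypermutation and antigen-experienced populations (rcMZ, MEM, DN) with
  4-6% per-site SHM, roughly 33,000 unique sequences per donor across five
  populations and three donors ($\approx 10^5$ sequences) — sizes chosen so
  that planted frequencies of $10^{-3}$ are measurable with tight binomial
  error while a full pipeline run stays well under a minute.
* **Junctions.** Amino-acid level composition (V tail + non-templated N
  additions + D core + N additions + J tail between the conserved anchors).
  `tdt_on = FALSE` removes the N additions, reproducing the reduced
  junctional diversity of the neonatal (cord-blood-like) repertoire.
* **SHM.** A uniform per-site substitution model on a nominal 300-nt V
  segment produces the germline identity; there are no hotspots and no
  selection. This is sufficient to exercise the concordance analyses, and
  no more.
* **Plants.** Standard plants start from the subset consensus and receive
  junctional variation at non-motif positions through same-similarity-group
  substitutions, then optional amino-acid noise (`shm_perturb`); each plant
  is re-checked against the full standard criteria and regenerated until it
  passes and is a distinct clonotype. Distinctness matters: stereotyped
  sequences across donors are quasi-identical, not identical, and planted
  *frequencies* are only recoverable if plants are distinct under the
  uniqueness key. Satellite plants additionally receive a 1-2 residue
  length edit and/or a motif shift within the tolerances and are verified
  to satisfy the satellite but not the standard criteria for *any* subset.
  Generation fails loudly after bounded retries rather than silently
  planting invalid sequences.
* **Truth.** Every planted clonotype is recorded with its subset and tier,
  so sensitivity, tier purity and frequency recovery are all measurable.

Because the generator works at the amino-acid level with idealised gene
usage and no clonal expansion, passing its recovery tests demonstrates that
the matching engine implements the criteria faithfully and that frequencies
propagate correctly — it does not demonstrate robustness to annotation
errors, allele ambiguity, clonal lineage structure or real SHM targeting
biases. `corrupt_repertoire()` provides a first instrument for the error
dimension (recovery degrades smoothly with substitution noise when the
motif is protected).

## Validation sizes

The shipped checks use: $10^4$ random CDR3 pairs against brute-force
re-implementations of identity/similarity/motif search; a constructed grid
of length/offset/identity variants around every toy subset compared against
the printed criteria written out independently; $10^4$ random
standard-matching sequences for the standard-implies-satellite implication;
one $\approx 10^5$-sequence repertoire for frequency recovery; and $10^4$
null replicates for the Kruskal-Wallis type-I calibration. These sizes make
binomial error bars a few per mille and run in minutes on one CPU.

## Known limitations

* The real subset catalog is not redistributable here; results on real data
  are only as good as the catalog supplied.
* Satellite matching at the gene level ("phylogenetically associated") is
  approximated by the clan relation unless the user supplies a finer map.
* The similarity grouping is a documented default, not the (unpublished)
  original partition; both identity and similarity thresholds are arguments.
* Frequencies are computed over unique amino-acid clonotypes; repertoires
  dominated by clonal expansions should consider the `n_copies` column
  before interpreting frequencies as cell-level quantities.
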