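---
title: "Residue-level dark-matter accounting: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level dark-matter accounting: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkspace)
```

## The accounting model

`darkspace` treats a proteome as a ledger of amino-acid residues. The
inputs are domain hits (Pfam profile-HMM matches from `hmmscan`
domtblout tables, CDD PSSM matches from RPS-BLAST tabular output) and
region annotations (low-complexity from SEG, transmembrane helices from
TMHMM2, coiled coils from PairCoil2, signal peptides from Phobius),
all in 1-based, both-ends-inclusive coordinates. Three rules turn these
into residue classes:

1. **Longest-domain overlap resolution.** Hits for one protein are
   ranked by (alignment length descending, E-value ascending, start
   ascending, model name ascending) and accepted greedily iff they
   overlap no already-accepted hit. This extends the pairwise
   "keep the longest of two overlapping domains" rule to arbitrary
   overlap chains deterministically, and yields a checkable
   certificate: accepted hits are pairwise disjoint and every rejected
   hit overlaps an accepted hit at least as long as itself. The rule is
   deliberately *not* coverage-maximizing — a 101-aa hit straddling two
   100-aa hits displaces both — and the test suite pins that behavior
   down rather than hiding it. An alternative `policy = "union"`
   (coverage is the residue union of all hits) is available because the
   multi-overlap behavior of large published pipelines is usually
   underdocumented; greedy is the default.

2. **Domain priority for regions.** A residue annotated as a region
   that also lies in an accepted domain counts as within-domain.
   Within one region type, residues are counted once (interval union);
   across types they are counted independently, so the "all regions"
   total is the *sum* of the four types and a residue can contribute to
   both an LC and a TM cell. The sum semantics is what makes the
   all-regions column of the database-scale table equal its row sum;
   a union-based alternative would need per-residue multi-type masks
   and cannot be reconstructed from published per-type totals.

3. **The 50-aa subtractability cutoff.** An uncovered segment is a
   subtractable *short linker* iff it is strictly shorter than
   `linker_max = 50` aa **and** bounded by domains or by a domain and a
   terminus. The rationale: domains span roughly 40–700 aa (mean
   ≈ 100) and interdomain linkers average 6–8 aa, so no segment under
   50 aa can hold even the smallest domain plus its flanking linkers.
   Strict `<` was chosen over `<=` (a 50-aa segment stays dark) because
   the source material states both "less than 50 aa" and "size limit at
   50 aa"; strictness is the conservative reading and the cutoff is a
   plain argument everywhere it appears. A protein with *no* accepted
   domain is classic dark matter over its whole length, however short:
   subtractability is an argument about what fits between known
   domains, and a domain-free protein has none.

Together these give the conservation identity checked for every
protein in every test:
`domain_aa + short_linker_aa + darkmatter_aa = length`.

Classic dark matter at database scale is `100 − pct_domain`; the
expanded estimate subtracts the short-linker residues as well. Regions
are *reported* (within/outside domains) but never subtracted from dark
matter, since no region type lies overwhelmingly outside domain
boundaries.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `linker_max` | 50 aa | strict subtractability cutoff for uncovered segments |
| `coords` | `"ali"` | domtblout coordinate pair; alignment coordinates are the conservative (shorter) choice over envelope coordinates, and the flag exists because published pipelines rarely say which they used |
| `policy` | `"greedy"` | overlap resolution; `"union"` caps coverage at the residue union |
| `sources` | `"pfam"` | hit sources that define domain coverage; Pfam models are domain-specific, while many CDD profiles (COG/PRK imports) span full proteins regardless of domain structure, which is why CDD serves as the redundancy cross-check rather than the coverage authority |
| `tm_source` | `"tmhmm"` | TM column authority; Phobius TM calls are parsed but excluded from totals unless selected, so the TM and SP columns have one tool each |
| `min_overlap_frac` | 0.75 | fraction of a secondary hit's residues inside primary coverage above which it is labelled confirmatory; no published value exists, 0.75 separates "mostly redundant" from "contributes new residues" and is configurable |

No E-value filtering is applied by default: Pfam hit tables are expected
to be produced with the curated per-family gathering thresholds
(`--cut_ga`), so rows are accepted as-is; `max_ievalue` provides an
optional extra filter.

Percentages are rounded half-up to one decimal, and only at
presentation — counts are never rounded internally. Base R's
round-half-even would turn e.g. an exact 0.05 boundary the wrong way
relative to published one-decimal tables.

## The synthetic proteome generator

The generator exists so that the entire pipeline — seven input dialects,
overlap resolution, segmentation, partitioning, aggregation — is
testable with known ground truth and no downloads. Its defaults are the
study conditions, chosen once from the field's reported statistics:

* domain length `min(700, 40 + Gamma(shape 2, scale 30))`: support
  40–700 aa, mean ≈ 100 aa;
* interdomain linkers `1 + Poisson(6)`: mean 7 aa, inside the reported
  6–8 aa band;
* 28% of proteins domain-free, the complement of the ≈ 72% of database
  sequences assignable to known families;
* domain count per domain-bearing protein: truncated geometric
  (p = 0.45, max 8), giving mostly 1–3 domains;
* terminal tails: a short/long mixture (85% geometric mean 10 aa, 15%
  50 + geometric mean 100 aa) so both subtractable terminal linkers and
  large uncovered termini — the pattern that motivates the expanded
  definition — occur;
* regions: TM helices ≈ 21 aa (membrane protein probability 0.25),
  N-terminal signal peptides 15–30 aa (probability 0.30),
  low-complexity (0.40) and coiled-coil (0.15) stretches; regions are
  anchored inside domains with probability 0.5 to exercise the
  domain-priority partition;
* CDD hits are planted as echoes of Pfam hits (probability 0.8) plus
  occasional full-length PRK-style profiles (probability 0.1),
  mirroring the observed partial redundancy of CDD with Pfam.

Architectures are built left to right (tail, domain, linker, …, tail),
so planted domains never overlap; `inject_overlap_decoys()` adds
strictly shorter decoy hits nested inside true domains, whose expected
resolution under the greedy rule is known exactly (all rejected,
coverage unchanged). Ground truth is recorded from the construction
blueprint, never by running the pipeline, which keeps
truth-vs-pipeline comparisons a genuine dual route.

`planted_coverage()` returns the analytic expectation of global
coverage: the ratio of expected domain residues to expected protein
length under the configured distributions, with the Gamma cap and
lognormal clamp handled by numeric integration. Sampled proteomes agree
with it to within Monte-Carlo error (the tests require 3 standard
errors over 20 seeds).

What the generator does **not** emulate: realistic amino-acid
composition, homology between proteins, correlated domain
architectures, prediction errors (false or missed hits), or coordinate
disagreements between tools. Passing tests therefore demonstrate that
the *accounting* is correct given annotations, not that any upstream
predictor is accurate on real sequences.

## Numerical and interface choices

* **Coordinates** are 1-based closed intervals throughout; "overlap"
  means sharing at least one residue. Interval merging also coalesces
  adjacent intervals, which changes neither residue counts nor gap
  extraction.
* **Ties** in overlap resolution break by E-value, then start, then
  model name, making output independent of input row order (tested by
  permutation).
* **Degenerate inputs**: zero-length proteins are errors; empty hit
  sets yield one `full_protein` segment; an empty proteome is an error
  for aggregation (no denominator) but valid for emission.
* **The unified TSV** carries one row per protein in addition to
  domain/region rows. The column specification alone would lose
  annotation-free proteins, and with them the total-space denominator
  and the sequence-level with/without-domain split; the `protein`
  category row makes read(write(T)) lossless up to residue strings.
* **RPS-BLAST rows** with reversed query coordinates are normalized by
  swapping (and flagged); domtblout rows with from > to are rejected
  (alignment coordinates should never be reversed, so a reversed pair
  there indicates a malformed table rather than a convention).
* **PairCoil2** input is the per-residue table; maximal runs at or
  above probability 0.5 become CC intervals.

## Problem sizes

The test suite runs the oracle comparisons on 1,000 random instances
each (lengths ≤ 500, ≤ 20 intervals), conservation on a 2,000-protein
proteome, recovery on 400–1,000-protein proteomes with 20 seeds for the
statistical check, and round-trips on 100–1,000-protein proteomes —
sizes at which every property that scales (conservation, additivity,
permutation invariance, round-trip losslessness) is already exercised
far beyond its corner cases. The acceptance script uses a
1,000-protein proteome plus 20 × 500 proteins for the seed-averaged
comparison.

## Known limitations

* The greedy longest-domain rule is one defensible reading of the
  pairwise published rule; real pipelines may have used union-capped
  coverage instead (hence the `policy` switch). Global coverage
  differences between the two are small because genuine multi-overlap
  chains are rare, but per-protein architectures can differ.
* "All regions" sum semantics can exceed the residue union when types
  overlap; the per-type cells are unions and unaffected.
* Only the SEG interval-list dialect (`seg -l`) is supported, not the
  masked-FASTA dialect; HMMER2 `hmmpfam` output is not supported.
* Database-scale published figures (51.39% of nr etc.) required
  database-scale scans; this package reproduces their *arithmetic*
  exactly from published residue counts and validates the accounting
  machinery on synthetic proteomes, but does not re-run the scans.
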