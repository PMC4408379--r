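---
title: "Methods: PTM curation and enrichment in ptmenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PTM curation and enrichment in ptmenrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmenrich)
```

## The problem

Post-translational modifications (PTMs) — phosphorylation, glycosylation,
acetylation, lipidation and several hundred rarer chemistries — are annotated
in UniProtKB/Swiss-Prot in two curated fields: the keyword (KW) lines, which
carry coarse category labels such as `Phosphoprotein`, and the feature table
(FT), whose `MOD_RES`, `LIPID` and `CROSSLNK` features name the exact modified
residue (e.g. `Phosphoserine`). Given a list of proteins from an experiment,
the question this package answers is: *which PTM categories are
over-represented in my list relative to what is typical for the organism?*
An enriched modification class is a direct hint for designing targeted
follow-up proteomics (e.g. phosphopeptide or glycopeptide enrichment).

Comment (CC) lines also mention modifications in free text, but free text is
not reliably curated for this purpose; the package parses and retains CC
topics verbatim and never mines them for PTM terms.

## The curation model

Curation proceeds in the order: parse, filter, vocabulary, index.

1. **Parse.** `parse_entries()` streams Swiss-Prot flat-file (DAT) text and
   keeps, per entry: ID, AC, OS, KW, FT, DR and CC. Both the classic
   (pre-2019, fixed-column positions) and modern (`begin..end` + `/note=`)
   feature-table dialects are supported, auto-detected with
   `detect_dialect()`; classic is the default when no feature lines are seen.
   Input is UTF-8 with a per-line Latin-1 fallback. Feature positions that
   are unknown or fuzzy (`?`, `<1`, `>100`) parse with `NA` coordinates but
   the feature still counts for term extraction — the analysis counts terms,
   not residues.
2. **Filter.** `build_database()` keeps only reviewed entries, and among
   those only proteins with at least one PTM annotation: a keyword matching
   a KW-level vocabulary term (case-insensitively), or a `MOD_RES` / `LIPID`
   / `CROSSLNK` feature whose description normalizes to a non-empty term.
   The mined feature keys are a build parameter; the default set is exactly
   these three structural-modification classes (`CARBOHYD`, `DISULFID` and
   the rest are excluded by default but can be added).
3. **Vocabulary.** The controlled vocabulary is a three-level rooted DAG
   (`build_dag()`): the literal root `PTM`, keyword-level terms at level 1,
   feature-level terms at level 2. Feature terms may have several keyword
   parents (`S-palmitoyl cysteine` sits under both `Lipoprotein` and
   `Palmitoylation`), which is why the structure is a DAG and not a tree.
   The DAG serializes to a flat XML schema
   (`<ptmdag><term id label level><parent ref/></term></ptmdag>`); flat term
   elements with parent references represent multi-parent nodes without
   duplication.
4. **Index.** The database indexes, per organism and term, the set of
   annotated protein accessions, plus an alias table (accessions and entry
   names) for identifier resolution and the evidence qualifier of every
   feature-level annotation.

### Feature-description normalization

`normalize_ft_description()` turns a raw FT description into a vocabulary
term plus an evidence qualifier, in this order: strip trailing
periods/whitespace; remove the parenthesized evidence qualifiers
`(By similarity)`, `(Probable)`, `(Potential)` — their presence marks the
annotation *putative*, their absence *experimental*; truncate at the first
`;`, which separates the term from agent clauses (`Phosphoserine; by PKA`);
collapse whitespace. Internal parentheses that belong to the chemistry
(`N6-(pyridoxal phosphate)lysine`) are preserved. The trailing-period strip
is greedy (all trailing periods, not just one) so the operation is
idempotent — a property the test suite asserts on randomized input. The
qualifier set is configurable; the default triple is the standard
non-experimental qualifier set used in putative/experimental dictionary
splits of Swiss-Prot PTM statistics.

A cleaned description that matches no feature-level vocabulary label is kept
as an *ad-hoc* term attached to a synthetic `Uncategorized` keyword parent,
so no annotation is silently dropped; an empty description is an "unnamed
feature" and is skipped.

### A note on the packaged vocabulary

`default_vocabulary()` ships a small illustrative vocabulary: the well-known
keyword categories and a set of common modified-residue terms. It includes
`Nucleotide-binding` among the keyword terms because PTM curation practice
built on Swiss-Prot keywords conventionally counts it, although it is a
binding property rather than a covalent modification — treat its rows
accordingly. The KW→FT edge set is illustrative, not a reproduction of any
official mapping; real analyses should load a complete vocabulary with
`read_vocabulary()` (tab-delimited: `level`, `label`, `parent_labels`).

## The statistical model

Let `N` be the number of PTM-annotated proteins of the organism (the
background), `K` of which carry a given term; the user's list resolves to
`n` proteins of which `m` carry the term. Under the null that the list is an
unstructured draw from the background, `m` is hypergeometric, and the
enrichment p-value is the exact upper tail

$$
P = \sum_{x=m}^{\min(K,n)} \frac{\binom{K}{x}\binom{N-K}{n-x}}{\binom{N}{n}}.
$$

`hypergeom_pvalue()` evaluates this sum in log space with log-gamma
binomial coefficients (`lchoose`) and a log-sum-exp reduction, so
backgrounds of 10^5+ proteins neither overflow nor lose the tail;
`m = 0` returns exactly 1. Results that underflow double precision are
floored at the smallest positive double and flagged (`attr(p, "underflow")`)
rather than reported as zero. The test suite checks the implementation
against exhaustive subset enumeration for every parameter tuple with
`N <= 12` (tolerance 1e-12), against direct rational arithmetic for
`N <= 60`, and against `stats::phyper` on large random tuples.

### Multiple testing

Across the `T` testable terms the package offers no correction, Bonferroni
(`min(1, pT)`, with the modified significance level `alpha/T` also reported —
the two views are decision-equivalent) and Benjamini–Hochberg step-up FDR.
Both corrections delegate to `stats::p.adjust`; hand-computed worked
examples pin the behaviour in the tests. `T` counts only terms with
`K >= 1` in the organism background: testing a term absent from the
background is vacuous (its p-value is identically 1) and would only inflate
the correction. This choice is configurable in effect by supplying a
trimmed vocabulary. The default decision rule is Bonferroni at
`alpha = 0.05`, the conservative convention for claiming an enriched
modification class.

### The background matters

The background is the organism's *PTM-annotated* proteins, not its whole
proteome — the database only stores annotated proteins. P-values answer
"is this term over-represented among PTM-carrying proteins of this
organism", which is the right question for prioritizing modification
classes, but numerically different from a whole-proteome background. This is
stated prominently because it is the single largest lever on the p-values.

## Analyses

* `enrich()` — resolves identifiers (primary/secondary accession or entry
  name, case-insensitive, deduplicated, organism-scoped), computes the tail
  probability per testable term, applies the correction, and orders rows by
  increasing p-value (ties broken by label). Terms with no list hit
  (`m = 0`) are excluded from the display rows — their p-value is 1 by
  construction — but retained in `all_terms` for matching.
* `match_results()` — integrates two enrichment results computed against the
  same database and organism (enforced via a database fingerprint). The
  matched table is the *union* of terms significant in either list; the
  `significant_in` column (`list1`/`list2`/`both`) recovers the intersection
  view, so the union loses no information. The operation is exported as
  `match_results` rather than `match` to avoid masking `base::match`.
* `list_frequency()` — the descriptive companion: per term, organism count
  and percentage next to list count and percentage, no testing, `m = 0`
  terms retained.
* Export: `export_table()` writes a tab-delimited table with a fixed header
  (ID, PTM vocabulary, frequencies and percentages in UniProt and in the
  list, accessions, raw and corrected p-value) and a footer recording `N`,
  `n`, alpha and the correction; percentages print with 2 decimals,
  p-values in scientific notation with 4 significant digits; identical
  inputs give byte-identical files. Accessions carry cross-reference
  markers harvested from DR lines — `(1)` PhosSite, `(2)` PhosphoSite,
  `(3)` UniCarbKB, configurable in `crossref_markers()`.
  `export_barchart()` draws `-log10` of the decision p-value per term
  (enrichment) or paired percentages (matched / frequency results) to PDF.

Reporting conventions: composition percentages round to 2 decimals;
Venn-style summaries of annotation sources round to the nearest integer
percentage. `ft_key_composition()` counts a protein once per feature key,
and a protein with two keys contributes to both counts and twice to the
denominator (a per-annotation-class composition). Published curation counts
for the 2014 Swiss-Prot release reproduce under these conventions except
one cell: the LIPID share computes to 11.51% from the printed counts while
the published figure shows 11.53%; the package reports the value computed
from counts.

## The synthetic-data generator

Real Swiss-Prot downloads are multi-gigabyte and release-dependent, so every
stage is validated on synthetic fixtures with known ground truth.
`generate_records()` emulates: UniProt-grammar accessions (letter + 5
alphanumerics), keyword and feature annotations sampled independently per
term with specified prevalences, a putative-qualifier fraction (default
20%), occasional PhosphoSite cross-references, and both FT dialects. The
default conditions are 2,000 proteins in one organism with 20 terms —
8 keyword-level (prevalences 5-30%) and 12 feature-level (2-15%) — chosen
once as a plausible Swiss-Prot-like mix. The truth table returned alongside
the records exactly matches the emitted annotations, and generation is
byte-deterministic in the seed.

`plant_enriched_list()` draws lists with a planted signal: with enrichment
factor `f` and background prevalence `p`, the carrier count is
Binomial(`n`, `min(1, f p)`) (clamped to feasibility), giving expected list
prevalence `min(1, f p)`; `f = 1` short-circuits to a plain uniform sample
without replacement — exactly the calibration null. Requests where
`f p > 1` and `n` exceeds the carrier count are refused as infeasible.

What the generator does *not* model: correlation between terms (real PTMs
co-occur — phosphosites cluster, glycoproteins are often also
disulfide-bonded), organism-specific term spectra, sequence content, and
annotation-depth bias across organisms. Passing calibration and recovery
tests therefore demonstrate correctness of the machinery under independent
annotations, not robustness to the correlation structure of real data.

## Validation conditions and numerical choices

The validation suite runs at these problem sizes, chosen as the package's
own standard conditions:

* exhaustive hypergeometric enumeration: all tuples with `N <= 12`
  (3,184 tuples), tolerance 1e-12;
* null calibration: 2,000-protein background, 20 terms, 10,000 uniform
  draws of size 50; the fraction of raw p <= 0.05 must stay below
  0.05 + 3 standard errors (the discrete tail makes the test conservative,
  so observed rates run near 3%);
* planted recovery: a 5x-planted term of ~5% prevalence, lists of 100, 100
  seeds; the planted term must rank first with a significant
  Bonferroni-adjusted p in at least 95% of seeds;
* round-trips: 1,000 randomized records written and re-parsed in both
  dialects, DAG XML, and exported tables re-imported at printed precision.

Tie-breaks are always lexicographic on the term label after the primary
sort, so outputs are deterministic. Degenerate inputs have defined
behaviour: empty record streams build an empty database; an all-zero
composition reports zero percentages; `K = N` forces `p = 1`; empty
identifier lists and lists matching nothing are errors that name the likely
cause (wrong organism).

## Limitations

* The packaged vocabulary is deliberately small; enrichment against it is
  only as complete as the vocabulary supplied.
* One entry dialect per stream; files mixing classic and modern FT layouts
  are rejected rather than reconciled.
* Isoform-specific feature descriptions are normalized like any other text;
  no isoform accounting is attempted.
* The database stores no sequences and supports no incremental updates; a
  new Swiss-Prot release means a rebuild.
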