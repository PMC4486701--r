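---
title: "Taxonomic binning of meta-barcoding amplicons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxonomic binning of meta-barcoding amplicons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplitax)
```

## Scope and data flow

`amplitax` implements the bespoke computational stages of an amplicon
meta-barcoding classification workflow, together with the machinery
needed to benchmark it on synthetic communities. The processing chain
for Illumina paired-end data is:

1. **Read preparation** — overlapping mates are merged into consensus
   sequences; non-overlapping pairs are 3'-quality-trimmed and
   length-filtered; consensus sequences are dereplicated into unique
   sequences with abundance counts.
2. **Alignment** — the dereplicated sequences are mapped to a
   taxonomically annotated reference database by an *external* aligner
   (BLASTN or a SAM-emitting mapper such as Bowtie2). `amplitax`
   deliberately does not wrap aligners as pipeline stages; it consumes
   their tabular/SAM output (`parse_blast_tabular()`, `parse_sam()`).
3. **Hit filtering** — per query, hits are retained by a three-stage
   rule (below) and written to a *match file* of candidate taxa.
4. **Assignment** — each query's candidate taxon set is placed on a
   guide tree (the reference taxonomy annotated with the reference
   sequences) by penalty minimisation, with the lowest common ancestor
   (LCA) as a special case.
5. **Profiling / evaluation** — assignments are aggregated into
   cumulative per-rank profiles, and, when truth labels exist,
   benchmarked as per-taxon/per-rank sensitivity and specificity.

## The taxonomy substrate

Taxonomies are rooted ranked trees in the NCBI dump dialect (or a plain
TSV fallback). Seven canonical ranks are used throughout — kingdom,
phylum, class, order, family, genus, species. Intermediate ranks
(subclass, tribe, ...) are loaded as `"no rank"` and are transparent to
rank projection: `rank_ancestor()` walks the lineage and returns the
unique ancestor-or-self at the requested canonical rank, or `NA` when
the lineage lacks it. A reference lineage is *complete*
(`is_complete_path()`) when all seven ranks are present and no lineage
name contains a placeholder pattern (`"uncultured"`,
`"environmental sample"`, `"unidentified"` by default; the patterns are
configurable because placeholder naming is a convention, not a rule).

References may legitimately be annotated above species rank (e.g.
genus-level entries in curated marker databases); the guide tree counts
them at their annotated node, and `leaves_under()` values are computed
in one bottom-up pass.

## Hit filtering

For each query the aligner's hits pass three stages, in this order:

1. **Numeric thresholds.** Percent identity ≥ 97 and query coverage
   ≥ 70, both inclusive. For SAM input, identity is
   `100·(aligned_columns − NM)/aligned_columns` over the CIGAR M/=/X
   columns and coverage counts soft-clipped bases in the denominator;
   properly paired records are combined into one hit with identity and
   coverage averaged over mates and score summed.
2. **Score tolerance.** With `B` the best surviving score, hits with
   score < 0.95·B are dropped ("within 5% of the best match", read
   fractionally, not as an absolute offset — the phrasing is a
   percentage). For SAM input the alignment score (`AS`) stands in for
   the bitscore.
3. **Completeness priority.** If any survivor maps to a reference with
   a complete taxonomic path, survivors mapping to incomplete-path
   references (placeholder names, missing ranks) are dropped; otherwise
   all survivors are kept.

The stage order is a genuine design choice: completeness-first would
change results (an incomplete-path hit can outscore a complete-path hit
by more than 5%, in which case thresholds-then-tolerance-then-
completeness retains only the complete one, while completeness-first
would too, but other orderings of the tolerance stage would not). The
chosen order applies the tolerance rule to the full threshold-passing
pool, then prefers informative references among near-best hits.

One property worth knowing: the *composed* filter is not monotone in
`min_identity`. Raising the threshold can remove the best-scoring hit,
lower the 5% bar `B`, and thereby let additional survivors through
stage 2. Monotonicity holds for the threshold stage in isolation; the
test suite asserts exactly that.

## Assignment by penalty minimisation

Let `M` be the set of matched reference sequences of a query (a
reference counts as matched when its annotated taxid is in the match
file). For every taxonomy node `n` define

- `FN(n)` — matched references *outside* the subtree of `n`;
- `FP(n)` — guide-tree references *inside* the subtree of `n` that are
  not matched;

and the penalty `score(n) = q·FN(n) + (1−q)·FP(n)` with `q ∈ [0, 1]`.
The query is assigned to the minimising node, ties broken toward the
deepest node and then the smallest node id, so runs are reproducible.

With `q = 1` only false negatives are penalised and the minimiser is
exactly `lca(M)`; the package guarantees and tests this identity. The
default is the symmetric `q = 0.5`: with no external reason to weight
missed references differently from swept-in ones, the neutral midpoint
is the least-surprising default, and users wanting classical LCA
behaviour set `q = 1`.

`assign_query()` evaluates *all* taxonomy nodes, not only nodes on the
LCA path: both aggregates (`matched refs under n`, `refs under n`) are
computed for every node in one O(N) bottom-up pass, so global
minimisation costs no more than a path restriction — and a path
restriction can miss the optimum for small `q` when references hang at
internal nodes. The unit tests compare against a literal
every-node brute-force minimiser.

Matched taxids with no reference mapped exactly at their node (possible
after a match-file round trip) count once in the FN aggregate so the
q = 1 ≡ LCA identity survives arbitrary match files.

Profiles count cumulatively: an assignment at a node increments the
node and all its ancestors (weighted by dereplication abundance), so
counts are non-increasing from root to leaves. Reads assigned at
`"no rank"` nodes report the nearest ranked ancestor in rank-indexed
tables. Outputs are a per-read CSV (with `k__...;p__...` lineage
strings), a per-rank counts CSV, and a Newick tree with counts embedded
as `[&count=N]` comments (the serializer is hand-written because
`ape::write.tree()` cannot emit comments; tests strip the comments and
re-parse the topology with `ape`).

## Read preparation

**Merging.** For a pair (read 1, reverse-complemented read 2) every
overlap length `o ≥ min_overlap` (default 10) is scored by its mismatch
ratio; the best ratio wins, ties going to the longer overlap, and the
pair is rejected when the best ratio exceeds `max_mismatch_ratio`
(default 0.25). These defaults are the published defaults of the
standard overlap-merging tools and both knobs are exposed. Consensus
bases at disagreements take the higher-Phred base (tie: read 1) with
quality `|q1 − q2|`; agreements take the max quality. Full containment
(overlap = shorter read) is allowed, which handles adapter
read-through of amplicons shorter than the read length.

**Trimming.** Only non-merged pairs are quality-trimmed (merged
consensus reads pass through — the overlap itself is the quality
evidence). The 3' trimmer is the BWA/Trim-Galore partial-sum rule: cut
at the position maximising the suffix sum of `(cutoff − q)`, trimming
whenever that maximum is ≥ 0 so trailing bases with Phred equal to the
cutoff (default 25) are removed. Ties resolve toward the longer trim.
Pairs with a mate shorter than 50 nt (strictly) after trimming are
dropped.

**Dereplication** is exact full-length, case-insensitive grouping; the
representative is the first-seen id. Every input pair ends in exactly
one of merged / kept-unmerged / dropped, and abundances sum to the
input count — both are asserted as invariants.

## The synthetic benchmark generator

The generator reproduces the logic of a primer-based benchmark
construction rather than any particular organism set:

- **Taxonomy**: a complete seven-rank tree; species are spread evenly
  over genera so co-generic species exist whenever
  `n_species > n_genera`. `sample_community()` can additionally force a
  minimum number of co-generic species (the benchmark communities of
  record force 58/102 and 60/101), with a tight feasibility bound and a
  deterministic draw under a seed.
- **Reference database**: per species a random core marker sequence
  (length uniform in a marker-specific range), with each reference copy
  carrying ≤ 1% random substitutions. Species cores are drawn
  independently, so between-species identity is ~25% while
  within-species identity is ≥ 99% — the separation the hit filter
  relies on, by construction.
- **In-silico PCR**: source sequences carry realized universal primer
  sites (the degenerate 16S V5-V6 or fungal ITS1 pairs are built in);
  `extract_amplicons()` scans both strands for degenerate-primer
  matches (0 mismatches by default, a `max_mismatches` knob exists),
  pairing leftmost-first and non-nested, with a 2,000 nt span cap —
  unbounded pairing is biologically meaningless. Amplicons retain their
  primer sequences by default (that is what the sequencer reads); a
  `trim_primers` flag removes them.
- **Reads**: MiSeq-like 250×2 layout; read 1 is the amplicon prefix,
  read 2 the reverse-complemented suffix; amplicons shorter than the
  read length yield reads at amplicon length (mirroring adapter
  read-through after trimming, rather than padding). Errors are i.i.d.
  substitutions (default rate 0.1%, a stand-in — no published error
  profile is claimed); Phred scores are truncated-normal draws clipped
  to [2, 41]. The V5-V6 length range is narrow (~300 nt) and the ITS1
  range wide (120–480 nt), reproducing the qualitative length
  variability contrast between the two markers.

What the generator does **not** emulate: hierarchical sequence
similarity (congeneric species are no more alike than cross-genus
ones), indels and homopolymer errors, chimeras, PCR bias, 454
flowgrams, and real-database artefacts such as mislabeled or
placeholder lineages (the latter are exercised by handmade fixtures in
the tests instead). Two consequences matter when reading benchmark
output. First, a perfect species-level recovery on the error-free
fixture shows the plumbing is lossless, not that real communities
classify perfectly. Second, in the depletion experiment orphaned reads
have *no* sub-97%-identity relatives in the depleted reference, so they
come back almost entirely "unassigned" rather than rescued at family
rank; with real databases a substantial family-level-rescue fraction
appears precisely because real congeners share sequence similarity
that the generator omits.

## Evaluation

Per rank, each read's truth and call are projected with
`rank_ancestor()`; calls above the rank (or absent) count against the
true taxon's false negatives. For taxon `i`: `TP_i` (truth `i`, call
`i`), `FN_i` (truth `i`, call ≠ `i`), `FP_i` (truth `j ≠ i`, call `i`),
`TN_i` (truth `j ≠ i`, call = own `j`). Rates are
`TPR_i = TP_i/(TP_i+FN_i)`, `TNR_i = TN_i/(TN_i+FP_i)`,
`FPR_i = FP_i/(TN_i+FP_i)`, `FNR_i = FN_i/(TP_i+FN_i)` (×100), and the
rank-level value is the *unweighted mean over taxa* (macro average,
denominator = number of taxa with a positive denominator for that
rate). Read-weighted averaging would differ; macro averaging is chosen
because the per-rank summary of record averages per-taxon rates over
the taxon count. Call-only taxa (present in calls, absent from truth)
contribute FP to themselves but are excluded from the TPR/FNR means —
no positives exist, and 0/0 is not a rate.

At a single-taxon rank (typically kingdom) there are no negatives, so
TNR and FPR are undefined. Internally they stay `NA`; the
report writer's compatibility mode displays them as `0.00`, mirroring
the conventional presentation of such rows, without asserting that the
convention is meaningful.

`TPR_i + FNR_i = 100` and `TNR_i + FPR_i = 100` hold exactly by
construction, per taxon and per macro-averaged rank; the suite asserts
them on random tables.

**Depletion experiment.** All references of a random 50% of the
community's genera are removed, the classifier is re-run, and each
orphaned read (true genus removed) is placed in exactly one bucket:
`unassigned`; `ancestor_family_or_higher` (call on the true lineage at
family rank or above); `wrong` (call off the true lineage, or an
on-lineage call *below* family — such a call overclaims a genus that no
longer has references). The buckets partition the orphaned reads by
construction.

## Numerical and degenerate-input choices

- Threshold comparisons are inclusive (97.0 and 70.0 pass); the 5%
  score rule uses `score ≥ 0.95·B − 1e−9` to absorb floating-point
  noise in `0.95·B`.
- Score ties in assignment break deepest-then-smallest-id; overlap
  ties in merging break toward the longer overlap; trim ties break
  toward the longer trim.
- Empty match sets assign to `NA` ("unassigned"), never an error;
  empty hit tables filter to empty; an empty dereplication input is an
  empty set with total 0.
- `lca()` of an empty set, a guide tree with no references, a taxonomy
  without a root, duplicate ids, orphan parents and parent cycles are
  hard errors with the offending node named.
- All stochastic components (taxonomy layout, reference cores, read
  errors, community draws, genus removal) are deterministic under an
  integer seed, and seeded calls restore the caller's RNG state.

## Problem sizes used in the shipped checks

The end-to-end checks run a 30-species / 10-genera community at 100
pairs per species (3,000 pairs per condition: error-free and 0.5%
substitution noise), three references per species, with BLASTN
(megablast) as the external aligner; the filter and assignment
operations are additionally verified against brute-force references on
10,000 random hit tables and 1,000 random guide trees. These sizes were
chosen so the whole suite exercises every stage at full fidelity while
remaining quick to run on a laptop; the generator scales to the
102-species / 5,000-pairs-per-species sizing of the dataset of record
(`readset_plan(102, 5000)` = 510,000 pairs) when heavier runs are
wanted.

## Known limitations

- The assignment objective is a faithful-in-spirit penalty formulation
  with an exact LCA special case; it does not claim bit-compatibility
  with any particular optimal-mapping implementation.
- Paired-end SAM semantics average mate identity/coverage and sum mate
  scores; other conventions (min, concatenated-alignment) exist and
  would shift borderline hits.
- Dereplication is exact-match only (no prefix clustering or
  single-linkage denoising).
- The error model is substitution-only; indel-rich platforms need an
  external denoiser upstream.
- BLAST XML is not parsed (tabular only), and aligners are not
  executed by the pipeline itself; the benchmark harness's
  `blast_align()` helper is a convenience for synthetic fixtures.
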