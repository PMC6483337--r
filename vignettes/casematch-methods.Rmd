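---
title: "casematch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{casematch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casematch)
```

This vignette is the package's own account of its science: the matching
model and its assumptions, the parameters that matter, the numerical
and design choices made where the design was genuinely open, and what
the synthetic fixtures do and do not demonstrate about real data.

## The problem

A "case" is one patient's set of candidate ("in limbo") DNA variants —
variants with a suspected but unconfirmed causal role — together with a
phenotype profile of one or more Human Phenotype Ontology (HPO) terms,
and optionally a suspected mode of inheritance and age of onset. The
engine maintains a watch list of such cases and, on every new
submission, searches for previously submitted cases of potential
diagnostic value: same variant, same position, same codon, or same
gene, with a similar phenotype. Matches are reported to both parties,
so each use of the service also grows the resource.

## Phenotype similarity

### Term level

Let $P(c, r)$ be the set of all distinct directed paths from term $c$
up the `is_a` hierarchy to the ontology root $r$, where a path is taken
as its *set of nodes* including both endpoints. The similarity of two
terms is the best Jaccard agreement over all path pairs:

$$\mathrm{sim}(c, c') = \max_{p \in P(c,r),\; p' \in P'(c',r)}
  \frac{|p \cap p'|}{|p \cup p'|}.$$

Properties that follow directly and that the test suite asserts:

* identity: $\mathrm{sim}(c, c) = 1$ (every path matches itself);
* symmetry and range $(0, 1]$ — any two paths share at least the root;
* the *deep-rooted annotation reward*: on a chain, parent–child pairs
  score $k/(k+1)$ at depth $k$, so precise annotations deep in the
  ontology outrank equally related but shallow ones. This is the reason
  an edge-based measure over root paths was preferred to node-based
  information-content measures (Resnik, Lin), which depend on the
  annotation frequencies of some reference population and therefore
  change whenever that population changes. Node-based measures are
  deliberately not implemented.

Two design points the equation itself does not fix:

* **Path endpoints.** A root path includes both the term and the root.
  This is forced: excluding the term would give
  $\mathrm{sim}(c,c) < 1$ for any non-root term, and the root's own
  path set would be empty.
* **Paths as sets.** The equation operates on $|p \cap p'|$ and
  $|p \cup p'|$, i.e. on node sets; two traversals identical as sets
  count once. Only `is_a` edges define the hierarchy — `part_of` and
  other relationships are ignored, the usual convention for HPO
  similarity.

### Case level

Profiles $d, d'$ (non-empty term sets) are compared with the
symmetrised best-match average

$$\mathrm{sim}(d,d') = \frac{1}{2|d|}\sum_{c \in d}\max_{c' \in d'}
  \mathrm{sim}(c,c') + \frac{1}{2|d'|}\sum_{c' \in d'}\max_{c \in d}
  \mathrm{sim}(c,c'),$$

which is symmetric, equals 1 on identical profiles, and collapses to
the term similarity for singletons.

### The path cache

All root paths of all non-obsolete terms are pre-computed once per
ontology release (`precompute_path_cache()`) and persisted as JSON, so
similarity evaluation at matching time is pure set arithmetic in
memory. Dense artificial DAGs can have exponentially many paths; cache
construction therefore enforces a per-term limit (default 10,000,
orders of magnitude above what real HPO releases need) and fails loudly
rather than silently truncating.

Submitted accessions are resolved before use: `alt_id` aliases map to
their primary term, obsolete terms are followed through `replaced_by`
when present, and anything else is rejected at validation with a trace
entry. The ontology root is detected structurally (the unique
parentless non-obsolete term) with an explicit override for real HPO
(`HP:0000001`).

## Variant handling

Coordinates are 1-based inclusive throughout (the VCF/GFF3/HGVS
convention); no half-open representation is used internally, to avoid
off-by-one conversions across the three formats. Chromosome names are
canonicalized by stripping `chr` prefixes at parse time. Alleles are
uppercased on ingest, and soft-masked (lower-case) reference bases
compare case-insensitively.

**Left normalization.** Every stored variant is reduced to its
left-most minimal representation: identical terminal bases of REF and
ALT are truncated; if an allele empties, the reference base to the left
is prepended to both and the position decremented; finally identical
leading bases are trimmed while both alleles keep length ≥ 2. Indels
always carry a left anchor base (VCF style), so no allele is ever
empty. The operation is idempotent and sequence-preserving, and the
test oracle certifies left-most minimality by exhaustively enumerating
every equivalent representation in a ±20 bp window. In a long tandem
repeat the normalizer may shift a variant further left than that
window; the window is the oracle's scope, not the normalizer's.

**HGVS.** Only genomic (`g.`) descriptions are parsed locally —
substitution, del, dup, ins, delins with explicit coordinates.
Transcript- and protein-level descriptions (`c.`, `p.`, ...) would
require a projection service; they are rejected with an
unsupported-level error and land in the processing trace. Duplications
are represented as insertions of the duplicated tract after its last
base and then normalized like everything else.

**Assembly conversion** is a provider interface. Shipped providers are
the identity (labels already equal) and an interval-offset map loadable
from a 4-column text file, which is exactly what synthetic fixtures
need; a chain-file liftover can be plugged in without touching the
pipeline. After remapping, REF is re-verified against the target
genome; failures are traced per variant.

## Annotation and filtering

The annotator is a deliberately minimal, deterministic, local
replacement for a full variant effect predictor: it computes exactly
the features matching needs — gene, transcript region, codon ordinal,
consequence, impact class — from GFF3 gene models and the reference
FASTA. Consequence names are a ten-term subset of the Sequence
Ontology vocabulary.

* Codon ordinal: position $k$ (1-based, 5'→3' in transcript
  orientation) of the coding sequence lies in codon
  $\lfloor (k-1)/3 \rfloor + 1$. The implementation walks the CDS
  intervals; the test oracle physically splices the CDS, reverse
  complements on the minus strand, and indexes the base — both agree on
  every CDS position of every generated gene.
* CDS substitutions are translated before and after with the standard
  genetic code: synonymous, missense, stop_gained, stop_lost,
  start_lost. CDS length changes: frameshift when
  $|\,|REF|-|ALT|\,| \bmod 3 \neq 0$, else inframe_indel.
* Impact classes: HIGH = stop_gained, stop_lost, start_lost,
  frameshift; MODERATE = missense, inframe_indel; LOW = synonymous;
  MODIFIER = all non-coding regions. Splice-site effects are *not*
  modelled — intronic positions are MODIFIER; this is an explicit
  simplification.
* Canonical transcript: a `canonical=1` attribute when present,
  otherwise the longest-CDS transcript per gene.

Filters decide *matchability*, never storage: a variant passes when its
minor allele frequency (from an optional local VCF with `AF` INFO
fields) is absent or ≤ `max_maf`, and at least one transcript hit
reaches `min_impact` (plus optional protein-coding / canonical gates).
Defaults: `max_maf = 0.01`, `min_impact = "MODERATE"`, both gates off.
The MODERATE default encodes one reading of "a predicted deleterious
effect" (missense and worse); it is configurable rather than asserted,
and an absent frequency passes the MAF gate — absence of evidence does
not exclude a rare candidate. Filter relaxation is monotone: lowering
`min_impact` or raising `max_maf` never shrinks the matchable set
(property-tested).

## Matching

Proximity categories, strongest first: IDENTICAL (equal
chrom/pos/ref/alt), SAME_POSITION, SAME_CODON, SAME_GENE. Two variants
are same-codon when *any* transcript shared by both variants'
filter-passing hits assigns them equal codon ordinals (which transcript
to use is otherwise under-determined); same-gene when their
filter-passing gene sets intersect. Using only filter-passing hits also
prevents flanking (up-/downstream MODIFIER) hits from spuriously
linking neighbouring genes.

Ranking is category-first, then phenotype similarity (computed once per
case pair over the full profiles and attached to all of the pair's
records), then hit-case submission order and id as deterministic
tie-breaks. Pruning to the top N (default 5, configurable) is *global*
across categories after that ordering; per-category quotas are not
used. At most one record is kept per (query variant, hit case) — the
best pair — so a single case cannot monopolize the top list with many
near-duplicate pairs. Self-matches are excluded at case level; matches
between two cases of the same submitter are allowed and flagged
`same_owner`, which supports internal quality-control use.

Reports are give-and-take: one to the submitter with all matches, one
to each distinct owner of a hit case with the roles swapped. A beacon
hit ("already publicized") only informs the submitter; it neither
removes the variant from matching nor down-ranks it — that policy is
left to the operator.

## The pipeline and the store

Stages run in fixed order: validate → extract → normalize → convert →
annotate → beacon → filter → match. After validation no stage can
abort a submission; every per-variant failure becomes a trace entry
(stage, record, reason) for submitter follow-up, and every input
variant is either stored or traced (a tested partition property). A
case ends PROCESSED (with an explicit "no matchable variants" trace
entry when everything was filtered out) or FAILED. Retraction flips the
status and excludes the case from all future matching while leaving
historical reports untouched.

The original service ran these stages on a distributed job system; here
they are pure functions executed sequentially, which preserves the
dependency order and makes the whole engine deterministic. For the same
reason, all timestamps are **logical submission sequence numbers**
rather than wall-clock times: replaying the same submissions from an
empty store must produce byte-identical exports and reports, and does
(tested). Case ids are sortable sequence-derived identifiers
(`CASE-000001`, ...). Persistence is a single JSON-lines file (one case
per line, fixed field order) plus a site-only VCF export; concurrent
writers are out of scope (single-operator deployment).

## Synthetic fixtures: what they show and what they don't

The generators produce everything the engine consumes:

* `generate_mini_ontology()` — a rooted hierarchy of `depth + 1` levels
  with `branching` children per term and a configurable fraction of
  multi-parent terms (second `is_a` edge one level up). Defaults
  (depth 4, branching 2, 20% multi-parent) give a 31-term DAG — deep
  enough for the depth-reward and multi-path machinery, small enough
  for exhaustive oracles. Multi-parent requests at depth < 3 are
  rejected as infeasible.
* `generate_toy_genome()` — genes with 1–3 exons, ATG-initiated CDS of
  length divisible by 3 without internal stops, mixed strands, short
  UTRs, and a 20 bp CA-repeat tract for normalization tests. Gene sizes
  (18–30 internal codons) keep every codon scan exhaustive but fast.
* `generate_cohort()` — for every planted pair, two cases whose
  variants realize exactly the requested proximity category in a
  dedicated gene (deleterious substitutions found by scanning the codon
  table, guaranteeing filter passage) and whose profiles share terms to
  the requested overlap: *high* = identical profiles, *medium* =
  sibling terms, *low* = terms from different top-level branches.
  Overlap brackets are checked as an ordering, not as exact values.
  Filler cases each occupy their own gene, so they are guaranteed
  category-none against everything.

All generators are seed-deterministic (identical seed ⇒ byte-identical
files). Fixtures are structural, not biological: they exercise formats,
coordinate arithmetic and matching semantics. They do not model
realistic allele-frequency spectra, linkage, splice biology, sequencing
error, or disease-gene architecture — so passing tests demonstrate the
*correctness of the machinery*, not clinical performance on real
cohorts. Real deployments substitute the real HPO (OBO), a real
reference genome and gene models, and a populated known-variant store
through the same readers.

## Problem sizes used in the checks

The test suite runs the full-strength property checks: brute-force
similarity cross-validation on 100 random DAGs of up to 50 terms (every
term pair), 1,000 random profile pairs for the similarity axioms, 1,000
random variants for normalization (each certified against an exhaustive
enumeration of equivalent representations in a ±20 bp window),
planted-truth recovery over ten seeded 20-case cohorts plus filler-only
cohorts, and a 30-submission replay compared byte for byte. The
acceptance script recomputes the same quantities at moderately reduced
sizes (30 DAGs, 300 variants, five cohort seeds) chosen to keep a full
from-scratch run in well under a minute per section on a single CPU.

## Known limitations

* No transcript-level (`c.`) HGVS resolution, structural variants, or
  genotype/sample semantics; VCF is read site-only.
* No splice-site consequences; intronic = MODIFIER.
* The known-variant store is a local stand-in for a beacon network; a
  networked beacon client would plug into the same `beacon_check()`
  interface.
* Matching triggers on submission (and on explicit `rescan`); there is
  no continuous background screening process — with an event-driven
  store the two are equivalent.
* Single-operator trust model: no authentication, encryption or
  multi-tenant user management.
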