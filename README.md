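# casematch

**Locally deployable variant/phenotype case matching for rare-disease
genetics.**

In clinical sequencing of suspected monogenic disease, most candidate
variants end up "in limbo": plausibly causal but unconfirmable from a
single patient. The established remedy is *matchmaking* — finding an
independent case with the same (or a closely related) variant and a
comparable phenotype. Public matchmaking platforms exist, but consortia
of diagnostic laboratories often need to match cases *internally* first,
under their own data-protection rules. `casematch` implements that
engine as a stand-alone R package: a persistent **watch list** of cases
(candidate variants + [HPO](https://hpo.jax.org/) phenotype terms) that
screens every new submission against all previous ones and reports
matches back to *both* parties — a give-and-take design in which the
watch list grows with every use.

## What the engine does

Each submission (VCF, genomic HGVS strings, or generic records, plus at
least one HPO term and a declared genome assembly) runs through a fixed
pipeline:

1. **validate** — structural sanity check; per-record failures go to a
   processing trace, not to an exception;
2. **extract & left-normalize** — all variants reduced to their
   left-most, minimal VCF-style representation against the reference;
3. **convert** — coordinates lifted to the internal assembly via
   pluggable mapping providers;
4. **annotate** — gene, transcript region, codon ordinal and consequence
   (standard genetic code) from local GFF3 gene models; impact classes
   HIGH / MODERATE / LOW / MODIFIER;
5. **beacon check** — yes/no presence in a local known-variant store
   (flags "already publicized", never excludes);
6. **filter** — MAF ≤ threshold, impact ≥ threshold, optional
   protein-coding / canonical-transcript gates;
7. **match & report** — the two-dimensional matching below, pruned to a
   configurable top-N (default 5).

### The matching model

Candidate pairs are ranked **category first** on a four-level genomic
proximity scale:

| rank | category | meaning |
|------|---------------|----------------------------------------|
| 1 | IDENTICAL | same chrom, pos, ref, alt |
| 2 | SAME_POSITION | same position, different allele |
| 3 | SAME_CODON | same codon ordinal on a shared transcript |
| 4 | SAME_GENE | overlapping filter-passing gene sets |

and **phenotype similarity second**. Term similarity is edge-based: with
*P(c, r)* the set of all distinct paths (as node sets) from term *c* to
the ontology root *r*,

```
sim(c, c') = max over p ∈ P(c,r), p' ∈ P'(c',r) of |p ∩ p'| / |p ∪ p'|
```

so deep (precise) annotations are rewarded: on a chain, a parent–child
pair at depth 4 scores 4/5 while the same relation near the root scores
only 1/2. Case profiles *d*, *d'* are compared by the symmetrised
best-match average

```
sim(d, d') = 1/(2|d|) Σ_{c∈d} max_{c'∈d'} sim(c,c')
           + 1/(2|d'|) Σ_{c'∈d'} max_{c∈d} sim(c,c')
```

All root paths are pre-computed once per ontology release into a path
cache (JSON on disk, set operations in memory).

## Worked example

```r
library(casematch)

# a fully synthetic deployment
onto   <- generate_mini_ontology(depth = 4, branching = 2,
                                 multi_parent_fraction = 0.2, seed = 1)
ont    <- parse_obo(onto$obo)
gen    <- generate_toy_genome(n_genes = 4, chrom_length = 6000, seed = 1)
genome <- read_genome_fasta(gen$fasta, gen$assembly)
models <- read_gff3(gen$gff3)
wl     <- watchlist(ont, genome, models)

# two labs submit the same candidate variant with related phenotypes
sub1 <- list(owner = "lab_A", assembly = "toy1",
             variants = list(list(chrom = "chrT1", pos = 255,
                                  ref = "C", alt = "A")),
             hpo_terms = list("TT:0000016"))
sub2 <- list(owner = "lab_B", assembly = "toy1",
             hgvs = list("chrT1:g.255C>A"),
             hpo_terms = list("TT:0000016", "TT:0000017"))

r1 <- submit_case(wl, sub1)
print(r1$case)
#> Case CASE-000001 ( lab_A ) - PROCESSED : 1 variant(s), 1 phenotype term(s)

r2 <- submit_case(wl, sub2)
print(r2$reports[[1]])
#> Match report for lab_B on case CASE-000002 - 1 match(es)
#> rank  category  similarity  query_variant  hit_variant  hit_case     owner  same_owner
#> 1     IDENTICAL 0.916667    T1:255:C>A     T1:255:C>A   CASE-000001  lab_A  false

case_status(wl, r1$case$case_id)$variants
#>      variant passed_filters beacon_hit match_count
#> 1 T1:255:C>A           TRUE      FALSE           1
```

lab_B's report shows an `IDENTICAL` hit on lab_A's case; the phenotype
similarity 0.9167 reflects one shared term plus one extra sibling term
in lab_B's profile. lab_A receives the mirror-image report (give and
take), and the per-variant match counter on the stored case increments.

## Command line

A thin wrapper is installed as `exec/casematch`:

```sh
casematch fixtures --dir=demo --seed=1     # generate a demo deployment
cd demo
casematch init    --config=config.yaml    # build store + path cache
casematch submit  --config=config.yaml submission01.json
casematch submit  --config=config.yaml submission02.json   # reports a match
casematch status  --config=config.yaml CASE-000001
casematch retract --config=config.yaml CASE-000002
casematch export  --config=config.yaml dump   # JSON-lines + VCF
```

Exit codes are stable: 0 success, 2 bad config/input, 3 submission
FAILED, 4 unknown case.

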