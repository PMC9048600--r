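# acealign

Ontology alignment for ecology and biodiversity vocabularies with an
adaptive compact evolutionary algorithm.

Ecology and biodiversity knowledge is spread over independently developed
ontologies (ENVO, SWEET, PTO, FLOPO, AGROVOC, ...) that describe
overlapping domains with different terminology: *Tectonic movement* in one
vocabulary is *Continental drift* in another, *Inflorescence absent*
appears elsewhere as *Inflorescenceless*. Integrating such resources
requires an **alignment**: a set of correspondences `(e1, e2, =, conf)`
between entities of the two class hierarchies, at most one per entity
(single cardinality). `acealign` finds such alignments by direct search
over the space of 0–1 *aligning matrices* and is aimed at anyone who needs
to match mid-sized class hierarchies reproducibly, without training data or
a reference alignment.

## The model

A candidate alignment between ontologies `O1` and `O2` is encoded as a 0–1
matrix `M` of shape `|O1| × |O2|`; `M[i, j] = 1` maps the i-th source
entity to the j-th target entity. Because reference alignments are rarely
available, candidates are scored with reference-free metrics:

- `recall′(A) = |A| / min(|O1|, |O2|)` — normalized alignment size
  (completeness proxy),
- `precision′(A) = mean(conf)` — average correspondence confidence
  (correctness proxy),
- `f′(A) = 2 · precision′ · recall′ / (precision′ + recall′)` — their
  harmonic mean, the objective `f(M)` the search maximizes.

Confidences come from a hybrid lexical similarity: labels are stripped of
digits, punctuation and stop-words, split (including camel-case
boundaries), stemmed with a fixed Porter stemmer, and deduplicated; two
words score 1 if a thesaurus lists them as synonyms and their character
bigram Dice coefficient otherwise; two token sets are compared by symmetric
best-match averaging.

The search itself is a **compact evolutionary algorithm**: the population
is summarized by one or more *probability matrices* (PMs) of Bernoulli
parameters. Each generation samples two individuals per PM, recombines
them by uniform crossover, repairs the offspring to single cardinality,
lets it compete with the PM's elite, and moves the PM a small step
(default 0.01) toward the winner. Two problem-specific mechanisms make the
search practical on sparse, large matrices:

- **anchor-based semantic pruning** — near-certain correspondences
  (confidence ≥ 0.95) are *positive anchors*; any candidate that maps an
  ancestor of an anchored concept to a descendant of its partner (a
  "crisscross" over the subsumption hierarchies) is contradictory and its
  cell is pinned to 0; very poor elite correspondences (*negative anchors*,
  confidence < 0.2) are zeroed and decay the probability of their
  hierarchical neighborhood;
- **adaptive PM maintenance** — PMs that converge onto the same region are
  deduplicated, and after 60 stagnant generations a fresh PM is synthesized
  to point away from the existing ones, restarting exploration without
  discarding the incumbent elites.

## Worked example

```r
library(acealign)
th <- fixture_thesaurus()

# a 12-concept hierarchy and a perturbed copy with a known reference
fx <- generate_fixture_pair(fixture_spec(n_concepts = 12, seed = 7))
head(fx$o2$entities$name, 2)
#> [1] "Seed reproduction"        "Biomassic marine mineral"

res <- acea_run(fx$o1, fx$o2,
                config = acea_config(max_gen = 500, seed = 1),
                thesaurus = th)
res$alignment
#> <alignment synthetic-source -> synthetic-target: 10 correspondence(s)>
#>      e1   e2 rel conf
#> 1  s002 t001   =    1
#> 2  s004 t002   =    1
#> ...
evaluate_against_reference(res$alignment, fx$reference)
#> $precision
#> [1] 1
#> $recall
#> [1] 1
#> $f_measure
#> [1] 1
```

The 12-concept target kept 10 concepts after deletion; the engine recovers
all 10 reference pairs (classical precision/recall/f-measure 1.0) despite
synonym swaps ("Biomassic" carries affix noise, other labels swap words or
gain stop-words). `res$trace` logs `generation, pm_count, best_fitness`
per generation; `res$fitness` is the reference-free objective `f′` of the
returned alignment.

Real ontology files work the same way through
`load_ontology("envo_subset.owl")` (OWL RDF/XML) or the plain
`id,label,parent` tabular dialect, and `align_ontologies()` wraps the whole
pipeline with file output (OAEI Alignment RDF + CSV + trace + run
metadata). From a shell:

```sh
exec/acea align --source o1.owl --target o2.owl --output alignment.rdf --seed 42
exec/acea evaluate --alignment alignment.rdf --reference reference.rdf
```

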