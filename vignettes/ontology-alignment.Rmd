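---
title: "Aligning ontologies with a compact evolutionary search: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning ontologies with a compact evolutionary search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acealign)
```

# The optimization model

`acealign` treats ontology matching as discrete optimization over 0–1
aligning matrices. Given two ontologies with `|O1|` and `|O2|` alignable
entities, a candidate solution is a matrix `M` whose 1-cells name the
mapped entity pairs. The objective is the reference-free f-measure
`f′`: the harmonic mean of

* `recall′ = |A| / min(|O1|, |O2|)`, the alignment size normalized by the
  largest possible 1:1 alignment (so `recall′ = 1` exactly at full cover;
  clamped to 1 in the unconstrained-cardinality mode where `|A|` can
  exceed the bound), and
* `precision′ = mean(conf)`, the mean confidence of the selected pairs.

Both are proxies: `recall′` rewards completeness without knowing which
pairs are truly correct, `precision′` rewards confident pairs without
knowing whether confident means right. Their harmonic mean is a workable
engine fitness precisely because the two pull in opposite directions —
adding a dubious pair raises `recall′` and lowers `precision′`. Empty
alignments score 0 on all three quantities; an empty ontology pair makes
`recall′` 0 by convention so the fitness stays total.

The classical reference-based precision/recall/f-measure
(`evaluate_against_reference()`) exist alongside for testing and
benchmarking; the engine never sees them.

# The hybrid similarity measure

Confidences come from label text alone. The pipeline
(`preprocess_name()`) is: strip digits and punctuation, split on
whitespace and lowercase-to-uppercase boundaries (ontology labels mix
`leafAlternatePlacement` with space-separated conventions; fused words
like *Inflorescenceless* stay single tokens), lowercase, drop stop-words,
stem, and deduplicate within the set — a token literally equal or
thesaurus-synonymous to an earlier token of the *same* set is dropped.
The deduplication is deliberately within-set only: removing words shared
*across* the two sets would drive the similarity of identical labels to
zero instead of one.

Word pairs score 1 when the thesaurus lists them as synonyms (the
thesaurus is reflexive and symmetric, and its entries are stemmed on load
so lookups happen in the same token space), otherwise the Dice
coefficient over character bigram multisets. Bigrams (`n = 2`) are the
conventional order for short technical vocabulary and are configurable;
words shorter than `n` contribute themselves as a single gram so that
one-letter tokens still compare. Token sets are aggregated by symmetric
best-match averaging: each word is credited with its best counterpart on
the other side and the two directional sums are divided by the total word
count. Conventions for degenerate sets: two empty sets score 1 only if
the raw labels were equal; one-sided empty scores 0.

No external lexical resource is required: the bundled fixture thesaurus
and stop-word list are static files versioned with the package, so
similarity values can never drift with a third-party database. A
WordNet-scale resource can be supplied through `read_thesaurus()` in the
same two-column format. Stemming uses a single fixed implementation of
the classic Porter algorithm; no lemmatization resource is bundled, so
stemming alone normalizes morphology (the pipeline was designed so a
lemmatizer could be inserted before the stemmer without changing any
interface).

# Anchor-based semantic reasoning

Concept hierarchies constrain which correspondences can coexist. If
`(a1, b1)` is a near-certain *positive anchor* and `a2` subsumes `a1`
while `b3` is subsumed by `b1`, then mapping `a2` to `b3` would invert
the subsumption relation across the pair — a crisscross contradiction.
`contradicts()` implements exactly this rule with strict transitive
ancestors/descendants: siblings and the anchor itself never contradict,
matching the narrowest reading of the motivating configuration
(`fig2_fixture()`), and the relation is symmetric in its two arguments.

Positive anchors are pairs at confidence ≥ `pa_threshold` (default 0.95
— "high confidence" made concrete; 1:1-filtered greedily by confidence).
The pruning mask zeroes every cell contradicting at least one anchor and
is applied to every probability matrix and sampled individual, shrinking
the effective search space before evolution starts. Negative anchors are
elite correspondences below `na_threshold` (default 0.2): their
probability cell is zeroed, and neighbor correspondences within hierarchy
radius 1 ("both entities within shortest-path distance 1") that do
**not** contradict the negative anchor are decayed by one step. Of the
two conceivable decay targets — the neighbors consistent with the bad
mapping or the ones contradicting it — the package weakens the
consistent ones: correspondences *in line with* a negative anchor
inherit its implausibility, whereas a pair that contradicts a wrong
mapping is, if anything, evidence for the alternative.

# The compact evolutionary engine

A probability matrix (PM) holds per-cell Bernoulli parameters and
replaces an explicit population. Per generation and per PM the engine:
samples two individuals (row-major draw order, fixed so runs are
bit-reproducible per seed), recombines them by uniform crossover, masks
and repairs the offspring, competes it against the PM's elite (ties keep
the incumbent, so elites only improve strictly), steps the PM by ±`step`
toward the elite with clamping to `[0, 1]`, and applies negative-anchor
decay. Fresh PMs start at 0.5 on all admissible cells — maximum
uncertainty, which also spreads sampled 1-cells evenly over the sparse
matrix. Fitness evaluations are memoized by the 1-cell pattern of the
matrix (capped at 20k entries), since converged PMs resample the same few
individuals.

Cardinality is enforced during evolution (default `"1:1"`): sampled
offspring are repaired greedily, visiting 1-cells in descending
confidence with ties broken by row then column index and keeping a cell
only when its row and column are free. Greedy repair rather than optimal
assignment is a deliberate choice: it is deterministic, cheap, and
doubles as the confidence-ranked extraction step. An
`"unconstrained"` mode skips repair for experimentation.

Adaptive maintenance operates on the PM list after each generation:

* **overlap removal** — two PMs closer than the overlap threshold explore
  the same region; the one with the worse elite is removed (never below
  one PM). A raw *sum* of absolute element differences below 0.5 is an
  implausibly strict criterion for large matrices, where a single cell
  pair can exceed it; the default is therefore the equivalent *mean*
  formulation (`0.5 / (|O1|·|O2|)`), with the literal sum mode available
  via `overlap_mode = "sum"`.
* **stagnation-triggered synthesis** — when no elite in any PM has been
  replaced for `delta` consecutive generations (bitwise elite equality;
  the counter resets on any replacement or insertion), a new PM is
  synthesized from the cell-wise
  maximum `m` and minimum `n` over the existing PMs: unanimous 0/1 cells
  are kept; `m < 0.5` cells are pushed right of `m`
  (`m + u(1 − m)`, `u ~ U(0,1)`); `n > 0.5` cells are pushed left
  (`(1 − u) n`); straddling cells sit at 0.5. Cells not covered by any
  of these rules (e.g. `m = n = 0.5`) default to 0.5, the "middle"
  placement consistent with the straddling case. The new PM receives a
  freshly sampled elite and the engine continues with one more search
  direction.

Each PM keeps its own elite and a global best is tracked separately;
per-PM elites are the only organization under which overlap removal
("the PM with the worse elite") is well-defined. Both generated parents
come from the same PM before crossover — kept deliberately even though
it is statistically close to a single sample.

Defaults: `max_gen = 3000`,
`step = 0.01` (the learning rate; larger steps converge fast but
prematurely, smaller ones waste generations), `delta = 60`,
`pm_num_init = 2`. `cea_config()` is the documented reduction to the
plain compact EA — one PM, no mask, no decay, no maintenance — used as
the benchmark baseline.

# The synthetic benchmark generator

`generate_fixture_pair()` emulates the heterogeneity observed between
real ecology/biodiversity ontologies: matched concepts whose labels
differ by synonym substitution (*forest* vs *woodland*), token
reordering, affix noise (*Biomassic*), and inserted stop-words, plus
concepts absent from one side. The source is a random tree (bounded
branching) with unique multi-word labels from a bundled 86-word
vocabulary; the target is a copy with per-label perturbations, a deleted
fraction of concepts (children re-attach to their nearest surviving
ancestor; the root survives), and permuted entity order. The reference
alignment is the surviving identity pairs. Everything is deterministic
given the spec's seed.

The default spec **is** the package's standard study condition: 40
source concepts, branching 3, synonym/shuffle/stop-word rates 0.3, affix
rate 0.2, deletion rate 0.1 — moderate perturbation with 10% deletion,
the regime in which lexical similarity is informative but imperfect and
reasoning has room to help. These values were fixed when the generator
was written and are not tuned per experiment.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: multi-parent (DAG-shaped) target hierarchies
beyond what deletion induces, multi-label entities and annotation text,
systematic vocabulary mismatch (every target word is either a vocabulary
word, a listed synonym, or an affixed variant, so the bundled thesaurus
has perfect coverage of the synonym operator by construction), n:m
correspondences, and the sheer scale of OAEI-track ontologies (tens of
thousands of entities). Results on the synthetic condition demonstrate
correct mechanics and the adaptive variant's advantage over its
reduction, not field performance on arbitrary ontology pairs.

# Numerical choices and degenerate inputs

* Entity order is file document order, so matrix indices are stable
  across reloads.
* Sampling uses strict `u < p`, making `p = 0` and `p = 1` exact
  boundaries.
* Greedy 1:1 repair ties break by row-then-column index; anchor 1:1
  filtering reuses the same rule.
* Empty ontologies: `acea_run()` warns and returns the empty alignment;
  `max_gen = 0` returns the best initial elite with a one-row trace.
* Seeds: every stochastic component (fixture generation, engine run)
  derives from a single integer seed and restores the caller's RNG
  state.

Problem sizes in the shipped tests were chosen to exercise every
mechanism at desk scale: exhaustive formula sweeps over a 6-word power
set plus randomized 12-word coverage, 20×20 fuzzed engine runs over 200
generations, and the 40-concept benchmark over 5 seeds at 1500
generations for the recovery and baseline-comparison checks.

# Known limitations

* When two source concepts have synonym-equivalent labels, their target
  copies are lexically indistinguishable (confidence 1 both ways); anchor
  selection then crosses the pairs by index tie-break, and pruning
  against the crossed anchor can lock a small number of correct cells out
  of the search. On unperturbed 40-concept copies this occasionally costs
  ~2 of 40 pairs.
* The plain compact-EA reduction can stall permanently once its single
  PM saturates around an imperfect elite — the failure mode the adaptive
  maintenance exists to fix; benchmark expectations for the baseline
  account for it.
* Only equivalence correspondences and 1:1 (or unconstrained)
  cardinality are supported; subsumption mappings and n:m matching are
  out of scope.
* OWL input is limited to named classes, `rdfs:label` and
  `rdfs:subClassOf` from RDF/XML (plus the tabular fixture dialect); no
  imports resolution, OWL-DL reasoning, Turtle parsing, or instance
  data.
* The similarity measure is purely lexical-plus-thesaurus; hierarchy
  structure enters only through reasoning, not through the confidence
  values themselves.
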