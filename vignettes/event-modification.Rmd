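---
title: "Detecting event modification with scope features and maximum entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting event modification with scope features and maximum entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventmod)
```

## The task and the model

Biomedical event extraction produces *events* — typed n-tuples anchored on
a trigger word, with role-labelled protein or event arguments — in the
BioNLP standoff convention (`.a1`/`.a2` files indexing into the document
text by 0-based, end-exclusive character offsets).  A third layer of
annotation marks *modification*: an `M` line asserting that an event is
**negated** or **speculated**.  `eventmod` treats modification detection as
two independent binary classification problems over events whose triggers
are already known; trigger detection itself is upstream and out of scope.

The discriminative signal comes from two places:

1. **Scope features over RMRS analyses.**  Robust Minimal Recursion
   Semantics represents a sentence as a flat bag of elementary
   predications (EPs), each with a scope label, a predicate name
   (`_require_v_1`), a character span, an intrinsic ARG0 variable and
   role-labelled arguments.  Scope is underspecified through *qeq*
   constraints (a handle outscopes a label modulo quantifiers) and *in-g*
   constraints (two labels may be treated as equal).  We need only the
   induced partial order: EP *A* *immediately outscopes* EP *B* if a
   handle argument of *A* qeq-outscopes *B*'s label after in-g
   propagation, and *outscopes* is the transitive closure.  Whether a
   negator, modal, or hedging verb takes the event trigger in its scope —
   possibly at a long surface distance — is precisely the information a
   flat window cannot see.

2. **Bag-of-words windows.**  Parsers have imperfect coverage, so a
   shallow, 100%-coverage complement is kept: lowercased token indicators
   in a window around the trigger token, never crossing a sentence
   boundary.  Defaults are three tokens each side for speculation
   (`W+3-3`) and four left / three right for negation (`W+3-4`), the
   window sizes that proved optimal for each subtask; both are
   configurable from 0 upward.

Each event becomes one instance per subtask: the union of scope features
(combined across parser sources) and window features, fed to a binary
maximum-entropy model.  The two subtasks never share a model — negation
cues and hedging cues are largely disjoint vocabularies — and an instance
with no active features (unparsed sentence, windows off) receives the
bias-only score, i.e. the empirical class prior, which for the low
modification rates of this domain means "unmodified".

## The feature sets

Negation, over the scope graph `g` and trigger EPs `t`:

* `NegOutscope2` — an EP from a small lexicon of semantically negative
  predicates outscopes a trigger EP.
* `NegConjIndex` — a negative conjunction (`_nor_c`, `_not_c`,
  `_but+not_c`) holds a trigger's ARG0 in one of its negated-daughter
  roles.  Conjunctions name their conjuncts through index roles rather
  than `ARG`*n*, and which roles count as negated is configured per
  conjunction: the right conjunct for *not* / *but not*, both for *nor*.
* `Arg0NegOutscopeeSA` — some EP shares the trigger's ARG0 in an argument
  slot and is itself outscoped by a negative predicate.  This is the
  nominal-trigger case ("proliferated *without* phosphorylation of ..."),
  where the negator dominates the embedding preposition or noun rather
  than the trigger itself.  We read the defining condition as attaching
  the outscoping requirement to the argument-sharing EP, not the trigger,
  since that is the configuration the feature exists to catch.
* `TrigPredProps` — the trigger EP's predicate name and POS letter.

Speculation:

* `SpecVObj2`+WN — a speculative verb's ARG2 (deep object) is the
  trigger's ARG0.  The verb lexicon is a seed set plus WordNet *sisters*
  (lemmas sharing a direct hypernym); a sister match additionally emits a
  feature naming its seed, so evidence pools across the cluster.
* `ModalOutscope` — a modal predicate outscopes a trigger EP.
* `AnalysisSA` — the trigger's ARG0 is an argument of an EP with lemma
  *analysis* (noun): "analysis of X" is a strong hedging construction in
  this genre.  Any argument role qualifies except the analysis EP's own
  ARG0; the source material does not pin this down, and excluding ARG0
  merely avoids self-identity.
* `ModAdj` — an adjectival/adverbial EP's ARG1 is the trigger's ARG0
  ("*putative* binding site").

Every rule emits a general feature and a predicate-specific one
(`NegOutscope2=_never_a`), letting the learner both generalize and
memorize.  For `TrigPredProps` only the specific and POS variants are
meaningful, so no bare general indicator is emitted.

### Lexicons

The shipped lexicons (`inst/lexicons/*.lex`) are explicit reconstructions:
only a few members of the original negative-predicate and seed-verb sets
are attested, so the files complete them with the predicates a precision
grammar emits for the common negators, hedging verbs and modals, and say
so in their comments.  Nothing is hard-coded: `read_lexicons()` accepts
any directory in the same one-entry-per-line format, and predicate
matching ignores the trailing sense field (`_require_v_1` matches
`_require_v`) because grammars attach senses inconsistently; an exact mode
exists for controlled experiments.  Whether `neg_rel` (the grammar's
predicate for *not*) belongs in the negative-predicate set is not
attested either; we include it, since the canonical worked example centres
on it.

## Combining parser sources

A sentence may have zero, one or two analyses (e.g. a precision grammar
and a statistical parser).  Three strategies:

* `fb` (fallback): features from the first available source in a priority
  list — trust the deep grammar where it parses, fall back elsewhere;
* `cb` (union): pool features from all available sources;
* `cb_tagged`: the union plus a source-prefixed copy of every feature
  (`ERG:NegOutscope2`), letting the learner weight sources differently.
  Untagged copies are retained alongside tagged ones, so restricting
  `cb_tagged` output to untagged names recovers `cb` exactly — dropping
  them would make the two strategies incomparable feature spaces.

`fb` output is always a subset of `cb` output for the same bundle; both
are deterministic.

## Numerical and representational choices

* **Closure computation.**  Label aliasing uses union–find with path
  compression; EP-level reachability uses boolean matrix repeated
  squaring.  Analyses are sentence-sized (tens of EPs), so worst-case
  cubic cost is irrelevant.  Cyclic constraint sets — malformed parser
  output — are tolerated: closure is plain reachability and no error is
  raised.  The test suite checks both against independent BFS/DFS oracles
  on 1,000 random instances.
* **Immediate outscoping is qeq-only** by default, exactly as defined; an
  opt-in flag (`direct_label_edges`) also treats a handle argument equal
  to an EP label as an edge, for RMRS producers that emit direct
  equalities.
* **Trigger EPs** are those whose span *contains* the trigger span
  (equality allowed); an overlap mode exists for noisy tokenisation.
  Covert EPs (no span, e.g. default quantifiers) are never trigger EPs.
* **Labels and handles are opaque strings**; numeric order is never
  consulted, since grammars assign indices arbitrarily.  The top handle is
  stored but unused — no feature refers to it.
* **MaxEnt fit.**  The L2-penalized conditional log-likelihood (Gaussian
  prior variance `sigma2 = 1`, intercept unpenalized) is maximized with
  BFGS and an analytic gradient at relative tolerance 1e-14, iteration cap
  200.  The objective is strictly convex, so the fit is deterministic and
  permutation-invariant; the original toolkit's settings are not
  documented anywhere, so these defaults are explicit, configurable
  stand-ins.  Features are presence indicators, not counts, matching
  their categorical nature.  Decision threshold 0.5, untuned.
* **Tokenizer.**  A regex tokenizer (alphanumeric runs with internal
  `-`/`+`, single punctuation marks) stands in for an external
  domain tokenizer; pre-tokenized sidecar files are accepted wherever a
  tokenized sentence is, and all downstream code depends only on
  offset-consistent spans.  Window features lowercase and de-duplicate
  (set semantics); the trigger's own token is excluded from the bag and
  emitted as `BOWTRIG` instead.
* **Scoring.**  A prediction is a true positive iff a gold record of the
  same type exists with a matching theme event, matched greedily
  one-to-one in document order.  Event matching is by id in the normal
  regime (predictions are made over a given event set) with a structural
  mode (type + trigger span + role/argument spans, recursive) for
  cross-system comparison.  Zero denominators yield 0 by convention, so
  reports are always defined.

## What the synthetic generator does and does not show

`generate_corpus()` realizes template sentences with genuine character
offsets and builds the matching standoff and RMRS layers, one event per
sentence.  Nine templates cover the eight feature families plus an
unmodified baseline; the negation-scope template routes its qeq through an
in-g constraint so that constraint propagation is exercised end to end.
Defaults encode the study conditions: per-event modification rates of 6%
(negation) and 5% (speculation), matching the modest rates of shared-task
abstracts; per-parser sentence coverage of 76% each with a joint 93%
(17% of sentences have only the shallow parse, 7% none); and a shallow
`RASP` analysis derived from the `ERG` one by dropping half the covert
quantifiers and 30% of qeqs, so fallback and union strategies are
empirically distinguishable.  A `noise` parameter flips gold labels
against their template (cue without label and vice versa), and the
manifest records every flip for test assertions.

What passing on this data shows: offsets, constraint propagation, feature
logic, combination contracts, learning and scoring all compose correctly,
and recall of scope-only classifiers is capped by parse coverage.  What it
cannot show: performance on real abstracts, where cues are rarer, noisier
and lexically diverse, parses are wrong rather than merely missing, and
triggers come from an upstream system with its own errors.  Headline
scores on generated corpora are therefore properties of the generator, not
estimates of corpus performance.

Problem sizes in the shipped tests and acceptance script — 200 training /
50 test documents (roughly 1,100 / 280 events) and 1,000 random analyses
for the oracle checks — were chosen as the smallest sizes at which class
priors, coverage fractions and weight estimates are stable.

## Known limitations

* No scope *resolution*: the package never enumerates fully scoped
  readings, only the outscoping partial order the features need.
* No parser drivers: analyses arrive as files (JSON or line dialect) or
  from the generator.  Discontinuous triggers are untested territory;
  fixtures use contiguous triggers only.
* Secondary event arguments (`Site` etc.) in `.a2` files are parsed and
  retained but ignored by all feature code.
* The shared-task dialect is the 2009 one; later equivalence /
  normalization line types are unsupported.
* WordNet sister expansion happens offline into the lexicon file; the
  pipeline never queries a lexical database at run time, trading recall of
  novel hedging verbs for determinism.
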