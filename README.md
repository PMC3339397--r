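# eventmod

Detects **negation** and **speculation** modification of biomedical event
mentions.  Event extraction systems for the molecular-biology literature
first find *events* — n-tuples anchored on a trigger word, e.g.
`Phosphorylation(Theme: TRADD)` for "... phosphorylation of TRADD ..." —
and then must decide whether each event is asserted, negated ("*no*
phosphorylation of TRADD occurred") or merely hedged ("we *investigated*
the phosphorylation of TRADD").  Getting this right is what separates a
retrieval system that can find "binding of A and B" from one that knows the
paper says binding did *not* happen.

`eventmod` implements a machine-learning pipeline for this modification
task over the BioNLP 2009 Shared Task standoff format, for researchers in
biomedical text mining who already have events (gold or predicted) and
per-sentence semantic analyses:

* **Standoff I/O** — `.txt` + `.a1` (proteins) + `.a2` (triggers, events,
  `M`-line modifications), with strict offset validation and a bit-exact
  `M`-line writer.
* **RMRS scope algebra** — Robust Minimal Recursion Semantics analyses as a
  bag of elementary predications (EPs) with qeq and in-g handle
  constraints.  EP *A* *immediately outscopes* *B* when a handle argument
  of *A* qeq-outscopes *B*'s label (after propagating label equivalences);
  `outscopes` is the transitive closure, and the *shared-argument* relation
  holds when one instance variable fills argument slots of two EPs.
* **Feature extraction** — the scope-based negation features
  (`NegOutscope2`, `NegConjIndex`, `Arg0NegOutscopeeSA`, `TrigPredProps`)
  and speculation features (`SpecVObj2`+WordNet sisters, `ModalOutscope`,
  `AnalysisSA`, `ModAdj`), each emitting a general and a
  predicate-specific indicator; plus bag-of-words context windows around
  the trigger token (`W+3-3` for speculation, `W+3-4` for negation by
  default), clamped at sentence boundaries.
* **Multi-parser combination** — fallback (`fb`: first available source by
  priority), union (`cb`), and source-tagged union (`cb_tagged`) of feature
  sets from several parsers' analyses of the same sentence.
* **Classification** — one maximum-entropy (L2-penalized logistic) model
  per subtask over binary features; an event in an unparsed sentence (with
  bag-of-words off) has an empty vector and receives the class-prior
  decision.
* **Scoring** — modification-level recall / precision / F1, per type and
  overall, with by-id or structural event matching.
* **Synthetic fixtures** — a generator producing offset-consistent corpora
  (text, standoff, per-parser RMRS, gold labels) for every phenomenon the
  features target, with configurable parser coverage, cue/label noise, and
  byte-reproducible seeding.  Parsing itself is out of scope: analyses come
  from files or from this generator.

## Worked example

The scope algebra on a classic negated sentence, *"Thus NF-kappa B
activation is not required for neuroblastoma cell differentiation."*
(`encode_figure1()` ships it as a permanent fixture):

```r
library(eventmod)
fig <- encode_figure1()
g <- build_scope_graph(fig$rmrs)

outscopes(g, "l3", "l20")      # scopal adverb over the verb, transitively
#> [1] TRUE

eff <- effective_qeqs(fig$rmrs)
eff[eff[, 1] == "h27", ]       # qeq inferred through "l28 in-g l104"
#>      [,1]  [,2]
#> [1,] "h27" "l28"
#> [2,] "h27" "l104"

shared_argument(fig$rmrs, "l28", "l104", roles_a = "ARG1", roles_b = "ARG0")
#> [1] TRUE                     # both slots filled by x23

lex <- default_lexicons()
tr <- trigger_eps(fig$rmrs, fig$trigger)
negation_features(fig$rmrs, g, tr, lex)
#> [1] "TrigPredProps=_differentiation_n" "TrigPredProps.pos=n"
```

(The negator here outscopes *require*, not the *differentiation* trigger,
so `NegOutscope2` correctly stays silent and only the trigger-property
features fire.)

End to end on generated corpora, with the default two-parser setting —
each parser covers 76% of sentences, jointly 93%:

```r
train <- generate_corpus(generator_config(n_docs = 100, seed = 1))
test  <- generate_corpus(generator_config(n_docs = 25, seed = 2))
train
#> <synthetic corpus: 100 docs, 532 events, 75 gold modifications>

res <- run_pipeline(train, test, quiet = TRUE)
res$negation$score
#> type         tp  fp  fn  R      P      F
#> Negation     9   0   2   81.8   100.0  90.0
#> Speculation  0   0   5   0.0    0.0    0.0
#> overall      9   0   7   56.2   100.0  72.0
```

Each subtask's classifier is scored against the full gold modification set,
so the negation run lists the gold speculation records among its false
negatives; read the row matching the subtask.  The two missed negations sit
in the ~7% of sentences with no analysis, where only the bag-of-words
window is available — exactly the coverage ceiling the pipeline is designed
around.

A thin command-line wrapper over the same functions is installed at
`inst/cli/eventmod.R` (`gen-fixtures` / `train` / `predict` / `evaluate`).

## Lexicons

The feature extractors consult plain-text lexicons under `inst/lexicons/`
(negative predicates, negative conjunctions with their negated-daughter
roles, speculative seed verbs with offline-expanded WordNet sisters, modal
predicates).  The shipped files are documented reconstructions and can be
replaced wholesale via `read_lexicons(dir)`.
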