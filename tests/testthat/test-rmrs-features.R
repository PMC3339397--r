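lex <- test_lexicons()

test_that("pos_of follows the _lemma_pos[_sense] convention", {
  expect_identical(pos_of("_differentiation_n_1"), "n")
  expect_identical(pos_of("_require_v_1"), "v")
  expect_identical(pos_of("_never_a"), "a")
  expect_identical(pos_of("_no_q"), "q")
  expect_identical(pos_of("_but+not_c"), "c")
  expect_identical(pos_of("_without_p"), "p")
  expect_identical(pos_of("_can_v_modal"), "v")
  expect_identical(pos_of("compound_rel"), NA_character_)
  expect_identical(pos_of("neg_rel"), NA_character_)
})

test_that("predicate matching ignores the sense field unless exact", {
  expect_identical(normalize_pred("_require_v_1"), "_require_v")
  expect_identical(normalize_pred("_differentiation_n_of"),
                   "_differentiation_n")
  expect_identical(normalize_pred("neg_rel"), "neg_rel")
  fx <- feature_fixture(
    list(ep("l2", "_never_a_1", 0L, 5L, "e2", c(ARG1 = "h3"))),
    qeqs = list(c("h3", "l1")))
  expect_true("NegOutscope2=_never_a" %in%
                negation_features(fx$r, fx$g, fx$triggers, lex))
  expect_false("NegOutscope2" %in%
                 negation_features(fx$r, fx$g, fx$triggers, lex,
                                   exact = TRUE))
})

test_that("NegOutscope2 fires on an outscoping negator and not otherwise", {
  fx <- feature_fixture(
    list(ep("l2", "neg_rel", 0L, 3L, "e2", c(ARG1 = "h3"))),
    qeqs = list(c("h3", "l1")))
  feats <- negation_features(fx$r, fx$g, fx$triggers, lex)
  expect_true(all(c("NegOutscope2", "NegOutscope2=neg_rel",
                    "TrigPredProps=_phosphorylation_n",
                    "TrigPredProps.pos=n") %in% feats))
  # distractor: the negator's handle leads elsewhere
  dx <- feature_fixture(
    list(ep("l2", "neg_rel", 0L, 3L, "e2", c(ARG1 = "h3")),
         ep("l4", "_occur_v_1", 30L, 35L, "e4")),
    qeqs = list(c("h3", "l4")))
  dfeats <- negation_features(dx$r, dx$g, dx$triggers, lex)
  expect_false(any(grepl("^NegOutscope2", dfeats)))
})

test_that("NegOutscope2 reaches the trigger through in-g propagation", {
  fx <- feature_fixture(
    list(ep("l2", "neg_rel", 0L, 3L, "e2", c(ARG1 = "h3")),
         ep("l5", "_of_p", 26L, 28L, "e5", c(ARG1 = "x1"))),
    qeqs = list(c("h3", "l5")),
    ings = list(c("l5", "l1")))
  expect_true("NegOutscope2" %in%
                negation_features(fx$r, fx$g, fx$triggers, lex))
})

test_that("NegConjIndex inspects the configured daughter roles", {
  fx <- feature_fixture(
    list(ep("l2", "_not_c", 0L, 3L, "x2",
            c(`L-INDEX` = "x9", `R-INDEX` = "x1"))))
  feats <- negation_features(fx$r, fx$g, fx$triggers, lex)
  expect_true(all(c("NegConjIndex", "NegConjIndex=_not_c") %in% feats))
  # distractor: the trigger is the non-negated left daughter of "not"
  dx <- feature_fixture(
    list(ep("l2", "_not_c", 0L, 3L, "x2",
            c(`L-INDEX` = "x1", `R-INDEX` = "x9"))))
  expect_false(any(grepl("^NegConjIndex",
                         negation_features(dx$r, dx$g, dx$triggers, lex))))
  # "nor" negates both daughters
  nx <- feature_fixture(
    list(ep("l2", "_nor_c", 0L, 3L, "x2",
            c(`L-INDEX` = "x1", `R-INDEX` = "x9"))))
  expect_true("NegConjIndex=_nor_c" %in%
                negation_features(nx$r, nx$g, nx$triggers, lex))
})

test_that("Arg0NegOutscopeeSA needs both sharing and negated dominance", {
  fx <- feature_fixture(
    list(ep("l2", "_without_p", 0L, 7L, "e2", c(ARG2 = "h3")),
         ep("l5", "_of_p", 26L, 28L, "e5", c(ARG1 = "x1"))),
    qeqs = list(c("h3", "l5")))
  feats <- negation_features(fx$r, fx$g, fx$triggers, lex)
  expect_true(all(c("Arg0NegOutscopeeSA",
                    "Arg0NegOutscopeeSA=_without_p") %in% feats))
  # the negator here outscopes the of-phrase, not the trigger itself
  expect_false("NegOutscope2" %in% feats)
  # distractor: sharing EP exists but is not outscoped by the negator
  dx <- feature_fixture(
    list(ep("l2", "_without_p", 0L, 7L, "e2"),
         ep("l5", "_of_p", 26L, 28L, "e5", c(ARG1 = "x1"))))
  expect_false(any(grepl("^Arg0NegOutscopeeSA",
                         negation_features(dx$r, dx$g, dx$triggers, lex))))
})

test_that("TrigPredProps reports trigger predicates and their POS", {
  fx <- feature_fixture()
  feats <- negation_features(fx$r, fx$g, fx$triggers, lex)
  expect_setequal(feats, c("TrigPredProps=_phosphorylation_n",
                           "TrigPredProps.pos=n"))
  expect_identical(negation_features(fx$r, fx$g, integer(), lex),
                   character())
})

test_that("SpecVObj2 requires the trigger ARG0 in object position", {
  fx <- feature_fixture(
    list(ep("l2", "_investigate_v_1", 0L, 9L, "e2",
            c(ARG1 = "x7", ARG2 = "x1"))))
  feats <- speculation_features(fx$r, fx$g, fx$triggers, lex)
  expect_true(all(c("SpecVObj2", "SpecVObj2=_investigate_v") %in% feats))
  expect_false(any(grepl("seed", feats)))
  # distractor: the trigger is the verb's subject
  dx <- feature_fixture(
    list(ep("l2", "_investigate_v_1", 0L, 9L, "e2",
            c(ARG1 = "x1", ARG2 = "x7"))))
  expect_false(any(grepl("^SpecVObj2",
                         speculation_features(dx$r, dx$g, dx$triggers, lex))))
})

test_that("a WordNet sister match adds the seed-verb feature", {
  fx <- feature_fixture(
    list(ep("l2", "_probe_v_1", 0L, 6L, "e2", c(ARG2 = "x1"))))
  feats <- speculation_features(fx$r, fx$g, fx$triggers, lex)
  expect_true(all(c("SpecVObj2", "SpecVObj2=_probe_v",
                    "SpecVObj2.seed=_investigate_v") %in% feats))
})

test_that("ModalOutscope fires only when the modal outscopes the trigger", {
  fx <- feature_fixture(
    list(ep("l2", "_may_v_modal", 0L, 3L, "e2", c(ARG1 = "h3"))),
    qeqs = list(c("h3", "l1")))
  feats <- speculation_features(fx$r, fx$g, fx$triggers, lex)
  expect_true(all(c("ModalOutscope", "ModalOutscope=_may_v") %in% feats))
  dx <- feature_fixture(
    list(ep("l2", "_may_v_modal", 0L, 3L, "e2", c(ARG1 = "h3")),
         ep("l4", "_occur_v_1", 30L, 35L, "e4")),
    qeqs = list(c("h3", "l4")))
  expect_false(any(grepl("^ModalOutscope",
                         speculation_features(dx$r, dx$g, dx$triggers, lex))))
})

test_that("AnalysisSA needs the trigger ARG0 as an analysis argument", {
  fx <- feature_fixture(
    list(ep("l2", "_analysis_n_1", 0L, 8L, "x4", c(ARG1 = "x1"))))
  feats <- speculation_features(fx$r, fx$g, fx$triggers, lex)
  expect_true("AnalysisSA" %in% feats)
  # distractor: an analysis EP with unrelated arguments
  dx <- feature_fixture(
    list(ep("l2", "_analysis_n_1", 0L, 8L, "x4", c(ARG1 = "x9"))))
  expect_false(any(grepl("^AnalysisSA",
                         speculation_features(dx$r, dx$g, dx$triggers, lex))))
})

test_that("ModAdj fires for adjectival modifiers of the trigger", {
  fx <- feature_fixture(
    list(ep("l2", "_putative_a_1", 0L, 8L, "e2", c(ARG1 = "x1"))))
  feats <- speculation_features(fx$r, fx$g, fx$triggers, lex)
  expect_true(all(c("ModAdj", "ModAdj=_putative_a") %in% feats))
  # distractors: a noun with ARG1 = trigger ARG0, and an adjective aimed
  # at another variable
  dx1 <- feature_fixture(
    list(ep("l2", "_kinase_n_1", 0L, 6L, "x4", c(ARG1 = "x1"))))
  expect_false(any(grepl("^ModAdj",
                         speculation_features(dx1$r, dx1$g, dx1$triggers, lex))))
  dx2 <- feature_fixture(
    list(ep("l2", "_putative_a_1", 0L, 8L, "e2", c(ARG1 = "x9"))))
  expect_false(any(grepl("^ModAdj",
                         speculation_features(dx2$r, dx2$g, dx2$triggers, lex))))
})

test_that("extractors are empty on the empty RMRS and monotone in lexicons", {
  empty <- rmrs()
  g <- build_scope_graph(empty)
  expect_identical(negation_features(empty, g, integer(), lex), character())
  expect_identical(speculation_features(empty, g, integer(), lex), character())

  fx <- feature_fixture(
    list(ep("l2", "_abolish_v_1", 0L, 7L, "e2", c(ARG1 = "h3"))),
    qeqs = list(c("h3", "l1")))
  before <- negation_features(fx$r, fx$g, fx$triggers, lex)
  bigger <- lex
  bigger$neg_preds <- c(bigger$neg_preds, "_abolish_v")
  after <- negation_features(fx$r, fx$g, fx$triggers, bigger)
  expect_true(all(before %in% after))
  expect_true("NegOutscope2=_abolish_v" %in% after)
})

test_that("every predicate-specific feature implies its general feature", {
  set.seed(45)
  for (rep in 1:30) {
    fx <- feature_fixture(
      list(ep("l2", sample(c("neg_rel", "_may_v_modal", "_investigate_v_1",
                             "_putative_a_1", "_not_c"), 1L),
              0L, 3L, "e2",
              c(ARG1 = "h3", ARG2 = "x1", `R-INDEX` = "x1")[
                sample(1:3, sample(1:3, 1L))])),
      qeqs = list(c("h3", "l1")))
    for (f in c(negation_features(fx$r, fx$g, fx$triggers, lex),
                speculation_features(fx$r, fx$g, fx$triggers, lex))) {
      if (grepl("=", f, fixed = TRUE) && !startsWith(f, "TrigPredProps")) {
        general <- sub("[.=].*$", "", f)
        expect_true(general %in%
                      c(negation_features(fx$r, fx$g, fx$triggers, lex),
                        speculation_features(fx$r, fx$g, fx$triggers, lex)),
                    info = f)
      }
    }
  }
})

test_that("features are invariant under label/variable renaming", {
  relabel <- function(r) {
    sub_map <- function(v) {
      chartr("0123456789", "5678901234", v)
    }
    eps <- lapply(r$eps, function(e) {
      ep(sub_map(e$label), e$pred, e$cfrom, e$cto, sub_map(e$arg0),
         stats::setNames(sub_map(e$args), names(e$args)))
    })
    q <- if (nrow(r$qeqs)) apply(r$qeqs, 2L, sub_map) else r$qeqs
    i <- if (nrow(r$ings)) apply(r$ings, 2L, sub_map) else r$ings
    if (is.null(dim(q))) q <- matrix(q, ncol = 2L)
    if (is.null(dim(i))) i <- matrix(i, ncol = 2L)
    rmrs(eps, q, i, r$sentence_span, r$source)
  }
  fx <- feature_fixture(
    list(ep("l2", "neg_rel", 0L, 3L, "e2", c(ARG1 = "h3")),
         ep("l5", "_of_p", 26L, 28L, "e5", c(ARG1 = "x1"))),
    qeqs = list(c("h3", "l5")),
    ings = list(c("l5", "l1")))
  r2 <- relabel(fx$r)
  g2 <- build_scope_graph(r2)
  tr2 <- trigger_eps(r2, list(start = 10L, end = 25L))
  expect_setequal(negation_features(fx$r, fx$g, fx$triggers, lex),
                  negation_features(r2, g2, tr2, lex))
})

test_that("lexicon files round-trip through the line format", {
  expect_s3_class(lex, "eventmod_lexicons")
  expect_true("neg_rel" %in% lex$neg_preds)
  expect_setequal(names(lex$neg_conjs), c("_nor_c", "_not_c", "_but+not_c"))
  expect_setequal(lex$neg_conjs[["_nor_c"]], c("L-INDEX", "R-INDEX"))
  expect_identical(unname(lex$spec_sisters[["_probe_v"]]), "_investigate_v")
  expect_true(all(normalize_pred(unname(lex$spec_sisters)) %in%
                    normalize_pred(lex$spec_seed_verbs)))
  expect_error(lexicons(neg_conjs = list(`_nor_c` = character())),
               "daughter")
  expect_error(lexicons(spec_seed_verbs = "_test_v",
                        spec_sisters = c(`_probe_v` = "_guess_v")),
               "_guess_v")
})
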