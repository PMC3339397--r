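lex <- test_lexicons()

test_that("generated corpora are valid, offset-consistent standoff", {
  cfg <- generator_config(n_docs = 8L, p_negation = 0.3, p_speculation = 0.3,
                          noise = 0.1, seed = 54L)
  corpus <- generate_corpus(cfg)
  for (doc_id in names(corpus$docs)) {
    doc <- corpus$docs[[doc_id]]
    # read_document already validated surfaces; check the analysis layer
    bundles <- corpus$analyses[[doc_id]]
    expect_identical(length(bundles), nrow(doc$sentences))
    for (s in seq_along(bundles)) {
      for (src in names(bundles[[s]])) {
        r <- bundles[[s]][[src]]
        if (is.null(r)) next
        expect_s3_class(r, "eventmod_rmrs")
        expect_identical(unname(r$sentence_span),
                         unname(doc$sentences[s, ]))
        for (e in r$eps) {
          if (is.na(e$cfrom)) next
          expect_gte(e$cfrom, r$sentence_span[[1]])
          expect_lte(e$cto, r$sentence_span[[2]])
        }
      }
    }
    # every trigger lies inside exactly one sentence
    for (tb in doc$triggers) {
      expect_silent(sentence_of(doc, tb$start, tb$end))
    }
  }
})

test_that("the same seed reproduces the corpus byte-for-byte", {
  cfg <- generator_config(n_docs = 4L, p_negation = 0.3, p_speculation = 0.3,
                          noise = 0.05, seed = 7L)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  d1 <- tempfile(); d2 <- tempfile()
  write_corpus(c1, d1); write_corpus(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     info = f)
  }
  cfg3 <- cfg; cfg3$seed <- 8L
  expect_false(identical(generate_corpus(cfg3), c1))
})

test_that("a degenerate all-negation config fires NegOutscope2 everywhere", {
  cfg <- generator_config(
    n_docs = 5L, p_negation = 1, p_speculation = 0,
    cue_mix = c(neg_scope = 1), coverage = c(ERG = 1, RASP = 1),
    coverage_union = 1, noise = 0, seed = 55L)
  corpus <- generate_corpus(cfg)
  for (doc_id in names(corpus$docs)) {
    doc <- corpus$docs[[doc_id]]
    mods <- vapply(doc$modifications, `[[`, "", "type")
    expect_identical(length(doc$modifications), length(doc$events))
    expect_true(all(mods == "Negation"))
    trig_ids <- vapply(doc$triggers, `[[`, "", "id")
    for (ev in doc$events) {
      tb <- doc$triggers[[which(trig_ids == ev$trigger)[[1]]]]
      s <- sentence_of(doc, tb$start, tb$end)
      r <- corpus$analyses[[doc_id]][[s]]$ERG
      g <- build_scope_graph(r)
      feats <- negation_features(r, g, trigger_eps(r, tb), lex)
      expect_true("NegOutscope2" %in% feats)
    }
  }
})

test_that("zero coverage yields empty RMRS feature vectors", {
  cfg <- generator_config(n_docs = 3L, coverage = c(ERG = 0, RASP = 0),
                          coverage_union = NA, seed = 56L)
  corpus <- generate_corpus(cfg)
  rc <- run_config("negation", bow = FALSE)
  ins <- build_instances(corpus, rc)
  expect_true(all(lengths(lapply(ins, `[[`, "features")) == 0L))
})

test_that("every phenomenon template makes its target extractor fire", {
  targets <- list(
    neg_scope = c("negation", "NegOutscope2"),
    neg_conj = c("negation", "NegConjIndex"),
    neg_nominal = c("negation", "Arg0NegOutscopeeSA"),
    spec_verb_obj = c("speculation", "SpecVObj2"),
    spec_sister = c("speculation", "SpecVObj2.seed="),
    modal = c("speculation", "ModalOutscope"),
    analysis_of = c("speculation", "AnalysisSA"),
    mod_adj = c("speculation", "ModAdj")
  )
  set.seed(57)
  for (tpl in names(targets)) {
    for (rep in 1:5) {
      sent <- eventmod:::build_sentence(tpl, "phosphorylation", "TRADD", 0L)
      r <- sent$rmrs
      g <- build_scope_graph(r)
      tb <- list(start = sent$starts[[sent$trig_idx]],
                 end = sent$ends[[sent$trig_idx]])
      tr <- trigger_eps(r, tb)
      expect_gt(length(tr), 0L)
      feats <- if (targets[[tpl]][[1]] == "negation") {
        negation_features(r, g, tr, lex)
      } else {
        speculation_features(r, g, tr, lex)
      }
      expect_true(any(startsWith(feats, targets[[tpl]][[2]])),
                  info = tpl)
    }
  }
  # plain sentences fire neither rule family
  sent <- eventmod:::build_sentence("plain", "binding", "TES2", 0L)
  g <- build_scope_graph(sent$rmrs)
  tb <- list(start = sent$starts[[sent$trig_idx]],
             end = sent$ends[[sent$trig_idx]])
  tr <- trigger_eps(sent$rmrs, tb)
  nf <- negation_features(sent$rmrs, g, tr, lex)
  sf <- speculation_features(sent$rmrs, g, tr, lex)
  expect_true(all(startsWith(nf, "TrigPredProps")))
  expect_length(sf, 0L)
})

test_that("noise records intended vs gold labels in the manifest", {
  cfg <- generator_config(n_docs = 20L, p_negation = 0.3,
                          p_speculation = 0.3, noise = 0.3, seed = 58L)
  corpus <- generate_corpus(cfg)
  m <- corpus$manifest
  expect_true(any(m$flipped))
  expect_true(all(m$gold[!m$flipped] == m$intended[!m$flipped]))
  expect_true(all(m$gold[m$flipped] != m$intended[m$flipped]))
  # gold labels in the manifest agree with the documents' M lines
  for (doc_id in names(corpus$docs)) {
    doc <- corpus$docs[[doc_id]]
    mods <- vapply(doc$modifications, `[[`, "", "theme")
    sub <- m[m$doc_id == doc_id & m$gold != "none", ]
    expect_setequal(sub$event_id, mods)
  }
})

test_that("corpora round-trip through the directory layout", {
  cfg <- generator_config(n_docs = 3L, p_negation = 0.4, p_speculation = 0.3,
                          noise = 0, seed = 59L)
  corpus <- generate_corpus(cfg)
  dir <- tempfile()
  write_corpus(corpus, dir)
  again <- read_corpus(dir)
  expect_identical(names(again$docs), names(corpus$docs))
  for (doc_id in names(corpus$docs)) {
    expect_equal(again$docs[[doc_id]], corpus$docs[[doc_id]])
    b1 <- corpus$analyses[[doc_id]]
    b2 <- again$analyses[[doc_id]]
    for (s in seq_along(b1)) {
      present <- as.character(
        names(b1[[s]])[!vapply(b1[[s]], is.null, logical(1))])
      expect_setequal(as.character(names(b2[[s]])), present)
      for (src in present) {
        expect_equal(b2[[s]][[src]], b1[[s]][[src]])
      }
    }
  }
  expect_equal(again$manifest$gold, corpus$manifest$gold)
  # writing again from the reread corpus is byte-stable
  dir2 <- tempfile()
  write_corpus(again, dir2)
  for (f in setdiff(list.files(dir), "manifest.tsv")) {
    expect_identical(readLines(file.path(dir2, f), warn = FALSE),
                     readLines(file.path(dir, f), warn = FALSE),
                     info = f)
  }
})

test_that("RASP degradation only removes material", {
  set.seed(60)
  for (rep in 1:20) {
    sent <- eventmod:::build_sentence("neg_scope", "expression", "RelA", 0L)
    r <- sent$rmrs
    d <- eventmod:::degrade_to_rasp(r, drop_qeq_p = 0.5)
    expect_identical(d$source, "RASP")
    expect_lte(length(d$eps), length(r$eps))
    expect_lte(nrow(d$qeqs), nrow(r$qeqs))
    # overt EPs survive
    overt <- function(x) vapply(Filter(function(e) !is.na(e$cfrom), x$eps),
                                `[[`, "", "pred")
    expect_setequal(overt(d), overt(r))
  }
})
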