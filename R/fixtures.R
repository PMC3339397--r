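#' @title Synthetic corpus generation
#' @description Generates desk-scale corpora — document text, standoff
#'   annotation, per-parser RMRS analyses and gold modification labels —
#'   exhibiting every phenomenon the feature extractors target: clausal
#'   negators outscoping the trigger, negative conjunctions, negated
#'   dominating predicates over nominal triggers, speculative verbs taking
#'   the event nominal as object (including WordNet-sister variants), modal
#'   outscoping, the analysis-of construction, and adjectival hedges.
#'   Sentences are template-realized English-like strings with real
#'   character offsets, so the bag-of-words and RMRS layers are exercised
#'   against the same text.
#' @name synthetic_fixtures
NULL

FIXTURE_PROTEINS <- c("TRADD", "TES2", "TRAF2", "CD40", "STAT1", "p53",
                      "RelA", "IKK1", "TNFR1", "JAK2", "GATA1", "BCL-2",
                      "IL-2", "MYC", "FOXP3")

FIXTURE_TRIGGERS <- c(
  phosphorylation = "Phosphorylation",
  expression      = "Gene_expression",
  binding         = "Binding",
  activation      = "Positive_regulation",
  degradation     = "Protein_catabolism",
  transcription   = "Transcription",
  localization    = "Localization",
  regulation      = "Regulation"
)

NEG_TEMPLATES <- c("neg_scope", "neg_conj", "neg_nominal")
SPEC_TEMPLATES <- c("spec_verb_obj", "spec_sister", "modal", "analysis_of",
                    "mod_adj")

SISTER_SURFACE <- c(probed = "_probe_v", explored = "_explore_v",
                    inspected = "_inspect_v", evaluated = "_evaluate_v")
SEED_SURFACE <- c(investigated = "_investigate_v", examined = "_examine_v",
                  tested = "_test_v", assessed = "_assess_v")

#' Generator configuration
#'
#' @param n_docs Number of documents.
#' @param sentences_per_doc Integer range `c(lo, hi)` of sentences (one
#'   event each) per document.
#' @param p_negation,p_speculation Per-event probabilities of the template
#'   intending a Negation / Speculation label (defaults mirror the modest
#'   modification rates of shared-task abstracts).
#' @param cue_mix Named probability vector over the phenomenon templates
#'   used *within* each modification class; defaults spread mass over all
#'   variants with extra weight on the scope and verb-object patterns.
#' @param coverage Named vector of per-source probabilities that a sentence
#'   has an analysis, e.g. `c(ERG = 0.76, RASP = 0.76)`.
#' @param coverage_union For exactly two sources, the target probability
#'   that at least one analysis exists (`0.93` emulates two parsers whose
#'   parseable sets overlap heavily); `NA` draws sources independently.
#' @param noise Probability that a sentence's gold label is flipped relative
#'   to its template: a cue without the label (distractor) or a plain
#'   sentence carrying the label.
#' @param rasp_degrade Probability of dropping each qeq constraint (and half
#'   of the covert quantifiers) when deriving the shallower RASP analysis
#'   from the ERG one.
#' @param seed Integer seed; fixes the corpus byte-for-byte.
#' @return An object of class `eventmod_genconfig`.
#' @export
generator_config <- function(n_docs = 20L,
                             sentences_per_doc = c(3L, 8L),
                             p_negation = 0.06,
                             p_speculation = 0.05,
                             cue_mix = NULL,
                             coverage = c(ERG = 0.76, RASP = 0.76),
                             coverage_union = 0.93,
                             noise = 0,
                             rasp_degrade = 0.3,
                             seed = 1L) {
  if (is.null(cue_mix)) {
    cue_mix <- c(neg_scope = 0.5, neg_conj = 0.25, neg_nominal = 0.25,
                 spec_verb_obj = 0.3, spec_sister = 0.15, modal = 0.2,
                 analysis_of = 0.2, mod_adj = 0.15, plain = 1)
  }
  stopifnot(p_negation >= 0, p_speculation >= 0,
            p_negation + p_speculation <= 1,
            noise >= 0, noise <= 1,
            all(coverage >= 0), all(coverage <= 1))
  structure(
    list(n_docs = as.integer(n_docs),
         sentences_per_doc = as.integer(sentences_per_doc),
         p_negation = p_negation, p_speculation = p_speculation,
         cue_mix = cue_mix, coverage = coverage,
         coverage_union = coverage_union, noise = noise,
         rasp_degrade = rasp_degrade, seed = as.integer(seed)),
    class = "eventmod_genconfig"
  )
}

# Fresh per-sentence variable/label factory.  Label indices start away from
# zero and step unevenly, as grammars assign them arbitrarily.
var_factory <- function() {
  k <- 2L
  nxt <- function(prefix) {
    k <<- k + 5L
    paste0(prefix, k)
  }
  list(l = function() nxt("l"), h = function() nxt("h"),
       x = function() nxt("x"), e = function() nxt("e"))
}

# Realize a word list as sentence text with per-word document spans; a full
# stop is glued to the last word.
realize_words <- function(words, offset) {
  n <- length(words)
  starts <- integer(n); ends <- integer(n)
  pos <- offset
  for (i in seq_len(n)) {
    starts[[i]] <- pos
    ends[[i]] <- pos + nchar(words[[i]])
    pos <- ends[[i]] + 1L
  }
  text <- paste0(paste(words, collapse = " "), ".")
  list(text = text, starts = starts, ends = ends,
       span = c(offset, offset + nchar(text)))
}

# Build one sentence for a phenomenon template: word list, trigger/protein
# word indices, and the ERG-style RMRS over the realized spans.
build_sentence <- function(template, trig_word, prot, offset) {
  cap <- function(w) paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
  spec_surface <- NULL
  words <- switch(
    template,
    plain         = c("We", "observed", trig_word, "of", prot, "in", "these",
                      "cells"),
    neg_scope     = c(cap(trig_word), "of", prot, "was", "not", "observed"),
    neg_conj      = c("Neither", trig_word, "nor", "degradation", "of", prot,
                      "occurred"),
    neg_nominal   = c(prot, "persisted", "without", trig_word, "of", prot),
    spec_verb_obj = {
      spec_surface <- sample(names(SEED_SURFACE), 1L)
      c("We", spec_surface, "the", trig_word, "of", prot)
    },
    spec_sister   = {
      spec_surface <- sample(names(SISTER_SURFACE), 1L)
      c("We", spec_surface, "the", trig_word, "of", prot)
    },
    modal         = c(cap(trig_word), "of", prot, "may", "occur"),
    analysis_of   = c("Analysis", "of", trig_word, "of", prot, "was",
                      "performed"),
    mod_adj       = c("Putative", trig_word, "of", prot, "was", "reported"),
    stop("unknown template ", template, call. = FALSE)
  )
  trig_idx <- switch(template,
                     plain = 3L, neg_scope = 1L, neg_conj = 2L,
                     neg_nominal = 4L, spec_verb_obj = 4L, spec_sister = 4L,
                     modal = 1L, analysis_of = 3L, mod_adj = 2L)
  prot_idx <- switch(template,
                     plain = 5L, neg_scope = 3L, neg_conj = 6L,
                     neg_nominal = 1L, spec_verb_obj = 6L, spec_sister = 6L,
                     modal = 3L, analysis_of = 5L, mod_adj = 4L)
  rw <- realize_words(words, offset)

  v <- var_factory()
  eps <- list(); qeqs <- list(); ings <- list()
  add_ep <- function(pred, widx, arg0, args = character(), label = v$l()) {
    e0 <- if (is.na(widx)) {
      ep(label, pred, NA, NA, arg0, args)
    } else {
      ep(label, pred, rw$starts[[widx]], rw$ends[[widx]], arg0, args)
    }
    eps[[length(eps) + 1L]] <<- e0
    label
  }
  xt <- v$x(); xp <- v$x()
  lt <- add_ep(paste0("_", tolower(trig_word), "_n_1"), trig_idx, xt)
  add_ep("named_rel", prot_idx, xp)
  # default quantifier for the event nominal, a covert EP
  hq <- v$h()
  add_ep("udef_q_rel", NA, xt, c(RSTR = hq, BODY = v$h()))
  qeqs[[length(qeqs) + 1L]] <- c(hq, lt)
  # "of PROT" complement where the surface has one directly after the trigger
  of_idx <- if (template %in% c("neg_scope", "modal")) trig_idx + 1L
            else if (template %in% c("neg_nominal", "spec_verb_obj",
                                     "spec_sister", "plain", "analysis_of",
                                     "mod_adj")) trig_idx + 1L
            else NA_integer_
  lo <- if (!is.na(of_idx) && words[[of_idx]] == "of") {
    add_ep("_of_p", of_idx, v$e(), c(ARG1 = xt, ARG2 = xp))
  } else NA_character_

  if (template == "neg_scope") {
    # the of-phrase modifier shares the trigger's label; the negator's
    # handle argument reaches the trigger only through that in-g link
    ings[[length(ings) + 1L]] <- c(lo, lt)
    hn <- v$h()
    add_ep("neg_rel", 5L, v$e(), c(ARG1 = hn))
    qeqs[[length(qeqs) + 1L]] <- c(hn, lo)
  } else if (template == "neg_conj") {
    x2 <- v$x()
    add_ep("_degradation_n_1", 4L, x2)
    add_ep("_nor_c", 3L, v$x(), c(`L-INDEX` = xt, `R-INDEX` = x2))
  } else if (template == "neg_nominal") {
    hw <- v$h()
    add_ep("_without_p", 3L, v$e(), c(ARG1 = v$e(), ARG2 = hw))
    qeqs[[length(qeqs) + 1L]] <- c(hw, lo)
  } else if (template %in% c("spec_verb_obj", "spec_sister")) {
    pred <- if (template == "spec_verb_obj") SEED_SURFACE[[spec_surface]]
            else SISTER_SURFACE[[spec_surface]]
    xw <- v$x()
    add_ep("pron_rel", 1L, xw)
    add_ep(paste0(pred, "_1"), 2L, v$e(), c(ARG1 = xw, ARG2 = xt))
  } else if (template == "modal") {
    hm <- v$h()
    add_ep("_may_v_modal", 4L, v$e(), c(ARG1 = hm))
    qeqs[[length(qeqs) + 1L]] <- c(hm, lt)
    add_ep("_occur_v_1", 5L, v$e(), c(ARG1 = xt))
  } else if (template == "analysis_of") {
    add_ep("_analysis_n_1", 1L, v$x(), c(ARG1 = xt))
  } else if (template == "mod_adj") {
    add_ep("_putative_a_1", 1L, v$e(), c(ARG1 = xt))
  } else if (template == "plain") {
    xw <- v$x()
    add_ep("pron_rel", 1L, xw)
    add_ep("_observe_v_1", 2L, v$e(), c(ARG1 = xw, ARG2 = xt))
  }

  r <- rmrs(eps = eps, qeqs = qeqs, ings = ings, sentence_span = rw$span,
            source = "ERG")
  list(words = words, text = rw$text, starts = rw$starts, ends = rw$ends,
       span = rw$span, trig_idx = trig_idx, prot_idx = prot_idx,
       trig_word = words[[trig_idx]], prot = prot, rmrs = r)
}

# Derive a degraded shallow-parser analysis from the ERG one: drop covert
# quantifiers (and their constraints) and a fraction of the qeqs.
degrade_to_rasp <- function(r, drop_qeq_p = 0.3, drop_covert_p = 0.5) {
  keep_ep <- vapply(r$eps, function(e) {
    !is.na(e$cfrom) || stats::runif(1) > drop_covert_p
  }, logical(1))
  eps <- r$eps[keep_ep]
  kept_labels <- vapply(eps, `[[`, "", "label")
  qeqs <- r$qeqs
  if (nrow(qeqs)) {
    qeqs <- qeqs[qeqs[, 2L] %in% kept_labels, , drop = FALSE]
  }
  if (nrow(qeqs)) {
    qeqs <- qeqs[stats::runif(nrow(qeqs)) > drop_qeq_p, , drop = FALSE]
  }
  ings <- r$ings
  if (nrow(ings)) {
    ings <- ings[ings[, 1L] %in% kept_labels & ings[, 2L] %in% kept_labels,
                 , drop = FALSE]
  }
  rmrs(eps = eps, qeqs = qeqs, ings = ings, sentence_span = r$sentence_span,
       source = "RASP")
}

sample_template <- function(cfg) {
  u <- stats::runif(1)
  class_ <- if (u < cfg$p_negation) "Negation"
            else if (u < cfg$p_negation + cfg$p_speculation) "Speculation"
            else "none"
  pool <- switch(class_, Negation = NEG_TEMPLATES,
                 Speculation = SPEC_TEMPLATES, none = "plain")
  w <- cfg$cue_mix[pool]
  w[is.na(w)] <- 0
  if (sum(w) <= 0) w <- rep(1, length(pool))
  tpl <- if (length(pool) == 1L) pool else sample(pool, 1L, prob = w)
  list(class_ = class_, template = tpl)
}

sample_sources <- function(cfg) {
  srcs <- names(cfg$coverage)
  if (length(srcs) == 2L && !is.na(cfg$coverage_union)) {
    p1 <- cfg$coverage[[1L]]; p2 <- cfg$coverage[[2L]]
    pu <- min(cfg$coverage_union, 1)
    p_both <- max(0, p1 + p2 - pu)
    p_only1 <- p1 - p_both
    p_only2 <- p2 - p_both
    p_none <- max(0, 1 - p_both - p_only1 - p_only2)
    pick <- sample(c("both", "only1", "only2", "none"), 1L,
                   prob = c(p_both, p_only1, p_only2, p_none))
    return(switch(pick, both = srcs, only1 = srcs[[1L]],
                  only2 = srcs[[2L]], none = character()))
  }
  srcs[stats::runif(length(srcs)) < cfg$coverage]
}

#' Generate a synthetic corpus
#'
#' @param cfg A [generator_config()].
#' @return An object of class `eventmod_corpus`: `docs` (named list of
#'   standoff documents), `analyses` (per doc, per sentence: named list of
#'   source tag to [rmrs()] or `NULL`), and `manifest` (data frame recording
#'   each event's template, intended label, gold label and whether noise
#'   flipped it).
#' @export
generate_corpus <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  docs <- list()
  analyses <- list()
  manifest <- list()
  for (d in seq_len(cfg$n_docs)) {
    doc_id <- sprintf("SYN%04d", d)
    n_sent <- sample(seq(cfg$sentences_per_doc[1L],
                         cfg$sentences_per_doc[2L]), 1L)
    offset <- 0L
    texts <- character(n_sent)
    sents <- matrix(0L, n_sent, 2L)
    doc_analyses <- vector("list", n_sent)
    a1 <- character(); a2 <- character()
    nt <- 0L; np <- 0L; ne <- 0L; nm <- 0L
    for (s in seq_len(n_sent)) {
      draw <- sample_template(cfg)
      trig_word <- sample(names(FIXTURE_TRIGGERS), 1L)
      prot <- sample(FIXTURE_PROTEINS, 1L)
      sent <- build_sentence(draw$template, trig_word, prot, offset)
      texts[[s]] <- sent$text
      sents[s, ] <- sent$span

      np <- np + 1L
      p_id <- sprintf("T%d", np + 1000L)   # protein ids live in their own range
      a1 <- c(a1, sprintf("%s\tProtein %d %d\t%s", p_id,
                          sent$starts[[sent$prot_idx]],
                          sent$ends[[sent$prot_idx]], sent$prot))
      nt <- nt + 1L
      t_id <- sprintf("T%d", nt)
      ev_type <- FIXTURE_TRIGGERS[[tolower(sent$trig_word)]]
      a2 <- c(a2, sprintf("%s\t%s %d %d\t%s", t_id, ev_type,
                          sent$starts[[sent$trig_idx]],
                          sent$ends[[sent$trig_idx]], sent$trig_word))
      ne <- ne + 1L
      e_id <- sprintf("E%d", ne)
      a2 <- c(a2, sprintf("%s\t%s:%s Theme:%s", e_id, ev_type, t_id, p_id))

      intended <- draw$class_
      gold <- intended
      flipped <- stats::runif(1) < cfg$noise
      if (flipped) {
        gold <- if (intended == "none") {
          sample(c("Negation", "Speculation"), 1L)
        } else "none"
      }
      if (gold != "none") {
        nm <- nm + 1L
        a2 <- c(a2, sprintf("M%d\t%s %s", nm, gold, e_id))
      }
      manifest[[length(manifest) + 1L]] <- data.frame(
        doc_id = doc_id, event_id = e_id, sentence = s,
        template = draw$template, intended = intended, gold = gold,
        flipped = flipped
      )

      srcs <- sample_sources(cfg)
      bundle <- stats::setNames(vector("list", length(cfg$coverage)),
                                names(cfg$coverage))
      for (src in srcs) {
        bundle[[src]] <- if (src == "RASP") {
          degrade_to_rasp(sent$rmrs, cfg$rasp_degrade)
        } else {
          r <- sent$rmrs; r$source <- src; r
        }
      }
      doc_analyses[[s]] <- bundle
      offset <- sent$span[[2L]] + 1L
    }
    text <- paste(texts, collapse = " ")
    docs[[doc_id]] <- read_document(text, a1 = a1, a2 = a2,
                                    sentences = sents, doc_id = doc_id)
    analyses[[doc_id]] <- doc_analyses
  }
  structure(
    list(docs = docs, analyses = analyses,
         manifest = do.call(rbind, manifest)),
    class = "eventmod_corpus"
  )
}

#' @export
print.eventmod_corpus <- function(x, ...) {
  n_ev <- sum(vapply(x$docs, function(d) length(d$events), 0L))
  n_mod <- sum(vapply(x$docs, function(d) length(d$modifications), 0L))
  cat(sprintf("<synthetic corpus: %d docs, %d events, %d gold modifications>\n",
              length(x$docs), n_ev, n_mod))
  invisible(x)
}

#' Write / read a corpus directory
#'
#' Layout per document: `<doc>.txt`, `<doc>.a1`, `<doc>.a2`, `<doc>.sents`
#' (tab-separated sentence spans), `<doc>.toks` (token sidecar), and
#' `<doc>.<source>.rmrs.json` per available analysis; plus `manifest.tsv`
#' recording gold-vs-distractor status for test assertions.
#'
#' @param corpus An `eventmod_corpus`.
#' @param dir Target directory (created if needed).
#' @param strip_modifications Drop `M` lines from the written `.a2` files
#'   (for prediction inputs).
#' @return `write_corpus()`: `dir`, invisibly.  `read_corpus()`: an
#'   `eventmod_corpus` (manifest included when present).
#' @export
write_corpus <- function(corpus, dir, strip_modifications = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc_id in names(corpus$docs)) {
    doc <- corpus$docs[[doc_id]]
    base <- file.path(dir, doc_id)
    writeLines(doc$text, paste0(base, ".txt"), sep = "")
    writeLines(write_a1(doc), paste0(base, ".a1"))
    a2 <- write_a2(doc)
    if (strip_modifications) a2 <- a2[!startsWith(a2, "M")]
    writeLines(a2, paste0(base, ".a2"))
    writeLines(sprintf("%d\t%d", doc$sentences[, 1L], doc$sentences[, 2L]),
               paste0(base, ".sents"))
    toks <- character()
    for (s in seq_len(nrow(doc$sentences))) {
      tk <- tokenize_sentence(doc$text, doc$sentences[s, ])$tokens
      toks <- c(toks, sprintf("%d\t%d\t%s", tk$start, tk$end, tk$surface))
    }
    writeLines(toks, paste0(base, ".toks"))
    bundles <- corpus$analyses[[doc_id]]
    for (s in seq_along(bundles)) {
      for (src in names(bundles[[s]])) {
        r <- bundles[[s]][[src]]
        if (is.null(r)) next
        writeLines(write_rmrs(r, "json"),
                   sprintf("%s.s%03d.%s.rmrs.json", base, s, src))
      }
    }
  }
  if (!is.null(corpus$manifest)) {
    utils::write.table(corpus$manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$"))
  docs <- list(); analyses <- list()
  for (f in txts) {
    doc_id <- sub("\\.txt$", "", f)
    base <- file.path(dir, doc_id)
    a2_path <- paste0(base, ".a2")
    doc <- read_document(
      text = paste0(base, ".txt"),
      a1 = paste0(base, ".a1"),
      a2 = if (file.exists(a2_path)) a2_path else NULL,
      sentences = paste0(base, ".sents"),
      doc_id = doc_id
    )
    docs[[doc_id]] <- doc
    rfiles <- list.files(dir, pattern = paste0("^", doc_id,
                                               "\\.s[0-9]+\\..*\\.rmrs\\.json$"))
    doc_analyses <- rep(list(list()), nrow(doc$sentences))
    for (rf in rfiles) {
      parts <- strsplit(rf, ".", fixed = TRUE)[[1]]
      s <- as.integer(sub("^s", "", parts[[2]]))
      src <- parts[[3]]
      doc_analyses[[s]][[src]] <- parse_rmrs(file.path(dir, rf), "json")
    }
    analyses[[doc_id]] <- doc_analyses
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  manifest <- if (file.exists(manifest_path)) {
    utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  } else NULL
  structure(list(docs = docs, analyses = analyses, manifest = manifest),
            class = "eventmod_corpus")
}

#' The worked scope-algebra example as a permanent regression fixture
#'
#' Encodes the sentence *"Thus NF-kappa B activation is not required for
#' neuroblastoma cell differentiation."* with the RMRS relations a precision
#' grammar assigns it: the scopal adverb outscoping the negator (`l3` over
#' `l17`), the negator outscoping the verb (`l17` over `l20`), a compound
#' relation sharing its ARG1 with the ARG0 of the event nominal via `x23`,
#' and a quantifier handle whose qeq reaches the nominal's label `l104`
#' only through the in-g constraint `l28 in-g l104`.  The document offset
#' places "differentiation." at characters 130–146.
#'
#' @return List with `text` (two-sentence document), `sentence_span`,
#'   `rmrs`, and `trigger` (span of the event nominal, including the glued
#'   full stop).
#' @export
encode_figure1 <- function() {
  sent <- "Thus NF-kappa B activation is not required for neuroblastoma cell differentiation."
  base <- 64L
  prefix <- sprintf("%-*s", base, "Neuroblastoma cells were cultured as described.")
  text <- paste0(prefix, sent)
  sp <- function(from, to) c(base + from, base + to)  # local -> document
  eps <- list(
    ep("l3",   "_thus_a_1",            base + 0L,  base + 4L,  "e2",
       c(ARG1 = "h4")),
    ep("l8",   "udef_q_rel",           NA, NA, "x9",
       c(RSTR = "h9", BODY = "h10")),
    ep("l11",  "_activation_n_1",      base + 16L, base + 26L, "x9"),
    ep("l17",  "neg_rel",              base + 30L, base + 33L, "e18",
       c(ARG1 = "h19")),
    ep("l20",  "_require_v_1",         base + 34L, base + 42L, "e21",
       c(ARG1 = "u22", ARG2 = "x9")),
    ep("l40",  "_for_p",               base + 43L, base + 46L, "e41",
       c(ARG1 = "e21", ARG2 = "x23")),
    ep("l26",  "udef_q_rel",           NA, NA, "x23",
       c(RSTR = "h27", BODY = "h25")),
    ep("l28",  "compound_rel",         base + 47L, base + 65L, "e29",
       c(ARG1 = "x23", ARG2 = "x31")),
    ep("l33",  "udef_q_rel",           NA, NA, "x31",
       c(RSTR = "h34", BODY = "h35")),
    ep("l36",  "_cell_n_1",            base + 61L, base + 65L, "x31"),
    ep("l104", "_differentiation_n_1", base + 66L, base + 82L, "x23")
  )
  r <- rmrs(
    eps = eps,
    qeqs = list(c("h4", "l17"), c("h19", "l20"), c("h9", "l11"),
                c("h27", "l28"), c("h34", "l36")),
    ings = list(c("l28", "l104")),
    sentence_span = c(base, base + nchar(sent)),
    source = "ERG"
  )
  list(text = text,
       sentence_span = c(base, base + nchar(sent)),
       rmrs = r,
       trigger = list(start = base + 66L, end = base + 82L,
                      surface = "differentiation."))
}
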