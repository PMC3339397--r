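#' @title Scope-based negation and speculation features
#' @description The two feature sets operate on an RMRS scope graph and the
#'   trigger EPs of an event.  For each rule a general feature fires (e.g.
#'   `NegOutscope2`) together with a predicate-specific variant
#'   (`NegOutscope2=_never_a`), so the learner can both generalize across
#'   cues and memorize reliable ones.
#' @name rmrs_features
NULL

#' Extract the part-of-speech letter from a predicate name
#'
#' Surface predicates follow the `_lemma_pos[_sense]` convention, where the
#' POS letter is `n` (noun), `v` (verb), `a` (adjective/adverb), `q`
#' (quantifier), `c` (conjunction) or `p` (preposition).  Grammar-internal
#' predicates (e.g. `neg_rel`, `compound_rel`) carry no POS.
#'
#' @param pred Predicate name string (vectorized).
#' @return POS letter or `NA` where the convention does not apply.
#' @export
pos_of <- function(pred) {
  m <- regmatches(pred, regexec("^_(.+)_([nvaqcp])(_[^_]+)?$", pred))
  vapply(m, function(g) if (length(g)) g[[3]] else NA_character_,
         NA_character_)
}

#' Normalize a predicate name by dropping its sense field
#'
#' Grammars attach trailing sense distinctions (`_require_v_1`,
#' `_differentiation_n_of`) inconsistently; lexicon matching ignores them by
#' default so `_require_v_1` matches the entry `_require_v`.
#'
#' @param pred Predicate name string (vectorized).
#' @return Predicate truncated after the POS letter; unchanged if the
#'   `_lemma_pos` convention does not apply.
#' @export
normalize_pred <- function(pred) {
  sub("^(_.+_[nvaqcp])(_[^_]+)?$", "\\1", pred)
}

pred_matches <- function(pred, lexset, exact = FALSE) {
  if (exact) pred %in% lexset
  else normalize_pred(pred) %in% normalize_pred(lexset)
}

#' Lexicons for the scope-based feature extractors
#'
#' Bundles the five lexical resources the extractors consult: semantically
#' negative predicates, negative conjunctions (with the roles holding their
#' negated daughters), speculative seed verbs, their WordNet sisters (mapped
#' back to the seed), and modal predicates.  Sister expansion is performed
#' offline into the lexicon file; the pipeline never queries a lexical
#' database at run time.
#'
#' @param neg_preds Character vector of negative predicate names.
#' @param neg_conjs Named list: conjunction predicate -> character vector of
#'   roles carrying the negated daughter(s) (e.g. `R-INDEX`).
#' @param spec_seed_verbs Character vector of speculative seed verbs.
#' @param spec_sisters Named character vector: sister predicate -> seed verb.
#' @param modal_preds Character vector of modal predicates.
#' @return An object of class `eventmod_lexicons`.
#' @export
lexicons <- function(neg_preds = character(), neg_conjs = list(),
                     spec_seed_verbs = character(),
                     spec_sisters = character(),
                     modal_preds = character()) {
  if (length(neg_conjs) && any(!lengths(neg_conjs))) {
    stop("every negative conjunction needs a non-empty daughter role set",
         call. = FALSE)
  }
  if (length(spec_sisters)) {
    orphan <- setdiff(normalize_pred(unname(spec_sisters)),
                      normalize_pred(spec_seed_verbs))
    if (length(orphan)) {
      stop("sister entries map to unknown seed verb(s): ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(neg_preds = neg_preds, neg_conjs = neg_conjs,
         spec_seed_verbs = spec_seed_verbs, spec_sisters = spec_sisters,
         modal_preds = modal_preds),
    class = "eventmod_lexicons"
  )
}

#' Read lexicons from a directory of lexicon files
#'
#' Each file holds one entry per line: `predicate[<TAB>key=value ...]`.
#' Lines starting with `#` are comments.  Conjunction entries carry
#' `daughters=R-INDEX[,L-INDEX]`; sister entries carry `seed=<pred>` and are
#' kept in the same file as the seed verbs.
#'
#' @param dir Directory containing `neg_preds.lex`, `neg_conjs.lex`,
#'   `spec_verbs.lex`, `modal_preds.lex`.  Defaults to the reconstructed
#'   lexicons shipped with the package.
#' @return An [lexicons()] object.
#' @export
read_lexicons <- function(dir = system.file("lexicons", package = "eventmod")) {
  read_entries <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) return(list())
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    lapply(lines, function(l) {
      fields <- strsplit(l, "\t", fixed = TRUE)[[1]]
      kv <- list(pred = fields[[1]])
      for (f in fields[-1L]) {
        p <- strsplit(f, "=", fixed = TRUE)[[1]]
        kv[[p[[1]]]] <- p[[2]]
      }
      kv
    })
  }
  negs <- read_entries("neg_preds.lex")
  conjs <- read_entries("neg_conjs.lex")
  specs <- read_entries("spec_verbs.lex")
  modals <- read_entries("modal_preds.lex")
  sisters <- Filter(function(e) !is.null(e$seed), specs)
  seeds <- Filter(function(e) is.null(e$seed), specs)
  lexicons(
    neg_preds = vapply(negs, `[[`, "", "pred"),
    neg_conjs = stats::setNames(
      lapply(conjs, function(e) {
        strsplit(e$daughters %||% "R-INDEX", ",", fixed = TRUE)[[1]]
      }),
      vapply(conjs, `[[`, "", "pred")),
    spec_seed_verbs = vapply(seeds, `[[`, "", "pred"),
    spec_sisters = stats::setNames(vapply(sisters, `[[`, "", "seed"),
                                   vapply(sisters, `[[`, "", "pred")),
    modal_preds = vapply(modals, `[[`, "", "pred")
  )
}

#' @rdname read_lexicons
#' @export
default_lexicons <- function() read_lexicons()

# Indices of EPs whose (normalized) predicate is in a lexicon set.
lex_hits <- function(r, lexset, exact = FALSE) {
  which(vapply(r$eps, function(e) pred_matches(e$pred, lexset, exact),
               logical(1)))
}

trigger_arg0s <- function(r, triggers) {
  unique(vapply(triggers, function(i) r$eps[[i]]$arg0, ""))
}

#' Negation feature set
#'
#' Four rule families over the scope graph:
#' \describe{
#'   \item{NegOutscope2}{a semantically negative predicate outscopes a
#'     trigger EP.}
#'   \item{NegConjIndex}{a negative conjunction's negated-daughter role holds
#'     the ARG0 of a trigger EP.}
#'   \item{Arg0NegOutscopeeSA}{an EP sharing an argument with a trigger's
#'     ARG0 is itself outscoped by a negative predicate — catches nominal
#'     triggers whose dominating predicate is negated.}
#'   \item{TrigPredProps}{the trigger EP's predicate name and POS.}
#' }
#'
#' @param r An [rmrs()] analysis.
#' @param g Its scope graph ([build_scope_graph()]).
#' @param triggers Integer indices of the trigger EPs (from [trigger_eps()]).
#' @param lex An [lexicons()] object.
#' @param exact Match lexicon predicates exactly instead of ignoring the
#'   sense field.
#' @return Character vector of feature names (a set).
#' @export
negation_features <- function(r, g, triggers, lex, exact = FALSE) {
  if (!length(triggers)) return(character())
  feats <- character()
  t_arg0 <- trigger_arg0s(r, triggers)

  neg_idx <- lex_hits(r, lex$neg_preds, exact)
  for (p in neg_idx) {
    if (any(vapply(triggers, function(t) g$closure[p, t], logical(1)))) {
      feats <- c(feats, "NegOutscope2",
                 paste0("NegOutscope2=", normalize_pred(r$eps[[p]]$pred)))
    }
  }

  if (length(lex$neg_conjs)) {
    conj_preds <- names(lex$neg_conjs)
    for (ci in lex_hits(r, conj_preds, exact)) {
      e <- r$eps[[ci]]
      entry <- which(normalize_pred(conj_preds) == normalize_pred(e$pred))[1]
      roles <- lex$neg_conjs[[entry]]
      daughters <- e$args[names(e$args) %in% roles]
      if (length(daughters) && any(daughters %in% t_arg0)) {
        feats <- c(feats, "NegConjIndex",
                   paste0("NegConjIndex=", normalize_pred(e$pred)))
      }
    }
  }

  # EPs (other than the triggers themselves) with an argument slot holding a
  # trigger ARG0, outscoped by a negative predicate.
  for (q in seq_along(r$eps)) {
    if (q %in% triggers) next
    e <- r$eps[[q]]
    vars <- e$args[!is_handle(e$args)]
    if (!any(vars %in% t_arg0)) next
    for (p in neg_idx) {
      if (p != q && g$closure[p, q]) {
        feats <- c(feats, "Arg0NegOutscopeeSA",
                   paste0("Arg0NegOutscopeeSA=", normalize_pred(r$eps[[p]]$pred)))
      }
    }
  }

  for (t in triggers) {
    pred <- normalize_pred(r$eps[[t]]$pred)
    pos <- pos_of(r$eps[[t]]$pred)
    feats <- c(feats, paste0("TrigPredProps=", pred))
    if (!is.na(pos)) feats <- c(feats, paste0("TrigPredProps.pos=", pos))
  }
  unique(feats)
}

#' Speculation feature set
#'
#' Four rule families over the scope graph:
#' \describe{
#'   \item{SpecVObj2+WN}{a speculative seed verb (or a WordNet sister of
#'     one) takes the trigger's ARG0 as its ARG2 (deep object); a sister
#'     match adds a feature for the seed verb it expands.}
#'   \item{ModalOutscope}{a modal predicate outscopes a trigger EP.}
#'   \item{AnalysisSA}{the trigger's ARG0 is an argument of an EP with
#'     lemma "analysis" (noun) — the analysis-of construction.}
#'   \item{ModAdj}{an adjectival/adverbial EP's ARG1 is the trigger's ARG0
#'     (the trigger is being modified).}
#' }
#'
#' @inheritParams negation_features
#' @return Character vector of feature names (a set).
#' @export
speculation_features <- function(r, g, triggers, lex, exact = FALSE) {
  if (!length(triggers)) return(character())
  feats <- character()
  t_arg0 <- trigger_arg0s(r, triggers)

  spec_all <- c(lex$spec_seed_verbs, names(lex$spec_sisters))
  for (vi in lex_hits(r, spec_all, exact)) {
    e <- r$eps[[vi]]
    arg2 <- e$args[names(e$args) == "ARG2"]
    if (length(arg2) && arg2 %in% t_arg0) {
      pred <- normalize_pred(e$pred)
      feats <- c(feats, "SpecVObj2", paste0("SpecVObj2=", pred))
      sis <- which(normalize_pred(names(lex$spec_sisters)) == pred)
      if (length(sis)) {
        feats <- c(feats,
                   paste0("SpecVObj2.seed=",
                          normalize_pred(lex$spec_sisters[[sis[1]]])))
      }
    }
  }

  for (mi in lex_hits(r, lex$modal_preds, exact)) {
    if (any(vapply(triggers, function(t) g$closure[mi, t], logical(1)))) {
      feats <- c(feats, "ModalOutscope",
                 paste0("ModalOutscope=", normalize_pred(r$eps[[mi]]$pred)))
    }
  }

  for (ai in seq_along(r$eps)) {
    e <- r$eps[[ai]]
    m <- regexec("^_(.+)_([nvaqcp])(_[^_]+)?$", e$pred)
    g1 <- regmatches(e$pred, m)[[1]]
    if (length(g1) && g1[[2]] == "analysis" && g1[[3]] == "n") {
      vars <- e$args[!is_handle(e$args)]   # any role except the EP's own ARG0
      if (any(vars %in% t_arg0)) {
        feats <- c(feats, "AnalysisSA",
                   paste0("AnalysisSA=", normalize_pred(e$pred)))
      }
    }
  }

  for (ai in seq_along(r$eps)) {
    e <- r$eps[[ai]]
    if (identical(pos_of(e$pred), "a")) {
      arg1 <- e$args[names(e$args) == "ARG1"]
      if (length(arg1) && arg1 %in% t_arg0 && !(ai %in% triggers)) {
        feats <- c(feats, "ModAdj",
                   paste0("ModAdj=", normalize_pred(e$pred)))
      }
    }
  }
  unique(feats)
}
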