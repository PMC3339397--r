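#' @title End-to-end pipeline: extract features, train, predict, score
#' @description Ties the layers together per subtask: each event's trigger
#'   selects the RMRS bundle of its containing sentence; scope features are
#'   combined across parser sources by the chosen strategy and optionally
#'   unioned with bag-of-words window features; one maximum-entropy model is
#'   trained per subtask; predictions are written as a2-format M lines and
#'   scored at the modification level.  Events in sentences with no analysis
#'   (and bag-of-words off) get empty vectors and hence the class-prior
#'   decision.
#' @name pipeline
NULL

subtask_type <- function(subtask) {
  switch(match.arg(subtask, c("negation", "speculation")),
         negation = "Negation", speculation = "Speculation")
}

#' Run configuration for one subtask
#'
#' @param subtask `"negation"` or `"speculation"`.
#' @param strategy A [combination_strategy()].
#' @param bow Bag-of-words window: a [window_spec()], a mnemonic like
#'   `"W+3-4"`, `TRUE` for the subtask default (speculation `W+3-3`,
#'   negation `W+3-4` — the window sizes that proved optimal for each
#'   subtask), or `FALSE`/`NULL` to disable.
#' @param rmrs Include RMRS-derived features (default `TRUE`).
#' @param lexicons An [lexicons()] object; default the shipped lexicons.
#' @param sigma2,max_iter Classifier settings, see [train_maxent()].
#' @return An object of class `eventmod_runconfig`.
#' @export
run_config <- function(subtask = c("negation", "speculation"),
                       strategy = combination_strategy("fb"),
                       bow = TRUE, rmrs = TRUE, lexicons = NULL,
                       sigma2 = 1, max_iter = 200L) {
  subtask <- match.arg(subtask)
  if (isTRUE(bow)) {
    bow <- parse_window(if (subtask == "negation") "W+3-4" else "W+3-3")
  } else if (is.character(bow)) {
    bow <- parse_window(bow)
  } else if (isFALSE(bow)) {
    bow <- NULL
  }
  if (is.null(lexicons)) lexicons <- default_lexicons()
  structure(
    list(subtask = subtask, strategy = strategy, bow = bow, rmrs = rmrs,
         lexicons = lexicons, sigma2 = sigma2, max_iter = max_iter),
    class = "eventmod_runconfig"
  )
}

# Feature extractor for one analysis, closed over the trigger span.
subtask_extractor <- function(subtask, trigger, lex) {
  force(trigger)
  function(r) {
    g <- build_scope_graph(r)
    tr <- trigger_eps(r, trigger)
    if (subtask == "negation") negation_features(r, g, tr, lex)
    else speculation_features(r, g, tr, lex)
  }
}

#' Build classification instances for every event of a corpus
#'
#' @param corpus An `eventmod_corpus`.
#' @param cfg A [run_config()].
#' @param labelled Attach gold labels from the documents' modification
#'   layer (for training) or leave labels `NA` (for prediction).
#' @return List of [instance()]s, one per event, in document order; each
#'   carries attributes `doc_id` and `event_id`.
#' @export
build_instances <- function(corpus, cfg, labelled = TRUE) {
  type <- subtask_type(cfg$subtask)
  out <- list()
  for (doc_id in names(corpus$docs)) {
    doc <- corpus$docs[[doc_id]]
    trig_ids <- vapply(doc$triggers, `[[`, "", "id")
    mod_themes <- vapply(doc$modifications, function(m) {
      if (m$type == type) m$theme else NA_character_
    }, "")
    for (ev in doc$events) {
      tb <- doc$triggers[[which(trig_ids == ev$trigger)[[1]]]]
      s <- sentence_of(doc, tb$start, tb$end)
      feats <- character()
      if (cfg$rmrs) {
        bundle <- corpus$analyses[[doc_id]][[s]]
        if (!is.null(bundle)) {
          feats <- combine_features(
            bundle, cfg$strategy,
            subtask_extractor(cfg$subtask, tb, cfg$lexicons))
        }
      }
      bow <- NULL
      if (!is.null(cfg$bow)) {
        tk <- tokenize_sentence(doc$text, doc$sentences[s, ])
        bow <- window_features(tk, locate_trigger_token(tk, tb), cfg$bow)
      }
      lab <- if (labelled) {
        if (ev$id %in% mod_themes) "positive" else "negative"
      } else NA_character_
      ins <- instance(paste(doc_id, ev$id, sep = "/"),
                      assemble_instance(feats, bow), lab)
      attr(ins, "doc_id") <- doc_id
      attr(ins, "event_id") <- ev$id
      out[[length(out) + 1L]] <- ins
    }
  }
  out
}

#' Train the subtask classifier on a gold-annotated corpus
#'
#' @param corpus An `eventmod_corpus` whose documents carry gold events and
#'   modifications.
#' @param cfg A [run_config()].
#' @param model_path Optional path; when given the model is serialized there
#'   as versioned JSON.
#' @param quiet Suppress the instance-count log line.
#' @return A [train_maxent()] model.
#' @export
run_train <- function(corpus, cfg, model_path = NULL, quiet = FALSE) {
  n_mod <- sum(vapply(corpus$docs, function(d) length(d$modifications), 0L))
  if (n_mod == 0L) {
    stop("corpus carries no gold modifications; cannot train", call. = FALSE)
  }
  instances <- build_instances(corpus, cfg, labelled = TRUE)
  labels <- vapply(instances, `[[`, "", "label")
  if (!quiet) {
    message(sprintf("[%s] %d instances, %.1f%% positive",
                    cfg$subtask, length(instances),
                    100 * mean(labels == "positive")))
  }
  model <- train_maxent(instances, sigma2 = cfg$sigma2,
                        max_iter = cfg$max_iter)
  if (!is.null(model_path)) write_maxent(model, model_path)
  model
}

#' Predict modifications for every event of a corpus
#'
#' @param model A [train_maxent()] model for `cfg$subtask`.
#' @param corpus An `eventmod_corpus` with events (modifications, if
#'   present, are ignored).
#' @param cfg The [run_config()] the model was trained under.
#' @return List with `pairs` (list of `(doc, mod)` pairs, as
#'   [score_modifications()] expects) and `lines` (named list: doc id to
#'   a2-format M lines, ids renumbered per document).
#' @export
run_predict <- function(model, corpus, cfg) {
  type <- subtask_type(cfg$subtask)
  instances <- build_instances(corpus, cfg, labelled = FALSE)
  pairs <- list()
  lines <- list()
  per_doc_count <- integer()
  for (ins in instances) {
    pred <- predict_maxent(model, ins$features)
    if (pred$label != "positive") next
    doc_id <- attr(ins, "doc_id")
    k <- if (doc_id %in% names(per_doc_count)) per_doc_count[[doc_id]] + 1L else 1L
    per_doc_count[doc_id] <- k
    mod <- modification_record(sprintf("M%d", k), type,
                               attr(ins, "event_id"))
    pairs[[length(pairs) + 1L]] <- list(doc = corpus$docs[[doc_id]],
                                        mod = mod)
  }
  for (doc_id in names(corpus$docs)) {
    doc_mods <- Filter(function(p) p$doc$doc_id == doc_id, pairs)
    lines[[doc_id]] <- write_modifications(corpus$docs[[doc_id]],
                                           lapply(doc_mods, `[[`, "mod"))
  }
  list(pairs = pairs, lines = lines)
}

#' Score predictions against a gold corpus
#'
#' @param gold_corpus An `eventmod_corpus` with gold modifications.
#' @param predictions A [run_predict()] result (its `pairs`), or a list of
#'   `(doc, mod)` pairs.
#' @param event_matcher See [score_modifications()].
#' @return An `eventmod_score`.
#' @export
run_evaluate <- function(gold_corpus, predictions,
                         event_matcher = c("by-id", "structural")) {
  if (!is.null(predictions$pairs)) predictions <- predictions$pairs
  score_modifications(unname(gold_corpus$docs), predictions,
                      event_matcher = match.arg(event_matcher))
}

#' Train and evaluate both subtasks end to end
#'
#' Convenience wrapper: trains one model per subtask on `train_corpus`,
#' predicts on `test_corpus`, and scores by event id.
#'
#' @param train_corpus,test_corpus `eventmod_corpus` objects.
#' @param strategy A [combination_strategy()].
#' @param bow See [run_config()].
#' @param rmrs Include RMRS features.
#' @param quiet Suppress log lines.
#' @return Named list per subtask: `model`, `predictions`, `score`.
#' @export
run_pipeline <- function(train_corpus, test_corpus,
                         strategy = combination_strategy("fb"),
                         bow = TRUE, rmrs = TRUE, quiet = TRUE) {
  out <- list()
  for (subtask in c("negation", "speculation")) {
    cfg <- run_config(subtask, strategy = strategy, bow = bow, rmrs = rmrs)
    model <- run_train(train_corpus, cfg, quiet = quiet)
    preds <- run_predict(model, test_corpus, cfg)
    out[[subtask]] <- list(
      model = model,
      predictions = preds,
      score = run_evaluate(test_corpus, preds)
    )
  }
  out
}
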