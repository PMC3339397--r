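#' @title Modification-level scoring
#' @description Scores predicted Negation/Speculation modifications against
#'   gold at the modification level: a prediction is a true positive iff a
#'   gold modification of the same type over a matching theme event exists,
#'   with greedy one-to-one matching in document order.  Recall, precision
#'   and F-score are reported per type and overall.
#' @name evaluation
NULL

# Canonical structural signature of an event: type, trigger span, and role ->
# argument signatures (protein spans or nested event signatures), so events
# can be matched across documents that use different ids.
event_signature <- function(doc, ev_id, seen = character()) {
  if (ev_id %in% seen) stop("cyclic event reference at ", ev_id, call. = FALSE)
  evs <- doc$events
  ids <- vapply(evs, `[[`, "", "id")
  ev <- evs[[which(ids == ev_id)[[1]]]]
  tbs <- c(doc$proteins, doc$triggers)
  tb_ids <- vapply(tbs, `[[`, "", "id")
  span_of <- function(id) {
    tb <- tbs[[which(tb_ids == id)[[1]]]]
    sprintf("%d-%d", tb$start, tb$end)
  }
  args <- ev$args
  arg_sigs <- vapply(seq_along(args), function(i) {
    ref <- args[[i]]
    sig <- if (ref %in% ids) {
      event_signature(doc, ref, c(seen, ev_id))
    } else {
      span_of(ref)
    }
    paste0(names(args)[[i]], "=", sig)
  }, "")
  paste0(ev$type, "[", span_of(ev$trigger), "](",
         paste(sort(arg_sigs), collapse = ","), ")")
}

match_key <- function(doc, mod, event_matcher) {
  theme <- if (event_matcher == "by-id") {
    mod$theme
  } else {
    event_signature(doc, mod$theme)
  }
  paste(doc$doc_id, mod$type, theme, sep = "\r")
}

#' Score predicted modifications against gold
#'
#' @param gold,pred Lists of `(doc, mod)` pairs — each element a list with
#'   fields `doc` (an `eventmod_document`) and `mod` (a
#'   [modification_record()]).  Convenience: a list of documents is accepted
#'   for `gold`, in which case each document's own modifications are used.
#' @param event_matcher `"by-id"` (theme events match when their ids match
#'   within a document — the normal regime when predictions are made over a
#'   given event set) or `"structural"` (same type, trigger span and
#'   role-argument spans, recursive through nested events).
#' @return An object of class `eventmod_score`: per-type and overall
#'   `tp`, `fp`, `fn`, `recall`, `precision`, `f1`.
#' @export
score_modifications <- function(gold, pred,
                                event_matcher = c("by-id", "structural")) {
  event_matcher <- match.arg(event_matcher)
  as_pairs <- function(x) {
    if (!length(x)) return(list())
    if (!inherits(x[[1]], "eventmod_document")) return(x)
    # list of documents: expand their own modification layer
    out <- list()
    for (doc in x) {
      for (m in doc$modifications) {
        out[[length(out) + 1L]] <- list(doc = doc, mod = m)
      }
    }
    out
  }
  gold <- as_pairs(gold)
  pred <- as_pairs(pred)

  pred_ids <- vapply(pred, function(p) paste(p$doc$doc_id, p$mod$id), "")
  if (anyDuplicated(pred_ids)) {
    stop("duplicate prediction ids within a document: ",
         pred_ids[duplicated(pred_ids)][1L], call. = FALSE)
  }

  gold_keys <- vapply(gold, function(p) match_key(p$doc, p$mod, event_matcher), "")
  pred_keys <- vapply(pred, function(p) match_key(p$doc, p$mod, event_matcher), "")
  gold_types <- vapply(gold, function(p) p$mod$type, "")
  pred_types <- vapply(pred, function(p) p$mod$type, "")

  types <- c("Negation", "Speculation")
  counts <- list()
  used <- logical(length(gold))
  matched_pred <- logical(length(pred))
  for (i in seq_along(pred)) {          # greedy one-to-one in document order
    j <- which(!used & gold_keys == pred_keys[[i]])
    if (length(j)) {
      used[j[[1]]] <- TRUE
      matched_pred[[i]] <- TRUE
    }
  }
  cell <- function(sel_gold, sel_pred) {
    tp <- sum(matched_pred[sel_pred])
    fp <- sum(!matched_pred[sel_pred])
    fn <- sum(!used[sel_gold])
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    f <- if (r + p > 0) 2 * r * p / (r + p) else 0
    list(tp = tp, fp = fp, fn = fn, recall = r, precision = p, f1 = f)
  }
  for (ty in types) {
    counts[[ty]] <- cell(gold_types == ty, pred_types == ty)
  }
  counts$overall <- cell(rep(TRUE, length(gold)), rep(TRUE, length(pred)))
  structure(counts, class = "eventmod_score")
}

#' @export
print.eventmod_score <- function(x, ...) {
  cat(format_score_report(x), sep = "\n")
  invisible(x)
}

#' Render a score report
#'
#' @param x An `eventmod_score`.
#' @param format `"tsv"` (percentages with one decimal) or `"json"`.
#' @return Character vector of report lines (tsv) or a JSON string.
#' @export
format_score_report <- function(x, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA))
  }
  rows <- vapply(names(x), function(nm) {
    c0 <- x[[nm]]
    sprintf("%s\t%d\t%d\t%d\t%.1f\t%.1f\t%.1f", nm, c0$tp, c0$fp, c0$fn,
            100 * c0$recall, 100 * c0$precision, 100 * c0$f1)
  }, "")
  c("type\ttp\tfp\tfn\tR\tP\tF", unname(rows))
}
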