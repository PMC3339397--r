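#' @title Multi-parser feature combination
#' @description A sentence may have zero, one, or several RMRS analyses
#'   (e.g. from a precision grammar and a statistical parser).  Three
#'   strategies merge their feature evidence: fallback (`fb`) trusts the
#'   highest-priority available source, union (`cb`) pools features from all
#'   sources, and tagged union (`cb_tagged`) additionally keeps a
#'   source-prefixed copy of every feature so the learner can weigh sources
#'   differently.
#' @name combiner
NULL

#' Combination strategy
#'
#' @param mode One of `"fb"` (fallback), `"cb"` (union), `"cb_tagged"`
#'   (union plus source-tagged copies).
#' @param priority Ordered character vector of source tags; required for
#'   `fb`, where the first available source wins.
#' @return An object of class `eventmod_strategy`.
#' @export
combination_strategy <- function(mode = c("fb", "cb", "cb_tagged"),
                                 priority = c("ERG", "RASP")) {
  mode <- match.arg(mode)
  if (mode == "fb" && !length(priority)) {
    stop("fallback strategy needs a non-empty source priority list",
         call. = FALSE)
  }
  structure(list(mode = mode, priority = priority),
            class = "eventmod_strategy")
}

#' Combine RMRS-derived features across parser sources
#'
#' @param bundle Named list mapping source tag to an [rmrs()] analysis (or
#'   `NULL` when that parser failed on the sentence).
#' @param strategy A [combination_strategy()].
#' @param extractor Function `(rmrs) -> character vector` computing the
#'   per-analysis feature set (closing over triggers and lexicons).
#' @return Character vector of feature names; empty when no source has an
#'   analysis.
#' @export
combine_features <- function(bundle, strategy, extractor) {
  available <- bundle[!vapply(bundle, is.null, logical(1))]
  if (!length(available)) return(character())
  if (strategy$mode == "fb") {
    for (src in strategy$priority) {
      if (!is.null(bundle[[src]])) return(unique(extractor(bundle[[src]])))
    }
    return(character())
  }
  feats <- character()
  for (src in names(available)) {
    f <- extractor(available[[src]])
    feats <- c(feats, f,
               if (strategy$mode == "cb_tagged") paste0(src, ":", f))
  }
  unique(feats)
}

#' Assemble the final feature vector for one instance
#'
#' Union of the RMRS-derived and bag-of-words feature sets.  Both empty
#' yields the empty vector, on which a trained classifier falls back to the
#' class priors.
#'
#' @param rmrs_features,bow Character vectors of feature names (`NULL`
#'   allowed).
#' @return Character vector of feature names (a set).
#' @export
assemble_instance <- function(rmrs_features, bow = NULL) {
  unique(c(rmrs_features, bow))
}
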