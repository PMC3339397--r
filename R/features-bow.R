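#' @title Bag-of-words context-window features
#' @description Shallow features from a sliding window of tokens around the
#'   trigger token, clamped at the sentence boundary.  These are robust (100%
#'   coverage) and complement the scope-based features, which are only
#'   available for parsed sentences.
#' @name bow_features
NULL

#' Tokenize a sentence with character offsets
#'
#' A regex tokenizer: maximal alphanumeric runs (hyphens and pluses kept
#' word-internal) and single punctuation marks, each with its document-level
#' character span.  Pre-tokenized sidecar input may be supplied instead
#' wherever a tokenized sentence is expected.
#'
#' @param text Full document text.
#' @param span `(start, end)` 0-based end-exclusive sentence span.
#' @return An object of class `eventmod_tokens`: list with `tokens`
#'   (data.frame of `surface`, `start`, `end`) and `sentence_span`.
#' @export
tokenize_sentence <- function(text, span) {
  sent <- substr(text, span[1L] + 1L, span[2L])
  m <- gregexpr("[A-Za-z0-9][A-Za-z0-9+-]*|[^A-Za-z0-9[:space:]]", sent)[[1]]
  if (m[1L] == -1L) {
    tokens <- data.frame(surface = character(), start = integer(),
                         end = integer())
  } else {
    starts <- span[1L] + as.integer(m) - 1L
    lens <- attr(m, "match.length")
    tokens <- data.frame(
      surface = regmatches(sent, list(m))[[1]],
      start = starts,
      end = starts + lens
    )
  }
  tokenized_sentence(tokens, span)
}

#' @rdname tokenize_sentence
#' @param tokens Data frame with columns `surface`, `start`, `end`
#'   (document coordinates, ordered, non-overlapping).
#' @export
tokenized_sentence <- function(tokens, span) {
  if (nrow(tokens)) {
    if (is.unsorted(tokens$start) ||
        any(tokens$start < span[1L]) || any(tokens$end > span[2L])) {
      stop("token spans must be ordered and lie within the sentence span",
           call. = FALSE)
    }
  }
  structure(list(tokens = tokens, sentence_span = as.integer(span)),
            class = "eventmod_tokens")
}

#' Window specification
#'
#' @param left Tokens preceding the trigger token (0–5 in evaluated
#'   configurations).
#' @param right Tokens following the trigger token.
#' @return An object of class `eventmod_window`.
#' @export
window_spec <- function(left, right) {
  if (left < 0 || right < 0) stop("window sizes must be >= 0", call. = FALSE)
  structure(list(left = as.integer(left), right = as.integer(right)),
            class = "eventmod_window")
}

#' Parse a window-size mnemonic like "W+3-4"
#'
#' `W+a-b` denotes `a` following and `b` preceding tokens (so `W+3-4` is
#' four words to the left and three to the right — the sign marks the
#' direction relative to the trigger, not an arithmetic order).
#'
#' @param s Mnemonic string.
#' @return A [window_spec()].
#' @export
parse_window <- function(s) {
  m <- regexec("^W\\+([0-9]+)-([0-9]+)$", s)
  g <- regmatches(s, m)[[1]]
  if (!length(g)) stop("bad window mnemonic: ", s, call. = FALSE)
  window_spec(left = as.integer(g[[3]]), right = as.integer(g[[2]]))
}

#' Locate the token corresponding to a trigger
#'
#' Returns the token with maximal character overlap with the trigger span;
#' ties break toward the earlier token.  Zero overlap with every token is an
#' error (the trigger lies outside the sentence).
#'
#' @param s A [tokenize_sentence()] result.
#' @param trigger A [text_bound()] or any list with `start` and `end`.
#' @return 1-based token index.
#' @export
locate_trigger_token <- function(s, trigger) {
  tk <- s$tokens
  if (!nrow(tk)) stop("sentence has no tokens", call. = FALSE)
  overlap <- pmax(0L, pmin(tk$end, trigger$end) - pmax(tk$start, trigger$start))
  if (max(overlap) == 0L) {
    stop("trigger [", trigger$start, ",", trigger$end,
         ") overlaps no token of the sentence", call. = FALSE)
  }
  which.max(overlap)
}

#' Bag-of-words window features around a trigger token
#'
#' Emits `BOW=<token>` for every token in the window (lowercased, duplicates
#' collapsed, truncated at the sentence edges — windows never cross a
#' sentence boundary) plus `BOWTRIG=<trigger token>` for the trigger token
#' itself, which is excluded from the bag.
#'
#' @param s A [tokenize_sentence()] result.
#' @param trigger_index 1-based index of the trigger token.
#' @param w A [window_spec()].
#' @return Character vector of feature names (a set).
#' @export
window_features <- function(s, trigger_index, w) {
  tk <- s$tokens
  n <- nrow(tk)
  if (trigger_index < 1L || trigger_index > n) {
    stop("trigger_index out of range", call. = FALSE)
  }
  lo <- max(1L, trigger_index - w$left)
  hi <- min(n, trigger_index + w$right)
  idx <- setdiff(seq(lo, hi), trigger_index)
  feats <- if (length(idx)) paste0("BOW=", tolower(tk$surface[idx]))
           else character()
  unique(c(feats, paste0("BOWTRIG=", tolower(tk$surface[trigger_index]))))
}
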