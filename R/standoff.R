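#' @title BioNLP shared-task standoff annotation I/O
#' @description Readers and writers for the BioNLP 2009 Shared Task standoff
#'   format: a plain-text document plus a `.a1` file holding protein
#'   annotations and a `.a2` file holding event triggers, events and
#'   modification (Negation/Speculation) meta-annotations.  All offsets are
#'   0-based, end-exclusive character indices into the document text.
#' @name standoff
NULL

#' Construct a text-bound annotation
#'
#' A text-bound annotation ties a type label to a character span of the
#' document.  Proteins (from `.a1`) and event triggers (from `.a2`) are both
#' text-bound.
#'
#' @param id Annotation identifier, conventionally `T`-prefixed.
#' @param type Label string, e.g. `"Protein"` or `"Binding"`.
#' @param start,end 0-based, end-exclusive character offsets.
#' @param surface Surface string; must equal the document text slice.
#' @return An object of class `eventmod_textbound`.
#' @export
text_bound <- function(id, type, start, end, surface) {
  if (start >= end) {
    stop("text_bound: start must be < end for ", id, call. = FALSE)
  }
  structure(
    list(id = id, type = type, start = as.integer(start),
         end = as.integer(end), surface = surface),
    class = "eventmod_textbound"
  )
}

#' Construct an event record
#'
#' An event is an n-tuple anchored on a trigger text-bound, with role-labelled
#' arguments that reference proteins or other events.
#'
#' @param id `E`-prefixed identifier.
#' @param type Event type string (e.g. `"Phosphorylation"`).
#' @param trigger Id of the trigger text-bound.
#' @param args Named character vector mapping role name (`Theme`, `Cause`,
#'   ...) to the id of the referenced annotation.
#' @return An object of class `eventmod_event`.
#' @export
event_record <- function(id, type, trigger, args = character()) {
  if (length(args) && (is.null(names(args)) || any(!nzchar(names(args))))) {
    stop("event_record: all arguments must have non-empty role names",
         call. = FALSE)
  }
  structure(
    list(id = id, type = type, trigger = trigger, args = args),
    class = "eventmod_event"
  )
}

#' Construct a modification record
#'
#' Marks an event as negated or speculated, mirroring `.a2` `M` lines.
#'
#' @param id `M`-prefixed identifier.
#' @param type `"Negation"` or `"Speculation"`.
#' @param theme Id of the modified event.
#' @return An object of class `eventmod_modification`.
#' @export
modification_record <- function(id, type, theme) {
  if (!type %in% c("Negation", "Speculation")) {
    stop("modification_record: type must be Negation or Speculation, got ",
         type, call. = FALSE)
  }
  structure(
    list(id = id, type = type, theme = theme),
    class = "eventmod_modification"
  )
}

split_tab <- function(line) strsplit(line, "\t", fixed = TRUE)[[1]]

parse_textbound_line <- function(line, doc_id) {
  fields <- split_tab(line)
  if (length(fields) < 3) {
    stop("malformed text-bound line in ", doc_id, ": ", line, call. = FALSE)
  }
  head <- strsplit(fields[[2]], " ", fixed = TRUE)[[1]]
  if (length(head) != 3) {
    stop("malformed text-bound header in ", doc_id, ": ", fields[[2]],
         call. = FALSE)
  }
  text_bound(fields[[1]], head[[1]], as.integer(head[[2]]),
             as.integer(head[[3]]), fields[[3]])
}

parse_event_line <- function(line, doc_id) {
  fields <- split_tab(line)
  parts <- strsplit(fields[[2]], " ", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, function(p) length(p) != 2, logical(1))
  if (any(bad)) {
    stop("malformed event line in ", doc_id, ": ", line, call. = FALSE)
  }
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  args <- vals[-1L]
  names(args) <- keys[-1L]
  event_record(fields[[1]], keys[[1]], vals[[1]], args)
}

validate_document <- function(doc) {
  tb_ids <- c(vapply(doc$proteins, `[[`, "", "id"),
              vapply(doc$triggers, `[[`, "", "id"))
  if (anyDuplicated(tb_ids)) {
    stop("duplicate text-bound id in ", doc$doc_id, ": ",
         tb_ids[duplicated(tb_ids)][1L], call. = FALSE)
  }
  for (tb in c(doc$proteins, doc$triggers)) {
    slice <- substr(doc$text, tb$start + 1L, tb$end)
    if (!identical(slice, tb$surface)) {
      stop("span/text mismatch for ", tb$id, " in ", doc$doc_id,
           ": annotation says ", dQuote(tb$surface),
           " but text slice is ", dQuote(slice), call. = FALSE)
    }
  }
  ev_ids <- vapply(doc$events, `[[`, "", "id")
  known <- c(tb_ids, ev_ids)
  for (ev in doc$events) {
    if (!ev$trigger %in% tb_ids) {
      stop("dangling trigger reference ", ev$trigger, " in event ", ev$id,
           " of ", doc$doc_id, call. = FALSE)
    }
    for (ref in ev$args) {
      if (!ref %in% known) {
        stop("dangling argument reference ", ref, " in event ", ev$id,
             " of ", doc$doc_id, call. = FALSE)
      }
    }
  }
  for (m in doc$modifications) {
    if (!m$theme %in% ev_ids) {
      stop("modification ", m$id, " in ", doc$doc_id,
           " references unknown event ", m$theme, call. = FALSE)
    }
  }
  if (length(doc$sentences)) {
    ss <- doc$sentences
    if (is.unsorted(ss[, 1L]) ||
        any(ss[, 2L] > nchar(doc$text)) || any(ss[, 1L] < 0L) ||
        any(ss[-1L, 1L] < ss[-nrow(ss), 2L])) {
      stop("sentence spans in ", doc$doc_id,
           " must be ordered, non-overlapping and within the text",
           call. = FALSE)
    }
  }
  invisible(doc)
}

#' Read a standoff document
#'
#' Parses document text together with its `.a1` (proteins) and optional `.a2`
#' (triggers, events, modifications) annotation and an optional sentence-span
#' sidecar.  Every text-bound surface string is validated against the text at
#' its offsets and all references are resolved; a dangling id or a span/text
#' mismatch is an error.
#'
#' @param text Document text as a single string, or a path/connection read
#'   with [readChar()] semantics (lines are re-joined with `"\n"`).
#' @param a1 Character vector of `.a1` lines, or a file path.
#' @param a2 Character vector of `.a2` lines, or a file path; `NULL` means no
#'   `.a2` layer (events and modifications come back empty).
#' @param sentences Two-column matrix of 0-based end-exclusive sentence
#'   spans, a path to a tab-separated sidecar file, or `NULL`.
#' @param doc_id Document identifier.
#' @return An object of class `eventmod_document`: a list with fields
#'   `doc_id`, `text`, `sentences` (integer matrix), `proteins`, `triggers`
#'   (lists of [text_bound()]), `events`, and `modifications`.
#' @export
read_document <- function(text, a1 = character(), a2 = NULL,
                          sentences = NULL, doc_id = "doc") {
  read_lines_arg <- function(x) {
    if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
      readLines(x, warn = FALSE)
    } else {
      x
    }
  }
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    text <- readChar(text, file.info(text)$size, useBytes = TRUE)
  }
  text <- paste(text, collapse = "\n")
  a1 <- read_lines_arg(a1)
  if (!is.null(a2)) a2 <- read_lines_arg(a2)
  if (is.character(sentences)) {
    lines <- readLines(sentences, warn = FALSE)
    lines <- lines[nzchar(lines)]
    sentences <- do.call(rbind, lapply(lines, function(l) {
      as.integer(split_tab(l)[1:2])
    }))
  }
  if (is.null(sentences)) {
    sentences <- matrix(integer(), ncol = 2L)
  }
  sentences <- matrix(as.integer(sentences), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))

  proteins <- lapply(a1[nzchar(a1)], parse_textbound_line, doc_id = doc_id)
  triggers <- list()
  events <- list()
  modifications <- list()
  for (line in a2[nzchar(a2)]) {
    tag <- substr(line, 1L, 1L)
    if (tag == "T") {
      triggers[[length(triggers) + 1L]] <- parse_textbound_line(line, doc_id)
    } else if (tag == "E") {
      events[[length(events) + 1L]] <- parse_event_line(line, doc_id)
    } else if (tag == "M") {
      fields <- split_tab(line)
      head <- strsplit(fields[[2]], " ", fixed = TRUE)[[1]]
      modifications[[length(modifications) + 1L]] <-
        modification_record(fields[[1]], head[[1]], head[[2]])
    } else {
      stop("unsupported annotation line type ", dQuote(tag), " in ",
           doc_id, ": ", line, call. = FALSE)
    }
  }
  doc <- structure(
    list(doc_id = doc_id, text = text, sentences = sentences,
         proteins = proteins, triggers = triggers, events = events,
         modifications = modifications),
    class = "eventmod_document"
  )
  validate_document(doc)
}

#' @export
print.eventmod_document <- function(x, ...) {
  cat(sprintf(
    "<standoff document %s: %d chars, %d sentences, %d proteins, %d triggers, %d events, %d modifications>\n",
    x$doc_id, nchar(x$text), nrow(x$sentences), length(x$proteins),
    length(x$triggers), length(x$events), length(x$modifications)))
  invisible(x)
}

#' Serialize predicted modifications as a2-format M lines
#'
#' Emits one line per prediction, re-numbered `M1..Mn` in input order, so the
#' output can be appended to the document's `.a2` event layer and re-read.
#'
#' @param doc An [read_document()] document whose events the predictions
#'   reference.
#' @param predictions List of [modification_record()]s.
#' @return Character vector of `M` lines (empty for no predictions).
#' @export
write_modifications <- function(doc, predictions) {
  ev_ids <- vapply(doc$events, `[[`, "", "id")
  lines <- character(length(predictions))
  for (i in seq_along(predictions)) {
    p <- predictions[[i]]
    if (!p$theme %in% ev_ids) {
      stop("prediction references unknown event ", p$theme, " in ",
           doc$doc_id, call. = FALSE)
    }
    lines[[i]] <- sprintf("M%d\t%s %s", i, p$type, p$theme)
  }
  lines
}

#' Serialize a document's full a1/a2 annotation layers
#'
#' Round-trip companions to [read_document()]: `write_a1()` emits the protein
#' lines and `write_a2()` the trigger/event/modification lines in their
#' original order.
#'
#' @param doc An `eventmod_document`.
#' @return Character vector of annotation lines.
#' @export
write_a1 <- function(doc) {
  vapply(doc$proteins, format_textbound_line, "")
}

format_textbound_line <- function(tb) {
  sprintf("%s\t%s %d %d\t%s", tb$id, tb$type, tb$start, tb$end, tb$surface)
}

#' @rdname write_a1
#' @export
write_a2 <- function(doc) {
  t_lines <- vapply(doc$triggers, format_textbound_line, "")
  e_lines <- vapply(doc$events, function(ev) {
    args <- if (length(ev$args)) {
      paste0(" ", paste0(names(ev$args), ":", ev$args, collapse = " "))
    } else ""
    sprintf("%s\t%s:%s%s", ev$id, ev$type, ev$trigger, args)
  }, "")
  m_lines <- vapply(doc$modifications, function(m) {
    sprintf("%s\t%s %s", m$id, m$type, m$theme)
  }, "")
  c(t_lines, e_lines, m_lines)
}

#' Locate the sentence containing a span
#'
#' Context windows and RMRS analyses are per-sentence, so annotations must be
#' attributable to a unique sentence.
#'
#' @param doc An `eventmod_document` with sentence spans.
#' @param start,end 0-based end-exclusive span.
#' @return 1-based sentence index.
#' @export
sentence_of <- function(doc, start, end) {
  ss <- doc$sentences
  if (!nrow(ss)) stop("document ", doc$doc_id, " has no sentence spans",
                      call. = FALSE)
  hit <- which(ss[, 1L] <= start & end <= ss[, 2L])
  if (length(hit) == 1L) return(hit)
  overlap <- which(ss[, 1L] < end & start < ss[, 2L])
  if (length(overlap) > 1L) {
    stop("span [", start, ",", end, ") straddles a sentence boundary in ",
         doc$doc_id, call. = FALSE)
  }
  stop("span [", start, ",", end, ") lies in no sentence of ", doc$doc_id,
       call. = FALSE)
}
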