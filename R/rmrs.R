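#' @title Robust Minimal Recursion Semantics structures and scope algebra
#' @description An RMRS analysis is a flat bag of elementary predications
#'   (EPs) — each a predicate instance with a scope label, character span,
#'   ARG0 variable and role-labelled arguments — plus two constraint sets:
#'   qeq constraints relating a handle to a label ("equality modulo
#'   quantifiers") and in-g constraints declaring two labels equivalent.
#'   The scope features downstream need only the outscoping partial order
#'   these induce, not full scope resolution.
#' @name rmrs
NULL

KNOWN_ROLES <- c(paste0("ARG", 1:9), "RSTR", "BODY",
                 "L-INDEX", "R-INDEX", "L-HNDL", "R-HNDL")

is_handle <- function(v) grepl("^h[0-9]+$", v)

#' Construct an elementary predication
#'
#' @param label Scope-label identifier, e.g. `"l104"`.
#' @param pred Predicate name, e.g. `"_differentiation_n_1"` for surface
#'   predicates or `"neg_rel"` for grammar-internal ones.
#' @param cfrom,cto Character span in document coordinates (end-exclusive),
#'   or `NA` for covert EPs such as default quantifiers that correspond to
#'   no surface word.
#' @param arg0 The EP's intrinsic (non-handle) variable, e.g. `"x23"`.
#' @param args Named character vector of further arguments: role name
#'   (`ARG1`..`ARGn`, `RSTR`, `BODY`, `L-INDEX`, `R-INDEX`, `L-HNDL`,
#'   `R-HNDL`) to variable or handle.
#' @return An object of class `eventmod_ep`.
#' @export
ep <- function(label, pred, cfrom = NA_integer_, cto = NA_integer_,
               arg0 = "u0", args = character()) {
  if (!is.na(cfrom) && !is.na(cto) && cfrom > cto) {
    stop("ep ", label, ": cfrom must be <= cto", call. = FALSE)
  }
  if (is_handle(arg0)) {
    stop("ep ", label, ": ARG0 must be an instance variable, not a handle",
         call. = FALSE)
  }
  if (length(args)) {
    unknown <- setdiff(names(args), KNOWN_ROLES)
    if (length(unknown)) {
      stop("ep ", label, ": unknown role name(s) ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(label = label, pred = pred, cfrom = as.integer(cfrom),
         cto = as.integer(cto), arg0 = arg0,
         args = if (length(args)) args else
           structure(character(), names = character())),
    class = "eventmod_ep"
  )
}

#' Construct an RMRS analysis for one sentence
#'
#' @param eps List of [ep()]s.
#' @param qeqs Two-column character matrix (or list of pairs) of
#'   `(handle, label)` qeq constraints.
#' @param ings Two-column character matrix (or list of pairs) of
#'   `(label, label)` in-g constraints.
#' @param sentence_span `(start, end)` of the analyzed sentence in document
#'   coordinates.
#' @param source Parser tag, e.g. `"ERG"` or `"RASP"`; free string.
#' @param top Designated top handle (stored; unused by any feature).
#' @return An object of class `eventmod_rmrs`.
#' @export
rmrs <- function(eps = list(), qeqs = NULL, ings = NULL,
                 sentence_span = c(0L, 0L), source = "ERG", top = NA_character_) {
  as_pairs <- function(x, what) {
    if (is.null(x) || !length(x)) {
      return(matrix(character(), ncol = 2L))
    }
    if (is.list(x)) x <- do.call(rbind, lapply(x, function(p) c(p[[1]], p[[2]])))
    m <- matrix(as.character(x), ncol = 2L)
    if (anyNA(m)) stop("malformed ", what, " constraint", call. = FALSE)
    m
  }
  qeqs <- as_pairs(qeqs, "qeq")
  ings <- as_pairs(ings, "in-g")
  labels <- vapply(eps, `[[`, "", "label")
  bad_q <- setdiff(qeqs[, 2L], labels)
  if (length(bad_q)) {
    stop("qeq constraint references label(s) absent from the EP bag: ",
         paste(bad_q, collapse = ", "), call. = FALSE)
  }
  bad_i <- setdiff(c(ings), labels)
  if (length(bad_i)) {
    stop("in-g constraint references label(s) absent from the EP bag: ",
         paste(bad_i, collapse = ", "), call. = FALSE)
  }
  structure(
    list(eps = eps, qeqs = qeqs, ings = ings,
         sentence_span = as.integer(sentence_span),
         source = source, top = top),
    class = "eventmod_rmrs"
  )
}

#' @export
print.eventmod_rmrs <- function(x, ...) {
  cat(sprintf("<RMRS [%s] span %d:%d — %d EPs, %d qeqs, %d in-gs>\n",
              x$source, x$sentence_span[1L], x$sentence_span[2L],
              length(x$eps), nrow(x$qeqs), nrow(x$ings)))
  invisible(x)
}

#' @export
print.eventmod_ep <- function(x, ...) {
  span <- if (is.na(x$cfrom)) "-" else sprintf("%d:%d", x$cfrom, x$cto)
  args <- if (length(x$args)) {
    paste0(" ", paste0(names(x$args), "=", x$args, collapse = " "))
  } else ""
  cat(sprintf("%s:%s <%s> ARG0=%s%s\n", x$label, x$pred, span, x$arg0, args))
  invisible(x)
}

# Union-find over label alias (in-g) classes; returns a named vector mapping
# each label to its class representative.
label_alias_map <- function(r) {
  labels <- unique(vapply(r$eps, `[[`, "", "label"))
  parent <- stats::setNames(labels, labels)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(r$ings)) {
    for (i in seq_len(nrow(r$ings))) {
      a <- find(r$ings[i, 1L]); b <- find(r$ings[i, 2L])
      if (a != b) parent[[a]] <- b
    }
  }
  vapply(labels, find, "")
}

#' Expand qeq constraints over in-g label equivalences
#'
#' An in-g constraint declares two labels equal for constraint purposes: if
#' `h qeq l` holds and `l` and `l'` share an alias class, then `h qeq l'` is
#' inferred.  Returns the closure of the qeq set under this propagation.
#'
#' @param r An [rmrs()] analysis.
#' @return Two-column character matrix of `(handle, label)` pairs.
#' @export
effective_qeqs <- function(r) {
  if (!nrow(r$qeqs)) return(r$qeqs)
  alias <- label_alias_map(r)
  labels <- names(alias)
  out <- vector("list", nrow(r$qeqs))
  for (i in seq_len(nrow(r$qeqs))) {
    h <- r$qeqs[i, 1L]
    cls <- alias[[r$qeqs[i, 2L]]]
    members <- labels[alias == cls]
    out[[i]] <- cbind(rep(h, length(members)), unname(members))
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  unique(m)
}

#' Build the scope graph of an RMRS
#'
#' EP `A` immediately outscopes EP `B` when `A` has a handle argument that
#' qeq-outscopes `B`'s label (after in-g propagation); `outscopes` is the
#' transitive closure.  Cyclic constraint sets (malformed parser output) are
#' tolerated: the closure is plain reachability.
#'
#' @param r An [rmrs()] analysis.
#' @param direct_label_edges Additionally treat a handle argument that is
#'   literally equal to an EP's label as outscoping (some RMRS producers emit
#'   direct equalities).  Off by default: immediate outscoping is qeq-only.
#' @return An object of class `eventmod_scopegraph` with fields `labels`
#'   (per-EP), `alias` (label to alias-class representative), `immediate`
#'   and `closure` (n-by-n logical matrices over EP indices).
#' @export
build_scope_graph <- function(r, direct_label_edges = FALSE) {
  n <- length(r$eps)
  imm <- matrix(FALSE, n, n)
  labels <- vapply(r$eps, `[[`, "", "label")
  alias <- label_alias_map(r)
  eff <- effective_qeqs(r)
  if (n) {
    # handle -> set of outscoped EP indices
    outscoped_by_handle <- new.env(parent = emptyenv())
    if (nrow(eff)) {
      for (i in seq_len(nrow(eff))) {
        h <- eff[i, 1L]
        idx <- which(labels == eff[i, 2L])
        assign(h, union(mget(h, envir = outscoped_by_handle,
                             ifnotfound = list(integer()))[[1]], idx),
               envir = outscoped_by_handle)
      }
    }
    for (a in seq_len(n)) {
      hargs <- r$eps[[a]]$args[is_handle(r$eps[[a]]$args)]
      for (h in hargs) {
        tgt <- mget(h, envir = outscoped_by_handle,
                    ifnotfound = list(integer()))[[1]]
        if (direct_label_edges) tgt <- union(tgt, which(labels == h))
        imm[a, tgt] <- TRUE
      }
    }
  }
  closure <- transitive_closure(imm)
  structure(
    list(labels = labels, alias = alias, immediate = imm, closure = closure),
    class = "eventmod_scopegraph"
  )
}

# Boolean reachability by repeated squaring; tolerates cycles.
transitive_closure <- function(m) {
  n <- nrow(m)
  if (!n) return(m)
  reach <- m
  repeat {
    step <- (reach %*% reach) > 0
    nxt <- reach | step
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

ep_index <- function(g, x) {
  if (is.numeric(x)) {
    i <- as.integer(x)
    if (i < 1L || i > length(g$labels)) {
      stop("EP index ", i, " not in scope graph", call. = FALSE)
    }
    return(i)
  }
  lbl <- if (inherits(x, "eventmod_ep")) x$label else as.character(x)
  i <- which(g$labels == lbl)
  if (!length(i)) stop("EP with label ", lbl, " not in scope graph",
                       call. = FALSE)
  i[[1]]
}

#' Test the outscopes relation
#'
#' @param g A scope graph from [build_scope_graph()].
#' @param a,b EPs, labels, or EP indices.
#' @return `TRUE` iff `a` (transitively) outscopes `b`.
#' @export
outscopes <- function(g, a, b) {
  g$closure[ep_index(g, a), ep_index(g, b)]
}

#' Test the shared-argument relation between two EPs
#'
#' True when some non-handle variable fills an argument slot of both EPs,
#' optionally restricted to given role sets on either side.  `ARG0` counts
#' as a role.
#'
#' @param r An [rmrs()] analysis.
#' @param a,b Two distinct EPs (objects, labels, or indices into `r$eps`).
#' @param roles_a,roles_b Optional character vectors restricting which roles
#'   of `a` / `b` may carry the shared variable; `NULL` means any role.
#' @return Logical.
#' @export
shared_argument <- function(r, a, b, roles_a = NULL, roles_b = NULL) {
  resolve <- function(x) {
    if (inherits(x, "eventmod_ep")) return(x)
    if (is.numeric(x)) return(r$eps[[x]])
    lbls <- vapply(r$eps, `[[`, "", "label")
    r$eps[[which(lbls == x)[[1]]]]
  }
  a <- resolve(a); b <- resolve(b)
  slot_vars <- function(e, roles) {
    vars <- c(ARG0 = e$arg0, e$args)
    if (!is.null(roles)) vars <- vars[names(vars) %in% roles]
    vars[!is_handle(vars)]
  }
  va <- slot_vars(a, roles_a)
  vb <- slot_vars(b, roles_b)
  length(intersect(va, vb)) > 0
}

#' Find the trigger EPs for an event trigger
#'
#' The trigger EPs of an event are those whose character span encompasses
#' the trigger word's span.  Covert EPs (no span) are never returned.  An
#' empty result is legal and signals that the parser produced no EP for the
#' trigger.
#'
#' @param r An [rmrs()] analysis.
#' @param trigger A [text_bound()] or any list with `start` and `end`.
#' @param mode `"contain"` (default): EP span must contain the trigger span,
#'   equality allowed.  `"overlap"`: any character overlap suffices (for
#'   noisy tokenisation).
#' @return Integer vector of indices into `r$eps`.
#' @export
trigger_eps <- function(r, trigger, mode = c("contain", "overlap")) {
  mode <- match.arg(mode)
  hits <- integer()
  for (i in seq_along(r$eps)) {
    e <- r$eps[[i]]
    if (is.na(e$cfrom) || is.na(e$cto)) next
    ok <- if (mode == "contain") {
      e$cfrom <= trigger$start && e$cto >= trigger$end
    } else {
      e$cfrom < trigger$end && trigger$start < e$cto
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

## ---- serialization ----

#' Serialize / parse RMRS analyses
#'
#' Two dialects are supported.  `"json"`: a single object with keys
#' `source`, `sentence_span`, `top`, `eps` (each
#' `{"label","pred","span"|null,"arg0","args"}`), `qeqs`, `ings`.
#' `"lines"`: one record per line —
#' `EP <label> <pred> <cfrom>:<cto> ARG0=<v> [ROLE=<v> ...]` (span `-` when
#' covert), `QEQ <h> <l>`, `ING <l> <l>`, plus optional `SOURCE`, `SPAN`,
#' `TOP` headers.
#'
#' @param r An [rmrs()] analysis.
#' @param dialect `"json"` or `"lines"`.
#' @return `write_rmrs()`: a character scalar (json) or vector of lines;
#'   `parse_rmrs()`: an `eventmod_rmrs`.
#' @export
write_rmrs <- function(r, dialect = c("json", "lines")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    obj <- list(
      source = r$source,
      sentence_span = r$sentence_span,
      top = if (is.na(r$top)) NULL else r$top,
      eps = lapply(r$eps, function(e) {
        list(label = e$label, pred = e$pred,
             span = if (is.na(e$cfrom)) NULL else c(e$cfrom, e$cto),
             arg0 = e$arg0,
             args = as.list(e$args))
      }),
      qeqs = apply(r$qeqs, 1L, function(p) as.list(p), simplify = FALSE),
      ings = apply(r$ings, 1L, function(p) as.list(p), simplify = FALSE)
    )
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"))
  }
  lines <- c(
    paste("SOURCE", r$source),
    paste("SPAN", r$sentence_span[1L], r$sentence_span[2L]),
    if (!is.na(r$top)) paste("TOP", r$top),
    vapply(r$eps, function(e) {
      span <- if (is.na(e$cfrom)) "-" else sprintf("%d:%d", e$cfrom, e$cto)
      args <- if (length(e$args)) {
        paste0(" ", paste0(names(e$args), "=", e$args, collapse = " "))
      } else ""
      sprintf("EP %s %s %s ARG0=%s%s", e$label, e$pred, span, e$arg0, args)
    }, ""),
    if (nrow(r$qeqs)) paste("QEQ", r$qeqs[, 1L], r$qeqs[, 2L]),
    if (nrow(r$ings)) paste("ING", r$ings[, 1L], r$ings[, 2L])
  )
  lines
}

#' @rdname write_rmrs
#' @param source Serialized form: a JSON string (or file path) for the json
#'   dialect, a character vector of lines (or file path) for the lines
#'   dialect.
#' @export
parse_rmrs <- function(source, dialect = c("json", "lines")) {
  dialect <- match.arg(dialect)
  if (length(source) == 1L && !grepl("[\n{]", source) && file.exists(source)) {
    source <- readLines(source, warn = FALSE)
    if (dialect == "json") source <- paste(source, collapse = "\n")
  }
  if (dialect == "json") {
    obj <- jsonlite::fromJSON(source, simplifyVector = FALSE)
    eps <- lapply(obj$eps, function(e) {
      ep(label = e$label, pred = e$pred,
         cfrom = if (is.null(e$span)) NA_integer_ else e$span[[1]],
         cto = if (is.null(e$span)) NA_integer_ else e$span[[2]],
         arg0 = e$arg0,
         args = unlist(e$args) %||% character())
    })
    pairs <- function(x) lapply(x, function(p) c(p[[1]], p[[2]]))
    return(rmrs(
      eps = eps, qeqs = pairs(obj$qeqs), ings = pairs(obj$ings),
      sentence_span = unlist(obj$sentence_span),
      source = obj$source %||% "ERG",
      top = obj$top %||% NA_character_
    ))
  }
  eps <- list(); qeqs <- list(); ings <- list()
  src <- "ERG"; span <- c(0L, 0L); top <- NA_character_
  for (line in source[nzchar(trimws(source))]) {
    toks <- strsplit(trimws(line), " +")[[1]]
    kind <- toks[[1]]
    if (kind == "SOURCE") {
      src <- toks[[2]]
    } else if (kind == "SPAN") {
      span <- as.integer(toks[2:3])
    } else if (kind == "TOP") {
      top <- toks[[2]]
    } else if (kind == "QEQ") {
      qeqs[[length(qeqs) + 1L]] <- toks[2:3]
    } else if (kind == "ING") {
      ings[[length(ings) + 1L]] <- toks[2:3]
    } else if (kind == "EP") {
      spanfield <- toks[[4]]
      if (spanfield == "-") {
        cfrom <- NA_integer_; cto <- NA_integer_
      } else {
        se <- as.integer(strsplit(spanfield, ":", fixed = TRUE)[[1]])
        cfrom <- se[[1]]; cto <- se[[2]]
      }
      kv <- strsplit(toks[-(1:4)], "=", fixed = TRUE)
      roles <- vapply(kv, `[[`, "", 1L)
      vals <- vapply(kv, `[[`, "", 2L)
      arg0 <- vals[roles == "ARG0"]
      if (!length(arg0)) {
        stop("EP line without ARG0: ", line, call. = FALSE)
      }
      rest <- stats::setNames(vals[roles != "ARG0"], roles[roles != "ARG0"])
      eps[[length(eps) + 1L]] <-
        ep(toks[[2]], toks[[3]], cfrom, cto, arg0[[1]], rest)
    } else {
      stop("unknown record type ", dQuote(kind), " in lines dialect",
           call. = FALSE)
    }
  }
  rmrs(eps = eps, qeqs = qeqs, ings = ings, sentence_span = span,
       source = src, top = top)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
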