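# Shared fixture builders and independent oracles for the scope algebra.

# Random well-formed RMRS instance (uses the current RNG state).
random_rmrs <- function(max_eps = 15L) {
  n <- sample(2:max_eps, 1L)
  labels <- paste0("l", sort(sample(1:500, n)))
  handle_pool <- paste0("h", sample(600:999, n + 3L))
  vars <- paste0("x", seq_len(max(2L, n %/% 2L)))
  eps <- lapply(seq_len(n), function(i) {
    args <- character()
    if (stats::runif(1) < 0.7) {
      args <- c(args, stats::setNames(sample(handle_pool, 1L), "ARG1"))
    }
    if (stats::runif(1) < 0.5) {
      args <- c(args, stats::setNames(sample(vars, 1L), "ARG2"))
    }
    ep(labels[[i]], sprintf("_p%d_v_1", i), i * 10L, i * 10L + 5L,
       sample(vars, 1L), args)
  })
  used_handles <- unique(unlist(lapply(eps, function(e) {
    e$args[grepl("^h", e$args)]
  })))
  nq <- sample(0:min(6L, n), 1L)
  qeqs <- if (nq > 0L && length(used_handles)) {
    lapply(seq_len(nq), function(i) {
      c(sample(used_handles, 1L), sample(labels, 1L))
    })
  }
  ni <- sample(0:3, 1L)
  ings <- if (ni > 0L && n >= 2L) {
    lapply(seq_len(ni), function(i) sample(labels, 2L))
  }
  rmrs(eps, qeqs, ings, c(0L, 1000L))
}

# Label equivalence classes by breadth-first search over the symmetric in-g
# relation (independent of the union-find used in the package).
oracle_alias_classes <- function(r) {
  labels <- vapply(r$eps, `[[`, "", "label")
  labels <- unique(labels)
  adj <- stats::setNames(rep(list(character()), length(labels)), labels)
  if (nrow(r$ings)) {
    for (i in seq_len(nrow(r$ings))) {
      a <- r$ings[i, 1L]; b <- r$ings[i, 2L]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  comp <- stats::setNames(rep(NA_integer_, length(labels)), labels)
  k <- 0L
  for (l in labels) {
    if (!is.na(comp[[l]])) next
    k <- k + 1L
    queue <- l
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[[cur]])) next
      comp[[cur]] <- k
      queue <- c(queue, adj[[cur]][is.na(comp[adj[[cur]]])])
    }
  }
  comp
}

# Effective qeq set computed from the BFS alias classes.
oracle_effective_qeqs <- function(r) {
  if (!nrow(r$qeqs)) return(character())
  comp <- oracle_alias_classes(r)
  out <- character()
  for (i in seq_len(nrow(r$qeqs))) {
    h <- r$qeqs[i, 1L]
    cls <- comp[[r$qeqs[i, 2L]]]
    for (l in names(comp)[comp == cls]) {
      out <- c(out, paste(h, l))
    }
  }
  sort(unique(out))
}

# EP-level reachability by per-node depth-first search over immediate
# edges built straight from the definition.
oracle_reachability <- function(r) {
  n <- length(r$eps)
  labels <- vapply(r$eps, `[[`, "", "label")
  comp <- oracle_alias_classes(r)
  adj <- rep(list(integer()), n)
  if (nrow(r$qeqs)) {
    for (a in seq_len(n)) {
      hargs <- r$eps[[a]]$args[grepl("^h[0-9]+$", r$eps[[a]]$args)]
      for (h in hargs) {
        for (i in seq_len(nrow(r$qeqs))) {
          if (r$qeqs[i, 1L] != h) next
          cls <- comp[[r$qeqs[i, 2L]]]
          tgt <- which(comp[labels] == cls)
          adj[[a]] <- union(adj[[a]], tgt)
        }
      }
    }
  }
  reach <- matrix(FALSE, n, n)
  for (s in seq_len(n)) {
    stack <- adj[[s]]
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (reach[s, cur]) next
      reach[s, cur] <- TRUE
      stack <- c(stack, adj[[cur]])
    }
  }
  reach
}

# Minimal one-trigger RMRS for feature-trace fixtures: a nominal trigger EP
# (label lt, ARG0 x1) plus caller-supplied cue EPs/constraints.
feature_fixture <- function(extra_eps = list(), qeqs = NULL, ings = NULL) {
  eps <- c(list(ep("l1", "_phosphorylation_n_1", 10L, 25L, "x1")), extra_eps)
  r <- rmrs(eps, qeqs = qeqs, ings = ings, sentence_span = c(0L, 60L))
  g <- build_scope_graph(r)
  tr <- trigger_eps(r, list(start = 10L, end = 25L))
  list(r = r, g = g, triggers = tr)
}

test_lexicons <- function() default_lexicons()

# Small two-sentence standoff document with one negated event.
small_doc <- function() {
  text <- "TRADD binds TES2. TES2 was not expressed."
  a1 <- c("T1\tProtein 0 5\tTRADD", "T2\tProtein 12 16\tTES2",
          "T3\tProtein 18 22\tTES2")
  a2 <- c("T4\tBinding 6 11\tbinds",
          "T5\tGene_expression 31 40\texpressed",
          "E1\tBinding:T4 Theme:T1 Theme2:T2",
          "E2\tGene_expression:T5 Theme:T3",
          "M1\tNegation E2")
  read_document(text, a1, a2, sentences = rbind(c(0L, 17L), c(18L, 41L)),
                doc_id = "D1")
}
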