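#' @title Maximum-entropy classifier over binary features
#' @description One binary maximum-entropy (logistic) model per subtask,
#'   trained by maximizing the L2-penalized conditional log-likelihood
#'   (Gaussian prior on the feature weights, intercept unpenalized).  An
#'   instance with no active features — e.g. an event in an unparsed
#'   sentence with bag-of-words features disabled — receives the bias-only
#'   score, i.e. the empirical class priors.
#' @name maxent
NULL

#' Training instance
#'
#' @param id Instance identifier (document + event id).
#' @param features Character vector of active binary feature names.
#' @param label `"positive"` (event is modified) or `"negative"`, or `NA`
#'   for test instances.
#' @return An object of class `eventmod_instance`.
#' @export
instance <- function(id, features, label = NA_character_) {
  if (!is.na(label) && !label %in% c("positive", "negative")) {
    stop("label must be positive/negative/NA", call. = FALSE)
  }
  structure(list(id = id, features = unique(features), label = label),
            class = "eventmod_instance")
}

#' Train a maximum-entropy model
#'
#' Maximizes the penalized conditional log-likelihood
#' `sum_i log p(y_i | x_i) - ||w||^2 / (2 sigma2)` with a quasi-Newton
#' optimizer (BFGS, analytic gradient).  The objective is strictly convex,
#' so the fit is deterministic and invariant to instance order.  Features
#' are binary indicators; the intercept carries the class prior and is not
#' penalized.
#'
#' @param instances List of labelled [instance()]s; both classes must be
#'   present.
#' @param sigma2 Gaussian prior variance on the weights (default 1).
#' @param max_iter Maximum optimizer iterations.
#' @return An object of class `eventmod_maxent`: `features` (dictionary),
#'   `weights` (named numeric), `bias`, `classes`, `training_meta`.
#' @export
train_maxent <- function(instances, sigma2 = 1, max_iter = 200L) {
  labels <- vapply(instances, `[[`, "", "label")
  if (anyNA(labels)) stop("all training instances must be labelled",
                          call. = FALSE)
  y <- as.numeric(labels == "positive")
  if (length(unique(y)) < 2L) {
    stop("degenerate training data: only one class present", call. = FALSE)
  }
  dict <- sort(unique(unlist(lapply(instances, `[[`, "features"))))
  p <- length(dict)
  n <- length(instances)
  X <- matrix(0, n, p, dimnames = list(NULL, dict))
  for (i in seq_len(n)) {
    f <- instances[[i]]$features
    if (length(f)) X[i, f] <- 1
  }

  nll <- function(theta) {
    b <- theta[1L]
    w <- theta[-1L]
    eta <- b + if (p) drop(X %*% w) else 0
    # log(1 + exp(eta)) computed stably
    ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
    -(ll - sum(w^2) / (2 * sigma2))
  }
  grad <- function(theta) {
    b <- theta[1L]
    w <- theta[-1L]
    eta <- b + if (p) drop(X %*% w) else 0
    mu <- stats::plogis(eta)
    resid <- y - mu
    gb <- sum(resid)
    gw <- if (p) drop(crossprod(X, resid)) - w / sigma2 else numeric()
    -c(gb, gw)
  }
  fit <- stats::optim(rep(0, p + 1L), nll, grad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  if (fit$convergence == 1L) {
    warning("maxent optimizer hit the iteration cap (", max_iter,
            "); returning the current model", call. = FALSE)
  }
  structure(
    list(
      features = dict,
      weights = stats::setNames(fit$par[-1L], dict),
      bias = fit$par[[1L]],
      classes = c("negative", "positive"),
      training_meta = list(sigma2 = sigma2, max_iter = max_iter,
                           n = n, p = p, converged = fit$convergence == 0L)
    ),
    class = "eventmod_maxent"
  )
}

#' Predict with a maximum-entropy model
#'
#' Feature names unseen in training are ignored; an empty (or entirely
#' unseen) feature set therefore yields the bias-only prediction — the class
#' priors.
#'
#' @param m A [train_maxent()] model.
#' @param features Character vector of active feature names.
#' @param threshold Positive-class probability threshold (default 0.5).
#' @return List with `label`, `prob` (named distribution over classes,
#'   summing to 1), and `score` (positive-class probability).
#' @export
predict_maxent <- function(m, features, threshold = 0.5) {
  active <- intersect(features, m$features)
  eta <- m$bias + sum(m$weights[active])
  p_pos <- stats::plogis(eta)
  list(
    label = if (p_pos > threshold) "positive" else "negative",
    prob = c(negative = 1 - p_pos, positive = p_pos),
    score = p_pos
  )
}

#' @export
print.eventmod_maxent <- function(x, ...) {
  cat(sprintf("<maxent model: %d features, bias %.4f, trained on n=%d%s>\n",
              length(x$features), x$bias, x$training_meta$n,
              if (x$training_meta$converged) "" else " (not converged)"))
  invisible(x)
}

#' Serialize / load a maxent model as versioned JSON
#'
#' @param m A [train_maxent()] model.
#' @param path File path.
#' @return `read_maxent()` returns the model; `write_maxent()` the path,
#'   invisibly.
#' @export
write_maxent <- function(m, path) {
  obj <- list(
    format = "eventmod-maxent-v1",
    classes = m$classes,
    bias = m$bias,
    weights = as.list(m$weights),
    training_meta = m$training_meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "eventmod-maxent-v1")) {
    stop("unrecognized model format in ", path, call. = FALSE)
  }
  w <- vapply(obj$weights, as.numeric, 0)
  structure(
    list(features = names(w), weights = w, bias = as.numeric(obj$bias),
         classes = unlist(obj$classes),
         training_meta = lapply(obj$training_meta, unlist)),
    class = "eventmod_maxent"
  )
}

#' Export instances as sparse feature-vector lines
#'
#' SVMlight-like interchange: each line `<label> <fid>:1 ...` with a
#' tab-separated feature-name dictionary sidecar, so vectors can be
#' inspected or fed to external learners.
#'
#' @param instances List of [instance()]s.
#' @return List with `lines` and `dictionary` character vectors.
#' @export
export_sparse <- function(instances) {
  dict <- sort(unique(unlist(lapply(instances, `[[`, "features"))))
  idx <- stats::setNames(seq_along(dict), dict)
  lines <- vapply(instances, function(ins) {
    lab <- if (is.na(ins$label)) "0" else if (ins$label == "positive") "+1" else "-1"
    ids <- sort(unname(idx[ins$features]))
    paste(c(lab, sprintf("%d:1", ids)), collapse = " ")
  }, "")
  list(lines = lines,
       dictionary = sprintf("%d\t%s", seq_along(dict), dict))
}
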