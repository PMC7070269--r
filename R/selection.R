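make_stratified_folds <- function(y01, k, seed) {
  local_seed(seed, {
    fold <- integer(length(y01))
    for (cls in unique(y01)) {
      idx <- which(y01 == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# Cross-validated accuracy of the wrapped classifier on a feature subset.
# The fold assignment is fixed per search so all subsets are scored on the
# same partition. An empty subset scores the majority-class baseline.
cv_subset_accuracy <- function(X, y01, fold, cols, algorithm, balance,
                               node_options) {
  k <- max(fold)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    yte <- y01[!tr]
    if (length(cols) == 0) {
      maj <- as.integer(sum(y01[tr] == 1) >= sum(y01[tr] == 0))
      correct <- correct + sum(yte == maj)
    } else {
      w <- if (balance) balance_weights(y01[tr]) else NULL
      node <- do.call(train_node,
                      c(list(X = X[tr, cols, drop = FALSE], y = y01[tr], w = w,
                             algorithm = algorithm), node_options))
      s <- node_scores(node, X[!tr, cols, drop = FALSE])
      correct <- correct + sum((s >= 0.5) == (yte == 1))
    }
  }
  correct / length(y01)
}

#' Wrapper feature-subset selection by best-first forward search
#'
#' Searches the space of feature subsets with greedy hill-climbing augmented
#' with backtracking (best-first search). The search starts from the empty
#' set and moves forward by single-feature additions; subsets are scored by
#' the stratified k-fold cross-validated accuracy of the wrapped node
#' classifier itself. When expansions stop improving, the search backtracks
#' to the best unexpanded subset; it terminates after `termination`
#' consecutive expanded nodes yield no improvement over the incumbent
#' (default 5). No subset is ever evaluated twice, and the incumbent is
#' replaced on ties only by a strictly smaller subset, so the result is
#' deterministic given the CV seed.
#'
#' @param X numeric feature matrix (any number of columns >= 1).
#' @param y binary labels.
#' @param node_algorithm algorithm passed to [train_node()].
#' @param folds number of stratified CV folds (default 5).
#' @param seed integer seed fixing the fold assignment.
#' @param termination consecutive non-improving expansions allowed before
#'   the search stops (default 5).
#' @param improvement minimum absolute accuracy gain counted as an
#'   improvement (guards against floating-point noise).
#' @param balance apply [balance_weights()] inside each training fold.
#' @param node_options list of options for [train_node()].
#' @return An object of class `wrapper_selection`: `indices` (selected
#'   column indices, in order of addition), `score` (CV accuracy),
#'   `trace` (one row per evaluated subset), `max_nonimproving_run` and
#'   `n_evaluated`.
#' @export
wrapper_select <- function(X, y, node_algorithm = "lda", folds = 5, seed = 1L,
                           termination = 5, improvement = 1e-5,
                           balance = FALSE, node_options = list()) {
  X <- as.matrix(X)
  m <- ncol(X)
  yf <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(yf) != 2) stop("y must be binary")
  if (termination < 1) stop("termination must be >= 1")
  y01 <- as.integer(yf) - 1L
  fold <- make_stratified_folds(y01, folds, seed)
  evalsub <- function(cols) cv_subset_accuracy(X, y01, fold, cols,
                                               node_algorithm, balance,
                                               node_options)

  key_of <- function(cols) paste0("s", paste(sort(cols), collapse = ","))
  closed <- new.env(parent = emptyenv())
  trace_step <- integer(0); trace_size <- integer(0)
  trace_score <- numeric(0); trace_key <- character(0)
  step <- 0L
  record <- function(cols, sc) {
    step <<- step + 1L
    assign(key_of(cols), TRUE, envir = closed)
    trace_step[step] <<- step
    trace_size[step] <<- length(cols)
    trace_score[step] <<- sc
    trace_key[step] <<- key_of(cols)
  }

  root_score <- evalsub(integer(0))
  record(integer(0), root_score)
  open <- list(list(indices = integer(0), score = root_score, expanded = FALSE))
  incumbent <- list(indices = integer(0), score = root_score)
  counter <- 0L
  max_run <- 0L

  repeat {
    cand <- which(!vapply(open, `[[`, TRUE, "expanded"))
    if (!length(cand) || counter >= termination) break
    scores <- vapply(open[cand], `[[`, 0, "score")
    sizes <- vapply(open[cand], function(o) length(o$indices), 0L)
    best <- cand[order(-scores, sizes)[1]]
    open[[best]]$expanded <- TRUE
    node <- open[[best]]
    improved <- FALSE
    for (j in setdiff(seq_len(m), node$indices)) {
      child <- c(node$indices, j)
      if (!is.null(closed[[key_of(child)]])) next
      sc <- evalsub(child)
      record(child, sc)
      open[[length(open) + 1L]] <- list(indices = child, score = sc,
                                        expanded = FALSE)
      if (sc > incumbent$score + improvement) {
        incumbent <- list(indices = child, score = sc)
        improved <- TRUE
      } else if (sc > incumbent$score - improvement &&
                 length(child) < length(incumbent$indices)) {
        incumbent <- list(indices = child, score = sc)
      }
    }
    counter <- if (improved) 0L else counter + 1L
    max_run <- max(max_run, counter)
  }

  structure(list(indices = incumbent$indices, score = incumbent$score,
                 trace = data.frame(step = trace_step, size = trace_size,
                                    score = trace_score, key = trace_key,
                                    stringsAsFactors = FALSE),
                 termination = termination, max_nonimproving_run = max_run,
                 n_evaluated = step),
            class = "wrapper_selection")
}

#' @export
print.wrapper_selection <- function(x, ...) {
  cat(sprintf("<wrapper_selection> %d feature(s), CV accuracy %.4f (%d subsets evaluated)\n",
              length(x$indices), x$score, x$n_evaluated))
  invisible(x)
}

#' Rank features by a weighted between/within variance ratio
#'
#' A fast univariate filter used to pre-rank candidate features before the
#' wrapper search when a full-width search is not wanted.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param w optional instance weights.
#' @param top how many top-ranked column indices to return (`NULL` = all,
#'   ranked).
#' @return Integer vector of column indices, best first.
#' @export
screen_features <- function(X, y, w = NULL, top = NULL) {
  X <- as.matrix(X)
  yf <- if (is.factor(y)) droplevels(y) else factor(y)
  y01 <- as.integer(yf) - 1L
  if (is.null(w)) w <- rep(1, length(y01))
  W <- sum(w)
  mu <- colSums(X * w) / W
  between <- 0
  within <- 0
  for (cls in c(0L, 1L)) {
    i <- y01 == cls
    Wc <- sum(w[i])
    muc <- colSums(X[i, , drop = FALSE] * w[i]) / Wc
    between <- between + Wc * (muc - mu)^2
    within <- within + colSums(sweep(X[i, , drop = FALSE], 2, muc)^2 * w[i])
  }
  ratio <- between / (within + 1e-12)
  ord <- order(ratio, decreasing = TRUE)
  if (!is.null(top)) ord <- ord[seq_len(min(top, length(ord)))]
  ord
}
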