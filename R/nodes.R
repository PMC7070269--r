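#' Class-balancing instance weights
#'
#' Weights each instance by `N / (K * n_class)` so that the weight mass of
#' every class is identical (`N / K`) and the mean weight is 1. Used for the
#' light-vs-moderate node, where light activity heavily outnumbers stair
#' activity.
#'
#' @param y labels (factor, character or numeric) with at least two classes
#'   present.
#' @return Numeric weight vector, one non-negative weight per instance.
#' @examples
#' balance_weights(c(rep("a", 9), "b"))  # 9:1 -> weights 10/18 and 5
#' @export
balance_weights <- function(y) {
  tab <- table(y)
  tab <- tab[tab > 0]
  if (length(tab) < 2) stop("y must contain at least two classes")
  n <- length(y)
  k <- length(tab)
  w <- n / (k * as.numeric(tab[match(as.character(y), names(tab))]))
  unname(w)
}

entropy2 <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  q <- p[ok]
  h[ok] <- -(q * log2(q) + (1 - q) * log2(1 - q))
  h
}

# ---- gain-ratio threshold tree (C4.5-style) --------------------------------

grow_tree <- function(X, y01, w, max_depth = 10, min_leaf_w = 2) {
  grow <- function(idx, depth) {
    wi <- w[idx]
    yi <- y01[idx]
    W <- sum(wi)
    W1 <- sum(wi[yi == 1])
    W0 <- W - W1
    node <- list(leaf = TRUE, w = W, w1 = W1,
                 prob = (W1 + 1) / (W + 2),       # Laplace-smoothed leaf score
                 label = as.integer(W1 >= W0))
    if (depth >= max_depth || W < 2 * min_leaf_w || W0 == 0 || W1 == 0)
      return(node)
    hp <- entropy2(W1 / W)
    best <- NULL
    best_gr <- 1e-12
    for (j in seq_len(ncol(X))) {
      x <- X[idx, j]
      o <- order(x)
      xs <- x[o]
      cw <- cumsum(wi[o])
      cw1 <- cumsum((wi * yi)[o])
      k <- which(xs[-length(xs)] < xs[-1])       # cuts between distinct values
      if (!length(k)) next
      Wl <- cw[k]; W1l <- cw1[k]
      Wr <- W - Wl; W1r <- W1 - W1l
      ok <- Wl >= min_leaf_w & Wr >= min_leaf_w
      if (!any(ok)) next
      k <- k[ok]; Wl <- Wl[ok]; W1l <- W1l[ok]; Wr <- Wr[ok]; W1r <- W1r[ok]
      gain <- hp - (Wl * entropy2(W1l / Wl) + Wr * entropy2(W1r / Wr)) / W
      si <- entropy2(Wl / W)
      gr <- ifelse(si > 0 & gain > 1e-12, gain / si, -Inf)
      jb <- which.max(gr)
      if (gr[jb] > best_gr) {
        best_gr <- gr[jb]
        best <- list(feature = j, threshold = (xs[k[jb]] + xs[k[jb] + 1]) / 2)
      }
    }
    if (is.null(best)) return(node)
    left <- idx[X[idx, best$feature] <= best$threshold]
    right <- idx[X[idx, best$feature] > best$threshold]
    node$leaf <- FALSE
    node$feature <- best$feature
    node$threshold <- best$threshold
    node$left <- grow(left, depth + 1)
    node$right <- grow(right, depth + 1)
    node
  }
  grow(seq_len(nrow(X)), 0L)
}

# Pessimistic-error pruning: a subtree is collapsed to a leaf when the
# leaf's upper-confidence-bound error estimate does not exceed the sum of
# its leaves' estimates (confidence factor 0.25, as in C4.5).
prune_tree <- function(node, cf = 0.25) {
  pess <- function(E, N) {
    if (N <= 0) return(0)
    N * stats::qbeta(1 - cf, E + 1, max(N - E, 1e-9))
  }
  rec <- function(nd) {
    err <- min(nd$w1, nd$w - nd$w1)
    if (nd$leaf) {
      nd$pess <- pess(err, nd$w)
      return(nd)
    }
    nd$left <- rec(nd$left)
    nd$right <- rec(nd$right)
    sub <- nd$left$pess + nd$right$pess
    as_leaf <- pess(err, nd$w)
    if (as_leaf <= sub + 1e-8) {
      nd <- list(leaf = TRUE, w = nd$w, w1 = nd$w1,
                 prob = (nd$w1 + 1) / (nd$w + 2),
                 label = as.integer(nd$w1 >= nd$w - nd$w1), pess = as_leaf)
    } else {
      nd$pess <- sub
    }
    nd
  }
  rec(node)
}

predict_tree_prob <- function(tree, X) {
  prob <- numeric(nrow(X))
  rec <- function(nd, idx) {
    if (!length(idx)) return(invisible())
    if (nd$leaf) {
      prob[idx] <<- nd$prob
      return(invisible())
    }
    left <- X[idx, nd$feature] <= nd$threshold
    rec(nd$left, idx[left])
    rec(nd$right, idx[!left])
  }
  rec(tree, seq_len(nrow(X)))
  prob
}

# ---- weighted linear discriminant analysis ---------------------------------

train_lda_w <- function(X, y01, w, ridge = 1e-6) {
  d <- ncol(X)
  i0 <- y01 == 0; i1 <- y01 == 1
  W0 <- sum(w[i0]); W1 <- sum(w[i1]); W <- W0 + W1
  mu0 <- colSums(X[i0, , drop = FALSE] * w[i0]) / W0
  mu1 <- colSums(X[i1, , drop = FALSE] * w[i1]) / W1
  d0 <- sweep(X[i0, , drop = FALSE], 2, mu0)
  d1 <- sweep(X[i1, , drop = FALSE], 2, mu1)
  S <- (crossprod(d0 * sqrt(w[i0])) + crossprod(d1 * sqrt(w[i1]))) /
    max(W - 2, 1)
  a <- tryCatch(solve(S, mu1 - mu0), error = function(e) NULL)
  if (is.null(a) || !all(is.finite(a)) || rcond_est(S) < 1e-10) {
    lam <- ridge * sum(diag(S)) / d
    if (lam <= 0) lam <- ridge
    message("lda: degenerate pooled covariance, adding ridge ", signif(lam, 3))
    S <- S + diag(lam, d)
    a <- solve(S, mu1 - mu0)
  }
  b <- -0.5 * sum((mu0 + mu1) * a) + log(W1 / W0)
  list(coef = a, intercept = b, mu0 = mu0, mu1 = mu1, cov = S)
}

rcond_est <- function(S) {
  if (nrow(S) == 1) return(ifelse(S[1, 1] > 0, 1, 0))
  tryCatch(rcond(S), error = function(e) 0)
}

# ---- weighted ridge-stabilised logistic regression -------------------------

train_logistic_w <- function(X, y01, w, lambda = 1e-6, max_iter = 60, tol = 1e-9) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- diag(lambda, p)
  pen[1, 1] <- 0                       # intercept not penalised
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    wt <- w * mu * (1 - mu) + 1e-12
    g <- drop(crossprod(Xd, w * (y01 - mu))) - drop(pen %*% beta)
    H <- crossprod(Xd, Xd * wt) + pen + diag(1e-12, p)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coef = beta[-1], intercept = beta[1])
}

# ---- node contract ---------------------------------------------------------

#' Train a binary node classifier
#'
#' Trains one internal node of the hierarchical classifier on a feature
#' matrix, with optional instance weights. Built-in algorithms:
#' \describe{
#'   \item{`"tree"`}{univariate threshold decision tree with gain-ratio
#'     splitting, minimum leaf weight 2 and pessimistic-error pruning
#'     (C4.5-style); leaf scores are Laplace-smoothed class frequencies.}
#'   \item{`"lda"`}{linear discriminant analysis with weighted class means,
#'     pooled weighted covariance and weighted priors; a ridge of
#'     `1e-6 * trace/d` is added (with a message) if the covariance is
#'     degenerate. Scores are posterior probabilities.}
#'   \item{`"logistic"`}{weighted maximum-likelihood logistic regression with
#'     an L2 stabiliser of 1e-6 on the slopes.}
#' }
#' A custom algorithm may be supplied as a function
#' `function(X, y01, w, ...)` returning a list with a `score(X)` function
#' (plug-in node contract).
#'
#' @param X numeric feature matrix (rows = instances).
#' @param y binary labels (factor/logical/character/numeric with exactly two
#'   levels); the second level is the positive meta-class.
#' @param w optional instance weights (default: all 1).
#' @param algorithm `"tree"`, `"lda"`, `"logistic"`, or a training function.
#' @param ... algorithm options (`max_depth`, `min_leaf_w`, `prune`, `cf` for
#'   the tree; `ridge` for lda; `lambda` for logistic).
#' @return An object of class `bhc_node` emitting a score in `[0, 1]` for
#'   the positive meta-class.
#' @export
train_node <- function(X, y, w = NULL, algorithm = c("tree", "lda", "logistic"),
                       ...) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) &&
      (any(colnames(X) == "") || anyDuplicated(colnames(X)) > 0))
    colnames(X) <- NULL                # unusable names: match by position
  if (!all(is.finite(X))) stop("X must be finite")
  yf <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(yf) != 2) stop("y must be binary (exactly two classes present)")
  y01 <- as.integer(yf) - 1L
  if (is.null(w)) w <- rep(1, length(y01))
  if (length(w) != length(y01)) stop("weights length must match y")
  opts <- list(...)
  if (is.function(algorithm)) {
    fit <- algorithm(X, y01, w, ...)
    alg <- "plug-in"
  } else {
    alg <- match.arg(algorithm)
    fit <- switch(alg,
      tree = {
        tr <- grow_tree(X, y01, w,
                        max_depth = opts$max_depth %||% 10,
                        min_leaf_w = opts$min_leaf_w %||% 2)
        if (opts$prune %||% TRUE) tr <- prune_tree(tr, opts$cf %||% 0.25)
        tr
      },
      lda = train_lda_w(X, y01, w, ridge = opts$ridge %||% 1e-6),
      logistic = train_logistic_w(X, y01, w, lambda = opts$lambda %||% 1e-6))
  }
  structure(list(algorithm = alg, fit = fit, levels = levels(yf),
                 features = colnames(X)),
            class = "bhc_node")
}

node_scores <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$features)) {
    if (!is.null(colnames(X))) {
      miss <- setdiff(model$features, colnames(X))
      if (length(miss))
        stop("missing features: ", paste(miss, collapse = ", "))
      X <- X[, model$features, drop = FALSE]
    } else if (ncol(X) != length(model$features)) {
      stop("newdata has ", ncol(X), " columns; model needs ",
           length(model$features))
    }
  }
  if (!all(is.finite(X))) stop("newdata must be finite")
  switch(model$algorithm,
    tree = predict_tree_prob(model$fit, X),
    lda = ,
    logistic = stats::plogis(drop(X %*% model$fit$coef) + model$fit$intercept),
    `plug-in` = model$fit$score(X))
}

#' Predict with a node classifier
#'
#' @param object a `bhc_node` from [train_node()].
#' @param newdata matrix (or named feature vector) containing the model's
#'   features.
#' @param ... unused.
#' @return A data frame with `label` (the predicted meta-class, score >= 0.5
#'   maps to the positive level) and `score` in `[0, 1]`.
#' @export
predict.bhc_node <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  s <- node_scores(object, newdata)
  data.frame(label = object$levels[(s >= 0.5) + 1L], score = s,
             stringsAsFactors = FALSE)
}

#' @rdname predict.bhc_node
#' @param model a `bhc_node`.
#' @param x a single feature vector (named) or one-row matrix.
#' @return `predict_node()` returns `list(label, score)` for one instance.
#' @export
predict_node <- function(model, x) {
  p <- predict(model, x)
  list(label = p$label[1], score = p$score[1])
}

#' @export
print.bhc_node <- function(x, ...) {
  cat(sprintf("<bhc_node> %s: %s vs %s, %d feature(s)\n", x$algorithm,
              x$levels[1], x$levels[2], length(x$features)))
  invisible(x)
}
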