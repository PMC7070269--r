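#' Specification of a binary hierarchical classifier fit
#'
#' Collects the tunable parameters of [bhc()]: node algorithms (defaults:
#' gain-ratio tree for the sedentary-vs-active node, weighted LDA for the
#' light-vs-moderate node -- the pair deployed on the device), whether and
#' how wrapper selection is run, and the CV settings.
#'
#' @param phi1,phi2 node algorithms for the upper (sedentary vs active) and
#'   lower (light vs moderate) node; see [train_node()].
#' @param select run [wrapper_select()] per node (`TRUE`) or use all columns.
#' @param screen_top candidate pool size for the wrapper search: features
#'   are pre-ranked by [screen_features()] and the search runs over the top
#'   `screen_top` of them (`NULL` = search all columns).
#' @param termination,cv_folds,seed,improvement passed to [wrapper_select()].
#' @param phi1_options,phi2_options option lists for [train_node()].
#' @return A list of class `bhc_spec`.
#' @export
bhc_spec <- function(phi1 = "tree", phi2 = "lda", select = TRUE,
                     screen_top = 24, termination = 5, cv_folds = 5,
                     seed = 1L, improvement = 1e-5,
                     phi1_options = list(max_depth = 8),
                     phi2_options = list()) {
  structure(list(phi1 = phi1, phi2 = phi2, select = select,
                 screen_top = screen_top, termination = termination,
                 cv_folds = cv_folds, seed = as.integer(seed),
                 improvement = improvement,
                 phi1_options = phi1_options, phi2_options = phi2_options),
            class = "bhc_spec")
}

select_for_node <- function(X, y, spec, algorithm, balance, node_options, seed) {
  if (!spec$select) {
    return(list(psi = seq_len(ncol(X)), score = NA_real_, selection = NULL))
  }
  w <- if (balance) balance_weights(y) else NULL
  pool <- screen_features(X, y, w, top = spec$screen_top)
  sel <- wrapper_select(X[, pool, drop = FALSE], y,
                        node_algorithm = algorithm, folds = spec$cv_folds,
                        seed = seed, termination = spec$termination,
                        improvement = spec$improvement, balance = balance,
                        node_options = node_options)
  psi <- pool[sel$indices]
  if (length(psi) == 0) psi <- pool[1]   # all-noise data: keep best-ranked
  list(psi = psi, score = sel$score, selection = sel)
}

#' Fit a binary hierarchical activity-intensity classifier
#'
#' Fits the two-node hierarchical classifier: the upper node phi1 separates
#' sedentary windows from active ones, and the lower node phi2 -- consulted
#' only when phi1 says "active" -- separates light from moderate intensity.
#' Each node gets its own wrapper-selected feature subset (psi1, psi2).
#' phi2 is trained only on light/moderate instances with class-balancing
#' instance weights ([balance_weights()]), because light activity heavily
#' outnumbers stair activity.
#'
#' @param X feature matrix (rows = windows, columns named as in
#'   [feature_catalog()]; any column set is accepted).
#' @param y intensity labels: integers 0/1/2 or a factor with levels
#'   sedentary/light/moderate. All three classes must be present.
#' @param spec a [bhc_spec()].
#' @return An object of class `bhc` with components `phi1`, `phi2`
#'   ([train_node()] node models), `psi1`, `psi2` (selected column indices),
#'   and `selection` (the two search traces).
#' @seealso [predict.bhc()], [loso_bhc()]
#' @export
bhc <- function(X, y, spec = bhc_spec()) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- if (ncol(X) == 98) feature_catalog()$name
                   else sprintf("F%03d", seq_len(ncol(X)))
  y <- canonical_intensity(y)
  if (length(unique(y)) < 3)
    stop("all three intensity classes must be present in y")

  y1 <- factor(ifelse(y == 0, "sedentary", "active"),
               levels = c("sedentary", "active"))
  s1 <- select_for_node(X, y1, spec, spec$phi1, balance = FALSE,
                        spec$phi1_options, seed = spec$seed)
  phi1 <- do.call(train_node,
                  c(list(X = X[, s1$psi, drop = FALSE], y = y1,
                         algorithm = spec$phi1), spec$phi1_options))

  act <- y > 0
  y2 <- factor(ifelse(y[act] == 1, "light", "moderate"),
               levels = c("light", "moderate"))
  s2 <- select_for_node(X[act, , drop = FALSE], y2, spec, spec$phi2,
                        balance = TRUE, spec$phi2_options,
                        seed = derive_seed(spec$seed, 2L))
  w2 <- balance_weights(y2)
  phi2 <- do.call(train_node,
                  c(list(X = X[act, s2$psi, drop = FALSE], y = y2, w = w2,
                         algorithm = spec$phi2), spec$phi2_options))

  structure(list(phi1 = phi1, phi2 = phi2,
                 psi1 = s1$psi, psi2 = s2$psi,
                 feature_names = colnames(X), spec = spec,
                 selection = list(phi1 = s1$selection, phi2 = s2$selection),
                 catalog_hash = if (ncol(X) == 98) catalog_hash() else NA_character_),
            class = "bhc")
}

canonical_intensity <- function(y) {
  if (is.factor(y) || is.character(y)) {
    m <- match(as.character(y), intensity_labels()) - 1L
    if (anyNA(m)) stop("labels must be sedentary/light/moderate or 0/1/2")
    return(m)
  }
  y <- as.integer(y)
  if (any(!y %in% 0:2)) stop("intensity classes must be 0, 1 or 2")
  y
}

#' Predict activity intensity with a fitted hierarchical classifier
#'
#' Class prediction follows the hierarchy: if phi1 predicts sedentary the
#' window is class 0 and phi2 is not consulted; otherwise phi2 decides
#' between light (1) and moderate (2). `type = "scores"` instead evaluates
#' both nodes on every row and returns their graded scores (used for ROC
#' analysis).
#'
#' @param object a [bhc()] fit.
#' @param newdata feature matrix or data frame with the model's features.
#' @param type `"class"` (default) or `"scores"`.
#' @param ... unused.
#' @return For `"class"`: integer vector of 0/1/2. For `"scores"`: a data
#'   frame with `s1` (probability of "active") and `s2` (probability of
#'   "moderate").
#' @export
predict.bhc <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) && ncol(newdata) == length(object$feature_names))
    colnames(newdata) <- object$feature_names
  s1 <- node_scores(object$phi1, newdata)
  if (type == "scores") {
    s2 <- node_scores(object$phi2, newdata)
    return(data.frame(s1 = s1, s2 = s2))
  }
  cls <- integer(nrow(newdata))
  active <- s1 >= 0.5
  if (any(active)) {
    s2 <- node_scores(object$phi2, newdata[active, , drop = FALSE])
    cls[active] <- ifelse(s2 >= 0.5, 2L, 1L)
  }
  cls
}

#' @rdname predict.bhc
#' @param model a `bhc` fit.
#' @param x one feature vector (named) or one-row matrix.
#' @return `predict_bhc()` returns `list(class, scores)` for one window;
#'   `scores$s2` is `NA` when phi1 short-circuits to sedentary.
#' @export
predict_bhc <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  s1 <- node_scores(model$phi1, x)[1]
  if (s1 < 0.5) {
    return(list(class = 0L, scores = list(s1 = s1, s2 = NA_real_)))
  }
  s2 <- node_scores(model$phi2, x)[1]
  list(class = if (s2 >= 0.5) 2L else 1L, scores = list(s1 = s1, s2 = s2))
}

#' @export
print.bhc <- function(x, ...) {
  cat("Binary hierarchical intensity classifier\n")
  cat(sprintf("  phi1 (%s): sedentary vs active, %d feature(s)\n",
              x$phi1$algorithm, length(x$psi1)))
  cat(sprintf("  phi2 (%s): light vs moderate, %d feature(s)\n",
              x$phi2$algorithm, length(x$psi2)))
  invisible(x)
}

#' @export
summary.bhc <- function(object, ...) {
  out <- list(
    phi1 = list(algorithm = object$phi1$algorithm,
                features = object$feature_names[object$psi1],
                cv_score = object$selection$phi1$score %||% NA_real_),
    phi2 = list(algorithm = object$phi2$algorithm,
                features = object$feature_names[object$psi2],
                cv_score = object$selection$phi2$score %||% NA_real_))
  class(out) <- "summary.bhc"
  out
}

#' @export
print.summary.bhc <- function(x, ...) {
  for (nm in c("phi1", "phi2")) {
    nd <- x[[nm]]
    cat(sprintf("%s [%s]%s\n  %s\n", nm, nd$algorithm,
                if (is.na(nd$cv_score)) "" else
                  sprintf(" selection CV accuracy %.4f", nd$cv_score),
                paste(nd$features, collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a fitted classifier to JSON
#'
#' Versioned JSON with the algorithm names, learned parameters, feature
#' subsets and the feature-catalogue hash, so a reader with a different
#' catalogue order fails loudly.
#'
#' @param model a [bhc()] fit.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_bhc_json <- function(model, path) {
  obj <- list(format = "actiflow-bhc-1",
              catalog_hash = model$catalog_hash,
              phi1 = list(algorithm = model$phi1$algorithm,
                          features = model$phi1$features,
                          fit = model$phi1$fit),
              phi2 = list(algorithm = model$phi2$algorithm,
                          features = model$phi2$features,
                          fit = model$phi2$fit))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
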