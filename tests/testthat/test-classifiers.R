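test_that("balance weights equalise per-class weight mass", {
  w <- balance_weights(c(rep("a", 9), "b"))
  expect_equal(w[1], 10 / 18)
  expect_equal(w[10], 5)
  expect_equal(sum(w[1:9]), sum(w[10]))
  expect_equal(mean(w), 1)

  expect_true(all(balance_weights(rep(c(0, 1), 5)) == 1))

  # the study's light/moderate imbalance
  y <- c(rep("light", 3115), rep("moderate", 550))
  w <- balance_weights(y)
  expect_equal(sum(w[y == "light"]), sum(w[y == "moderate"]), tolerance = 1e-9)
  expect_equal(sum(w), length(y))

  expect_error(balance_weights(rep("a", 10)), "two classes")
})

test_that("LDA places the boundary midway between symmetric classes", {
  set.seed(100)
  n <- 10000
  X <- matrix(c(rnorm(n / 2, -1), rnorm(n / 2, 1)), ncol = 1)
  y <- rep(c(0, 1), each = n / 2)
  node <- train_node(X, y, algorithm = "lda")
  boundary <- -node$fit$intercept / node$fit$coef
  expect_lt(abs(boundary), 0.05)
  # exactly at the boundary the posterior is 1/2
  p <- predict(node, matrix(boundary, 1, 1))
  expect_equal(p$score, 0.5, tolerance = 1e-9)
})

test_that("LDA approaches the Bayes error on Gaussian classes", {
  set.seed(101)
  delta <- 2
  n <- 4000
  X <- matrix(c(rnorm(n / 2, -delta / 2), rnorm(n / 2, delta / 2)), ncol = 1)
  y <- rep(c(0, 1), each = n / 2)
  node <- train_node(X, y, algorithm = "lda")
  nt <- 20000
  Xt <- matrix(c(rnorm(nt / 2, -delta / 2), rnorm(nt / 2, delta / 2)), ncol = 1)
  yt <- rep(c(0, 1), each = nt / 2)
  err <- mean((node_scores(node, Xt) >= 0.5) != (yt == 1))
  bayes <- pnorm(-delta / 2)
  expect_lt(abs(err - bayes), 0.02)
})

test_that("weighted LDA agrees with MASS::lda in the unweighted case", {
  skip_if_not_installed("MASS")
  set.seed(5)
  X <- matrix(rnorm(400), ncol = 2)
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(200, 0, 0.8) > 0)
  ours <- train_node(X, y, algorithm = "lda")
  ref <- MASS::lda(X, grouping = y)
  ref_pred <- predict(ref, X)$class
  our_pred <- (node_scores(ours, X) >= 0.5) + 0L
  expect_equal(as.integer(as.character(ref_pred)), our_pred)
})

test_that("the tree fits noise-free threshold-separable data exactly", {
  set.seed(6)
  X <- matrix(runif(200 * 4), 200, 4)
  y <- as.integer(X[, 3] > 0.7)
  node <- train_node(X, y, algorithm = "tree", prune = FALSE)
  expect_equal(mean((node_scores(node, X) >= 0.5) == (y == 1)), 1.0)
  # pruning keeps the clean single split
  pruned <- train_node(X, y, algorithm = "tree")
  expect_gte(mean((node_scores(pruned, X) >= 0.5) == (y == 1)), 0.99)
})

test_that("tree predictions are invariant to monotone feature transforms", {
  set.seed(8)
  X <- matrix(rnorm(300 * 3), 300, 3)
  y <- as.integer(X[, 1] + X[, 2]^2 > 0.5)
  Xt <- X
  Xt[, 1] <- exp(X[, 1])              # strictly monotone map of feature 1
  a <- train_node(X, y, algorithm = "tree")
  b <- train_node(Xt, y, algorithm = "tree")
  expect_equal(node_scores(a, X), node_scores(b, Xt))
})

test_that("tree leaves give near-pure scores on separable training points", {
  X <- matrix(c(rep(0, 20), rep(1, 20)), ncol = 1)
  y <- rep(c(0, 1), each = 20)
  node <- train_node(X, y, algorithm = "tree")
  p0 <- predict_node(node, c(F001 = 0))
  p1 <- predict_node(node, c(F001 = 1))
  expect_equal(round(p0$score), 0)
  expect_equal(round(p1$score), 1)
})

test_that("logistic node separates weighted data and respects weights", {
  set.seed(10)
  X <- matrix(rnorm(300), ncol = 1)
  y <- as.integer(X[, 1] + rnorm(300, 0, 0.5) > 0)
  node <- train_node(X, y, algorithm = "logistic")
  expect_gt(mean((node_scores(node, X) >= 0.5) == (y == 1)), 0.8)
  expect_gt(node$fit$coef, 0)
})

test_that("node scores are monotone in the discriminant", {
  set.seed(11)
  X <- matrix(rnorm(100 * 2), 100, 2)
  y <- as.integer(rowSums(X) > 0)
  node <- train_node(X, y, algorithm = "lda")
  xs <- matrix(rnorm(200), 100, 2)
  disc <- drop(xs %*% node$fit$coef) + node$fit$intercept
  expect_identical(order(node_scores(node, xs)), order(disc))
})

test_that("degenerate covariance is ridged, never a silent failure", {
  X <- cbind(rep(c(0, 1), each = 20), rep(c(0, 1), each = 20))  # collinear
  y <- rep(c(0, 1), each = 20)
  expect_message(node <- train_node(X, y, algorithm = "lda"), "ridge")
  expect_true(all(is.finite(node_scores(node, X))))
})

test_that("the hierarchical classifier wires its two nodes as specified", {
  d <- gaussian_intensity_data()
  spec <- bhc_spec(select = FALSE)
  fit <- bhc(d$X, d$y, spec)
  expect_s3_class(fit, "bhc")
  expect_equal(fit$phi1$algorithm, "tree")
  expect_equal(fit$phi2$algorithm, "lda")

  both_lda <- bhc(d$X, d$y, bhc_spec(phi1 = "lda", phi2 = "lda", select = FALSE))
  expect_equal(both_lda$phi1$algorithm, "lda")
  expect_equal(both_lda$phi2$algorithm, "lda")

  expect_error(bhc(d$X, pmin(d$y, 1)), "three")
})

test_that("prediction short-circuits at the sedentary node", {
  d <- gaussian_intensity_data()
  fit <- bhc(d$X, d$y, bhc_spec(select = FALSE))
  sed <- which(d$y == 0)[1]
  out <- predict_bhc(fit, d$X[sed, ])
  expect_equal(out$class, 0L)
  expect_true(is.na(out$scores$s2))
  mod <- which(d$y == 2)[1]
  out2 <- predict_bhc(fit, d$X[mod, ])
  expect_equal(out2$class, 2L)
  expect_false(is.na(out2$scores$s2))
})

test_that("vectorised prediction equals the manual two-step composition", {
  d <- gaussian_intensity_data(n_per_class = 40)
  fit <- bhc(d$X, d$y, bhc_spec(select = FALSE))
  set.seed(12)
  Xn <- matrix(rnorm(1000 * ncol(d$X), sd = 2), ncol = ncol(d$X),
               dimnames = list(NULL, colnames(d$X)))
  got <- predict(fit, Xn)
  s1 <- node_scores(fit$phi1, Xn)
  s2 <- node_scores(fit$phi2, Xn)
  manual <- ifelse(s1 < 0.5, 0L, ifelse(s2 >= 0.5, 2L, 1L))
  expect_identical(got, as.integer(manual))
  # and per-instance predict_bhc agrees too on a sample
  for (i in seq(1, 1000, by = 97)) {
    expect_equal(predict_bhc(fit, Xn[i, ])$class, got[i])
  }
})

test_that("bhc training on a separable synthetic cohort is accurate", {
  co <- make_cohort(3, seed = 33L)
  fm <- cohort_features(co)
  fit <- bhc(fm$X, fm$label, bhc_spec(screen_top = 10))
  acc <- mean(predict(fit, fm$X) == fm$label)
  expect_gte(acc, 0.95)
})
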