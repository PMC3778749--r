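blobs <- make_blobs()

test_that("the symmetric 1-D problem yields the mid-plane with both points on the margin", {
  x <- matrix(c(-1, 1), 2)
  y <- factor(c("neg", "pos"), levels = c("pos", "neg"))
  m <- train_max_margin(x, y, cost = 1000)
  # decision values of the two training points sit exactly on the margin
  xs <- (x - m$center) / m$scale
  dv <- as.numeric(xs %*% m$w + m$b)
  expect_equal(dv, c(-1, 1), tolerance = 1e-6)
  expect_equal(m$b, 0, tolerance = 1e-6)
  expect_equal(as.character(predict_max_margin(m, matrix(0.5))), "pos")
  expect_equal(as.character(predict_max_margin(m, matrix(-0.5))), "neg")
})

test_that("all three classifiers separate well-separated blobs perfectly", {
  for (train_fn in list(
    function() train_max_margin(blobs$x, blobs$y),
    function() train_knn(blobs$x, blobs$y),
    function() train_nb(blobs$x, blobs$y))) {
    model <- train_fn()
    pred <- switch(class(model)[1],
                   max_margin_model = predict_max_margin(model, blobs$x),
                   knn_model = predict_knn(model, blobs$x),
                   naive_bayes_model = predict_nb(model, blobs$x))
    expect_equal(mean(pred == blobs$y), 1)
  }
})

test_that("max-margin honours the documented tie and symmetry rules", {
  x <- matrix(c(-2, -1, 1, 2), 4)
  y <- factor(c("m", "m", "p", "p"), levels = c("p", "m"))
  m <- train_max_margin(x, y, cost = 100)
  # a point exactly on the hyperplane maps to the positive (first) level
  on_plane <- m$center  # standardizes to 0; with b = 0 the decision value is 0
  expect_equal(as.character(predict_max_margin(m, matrix(on_plane))), "p")
  # reflecting a point across the hyperplane flips its label
  expect_false(predict_max_margin(m, matrix(1.5)) ==
                 predict_max_margin(m, matrix(-1.5)))
  # duplicating every training point leaves the decision boundary unchanged
  # (compare the boundary, not w: the per-point box constraint redistributes
  # dual weights across duplicates away from the hard-margin limit)
  m2 <- train_max_margin(rbind(x, x), factor(rep(y, 2), levels = levels(y)),
                         cost = 100)
  boundary <- function(mod) mod$center - mod$b / mod$w * mod$scale
  expect_equal(boundary(m2), boundary(m), tolerance = 1e-6)
  probes <- matrix(seq(-3, 3, by = 0.25))
  expect_equal(predict_max_margin(m2, probes), predict_max_margin(m, probes))
})

test_that("label swap flips every prediction for all three classifiers", {
  x <- blobs$x
  y <- blobs$y
  y_swapped <- factor(ifelse(y == "a", "b", "a"), levels = c("a", "b"))
  set.seed(5)
  probes <- matrix(rnorm(10 * ncol(x), mean = 3), 10)
  p1 <- predict_max_margin(train_max_margin(x, y), probes)
  p2 <- predict_max_margin(train_max_margin(x, y_swapped), probes)
  expect_true(all(p1 != p2))
  k1 <- predict_knn(train_knn(x, y), probes)
  k2 <- predict_knn(train_knn(x, y_swapped), probes)
  expect_true(all(k1 != k2))
  n1 <- predict_nb(train_nb(x, y), probes)
  n2 <- predict_nb(train_nb(x, y_swapped), probes)
  expect_true(all(n1 != n2))
})

test_that("k-NN majority vote, self-similarity and scale invariance behave", {
  # unanimous training class
  uni <- train_knn(matrix(rnorm(12), 4), factor(rep("z", 4)), k = 2)
  expect_equal(as.character(predict_knn(uni, rnorm(3))), "z")

  # query identical to one training vector, k = 1: that vector's class
  x <- matrix(rnorm(30), 6)
  y <- factor(c("a", "b", "a", "b", "a", "b"))
  m1 <- train_knn(x, y, k = 1)
  expect_equal(as.character(predict_knn(m1, x[4, ])), "b")

  # k = 6 with a 4-vs-2 split: majority of the 4 wins
  base <- c(1, 2, 3, 4, 5)
  xt <- rbind(base, base + 0.01, base + 0.02, base * 1.1, # class 'big': 4 correlated
              rev(base), rev(base) + 0.01)                # class 'small': 2
  yt <- factor(c("big", "big", "big", "big", "small", "small"))
  m6 <- train_knn(xt, yt, k = 6)
  expect_equal(as.character(predict_knn(m6, base + 0.005)), "big")

  # per-subject affine rescaling leaves Pearson similarity untouched
  m <- train_knn(blobs$x, blobs$y, k = 6)
  probe <- blobs$x[3, ]
  expect_equal(predict_knn(m, probe), predict_knn(m, 5 * probe + 2))

  # constant query vector warns and gets zero similarity
  expect_warning(predict_knn(m, rep(1, ncol(blobs$x))), "constant")
  expect_error(train_knn(blobs$x, blobs$y, k = 1000), "exceeds")
})

test_that("naive Bayes follows the factorized Gaussian rule with documented ties", {
  # test point at the class-A mean with equal priors and variances
  set.seed(11)
  xa <- matrix(rnorm(40, 0, 1), 20)
  xb <- matrix(rnorm(40, 4, 1), 20)
  m <- train_nb(rbind(xa, xb), factor(rep(c("A", "B"), each = 20)))
  expect_equal(as.character(predict_nb(m, m$means["A" == m$levels, ])), "A")

  # identical likelihoods: the larger prior wins
  x_same <- rbind(matrix(rnorm(18, 0, 1), 9), matrix(rnorm(2, 0, 1), 1))
  y_prior <- factor(rep(c("big", "rare"), c(9, 1)))
  mp <- train_nb(x_same, y_prior)
  # probe far from both (identical) class distributions: prior dominates
  expect_equal(as.character(predict_nb(mp, colMeans(x_same))), "big")

  # exact symmetric tie: equal priors, means 0 and 2, x = 1 -> lower class index
  xt <- matrix(c(-1, 1, 1, 3), 4)
  yt <- factor(c("a", "a", "b", "b"))
  mt <- train_nb(xt, yt)
  expect_equal(mt$means[, 1], c(0, 2), ignore_attr = TRUE)
  expect_equal(as.character(predict_nb(mt, matrix(1))), "a")

  # zero-variance features are floored with a warning
  xz <- cbind(c(1, 1, 2, 2), c(5, 5, 5, 5))
  expect_warning(mz <- train_nb(xz, yt), "floored")
  expect_true(all(mz$variances > 0))
})

test_that("hand-rolled naive Bayes agrees with an independent implementation", {
  set.seed(13)
  x <- rbind(matrix(rnorm(60, 0), 15), matrix(rnorm(60, 1.2), 15))
  y <- factor(rep(c("a", "b"), each = 15))
  probes <- matrix(rnorm(80, 0.6), 20)
  ours <- predict_nb(train_nb(x, y), probes)
  df <- data.frame(x, y = y)
  ref_model <- e1071::naiveBayes(y ~ ., data = df)
  ref <- predict(ref_model, data.frame(matrix(probes, 20,
                                              dimnames = list(NULL, names(df)[1:4]))))
  expect_equal(as.character(ours), as.character(ref))
})

test_that("classifier models serialize to JSON", {
  m <- train_nb(blobs$x[, 1:3], blobs$y)
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$model_class, "naive_bayes_model")
  expect_equal(unlist(back$priors), m$priors, ignore_attr = TRUE)
})
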