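#' Maximum-margin (soft-margin SVM) classifier
#'
#' Trains the soft-margin maximum-margin hyperplane
#' `min 1/2 w'w + C sum(eps_k)` subject to `y_k (w' x_k + b) >= 1 - eps_k`,
#' with a linear kernel, on training-fold-standardized features. The quadratic
#' program is solved by libsvm (via e1071) to its default tolerance; the
#' normal vector `w` and offset `b` are extracted so prediction is the
#' explicit decision rule `sign(w' x + b)`, with `0` mapped to `+1`.
#' Standardization parameters (per-feature mean and sd, sd floored at 1e-12)
#' are learned on the training data only.
#'
#' @param x numeric feature matrix (rows = subjects).
#' @param y two-class labels (any two values; factor order fixes the sign:
#'   the first level is the positive class).
#' @param cost penalty C on training error, default 1.
#' @return an object of class `max_margin_model` with `w`, `b`, `center`,
#'   `scale`, `levels`.
#' @export
train_max_margin <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (length(levels(droplevels(y))) != 2) stop_validation("exactly two classes are required")
  y <- droplevels(y)
  check_positive(cost, "cost", 1)
  center <- colMeans(x)
  scl <- pmax(apply(x, 2, sd), 1e-12)
  xs <- scale(x, center = center, scale = scl)
  fit <- e1071::svm(xs, y, type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients its decision value by order of appearance in the training
  # data; re-orient w, b so a positive value means the FIRST factor level of y
  dv <- attr(predict(fit, xs[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  positive_class <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  if (positive_class != levels(y)[1]) {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, center = center, scale = scl,
                 levels = levels(y), cost = cost),
            class = "max_margin_model")
}

#' @rdname train_max_margin
#' @param model a trained `max_margin_model`.
#' @param newdata matrix or vector of feature values.
#' @return predicted labels (factor with the training levels).
#' @export
predict_max_margin <- function(model, newdata) {
  stopifnot(inherits(model, "max_margin_model"))
  nd <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(nd) != length(model$w)) stop_validation("feature dimension mismatch")
  nds <- scale(nd, center = model$center, scale = model$scale)
  dv <- as.numeric(nds %*% model$w + model$b)
  factor(ifelse(dv >= 0, model$levels[1], model$levels[2]),
         levels = model$levels)
}

#' k-nearest-neighbor classifier with Pearson-correlation similarity
#'
#' Stores the training matrix; a query is classified by a majority vote of
#' the `k` training subjects with the highest Pearson correlation to it.
#' Vote ties are broken by the larger summed similarity, then by the class of
#' the single most similar neighbor. Correlations with a constant vector are
#' undefined and treated as 0 (with a warning).
#'
#' @param x training feature matrix.
#' @param y class labels.
#' @param k number of neighbors, default 6.
#' @return an object of class `knn_model`.
#' @export
train_knn <- function(x, y, k = 6) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  check_positive(k, "k", 1)
  if (k > nrow(x)) stop_validation("k exceeds the number of training subjects")
  structure(list(x = x, y = y, k = as.integer(k)), class = "knn_model")
}

# Pearson correlation of a query with every training row; vectors on which the
# correlation is undefined (constant, or fewer than 2 features) count as 0
pearson_similarity <- function(train_x, query) {
  varies <- function(v) length(v) >= 2 && isTRUE(sd(v) > 0)
  warn_const <- !varies(query)
  sims <- apply(train_x, 1, function(row) {
    if (!varies(row)) {
      warn_const <<- TRUE
      return(0)
    }
    if (!varies(query)) return(0)
    cor(row, query)
  })
  if (warn_const) warning("constant feature vector: correlation treated as 0")
  sims
}

#' @rdname train_knn
#' @param model a `knn_model`.
#' @param newdata matrix or vector of feature values.
#' @return predicted labels.
#' @export
predict_knn <- function(model, newdata) {
  stopifnot(inherits(model, "knn_model"))
  nd <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(nd) != ncol(model$x)) stop_validation("feature dimension mismatch")
  out <- character(nrow(nd))
  for (q in seq_len(nrow(nd))) {
    sims <- pearson_similarity(model$x, nd[q, ])
    ord <- order(-sims, seq_along(sims))   # deterministic on similarity ties
    nb <- ord[seq_len(model$k)]
    votes <- table(model$y[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      sums <- vapply(top, function(cl) sum(sims[nb][model$y[nb] == cl]), 0)
      top <- top[sums == max(sums)]
      if (length(top) > 1) top <- as.character(model$y[nb[1]])
    }
    out[q] <- top[1]
  }
  factor(out, levels = levels(model$y))
}

#' Gaussian naive Bayes classifier
#'
#' Class-conditional densities factorize over features with Gaussian
#' `p(x_i | c)`; prediction maximizes `log p(c) + sum_i log p(x_i | c)`
#' (log-space throughout). Per-class feature variances are floored at
#' `1e-9` times the pooled variance of that feature (with an absolute floor
#' for all-constant features), with a warning when flooring occurs.
#' Exact posterior ties are broken toward the class with the larger prior,
#' then the lower class index.
#'
#' @param x training feature matrix.
#' @param y class labels (two or more classes).
#' @return an object of class `naive_bayes_model` with `priors`, `means`,
#'   `variances`, `levels`.
#' @export
train_nb <- function(x, y) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (length(levels(y)) < 2) stop_validation("at least two classes are required")
  classes <- levels(y)
  priors <- as.numeric(table(y)[classes]) / length(y)
  pooled <- apply(x, 2, var)
  floor_var <- pmax(1e-9 * pooled, .Machine$double.eps)
  means <- do.call(rbind, lapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE])))
  vars <- do.call(rbind, lapply(classes, function(cl) {
    v <- apply(x[y == cl, , drop = FALSE], 2, var)
    v[is.na(v)] <- 0
    v
  }))
  if (any(vars < matrix(floor_var, nrow(vars), ncol(vars), byrow = TRUE))) {
    warning("zero-variance feature(s): variance floored")
  }
  vars <- pmax(vars, matrix(floor_var, nrow(vars), ncol(vars), byrow = TRUE))
  structure(list(priors = priors, means = means, variances = vars,
                 levels = classes), class = "naive_bayes_model")
}

#' @rdname train_nb
#' @param model a `naive_bayes_model`.
#' @param newdata matrix or vector of feature values.
#' @return predicted labels.
#' @export
predict_nb <- function(model, newdata) {
  stopifnot(inherits(model, "naive_bayes_model"))
  nd <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(nd) != ncol(model$means)) stop_validation("feature dimension mismatch")
  n_class <- length(model$levels)
  out <- character(nrow(nd))
  for (q in seq_len(nrow(nd))) {
    ll <- vapply(seq_len(n_class), function(c) {
      log(model$priors[c]) +
        sum(dnorm(nd[q, ], model$means[c, ], sqrt(model$variances[c, ]), log = TRUE))
    }, 0)
    best <- which(ll >= max(ll) - 1e-12)
    if (length(best) > 1) {
      best <- best[order(-model$priors[best], best)]
    }
    out[q] <- model$levels[best[1]]
  }
  factor(out, levels = model$levels)
}

#' Serialize a trained classifier to JSON
#'
#' @param model a `max_margin_model`, `knn_model` or `naive_bayes_model`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  obj <- unclass(model)
  obj$model_class <- class(model)[1]
  if (!is.null(obj$y)) obj$y <- as.character(obj$y)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
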