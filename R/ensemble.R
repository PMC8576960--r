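#' Train a CART base learner
#'
#' Grows a classification tree (rpart) with cost-complexity pruning at
#' the given complexity parameter, optional per-sample weights, and
#' class-probability output. Settings allow splits down to single
#' samples so the complexity parameter alone governs tree size. A
#' single-class response yields a flagged degenerate model that always
#' predicts that class.
#'
#' @param X Feature data frame (numeric columns).
#' @param y Class labels, values in `{PAF, normal}`.
#' @param cp Complexity parameter (default 0.1).
#' @param weights Optional nonnegative sample weights.
#' @return An object of class `cart_model`.
#' @export
train_cart <- function(X, y, cp = 0.1, weights = NULL) {
  if (cp <= 0) stopf("complexity parameter must be positive")
  y <- factor(as.character(y), levels = c("normal", "PAF"))
  if (anyNA(y)) stopf("labels must be 'PAF' or 'normal'")
  if (length(unique(y)) < 2L) {
    return(structure(list(fit = NULL, constant = as.character(y[1L]),
                          degenerate = TRUE), class = "cart_model"))
  }
  df <- cbind(.y = y, X)
  fit <- rpart::rpart(.y ~ ., data = df, weights = weights,
                      method = "class",
                      control = rpart::rpart.control(
                        cp = cp, xval = 0, minsplit = 2, minbucket = 1,
                        maxcompete = 0, maxsurrogate = 0))
  structure(list(fit = fit, constant = NULL, degenerate = FALSE),
            class = "cart_model")
}

# P(PAF) scores from a cart_model
cart_score <- function(model, X) {
  if (model$degenerate)
    return(rep(if (model$constant == "PAF") 1 else 0, nrow(X)))
  p <- predict(model$fit, newdata = X, type = "prob")
  if ("PAF" %in% colnames(p)) unname(p[, "PAF"]) else rep(0, nrow(X))
}

#' @export
predict.cart_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  s <- cart_score(object, newdata)
  if (type == "score") s else ifelse(s >= 0.5, "PAF", "normal")
}

# --- internal trainers ------------------------------------------------

# Bagging: bootstrap resample -> tree; redraw until the member's accuracy
# on its own resample exceeds 0.5, within the retry budget.
fit_bagging <- function(X, y, n_members, cp, max_retries) {
  n <- nrow(X)
  members <- vector("list", n_members)
  train_acc <- numeric(n_members)
  for (m in seq_len(n_members)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      idx <- sample.int(n, n, replace = TRUE)
      tree <- train_cart(X[idx, , drop = FALSE], y[idx], cp = cp)
      acc <- mean(predict(tree, X[idx, , drop = FALSE]) == y[idx])
      if (acc > 0.5) { ok <- TRUE; break }
    }
    if (!ok)
      stopf("training error: bagging member %d never exceeded 0.5 resample accuracy in %d redraws",
            m, max_retries)
    members[[m]] <- tree
    train_acc[m] <- acc
  }
  list(members = members, train_acc = train_acc)
}

# one AdaBoost weight update: correct samples' weights shrink by beta,
# then all weights renormalize to sum 1
adaboost_update_weights <- function(w, correct, beta) {
  w[correct] <- w[correct] * beta
  w / sum(w)
}

# AdaBoost (AdaBoost.M1 completion of the 7-step procedure): uniform
# initial weights; weighted bootstrap resample; redraw while the member's
# weighted accuracy is <= 0.5; beta = eps/(1 - eps); member vote weight
# log(1/beta); weights renormalized each round.
fit_adaboost <- function(X, y, n_members, cp, max_retries) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  members <- vector("list", n_members)
  alpha <- numeric(n_members)
  train_acc <- numeric(n_members)
  for (m in seq_len(n_members)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      tree <- train_cart(X[idx, , drop = FALSE], y[idx], cp = cp)
      pred <- predict(tree, X)
      wacc <- sum(w[pred == y])
      if (wacc > 0.5) { ok <- TRUE; break }
    }
    if (!ok)
      stopf("training error: adaboost member %d never exceeded 0.5 weighted accuracy in %d redraws",
            m, max_retries)
    eps <- 1 - wacc
    beta <- if (eps <= 0) 1e-10 else eps / (1 - eps)
    w <- adaboost_update_weights(w, pred == y, beta)
    members[[m]] <- tree
    alpha[m] <- log(1 / beta)
    train_acc[m] <- wacc
  }
  list(members = members, alpha = alpha, train_acc = train_acc)
}

ensemble_score <- function(members, weights, X) {
  votes <- vapply(members, function(m) predict(m, X) == "PAF",
                  logical(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  unname(drop(votes %*% weights)) / sum(weights)
}

#' Fit a CART-based ensemble classifier for PAF screening
#'
#' The single entry point for the three ensemble procedures over a CART
#' base learner:
#' \describe{
#'   \item{bagging}{`n_members` trees, each on a bootstrap resample,
#'     redrawn until its resample accuracy exceeds 0.5; unweighted
#'     majority vote.}
#'   \item{adaboost}{sequential weighted-bootstrap boosting: members
#'     with weighted accuracy `<= 0.5` are redrawn; correctly classified
#'     samples' weights shrink by `beta = eps / (1 - eps)` and are
#'     renormalized; members vote with weight `log(1 / beta)`.}
#'   \item{stacking}{two layers: the layer-1 ensembles (default bagging
#'     and adaboost) are trained on all training data; their
#'     out-of-fold prediction scores (5-fold by default, avoiding
#'     leakage into the meta-learner) form the inputs of a
#'     logistic-regression meta-model.}
#' }
#' Missing feature values are imputed by training-set medians stored in
#' the model and reapplied at prediction time. PAF is the positive
#' class; majority-vote and probability ties break toward PAF (favoring
#' screening sensitivity).
#'
#' @param formula Model formula, e.g. `label ~ .`; the response must
#'   take values in `{PAF, normal}`.
#' @param data Data frame with the response and numeric features.
#' @param method `"bagging"`, `"adaboost"` or `"stacking"`.
#' @param n_members Trees per ensemble (default 100).
#' @param cp CART complexity parameter (default 0.1).
#' @param layer1 Layer-1 methods for stacking.
#' @param oof_meta Use out-of-fold layer-1 scores for meta-training
#'   (`FALSE` uses in-sample scores).
#' @param oof_folds Folds for the out-of-fold scores.
#' @param max_retries Redraw budget per member slot.
#' @param seed Seed; training is deterministic given the seed.
#' @return An object of class `paf_ensemble` (and
#'   `paf_<method>`), with [predict.paf_ensemble()], `print`, `summary`
#'   and `coef` methods.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = c(rnorm(20, 0), rnorm(20, 3)),
#'                 label = rep(c("normal", "PAF"), each = 20))
#' fit <- paf_ensemble(label ~ ., d, method = "bagging", n_members = 11,
#'                     seed = 1)
#' mean(predict(fit, d) == d$label)
#' @export
paf_ensemble <- function(formula, data,
                         method = c("bagging", "adaboost", "stacking"),
                         n_members = 100, cp = 0.1,
                         layer1 = c("bagging", "adaboost"),
                         oof_meta = TRUE, oof_folds = 5,
                         max_retries = 50, seed = 1) {
  method <- match.arg(method)
  if (n_members < 1) stopf("'n_members' must be >= 1")
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- as.character(stats::model.response(mf))
  X <- mf[, -1L, drop = FALSE]
  X <- X[vapply(X, is.numeric, logical(1))]
  if (!all(y %in% c("PAF", "normal")))
    stopf("response values must be 'PAF' or 'normal'")
  if (length(unique(y)) < 2L)
    stopf("training data must contain both classes")
  medians <- vapply(X, function(col) stats::median(col, na.rm = TRUE),
                    numeric(1))
  X <- impute_medians(X, medians)
  obj <- with_seed(seed, {
    if (method == "bagging") {
      fb <- fit_bagging(X, y, n_members, cp, max_retries)
      list(members = fb$members, member_weights = rep(1, n_members),
           member_train_acc = fb$train_acc)
    } else if (method == "adaboost") {
      fa <- fit_adaboost(X, y, n_members, cp, max_retries)
      list(members = fa$members, member_weights = fa$alpha,
           member_train_acc = fa$train_acc)
    } else {
      if (length(layer1) < 2L)
        stopf("configuration error: stacking needs >= 2 layer-1 models")
      fit_one <- function(meth, Xd, yd) {
        if (meth == "bagging") {
          fb <- fit_bagging(Xd, yd, n_members, cp, max_retries)
          list(members = fb$members, weights = rep(1, n_members))
        } else if (meth == "adaboost") {
          fa <- fit_adaboost(Xd, yd, n_members, cp, max_retries)
          list(members = fa$members, weights = fa$alpha)
        } else stopf("unknown layer-1 method '%s'", meth)
      }
      l1 <- lapply(layer1, fit_one, Xd = X, yd = y)
      names(l1) <- layer1
      meta_X <- if (oof_meta) {
        folds <- stratified_folds(y, min(oof_folds, min(table(y))))
        mx <- matrix(NA_real_, nrow(X), length(layer1),
                     dimnames = list(NULL, layer1))
        for (f in sort(unique(folds))) {
          tr <- folds != f
          for (j in seq_along(layer1)) {
            m <- fit_one(layer1[j], X[tr, , drop = FALSE], y[tr])
            mx[!tr, j] <- ensemble_score(m$members, m$weights,
                                         X[!tr, , drop = FALSE])
          }
        }
        mx
      } else {
        mx <- vapply(l1, function(m)
          ensemble_score(m$members, m$weights, X), numeric(nrow(X)))
        colnames(mx) <- layer1
        mx
      }
      meta_df <- data.frame(.y = factor(y, levels = c("normal", "PAF")),
                            meta_X)
      meta <- suppressWarnings(
        stats::glm(.y ~ ., data = meta_df, family = stats::binomial()))
      list(layer1 = l1, meta = meta, meta_features = meta_X)
    }
  })
  structure(c(obj, list(method = method, n_members = n_members, cp = cp,
                        feature_names = names(medians), medians = medians,
                        layer1_names = if (method == "stacking") layer1,
                        seed = seed, call = match.call())),
            class = c(paste0("paf_", method), "paf_ensemble"))
}

impute_medians <- function(X, medians) {
  for (nm in names(medians)) {
    i <- is.na(X[[nm]])
    if (any(i)) X[[nm]][i] <- medians[[nm]]
  }
  X
}

#' Predict method for PAF ensembles
#'
#' @param object A fitted [paf_ensemble()].
#' @param newdata Data frame with the training feature columns.
#' @param type `"class"` for labels, `"score"` for the PAF score
#'   (vote fraction, normalized weighted vote, or meta-model
#'   probability, by method). Scores at exactly 0.5 classify as PAF.
#' @param ... Unused.
#' @return Character labels or numeric scores.
#' @export
predict.paf_ensemble <- function(object, newdata,
                                 type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- newdata[object$feature_names]
  X <- impute_medians(X, object$medians)
  s <- if (object$method == "stacking") {
    mx <- vapply(object$layer1, function(m)
      ensemble_score(m$members, m$weights, X), numeric(nrow(X)))
    mx <- matrix(mx, nrow = nrow(X),
                 dimnames = list(NULL, object$layer1_names))
    as.numeric(stats::predict(object$meta, newdata = as.data.frame(mx),
                              type = "response"))
  } else {
    ensemble_score(object$members, object$member_weights, X)
  }
  if (type == "score") s else ifelse(s >= 0.5, "PAF", "normal")
}

#' @export
print.paf_ensemble <- function(x, ...) {
  cat(sprintf("PAF %s ensemble: %d CART members (cp = %g)\n",
              x$method, x$n_members, x$cp))
  if (x$method == "stacking")
    cat("  layer 1:", paste(x$layer1_names, collapse = " + "),
        "-> logistic meta-model\n")
  invisible(x)
}

#' @export
summary.paf_ensemble <- function(object, ...) {
  print(object)
  if (object$method %in% c("bagging", "adaboost")) {
    cat(sprintf("  member training accuracy: min %.3f, median %.3f, max %.3f\n",
                min(object$member_train_acc),
                stats::median(object$member_train_acc),
                max(object$member_train_acc)))
    if (object$method == "adaboost")
      cat(sprintf("  member vote weights: min %.3f, max %.3f\n",
                  min(object$member_weights), max(object$member_weights)))
  } else {
    cat("  meta-model coefficients:\n")
    print(stats::coef(object$meta))
  }
  invisible(object)
}

#' @export
coef.paf_ensemble <- function(object, ...) {
  switch(object$method,
         adaboost = object$member_weights,
         stacking = stats::coef(object$meta),
         NULL)
}
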