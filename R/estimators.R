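#' Fit a conditional class-probability estimator
#'
#' Any estimator of P(y | x) can be plugged into the set-valued classifier;
#' the reference implementation is a main-terms multinomial logistic
#' regression ([nnet::multinom()]), which is always available. Optional
#' adapters for penalized multinomial regression (`"glmnet"`) and random
#' forests (`"ranger"`) are provided when those packages are installed.
#'
#' @param train a labeled [cohort()].
#' @param spec estimator name: `"multinom"` (default), `"glmnet"`, or
#'   `"ranger"`.
#' @param ... hyperparameters forwarded to the underlying fitting function
#'   (e.g. `min.node.size`, `num.trees` for ranger; `alpha` for glmnet).
#' @return An object of class `"prob_estimator"` with elements `fit`,
#'   `spec`, `feature_names`, `n_classes`, `class_levels`.
#' @details Probability columns always follow the sorted class labels
#'   `1..K`. A class absent from the training data is an error: no
#'   probability could be estimated for it.
#' @examples
#' ch <- cohort(matrix(rnorm(60), 30, 2), labels = rep(1:3, 10))
#' fit <- fit_prob_estimator(ch)
#' p <- predict_proba(fit, ch$features)
#' stopifnot(all(abs(rowSums(p) - 1) < 1e-8))
#' @export
fit_prob_estimator <- function(train, spec = "multinom", ...) {
  stopifnot(inherits(train, "cohort"))
  if (is.null(train$labels)) stop("training cohort must carry labels")
  K <- train$n_classes
  present <- tabulate(train$labels, K) > 0L
  if (!all(present))
    stop("class ", which(!present)[1L], " absent from training data")
  x <- train$features
  y <- factor(train$labels, levels = seq_len(K))
  fit <- switch(
    spec,
    multinom = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      nnet::multinom(.y ~ ., data = df, trace = FALSE,
                     maxit = 500, MaxNWts = 5000, ...)
    },
    glmnet = {
      if (!requireNamespace("glmnet", quietly = TRUE))
        stop("estimator 'glmnet' requires the glmnet package")
      glmnet::cv.glmnet(x, y, family = "multinomial", ...)
    },
    ranger = {
      if (!requireNamespace("ranger", quietly = TRUE))
        stop("estimator 'ranger' requires the ranger package")
      ranger::ranger(x = x, y = y, probability = TRUE, ...)
    },
    stop("unknown estimator spec: '", spec, "'")
  )
  structure(
    list(fit = fit, spec = spec, feature_names = colnames(x),
         n_classes = K, class_levels = seq_len(K)),
    class = "prob_estimator"
  )
}

#' Predict conditional class probabilities
#'
#' @param model a fitted [fit_prob_estimator()].
#' @param features numeric matrix whose columns match the training features.
#' @return An n x K row-stochastic probability matrix, columns ordered by
#'   class label.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "prob_estimator"))
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- model$feature_names[seq_len(ncol(features))]
  missing_cols <- setdiff(model$feature_names, colnames(features))
  extra_cols <- setdiff(colnames(features), model$feature_names)
  if (length(missing_cols) || length(extra_cols))
    stop("feature columns do not match training",
         if (length(missing_cols))
           paste0("; missing: ", paste(missing_cols, collapse = ", ")),
         if (length(extra_cols))
           paste0("; extra: ", paste(extra_cols, collapse = ", ")))
  features <- features[, model$feature_names, drop = FALSE]
  K <- model$n_classes
  p <- switch(
    model$spec,
    multinom = {
      df <- as.data.frame(features)
      pr <- stats::predict(model$fit, newdata = df, type = "probs")
      if (is.null(dim(pr))) {    # K = 2: multinom returns P(class 2)
        if (K != 2L) pr <- matrix(pr, nrow = 1) else pr <- cbind(1 - pr, pr)
      }
      pr
    },
    glmnet = {
      pr <- stats::predict(model$fit, newx = features, type = "response",
                           s = "lambda.min")
      pr[, , 1L]
    },
    ranger = stats::predict(model$fit, data = features)$predictions
  )
  p <- matrix(as.numeric(p), nrow = nrow(features), ncol = K)
  validate_prob_matrix(p)
}

#' Validate (and minimally renormalize) a probability matrix
#'
#' Checks that all entries lie in `[0, 1]` and each row sums to 1 within
#' `tol`; rows within tolerance are renormalized to sum exactly to 1,
#' anything further off is an error.
#'
#' @param probs numeric matrix.
#' @param tol row-sum tolerance.
#' @return The validated, renormalized matrix.
#' @export
validate_prob_matrix <- function(probs, tol = 1e-8) {
  probs <- as.matrix(probs)
  if (anyNA(probs)) stop("probability matrix contains NA")
  if (any(probs < -tol) || any(probs > 1 + tol))
    stop("probabilities outside [0, 1]")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > tol))
    stop("probability rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  probs / rs
}
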