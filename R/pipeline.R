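#' Classification pipeline components
#'
#' A trained pipeline couples min-max scaler parameters (fit on training
#' data only) with one of two classifiers: a linear soft-margin support
#' vector classifier (SVC) or a small fully connected network (DLC) with
#' two hidden layers and a 2-node softmax output. Inputs are always scaled
#' per ROI before classification so that volume-scale features cannot
#' dominate thickness-scale ones.
#'
#' @name pipeline
NULL

#' Undersample the majority class to balance a binary task
#'
#' Randomly drops majority-class subjects (without replacement) until both
#' classes have the minority size. The minority class is untouched and the
#' original row order is preserved among kept rows.
#'
#' @param cohort A [roi_cohort].
#' @param labels Integer 0/1 vector aligned with the cohort rows.
#' @param seed Integer seed controlling the subsample.
#' @return A list with the balanced `cohort` and `labels`.
#' @export
balance_cohort <- function(cohort, labels, seed = 1L) {
  stopifnot(length(labels) == n_subjects(cohort))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  if (n1 == n0) return(list(cohort = cohort, labels = labels))
  maj <- if (n0 > n1) 0L else 1L
  maj_idx <- which(labels == maj)
  keep_maj <- with_seed(seed, sample(maj_idx, min(n0, n1)))
  keep <- sort(c(which(labels != maj), keep_maj))
  list(cohort = subset_cohort(cohort, keep), labels = labels[keep])
}

#' Fit per-ROI min-max scaling parameters
#'
#' @param X_fit Numeric training matrix (rows = subjects).
#' @return A `scaler_params` object with per-feature `min` and `max`.
#' @export
fit_scaler <- function(X_fit) {
  if (!nrow(X_fit)) stopf("cannot fit scaler on an empty matrix")
  structure(list(min = apply(X_fit, 2, min), max = apply(X_fit, 2, max)),
            class = "scaler_params")
}

#' Apply fitted min-max scaling
#'
#' `x' = (x - min)/(max - min)` with fitted parameters; a constant feature
#' (max = min) maps to 0 on its fitting data. Held-out values outside the
#' fitted range are not clipped.
#'
#' @param params A `scaler_params` from [fit_scaler()].
#' @param X Matrix to scale (same feature count/order).
#' @return Scaled matrix.
#' @export
apply_scaler <- function(params, X) {
  rng <- params$max - params$min
  rng[rng == 0] <- 1  # constant feature: x - min = 0 on fitting data
  sweep(sweep(X, 2, params$min, "-"), 2, rng, "/")
}

# ---- linear SVC --------------------------------------------------------

#' Train a linear soft-margin support vector classifier
#'
#' Solved by deterministic dual coordinate descent (hinge loss, L2
#' regularization, regularized bias).
#'
#' @param X Scaled feature matrix.
#' @param y Integer 0/1 labels.
#' @param C Regularization strength (> 0); larger C fits the margin harder.
#' @param tol,max_passes Solver stopping parameters.
#' @return An `svc_model` with weight vector `w`, bias `b` and `C`.
#' @export
train_svc <- function(X, y, C = 1.0, tol = 0.01, max_passes = 1000L) {
  if (length(unique(y)) < 2) stopf("training labels contain a single class")
  if (C <= 0) stopf("C must be > 0")
  fit <- svm_dcd(as.matrix(X), as.integer(y), C, tol, max_passes)
  structure(list(w = as.numeric(fit$w), b = fit$b, C = C,
                 passes = fit$passes), class = "svc_model")
}

#' @export
predict.svc_model <- function(object, newdata, type = c("class", "score"),
                              ...) {
  type <- match.arg(type)
  score <- as.numeric(as.matrix(newdata) %*% object$w + object$b)
  if (type == "score") score else as.integer(score > 0)
}

# ---- dense network (DLC) ----------------------------------------------

#' DLC hyperparameter configuration
#'
#' Defaults sit at the low end / middle of the standard search ranges:
#' learning rate 0.001-0.01, epochs 100-800, hidden layer 1 width 5-100,
#' hidden layer 2 width 3-20, L2 penalty 0.1-0.7, dropout 0.2-0.5.
#'
#' @param learning_rate Adam step size.
#' @param epochs Full-batch training epochs.
#' @param hidden1,hidden2 Hidden layer widths (>= 1).
#' @param l2_penalty L2 penalty coefficient on the first hidden layer's
#'   weights.
#' @param dropout_rate Dropout fraction after hidden layer 1 (training
#'   only); between 0 and 1 (exclusive).
#' @param activation `"linear"` (default, making the net affine end to
#'   end) or `"relu"`.
#' @param seed Integer seed for weight initialization and dropout masks.
#' @return A validated `dlc_config` list.
#' @export
dlc_config <- function(learning_rate = 0.005, epochs = 300, hidden1 = 20,
                       hidden2 = 10, l2_penalty = 0.1, dropout_rate = 0.2,
                       activation = c("linear", "relu"), seed = 1L) {
  activation <- match.arg(activation)
  if (hidden1 < 1 || hidden2 < 1) stopf("hidden layer sizes must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("dropout_rate must be in [0, 1)")
  if (learning_rate <= 0 || epochs < 1) stopf("invalid optimizer settings")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
                 l2_penalty = l2_penalty, dropout_rate = dropout_rate,
                 activation = activation, seed = as.integer(seed)),
            class = "dlc_config")
}

#' Train the dense network classifier
#'
#' Fully connected net: input (one node per ROI) -> hidden1 (L2-penalized,
#' dropout) -> hidden2 -> 2 output nodes with softmax, trained with
#' full-batch Adam on the cross-entropy loss. Dropout is active only
#' during training. Fully reproducible from `config$seed`.
#'
#' @param X Scaled feature matrix.
#' @param y Integer 0/1 labels.
#' @param config A [dlc_config()].
#' @return A `dlc_model` holding the layer weights and the configuration.
#' @export
train_dlc <- function(X, y, config = dlc_config()) {
  stopifnot(inherits(config, "dlc_config"))
  if (length(unique(y)) < 2) stopf("training labels contain a single class")
  X <- as.matrix(X)
  with_seed(config$seed, train_dlc_impl(X, as.integer(y), config))
}

train_dlc_impl <- function(X, y, cfg) {
  n <- nrow(X); p <- ncol(X)
  h1 <- cfg$hidden1; h2 <- cfg$hidden2
  relu <- cfg$activation == "relu"
  glorot <- function(a, b) matrix(rnorm(a * b, sd = sqrt(2 / (a + b))), a, b)
  W1 <- glorot(p, h1); b1 <- numeric(h1)
  W2 <- glorot(h1, h2); b2 <- numeric(h2)
  W3 <- glorot(h2, 2);  b3 <- numeric(2)
  Y <- cbind(1 - y, y)                      # one-hot: col 1 = class 0
  params <- list(W1, b1, W2, b2, W3, b3)
  mom <- lapply(params, function(p) p * 0)
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  keep <- 1 - cfg$dropout_rate
  lr <- cfg$learning_rate

  for (t in seq_len(cfg$epochs)) {
    A1 <- sweep(X %*% W1, 2, b1, "+")
    H1 <- if (relu) pmax(A1, 0) else A1
    mask <- if (cfg$dropout_rate > 0)
      matrix(rbinom(n * h1, 1, keep), n, h1) / keep
    else matrix(1, n, h1)
    H1d <- H1 * mask
    A2 <- sweep(H1d %*% W2, 2, b2, "+")
    H2 <- if (relu) pmax(A2, 0) else A2
    O <- sweep(H2 %*% W3, 2, b3, "+")
    P <- softmax_rows(O)

    dO <- (P - Y) / n
    gW3 <- crossprod(H2, dO); gb3 <- colSums(dO)
    dH2 <- dO %*% t(W3)
    if (relu) dH2 <- dH2 * (A2 > 0)
    gW2 <- crossprod(H1d, dH2); gb2 <- colSums(dH2)
    dH1 <- (dH2 %*% t(W2)) * mask
    if (relu) dH1 <- dH1 * (A1 > 0)
    gW1 <- crossprod(X, dH1) + 2 * cfg$l2_penalty * W1
    gb1 <- colSums(dH1)

    grads <- list(gW1, gb1, gW2, gb2, gW3, gb3)
    params <- list(W1, b1, W2, b2, W3, b3)
    for (k in seq_along(params)) {
      mom[[k]] <- beta1 * mom[[k]] + (1 - beta1) * grads[[k]]
      vel[[k]] <- beta2 * vel[[k]] + (1 - beta2) * grads[[k]]^2
      mhat <- mom[[k]] / (1 - beta1^t)
      vhat <- vel[[k]] / (1 - beta2^t)
      params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
    W1 <- params[[1]]; b1 <- params[[2]]; W2 <- params[[3]]
    b2 <- params[[4]]; W3 <- params[[5]]; b3 <- params[[6]]
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3,
                 config = cfg), class = "dlc_model")
}

softmax_rows <- function(O) {
  E <- exp(O - apply(O, 1, max))
  E / rowSums(E)
}

dlc_forward <- function(model, X) {
  relu <- model$config$activation == "relu"
  H1 <- sweep(as.matrix(X) %*% model$W1, 2, model$b1, "+")
  if (relu) H1 <- pmax(H1, 0)
  H2 <- sweep(H1 %*% model$W2, 2, model$b2, "+")
  if (relu) H2 <- pmax(H2, 0)
  softmax_rows(sweep(H2 %*% model$W3, 2, model$b3, "+"))
}

#' @export
predict.dlc_model <- function(object, newdata,
                              type = c("class", "prob", "score"), ...) {
  type <- match.arg(type)
  P <- dlc_forward(object, newdata)
  switch(type,
         class = as.integer(P[, 2] > P[, 1]),
         prob = P,
         score = as.numeric(P[, 2]))
}

# ---- trained pipeline (scaler + classifier) ---------------------------

#' Fit a full pipeline (scaler + classifier) on training data
#'
#' @param X Unscaled training matrix.
#' @param y Integer 0/1 labels.
#' @param kind `"svc"` or `"dlc"`.
#' @param params For `"svc"`, a list with `C`; for `"dlc"`, a list of
#'   [dlc_config()] arguments.
#' @return A `pipeline_model` with `scaler`, `classifier`, `kind`, `params`.
#' @export
fit_pipeline <- function(X, y, kind = c("svc", "dlc"), params = list()) {
  kind <- match.arg(kind)
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  classifier <- if (kind == "svc") {
    train_svc(Xs, y, C = params$C %||% 1.0)
  } else {
    train_dlc(Xs, y, do.call(dlc_config, params))
  }
  structure(list(scaler = scaler, classifier = classifier, kind = kind,
                 params = params), class = "pipeline_model")
}

#' @export
predict.pipeline_model <- function(object, newdata,
                                   type = c("class", "score"), ...) {
  type <- match.arg(type)
  Xs <- apply_scaler(object$scaler, as.matrix(newdata))
  if (object$kind == "svc") predict(object$classifier, Xs, type = type)
  else predict(object$classifier, Xs,
               type = if (type == "class") "class" else "score")
}
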