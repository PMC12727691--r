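# The population read-out: a one-layer network with a single sigmoid unit
# trained on cross-entropy, early-stopped on validation error.

#' Decoder training contract
#'
#' @param patience Stop after this many successive epochs of rising
#'   validation error, returning the weights at minimum validation error
#'   (default 6).
#' @param gradient_tol Stop when the gradient infinity-norm falls below
#'   this (default 1e-7).
#' @param max_epochs Epoch cap (default 10000).
#' @param learning_rate Initial step size of the (bold-driver adapted)
#'   batch gradient descent.
#' @return List of class `decoder_spec`.
#' @export
decoder_spec <- function(patience = 6, gradient_tol = 1e-7,
                         max_epochs = 10000, learning_rate = 1) {
  structure(list(patience = as.integer(patience),
                 gradient_tol = gradient_tol,
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate),
            class = "decoder_spec")
}

#' Z-score a trials-by-neurons matrix per neuron
#'
#' Each column is centred and scaled to unit SD (denominator n - 1).
#' Constant columns become all zeros with a warning.
#'
#' @param x Numeric matrix, trials in rows.
#' @return Matrix of the same shape.
#' @export
zscore_per_neuron <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 trials to z-score")
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  flat <- s == 0 | !is.finite(s)
  if (any(flat)) {
    warning(sum(flat), " constant column(s) z-scored to 0")
    s[flat] <- 1
  }
  out <- sweep(sweep(x, 2, mu), 2, s, "/")
  out[, flat] <- 0
  out
}

#' Train the category read-out
#'
#' Single linear unit with sigmoid output, trained on cross-entropy by a
#' deterministic batch gradient method honouring the early-stopping
#' contract of [decoder_spec()]. Deterministic given its inputs (weights
#' start at zero; the loss is convex).
#'
#' @param x_train,y_train Training matrix and 0/1 labels (both classes
#'   required).
#' @param x_val,y_val Validation matrix and labels (used only for early
#'   stopping).
#' @param spec A [decoder_spec()].
#' @return List of class `linear_decoder`: `weights`, `bias`, `epochs`,
#'   `stop_reason`, `val_error`.
#' @export
train_decoder <- function(x_train, y_train, x_val, y_val,
                          spec = decoder_spec()) {
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  y_train <- as.integer(y_train); y_val <- as.integer(y_val)
  if (length(unique(y_train)) < 2) stop("single-class training set")
  if (length(unique(y_val)) < 2) stop("single-class validation set")
  fit <- .train_logistic_unit(x_train, y_train, x_val, y_val,
                              spec$max_epochs, spec$patience,
                              spec$gradient_tol, spec$learning_rate)
  class(fit) <- "linear_decoder"
  fit
}

#' Decoder scores and class predictions
#'
#' @param object A `linear_decoder`.
#' @param x Matrix of trials to score.
#' @param type `"response"` (sigmoid output), `"link"` (logit scale) or
#'   `"class"` (0/1 at threshold 0.5).
#' @param ... Unused.
#' @return Numeric (or integer for `"class"`) vector.
#' @export
predict.linear_decoder <- function(object, x, type = "response", ...) {
  type <- match.arg(type, c("response", "link", "class"))
  s <- .sigmoid_scores(as.matrix(x), object$weights, object$bias)
  switch(type,
         response = s,
         link = log(s / (1 - s)),
         class = as.integer(s > 0.5))
}
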