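# Small configurable multilayer perceptron, trained by mini-batch gradient
# descent on cross-entropy. One ReLU hidden layer by default; the output
# layer is zero-initialized so the untrained network is exactly uninformative
# (all logits zero) and class scores grow only through training signal.

#' Initialize a multilayer-perceptron classifier
#'
#' @param d Input feature dimension.
#' @param C Number of output classes.
#' @param hidden Hidden-layer width. Default 32.
#' @param seed Integer seed for the (hidden-layer) weight initialization.
#' @return An object of class `mlp_model`.
#' @export
mlp_init <- function(d, C, hidden = 32L, seed = 1) {
  stopifnot_scalar(d, "d", lower = 1, integer = TRUE)
  stopifnot_scalar(C, "C", lower = 1, integer = TRUE)
  stopifnot_scalar(hidden, "hidden", lower = 1, integer = TRUE)
  with_seed(seed, {
    structure(
      list(
        W1 = matrix(stats::rnorm(d * hidden, sd = 1 / sqrt(d)), d, hidden),
        b1 = numeric(hidden),
        W2 = matrix(0, hidden, C),
        b2 = numeric(C),
        d = as.integer(d), C = as.integer(C), hidden = as.integer(hidden)
      ),
      class = "mlp_model"
    )
  })
}

#' Logits of an MLP on a feature matrix
#'
#' @param model An `mlp_model`.
#' @param X Feature matrix (rows = samples).
#' @return Matrix of logits (`nrow(X)` by `C`).
#' @export
mlp_logits <- function(model, X) {
  X <- as_matrix(X, "X")
  if (ncol(X) != model$d) stop("feature dimension mismatch", call. = FALSE)
  H <- pmax(sweep(X %*% model$W1, 2L, model$b1, "+"), 0)
  sweep(H %*% model$W2, 2L, model$b2, "+")
}

#' Class probabilities and class predictions of an MLP
#'
#' `mlp_probs` returns softmax-normalized logits; `mlp_classify` returns
#' 0-based argmax class indices with ties broken toward the lowest index.
#'
#' @param model An `mlp_model`.
#' @param X Feature matrix.
#' @return Probability matrix, or integer class vector.
#' @export
mlp_probs <- function(model, X) {
  softmax(mlp_logits(model, X))
}

#' @rdname mlp_probs
#' @export
mlp_classify <- function(model, X) {
  P <- mlp_logits(model, X)
  max.col(P, ties.method = "first") - 1L
}

#' Train an MLP by mini-batch gradient descent on cross-entropy
#'
#' Targets may be hard labels (0-based class indices) or soft labels (simplex
#' rows); in both cases the loss is the cross-entropy between the softmax of
#' the model logits and the target distribution. With `epochs = 0` the model
#' is returned unchanged. Training is deterministic given the seed.
#'
#' @param model An `mlp_model`.
#' @param X Feature matrix.
#' @param targets Integer class vector (0-based) or target probability
#'   matrix with one row per sample.
#' @param epochs Number of passes over the data (>= 0).
#' @param lr Positive learning rate. Default 0.05.
#' @param batch_size Mini-batch size. Default 32.
#' @param seed Integer seed controlling the per-epoch shuffling.
#' @return The updated `mlp_model`.
#' @export
mlp_train <- function(model, X, targets, epochs, lr = 0.05, batch_size = 32L,
                      seed = 1) {
  stopifnot(inherits(model, "mlp_model"))
  X <- as_matrix(X, "X")
  stopifnot_scalar(epochs, "epochs", lower = 0, integer = TRUE)
  stopifnot_scalar(lr, "lr", lower = 0, strict_lower = TRUE)
  if (epochs == 0L || nrow(X) == 0L) return(model)
  Y <- if (is.null(dim(targets))) {
    one_hot_matrix(as.integer(targets), model$C)
  } else {
    if (ncol(targets) != model$C) stop("target width != C", call. = FALSE)
    targets
  }
  n <- nrow(X)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        A1 <- sweep(Xb %*% model$W1, 2L, model$b1, "+")
        H <- pmax(A1, 0)
        P <- softmax(sweep(H %*% model$W2, 2L, model$b2, "+"))
        dL <- (P - Yb) / length(idx)
        gW2 <- crossprod(H, dL)
        gb2 <- colSums(dL)
        dH <- tcrossprod(dL, model$W2) * (A1 > 0)
        gW1 <- crossprod(Xb, dH)
        gb1 <- colSums(dH)
        if (any(!is.finite(gW2))) {
          stop("non-finite training loss gradient", call. = FALSE)
        }
        model$W1 <- model$W1 - lr * gW1
        model$b1 <- model$b1 - lr * gb1
        model$W2 <- model$W2 - lr * gW2
        model$b2 <- model$b2 - lr * gb2
      }
    }
  })
  model
}

# Total number of trainable parameters; used in communication accounting.
mlp_param_count <- function(model) {
  length(model$W1) + length(model$b1) + length(model$W2) + length(model$b2)
}
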