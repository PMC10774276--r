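# Two-stage selective knowledge sharing.
#
# Stage 1 (client side): a prediction on a proxy sample is shared only if the
# client's estimated density ratio at that sample clears its calibrated
# threshold; far-OOD samples have ratios near zero and are suppressed.
# Stage 2 (server side): ensemble predictions whose l1 ambiguity
# || p - onehot(argmax p) ||_1 = 2 (1 - max p) exceeds tau_server are
# suppressed as high-entropy knowledge. The l1 rule is exactly equivalent to
# the confidence rule max(p) >= 1 - tau_server / 2.

#' Client-side selection mask
#'
#' Keeps proxy IDs whose density ratio is at or above the calibrated
#' threshold; ties share (`>=`), so a zero quantile keeps everything at
#' least as typical as the validation minimum. Predictions for dropped IDs
#' are never transmitted.
#'
#' @param threshold A `client_threshold` from [calibrate_threshold()], or a
#'   single numeric threshold value.
#' @param ratios Numeric vector of estimated density ratios over proxy IDs.
#' @return Logical vector `kept`, one entry per proxy ID.
#' @export
client_select <- function(threshold, ratios) {
  thr <- if (inherits(threshold, "client_threshold")) {
    threshold$threshold_value
  } else {
    stopifnot_scalar(threshold, "threshold")
    threshold
  }
  ratios >= thr
}

#' Aggregate client predictions into ensemble soft labels
#'
#' Averages the predictions of sharing clients per proxy ID. In `"hard"`
#' mode each shared prediction is a class index, reconstructed as a one-hot
#' vector before averaging; in `"soft"` mode predictions are simplex rows.
#' IDs with zero sharers are dropped and reported.
#'
#' @param predictions List of K matrices (`n_ids` by `C`, soft mode) or K
#'   integer vectors of 0-based class indices (hard mode), one per client,
#'   aligned with `ids`.
#' @param masks List of K logical vectors: the client-stage selection masks.
#' @param ids Integer vector of proxy IDs the predictions refer to.
#' @param C Number of classes.
#' @param mode `"hard"` or `"soft"`.
#' @return A list with `ids` (IDs having >= 1 sharer), `ensemble` (matrix of
#'   averaged simplex rows aligned with `ids`), `sharers` (integer counts),
#'   and `dropped_no_sharer` (count of IDs dropped for lack of sharers).
#' @export
aggregate_predictions <- function(predictions, masks, ids, C,
                                  mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  K <- length(predictions)
  if (length(masks) != K) stop("one mask per client required", call. = FALSE)
  n <- length(ids)
  acc <- matrix(0, n, C)
  sharers <- integer(n)
  for (k in seq_len(K)) {
    kept <- masks[[k]]
    if (length(kept) != n) stop("mask length mismatch", call. = FALSE)
    P <- if (mode == "hard") {
      cls <- predictions[[k]]
      if (any(cls[kept] < 0 | cls[kept] >= C)) {
        stop("class index outside [0, C)", call. = FALSE)
      }
      one_hot_matrix(cls, C)
    } else {
      P <- predictions[[k]]
      if (ncol(P) != C) stop("inconsistent C across clients", call. = FALSE)
      P
    }
    acc[kept, ] <- acc[kept, , drop = FALSE] + P[kept, , drop = FALSE]
    sharers <- sharers + as.integer(kept)
  }
  keep <- sharers > 0L
  ensemble <- acc[keep, , drop = FALSE] / sharers[keep]
  list(ids = ids[keep], ensemble = ensemble, sharers = sharers[keep],
       dropped_no_sharer = sum(!keep))
}

#' l1 ambiguity of a simplex prediction
#'
#' The l1 distance between a probability vector and the one-hot vector of
#' its argmax, `|| p - onehot(argmax p) ||_1 = 2 (1 - max p)`. Zero for a
#' one-hot prediction; at most `2 (1 - 1/C)` for a uniform one. Argmax ties
#' are broken toward the lowest class index (the value is unaffected).
#'
#' @param p A probability vector, or a matrix of row vectors.
#' @return Scalar (or vector, for matrix input) ambiguity in `[0, 2)`.
#' @export
ambiguity <- function(p) {
  if (is.null(dim(p))) {
    check_simplex(p)
    return(2 * (1 - max(p)))
  }
  apply(p, 1L, function(r) {
    check_simplex(r)
    2 * (1 - max(r))
  })
}

check_simplex <- function(p, tol = 1e-9) {
  if (any(p < -tol) || abs(sum(p) - 1) > 1e-6) {
    stop("not a probability vector", call. = FALSE)
  }
  invisible(p)
}

#' Server-side selection mask
#'
#' Keeps ensemble predictions whose l1 ambiguity is at most `tau_server`
#' (equivalently, whose maximum probability is at least
#' `1 - tau_server / 2`). With `tau_server = 2` every prediction is kept,
#' since ambiguity is bounded by `2 (1 - 1/C) < 2`.
#'
#' @param ensemble Matrix of ensemble simplex rows (or a single vector).
#' @param tau_server Positive ambiguity ceiling, usually in `(0, 2]`.
#' @return Logical vector `kept`, one entry per ensemble row.
#' @export
server_select <- function(ensemble, tau_server) {
  stopifnot_scalar(tau_server, "tau_server", lower = 0, strict_lower = TRUE)
  ambiguity(ensemble) <= tau_server
}

#' Confidence score of a prediction
#'
#' The maximum probability of the (softmax-normalized) logits; the standard
#' baseline OOD score that reads high confidence as in-distribution.
#'
#' @param p A probability vector, or matrix of row vectors.
#' @return Scalar (or vector) in `(0, 1]`.
#' @export
confidence_score <- function(p) {
  if (is.null(dim(p))) {
    check_simplex(p)
    return(max(p))
  }
  apply(p, 1L, function(r) {
    check_simplex(r)
    max(r)
  })
}

#' Energy score of a logit vector
#'
#' The logit-energy OOD score `-T log sum_c exp(logit_c / T)`, computed with
#' a max-shift for numerical stability. Lower values indicate more
#' in-distribution; negate before computing AUROC so that all selector
#' scores share the "higher = in-distribution" orientation.
#'
#' @param logits Numeric vector of unnormalized class scores, or a matrix of
#'   row vectors.
#' @param temperature Positive temperature. Default 1.
#' @return Scalar (or vector) energy.
#' @export
energy_score <- function(logits, temperature = 1) {
  stopifnot_scalar(temperature, "temperature", lower = 0, strict_lower = TRUE)
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  if (any(!is.finite(logits))) stop("logits must be finite", call. = FALSE)
  out <- apply(logits, 1L, function(z) -temperature * logsumexp(z / temperature))
  if (length(out) == 1L) out[[1L]] else out
}
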