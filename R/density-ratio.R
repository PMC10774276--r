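# Client-side density-ratio estimation.
#
# Each client estimates w(x) = p_k(x) / u(x), the ratio of its local data
# density to a uniform reference density over a compact box, with kernelized
# unconstrained least-squares importance fitting (KuLSIF). Far out-of-
# distribution points have p_k(x) ~ 0 and hence w(x) ~ 0, so a threshold on
# the estimated ratio yields an OOD detector. The regularized least-squares
# objective
#
#   (1 / 2 n_u) sum_{x in S_u} w(x)^2 - (1 / n_k) sum_{x in S_k} w(x)
#     + (beta / 2) ||w||^2_H
#
# over a Gaussian-kernel RKHS H has a closed-form minimizer: by the
# representer property the solution lies in the span of kernel functions
# centered at S_k and S_u, with S_k coefficients all equal to 1/(beta n_k)
# and S_u coefficients alpha solving
#
#   (K_uu + beta n_u I) alpha = -(1 / (beta n_k)) K_uk 1.

#' Draw a uniform reference sample over the data bounding box
#'
#' The reference distribution is uniform over the axis-aligned bounding box
#' of the client's local features, optionally widened by `margin` times the
#' per-dimension range on each side. Dimensions with zero range are widened
#' by a machine-epsilon-scaled amount (with a warning) so the box never
#' degenerates.
#'
#' @param local_features Numeric matrix of the client's local data (rows =
#'   samples).
#' @param n_u Number of uniform points to draw (>= 1).
#' @param margin Nonnegative widening factor per dimension. Default 0.05.
#' @param seed Integer seed.
#' @return A list with `sample` (`n_u` by `d` matrix) and `box` (`d` by 2
#'   matrix of per-dimension lower/upper bounds).
#' @export
sample_uniform_reference <- function(local_features, n_u, margin = 0.05,
                                     seed = 1) {
  X <- as_matrix(local_features, "local_features")
  if (nrow(X) < 1L) stop("`local_features` must be non-empty", call. = FALSE)
  stopifnot_scalar(n_u, "n_u", lower = 1, integer = TRUE)
  stopifnot_scalar(margin, "margin", lower = 0)
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rng <- hi - lo
  if (any(rng == 0)) {
    warning("zero-variance dimension; widening box by an epsilon amount")
    eps <- pmax(abs(lo), 1) * sqrt(.Machine$double.eps)
    lo <- ifelse(rng == 0, lo - eps, lo)
    hi <- ifelse(rng == 0, hi + eps, hi)
    rng <- hi - lo
  }
  lo <- lo - margin * rng
  hi <- hi + margin * rng
  d <- ncol(X)
  sample <- with_seed(seed, {
    u <- matrix(stats::runif(n_u * d), n_u, d)
    sweep(sweep(u, 2L, hi - lo, "*"), 2L, lo, "+")
  })
  list(sample = sample, box = cbind(lo = lo, hi = hi))
}

#' Median-heuristic kernel bandwidth
#'
#' Returns the median of pairwise Euclidean distances between rows,
#' subsampling to at most `max_points` rows (deterministically, from a fixed
#' internal seed) to bound the quadratic cost.
#'
#' @param points Numeric matrix with >= 2 rows.
#' @param max_points Subsample cap. Default 1000.
#' @return A strictly positive scalar bandwidth.
#' @export
median_bandwidth <- function(points, max_points = 1000L) {
  X <- as_matrix(points, "points")
  if (nrow(X) < 2L) stop("need at least 2 points", call. = FALSE)
  if (nrow(X) > max_points) {
    keep <- with_seed(104729L, sample(nrow(X), max_points))
    X <- X[keep, , drop = FALSE]
  }
  med <- stats::median(stats::dist(X))
  if (!is.finite(med) || med <= 0) {
    stop("bandwidth undefined: all points identical", call. = FALSE)
  }
  med
}

#' Fit a KuLSIF density-ratio model
#'
#' Minimizes the regularized least-squares importance-fitting objective over
#' the Gaussian-kernel RKHS, using the closed-form solution (an
#' `n_u` by `n_u` ridge-regularized linear system). The returned model is a
#' callable density-ratio estimate `w(x)`; use [evaluate_ratio()] or
#' `predict()`.
#'
#' @param S_k Numeric matrix of samples from the client (numerator) density
#'   (`n_k` by `d`).
#' @param S_u Numeric matrix of samples from the uniform reference
#'   (denominator) density (`n_u` by `d`).
#' @param bandwidth Positive Gaussian-kernel bandwidth, or
#'   `"median-heuristic"` (default) for the median pairwise distance of
#'   `S_k`. The numerator sample sets the kernel scale: the target ratio
#'   inherits the local density's structure, and a kernel matched to it can
#'   represent the ratio's peaks.
#' @param beta Positive ridge regularization. Default `1e-3`.
#' @param box Optional `d` by 2 matrix recording the reference box (stored
#'   for serialization; not used in fitting).
#' @return An object of class `kulsif_model` with fields `support_points`
#'   (the `n_k + n_u` fitting points), `coefficients`, `bandwidth`, `beta`,
#'   `n_k`, `n_u`, and `box`.
#' @examples
#' set.seed(1)
#' S_k <- matrix(rnorm(200, sd = 0.5), ncol = 1)
#' ref <- sample_uniform_reference(S_k, n_u = 200, seed = 2)
#' fit <- fit_kulsif(S_k, ref$sample, box = ref$box)
#' evaluate_ratio(fit, matrix(c(0, 5), ncol = 1))
#' @export
fit_kulsif <- function(S_k, S_u, bandwidth = "median-heuristic", beta = 1e-3,
                       box = NULL) {
  S_k <- as_matrix(S_k, "S_k")
  S_u <- as_matrix(S_u, "S_u")
  if (nrow(S_k) < 1L || nrow(S_u) < 1L) {
    stop("S_k and S_u must be non-empty", call. = FALSE)
  }
  if (ncol(S_k) != ncol(S_u)) stop("dimension mismatch", call. = FALSE)
  stopifnot_scalar(beta, "beta", lower = 0, strict_lower = TRUE)
  if (identical(bandwidth, "median-heuristic")) {
    bandwidth <- median_bandwidth(S_k)
  }
  stopifnot_scalar(bandwidth, "bandwidth", lower = 0, strict_lower = TRUE)

  n_k <- nrow(S_k)
  n_u <- nrow(S_u)
  K_uu <- gauss_kernel(S_u, S_u, bandwidth)
  K_uk <- gauss_kernel(S_u, S_k, bandwidth)
  rhs <- -rowSums(K_uk) / (beta * n_k)
  A <- K_uu
  diag(A) <- diag(A) + beta * n_u
  ch <- chol(A)
  alpha <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  coefficients <- c(rep(1 / (beta * n_k), n_k), alpha)

  structure(
    list(support_points = rbind(S_k, S_u), coefficients = coefficients,
         bandwidth = bandwidth, beta = beta, n_k = n_k, n_u = n_u, box = box),
    class = "kulsif_model"
  )
}

#' @export
print.kulsif_model <- function(x, ...) {
  cat(sprintf(
    "<kulsif_model> n_k=%d, n_u=%d, d=%d, bandwidth=%.4g, beta=%.3g\n",
    x$n_k, x$n_u, ncol(x$support_points), x$bandwidth, x$beta))
  invisible(x)
}

#' Evaluate a fitted density-ratio model
#'
#' @param model A `kulsif_model`.
#' @param X Numeric matrix of evaluation points (rows), matching the model's
#'   feature dimension. A zero-row matrix yields an empty vector.
#' @return Numeric vector of estimated ratios `w(x)` per row of `X`. The
#'   least-squares estimator is unconstrained, so small negative values can
#'   occur in low-density regions.
#' @export
evaluate_ratio <- function(model, X) {
  stopifnot(inherits(model, "kulsif_model"))
  X <- as_matrix(X, "X")
  if (ncol(X) != ncol(model$support_points)) {
    stop("dimension mismatch between X and model", call. = FALSE)
  }
  if (nrow(X) == 0L) return(numeric(0))
  drop(gauss_kernel(X, model$support_points, model$bandwidth) %*%
         model$coefficients)
}

#' @rdname evaluate_ratio
#' @param object A `kulsif_model`.
#' @param newdata Evaluation points.
#' @param ... Unused.
#' @export
predict.kulsif_model <- function(object, newdata, ...) {
  evaluate_ratio(object, newdata)
}

# Objective value of the KuLSIF quadratic for a coefficient vector over the
# representer subspace spanned by the model's support points. Used by the
# oracle-equivalence tests; exported because it defines the fitting contract.

#' KuLSIF objective value for given representer coefficients
#'
#' Evaluates the regularized least-squares importance-fitting objective for a
#' function `w = sum_j coef_j k(z_j, .)` over support points
#' `z = rbind(S_k, S_u)`.
#'
#' @param coefficients Coefficient vector of length `n_k + n_u`.
#' @param S_k,S_u The fitting samples.
#' @param bandwidth,beta Kernel bandwidth and regularization.
#' @return Scalar objective value.
#' @export
kulsif_objective <- function(coefficients, S_k, S_u, bandwidth, beta) {
  S_k <- as_matrix(S_k, "S_k")
  S_u <- as_matrix(S_u, "S_u")
  Z <- rbind(S_k, S_u)
  Kz <- gauss_kernel(Z, Z, bandwidth)
  w_all <- drop(Kz %*% coefficients)
  w_u <- w_all[nrow(S_k) + seq_len(nrow(S_u))]
  w_k <- w_all[seq_len(nrow(S_k))]
  sum(w_u^2) / (2 * nrow(S_u)) - sum(w_k) / nrow(S_k) +
    (beta / 2) * drop(crossprod(coefficients, Kz %*% coefficients))
}

#' Calibrate the client-side selection threshold
#'
#' The threshold is the empirical `tau_client` quantile (inverse-CDF, type-1
#' convention) of the estimated density ratios over the client's validation
#' set. The lower quantile convention guarantees that at most a
#' `tau_client` fraction of validation ratios lie strictly below the
#' threshold, and that `tau_client = 0` shares everything at least as
#' typical as the least typical validation point.
#'
#' @param model A fitted `kulsif_model`.
#' @param validation_features Matrix of held-out local samples (>= 1 row).
#' @param tau_client Quantile level in `[0, 1]`. Default 0.25.
#' @return An object of class `client_threshold`: list with `tau_client` and
#'   `threshold_value`.
#' @export
calibrate_threshold <- function(model, validation_features, tau_client = 0.25) {
  stopifnot_scalar(tau_client, "tau_client", lower = 0, upper = 1)
  V <- as_matrix(validation_features, "validation_features")
  if (nrow(V) < 1L) stop("need at least one validation sample", call. = FALSE)
  ratios <- evaluate_ratio(model, V)
  thr <- unname(stats::quantile(ratios, probs = tau_client, type = 1))
  structure(list(tau_client = tau_client, threshold_value = thr),
            class = "client_threshold")
}

#' Serialize / restore a density-ratio model
#'
#' Writes support points, coefficients, bandwidth, regularization and the
#' reference box to a portable JSON file.
#'
#' @param model A `kulsif_model`.
#' @param path File path.
#' @return `write_ratio_model` returns `path` invisibly; `read_ratio_model`
#'   returns the restored `kulsif_model`.
#' @export
write_ratio_model <- function(model, path) {
  stopifnot(inherits(model, "kulsif_model"))
  obj <- list(
    support_points = model$support_points,
    coefficients = model$coefficients,
    bandwidth = model$bandwidth,
    beta = model$beta,
    n_k = model$n_k,
    n_u = model$n_u,
    box = model$box
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ratio_model
#' @export
read_ratio_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(support_points = as.matrix(obj$support_points),
         coefficients = as.numeric(obj$coefficients),
         bandwidth = obj$bandwidth, beta = obj$beta,
         n_k = as.integer(obj$n_k), n_u = as.integer(obj$n_u),
         box = if (is.null(obj$box)) NULL else as.matrix(obj$box)),
    class = "kulsif_model"
  )
}
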