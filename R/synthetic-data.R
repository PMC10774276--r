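# Synthetic multi-class data and federated splits.
#
# The generator produces isotropic Gaussian class blobs with guaranteed
# centroid separation and carves them into the splits a federated
# distillation experiment needs: per-client train/validation data under
# IID or non-IID assignment, an unlabeled class-balanced proxy pool, and a
# class-balanced held-out test set.

#' Generate a labeled dataset of separated Gaussian class blobs
#'
#' Class `c` is drawn from an isotropic Gaussian centered at a distinct
#' centroid; centroids are placed on the (signed) coordinate axes at distance
#' `separation * noise_sd` from the origin, which guarantees every pair of
#' centroids is at least `separation * noise_sd` apart without tuning.
#'
#' @param C Number of classes (>= 1; at most `2 * d` so that signed axis
#'   placement keeps centroids separated).
#' @param per_class Samples generated per class (>= 1).
#' @param d Feature dimension (>= 1).
#' @param separation Centroid spacing as a multiple of `noise_sd` (> 0).
#' @param noise_sd Per-dimension standard deviation of each blob (> 0).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return An object of class `labeled_dataset`: a list with `features`
#'   (numeric matrix, `C * per_class` rows by `d` columns), `labels`
#'   (integer vector with values in `0:(C-1)`), `C`, `centroids`
#'   (`C` by `d` matrix), `noise_sd`, and `seed`.
#' @examples
#' ds <- make_blobs(C = 3, per_class = 20, d = 2, separation = 6,
#'                  noise_sd = 1, seed = 1)
#' table(ds$labels)
#' @export
make_blobs <- function(C, per_class, d = 2, separation = 6, noise_sd = 1,
                       seed = 1) {
  stopifnot_scalar(C, "C", lower = 1, integer = TRUE)
  stopifnot_scalar(per_class, "per_class", lower = 1, integer = TRUE)
  stopifnot_scalar(d, "d", lower = 1, integer = TRUE)
  stopifnot_scalar(separation, "separation", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  if (C > 2 * d) {
    stop("signed-axis centroid placement requires C <= 2 * d", call. = FALSE)
  }
  centroids <- matrix(0, C, d)
  for (c in seq_len(C)) {
    axis <- ((c - 1L) %% d) + 1L
    sign <- if (c <= d) 1 else -1
    centroids[c, axis] <- sign * separation * noise_sd
  }
  n <- C * per_class
  labels <- rep(0:(C - 1L), each = per_class)
  features <- with_seed(seed, {
    noise <- matrix(stats::rnorm(n * d, sd = noise_sd), n, d)
    centroids[labels + 1L, , drop = FALSE] + noise
  })
  structure(
    list(features = features, labels = as.integer(labels), C = as.integer(C),
         centroids = centroids, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples, %d features, %d classes\n",
              nrow(x$features), ncol(x$features), x$C))
  invisible(x)
}

#' Write / read a labeled dataset as delimited text
#'
#' The CSV layout is `d` feature columns (`x1..xd`) followed by an integer
#' `label` column, with a header row, so externally computed feature tables
#' can be substituted for the synthetic generator.
#'
#' @param ds A `labeled_dataset`.
#' @param path File path.
#' @return `write_dataset_csv` returns `path` invisibly; `read_dataset_csv`
#'   returns a `labeled_dataset` (without generator metadata).
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"))
  df <- as.data.frame(ds$features)
  names(df) <- paste0("x", seq_len(ncol(ds$features)))
  df$label <- ds$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"label" %in% names(df)) stop("missing `label` column", call. = FALSE)
  labels <- as.integer(df$label)
  features <- as.matrix(df[setdiff(names(df), "label")])
  if (any(!is.finite(features))) stop("non-finite feature values", call. = FALSE)
  if (any(labels < 0)) stop("labels must be >= 0", call. = FALSE)
  structure(
    list(features = features, labels = labels, C = max(labels) + 1L,
         centroids = NULL, noise_sd = NA_real_, seed = NA_integer_),
    class = "labeled_dataset"
  )
}

#' Partition a dataset into federated client, proxy, and test splits
#'
#' The test set is drawn class-balanced first; a stratified fraction of the
#' remaining pool of each class becomes the unlabeled proxy set; the rest is
#' assigned to clients. Under strong non-IID (`classes_per_client = 1`)
#' client `k` owns class `k mod C`; under weak non-IID
#' (`classes_per_client = 2`) client `k` owns classes
#' `{k mod C, (k+1) mod C}`, so every class is covered; under
#' `classes_per_client = "all"` each client receives an IID share of all
#' classes. Each client reserves `val_fraction` of its data as a validation
#' set used for selector threshold calibration.
#'
#' @param ds A `labeled_dataset`.
#' @param K Number of clients (>= 1; `K >= C` is required under strong
#'   non-IID so every class is owned by some client).
#' @param classes_per_client `1`, `2`, or `"all"`.
#' @param val_fraction Fraction of each client's data held out for
#'   validation, in (0, 1). Default 0.2.
#' @param proxy_fraction Stratified fraction of each class's non-test pool
#'   moved to the unlabeled proxy set, in (0, 1). Default 0.15.
#' @param test_fraction Fraction of each class drawn (class-balanced) into
#'   the held-out test set, in (0, 1). Default 0.1.
#' @param seed Integer seed.
#' @return An object of class `fed_partition`: a list with `client_train`
#'   and `client_val` (lists of K integer index vectors), `proxy`, `test`
#'   (integer index vectors into `ds$features` rows), `classes_per_client`,
#'   `K`, and `seed`. All index families are pairwise disjoint.
#' @examples
#' ds <- make_blobs(C = 3, per_class = 40, d = 2, separation = 6, seed = 1)
#' part <- partition_clients(ds, K = 3, classes_per_client = 1, seed = 1)
#' lengths(part$client_train)
#' @export
partition_clients <- function(ds, K, classes_per_client = 1,
                              val_fraction = 0.2, proxy_fraction = 0.15,
                              test_fraction = 0.1, seed = 1) {
  stopifnot(inherits(ds, "labeled_dataset"))
  stopifnot_scalar(K, "K", lower = 1, integer = TRUE)
  stopifnot_scalar(val_fraction, "val_fraction", lower = 0, upper = 1,
                   strict_lower = TRUE)
  if (val_fraction >= 1) stop("`val_fraction` must be in (0,1)", call. = FALSE)
  stopifnot_scalar(proxy_fraction, "proxy_fraction", lower = 0, upper = 1,
                   strict_lower = TRUE)
  if (proxy_fraction >= 1) stop("`proxy_fraction` must be in (0,1)", call. = FALSE)
  stopifnot_scalar(test_fraction, "test_fraction", lower = 0, upper = 1,
                   strict_lower = TRUE)
  if (test_fraction >= 1) stop("`test_fraction` must be in (0,1)", call. = FALSE)
  C <- ds$C
  if (!identical(classes_per_client, "all")) {
    stopifnot_scalar(classes_per_client, "classes_per_client", lower = 1,
                     integer = TRUE)
    if (!classes_per_client %in% c(1, 2)) {
      stop('`classes_per_client` must be 1, 2 or "all"', call. = FALSE)
    }
    if (classes_per_client == 1 && K < C) {
      stop("strong non-IID requires K >= C so every class is owned",
           call. = FALSE)
    }
  }

  with_seed(seed, {
    by_class <- split(seq_along(ds$labels), ds$labels)
    if (length(by_class) != C) stop("empty class in dataset", call. = FALSE)
    test <- integer(0)
    proxy <- integer(0)
    pool_by_class <- vector("list", C)
    for (c in seq_len(C)) {
      idx <- sample(by_class[[c]])
      n_test <- round(test_fraction * length(idx))
      n_proxy <- round(proxy_fraction * (length(idx) - n_test))
      test <- c(test, idx[seq_len(n_test)])
      proxy <- c(proxy, idx[n_test + seq_len(n_proxy)])
      rest <- idx[-seq_len(n_test + n_proxy)]
      if (length(rest) == 0L) stop("empty class after splitting", call. = FALSE)
      pool_by_class[[c]] <- rest
    }

    client_all <- vector("list", K)
    if (identical(classes_per_client, "all")) {
      # IID: deal every class's pool across clients round-robin.
      for (c in seq_len(C)) {
        shares <- split(pool_by_class[[c]],
                        rep_len(seq_len(K), length(pool_by_class[[c]])))
        for (k in seq_len(K)) {
          client_all[[k]] <- c(client_all[[k]], shares[[as.character(k)]])
        }
      }
    } else {
      owners <- vector("list", C)  # clients owning each class
      for (k in seq_len(K)) {
        cls <- ((k - 1L) + seq_len(classes_per_client) - 1L) %% C + 1L
        for (c in cls) owners[[c]] <- c(owners[[c]], k)
      }
      for (c in seq_len(C)) {
        own <- owners[[c]]
        if (length(own) == 0L) next
        shares <- split(pool_by_class[[c]],
                        rep_len(seq_along(own), length(pool_by_class[[c]])))
        for (i in seq_along(own)) {
          sh <- shares[[as.character(i)]]
          if (is.null(sh) || length(sh) == 0L) {
            stop("empty class share after splitting", call. = FALSE)
          }
          client_all[[own[i]]] <- c(client_all[[own[i]]], sh)
        }
      }
    }

    client_train <- vector("list", K)
    client_val <- vector("list", K)
    for (k in seq_len(K)) {
      idx <- sample(client_all[[k]])
      if (length(idx) < 2L) stop("client with fewer than 2 samples", call. = FALSE)
      n_val <- max(1L, round(val_fraction * length(idx)))
      client_val[[k]] <- sort(idx[seq_len(n_val)])
      client_train[[k]] <- sort(idx[-seq_len(n_val)])
    }

    structure(
      list(client_train = client_train, client_val = client_val,
           proxy = sort(proxy), test = sort(test),
           classes_per_client = classes_per_client, K = as.integer(K),
           seed = as.integer(seed)),
      class = "fed_partition"
    )
  })
}

#' @export
print.fed_partition <- function(x, ...) {
  cat(sprintf(
    "<fed_partition> K=%d clients (%s classes each), proxy=%d, test=%d\n",
    x$K, as.character(x$classes_per_client), length(x$proxy), length(x$test)))
  invisible(x)
}

#' Unlabeled view of the proxy set
#'
#' Returns proxy features and stable opaque sample IDs only; no label channel
#' is exposed, so nothing downstream of this view can train on proxy labels.
#' IDs are `0:(m-1)` in a fixed order and identical across rounds.
#'
#' @param ds A `labeled_dataset`.
#' @param part A `fed_partition` of `ds`.
#' @return A list with `features` (matrix) and `ids` (integer vector).
#' @seealso [proxy_label_oracle()] for the evaluation-only label back-door.
#' @export
proxy_view <- function(ds, part) {
  stopifnot(inherits(ds, "labeled_dataset"), inherits(part, "fed_partition"))
  if (any(part$proxy < 1) || any(part$proxy > nrow(ds$features))) {
    stop("partition indices out of range", call. = FALSE)
  }
  list(features = ds$features[part$proxy, , drop = FALSE],
       ids = seq_along(part$proxy) - 1L)
}

#' Evaluation-only label oracle for proxy samples
#'
#' Returns the hidden ground-truth labels of proxy IDs. This back-door exists
#' solely for evaluation (AUROC of incorrect-prediction detection, invariant
#' checks); the training pipeline never calls it.
#'
#' @param ds A `labeled_dataset`.
#' @param part A `fed_partition` of `ds`.
#' @param ids Integer proxy IDs as returned by [proxy_view()]. Default: all.
#' @return Integer labels in `0:(C-1)` aligned with `ids`.
#' @export
proxy_label_oracle <- function(ds, part, ids = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"), inherits(part, "fed_partition"))
  if (is.null(ids)) ids <- seq_along(part$proxy) - 1L
  if (any(ids < 0) || any(ids >= length(part$proxy))) {
    stop("proxy ids out of range", call. = FALSE)
  }
  ds$labels[part$proxy[ids + 1L]]
}
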