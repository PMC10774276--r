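# Federated distillation engine.
#
# One round of selective federated distillation:
#   1. every client trains its local model on its private data;
#   2. the server draws a batch of proxy IDs; every client predicts on them
#      and uploads only predictions passing its client-side selector;
#   3. the server averages shared predictions per ID, drops IDs without
#      sharers, applies the server-side ambiguity selector, and returns the
#      surviving ensemble targets;
#   4. every client fine-tunes on the surviving proxy samples by knowledge
#      distillation.
# The same loop with both selectors forced open is the selection-free
# baseline; local training alone is independent learning; parameter
# averaging of a shared architecture is the FedAvg baseline.

#' Configuration for a federated distillation run
#'
#' @param K Number of clients.
#' @param C Number of classes.
#' @param T Number of communication rounds (>= 0).
#' @param label_mode `"hard"` (clients share predicted class indices; the
#'   distillation target is the one-hot of the ensemble argmax) or `"soft"`
#'   (clients share softmax-normalized logits; the target is the averaged
#'   simplex vector).
#' @param tau_client Client-side quantile threshold in `[0, 1]`. Default
#'   0.25.
#' @param tau_server Server-side ambiguity ceiling in `(0, 2]`. Default 2.
#' @param local_epochs Local-training epochs per round. Default 2.
#' @param distill_epochs Distillation epochs per round. Default 2.
#' @param proxy_batch Number of proxy IDs drawn per round. Default 300
#'   (capped at the proxy size when the run starts).
#' @param learning_rate Gradient-descent step size. Default 0.05.
#' @param hidden Hidden-layer width of the client MLPs. Default 32.
#' @param batch_size Mini-batch size for training. Default 32.
#' @param kulsif_beta Ridge regularization of the density-ratio fit.
#'   Default `1e-3`.
#' @param margin Widening of the uniform reference box. Default 0.05.
#' @param feature_map Optional function applied to feature matrices before
#'   density-ratio estimation (a fixed representation hook for
#'   high-dimensional inputs). Default `NULL` (raw features).
#' @param seed Master seed; every random stage derives its own stream from
#'   it.
#' @return An object of class `fed_config`.
#' @export
federation_config <- function(K, C, T = 10L, label_mode = c("hard", "soft"),
                              tau_client = 0.25, tau_server = 2,
                              local_epochs = 2L, distill_epochs = 2L,
                              proxy_batch = 300L, learning_rate = 0.05,
                              hidden = 32L, batch_size = 32L,
                              kulsif_beta = 1e-3, margin = 0.05,
                              feature_map = NULL, seed = 1) {
  label_mode <- match.arg(label_mode)
  stopifnot_scalar(K, "K", lower = 1, integer = TRUE)
  stopifnot_scalar(C, "C", lower = 1, integer = TRUE)
  stopifnot_scalar(T, "T", lower = 0, integer = TRUE)
  stopifnot_scalar(tau_client, "tau_client", lower = 0, upper = 1)
  stopifnot_scalar(tau_server, "tau_server", lower = 0, upper = 2,
                   strict_lower = TRUE)
  stopifnot_scalar(local_epochs, "local_epochs", lower = 0, integer = TRUE)
  stopifnot_scalar(distill_epochs, "distill_epochs", lower = 0, integer = TRUE)
  stopifnot_scalar(proxy_batch, "proxy_batch", lower = 1, integer = TRUE)
  stopifnot_scalar(learning_rate, "learning_rate", lower = 0,
                   strict_lower = TRUE)
  stopifnot_scalar(kulsif_beta, "kulsif_beta", lower = 0, strict_lower = TRUE)
  if (!is.null(feature_map) && !is.function(feature_map)) {
    stop("`feature_map` must be NULL or a function", call. = FALSE)
  }
  structure(
    list(K = as.integer(K), C = as.integer(C), T = as.integer(T),
         label_mode = label_mode, tau_client = tau_client,
         tau_server = tau_server, local_epochs = as.integer(local_epochs),
         distill_epochs = as.integer(distill_epochs),
         proxy_batch = as.integer(proxy_batch),
         learning_rate = learning_rate, hidden = as.integer(hidden),
         batch_size = as.integer(batch_size), kulsif_beta = kulsif_beta,
         margin = margin, feature_map = feature_map, seed = as.integer(seed)),
    class = "fed_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' All scalar `fed_config` fields round-trip; the `feature_map` hook is not
#' serializable and is dropped with a warning on write.
#'
#' @param config A `fed_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `fed_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fed_config"))
  obj <- unclass(config)
  if (!is.null(obj$feature_map)) {
    warning("`feature_map` is not serializable; dropped from the config file")
  }
  obj$feature_map <- NULL
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(federation_config, obj)
}

per_id_bytes <- function(label_mode, C) {
  # 4-byte sample ID + payload: 4-byte class index (hard) or C 4-byte floats.
  if (label_mode == "hard") 8 else 4 + 4 * C
}

# --- client construction ------------------------------------------------

map_features <- function(config, X) {
  if (is.null(config$feature_map)) X else as_matrix(config$feature_map(X))
}

build_client_states <- function(ds, part, config, fit_selectors = TRUE) {
  K <- config$K
  clients <- vector("list", K)
  for (k in seq_len(K)) {
    train_idx <- part$client_train[[k]]
    val_idx <- part$client_val[[k]]
    model <- mlp_init(ncol(ds$features), config$C, hidden = config$hidden,
                      seed = derive_seed(config$seed, 900, k))
    selector <- NULL
    if (fit_selectors) {
      S_k <- map_features(config, ds$features[train_idx, , drop = FALSE])
      ref <- sample_uniform_reference(S_k, n_u = nrow(S_k),
                                      margin = config$margin,
                                      seed = derive_seed(config$seed, 700, k))
      model_w <- fit_kulsif(S_k, ref$sample, beta = config$kulsif_beta,
                            box = ref$box)
      thr <- calibrate_threshold(
        model_w, map_features(config, ds$features[val_idx, , drop = FALSE]),
        tau_client = config$tau_client)
      selector <- list(ratio_model = model_w, threshold = thr)
    }
    clients[[k]] <- list(k = k, model = model, selector = selector,
                         train_idx = train_idx, val_idx = val_idx)
  }
  clients
}

# --- single-client operations -------------------------------------------

#' Train a client's local model on its private data
#'
#' One or more epochs of mini-batch gradient descent on cross-entropy over
#' the client's private training set. `epochs = 0` leaves the parameters
#' unchanged.
#'
#' @param client A client state as built inside the run functions: a list
#'   with at least `model` (an `mlp_model`) and `train_idx`.
#' @param ds The parent `labeled_dataset`.
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed.
#' @return The client state with an updated model.
#' @export
local_train <- function(client, ds, epochs, lr = 0.05, batch_size = 32L,
                        seed = 1) {
  X <- ds$features[client$train_idx, , drop = FALSE]
  y <- ds$labels[client$train_idx]
  if (length(y) < 1L) stop("client has no training samples", call. = FALSE)
  client$model <- mlp_train(client$model, X, y, epochs = epochs, lr = lr,
                            batch_size = batch_size, seed = seed)
  client
}

#' Fine-tune a client on selected proxy samples by knowledge distillation
#'
#' Minimizes the cross-entropy between the client's softmax outputs and the
#' ensemble targets on the surviving proxy samples. An empty target set is a
#' no-op.
#'
#' @param client A client state (list with `model`).
#' @param kept_features Feature matrix of surviving proxy samples.
#' @param targets One-hot / soft target matrix (rows aligned with
#'   `kept_features`) or a 0-based class vector.
#' @param epochs Distillation epochs.
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed.
#' @return The client state with an updated model.
#' @export
distill <- function(client, kept_features, targets, epochs, lr = 0.05,
                    batch_size = 32L, seed = 1) {
  if (is.null(kept_features) || nrow(kept_features) == 0L) return(client)
  client$model <- mlp_train(client$model, kept_features, targets,
                            epochs = epochs, lr = lr,
                            batch_size = batch_size, seed = seed)
  client
}

# --- round-level knowledge generation -----------------------------------

#' Generate ensemble distillation targets for one round
#'
#' Draws a batch of proxy IDs, collects every client's predictions,
#' applies the client-side masks, averages shared predictions, applies the
#' server-side ambiguity selector, and returns surviving IDs with their
#' targets plus the round's communication byte counts.
#'
#' @param clients List of client states.
#' @param proxy A proxy view from [proxy_view()].
#' @param batch_ids Integer vector of drawn proxy IDs.
#' @param config A `fed_config`.
#' @param client_masks List of K logical vectors over `batch_ids` (the
#'   client-stage selection), or `NULL` to keep everything.
#' @param select_server Apply the server-side ambiguity filter? Default
#'   `TRUE`.
#' @return A list with `ids` (surviving proxy IDs), `targets` (matrix or
#'   0-based class vector per `label_mode`), `ensemble`, `sharers`,
#'   `kept_counts` (per-client uploads), `dropped_no_sharer`,
#'   `dropped_ambiguous`, `bytes_up`, `bytes_down`.
#' @export
generate_ensemble_predictions <- function(clients, proxy, batch_ids, config,
                                          client_masks = NULL,
                                          select_server = TRUE) {
  K <- length(clients)
  Xb <- proxy$features[match(batch_ids, proxy$ids), , drop = FALSE]
  predictions <- vector("list", K)
  for (k in seq_len(K)) {
    predictions[[k]] <- if (config$label_mode == "hard") {
      mlp_classify(clients[[k]]$model, Xb)
    } else {
      mlp_probs(clients[[k]]$model, Xb)
    }
  }
  if (is.null(client_masks)) {
    client_masks <- rep(list(rep(TRUE, length(batch_ids))), K)
  }
  agg <- aggregate_predictions(predictions, client_masks, batch_ids,
                               C = config$C, mode = config$label_mode)
  kept_server <- if (select_server && nrow(agg$ensemble) > 0L) {
    server_select(agg$ensemble, config$tau_server)
  } else {
    rep(TRUE, length(agg$ids))
  }
  ids <- agg$ids[kept_server]
  ensemble <- agg$ensemble[kept_server, , drop = FALSE]
  targets <- if (config$label_mode == "hard") {
    max.col(ensemble, ties.method = "first") - 1L
  } else {
    ensemble
  }
  wire <- per_id_bytes(config$label_mode, config$C)
  kept_counts <- vapply(client_masks, sum, integer(1))
  list(ids = ids, targets = targets, ensemble = ensemble,
       sharers = agg$sharers[kept_server], kept_counts = kept_counts,
       dropped_no_sharer = agg$dropped_no_sharer,
       dropped_ambiguous = sum(!kept_server),
       bytes_up = sum(kept_counts) * wire,
       bytes_down = K * length(ids) * wire)
}

# --- proxy batch scheduler ----------------------------------------------

# Draw without replacement; reshuffle the pool when exhausted.
new_proxy_pool <- function(ids, seed) {
  env <- new.env(parent = emptyenv())
  env$ids <- ids
  env$queue <- with_seed(seed, sample(ids))
  env$reshuffles <- 0L
  env
}

draw_proxy_batch <- function(pool, n, seed) {
  n <- min(n, length(pool$ids))
  if (length(pool$queue) < n) {
    taken <- pool$queue
    pool$reshuffles <- pool$reshuffles + 1L
    refill <- with_seed(derive_seed(seed, 300, pool$reshuffles),
                        sample(setdiff(pool$ids, taken)))
    pool$queue <- c(taken, refill)
  }
  batch <- pool$queue[seq_len(n)]
  pool$queue <- pool$queue[-seq_len(n)]
  batch
}

# --- run loop ------------------------------------------------------------

client_scores <- function(clients, config, X_by_client, selector_type,
                          proxy_X_raw) {
  # Scores with "higher = more in-distribution" orientation, per client.
  lapply(seq_along(clients), function(k) {
    cl <- clients[[k]]
    switch(selector_type,
      "density-ratio" = evaluate_ratio(cl$selector$ratio_model,
                                       X_by_client[[k]]),
      "confidence" = confidence_score(mlp_probs(cl$model, proxy_X_raw)),
      "energy" = -energy_score(mlp_logits(cl$model, proxy_X_raw))
    )
  })
}

fd_loop <- function(ds, part, config, method, selector_type = "density-ratio",
                    select_client = TRUE, select_server = TRUE) {
  proxy <- proxy_view(ds, part)
  test_X <- ds$features[part$test, , drop = FALSE]
  test_y <- ds$labels[part$test]
  fit_sel <- select_client && selector_type == "density-ratio"
  clients <- build_client_states(ds, part, config, fit_selectors = fit_sel)
  K <- config$K
  proxy_mapped <- map_features(config, proxy$features)

  # Density ratios over the proxy view are fixed once the selectors are
  # built; score-based selectors are recomputed each round from the current
  # models.
  static_ratios <- NULL
  if (fit_sel) {
    static_ratios <- lapply(clients, function(cl) {
      evaluate_ratio(cl$selector$ratio_model, proxy_mapped)
    })
  }

  pool <- new_proxy_pool(proxy$ids, derive_seed(config$seed, 200))
  logs <- vector("list", config$T)
  kept_ids <- vector("list", config$T)
  ensembles <- vector("list", config$T)
  kept_counts <- matrix(0L, config$T, K)
  acc <- matrix(NA_real_, config$T, K)

  for (t in seq_len(config$T)) {
    for (k in seq_len(K)) {
      clients[[k]] <- local_train(
        clients[[k]], ds, epochs = config$local_epochs,
        lr = config$learning_rate, batch_size = config$batch_size,
        seed = derive_seed(config$seed, 10, t, k))
    }

    batch_ids <- draw_proxy_batch(pool, config$proxy_batch,
                                  derive_seed(config$seed, 200, t))
    pos <- match(batch_ids, proxy$ids)

    masks <- NULL
    if (select_client) {
      if (selector_type == "density-ratio") {
        masks <- lapply(seq_len(K), function(k) {
          client_select(clients[[k]]$selector$threshold,
                        static_ratios[[k]][pos])
        })
      } else {
        Xb_raw <- proxy$features[pos, , drop = FALSE]
        scores <- client_scores(clients, config, NULL, selector_type, Xb_raw)
        masks <- lapply(seq_len(K), function(k) {
          val_X <- ds$features[clients[[k]]$val_idx, , drop = FALSE]
          val_scores <- switch(selector_type,
            "confidence" = confidence_score(mlp_probs(clients[[k]]$model,
                                                      val_X)),
            "energy" = -energy_score(mlp_logits(clients[[k]]$model, val_X)))
          thr <- unname(stats::quantile(val_scores, config$tau_client,
                                        type = 1))
          scores[[k]] >= thr
        })
      }
    }

    ens <- generate_ensemble_predictions(clients, proxy, batch_ids, config,
                                         client_masks = masks,
                                         select_server = select_server)
    if (length(ens$ids) > 0L) {
      Xd <- proxy$features[match(ens$ids, proxy$ids), , drop = FALSE]
      for (k in seq_len(K)) {
        clients[[k]] <- distill(
          clients[[k]], Xd, ens$targets, epochs = config$distill_epochs,
          lr = config$learning_rate, batch_size = config$batch_size,
          seed = derive_seed(config$seed, 20, t, k))
      }
    }

    for (k in seq_len(K)) {
      acc[t, k] <- accuracy(mlp_classify(clients[[k]]$model, test_X), test_y)
    }
    kept_ids[[t]] <- ens$ids
    ensembles[[t]] <- ens$ensemble
    kept_counts[t, ] <- ens$kept_counts
    logs[[t]] <- data.frame(
      round = t,
      p_proxy_round = 100 * length(ens$ids) / length(batch_ids),
      mean_accuracy = mean(acc[t, ]),
      dropped_no_sharer = ens$dropped_no_sharer,
      dropped_ambiguous = ens$dropped_ambiguous,
      survivors = length(ens$ids),
      bytes_up = ens$bytes_up,
      bytes_down = ens$bytes_down
    )
  }

  run <- new_fd_run(method, config, logs, acc, kept_ids, kept_counts,
                    clients, length(proxy$ids))
  run$ensembles <- ensembles
  run
}

new_fd_run <- function(method, config, logs, acc, kept_ids, kept_counts,
                       clients, proxy_size) {
  logs <- if (length(logs)) do.call(rbind, logs) else data.frame(
    round = integer(0), p_proxy_round = numeric(0),
    mean_accuracy = numeric(0), dropped_no_sharer = integer(0),
    dropped_ambiguous = integer(0), survivors = integer(0),
    bytes_up = numeric(0), bytes_down = numeric(0))
  structure(
    list(method = method, config = config, logs = logs,
         accuracy = acc, kept_ids = kept_ids, kept_counts = kept_counts,
         models = lapply(clients, `[[`, "model"),
         clients = clients, proxy_size = proxy_size),
    class = "fd_run"
  )
}

#' @export
print.fd_run <- function(x, ...) {
  fin <- final_accuracy(x)
  cat(sprintf("<fd_run> method=%s, K=%d, T=%d rounds\n", x$method,
              x$config$K, x$config$T))
  if (length(fin)) {
    cat(sprintf("  final mean test accuracy: %.2f%% (sd %.2f)\n",
                mean(fin), stats::sd(fin)))
    cat(sprintf("  cumulative p_proxy: %.1f%%; bytes up/down: %.0f / %.0f\n",
                p_proxy_cumulative(x), sum(x$logs$bytes_up),
                sum(x$logs$bytes_down)))
  }
  invisible(x)
}

#' Final per-client test accuracy of a run
#'
#' @param run An `fd_run`.
#' @return Numeric vector of per-client accuracies (%) after the last round;
#'   zero-length for `T = 0`.
#' @export
final_accuracy <- function(run) {
  stopifnot(inherits(run, "fd_run"))
  if (nrow(run$logs) == 0L) return(numeric(0))
  run$accuracy[nrow(run$accuracy), ]
}

#' Run selective federated distillation
#'
#' Builds client-side density-ratio selectors once, then runs `T` rounds of
#' local training, two-stage selective knowledge sharing, and distillation.
#'
#' @param ds A `labeled_dataset`.
#' @param part A `fed_partition`.
#' @param config A `fed_config`.
#' @return An `fd_run`: per-round logs (`p_proxy_round`, mean accuracy,
#'   bytes up/down), the per-round surviving proxy IDs, per-round per-client
#'   accuracy matrix, and final models.
#' @examples
#' \donttest{
#' ds <- make_blobs(C = 4, per_class = 60, d = 2, separation = 8, seed = 1)
#' part <- partition_clients(ds, K = 4, classes_per_client = 1, seed = 1)
#' cfg <- federation_config(K = 4, C = 4, T = 3, proxy_batch = 24, seed = 1)
#' run <- run_selective_fd(ds, part, cfg)
#' run
#' }
#' @export
run_selective_fd <- function(ds, part, config) {
  fd_loop(ds, part, config, method = "selective-fd")
}

#' Run federated distillation with both selectors disabled
#'
#' The identical loop with every client sharing every prediction and the
#' server keeping every ensemble; the selection-free baseline.
#'
#' @inheritParams run_selective_fd
#' @return An `fd_run`.
#' @export
run_fd_noselect <- function(ds, part, config) {
  fd_loop(ds, part, config, method = "fd-noselect",
          select_client = FALSE, select_server = FALSE)
}

#' Run independent learning (no communication)
#'
#' Each client trains on its local data only; zero bytes are exchanged.
#'
#' @inheritParams run_selective_fd
#' @return An `fd_run` with zero byte counts and 0% proxy usage.
#' @export
run_indep <- function(ds, part, config) {
  test_X <- ds$features[part$test, , drop = FALSE]
  test_y <- ds$labels[part$test]
  clients <- build_client_states(ds, part, config, fit_selectors = FALSE)
  K <- config$K
  acc <- matrix(NA_real_, config$T, K)
  logs <- vector("list", config$T)
  for (t in seq_len(config$T)) {
    for (k in seq_len(K)) {
      clients[[k]] <- local_train(
        clients[[k]], ds, epochs = config$local_epochs,
        lr = config$learning_rate, batch_size = config$batch_size,
        seed = derive_seed(config$seed, 10, t, k))
      acc[t, k] <- accuracy(mlp_classify(clients[[k]]$model, test_X), test_y)
    }
    logs[[t]] <- data.frame(
      round = t, p_proxy_round = 0, mean_accuracy = mean(acc[t, ]),
      dropped_no_sharer = 0L, dropped_ambiguous = 0L, survivors = 0L,
      bytes_up = 0, bytes_down = 0)
  }
  new_fd_run("indep", config, logs, acc,
             rep(list(integer(0)), config$T),
             matrix(0L, config$T, K), clients, length(part$proxy))
}

#' Run federated averaging (FedAvg)
#'
#' Per round, every client trains a copy of the global model locally; the
#' server replaces the global model with the average of the client models
#' weighted by local training-set size. All clients share one architecture.
#' Bytes exchanged per round are `parameter_count * 4` up and down per
#' client.
#'
#' @inheritParams run_selective_fd
#' @return An `fd_run`.
#' @export
run_fedavg <- function(ds, part, config) {
  test_X <- ds$features[part$test, , drop = FALSE]
  test_y <- ds$labels[part$test]
  clients <- build_client_states(ds, part, config, fit_selectors = FALSE)
  K <- config$K
  global <- clients[[1L]]$model
  n_param <- mlp_param_count(global)
  weights <- vapply(clients, function(cl) length(cl$train_idx), numeric(1))
  weights <- weights / sum(weights)
  acc <- matrix(NA_real_, config$T, K)
  logs <- vector("list", config$T)
  for (t in seq_len(config$T)) {
    for (k in seq_len(K)) {
      clients[[k]]$model <- global
      clients[[k]] <- local_train(
        clients[[k]], ds, epochs = config$local_epochs,
        lr = config$learning_rate, batch_size = config$batch_size,
        seed = derive_seed(config$seed, 10, t, k))
    }
    for (f in c("W1", "b1", "W2", "b2")) {
      global[[f]] <- Reduce(`+`, lapply(seq_len(K), function(k) {
        weights[k] * clients[[k]]$model[[f]]
      }))
    }
    for (k in seq_len(K)) {
      clients[[k]]$model <- global
      acc[t, k] <- accuracy(mlp_classify(global, test_X), test_y)
    }
    logs[[t]] <- data.frame(
      round = t, p_proxy_round = 0, mean_accuracy = mean(acc[t, ]),
      dropped_no_sharer = 0L, dropped_ambiguous = 0L, survivors = 0L,
      bytes_up = K * n_param * 4, bytes_down = K * n_param * 4)
  }
  run <- new_fd_run("fedavg", config, logs, acc,
                    rep(list(integer(0)), config$T),
                    matrix(0L, config$T, K), clients, length(part$proxy))
  run$parameter_count <- n_param
  run
}

#' Write a run's log and summary to a directory
#'
#' Emits `log.csv` (one row per round) and `summary.json` (final per-client
#' accuracies, cumulative proxy usage and bytes, and the configuration).
#'
#' @param run An `fd_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_summary <- function(run, dir) {
  stopifnot(inherits(run, "fd_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(run$logs, file.path(dir, "log.csv"), row.names = FALSE)
  cfg <- unclass(run$config)
  cfg$feature_map <- NULL
  jsonlite::write_json(
    list(method = run$method,
         final_accuracy = final_accuracy(run),
         mean_final_accuracy = mean(final_accuracy(run)),
         p_proxy_cumulative = p_proxy_cumulative(run),
         bytes_up_total = sum(run$logs$bytes_up),
         bytes_down_total = sum(run$logs$bytes_down),
         config = cfg, seed = run$config$seed),
    file.path(dir, "summary.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
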