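# Metrics, ablation and sweep harnesses, communication accounting.

#' Classification accuracy in percent
#'
#' @param predicted Integer class predictions.
#' @param truth Integer ground-truth classes of equal length.
#' @return `100 * matches / total`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("length mismatch", call. = FALSE)
  }
  if (length(predicted) == 0L) stop("empty inputs", call. = FALSE)
  100 * mean(predicted == truth)
}

#' AUROC for incorrect-prediction detection
#'
#' The probability that a randomly chosen incorrectly predicted sample
#' scores lower (more out-of-distribution) than a correctly predicted one,
#' with half credit for ties — the rank (Mann-Whitney) estimator of the area
#' under the ROC curve. Scores must be oriented so that higher means "more
#' in-distribution / more likely correct".
#'
#' @param scores Numeric selector scores.
#' @param is_correct Logical vector: was the prediction correct?
#' @return AUROC in `[0, 1]`; 0.5 is the random-guess level.
#' @export
auroc_incorrect_detection <- function(scores, is_correct) {
  if (length(scores) != length(is_correct)) {
    stop("length mismatch", call. = FALSE)
  }
  is_correct <- as.logical(is_correct)
  n1 <- sum(is_correct)
  n0 <- sum(!is_correct)
  if (n1 == 0L || n0 == 0L) {
    stop("both correct and incorrect samples are required", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[is_correct]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cumulative percentage of proxy samples used for distillation
#'
#' The percentage of the proxy pool that survived both selectors in at least
#' one round over the whole training process.
#'
#' @param run An `fd_run`, or a list of per-round surviving proxy ID
#'   vectors.
#' @param proxy_size Proxy pool size; taken from the run when omitted.
#' @return Percentage in `[0, 100]`.
#' @export
p_proxy_cumulative <- function(run, proxy_size = NULL) {
  kept <- if (inherits(run, "fd_run")) run$kept_ids else run
  if (is.null(proxy_size)) {
    if (!inherits(run, "fd_run")) {
      stop("`proxy_size` required when `run` is a plain list", call. = FALSE)
    }
    proxy_size <- run$proxy_size
  }
  if (length(kept) == 0L) return(0)
  100 * length(unique(unlist(kept))) / proxy_size
}

#' Closed-form communication byte accounting
#'
#' Reproduces the wire conventions of the run loop: hard labels cost a
#' 4-byte sample ID plus a 4-byte class index, soft labels a 4-byte ID plus
#' `C` 4-byte floats, and FedAvg exchanges `parameter_count` 4-byte floats
#' per client in each direction every round.
#'
#' @param mode `"fd-hard"`, `"fd-soft"`, or `"fedavg"`.
#' @param C Number of classes (FD modes).
#' @param uploads For FD modes: per-round per-client shared-prediction
#'   counts — a `T` by `K` matrix, or a length-`T` vector applied to every
#'   client.
#' @param survivors For FD modes: length-`T` vector of server-surviving IDs
#'   per round (the download counts).
#' @param parameter_count For `"fedavg"`: model parameter count.
#' @param K Number of clients.
#' @param T Number of rounds; inferred from `uploads`/`survivors` for FD
#'   modes.
#' @return A list with `per_round` (data.frame: round, bytes_up,
#'   bytes_down) and `total` (bytes_up + bytes_down summed over rounds).
#' @export
comm_bytes <- function(mode = c("fd-hard", "fd-soft", "fedavg"), C = NULL,
                       uploads = NULL, survivors = NULL,
                       parameter_count = NULL, K = NULL, T = NULL) {
  mode <- match.arg(mode)
  if (mode == "fedavg") {
    stopifnot_scalar(parameter_count, "parameter_count", lower = 1,
                     integer = TRUE)
    stopifnot_scalar(K, "K", lower = 1, integer = TRUE)
    stopifnot_scalar(T, "T", lower = 0, integer = TRUE)
    per <- data.frame(round = seq_len(T),
                      bytes_up = rep(K * parameter_count * 4, T),
                      bytes_down = rep(K * parameter_count * 4, T))
  } else {
    stopifnot_scalar(C, "C", lower = 1, integer = TRUE)
    stopifnot_scalar(K, "K", lower = 1, integer = TRUE)
    wire <- per_id_bytes(if (mode == "fd-hard") "hard" else "soft", C)
    if (is.null(dim(uploads))) {
      uploads <- matrix(rep(uploads, K), ncol = K)
    }
    if (is.null(T)) T <- nrow(uploads)
    if (length(survivors) != T || nrow(uploads) != T) {
      stop("uploads and survivors must cover T rounds", call. = FALSE)
    }
    per <- data.frame(round = seq_len(T),
                      bytes_up = rowSums(uploads) * wire,
                      bytes_down = K * survivors * wire)
  }
  list(per_round = per, total = sum(per$bytes_up) + sum(per$bytes_down))
}

#' Selector ablation: density-ratio vs confidence vs energy
#'
#' Replicates the incorrect-prediction-detection comparison: clients first
#' train locally (`pretrain_epochs`), then each selector type scores every
#' (client, proxy sample) pair for OOD-ness and is evaluated by per-client
#' AUROC against the correctness of that client's prediction (using the
#' evaluation-only proxy label oracle). Each selector is then plugged into
#' the full distillation loop and the final mean test accuracy recorded.
#'
#' @param ds A `labeled_dataset`.
#' @param part A `fed_partition` (intended: strong non-IID).
#' @param config A `fed_config` (intended: hard-label mode).
#' @param pretrain_epochs Local epochs before scoring. Default
#'   `config$local_epochs * config$T`.
#' @param run_accuracy Also run the full loop per selector? Default `TRUE`.
#' @return A data.frame with one row per selector: `selector`, `mean_auroc`,
#'   `sd_auroc`, and (if requested) `final_accuracy`.
#' @export
run_selector_ablation <- function(ds, part, config, pretrain_epochs = NULL,
                                  run_accuracy = TRUE) {
  if (is.null(pretrain_epochs)) {
    pretrain_epochs <- config$local_epochs * max(config$T, 1L)
  }
  proxy <- proxy_view(ds, part)
  truth <- proxy_label_oracle(ds, part, proxy$ids)
  clients <- build_client_states(ds, part, config, fit_selectors = TRUE)
  for (k in seq_along(clients)) {
    clients[[k]] <- local_train(
      clients[[k]], ds, epochs = pretrain_epochs, lr = config$learning_rate,
      batch_size = config$batch_size, seed = derive_seed(config$seed, 10, 0, k))
  }
  proxy_mapped <- map_features(config, proxy$features)
  selectors <- c("density-ratio", "confidence", "energy")
  out <- lapply(selectors, function(sel) {
    aurocs <- vapply(seq_along(clients), function(k) {
      cl <- clients[[k]]
      scores <- switch(sel,
        "density-ratio" = evaluate_ratio(cl$selector$ratio_model,
                                         proxy_mapped),
        "confidence" = confidence_score(mlp_probs(cl$model, proxy$features)),
        "energy" = -energy_score(mlp_logits(cl$model, proxy$features)))
      correct <- mlp_classify(cl$model, proxy$features) == truth
      auroc_incorrect_detection(scores, correct)
    }, numeric(1))
    row <- data.frame(selector = sel, mean_auroc = mean(aurocs),
                      sd_auroc = stats::sd(aurocs))
    if (run_accuracy) {
      run <- fd_loop(ds, part, config, method = paste0("ablate-", sel),
                     selector_type = sel)
      row$final_accuracy <- mean(final_accuracy(run))
    }
    row
  })
  do.call(rbind, out)
}

#' Threshold sweep over the two selectors
#'
#' Runs the full selective loop once per grid point, varying one threshold
#' while holding the other at its default (`tau_client = 0.25`,
#' `tau_server = 2`). Every grid point reuses the same derived seed so that
#' data draws and selector calibration are held fixed and only the threshold
#' varies.
#'
#' @param ds A `labeled_dataset`.
#' @param part A `fed_partition`.
#' @param config A `fed_config` providing the defaults.
#' @param tau_client_grid Vector of client thresholds in `[0, 1]`.
#' @param tau_server_grid Vector of server thresholds in `(0, 2]`.
#' @return A tidy data.frame: `which` (`"tau_client"` / `"tau_server"`),
#'   `tau`, `accuracy` (final mean, %), `p_proxy` (cumulative, %).
#' @export
run_threshold_sweep <- function(ds, part, config,
                                tau_client_grid = c(0, 0.25, 0.5, 0.75, 1),
                                tau_server_grid = c(0.4, 0.8, 1.2, 1.6, 2)) {
  if (any(tau_client_grid < 0 | tau_client_grid > 1)) {
    stop("tau_client grid must lie in [0, 1]", call. = FALSE)
  }
  if (any(tau_server_grid <= 0 | tau_server_grid > 2)) {
    stop("tau_server grid must lie in (0, 2]", call. = FALSE)
  }
  one <- function(which, tau) {
    cfg <- config
    if (which == "tau_client") cfg$tau_client <- tau else cfg$tau_server <- tau
    run <- run_selective_fd(ds, part, cfg)
    data.frame(which = which, tau = tau,
               accuracy = mean(final_accuracy(run)),
               p_proxy = p_proxy_cumulative(run))
  }
  rbind(
    do.call(rbind, lapply(tau_client_grid, function(x) one("tau_client", x))),
    do.call(rbind, lapply(tau_server_grid, function(x) one("tau_server", x)))
  )
}
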