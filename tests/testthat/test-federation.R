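test_that("T = 0 returns initial models and zero traffic", {
  tt <- tiny_task()
  cfg <- federation_config(K = 4, C = 4, T = 0, proxy_batch = 24, seed = 3)
  run <- run_selective_fd(tt$ds, tt$part, cfg)
  expect_equal(nrow(run$logs), 0)
  expect_equal(sum(run$logs$bytes_up), 0)
  expect_length(final_accuracy(run), 0)
  # initial models are untouched zero-logit networks
  expect_true(all(vapply(run$models, function(m) all(m$W2 == 0), logical(1))))
})

test_that("full runs are reproducible given the seed", {
  tt <- tiny_task()
  r1 <- run_selective_fd(tt$ds, tt$part, tt$cfg)
  r2 <- run_selective_fd(tt$ds, tt$part, tt$cfg)
  expect_identical(r1$logs, r2$logs)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$kept_ids, r2$kept_ids)
  expect_identical(r1$models, r2$models)
})

test_that("independent learning is communication-free and degenerate under
           strong non-IID", {
  tt <- tiny_task()
  run <- run_indep(tt$ds, tt$part, tt$cfg)
  expect_true(all(run$logs$bytes_up == 0))
  expect_true(all(run$logs$bytes_down == 0))
  expect_equal(p_proxy_cumulative(run), 0)
  # constant one-class predictors on a balanced C-class test set: 100 / C
  expect_equal(unname(final_accuracy(run)), rep(100 / 4, 4))
  # a single IID client learns the separable task
  ds <- make_blobs(C = 4, per_class = 80, d = 2, separation = 8, seed = 11)
  part <- partition_clients(ds, K = 1, classes_per_client = "all", seed = 11)
  cfg <- federation_config(K = 1, C = 4, T = 5, proxy_batch = 10, seed = 11)
  expect_gte(mean(final_accuracy(run_indep(ds, part, cfg))), 95)
})

test_that("distillation on self-consistent targets is a near no-op", {
  tt <- tiny_task()
  clients <- fdselect:::build_client_states(tt$ds, tt$part, tt$cfg,
                                            fit_selectors = FALSE)
  cl <- fdselect:::local_train(clients[[1]], tt$ds, epochs = 10, seed = 1)
  pv <- proxy_view(tt$ds, tt$part)
  X <- pv$features[1:8, , drop = FALSE]
  targets <- mlp_probs(cl$model, X)
  upd <- distill(cl, X, targets, epochs = 1, lr = 1e-3, seed = 1)
  delta <- sqrt(sum((upd$model$W2 - cl$model$W2)^2) +
                  sum((upd$model$W1 - cl$model$W1)^2))
  expect_lt(delta, 1e-3)
  # empty target set is a strict no-op
  expect_identical(distill(cl, X[0, , drop = FALSE], targets[0, ],
                           epochs = 5)$model, cl$model)
  # a single proxy point with a one-hot target is memorized
  x1 <- X[1, , drop = FALSE]
  mem <- distill(cl, x1, 3L, epochs = 300, lr = 0.3, seed = 1)
  expect_equal(mlp_classify(mem$model, x1), 3L)
})

test_that("selective distillation lifts every client above its local-only
           accuracy", {
  tt <- tiny_task()
  run <- run_selective_fd(tt$ds, tt$part, tt$cfg)
  indep <- run_indep(tt$ds, tt$part, tt$cfg)
  expect_true(all(final_accuracy(run) > final_accuracy(indep)))
})

test_that("disabling both selectors keeps the full proxy batch every round", {
  tt <- tiny_task()
  run <- run_fd_noselect(tt$ds, tt$part, tt$cfg)
  expect_true(all(run$logs$p_proxy_round == 100))
  expect_true(all(run$logs$dropped_no_sharer == 0))
  expect_true(all(run$logs$dropped_ambiguous == 0))
  # under strong non-IID hard labels the unselected ensembles are ambiguous:
  # one-class clients each vote their own class, so ensemble ambiguity is
  # near 2 (1 - 1/K)
  pv <- proxy_view(tt$ds, tt$part)
  clients <- fdselect:::build_client_states(tt$ds, tt$part, tt$cfg,
                                            fit_selectors = FALSE)
  for (k in seq_along(clients)) {
    clients[[k]] <- fdselect:::local_train(clients[[k]], tt$ds, epochs = 20,
                                           seed = k)
  }
  ens <- generate_ensemble_predictions(clients, pv, pv$ids, tt$cfg,
                                       client_masks = NULL,
                                       select_server = FALSE)
  expect_gte(mean(ambiguity(ens$ensemble)), 0.9 * 2 * (1 - 1 / 4))
})

test_that("soft-label sharing is at least as good as hard up to 5 points", {
  for (seed in c(7, 8)) {
    task <- strong_noniid_task(seed = seed, per_class = 200)
    hard <- run_selective_fd(task$ds, task$part,
                             default_config(seed = seed, proxy_batch = 200))
    soft <- run_selective_fd(task$ds, task$part,
                             default_config(seed = seed, proxy_batch = 200,
                                            label_mode = "soft"))
    expect_gte(mean(final_accuracy(soft)), mean(final_accuracy(hard)) - 5)
  }
})

test_that("K = 1 ensembles equal the single client's prediction", {
  ds <- make_blobs(C = 4, per_class = 80, d = 2, separation = 8, seed = 11)
  part <- partition_clients(ds, K = 1, classes_per_client = "all", seed = 11)
  cfg <- federation_config(K = 1, C = 4, T = 1, proxy_batch = 10,
                           label_mode = "soft", seed = 11)
  clients <- fdselect:::build_client_states(ds, part, cfg,
                                            fit_selectors = FALSE)
  clients[[1]] <- fdselect:::local_train(clients[[1]], ds, epochs = 10,
                                         seed = 1)
  pv <- proxy_view(ds, part)
  ens <- generate_ensemble_predictions(clients, pv, pv$ids[1:10], cfg,
                                       select_server = FALSE)
  own <- mlp_probs(clients[[1]]$model,
                   pv$features[match(ens$ids, pv$ids), , drop = FALSE])
  expect_equal(ens$ensemble, own, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("FedAvg with one client reproduces independent learning", {
  ds <- make_blobs(C = 4, per_class = 80, d = 2, separation = 8, seed = 11)
  part <- partition_clients(ds, K = 1, classes_per_client = "all", seed = 11)
  cfg <- federation_config(K = 1, C = 4, T = 5, proxy_batch = 10, seed = 11)
  fa <- run_fedavg(ds, part, cfg)
  ind <- run_indep(ds, part, cfg)
  expect_equal(fa$accuracy, ind$accuracy)
  expect_identical(fa$models[[1]][c("W1", "b1", "W2", "b2")],
                   ind$models[[1]][c("W1", "b1", "W2", "b2")])
  # bytes: parameter_count * 4 per client per direction per round
  expect_true(all(fa$logs$bytes_up == fa$parameter_count * 4))
})

test_that("configuration validates and round-trips through YAML", {
  expect_error(federation_config(K = 4, C = 4, tau_client = 1.2))
  expect_error(federation_config(K = 4, C = 4, tau_server = 0))
  expect_error(federation_config(K = 4, C = 4, tau_server = 2.5))
  expect_error(federation_config(K = 0, C = 4))
  cfg <- federation_config(K = 4, C = 4, T = 3, label_mode = "soft",
                           tau_client = 0.4, seed = 12)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  expect_equal(read_config(path), cfg)
})

test_that("run summaries are written as CSV log plus JSON summary", {
  tt <- tiny_task()
  run <- run_selective_fd(tt$ds, tt$part, tt$cfg)
  dir <- withr::local_tempdir()
  write_run_summary(run, dir)
  log <- read.csv(file.path(dir, "log.csv"))
  expect_equal(nrow(log), 3)
  expect_equal(log$bytes_up, run$logs$bytes_up)
  summ <- jsonlite::read_json(file.path(dir, "summary.json"),
                              simplifyVector = TRUE)
  expect_equal(summ$method, "selective-fd")
  expect_equal(summ$mean_final_accuracy, mean(final_accuracy(run)))
})
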