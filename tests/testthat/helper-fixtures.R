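# Shared fixtures: all synthetic, built in code at test time.

# Standard strong non-IID task used across federation tests: 10 classes,
# 10 one-class clients, well-separated blobs.
strong_noniid_task <- function(seed = 7, per_class = 600) {
  ds <- make_blobs(C = 10, per_class = per_class, d = 8, separation = 8,
                   noise_sd = 1, seed = seed)
  part <- partition_clients(ds, K = 10, classes_per_client = 1, seed = seed)
  list(ds = ds, part = part)
}

default_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(K = 10, C = 10, T = 10, label_mode = "hard", seed = seed),
    list(...))
  do.call(federation_config, args)
}

# Tiny task for fast structural checks.
tiny_task <- function(seed = 3) {
  ds <- make_blobs(C = 4, per_class = 60, d = 2, separation = 8, seed = seed)
  part <- partition_clients(ds, K = 4, classes_per_client = 1, seed = seed)
  cfg <- federation_config(K = 4, C = 4, T = 3, proxy_batch = 24, seed = seed)
  list(ds = ds, part = part, cfg = cfg)
}

# Samples from a Gaussian truncated to [-1, 1].
rtruncnorm01 <- function(n, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * n, sd = sd)
    out <- c(out, draw[abs(draw) <= 1])
  }
  out[seq_len(n)]
}

# Brute-force pairwise AUROC estimator (independent oracle).
auroc_bruteforce <- function(scores, is_correct) {
  pos <- scores[is_correct]
  neg <- scores[!is_correct]
  cmp <- outer(neg, pos, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

# Direct minimization oracles for the KuLSIF quadratic over the representer
# subspace: (a) solve the stationary system of the objective itself,
# (b) iterative BFGS descent with the objective's exact gradient.
kulsif_oracle_solve <- function(S_k, S_u, bandwidth, beta) {
  Z <- rbind(S_k, S_u)
  Kz <- exp(-as.matrix(stats::dist(Z))^2 / (2 * bandwidth^2))
  n_k <- nrow(S_k)
  iu <- n_k + seq_len(nrow(S_u))
  H <- crossprod(Kz[iu, , drop = FALSE]) / nrow(S_u) + beta * Kz
  b <- colSums(Kz[seq_len(n_k), , drop = FALSE]) / n_k
  # pseudo-inverse: H can be singular to machine precision when the kernel
  # matrix is; flat directions do not change the attained minimum
  s <- svd(H)
  keep <- s$d > max(s$d) * 1e-12
  drop(s$v[, keep, drop = FALSE] %*%
         ((crossprod(s$u[, keep, drop = FALSE], b)) / s$d[keep]))
}

kulsif_oracle_bfgs <- function(S_k, S_u, bandwidth, beta) {
  Z <- rbind(S_k, S_u)
  Kz <- exp(-as.matrix(stats::dist(Z))^2 / (2 * bandwidth^2))
  n_k <- nrow(S_k)
  iu <- n_k + seq_len(nrow(S_u))
  ik <- seq_len(n_k)
  fn <- function(cf) kulsif_objective(cf, S_k, S_u, bandwidth, beta)
  gr <- function(cf) {
    w <- drop(Kz %*% cf)
    drop(crossprod(Kz[iu, , drop = FALSE], w[iu])) / nrow(S_u) -
      colSums(Kz[ik, , drop = FALSE]) / n_k + beta * w
  }
  stats::optim(rep(0, nrow(Z)), fn, gr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))$value
}

# Random simplex vector.
rsimplex <- function(C) {
  g <- -log(stats::runif(C))
  g / sum(g)
}
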