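test_that("uniform reference stays in the data box and is deterministic", {
  set.seed(1)
  X <- matrix(runif(200), ncol = 2)
  ref <- sample_uniform_reference(X, n_u = 100, margin = 0, seed = 4)
  expect_equal(dim(ref$sample), c(100, 2))
  for (j in 1:2) {
    expect_true(all(ref$sample[, j] >= min(X[, j])))
    expect_true(all(ref$sample[, j] <= max(X[, j])))
    expect_equal(unname(ref$box[j, ]), range(X[, j]))
  }
  expect_identical(ref, sample_uniform_reference(X, n_u = 100, margin = 0,
                                                 seed = 4))
  expect_error(sample_uniform_reference(X, n_u = 0))
  # degenerate dimension widens with a warning instead of collapsing
  Xd <- cbind(X[, 1], 2)
  expect_warning(refd <- sample_uniform_reference(Xd, n_u = 10, margin = 0,
                                                  seed = 1),
                 "zero-variance")
  expect_gt(refd$box[2, "hi"], refd$box[2, "lo"])
})

test_that("median bandwidth matches enumerable cases and a Monte-Carlo law", {
  expect_equal(median_bandwidth(matrix(c(0, 3), ncol = 1)), 3)
  expect_equal(median_bandwidth(matrix(c(0, 1, 2), ncol = 1)), 1)
  expect_error(median_bandwidth(matrix(1, 5, 2)), "identical")
  expect_error(median_bandwidth(matrix(1, 1, 1)))
  # 2D standard normal: ||X - Y||^2 ~ 2 * chisq(2), so the analytic median
  # interpoint distance is sqrt(2 * qchisq(0.5, 2)).
  set.seed(10)
  pts <- matrix(rnorm(2000), ncol = 2)
  analytic <- sqrt(2 * qchisq(0.5, df = 2))
  expect_lt(abs(median_bandwidth(pts) - analytic) / analytic, 0.15)
})

test_that("analytic KuLSIF solve minimizes its objective (oracle check)", {
  # 20 random small instances; compare against (a) a direct solve of the
  # quadratic's stationary system and (b) iterative BFGS descent, both built
  # straight from the objective definition.
  set.seed(42)
  for (i in 1:20) {
    n_k <- sample(3:30, 1)
    n_u <- sample(3:30, 1)
    d <- sample(1:3, 1)
    S_k <- matrix(rnorm(n_k * d), n_k, d)
    S_u <- matrix(runif(n_u * d, -2, 2), n_u, d)
    bw <- median_bandwidth(rbind(S_k, S_u))
    beta <- 10^runif(1, -3, -1)
    fit <- fit_kulsif(S_k, S_u, bandwidth = bw, beta = beta)
    expect_length(fit$coefficients, n_k + n_u)
    obj_fit <- kulsif_objective(fit$coefficients, S_k, S_u, bw, beta)
    obj_direct <- kulsif_objective(kulsif_oracle_solve(S_k, S_u, bw, beta),
                                   S_k, S_u, bw, beta)
    expect_lt(abs(obj_fit - obj_direct) / abs(obj_direct), 1e-6)
    # iterative descent can stall short of the minimum but never below it
    obj_bfgs <- kulsif_oracle_bfgs(S_k, S_u, bw, beta)
    expect_lte(obj_fit, obj_bfgs + 1e-9 * abs(obj_bfgs))
  }
})

test_that("ratio of identical distributions concentrates at one", {
  # p = u implies w* = 1; mean estimated ratio within +-0.2 at n = 1000.
  set.seed(5)
  S_k <- matrix(runif(2000), ncol = 2)
  S_u <- matrix(runif(2000), ncol = 2)
  fit <- fit_kulsif(S_k, S_u, beta = 1e-3)
  fresh <- matrix(runif(1000), ncol = 2)
  expect_lt(abs(mean(evaluate_ratio(fit, fresh)) - 1), 0.2)
})

test_that("evaluate_ratio is pointwise, finite, and shape-safe", {
  set.seed(6)
  S_k <- matrix(rnorm(100, sd = 0.5), ncol = 1)
  ref <- sample_uniform_reference(S_k, n_u = 100, seed = 6)
  fit <- fit_kulsif(S_k, ref$sample, box = ref$box)
  expect_identical(evaluate_ratio(fit, matrix(0, 0, 1)), numeric(0))
  X <- matrix(c(0.1, 0.1, 0.9), ncol = 1)
  r <- evaluate_ratio(fit, X)
  expect_true(all(is.finite(r)))
  expect_identical(r[1], r[2])  # repeated rows -> identical outputs
  expect_error(evaluate_ratio(fit, matrix(0, 2, 3)), "dimension")
  # a support point of S_k scores far above a point far outside the box
  in_pt <- S_k[1, , drop = FALSE]
  out_pt <- matrix(max(S_k) + 50)
  expect_gt(evaluate_ratio(fit, in_pt), evaluate_ratio(fit, out_pt))
  expect_lt(abs(evaluate_ratio(fit, out_pt)), 0.05)  # far-OOD ratio ~ 0
  expect_identical(predict(fit, X), r)
})

test_that("threshold calibration follows the lower-quantile convention", {
  set.seed(8)
  S_k <- matrix(rnorm(200, sd = 0.5), ncol = 1)
  ref <- sample_uniform_reference(S_k, n_u = 200, seed = 8)
  fit <- fit_kulsif(S_k, ref$sample)
  V <- matrix(rnorm(100, sd = 0.5), ncol = 1)
  ratios <- evaluate_ratio(fit, V)
  t0 <- calibrate_threshold(fit, V, tau_client = 0)
  expect_equal(t0$threshold_value, min(ratios))
  expect_equal(sum(ratios < t0$threshold_value), 0)
  t1 <- calibrate_threshold(fit, V, tau_client = 1)
  expect_equal(t1$threshold_value, max(ratios))
  for (tau in c(0.1, 0.25, 0.5, 0.9)) {
    tq <- calibrate_threshold(fit, V, tau_client = tau)
    expect_true(tq$threshold_value %in% ratios)  # attained, type-1 quantile
    expect_lte(mean(ratios < tq$threshold_value), tau)
  }
  expect_error(calibrate_threshold(fit, V, tau_client = 1.5))
  expect_error(calibrate_threshold(fit, V[0, , drop = FALSE], 0.5))
})

test_that("fitting is deterministic and serialization round-trips", {
  set.seed(9)
  S_k <- matrix(rnorm(60), ncol = 2)
  ref <- sample_uniform_reference(S_k, n_u = 30, seed = 9)
  f1 <- fit_kulsif(S_k, ref$sample, box = ref$box)
  f2 <- fit_kulsif(S_k, ref$sample, box = ref$box)
  expect_identical(f1, f2)
  expect_error(fit_kulsif(S_k, ref$sample, beta = 0))
  expect_error(fit_kulsif(S_k, matrix(0, 3, 3)))
  path <- withr::local_tempfile(fileext = ".json")
  write_ratio_model(f1, path)
  back <- read_ratio_model(path)
  X <- matrix(rnorm(20), ncol = 2)
  expect_equal(evaluate_ratio(back, X), evaluate_ratio(f1, X),
               tolerance = 1e-12)
})
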