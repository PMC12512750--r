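# The 25-preset zoo, training/evaluation contracts and metric identities.

make_linear_data <- function(n_trials = 6, n_sweeps = 30, noise = 0,
                             seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_trials), function(t) {
    a <- runif(n_sweeps, 0, 30)
    tibble::tibble(trial_id = sprintf("T%d", t), variant = "Ds1",
                   sweep_index = seq_len(n_sweeps),
                   p_mmHg = 2 * a + rnorm(n_sweeps, 0, noise), a = a)
  }))
}

test_that("the registry holds the 25 unique presets by family", {
  reg <- model_registry()
  expect_equal(nrow(reg), 25)
  expect_equal(anyDuplicated(reg$preset_id), 0L)
  expect_equal(anyDuplicated(reg$label), 0L)
  fam <- table(reg$family)
  expect_equal(as.integer(fam[c("linear", "tree", "svm", "ensemble", "gpr",
                                "nn", "kernel")]),
               c(3L, 3L, 6L, 2L, 4L, 5L, 2L))
  expect_equal(reg$label[reg$preset_id == "gpr_matern52"], "GPR Matern 5/2")
})

test_that("unknown presets are rejected", {
  expect_error(icpsweep:::fit_preset("not_a_model", data.frame(a = 1:5),
                                     1:5),
               class = "icp_unknown_preset")
})

test_that("a realizable linear map is fit to numerical precision", {
  data <- make_linear_data()
  split <- split_trials(unique(data$trial_id), seed = 2)
  ms <- train_models(data, split, presets = model_registry()[1, ],
                     cv_folds = 0)
  expect_lt(ms$metrics$train_mae, 1e-6)
})

test_that("constant labels are flagged degenerate with R2 = 0", {
  pred <- rep(5, 10)
  m <- icpsweep:::metrics_from_pred(pred, rep(5, 10))
  expect_equal(m$r2, 0)
  expect_true(m$degenerate_sst)
})

test_that("cross-validation fold assignment is deterministic under a seed", {
  data <- make_linear_data(n_trials = 10, noise = 1)
  split <- split_trials(unique(data$trial_id), seed = 2)
  ms1 <- train_models(data, split, presets = model_registry()[1, ],
                      cv_folds = 5, seed = 42)
  ms2 <- train_models(data, split, presets = model_registry()[1, ],
                      cv_folds = 5, seed = 42)
  expect_equal(ms1$metrics, ms2$metrics)
})

test_that("evaluation metrics satisfy their defining identities", {
  m <- icpsweep:::metrics_from_pred(1:10, 1:10)
  expect_equal(c(m$mae, m$rmse, m$r2), c(0, 0, 1))
  truth <- c(1, 5, 9, 2, 8)
  m2 <- icpsweep:::metrics_from_pred(rep(mean(truth), 5), truth)
  expect_equal(m2$r2, 0)
  m3 <- icpsweep:::metrics_from_pred(c(2, 0, 2, 0), c(1, 1, 1, 1))
  expect_equal(m3$mae, 1)
  expect_equal(m3$rmse, 1)   # equality case of MAE <= RMSE
})

test_that("MAE never exceeds RMSE across fitted reports", {
  data <- make_linear_data(n_trials = 8, noise = 2)
  split <- split_trials(unique(data$trial_id), seed = 4)
  presets <- model_registry()[model_registry()$preset_id %in%
                                c("lr_linear", "tree_fine", "svm_linear",
                                  "gpr_sqexp", "nn_narrow"), ]
  ms <- train_models(data, split, presets = presets, cv_folds = 0, seed = 1)
  ev <- evaluate_models(ms, data, role = "test")
  expect_true(all(ev$mae <= ev$rmse + 1e-12))
  expect_true(all(ms$metrics$train_mae <= ms$metrics$train_rmse + 1e-12))
  expect_true(all(ev$r2 <= 1))
  expect_equal(lengths(ev$residuals), ev$n_obs)
})

test_that("evaluation refuses trials that were used in training", {
  data <- make_linear_data()
  split <- split_trials(unique(data$trial_id), seed = 2)
  ms <- train_models(data, split, presets = model_registry()[1, ],
                     cv_folds = 0)
  # Relabel a training trial as test: the guard must fire.
  train_id <- split_role(ms$split, "train")[1]
  ms$split$role[ms$split$trial_id == train_id] <- "test"
  expect_error(evaluate_models(ms, data, role = "test"),
               class = "icp_leakage_error")
})

test_that("select_best ranks by RMSE, then MAE, then registry order", {
  rep1 <- tibble::tibble(preset_id = c("lr_linear", "tree_fine", "svm_linear"),
                         rmse = c(0.3, 0.2, 0.5), mae = c(0.1, 0.1, 0.1))
  expect_equal(select_best(rep1), "tree_fine")
  rep2 <- tibble::tibble(preset_id = c("lr_linear", "tree_fine"),
                         rmse = c(0.2, 0.2), mae = c(0.2, 0.1))
  expect_equal(select_best(rep2), "tree_fine")
  rep3 <- tibble::tibble(preset_id = c("tree_fine", "lr_linear"),
                         rmse = c(0.2, 0.2), mae = c(0.1, 0.1))
  expect_equal(select_best(rep3), "lr_linear")  # registry order
  expect_equal(select_best(rep1[1, ]), "lr_linear")
})

test_that("every preset fits and predicts finite values on small data", {
  data <- make_linear_data(n_trials = 5, n_sweeps = 25, noise = 1, seed = 3)
  data$b <- data$a^1.5 + rnorm(nrow(data), 0, 0.5)   # second feature
  x <- data[c("a", "b")]
  y <- data$p_mmHg
  for (pid in model_registry()$preset_id) {
    fit <- icpsweep:::fit_preset(pid, x, y, seed = 7)
    pred <- fit$predict(x)
    expect_length(pred, nrow(x))
    expect_true(all(is.finite(pred)), label = pid)
    # Every learner should beat the trivial mean predictor in-sample.
    expect_lt(sqrt(mean((pred - y)^2)), sd(y))
  }
})

test_that("GP presets are exact interpolators of smooth targets up to noise", {
  set.seed(6)
  x <- data.frame(a = seq(0, 10, length.out = 40))
  y <- sin(x$a)
  for (kern in c("gpr_sqexp", "gpr_matern52", "gpr_exponential",
                 "gpr_ratquad")) {
    fit <- icpsweep:::fit_preset(kern, x, y, seed = 1)
    expect_lt(sqrt(mean((fit$predict(x) - y)^2)), 0.2)
  }
})

test_that("squared-exponential GP agrees with kernlab on shared settings", {
  skip_if_not_installed("kernlab")
  set.seed(12)
  x <- matrix(runif(60, -2, 2), ncol = 2)
  y <- drop(sin(x[, 1]) + 0.5 * cos(x[, 2]))
  # Fix the same kernel width and noise on both routes.
  l <- 1.3
  noise <- 0.1
  d <- as.matrix(dist(x))
  K <- exp(-d^2 / (2 * l^2))
  mine <- unname(drop(K %*% solve(K + diag(noise^2, nrow(x)), y)))
  kl <- kernlab::gausspr(x, y, kernel = "rbfdot",
                         kpar = list(sigma = 1 / (2 * l^2)),
                         var = noise^2, scaled = FALSE, tol = 1e-8)
  theirs <- drop(kernlab::predict(kl, x))
  expect_equal(mine, theirs, tolerance = 1e-4)
})

test_that("tidy and glance summarise a model set", {
  data <- make_linear_data()
  split <- split_trials(unique(data$trial_id), seed = 2)
  ms <- train_models(data, split, presets = model_registry()[c(1, 4), ],
                     cv_folds = 0)
  td <- tidy(ms)
  expect_equal(nrow(td), 2)
  gl <- glance(ms)
  expect_equal(gl$n_presets, 2)
  expect_true(gl$best_preset %in% td$preset_id)
})
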