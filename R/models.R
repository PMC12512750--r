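# Internal learners backing the regression presets.
#
# Established packages carry every standard fit (lm/MASS, rpart, e1071,
# randomForest, xgboost, nnet). Three small learners are implemented here
# because no installed package provides them in the required form: an exact
# Gaussian-process posterior mean with pluggable kernels (Matern 5/2 and
# rational quadratic are not available in kernlab), a dense multilayer
# perceptron with two/three hidden layers (nnet is single-layer), and a
# random Fourier feature expansion for the kernel-approximation presets.

# ---- scaling ---------------------------------------------------------------

fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(x, s) {
  sweep(sweep(x, 2, s$center), 2, s$scale, "/")
}

# Deterministic median-distance heuristic for kernel length scales.
median_lengthscale <- function(x, max_rows = 400) {
  n <- nrow(x)
  idx <- if (n > max_rows) round(seq(1, n, length.out = max_rows)) else seq_len(n)
  d <- stats::dist(x[idx, , drop = FALSE])
  m <- median(d[d > 0])
  if (!is.finite(m) || m == 0) 1 else m
}

# ---- exact GP posterior mean ----------------------------------------------

gp_kernel_matrix <- function(kernel, d, l, alpha = 1) {
  switch(kernel,
    sqexp = exp(-d^2 / (2 * l^2)),
    matern52 = {
      s <- sqrt(5) * d / l
      (1 + s + s^2 / 3) * exp(-s)
    },
    exponential = exp(-d / l),
    ratquad = (1 + d^2 / (2 * alpha * l^2))^(-alpha),
    abort(sprintf("Unknown GP kernel '%s'.", kernel))
  )
}

fit_gpr <- function(x, y, kernel, noise_sd = 0.1) {
  sx <- fit_scaler(x)
  xs <- apply_scaler(x, sx)
  y_ctr <- mean(y)
  y_scl <- sd(y)
  if (y_scl == 0) y_scl <- 1
  ys <- (y - y_ctr) / y_scl
  l <- median_lengthscale(xs)
  d <- as.matrix(stats::dist(xs))
  K <- gp_kernel_matrix(kernel, d, l)
  n <- nrow(K)
  alpha_w <- solve(K + diag(noise_sd^2 + 1e-8, n), ys)
  structure(list(xs = xs, scaler = sx, y_ctr = y_ctr, y_scl = y_scl,
                 alpha_w = alpha_w, kernel = kernel, l = l),
            class = "icp_gpr")
}

#' @export
predict.icp_gpr <- function(object, newdata, ...) {
  ns <- apply_scaler(as.matrix(newdata), object$scaler)
  d <- pracma::distmat(ns, object$xs)
  Ks <- gp_kernel_matrix(object$kernel, d, object$l)
  drop(Ks %*% object$alpha_w) * object$y_scl + object$y_ctr
}

# ---- dense MLP (2-3 hidden layers of tanh units) ---------------------------

mlp_init <- function(sizes, seed) {
  with_fixed_seed(seed, {
    lapply(seq_len(length(sizes) - 1), function(i) {
      list(W = matrix(rnorm(sizes[i] * sizes[i + 1], 0,
                            1 / sqrt(sizes[i])), sizes[i], sizes[i + 1]),
           b = rep(0, sizes[i + 1]))
    })
  })
}

mlp_flatten <- function(layers) {
  unlist(lapply(layers, function(l) c(as.vector(l$W), l$b)))
}

mlp_unflatten <- function(theta, sizes) {
  layers <- list()
  pos <- 0
  for (i in seq_len(length(sizes) - 1)) {
    nw <- sizes[i] * sizes[i + 1]
    layers[[i]] <- list(
      W = matrix(theta[pos + seq_len(nw)], sizes[i], sizes[i + 1]),
      b = theta[pos + nw + seq_len(sizes[i + 1])])
    pos <- pos + nw + sizes[i + 1]
  }
  layers
}

mlp_forward <- function(layers, x) {
  acts <- list(x)
  a <- x
  n_lay <- length(layers)
  for (i in seq_len(n_lay)) {
    z <- a %*% layers[[i]]$W + matrix(layers[[i]]$b, nrow(a),
                                      length(layers[[i]]$b), byrow = TRUE)
    a <- if (i < n_lay) tanh(z) else z
    acts[[i + 1]] <- a
  }
  acts
}

fit_mlp <- function(x, y, hidden = c(10, 10), decay = 1e-3, maxit = 300,
                    seed = 1L) {
  sx <- fit_scaler(x)
  xs <- apply_scaler(x, sx)
  y_ctr <- mean(y); y_scl <- sd(y); if (y_scl == 0) y_scl <- 1
  ys <- (y - y_ctr) / y_scl
  sizes <- c(ncol(xs), hidden, 1)
  layers0 <- mlp_init(sizes, seed)
  n <- nrow(xs)
  objective <- function(theta) {
    layers <- mlp_unflatten(theta, sizes)
    acts <- mlp_forward(layers, xs)
    pred <- acts[[length(acts)]]
    mean((pred - ys)^2) + decay * sum(theta^2)
  }
  gradient <- function(theta) {
    layers <- mlp_unflatten(theta, sizes)
    acts <- mlp_forward(layers, xs)
    n_lay <- length(layers)
    delta <- 2 * (acts[[n_lay + 1]] - ys) / n
    grads <- vector("list", n_lay)
    for (i in rev(seq_len(n_lay))) {
      grads[[i]] <- list(W = t(acts[[i]]) %*% delta,
                         b = colSums(delta))
      if (i > 1) {
        delta <- (delta %*% t(layers[[i]]$W)) * (1 - acts[[i]]^2)
      }
    }
    mlp_flatten(grads) + 2 * decay * theta
  }
  opt <- stats::optim(mlp_flatten(layers0), objective, gradient,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  structure(list(layers = mlp_unflatten(opt$par, sizes), sizes = sizes,
                 scaler = sx, y_ctr = y_ctr, y_scl = y_scl),
            class = "icp_mlp")
}

#' @export
predict.icp_mlp <- function(object, newdata, ...) {
  xs <- apply_scaler(as.matrix(newdata), object$scaler)
  acts <- mlp_forward(object$layers, xs)
  drop(acts[[length(acts)]]) * object$y_scl + object$y_ctr
}

# ---- random Fourier features (RBF kernel approximation) --------------------

rff_map <- function(x, proj) {
  sqrt(2 / ncol(proj$W)) * cos(x %*% proj$W +
    matrix(proj$b, nrow(x), ncol(proj$W), byrow = TRUE))
}

make_rff <- function(xs, n_features = 100, seed = 1L) {
  l <- median_lengthscale(xs)
  with_fixed_seed(seed, {
    list(W = matrix(rnorm(ncol(xs) * n_features, 0, 1 / l),
                    ncol(xs), n_features),
         b = stats::runif(n_features, 0, 2 * pi))
  })
}

fit_rff <- function(x, y, learner = c("svm", "ols"), n_features = 100,
                    seed = 1L) {
  learner <- match.arg(learner)
  sx <- fit_scaler(x)
  xs <- apply_scaler(x, sx)
  proj <- make_rff(xs, n_features, seed)
  z <- rff_map(xs, proj)
  fit <- if (learner == "svm") {
    e1071::svm(z, y, type = "eps-regression", kernel = "linear",
               cost = 1, epsilon = 0.1, scale = FALSE)
  } else {
    zd <- as.data.frame(z)
    names(zd) <- paste0("z", seq_len(ncol(z)))
    lm(y ~ ., data = cbind(zd, y = y))
  }
  structure(list(fit = fit, learner = learner, scaler = sx, proj = proj),
            class = "icp_rff")
}

#' @export
predict.icp_rff <- function(object, newdata, ...) {
  z <- rff_map(apply_scaler(as.matrix(newdata), object$scaler), object$proj)
  if (object$learner == "svm") {
    as.numeric(predict(object$fit, z))
  } else {
    zd <- as.data.frame(z)
    names(zd) <- paste0("z", seq_len(ncol(z)))
    as.numeric(predict(object$fit, zd))
  }
}

# ---- preset catalogue ------------------------------------------------------

#' Catalogue of the 25 regression presets
#'
#' The fixed model zoo evaluated by the pipeline: 3 linear presets, 3
#' decision trees (leaf sizes 4/12/36), 6 support-vector machines (linear,
#' quadratic, cubic, fine/medium/coarse Gaussian), 2 tree ensembles
#' (boosted, bagged), 4 Gaussian-process kernels (squared exponential,
#' Matern 5/2, exponential, rational quadratic), 5 neural networks (narrow
#' 10, medium 25, wide 100, bilayered 10-10, trilayered 10-10-10) and 2
#' kernel-approximation presets (SVM kernel, least-squares kernel).
#' Hyperparameters are fixed; there is no tuning stage.
#'
#' @return Tibble with `no`, `preset_id`, `label`, `family` (25 rows).
#' @export
model_registry <- function() {
  tibble::tribble(
    ~no, ~preset_id,        ~label,                          ~family,
    1L,  "lr_linear",       "Linear",                        "linear",
    2L,  "lr_interactions", "Interactions linear",           "linear",
    3L,  "lr_robust",       "Robust linear",                 "linear",
    4L,  "tree_fine",       "Fine tree (leaf size=4)",       "tree",
    5L,  "tree_medium",     "Medium tree (leaf size=12)",    "tree",
    6L,  "tree_coarse",     "Coarse tree (leaf size=36)",    "tree",
    7L,  "svm_linear",      "Linear SVM",                    "svm",
    8L,  "svm_quadratic",   "Quadratic SVM",                 "svm",
    9L,  "svm_cubic",       "Cubic SVM",                     "svm",
    10L, "svm_fine_gauss",  "Fine Gaussian SVM",             "svm",
    11L, "svm_med_gauss",   "Medium Gaussian SVM",           "svm",
    12L, "svm_coarse_gauss","Coarse Gaussian SVM",           "svm",
    13L, "ens_boosted",     "Boosted trees",                 "ensemble",
    14L, "ens_bagged",      "Bagged trees",                  "ensemble",
    15L, "gpr_sqexp",       "GPR squared exponential",       "gpr",
    16L, "gpr_matern52",    "GPR Matern 5/2",                "gpr",
    17L, "gpr_exponential", "GPR exponential",               "gpr",
    18L, "gpr_ratquad",     "GPR rational quadratic",        "gpr",
    19L, "nn_narrow",       "Narrow NN (size=10)",           "nn",
    20L, "nn_medium",       "Medium NN (size=25)",           "nn",
    21L, "nn_wide",         "Wide NN (size=100)",            "nn",
    22L, "nn_bilayered",    "Bilayered NN (size=10)",        "nn",
    23L, "nn_trilayered",   "Trilayered NN (size=10)",       "nn",
    24L, "kernel_svm",      "SVM kernel",                    "kernel",
    25L, "kernel_lsr",      "LSR kernel",                    "kernel"
  )
}

# Columns forming a full-rank design under the same QR tolerance the
# downstream fitter applies to its raw intercept-augmented model matrix.
qr_independent_columns <- function(xm) {
  q <- qr(cbind(1, xm))
  piv <- q$pivot[seq_len(q$rank)]
  sort(colnames(xm)[setdiff(piv, 1) - 1])
}

svm_gamma <- function(p, scale_factor) {
  ks <- scale_factor * sqrt(p)
  1 / ks^2
}

# Fit one preset; returns a list(preset_id, model, predict(newdata)).
fit_preset <- function(preset_id, x, y, seed = 1L) {
  x <- as.data.frame(x)
  xm <- as.matrix(x)
  p <- ncol(xm)
  df <- cbind(x, .y = y)
  svm_fit <- function(kernel, ...) {
    e1071::svm(xm, y, type = "eps-regression", kernel = kernel,
               cost = 1, epsilon = 0.1, scale = TRUE, ...)
  }
  tree_fit <- function(leaf) {
    rpart::rpart(.y ~ ., data = df,
                 control = rpart::rpart.control(minbucket = leaf,
                                                minsplit = 2 * leaf,
                                                cp = 1e-4, xval = 0))
  }
  model <- switch(preset_id,
    lr_linear = lm(.y ~ ., data = df),
    lr_interactions = lm(.y ~ .^2, data = df),
    lr_robust = {
      # rlm has no aliased-coefficient handling; reduce to a full-rank
      # column set first.
      keep <- qr_independent_columns(xm)
      MASS::rlm(.y ~ ., data = cbind(x[keep], .y = y), maxit = 100)
    },
    tree_fine = tree_fit(4),
    tree_medium = tree_fit(12),
    tree_coarse = tree_fit(36),
    svm_linear = svm_fit("linear"),
    svm_quadratic = svm_fit("polynomial", degree = 2, coef0 = 1,
                            gamma = 1 / p),
    svm_cubic = svm_fit("polynomial", degree = 3, coef0 = 1, gamma = 1 / p),
    svm_fine_gauss = svm_fit("radial", gamma = svm_gamma(p, 0.25)),
    svm_med_gauss = svm_fit("radial", gamma = svm_gamma(p, 1)),
    svm_coarse_gauss = svm_fit("radial", gamma = svm_gamma(p, 4)),
    ens_boosted = xgboost::xgboost(xm, y, nrounds = 150,
                                   learning_rate = 0.1, max_depth = 6,
                                   nthreads = 1, verbosity = 0,
                                   seed = as.integer(seed),
                                   objective = "reg:squarederror"),
    ens_bagged = with_fixed_seed(seed,
      randomForest::randomForest(xm, y, ntree = 200, mtry = max(1, p))),
    gpr_sqexp = fit_gpr(xm, y, "sqexp"),
    gpr_matern52 = fit_gpr(xm, y, "matern52"),
    gpr_exponential = fit_gpr(xm, y, "exponential"),
    gpr_ratquad = fit_gpr(xm, y, "ratquad"),
    nn_narrow = nnet_fit(xm, y, size = 10, seed = seed),
    nn_medium = nnet_fit(xm, y, size = 25, seed = seed),
    nn_wide = nnet_fit(xm, y, size = 100, seed = seed),
    nn_bilayered = fit_mlp(xm, y, hidden = c(10, 10), seed = seed),
    nn_trilayered = fit_mlp(xm, y, hidden = c(10, 10, 10), seed = seed),
    kernel_svm = fit_rff(xm, y, "svm", seed = seed),
    kernel_lsr = fit_rff(xm, y, "ols", seed = seed),
    abort(sprintf("Unknown preset '%s'.", preset_id),
          class = "icp_unknown_preset")
  )
  predictor <- make_predictor(preset_id, model, colnames(x))
  list(preset_id = preset_id, model = model, predict = predictor)
}

nnet_fit <- function(xm, y, size, seed, decay = 1e-3, maxit = 500) {
  sx <- fit_scaler(xm)
  xs <- apply_scaler(xm, sx)
  y_ctr <- mean(y); y_scl <- sd(y); if (y_scl == 0) y_scl <- 1
  fit <- with_fixed_seed(seed,
    nnet::nnet(xs, (y - y_ctr) / y_scl, size = size, linout = TRUE,
               decay = decay, maxit = maxit, MaxNWts = 50000, trace = FALSE))
  structure(list(fit = fit, scaler = sx, y_ctr = y_ctr, y_scl = y_scl),
            class = "icp_nnet")
}

#' @export
predict.icp_nnet <- function(object, newdata, ...) {
  xs <- apply_scaler(as.matrix(newdata), object$scaler)
  drop(predict(object$fit, xs)) * object$y_scl + object$y_ctr
}

make_predictor <- function(preset_id, model, feature_names) {
  function(newdata) {
    nd <- as.data.frame(newdata)[, feature_names, drop = FALSE]
    nm <- as.matrix(nd)
    out <- switch(preset_id,
      lr_linear = , lr_robust = predict(model, nd),
      # interaction designs may be rank-deficient on correlated features
      lr_interactions = suppressWarnings(predict(model, nd)),
      tree_fine = , tree_medium = , tree_coarse = predict(model, nd),
      svm_linear = , svm_quadratic = , svm_cubic = , svm_fine_gauss = ,
      svm_med_gauss = , svm_coarse_gauss = predict(model, nm),
      ens_boosted = predict(model, nm),
      ens_bagged = predict(model, nm),
      predict(model, nm)
    )
    as.numeric(out)
  }
}
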