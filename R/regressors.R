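# The five regression model families. Ridge/Lasso/ElasticNet are glmnet fits
# with a small inner cross-validated lambda grid chosen on the training fold
# only; SVR is a smoothed epsilon-insensitive kernel regression fitted by
# L-BFGS on the primal; AdaBoost is the classic AdaBoost.R2 scheme over
# shallow CART trees. Each fitter returns a closure-based model with a
# predict() method so the LOO driver can treat them uniformly.

sn_model_names <- c("ridge", "lasso", "elasticnet", "svr", "adaboost")

fit_glmnet_model <- function(X, y, alpha, lambda = NULL, seed = 1) {
  n <- nrow(X)
  padded <- ncol(X) < 2        # glmnet requires >= 2 predictor columns
  if (padded) X <- cbind(X, `.pad` = 0)
  if (is.null(lambda)) {
    nfolds <- min(5, n)
    foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
    cv <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                            standardize = TRUE)
    lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lambda, standardize = TRUE)
  structure(list(fit = fit, lambda = lambda, padded = padded),
            class = "sn_glmnet_model")
}

#' @export
predict.sn_glmnet_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (isTRUE(object$padded)) newdata <- cbind(newdata, `.pad` = 0)
  drop(stats::predict(object$fit, newx = newdata, s = object$lambda))
}

# Smoothed epsilon-insensitive loss: 0 inside the tube, quadratic over a
# transition of width delta, then linear. Keeps the primal differentiable so
# L-BFGS converges reliably on these small problems.
.svr_loss <- function(r, epsilon, delta) {
  a <- abs(r) - epsilon
  ifelse(a <= 0, 0, ifelse(a <= delta, a^2 / (2 * delta), a - delta / 2))
}
.svr_dloss <- function(r, epsilon, delta) {
  a <- abs(r) - epsilon
  sign(r) * ifelse(a <= 0, 0, ifelse(a <= delta, a / delta, 1))
}

fit_svr_model <- function(X, y, kernel = "rbf", cost = 10, epsilon = 0.1,
                          gamma = NULL, delta = 0.01) {
  X <- as.matrix(X)
  xc <- colMeans(X)
  xs <- pmax(apply(X, 2, stats::sd), 1e-12)
  Z <- sweep(sweep(X, 2, xc), 2, xs, "/")
  yc <- mean(y)
  ys <- max(stats::sd(y), 1e-12)
  yz <- (y - yc) / ys
  n <- nrow(Z)
  gamma <- gamma %||% (1 / ncol(Z))
  kfun <- if (kernel == "linear") {
    function(A, B) A %*% t(B)
  } else {
    function(A, B) {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      exp(-gamma * pmax(d2, 0))
    }
  }
  K <- kfun(Z, Z)
  obj <- function(par) {
    a <- par[seq_len(n)]; b <- par[n + 1]
    r <- yz - drop(K %*% a) - b
    cost * sum(.svr_loss(r, epsilon, delta)) + 0.5 * drop(a %*% K %*% a)
  }
  grad <- function(par) {
    a <- par[seq_len(n)]; b <- par[n + 1]
    r <- yz - drop(K %*% a) - b
    psi <- .svr_dloss(r, epsilon, delta)
    c(-cost * drop(K %*% psi) + drop(K %*% a), -cost * sum(psi))
  }
  opt <- stats::optim(rep(0, n + 1), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 200))
  structure(list(alpha = opt$par[seq_len(n)], b = opt$par[n + 1], Z = Z,
                 kfun = kfun, xc = xc, xs = xs, yc = yc, ys = ys),
            class = "sn_svr_model")
}

#' @export
predict.sn_svr_model <- function(object, newdata, ...) {
  Zn <- sweep(sweep(as.matrix(newdata), 2, object$xc), 2, object$xs, "/")
  drop(object$kfun(Zn, object$Z) %*% object$alpha + object$b) * object$ys + object$yc
}

weighted_median <- function(x, w) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  x[ord][which(cw >= 0.5)[1]]
}

# AdaBoost.R2 (linear loss) over shallow least-squares CART trees.
fit_adaboost_model <- function(X, y, n_estimators = 50, maxdepth = 3,
                               minsplit = 5, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list()
  betas <- numeric(0)
  with_seed(seed, {
    for (m in seq_len(n_estimators)) {
      rows <- sample.int(n, replace = TRUE, prob = w)
      tree <- grow_tree(X[rows, , drop = FALSE], y[rows], maxdepth, minsplit)
      pred <- predict_tree(tree, X)
      err <- abs(pred - y)
      emax <- max(err)
      if (emax <= 0) {
        trees[[length(trees) + 1]] <- tree
        betas <- c(betas, 1e-10)
        break
      }
      e <- err / emax
      ebar <- sum(w * e)
      if (ebar >= 0.5) break
      beta <- ebar / (1 - ebar)
      trees[[length(trees) + 1]] <- tree
      betas <- c(betas, beta)
      w <- w * beta^(1 - e)
      w <- w / sum(w)
    }
  })
  if (length(trees) == 0) {
    # no learner beat weighted-median chance: fall back to the mean predictor
    trees <- list(list(value = mean(y), n = n))
    betas <- 1
  }
  structure(list(trees = trees, log_inv_beta = log(1 / betas)),
            class = "sn_adaboost_model")
}

#' @export
predict.sn_adaboost_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  P <- vapply(object$trees, function(tr) predict_tree(tr, newdata),
              numeric(nrow(newdata)))
  if (is.null(dim(P))) P <- matrix(P, nrow = nrow(newdata))
  apply(P, 1, weighted_median, w = object$log_inv_beta + 1e-12)
}

# Uniform entry point used by the LOO driver.
fit_regressor <- function(model, X, y, seed = 1, hyper = list()) {
  X <- as.matrix(X)
  switch(model,
    ridge = fit_glmnet_model(X, y, alpha = 0, lambda = hyper$lambda, seed = seed),
    lasso = fit_glmnet_model(X, y, alpha = 1, lambda = hyper$lambda, seed = seed),
    elasticnet = fit_glmnet_model(X, y, alpha = hyper$alpha %||% 0.5,
                                  lambda = hyper$lambda, seed = seed),
    svr = fit_svr_model(X, y, kernel = hyper$kernel %||% "rbf",
                        cost = hyper$cost %||% 10,
                        epsilon = hyper$epsilon %||% 0.1,
                        gamma = hyper$gamma),
    adaboost = fit_adaboost_model(X, y,
                                  n_estimators = hyper$n_estimators %||% 50,
                                  maxdepth = hyper$maxdepth %||% 3,
                                  seed = seed),
    sn_stop(sprintf("unknown model '%s' (choose from %s)", model,
                    paste(sn_model_names, collapse = ", ")),
            "invalid_parameter"))
}
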