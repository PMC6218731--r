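test_that("MLR recovers exact linear relationships and constants", {
  set.seed(4)
  X <- cbind(area = runif(30), cresttime = runif(30), width_25 = runif(30))
  y <- 100 + 10 * X[, 1] - 20 * X[, 2] + 5 * X[, 3]
  m <- fit_mlr(X, y)
  expect_equal(unname(m$coefficients), c(100, 10, -20, 5), tolerance = 1e-8)
  m0 <- fit_mlr(X, rep(77, 30))
  expect_equal(unname(m0$coefficients), c(77, 0, 0, 0), tolerance = 1e-8)
  expect_equal(mean(y - predict(m, X)), 0, tolerance = 1e-9)
})

test_that("MLR equals the explicit normal-equations oracle", {
  set.seed(50)
  X <- matrix(rnorm(150), ncol = 3)
  colnames(X) <- c("a", "b", "c")
  y <- rnorm(50, 100, 15)
  m <- fit_mlr(X, y)
  Z <- cbind(1, X)
  theta <- solve(t(Z) %*% Z, t(Z) %*% y)
  expect_equal(unname(m$coefficients), unname(drop(theta)), tolerance = 1e-9)
})

test_that("MLR detects singular designs and shifts with the response", {
  set.seed(6)
  x <- rnorm(20)
  X <- cbind(a = x, b = 2 * x)
  expect_error(fit_mlr(X, rnorm(20)), "singular")
  X2 <- cbind(a = x, b = rnorm(20))
  y <- rnorm(20, 120, 10)
  m1 <- fit_mlr(X2, y)
  m2 <- fit_mlr(X2, y + 50)
  expect_equal(m2$coefficients[["(Intercept)"]],
               m1$coefficients[["(Intercept)"]] + 50, tolerance = 1e-9)
  expect_equal(m2$coefficients[-1], m1$coefficients[-1], tolerance = 1e-9)
})

test_that("MLR prediction applies the linear form", {
  m <- structure(list(coefficients = c(100, 10, -20, 5),
                      feature_names = NULL),
                 class = "bp_mlr")
  expect_equal(predict(m, matrix(c(0.5, 0.2, 0.7), nrow = 1)), 104.5)
})

test_that("SVR fits a noiseless line within the epsilon tube", {
  set.seed(10)
  x <- matrix(seq(-2, 2, length.out = 24), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- 3 * drop(x) + 2
  m <- fit_svr(x, y, epsilon = 0.1, C = 1000, gap_tol = 1e-4)
  expect_lt(abs(m$weights[["f"]] - 3), 0.05)
  expect_true(all(abs(y - predict(m, x)) <= 0.1 + 1e-6))
  expect_lt(m$gap, 1e-4)
})

test_that("SVR on a constant response returns zero weights", {
  set.seed(11)
  x <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_svr(x, rep(60, 10), epsilon = 2, C = 1)
  expect_equal(unname(m$weights), c(0, 0), tolerance = 1e-9)
  expect_lt(abs(m$bias - 60), 2 + 1e-9)
})

test_that("SVR matches the exact tiny-QP oracle", {
  set.seed(12)
  for (rep_i in 1:4) {
    X <- matrix(round(rnorm(6), 2), ncol = 1)
    X <- scale(X)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    colnames(X) <- "f"
    y <- round(2 * drop(X) + rnorm(6, 0, 1), 2)
    eps <- 0.5
    Cc <- 2
    oracle <- svr_exact_tiny(X, y, eps, Cc)
    m <- fit_svr(X, y, epsilon = eps, C = Cc, gap_tol = 1e-7)
    # the optimum is unique in (w, b) direction of the prediction function
    pred_o <- drop(X %*% oracle$w) + oracle$b
    expect_equal(unname(predict(m, X)), pred_o, tolerance = 5e-3)
    # dual coefficients respect the box and KKT sign structure
    expect_true(all(abs(m$dual_coefficients) <= Cc + 1e-8))
  }
})

test_that("duplicated training rows leave the SVR prediction unchanged", {
  X <- matrix(c(-1.5, -0.5, 0.5, 1.5), ncol = 1, dimnames = list(NULL, "f"))
  y <- 2 * drop(X) + 1
  m1 <- fit_svr(X, y, epsilon = 0.2, C = 50, gap_tol = 1e-6)
  m2 <- fit_svr(rbind(X, X), c(y, y), epsilon = 0.2, C = 50, gap_tol = 1e-6)
  grid <- matrix(seq(-2, 2, 0.5), ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(predict(m1, grid), predict(m2, grid), tolerance = 0.02)
})

test_that("SVR agrees with an independent implementation on small data", {
  skip_if_not_installed("e1071")
  set.seed(14)
  X <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- 5 * X[, 1] - 3 * X[, 2] + 100 + rnorm(30, 0, 0.5)
  m <- fit_svr(X, y, epsilon = 1, C = 10, gap_tol = 1e-6)
  ref <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                    cost = 10, epsilon = 1, scale = FALSE, tolerance = 1e-6)
  expect_equal(unname(predict(m, X)), unname(predict(ref, X)),
               tolerance = 0.05)
})

test_that("SVR stores the feasibility gap and validates its inputs", {
  x <- matrix(1:10, ncol = 1, dimnames = list(NULL, "f"))
  y <- as.numeric(1:10)
  expect_error(fit_svr(x, y, epsilon = -1), "epsilon")
  expect_error(fit_svr(x, y, C = 0), "C > 0")
  m <- fit_svr(x, y)
  expect_lt(m$gap, m$gap_tol)
  expect_true(is.finite(m$primal) && is.finite(m$dual_neg))
})

test_that("tree on a pure response is a single leaf", {
  set.seed(16)
  X <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_tree(X, rep(60, 20), min_leaf = 1)
  expect_identical(nrow(m$nodes), 1L)
  expect_equal(predict(m, X), rep(60, 20))
})

test_that("tree splits a step function perfectly at depth 1", {
  x <- matrix(seq(-1, 1, length.out = 20), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- ifelse(drop(x) < 0, 0, 10)
  m <- fit_tree(x, y, min_leaf = 1)
  expect_identical(nrow(m$nodes), 3L)
  expect_equal(predict(m, x), y)
})

test_that("tree splits match exhaustive enumeration at small n", {
  set.seed(18)
  X <- matrix(round(rnorm(60), 2), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- round(rnorm(20, 100, 15), 1)
  min_leaf <- 3
  m <- fit_tree(X, y, max_depth = 2, min_leaf = min_leaf, purity_tol = 0)
  root <- m$nodes[1, ]
  oracle_root <- best_split_brute(X, y, min_leaf)
  expect_identical(root$feature, oracle_root$feature)
  expect_equal(root$threshold, oracle_root$threshold, tolerance = 1e-12)
  # children chosen greedily on their own subsets
  left_rows <- X[, root$feature] <= root$threshold
  for (side in c("left", "right")) {
    child <- m$nodes[root[[side]], ]
    rows <- if (side == "left") left_rows else !left_rows
    oc <- best_split_brute(X[rows, , drop = FALSE], y[rows], min_leaf)
    if (is.na(child$feature)) {
      # implementation declared a leaf: the oracle must agree no admissible
      # split exists (or the node is too small to split)
      expect_true(is.null(oc) || sum(rows) < 2 * min_leaf)
    } else {
      expect_identical(child$feature, oc$feature)
      expect_equal(child$threshold, oc$threshold, tolerance = 1e-12)
    }
  }
})

test_that("leaf predictions are exact training means and respect min_leaf", {
  set.seed(20)
  X <- matrix(rnorm(100), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(50, 100, 10)
  m <- fit_tree(X, y, max_depth = 4, min_leaf = 5)
  leaves <- m$nodes[is.na(m$nodes$feature), ]
  expect_true(all(leaves$n >= 5))
  # route training rows and compare each leaf mean
  pred <- predict(m, X)
  for (v in unique(pred)) {
    expect_equal(v, mean(y[pred == v]), tolerance = 1e-12)
  }
})

test_that("training error is nonincreasing in tree depth", {
  set.seed(22)
  X <- matrix(rnorm(150), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 100 + 20 * X[, 1] + rnorm(50, 0, 5)
  mse <- vapply(1:6, function(d) {
    m <- fit_tree(X, y, max_depth = d, min_leaf = 2)
    mean((y - predict(m, X))^2)
  }, numeric(1))
  expect_true(all(diff(mse) <= 1e-9))
})

test_that("fitted models predict finite values on their training data", {
  set.seed(24)
  X <- matrix(runif(90), ncol = 3,
              dimnames = list(NULL, c("area", "rising_time", "width_25")))
  y <- rnorm(30, 110, 12)
  for (m in list(fit_mlr(X, y), fit_svr(X, y), fit_tree(X, y, min_leaf = 2)))
    expect_true(all(is.finite(predict(m, X))))
})

test_that("models survive a plain-text save/load round trip", {
  dir <- withr::local_tempdir()
  set.seed(26)
  X <- matrix(runif(60), ncol = 3,
              dimnames = list(NULL, c("area", "rising_time", "width_25")))
  y <- rnorm(20, 110, 12)
  grid <- matrix(runif(15), ncol = 3,
                 dimnames = list(NULL, c("area", "rising_time", "width_25")))
  for (m in list(fit_mlr(X, y), fit_svr(X, y), fit_tree(X, y, min_leaf = 2))) {
    path <- file.path(dir, paste0(class(m)[1], ".json"))
    write_model(m, path)
    back <- read_model(path)
    expect_identical(class(back), class(m))
    expect_equal(predict(back, grid), predict(m, grid), tolerance = 1e-10)
  }
})

test_that("prediction rejects mismatched feature schemas", {
  set.seed(28)
  X <- matrix(runif(60), ncol = 3,
              dimnames = list(NULL, c("area", "rising_time", "width_25")))
  m <- fit_mlr(X, rnorm(20, 110, 10))
  bad <- matrix(runif(6), ncol = 2, dimnames = list(NULL, c("area", "x")))
  expect_error(predict(m, bad), "lacks feature")
})
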