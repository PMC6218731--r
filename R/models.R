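#' Fit a multiple linear regression BP estimator
#'
#' Ordinary least squares of the reference pressure on the selected
#' morphology features (with intercept), solved in closed form by QR
#' decomposition — the unique minimizer of the squared training error.
#'
#' @param x Numeric matrix or data.frame of features (rows = segments).
#' @param y Numeric vector of reference pressures (mmHg).
#' @return An object of class `bp_mlr` with fields `coefficients`
#'   (intercept first), `feature_names`, `residual_sd` (mmHg).
#' @export
fit_mlr <- function(x, y) {
  x <- as.matrix(x)
  check_training(x, y, min_rows = ncol(x) + 1L)
  X <- cbind("(Intercept)" = 1, x)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X))
    stop("singular design: features are linearly dependent", call. = FALSE)
  coefs <- fit$coefficients
  structure(list(coefficients = coefs,
                 feature_names = colnames(x),
                 residual_sd = stats::sd(fit$residuals)),
            class = "bp_mlr")
}

#' @export
predict.bp_mlr <- function(object, newdata, ...) {
  X <- model_matrix_for(object$feature_names, newdata)
  drop(cbind(1, X) %*% object$coefficients)
}

#' Fit a linear epsilon-insensitive support vector regressor
#'
#' Linear-kernel \eqn{\varepsilon}-SVR (L1 loss): residuals inside the
#' \eqn{\varepsilon}-tube are free, residuals outside are penalized linearly
#' with box constraint `C`.  The dual is solved by an SMO-style
#' maximal-violating-pair method; convergence is declared only when the
#' normalized primal-dual feasibility gap
#' \deqn{\Delta = (J(\beta) + L(\alpha)) / (J(\beta) + 1)}
#' (primal objective `J`, negated dual objective `L`) falls below `gap_tol`.
#' Features are standardized to zero mean / unit variance inside the fit so
#' that `C` is comparable across features; \eqn{\varepsilon} stays on the
#' mmHg scale of the response.
#'
#' @inheritParams fit_mlr
#' @param epsilon Tube half-width in mmHg (default 2).
#' @param C Box constraint on the dual coefficients (default 1).
#' @param gap_tol Feasibility-gap tolerance (default 1e-3).
#' @param max_iter Maximum number of pair updates.
#' @return An object of class `bp_svr` with the weights and bias on the
#'   original feature scale, the dual coefficients, the primal and (negated)
#'   dual objectives, and the final feasibility gap `gap`.
#' @export
fit_svr <- function(x, y, epsilon = 2, C = 1, gap_tol = 1e-3,
                    max_iter = 200000L) {
  x <- as.matrix(x)
  check_training(x, y, min_rows = 2L)
  if (epsilon < 0 || C <= 0 || gap_tol <= 0)
    stop("need epsilon >= 0, C > 0, gap_tol > 0", call. = FALSE)

  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  sol <- smo_svr(Xs, y, epsilon = epsilon, C = C, gap_tol = gap_tol,
                 max_iter = max_iter)
  if (sol$gap >= gap_tol)
    stop(sprintf(
      "SVR did not converge: feasibility gap %.3g >= tolerance %.3g after %d iterations",
      sol$gap, gap_tol, sol$iter), call. = FALSE)

  w_orig <- sol$w / scale_
  b_orig <- sol$b - sum(sol$w * center / scale_)
  structure(list(weights = stats::setNames(w_orig, colnames(x)),
                 bias = b_orig,
                 weights_std = sol$w, bias_std = sol$b,
                 center = center, scale = scale_,
                 dual_coefficients = sol$beta,
                 epsilon = epsilon, C = C, gap_tol = gap_tol,
                 primal = sol$primal, dual_neg = sol$dual_neg,
                 gap = sol$gap, iterations = sol$iter,
                 feature_names = colnames(x)),
            class = "bp_svr")
}

#' @export
predict.bp_svr <- function(object, newdata, ...) {
  X <- model_matrix_for(object$feature_names, newdata)
  drop(X %*% object$weights + object$bias)
}

# SMO (maximal violating pair) on the epsilon-SVR dual in beta = alpha - alpha*:
#   min D(beta) = 1/2 beta' K beta - y' beta + eps ||beta||_1
#   s.t. sum(beta) = 0, -C <= beta_i <= C      (K = X X', linear kernel)
# w = X' beta is maintained incrementally; the bias b is recovered as the
# minimizer of the primal slack term, so the reported primal J is valid at
# every iteration.
smo_svr <- function(X, y, epsilon, C, gap_tol, max_iter) {
  n <- nrow(X)
  beta <- numeric(n)
  w <- numeric(ncol(X))
  f <- numeric(n)
  xx <- rowSums(X^2)                  # kernel diagonal
  iter <- 0L
  check_every <- max(64L, n %/% 2L)
  stuck <- FALSE
  repeat {
    conv <- convergence_state(y, f, w, beta, epsilon, C)
    if (conv$gap < gap_tol || iter >= max_iter || stuck)
      return(list(beta = beta, w = w, b = conv$b, primal = conv$primal,
                  dual_neg = conv$dual_neg, gap = conv$gap, iter = iter))
    for (step in seq_len(check_every)) {
      # one-sided derivatives of the dual along +e_i and -e_i
      u <- f - y + ifelse(beta >= 0, epsilon, -epsilon)
      v <- y - f + ifelse(beta <= 0, epsilon, -epsilon)
      iu <- which(beta < C)
      iv <- which(beta > -C)
      if (-(min(u[iu]) + min(v[iv])) <= 1e-12) { stuck <- TRUE; break }
      # try the top-ranked violating pairs: the single most violating pair
      # can be numerically blocked (e.g. duplicated rows) while another
      # still admits a strict improvement
      is <- iu[order(u[iu])[seq_len(min(4L, length(iu)))]]
      js <- iv[order(v[iv])[seq_len(min(4L, length(iv)))]]
      t_star <- 0
      for (i in is) {
        for (j in js) {
          if (i == j || -(u[i] + v[j]) <= 1e-12) next
          t_star <- solve_pair(beta[i], beta[j], f[i], f[j], y[i], y[j],
                               eta = xx[i] + xx[j] - 2 * sum(X[i, ] * X[j, ]),
                               epsilon = epsilon, C = C)
          if (t_star != 0) break
        }
        if (t_star != 0) break
      }
      if (t_star == 0) { stuck <- TRUE; break }   # numerically blocked
      beta[i] <- beta[i] + t_star
      beta[j] <- beta[j] - t_star
      dw <- t_star * (X[i, ] - X[j, ])
      w <- w + dw
      f <- f + drop(X %*% dw)
      iter <- iter + 1L
      if (iter >= max_iter) break
    }
  }
}

# exact minimization of the pair subproblem along e_i - e_j:
# phi(t) = 1/2 eta t^2 + g t + eps(|bi + t| + |bj - t|), t in the box
solve_pair <- function(bi, bj, fi, fj, yi, yj, eta, epsilon, C) {
  g <- fi - fj - yi + yj
  lo <- max(-C - bi, bj - C)
  hi <- min(C - bi, bj + C)
  if (lo >= hi) return(0)
  cand <- c(lo, hi)
  br <- c(-bi, bj)
  cand <- c(cand, br[br > lo & br < hi])
  if (eta > 1e-14) {
    for (si in c(-1, 1)) for (sj in c(-1, 1)) {
      t0 <- -(g + epsilon * (si - sj)) / eta
      # keep t0 only if it lies in the sign-region it was derived for
      if (sign0(bi + t0) * si >= 0 && sign0(bj - t0) * sj >= 0 &&
          t0 > lo && t0 < hi)
        cand <- c(cand, t0)
    }
  }
  phi <- function(t) 0.5 * eta * t^2 + g * t +
    epsilon * (abs(bi + t) + abs(bj - t))
  vals <- vapply(cand, phi, numeric(1))
  t_best <- cand[which.min(vals)]
  if (phi(t_best) < phi(0) - 1e-15) t_best else 0
}

sign0 <- function(x) if (x > 0) 1 else if (x < 0) -1 else 0

# primal objective at the exactly-optimal bias given w, plus the negated dual
# objective, and the normalized feasibility gap between them.  The slack term
# sum(max(|r - b| - eps, 0)) is piecewise linear in b with knots r -/+ eps;
# its subderivative at b is #(r + eps < b) - #(r - eps > b), so the optimum is
# the first knot where the subderivative turns non-negative.
convergence_state <- function(y, f, w, beta, epsilon, C) {
  r <- y - f
  knots <- sort(c(r - epsilon, r + epsilon))
  deriv <- vapply(knots, function(b) sum(r + epsilon < b) - sum(r - epsilon > b),
                  numeric(1))
  b <- knots[which(deriv >= 0)[1L]]
  primal <- 0.5 * sum(w^2) + C * sum(pmax(abs(r - b) - epsilon, 0))
  dual_value <- sum(y * beta) - 0.5 * sum(w^2) - epsilon * sum(abs(beta))
  dual_neg <- -dual_value
  gap <- (primal + dual_neg) / (primal + 1)
  list(b = b, primal = primal, dual_neg = dual_neg, gap = gap)
}

#' Fit a CART regression tree BP estimator
#'
#' Binary regression tree grown by greedy recursive partitioning: every
#' (feature, midpoint-between-adjacent-sorted-values) candidate split is
#' scored by the weighted sum of child response mean squared errors, and the
#' best split is taken (ties towards the lowest feature index, then the
#' smallest threshold).  A node is declared pure — and not split — when its
#' response MSE falls below the whole-sample MSE times `purity_tol`; growth
#' is further limited by `max_depth` and a minimum leaf size `min_leaf`.
#' Each leaf predicts the arithmetic mean of its training responses.
#'
#' @inheritParams fit_mlr
#' @param max_depth Maximum tree depth (root = depth 0; default 12).
#' @param min_leaf Minimum number of training rows per leaf (default 5).
#' @param purity_tol Pure-node tolerance relative to the root MSE
#'   (default 1e-4).
#' @return An object of class `bp_tree`: list with `nodes` (a data.frame of
#'   the tree structure), `feature_names`, and the hyperparameters.
#' @export
fit_tree <- function(x, y, max_depth = 12, min_leaf = 5, purity_tol = 1e-4) {
  x <- as.matrix(x)
  check_training(x, y, min_rows = 2 * min_leaf)
  root_mse <- mean((y - mean(y))^2)
  pure_level <- root_mse * purity_tol

  nodes <- new.env()
  nodes$df <- data.frame(id = integer(0), depth = integer(0),
                         feature = integer(0), threshold = numeric(0),
                         left = integer(0), right = integer(0),
                         prediction = numeric(0), n = integer(0))
  add_node <- function(rows, depth) {
    id <- nrow(nodes$df) + 1L
    yy <- y[rows]
    node <- data.frame(id = id, depth = depth, feature = NA_integer_,
                       threshold = NA_real_, left = NA_integer_,
                       right = NA_integer_, prediction = mean(yy),
                       n = length(rows))
    nodes$df <- rbind(nodes$df, node)
    mse <- mean((yy - mean(yy))^2)
    pure <- if (root_mse > 0) mse < pure_level else mse <= 0
    if (pure || depth >= max_depth || length(rows) < 2 * min_leaf)
      return(id)
    sp <- best_split(x[rows, , drop = FALSE], yy, min_leaf)
    if (is.null(sp)) return(id)
    go_left <- x[rows, sp$feature] <= sp$threshold
    left_id <- add_node(rows[go_left], depth + 1L)
    right_id <- add_node(rows[!go_left], depth + 1L)
    nodes$df[id, c("feature", "threshold", "left", "right")] <-
      list(sp$feature, sp$threshold, left_id, right_id)
    id
  }
  add_node(seq_along(y), 0L)
  structure(list(nodes = nodes$df, feature_names = colnames(x),
                 max_depth = max_depth, min_leaf = min_leaf,
                 purity_tol = purity_tol, root_mse = root_mse),
            class = "bp_tree")
}

# best (feature, midpoint threshold) by weighted child SSE, computed from
# cumulative sums over each feature's sort order; ties -> lowest feature
# index, then smallest threshold
best_split <- function(x, y, min_leaf) {
  n <- length(y)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j], y)              # y as tie key for determinism
    xs <- x[ord, j]
    ys <- y[ord]
    csum <- cumsum(ys)
    csq <- cumsum(ys^2)
    total_sum <- csum[n]
    total_sq <- csq[n]
    k <- seq_len(n - 1L)
    valid <- xs[k] < xs[k + 1L] & k >= min_leaf & (n - k) >= min_leaf
    if (!any(valid)) next
    k <- k[valid]
    sse <- (csq[k] - csum[k]^2 / k) +
      ((total_sq - csq[k]) - (total_sum - csum[k])^2 / (n - k))
    kb <- k[which.min(sse)]           # first minimum -> smallest threshold
    cand_sse <- sse[which.min(sse)]
    thr <- (xs[kb] + xs[kb + 1L]) / 2
    # strict improvement only, so the lowest feature index wins ties
    if (is.null(best) || cand_sse < best$sse - 1e-12)
      best <- list(feature = j, threshold = thr, sse = cand_sse)
  }
  best
}

#' @export
predict.bp_tree <- function(object, newdata, ...) {
  X <- model_matrix_for(object$feature_names, newdata)
  nd <- object$nodes
  vapply(seq_len(nrow(X)), function(i) {
    id <- 1L
    repeat {
      row <- nd[id, ]
      if (is.na(row$feature)) return(row$prediction)
      # values at or above the threshold go right; thresholds are midpoints
      # between training values, so equality can only arise on unseen data
      id <- if (X[i, row$feature] >= row$threshold) row$right else row$left
    }
  }, numeric(1))
}

#' @export
print.bp_mlr <- function(x, ...) {
  cat("<bp_mlr> coefficients (mmHg):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
print.bp_svr <- function(x, ...) {
  cat(sprintf("<bp_svr> epsilon=%g C=%g gap=%.2e (tol %.1e), %d iterations\n",
              x$epsilon, x$C, x$gap, x$gap_tol, x$iterations))
  cat("  weights:", paste(sprintf("%s=%.4g", names(x$weights), x$weights),
                          collapse = ", "),
      sprintf(" bias=%.4g\n", x$bias))
  invisible(x)
}

#' @export
print.bp_tree <- function(x, ...) {
  n_leaf <- sum(is.na(x$nodes$feature))
  cat(sprintf("<bp_tree> %d nodes (%d leaves), depth <= %d, min_leaf %d\n",
              nrow(x$nodes), n_leaf, x$max_depth, x$min_leaf))
  invisible(x)
}

#' Save / load a fitted model as versioned plain text (JSON)
#'
#' @param model A `bp_mlr`, `bp_svr` or `bp_tree`.
#' @param path File path.
#' @return `read_model` returns the model object.
#' @export
write_model <- function(model, path) {
  kind <- class(model)[1]
  payload <- unclass(model)
  payload$nodes <- if (!is.null(payload$nodes)) payload$nodes else NULL
  obj <- list(format = "ppgbp-model", version = 1L, kind = kind,
              payload = payload)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ppgbp-model"))
    stop("not a ppgbp model file: ", path, call. = FALSE)
  payload <- obj$payload
  if (!is.null(payload$nodes)) payload$nodes <- as.data.frame(payload$nodes)
  for (nm in c("coefficients", "weights", "center", "scale"))
    if (!is.null(payload[[nm]]))
      payload[[nm]] <- unlist(payload[[nm]])
  structure(payload, class = obj$kind)
}

# ---- shared helpers ---------------------------------------------------------

check_training <- function(x, y, min_rows = 10L) {
  if (!is.numeric(y) || nrow(x) != length(y))
    stop("x and y sizes disagree", call. = FALSE)
  if (nrow(x) < min_rows)
    stop("need at least ", min_rows, " training rows", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("training data must be finite (no missing values)", call. = FALSE)
  invisible(TRUE)
}

model_matrix_for <- function(feature_names, newdata) {
  X <- as.matrix(newdata)
  if (!is.null(feature_names)) {
    if (!is.null(colnames(X))) {
      missing_cols <- setdiff(feature_names, colnames(X))
      if (length(missing_cols))
        stop("newdata lacks feature column(s): ",
             paste(missing_cols, collapse = ", "), call. = FALSE)
      X <- X[, feature_names, drop = FALSE]
    } else if (ncol(X) != length(feature_names)) {
      stop("newdata has ", ncol(X), " columns; model expects ",
           length(feature_names), call. = FALSE)
    }
  }
  X
}
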