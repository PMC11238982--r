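#' Regression random forest (bagged CART)
#'
#' A compact regression forest used by the two-stage variable selection:
#' bootstrap-aggregated variance-reduction trees with per-node feature
#' subsampling (mtry), out-of-bag error, and permutation importance. It is
#' deliberately minimal — enough machinery to rank predictors and compare
#' nested predictor sets by OOB error, which is all the selection procedure
#' needs.
#'
#' @param X numeric matrix or data.frame of predictors.
#' @param y numeric response.
#' @param n_trees number of trees (default 100).
#' @param mtry features tried per split; default max(1, floor(p / 3)).
#' @param min_node minimum node size to attempt a split (default 5).
#' @param seed integer seed.
#' @return object of class \code{rf_fit}: trees, OOB predictions and error.
#' @export
rf_fit <- function(X, y, n_trees = 100, mtry = NULL, min_node = 5,
                   seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n == length(y), p >= 1)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  set.seed(seed)
  trees <- vector("list", n_trees)
  oob_sum <- numeric(n); oob_n <- integer(n)
  for (t in seq_len(n_trees)) {
    bag <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(bag))
    tr <- .grow_tree(X, y, bag, mtry, min_node)
    trees[[t]] <- list(tree = tr, oob = oob)
    if (length(oob)) {
      ph <- .predict_tree(tr, X[oob, , drop = FALSE])
      oob_sum[oob] <- oob_sum[oob] + ph
      oob_n[oob] <- oob_n[oob] + 1L
    }
  }
  seen <- oob_n > 0
  oob_pred <- ifelse(seen, oob_sum / pmax(1L, oob_n), NA_real_)
  sqerr <- (y - oob_pred)^2
  structure(list(trees = trees, n = n, p = p, mtry = mtry,
                 var_names = colnames(X),
                 oob_pred = oob_pred,
                 oob_mse = mean(sqerr[seen]),
                 oob_se = stats::sd(sqerr[seen]) / sqrt(sum(seen))),
            class = "rf_fit")
}

# grow one tree; nodes as parallel vectors, children grown breadth-first
.grow_tree <- function(X, y, idx, mtry, min_node) {
  var <- integer(); split <- numeric(); left <- integer(); right <- integer()
  pred <- numeric()
  queue <- list(idx)
  node_of <- integer()          # queue bookkeeping
  add_node <- function() {
    var[length(var) + 1L] <<- NA_integer_
    split[length(split) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L; right[length(right) + 1L] <<- 0L
    pred[length(pred) + 1L] <<- NA_real_
    length(var)
  }
  node_of[1L] <- add_node()
  qi <- 1L
  while (qi <= length(queue)) {
    rows <- queue[[qi]]; me <- node_of[qi]
    yv <- y[rows]
    pred[me] <- mean(yv)
    if (length(rows) >= 2L * min_node && stats::var(yv) > 0) {
      feats <- sample.int(ncol(X), min(mtry, ncol(X)))
      best <- .best_split(X, yv, rows, feats, min_node)
      if (!is.null(best)) {
        var[me] <- best$feat; split[me] <- best$cut
        lrows <- rows[X[rows, best$feat] <= best$cut]
        rrows <- rows[X[rows, best$feat] > best$cut]
        queue[[length(queue) + 1L]] <- lrows
        node_of[length(queue)] <- add_node(); left[me] <- node_of[length(queue)]
        queue[[length(queue) + 1L]] <- rrows
        node_of[length(queue)] <- add_node(); right[me] <- node_of[length(queue)]
      }
    }
    qi <- qi + 1L
  }
  list(var = var, split = split, left = left, right = right, pred = pred)
}

# best variance-reduction split over the sampled features
.best_split <- function(X, yv, rows, feats, min_node) {
  n <- length(rows)
  tot <- sum(yv)
  best <- NULL; best_gain <- 1e-12
  for (f in feats) {
    x <- X[rows, f]
    o <- order(x)
    xs <- x[o]; ys <- yv[o]
    cs <- cumsum(ys)
    k <- seq_len(n - 1L)
    valid <- xs[k] < xs[k + 1L] & k >= min_node & (n - k) >= min_node
    if (!any(valid)) next
    # SSE reduction = SS_total - (SS_left + SS_right); compare via the
    # between-group term only (SS_total constant for the node)
    gain <- cs[k]^2 / k + (tot - cs[k])^2 / (n - k)
    gain[!valid] <- -Inf
    j <- which.max(gain)
    g <- gain[j] - tot^2 / n
    if (g > best_gain) {
      best_gain <- g
      best <- list(feat = f, cut = (xs[j] + xs[j + 1L]) / 2)
    }
  }
  best
}

.predict_tree <- function(tr, X) {
  out <- numeric(nrow(X))
  stack <- list(list(node = 1L, rows = seq_len(nrow(X))))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    nd <- top$node; rows <- top$rows
    if (!length(rows)) next
    if (is.na(tr$var[nd])) {
      out[rows] <- tr$pred[nd]
    } else {
      go_l <- X[rows, tr$var[nd]] <= tr$split[nd]
      stack[[length(stack) + 1L]] <- list(node = tr$left[nd],
                                          rows = rows[go_l])
      stack[[length(stack) + 1L]] <- list(node = tr$right[nd],
                                          rows = rows[!go_l])
    }
  }
  out
}

#' Predict from a regression forest
#' @param object an \code{rf_fit}.
#' @param newdata matrix/data.frame of predictors.
#' @param ... unused.
#' @return numeric predictions (tree average).
#' @export
predict.rf_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  ph <- matrix(0, nrow(X), length(object$trees))
  for (t in seq_along(object$trees))
    ph[, t] <- .predict_tree(object$trees[[t]]$tree, X)
  rowMeans(ph)
}

#' Permutation importance of a fitted forest
#'
#' For each tree and each variable: the increase in OOB mean squared error
#' after permuting that variable among the tree's OOB rows, averaged over
#' trees.
#'
#' @param fit an \code{rf_fit}.
#' @param X,y the training data.
#' @param seed permutation seed.
#' @return numeric vector of importances, named by variable.
#' @export
rf_importance <- function(fit, X, y, seed = 1L) {
  X <- as.matrix(X)
  set.seed(seed)
  imp <- numeric(fit$p)
  for (t in seq_along(fit$trees)) {
    oob <- fit$trees[[t]]$oob
    if (length(oob) < 2) next
    tr <- fit$trees[[t]]$tree
    Xo <- X[oob, , drop = FALSE]
    base <- mean((y[oob] - .predict_tree(tr, Xo))^2)
    for (j in seq_len(fit$p)) {
      Xp <- Xo
      Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
      imp[j] <- imp[j] + mean((y[oob] - .predict_tree(tr, Xp))^2) - base
    }
  }
  stats::setNames(imp / length(fit$trees),
                  fit$var_names %||% paste0("V", seq_len(fit$p)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
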