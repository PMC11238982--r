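#' Two-stage random-forest variable selection
#'
#' Stage 1 ("thresholding"): permutation importance is averaged over
#' \code{n_runs} forests; variables whose mean importance falls below a
#' threshold derived from the importance variability of the lowest-ranked
#' variables (the mean importance SD over the bottom half of the ranking)
#' are discarded. Stage 2 ("interpretation"): forests are fitted on nested
#' predictor sets, adding survivors in rank order, and the selected set is
#' the smallest one whose OOB error is within one standard error of the
#' minimum.
#'
#' @param X data.frame/matrix of predictors (>= 2 columns).
#' @param y numeric response.
#' @param n_trees trees per forest (default 100).
#' @param n_runs forests averaged in stage 1 (default 5).
#' @param seed integer seed; all forests derive their seeds from it.
#' @return list of class \code{rf_selection}: \code{ranking} (data.frame
#'   variable/mean_importance/sd_importance), \code{threshold},
#'   \code{survivors}, \code{selected}, \code{oob} (nested-model OOB
#'   errors and SEs).
#' @export
rf_select <- function(X, y, n_trees = 100, n_runs = 5, seed = 1L) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p < 2) stop("rf_select needs at least 2 predictors")
  imp <- matrix(0, n_runs, p, dimnames = list(NULL, names(X)))
  for (r in seq_len(n_runs)) {
    f <- rf_fit(X, y, n_trees = n_trees, seed = seed + 1000L * r)
    imp[r, ] <- rf_importance(f, X, y, seed = seed + 1000L * r + 1L)
  }
  mi <- colMeans(imp)
  si <- apply(imp, 2, stats::sd)
  ord <- order(-mi)
  ranking <- data.frame(variable = names(X)[ord],
                        mean_importance = mi[ord],
                        sd_importance = si[ord],
                        stringsAsFactors = FALSE)
  bottom <- ranking$sd_importance[seq(ceiling(p / 2) + 1, p)]
  threshold <- mean(bottom)
  if (!is.finite(threshold)) threshold <- 0
  survivors <- ranking$variable[ranking$mean_importance >= threshold &
                                  ranking$mean_importance > 0]
  selected <- character()
  oob <- NULL
  if (length(survivors) >= 1) {
    oob <- data.frame(k = seq_along(survivors),
                      variables = vapply(seq_along(survivors), function(k)
                        paste(survivors[seq_len(k)], collapse = "+"), ""),
                      oob_mse = NA_real_, oob_se = NA_real_,
                      stringsAsFactors = FALSE)
    for (k in seq_along(survivors)) {
      Xi <- X[, survivors[seq_len(k)], drop = FALSE]
      # single-predictor forests still need mtry = 1
      f <- rf_fit(Xi, y, n_trees = n_trees, seed = seed + 77L * k)
      oob$oob_mse[k] <- f$oob_mse
      oob$oob_se[k] <- f$oob_se
    }
    kmin <- which.min(oob$oob_mse)
    cutoff <- oob$oob_mse[kmin] + oob$oob_se[kmin]
    ksel <- min(which(oob$oob_mse <= cutoff))
    selected <- survivors[seq_len(ksel)]
  }
  structure(list(ranking = ranking, threshold = threshold,
                 survivors = survivors, selected = selected, oob = oob),
            class = "rf_selection")
}

#' @export
print.rf_selection <- function(x, ...) {
  cat("rf_select:", length(x$selected), "of", nrow(x$ranking),
      "variables selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a generalized additive model with penalized-spline smooths
#'
#' One thin-plate smooth per predictor, smoothing parameters by REML;
#' reports BIC (using the effective degrees of freedom of the penalized
#' smooths) and adjusted R-squared. Richness responses default to a Poisson
#' family with log link; \code{"gaussian"} fits on the identity scale and
#' \code{"gaussian_logit"} logit-transforms a (0, 1) response before a
#' Gaussian fit (for proportions such as mean dissimilarity).
#'
#' @param y response vector (>= 30 observations).
#' @param X data.frame of standardized predictors.
#' @param family "poisson", "gaussian" or "gaussian_logit".
#' @param basis_size spline basis dimension per smooth (default 5).
#' @param linear_terms optional character vector naming columns of X to
#'   enter linearly instead of smoothed (used for the autocovariate).
#' @return object of class \code{gam_fit}: the mgcv fit plus response,
#'   fitted values, residuals (working scale), edf, bic, adj_r2, has_rac.
#' @export
fit_gam <- function(y, X, family = c("poisson", "gaussian",
                                     "gaussian_logit"),
                    basis_size = 5, linear_terms = character()) {
  family <- match.arg(family)
  X <- as.data.frame(X)
  if (length(y) < 30) stop("need at least 30 observations")
  # rank check: perfectly collinear predictor pairs break the additive fit
  cm <- suppressWarnings(stats::cor(as.matrix(X)))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  if (any(abs(cm) > 1 - 1e-10)) {
    bad <- which(abs(cm) > 1 - 1e-10, arr.ind = TRUE)[1, ]
    stop("collinear predictors: ", colnames(cm)[bad[1]], " and ",
         colnames(cm)[bad[2]])
  }
  yfit <- y
  if (family == "gaussian_logit") {
    eps <- 1e-4
    yfit <- stats::qlogis(pmin(1 - eps, pmax(eps, y)))
  }
  fam <- if (family == "poisson") stats::poisson() else stats::gaussian()
  smooth_vars <- setdiff(names(X), linear_terms)
  k_of <- vapply(smooth_vars, function(v)
    max(3L, min(as.integer(basis_size),
                length(unique(X[[v]])) - 1L)), 0L)
  terms <- c(sprintf("s(%s, k = %d)", smooth_vars, k_of), linear_terms)
  dat <- cbind(data.frame(.y = yfit), X)
  form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, family = fam, data = dat, method = "REML")
  sm <- summary(fit)
  structure(list(fit = fit, response = yfit, observed = y,
                 family = family, predictors = names(X),
                 linear_terms = linear_terms,
                 fitted = as.numeric(stats::fitted(fit)),
                 residuals = yfit - as.numeric(stats::fitted(fit)),
                 edf = sum(fit$edf),
                 bic = stats::BIC(fit),
                 adj_r2 = sm$r.sq,
                 has_rac = "rac" %in% linear_terms),
            class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("gam_fit (%s): %s ~ %s | BIC %.2f, adj-R2 %.3f%s\n",
              x$family, ".y", paste(x$predictors, collapse = " + "),
              x$bic, x$adj_r2, if (x$has_rac) " (+RAC)" else ""))
  invisible(x)
}

#' Residual autocovariate
#'
#' The neighborhood mean of model residuals: for each cell, the
#' row-standardized weighted mean of its neighbors' residuals (self
#' excluded). Cells with no neighbors get 0 with a warning. Adding this as a
#' predictor absorbs residual spatial autocorrelation.
#'
#' @param residuals numeric vector, one per weight id.
#' @param w a \code{cell_weights} built without self.
#' @return numeric RAC vector.
#' @export
residual_autocovariate <- function(residuals, w) {
  stopifnot(length(residuals) == length(w$ids))
  if (w$include_self) stop("RAC weights must exclude self")
  out <- vapply(seq_along(residuals), function(i) {
    j <- w$nb[[i]]
    if (!length(j)) return(NA_real_)
    wt <- w$w[[i]] / sum(w$w[[i]])
    sum(wt * residuals[j])
  }, 0)
  if (anyNA(out)) {
    warning(sum(is.na(out)), " cell(s) without neighbors: RAC set to 0")
    out[is.na(out)] <- 0
  }
  out
}

#' GAM with residual-autocovariate term
#'
#' Fits the base GAM, measures the spatial autocorrelation of its residuals
#' (Moran's I), computes the residual autocovariate, refits with the RAC as
#' an additional linear term, and measures Moran's I again. The pair of I
#' statistics documents whether the RAC absorbed the residual spatial
#' structure.
#'
#' @inheritParams fit_gam
#' @param w a \code{cell_weights} over the same cells as the rows of X
#'   (self excluded).
#' @param n_perm permutations for the Moran tests (default 199).
#' @param seed seed for the permutation tests.
#' @return list of class \code{gam_rac_fit}: \code{fit} (the RAC model,
#'   a \code{gam_fit}), \code{base_fit}, \code{rac},
#'   \code{moran_before}, \code{moran_after}.
#' @export
fit_gam_rac <- function(y, X, w, family = c("poisson", "gaussian",
                                            "gaussian_logit"),
                        basis_size = 5, n_perm = 199, seed = 1L) {
  family <- match.arg(family)
  base <- fit_gam(y, X, family = family, basis_size = basis_size)
  m0 <- morans_i(base$residuals, w, n_perm = n_perm, seed = seed)
  rac <- residual_autocovariate(base$residuals, w)
  X2 <- cbind(as.data.frame(X), rac = rac)
  fit2 <- fit_gam(y, X2, family = family, basis_size = basis_size,
                  linear_terms = "rac")
  m1 <- morans_i(fit2$residuals, w, n_perm = n_perm, seed = seed + 1L)
  structure(list(fit = fit2, base_fit = base, rac = rac,
                 moran_before = m0, moran_after = m1),
            class = "gam_rac_fit")
}

#' BIC model selection table
#'
#' Fits every candidate predictor set, computes \eqn{\Delta BIC = BIC_m -
#' BIC^*} against the minimum, flags the best model, and attaches the usual
#' verbal evidence categories (< 2 barely worth a mention; 2-6 positive;
#' 6-10 strong; > 10 very strong evidence against the candidate).
#'
#' @param candidates named list of character vectors (predictor sets), or a
#'   named numeric vector of precomputed BIC values.
#' @param fit_fun function(predictors) returning an object with a
#'   \code{$bic} element (ignored when \code{candidates} is numeric).
#' @return data.frame of class \code{model_table}: model, bic, delta_bic,
#'   evidence, best; plus a \code{fits} attribute when models were fitted.
#' @export
bic_select <- function(candidates, fit_fun = NULL) {
  if (is.numeric(candidates)) {
    bics <- candidates
    fits <- NULL
    labs <- names(candidates) %||% paste0("model_", seq_along(candidates))
  } else {
    stopifnot(is.function(fit_fun))
    fits <- lapply(candidates, fit_fun)
    bics <- vapply(fits, function(f) f$bic, 0)
    labs <- names(candidates) %||%
      vapply(candidates, paste, "", collapse = "+")
  }
  delta <- bics - min(bics)
  evid <- cut(delta, c(-Inf, 2, 6, 10, Inf),
              labels = c("<2: not worth more than a mention",
                         "2-6: positive", "6-10: strong",
                         ">10: very strong"), right = FALSE)
  out <- data.frame(model = labs, bic = as.numeric(bics),
                    delta_bic = as.numeric(delta),
                    evidence = as.character(evid),
                    best = delta == 0, stringsAsFactors = FALSE)
  if (sum(out$best) > 1) {               # deterministic single best on ties
    first <- which(out$best)[1]
    out$best <- FALSE; out$best[first] <- TRUE
  }
  attr(out, "fits") <- fits
  class(out) <- c("model_table", "data.frame")
  out
}

#' Predicted-vs-observed diagnostics
#'
#' Pearson correlation between fitted and observed values, plus the split of
#' residual signs: negative residuals (model over-predicts — candidate
#' knowledge shortfalls, places where fewer species were recorded than the
#' environment suggests) versus positive residuals (under-estimated cells).
#'
#' @param fit a \code{gam_fit}.
#' @return list: r, n_negative_residuals, n_positive_residuals, residuals.
#' @export
predicted_vs_observed <- function(fit) {
  r <- stats::cor(fit$fitted, fit$response)
  res <- fit$response - fit$fitted
  list(r = r,
       n_negative_residuals = sum(res < 0),
       n_positive_residuals = sum(res > 0),
       residuals = res)
}
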