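#' Build a site-pair table for dissimilarity modelling
#'
#' All unordered pairs of PAM cells with at least one species (optionally a
#' seeded random subsample of at most \code{max_pairs}), with the observed
#' Sorensen (or Simpson) dissimilarity and the predictor values at both
#' sites. Geographic great-circle distance between cell centers is carried
#' as an extra column but is not a fitted predictor by default.
#'
#' @param pam a \code{pam}.
#' @param env_table per-cell predictors (must cover the PAM cells).
#' @param predictors predictor column names; default all numeric columns.
#' @param response "beta_sor" (default) or "beta_sim".
#' @param max_pairs subsample cap (default 50000).
#' @param seed subsampling seed.
#' @param spec grid spec for the distance column.
#' @return data.frame of class \code{site_pair_table}: cell_i, cell_j,
#'   dissimilarity, distance_km, and s1.<var>/s2.<var> columns; attribute
#'   \code{predictors}.
#' @export
build_site_pairs <- function(pam, env_table, predictors = NULL,
                             response = c("beta_sor", "beta_sim"),
                             max_pairs = 50000, seed = 1L,
                             spec = grid_spec()) {
  response <- match.arg(response)
  if (is.null(predictors))
    predictors <- setdiff(names(env_table)[vapply(env_table, is.numeric,
                                                  TRUE)], "cell_id")
  occ <- pam$cells[rowSums(pam$incidence) > 0]
  occ <- occ[occ %in% env_table$cell_id]
  keep <- match(occ, pam$cells)
  sub <- new_pam(pam$counts[keep, , drop = FALSE])
  bp <- beta_pairwise(sub)[[response]]
  n <- length(occ)
  if (n < 2) stop("need at least 2 occupied cells with predictors")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (nrow(ij) > max_pairs) {
    set.seed(seed)
    ij <- ij[sample.int(nrow(ij), max_pairs), , drop = FALSE]
  }
  ctr <- cell_center(occ, spec)
  ev <- env_table[match(occ, env_table$cell_id), predictors, drop = FALSE]
  out <- data.frame(cell_i = occ[ij[, 1]], cell_j = occ[ij[, 2]],
                    dissimilarity = bp[cbind(ij[, 1], ij[, 2])],
                    distance_km = gc_dist(ctr$lon[ij[, 1]], ctr$lat[ij[, 1]],
                                          ctr$lon[ij[, 2]], ctr$lat[ij[, 2]]),
                    stringsAsFactors = FALSE)
  for (v in predictors) {
    out[[paste0("s1.", v)]] <- ev[[v]][ij[, 1]]
    out[[paste0("s2.", v)]] <- ev[[v]][ij[, 2]]
  }
  attr(out, "predictors") <- predictors
  class(out) <- c("site_pair_table", "data.frame")
  out
}

#' Monotone I-spline basis
#'
#' Order-2 I-splines (piecewise-quadratic integrals of linear M-splines) on
#' three knots, by default the min/median/max of the predictor. Each of the
#' three basis functions is nondecreasing, 0 at the lowest knot and 1 at the
#' highest, so any nonnegative combination is a monotone transform with
#' height equal to the coefficient sum.
#'
#' @param x numeric vector.
#' @param knots numeric length 3, strictly increasing; default
#'   min/median/max of x.
#' @return matrix length(x) x 3; values outside the knot span are clamped.
#' @export
ispline_basis <- function(x, knots = NULL) {
  if (is.null(knots))
    knots <- as.numeric(stats::quantile(x, c(0, 0.5, 1), names = FALSE))
  stopifnot(length(knots) == 3)
  q1 <- knots[1]; q2 <- knots[2]; q3 <- knots[3]
  if (!(q1 < q3)) stop("degenerate knots: min and max coincide")
  if (!(q1 < q2 && q2 < q3)) {
    # collapse the midpoint tie by nudging to the span center
    q2 <- (q1 + q3) / 2
  }
  x <- pmin(q3, pmax(q1, x))
  b1 <- ifelse(x < q2, 1 - (q2 - x)^2 / (q2 - q1)^2, 1)
  b2 <- ifelse(x < q2,
               (x - q1)^2 / ((q3 - q1) * (q2 - q1)),
               1 - (q3 - x)^2 / ((q3 - q1) * (q3 - q2)))
  b3 <- ifelse(x < q2, 0, (x - q2)^2 / (q3 - q2)^2)
  cbind(b1, b2, b3)
}

#' Nonnegative least squares (Lawson-Hanson)
#'
#' Solves min ||Ax - b|| subject to x >= 0 by the active-set algorithm.
#'
#' @param A design matrix.
#' @param b response vector.
#' @param tol tolerance on the optimality check.
#' @return numeric coefficient vector (>= 0).
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  wres <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & wres > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, wres))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- as.numeric(qr.coef(qr(Ap), b))
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    wres <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}

# binomial-type deviance between observed and predicted dissimilarities
.gdm_deviance <- function(d, mu) {
  mu <- pmin(1 - 1e-9, pmax(1e-9, mu))
  t1 <- ifelse(d > 0, d * log(d / mu), 0)
  t2 <- ifelse(d < 1, (1 - d) * log((1 - d) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

#' Fit a generalized dissimilarity model
#'
#' Models pairwise compositional dissimilarity as \eqn{d = 1 - e^{-\eta}}
#' with predicted ecological distance \eqn{\eta = \alpha + \sum_p |f_p(x_i)
#' - f_p(x_j)|}, each \eqn{f_p} a nonnegative combination of monotone
#' I-splines. Coefficients (all constrained >= 0, including the intercept)
#' are estimated by iteratively reweighted nonnegative least squares
#' maximizing a binomial-type likelihood; convergence when the maximum
#' coefficient change drops below \code{tol}.
#'
#' @param pairs a \code{site_pair_table}.
#' @param predictors predictor names; default the table's attribute.
#' @param max_iter IRLS iteration cap (default 100).
#' @param tol coefficient-change convergence tolerance (default 1e-6).
#' @return object of class \code{gdm_fit}: per-predictor knots and
#'   coefficients, intercept, fitted values, deviance explained.
#' @export
fit_gdm <- function(pairs, predictors = NULL, max_iter = 100, tol = 1e-6) {
  if (is.null(predictors)) predictors <- attr(pairs, "predictors")
  stopifnot(length(predictors) >= 1)
  if (nrow(pairs) < 30) stop("need at least 30 site pairs")
  d <- pairs$dissimilarity
  stopifnot(all(d >= 0 & d <= 1))

  knots <- list()
  cols <- list()
  for (v in predictors) {
    xall <- c(pairs[[paste0("s1.", v)]], pairs[[paste0("s2.", v)]])
    kn <- as.numeric(stats::quantile(xall, c(0, 0.5, 1), names = FALSE))
    knots[[v]] <- kn
    if (kn[1] == kn[3]) {                     # constant predictor: no basis
      cols[[v]] <- matrix(0, nrow(pairs), 3)
    } else {
      b1 <- ispline_basis(pairs[[paste0("s1.", v)]], kn)
      b2 <- ispline_basis(pairs[[paste0("s2.", v)]], kn)
      cols[[v]] <- abs(b1 - b2)
    }
  }
  Xs <- do.call(cbind, cols)
  A <- cbind(intercept = 1, Xs)

  beta <- rep(0, ncol(A))
  mu0 <- mean(d)
  beta[1] <- max(0, -log(1 - min(0.99, max(0.01, mu0))))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(A %*% beta)
    mu <- 1 - exp(-eta)
    mu_c <- pmin(1 - 1e-6, pmax(1e-6, mu))
    dmu <- 1 - mu_c                        # d mu / d eta
    wt <- dmu^2 / (mu_c * (1 - mu_c))      # IRLS weights
    z <- eta + (d - mu) / dmu              # working response
    sw <- sqrt(wt)
    beta_new <- nnls_solve(A * sw, z * sw)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  if (!converged)
    stop("GDM did not converge in ", max_iter,
         " iterations (last max coefficient change above tol)")
  eta <- as.numeric(A %*% beta)
  fitted <- 1 - exp(-eta)
  dev <- .gdm_deviance(d, fitted)
  dev_null <- .gdm_deviance(d, rep(mean(d), length(d)))
  coefs <- lapply(seq_along(predictors), function(k)
    beta[1 + (3 * (k - 1) + 1):(3 * k)])
  names(coefs) <- predictors
  structure(list(predictors = predictors, knots = knots,
                 coefficients = coefs, intercept = beta[1],
                 fitted = fitted, observed = d,
                 deviance = dev, null_deviance = dev_null,
                 deviance_explained = if (dev_null > 0)
                   100 * (1 - dev / dev_null) else 0,
                 n_pairs = nrow(pairs)),
            class = "gdm_fit")
}

#' @export
print.gdm_fit <- function(x, ...) {
  cat(sprintf("gdm_fit: %d pairs, %d predictors, %.1f%% deviance explained\n",
              x$n_pairs, length(x$predictors), x$deviance_explained))
  invisible(x)
}

#' Evaluate a fitted GDM transform for one predictor
#'
#' @param fit a \code{gdm_fit}.
#' @param predictor predictor name.
#' @param x values at which to evaluate.
#' @return f_p(x), the monotone transformed predictor.
#' @export
gdm_transform <- function(fit, predictor, x) {
  kn <- fit$knots[[predictor]]
  if (kn[1] == kn[3]) return(rep(0, length(x)))
  as.numeric(ispline_basis(x, kn) %*% fit$coefficients[[predictor]])
}

#' Predictor importance: maximum spline heights
#'
#' The height of each fitted transform, \eqn{f_p(\max) - f_p(\min)} — the
#' sum of the predictor's I-spline coefficients. Zero-height predictors are
#' flagged for exclusion from composition mapping.
#'
#' @param fit a \code{gdm_fit}.
#' @return data.frame predictor/height/retained, sorted by height.
#' @export
predictor_importance <- function(fit) {
  h <- vapply(fit$coefficients, sum, 0)
  out <- data.frame(predictor = names(h), height = as.numeric(h),
                    retained = h > 0, stringsAsFactors = FALSE)
  out[order(-out$height, out$predictor), , drop = FALSE]
}

#' Transform predictors and map composition as RGB channels
#'
#' Applies the fitted monotone transforms to each cell's predictors
#' (dropping zero-height predictors), runs a PCA on the transformed cell x
#' predictor matrix, and min-max scales the first three component scores to
#' [0, 255] per channel. PCA signs are fixed by forcing the first retained
#' predictor's loading positive on each component, so maps are reproducible.
#' With fewer than three retained predictors the missing channels are
#' zero-padded with a warning.
#'
#' @param fit a \code{gdm_fit}.
#' @param env_table per-cell predictors.
#' @return data.frame cell_id, R, G, B (integers 0-255); attributes
#'   \code{scores} and \code{loadings}.
#' @export
transform_and_map <- function(fit, env_table) {
  imp <- predictor_importance(fit)
  keep <- imp$predictor[imp$retained]
  if (length(keep) == 0) stop("no predictor with positive spline height")
  tx <- sapply(keep, function(v) gdm_transform(fit, v, env_table[[v]]))
  tx <- matrix(tx, nrow = nrow(env_table),
               dimnames = list(env_table$cell_id, keep))
  nc <- min(3, ncol(tx), nrow(tx) - 1)
  pc <- stats::prcomp(tx, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(nc), drop = FALSE]
  load <- pc$rotation[, seq_len(nc), drop = FALSE]
  for (k in seq_len(nc)) {                 # sign fix on first retained var
    if (load[1, k] < 0) { load[, k] <- -load[, k]; scores[, k] <- -scores[, k] }
  }
  chan <- matrix(0, nrow(tx), 3)
  for (k in seq_len(nc)) {
    rg <- range(scores[, k])
    chan[, k] <- if (diff(rg) > 0)
      round(255 * (scores[, k] - rg[1]) / diff(rg)) else 0
  }
  if (nc < 3) warning("fewer than 3 retained PCA axes: channels zero-padded")
  out <- data.frame(cell_id = env_table$cell_id,
                    R = as.integer(chan[, 1]), G = as.integer(chan[, 2]),
                    B = as.integer(chan[, 3]), stringsAsFactors = FALSE)
  attr(out, "scores") <- scores
  attr(out, "loadings") <- load
  out
}
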