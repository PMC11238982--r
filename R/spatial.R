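#' Spatial weights on the cell grid
#'
#' Builds neighbor weights between grid cells: first-order queen contiguity
#' on the integer cell lattice (with dateline wrap: cells at -180 and +179
#' longitude are adjacent), or a great-circle distance band between cell
#' centers. Weights are binary before optional row-standardization.
#'
#' @param cell_id character cell ids.
#' @param scheme "queen" or "band".
#' @param band_km distance band radius in km (scheme = "band").
#' @param include_self include each cell in its own neighbor set (needed for
#'   the Getis-Ord G* statistic).
#' @param row_standardize divide each row by its sum.
#' @param spec grid spec.
#' @return object of class \code{cell_weights}: ids, neighbor index list,
#'   weight list, and the scheme flags. Isolated cells get empty neighbor
#'   lists and are flagged in the \code{isolated} attribute.
#' @export
build_weights <- function(cell_id, scheme = c("queen", "band"),
                          band_km = 500, include_self = FALSE,
                          row_standardize = FALSE, spec = grid_spec()) {
  scheme <- match.arg(scheme)
  n <- length(cell_id)
  ctr <- cell_center(cell_id, spec)
  if (scheme == "queen") {
    sw <- cell_sw_corner(cell_id)
    sz <- spec$cell_size
    nb <- lapply(seq_len(n), function(i) {
      dlon <- abs(wrap_lon(sw$lon - sw$lon[i]))
      dlat <- abs(sw$lat - sw$lat[i])
      which(dlon <= sz + 1e-9 & dlat <= sz + 1e-9)
    })
  } else {
    nb <- lapply(seq_len(n), function(i) {
      d <- gc_dist(ctr$lon[i], ctr$lat[i], ctr$lon, ctr$lat)
      which(d <= band_km)
    })
  }
  if (!include_self)
    nb <- lapply(seq_len(n), function(i) setdiff(nb[[i]], i))
  w <- lapply(nb, function(j) rep(1, length(j)))
  if (row_standardize)
    w <- lapply(w, function(x) if (length(x)) x / sum(x) else x)
  iso <- which(lengths(nb) == 0)
  structure(list(ids = cell_id, nb = nb, w = w, scheme = scheme,
                 include_self = include_self,
                 row_standardized = row_standardize),
            isolated = iso, class = "cell_weights")
}

#' Dense matrix form of a weights object
#' @param w a \code{cell_weights}.
#' @return n x n numeric matrix.
#' @export
as_weights_matrix <- function(w) {
  n <- length(w$ids)
  m <- matrix(0, n, n, dimnames = list(w$ids, w$ids))
  for (i in seq_len(n)) m[i, w$nb[[i]]] <- w$w[[i]]
  m
}

#' Global Moran's I with analytic and permutation inference
#'
#' \eqn{I = (n / S_0) \sum_i \sum_j w_{ij} z_i z_j / \sum_i z_i^2} with z the
#' deviations from the mean and \eqn{S_0} the total weight. The expectation
#' under no autocorrelation is \eqn{-1/(n-1)}; the analytic p-value uses the
#' normality variance, the permutation p-value relabels the values over the
#' cells \code{n_perm} times.
#'
#' @param values numeric vector, one per weight id (NA cells are dropped
#'   together with their weights).
#' @param w a \code{cell_weights} (self excluded).
#' @param n_perm permutation count (default 999); 0 skips.
#' @param seed seed for the permutations.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return list: I, expectation, sd_norm, p_norm, p_perm, n.
#' @export
morans_i <- function(values, w, n_perm = 999, seed = 1L,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  W <- as_weights_matrix(w)
  ok <- !is.na(values)
  W <- W[ok, ok, drop = FALSE]
  x <- values[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 non-missing cells")
  if (stats::sd(x) == 0) stop("zero variance field")
  z <- x - mean(x)
  S0 <- sum(W)
  if (S0 == 0) stop("no neighbor links among non-missing cells")
  istat <- function(zz) (n / S0) * sum(W * outer(zz, zz)) / sum(zz^2)
  I <- istat(z)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  # variance under normality
  VarI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  sdI <- sqrt(max(VarI, 0))
  zscore <- (I - EI) / sdI
  p_norm <- switch(alternative,
                   two.sided = 2 * stats::pnorm(-abs(zscore)),
                   greater = stats::pnorm(zscore, lower.tail = FALSE),
                   less = stats::pnorm(zscore))
  p_perm <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    Ip <- vapply(seq_len(n_perm), function(k) istat(sample(z)), 0)
    r_hi <- sum(Ip >= I); r_lo <- sum(Ip <= I)
    p_perm <- switch(alternative,
                     greater = (r_hi + 1) / (n_perm + 1),
                     less = (r_lo + 1) / (n_perm + 1),
                     two.sided = min(1, 2 * (min(r_hi, r_lo) + 1) /
                                       (n_perm + 1)))
  }
  list(I = I, expectation = EI, sd_norm = sdI, p_norm = p_norm,
       p_perm = p_perm, n = n)
}

#' Getis-Ord G* hot/cold-spot classification
#'
#' Per-cell z-scores of the G* statistic (neighborhood including the focal
#' cell):
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar X \sum_j w_{ij}}
#'   {S \sqrt{[n \sum_j w_{ij}^2 - (\sum_j w_{ij})^2] / (n - 1)}}}
#' with \eqn{\bar X} and S the global mean and (population) standard
#' deviation. Cells are classified hot/cold at the 90/95/99% two-sided
#' thresholds (|z| over 1.65, 1.96, 2.58): a hot spot is a significant
#' cluster of high values, a cold spot of low values.
#'
#' @param values numeric vector, one per weight id.
#' @param w a \code{cell_weights} built with \code{include_self = TRUE}.
#' @return data.frame \code{cell_id}, \code{z}, \code{class} with class
#'   levels hot99/hot95/hot90/ns/cold90/cold95/cold99.
#' @export
getis_ord_gstar <- function(values, w) {
  if (!w$include_self)
    stop("G* requires weights built with include_self = TRUE")
  W <- as_weights_matrix(w)
  ok <- !is.na(values)
  W <- W[ok, ok, drop = FALSE]
  x <- values[ok]
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(max(0, sum(x^2) / n - xbar^2))
  if (S == 0) {
    # uniform field: no clustering signal anywhere — the degenerate limit
    return(data.frame(cell_id = w$ids[ok], z = rep(0, n),
                      class = rep("ns", n), stringsAsFactors = FALSE))
  }
  wi <- rowSums(W)
  wi2 <- rowSums(W^2)
  num <- as.vector(W %*% x) - xbar * wi
  den <- S * sqrt(pmax(0, (n * wi2 - wi^2) / (n - 1)))
  z <- ifelse(den > 0, num / den, 0)
  cls <- cut(z, c(-Inf, -2.58, -1.96, -1.65, 1.65, 1.96, 2.58, Inf),
             labels = c("cold99", "cold95", "cold90", "ns",
                        "hot90", "hot95", "hot99"))
  out <- data.frame(cell_id = w$ids[ok], z = z,
                    class = as.character(cls), stringsAsFactors = FALSE)
  out
}

#' Inverse distance weighted interpolation
#'
#' Weighted mean with weights \eqn{d^{-p}} over great-circle distances;
#' exact at sample locations, and predictions clamped to the range of the
#' sample values (the interpolation never extrapolates beyond observed
#' values).
#'
#' @param sample data.frame \code{lon}, \code{lat}, \code{value}.
#' @param target data.frame \code{lon}, \code{lat} of prediction points.
#' @param power distance exponent (default 2).
#' @param max_dist optional search radius in km; targets with no sample
#'   inside get NA.
#' @return numeric vector of predictions, one per target row.
#' @export
idw <- function(sample, target, power = 2, max_dist = NULL) {
  stopifnot(nrow(sample) >= 1)
  rng <- range(sample$value)
  vapply(seq_len(nrow(target)), function(i) {
    d <- gc_dist(target$lon[i], target$lat[i], sample$lon, sample$lat)
    if (!is.null(max_dist)) {
      use <- d <= max_dist
      if (!any(use)) return(NA_real_)
      d <- d[use]; v <- sample$value[use]
    } else v <- sample$value
    if (any(d < 1e-9)) return(v[which.min(d)])
    wt <- d^(-power)
    min(rng[2], max(rng[1], sum(wt * v) / sum(wt)))
  }, 0)
}

# semivariogram models; a = range, psill = partial sill
.vgm <- function(h, model, nugget, psill, a) {
  g <- switch(model,
              spherical = ifelse(h < a,
                                 psill * (1.5 * h / a - 0.5 * (h / a)^3),
                                 psill),
              exponential = psill * (1 - exp(-3 * h / a)),
              stop("unknown variogram model: ", model))
  ifelse(h > 0, nugget + g, 0)
}

#' Fit an empirical semivariogram
#'
#' Bins pairwise squared half-differences by great-circle distance and fits
#' the chosen model by weighted least squares over a grid of ranges
#' (weights = pair counts); nugget fixed at 0 by default so kriging stays an
#' exact interpolator.
#'
#' @param sample data.frame \code{lon}, \code{lat}, \code{value}.
#' @param model "spherical" or "exponential".
#' @param n_bins number of distance bins.
#' @param nugget fixed nugget (default 0).
#' @return list: model, nugget, psill, range_km, and the binned empirical
#'   semivariogram.
#' @export
fit_variogram <- function(sample, model = c("spherical", "exponential"),
                          n_bins = 12, nugget = 0) {
  model <- match.arg(model)
  n <- nrow(sample)
  stopifnot(n >= 5)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- gc_dist(sample$lon[ij[, 1]], sample$lat[ij[, 1]],
               sample$lon[ij[, 2]], sample$lat[ij[, 2]])
  g <- 0.5 * (sample$value[ij[, 1]] - sample$value[ij[, 2]])^2
  maxd <- max(d)
  br <- seq(0, maxd, length.out = n_bins + 1)
  bin <- findInterval(d, br, rightmost.closed = TRUE, all.inside = TRUE)
  emp <- data.frame(
    dist = tapply(d, bin, mean),
    gamma = tapply(g, bin, mean),
    npairs = as.integer(table(bin)))
  sill0 <- stats::var(sample$value)
  ranges <- seq(maxd / 20, maxd * 1.5, length.out = 60)
  best <- NULL; best_sse <- Inf
  for (a in ranges) {
    # psill by weighted least squares given range
    base <- .vgm(emp$dist, model, 0, 1, a)
    psill <- sum(emp$npairs * base * (emp$gamma - nugget)) /
      max(1e-12, sum(emp$npairs * base^2))
    psill <- max(psill, 1e-12 * max(sill0, 1))
    sse <- sum(emp$npairs *
                 (emp$gamma - .vgm(emp$dist, model, nugget, psill, a))^2)
    if (sse < best_sse) { best_sse <- sse; best <- c(psill, a) }
  }
  list(model = model, nugget = nugget, psill = best[1], range_km = best[2],
       empirical = emp)
}

#' Ordinary kriging
#'
#' Solves the ordinary-kriging system per target with a Lagrange multiplier,
#' using the (fitted or supplied) semivariogram. With a zero nugget the
#' predictor is exact at sample locations with zero kriging variance.
#' Duplicate sample locations make the system singular and are an error.
#'
#' @param sample data.frame \code{lon}, \code{lat}, \code{value}.
#' @param target data.frame \code{lon}, \code{lat}.
#' @param variogram NULL (fit automatically) or a \code{fit_variogram}
#'   result / list(model, nugget, psill, range_km).
#' @param model variogram model when fitting.
#' @param clamp clamp predictions to the sample value range (default FALSE;
#'   raw kriging may lawfully exceed it).
#' @return list: \code{prediction}, \code{variance} (per target),
#'   \code{variogram}.
#' @export
ordinary_kriging <- function(sample, target, variogram = NULL,
                             model = c("spherical", "exponential"),
                             clamp = FALSE) {
  model <- match.arg(model)
  n <- nrow(sample)
  stopifnot(n >= 5)
  D <- outer(seq_len(n), seq_len(n), function(i, j)
    gc_dist(sample$lon[i], sample$lat[i], sample$lon[j], sample$lat[j]))
  if (any(D[upper.tri(D)] < 1e-9))
    stop("duplicate sample locations make the kriging system singular")
  if (is.null(variogram)) variogram <- fit_variogram(sample, model)
  vg <- function(h) .vgm(h, variogram$model, variogram$nugget,
                         variogram$psill, variogram$range_km)
  A <- rbind(cbind(vg(D), 1), c(rep(1, n), 0))
  Ai <- solve(A)
  pred <- numeric(nrow(target)); pvar <- numeric(nrow(target))
  rng <- range(sample$value)
  for (k in seq_len(nrow(target))) {
    d0 <- gc_dist(target$lon[k], target$lat[k], sample$lon, sample$lat)
    b <- c(vg(d0), 1)
    lam <- Ai %*% b
    pred[k] <- sum(lam[seq_len(n)] * sample$value)
    pvar[k] <- max(0, sum(lam * b))
    if (clamp) pred[k] <- min(rng[2], max(rng[1], pred[k]))
  }
  list(prediction = pred, variance = pvar, variogram = variogram)
}
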