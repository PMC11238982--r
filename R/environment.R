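#' Environmental predictor construction
#'
#' Builds the per-cell predictor table used by the richness and composition
#' models: depth/period averaging of gridded stacks, block-mean resampling
#' from 0.25 to 1 degree, temperature deviation and stability, per-variable
#' z-standardization and the Spearman association matrix.
#'
#' @name environment-module
NULL

#' Average an environmental stack over depth and time
#'
#' Arithmetic, missing-aware mean per cell and variable over the selected
#' depth levels and time steps. Input is a long table (one row per cell x
#' slice x variable) as produced by \code{\link{make_env_fields}} or read
#' from CSV; optional \code{depth} and \code{year} columns are filtered by
#' the windows before averaging.
#'
#' @param stack long data.frame with columns \code{cell_id},
#'   \code{variable}, \code{value} and optionally \code{depth}, \code{year}.
#' @param depth_range numeric c(min, max) metres, applied if a depth column
#'   exists. Default c(0, 200).
#' @param period integer c(first, last) year, applied if a year column
#'   exists. Default c(1993, 2019).
#' @return wide data.frame: \code{cell_id} plus one column per variable;
#'   cells with no data for a variable get NA.
#' @export
aggregate_mean <- function(stack, depth_range = c(0, 200),
                           period = c(1993L, 2019L)) {
  stopifnot(all(c("cell_id", "variable", "value") %in% names(stack)))
  if ("depth" %in% names(stack))
    stack <- stack[!is.na(stack$depth) & stack$depth >= depth_range[1] &
                     stack$depth <= depth_range[2], ]
  if ("year" %in% names(stack) && !is.null(period))
    stack <- stack[stack$year >= period[1] & stack$year <= period[2], ]
  cells <- sort(unique(stack$cell_id))
  vars <- unique(stack$variable)
  out <- data.frame(cell_id = cells, stringsAsFactors = FALSE)
  for (v in vars) {
    sub <- stack[stack$variable == v & !is.na(stack$value), ]
    m <- tapply(sub$value, factor(sub$cell_id, cells), mean)
    out[[v]] <- as.numeric(m)
  }
  out
}

#' Block-mean resampling of a fine grid onto a coarse grid
#'
#' Each coarse cell's value is the missing-aware mean of the fine-grid cells
#' it covers (16 of them for 0.25 degree data on a 1 degree target); a coarse
#' cell covered by no non-missing fine cell gets NA.
#'
#' @param fine data.frame with \code{lon}, \code{lat} (fine cell centers or
#'   south-west corners — any point inside the fine cell) and \code{value}.
#' @param spec coarse \code{\link{grid_spec}}.
#' @return data.frame \code{cell_id}, \code{value} on the coarse grid.
#' @export
resample_block_mean <- function(fine, spec = grid_spec()) {
  stopifnot(all(c("lon", "lat", "value") %in% names(fine)))
  id <- cell_id_from_coords(fine$lon, fine$lat, spec)
  ok <- !is.na(fine$value)
  cells <- sort(unique(id))
  m <- tapply(fine$value[ok], factor(id[ok], cells), mean)
  data.frame(cell_id = cells, value = as.numeric(m),
             stringsAsFactors = FALSE)
}

#' Temperature deviation and stability
#'
#' From a per-cell temperature time series: slices are grouped into
#' consecutive \code{lag_years}-year windows (window mean per cell); for each
#' adjacent pair of windows the per-cell sample standard deviation of the two
#' window values is divided by the elapsed years (the lag); the deviation
#' \code{T_sd} is the mean of these over all pairs. Stability \code{T_stab}
#' is the inverse deviation rescaled by its maximum over cells so the most
#' stable cell is exactly 1; cells with zero deviation are pinned to 1 before
#' inversion.
#'
#' @param t_stack long data.frame \code{cell_id}, \code{year}, \code{value}
#'   of temperature slices (one slice per year), or the
#'   \code{\link{make_env_fields}} output (rows with
#'   \code{variable == "T_mean"} are used).
#' @param lag_years window length and pair lag in years (default 2).
#' @return data.frame \code{cell_id}, \code{T_sd}, \code{T_stab}.
#' @export
temperature_deviation_stability <- function(t_stack, lag_years = 2) {
  if ("variable" %in% names(t_stack))
    t_stack <- t_stack[t_stack$variable == "T_mean", ]
  stopifnot(all(c("cell_id", "year", "value") %in% names(t_stack)))
  years <- sort(unique(t_stack$year))
  if (length(years) < 2) stop("need at least 2 time slices")
  cells <- sort(unique(t_stack$cell_id))
  # window index: consecutive lag_years-year blocks
  win <- floor((t_stack$year - min(years)) / lag_years)
  wmean <- tapply(t_stack$value,
                  list(factor(t_stack$cell_id, cells), factor(win)), mean)
  nw <- ncol(wmean)
  if (nw < 2) {
    # all slices fall in one window: fall back to per-slice pairs
    wmean <- tapply(t_stack$value,
                    list(factor(t_stack$cell_id, cells),
                         factor(t_stack$year, years)), mean)
    nw <- ncol(wmean)
  }
  devs <- sapply(seq_len(nw - 1), function(j) {
    apply(wmean[, c(j, j + 1), drop = FALSE], 1, stats::sd) / lag_years
  })
  t_sd <- rowMeans(as.matrix(devs))
  inv <- ifelse(t_sd > 0, 1 / t_sd, NA_real_)
  if (all(is.na(inv))) {
    t_stab <- rep(1, length(t_sd))          # perfectly constant everywhere
  } else {
    t_stab <- inv / max(inv, na.rm = TRUE)
    t_stab[t_sd == 0] <- 1
  }
  data.frame(cell_id = cells, T_sd = as.numeric(t_sd),
             T_stab = as.numeric(t_stab), stringsAsFactors = FALSE)
}

#' Z-standardize environmental predictors
#'
#' Subtracts the mean and divides by the sample standard deviation (n - 1
#' denominator), per variable, over non-missing cells. Idempotent to within
#' floating-point noise. A zero-variance variable is an error naming it.
#'
#' @param env_table data.frame with \code{cell_id} and numeric predictor
#'   columns.
#' @param vars columns to standardize; default all numeric columns.
#' @return the table with standardized columns and attribute
#'   \code{standardized = TRUE}.
#' @export
standardize_env <- function(env_table, vars = NULL) {
  if (is.null(vars))
    vars <- setdiff(names(env_table)[vapply(env_table, is.numeric, TRUE)],
                    "cell_id")
  for (v in vars) {
    x <- env_table[[v]]
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) stop("zero-variance variable: ", v)
    env_table[[v]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  attr(env_table, "standardized") <- TRUE
  env_table
}

#' Spearman rank correlation matrix of predictors
#'
#' Pairwise-complete Spearman rank correlations with average ranks for ties;
#' the standard redundancy check before model fitting.
#'
#' @inheritParams standardize_env
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(env_table, vars = NULL) {
  if (is.null(vars))
    vars <- setdiff(names(env_table)[vapply(env_table, is.numeric, TRUE)],
                    "cell_id")
  m <- stats::cor(as.matrix(env_table[vars]), method = "spearman",
                  use = "pairwise.complete.obs")
  diag(m) <- 1
  m
}
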