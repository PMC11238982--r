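#' Sample-size-based rarefaction and extrapolation of species richness
#'
#' Seamless interpolation/extrapolation of expected species richness as a
#' function of sample size, for an abundance-type frequency vector (here:
#' occurrence records per species within a region).
#'
#' Interpolation (m <= n): \eqn{E[S(m)] = S_{obs} - \sum_i \binom{n - x_i}{m}
#' / \binom{n}{m}}, evaluated in log space. Extrapolation (m = n + m*):
#' \eqn{S_{obs} + \hat f_0 [1 - (1 - f_1 / (n \hat f_0 + f_1))^{m*}]} with
#' the Chao1 unseen-species estimate \eqn{\hat f_0 = \frac{n-1}{n}
#' f_1^2 / (2 f_2)} when doubletons exist, else \eqn{\frac{n-1}{n}
#' f_1 (f_1 - 1) / 2}. 95% bounds come from a seeded multinomial bootstrap of
#' the reference sample with a normal approximation.
#'
#' @param freq positive integer frequencies per species.
#' @param m_grid sample sizes to evaluate; default 40 points from 1 to 2n.
#' @param n_boot bootstrap resamples (default 200); 0 skips the bounds.
#' @param seed bootstrap seed.
#' @param conf confidence level (default 0.95).
#' @return data.frame of class \code{rarefaction_curve}: \code{m},
#'   \code{S}, \code{lower}, \code{upper}, \code{type}
#'   ("rarefied"/"observed"/"extrapolated"); attributes \code{n},
#'   \code{S_obs}, \code{f1}, \code{f2}, and \code{unreliable}
#'   (TRUE when every species is a singleton).
#' @export
rarefy_extrapolate <- function(freq, m_grid = NULL, n_boot = 200,
                               seed = 1L, conf = 0.95) {
  freq <- freq[freq > 0]
  if (any(freq != round(freq))) stop("frequencies must be integers")
  n <- sum(freq)
  if (n < 2) stop("need a reference sample of at least 2 records")
  if (is.null(m_grid))
    m_grid <- sort(unique(c(round(seq(1, 2 * n, length.out = 40)), n)))
  S_obs <- length(freq)
  f1 <- sum(freq == 1); f2 <- sum(freq == 2)
  unreliable <- f1 == n

  point <- function(fr, nn, ss, m) {
    f1b <- sum(fr == 1); f2b <- sum(fr == 2)
    f0 <- if (f2b > 0) ((nn - 1) / nn) * f1b^2 / (2 * f2b)
          else ((nn - 1) / nn) * f1b * (f1b - 1) / 2
    vapply(m, function(mm) {
      if (mm <= nn) {
        # log-space hypergeometric absence probabilities
        keep <- fr <= nn - mm
        miss <- if (any(keep))
          sum(exp(lchoose(nn - fr[keep], mm) - lchoose(nn, mm))) else 0
        ss - miss
      } else {
        mstar <- mm - nn
        if (f0 <= 0 || f1b == 0) ss
        else ss + f0 * (1 - (1 - f1b / (nn * f0 + f1b))^mstar)
      }
    }, 0)
  }
  S <- point(freq, n, S_obs, m_grid)
  lower <- upper <- rep(NA_real_, length(m_grid))
  if (n_boot > 0) {
    set.seed(seed)
    boot <- matrix(0, n_boot, length(m_grid))
    prob <- freq / n
    for (b in seq_len(n_boot)) {
      fr <- as.integer(stats::rmultinom(1, n, prob))
      fr <- fr[fr > 0]
      boot[b, ] <- point(fr, n, length(fr), m_grid)
    }
    se <- apply(boot, 2, stats::sd)
    zq <- stats::qnorm(1 - (1 - conf) / 2)
    lower <- S - zq * se
    upper <- S + zq * se
  }
  out <- data.frame(m = m_grid, S = S, lower = lower, upper = upper,
                    type = ifelse(m_grid < n, "rarefied",
                                  ifelse(m_grid == n, "observed",
                                         "extrapolated")),
                    stringsAsFactors = FALSE)
  attr(out, "n") <- n; attr(out, "S_obs") <- S_obs
  attr(out, "f1") <- f1; attr(out, "f2") <- f2
  attr(out, "unreliable") <- unreliable
  if (unreliable)
    warning("all species are singletons: extrapolation unreliable")
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Region coverage statistics
#'
#' Per region (current system), the number of grid cells whose centers fall
#' inside the region mask, how many of those were sampled (>= 1 record), the
#' observation and species totals, spherical areas, and the percentage of the
#' region and of the whole basin that was sampled. A cell whose center falls
#' in several masks is assigned to the first one in list order.
#'
#' @param spec grid spec.
#' @param regions named list of regions (from
#'   \code{\link{read_geojson_polygons}}).
#' @param records gridded records (with \code{cell_id}).
#' @param basin_cells optional character vector of cell ids delimiting the
#'   basin; defaults to the union of all region cells.
#' @return data.frame, one row per region plus a "Total" row: region,
#'   area_km2, total_cells, sampled_cells, observations, species_observed,
#'   sampled_area_km2, pct_region_sampled, pct_basin_sampled.
#' @export
region_coverage <- function(spec, regions, records, basin_cells = NULL) {
  cells <- grid_cells(spec)
  ctr <- data.frame(lon = cells$lon + spec$cell_size / 2,
                    lat = cells$lat + spec$cell_size / 2)
  assign <- rep(NA_character_, nrow(cells))
  for (nm in names(regions)) {
    hit <- is.na(assign) & point_in_polygon(ctr$lon, ctr$lat, regions[[nm]])
    assign[hit] <- nm
  }
  area <- cell_area(cells$lat, spec$cell_size)
  if (is.null(basin_cells)) basin_cells <- cells$cell_id[!is.na(assign)]
  basin_area <- sum(area[cells$cell_id %in% basin_cells])
  sampled <- cells$cell_id %in% records$cell_id

  rows <- lapply(names(regions), function(nm) {
    in_reg <- !is.na(assign) & assign == nm
    reg_cells <- cells$cell_id[in_reg]
    reg_rec <- records[records$cell_id %in% reg_cells, , drop = FALSE]
    samp <- in_reg & sampled
    data.frame(region = nm,
               area_km2 = sum(area[in_reg]),
               total_cells = sum(in_reg),
               sampled_cells = sum(samp),
               observations = nrow(reg_rec),
               species_observed = length(unique(reg_rec$scientific_name)),
               sampled_area_km2 = sum(area[samp]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pct_region_sampled <- ifelse(out$area_km2 > 0,
                                   100 * out$sampled_area_km2 / out$area_km2, 0)
  out$pct_basin_sampled <- if (basin_area > 0)
    100 * out$sampled_area_km2 / basin_area else 0
  total <- data.frame(region = "Total",
                      area_km2 = basin_area,
                      total_cells = length(basin_cells),
                      sampled_cells = sum(out$sampled_cells),
                      observations = sum(out$observations),
                      species_observed = NA_integer_,
                      sampled_area_km2 = sum(out$sampled_area_km2),
                      pct_region_sampled = NA_real_,
                      pct_basin_sampled = if (basin_area > 0)
                        100 * sum(out$sampled_area_km2) / basin_area else 0,
                      stringsAsFactors = FALSE)
  rbind(out, total)
}
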