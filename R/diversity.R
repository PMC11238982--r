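#' Alpha richness per cell
#'
#' The absolute number of species recorded in each cell: row sums of the
#' PAM incidence matrix.
#'
#' @param pam a \code{pam}.
#' @return data.frame \code{cell_id}, \code{value}; attribute
#'   \code{statistic = "alpha_richness"}.
#' @export
alpha_richness <- function(pam) {
  cell_stat(pam$cells, rowSums(pam$incidence), "alpha_richness")
}

cell_stat <- function(cell_id, value, statistic) {
  structure(data.frame(cell_id = cell_id, value = as.numeric(value),
                       stringsAsFactors = FALSE),
            statistic = statistic)
}

#' Shannon-Wiener index from occurrence counts
#'
#' \eqn{H = -\sum_i p_i \ln p_i} with \eqn{p_i = n_i / N}: the proportion of
#' a cell's species-level records belonging to species i. Occurrence counts
#' stand in for abundances — a documented proxy, not a measured abundance.
#' Cells with no records get NA, not 0.
#'
#' @param pam a \code{pam} (uses the \code{counts} matrix).
#' @return data.frame \code{cell_id}, \code{value} with attribute
#'   \code{statistic = "shannon"}.
#' @export
shannon_index <- function(pam) {
  N <- rowSums(pam$counts)
  h <- vapply(seq_along(N), function(i) {
    if (N[i] == 0) return(NA_real_)
    p <- pam$counts[i, ] / N[i]
    p <- p[p > 0]
    -sum(p * log(p))
  }, 0)
  cell_stat(pam$cells, h, "shannon")
}

#' Pairwise Sorensen dissimilarity partitioned into turnover and nestedness
#'
#' For two cells' species sets with a shared species, b unique to the poorer
#' cell and c unique to the richer (b <= c):
#' \deqn{\beta_{sor} = (b + c) / (2a + b + c)}
#' \deqn{\beta_{sim} = b / (b + a)}
#' \deqn{\beta_{sne} = \beta_{sor} - \beta_{sim}}
#' so the Sorensen dissimilarity splits exactly into its turnover (Simpson)
#' and nestedness components.
#'
#' @param x,y binary incidence vectors over the same species list.
#' @return list with a, b, c, beta_sor, beta_sim, beta_sne.
#' @export
beta_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  x <- x > 0; y <- y > 0
  if (!any(x) && !any(y)) stop("beta_pair undefined: both cells empty")
  a <- sum(x & y)
  u1 <- sum(x & !y); u2 <- sum(y & !x)
  b <- min(u1, u2); c <- max(u1, u2)
  bsor <- if (2 * a + b + c == 0) 0 else (b + c) / (2 * a + b + c)
  bsim <- if (a + b == 0) 0 else b / (b + a)
  list(a = a, b = b, c = c,
       beta_sor = bsor, beta_sim = bsim, beta_sne = bsor - bsim)
}

#' Full pairwise beta-diversity matrices
#'
#' Vectorized computation of the three components for all cell pairs of a
#' PAM. Cells with no species are excluded (the pair statistic is undefined
#' for them).
#'
#' @param pam a \code{pam}.
#' @return list of three symmetric matrices \code{beta_sor},
#'   \code{beta_sim}, \code{beta_sne} (zero diagonal).
#' @export
beta_pairwise <- function(pam) {
  inc <- pam$incidence[rowSums(pam$incidence) > 0, , drop = FALSE]
  A <- inc %*% t(inc)                       # shared
  rich <- rowSums(inc)
  U1 <- outer(rich, rep(1, length(rich))) - A  # unique to row cell
  U2 <- t(U1)
  B <- pmin(U1, U2); C <- pmax(U1, U2)
  denom_sor <- 2 * A + B + C
  bsor <- ifelse(denom_sor > 0, (B + C) / denom_sor, 0)
  denom_sim <- A + B
  bsim <- ifelse(denom_sim > 0, B / denom_sim, 0)
  diag(bsor) <- 0; diag(bsim) <- 0
  list(beta_sor = bsor, beta_sim = bsim, beta_sne = bsor - bsim)
}

#' Per-cell mean beta diversity and its components
#'
#' For each focal cell, the mean of the pairwise Sorensen, turnover and
#' nestedness components against its neighbor cells (all pairs within the
#' analysis region by default; queen contiguity and distance bands are also
#' supported). Cells with no species, or no neighbors, get NA. The grand
#' means over cells are attached as the \code{grand_means} attribute.
#'
#' @param pam a \code{pam}.
#' @param neighborhood \code{"all"}, \code{"queen"}, or \code{"band"}.
#' @param band_km distance band radius (km) when \code{neighborhood="band"}.
#' @param spec grid spec (for queen/band neighbor construction).
#' @return list of three cell-stat data.frames: \code{beta_sor},
#'   \code{beta_sim}, \code{beta_sne}.
#' @export
beta_per_cell <- function(pam, neighborhood = c("all", "queen", "band"),
                          band_km = 500, spec = grid_spec()) {
  neighborhood <- match.arg(neighborhood)
  occ <- rowSums(pam$incidence) > 0
  bp <- beta_pairwise(pam)
  ids <- pam$cells[occ]
  n <- length(ids)
  nbmask <- if (neighborhood == "all") {
    matrix(TRUE, n, n)
  } else {
    w <- build_weights(ids, scheme = if (neighborhood == "queen") "queen"
                       else "band", band_km = band_km, spec = spec)
    as_weights_matrix(w) > 0
  }
  diag(nbmask) <- FALSE
  mean_over <- function(m) {
    vapply(seq_len(n), function(i) {
      j <- nbmask[i, ]
      if (!any(j)) NA_real_ else mean(m[i, j])
    }, 0)
  }
  out <- list()
  for (comp in names(bp)) {
    v <- rep(NA_real_, length(pam$cells))
    v[occ] <- mean_over(bp[[comp]])
    out[[comp]] <- cell_stat(pam$cells, v, paste0("mean_", comp))
    attr(out[[comp]], "grand_mean") <- mean(v, na.rm = TRUE)
  }
  attr(out, "grand_means") <- vapply(out, function(d)
    attr(d, "grand_mean"), 0)
  out
}

#' Sampling redundancy index
#'
#' \eqn{R = 1 - S/N} per cell (S species, N records), clipped to [0, 1]:
#' values near 0 mean nearly every record added a new species
#' (under-sampling), values near 1 mean the species list is saturated
#' relative to effort. N = 0 gives NA.
#'
#' @param pam a \code{pam}.
#' @return cell-stat data.frame, statistic \code{"redundancy"}.
#' @export
redundancy_index <- function(pam) {
  S <- rowSums(pam$incidence)
  N <- rowSums(pam$counts)
  r <- ifelse(N > 0, pmin(1, pmax(0, 1 - S / N)), NA_real_)
  cell_stat(pam$cells, r, "redundancy")
}

#' Dominant species within a region
#'
#' Species ranked by occurrence count over the cells inside the region mask
#' (ties broken alphabetically); the deterministic replacement for visual
#' dominance selection.
#'
#' @param records gridded records (with \code{cell_id}).
#' @param region_cells character vector of cell ids defining the region, or
#'   NULL for all cells.
#' @param k how many species to return.
#' @return data.frame \code{species}, \code{n_occurrences}, \code{rank}.
#' @export
dominant_species <- function(records, region_cells = NULL, k = 10) {
  if (!is.null(region_cells))
    records <- records[records$cell_id %in% region_cells, ]
  if (nrow(records) == 0)
    return(data.frame(species = character(), n_occurrences = integer(),
                      rank = integer()))
  tab <- table(records$scientific_name)
  ord <- order(-as.integer(tab), names(tab))
  top <- utils::head(ord, k)
  data.frame(species = names(tab)[top],
             n_occurrences = as.integer(tab)[top],
             rank = seq_along(top), stringsAsFactors = FALSE)
}

#' Species present across the whole range of a cell statistic
#'
#' Cells are binned into \code{n_bins} equal-width intervals of the
#' statistic; returns the species occurring in at least one cell of every
#' bin — the deterministic version of picking, from a matrix plot, the
#' species that occur over all ranges of the statistic.
#'
#' @param pam a \code{pam}.
#' @param stat_field cell-stat data.frame (cell_id, value).
#' @param n_bins number of equal-width bins (default 4).
#' @return character vector of species names, sorted.
#' @export
dominant_by_stat_range <- function(pam, stat_field, n_bins = 4) {
  v <- stat_field$value[match(pam$cells, stat_field$cell_id)]
  ok <- !is.na(v)
  if (!any(ok)) return(character())
  rng <- range(v[ok])
  if (rng[1] == rng[2]) {
    bins <- rep(1L, sum(ok))
  } else {
    br <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bins <- findInterval(v[ok], br, rightmost.closed = TRUE,
                         all.inside = TRUE)
  }
  inc <- pam$incidence[ok, , drop = FALSE]
  present <- lapply(sort(unique(bins)), function(b)
    pam$species[colSums(inc[bins == b, , drop = FALSE]) > 0])
  sort(Reduce(intersect, present))
}
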