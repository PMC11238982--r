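#' Synthetic world generators
#'
#' The generator suite produces occurrence records, environmental fields and
#' ground-truth diversity surfaces with known structure, so that every
#' downstream stage of the pipeline (cleaning, gridding, diversity, hotspot
#' detection, modelling) has a recovery test against a known answer. The
#' stated world is a heavily under-sampled ocean basin: per-cell sampling
#' effort is strongly right-skewed (most cells see almost no sampling events),
#' species respond to the environment through Gaussian niche kernels, and a
#' configurable fraction of records is corrupted the way raw aggregated
#' occurrence downloads are (missing or zero coordinates, genus-level
#' determinations, exact duplicates).
#'
#' @name synthetic
NULL

# fixed offsets deriving independent sub-streams from one global seed
.seed_offsets <- c(env = 101L, pool = 211L, effort = 307L,
                   events = 401L, dirty = 503L)

#' Create a synthetic species pool
#'
#' Each species gets a Gaussian niche (center and width) on each of the
#' driver variables, plus a baseline prevalence: the probability of being
#' recorded in a single sampling event at its niche optimum. Non-driver
#' variables get infinite niche width, i.e. no response.
#'
#' @param n_species pool size. Default 178, the scale of a basin-wide
#'   epipelagic copepod species list.
#' @param env_ranges named list of c(lo, hi) ranges per environmental
#'   variable, used to place niche centers.
#' @param driver_vars character, the variables species actually respond to.
#' @param prevalence_range range of baseline prevalences, uniform.
#' @param seed integer seed.
#' @return data.frame of class \code{species_pool}: \code{species_id},
#'   \code{name}, \code{baseline_prevalence}, and per variable
#'   \code{center_<var>} and \code{width_<var>} columns.
#' @export
make_species_pool <- function(n_species = 178,
                              env_ranges = list(T_mean = c(2, 28),
                                                S = c(33.5, 36.5)),
                              driver_vars = names(env_ranges),
                              prevalence_range = c(0.05, 0.6),
                              seed = 1L) {
  stopifnot(n_species >= 1, length(env_ranges) >= 1)
  set.seed(seed + .seed_offsets[["pool"]])
  genera <- c("Synthocalanus", "Pseudogridia", "Basinella", "Oceanites",
              "Gridopia", "Cellina", "Pelagomima", "Australomima",
              "Epicyclops", "Neritomima")
  name <- sprintf("%s sp%03d", sample(genera, n_species, replace = TRUE),
                  seq_len(n_species))
  pool <- data.frame(species_id = seq_len(n_species), name = name,
                     baseline_prevalence = stats::runif(
                       n_species, prevalence_range[1], prevalence_range[2]),
                     stringsAsFactors = FALSE)
  for (v in names(env_ranges)) {
    r <- env_ranges[[v]]
    pool[[paste0("center_", v)]] <- stats::runif(n_species, r[1], r[2])
    if (v %in% driver_vars) {
      # widths around a quarter of the gradient: niches broad enough to
      # overlap, narrow enough to create composition turnover
      pool[[paste0("width_", v)]] <-
        (r[2] - r[1]) * stats::runif(n_species, 0.15, 0.4)
    } else {
      pool[[paste0("width_", v)]] <- Inf
    }
  }
  class(pool) <- c("species_pool", "data.frame")
  pool
}

#' Create a heterogeneous sampling-effort field
#'
#' Expected sampling events per cell drawn from a gamma distribution with a
#' small shape parameter, giving the heavy right skew of real survey effort:
#' a few intensely sampled cells and a long tail of near-zero effort.
#'
#' @param cells data.frame with a \code{cell_id} column (e.g. from
#'   \code{\link{grid_cells}}).
#' @param mean_events mean expected sampling events per cell.
#' @param shape gamma shape; smaller = more skewed. Default 0.35.
#' @param seed integer seed.
#' @return data.frame \code{cell_id}, \code{expected_samples}.
#' @export
make_effort_field <- function(cells, mean_events = 2, shape = 0.35,
                              seed = 1L) {
  set.seed(seed + .seed_offsets[["effort"]])
  ef <- data.frame(cell_id = cells$cell_id,
                   expected_samples = stats::rgamma(
                     nrow(cells), shape = shape, rate = shape / mean_events),
                   stringsAsFactors = FALSE)
  if (mean_events > 0 && all(ef$expected_samples <= 0))
    ef$expected_samples[1] <- mean_events
  ef
}

# circulant gaussian smoother matrix for one axis; scale in cell units.
# scale = Inf gives uniform weights, i.e. a constant (mean) field.
.gauss_circ <- function(n, scale) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  d <- pmin(d, n - d)                      # circular distance
  k <- if (is.infinite(scale)) matrix(1, n, n) else exp(-0.5 * (d / scale)^2)
  sweep(k, 1, rowSums(k), "/")
}

#' Generate synthetic environmental field stacks
#'
#' Produces, per time slice, smooth fields for T_mean, S, Chla, O2 and MLD on
#' the grid: a latitudinal gradient plus a Gaussian-random-field perturbation
#' (circularly smoothed white noise, correlation scale in cell units), with a
#' small slice-to-slice interannual offset. Dissolved oxygen is generated as a
#' strongly decreasing function of temperature with only weak independent
#' noise, reproducing the near-perfect negative rank correlation between the
#' two observed in ocean climatologies.
#'
#' @param spec a \code{\link{grid_spec}}; must define at least 4 x 4 cells.
#' @param n_time_slices number of (annual) slices; slice \code{t} is labelled
#'   year \code{start_year + t - 1}.
#' @param spatial_scale GRF correlation scale in cell units; \code{Inf} gives
#'   per-slice fields constant across cells.
#' @param seed integer seed.
#' @param start_year first slice year (default 1993).
#' @return long data.frame (cell_id, year, variable, value), attribute
#'   \code{spec}.
#' @export
make_env_fields <- function(spec = grid_spec(), n_time_slices = 4,
                            spatial_scale = 3, seed = 1L,
                            start_year = 1993L) {
  cells <- grid_cells(spec)
  nx <- length(unique(cells$lon)); ny <- length(unique(cells$lat))
  if (nx < 4 || ny < 4)
    stop("degenerate grid: make_env_fields needs at least 4 x 4 cells")
  stopifnot(n_time_slices >= 1)
  set.seed(seed + .seed_offsets[["env"]])

  lat_c <- cells$lat + spec$cell_size / 2
  Kx <- .gauss_circ(nx, spatial_scale)
  Ky <- .gauss_circ(ny, spatial_scale)
  grf <- function(sd) {
    z <- matrix(stats::rnorm(nx * ny), nx, ny)
    z <- Kx %*% z %*% t(Ky)
    s <- stats::sd(as.vector(z))
    if (s > 0) z <- z / s * sd
    as.vector(z)                        # cells ordered lon-fastest, like grid_cells
  }
  lat_frac <- (lat_c - min(lat_c)) / max(1e-9, diff(range(lat_c)))

  out <- vector("list", n_time_slices)
  for (t in seq_len(n_time_slices)) {
    yr_off <- stats::rnorm(1, 0, 0.3)   # basin-wide interannual anomaly
    T_mean <- 2 + 26 * lat_frac + yr_off + grf(1.2)
    S      <- 34 + 2 * lat_frac^2 + 0.1 * yr_off + grf(0.25)
    Chla   <- exp(-1.5 + 1.2 * (1 - lat_frac) + grf(0.35))
    O2     <- 330 - 4.5 * T_mean + grf(0.8)
    MLD    <- pmax(5, 30 + 50 * (1 - lat_frac) + grf(8))
    vals <- cbind(T_mean = T_mean, S = S, Chla = Chla, O2 = O2, MLD = MLD)
    out[[t]] <- data.frame(cell_id = rep(cells$cell_id, ncol(vals)),
                           year = start_year + t - 1L,
                           variable = rep(colnames(vals), each = nrow(cells)),
                           value = as.vector(vals),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "spec") <- spec
  res
}

#' Per-event occupancy probabilities
#'
#' Probability that a species is recorded in a single sampling event in each
#' cell: baseline prevalence times the product of per-variable Gaussian niche
#' kernels evaluated at the cell's environment.
#'
#' @param env_table data.frame with \code{cell_id} and one column per
#'   environmental variable.
#' @param pool a \code{\link{make_species_pool}} result.
#' @return matrix cells x species, dimnames (cell_id, species name).
#' @export
occupancy_prob <- function(env_table, pool) {
  vars <- sub("^center_", "",
              grep("^center_", names(pool), value = TRUE))
  vars <- intersect(vars, names(env_table))
  p <- matrix(rep(pool$baseline_prevalence, each = nrow(env_table)),
              nrow(env_table), nrow(pool))
  for (v in vars) {
    e <- env_table[[v]]
    ctr <- pool[[paste0("center_", v)]]
    wid <- pool[[paste0("width_", v)]]
    k <- exp(-0.5 * (outer(e, ctr, "-") / rep(wid, each = length(e)))^2)
    k[, is.infinite(wid)] <- 1
    p <- p * k
  }
  dimnames(p) <- list(env_table$cell_id, pool$name)
  p
}

#' Simulate occurrence records
#'
#' Per cell the number of sampling events is Poisson(expected_samples); in
#' each event every species is recorded independently with its per-event
#' occupancy probability. A fraction \code{dirty_fraction} of the clean
#' records is then corrupted, cycling through four corruption types (missing
#' coordinates, (0,0) coordinates, genus-level rank, exact duplicate row);
#' every row carries a hidden \code{.audit} tag ("clean" or the corruption
#' type) that the cleaning stage never reads, so cleaning can be audited.
#'
#' @param env_table per-cell environment (see \code{\link{occupancy_prob}}).
#' @param pool species pool.
#' @param effort data.frame \code{cell_id}, \code{expected_samples}.
#' @param dirty_fraction fraction of clean records corrupted, in [0, 1].
#' @param seed integer seed.
#' @param spec grid spec used to scatter record coordinates inside cells.
#' @param period integer c(first, last) year for event dates.
#' @return data.frame of records in Darwin Core-style columns
#'   (\code{scientificName}, \code{taxonRank}, \code{decimalLatitude},
#'   \code{decimalLongitude}, \code{eventDate}, \code{depthMin},
#'   \code{depthMax}, \code{source_id}, \code{.audit}).
#' @export
simulate_occurrences <- function(env_table, pool, effort,
                                 dirty_fraction = 0.05, seed = 1L,
                                 spec = grid_spec(),
                                 period = c(1993L, 2019L)) {
  if (!is.numeric(dirty_fraction) || dirty_fraction < 0 || dirty_fraction > 1)
    stop("dirty_fraction must be in [0, 1]")
  if (!all(effort$cell_id %in% env_table$cell_id))
    stop("env_table must cover all effort cells")
  set.seed(seed + .seed_offsets[["events"]])
  p <- occupancy_prob(env_table, pool)
  p <- p[match(effort$cell_id, env_table$cell_id), , drop = FALSE]

  n_events <- stats::rpois(nrow(effort), effort$expected_samples)
  recs <- vector("list", nrow(effort))
  sw <- cell_sw_corner(effort$cell_id)
  for (i in seq_len(nrow(effort))) {
    k <- n_events[i]
    if (k == 0) next
    # k events x species Bernoulli draws
    hits <- which(matrix(stats::runif(k * ncol(p)), k) <
                    matrix(p[i, ], k, ncol(p), byrow = TRUE),
                  arr.ind = TRUE)
    if (nrow(hits) == 0) next
    recs[[i]] <- data.frame(
      scientificName = colnames(p)[hits[, 2]],
      taxonRank = "species",
      decimalLatitude = sw$lat[i] +
        stats::runif(nrow(hits)) * spec$cell_size,
      decimalLongitude = wrap_lon(sw$lon[i] +
        stats::runif(nrow(hits)) * spec$cell_size),
      # year and day-of-year drawn separately so dates stay inside the period
      eventDate = as.character(as.Date(sprintf(
        "%d-%03d",
        period[1] + floor(stats::runif(nrow(hits)) *
                            (period[2] - period[1] + 1)),
        1L + floor(stats::runif(nrow(hits)) * 365)), format = "%Y-%j")),
      depthMin = round(stats::runif(nrow(hits), 0, 150), 1),
      stringsAsFactors = FALSE)
    recs[[i]]$depthMax <- pmin(200, recs[[i]]$depthMin +
                                 round(stats::runif(nrow(hits), 0, 50), 1))
    recs[[i]]$.event <- hits[, 1]  # dedup below
    recs[[i]] <- recs[[i]][!duplicated(recs[[i]][c("scientificName", ".event")]), ]
    recs[[i]]$.event <- NULL
  }
  rec <- do.call(rbind, recs)
  if (is.null(rec))
    rec <- data.frame(scientificName = character(), taxonRank = character(),
                      decimalLatitude = numeric(), decimalLongitude = numeric(),
                      eventDate = character(), depthMin = numeric(),
                      depthMax = numeric(), stringsAsFactors = FALSE)
  rec$source_id <- if (nrow(rec)) sprintf("syn-%06d", seq_len(nrow(rec))) else character()
  rec$.audit <- rep("clean", nrow(rec))
  rownames(rec) <- NULL

  n_corrupt <- round(dirty_fraction * nrow(rec))
  if (n_corrupt > 0) {
    set.seed(seed + .seed_offsets[["dirty"]])
    types <- rep(c("missing_coords", "zero_coords", "genus_rank", "duplicate"),
                 length.out = n_corrupt)
    n_inplace <- sum(types != "duplicate")
    idx <- sample(nrow(rec), n_inplace)
    ti <- types[types != "duplicate"]
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (ti[j] == "missing_coords") {
        rec$decimalLatitude[i] <- NA_real_; rec$decimalLongitude[i] <- NA_real_
      } else if (ti[j] == "zero_coords") {
        rec$decimalLatitude[i] <- 0; rec$decimalLongitude[i] <- 0
      } else {
        rec$taxonRank[i] <- "genus"
        rec$scientificName[i] <- sub(" .*$", "", rec$scientificName[i])
      }
      rec$.audit[i] <- ti[j]
    }
    n_dup <- sum(types == "duplicate")
    if (n_dup > 0) {
      clean_idx <- which(rec$.audit == "clean")
      src <- sample(clean_idx, min(n_dup, length(clean_idx)))
      dup <- rec[src, , drop = FALSE]
      dup$.audit <- "duplicate"
      rec <- rbind(rec, dup)
      rownames(rec) <- NULL
    }
  }
  rec
}

#' Ground-truth diversity surfaces
#'
#' Analytic reference values for recovery tests. \code{expected_richness} is
#' the sum over species of per-event occupancy probabilities (an effort-free
#' diversity index); when \code{effort} is supplied,
#' \code{expected_realized_richness} is the expected number of species
#' actually observed under Poisson sampling, \eqn{\sum_s (1 - e^{-\lambda_c
#' p_{cs}})}. Hotspots are the top decile of expected richness.
#'
#' @param env_table per-cell environment.
#' @param pool species pool.
#' @param effort optional effort field for the realized-richness expectation.
#' @return data.frame: cell_id, expected_richness, true_richness (rounded),
#'   true_shannon, hotspot_flag, and expected_realized_richness when effort
#'   is given.
#' @export
ground_truth <- function(env_table, pool, effort = NULL) {
  p <- occupancy_prob(env_table, pool)
  er <- rowSums(p)
  q <- p / ifelse(er > 0, er, 1)
  h <- -rowSums(ifelse(q > 0, q * log(q), 0))
  h[er == 0] <- 0
  out <- data.frame(cell_id = env_table$cell_id,
                    expected_richness = er,
                    true_richness = as.integer(round(er)),
                    true_shannon = h,
                    hotspot_flag = er >= stats::quantile(er, 0.9),
                    stringsAsFactors = FALSE)
  if (!is.null(effort)) {
    lam <- effort$expected_samples[match(env_table$cell_id, effort$cell_id)]
    out$expected_realized_richness <-
      rowSums(1 - exp(-lam * p))
  }
  out
}
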