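# shared fixtures, all built in code at test time

# small synthetic world: grid, env means, pool, effort
small_world <- function(seed = 1, nx = 8, ny = 8, n_species = 30,
                        mean_events = 3, dirty_fraction = 0) {
  spec <- grid_spec(1, c(0, nx), c(-40, -40 + ny))
  stack <- make_env_fields(spec, n_time_slices = 3, seed = seed)
  envm <- aggregate_mean(stack)
  pool <- make_species_pool(n_species = n_species, seed = seed)
  effort <- make_effort_field(grid_cells(spec), mean_events = mean_events,
                              seed = seed)
  rec <- simulate_occurrences(envm, pool, effort,
                              dirty_fraction = dirty_fraction,
                              seed = seed, spec = spec)
  list(spec = spec, stack = stack, env = envm, pool = pool,
       effort = effort, records = rec)
}

# PAM from explicit incidence rows (list of species-name vectors)
pam_from_lists <- function(cells, species_lists, counts = NULL) {
  species <- sort(unique(unlist(species_lists)))
  m <- matrix(0L, length(cells), length(species),
              dimnames = list(cells, species))
  for (i in seq_along(cells))
    for (s in species_lists[[i]])
      m[i, s] <- m[i, s] + if (is.null(counts)) 1L else counts[[i]][[s]]
  oceandiv:::new_pam(m)
}

# uniform-effort world for recovery tests: every cell sampled hard
dense_world <- function(seed = 1, nx = 6, ny = 6, n_species = 25,
                        events = 50) {
  spec <- grid_spec(1, c(0, nx), c(-40, -40 + ny))
  stack <- make_env_fields(spec, n_time_slices = 3, seed = seed)
  envm <- aggregate_mean(stack)
  pool <- make_species_pool(n_species = n_species, seed = seed)
  effort <- data.frame(cell_id = grid_cells(spec)$cell_id,
                       expected_samples = events)
  rec <- simulate_occurrences(envm, pool, effort, dirty_fraction = 0,
                              seed = seed, spec = spec)
  list(spec = spec, env = envm, pool = pool, effort = effort,
       records = rec)
}

# rook-adjacency weights on an explicit edge list (for hand-checked cases)
manual_weights <- function(ids, edges, include_self = FALSE) {
  nb <- lapply(seq_along(ids), function(i) {
    j <- sort(unique(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])))
    if (include_self) sort(unique(c(i, j))) else j
  })
  structure(list(ids = ids, nb = nb,
                 w = lapply(nb, function(j) rep(1, length(j))),
                 scheme = "queen", include_self = include_self,
                 row_standardized = FALSE),
            class = "cell_weights")
}

# generator records use Darwin Core column names; convert to the internal
# record-table schema for tests that skip read_occurrences()
gen_to_internal <- function(rec) {
  data.frame(scientific_name = rec$scientificName,
             taxon_rank = rec$taxonRank,
             longitude = rec$decimalLongitude,
             latitude = rec$decimalLatitude,
             event_date = as.Date(rec$eventDate),
             depth_min = rec$depthMin, depth_max = rec$depthMax,
             source_id = rec$source_id, stringsAsFactors = FALSE)
}
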