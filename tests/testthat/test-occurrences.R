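write_rec_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

test_that("read_occurrences types records and tolerates bad fields", {
  f <- write_rec_csv(data.frame(
    scientificName = c("Calanus simillimus", "Oithona similis",
                       "Acartia tonsa"),
    taxonRank = "species",
    decimalLatitude = c("-33.2", "abc", "-35"),
    decimalLongitude = c("-70.5", "-71", "-72"),
    eventDate = c("2001-05-05", "not a date", "2003-01-01"),
    depthMin = c("0", "10", "5"), depthMax = c("100", "20", "x"),
    source_id = c("a", "b", "c")))
  rt <- read_occurrences(f)
  expect_equal(nrow(rt), 3)
  expect_true(is.na(rt$latitude[2]))       # unparseable -> missing
  expect_true(is.na(rt$event_date[2]))
  expect_true(is.na(rt$depth_max[3]))
  expect_equal(rt$latitude[1], -33.2)

  f2 <- write_rec_csv(data.frame(name = "x", lat = 1))
  expect_error(read_occurrences(f2), "scientific_name")

  # row count preserved on a 500-record synthetic fixture
  w <- small_world(seed = 21, dirty_fraction = 0.05, mean_events = 3)
  stopifnot(nrow(w$records) > 500)
  rec500 <- w$records[1:500, ]
  expect_equal(nrow(read_occurrences(write_rec_csv(rec500))), 500)
})

test_that("clean_records applies first-matching rules and conserves counts", {
  rec <- data.frame(
    scientific_name = c("Calanus simillimus", "Calanus simillimus",
                        "Oithona", "Acartia tonsa", "Acartia tonsa",
                        "Paracalanus parvus", "Calanus australis",
                        "Oncaea media"),
    taxon_rank = c("species", "species", "genus", "species", "species",
                   "species", "species", "species"),
    latitude = c(-30, 0, -31, -32, -32, NA, -33, -34),
    longitude = c(-70, 0, -71, -72, -72, -73, -74, -75),
    event_date = as.Date(c("2000-01-01", "2000-01-01", "2000-01-01",
                           "2005-06-01", "2005-06-01", "2000-01-01",
                           "1980-01-01", "2001-01-01")),
    depth_min = c(10, 10, 10, 10, 10, 10, 10, 400),
    depth_max = c(20, 20, 20, 20, 20, 20, 20, 500),
    source_id = letters[1:8], stringsAsFactors = FALSE)
  cl <- clean_records(rec)
  rep <- cl$report
  expect_equal(rep$dropped$zero_coords, 1)     # row 2
  expect_equal(rep$dropped$missing_coords, 1)  # row 6
  expect_equal(rep$dropped$non_species_rank, 1) # row 3
  expect_equal(rep$dropped$outside_depth, 1)   # row 8 (midpoint 450)
  expect_equal(rep$dropped$outside_period, 1)  # row 7 (1980)
  expect_equal(rep$dropped$duplicate, 1)       # row 5 duplicates row 4
  expect_equal(rep$input, rep$output + sum(unlist(rep$dropped)))
  expect_equal(nrow(cl$records), 2)
  # requesting a mask without supplying one names the rule
  expect_error(clean_records(rec, apply_land = TRUE), "on_land")
})

test_that("cleaning report conservation holds on dirty synthetic tables", {
  for (s in c(2, 8)) {
    w <- small_world(seed = s, dirty_fraction = 0.15, mean_events = 3)
    f <- write_rec_csv(w$records)
    cl <- clean_records(read_occurrences(f))
    expect_equal(cl$report$input,
                 cl$report$output + sum(unlist(cl$report$dropped)))
    expect_equal(nrow(cl$records), sum(w$records$.audit == "clean"))
  }
})

test_that("harmonize_taxonomy follows chains, errors on cycles", {
  rec <- data.frame(scientific_name = c("Paracalanus indicus",
                                        "Paracalanus cf. indicus",
                                        "Acartia tonsa"),
                    stringsAsFactors = FALSE)
  ident <- data.frame(name = "Paracalanus indicus",
                      accepted_name = "Paracalanus indicus")
  expect_equal(harmonize_taxonomy(rec, ident)$scientific_name,
               rec$scientific_name)
  syn <- data.frame(name = c("Paracalanus cf. indicus", "Paracalanus old"),
                    accepted_name = c("Paracalanus indicus",
                                      "Paracalanus cf. indicus"))
  out <- harmonize_taxonomy(rec, syn)
  expect_equal(out$scientific_name[2], "Paracalanus indicus")
  expect_equal(attr(out, "n_unmatched"), 2)  # indicus + tonsa not in map
  cyc <- data.frame(name = c("A b", "C d"), accepted_name = c("C d", "A b"))
  expect_error(harmonize_taxonomy(data.frame(scientific_name = "A b"), cyc),
               "cyclic")

  # two synonyms in one cell -> one presence after PAM build
  rec2 <- data.frame(scientific_name = c("Old name", "New name"),
                     cell_id = "0:0", stringsAsFactors = FALSE)
  rec2 <- harmonize_taxonomy(rec2, data.frame(name = "Old name",
                                              accepted_name = "New name"))
  pam <- build_pam(rec2)
  expect_equal(dim(pam$incidence), c(1L, 1L))
  expect_equal(sum(pam$counts), 2)

  # random synonym map over a synthetic pool: species count after
  # harmonization equals the accepted-name count
  pool <- make_species_pool(n_species = 20, seed = 3)
  set.seed(4)
  accepted <- sample(pool$name, 8)
  synonyms <- setdiff(pool$name, accepted)
  map <- data.frame(name = synonyms,
                    accepted_name = sample(accepted, length(synonyms),
                                           replace = TRUE))
  rec3 <- data.frame(scientific_name = rep(pool$name, 3),
                     stringsAsFactors = FALSE)
  out3 <- harmonize_taxonomy(rec3, map)
  expect_setequal(unique(out3$scientific_name), accepted)
})

test_that("assign_cells floors, wraps the dateline, and is idempotent", {
  rec <- data.frame(scientific_name = "x",
                    longitude = c(-70.5, 180, -180, 179.99, 0),
                    latitude = c(-33.2, -10, -10, -10.5, 0))
  g <- assign_cells(rec)
  expect_equal(g$cell_id[1], "-71:-34")
  expect_equal(g$cell_id[2], "-180:-10")   # 180 wraps to -180
  expect_equal(g$cell_id[3], "-180:-10")
  expect_equal(g$cell_id[4], "179:-11")
  expect_equal(g$cell_id[5], "0:0")        # edges belong to the SW-floored cell
  expect_identical(assign_cells(g)$cell_id, g$cell_id)
})

test_that("PAM reconstruction matches the generator exactly", {
  w <- dense_world(seed = 6, nx = 5, ny = 5, n_species = 15, events = 10)
  f <- write_rec_csv(w$records)
  cl <- clean_records(read_occurrences(f))
  g <- assign_cells(cl$records, w$spec)
  pam <- build_pam(g)
  expect_equal(sum(pam$counts), nrow(w$records))   # conservation
  # generator truth: realized presence per cell
  gen <- assign_cells(gen_to_internal(w$records), w$spec)
  truth <- table(gen$cell_id, gen$scientific_name) > 0
  expect_equal(sort(rownames(truth)), pam$cells)
  m <- truth[pam$cells, pam$species]
  expect_true(all((m * 1L) == pam$incidence))
})

test_that("filter_cells matches a brute-force filter", {
  w <- dense_world(seed = 13, nx = 6, ny = 4, n_species = 20, events = 8)
  pam <- build_pam(assign_cells(
    gen_to_internal(w$records), w$spec))
  expect_identical(filter_cells(pam, 0)$cells, pam$cells)  # identity
  fp <- filter_cells(pam, 5, excluded_lon_band = c(2, 3), spec = w$spec)
  rich <- rowSums(pam$incidence)
  ctr <- cell_center(pam$cells, w$spec)$lon
  brute <- pam$cells[rich >= 5 & !(ctr >= 2 & ctr <= 3)]
  expect_identical(fp$cells, brute)
  expect_equal(attr(fp, "n_retained"), length(brute))
  expect_warning(empty <- filter_cells(pam, 10000), "no cells")
  expect_equal(length(empty$cells), 0)
})

test_that("write_pam round-trips through wide CSV and triplet text", {
  pam <- pam_from_lists(c("0:0", "1:0"),
                        list(c("A a", "B b"), c("B b")))
  fc <- tempfile(fileext = ".csv"); ft <- tempfile(fileext = ".mtx")
  write_pam(pam, fc, ft)
  wide <- utils::read.csv(fc, check.names = FALSE)
  expect_equal(wide$cell_id, pam$cells)
  expect_equal(as.matrix(wide[, -1]), pam$counts,
               ignore_attr = TRUE)
  trip <- readLines(ft)
  expect_match(trip[1], "MatrixMarket")
  expect_equal(as.integer(strsplit(trip[2], " ")[[1]]), c(2L, 2L, 3L))
})
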