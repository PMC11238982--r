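#' Read occurrence records from delimited text
#'
#' Ingests a Darwin Core-style export into a typed record table. Column names
#' are resolved through \code{column_map} so exports with different header
#' conventions can be read without editing the file. Unparseable coordinates,
#' depths or dates become missing values rather than errors: cleaning, not
#' ingestion, is where records are judged.
#'
#' @param path delimited text file.
#' @param column_map named character vector mapping internal names
#'   (\code{scientific_name}, \code{taxon_rank}, \code{latitude},
#'   \code{longitude}, \code{event_date}, \code{depth_min}, \code{depth_max},
#'   \code{source_id}) to file column names. Defaults cover Darwin Core terms.
#' @param sep field separator (default comma).
#' @return data.frame with the internal columns; class \code{record_table}.
#' @export
read_occurrences <- function(path,
                             column_map = c(
                               scientific_name = "scientificName",
                               taxon_rank = "taxonRank",
                               latitude = "decimalLatitude",
                               longitude = "decimalLongitude",
                               event_date = "eventDate",
                               depth_min = "depthMin",
                               depth_max = "depthMax",
                               source_id = "source_id"),
                             sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!column_map[["scientific_name"]] %in% names(raw))
    stop("missing scientific_name column: ", column_map[["scientific_name"]])
  get <- function(key) {
    cn <- column_map[key]
    if (!is.na(cn) && cn %in% names(raw)) raw[[cn]] else rep(NA_character_, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    scientific_name = get("scientific_name"),
    taxon_rank = tolower(trimws(get("taxon_rank"))),
    latitude = num(get("latitude")),
    longitude = num(get("longitude")),
    event_date = as.Date(suppressWarnings(
      as.Date(get("event_date"), format = "%Y-%m-%d")), origin = "1970-01-01"),
    depth_min = num(get("depth_min")),
    depth_max = num(get("depth_max")),
    source_id = get("source_id"),
    stringsAsFactors = FALSE)
  out$latitude[!is.na(out$latitude) &
                 (out$latitude < -90 | out$latitude > 90)] <- NA_real_
  class(out) <- c("record_table", "data.frame")
  out
}

#' Is a name binomial?
#'
#' Heuristic used when taxon_rank is absent: exactly two tokens, the second
#' all lowercase letters/digits.
#' @param x character vector of names.
#' @return logical vector.
#' @export
is_binomial <- function(x) {
  grepl("^[A-Z][A-Za-z-]+ [a-z][a-z0-9.-]*$", trimws(x))
}

#' Clean occurrence records
#'
#' Applies the standard curation rules for aggregated occurrence downloads,
#' in a fixed order; each dropped record is attributed to the first rule it
#' violates, so the report counts partition the input exactly. Rules:
#' \enumerate{
#'   \item \code{missing_coords}: latitude or longitude missing;
#'   \item \code{zero_coords}: the (0, 0) coordinate pair;
#'   \item \code{on_land}: inside the supplied land-mask polygon(s);
#'   \item \code{outside_basin}: outside the supplied basin polygon(s);
#'   \item \code{non_species_rank}: taxon_rank not "species" (or, when rank
#'     is missing, name fails the binomial heuristic — logged);
#'   \item \code{outside_depth}: depth-interval midpoint outside the window;
#'   \item \code{outside_period}: event year outside the study period
#'     (dateless records pass);
#'   \item \code{duplicate}: identical (name, coordinates rounded to 4
#'     decimals, date, depth midpoint) tuple; first occurrence kept.
#' }
#'
#' @param records a \code{record_table}.
#' @param depth_window numeric c(min, max) metres; default c(0, 200), the
#'   epipelagic layer.
#' @param period integer c(first, last) year, or NULL to skip.
#' @param land_mask,basin_polygon polygon lists as returned by
#'   \code{\link{read_geojson_polygons}}, or NULL to skip those rules.
#' @param apply_land,apply_basin set TRUE to require the corresponding mask;
#'   an absent mask then errors naming the rule.
#' @return list with \code{records} (survivors) and \code{report} (a
#'   \code{cleaning_report}: per-rule drop counts, input/output totals).
#' @export
clean_records <- function(records, depth_window = c(0, 200),
                          period = c(1993L, 2019L),
                          land_mask = NULL, basin_polygon = NULL,
                          apply_land = !is.null(land_mask),
                          apply_basin = !is.null(basin_polygon)) {
  if (apply_land && is.null(land_mask))
    stop("rule on_land requested but no land_mask supplied")
  if (apply_basin && is.null(basin_polygon))
    stop("rule outside_basin requested but no basin_polygon supplied")

  n_in <- nrow(records)
  rules <- c("missing_coords", "zero_coords", "on_land", "outside_basin",
             "non_species_rank", "outside_depth", "outside_period",
             "duplicate")
  dropped <- stats::setNames(integer(length(rules)), rules)
  keep <- rep(TRUE, n_in)
  drop_by <- function(bad, rule) {
    bad <- bad & keep
    dropped[[rule]] <<- sum(bad)
    keep[bad] <<- FALSE
  }

  drop_by(is.na(records$latitude) | is.na(records$longitude),
          "missing_coords")
  drop_by(records$latitude == 0 & records$longitude == 0, "zero_coords")
  if (apply_land)
    drop_by(point_in_polygons(records$longitude, records$latitude, land_mask),
            "on_land")
  if (apply_basin)
    drop_by(!point_in_polygons(records$longitude, records$latitude,
                               basin_polygon), "outside_basin")
  rank_known <- !is.na(records$taxon_rank) & nzchar(records$taxon_rank)
  bad_rank <- (rank_known & records$taxon_rank != "species") |
    (!rank_known & !is_binomial(records$scientific_name))
  if (any(!rank_known & keep))
    message(sum(!rank_known & keep),
            " record(s) judged by the binomial-name heuristic (no taxon_rank)")
  drop_by(bad_rank, "non_species_rank")
  mid <- depth_midpoint(records$depth_min, records$depth_max)
  drop_by(!is.na(mid) & (mid < depth_window[1] | mid > depth_window[2]),
          "outside_depth")
  if (!is.null(period)) {
    yr <- as.integer(format(records$event_date, "%Y"))
    drop_by(!is.na(yr) & (yr < period[1] | yr > period[2]), "outside_period")
  }
  key <- paste(records$scientific_name,
               round(records$longitude, 4), round(records$latitude, 4),
               records$event_date, round(mid, 4), sep = "|")
  key[!keep] <- paste0("dropped|", seq_len(n_in)[!keep])
  drop_by(duplicated(key), "duplicate")

  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- structure(list(input = n_in, output = nrow(out),
                           dropped = as.list(dropped)),
                      class = "cleaning_report")
  stopifnot(report$input == report$output + sum(unlist(report$dropped)))
  list(records = out, report = report)
}

depth_midpoint <- function(dmin, dmax) {
  mid <- (dmin + dmax) / 2
  mid[is.na(dmin) & !is.na(dmax)] <- dmax[is.na(dmin) & !is.na(dmax)]
  mid[!is.na(dmin) & is.na(dmax)] <- dmin[!is.na(dmin) & is.na(dmax)]
  mid
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("cleaning report:", x$input, "in,", x$output, "out\n")
  for (r in names(x$dropped))
    if (x$dropped[[r]] > 0) cat(sprintf("  %-18s %d\n", r, x$dropped[[r]]))
  invisible(x)
}

#' Harmonize taxonomy through an offline synonym table
#'
#' Replaces names by their accepted names, following chains (synonym of a
#' synonym) to a fixed point. Cyclic chains are an error; names absent from
#' the table pass through unchanged and are counted in the
#' \code{n_unmatched} attribute.
#'
#' @param records a \code{record_table}.
#' @param synonym_table data.frame with columns \code{name},
#'   \code{accepted_name}.
#' @return the record table with harmonized \code{scientific_name}.
#' @export
harmonize_taxonomy <- function(records, synonym_table) {
  stopifnot(all(c("name", "accepted_name") %in% names(synonym_table)))
  map <- stats::setNames(as.character(synonym_table$accepted_name),
                         as.character(synonym_table$name))
  resolve <- function(nm) {
    seen <- character()
    while (nm %in% names(map) && map[[nm]] != nm) {
      if (nm %in% seen) stop("cyclic synonym chain involving: ", nm)
      seen <- c(seen, nm)
      nm <- map[[nm]]
    }
    nm
  }
  uniq <- unique(records$scientific_name)
  resolved <- vapply(uniq, resolve, character(1))
  records$scientific_name <- unname(resolved[match(records$scientific_name, uniq)])
  attr(records, "n_unmatched") <- sum(!uniq %in% names(map))
  records
}

#' Assign records to grid cells
#'
#' Each record gains a \code{cell_id}: longitudes are wrapped into
#' [-180, 180), then floored to the cell size; cells are half-open so a
#' record exactly on an edge belongs to the cell whose south-west corner is
#' the floored coordinate. Idempotent.
#'
#' @param records cleaned \code{record_table}.
#' @param spec a \code{\link{grid_spec}}.
#' @return the table with a \code{cell_id} column.
#' @export
assign_cells <- function(records, spec = grid_spec()) {
  records$cell_id <- cell_id_from_coords(records$longitude,
                                         records$latitude, spec)
  records
}

#' Build the presence-absence matrix
#'
#' @param records gridded records (after \code{\link{assign_cells}}).
#' @return object of class \code{pam}: list with \code{cells},
#'   \code{species}, binary \code{incidence} and integer \code{counts}
#'   matrices (cells x species). Species columns with no occurrences cannot
#'   arise by construction.
#' @export
build_pam <- function(records) {
  stopifnot("cell_id" %in% names(records), nrow(records) > 0)
  cells <- sort(unique(records$cell_id))
  species <- sort(unique(records$scientific_name))
  counts <- unclass(table(factor(records$cell_id, cells),
                          factor(records$scientific_name, species)))
  counts <- matrix(as.integer(counts), nrow = length(cells),
                   dimnames = list(cells, species))
  new_pam(counts)
}

new_pam <- function(counts) {
  structure(list(cells = rownames(counts), species = colnames(counts),
                 incidence = (counts > 0) * 1L, counts = counts),
            class = "pam_matrix")
}

#' @export
print.pam_matrix <- function(x, ...) {
  cat(sprintf("pam: %d cells x %d species, %d records\n",
              length(x$cells), length(x$species), sum(x$counts)))
  invisible(x)
}

#' Filter PAM cells by richness and longitude band
#'
#' Drops cells with fewer than \code{min_richness} species and, optionally,
#' cells whose center longitude falls in a poorly sampled longitudinal band
#' (band given as c(lo, hi) in degrees, order-free; membership tested on the
#' wrapped center).
#'
#' @param pam a \code{pam}.
#' @param min_richness minimum species per retained cell (default 10,
#'   the usual threshold for interpolation-quality cells).
#' @param excluded_lon_band NULL or numeric c(lo, hi).
#' @param spec grid spec for cell centers.
#' @return filtered \code{pam} (species with no remaining occurrences are
#'   dropped); attribute \code{n_retained}. Empty result warns.
#' @export
filter_cells <- function(pam, min_richness = 10, excluded_lon_band = NULL,
                         spec = grid_spec()) {
  rich <- rowSums(pam$incidence)
  keep <- rich >= min_richness
  if (!is.null(excluded_lon_band)) {
    lo <- min(excluded_lon_band); hi <- max(excluded_lon_band)
    ctr <- cell_center(pam$cells, spec)$lon
    keep <- keep & !(ctr >= lo & ctr <= hi)
  }
  counts <- pam$counts[keep, , drop = FALSE]
  if (nrow(counts) == 0) {
    warning("no cells retained by filter_cells")
    out <- new_pam(counts)
  } else {
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
    out <- new_pam(counts)
  }
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Write a PAM as wide CSV and sparse triplet text
#'
#' @param pam a \code{pam}.
#' @param path_csv wide CSV path (cells as rows) or NULL.
#' @param path_triplet sparse MTX-style triplet path or NULL.
#' @return invisibly, the paths written.
#' @export
write_pam <- function(pam, path_csv = NULL, path_triplet = NULL) {
  if (!is.null(path_csv)) {
    df <- data.frame(cell_id = pam$cells, pam$counts, check.names = FALSE)
    utils::write.csv(df, path_csv, row.names = FALSE)
  }
  if (!is.null(path_triplet)) {
    idx <- which(pam$counts > 0, arr.ind = TRUE)
    con <- file(path_triplet, "w")
    writeLines("%%MatrixMarket matrix coordinate integer general", con)
    writeLines(sprintf("%d %d %d", nrow(pam$counts), ncol(pam$counts),
                       nrow(idx)), con)
    writeLines(sprintf("%d %d %d", idx[, 1], idx[, 2],
                       pam$counts[idx]), con)
    close(con)
  }
  invisible(c(path_csv, path_triplet))
}
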