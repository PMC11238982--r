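#' Validate and normalize a pipeline run configuration
#'
#' Checks a configuration list (or plain-text \code{key = value} file read
#' with \code{\link{read_config}}) and fills documented defaults: 1-degree
#' grid, 0-200 m depth window, 1993-2019 period, the -170..-110 longitude
#' exclusion band, a 10-species minimum per interpolation cell, queen
#' weights, Poisson richness family and logit-Gaussian composition family.
#' Every problem is reported by offending key; normalization is idempotent.
#'
#' @param config named list. Recognized keys: \code{occurrences},
#'   \code{env}, \code{masks}, \code{synonyms} (paths, optional but must
#'   exist if given); \code{cell_size}, \code{lon_range}, \code{lat_range},
#'   \code{depth_window}, \code{period}, \code{exclude_lon_band},
#'   \code{min_richness}, \code{weights}, \code{family_richness},
#'   \code{family_composition}, \code{seed}, \code{outdir},
#'   \code{synthetic} (logical: generate inputs).
#' @return normalized config (class \code{run_config}), or an error listing
#'   every offending key.
#' @export
validate_config <- function(config) {
  if (inherits(config, "run_config")) config <- unclass(config)
  if (!is.list(config)) stop("config must be a list")
  errors <- character()
  defaults <- list(cell_size = 1, lon_range = c(-180, 180),
                   lat_range = c(-60, 0), depth_window = c(0, 200),
                   period = c(1993L, 2019L),
                   exclude_lon_band = c(-170, -110), min_richness = 10,
                   weights = "queen", family_richness = "poisson",
                   family_composition = "gaussian_logit", seed = 1L,
                   synthetic = TRUE, outdir = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$outdir)) errors <- c(errors, "outdir: required")
  for (k in c("occurrences", "env", "masks", "synonyms"))
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      errors <- c(errors, paste0(k, ": path does not exist: ", config[[k]]))
  num2 <- function(k) {
    v <- suppressWarnings(as.numeric(config[[k]]))
    if (length(v) != 2 || anyNA(v))
      errors <<- c(errors, paste0(k, ": must be two numbers"))
    v
  }
  config$depth_window <- num2("depth_window")
  config$period <- as.integer(num2("period"))
  config$lon_range <- num2("lon_range")
  config$lat_range <- num2("lat_range")
  if (!is.null(config$exclude_lon_band))
    config$exclude_lon_band <- num2("exclude_lon_band")
  config$seed <- suppressWarnings(as.integer(config$seed))
  if (is.na(config$seed)) errors <- c(errors, "seed: must be an integer")
  if (!config$weights %in% c("queen", "band"))
    errors <- c(errors, "weights: must be 'queen' or 'band'")
  if (!config$family_richness %in% c("poisson", "gaussian"))
    errors <- c(errors, "family_richness: must be poisson or gaussian")
  if (!config$family_composition %in% c("gaussian_logit", "gaussian"))
    errors <- c(errors,
                "family_composition: must be gaussian_logit or gaussian")
  if (length(errors)) stop("invalid config:\n  ",
                           paste(errors, collapse = "\n  "))
  config <- config[order(names(config))]
  class(config) <- "run_config"
  config
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form \code{key = value}; values with commas become vectors;
#' blank lines and \code{#} comments ignored.
#'
#' @param path file path.
#' @return named list (unvalidated).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("bad config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums
    else if (val %in% c("TRUE", "FALSE")) as.logical(val)
    else val
  }
  out
}

.manifest_add <- function(state, stage, path) {
  state$manifest[[length(state$manifest) + 1L]] <- list(
    stage = stage, path = path,
    md5 = unname(tools::md5sum(path)),
    seed = state$config$seed,
    version = as.character(utils::packageVersion("oceandiv")))
  invisible(state)
}

#' Run the full analysis pipeline
#'
#' Executes the study stages in dependency order — simulate (when no
#' occurrence path is configured), clean, grid/PAM, diversity, sampling
#' effort, hotspots, environment, variable selection, GAM+RAC, GDM and
#' composition mapping — writing every artifact under \code{outdir} and a
#' JSON manifest listing each output with its stage, md5 checksum, seed and
#' package version. A stage failure halts the run with the stage name after
#' writing the partial manifest.
#'
#' @param config a validated \code{run_config} (or a list, validated here).
#' @param stages subset of stage names to run (default all, in order).
#' @return invisibly, the manifest (list of artifact entries).
#' @export
run_pipeline <- function(config, stages = NULL) {
  config <- validate_config(config)
  all_stages <- c("simulate", "clean", "pam", "diversity", "effort",
                  "hotspots", "environment", "select", "gam_rac", "gdm")
  if (is.null(stages)) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  state$config <- config
  state$manifest <- list()
  spec <- grid_spec(config$cell_size, config$lon_range, config$lat_range)
  state$spec <- spec
  out <- function(f) file.path(config$outdir, f)

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible())
    t0 <- Sys.time()
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      jsonlite::write_json(state$manifest, out("manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }

  run_stage("simulate", function() {
    if (!is.null(config$occurrences)) return()
    if (!isTRUE(config$synthetic))
      stop("no occurrences path and synthetic = FALSE")
    env_stack <- make_env_fields(spec, n_time_slices = 4,
                                 seed = config$seed)
    envm <- aggregate_mean(env_stack, config$depth_window, config$period)
    pool <- make_species_pool(seed = config$seed)
    effort <- make_effort_field(grid_cells(spec), seed = config$seed)
    rec <- simulate_occurrences(envm, pool, effort, dirty_fraction = 0.05,
                                seed = config$seed, spec = spec,
                                period = config$period)
    truth <- ground_truth(envm, pool, effort)
    utils::write.csv(env_stack, out("env_stack.csv"), row.names = FALSE)
    utils::write.csv(rec, out("occurrences_raw.csv"), row.names = FALSE)
    utils::write.csv(truth, out("ground_truth.csv"), row.names = FALSE)
    state$env_stack <- env_stack
    state$raw_path <- out("occurrences_raw.csv")
    for (f in c("env_stack.csv", "occurrences_raw.csv", "ground_truth.csv"))
      .manifest_add(state, "simulate", out(f))
  })

  run_stage("clean", function() {
    path <- config$occurrences %||% state$raw_path
    if (is.null(path)) stop("no occurrence records available")
    rec <- read_occurrences(path)
    cl <- clean_records(rec, depth_window = config$depth_window,
                        period = config$period)
    if (!is.null(config$synonyms)) {
      syn <- utils::read.csv(config$synonyms, stringsAsFactors = FALSE)
      cl$records <- harmonize_taxonomy(cl$records, syn)
    }
    state$records <- cl$records
    utils::write.csv(cl$records, out("occurrences_clean.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(cl$report), out("cleaning_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    .manifest_add(state, "clean", out("occurrences_clean.csv"))
    .manifest_add(state, "clean", out("cleaning_report.json"))
  })

  run_stage("pam", function() {
    rec <- assign_cells(state$records, spec)
    state$records <- rec
    pam <- build_pam(rec)
    state$pam <- pam
    state$pam_filtered <- filter_cells(pam, config$min_richness,
                                       config$exclude_lon_band, spec)
    write_pam(pam, out("pam_wide.csv"), out("pam_triplet.mtx"))
    .manifest_add(state, "pam", out("pam_wide.csv"))
    .manifest_add(state, "pam", out("pam_triplet.mtx"))
  })

  run_stage("diversity", function() {
    pam <- state$pam
    alpha <- alpha_richness(pam)
    shan <- shannon_index(pam)
    beta <- beta_per_cell(pam)
    red <- redundancy_index(pam)
    div <- data.frame(cell_id = pam$cells, alpha = alpha$value,
                      shannon = shan$value,
                      beta_sor = beta$beta_sor$value,
                      beta_sim = beta$beta_sim$value,
                      beta_sne = beta$beta_sne$value,
                      redundancy = red$value)
    state$diversity <- div
    utils::write.csv(div, out("diversity.csv"), row.names = FALSE)
    dom <- dominant_species(state$records, k = 10)
    utils::write.csv(dom, out("dominant_species.csv"), row.names = FALSE)
    .manifest_add(state, "diversity", out("diversity.csv"))
    .manifest_add(state, "diversity", out("dominant_species.csv"))
  })

  run_stage("effort", function() {
    freq <- as.integer(table(state$records$scientific_name))
    curve <- rarefy_extrapolate(freq, n_boot = 50, seed = config$seed)
    utils::write.csv(curve, out("rarefaction.csv"), row.names = FALSE)
    .manifest_add(state, "effort", out("rarefaction.csv"))
    if (!is.null(config$masks)) {
      regions <- read_geojson_polygons(config$masks)
      cov <- region_coverage(spec, regions, state$records)
      utils::write.csv(cov, out("coverage.csv"), row.names = FALSE)
      .manifest_add(state, "effort", out("coverage.csv"))
    }
  })

  run_stage("hotspots", function() {
    pam <- state$pam
    rich <- rowSums(pam$incidence)
    wg <- build_weights(pam$cells, scheme = config$weights,
                        include_self = TRUE, spec = spec)
    hs <- getis_ord_gstar(rich, wg)
    w0 <- build_weights(pam$cells, scheme = config$weights, spec = spec)
    mi <- morans_i(rich, w0, n_perm = 199, seed = config$seed)
    utils::write.csv(hs, out("hotspots.csv"), row.names = FALSE)
    jsonlite::write_json(mi, out("moran_richness.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    .manifest_add(state, "hotspots", out("hotspots.csv"))
    .manifest_add(state, "hotspots", out("moran_richness.json"))
  })

  run_stage("environment", function() {
    stack <- if (!is.null(state$env_stack)) state$env_stack
    else if (!is.null(config$env))
      utils::read.csv(config$env, stringsAsFactors = FALSE)
    else stop("no environmental stack: supply 'env' or run synthetically")
    envm <- aggregate_mean(stack, config$depth_window, config$period)
    ts <- temperature_deviation_stability(stack)
    envm <- merge(envm, ts, by = "cell_id")
    state$env_raw <- envm
    envz <- standardize_env(envm,
                            setdiff(names(envm), c("cell_id", "T_stab")))
    state$env <- envz
    rho <- spearman_matrix(envm, setdiff(names(envm), "cell_id"))
    utils::write.csv(envz, out("env_table.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(rho), out("env_spearman.csv"))
    .manifest_add(state, "environment", out("env_table.csv"))
    .manifest_add(state, "environment", out("env_spearman.csv"))
  })

  model_frame <- function() {
    pam <- state$pam_filtered
    if (length(pam$cells) < 30) pam <- state$pam   # tiny synthetic grids
    cells <- intersect(pam$cells, state$env$cell_id)
    keep <- match(cells, pam$cells)
    sub <- new_pam(pam$counts[keep, , drop = FALSE])
    ev <- state$env[match(cells, state$env$cell_id), , drop = FALSE]
    ok <- stats::complete.cases(ev)
    if (sum(!ok) > 0) message(sum(!ok), " cell(s) dropped: missing predictors")
    list(pam = new_pam(sub$counts[ok, , drop = FALSE]),
         env = ev[ok, , drop = FALSE])
  }

  run_stage("select", function() {
    mf <- model_frame()
    state$mf <- mf
    rich <- rowSums(mf$pam$incidence)
    vars <- setdiff(names(mf$env), "cell_id")
    sel <- rf_select(mf$env[vars], rich, n_trees = 60, n_runs = 3,
                     seed = config$seed)
    state$selected <- if (length(sel$selected) >= 2) sel$selected
    else utils::head(sel$ranking$variable, 3)
    utils::write.csv(sel$ranking, out("variable_ranking.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(selected = state$selected,
                              threshold = sel$threshold),
                         out("variable_selection.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .manifest_add(state, "select", out("variable_ranking.csv"))
    .manifest_add(state, "select", out("variable_selection.json"))
  })

  run_stage("gam_rac", function() {
    mf <- state$mf %||% model_frame()
    state$mf <- mf
    rich <- rowSums(mf$pam$incidence)
    sel <- state$selected %||% utils::head(
      setdiff(names(mf$env), "cell_id"), 3)
    wg <- build_weights(mf$pam$cells, scheme = config$weights, spec = spec)
    fit <- fit_gam_rac(rich, mf$env[sel], wg,
                       family = config$family_richness,
                       n_perm = 99, seed = config$seed)
    beta <- beta_per_cell(mf$pam)
    comp <- beta$beta_sor$value
    okc <- !is.na(comp)
    fitc <- NULL
    if (sum(okc) >= 30) {
      wgc <- build_weights(mf$pam$cells[okc], scheme = config$weights,
                           spec = spec)
      fitc <- fit_gam_rac(comp[okc], mf$env[okc, sel, drop = FALSE], wgc,
                          family = config$family_composition,
                          n_perm = 99, seed = config$seed)
    }
    # candidate table: nested predictor sets, all with RAC
    cands <- lapply(seq_along(sel), function(k) sel[seq_len(k)])
    names(cands) <- vapply(cands, paste, "", collapse = "+")
    tab <- bic_select(cands, function(v) {
      rac <- fit$rac
      fit_gam(rich, cbind(mf$env[v], rac = rac),
              family = config$family_richness, linear_terms = "rac")
    })
    state$gam_rac <- fit
    utils::write.csv(tab, out("model_table_richness.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(richness = list(bic = fit$fit$bic, adj_r2 = fit$fit$adj_r2,
                           moran_before = fit$moran_before[c("I", "p_perm")],
                           moran_after = fit$moran_after[c("I", "p_perm")],
                           r = predicted_vs_observed(fit$fit)$r),
           composition = if (!is.null(fitc))
             list(bic = fitc$fit$bic, adj_r2 = fitc$fit$adj_r2,
                  r = predicted_vs_observed(fitc$fit)$r)),
      out("gam_rac_summary.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    .manifest_add(state, "gam_rac", out("model_table_richness.csv"))
    .manifest_add(state, "gam_rac", out("gam_rac_summary.json"))
  })

  run_stage("gdm", function() {
    mf <- state$mf %||% model_frame()
    vars <- setdiff(names(mf$env), "cell_id")
    pairs <- build_site_pairs(mf$pam, mf$env, predictors = vars,
                              seed = config$seed, spec = spec)
    fit <- fit_gdm(pairs)
    imp <- predictor_importance(fit)
    map <- transform_and_map(fit, mf$env)
    utils::write.csv(imp, out("gdm_importance.csv"), row.names = FALSE)
    utils::write.csv(map, out("composition_rgb.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(deviance_explained = fit$deviance_explained,
           intercept = fit$intercept,
           coefficients = fit$coefficients, knots = fit$knots),
      out("gdm_fit.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .manifest_add(state, "gdm", out("gdm_importance.csv"))
    .manifest_add(state, "gdm", out("composition_rgb.csv"))
    .manifest_add(state, "gdm", out("gdm_fit.json"))
  })

  jsonlite::write_json(state$manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(state$manifest)
}
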