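#' Read and write occupancy matrices as CSV
#'
#' The on-disk form is a CSV with a `patch_id` column followed by one
#' column per survey year (calendar labels), cells in \{0, 1, NA\}. A year
#' column that is entirely `NA` encodes an unsurveyed year; year labels
#' are kept so the gap stays detectable.
#'
#' @param path file path.
#' @param network_ref street label to attach to the series (default: the
#'   file name without extension).
#' @return `read_occupancy()` returns an [occupancy_series()];
#'   `write_occupancy()` returns `path` invisibly.
#' @export
read_occupancy <- function(path, network_ref = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(tab)[1] != "patch_id")
    stop("occupancy CSV must start with a 'patch_id' column")
  if (anyDuplicated(tab$patch_id))
    stop(sprintf("duplicate patch_id in %s: %s", path,
                 paste(unique(tab$patch_id[duplicated(tab$patch_id)]), collapse = ", ")))
  years <- names(tab)[-1]
  if (anyNA(suppressWarnings(as.integer(years))))
    stop("year columns must be integer calendar labels")
  cells <- as.matrix(tab[, -1, drop = FALSE])
  bad <- !(cells %in% c("0", "1", "NA", "")) & !is.na(cells)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(cells)), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid occupancy cell '%s' at patch '%s', year %s",
                 cells[bad][1], tab$patch_id[idx[1]], years[idx[2]]))
  }
  states <- matrix(suppressWarnings(as.numeric(cells)), nrow(cells))
  if (is.null(network_ref))
    network_ref <- sub("\\.[^.]*$", "", basename(path))
  occupancy_series(states, years = as.integer(years),
                   network_ref = network_ref, patch_ids = tab$patch_id)
}

#' @rdname read_occupancy
#' @param series an [occupancy_series()].
#' @export
write_occupancy <- function(series, path) {
  tab <- data.frame(patch_id = rownames(series$states),
                    series$states, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read and write patch networks as CSV
#'
#' Columns `patch_id,street_id,x_m,y_m` (header required, UTF-8, '.'
#' decimal separator).
#'
#' @param path file path.
#' @return `read_network()` returns a [patch_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
read_network <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("patch_id", "street_id", "x_m", "y_m")
  if (!all(need %in% names(tab)))
    stop(sprintf("network CSV must have columns: %s", paste(need, collapse = ", ")))
  if (length(unique(tab$street_id)) != 1)
    stop("a network CSV must describe a single street")
  patch_network(tab$patch_id, x = tab$x_m, y = tab$y_m,
                street_id = tab$street_id[1])
}

#' @rdname read_network
#' @param network a [patch_network()].
#' @export
write_network <- function(network, path) {
  tab <- data.frame(patch_id = network$patch_ids,
                    street_id = network$street_id,
                    x_m = network$coords[, 1], y_m = network$coords[, 2])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

selection_records <- function(selections) {
  do.call(rbind, lapply(selections, function(sel) {
    data.frame(street = sel$street, species = sel$species, best = sel$best,
               row.names = NULL)
  }))
}

#' Run the full pipeline: simulate, fit, select, aggregate, regress
#'
#' Generates a synthetic study from `config`, writes networks and
#' occupancy CSVs, runs four-way model selection for every street-species
#' pair, aggregates best-model proportions by street and by species, fits
#' the two headline proportion regressions (PRM vs distance to the nearest
#' green space; LM+R vs maximum plant height), and writes all outputs plus
#' a manifest (config snapshot, seed, package version, file digests,
#' timestamps) under `out_dir`. Reruns with the same config and seed are
#' identical apart from timestamps.
#'
#' @param config a [study_config()].
#' @param out_dir run directory (created; must not already contain a manifest).
#' @param control a [fit_control()].
#' @param verbose print progress?
#' @return Invisibly, a list with `selections`, `by_street`, `by_species`,
#'   `glm_distance`, `glm_height`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config = study_config(), out_dir = tempfile("spomlab_run_"),
                         control = fit_control(), verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_study(config)
  occ_dir <- file.path(out_dir, "occupancy")
  net_dir <- file.path(out_dir, "networks")
  dir.create(occ_dir, showWarnings = FALSE)
  dir.create(net_dir, showWarnings = FALSE)
  for (nm in names(study$networks))
    write_network(study$networks[[nm]], file.path(net_dir, paste0(nm, ".csv")))
  for (key in names(study$series))
    write_occupancy(study$series[[key]],
                    file.path(occ_dir, paste0(gsub("[^A-Za-z0-9_-]", "_", key), ".csv")))

  selections <- select_all(study, control = control, verbose = verbose)
  records <- selection_records(selections)
  utils::write.csv(records, file.path(out_dir, "best_models.csv"), row.names = FALSE)

  by_street <- model_proportions(records, by = "street")
  by_species <- model_proportions(records, by = "species")
  utils::write.csv(by_street, file.path(out_dir, "proportions_by_street.csv"),
                   row.names = FALSE)
  utils::write.csv(by_species, file.path(out_dir, "proportions_by_species.csv"),
                   row.names = FALSE)

  cov <- study$street_covariates[match(by_street$unit, study$street_covariates$street), ]
  tra <- study$species_traits[match(by_species$unit, study$species_traits$species), ]
  glm_distance <- fit_proportion_glm(by_street$n_PRM, cov$smallest_distance_m,
                                     denom = by_street$denom[1])
  glm_height <- fit_proportion_glm(by_species$`n_LM+R`, tra$max_height_cm,
                                   denom = by_species$denom[1])

  manifest <- list(
    package = "spomlab",
    version = as.character(utils::packageVersion("spomlab")),
    rng_seed = config$rng_seed,
    years = config$years, missing_years = config$missing_years,
    n_streets = nrow(config$streets), n_species = nrow(config$species),
    n_selections = length(selections),
    best_model_counts = as.list(table(records$best)),
    glm = list(
      prm_vs_distance_slope = unname(glm_distance$coefficients["x"]),
      lmr_vs_height_slope = unname(glm_height$coefficients["x"])),
    file_digests = file_digests(out_dir),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(selections = selections, by_street = by_street,
                 by_species = by_species, glm_distance = glm_distance,
                 glm_height = glm_height, manifest = manifest,
                 out_dir = out_dir))
}

# content digests (sum of byte values per file) without external deps
file_digests <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  dig <- vapply(files, function(f) {
    bytes <- readBin(f, "integer", file.info(f)$size, size = 1, signed = FALSE)
    sprintf("%d:%d", length(bytes), sum(as.double(bytes)) %% 2^31)
  }, character(1))
  as.list(stats::setNames(dig, sub(paste0("^", dir, "/?"), "", files)))
}

#' Command-line entry point
#'
#' A thin command dispatcher around the package, used by the
#' `inst/cli/spomlab` script:
#' \describe{
#'   \item{`simulate`}{`--seed <int> --out <dir>`: generate the default
#'     synthetic study and write its CSVs.}
#'   \item{`select`}{`--occupancy <csv> --network <csv> [--species <label>]`:
#'     four-way model selection for one series; prints the AICc table as JSON.}
#'   \item{`pipeline`}{`--seed <int> --out <dir>`: full simulate-fit-select-
#'     aggregate-regress run.}
#'   \item{`reproduce-tables`}{recompute the published ensemble quantities
#'     from the packaged tables; prints the report as JSON.}
#' }
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) stop("usage: spomlab <simulate|select|pipeline|reproduce-tables> [options]")
    cmd <- args[1]
    opts <- parse_cli_opts(args[-1])
    switch(cmd,
      "simulate" = {
        seed <- as.integer(opts_get(opts, "seed", 1))
        out <- opts_get(opts, "out", "spomlab_run")
        study <- generate_study(study_config(rng_seed = seed))
        dir.create(file.path(out, "occupancy"), recursive = TRUE, showWarnings = FALSE)
        dir.create(file.path(out, "networks"), showWarnings = FALSE)
        for (nm in names(study$networks))
          write_network(study$networks[[nm]], file.path(out, "networks", paste0(nm, ".csv")))
        for (key in names(study$series))
          write_occupancy(study$series[[key]],
                          file.path(out, "occupancy", paste0(gsub("[^A-Za-z0-9_-]", "_", key), ".csv")))
        message(sprintf("wrote %d series to %s (seed %d)", length(study$series), out, seed))
      },
      "select" = {
        series <- read_occupancy(opts_get(opts, "occupancy"))
        network <- read_network(opts_get(opts, "network"))
        sel <- select_model(series, network,
                            species = opts_get(opts, "species", NA_character_))
        cat(jsonlite::toJSON(list(street = sel$street, species = sel$species,
                                  best = sel$best, aicc = sel$aicc_table),
                             auto_unbox = TRUE, digits = NA, dataframe = "rows"), "\n")
      },
      "pipeline" = {
        seed <- as.integer(opts_get(opts, "seed", 1))
        out <- opts_get(opts, "out", "spomlab_run")
        res <- run_pipeline(study_config(rng_seed = seed), out_dir = out)
        message(sprintf("pipeline complete: %d selections in %s",
                        length(res$selections), out))
      },
      "reproduce-tables" = {
        rep <- reproduce_published_tables()
        cat(jsonlite::toJSON(list(checks = rep$checks, all_pass = rep$all_pass),
                             auto_unbox = TRUE, digits = NA, dataframe = "rows"), "\n")
        if (!rep$all_pass) stop("some published-value checks failed")
      },
      stop(sprintf("unknown command '%s'", cmd))
    )
    0L
  }, error = function(e) {
    message("spomlab error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop(sprintf("unexpected argument '%s'", args[i]))
    if (i + 1 > length(args)) stop(sprintf("option %s needs a value", args[i]))
    opts[[substring(args[i], 3)]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

opts_get <- function(opts, name, default = NULL) {
  if (!is.null(opts[[name]])) return(opts[[name]])
  if (is.null(default)) stop(sprintf("missing required option --%s", name))
  default
}
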