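#' Generate a linear street network of tree-base patches
#'
#' Patches are laid out along a line at positions `k * spacing` (k = 0, 1,
#' ...) plus independent uniform jitter in `[-jitter, +jitter]` meters,
#' emulating the near-constant spacing of street trees.
#'
#' @param n_patches number of patches, `>= 2`.
#' @param spacing nominal inter-patch distance in meters, `> 0`.
#' @param jitter half-width of the uniform positional jitter in meters, `>= 0`.
#' @param seed optional integer seed for the jitter draw.
#' @param street_id street label.
#' @param origin planar (x, y) offset in meters of the first patch.
#' @return A [patch_network()].
#' @examples
#' generate_network(3, spacing = 10)$dist
#' @export
generate_network <- function(n_patches, spacing, jitter = 0, seed = NULL,
                             street_id = "street", origin = c(0, 0)) {
  if (n_patches < 2) stop("a street needs at least 2 patches")
  if (spacing <= 0) stop("spacing must be > 0")
  if (jitter < 0) stop("jitter must be >= 0")
  x <- (seq_len(n_patches) - 1) * spacing
  if (jitter > 0) {
    x <- x + with_seed(seed, stats::runif(n_patches, -jitter, jitter))
  }
  patch_network(paste0(street_id, "_", seq_len(n_patches)),
                x = origin[1] + x, y = rep(origin[2], n_patches),
                street_id = street_id)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed` (NULL = use
# the current stream), restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable 31-bit hash of a label, for deriving independent substreams per
# (street, species) from one study seed without order dependence.
label_hash <- function(label) {
  codes <- utf8ToInt(label)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

substream_seed <- function(seed, ...) {
  h <- as.integer(seed) %% 2147483647L
  for (lab in c(...)) h <- as.integer((h * 1103 + label_hash(lab)) %% 2147483647)
  h
}

#' A district green space as a point seed source
#'
#' @param name label of the green space.
#' @param x,y planar coordinates in meters.
#' @return An object of class `green_space`.
#' @export
green_space <- function(name, x, y) {
  if (!is.finite(x) || !is.finite(y)) stop("green space coordinates must be finite")
  structure(list(name = as.character(name), location = c(x = x, y = y)),
            class = "green_space")
}

#' Mean distance from a street to its nearest green space
#'
#' For each green space, computes the mean over the street's patches of the
#' patch-to-space Euclidean distance, and returns the smallest of these
#' means together with the green space that attains it.
#'
#' @param network a [patch_network()].
#' @param spaces a list of [green_space()] objects (at least one).
#' @return A list with `distance_m` (the smallest mean distance) and
#'   `nearest` (the name of the argmin green space).
#' @export
street_distance_to_green_spaces <- function(network, spaces) {
  if (inherits(spaces, "green_space")) spaces <- list(spaces)
  if (length(spaces) == 0) stop("at least one green space is required")
  means <- vapply(spaces, function(sp) {
    dx <- network$coords[, 1] - sp$location[["x"]]
    dy <- network$coords[, 2] - sp$location[["y"]]
    mean(sqrt(dx^2 + dy^2))
  }, numeric(1))
  j <- which.min(means)
  list(distance_m = means[[j]],
       nearest = vapply(spaces, `[[`, character(1), "name")[[j]])
}

#' Forward-simulate an occupancy series under a patch occupancy model
#'
#' Annual synchronous Markov-chain update: from the year-t state `O(t)`,
#' every patch's colonization probability `C_i(t)` (constant under PRM,
#' connectivity-driven under LM) and extinction probability `E_i(t)` are
#' computed, then each patch draws its year-(t+1) state independently —
#' empty patches become occupied with probability `C_i(t)`, occupied
#' patches go extinct with probability `E_i(t)`.
#'
#' @param network a [patch_network()].
#' @param spec a [model_spec()].
#' @param params a [spom_params()] valid for `spec`.
#' @param initial 0/1 vector of starting occupancy (no `NA`).
#' @param n_steps number of annual transitions to simulate, `>= 1`.
#' @param seed optional integer seed (reproducible output for a given seed).
#' @param start_year calendar label of the initial state.
#' @param base_extinction passed to [extinction_prob()].
#' @return An [occupancy_series()] with `n_steps + 1` year columns.
#' @examples
#' net <- generate_network(10, spacing = 8, street_id = "S")
#' sim <- simulate_series(net, model_spec("PRM"), spom_params(C = 0.3, E = 0.2),
#'                        initial = rep(0, 10), n_steps = 6, seed = 1)
#' @export
simulate_series <- function(network, spec, params, initial, n_steps,
                            seed = NULL, start_year = 2009L,
                            base_extinction = "eq5") {
  np <- n_patches(network)
  if (length(initial) != np) stop("initial occupancy length must equal patch count")
  if (anyNA(initial)) stop("initial occupancy must not contain NA")
  if (!all(initial %in% c(0, 1))) stop("initial occupancy must be 0/1")
  if (n_steps < 1) stop("n_steps must be >= 1")
  check_params(spec, params)

  with_seed(seed, {
    states <- matrix(NA_real_, np, n_steps + 1)
    states[, 1] <- initial
    for (t in seq_len(n_steps)) {
      O <- states[, t]
      S <- if (spec$family == "LM") connectivity(O, network, params[["alpha"]]) else NULL
      Cit <- colonization_prob(spec, params, S_i = if (is.null(S)) rep(NA_real_, np) else S)
      Eit <- extinction_prob(spec, params, Cit, base_extinction = base_extinction)
      u <- stats::runif(np)
      states[, t + 1] <- ifelse(O == 0, as.numeric(u < Cit), as.numeric(u >= Eit))
    }
    occupancy_series(states, years = start_year + 0:n_steps,
                     network_ref = network$street_id,
                     patch_ids = network$patch_ids)
  })
}

#' Blank unsurveyed years in an occupancy series
#'
#' Sets the named year columns to `NA` while keeping the year labels, so
#' the survey gap remains detectable (as in a census year lost for lack of
#' observers).
#'
#' @param series an [occupancy_series()].
#' @param missing year labels to blank; must be a subset of `series$years`.
#' @return The series with those columns unobserved.
#' @export
apply_missing_years <- function(series, missing) {
  missing <- as.integer(missing)
  unknown <- setdiff(missing, series$years)
  if (length(unknown))
    stop(sprintf("unknown year label(s): %s", paste(unknown, collapse = ", ")))
  series$states[, as.character(missing)] <- NA_real_
  series
}

#' Configuration of a full synthetic street-flora study
#'
#' Describes a multi-street, multi-species occupancy study: street layouts,
#' species with their generating models and traits, survey years and the
#' years lost to missing surveys. The defaults reproduce the design of the
#' Bercy district survey: 15 streets whose tree-base counts (31-186, total
#' 1,324) and green-space distances follow the published street table, 15
#' species with the published trait values, yearly surveys 2009-2015 with
#' 2013 unsurveyed.
#'
#' @param streets data.frame with columns `name`, `n_patches`,
#'   `patch_spacing_m`, `green_space_distance_m`, `nearest_green_space`.
#' @param species data.frame with columns `name`, `family`, `rescue`,
#'   `C`, `E`, `alpha`, `y`, `R` (NA where a parameter does not apply),
#'   `longevity_class` (1 short-term, 2 long-term), `max_height_cm`.
#' @param years survey-year labels.
#' @param missing_years subset of `years` that was not surveyed.
#' @param initial_occupancy_prob per-patch probability of initial presence.
#' @param jitter_m positional jitter of patches along the street, meters.
#' @param rng_seed integer master seed for the whole study.
#' @return An object of class `study_config`.
#' @export
study_config <- function(streets = default_streets(),
                         species = default_species(),
                         years = 2009:2015,
                         missing_years = 2013L,
                         initial_occupancy_prob = 0.2,
                         jitter_m = 1,
                         rng_seed = 1L) {
  stopifnot(is.data.frame(streets), is.data.frame(species))
  if (anyDuplicated(streets$name)) stop("duplicate street names")
  if (anyDuplicated(species$name)) stop("duplicate species names")
  if (any(streets$n_patches < 2)) stop("every street needs >= 2 patches")
  if (!all(missing_years %in% years)) stop("missing_years must be a subset of years")
  if (initial_occupancy_prob < 0 || initial_occupancy_prob > 1)
    stop("initial_occupancy_prob must lie in [0, 1]")
  if (length(setdiff(years, missing_years)) < 2)
    stop("at least 2 surveyed years are required")
  structure(
    list(streets = streets, species = species, years = as.integer(years),
         missing_years = as.integer(missing_years),
         initial_occupancy_prob = initial_occupancy_prob,
         jitter_m = jitter_m, rng_seed = as.integer(rng_seed)),
    class = "study_config"
  )
}

#' @rdname study_config
#' @export
default_streets <- function() {
  data.frame(
    name = c("BARO", "BATA", "BERC", "BERY", "CHAR", "DAUM", "KESS", "LACH",
             "MONT", "POMM", "RAPE", "RBER", "REUI", "TAIN", "TERR"),
    n_patches = c(62L, 31L, 126L, 99L, 144L, 186L, 69L, 31L, 52L, 39L, 97L,
                  136L, 145L, 62L, 45L),
    patch_spacing_m = 8,
    green_space_distance_m = c(166, 63, 33, 148, 41, 7, 3, 13, 125, 17, 64,
                               88, 224, 38, 177),
    nearest_green_space = c("railways", "railways", "railways", "river",
                            "railways", "footpath", "park", "railways",
                            "footpath", "park", "river", "railways",
                            "footpath", "railways", "river")
  )
}

#' @rdname study_config
#' @export
default_species <- function() {
  sp <- data.frame(
    name = c("Capsella bursa-pastoris", "Chenopodium album", "Conyza canadensis",
             "Hordeum murinum", "Lactuca serriola", "Lolium perenne",
             "Plantago major", "Poa annua", "Polygonum aviculare",
             "Senecio inaequidens", "Senecio vulgaris", "Sisymbrium irio",
             "Sonchus oleraceus", "Stellaria media", "Taraxacum campylodes"),
    longevity_class = c(2L, 2L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 1L, 1L, 2L, 1L, 2L),
    max_height_cm = c(50, 100, 80, 50, 100, 60, 50, 30, 80, 80, 60, 90, 80, 30, 40)
  )
  # Generating models chosen to echo the observed best-model mix
  # (~half external propagule rain, ~40% stepwise Levins, a few with rescue).
  fam <- c("LM", "LM", "LM", "LM+R", "PRM", "LM", "PRM", "PRM", "PRM", "PRM",
           "LM", "LM", "PRM", "LM+R", "PRM")
  sp$family <- ifelse(grepl("^PRM", fam), "PRM", "LM")
  sp$rescue <- grepl("\\+R$", fam)
  sp$C <- ifelse(sp$family == "PRM", 0.3, NA_real_)
  sp$alpha <- ifelse(sp$family == "LM", 0.125, NA_real_)
  sp$y <- ifelse(sp$family == "LM", 1, NA_real_)
  sp$E <- 0.2
  sp$R <- ifelse(sp$rescue, 2, NA_real_)
  sp
}

species_spec <- function(row) model_spec(row$family, rescue = row$rescue)

species_params <- function(row) {
  args <- list(C = row$C, E = row$E, alpha = row$alpha, y = row$y, R = row$R)
  do.call(spom_params, args[!vapply(args, is.na, logical(1))])
}

#' Generate a complete synthetic occupancy study
#'
#' Builds every street network, then simulates one occupancy series per
#' street-species pair under that species' generating model, blanks the
#' unsurveyed years, and assembles the street-covariate and species-trait
#' tables. Initial occupancy is Bernoulli(`initial_occupancy_prob`)
#' conditioned on at least one occupied patch per pair (the study design
#' only retained prevalent species). The master seed is expanded into
#' per-(street, species) substreams by stable label hashing, so results
#' are reproducible and adding a species does not perturb the others.
#'
#' @param config a [study_config()].
#' @return A list of class `synthetic_study` with elements `series` (named
#'   list, one [occupancy_series()] per `street|species`), `networks`
#'   (named list of [patch_network()]), `street_covariates`,
#'   `species_traits` (data.frames) and `config`.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  streets <- config$streets
  species <- config$species
  n_steps <- length(config$years) - 1L

  networks <- lapply(seq_len(nrow(streets)), function(s) {
    generate_network(streets$n_patches[s], streets$patch_spacing_m[s],
                     jitter = config$jitter_m,
                     seed = substream_seed(config$rng_seed, "net", streets$name[s]),
                     street_id = streets$name[s])
  })
  names(networks) <- streets$name

  series <- list()
  for (s in seq_len(nrow(streets))) {
    net <- networks[[s]]
    for (v in seq_len(nrow(species))) {
      row <- species[v, ]
      seed <- substream_seed(config$rng_seed, streets$name[s], row$name)
      init <- with_seed(seed, {
        o <- as.numeric(stats::runif(streets$n_patches[s]) < config$initial_occupancy_prob)
        if (sum(o) == 0) o[sample.int(length(o), 1)] <- 1
        o
      })
      sim <- simulate_series(net, species_spec(row), species_params(row),
                             initial = init, n_steps = n_steps,
                             seed = substream_seed(seed, "sim"),
                             start_year = config$years[1])
      sim <- apply_missing_years(sim, config$missing_years)
      series[[paste(streets$name[s], row$name, sep = "|")]] <- sim
    }
  }

  street_covariates <- data.frame(
    street = streets$name,
    n_tree_bases = streets$n_patches,
    smallest_distance_m = streets$green_space_distance_m,
    nearest_green_space = streets$nearest_green_space
  )
  species_traits <- data.frame(
    species = species$name,
    longevity_class = species$longevity_class,
    max_height_cm = species$max_height_cm,
    generating_model = paste0(species$family, ifelse(species$rescue, "+R", ""))
  )
  structure(list(series = series, networks = networks,
                 street_covariates = street_covariates,
                 species_traits = species_traits, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d streets x %d species = %d series (%d patches total)\n",
              nrow(x$street_covariates), nrow(x$species_traits),
              length(x$series), sum(x$street_covariates$n_tree_bases)))
  invisible(x)
}
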