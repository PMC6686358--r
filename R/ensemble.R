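#' Packaged Bercy district survey tables
#'
#' Load the packaged street-covariate and species-trait tables of the
#' seven-year Bercy district (Paris) tree-base survey, including the
#' published percentage of each street's species (resp. each species'
#' streets) whose dynamics conformed to each model (columns `pct_LM`,
#' `pct_LMR`, `pct_PRM`; PRM with rescue never occurred).
#'
#' @return A data.frame of 15 streets (`bercy_streets()`) or 15 species
#'   (`bercy_species()`).
#' @export
bercy_streets <- function() {
  utils::read.csv(system.file("extdata", "bercy_streets.csv",
                              package = "spomlab", mustWork = TRUE))
}

#' @rdname bercy_streets
#' @export
bercy_species <- function() {
  utils::read.csv(system.file("extdata", "bercy_species.csv",
                              package = "spomlab", mustWork = TRUE))
}

#' Recover an integer count from a printed rounded percentage
#'
#' Inverts the percentage printing of a count out of `denom`: the printed
#' value `pct` maps back to `round(pct * denom / 100)` with halves rounded
#' away from zero. On the published tables (denominator 15) this inversion
#' is exact: re-printing the recovered count reproduces every cell.
#'
#' @param pct printed percentage(s) in `[0, 100]`.
#' @param denom the denominator the percentage was computed from.
#' @return Integer count(s) in `0..denom`.
#' @examples
#' counts_from_percent(73)  # 11 (11/15 = 73.3% prints as 73)
#' @export
counts_from_percent <- function(pct, denom = 15L) {
  if (any(pct < 0 | pct > 100)) stop("percentages must lie in [0, 100]")
  as.integer(floor(pct * denom / 100 + 0.5))
}

#' Best-model counts and proportions per street or per species
#'
#' Aggregates best-model labels over each unit's partners (each street's 15
#' species, or each species' 15 streets) into counts and proportions per
#' model label. Input is either a list of [select_model()] results or a
#' data.frame with columns `street`, `species`, `best`.
#'
#' @param selections selection results or a `street`/`species`/`best`
#'   data.frame.
#' @param by aggregate `"street"`-wise or `"species"`-wise.
#' @return A data.frame of class `ensemble_table`: `unit`, one `n_<label>`
#'   count column and one `p_<label>` proportion column per model label,
#'   and `denom`. Proportions sum to 1 per unit.
#' @export
model_proportions <- function(selections, by = c("street", "species")) {
  by <- match.arg(by)
  if (!is.data.frame(selections)) {
    selections <- data.frame(
      street = vapply(selections, `[[`, character(1), "street"),
      species = vapply(selections, `[[`, character(1), "species"),
      best = vapply(selections, `[[`, character(1), "best"))
  }
  stopifnot(all(c("street", "species", "best") %in% names(selections)))
  if (!all(selections$best %in% MODEL_LABELS))
    stop("unknown best-model label(s)")
  complete <- table(selections$street, selections$species)
  if (any(complete > 1)) stop("duplicate street-species pairs")
  if (any(complete == 0)) {
    miss <- which(complete == 0, arr.ind = TRUE)
    stop(sprintf("missing street-species pair(s): %s",
                 paste(rownames(complete)[miss[, 1]],
                       colnames(complete)[miss[, 2]], sep = "|", collapse = ", ")))
  }
  unit <- selections[[by]]
  counts <- table(unit, factor(selections$best, levels = MODEL_LABELS))
  denom <- unique(rowSums(counts))
  if (length(denom) != 1)
    stop("every unit must have the same number of partners")
  out <- data.frame(unit = rownames(counts))
  for (m in MODEL_LABELS) out[[paste0("n_", m)]] <- as.integer(counts[, m])
  for (m in MODEL_LABELS) out[[paste0("p_", m)]] <- counts[, m] / denom
  out$denom <- as.integer(denom)
  rownames(out) <- NULL
  structure(out, class = c("ensemble_table", "data.frame"), by = by)
}

#' Ensemble table from published percentage columns
#'
#' Converts a fixture table with `pct_LM`, `pct_LMR`, `pct_PRM` columns
#' (and implicitly `pct_PRMR = 0`) into the same form as
#' [model_proportions()], recovering integer counts out of `denom` first.
#'
#' @param tab a data.frame with a unit column and the `pct_*` columns.
#' @param unit_col name of the unit column (e.g. `"street"`, `"species"`).
#' @param denom partner count behind the percentages.
#' @return An `ensemble_table` data.frame.
#' @export
ensemble_from_percent <- function(tab, unit_col, denom = 15L) {
  pct_cols <- c("LM" = "pct_LM", "LM+R" = "pct_LMR", "PRM" = "pct_PRM")
  stopifnot(all(pct_cols %in% names(tab)), unit_col %in% names(tab))
  out <- data.frame(unit = tab[[unit_col]])
  for (m in MODEL_LABELS) {
    out[[paste0("n_", m)]] <-
      if (m %in% names(pct_cols)) counts_from_percent(tab[[pct_cols[[m]]]], denom)
      else 0L
  }
  bad <- which(rowSums(out[paste0("n_", MODEL_LABELS)]) != denom)
  if (length(bad))
    stop(sprintf("recovered counts do not sum to %d for unit(s): %s",
                 denom, paste(out$unit[bad], collapse = ", ")))
  for (m in MODEL_LABELS)
    out[[paste0("p_", m)]] <- out[[paste0("n_", m)]] / denom
  out$denom <- as.integer(denom)
  structure(out, class = c("ensemble_table", "data.frame"), by = unit_col)
}

#' Mean model proportion within trait groups
#'
#' Arithmetic mean, over the species in each level of a trait, of the
#' proportion of streets whose dynamics conformed to a given model (e.g.
#' mean PRM proportion among species with long-term persistent seeds).
#'
#' @param table a species-level `ensemble_table`.
#' @param traits a data.frame with a `species` column and the trait.
#' @param model model label (`"LM"`, `"PRM"`, `"LM+R"`, `"PRM+R"`).
#' @param group_by name of the trait column in `traits`.
#' @return Named numeric vector of group means, one per trait level.
#' @export
group_mean_proportion <- function(table, traits, model = "PRM",
                                  group_by = "longevity_class") {
  stopifnot(model %in% MODEL_LABELS, group_by %in% names(traits))
  idx <- match(table$unit, traits$species)
  if (anyNA(idx))
    stop(sprintf("trait table lacks species: %s",
                 paste(table$unit[is.na(idx)], collapse = ", ")))
  g <- traits[[group_by]][idx]
  if (anyNA(g)) stop("trait undefined for some species")
  means <- tapply(table[[paste0("p_", model)]], g, mean)
  if (any(is.na(means))) stop("empty trait group")
  stats::setNames(as.numeric(means), names(means))
}

#' Quasi-binomial logistic regression of model proportions on a covariate
#'
#' Fits `cbind(successes, denom - successes) ~ covariate` with a
#' quasi-binomial error distribution: binomial-logit point estimates with
#' a free Pearson dispersion scale, the standard treatment of grouped,
#' possibly over/under-dispersed proportions. Point estimates coincide
#' with the plain binomial fit; quasi-likelihood only rescales the
#' standard errors.
#'
#' @param counts successes per unit (best-model counts).
#' @param covariate numeric or binary covariate, one value per unit.
#' @param denom common denominator (partner count per unit).
#' @return An object of class `glm_fit`: `coefficients` (intercept, slope
#'   on the logit scale), `se`, `t`, `p_value` (t reference on
#'   `n_units - 2` df), `dispersion`, `pseudo_r2` (deviance-based),
#'   `n_units`, and the underlying `glm` object.
#' @export
fit_proportion_glm <- function(counts, covariate, denom = 15L) {
  if (length(counts) != length(covariate))
    stop("counts and covariate must have the same length")
  if (length(counts) < 3) stop("need at least 3 units")
  if (length(unique(covariate)) < 2) stop("covariate is constant")
  if (any(counts < 0 | counts > denom)) stop("counts must lie in 0..denom")
  df <- data.frame(s = counts, f = denom - counts, x = covariate)
  fit <- stats::glm(cbind(s, f) ~ x, family = stats::quasibinomial(), data = df)
  if (!fit$converged || any(abs(stats::coef(fit)) > 1e3))
    stop("quasi-binomial fit did not converge (possible complete separation)")
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(coefficients = stats::coef(fit), se = co[, "Std. Error"],
         t = co[, "t value"], p_value = co[, "Pr(>|t|)"],
         dispersion = sm$dispersion,
         pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
         n_units = length(counts), glm = fit),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> quasi-binomial, %d units, dispersion %.3f, pseudo-R2 %.3f\n",
              x$n_units, x$dispersion, x$pseudo_r2))
  print(data.frame(estimate = x$coefficients, se = x$se, t = x$t,
                   p = x$p_value))
  invisible(x)
}

#' Recompute the published ensemble-level quantities from the fixtures
#'
#' From the packaged street and species tables, recovers the per-unit
#' best-model counts, and recomputes: the overall model fractions over the
#' 225 street-species combinations; the mean PRM proportion by
#' seed-longevity class; the quasi-binomial slope of PRM proportion per
#' street on distance to the nearest green space; and the slope of LM+R
#' proportion per species on maximum plant height. Each quantity is
#' compared with its published value at the given tolerances.
#'
#' @param slope_rtol relative tolerance for the two regression slopes.
#' @param mean_atol absolute tolerance for group means and overall shares.
#' @return A list of class `table_report` with elements `overall`
#'   (fractions and counts), `longevity_means`, `slope_distance`,
#'   `slope_height`, `checks` (data.frame of quantity, value, reference,
#'   pass) and `all_pass`.
#' @export
reproduce_published_tables <- function(slope_rtol = 0.05, mean_atol = 0.01) {
  streets <- bercy_streets()
  species <- bercy_species()
  es <- ensemble_from_percent(streets, "street")
  ev <- ensemble_from_percent(species, "species")

  tot <- vapply(MODEL_LABELS, function(m) sum(es[[paste0("n_", m)]]), numeric(1))
  n_comb <- sum(tot)
  overall <- list(counts = tot, n_combinations = n_comb, fractions = tot / n_comb)

  means <- group_mean_proportion(ev, species, model = "PRM",
                                 group_by = "longevity_class")
  g_dist <- fit_proportion_glm(es$n_PRM, streets$smallest_distance_m)
  g_height <- fit_proportion_glm(ev$`n_LM+R`, species$max_height_cm)

  checks <- data.frame(
    quantity = c("overall_LM_share_pct", "n_combinations",
                 "mean_PRM_longterm", "mean_PRM_shortterm",
                 "slope_PRM_vs_distance", "slope_LMR_vs_height",
                 "n_PRMR_overall"),
    value = c(100 * overall$fractions[["LM"]], n_comb,
              means[["2"]], means[["1"]],
              unname(g_dist$coefficients["x"]),
              unname(g_height$coefficients["x"]), tot[["PRM+R"]]),
    reference = c(40, 225, 0.57, 0.43, -0.0048, -0.026, 0)
  )
  tol <- c(mean_atol * 100, 0, mean_atol, mean_atol,
           slope_rtol * 0.0048, slope_rtol * 0.026, 0)
  checks$pass <- abs(checks$value - checks$reference) <= tol
  structure(
    list(overall = overall, longevity_means = means,
         slope_distance = g_dist, slope_height = g_height,
         checks = checks, all_pass = all(checks$pass)),
    class = "table_report"
  )
}

#' @export
print.table_report <- function(x, ...) {
  cat("Recomputed ensemble quantities vs published values:\n")
  print(transform(x$checks, value = signif(value, 5)))
  cat(if (x$all_pass) "All checks pass.\n" else "SOME CHECKS FAIL.\n")
  invisible(x)
}
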