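#' Activity-data coefficient of variation from three dataset variants
#'
#' Quantifies the discrepancy among independently compiled activity
#' datasets (e.g. the city-compiled panel, a national yearbook, an
#' international dataset). Per (city, year, category, subclass) cell with
#' head counts x1, x2, x3, the default reading is
#' `CV = mean(|x_d - mean(x)|) / mean(x)` (mean absolute deviation from
#' the mean, normalised); `method = "pairwise"` uses the mean absolute
#' pairwise difference instead. Category-level CVs are head-count-weighted
#' means over cells; cells with zero or missing mean are skipped with a
#' warning.
#'
#' @param variants List of three aligned activity panels (identical keys).
#' @param method `"mean_absdev"` (default) or `"pairwise"`.
#' @return A `data.table` (`category`, `cv`).
#' @export
activity_cv <- function(variants, method = c("mean_absdev", "pairwise")) {
  method <- match.arg(method)
  stopifnot(length(variants) == 3L)
  keys <- c("city_id", "year", "category", "subclass")
  v <- lapply(variants, function(p) {
    p <- as.data.table(p)
    p[, .(heads = stock_head + slaughtered_head), keyby = keys]
  })
  m <- v[[1L]][, c(keys, "heads"), with = FALSE]
  setnames(m, "heads", "x1")
  m[, x2 := v[[2L]]$heads][, x3 := v[[3L]]$heads]

  m[, mu := (x1 + x2 + x3) / 3]
  bad <- m[is.na(mu) | mu == 0]
  if (nrow(bad)) {
    warning(nrow(bad), " cells with zero or missing mean skipped",
            call. = FALSE)
    m <- m[!is.na(mu) & mu > 0]
  }
  if (method == "mean_absdev") {
    m[, cv_cell := (abs(x1 - mu) + abs(x2 - mu) + abs(x3 - mu)) / 3 / mu]
  } else {
    m[, cv_cell := (abs(x1 - x2) + abs(x1 - x3) + abs(x2 - x3)) / 3 / mu]
  }
  m[, .(cv = sum(cv_cell * mu) / sum(mu)), keyby = category][]
}

#' Monte Carlo specification
#'
#' @param n_sims Number of simulations (>= 100; default 10000).
#' @param seed Integer seed.
#' @param ef_cv Named numeric: per-category CV (sd/mean) of the normal
#'   emission-factor perturbation.
#' @param activity_cv_map Named numeric: per-category CV of the uniform
#'   activity-data perturbation.
#' @param ci_level Confidence level in (0, 1); default 0.95.
#' @param pars Parameter set supplying default CVs for categories absent
#'   from the maps.
#' @return A list of class `ch4_uncertainty_spec`.
#' @export
uncertainty_spec <- function(n_sims = 10000L, seed = 1L, ef_cv = NULL,
                             activity_cv_map = NULL, ci_level = 0.95,
                             pars = default_parameter_set()) {
  n_sims <- as.integer(n_sims)
  if (n_sims < 100L) stop("n_sims must be >= 100", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1)
    stop("ci_level must lie in (0, 1)", call. = FALSE)
  def_ef <- vapply(pars$cvs, `[[`, numeric(1), "ef")
  def_act <- vapply(pars$cvs, `[[`, numeric(1), "activity")
  ef <- def_ef; act <- def_act
  if (!is.null(ef_cv)) ef[names(ef_cv)] <- unlist(ef_cv)
  if (!is.null(activity_cv_map))
    act[names(activity_cv_map)] <- unlist(activity_cv_map)
  if (any(ef < 0) || any(act < 0)) stop("CVs must be >= 0", call. = FALSE)
  structure(list(n_sims = n_sims, seed = as.integer(seed), ef_cv = ef,
                 activity_cv = act, ci_level = ci_level),
            class = "ch4_uncertainty_spec")
}

# deterministic per-category perturbation factor matrices (n_sims x cats).
# activity ~ Uniform(1 - sqrt(3) cv, 1 + sqrt(3) cv) so the draw's CV is cv
# (clipped at 0); EF ~ Normal(1, cv) truncated at 0 by resampling.
mc_factors <- function(spec, categories) {
  ns <- spec$n_sims
  act <- matrix(1, ns, length(categories),
                dimnames = list(NULL, categories))
  ef <- act
  with_seed(spec$seed, {
    for (cc in categories) {
      cv <- spec$activity_cv[[cc]]
      if (is.null(cv) || is.na(cv))
        stop("no activity CV for category ", cc, call. = FALSE)
      hw <- sqrt(3) * cv
      if (hw > 1)
        warning("activity CV ", cv, " for ", cc,
                " puts the uniform lower bound below 0; clipped",
                call. = FALSE)
      if (cv > 0)
        act[, cc] <- pmax(runif(ns, 1 - hw, 1 + hw), 0)
      cvE <- spec$ef_cv[[cc]]
      if (is.null(cvE) || is.na(cvE))
        stop("no EF CV for category ", cc, call. = FALSE)
      if (cvE > 0) {
        x <- rnorm(ns, 1, cvE)
        while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), 1, cvE)
        ef[, cc] <- x
      }
    }
  })
  list(activity = act, ef = ef)
}

#' Draw one simulation's perturbed inputs
#'
#' Returns the activity panel and emission-factor tables perturbed by the
#' `sim_index`-th Monte Carlo draw: one uniform activity factor and one
#' truncated-normal EF factor per category, shared across all cities
#' (systematic-bias convention). Deterministic given
#' `(spec$seed, sim_index)`.
#'
#' @param panel Activity panel.
#' @param enteric_ef,manure_ef Emission-factor tables.
#' @param spec A [uncertainty_spec()].
#' @param sim_index Simulation number in `1:spec$n_sims`.
#' @return List with perturbed `panel`, `enteric_ef`, `manure_ef`.
#' @export
sample_inputs <- function(panel, enteric_ef, manure_ef, spec, sim_index) {
  stopifnot(sim_index >= 1L, sim_index <= spec$n_sims)
  cats <- sort(unique(as.data.table(panel)$category))
  f <- mc_factors(spec, cats)
  af <- f$activity[sim_index, ]; ev <- f$ef[sim_index, ]
  p <- copy(as.data.table(panel))
  p[, `:=`(stock_head = stock_head * af[category],
           slaughtered_head = slaughtered_head * af[category])]
  e <- copy(as.data.table(enteric_ef))
  e[category %in% cats, ef := ef * ev[category]]
  m <- copy(as.data.table(manure_ef))
  m[category %in% cats, ef := ef * ev[category]]
  list(panel = p[], enteric_ef = e[], manure_ef = m[])
}

#' Monte Carlo uncertainty of national annual emissions
#'
#' Propagates activity-data and emission-factor uncertainty through the
#' inventory: per simulation, every category's head counts are scaled by
#' a uniform draw and its emission factors by a truncated-normal draw
#' (both shared across cities, reflecting systematic statistical bias),
#' and national totals per year are recomputed. Because the inventory is
#' bilinear in head counts and emission factors, the recomputation uses
#' the base cube's per-(year, category) contributions scaled by the two
#' factors — algebraically identical to rerunning [compute_emissions()]
#' on the perturbed inputs (a property the test suite verifies). The
#' confidence interval per year is the empirical
#' `(1-ci)/2` / `1-(1-ci)/2` percentile pair of the simulated totals.
#'
#' @param panel Complete activity panel.
#' @param enteric_ef,manure_ef Emission-factor tables.
#' @param climate City-year climate table.
#' @param spec A [uncertainty_spec()].
#' @param pars Parameter set.
#' @return A `data.table` of class `ch4_uncertainty_result`: per year the
#'   point estimate, `ci_low`, `ci_high` (Gg), `rel_low_pct`,
#'   `rel_high_pct` (% deviation from the point estimate), `sim_mean`,
#'   `sim_sd`. The full simulation matrix (n_sims x years) is attached as
#'   attribute `"draws"`.
#' @export
run_monte_carlo <- function(panel, enteric_ef, manure_ef, climate, spec,
                            pars = default_parameter_set()) {
  base <- compute_emissions(panel, enteric_ef, manure_ef, climate, pars)
  contrib <- base$records[, .(emissions_gg = sum(emissions_gg)),
                          keyby = .(year, category)]
  years <- sort(unique(contrib$year))
  cats <- sort(unique(contrib$category))
  M <- matrix(0, length(cats), length(years),
              dimnames = list(cats, as.character(years)))
  M[cbind(match(contrib$category, cats),
          match(contrib$year, years))] <- contrib$emissions_gg

  f <- mc_factors(spec, cats)
  draws <- (f$activity[, cats, drop = FALSE] *
              f$ef[, cats, drop = FALSE]) %*% M   # n_sims x years

  point <- colSums(M)
  alpha <- (1 - spec$ci_level) / 2
  lo <- apply(draws, 2L, quantile, probs = alpha, names = FALSE)
  hi <- apply(draws, 2L, quantile, probs = 1 - alpha, names = FALSE)
  out <- data.table(
    year = years, point_estimate = point, ci_low = lo, ci_high = hi,
    rel_low_pct = 100 * (lo - point) / point,
    rel_high_pct = 100 * (hi - point) / point,
    sim_mean = colMeans(draws), sim_sd = apply(draws, 2L, stats::sd))
  setattr(out, "draws", draws)
  setattr(out, "class", c("ch4_uncertainty_result", class(out)))
  out[]
}

#' @export
print.ch4_uncertainty_result <- function(x, ...) {
  cat("<ch4_uncertainty_result>",
      nrow(attr(x, "draws")), "simulations\n")
  print(as.data.table(x), ...)
  invisible(x)
}
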