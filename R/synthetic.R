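#' Specification for the synthetic activity-data world
#'
#' Describes the panel the generator emulates: a multi-city, multi-year
#' livestock panel with realistic municipal herd-size magnitudes
#' (heavy-tailed, lognormal per category), smooth year-over-year dynamics
#' (multiplicative random walk, |log ratio| <= 0.3), a north-heavier
#' body-weight gradient, a small fraction of cities with no breeding
#' records but with meat production (so gap-filling is exercisable), and
#' three discrepant activity-data variants used to estimate the
#' activity-data CV.
#'
#' @param n_cities Number of cities (default 347).
#' @param n_provinces Number of provinces cities are assigned to
#'   (default 31); must not exceed `n_cities`.
#' @param years Inclusive integer year range within 2000–2030
#'   (default 2010:2020).
#' @param seed Integer seed; all generators are deterministic given it.
#' @param missing_city_fraction Fraction of cities whose stock/slaughter
#'   records are blanked (default 0.05, must be < 0.1).
#' @param category_abundance `data.table` with columns `category`,
#'   `median_head`, `sdlog`, `slaughter_rate`; default
#'   [default_category_abundance()].
#' @param north_south_weight_gradient Multiplier applied to body weights
#'   of northern provinces (default 1.15).
#' @param dataset_discrepancy_cv CV of the multiplicative noise separating
#'   the three activity-data variants (default 0.1).
#' @return A list of class `ch4_synthetic_spec`.
#' @export
synthetic_spec <- function(n_cities = 347L, n_provinces = 31L,
                           years = 2010:2020, seed = 1L,
                           missing_city_fraction = 0.05,
                           category_abundance = default_category_abundance(),
                           north_south_weight_gradient = 1.15,
                           dataset_discrepancy_cv = 0.1) {
  years <- as.integer(years)
  if (any(years < 2000L) || any(years > 2030L))
    stop("years must lie within 2000-2030", call. = FALSE)
  if (missing_city_fraction < 0 || missing_city_fraction >= 0.1)
    stop("missing_city_fraction must lie in [0, 0.1)", call. = FALSE)
  n_provinces <- min(as.integer(n_provinces), as.integer(n_cities))
  spec <- list(n_cities = as.integer(n_cities), n_provinces = n_provinces,
               years = sort(unique(years)), seed = as.integer(seed),
               missing_city_fraction = missing_city_fraction,
               category_abundance = as.data.table(category_abundance),
               north_south_weight_gradient = north_south_weight_gradient,
               dataset_discrepancy_cv = dataset_discrepancy_cv)
  class(spec) <- "ch4_synthetic_spec"
  spec
}

#' @rdname synthetic_spec
#' @export
default_category_abundance <- function() {
  data.table(
    category = CATEGORY_CODES,
    median_head = c(2e4, 8e4, 1e4, 1.5e5, 1e5, 1e6,
                    1e3, 8e3, 5e3, 2e3, 5e6, 5e4),
    sdlog = c(0.9, 0.9, 1.2, 1.1, 1.1, 0.8, 1.5, 1.0, 1.0, 1.2, 0.9, 1.2),
    slaughter_rate = c(0.25, 0.35, 0.25, 0.9, 0.9, 1.5,
                       0.1, 0.1, 0.1, 0.1, 3.0, 2.0)
  )
}

# run code under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# row-wise cumulative sum that keeps matrix shape for 0/1-column inputs
row_cumsum <- function(m) {
  if (ncol(m) <= 1L) return(m)
  t(apply(m, 1L, cumsum))
}

# city -> province assignment; first ceiling(n/2) provinces are "northern"
synthetic_city_table <- function(spec) {
  prov_idx <- ((seq_len(spec$n_cities) - 1L) %% spec$n_provinces) + 1L
  data.table(
    city_id = sprintf("C%04d", seq_len(spec$n_cities)),
    province_id = sprintf("P%02d", prov_idx),
    north = prov_idx <= ceiling(spec$n_provinces / 2)
  )
}

#' Generate a synthetic activity panel
#'
#' Draws a city-year-category-subclass panel of stock and slaughtered
#' head counts plus a meat-production side table. Stock counts start from
#' a lognormal per-category city base and follow a multiplicative random
#' walk over years with log steps clipped to \[-0.3, 0.3\]. Slaughtered
#' counts are stock times a per-(city, category) slaughter rate; meat
#' production is slaughtered head times the configured carcass weight, so
#' gap-filling can recover blanked counts exactly up to rounding. A
#' `missing_city_fraction` share of cities has all head counts blanked
#' (`NA`) while keeping meat rows. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param pars Parameter set supplying subclass shares and carcass
#'   weights.
#' @return A list with `panel` (activity `data.table`), `meat`
#'   (`city_id`, `year`, `category`, `meat_production` in kg carcass
#'   weight), `cities` (city/province/north table) and `missing_cities`
#'   (character vector of blanked city ids).
#' @export
generate_activity_panel <- function(spec, pars = default_parameter_set()) {
  stopifnot(inherits(spec, "ch4_synthetic_spec"))
  cities <- synthetic_city_table(spec)
  years <- spec$years
  ny <- length(years)

  with_seed(spec$seed, {
    base <- CJ(city_id = cities$city_id,
               category = spec$category_abundance$category, sorted = FALSE)
    base <- spec$category_abundance[base, on = "category"]
    n <- nrow(base)
    base[, stock0 := rlnorm(n, meanlog = log(median_head), sdlog = sdlog)]
    base[, rate := slaughter_rate * runif(n, 0.9, 1.1)]

    # multiplicative random walk over years, |log step| <= 0.3
    steps <- matrix(pmin(pmax(rnorm(n * (ny - 1L), 0, 0.08), -0.3), 0.3),
                    nrow = n, ncol = ny - 1L)
    logpath <- cbind(0, row_cumsum(steps))
    stock <- base$stock0 * exp(logpath)   # n x ny

    long <- data.table(
      city_id = rep(base$city_id, times = ny),
      category = rep(base$category, times = ny),
      rate = rep(base$rate, times = ny),
      year = rep(years, each = n),
      stock = as.vector(stock)
    )
    missing_cities <- sort(sample(cities$city_id,
                                  round(spec$missing_city_fraction *
                                        spec$n_cities)))
  })

  long[, slaughtered := stock * rate]
  cw <- unlist(pars$gapfill$carcass_weight)
  long[, meat_production := slaughtered * cw[category]]
  meat <- long[, .(city_id, year, category,
                   meat_production = round(meat_production, 1))]

  # split whole-herd counts into subclasses by configured shares
  shares <- rbindlist(lapply(names(pars$subclass_shares), function(cc)
    data.table(category = cc,
               subclass = names(pars$subclass_shares[[cc]]),
               share = unlist(pars$subclass_shares[[cc]]))))
  whole <- subclass_table()[!shares$category, on = "category"][, share := 1]
  shares <- rbind(shares, whole)

  panel <- shares[long, on = "category", allow.cartesian = TRUE]
  panel <- cities[, .(city_id, province_id)][panel, on = "city_id"]
  panel[, `:=`(stock_head = round(stock * share),
               slaughtered_head = round(slaughtered * share),
               source_flag = "observed")]
  panel[city_id %in% missing_cities,
        `:=`(stock_head = NA_real_, slaughtered_head = NA_real_)]
  setcolorder(panel, ACTIVITY_COLS)
  panel <- panel[, ACTIVITY_COLS, with = FALSE]
  setkey(panel, city_id, year, category, subclass)

  list(panel = panel[], meat = meat[order(city_id, year, category)],
       cities = cities, missing_cities = missing_cities)
}

#' Generate synthetic trait and climate tables
#'
#' Province-year animal traits and city-year temperatures consistent with
#' the inventory's assumptions: body weights vary smoothly over years
#' (year-adjacent ratio within \[0.96, 1.04\]) around the shipped default
#' for each category/subclass, with northern provinces scaled up by the
#' spec's weight gradient; dairy milk yields lie in 3000–9000 kg head-1
#' yr-1 and drift smoothly; digestibility DE gets a small province
#' offset; city annual mean temperatures span all three climate classes
#' for panels of realistic size. Deterministic given `spec$seed`.
#'
#' @inheritParams generate_activity_panel
#' @return A list with `traits` (`region_id`, `year`, `category`,
#'   `subclass`, trait columns) and `climate` (`city_id`, `province_id`,
#'   `year`, `mean_temp`, `climate_class`).
#' @export
generate_trait_and_climate_tables <- function(spec,
                                              pars = default_parameter_set()) {
  stopifnot(inherits(spec, "ch4_synthetic_spec"))
  cities <- synthetic_city_table(spec)
  provs <- unique(cities[, .(province_id, north)])
  years <- spec$years
  ny <- length(years)

  # flat default trait table (category x subclass)
  def <- rbindlist(lapply(names(pars$traits), function(cc)
    rbindlist(lapply(names(pars$traits[[cc]]), function(sc)
      c(list(category = cc, subclass = sc), pars$traits[[cc]][[sc]])))))

  with_seed(spec$seed + 1001L, {
    tr <- CJ(province_id = provs$province_id, idx = seq_len(nrow(def)),
             sorted = FALSE)
    tr <- cbind(tr[, .(province_id)], def[tr$idx])
    tr <- provs[tr, on = "province_id"]
    n <- nrow(tr)

    grad <- ifelse(tr$north, spec$north_south_weight_gradient, 1)
    w0 <- tr$body_weight * grad * rlnorm(n, 0, 0.05)
    de0 <- pmin(pmax(tr$DE + runif(n, -2, 2), 45), 85)
    steps <- matrix(runif(n * (ny - 1L), log(0.96), log(1.04)),
                    nrow = n, ncol = ny - 1L)
    wmat <- w0 * exp(cbind(0, row_cumsum(steps)))

    milk0 <- ifelse(tr$category == "dairy_cattle" &
                    tr$subclass == "mature_female",
                    runif(n, 3500, 8500), tr$milk_yield)
    msteps <- matrix(runif(n * (ny - 1L), log(0.97), log(1.03)),
                     nrow = n, ncol = ny - 1L)
    mmat <- milk0 * exp(cbind(0, row_cumsum(msteps)))
    mmat[tr$category == "dairy_cattle" & tr$subclass == "mature_female", ] <-
      pmin(pmax(mmat[tr$category == "dairy_cattle" &
                     tr$subclass == "mature_female", , drop = FALSE],
                3000), 9000)

    traits <- data.table(
      region_id = rep(tr$province_id, times = ny),
      year = rep(years, each = n),
      category = rep(tr$category, times = ny),
      subclass = rep(tr$subclass, times = ny),
      body_weight = as.vector(wmat),
      weight_gain = rep(tr$weight_gain, times = ny),
      milk_yield = as.vector(mmat),
      milk_fat = rep(tr$milk_fat, times = ny),
      wool_yield = rep(tr$wool_yield, times = ny),
      pregnancy_fraction = rep(tr$pregnancy_fraction, times = ny),
      DE = rep(de0, times = ny),
      Ym = rep(tr$Ym, times = ny),
      feeding_situation = rep(tr$feeding_situation, times = ny)
    )

    # temperatures: a deterministic north-cold/south-warm gradient across
    # provinces (stratified so all three climate classes are represented
    # whenever there are a few provinces), plus small city/year offsets
    pt <- provs[, .(province_id)]
    pt[, base_temp := seq(5, 28, length.out = .N) + runif(.N, -1, 1)]
    ct <- pt[cities, on = "province_id"]
    ct[, city_off := runif(.N, -1.5, 1.5)]
    clim <- CJ(city_id = ct$city_id, year = years, sorted = FALSE)
    clim <- ct[, .(city_id, province_id, base_temp, city_off)][
      clim, on = "city_id"]
    clim[, mean_temp := round(base_temp + city_off +
                              runif(.N, -0.5, 0.5), 2)]
  })

  clim[, climate_class := classify_climate(mean_temp)]
  climate <- clim[order(city_id, year),
                  .(city_id, province_id, year, mean_temp, climate_class)]
  setkey(traits, region_id, year, category, subclass)
  list(traits = traits[], climate = climate)
}

#' Generate three discrepant activity-data variants
#'
#' Emulates comparing the compiled city panel against a national-yearbook
#' style dataset and an international (FAOSTAT-like) dataset: variant 1
#' is the base panel unchanged; variants 2 and 3 perturb each head count
#' with independent multiplicative lognormal noise of coefficient of
#' variation `spec$dataset_discrepancy_cv`. Positivity is preserved by
#' construction. Deterministic given `spec$seed`.
#'
#' @param panel Base activity panel.
#' @inheritParams generate_activity_panel
#' @return A list of three activity panels.
#' @export
generate_dataset_variants <- function(panel, spec) {
  stopifnot(inherits(spec, "ch4_synthetic_spec"), nrow(panel) > 0)
  cv <- spec$dataset_discrepancy_cv
  sdlog <- sqrt(log(1 + cv^2))
  perturb <- function(p, which_seed) {
    p <- copy(p)
    if (cv == 0) return(p)
    with_seed(spec$seed + which_seed, {
      mult_s <- rlnorm(nrow(p), -sdlog^2 / 2, sdlog)
      mult_l <- rlnorm(nrow(p), -sdlog^2 / 2, sdlog)
    })
    p[, `:=`(stock_head = stock_head * mult_s,
             slaughtered_head = slaughtered_head * mult_l)]
    p[]
  }
  list(copy(as.data.table(panel)),
       perturb(as.data.table(panel), 2001L),
       perturb(as.data.table(panel), 2002L))
}
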