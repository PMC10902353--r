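round_half_up <- function(x) floor(x + 0.5)

#' Estimate slaughtered head counts from meat production
#'
#' For cities with no breeding records, the slaughtered population of a
#' category is extrapolated from its meat production divided by carcass
#' weight, rounded half-up to whole head.
#'
#' @param meat_production Meat production, kg carcass weight per year
#'   (vectorised, non-negative).
#' @param carcass_weight Carcass weight, kg per head (> 0).
#' @return Integer-valued slaughtered head counts.
#' @export
#' @examples
#' estimate_slaughtered_from_meat(1500000, 150)  # 10000
estimate_slaughtered_from_meat <- function(meat_production, carcass_weight) {
  if (any(!is.finite(carcass_weight)) || any(carcass_weight <= 0))
    stop("carcass_weight must be positive", call. = FALSE)
  if (any(!is.finite(meat_production)) || any(meat_production < 0))
    stop("meat_production must be finite and non-negative", call. = FALSE)
  round_half_up(meat_production / carcass_weight)
}

#' Estimate the stock population from the slaughtered population
#'
#' Inverts the slaughter rate (slaughtered / stock): stock = slaughtered /
#' rate, rounded half-up to whole head.
#'
#' @param slaughtered_head Slaughtered head count (vectorised,
#'   non-negative).
#' @param slaughter_rate Slaughtered-to-stock ratio (> 0).
#' @return Integer-valued stock head counts.
#' @export
#' @examples
#' estimate_stock_from_slaughter(10000, 1.25)  # 8000
estimate_stock_from_slaughter <- function(slaughtered_head, slaughter_rate) {
  if (any(!is.finite(slaughter_rate)) || any(slaughter_rate <= 0))
    stop("slaughter_rate must be positive", call. = FALSE)
  if (any(!is.finite(slaughtered_head)) || any(slaughtered_head < 0))
    stop("slaughtered_head must be finite and non-negative", call. = FALSE)
  round_half_up(slaughtered_head / slaughter_rate)
}

#' Fill gaps in a body-weight time series
#'
#' Gap years between observations are filled by geometric interpolation
#' between the bracketing observed years; years before the first / after
#' the last observation are extended geometrically using the mean
#' year-over-year log change rate of the observed years. A
#' single-observation series is held constant (body weight is assumed
#' stable with no abrupt changes).
#'
#' @param series Named numeric vector, names = years, values = kg; `NA`
#'   values are treated as gaps.
#' @param years Years to return; default: the full observed range.
#' @return Named numeric vector over `years` with all gaps filled.
#' @export
#' @examples
#' fill_body_weight_series(c("2010" = 100, "2012" = 121))  # 2011 -> 110
fill_body_weight_series <- function(series, years = NULL) {
  series <- series[!is.na(series)]
  if (!length(series)) stop("series has no observed values", call. = FALSE)
  if (any(series <= 0)) stop("body weights must be positive", call. = FALSE)
  yrs_obs <- as.integer(names(series))
  if (any(is.na(yrs_obs))) stop("series names must be years", call. = FALSE)
  o <- order(yrs_obs); yrs_obs <- yrs_obs[o]; series <- as.numeric(series[o])
  if (is.null(years)) years <- seq(min(yrs_obs), max(yrs_obs))
  years <- as.integer(years)

  if (length(series) == 1L)
    return(setNames(rep(series, length(years)), years))

  # mean annual log change over the observed span
  rate <- (log(series[length(series)]) - log(series[1L])) /
    (yrs_obs[length(yrs_obs)] - yrs_obs[1L])

  out <- vapply(years, function(y) {
    if (y %in% yrs_obs) return(series[match(y, yrs_obs)])
    if (y < yrs_obs[1L])
      return(series[1L] * exp(rate * (y - yrs_obs[1L])))
    if (y > yrs_obs[length(yrs_obs)])
      return(series[length(series)] *
               exp(rate * (y - yrs_obs[length(yrs_obs)])))
    lo <- max(which(yrs_obs < y)); hi <- min(which(yrs_obs > y))
    # geometric interpolation between bracketing observations
    f <- (y - yrs_obs[lo]) / (yrs_obs[hi] - yrs_obs[lo])
    exp((1 - f) * log(series[lo]) + f * log(series[hi]))
  }, numeric(1))
  setNames(out, years)
}

# slaughter rate for one (city, year, category): same city, other years
# (mean) -> same-province cities, same year (mean) -> province mean across
# all years; NA if none resolvable
resolve_slaughter_rate <- function(rates, city, prov, yr, cat) {
  pick <- function(r) if (length(r) && any(is.finite(r)))
    mean(r[is.finite(r)]) else NA_real_
  r <- pick(rates[city_id == city & category == cat, rate])
  if (!is.na(r)) return(r)
  r <- pick(rates[province_id == prov & year == yr & category == cat, rate])
  if (!is.na(r)) return(r)
  pick(rates[province_id == prov & category == cat, rate])
}

#' Gap-fill missing activity records from meat production
#'
#' For every (city, year, category) cell whose head counts are `NA`,
#' reconstructs the whole-herd slaughtered count from the meat-production
#' table (meat / carcass weight), then the stock count via the slaughter
#' rate, resolved in priority order: mean rate of the same city in
#' observed years, then same-province cities in the same year, then the
#' province mean across all years, failing which the cell is left
#' unfilled and reported. Reconstructed whole-herd
#' counts are split into subclasses with the configured shares, and all
#' filled rows carry `source_flag = "gapfilled"`. Observed rows are never
#' modified.
#'
#' @param panel Activity panel with `NA` counts marking missing records.
#' @param meat Meat table (`city_id`, `year`, `category`,
#'   `meat_production` kg).
#' @param pars Parameter set (carcass weights, subclass shares).
#' @param on_unresolved `"error"` (default) or `"keep"` (leave `NA`).
#' @return The completed panel (a new `data.table`).
#' @export
gapfill_panel <- function(panel, meat, pars = default_parameter_set(),
                          on_unresolved = c("error", "keep")) {
  on_unresolved <- match.arg(on_unresolved)
  panel <- copy(as.data.table(panel))
  meat <- as.data.table(meat)

  # whole-herd slaughter rates from observed cells
  obs <- panel[!is.na(stock_head) & !is.na(slaughtered_head),
               .(stock = sum(stock_head), slaughtered = sum(slaughtered_head)),
               by = .(city_id, province_id, year, category)]
  rates <- obs[stock > 0, .(rate = slaughtered / stock),
               by = .(city_id, province_id, year, category)]

  miss <- unique(panel[is.na(stock_head) | is.na(slaughtered_head),
                       .(city_id, province_id, year, category)])
  if (!nrow(miss)) return(panel)

  cw <- unlist(pars$gapfill$carcass_weight)
  miss <- meat[miss, on = c("city_id", "year", "category")]
  unresolved <- miss[is.na(meat_production)]
  miss <- miss[!is.na(meat_production)]

  if (nrow(miss)) {
    miss[, slaughtered := estimate_slaughtered_from_meat(
      meat_production, cw[category])]
    miss[, rate := mapply(resolve_slaughter_rate, city_id, province_id,
                          year, category, MoreArgs = list(rates = rates))]
    unresolved <- rbind(unresolved,
                        miss[is.na(rate), .SD, .SDcols = names(unresolved)])
    miss <- miss[!is.na(rate)]
    miss[, stock := estimate_stock_from_slaughter(slaughtered, rate)]
  }

  if (nrow(unresolved) && on_unresolved == "error")
    stop("gap-fill failed, no meat record or resolvable slaughter rate for: ",
         paste(utils::head(unresolved[, paste(city_id, year, category,
                                              sep = "/")], 10L),
               collapse = ", "), call. = FALSE)

  if (nrow(miss)) {
    shares <- rbindlist(lapply(names(pars$subclass_shares), function(cc)
      data.table(category = cc,
                 subclass = names(pars$subclass_shares[[cc]]),
                 share = unlist(pars$subclass_shares[[cc]]))))
    whole <- subclass_table()[!shares$category, on = "category"][, share := 1]
    shares <- rbind(shares, whole)
    fill <- shares[miss, on = "category", allow.cartesian = TRUE]
    fill[, `:=`(stock_head = round_half_up(stock * share),
                slaughtered_head = round_half_up(slaughtered * share))]
    panel[fill, on = c("city_id", "year", "category", "subclass"),
          `:=`(stock_head = i.stock_head,
               slaughtered_head = i.slaughtered_head,
               source_flag = "gapfilled")]
  }
  panel[]
}
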