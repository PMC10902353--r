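#' Energy partitioning fractions REM and REG
#'
#' `rem()` is the fraction of digestible energy available as net energy
#' for maintenance-type uses; `reg()` the fraction available for
#' growth-type uses. Both are the standard empirical functions of feed
#' digestibility DE (digestible energy as % of gross energy):
#' \deqn{REM = 1.123 - 4.092\times10^{-3} DE + 1.126\times10^{-5} DE^2 - 25.4/DE}
#' \deqn{REG = 1.164 - 5.16\times10^{-3} DE + 1.308\times10^{-5} DE^2 - 37.4/DE}
#'
#' @param DE Digestibility of feed, percent, in \[45, 85\] (vectorised).
#' @return Fractions strictly between 0 and 1 on the domain.
#' @export
#' @examples
#' rem(65)  # ~0.5138
#' reg(65)  # ~0.3085
rem <- function(DE) {
  check_de(DE)
  1.123 - 4.092e-3 * DE + 1.126e-5 * DE^2 - 25.4 / DE
}

#' @rdname rem
#' @export
reg <- function(DE) {
  check_de(DE)
  1.164 - 5.16e-3 * DE + 1.308e-5 * DE^2 - 37.4 / DE
}

check_de <- function(DE) {
  if (any(!is.finite(DE)) || any(DE < 45) || any(DE > 85))
    stop("DE must lie in [45, 85] percent", call. = FALSE)
  invisible(DE)
}

#' Net-energy components of daily gross energy intake
#'
#' Decomposes an animal's daily energy requirement into net-energy
#' components (all MJ day-1):
#' maintenance `NE_m = cf * W^0.75`; activity `NE_a = ca * NE_m` with
#' `ca` keyed to the feeding situation; lactation
#' `NE_l = milk_daily * (1.47 + 0.40 * fat%)`; pregnancy
#' `NE_p = cp * NE_m * pregnancy_fraction`; growth
#' `NE_g = 22.02 * (W / (c_gender * MW))^0.75 * WG^1.097`; wool
#' `NE_wool = ev_wool * wool_yield / 365`. Lactation and pregnancy accrue
#' only to mature females, growth only to young animals (and, if
#' configured, to the residual class of sheep/goats); work energy is
#' always zero (draft animals are excluded from the accounting).
#'
#' @param traits Named list (or one-row list) of trait values:
#'   `body_weight` (kg), `weight_gain` (kg day-1), `milk_yield`
#'   (kg head-1 yr-1), `milk_fat` (%), `wool_yield` (kg head-1 yr-1),
#'   `pregnancy_fraction`, `feeding_situation`.
#' @param category,subclass Category and subclass codes.
#' @param pars Parameter set providing the energy coefficients.
#' @param mature_weight Mature weight MW (kg) for the growth term;
#'   default: the category's default mature-female body weight.
#' @return A list of class `ch4_energy_breakdown` with components `NE_m`,
#'   `NE_a`, `NE_l`, `NE_work`, `NE_p`, `NE_g`, `NE_wool` (MJ day-1).
#' @export
net_energy_components <- function(traits, category, subclass,
                                  pars = default_parameter_set(),
                                  mature_weight = NULL) {
  assert_category(category)
  cf <- pars$energy$cf[[category]][[subclass]]
  if (is.null(cf))
    stop("missing maintenance coefficient cf for ", category, ".", subclass,
         call. = FALSE)
  ca <- pars$energy$ca[[traits$feeding_situation]]
  if (is.null(ca))
    stop("missing activity coefficient ca for feeding situation '",
         traits$feeding_situation, "'", call. = FALSE)
  cp <- pars$energy$cp[[category]]
  if (is.null(cp))
    stop("missing pregnancy coefficient cp for ", category, call. = FALSE)

  W <- traits$body_weight
  if (!is.finite(W) || W <= 0) stop("body_weight must be positive",
                                    call. = FALSE)
  ne_m <- cf * W^0.75
  ne_a <- ca * ne_m

  is_mf <- subclass == "mature_female"
  ne_l <- if (is_mf && traits$milk_yield > 0) {
    (traits$milk_yield / 365) * (1.47 + 0.40 * traits$milk_fat)
  } else 0
  ne_p <- if (is_mf) cp * ne_m * traits$pregnancy_fraction else 0

  grows <- subclass == "young" ||
    (isTRUE(pars$energy$others_grow) && subclass == "other" &&
       category %in% c("sheep", "goat"))
  ne_g <- if (grows && traits$weight_gain > 0) {
    mw <- if (!is.null(mature_weight)) mature_weight
    else pars$traits[[category]][["mature_female"]]$body_weight
    if (is.null(mw)) mw <- W
    22.02 * (W / (pars$energy$c_gender * mw))^0.75 *
      traits$weight_gain^1.097
  } else 0

  ne_wool <- pars$energy$ev_wool * traits$wool_yield / 365

  out <- list(NE_m = ne_m, NE_a = ne_a, NE_l = ne_l, NE_work = 0,
              NE_p = ne_p, NE_g = ne_g, NE_wool = ne_wool)
  class(out) <- "ch4_energy_breakdown"
  out
}

#' Daily gross energy intake from net-energy components
#'
#' \deqn{GE = \frac{(NE_m + NE_a + NE_l + NE_{work} + NE_p)/REM +
#'   (NE_g + NE_{wool})/REG}{DE/100}}
#' Maintenance-type components are scaled by REM, growth-type components
#' by REG, and the digestible-energy total is inflated to gross energy by
#' the digestibility fraction DE/100.
#'
#' @param components A `ch4_energy_breakdown` (or list with the same
#'   names, MJ day-1).
#' @param DE Digestibility, percent, in \[45, 85\].
#' @return Gross energy intake, MJ day-1.
#' @export
gross_energy <- function(components, DE) {
  check_de(DE)
  m <- rem(DE); g <- reg(DE)
  if (m <= 0 || g <= 0) stop("REM/REG must be positive", call. = FALSE)
  comp <- unlist(components[c("NE_m", "NE_a", "NE_l", "NE_work", "NE_p",
                              "NE_g", "NE_wool")])
  if (any(!is.finite(comp)) || any(comp < 0))
    stop("energy components must be finite and non-negative", call. = FALSE)
  maintenance <- components$NE_m + components$NE_a + components$NE_l +
    components$NE_work + components$NE_p
  growth <- components$NE_g + components$NE_wool
  (maintenance / m + growth / g) / (DE / 100)
}

#' Tier 2 enteric emission factor from gross energy
#'
#' \deqn{EF = \frac{GE \times (Y_m/100) \times 365}{55.65}}
#' where 55.65 MJ kg-1 is the energy content of methane: the fraction Ym
#' of annual gross energy intake leaves the rumen as methane.
#'
#' @param GE Gross energy intake, MJ day-1 (vectorised, >= 0).
#' @param Ym Methane conversion factor, percent of GE, in \[0, 15\].
#' @param methane_energy Energy content of methane, MJ kg-1.
#' @return Emission factor, kg CH4 head-1 yr-1.
#' @export
#' @examples
#' ef_enteric_tier2(250, 6.5)  # ~106.59
ef_enteric_tier2 <- function(GE, Ym, methane_energy = 55.65) {
  if (any(!is.finite(GE)) || any(GE < 0))
    stop("GE must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(Ym)) || any(Ym < 0) || any(Ym > 15))
    stop("Ym must lie in [0, 15] percent", call. = FALSE)
  GE * (Ym / 100) * 365 / methane_energy
}

#' Dairy-cattle enteric emission factor from milk production
#'
#' Dairy-cattle body weights are poorly recorded, so the enteric factor
#' is regressed on annual milk production per head:
#' \deqn{EF = a \cdot production^{b} - c}
#' with shipped coefficients a = 30.8, b = 0.2, c = 53.6 and production
#' in kg head-1 yr-1 (daily units would drive the factor negative).
#'
#' @param milk_production Milk production, kg head-1 yr-1 (vectorised,
#'   > 0 and large enough that the factor is positive, roughly > 16).
#' @param coefs List with elements `a`, `b`, `c`.
#' @return Emission factor, kg CH4 head-1 yr-1.
#' @export
#' @examples
#' ef_dairy(6000)  # ~121.9
ef_dairy <- function(milk_production,
                     coefs = default_parameter_set()$constants$dairy_regression) {
  if (any(!is.finite(milk_production)) || any(milk_production <= 0))
    stop("milk_production must be positive (kg head-1 yr-1)", call. = FALSE)
  ef <- coefs$a * milk_production^coefs$b - coefs$c
  if (any(ef <= 0))
    stop("dairy EF non-positive; check milk production units ",
         "(expected kg head-1 yr-1)", call. = FALSE)
  ef
}

#' Tier 1 enteric emission factor lookup
#'
#' Minor species (horse, donkey, mule, poultry, rabbit, camel) use fixed
#' provincial-guideline emission factors, constant over regions and
#' years.
#'
#' @param category A tier1 category code.
#' @param pars Parameter set holding the `tier1_efs` table.
#' @return Emission factor, kg CH4 head-1 yr-1.
#' @export
ef_enteric_tier1 <- function(category, pars = default_parameter_set()) {
  assert_category(category)
  if (is_tier2(category))
    stop(category, " is a tier2 category; use the gross-energy pathway",
         call. = FALSE)
  pars$tier1_efs[[category]]$enteric
}

#' Build the enteric emission-factor table
#'
#' One factor per (region, year, category, subclass): Tier 2 ruminants via
#' the gross-energy pathway, dairy cattle via the milk regression, swine
#' via the configured constant, and Tier 1 categories via lookup. Traits
#' come from a region-year trait table (e.g.
#' [generate_trait_and_climate_tables()]); any (region, year, category,
#' subclass) absent from it falls back to the parameter-set defaults.
#'
#' @param pars Parameter set.
#' @param regions Character vector of region (province) ids.
#' @param years Integer vector of years.
#' @param traits Optional region-year trait `data.table` (columns
#'   `region_id`, `year`, `category`, `subclass`, trait fields).
#' @return A `data.table` (`region_id`, `year`, `category`, `subclass`,
#'   `pathway = "enteric"`, `ef` in kg CH4 head-1 yr-1).
#' @export
build_enteric_ef_table <- function(pars, regions, years, traits = NULL) {
  # cartesian of (category, subclass) x (region, year)
  sc <- subclass_table()
  grid <- CJ(idx = seq_len(nrow(sc)), region_id = regions,
             year = as.integer(years))
  grid[, `:=`(category = sc$category[idx], subclass = sc$subclass[idx])]
  grid[, idx := NULL]

  lookup_traits <- function(region, yr, cc, scx) {
    if (!is.null(traits)) {
      row <- traits[list(region, yr, cc, scx),
                    on = c("region_id", "year", "category", "subclass"),
                    nomatch = NULL]
      if (nrow(row) == 1L) return(as.list(row))
    }
    pars$traits[[cc]][[scx]]
  }

  efs <- mapply(function(region, yr, cc, scx) {
    if (!is_tier2(cc)) return(ef_enteric_tier1(cc, pars))
    if (cc == "swine") return(pars$constants$swine_enteric_ef)
    tr <- lookup_traits(region, yr, cc, scx)
    if (is.null(tr))
      stop("no traits for ", cc, ".", scx, " in region ", region, call. = FALSE)
    if (cc == "dairy_cattle") {
      mf <- lookup_traits(region, yr, cc, "mature_female")
      return(ef_dairy(mf$milk_yield, pars$constants$dairy_regression))
    }
    mw <- lookup_traits(region, yr, cc, "mature_female")$body_weight
    comp <- net_energy_components(tr, cc, scx, pars, mature_weight = mw)
    ge <- gross_energy(comp, tr$DE)
    ef_enteric_tier2(ge, tr$Ym, pars$constants$methane_energy_mj_per_kg)
  }, grid$region_id, grid$year, grid$category, grid$subclass,
  USE.NAMES = FALSE)

  grid[, `:=`(pathway = "enteric", ef = efs)]
  setkey(grid, region_id, year, category, subclass)
  grid[]
}
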