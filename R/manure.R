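#' Daily volatile-solids excretion per head
#'
#' Volatile solids are the degradable organic fraction of excreted
#' manure, the substrate for methanogenesis. Excretion scales with animal
#' mass: `VS = vs_rate * animal_mass / 1000` (kg VS head-1 day-1).
#' Annualisation happens once, in [ef_manure()].
#'
#' @param vs_rate Excretion rate, kg VS per 1000 kg animal mass per day
#'   (> 0, vectorised).
#' @param animal_mass Live animal mass, kg (> 0, vectorised).
#' @return kg VS head-1 day-1.
#' @export
#' @examples
#' vs_daily(2.8, 80)  # 0.224
vs_daily <- function(vs_rate, animal_mass) {
  if (any(!is.finite(vs_rate)) || any(vs_rate <= 0))
    stop("vs_rate must be positive", call. = FALSE)
  if (any(!is.finite(animal_mass)) || any(animal_mass <= 0))
    stop("animal_mass must be positive", call. = FALSE)
  vs_rate * animal_mass / 1000
}

#' Manure-management emission factor
#'
#' Annual methane per head from manure handling:
#' \deqn{EF = 365 \cdot VS_{daily} \cdot B_0 \cdot \rho \cdot
#'   \sum_S \frac{MCF_{S,k}}{100} \cdot Management_S}
#' where `B0` is the manure's maximum methane-producing capacity (m3 CH4
#' per kg VS), `rho` the methane density converting volume to mass
#' (0.67 kg m-3 by default), `MCF` the percent of that capacity realised
#' under management system S in climate class k, and `Management_S` the
#' fraction of manure handled in system S. Systems with zero fraction
#' need no MCF entry.
#'
#' @param vs_daily kg VS head-1 day-1 (>= 0).
#' @param B0 m3 CH4 per kg VS (> 0).
#' @param system_fractions Named numeric (or list): fraction of manure per
#'   management system, summing to 1.
#' @param mcf_table MCF lookup, `list(system = list(cool=, temperate=,
#'   warm=))`, percent.
#' @param climate_class `"cool"`, `"temperate"` or `"warm"`.
#' @param methane_density kg CH4 per m3 (default 0.67; set 0.067 for
#'   literal-paper mode).
#' @return Emission factor, kg CH4 head-1 yr-1.
#' @export
#' @examples
#' ef_manure(0.224, 0.29,
#'           c(liquid_slurry = 0.5, solid_storage = 0.5),
#'           list(liquid_slurry = list(temperate = 35),
#'                solid_storage = list(temperate = 2)),
#'           "temperate")  # ~2.94
ef_manure <- function(vs_daily, B0, system_fractions, mcf_table,
                      climate_class, methane_density = 0.67) {
  if (!is.finite(vs_daily) || vs_daily < 0)
    stop("vs_daily must be finite and non-negative", call. = FALSE)
  if (!is.finite(B0) || B0 <= 0) stop("B0 must be positive", call. = FALSE)
  if (!climate_class %in% CLIMATE_CLASSES)
    stop("unknown climate class: ", climate_class, call. = FALSE)
  fr <- unlist(system_fractions)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("system_fractions must sum to 1", call. = FALSE)

  weighted_mcf <- 0
  for (s in names(fr)) {
    if (fr[[s]] == 0) next
    m <- mcf_table[[s]][[climate_class]]
    if (is.null(m))
      stop("missing MCF cell: (", s, ", ", climate_class, ")", call. = FALSE)
    weighted_mcf <- weighted_mcf + (m / 100) * fr[[s]]
  }
  365 * vs_daily * B0 * methane_density * weighted_mcf
}

#' Build the manure emission-factor table
#'
#' One factor per (region, year, category, subclass, climate class).
#' Tier 2 categories use the volatile-solids pathway with the
#' subclass-specific body weight as animal mass (region-year traits when
#' available, parameter-set defaults otherwise); Tier 1 categories use
#' their fixed manure factor, identical across climate classes.
#'
#' @inheritParams build_enteric_ef_table
#' @return A `data.table` (`region_id`, `year`, `category`, `subclass`,
#'   `climate_class`, `pathway = "manure"`, `ef` in kg CH4 head-1 yr-1).
#' @export
build_manure_ef_table <- function(pars, regions, years, traits = NULL) {
  sc <- subclass_table()
  grid <- CJ(idx = seq_len(nrow(sc)), region_id = regions,
             year = as.integer(years), climate_class = CLIMATE_CLASSES)
  grid[, `:=`(category = sc$category[idx], subclass = sc$subclass[idx])]
  grid[, idx := NULL]

  body_weight_of <- function(region, yr, cc, scx) {
    if (!is.null(traits)) {
      row <- traits[list(region, yr, cc, scx),
                    on = c("region_id", "year", "category", "subclass"),
                    nomatch = NULL]
      if (nrow(row) == 1L) return(row$body_weight)
    }
    pars$traits[[cc]][[scx]]$body_weight
  }

  efs <- mapply(function(region, yr, cc, scx, k) {
    if (!is_tier2(cc)) return(pars$tier1_efs[[cc]]$manure)
    mp <- pars$manure[[cc]]
    am <- body_weight_of(region, yr, cc, scx)
    if (is.null(am))
      stop("no body weight for ", cc, ".", scx, " in region ", region,
           call. = FALSE)
    ef_manure(vs_daily(mp$vs_rate, am), mp$B0, mp$system_fractions,
              pars$mcf, k, pars$constants$methane_density_kg_per_m3)
  }, grid$region_id, grid$year, grid$category, grid$subclass,
  grid$climate_class, USE.NAMES = FALSE)

  grid[, `:=`(pathway = "manure", ef = efs)]
  setcolorder(grid, c("region_id", "year", "category", "subclass",
                      "climate_class", "pathway", "ef"))
  setkey(grid, region_id, year, category, subclass, climate_class)
  grid[]
}
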