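lifespan_table <- function(pars) {
  rbindlist(lapply(names(pars$lifespans), function(cc)
    data.table(category = cc,
               als_stock = pars$lifespans[[cc]]$stock,
               als_slaughtered = pars$lifespans[[cc]]$slaughtered)))
}

#' Compute the emission inventory cube
#'
#' Combines an activity panel with enteric and manure emission-factor
#' tables under average-lifespan (ALS) weighting. Each head contributes
#' `EF * ALS / 12`: stock animals for the months their category emits
#' within a calendar year (e.g. 12 for stocked cattle, 5.6 for stocked
#' sheep), slaughtered animals for their shorter pre-slaughter span,
#' assumed uniformly distributed through the year. Emissions are summed
#' over subclasses to (city, year, category, pathway) and reported in
#' Gg CH4 yr-1.
#'
#' @param panel Complete activity panel (no `NA` head counts; run
#'   [gapfill_panel()] first if needed).
#' @param enteric_ef Table from [build_enteric_ef_table()].
#' @param manure_ef Table from [build_manure_ef_table()].
#' @param climate City-year climate table (`city_id`, `year`,
#'   `climate_class`), used to pick each city's manure MCF column.
#' @param pars Parameter set (lifespans).
#' @return An object of class `ch4_inventory_cube`: list with `records`
#'   (`city_id`, `province_id`, `year`, `category`, `pathway`,
#'   `emissions_gg`) and `cities` (city-to-province map).
#' @export
compute_emissions <- function(panel, enteric_ef, manure_ef, climate,
                              pars = default_parameter_set()) {
  panel <- as.data.table(panel)
  if (!nrow(panel)) {
    rec <- data.table(city_id = character(), province_id = character(),
                      year = integer(), category = character(),
                      pathway = character(), emissions_gg = numeric())
    return(structure(list(records = rec,
                          cities = data.table(city_id = character(),
                                              province_id = character())),
                     class = "ch4_inventory_cube"))
  }
  if (anyNA(panel$stock_head) || anyNA(panel$slaughtered_head))
    stop("panel has NA head counts; gap-fill before computing emissions",
         call. = FALSE)

  als <- lifespan_table(pars)
  miss_als <- setdiff(unique(panel$category), als$category)
  if (length(miss_als))
    stop("no lifespan entry for: ", paste(miss_als, collapse = ", "),
         call. = FALSE)

  work <- als[panel, on = "category"]
  work[, head_weight := stock_head * als_stock / 12 +
         slaughtered_head * als_slaughtered / 12]

  # enteric: region-year-category-subclass factor
  ent <- work[enteric_ef, on = c(province_id = "region_id", "year",
                                 "category", "subclass"),
              nomatch = NULL]
  if (nrow(ent) != nrow(work))
    stop("enteric EF table does not cover the panel (",
         nrow(work) - nrow(ent), " uncovered rows)", call. = FALSE)
  ent <- ent[, .(emissions_gg = sum(head_weight * ef) / 1e6),
             by = .(city_id, province_id, year, category)]
  ent[, pathway := "enteric"]

  # manure: additionally keyed by the city-year climate class
  cl <- as.data.table(climate)[, .(city_id, year, climate_class)]
  workm <- cl[work, on = c("city_id", "year"), nomatch = NULL]
  if (nrow(workm) != nrow(work))
    stop("climate table does not cover the panel", call. = FALSE)
  man <- workm[manure_ef, on = c(province_id = "region_id", "year",
                                 "category", "subclass", "climate_class"),
               nomatch = NULL]
  if (nrow(man) != nrow(work))
    stop("manure EF table does not cover the panel (",
         nrow(work) - nrow(man), " uncovered rows)", call. = FALSE)
  man <- man[, .(emissions_gg = sum(head_weight * ef) / 1e6),
             by = .(city_id, province_id, year, category)]
  man[, pathway := "manure"]

  records <- rbind(ent, man)
  setcolorder(records, c("city_id", "province_id", "year", "category",
                         "pathway", "emissions_gg"))
  setkey(records, city_id, year, category, pathway)
  structure(list(records = records[],
                 cities = unique(records[, .(city_id, province_id)])),
            class = "ch4_inventory_cube")
}

#' @export
print.ch4_inventory_cube <- function(x, ...) {
  r <- x$records
  cat("<ch4_inventory_cube>\n")
  cat("  cities:", nrow(x$cities), " years:",
      if (nrow(r)) paste(range(r$year), collapse = "-") else "-", "\n")
  cat("  records:", nrow(r), "\n")
  if (nrow(r))
    cat("  national total:",
        sprintf("%.4g Gg CH4 yr-1 (mean over years)",
                r[, sum(emissions_gg)] / length(unique(r$year))), "\n")
  invisible(x)
}

#' Aggregate an inventory cube
#'
#' Exact sums of city-level records to the requested level, keeping the
#' pathway split.
#'
#' @param cube A `ch4_inventory_cube`.
#' @param level `"city"`, `"province"` or `"national"`.
#' @param by_category Keep the category split? Default `FALSE`.
#' @return A `data.table` of emissions (Gg CH4 yr-1) at the requested
#'   level with columns `year`, `pathway`, `emissions_gg` and the level
#'   id / `category` columns as applicable.
#' @export
aggregate_emissions <- function(cube, level = c("city", "province",
                                                "national"),
                                by_category = FALSE) {
  level <- match.arg(level)
  keys <- switch(level,
                 city = c("city_id", "province_id", "year", "pathway"),
                 province = c("province_id", "year", "pathway"),
                 national = c("year", "pathway"))
  if (by_category) keys <- c(keys, "category")
  out <- cube$records[, .(emissions_gg = sum(emissions_gg)), keyby = keys]
  out[]
}

#' Split an inventory cube into ruminant and nonruminant emissions
#'
#' @param cube A `ch4_inventory_cube`.
#' @return A `data.table` with two records per (city, year): columns
#'   `city_id`, `province_id`, `year`, `animal_class`
#'   (`"ruminant"`/`"nonruminant"`), `emissions_gg`; the two records sum
#'   to the city-year total.
#' @export
split_ruminant <- function(cube) {
  r <- copy(cube$records)
  r[, animal_class := ifelse(is_ruminant(category), "ruminant",
                             "nonruminant")]
  full <- CJ(city_id = cube$cities$city_id,
             year = unique(r$year),
             animal_class = c("ruminant", "nonruminant"))
  out <- r[, .(emissions_gg = sum(emissions_gg)),
           by = .(city_id, province_id, year, animal_class)]
  out <- out[full, on = c("city_id", "year", "animal_class")]
  out[is.na(emissions_gg), emissions_gg := 0]
  out <- cube$cities[out[, -"province_id"], on = "city_id"]
  setcolorder(out, c("city_id", "province_id", "year", "animal_class",
                     "emissions_gg"))
  setkey(out, city_id, year, animal_class)
  out[]
}

#' Export the six inventory dataset files
#'
#' Writes the canonical dataset layout as CSV: (1) city-year totals,
#' (2) city-year enteric emissions, (3) city-year manure emissions,
#' (4) city-year ruminant/nonruminant emissions (two records per cell),
#' (5) national and provincial series with the pathway structure,
#' (6) per-category national series. For a full 347-city x 11-year panel
#' files 1–4 carry 3817, 3817, 3817 and 7634 records. Values are written
#' at full precision so that partition identities (categories sum to
#' national totals, pathways sum to totals) survive a round-trip through
#' the files.
#'
#' @param cube A `ch4_inventory_cube`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the six file paths.
#' @export
export_dataset <- function(cube, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  city <- aggregate_emissions(cube, "city")
  wide_total <- city[, .(emissions_gg = sum(emissions_gg)),
                     by = .(city_id, province_id, year)]

  paths <- c(
    city_total = "city_total_emissions.csv",
    city_enteric = "city_enteric_emissions.csv",
    city_manure = "city_manure_emissions.csv",
    city_ruminant = "city_ruminant_nonruminant_emissions.csv",
    national_provincial = "national_provincial_emissions.csv",
    category_national = "category_national_emissions.csv")
  paths <- setNames(file.path(out_dir, paths), names(paths))

  fwrite(wide_total[order(city_id, year)], paths["city_total"])
  fwrite(city[pathway == "enteric"][order(city_id, year),
              .(city_id, province_id, year, emissions_gg)],
         paths["city_enteric"])
  fwrite(city[pathway == "manure"][order(city_id, year),
              .(city_id, province_id, year, emissions_gg)],
         paths["city_manure"])
  fwrite(split_ruminant(cube), paths["city_ruminant"])

  prov <- aggregate_emissions(cube, "province")
  prov_tot <- prov[, .(pathway = "total", emissions_gg = sum(emissions_gg)),
                   by = .(province_id, year)]
  natl <- aggregate_emissions(cube, "national")
  natl_tot <- natl[, .(pathway = "total", emissions_gg = sum(emissions_gg)),
                   by = year]
  np <- rbind(
    rbind(prov, prov_tot)[, .(level = province_id, year, pathway,
                              emissions_gg)],
    rbind(natl, natl_tot)[, .(level = "national", year, pathway,
                              emissions_gg)])
  fwrite(np[order(level, year, pathway)], paths["national_provincial"])

  bycat <- aggregate_emissions(cube, "national", by_category = TRUE)
  fwrite(bycat[order(category, year, pathway)], paths["category_national"])

  invisible(paths)
}
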