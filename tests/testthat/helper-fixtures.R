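library(data.table)

# small deterministic world used across test files
tiny_spec <- function(seed = 42L, n_cities = 12L, n_provinces = 4L,
                      years = 2012:2015, missing = 0.08, ...) {
  synthetic_spec(n_cities = n_cities, n_provinces = n_provinces,
                 years = years, seed = seed,
                 missing_city_fraction = missing, ...)
}

# memoised tiny world: panel + traits/climate + EF tables + filled panel
tiny_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pars <- default_parameter_set()
    spec <- tiny_spec()
    gen <- generate_activity_panel(spec, pars)
    tc <- generate_trait_and_climate_tables(spec, pars)
    filled <- gapfill_panel(gen$panel, gen$meat, pars)
    regions <- sort(unique(gen$panel$province_id))
    ent <- build_enteric_ef_table(pars, regions, spec$years, tc$traits)
    man <- build_manure_ef_table(pars, regions, spec$years, tc$traits)
    cube <- compute_emissions(filled, ent, man, tc$climate, pars)
    cache <<- list(pars = pars, spec = spec, gen = gen, tc = tc,
                   filled = filled, regions = regions, ent = ent,
                   man = man, cube = cube)
    cache
  }
})

# one-line independent oracles for the EF formulas
oracle_rem <- function(DE) 1.123 - 0.004092 * DE + 1.126e-5 * DE^2 - 25.4 / DE
oracle_reg <- function(DE) 1.164 - 0.00516 * DE + 1.308e-5 * DE^2 - 37.4 / DE
oracle_ge <- function(maint, growth, DE)
  (maint / oracle_rem(DE) + growth / oracle_reg(DE)) / (DE / 100)
oracle_ef_tier2 <- function(GE, Ym) GE * (Ym / 100) * 365 / 55.65
oracle_ef_dairy <- function(p) 30.8 * p^0.2 - 53.6
oracle_vs <- function(rate, mass) rate * mass / 1000
oracle_ef_manure <- function(vs, B0, fr, mcf, k, dens = 0.67) {
  s <- 0
  for (nm in names(fr)) s <- s + mcf[[nm]][[k]] / 100 * fr[[nm]]
  365 * vs * B0 * dens * s
}

# minimal hand-built single-category world for exact arithmetic checks
manual_world <- function(stock = 1000, slaughtered = 0, ef_ent = 100,
                         ef_man = 0, category = "horse",
                         als_stock = 12, als_slaughtered = 6) {
  pars <- default_parameter_set()
  pars$lifespans[[category]] <- list(stock = als_stock,
                                     slaughtered = als_slaughtered)
  panel <- data.table(city_id = "C1", province_id = "P1", year = 2015L,
                      category = category, subclass = "whole_herd",
                      stock_head = stock, slaughtered_head = slaughtered,
                      source_flag = "observed")
  ent <- data.table(region_id = "P1", year = 2015L, category = category,
                    subclass = "whole_herd", pathway = "enteric",
                    ef = ef_ent)
  man <- data.table(region_id = "P1", year = 2015L, category = category,
                    subclass = "whole_herd", climate_class = "temperate",
                    pathway = "manure", ef = ef_man)
  climate <- data.table(city_id = "C1", year = 2015L,
                        climate_class = "temperate")
  list(pars = pars, panel = panel, ent = ent, man = man, climate = climate)
}
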