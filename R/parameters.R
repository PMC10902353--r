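#' Default parameter set for the inventory
#'
#' Builds the shipped parameter registry: animal traits per Tier 2
#' category and subclass (body weight, weight gain, milk yield and fat,
#' wool yield, pregnancy fraction, feed digestibility DE, methane
#' conversion factor Ym, feeding situation), net-energy coefficients,
#' manure profiles (volatile-solids excretion rate, B0, management-system
#' fractions), the MCF lookup by system and climate class, average
#' lifespans for stock and slaughtered populations, Tier 1 emission-factor
#' pairs, Monte Carlo CVs, whole-herd subclass shares, carcass weights for
#' gap-filling, and physical constants.
#'
#' Values are IPCC-2019-refinement-style defaults chosen to give plausible
#' emission-factor magnitudes for Chinese livestock systems; every value
#' can be overridden through a YAML/JSON config read by
#' [load_parameter_set()]. Traits here are national defaults (region
#' `"default"`); region-year trait tables (e.g. from
#' [generate_trait_and_climate_tables()]) override them when building
#' emission-factor tables.
#'
#' @return A list of class `ch4_parameter_set`.
#' @seealso [load_parameter_set()], [validate_parameter_set()],
#'   [write_parameter_set()]
#' @export
default_parameter_set <- function() {
  traits <- list(
    dairy_cattle = list(
      mature_female = list(body_weight = 480, weight_gain = 0, milk_yield = 5500,
                           milk_fat = 3.5, wool_yield = 0, pregnancy_fraction = 0.67,
                           DE = 65, Ym = 6.0, feeding_situation = "stall"),
      young         = list(body_weight = 220, weight_gain = 0.5, milk_yield = 0,
                           milk_fat = 0, wool_yield = 0, pregnancy_fraction = 0,
                           DE = 65, Ym = 6.0, feeding_situation = "stall"),
      other         = list(body_weight = 400, weight_gain = 0, milk_yield = 0,
                           milk_fat = 0, wool_yield = 0, pregnancy_fraction = 0,
                           DE = 65, Ym = 6.0, feeding_situation = "stall")
    ),
    nondairy_cattle = list(
      mature_female = list(body_weight = 380, weight_gain = 0, milk_yield = 500,
                           milk_fat = 4.0, wool_yield = 0, pregnancy_fraction = 0.67,
                           DE = 60, Ym = 6.5, feeding_situation = "pasture"),
      young         = list(body_weight = 200, weight_gain = 0.4, milk_yield = 0,
                           milk_fat = 0, wool_yield = 0, pregnancy_fraction = 0,
                           DE = 60, Ym = 6.5, feeding_situation = "pasture"),
      other         = list(body_weight = 350, weight_gain = 0, milk_yield = 0,
                           milk_fat = 0, wool_yield = 0, pregnancy_fraction = 0,
                           DE = 60, Ym = 6.5, feeding_situation = "pasture")
    ),
    buffalo = list(
      mature_female = list(body_weight = 420, weight_gain = 0, milk_yield = 400,
                           milk_fat = 6.5, wool_yield = 0, pregnancy_fraction = 0.6,
                           DE = 55, Ym = 6.5, feeding_situation = "pasture"),
      young         = list(body_weight = 230, weight_gain = 0.35, milk_yield = 0,
                           milk_fat = 0, wool_yield = 0, pregnancy_fraction = 0,
                           DE = 55, Ym = 6.5, feeding_situation = "pasture"),
      other         = list(body_weight = 380, weight_gain = 0, milk_yield = 0,
                           milk_fat = 0, wool_yield = 0, pregnancy_fraction = 0,
                           DE = 55, Ym = 6.5, feeding_situation = "pasture")
    ),
    sheep = list(
      mature_female = list(body_weight = 45, weight_gain = 0, milk_yield = 0,
                           milk_fat = 0, wool_yield = 1.5, pregnancy_fraction = 0.8,
                           DE = 60, Ym = 6.5, feeding_situation = "pasture"),
      other         = list(body_weight = 35, weight_gain = 0, milk_yield = 0,
                           milk_fat = 0, wool_yield = 1.0, pregnancy_fraction = 0,
                           DE = 60, Ym = 5.5, feeding_situation = "pasture")
    ),
    goat = list(
      mature_female = list(body_weight = 38, weight_gain = 0, milk_yield = 0,
                           milk_fat = 0, wool_yield = 0.35, pregnancy_fraction = 0.8,
                           DE = 60, Ym = 6.5, feeding_situation = "pasture"),
      other         = list(body_weight = 30, weight_gain = 0, milk_yield = 0,
                           milk_fat = 0, wool_yield = 0.25, pregnancy_fraction = 0,
                           DE = 60, Ym = 5.5, feeding_situation = "pasture")
    ),
    swine = list(
      whole_herd    = list(body_weight = 90, weight_gain = 0, milk_yield = 0,
                           milk_fat = 0, wool_yield = 0, pregnancy_fraction = 0,
                           DE = 75, Ym = 0.6, feeding_situation = "stall")
    )
  )

  energy <- list(
    # NE_m = cf * W^0.75; maintenance coefficient by category/subclass
    cf = list(
      dairy_cattle    = list(mature_female = 0.386, young = 0.322, other = 0.322),
      nondairy_cattle = list(mature_female = 0.386, young = 0.322, other = 0.322),
      buffalo         = list(mature_female = 0.386, young = 0.322, other = 0.322),
      sheep           = list(mature_female = 0.236, other = 0.217),
      goat            = list(mature_female = 0.236, other = 0.217),
      swine           = list(whole_herd = 0.197)
    ),
    # NE_a = ca * NE_m; activity coefficient by feeding situation
    ca = list(stall = 0.0, pasture = 0.17, grazing_large_area = 0.36),
    # NE_p = cp * NE_m * pregnancy_fraction
    cp = list(dairy_cattle = 0.10, nondairy_cattle = 0.10, buffalo = 0.10,
              sheep = 0.077, goat = 0.077, swine = 0.10),
    # NE_g = 22.02 * (W / (c_gender * MW))^0.75 * WG^1.097
    c_gender = 1.0,
    # net energy per kg of clean wool/fibre, MJ
    ev_wool = 24,
    # whether the residual ("other") class of sheep/goats accrues NE_g
    others_grow = FALSE
  )

  manure <- list(
    dairy_cattle    = list(vs_rate = 8.8, B0 = 0.13, system_fractions = list(
      liquid_slurry = 0.25, solid_storage = 0.45, daily_spread = 0.10,
      pasture = 0.10, anaerobic_digester = 0.10)),
    nondairy_cattle = list(vs_rate = 7.4, B0 = 0.10, system_fractions = list(
      solid_storage = 0.50, dry_lot = 0.15, pasture = 0.25, daily_spread = 0.10)),
    buffalo         = list(vs_rate = 9.1, B0 = 0.10, system_fractions = list(
      solid_storage = 0.45, pasture = 0.35, daily_spread = 0.20)),
    sheep           = list(vs_rate = 8.2, B0 = 0.13, system_fractions = list(
      pasture = 0.70, solid_storage = 0.30)),
    goat            = list(vs_rate = 9.0, B0 = 0.13, system_fractions = list(
      pasture = 0.70, solid_storage = 0.30)),
    swine           = list(vs_rate = 5.4, B0 = 0.29, system_fractions = list(
      liquid_slurry = 0.35, solid_storage = 0.30, lagoon = 0.10,
      anaerobic_digester = 0.15, other = 0.10))
  )

  # MCF (%) by management system x climate class; non-decreasing cool->warm
  mcf <- list(
    pasture            = list(cool = 1.0,  temperate = 1.5,  warm = 2.0),
    daily_spread       = list(cool = 0.1,  temperate = 0.5,  warm = 1.0),
    solid_storage      = list(cool = 2.0,  temperate = 4.0,  warm = 5.0),
    dry_lot            = list(cool = 1.0,  temperate = 1.5,  warm = 2.0),
    liquid_slurry      = list(cool = 17.0, temperate = 35.0, warm = 55.0),
    anaerobic_digester = list(cool = 1.0,  temperate = 1.5,  warm = 2.0),
    lagoon             = list(cool = 60.0, temperate = 73.0, warm = 80.0),
    other              = list(cool = 3.0,  temperate = 5.0,  warm = 8.0)
  )

  # months of emission within a calendar year, stock vs slaughtered herds
  lifespans <- list(
    dairy_cattle    = list(stock = 12,  slaughtered = 6),
    nondairy_cattle = list(stock = 12,  slaughtered = 6),
    buffalo         = list(stock = 12,  slaughtered = 6),
    sheep           = list(stock = 5.6, slaughtered = 3),
    goat            = list(stock = 5.6, slaughtered = 3),
    swine           = list(stock = 10,  slaughtered = 6),
    camel           = list(stock = 12,  slaughtered = 6),
    horse           = list(stock = 12,  slaughtered = 6),
    donkey          = list(stock = 12,  slaughtered = 6),
    mule            = list(stock = 12,  slaughtered = 6),
    poultry         = list(stock = 6,   slaughtered = 2),
    rabbit          = list(stock = 6,   slaughtered = 3)
  )

  # fixed EF pairs (kg CH4 head-1 yr-1) for minor species
  tier1_efs <- list(
    camel   = list(enteric = 46,    manure = 1.92),
    horse   = list(enteric = 18,    manure = 1.64),
    donkey  = list(enteric = 10,    manure = 0.90),
    mule    = list(enteric = 10,    manure = 0.90),
    poultry = list(enteric = 0,     manure = 0.02),
    rabbit  = list(enteric = 0.254, manure = 0.08)
  )

  cvs <- list(
    dairy_cattle    = list(ef = 0.15, activity = 0.10),
    nondairy_cattle = list(ef = 0.15, activity = 0.10),
    buffalo         = list(ef = 0.20, activity = 0.10),
    sheep           = list(ef = 0.20, activity = 0.10),
    goat            = list(ef = 0.20, activity = 0.10),
    swine           = list(ef = 0.20, activity = 0.10),
    camel           = list(ef = 0.25, activity = 0.15),
    horse           = list(ef = 0.25, activity = 0.15),
    donkey          = list(ef = 0.25, activity = 0.15),
    mule            = list(ef = 0.25, activity = 0.15),
    poultry         = list(ef = 0.25, activity = 0.15),
    rabbit          = list(ef = 0.25, activity = 0.15)
  )

  subclass_shares <- list(
    dairy_cattle    = list(mature_female = 0.45, young = 0.25, other = 0.30),
    nondairy_cattle = list(mature_female = 0.45, young = 0.25, other = 0.30),
    buffalo         = list(mature_female = 0.45, young = 0.25, other = 0.30),
    sheep           = list(mature_female = 0.60, other = 0.40),
    goat            = list(mature_female = 0.60, other = 0.40)
  )

  gapfill <- list(
    carcass_weight = list(
      dairy_cattle = 150, nondairy_cattle = 150, buffalo = 160, sheep = 15,
      goat = 12, swine = 77, camel = 200, horse = 150, donkey = 90,
      mule = 100, poultry = 1.5, rabbit = 1.2)
  )

  constants <- list(
    methane_energy_mj_per_kg = 55.65,  # energy content of methane
    methane_density_kg_per_m3 = 0.67,  # 0.067 selectable (literal-paper mode)
    dairy_regression = list(a = 30.8, b = 0.2, c = 53.6),
    swine_enteric_ef = 1.0             # kg head-1 yr-1, fixed
  )

  ps <- list(traits = traits, energy = energy, manure = manure, mcf = mcf,
             lifespans = lifespans, tier1_efs = tier1_efs, cvs = cvs,
             subclass_shares = subclass_shares, gapfill = gapfill,
             constants = constants)
  class(ps) <- "ch4_parameter_set"
  ps
}

#' Validate a parameter set
#'
#' Checks structural completeness and invariants: every Tier 2 category
#' has full trait, manure and lifespan entries for each admitted subclass;
#' every Tier 1 category has an (enteric, manure) factor pair; management
#' fractions and subclass shares sum to 1; every MCF cell exists in
#' (0, 100]; DE in (0, 100], Ym in [0, 15], body weights positive. All
#' problems are collected and reported together.
#'
#' @param pars A `ch4_parameter_set` (or plain list with the same shape).
#' @return Invisibly, a character vector of problems (length 0 when
#'   valid). With `error = TRUE` (default) a non-empty problem list is
#'   raised as an error naming every missing or invalid key.
#' @param error Raise an error on problems rather than returning them?
#' @export
validate_parameter_set <- function(pars, error = TRUE) {
  problems <- character()
  note <- function(...) problems <<- c(problems, paste0(...))

  tier2 <- c("dairy_cattle", "nondairy_cattle", "buffalo", "sheep", "goat",
             "swine")
  tier1 <- c("camel", "horse", "donkey", "mule", "poultry", "rabbit")
  trait_fields <- c("body_weight", "weight_gain", "milk_yield", "milk_fat",
                    "wool_yield", "pregnancy_fraction", "DE", "Ym",
                    "feeding_situation")

  for (cc in tier2) {
    for (sc in subclasses_of(cc)) {
      tr <- pars$traits[[cc]][[sc]]
      if (is.null(tr)) { note("missing traits: ", cc, ".", sc); next }
      for (f in trait_fields)
        if (is.null(tr[[f]])) note("missing trait field: ", cc, ".", sc, ".", f)
      if (!is.null(tr$DE) && (tr$DE <= 0 || tr$DE > 100))
        note("DE out of (0, 100]: ", cc, ".", sc)
      if (!is.null(tr$Ym) && (tr$Ym < 0 || tr$Ym > 15))
        note("Ym out of [0, 15]: ", cc, ".", sc)
      if (!is.null(tr$body_weight) && tr$body_weight <= 0)
        note("body_weight must be positive: ", cc, ".", sc)
      if (!is.null(tr$pregnancy_fraction) &&
          (tr$pregnancy_fraction < 0 || tr$pregnancy_fraction > 1))
        note("pregnancy_fraction out of [0, 1]: ", cc, ".", sc)
    }
    mp <- pars$manure[[cc]]
    if (is.null(mp)) { note("missing manure profile: ", cc) } else {
      if (is.null(mp$vs_rate) || mp$vs_rate <= 0)
        note("manure vs_rate must be positive: ", cc)
      if (is.null(mp$B0) || mp$B0 <= 0)
        note("manure B0 must be positive: ", cc)
      fr <- unlist(mp$system_fractions)
      if (is.null(fr) || !length(fr)) {
        note("missing system_fractions: ", cc)
      } else {
        if (abs(sum(fr) - 1) > 1e-9)
          note("system_fractions do not sum to 1: ", cc,
               " (sum = ", format(sum(fr)), ")")
        bad <- setdiff(names(fr), MGMT_SYSTEMS)
        if (length(bad))
          note("unknown management system for ", cc, ": ",
               paste(bad, collapse = ", "))
        for (s in names(fr)) for (k in CLIMATE_CLASSES) {
          m <- pars$mcf[[s]][[k]]
          if (is.null(m)) note("missing MCF cell: (", s, ", ", k, ")")
          else if (m <= 0 || m > 100) note("MCF out of (0, 100]: (", s, ", ", k, ")")
        }
      }
    }
  }

  for (cc in tier1) {
    ef <- pars$tier1_efs[[cc]]
    if (is.null(ef$enteric) || is.null(ef$manure))
      note("missing tier1 EF pair: ", cc)
    else if (ef$enteric < 0 || ef$manure < 0)
      note("tier1 EFs must be non-negative: ", cc)
  }

  for (cc in CATEGORY_CODES) {
    ls <- pars$lifespans[[cc]]
    if (is.null(ls$stock) || is.null(ls$slaughtered)) {
      note("missing lifespan entry: ", cc)
    } else {
      if (ls$stock <= 0 || ls$stock > 12 || ls$slaughtered <= 0 ||
          ls$slaughtered > 12)
        note("lifespans must lie in (0, 12] months: ", cc)
      if (ls$slaughtered > ls$stock)
        note("slaughtered lifespan exceeds stock lifespan: ", cc)
    }
    if (is.null(pars$cvs[[cc]]$ef) || is.null(pars$cvs[[cc]]$activity))
      note("missing CV entry: ", cc)
  }

  for (cc in names(pars$subclass_shares)) {
    sh <- unlist(pars$subclass_shares[[cc]])
    if (abs(sum(sh) - 1) > 1e-9)
      note("subclass_shares do not sum to 1: ", cc)
    if (!setequal(names(sh), subclasses_of(cc)))
      note("subclass_shares keys do not match subclasses: ", cc)
  }

  cn <- pars$constants
  if (is.null(cn$methane_energy_mj_per_kg) || cn$methane_energy_mj_per_kg <= 0)
    note("constants.methane_energy_mj_per_kg must be positive")
  if (is.null(cn$methane_density_kg_per_m3) || cn$methane_density_kg_per_m3 <= 0)
    note("constants.methane_density_kg_per_m3 must be positive")

  if (error && length(problems))
    stop("invalid parameter set:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(problems)
}

#' Read and write parameter configs
#'
#' `load_parameter_set()` reads a YAML (or JSON) config, overlays it on
#' the shipped defaults (so a config need only state the values it
#' changes, but a complete config round-trips exactly) and validates the
#' result. `write_parameter_set()` serialises a parameter set to YAML.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @param base Parameter set the config is overlaid on; use `NULL` to
#'   require a fully self-contained config.
#' @return `load_parameter_set()`: a validated `ch4_parameter_set`;
#'   `write_parameter_set()`: `path`, invisibly.
#' @export
load_parameter_set <- function(path, base = default_parameter_set()) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  pars <- if (is.null(base)) raw else modify_list_deep(unclass(base), raw)
  class(pars) <- "ch4_parameter_set"
  validate_parameter_set(pars)
  pars
}

#' @rdname load_parameter_set
#' @param pars A `ch4_parameter_set`.
#' @export
write_parameter_set <- function(pars, path) {
  yaml::write_yaml(unclass(pars), path)
  invisible(path)
}

# recursive list overlay: values in `new` replace values in `old`
modify_list_deep <- function(old, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(old[[nm]]) &&
        !is.null(names(new[[nm]]))) {
      old[[nm]] <- modify_list_deep(old[[nm]], new[[nm]])
    } else {
      old[[nm]] <- new[[nm]]
    }
  }
  old
}

#' @export
print.ch4_parameter_set <- function(x, ...) {
  cat("<ch4_parameter_set>\n")
  cat("  tier2 trait categories:", paste(names(x$traits), collapse = ", "), "\n")
  cat("  tier1 EF categories:   ", paste(names(x$tier1_efs), collapse = ", "), "\n")
  cat("  MCF systems:           ", length(x$mcf), "x",
      length(CLIMATE_CLASSES), "climate classes\n")
  cat("  methane density:       ", x$constants$methane_density_kg_per_m3,
      "kg m-3\n")
  invisible(x)
}
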