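test_that("REM and REG match hand-evaluated values and stay ordered", {
  expect_equal(rem(65), 0.5138, tolerance = 1e-4)
  expect_equal(rem(50), 1.123 - 0.2046 + 0.02815 - 0.508, tolerance = 1e-9)
  expect_equal(reg(65), 0.30849, tolerance = 1e-4)
  expect_gt(reg(45), 0)
  expect_error(rem(44.9), "45")
  expect_error(reg(85.1), "85")

  grid <- seq(45, 85, by = 0.1)
  expect_true(all(diff(rem(grid)) > 0))          # monotone increasing
  expect_true(all(rem(grid) > 0 & rem(grid) < 1))
  expect_true(all(reg(grid) > 0 & reg(grid) < 1))
  expect_true(all(reg(grid) < rem(grid)))        # growth < maintenance
})

test_that("net-energy components follow the subclass restrictions", {
  pars <- default_parameter_set()
  tr <- pars$traits$nondairy_cattle$other
  tr$body_weight <- 400; tr$feeding_situation <- "stall"
  comp <- net_energy_components(tr, "nondairy_cattle", "other", pars)
  expect_equal(comp$NE_m, 0.322 * 400^0.75, tolerance = 1e-9)
  expect_equal(comp$NE_m, 28.80, tolerance = 2e-3)
  # residual class: no lactation, pregnancy or growth; never any work
  expect_identical(c(comp$NE_l, comp$NE_p, comp$NE_g, comp$NE_work),
                   c(0, 0, 0, 0))

  # lactation: 10 kg day-1 at 3.5% fat -> 28.7 MJ day-1
  trf <- pars$traits$dairy_cattle$mature_female
  trf$milk_yield <- 10 * 365; trf$milk_fat <- 3.5
  compf <- net_energy_components(trf, "dairy_cattle", "mature_female", pars)
  expect_equal(compf$NE_l, 10 * (1.47 + 0.40 * 3.5), tolerance = 1e-9)
  expect_gt(compf$NE_p, 0)

  # growth only for young animals; activity scales with feeding situation
  try <- pars$traits$nondairy_cattle$young
  compy <- net_energy_components(try, "nondairy_cattle", "young", pars,
                                 mature_weight = 380)
  expect_equal(compy$NE_g,
               22.02 * (200 / 380)^0.75 * 0.4^1.097, tolerance = 1e-9)
  expect_equal(compy$NE_a, 0.17 * compy$NE_m, tolerance = 1e-12)

  tr$feeding_situation <- "no_such_system"
  expect_error(net_energy_components(tr, "nondairy_cattle", "other", pars),
               "feeding situation")
})

test_that("gross energy combines components per the energy model", {
  comp <- list(NE_m = 28.8, NE_a = 0, NE_l = 0, NE_work = 0, NE_p = 0,
               NE_g = 0, NE_wool = 0)
  expect_equal(gross_energy(comp, 65), (28.8 / rem(65)) / 0.65,
               tolerance = 1e-12)
  expect_equal(gross_energy(comp, 65), 86.24, tolerance = 2e-3)
  zero <- lapply(comp, function(x) 0)
  expect_identical(gross_energy(zero, 65), 0)

  # strictly decreasing in digestibility at fixed components
  ge <- vapply(seq(45, 85, by = 0.5), gross_energy, numeric(1),
               components = comp)
  expect_true(all(diff(ge) < 0))
  comp$NE_g <- -1
  expect_error(gross_energy(comp, 65), "non-negative")
})

test_that("Tier 2, dairy and Tier 1 emission factors match their formulas", {
  expect_equal(ef_enteric_tier2(250, 6.5), 250 * 0.065 * 365 / 55.65,
               tolerance = 1e-12)
  expect_equal(ef_enteric_tier2(250, 6.5), 106.58, tolerance = 1e-4)
  expect_identical(ef_enteric_tier2(250, 0), 0)
  expect_equal(ef_enteric_tier2(2 * 250, 6.5), 2 * ef_enteric_tier2(250, 6.5))
  expect_error(ef_enteric_tier2(-1, 6), "GE")
  expect_error(ef_enteric_tier2(100, 16), "Ym")

  expect_equal(ef_dairy(6000), oracle_ef_dairy(6000), tolerance = 1e-12)
  expect_equal(ef_dairy(6000), 121.86, tolerance = 1e-4)
  expect_equal(ef_dairy(4000), oracle_ef_dairy(4000), tolerance = 1e-12)
  prods <- seq(1000, 12000, by = 100)
  efs <- ef_dairy(prods)
  expect_true(all(diff(efs) > 0))        # increasing
  expect_true(all(diff(diff(efs)) < 0))  # concave
  expect_error(ef_dairy(10), "units")    # below the positive-EF domain
  expect_error(ef_dairy(0), "positive")

  pars <- default_parameter_set()
  expect_identical(ef_enteric_tier1("horse", pars),
                   pars$tier1_efs$horse$enteric)
  expect_error(ef_enteric_tier1("swine", pars), "tier2")
  expect_error(ef_enteric_tier1("dragon", pars), "unknown")
})

test_that("the enteric EF table covers the grid with the right pathways", {
  pars <- default_parameter_set()
  tab <- build_enteric_ef_table(pars, c("P1", "P2"), 2014:2015)
  expect_identical(nrow(tab), 2L * 2L * 20L)
  expect_true(all(tab$ef >= 0))
  expect_true(all(tab[!category %in% c("poultry"), ef] > 0))

  # heavier region -> larger nondairy EF; dairy ignores body weight
  mk_traits <- function(w_other) {
    tr <- data.table(region_id = "R", year = 2015L,
                     category = "nondairy_cattle", subclass = "other",
                     body_weight = w_other, weight_gain = 0, milk_yield = 0,
                     milk_fat = 0, wool_yield = 0, pregnancy_fraction = 0,
                     DE = 60, Ym = 6.5, feeding_situation = "pasture")
    setkey(tr, region_id, year, category, subclass)
    tr
  }
  t400 <- build_enteric_ef_table(pars, "R", 2015L, mk_traits(400))
  t300 <- build_enteric_ef_table(pars, "R", 2015L, mk_traits(300))
  pick <- function(t) t[category == "nondairy_cattle" & subclass == "other", ef]
  expect_gt(pick(t400), pick(t300))
  dairy <- function(t) t[category == "dairy_cattle", ef]
  expect_identical(dairy(t400), dairy(t300))

  # sanity envelope over the synthetic trait ranges
  w <- tiny_world()
  nd <- w$ent[category == "nondairy_cattle", ef]
  expect_true(all(nd >= 30 & nd <= 120))
  dc <- w$ent[category == "dairy_cattle", ef]
  expect_true(all(dc >= 60 & dc <= 180))
})

test_that("tier 2 EF responds monotonically to its drivers", {
  pars <- default_parameter_set()
  base <- pars$traits$nondairy_cattle$other
  ef_of <- function(field, value) {
    tr <- base; tr[[field]] <- value
    comp <- net_energy_components(tr, "nondairy_cattle", "other", pars)
    ef_enteric_tier2(gross_energy(comp, tr$DE), tr$Ym)
  }
  expect_true(all(diff(sapply(seq(250, 500, 25), function(v)
    ef_of("body_weight", v))) > 0))
  expect_true(all(diff(sapply(seq(45, 85, 5), function(v)
    ef_of("DE", v))) < 0))
  expect_true(all(diff(sapply(seq(4, 8, 0.5), function(v)
    ef_of("Ym", v))) > 0))
  expect_true(all(diff(ef_dairy(seq(3000, 9000, 500))) > 0))
})
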