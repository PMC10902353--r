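mk_variant_panels <- function(stocks) {
  lapply(stocks, function(s) data.table(
    city_id = "C1", province_id = "P1", year = 2015L, category = "swine",
    subclass = "whole_herd", stock_head = s, slaughtered_head = 0,
    source_flag = "observed"))
}

test_that("activity CV implements the deviation-from-mean reading", {
  v <- mk_variant_panels(c(90, 100, 110))
  expect_equal(activity_cv(v)$cv, (10 + 0 + 10) / 3 / 100, tolerance = 1e-12)
  expect_equal(activity_cv(mk_variant_panels(c(100, 100, 100)))$cv, 0)
  # scale invariance
  expect_equal(activity_cv(mk_variant_panels(c(900, 1000, 1100)))$cv,
               activity_cv(v)$cv, tolerance = 1e-12)
  # pairwise reading as documented alternative
  expect_equal(activity_cv(v, method = "pairwise")$cv,
               (10 + 20 + 10) / 3 / 100, tolerance = 1e-12)
  # zero-mean cells are skipped with a warning, others still scored
  vz <- lapply(1:3, function(k) rbind(
    mk_variant_panels(c(0, 0, 0))[[k]],
    data.table(city_id = "C2", province_id = "P1", year = 2015L,
               category = "swine", subclass = "whole_herd",
               stock_head = c(90, 100, 110)[k], slaughtered_head = 0,
               source_flag = "observed")))
  expect_warning(res <- activity_cv(vz), "skipped")
  expect_equal(res$cv, (10 + 0 + 10) / 3 / 100, tolerance = 1e-12)

  # head-count weighting across cells of one category
  v2 <- lapply(1:3, function(k) rbind(
    mk_variant_panels(c(90, 100, 110))[[k]],
    data.table(city_id = "C2", province_id = "P1", year = 2015L,
               category = "swine", subclass = "whole_herd",
               stock_head = c(300, 300, 300)[k], slaughtered_head = 0,
               source_flag = "observed")))
  want <- (100 * (20 / 3 / 100) + 300 * 0) / 400
  expect_equal(activity_cv(v2)$cv, want, tolerance = 1e-12)
})

test_that("uncertainty specs validate their inputs", {
  expect_error(uncertainty_spec(n_sims = 50), "100")
  expect_error(uncertainty_spec(ci_level = 1), "ci_level")
  expect_error(uncertainty_spec(ef_cv = c(swine = -0.1)), "CVs")
  s <- uncertainty_spec(n_sims = 500, seed = 3,
                        ef_cv = c(swine = 0.3))
  expect_equal(s$ef_cv[["swine"]], 0.3)
  expect_equal(s$ef_cv[["horse"]], default_parameter_set()$cvs$horse$ef)
})

test_that("sampled factors reproduce the stated distribution moments", {
  cats <- "swine"
  spec <- uncertainty_spec(n_sims = 10000L, seed = 4L,
                           ef_cv = c(swine = 0.2),
                           activity_cv_map = c(swine = 0.1))
  f <- livestockCH4:::mc_factors(spec, cats)
  expect_equal(stats::sd(f$ef[, 1]) / mean(f$ef[, 1]), 0.2,
               tolerance = 0.01 / 0.2)
  expect_equal(stats::sd(f$activity[, 1]) / mean(f$activity[, 1]), 0.1,
               tolerance = 0.005 / 0.1)
  expect_true(all(f$ef > 0))
  # uniform bounds: mean +- sqrt(3) * cv * mean
  expect_true(all(f$activity[, 1] >= 1 - sqrt(3) * 0.1 - 1e-12 &
                    f$activity[, 1] <= 1 + sqrt(3) * 0.1 + 1e-12))

  # CV = 0 -> factors are exactly 1
  spec0 <- uncertainty_spec(n_sims = 200L, seed = 4L,
                            ef_cv = c(swine = 0),
                            activity_cv_map = c(swine = 0))
  f0 <- livestockCH4:::mc_factors(spec0, cats)
  expect_true(all(f0$ef == 1) && all(f0$activity == 1))
})

test_that("the fast Monte Carlo path equals literal pipeline reruns", {
  w <- tiny_world()
  spec <- uncertainty_spec(n_sims = 200L, seed = 11L, pars = w$pars)
  res <- run_monte_carlo(w$filled, w$ent, w$man, w$tc$climate, spec, w$pars)
  draws <- attr(res, "draws")
  for (k in c(1L, 57L, 200L)) {
    pert <- sample_inputs(w$filled, w$ent, w$man, spec, k)
    cube_k <- compute_emissions(pert$panel, pert$enteric_ef,
                                pert$manure_ef, w$tc$climate, w$pars)
    natl <- aggregate_emissions(cube_k, "national")[
      , .(tot = sum(emissions_gg)), keyby = year]
    expect_equal(unname(draws[k, ]), natl$tot, tolerance = 1e-9)
  }
})

test_that("Monte Carlo results are calibrated and reproducible", {
  w <- tiny_world()
  zero <- setNames(rep(0, 12), livestock_categories()$category)
  spec0 <- uncertainty_spec(n_sims = 200L, seed = 2L, ef_cv = zero,
                            activity_cv_map = zero)
  res0 <- run_monte_carlo(w$filled, w$ent, w$man, w$tc$climate, spec0,
                          w$pars)
  expect_equal(res0$ci_low, res0$point_estimate, tolerance = 1e-12)
  expect_equal(res0$ci_high, res0$point_estimate, tolerance = 1e-12)

  spec <- uncertainty_spec(n_sims = 400L, seed = 21L, pars = w$pars)
  r1 <- run_monte_carlo(w$filled, w$ent, w$man, w$tc$climate, spec, w$pars)
  r2 <- run_monte_carlo(w$filled, w$ent, w$man, w$tc$climate, spec, w$pars)
  expect_identical(as.data.table(r1), as.data.table(r2))
  expect_true(all(r1$ci_low <= r1$sim_mean & r1$sim_mean <= r1$ci_high))
  expect_true(all(r1$rel_low_pct <= 0 & r1$rel_high_pct >= 0))

  # symmetric CVs <= 0.2: simulated mean concentrates on the point estimate
  caps <- setNames(pmin(
    vapply(default_parameter_set()$cvs, `[[`, numeric(1), "ef"), 0.2),
    livestock_categories()$category)
  spec_c <- uncertainty_spec(n_sims = 2000L, seed = 9L, ef_cv = caps)
  rc <- run_monte_carlo(w$filled, w$ent, w$man, w$tc$climate, spec_c,
                        w$pars)
  expect_true(all(abs(rc$sim_mean / rc$point_estimate - 1) < 0.01))
})

test_that("CI width grows with every CV", {
  w <- tiny_world()
  width_at <- function(mult) {
    base <- default_parameter_set()$cvs
    ef <- setNames(vapply(base, `[[`, numeric(1), "ef") * mult,
                   names(base))
    act <- setNames(vapply(base, `[[`, numeric(1), "activity") * mult,
                    names(base))
    spec <- uncertainty_spec(n_sims = 400L, seed = 13L, ef_cv = ef,
                             activity_cv_map = act)
    res <- run_monte_carlo(w$filled, w$ent, w$man, w$tc$climate, spec,
                           w$pars)
    mean(res$ci_high - res$ci_low)
  }
  widths <- vapply(c(0.5, 1, 2), width_at, numeric(1))
  expect_true(all(diff(widths) > 0))
})
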