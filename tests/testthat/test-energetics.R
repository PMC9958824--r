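test_that("per-ion works of isotonic mixing match the printed energy budget", {
  w <- mixing_work_closed(default_model)
  expect_equal(unname(round(w[c("Na", "K", "Cl", "HCO3", "A")], 1)),
               c(138.5, 8.6, 109.4, 13.3, 0.0))
  expect_equal(sum(w), 269.8, tolerance = 2e-4)
  # no work at the start of the path
  expect_equal(unname(mixing_work_closed(default_model, 0.25)), rep(0, 5))
})

test_that("closed form agrees with the quadrature oracle everywhere", {
  m <- default_model
  for (at in c(m$equilibrium$omega, 0.05, 0.1, 0.2)) {
    closed <- mixing_work_closed(m, at)
    for (sp in c("Na", "K", "Cl", "HCO3")) {
      num <- mixing_work_numeric(m, sp, at, n_steps = 1e5)
      expect_equal(num, closed[[sp]], tolerance = 1e-6)
    }
  }
  expect_equal(mixing_work_numeric(m, "Na", n_steps = 1e6), 138.5,
               tolerance = 1e-3)
  expect_equal(mixing_work_numeric(m, "A"), 0)
  expect_error(mixing_work_numeric(m, "Na", n_steps = 10), "at least 100")
})

test_that("quadrature error shrinks monotonically with refinement", {
  m <- default_model
  closed <- mixing_work_closed(m)[["Na"]]
  errs <- vapply(c(400, 800, 1600, 3200, 6400),
                 function(n) abs(mixing_work_numeric(m, "Na", n_steps = n) -
                                   closed), NA_real_)
  expect_true(all(diff(errs) < 0))
})

test_that("a zero-gradient species does no work of mixing", {
  zg <- swell_model(zero_gradient_ions())
  expect_equal(coef(zg)[["Na"]], 150)        # c_K equals the flat concentration
  expect_equal(mixing_work_closed(zg)[["Na"]], 0, tolerance = 1e-12)
  expect_equal(mixing_work_numeric(zg, "Na"), 0, tolerance = 1e-12)
})

test_that("osmotic work follows the sign pattern and cancels in total", {
  m <- default_model
  for (at in c(m$equilibrium$omega, 0.05, 0.12, 0.2)) {
    osm <- osmotic_work(m, at)
    expect_lte(osm[["Na"]], 0)      # shrinking high-concentration compartment
    expect_lte(osm[["Cl"]], 0)
    expect_gte(osm[["K"]], 0)       # expanding high-concentration compartment
    expect_gte(osm[["A"]], 0)
    expect_equal(sum(osm), 0, tolerance = 1e-9)
  }
  expect_equal(unname(osmotic_work(m, 0.25)), rep(0, 5))
  expect_error(osmotic_work(m, -0.1))
})

test_that("the word equation holds: mixing = chemical-potential drop - osmotic work", {
  m <- default_model
  for (at in c(m$equilibrium$omega, 0.1, 0.2)) {
    v <- volume_change(at, m$alpha)
    s <- path_state(m, at)
    drop <- isoswell:::.chem_drop(m$constants, m$alpha,
                                  m$ions$conc_out, m$ions$conc_in,
                                  s$conc_out, s$conc_in, v$w, v$y)
    expect_equal(unname(mixing_work_closed(m, at)),
                 unname(drop) - unname(osmotic_work(m, at)), tolerance = 1e-9)
  }
  # impermeant anions: zero mixing work, so their osmotic work equals the
  # full drop of their chemical potential energy (term cancellation)
  at <- m$equilibrium$omega
  v <- volume_change(at, m$alpha)
  s <- path_state(m, at)
  dropA <- isoswell:::.chem_drop(m$constants, m$alpha, 10, 134,
                                 s$conc_out[["A"]], s$conc_in[["A"]], v$w, v$y)
  expect_equal(osmotic_work(m, at)[["A"]], dropA, tolerance = 1e-9)
  expect_equal(mixing_work_closed(m, at)[["A"]], 0)
})

test_that("isochoric complete mixing redistributes but conserves the total work", {
  b <- isochoric_complete_mixing(default_model)
  expect_equal(unname(round(b$mixing_work[c("Na", "K", "Cl", "A", "HCO3")], 1)),
               c(80.3, 66.8, 64.4, 53.1, 5.1))
  expect_equal(b$total_mixing, sum(mixing_work_closed(default_model)),
               tolerance = 1e-9)
  expect_equal(b$total_osmotic, 0)
  # an already mixed system releases nothing
  ions <- ion_table(c("Na", "Cl", "A"), c(1, -1, -1), c(TRUE, TRUE, FALSE),
                    conc_out = c(150, 50, 100), conc_in = c(150, 50, 100))
  b0 <- isochoric_complete_mixing(swell_model(ions))
  expect_equal(unname(b0$mixing_work), rep(0, 3))
})

test_that("work toward Donnan equilibria matches its printed anchors", {
  m <- default_model
  b25 <- work_to_donnan(m, 0.25)
  expect_equal(b25$total_mixing, 197, tolerance = 5e-4)
  expect_equal(b25$total_osmotic, 0)
  expect_equal(b25$mixing_work[["A"]], 0)
  # at omega the Donnan target is the full-equilibrium state itself
  bo <- work_to_donnan(m, m$equilibrium$omega)
  expect_equal(unname(bo$mixing_work),
               unname(mixing_work_closed(m)), tolerance = 1e-9)
  expect_equal(bo$total_osmotic, 0, tolerance = 1e-9)
  # in between, swelling toward a Donnan state does net osmotic work
  for (at in c(0.05, 0.1, 0.15, 0.2))
    expect_gt(work_to_donnan(m, at)$total_osmotic, 0)
  expect_error(work_to_donnan(m, 0.3), "alpha\\]")
})

test_that("the equal-work volume reproduces the halving of extracellular space", {
  m <- default_model
  a_eq <- find_equal_work_volume(m)
  target <- work_to_donnan(m, 0.25)$total_mixing
  expect_lt(abs(sum(mixing_work_closed(m, a_eq)) - target), 1e-9)
  expect_equal(a_eq, 0.115, tolerance = 0.02)
  expect_equal(round(100 * (1 - a_eq / m$alpha)), 54)  # shrinks by 54%
  # degenerate: asking for the full-equilibrium work returns omega itself
  expect_equal(find_equal_work_volume(m, sum(mixing_work_closed(m))),
               m$equilibrium$omega)
  expect_error(find_equal_work_volume(m, 1e4), "no crossing")
})

test_that("total isotonic mixing work increases monotonically during shrinkage", {
  m <- default_model
  grid <- seq(m$equilibrium$omega, m$alpha, length.out = 150)
  W <- vapply(grid, function(a) sum(mixing_work_closed(m, a)), NA_real_)
  expect_true(all(diff(W) < 0))   # grid ascends, work accumulates downward
  expect_equal(W[length(W)], 0, tolerance = 1e-12)
})

test_that("alternative isotonic plans do less work than the full-equilibrium path", {
  mv <- swell_model(c_override = c(Na = 179, K = -27))
  # still isotonic and electro-neutral ...
  expect_true(audit_path(mv, n_points = 200, from = mv$alpha_min)$pass)
  # ... but Na+ depletes before the anions equalise, truncating the path
  W_var <- sum(mixing_work_closed(mv, mv$alpha_min))
  expect_lt(W_var, 269.8)
  expect_gt(W_var, 0)
})

test_that("the van 't Hoff equivalence and water stoichiometry are reproduced", {
  p <- vant_hoff_pressure(1)
  expect_equal(p$pascal, 2576, tolerance = 1e-3)   # reference value uses R rounded to 8.31
  expect_equal(p$mmHg, 19.3, tolerance = 3e-3)  # printed to 3 significant figures
  expect_equal(vant_hoff_pressure(0)$pascal, 0)
  expect_equal(vant_hoff_pressure(171)$pascal, 171 * p$pascal, tolerance = 1e-12)

  wpi <- water_per_ion(default_model)
  expect_equal(wpi$overall, 183, tolerance = 2e-3)    # 55.6 M / 0.304 M
  expect_equal(wpi$per_species[["Cl"]], 458, tolerance = 2e-3)
  expect_true(is.na(wpi$per_species[["A"]]))
  # a carrier transporting at the water molarity moves one H2O per ion
  expect_equal(55.6e3 / water_per_ion(default_model)$overall, 304,
               tolerance = 1e-12)
})

test_that("mixing work rejects negative final concentrations", {
  m <- default_model
  expect_error(
    isoswell:::.eq12(m$constants, m$alpha, m$ions$conc_out, m$ions$conc_in,
                     c(-1, 4, 113, 29, 10), m$ions$conc_in, 1, 1,
                     coef(m), m$ions$permeant),
    "non-negative")
})
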