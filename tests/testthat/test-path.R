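test_that("path endpoints reproduce the initial and full-equilibrium states", {
  m <- default_model
  s0 <- path_state(m, 0.25)
  expect_equal(unname(s0$conc_out), m$ions$conc_out, tolerance = 1e-12)
  expect_equal(unname(s0$conc_in), m$ions$conc_in, tolerance = 1e-12)

  se <- path_state(m, m$equilibrium$omega)
  expect_equal(unname(se$conc_out), unname(m$equilibrium$K_e), tolerance = 1e-12)
  expect_equal(unname(se$conc_out[m$ions$permeant]),
               unname(se$conc_in[m$ions$permeant]), tolerance = 1e-12)
})

test_that("an intermediate state matches hand-evaluated hyperbolic laws", {
  # at alpha_tilde = 0.1 (w = 0.4, y = 1.2): Ko = c_K - (c_K - Ko*)/w
  s <- path_state(default_model, 0.1)
  cK <- coef(default_model)
  Ko0 <- c(Na = 148, K = 4, Cl = 113, HCO3 = 29)
  expected <- cK[names(Ko0)] - (cK[names(Ko0)] - Ko0) / 0.4
  expect_equal(s$conc_out[names(Ko0)], expected, tolerance = 1e-12)
  expect_equal(s$conc_out[["A"]], 10 / 0.4)        # 25 mM, pure rescaling
  expect_equal(total_concentration(s, "outside"), 304, tolerance = 1e-12)
  expect_equal(charge_imbalance(s, "outside"), 0, tolerance = 1e-12)
  expect_true(attr(s, "below_equilibrium") == FALSE)
  expect_true(attr(path_state(default_model, 0.02), "below_equilibrium"))
})

test_that("validity range matches a brute-force scan and the depletion bound", {
  m <- default_model
  # brute-force: finest alpha_tilde at which all concentrations stay >= 0
  scan <- seq(1e-4, m$alpha, by = 1e-5)
  ok <- vapply(scan, function(a) {
    v <- volume_change(a, m$alpha)
    cK <- coef(m)
    Ko <- cK - (cK - m$ions$conc_out) / v$w
    Ki <- cK - (cK - m$ions$conc_in) / v$y
    imp <- !m$ions$permeant
    Ko[imp] <- m$ions$conc_out[imp] / v$w
    Ki[imp] <- m$ions$conc_in[imp] / v$y
    all(Ko >= 0 & Ki >= 0)
  }, NA)
  brute <- scan[which(ok)[1]]
  expect_equal(m$alpha_min, brute, tolerance = 1e-3)
  expect_lte(m$alpha_min, 0.02)    # physical solutions disappear below ~0.02
  # each species' own closed-form depletion volume
  expect_equal(0.25 * (coef(m)[["Na"]] - 148) / coef(m)[["Na"]], 0.01725,
               tolerance = 1e-3)
  expect_equal(m$alpha_min, 0.25 * (coef(m)[["Cl"]] - 113) / coef(m)[["Cl"]],
               tolerance = 1e-12)
  expect_error(path_state(m, 0.01), "below the validity bound")

  # pure volume rescaling (all c_K = 0) never depletes anything
  m0 <- swell_model(c_override = c(Na = 0, K = 0, Cl = 0, HCO3 = 0))
  expect_equal(m0$alpha_min, 0)
})

test_that("the raised-sodium transport plan depletes Na+ before equilibrium", {
  mv <- swell_model(c_override = c(Na = 179, K = -27))
  expect_equal(mv$alpha_min, 0.25 * 31 / 179, tolerance = 1e-12)
  expect_identical(mv$alpha_min_species, "Na")
  expect_gt(mv$alpha_min, mv$equilibrium$omega)  # blocks full equilibration
  s <- path_state(mv, mv$alpha_min)
  expect_equal(s$conc_out[["Na"]], 0, tolerance = 1e-9)
})

test_that("Nernst potentials take textbook values and converge to zero at omega", {
  expect_equal(nernst_potential(100, 100, 1), 0)
  expect_equal(nernst_potential(148, 12, 1), 67.1, tolerance = 1e-3)
  # independent arithmetic: (RT/F) ln(148/12) at 310 K
  expect_equal(nernst_potential(148, 12, 1),
               1000 * 8.3145 * 310 / 96485 * log(148 / 12), tolerance = 1e-12)
  expect_equal(nernst_potential(10, 100, -1), nernst_potential(100, 10, 1),
               tolerance = 1e-12)
  s <- path_state(default_model, default_model$equilibrium$omega)
  perm <- default_model$ions$permeant
  vn <- nernst_potential(s$conc_out[perm], s$conc_in[perm],
                         default_model$ions$valence[perm])
  expect_lt(max(abs(vn)), 1e-9)
  expect_error(nernst_potential(0, 10, 1), "positive")
})

test_that("inter-ion relations are straight lines with the printed slopes", {
  m <- default_model
  expect_equal(interion_slope(m, "Na", "K"), -1)
  expect_equal(interion_slope(m, "Cl", "K"), -105 / 136)  # about -0.77
  zg <- swell_model(zero_gradient_ions())
  expect_error(interion_slope(zg, "Cl", "Na"), "zero physiological gradient")
  expect_equal(interion_slope(zg, "Na", "Cl"), 0)
  # finite-difference slope along the path matches exactly (linear in 1/w)
  grid <- seq(m$equilibrium$omega, m$alpha, length.out = 200)
  pr <- predict(m, grid)
  na <- pr$conc_out[pr$species == "Na"]
  k <- pr$conc_out[pr$species == "K"]
  cl <- pr$conc_out[pr$species == "Cl"]
  expect_lt(max(abs(diff(na) / diff(k) - interion_slope(m, "Na", "K"))), 1e-9)
  expect_lt(max(abs(diff(cl) / diff(k) - interion_slope(m, "Cl", "K"))), 1e-9)
})

test_that("extracellular concentrations move monotonically during shrinkage", {
  grid <- seq(default_model$equilibrium$omega, 0.25, length.out = 300)
  pr <- predict(default_model, grid)
  out <- function(sp) pr$conc_out[pr$species == sp]
  expect_true(all(diff(out("K")) < 0))   # rises as alpha_tilde falls
  expect_true(all(diff(out("A")) < 0))
  expect_true(all(diff(out("Na")) > 0))  # falls as alpha_tilde falls
  expect_true(all(diff(out("Cl")) > 0))
})

test_that("all intermediate path states are isotonic, electro-neutral and conservative", {
  aud <- audit_path(default_model, n_points = 1000)
  expect_true(aud$pass)
  expect_lt(max(aud$max_residuals), 1e-9)
  # endpoints only
  aud2 <- audit_path(default_model, n_points = 2)
  expect_lt(max(aud2$max_residuals), 1e-9)
  expect_error(audit_path(default_model, n_points = 1), "at least 2")
  # randomized models inherit the theorem too
  set.seed(7)
  for (rep in 1:5) {
    m <- swell_model(random_ions(), runif(1, 0.15, 0.4))
    expect_true(audit_path(m, n_points = 200)$pass)
  }
})

test_that("a non-isotonic transport plan breaks the audits progressively", {
  m1 <- swell_model(c_override = c(Na = coef(default_model)[["Na"]] + 1))
  aud <- audit_path(m1, n_points = 200)
  expect_false(aud$pass)
  # residuals grow monotonically as the extracellular space shrinks
  tono <- abs(aud$per_point[, "tonicity_out"])
  expect_true(all(diff(tono) < 1e-12))   # grid runs from omega up to alpha
  expect_gt(tono[1], tono[200])
})

test_that("path state and Donnan equilibrium intersect at omega", {
  omega <- default_model$equilibrium$omega
  ps <- path_state(default_model, omega)
  d <- donnan_equilibrium(default_model, omega)
  expect_equal(unname(ps$conc_out), unname(d$state$conc_out), tolerance = 1e-9)
  expect_equal(unname(ps$conc_in), unname(d$state$conc_in), tolerance = 1e-9)
})
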