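test_that("fiber stretch follows the in-plane kinematics", {
  expect_equal(fiber_stretch(1.7, 1.28, 0), 1.28)
  expect_equal(fiber_stretch(1.7, 1.28, 90), 1.7)
  ## diagonal family, checked against a direct evaluation of the formula
  e <- 41.92 * pi / 180
  expect_equal(fiber_stretch(1.7, 1.28, 41.92),
               sqrt(1.28^2 * cos(e)^2 + 1.7^2 * sin(e)^2), tolerance = 1e-12)
  ## the two diagonal families are mirror images
  expect_equal(fiber_stretch(1.3, 1.28, 41.92), fiber_stretch(1.3, 1.28, -41.92))
  expect_error(fiber_stretch(-1, 1.28, 0), "positive")
})

mod <- umbilical_artery_model()

test_that("passive extra stress has the right closed forms", {
  ## all fiber terms vanish at lambda_k = 1
  s <- passive_extra_stress(1, 1, 1, mod$outer)
  expect_equal(unlist(s), c(srr = 0.1, stt = 0.1, szz = 0.1))
  ## inner layer is neo-Hookean only
  s <- passive_extra_stress(0.7, 1.5, 1.28, mod$inner)
  expect_equal(unlist(s), 3.0 * c(srr = 0.7^2, stt = 1.5^2, szz = 1.28^2))
  ## loaded outer layer: circumferential dominates radial
  s <- passive_extra_stress(0.6, 1.6, 1.28, mod$outer)
  expect_true(is.finite(s$stt) && s$stt > s$srr && s$stt > 0)
})

test_that("extra stress equals lambda_i dW/dlambda_i by finite differences", {
  for (material in list(mod$inner, mod$outer)) {
    ## stretch ranges keep the exponential fiber terms moderate so the
    ## central-difference oracle is not dominated by cancellation error
    lam <- cbind(runif_seeded(8, 0.6, 1.3, 101),
                 runif_seeded(8, 0.7, 1.25, 102),
                 runif_seeded(8, 0.95, 1.25, 103))
    for (k in seq_len(nrow(lam))) {
      lr <- lam[k, 1]; lt <- lam[k, 2]; lz <- lam[k, 3]
      s <- passive_extra_stress(lr, lt, lz, material)
      expect_equal(s$srr, lr * fd_deriv(function(x)
        oracle_energy(x, lt, lz, material), lr), tolerance = 1e-6)
      expect_equal(s$stt, lt * fd_deriv(function(x)
        oracle_energy(lr, x, lz, material), lt), tolerance = 1e-6)
      expect_equal(s$szz, lz * fd_deriv(function(x)
        oracle_energy(lr, lt, x, material), lz), tolerance = 1e-6)
    }
  }
})

test_that("fiber stress is tension-only and monotone in extension", {
  lt <- seq(0.4, 2.0, by = 0.05)
  s <- passive_extra_stress(rep(1, length(lt)), lt, rep(1, length(lt)),
                            mod$outer)
  fib <- s$stt - mod$outer$mu * lt^2   # isolate the fiber contribution
  ## compressed circumferential families contribute nothing beyond the
  ## (slightly taut at lambda_z = 1? here lambda_z = 1 so no) axial family
  expect_true(all(fib[lt <= 1] < 1e-12))
  ext <- fib[lt >= 1.05]
  expect_true(all(diff(ext) > 0))
  expect_true(all(ext >= 0))
})

test_that("stresses scale linearly in mu and c1", {
  m1 <- layer_material(1, fibers = list(fiber_family(2, 3, 30)))
  m2 <- layer_material(2, fibers = list(fiber_family(4, 3, 30)))
  s1 <- passive_extra_stress(0.8, 1.4, 1.1, m1)
  s2 <- passive_extra_stress(0.8, 1.4, 1.1, m2)
  expect_equal(unlist(s2), 2 * unlist(s1), tolerance = 1e-12)
})

test_that("active tone law matches its closed-form values", {
  tone <- active_tone(50, 2.5, 0.2)
  expect_equal(active_stress(0.2, tone), 0)
  expect_equal(active_stress(2.5, tone), 125)
  expect_equal(active_stress(1.35, tone), 50 * 1.35 * (1 - (1.15 / 2.3)^2))
  ## zero outside the contractile window, continuous at its edges
  expect_equal(active_stress(0.12, tone), 0)
  expect_lt(active_stress(0.2 + 1e-8, tone), 1e-5)
  ## linear in T_act
  expect_equal(active_stress(1.1, tone, T_act = 80),
               8 * active_stress(1.1, tone, T_act = 10))
  ## slope consistent with finite differences inside the window
  for (lt in c(0.5, 1.0, 1.8, 2.3)) {
    expect_equal(active_stress_slope(lt, tone),
                 fd_deriv(function(x) active_stress(x, tone), lt),
                 tolerance = 1e-6)
  }
  expect_error(active_tone(10, lambda_m = 0.2, lambda_0 = 2.5), "lambda_0")
})

test_that("parameter containers validate their invariants", {
  expect_error(vessel_geometry(200, 150, 250), "A < B < C")
  expect_error(layer_material(-1), "positive")
  expect_error(fiber_family(1, 1, 120), "eta")
  expect_error(active_tone(-5), "non-negative")
})

test_that("the packaged parameter file reproduces the published set", {
  g <- mod$geometry
  expect_equal(c(g$A, g$B, g$C, g$lambda_z), c(161.77, 206.86, 236.92, 1.28))
  expect_equal(mod$inner$mu, 3.0)
  expect_equal(mod$outer$mu, 0.1)
  f <- mod$outer$fibers
  expect_equal(vapply(f, `[[`, numeric(1), "c1"), c(0.013, 2.66, 3.04, 3.04))
  expect_equal(vapply(f, `[[`, numeric(1), "c2"), c(11.65, 1.20, 4.23, 4.23))
  expect_equal(vapply(f, `[[`, numeric(1), "eta"), c(0, 90, 41.92, -41.92))
  expect_equal(c(mod$tone$lambda_m, mod$tone$lambda_0), c(2.5, 0.2))
  expect_false(mod$inner$contractile)
  expect_true(mod$outer$contractile)
})
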