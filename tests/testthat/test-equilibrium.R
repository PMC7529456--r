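mod <- umbilical_artery_model()
geom <- mod$geometry

test_that("radius map honours the per-layer volumetric constraints", {
  ## identity map in the stress-free reference
  f <- radius_map(geom$A, geom, v = 1, lambda_z = 1)
  R <- seq(geom$A, geom$C, length.out = 11)
  expect_equal(f(R), R, tolerance = 1e-12)
  ## closed form for the loaded outer radius
  f <- radius_map(161.77, geom, v = 1, lambda_z = 1.28)
  expect_equal(f(geom$C), sqrt(161.77^2 + (geom$C^2 - geom$A^2) / 1.28),
               tolerance = 1e-12)
  ## halving v halves the deformed inner annular volume at equal a
  f1 <- radius_map(200, geom, v = 1);  b1 <- attr(f1, "b")
  f5 <- radius_map(200, geom, v = 0.5); b5 <- attr(f5, "b")
  expect_equal((b5^2 - 200^2) / (b1^2 - 200^2), 0.5, tolerance = 1e-12)
  expect_error(f1(geom$C + 10), "outside")
  expect_error(radius_map(-5, geom), "non-negative")
})

test_that("luminal pressure vanishes in the reference and round-trips 25 mmHg", {
  expect_equal(luminal_pressure(mod, geom$A, T_act = 0, v = 1, lambda_z = 1),
               0, tolerance = 1e-10)
  st <- solve_inner_radius(mod, 25)
  expect_equal(luminal_pressure(mod, st$a), mmHg_to_kPa(25), tolerance = 1e-6)
  expect_equal(mmHg_to_kPa(25), 3.33305, tolerance = 1e-6)
  ## activation raises the pressure carried at fixed geometry
  P <- vapply(c(0, 20, 40, 60), function(Tq)
    luminal_pressure(mod, 250, T_act = Tq), numeric(1))
  expect_true(all(diff(P) > 0))
})

test_that("the unloaded reference is the zero-pressure solution", {
  st <- solve_inner_radius(mod, 0, T_act = 0, v = 1, lambda_z = 1)
  expect_equal(st$a, geom$A, tolerance = 1e-4)
})

test_that("solved states satisfy boundary conditions and volume constraints", {
  cases <- data.frame(P = runif_seeded(6, 2, 25, 11),
                      v = runif_seeded(6, 0.5, 1.3, 12),
                      T_act = c(0, 0, 10, 25, 40, 5))
  for (k in seq_len(nrow(cases))) {
    st <- solve_inner_radius(mod, cases$P[k], T_act = cases$T_act[k],
                             v = cases$v[k])
    prof <- st$profiles
    ## traction boundary conditions
    expect_equal(prof$srr[1], -st$P_kPa, tolerance = 1e-5)
    expect_lt(abs(prof$srr[nrow(prof)]), 1e-5)
    ## radial stress continuous at the interface
    i <- which(prof$layer == "inner"); o <- which(prof$layer == "outer")
    expect_equal(prof$srr[max(i)], prof$srr[min(o)], tolerance = 1e-8)
    ## per-layer volumetric constraints (deformed/reference, per unit
    ## reference length, axial stretch included)
    ratio_in <- st$lambda_z * (st$b^2 - st$a^2) / (geom$B^2 - geom$A^2)
    ratio_out <- st$lambda_z * (st$c_out^2 - st$b^2) / (geom$C^2 - geom$B^2)
    expect_equal(ratio_in, cases$v[k], tolerance = 1e-6)
    expect_equal(ratio_out, 1, tolerance = 1e-6)
  }
})

test_that("equilibria agree with the total-potential-energy oracle", {
  set.seed(21)
  cases <- data.frame(P = runif(10, 2, 25),
                      v = runif(10, 0.6, 1.3),
                      lz = runif(10, 1.1, 1.4))
  for (k in seq_len(nrow(cases))) {
    st <- solve_inner_radius(mod, cases$P[k], v = cases$v[k],
                             lambda_z = cases$lz[k])
    a_or <- oracle_equilibrium_radius(mod, cases$P[k], v = cases$v[k],
                                      lambda_z = cases$lz[k])
    expect_equal(st$a, a_or, tolerance = 1e-3)
  }
})

test_that("passive swelling narrows the pressurized lumen", {
  a1 <- solve_inner_radius(mod, 25, v = 1)$a
  a_sw <- solve_inner_radius(mod, 25, v = 1.3)$a
  expect_lt(a_sw, a1)
})

test_that("closure curves are normalized, monotone and plateau", {
  Tg <- seq(0, 150, by = 5)
  sw <- closure_sweep(mod, P = 25, T_act = Tg, v = c(0.5, 1))
  for (vv in c(0.5, 1)) {
    cur <- sw[sw$v == vv, ]
    expect_equal(cur$a_normalized[1], 1)
    expect_true(all(diff(cur$a_um) <= 1e-6))
    ## near-constant radius at the top of the grid
    tail_slope <- abs(diff(tail(cur$a_um, 3)) / diff(tail(cur$T_act_kPa, 3)))
    expect_true(all(tail_slope < 0.5))   # um per kPa
  }
  ## strong contraction with volume loss narrows more than without
  a_low <- sw$a_um[sw$v == 0.5 & sw$T_act_kPa == 150]
  a_high <- sw$a_um[sw$v == 1 & sw$T_act_kPa == 150]
  expect_lt(a_low, a_high)
  ## the transition is sharper for the shrunken inner layer
  tr <- attr(sw, "transitions")
  expect_gt(tr$max_abs_slope[tr$v == 0.5], tr$max_abs_slope[tr$v == 1])
})

test_that("swelling crossover is located and grid-robust", {
  expect_error(swelling_crossover(mod, v_low = 1, v_high = 1), "v_low < v_high")
  cr1 <- swelling_crossover(mod, P = 25, v_low = 0.5, v_high = 1,
                            T_act = seq(30, 70, by = 10))
  cr2 <- swelling_crossover(mod, P = 25, v_low = 0.5, v_high = 1,
                            T_act = seq(30, 70, by = 5))
  expect_true(is.finite(cr1$T_cross))
  expect_lt(abs(cr1$T_cross - cr2$T_cross), 1)
})
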