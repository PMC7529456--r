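mod <- umbilical_artery_model()

test_that("incremental moduli reduce to the classical isotropic limit", {
  ## stress-free neo-Hookean point: plane-strain incremental response of an
  ## incompressible solid with shear modulus mu
  nh <- vessel_model(vessel_geometry(99, 100, 101, 1),
                     layer_material(10), layer_material(10), active_tone(0))
  st <- solve_inner_radius(nh, 0, T_act = 0, v = 1, lambda_z = 1)
  m <- incremental_moduli(st, c(99.5, 100.5))
  expect_equal(m$A_rrrr, c(10, 10), tolerance = 1e-6)
  expect_equal(m$A_tttt, c(10, 10), tolerance = 1e-6)
  expect_equal(m$A_rtrt, c(10, 10), tolerance = 1e-6)
  expect_equal(m$A_trtr, c(10, 10), tolerance = 1e-6)
  expect_equal(m$pbar, c(10, 10), tolerance = 1e-4)
})

test_that("moduli agree with finite differences of the strain energy", {
  st <- solve_inner_radius(mod, 20, T_act = 10, v = 0.8)
  r <- seq(st$a * 1.01, st$c_out * 0.99, length.out = 7)
  m <- incremental_moduli(st, r, active_stiffness = TRUE)
  for (k in seq_len(nrow(m))) {
    mat <- if (m$layer[k] == "inner") mod$inner else mod$outer
    lr <- m$lambda_r[k]; lt <- m$lambda_t[k]
    ## normal moduli are lambda_i^2 W_ii for this separable energy
    W_rr <- fd_deriv(function(x) fd_deriv(function(y)
      oracle_energy(y, lt, st$lambda_z, mat), x, 1e-4), lr, 1e-4)
    expect_equal(m$A_rrrr[k], lr^2 * W_rr, tolerance = 1e-5)
    w_tt_tot <- function(y) {
      w <- oracle_energy(lr, y, st$lambda_z, mat)
      if (mat$contractile) w <- w + oracle_active_potential(y, mod$tone, st$T_act)
      w
    }
    W_tt <- fd_deriv(function(x) fd_deriv(w_tt_tot, x, 1e-4), lt, 1e-4)
    expect_equal(m$A_tttt[k], lt^2 * W_tt, tolerance = 1e-5)
    ## moduli-stress identity: A_trtr - A_rttr = total hoop extra stress
    s <- passive_extra_stress(lr, lt, st$lambda_z, mat)
    sa <- if (mat$contractile) active_stress(lt, mod$tone, st$T_act) else 0
    expect_equal(m$A_trtr[k] - m$A_rttr[k], s$stt + sa, tolerance = 1e-8)
  }
  ## without activation the active contribution vanishes identically
  st0 <- solve_inner_radius(mod, 20, T_act = 0, v = 0.8)
  r0 <- seq(st0$a * 1.01, st0$c_out * 0.99, length.out = 7)
  m0 <- incremental_moduli(st0, r0, active_stiffness = TRUE)
  m0b <- incremental_moduli(st0, r0, active_stiffness = FALSE)
  expect_equal(m0$A_tttt, m0b$A_tttt)
})

test_that("rigid translation is a neutral mode of the free tube", {
  st <- solve_inner_radius(mod, 25, T_act = 0, v = 1)
  expect_lt(abs(mode_determinant(st, 1, outer_support = "free")), 1e-12)
  st2 <- solve_inner_radius(mod, 25, T_act = 60, v = 0.5)
  expect_lt(abs(mode_determinant(st2, 1, outer_support = "free")), 1e-12)
})

test_that("thin-ring collapse load matches shell theory", {
  ## a thin neo-Hookean ring under luminal suction carries compressive hoop
  ## stress; classical hydrostatic shell theory gives the critical load
  ## q = (n^2 - 1) mu h^3 / (3 R^3)
  ring <- vessel_model(vessel_geometry(99, 100, 101, 1),
                       layer_material(10), layer_material(10), active_tone(0))
  for (n in 2:3) {
    q_th <- (n^2 - 1) * 10 * 2^3 / (3 * 100^3)
    f <- function(Pk) mode_determinant(make_state_kPa(ring, Pk), n,
                                       n_steps = 300, outer_support = "free")
    rt <- stats::uniroot(f, c(-2 * q_th, -0.5 * q_th), tol = 1e-10)$root
    expect_equal(-rt, q_th, tolerance = 0.02)
  }
})

test_that("determinant is stable under node doubling", {
  st <- solve_inner_radius(mod, 25, T_act = 40, v = 0.5)
  for (n in c(2, 7)) {
    d1 <- mode_determinant(st, n, n_steps = 150)
    d2 <- mode_determinant(st, n, n_steps = 300)
    expect_equal(d1, d2, tolerance = 1e-3)
  }
})

test_that("stress-free tube shows no spontaneous buckling", {
  st <- solve_inner_radius(mod, 0, T_act = 0, v = 1, lambda_z = 1)
  for (n in 2:5) {
    expect_gt(abs(mode_determinant(st, n)), 1e-10)
  }
})

test_that("critical stress for 7 folds is bracketed by the eigenvalue oracle", {
  res <- critical_active_stress(mod, 7, v = 0.5, P = 25)
  expect_true(res$converged)
  tc <- res$T_act_crit
  a_prev <- NULL
  eigs <- vapply(c(tc - 2, tc + 2), function(Tq) {
    st <- solve_inner_radius(mod, 25, T_act = Tq, v = 0.5, a_init = a_prev)
    a_prev <<- st$a
    oracle_buckling_min_eig(st, 7)
  }, numeric(1))
  expect_gt(eigs[1], 0)   # stable just below the critical stress
  expect_lt(eigs[2], 0)   # unstable just above
  ## compressive mean hoop stress in the inner layer at the critical state
  st_c <- solve_inner_radius(mod, 25, T_act = tc, v = 0.5)
  expect_lt(st_c$mean_stt_inner, 0)
})

test_that("plateau detection picks the constructed corner", {
  tbl <- data.frame(n = 2:8,
                    T_act_crit_kPa = c(200, 150, 120, 105, 97, 95.5, 95))
  ## drops: 25%, 20%, 12.5%, 7.6%, 1.5% -> first below 5% is n = 6
  expect_identical(plateau_mode(tbl, 0.05), 6L)
  expect_identical(plateau_mode(tbl, 0.10), 5L)
  expect_true(is.na(plateau_mode(tbl[1:3, ], 0.01)))
})

test_that("critical stress declines with fold number toward a plateau", {
  fs <- fold_sweep(mod, n = 5:8, v = 0.5, P = 25)
  expect_true(all(fs$converged))
  expect_true(all(diff(fs$T_act_crit_kPa) < 0))
  ## relative drops shrink as the curve flattens
  drops <- -diff(fs$T_act_crit_kPa) / head(fs$T_act_crit_kPa, -1)
  expect_true(all(diff(drops) < 0))
})
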