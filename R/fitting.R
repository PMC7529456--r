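#' Forward-predict a biaxial protocol
#'
#' For each protocol record the measured kinematic state (axial stretch and
#' outer diameter) determines the full deformation of the incompressible
#' bilayer in closed form; the model then predicts the luminal pressure and
#' transducer axial force at that state. Alternatively, if `from =
#' "pressure"`, the loaded inner radius is solved from the recorded
#' pressure and the outer diameter and axial force are predicted.
#'
#' @param model A [vessel_model()].
#' @param protocol A data.frame with columns `lambda_z` and
#'   `outer_diameter_um` (default mode) or `pressure_mmHg`.
#' @param from Which measured channel drives the prediction.
#' @param v Normalized inner-layer volume (passive tests: 1).
#' @param T_act Active stress magnitude (kPa; passive tests: 0).
#' @param n_nodes Quadrature nodes per layer.
#' @return The protocol data.frame with predicted columns
#'   `P_mmHg_pred`, `f_mN_pred` (and `outer_diameter_um_pred` when driven
#'   by pressure); rows whose kinematics are infeasible are flagged in
#'   `feasible`.
#' @export
predict_protocol <- function(model, protocol,
                             from = c("diameter", "pressure"),
                             v = 1, T_act = 0, n_nodes = 100) {
  from <- match.arg(from)
  geom <- model$geometry
  out <- protocol
  if (from == "diameter") {
    stopifnot(all(c("lambda_z", "outer_diameter_um") %in% names(protocol)))
    lamz <- protocol$lambda_z
    c_out <- protocol$outer_diameter_um / 2
    a2 <- c_out^2 - (geom$C^2 - geom$B^2) / lamz - v * (geom$B^2 - geom$A^2) / lamz
    feas <- a2 > 0
    out$feasible <- feas
    out$P_mmHg_pred <- NA_real_
    out$f_mN_pred <- NA_real_
    if (any(feas)) {
      resp <- .wall_response(model, sqrt(a2[feas]), lamz[feas], v, T_act,
                             n_nodes)
      out$P_mmHg_pred[feas] <- kPa_to_mmHg(resp$P_kPa)
      out$f_mN_pred[feas] <- resp$f_mN
    }
  } else {
    stopifnot(all(c("lambda_z", "pressure_mmHg") %in% names(protocol)))
    out$feasible <- TRUE
    out$outer_diameter_um_pred <- NA_real_
    out$f_mN_pred <- NA_real_
    for (i in seq_len(nrow(protocol))) {
      st <- tryCatch(
        solve_inner_radius(model, protocol$pressure_mmHg[i], T_act = T_act,
                           v = v, lambda_z = protocol$lambda_z[i],
                           n_nodes = n_nodes),
        error = function(e) NULL)
      if (is.null(st) || st$occluded) { out$feasible[i] <- FALSE; next }
      out$outer_diameter_um_pred[i] <- 2 * st$c_out
      out$f_mN_pred[i] <- st$f_axial_mN
    }
  }
  out
}

## Vectorized inversion of the passive pressure-radius relation: solves
## luminal_pressure(a_j; lambda_z_j) = P_j for all protocol points at once
## (bracketed bisection to localize, Newton polish), so that regression
## residuals can live on the measured-response channels.
.solve_a_vec <- function(model, P_kPa, lamz, v = 1, T_act = 0, n_nodes = 60,
                         bracket = c(0.5, 3.5), a_init = NULL,
                         newton_iter = 10, tol = 1e-11) {
  geom <- model$geometry
  m <- length(P_kPa)
  f <- function(a) .wall_response(model, a, lamz, v, T_act, n_nodes)$P_kPa - P_kPa
  bisect <- function() {
    lo <- rep(bracket[1] * geom$A, m); hi <- rep(bracket[2] * geom$A, m)
    flo <- f(lo)
    ## passive pressure increases with radius: bisect on the bracket
    for (i in 1:22) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      up <- (fm < 0) == (flo < 0)
      lo <- ifelse(up, mid, lo); flo <- ifelse(up, fm, flo)
      hi <- ifelse(up, hi, mid)
    }
    (lo + hi) / 2
  }
  newton <- function(a, iters) {
    h <- 1e-4 * geom$A
    for (i in seq_len(iters)) {
      fa <- f(a)
      if (all(abs(fa) < tol)) break
      sl <- (f(a + h) - fa) / h
      step <- ifelse(is.finite(sl) & sl > 0, fa / sl, 0)
      step <- pmin(pmax(step, -0.15 * geom$A), 0.15 * geom$A)
      a <- pmin(pmax(a - step, bracket[1] * geom$A), bracket[2] * geom$A)
    }
    a
  }
  a <- if (is.null(a_init)) newton(bisect(), 6) else newton(a_init, newton_iter)
  ## re-localize any point the warm-started polish failed to converge; the
  ## solve must be tight so that optimizer finite-difference Jacobians of
  ## downstream residuals are not polluted by solver state
  bad <- abs(f(a)) > 1e-9 * pmax(abs(P_kPa), 0.1)
  if (any(bad)) {
    a_fresh <- newton(bisect(), 6)
    a[bad] <- a_fresh[bad]
  }
  a
}

## Pack/unpack the fitted parameter vector. Moduli and exponents are
## searched in log space; the diagonal-family angle in degrees.
.fit_par_names <- c("mu2", "c11", "c21", "c12", "c22", "c134", "c234", "eta")

.theta_to_model <- function(theta, geometry, mu1) {
  p <- exp(theta[1:7])
  eta <- theta[8]
  outer <- layer_material(p[1], fibers = list(
    fiber_family(p[2], p[3], 0),
    fiber_family(p[4], p[5], 90),
    fiber_family(p[6], p[7], eta),
    fiber_family(p[6], p[7], -eta)), contractile = TRUE)
  vessel_model(geometry, layer_material(mu1), outer, active_tone(0))
}

#' Nonlinear regression of passive biaxial data
#'
#' Recovers the outer-layer constitutive parameters (matrix shear modulus,
#' four fiber-family parameters with the two diagonal families sharing
#' `c1`, `c2` and symmetric angles `+/- eta`) from pressure-diameter and
#' axial force data by bounded, multi-start nonlinear least squares
#' (Levenberg-Marquardt). Residuals are weighted by per-protocol response
#' standard deviations; see `residual` for the two supported channel
#' conventions. The inner (GAG) modulus `mu1` is held fixed: the swollen
#' inner layer is not identifiable from passive pressure-diameter data
#' alone.
#'
#' @param data A data.frame of protocol records: columns `protocol`,
#'   `lambda_z`, `pressure_mmHg`, `outer_diameter_um`, `f_axial_mN`
#'   (a `vessel` column is allowed and pooled).
#' @param geometry The unloaded [vessel_geometry()] of the tested vessel.
#' @param mu1 Fixed inner-layer shear modulus (kPa).
#' @param init Optional named initial parameter vector on the natural scale
#'   (`mu2, c11, c21, c12, c22, c134, c234, eta`). Used as the first start.
#' @param lower,upper Bounds on the natural scale: moduli in kPa,
#'   exponents dimensionless, `eta` in degrees.
#' @param n_starts Number of multi-start runs (first start = `init`).
#' @param seed Seed for the start sampler.
#' @param weights Optional list with per-channel standard deviations
#'   (`sigma_d`/`sigma_P` and `sigma_f`).
#' @param residual Residual channels. `"response"` (default) solves the
#'   loaded state from the controlled pressure and residualizes the
#'   measured outer diameter and axial force, matching a noise model in
#'   which the rig controls pressure and measures diameter and force
#'   (statistically consistent under response-only noise).
#'   `"pressure"` predicts pressure and force at the measured diameter,
#'   the computationally lighter classical weighted least squares.
#' @param n_nodes Quadrature nodes per layer in the forward model.
#' @return An object of class `fit_result`: best-fit [vessel_model()],
#'   parameter table with bound-hit flags, objective value, residuals,
#'   and per-start diagnostics.
#' @export
fit_passive <- function(data, geometry, mu1 = 3.0, init = NULL,
                        lower = c(mu2 = 1e-4, c11 = 1e-4, c21 = 1e-3,
                                  c12 = 1e-4, c22 = 1e-3, c134 = 1e-4,
                                  c234 = 1e-3, eta = 1),
                        upper = c(mu2 = 1e3, c11 = 1e3, c21 = 50,
                                  c12 = 1e3, c22 = 50, c134 = 1e3,
                                  c234 = 50, eta = 89),
                        n_starts = 10, seed = 17, weights = NULL,
                        residual = c("response", "pressure"),
                        n_nodes = 60) {
  residual <- match.arg(residual)
  need <- c("protocol", "lambda_z", "pressure_mmHg", "outer_diameter_um",
            "f_axial_mN")
  stopifnot(all(need %in% names(data)))
  if (length(unique(data$lambda_z)) < 2) {
    stop("at least two distinct axial stretches are needed for identifiability",
         call. = FALSE)
  }
  guard_sd <- function(x, fallback) {
    x[!is.finite(x) | x <= 0] <- fallback
    x
  }
  sF <- if (is.null(weights)) {
    guard_sd(stats::ave(data$f_axial_mN, data$protocol, FUN = stats::sd),
             max(stats::sd(data$f_axial_mN), 1e-5))
  } else rep_len(weights$sigma_f, nrow(data))

  lo <- c(log(lower[1:7]), lower[8])
  hi <- c(log(upper[1:7]), upper[8])

  if (residual == "pressure") {
    sP <- if (is.null(weights)) {
      guard_sd(stats::ave(data$pressure_mmHg, data$protocol, FUN = stats::sd),
               max(stats::sd(data$pressure_mmHg), 1))
    } else rep_len(weights$sigma_P, nrow(data))
    resid_fun <- function(theta) {
      m <- .theta_to_model(theta, geometry, mu1)
      pred <- predict_protocol(m, data, from = "diameter", n_nodes = n_nodes)
      r <- c((pred$P_mmHg_pred - data$pressure_mmHg) / sP,
             (pred$f_mN_pred - data$f_axial_mN) / sF)
      r[!is.finite(r)] <- 1e3
      r
    }
  } else {
    sD <- if (is.null(weights)) {
      guard_sd(stats::ave(data$outer_diameter_um, data$protocol, FUN = stats::sd),
               max(stats::sd(data$outer_diameter_um), 1))
    } else rep_len(weights$sigma_d, nrow(data))
    P_kPa <- mmHg_to_kPa(data$pressure_mmHg)
    a_cache <- new.env(parent = emptyenv())
    resid_fun <- function(theta) {
      m <- .theta_to_model(theta, geometry, mu1)
      ## warm-start the radius solve from the previous objective call
      a <- .solve_a_vec(m, P_kPa, data$lambda_z, n_nodes = n_nodes,
                        a_init = a_cache$a)
      a_cache$a <- a
      resp <- .wall_response(m, a, data$lambda_z, 1, 0, n_nodes)
      r <- c((2 * resp$c_out - data$outer_diameter_um) / sD,
             (resp$f_mN - data$f_axial_mN) / sF)
      r[!is.finite(r)] <- 1e3
      r
    }
  }

  default_init <- c(mu2 = 0.5, c11 = 0.1, c21 = 5, c12 = 1, c22 = 1,
                    c134 = 1, c234 = 2, eta = 45)
  if (!is.null(init)) default_init[names(init)] <- init
  th0 <- c(log(default_init[1:7]), default_init[8])

  set.seed(seed)
  starts <- matrix(NA_real_, n_starts, 8)
  starts[1, ] <- th0
  if (n_starts > 1) {
    u <- pracma::rand(n_starts - 1, 8)
    ## sample within a broad but plausible interior region of the bounds
    slo <- c(log(c(1e-3, 1e-3, 0.1, 1e-3, 0.1, 1e-3, 0.1)), 20)
    shi <- c(log(c(10, 10, 20, 10, 10, 10, 10)), 70)
    starts[-1, ] <- sweep(sweep(u, 2, shi - slo, "*"), 2, slo, "+")
  }

  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    if (residual == "response") rm(list = ls(a_cache), envir = a_cache)
    runs[[s]] <- tryCatch({
      fit <- minpack.lm::nls.lm(par = starts[s, ], lower = lo, upper = hi,
                                fn = resid_fun,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 120, ptol = 1e-10, ftol = 1e-10))
      list(par = fit$par, obj = sum(fit$fvec^2), info = fit$info,
           message = fit$message)
    }, error = function(e) list(par = rep(NA_real_, 8), obj = Inf,
                                info = -1, message = conditionMessage(e)))
  }
  objs <- vapply(runs, `[[`, numeric(1), "obj")
  if (all(!is.finite(objs))) stop("all optimization starts failed", call. = FALSE)
  best <- runs[[which.min(objs)]]
  th <- best$par
  est <- c(exp(th[1:7]), th[8])
  names(est) <- .fit_par_names
  at_bound <- (th <= lo + 1e-8) | (th >= hi - 1e-8)
  model <- .theta_to_model(th, geometry, mu1)
  res <- resid_fun(th)
  structure(list(model = model, estimates = est, mu1 = mu1,
                 at_bound = stats::setNames(at_bound, .fit_par_names),
                 objective = best$obj, residuals = res,
                 start_objectives = objs, info = best$info,
                 message = best$message, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Passive biaxial fit (weighted least squares)\n")
  cat(sprintf("  objective %.4g over %d residuals; %d starts (best %.4g, worst %.4g)\n",
              x$objective, length(x$residuals), length(x$start_objectives),
              min(x$start_objectives), max(x$start_objectives)))
  est <- signif(x$estimates, 4)
  for (nm in names(est)) {
    cat(sprintf("  %-5s = %-10g%s\n", nm, est[[nm]],
                if (x$at_bound[[nm]]) " (at bound)" else ""))
  }
  invisible(x)
}

#' Calibrate active-tone magnitude from a contraction observation
#'
#' Solves for the active stress magnitude `T_act` at which the model's
#' outer diameter at fixed pressure is reduced by the observed fraction
#' relative to the passive state (e.g. the 30-50 percent reduction of the
#' murine umbilical artery under KCl at 25 mmHg).
#'
#' @param model A [vessel_model()] with passive parameters set.
#' @param reduction Target fractional outer-diameter reduction in (0, 1);
#'   0 returns `T_act = 0`.
#' @param P Fixed luminal pressure (mmHg).
#' @param v Normalized inner-layer volume during contraction.
#' @param T_range Search range (kPa).
#' @param tol Tolerance on `T_act` (kPa).
#' @param n_nodes Quadrature nodes per layer.
#' @return An [active_tone()] with the calibrated `T_act`, plus attributes
#'   `achieved_reduction` and `passive_diameter_um`; if the target is not
#'   attainable in `T_range` an error condition is raised.
#' @export
fit_active_tone <- function(model, reduction, P = 25, v = 1,
                            T_range = c(0, 500), tol = 0.1, n_nodes = 150) {
  if (reduction < 0 || reduction >= 1) {
    stop("reduction must lie in [0, 1)", call. = FALSE)
  }
  d0 <- 2 * solve_inner_radius(model, P, T_act = 0, v = v,
                               n_nodes = n_nodes)$c_out
  if (reduction == 0) {
    tone <- active_tone(0, model$tone$lambda_m, model$tone$lambda_0)
    attr(tone, "achieved_reduction") <- 0
    attr(tone, "passive_diameter_um") <- d0
    return(tone)
  }
  a_prev <- NULL
  red_at <- function(Tq) {
    st <- solve_inner_radius(model, P, T_act = Tq, v = v, a_init = a_prev,
                             n_nodes = n_nodes)
    if (st$occluded) return(1)
    a_prev <<- st$a
    1 - 2 * st$c_out / d0
  }
  ## march to bracket (the reduction is monotone along the quasi-static path)
  Tg <- seq(T_range[1], T_range[2], length.out = 101)
  lo <- T_range[1]; hi <- NA
  r_prev <- 0
  for (Tq in Tg[-1]) {
    r <- red_at(Tq)
    if (r >= reduction) { hi <- Tq; break }
    lo <- Tq; r_prev <- r
  }
  if (is.na(hi)) {
    stop(sprintf("target reduction %.1f%% not attainable for T_act in [%g, %g] kPa",
                 100 * reduction, T_range[1], T_range[2]), call. = FALSE)
  }
  while (hi - lo > tol) {
    Tm <- (lo + hi) / 2
    if (red_at(Tm) >= reduction) hi <- Tm else lo <- Tm
  }
  T_fit <- (lo + hi) / 2
  tone <- active_tone(T_fit, model$tone$lambda_m, model$tone$lambda_0)
  attr(tone, "achieved_reduction") <- red_at(T_fit)
  attr(tone, "passive_diameter_um") <- d0
  tone
}
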