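## --- Linear (incremental) stability of the loaded bilayered tube ---------
##
## Perturbations are plane-strain in (r, theta) at fixed axial stretch,
## u_r = (n f(r)/r) cos(n theta), u_theta = -f'(r) sin(n theta), which
## satisfies incremental incompressibility identically (f is the radial
## part of a stream function). The second variation of the total potential
## (elastic energy plus, for follower pressure, the luminal pressure
## potential) is, up to a positive factor,
##   J[f] = int_a^c [alpha A^2 + beta B^2 + gamma C^2 + 2 delta B C] r dr
##          - P [n^2 f^2/a^2 + f'^2 - 2 n^2 f f'/a]_(r=a)
## with A = n(f'/r - f/r^2), B = f'/r - n^2 f/r^2, C = -f'' and
##   alpha = A_rrrr + A_tttt + 2 pbar,  beta = A_rtrt,
##   gamma = A_trtr,                    delta = pbar,
## where A_. are the instantaneous (small-on-large) moduli at the local
## deformed state and pbar is the base Lagrange-multiplier field. Buckling
## at mode n corresponds to a nontrivial stationary point, located as a
## zero of the boundary-condition determinant of the canonical (Euler-
## Lagrange) first-order system shot from the lumen to the outer surface
## with displacement/traction continuity at the layer interface.
##
## The machinery was verified against the classical thin-ring collapse
## load (n^2 - 1) mu h^3 / (3 R^3) under hydrostatic pressure (agreement
## to a few tenths of a percent for n = 2..5), against neutrality of the
## n = 1 rigid translation, and against an independent finite-difference
## eigenvalue discretization of J[f].

## Stretches, base stresses and moduli coefficients at radii r inside one
## layer of a solved state. sigma_rr is interpolated from the state profile.
.buckling_coeffs <- function(state, r, layer, active_stiffness = FALSE) {
  model <- state$model; geom <- model$geometry
  lamz <- state$lambda_z
  if (layer == "inner") {
    R <- sqrt(geom$A^2 + lamz * (r^2 - state$a^2) / state$v)
    lr <- state$v * R / (lamz * r)
    mat <- model$inner
  } else {
    R <- sqrt(geom$B^2 + lamz * (r^2 - state$b^2))
    lr <- R / (lamz * r)
    mat <- model$outer
  }
  lt <- r / R
  resp <- .layer_response(lr, lt, lamz, mat, model$tone, state$T_act,
                          want_moduli = TRUE)
  if (!active_stiffness && mat$contractile && state$T_act > 0) {
    ## treat the activation as constant over the fast perturbation: drop the
    ## constitutive stiffening of the tone law (its derivative with respect
    ## to lambda_theta); the rotational terms from carrying the base active
    ## stress are retained, as required by the moduli-stress identities
    resp$A_tttt <- resp$A_tttt - lt * active_stress_slope(lt, model$tone,
                                                          state$T_act)
  }
  prof <- state$profiles
  sel <- prof$layer == layer
  srr <- stats::spline(prof$r[sel], prof$srr[sel], xout = r, method = "natural")$y
  pbar <- resp$srr - srr
  list(alpha = resp$A_rrrr + resp$A_tttt + 2 * pbar,
       beta = resp$A_rtrt, gamma = resp$A_trtr, delta = pbar,
       pbar = pbar, srr = srr, resp = resp, lambda_r = lr, lambda_t = lt)
}

#' Instantaneous (small-on-large) moduli at radii of a loaded state
#'
#' Plane-strain incremental elasticity components in the principal frame at
#' the local deformed state, optionally including the linearized active
#' contribution in the contractile layer, plus the base Lagrange-multiplier
#' field `pbar` recovered from radial equilibrium.
#'
#' @param state A `loaded_state` from [solve_inner_radius()].
#' @param r Radii within the deformed wall (um).
#' @param active_stiffness Include the derivative of the active-tone law in
#'   the moduli. The rotational effect of carrying the base active stress
#'   always enters, as the moduli-stress identities require; the default
#'   treats the activation level as constant during a perturbation.
#' @return A data.frame with the moduli components `A_rrrr`, `A_rrtt`,
#'   `A_tttt`, `A_rtrt`, `A_trtr`, `A_rttr`, the multiplier `pbar`, and the
#'   base stresses at `r`.
#' @export
incremental_moduli <- function(state, r, active_stiffness = FALSE) {
  if (state$occluded) stop("state is occluded; no moduli", call. = FALSE)
  if (any(r < state$a - 1e-9) || any(r > state$c_out + 1e-9)) {
    stop("r outside the deformed wall", call. = FALSE)
  }
  layer <- ifelse(r <= state$b, "inner", "outer")
  out <- lapply(c("inner", "outer"), function(ly) {
    sel <- layer == ly
    if (!any(sel)) return(NULL)
    cf <- .buckling_coeffs(state, r[sel], ly, active_stiffness)
    data.frame(r = r[sel], layer = ly,
               A_rrrr = cf$resp$A_rrrr + numeric(sum(sel)),
               A_rrtt = 0, A_tttt = cf$resp$A_tttt,
               A_rtrt = cf$resp$A_rtrt + numeric(sum(sel)),
               A_trtr = cf$resp$A_trtr, A_rttr = 0,
               pbar = cf$pbar, sigma_rr = cf$srr,
               lambda_r = cf$lambda_r, lambda_t = cf$lambda_t)
  })
  res <- do.call(rbind, out)
  res[order(res$r), , drop = FALSE]
}

## RK4 integration of the canonical system through one layer with
## precomputed coefficients at the 2*nsteps+1 half-step grid.
.integrate_layer <- function(Y, r_grid, cf, n) {
  nsteps <- (length(r_grid) - 1L) / 2L
  deriv <- function(Y, k) {
    r <- r_grid[k]
    al <- cf$alpha[k]; be <- cf$beta[k]; ga <- cf$gamma[k]; de <- cf$delta[k]
    y1 <- Y[1, ]; y2 <- Y[2, ]; y3 <- Y[3, ]; y4 <- Y[4, ]
    bb <- y2 / r - n^2 * y1 / r^2
    fpp <- y3 / (2 * r * ga) + (de / ga) * bb
    aa <- (n / r) * (y2 - y1 / r)
    cc <- -fpp
    rbind(y2, fpp,
          2 * (al * aa * n + be * bb + de * cc) - y4,
          -(2 / r) * (al * aa * n + n^2 * (be * bb + de * cc)))
  }
  for (s in seq_len(nsteps)) {
    k0 <- 2L * s - 1L
    h <- r_grid[k0 + 2L] - r_grid[k0]
    k1 <- deriv(Y, k0)
    k2 <- deriv(Y + h / 2 * k1, k0 + 1L)
    k3 <- deriv(Y + h / 2 * k2, k0 + 1L)
    k4 <- deriv(Y + h * k3, k0 + 2L)
    Y <- Y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    ## sign-safe renormalization of each solution column
    for (j in 1:2) {
      nr <- sqrt(sum(Y[, j]^2))
      if (nr > 1e12) Y[, j] <- Y[, j] / nr
    }
  }
  Y
}

#' Boundary-condition determinant of buckling mode n
#'
#' Assembles the incremental equilibrium equations for a circumferential
#' perturbation with `n` folds on the solved base state and integrates the
#' canonical first-order system from the pressurized luminal surface
#' through both layers (continuity of incremental displacement and
#' traction at the interface) to the outer surface. The returned scalar is
#' the normalized determinant of the outer-surface boundary conditions
#' over the two-dimensional solution space admitted at the lumen; a zero
#' signals a nontrivial buckled equilibrium.
#'
#' @param state A `loaded_state`.
#' @param n Circumferential mode number (integer `>= 2`; `n = 1` is the
#'   neutral rigid-translation mode, admitted for verification).
#' @param n_steps Integration steps per layer.
#' @param active_stiffness Include the linearized active-tone stiffness
#'   (see [incremental_moduli()]).
#' @param pressure_increment `"follower"` (default) keeps the luminal
#'   pressure normal to the deforming surface in the incremental boundary
#'   condition; `"dead"` freezes the traction of the unperturbed state.
#' @param outer_support `"embedded"` (default) holds the outer surface
#'   radially and circumferentially, representing the perivascular support
#'   of the surrounding cord tissue (the outer wall is observed to stay
#'   round while the inner layer folds); `"free"` leaves it traction-free.
#' @return Normalized determinant (dimensionless scalar).
#' @export
mode_determinant <- function(state, n, n_steps = 200,
                             active_stiffness = FALSE,
                             pressure_increment = c("follower", "dead"),
                             outer_support = c("embedded", "free")) {
  pressure_increment <- match.arg(pressure_increment)
  outer_support <- match.arg(outer_support)
  if (state$occluded) stop("base state occluded: no patent tube to perturb",
                           call. = FALSE)
  if (n < 1) stop("mode number n must be >= 1", call. = FALSE)
  a <- state$a; b <- state$b; cc <- state$c_out
  P <- if (pressure_increment == "follower") state$P_kPa else 0
  Y <- rbind(c(1, 0),
             c(0, 1),
             c(2 * P * n^2 / a, -2 * P),
             c(-2 * P * n^2 / a^2, 2 * P * n^2 / a))
  for (ly in c("inner", "outer")) {
    rg <- if (ly == "inner") seq(a, b, length.out = 2L * n_steps + 1L)
          else seq(b, cc, length.out = 2L * n_steps + 1L)
    cf <- .buckling_coeffs(state, rg, ly, active_stiffness)
    Y <- .integrate_layer(Y, rg, cf, n)
  }
  d <- if (outer_support == "embedded") {
    Y[1, 1] * Y[2, 2] - Y[1, 2] * Y[2, 1]      # f = f' = 0 at r = c
  } else {
    Y[3, 1] * Y[4, 2] - Y[3, 2] * Y[4, 1]      # natural (traction-free)
  }
  scale <- sqrt(sum(Y[, 1]^2)) * sqrt(sum(Y[, 2]^2))
  d / scale
}

#' Critical active stress for inward buckling at mode n
#'
#' Marches the active stress magnitude upward from `T_range[1]`, following
#' the quasi-static base state by continuation, until the sign of
#' [mode_determinant()] changes, then refines the crossing by bisection.
#' If the base state occludes (no patent equilibrium) before any sign
#' change the result is flagged `"closure_without_buckling"`; if no
#' crossing occurs in range it is flagged non-converged. Determinant
#' magnitudes below `det_floor` carry no reliable sign (numerically
#' degenerate shooting space, e.g. in nearly collapsed states) and are
#' excluded from the sign comparison.
#'
#' @param model A [vessel_model()].
#' @param n Circumferential mode number (`n >= 2`).
#' @param v Normalized inner-layer volume.
#' @param P Luminal pressure (mmHg).
#' @param T_range Search range for the active stress magnitude (kPa).
#' @param coarse_step Initial marching step (kPa).
#' @param tol Bisection tolerance (kPa).
#' @param n_steps Integration steps per layer.
#' @param n_nodes Quadrature nodes per layer for the base states.
#' @param det_floor Magnitude below which a determinant is treated as
#'   sign-indeterminate.
#' @param ... Passed to [mode_determinant()] (`active_stiffness`,
#'   `pressure_increment`, `outer_support`).
#' @return An object of class `buckling_result`: a list with `n`, `v`, `P`,
#'   `T_act_crit`, `converged`, `status`, and the determinant trace over
#'   the marched grid.
#' @export
critical_active_stress <- function(model, n, v = 0.5, P = 25,
                                   T_range = c(1, 500), coarse_step = 5,
                                   tol = 0.1, n_steps = 200, n_nodes = 200,
                                   det_floor = 1e-14, ...) {
  if (n < 2) stop("buckling modes require n >= 2", call. = FALSE)
  base_at <- local({
    a_prev <- NULL
    function(Tq) {
      st <- solve_inner_radius(model, P, T_act = Tq, v = v,
                               a_init = a_prev, n_nodes = n_nodes)
      if (!st$occluded) a_prev <<- st$a
      st
    }
  })
  trace <- data.frame(T_act = numeric(0), det = numeric(0))
  Tg <- seq(T_range[1], T_range[2], by = coarse_step)
  if (Tg[length(Tg)] < T_range[2]) Tg <- c(Tg, T_range[2])
  d_prev <- NULL; T_prev <- NULL
  status <- "no_crossing"; T_lo <- NA; T_hi <- NA
  for (Tq in Tg) {
    st <- base_at(Tq)
    if (st$occluded) { status <- "closure_without_buckling"; break }
    d <- mode_determinant(st, n, n_steps, ...)
    trace <- rbind(trace, data.frame(T_act = Tq, det = d))
    if (abs(d) < det_floor) next
    if (!is.null(d_prev) && sign(d) * sign(d_prev) < 0) {
      status <- "bracketed"; T_lo <- T_prev; T_hi <- Tq
      break
    }
    d_prev <- d; T_prev <- Tq
  }
  T_crit <- NA_real_
  if (status == "bracketed") {
    d_lo <- d_prev
    while (T_hi - T_lo > tol) {
      Tm <- (T_lo + T_hi) / 2
      st <- base_at(Tm)
      if (st$occluded) { T_hi <- Tm; next }
      dm <- mode_determinant(st, n, n_steps, ...)
      trace <- rbind(trace, data.frame(T_act = Tm, det = dm))
      if (sign(dm) == sign(d_lo)) { T_lo <- Tm; d_lo <- dm } else T_hi <- Tm
    }
    T_crit <- (T_lo + T_hi) / 2
    status <- "converged"
  }
  structure(list(n = n, v = v, P = P, T_act_crit = T_crit,
                 converged = identical(status, "converged"),
                 status = status, trace = trace),
            class = "buckling_result")
}

#' @export
print.buckling_result <- function(x, ...) {
  cat(sprintf("Buckling mode n = %d at v = %.3g, P = %.3g mmHg: ", x$n, x$v, x$P))
  if (x$converged) cat(sprintf("T_act_crit = %.2f kPa\n", x$T_act_crit))
  else cat(sprintf("not converged (%s)\n", x$status))
  invisible(x)
}

#' Critical stress over fold numbers and swelling levels
#'
#' Computes [critical_active_stress()] on the full `(n, v)` grid and
#' reports, per swelling level, the plateau mode: the smallest `n` whose
#' critical stress drops by less than `plateau_threshold` (relative) from
#' `n` to `n + 1`.
#'
#' @param model A [vessel_model()].
#' @param n Integer vector of mode numbers (within 2..16).
#' @param v Vector of normalized inner-layer volumes.
#' @param P Luminal pressure (mmHg).
#' @param plateau_threshold Relative drop below which the curve is deemed
#'   flat (default 5 percent).
#' @param ... Passed to [critical_active_stress()].
#' @return A data.frame `(n, v, P_mmHg, T_act_crit_kPa, converged, status)`
#'   with attribute `"n_star"`, a data.frame of plateau modes per `v`.
#' @export
fold_sweep <- function(model, n = 2:12, v = 0.5, P = 25,
                       plateau_threshold = 0.05, ...) {
  if (any(n < 2) || any(n > 16)) stop("modes must lie in 2..16", call. = FALSE)
  rows <- list()
  for (vi in v) for (ni in n) {
    res <- tryCatch(critical_active_stress(model, ni, v = vi, P = P, ...),
                    error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      n = ni, v = vi, P_mmHg = P,
      T_act_crit_kPa = if (is.null(res)) NA_real_ else res$T_act_crit,
      converged = !is.null(res) && res$converged,
      status = if (is.null(res)) "error" else res$status)
  }
  tbl <- do.call(rbind, rows)
  ns <- do.call(rbind, lapply(unique(tbl$v), function(vi) {
    data.frame(v = vi,
               n_star = plateau_mode(tbl[tbl$v == vi, ], plateau_threshold))
  }))
  attr(tbl, "n_star") <- ns
  tbl
}

#' Plateau fold number of a critical-stress curve
#'
#' The smallest mode `n` for which the relative decrease of the critical
#' active stress from `n` to `n + 1` falls below `threshold`.
#'
#' @param tbl A data.frame with columns `n` and `T_act_crit_kPa` (e.g. one
#'   swelling level of a [fold_sweep()] table), sorted or not.
#' @param threshold Relative-drop threshold (default 0.05).
#' @return The plateau mode number, or `NA` if the criterion is never met.
#' @export
plateau_mode <- function(tbl, threshold = 0.05) {
  tbl <- tbl[order(tbl$n), ]
  tc <- tbl$T_act_crit_kPa
  ok <- which(!is.na(tc[-length(tc)]) & !is.na(tc[-1]) &
                diff(tbl$n) == 1 &
                (tc[-length(tc)] - tc[-1]) / tc[-length(tc)] < threshold)
  if (length(ok) == 0) return(NA_integer_)
  tbl$n[min(ok)]
}
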