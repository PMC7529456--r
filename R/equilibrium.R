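## Gauss-Legendre nodes on [-1, 1], cached per node count.
.gl_cache <- new.env(parent = emptyenv())
.gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  .gl_cache[[key]]
}

## Loaded interface and outer radii for a given loaded inner radius.
## Per-layer volumetric constraints: the inner (swollen) layer satisfies
## det F = v pointwise, the outer layer det F = 1, both at axial stretch
## lambda_z, so b and c follow from a in closed form.
.loaded_radii <- function(a, geom, v, lambda_z = geom$lambda_z) {
  b2 <- a^2 + v * (geom$B^2 - geom$A^2) / lambda_z
  c2 <- b2 + (geom$C^2 - geom$B^2) / lambda_z
  list(b = sqrt(b2), c_out = sqrt(c2))
}

#' Swelling-constrained map from reference to loaded radius
#'
#' Given the loaded inner radius `a`, the reference-to-loaded radius map of
#' the bilayered tube follows from incompressibility at swelling ratio `v`
#' in the inner layer (`det F = v`) and `det F = 1` in the outer layer, at
#' fixed axial stretch: `r^2 = a^2 + v (R^2 - A^2)/lambda_z` for
#' `A <= R <= B` and `r^2 = b^2 + (R^2 - B^2)/lambda_z` beyond.
#'
#' @param a Loaded inner radius (um), `a >= 0`.
#' @param geometry A [vessel_geometry()].
#' @param v Normalized inner-layer volume (current/reference), `v > 0`.
#' @param lambda_z Axial stretch; defaults to the geometry's loaded value.
#' @return A function mapping reference radii `R` to loaded radii `r`, with
#'   attributes `b` and `c_out` (loaded interface and outer radii).
#' @export
radius_map <- function(a, geometry, v = 1, lambda_z = geometry$lambda_z) {
  if (a < 0) stop("inner radius a must be non-negative", call. = FALSE)
  if (v <= 0) stop("swelling ratio v must be positive", call. = FALSE)
  rad <- .loaded_radii(a, geometry, v, lambda_z)
  b <- rad$b
  f <- function(R) {
    if (any(R < geometry$A - 1e-9) || any(R > geometry$C + 1e-9)) {
      stop("R outside the reference wall", call. = FALSE)
    }
    inner <- R <= geometry$B
    r2 <- ifelse(inner,
                 a^2 + v * (R^2 - geometry$A^2) / lambda_z,
                 b^2 + (R^2 - geometry$B^2) / lambda_z)
    if (any(r2 < 0)) stop("infeasible geometry: negative squared radius", call. = FALSE)
    sqrt(r2)
  }
  attr(f, "b") <- b
  attr(f, "c_out") <- rad$c_out
  f
}

## Vectorized wall response: for equal-length vectors of inner radius `a`
## and axial stretch `lamz`, integrate the radial equilibrium and axial
## force integrals by composite Gauss-Legendre quadrature per layer.
## Returns luminal pressure (kPa), transducer axial force (mN), and outer
## radius (um).
.wall_response <- function(model, a, lamz, v = 1, T_act = 0, n_nodes = 200) {
  geom <- model$geometry
  m <- max(length(a), length(lamz))
  a <- rep_len(a, m); lamz <- rep_len(lamz, m)
  gl <- .gl_nodes(n_nodes)
  P <- numeric(m); fz <- numeric(m)

  layer_part <- function(r_lo, r_hi, R2_of_r2, lam_r_coef, material, tone, T_act) {
    ## r nodes: n_nodes x m
    half <- (r_hi - r_lo) / 2
    mid <- (r_hi + r_lo) / 2
    r <- outer(gl$x, half) + matrix(mid, n_nodes, m, byrow = TRUE)
    lamz_m <- matrix(lamz, n_nodes, m, byrow = TRUE)
    R2 <- R2_of_r2(r^2, lamz_m)
    R <- sqrt(R2)
    lt <- r / R
    lr <- lam_r_coef * R / (lamz_m * r)
    resp <- .layer_response(lr, lt, lamz_m, material, tone, T_act)
    integ_P <- (resp$stt + resp$sact - resp$srr) / r
    integ_f <- (2 * resp$szz - resp$stt - resp$sact - resp$srr) * r
    wts <- gl$w
    list(P = colSums(integ_P * wts) * half,
         f = colSums(integ_f * wts) * half)
  }

  rad <- .loaded_radii(a, geom, v, lamz)
  b <- rad$b; c_out <- rad$c_out
  inner <- layer_part(a, b,
                      function(r2, lz) geom$A^2 + lz * sweep(r2, 2, a^2) / v,
                      v, model$inner, model$tone, T_act)
  outer_l <- layer_part(b, c_out,
                        function(r2, lz) geom$B^2 + lz * sweep(r2, 2, b^2),
                        1, model$outer, model$tone, T_act)
  P <- inner$P + outer_l$P
  fz <- pi * (inner$f + outer_l$f) * 1e-6   # kPa um^2 -> mN
  list(P_kPa = P, f_mN = fz, c_out = c_out, b = b)
}

#' Luminal pressure supported at a given inner radius
#'
#' Radial equilibrium of the axisymmetric bilayered tube gives the luminal
#' pressure as the transmural integral `P = int_a^c (sigma_tt - sigma_rr)/r
#' dr`, where the circumferential stress includes the smooth-muscle active
#' stress in the contractile layer. Evaluated by composite Gauss-Legendre
#' quadrature per layer.
#'
#' @param model A [vessel_model()].
#' @param a Loaded inner radius (um); may be a vector.
#' @param T_act Active stress magnitude (kPa).
#' @param v Normalized inner-layer volume.
#' @param lambda_z Axial stretch; defaults to the loaded value in the
#'   geometry.
#' @param n_nodes Quadrature nodes per layer.
#' @return Luminal pressure(s) in kPa.
#' @export
luminal_pressure <- function(model, a, T_act = 0, v = 1,
                             lambda_z = model$geometry$lambda_z,
                             n_nodes = 200) {
  if (any(a <= 0)) stop("a must be positive", call. = FALSE)
  .wall_response(model, a, lambda_z, v, T_act, n_nodes)$P_kPa
}

## Radial profiles of stretch and stress on a trapezoid grid, plus summary
## quantities, for a solved configuration.
.state_profiles <- function(model, a, lamz, v, T_act, P_kPa, n_prof = 401) {
  geom <- model$geometry
  rad <- .loaded_radii(a, geom, v, lamz)
  build <- function(r_lo, r_hi, layer) {
    r <- seq(r_lo, r_hi, length.out = n_prof)
    if (layer == "inner") {
      R <- sqrt(geom$A^2 + lamz * (r^2 - a^2) / v)
      lr <- v * R / (lamz * r)
      mat <- model$inner
    } else {
      R <- sqrt(geom$B^2 + lamz * (r^2 - rad$b^2))
      lr <- R / (lamz * r)
      mat <- model$outer
    }
    lt <- r / pmax(R, .Machine$double.eps)
    resp <- .layer_response(lr, lt, lamz, mat, model$tone, T_act)
    data.frame(r = r, layer = layer, lambda_r = lr, lambda_t = lt,
               srr_hat = resp$srr, stt_hat = resp$stt, szz_hat = resp$szz,
               sact = resp$sact + numeric(n_prof))
  }
  prof <- rbind(build(a, rad$b, "inner"), build(rad$b, rad$c_out, "outer"))
  integrand <- (prof$stt_hat + prof$sact - prof$srr_hat) / prof$r
  ## cumulative trapezoid of d(sigma_rr)/dr from the lumen outwards;
  ## the duplicated interface point contributes a zero-width panel.
  dr <- diff(prof$r)
  cum <- c(0, cumsum((integrand[-1] + integrand[-length(integrand)]) / 2 * dr))
  prof$srr <- -P_kPa + cum
  prof$stt <- prof$srr + (prof$stt_hat + prof$sact - prof$srr_hat)
  prof$szz <- prof$srr + (prof$szz_hat - prof$srr_hat)
  prof$pbar <- prof$srr_hat - prof$srr
  prof
}

#' Solve the loaded configuration at prescribed pressure
#'
#' Finds loaded inner radii at which the wall supports the prescribed
#' luminal pressure, by a bracketed scan of [luminal_pressure()] over the
#' inner radius followed by root refinement. With strong active stress the
#' pressure-radius relation can admit several equilibria (the origin of the
#' sharp patent-to-narrow transition); by default the solution follows the
#' mechanically stable branch nearest `a_init` (quasi-static continuation),
#' or the largest stable root when no `a_init` is given. If no equilibrium
#' with `a > 1e-3 A` exists the state is reported as occluded (`a = 0`).
#'
#' @param model A [vessel_model()].
#' @param P Luminal pressure in mmHg.
#' @param T_act Active stress magnitude (kPa).
#' @param v Normalized inner-layer volume.
#' @param lambda_z Axial stretch.
#' @param a_init Optional previous inner radius for branch continuation (um).
#' @param n_nodes Quadrature nodes per layer.
#' @param tol Root tolerance on the inner radius (um).
#' @return An object of class `loaded_state` with the solved radii, radial
#'   stress/stretch profiles, axial force (mN), layer-mean circumferential
#'   stresses and all equilibrium roots found.
#' @export
solve_inner_radius <- function(model, P, T_act = 0, v = 1,
                               lambda_z = model$geometry$lambda_z,
                               a_init = NULL, n_nodes = 200, tol = 1e-6) {
  if (P < 0) stop("P must be non-negative", call. = FALSE)
  geom <- model$geometry
  P_kPa <- mmHg_to_kPa(P)
  lo <- 1e-3 * geom$A; hi <- 3 * geom$A
  grid <- unique(sort(c(exp(seq(log(lo), log(0.3 * geom$A), length.out = 50)),
                        seq(0.3 * geom$A, hi, length.out = 170))))
  g <- .wall_response(model, grid, lambda_z, v, T_act, n_nodes)$P_kPa - P_kPa
  sgn <- sign(g)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- numeric(0)
  for (i in idx) {
    rt <- stats::uniroot(function(x)
      .wall_response(model, x, lambda_z, v, T_act, n_nodes)$P_kPa - P_kPa,
      lower = grid[i], upper = grid[i + 1], tol = tol)$root
    roots <- c(roots, rt)
  }
  roots <- c(roots, grid[g == 0])
  if (length(roots) == 0) {
    occluded <- all(g < 0)
    st <- structure(list(a = 0, b = NA_real_, c_out = NA_real_,
                         P_mmHg = P, P_kPa = P_kPa, lambda_z = lambda_z,
                         T_act = T_act, v = v, model = model,
                         occluded = occluded, roots = roots,
                         profiles = NULL, f_axial_mN = NA_real_,
                         mean_stt_inner = NA_real_, mean_stt_outer = NA_real_),
                    class = "loaded_state")
    if (!occluded) {
      st$infeasible <- TRUE
      warning("no equilibrium found in bracket and wall over-supports pressure",
              call. = FALSE)
    }
    return(st)
  }
  ## stability under pressure control: dP/da > 0
  eps <- 1e-4 * geom$A
  dP <- (.wall_response(model, roots + eps, lambda_z, v, T_act, n_nodes)$P_kPa -
         .wall_response(model, pmax(roots - eps, lo / 2), lambda_z, v, T_act,
                        n_nodes)$P_kPa)
  stable <- dP > 0
  cand <- if (any(stable)) roots[stable] else roots
  a_sol <- if (is.null(a_init)) max(cand) else cand[which.min(abs(cand - a_init))]

  rad <- .loaded_radii(a_sol, geom, v, lambda_z)
  resp <- .wall_response(model, a_sol, lambda_z, v, T_act, n_nodes)
  prof <- .state_profiles(model, a_sol, lambda_z, v, T_act, P_kPa)
  inner_i <- prof$layer == "inner"
  mean_layer <- function(sel) {
    r <- prof$r[sel]; s <- prof$stt[sel]
    ## area-weighted mean over the annular cross-section
    pracma::trapz(r, s * r) / pracma::trapz(r, r)
  }
  structure(list(a = a_sol, b = rad$b, c_out = rad$c_out,
                 P_mmHg = P, P_kPa = P_kPa, lambda_z = lambda_z,
                 T_act = T_act, v = v, model = model,
                 occluded = FALSE, roots = sort(roots), stable = stable,
                 profiles = prof, f_axial_mN = resp$f_mN,
                 mean_stt_inner = mean_layer(inner_i),
                 mean_stt_outer = mean_layer(!inner_i)),
            class = "loaded_state")
}

#' @export
print.loaded_state <- function(x, ...) {
  cat("Loaded bilayered-tube state\n")
  cat(sprintf("  P = %.2f mmHg, T_act = %.2f kPa, v = %.3f, lambda_z = %.3f\n",
              x$P_mmHg, x$T_act, x$v, x$lambda_z))
  if (x$occluded) {
    cat("  occluded: no patent equilibrium (a -> 0)\n")
  } else {
    cat(sprintf("  a = %.3f um, b = %.3f um, c = %.3f um\n", x$a, x$b, x$c_out))
    cat(sprintf("  axial force %.4g mN; mean stt inner %.3g kPa, outer %.3g kPa\n",
                x$f_axial_mN, x$mean_stt_inner, x$mean_stt_outer))
  }
  invisible(x)
}

#' Closure curves: inner radius versus active stress
#'
#' Sweeps the active stress magnitude at fixed pressure for each swelling
#' level, following the quasi-static branch by continuation, and normalizes
#' the inner radius by its passive (`T_act = 0`) value at the same
#' `(P, v)`. The sharpest point of each curve (largest `|d a_norm / d
#' T_act|`) is recorded as the transition location.
#'
#' @param model A [vessel_model()].
#' @param P Luminal pressure (mmHg).
#' @param T_act Increasing grid of active stress magnitudes (kPa).
#' @param v Vector of normalized inner-layer volumes.
#' @param lambda_z Axial stretch.
#' @param n_nodes Quadrature nodes per layer.
#' @return A data.frame with columns `v`, `P_mmHg`, `T_act_kPa`, `a_um`,
#'   `a_normalized`, `mean_sigma_theta_inner_kPa`, `mean_sigma_theta_outer_kPa`,
#'   `f_axial_mN`, `occluded`; attribute `"transitions"` holds the per-`v`
#'   location and magnitude of the steepest slope.
#' @export
closure_sweep <- function(model, P = 25, T_act = seq(0, 150, by = 1),
                          v = c(0.5, 1), lambda_z = model$geometry$lambda_z,
                          n_nodes = 200) {
  if (is.unsorted(T_act) || any(T_act < 0)) {
    stop("T_act must be a sorted non-negative grid", call. = FALSE)
  }
  out <- list(); trans <- list()
  for (vi in v) {
    a_prev <- NULL
    rows <- vector("list", length(T_act))
    for (j in seq_along(T_act)) {
      st <- tryCatch(
        solve_inner_radius(model, P, T_act = T_act[j], v = vi,
                           lambda_z = lambda_z, a_init = a_prev,
                           n_nodes = n_nodes),
        error = function(e) NULL)
      if (is.null(st)) {
        rows[[j]] <- data.frame(v = vi, P_mmHg = P, T_act_kPa = T_act[j],
                                a_um = NA_real_, mean_sigma_theta_inner_kPa = NA_real_,
                                mean_sigma_theta_outer_kPa = NA_real_,
                                f_axial_mN = NA_real_, occluded = NA)
        next
      }
      a_prev <- if (st$occluded) NULL else st$a
      rows[[j]] <- data.frame(v = vi, P_mmHg = P, T_act_kPa = T_act[j],
                              a_um = if (st$occluded) 0 else st$a,
                              mean_sigma_theta_inner_kPa = st$mean_stt_inner,
                              mean_sigma_theta_outer_kPa = st$mean_stt_outer,
                              f_axial_mN = st$f_axial_mN,
                              occluded = st$occluded)
    }
    cur <- do.call(rbind, rows)
    cur$a_normalized <- cur$a_um / cur$a_um[1]
    sl <- diff(cur$a_normalized) / diff(cur$T_act_kPa)
    k <- which.max(abs(sl))
    trans[[as.character(vi)]] <- data.frame(
      v = vi, T_act_transition = mean(cur$T_act_kPa[k + 0:1]),
      max_abs_slope = abs(sl[k]))
    out[[as.character(vi)]] <- cur
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[, c("v", "P_mmHg", "T_act_kPa", "a_um", "a_normalized",
                 "mean_sigma_theta_inner_kPa", "mean_sigma_theta_outer_kPa", "f_axial_mN",
                 "occluded")]
  attr(res, "transitions") <- do.call(rbind, trans)
  res
}

#' Active stress at which two swelling levels exchange effect on radius
#'
#' Below a critical active stress a smaller inner-layer volume gives a
#' larger loaded inner radius (the shrunken layer leaves more room at equal
#' outer constraint); above it, inner-layer volume loss aids narrowing. The
#' crossover is located as the sign change of `a(T; v_low) - a(T; v_high)`
#' on the grid, refined by root-finding on the exact difference.
#'
#' @param model A [vessel_model()].
#' @param P Luminal pressure (mmHg).
#' @param v_low,v_high The two normalized inner-layer volumes,
#'   `v_low < v_high`.
#' @param T_act Sorted scan grid of active stress (kPa).
#' @param lambda_z Axial stretch.
#' @param n_nodes Quadrature nodes per layer.
#' @param tol Tolerance on the crossover active stress (kPa).
#' @return A list with `T_cross` (kPa, or `NA` if the curves do not cross on
#'   the grid), the scanned difference curve, and the two sweeps.
#' @export
swelling_crossover <- function(model, P = 25, v_low = 0.5, v_high = 1.0,
                               T_act = seq(0, 150, by = 2),
                               lambda_z = model$geometry$lambda_z,
                               n_nodes = 200, tol = 0.05) {
  if (!(v_low < v_high)) stop("requires v_low < v_high", call. = FALSE)
  sw <- closure_sweep(model, P = P, T_act = T_act, v = c(v_low, v_high),
                      lambda_z = lambda_z, n_nodes = n_nodes)
  a_lo <- sw$a_um[sw$v == v_low]
  a_hi <- sw$a_um[sw$v == v_high]
  d <- a_lo - a_hi
  sgn <- sign(d)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(idx) == 0) {
    return(list(T_cross = NA_real_, difference = data.frame(T_act = T_act, d = d),
                sweeps = sw, message = "no crossing on the scanned grid"))
  }
  i <- idx[1]
  diff_fun <- function(Tq) {
    alo <- solve_inner_radius(model, P, T_act = Tq, v = v_low,
                              lambda_z = lambda_z,
                              a_init = stats::approx(T_act, a_lo, Tq)$y,
                              n_nodes = n_nodes)$a
    ahi <- solve_inner_radius(model, P, T_act = Tq, v = v_high,
                              lambda_z = lambda_z,
                              a_init = stats::approx(T_act, a_hi, Tq)$y,
                              n_nodes = n_nodes)$a
    alo - ahi
  }
  rt <- stats::uniroot(diff_fun, lower = T_act[i], upper = T_act[i + 1],
                       tol = tol)
  list(T_cross = rt$root, difference = data.frame(T_act = T_act, d = d),
       sweeps = sw)
}
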