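#' Stretch of a fiber family
#'
#' A fiber at angle `eta` from the vessel axis, carried by the principal
#' stretches, deforms with `lambda_k = sqrt(lambda_z^2 cos^2(eta) +
#' lambda_theta^2 sin^2(eta))`; radial stretch does not enter because the
#' families lie in the theta-z tangent plane.
#'
#' @param lambda_theta Circumferential stretch(es), positive.
#' @param lambda_z Axial stretch, positive.
#' @param eta Fiber angle from the axial direction (degrees).
#' @return Fiber stretch(es), same length as `lambda_theta`.
#' @export
fiber_stretch <- function(lambda_theta, lambda_z, eta) {
  if (any(lambda_theta <= 0) || any(lambda_z <= 0)) {
    stop("stretches must be positive", call. = FALSE)
  }
  e <- eta * pi / 180
  sqrt(lambda_z^2 * cos(e)^2 + lambda_theta^2 * sin(e)^2)
}

## Exponential fiber stress coefficient f_k = c1 (lk2 - 1) exp(c2 (lk2-1)^2),
## as a function of lk2 = lambda_k^2, tension-only (zero for lk2 <= 1).
## Returns the coefficient and its derivative wrt lk2 when deriv = TRUE.
.fiber_coef <- function(lk2, c1, c2, deriv = FALSE) {
  e <- lk2 - 1
  act <- e > 0
  ex <- exp(c2 * e^2)
  f <- ifelse(act, c1 * e * ex, 0)
  if (!deriv) return(f)
  fp <- ifelse(act, c1 * ex * (1 + 2 * c2 * e^2), 0)
  list(f = f, fprime = fp)
}

## Per-layer extra Cauchy stresses and (optionally) the incremental moduli
## pieces needed by the plane-strain stability analysis; fully vectorized
## over equal-length stretch vectors. Active tone is included when the layer
## is contractile and T_act > 0. Stress convention: sigma_hat_i =
## lambda_i dW/dlambda_i with the volumetric Lagrange multiplier excluded.
.layer_response <- function(lr, lt, lz, material, tone = NULL, T_act = 0,
                            want_moduli = FALSE) {
  mu <- material$mu
  srr <- mu * lr^2
  stt <- mu * lt^2
  szz <- mu * lz^2
  ## A_tttt excess over mu*lt^2; A_trtr excess over mu*lt^2
  d_tttt <- 0
  d_trtr <- 0
  for (fb in material$fibers) {
    e <- fb$eta * pi / 180
    s2 <- sin(e)^2; c2a <- cos(e)^2
    lk2 <- lz^2 * c2a + lt^2 * s2
    fc <- .fiber_coef(lk2, fb$c1, fb$c2, deriv = want_moduli)
    f <- if (want_moduli) fc$f else fc
    stt <- stt + f * lt^2 * s2
    szz <- szz + f * lz^2 * c2a
    if (want_moduli) {
      d_tttt <- d_tttt + f * lt^2 * s2 + 2 * fc$fprime * lt^4 * s2^2
      d_trtr <- d_trtr + f * lt^2 * s2
    }
  }
  sa <- 0
  da_tttt <- 0
  if (material$contractile && !is.null(tone) && T_act > 0) {
    sa <- active_stress(lt, tone, T_act)
    if (want_moduli) {
      sap <- active_stress_slope(lt, tone, T_act)
      da_tttt <- lt * sap - sa
    }
  }
  out <- list(srr = srr, stt = stt, szz = szz, sact = sa)
  if (want_moduli) {
    ## plane-strain instantaneous moduli in principal axes (current config):
    ## A_rrrr = mu lr^2; A_rrtt = A_rttr = 0;
    ## A_tttt = mu lt^2 + fiber + (lt sa' - sa); A_rtrt = mu lr^2;
    ## A_trtr = mu lt^2 + fiber sigma + sa.
    out$A_rrrr <- mu * lr^2
    out$A_tttt <- mu * lt^2 + d_tttt + da_tttt
    out$A_rtrt <- mu * lr^2
    out$A_trtr <- mu * lt^2 + d_trtr + sa
  }
  out
}

#' Passive extra Cauchy stresses of a layer
#'
#' Principal "extra" Cauchy stresses `sigma_hat_i = lambda_i dW/dlambda_i`
#' of the layer strain energy `W = mu/2 (lambda_r^2 + lambda_theta^2 +
#' lambda_z^2 - 3) + sum_k c1k/(4 c2k) (exp(c2k (lambda_k^2 - 1)^2) - 1)`.
#' The Lagrange multiplier that enforces the volumetric constraint is not
#' included; fibers are tension-only (no stress when `lambda_k <= 1`).
#'
#' @param lambda_r,lambda_theta,lambda_z Principal stretches (radial,
#'   circumferential, axial); vectors of common length allowed.
#' @param material A [layer_material()].
#' @return A data.frame with columns `srr`, `stt`, `szz` (kPa).
#' @export
passive_extra_stress <- function(lambda_r, lambda_theta, lambda_z, material) {
  if (any(lambda_r <= 0) || any(lambda_theta <= 0) || any(lambda_z <= 0)) {
    stop("stretches must be positive", call. = FALSE)
  }
  r <- .layer_response(lambda_r, lambda_theta, lambda_z, material)
  data.frame(srr = r$srr, stt = r$stt, szz = r$szz)
}

#' Smooth-muscle active circumferential stress
#'
#' Parabolic length-tension law `T_act * lambda_theta * (1 - ((lambda_m -
#' lambda_theta)/(lambda_m - lambda_0))^2)`, clamped to zero wherever the
#' bracket is negative, so the response is continuous, vanishes at the
#' minimum contractile stretch `lambda_0` and peaks in force density at
#' `lambda_m`.
#'
#' @param lambda_theta Circumferential stretch(es), positive.
#' @param tone An [active_tone()].
#' @param T_act Active stress magnitude (kPa); defaults to `tone$T_act`.
#' @return Active Cauchy stress(es) in kPa.
#' @export
active_stress <- function(lambda_theta, tone, T_act = tone$T_act) {
  if (any(lambda_theta <= 0)) stop("lambda_theta must be positive", call. = FALSE)
  br <- 1 - ((tone$lambda_m - lambda_theta) / (tone$lambda_m - tone$lambda_0))^2
  T_act * lambda_theta * pmax(br, 0)
}

#' @rdname active_stress
#' @details `active_stress_slope()` returns the derivative of the active
#'   stress with respect to `lambda_theta`, used when linearizing the active
#'   contribution in the buckling analysis.
#' @export
active_stress_slope <- function(lambda_theta, tone, T_act = tone$T_act) {
  dm <- tone$lambda_m - tone$lambda_0
  br <- 1 - ((tone$lambda_m - lambda_theta) / dm)^2
  on <- br > 0
  ifelse(on, T_act * (br + lambda_theta * 2 * (tone$lambda_m - lambda_theta) / dm^2), 0)
}

## Strain energy density of a layer at given stretches (kPa); used by the
## finite-difference consistency tests and the energy-based oracles.
.layer_energy <- function(lr, lt, lz, material) {
  w <- material$mu / 2 * (lr^2 + lt^2 + lz^2 - 3)
  for (fb in material$fibers) {
    e <- fb$eta * pi / 180
    lk2 <- lz^2 * cos(e)^2 + lt^2 * sin(e)^2
    ex <- lk2 - 1
    w <- w + ifelse(ex > 0, fb$c1 / (4 * fb$c2) * (exp(fb$c2 * ex^2) - 1), 0)
  }
  w
}
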