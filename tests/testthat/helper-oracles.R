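## Independent oracles used across the suite. These deliberately take
## different numerical routes than the package internals they check.

## central finite difference of a scalar function
fd_deriv <- function(f, x, h = 1e-6 * max(abs(x), 1)) {
  (f(x + h) - f(x - h)) / (2 * h)
}

## Strain energy of one layer as an R function of the three stretches,
## written independently of the package internals.
oracle_energy <- function(lr, lt, lz, material) {
  w <- material$mu / 2 * (lr^2 + lt^2 + lz^2 - 3)
  for (fb in material$fibers) {
    e <- fb$eta * pi / 180
    lk2 <- lz^2 * cos(e)^2 + lt^2 * sin(e)^2
    if (lk2 > 1) {
      w <- w + fb$c1 / (4 * fb$c2) * (exp(fb$c2 * (lk2 - 1)^2) - 1)
    }
  }
  w
}

## pseudo-potential of the active tone law: integral of sigma_a/lambda
oracle_active_potential <- function(lt, tone, T_act) {
  lm <- tone$lambda_m; l0 <- tone$lambda_0
  up <- 2 * lm - l0                 # upper zero of the parabola
  x <- pmin(pmax(lt, l0), up)
  T_act * ((x - l0) + ((lm - x)^3 - (lm - l0)^3) / (3 * (lm - l0)^2))
}

## Total-potential-energy equilibrium oracle: minimizes
##   Pi(a) = 2 pi [ v int_A^B W R dR + int_B^C W R dR + active part ]
##           - P lambda_z pi a^2
## over the inner radius by golden-section search on a trapezoid grid in
## the reference radius (a route independent of the package's
## stress-integral + root-finding path).
oracle_equilibrium_radius <- function(model, P_mmHg, v = 1,
                                      lambda_z = model$geometry$lambda_z,
                                      T_act = 0, nR = 600,
                                      interval = NULL) {
  geom <- model$geometry
  P_kPa <- P_mmHg * 0.133322
  potential <- function(a) {
    Ri <- seq(geom$A, geom$B, length.out = nR)
    ri2 <- a^2 + v * (Ri^2 - geom$A^2) / lambda_z
    lti <- sqrt(ri2) / Ri
    lri <- v * Ri / (lambda_z * sqrt(ri2))
    wi <- vapply(seq_len(nR), function(k)
      oracle_energy(lri[k], lti[k], lambda_z, model$inner), numeric(1))
    if (model$inner$contractile && T_act > 0) {
      wi <- wi + oracle_active_potential(lti, model$tone, T_act)
    }
    b2 <- a^2 + v * (geom$B^2 - geom$A^2) / lambda_z
    Ro <- seq(geom$B, geom$C, length.out = nR)
    ro2 <- b2 + (Ro^2 - geom$B^2) / lambda_z
    lto <- sqrt(ro2) / Ro
    lro <- Ro / (lambda_z * sqrt(ro2))
    wo <- vapply(seq_len(nR), function(k)
      oracle_energy(lro[k], lto[k], lambda_z, model$outer), numeric(1))
    if (model$outer$contractile && T_act > 0) {
      wo <- wo + oracle_active_potential(lto, model$tone, T_act)
    }
    2 * pi * (v * pracma::trapz(Ri, wi * Ri) + pracma::trapz(Ro, wo * Ro)) -
      P_kPa * lambda_z * pi * a^2
  }
  if (is.null(interval)) interval <- c(0.5, 2.5) * geom$A
  stats::optimize(potential, interval = interval, tol = 1e-7)$minimum
}

## Finite-difference eigenvalue discretization of the buckling second
## variation: an implementation path independent of the shooting
## determinant. Returns the smallest eigenvalue of the discretized
## quadratic form (negative = unstable at this mode).
oracle_buckling_min_eig <- function(state, n, N = 481,
                                    active_stiffness = FALSE,
                                    pressure_increment = "follower",
                                    outer_support = "embedded") {
  a <- state$a; cc <- state$c_out
  r <- seq(a, cc, length.out = N); h <- r[2] - r[1]
  layer <- ifelse(r <= state$b, "inner", "outer")
  cf <- matrix(0, N, 4)
  for (ly in c("inner", "outer")) {
    sel <- layer == ly
    if (!any(sel)) next
    co <- cordclose:::.buckling_coeffs(state, r[sel], ly, active_stiffness)
    cf[sel, ] <- cbind(co$alpha, co$beta, co$gamma, co$delta)
  }
  D1 <- matrix(0, N, N); D2 <- matrix(0, N, N)
  for (i in 2:(N - 1)) {
    D1[i, i - 1] <- -1 / (2 * h); D1[i, i + 1] <- 1 / (2 * h)
    D2[i, i - 1] <- 1 / h^2; D2[i, i] <- -2 / h^2; D2[i, i + 1] <- 1 / h^2
  }
  D1[1, 1:3] <- c(-3, 4, -1) / (2 * h)
  D1[N, (N - 2):N] <- c(1, -4, 3) / (2 * h)
  D2[1, 1:4] <- c(2, -5, 4, -1) / h^2
  D2[N, (N - 3):N] <- c(-1, 4, -5, 2) / h^2
  w <- rep(h, N); w[c(1, N)] <- h / 2
  Aop <- diag(n / r) %*% D1 - diag(n / r^2)
  Bop <- diag(1 / r) %*% D1 - diag(n^2 / r^2)
  Cop <- -D2
  M <- t(Aop) %*% (w * cf[, 1] * r * Aop) +
       t(Bop) %*% (w * cf[, 2] * r * Bop) +
       t(Cop) %*% (w * cf[, 3] * r * Cop) +
       t(Bop) %*% (w * cf[, 4] * r * Cop) +
       t(Cop) %*% (w * cf[, 4] * r * Bop)
  if (pressure_increment == "follower") {
    P <- state$P_kPa
    e1 <- numeric(N); e1[1] <- 1
    d1 <- D1[1, ]
    M <- M - P * (n^2 / a^2 * outer(e1, e1) + outer(d1, d1) -
                  n^2 / a * (outer(e1, d1) + outer(d1, e1)))
  }
  keep <- seq_len(N)
  if (outer_support == "embedded") keep <- seq_len(N - 2)  # f = f' = 0 at c
  M <- (M + t(M)) / 2
  M <- M[keep, keep]
  min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}

## Build a loaded_state directly from a prescribed luminal pressure in kPa
## (possibly negative, for benchmark loadings outside the public API).
make_state_kPa <- function(model, P_kPa, v = 1,
                           lambda_z = model$geometry$lambda_z,
                           bracket = c(0.8, 1.2)) {
  geom <- model$geometry
  f <- function(a)
    cordclose:::.wall_response(model, a, lambda_z, v, 0, 300)$P_kPa - P_kPa
  a <- stats::uniroot(f, bracket * geom$A, tol = 1e-12)$root
  rad <- cordclose:::.loaded_radii(a, geom, v, lambda_z)
  prof <- cordclose:::.state_profiles(model, a, lambda_z, v, 0, P_kPa,
                                      n_prof = 801)
  structure(list(a = a, b = rad$b, c_out = rad$c_out,
                 P_mmHg = P_kPa / 0.133322, P_kPa = P_kPa,
                 lambda_z = lambda_z, T_act = 0, v = v, model = model,
                 occluded = FALSE, profiles = prof),
            class = "loaded_state")
}

## small deterministic latin-hypercube-free sampler for property tests
runif_seeded <- function(n, lo, hi, seed) {
  set.seed(seed)
  lo + (hi - lo) * stats::runif(n)
}
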