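#' Specification of a synthetic ex vivo biaxial experiment
#'
#' Describes the virtual counterpart of a murine biaxial test session:
#' ground-truth model, protocol grids (pressure sweeps at several fixed
#' axial stretches; axial force-length sweeps at several fixed pressures),
#' a multiplicative Gaussian noise model on the measured responses, the
#' number of vessels, and the random seed. The defaults emulate passive
#' tests of embryonic-day-18.5 murine umbilical vessels: n = 4 vessels,
#' pressures up to 25 mmHg, axial stretches bracketing the in vivo value.
#'
#' @param model Ground-truth [vessel_model()].
#' @param n_vessels Number of vessels (independent noise realizations).
#' @param pressures_mmHg Pressure grid of the pressure-diameter protocols.
#' @param lambda_z_factors Axial stretches of the pressure sweeps, as
#'   multiples of the in vivo axial stretch.
#' @param fl_pressures_mmHg Fixed pressures of the force-length protocols.
#' @param fl_lambda_z Axial stretch grid of the force-length protocols.
#' @param sd_diameter,sd_force Multiplicative noise standard deviations on
#'   outer diameter and axial force (fractions; defaults 1 and 3 percent,
#'   conservative for video-tracked diameter and transducer force).
#' @param seed Random seed, recorded in the output metadata.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(model = umbilical_artery_model(),
                           n_vessels = 4,
                           pressures_mmHg = seq(2.5, 25, by = 2.5),
                           lambda_z_factors = c(0.95, 1, 1.05),
                           fl_pressures_mmHg = c(5, 15, 25),
                           fl_lambda_z = seq(1.16, 1.40, by = 0.04),
                           sd_diameter = 0.01, sd_force = 0.03,
                           seed = 17) {
  stopifnot(sd_diameter >= 0, sd_force >= 0, n_vessels >= 1)
  structure(list(model = model, n_vessels = n_vessels,
                 pressures_mmHg = pressures_mmHg,
                 lambda_z_factors = lambda_z_factors,
                 fl_pressures_mmHg = fl_pressures_mmHg,
                 fl_lambda_z = fl_lambda_z,
                 sd_diameter = sd_diameter, sd_force = sd_force,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic passive biaxial dataset
#'
#' Forward-simulates every protocol point of the spec with the ground-truth
#' model (passive: `T_act = 0`, `v = 1`), then perturbs the measured
#' responses (outer diameter, axial force) with multiplicative Gaussian
#' noise. Infeasible protocol points (no patent equilibrium) are dropped
#' with a recorded count. The output is reproducible byte-for-byte from
#' `(spec, seed)`.
#'
#' @param spec A [synthetic_spec()].
#' @param n_nodes Quadrature nodes per layer in the forward solves.
#' @return A data.frame with columns `vessel`, `protocol`, `lambda_z`,
#'   `pressure_mmHg`, `outer_diameter_um`, `f_axial_mN`; attributes
#'   `truth` (the generating parameters as a named list), `spec`,
#'   `n_dropped`.
#' @export
generate_biaxial <- function(spec, n_nodes = 150) {
  stopifnot(inherits(spec, "synthetic_spec"))
  model <- spec$model
  lamz0 <- model$geometry$lambda_z
  ## protocol table: pressure-diameter sweeps + force-length sweeps
  pd <- do.call(rbind, lapply(seq_along(spec$lambda_z_factors), function(i) {
    data.frame(protocol = sprintf("pd_lz%02d", i),
               lambda_z = spec$lambda_z_factors[i] * lamz0,
               pressure_mmHg = spec$pressures_mmHg)
  }))
  fl <- do.call(rbind, lapply(seq_along(spec$fl_pressures_mmHg), function(i) {
    data.frame(protocol = sprintf("fl_P%02d", i),
               lambda_z = spec$fl_lambda_z,
               pressure_mmHg = spec$fl_pressures_mmHg[i])
  }))
  proto <- rbind(pd, fl)

  ## noise-free forward responses (shared across vessels)
  clean <- data.frame(proto, outer_diameter_um = NA_real_, f_axial_mN = NA_real_)
  for (i in seq_len(nrow(clean))) {
    st <- tryCatch(
      solve_inner_radius(model, clean$pressure_mmHg[i], T_act = 0, v = 1,
                         lambda_z = clean$lambda_z[i], n_nodes = n_nodes),
      error = function(e) NULL)
    if (!is.null(st) && !st$occluded) {
      clean$outer_diameter_um[i] <- 2 * st$c_out
      clean$f_axial_mN[i] <- st$f_axial_mN
    }
  }
  dropped <- sum(is.na(clean$outer_diameter_um))
  if (dropped > 0) {
    warning(sprintf("%d infeasible protocol points dropped", dropped),
            call. = FALSE)
    clean <- clean[!is.na(clean$outer_diameter_um), ]
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  out <- do.call(rbind, lapply(seq_len(spec$n_vessels), function(vk) {
    d <- clean
    d$vessel <- vk
    d$outer_diameter_um <- d$outer_diameter_um *
      (1 + spec$sd_diameter * stats::rnorm(nrow(d)))
    d$f_axial_mN <- d$f_axial_mN * (1 + spec$sd_force * stats::rnorm(nrow(d)))
    d
  }))
  rownames(out) <- NULL
  out <- out[, c("vessel", "protocol", "lambda_z", "pressure_mmHg",
                 "outer_diameter_um", "f_axial_mN")]
  attr(out, "truth") <- .model_truth(model)
  attr(out, "spec") <- spec
  attr(out, "n_dropped") <- dropped
  out
}

## flatten the generating parameters for recovery scoring
.model_truth <- function(model) {
  f <- model$outer$fibers
  out <- list(geometry = unclass(model$geometry),
              mu1 = model$inner$mu, mu2 = model$outer$mu,
              lambda_m = model$tone$lambda_m, lambda_0 = model$tone$lambda_0)
  if (length(f) >= 4) {
    out <- c(out, list(c11 = f[[1]]$c1, c21 = f[[1]]$c2,
                       c12 = f[[2]]$c1, c22 = f[[2]]$c2,
                       c134 = f[[3]]$c1, c234 = f[[3]]$c2,
                       eta = abs(f[[3]]$eta)))
  }
  out
}

#' Generate a synthetic contraction (KCl-type) dataset
#'
#' Simulates the stimulated-contraction readout of the biaxial rig:
#' passive and contracted outer diameters at fixed pressure for each
#' vessel, with multiplicative measurement noise, and the per-vessel
#' percent diameter reduction. An artery-like spec (substantial `T_act`)
#' targets the observed 30-50 percent reduction at 25 mmHg; a vein-like
#' spec uses a small `T_act`.
#'
#' @param spec A [synthetic_spec()].
#' @param T_act Active stress magnitude of the contracted state (kPa).
#' @param v_contracted Normalized inner-layer volume during contraction
#'   (fluid exudation under compression gives values below 1).
#' @param P Fixed pressure (mmHg).
#' @param n_nodes Quadrature nodes per layer.
#' @return A data.frame with one row per vessel: passive and contracted
#'   outer diameters (um) and `reduction_pct`; attribute `truth` holds the
#'   noise-free values.
#' @export
generate_contraction <- function(spec, T_act, v_contracted = 1, P = 25,
                                 n_nodes = 150) {
  stopifnot(inherits(spec, "synthetic_spec"))
  model <- spec$model
  st0 <- solve_inner_radius(model, P, T_act = 0, v = 1, n_nodes = n_nodes)
  d_pass <- 2 * st0$c_out
  stc <- solve_inner_radius(model, P, T_act = T_act, v = v_contracted,
                            a_init = st0$a, n_nodes = n_nodes)
  d_con <- if (stc$occluded) 0 else 2 * stc$c_out

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed + 1L)
  n <- spec$n_vessels
  dp <- d_pass * (1 + spec$sd_diameter * stats::rnorm(n))
  dc <- d_con * (1 + spec$sd_diameter * stats::rnorm(n))
  out <- data.frame(vessel = seq_len(n), P_mmHg = P, T_act_kPa = T_act,
                    v = v_contracted,
                    passive_diameter_um = dp, contracted_diameter_um = dc,
                    reduction_pct = 100 * (1 - dc / dp))
  attr(out, "truth") <- list(passive_diameter_um = d_pass,
                             contracted_diameter_um = d_con,
                             reduction_pct = 100 * (1 - d_con / d_pass))
  out
}

#' Read or write biaxial protocol data as CSV
#'
#' The on-disk format is a plain CSV with the documented header
#' `vessel, protocol, lambda_z, pressure_mmHg, outer_diameter_um,
#' f_axial_mN`.
#'
#' @param data A biaxial data.frame (see [generate_biaxial()]).
#' @param path File path.
#' @return `read_biaxial_csv()` returns the data.frame;
#'   `write_biaxial_csv()` returns `path` invisibly.
#' @export
write_biaxial_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_biaxial_csv
#' @export
read_biaxial_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel", "protocol", "lambda_z", "pressure_mmHg",
            "outer_diameter_um", "f_axial_mN")
  if (!all(need %in% names(d))) {
    stop("missing required biaxial CSV columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  d
}
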