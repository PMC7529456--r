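#' Reference (unloaded) bilayer geometry
#'
#' The wall is a two-layer annulus in its unloaded configuration: the inner,
#' glycosaminoglycan (GAG)-rich tunica media occupies radii `A <= R <= B`,
#' the outer smooth-muscle-rich tunica media `B <= R <= C`. The vessel is
#' held at a fixed in vivo axial stretch `lambda_z` in all loaded states.
#'
#' @param A Unloaded inner radius (micrometers).
#' @param B Unloaded inner/outer interface radius (micrometers).
#' @param C Unloaded outer radius (micrometers).
#' @param lambda_z Loaded axial stretch (dimensionless).
#' @return An object of class `vessel_geometry`.
#' @examples
#' vessel_geometry(161.77, 206.86, 236.92, 1.28)
#' @export
vessel_geometry <- function(A, B, C, lambda_z = 1) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C), is.numeric(lambda_z))
  if (!(A > 0 && B > A && C > B)) {
    stop("vessel_geometry requires 0 < A < B < C", call. = FALSE)
  }
  if (lambda_z <= 0) stop("lambda_z must be positive", call. = FALSE)
  structure(list(A = A, B = B, C = C, lambda_z = lambda_z),
            class = "vessel_geometry")
}

#' One fiber family of the passive wall
#'
#' Collagen-dominated fiber family with an exponential stress response,
#' oriented at angle `eta` from the vessel axis (0 = axial, 90 =
#' circumferential, diagonal families at +/- eta).
#'
#' @param c1 Stress-like stiffness parameter (kPa), `c1 >= 0`.
#' @param c2 Dimensionless exponential parameter, `c2 >= 0`.
#' @param eta Orientation angle from the axial direction (degrees),
#'   in (-90, 90].
#' @return An object of class `fiber_family`.
#' @export
fiber_family <- function(c1, c2, eta) {
  if (c1 < 0 || c2 < 0) stop("fiber parameters must be non-negative", call. = FALSE)
  if (eta <= -90 || eta > 90) stop("eta must lie in (-90, 90] degrees", call. = FALSE)
  structure(list(c1 = c1, c2 = c2, eta = eta), class = "fiber_family")
}

#' Passive material of one wall layer
#'
#' Isotropic neo-Hookean ground matrix of shear modulus `mu` plus zero or
#' more embedded [fiber_family()] entries. Fibers carry load in extension
#' only. A layer may additionally be flagged `contractile`, in which case
#' smooth-muscle active stress (see [active_stress()]) acts circumferentially
#' within it.
#'
#' @param mu Shear modulus of the ground matrix (kPa), `mu > 0`.
#' @param fibers List of [fiber_family()] objects (possibly empty).
#' @param contractile Logical; does smooth-muscle active stress act in this
#'   layer?
#' @return An object of class `layer_material`.
#' @export
layer_material <- function(mu, fibers = list(), contractile = FALSE) {
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  if (!all(vapply(fibers, inherits, logical(1), "fiber_family"))) {
    stop("fibers must be a list of fiber_family objects", call. = FALSE)
  }
  structure(list(mu = mu, fibers = fibers, contractile = isTRUE(contractile)),
            class = "layer_material")
}

#' Smooth-muscle active tone
#'
#' Parabolic length-tension law: the circumferential active Cauchy stress is
#' `T_act * lambda_theta * (1 - ((lambda_m - lambda_theta)/(lambda_m -
#' lambda_0))^2)` wherever that bracket is positive and zero elsewhere, so
#' the muscle generates no force at or below the minimum contractile stretch
#' `lambda_0` and peak force density at `lambda_m`.
#'
#' @param T_act Active stress magnitude (kPa), `T_act >= 0`.
#' @param lambda_m Stretch of maximal active force generation.
#' @param lambda_0 Minimum contractile stretch (no force at or below it).
#' @return An object of class `active_tone`.
#' @export
active_tone <- function(T_act, lambda_m = 2.5, lambda_0 = 0.2) {
  if (T_act < 0) stop("T_act must be non-negative", call. = FALSE)
  if (!(lambda_0 > 0 && lambda_m > lambda_0)) {
    stop("active tone requires 0 < lambda_0 < lambda_m", call. = FALSE)
  }
  structure(list(T_act = T_act, lambda_m = lambda_m, lambda_0 = lambda_0),
            class = "active_tone")
}

#' Bundle geometry and layer materials into a vessel model
#'
#' @param geometry A [vessel_geometry()].
#' @param inner [layer_material()] of the inner (GAG-rich) layer.
#' @param outer [layer_material()] of the outer (smooth-muscle-rich) layer.
#' @param tone An [active_tone()] giving the length-tension window; its
#'   `T_act` serves as the default magnitude and is overridden per call.
#' @return An object of class `vessel_model`.
#' @export
vessel_model <- function(geometry, inner, outer, tone = active_tone(0)) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(inner, "layer_material"),
            inherits(outer, "layer_material"),
            inherits(tone, "active_tone"))
  structure(list(geometry = geometry, inner = inner, outer = outer, tone = tone),
            class = "vessel_model")
}

#' @export
print.vessel_model <- function(x, ...) {
  g <- x$geometry
  cat("Bilayered vessel model\n")
  cat(sprintf("  unloaded radii A, B, C: %.2f, %.2f, %.2f um; lambda_z = %.3f\n",
              g$A, g$B, g$C, g$lambda_z))
  cat(sprintf("  inner layer: mu = %.3g kPa, %d fiber families%s\n",
              x$inner$mu, length(x$inner$fibers),
              if (x$inner$contractile) ", contractile" else ""))
  cat(sprintf("  outer layer: mu = %.3g kPa, %d fiber families%s\n",
              x$outer$mu, length(x$outer$fibers),
              if (x$outer$contractile) ", contractile" else ""))
  cat(sprintf("  tone window: lambda_0 = %.2f, lambda_m = %.2f\n",
              x$tone$lambda_0, x$tone$lambda_m))
  invisible(x)
}

#' Read model parameters from a flat YAML/JSON file
#'
#' The file mirrors the published parameter table for the umbilical artery:
#' geometry (`A`, `B`, `C`, `lambda_z`), layer shear moduli (`mu1`, `mu2`),
#' fiber families of the outer layer (axial, circumferential, two diagonal),
#' and the contractile stretch window (`lambda_m`, `lambda_0`).
#'
#' @param path Path to a YAML (or JSON) parameter file.
#' @return A [vessel_model()].
#' @seealso [umbilical_artery_model()] for the packaged murine parameter set.
#' @export
read_vessel_params <- function(path) {
  p <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  geom <- vessel_geometry(p$geometry$A, p$geometry$B, p$geometry$C,
                          p$geometry$lambda_z)
  fibs <- lapply(p$outer$fibers, function(f) fiber_family(f$c1, f$c2, f$eta))
  inner <- layer_material(p$inner$mu, contractile = isTRUE(p$inner$contractile))
  outer <- layer_material(p$outer$mu, fibers = fibs,
                          contractile = !isFALSE(p$outer$contractile))
  tone <- active_tone(if (is.null(p$tone$T_act)) 0 else p$tone$T_act,
                      p$tone$lambda_m, p$tone$lambda_0)
  vessel_model(geom, inner, outer, tone)
}

#' Packaged umbilical-artery parameter set
#'
#' Returns the vessel model with the parameter values fixed for all
#' umbilical-artery simulations: unloaded radii 161.77 / 206.86 / 236.92 um,
#' axial stretch 1.28, inner (GAG) shear modulus 3.0 kPa, outer matrix
#' shear modulus 0.1 kPa, four outer-layer fiber families (axial,
#' circumferential, diagonals at +/- 41.92 degrees), and contractile
#' stretch window (0.2, 2.5). Only the outer layer is contractile.
#'
#' @return A [vessel_model()].
#' @export
umbilical_artery_model <- function() {
  read_vessel_params(system.file("extdata", "umbilical_artery_params.yaml",
                                 package = "cordclose", mustWork = TRUE))
}

#' Unit conversion between mmHg and kPa
#'
#' Pressures are quoted in mmHg at the user interface (the convention of
#' biaxial testing rigs) and carried in kPa internally; 1 mmHg =
#' 0.133322 kPa.
#'
#' @param x Pressure value(s).
#' @return Converted pressure value(s).
#' @export
mmHg_to_kPa <- function(x) x * 0.133322

#' @rdname mmHg_to_kPa
#' @export
kPa_to_mmHg <- function(x) x / 0.133322
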