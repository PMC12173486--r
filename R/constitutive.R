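#' Constitutive parameters of the transversely isotropic tendon model
#'
#' Constructs the parameter set of the uncoupled, transversely isotropic
#' hyperelastic tendon material: an isotropic Mooney--Rivlin ground matrix
#' (`C1`, `C2`) with embedded collagen fibres whose tensile response is
#' exponential while uncrimping (`C3` scale, `C4` rate) and linear with
#' modulus `C5` once straightened beyond the engagement stretch
#' `lambda_star`.  The continuity constant `C6` is derived, not supplied
#' (see [derive_c6()]).
#'
#' Moduli are supplied in MPa -- the convention of finite element input
#' decks -- and stored internally in Pa so that densities (kg m^-3) and
#' wave speeds (m s^-1) combine without unit factors.  The defaults are
#' the reference tendon parameter set: rho = 1500 kg m^-3, C1 = C2 =
#' 2.05 MPa, C3 = 1.75 MPa, C4 = 50, C5 = 350 MPa, lambda* = 1.03 and a
#' near-incompressibility bulk modulus K = 1e3 x C1.
#'
#' @param rho mass density, kg m^-3.
#' @param C1,C2 Mooney--Rivlin matrix coefficients, MPa.
#' @param C3 fibre exponential stress scale, MPa.
#' @param C4 fibre uncrimping rate, dimensionless.
#' @param C5 straightened-fibre elastic modulus, MPa.
#' @param lambda_star fibre engagement stretch (> 1), dimensionless.
#' @param K bulk modulus, MPa; defaults to `1e3 * C1`.
#' @return An object of class `material_params`: a list with elements
#'   `rho` (kg m^-3), `C1 ... C5`, `K` (Pa), `lambda_star`, and the derived
#'   `C6` (Pa) and `mu` (matrix tangential shear modulus, Pa).
#' @examples
#' p <- material_params()
#' p$mu / 1e6           # 8.2 MPa
#' p$C6 / 1e6           # about -354.4 MPa
#' @seealso [derive_c6()], [fiber_stress_term()], [matrix_shear_modulus()]
#' @export
material_params <- function(rho = 1500, C1 = 2.05, C2 = 2.05, C3 = 1.75,
                            C4 = 50, C5 = 350, lambda_star = 1.03,
                            K = 1e3 * C1) {
  vals <- c(rho = rho, C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5,
            lambda_star = lambda_star, K = K)
  if (any(!is.finite(vals)))
    stop("all material parameters must be finite")
  if (rho <= 0) stop("density 'rho' must be > 0")
  if (any(c(C1, C2, C3, C5, K) < 0))
    stop("moduli C1, C2, C3, C5, K must be >= 0")
  if (C4 < 0) stop("uncrimping rate C4 must be >= 0")
  if (lambda_star <= 1) stop("engagement stretch 'lambda_star' must be > 1")
  mpa <- 1e6
  p <- structure(list(
    rho = rho,
    C1 = C1 * mpa, C2 = C2 * mpa, C3 = C3 * mpa, C4 = C4, C5 = C5 * mpa,
    lambda_star = lambda_star, K = K * mpa),
    class = "material_params")
  p$C6 <- derive_c6(p)
  p$mu <- matrix_shear_modulus(p)
  p
}

#' @export
print.material_params <- function(x, ...) {
  cat("Transversely isotropic tendon material\n")
  cat(sprintf("  rho     %8.1f kg m^-3\n", x$rho))
  for (nm in c("C1", "C2", "C3", "C5", "C6", "K"))
    cat(sprintf("  %-7s %8.3f MPa\n", nm, x[[nm]] / 1e6))
  cat(sprintf("  C4      %8.3f\n", x$C4))
  cat(sprintf("  lambda* %8.4f\n", x$lambda_star))
  cat(sprintf("  mu      %8.3f MPa  (= 2 (C1 + C2))\n", x$mu / 1e6))
  invisible(x)
}

#' Fibre-law continuity constant C6
#'
#' The piecewise fibre stress law is exponential below the engagement
#' stretch and linear (`C5 * lambda + C6`) above it; `C6` is fixed by
#' requiring the stress to be continuous at `lambda_star`:
#' `C6 = C3 (exp(C4 (lambda* - 1)) - 1) - C5 lambda*`.
#'
#' @param params a [material_params()] object.
#' @return C6 in Pa (negative for physiological parameter sets).
#' @export
derive_c6 <- function(params) {
  stopifnot(inherits(params, "material_params"))
  if (params$C5 <= 0)
    stop("C5 must be > 0 to define the linear fibre branch")
  if (params$lambda_star <= 1)
    stop("lambda_star must be > 1")
  with(params, C3 * (exp(C4 * (lambda_star - 1)) - 1) - C5 * lambda_star)
}

#' Fibre contribution to axial stress
#'
#' Evaluates the piecewise fibre stress term `lambda * dF/dlambda` at a
#' tissue stretch along the fibre direction: zero for slack fibres
#' (`lambda <= 1`), exponential while uncrimping
#' (`C3 (exp(C4 (lambda - 1)) - 1)` for `1 < lambda < lambda*`), linear
#' (`C5 lambda + C6`) once the fibres are straight.
#'
#' @param lambda_t tissue stretch along the fibre (vectorised), > 0.
#' @param params a [material_params()] object.
#' @return stress contribution in Pa, same length as `lambda_t`.
#' @examples
#' p <- material_params()
#' fiber_stress_term(c(1, 1.02, 1.05), p) / 1e6
#' @export
fiber_stress_term <- function(lambda_t, params) {
  stopifnot(inherits(params, "material_params"))
  if (any(lambda_t <= 0)) stop("stretch 'lambda_t' must be > 0")
  C6 <- params$C6
  out <- numeric(length(lambda_t))
  mid <- lambda_t > 1 & lambda_t < params$lambda_star
  hi <- lambda_t >= params$lambda_star
  out[mid] <- params$C3 * (exp(params$C4 * (lambda_t[mid] - 1)) - 1)
  out[hi] <- params$C5 * lambda_t[hi] + C6
  out
}

#' Tangential shear modulus of the ground matrix
#'
#' In the unloaded state the transverse tangential shear modulus of the
#' Mooney--Rivlin matrix (and hence of the transversely isotropic tissue)
#' is `2 (C1 + C2)`.
#'
#' @param params a [material_params()] object.
#' @return shear modulus mu in Pa.
#' @export
matrix_shear_modulus <- function(params) {
  stopifnot(inherits(params, "material_params"))
  2 * (params$C1 + params$C2)
}

#' Closed-form tensioned-beam shear wave speed
#'
#' Inverts the tensioned-beam relationship `sigma = rho c^2 - k' mu`:
#' the transverse wave speed of an axially stressed beam with shear
#' correction factor `kprime` and tangential shear modulus `mu` is
#' `c = sqrt((sigma + k' mu) / rho)`.
#'
#' @param sigma axial stress, Pa (vectorised).
#' @param kprime shear correction factor (dimensionless, default 1).
#' @param mu tangential shear modulus, Pa.
#' @param rho mass density, kg m^-3.
#' @return wave speed in m s^-1.
#' @examples
#' closed_form_wave_speed(5e6, 1, 8.2e6, 1500)  # 93.8 m/s
#' @export
closed_form_wave_speed <- function(sigma, kprime = 1, mu = 0, rho = 1500) {
  if (rho <= 0) stop("'rho' must be > 0")
  rad <- sigma + kprime * mu
  if (any(rad < 0))
    stop("negative radicand: sigma + k'mu must be >= 0 ",
         "(compressive regime is outside the tensioned-beam model)")
  sqrt(rad / rho)
}

#' Read or write material parameters as flat JSON
#'
#' Parameters are serialised as a flat JSON document keyed by the
#' conventional symbol names (`rho`, `C1`..`C5`, `lambda_star`, `K`) with
#' moduli in MPa, so files are interchangeable with finite element decks.
#'
#' @param params a [material_params()] object.
#' @param path file path.
#' @return `write_material_params()` returns `path` invisibly;
#'   `read_material_params()` returns a [material_params()] object.
#' @export
write_material_params <- function(params, path) {
  stopifnot(inherits(params, "material_params"))
  doc <- list(rho = params$rho, C1 = params$C1 / 1e6, C2 = params$C2 / 1e6,
              C3 = params$C3 / 1e6, C4 = params$C4, C5 = params$C5 / 1e6,
              lambda_star = params$lambda_star, K = params$K / 1e6)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_material_params
#' @export
read_material_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("rho", "C1", "C2", "C3", "C4", "C5", "lambda_star", "K")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("material JSON is missing keys: ", paste(miss, collapse = ", "))
  material_params(rho = doc$rho, C1 = doc$C1, C2 = doc$C2, C3 = doc$C3,
                  C4 = doc$C4, C5 = doc$C5, lambda_star = doc$lambda_star,
                  K = doc$K)
}
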