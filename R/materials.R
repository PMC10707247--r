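#' Define an elastic material
#'
#' Materials carry a Young's modulus, density and a dimensionless structural
#' loss factor. If a viscoelastic specification is attached, the complex
#' frequency-dependent modulus from [maxwell_complex_modulus()] replaces the
#' static Young's modulus during assembly.
#'
#' @param name Material identifier.
#' @param young_modulus Young's modulus in Pa (> 0). Ignored during assembly
#'   when `viscoelastic` is given, but still required as a bookkeeping value.
#' @param density Density in kg/m^3 (> 0). Element mass is neglected in the
#'   reduced network (inertia is carried by [rigid_inertia()] bodies), so the
#'   density is informational.
#' @param loss_factor Structural damping loss factor (>= 0); the assembled
#'   element modulus is `E * (1 + 1i * loss_factor)`.
#' @param viscoelastic Optional [viscoelastic_spec()].
#' @return An object of class `ear_material`.
#' @export
#' @examples
#' material_spec("sal_ligament", young_modulus = 6.5e4, density = 1200,
#'               loss_factor = 0.15)
material_spec <- function(name, young_modulus, density, loss_factor = 0,
                          viscoelastic = NULL) {
  if (!is_scalar_string(name)) abort_config("material 'name' must be a non-empty string")
  if (!is_scalar_number(young_modulus) || young_modulus <= 0) {
    abort_config(sprintf("material '%s': 'young_modulus' must be > 0", name))
  }
  if (!is_scalar_number(density) || density <= 0) {
    abort_config(sprintf("material '%s': 'density' must be > 0", name))
  }
  if (!is_scalar_number(loss_factor) || loss_factor < 0) {
    abort_config(sprintf("material '%s': 'loss_factor' must be >= 0", name))
  }
  if (!is.null(viscoelastic) && !inherits(viscoelastic, "ear_viscoelastic")) {
    abort_config(sprintf("material '%s': 'viscoelastic' must be a viscoelastic_spec()", name))
  }
  structure(
    list(name = name, young_modulus = young_modulus, density = density,
         loss_factor = loss_factor, viscoelastic = viscoelastic),
    class = "ear_material"
  )
}

#' Generalized Maxwell viscoelastic specification
#'
#' A spring of modulus `e_inf` in parallel with Maxwell arms, each a spring
#' `e_i` in series with a dashpot of relaxation time `tau_i`.
#'
#' @param e_inf Equilibrium (fully relaxed) modulus in Pa (>= 0).
#' @param e Moduli of the Maxwell arms in Pa (each > 0, at least one).
#' @param tau Relaxation times of the arms in s (each > 0, same length as `e`).
#' @return An object of class `ear_viscoelastic`.
#' @export
#' @examples
#' viscoelastic_spec(e_inf = 6.5e5, e = 6.5e6, tau = 8e-5)
viscoelastic_spec <- function(e_inf, e, tau) {
  if (!is_scalar_number(e_inf) || e_inf < 0) abort_config("'e_inf' must be >= 0")
  if (!is.numeric(e) || length(e) < 1L || any(!is.finite(e)) || any(e <= 0)) {
    abort_config("'e' must contain at least one finite positive modulus")
  }
  if (!is.numeric(tau) || length(tau) != length(e) || any(!is.finite(tau)) || any(tau <= 0)) {
    abort_config("'tau' must be positive and the same length as 'e'")
  }
  structure(list(e_inf = e_inf, e = as.numeric(e), tau = as.numeric(tau)),
            class = "ear_viscoelastic")
}

#' Complex modulus of a generalized Maxwell material
#'
#' Storage modulus `e_inf + sum_i e_i (w tau_i)^2 / (1 + (w tau_i)^2)` and
#' loss modulus `sum_i e_i (w tau_i) / (1 + (w tau_i)^2)` with `w = 2 pi f`.
#' The storage modulus is non-decreasing in frequency; at `f = 0` all arms
#' are relaxed and the modulus is `e_inf`; for a single arm the loss modulus
#' vanishes at both frequency extremes and peaks at `w tau = 1`.
#'
#' @param spec A [viscoelastic_spec()].
#' @param freq Frequency in Hz (vectorised, each >= 0).
#' @return Complex modulus in Pa (storage + 1i * loss), one value per frequency.
#' @export
#' @examples
#' sp <- viscoelastic_spec(e_inf = 1e5, e = 2e5, tau = 1e-3)
#' maxwell_complex_modulus(sp, 0)                   # e_inf
#' maxwell_complex_modulus(sp, 1 / (2 * pi * 1e-3)) # e_inf + e/2 + 1i*e/2
maxwell_complex_modulus <- function(spec, freq) {
  if (!inherits(spec, "ear_viscoelastic")) {
    abort_config("'spec' must be a viscoelastic_spec()")
  }
  if (!is.numeric(freq) || any(!is.finite(freq)) || any(freq < 0)) {
    abort_domain("'freq' must be non-negative and finite")
  }
  omega <- 2 * pi * freq
  storage <- vapply(omega, function(w) {
    wt <- w * spec$tau
    spec$e_inf + sum(spec$e * wt^2 / (1 + wt^2))
  }, numeric(1))
  loss <- vapply(omega, function(w) {
    wt <- w * spec$tau
    sum(spec$e * wt / (1 + wt^2))
  }, numeric(1))
  complex(real = storage, imaginary = loss)
}
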