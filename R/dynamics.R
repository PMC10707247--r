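# Harmonic assembly and solution: D(f) u = F with
# D(f) = K(f) - w^2 M + (cochlear load), K complex through structural damping
# or the frequency-dependent Maxwell modulus.

element_complex_modulus <- function(material, freq) {
  if (!is.null(material$viscoelastic)) {
    maxwell_complex_modulus(material$viscoelastic, freq)
  } else {
    material$young_modulus * (1 + 1i * material$loss_factor)
  }
}

element_complex_stiffness <- function(model, el, freq) {
  E <- element_complex_modulus(model$materials[[el$material]], freq)
  k <- E * el$area / el$length
  if (el$kind == "shear") k <- k / (2 * (1 + 0.3))
  k
}

#' Assemble the complex dynamic stiffness matrix
#'
#' Builds `D(f) = K(f) - (2 pi f)^2 M + Z_cochlea(f)` over the active dofs.
#' Element contributions are truss-style `k d d^T` blocks with
#' `k = E(f) A / L` along the element direction `d`; the cochlear load adds
#' `1i w R + 1/C` at the footplate piston dof. The matrix is complex symmetric
#' at every frequency.
#'
#' @param model A `middle_ear_model`.
#' @param freq Frequency in Hz (> 0).
#' @return Complex square matrix with dimnames `"<node>.<dof>"`.
#' @export
#' @seealso [harmonic_response()]
assemble_dynamic_stiffness <- function(model, freq) {
  stopifnot(inherits(model, "middle_ear_model"))
  if (!is_scalar_number(freq) || freq <= 0) {
    abort_domain("'freq' must be a single positive frequency in Hz")
  }
  omega <- 2 * pi * freq
  n <- model$n_dof
  D <- matrix(0 + 0i, n, n, dimnames = list(model$dof_labels, model$dof_labels))

  for (el in model$elements) {
    k <- element_complex_stiffness(model, el, freq)
    d <- model$directions[[el$id]]
    ia <- model$node_dofs[[el$node_a]] # named: dof -> global index (if mobile)
    ib <- model$node_dofs[[el$node_b]]
    add_block <- function(ii, jj, sign) {
      for (p in names(ii)) {
        for (q in names(jj)) {
          w <- k * d[DOF_AXES[[p]]] * d[DOF_AXES[[q]]] * sign
          D[ii[[p]], jj[[q]]] <<- D[ii[[p]], jj[[q]]] + w
        }
      }
    }
    if (!is.null(ia)) add_block(ia, ia, 1)
    if (!is.null(ib)) add_block(ib, ib, 1)
    if (!is.null(ia) && !is.null(ib)) {
      add_block(ia, ib, -1)
      add_block(ib, ia, -1)
    }
  }

  for (nid in names(model$node_dofs)) {
    m <- model$node_mass[[nid]]
    if (m > 0) {
      ii <- model$node_dofs[[nid]]
      D[cbind(ii, ii)] <- D[cbind(ii, ii)] - omega^2 * m
    }
  }

  ci <- model$node_dofs[[model$cochlea$node]]
  if (!is.null(ci) && "ux" %in% names(ci)) {
    i <- ci[["ux"]]
    D[i, i] <- D[i, i] + 1i * omega * model$cochlea$resistance +
      1 / model$cochlea$compliance
  }
  D
}

#' Solve the harmonic response to the tympanic drive
#'
#' Applies the tonal drive force (pressure times effective tympanic-membrane
#' area, along the piston axis at the drive node), solves the assembled system
#' for complex displacement and returns nodal velocity `v = 1i w u`. The
#' response is linear in the drive pressure.
#'
#' @param model A `middle_ear_model`.
#' @param freq Frequency in Hz, in (0, 20000].
#' @param pressure_pa Optional drive-pressure override in Pa (default: the
#'   model's configured drive level).
#' @return Named complex vector of nodal velocities in m/s (names
#'   `"<node>.<dof>"`), with attributes `freq` and `pressure_pa`.
#' @export
#' @examples
#' model <- build_normal_model()
#' v <- harmonic_response(model, 1000)
#' abs(v["umbo.ux"])
harmonic_response <- function(model, freq, pressure_pa = NULL) {
  stopifnot(inherits(model, "middle_ear_model"))
  if (!is_scalar_number(freq) || freq <= 0 || freq > 20000) {
    abort_domain("'freq' must lie in (0, 20000] Hz")
  }
  p <- pressure_pa %||% model$drive$pressure_pa
  if (!is_scalar_number(p) || p < 0) abort_domain("'pressure_pa' must be >= 0")

  D <- assemble_dynamic_stiffness(model, freq)
  F <- stats::setNames(rep(0 + 0i, model$n_dof), model$dof_labels)
  di <- model$node_dofs[[model$drive$node]]
  if (is.null(di) || !"ux" %in% names(di)) {
    abort_topology(sprintf("drive node '%s' has no piston (ux) dof", model$drive$node))
  }
  F[di[["ux"]]] <- p * model$drive$effective_area

  u <- tryCatch(
    solve(D, F),
    error = function(e) {
      rc <- tryCatch(rcond(D), error = function(...) NA_real_)
      abort_solver(sprintf(
        "dynamic stiffness is singular at %.6g Hz (reciprocal condition estimate %.3g): %s",
        freq, rc, conditionMessage(e)))
    }
  )
  v <- 1i * 2 * pi * freq * u
  names(v) <- model$dof_labels
  attr(v, "freq") <- freq
  attr(v, "pressure_pa") <- p
  v
}

#' Stapes-footplate volume velocity
#'
#' `V_SF = (footplate piston velocity) * (footplate area)`, the model's proxy
#' for acoustic input to the cochlea.
#'
#' @param model A `middle_ear_model`.
#' @param response A nodal velocity vector from [harmonic_response()].
#' @return Complex volume velocity in m^3/s.
#' @export
footplate_volume_velocity <- function(model, response) {
  stopifnot(inherits(model, "middle_ear_model"))
  lab <- paste0(model$footplate$node, ".ux")
  if (!lab %in% names(response)) {
    abort_topology(sprintf("footplate dof '%s' is absent from the response", lab))
  }
  unname(response[lab]) * model$footplate$area
}

#' Sweep the footplate volume-velocity magnitude over frequency
#'
#' @param model A `middle_ear_model`.
#' @param freqs Frequencies in Hz, non-empty, each in (0, 20000]. The sweep is
#'   returned sorted by frequency.
#' @param pressure_pa Optional drive-pressure override in Pa.
#' @return A `data.frame` with columns `frequency_hz` and `vsf_abs` (m^3/s).
#' @export
#' @examples
#' model <- build_normal_model()
#' transmission_curve(model, audiometric_frequencies())
transmission_curve <- function(model, freqs = model$frequency_grid,
                               pressure_pa = NULL) {
  if (!is.numeric(freqs) || !length(freqs) || any(!is.finite(freqs)) ||
      any(freqs <= 0) || any(freqs > 20000)) {
    abort_domain("'freqs' must be non-empty, each in (0, 20000] Hz")
  }
  freqs <- sort(freqs)
  vsf <- vapply(freqs, function(f) {
    v <- tryCatch(
      harmonic_response(model, f, pressure_pa = pressure_pa),
      earmech_solver_error = function(e) {
        abort_solver(sprintf("transmission sweep failed at %.6g Hz: %s",
                             f, conditionMessage(e)))
      }
    )
    Mod(footplate_volume_velocity(model, v))
  }, numeric(1))
  data.frame(frequency_hz = freqs, vsf_abs = vsf)
}

probe_node <- function(model, probe = c("umbo", "footplate")) {
  probe <- match.arg(probe)
  if (probe == "umbo") model$drive$node else model$footplate$node
}

#' Locate the resonant frequency of a probe point
#'
#' Maximises the probe-point velocity magnitude per unit drive pressure over a
#' logarithmic grid, then refines the peak with golden-section search on the
#' bracketing interval (ties broken toward the lower frequency). Reproducible
#' to within 1 Hz. A maximum on the boundary of the search range (monotone
#' response, no interior peak) is flagged rather than raised as an error.
#'
#' @param model A `middle_ear_model`.
#' @param probe `"umbo"` (the drive node; mirrors what wideband tympanometry
#'   estimates clinically) or `"footplate"`.
#' @param search_range Frequency interval in Hz, inside (0, 20000].
#' @param n_grid Number of log-spaced grid points (default 512).
#' @return An object of class `ear_resonance`: list with `frequency_hz`,
#'   `velocity_per_pressure` ((m/s)/Pa at the peak), `probe`, `no_resonance`.
#' @export
#' @examples
#' model <- build_normal_model()
#' resonant_frequency(model, probe = "umbo")
resonant_frequency <- function(model, probe = c("umbo", "footplate"),
                               search_range = c(200, 4000), n_grid = 512L) {
  probe <- match.arg(probe)
  if (!is.numeric(search_range) || length(search_range) != 2L ||
      search_range[1] <= 0 || search_range[2] > 20000 ||
      search_range[1] >= search_range[2]) {
    abort_domain("'search_range' must be an increasing interval inside (0, 20000] Hz")
  }
  node <- probe_node(model, probe)
  lab <- paste0(node, ".ux")
  p <- max(model$drive$pressure_pa, PRESSURE_REF_PA)
  val <- function(f) {
    v <- harmonic_response(model, f, pressure_pa = p)
    Mod(v[[lab]]) / p
  }
  grid <- exp(seq(log(search_range[1]), log(search_range[2]), length.out = n_grid))
  vals <- vapply(grid, val, numeric(1))
  i <- which.max(vals) # first index on ties: lower frequency
  if (i == 1L || i == n_grid) {
    return(structure(list(frequency_hz = grid[i], velocity_per_pressure = vals[i],
                          probe = probe, no_resonance = TRUE),
                     class = "ear_resonance"))
  }
  # refinement tolerance: 0.25 Hz in the audio band, proportionally finer for
  # sub-Hz test oscillators
  tol_hz <- min(0.25, 1e-3 * grid[i])
  f_peak <- golden_max(val, grid[i - 1L], grid[i + 1L], tol_hz = tol_hz)
  structure(list(frequency_hz = f_peak, velocity_per_pressure = val(f_peak),
                 probe = probe, no_resonance = FALSE),
            class = "ear_resonance")
}

# Golden-section maximisation on a log-frequency interval; on ties keeps the
# left (lower-frequency) subinterval.
golden_max <- function(fun, lo, hi, tol_hz = 0.25) {
  gr <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- fun(exp(c1)); fd <- fun(exp(d1))
  while ((exp(b) - exp(a)) > tol_hz) {
    if (fc >= fd) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- fun(exp(c1))
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- fun(exp(d1))
    }
  }
  exp((a + b) / 2)
}

#' @export
print.ear_resonance <- function(x, ...) {
  if (x$no_resonance) {
    cat(sprintf("No interior resonance (%s probe): response extreme at %.1f Hz\n",
                x$probe, x$frequency_hz))
  } else {
    cat(sprintf("Resonant frequency (%s probe): %.1f Hz (peak %.4g (m/s)/Pa)\n",
                x$probe, x$frequency_hz, x$velocity_per_pressure))
  }
  invisible(x)
}
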