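# Pathology layer: every malformation manipulation is a pure function
# model -> modified model. Scalings are defined against the pristine
# (build-time) modulus/area of the targeted element, so composition never
# compounds factors, and a modified copy is always returned.

CORD_E_SCALES <- c(1e-3, 1e-4, 1e-5)
CORD_AREA_FACTORS <- c(Ver1 = 1 / 4, Ver2 = 1 / 16)
FIXATION_FACTORS <- c(x10 = 10, x100 = 100, x1000 = 1000)
FIXATION_LEVELS <- c(names(FIXATION_FACTORS), "ossified")
LIGAMENT_NAMES <- c("AML", "PIL", "SIL", "SML", "LML", "PML")

# Rewire an element onto a derived material so sibling elements sharing the
# original material are untouched.
set_element_material <- function(model, element_id, young_modulus = NULL,
                                 loss_factor = NULL, viscoelastic = NULL,
                                 tag = "mod") {
  el <- model$elements[[element_id]]
  base_mat <- model$materials[[el$material]]
  new_name <- paste0(element_id, "__", tag)
  ym <- young_modulus %||%
    (if (!is.null(viscoelastic)) viscoelastic$e_inf + sum(viscoelastic$e)
     else base_mat$young_modulus)
  model$materials[[new_name]] <- material_spec(
    name = new_name, young_modulus = ym, density = base_mat$density,
    loss_factor = loss_factor %||% base_mat$loss_factor,
    viscoelastic = viscoelastic
  )
  model$elements[[element_id]]$material <- new_name
  model$normal <- FALSE
  model
}

require_element <- function(model, id, what = "element") {
  if (!id %in% names(model$elements)) {
    abort_topology(sprintf("%s '%s' is not present in the model", what, id))
  }
  invisible(TRUE)
}

#' Replace the incudostapedial path by a soft cord
#'
#' Models partial discontinuity of the incus long process / incudostapedial
#' joint: the bony long-process element becomes a fibrous cord whose Young's
#' modulus is a small fraction of the ossicular modulus and whose
#' cross-section is 1/4 ("Ver1") or 1/16 ("Ver2") of the pristine long-process
#' section. Softer and thinner cords transmit less.
#'
#' @param model A `middle_ear_model` containing the long-process element.
#' @param e_scale Young's-modulus scale, one of `1e-3`, `1e-4`, `1e-5`
#'   (staged severities) unless `allow_custom = TRUE`.
#' @param area_version `"Ver1"` (1/4 section) or `"Ver2"` (1/16 section).
#' @param allow_custom Allow an off-enumeration `e_scale`.
#' @param element Id of the long-process element (default
#'   `"incus_long_process"`).
#' @param loss_factor Structural loss factor of the fibrous cord material.
#' @return Modified copy of the model.
#' @export
apply_cord_replacement <- function(model, e_scale,
                                   area_version = c("Ver1", "Ver2"),
                                   allow_custom = FALSE,
                                   element = "incus_long_process",
                                   loss_factor = 0.1) {
  stopifnot(inherits(model, "middle_ear_model"))
  area_version <- match.arg(area_version)
  if (!is_scalar_number(e_scale) || e_scale <= 0) {
    abort_domain("'e_scale' must be a positive number")
  }
  if (!allow_custom && !any(abs(log10(e_scale) - log10(CORD_E_SCALES)) < 1e-9)) {
    abort_config(sprintf(
      "'e_scale' %g is outside the staged severities {1e-3, 1e-4, 1e-5}; set allow_custom = TRUE to override",
      e_scale))
  }
  require_element(model, element, "incudostapedial path element")
  base <- model$bases[[element]]
  model <- set_element_material(model, element,
                                young_modulus = base$young_modulus * e_scale,
                                loss_factor = loss_factor, tag = "cord")
  model$elements[[element]]$area <- base$area * CORD_AREA_FACTORS[[area_version]]
  model
}

#' Scale or ossify the stapedial annular ligament
#'
#' Stiffening the SAL models otosclerotic fixation of the stapes footplate;
#' `factor = "ossified"` replaces the ligament modulus by the ossicular bone
#' modulus (1.2e10 Pa).
#'
#' @param model A `middle_ear_model` with a SAL element.
#' @param factor Positive multiplier of the normal SAL Young's modulus, or
#'   `"ossified"`.
#' @param element Id of the SAL element.
#' @return Modified copy of the model.
#' @export
apply_sal_modification <- function(model, factor, element = "SAL") {
  stopifnot(inherits(model, "middle_ear_model"))
  require_element(model, element, "SAL element")
  base <- model$bases[[element]]
  if (identical(factor, "ossified")) {
    return(set_element_material(model, element,
                                young_modulus = OSSICLE_YOUNG_MODULUS,
                                loss_factor = 0.01, tag = "ossified"))
  }
  if (!is_scalar_number(factor) || factor <= 0) {
    abort_domain("'factor' must be a positive number or \"ossified\"")
  }
  set_element_material(model, element,
                       young_modulus = base$young_modulus * factor,
                       tag = "scaled")
}

#' Fix or ossify a suspensory ligament
#'
#' Models adhesion of the malleus head or incus body to the attic wall by
#' stiffening one of the six suspensory ligaments: 10x (mild), 100x, 1000x
#' (severe) the normal modulus, or full ossification at the ossicular bone
#' modulus (1.2e10 Pa).
#'
#' @param model A `middle_ear_model`.
#' @param ligament One of `"AML"`, `"PIL"`, `"SIL"`, `"SML"`, `"LML"`, `"PML"`.
#' @param level One of `"x10"`, `"x100"`, `"x1000"`, `"ossified"`.
#' @return Modified copy of the model.
#' @export
apply_ligament_fixation <- function(model, ligament, level) {
  stopifnot(inherits(model, "middle_ear_model"))
  if (!is_scalar_string(ligament) || !ligament %in% LIGAMENT_NAMES) {
    abort_config(sprintf("unknown ligament '%s'; valid names: %s",
                         as.character(ligament)[1],
                         paste(LIGAMENT_NAMES, collapse = ", ")))
  }
  if (!is_scalar_string(level) || !level %in% FIXATION_LEVELS) {
    abort_config(sprintf("unknown fixation level '%s'; valid levels: %s",
                         as.character(level)[1],
                         paste(FIXATION_LEVELS, collapse = ", ")))
  }
  require_element(model, ligament, "ligament")
  base <- model$bases[[ligament]]
  if (level == "ossified") {
    set_element_material(model, ligament, young_modulus = OSSICLE_YOUNG_MODULUS,
                         loss_factor = 0.01, tag = "ossified")
  } else {
    set_element_material(model, ligament,
                         young_modulus = base$young_modulus * FIXATION_FACTORS[[level]],
                         tag = level)
  }
}

#' Replace the stapes superstructure by a monopodal crus
#'
#' Removes the anterior crus and replaces the posterior-crus material either by
#' a plain elastic modulus or by a generalized Maxwell viscoelastic
#' specification (the storage/loss moduli then enter the assembly at each
#' frequency through [maxwell_complex_modulus()]). Applying the operation to a
#' model whose anterior crus is already absent emits an idempotency warning,
#' not an error.
#'
#' @param model A `middle_ear_model` with both crura.
#' @param crus_spec A positive Young's modulus in Pa, or a
#'   [viscoelastic_spec()].
#' @param anterior,posterior Element ids of the two crura.
#' @return Modified copy of the model.
#' @export
apply_monopod_stapes <- function(model, crus_spec,
                                 anterior = "anterior_crus",
                                 posterior = "posterior_crus") {
  stopifnot(inherits(model, "middle_ear_model"))
  require_element(model, posterior, "posterior crus")
  if (anterior %in% names(model$elements)) {
    model <- remove_element(model, anterior)
  } else {
    warn_earmech(sprintf("anterior crus '%s' already absent; monopod replacement is idempotent",
                         anterior),
                 "earmech_idempotency_warning")
  }
  if (inherits(crus_spec, "ear_viscoelastic")) {
    set_element_material(model, posterior, viscoelastic = crus_spec,
                         tag = "monopod")
  } else if (is_scalar_number(crus_spec) && crus_spec > 0) {
    set_element_material(model, posterior, young_modulus = crus_spec,
                         loss_factor = 0.01, tag = "monopod")
  } else {
    abort_config("'crus_spec' must be a positive modulus or a viscoelastic_spec()")
  }
}

#' Remove an element from the model
#'
#' @param model A `middle_ear_model`.
#' @param element Id of the element to drop. Removal that disconnects the
#'   drive from the footplate raises a topology error.
#' @return Modified copy of the model.
#' @export
remove_element <- function(model, element) {
  stopifnot(inherits(model, "middle_ear_model"))
  require_element(model, element)
  model$elements[[element]] <- NULL
  model$directions[[element]] <- NULL
  model$bases[[element]] <- NULL
  model$normal <- FALSE
  check_connectivity(model)
  model
}

#' Construct a single model modification
#'
#' @param variant One of `"cord_replacement"`, `"sal_scale"`,
#'   `"ligament_fixation"`, `"monopod_stapes"`, `"remove_element"`.
#' @param ... Parameters forwarded to the corresponding `apply_*` function
#'   (e.g. `e_scale`, `area_version` for a cord replacement).
#' @return An object of class `ear_modification`.
#' @export
#' @examples
#' modification("sal_scale", factor = 10)
modification <- function(variant, ...) {
  variant <- match.arg(variant, c("cord_replacement", "sal_scale",
                                  "ligament_fixation", "monopod_stapes",
                                  "remove_element"))
  params <- list(...)
  structure(list(variant = variant, params = params), class = "ear_modification")
}

apply_modification <- function(model, mod) {
  stopifnot(inherits(mod, "ear_modification"))
  fn <- switch(mod$variant,
    cord_replacement = apply_cord_replacement,
    sal_scale = apply_sal_modification,
    ligament_fixation = apply_ligament_fixation,
    monopod_stapes = apply_monopod_stapes,
    remove_element = remove_element
  )
  do.call(fn, c(list(model), mod$params))
}

#' Construct a named pathology scenario
#'
#' @param name Scenario identifier.
#' @param modifications List of [modification()] objects, applied in order
#'   (structural removal/replacement before material scalings).
#' @param provenance Free-text clinical description of what the scenario
#'   represents.
#' @return An object of class `ear_scenario`.
#' @export
pathology_scenario <- function(name, modifications, provenance = "") {
  if (!is_scalar_string(name)) abort_config("scenario 'name' must be a non-empty string")
  if (inherits(modifications, "ear_modification")) modifications <- list(modifications)
  if (!is.list(modifications) ||
      !all(vapply(modifications, inherits, TRUE, "ear_modification"))) {
    abort_config("'modifications' must be a list of modification() objects")
  }
  structure(list(name = name, modifications = modifications,
                 provenance = provenance),
            class = "ear_scenario")
}

#' Apply a pathology scenario to a model
#'
#' Applies the scenario's modifications in order, with structural variants
#' (`monopod_stapes`, `remove_element`) applied before material scalings so
#' that composition is deterministic. The input model is never mutated.
#'
#' @param model A `middle_ear_model`.
#' @param scenario An [pathology_scenario()].
#' @return Modified copy of the model.
#' @export
#' @examples
#' model <- build_normal_model()
#' sc <- scenario_catalog()[["patient2"]]
#' diseased <- compose_scenario(model, sc)
compose_scenario <- function(model, scenario) {
  stopifnot(inherits(model, "middle_ear_model"), inherits(scenario, "ear_scenario"))
  mods <- scenario$modifications
  structural <- vapply(mods, function(m) {
    m$variant %in% c("monopod_stapes", "remove_element")
  }, logical(1))
  ord <- order(!structural) # stable: structural first, original order otherwise
  out <- model
  for (i in ord) {
    out <- tryCatch(
      apply_modification(out, mods[[i]]),
      earmech_error = function(e) {
        abort_earmech(sprintf("scenario '%s': modification %d (%s) failed: %s",
                              scenario$name, i, mods[[i]]$variant,
                              conditionMessage(e)),
                      class(e)[1])
      }
    )
  }
  out$meta$scenario <- scenario$name
  out
}

#' Default viscoelastic crus specification
#'
#' Generalized Maxwell parameters of the fibrous monopodal crus used by the
#' `patient3` scenario. The parameters are package defaults (storage modulus
#' rising through the audio band, loss modulus peaking near 2 kHz), exposed so
#' they can be varied; they are not asserted physiological constants.
#'
#' @param e_inf Equilibrium modulus in Pa.
#' @param e Maxwell-arm moduli in Pa.
#' @param tau Relaxation times in s.
#' @return A [viscoelastic_spec()].
#' @export
default_crus_viscoelastic <- function(e_inf = 6.5e5, e = 6.5e6, tau = 8e-5) {
  viscoelastic_spec(e_inf = e_inf, e = e, tau = tau)
}

#' Catalog of shipped pathology scenarios
#'
#' Six per-case scenarios matching the shipped clinical table plus the
#' single-ligament ossification sweep. Every entry composes without error on
#' the shipped normal model.
#'
#' @return Named list of [pathology_scenario()] objects.
#' @export
#' @examples
#' names(scenario_catalog())
scenario_catalog <- function() {
  sc <- list(
    pathology_scenario(
      "patient1",
      list(modification("cord_replacement", e_scale = 1e-4, area_version = "Ver2"),
           modification("sal_scale", factor = 8)),
      provenance = "case 1: incomplete incudostapedial discontinuity (thin soft cord) with mild stapes fixation"
    ),
    pathology_scenario(
      "patient2",
      list(modification("cord_replacement", e_scale = 1e-5, area_version = "Ver1")),
      provenance = "case 2: incomplete loss of the incus long process (thicker, very soft cord)"
    ),
    pathology_scenario(
      "patient3",
      list(modification("monopod_stapes", crus_spec = default_crus_viscoelastic())),
      provenance = "case 3: monopodal stapes, posterior crus replaced by a viscoelastic fibrous cord"
    ),
    pathology_scenario(
      "patient4",
      list(modification("monopod_stapes", crus_spec = OSSICLE_YOUNG_MODULUS),
           modification("sal_scale", factor = "ossified")),
      provenance = "case 4: monopodal stapes with rigid crus and ossified annular ligament"
    ),
    pathology_scenario(
      "patient5",
      list(modification("ligament_fixation", ligament = "AML", level = "ossified"),
           modification("ligament_fixation", ligament = "SML", level = "ossified"),
           modification("sal_scale", factor = 10)),
      provenance = "case 5 (illustrative): malleus-head adhesion (AML+SML ossified) with mild stapes fixation"
    ),
    pathology_scenario(
      "patient6",
      lapply(c("AML", "LML", "SML", "PML", "SIL", "PIL"), function(lig) {
        modification("ligament_fixation", ligament = lig, level = "ossified")
      }),
      provenance = "case 6: adhesion of malleus and incus (all six suspensory ligaments ossified, SAL untouched)"
    )
  )
  sweep <- lapply(LIGAMENT_NAMES, function(lig) {
    pathology_scenario(
      paste0("ossify_", lig),
      list(modification("ligament_fixation", ligament = lig, level = "ossified")),
      provenance = sprintf("single-ligament ossification sweep: %s", lig)
    )
  })
  sc <- c(sc, sweep)
  stats::setNames(sc, vapply(sc, `[[`, "", "name"))
}

#' @export
print.ear_scenario <- function(x, ...) {
  cat(sprintf("Pathology scenario '%s' (%d modification%s)\n", x$name,
              length(x$modifications),
              if (length(x$modifications) == 1L) "" else "s"))
  for (m in x$modifications) {
    ps <- paste(names(m$params),
                vapply(m$params, function(p) {
                  if (inherits(p, "ear_viscoelastic")) "<viscoelastic>" else format(p)
                }, ""),
                sep = "=", collapse = ", ")
    cat(sprintf("  - %s(%s)\n", m$variant, ps))
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
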