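DOF_AXES <- c(ux = 1L, uy = 2L, uz = 3L)

#' Define a network node
#'
#' @param id Node identifier, unique within a model.
#' @param position 3-vector position in m. Positions fix element orientations
#'   only; elastic lengths are element properties.
#' @param dofs Active translational degrees of freedom, a subset of
#'   `c("ux", "uy", "uz")`. A node with no active dofs is fixed (grounded).
#' @return An object of class `ear_node`.
#' @export
node_spec <- function(id, position = c(0, 0, 0), dofs = "ux") {
  if (!is_scalar_string(id)) abort_config("node 'id' must be a non-empty string")
  if (!is.numeric(position) || length(position) != 3L || any(!is.finite(position))) {
    abort_config(sprintf("node '%s': 'position' must be a finite 3-vector", id))
  }
  dofs <- as.character(dofs)
  if (length(dofs) && (anyDuplicated(dofs) || !all(dofs %in% names(DOF_AXES)))) {
    abort_config(sprintf("node '%s': 'dofs' must be distinct values among ux, uy, uz", id))
  }
  structure(list(id = id, position = as.numeric(position), dofs = dofs),
            class = "ear_node")
}

#' Define an elastic element
#'
#' An element connects two nodes along the line between their positions and
#' contributes an axial stiffness `E(f) * A / L`. `kind = "shear"` uses the
#' shear modulus `E / (2 (1 + nu))` with `nu = 0.3`; `kind = "rotational"` is
#' an effective linearised rotational restraint assembled with the axial
#' formula.
#'
#' @param id Element identifier.
#' @param node_a,node_b Ids of the connected nodes (must differ).
#' @param material Name of a [material_spec()] in the model.
#' @param area Cross-sectional area in m^2 (> 0).
#' @param length Elastic length in m (> 0).
#' @param kind One of `"axial"`, `"shear"`, `"rotational"`.
#' @return An object of class `ear_element`.
#' @export
elastic_element <- function(id, node_a, node_b, material, area, length,
                            kind = c("axial", "shear", "rotational")) {
  kind <- match.arg(kind)
  if (!is_scalar_string(id)) abort_config("element 'id' must be a non-empty string")
  if (!is_scalar_string(node_a) || !is_scalar_string(node_b)) {
    abort_config(sprintf("element '%s': node ids must be non-empty strings", id))
  }
  if (identical(node_a, node_b)) {
    abort_config(sprintf("element '%s': 'node_a' and 'node_b' must differ", id))
  }
  if (!is_scalar_string(material)) {
    abort_config(sprintf("element '%s': 'material' must name a material", id))
  }
  if (!is_scalar_number(area) || area <= 0) {
    abort_config(sprintf("element '%s': 'area' must be > 0", id))
  }
  if (!is_scalar_number(length) || length <= 0) {
    abort_config(sprintf("element '%s': 'length' must be > 0", id))
  }
  structure(list(id = id, kind = kind, node_a = node_a, node_b = node_b,
                 material = material, area = area, length = length),
            class = "ear_element")
}

#' Define a rigid inertia
#'
#' Lumped mass of an ossicle (or the effective moving mass of the tympanic
#' membrane), divided equally over its attachment nodes.
#'
#' @param body One of `"malleus"`, `"incus"`, `"stapes"`,
#'   `"tympanic_membrane_effective"`.
#' @param mass Mass in kg (> 0).
#' @param nodes Node ids carrying the mass.
#' @return An object of class `ear_inertia`.
#' @export
rigid_inertia <- function(body, mass, nodes) {
  body <- match.arg(body, c("malleus", "incus", "stapes",
                            "tympanic_membrane_effective"))
  if (!is_scalar_number(mass) || mass <= 0) {
    abort_config(sprintf("inertia '%s': 'mass' must be > 0", body))
  }
  nodes <- as.character(nodes)
  if (!length(nodes) || anyDuplicated(nodes)) {
    abort_config(sprintf("inertia '%s': 'nodes' must be distinct node ids", body))
  }
  structure(list(body = body, mass = mass, nodes = nodes), class = "ear_inertia")
}

#' Construct a middle-ear network model
#'
#' Low-level constructor; most users build the shipped configuration with
#' [build_normal_model()]. Validates the network (unique ids, positive
#' parameters, connectivity from the drive node to the footplate through
#' mobile nodes) and precomputes the degree-of-freedom table used by
#' [assemble_dynamic_stiffness()].
#'
#' @param materials List of [material_spec()].
#' @param nodes List of [node_spec()].
#' @param elements List of [elastic_element()].
#' @param inertias List of [rigid_inertia()].
#' @param drive List with `node` (id), `effective_area` (m^2, > 0) and either
#'   `pressure_pa` (Pa, >= 0) or `pressure_db_spl` (dB SPL).
#' @param footplate List with `node` (id) and `area` (m^2, > 0): the stapes
#'   footplate whose volume velocity is the model output.
#' @param cochlea List with `resistance` (N s/m, > 0), `compliance` (m/N, > 0)
#'   and optionally `node` (default: the footplate node).
#' @param frequency_grid Audiometric output grid in Hz, ascending within
#'   125-8000 Hz.
#' @param meta Free-form metadata list.
#' @param normal Logical flag: is this the unmodified normal-ear model?
#' @return An object of class `middle_ear_model`.
#' @export
middle_ear_model <- function(materials, nodes, elements, inertias, drive,
                             footplate, cochlea,
                             frequency_grid = audiometric_frequencies(),
                             meta = list(), normal = TRUE) {
  stopifnot(is.list(materials), is.list(nodes), is.list(elements), is.list(inertias))
  if (!all(vapply(materials, inherits, TRUE, "ear_material"))) {
    abort_config("'materials' must all be material_spec() objects")
  }
  if (!all(vapply(nodes, inherits, TRUE, "ear_node"))) {
    abort_config("'nodes' must all be node_spec() objects")
  }
  if (!all(vapply(elements, inherits, TRUE, "ear_element"))) {
    abort_config("'elements' must all be elastic_element() objects")
  }
  if (!all(vapply(inertias, inherits, TRUE, "ear_inertia"))) {
    abort_config("'inertias' must all be rigid_inertia() objects")
  }

  names(materials) <- vapply(materials, `[[`, "", "name")
  if (anyDuplicated(names(materials))) abort_config("duplicated material names")
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  if (anyDuplicated(names(nodes))) abort_config("duplicated node ids")
  names(elements) <- vapply(elements, `[[`, "", "id")
  if (anyDuplicated(names(elements))) abort_config("duplicated element ids")

  bodies <- vapply(inertias, `[[`, "", "body")
  if (anyDuplicated(bodies)) abort_config("each inertia body may appear at most once")

  for (el in elements) {
    for (nid in c(el$node_a, el$node_b)) {
      if (!nid %in% names(nodes)) {
        abort_config(sprintf("element '%s' references unknown node '%s'", el$id, nid))
      }
    }
    if (!el$material %in% names(materials)) {
      abort_config(sprintf("element '%s' references unknown material '%s'",
                           el$id, el$material))
    }
    dist <- sqrt(sum((nodes[[el$node_b]]$position - nodes[[el$node_a]]$position)^2))
    if (dist <= 0) {
      abort_config(sprintf("element '%s': its nodes share a position, orientation undefined", el$id))
    }
  }
  for (inr in inertias) {
    bad <- setdiff(inr$nodes, names(nodes))
    if (length(bad)) {
      abort_config(sprintf("inertia '%s' references unknown node(s): %s",
                           inr$body, paste(bad, collapse = ", ")))
    }
  }

  drive <- validate_drive(drive, nodes)
  footplate <- validate_footplate(footplate, nodes)
  cochlea <- validate_cochlea(cochlea, nodes, footplate)

  if (!is.numeric(frequency_grid) || !length(frequency_grid) ||
      any(!is.finite(frequency_grid)) || is.unsorted(frequency_grid, strictly = TRUE) ||
      any(frequency_grid < 125) || any(frequency_grid > 8000)) {
    abort_config("'frequency_grid' must be strictly increasing within [125, 8000] Hz")
  }

  model <- structure(
    list(materials = materials, nodes = nodes, elements = elements,
         inertias = inertias, drive = drive, footplate = footplate,
         cochlea = cochlea, frequency_grid = as.numeric(frequency_grid),
         meta = meta, normal = isTRUE(normal)),
    class = "middle_ear_model"
  )
  model <- index_model(model)
  check_connectivity(model)

  # Pristine per-element moduli/areas: pathology scalings are defined relative
  # to these, so composed modifications never compound on one another.
  model$bases <- lapply(model$elements, function(el) {
    list(young_modulus = materials[[el$material]]$young_modulus, area = el$area)
  })
  model
}

# Build dof bookkeeping: global index per (node, axis).
index_model <- function(model) {
  node_dofs <- list()
  idx <- 0L
  labels <- character(0)
  for (nd in model$nodes) {
    if (!length(nd$dofs)) next
    ii <- seq_along(nd$dofs) + idx
    names(ii) <- nd$dofs
    node_dofs[[nd$id]] <- ii
    labels <- c(labels, paste(nd$id, nd$dofs, sep = "."))
    idx <- idx + length(nd$dofs)
  }
  model$node_dofs <- node_dofs
  model$dof_labels <- labels
  model$n_dof <- idx

  model$directions <- lapply(model$elements, function(el) {
    d <- model$nodes[[el$node_b]]$position - model$nodes[[el$node_a]]$position
    d / sqrt(sum(d^2))
  })

  mass <- stats::setNames(numeric(length(model$nodes)), names(model$nodes))
  for (inr in model$inertias) {
    mass[inr$nodes] <- mass[inr$nodes] + inr$mass / length(inr$nodes)
  }
  model$node_mass <- mass
  model
}

# The drive must reach the footplate through mobile (non-grounded) nodes.
check_connectivity <- function(model) {
  mobile <- names(model$node_dofs)
  if (!model$drive$node %in% mobile) {
    abort_topology(sprintf("drive node '%s' has no active dofs", model$drive$node))
  }
  adj <- lapply(stats::setNames(nm = mobile), function(x) character(0))
  for (el in model$elements) {
    a <- el$node_a; b <- el$node_b
    if (a %in% mobile && b %in% mobile) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- model$drive$node
  queue <- seen
  while (length(queue)) {
    nxt <- setdiff(unique(unlist(adj[queue])), seen)
    seen <- c(seen, nxt)
    queue <- nxt
  }
  if (!model$footplate$node %in% seen) {
    abort_topology(sprintf(
      "network is disconnected: no elastic path from drive node '%s' to footplate node '%s'; unreachable node(s): %s",
      model$drive$node, model$footplate$node,
      paste(setdiff(mobile, seen), collapse = ", ")))
  }
  invisible(model)
}

validate_drive <- function(drive, nodes) {
  if (!is.list(drive) || !is_scalar_string(drive$node %||% NULL)) {
    abort_config("'drive' must be a list with a 'node' id")
  }
  if (!drive$node %in% names(nodes)) {
    abort_config(sprintf("drive node '%s' is not a model node", drive$node))
  }
  if (!is_scalar_number(drive$effective_area %||% NA) || drive$effective_area <= 0) {
    abort_config("drive 'effective_area' must be > 0")
  }
  if (is.null(drive$pressure_pa)) {
    if (is.null(drive$pressure_db_spl)) {
      abort_config("drive needs 'pressure_pa' or 'pressure_db_spl'")
    }
    drive$pressure_pa <- spl_to_pressure(drive$pressure_db_spl)
  }
  if (!is_scalar_number(drive$pressure_pa) || drive$pressure_pa < 0) {
    abort_config("drive 'pressure_pa' must be >= 0")
  }
  drive[c("node", "effective_area", "pressure_pa", "pressure_db_spl")[
    c(TRUE, TRUE, TRUE, !is.null(drive$pressure_db_spl))]]
}

validate_footplate <- function(footplate, nodes) {
  if (!is.list(footplate) || !is_scalar_string(footplate$node %||% NULL)) {
    abort_config("'footplate' must be a list with a 'node' id")
  }
  if (!footplate$node %in% names(nodes)) {
    abort_config(sprintf("footplate node '%s' is not a model node", footplate$node))
  }
  if (!is_scalar_number(footplate$area %||% NA) || footplate$area <= 0) {
    abort_config("footplate 'area' must be > 0")
  }
  footplate[c("node", "area")]
}

validate_cochlea <- function(cochlea, nodes, footplate) {
  if (!is.list(cochlea)) abort_config("'cochlea' must be a list")
  cochlea$node <- cochlea$node %||% footplate$node
  if (!cochlea$node %in% names(nodes)) {
    abort_config(sprintf("cochlea node '%s' is not a model node", cochlea$node))
  }
  if (!is_scalar_number(cochlea$resistance %||% NA) || cochlea$resistance <= 0) {
    abort_config("cochlea 'resistance' must be > 0")
  }
  if (!is_scalar_number(cochlea$compliance %||% NA) || cochlea$compliance <= 0) {
    abort_config("cochlea 'compliance' must be > 0")
  }
  cochlea[c("node", "resistance", "compliance")]
}

# The eleven anatomical components every normal-ear configuration must carry.
NORMAL_COMPONENTS <- c("AML", "PIL", "SIL", "SML", "LML", "PML", "SAL",
                       "tensor_tympani", "stapedial_tendon",
                       "incudomalleolar_joint", "incudostapedial_joint")

#' Build the normal middle-ear model from a configuration
#'
#' Reads (or accepts) a structured configuration, validates it against the
#' model schema, checks that all eleven anatomical components (six suspensory
#' ligaments, the stapedial annular ligament, two tendons, two ossicular
#' joints) are present unless explicitly disabled, and returns the assembled
#' network. With no argument the shipped calibrated configuration is used.
#'
#' @param config Path to a YAML configuration, or an already-parsed
#'   configuration list (see [read_model_config()]). `config$disabled` may
#'   name components deliberately left out; the model is then flagged
#'   non-normal.
#' @return A `middle_ear_model`.
#' @export
#' @examples
#' model <- build_normal_model()
#' model$materials[["aml_ligament"]]$young_modulus # 2.1e7 Pa
build_normal_model <- function(config = default_config_path()) {
  if (is.character(config)) config <- read_model_config(config)
  validate_model_config(config)

  materials <- lapply(config$materials, function(m) {
    ve <- NULL
    if (!is.null(m$viscoelastic)) {
      ve <- viscoelastic_spec(m$viscoelastic$e_inf,
                              as.numeric(unlist(m$viscoelastic$e)),
                              as.numeric(unlist(m$viscoelastic$tau)))
    }
    material_spec(m$name, m$young_modulus, m$density, m$loss_factor %||% 0, ve)
  })
  nodes <- lapply(config$nodes, function(n) {
    node_spec(n$id, as.numeric(unlist(n$position)),
              as.character(unlist(n$dofs)))
  })
  elements <- lapply(config$elements, function(e) {
    elastic_element(e$id, e$node_a, e$node_b, e$material, e$area, e$length,
                    e$kind %||% "axial")
  })
  inertias <- lapply(config$inertias, function(i) {
    rigid_inertia(i$body, i$mass, as.character(unlist(i$nodes)))
  })

  disabled <- as.character(unlist(config$disabled %||% character(0)))
  elements <- elements[!vapply(elements, function(e) e$id %in% disabled, TRUE)]
  present <- vapply(elements, `[[`, "", "id")
  missing <- setdiff(setdiff(NORMAL_COMPONENTS, disabled), present)
  if (length(missing)) {
    abort_config(sprintf("normal-ear configuration is missing component(s): %s",
                         paste(missing, collapse = ", ")))
  }

  middle_ear_model(
    materials = materials, nodes = nodes, elements = elements,
    inertias = inertias, drive = config$drive, footplate = config$footplate,
    cochlea = config$cochlea,
    frequency_grid = as.numeric(unlist(config$frequency_grid %||% audiometric_frequencies())),
    meta = config$meta %||% list(),
    normal = !length(disabled)
  )
}

#' @export
print.middle_ear_model <- function(x, ...) {
  cat("Middle-ear network model",
      if (isTRUE(x$normal)) "(normal)" else "(modified)", "\n")
  cat(sprintf("  nodes: %d (%d active dofs), elements: %d, inertias: %d\n",
              length(x$nodes), x$n_dof, length(x$elements), length(x$inertias)))
  cat(sprintf("  drive: %.1f Pa on %s (area %.3g m^2); footplate: %s (area %.3g m^2)\n",
              x$drive$pressure_pa, x$drive$node, x$drive$effective_area,
              x$footplate$node, x$footplate$area))
  invisible(x)
}
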