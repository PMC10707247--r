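# Fixture models built in code.

# Single-dof oscillator expressed as a middle-ear network: one mobile node on
# a spring to the wall, the cochlear load reused as the viscous damper
# (compliance huge so it adds negligible stiffness), unit drive area so the
# applied force equals the drive pressure.
sdof_model <- function(k = 1, m = 1, c = 0, pressure_pa = 1) {
  c <- max(c, 1e-15) # the cochlear resistance must be positive
  middle_ear_model(
    materials = list(material_spec("spring", young_modulus = k, density = 1000)),
    nodes = list(node_spec("mass", c(0, 0, 0), "ux"),
                 node_spec("wall", c(1, 0, 0), character(0))),
    elements = list(elastic_element("spring", "mass", "wall", "spring",
                                    area = 1, length = 1)),
    inertias = list(rigid_inertia("stapes", mass = m, nodes = "mass")),
    drive = list(node = "mass", effective_area = 1, pressure_pa = pressure_pa),
    footplate = list(node = "mass", area = 1),
    cochlea = list(resistance = c, compliance = 1e12),
    normal = FALSE
  )
}

# Two free nodes joined by one unit element: the textbook 2x2 spring matrix.
free_spring_model <- function(E = 1, area = 1, len = 1, loss = 0) {
  middle_ear_model(
    materials = list(material_spec("unit", young_modulus = E, density = 1000,
                                   loss_factor = loss)),
    nodes = list(node_spec("a", c(0, 0, 0), "ux"),
                 node_spec("b", c(1, 0, 0), "ux")),
    elements = list(elastic_element("el", "a", "b", "unit", area = area,
                                    length = len)),
    inertias = list(rigid_inertia("stapes", mass = 1e-20, nodes = "a")),
    drive = list(node = "a", effective_area = 1, pressure_pa = 1),
    footplate = list(node = "b", area = 1),
    cochlea = list(node = "b", resistance = 1e-15, compliance = 1e15),
    normal = FALSE
  )
}

# The shipped calibrated model and its normal transmission curve, computed
# once per test run.
normal_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_normal_model()
    cache
  }
})

normal_curve <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- transmission_curve(normal_model())
    cache
  }
})

loss_for <- function(diseased, freqs = audiometric_frequencies()) {
  vsf_ratio_db(normal_curve(), transmission_curve(diseased, freqs))
}

mean_loss_below <- function(loss_db, freqs, f_hi) {
  mean(loss_db[freqs <= f_hi])
}
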