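test_that("spl_to_pressure follows the 20 uPa reference", {
  expect_equal(spl_to_pressure(0), 2e-5)
  expect_equal(spl_to_pressure(80), 0.2)
  expect_equal(spl_to_pressure(94), 20e-6 * 10^(94 / 20), tolerance = 1e-12)
  expect_error(spl_to_pressure(NaN), class = "earmech_domain_error")
})

test_that("Maxwell complex modulus matches its limits and the arm-by-arm oracle", {
  sp <- viscoelastic_spec(e_inf = 1e5, e = 2e5, tau = 1e-3)
  expect_equal(maxwell_complex_modulus(sp, 0), complex(real = 1e5, imaginary = 0))

  # single arm at w*tau = 1: storage e_inf + e/2, loss e/2
  f1 <- 1 / (2 * pi * 1e-3)
  expect_equal(maxwell_complex_modulus(sp, f1),
               complex(real = 1e5 + 1e5, imaginary = 1e5), tolerance = 1e-12)

  # high-frequency limit of a single arm: e_inf + e, vanishing loss
  hi <- maxwell_complex_modulus(sp, 1e9)
  expect_equal(Re(hi), 3e5, tolerance = 1e-6)
  expect_lt(Im(hi) / Re(hi), 1e-5)

  # multi-arm spec against the independent oracle over a log sweep
  sp2 <- viscoelastic_spec(e_inf = 6.5e5, e = c(2e6, 6.5e6), tau = c(5e-3, 8e-5))
  freqs <- 10^seq(0, 5, length.out = 40)
  expect_equal(maxwell_complex_modulus(sp2, freqs),
               maxwell_oracle(6.5e5, c(2e6, 6.5e6), c(5e-3, 8e-5), freqs),
               tolerance = 1e-12)

  expect_error(maxwell_complex_modulus(sp, -1), class = "earmech_domain_error")
})

test_that("Maxwell storage modulus is non-decreasing in frequency", {
  set.seed(42)
  freqs <- sort(c(0, 10^seq(-1, 5, length.out = 60)))
  for (rep in 1:20) {
    sp <- viscoelastic_spec(e_inf = runif(1, 0, 1e6),
                            e = runif(3, 1e4, 1e7),
                            tau = 10^runif(3, -6, -1))
    storage <- Re(maxwell_complex_modulus(sp, freqs))
    expect_true(all(diff(storage) >= -1e-9 * max(storage)))
  }
})

test_that("a single free spring assembles to the textbook 2x2 stiffness matrix", {
  D <- assemble_dynamic_stiffness(free_spring_model(), 137)
  expect_equal(unname(D), matrix(c(1, -1, -1, 1), 2) + 0i, tolerance = 1e-12)
})

test_that("the assembled dynamic stiffness is complex symmetric at every frequency", {
  model <- normal_model()
  for (f in c(125, 500, 1000, 3000, 8000)) {
    D <- assemble_dynamic_stiffness(model, f)
    expect_identical(D, t(D))
  }
})

test_that("a 1-dof oscillator has zero dynamic stiffness at sqrt(k/m)/2pi", {
  model <- sdof_model(k = 1, m = 1, c = 0)
  D <- assemble_dynamic_stiffness(model, 1 / (2 * pi))
  # cochlear placeholder adds only 1e-12 stiffness
  expect_lt(Mod(D[1, 1]), 1e-10)
})

test_that("harmonic response reproduces the closed-form single oscillator", {
  k <- 2500; m <- 5e-5; c <- 0.3
  model <- sdof_model(k = k, m = m, c = c, pressure_pa = 0.2)
  for (f in audiometric_frequencies()) {
    v <- harmonic_response(model, f)
    expect_equal(v[["mass.ux"]],
                 sdof_velocity(k + 1e-12, m, c, force = 0.2, freq = f),
                 tolerance = 1e-10)
  }
})

test_that("response is linear in drive pressure", {
  model <- normal_model()
  v1 <- harmonic_response(model, 1000, pressure_pa = 0.2)
  v2 <- harmonic_response(model, 1000, pressure_pa = 0.4)
  expect_equal(as.complex(2 * v1), as.complex(v2), tolerance = 1e-12)
})

test_that("the solver agrees with brute-force Gaussian elimination", {
  model <- normal_model()
  for (f in c(125, 986, 4000)) {
    D <- assemble_dynamic_stiffness(model, f)
    F <- rep(0 + 0i, nrow(D))
    F[which(rownames(D) == "umbo.ux")] <- model$drive$pressure_pa * model$drive$effective_area
    u_oracle <- dense_gauss_solve(D, F)
    v <- harmonic_response(model, f)
    expect_equal(as.complex(v), 1i * 2 * pi * f * u_oracle, tolerance = 1e-8)
  }
})

test_that("footplate volume velocity is velocity times area", {
  model <- normal_model()
  resp <- stats::setNames(rep(0 + 0i, model$n_dof), model$dof_labels)
  resp["footplate.ux"] <- 1e-3 + 0i
  expect_equal(footplate_volume_velocity(model, resp), 3.2e-9 + 0i)
  resp[] <- 0
  expect_equal(footplate_volume_velocity(model, resp), 0 + 0i)
  names(resp) <- paste0("x", seq_along(resp))
  expect_error(footplate_volume_velocity(model, resp),
               class = "earmech_topology_error")
})

test_that("transmission_curve sweeps, sorts and matches the single solve", {
  model <- normal_model()
  tc <- transmission_curve(model, audiometric_frequencies())
  expect_equal(nrow(tc), 7L)
  expect_equal(tc$frequency_hz, audiometric_frequencies())

  one <- transmission_curve(model, 1000)
  v <- harmonic_response(model, 1000)
  expect_equal(one$vsf_abs, Mod(footplate_volume_velocity(model, v)))

  shuffled <- transmission_curve(model, rev(audiometric_frequencies()))
  expect_equal(shuffled, tc)
  expect_error(transmission_curve(model, numeric(0)), class = "earmech_domain_error")
  expect_error(transmission_curve(model, c(1000, 25000)), class = "earmech_domain_error")
})

test_that("resonant_frequency recovers the analytic oscillator peak", {
  model <- sdof_model(k = 1, m = 1, c = 0.02)
  r <- resonant_frequency(model, probe = "footplate", search_range = c(0.05, 1))
  expect_false(r$no_resonance)
  expect_equal(r$frequency_hz, sdof_resonance_hz(1, 1), tolerance = 2e-3)

  # stiffness x4 doubles the resonance (within the damping correction)
  r4 <- resonant_frequency(sdof_model(k = 4, m = 1, c = 0.02),
                           probe = "footplate", search_range = c(0.05, 1))
  expect_equal(r4$frequency_hz / r$frequency_hz, 2, tolerance = 5e-3)
})

test_that("resonance search is reproducible and flags boundary maxima", {
  model <- normal_model()
  r1 <- resonant_frequency(model, probe = "umbo")
  r2 <- resonant_frequency(model, probe = "umbo")
  expect_lt(abs(r1$frequency_hz - r2$frequency_hz), 1)

  # peak far below the window: response is monotone over the range searched
  flat <- resonant_frequency(sdof_model(k = 1, m = 1, c = 0.02),
                             probe = "footplate", search_range = c(10, 100))
  expect_true(flat$no_resonance)
})

test_that("build_normal_model carries the anatomical components and printed moduli", {
  model <- normal_model()
  expect_true(all(c("AML", "PIL", "SIL", "SML", "LML", "PML", "SAL",
                    "tensor_tympani", "stapedial_tendon",
                    "incudomalleolar_joint", "incudostapedial_joint")
                  %in% names(model$elements)))
  get_E <- function(el) model$materials[[model$elements[[el]]$material]]$young_modulus
  expect_equal(get_E("AML"), 2.1e7)
  expect_equal(get_E("PIL"), 6.5e5)
  expect_equal(get_E("SIL"), 4.9e6)
  expect_equal(get_E("SML"), 4.9e6)
  expect_equal(get_E("SAL"), 6.5e4)
  expect_equal(get_E("incus_long_process"), 1.2e10)
})

test_that("missing components and disconnected networks are reported", {
  config <- read_model_config(default_config_path())

  broken <- config
  broken$elements <- Filter(function(e) e$id != "PIL", broken$elements)
  expect_error(build_normal_model(broken), "PIL",
               class = "earmech_config_error")

  # disabling the SAL is allowed (footplate stays connected via the crura)
  # but the model is no longer normal
  no_sal <- config
  no_sal$disabled <- list("SAL")
  m <- build_normal_model(no_sal)
  expect_false(m$normal)

  # severing the whole incudostapedial path disconnects the footplate
  cut <- config
  cut$disabled <- list("incudostapedial_joint")
  cut$elements <- Filter(function(e) e$id != "incus_long_process", cut$elements)
  expect_error(
    {
      cfg <- cut
      cfg$elements <- Filter(function(e) e$id != "incudostapedial_joint", cfg$elements)
      build_normal_model(cfg)
    },
    class = "earmech_topology_error"
  )
})

test_that("the calibrated normal model resonates inside the physiological window", {
  r <- resonant_frequency(normal_model(), probe = "umbo")
  expect_false(r$no_resonance)
  expect_gte(r$frequency_hz, 800)
  expect_lte(r$frequency_hz, 1200)
})

test_that("calibration rescales suspension areas back into the window", {
  config <- read_model_config(default_config_path())
  heavy <- config
  for (i in seq_along(heavy$inertias)) {
    heavy$inertias[[i]]$mass <- heavy$inertias[[i]]$mass * 4
  }
  f_heavy <- resonant_frequency(build_normal_model(heavy), "umbo")$frequency_hz
  expect_lt(f_heavy, 800)
  calibrated <- calibrate_normal_config(heavy)
  expect_true(calibrated$meta$calibrated)
  f_new <- resonant_frequency(build_normal_model(calibrated), "umbo")$frequency_hz
  expect_gte(f_new, 800)
  expect_lte(f_new, 1200)
  # printed moduli untouched by calibration
  expect_equal(
    Filter(function(m) m$name == "aml_ligament", calibrated$materials)[[1]]$young_modulus,
    2.1e7
  )
})
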