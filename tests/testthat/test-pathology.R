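test_that("cord replacement scales the printed modulus and section ratios", {
  model <- normal_model()
  base_area <- model$elements[["incus_long_process"]]$area

  m4 <- apply_cord_replacement(model, 1e-4, "Ver2")
  el <- m4$elements[["incus_long_process"]]
  expect_equal(m4$materials[[el$material]]$young_modulus, 1.2e6)
  expect_equal(el$area, base_area / 16)
  expect_false(m4$normal)

  m1 <- apply_cord_replacement(model, 1e-3, "Ver1")
  expect_equal(m1$elements[["incus_long_process"]]$area, base_area / 4)

  # off-enumeration scale requires allow_custom; with it, Ver1 at scale 1 is
  # exactly a quarter of the pristine long-process stiffness (E*A/L)
  expect_error(apply_cord_replacement(model, 0.5, "Ver1"),
               class = "earmech_config_error")
  mc <- apply_cord_replacement(model, 1, "Ver1", allow_custom = TRUE)
  k_ratio <- (mc$materials[[mc$elements[["incus_long_process"]]$material]]$young_modulus *
                mc$elements[["incus_long_process"]]$area) /
    (1.2e10 * base_area)
  expect_equal(k_ratio, 1 / 4)

  # the input model is never mutated
  expect_equal(model$elements[["incus_long_process"]]$area, base_area)
})

test_that("SAL modification scales or ossifies the annular ligament", {
  model <- normal_model()
  E_of <- function(m) m$materials[[m$elements[["SAL"]]$material]]$young_modulus
  expect_equal(E_of(apply_sal_modification(model, 10)), 6.5e5)
  expect_equal(E_of(apply_sal_modification(model, 8)), 5.2e5)
  expect_equal(E_of(apply_sal_modification(model, "ossified")), 1.2e10)
  expect_error(apply_sal_modification(model, -2), class = "earmech_domain_error")

  # factor 1 is the identity: transmission unchanged
  tc1 <- transmission_curve(apply_sal_modification(model, 1))
  expect_equal(tc1$vsf_abs, normal_curve()$vsf_abs, tolerance = 1e-12)
})

test_that("ligament fixation applies the staged factors and ossification modulus", {
  model <- normal_model()
  E_of <- function(m, lig) m$materials[[m$elements[[lig]]$material]]$young_modulus
  expect_equal(E_of(apply_ligament_fixation(model, "AML", "x100"), "AML"), 2.1e9)
  expect_equal(E_of(apply_ligament_fixation(model, "PIL", "ossified"), "PIL"), 1.2e10)
  expect_equal(E_of(apply_ligament_fixation(model, "SIL", "x10"), "SIL"), 4.9e7)
  err <- tryCatch(apply_ligament_fixation(model, "XXX", "x10"),
                  earmech_config_error = identity)
  expect_match(conditionMessage(err), "AML, PIL, SIL, SML, LML, PML")
})

test_that("monopod stapes removes the anterior crus and swaps the posterior material", {
  model <- normal_model()
  rigid <- apply_monopod_stapes(model, 1.2e10)
  expect_false("anterior_crus" %in% names(rigid$elements))
  expect_equal(rigid$materials[[rigid$elements[["posterior_crus"]]$material]]$young_modulus,
               1.2e10)

  ve <- default_crus_viscoelastic()
  visc <- apply_monopod_stapes(model, ve)
  mat <- visc$materials[[visc$elements[["posterior_crus"]]$material]]
  expect_identical(mat$viscoelastic, ve)
  # delegation contract: the element modulus at each frequency is the Maxwell value
  for (f in c(125, 1000, 8000)) {
    E <- earmech:::element_complex_modulus(mat, f)
    expect_equal(E, maxwell_complex_modulus(ve, f))
  }

  # idempotent: applying twice warns but yields the same model
  expect_warning(twice <- apply_monopod_stapes(rigid, 1.2e10),
                 class = "earmech_idempotency_warning")
  expect_equal(transmission_curve(twice)$vsf_abs, transmission_curve(rigid)$vsf_abs)
})

test_that("scenario composition is ordered, pure and annotates failures", {
  model <- normal_model()

  empty <- pathology_scenario("identity", list())
  expect_equal(transmission_curve(compose_scenario(model, empty))$vsf_abs,
               normal_curve()$vsf_abs)

  single <- pathology_scenario("sal10", list(modification("sal_scale", factor = 10)))
  expect_equal(transmission_curve(compose_scenario(model, single))$vsf_abs,
               transmission_curve(apply_sal_modification(model, 10))$vsf_abs)

  p1 <- compose_scenario(model, scenario_catalog()[["patient1"]])
  cord <- p1$elements[["incus_long_process"]]
  expect_equal(p1$materials[[cord$material]]$young_modulus, 1.2e6)
  expect_equal(cord$area, model$elements[["incus_long_process"]]$area / 16)
  expect_equal(p1$materials[[p1$elements[["SAL"]]$material]]$young_modulus, 5.2e5)

  bad <- pathology_scenario("bad", list(modification("sal_scale", factor = 10),
                                        modification("ligament_fixation",
                                                     ligament = "XXX", level = "x10")))
  err <- tryCatch(compose_scenario(model, bad), earmech_config_error = identity)
  expect_match(conditionMessage(err), "modification 2")
})

test_that("the scenario catalog matches the case descriptions and composes cleanly", {
  cat_scen <- scenario_catalog()
  expect_true(all(c("patient1", "patient2", "patient3", "patient4", "patient5",
                    "patient6", paste0("ossify_", c("AML", "PIL", "SIL", "SML",
                                                    "LML", "PML")))
                  %in% names(cat_scen)))

  p2 <- cat_scen[["patient2"]]$modifications[[1]]
  expect_equal(p2$variant, "cord_replacement")
  expect_equal(p2$params$e_scale, 1e-5)
  expect_equal(p2$params$area_version, "Ver1")

  p6 <- cat_scen[["patient6"]]$modifications
  expect_length(p6, 6L)
  fixed <- vapply(p6, function(m) m$params$ligament, "")
  expect_setequal(fixed, c("AML", "LML", "SML", "PML", "SIL", "PIL"))
  model <- normal_model()
  p6m <- compose_scenario(model, cat_scen[["patient6"]])
  expect_identical(p6m$elements[["SAL"]]$material,
                   model$elements[["SAL"]]$material)

  for (sc in cat_scen) {
    expect_s3_class(compose_scenario(model, sc), "middle_ear_model")
  }
})

test_that("softer and thinner cords never transmit better", {
  model <- normal_model()
  freqs <- audiometric_frequencies()
  for (ver in c("Ver1", "Ver2")) {
    losses <- sapply(c(1e-3, 1e-4, 1e-5), function(es) {
      loss_for(apply_cord_replacement(model, es, ver))$loss_db
    })
    expect_true(all(losses[, 2] >= losses[, 1] - 1e-9))
    expect_true(all(losses[, 3] >= losses[, 2] - 1e-9))
  }
  for (es in c(1e-3, 1e-4, 1e-5)) {
    d <- loss_for(apply_cord_replacement(model, es, "Ver2"))$loss_db -
      loss_for(apply_cord_replacement(model, es, "Ver1"))$loss_db
    expect_true(all(d >= -1e-9))
  }
})

test_that("stiffer ligaments cause no less low-frequency loss", {
  model <- normal_model()
  freqs <- audiometric_frequencies()
  levels <- c("x10", "x100", "x1000", "ossified")
  for (lig in c("AML", "PIL", "SIL", "SML", "LML", "PML")) {
    moduli <- c(10, 100, 1000, 1.2e10 / earmech:::LIGAMENT_YOUNG_MODULI[[lig]])
    mean_low <- sapply(levels, function(lv) {
      mean_loss_below(loss_for(apply_ligament_fixation(model, lig, lv))$loss_db,
                      freqs, 1000)
    })
    # non-decreasing in the ligament's actual Young's modulus (for the AML the
    # x1000 level exceeds the ossification modulus, so the enum order and the
    # modulus order differ there)
    expect_true(all(diff(mean_low[order(moduli)]) >= -1e-9),
                label = sprintf("fixation severity monotone for %s", lig))
  }
})

test_that("fixing more ligaments never lowers the low-frequency loss", {
  model <- normal_model()
  freqs <- audiometric_frequencies()
  sets <- list("AML",
               c("AML", "SML"),
               c("AML", "SML", "PIL"),
               c("AML", "LML", "SML", "PML", "SIL", "PIL"))
  mean_low <- sapply(sets, function(ligs) {
    m <- model
    for (lig in ligs) m <- apply_ligament_fixation(m, lig, "ossified")
    mean_loss_below(loss_for(m)$loss_db, freqs, 1000)
  })
  expect_true(all(diff(mean_low) >= -1e-9))
})

test_that("SAL stiffening raises the low-frequency loss", {
  model <- normal_model()
  freqs <- audiometric_frequencies()
  mean_low <- sapply(c(1, 10, 100), function(fac) {
    mean_loss_below(loss_for(apply_sal_modification(model, fac))$loss_db,
                    freqs, 500)
  })
  expect_true(all(diff(mean_low) >= -1e-9))
})

test_that("PIL ossification is the most damaging single-ligament fixation", {
  model <- normal_model()
  freqs <- audiometric_frequencies()
  mean_low <- sapply(c("AML", "PIL", "SIL", "SML", "LML", "PML"), function(lig) {
    mean_loss_below(loss_for(apply_ligament_fixation(model, lig, "ossified"))$loss_db,
                    freqs, 1000)
  })
  expect_equal(names(which.max(mean_low)), "PIL")
})
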