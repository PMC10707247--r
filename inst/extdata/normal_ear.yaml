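# Calibrated normal middle-ear network configuration.
#
# The Young's moduli of ossicular bone, the six suspensory ligaments and the
# stapedial annular ligament are fixed physiological constants and must not be
# edited. Element cross-sections and lengths, lumped masses, damping loss
# factors and the cochlear load are *effective* reduced-network values: they
# were set by the resonance calibration routine so that the umbo-probe
# resonance of the normal model sits in the 800-1200 Hz physiological window.
# Node positions fix element orientations only (piston axis = x); the elastic
# length of each element is its `length` field.
meta:
  name: normal_ear
  config_version: 1
  calibrated: true
drive:
  node: umbo
  effective_area: 5.5e-5      # m^2, effective tympanic-membrane area
  pressure_db_spl: 80.0       # pure-tone drive level re 20 uPa
footplate:
  node: footplate
  area: 3.2e-6                # m^2, stapes footplate
cochlea:
  node: footplate
  resistance: 0.2             # N s/m, resistive part of the lumped cochlear load
  compliance: 5.0e-3          # m/N
frequency_grid: [125.0, 250.0, 500.0, 1000.0, 2000.0, 4000.0, 8000.0]
materials:
  - {name: ossicle_bone,   young_modulus: 1.2e+10, density: 2200.0, loss_factor: 0.01}
  - {name: joint_capsule,  young_modulus: 6.0e+8,  density: 1200.0, loss_factor: 0.1}
  - {name: aml_ligament,   young_modulus: 2.1e+7,  density: 1200.0, loss_factor: 0.15}
  - {name: pil_ligament,   young_modulus: 6.5e+5,  density: 1200.0, loss_factor: 0.15}
  - {name: sil_ligament,   young_modulus: 4.9e+6,  density: 1200.0, loss_factor: 0.15}
  - {name: sml_ligament,   young_modulus: 4.9e+6,  density: 1200.0, loss_factor: 0.15}
  - {name: lml_ligament,   young_modulus: 4.9e+6,  density: 1200.0, loss_factor: 0.15}
  - {name: pml_ligament,   young_modulus: 4.9e+6,  density: 1200.0, loss_factor: 0.15}
  - {name: sal_ligament,   young_modulus: 6.5e+4,  density: 1200.0, loss_factor: 0.15}
  - {name: tendon,         young_modulus: 2.6e+6,  density: 1200.0, loss_factor: 0.15}
  - {name: tm_tissue,      young_modulus: 2.0e+7,  density: 1200.0, loss_factor: 0.5}
nodes:
  - {id: umbo,        position: [0.0,    0.0, 0.0], dofs: [ux]}
  - {id: malleus,     position: [0.002,  0.0, 0.0], dofs: [ux]}
  - {id: incus,       position: [0.004,  0.0, 0.0], dofs: [ux]}
  - {id: lenticular,  position: [0.006,  0.0, 0.0], dofs: [ux]}
  - {id: stapes_head, position: [0.007,  0.0, 0.0], dofs: [ux]}
  - {id: footplate,   position: [0.009,  0.0, 0.0], dofs: [ux]}
  - {id: wall,        position: [0.02,   0.0, 0.0], dofs: []}
elements:
  - {id: manubrium,             kind: axial, node_a: umbo,        node_b: malleus,     material: ossicle_bone,  area: 5.0e-7,  length: 4.0e-3}
  - {id: tympanic_membrane,     kind: axial, node_a: umbo,        node_b: wall,        material: tm_tissue,     area: 2.0e-8,  length: 1.0e-3}
  - {id: AML,                   kind: axial, node_a: malleus,     node_b: wall,        material: aml_ligament,  area: 1.2e-8,  length: 1.0e-3}
  - {id: SML,                   kind: axial, node_a: malleus,     node_b: wall,        material: sml_ligament,  area: 3.0e-8,  length: 1.0e-3}
  - {id: LML,                   kind: axial, node_a: malleus,     node_b: wall,        material: lml_ligament,  area: 5.0e-9,  length: 1.0e-3}
  - {id: PML,                   kind: axial, node_a: malleus,     node_b: wall,        material: pml_ligament,  area: 3.0e-9,  length: 1.0e-3}
  - {id: tensor_tympani,        kind: axial, node_a: malleus,     node_b: wall,        material: tendon,        area: 1.0e-7,  length: 5.0e-3}
  - {id: incudomalleolar_joint, kind: axial, node_a: malleus,     node_b: incus,       material: joint_capsule, area: 1.0e-6,  length: 2.0e-3}
  - {id: PIL,                   kind: axial, node_a: incus,       node_b: wall,        material: pil_ligament,  area: 4.0e-7,  length: 1.0e-3}
  - {id: SIL,                   kind: axial, node_a: incus,       node_b: wall,        material: sil_ligament,  area: 1.0e-8,  length: 1.0e-3}
  - {id: incus_long_process,    kind: axial, node_a: incus,       node_b: lenticular,  material: ossicle_bone,  area: 6.0e-7,  length: 3.0e-3}
  - {id: incudostapedial_joint, kind: axial, node_a: lenticular,  node_b: stapes_head, material: joint_capsule, area: 1.0e-6,  length: 1.2e-3}
  - {id: stapedial_tendon,      kind: axial, node_a: stapes_head, node_b: wall,        material: tendon,        area: 2.5e-8,  length: 5.0e-3}
  - {id: anterior_crus,         kind: axial, node_a: stapes_head, node_b: footplate,   material: ossicle_bone,  area: 3.0e-7,  length: 3.0e-3}
  - {id: posterior_crus,        kind: axial, node_a: stapes_head, node_b: footplate,   material: ossicle_bone,  area: 3.0e-7,  length: 3.0e-3}
  - {id: SAL,                   kind: axial, node_a: footplate,   node_b: wall,        material: sal_ligament,  area: 1.6e-6,  length: 1.0e-4}
inertias:
  - {body: tympanic_membrane_effective, mass: 1.2e-5, nodes: [umbo]}
  - {body: malleus,                     mass: 2.5e-5, nodes: [malleus]}
  - {body: incus,                       mass: 2.8e-5, nodes: [incus]}
  - {body: stapes,                      mass: 3.0e-6, nodes: [stapes_head, footplate]}
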