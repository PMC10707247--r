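---
title: "Simulating ossicular malformations with a reduced middle-ear network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ossicular malformations with a reduced middle-ear network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earmech)
```

## The model and its assumptions

`earmech` represents the sound-conduction chain of the human middle ear as a
small elastic network solved in the frequency domain. Six mobile nodes sit on
a piston axis — umbo, malleus, incus, lenticular process, stapes head,
footplate — plus one fixed node standing in for the temporal bone (tympanic
annulus and attic wall). Elastic elements connect the nodes: the tympanic
membrane and its manubrial coupling, the six suspensory ligaments (AML, SML,
LML, PML on the malleus; PIL, SIL on the incus), the two intra-ossicular
joints, the incus long process, the two stapedial crura, the two tendons, and
the stapedial annular ligament (SAL) seating the footplate. Lumped masses
carry the ossicular and effective tympanic-membrane inertia, and a lumped
resistance-plus-compliance at the footplate stands in for the cochlear input
impedance.

Each element contributes an axial stiffness $k = E(f)\,A/L$. For ordinary
materials $E(f) = E\,(1 + i\eta)$ with a structural loss factor $\eta$; for
viscoelastic materials the generalized Maxwell modulus

$$E^{*}(\omega) = E_\infty + \sum_i E_i \frac{(\omega\tau_i)^2}{1+(\omega\tau_i)^2}
  \; + \; i \sum_i E_i \frac{\omega\tau_i}{1+(\omega\tau_i)^2}$$

replaces it frequency by frequency. A pure tone of pressure $p$ (default
80 dB SPL re 20 µPa) acting on the effective tympanic-membrane area drives
the umbo; the complex symmetric system
$[K(\omega) - \omega^2 M + Z_c(\omega)]\,u = F$ is solved densely per
frequency and velocities are $v = i\omega u$. The package's output proxy for
cochlear input is the footplate volume velocity
$V_{SF} = v_{fp} A_{fp}$, and the simulated conductive loss of a modified ear
is $20\log_{10}(|V_{SF,\mathrm{normal}}| / |V_{SF,\mathrm{diseased}}|)$ dB —
a pure ratio, so it is exactly invariant to the drive level and to the
interpretation of "80 dB" (SPL at the membrane vs. in the canal); the shipped
configuration documents the SPL-at-the-membrane assumption regardless.

Key simplifications, stated up front:

* **One translational degree of freedom per node.** The real chain moves with
  lever ratios and rocking modes; here every element acts along the piston
  axis. Consequently element sections and lengths are *effective* values, not
  anatomical measurements — an axial surrogate for what is, in a full 3-D
  model, largely bending compliance.
* **Massless elements.** Inertia lives only in the lumped bodies (malleus
  25 mg, incus 28 mg, stapes 3 mg, effective tympanic membrane 12 mg —
  standard temporal-bone values).
* **Harmonic steady state only**; no time-domain transients.
* **The cochlea is a lumped load** (0.2 N·s/m resistance, 5×10⁻³ m/N
  compliance at the footplate); no cochlear partition mechanics.
* **Bone conduction is not modelled**: measured bone thresholds are inputs.

## Fixed constants versus calibrated parameters

The Young's moduli of ossicular bone (1.2×10¹⁰ N/m²), the SAL
(6.5×10⁴ N/m²), and the suspensory ligaments (AML 2.1×10⁷, PIL 6.5×10⁵,
SIL and SML 4.9×10⁶ N/m²) are fixed physiological constants of the model and
are never touched by calibration. The LML and PML moduli are not separately
established; both default to the SML value (same anatomical class) and are
exposed in the configuration.

Everything else — element sections and lengths, masses, loss factors, the
cochlear load — is an effective reduced-network parameter. These were set
once, by the calibration rule that only unprinted parameters may move, so
that:

* the normal umbo-probe resonance sits in the 800–1200 Hz window that
  wideband tympanometry reports for normal ears (shipped config: 986 Hz);
* severe cord softening (Ver2, 10⁻⁵) drops it to the dehiscence level
  (≤ 750 Hz) and SAL ×10 raises it past the otosclerosis level (≥ 1400 Hz).

`calibrate_normal_config()` implements the routine: it rescales a single
global factor on the cross-sectional areas of the wall-anchored (suspension)
elements by a monotone root search until the umbo resonance hits the window
centre, and stamps the result. The shipped `inst/extdata/normal_ear.yaml` is
the frozen calibrated configuration.

Damping defaults: bone 0.01, joint capsules 0.1, ligaments and tendons 0.15,
tympanic membrane 0.5 (all dimensionless structural loss factors). Soft
tissue is strongly dissipative and the membrane especially so; with membrane
damping included, the normal admittance peak is broad, as measured ears are,
and the decoupled malleus-incus resonance that appears under cord softening
does not put a spurious sharp dip into the loss curves. Two further geometry
choices were genuinely open and are worth recording: the SIL, LML and PML were
given distinct effective sections (10, 5 and 3×10⁻⁹ m²). With identical
sections the LML and PML ossification scenarios would be *exactly* degenerate
— indistinguishable in principle by any fitting procedure — and near-identical
sections leave the three accessory-ligament scenarios confusable at realistic
audiometric noise. The spread keeps every catalog scenario identifiable while
preserving the intended stiffness ordering (ossified: PIL > SML > AML > SIL,
the published severity order).

## The pathology layer

Every malformation is a pure function returning a modified copy; scalings are
defined against the pristine build-time modulus, so composition never
compounds factors and is deterministic (structural edits — crus removal —
apply before material scalings).

* `apply_cord_replacement()` — the incus long process becomes a fibrous cord:
  modulus 1.2×10¹⁰ × {10⁻³, 10⁻⁴, 10⁻⁵}, section ×1/4 (Ver1) or ×1/16 (Ver2).
  The staged enumeration is the default surface; `allow_custom` unlocks other
  values. Zero-stiffness severance is deliberately not offered: the harmonic
  formulation cannot represent complete discontinuity, so 10⁻⁵ is the floor.
* `apply_sal_modification()` — SAL modulus ×factor, or ossified (1.2×10¹⁰).
* `apply_ligament_fixation()` — one of the six suspensory ligaments at
  ×10/×100/×1000/ossified. Note one subtlety: for the AML (2.1×10⁷ N/m²) the
  ×1000 level (2.1×10¹⁰) is *stiffer* than ossification (1.2×10¹⁰), so the
  physically monotone ordering is by resulting modulus, not by enum position;
  the tests assert monotone loss in the modulus.
* `apply_monopod_stapes()` — removes the anterior crus (idempotent: a second
  application warns instead of failing) and replaces the posterior-crus
  material by a plain modulus or a Maxwell viscoelastic spec. The default
  viscoelastic parameters (`default_crus_viscoelastic()`: E∞ = 6.5×10⁵ Pa,
  one arm E₁ = 6.5×10⁶ Pa, τ = 8×10⁻⁵ s) make the storage modulus rise
  through the audio band with a loss peak near 2 kHz; they are package
  defaults for the case-3 scenario, not asserted physiological values.

`scenario_catalog()` ships the six clinical-case scenarios plus the
single-ligament ossification sweep. The case-5 entry ({AML, SML ossified,
SAL ×10}) is labelled illustrative: the clinical narrative for that case
mixes malleus adhesion with an annular-ligament change without fixing exact
factors.

## The audiology layer

Simulated loss is compared against the measured **air-bone gap**, not raw air
thresholds: the network predicts conductive loss only, and the AB gap is the
audiometric signature of the conductive component. Sign convention (tested,
because it is a classic polarity trap): an *up-sloping* audiogram means loss
concentrated at **low** frequencies (stiffness-dominated — otosclerosis,
attic fixation); *down-sloping* means loss concentrated at high frequencies
(discontinuity pattern). `classify_slope()` fits value against
log₂(frequency); |slope| ≥ 3 dB/octave labels the direction, and an interior
point deviating > 10 dB from its neighbours' mean overrides as peaked/dipped.
Both thresholds are exposed arguments. `pta4()` offers the unweighted
500/1k/2k/4k mean (default) and the Japanese weighted (500 + 2×1000 + 2000)/4
convention; the shipped case table stores its published PTA values as given
— the underlying audiograms exist only as figures, so neither convention is
asserted against them.

`rank_scenarios()` simulates every scenario on the measured grid and sorts by
RMS misfit (ties: higher Pearson correlation, then catalog order). Scenarios
that fail to compose are excluded and listed, never silently dropped.

## Numerical choices

* **Assembly/solve.** Dense complex LU (`solve()`) on the ~6-dof system; a
  singular system raises a solver error carrying a reciprocal-condition
  estimate and, in sweeps, the failing frequency. The matrix is complex
  symmetric by construction and the tests pin this to machine precision,
  alongside a hand-written Gaussian-elimination oracle (10⁻⁸) and the
  closed-form single-oscillator limit (10⁻¹⁰).
* **Resonance search.** 512-point log grid over the search range (default
  200–4000 Hz), then golden-section refinement of the bracketing interval in
  log-frequency to 0.25 Hz (proportionally finer below 250 Hz so sub-Hz test
  oscillators resolve); grid and refinement both break ties toward the lower
  frequency, making the result reproducible to ±1 Hz. A maximum on the range
  boundary is flagged `no_resonance` rather than raised.
* **Degenerate inputs.** A zero diseased magnitude yields a `+Inf` loss
  sentinel with a warning, not an exception; a single-record cohort reports
  SD as `NA`; removal that disconnects drive from footplate is a topology
  error listing the unreachable nodes.
* **Determinism.** No randomness anywhere in the mechanics; CLI runs embed
  the tool version, config hash and seed in every output header, and equal
  config + seed gives byte-identical files.

## What the tests show — and what they do not

The property suite runs entirely on the shipped calibrated configuration at
the seven audiometric frequencies (plus 512-point resonance sweeps), and the
Monte-Carlo recovery experiment uses 100 replicates of σ = 3 dB Gaussian
noise on 7-point curves — sizes chosen so the whole suite runs in seconds.
Passing it shows that the *reduced network* reproduces the qualitative
physiology: monotone severity orderings, low- vs high-frequency selectivity
of stiffness vs discontinuity pathologies, the published resonance shifts,
and identifiability of the catalog under realistic audiometric noise. It does
**not** show that absolute per-patient loss curves match measured audiograms:
real ears add 3-D lever mechanics, individual anatomy, middle-ear cavity
acoustics and external-canal effects (the known failure mode for case 6,
whose narrow external auditory canal is outside the model), none of which a
piston-axis network represents. The scenario ranking is therefore a
model-relative diagnosis aid, not a calibrated clinical predictor.

## Known limitations

* Effective geometry: element sections/lengths are calibration parameters;
  do not read them as anatomical measurements.
* Complete ossicular discontinuity and mass-loading pathologies
  (granulation tissue, cholesteatoma) are out of scope.
* The viscoelastic parameters of the monopodal-stapes cord are defaults, not
  fitted constants; use `apply_monopod_stapes()` with your own
  `viscoelastic_spec()` to explore them.
* External-auditory-canal malformations are not modelled.
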