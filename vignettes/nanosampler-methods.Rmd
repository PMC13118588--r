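---
title: "Models and methods behind nanosampler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanosampler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosampler)
```

# What this package models

`nanosampler` is a hardware-free re-creation of the control and analysis
stack of a converted low-cost pipetting robot used as a nanoliter liquid
handler and nano-LC autosampler. The physical instrument replaces one of
the robot's electronic pipettes with a 25 uL gastight syringe, mounts an
eight-position selector valve and a six-port two-position valve on the
gantry frame, and drives everything — XYZ motion, plunger, valve
actuators, a GPIO bridge for relay/pump handshaking, a temperature deck —
from custom software. Here every device is a deterministic simulator on a
shared *virtual clock*, so methods that take 50 minutes on the bench
execute instantly and bit-reproducibly, and the volumetric reasoning the
instrument relies on (loop underfill/overfill, dead volumes, flush
accounting) can be tested exactly.

The package has six layers: plate-calibration geometry, syringe
kinematics, simulated devices, the valve/loop fluid network, a YAML
method interpreter with LC-pump handshaking, and the fluorimetric
volumetry used to verify sub-microliter dispensing.

# Plate calibration

Well plates are assumed evenly spaced, so nominal well positions form a
regular grid with A1 at the origin: X = (column−1)·pitch,
Y = (row−1)·pitch. Calibration measures the machine coordinates of three
corner wells; three 2-D point pairs exactly determine a 2-D affine map,
so the fit is an interpolation, not a regression:

$$\mathbf{m} = A\,\mathbf{g} + \mathbf{b}$$

with \(A\) a 2×2 linear part and \(\mathbf{b}\) a translation. We solve
the 3×3 linear system \([\,\mathbf{g}\;1\,]\,\beta = \mathbf{m}\) per
machine axis. Z is treated as a *plane* through the three measured z
values — the source description is silent on z, and a plane supports
tilted labware at no extra cost; holding z constant is the special case
of a level plate.

**Corner convention.** We calibrate A1, A(last column) and (last row)1
and verify at (last row)(last column). With that choice the predicted
fourth corner is the parallelogram completion
\(m_{A24} + m_{P1} - m_{A1}\) (for a 384-well plate), which makes the
instrument's "move to the fourth corner and accept or recalibrate" check
well defined. The default acceptance tolerance is 0.5 mm — roughly a
tenth of a 4.5 mm well pitch, i.e. clearly inside the well — and is
user-overridable.

Degenerate corner sets (collinear or duplicated) are rejected by the
area test \(|\det[\mathbf{g}_2-\mathbf{g}_1;\,\mathbf{g}_3-\mathbf{g}_1]|
< 10^{-9}\), and a fitted linear part with \(|\det A| < 10^{-9}\) is
rejected as singular.

Calibrations persist as JSON with 17 significant digits (beyond the
precision of a double), so a save/load round trip is bit-exact. The
registry deliberately starts empty at every session: saved files must be
loaded explicitly, mirroring the instrument's restart rule. Syringe
profiles, by contrast, are *never* persisted — recalibration after every
restart guarantees the plunger's range of motion.

# Syringe kinematics and the stock-software conversion

The syringe barrel is cylindrical, so volume↔travel is linear:
`units_per_mm = nominal_volume / |max − min|` (25 uL over a 60 mm stroke
by default). No backlash model is fitted; a dead-band would enter here if
a physical syringe needed one.

Driving the syringe through the *unmodified* robot software requires a
second conversion: target volume → plunger distance → the commanded
"pipette volume" the stock software would translate into that distance.
The vendor's piecewise coefficients are not public, so the breakpoint
table is user configuration (monotone in both coordinates, anchored at
(0,0)), and we interpolate *linearly between breakpoints* — the
alternative, per-range constant uL/mm, is the same model with different
breakpoints, and the linear choice makes the composition of forward and
inverse maps exactly the identity on the travel range.

Capillary volumes use the cylinder formula
\(V = \pi (d/2)^2 L\); the 13 cm × 100 um sample loop computes to
1.021 uL, the "1 uL loop" of the instrument description.

# Simulated devices

Each device is an R6 object speaking a bespoke line protocol (one
command, exactly one `OK`/`ERR` response; errors leave state unchanged).
The protocol makes no claim of compatibility with any vendor dialect —
real transports are out of scope — it only needs internal consistency.

* **Motion**: point-to-point moves, per-axis soft limits, homing flags;
  moves before homing or beyond limits are rejected with state
  unchanged. Time advances by distance/speed.
* **Valves**: a selector (`GOTO 1..8`) and a two-position valve
  (`SWITCH`/`GOTO A|B`), both counting actuations; commanding the
  current position acknowledges without actuating.
* **Signal bridge**: GPIO pins configured as inputs or outputs. Input
  edges are *scripted* `(time, pin, level)` events: `wait_for_input()`
  advances the clock to the matching event or by the timeout. A timeout
  is an outcome, not an exception — methods decide what to do with it.
* **Tempdeck**: first-order relaxation
  \(T(t) = T_{set} + (T_0 - T_{set})e^{-\Delta t/\tau}\), monotone toward
  the setpoint (default \(\tau\) = 120 s, a plausible Peltier deck
  scale).
* The foil puncher is a second mounted tool with its own XYZ offset and
  plunge depth; the foil is a per-well boolean flipped by a punch.

Determinism: given the same command sequence and scripted events, traces
are identical, which the suite asserts directly.

# Fluid network and injection planning

The flow path is a graph of ports and capillary segments with volumes.
The two-position valve's *pairing convention* — position A connects
(1-2)(3-4)(5-6), position B connects (2-3)(4-5)(6-1) — is not part of
the instrument description, which only assigns ports; this convention is
the one that reproduces the described behavior: in LOAD the needle,
loop and syringe are in series while the pump flows straight to the
column, and in INJECT the loop sits online between pump and column.

Sample plugs are sharp 1-D intervals of path volume measured from the
needle tip (no Taylor dispersion — the instrument's own reasoning is
purely volumetric). Aspirating V at the tip shifts every boundary by +V;
dispensing shifts by −V; widths are invariant, and plugs leaving the path
are truncated with the lost volume reported.

An injection aspirates `sample` then `chase` (chase drawn at the tip,
from a solvent well — the only location from which aspiration moves the
plug toward the loop), leaving the plug on `[chase, chase+sample]` while
the loop occupies `[D, D+V_loop]`, `D` being the tip-to-loop dead
volume. Validity is interval containment:

* **underfill**: plug ⊆ loop, injected volume = sample volume;
* **overfill**: plug ⊇ loop, injected volume = loop volume.

Either way the injected volume can never exceed the loop volume.
Geometric impossibilities (chase smaller than `D`, sample larger than
the loop) produce an *invalid plan with a diagnostic*, not an error —
that is a method-check result, not a programming fault.

**The dead volume `D` is configuration, defaulting to 3.2 uL.** The
autosampler's needle dimensions are not stated in the source
description (the 40 cm × 100 um needle belongs to the basic
liquid-handling configuration), so no true value can be claimed. 3.2 uL
is chosen once because it makes the published recipes valid with
comfortable margins — underfill 500+3500 nL gives plug [3.5, 4.0] inside
loop [3.2, 4.22]; overfill 1700+3000 nL gives plug [3.0, 4.7] covering
it — and is flagged here as a repository assumption.

The between-injection flush draws solvent A through the selector into
the syringe and dispenses it back out through the transfer line, loop
and needle, so every dispensed microliter transits the loop segment;
25 uL (the protocol volume) runs as one full syringe cycle, and the
trace accounting sums exactly the requested volume through the loop.

# Method engine

Method files are YAML — hand-editable, one step per list item, with a
twelve-step vocabulary (`move_to_well`, `aspirate`, `dispense`, valve
steps, GPIO steps, `set_temp`, `punch_foil`, `pause`, `comment`).
Validation is fail-fast and *complete*: all violations are reported
together with step indices, and a program that fails validation (or
pre-flight: uncalibrated labware, uncalibrated syringe) cannot touch
device state. Queues run first-in-first-out; a failure aborts the
failing method and halts the queue, reporting what never ran.

The LC pump is modeled as a scripted device: the relay pulse starts its
program, and the end-of-method input edge is scheduled at pulse time
plus the gradient duration on the virtual clock. The bundled 50-minute
gradient is the breakpoint encoding of the pump program — %B 1→5 in the
first minute, the 5→25% elution ramp over 20 min, wash oscillations to
75% and a 15-min re-equilibration at 1% — i.e. breakpoints
(0,1)(1,5)(21,25)(23,45)(24,75)(28,75)(29,25)(30,25)(31,75)(34,75)(35,1)(50,1),
evaluated by linear interpolation. The default wait timeout is the
profile duration plus 10%, which converts a missing pump signal into a
detectable timeout outcome in simulation.

# Volumetry: verifying sub-microliter dispensing

Gravimetry fails below a microliter (evaporation dominates), so
dispensing is verified fluorimetrically: dispense V of fluorescein stock
C₀ into a well prefilled with W = 20 uL of buffer, read fluorescence
against hand-pipetted standards (3–7 uM, five replicates), and invert.

Two dilution conventions coexist and both are implemented:

* **design ratio** `C = C₀·V/W` — the convention the published design
  satisfies (every pair of 500…5 nL with 0.2…20 mM targets exactly
  5 uM);
* **exact** `C = C₀·V/(W+V)` — used for estimation, inverted in closed
  form as `V = C·W/(C₀ − C)`.

The conventions differ by at most V/(W+V) = 2.5% at the largest design
volume, which the suite asserts numerically. Which one the original
calculation used is not stated, so neither is claimed as "the"
instrument's formula.

The standard curve is ordinary least squares of intensity on
concentration; standards are treated as error-free in concentration
(their hand-pipetting scatter enters only through the fit). Outliers are
screened with an **iterative two-sided Grubbs test** at α = 0.05 (the
level is not stated in the source; 0.05 is the conventional choice):
remove the most extreme value while
\(G = \max|x-\bar x|/s\) exceeds
\(\frac{N-1}{\sqrt N}\sqrt{\frac{t^2}{N-2+t^2}}\), with \(t\) the upper
\(\alpha/(2N)\) t-quantile on N−2 degrees of freedom; not applicable
below N = 3. Per-group summaries report mean, CV% = 100·sd/mean and
absolute error % = 100·|mean−nominal|/nominal, grouped by
(volume × batch) to mirror per-batch analysis.

## The synthetic assay generator

`generate_synthetic_assay()` is first-class, tested code, not a test
fixture. It forward-simulates the experiment: dispensed volumes are
`nominal · (1+bias) · (1+ε)` with ε ~ N(0, CV); mixture intensities
follow the exact dilution model through a linear curve (default slope
1000 a.u./uM, intercept 50 — an arbitrary but plausible plate-reader
scale) with additive read noise; gross outliers replace the volume with
0.25× or 4× its value (a mis-hit or double dispense) at a configurable
rate, flagged in a truth column. Defaults are the stated experimental
design: the six (volume, stock) pairs, 20 uL prefill, five replicates,
standards 3–7 uM × 5.

What the generator does **not** emulate: photometric path-length and
gain effects, well-position (edge) effects, evaporation drift between
batches, pipetting correlation within a batch, and detector saturation.
A green test therefore establishes that the *analysis* is correct and
well-calibrated under the stated noise model — it does not reproduce the
instrument's measured CVs or errors, which depend on hardware and are
explicitly out of scope.

Calibration checks the suite runs: noiseless assays are recovered
exactly; at 5% dispense CV over 200 seeds the pooled CV estimate centers
on \(c_4 \times 5\%\) (the known small-sample bias of the sd with n = 5);
absolute-error estimates center on an injected bias; and Grubbs removes
at least half of injected gross outliers at a 20% contamination rate.

# Numerical choices and degenerate inputs

* Exact 3-point affine interpolation (linear solve), no least squares;
  singularity floors at 1e-9 (mm² and determinant).
* Calibration JSON at 17 significant digits for bit-exact round trips.
* Piecewise tables: strict monotonicity required, linear interpolation,
  range violations rejected (not extrapolated).
* Plug truncation at path boundaries warns and reports lost volume;
  advection by zero is the identity.
* Volume estimation rejects concentrations ≤ 1e-9 uM (indistinguishable
  from blank) and ≥ the stock concentration (impossible dilution).
* The virtual clock refuses to run backwards; all timestamps are
  monotone.
* Units: uL and mm internally; nL and quantity strings ("500 nL")
  converted on entry.

# Known limitations

No pressure/viscosity or flow-rate-dependent accuracy model; no
dispersion or carryover chemistry (carryover is reported only as
un-flushed plug volume); no real serial transports or vendor protocol
compatibility; no collision checking beyond soft limits; no concurrent
multi-instrument scheduling; the graphical interface of the original
software is represented by the package's functions and the thin CLI
script (`inst/scripts/nanosampler-cli.R`). Identification results from
LC-MS runs of protein digests are entirely out of scope — the package
reproduces the *volumetric* claims (injected masses, loop volume, flush
volume, gradient program), not chromatography or mass spectrometry.
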