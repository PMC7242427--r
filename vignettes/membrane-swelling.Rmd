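---
title: "Osmotic swelling with membrane mechanics: model, assumptions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Osmotic swelling with membrane mechanics: model, assumptions and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memswell)
```

## The problem

A cell or organelle bounded by a closed membrane swells when its interior is
hypertonic: water flows in, the volume grows, solutes dilute.  Classical
treatments stop there -- swelling ends only when the concentrations equalise.
But the membrane itself resists: stretching it generates an inward mechanical
pressure that can balance the osmotic drive long before concentrations
equalise, and at large strain the membrane tears, removing that resistance and
tipping the system from reversible (physiological) into irreversible
(pathological) swelling.  `memswell` implements this coupled picture for an
erythrocyte-like oblate axisymmetric ellipsoid (semi-axes $a = b$, $c$;
at rest $a = 8\,\mu m$, $c = 2\,\mu m$), together with an inverse Helfrich
solver that extracts the bending-induced pressure and surface tension implied
by any equilibrium shape.

## The model

**Osmotic pressure.** Van 't Hoff:
$\Delta P_{os} = R\,T \sum_i (C_i^{in} - C_i^{out})$, with concentrations in
$mol/m^3$ (numerically equal to mM).  Positive when the interior is
hypertonic.  Temperature defaults to 310 K (physiological; the model is not
tied to a particular organism).

**Stretching rigidity with disruption.** The membrane's stretching stiffness
is a diagonal rigidity tensor with in-plane component $g_0$ and axial
component $g_{zz}$, each decaying from its zero-strain value through a
phenomenological disruption law,

$$g_0 = \frac{g_{00}}{1 + \beta_0\,\Delta r^{n_1}}, \qquad
  g_{zz} = \frac{g_{zz,0}}{1 + \beta_z\,\Delta z^{n_1}},$$

where $\Delta r = a(t) - a(0)$ and $\Delta z = c(t) - c(0)$ are the semi-axis
deformations in $\mu m$.  Rigidity falls to zero asymptotically at large
strain -- the membrane disrupts.  For odd $n_1$ the absolute deformation is
used inside the ratio so that shrinkage also weakens, never stiffens, the
membrane.  The shipped preset ($n_1 = 4$, $g_{zz,0} = 0.008$,
$g_{00} = 0.0101$ dyn/nm, $\beta_z = 1.6\times10^4$,
$\beta_0 = 1.8\times10^4\ \mu m^{-4}$) is an inner-mitochondrial-membrane
estimate, carried digit-for-digit in the `table1_imm` fixture.

**Stretching pressure.** The stretch-induced inward pressure is

$$\Delta P_{IMM} = \frac{2 g_0 \Delta r + g_{zz} \Delta z}{S},$$

evaluated strictly in SI (1 dyn/nm = $10^4$ N/m, $\mu m \to m$,
$\mu m^2 \to m^2$); the result is in Pa.

**Volume dynamics.** Water flux drives the volume,

$$\frac{dV}{dt} = S(t)\, p_w \,(\Delta P_{os} - \Delta P_{IMM}),$$

with $p_w$ the water permeability per unit area per unit pressure.  Solute
content is conserved ($C_i V = const$), which is the exact solution of the
dilution equation $dC_i/dt = -(C_i/V)\,dV/dt$; we therefore integrate a single
ODE in $V$ and obtain concentrations in closed form.  This removes stiffness
and enforces conservation to machine precision.

**Shape closure.** One volume ODE cannot determine two shape degrees of
freedom.  `partition_deformation()` closes the system; the rule is explicit
configuration, never hard-coded:

* `energy-min` (default): minimise the elastic work
  $W = \int_0^{\Delta r} 2 g_0(r)\,r\,dr + \int_0^{\Delta z} g_{zz}(z)\,z\,dz$
  subject to the exact volume constraint.  Small-strain limit:
  $\Delta r/\Delta z \to c\,g_{zz,0}/(a\,g_{00}) \approx 0.198$ at the resting
  geometry.
* `self-similar`: uniform scaling $\Delta r/a_0 = \Delta z/c_0$, so the two
  relative deformations are equal.
* `fixed-ratio:x`: $\Delta r = x\,\Delta z$.

The equilibrium-shape family in `table2_shapes.csv` has
$\Delta r/\Delta z \approx 3.1$--$3.3$, close to the self-similar value
$a/c = 4$ and far from the energy-min small-strain ratio; the sweep presets
therefore use `self-similar`, while `energy-min` remains the physically
motivated default for free simulations.

**Saturation.** Swelling saturates when the fluxes balance:
$\Delta P_{os}(V) = \Delta P_{IMM}(V)$.  `saturation_state()` solves this by
a 512-point bracketing scan from $V_0$ up to the classical equilibrium volume
followed by `uniroot`.  The equilibrium is *reversible* when it lies on the
rising (intact-membrane) branch of $\Delta P_{IMM}$.  When the osmotic drive
exceeds the membrane's maximum restoring pressure -- which the disruption law
caps -- the only balance point sits on the disrupted branch just below the
classical volume; this irreversible regime is reported with
`reversible = FALSE`, not as an error.

**Linearized model.** For small strains
$\Delta P_{IMM} \approx \alpha \Delta V$ and the ODE becomes linear with
solution $\Delta V(t) = (\Delta P_{os}/\alpha)(1 - e^{-\alpha \bar S \bar p_w t})$:
the risetime $1/(\alpha \bar S \bar p_w)$ is independent of the osmotic
drive while the amplitude is proportional to it.  `linearize_config()` builds
this model from a configuration; `fit_alpha()` recovers $\alpha$ and the rate
from a trajectory.

**Classical baseline.** `classical_swelling()` integrates the osmotic-only
model (no mechanical term) and reports the inward/outward water fluxes; it
saturates exactly at $\sum C^{in} = \sum C^{out}$, i.e.
$V_{sat} = V_0 \sum C^{in}(0) / \sum C^{out}$, always far above the
mechanical model's equilibrium when the membrane is intact.

**Bending.** The curvature-elastic energy is
$F = \int_S \left[\tfrac{k_c}{2}(2H + c_0)^2 + k_d K + \lambda\right] dA
+ \Delta p\, V$, whose stationarity condition for an axisymmetric vesicle is

$$\Delta p - 2\lambda H + k_c (2H + c_0)(2H^2 - c_0 H - 2K)
  + 2 k_c \nabla^2 H = 0.$$

We deliberately define the energy density with the *total* curvature $2H$:
this is the convention under which the energy and the shape equation above are
mutually consistent (the squared-mean-curvature convention would produce a
different Euler--Lagrange equation).  A sphere with $\Delta p = 2\lambda/R$
solves the equation exactly (Laplace's law), which the test suite uses as an
exact oracle.  Spontaneous curvature $c_0$ defaults to zero (symmetric planar
bilayer) and is not fitted.

Given a shape and $(k_c, k_d)$, $\Delta p$ and $\lambda$ enter the residual
linearly, so `solve_inverse_bending()` is an area-weighted linear least
squares with design columns $(1, -2H)$.  On a sphere those columns are
collinear: the fit is flagged degenerate with its condition number and only
$\Delta p - 2\lambda/R$ is identifiable; a `lam_fixed` mode restores
uniqueness there.  Condition numbers are always reported -- degenerate systems
never return silently.

**Gaussian modulus identifiability.** For any closed genus-0 surface
$\int K\,dA = 4\pi$, so $k_d$ contributes only a constant to the energy and
drops out of the shape equation entirely.  Consequently $(k_c, k_d)$ *cannot*
both be recovered from shapes alone, and the residual norm is homogeneous in
$k_c$ (its unconstrained minimum is the useless $k_c = 0$).
`fit_bending_constants()` is therefore formulated as recovery against
*observations*: a residual-field misfit determines $k_c$ (warm-started by the
closed-form linear projection, then polished by a deterministic Nelder--Mead
simplex in log-parameter space, objective tolerance $10^{-10}$) and an energy
misfit pins $k_d$.  The homogeneous-sheet relation
$k_c = g h^2 / (12(1-\nu^2))$ (`bending_from_stretching()`) provides the
deterministic fallback start.

## Unit conventions and the parameter audit

The source literature for this class of model mixes CGS, SI and practical
units freely, and the printed magnitudes are mutually inconsistent.  The
package's position: *all* internal computation is SI; constructors and the
config schema accept explicit `"value unit"` strings (dyn/nm, erg, mM,
$\mu$l/min/Pa/$\mu m^2$, ...) and convert them once, visibly.  A dedicated
test evaluates the pressure formulas twice -- once in CGS with explicit
conversion factors, once in SI -- and requires agreement to $10^{-12}$.

Three audit results, all recomputed by the test suite and the acceptance
script, matter for interpreting shipped presets:

1. **The stretching pressure at the 50 mM equilibrium.**  Evaluating the
   rigidity and stretching-pressure laws literally in SI at the 50 mM
   equilibrium deformation ($\Delta r = 0.53$, $\Delta z = 0.17\,\mu m$,
   $S(8.53, 2.17) = 519.7\,\mu m^2$) gives $1.9667\times10^3$ Pa.  Any
   self-consistent unit system gives this same number, so it is the package's
   audited reference value for that configuration.
2. **The permeability preset.**  The printed
   $3.1\times10^2\ \mu l\,min^{-1} Pa^{-1} \mu m^{-2}$ converts to
   $5.2\times10^3\ m\,s^{-1} Pa^{-1}$, about sixteen orders of magnitude
   above measured erythrocyte hydraulic conductivities.  The `table1_imm`
   fixture carries the printed value verbatim for traceability, but the
   shipped simulation default is $p_w = 10^{-13}\ m\,s^{-1} Pa^{-1}$, a
   physically plausible conductivity that yields tens-of-seconds risetimes
   and minutes-scale saturation at erythrocyte scale.
3. **The disruption coefficients at erythrocyte strains.**  With
   $\beta_0, \beta_z \sim 10^4\ \mu m^{-4}$ the restoring pressure peaks near
   $\Delta r \approx 0.07\,\mu m$ at about $3\times10^4$ Pa -- *below* the
   osmotic drive of even the mildest (10 mM vs 1 mM) scenario,
   $4.6\times10^4$ Pa.  With disruption active, every 10--50 mM run is
   therefore irreversible.  Conversely, with disruption inactive the
   stretching pressure at the 50 mM equilibrium shape ($2.3\times10^5$ Pa)
   balances the osmotic pressure there ($2.0\times10^5$ Pa) to within 15%:
   the equilibrium-shape family is consistent with the mechanics only when
   the disruption factors are off.  The sweep presets
   (`sweep_10mM.yaml` ... `sweep_50mM.yaml`) therefore model the reversible
   physiological regime with the zero-strain rigidities and
   $\beta_0 = \beta_z = 0$, while `pathological_50mM.yaml` keeps the full
   disruption law to exhibit the irreversible regime.  Both presets are
   plain-text configuration; nothing is hard-coded.

## What the scenario presets emulate -- and what they do not

The fixtures emulate a single cell in an effectively infinite bath: external
concentrations are constant (1 mM NaCl in the sweeps), the interior carries
only Na$^+$ and Cl$^-$, and water is the only species crossing the membrane.
Real systems violate all three: solutes leak or are pumped, membrane potential
and metabolism shift the effective osmotic balance, and the cytoskeleton
contributes elasticity that this membrane-only model omits.  Passing tests
therefore demonstrate internal consistency of the coupled
osmotic--mechanical model under these idealisations -- not predictive accuracy
for any particular cell type.  Time-dependent permeability (e.g. transition
pores opening under strain) is likewise out of scope: $p_w$ is a constant per
run.

## Numerical choices

* **Surface quadrature**: Gauss--Legendre nodes in the polar angle on
  $(0, \pi)$; axisymmetry reduces all surface integrals to 1-D with spectral
  accuracy.  Nodes are interior, so pole singularities of the parameterisation
  are never evaluated.  Default 200 nodes closes Gauss--Bonnet
  ($\sum K\,dA = 4\pi$) and the closed-form area to better than $10^{-8}$
  relative; trajectory output uses 501 grid points over the time span.
* **Curvatures**: closed-form spheroid principal curvatures;
  $\nabla^2 H$ fully analytic via the axisymmetric Laplace--Beltrami
  operator (validated against nested finite differences and a
  finite-difference shape operator to $10^{-4}$ relative).
* **Sphere limit**: the oblate area formula is $0/0$ at $a = c$; the code
  switches to the series limit at $|1 - c/a| < 10^{-8}$, continuously.
* **ODE integration**: `deSolve::ode` (`lsoda`), default tolerances
  $10^{-8}/10^{-10}$; halving them moves the saturated volume by far less
  than 0.1%.  Saturation is declared when the relative rate $|dV/dt|/V$
  stays below $10^{-8}\,s^{-1}$ for three consecutive output points after
  swelling has started (so an isotonic fixed point runs its full span).
* **Energy-min partition**: the inner 1-D search uses a 129-point coarse scan
  plus Brent refinement (tolerance $10^{-12}$); the volume constraint is
  eliminated in closed form, so the achieved volume matches the target to
  $10^{-10}$ relative.  The elastic work integrals have closed forms for
  $\beta = 0$ and $n_1 = 4$ (arctan), and fall back to adaptive quadrature
  otherwise.
* **Degenerate inputs**: non-positive axes, volumes, areas and mismatched
  species lists are rejected with named errors; prolate shapes warn but
  proceed; near-sphere inverse bending is flagged, never silently averaged.

## Known limitations

* The partition of one volume change into two axis deformations is a modelling
  choice, not derived physics; results in the nonlinear regime depend on the
  chosen rule (which is why it is surfaced in every config).
* The first-crossing scan in `saturation_state()` uses a 512-point bracket; a
  sign change confined to less than one grid interval could in principle be
  missed.
* $k_d$ is fundamentally unidentifiable from closed-surface shape data; it is
  recoverable here only through energy observations (see above).
* The inverse bending pressures scale linearly with $k_c$, whose physical
  value for a composite membrane (bilayer + embedded proteins + cytoskeleton
  coupling) is poorly constrained; the module treats $(k_c, k_d)$ strictly as
  inputs.
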