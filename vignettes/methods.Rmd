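---
title: "Models and methods: VWF margination in 2D blood flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: VWF margination in 2D blood flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vwfmarg)
```

## The problem

Von Willebrand factor (VWF) is a long multimeric blood protein that mediates
platelet adhesion at injured vessel walls. In equilibrium it is held in a
compact, globule-like shape by internal associations and is non-adhesive;
above a critical shear stress it unfolds and exposes its adhesive sites.
Whether a given VWF multimer can actually adhere in the microcirculation
therefore depends on two preconditions that must be met *simultaneously*:
the molecule has to be near the wall (margination), and it has to be locally
stretched there. Both are controlled by the flowing red blood cells (RBCs),
which migrate to the vessel centre, form a cell-free layer (RBC-FL) at the
walls, and expel other suspended species into it.

`vwfmarg` simulates this system in two dimensions with dissipative particle
dynamics (DPD) and measures the quantities that characterize it: the
margination probability $P$, the RBC-free-layer thickness
$\delta_{\mathrm{CFL}}$, the regional chain extension
$\langle R_s\rangle/L_{\mathrm{VWF}}$, per-bead adhesion *activity*, and the
potential-adhesion probability $\Psi$, organized into hematocrit/shear-rate
diagrams.

## Fluid model

The solvent is a standard DPD fluid: point particles interacting through
conservative, dissipative and random pair forces with the usual weight
functions,

$$ F^C = a\,(1 - r/r_c)\,\hat{e},\qquad
   F^D = -\gamma\, w_R^2(r)\,(\hat e\cdot v_{ij})\,\hat e,\qquad
   F^R = \sigma\, w_R(r)\,\xi_{ij}\,\Delta t^{-1/2}\,\hat e, $$

with $w_R = (1-r/r_c)^s$ and the fluctuation–dissipation relation
$\sigma^2 = 2\gamma k_BT$. Equations of motion are integrated with the
velocity-Verlet scheme. One simulation length unit corresponds to
1&nbsp;µm.

Fluid parameters are a package choice (the defaults of `dpd_params()` /
`channel_config()`): number density $\rho = 6\,/\mu m^2$, cutoff
$r_c = 1\,\mu m$, conservative amplitude $a = 25$ (in absolute energy/length
units, deliberately *not* rescaled with $k_BT$ so the fluid stays stiff at
low thermal energy), friction $\gamma = 4.5$, weight exponent $s = 1$, time
step $\Delta t = 0.005$. The measured dynamic viscosity under these defaults
is $\eta \approx 1.75$ at $k_BT = 1$ and $\eta \approx 6.3$ at $k_BT = 0.1$
(from the parabolic fit of a body-force-driven channel run,
`measure_viscosity()`); every run manifest records the parameters so each
published number can be traced. The random pair force uses one symmetric
unit-variance draw per pair per step from a counter-based generator keyed by
(seed, step, pair), making trajectories bit-reproducible and independent of
pair enumeration order.

Walls are slabs of frozen particles with the fluid's density and a
disordered structure, one cutoff thick, beyond the planes $y = 0$ and
$y = W$; their interactions with everything mobile are identical in form to
fluid–fluid interactions. Mobile particles that cross a wall plane are
bounced back (mirrored, full velocity reversal). Because frozen-particle
walls alone leave a small residual slip, a tangential adaptive shear force
acts on fluid particles within one cutoff of each wall: a proportional
controller measures the extrapolated wall velocity over an interval and
increments a uniform counter-force. Together these enforce no-slip to
within a few percent of the centreline velocity.

## Suspended structures

**RBCs** are closed bead-spring rings (`rbc_params()`): $N_v = 50$ vertices,
circumference $L_0 = 19.22\,\mu m$, effective diameter $D_r = L_0/\pi$.
Springs connect neighbours ($N_s = N_v$); their form is a worm-like-chain
attraction balanced by an inverse-power repulsion ($k_p/r$), the common
choice in this model family, with maximum extension $l_m/l_0 = 2.2$ and
persistence length $p = l_0/4$ by default (a plain harmonic spring is
available for tests — the original 2D ring reference does not restate its
exact spring form, so the stiffness scale is a package default). Bending
rigidity $U_b = k_b\,(1 - \cos(\theta - \theta_0))$ acts on every angle
between neighbouring springs with $k_b = 50\,k_BT$ and spontaneous angle
$\theta_0 = 0$; a global area constraint
$U_A = k_a (A - A_0)^2 / (2 A_0)$ with $k_a = 17640\,k_BT/D_r^2$ preserves
the enclosed (shoelace) area. The 2D target area is set through the reduced
area $A_0 / (\pi (L_0/2\pi)^2) = 0.48$, a biconcave-like cross-section,
giving $A_0 \approx 14.1\,\mu m^2$; this value is never printed in the
source literature and is exposed in the configuration. Aggregation
interactions between RBCs are not modelled (they matter only at shear rates
too low for VWF stretching); distinct cells and cell–chain pairs interact
through a purely repulsive truncated-shifted Lennard-Jones (WCA) potential
that prevents overlap.

**VWF** is a linear bead-spring chain (`chain_params()`): harmonic bonds
with stiffness $k_s = 400\,k_BT a_m^{-2}$ and equilibrium length
$l_b = 0.6\,\mu m$ ($a_m = l_b/2$), plus a Lennard-Jones pair interaction
between non-bonded beads of the same chain with $\sigma = l_b$ and
$\varepsilon = 4\,k_BT$ — the depth that reproduces the experimentally
observed critical shear rate for VWF stretching. The *attractive* (VWF)
mode uses the full 12-6 potential cut at $2.5\sigma$ and shifted to zero
there; the *repulsive* control polymer truncates at the minimum
$2^{1/6}\sigma$ (self-avoiding, no internal associations). Directly bonded
neighbours are excluded from the LJ sum (the bond term governs them; the
overlap at $\sigma = l_b$ would otherwise be double-counted). The contour
length is $L_{\mathrm{VWF}} = (N-1)\,l_b$: 15&nbsp;µm for $N = 26$,
9.6&nbsp;µm for $N = 17$, 24.6&nbsp;µm for $N = 42$.

Fluid–structure coupling is purely frictional: membrane vertices and chain
beads interact with fluid (and wall) particles through the dissipative and
random DPD forces only, with a larger friction $\gamma_{fs} = 3\gamma$ so
the structures follow the local flow closely. There is no conservative
fluid–structure force; excluded volume acts only between structures.

## Channel assembly

`channel_config()` + `run_channel()` assemble the standard setup: a slit of
width $W = 20\,\mu m$ and length $L = 28.6\,D_r$ (periodic in $x$), a body
force $g$ on all mobile particles driving the flow, $N_{\mathrm{VWF}} = 6$
chains, and RBCs at the target hematocrit
($n_{\mathrm{RBC}} = \mathrm{round}(H_t W L / A_0)$, $H_t$ being the RBC
*area* fraction in 2D). Because $H_t = 0.5$ is close to the jamming
fraction of random sequential placement, cells are initialized on a
staggered, jittered lattice of ellipses matched to $(L_0, A_0)$ and relaxed
with damped membrane dynamics under force capping before the fluid is
added; the realized hematocrit lands within 2% of the target. Chains start
as compact Archimedean-spiral coils (bond length preserved, turns one
$\sigma$ apart).

Two initial-condition helpers shorten transients in scaled-down runs and
are plainly recorded in the manifest: the fluid velocity field can start at
the expected parabola (`init_flow = "parabola"`), and chains can start
*stratified* — compact coils at the RBC-core edge near each wall and at
the centreline, with both polymer modes represented at every height
(`chain_init = "stratified"`). The stratified start approaches the
stationary cross-stream distribution from both sides: the edge chains
probe the discriminating mechanism directly (collisions with the RBC core
displace the softer repulsive chain centreward while the compact globule
persists near the wall), and the centreline chains sample the low-shear
core.

## Flow measurement and scales

`velocity_profile()` bins the axial fluid velocity across the width;
$\bar v$ is the equal-bin mean and the pseudo-shear rate is
$\bar{\dot\gamma} = \bar v / W$. `wall_shear_rate()` estimates the wall
gradient $\dot\gamma_w$: the default fits a local parabola over a window
offset half a micrometre from the wall (excluding the thin layer where
particle walls distort the binned profile) and evaluates its derivative
*at the wall plane* — exact for parabolic flow. A plain linear window fit
is also provided; note that for a curved profile the straight-line slope
estimates the gradient at the window centre, which biases the Newtonian
ratio $\dot\gamma_w/\bar{\dot\gamma} = 6$ low by $2\bar y/W \approx 5\%$
for a 1&nbsp;µm window — more than the tolerance of the package's own
Newtonian validation, which is why the curvature-corrected fit is the
default. For Newtonian parabolic flow $\dot\gamma_w = 6\bar{\dot\gamma}$ in
a 2D slit and $8\bar{\dot\gamma}$ in a 3D tube (`poiseuille_reference()`);
suspensions push the ratio higher.

Flow strength is reported as the non-dimensional shear rate
$\dot\gamma^* = \bar{\dot\gamma}\,\tau_{\mathrm{RBC}}$ with
$\tau_{\mathrm{RBC}} = \eta D_r^3/\kappa_r$. Physiologically
(`rbc_relaxation_time()`: $\eta = 1.2$ mPa s, $D_r = \sqrt{A_0/\pi}$ with
$A_0 = 133\,\mu m^2$, $\kappa_r = 70\,k_BT$ at 310 K) this gives
$\tau_{\mathrm{RBC}} \approx 1.10$ s, so $\bar{\dot\gamma}$ in 1/s and
$\dot\gamma^*$ are roughly equal in magnitude. The literature also implies
a slightly smaller conversion ($\dot\gamma^*/\bar{\dot\gamma}\approx 0.96$
s in some figure annotations); both numbers are exposed and nothing in the
package silently prefers one. In model units the package uses the measured
$\eta$, $D_r = L_0/\pi$ and $\kappa_r = k_b = 50\,k_BT$; blood-channel runs
use $k_BT = 0.1$ because with $\kappa_r$ pinned to $50\,k_BT$ by the ring
model, moderate $\dot\gamma^*$ at subsonic Mach number requires flow
stresses well above the thermal scale.

## Observables

* **COM distributions** (`com_distribution()`): per-snapshot structure
  centres of mass binned across the width, normalized to integrate to 1.
* **RBC-free layer** (`rbc_free_layer()`): per snapshot and axial bin
  (width $D_r/2$), the distance from each wall to the nearest RBC membrane
  particle, averaged over bins, snapshots and walls. Without RBCs it is
  defined as $W/2$ and flagged.
* **Margination probability** (`margination_probability()`): the fraction
  of chain-snapshots whose COM lies within $\delta = 2\,\mu m$ of either
  wall (the range of potential VWF adhesion; the choice scales $P$ but not
  its ordering across conditions), with a bootstrap standard error over
  snapshots.
* **Regional stretch** (`regional_stretch()`): each chain-snapshot is
  assigned to the RBC-FL or the core and the flow-direction extension
  $R_s$ (max minus min bead coordinate after periodic unwrapping) is
  normalized by $L_{\mathrm{VWF}}$. The default assignment compares the
  COM wall distance with the *time-averaged* $\delta_{\mathrm{CFL}}$; an
  instantaneous option compares with the locally nearest RBC in the
  chain's axial bin instead. In short scaled-down runs the time-averaged
  edge ($\approx 1.3\,\mu m$ at 2D $H_t = 0.5$) is narrower than the
  pockets chains actually occupy, so the acceptance runs use the
  instantaneous rule; empty regions are flagged, never zero-filled.
* **Bead activity** (`bead_activity()`): a bead is active — its adhesive
  sites exposed — if no non-bonded bead of its chain lies within
  $R_{\mathrm{thres}} = 1.2\,l_b$ *and*, for interior beads, its two bonds
  make an angle above $\theta_{\mathrm{thres}} = 130^\circ$ (end beads are
  exempt from the angle condition only; the radius condition still
  applies). The threshold angle is interpreted in degrees. Activity is
  evaluated against beads of the same chain (the rule describes local
  stretching of one molecule).
* **Potential-adhesion probability** (`adhesion_potential()`):
  $\Psi = \sum_i N^i_{\mathrm{act}} / (N_{\mathrm{tot}} N_{\mathrm{time}})$,
  counting beads that are both active and within
  $\delta_{\mathrm{adhes}} = 1\,\mu m$ of a wall. $\Psi$ scores the
  *convolution* of margination and stretching; mapping it to an absolute
  adhesion rate (multiplying by a bond-formation rate) is deliberately out
  of scope.
* **Diagrams** (`assemble_diagram()`): observable values on scattered
  $(H_t, \dot\gamma^*)$ nodes with piecewise-linear (barycentric)
  interpolation — exact at nodes, no overshoot beyond the node range.

## Calibration scan

`shear_stretch_scan()` reproduces the qualitative single-chain calibration:
one chain in unbounded simple shear, coupled to the linear background flow
$v_x = \dot\gamma y$ through inertial Langevin (BAOAB) dynamics — a
free-draining solvent coupling, chosen over an explicit DPD solvent because
the calibration curve is qualitative and the free-draining chain already
shows the globule–stretch transition. At rest the attractive chain stays
collapsed ($\langle R_s\rangle/L_{\mathrm{VWF}} \approx 0.2$,
$R_g \approx 1.25\,\mu m$ for $N = 26$) while the repulsive chain is a
swollen coil ($R_g \approx 2.3\,\mu m$); with increasing shear both extend
monotonically, the repulsive one at much lower rates. The time step is
capped at $0.01/\dot\gamma$ so relative advection per step stays well below
a bead diameter; at very high rates bonds stretch visibly and
$R_s/L_{\mathrm{VWF}}$ can exceed one — real extensibility of the harmonic
backbone, not an artifact.

## What the scaled-down runs do and do not show

Test and acceptance runs are deliberately small: the Newtonian validation
uses $\sim 5\times10^3$ particles and a few times $10^4$ steps; the blood
runs use $H_t = 0.5$, $L = 15 D_r$ ($\approx 1.5\times10^4$ particles),
$11000 + 25000$ steps at $\Delta t = 0.005$ ($t = 180$, total strain
$\approx 17$) at $\dot\gamma^* \approx 27$, three seeds, with 3 attractive
and 3 repulsive chains sharing one suspension (a matched-pairs design: both
modes see the same RBC environment, which sharpens ordering comparisons at
half the compute). These runs resolve *orderings* — $P(\mathrm{VWF}) >
P(\mathrm{repulsive})$, FL stretch $>$ core stretch, extension increasing
with shear — not converged heat-map values, which require cluster-scale
sampling of the full $(H_t, \dot\gamma^*)$ grid. The synthetic fixture
scenes exercise the observables exactly but are static geometry: they
validate counting and thresholds, not dynamics. None of the 2D runs should
be read as quantitative 3D predictions; hematocrit in 2D maps to a lower
3D hematocrit at equal RBC-FL thickness.

## Numerical choices and degenerate inputs

Cell-list neighbour search at the DPD cutoff with minimum-image convention;
intra-chain attractive LJ pairs (cutoff $2.5\sigma > r_c$) are summed
directly per chain. Coincident particles raise a degenerate-pair error;
zero-length bonds and bending triples raise geometry errors; exceeding the
WLC maximum spring extension raises an extension-overflow error at the API
level, while inside the integrator the WLC force switches to a linear
continuation beyond $x = 0.95$ so capped-force overlap relaxation cannot
abort on a transient overshoot. The temperature guard compares an
exponentially smoothed kinetic-temperature estimate (from the wall-normal
velocity component, which carries no mean flow) against the target and can
warn or abort. Interpolation queries outside the diagram's node hull return
`NA` rather than extrapolating. The placement lattice refuses hematocrits
it cannot seat (`overcrowding` error) rather than silently under-filling.

## Known limitations

Two-dimensional hydrodynamics (no out-of-plane tumbling or orbits), a
free-draining calibration scan, frictional (no-conservative) fluid-structure
coupling with a fixed $\gamma_{fs}$ rather than a per-setup no-slip
calibration, no explicit adhesion-bond kinetics (the package scores
*potential* adhesion only, as the underlying analysis does), no RBC
aggregation, and fluid parameters standing in for an unavailable
supplementary table — exposed in configuration and reported in manifests so
that every published number carries its provenance.
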