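---
title: "Modeling 3D tumor growth, angiogenesis and chemotherapy with oncovasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling 3D tumor growth, angiogenesis and chemotherapy with oncovasc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`oncovasc` simulates the progression of a small solid tumor from five seed
cells through avascular growth, quiescence and necrosis, angiogenic rescue,
and cytotoxic chemotherapy, on a regular 3D lattice representing a 1 cm cube
of tissue. It is a hybrid model: tumor cells and endothelial (vessel)
segments are discrete lattice agents, while interstitial pressure, oxygen,
carbon dioxide, tumor angiogenesis factor (TAF) and drug are continuum
fields advanced by explicit finite differences. One iteration represents
1/33 of a day, so a full 60-day course is 1980 iterations.

### Interstitial pressure (growth pressurization)

Tumor pressure is built from Gaussian-like kernels rather than a mechanical
constitutive law. At every lattice point $X_0$ the cell-induced tumor
pressure is

$$\mathrm{CTP}(X_0) = \sum_{i}\rho(\theta^c)\,
  \exp\!\left(-\frac{\lVert X_i - X_0\rVert^2}{2\lambda(\theta^c)^2}\right),$$

summing over tumor cells $X_i$ within the Chebyshev $K$-cube of $X_0$
(default $K = 3$). $\theta^c$ is the occupancy fraction of the
$(2K+1)^3$-point cube centred on $X_0$, with the nominal denominator kept at
the boundary (outside points hold no cells). The density maps default to
$\rho(\theta) = \rho_{\max}\theta$ and
$\lambda(\theta) = \lambda_{\min} + (\lambda_{\max}-\lambda_{\min})\theta$
(widths in lattice units, defaults 1 and 3): denser tissue pushes harder and
further. $\rho_{\max}$ is calibrated at initialisation so that a fully dense
core reaches the configured tumor pressure `p_tumor` (60 mmHg by default),
preserving the published pressure scale while leaving the kernel shape
config-exposed. A structurally identical vasculature-induced term (VTP) sums
over endothelial segments with amplitude `rho_max_v_frac * rho_max` and the
endothelial occupancy fraction; the interstitial pressure is
$p_i = \mathrm{CTP} + \mathrm{VTP}$. Two conventions the underlying formulation leaves open are fixed here: $\theta$ is evaluated at the target
point $X_0$, not at each contributing cell, and kernel distances are
Euclidean in lattice units.

Interstitial fluid moves by Darcy's law, $u = -k\nabla p_i$, with central
differences in the interior and one-sided differences at the faces.

### Mass transport

Each continuum species obeys

$$\partial_t\varphi = D\nabla^2\varphi - \nabla\!\cdot\!(u\varphi)
  + \text{source} - \text{sink},$$

discretised with a 7-point Laplacian, conservative first-order upwind fluxes
(face velocities are arithmetic means of the adjacent cell-centred Darcy
velocities; no flux crosses the domain boundary), Dirichlet values reset on
all six faces after each sub-step (a species' boundary value may instead be
set to `NA` for a zero-flux closure), and explicit Euler time stepping. A step
is split into the smallest $m$ with
$(\Delta t/m)(6D/h^2 + \sum|u|_{\max}/h) \le 1/2$. Upwinding can undershoot
zero near sharp sinks; negative values are clipped to zero and the removed
mass is accumulated in the state diagnostics rather than silently discarded.

Concentrations are normalised by the standard concentrations
($n_0 = 8.4$, $w_0 = 10.5$ mol/m³, $c_0 = 4.3\times10^{-4}$ kg/m³,
$d_0 = 2.13$ mol/m³); the published rate table mixes mol/(m³ s) supply rates
with ml/(cm³ s) consumption rates, which are reconciled in one documented
pass: supply and secretion rates are divided by the species' standard
concentration, consumption and decay rates (a volume fraction per second)
are used directly as first-order rates, and everything is multiplied by the
2618 s step.

The exchange terms follow the indicator structure of the model: oxygen is
supplied only at vessel voxels, weighted by vessel maturity $R_i/R_{\max}$
and by the transmural pressure factor $\max(p_v - p_i, 0)/p_v$ (no supply
against an adverse gradient), and consumed at cell voxels in proportion to
activity; carbon dioxide mirrors this with secretion at cells and clearance
at vessels. The maturity weight on the vascular CO2 clearance is underdetermined in
the underlying formulation; it is taken equal to the oxygen supply weight, by
symmetry of the two vascular exchange processes. Oxygen supply additionally
carries the saturation headroom $\max(1 - n, 0)$, since wall exchange stops
at the plasma level. TAF is secreted by live cells with the hypoxia weight
$s(n) = \max(0, 1 - n/n_{\text{thr}})$ — the stated biology (hypoxic cells
secrete more) wins over a literal "proportional to oxygen" reading — with
the onset $n_{\text{thr}} = 0.5$ tying secretion to deep hypoxia just below
quiescence, so angiogenesis is induced by quiescent tumor tissue; secretion
also shuts off as the local field approaches `taf_saturation` (receptor
saturation), which bounds the branching drive. TAF removal, damped in
high-pressure regions as $p_v/(p_v+p)$, defaults to zero as published. The
TAF standard concentration is published as a mass concentration while its
secretion rate is molar; the two are reconciled with a 45 kDa molar mass
for the canonical angiogenic growth factor (`taf_molar_mass`).

### Cells: activity, vital energy, division

Cell activity uses double-Hill kinetics,
$A = \frac{n^{3}}{n^{3} + K_n^{3}}\cdot\frac{K_w^{4}}{w^{4} + K_w^{4}}$
with $K_n = 0.25$ and $K_w = 1.8$, so $A(1,1) \approx 0.90$ sits well above
the 0.5 active/quiescent threshold, $A$ increases with oxygen, decreases
with waste, and vanishes without oxygen. The switch-like oxygen response is
load-bearing: with a shallow (first-order) law the outermost cell monolayer
always sees slightly better oxygen than any quiescence point, and an
avascular tumor never stops expanding. The exact algebraic form and
constants are config-exposed.

The CVE cost curve doubles as a proliferation gate. With the default Hill
cost (coefficient 2, half-max 0.35, peak cost 0.716 of $k_{\text{active}}$)
the net CVE gain $k_{\text{active}}A - \mathrm{hill}(A)$ is positive only
for $A \gtrsim 0.6$: cells between the activity threshold (0.5) and the
gate (0.6) are alive and metabolically active but accumulate nothing toward
division, which is what turns a smooth decline in supply into a genuine
growth arrest rather than an ever-slower creep.

Cell vital energy (CVE) is the store a cell fills on its way to division.
Active cells gain $k_{\text{active}}A$ per step, pay the Hill-shaped
synthesis cost above, and lose $k_{\text{drug}}\,A\,d$ to cytotoxic damage;
quiescent cells pay the housekeeping drain $k_{\text{quiescent}} = 0.1$ plus
drug damage and gain nothing. Necrosis (CVE $\le 0$) is terminal; the
active/quiescent transition is reversible. The death condition is sometimes written against the activity symbol, but
CVE is the depletable store, so CVE $\le 0$ is the condition used here.

The division threshold is not a free parameter: it is calibrated at start-up
so that under pinned abundant conditions ($n = w = 1$, no drug) a newborn
cell — which starts at half its parent's pre-division CVE — needs exactly
`steps_per_day` iterations to refill, making the 24-hour cell cycle true by
construction. Daughters are placed on the 26-neighbour shell among free
voxels with probability softmax(pressure drop / `division_softness`): where
pressure differences dwarf the softness scale (1 mmHg by default) the
daughter goes to the steepest drop, where they are comparable, placement is
random. The softness matters twice. First, a strict argmax always points
radially outward from the cluster, and a tumor whose cycles are even
slightly staggered then grows as a diffuse gas-like cloud that never builds
core density or pressure; probabilistic placement, consistent with reading the
spatial transition as density-dependent probabilities, fills interior gaps and gives
compact tumors with dense cores. Second, it makes morphology sensitive to
the pressure *scale*: a tumor calibrated to 60 mmHg presents its daughters
sharper (more directional, more dendritic) placement odds than one
calibrated to 40 mmHg, which is the pressure–morphology effect the
sphericity analysis quantifies. With no free neighbour the division defers
and CVE caps at the threshold. A mitosis volume threshold mentioned
alongside the division rule is not modeled: division is CVE-gated only, and
no separate migration process exists — movement is entirely division-driven
displacement toward low pressure.

### Angiogenesis

Vessel tips migrate on the lattice toward TAF. Each tip accumulates advance
at `tip_rate * (g1 + g2 * max(p_v - p_i, 0)/p_v)` lattice steps per
iteration — `tip_rate_normal = 0.1` in normal tissue and
`tip_rate_tumor = 1/3` inside the tumor (published vessel growth-rate calibrations vary; these defaults are
config-exposed) — and
moves one voxel once the accumulator reaches one. The direction is sampled
among the six face neighbours with weights proportional to the positive
directional TAF derivative; necrotic and vessel-occupied voxels are
excluded. When no derivative is positive the tip samples uniformly among
admissible voxels instead of deadlocking, and it stalls only when no voxel
is admissible.

Branching uses sampled hotpoints: every vessel-adjacent point becomes a
hotpoint with probability $\min(1, k_{BH}\,c^{\alpha_{BH}})$
($k_{BH} = 3\times10^{-4}$, $\alpha_{BH} = 1.3$), and a segment adjacent to
a hotpoint spawns a new tip there, at most one branch per segment per step.
Sprouting also has a deterministic seed: when an activated vessel network
has no growing tip and TAF at some admissible vessel contact exceeds
`taf_sprout_threshold` (0.2), a tip cell is selected at the strongest
contact — the classic tip-cell selection step. Without it the first sprout
waits on a Bernoulli draw at probabilities of order $10^{-4}$ per site and
step, and whether angiogenic rescue arrives in time becomes a coin flip
across seeds.
Segments age one iteration at a time and mature as
$R(\text{age}) = R_{\max} k_{AR1}\,\text{age}/(k_{AR2} + \text{age})$
($k_{AR1} = 1$, $k_{AR2} = 500$, $R_{\max} = 10\ \mu$m), which feeds back
into oxygen supply and drug exchange through the maturity weight. Pruning
removes segments whose age reaches zero together with their distal subtree.
The source states the pruning rule but not the path to age zero; here a tip
stalled for `stall_steps` consecutive iterations ages backwards (loss of
perfusion), and segments overrun by the necrotic core are set to age zero
directly, which keeps vessels out of the dead centre of the tumor.

### Drug delivery and pharmacodynamics

Drug enters through vessel walls with both convective and diffusive
components. The Starling fluid flux per tissue volume is
$J_v = L_p (S/V)(p_v - p_i - \sigma_{\text{avg}}(\pi_v - \pi_e))$, with
$S/V = 2\pi R/h^2$ for a segment of radius $R$ in an $h$-voxel. The wall
Peclet number $Pe = J_v(1-\sigma_f)/(P_{\text{perm}}S/V)$ splits the
exchange into the convective part $(1-\sigma_f)J_v d_{\text{plasma}}$ and
the diffusive part
$P_{\text{perm}}(S/V)(d_{\text{plasma}} - d)\,Pe/(e^{Pe}-1)$, the Patlak
factor evaluated by series near $Pe = 0$ where its limit is 1 (and computed
with `expm1` elsewhere — the naive `exp(Pe) - 1` loses eight digits at
$Pe \sim 10^{-8}$). Negative net exchange (washout into the blood) is
clipped off by default and available behind `washout_enabled`. Interstitial
drug then diffuses and advects like the other species and is removed by
activity-linear cellular uptake plus first-order decay. Plasma concentration
is a constant-infusion schedule: zero before `drug_start_day` (day 40 of the
reference course), then the configured dose.

The cellular damage coefficient `k_drug` is not published. It is calibrated
once from the dose ladder the model is meant to reproduce: at the highest
reference dose (10 mol/m³, taking the interstitial level as half the
normalised plasma level) the damage term empties a full CVE reserve in about
5 days, while at 0.1 mol/m³ it cannot overcome the net CVE gain of an active
cell. This yields little suppression at low dose and outright kill at high
dose, with the intermediate dose in between.

## The per-iteration loop

Operator splitting runs in a fixed order: (1) pressure kernels and Darcy
velocity (every `k_press` steps); (2) transport of oxygen, CO2, TAF, drug;
(3) cell activity, CVE, phenotype, divisions (cells see end-of-transport
fields); (4) angiogenesis: tip advance, branching, aging/maturation,
necrotic exclusion, pruning; (5) bookkeeping. The update order is a design
choice of this package, and determinism is guaranteed by
drawing every stochastic decision (division tie-breaks and ordering, tip
directions, hotpoint Bernoullis) from the single seeded RNG in a documented
order.

## The desk-scale scenario

Development, tests and the bundled analyses use `desk_config()`: a 50³
lattice over the same 1 cm domain, 20 simulated days, the five-cell seed,
and one straight mature parent vessel spanning the domain at a 24% lateral
offset from the tumor. The scenario makes three kinds of adjustment, all
config-visible:

* **Resolution matching.** Diffusivities are multiplied by
  $(h/h_{\text{ref}})^2$ with $h_{\text{ref}} = 50\ \mu$m (the 200³
  spacing), keeping the per-voxel diffusion number $D\,\Delta t/h^2$ — and
  with it the per-voxel balance between a cell's consumption and diffusive
  resupply — identical to the fine-lattice reference.
* **Time compression.** The slow arms of the model — waste accumulation
  (`rho_w0`, `lambda_w0`), the TAF field (`rho_c0`, `D_c`) and vessel
  maturation (`k_AR2`) — are sped up threefold, mapping the 60-day
  reference course onto the 20-day horizon; oxygen metabolism and the
  24-hour cell cycle stay on the calendar. The dosing window is rescaled
  the same way (start day 13.5 of 20, mirroring day 40 of 60).
* **A finite tissue reservoir.** Metabolite boundaries are zero-flux
  instead of Dirichlet: the reference domain's faces sit many diffusion
  lengths from the tumor, so the small desk box must not behave as an
  infinite oxygen bath 18 voxels away (with close Dirichlet faces the
  tumor rim is externally fed forever and never arrests). The host tissue
  itself respires (`background_oxygen_consumption`, $7\times10^{-7}$/s),
  draining the unvascularised reservoir over about two weeks, so
  vasculature becomes the only sustainable oxygen source — which is
  exactly the supply structure of the model's exchange terms. The TAF
  background starts at zero so sprouting is induced by hypoxic tumor
  cells rather than a pre-existing uniform stimulus, matching the
  assumption that angiogenesis is triggered by tumor-cell quiescence.

Under this scenario the cell-count curve passes exponential growth (T1),
decelerating expansion (T2) and a hard, irreversible stasis (T3) as the
reservoir empties; renewed growth (T4) appears only when angiogenesis is
enabled, when TAF-guided sprouts deliver fresh supply and re-activate the
arrested rim. The stage detector is a sliding-window classifier on daily
totals (window 2 days): a window is stasis when absolute growth is within
1%/day of the current count, exponential when it grows relatively faster
than `r_exp = 0.05` per window *and* accelerates at least 1.4-fold over
the previous window, and linear when the absolute rate is positive and
roughly constant (the defining property of the expansion stage); T4 is
renewed growth after stasis. These tolerances are config-exposed.

What the generator does *not* emulate: real vascular geometry (the parent
fixture is a straight comb or axis, though measured networks can be loaded
from the CSV edge-list format), lymphatic drainage, mechanical tissue
deformation, cell migration and invasion, intravasation or metastasis, and
body-level pharmacokinetics (plasma concentration is a constant). Passing
tests therefore demonstrate internal consistency and the qualitative
phenomenology above, not calibration to any particular tumor.

## Numerical choices and degenerate inputs

* Explicit stepping with CFL sub-stepping; the uniform field at the
  Dirichlet value is an exact fixed point, and 1D steady diffusion
  reproduces the linear profile to $10^{-6}$.
* Concentration clipping at zero with mass logging (see above).
* Kernel evaluation uses the exact discreteness of the problem: the
  occupancy fraction takes $(2K+1)^3+1$ levels and squared distances at most
  $3K^2$ values, so weights are precomputed as a small table; results are
  bit-identical to direct evaluation and validated against a brute-force
  pairwise oracle to $10^{-10}$.
* Division with a fully occupied shell defers; a tip with no admissible
  neighbour stalls; an empty domain is a fixed point of the whole loop.
* Problem sizes in the test-suite: solver oracles run on 8³–12³ lattices,
  bookkeeping properties on ~10⁴ randomized events, and the phenomenology
  scenarios on the 50³/15–20-day desk scale described above, chosen so the
  whole suite completes on a laptop-class single core.

## Known limitations

* Several relations (the pressure kernels' density maps, the activity law,
  the CVE Hill constants, the tip growth-rate law, the radius–age map)
  are constrained only qualitatively in the literature this model builds
  on; all are implemented as simple monotone defaults
  with their parameters config-exposed, and the tests assert the contracts
  (monotonicity, bounds, saturation, calibration targets) rather than exact
  shapes.
* The whole-grid spatial mean is used for the sensitivity scan's output
  statistic; restricting to the tumor region is a plausible alternative the
  scan does not currently offer.
* First-order upwinding is diffusive; sharp drug fronts near vessels are
  smeared by about a voxel.
* The 26-neighbour division rule plus argmax placement imprints a mild
  lattice anisotropy on small tumors; it fades once counts reach a few
  thousand.
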