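---
title: "A compartmental model of aqueous humor secretion by the ciliary epithelium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental model of aqueous humor secretion by the ciliary epithelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquahumor)
```

## The model

Aqueous humor (AH) is secreted into the posterior chamber (PC) of the eye by
the ciliary epithelium (CE), a bilayer of pigmented and non-pigmented cells
joined by gap junctions that behaves as a single secretory layer. `aquahumor`
implements a lumped (0-dimensional) steady-state model of this process with
three compartments — stroma (s), cell (c) and posterior chamber (p) —
separated by the stromal membrane, the PC membrane and the tight junction
that links stroma and PC directly. The stroma is a fixed boundary condition;
everything on the PC side, including the water production rate itself, is
*predicted*, which is what makes the model able to say how secretion responds
when a specific channel or enzyme is inhibited.

Seven solutes are tracked in every compartment: Na+, K+, Cl-, HCO3-, H+,
CO2 and H2CO3, with concentrations `C_i^m` (mM, numerically equal to
mol/m^3) and compartment potentials `V^m` (mV, stroma grounded). The cell
additionally contains non-diffusible fixed charge at concentration `C_X`
with valence `z_X = -1.5`.

### Membrane transport

Every pathway is one of three functional forms.

* **Channels** (K+ on both membranes, Cl- on the PC membrane, and Na+, K+,
  Cl-, HCO3- through the tight junction) carry Goldman–Hodgkin–Katz
  constant-field electrodiffusion,
  `J = A P xi (C^m - C^k e^{-xi}) / (1 - e^{-xi})` with
  `xi = z F (V^m - V^k) / RT`. The removable singularity at `xi = 0` is
  handled by a first-order expansion below `|xi| < 1e-6`, and the flux tends
  to the Fickian limit `A P (C^m - C^k)` there (verified against a
  Nernst–Planck boundary-value oracle in the tests). CO2 and H2CO3 cross
  every membrane by simple diffusion.

* **Coupled transporters** (nkcc 1Na:1K:2Cl, the two anion exchangers
  aes/aep exchanging Cl- for HCO3- 1:1, nhe exchanging Na+ for H+ 1:1, and
  the two Na+/HCO3- cotransporters nbcs/nbcp with 1:2 stoichiometry) are
  driven by the logarithm of their thermodynamic mass-action quotient,
  `J = A P_k ln(Q_a/Q_b)`, with an additional `- F dV / RT` term for the
  nbc carriers, whose net charge is -1. This near-equilibrium linear
  flux–force form makes every transporter exactly antisymmetric under
  swapping its two sides and exactly stoichiometric, two properties the
  test suite asserts for random states.

* **The Na+-K+ ATPase** extrudes 3 Na+ and imports 2 K+ per cycle at rate
  `v = A P_pump (Na_c/(Na_c+K_Na))^3 (K_p/(K_p+K_K))^2`, the saturable
  Michaelis–Menten form standard in epithelial transport models, with
  `K_Na = 0.2071 (1 + K_c/8.33)` mM and `K_K = 0.1156 (1 + Na_p/18.5)` mM
  (see *Calibration*).

### Buffer chemistry

The solutes react through `HCO3- + H+ <-> H2CO3 <-> CO2 + H2O`. The first
step is effectively instantaneous and is imposed as the algebraic
equilibrium `C_H2CO3 = K_eq C_H C_HCO3` (`K_eq = 5.3` 1/mM, an association
constant). The second, slow step follows mass action,
`R_CO2 = k_d C_H2CO3 - k_h C_CO2`, with `k_d = 4.96e5` 1/s and
`k_h = 1.45e3` 1/s when carbonic anhydrase (CA) is active. CA inhibition
divides both constants by 1e6. With the imposed stromal pH 7.42 and
HCO3- 25 mM these equilibria put stromal CO2 at 1.72 mM (a physiological
value, and the effective pK of 6.26 lands on the accepted CO2/HCO3- value),
which is why the stromal minor species are *derived* from the printed
majors rather than imposed independently.

### The steady-state system

Eighteen unknowns — `C_1..7^c`, `C_1..7^p`, `C_X`, the water production
rate `Q`, `V^c` and `V^p` — satisfy, per compartment, the solute balances
`J_i^sc - J_i^cp + R_i^c = 0` and `J_i^cp + J_i^sp - Q C_i^p + R_i^p = 0`
(PC export is purely advective: the Péclet number of the PC outlet,
`Pe = U H / D ~ 600`, makes diffusion there negligible), water balances
`Q^sc = Q^cp` and `Q = Q^cp + Q^sp` with the osmotic law
`Q^mk = -A K sigma R T (sum_i C_i^m - sum_i C_i^k)` (the fixed charge
counts toward cell osmolarity), and electroneutrality of cell and PC.

The instantaneous first buffer step is eliminated by replacing the HCO3-,
H+ and H2CO3 balances with three combinations that do not contain its
rate: the difference of the HCO3- and H+ balances, total carbon
conservation, and the slow-step kinetic balance, plus the equilibrium
constraint itself. Exactly one row carries the (possibly enormous)
catalyzed reaction term, and that row is rescaled by
`J_ref + vol (k_d C7_ref + k_h C6_ref)` so the system stays well
conditioned whether CA is active or inhibited.

## Numerics

The solver works in transformed variables: log concentrations (which keeps
every concentration and `C_X` strictly positive), `Q/1e-11` and
`V/(RT/F)`. In these variables every transporter log-quotient is linear, and
the residual is emitted by a closure that folds all parameter products in
once — the 18-equation residual evaluates in ~0.1 ms, which is what makes
tens of thousands of ensemble solves cheap.

The root is found by a damped quasi-Newton method: a forward-difference
Jacobian is factored when needed and maintained by Broyden rank-1 updates
between refreshes. Step acceptance uses Deuflhard's affine-invariant
natural-level test (`||J^{-1} f||` must shrink) rather than the raw
residual norm: the water balances multiply osmolarity differences of order
0.1 mM against sums of order 300 mM, carving a narrow curved valley into
the residual landscape in which an ordinary line search stalls. Steps are
capped at 5 in log space. The default start is a physiological composition;
failed solves restart from seeded random perturbations of it. Warm-started
re-solves (as used along eFAST search curves) typically converge in under
ten iterations and a few milliseconds.

Two structural facts discovered while validating are worth recording.
First, electroneutrality plus charge-conserving reactions force only the
Kirchhoff node conditions `I_sc = I_cp` and `I_cp + I_sp = 0`; the
converged baseline carries a small *circulating* current
(stroma → cell → PC → tight junction, about 2% of `F P_pump A`), so "zero
current across each membrane" is not an invariant of this model class.
Second, because the uncatalyzed hydration left after dividing `k_d`, `k_h`
by 1e6 is not entirely negligible in the PC volume, inhibiting CA a second
time still lowers `Q` by a few percent — CA inhibition is a 10^6-fold
reduction, not a removal, of the pathway.

### Transient relaxation and stability

Stability of the algebraic root is verified by integrating a
time-dependent relaxation (deSolve/lsoda). The dynamic variables per
compartment are Na+, K+, Cl-, CO2 and the two invariants of the fast
buffer step, `B = HCO3 + H2CO3` and `W = H + H2CO3`; the equilibrium
splits them back at every instant. The potentials are algebraic unknowns
enforcing zero net current into cell and PC (a 2-variable inner Newton
solve), the water flux takes its instantaneous osmotic value, and `C_X`
is a conserved constant — consequently trajectories relax to the steady
state *belonging to their* `C_X`, and perturbation tests project initial
states back onto the electroneutrality constraint (adjusting Cl-) at the
root's `C_X`. Cell volume is `A_mem L = 6e-9` m^3 and PC volume
`A_pc H = 1.56e-7` m^3; the slowest relaxation mode is the PC washout,
with a time constant of roughly an hour, so stability runs integrate a few
multiples of that (default horizon 2e5–3e5 s).

## Calibration

All parameters except four are fixed independently (geometry, hydraulic
conductivities, gas permeabilities, rate constants, and the measured
channel permeabilities and transporter intensities). The two Na+/HCO3-
cotransporter intensities have no direct measurement, and the pump's two
leading Michaelis constants are only known to literature precision; these
four were calibrated once, by Nelder–Mead on weighted relative errors
against the reference composition, potentials and fluxes of both the
baseline and the CA-inhibited state, and then frozen:

| parameter | value | started from |
|---|---|---|
| `P_nbcp` | 1.423e-6 mol/m^2/s | order of `P_aep` |
| `P_nbcs` | 5.901e-7 mol/m^2/s | order of `P_aep` |
| `pump_K_Na0` | 0.2071 mM | 0.2 mM |
| `pump_K_K0` | 0.1156 mM | 0.1 mM |

With these values the baseline solve lands within ~10% of every reference
concentration, reproduces the transepithelial potential to 0.02 mV, the
water flux to 1.5%, and — with no further freedom — the CA-inhibited state
within ~5% and a 47% flux reduction against the reported ~45%. One
reported figure-level detail comes out quantitatively different: the nhe
throughput collapses ~17-fold under CA inhibition rather than ~6-fold;
the direction and the sign reversal of both nbc carriers are reproduced.

```{r baseline}
p <- default_parameters()
s <- stroma_state(p)
sol <- solve_steady_state(p, s)
sol
transepithelial_fluxes(sol)
```

## Global sensitivity analysis

The ten channel intensities/permeabilities (`P_pump` held fixed) are
varied within ±50% of baseline and their influence on `Q` and the PC
composition quantified with the extended Fourier Amplitude Sensitivity
Test (eFAST), implemented in the package: each target parameter in turn
oscillates along the search curve
`x = 1/2 + asin(sin(omega s + phi)) / pi` at the highest interference-free
frequency `omega_max = floor((Ns-1)/(2M))` (interference factor `M = 4`),
the others at complementary frequencies at most `omega_max/(2M)`; the
total-order index is one minus the share of output variance found below
`omega_max/2`, averaged over random-phase resample curves. Effect
directions are reported as the sign of the Spearman correlation across the
ensemble (total indices themselves are unsigned). Failed solves (none
occur at baseline settings) would exclude their whole curve, never be
imputed.

The estimator is validated against the Ishigami function's closed-form
total-order indices. That benchmark also documents an intrinsic eFAST
limitation: an index whose *complementary* set both interacts and is
crowded onto commensurate low frequencies (Ishigami's x2) has a
single-curve spread of ~0.16 and converges only through resample
averaging; a doubling-invariance check to ±0.02 is realistic only for
near-additive responses, and is tested on one.

Problem sizes: the shipped full-scale configuration is 5973 runs per
parameter (three resample curves of 1991 points, 59,730 solves, ~6 min on
one CPU). The reduced scale used by the tests and the acceptance script is
257 runs per parameter (2570 solves, ~12 s) for ensemble means, which are
robust at that scale, and 1285 runs per parameter (5 × 257) for the
influence *ranking*, because at 257 the spectral estimate cannot separate
ranks four and five (nkcc vs aes); at 1285 and at full scale the top four
parameters for `Q` are stably the PC-membrane K+ and Cl- permeabilities
and the nhe and nkcc intensities.

The same ±50% ensemble drives two in-silico experiments: the paired
CA-inhibition comparison (identical design solved with CA active and
inhibited; mean `Q` reduction ~43%) and the pump knockdown (each member
solved with `P_pump` at its value and at half; mean `Q` decrease ~27%).

## Degenerate inputs and guards

Concentrations entering log quotients are clamped at 1e-12 mM with a
warning, never silently. Negative permeabilities, areas or intensities are
parameter errors; `sigma` must lie in (0, 1]; `z_X` must be negative. The
stromal boundary must be electroneutral to 1e-3 mM of charge — the printed
major-ion row balances exactly, and the H+ implied by pH 7.42 contributes
only 4e-5 mM, which is why the tolerance is not tighter. Ensemble
evaluations abort if more than 25% of solves fail and warn above 5%.

## Known limitations

* No standing-gradient (local) osmosis in the lateral clefts; the model
  relies on the bulk osmolarity jump it predicts across the epithelium,
  which is why it mildly underestimates measured water flux.
* No coupling to ciliary blood flow, oxygen, or IOP; the model yields a
  production rate, not a pressure.
* Fixed compartment volumes (no cell-volume regulation); `C_X` is a
  concentration treated as an unknown of the steady state and a constant
  of the transient.
* Hydrostatic and oncotic pressure terms are omitted entirely (they are
  believed to approximately cancel); `sigma = 1` treats all membranes as
  ideally semipermeable, for gases as well as ions.
* The pump kinetic form and the two nbc intensities are calibrated, not
  measured; conclusions that hinge on their exact values (e.g. the nhe
  collapse factor under CA inhibition) inherit that uncertainty.
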