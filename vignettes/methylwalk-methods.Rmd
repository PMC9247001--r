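---
title: "Methods: structure-based methyl assignment with paramagnetic restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based methyl assignment with paramagnetic restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylwalk)
```

This vignette documents the models behind `methylwalk`, the assumptions
they rest on, the numerical choices made where the design was genuinely
open, and what the synthetic-data tests do and do not demonstrate about
real data.

## The assignment model

A methyl-TROSY HMQC spectrum gives one peak per labeled methyl; a
crystal structure gives the coordinates of every candidate probe. The
assignment problem is a constrained matching: within each residue type
(established beforehand from selectively labeled samples) the peak→probe
mapping must be injective, and a good mapping places NOE-connected peaks
on spatially close probes.

We score a mapping by **restraint violation counting**:

$$E = w_{noe}\sum_{e}{w_e\,[\,d(a_i,a_j) > c\,]} \;+\;
      w_{pcs}\sum_i |\delta^{obs}_i - \delta^{calc}_{a_i}| \;+\;
      w_{cs}(\cdot)$$

where $d$ is the carbon–carbon distance of the mapped probe pair, $c$
the NOE cut-off, and $w_e$ the edge weight. The energy of the true
mapping on ideal data generated at the same cut-off is exactly zero,
which makes the scheme verifiable against brute-force oracles — the test
suite checks the energy against an independent recount and the optimizer
against exhaustive permutation search on small problems.

Choices worth stating explicitly:

* **Inter-methyl distance** is measured between methyl *carbons* — one
  well-defined atom per probe, the convention of methyl-walk software.
  A pseudo-proton variant would change distances by fractions of an
  Angstrom, well inside the cut-off granularity.
* **Mutual NOE edges** (seen in both 4D directions) count with weight 1;
  one-sided edges count ½. One-sided peaks carry real information but
  are more often artefacts, so they are retained at half confidence
  rather than dropped or trusted fully.
* **Unassigned ends count as violations.** When peaks outnumber probes
  of a type (overlap), surplus peaks float; any NOE edge touching a
  floating peak counts as violated, pressuring the sampler to assign
  connected peaks first.
* **Chemical shifts are carried but neutralised** by default
  ($w_{cs} = 10^{-12}$): predicted methyl shifts are error-prone enough
  to cause misassignment, so they are de facto excluded while keeping
  the machinery in place.

### Sampling and consensus

`run_mmc()` anneals from a random type-respecting permutation:
within-type swaps and relocations to free probes, Metropolis acceptance,
geometric cooling over 50 levels from pseudo-temperature 5 to 0.01 in
energy units (violations), 20 000 proposals per trial by default. These
defaults converge well beyond the point where 20 independent trials
agree on problems of ~200 probes; all are exposed in `mmc_config()`.

A peak is only *consistently assigned* when **all** trials place it on
the same probe (unanimity; a relaxed quorum exists but is off by
default). The NOE cut-off is scanned (5–11 Å by default) and chosen to
maximise the consistent count, ties resolved toward the smallest
cut-off — a smaller cut-off imposes the stricter geometric constraint.

### Two protein states

Conformational change redistributes NOE contacts: probes isolated in
one state may be well-connected in the other, and overlapped peaks may
resolve. `combine_states()` runs each state's consensus independently,
transfers assignments that only one state established through the
titration-derived peak map, fixes them in the other state, and iterates
until the consistent sets stop growing. Iteration count is not limited
to one pass because transfers can cascade; each pass reuses the same
trial seeds so that successive passes differ only by the grown fixed
sets and the consistent sets can only widen. Transfers that contradict
the target state's own consistent assignment are reported as conflicts
and never overwrite anything; fixed peaks whose incident-edge violation
fraction exceeds 0.5 in the final state are flagged as suspect.

## Pseudocontact shifts

The PCS of a nucleus at offset $(x,y,z)$ from the metal is linear in the
five independent components of the traceless susceptibility-anisotropy
tensor (working unit $10^{-32}\,\mathrm{m^3}$; coordinates in Å; shifts
in ppm internally, Hz at I/O given the spectrometer frequency). This
linearity drives the fitting strategy: at a fixed metal position the
components are a linear least-squares solve; the metal coordinates are
then refined by BFGS over the profiled residual. Initialisation at a
crystallographic metal site displaced by a few Å recovers synthetic
truth tensors to well under 1% and the position to under 0.1 Å, which
the acceptance tests assert.

Only ¹H-dimension PCS enter fits; ¹³C shifts are stored but excluded
(lower resolution, larger residual anisotropy effects). Residual
anisotropic shift corrections (RACS/RADS) are *not* applied — a known
simplification; with methyl ¹H observables the correction is small
against typical fit residuals.

For ensembles the calculated PCS of a probe is the average over member
models, consistent with the ensemble Q factor

$$Q = \sqrt{\frac{\sum_i \left[\sum_m (a^{obs}_i - a^{calc}_{m,i})\right]^2}
{\sum_i \left[\sum_m a^{obs}_i\right]^2}}$$

which reduces to the standard Q for one model. Parameter uncertainties
come from bootstrap refits (1000 iterations, 80% subsampling by
default); underdetermined draws are skipped and counted.

**Unique tensor representation.** The traceless 3×3 form is
diagonalised; eigenvalues are ordered $|\chi_{zz}| \ge |\chi_{yy}| \ge
|\chi_{xx}|$, giving $\Delta\chi_{ax} = \chi_{zz} - (\chi_{xx} +
\chi_{yy})/2$ and $\Delta\chi_{rh} = \chi_{xx} - \chi_{yy}$ (so
$|\Delta\chi_{ax}| \ge \tfrac{3}{2}|\Delta\chi_{rh}|$ always holds), plus
ZYZ Euler angles of the eigenframe. Degenerate eigenvalues leave the
angles undefined and flagged, not silently zeroed.

**Opposite tensors.** PCS-based assignment expansion accepts a new
assignment only when at least two tensors of *opposite orientation*
agree on it. "Opposite" is operationalised as a negative Pearson
correlation between the PCS fields the tensors predict over the probe
set — the literature describes the idea only by example (Tb³⁺ vs Tm³⁺),
so a quantitative criterion had to be defined; field anticorrelation is
the property that actually makes joint agreement informative. The PCS
term enters those runs with weight 10, the conventional scaling that
puts PCS deviations on the same footing as the restraint counts.

## Paramagnetic relaxation enhancements

Rates come from exponential decay fits $I(t) = I_0 e^{-R_2 t}$ on the
interleaved delay grid (0, 6, 15, 25, 36, 50, 100 ms). Peaks below 3× the
spectral noise floor at the 6 ms delay are excluded — weaker peaks no
longer constrain the rate. Fit errors are one standard deviation over
Monte Carlo refits with noise-floor perturbations. The decay objective
is optimised by a simplex search seeded from a log-linear fit with a
BFGS polish: intensities can go negative under noise, so the log-linear
route alone is not robust.

$\Gamma_2 = R_{2,para} - R_{2,dia}$ feeds the SBM model with electron
parameters for Mn²⁺ ($S = 5/2$, $g = 2$, $\tau_s = 9.6$ ns at 600 MHz)
and the protein's rotational correlation time $\tau_r$ (an input, e.g.
from TRACT). Predicted rates are scaled by the **bound fraction** — the
equilibrium share of protein carrying the paramagnetic ternary complex,
computed by the binding module — because only that species relaxes
specifically. Γ₂ is predicted at the methyl carbon for the three
equivalent protons treated as one probe; an r⁻⁶-averaged proton variant
would differ by less than the typical experimental uncertainty at the
informative distances.

The metal position minimises the ensemble cost
$\sum_i [\sum_m(\Gamma^{obs}_{2,i} - \Gamma^{calc}_{2,m,i})]^2 /
S_{\Gamma_2,i}^2$ — implemented literally as printed, with the model sum
inside the square (a mean-over-models switch is a one-line change and
alters nothing at a single model). The surface is extremely stiff in
r⁻⁶ near probes: plain gradient steps diverge from starts a few Å off,
so every start (the initial guess plus 5 random restarts within 5 Å)
runs a Nelder–Mead simplex pre-optimisation before the BFGS polish.
Positional uncertainty is one SD over Monte Carlo refits at the stated
$S_{\Gamma_2}$.

**Curie-spin relaxation** is computed (standard expression,
$S^2(S+1)^2$ prefactor, rotational correlation time) purely as a
diagnostic ratio Curie/(Curie+SBM); it never enters fits. For Mn²⁺ at
600 MHz and 293 K it stays below ~6% across $\tau_r$ of 10–40 ns by this
expression. We note that smaller published estimates exist for this
share; since the expressions behind them are not always stated, the
package keeps the textbook form and treats the number only as a
negligibility check.

**Validation band.** PRE-based checks apply only to methyls 10–30 Å
from the metal: closer ones broaden beyond detection, farther ones carry
no signal above noise. Within the band, assigned peaks whose observed
Γ₂ deviates by more than 3 observation SDs are flagged; an unassigned
peak is proposed for an unassigned methyl only when exactly one in-band
candidate matches within that tolerance.

## The four-state binding model

Species U (ligand), M (metal), P (protein) couple through
$K_{D1}$ (U·M), $K_{D2}$ (U·P), $K_{D3}$ (UM·P), $K_{D4}$ (UP·M), with
the cycle $K_{D1}K_{D3} = K_{D2}K_{D4}$. The solver works on the three
mass balances with $UP = PU/K_{D2}$, $UM = UM/K_{D1}$,
$UMP = PUM/(K_{D2}K_{D4})$: damped Newton on log free concentrations
(positivity by construction, analytic Jacobian, residuals to $10^{-10}$
relative), with a nested-bisection fallback over free metal — the same
construction serves as the independent oracle in the tests, where 100
random parameter sets agree to $10^{-6}$ relative.

Constant handling follows the measurement reality: a missing $K_{D3}$
or $K_{D4}$ is filled through the cycle; where both are given but
inconsistent (the Mn case, whose $K_{D3}$ is borrowed from Mg), the
directly relevant $K_{D4}$ governs ternary-complex formation and the
cycle deviation is reported via provenance flags rather than hidden.
Tb/Tm, whose $K_{D1}$ is unmeasurable under strong PREs, use the mean
of the measured lanthanide $K_{D1}$ values. **Occupancy** is defined as
UMP/P_t (total protein in the denominator); the alternative denominator
(UTP-bound protein) gives a nearly identical number at these saturating
ligand ratios because >95% of protein is ligand-bound.

Sample planning solves the model over a grid of total metal and
recommends the largest metal concentration whose *free* metal stays
under a ceiling (default 80 µM, where unspecific surface PREs appear) —
occupancy rises monotonically with total metal, so the ceiling is the
binding constraint.

K_D fitting from titrations uses the closed-form two-state isotherm.
Peaks are selected by the endpoint rule (Euclidean CSP above
mean + 2 SD at the highest ligand point); the shared $K_D$ is profiled —
at each candidate $K_D$ the per-peak $\Delta\nu_{max}$ are exact linear
solves — reducing the global fit to a robust 1-D optimisation on
$\log K_D$. Errors are Monte Carlo SDs over refits at the residual (or
user-stated) noise.

## What the synthetic generator emulates — and what it does not

`make_two_state_toy()` places probes with hard-sphere packing (minimum
4 Å, nearest-neighbour spacing typically 5–8 Å) in a cube sized for
protein-like probe density, draws residue types in the proportions of
the 199-probe reference protein (43 Ala : 16 Ile : 50 Leu : 19 Met :
30 Thr : 41 Val), assigns chemical shifts inside literature-like
type-specific regions, and creates the second state by rotating a
spatially contiguous probe subset about a random axis — a rigid hinge
like a domain tilt. Peaks are kept separable by a minimum distance of
0.06 ppm in the scaled (δH, δC/5) metric by default, matching the
near-complete peak resolution achievable for well-behaved systems at
this probe count; setting `min_shift_sep = 0` re-enables overlap.
Cross-peak lists get per-direction dropout, false peaks, and optional
overlap merging; PCS/PRE/titration observables follow the forward models
plus Gaussian noise, all as pure functions of (parameters, seed).

What passing these tests shows: the estimators invert their own forward
models correctly, the sampler finds global optima it can be checked
against, and the multi-state logic yields strictly more assignments than
either state alone with zero false positives under unanimity. What it
does **not** show: robustness to spin diffusion and relaxation-pathway
artefacts in NOESY intensities, non-rigid conformational averaging,
peak-picking errors, or shift-region deviations in real spectra — none
of which the generator models.

## Problem sizes and numerical settings used by the tests

The suite runs toys of 8–50 probes with 2–20 Monte Carlo trials and
3000–4000 proposals per trial; bootstrap and Monte Carlo error loops use
40–200 iterations. These sizes keep the whole suite in the minutes
range on one CPU while staying large enough that every recovery check is
non-trivial (the end-to-end two-state fixture uses the full 50-probe,
10%-dropout configuration). The package defaults
(`mmc_config()`: 20 trials × 20 000 steps; 1000 bootstrap or Monte Carlo
iterations) are what an analysis of a ~200-probe protein would use.

Degenerate inputs are handled explicitly rather than by convention:
zero-distance PCS evaluation, all-zero observed vectors in Q factors,
empty methyl intersections, infeasible fixed assignments, flat PRE cost
landscapes and non-injective peak maps are all errors with messages;
degenerate tensor eigenvalues flag the Euler angles as undefined.

## Known limitations

* NOE information is used as binary contacts against a cut-off;
  intensity-based distance calibration is out of scope.
* RACS/RADS corrections and CSA tensors are omitted from PCS fits.
* The Curie-spin share is reported by the textbook expression only.
* Multi-chain structures require explicit chain selection; alternate
  locations keep the highest-occupancy conformer.
* The MMC energy is this package's own violation-counting definition —
  deliberately simple and oracle-checkable, not a port of any published
  program's unpublished energy function.
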