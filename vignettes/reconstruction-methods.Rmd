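---
title: "Methods: historical reconstruction of drinking-water VOC concentrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: historical reconstruction of drinking-water VOC concentrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarecon)
```

## The problem

Epidemiological studies of communities whose drinking water was contaminated
by volatile organic compounds (VOCs) decades ago need monthly mean
concentrations at the tap — yet measured water-quality data from the exposure
period are typically sparse (often a handful of samples per supply well) or
absent altogether.  Historical reconstruction fills the gap by simulation
constrained to what *was* recorded: well construction and service dates,
treatment-plant production, utility log books, source histories.  aquarecon
implements that chain of models as a tested, reusable pipeline, exercised
end-to-end on synthetic study areas whose structure mirrors the settings such
reconstructions are used in (a layered Coastal-Plain-style aquifer stack,
industrial solvent sources with documented onset months, supply wells mixed
at a water treatment plant, and a second distribution system that received
contaminated water only during intermittent interconnection events).

Every number the pipeline emits is on a monthly clock.  A value stamped
`1983-11` is the simulated state on the last day of November 1983 and is
interpreted as that month's mean.  Missing values are explicit `NA`s: a month
in which a well pumped no water is *unknown* at the tap, never "clean".

## Stage 1: groundwater flow

The flow model solves the confined groundwater-flow equation

$$ S_s \frac{\partial h}{\partial t} =
   \nabla \cdot (K \nabla h) + W $$

on a layered block-centred finite-difference grid (7-point stencil,
harmonic-mean intercell conductances).  Aquitard layers carry vertical
leakance only (conductance $K_v/b$ per unit area), the standard quasi-3-D
treatment of semi-confining units.  Streams are head-dependent boundaries
with fixed stage, $Q = C_s(z_s - h)$, one-way coupled.  All layers are
treated as confined (linear): at desk scale this keeps every solve a sparse
SPD factorisation and the verification suite exact; water-table nonlinearity
is deliberately out of scope.  Pumping at a multi-layer well is apportioned
across its screened layers by transmissivity share — the same fixed weights
later used to extract flow-weighted well concentrations, so flow and
transport agree by construction.

Transient solves use implicit Euler with monthly stress periods (rates
constant within a month) subdivided into equal sub-steps; the storage term is
$S_s b$ per unit area.  Budgets are accumulated per sub-step and must close:
the suite enforces a volumetric discrepancy below 0.5% on every period, and
verification includes the exact linear/parabolic 1-D profiles, a
grid-refinement study against a leakance closed form (observed order ≈ 2),
and transient drawdown against the Theis solution within 5% for radii of
2–10 cells, the Theis well function being computed by independent numerical
integration.

## Stage 2: solute transport

Dissolved-phase transport uses operator splitting per stress period:

1. **Advection** — explicit first-order upwind, automatically sub-stepped so
   every cell's Courant number stays ≤ 1.  Upwinding is chosen over
   higher-order schemes for monotonicity: it introduces numerical dispersion
   (≈ $v\,\Delta x/2$), which the verification tolerances absorb, but can
   never create new extrema or negative concentrations.
2. **Dispersion** — implicit finite-volume step with
   longitudinal/transverse decomposition
   ($D_L = \alpha_L |v| + D_m$, $D_T = \alpha_T |v| + D_m$; tensor
   cross-terms neglected), solved by Jacobi-preconditioned conjugate
   gradients on the SPD system.
3. **Reaction** — exact exponential decay $e^{-\lambda \Delta t / R}$.

Retardation $R$ divides the advective/dispersive time step and the decay
rate (effective-parameter scaling), so a no-flow decay test reduces to
$C(t) = C_0 e^{-\lambda t/R}$ exactly.  Sources are constant-concentration
cells active over an inclusive month window — the right representation when
source *concentrations and durations* are documented but release masses are
not — and are held fixed (Dirichlet-style) through every sub-operation.
Each VOC is simulated independently: no mixing terms, no degradation
by-products.  Verification: breakthrough against the Ogata–Banks closed form
within 5% at a grid Péclet number of 2, strict linearity in source strength,
mass conservation for a closed tracer system, and a monotone-scheme property
test on random fields.

The choice to weight multi-layer well extraction by *static* transmissivity
shares (rather than simulated transient layer fluxes) is fixed and
documented: it is the convention that keeps the flow solver's pumping
apportionment and the concentration extraction identical.

## Stage 3: well operations and WTP mixing

Monthly pumping schedules are reconstructed from what operations records
actually document — rated capacities, in/out-of-service dates and total
plant demand — by capacity-proportional allocation across the wells in
service:

$$ Q_i(m) = D(m)\,\frac{c_i}{\sum_{j \in \text{service}(m)} c_j}. $$

This is the minimal rule satisfying the documented constraints; alternative
policies can be injected through a strategy hook.  Months are atomic: a well
entering service mid-month is in service for that month.  Demand exceeding
in-service capacity is an error, not a silent re-normalisation.

Treated-water concentrations follow from a materials mass balance at the
plant, $C_{\mathrm{wtp}} = \sum_i Q_i C_i / \sum_i Q_i$, with no treatment
removal: the mixed value is taken to represent drinking water throughout the
service area.  The suite checks convexity, pumping-scale invariance, and
bit-for-bit agreement with a brute-force recomputation.  MCL exceedance is
strict (`> MCL`), and exceedance periods are maximal runs of consecutive
exceeding months, with missing months breaking runs.

## Stage 4: interconnection events

Transfers from the contaminated to the uncontaminated system were
intermittent, seasonal (April–August) and only partially logged.  The
package models monthly transfer occurrence as a two-state Markov chain,
fitted by maximum likelihood to documented consecutive-month pairs (pairs
spanning unknown months or season gaps are excluded; a transition row with
zero pairs is an error unless its state never appears documented, in which
case the row is inert).  Undocumented months are imputed by *exact bridge
sampling*: backward messages condition each unknown stretch on both
documented neighbours within its season, which is equivalent to enumerating
all compatible paths — and is unit-tested against explicit path enumeration
on up to three unknown months.  Seasons are independent chains (no
December-to-April memory): transfers were driven by seasonal demand, an
annually resetting condition.

A month with a transfer event contributes a duration-weighted mixture
$(h\,C_{\mathrm{on}} + (H-h)\,C_{\mathrm{off}})/H$, where $H$ is the hours
in the month and $h$ the transfer hours — documented where available,
otherwise a configured default (the default is a site parameter, 240 h in
the two-system template; historical logs rarely record event durations, so
no universal value is claimed).  The orchestration layer exploits linearity
of conservative network transport: the event scenario is simulated once at
unit source concentration and scaled by the month's upstream WTP value.

## Stage 5: network extended-period simulation

The receiving distribution system is simulated at hourly resolution during
events.  Hydraulics are demand-driven nodal continuity with Hazen–Williams
losses, solved by the global-gradient (Todini) iteration; the loss law is
linearised below 10^-3 m³/day so the Newton slope stays bounded at zero
flow.  Pumps add head along a curve $h_0 - rQ^2$; closed valves are removed
from the graph and stranded demand is a connectivity error.  The
contaminated upstream system is abstracted as a single fixed-head,
fixed-concentration reservoir.

Water quality is Lagrangian plug flow: ordered parcel queues in links,
complete instantaneous mixing at nodes, no decay (VOC loss over
hours-to-days in mains is negligible relative to monthly aggregation).
Adjacent parcels of equal concentration are merged, keeping queues compact
over long events.  Verification covers single-pipe travel-time delay,
flow-weighted junction mixing, symmetry, node-relabelling invariance, mass
balance within 0.5%, and saturation of every reachable area at the source
concentration for events much longer than the maximum travel time.

## Sensitivity and uncertainty

Any numeric field of the YAML configuration is addressable by dotted path,
either absolutely or as a multiplier.  One-at-a-time sweeps evaluate the
pipeline across a parameter's bounds (log-spaced for log-families), all else
nominal.  Monte Carlo propagation re-runs the full
flow → transport → mixing chain per realization — on the "small" template a
realization takes about 2 s, so batches of n = 200 complete at desk scale —
with Latin-hypercube sampling by default (each parameter's n draws occupy
each equal-probability stratum exactly once).  Failed realizations (e.g. a
capacity shortfall under an extreme demand draw) are recorded rather than
silently dropped, because dropped tails bias percentiles; more than 20%
failures aborts the batch.  Results are monthly 2.5/25/50/75/97.5
percentiles plus a one-number uncertainty ratio (97.5th/2.5th percentile at
the peak month).

## The synthetic-site generator and what passing tests mean

`generate_site()` builds the three study templates (industrial area with
multiple sources and wells; a landfill with one late-starting well over a
deep source; a two-system site adding the interconnection history and pipe
network).  The templates hard-code the *qualitative* structure —
7-layer aquifer/aquitard stack with aquifers at layers 1, 3, 5, 7; sources
up-gradient of wells switched on in a fixed January; a stream boundary that
bends plumes; a replacement well pair with disjoint service windows; 1–5
noisy samples per well; interconnection records documented for only a
fraction of season months — with synthetic parameter values chosen once as
field-plausible (100 m cells, aquifer $K_h$ 10–18 m/day, porosity 0.25,
recharge 3×10⁻⁴ m/day, source concentrations ~800–3000 µg/L, TCE
retardation 1.3).  One global seed fans out to per-component substreams via
a documented rule, so adding a component never perturbs another's draws.

`make_scenario_truth()` runs the site's own forward operators at finer time
resolution (3 sub-steps per month) to produce the truth that observation
noise, uncertainty bands and end-to-end reconstructions are judged against.
Because truth and reconstruction share the same operators (at different
resolutions), these harnesses demonstrate *self-consistency, calibration of
the imputation machinery, and numerical convergence* — not geological
realism.  Real applications face model-structure error, heterogeneity below
grid scale and archival data quality, none of which a synthetic site can
exhibit.

## Numerical choices and degenerate inputs

* Internal units are SI (m, day, m³/day, µg/L); US-unit configurations are
  converted once on load using exact legal factors.  Grid indexing is
  1-based with layer 1 at the top.
* Linear solves: sparse Cholesky for flow (one factorisation per distinct
  time-step length, reused across months); conjugate gradients at relative
  tolerance 10⁻¹⁰ for dispersion.
* The advection Courant sub-step count is capped (default 500/step);
  exceeding it raises a stability error rather than silently coarsening.
* Zero-pumping months yield `NA` well concentrations; an all-idle month
  yields an `NA` WTP value.  Zero demand in the network solver converges to
  the quiescent solution via the linearised loss law.
* Monte-Carlo coverage checks use an absolute slack of 10⁻⁶ µg/L so months
  that are identically zero on both sides (before any plume arrives) count
  as covered rather than as 0/0 comparisons.
* The chain-fitting pseudocount is 0 (pure ML) in `fit_chain()`; the
  orchestration layer passes 0.5 by default so a sparsely documented
  configuration still runs, and records that choice in its configuration.

## Known limitations

* Confined flow only; no water-table dynamics, no variably-saturated zone.
* No multiphase (LNAPL) transport: fuel-derived benzene migrating as free
  product is outside this model family.
* No parameter estimation: the historical calibration loop is represented
  by the residual report (`compute_residuals()`, fraction of head residuals
  within ±1.5 m) plus the OAT/uncertainty tooling and manual configuration
  edits — matching reconstruction practice, where calibration was
  expert-driven.
* Network templates are synthetic; real pipe inventories, demand patterns
  and tank storage are not reproduced (tanks are specified as an optional
  node type but absent from the v1 templates).
* The exposure table is structurally blinded: the package has no
  health-outcome inputs anywhere.
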