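---
title: "Models and methods in fluxslice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fluxslice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxslice)
```

fluxslice quantifies how much of a metabolite or lipid pool was made *de
novo* during a stable-isotope trace, and from which precursors, in systems —
such as cultured tumor tissue slices — where synthesis and salvage compete.
This vignette describes the models, their assumptions, the tunable
parameters, and the numerical choices, in the order the analysis chain runs
them.

## Mass isotopologue distributions

All quantities are built on the mass isotopologue distribution (MID): the
vector of mole fractions of a metabolite at nominal mass shifts M+0, M+1, …
Fractions are non-negative and sum to one; raw intensity vectors are
normalized on ingest, because every downstream quantity ("total fraction
labeled", fractional synthesis) is fractional. The algebra is deliberately
strict: negative fractions are rejected everywhere except inside the
natural-abundance correction, which is the one place negativity can
legitimately arise and is cleaned up; and vectors are zero-padded rather
than truncated (truncation that would discard more than 1e-6 mole fraction
is an error), because silent mass loss corrupts the mean-mass bookkeeping
used to validate convolutions.

Two facts drive everything else. First, the MID of a molecule assembled
from independent moieties is the convolution of the moiety MIDs. Second, a
pool that is partly pre-existing and partly newly made is a convex mixture
of an unlabeled point mass and the synthesis MID. `mid_convolve()`,
`mid_nfold_convolve()`, `mid_mixture()`, `mid_enrichment()` and
`mid_mean_shift()` implement exactly these operations and nothing more.

Only nominal-mass MIDs are supported: positional isotopomers and
ultra-high-resolution separation of equal-nominal-mass species are out of
scope.

## Natural isotope abundance correction

Measured spectra are contaminated by naturally occurring heavy isotopes of
*every* atom in the detected species — including derivatization atoms
(TBDMS silicon contributes a large envelope) and the unlabeled atoms of the
tracer element itself. `build_correction_matrix()` constructs, for each
analyte, a matrix whose column *j* is the natural-abundance spectrum of the
molecule with *j* tracer atoms forced labeled, shifted up by *j*. Rows
extend four shifts beyond the traceable-atom count to hold heavy-isotope
tails; tail mass beyond that is dropped and recorded on the model object.

`correct_mid()` inverts the matrix by least squares under a non-negativity
constraint (`pracma::lsqnonneg`), then renormalizes. Plain matrix inversion
produces negative fractions at low enrichment; the constrained solve
confines that cleanup to this one step. The residual norm is attached to
the result, and an ill-conditioned matrix raises a warning rather than an
error. The forward direction, `contaminate()`, is the same matrix applied
to a tracer-only MID and is what the synthetic-data generator uses, so the
correction is tested as a genuine round trip.

Isotope abundances (IUPAC values for C, H, N, O, S, Si, P) ship as data and
can be overridden from a CSV. Deuterium tracing reuses the same machinery
with hydrogen as the tracer element. The shipped metabolite dictionary uses
standard TBDMS / FAME fragment chemistry and intact lipid formulas; these
are documented reconstructions of typical fragments, replaceable via
`read_metabolite_dictionary()`.

## Isotopomer spectral analysis

Palmitate is condensed from eight 2-carbon acetyl units. With a uniformly
carbon-labeled tracer, each lipogenic unit is fully labeled with
probability `D` (the lipogenic acetyl-unit enrichment) or unlabeled, so a
newly made palmitate molecule follows a binomial over even mass shifts, and
the measured pool is

    MID = (1 - g) * delta(M+0) + g * [1-D, 0, D]^(x8)

where `g` is the fraction of the pool newly synthesized during the trace.
The acetyl unit has no M+1 component by default — correction has already
removed natural M+1, and a uniform tracer produces all-or-nothing units —
but an optional `unit_m1` exists for partially labeled tracers. Whether a
dilution or M+1 term belongs in any given experiment is left to the user;
neither is guessed as a default truth.

`isa_fit()` minimizes the weighted sum of squared residuals over all
replicates concurrently (residuals concatenated, never averaged into a mean
MID), with per-isotopologue SDs pooled across replicates and floored at
0.003 mole fraction — the floor is the community-standard MID error scale
and prevents zero-weight blowup when replicates coincide. Optimization is
bounded Levenberg–Marquardt on the residual vector from 20 Latin-hypercube
starts over the unit square (local seed, default 17), because the objective
can be multimodal near the boundary.

### Profile-likelihood confidence intervals

95% intervals are found by parameter continuation: step the parameter of
interest away from its estimate in increments of 0.01, re-optimizing all
other parameters at each step (warm-started from the previous step), until
the SSR crosses `SSR_min + qchisq(0.95, 1) = 3.841`; the crossing is then
refined by bisection to 1e-4. If the profile reaches a parameter bound
before crossing, the bound is the interval end (the clamping rule used for
parameters at 0 or 1). A profile that dips back below the threshold after
crossing is non-monotone; the scan then continues to the bound and the
widest crossing is reported with a warning. Two fitted conditions are
called significantly different exactly when their intervals do not overlap;
no t-tests are applied to fitted fluxes.

## Moiety-convolution lipid networks

Complex lipids are modeled as ordered lists of moieties: measured fixed
inputs (e.g. the ceramide or lactosylceramide pool feeding downstream
glycosphingolipids), parameterized precursor pools, or other species in the
network (the dependency graph must be acyclic). Precursors are assumed at
isotopic (pseudo-)steady state, so each species is an algebraic mixture

    species = (1 - g) * delta(M+0) + g * (moiety_1 (x) moiety_2 (x) ...)

Pre-existing material is unlabeled M+0 because correction has already
removed natural abundance. Pool units encode the biochemistry of what a
uniformly labeled hexose tracer can deliver: Glyc3P contributes M+3;
acetyl units M+2; hexose M+6; HexNAc M+6 or M+8 (hexose-only versus
hexose-plus-acetyl labeling); sialic acid M+9 or M+11; and the sphingoid
base carries a serine-derived M+2 unit (serine M+3 loses one carbon to
decarboxylation during sphinganine synthesis — that atom mapping is encoded
once, visibly, in the elongation preset).

Two presets ship. The elongation network covers LPC(16:0), LPC(24:0),
SM(34:1) and SM(42:1), with the 24:0 chain a latent pool elongated from the
measured 16:0 chain by four acetyl cycles. The glycosphingolipid network
covers LacCer, GM3 and Gb4 from measured ceramide and LacCer inputs; the
Gb3 intermediate is implicit (LacCer + hexose + HexNAc → Gb4 directly),
a documented reconstruction, and the sialic pool can equally be supplied
as a measured fixed input instead of free parameters by editing the pool
mode.

`network_fit()` shares the ISA machinery: joint weighted least squares
over every measured species and replicate, multistart Levenberg–Marquardt
(10 starts by default — the network objectives are better conditioned than
the ISA boundary cases), the same continuation intervals. Pools with two
labeled states (sialic, HexNAc) live on a simplex; a quadratic penalty
keeps the optimizer inside it. A parameter whose profile never crosses the
chi-square threshold anywhere in [0, 1] is flagged non-identifiable rather
than silently assigned an interval or an arbitrary point value.

`moiety_deconvolve()` is the generic constrained mixture solve used to
attribute nucleotide and nucleotide-sugar labeling to moieties (ribose
versus base, activated hexose versus nucleotide): non-negative least
squares over candidate basis MIDs with renormalization, warning on a
rank-deficient basis.

## Turnover calculations

For deuterated-water tracing, a fatty acid synthesized at body-water
enrichment `p` with `N` exchangeable hydrogens plateaus at a labeled
fraction `1 - (1 - p)^N`; the fraction newly synthesized is the measured
enrichment divided by that plateau, clamped to [0, 1] with a flag.
Enrichment means total labeled fraction (1 − M+0) for consistency with the
rest of the package; an M+1-only convention is available as a switch since
published variants differ and no claim is made about which variant any
particular external script used. `N` defaults to 22 for palmitate and is a
deliberate, logged configuration value per fatty acid — hiding it would
make results irreproducible. Body-water enrichment comes from an external
acetone-exchange standard curve (`calibrate_d2o()`, ordinary least squares
on at least three standards, inverted for samples); physiological modeling
of body-water kinetics is out of scope, `p` is taken as measured.

Biomass fractional synthesis is the ratio of a monomer's enrichment in
hydrolyzed biomass to its free-pool enrichment; a ratio above 1 is flagged,
not clamped, and a zero free pool is an error with guidance. At 25 mM
medium glucose, glucose in biomass plausibly reflects glycogen synthesis;
this is a reporting caveat, not a numerical correction.

## The synthetic-data generator

`generate_synth()` forward-simulates complete datasets through the same
public operations the fitters use — `isa_simulate()`,
`species_synth_mid()`, `contaminate()` — so generator and fitter
disagreeing indicates a real bug, not drift between two copies of the
model. Defaults mirror the study design the package targets: three
replicate slices per condition, additive Gaussian noise of 0.003 mole
fraction per isotopologue (clipped at 0 and renormalized), corrected MIDs
emitted alongside raw spectra contaminated through the per-analyte
correction matrices, and every scenario containing a boundary case (a
zero-synthesis pool) whose upstream enrichment is structurally
unidentifiable, for negative-path testing. Ground-truth values (e.g.
palmitate `D = 0.5`, `g = 0.2`; GM3 synthesis 0.4 on a 90%-enriched hexose
and 70/10% sialic pool; body water at 4.5% with a lipogenic liver and a
salvage-dominated tumor) were chosen once as representative of the
labeling regimes the models target and are not tuned.

What the generator does *not* emulate: chromatographic artifacts,
integration error, analyte-dependent noise scales, between-slice biological
heterogeneity beyond i.i.d. Gaussian noise, and isotopic non-steady state.
Passing recovery tests therefore demonstrates correctness of the estimation
chain under its own assumptions, not robustness to real-data pathologies.

## Numerical choices and problem sizes

Multistart counts (20 for ISA, 10 for networks), the continuation step
(0.01, bisection to 1e-4), the SD floor (0.003), and the correction-matrix
tail (4 shifts) are the package-wide defaults discussed above. Simulation
studies in the test suite and acceptance script use 200 replicate datasets
per study — enough to estimate a 95% coverage probability to about ±1.5%
— with three replicates each, and exact-recovery checks use noiseless data
with tolerance 1e-6. The test suite completes in a few minutes on a single
core.

## Known limitations

Clipping noisy MIDs at zero and renormalizing — unavoidable for
compositional data with structural zeros, such as the odd shifts of an
even-unit polymer — adds a small spurious positive mass (about
`noise_sd / sqrt(2*pi)` per structural zero) and scales true fractions
down. At the default noise level this biases fractional-synthesis
estimates upward by roughly +0.004 to +0.009, well inside the estimators'
bias tolerances but *comparable to the width of the profile-likelihood
intervals*, which are extremely tight when replicate agreement is good.
Consequently the nominal 95% intervals under-cover `g`-type parameters in
simulation (roughly 30–60% observed coverage at `noise_sd = 0.003`),
while `D` is essentially unaffected. This is a property of non-negative
compositional noise itself — it persists when noise is injected at the raw
stage and propagated through the constrained correction — and users should
read very tight profile intervals on fractional-synthesis parameters as
optimistic. Widening the error model or debiasing the renormalization
would trade transparency for calibration and is deliberately not done.

Other limitations: fits assume isotopic pseudo-steady state (no kinetic
trajectory fitting; each time point is fit independently); bulk-tissue
MIDs mix cell-type-specific fluxes that cannot be deconvolved here; and
the shipped fragment formulas are reconstructions that should be replaced
with instrument-verified ones for real data.
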