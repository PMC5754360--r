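---
title: "Methods: the dilution-fixation model of spore memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dilution-fixation model of spore memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporememory)
```

## The scientific problem

When a *Bacillus subtilis* microcolony runs out of nutrients, its cells do
not sporulate synchronously: a first wave of spores forms within roughly
10–20 h of the downshift, and a second wave follows hours later. These
"early" and "late" spores are genetically identical, yet they revive very
differently when nutrients return — early spores germinate about twice as
fast, and essentially only early spores manage l-alanine-induced outgrowth.

`sporememory` implements a quantitative account of this phenotypic memory:
a revival-limiting enzyme (alanine dehydrogenase is the concrete example)
stops being produced at the nutrient downshift; continued growth then
dilutes it, and whatever concentration remains at the moment of sporulation
is fixed into the spore. Sporulation timing is thereby written into spore
composition, and spore composition determines revival capacity.

## The kinetic model

Cells start in a naive state $c_0$, progress at rate $\eta$ through $k$
intermediate states $c_1,\dots,c_k$ into a starved state $c_s$, grow
(divide) at rate $\lambda$, and die at rate $\mu$ in the starved state
only. Sporulation occurs at rate $\delta$ from $c_1,\dots,c_k$ and $c_s$
(not from $c_0$). Occupancies are normalized per initial cell, with
$c_0(0) = 1$. Because enzyme production stops at $t = 0$ while biomass
keeps growing, the per-cell enzyme concentration is
$e(t) = \exp(-\lambda t)$, and a spore formed at time $t$ carries exactly
that level.

Three quantities summarise the outcome:

* **spore quantity** $s = \int_0^\infty r(t)\,dt$ with spore-formation
  rate $r(t) = \delta\,(\sum_{i\ge 1} c_i(t) + c_s(t))$;
* **spore quality** $\bar e = \frac{1}{s}\int_0^\infty e(t)\,r(t)\,dt$;
* the **enzyme-level density** $\rho(e) = r(-\ln e/\lambda)/(\lambda e s)$
  on $(0, 1]$, obtained by the change of variable $e = \exp(-\lambda t)$.

### The two variants

The package exposes two readings of the state equations, selected by
`model_params(variant = )`:

* **`as_written`** treats sporulation as a pure *marking* process: spores
  are counted at rate $\delta$ but the sporulating cell is not removed
  from the vegetative pool. Under this reading $\delta$ factors out of
  both integrals, so the yield is exactly linear in $\delta$ and the mean
  enzyme level does not depend on it at all (a documented, tested property).
* **`depleting`** (the default) removes the cell upon sporulation, adding
  a $-\delta c$ loss to each sporulation-competent state. This is the
  physically consistent branching interpretation — a cell that has become a
  spore can no longer divide or progress — and it is the variant under
  which a faster sporulation rate genuinely trades spore quantity against
  spore quality. It is also the variant realized naturally by the
  stochastic simulator.

Both variants are first-class citizens: the marking form is retained for
fidelity to the linear state equations as commonly written, the depleting
form because only it couples $\delta$ to quality. The packaged tradeoff
demonstration sweeps $\delta$ under `depleting`; sweeping $\eta$ under
`as_written` produces the same qualitative anticorrelation.

### Closed form and numerics

The cascade is linear, so each occupancy is a sum of terms
$c\,t^m e^{-dt}$ built by iterated convolution of exponentials down the
chain; repeated loss rates (which occur whenever parameters coincide, e.g.
`as_written` with $\mu = \eta$) produce the polynomial factors. The yield
and quality integrals then follow from the chain-integral identity of
linear cascades — a state with loss rate $\kappa$ fed at rate $\eta$ by a
source with known integral $I$ has integral $\eta I / \kappa$ — with the
quality route using loss rates shifted by $+\lambda$ for the
$e^{-\lambda t}$ weight.

Every closed-form quantity has an independent numerical route: trajectories
are cross-checked against `deSolve::ode()` (`lsoda`, `rtol = 1e-11`) and
the improper integrals against `stats::integrate()` on $[0, \infty)$. The
test suite requires agreement to `1e-8` relative everywhere, and `1e-6`
for the grid-quadrature-limited density normalization. Convergence of the
$t \to \infty$ integrals requires every loss rate to be positive
($\lambda < \eta$, plus $\lambda < \mu$ for `as_written` or
$\lambda < \mu + \delta$ for `depleting`); operations that integrate to
infinity refuse divergent parameter sets and name the violated inequality.
Two numerical caveats are deliberate: rates are treated as equal when they
differ by less than $10^{-12}$ (the convolution switches to the
repeated-rate branch), and *nearly* degenerate spacings between loss rates
(below ~$10^{-6}$) can lose precision through cancellation; parameters in
that regime are better nudged onto exact equality.

## The stochastic lineage simulator

`simulate_population()` realizes the same model as a continuous-time
branching process with per-cell exponential clocks: division at $\lambda$
(two daughters inherit state and absolute clock), progression at $\eta$,
sporulation at $\delta$ (removing the cell under `depleting`, marking
under `as_written`), death at $\mu$ in the starved state. Cells are
independent, so expected occupancies equal the deterministic solution by
linearity of expectation — which is what makes the simulator an
*independent* Monte-Carlo oracle for the closed form rather than a
re-implementation of it. Simulation is exact first-reaction (no
tau-leaping); the implementation processes all live cells in vectorised
rounds, which keeps $10^4$ founders well under a second.

Enzyme concentration is the deterministic global curve
$\exp(-\lambda t)$: in this model dilution is by growth of the whole
population, so division events do not change concentration and spores
record $\exp(-\lambda t_{\text{spor}})$ exactly. Partitioning noise at
division is real in cells but absent from the model, and is therefore
deliberately absent here too.

The horizon defaults to $t_{\max} = 20/\min(\eta, \mu + \delta)$. If any
cell is still alive at the horizon the summary carries a
`truncated` flag and a warning — never a silent loss of mass. Yield
standard errors are computed across founders (lineages are i.i.d.),
quality standard errors across spores.

## The synthetic observation tables

`generate_spore_table()` produces the per-spore tidy table that the
quantification layer consumes, emulating the structure of single-cell
time-lapse measurements:

* **Sporulation times.** Parametric mode draws from a two-component
  lognormal mixture: an early wave (median 15 h, log-sd 0.2) and a late
  wave (median 30 h, log-sd 0.3), weighted 50/50 — matching the observed
  first wave at 10–20 h, the late spores at 20 h or more, and the roughly
  even split. The components are truncated at the 20-h wave boundary, so
  the generative label `group_true` coincides with the timing definition
  of the waves. Mechanistic mode instead takes spore births straight from
  the lineage simulator. The 20-h boundary, weights and shapes are all
  configurable.
* **Enzyme levels** follow $\exp(-\lambda_{\text{eff}} t)$ with
  $\lambda_{\text{eff}} = 0.1\,\mathrm{h^{-1}}$ by default in parametric
  mode — slow residual growth under starvation — and are the simulator's
  exact values in mechanistic mode.
* **Reporters.** The Ald reporter is `E0 * enzyme` times *unit-mean*
  multiplicative lognormal noise (log-sd 0.2), so mean fluorescence is an
  unbiased readout of mean enzyme level; the timing reporter is an
  increasing exponential map of sporulation time (slope
  $0.2\,\mathrm{h^{-1}}$ on the log scale, log-sd 0.3), which yields the
  observed bimodal marginal under the default mixture. Absolute
  fluorescence scales are not experimentally constrained; all reporter
  defaults are placeholders in arbitrary units.
* **Revival.** Germination is Bernoulli with probability
  `p_g_base * stimulus` — identical for early and late spores, since the
  experiments found stimulus-dependent germination *probability*
  indistinguishable between groups. Germination *times* are exponential
  with a 2:1 early:late rate ratio (default early rate
  $1\,\mathrm{h^{-1}}$), the minimal model consistent with "about twice
  as fast"; the ratio is configurable. Outgrowth among germinated spores
  is Bernoulli with probability
  `stimulus * plogis(slope * (log e - log midpoint))` — a threshold-like
  requirement for the carried-over enzyme. Named presets map germinant
  conditions to these knobs; the AGFK preset decouples outgrowth from the
  enzyme level entirely, reflecting the observation that the enzyme
  specifically controls the alanine route.
* **Acquisition.** Events are detected at the first frame after they
  occur: germination times are rounded *up* to the 20-min frame grid, and
  events past the 12-h scoring window become unobserved (flags updated,
  time missing). Ceiling censoring inflates times by at most one frame.

What passing tests on these tables show — and what they do not: the
generator reproduces the *statistical skeleton* of the experiments
(waves, carried-over reporter, stimulus response, censoring), so the
quantification layer is exercised end to end on data whose ground truth is
known. It does not model spatial colony structure, per-frame intensity
traces, spore maturation/aging, spontaneous germination, or pixel-level
segmentation; agreement on synthetic tables is therefore evidence about
the analysis code, not about real micrographs.

## Quantification and statistics

The classification and counting rules mirror the experimental definitions:
a spore is "early" iff it formed strictly before the 20-h threshold (ties
are late); the fluorescence classifier splits at the sample median (ties
early, so a constant column classifies as all early — documented
degenerate behaviour) or at the equal-posterior valley of a two-component
Gaussian mixture on log fluorescence. From counts $N_s \ge N_g \ge N_o$
(dormant, germinated, outgrown): $f_r = N_o/N_s$, $f_g = N_g/N_s$,
$f_o = N_o/N_g$, so $f_r = f_g f_o$; $f_o$ is reported as *undefined* (not
zero) when $N_g = 0$. Yield is $Y = N_s/A_c$ per initial colony area and
quality $Q$ is mean Ald-reporter fluorescence; both are reported relative
to a co-cultured wild type via `normalize_to_wt()`. Group comparisons use
the unpaired $t$ test with Welch's unequal-variance form as the default
(the safer choice for unequal group sizes; the pooled form is available),
with stars at $p \le 0.05/0.01/0.001/0.0001$. Per-group frequencies can be
pooled or computed per colony and then averaged (colony mean ± SEM is the
natural unit for microcolony movies); both modes are exposed.

## Problem sizes and reproducibility

The packaged checks use $10^4$ founders for simulator-vs-model agreement
(estimates are required to fall within 3 standard errors), 100 seeded
replicates for distribution-level tests (Kolmogorov–Smirnov against
$\rho(e)$ at the 1% level; two-proportion tests for the
germination/outgrowth dissociation at ~500 spores per group), and 5
induction levels × 5000 founders for the in-silico tradeoff experiment.
These sizes give comfortable statistical resolution while keeping the
whole suite in the minutes range on a single core. Every stochastic stage
derives its seed from one master seed, and pipeline outputs embed the
resolved configuration, so any run can be reproduced bit-identically.

## Known limitations

* The enzyme is a single lumped factor with first-order dilution; no
  degradation term is separated from growth (they are observationally
  confounded in the exponential), and no stochastic gene expression feeds
  the enzyme level.
* The cascade is memoryless by construction; experimentally motivated
  non-exponential stage durations would need an extended state space.
* The closed-form evaluator loses precision for nearly (but not exactly)
  degenerate loss-rate spacings, as noted above.
* Generator reporter scales and noise magnitudes are placeholders; only
  their monotonicity/bimodality structure is anchored to observations.
* Fitting the model to experimental time-lapse data is out of scope; the
  package generates and analyses data under known ground truth.
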