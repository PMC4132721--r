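---
title: "Models and methods behind trnaip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trnaip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnaip)
```

# The experimental system being modeled

Ring-shaped, ATP-driven translocases such as the bacterial transcription
terminator Rho unwind RNA:DNA duplexes by threading the RNA track through
their central channel one nucleotide at a time.  Interference probing
interrogates this cycle chemically: transcripts are doped during in vitro
transcription with phosphorothioate-tagged nucleotide analogs (2'-deoxy,
2'-O-methyl, 2'-fluoro, or the inert parent alpha-S tag) at ~5% of the
eligible positions, reacted with the enzyme under single-run conditions (a
trap prevents re-binding of dissociated enzyme), partitioned into an
unwound supernatant fraction (S1) and a bead-retained fraction (S2), and
cleaved with iodine at the analog tags.  On a sequencing gel, the band for
position *i* in a fraction reports how many molecules carrying an analog
at *i* ended up in that fraction.

Two readouts are supported:

* **time-resolved probing (trNAIP)** samples the reaction at many times and
  assigns each track position a kinetic trace
  \(F_{t,i} = I(\mathrm{S1})_i / (I(\mathrm{S1})_i + I(\mathrm{S2})_i)\);
* **endpoint interference mapping (NAIM)** selects the unwound pool at one
  early time and quantifies per-position depletion relative to the input
  pool.

# The kinetic model

`rate_scheme()` describes a linear first-order chain: a slow, irreversible
activation step (rate `k_act`), then one translocation/unwinding step per
nucleotide.  Step *i* either advances at `k_U[i]` or dissociates
irreversibly at `k_D[i]`.  Under single-run conditions dissociation is
absorbing, so the probability of completing step *i* (its *processivity*)
is \(k_U/(k_U+k_D)\) and the reaction amplitude is

\[
A \;=\; A_0 \prod_i \frac{k_{U,i}}{k_{U,i}+k_{D,i}},
\]

with `baseline_amplitude` \(A_0\) carrying any sub-maximal starting
competence.  `simulate_progress()` evaluates the full master equation by
matrix exponential of the constant rate matrix (scaling-and-squaring Pade;
relative accuracy far below the documented 1e-9 for these small, well
conditioned generators).  When every step is much faster than activation,
the curve collapses to the single exponential \(A(1-e^{-k_\mathrm{act}t})\):
this is the regime in which an analog can change the *amplitude* (through
processivity) without changing the observed *rate* — the central
diagnostic contrast of the analysis.

Analog incorporation is modeled as multiplicative penalties on the step
consuming the modified position (`apply_penalties()`); penalties sharing a
step compose multiplicatively and the parent alpha-S tag is pinned to
(1, 1).  Activation itself has no dissociation branch and positions map to
steps by an identity shifted by a configurable track origin; whether
dissociation can occur before activation is not observable in this design,
so it is modeled as absent.

`regulatory_geometry()` holds the ring bookkeeping: a 6-subunit ring whose
weak (non-RNA-bridged) interface passes through a dissociation-prone
"regulatory" state every `period = 7` nucleotides.  The period is a free
parameter, not derived from the subunit count — the 6-subunit/7-nt
relationship is an empirical property of the system, not arithmetic — and
the phase (`offset`, default 4) is substrate-specific, so the default is
simply a mid-period choice.

# The stated synthetic world

The generator's defaults describe one fixed reference world, chosen once:

| quantity | default | rationale |
|---|---|---|
| `k_act` | 0.01 /s | slow activation; half-time ~69 s, resolvable on a minutes time course |
| `k_U`, `k_D` | 50, 0.5 /s per step | stepping ~5000x faster than activation; per-step processivity 0.990 |
| `baseline_amplitude` | 0.9 | ~10% of complexes never start |
| track / window | 118 nt, 25–118 | 94 analyzed positions; outermost positions excluded |
| molecules | 1e5 | comfortably above per-band counting noise |
| incorporation | 5% per eligible position | the bench doping level; ~5 scattered analogs per molecule |
| cleavage efficiency | 0.9 | iodine cleavage is efficient but not complete |
| band noise CV | 10% | typical densitometry repeatability |
| lane (aliquot) factor SD | 0.05 (log) | loading/volume error per aliquot |
| times | 12 points, 5–720 s | spans rise and plateau of the control |
| NAIM extent | 0.2 (absolute F) | early-selection endpoint |
| controls | 12 replicates | the dispersion basis for significance calls |

Default analog penalties act only where a 2'-OH contact matters, i.e. at
the regulatory positions: 2'-deoxy and 2'-fluoro multiply `k_D` by 100,
which under the default rates makes the penalized step's processivity
exactly 0.5 — escape from the vulnerable state and dissociation become
equally likely when the key 2'-OH is absent; the bulkier 2'-O-methyl uses
400 (processivity 0.2, ~80% amplitude loss, the strongest effect class).

Two structural choices deserve emphasis:

* **The control is the library average.**  Control traces are total-RNA
  readouts of the *same modified pool* (no iodine sequencing), as at the
  bench.  With ~5 modifications scattered per molecule, every
  subpopulation shares the same background of co-modifications, so inert
  positions match the library-average control even though all of them sit
  below an unmodified-substrate curve.  Comparing against an unmodified
  control instead would call almost every position detrimental.
* **Loading error is per aliquot.**  The S1/S2 pair of one time point is
  split from a single quenched aliquot, so its loading factor is shared —
  and cancels exactly in the ratio \(F\).  The independent loading factors
  of the selected/unselected NAIM lanes are cancelled by the total-lane
  normalization inside kappa.  This is the actual reason the field
  analyzes ratio statistics; modeling lane factors as fully independent
  would instead put a common-mode shift on every position of a dataset
  and break the nominal calibration of the SD bands.

The generator is an exact molecule-level simulation: each molecule's
completion is a Bernoulli draw with its penalized processivity product,
and its unwinding time is Exp(`k_act`) plus the chain passage time (drawn
as a Gamma for runs of identical unpenalized steps plus one exponential
per penalized step — exact, by the competing-risks property that a step's
dwell time is Exp(`k_U + k_D`) regardless of the branch taken).  This is
distributionally identical to "deterministic F per modification set +
binomial allocation" but scales to libraries in which nearly every
molecule has a unique modification set.

What the generator does *not* emulate: sequence-dependent incorporation
and penalty landscapes (uniform per analog), multi-cut iodine artifacts
(each modified position contributes its full band; single-hit bookkeeping),
gel migration/band-overlap effects, and partial S2 recovery (recovery is
complete, as in the bead protocol it mimics).  A green test therefore
establishes that the *analysis* recovers what the *model* planted — not
that the model captures every feature of real gels.

# trNAIP analysis

`fraction_unwound()` computes \(F_{t,i}\), masking (never zeroing or
imputing) points whose total intensity is at or below a configurable
floor.  `fit_single_exponential()` fits \(F(t) = A(1-e^{-kt})\) by
unweighted least squares (`nls`, port algorithm), initialized at
\(A_0=\max F\), \(k_0=\ln 2/t_{1/2}\), bounded \(A\in[0,1.2]\), \(k>0\),
with a bounded quasi-Newton fallback; non-convergence and traces that do
not span both rise and plateau are flagged rather than silently
propagated.  Residuals are unweighted because band-level uncertainties
are roughly proportional to intensity while F is a bounded ratio; no
claim is made that this is optimal, only that it is stated.

`detect_lag()` compares the single exponential against the equal-parameter
two-step alternative \(A(1-(1+kt)e^{-kt})\) by AIC: a preferred lag model
indicates at least two comparably slow steps (activation no longer
uniquely rate-limiting).

`classify_positions()` converts fits to z-scores against the mean and SD
of the 12 control replicates and applies the 1 / 2.5 SD bands (68.3% and
98.8% normal coverage).  The class label follows the amplitude z-score
(detrimental below −2.5, favorable above +2.5, slight between 1 and 2.5 in
absolute value); rate flags are carried independently.  Because the
control mean and SD are *estimates* from 12 replicates, null z-scores are
slightly over-dispersed (variance ≈ 1 + 1/12, plus heavy-ish tails from
the 11-df SD estimate): among ~90 null positions, one borderline
false call is expected in a third or more of experiments even under
perfect modeling.  The tests encode this honestly (a planted effect must
be the unique strong minimum; at most one borderline null call).

# NAIM analysis

`kappa_from_selection()` computes
\(\kappa_i = (I_{u,i}/\Sigma I_u)\,/\,(I_{s,i}/\Sigma I_s)\) after
total-lane normalization, optionally divided by the parent alpha-S
profile to cancel tag-only effects; zero selected bands are capped at a
configurable ceiling and flagged.  `lambda_normalize()` maps
\(\log_2\kappa\) to a robust z-score (median centering, MAD x 1.4826
scale), so that under pure noise \(\lambda\) is approximately standard
normal and \(|\lambda|>2.5\) corresponds to the 98.8% two-sided interval;
\(\lambda>0\) is detrimental.  The exact normalization used historically
lives in prior literature, so it is isolated behind this one function; a
`scale_floor` argument lets degenerate (constant) profiles report
all-zero lambdas instead of erroring, which the CLI uses.

`cumulative_curve()` accumulates only the detrimental part
\(\max(\lambda,0)\) — the handling of favorable values is unstated
historically, and summing signed values would let favorable noise erode
the step-like structure the curve exists to show.  `find_clusters()`
reports maximal runs above threshold with a configurable gap tolerance
(default: strictly contiguous) and intensity-weighted centers.

`interference_autocorrelation()` works on the continuous lambda profile
(binarized calls would discard power at ~100-position track lengths),
normalized at lag 0.  The step-size estimate is the first local maximum
whose value exceeds a permutation noise band: the 95th percentile of the
*maximum* autocorrelation over all lags in 1000 shuffles of the profile —
deliberately conservative (max-statistic, multiple-lag aware).  Boundary
lags are not eligible local maxima (one-sided evidence only).

# Numerical and interface choices

* The NAIM `extent` is an *absolute* fraction unwound; requesting an
  extent at or above the control asymptote errors, naming the asymptote.
  In the activation-limited regime, kappa is extent-independent (all
  subpopulations share the same time law), so this convention choice has
  no effect on the computed statistics.
* All randomness flows from explicit seeds; pipeline stages derive child
  seeds from the single config seed, and RNG state is restored after
  every call (no hidden global state).
* TSV writers rely on R's shortest-round-trip decimal representation, so
  write/read round-trips are exact to the last bit; configs and metadata
  are JSON (no YAML dependency in the target environment).
* A fitted curve that never reaches \(k\,t_{\max} \ge 2\) (or whose first
  sample is already at >90% of plateau) is flagged low-confidence; the
  chain passage delay (n/k_U ≈ 2.4 s in the default world) biases the
  fitted rate a few percent low — within the stated 5% band, and shared
  by control and positions alike, so classification is unaffected.

# Known limitations

* Incorporation probability is uniform per analog; real incorporation is
  sequence-context dependent.
* The noise model is multiplicative lognormal with a per-aliquot loading
  factor; gel artifacts that are neither (smears, band compression) are
  out of scope.
* Re-binding of dissociated enzyme is never modeled (single-cycle
  conditions are assumed exact), and the dissociated state is absorbing.
* The 12-replicate control design bounds how well calibrated the SD bands
  can be; see the over-dispersion note above.
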