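# trnaip

Kinetic modeling and interference analysis for nucleotide-analog probing
of ring-translocase helicases.

## The problem

Ring-shaped, ATP-dependent translocases such as the bacterial
transcription terminator Rho thread an RNA track through their central
channel in single-nucleotide steps, unwinding a reporter duplex as they
go.  Chemical interference probing asks *which atoms of the track the
motor actually needs*: transcripts are randomly doped (~5% per position)
with phosphorothioate-tagged ribose analogs (2′-deoxy, 2′-OMe, 2′-F),
reacted under single-run conditions, partitioned into unwound (S1) and
retained (S2) fractions, cleaved with iodine at the tags, and quantified
as sequencing-gel bands.  Time-resolved probing (trNAIP) gives every
position its own kinetic trace; endpoint selection (NAIM) gives
per-position depletion statistics.

`trnaip` is for analysts of such experiments (and for method development
against a fully known ground truth).  It implements:

* a **sequential-step kinetic model** of single-run unwinding with
  competing dissociation.  Step processivity is `k_U / (k_U + k_D)`; the
  reaction amplitude is `A = A0 * prod_i k_Ui / (k_Ui + k_Di)`, and the
  progress curve is the matrix-exponential solution of the full chain.
  With stepping much faster than the slow activation step, the curve is
  single-exponential: analog penalties move the **amplitude** (via
  processivity) but not the observed **rate**;
* a **synthetic gel-data generator** (molecule-level, exact, seeded)
  emulating library doping, fraction partitioning, iodine cleavage and
  densitometry noise;
* **trNAIP analysis**: `F_t,i = I(S1)_i / (I(S1)_i + I(S2)_i)`,
  single-exponential fits `F = A(1 − exp(−k t))`, lag detection, and
  classification against 12-replicate control dispersion at the 1 / 2.5
  SD bands (68.3% / 98.8% coverage);
* **NAIM analysis**: lane-normalized band ratios `kappa`, robust
  z-scored `lambda` interference factors (significant at |λ| > 2.5),
  cumulative detrimental-effect curves, interference clusters, and
  positional autocorrelation with a permutation noise band — the first
  significant autocorrelation maximum is the motor's step-size estimate;
* a **CLI** (`inst/cli/trnaip`): `simulate`, `trnaip`, `naim`,
  `periodicity`, `report` on TSV/JSON files.

## Worked example

A 100-nt track whose only 2′-OH-dependent steps are the periodic
regulatory positions of the default ring geometry (6 subunits, one
vulnerable state every 7 nt, first at position 4):

```r
library(trnaip)

geometry  <- regulatory_geometry()                 # period 7, offset 4
track     <- 100L
penalties <- regulatory_penalty_table(geometry, track, analog = "2'-deoxy")
spec      <- library_spec(track, n_molecules = 1e5,
                          analogs = list(analog_spec("2'-deoxy",
                                                     penalties = penalties)))
scheme    <- uniform_rate_scheme(track)
scheme
#> <rate_scheme> 100 step(s); k_act = 0.01 /s; baseline amplitude = 0.9
#>   k_U: 50 /s (all steps)
#>   k_D: 0.5 /s (all steps)
#>   total amplitude: 0.3327
```

Endpoint NAIM selection at 20% absolute extent, then the interference
profile and its periodicity:

```r
sel  <- simulate_naim_selection(spec, scheme, extent = 0.2, seed = 1)
kap  <- kappa_from_selection(sel$selected, sel$unselected)
prof <- lambda_normalize(kap)
prof
#> <interference_profile> 100 positions, 14 significant at |lambda| > 2.5

interference_autocorrelation(prof, seed = 2)
#> <autocorr_result> periodic: step size 7 nt (acf 0.685 > null q95 0.267)
```

All 14 planted positions are significant and the autocorrelation recovers
the 7-nt step size against its permutation null.  The trNAIP arm of the
same library reproduces the diagnostic "amplitude down, rate unchanged"
signature:

```r
times   <- c(5, 10, 20, 40, 60, 90, 120, 180, 240, 360, 480, 720)
ds      <- simulate_gel(spec, scheme, times, seed = 3)
fits    <- lapply(fraction_unwound(ds), fit_single_exponential)
ctl     <- simulate_control_replicates(spec, scheme, times,
                                       n_replicates = 12, seed = 4)
control <- control_statistics(lapply(ctl, fit_single_exponential))
control
#> <control_stats> n = 12: A = 0.2385 +/- 0.0180, k = 0.009716 +/- 0.0012 /s

profile <- classify_positions(fits, control)
profile
#> <position_profile> 100 positions: indistinguishable = 61, slight = 25,
#>   favorable = 0, detrimental = 14

profile$position[profile$class == "detrimental"]
#>  [1]  4 11 18 25 32 39 46 53 60 67 74 81 88 95
```

The detrimental set is exactly `regulatory_positions(geometry, 100)`: the
control (the library-average trace, as measured at the bench) absorbs the
shared background of co-modifications, so inert positions stay inside the
SD bands while every planted position shows a significant amplitude
deficit — at a rate indistinguishable from control.

## Layout

* `R/` — rate schemes & penalties, chain solver, generator, trNAIP fits &
  classification, NAIM λ/cluster/autocorrelation, config & CLI.
* `vignettes/trnaip-methods.Rmd` — the model, the stated synthetic world,
  normalization and calibration choices, known limitations.
* `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (stochastic chain walk, closed forms, permutation
  and Monte-Carlo nulls).
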