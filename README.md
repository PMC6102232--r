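# photonhmm

Kinetic analysis of single-molecule FRET photon time traces with hidden
Markov models — simulation, maximum-likelihood rate inference, Viterbi
state decoding, dwell-time statistics, and FCS-based concentration
calibration.

## What it is for

In surface-immobilization smFRET experiments, a donor-labeled protein on a
passivated coverslip binds an acceptor-labeled ligand from solution; every
association/dissociation event appears as an anticorrelated step in the
two photon channels. `photonhmm` turns such two-channel **binned photon
traces** into rate coefficients. It was built for a system with a twist:
an intrinsically disordered receptor (NCBD, binding its partner ACTR)
whose peptidyl-prolyl *cis/trans* isomerization switches the molecule
between a high-affinity and a low-affinity form every few tens of
seconds, so the trace kinetics are a hidden mixture of two regimes with
identical FRET efficiency.

The package is aimed at single-molecule spectroscopists who need to

* model binding schemes as continuous-time Markov generator matrices
  (two-state, with fluorophore dark state, two bound states, and the full
  four-state binding/isomerization scheme);
* simulate realistic photon-count traces with exact ground truth;
* fit rate coefficients by the binned-photon likelihood
  `L = 1ᵀ [∏ₜ Fₜ e^(ΔK)] p_eq` (Poisson emission factors `Fₜ`, propagator
  `e^(ΔK)`, stationary start `p_eq`), per trace and globally across
  traces, with bootstrap errors;
* decode state trajectories (Viterbi), extract bound/unbound dwell times,
  and fit truncated single/double-exponential dwell distributions;
* estimate ligand concentrations from FCS curves
  (diffusion + triplet model, two-pass protocol).

The core recursions are compiled (Rcpp); a 60,000-bin six-state trace
evaluates in ~6 ms, so global 1-ms-binned fits over hundreds of traces are
routine.

## Worked example

Closed-form quantities from fitted rate coefficients — dissociation
constants, unbound isomer populations, and the fraction of binding events
entering the low-affinity complex:

```r
library(photonhmm)
dq <- derive_quantities(rate_spec(koff1 = 7.3, kon1 = 0.93e8,
                                  koff2 = 30,  kon2 = 0.46e8,
                                  k12 = 0.04, k21 = 0.07,
                                  c_ligand = 65e-9))
dq
#> # A tibble: 1 × 6
#>            Kd1         Kd2    p1    p2 frac_fast affinity_ratio
#>          <dbl>       <dbl> <dbl> <dbl>     <dbl>          <dbl>
#> 1 0.0000000785 0.000000652 0.636 0.364     0.220           8.31
```

`Kd1 ≈ 78 nM` and `Kd2 ≈ 652 nM`: the two isomers differ about eightfold
in affinity; 64% of the unbound receptor is in the high-affinity (trans)
form, and 22% of binding events enter the low-affinity complex. At NMR
concentrations the low-affinity complex is marginal:

```r
eq <- four_state_binding_equilibrium(
  list(Kd1 = 78e-9, Kd2 = 650e-9, k12 = 0.04, k21 = 0.07),
  total_receptor = 3e-3, total_ligand = 6e-3)
round(100 * eq$fractions, 1)
#> unbound_trans   unbound_cis   bound_trans     bound_cis
#>           0.0           0.0          93.6           6.4
```

End-to-end: simulate a switching dataset and recover every rate with the
iterative four-state pipeline (blink rates → dwell-map initial values →
per-trace isomerization estimates → decode and split into cis/trans
segments → segment refits → global isomerization fit):

```r
ncbd <- rate_spec(kon1_prime = 6.0, kon2_prime = 3.0, koff1 = 7.3,
                  koff2 = 30, k12 = 0.04, k21 = 0.07,
                  kb_plus = 1.7, kb_minus = 38)
ds  <- run_simulation(ncbd, "four_state_blink", n_traces = 150,
                      mean_duration = 60, delta = 0.001, seed = 42)
rep <- run_four_state_iterative(ds$traces, analysis_config(n_boot = 0,
                                                           seed = 42))
str(Filter(Negate(is.null), rep$fit$rates))
#> List of 8
#>  $ kon1_prime: num 5.7
#>  $ kon2_prime: num 2.96
#>  $ koff1     : num 7.35
#>  $ koff2     : num 29.3
#>  $ k12       : num 0.0317
#>  $ k21       : num 0.0637
#>  $ kb_plus   : num 1.64
#>  $ kb_minus  : num 38.1
```

All eight generating rates come back: binding rates within ~5%, the
100-fold slower isomerization rates within their uncertainty. Results are
tibble-friendly (`tidy()`, `glance()`) and plottable
(`autoplot()` on traces, dwell maps, count-ratio histograms, FCS fits).

## Documentation

The methods vignette (`vignettes/proline-switch-kinetics.Rmd`) describes
the kinetic schemes, the likelihood and its numerical treatment, the
decoder and dwell statistics, the iterative four-state procedure, the
synthetic-data generator and its limits, and the FCS calibration model.
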