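# polterm

Pausing-coupled premature termination of transcription (PTT) by RNA
polymerase I, as a model, a simulator, and the occupancy analytics to go
with it.

## What this is for

Pol I transcribes the 35S pre-rRNA (5'ETS–18S–ITS1–5.8S–ITS2–25S–3'ETS)
and pauses heavily in the first ~300 nt of the 5'ETS. Paused complexes are
prone to premature release of both polymerase and nascent transcript, so
pausing taxes rRNA output. `polterm` is for people who study this with
3'-end occupancy profiling (CRAC/NET-seq style) and nascent-transcript
densitometry: it implements the comparative analytics those experiments
need, and a mechanistic generator that produces realistic synthetic data
so the whole pipeline is testable at desk scale.

The core model: at site `x` the polymerase dwells `Exp(tau(x))` and
terminates there with probability `p(x) = 1 − exp(−kappa·tau(x))` — the
longer the pause, the more frequent the release. Its steady state is
closed-form: survival `S(x) = Π_{y<x}(1−p(y))`, flux `J = alpha·S`,
occupancy `O = J·tau`, abortive production `A = J·p`, full-length rate
`F = alpha·S(L+1)`, with `alpha = F + ΣA` exactly.

On top of that:

* `simulate_molecules()`, `emit_crac_reads()`, `emit_abortive_spectrum()`,
  `emit_probe_signals()` — exact stochastic twin of the closed form, with
  UMIs, PCR duplicates, and slot-blot-style intensity tables;
* `dedup()`, `coverage_3p()`, `aggregate_replicates()` — duplicate removal
  on the `(start, end, strand, UMI)` key, per-base 3'-end coverage in hits
  per million, replicate mean and min–max envelope;
* `envelope_difference()`, `log2_ratio()`, `region_stats()`,
  `cdf_profile()`/`cdf_shift()` — conservative envelope differencing,
  low-coverage-masked log2 ratios, per-region Welch tests, CDF-shift
  metrics;
* `normalize_to_5s()`, `composite_poli_signal()`, `window_quant()`,
  `fold_change_stats()` — densitometry arithmetic (5S normalization,
  70–90 nt abortive-window integration, fold changes with tests);
* presets `"wt"`, `"superpol"`, `"wt_bmh21"`, `"superpol_bmh21"` — packaged
  condition pairs; the SuperPol preset is calibrated at construction so the
  closed form gives a 5'ETS occupancy-share ratio WT/SuperPol of exactly
  1.25 and a full-length ratio SuperPol/WT of exactly 1.5.

## Worked example

```r
library(polterm)
ann <- default_annotation()
cfg <- preset_config(seed = 1)              # 3 reps x 50,000 events
reads <- simulate_crac_experiment(list(wt = "wt", superpol = "superpol"), cfg)
profs <- process_reads(reads, unit_length(ann))   # dedup + 3'-end coverage
rs <- region_stats(profs$wt, profs$superpol, ann)
rs[rs$region == "5'ETS", c("region", "ratio_ab", "p", "stars")]
#>   region ratio_ab            p stars
#> 1  5'ETS 1.252418 6.219801e-07   ***
cdf_shift(cdf_profile(profs$wt), cdf_profile(profs$superpol))
#> $delta_median
#> [1] -71
#> $signed_area
#> [1] 0.08546351
```

The wild type shows ~25% more summed 5'ETS frequency than the fast
variant, and the variant's cumulative occupancy lies rightward of the wild
type's (negative median difference, positive signed area with WT first):
less 5'-proximal accumulation, consistent with fewer pauses and less
premature termination. The same calculations for the drug preset localize
the maximal occupancy loss inside the 5'ETS pause cluster.

The `analysis/` directory holds the full workflow as numbered drivers —
`01_simulate_conditions.R` (conditions and synthetic data),
`02_process_reads.R` (dedup → coverage → envelopes),
`03_compare_conditions.R` (region stats, envelope difference, masked log2
ratio, CDF shift, drug localization), `04_blot_quantification.R`
(5S-normalized fold changes, composite Pol I signal, abortive-window
integrals). Each writes its tables under `results/` (bulky intermediates
under `scratch/`).

## Documentation

The methods vignette (`vignettes/polymerase-pausing-termination.Rmd`)
describes the model and its assumptions, the packaged pause landscape and
preset calibration, the exact definitions of every pipeline statistic, and
what the synthetic generator does and does not emulate.
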