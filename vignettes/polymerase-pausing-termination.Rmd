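---
title: "Pausing-coupled premature termination of Pol I: model, simulator and occupancy analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pausing-coupled premature termination of Pol I}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polterm)
```

## The problem

RNA polymerase I (Pol I) transcribes the 35S pre-rRNA from the rDNA unit
(5'ETS, 18S, ITS1, 5.8S, ITS2, 25S, 3'ETS; 6859 nt in the packaged
annotation). Elongating Pol I pauses frequently, most heavily across the
first ~300 nt of the 5' external transcribed spacer, and paused complexes
are prone to premature termination of transcription (PTT): release of the
polymerase and its nascent transcript before the end of the gene. PTT
therefore taxes rRNA output, and perturbations that change pausing — a
faster polymerase variant ("SuperPol", RPA135-F301S), or a drug such as
BMH-21 that acts on paused complexes — change both the occupancy profile
along the unit and the yield of full-length transcripts.

`polterm` provides (i) a mechanistic single-molecule model of this
pause/termination coupling, with a closed-form steady state and an exact
stochastic simulator; (ii) a CRAC-like read generator (3'-end reads, UMIs,
PCR duplicates) so the whole downstream pipeline can be exercised without
any sequencing data; and (iii) the occupancy analytics used for such data:
UMI-aware duplicate removal, per-base 3'-end coverage with per-million
normalization, replicate envelopes, conservative envelope differences,
masked log2 ratios, per-region statistics, CDF-shift metrics, and the
densitometry arithmetic of slot-blot/northern quantification.

## The model

A molecule enters at site 1 and walks site by site to `L`. At site `x` it
dwells an Exponential time with mean `tau(x)` (arbitrary time units) and
terminates there with probability

    p(x) = 1 - exp(-kappa(x) * tau(x)),

i.e. a constant termination hazard `kappa` acting throughout the dwell:
the longer the pause, the more likely the release. `kappa = 0` recovers
uninterrupted elongation. With initiation rate `alpha`, the steady state is
closed-form:

* survival `S(x) = prod_{y<x} (1 - p(y))`,
* flux `J(x) = alpha * S(x)`,
* occupancy `O(x) = J(x) * tau(x)` — what a cross-linking snapshot samples,
* abortive production `A(x) = J(x) * p(x)`,
* full-length rate `F = alpha * S(L+1)`, with `alpha = F + sum(A)` exactly.

```{r}
m <- pause_termination_model(tau = rep(1, 3), kappa = log(2))
ss <- steady_state(m)
ss$S            # (1, 0.5, 0.25, 0.125): survival halves at each site
ss$full_length_rate
```

Assumptions worth spelling out: dwell times are memoryless (a single rate
per site); backtracking/cleavage cycles are absorbed into `tau(x)` rather
than modelled explicitly, because occupancy profiling cannot distinguish
them from simple dwelling; termination probability depends on position
only through `tau` and `kappa`; and molecules do not interact (no
exclusion/TASEP effects — see Limitations).

## Simulation semantics

`simulate_molecules()` samples each molecule's fate from the exact outcome
distribution (`S(x) p(x)` per site, `S(L+1)` full-length) instead of
walking site by site, and draws per-site dwell totals as Gamma sums of the
per-visit Exponentials; both shortcuts are distributionally identical to
the explicit walk and keep the cost linear in `L`. `emit_crac_reads()`
samples read 3' ends proportionally to the realized dwell at each site —
time-weighted "snapshot" semantics, since cross-linking captures enzymes
in proportion to residence time — so expected coverage is proportional to
`O(x)`, including the dwell of visits that end in termination. Each read
gets `end = x`, `start = max(1, x - readlen + 1)`, the `+` strand, and a
random UMI; PCR then adds Geometric-distributed extra copies that share
coordinates and UMI exactly (no UMI errors are modelled, which keeps the
deduplication contract exact).

## The packaged landscape and presets

Defaults (package constants, chosen once as a realistic desk-scale stand-in
for triplicate Pol I profiling data):

| parameter | value | meaning |
|---|---|---|
| `unit_length` | 6859 nt | the seven-region 35S map |
| baseline `tau` | 1 | flat dwell outside pause elements |
| 5'ETS cluster | 16 elements x 5 nt, positions 24-298, `tau = 400` | the strong early pause cluster |
| secondary cluster | 12 elements x 5 nt, 2880-3324, `tau = 40` | weaker accumulation near the 5.8S/25S boundary |
| `kappa` (WT) | 5.1e-5 | gives ~12% full-length yield and ~92% 5'ETS occupancy share |
| reads | 50,000 events/replicate, 20-50 nt, UMI 5 nt, 1 extra PCR copy on average | `preset_config()` |
| replicates | 3 (2 for the drug comparison) | matching the experimental designs emulated |

With these constants most occupancy sits in the 5'ETS and most abortive
transcripts are shorter than 300 nt, reproducing the heavy 5'-proximal
concentration seen in Pol I 3'-end profiling. The default read-length
range (20-50 nt rather than the bare `simulation_config()` default of a
fixed 30 nt) reflects nuclease-trimming variability and, practically,
gives hotspot positions enough `(start, UMI)` key diversity that duplicate
removal does not saturate; with a 5-nt UMI and fixed-length reads, a
position receiving several hundred events would alias distinct biological
events into the same key.

The `"superpol"` preset scales the 5'ETS-cluster dwell times by a factor
`s` and re-solves a global hazard `kappa` such that the closed form gives
*exactly* a 5'ETS occupancy-share ratio WT/SuperPol of 1.25 and a
full-length ratio SuperPol/WT of 1.5 — the two relative magnitudes the
variant is characterized by. The solve (nested `uniroot` on the closed
form) runs at preset construction and a self-check recomputes both targets
from `steady_state()`. One consequence is worth flagging: the solution has
`s ≈ 0.30` and `kappa ≈ 9.0e-5`, i.e. the raw hazard is slightly *higher*
than WT while the pauses are much shorter. The biologically meaningful
quantities all move the right way — the per-visit release probability at
pause sites is roughly halved, total abortive output drops, survival to
the 3' end rises 1.5-fold — because termination exposure is the product
`kappa * tau`. With a single global hazard and this landscape, hitting both
calibration targets forces that trade-off; a per-region hazard could avoid
it at the cost of an extra free parameter nothing in the data constrains.

The `"wt_bmh21"` / `"superpol_bmh21"` presets multiply `kappa` by 8 at the
5'ETS pause-cluster sites only, representing a drug that acts
preferentially on long-paused complexes. The multiplier is deliberately
restricted to the strong cluster: the observable signature being emulated
is occupancy loss localized where the polymerase accumulates most, and
because flux loss is cumulative along the template, boosting every
elevated-`tau` site would relocate the maximal log2-ratio contrast
downstream of the last boosted site instead. Treatment under these presets
is close to a complete block of full-length synthesis — an acute, strong
inhibition regime.

## Pipeline definitions

* **Deduplication** collapses reads on the `(start, end, strand, UMI)`
  key, keeping the first record in input order (records are value-identical
  on the key, so the choice only affects provenance). Strand is included
  conservatively; it is a no-op for sense-only data.
* **Coverage** counts 3' ends per base (sense reads at `end`; antisense
  reads, excluded by default, would count at their leftmost coordinate).
  Frequencies are hits per million of reads mapped to the unit — users
  supplying their own tables should pre-filter to the rDNA unit
  accordingly.
* **Envelope difference**: `d(x) = minA - maxB` where A's replicate
  envelope sits wholly above B's, `-(minB - maxA)` in the opposite case,
  else 0. It is antisymmetric and never exceeds the difference of means —
  a deliberately conservative per-position contrast.
* **Masked log2 ratio**: `log2(meanA/meanB)`, masking any position where
  the minimum raw count over all replicates of both conditions is below
  `c_min = 5`. The threshold is a parameter; five deduplicated reads per
  replicate is where a log2 ratio stops being dominated by shot noise.
  Positions that still hit a zero mean off-mask are force-masked with a
  warning rather than emitting infinities.
* **Region statistics**: per-replicate sums of normalized frequency over
  the seven regions (each replicate's sums total 1e6 by construction),
  Welch unequal-variance two-sided t-tests, stars at 0.05/0.01/0.005.
  Welch is the robust default at n = 3; the choice is configurable only in
  the sense that the per-replicate sums are returned for any other test.
* **CDF shift**: CDFs of the mean profile with a replicate envelope;
  `delta_median` uses the first position reaching 0.5 (ties toward smaller
  x, deterministic on step functions); `signed_area = mean(C_A - C_B)` is
  positive when condition A accumulates more 5'-proximally, i.e. when B's
  CDF lies at-or-right of A's. The CDF domain is the annotated unit
  (1..6859); published coordinate sets for this locus differ by 2 nt
  (6859 vs 6861) and `unit_length` is parameterized rather than guessing.
* **Densitometry**: probe/5S ratios divide by the *mean* of the two 5S
  control probes (scale-free, fixed for reproducibility); the composite
  Pol I signal averages the three 5'ETS probes into a single member before
  averaging members; window integration is trapezoidal with interpolated
  window edges (default 70-90 nt, the abortive-species window, and a
  parameter because the exact integration bounds are a choice);
  backgrounds are assumed already subtracted.

## What the generator does and does not emulate

It reproduces: triplicate structure, heavily non-uniform 3'-end coverage
concentrated in the 5'ETS, PCR duplication with shared UMIs, condition
pairs differing in pause strength and termination hazard, abortive-length
spectra dominated by the early pause cluster, and
slot-blot/northern-style intensity tables with lognormal replicate noise.

It does not emulate: sequence-dependent pausing, UMI sequencing errors,
antisense or off-unit reads, alignment artifacts (soft-clipping,
multi-mapping across the rDNA array), polymerase-polymerase exclusion,
co-transcriptional processing of the nascent RNA, or torpedo-mechanism
termination at the 3' end. Passing tests on simulated data therefore
validate the *analytics* and the model's internal consistency, not any
claim about real sequencing libraries; with real data the pipeline starts
from the read table or coverage track and every upstream caveat applies.

## Numerical choices and degenerate inputs

Conservation holds to ~1e-15 relative (products of `1 - p` via `expm1`);
the conservation test demands 1e-9. All-zero profiles refuse to form CDFs;
empty read lists give zero profiles; single replicates give degenerate
envelopes and no t-test; identical zero-variance samples return t = 0,
p = 1 (no evidence) rather than NaN. Random-number use is confined to the
simulator and every simulating function takes a `seed`; fixed seeds give
byte-identical output.

Problem sizes used throughout the packaged analyses and checks — 20,000
molecules and 50,000 CRAC events per replicate, three replicates (two for
the drug pair), 200 repetitions for quantification-bias checks — were
chosen so that sampling error sits well inside the 10% relative windows of
the recovered contrasts while the whole suite stays desk-scale.

## Limitations

The model is intentionally minimal: one hazard parameter couples pausing
to termination, so it cannot represent termination pathways independent of
dwell time; dwell-time distributions are exponential, so strongly
non-exponential pause-duration data would be mis-fit; and calibration
targets are relative magnitudes, so absolute rates are only defined up to
the arbitrary time unit. The analytics operate on a single canonical rDNA
unit — multi-copy array variation, genome-wide normalization and
spike-in-based absolute quantification are out of scope (per-million
normalization is blind to uniform absolute changes, which is why the
drug analysis reports absolute occupancy depletion from the simulated
dwell field, a quantity a spike-in would estimate in a real experiment).
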