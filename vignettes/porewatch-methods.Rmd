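---
title: "porewatch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{porewatch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porewatch)
```

This vignette explains what porewatch computes, why each default is what it
is, and which choices were genuinely open. It is the package's own account of
its methods; every number it mentions is recomputed by the test suite or by
`scripts/acceptance.R`, never asserted from memory.

## The monitoring model

A nanopore basecaller appends one row per read to a tab-separated
`sequencing_summary.txt` while the experiment runs. porewatch treats this
file as an append-only log and the run as a stream of *read records*
`(read_id, channel, start_time, duration, sequence_length, mean_qscore,
passes_filtering?)`. All statistics are functions of this stream:

* **Windowing.** A read belongs to the half-open elapsed-time slice
  `[k·w, (k+1)·w)` containing its *start* time, with `w = 600` s by default.
  Start time is used rather than end time because it is universally present
  and unambiguous; a config switch is not offered, since mixing conventions
  across runs would silently break comparisons. Empty windows are emitted
  explicitly with `NA` metrics — a silent half hour is exactly what a
  monitoring plot must show.
* **Translocation speed.** Per read, speed is `sequence_length / duration`
  (bases per second of pore dwell time). Per window the primary statistic is
  the duration-weighted speed `Σ length / Σ duration`, not the mean of
  per-read speeds: many tiny reads would otherwise dominate, and the
  weighted form is bounded by the per-read extremes within the window (a
  property the tests enforce). A window is flagged when its speed falls
  below `low_speed_threshold`, default 300 b/s — the floor below which the
  vendor recommends refueling.
* **Aggregated means.** Window and cumulative means are recomputed from
  running sums (never means of means); medians are exact, computed from the
  retained per-window length lists. Mean q-score is the arithmetic mean of
  per-read mean q-scores, matching what the basecaller itself reports; an
  error-probability-space average would read systematically lower and
  confuse users comparing against instrument dashboards.
* **Pass/fail.** When the file carries `passes_filtering`, that verdict
  wins; otherwise a read passes iff `mean_qscore >= 7`, inclusive at the
  boundary, matching the basecaller's convention.
* **Channel grid.** Channels map row-major onto a 16 × 32 rectangle
  (512-channel MinION/GridION/Mk1C class) or 30 × 100 (3000-channel
  PromethION class). This is a plotting convention: the vendor's physical
  pore layout is undocumented and out of scope, and any injective mapping
  serves the purpose of making spatial structure visible.

## Incremental reading

The reader seeks to a persisted byte offset and consumes only complete,
newline-terminated lines; a trailing partial line is left for the next poll,
because the writer flushes per buffer, not per line. The checkpoint carries a
file signature — size at last read plus the verbatim first header line — and
a size shrink or a changed first line forces a full reprocess of that run.
This is deliberately conservative: of the failure modes a monitoring daemon
meets (truncation, re-basecalling into the same path, copy-in-place), none is
distinguishable from the others cheaply, and reprocessing a file is always
correct. A replacement that *grows* the file while preserving its first line
is not detectable this way; it is also not a failure mode any basecaller
produces.

Malformed lines are counted by reason (`bad_field_count`, `non_numeric`,
`nonpositive_duration`, `negative_value`) and skipped, never fatal. Header
synonyms cover the guppy renames (`sequence_length_template` vs
`sequence_length`, `mean_qscore_template` vs `mean_qscore`). Encoding is
assumed ASCII/UTF-8 with a single tab separator and `\n` line endings, the
basecaller's convention.

## Exactness guarantees

Three properties were non-negotiable and shaped the accumulator's design:

1. **Order independence** — summaries are near-sorted but not guaranteed
   sorted, so any permutation of updates must finalize identically;
2. **Streamed ≡ batch** — processing a run in any number of increments must
   emit files byte-identical to one-shot processing;
3. **Exact conservation** — reads and bases must sum identically across the
   window, channel and length-histogram decompositions.

The accumulator therefore retains the accepted records themselves and every
finalization first sorts them deterministically (start time, then read id,
in C locale). Floating-point sums are then bit-reproducible regardless of
arrival order, medians are exact, and the streamed/batch equivalence is
exact rather than approximate. The memory cost is linear in reads — tens of
MB for the largest desk-scale runs this package targets — and is the
documented trade-off; a facility processing 83 M-read PromethION summaries
would swap the record store for fixed-size sufficient statistics and
approximate medians, losing property 2 at the last bit.

Emitted TSVs are written with shortest-round-trip double formatting and read
back with strtod, so values survive the file round trip bit-for-bit. Every
file is written to a temporary name and renamed into place: a polling
consumer never observes a partial file. Per-run state (checkpoint plus
records) persists under a hidden `.state/` directory with the JSON metadata
renamed last as the commit point; a crash between any two operations is
recovered by reprocessing at most one increment, and a corrupt or
missing snapshot degrades to a full reprocess, never to wrong numbers.

## The five files and the registry

Each pass rewrites, per run: `windowed.tsv`, `cumulative.tsv`,
`channels.tsv`, `quality_time.tsv` (the four 10-minute series) and
`length_dist.tsv` (the read-length distribution), plus the `runs.tsv`
registry (run id, status, latest metrics). Which four tables constitute the
time-windowed set was an open choice; these four are the ones every
monitoring question in the package's scope draws on. File names are fixed so
the comparison layer and any external dashboard can rely on them. The
comparison layer consumes only these files — re-running it can never mutate
run outputs — and aligns runs on each run's own elapsed time, as every
run-comparison question here is about run efficiency, not calendar
coincidence.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `window_width` | 600 | s | 10-minute slices: fine enough to catch a speed drop within one refuel decision, coarse enough to keep files small |
| `length_bin` | 500 | bases | resolves the 1–30 kb structure of typical long-read libraries |
| `q_bin` | 0.5 | q units | half-unit bins resolve the pass boundary at q = 7 |
| `low_speed_threshold` | 300 | b/s | vendor-recommended translocation floor |
| `pass_q_threshold` | 7 | q units | basecaller pass/fail convention (fallback only) |
| `poll_interval` | 60 | s | minute-cadence updates; cheap because polls cost only new bytes |

All are exposed through `emitter_config()`, as CLI flags, and as a YAML
config file.

## The synthetic generator

`synthetic_run_config()` encodes the run the monitor exists to catch: reads
arrive homogeneously over 48 h on 512 channels; lengths are log-normal
(`meanlog log(5000)`, `sdlog 1`, truncated to [50, 2e6] b — median 5 kb,
mean ≈ 8.2 kb, a realistic plant/animal long-read library); mean q-scores
are normal(10, 1.5) truncated to [1, 30]; speed starts at 400 b/s, decays
exponentially at 0.05/h, and resets to base at refuels 1200, 1650 and
2450 min into the run. Reads started while speed is below 300 b/s lose one
q-score unit, reproducing the quality dip that accompanies reagent
exhaustion. Sampling uses inverse-CDF draws from the truncated
distributions, so truncation is exact and the analytic mean/sd
(`length_model_moments()`) are the right recovery targets.

Two design points matter more than the distribution choices. First,
durations are *derived* as `length / speed(start_time)` rather than sampled:
the decay-and-refuel signal is thereby guaranteed to exist in the data, and
a window's duration-weighted speed is analytically the length-weighted
harmonic mean of the closed-form profile — which is how the tests can check
recovered speeds against `speed_profile()` to within the file's 5-decimal
duration rounding. Second, ground-truth numeric fields are re-parsed from
the formatted file text, so ground truth equals exactly what any reader of
the file sees and conservation checks can demand exact equality.

What the generator does **not** emulate: channel-specific pore death (channel
assignment stays uniform), mux scans and pore-state transitions, barcode
structure, length/quality autocorrelation within channels, diurnal loading
effects, or any sequence content. Passing tests therefore demonstrate the
*bookkeeping* is exact and the *speed/quality mechanics* are recovered; they
say nothing about basecaller quirks beyond the header dialects and the
buffer-flush partial lines the streamer deliberately produces (its chunk
boundaries are uniform random byte positions, so most cuts land mid-line).

## Numerical and degenerate-input choices

* Window bins are half-open `[k·w, (k+1)·w)`; a read at exactly `t = k·w`
  belongs to window `k`. Length and q-score bins use the same `floor(x/w)`
  convention.
* Medians over an even count are the mean of the two central values
  (`stats::median`).
* An empty run emits a zero-row windowed table, a header-only length
  histogram, zeros in the registry and an `NA` speed; the percent-of-bases
  view of zero bases is an error (`porewatch_empty_run`), not a `NaN` table.
* Records on channels beyond the configured layout are kept in an overflow
  bucket (channel `NA` in `channels.tsv`) with a warning, so conservation
  holds even under a mis-set layout.
* Ties in the deterministic finalization sort are broken by read id; read
  ids are unique per file, so the sort is total.
* `speed = Σlen/Σdur` divides by a sum of strictly positive durations
  (records with `duration <= 0` were rejected at parse time), so no window
  with reads can produce a non-finite speed.

## Test and acceptance problem sizes

The suite exercises parsing and windowing on hand-built 3–40 line files
where expected values are computable by hand; property-style checks
(order independence, conservation, incremental/batch equality, speed
bounds) run on seeded random tables of 300–1000 reads; end-to-end
streamed-vs-batch byte identity runs on 20 random synthetic runs of
1,000–50,000 reads split into 1–10 appends; refuel detection and parameter
recovery use 10,000–20,000-read runs under the default configuration. These
sizes were chosen so the full suite finishes in about a minute while every
claim is still tested at a scale where floating-point and off-by-one-line
mistakes would surface.

## Known limitations

* Memory grows linearly with accepted reads per run (the exactness
  trade-off above).
* The watcher polls; it does not use filesystem events. At a 60 s cadence
  polling is cheaper and far more portable than inotify-class APIs.
* The channel grid is a convention, not the physical pore map.
* Gzip-compressed summaries, FASTQ/FAST5/POD5/BAM inputs, alignment-derived
  metrics (N50 against a reference, coverage), and barcode-level breakdowns
  are out of scope.
* A file replacement that grows the file while keeping its first line
  intact defeats the replacement heuristic (see *Incremental reading*).
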