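---
title: "Quantifying terminus over-replication by marker frequency analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying terminus over-replication by marker frequency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termfa)
```

## The measurement problem

In an exponentially growing bacterial culture, loci near the origin of
replication (*oriC*) are present in more copies than loci near the terminus,
because at any instant a fraction of cells has already re-replicated the
origin-proximal part of the chromosome. Deep sequencing of genomic DNA from
such a culture therefore shows a smooth copy-number gradient from *oriC*
down to the terminus — marker frequency analysis (MFA). Deviations from
that gradient are diagnostic: a local excess of reads between the innermost
*Ter*/Tus replication fork barriers (a "Ter peak") indicates
origin-independent over-replication of the terminus region, as seen in
*E. coli* mutants lacking type 1A topoisomerases, where R-loop-dependent
replication (RLDR) fires from weak, dispersed origins and the resulting
forks are captured by the polar Tus/*Ter* trap.

`termfa` implements the quantification side of such a study — windowed
read counts, control normalization, loess smoothing, the
spectinomycin peak-increase statistic, marker-locus ratios and 2^-dCt qPCR
arithmetic — together with a generative simulator that produces coverage
data with the same statistical structure, so that every stage of the
pipeline can be validated against a known ground truth without access to
the original sequencing runs.

## The coverage pipeline

Reads (SAM, or pre-binned TSV tables) are filtered at a minimum mapping
quality of 10 (inclusive; this discards multi-mapping reads), assigned to
windows by their 0-based leftmost mapped coordinate, and counted on a grid
of 10,000 windows that exactly partitions the chromosome (base width
`floor(L/n)`, the first `L mod n` windows one bp wider) — about 465–500 bp
per window for an *E. coli*-scale genome. Counts are normalized against a
stationary-phase control to absorb window-specific depth biases, and
library-size scaled:

$$ r_i = \log_2\!\left( \frac{s_i + p}{S} \cdot \frac{C}{c_i + p} \right), $$

with $S, C$ the total sample/control read counts and $p = 0.5$ a symmetric
pseudocount guarding zero-count windows (the choice of $p$ only affects
windows with counts comparable to $p$; at the depths involved it is
inconsequential, but it keeps deleted regions finite). Because of the
library-size scaling, multiplying all counts of a sample by a constant
changes no ratio.

The smoothed curve is a locally weighted linear regression (loess) with
span 0.1: each window's fit uses the `ceiling(0.1 n)` nearest windows,
tricube-weighted by distance, degree 1, no robustness iterations — the
canonical loess defaults. Two implementation details matter:

* **Circularity.** The chromosome is circular; fitting on the linear
  coordinate would create edge artifacts at position 0. `loess_smooth()`
  wraps `span/2` of the data from each end (shifted by ± one genome length)
  before fitting and crops afterwards, so the curve is continuous across
  the origin of the coordinate system.
* **Ties and degeneracy.** Nearest-neighbour windows are contiguous in the
  sorted coordinate; the window is chosen to minimize the maximum distance
  to its ends. If all neighbours share one coordinate the fit degenerates
  to a tricube-weighted mean. A constant input is reproduced exactly, and
  an exactly linear input is reproduced to numerical precision (a degree-1
  local fit is exact on lines) — both are tested, as is agreement to 1e-6
  with an independent brute-force weighted-least-squares implementation.

## The peak statistics

`peak_height()` is the difference between the highest loess value inside a
candidate region (by default the innermost *Ter* interval, i.e. the first
barrier each *oriC* fork would be arrested at) and the lowest loess value
in a fixed-width flank immediately clockwise of the region (default 200
windows; the published description does not bound its search window, so a
fixed flank makes the statistic deterministic). The statistic operates in
log2 space — the scale the profiles are plotted and the published values
(tenths of a unit) suggest — and is invariant to adding a constant to the
curve, hence to global normalization choices.

`ter_peak_increase()` subtracts the pre-spectinomycin peak height from the
post-run-off one. Spectinomycin stops protein synthesis and with it new
*oriC* initiations; ongoing rounds complete, flattening the *oriC*
gradient, while RLDR continues. A positive increase therefore measures
continued origin-independent synthesis in Ter. `marker_ratio()` is the
sequencing analogue of the qPCR marker ratios (ydcM/lepA for peak height,
qseC/lepA for the *parC parE* amplification): mean counts (or `2^loess`)
over `2w+1` windows centred at each locus. `flatness_test()` calls a
profile flat when its peak height falls below a threshold, by default 3
standard deviations of a control profile's loess (or, absent a control, of
this profile's loess outside the region and flank).

One caveat discovered during validation and worth stating: because the
statistic lives in log space, it saturates. When dispersed RLDR coverage
grows proportionally in both the peak and its flank, the log-ratio
plateaus, so the increase is monotone in the RLDR initiation rate only
while the dispersed background is small against the non-replicating
baseline; at high rates consecutive rate levels differ by only a few
hundredths of a log2 unit. The rate-monotonicity test therefore (i) runs
in the weak-background regime (short fork runs) and (ii) compares rate
levels on coupled Monte-Carlo draws — one master event set per replicate,
binomially thinned to each rate, which is exact for Poisson processes and
removes between-rate simulation variance. This is variance reduction, not
a relaxation of the property being tested.

## The generative model

`expected_copy_profile()` composes three strictly positive parts and
normalizes the product to genome-wide mean 1:

1. **oriC component.** The standard exponential-culture marker-frequency
   form $2^{(C/\tau)(1 - m(x))}$, where $m(x) \in [0,1]$ is the fraction of
   the replication period at which position $x$ is replicated. $m$ is
   computed by advancing both *oriC* forks at equal speed on the circle;
   each position belongs to the first fork that reaches it, forks arrest at
   full-efficiency barriers in blocking orientation, and if both forks
   arrest before meeting the residual gap is assigned the completion time.
   Under spectinomycin this component is identically 1 (all rounds have
   completed). Partial-efficiency barriers are ignored here — they matter
   for individual stochastic forks, not for the deterministic mean of
   *oriC* replication, which normally meets inside the trap before
   reaching either barrier.
2. **RLDR component.** `Poisson(rate × n_cells)` initiation events with
   origins uniform on the chromosome ("weak, widely distributed origins").
   Each event fires two unidirectional forks that run an exponential
   distance (mean `rldr_run_mean`) or stop at the first barrier in
   blocking orientation, each encountered barrier arresting with
   probability equal to its efficiency. When **both** forks of an event
   are trapped (a fork pair held at the two barriers flanking its origin —
   the configuration whose fusion/restart is thought to trigger runaway
   re-replication), the event adds, with probability `rereplication_prob`,
   a geometric number (mean `rereplication_gain`) of extra copies of the
   trapped interval. The per-window Monte-Carlo average of event coverage
   is added to the profile. A single event's replicated interval is capped
   at one genome length.
3. **Amplification.** A multiplicative fold over a stated region, modelling
   stable genomic amplifications such as the *parC parE* block; it
   multiplies total copy number (a duplicated segment duplicates whatever
   is synthesized in it).

Read counts are then `Poisson(depth × expected)` per window, independent
across windows — the standard shotgun-depth noise model. Everything is
deterministic given the config seed.

### Barrier polarity convention

Coordinates increase clockwise and wrap at the genome length. A `ter_site`
records the side from which an arriving fork is arrested: `blocks = "cw"`
arrests forks approaching from the clockwise side (moving toward lower
coordinates), `blocks = "ccw"` the reverse. With a left trap boundary
blocking `"cw"` and a right boundary blocking `"ccw"`, forks *entering*
the terminus from either replichore pass the near barrier and stop at the
far one, and forks *originating inside* the trap are caught at both edges
— the permissive-inward, blocking-outward geometry of the Tus/*Ter*
system. `apply_inversion()` maps positions $p \in [a,b)$ to $a+b-1-p$ and
flips the blocked side of barriers inside the segment; it is an involution
on the full feature set.

### Scenario presets and their defaults

The study's strain classes map to `make_scenario()` presets (all with
$C/\tau = 1$, so the wild-type origin:terminus ratio is 2, typical of
moderate growth):

| preset | rldr_rate | burst prob × gain | tus | amplification | inversion |
|---|---|---|---|---|---|
| `wild_type` | 0 | — | yes | none | none |
| `topA` | 0.5 | 0.5 × 70 | yes | 1.15× @ 2.99–3.24 Mb | none |
| `topA_topB` | 3 | 0.5 × 70 | yes | 2× @ 2.99–3.24 Mb | none |
| `topA_topB_tus` | 3 | 0.5 × 70 | no | 2× | none |
| `topA_topB_inv` | 3 | 0.5 × 70 | yes | 2× | [1.52, 1.84) Mb |

No quantitative values for the RLDR initiation rate, fork run length or
re-replication gain are published; they are free knobs of this package,
chosen once from the generative model's arithmetic: with run mean 500 kb,
the probability that both forks of a trap-interval event reach their
barriers is `exp(-345/500) ≈ 0.5`, so the mean number of extra Ter copies
per cell is `0.0186 × rate × gain`. Rate 3 with gain 70 puts the
simulated log-phase ydcM/lepA ratio near the published 2.8 and the
spectinomycin Ter peak in the multi-fold elevation regime of the published
profiles, while keeping bursts frequent enough (~0.06/cell) that the
Monte-Carlo error of the peak statistic at `n_cells` = 2000–5000 is small
against the spectinomycin increase. The two-hour spectinomycin run-off is
not modelled in time; `make_scenario(..., spc = TRUE)` doubles the rate
(continued RLDR accumulation) and flattens the *oriC* component, which is
all the profile shape can expose.

The preset amplification fold is 2 rather than the ~4.3 that would
reproduce the published *topA topB* qseC/lepA ratio of 4.9. The two
constraints cannot hold simultaneously in this model: the amplified block
multiplies total copy number, so a 4.3× block would exceed any attainable
relocated Ter peak in the inversion scenario and move the profile argmax
into the amplification — contradicting the observed profile shapes, where
the Ter peak towers over the *amp* bump. The fold-recovery tests inject
1.3 and 4.9 directly and are unaffected by the preset. The `topA` preset
fold of 1.15 reproduces the published *topA*-null qseC/lepA of 1.3 once
the *oriC* gradient between the two loci is included.

### The default chromosome map

The shipped map (4.64 Mb, oriC at 3.925 Mb, TerA 1.34 / TerB 1.685 /
TerG 2.38 Mb with TerG at efficiency 0.5 — a weak barrier — and loci ydcM
1.525, lepA 2.73, qseC 3.17 Mb) uses approximate coordinates at the right
genomic scale; exact published coordinates exist only at Mb precision, so
the file is explicitly synthetic and user-editable
(`inst/extdata/ecoli_w3110_synthetic_map.tsv`, `read_map_tsv()`). All
package tests run on this map or on smaller toy maps built in code.

## What a green simulation test does and does not establish

The simulator reproduces the *statistical structure* of MFA data — the
exponential-culture gradient, trap-bounded over-replication, run-off
flattening, barrier relocation after an inversion, amplification blocks,
Poisson depth noise — so passing tests establish that the estimators
recover known inputs under that structure (fold recovery within 10%,
origin:terminus ratio within 5%, relocation of the argmax, sign and
monotonicity of the peak-increase statistic). They do not establish
robustness to features real data have and the model omits: GC and
mappability bias, overdispersed counts, *rrn*-operon extraction artifacts,
deletion gaps, replication-transcription conflict hotspots, non-uniform
RLDR origin placement, or time-resolved run-off kinetics. The control
normalization absorbs multiplicative window biases shared with the
stationary control; everything else is out of model scope.

## Numerical and interface choices

* Reads are assigned by leftmost coordinate only (CIGAR ignored): depth
  here is a read-start count, which is deterministic and exactly
  conserving; duplicate reads are not removed (no deduplication step is
  part of the published pipeline).
* A SAM position equal to the genome length is the valid last base
  (1-based input, 0-based half-open internally); positions beyond it are
  errors, never wrapped.
* qPCR ratios are computed per replicate with `2^-dCt` (100% efficiency
  assumed) and averaged as ratios — mean and SD are taken over the
  per-replicate ratios, not over Ct values; a single replicate reports
  SD 0 with `sd_defined = FALSE`. The two DNA input amounts (50/100 ng)
  are treated as replicates.
* `adjusted_activity(b, r, k)` = `b + (r - b)/k` linearly interpolates the
  activity of an overexpressed fusion enzyme that is `k`-fold less active
  than the native one; `k` outside the published 5–10 range warns rather
  than errors.
* Scenario configs serialize to JSON (`write_config_json()`);
  `run_pipeline()` writes a manifest with every parameter and derived
  stage seed, and its outputs are byte-identical across runs of the same
  config.

## Known limitations

Log-scale saturation of the peak statistic at high RLDR rates (above); no
overdispersion knob in the noise model; the mean *oriC* component treats
sub-unit-efficiency barriers as transparent; re-replication bursts require
both forks trapped, so configurations with only one barrier polarity never
burst; and the flatness threshold, when no control profile is supplied,
uses the profile's own off-peak loess SD, which inflates (conservatively)
when the *oriC* gradient is present.
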