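---
title: "Models and methods behind poliseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poliseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poliseq)
```

`poliseq` quantifies RNA polymerase I (Pol I) transcription of the rDNA 35S
unit from two complementary kinds of data: in vivo NET-seq occupancy
(single-nucleotide positions of elongating polymerases) and in vitro
single-round transcription assays on a C-less cassette template. This
vignette is the package's account of its models, the assumptions behind
them, the simulator that generates its inputs, and the numerical choices a
maintainer would want written down.

## The occupancy model

NET-seq reads are aligned to a single rDNA repeat unit. The 5′ end of a
sense-strand read marks the 3′ end of a nascent transcript, so the count of
read 5′ ends at position *p* estimates the number of polymerases whose
active site sits at *p*. Analysis is deliberately restricted to one repeat
unit: the biological signal of interest (occupancy shape along the 35S
unit) is identical across the tandem repeats, and collapsing multi-copy
alignments is upstream alignment plumbing, not analysis. Coordinates are
0-based half-open internally (BED convention) and 1-based in every report.

Three filters precede counting: only primary, mapped, plus-strand
alignments with 5′ ends inside the 35S span are kept (the unit is
transcribed from one strand; antisense reads are artefacts), and reads are
UMI-deduplicated — exactly one read per distinct (5′ position, UMI) pair,
keeping the first in coordinate order so the operation is deterministic and
idempotent. Tracks are scaled to counts-per-million over the 35S span by
default. The scaling matters: per-position tests across libraries of
different depth are meaningless on raw counts. A `normalize = FALSE` escape
hatch exists for depth-matched designs.

**Reproducibility** is Spearman's rank correlation with average-rank tie
handling, computed over positions where at least one of the two libraries
is nonzero. Positions at zero in both libraries carry no ranking
information and would only inflate the tie mass. Fewer than three
informative positions is an error, not a coefficient.

**Differential occupancy** is a per-position two-sided Welch *t*-test
between replicate sets. Welch rather than pooled-variance: with three
replicates per condition there is no basis for assuming equal variances.
Positions with *p* below α (default 0.05) are classified `increased` or
`decreased` by the direction of the median difference (drug relative to
vehicle); everything else is `ns`. No multiple-testing correction is
applied — the raw per-position threshold is the convention for this assay
and is recorded in the output metadata so downstream users are not misled.
Degenerate positions (zero variance in both groups) get *p* = 1 when the
means agree and *p* = 0 with a `degenerate` flag when they differ; they are
reported rather than dropped so tracks stay alignable position-for-position.

**Per-spacer distribution tests** use the two-sample Kolmogorov–Smirnov
statistic. The two samples are the per-position median occupancy values of
each condition within one spacer region. This is an interpretation
decision: a distribution test needs two samples, and treating the vehicle
values and drug values over the region's positions as those samples is the
reading that matches a "distribution of occupancy within the region"
comparison. The spacers (ETS1, ITS1, ITS2, ETS2) are the informative
regions because mature-rRNA contamination is confined to the 18S/5.8S/25S
gene regions — spacer RNA is removed during rRNA maturation, so spacer
signal can only come from nascent transcripts. Regions shorter than 10
positions are refused (the ECDF gap is uninformative there).

## Pause calling and the differential logo

Pause sites for a condition are the top 2.5% (configurable) most-occupied
positions of that condition's median track, among eligible positions:
spacer positions with nonzero occupancy. Ranking is by count descending
with ties broken by ascending position, truncated at
`ceiling(quantile * n_eligible)` — fully deterministic, and a degenerate-tie
message is emitted when the boundary splits a tie run.

Around each site, the ±15 nt sense-strand window is extracted with column
0 the last incorporated nucleotide. Fifteen nucleotides cover the RNA:DNA
hybrid (~9 nt upstream) and the downstream duplex a DNA intercalator would
engage; both half-widths are configurable. Windows that would run off the
unit are dropped with a warning and counted.

Per-column base probabilities get a pseudocount of 0.5 per base before
normalization. Without it, a small pause set can produce zero
probabilities, and the divergence of a zero-containing column against a
point mass saturates regardless of the data.

The differential logo compares two probability matrices column by column:
stack height is the Jensen–Shannon divergence in bits (base-2 logarithm,
equal weights), which is symmetric and bounded by 1 bit; each base's signed
contribution is its probability difference rescaled so that the magnitudes
in a column sum to that column's divergence, positive when the base is
enriched in the first (drug) condition. This reimplements the
difference-logo idea natively; the exact normalization constant of external
difference-logo software is not reproduced, so numerical equality with
other tools is not expected — divergences and directions are.

## The in vitro models

**Dose–response.** Full-length product signal against inhibitor
concentration is fit to a single exponential, S(c) = A·exp(−c·ln2/IC50),
by Levenberg–Marquardt nonlinear least squares (A₀ = max signal, IC50₀ =
median nonzero concentration, bounds IC50 ∈ [10⁻⁶, 10³] µM). The ln 2
factor makes IC50 exactly the half-amplitude concentration, which is what
an IC50 should mean; this parameterization choice is recorded in the fit
metadata. A fit driven to the upper IC50 bound (non-decaying data) is
reported with `converged = FALSE` rather than as a number.

**Promoter escape.** reduction(t) = 100·(1 − drug(t)/vehicle(t)), with the
maximum and its time point attached as attributes. Time points with zero
vehicle signal are undefined and flagged NA with a warning; when both
signals are nonnegative the reduction can never exceed 100%.

**Densitometry.** Lane profiles are intensity against migration, migration
increasing with mobility (shorter RNA migrates further). Ladder
calibration pairs rung lengths (descending) with detected band peaks
(ascending migration; local maxima at or above 10% of lane maximum,
strongest peaks kept if extras are present) and fits log₁₀(length) linear
in migration — the standard semi-log gel model. The leading edge of a lane
is the least-migrated contiguous region at or above 20% of the lane
maximum; its intensity-weighted centroid, converted through the
calibration, is the leading-population RNA length. The 10% and 20%
thresholds are ordinary densitometry boxing choices standing in for
boxing-by-eye in gel software, and both are arguments. Elongation rate is
the OLS slope of leading-edge length against time. Pause bands are
sub-leading local maxima (same 20% rule) converted to lengths and
single-linkage clustered across lanes with a ±5 nt tolerance; a band must
appear in at least half the lanes to be called conserved. No background
subtraction is modelled: synthetic lanes are generated background-free,
and real-gel background correction is out of scope.

## The synthetic data generator

The simulator is first-class, tested code: it defines the data-generating
process every statistical claim in the test suite is made against.

The reference is one 9.1 kb repeat unit (`build_rdna_reference()`) with the
canonical region order promoter–ETS1–18S–ITS1–5.8S–ITS2–25S–ETS2–5S,
proportioned roughly like the yeast repeat but configurable; exact genomic
coordinates are intentionally not reproduced because every downstream
computation is coordinate-agnostic. Base composition is uniform except
that spacers are seeded with G-runs (≥4 G, about one per 60 nt) so that a
G-dependent pausing mechanism has sequence to act on.

Per-position nascent intensity λ is a lognormal landscape (median-1 scale,
`lambda_sdlog` log-SD) shared between conditions. Condition effects:

- vehicle: positions inside G-rich sequence (G fraction ≥ `gc_threshold`
  in the `gc_window` centred on the position) are multiplied by
  `base_pause_weight` — intrinsic pausing within G-rich tracts;
- drug: every position is multiplied by `initiation_scale` (< 1; fewer
  initiating polymerases), and positions whose strictly downstream window
  is G-rich are multiplied by `drug_pause_weight` — the polymerase stalls
  with the G-rich DNA ahead of it, where an intercalator would sit. The
  position is the last incorporated nucleotide.

Libraries sample exactly `depth` read 5′ ends: contamination reads
uniformly over the gene regions only, nascent reads proportional to λ.
The contamination pool is a fixed absolute load anchored to the unweighted
baseline (parameterized as the vehicle-condition fraction,
`contamination_fraction`), so a drug library — with less nascent RNA but
unchanged mature rRNA — is automatically relatively more contaminated.
Each read carries a random 6-mer UMI in the `RX` SAM tag (a tag rather
than a read-name convention: self-contained and parseable), and a
`duplicate_rate` fraction of reads re-emit an earlier (position, UMI) pair
so deduplication has real work to do. Every generator is a pure function
of its configuration and seed.

In vitro fixtures: titrations follow the single-exponential model exactly
at zero noise; the default concentration series is vehicle plus the
two-fold series 0.125–4 µM. The default promoter-escape time course
(0.5–4 min) multiplies a first-order vehicle accumulation curve by an
escape-competent fraction relaxing from 0.95 toward 0.50, calibrated so
the drug/vehicle ratio at 4 min is 0.51 — i.e. the 49% maximal suppression
the assay it emulates reports; 300 nM is the drug concentration this
time-course design corresponds to. Elongation lanes render leading-edge
bands at start + rate·t (default start 55 nt, times 4–10 s, template
800 nt) as Gaussian bands on a log-linear migration axis, with optional
fixed-length pause sub-bands shared across lanes and a ladder lane. Noise
everywhere is additive Gaussian, matching assays that report means ± SD of
triplicates.

### Calibration and problem sizes

Two generator defaults were calibrated jointly so that the statistical
properties the simulator is meant to exhibit hold with margin,
and they are worth explaining:

- `lambda_sdlog = 0.7`: enough position-to-position heterogeneity that
  replicate ranking is informative (Spearman ρ of replicate pairs well
  above 0.9 at the simulation depths used) while keeping the per-spacer
  occupancy distributions narrow enough that a ~2-fold median shift is
  detectable by the K-S test at spacer-region sample sizes.
- simulation studies (reproducibility, differential power, type-I control,
  pause-context recovery) run on a **compact unit**,
  `compact_region_lengths()` (~1.2 kb): spacers at roughly one third of
  their full lengths, gene regions at roughly one tenth. At 10⁵ reads per
  library this gives per-position coverage comparable to deeply sequenced
  real libraries over the full 9.1 kb unit. The asymmetric scaling is
  deliberate: the K-S tests need per-spacer position counts (≥ ~50) while
  the per-position *t*-tests and rank correlations need per-position read
  counts (≥ ~25), and no proportional shrinkage satisfies both at that
  depth. On a full-size unit at 10⁵ reads, vehicle spacer coverage
  averages ~7 reads per position, and a 3-vs-3 Welch test simply cannot
  resolve a ~2-fold shift at such counts for the majority of positions —
  that is a property of the t distribution, not of the implementation.

What the simulator does *not* emulate: sequencing errors, adapters and
quality scores; multi-copy rDNA alignment ambiguity; co-transcriptional
processing structure within the contamination (it is uniform over genes);
replicate-level batch effects (replicates differ only by sampling noise);
gel background and lane distortion. Passing tests therefore demonstrate
that the statistics recover the encoded mechanisms from data with
realistic sampling noise — not that they are robust to every artefact of
real libraries.

## Defaults at a glance

| parameter | default | meaning |
|---|---|---|
| `depth` | 1e5 | primary alignments per library |
| `contamination_fraction` | 0.5 | mature-rRNA read fraction in a vehicle library (unquantified in practice; configurable by design) |
| `initiation_scale` | 0.4 | drug-condition multiplier on all nascent λ |
| `base_pause_weight` / `drug_pause_weight` | 3 / 12 | occupancy multiplier at G-rich (vehicle) / pre-G-rich (drug) positions |
| `gc_window`, `gc_threshold` | 6 nt, 0.6 | window and G fraction defining "G-rich" |
| `lambda_sdlog` | 0.7 | log-SD of the baseline occupancy landscape |
| `umi_length`, `duplicate_rate` | 6, 0.1 | UMI width; fraction of re-emitted (position, UMI) pairs |
| `alpha` | 0.05 | per-position significance threshold |
| `quantile` | 0.025 | pause-calling fraction of eligible spacer positions |
| `window` (±) | 15 nt | pause-context half-width |
| pseudocount | 0.5 | per base per column, before PPM normalization |
| peak / leading-edge thresholds | 10% / 20% | of lane maximum |
| pause-band tolerance | ±5 nt | cross-lane band matching |

## Known limitations

- The K-S "distribution of medians" interpretation is one of several
  defensible readings of a per-region distribution comparison; it is
  logged in the run metadata.
- Raw per-position *p*-values with no multiplicity control inflate
  family-wise error by construction; the output flags this, and users who
  need FDR control can apply `p.adjust` to the `p_value` column.
- The differential logo's stack scaling follows the
  contributions-sum-to-JSD convention; other difference-logo
  implementations normalize differently, so compare shapes and
  divergences, not raw letter heights, across tools.
- Single-repeat analysis cannot see copy-number or inter-repeat
  variation.
- The IC50 model is a pure exponential decay with no floor; assays with a
  resistant signal fraction would need an offset term the current model
  does not include.
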