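# poliseq

Quantitative analysis of RNA polymerase I (Pol I) transcription of the rDNA
35S unit, for researchers studying Pol I inhibitors (such as the GC-rich DNA
intercalator BMH-21) with a combination of **in vivo NET-seq** and
**promoter-dependent in vitro transcription assays**.

Native elongating transcript sequencing (NET-seq) reads out polymerase
positions at single-nucleotide resolution: the 5′ end of each aligned read
marks the 3′ end of a nascent transcript, so per-position read counts are
per-position Pol I occupancy. `poliseq` turns aligned reads into occupancy
tracks and asks, between a vehicle- and a drug-treated condition, where
occupancy falls, where polymerases pause, and what sequence lies around the
pause sites. A companion set of functions quantifies the in vitro assays run
on a C-less cassette template (no cytosine encoded in the transcript until
+56, so withholding CTP synchronises polymerases at +55): dose–response
inhibition, promoter-escape suppression, and gel-based elongation-rate
measurement.

## What it computes

**NET-seq side** (per-position over the 35S unit ETS1–18S–ITS1–5.8S–ITS2–25S–ETS2):

- UMI deduplication (one read per distinct 5′-position × UMI pair) and
  counts-per-million occupancy tracks;
- replicate reproducibility as Spearman's rank correlation ρ over informative
  positions;
- per-position two-sided Welch *t*-tests between conditions, classifying each
  position as `increased` / `decreased` / `ns` at raw *p* < α (α = 0.05, no
  multiple-testing correction, matching the per-position convention of the
  assay);
- per-spacer two-sample Kolmogorov–Smirnov tests (D = max ECDF gap) on the
  distribution of median occupancy values, spacers being the regions
  (ETS1/ITS1/ITS2/ETS2) free of mature-rRNA contamination;
- pause sites as the top 2.5% most-occupied nonzero spacer positions per
  condition, and a differential sequence logo comparing their ±15 nt context:
  per column, stack height = Jensen–Shannon divergence (bits, ≤ 1) between
  the two base-probability columns, letters signed by the enriched condition,
  with column 0 the last incorporated nucleotide.

**In vitro side:**

- single-exponential dose–response fits, signal(c) = A·exp(−c·ln2/IC50), so
  IC50 is exactly the half-amplitude concentration;
- promoter-escape suppression, reduction(t) = 100·(1 − drug(t)/vehicle(t));
- ladder-calibrated densitometry (log₁₀ length linear in migration),
  leading-edge centroid lengths, OLS elongation-rate fits (nt/s), and
  detection of pause bands conserved across lanes.

A seed-reproducible simulator (`sim_config()`, `build_rdna_reference()`,
`simulate_condition_occupancy()`, `simulate_netseq_library()`, …) generates
every input the pipeline consumes, emulating reduced initiation, a fixed
mature-rRNA contamination pool confined to the 18S/5.8S/25S genes, and
drug-induced pausing immediately upstream of G-rich sequence.

## Worked example

```r
library(poliseq)

# --- in vitro: refit a noiseless titration generated at IC50 = 0.81 uM
fit_dose_response_ic50(simulate_titration(0.81, amplitude = 1))
#> <dose_response_fit> IC50 = 0.81 uM, amplitude = 1, SSE = 3.27e-33, converged

# --- promoter escape: percent reduction of drug vs vehicle full-length RNA
promoter_escape_reduction(simulate_escape_timecourse())
#>   time_min vehicle  drug reduction_pct
#> 1      0.5    33.0  25.7          22.0
#> 2      1      55.1  37.1          32.6
#> 3      1.5    69.9  42.5          39.2
#> 4      2      79.8  45.3          43.3
#> 5      4      95.9  48.9          49
```

The maximal reduction, 49% at the 4-minute point, is the headline
suppression of promoter escape; the titration refit recovers the generating
half-maximal concentration exactly.

```r
# --- elongation rate from synthetic gel lanes (ladder: 100/200/400/800 nt)
g   <- simulate_elongation_timecourse(rate = 40, pause_sites = c(150, 320))
cal <- calibrate_ladder(g$ladder, c(100, 200, 400, 800))
lanes <- split(g$lanes, g$lanes$lane_id)
pts <- tibble::tibble(
  time_s    = sapply(lanes, function(l) l$time_s[1]),
  length_nt = sapply(lanes, function(l) leading_edge_length(l, cal))
)
fit_elongation_rate(pts)
#> <elongation_fit> rate = 40 nt/s, intercept = 55 nt, R^2 = 1.0000 (n = 4)
detect_pause_bands(g$lanes, cal)
#>   band_length_nt n_lanes
#> 1           320.       2
#> 2           150.       4
```

The fitted slope is the elongation rate (40 nt/s here), the intercept the
synchronized +55 halt length, and the two sub-bands shared across lanes are
recovered at their generating lengths.

```r
# --- NET-seq: simulate a two-condition study on a compact unit and analyse it
rl  <- compact_region_lengths()
ref <- build_rdna_reference(unit_length = sum(rl) + 60, region_lengths = rl,
                            seed = 101)
cfg <- sim_config(seed = 101)          # depth 1e5, initiation_scale 0.4, ...
tracks <- function(cond, seeds) lapply(seeds, function(s) {
  lam   <- simulate_condition_occupancy(ref$sequence, ref$annotation, cfg, cond)
  reads <- dedup_umis(simulate_netseq_library(lam, ref$annotation, cfg,
                                              replicate_seed = s))
  build_occupancy_track(reads, ref$annotation, condition = cond)
})
v <- tracks("vehicle", 102:104); d <- tracks("drug", 115:117)

spearman_reproducibility(v[[1]], v[[2]])$rho            # 0.952
spacer_ks_test(median_occupancy(v), median_occupancy(d),
               ref$annotation, "ETS1")                  # D = 0.36, p = 1.4e-13
table(positionwise_ttest(v, d)$sig_class)
#> increased decreased        ns
#>       124       376       550
```

Replicates from one intensity landscape are highly reproducible (ρ > 0.9),
drug-treated occupancy is significantly depleted in the spacers, and the
majority of significant positions are decreases — the drug phenotype the
simulator encodes. `call_pause_sites()`, `extract_windows()`,
`window_probability_matrix()` and `differential_logo()` then recover
downstream G-enrichment at drug pause sites; `autoplot()` methods draw each
result type.

`run_netseq_pipeline()` and `run_invitro_pipeline()` chain these stages from
files on disk (SAM/BAM + FASTA + BED, or CSV tables) to a report bundle
(bedGraph tracks, CSV tables, BED pause sites, JSON metadata), and
`simulate_study()` writes a complete synthetic input set.

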