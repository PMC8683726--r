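# Shared fixtures, all generated in code at test time.

# A 200 nt toy unit with all canonical regions, small enough to reason about
# by hand. Spacer span: ETS1 10-40, ITS1 80-100, ITS2 112-130, ETS2 170-190.
toy_annotation <- function() {
  rdna_annotation(
    tibble::tribble(
      ~region,    ~start, ~end,
      "promoter",     0L,  10L,
      "ETS1",        10L,  40L,
      "18S",         40L,  80L,
      "ITS1",        80L, 100L,
      "5.8S",       100L, 112L,
      "ITS2",       112L, 130L,
      "25S",        130L, 170L,
      "ETS2",       170L, 190L
    ),
    unit_length = 200L
  )
}

# Deterministic toy reference matching toy_annotation(), with a known G-run
# at 1-based positions 21-28 (inside ETS1).
toy_reference <- function(seed = 5L) {
  base <- withr::with_seed(seed, {
    sample(c("A", "C", "T"), 200, replace = TRUE)
  })
  base[21:28] <- "G"
  paste(base, collapse = "")
}

# The compact spacer-weighted study unit used for simulation properties.
compact_reference <- function(seed = 101L) {
  rl <- compact_region_lengths()
  build_rdna_reference(
    unit_length = as.integer(sum(rl) + 60L),
    region_lengths = rl,
    seed = seed
  )
}

# Simulate replicate occupancy tracks for one condition on a given unit.
simulate_tracks <- function(ref, config, condition, replicate_seeds,
                            normalize = TRUE) {
  lambda <- simulate_condition_occupancy(ref$sequence, ref$annotation,
                                         config, condition)
  lapply(seq_along(replicate_seeds), function(i) {
    reads <- simulate_netseq_library(
      lambda, ref$annotation, config,
      replicate_seed = replicate_seeds[i],
      library_id = sprintf("%s_rep%d", condition, i)
    )
    reads <- dedup_umis(reads)
    build_occupancy_track(reads, ref$annotation, normalize = normalize,
                          condition = condition)
  })
}

# Build an occupancy_track directly from a count vector (bypassing reads),
# for tests that exercise downstream statistics only.
track_from_counts <- function(counts, annotation, condition = "vehicle",
                              normalized = FALSE, library_id = "manual") {
  out <- tibble::tibble(position = positions_35s(annotation),
                        count = as.numeric(counts))
  attr(out, "condition") <- condition
  attr(out, "normalized") <- normalized
  attr(out, "library_id") <- library_id
  attr(out, "total_reads") <- sum(counts)
  class(out) <- c("occupancy_track", class(out))
  out
}

# Write a small SAM file from a record tibble (qname, flag, pos, umi).
write_toy_sam <- function(path, records, reference_name = "rdna_unit",
                          unit_length = 200L, with_umi = TRUE) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", reference_name, unit_length)
  )
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    tag <- if (with_umi && !is.na(r$umi)) sprintf("\tRX:Z:%s", r$umi) else ""
    sprintf("%s\t%d\t%s\t%d\t255\t10M\t*\t0\t0\tACGTACGTAC\t*%s",
            r$qname, r$flag, reference_name, r$pos, tag)
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Average-rank (midrank) computation, written independently of base rank().
midranks <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  out
}
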