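#' Simulation configuration for synthetic NET-seq libraries
#'
#' Bundles the parameters of the data-generating process the simulator
#' emulates: sequencing depth, mature-rRNA contamination, drug-induced
#' reduction of initiation, and sequence-dependent pause weighting around
#' G-rich windows.
#'
#' @param seed Integer master seed; identical config + seed gives
#'   bit-identical outputs.
#' @param depth Primary alignments per library.
#' @param contamination_fraction Fraction of reads that are mature-rRNA
#'   contamination in a vehicle-condition library, in `[0, 1]`. The
#'   contamination pool is modelled as a fixed absolute load, so conditions
#'   with reduced nascent synthesis show a proportionally larger effective
#'   contamination fraction.
#' @param initiation_scale Multiplier (< 1 for the drug condition) applied
#'   to all nascent intensities, modelling reduced initiation.
#' @param base_pause_weight Occupancy multiplier at intrinsically pause-prone
#'   (G-rich) positions in the vehicle condition.
#' @param drug_pause_weight Occupancy multiplier at positions immediately
#'   upstream of G-rich windows in the drug condition, modelling a
#'   drug-intercalation barrier to elongation.
#' @param gc_window Width (nt) of the window used to score G-richness.
#' @param gc_threshold Minimum G fraction of the window, in `[0, 1]`.
#' @param n_replicates Replicate libraries per condition.
#' @param umi_length Length of the random UMI carried by each read.
#' @param duplicate_rate Fraction of reads that re-emit an already-emitted
#'   (position, UMI) pair, exercising deduplication.
#' @param lambda_sdlog Log-scale SD of the lognormal per-position baseline
#'   intensity (position-to-position occupancy heterogeneity).
#' @param read_length Aligned read length in nt.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       depth = 1e5,
                       contamination_fraction = 0.5,
                       initiation_scale = 0.4,
                       base_pause_weight = 3,
                       drug_pause_weight = 12,
                       gc_window = 6L,
                       gc_threshold = 0.6,
                       n_replicates = 3L,
                       umi_length = 6L,
                       duplicate_rate = 0.1,
                       lambda_sdlog = 0.7,
                       read_length = 30L) {
  cfg <- list(
    seed = as.integer(seed), depth = as.integer(depth),
    contamination_fraction = contamination_fraction,
    initiation_scale = initiation_scale,
    base_pause_weight = base_pause_weight,
    drug_pause_weight = drug_pause_weight,
    gc_window = as.integer(gc_window), gc_threshold = gc_threshold,
    n_replicates = as.integer(n_replicates),
    umi_length = as.integer(umi_length), duplicate_rate = duplicate_rate,
    lambda_sdlog = lambda_sdlog, read_length = as.integer(read_length)
  )
  probs <- c(cfg$contamination_fraction, cfg$gc_threshold, cfg$duplicate_rate)
  if (any(probs < 0) || any(probs > 1)) {
    stop_invalid("contamination_fraction, gc_threshold and duplicate_rate must lie in [0, 1].")
  }
  if (cfg$depth <= 0L) stop_invalid("`depth` must be positive.")
  if (cfg$initiation_scale <= 0) stop_invalid("`initiation_scale` must be positive.")
  if (cfg$base_pause_weight <= 0 || cfg$drug_pause_weight <= 0) {
    stop_invalid("Pause weights must be positive.")
  }
  if (cfg$n_replicates < 1L) stop_invalid("`n_replicates` must be >= 1.")
  structure(cfg, class = "sim_config")
}

# G fraction of every window of `width` nt starting at each 1-based unit
# position (NA where the window runs off the unit).
g_window_fraction <- function(is_g, width, from) {
  n <- length(is_g)
  cs <- c(0, cumsum(is_g))
  starts <- seq_len(n) + from
  ends <- starts + width - 1L
  out <- rep(NA_real_, n)
  ok <- starts >= 1L & ends <= n
  out[ok] <- (cs[ends[ok] + 1L] - cs[starts[ok]]) / width
  out
}

#' Simulate per-position Pol I occupancy intensity over the 35S unit
#'
#' Produces the expected nascent-3'-end intensity lambda at each position of
#' the 35S transcription unit for one condition. The baseline is a
#' seed-determined lognormal landscape shared by both conditions. In the
#' vehicle condition, positions sitting inside G-rich sequence (G fraction of
#' the window centred on the position >= `gc_threshold`) are up-weighted by
#' `base_pause_weight`. In the drug condition all intensities are scaled by
#' `initiation_scale` and positions whose strictly downstream
#' `gc_window`-nt window is G-rich are up-weighted by `drug_pause_weight`
#' (position = last incorporated nucleotide; the G-rich DNA lies ahead of
#' the polymerase).
#'
#' @param reference Single DNA string for the repeat unit.
#' @param annotation Matching [rdna_annotation()].
#' @param config A [sim_config()].
#' @param condition `"vehicle"` or `"drug"`.
#' @return A tibble of class `occupancy_intensity` with columns `position`
#'   (1-based unit coordinate over the 35S span) and `intensity`; attributes
#'   `condition` and `base_total` (sum of the unweighted baseline, used to
#'   anchor the contamination load).
#' @export
simulate_condition_occupancy <- function(reference, annotation, config,
                                         condition = c("vehicle", "drug")) {
  condition <- match.arg(condition)
  if (nchar(reference) != unit_length(annotation)) {
    stop_input("Reference length does not match the annotation unit length.")
  }
  pos <- positions_35s(annotation)
  base <- with_seed(config$seed, {
    rlnorm(length(pos), meanlog = -config$lambda_sdlog^2 / 2,
           sdlog = config$lambda_sdlog)
  })

  is_g <- as.integer(str_chars(reference) == "G")
  w <- config$gc_window
  # Drug: window strictly downstream of the last incorporated nucleotide.
  g_down <- g_window_fraction(is_g, w, from = 1L)[pos]
  # Vehicle: window covering the position itself (centred).
  g_at <- g_window_fraction(is_g, w, from = -(w %/% 2L))[pos]

  lambda <- base
  if (condition == "vehicle") {
    hit <- !is.na(g_at) & g_at >= config$gc_threshold
    lambda[hit] <- lambda[hit] * config$base_pause_weight
  } else {
    lambda <- lambda * config$initiation_scale
    hit <- !is.na(g_down) & g_down >= config$gc_threshold
    lambda[hit] <- lambda[hit] * config$drug_pause_weight
  }

  out <- tibble(position = pos, intensity = lambda)
  attr(out, "condition") <- condition
  attr(out, "base_total") <- sum(base)
  class(out) <- c("occupancy_intensity", class(out))
  out
}

random_umis <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate one UMI-tagged NET-seq library
#'
#' Emits exactly `config$depth` primary sense-strand alignments against the
#' repeat unit. A fraction of reads are mature-rRNA contamination whose
#' 5' ends fall uniformly over the 18S/5.8S/25S gene regions only; the
#' remainder sample 5'-end positions proportionally to `intensity` (the read
#' 5' end marks the 3' end of the nascent transcript). Each read carries a
#' random fixed-length UMI; `duplicate_rate` re-emits already-seen
#' (position, UMI) pairs so that deduplication is exercised.
#'
#' The effective contamination fraction is
#' `C / (C + sum(intensity))` with the contamination load
#' `C = contamination_fraction / (1 - contamination_fraction) * base_total`:
#' a fixed absolute pool, so drug-scaled libraries are relatively more
#' contaminated, as mature rRNA is unaffected by an acute treatment.
#'
#' @param intensity An `occupancy_intensity` (or tibble with `position` and
#'   `intensity`).
#' @param annotation Matching [rdna_annotation()].
#' @param config A [sim_config()].
#' @param replicate_seed Integer seed for this library's sampling noise.
#' @param library_id Library identifier stored on the result.
#' @return A tibble of class `netseq_reads` (columns `qname`, `flag`,
#'   `pos` (1-based 5' end), `strand`, `umi`) sorted by coordinate, with
#'   attributes `library_id`, `condition`, `n_contamination`, `n_nascent`.
#' @export
simulate_netseq_library <- function(intensity, annotation, config,
                                    replicate_seed = config$seed,
                                    library_id = "lib") {
  if (nrow(intensity) == 0L || all(intensity$intensity <= 0)) {
    stop_input("`intensity` is empty; nothing to simulate.")
  }
  depth <- config$depth
  cf <- config$contamination_fraction
  base_total <- attr(intensity, "base_total") %||% sum(intensity$intensity)

  eff_cf <- if (cf >= 1) 1 else if (cf <= 0) 0 else {
    load <- cf / (1 - cf) * base_total
    load / (load + sum(intensity$intensity))
  }

  gene_pos <- region_positions(annotation, GENE_REGIONS)

  with_seed(replicate_seed, {
    n_contam <- rbinom(1L, depth, eff_cf)
    n_nascent <- depth - n_contam
    pos_contam <- if (n_contam > 0L) {
      sample(gene_pos, n_contam, replace = TRUE)
    } else integer()
    pos_nascent <- if (n_nascent > 0L) {
      sample(intensity$position, n_nascent, replace = TRUE,
             prob = intensity$intensity)
    } else integer()
    pos5 <- c(pos_nascent, pos_contam)
    umi <- random_umis(depth, config$umi_length)

    # Re-emit earlier (position, UMI) pairs to create PCR-style duplicates.
    if (config$duplicate_rate > 0 && depth > 1L) {
      dup <- which(runif(depth) < config$duplicate_rate)
      dup <- dup[dup > 1L]
      if (length(dup) > 0L) {
        src <- vapply(dup, function(i) sample.int(i - 1L, 1L), integer(1))
        pos5[dup] <- pos5[src]
        umi[dup] <- umi[src]
      }
    }

    ord <- order(pos5)
    out <- tibble(
      qname = sprintf("%s_read%06d", library_id, seq_len(depth)),
      flag = 0L,
      pos = as.integer(pos5[ord]),
      strand = "+",
      umi = umi[ord]
    )
    attr(out, "library_id") <- library_id
    attr(out, "condition") <- attr(intensity, "condition")
    attr(out, "n_contamination") <- n_contam
    attr(out, "n_nascent") <- n_nascent
    class(out) <- c("netseq_reads", class(out))
    out
  })
}

#' Write simulated reads as coordinate-sorted SAM
#'
#' Emits a minimal single-reference SAM with the UMI in the `RX` tag.
#' Read sequences are taken from the reference; reads are clipped at the
#' unit end.
#'
#' @param reads A `netseq_reads` tibble.
#' @param path Output SAM path.
#' @param reference Single DNA string for the repeat unit (used for read
#'   sequences and the header length).
#' @param reference_name Reference sequence name (default `"rdna_unit"`).
#' @param read_length Read length in nt (default 30).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, reference, reference_name = "rdna_unit",
                      read_length = 30L) {
  ulen <- nchar(reference)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", reference_name, ulen),
    "@PG\tID:poliseq\tPN:poliseq"
  )
  len <- pmin(read_length, ulen - reads$pos + 1L)
  seqs <- substring(reference, reads$pos, reads$pos + len - 1L)
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tRX:Z:%s",
    reads$qname, reads$flag, reference_name, reads$pos, len, seqs, reads$umi
  )
  writeLines(c(header, lines), path)
  invisible(path)
}
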