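#' Construct a strand-aware rDNA repeat-unit annotation
#'
#' An annotation is a tibble of named, non-overlapping intervals on a single
#' rDNA repeat unit, in 0-based half-open coordinates (BED convention).
#' The seven regions of the 35S primary transcript (ETS1, 18S, ITS1, 5.8S,
#' ITS2, 25S, ETS2) must appear in that order; spacers are
#' ETS1/ITS1/ITS2/ETS2 and mature-rRNA genes are 18S/5.8S/25S. The 35S unit
#' is transcribed from the plus strand only.
#'
#' @param regions A data frame with columns `region`, `start`, `end`
#'   (0-based half-open) and optionally `strand` (default `"+"`).
#' @param unit_length Length of the repeat unit in nt.
#' @return A tibble of class `rdna_annotation` with attribute `unit_length`.
#' @export
rdna_annotation <- function(regions, unit_length) {
  regions <- as_tibble(regions)
  if (!all(c("region", "start", "end") %in% names(regions))) {
    stop_invalid("`regions` needs columns region, start, end.")
  }
  if (!"strand" %in% names(regions)) regions$strand <- "+"
  regions <- arrange(regions, .data$start)
  if (any(regions$start < 0L) || any(regions$end > unit_length) ||
      any(regions$start >= regions$end)) {
    stop_invalid("Each region must satisfy 0 <= start < end <= unit_length.")
  }
  if (any(regions$start[-1L] < regions$end[-nrow(regions)])) {
    stop_invalid("Regions must not overlap.")
  }
  present <- intersect(REGIONS_35S, regions$region)
  if (!identical(regions$region[regions$region %in% REGIONS_35S], present) ||
      !setequal(present, REGIONS_35S)) {
    stop_invalid(paste(
      "The seven 35S regions must all be present, in order:",
      paste(REGIONS_35S, collapse = ", ")
    ))
  }
  out <- regions[, c("region", "start", "end", "strand")]
  attr(out, "unit_length") <- as.integer(unit_length)
  class(out) <- c("rdna_annotation", class(out))
  out
}

#' Default region lengths for a synthetic 9.1 kb rDNA repeat unit
#'
#' Proportioned roughly to the yeast rDNA repeat (which is ~9.1 kb and
#' contains the 35S and 5S genes); exact genomic coordinates are not
#' reproduced because the analysis is coordinate-agnostic.
#'
#' @return A named integer vector of region lengths in nt.
#' @export
default_region_lengths <- function() {
  c(promoter = 200L, ETS1 = 700L, `18S` = 1800L, ITS1 = 360L, `5.8S` = 160L,
    ITS2 = 230L, `25S` = 3400L, ETS2 = 210L, `5S` = 120L)
}

#' Compact region lengths for desk-scale simulation studies
#'
#' A miniature repeat unit (~1.1 kb) for simulation studies run at moderate
#' sequencing depth. Spacer regions are kept long relative to the
#' mature-rRNA genes because the spacers carry the nascent-transcription
#' signal the analysis interrogates, while the genes mostly absorb
#' mature-rRNA contamination; weighting the miniature unit toward spacers
#' preserves both per-position coverage and per-region sample sizes at
#' depths that run in seconds.
#'
#' @return A named integer vector of region lengths in nt.
#' @export
compact_region_lengths <- function() {
  c(promoter = 40L, ETS1 = 233L, `18S` = 180L, ITS1 = 120L, `5.8S` = 30L,
    ITS2 = 77L, `25S` = 340L, ETS2 = 70L, `5S` = 24L)
}

#' Unit length getter
#' @param annotation An `rdna_annotation`.
#' @return Integer unit length in nt.
#' @export
unit_length <- function(annotation) attr(annotation, "unit_length")

#' 0-based half-open span of the 35S transcription unit
#' @param annotation An `rdna_annotation`.
#' @return `c(start, end)`, 0-based half-open.
#' @export
span_35s <- function(annotation) {
  r <- annotation[annotation$region %in% REGIONS_35S, ]
  c(min(r$start), max(r$end))
}

#' 1-based repeat-unit positions covered by the 35S unit
#' @param annotation An `rdna_annotation`.
#' @return Integer vector of 1-based positions.
#' @export
positions_35s <- function(annotation) {
  s <- span_35s(annotation)
  seq.int(s[1L] + 1L, s[2L])
}

#' 1-based positions covered by a set of named regions
#' @param annotation An `rdna_annotation`.
#' @param region_names Character vector of region names.
#' @return Sorted integer vector of 1-based positions.
#' @export
region_positions <- function(annotation, region_names) {
  r <- annotation[annotation$region %in% region_names, ]
  if (nrow(r) == 0L) stop_input("No such region in the annotation.")
  sort(unlist(Map(function(s, e) seq.int(s + 1L, e), r$start, r$end),
              use.names = FALSE))
}

#' Build a synthetic single-repeat rDNA reference
#'
#' Generates one rDNA repeat unit of `unit_length` nt with the canonical
#' region layout (promoter, the seven 35S regions in order, then 5S).
#' Base composition is uniform except in the 35S spacers, which are seeded
#' with runs of >= `g_run_min` G's at density `g_run_density` so that the
#' G-rich pause-context signal analysed downstream is recoverable.
#'
#' @param unit_length Repeat-unit length in nt (default 9100).
#' @param region_lengths Named vector of region lengths; must contain the
#'   seven 35S region names. Lengths must sum to at most `unit_length`.
#' @param seed Integer seed; identical inputs give identical output.
#' @param g_run_density Expected G-runs per nt of spacer (default 1/60).
#' @param g_run_min,g_run_max Minimum/maximum G-run length (default 4, 8).
#' @return A list with `sequence` (single DNA string) and `annotation`
#'   (an [rdna_annotation()]).
#' @export
build_rdna_reference <- function(unit_length = 9100L,
                                 region_lengths = default_region_lengths(),
                                 seed = 1L,
                                 g_run_density = 1 / 60,
                                 g_run_min = 4L,
                                 g_run_max = 8L) {
  if (any(region_lengths <= 0L)) {
    stop_invalid("All region lengths must be positive.")
  }
  if (sum(region_lengths) > unit_length) {
    stop_invalid("Region lengths must sum to at most `unit_length`.")
  }
  if (!all(REGIONS_35S %in% names(region_lengths))) {
    stop_invalid("`region_lengths` must include all seven 35S regions.")
  }

  # Lay regions out left to right in canonical order, 35S regions contiguous,
  # remaining slack split after the last region.
  order_names <- intersect(
    c("promoter", REGIONS_35S, "5S"),
    names(region_lengths)
  )
  extra <- setdiff(names(region_lengths), order_names)
  order_names <- c(order_names, extra)
  starts <- cumsum(c(0L, unname(region_lengths[order_names])))
  regions <- tibble(
    region = order_names,
    start = starts[-length(starts)],
    end = starts[-1L]
  )
  annotation <- rdna_annotation(regions, unit_length)

  sequence <- with_seed(seed, {
    base <- sample(c("A", "C", "G", "T"), unit_length, replace = TRUE)
    for (sp in SPACER_REGIONS) {
      pos <- region_positions(annotation, sp)
      n_runs <- max(1L, round(g_run_density * length(pos)))
      run_starts <- sort(sample(pos, n_runs))
      run_lens <- sample(seq.int(g_run_min, g_run_max), n_runs, replace = TRUE)
      for (i in seq_len(n_runs)) {
        idx <- seq.int(run_starts[i],
                       min(run_starts[i] + run_lens[i] - 1L, max(pos)))
        base[idx] <- "G"
      }
    }
    paste(base, collapse = "")
  })

  list(sequence = sequence, annotation = annotation)
}

#' Write / read the reference as FASTA
#'
#' @param sequence Single DNA string.
#' @param path Output FASTA path.
#' @param name Sequence name (default `"rdna_unit"`).
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(sequence, path, name = "rdna_unit") {
  x <- Biostrings::DNAStringSet(setNames(sequence, name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @return For `read_reference_fasta()`, a named character vector of length 1.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x[1L]), names(x)[1L])
}

#' Write / read the annotation as 6-column BED
#'
#' BED uses the same 0-based half-open convention as the annotation itself;
#' the name column holds the region name and the score column is 0.
#'
#' @param annotation An `rdna_annotation`.
#' @param path Output BED path.
#' @param chrom Reference name to use in column 1 (default `"rdna_unit"`).
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(annotation, path, chrom = "rdna_unit") {
  bed <- tibble(
    chrom = chrom,
    start = annotation$start,
    end = annotation$end,
    name = annotation$region,
    score = 0L,
    strand = annotation$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @param unit_length_hint Unit length for the reconstructed annotation; if
#'   `NULL`, the maximum interval end is used.
#' @return For `read_annotation_bed()`, an `rdna_annotation`.
#' @export
read_annotation_bed <- function(path, unit_length_hint = NULL) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic", progress = FALSE
  )
  rdna_annotation(
    tibble(region = bed$name, start = bed$start, end = bed$end,
           strand = bed$strand),
    unit_length = unit_length_hint %||% max(bed$end)
  )
}
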