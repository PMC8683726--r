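#' Load and filter NET-seq alignments from SAM/BAM
#'
#' Reads a single-reference SAM or BAM and keeps primary, mapped,
#' sense-strand (+) alignments whose 5' end lies within the 35S span.
#' Counts of discarded records (unmapped, antisense, secondary/supplementary,
#' outside the 35S span) are stored in the `discarded` attribute and
#' reported with a message.
#'
#' @param path Path to a SAM or BAM file with a single reference sequence.
#' @param annotation Matching [rdna_annotation()].
#' @param reference_name Expected reference name (default `"rdna_unit"`).
#' @return A tibble of class `netseq_reads` with columns `qname`, `flag`,
#'   `pos` (1-based 5' end), `strand`, `umi` (NA when the RX tag is absent),
#'   sorted by coordinate.
#' @export
read_netseq_alignments <- function(path, annotation,
                                   reference_name = "rdna_unit") {
  if (!file.exists(path)) stop_input(paste0("Cannot read alignments: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!reference_name %in% names(hdr)) {
    stop_input(sprintf("Reference '%s' not found in %s.", reference_name, path))
  }
  if (hdr[[reference_name]] != unit_length(annotation)) {
    stop_input(sprintf(
      "Reference length %d does not match annotation unit length %d.",
      hdr[[reference_name]], unit_length(annotation)
    ))
  }

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "strand"),
    tag = "RX"
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(rec$qname)
  umi <- rec$tag$RX %||% rep(NA_character_, n)
  if (length(umi) == 0L) umi <- rep(NA_character_, n)

  flag <- rec$flag
  unmapped <- bitwAnd(flag, 4L) != 0L | is.na(rec$pos)
  secondary <- bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L
  antisense <- !unmapped & as.character(rec$strand) == "-"
  span <- span_35s(annotation)
  outside <- !unmapped & !antisense &
    (rec$pos < span[1L] + 1L | rec$pos > span[2L])
  keep <- !unmapped & !secondary & !antisense & !outside

  discarded <- c(
    unmapped = sum(unmapped), secondary = sum(secondary & !unmapped),
    antisense = sum(antisense & !secondary),
    outside_35s = sum(outside & !secondary)
  )
  if (n == 0L) warn("Alignment file contains no records.")
  inform(sprintf(
    "%d of %d alignments kept (discarded: %s).", sum(keep), n,
    paste(names(discarded), discarded, sep = "=", collapse = ", ")
  ))

  out <- tibble(
    qname = rec$qname[keep],
    flag = as.integer(flag[keep]),
    pos = as.integer(rec$pos[keep]),
    strand = as.character(rec$strand[keep]),
    umi = umi[keep]
  )
  out <- arrange(out, .data$pos)
  attr(out, "discarded") <- discarded
  class(out) <- c("netseq_reads", class(out))
  out
}

#' Collapse UMI duplicates
#'
#' Keeps exactly one read per distinct (5'-end position, UMI) pair. The
#' retained read is the first in coordinate order, making the operation
#' deterministic and idempotent.
#'
#' @param reads A `netseq_reads` tibble with a `umi` column.
#' @return The deduplicated reads, same class and column layout.
#' @export
dedup_umis <- function(reads) {
  if (!"umi" %in% names(reads)) stop_input("Reads carry no `umi` column.")
  missing <- which(is.na(reads$umi) | reads$umi == "")
  if (length(missing) > 0L) {
    stop_input(sprintf(
      "Read '%s' has no UMI tag (%d reads missing UMIs).",
      reads$qname[missing[1L]], length(missing)
    ))
  }
  at <- attributes(reads)
  out <- distinct(arrange(reads, .data$pos), .data$pos, .data$umi,
                  .keep_all = TRUE)
  for (a in setdiff(names(at), c("names", "row.names", "class"))) {
    attr(out, a) <- at[[a]]
  }
  class(out) <- class(reads)
  out
}

#' Build a per-position occupancy track
#'
#' Counts read 5' ends (the 3' ends of nascent transcripts) at every
#' position of the 35S span. With `normalize = TRUE` counts are rescaled to
#' counts-per-million over the span, making libraries of different depth
#' comparable.
#'
#' @param reads Deduplicated `netseq_reads`.
#' @param annotation Matching [rdna_annotation()].
#' @param normalize Rescale to counts-per-million (default `TRUE`).
#' @param library_id,condition Metadata stored on the track; taken from the
#'   reads' attributes when `NULL`.
#' @return A tibble of class `occupancy_track` with columns `position`
#'   (1-based unit coordinate) and `count`; attributes `library_id`,
#'   `condition`, `total_reads`, `normalized`.
#' @export
build_occupancy_track <- function(reads, annotation, normalize = TRUE,
                                  library_id = NULL, condition = NULL) {
  pos <- positions_35s(annotation)
  offset <- pos[1L] - 1L
  counts <- tabulate(reads$pos - offset, nbins = length(pos))
  total <- sum(counts)
  counts <- as.numeric(counts)
  if (normalize && total > 0L) counts <- counts / total * 1e6
  out <- tibble(position = pos, count = counts)
  attr(out, "library_id") <- library_id %||% attr(reads, "library_id")
  attr(out, "condition") <- condition %||% attr(reads, "condition")
  attr(out, "total_reads") <- total
  attr(out, "normalized") <- normalize
  class(out) <- c("occupancy_track", class(out))
  out
}

#' Spearman reproducibility of two occupancy tracks
#'
#' Ranks per-position occupancy in the two libraries and correlates the
#' rankings (Spearman rho with average-rank tie handling), over positions
#' where at least one library is nonzero; all-zero positions carry no
#' ranking information. A coefficient of 1 indicates identical ranking.
#'
#' @param track_a,track_b Equal-length `occupancy_track`s.
#' @return A one-row tibble with `rho`, `n_positions`, `library_a`,
#'   `library_b`.
#' @export
spearman_reproducibility <- function(track_a, track_b) {
  if (nrow(track_a) != nrow(track_b) ||
      !all(track_a$position == track_b$position)) {
    stop_input("Tracks must cover identical positions.")
  }
  keep <- track_a$count > 0 | track_b$count > 0
  if (sum(keep) < 3L) {
    stop_insufficient("Fewer than 3 informative positions; cannot rank.")
  }
  rho <- cor(track_a$count[keep], track_b$count[keep], method = "spearman")
  tibble(
    rho = rho,
    n_positions = sum(keep),
    library_a = attr(track_a, "library_id") %||% NA_character_,
    library_b = attr(track_b, "library_id") %||% NA_character_
  )
}
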