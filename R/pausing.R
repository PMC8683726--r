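#' Call pause sites as the most-occupied spacer positions
#'
#' Pause sites for a condition are the top `quantile` fraction (default
#' 2.5%) of eligible positions of that condition's median occupancy track,
#' where eligible positions are spacer-region positions with nonzero
#' occupancy. Ranking is by count descending with ties broken by ascending
#' position; exactly `ceiling(quantile * n_eligible)` sites are returned.
#'
#' @param median_track A median `occupancy_track`.
#' @param annotation Matching [rdna_annotation()].
#' @param quantile Fraction of eligible positions to call (default 0.025).
#' @param condition Condition label (taken from the track when `NULL`).
#' @return A tibble of class `pause_set` with columns `position`, `count`,
#'   sorted by count descending then position ascending; attributes
#'   `condition`, `quantile`, `n_eligible`.
#' @export
call_pause_sites <- function(median_track, annotation, quantile = 0.025,
                             condition = NULL) {
  if (quantile <= 0 || quantile >= 1) {
    stop_invalid("`quantile` must lie strictly between 0 and 1.")
  }
  spacer_pos <- region_positions(annotation, SPACER_REGIONS)
  idx <- match(spacer_pos, median_track$position)
  eligible <- tibble(
    position = spacer_pos,
    count = median_track$count[idx]
  )
  eligible <- filter(eligible, !is.na(.data$count) & .data$count > 0)
  if (nrow(eligible) == 0L) {
    stop_insufficient("No nonzero spacer positions; cannot call pauses.")
  }
  n_sites <- ceiling(quantile * nrow(eligible))
  ord <- order(-eligible$count, eligible$position)
  out <- eligible[ord[seq_len(n_sites)], ]
  if (n_sites < nrow(eligible) &&
      eligible$count[ord[n_sites]] == eligible$count[ord[n_sites + 1L]]) {
    inform("Tied counts at the quantile boundary; truncation is by ascending position (degenerate ties).")
  }
  attr(out, "condition") <- condition %||% attr(median_track, "condition")
  attr(out, "quantile") <- quantile
  attr(out, "n_eligible") <- nrow(eligible)
  class(out) <- c("pause_set", class(out))
  out
}

#' Extract sequence windows around pause sites
#'
#' For each pause site at 1-based position p — interpreted as the last
#' incorporated nucleotide of the nascent transcript — returns the
#' sense-strand DNA window from p - upstream to p + downstream inclusive.
#' Sites whose window would run off the repeat unit are dropped with a
#' warning.
#'
#' @param pause_set A [call_pause_sites()] result.
#' @param reference Single DNA string for the repeat unit.
#' @param annotation Matching [rdna_annotation()] (bounds check).
#' @param upstream,downstream Window half-widths in nt (default 15 each).
#' @return A character vector of class `pause_windows` of equal-length
#'   windows (length upstream + downstream + 1); attributes `upstream`,
#'   `downstream`, `n_dropped`, `condition`.
#' @export
extract_windows <- function(pause_set, reference, annotation,
                            upstream = 15L, downstream = 15L) {
  ulen <- unit_length(annotation)
  if (nchar(reference) != ulen) {
    stop_input("Reference length does not match the annotation unit length.")
  }
  p <- pause_set$position
  ok <- p - upstream >= 1L & p + downstream <= ulen
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    warn(sprintf("%d pause site(s) dropped: window exceeds unit bounds.",
                 n_dropped))
  }
  windows <- substring(reference, p[ok] - upstream, p[ok] + downstream)
  structure(
    windows,
    upstream = as.integer(upstream),
    downstream = as.integer(downstream),
    n_dropped = n_dropped,
    condition = attr(pause_set, "condition"),
    class = "pause_windows"
  )
}

#' Per-column base probability matrix of pause-context windows
#'
#' Tallies base frequencies at each window column. Column offsets run from
#' -upstream to +downstream with 0 the last incorporated nucleotide. A
#' pseudocount (default 0.5 per base) is added before normalization so that
#' small pause sets cannot produce zero probabilities, which would make
#' divergence columns degenerate.
#'
#' @param windows Equal-length character windows (a `pause_windows` or plain
#'   character vector).
#' @param pseudocount Pseudocount per base per column (default 0.5).
#' @param upstream Offset of the anchor column; taken from the `pause_windows`
#'   attribute when available, else the window midpoint.
#' @return A 4 x W numeric matrix of class `ppm` (rows A, C, G, T; columns
#'   named by signed offset), each column summing to 1; attributes
#'   `n_sequences`, `offsets`, `condition`.
#' @export
window_probability_matrix <- function(windows, pseudocount = 0.5,
                                      upstream = NULL) {
  if (length(windows) < 1L) stop_input("Need at least one window.")
  lens <- nchar(windows)
  if (length(unique(lens)) != 1L) {
    stop_input("Windows must all have the same length.")
  }
  w <- lens[1L]
  upstream <- upstream %||% attr(windows, "upstream") %||% ((w - 1L) %/% 2L)
  offsets <- seq_len(w) - upstream - 1L
  chars <- matrix(unlist(strsplit(toupper(unclass(windows)), "",
                                  fixed = TRUE)),
                  nrow = w)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(w), function(j) {
    tab <- table(factor(chars[j, ], levels = bases))
    as.numeric(tab)
  }, numeric(4))
  probs <- (counts + pseudocount) /
    rep(colSums(counts) + 4 * pseudocount, each = 4L)
  dimnames(probs) <- list(bases, as.character(offsets))
  structure(
    probs,
    n_sequences = length(windows),
    offsets = offsets,
    condition = attr(windows, "condition"),
    class = "ppm"
  )
}

# Jensen-Shannon divergence of two probability vectors, in bits.
js_divergence_bits <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Differential logo between two pause-context probability matrices
#'
#' Column-wise comparison of two base probability matrices in the style of
#' difference logos: the stack height of each column is the Jensen-Shannon
#' divergence (base 2, equal weights, bounded by 1 bit) between the two
#' column distributions, and each base contributes a signed share
#' proportional to its probability difference -- positive when the base is
#' enriched in the first condition. The contribution magnitudes of a column
#' sum to its divergence.
#'
#' @param ppm_a,ppm_b `ppm` matrices with identical column offsets;
#'   condition A (e.g. drug) first.
#' @param conditions Length-2 character vector of condition labels.
#' @return A tibble of class `diff_logo` in long form with columns `offset`,
#'   `js_divergence`, `base`, `contribution`; attribute `conditions`.
#' @export
differential_logo <- function(ppm_a, ppm_b,
                              conditions = c(
                                attr(ppm_a, "condition") %||% "A",
                                attr(ppm_b, "condition") %||% "B"
                              )) {
  if (!identical(dim(ppm_a), dim(ppm_b)) ||
      !identical(colnames(ppm_a), colnames(ppm_b))) {
    stop_input("Probability matrices must share the same column offsets.")
  }
  offsets <- as.integer(colnames(ppm_a))
  bases <- rownames(ppm_a)
  rows <- lapply(seq_along(offsets), function(j) {
    p <- ppm_a[, j]; q <- ppm_b[, j]
    js <- js_divergence_bits(p, q)
    d <- p - q
    contrib <- if (sum(abs(d)) > 0) d / sum(abs(d)) * js else rep(0, 4L)
    tibble(
      offset = offsets[j],
      js_divergence = js,
      base = bases,
      contribution = unname(contrib)
    )
  })
  out <- bind_rows(rows)
  attr(out, "conditions") <- conditions
  class(out) <- c("diff_logo", class(out))
  out
}
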