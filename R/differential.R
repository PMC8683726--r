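track_matrix <- function(tracks) {
  norms <- vapply(tracks, function(t) isTRUE(attr(t, "normalized")), logical(1))
  if (length(unique(norms)) > 1L) {
    stop_input("Tracks mix raw and normalized scales.")
  }
  pos <- tracks[[1L]]$position
  for (t in tracks) {
    if (!identical(t$position, pos)) {
      stop_input("Tracks must cover identical positions.")
    }
  }
  vapply(tracks, function(t) t$count, numeric(length(pos)))
}

#' Per-position median occupancy across replicate tracks
#'
#' @param tracks List of equal-length `occupancy_track`s on the same scale.
#' @param condition Condition label for the result (taken from the first
#'   track when `NULL`).
#' @return An `occupancy_track` whose `count` is the per-position median.
#' @export
median_occupancy <- function(tracks, condition = NULL) {
  if (length(tracks) < 1L) stop_input("Need at least one track.")
  m <- track_matrix(tracks)
  out <- tibble(
    position = tracks[[1L]]$position,
    count = apply(m, 1L, median)
  )
  attr(out, "condition") <- condition %||% attr(tracks[[1L]], "condition")
  attr(out, "normalized") <- isTRUE(attr(tracks[[1L]], "normalized"))
  attr(out, "library_id") <- "median"
  class(out) <- c("occupancy_track", class(out))
  out
}

#' Per-position Welch t-tests between vehicle and drug replicate sets
#'
#' At every position of the 35S span, a two-sided Welch (unequal-variance)
#' two-sample t-test compares the replicate occupancy values between the
#' two conditions. Positions with p below `alpha` are classified
#' `increased` or `decreased` (drug relative to vehicle, by median
#' direction); all others are `ns`. Positions with zero variance in both
#' groups get p = 1 (equal means) or p = 0 with `degenerate = TRUE`
#' (unequal means). No multiple-testing correction is applied; the raw
#' per-position threshold is deliberate and recorded in the attributes.
#'
#' @param vehicle_tracks,drug_tracks Lists of >= 2 replicate
#'   `occupancy_track`s per condition, same positions and scale.
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @return A tibble of class `differential_track` with columns `position`,
#'   `median_vehicle`, `median_drug`, `p_value`, `sig_class`
#'   (`increased`/`decreased`/`ns`) and `degenerate`; attributes `alpha` and
#'   `multiple_testing = "none"`.
#' @export
positionwise_ttest <- function(vehicle_tracks, drug_tracks, alpha = 0.05) {
  if (length(vehicle_tracks) < 2L) {
    stop_insufficient("Need >= 2 vehicle replicates for a t-test.")
  }
  if (length(drug_tracks) < 2L) {
    stop_insufficient("Need >= 2 drug replicates for a t-test.")
  }
  m <- track_matrix(c(vehicle_tracks, drug_tracks))
  v <- m[, seq_along(vehicle_tracks), drop = FALSE]
  d <- m[, length(vehicle_tracks) + seq_along(drug_tracks), drop = FALSE]
  nv <- ncol(v); nd <- ncol(d)
  mv <- rowMeans(v); md <- rowMeans(d)
  sv <- rowSums((v - mv)^2) / (nv - 1L)
  sd2 <- rowSums((d - md)^2) / (nd - 1L)

  se2 <- sv / nv + sd2 / nd
  tstat <- (md - mv) / sqrt(se2)
  df <- se2^2 / ((sv / nv)^2 / (nv - 1L) + (sd2 / nd)^2 / (nd - 1L))
  p <- 2 * pt(-abs(tstat), df)

  both_zero_var <- sv == 0 & sd2 == 0
  degenerate <- both_zero_var & mv != md
  p[both_zero_var & mv == md] <- 1
  p[degenerate] <- 0

  med_v <- apply(v, 1L, median)
  med_d <- apply(d, 1L, median)
  sig <- p < alpha
  direction <- sign(med_d - med_v)
  # Median tie with significant mean difference: fall back to mean direction.
  tie <- sig & direction == 0
  direction[tie] <- sign(md[tie] - mv[tie])
  cls <- rep("ns", length(p))
  cls[sig & direction > 0] <- "increased"
  cls[sig & direction < 0] <- "decreased"

  out <- tibble(
    position = vehicle_tracks[[1L]]$position,
    median_vehicle = med_v,
    median_drug = med_d,
    p_value = p,
    sig_class = factor(cls, levels = c("increased", "decreased", "ns")),
    degenerate = degenerate
  )
  attr(out, "alpha") <- alpha
  attr(out, "multiple_testing") <- "none"
  class(out) <- c("differential_track", class(out))
  out
}

#' Two-sample Kolmogorov-Smirnov test on spacer occupancy distributions
#'
#' Compares the distribution of per-position median occupancy values between
#' the two conditions within one spacer region (ETS1/ITS1/ITS2/ETS2): the
#' vehicle values and the drug values over the region's positions form the
#' two samples, and the test statistic D is the maximum ECDF gap.
#'
#' @param vehicle_median,drug_median Median `occupancy_track`s (see
#'   [median_occupancy()]).
#' @param annotation Matching [rdna_annotation()].
#' @param region_name One of the spacer regions.
#' @return A one-row tibble with `region`, `D`, `p_value`, `n_vehicle`,
#'   `n_drug`.
#' @export
spacer_ks_test <- function(vehicle_median, drug_median, annotation,
                           region_name) {
  if (!region_name %in% SPACER_REGIONS) {
    stop_input(sprintf(
      "'%s' is not a spacer region (expected one of %s).",
      region_name, paste(SPACER_REGIONS, collapse = ", ")
    ))
  }
  pos <- region_positions(annotation, region_name)
  if (length(pos) < 10L) {
    stop_insufficient("Region shorter than 10 positions.")
  }
  vv <- vehicle_median$count[match(pos, vehicle_median$position)]
  dd <- drug_median$count[match(pos, drug_median$position)]
  kt <- suppressWarnings(ks.test(vv, dd))
  tibble(
    region = region_name,
    D = unname(kt$statistic),
    p_value = kt$p.value,
    n_vehicle = length(vv),
    n_drug = length(dd)
  )
}
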