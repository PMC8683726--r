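#' Simulate a dose-response titration series
#'
#' Full-length RNA product signal as a function of inhibitor concentration
#' under the single-exponential inhibition model
#' `signal(c) = amplitude * exp(-c * ln(2) / ic50)`, with optional additive
#' Gaussian noise. With `noise_sd = 0` the exact model values are returned,
#' and the signal at `c = ic50` is exactly half the amplitude.
#'
#' @param ic50 Half-maximal concentration in uM (> 0).
#' @param amplitude Signal at zero dose.
#' @param concentrations Concentrations in uM (default vehicle plus the
#'   two-fold series 0.125-4 uM).
#' @param noise_sd SD of additive Gaussian noise, signal units.
#' @param seed Integer seed for the noise (required when `noise_sd > 0`).
#' @return A tibble with columns `concentration_uM` and `signal`.
#' @export
simulate_titration <- function(ic50, amplitude = 1,
                               concentrations = c(0, 0.125, 0.25, 0.5, 1, 2, 4),
                               noise_sd = 0, seed = 1L) {
  if (ic50 <= 0) stop_invalid("`ic50` must be positive.")
  if (any(concentrations < 0)) stop_invalid("Concentrations must be >= 0.")
  signal <- amplitude * exp(-concentrations * log(2) / ic50)
  if (noise_sd > 0) {
    signal <- signal + with_seed(seed, stats::rnorm(length(signal), 0, noise_sd))
  }
  tibble(concentration_uM = concentrations, signal = signal)
}

#' Fit a single-exponential dose-response curve and extract the IC50
#'
#' Nonlinear least squares on `signal(c) = A * exp(-c * ln(2) / IC50)`;
#' under this parameterization the IC50 is exactly the concentration at
#' half-amplitude. Initial values are `A0 = max(signal)` and
#' `IC50_0 = median(nonzero concentrations)`. Fits whose IC50 is driven to
#' the upper bound of 1e3 uM (non-decaying data) are reported with
#' `converged = FALSE`.
#'
#' @param series A tibble with columns `concentration_uM` (or
#'   `concentration`) and `signal`.
#' @return An object of class `dose_response_fit`: list with `ic50`,
#'   `amplitude`, `residual_sse`, `converged`, `n_points`.
#' @export
fit_dose_response_ic50 <- function(series) {
  conc_col <- intersect(c("concentration_uM", "concentration"), names(series))
  if (length(conc_col) == 0L) stop_input("`series` needs a concentration column.")
  conc <- series[[conc_col[1L]]]
  sig <- series$signal
  if (length(conc) < 3L) stop_insufficient("Need >= 3 concentration points.")
  if (length(unique(conc[conc > 0])) < 1L) {
    stop_insufficient("Need at least one nonzero concentration.")
  }
  df <- data.frame(conc = conc, signal = sig)
  upper_ic50 <- 1e3
  fit <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ A * exp(-conc * log(2) / ic50),
      data = df,
      start = list(A = max(sig), ic50 = median(conc[conc > 0])),
      lower = c(A = 0, ic50 = 1e-6),
      upper = c(A = Inf, ic50 = upper_ic50),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(ic50 = NA_real_, amplitude = NA_real_,
                residual_sse = NA_real_, converged = FALSE,
                n_points = length(conc))
    return(structure(out, class = "dose_response_fit"))
  }
  est <- coef(fit)
  converged <- isTRUE(fit$convInfo$isConv) && est[["ic50"]] < 0.999 * upper_ic50
  structure(
    list(
      ic50 = unname(est[["ic50"]]),
      amplitude = unname(est[["A"]]),
      residual_sse = sum(stats::residuals(fit)^2),
      converged = converged,
      n_points = length(conc)
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> IC50 = %.4g uM, amplitude = %.4g, SSE = %.3g, %s\n",
    x$ic50, x$amplitude, x$residual_sse,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Simulate promoter-escape time courses for vehicle and drug
#'
#' Full-length product accumulation in a single-round assay:
#' `vehicle(t) = amplitude * (1 - exp(-rate * t))`. The drug curve is the
#' vehicle curve times an escape-competent fraction that relaxes
#' exponentially from `ratio_start` toward `ratio_end` with rate
#' `ratio_decay`, modelling progressive engagement of the intercalating
#' drug over the time course; with the defaults the drug/vehicle ratio at
#' 4 min is 0.51, i.e. a 49% reduction.
#'
#' @param times_min Time points in minutes (default 0.5, 1, 1.5, 2, 4).
#' @param amplitude Plateau signal of the vehicle curve.
#' @param rate_per_min First-order accumulation rate, per minute.
#' @param ratio_start,ratio_end Initial and asymptotic drug/vehicle ratio.
#' @param ratio_decay Relaxation rate of the ratio, per minute.
#' @param noise_sd SD of additive Gaussian noise on both curves.
#' @param seed Integer seed for the noise.
#' @return A tibble with columns `time_min`, `vehicle`, `drug`.
#' @export
simulate_escape_timecourse <- function(times_min = c(0.5, 1, 1.5, 2, 4),
                                       amplitude = 100,
                                       rate_per_min = 0.8,
                                       ratio_start = 0.95,
                                       ratio_end = 0.5,
                                       ratio_decay = log(45) / 4,
                                       noise_sd = 0, seed = 1L) {
  if (any(times_min <= 0)) stop_invalid("Time points must be positive.")
  vehicle <- amplitude * (1 - exp(-rate_per_min * times_min))
  ratio <- ratio_end + (ratio_start - ratio_end) * exp(-ratio_decay * times_min)
  drug <- vehicle * ratio
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(2L * length(times_min), 0, noise_sd))
    vehicle <- vehicle + noise[seq_along(times_min)]
    drug <- drug + noise[-seq_along(times_min)]
  }
  tibble(time_min = times_min, vehicle = vehicle, drug = drug)
}

#' Percent reduction of drug relative to vehicle over a time course
#'
#' `reduction(t) = 100 * (1 - drug(t) / vehicle(t))`. Time points where the
#' vehicle signal is zero are flagged undefined (NA) with a warning. The
#' maximum reduction and its time point are stored as attributes.
#'
#' @param vehicle_timecourse,drug_timecourse Tibbles with columns `time_min`
#'   and `signal`; alternatively pass a single tibble with columns
#'   `time_min`, `vehicle`, `drug` (see [simulate_escape_timecourse()]) as
#'   the first argument.
#' @return A tibble with columns `time_min`, `vehicle`, `drug`,
#'   `reduction_pct`; attributes `max_reduction_pct`, `max_time_min`.
#' @export
promoter_escape_reduction <- function(vehicle_timecourse,
                                      drug_timecourse = NULL) {
  if (is.null(drug_timecourse)) {
    tc <- vehicle_timecourse
    if (!all(c("time_min", "vehicle", "drug") %in% names(tc))) {
      stop_input("Single-table input needs columns time_min, vehicle, drug.")
    }
  } else {
    if (!isTRUE(all.equal(vehicle_timecourse$time_min,
                          drug_timecourse$time_min))) {
      stop_input("Vehicle and drug time grids must match.")
    }
    tc <- tibble(
      time_min = vehicle_timecourse$time_min,
      vehicle = vehicle_timecourse$signal,
      drug = drug_timecourse$signal
    )
  }
  undefined <- tc$vehicle == 0
  if (any(undefined)) {
    warn(sprintf("Reduction undefined at %d time point(s) with zero vehicle signal.",
                 sum(undefined)))
  }
  red <- 100 * (1 - tc$drug / tc$vehicle)
  red[undefined] <- NA_real_
  out <- mutate(tc, reduction_pct = red)
  imax <- which.max(replace(red, is.na(red), -Inf))
  attr(out, "max_reduction_pct") <- red[imax]
  attr(out, "max_time_min") <- tc$time_min[imax]
  out
}

# Migration (arbitrary units, larger = further migrated = shorter RNA) of an
# RNA of a given length under the synthetic log-linear gel model.
migration_of_length <- function(length_nt, map_intercept = 2.2,
                                map_slope = -0.55) {
  map_intercept + map_slope * log10(length_nt)
}

gaussian_band <- function(grid, center, sd, amplitude) {
  amplitude * exp(-((grid - center)^2) / (2 * sd^2))
}

#' Simulate an elongation time course as synthetic gel lane profiles
#'
#' The leading-edge RNA length at time t is
#' `min(start_length + rate * t, template_length)`; each lane renders it as
#' a Gaussian band on a log-linear migration axis (longer RNA migrates
#' less). Pause sites add lower-amplitude sub-bands at fixed lengths shared
#' across lanes (only once the leading edge has passed them). A ladder lane
#' is rendered from `ladder_lengths`.
#'
#' @param rate Elongation rate in nt/s (> 0).
#' @param start_length Synchronized halt length in nt (default 55).
#' @param times_s Sorted time points in seconds (default 4, 6, 8, 10).
#' @param pause_sites Pause-band lengths in nt (default none).
#' @param template_length Full template length in nt (default 800).
#' @param ladder_lengths Ladder rung lengths in nt.
#' @param band_sd Band SD on the migration axis.
#' @param pause_amplitude Pause band amplitude relative to the leading band.
#' @param noise_sd SD of additive Gaussian intensity noise.
#' @param seed Integer seed for the noise.
#' @return A list with `lanes` (long tibble: `lane_id`, `time_s`,
#'   `migration`, `intensity`) and `ladder` (tibble: `migration`,
#'   `intensity`).
#' @export
simulate_elongation_timecourse <- function(rate, start_length = 55,
                                           times_s = c(4, 6, 8, 10),
                                           pause_sites = numeric(),
                                           template_length = 800,
                                           ladder_lengths = c(100, 200, 400, 800),
                                           band_sd = 0.004,
                                           pause_amplitude = 0.45,
                                           noise_sd = 0, seed = 1L) {
  if (rate <= 0) stop_invalid("`rate` must be positive.")
  if (is.unsorted(times_s, strictly = TRUE)) {
    stop_invalid("`times_s` must be sorted ascending.")
  }
  grid <- seq(0.4, 1.5, by = 5e-4)
  render_lane <- function(leading_nt) {
    intensity <- gaussian_band(grid, migration_of_length(leading_nt),
                               band_sd, 1)
    for (p in pause_sites) {
      if (p < leading_nt) {
        intensity <- intensity +
          gaussian_band(grid, migration_of_length(p), band_sd, pause_amplitude)
      }
    }
    intensity
  }
  lanes <- bind_rows(lapply(seq_along(times_s), function(i) {
    leading <- min(start_length + rate * times_s[i], template_length)
    tibble(
      lane_id = sprintf("t%gs", times_s[i]),
      time_s = times_s[i],
      migration = grid,
      intensity = render_lane(leading)
    )
  }))
  ladder_int <- Reduce(`+`, lapply(ladder_lengths, function(L) {
    gaussian_band(grid, migration_of_length(L), band_sd, 1)
  }))
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(nrow(lanes) + length(grid), 0, noise_sd))
    lanes$intensity <- pmax(0, lanes$intensity + noise[seq_len(nrow(lanes))])
    ladder_int <- pmax(0, ladder_int + noise[-seq_len(nrow(lanes))])
  }
  list(
    lanes = lanes,
    ladder = tibble(migration = grid, intensity = ladder_int)
  )
}

# Indices of local maxima of `y` at or above `threshold * max(y)`.
local_maxima <- function(y, threshold) {
  n <- length(y)
  if (n < 3L) return(integer())
  cand <- which(y[2:(n - 1L)] >= y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n]) + 1L
  cand[y[cand] >= threshold * max(y)]
}

#' Calibrate a ladder lane
#'
#' Detects ladder band peaks (local maxima at or above 10% of the lane
#' maximum), pairs rung lengths (descending) with peak migrations
#' (ascending) — longer RNA migrates less — and least-squares fits
#' `log10(length) ~ migration`.
#'
#' @param ladder_profile Tibble with `migration` (ascending) and `intensity`.
#' @param rung_lengths Rung lengths in nt (>= 2).
#' @return An object of class `ladder_calibration`: list with `slope`,
#'   `intercept`, `r_squared`, `n_rungs`.
#' @export
calibrate_ladder <- function(ladder_profile, rung_lengths) {
  if (length(rung_lengths) < 2L) {
    stop_input("Need at least 2 ladder rungs to calibrate.")
  }
  peaks <- local_maxima(ladder_profile$intensity, 0.1)
  if (length(peaks) < length(rung_lengths)) {
    abort(sprintf(
      "Calibration failed: %d peaks detected for %d rungs.",
      length(peaks), length(rung_lengths)
    ), class = "poliseq_calibration_error")
  }
  # Keep the strongest peaks if spurious extras are present.
  peaks <- peaks[order(ladder_profile$intensity[peaks],
                       decreasing = TRUE)][seq_along(rung_lengths)]
  mig <- sort(ladder_profile$migration[peaks])
  len <- sort(rung_lengths, decreasing = TRUE)
  fit <- lm(log10(len) ~ mig)
  rsq <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      r_squared = rsq,
      n_rungs = length(rung_lengths)
    ),
    class = "ladder_calibration"
  )
}

#' Convert migration to RNA length via a ladder calibration
#' @param calibration A [calibrate_ladder()] result.
#' @param migration Migration values.
#' @return Lengths in nt.
#' @export
length_from_migration <- function(calibration, migration) {
  10^(calibration$intercept + calibration$slope * migration)
}

#' Leading-edge RNA length of one lane
#'
#' Identifies the leading (least-migrated, longest-RNA) contiguous region
#' with intensity at or above `threshold` (default 20%) of the lane maximum,
#' computes its intensity-weighted centroid migration and converts it to nt
#' via the calibration.
#'
#' @param lane Tibble with `migration` (ascending) and `intensity`.
#' @param calibration A [calibrate_ladder()] result.
#' @param threshold Fraction of the lane maximum (default 0.2).
#' @return Leading-edge length in nt.
#' @export
leading_edge_length <- function(lane, calibration, threshold = 0.2) {
  if (all(lane$intensity <= 0)) {
    abort("Lane has no signal.", class = "poliseq_no_signal")
  }
  mask <- lane$intensity >= threshold * max(lane$intensity)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  first_true <- which(r$values)[1L]
  idx <- seq.int(starts[first_true], ends[first_true])
  centroid <- weighted.mean(lane$migration[idx], lane$intensity[idx])
  length_from_migration(calibration, centroid)
}

#' Fit a transcription elongation rate
#'
#' Ordinary least-squares line through (time, leading-edge RNA length)
#' points; the elongation rate is the slope in nt/s and the intercept the
#' synchronized start length.
#'
#' @param points Tibble with columns `time_s` and `length_nt`.
#' @return An object of class `elongation_fit`: list with `rate`,
#'   `intercept`, `r_squared`, `n_points`.
#' @export
fit_elongation_rate <- function(points) {
  if (nrow(points) < 2L || length(unique(points$time_s)) < 2L) {
    stop_insufficient("Need >= 2 points with distinct times.")
  }
  fit <- lm(length_nt ~ time_s, data = points)
  rsq <- suppressWarnings(summary(fit)$r.squared)
  if (is.nan(rsq)) rsq <- 1
  structure(
    list(
      rate = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      r_squared = rsq,
      n_points = nrow(points)
    ),
    class = "elongation_fit"
  )
}

#' @export
print.elongation_fit <- function(x, ...) {
  cat(sprintf(
    "<elongation_fit> rate = %.3g nt/s, intercept = %.3g nt, R^2 = %.4f (n = %d)\n",
    x$rate, x$intercept, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' Detect pause bands conserved across lanes
#'
#' Per lane, finds local intensity maxima at or above `threshold` of the
#' lane maximum that migrate further than the leading-edge region (i.e.
#' shorter RNAs), converts them to lengths, and reports bands whose lengths
#' agree within `tol_nt` across at least `min_fraction` of the lanes as
#' conserved pause bands (mean length per band).
#'
#' @param lanes Either the `lanes` tibble from
#'   [simulate_elongation_timecourse()] (grouped by `lane_id`) or a list of
#'   lane tibbles.
#' @param calibration A [calibrate_ladder()] result.
#' @param threshold Fraction of the lane maximum (default 0.2).
#' @param tol_nt Length tolerance for matching bands across lanes (default 5).
#' @param min_fraction Minimum fraction of lanes a band must appear in
#'   (default 0.5).
#' @return A tibble with columns `band_length_nt` and `n_lanes`, sorted by
#'   length descending; zero rows when no conserved sub-bands exist.
#' @export
detect_pause_bands <- function(lanes, calibration, threshold = 0.2,
                               tol_nt = 5, min_fraction = 0.5) {
  if (is.data.frame(lanes)) {
    lanes <- split(lanes[, c("migration", "intensity")], lanes$lane_id)
  }
  if (length(lanes) < 2L) stop_input("Need >= 2 lanes.")
  candidates <- bind_rows(lapply(seq_along(lanes), function(i) {
    lane <- lanes[[i]]
    mask <- lane$intensity >= threshold * max(lane$intensity)
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    first_true <- which(r$values)[1L]
    lead_end <- ends[first_true]
    pk <- local_maxima(lane$intensity, threshold)
    pk <- pk[pk > lead_end]
    if (length(pk) == 0L) return(NULL)
    band_nt <- length_from_migration(calibration, lane$migration[pk])
    tibble(lane = i, length_nt = band_nt)
  }))
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(tibble(band_length_nt = numeric(), n_lanes = integer()))
  }
  # Greedy single-linkage clustering of candidate lengths.
  candidates <- arrange(candidates, dplyr::desc(.data$length_nt))
  cl <- cumsum(c(TRUE, diff(candidates$length_nt) < -tol_nt))
  out <- candidates |>
    mutate(cluster = cl) |>
    group_by(.data$cluster) |>
    summarise(
      band_length_nt = mean(.data$length_nt),
      n_lanes = dplyr::n_distinct(.data$lane),
      .groups = "drop"
    ) |>
    filter(.data$n_lanes >= ceiling(min_fraction * length(lanes))) |>
    select("band_length_nt", "n_lanes") |>
    arrange(dplyr::desc(.data$band_length_nt))
  out
}
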