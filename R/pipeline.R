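#' Write / read a simulation configuration as YAML
#'
#' Flat-key YAML round trip for [sim_config()], so a simulated study can be
#' driven from a config file.
#'
#' @param config A [sim_config()].
#' @param path YAML path.
#' @return `path` invisibly; `read_sim_config()` returns a validated
#'   [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_input(paste0("No such config file: ", path))
  do.call(sim_config, yaml::read_yaml(path))
}

write_bedgraph <- function(track, path, chrom = "rdna_unit") {
  bg <- tibble(
    chrom = chrom,
    start = track$position - 1L,
    end = track$position,
    value = track$count
  )
  readr::write_tsv(bg, path, col_names = FALSE)
  invisible(path)
}

run_metadata <- function(seed, config, decisions) {
  list(
    package = "poliseq",
    version = as.character(packageVersion("poliseq")),
    seed = seed,
    config_hash = rlang::hash(config),
    config = config,
    decisions = decisions,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}

#' Simulate a complete synthetic study
#'
#' Generates every input the analysis pipeline consumes and writes them
#' under `out_dir`: the single-repeat rDNA reference (FASTA), its
#' annotation (BED6), coordinate-sorted UMI-tagged NET-seq alignments (SAM,
#' `n_replicates` per condition), a dose-response titration, a
#' promoter-escape time course, and elongation-time-course lane profiles
#' with a ladder lane (CSV). All outputs are pure functions of the config
#' and seed; a `manifest.json` records the seed and a config hash.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param titration_ic50,titration_amplitude Parameters of the simulated
#'   titration (defaults: the initiation-phase inhibition, 0.81 uM).
#' @param elongation_rate Vehicle elongation rate in nt/s (default 40).
#' @param pause_sites Pause-band lengths (nt) for the drug-like elongation
#'   lanes.
#' @return Invisibly, a named list of all written paths (the manifest).
#' @export
simulate_study <- function(out_dir, config = sim_config(),
                           titration_ic50 = 0.81,
                           titration_amplitude = 1,
                           elongation_rate = 40,
                           pause_sites = c(150, 320)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  ref <- build_rdna_reference(seed = config$seed)
  write_reference_fasta(ref$sequence, p("reference.fasta"))
  write_annotation_bed(ref$annotation, p("annotation.bed"))

  manifest <- list(
    reference = p("reference.fasta"),
    annotation = p("annotation.bed")
  )
  for (cond in c("vehicle", "drug")) {
    lambda <- simulate_condition_occupancy(ref$sequence, ref$annotation,
                                           config, cond)
    for (r in seq_len(config$n_replicates)) {
      id <- sprintf("%s_rep%d", cond, r)
      reads <- simulate_netseq_library(
        lambda, ref$annotation, config,
        replicate_seed = config$seed + 1000L * match(cond, c("vehicle", "drug")) + r,
        library_id = id
      )
      path <- p(paste0(id, ".sam"))
      write_sam(reads, path, ref$sequence, read_length = config$read_length)
      manifest[[id]] <- path
    }
  }

  titr <- simulate_titration(titration_ic50, titration_amplitude)
  readr::write_csv(titr, p("titration.csv"))
  escape <- simulate_escape_timecourse()
  readr::write_csv(escape, p("escape_timecourse.csv"))
  gel <- simulate_elongation_timecourse(elongation_rate,
                                        pause_sites = pause_sites)
  readr::write_csv(gel$lanes, p("elongation_lanes.csv"))
  readr::write_csv(gel$ladder, p("elongation_ladder.csv"))
  manifest <- c(manifest, list(
    titration = p("titration.csv"),
    escape_timecourse = p("escape_timecourse.csv"),
    elongation_lanes = p("elongation_lanes.csv"),
    elongation_ladder = p("elongation_ladder.csv")
  ))

  meta <- run_metadata(config$seed, unclass(config), decisions = list(
    single_repeat_reference = "reads simulated/analysed against one rDNA repeat unit",
    coordinates = "0-based half-open internally, 1-based in reports"
  ))
  meta$manifest <- manifest
  jsonlite::write_json(meta, p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the NET-seq occupancy analysis pipeline
#'
#' Chains alignment loading, UMI deduplication, occupancy tracks,
#' reproducibility, per-position differential tests, per-spacer K-S tests,
#' pause calling and the differential pause-context logo, and writes the
#' report bundle under `out_dir`: per-library bedGraph tracks, a
#' reproducibility matrix, the differential track, the K-S table, pause-site
#' BEDs, per-condition probability matrices, the differential-logo table,
#' and JSON metadata. Reported positions are 1-based; interval files (BED,
#' bedGraph) use 0-based half-open starts.
#'
#' @param sam_files Named list with character vectors `vehicle` and `drug`
#'   of SAM/BAM paths (>= 2 replicates each).
#' @param reference_fasta Path to the single-repeat reference FASTA.
#' @param annotation_bed Path to the annotation BED.
#' @param out_dir Output directory.
#' @param alpha Per-position significance threshold (default 0.05).
#' @param quantile Pause-calling quantile (default 0.025).
#' @param window Pause-context window half-width in nt (default 15).
#' @param normalize Use counts-per-million tracks (default `TRUE`).
#' @return Invisibly, a list of results (`tracks`, `reproducibility`,
#'   `differential`, `ks`, `pauses`, `diff_logo`, `paths`).
#' @export
run_netseq_pipeline <- function(sam_files, reference_fasta, annotation_bed,
                                out_dir, alpha = 0.05, quantile = 0.025,
                                window = 15L, normalize = TRUE) {
  for (cond in c("vehicle", "drug")) {
    if (length(sam_files[[cond]] %||% character()) < 2L) {
      stop_insufficient(sprintf(
        "Condition '%s' has fewer than 2 replicates.", cond
      ))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  reference <- read_reference_fasta(reference_fasta)
  annotation <- read_annotation_bed(annotation_bed,
                                    unit_length_hint = nchar(reference))
  paths <- list()

  tracks <- list(vehicle = list(), drug = list())
  for (cond in c("vehicle", "drug")) {
    for (i in seq_along(sam_files[[cond]])) {
      id <- sprintf("%s_rep%d", cond, i)
      reads <- read_netseq_alignments(sam_files[[cond]][i], annotation)
      reads <- dedup_umis(reads)
      tr <- build_occupancy_track(reads, annotation, normalize = normalize,
                                  library_id = id, condition = cond)
      tracks[[cond]][[i]] <- tr
      paths[[paste0(id, "_bedgraph")]] <- write_bedgraph(
        tr, p(paste0(id, ".bedGraph"))
      )
    }
  }

  pair_rho <- bind_rows(lapply(c("vehicle", "drug"), function(cond) {
    ts <- tracks[[cond]]
    combs <- utils::combn(length(ts), 2L)
    bind_rows(lapply(seq_len(ncol(combs)), function(k) {
      mutate(
        spearman_reproducibility(ts[[combs[1L, k]]], ts[[combs[2L, k]]]),
        condition = cond, .before = 1L
      )
    }))
  }))
  readr::write_csv(pair_rho, p("reproducibility.csv"))
  paths$reproducibility <- p("reproducibility.csv")

  diff <- positionwise_ttest(tracks$vehicle, tracks$drug, alpha = alpha)
  readr::write_csv(as_tibble(diff), p("differential_track.csv"))
  paths$differential <- p("differential_track.csv")

  med_v <- median_occupancy(tracks$vehicle, condition = "vehicle")
  med_d <- median_occupancy(tracks$drug, condition = "drug")
  ks <- bind_rows(lapply(SPACER_REGIONS, function(rg) {
    spacer_ks_test(med_v, med_d, annotation, rg)
  }))
  readr::write_csv(ks, p("spacer_ks.csv"))
  paths$spacer_ks <- p("spacer_ks.csv")

  pauses <- list()
  ppms <- list()
  for (cond in c("vehicle", "drug")) {
    med <- if (cond == "vehicle") med_v else med_d
    ps <- call_pause_sites(med, annotation, quantile = quantile,
                           condition = cond)
    pauses[[cond]] <- ps
    bed <- tibble(
      chrom = "rdna_unit", start = ps$position - 1L, end = ps$position,
      name = sprintf("%s_pause_%d", cond, seq_len(nrow(ps))),
      score = ps$count, strand = "+"
    )
    readr::write_tsv(bed, p(sprintf("pause_sites_%s.bed", cond)),
                     col_names = FALSE)
    paths[[sprintf("pause_sites_%s", cond)]] <- p(sprintf("pause_sites_%s.bed", cond))
    wins <- extract_windows(ps, reference, annotation,
                            upstream = window, downstream = window)
    ppms[[cond]] <- window_probability_matrix(wins)
    ppm_tbl <- as_tibble(t(unclass(ppms[[cond]])), rownames = "offset")
    readr::write_csv(ppm_tbl, p(sprintf("ppm_%s.csv", cond)))
    paths[[sprintf("ppm_%s", cond)]] <- p(sprintf("ppm_%s.csv", cond))
  }
  dlogo <- differential_logo(ppms$drug, ppms$vehicle,
                             conditions = c("drug", "vehicle"))
  readr::write_csv(as_tibble(dlogo), p("diff_logo.csv"))
  paths$diff_logo <- p("diff_logo.csv")

  meta <- run_metadata(
    seed = NA,
    config = list(alpha = alpha, quantile = quantile, window = window,
                  normalize = normalize, sam_files = sam_files),
    decisions = list(
      t_test = "Welch unequal-variance, two-sided",
      multiple_testing = "none (raw per-position p < alpha)",
      spearman_domain = "positions nonzero in at least one library",
      normalization = if (normalize) "counts-per-million over 35S span" else "raw counts"
    )
  )
  jsonlite::write_json(meta, p("netseq_metadata.json"), auto_unbox = TRUE,
                       digits = NA)
  paths$metadata <- p("netseq_metadata.json")

  invisible(list(
    tracks = tracks, reproducibility = pair_rho, differential = diff,
    ks = ks, pauses = pauses, ppms = ppms, diff_logo = dlogo, paths = paths
  ))
}

#' Run the in vitro kinetics analysis pipeline
#'
#' Fits the dose-response titration (IC50), computes the promoter-escape
#' percent-reduction table, calibrates the ladder lane, measures
#' leading-edge lengths per lane, fits the elongation rate, and detects
#' conserved pause bands; writes one CSV per result plus JSON metadata.
#'
#' @param titration_csv CSV with `concentration_uM`, `signal`.
#' @param escape_csv CSV with `time_min`, `vehicle`, `drug`.
#' @param lanes_csv CSV of lane profiles (`lane_id`, `time_s`, `migration`,
#'   `intensity`).
#' @param ladder_csv CSV of the ladder lane (`migration`, `intensity`).
#' @param rung_lengths Ladder rung lengths in nt.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `dose_response`, `escape`, `calibration`,
#'   `elongation`, `pause_bands`, `paths`.
#' @export
run_invitro_pipeline <- function(titration_csv, escape_csv, lanes_csv,
                                 ladder_csv,
                                 rung_lengths = c(100, 200, 400, 800),
                                 out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  read_nonempty <- function(path) {
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(x) == 0L) stop_input(paste0("Empty input table: ", path))
    x
  }

  titr <- read_nonempty(titration_csv)
  dr <- fit_dose_response_ic50(titr)
  readr::write_csv(glance(dr), p("dose_response_fit.csv"))

  escape <- read_nonempty(escape_csv)
  red <- promoter_escape_reduction(escape)
  readr::write_csv(red, p("escape_reduction.csv"))

  lanes <- read_nonempty(lanes_csv)
  ladder <- read_nonempty(ladder_csv)
  cal <- calibrate_ladder(ladder, rung_lengths)

  lane_split <- split(lanes, lanes$lane_id)
  points <- bind_rows(lapply(lane_split, function(lane) {
    tibble(
      time_s = lane$time_s[1L],
      length_nt = leading_edge_length(lane, cal)
    )
  }))
  points <- arrange(points, .data$time_s)
  readr::write_csv(points, p("leading_edge_lengths.csv"))
  el <- fit_elongation_rate(points)
  readr::write_csv(glance(el), p("elongation_fit.csv"))

  bands <- detect_pause_bands(lanes, cal)
  readr::write_csv(bands, p("pause_bands.csv"))

  meta <- run_metadata(
    seed = NA,
    config = list(titration = titration_csv, escape = escape_csv,
                  lanes = lanes_csv, ladder = ladder_csv,
                  rung_lengths = rung_lengths),
    decisions = list(
      ic50_model = "signal = A * exp(-c*ln2/IC50); IC50 = half-amplitude concentration",
      leading_edge = "intensity-weighted centroid of least-migrated region >= 20% lane max",
      ladder = "log10(length) linear in migration"
    )
  )
  jsonlite::write_json(meta, p("invitro_metadata.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(
    dose_response = dr, escape = red, calibration = cal,
    leading_edges = points, elongation = el, pause_bands = bands,
    paths = list(
      dose_response = p("dose_response_fit.csv"),
      escape = p("escape_reduction.csv"),
      leading_edges = p("leading_edge_lengths.csv"),
      elongation = p("elongation_fit.csv"),
      pause_bands = p("pause_bands.csv"),
      metadata = p("invitro_metadata.json")
    )
  ))
}
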