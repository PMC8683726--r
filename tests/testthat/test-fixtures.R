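test_that("default reference is a 9.1 kb unit with 35S and 5S annotated", {
  ref <- build_rdna_reference(seed = 7)
  expect_equal(nchar(ref$sequence), 9100L)
  expect_equal(unit_length(ref$annotation), 9100L)
  expect_true(all(c("ETS1", "18S", "ITS1", "5.8S", "ITS2", "25S", "ETS2",
                    "5S") %in% ref$annotation$region))
  ann <- ref$annotation
  expect_true(all(ann$start >= 0 & ann$end <= 9100 & ann$start < ann$end))
  # 35S regions appear contiguously in canonical order
  r35 <- ann[ann$region %in% c("ETS1", "18S", "ITS1", "5.8S", "ITS2",
                               "25S", "ETS2"), ]
  expect_equal(r35$region,
               c("ETS1", "18S", "ITS1", "5.8S", "ITS2", "25S", "ETS2"))
  # spacers carry seeded G-runs
  for (sp in c("ETS1", "ITS1", "ITS2", "ETS2")) {
    reg <- ann[ann$region == sp, ]
    expect_true(grepl("GGGG",
                      substr(ref$sequence, reg$start + 1L, reg$end)),
                info = sp)
  }
})

test_that("reference generation is deterministic and validates config", {
  a <- build_rdna_reference(seed = 7)
  b <- build_rdna_reference(seed = 7)
  expect_identical(a$sequence, b$sequence)
  expect_identical(as.data.frame(a$annotation), as.data.frame(b$annotation))
  expect_false(identical(a$sequence, build_rdna_reference(seed = 8)$sequence))

  rl <- default_region_lengths()
  expect_error(
    build_rdna_reference(unit_length = sum(rl) - 1L, region_lengths = rl),
    class = "poliseq_invalid_config"
  )
  expect_error(
    build_rdna_reference(region_lengths = c(ETS1 = -5L)),
    class = "poliseq_invalid_config"
  )
})

test_that("annotation invariants reject overlap and misordered 35S regions", {
  regs <- tibble::tibble(
    region = c("ETS1", "18S", "ITS1", "5.8S", "ITS2", "25S", "ETS2"),
    start = c(0L, 10L, 20L, 30L, 40L, 50L, 60L),
    end = c(10L, 20L, 30L, 40L, 50L, 60L, 70L)
  )
  expect_s3_class(rdna_annotation(regs, 100L), "rdna_annotation")
  overlapping <- regs
  overlapping$start[2L] <- 5L
  expect_error(rdna_annotation(overlapping, 100L),
               class = "poliseq_invalid_config")
  swapped <- regs
  swapped$region[c(2L, 3L)] <- c("ITS1", "18S")
  expect_error(rdna_annotation(swapped, 100L),
               class = "poliseq_invalid_config")
  expect_error(rdna_annotation(regs[-2L, ], 100L),
               class = "poliseq_invalid_config")
})

test_that("C-less cassette has its first C just past the halt point", {
  tpl <- build_cless_template()
  expect_equal(tpl$transcript_length, 800L)
  expect_equal(tpl$halt_position, 55L)
  expect_equal(tpl$first_C_position, 56L)
  head_seq <- substr(tpl$transcript_sequence, 1L, 55L)
  expect_false(grepl("C", head_seq))
  expect_equal(substr(tpl$transcript_sequence, 56L, 56L), "C")
  # template strand is the reverse complement of the transcript
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", tpl$transcript_sequence))
  ))
  expect_identical(tpl$template_dna, rc)
  expect_identical(build_cless_template(seed = 3)$transcript_sequence,
                   build_cless_template(seed = 3)$transcript_sequence)
  expect_error(build_cless_template(halt_position = 0L),
               class = "poliseq_invalid_config")
  expect_error(build_cless_template(transcript_length = 55L,
                                    halt_position = 55L),
               class = "poliseq_invalid_config")
})

test_that("drug intensity scaling reduces mean spacer intensity by initiation_scale", {
  ann <- toy_annotation()
  ref <- toy_reference()
  cfg <- sim_config(seed = 3, initiation_scale = 0.4,
                    base_pause_weight = 1, drug_pause_weight = 1)
  lam_v <- simulate_condition_occupancy(ref, ann, cfg, "vehicle")
  lam_d <- simulate_condition_occupancy(ref, ann, cfg, "drug")
  sp <- region_positions(ann, c("ETS1", "ITS1", "ITS2", "ETS2"))
  ratio <- mean(lam_d$intensity[lam_d$position %in% sp]) /
    mean(lam_v$intensity[lam_v$position %in% sp])
  expect_equal(ratio, 0.4, tolerance = 1e-12)
})

test_that("intensity is nonnegative and reduces to identity without drug effects", {
  ann <- toy_annotation()
  ref <- toy_reference()
  id_cfg <- sim_config(seed = 3, initiation_scale = 1,
                       base_pause_weight = 1, drug_pause_weight = 1)
  lam_v <- simulate_condition_occupancy(ref, ann, id_cfg, "vehicle")
  lam_d <- simulate_condition_occupancy(ref, ann, id_cfg, "drug")
  expect_equal(lam_v$intensity, lam_d$intensity)
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, initiation_scale = runif(1, 0.1, 1),
                      base_pause_weight = runif(1, 1, 5),
                      drug_pause_weight = runif(1, 1, 20))
    for (cond in c("vehicle", "drug")) {
      lam <- simulate_condition_occupancy(ref, ann, cfg, cond)
      expect_true(all(lam$intensity >= 0))
    }
  }
})

test_that("drug pause weighting targets positions upstream of G-rich windows", {
  ann <- toy_annotation()
  ref <- toy_reference()  # G-run at 1-based 21-28
  cfg <- sim_config(seed = 3, initiation_scale = 1, base_pause_weight = 1,
                    drug_pause_weight = 10, gc_window = 6, gc_threshold = 1)
  lam_v <- simulate_condition_occupancy(ref, ann, cfg, "vehicle")
  lam_d <- simulate_condition_occupancy(ref, ann, cfg, "drug")
  boosted <- lam_d$position[lam_d$intensity > lam_v$intensity * 5]
  # windows p+1..p+6 fully G exist for p in 20..22
  expect_equal(boosted, c(20L, 21L, 22L))
})

test_that("library simulation conserves depth and places contamination in genes", {
  ann <- toy_annotation()
  ref <- toy_reference()
  cfg <- sim_config(seed = 3, depth = 10000, contamination_fraction = 1)
  lam <- simulate_condition_occupancy(ref, ann, cfg, "vehicle")
  reads <- simulate_netseq_library(lam, ann, cfg, replicate_seed = 9)
  expect_equal(nrow(reads), 10000L)
  sp <- region_positions(ann, c("ETS1", "ITS1", "ITS2", "ETS2"))
  expect_equal(sum(reads$pos %in% sp), 0L)
  gene <- region_positions(ann, c("18S", "5.8S", "25S"))
  expect_true(all(reads$pos %in% gene))
})

test_that("degenerate intensity concentrates all 5' ends at one position", {
  ann <- toy_annotation()
  lam <- tibble::tibble(position = positions_35s(ann), intensity = 0)
  lam$intensity[lam$position == 85L] <- 1
  cfg <- sim_config(seed = 3, depth = 500, contamination_fraction = 0,
                    duplicate_rate = 0)
  reads <- simulate_netseq_library(lam, ann, cfg, replicate_seed = 2)
  expect_equal(nrow(reads), 500L)
  expect_true(all(reads$pos == 85L))
  expect_error(
    simulate_netseq_library(lam[0, ], ann, cfg),
    class = "poliseq_input_error"
  )
})

test_that("library simulation is a pure function of config and seed", {
  ann <- toy_annotation()
  ref <- toy_reference()
  cfg <- sim_config(seed = 3, depth = 2000)
  lam <- simulate_condition_occupancy(ref, ann, cfg, "drug")
  a <- simulate_netseq_library(lam, ann, cfg, replicate_seed = 4)
  b <- simulate_netseq_library(lam, ann, cfg, replicate_seed = 4)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_netseq_library(lam, ann, cfg, replicate_seed = 5)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("duplicate re-emission creates repeated (position, UMI) pairs", {
  ann <- toy_annotation()
  ref <- toy_reference()
  cfg <- sim_config(seed = 3, depth = 5000, duplicate_rate = 0.3)
  lam <- simulate_condition_occupancy(ref, ann, cfg, "vehicle")
  reads <- simulate_netseq_library(lam, ann, cfg, replicate_seed = 1)
  keys <- paste(reads$pos, reads$umi)
  expect_lt(length(unique(keys)), nrow(reads))
})

test_that("titration generator matches the exponential model exactly at zero noise", {
  s <- simulate_titration(ic50 = 0.81, amplitude = 2,
                          concentrations = c(0, 0.81, 1.62))
  expect_equal(s$signal[1L], 2)
  expect_equal(s$signal[2L], 1)       # half-maximal at c = IC50
  expect_equal(s$signal[3L], 0.5)
  expect_error(simulate_titration(ic50 = 0), class = "poliseq_invalid_config")
  expect_error(simulate_titration(ic50 = 1, concentrations = c(-1, 1)),
               class = "poliseq_invalid_config")
})

test_that("elongation lane generator renders the stated leading-edge model", {
  g <- simulate_elongation_timecourse(rate = 40, start_length = 55,
                                      times_s = c(4, 6, 8, 10))
  # single band per lane when no pause sites are given
  for (lane in split(g$lanes, g$lanes$lane_id)) {
    above <- lane$intensity >= 0.2 * max(lane$intensity)
    expect_equal(sum(rle(above)$values), 1L)
  }
  # determinism, and cap at template length
  g2 <- simulate_elongation_timecourse(rate = 40, start_length = 55,
                                       times_s = c(4, 6, 8, 10))
  expect_identical(g$lanes, g2$lanes)
  expect_error(simulate_elongation_timecourse(rate = -1),
               class = "poliseq_invalid_config")
  expect_error(simulate_elongation_timecourse(rate = 40, times_s = c(6, 4)),
               class = "poliseq_invalid_config")
})
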