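test_that("alignment loading keeps primary sense reads and logs the rest", {
  ann <- toy_annotation()
  recs <- tibble::tibble(
    qname = sprintf("r%d", 1:6),
    flag = c(0L, 0L, 0L, 16L, 16L, 4L),   # 3 sense, 2 antisense, 1 unmapped
    pos = c(15L, 20L, 90L, 25L, 30L, 50L),
    umi = c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT", "ACACAC", "GTGTGT")
  )
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam, recs)
  reads <- suppressMessages(read_netseq_alignments(sam, ann))
  expect_equal(nrow(reads), 3L)
  expect_setequal(reads$qname, c("r1", "r2", "r3"))
  disc <- attr(reads, "discarded")
  expect_equal(unname(disc["antisense"]), 2)
  expect_equal(unname(disc["unmapped"]), 1)
})

test_that("reads outside the 35S span are discarded, not counted", {
  ann <- toy_annotation()  # 35S span is 0-based [10, 190) -> 1-based 11..190
  recs <- tibble::tibble(
    qname = c("in1", "out_left", "out_right"),
    flag = 0L,
    pos = c(11L, 5L, 195L),
    umi = "AAAAAA"
  )
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam, recs)
  reads <- suppressMessages(read_netseq_alignments(sam, ann))
  expect_equal(reads$qname, "in1")
  expect_equal(unname(attr(reads, "discarded")["outside_35s"]), 2)
})

test_that("header-only SAM yields an empty result with a warning", {
  ann <- toy_annotation()
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:rdna_unit\tLN:200"), sam)
  expect_warning(
    reads <- suppressMessages(read_netseq_alignments(sam, ann)),
    "no records"
  )
  expect_equal(nrow(reads), 0L)
})

test_that("SAM and BAM encodings of the same records load identically", {
  ann <- toy_annotation()
  recs <- tibble::tibble(
    qname = sprintf("r%d", 1:5),
    flag = 0L,
    pos = c(15L, 15L, 40L, 90L, 150L),
    umi = c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT", "ACACAC")
  )
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam, recs)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  from_sam <- suppressMessages(read_netseq_alignments(sam, ann))
  from_bam <- suppressMessages(read_netseq_alignments(bam, ann))
  expect_identical(as.data.frame(from_sam), as.data.frame(from_bam))
})

test_that("reference name or length mismatch is an input error", {
  ann <- toy_annotation()
  recs <- tibble::tibble(qname = "r1", flag = 0L, pos = 15L, umi = "AAAAAA")
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam, recs, unit_length = 999L)
  expect_error(suppressMessages(read_netseq_alignments(sam, ann)),
               class = "poliseq_input_error")
  sam2 <- tempfile(fileext = ".sam")
  write_toy_sam(sam2, recs, reference_name = "chrI")
  expect_error(suppressMessages(read_netseq_alignments(sam2, ann)),
               class = "poliseq_input_error")
  expect_error(suppressMessages(read_netseq_alignments(tempfile(), ann)),
               class = "poliseq_input_error")
})

test_that("UMI deduplication matches a set-based oracle and is idempotent", {
  set.seed(31)
  n <- 400L
  reads <- tibble::tibble(
    qname = sprintf("r%03d", seq_len(n)),
    flag = 0L,
    pos = sample(11:190, n, replace = TRUE),
    strand = "+",
    umi = sample(c("AA", "CC", "GG", "TT"), n, replace = TRUE)
  )
  dd <- dedup_umis(reads)
  expect_equal(nrow(dd), length(unique(paste(reads$pos, reads$umi))))
  expect_identical(as.data.frame(dedup_umis(dd)), as.data.frame(dd))
  # all distinct -> identity
  distinct_reads <- tibble::tibble(
    qname = sprintf("r%d", 1:4), flag = 0L,
    pos = c(11L, 12L, 13L, 14L), strand = "+",
    umi = c("AA", "AA", "AA", "AA")
  )
  expect_equal(nrow(dedup_umis(distinct_reads)), 4L)
  # 5 copies of one pair -> 1 retained, first in coordinate order
  dup_reads <- tibble::tibble(
    qname = sprintf("r%d", 1:5), flag = 0L, pos = rep(20L, 5L),
    strand = "+", umi = rep("AC", 5L)
  )
  expect_equal(nrow(dedup_umis(dup_reads)), 1L)
})

test_that("a read without a UMI fails deduplication by name", {
  reads <- tibble::tibble(
    qname = c("good", "naked"), flag = 0L, pos = c(11L, 12L),
    strand = "+", umi = c("AAAAAA", NA)
  )
  expect_error(dedup_umis(reads), "naked", class = "poliseq_input_error")
})

test_that("occupancy track counts 5' ends and conserves read totals", {
  ann <- toy_annotation()
  reads <- tibble::tibble(
    qname = sprintf("r%d", 1:4), flag = 0L,
    pos = rep(85L, 4L), strand = "+", umi = sprintf("U%d", 1:4)
  )
  tr <- build_occupancy_track(reads, ann, normalize = FALSE)
  expect_equal(tr$count[tr$position == 85L], 4)
  expect_equal(sum(tr$count), 4)
  expect_equal(nrow(tr), length(positions_35s(ann)))

  # CPM: 10 reads all at one position -> 1e6 there
  reads10 <- tibble::tibble(
    qname = sprintf("r%d", 1:10), flag = 0L,
    pos = rep(100L, 10L), strand = "+", umi = sprintf("U%d", 1:10)
  )
  trn <- build_occupancy_track(reads10, ann, normalize = TRUE)
  expect_equal(trn$count[trn$position == 100L], 1e6)
  expect_equal(sum(trn$count), 1e6)

  # conservation on a random fixture
  set.seed(8)
  rnd <- tibble::tibble(
    qname = sprintf("r%d", 1:250), flag = 0L,
    pos = sample(11:190, 250, replace = TRUE), strand = "+",
    umi = replicate(250, paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                               collapse = ""))
  )
  rnd <- dedup_umis(rnd)
  tr2 <- build_occupancy_track(rnd, ann, normalize = FALSE)
  expect_equal(sum(tr2$count), nrow(rnd))
})

test_that("Spearman reproducibility has the textbook fixed points", {
  ann <- toy_annotation()
  set.seed(12)
  counts <- sample(0:50, 180, replace = TRUE)
  a <- track_from_counts(counts, ann)
  expect_equal(spearman_reproducibility(a, a)$rho, 1)
  # rank reversal with distinct counts
  distinct_counts <- sample(180)
  b <- track_from_counts(distinct_counts, ann)
  rev_b <- track_from_counts(max(distinct_counts) + 1 - distinct_counts, ann)
  expect_equal(spearman_reproducibility(b, rev_b)$rho, -1)
})

test_that("Spearman with ties matches the average-rank oracle", {
  ann <- toy_annotation()
  x <- c(5, 3, 3, 2, 1, 4, rep(0, 174))
  y <- c(4, 4, 2, 1, 3, 5, rep(0, 174))
  # informative positions are the first six; both-zero positions drop out
  a <- track_from_counts(x, ann)
  b <- track_from_counts(y, ann)
  got <- spearman_reproducibility(a, b)
  expect_equal(got$n_positions, 6L)
  rx <- midranks(x[1:6]); ry <- midranks(y[1:6])
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, oracle, tolerance = 1e-12)
})

test_that("Spearman rho is invariant to CPM scaling and needs >= 3 positions", {
  ann <- toy_annotation()
  set.seed(4)
  counts_a <- rpois(180, 3)
  counts_b <- rpois(180, 3)
  raw_a <- track_from_counts(counts_a, ann)
  raw_b <- track_from_counts(counts_b, ann)
  cpm_a <- track_from_counts(counts_a / sum(counts_a) * 1e6, ann,
                             normalized = TRUE)
  cpm_b <- track_from_counts(counts_b / sum(counts_b) * 1e6, ann,
                             normalized = TRUE)
  expect_equal(spearman_reproducibility(raw_a, raw_b)$rho,
               spearman_reproducibility(cpm_a, cpm_b)$rho)
  near_empty <- track_from_counts(c(1, 1, rep(0, 178)), ann)
  empty <- track_from_counts(rep(0, 180), ann)
  expect_error(spearman_reproducibility(near_empty, empty),
               class = "poliseq_insufficient_data")
})

test_that("replicates simulated from one intensity landscape rank-correlate", {
  ref <- compact_reference(seed = 17)
  cfg <- sim_config(seed = 17, depth = 5e4)
  tracks <- simulate_tracks(ref, cfg, "vehicle", replicate_seeds = c(21, 22))
  rho <- spearman_reproducibility(tracks[[1L]], tracks[[2L]])$rho
  expect_gt(rho, 0.8)
})
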