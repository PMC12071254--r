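test_that("BED loading applies the insert-size filter and validates records", {
  bed <- write_bed(data.frame(chrom = "chr1",
                              start = c(0L, 100L, 1000L),
                              end = c(150L, 400L, 1700L)),
                   withr::local_tempfile(fileext = ".bed"))
  fr <- load_fragments(bed)
  expect_equal(nrow(fr), 2L)  # 700-bp span dropped at max_insert 600
  expect_equal(fr$end - fr$start, c(150L, 300L))

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), empty)
  expect_warning(fr0 <- load_fragments(empty), "no fragments")
  expect_equal(nrow(fr0), 0L)

  bad <- write_bed(data.frame("chr1", 100L, 100L),
                   withr::local_tempfile(fileext = ".bed"))
  expect_error(load_fragments(bad), "line 1")
})

test_that("end motifs are the reference 4-mers at the two 5' ends", {
  ref <- toy_reference()
  m <- end_motifs_of_fragment("chrT", 0, 8, ref)
  expect_equal(m$watson, "ACGT")
  expect_equal(m$crick, "ACGT")  # revcomp of right-end "ACGT"

  ref2 <- c(chrT = "AAAACCCCGGGGTTTT")
  m2 <- end_motifs_of_fragment("chrT", 0, 16, ref2)
  expect_equal(m2$watson, "AAAA")
  expect_equal(m2$crick, "AAAA")  # revcomp of "TTTT"

  refN <- c(chrT = "ACGTNCGTACGT")
  expect_null(end_motifs_of_fragment("chrT", 0, 8, refN))
  expect_null(end_motifs_of_fragment("chrT", 10, 20, toy_reference()))
})

test_that("mirror fragments on a palindromic reference give identical motif pairs", {
  # ACGTACGT... is its own reverse complement over full periods
  ref <- c(chrT = strrep("ACGT", 10))
  a <- end_motifs_of_fragment("chrT", 4, 16, ref)
  b <- end_motifs_of_fragment("chrT", 40 - 16, 40 - 4, ref)
  expect_equal(a, b)
})

test_that("profiles count two ends per fragment and normalize to 1", {
  fr <- data.frame(chrom = "chrT", start = 0L, end = 8L)
  pr <- build_profile(fr, toy_reference(), "s1")
  expect_s3_class(pr, "end_motif_profile")
  expect_equal(sum(pr$counts), 2L)
  expect_equal(unname(pr$counts["ACGT"]), 2L)
  expect_equal(unname(pr$frequencies["ACGT"]), 1)
  expect_equal(sum(pr$frequencies), 1, tolerance = 1e-12)

  # fragment skipped for a non-ACGT window, counted not fatal
  refN <- c(chrT = paste0("NNNN", strrep("ACGT", 5)))
  fr2 <- data.frame(chrom = "chrT", start = c(0L, 4L), end = c(8L, 12L))
  pr2 <- build_profile(fr2, refN, "s2")
  expect_equal(pr2$n_skipped, 1L)
  expect_equal(sum(pr2$counts), 2L)

  expect_error(build_profile(fr[0, ], toy_reference()), "empty profile")
})

test_that("extraction recovers a simulated generating distribution", {
  target <- baseline_profile_fixture()
  sim <- simulate_fragments(target, n_fragments = 30000, seed = 21)
  fasta <- withr::local_tempfile(fileext = ".fa")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_simulated_fragments(sim, fasta, bed)
  fr <- load_fragments(bed)
  pr <- build_profile(fr, fasta, "sim")
  # every motif within sampling error of the target (4 SE keeps the
  # expected number of exceedances over 256 motifs far below 1)
  n <- sum(pr$counts)
  se <- sqrt(target * (1 - target) / n)
  expect_true(all(abs(pr$frequencies - target) <= 4 * se + 1e-9))
  # total-variation convergence
  expect_lt(sum(abs(pr$frequencies - target)) / 2, 0.03)
})

test_that("profile matrix TSV round-trips and validates columns", {
  pm <- simulate_profiles(2, 1, effect_size = 0.2, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(pm, path)
  back <- read_profile_matrix(path)
  expect_identical(colnames(back$x), all_motifs())
  expect_equal(back$x, pm$x, tolerance = 1e-12)
  expect_equal(back$labels, pm$labels)

  # missing motif column is named in the error
  df <- utils::read.delim(path, check.names = FALSE)
  df$TTTT <- NULL
  broken <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, broken, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_profile_matrix(broken), "TTTT")

  # a row not summing to 1 is renormalized with a warning
  x <- pm$x
  x[1, ] <- x[1, ] * 0.9
  expect_warning(pm2 <- profile_matrix(x), "renormalized")
  expect_equal(unname(rowSums(pm2$x)), rep(1, 3), tolerance = 1e-9)

  # duplicate ids rejected
  expect_error(profile_matrix(pm$x, sample_ids = c("a", "a", "b")),
               "duplicate")
})

test_that("BAM input yields the same fragments as the equivalent BED", {
  skip_if_not_installed("Rsamtools")
  ref <- c(chrT = strrep("ACGTTGCA", 40))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrT\tLN:320",
    paste("r1", 99, "chrT", 5, 60, "20M", "=", 45, 60,
          strrep("A", 20), "*", sep = "\t"),
    paste("r1", 147, "chrT", 45, 60, "20M", "=", 5, -60,
          strrep("A", 20), "*", sep = "\t"),
    paste("r2", 1123, "chrT", 10, 60, "20M", "=", 30, 40,
          strrep("A", 20), "*", sep = "\t")  # duplicate-flagged, skipped
  ), sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(),
                          overwrite = TRUE)
  fr <- load_fragments(bam, format = "bam")
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$start, 4L)   # POS 5 -> 0-based 4
  expect_equal(fr$end, 64L)    # + TLEN 60
})
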