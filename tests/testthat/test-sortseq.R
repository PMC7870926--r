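test_that("variable-region extraction slices bases 23-128 and drops short reads", {
  ref <- example_reference()
  read150 <- paste0(strrep("A", 22), ref, strrep("G", 22))
  seg <- extract_variable_region(c(read150, strrep("A", 127)))
  expect_equal(nchar(seg[1]), 106)
  expect_equal(seg[1], ref)
  expect_true(is.na(seg[2]))
  expect_equal(attr(seg, "n_discarded"), 1L)
})

test_that("duplicate grouping matches a brute-force tally and applies the threshold", {
  set.seed(31)
  pool <- c("AAAA", "AAAT", "CGCG", "TTTT")
  segs <- tibble::tibble(
    bin = sample(-2:2, 100, replace = TRUE),
    segment = sample(pool, 100, replace = TRUE, prob = c(.5, .3, .15, .05))
  )
  out <- group_and_filter(segs, min_reads = 10)
  # brute-force tally oracle
  naive <- table(segs$segment, segs$bin)
  for (i in seq_len(nrow(out))) {
    expect_equal(out$n[i],
                 unname(naive[out$segment[i], as.character(out$bin[i])]))
  }
  totals <- rowSums(naive)
  expect_setequal(unique(out$segment), names(totals)[totals >= 10])

  # threshold boundary: 9 total reads excluded, 10 retained
  edge <- tibble::tibble(bin = c(rep(0L, 9), rep(1L, 10)),
                         segment = c(rep("AAAA", 9), rep("CCCC", 10)))
  kept <- group_and_filter(edge, min_reads = 10)
  expect_setequal(unique(kept$segment), "CCCC")
  # the threshold pools counts across bins
  split9 <- tibble::tibble(bin = c(rep(-1L, 5), rep(2L, 5)),
                           segment = rep("GGGG", 10))
  expect_equal(sum(group_and_filter(split9, 10)$n), 10)
  empty <- group_and_filter(tibble::tibble(bin = integer(), segment = character()))
  expect_equal(nrow(empty), 0)
})

test_that("variants classify by Hamming comparison", {
  ref <- example_reference()
  refv <- strsplit(ref, "")[[1]]
  mut1 <- refv; mut1[29] <- setdiff(c("A", "C", "G", "T"), refv[29])[1]
  mut2 <- refv; mut2[4] <- setdiff(c("A","C","G","T"), refv[4])[1]
  mut2[90] <- setdiff(c("A","C","G","T"), refv[90])[1]
  res <- classify_variant(
    c(ref, paste(mut1, collapse = ""), paste(mut2, collapse = ""),
      substr(ref, 1, 50), sub("^.", "N", ref)),
    ref)
  expect_equal(res$class, c("wild_type", "single_substitution",
                            "multi_substitution", "other", "other"))
  expect_equal(res$position[2], 29L)
  expect_equal(res$base[2], mut1[29])
})

test_that("intensity moment matches hand arithmetic and degenerate cases", {
  bins2 <- tibble::tibble(bin = 1:2, c_k = c(0.5, 0.5), I_k = c(10, 100),
                          N_k = c(100, 100))
  expect_equal(intensity_moment(c(`1` = 10, `2` = 30), bins2), 77.5)
  # all reads in one bin -> that bin's intensity
  bins5 <- tibble::tibble(bin = -2:2, c_k = unname(default_bin_occupancy),
                          I_k = c(1, 3, 10, 30, 100), N_k = rep(1000, 5))
  expect_equal(intensity_moment(c(`1` = 57), bins5), 30)
  # uniform occupancy and uniform depth share -> plain mean of intensities
  binsu <- tibble::tibble(bin = -2:2, c_k = rep(0.2, 5),
                          I_k = c(1, 3, 10, 30, 100), N_k = rep(500, 5))
  expect_equal(intensity_moment(stats::setNames(rep(25, 5), -2:2), binsu),
               mean(binsu$I_k))
  # no reads anywhere -> missing
  expect_true(is.na(intensity_moment(numeric(0), bins5)))
})

test_that("intensity moment is scale-invariant and a convex combination", {
  bins <- tibble::tibble(bin = -2:2, c_k = unname(default_bin_occupancy),
                         I_k = c(2, 5, 20, 60, 180), N_k = c(900, 1600, 1500, 700, 150))
  set.seed(99)
  for (i in 1:20) {
    n <- stats::setNames(rpois(5, 20), -2:2)
    k <- intensity_moment(n, bins)
    if (is.na(k)) next
    expect_gte(k, min(bins$I_k))
    expect_lte(k, max(bins$I_k))
    scaled <- dplyr::mutate(bins, N_k = N_k * 7)
    expect_equal(intensity_moment(n * 7, scaled), k, tolerance = 1e-12)
  }
})

test_that("standard scores use population statistics over non-missing entries", {
  tbl <- tibble::tibble(position = 1:3, base = "A", K = c(1, 2, 3),
                        total_reads = 10, missing = FALSE)
  z <- z_scores(tbl)$z
  expect_equal(z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(z[2], 0)
  # translation invariance
  z2 <- z_scores(dplyr::mutate(tbl, K = K + 57))$z
  expect_equal(z2, z, tolerance = 1e-12)
  # zero spread -> zeros with a warning
  expect_warning(zc <- z_scores(dplyr::mutate(tbl, K = 5))$z, "zero spread")
  expect_equal(zc, rep(0, 3))
  expect_error(z_scores(tbl[1, ]), "at least 2")
})

test_that("heatmap table flags wild-type and missing cells and round-trips CSV", {
  ref <- example_reference()
  refv <- strsplit(ref, "")[[1]]
  tbl <- tibble::tibble(position = c(5L, 9L), base = c("A", "T"),
                        K = c(12.5, 80), total_reads = c(20, 15),
                        missing = FALSE)
  tbl <- dplyr::filter(tbl, base != refv[position])
  hm <- heatmap_matrix(tbl, ref, coordinate_offset = 148)
  expect_equal(nrow(hm), 106 * 4)
  wt <- dplyr::filter(hm, wild_type)
  expect_equal(nrow(wt), 106)
  expect_equal(sum(!is.na(hm$value)), nrow(tbl))
  expect_equal(min(hm$coordinate), 149)
  # RNA alphabet out
  expect_setequal(unique(hm$base), c("A", "C", "G", "U"))
  f <- tempfile(fileext = ".csv")
  readr::write_csv(hm, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$value, hm$value)
  expect_error(heatmap_matrix(dplyr::mutate(tbl, position = 200L), ref),
               "outside")
})

test_that("the pipeline recovers the ordering of true variant fluorescence", {
  ref <- example_reference()
  refv <- strsplit(ref, "")[[1]]
  set.seed(12)
  pos <- sample(1:106, 15)
  em <- tibble::tibble(
    position = pos,
    base = vapply(pos, function(i) sample(setdiff(c("A", "C", "G", "T"),
                                                  refv[i]), 1), character(1)),
    fluor = exp(seq(log(20), log(2000), length.out = 15))
  )
  lib <- sim_sortseq_library(em, cells_per_variant = 300, reads_per_cell = 2,
                             seed = 5)
  eff <- sortseq_effects(lib$reads, ref, lib$bins)
  j <- dplyr::inner_join(eff, lib$truth, by = c("position", "base"))
  expect_gte(nrow(j), 14)
  expect_gte(cor(j$K, j$fluor, method = "spearman"), 0.9)
  # z-scores present and centred
  expect_lt(abs(mean(j$z)), 1)
})

test_that("FASTQ round trip reproduces the in-memory analysis", {
  ref <- example_reference()
  refv <- strsplit(ref, "")[[1]]
  em <- tibble::tibble(position = c(10L, 60L),
                       base = vapply(c(10L, 60L), function(i)
                         setdiff(c("A", "C", "G", "T"), refv[i])[1], character(1)),
                       fluor = c(50, 800))
  dir <- file.path(tempdir(), "sortseq_rt")
  lib <- sim_sortseq_library(em, cells_per_variant = 100, reads_per_cell = 2,
                             seed = 9, dir = dir)
  files <- list.files(dir, pattern = "^bin_.*fastq$", full.names = TRUE)
  names(files) <- sub("^bin_(-?\\d)\\.fastq$", "\\1", basename(files))
  reads <- read_binned_fastq(files)
  expect_equal(nrow(reads), nrow(lib$reads))
  eff_disk <- sortseq_effects(reads, ref, lib$bins)
  eff_mem <- sortseq_effects(lib$reads, ref, lib$bins)
  expect_equal(dplyr::arrange(eff_disk, position, base)$K,
               dplyr::arrange(eff_mem, position, base)$K)
})
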