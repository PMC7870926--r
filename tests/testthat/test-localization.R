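make_points <- function(m, cell_id = 1L) {
  tibble::tibble(x_nm = m[, 1], y_nm = m[, 2], z_nm = m[, 3], cell_id = cell_id)
}

test_that("isolated points below MinPts are all noise", {
  pts <- make_points(cbind(seq(0, 2000, by = 1000), 0, 0))  # 3 points, nps 4
  out <- dbscan_clusters(pts, eps = 15, nps = 4)
  expect_true(all(out$cluster == 0))
})

test_that("two well-separated dense blobs give exactly two clusters", {
  set.seed(5)
  blob <- function(center) cbind(rnorm(20, center[1], 5), rnorm(20, center[2], 5),
                                 rnorm(20, center[3], 5))
  pts <- make_points(rbind(blob(c(0, 0, 0)), blob(c(1500, 0, 0))))
  out <- dbscan_clusters(pts, eps = 15, nps = 3)
  expect_equal(sort(unique(out$cluster[out$cluster > 0])), c(1L, 2L))
  expect_equal(length(unique(out$cluster[1:20])), 1L)
  expect_equal(length(unique(out$cluster[21:40])), 1L)
})

test_that("DBSCAN agrees with the exhaustive oracle on random clouds", {
  set.seed(77)
  for (trial in 1:20) {
    m <- cbind(runif(50, 0, 120), runif(50, 0, 120), runif(50, 0, 120))
    got <- dbscan_clusters(make_points(m), eps = 15, nps = 3)$cluster
    want <- dbscan_brute(m, eps = 15, minpts = 3)
    expect_identical(got, want)
  }
})

test_that("DBSCAN is invariant to rigid translation and partitions all points", {
  set.seed(13)
  m <- cbind(runif(80, 0, 150), runif(80, 0, 150), runif(80, 0, 150))
  a <- dbscan_clusters(make_points(m), eps = 20, nps = 3)
  b <- dbscan_clusters(make_points(m + 5000), eps = 20, nps = 3)
  expect_identical(a$cluster, b$cluster)
  ct <- cluster_table(a)
  expect_equal(sum(ct$n_loc) + sum(a$cluster == 0), nrow(m))
})

test_that("single-RNA calibration takes the median cluster size", {
  calib_tbl <- tibble::tibble(cell_id = rep(1:5, each = 5), cluster = 1:25,
                              n_loc = rep(12, 25), radius_nm = 10,
                              x_nm = 0, y_nm = 0, z_nm = 0)
  calib <- calibrate_single_rna(calib_tbl)
  expect_equal(calib$statistic, 12)
  expect_equal(calib$background, 0)
  expect_error(calibrate_single_rna(calib_tbl[1:10, ]), "too small")
  # deletion strain with clusters contributes mean clusters per cell
  bg <- calib_tbl[1:6, ]
  bg$cell_id <- c(1, 1, 1, 2, 2, 3)
  calib2 <- calibrate_single_rna(calib_tbl, bg, n_background_cells = 3)
  expect_equal(calib2$background, 2)
})

test_that("copy numbers follow the rounding and baseline-subtraction rules", {
  calib <- list(statistic = 12, background = 2)
  cl <- tibble::tibble(cell_id = c(1, 1, 2, 3), cluster = 1:4,
                       n_loc = c(12, 36, 5, 24), radius_nm = 10,
                       x_nm = 0, y_nm = 0, z_nm = 0)
  est <- estimate_copy_numbers(cl, calib, cell_ids = 1:4)
  # cell 1: 1 + 3 copies - 2 background = 2; cell 2: max(1, round(5/12)) = 1 -> 0
  expect_equal(est$copies, c(2, 0, 0, 0))
  calib0 <- list(statistic = 12, background = 0)
  est0 <- estimate_copy_numbers(cl, calib0)
  expect_equal(est0$copies[est0$cell_id == 1], 4)
  # doubling localization counts doubles copies (above the max(1, .) floor)
  est2 <- estimate_copy_numbers(dplyr::mutate(cl, n_loc = n_loc * 2), calib0)
  expect_equal(est2$copies[est2$cell_id == 1],
               2 * est0$copies[est0$cell_id == 1])
  expect_error(estimate_copy_numbers(cl, list(statistic = 0)), "calibration")
})

test_that("colocalization detects perfect overlap and perfect displacement", {
  cl <- tibble::tibble(cell_id = 1, cluster = 1:4, n_loc = 20, radius_nm = 10,
                       x_nm = c(0, 200, 400, 600), y_nm = 0, z_nm = 0)
  on_top <- tibble::tibble(x_nm = cl$x_nm, y_nm = 0, z_nm = 0, cell_id = 1)
  expect_equal(colocalize(cl, on_top, 40)$raw_fraction, 100)
  displaced <- dplyr::mutate(on_top, x_nm = x_nm + 400)
  res <- colocalize(cl, displaced, 40)
  expect_equal(res$n_coloc, 2L)  # 400 and 600 nm centroids are hit
  far <- dplyr::mutate(on_top, z_nm = 1000)
  expect_equal(colocalize(cl, far, 40)$raw_fraction, 0)
})

test_that("chance correction fits a line through the origin and subtracts", {
  control <- tibble::tibble(sgrs_copies = c(10, 50, 100, 200),
                            raw_fraction = 0.1 * c(10, 50, 100, 200))
  res <- chance_correction(control, raw_fraction = 35, sgrs_copies = 100)
  expect_equal(res$slope, 0.1, tolerance = 1e-12)
  expect_equal(res$corrected_fraction, 25)
  # zero slope leaves raw untouched
  flat <- dplyr::mutate(control, raw_fraction = 0)
  expect_equal(chance_correction(flat, 35, 100)$corrected_fraction, 35)
  expect_error(chance_correction(control[1:2, ], 35, 100), "3 control")
  zero <- dplyr::mutate(control, sgrs_copies = 0)
  expect_error(chance_correction(zero, 35, 100), "slope undefined")
  # over-correction clips at zero and is flagged
  res2 <- chance_correction(control, raw_fraction = 5, sgrs_copies = 100)
  expect_equal(res2$corrected_fraction, 0)
  expect_true(res2$clipped)
})

test_that("copy-number estimation recovers generated copies within 20 percent", {
  calib_cells <- tibble::tibble(cell_id = 1:30, sgrs_copies = 3, ptsg_copies = 0)
  calib_loc <- dplyr::filter(sim_localizations(calib_cells, seed = 6),
                             channel == "sgrs")
  calib <- calibrate_single_rna(
    cluster_table(dbscan_clusters(calib_loc, eps = 15, nps = 3)))
  cells <- tibble::tibble(cell_id = 1:8,
                          sgrs_copies = c(10, 30, 60, 90, 120, 150, 180, 200),
                          ptsg_copies = 0)
  loc <- dplyr::filter(sim_localizations(cells, seed = 17), channel == "sgrs")
  est <- estimate_copy_numbers(
    cluster_table(dbscan_clusters(loc, eps = 15, nps = 3)),
    calib, cell_ids = cells$cell_id)
  rel <- abs(est$copies - cells$sgrs_copies) / cells$sgrs_copies
  expect_lt(median(rel), 0.2)
})
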