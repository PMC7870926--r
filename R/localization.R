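#' Cluster 3D single-molecule localizations with DBSCAN
#'
#' Groups the localization point cloud of one imaging channel into density
#' clusters (candidate RNA spots) using DBSCAN. A core point has at least
#' `nps` points within `eps` of itself (itself included); border points
#' reachable from more than one cluster are assigned to the
#' first-discovered cluster with points visited in index order, so the
#' output is deterministic.
#'
#' The published parameters for this imaging system are `eps = 15`,
#' `nps = 3` for the sRNA channel (9 FISH probes) and `eps = 25`,
#' `nps = 10` for the mRNA channel (28 probes), with coordinates in
#' nanometres.
#'
#' @param points Tibble with columns `x_nm`, `y_nm`, `z_nm` and optionally
#'   `cell_id` (clustering is done within each cell) and `channel`.
#' @param eps Neighbourhood radius, same units as the coordinates.
#' @param nps Minimum number of points (MinPts), at least 1.
#' @return The input with a `cluster` column added: 0 for noise, otherwise
#'   a cluster id unique within each cell.
#' @export
dbscan_clusters <- function(points, eps, nps) {
  stopifnot(all(c("x_nm", "y_nm", "z_nm") %in% names(points)))
  if (!is.numeric(eps) || eps <= 0) stop("`eps` must be positive", call. = FALSE)
  if (!is.numeric(nps) || nps < 1) stop("`nps` must be at least 1", call. = FALSE)
  if (!nrow(points)) return(dplyr::mutate(points, cluster = integer()))
  if (!("cell_id" %in% names(points))) points$cell_id <- 1L
  points |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(d, key) {
      m <- as.matrix(d[, c("x_nm", "y_nm", "z_nm")])
      d$cluster <- dbscan_labels(m, eps, as.integer(nps))
      d
    }) |>
    dplyr::ungroup()
}

#' Summarize DBSCAN clusters
#'
#' @param clustered Output of [dbscan_clusters()].
#' @return Tibble with one row per cluster per cell: `cell_id`, `cluster`,
#'   `n_loc`, centroid coordinates, and `radius_nm` (RMS distance of
#'   members from the centroid).
#' @export
cluster_table <- function(clustered) {
  clustered |>
    dplyr::filter(.data$cluster > 0) |>
    dplyr::group_by(.data$cell_id, .data$cluster) |>
    dplyr::summarise(
      n_loc = dplyr::n(),
      radius_nm = sqrt(mean((.data$x_nm - mean(.data$x_nm))^2 +
                            (.data$y_nm - mean(.data$y_nm))^2 +
                            (.data$z_nm - mean(.data$z_nm))^2)),
      x_nm = mean(.data$x_nm), y_nm = mean(.data$y_nm), z_nm = mean(.data$z_nm),
      .groups = "drop"
    )
}

#' Calibrate the per-RNA localization statistic
#'
#' From a low-copy calibration sample in which each cluster can be assumed
#' to be a single RNA, the statistic is the median number of localizations
#' per cluster. The background cluster density comes from deletion strains
#' lacking the RNA (clusters arise there only from nonspecific probe
#' binding): mean clusters per cell.
#'
#' @param calib_clusters [cluster_table()] of the low-copy sample; at least
#'   `min_clusters` clusters are required.
#' @param background_clusters [cluster_table()] of the deletion-strain
#'   sample, or `NULL` for zero background.
#' @param n_background_cells Number of cells imaged in the deletion-strain
#'   sample (needed because cells with no clusters leave no rows).
#' @param min_clusters Minimum calibration ensemble size, default 20.
#' @return List with `statistic` (median localizations per RNA) and
#'   `background` (mean background clusters per cell).
#' @export
calibrate_single_rna <- function(calib_clusters, background_clusters = NULL,
                                 n_background_cells = NULL, min_clusters = 20) {
  n <- nrow(calib_clusters)
  if (n < min_clusters) {
    stop("calibration ensemble too small: ", n, " clusters (need ",
         min_clusters, ")", call. = FALSE)
  }
  statistic <- stats::median(calib_clusters$n_loc)
  background <- 0
  if (!is.null(background_clusters) && nrow(background_clusters) > 0) {
    ncell <- if (is.null(n_background_cells)) {
      length(unique(background_clusters$cell_id))
    } else n_background_cells
    background <- nrow(background_clusters) / ncell
  }
  list(statistic = statistic, background = background)
}

#' Estimate RNA copy numbers per cell from clusters
#'
#' Each cluster contributes `max(1, round(n_loc / statistic))` copies (a
#' dense cluster may hold several RNAs; a sparse one at least one), summed
#' per cell; the mean background cluster count from the deletion strain is
#' subtracted and the result floored at zero.
#'
#' @param clusters A [cluster_table()].
#' @param calibration Output of [calibrate_single_rna()].
#' @param cell_ids Optional vector of all imaged cells, so cells with no
#'   clusters report zero copies.
#' @return Tibble with `cell_id` and `copies`.
#' @export
estimate_copy_numbers <- function(clusters, calibration, cell_ids = NULL) {
  if (is.null(calibration$statistic) || calibration$statistic <= 0) {
    stop("invalid calibration: positive `statistic` required", call. = FALSE)
  }
  per_cell <- clusters |>
    dplyr::mutate(copies = pmax(1, round(.data$n_loc / calibration$statistic))) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(copies = sum(.data$copies), .groups = "drop")
  if (!is.null(cell_ids)) {
    per_cell <- tibble::tibble(cell_id = cell_ids) |>
      dplyr::left_join(per_cell, by = "cell_id") |>
      dplyr::mutate(copies = dplyr::coalesce(.data$copies, 0))
  }
  dplyr::mutate(per_cell, copies = pmax(0, .data$copies - calibration$background))
}

#' Raw colocalization fraction of mRNA clusters with sRNA localizations
#'
#' A target mRNA cluster counts as colocalized when at least one sRNA
#' localization lies within a 3D sphere of `radius_nm` around its centroid
#' (counted once, however many sRNA points fall inside). The default 40 nm
#' is the average measured mRNA cluster radius.
#'
#' @param ptsg_clusters [cluster_table()] of the mRNA channel.
#' @param sgrs_points Localization tibble of the sRNA channel (`x_nm`,
#'   `y_nm`, `z_nm`, `cell_id`); typically the clustered points with noise
#'   removed.
#' @param radius_nm Sphere radius, default 40.
#' @return Tibble per cell: `cell_id`, `n_clusters`, `n_coloc`,
#'   `raw_fraction` (percent). Cells with no mRNA clusters are flagged with
#'   `NA` fraction.
#' @export
colocalize <- function(ptsg_clusters, sgrs_points, radius_nm = 40) {
  if (radius_nm <= 0) stop("`radius_nm` must be positive", call. = FALSE)
  r2 <- radius_nm^2
  split_pts <- split(sgrs_points, sgrs_points$cell_id)
  ptsg_clusters |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(d, key) {
      pts <- split_pts[[as.character(key$cell_id)]]
      hit <- if (is.null(pts) || !nrow(pts)) rep(FALSE, nrow(d)) else {
        vapply(seq_len(nrow(d)), function(i) {
          any((pts$x_nm - d$x_nm[i])^2 + (pts$y_nm - d$y_nm[i])^2 +
                (pts$z_nm - d$z_nm[i])^2 <= r2)
        }, logical(1))
      }
      tibble::tibble(
        n_clusters = nrow(d), n_coloc = sum(hit),
        raw_fraction = if (nrow(d)) 100 * sum(hit) / nrow(d) else NA_real_
      )
    }) |>
    dplyr::ungroup()
}

#' Chance-colocalization correction
#'
#' Nonspecific (chance) colocalization grows with the sRNA copy number. A
#' negative-control strain with no true interaction provides pairs of
#' (sRNA copies, raw colocalization percent); a line through the origin
#' `y = a x` fitted by least squares (`a = sum(xy)/sum(x^2)`) calibrates
#' the chance rate, and the corrected fraction of a sample is
#' `raw - a * copies`, clipped at zero (flagged when clipping occurs).
#'
#' @param control Tibble with columns `sgrs_copies` and `raw_fraction`
#'   (percent) from the negative control; at least 3 rows.
#' @param raw_fraction Raw colocalization percent of the sample.
#' @param sgrs_copies sRNA copy number of the sample.
#' @return Tibble with `raw_fraction`, `slope`, `corrected_fraction`,
#'   `clipped`.
#' @export
chance_correction <- function(control, raw_fraction, sgrs_copies) {
  stopifnot(all(c("sgrs_copies", "raw_fraction") %in% names(control)))
  ctl <- dplyr::filter(control, !is.na(.data$raw_fraction))
  if (nrow(ctl) < 3L) stop("need at least 3 control pairs", call. = FALSE)
  if (all(ctl$sgrs_copies == 0)) {
    stop("all control copy numbers are zero; slope undefined", call. = FALSE)
  }
  a <- sum(ctl$sgrs_copies * ctl$raw_fraction) / sum(ctl$sgrs_copies^2)
  corrected <- raw_fraction - a * sgrs_copies
  tibble::tibble(
    raw_fraction = raw_fraction,
    slope = a,
    corrected_fraction = pmax(0, corrected),
    clipped = corrected < 0
  )
}
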