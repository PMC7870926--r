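#' Synthetic-data generators
#'
#' Desk-scale emulators of the four input kinds the analysis consumes:
#' kinetic time courses with counting noise, FACS-binned mutant-library
#' reads, 3D localization point clouds, and decay series. Each generator is
#' deterministic given its `seed` and attaches a machine-readable `truth`
#' attribute recording the generating parameters, which downstream recovery
#' tests read instead of re-deriving ground truth.
#'
#' @name synthetic
NULL

#' Default generating rate constants (wild-type regime)
#'
#' A realistic wild-type parameter regime for the simulators: association
#' 1.9e5 M^-1 s^-1, dissociation 0.22 s^-1, co-degradation 0.3 s^-1, target
#' transcription 0.5 copies/s with endogenous degradation 0.005 s^-1
#' (pre-stress steady state of 100 copies), sRNA transcription 0.6
#' copies/s and target-independent sRNA degradation 0.001 s^-1.
#'
#' @return A [rate_constants()] object.
#' @export
default_true_params <- function() {
  rate_constants(k_on = 1.9e5, k_off = 0.22, k_cat = 0.3,
                 alpha_p = 0.5, alpha_S = 0.6,
                 beta_p = 0.005, beta_Sp = 0.001)
}

#' Simulate the six kinetic time courses with counting noise
#'
#' Integrates the mass-action model for both strain backgrounds (the RNase E
#' mutant gets `k_cat_mut`, near zero, instead of the wild-type `k_cat`) on
#' the standard induction grid (0, 2, 4, 6, 8, 10, 15, 20 min) and emulates
#' the per-time-point measurement: the reported mean is the average of
#' `n_cells` Poisson draws around the deterministic value, with its SEM.
#'
#' @param params Generating [rate_constants()] for the wild-type background.
#' @param k_cat_mut Co-degradation rate of the RNase E mutant (default
#'   0.02 s^-1: co-degradation is strongly impaired but minor pathways
#'   remain).
#' @param state0 Initial copies `c(p=, S=, Sp=)`; default target at steady
#'   state, a little basal sRNA and near-background complex.
#' @param times_s Measurement grid in seconds.
#' @param n_cells Cells measured per time point (scalar or per-point).
#' @param noise If `FALSE`, return the deterministic means (SEM 0).
#' @param seed Integer seed.
#' @param cell A [cell_model()].
#' @return Tidy tibble (`background`, `time_s`, `species`, `mean_copies`,
#'   `sem`, `n_cells`) with a `truth` attribute.
#' @export
sim_timecourses <- function(params = default_true_params(), k_cat_mut = 0.02,
                            state0 = NULL, times_s = c(0, 2, 4, 6, 8, 10, 15, 20) * 60,
                            n_cells = 100, noise = TRUE, seed = 1,
                            cell = cell_model()) {
  if (is.null(state0)) {
    state0 <- c(p = params$alpha_p / params$beta_p, S = 2, Sp = 0.5)
  }
  set.seed(seed)
  par_bg <- list(
    wt_rnase_e = params,
    rnase_e_mutant = rate_constants(
      k_on = params$k_on, k_off = params$k_off, k_cat = k_cat_mut,
      alpha_p = params$alpha_p, alpha_S = params$alpha_S,
      beta_p = params$beta_p, beta_Sp = params$beta_Sp
    )
  )
  out <- purrr::imap_dfr(par_bg, function(p, bg) {
    sim <- simulate_kinetics(p, state0, times_s, cell)
    sim$background <- bg
    sim
  })
  n_cells <- rep_len(n_cells, length(times_s))
  out$n_cells <- n_cells[match(out$time_s, times_s)]
  if (noise) {
    draws <- purrr::map2(out$copies, out$n_cells,
                         function(mu, n) stats::rpois(n, mu))
    out$mean_copies <- vapply(draws, mean, numeric(1))
    out$sem <- vapply(draws, function(d) stats::sd(d) / sqrt(length(d)), numeric(1))
  } else {
    out$mean_copies <- out$copies
    out$sem <- 0
  }
  res <- dplyr::select(out, "background", "time_s", "species",
                       "mean_copies", "sem", "n_cells")
  attr(res, "truth") <- list(
    params = params, k_cat_mut = k_cat_mut, state0 = state0,
    n_cells = n_cells, seed = seed, volume = cell$volume
  )
  res
}

# Fixed synthetic 106-nt variable-region reference (DNA alphabet) and the
# constant 22-nt adaptor flanks used when emitting full-length reads.
SYNTH_REFERENCE <- paste0(
  "ACCTCTATCAAGACGCCATGCAGCCTCCTGAATTATCACCAGTTTCTCAGGGTG",
  "GAAGCACACTTCTCGACCCCAGGACAGGAAAGCCATGGGTTCCAAACTGTAT"
)
SYNTH_ADAPTOR_5 <- "CATCCTTGAAGTGTTTCTCGTA"
SYNTH_ADAPTOR_3 <- "ATTGTAGGACTAGAATTGCCGC"

#' The synthetic wild-type variable-region reference
#'
#' A fixed, synthetic 106-nt sequence standing in for the sequenced
#' wild-type segment in examples and generated libraries (the real segment
#' is experiment-specific). DNA alphabet.
#' @return A single character string of length 106.
#' @export
example_reference <- function() SYNTH_REFERENCE

#' Simulate a FACS-binned mutant-library sequencing experiment
#'
#' Each variant (the wild type plus every row of `effect_map`) contributes
#' `cells_per_variant` cells whose fluorescence is log-normal around the
#' variant's true value. Cells are sorted into 5 log-spaced bins spanning
#' the population; each cell yields `reads_per_cell` reads of its variant
#' sequence, emitted as 150-nt reads with constant adaptor flanks so that
#' bases 23--128 recover the variable segment.
#'
#' @param effect_map Tibble with columns `position`, `base`, `fluor` (true
#'   mean fluorescence, a.u.) for single-substitution variants of the
#'   reference.
#' @param reference Wild-type segment, default [example_reference()].
#' @param wt_fluor True wild-type fluorescence.
#' @param cells_per_variant Cells drawn per variant.
#' @param reads_per_cell Mean sequencing reads per sorted cell.
#' @param sdlog Log-normal spread of single-cell fluorescence.
#' @param seed Integer seed.
#' @param dir If non-`NULL`, additionally write one FASTQ per bin
#'   (`bin_-2.fastq` ... `bin_2.fastq`) and `bins.csv` into this directory.
#' @return List with `reads` (tibble `bin`, `read`), `bins` (tibble `bin`,
#'   `c_k`, `I_k`, `N_k`), and `truth` (the effect map with the wild type).
#' @export
sim_sortseq_library <- function(effect_map, reference = example_reference(),
                                wt_fluor = 100, cells_per_variant = 500,
                                reads_per_cell = 2, sdlog = 0.35, seed = 1,
                                dir = NULL) {
  stopifnot(all(c("position", "base", "fluor") %in% names(effect_map)))
  set.seed(seed)
  ref <- strsplit(reference, "")[[1]]
  bad <- ref[effect_map$position] == effect_map$base
  if (any(bad)) stop("effect_map contains wild-type bases", call. = FALSE)

  variants <- dplyr::bind_rows(
    tibble::tibble(position = NA_integer_, base = NA_character_,
                   fluor = wt_fluor, segment = reference),
    dplyr::mutate(effect_map, segment = purrr::map2_chr(
      .data$position, .data$base,
      function(i, b) { s <- ref; s[i] <- b; paste(s, collapse = "") }
    ))
  )

  cells <- variants |>
    dplyr::mutate(variant = dplyr::row_number()) |>
    tidyr::uncount(cells_per_variant) |>
    dplyr::mutate(cell_fluor = stats::rlnorm(dplyr::n(),
                                             meanlog = log(.data$fluor),
                                             sdlog = sdlog))
  edges <- exp(seq(log(min(cells$cell_fluor)) - 1e-9,
                   log(max(cells$cell_fluor)) + 1e-9, length.out = 6))
  cells$bin <- as.integer(cut(cells$cell_fluor, breaks = edges,
                              include.lowest = TRUE)) - 3L

  bins <- cells |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(c_k = dplyr::n() / nrow(cells),
                     I_k = stats::median(.data$cell_fluor), .groups = "drop")

  cells$n_reads <- stats::rpois(nrow(cells), reads_per_cell)
  reads_tbl <- cells |>
    dplyr::filter(.data$n_reads > 0) |>
    tidyr::uncount(.data$n_reads) |>
    dplyr::transmute(
      bin = .data$bin,
      read = paste0(SYNTH_ADAPTOR_5, .data$segment, SYNTH_ADAPTOR_3)
    )
  nk <- reads_tbl |> dplyr::count(.data$bin, name = "N_k")
  bins <- dplyr::left_join(bins, nk, by = "bin") |>
    dplyr::mutate(N_k = dplyr::coalesce(.data$N_k, 0L))

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (b in sort(unique(reads_tbl$bin))) {
      rr <- reads_tbl$read[reads_tbl$bin == b]
      x <- Biostrings::DNAStringSet(rr)
      names(x) <- sprintf("read_%06d", seq_along(rr))
      Biostrings::writeXStringSet(
        x, filepath = file.path(dir, sprintf("bin_%d.fastq", b)),
        format = "fastq",
        qualities = Biostrings::BStringSet(rep(strrep("I", 150), length(rr)))
      )
    }
    readr::write_csv(bins, file.path(dir, "bins.csv"))
  }
  list(reads = reads_tbl, bins = bins,
       truth = dplyr::select(variants, "position", "base", "fluor"))
}

#' Simulate smFISH localization point clouds
#'
#' Places RNAs uniformly in a 1 x 1 x 2 um box per cell. Each RNA is
#' decorated by `Binomial(n_probes, p_bind)` bound probes; each bound probe
#' emits a geometric number of localizations (mean `locs_per_probe`)
#' scattered around the RNA position with Gaussian precision `sigma_xy` /
#' `sigma_z`. A fraction of the mRNAs are true complexes sharing their
#' position with an sRNA. Uniform background points emulate nonspecific
#' probe binding.
#'
#' @param cells Tibble with columns `cell_id`, `sgrs_copies`, `ptsg_copies`.
#' @param coloc_fraction Fraction of mRNAs bound in a true complex (their
#'   sRNA partner sits at the same position); consumed from `sgrs_copies`.
#' @param n_probes Named vector, probes per RNA for each channel.
#' @param p_bind Probe binding probability.
#' @param locs_per_probe Mean localizations per bound probe (geometric).
#' @param sigma_xy,sigma_z Localization scatter (nm).
#' @param background Mean background localizations per cell per channel.
#' @param box_nm Cell box dimensions (nm).
#' @param seed Integer seed.
#' @return Localization tibble (`x_nm`, `y_nm`, `z_nm`, `channel`,
#'   `cell_id`) with a `truth` attribute.
#' @export
sim_localizations <- function(cells, coloc_fraction = 0,
                              n_probes = c(sgrs = 9, ptsg = 28), p_bind = 0.6,
                              locs_per_probe = 3, sigma_xy = 6, sigma_z = 10,
                              background = 30, box_nm = c(1000, 1000, 2000),
                              seed = 1) {
  stopifnot(all(c("cell_id", "sgrs_copies", "ptsg_copies") %in% names(cells)))
  stopifnot(coloc_fraction >= 0, coloc_fraction <= 1)
  set.seed(seed)

  emit_rna <- function(pos, channel) {
    n_bound <- stats::rbinom(1, n_probes[[channel]], p_bind)
    if (n_bound == 0) return(NULL)
    n_loc <- stats::rgeom(n_bound, 1 / locs_per_probe) + 1L
    total <- sum(n_loc)
    tibble::tibble(
      x_nm = stats::rnorm(total, pos[1], sigma_xy),
      y_nm = stats::rnorm(total, pos[2], sigma_xy),
      z_nm = stats::rnorm(total, pos[3], sigma_z),
      channel = channel
    )
  }
  uniform_pos <- function(n) {
    cbind(stats::runif(n, 0, box_nm[1]), stats::runif(n, 0, box_nm[2]),
          stats::runif(n, 0, box_nm[3]))
  }

  out <- purrr::pmap_dfr(cells, function(cell_id, sgrs_copies, ptsg_copies, ...) {
    n_complex <- min(round(coloc_fraction * ptsg_copies), sgrs_copies)
    ptsg_pos <- uniform_pos(ptsg_copies)
    sgrs_free <- sgrs_copies - n_complex
    sgrs_pos <- rbind(
      if (n_complex > 0) ptsg_pos[seq_len(n_complex), , drop = FALSE] +
        matrix(stats::rnorm(3 * n_complex, 0, 5), ncol = 3) else NULL,
      uniform_pos(sgrs_free)
    )
    pts <- dplyr::bind_rows(
      purrr::map_dfr(seq_len(nrow(ptsg_pos)),
                     function(i) emit_rna(ptsg_pos[i, ], "ptsg")),
      purrr::map_dfr(seq_len(nrow(sgrs_pos)),
                     function(i) emit_rna(sgrs_pos[i, ], "sgrs")),
      purrr::map_dfr(c("ptsg", "sgrs"), function(ch) {
        nb <- stats::rpois(1, background)
        if (nb == 0) return(NULL)
        bp <- uniform_pos(nb)
        tibble::tibble(x_nm = bp[, 1], y_nm = bp[, 2], z_nm = bp[, 3],
                       channel = ch)
      })
    )
    if (is.null(pts) || !nrow(pts)) return(NULL)
    pts$cell_id <- cell_id
    pts
  })
  attr(out, "truth") <- list(
    cells = cells, coloc_fraction = coloc_fraction, n_probes = n_probes,
    p_bind = p_bind, locs_per_probe = locs_per_probe,
    sigma_xy = sigma_xy, sigma_z = sigma_z, background = background,
    box_nm = box_nm, seed = seed
  )
  out
}

#' Simulate an exponential decay series with multiplicative noise
#'
#' @param rate Decay rate (s^-1); 0 gives a constant series.
#' @param times_s Time grid in seconds (default the 0--20 min imaging grid).
#' @param value0 Initial value (copies or relative abundance).
#' @param noise_sigma Log-normal sigma of the multiplicative noise.
#' @param plateau Additive plateau (for one-phase scenarios).
#' @param seed Integer seed.
#' @return Tibble (`time_s`, `value`) with a `truth` attribute.
#' @export
sim_decay_series <- function(rate, times_s = c(0, 2, 4, 6, 8, 10, 15, 20) * 60,
                             value0 = 100, noise_sigma = 0, plateau = 0,
                             seed = 1) {
  stopifnot(rate >= 0)
  set.seed(seed)
  mu <- plateau + (value0 - plateau) * exp(-rate * times_s)
  value <- mu * stats::rlnorm(length(times_s), 0, noise_sigma)
  out <- tibble::tibble(time_s = times_s, value = value)
  attr(out, "truth") <- list(rate = rate, value0 = value0, plateau = plateau,
                             noise_sigma = noise_sigma, seed = seed)
  out
}
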