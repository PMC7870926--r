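#' Sort-Seq analysis of a FACS-binned mutant library
#'
#' A pooled library of sRNA variants (error-prone PCR mutagenesis) is sorted
#' into five log-spaced fluorescence bins of a target--GFP reporter and each
#' bin is sequenced. For each single-substitution variant, the
#' intensity-moment statistic summarizes which bins its reads concentrate
#' in, weighted by bin occupancy and depth, yielding a per-mutation estimate
#' of regulatory activity. These functions implement the read slicing,
#' exact-duplicate grouping, variant classification, intensity moments,
#' standard scores and heatmap export.
#'
#' @name sortseq
NULL

#' Bin occupancy fractions of the reference sorting experiment
#'
#' Overall fraction of sorted cells in each of the five log-spaced
#' fluorescence bins (`k = -2` dimmest to `k = 2` brightest), used as the
#' default `c_k` in tests and examples. Real analyses should always supply
#' the occupancies reported by the FACS acquisition software for their own
#' sort.
#' @format Named numeric vector of length 5 summing to 1.
#' @export
default_bin_occupancy <- c(`-2` = 0.1874, `-1` = 0.3376, `0` = 0.3091,
                           `1` = 0.1383, `2` = 0.0276)

#' Extract the variable segment from raw reads
#'
#' Slices bases 23--128 (1-based, inclusive; 106 nt) out of each read,
#' removing the constant PCR adaptor prefix. Reads shorter than 128 nt are
#' returned as `NA` and counted.
#'
#' @param reads Character vector of read sequences (DNA alphabet).
#' @param start,end 1-based inclusive slice, defaults 23 and 128.
#' @return Character vector of segments with attribute `n_discarded` giving
#'   the number of short reads dropped.
#' @export
extract_variable_region <- function(reads, start = 23L, end = 128L) {
  stopifnot(is.character(reads), start >= 1L, end >= start)
  ok <- !is.na(reads) & nchar(reads) >= end
  out <- rep(NA_character_, length(reads))
  out[ok] <- substr(reads[ok], start, end)
  structure(out, n_discarded = sum(!ok))
}

#' Group identical segments and apply the minimum read-count filter
#'
#' Exact-duplicate segments are grouped; a variant sequence is retained only
#' if its total read count across all bins reaches `min_reads` (the
#' threshold applies to the whole dataset, never per bin). Base-call
#' qualities are ignored throughout by design.
#'
#' @param segments Tibble with columns `bin` (integer in -2..2) and
#'   `segment` (equal-length strings); `NA` segments are dropped first.
#' @param min_reads Minimum total reads per variant sequence (default 10).
#' @return Tibble with columns `segment`, `bin`, `n` for retained variants.
#' @export
group_and_filter <- function(segments, min_reads = 10) {
  stopifnot(all(c("bin", "segment") %in% names(segments)))
  segments <- dplyr::filter(segments, !is.na(.data$segment))
  if (!nrow(segments)) {
    return(tibble::tibble(segment = character(), bin = integer(), n = integer()))
  }
  counts <- segments |>
    dplyr::count(.data$segment, .data$bin, name = "n")
  keep <- counts |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop") |>
    dplyr::filter(.data$total >= min_reads)
  dplyr::semi_join(counts, keep, by = "segment")
}

#' Classify a segment against the wild-type reference
#'
#' Position-wise (Hamming) comparison. A segment with exactly one mismatch
#' is a single substitution at 1-based `position` to `base`; segments of a
#' different length or containing characters outside `ACGTN` are `other`.
#'
#' @param segment Character vector of segments.
#' @param reference Single wild-type segment (same length, DNA alphabet).
#' @return Tibble with columns `segment`, `class` (`wild_type`,
#'   `single_substitution`, `multi_substitution`, `other`), `position`,
#'   `base` (`NA` unless single substitution).
#' @export
classify_variant <- function(segment, reference) {
  stopifnot(is.character(reference), length(reference) == 1L)
  ref <- strsplit(reference, "")[[1]]
  res <- lapply(segment, function(s) {
    if (is.na(s) || nchar(s) != length(ref) || grepl("[^ACGTN]", s)) {
      return(list(class = "other", position = NA_integer_, base = NA_character_))
    }
    ss <- strsplit(s, "")[[1]]
    mism <- which(ss != ref)
    if (length(mism) == 0L) {
      list(class = "wild_type", position = NA_integer_, base = NA_character_)
    } else if (length(mism) == 1L) {
      if (ss[mism] == "N") {
        list(class = "other", position = NA_integer_, base = NA_character_)
      } else {
        list(class = "single_substitution", position = mism, base = ss[mism])
      }
    } else {
      list(class = "multi_substitution", position = NA_integer_, base = NA_character_)
    }
  })
  tibble::tibble(
    segment = segment,
    class = vapply(res, `[[`, character(1), "class"),
    position = vapply(res, `[[`, integer(1), "position"),
    base = vapply(res, `[[`, character(1), "base")
  )
}

#' Intensity moment of one variant
#'
#' The depth- and occupancy-normalized mean bin fluorescence,
#' \deqn{K = \frac{\sum_k I_k c_k n_k / N_k}{\sum_k c_k n_k / N_k},}
#' a convex combination of the median bin intensities `I_k` weighted by the
#' fraction of the library's bin-`k` reads belonging to this variant
#' (`n_k/N_k`) scaled by the bin occupancy `c_k`.
#'
#' @param n Named numeric vector of per-bin read counts for the variant
#'   (names matching `bins$bin`); bins absent from `n` count as 0.
#' @param bins Tibble with columns `bin`, `c_k` (occupancy fraction), `I_k`
#'   (median intensity), `N_k` (total acceptable reads in the bin).
#' @return The intensity moment, or `NA` if every weight is zero.
#' @examples
#' bins <- tibble::tibble(bin = 1:2, c_k = c(0.5, 0.5),
#'                        I_k = c(10, 100), N_k = c(100, 100))
#' intensity_moment(c(`1` = 10, `2` = 30), bins) # 77.5
#' @export
intensity_moment <- function(n, bins) {
  stopifnot(all(c("bin", "c_k", "I_k", "N_k") %in% names(bins)))
  nn <- n[match(as.character(bins$bin), names(n))]
  nn[is.na(nn)] <- 0
  if (any(nn > 0 & bins$N_k <= 0)) {
    stop("N_k must be positive for bins holding reads", call. = FALSE)
  }
  w <- bins$c_k * nn / pmax(bins$N_k, 1)
  if (sum(w) == 0) return(NA_real_)
  sum(bins$I_k * w) / sum(w)
}

#' Intensity moments for a table of single-substitution variants
#'
#' @param variant_counts Tibble with columns `position`, `base`, `bin`, `n`
#'   (long form; one row per variant per bin with reads).
#' @param bins See [intensity_moment()].
#' @return Tibble with one row per `(position, base)`: `K`, `total_reads`,
#'   `missing`.
#' @export
intensity_moments <- function(variant_counts, bins) {
  stopifnot(all(c("position", "base", "bin", "n") %in% names(variant_counts)))
  variant_counts |>
    dplyr::group_by(.data$position, .data$base) |>
    dplyr::summarise(
      K = intensity_moment(stats::setNames(.data$n, .data$bin), bins),
      total_reads = sum(.data$n),
      .groups = "drop"
    ) |>
    dplyr::mutate(missing = is.na(.data$K)) |>
    dplyr::arrange(.data$position, .data$base)
}

#' Standard scores of intensity moments
#'
#' `z = (K - <K>)/sigma(K)` with the mean and *population* standard
#' deviation taken over all non-missing entries of the table (wild-type
#' cells are not entries; the moment is defined for mutants only). With
#' `per_position = TRUE` the normalization is computed within each
#' position instead.
#'
#' @param table Output of [intensity_moments()] (columns `K`, `missing`).
#' @param per_position Normalize per position instead of globally.
#' @return The table with a `z` column added.
#' @export
z_scores <- function(table, per_position = FALSE) {
  stopifnot("K" %in% names(table))
  ok <- !is.na(table$K)
  if (sum(ok) < 2L) stop("need at least 2 non-missing entries", call. = FALSE)
  zfun <- function(k) {
    kk <- k[!is.na(k)]
    s <- sqrt(mean((kk - mean(kk))^2))
    if (s == 0) {
      warning("zero spread among intensity moments; z set to 0")
      return(ifelse(is.na(k), NA_real_, 0))
    }
    (k - mean(kk)) / s
  }
  if (per_position) {
    dplyr::mutate(dplyr::group_by(table, .data$position), z = zfun(.data$K)) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(table, z = zfun(.data$K))
  }
}

#' Position-by-base heatmap table of mutational effects
#'
#' Expands a variant-effect table to the full grid of positions and bases in
#' RNA alphabet (reads are DNA; coordinates and bases are reported as RNA,
#' T -> U), flagging wild-type cells and missing mutants, with segment
#' positions mapped to sRNA nucleotide coordinates through an offset.
#'
#' @param table Output of [z_scores()] or [intensity_moments()].
#' @param reference Wild-type segment (DNA alphabet).
#' @param coordinate_offset Added to segment position 1..L to obtain the
#'   sRNA nucleotide number (e.g. 148 maps position 1 to nucleotide 149).
#' @param coordinates Optional integer range of sRNA coordinates to keep.
#' @return Tidy tibble with `coordinate`, `base` (A/C/G/U), `value`
#'   (z if present, else K), `wild_type`, `missing`.
#' @export
heatmap_matrix <- function(table, reference, coordinate_offset = 0,
                           coordinates = NULL) {
  ref <- strsplit(reference, "")[[1]]
  len <- length(ref)
  if (any(table$position < 1L | table$position > len)) {
    stop("variant positions fall outside the reference", call. = FALSE)
  }
  to_rna <- function(b) ifelse(b == "T", "U", b)
  value_col <- if ("z" %in% names(table)) "z" else "K"
  grid <- tidyr::expand_grid(position = seq_len(len), base = c("A", "C", "G", "U"))
  tbl <- table |>
    dplyr::mutate(base = to_rna(.data$base)) |>
    dplyr::select("position", "base", value = dplyr::all_of(value_col))
  out <- grid |>
    dplyr::left_join(tbl, by = c("position", "base")) |>
    dplyr::mutate(
      coordinate = .data$position + coordinate_offset,
      wild_type = .data$base == to_rna(ref[.data$position]),
      missing = !.data$wild_type & is.na(.data$value)
    ) |>
    dplyr::select("coordinate", "base", "value", "wild_type", "missing")
  if (!is.null(coordinates)) {
    if (!all(coordinates %in% out$coordinate)) {
      stop("requested coordinates fall outside the mapped segment", call. = FALSE)
    }
    out <- dplyr::filter(out, .data$coordinate %in% coordinates)
  }
  out
}

#' Read FACS-binned FASTQ files
#'
#' @param files Named character vector of FASTQ paths; names are the bin
#'   indices (e.g. `"-2"` .. `"2"`).
#' @return Tibble with columns `bin` (integer) and `read` (character).
#' @export
read_binned_fastq <- function(files) {
  stopifnot(!is.null(names(files)))
  purrr::map2_dfr(files, names(files), function(f, b) {
    reads <- Biostrings::readDNAStringSet(f, format = "fastq")
    tibble::tibble(bin = as.integer(b), read = as.character(reads))
  })
}

#' Full Sort-Seq pipeline: reads to variant-effect table
#'
#' Slices the variable region from every read, counts exact-duplicate
#' variant sequences, drops variants under the read threshold, classifies
#' each retained sequence against the wild-type reference, computes
#' intensity moments for the single-substitution variants and their
#' standard scores.
#'
#' @param reads Tibble with columns `bin`, `read` (see
#'   [read_binned_fastq()]), or `bin`, `segment` if already sliced.
#' @param reference Wild-type variable-region sequence (106 nt by default
#'   design; DNA alphabet).
#' @param bins Tibble with `bin`, `c_k`, `I_k` (and optionally `N_k`; when
#'   absent, `N_k` is the number of acceptable full-length reads per bin).
#' @param min_reads Variant read-count threshold, default 10.
#' @param per_position Normalization set for the z-scores.
#' @return Variant-effect tibble (`position`, `base`, `K`, `total_reads`,
#'   `missing`, `z`) with attribute `read_stats` (reads in, short reads
#'   discarded, per-bin `N_k`).
#' @export
sortseq_effects <- function(reads, reference, bins, min_reads = 10,
                            per_position = FALSE) {
  if ("read" %in% names(reads)) {
    seg <- extract_variable_region(reads$read)
    segments <- tibble::tibble(bin = reads$bin, segment = as.character(seg))
    n_short <- attr(seg, "n_discarded")
  } else {
    segments <- reads
    n_short <- 0L
  }
  segments <- dplyr::filter(segments, !is.na(.data$segment))
  if (!("N_k" %in% names(bins))) {
    nk <- segments |> dplyr::count(.data$bin, name = "N_k")
    bins <- dplyr::left_join(bins, nk, by = "bin") |>
      dplyr::mutate(N_k = dplyr::coalesce(.data$N_k, 0L))
  }
  grouped <- group_and_filter(segments, min_reads = min_reads)
  classes <- classify_variant(unique(grouped$segment), reference)
  singles <- dplyr::inner_join(
    grouped,
    dplyr::filter(classes, .data$class == "single_substitution"),
    by = "segment"
  )
  counts <- dplyr::select(singles, "position", "base", "bin", "n")
  out <- intensity_moments(counts, bins)
  out <- z_scores(out, per_position = per_position)
  attr(out, "read_stats") <- list(
    n_reads = nrow(segments) + n_short,
    n_short_discarded = n_short,
    bins = bins
  )
  out
}
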