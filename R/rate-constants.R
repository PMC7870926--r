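#' Kinetic rate constants for sRNA-mediated target degradation
#'
#' Bundles the rate constants of the mass-action model of small-RNA (sRNA)
#' regulation of a target mRNA: reversible sRNA--mRNA association
#' (`k_on`, `k_off`), RNase E-mediated co-degradation of the complex
#' (`k_cat`), transcription of target and sRNA (`alpha_p`, `alpha_S`), and
#' first-order degradation of the free species (`beta_p`, `beta_Sp`, the
#' sRNA rate excluding co-degradation with this target).
#'
#' @param k_on Bimolecular association rate constant (M^-1 s^-1).
#' @param k_off Dissociation rate constant of the complex (s^-1).
#' @param k_cat Co-degradation rate constant of the complex (s^-1).
#' @param alpha_p Target mRNA transcription rate (copies cell^-1 s^-1).
#' @param alpha_S sRNA transcription rate (copies cell^-1 s^-1).
#' @param beta_p Endogenous target mRNA degradation rate (s^-1).
#' @param beta_Sp sRNA degradation rate excluding co-degradation with this
#'   target (s^-1).
#' @return An object of class `rate_constants` (a named list).
#' @examples
#' rate_constants(k_on = 1.9e5, k_off = 0.22, k_cat = 0.3)
#' @export
rate_constants <- function(k_on = 0, k_off = 0, k_cat = 0,
                           alpha_p = 0, alpha_S = 0,
                           beta_p = 0, beta_Sp = 0) {
  x <- list(k_on = k_on, k_off = k_off, k_cat = k_cat,
            alpha_p = alpha_p, alpha_S = alpha_S,
            beta_p = beta_p, beta_Sp = beta_Sp)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("`", nm, "` must be a single finite non-negative number", call. = FALSE)
    }
  }
  structure(x, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("<rate_constants>\n")
  cat(sprintf("  k_on    %.4g M^-1 s^-1\n", x$k_on))
  cat(sprintf("  k_off   %.4g s^-1\n", x$k_off))
  cat(sprintf("  k_cat   %.4g s^-1\n", x$k_cat))
  cat(sprintf("  alpha_p %.4g copies/s   alpha_S %.4g copies/s\n",
              x$alpha_p, x$alpha_S))
  cat(sprintf("  beta_p  %.4g s^-1       beta_Sp %.4g s^-1\n",
              x$beta_p, x$beta_Sp))
  invisible(x)
}

#' Cell geometry used to convert copy numbers to concentrations
#'
#' @param volume Cell volume in cubic micrometres. The default 0.7 is a
#'   typical *E. coli* volume under the growth conditions modelled here.
#' @param p0 Pre-stress steady-state target mRNA copy number per cell.
#' @return An object of class `cell_model`.
#' @export
cell_model <- function(volume = 0.7, p0 = 0) {
  stopifnot(is.numeric(volume), length(volume) == 1L, is.finite(volume))
  if (volume <= 0) stop("`volume` must be positive", call. = FALSE)
  stopifnot(is.numeric(p0), length(p0) == 1L, is.finite(p0), p0 >= 0)
  structure(list(volume = volume, p0 = p0), class = "cell_model")
}

# Avogadro constant (exact, SI 2019)
AVOGADRO <- 6.02214076e23

#' Convert copies per cell to molar concentration
#'
#' @param copies Copy number per cell (non-negative).
#' @param volume Cell volume in cubic micrometres (default 0.7).
#' @return Concentration in mol/L.
#' @examples
#' copies_to_molar(200, 0.7) # ~4.7e-7 M, i.e. ~0.5 uM
#' @export
copies_to_molar <- function(copies, volume = 0.7) {
  stopifnot(is.numeric(copies), all(copies >= 0))
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0) {
    stop("`volume` must be a single positive number", call. = FALSE)
  }
  copies / (AVOGADRO * volume * 1e-15)
}

#' @rdname copies_to_molar
#' @param molar Concentration in mol/L.
#' @export
molar_to_copies <- function(molar, volume = 0.7) {
  stopifnot(is.numeric(molar), all(molar >= 0))
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0) {
    stop("`volume` must be a single positive number", call. = FALSE)
  }
  molar * AVOGADRO * volume * 1e-15
}

#' Steady-state transcription rate from degradation rate and copy number
#'
#' Before stress induction the target mRNA is at steady state, so its
#' transcription rate equals the degradation rate times the steady-state
#' copy number: `alpha_p = beta_p * p0`.
#'
#' @param beta_p Degradation rate (s^-1).
#' @param p0 Steady-state copy number per cell.
#' @return Transcription rate in copies cell^-1 s^-1.
#' @export
steady_state_transcription <- function(beta_p, p0) {
  stopifnot(is.numeric(beta_p), is.numeric(p0))
  if (any(beta_p < 0) || any(p0 < 0)) {
    stop("`beta_p` and `p0` must be non-negative", call. = FALSE)
  }
  beta_p * p0
}

#' Equilibrium dissociation constant
#'
#' `K_D = k_off / k_on`, in molar units when `k_on` is in M^-1 s^-1.
#'
#' @param params A [rate_constants()] object (or anything with `k_on`,
#'   `k_off` fields).
#' @return Dissociation constant in M.
#' @examples
#' dissociation_constant(rate_constants(k_on = 1.9e5, k_off = 0.22)) # 1.16e-6
#' @export
dissociation_constant <- function(params) {
  if (!is.numeric(params$k_on) || params$k_on <= 0) {
    stop("K_D is undefined when k_on is zero", call. = FALSE)
  }
  params$k_off / params$k_on
}

#' Target search and destruction statistics
#'
#' Computes, from the fitted rate constants and an sRNA concentration, the
#' mean number of binding events before co-degradation
#' `(k_off + k_cat)/k_cat`, the mean time to find the target
#' `1/(k_on * [S])`, and the expected overall destruction time (binding
#' events times search time; the residence times between events are short
#' relative to the search and are not added).
#'
#' @param params A [rate_constants()] object.
#' @param s_conc Free sRNA concentration in M.
#' @return A tibble with columns `mean_binding_events`, `search_time_s`,
#'   `destruction_time_s`.
#' @examples
#' search_metrics(rate_constants(k_on = 1.9e5, k_off = 0.22, k_cat = 0.3),
#'                s_conc = 0.48e-6)
#' @export
search_metrics <- function(params, s_conc) {
  if (params$k_cat <= 0) {
    stop("mean binding events diverge when k_cat is zero", call. = FALSE)
  }
  if (params$k_on <= 0) stop("k_on must be positive", call. = FALSE)
  stopifnot(is.numeric(s_conc), length(s_conc) == 1L, s_conc > 0)
  events <- (params$k_off + params$k_cat) / params$k_cat
  search <- 1 / (params$k_on * s_conc)
  tibble::tibble(
    mean_binding_events = events,
    search_time_s = search,
    destruction_time_s = events * search
  )
}
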