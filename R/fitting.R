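#' Poisson-weighted coefficient of determination
#'
#' Computes `R^2 = 1 - SS_res/SS_tot` for count-like data. Under
#' `weighting = "poisson"` both sums of squares are weighted by `1/f_i`
#' (variance approximately equal to the mean for counting noise):
#' `SS_res = sum((y_i - f_i)^2 / f_i)` and
#' `SS_tot = sum((y_i - ybar)^2 / f_i)`. With `weighting = "unweighted"`
#' the ordinary sums of squares are used.
#'
#' When `group` is supplied, `ybar` is computed within each group (e.g. per
#' species per strain background) and the sums are pooled, so that no single
#' species dominates the total variance.
#'
#' @param observed Numeric vector of observed values `y_i`.
#' @param fitted Numeric vector of fitted values `f_i`; must be positive
#'   (values below `eps` are floored at `eps`).
#' @param weighting `"poisson"` (default) or `"unweighted"`.
#' @param group Optional grouping vector (same length) for the per-group
#'   mean in `SS_tot`.
#' @param eps Floor applied to `f_i` in the weights, default `1e-6` copies.
#' @return A single numeric value, at most 1.
#' @examples
#' poisson_weighted_r2(c(10, 20, 30), c(12, 18, 33)) # 0.9271
#' @export
poisson_weighted_r2 <- function(observed, fitted,
                                weighting = c("poisson", "unweighted"),
                                group = NULL, eps = 1e-6) {
  weighting <- match.arg(weighting)
  stopifnot(is.numeric(observed), is.numeric(fitted))
  if (length(observed) != length(fitted)) {
    stop("`observed` and `fitted` must have equal length", call. = FALSE)
  }
  if (length(observed) < 2L) stop("need at least 2 points", call. = FALSE)
  if (any(fitted <= 0)) {
    if (any(fitted < 0)) stop("fitted values must be positive", call. = FALSE)
    fitted <- pmax(fitted, eps)
  }
  w <- if (weighting == "poisson") 1 / pmax(fitted, eps) else rep(1, length(fitted))
  if (is.null(group)) group <- rep(1L, length(observed))
  ybar <- stats::ave(observed, group)
  ss_res <- sum(w * (observed - fitted)^2)
  ss_tot <- sum(w * (observed - ybar)^2)
  if (ss_tot == 0) stop("total sum of squares is zero; R^2 undefined", call. = FALSE)
  1 - ss_res / ss_tot
}

#' Poisson chi-squared goodness of fit
#'
#' `chi^2 = sum((y_i - f_i)^2 / f_i)`, with a significance level from the
#' chi-squared distribution at `dof = n - n_free`. Used in place of `R^2`
#' for species whose copy numbers sit near background, where the total
#' variance is too small for `R^2` to be informative.
#'
#' @param observed,fitted Numeric vectors of equal length; `fitted` must be
#'   positive.
#' @param n_free Number of free parameters consumed by the fit (default 0).
#' @return A tibble with columns `chi2`, `dof`, `significance`.
#' @examples
#' chi_squared_gof(c(4, 9), c(5, 8)) # chi2 = 0.325
#' @export
chi_squared_gof <- function(observed, fitted, n_free = 0) {
  stopifnot(is.numeric(observed), is.numeric(fitted))
  if (length(observed) != length(fitted)) {
    stop("`observed` and `fitted` must have equal length", call. = FALSE)
  }
  if (any(fitted <= 0)) stop("fitted values must be positive", call. = FALSE)
  chi2 <- sum((observed - fitted)^2 / fitted)
  dof <- length(observed) - n_free
  if (dof <= 0) {
    warning("non-positive degrees of freedom; significance omitted")
    sig <- NA_real_
    dof <- NA_integer_
  } else {
    sig <- stats::pchisq(chi2, df = dof, lower.tail = FALSE)
  }
  tibble::tibble(chi2 = chi2, dof = dof, significance = sig)
}

#' Specification of a global kinetic fit
#'
#' Collects the measured (fixed) parameters, the free parameters with their
#' box bounds, and the optimizer settings for [fit_kinetics()].
#'
#' The default free set is `alpha_S`, `beta_Sp`, `k_on`, `k_off`, and a
#' co-degradation rate per strain background (`k_cat_wt`, `k_cat_mut`);
#' set `shared_kcat = TRUE` for a strict five-parameter fit with a single
#' `k_cat`. `beta_Sp` is bounded by the two measured sRNA degradation
#' rates: `beta_S0` (RNase E-independent, lower bound) and `beta_S_total`
#' (including co-degradation, upper bound).
#'
#' @param alpha_p Target transcription rate (copies/s), a single value or a
#'   named vector with entries `wt_rnase_e` and `rnase_e_mutant`.
#' @param beta_p Target degradation rate (s^-1), scalar or named as above.
#' @param beta_S0,beta_S_total Lower/upper bounds for `beta_Sp` (s^-1).
#' @param bounds Named list of `c(lower, upper)` overrides for free
#'   parameters (`k_on` in M^-1 s^-1, others s^-1 or copies/s).
#' @param shared_kcat Logical; share one `k_cat` across backgrounds.
#' @param pin Optional named vector pinning `k_on` and/or `k_off` at fixed
#'   values (used for the constrained robustness comparison).
#' @param n_starts Number of multi-start points (log-uniform over bounds).
#' @param seed Integer seed controlling the multi-start draw.
#' @param weighting Passed to [poisson_weighted_r2()].
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(alpha_p, beta_p, beta_S0 = 1e-5, beta_S_total = 0.1,
                     bounds = list(), shared_kcat = FALSE, pin = NULL,
                     n_starts = 20, seed = 1,
                     weighting = c("poisson", "unweighted")) {
  weighting <- match.arg(weighting)
  if (beta_S0 < 0 || beta_S_total < beta_S0) {
    stop("need 0 <= beta_S0 <= beta_S_total", call. = FALSE)
  }
  per_bg <- function(x, nm) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- c(wt_rnase_e = unname(x), rnase_e_mutant = unname(x))
    }
    if (!all(c("wt_rnase_e", "rnase_e_mutant") %in% names(x))) {
      stop("`", nm, "` must be a scalar or named for both backgrounds", call. = FALSE)
    }
    x[c("wt_rnase_e", "rnase_e_mutant")]
  }
  default_bounds <- list(
    alpha_S = c(1e-3, 10),
    beta_Sp = c(max(beta_S0, 1e-6), beta_S_total),
    k_on = c(1e3, 1e7),
    k_off = c(1e-3, 10),
    k_cat_wt = c(1e-4, 10),
    k_cat_mut = c(1e-4, 10),
    k_cat = c(1e-4, 10)
  )
  for (nm in names(bounds)) default_bounds[[nm]] <- bounds[[nm]]
  free <- if (shared_kcat) {
    c("alpha_S", "beta_Sp", "k_on", "k_off", "k_cat")
  } else {
    c("alpha_S", "beta_Sp", "k_on", "k_off", "k_cat_wt", "k_cat_mut")
  }
  if (!is.null(pin)) {
    bad <- setdiff(names(pin), c("k_on", "k_off"))
    if (length(bad)) stop("`pin` supports only k_on and k_off", call. = FALSE)
    free <- setdiff(free, names(pin))
  }
  structure(list(
    alpha_p = per_bg(alpha_p, "alpha_p"),
    beta_p = per_bg(beta_p, "beta_p"),
    beta_S0 = beta_S0, beta_S_total = beta_S_total,
    free = free, bounds = default_bounds[free],
    shared_kcat = shared_kcat, pin = pin,
    n_starts = n_starts, seed = seed, weighting = weighting
  ), class = "fit_spec")
}

# Assemble per-background rate_constants from a named free-parameter vector.
spec_params <- function(spec, theta) {
  full <- c(as.list(theta), as.list(spec$pin))
  kcat <- function(bg) {
    if (spec$shared_kcat) full$k_cat
    else if (bg == "wt_rnase_e") full$k_cat_wt else full$k_cat_mut
  }
  lapply(stats::setNames(nm = c("wt_rnase_e", "rnase_e_mutant")), function(bg) {
    rate_constants(
      k_on = full$k_on, k_off = full$k_off, k_cat = kcat(bg),
      alpha_p = spec$alpha_p[[bg]], alpha_S = full$alpha_S,
      beta_p = spec$beta_p[[bg]], beta_Sp = full$beta_Sp
    )
  })
}

# Predicted copies for every (background, time_s, species) row of `data`.
predict_curves <- function(spec, theta, data, cell, state0) {
  par_bg <- spec_params(spec, theta)
  out <- lapply(names(par_bg), function(bg) {
    d <- data[data$background == bg, ]
    if (!nrow(d)) return(NULL)
    times <- sort(unique(d$time_s))
    sim <- simulate_kinetics(par_bg[[bg]], state0[[bg]], times, cell)
    key <- paste(sim$time_s, sim$species)
    d$fitted <- sim$copies[match(paste(d$time_s, d$species), key)]
    d
  })
  dplyr::bind_rows(out)
}

#' Globally fit the kinetic model to multi-species time courses
#'
#' Fits the mass-action model simultaneously to the six time courses (three
#' species in two strain backgrounds: wild-type RNase E and a co-degradation
#' deficient RNase E mutant) by maximizing the Poisson-weighted global
#' `R^2` pooled over all points. The group mean entering `SS_tot` is taken
#' per species per background so no species biases the objective.
#'
#' Optimization is multi-start Nelder--Mead in log10 parameter space inside
#' the box bounds, with the best starts refined by bounded quasi-Newton
#' (L-BFGS-B) on the same objective. Deterministic given `spec$seed`.
#'
#' Initial conditions per background: the target starts at its pre-stress
#' steady state `alpha_p/beta_p`; free sRNA and complex start at the
#' measured `t = 0` means.
#'
#' @param data Tidy time-course tibble with columns `background`
#'   (`"wt_rnase_e"` / `"rnase_e_mutant"`), `time_s`, `species`
#'   (`"p"`, `"S"`, `"Sp"`), `mean_copies`, and optionally `sem`, `n_cells`.
#' @param spec A [fit_spec()].
#' @param cell A [cell_model()] for the `k_on` unit conversion.
#' @param refine_n How many of the best simplex starts to refine.
#' @return An object of class `srna_fit` with fitted parameters, global
#'   `R^2`, per-curve chi-squared diagnostics, and the residual table. Use
#'   [tidy.srna_fit()], [glance.srna_fit()], [autoplot.srna_fit()].
#' @export
fit_kinetics <- function(data, spec, cell = cell_model(), refine_n = 3) {
  stopifnot(inherits(spec, "fit_spec"))
  need <- c("background", "time_s", "species", "mean_copies")
  if (!all(need %in% names(data))) {
    stop("`data` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  bgs <- c("wt_rnase_e", "rnase_e_mutant")
  if (!setequal(unique(data$background), bgs)) {
    stop("`data` must cover both strain backgrounds", call. = FALSE)
  }
  if (!setequal(unique(data$species), c("p", "S", "Sp"))) {
    stop("`data` must cover species p, S and Sp", call. = FALSE)
  }
  data <- dplyr::arrange(data, .data$background, .data$species, .data$time_s)

  state0 <- lapply(stats::setNames(nm = bgs), function(bg) {
    d0 <- data[data$background == bg & data$time_s == min(data$time_s), ]
    c(p = spec$alpha_p[[bg]] / spec$beta_p[[bg]],
      S = d0$mean_copies[d0$species == "S"][1],
      Sp = d0$mean_copies[d0$species == "Sp"][1])
  })

  lo <- log10(vapply(spec$bounds, `[`, numeric(1), 1L))
  hi <- log10(vapply(spec$bounds, `[`, numeric(1), 2L))
  grp <- paste(data$background, data$species)

  # Precomputed flat structures for the optimizer hot path: per background,
  # the output time grid and the flat index of each data row into the
  # integrator's time-by-species matrix.
  kon_scale <- 1 / (AVOGADRO * cell$volume * 1e-15)
  spi <- c(p = 1L, S = 2L, Sp = 3L)
  hot <- lapply(stats::setNames(nm = bgs), function(bg) {
    d <- data[data$background == bg, ]
    times <- sort(unique(d$time_s))
    list(times = times,
         idx = cbind(match(d$time_s, times), spi[d$species]),
         y = d$mean_copies)
  })
  y_all <- c(hot[[1]]$y, hot[[2]]$y)
  grp_all <- c(grp[data$background == bgs[1]], grp[data$background == bgs[2]])
  ybar_all <- stats::ave(y_all, grp_all)
  w_unit <- spec$weighting == "unweighted"

  free_idx <- stats::setNames(seq_along(spec$free), spec$free)
  pinned <- as.list(spec$pin)
  pick <- function(theta, nm, default = NULL) {
    if (nm %in% names(free_idx)) theta[[free_idx[[nm]]]]
    else if (nm %in% names(pinned)) pinned[[nm]]
    else default
  }
  par_vec_bg <- function(theta, bg) {
    kcat <- if (spec$shared_kcat) pick(theta, "k_cat") else {
      pick(theta, if (bg == "wt_rnase_e") "k_cat_wt" else "k_cat_mut")
    }
    c(spec$alpha_p[[bg]], spec$beta_p[[bg]], pick(theta, "alpha_S"),
      pick(theta, "beta_Sp"), pick(theta, "k_on") * kon_scale,
      pick(theta, "k_off"), kcat)
  }

  objective <- function(lt) {
    # penalized outside the box so the simplex stays honest
    pen <- sum(pmax(0, lo - lt)^2) + sum(pmax(0, lt - hi)^2)
    lt <- pmin(pmax(lt, lo), hi)
    theta <- 10^lt
    f_all <- tryCatch({
      unlist(lapply(bgs, function(bg) {
        h <- hot[[bg]]
        m <- kinetics_dopri(par_vec_bg(theta, bg), unname(state0[[bg]]),
                            h$times, rtol = 1e-8, atol = 1e-10)
        m[h$idx]
      }), use.names = FALSE)
    }, error = function(e) NULL)
    if (is.null(f_all) || anyNA(f_all)) return(1e6)
    f_all <- pmax(f_all, 1e-6)
    w <- if (w_unit) 1 else 1 / f_all
    ss_tot <- sum(w * (y_all - ybar_all)^2)
    if (ss_tot <= 0) return(1e6)
    r2 <- 1 - sum(w * (y_all - f_all)^2) / ss_tot
    if (!is.finite(r2)) return(1e6)
    -r2 + 1e3 * pen
  }

  set.seed(spec$seed)
  starts <- replicate(spec$n_starts, stats::runif(length(lo), lo, hi),
                      simplify = FALSE)
  starts <- c(list((lo + hi) / 2), starts)

  stage1 <- lapply(starts, function(s) {
    stats::optim(s, objective, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-10))
  })
  ord <- order(vapply(stage1, `[[`, numeric(1), "value"))
  refined <- lapply(stage1[ord[seq_len(min(refine_n, length(ord)))]], function(fit) {
    nm <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                       control = list(maxit = 1500, reltol = 1e-14))
    lb <- tryCatch(
      stats::optim(pmin(pmax(nm$par, lo), hi), objective, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 200, factr = 100)),
      error = function(e) nm
    )
    if (lb$value <= nm$value) lb else nm
  })
  best <- refined[[which.min(vapply(refined, `[[`, numeric(1), "value"))]]

  lt <- pmin(pmax(best$par, lo), hi)
  theta <- stats::setNames(10^lt, spec$free)
  at_bound <- stats::setNames(lt <= lo + 1e-10 | lt >= hi - 1e-10, spec$free)
  if (any(at_bound)) {
    warning("parameter(s) at bound: ",
            paste(spec$free[at_bound], collapse = ", "))
  }

  pred <- predict_curves(spec, theta, data, cell, state0)
  r2 <- poisson_weighted_r2(pred$mean_copies, pred$fitted,
                            weighting = spec$weighting, group = grp)
  n_free <- length(spec$free)
  chi2_tbl <- pred |>
    dplyr::group_by(.data$background, .data$species) |>
    dplyr::reframe(chi_squared_gof(.data$mean_copies, pmax(.data$fitted, 1e-6)))

  structure(list(
    estimates = theta,
    params = spec_params(spec, theta),
    global_r2 = r2,
    chi2 = chi2_tbl,
    residuals = dplyr::mutate(pred, residual = .data$mean_copies - .data$fitted),
    spec = spec,
    cell = cell,
    state0 = state0,
    convergence = list(
      objective = -best$value, n_starts = spec$n_starts,
      start_values = -vapply(stage1, `[[`, numeric(1), "value"),
      at_bound = at_bound
    )
  ), class = "srna_fit")
}

#' @export
print.srna_fit <- function(x, ...) {
  cat("<srna_fit> global Poisson-weighted R^2 =", format(x$global_r2, digits = 5), "\n")
  cat("free parameters:\n")
  print(tibble::enframe(x$estimates, name = "parameter", value = "estimate"))
  invisible(x)
}

#' Tidy the free-parameter estimates of a kinetic fit
#'
#' @param x An `srna_fit` from [fit_kinetics()].
#' @param ... Unused.
#' @return A tibble with `parameter`, `estimate`, `at_bound`.
#' @export
tidy.srna_fit <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$estimates),
    estimate = unname(x$estimates),
    at_bound = unname(x$convergence$at_bound)
  )
}

#' One-row summary of a kinetic fit
#'
#' @inheritParams tidy.srna_fit
#' @return A tibble with `global_r2`, `n_free`, `n_points`, `n_starts`.
#' @export
glance.srna_fit <- function(x, ...) {
  tibble::tibble(
    global_r2 = x$global_r2,
    n_free = length(x$estimates),
    n_points = nrow(x$residuals),
    n_starts = x$convergence$n_starts
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
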