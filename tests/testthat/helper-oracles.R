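# Independent oracles used by the tests. These deliberately share no code
# with the package implementations they check.

# Fixed-step classical RK4 integration of the three-species mass-action
# system. `kon_cell` is in (copies/cell)^-1 s^-1.
rk4_oracle <- function(par, y0, times, dt = 0.01) {
  # par: list(alpha_p, beta_p, alpha_S, beta_Sp, kon_cell, k_off, k_cat)
  f <- function(y) {
    bind <- par$kon_cell * y[2] * y[1]
    unbind <- par$k_off * y[3]
    c(par$alpha_p - par$beta_p * y[1] - bind + unbind,
      par$alpha_S - par$beta_Sp * y[2] - bind + unbind,
      bind - unbind - par$k_cat * y[3])
  }
  out <- matrix(NA_real_, nrow = length(times), ncol = 3)
  y <- y0
  out[1, ] <- y
  for (i in seq_along(times)[-1]) {
    span <- times[i] - times[i - 1]
    nstep <- max(1L, round(span / dt))
    h <- span / nstep
    for (s in seq_len(nstep)) {
      k1 <- f(y)
      k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i, ] <- y
  }
  out
}

# Exhaustive O(n^2) DBSCAN with the same conventions as the package
# implementation (self counts toward MinPts; points visited in index order;
# border points go to the first-discovered cluster). Written from the
# textbook pseudocode against a full distance matrix.
dbscan_brute <- function(m, eps, minpts) {
  n <- nrow(m)
  labels <- integer(n)
  if (n == 0) return(labels)
  D <- as.matrix(stats::dist(m))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    if (length(nb[[i]]) < minpts) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) labels[j] <- cl
      if (!visited[j]) {
        visited[j] <- TRUE
        if (length(nb[[j]]) >= minpts) queue <- c(queue, nb[[j]])
      }
    }
  }
  labels
}

# Random non-negative rate constants spanning realistic scales, for
# property-style loops.
random_rate_constants <- function() {
  rate_constants(
    k_on = 10^stats::runif(1, 4, 6),
    k_off = 10^stats::runif(1, -2, 0),
    k_cat = 10^stats::runif(1, -2, 0),
    alpha_p = stats::runif(1, 0.1, 1),
    alpha_S = stats::runif(1, 0.1, 1),
    beta_p = 10^stats::runif(1, -3, -2),
    beta_Sp = 10^stats::runif(1, -4, -3)
  )
}

# Study-condition fit specification shared by the fitting tests.
default_fit_spec <- function(truth = default_true_params(), ...) {
  fit_spec(alpha_p = truth$alpha_p, beta_p = truth$beta_p,
           beta_S0 = 1e-4, beta_S_total = 0.0016, ...)
}
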