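# Independent oracles used across the suite. These deliberately avoid the
# package's own analytic/optimize code paths: derivatives are checked by
# finite differences, extrema and phenological dates by dense-grid brute
# force, SMA by raw moment formulas, and p-values by permutation.

# central finite differences of the curve itself
num_rate <- function(family, params, t, h = 1e-4) {
  (grow_eval(family, params, t + h) - grow_eval(family, params, t - h)) / (2 * h)
}
num_accel <- function(family, params, t, h = 1e-3) {
  (grow_eval(family, params, t + h) - 2 * grow_eval(family, params, t) +
     grow_eval(family, params, t - h)) / h^2
}

# random valid parameter draws spanning realistic seasonal shapes
rand_params <- function(family) {
  switch(family,
    logistic = c(A1 = 0, A2 = runif(1, 50, 300), x0 = runif(1, 90, 130),
                 p = runif(1, 4, 12)),
    bihill = c(Pm = runif(1, 100, 300), Ka = runif(1, 120, 160),
               Ha = runif(1, 3, 8), Ki = runif(1, 250, 400),
               Hi = runif(1, 4, 10)),
    bidoseresp = {
      L1 <- runif(1, 140, 180)
      c(A1 = 0, A2 = runif(1, 100, 250), L1 = L1,
        L2 = L1 + runif(1, 60, 120), h1 = runif(1, 0.02, 0.08),
        h2 = runif(1, 0.04, 0.12), P = runif(1, 0.4, 0.75))
    })
}

# dense-grid brute-force phenology: same definitions as extract_phenology,
# but everything read straight off a fine grid (no optimize/uniroot)
brute_phenology <- function(family, params, window, step = 0.001,
                            theta_o = 0.05, theta_t = 0.95) {
  g <- seq(window[1], window[2], by = step)
  yv <- grow_eval(family, params, g)
  rv <- grow_rate(family, params, g)
  av <- grow_accel(family, params, g)
  W_max <- max(yv)
  s <- sign(diff(rv))
  turn <- which(s[-1] * s[-length(s)] < 0) + 1
  peaks <- turn[s[turn - 1] > 0]
  stopifnot(length(peaks) >= 1)
  D_vmax <- g[peaks[1]]
  split_i <- if (length(peaks) >= 2) {
    seg <- seq(peaks[1], peaks[2])
    peaks[1] + which.min(rv[seg]) - 1
  } else length(g)
  D_o <- g[which(yv >= theta_o * W_max)[1]]
  D_t <- g[which(yv >= theta_t * W_max)[1]]
  D_r <- g[which.max(av[seq_len(peaks[1])])]
  seg1 <- seq(peaks[1], split_i)
  D_st <- g[seg1[which.min(av[seg1])]]
  out <- list(W_max = W_max, V_max = rv[peaks[1]], D_o = D_o, D_r = D_r,
              D_vmax = D_vmax, D_st = D_st, D_t = D_t,
              bimodal = length(peaks) >= 2)
  if (out$bimodal) {
    out$D_vmax2 <- g[peaks[2]]
    out$V_max2 <- rv[peaks[2]]
    seg2a <- seq(split_i, peaks[2])
    out$D_r2 <- g[seg2a[which.max(av[seg2a])]]
    seg2b <- seq(peaks[2], length(g))
    out$D_st2 <- g[seg2b[which.min(av[seg2b])]]
  }
  out
}

# SMA slope/intercept from raw moments (no sd/cor shortcuts)
moment_sma <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sign(sxy) * sqrt(syy / sxx)
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r2 = sxy^2 / (sxx * syy))
}

# permutation p-value for the association between u = y - Bx and v = y + Bx
perm_slope_p <- function(x, y, B, n_perm = 10000) {
  u <- y - B * x; v <- y + B * x
  r_obs <- abs(cor(u, v))
  hits <- 0L
  for (i in seq_len(n_perm))
    if (abs(cor(u, sample(v))) >= r_obs - 1e-12) hits <- hits + 1L
  hits / n_perm
}

# natural cubic spline via the textbook tridiagonal second-derivative solve
natural_spline_eval <- function(xk, yk, xout) {
  n <- length(xk)
  h <- diff(xk)
  rhs <- 6 * diff(diff(yk) / h)
  A <- matrix(0, n - 2, n - 2)
  for (i in seq_len(n - 2)) {
    A[i, i] <- 2 * (h[i] + h[i + 1])
    if (i > 1) A[i, i - 1] <- h[i]
    if (i < n - 2) A[i, i + 1] <- h[i + 1]
  }
  M <- c(0, solve(A, rhs), 0)  # second derivatives, natural BC
  vapply(xout, function(x) {
    j <- max(1, min(findInterval(x, xk), n - 1))
    d <- x - xk[j]
    yk[j] + d * ((yk[j + 1] - yk[j]) / h[j] - h[j] * (2 * M[j] + M[j + 1]) / 6) +
      d^2 * M[j] / 2 + d^3 * (M[j + 1] - M[j]) / (6 * h[j])
  }, numeric(1))
}

# simulate one noisy series from a family on a survey grid
sim_series <- function(family, params, doys, sigma, trait = "plant_height") {
  y <- grow_eval(family, params, doys)
  if (sigma > 0) y <- pmax(y + rnorm(length(doys), 0, sigma), 0)
  trait_series("sim", 1, trait, "asexual", doys, y)
}

doys_aboveground <- function() survey_schedule("2021-03-25", "2021-11-05", 5)
doys_rhizome <- function() survey_schedule("2021-02-25", "2021-12-15", 10)
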